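# Scenario-expanded two-stage model. Facility open decisions are first
# stage (shared across scenarios); flows, inventory and shortage are
# recourse, replicated per scenario with that scenario's demand, capacity
# and temporary-setup-cost multipliers applied. The default objective is
# expected cost plus a per-unit penalty on expected shortage; a min-max
# (worst-case) variant optimizes the worst scenario instead.

#' Solve the two-stage scenario model
#'
#' Minimizes `sum_s p_s * cost_s + penalty * sum_s p_s * shortage_s` over
#' shared first-stage open decisions and per-scenario recourse flows, where
#' `cost_s` is the scenario's setup + transport + testing cost (temporary
#' setup costs scaled by the scenario's multiplier) and `shortage_s` its
#' total unmet transfusion demand in units. Every scenario's constraint
#' block, including the per-scenario service level, must hold.
#'
#' @param inst a `bsc_instance` with one or more scenarios.
#' @param penalty currency per unit of expected shortage.
#' @param opts a [solve_options()] object.
#' @return a `bsc_scenario_solution`: first-stage opens, per-scenario
#'   recourse solutions with cost breakdowns, `expected_cost` (excluding the
#'   penalty term), `expected_shortage_units`, `worst_case_shortage`, and
#'   solver metadata. On infeasibility, `solver_status` is `"infeasible"`
#'   and `infeasible_hint` names the offending scenario-periods.
#' @export
solve_two_stage <- function(inst, penalty = 0, opts = solve_options()) {
  diags <- validate_instance(inst)
  if (length(diags) > 0)
    stop("invalid instance:\n  ", paste(diags, collapse = "\n  "))
  stopifnot(penalty >= 0)
  mod <- bsc_build(inst, formulation = opts$formulation)
  objvec <- mod$cost_vec + penalty * mod$short_units_vec
  res <- milp_solve(objvec, mod$A, mod$dir, mod$rhs, mod$binary_idx,
                    mod$ub_rows, mod$lb_rows, mip_gap = opts$mip_gap,
                    time_limit = opts$time_limit)
  scenario_solution(inst, mod, res, penalty, opts, worst_case = FALSE)
}

#' Solve the worst-case (min-max) scenario model
#'
#' Minimizes `max_s (cost_s + penalty * shortage_s)` over shared first-stage
#' decisions: a robust counterpart over the discrete scenario set, with no
#' probability weighting.
#'
#' @inheritParams solve_two_stage
#' @return a `bsc_scenario_solution` with the additional field
#'   `objective_worst_case`.
#' @export
solve_worst_case <- function(inst, penalty = 0, opts = solve_options()) {
  diags <- validate_instance(inst)
  if (length(diags) > 0)
    stop("invalid instance:\n  ", paste(diags, collapse = "\n  "))
  stopifnot(penalty >= 0)
  mod <- bsc_build(inst, formulation = opts$formulation)
  nS <- mod$dims$nS
  eta <- mod$ncol + 1L
  A <- cbind(mod$A, 0)
  dir <- mod$dir; rhs <- mod$rhs
  for (s in seq_len(nS)) {
    v <- c(mod$setup_vec_s(s) + mod$tv_s[[s]] + penalty * mod$sh_s[[s]], -1)
    A <- rbind(A, v); dir <- c(dir, "<="); rhs <- c(rhs, 0)
  }
  objvec <- c(numeric(mod$ncol), 1)
  res <- milp_solve(objvec, A, dir, rhs, mod$binary_idx, mod$ub_rows,
                    mod$lb_rows, mip_gap = opts$mip_gap,
                    time_limit = opts$time_limit)
  out <- scenario_solution(inst, mod, res, penalty, opts, worst_case = TRUE)
  if (identical(out$solver_status, "optimal"))
    out$objective_worst_case <- res$obj
  out
}

scenario_solution <- function(inst, mod, res, penalty, opts, worst_case) {
  nS <- mod$dims$nS
  if (res$status != "optimal") {
    status <- if (res$status == "infeasible") "infeasible" else "limit"
    hint <- if (status == "infeasible") infeasibility_hint(inst) else NULL
    return(structure(list(
      instance_id = inst$id, first_stage = NULL, per_scenario = NULL,
      expected_cost = NA_real_, expected_shortage_units = NA_real_,
      worst_case_shortage = NA_real_, penalty = penalty,
      mode = if (worst_case) "worstcase" else "expected",
      solver_status = status, infeasible_hint = hint,
      nodes = res$nodes, options = opts), class = "bsc_scenario_solution"))
  }
  x <- res$x
  per <- vector("list", nS)
  names(per) <- inst$scenarios$id
  for (s in seq_len(nS)) {
    rs <- restrict_to_scenario(inst, s)
    sol <- make_solution(rs, mod, x, "optimal", opts, s = s,
                         nodes = res$nodes)
    parts <- cost_parts(rs, sol, integral_vehicles = opts$integral_vehicles)
    per[[s]] <- list(
      solution = sol,
      probability = inst$scenarios$probability[s],
      cost = sol$objective_cost,
      shortage_units = sol$objective_shortage_units,
      shortage_by_period = sol$shortage,
      breakdown = c(setup = parts$setup, transport = parts$transport,
                    testing = parts$testing,
                    penalty = penalty * sol$objective_shortage_units))
  }
  p <- inst$scenarios$probability
  costs <- vapply(per, function(e) e$cost, 0)
  shorts <- vapply(per, function(e) e$shortage_units, 0)
  fs <- per[[1]]$solution
  structure(list(
    instance_id = inst$id,
    first_stage = list(open_temp = fs$open_temp, open_perm = fs$open_perm,
                       open_center = fs$open_center,
                       open_field = fs$open_field),
    per_scenario = per,
    expected_cost = sum(p * costs),
    expected_shortage_units = sum(p * shorts),
    worst_case_shortage = max(shorts),
    penalty = penalty,
    mode = if (worst_case) "worstcase" else "expected",
    solver_status = "optimal", infeasible_hint = NULL,
    nodes = res$nodes, options = opts
  ), class = "bsc_scenario_solution")
}

#' @export
print.bsc_scenario_solution <- function(x, ...) {
  cat(sprintf("<bsc_scenario_solution for '%s' [%s, %s]>\n", x$instance_id,
              x$mode, x$solver_status))
  if (identical(x$solver_status, "optimal")) {
    cat(sprintf("  expected cost %.6g; expected shortage %.6g units; worst case %.6g units; penalty %.6g\n",
                x$expected_cost, x$expected_shortage_units,
                x$worst_case_shortage, x$penalty))
  } else if (!is.null(x$infeasible_hint)) {
    cat("  infeasible; service level unattainable at full capacity in:\n")
    print(x$infeasible_hint)
  }
  invisible(x)
}

#' Default shortage-penalty grid
#'
#' An increasing grid of per-unit shortage fines for [sweep_penalty()],
#' spanning no penalty to far beyond the balance point; includes the
#' reference fine of 1,450,000 currency units per unit.
#'
#' @return numeric vector of penalties.
#' @export
default_penalty_grid <- function() {
  c(0, 5e4, 2e5, 5e5, 1e6, 1.45e6, 5e6, 1e7)
}

#' Sweep the shortage penalty
#'
#' Solves the two-stage model once per fine in the grid. Along an increasing
#' grid the expected shortage is non-increasing and the non-penalty expected
#' cost non-decreasing (scalarization monotonicity); the sweep is the tool
#' for choosing a fine that balances cost against unmet demand.
#'
#' @param inst a `bsc_instance`.
#' @param grid increasing vector of nonnegative penalties; defaults to
#'   [default_penalty_grid()].
#' @param opts a [solve_options()] object.
#' @return a `bsc_penalty_sweep`: data frame with one row per penalty
#'   (`penalty`, `expected_cost_excl_penalty`, `expected_shortage_units`,
#'   `total_objective`, `status`). Failed rows are flagged in `status` and
#'   the sweep continues.
#' @export
sweep_penalty <- function(inst, grid = default_penalty_grid(),
                          opts = solve_options()) {
  stopifnot(length(grid) > 0, all(grid >= 0))
  rows <- lapply(grid, function(pen) {
    sol <- tryCatch(solve_two_stage(inst, penalty = pen, opts = opts),
                    error = function(e) NULL)
    if (is.null(sol) || sol$solver_status != "optimal") {
      data.frame(penalty = pen, expected_cost_excl_penalty = NA_real_,
                 expected_shortage_units = NA_real_,
                 total_objective = NA_real_,
                 status = if (is.null(sol)) "error" else sol$solver_status,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(penalty = pen,
                 expected_cost_excl_penalty = sol$expected_cost,
                 expected_shortage_units = sol$expected_shortage_units,
                 total_objective = sol$expected_cost +
                   pen * sol$expected_shortage_units,
                 status = "optimal", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bsc_penalty_sweep", class(out))
  out
}

#' Per-scenario report of a two-stage solution
#'
#' One row per scenario: probability, total and per-period shortage, the
#' cost breakdown (setup, transport, testing, penalty) and the facilities
#' opened. Totals are consistent with the stored expected values.
#'
#' @param sol an optimally solved `bsc_scenario_solution`.
#' @return data frame of class `bsc_scenario_report`.
#' @export
scenario_report <- function(sol) {
  stopifnot(inherits(sol, "bsc_scenario_solution"))
  if (!identical(sol$solver_status, "optimal"))
    stop("scenario_report() needs an optimally solved scenario solution")
  fs <- sol$first_stage
  opened <- unlist(lapply(fs, function(v) names(v)[v]), use.names = FALSE)
  rows <- lapply(names(sol$per_scenario), function(sid) {
    e <- sol$per_scenario[[sid]]
    df <- data.frame(scenario = sid, probability = e$probability,
                     total_shortage_units = e$shortage_units,
                     stringsAsFactors = FALSE)
    for (t in seq_along(e$shortage_by_period))
      df[[sprintf("shortage_t%d", t)]] <- e$shortage_by_period[t]
    df$setup_cost <- e$breakdown[["setup"]]
    df$transport_cost <- e$breakdown[["transport"]]
    df$testing_cost <- e$breakdown[["testing"]]
    df$penalty_cost <- e$breakdown[["penalty"]]
    df$total_cost <- e$cost
    df
  })
  out <- do.call(rbind, rows)
  attr(out, "facilities_opened") <- opened
  attr(out, "expected_cost") <- sol$expected_cost
  attr(out, "expected_shortage_units") <- sol$expected_shortage_units
  class(out) <- c("bsc_scenario_report", class(out))
  out
}

#' @export
print.bsc_scenario_report <- function(x, ...) {
  cat("<bsc_scenario_report>\n")
  cat("  facilities opened:",
      paste(attr(x, "facilities_opened"), collapse = ", "), "\n")
  print(as.data.frame(x), row.names = FALSE)
  cat(sprintf("  expected cost %.6g; expected shortage %.6g units\n",
              attr(x, "expected_cost"), attr(x, "expected_shortage_units")))
  invisible(x)
}
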