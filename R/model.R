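# Core MILP: assemble the deterministic/scenario-expanded model, solve it
# under a chosen objective, and evaluate objectives on any solution.
#
# Decision variables (per scenario s): QT[i,z,t] units shipped from temporary
# site i to blood center z in period t; QC[u,z,t] likewise from permanent
# facility u; TH[z,n,t] usable units delivered from center z to treatment
# node n; IN[z,t] end-of-period usable inventory at center z; IB[t] unmet
# transfusion demand. Collected amounts CH[i,t] and BH[u,t] are identities
# (row sums of QT/QC) and are reconstructed on extraction. First-stage
# binaries open candidate sites.
#
# Two assemblies are available: "tight", which folds each big-M linkage into
# its capacity row (sum_z QT[i,z,t] <= capa[i,t] * X_i, etc.) for a strong LP
# relaxation, and "bigM", the literal row-per-linkage form with an explicit
# constant M. Both describe the same mixed-integer feasible set when M is
# large enough; the equality of their optima is exercised in the tests.

#' Solver options
#'
#' @param objective which objective to minimize: total cost (`"cost"`), total
#'   shortage in blood units (`"shortage_units"`), or the sum over periods of
#'   shortage/demand ratios (`"shortage_ratio"`).
#' @param mip_gap relative optimality gap for branch and bound.
#' @param time_limit wall-clock seconds before the solver returns status
#'   `"limit"`.
#' @param integral_vehicles if `TRUE`, [evaluate_cost()] prices transport per
#'   truck trip (`ceiling(flow / vehicle_capacity)` trips per arc and period)
#'   instead of per unit-km. The MILP itself always prices per unit-km.
#' @param solver_backend backend name; `"bb-simplex"` is the built-in branch
#'   and bound over the package's simplex.
#' @param formulation `"tight"` (aggregated big-M, default) or `"bigM"`
#'   (literal linkage rows with `M = 1e9`), mainly for diagnostics.
#' @return an object of class `bsc_solve_options`.
#' @export
solve_options <- function(objective = c("cost", "shortage_units", "shortage_ratio"),
                          mip_gap = 1e-6, time_limit = Inf,
                          integral_vehicles = FALSE,
                          solver_backend = "bb-simplex",
                          formulation = c("tight", "bigM")) {
  objective <- match.arg(objective)
  formulation <- match.arg(formulation)
  stopifnot(is.numeric(mip_gap), mip_gap >= 0)
  if (!identical(solver_backend, "bb-simplex"))
    stop("unknown solver backend: ", solver_backend)
  structure(list(objective = objective, mip_gap = mip_gap,
                 time_limit = time_limit,
                 integral_vehicles = isTRUE(integral_vehicles),
                 solver_backend = solver_backend,
                 formulation = formulation),
            class = "bsc_solve_options")
}

# transfusion demand in blood units for scenario s (vector over periods)
demand_units <- function(inst, s) {
  inst$alpha * inst$units_per_patient * eff_demand(inst, s)
}

# ---- model assembly -----------------------------------------------------

# Builds A, dir, rhs and the objective coefficient vectors for the scenario-
# expanded model with shared first-stage binaries. Returns index bookkeeping
# used by the extractor and by the scenario module.
#
# In the "bigM" formulation the user-supplied M is clamped per row to the
# tightest valid bound (coefficient-tightening presolve): an arbitrarily
# large M leaves the mixed-integer optimum unchanged but would make the
# matrix catastrophically ill-conditioned for the dense simplex.
bsc_build <- function(inst, formulation = "tight", relax_service = FALSE,
                      bigM = 1e9) {
  temp <- site_ids(inst, "temp"); perm <- site_ids(inst, "perm")
  cent <- site_ids(inst, "center"); trt <- site_ids(inst, "treat")
  nI <- length(temp); nU <- length(perm); nZ <- length(cent); nN <- length(trt)
  nT <- n_periods(inst); nS <- n_scenarios(inst)
  p <- inst$scenarios$probability

  # binaries: candidate sites with an open decision
  cand <- inst$sites[!inst$sites$exists &
                       inst$sites$kind != "treatment_center", , drop = FALSE]
  bin_ids <- cand$id; bin_kind <- cand$kind
  nb <- length(bin_ids)
  bidx <- stats::setNames(seq_len(nb), bin_ids)
  # open-variable column for any site id (NA if existing / always open)
  bin_of <- function(ids) unname(bidx[ids])

  nQT <- nI * nZ * nT; nQC <- nU * nZ * nT; nTH <- nZ * nN * nT
  blk <- nQT + nQC + nTH + nZ * nT + nT
  nV <- if (relax_service) nS * nT else 0L
  ncol_tot <- nb + nS * blk + nV

  off <- function(s) nb + (s - 1L) * blk
  i_qt <- function(s, i, z, t) off(s) + i + nI * (z - 1L) + nI * nZ * (t - 1L)
  i_qc <- function(s, u, z, t) off(s) + nQT + u + nU * (z - 1L) + nU * nZ * (t - 1L)
  i_th <- function(s, z, n, t) off(s) + nQT + nQC + z + nZ * (n - 1L) + nZ * nN * (t - 1L)
  i_in <- function(s, z, t)    off(s) + nQT + nQC + nTH + z + nZ * (t - 1L)
  i_ib <- function(s, t)       off(s) + nQT + nQC + nTH + nZ * nT + t
  i_v  <- function(s, t)       nb + nS * blk + (s - 1L) * nT + t

  ri <- integer(0); ci <- integer(0); vv <- numeric(0)
  dir <- character(0); rhs <- numeric(0)
  nrow_cur <- 0L
  add_row <- function(cols, vals, sense, b) {
    nrow_cur <<- nrow_cur + 1L
    ri <<- c(ri, rep.int(nrow_cur, length(cols)))
    ci <<- c(ci, cols); vv <<- c(vv, vals)
    dir[nrow_cur] <<- sense; rhs[nrow_cur] <<- b
    nrow_cur
  }

  # binary bound rows first (branch and bound retargets their rhs)
  ub_rows <- integer(nb); lb_rows <- integer(nb)
  for (j in seq_len(nb)) ub_rows[j] <- add_row(j, 1, "<=", 1)
  for (j in seq_len(nb)) lb_rows[j] <- add_row(j, 1, ">=", 0)

  coll_ids <- c(temp, perm)
  coll_is_temp <- c(rep(TRUE, nI), rep(FALSE, nU))
  coll_bin <- bin_of(coll_ids)
  cent_bin <- bin_of(cent)
  trt_bin <- bin_of(trt)          # NA for existing treatment nodes
  beta <- inst$beta

  for (s in seq_len(nS)) {
    cm <- inst$scenarios$capacity_multiplier[s]
    dem_u <- demand_units(inst, s)
    capa_coll <- rbind(inst$capa_temp, inst$capa_perm) * cm
    capd <- inst$capd_center * cm
    capf <- inst$capf_treat * cm
    m_out <- inst$initial_inventory + beta * t(apply(capd, 1, cumsum))
    if (nT == 1) m_out <- matrix(inst$initial_inventory + beta * capd[, 1],
                                 nZ, 1)

    q_cols <- function(c_, t) {
      if (coll_is_temp[c_]) vapply(seq_len(nZ), function(z) i_qt(s, c_, z, t), 0L)
      else vapply(seq_len(nZ), function(z) i_qc(s, c_ - nI, z, t), 0L)
    }

    for (t in seq_len(nT)) {
      # collection capacity + open linkage (eqs 1-6, 10, 11 folded)
      for (c_ in seq_along(coll_ids)) {
        cols <- q_cols(c_, t)
        if (formulation == "tight") {
          if (!is.na(coll_bin[c_])) {
            add_row(c(cols, coll_bin[c_]), c(rep(1, nZ), -capa_coll[c_, t]),
                    "<=", 0)
          } else add_row(cols, rep(1, nZ), "<=", capa_coll[c_, t])
        } else {
          add_row(cols, rep(1, nZ), "<=", capa_coll[c_, t])        # eq 1/3
          if (!is.na(coll_bin[c_])) {
            add_row(c(cols, coll_bin[c_]),
                    c(rep(1, nZ), -min(bigM, capa_coll[c_, t])), "<=", 0) # eq 2/4
            for (z in seq_len(nZ))                                  # eq 10/11
              add_row(c(cols[z], coll_bin[c_]),
                      c(1, -min(bigM, capa_coll[c_, t], capd[z, t])), "<=", 0)
          }
        }
      }
      # center intake (eqs 7-9 folded)
      for (z in seq_len(nZ)) {
        cols <- c(vapply(seq_len(nI), function(i) i_qt(s, i, z, t), 0L),
                  vapply(seq_len(nU), function(u) i_qc(s, u, z, t), 0L))
        if (formulation == "tight") {
          if (!is.na(cent_bin[z])) {
            add_row(c(cols, cent_bin[z]), c(rep(1, nI + nU), -capd[z, t]),
                    "<=", 0)
          } else add_row(cols, rep(1, nI + nU), "<=", capd[z, t])
        } else {
          add_row(cols, rep(1, nI + nU), "<=", capd[z, t])          # eq 7
          if (!is.na(cent_bin[z]))
            for (k in seq_along(cols))                              # eq 8/9
              add_row(c(cols[k], cent_bin[z]),
                      c(1, -min(bigM, capa_coll[k, t], capd[z, t])), "<=", 0)
        }
      }
      # center outflow requires the center open (eq 15)
      for (z in seq_len(nZ)) {
        if (is.na(cent_bin[z])) next
        cols <- vapply(seq_len(nN), function(n) i_th(s, z, n, t), 0L)
        if (formulation == "tight") {
          add_row(c(cols, cent_bin[z]), c(rep(1, nN), -m_out[z, t]), "<=", 0)
        } else {
          for (n in seq_len(nN))
            add_row(c(i_th(s, z, n, t), cent_bin[z]),
                    c(1, -min(bigM, m_out[z, t], capf[n])), "<=", 0)
        }
      }
      # treatment capacity + destination-open linkage (eqs 13, 16, 17 folded)
      for (n in seq_len(nN)) {
        cols <- vapply(seq_len(nZ), function(z) i_th(s, z, n, t), 0L)
        if (formulation == "tight") {
          if (!is.na(trt_bin[n])) {
            add_row(c(cols, trt_bin[n]), c(rep(1, nZ), -capf[n]), "<=", 0)
          } else add_row(cols, rep(1, nZ), "<=", capf[n])
        } else {
          add_row(cols, rep(1, nZ), "<=", capf[n])                  # eq 13
          if (!is.na(trt_bin[n]))
            for (z in seq_len(nZ))                                  # eq 16/17
              add_row(c(i_th(s, z, n, t), trt_bin[n]),
                      c(1, -min(bigM, m_out[z, t], capf[n])), "<=", 0)
        }
      }
      # inventory balance (eq 12):
      # beta * inflow + IN[z,t-1] - outflow - IN[z,t] = -init (t = 1)
      for (z in seq_len(nZ)) {
        cols <- c(vapply(seq_len(nI), function(i) i_qt(s, i, z, t), 0L),
                  vapply(seq_len(nU), function(u) i_qc(s, u, z, t), 0L),
                  vapply(seq_len(nN), function(n) i_th(s, z, n, t), 0L),
                  i_in(s, z, t))
        vals <- c(rep(beta, nI + nU), rep(-1, nN), -1)
        if (t > 1) {
          cols <- c(cols, i_in(s, z, t - 1L)); vals <- c(vals, 1)
          add_row(cols, vals, "==", 0)
        } else {
          add_row(cols, vals, "==", -inst$initial_inventory[z])
        }
      }
      # demand accounting (eq 14)
      th_all <- as.vector(vapply(seq_len(nN), function(n)
        vapply(seq_len(nZ), function(z) i_th(s, z, n, t), 0L), integer(nZ)))
      add_row(c(th_all, i_ib(s, t)), c(rep(1, nZ * nN), 1), "==", dem_u[t])
      # service level (eq 18), written on IB via eq 14
      if (relax_service) {
        add_row(c(i_ib(s, t), i_v(s, t)), c(1, -1), "<=",
                (1 - inst$lam) * dem_u[t])
      } else {
        add_row(i_ib(s, t), 1, "<=", (1 - inst$lam) * dem_u[t])
      }
    }
  }

  A <- matrix(0, nrow_cur, ncol_tot)
  A[cbind(ri, ci)] <- vv

  # objective coefficient vectors
  setup_base <- site_setup(inst, bin_ids)
  smult <- inst$scenarios$setup_cost_multiplier
  setup_exp <- ifelse(bin_kind == "temporary_collection",
                      setup_base * sum(p * smult), setup_base)
  utc <- inst$unit_transport_cost; ute <- inst$unit_test_cost
  dcc <- inst$dist_coll_center; dct <- inst$dist_center_treat

  tv_s <- vector("list", nS)       # transport + testing, per scenario
  sh_s <- vector("list", nS)       # shortage units, per scenario
  for (s in seq_len(nS)) {
    v <- numeric(ncol_tot)
    for (t in seq_len(nT)) {
      for (z in seq_len(nZ)) {
        for (i in seq_len(nI)) v[i_qt(s, i, z, t)] <- dcc[i, z] * utc + ute
        for (u in seq_len(nU)) v[i_qc(s, u, z, t)] <- dcc[nI + u, z] * utc + ute
        for (n in seq_len(nN)) v[i_th(s, z, n, t)] <- dct[z, n] * utc
      }
    }
    tv_s[[s]] <- v
    w <- numeric(ncol_tot)
    for (t in seq_len(nT)) w[i_ib(s, t)] <- 1
    sh_s[[s]] <- w
  }
  setup_vec <- numeric(ncol_tot)
  setup_vec[seq_len(nb)] <- setup_exp
  setup_vec_s <- function(s) {
    v <- numeric(ncol_tot)
    v[seq_len(nb)] <- ifelse(bin_kind == "temporary_collection",
                             setup_base * smult[s], setup_base)
    v
  }
  cost_vec <- setup_vec + Reduce(`+`, Map(function(v, ps) v * ps, tv_s, as.list(p)))
  short_units_vec <- Reduce(`+`, Map(function(v, ps) v * ps, sh_s, as.list(p)))
  ratio_vec <- numeric(ncol_tot)
  for (s in seq_len(nS)) {
    dem_u <- demand_units(inst, s)
    for (t in seq_len(nT))
      if (dem_u[t] > 0) ratio_vec[i_ib(s, t)] <- p[s] / dem_u[t]
  }

  list(A = A, dir = dir, rhs = rhs, ncol = ncol_tot,
       nb = nb, bin_ids = bin_ids, bin_kind = bin_kind,
       binary_idx = seq_len(nb), ub_rows = ub_rows, lb_rows = lb_rows,
       idx = list(qt = i_qt, qc = i_qc, th = i_th, inv = i_in, ib = i_ib,
                  v = i_v),
       dims = list(nI = nI, nU = nU, nZ = nZ, nN = nN, nT = nT, nS = nS),
       ids = list(temp = temp, perm = perm, cent = cent, trt = trt),
       cost_vec = cost_vec, short_units_vec = short_units_vec,
       ratio_vec = ratio_vec, tv_s = tv_s, sh_s = sh_s,
       setup_vec_s = setup_vec_s,
       relax_idx = if (relax_service)
         vapply(seq_len(nS), function(s)
           vapply(seq_len(nT), function(t) i_v(s, t), 0L), integer(nT))
       else NULL)
}

row_period_sums <- function(arr) {
  d <- dim(arr)
  if (d[1] == 0) return(matrix(0, 0, d[3]))
  m <- apply(arr, c(1, 3), sum)
  rownames(m) <- dimnames(arr)[[1]]
  m
}

# extract the per-scenario solution arrays from a variable vector
bsc_extract <- function(inst, mod, x, s) {
  d <- mod$dims; ids <- mod$ids
  cl <- function(v) pmax(v, 0)
  QT <- array(0, c(d$nI, d$nZ, d$nT), dimnames = list(ids$temp, ids$cent, NULL))
  QC <- array(0, c(d$nU, d$nZ, d$nT), dimnames = list(ids$perm, ids$cent, NULL))
  TH <- array(0, c(d$nZ, d$nN, d$nT), dimnames = list(ids$cent, ids$trt, NULL))
  IN <- matrix(0, d$nZ, d$nT, dimnames = list(ids$cent, NULL))
  IB <- numeric(d$nT)
  for (t in seq_len(d$nT)) {
    for (z in seq_len(d$nZ)) {
      for (i in seq_len(d$nI)) QT[i, z, t] <- cl(x[mod$idx$qt(s, i, z, t)])
      for (u in seq_len(d$nU)) QC[u, z, t] <- cl(x[mod$idx$qc(s, u, z, t)])
      for (n in seq_len(d$nN)) TH[z, n, t] <- cl(x[mod$idx$th(s, z, n, t)])
      IN[z, t] <- cl(x[mod$idx$inv(s, z, t)])
    }
    IB[t] <- cl(x[mod$idx$ib(s, t)])
  }
  list(QT = QT, QC = QC, TH = TH, IN = IN, IB = IB)
}

open_vectors <- function(inst, mod, x) {
  openb <- stats::setNames(round(x[seq_len(mod$nb)]) >= 1, mod$bin_ids)
  open_of <- function(ids) {
    v <- site_exists(inst, ids)
    cand <- !v
    v[cand] <- openb[ids[cand]]
    stats::setNames(as.logical(v), ids)
  }
  list(open_temp = open_of(site_ids(inst, "temp")),
       open_perm = open_of(site_ids(inst, "perm")),
       open_center = open_of(site_ids(inst, "center")),
       open_field = open_of(site_ids(inst, "field")))
}

make_solution <- function(inst, mod, x, status, opts, s = 1L,
                          infeasible_hint = NULL, nodes = NA_integer_) {
  opens <- if (!is.null(x)) open_vectors(inst, mod, x) else
    list(open_temp = site_exists(inst, site_ids(inst, "temp")),
         open_perm = site_exists(inst, site_ids(inst, "perm")),
         open_center = site_exists(inst, site_ids(inst, "center")),
         open_field = site_exists(inst, site_ids(inst, "field")))
  arrs <- if (!is.null(x)) bsc_extract(inst, mod, x, s) else NULL
  d <- mod$dims
  sol <- structure(list(
    instance_id = inst$id,
    scenario_id = inst$scenarios$id[min(s, nrow(inst$scenarios))],
    open_temp = opens$open_temp, open_perm = opens$open_perm,
    open_center = opens$open_center, open_field = opens$open_field,
    collected_temp = if (!is.null(arrs)) row_period_sums(arrs$QT) else
      matrix(0, d$nI, d$nT, dimnames = list(mod$ids$temp, NULL)),
    collected_perm = if (!is.null(arrs)) row_period_sums(arrs$QC) else
      matrix(0, d$nU, d$nT, dimnames = list(mod$ids$perm, NULL)),
    ship_temp = if (!is.null(arrs)) arrs$QT else
      array(0, c(d$nI, d$nZ, d$nT), dimnames = list(mod$ids$temp, mod$ids$cent, NULL)),
    ship_perm = if (!is.null(arrs)) arrs$QC else
      array(0, c(d$nU, d$nZ, d$nT), dimnames = list(mod$ids$perm, mod$ids$cent, NULL)),
    deliver = if (!is.null(arrs)) arrs$TH else
      array(0, c(d$nZ, d$nN, d$nT), dimnames = list(mod$ids$cent, mod$ids$trt, NULL)),
    inventory = if (!is.null(arrs)) arrs$IN else
      matrix(0, d$nZ, d$nT, dimnames = list(mod$ids$cent, NULL)),
    shortage = if (!is.null(arrs)) arrs$IB else rep(NA_real_, d$nT),
    objective_cost = NA_real_, objective_shortage_ratio = NA_real_,
    objective_shortage_units = NA_real_,
    solver_status = status, nodes = nodes,
    infeasible_hint = infeasible_hint,
    options = opts
  ), class = "bsc_solution")
  if (identical(status, "optimal")) {
    sol$objective_cost <- evaluate_cost(inst, sol,
                                        integral_vehicles = opts$integral_vehicles)
    ev <- evaluate_shortage(inst, sol)
    sol$objective_shortage_ratio <- ev[["ratio_sum"]]
    sol$objective_shortage_units <- ev[["total_units"]]
  }
  sol
}

#' @export
print.bsc_solution <- function(x, ...) {
  cat(sprintf("<bsc_solution for '%s' [%s]>\n", x$instance_id, x$solver_status))
  if (identical(x$solver_status, "optimal")) {
    nopen <- sum(c(x$open_temp, x$open_perm, x$open_center, x$open_field))
    cat(sprintf("  open facilities: %d; cost %.6g; shortage %.6g units (ratio sum %.4g)\n",
                nopen, x$objective_cost, x$objective_shortage_units,
                x$objective_shortage_ratio))
    cat(sprintf("  shortage by period: %s\n",
                paste(format(round(x$shortage, 3)), collapse = ", ")))
  } else if (!is.null(x$infeasible_hint)) {
    cat("  infeasible; service level unattainable at full capacity in:\n")
    print(x$infeasible_hint)
  }
  invisible(x)
}

# explain infeasibility: with every candidate open, which (scenario, period)
# service levels are unattainable, and by how many units
infeasibility_hint <- function(inst) {
  mod <- bsc_build(inst, relax_service = TRUE)
  obj <- numeric(mod$ncol)
  obj[as.vector(mod$relax_idx)] <- 1
  res <- milp_solve(obj, mod$A, mod$dir, mod$rhs, mod$binary_idx,
                    mod$ub_rows, mod$lb_rows,
                    fixed = rep(1L, mod$nb), mip_gap = 1e-9)
  if (res$status != "optimal") return(NULL)
  out <- NULL
  for (s in seq_len(mod$dims$nS)) for (t in seq_len(mod$dims$nT)) {
    v <- res$x[mod$idx$v(s, t)]
    if (v > 1e-6)
      out <- rbind(out, data.frame(scenario = inst$scenarios$id[s],
                                   period = t, missing_units = v))
  }
  out
}

# shared solving core: minimize objvec over the instance model, with optional
# extra linear rows (used for epsilon bounds and lexicographic passes)
solve_core <- function(inst, objvec_name, opts, extra = NULL,
                       objvec = NULL, mod = NULL) {
  if (is.null(mod)) mod <- bsc_build(inst, formulation = opts$formulation)
  if (is.null(objvec))
    objvec <- switch(objvec_name,
                     cost = mod$cost_vec,
                     shortage_units = mod$short_units_vec,
                     shortage_ratio = mod$ratio_vec)
  A <- mod$A; dir <- mod$dir; rhs <- mod$rhs
  if (!is.null(extra)) {
    for (row in extra) {
      v <- numeric(mod$ncol); v[seq_along(row$coef)] <- row$coef
      A <- rbind(A, v); dir <- c(dir, row$dir); rhs <- c(rhs, row$rhs)
    }
  }
  res <- milp_solve(objvec, A, dir, rhs, mod$binary_idx, mod$ub_rows,
                    mod$lb_rows, mip_gap = opts$mip_gap,
                    time_limit = opts$time_limit)
  list(mod = mod, res = res)
}

#' Solve the deterministic single-scenario model under one objective
#'
#' Assembles the full facility-location / flow / inventory / shortage MILP for
#' a single-scenario instance and minimizes the objective named in `opts`.
#' All three objective evaluations are populated on the returned solution,
#' computed by [evaluate_cost()] and [evaluate_shortage()] rather than copied
#' from the solver.
#'
#' @param inst a validated single-scenario `bsc_instance` (use
#'   [restrict_to_scenario()] or the scenario module otherwise).
#' @param opts a [solve_options()] object.
#' @return a `bsc_solution`. `solver_status` is one of `optimal`,
#'   `infeasible`, `unbounded`, `limit`; on infeasibility the
#'   `infeasible_hint` field lists the periods whose service level cannot be
#'   met even with every candidate facility open.
#' @export
solve_single_objective <- function(inst, opts = solve_options()) {
  diags <- validate_instance(inst)
  if (length(diags) > 0)
    stop("invalid instance:\n  ", paste(diags, collapse = "\n  "))
  if (n_scenarios(inst) != 1)
    stop("solve_single_objective() needs a single-scenario instance; ",
         "use restrict_to_scenario() or solve_two_stage()")
  sc <- solve_core(inst, opts$objective, opts)
  res <- sc$res
  status <- res$status
  if (status == "optimal") {
    make_solution(inst, sc$mod, res$x, "optimal", opts, nodes = res$nodes)
  } else if (status == "infeasible") {
    make_solution(inst, sc$mod, NULL, "infeasible", opts,
                  infeasible_hint = infeasibility_hint(inst),
                  nodes = res$nodes)
  } else {
    make_solution(inst, sc$mod, NULL, "limit", opts, nodes = res$nodes)
  }
}

# ---- objective evaluation ----------------------------------------------

#' Total cost of a solution
#'
#' Setup costs of newly opened candidate facilities, plus transport over the
#' three arc layers, plus testing costs for every raw unit entering a blood
#' center. With `integral_vehicles`, transport on an arc in a period costs
#' `ceiling(flow / vehicle_capacity) * distance * unit_transport_cost`
#' (whole truck trips); otherwise it is priced per unit-km.
#'
#' @param inst the (single-scenario) instance the solution belongs to.
#' @param sol a `bsc_solution`.
#' @param integral_vehicles price transport per truck trip instead of per
#'   unit-km.
#' @return total cost in currency units.
#' @export
evaluate_cost <- function(inst, sol, integral_vehicles = FALSE) {
  p <- cost_parts(inst, sol, integral_vehicles)
  p$setup + p$transport + p$testing
}

# setup / transport / testing components of the cost objective
cost_parts <- function(inst, sol, integral_vehicles = FALSE) {
  tol <- 1e-9
  setup <- 0
  for (role in c("temp", "perm", "center", "field")) {
    ids <- site_ids(inst, role)
    if (length(ids) == 0) next
    open <- sol[[c(temp = "open_temp", perm = "open_perm",
                   center = "open_center", field = "open_field")[role]]]
    newly <- ids[open[ids] & !site_exists(inst, ids)]
    setup <- setup + sum(site_setup(inst, newly))
  }
  utc <- inst$unit_transport_cost
  arc_cost <- function(flow_by_arc, dist) {
    # flow_by_arc: matrix arcs x periods; dist: vector over arcs
    if (anyNA(dist)) {
      bad <- rowSums(flow_by_arc) > tol & is.na(dist)
      if (any(bad)) stop("flow on an arc with missing distance")
    }
    if (integral_vehicles) {
      trips <- ceiling(pmax(flow_by_arc, 0) / inst$vehicle_capacity)
      trips[flow_by_arc <= tol] <- 0
      sum(trips * dist * utc, na.rm = TRUE)
    } else {
      sum(flow_by_arc * dist * utc, na.rm = TRUE)
    }
  }
  d <- dim(sol$ship_temp)
  qt_flat <- matrix(sol$ship_temp, d[1] * d[2], d[3])
  d2 <- dim(sol$ship_perm)
  qc_flat <- matrix(sol$ship_perm, d2[1] * d2[2], d2[3])
  d3 <- dim(sol$deliver)
  th_flat <- matrix(sol$deliver, d3[1] * d3[2], d3[3])
  nI <- d[1]
  transport <-
    arc_cost(qt_flat, as.vector(inst$dist_coll_center[seq_len(nI), , drop = FALSE])) +
    arc_cost(qc_flat, as.vector(inst$dist_coll_center[nI + seq_len(d2[1]), , drop = FALSE])) +
    arc_cost(th_flat, as.vector(inst$dist_center_treat))
  testing <- inst$unit_test_cost * (sum(sol$ship_temp) + sum(sol$ship_perm))
  list(setup = setup, transport = transport, testing = testing)
}

#' Shortage objectives of a solution
#'
#' @param inst the (single-scenario) instance the solution belongs to.
#' @param sol a `bsc_solution`.
#' @return named numeric vector with `ratio_sum` (sum over periods of
#'   shortage / transfusion demand, zero-demand periods contributing 0) and
#'   `total_units` (total shortage in blood units).
#' @export
evaluate_shortage <- function(inst, sol) {
  dem_u <- demand_units(inst, 1L)
  sh <- sol$shortage
  if (any(sh > 1e-9 & dem_u <= 0))
    stop("inconsistent solution: shortage reported in a zero-demand period")
  pos <- dem_u > 0
  c(ratio_sum = sum(sh[pos] / dem_u[pos]), total_units = sum(sh))
}

# ---- literal constraint system description ------------------------------

#' Describe the literal constraint system of an instance
#'
#' Emits one descriptor row per constraint of the model in its literal
#' (row-per-linkage) form, labeled by family: collection capacity (eq1/eq3),
#' collection-open linkage (eq2/eq4), collection-shipment conservation
#' (eq5/eq6), center intake capacity (eq7), shipment linkage to open centers
#' and collection sites (eq8-eq11), inventory balance (eq12), treatment
#' capacity (eq13), demand/shortage accounting (eq14), delivery linkage
#' (eq15-eq17) and the minimum service level (eq18). Linkage rows exist only
#' for candidate facilities; existing sites are always open.
#'
#' @param inst a `bsc_instance`.
#' @return data frame with columns `family`, `scenario`, `period`, `site`,
#'   `center`, `treat`, `sense`, `rhs` (`NA` for symbolic big-M rows), class
#'   `bsc_constraints`.
#' @export
assemble_constraints <- function(inst) {
  temp <- site_ids(inst, "temp"); perm <- site_ids(inst, "perm")
  cent <- site_ids(inst, "center"); trt <- site_ids(inst, "treat")
  nT <- n_periods(inst); nS <- n_scenarios(inst)
  ex <- function(ids) site_exists(inst, ids)
  rows <- list()
  emit <- function(family, s, t, site = NA, center = NA, treat = NA,
                   sense, rhs) {
    rows[[length(rows) + 1L]] <<-
      data.frame(family = family, scenario = inst$scenarios$id[s], period = t,
                 site = site, center = center, treat = treat,
                 sense = sense, rhs = rhs, stringsAsFactors = FALSE)
  }
  trt_kind <- inst$sites$kind[match(trt, inst$sites$id)]
  for (s in seq_len(nS)) {
    cm <- inst$scenarios$capacity_multiplier[s]
    dem_u <- demand_units(inst, s)
    for (t in seq_len(nT)) {
      for (i in seq_along(temp)) {
        emit("eq1", s, t, site = temp[i], sense = "<=",
             rhs = inst$capa_temp[i, t] * cm)
        if (!ex(temp)[i]) emit("eq2", s, t, site = temp[i], sense = "<=", rhs = NA)
        emit("eq5", s, t, site = temp[i], sense = "==", rhs = 0)
      }
      for (u in seq_along(perm)) {
        emit("eq3", s, t, site = perm[u], sense = "<=",
             rhs = inst$capa_perm[u, t] * cm)
        if (!ex(perm)[u]) emit("eq4", s, t, site = perm[u], sense = "<=", rhs = NA)
        emit("eq6", s, t, site = perm[u], sense = "==", rhs = 0)
      }
      for (z in seq_along(cent)) {
        emit("eq7", s, t, center = cent[z], sense = "<=",
             rhs = inst$capd_center[z, t] * cm)
        if (!ex(cent)[z]) {
          for (i in seq_along(temp))
            emit("eq8", s, t, site = temp[i], center = cent[z], sense = "<=", rhs = NA)
          for (u in seq_along(perm))
            emit("eq9", s, t, site = perm[u], center = cent[z], sense = "<=", rhs = NA)
        }
        for (i in seq_along(temp))
          if (!ex(temp)[i])
            emit("eq10", s, t, site = temp[i], center = cent[z], sense = "<=", rhs = NA)
        for (u in seq_along(perm))
          if (!ex(perm)[u])
            emit("eq11", s, t, site = perm[u], center = cent[z], sense = "<=", rhs = NA)
        emit("eq12", s, t, center = cent[z], sense = "==",
             rhs = if (t == 1) inst$initial_inventory[z] else 0)
        if (!ex(cent)[z])
          for (n in seq_along(trt))
            emit("eq15", s, t, center = cent[z], treat = trt[n], sense = "<=", rhs = NA)
      }
      for (n in seq_along(trt)) {
        emit("eq13", s, t, treat = trt[n], sense = "<=",
             rhs = inst$capf_treat[n] * cm)
        if (!ex(trt)[n]) {
          fam <- if (trt_kind[n] == "permanent_facility") "eq16" else "eq17"
          for (z in seq_along(cent))
            emit(fam, s, t, center = cent[z], treat = trt[n], sense = "<=", rhs = NA)
        }
      }
      emit("eq14", s, t, sense = "==", rhs = dem_u[t])
      emit("eq18", s, t, sense = ">=", rhs = inst$lam * dem_u[t])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bsc_constraints", class(out))
  out
}

#' @export
print.bsc_constraints <- function(x, ...) {
  cat("<bsc_constraints>: rows per family\n")
  print(table(factor(x$family, levels = paste0("eq", 1:18))))
  invisible(x)
}

#' Tightest valid big-M value for every linkage row
#'
#' For each big-M linkage constraint of the literal model, the smallest
#' right-hand-side coefficient that preserves the mixed-integer feasible set:
#' the relevant capacity for collection linkages, the minimum of collection
#' and intake capacity for shipment linkages, and the minimum of maximum
#' cumulative center outflow and treatment capacity for delivery linkages.
#' Replacing these by any larger constant leaves the optimal objective
#' unchanged.
#'
#' @param inst a `bsc_instance`.
#' @return data frame with the linkage families of [assemble_constraints()]
#'   plus a numeric column `M`.
#' @export
tight_big_m <- function(inst) {
  cons <- assemble_constraints(inst)
  link <- cons[cons$family %in% paste0("eq", c(2, 4, 8:11, 15:17)), ]
  temp <- site_ids(inst, "temp"); perm <- site_ids(inst, "perm")
  cent <- site_ids(inst, "center"); trt <- site_ids(inst, "treat")
  M <- numeric(nrow(link))
  for (k in seq_len(nrow(link))) {
    r <- link[k, ]
    s <- match(r$scenario, inst$scenarios$id)
    cm <- inst$scenarios$capacity_multiplier[s]
    t <- r$period
    capa_of <- function(id) {
      if (id %in% temp) inst$capa_temp[match(id, temp), t] * cm
      else inst$capa_perm[match(id, perm), t] * cm
    }
    M[k] <- switch(r$family,
      eq2 = , eq4 = capa_of(r$site),
      eq8 = , eq9 = , eq10 = , eq11 =
        min(capa_of(r$site), inst$capd_center[match(r$center, cent), t] * cm),
      eq15 = , eq16 = , eq17 = {
        z <- match(r$center, cent)
        out_cap <- inst$initial_inventory[z] +
          inst$beta * sum(inst$capd_center[z, seq_len(t)] * cm)
        min(out_cap, inst$capf_treat[match(r$treat, trt)] * cm)
      })
  }
  link$M <- M
  rownames(link) <- NULL
  link
}
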