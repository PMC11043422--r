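# Bi-objective drivers. The two objectives -- total cost and transfusion
# shortage -- conflict: covering more demand means opening and operating more
# facilities. This module computes the individual optima (the ideal point),
# weighted-sum compromises with an optional hard cost bound, and the Pareto
# front by the epsilon-constraint method (minimize shortage subject to
# cost <= epsilon, swept over a grid of cost bounds).

short_vec_of <- function(mod, metric) {
  switch(metric, shortage_units = mod$short_units_vec,
         shortage_ratio = mod$ratio_vec,
         stop("unknown shortage metric: ", metric))
}

short_value_of <- function(sol, metric) {
  switch(metric, shortage_units = sol$objective_shortage_units,
         shortage_ratio = sol$objective_shortage_ratio)
}

# absolute slack added to objective-bound rows so that re-optimizing under a
# bound equal to an attained optimum is never cut off by round-off
bound_slack <- function(v) 1e-7 * max(1, abs(v))

run_milp <- function(inst, mod, objvec, opts, extra = NULL) {
  A <- mod$A; dir <- mod$dir; rhs <- mod$rhs
  if (!is.null(extra)) for (row in extra) {
    A <- rbind(A, row$coef); dir <- c(dir, row$dir); rhs <- c(rhs, row$rhs)
  }
  milp_solve(objvec, A, dir, rhs, mod$binary_idx, mod$ub_rows, mod$lb_rows,
             mip_gap = opts$mip_gap, time_limit = opts$time_limit)
}

milp_solution <- function(inst, mod, res, opts) {
  if (res$status != "optimal")
    stop("solver returned status '", res$status, "'",
         if (res$status == "infeasible") " (model infeasible)" else "")
  make_solution(inst, mod, res$x, "optimal", opts, nodes = res$nodes)
}

#' Individual optima of the two objectives (the ideal point)
#'
#' Solves the model once per objective. Each value is a valid lower bound on
#' the corresponding objective of any feasible solution.
#'
#' @param inst a single-scenario `bsc_instance`.
#' @param opts a [solve_options()] object.
#' @param metric shortage metric: `"shortage_units"` (default) or
#'   `"shortage_ratio"`.
#' @return list with `cost`, `shortage`, and the two anchoring solutions
#'   (`cost_solution`, `shortage_solution`).
#' @export
ideal_points <- function(inst, opts = solve_options(),
                         metric = c("shortage_units", "shortage_ratio")) {
  metric <- match.arg(metric)
  if (n_scenarios(inst) != 1)
    stop("ideal_points() needs a single-scenario instance")
  mod <- bsc_build(inst, formulation = opts$formulation)
  rc <- run_milp(inst, mod, mod$cost_vec, opts)
  sol_c <- milp_solution(inst, mod, rc, opts)
  rs <- run_milp(inst, mod, short_vec_of(mod, metric), opts)
  sol_s <- milp_solution(inst, mod, rs, opts)
  list(cost = sol_c$objective_cost,
       shortage = short_value_of(sol_s, metric),
       cost_solution = sol_c, shortage_solution = sol_s,
       metric = metric, mod = mod)
}

pareto_point <- function(sol, metric, epsilon = NA_real_) {
  structure(list(cost = sol$objective_cost,
                 shortage = short_value_of(sol, metric),
                 solution = sol, epsilon = epsilon, metric = metric),
            class = "bsc_pareto_point")
}

#' @export
print.bsc_pareto_point <- function(x, ...) {
  cat(sprintf("<bsc_pareto_point> cost %.6g, shortage %.6g (%s)%s\n",
              x$cost, x$shortage, x$metric,
              if (!is.na(x$epsilon)) sprintf(", epsilon %.6g", x$epsilon) else ""))
  invisible(x)
}

#' Weighted-sum compromise with an optional cost bound
#'
#' Minimizes `w_cost * cost / n_c + w_short * shortage / n_s`, where the
#' normalizers are the ideal values (floored at 1) so the two objectives,
#' which differ by orders of magnitude, are commensurable. When `cost_bound`
#' is given, the hard constraint `cost <= cost_bound` is added -- the hybrid
#' "weighted method with the cost objective as a constraint".
#'
#' @param inst single-scenario `bsc_instance`.
#' @param w_cost,w_short nonnegative weights, not both zero.
#' @param cost_bound optional hard upper bound on total cost.
#' @param opts a [solve_options()] object.
#' @param metric shortage metric (see [ideal_points()]).
#' @param ideal optionally, a precomputed [ideal_points()] result.
#' @return a `bsc_pareto_point`.
#' @export
solve_weighted <- function(inst, w_cost, w_short, cost_bound = NULL,
                           opts = solve_options(),
                           metric = c("shortage_units", "shortage_ratio"),
                           ideal = NULL) {
  metric <- match.arg(metric)
  stopifnot(w_cost >= 0, w_short >= 0)
  if (w_cost == 0 && w_short == 0) stop("weights must not both be zero")
  if (is.null(ideal)) ideal <- ideal_points(inst, opts, metric)
  mod <- ideal$mod
  if (!is.null(cost_bound) && cost_bound < ideal$cost - bound_slack(ideal$cost))
    stop(sprintf("cost bound %.6g is below the minimum achievable cost %.6g",
                 cost_bound, ideal$cost))
  nc <- max(abs(ideal$cost), 1); ns <- max(abs(ideal$shortage), 1)
  objvec <- (w_cost / nc) * mod$cost_vec +
    (w_short / ns) * short_vec_of(mod, metric)
  extra <- if (!is.null(cost_bound))
    list(list(coef = mod$cost_vec, dir = "<=",
              rhs = cost_bound + bound_slack(cost_bound)))
  res <- run_milp(inst, mod, objvec, opts, extra)
  sol <- milp_solution(inst, mod, res, opts)
  pareto_point(sol, metric, epsilon = if (is.null(cost_bound)) NA_real_ else cost_bound)
}

#' Pareto front by the epsilon-constraint method
#'
#' Sweeps a grid of cost bounds between the cost optimum and the cost of the
#' shortage-anchored solution; at each bound epsilon it minimizes shortage
#' subject to `cost <= epsilon`, then (lexicographically) minimizes cost at
#' that shortage level so each reported point is extreme. The result is
#' filtered to its non-dominated subset; its endpoints reproduce the two
#' individual optima.
#'
#' @param inst single-scenario `bsc_instance`.
#' @param n_points number of grid points (at least 2), ignored if `eps_grid`
#'   is given.
#' @param eps_grid optional explicit vector of cost bounds.
#' @param opts a [solve_options()] object.
#' @param metric shortage metric (see [ideal_points()]).
#' @return a `bsc_pareto_front`: list with `points` (cost-ascending,
#'   non-dominated `bsc_pareto_point`s), `ideal` (named vector `cost`,
#'   `shortage`) and `metric`.
#' @export
solve_epsilon_front <- function(inst, n_points = 5, eps_grid = NULL,
                                opts = solve_options(),
                                metric = c("shortage_units", "shortage_ratio")) {
  metric <- match.arg(metric)
  if (is.null(eps_grid) && n_points < 2) stop("n_points must be at least 2")
  ideal <- ideal_points(inst, opts, metric)
  mod <- ideal$mod
  short_vec <- short_vec_of(mod, metric)

  solve_at <- function(eps) {
    bound <- list(coef = mod$cost_vec, dir = "<=",
                  rhs = eps + bound_slack(eps))
    r1 <- run_milp(inst, mod, short_vec, opts, list(bound))
    if (r1$status == "infeasible")
      stop(sprintf("epsilon %.6g is below the minimum achievable cost", eps))
    s1 <- milp_solution(inst, mod, r1, opts)
    s_lev <- short_value_of(s1, metric)
    r2 <- run_milp(inst, mod, mod$cost_vec, opts,
                   list(bound, list(coef = short_vec, dir = "<=",
                                    rhs = s_lev + bound_slack(s_lev))))
    s2 <- if (r2$status == "optimal") milp_solution(inst, mod, r2, opts) else s1
    pareto_point(s2, metric, epsilon = eps)
  }

  cost_b <- ideal$shortage_solution$objective_cost
  grid <- if (!is.null(eps_grid)) sort(as.numeric(eps_grid))
          else seq(ideal$cost, cost_b, length.out = n_points)
  pts <- lapply(grid, solve_at)
  front <- filter_nondominated(pts)
  front$ideal <- c(cost = ideal$cost, shortage = ideal$shortage)
  front$metric <- metric
  front
}

#' Keep the non-dominated subset of a point set
#'
#' A point is dropped iff another point is no worse in both objectives and
#' strictly better in at least one. The result is ordered by cost ascending
#' (shortage descending on ties) and is idempotent under re-filtering.
#'
#' @param points list of `bsc_pareto_point`s.
#' @return a `bsc_pareto_front`.
#' @export
filter_nondominated <- function(points) {
  if (length(points) == 0)
    return(structure(list(points = list(), ideal = c(cost = NA_real_,
                                                     shortage = NA_real_),
                          metric = NA_character_), class = "bsc_pareto_front"))
  costs <- vapply(points, function(p) p$cost, 0)
  shorts <- vapply(points, function(p) p$shortage, 0)
  n <- length(points)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !keep[i]) next
      if (costs[j] <= costs[i] && shorts[j] <= shorts[i] &&
          (costs[j] < costs[i] || shorts[j] < shorts[i])) {
        keep[i] <- FALSE
      }
    }
  }
  idx <- which(keep)
  # drop duplicated objective pairs, keep stable order by cost
  ord <- idx[order(costs[idx], shorts[idx])]
  dedup <- ord[!duplicated(cbind(costs[ord], shorts[ord]))]
  structure(list(points = points[dedup],
                 ideal = c(cost = min(costs), shortage = min(shorts)),
                 metric = points[[1]]$metric),
            class = "bsc_pareto_front")
}

#' @export
print.bsc_pareto_front <- function(x, ...) {
  cat(sprintf("<bsc_pareto_front> %d points (%s)\n", length(x$points),
              x$metric))
  if (length(x$points) > 0) {
    df <- data.frame(
      epsilon = vapply(x$points, function(p) p$epsilon, 0),
      cost = vapply(x$points, function(p) p$cost, 0),
      shortage = vapply(x$points, function(p) p$shortage, 0))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Tabulate a Pareto front
#'
#' @param x a `bsc_pareto_front`.
#' @param ... unused.
#' @return data frame with columns `epsilon`, `cost`, `shortage`.
#' @export
as.data.frame.bsc_pareto_front <- function(x, ...) {
  data.frame(epsilon = vapply(x$points, function(p) p$epsilon, 0),
             cost = vapply(x$points, function(p) p$cost, 0),
             shortage = vapply(x$points, function(p) p$shortage, 0))
}
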