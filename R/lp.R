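# Linear-programming layer: thin R interface over the compiled two-phase
# simplex, plus the branch-and-bound driver used for the binary siting
# decisions.  Solves min c'x, A x (dir) b, x >= 0.

#' @useDynLib bloodnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Solve a linear program
#'
#' Minimizes `c'x` subject to `A x (dir) b` and `x >= 0`, using the package's
#' dense two-phase simplex. Intended for the moderate-size models this package
#' assembles; not a general sparse LP solver.
#'
#' @param obj numeric objective coefficient vector.
#' @param A dense constraint matrix (one row per constraint).
#' @param dir character vector of row senses: `"<="`, `"=="` (or `"="`), `">="`.
#' @param rhs numeric right-hand sides.
#' @param max_iter simplex pivot limit.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"limit"`), `x` (primal solution), `obj` (objective value) and `iter`
#'   (pivot count).
#' @keywords internal
lp_solve <- function(obj, A, dir, rhs, max_iter = 100000L) {
  stopifnot(is.matrix(A), length(obj) == ncol(A),
            length(dir) == nrow(A), length(rhs) == nrow(A))
  dcode <- match(dir, c("<=", "==", ">=", "="))
  if (anyNA(dcode)) stop("unknown constraint direction: ",
                         paste(unique(dir[is.na(dcode)]), collapse = ", "))
  dcode <- c(-1L, 0L, 1L, 0L)[dcode]
  res <- .simplex_core(as.numeric(obj), A, dcode, as.numeric(rhs),
                       as.integer(max_iter))
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "3" = "limit")
  list(status = status, x = as.numeric(res$x),
       obj = if (status == "optimal") res$obj else NA_real_,
       iter = res$iter)
}

#' Solve a mixed-binary linear program by branch and bound
#'
#' Depth-first branch and bound over [lp_solve()] relaxations. Binary
#' variables are controlled through dedicated bound rows (`x_j <= ub`,
#' `x_j >= lb`) whose right-hand sides are tightened per node, so each node
#' reuses the same matrix. An initial incumbent is sought by rounding the root
#' relaxation and fixing binaries.
#'
#' @param obj,A,dir,rhs as in [lp_solve()].
#' @param binary_idx integer indices of binary variables.
#' @param ub_rows,lb_rows row indices of the `x_j <= 1` and `x_j >= 0` bound
#'   rows of each binary, aligned with `binary_idx`.
#' @param fixed optional integer vector aligned with `binary_idx`: `NA` free,
#'   0/1 pre-fixed.
#' @param mip_gap relative optimality gap at which a node is pruned.
#' @param time_limit wall-clock seconds; `Inf` to disable.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"limit"`), `x`,
#'   `obj`, `nodes`.
#' @keywords internal
milp_solve <- function(obj, A, dir, rhs, binary_idx, ub_rows, lb_rows,
                       fixed = NULL, mip_gap = 1e-6, time_limit = Inf) {
  nb <- length(binary_idx)
  t0 <- Sys.time()
  int_tol <- 1e-6
  base_fix <- rep(NA_integer_, nb)
  if (!is.null(fixed)) base_fix <- as.integer(fixed)

  solve_node <- function(fix) {
    r <- rhs
    r[ub_rows] <- ifelse(is.na(fix), 1, fix)
    r[lb_rows] <- ifelse(is.na(fix) | fix == 0L, 0, 1)
    lp_solve(obj, A, dir, r)
  }
  frac_of <- function(x) {
    if (nb == 0L) return(numeric(0))
    v <- x[binary_idx]
    abs(v - round(v))
  }

  if (nb == 0L) {
    root <- solve_node(integer(0))
    return(list(status = root$status, x = root$x, obj = root$obj, nodes = 1L))
  }

  best_obj <- Inf
  best_x <- NULL
  nodes <- 0L
  hit_limit <- FALSE

  root <- solve_node(base_fix)
  nodes <- nodes + 1L
  if (root$status == "infeasible")
    return(list(status = "infeasible", x = NULL, obj = NA_real_, nodes = nodes))
  if (root$status != "optimal")
    return(list(status = "limit", x = NULL, obj = NA_real_, nodes = nodes))

  # Accepting an incumbent always goes through a re-solve with the binaries
  # hard-fixed at their rounded values: a relaxation solution that merely
  # looks integral (e.g. 1e-8 under a large big-M) is never trusted.
  try_incumbent <- function(fix, x) {
    f <- fix; free <- is.na(f)
    f[free] <- as.integer(round(x[binary_idx][free]))
    r <- solve_node(f)
    nodes <<- nodes + 1L
    if (r$status == "optimal" && r$obj < best_obj) {
      best_obj <<- r$obj; best_x <<- r$x
    }
    r
  }

  # rounding heuristic for an early incumbent (round up: opening more
  # facilities never removes feasibility in these models)
  fr <- frac_of(root$x)
  if (any(fr > int_tol)) {
    hfix <- base_fix
    free <- is.na(hfix)
    hfix[free] <- as.integer(root$x[binary_idx][free] > int_tol)
    h <- solve_node(hfix)
    nodes <- nodes + 1L
    if (h$status == "optimal" && h$obj < best_obj) {
      best_obj <- h$obj; best_x <- h$x
    }
  }

  stack <- list(list(fix = base_fix, bound = root$obj))
  while (length(stack) > 0L) {
    if (is.finite(time_limit) &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit) {
      hit_limit <- TRUE
      break
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    cutoff <- if (is.finite(best_obj))
      best_obj - mip_gap * max(1, abs(best_obj)) else Inf
    if (node$bound >= cutoff) next
    lp <- solve_node(node$fix)
    nodes <- nodes + 1L
    if (lp$status == "infeasible") next
    if (lp$status != "optimal") { hit_limit <- TRUE; next }
    if (lp$obj >= cutoff) next
    fr <- frac_of(lp$x)
    fr[!is.na(node$fix)] <- 0
    if (all(fr <= int_tol)) {
      r <- try_incumbent(node$fix, lp$x)
      # if fixing at the rounded values reproduces the node bound, the node
      # is solved; otherwise near-zero binaries were doing real work under a
      # big-M and the node must still be branched
      if (r$status == "optimal" &&
          r$obj <= lp$obj + 1e-7 * max(1, abs(lp$obj))) next
      if (all(fr <= 0)) next  # nothing left to branch on
    }
    j <- which.max(fr)
    v <- lp$x[binary_idx][j]
    first <- as.integer(v >= 0.5)
    f1 <- node$fix; f1[j] <- first
    f2 <- node$fix; f2[j] <- 1L - first
    # depth-first: push the less promising child first
    stack[[length(stack) + 1L]] <- list(fix = f2, bound = lp$obj)
    stack[[length(stack) + 1L]] <- list(fix = f1, bound = lp$obj)
  }

  if (is.null(best_x)) {
    status <- if (hit_limit) "limit" else "infeasible"
    return(list(status = status, x = NULL, obj = NA_real_, nodes = nodes))
  }
  list(status = if (hit_limit) "limit" else "optimal",
       x = best_x, obj = best_obj, nodes = nodes)
}
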