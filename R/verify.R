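# Solver-independent verification: a residual checker for every constraint
# family of the model, and exhaustive flow-based oracles that establish
# ground truth on tiny instances. Nothing here shares model-assembly code
# with the MILP builder: residuals are evaluated directly from the instance
# data, and the oracles replace the LP entirely (configuration enumeration
# plus augmenting-path max-flow / successive-shortest-path min-cost flow on
# a time-expanded network).
#
# The testing-survival fraction beta is a single uniform multiplier applied
# where raw collected units become usable units, so the flow network is
# expressed entirely in raw units: downstream capacities and demands are
# divided by beta, and delivered usable units are beta times the raw flow
# reaching the sink. This avoids generalized (gain) flows while remaining
# exact.

CHECK_FAMILIES <- c(paste0("eq", 1:18), "nonneg", "binarity")

#' Check a solution against every model constraint
#'
#' Independent re-evaluation of all constraint families directly from the
#' instance data: capacities (eq1/eq3/eq7/eq13), open-facility linkages
#' (eq2/eq4/eq8-eq11/eq15-eq17, with the symbolic big-M semantics: positive
#' flow through a closed facility is a violation), conservation (eq5/eq6),
#' inventory balance (eq12), demand accounting (eq14), service level (eq18),
#' nonnegativity and binarity. Reports, never raises.
#'
#' @param inst the single-scenario `bsc_instance` the solution refers to.
#' @param sol a `bsc_solution` (or compatible list).
#' @param tol absolute tolerance on residuals.
#' @return an object of class `bsc_check`: list with `passed` (logical) and
#'   `violations` (data frame: `family`, `index`, `magnitude`, `tolerance`).
#' @export
check_solution <- function(inst, sol, tol = 1e-6) {
  temp <- site_ids(inst, "temp"); perm <- site_ids(inst, "perm")
  cent <- site_ids(inst, "center"); trt <- site_ids(inst, "treat")
  nT <- n_periods(inst)
  trt_kind <- inst$sites$kind[match(trt, inst$sites$id)]
  dem_u <- demand_units(inst, 1L)

  viol <- list()
  flag <- function(family, index, magnitude) {
    if (magnitude > tol)
      viol[[length(viol) + 1L]] <<-
        data.frame(family = family, index = index, magnitude = magnitude,
                   tolerance = tol, stringsAsFactors = FALSE)
  }
  num_open <- function(v) as.numeric(v)

  CH <- sol$collected_temp; BH <- sol$collected_perm
  QT <- sol$ship_temp; QC <- sol$ship_perm; TH <- sol$deliver
  IN <- sol$inventory; IB <- sol$shortage
  X <- num_open(sol$open_temp)[match(temp, names(sol$open_temp))]
  Y <- num_open(sol$open_perm)[match(perm, names(sol$open_perm))]
  W <- num_open(sol$open_center)[match(cent, names(sol$open_center))]
  Fa <- num_open(sol$open_field)

  # binarity, and existing sites must be open
  opens <- c(X, Y, W, Fa)
  names(opens) <- c(temp, perm, cent, names(sol$open_field))
  for (k in seq_along(opens)) {
    v <- opens[k]
    flag("binarity", names(opens)[k], min(abs(v), abs(v - 1)))
  }
  for (role in c("temp", "perm", "center", "field")) {
    ids <- site_ids(inst, role)
    ex <- ids[site_exists(inst, ids)]
    for (id in ex)
      if (!is.na(opens[id]) && opens[id] < 0.5)
        flag("binarity", paste0(id, " (existing closed)"), 1)
  }

  # nonnegativity over all continuous quantities
  for (nm in c("collected_temp", "collected_perm", "ship_temp", "ship_perm",
               "deliver", "inventory", "shortage")) {
    v <- sol[[nm]]
    if (length(v) == 0) next
    flag("nonneg", nm, -min(0, min(v)))
  }

  is_cand <- function(ids) !site_exists(inst, ids)
  for (t in seq_len(nT)) {
    for (i in seq_along(temp)) {
      flag("eq1", sprintf("i=%s,t=%d", temp[i], t), CH[i, t] - inst$capa_temp[i, t])
      if (is_cand(temp)[i] && X[i] < 0.5)
        flag("eq2", sprintf("i=%s,t=%d", temp[i], t), CH[i, t])
      flag("eq5", sprintf("i=%s,t=%d", temp[i], t),
           abs(CH[i, t] - sum(QT[i, , t])))
      for (z in seq_along(cent)) {
        if (is_cand(cent)[z] && W[z] < 0.5)
          flag("eq8", sprintf("i=%s,z=%s,t=%d", temp[i], cent[z], t), QT[i, z, t])
        if (is_cand(temp)[i] && X[i] < 0.5)
          flag("eq10", sprintf("i=%s,z=%s,t=%d", temp[i], cent[z], t), QT[i, z, t])
      }
    }
    for (u in seq_along(perm)) {
      flag("eq3", sprintf("u=%s,t=%d", perm[u], t), BH[u, t] - inst$capa_perm[u, t])
      if (is_cand(perm)[u] && Y[u] < 0.5)
        flag("eq4", sprintf("u=%s,t=%d", perm[u], t), BH[u, t])
      flag("eq6", sprintf("u=%s,t=%d", perm[u], t),
           abs(BH[u, t] - sum(QC[u, , t])))
      for (z in seq_along(cent)) {
        if (is_cand(cent)[z] && W[z] < 0.5)
          flag("eq9", sprintf("u=%s,z=%s,t=%d", perm[u], cent[z], t), QC[u, z, t])
        if (is_cand(perm)[u] && Y[u] < 0.5)
          flag("eq11", sprintf("u=%s,z=%s,t=%d", perm[u], cent[z], t), QC[u, z, t])
      }
    }
    for (z in seq_along(cent)) {
      inflow <- sum(QT[, z, t]) + sum(QC[, z, t])
      flag("eq7", sprintf("z=%s,t=%d", cent[z], t),
           inflow - inst$capd_center[z, t])
      prev <- if (t == 1) inst$initial_inventory[z] else IN[z, t - 1]
      flag("eq12", sprintf("z=%s,t=%d", cent[z], t),
           abs(inst$beta * inflow + prev - sum(TH[z, , t]) - IN[z, t]))
      for (n in seq_along(trt)) {
        if (is_cand(cent)[z] && W[z] < 0.5)
          flag("eq15", sprintf("z=%s,n=%s,t=%d", cent[z], trt[n], t), TH[z, n, t])
        if (is_cand(trt)[n]) {
          open_n <- opens[trt[n]]
          fam <- if (trt_kind[n] == "permanent_facility") "eq16" else "eq17"
          if (!is.na(open_n) && open_n < 0.5)
            flag(fam, sprintf("z=%s,n=%s,t=%d", cent[z], trt[n], t), TH[z, n, t])
        }
      }
    }
    for (n in seq_along(trt))
      flag("eq13", sprintf("n=%s,t=%d", trt[n], t),
           sum(TH[, n, t]) - inst$capf_treat[n])
    delivered <- sum(TH[, , t])
    flag("eq14", sprintf("t=%d", t), abs(delivered + IB[t] - dem_u[t]))
    flag("eq18", sprintf("t=%d", t), inst$lam * dem_u[t] - delivered)
  }

  violations <- if (length(viol) > 0) do.call(rbind, viol) else
    data.frame(family = character(0), index = character(0),
               magnitude = numeric(0), tolerance = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(passed = nrow(violations) == 0, violations = violations),
            class = "bsc_check")
}

#' @export
print.bsc_check <- function(x, ...) {
  if (x$passed) cat("<bsc_check> passed: no constraint violations\n")
  else {
    cat(sprintf("<bsc_check> FAILED: %d violation(s)\n", nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}

# ---- flow primitives ----------------------------------------------------

# Edmonds-Karp max flow on a dense capacity matrix; optionally warm-started
# from an existing feasible flow.
ek_maxflow <- function(cap, s, t, flow0 = NULL) {
  n <- nrow(cap)
  flow <- if (is.null(flow0)) matrix(0, n, n) else flow0
  repeat {
    # BFS on the residual graph
    parent <- rep(NA_integer_, n)
    parent[s] <- s
    queue <- c(s); head <- 1L
    while (head <= length(queue) && is.na(parent[t])) {
      u <- queue[head]; head <- head + 1L
      res <- cap[u, ] - flow[u, ] + flow[, u]
      nxt <- which(res > 1e-9 & is.na(parent))
      parent[nxt] <- u
      queue <- c(queue, nxt)
    }
    if (is.na(parent[t])) break
    # bottleneck along the path
    path <- t; v <- t
    while (v != s) { v <- parent[v]; path <- c(v, path) }
    aug <- Inf
    for (k in seq_len(length(path) - 1)) {
      u <- path[k]; v <- path[k + 1]
      aug <- min(aug, cap[u, v] - flow[u, v] + flow[v, u])
    }
    for (k in seq_len(length(path) - 1)) {
      u <- path[k]; v <- path[k + 1]
      back <- min(flow[v, u], aug)
      flow[v, u] <- flow[v, u] - back
      flow[u, v] <- flow[u, v] + (aug - back)
    }
  }
  list(value = sum(flow[s, ]) - sum(flow[, s]), flow = flow)
}

# Successive-shortest-path min-cost flow: pushes as much flow as possible
# from s to t (up to `target`), at minimum cost. Bellman-Ford on the
# residual network (residual arcs carry negated costs).
ssp_mincost <- function(cap, cost, s, t, target = Inf) {
  n <- nrow(cap)
  flow <- matrix(0, n, n)
  total <- 0; total_cost <- 0
  while (total < target - 1e-9) {
    dist <- rep(Inf, n); dist[s] <- 0
    parent <- rep(NA_integer_, n)
    for (it in seq_len(n)) {
      changed <- FALSE
      for (u in seq_len(n)) {
        if (!is.finite(dist[u])) next
        fwd <- which(cap[u, ] - flow[u, ] > 1e-9)
        for (v in fwd) {
          nd <- dist[u] + cost[u, v]
          if (nd < dist[v] - 1e-12) { dist[v] <- nd; parent[v] <- u; changed <- TRUE }
        }
        bwd <- which(flow[, u] > 1e-9)
        for (v in bwd) {
          nd <- dist[u] - cost[v, u]
          if (nd < dist[v] - 1e-12) { dist[v] <- nd; parent[v] <- u; changed <- TRUE }
        }
      }
      if (!changed) break
    }
    if (!is.finite(dist[t])) break
    path <- t; v <- t
    while (v != s) { v <- parent[v]; path <- c(v, path) }
    aug <- target - total
    for (k in seq_len(length(path) - 1)) {
      u <- path[k]; v <- path[k + 1]
      fwd_res <- cap[u, v] - flow[u, v]
      aug <- min(aug, if (fwd_res > 1e-9) fwd_res + flow[v, u] else flow[v, u])
    }
    for (k in seq_len(length(path) - 1)) {
      u <- path[k]; v <- path[k + 1]
      back <- min(flow[v, u], aug)
      flow[v, u] <- flow[v, u] - back
      total_cost <- total_cost - back * cost[v, u]
      fwd <- aug - back
      flow[u, v] <- flow[u, v] + fwd
      total_cost <- total_cost + fwd * cost[u, v]
    }
    total <- total + aug
  }
  list(value = total, cost = total_cost, flow = flow)
}

# ---- time-expanded network ---------------------------------------------

# Build the raw-unit time-expanded network for one facility configuration.
# Nodes: source, open collection sites per period, center intake / pool per
# period (pool-to-pool arcs are the inventory), open treatment nodes per
# period, one demand node per period, sink.
flow_network <- function(inst, open_coll, open_cent, open_trt, sink_caps) {
  temp <- site_ids(inst, "temp"); perm <- site_ids(inst, "perm")
  cent <- site_ids(inst, "center"); trt <- site_ids(inst, "treat")
  coll <- c(temp, perm)
  nT <- n_periods(inst)
  beta <- inst$beta
  capa <- rbind(inst$capa_temp, inst$capa_perm)

  oc <- which(open_coll); oz <- which(open_cent); on_ <- which(open_trt)
  id <- 0L; node <- function() { id <<- id + 1L; id }
  S <- node()
  n_coll <- array(NA_integer_, c(length(coll), nT))
  n_cin <- array(NA_integer_, c(length(cent), nT))
  n_pool <- array(NA_integer_, c(length(cent), nT))
  n_trt <- array(NA_integer_, c(length(trt), nT))
  n_dem <- integer(nT)
  for (t in seq_len(nT)) {
    for (c_ in oc) n_coll[c_, t] <- node()
    for (z in oz) { n_cin[z, t] <- node(); n_pool[z, t] <- node() }
    for (n in on_) n_trt[n, t] <- node()
    n_dem[t] <- node()
  }
  Tn <- node()
  N <- id
  cap <- matrix(0, N, N); cost <- matrix(0, N, N)
  BIG <- sum(capa) + sum(inst$initial_inventory) / beta + 1
  utc <- inst$unit_transport_cost; ute <- inst$unit_test_cost
  for (t in seq_len(nT)) {
    for (c_ in oc) {
      cap[S, n_coll[c_, t]] <- capa[c_, t]
      for (z in oz) {
        cap[n_coll[c_, t], n_cin[z, t]] <- BIG
        cost[n_coll[c_, t], n_cin[z, t]] <- inst$dist_coll_center[c_, z] * utc + ute
      }
    }
    for (z in oz) {
      cap[n_cin[z, t], n_pool[z, t]] <- inst$capd_center[z, t]
      if (t == 1) cap[S, n_pool[z, 1]] <- inst$initial_inventory[z] / beta
      else cap[n_pool[z, t - 1], n_pool[z, t]] <- BIG
      for (n in on_) {
        cap[n_pool[z, t], n_trt[n, t]] <- BIG
        cost[n_pool[z, t], n_trt[n, t]] <- beta * inst$dist_center_treat[z, n] * utc
      }
    }
    for (n in on_) cap[n_trt[n, t], n_dem[t]] <- inst$capf_treat[n] / beta
    cap[n_dem[t], Tn] <- sink_caps[t] / beta
  }
  list(cap = cap, cost = cost, S = S, T = Tn, n_dem = n_dem, N = N)
}

# enumerate open configurations over candidate sites
enumerate_configs <- function(inst) {
  cand <- inst$sites[!inst$sites$exists &
                       inst$sites$kind != "treatment_center", , drop = FALSE]
  nc <- nrow(cand)
  if (nc > 12) stop("instance exceeds tiny bounds: ", 2^nc, " configurations")
  masks <- if (nc == 0) list(logical(0)) else
    lapply(seq_len(2^nc) - 1L, function(m) as.logical(bitwAnd(m, 2^(seq_len(nc) - 1)) > 0))
  list(cand_ids = cand$id, cand_setup = cand$setup_cost, masks = masks)
}

config_opens <- function(inst, cand_ids, mask) {
  temp <- site_ids(inst, "temp"); perm <- site_ids(inst, "perm")
  cent <- site_ids(inst, "center"); trt <- site_ids(inst, "treat")
  open_of <- function(ids) {
    v <- site_exists(inst, ids)
    m <- match(ids, cand_ids)
    v[!is.na(m)] <- mask[m[!is.na(m)]]
    v
  }
  list(coll = open_of(c(temp, perm)), cent = open_of(cent), trt = open_of(trt))
}

check_tiny <- function(inst) {
  if (n_scenarios(inst) != 1)
    stop("oracles need a single-scenario instance; restrict_to_scenario() first")
  diags <- validate_instance(inst)
  if (length(diags) > 0) stop("invalid instance: ", paste(diags, collapse = "; "))
}

# max deliverable per config: lambda feasibility then full augmentation
config_max_delivery <- function(inst, opens, dem_u) {
  lam_caps <- inst$lam * dem_u
  net <- flow_network(inst, opens$coll, opens$cent, opens$trt, lam_caps)
  f1 <- ek_maxflow(net$cap, net$S, net$T)
  need <- sum(lam_caps) / inst$beta
  if (f1$value < need - 1e-7) return(NULL)  # lambda infeasible
  net2 <- flow_network(inst, opens$coll, opens$cent, opens$trt, dem_u)
  f2 <- ek_maxflow(net2$cap, net2$S, net2$T, flow0 = f1$flow)
  list(delivered_raw = f2$value, flow = f2$flow, net = net2)
}

#' Exhaustive minimum-shortage oracle for tiny instances
#'
#' Enumerates every facility open-configuration and computes, for each, the
#' maximum deliverable usable units on the time-expanded flow network
#' (augmenting-path max flow in raw units; see the module notes on the beta
#' rescaling), subject to the per-period service level. Returns the minimum
#' over configurations of the total shortage, ignoring costs; `Inf` if no
#' configuration can meet the service level.
#'
#' @param inst a tiny single-scenario `bsc_instance` (at most 2^12
#'   configurations).
#' @return minimum total shortage in blood units (`Inf` if infeasible).
#' @export
oracle_min_shortage <- function(inst) {
  check_tiny(inst)
  dem_u <- demand_units(inst, 1L)
  en <- enumerate_configs(inst)
  best <- Inf
  for (mask in en$masks) {
    opens <- config_opens(inst, en$cand_ids, mask)
    r <- config_max_delivery(inst, opens, dem_u)
    if (is.null(r)) next
    shortage <- sum(dem_u) - inst$beta * r$delivered_raw
    best <- min(best, max(0, shortage))
  }
  best
}

#' Exhaustive minimum-cost oracle for tiny instances
#'
#' Enumerates facility configurations; for each configuration that can meet
#' the per-period service level, solves the remaining transport problem by
#' successive-shortest-path min-cost flow (per-unit costing), delivering
#' exactly the service-level requirement (delivering more never costs less).
#' Returns the minimum of setup plus flow cost, or `NA` if no configuration
#' is feasible (which must agree with MILP infeasibility).
#'
#' @param inst a tiny single-scenario `bsc_instance` with integer data.
#' @param require_lambda enforce the service level (the model's semantics);
#'   with `FALSE` the empty network at zero cost is always optimal.
#' @return minimum total cost, or `NA_real_` if infeasible.
#' @export
oracle_min_cost <- function(inst, require_lambda = TRUE) {
  check_tiny(inst)
  dem_u <- demand_units(inst, 1L)
  lam_caps <- if (require_lambda) inst$lam * dem_u else rep(0, length(dem_u))
  en <- enumerate_configs(inst)
  best <- NA_real_
  for (mask in en$masks) {
    opens <- config_opens(inst, en$cand_ids, mask)
    net <- flow_network(inst, opens$coll, opens$cent, opens$trt, lam_caps)
    need <- sum(lam_caps) / inst$beta
    if (need > 0) {
      feas <- ek_maxflow(net$cap, net$S, net$T)
      if (feas$value < need - 1e-7) next
    }
    sc <- ssp_mincost(net$cap, net$cost, net$S, net$T, target = need)
    total <- sum(en$cand_setup[mask]) + sc$cost
    if (is.na(best) || total < best) best <- total
  }
  best
}

#' Cross-validate the MILP solver against the flow oracles
#'
#' For each seed, generates a tiny instance, solves both objectives with the
#' MILP, and compares against [oracle_min_shortage()] and
#' [oracle_min_cost()]. Infeasibility verdicts must agree too.
#'
#' @param seeds integer vector of generator seeds.
#' @param solver solving function with the signature of
#'   [solve_single_objective()] (injectable for mutation testing).
#' @param dims tiny dimensions forwarded to [generate_tiny()].
#' @return data frame with one row per seed (objective values from both
#'   routes and a `match` flag); mismatching rows have `match = FALSE`.
#' @export
compare_solver_to_oracle <- function(seeds, solver = solve_single_objective,
                                     dims = list()) {
  if (length(seeds) == 0) {
    res <- data.frame(seed = integer(0), milp_shortage = numeric(0),
                      oracle_shortage = numeric(0), milp_cost = numeric(0),
                      oracle_cost = numeric(0), match = logical(0))
    attr(res, "mismatches") <- 0L
    return(res)
  }
  out <- lapply(seeds, function(seed) {
    inst <- generate_tiny(seed, dims)
    or_sh <- oracle_min_shortage(inst)
    or_ct <- oracle_min_cost(inst)
    sol_sh <- solver(inst, solve_options(objective = "shortage_units"))
    sol_ct <- solver(inst, solve_options(objective = "cost"))
    milp_sh <- if (sol_sh$solver_status == "optimal")
      sol_sh$objective_shortage_units else Inf
    milp_ct <- if (sol_ct$solver_status == "optimal")
      sol_ct$objective_cost else NA_real_
    feas_agree <- (is.finite(or_sh) == (sol_sh$solver_status == "optimal")) &&
      (!is.na(or_ct) == (sol_ct$solver_status == "optimal"))
    sh_ok <- if (is.finite(or_sh)) abs(milp_sh - or_sh) <= 1e-6 else TRUE
    ct_ok <- if (!is.na(or_ct))
      abs(milp_ct - or_ct) <= 1e-6 * max(1, abs(or_ct)) else TRUE
    data.frame(seed = seed,
               milp_shortage = milp_sh, oracle_shortage = or_sh,
               milp_cost = milp_ct, oracle_cost = or_ct,
               match = feas_agree && sh_ok && ct_ok,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "mismatches") <- sum(!res$match)
  res
}
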