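# Problem instances: typed container, validation, canonical JSON I/O.
#
# An instance holds the whole network design problem: facility sites with
# candidate/existing status and setup costs, response periods, demand
# scenarios, per-period capacities, per-scenario demand, the two distance
# layers (collection -> blood center, blood center -> treatment), unit costs
# and the model parameters alpha (fraction of injured needing transfusion),
# beta (fraction of collected blood passing testing) and lambda (minimum
# per-period service level).

SITE_KINDS <- c("temporary_collection", "permanent_facility", "blood_center",
                "treatment_center", "field_hospital")

#' Construct a blood supply chain network instance
#'
#' Builds and validates the full problem description used by every solver in
#' the package. Collection happens at temporary and permanent sites, collected
#' blood is tested and stored at blood centers (a fraction `beta` survives
#' testing), and usable units are delivered to treatment nodes (permanent
#' facilities, standing treatment centers and candidate field hospitals) to
#' cover transfusion demand `alpha * demand * units_per_patient` per period.
#'
#' @param sites data frame with columns `id`, `kind` (one of
#'   `temporary_collection`, `permanent_facility`, `blood_center`,
#'   `treatment_center`, `field_hospital`), `exists`
#'   (logical; existing sites are open and never charged a setup cost),
#'   `setup_cost`, and optional coordinates `x`, `y` in km.
#' @param periods numeric vector of period lengths in hours (metadata; the
#'   model is period-indexed).
#' @param scenarios data frame with columns `id`, `probability`,
#'   `demand_multiplier`, `setup_cost_multiplier`, `capacity_multiplier`;
#'   defaults to a single certain scenario with all multipliers 1.
#' @param capa_temp,capa_perm collection capacity matrices (site x period), in
#'   blood units per period, rows ordered like the corresponding sites.
#' @param capd_center blood-center intake/processing capacity (site x period),
#'   in raw collected units per period.
#' @param capf_treat named vector of treatment capacity per treatment node, in
#'   usable blood units per period.
#' @param demand base demand in injured persons: either a length-`T` vector
#'   (shared across scenarios) or a `T x S` matrix. Scenario demand
#'   multipliers are applied on top of these values.
#' @param dist_coll_center distance matrix (collection sites x blood centers),
#'   km. Collection sites are the temporary sites followed by the permanent
#'   facilities, in site order. `NULL` to derive from coordinates (Euclidean).
#' @param dist_center_treat distance matrix (blood centers x treatment nodes),
#'   km; `NULL` to derive from coordinates.
#' @param unit_transport_cost currency per unit and km.
#' @param unit_test_cost currency per raw unit entering a blood center.
#' @param vehicle_capacity units per truck trip (used by the integral-vehicle
#'   costing mode).
#' @param alpha,beta,lam model fractions in (0, 1]; see Details.
#' @param units_per_patient blood units required per transfused patient.
#' @param initial_inventory named vector of usable units held at each blood
#'   center before period 1; defaults to zero.
#' @param id instance identifier string.
#' @return an object of class `bsc_instance`.
#' @seealso [validate_instance()], [load_instance()], [save_instance()]
#' @export
network_instance <- function(sites, periods, scenarios = NULL,
                             capa_temp, capa_perm, capd_center, capf_treat,
                             demand,
                             dist_coll_center = NULL, dist_center_treat = NULL,
                             unit_transport_cost = 5000,
                             unit_test_cost = 5000,
                             vehicle_capacity = 100,
                             alpha = 0.8, beta = 0.8, lam = 0.7,
                             units_per_patient = 1,
                             initial_inventory = NULL,
                             id = "instance") {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (is.null(sites$x)) sites$x <- NA_real_
  if (is.null(sites$y)) sites$y <- NA_real_
  sites$id <- as.character(sites$id)
  sites$kind <- as.character(sites$kind)
  sites$exists <- as.logical(sites$exists)
  sites$setup_cost <- as.numeric(sites$setup_cost)
  sites <- sites[, c("id", "kind", "exists", "setup_cost", "x", "y")]
  rownames(sites) <- NULL

  if (is.null(scenarios)) {
    scenarios <- data.frame(id = "s1", probability = 1,
                            demand_multiplier = 1, setup_cost_multiplier = 1,
                            capacity_multiplier = 1,
                            stringsAsFactors = FALSE)
  }
  scenarios <- as.data.frame(scenarios, stringsAsFactors = FALSE)
  scenarios$id <- as.character(scenarios$id)
  for (cl in c("probability", "demand_multiplier", "setup_cost_multiplier",
               "capacity_multiplier"))
    scenarios[[cl]] <- as.numeric(scenarios[[cl]])
  rownames(scenarios) <- NULL

  nT <- length(periods)
  nS <- nrow(scenarios)
  temp_ids <- sites$id[sites$kind == "temporary_collection"]
  perm_ids <- sites$id[sites$kind == "permanent_facility"]
  center_ids <- sites$id[sites$kind == "blood_center"]
  treat_ids <- sites$id[sites$kind %in%
                          c("permanent_facility", "treatment_center",
                            "field_hospital")]
  coll_ids <- c(temp_ids, perm_ids)

  as_cap_matrix <- function(x, ids, what) {
    x <- as.matrix(x)
    if (nrow(x) != length(ids) || ncol(x) != nT)
      stop(sprintf("%s must be %d x %d (sites x periods)", what,
                   length(ids), nT))
    dimnames(x) <- list(ids, NULL)
    x
  }
  capa_temp <- as_cap_matrix(capa_temp, temp_ids, "capa_temp")
  capa_perm <- as_cap_matrix(capa_perm, perm_ids, "capa_perm")
  capd_center <- as_cap_matrix(capd_center, center_ids, "capd_center")
  capf_treat <- as.numeric(capf_treat)[seq_along(treat_ids)]
  names(capf_treat) <- treat_ids

  if (is.matrix(demand)) {
    if (nrow(demand) != nT || ncol(demand) != nS)
      stop("demand matrix must be periods x scenarios")
    demand <- matrix(as.numeric(demand), nT, nS)
  } else {
    if (length(demand) != nT) stop("demand vector must have one entry per period")
    demand <- matrix(as.numeric(demand), nT, nS)
  }
  dimnames(demand) <- list(NULL, scenarios$id)

  euclid <- function(from_ids, to_ids) {
    fx <- sites$x[match(from_ids, sites$id)]
    fy <- sites$y[match(from_ids, sites$id)]
    tx <- sites$x[match(to_ids, sites$id)]
    ty <- sites$y[match(to_ids, sites$id)]
    m <- sqrt(outer(fx, tx, "-")^2 + outer(fy, ty, "-")^2)
    dimnames(m) <- list(from_ids, to_ids)
    m
  }
  if (is.null(dist_coll_center)) dist_coll_center <- euclid(coll_ids, center_ids)
  if (is.null(dist_center_treat)) dist_center_treat <- euclid(center_ids, treat_ids)
  dist_coll_center <- matrix(as.numeric(as.matrix(dist_coll_center)),
                             length(coll_ids), length(center_ids),
                             dimnames = list(coll_ids, center_ids))
  dist_center_treat <- matrix(as.numeric(as.matrix(dist_center_treat)),
                              length(center_ids), length(treat_ids),
                              dimnames = list(center_ids, treat_ids))

  if (is.null(initial_inventory)) {
    initial_inventory <- rep(0, length(center_ids))
  }
  initial_inventory <- as.numeric(initial_inventory)[seq_along(center_ids)]
  names(initial_inventory) <- center_ids

  inst <- structure(list(
    id = as.character(id),
    sites = sites,
    periods = as.numeric(periods),
    scenarios = scenarios,
    capa_temp = capa_temp,
    capa_perm = capa_perm,
    capd_center = capd_center,
    capf_treat = capf_treat,
    demand = demand,
    dist_coll_center = dist_coll_center,
    dist_center_treat = dist_center_treat,
    unit_transport_cost = as.numeric(unit_transport_cost),
    unit_test_cost = as.numeric(unit_test_cost),
    vehicle_capacity = as.numeric(vehicle_capacity),
    alpha = as.numeric(alpha),
    beta = as.numeric(beta),
    lam = as.numeric(lam),
    units_per_patient = as.numeric(units_per_patient),
    initial_inventory = initial_inventory
  ), class = "bsc_instance")
  inst
}

# ---- internal site helpers ---------------------------------------------

site_ids <- function(inst, role) {
  s <- inst$sites
  switch(role,
         temp = s$id[s$kind == "temporary_collection"],
         perm = s$id[s$kind == "permanent_facility"],
         center = s$id[s$kind == "blood_center"],
         field = s$id[s$kind == "field_hospital"],
         treat_existing = s$id[s$kind == "treatment_center"],
         coll = c(s$id[s$kind == "temporary_collection"],
                  s$id[s$kind == "permanent_facility"]),
         treat = s$id[s$kind %in% c("permanent_facility", "treatment_center",
                                    "field_hospital")],
         stop("unknown role ", role))
}

site_exists <- function(inst, ids) {
  inst$sites$exists[match(ids, inst$sites$id)]
}

site_setup <- function(inst, ids) {
  stats::setNames(inst$sites$setup_cost[match(ids, inst$sites$id)], ids)
}

n_periods <- function(inst) length(inst$periods)
n_scenarios <- function(inst) nrow(inst$scenarios)

# effective per-scenario values (scenario multipliers applied)
eff_demand <- function(inst, s) {
  inst$demand[, s] * inst$scenarios$demand_multiplier[s]
}
eff_cap <- function(m, inst, s) m * inst$scenarios$capacity_multiplier[s]

#' Validate a network instance
#'
#' Checks every structural invariant of the instance and returns diagnostics
#' instead of raising: an empty character vector means the instance is valid.
#' Each diagnostic names the violated invariant and the offending element.
#'
#' @param inst a `bsc_instance` (or anything; a non-instance yields a
#'   diagnostic, never an error).
#' @return character vector of diagnostics (empty if valid).
#' @export
validate_instance <- function(inst) {
  d <- character(0)
  say <- function(...) d <<- c(d, sprintf(...))
  if (!inherits(inst, "bsc_instance")) return("not a bsc_instance object")

  s <- inst$sites
  if (anyDuplicated(s$id)) say("duplicate site ids: %s",
                               paste(unique(s$id[duplicated(s$id)]), collapse = ", "))
  bad_kind <- !(s$kind %in% SITE_KINDS)
  if (any(bad_kind)) say("unknown site kind for %s",
                         paste(s$id[bad_kind], collapse = ", "))
  if (any(is.na(s$setup_cost) | s$setup_cost < 0))
    say("negative or missing setup_cost for %s",
        paste(s$id[is.na(s$setup_cost) | s$setup_cost < 0], collapse = ", "))
  tc_cand <- s$kind == "treatment_center" & !s$exists
  if (any(tc_cand))
    say("treatment_center sites must be existing (candidates are modeled as field hospitals): %s",
        paste(s$id[tc_cand], collapse = ", "))

  sc <- inst$scenarios
  if (nrow(sc) == 0) say("instance has no scenarios")
  if (any(is.na(sc$probability) | sc$probability <= 0 | sc$probability > 1))
    say("scenario probability outside (0,1] for %s",
        paste(sc$id[is.na(sc$probability) | sc$probability <= 0 |
                      sc$probability > 1], collapse = ", "))
  if (nrow(sc) > 0 && abs(sum(sc$probability) - 1) > 1e-9)
    say("scenario probabilities sum != 1 (sum = %.12g)", sum(sc$probability))
  if (any(is.na(sc$demand_multiplier) | sc$demand_multiplier < 0))
    say("negative demand_multiplier for %s",
        paste(sc$id[is.na(sc$demand_multiplier) | sc$demand_multiplier < 0],
              collapse = ", "))
  if (any(is.na(sc$setup_cost_multiplier) | sc$setup_cost_multiplier < 0))
    say("negative setup_cost_multiplier for %s",
        paste(sc$id[is.na(sc$setup_cost_multiplier) |
                      sc$setup_cost_multiplier < 0], collapse = ", "))
  if (any(is.na(sc$capacity_multiplier) | sc$capacity_multiplier <= 0))
    say("capacity_multiplier must be > 0 for %s",
        paste(sc$id[is.na(sc$capacity_multiplier) |
                      sc$capacity_multiplier <= 0], collapse = ", "))

  for (p in c("alpha", "beta", "lam")) {
    v <- inst[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1)
      say("%s must be a fraction in (0,1], got %s", p, format(v))
  }
  for (p in c("unit_transport_cost", "unit_test_cost", "vehicle_capacity",
              "units_per_patient")) {
    v <- inst[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      say("%s must be a nonnegative scalar", p)
  }

  check_mat <- function(m, what) {
    bad <- which(is.na(m) | m < 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      for (k in seq_len(min(nrow(bad), 5)))
        say("negative or missing %s[%s,%s]", what,
            if (!is.null(rownames(m))) rownames(m)[bad[k, 1]] else bad[k, 1],
            bad[k, 2])
      if (nrow(bad) > 5) say("... and %d more in %s", nrow(bad) - 5, what)
    }
  }
  check_mat(inst$capa_temp, "capa_temp")
  check_mat(inst$capa_perm, "capa_perm")
  check_mat(inst$capd_center, "capd_center")
  if (any(is.na(inst$capf_treat) | inst$capf_treat < 0))
    say("negative or missing capf_treat for %s",
        paste(names(inst$capf_treat)[is.na(inst$capf_treat) |
                                       inst$capf_treat < 0], collapse = ", "))
  check_mat(inst$demand, "demand")
  if (any(is.na(inst$initial_inventory) | inst$initial_inventory < 0))
    say("negative or missing initial_inventory")

  if (anyNA(inst$dist_coll_center) || any(inst$dist_coll_center < 0, na.rm = TRUE))
    say("incomplete distance matrix dist_coll_center (missing or negative entries)")
  if (anyNA(inst$dist_center_treat) || any(inst$dist_center_treat < 0, na.rm = TRUE))
    say("incomplete distance matrix dist_center_treat (missing or negative entries)")

  d
}

#' Restrict a multi-scenario instance to one deterministic scenario
#'
#' Applies all of scenario `s`'s multipliers (demand, temporary setup costs,
#' capacities) and returns a single-scenario instance with probability 1 and
#' neutral multipliers.
#'
#' @param inst a `bsc_instance`.
#' @param s scenario id (or index).
#' @return a single-scenario `bsc_instance`.
#' @export
restrict_to_scenario <- function(inst, s) {
  if (is.character(s)) {
    si <- match(s, inst$scenarios$id)
    if (is.na(si)) stop("unknown scenario id: ", s)
  } else {
    si <- as.integer(s)
    if (si < 1 || si > n_scenarios(inst)) stop("unknown scenario index: ", s)
  }
  sc <- inst$scenarios[si, ]
  out <- inst
  out$scenarios <- data.frame(id = sc$id, probability = 1,
                              demand_multiplier = 1, setup_cost_multiplier = 1,
                              capacity_multiplier = 1, stringsAsFactors = FALSE)
  out$demand <- matrix(inst$demand[, si] * sc$demand_multiplier,
                       ncol = 1, dimnames = list(NULL, sc$id))
  out$capa_temp <- inst$capa_temp * sc$capacity_multiplier
  out$capa_perm <- inst$capa_perm * sc$capacity_multiplier
  out$capd_center <- inst$capd_center * sc$capacity_multiplier
  out$capf_treat <- inst$capf_treat * sc$capacity_multiplier
  is_temp <- out$sites$kind == "temporary_collection"
  out$sites$setup_cost[is_temp] <-
    out$sites$setup_cost[is_temp] * sc$setup_cost_multiplier
  out
}

#' @export
print.bsc_instance <- function(x, ...) {
  tab <- table(factor(x$sites$kind, levels = SITE_KINDS))
  cat(sprintf("<bsc_instance '%s'>\n", x$id))
  cat(sprintf("  sites: %d temporary, %d permanent, %d blood centers, %d treatment centers, %d field hospitals\n",
              tab[1], tab[2], tab[3], tab[4], tab[5]))
  cat(sprintf("  periods: %d (%s h); scenarios: %d (p = %s)\n",
              length(x$periods), paste(x$periods, collapse = "/"),
              nrow(x$scenarios),
              paste(format(x$scenarios$probability), collapse = "/")))
  cat(sprintf("  alpha %.3g, beta %.3g, lambda %.3g; demand %g..%g persons/period\n",
              x$alpha, x$beta, x$lam, min(x$demand), max(x$demand)))
  invisible(x)
}

# ---- serialization ------------------------------------------------------

instance_to_list <- function(inst) {
  # canonical representation: object keys alphabetical, arrays in declared
  # site order
  sites <- lapply(seq_len(nrow(inst$sites)), function(i) {
    r <- inst$sites[i, ]
    out <- list(exists = r$exists, id = r$id, kind = r$kind,
                setup_cost = r$setup_cost)
    if (!is.na(r$x) && !is.na(r$y)) { out$x <- r$x; out$y <- r$y }
    out[order(names(out))]
  })
  scen <- lapply(seq_len(nrow(inst$scenarios)), function(i) {
    r <- inst$scenarios[i, ]
    list(capacity_multiplier = r$capacity_multiplier,
         demand_multiplier = r$demand_multiplier,
         id = r$id,
         probability = r$probability,
         setup_cost_multiplier = r$setup_cost_multiplier)
  })
  mat_rows <- function(m) unname(lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
  list(
    capacities = list(center = mat_rows(inst$capd_center),
                      permanent = mat_rows(inst$capa_perm),
                      temporary = mat_rows(inst$capa_temp),
                      treatment = unname(inst$capf_treat)),
    costs = list(unit_test = inst$unit_test_cost,
                 unit_transport = inst$unit_transport_cost),
    demand = mat_rows(inst$demand),
    distances = list(center_treat = mat_rows(inst$dist_center_treat),
                     coll_center = mat_rows(inst$dist_coll_center)),
    id = inst$id,
    params = list(alpha = inst$alpha, beta = inst$beta,
                  initial_inventory = unname(inst$initial_inventory),
                  lambda = inst$lam,
                  units_per_patient = inst$units_per_patient,
                  vehicle_capacity = inst$vehicle_capacity),
    periods = inst$periods,
    scenarios = scen,
    sites = sites
  )
}

#' Write an instance to its canonical JSON form
#'
#' The serialization is canonical (alphabetical keys, arrays in declared site
#' order, full numeric precision), so identical instances always produce
#' byte-identical files.
#'
#' @param inst a `bsc_instance`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_instance <- function(inst, path) {
  json <- jsonlite::toJSON(instance_to_list(inst), auto_unbox = TRUE,
                           digits = NA, pretty = 2)
  writeLines(json, path)
  invisible(path)
}

#' Read an instance from a JSON file
#'
#' Accepts the schema written by [save_instance()]. The three matrices
#' (distances and capacities) may alternatively be given as strings naming CSV
#' sidecar files (with site-id headers), resolved relative to the instance
#' file. The loaded instance is validated; any invariant violation is a
#' structured error naming the offending field.
#'
#' @param path path to the instance JSON document.
#' @return a validated `bsc_instance`.
#' @export
load_instance <- function(path) {
  if (!file.exists(path)) stop("instance file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- function(key, where = doc, ctx = "instance") {
    if (is.null(where[[key]]))
      stop(sprintf("instance schema violation: missing field '%s' in %s", key, ctx))
    where[[key]]
  }
  sites <- do.call(rbind, lapply(need("sites"), function(s) {
    data.frame(id = as.character(need("id", s, "site")),
               kind = as.character(need("kind", s, "site")),
               exists = as.logical(need("exists", s, "site")),
               setup_cost = as.numeric(need("setup_cost", s, "site")),
               x = if (is.null(s$x)) NA_real_ else as.numeric(s$x),
               y = if (is.null(s$y)) NA_real_ else as.numeric(s$y),
               stringsAsFactors = FALSE)
  }))
  scen <- do.call(rbind, lapply(need("scenarios"), function(s) {
    data.frame(id = as.character(need("id", s, "scenario")),
               probability = as.numeric(need("probability", s, "scenario")),
               demand_multiplier = as.numeric(need("demand_multiplier", s, "scenario")),
               setup_cost_multiplier = as.numeric(need("setup_cost_multiplier", s, "scenario")),
               capacity_multiplier = as.numeric(need("capacity_multiplier", s, "scenario")),
               stringsAsFactors = FALSE)
  }))
  periods <- as.numeric(unlist(need("periods")))
  nT <- length(periods)

  read_matrix <- function(node, nr, nc, what) {
    if (is.character(node) && length(node) == 1) {
      f <- file.path(dirname(path), node)
      if (!file.exists(f)) stop("CSV sidecar not found for ", what, ": ", f)
      m <- as.matrix(utils::read.csv(f, row.names = 1, check.names = FALSE))
      return(unname(m))
    }
    m <- do.call(rbind, lapply(node, function(r) as.numeric(unlist(r))))
    if (is.null(m)) m <- matrix(numeric(0), 0, nc)
    if (nrow(m) != nr || ncol(m) != nc)
      stop(sprintf("instance schema violation: field '%s' must be %d x %d",
                   what, nr, nc))
    m
  }
  caps <- need("capacities")
  dists <- need("distances")
  costs <- need("costs")
  params <- need("params")

  n_temp <- sum(sites$kind == "temporary_collection")
  n_perm <- sum(sites$kind == "permanent_facility")
  n_center <- sum(sites$kind == "blood_center")
  n_treat <- sum(sites$kind %in% c("permanent_facility", "treatment_center",
                                   "field_hospital"))
  dm_node <- need("demand")
  dm <- if (!is.list(dm_node) || !is.list(dm_node[[1]])) {
    matrix(as.numeric(unlist(dm_node)), nT, nrow(scen))
  } else read_matrix(dm_node, nT, nrow(scen), "demand")

  inst <- network_instance(
    sites = sites, periods = periods, scenarios = scen,
    capa_temp = read_matrix(need("temporary", caps, "capacities"), n_temp, nT, "capacities.temporary"),
    capa_perm = read_matrix(need("permanent", caps, "capacities"), n_perm, nT, "capacities.permanent"),
    capd_center = read_matrix(need("center", caps, "capacities"), n_center, nT, "capacities.center"),
    capf_treat = as.numeric(unlist(need("treatment", caps, "capacities"))),
    demand = dm,
    dist_coll_center = read_matrix(need("coll_center", dists, "distances"),
                                   n_temp + n_perm, n_center, "distances.coll_center"),
    dist_center_treat = read_matrix(need("center_treat", dists, "distances"),
                                    n_center, n_treat, "distances.center_treat"),
    unit_transport_cost = as.numeric(need("unit_transport", costs, "costs")),
    unit_test_cost = as.numeric(need("unit_test", costs, "costs")),
    vehicle_capacity = as.numeric(need("vehicle_capacity", params, "params")),
    alpha = as.numeric(need("alpha", params, "params")),
    beta = as.numeric(need("beta", params, "params")),
    lam = as.numeric(need("lambda", params, "params")),
    units_per_patient = if (is.null(params$units_per_patient)) 1
                        else as.numeric(params$units_per_patient),
    initial_inventory = if (is.null(params$initial_inventory)) NULL
                        else as.numeric(unlist(params$initial_inventory)),
    id = as.character(need("id"))
  )
  diags <- validate_instance(inst)
  if (length(diags) > 0)
    stop("invalid instance '", path, "':\n  ", paste(diags, collapse = "\n  "))
  inst
}
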