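# Seeded synthetic instance generation.
#
# No public dataset exists for the case study this package emulates (the case
# data appear only as figures), so instances are generated from a documented
# profile: site counts, capacity/cost/distance ranges, a front-loaded demand
# shape over the response periods, and scenario multipliers that grow with
# crisis severity. The default profile reproduces the published network
# shape: 8 temporary collection sites, 5 permanent facilities (collection +
# treatment), 3 blood centers and 5 candidate field hospitals, 4 periods,
# and 3 scenarios with probabilities 0.15 / 0.35 / 0.5.

#' Construct a generator profile
#'
#' A profile fixes everything [generate_instance()] needs: site counts,
#' ranges to draw capacities, setup costs and distances from, the per-period
#' demand shape and the scenario set. All ranges are `c(low, high)` pairs.
#'
#' @param counts named list with `n_temp`, `n_perm`, `n_center`,
#'   `n_treat_existing`, `n_field`.
#' @param period_hours period lengths in hours.
#' @param scenarios scenario data frame (see [network_instance()]).
#' @param demand_base range of period-1 demand in injured persons.
#' @param demand_period_shape per-period multipliers applied to the base
#'   demand (length = number of periods).
#' @param distance_range range of inter-facility distances in km.
#' @param capacity named list of ranges (`temp`, `perm`, `center`, `treat`)
#'   in blood units per period.
#' @param setup named list of setup-cost ranges (`temp`, `perm`, `center`,
#'   `field`) in currency units.
#' @param n_perm_existing,n_center_existing how many permanent facilities /
#'   blood centers already exist (the rest are candidates; temporary sites
#'   and field hospitals are always candidates).
#' @param alpha,beta,lam,vehicle_capacity,unit_transport_cost,unit_test_cost,units_per_patient
#'   model parameters, see [network_instance()].
#' @return an object of class `bsc_profile`.
#' @export
generator_profile <- function(counts, period_hours, scenarios,
                              demand_base, demand_period_shape,
                              distance_range = c(1, 30),
                              capacity, setup,
                              n_perm_existing = 0, n_center_existing = 0,
                              alpha = 0.8, beta = 0.8, lam = 0.7,
                              vehicle_capacity = 100,
                              unit_transport_cost = 5000,
                              unit_test_cost = 5000,
                              units_per_patient = 1) {
  p <- structure(list(
    counts = counts, period_hours = as.numeric(period_hours),
    scenarios = as.data.frame(scenarios, stringsAsFactors = FALSE),
    demand_base = as.numeric(demand_base),
    demand_period_shape = as.numeric(demand_period_shape),
    distance_range = as.numeric(distance_range),
    capacity = capacity, setup = setup,
    n_perm_existing = n_perm_existing,
    n_center_existing = n_center_existing,
    alpha = alpha, beta = beta, lam = lam,
    vehicle_capacity = vehicle_capacity,
    unit_transport_cost = unit_transport_cost,
    unit_test_cost = unit_test_cost,
    units_per_patient = units_per_patient
  ), class = "bsc_profile")
  diags <- validate_profile(p)
  if (length(diags) > 0)
    stop("invalid generator profile:\n  ", paste(diags, collapse = "\n  "))
  p
}

validate_profile <- function(p) {
  d <- character(0)
  say <- function(...) d <<- c(d, sprintf(...))
  for (k in c("n_temp", "n_perm", "n_center", "n_treat_existing", "n_field"))
    if (is.null(p$counts[[k]]) || p$counts[[k]] < 0)
      say("counts$%s missing or negative", k)
  rng_ok <- function(r) length(r) == 2 && !anyNA(r) && r[1] >= 0 && r[1] <= r[2]
  if (!rng_ok(p$demand_base)) say("demand_base is not a valid range")
  if (!rng_ok(p$distance_range)) say("distance_range is not a valid range")
  for (k in names(p$capacity))
    if (!rng_ok(p$capacity[[k]])) say("capacity$%s is not a valid range", k)
  for (k in names(p$setup))
    if (!rng_ok(p$setup[[k]])) say("setup$%s is not a valid range", k)
  if (length(p$demand_period_shape) != length(p$period_hours))
    say("demand_period_shape must have one multiplier per period")
  if (abs(sum(p$scenarios$probability) - 1) > 1e-9)
    say("scenario probabilities sum != 1")
  if (is.unsorted(p$scenarios$demand_multiplier))
    say("scenario demand multipliers must be non-decreasing with severity")
  d
}

#' The default case-study-shaped generator profile
#'
#' Emulates the published urban disaster-response network: 8 temporary
#' collection sites, 5 permanent facilities (2 existing, 3 candidates) that
#' both collect and treat, 3 blood centers (1 existing) at a setup cost of
#' one billion currency units each, and 5 candidate field hospitals; 4
#' response periods (0-24 h, 24-72 h, the next 72 h, the following week) with
#' front-loaded demand; 3 severity scenarios with probabilities 0.15, 0.35
#' and 0.5 and demand, setup-cost and capacity multipliers growing with
#' severity. Fractions alpha = beta = 0.8, service level lambda = 0.7,
#' 100-unit vehicles, and 5000 currency units per unit-km transported and per
#' unit tested.
#'
#' @return a `bsc_profile`.
#' @export
kermanshah_profile <- function() {
  generator_profile(
    counts = list(n_temp = 8, n_perm = 5, n_center = 3,
                  n_treat_existing = 0, n_field = 5),
    period_hours = c(24, 48, 72, 168),
    scenarios = data.frame(
      id = c("mild", "moderate", "severe"),
      probability = c(0.15, 0.35, 0.5),
      demand_multiplier = c(1, 1.4, 1.8),
      setup_cost_multiplier = c(1, 1.15, 1.3),
      capacity_multiplier = c(1, 1.1, 1.2),
      stringsAsFactors = FALSE),
    demand_base = c(3000, 4500),
    demand_period_shape = c(1, 0.8, 0.6, 0.4),
    distance_range = c(1, 30),
    capacity = list(temp = c(400, 700), perm = c(600, 1100),
                    center = c(2000, 3000), treat = c(1000, 1600)),
    setup = list(temp = c(1e6, 5e6), perm = c(2e8, 6e8),
                 center = c(1e9, 1e9), field = c(3e8, 8e8)),
    n_perm_existing = 2, n_center_existing = 1,
    alpha = 0.8, beta = 0.8, lam = 0.7,
    vehicle_capacity = 100,
    unit_transport_cost = 5000, unit_test_cost = 5000,
    units_per_patient = 1
  )
}

runifr <- function(n, r) stats::runif(n, r[1], r[2])

#' Generate a network instance from a profile
#'
#' Fully deterministic in `(profile, seed)`: all draws come from the
#' profile's ranges under a local RNG seed (the caller's RNG state is left
#' untouched). The generated instance always validates.
#'
#' @param profile a `bsc_profile`.
#' @param seed integer seed.
#' @return a `bsc_instance`.
#' @export
generate_instance <- function(profile, seed) {
  stopifnot(inherits(profile, "bsc_profile"))
  cn <- profile$counts
  nT <- length(profile$period_hours)
  with_seed(seed, {
    mk_ids <- function(prefix, n) if (n > 0) sprintf("%s%d", prefix, seq_len(n)) else character(0)
    temp_ids <- mk_ids("T", cn$n_temp)
    perm_ids <- mk_ids("H", cn$n_perm)
    cent_ids <- mk_ids("B", cn$n_center)
    tc_ids <- mk_ids("C", cn$n_treat_existing)
    field_ids <- mk_ids("F", cn$n_field)

    perm_exists <- seq_len(cn$n_perm) <= profile$n_perm_existing
    cent_exists <- seq_len(cn$n_center) <= profile$n_center_existing
    sites <- data.frame(
      id = c(temp_ids, perm_ids, cent_ids, tc_ids, field_ids),
      kind = c(rep("temporary_collection", cn$n_temp),
               rep("permanent_facility", cn$n_perm),
               rep("blood_center", cn$n_center),
               rep("treatment_center", cn$n_treat_existing),
               rep("field_hospital", cn$n_field)),
      exists = c(rep(FALSE, cn$n_temp), perm_exists, cent_exists,
                 rep(TRUE, cn$n_treat_existing), rep(FALSE, cn$n_field)),
      setup_cost = c(round(runifr(cn$n_temp, profile$setup$temp)),
                     ifelse(perm_exists, 0,
                            round(runifr(cn$n_perm, profile$setup$perm))),
                     ifelse(cent_exists, 0,
                            round(runifr(cn$n_center, profile$setup$center))),
                     rep(0, cn$n_treat_existing),
                     round(runifr(cn$n_field, profile$setup$field))),
      stringsAsFactors = FALSE)

    cap_draw <- function(n, rng) matrix(round(runifr(n * nT, rng)), n, nT)
    capa_temp <- cap_draw(cn$n_temp, profile$capacity$temp)
    capa_perm <- cap_draw(cn$n_perm, profile$capacity$perm)
    capd_center <- cap_draw(cn$n_center, profile$capacity$center)
    n_treat <- cn$n_perm + cn$n_treat_existing + cn$n_field
    capf_treat <- round(runifr(n_treat, profile$capacity$treat))

    base1 <- runifr(1, profile$demand_base)
    dem <- round(base1 * profile$demand_period_shape)
    demand <- matrix(dem, nT, nrow(profile$scenarios))

    n_coll <- cn$n_temp + cn$n_perm
    dist1 <- matrix(round(runifr(n_coll * cn$n_center,
                                 profile$distance_range), 1),
                    n_coll, cn$n_center)
    dist2 <- matrix(round(runifr(cn$n_center * n_treat,
                                 profile$distance_range), 1),
                    cn$n_center, n_treat)

    network_instance(
      sites = sites, periods = profile$period_hours,
      scenarios = profile$scenarios,
      capa_temp = capa_temp, capa_perm = capa_perm,
      capd_center = capd_center, capf_treat = capf_treat,
      demand = demand,
      dist_coll_center = dist1, dist_center_treat = dist2,
      unit_transport_cost = profile$unit_transport_cost,
      unit_test_cost = profile$unit_test_cost,
      vehicle_capacity = profile$vehicle_capacity,
      alpha = profile$alpha, beta = profile$beta, lam = profile$lam,
      units_per_patient = profile$units_per_patient,
      id = sprintf("synthetic-%d", seed)
    )
  })
}

#' Generate a tiny integer instance for exhaustive verification
#'
#' Produces instances small enough that every facility configuration can be
#' enumerated and the flow subproblem solved exactly (at most 2^12
#' configurations), with integer capacities and demands so the flow oracles
#' are exact. Used to establish ground truth for the MILP solver.
#'
#' @param seed integer seed.
#' @param dims named list of counts: `n_temp`, `n_perm`, `n_center`,
#'   `n_treat_existing`, `n_field` (each at most 3), `n_periods` (at most 2)
#'   and `n_scenarios` (at most 2).
#' @return a `bsc_instance` with small integer data.
#' @export
generate_tiny <- function(seed, dims = list()) {
  d <- utils::modifyList(list(n_temp = 2, n_perm = 1, n_center = 2,
                              n_treat_existing = 0, n_field = 1,
                              n_periods = 2, n_scenarios = 1), dims)
  for (k in c("n_temp", "n_perm", "n_center", "n_treat_existing", "n_field"))
    if (d[[k]] > 3) stop("tiny bounds exceeded: ", k, " > 3")
  if (d$n_periods > 2) stop("tiny bounds exceeded: n_periods > 2")
  if (d$n_scenarios > 2) stop("tiny bounds exceeded: n_scenarios > 2")

  nT <- d$n_periods
  scen <- if (d$n_scenarios == 1) {
    data.frame(id = "s1", probability = 1, demand_multiplier = 1,
               setup_cost_multiplier = 1, capacity_multiplier = 1,
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = c("s1", "s2"), probability = c(0.4, 0.6),
               demand_multiplier = c(1, 1.5),
               setup_cost_multiplier = c(1, 1.25),
               capacity_multiplier = c(1, 1),
               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    mk_ids <- function(prefix, n) if (n > 0) sprintf("%s%d", prefix, seq_len(n)) else character(0)
    temp_ids <- mk_ids("t", d$n_temp); perm_ids <- mk_ids("h", d$n_perm)
    cent_ids <- mk_ids("b", d$n_center); tc_ids <- mk_ids("c", d$n_treat_existing)
    field_ids <- mk_ids("f", d$n_field)
    n_all <- d$n_temp + d$n_perm + d$n_center + d$n_treat_existing + d$n_field
    exists <- c(stats::runif(d$n_temp) < 0.25,
                stats::runif(d$n_perm) < 0.5,
                stats::runif(d$n_center) < 0.5,
                rep(TRUE, d$n_treat_existing),
                stats::runif(d$n_field) < 0.25)
    setup <- c(sample(20:100, d$n_temp, replace = TRUE),
               sample(50:300, d$n_perm, replace = TRUE),
               sample(200:1000, d$n_center, replace = TRUE),
               rep(0, d$n_treat_existing),
               sample(50:400, d$n_field, replace = TRUE))
    setup[exists] <- 0
    sites <- data.frame(
      id = c(temp_ids, perm_ids, cent_ids, tc_ids, field_ids),
      kind = c(rep("temporary_collection", d$n_temp),
               rep("permanent_facility", d$n_perm),
               rep("blood_center", d$n_center),
               rep("treatment_center", d$n_treat_existing),
               rep("field_hospital", d$n_field)),
      exists = exists, setup_cost = setup, stringsAsFactors = FALSE)

    icap <- function(n) matrix(sample(0:12, n * nT, replace = TRUE), n, nT)
    n_treat <- d$n_perm + d$n_treat_existing + d$n_field
    n_coll <- d$n_temp + d$n_perm
    network_instance(
      sites = sites, periods = rep(24, nT), scenarios = scen,
      capa_temp = icap(d$n_temp), capa_perm = icap(d$n_perm),
      capd_center = matrix(sample(2:20, d$n_center * nT, replace = TRUE),
                           d$n_center, nT),
      capf_treat = sample(2:20, n_treat, replace = TRUE),
      demand = matrix(sample(0:15, nT * d$n_scenarios, replace = TRUE),
                      nT, d$n_scenarios),
      dist_coll_center = matrix(sample(1:10, n_coll * d$n_center,
                                       replace = TRUE),
                                n_coll, d$n_center),
      dist_center_treat = matrix(sample(1:10, d$n_center * n_treat,
                                        replace = TRUE),
                                 d$n_center, n_treat),
      unit_transport_cost = 2, unit_test_cost = 1, vehicle_capacity = 5,
      alpha = 0.8, beta = 0.8, lam = 0.5, units_per_patient = 1,
      id = sprintf("tiny-%d", seed)
    )
  })
}
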