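# Fixtures built in code: the single-path chain instance (closed-form
# optima), a designed cost/shortage trade-off instance, and hand-built
# solutions for checker mutation tests.

# one temporary site -> one blood center -> one treatment center
chain_instance <- function(dem, capa = 10, capd = 10, capf = 10,
                           alpha = 0.8, beta = 0.8, lam = 0.5,
                           nT = 1) {
  sites <- data.frame(
    id = c("t1", "b1", "c1"),
    kind = c("temporary_collection", "blood_center", "treatment_center"),
    exists = c(FALSE, FALSE, TRUE),
    setup_cost = c(100, 500, 0))
  network_instance(
    sites, periods = rep(24, nT),
    capa_temp = matrix(capa, 1, nT), capa_perm = matrix(numeric(0), 0, nT),
    capd_center = matrix(capd, 1, nT), capf_treat = capf,
    demand = rep(dem, nT),
    dist_coll_center = matrix(3, 1, 1), dist_center_treat = matrix(4, 1, 1),
    unit_transport_cost = 2, unit_test_cost = 1, vehicle_capacity = 5,
    alpha = alpha, beta = beta, lam = lam,
    id = sprintf("chain-%g", dem))
}

# two cheap temporary sites; one existing center and one expensive candidate
# center whose opening halves the shortage; beta = 1 for round numbers
tradeoff_instance <- function() {
  sites <- data.frame(
    id = c("t1", "t2", "b1", "b2", "c1"),
    kind = c("temporary_collection", "temporary_collection",
             "blood_center", "blood_center", "treatment_center"),
    exists = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    setup_cost = c(10, 10, 0, 1000, 0))
  network_instance(
    sites, periods = 24,
    capa_temp = matrix(10, 2, 1), capa_perm = matrix(numeric(0), 0, 1),
    capd_center = matrix(10, 2, 1), capf_treat = 30,
    demand = 25,
    dist_coll_center = matrix(c(2, 2, 3, 3), 2, 2),
    dist_center_treat = matrix(c(2, 2), 2, 1),
    unit_transport_cost = 1, unit_test_cost = 1, vehicle_capacity = 5,
    alpha = 0.8, beta = 1, lam = 0.25,
    id = "tradeoff")
}

# hand-buildable solution object for checker tests
manual_solution <- function(inst, open_temp, open_perm, open_center,
                            open_field, QT, QC, TH, IN, IB) {
  temp <- inst$sites$id[inst$sites$kind == "temporary_collection"]
  perm <- inst$sites$id[inst$sites$kind == "permanent_facility"]
  cent <- inst$sites$id[inst$sites$kind == "blood_center"]
  trt <- inst$sites$id[inst$sites$kind %in%
                         c("permanent_facility", "treatment_center",
                           "field_hospital")]
  fld <- inst$sites$id[inst$sites$kind == "field_hospital"]
  nT <- length(inst$periods)
  dimnames(QT) <- list(temp, cent, NULL)
  dimnames(QC) <- list(perm, cent, NULL)
  dimnames(TH) <- list(cent, trt, NULL)
  rps <- function(a) {
    if (dim(a)[1] == 0) return(matrix(0, 0, dim(a)[3]))
    m <- apply(a, c(1, 3), sum); rownames(m) <- dimnames(a)[[1]]; m
  }
  structure(list(
    instance_id = inst$id, scenario_id = inst$scenarios$id[1],
    open_temp = stats::setNames(open_temp, temp),
    open_perm = stats::setNames(open_perm, perm),
    open_center = stats::setNames(open_center, cent),
    open_field = stats::setNames(open_field, fld),
    collected_temp = rps(QT), collected_perm = rps(QC),
    ship_temp = QT, ship_perm = QC, deliver = TH,
    inventory = matrix(IN, length(cent), nT, dimnames = list(cent, NULL)),
    shortage = IB,
    objective_cost = NA_real_, objective_shortage_ratio = NA_real_,
    objective_shortage_units = NA_real_,
    solver_status = "manual", nodes = NA_integer_,
    infeasible_hint = NULL, options = solve_options()
  ), class = "bsc_solution")
}

# base instance A for mutation fixtures: temp + perm collectors, one
# candidate center (Capd 15), treatment nodes = perm + existing center +
# candidate field hospital; demand 10 (transfusion demand 8, lambda floor 4)
checker_instance_a <- function(capd = 15, dem = 10, capf = c(10, 10, 10),
                               init = 0) {
  sites <- data.frame(
    id = c("t1", "h1", "b1", "c1", "f1"),
    kind = c("temporary_collection", "permanent_facility", "blood_center",
             "treatment_center", "field_hospital"),
    exists = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    setup_cost = c(10, 10, 10, 0, 10))
  network_instance(
    sites, periods = 24,
    capa_temp = matrix(10, 1, 1), capa_perm = matrix(10, 1, 1),
    capd_center = matrix(capd, 1, 1), capf_treat = capf,
    demand = dem,
    dist_coll_center = matrix(1, 2, 1), dist_center_treat = matrix(1, 1, 3),
    unit_transport_cost = 1, unit_test_cost = 1,
    alpha = 0.8, beta = 0.8, lam = 0.5,
    initial_inventory = init,
    id = "checker-a")
}

# feasible base solution on checker_instance_a: collect 5 + 5, 8 usable,
# deliver 2 to h1, 4 to c1, 2 to f1, no inventory, no shortage
checker_base_a <- function(inst = checker_instance_a(),
                           qt = 5, qc = 5, th = c(2, 4, 2), inb = 0,
                           inv = NULL) {
  usable <- inst$beta * (qt + qc)
  if (is.null(inv)) inv <- usable - sum(th) + inst$initial_inventory[1]
  manual_solution(inst,
                  open_temp = TRUE, open_perm = TRUE, open_center = TRUE,
                  open_field = TRUE,
                  QT = array(qt, c(1, 1, 1)), QC = array(qc, c(1, 1, 1)),
                  TH = array(th, c(1, 3, 1)), IN = inv, IB = inb)
}

flagged_families <- function(report) unique(report$violations$family)
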