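# Deterministic MILP core: closed-form chain optima, objective evaluation
# arithmetic, literal constraint emission, big-M tightening, monotonicity.

test_that("single-path chain instance has its closed-form optima", {
  # capacity 10 everywhere, alpha = beta = 0.8: 8 usable units deliverable
  s10 <- solve_single_objective(chain_instance(10),
                                solve_options(objective = "shortage_units"))
  expect_equal(s10$solver_status, "optimal")
  expect_equal(s10$objective_shortage_units, 0, tolerance = 1e-7)

  s20 <- solve_single_objective(chain_instance(20),
                                solve_options(objective = "shortage_units"))
  expect_equal(s20$objective_shortage_units, 8, tolerance = 1e-7)
  expect_equal(s20$objective_shortage_ratio, 0.5, tolerance = 1e-7)
  # feasible exactly at the lambda bound: delivered 8 >= 0.5 * 16
  expect_equal(sum(s20$deliver), 8, tolerance = 1e-7)
})

test_that("zero demand with all-candidate sites costs nothing", {
  inst <- chain_instance(0)
  inst$sites$exists <- c(FALSE, FALSE, TRUE)
  sol <- solve_single_objective(inst, solve_options(objective = "cost"))
  expect_equal(sol$solver_status, "optimal")
  expect_equal(sol$objective_cost, 0, tolerance = 1e-9)
  expect_false(any(sol$open_temp, sol$open_center))
})

test_that("cost evaluation reproduces hand arithmetic at published unit costs", {
  # one temporary site (setup 2e6), one blood center (setup 1e9), ship 100
  # units over 10 km at 5000/unit-km, test 100 units at 5000/unit
  sites <- data.frame(
    id = c("t1", "b1", "c1"),
    kind = c("temporary_collection", "blood_center", "treatment_center"),
    exists = c(FALSE, FALSE, TRUE),
    setup_cost = c(2e6, 1e9, 0))
  inst <- network_instance(
    sites, periods = 24,
    capa_temp = matrix(100, 1, 1), capa_perm = matrix(numeric(0), 0, 1),
    capd_center = matrix(100, 1, 1), capf_treat = 100,
    demand = 0,
    dist_coll_center = matrix(10, 1, 1), dist_center_treat = matrix(5, 1, 1),
    unit_transport_cost = 5000, unit_test_cost = 5000,
    vehicle_capacity = 100, alpha = 0.8, beta = 0.8, lam = 0.5,
    id = "hand-cost")
  sol <- manual_solution(inst, open_temp = TRUE, open_perm = logical(0),
                         open_center = TRUE, open_field = logical(0),
                         QT = array(100, c(1, 1, 1)),
                         QC = array(0, c(0, 1, 1)),
                         TH = array(0, c(1, 1, 1)), IN = 80, IB = 0)
  expect_equal(evaluate_cost(inst, sol),
               2e6 + 1e9 + 100 * 10 * 5000 + 100 * 5000)
  # integral vehicle mode: 101 units over 10 km at capacity 100 -> 2 trips
  sol2 <- sol
  sol2$ship_temp[1, 1, 1] <- 101
  sol2$collected_temp[1, 1] <- 101
  expect_equal(bloodnet:::cost_parts(inst, sol2, integral_vehicles = TRUE)$transport,
               2 * 10 * 5000)
})

test_that("shortage evaluation follows the ratio-sum definition", {
  inst <- chain_instance(10, nT = 4)
  inst$demand <- matrix(c(20, 12.5, 10, 12.5), 4, 1)  # alpha*dem = 16,10,8,10
  sol <- manual_solution(inst, TRUE, logical(0), TRUE, logical(0),
                         QT = array(0, c(1, 1, 4)), QC = array(0, c(0, 1, 4)),
                         TH = array(0, c(1, 1, 4)), IN = matrix(0, 1, 4),
                         IB = c(8, 0, 4, 0))
  ev <- evaluate_shortage(inst, sol)
  expect_equal(ev[["ratio_sum"]], 1.0)
  expect_equal(ev[["total_units"]], 12)

  # zero-demand period with zero shortage contributes 0
  inst0 <- chain_instance(0)
  sol0 <- manual_solution(inst0, TRUE, logical(0), TRUE, logical(0),
                          QT = array(0, c(1, 1, 1)), QC = array(0, c(0, 1, 1)),
                          TH = array(0, c(1, 1, 1)), IN = 0, IB = 0)
  expect_equal(evaluate_shortage(inst0, sol0)[["ratio_sum"]], 0)
  # shortage in a zero-demand period is inconsistent
  sol0$shortage <- 1
  expect_error(evaluate_shortage(inst0, sol0), "zero-demand")
})

test_that("literal constraint emission matches a hand count", {
  inst <- checker_instance_a()  # 1 temp, 1 perm, 1 center, 1 tc, 1 field; T=1
  cons <- assemble_constraints(inst)
  counts <- table(cons$family)
  # candidates: t1, h1, b1, f1; existing: c1; treatment nodes: h1, c1, f1
  expect_equal(unname(counts[["eq1"]]), 1)
  expect_equal(unname(counts[["eq2"]]), 1)
  expect_equal(unname(counts[["eq3"]]), 1)
  expect_equal(unname(counts[["eq4"]]), 1)
  expect_equal(unname(counts[["eq5"]]), 1)
  expect_equal(unname(counts[["eq6"]]), 1)
  expect_equal(unname(counts[["eq7"]]), 1)
  expect_equal(unname(counts[["eq8"]]), 1)   # temp -> candidate center
  expect_equal(unname(counts[["eq9"]]), 1)
  expect_equal(unname(counts[["eq10"]]), 1)
  expect_equal(unname(counts[["eq11"]]), 1)
  expect_equal(unname(counts[["eq12"]]), 1)
  expect_equal(unname(counts[["eq13"]]), 3)  # one per treatment node
  expect_equal(unname(counts[["eq14"]]), 1)
  expect_equal(unname(counts[["eq15"]]), 3)  # candidate center x 3 nodes
  expect_equal(unname(counts[["eq16"]]), 1)  # candidate permanent treat node
  expect_equal(unname(counts[["eq17"]]), 1)  # candidate field hospital
  expect_equal(unname(counts[["eq18"]]), 1)

  # all-existing instance emits no big-M linkage rows at all
  inst2 <- inst
  inst2$sites$exists <- TRUE
  cons2 <- assemble_constraints(inst2)
  expect_false(any(cons2$family %in% paste0("eq", c(2, 4, 8:11, 15:17))))
})

test_that("lambda = 1 forces zero shortage whenever feasible", {
  inst <- chain_instance(10)
  inst$lam <- 1
  sol <- solve_single_objective(inst, solve_options(objective = "cost"))
  expect_equal(sol$solver_status, "optimal")
  expect_equal(sol$objective_shortage_units, 0, tolerance = 1e-7)

  inst2 <- chain_instance(20)  # only 8 of 16 units deliverable
  inst2$lam <- 1
  sol2 <- solve_single_objective(inst2, solve_options(objective = "cost"))
  expect_equal(sol2$solver_status, "infeasible")
  expect_false(is.null(sol2$infeasible_hint))
  expect_equal(sol2$infeasible_hint$period, 1)
})

test_that("tight big-M values are the smallest valid bounds", {
  inst <- checker_instance_a()
  tm <- tight_big_m(inst)
  eq2 <- tm[tm$family == "eq2", ]
  expect_equal(eq2$M, unname(inst$capa_temp[1, 1]))
  eq10 <- tm[tm$family == "eq10", ]
  expect_equal(eq10$M, unname(min(inst$capa_temp[1, 1], inst$capd_center[1, 1])))

  inst0 <- inst
  inst0$capa_temp[] <- 0; inst0$capa_perm[] <- 0; inst0$capd_center[] <- 0
  inst0$capf_treat[] <- 0
  expect_true(all(tight_big_m(inst0)$M == 0))
})

test_that("tight and loose big-M formulations give equal optima", {
  for (seed in 1:20) {
    inst <- generate_tiny(seed)
    for (objective in c("cost", "shortage_units")) {
      a <- solve_single_objective(inst, solve_options(objective = objective))
      b <- solve_single_objective(inst, solve_options(objective = objective,
                                                      formulation = "bigM"))
      expect_equal(a$solver_status, b$solver_status)
      if (a$solver_status == "optimal") {
        va <- if (objective == "cost") a$objective_cost else a$objective_shortage_units
        vb <- if (objective == "cost") b$objective_cost else b$objective_shortage_units
        expect_equal(va, vb, tolerance = 1e-6)
      }
    }
  }
})

test_that("raising a capacity never increases the shortage optimum, raising lambda never lowers cost", {
  for (seed in c(2, 9, 17)) {
    inst <- generate_tiny(seed)
    base <- solve_single_objective(inst, solve_options(objective = "shortage_units"))
    if (base$solver_status != "optimal") next
    up <- inst
    up$capd_center[1, 1] <- up$capd_center[1, 1] + 5
    more <- solve_single_objective(up, solve_options(objective = "shortage_units"))
    expect_lte(more$objective_shortage_units,
               base$objective_shortage_units + 1e-6)

    c0 <- solve_single_objective(inst, solve_options(objective = "cost"))
    lam_up <- inst
    lam_up$lam <- min(1, inst$lam + 0.3)
    c1 <- solve_single_objective(lam_up, solve_options(objective = "cost"))
    if (c1$solver_status == "optimal")
      expect_gte(c1$objective_cost, c0$objective_cost - 1e-6)
  }
})

test_that("optimal solutions pass the independent checker", {
  for (seed in c(1, 4, 8)) {
    inst <- generate_tiny(seed)
    for (objective in c("cost", "shortage_units", "shortage_ratio")) {
      sol <- solve_single_objective(inst, solve_options(objective = objective))
      if (sol$solver_status != "optimal") next
      expect_true(check_solution(inst, sol)$passed)
    }
  }
})
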