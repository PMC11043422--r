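# Two-stage scenario model: collapse identity, expectation accounting,
# penalty sweep, worst case, reporting.

test_that("one-scenario two-stage collapses to the deterministic model", {
  for (seed in c(1, 5, 12)) {
    inst <- generate_tiny(seed)
    ts <- solve_two_stage(inst, penalty = 0)
    det <- solve_single_objective(restrict_to_scenario(inst, 1L),
                                  solve_options(objective = "cost"))
    expect_equal(ts$solver_status, det$solver_status)
    if (ts$solver_status == "optimal")
      expect_equal(ts$expected_cost, det$objective_cost,
                   tolerance = 1e-6 * max(1, det$objective_cost))
  }
  # also with non-neutral scenario multipliers
  inst <- generate_tiny(3)
  inst$scenarios$demand_multiplier <- 1.5
  inst$scenarios$capacity_multiplier <- 1.2
  ts <- solve_two_stage(inst, penalty = 0)
  det <- solve_single_objective(restrict_to_scenario(inst, 1L),
                                solve_options(objective = "cost"))
  expect_equal(ts$expected_cost, det$objective_cost,
               tolerance = 1e-6 * max(1, det$objective_cost))
})

test_that("expected values are the probability-weighted scenario values", {
  inst <- generate_tiny(7, list(n_scenarios = 2))
  sol <- solve_two_stage(inst, penalty = 5)
  if (sol$solver_status == "optimal") {
    p <- vapply(sol$per_scenario, function(e) e$probability, 0)
    costs <- vapply(sol$per_scenario, function(e) e$cost, 0)
    shorts <- vapply(sol$per_scenario, function(e) e$shortage_units, 0)
    expect_equal(sol$expected_cost, sum(p * costs),
                 tolerance = 1e-6 * max(1, sol$expected_cost))
    expect_equal(sol$expected_shortage_units, sum(p * shorts),
                 tolerance = 1e-6)
    expect_equal(sol$worst_case_shortage, max(shorts))
    # first-stage decisions are shared by construction
    for (e in sol$per_scenario)
      expect_identical(e$solution$open_center, sol$first_stage$open_center)
  }
})

test_that("the scenario expectation of (10, 20, 40) at p = (0.15, 0.35, 0.5) is 28.5", {
  # direct expectation arithmetic used by the model accounting
  expect_equal(sum(c(0.15, 0.35, 0.5) * c(10, 20, 40)), 28.5)
})

test_that("penalty sweep is monotone and anchored at the pure cost optimum", {
  inst <- generate_tiny(9, list(n_scenarios = 2))
  grid <- c(0, 10, 1000, 1e5)
  sw <- sweep_penalty(inst, grid)
  expect_equal(nrow(sw), length(grid))
  ok <- sw$status == "optimal"
  expect_true(all(ok))
  expect_true(all(diff(sw$expected_shortage_units[ok]) <= 1e-6))
  expect_true(all(diff(sw$expected_cost_excl_penalty[ok]) >= -1e-6))
  # zero penalty is the pure expected-cost optimum
  pure <- solve_two_stage(inst, penalty = 0)
  expect_equal(sw$expected_cost_excl_penalty[1], pure$expected_cost,
               tolerance = 1e-6 * max(1, pure$expected_cost))
  # a huge penalty drives shortage to its minimum (all-open max delivery)
  s1 <- oracle_min_shortage(restrict_to_scenario(inst, 1L))
  s2 <- oracle_min_shortage(restrict_to_scenario(inst, 2L))
  p <- inst$scenarios$probability
  expect_equal(sw$expected_shortage_units[length(grid)],
               p[1] * s1 + p[2] * s2, tolerance = 1e-5)
})

test_that("the default penalty grid contains the reference fine", {
  expect_true(1450000 %in% default_penalty_grid())
  expect_true(all(diff(default_penalty_grid()) > 0))
})

test_that("worst case dominates expectation and matches brute force", {
  inst <- generate_tiny(4, list(n_scenarios = 2))
  pen <- 50
  wc <- solve_worst_case(inst, penalty = pen)
  expect_equal(wc$solver_status, "optimal")
  # max >= mean for the same first-stage decisions
  p <- vapply(wc$per_scenario, function(e) e$probability, 0)
  tot <- vapply(wc$per_scenario,
                function(e) e$cost + pen * e$shortage_units, 0)
  expect_gte(wc$objective_worst_case + 1e-6, sum(p * tot))
  expect_equal(wc$objective_worst_case, max(tot),
               tolerance = 1e-6 * max(1, max(tot)))

  # brute force over facility configurations: per configuration and
  # scenario, the recourse LP with all binaries fixed
  mod <- bloodnet:::bsc_build(inst)
  nb <- mod$nb
  best <- Inf
  for (m in 0:(2^nb - 1)) {
    fix <- as.integer(bitwAnd(m, 2^(seq_len(nb) - 1)) > 0)
    worst <- -Inf
    feas <- TRUE
    for (s in seq_len(2)) {
      objv <- mod$setup_vec_s(s) + mod$tv_s[[s]] + pen * mod$sh_s[[s]]
      r <- bloodnet:::milp_solve(objv, mod$A, mod$dir, mod$rhs,
                                 mod$binary_idx, mod$ub_rows, mod$lb_rows,
                                 fixed = fix)
      if (r$status != "optimal") { feas <- FALSE; break }
      worst <- max(worst, r$obj)
    }
    if (feas) best <- min(best, worst)
  }
  expect_equal(wc$objective_worst_case, best,
               tolerance = 1e-6 * max(1, abs(best)))

  # single scenario: worst case and expectation coincide
  one <- generate_tiny(4)
  a <- solve_worst_case(one, penalty = pen)
  b <- solve_two_stage(one, penalty = pen)
  expect_equal(a$objective_worst_case,
               b$expected_cost + pen * b$expected_shortage_units,
               tolerance = 1e-6 * max(1, a$objective_worst_case))
})

test_that("scenario reports are consistent with the stored solution", {
  inst <- generate_tiny(11, list(n_scenarios = 2))
  sol <- solve_two_stage(inst, penalty = 20)
  rep <- scenario_report(sol)
  expect_equal(nrow(rep), 2)
  # per-period shortages add up to the scenario totals
  per_cols <- grep("^shortage_t", names(rep))
  expect_equal(unname(rowSums(rep[, per_cols, drop = FALSE])),
               rep$total_shortage_units, tolerance = 1e-9)
  # probability-weighted totals reproduce the expectations
  expect_equal(sum(rep$probability * rep$total_shortage_units),
               sol$expected_shortage_units, tolerance = 1e-9)
  expect_equal(sum(rep$probability * rep$total_cost),
               sol$expected_cost, tolerance = 1e-6 * max(1, sol$expected_cost))
  # breakdown adds up (penalty is reported separately from cost)
  expect_equal(rep$setup_cost + rep$transport_cost + rep$testing_cost,
               rep$total_cost, tolerance = 1e-6)
})

test_that("single-scenario report equals the deterministic solution", {
  inst <- generate_tiny(2)
  sol <- solve_two_stage(inst, penalty = 0)
  rep <- scenario_report(sol)
  det <- solve_single_objective(restrict_to_scenario(inst, 1L),
                                solve_options(objective = "cost"))
  expect_equal(rep$total_cost, det$objective_cost,
               tolerance = 1e-6 * max(1, det$objective_cost))
})
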