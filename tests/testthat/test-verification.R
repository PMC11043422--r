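# Independent checker and flow oracles.

test_that("the all-zero solution on a zero-demand instance passes", {
  inst <- checker_instance_a(dem = 0)
  sol <- checker_base_a(inst, qt = 0, qc = 0, th = c(0, 0, 0))
  expect_true(check_solution(inst, sol)$passed)
})

test_that("shipping from a closed site is flagged in the linkage family", {
  inst <- checker_instance_a()
  sol <- checker_base_a(inst)
  sol$open_temp[] <- FALSE
  rep <- check_solution(inst, sol)
  expect_false(rep$passed)
  expect_true("eq10" %in% flagged_families(rep))
  v <- rep$violations[rep$violations$family == "eq10", ]
  expect_equal(v$magnitude, 5)  # the QT flow through the closed site
})

test_that("a unit inventory perturbation yields exactly one eq12 violation of magnitude 1", {
  inst <- checker_instance_a()
  sol <- checker_base_a(inst)
  expect_true(check_solution(inst, sol)$passed)
  sol$inventory[1, 1] <- sol$inventory[1, 1] + 1
  rep <- check_solution(inst, sol)
  expect_equal(flagged_families(rep), "eq12")
  expect_equal(nrow(rep$violations), 1)
  expect_equal(rep$violations$magnitude, 1)
})

test_that("chain max-flow oracle matches hand values", {
  expect_equal(oracle_min_shortage(chain_instance(10)), 0)
  expect_equal(oracle_min_shortage(chain_instance(20)), 8)
  # severing the only path loses everything: alpha * total demand
  cut <- chain_instance(10)
  cut$capd_center[1, 1] <- 0
  cut$lam <- 1e-9  # nothing deliverable; keep the service level attainable
  expect_equal(oracle_min_shortage(cut), 8)
})

test_that("min-cost oracle agrees with hand arithmetic on the chain", {
  # lambda 0.5 of 8 usable units: deliver 4, i.e. collect 5 raw
  # cost = setup (100 + 500) + 5 raw * (3 km * 2 + 1 test) + 4 * (4 km * 2)
  expect_equal(oracle_min_cost(chain_instance(10)),
               600 + 5 * 7 + 4 * 8)
  # zero demand, all candidates: nothing opened, zero cost
  z <- chain_instance(0)
  expect_equal(oracle_min_cost(z), 0)
})

test_that("oracles refuse non-tiny instances", {
  big <- generate_instance(kermanshah_profile(), 1)
  expect_error(oracle_min_shortage(restrict_to_scenario(big, 1)),
               "tiny bounds")
  expect_error(oracle_min_shortage(generate_tiny(1, list(n_scenarios = 2))),
               "single-scenario")
})

test_that("solver and oracles agree across seeded tiny instances", {
  cmp <- compare_solver_to_oracle(1:15)
  expect_equal(attr(cmp, "mismatches"), 0)
})

test_that("a corrupted solver is detected by the oracle comparison", {
  # wrap the true solver but leak a beta-scaled shortage value
  corrupted <- function(inst, opts) {
    sol <- solve_single_objective(inst, opts)
    if (sol$solver_status == "optimal" && sol$objective_shortage_units > 0)
      sol$objective_shortage_units <- sol$objective_shortage_units / inst$beta
    sol
  }
  cmp <- compare_solver_to_oracle(1:15, solver = corrupted)
  expect_gt(attr(cmp, "mismatches"), 0)
})

test_that("empty seed list gives an empty summary", {
  cmp <- compare_solver_to_oracle(integer(0))
  expect_equal(nrow(cmp), 0)
  expect_equal(attr(cmp, "mismatches"), 0L)
})
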