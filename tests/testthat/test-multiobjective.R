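# Bi-objective drivers: ideal point, weighted scalarization, epsilon front,
# non-dominance filtering.

make_point <- function(cost, shortage) {
  structure(list(cost = cost, shortage = shortage, solution = NULL,
                 epsilon = NA_real_, metric = "shortage_units"),
            class = "bsc_pareto_point")
}

test_that("non-dominance filtering keeps exactly the efficient points", {
  pts <- list(make_point(1, 5), make_point(2, 3), make_point(3, 3))
  fr <- filter_nondominated(pts)
  expect_equal(vapply(fr$points, function(p) p$cost, 0), c(1, 2))

  single <- filter_nondominated(list(make_point(4, 4)))
  expect_length(single$points, 1)

  # idempotence
  fr2 <- filter_nondominated(fr$points)
  expect_equal(lapply(fr2$points, function(p) c(p$cost, p$shortage)),
               lapply(fr$points, function(p) c(p$cost, p$shortage)))
})

test_that("ideal point values bound every feasible solution and match the oracle", {
  inst <- chain_instance(20)
  ideal <- ideal_points(inst)
  expect_equal(ideal$shortage, oracle_min_shortage(inst), tolerance = 1e-6)
  expect_equal(ideal$cost, oracle_min_cost(inst),
               tolerance = 1e-6 * max(1, oracle_min_cost(inst)))
  # each anchor solution respects both bounds
  for (sol in list(ideal$cost_solution, ideal$shortage_solution)) {
    expect_gte(sol$objective_cost, ideal$cost - 1e-6)
    expect_gte(sol$objective_shortage_units, ideal$shortage - 1e-6)
  }
})

test_that("degenerate weights reproduce the individual optima", {
  inst <- tradeoff_instance()
  ideal <- ideal_points(inst)
  pc <- solve_weighted(inst, 1, 0, ideal = ideal)
  expect_equal(pc$cost, ideal$cost, tolerance = 1e-6)
  ps <- solve_weighted(inst, 0, 1, ideal = ideal)
  expect_equal(ps$shortage, ideal$shortage, tolerance = 1e-6)
})

test_that("a balanced weighting is dominated by neither endpoint", {
  inst <- tradeoff_instance()
  ideal <- ideal_points(inst)
  p <- solve_weighted(inst, 0.5, 0.5, ideal = ideal)
  e1 <- ideal$cost_solution; e2 <- ideal$shortage_solution
  dominates <- function(ca, sa, cb, sb)
    ca <= cb && sa <= sb && (ca < cb || sa < sb)
  expect_false(dominates(e1$objective_cost, e1$objective_shortage_units,
                         p$cost, p$shortage))
  expect_false(dominates(e2$objective_cost, e2$objective_shortage_units,
                         p$cost, p$shortage))
})

test_that("a cost bound below the cost optimum is rejected with an explanation", {
  inst <- tradeoff_instance()
  ideal <- ideal_points(inst)
  expect_error(solve_weighted(inst, 0, 1, cost_bound = ideal$cost * 0.5,
                              ideal = ideal),
               "below the minimum achievable cost")
})

test_that("the epsilon front on the trade-off instance is monotone with ideal endpoints", {
  inst <- tradeoff_instance()
  front <- solve_epsilon_front(inst, n_points = 5)
  df <- as.data.frame(front)
  ideal <- front$ideal
  # endpoints reproduce the individual optima
  expect_equal(min(df$cost), ideal[["cost"]], tolerance = 1e-6)
  expect_equal(min(df$shortage), ideal[["shortage"]], tolerance = 1e-4)
  # cost ascending, shortage non-increasing, no dominated points
  expect_true(all(diff(df$cost) >= -1e-9))
  expect_true(all(diff(df$shortage) <= 1e-9))
  # the expensive extra center removes the shortage entirely
  expect_equal(ideal[["shortage"]], 0, tolerance = 1e-6)
  expect_gt(max(df$shortage), 0)
})

test_that("weighted solutions never dominate epsilon-front points", {
  inst <- tradeoff_instance()
  front <- solve_epsilon_front(inst, n_points = 4)
  ideal <- ideal_points(inst)
  for (w in list(c(1, 1), c(0.2, 0.8), c(0.8, 0.2))) {
    p <- solve_weighted(inst, w[1], w[2], ideal = ideal)
    for (q in front$points) {
      dominates <- p$cost <= q$cost - 1e-6 && p$shortage <= q$shortage - 1e-6
      expect_false(dominates)
    }
  }
})

test_that("ample free capacity collapses both objectives onto one solution", {
  inst <- chain_instance(10)
  inst$sites$setup_cost <- c(0, 0, 0)
  inst$lam <- 1  # full coverage attainable and required
  ideal <- ideal_points(inst)
  sol <- ideal$cost_solution
  expect_equal(sol$objective_shortage_units, ideal$shortage, tolerance = 1e-6)
})
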