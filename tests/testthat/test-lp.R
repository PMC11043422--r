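# The LP/MILP engine, against hand solutions and exhaustive enumeration.

test_that("simplex solves small LPs with known optima", {
  # max 3x + 2y s.t. x + y <= 4, x + 3y <= 6  ->  x = 4, y = 0
  r <- bloodnet:::lp_solve(c(-3, -2), rbind(c(1, 1), c(1, 3)),
                           c("<=", "<="), c(4, 6))
  expect_equal(r$status, "optimal")
  expect_equal(r$obj, -12)
  expect_equal(r$x, c(4, 0))

  # equality + lower bound
  r <- bloodnet:::lp_solve(c(2, 3), rbind(c(1, 1), c(1, 0)),
                           c("==", ">="), c(10, 3))
  expect_equal(r$obj, 20)

  # degenerate transportation problem
  A <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 1, 0), c(0, 1, 0, 1))
  r <- bloodnet:::lp_solve(c(4, 1, 2, 6), A, rep("==", 4), c(5, 5, 5, 5))
  expect_equal(r$status, "optimal")
  expect_equal(r$obj, 5 * 1 + 5 * 2)  # ship on the cheap arcs
})

test_that("simplex detects infeasible and unbounded programs", {
  r <- bloodnet:::lp_solve(1, rbind(1, 1), c("<=", ">="), c(1, 2))
  expect_equal(r$status, "infeasible")
  r <- bloodnet:::lp_solve(-1, matrix(1, 1, 1), ">=", 1)
  expect_equal(r$status, "unbounded")
})

test_that("branch and bound matches exhaustive enumeration on binary knapsacks", {
  set.seed(42)
  for (k in 1:15) {
    n <- sample(3:8, 1)
    w <- sample(1:9, n, replace = TRUE)
    v <- sample(1:9, n, replace = TRUE)
    capk <- sum(w) %/% 2
    # exhaustive oracle
    best <- 0
    for (m in 0:(2^n - 1)) {
      pick <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
      if (sum(w[pick]) <= capk) best <- max(best, sum(v[pick]))
    }
    # as a MILP: minimize -v'x s.t. w'x <= cap, x binary
    A <- rbind(diag(n), diag(n), matrix(w, 1, n))
    dir <- c(rep("<=", n), rep(">=", n), "<=")
    rhs <- c(rep(1, n), rep(0, n), capk)
    r <- bloodnet:::milp_solve(-v, A, dir, rhs, binary_idx = seq_len(n),
                               ub_rows = seq_len(n),
                               lb_rows = n + seq_len(n))
    expect_equal(r$status, "optimal")
    expect_equal(-r$obj, best, tolerance = 1e-9)
  }
})

test_that("branch and bound honors pre-fixed binaries", {
  # min x1 + x2 s.t. x1 + x2 >= 1, binaries; fixing x1 = 1 forces that choice
  A <- rbind(diag(2), diag(2), matrix(1, 1, 2))
  dir <- c("<=", "<=", ">=", ">=", ">=")
  rhs <- c(1, 1, 0, 0, 1)
  r <- bloodnet:::milp_solve(c(3, 1), A, dir, rhs, binary_idx = 1:2,
                             ub_rows = 1:2, lb_rows = 3:4,
                             fixed = c(1L, NA))
  expect_equal(r$status, "optimal")
  expect_equal(r$x[1], 1, tolerance = 1e-9)
  expect_equal(r$obj, 3, tolerance = 1e-9)
})
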