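# Synthetic instance generation: determinism, validity, the case-study
# profile, and the tiny-instance bounds.

test_that("the default profile carries the case-study parameters", {
  p <- kermanshah_profile()
  expect_equal(p$scenarios$probability, c(0.15, 0.35, 0.5))
  expect_equal(p$counts$n_temp, 8)
  expect_equal(p$counts$n_perm, 5)
  expect_equal(p$counts$n_center, 3)
  expect_equal(p$counts$n_field, 5)
  expect_equal(length(p$period_hours), 4)
  expect_equal(p$alpha, 0.8)
  expect_equal(p$beta, 0.8)
  expect_equal(p$lam, 0.7)
  expect_equal(p$vehicle_capacity, 100)
  expect_equal(p$unit_transport_cost, 5000)
  expect_equal(p$unit_test_cost, 5000)
  expect_equal(p$setup$center, c(1e9, 1e9))
  expect_length(validate_profile <- bloodnet:::validate_profile(p), 0)
})

test_that("generation is deterministic in (profile, seed) and leaves the RNG alone", {
  p <- kermanshah_profile()
  set.seed(999)
  before <- .Random.seed
  i1 <- generate_instance(p, 42)
  expect_identical(.Random.seed, before)
  i2 <- generate_instance(p, 42)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  save_instance(i1, f1); save_instance(i2, f2)
  expect_identical(readLines(f1), readLines(f2))
  i3 <- generate_instance(p, 43)
  expect_false(identical(i1$demand, i3$demand) &&
                 identical(i1$dist_coll_center, i3$dist_coll_center))
})

test_that("generated case-study instances have the published shape and validate", {
  for (seed in c(1, 7, 123)) {
    inst <- generate_instance(kermanshah_profile(), seed)
    expect_length(validate_instance(inst), 0)
    kinds <- table(inst$sites$kind)
    expect_equal(unname(kinds[["temporary_collection"]]), 8)
    expect_equal(unname(kinds[["permanent_facility"]]), 5)
    expect_equal(unname(kinds[["blood_center"]]), 3)
    expect_equal(unname(kinds[["field_hospital"]]), 5)
    expect_equal(n_periods <- length(inst$periods), 4)
    expect_equal(nrow(inst$scenarios), 3)
  }
})

test_that("scenario severity ordering means non-decreasing demand", {
  inst <- generate_instance(kermanshah_profile(), 3)
  totals <- vapply(seq_len(nrow(inst$scenarios)), function(s)
    sum(inst$demand[, s] * inst$scenarios$demand_multiplier[s]), 0)
  expect_true(all(diff(totals) >= 0))
})

test_that("tiny instances respect their bounds and always validate", {
  for (seed in 1:30) {
    inst <- generate_tiny(seed)
    expect_length(validate_instance(inst), 0)
    nc <- sum(!inst$sites$exists & inst$sites$kind != "treatment_center")
    expect_lte(2^nc, 4096)
    expect_true(all(inst$demand == round(inst$demand)))
    expect_true(all(inst$capa_temp == round(inst$capa_temp)))
  }
  expect_error(generate_tiny(1, list(n_temp = 4)), "tiny bounds")
  expect_error(generate_tiny(1, list(n_periods = 3)), "tiny bounds")
  expect_error(generate_tiny(1, list(n_scenarios = 3)), "tiny bounds")
})
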