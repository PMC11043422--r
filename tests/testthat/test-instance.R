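# Instance container: validation diagnostics, canonical serialization,
# scenario restriction.

test_that("save/load round-trips an instance losslessly and canonically", {
  inst <- generate_instance(kermanshah_profile(), 11)
  f <- withr::local_tempfile(fileext = ".json")
  save_instance(inst, f)
  inst2 <- load_instance(f)
  expect_equal(inst2, inst)
  f2 <- withr::local_tempfile(fileext = ".json")
  save_instance(inst2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("loading rejects scenario probabilities that do not sum to 1", {
  inst <- generate_tiny(1, list(n_scenarios = 2))
  inst$scenarios$probability <- c(0.5, 0.6)
  f <- withr::local_tempfile(fileext = ".json")
  save_instance(inst, f)
  expect_error(load_instance(f), "probabilities sum != 1")
})

test_that("loading rejects files with missing fields, naming the field", {
  inst <- generate_tiny(2)
  f <- withr::local_tempfile(fileext = ".json")
  save_instance(inst, f)
  doc <- jsonlite::read_json(f)
  doc$params$alpha <- NULL
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), f)
  expect_error(load_instance(f), "alpha")
})

test_that("validate_instance reports diagnostics instead of raising", {
  inst <- generate_tiny(3)
  expect_length(validate_instance(inst), 0)

  bad <- inst
  bad$capa_temp[1, 1] <- -1
  d <- validate_instance(bad)
  expect_true(any(grepl("capa_temp", d)))

  bad2 <- inst
  bad2$dist_coll_center[1, 1] <- NA
  d2 <- validate_instance(bad2)
  expect_true(any(grepl("incomplete distance matrix", d2)))

  # total: junk input yields diagnostics, not an error
  expect_type(validate_instance(list()), "character")
})

test_that("distance matrices can come from CSV sidecar files", {
  inst <- generate_tiny(4)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "inst.json")
  save_instance(inst, f)
  doc <- jsonlite::read_json(f)
  m <- inst$dist_coll_center
  utils::write.csv(as.data.frame(m), file.path(dir, "dcc.csv"))
  doc$distances$coll_center <- "dcc.csv"
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), f)
  inst2 <- load_instance(f)
  expect_equal(unname(inst2$dist_coll_center), unname(m))
})

test_that("restrict_to_scenario applies multipliers and is identity for neutral scenarios", {
  inst <- generate_tiny(5)  # one scenario, all multipliers 1
  expect_equal(restrict_to_scenario(inst, 1L), inst)

  inst2 <- generate_tiny(6, list(n_scenarios = 2))
  inst2$scenarios$demand_multiplier <- c(1, 2)
  r <- restrict_to_scenario(inst2, "s2")
  expect_equal(r$demand[, 1], inst2$demand[, 2] * 2)
  expect_equal(nrow(r$scenarios), 1)
  expect_equal(r$scenarios$probability, 1)
  expect_error(restrict_to_scenario(inst2, "nope"), "unknown scenario")
})

test_that("restriction of any valid instance to any scenario validates", {
  for (seed in 1:30) {
    inst <- generate_tiny(seed, list(n_scenarios = 2))
    for (s in seq_len(nrow(inst$scenarios)))
      expect_length(validate_instance(restrict_to_scenario(inst, s)), 0)
  }
})
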