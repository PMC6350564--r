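# Input derivations, conversions, and parameter validation.

test_that("severity-weighted utility reproduces the published composite", {
  expect_equal(derive_copd_utility(c(0.27, 0.55, 0.15, 0.03),
                                   c(0.97, 0.93, 0.72, 0.52)),
               0.897, tolerance = 1e-12)
  expect_equal(derive_copd_utility(c(1, 0, 0, 0),
                                   c(0.97, 0.93, 0.72, 0.52)), 0.97)
  expect_equal(derive_copd_utility(c(0.5, 0.5), c(1, 1)), 1)
})

test_that("severity-weighted utility is linear and permutation-invariant", {
  set.seed(4)
  for (i in 1:20) {
    w <- runif(4); w <- w / sum(w)
    u1 <- runif(4); u2 <- runif(4)
    a <- runif(1)
    # linear in utilities
    expect_equal(derive_copd_utility(w, a * u1 + (1 - a) * u2),
                 a * derive_copd_utility(w, u1) +
                   (1 - a) * derive_copd_utility(w, u2),
                 tolerance = 1e-12)
    # invariant under joint permutation
    perm <- sample(4)
    expect_equal(derive_copd_utility(w[perm], u1[perm]),
                 derive_copd_utility(w, u1), tolerance = 1e-12)
  }
})

test_that("utility aggregation rejects malformed inputs", {
  expect_error(derive_copd_utility(c(0.5, 0.5), c(1, 1, 1)),
               class = "opep_validation_error")
  expect_error(derive_copd_utility(c(0.6, 0.5), c(1, 1)),
               class = "opep_validation_error")
})

test_that("outpatient follow-up cost is the utilisation-weighted sum", {
  # published ingredients give $64.80, printed rounded to $65
  expect_equal(derive_no_exac_cost(c(78, 251, 101), c(0.131, 0.172, 0.113)),
               64.803, tolerance = 1e-9)
  expect_equal(round(derive_no_exac_cost(c(78, 251, 101),
                                         c(0.131, 0.172, 0.113))), 65)
  expect_equal(derive_no_exac_cost(c(100, 100), c(0.1, 0.2)), 30)
  expect_equal(derive_no_exac_cost(c(123, 456), c(0, 0)), 0)
  expect_error(derive_no_exac_cost(c(-1, 2), c(1, 1)),
               class = "opep_validation_error")
})

test_that("annual decrements scale to per-event-month decrements", {
  expect_equal(derive_monthly_decrement(0.042), 0.504)
  expect_equal(derive_monthly_decrement(0.01), 0.12)
  expect_equal(derive_monthly_decrement(0), 0)
  expect_error(derive_monthly_decrement(-0.1),
               class = "opep_validation_error")
})

test_that("annual-to-monthly conversion is a constant-hazard root", {
  expect_equal(annual_to_monthly_probability(0), 0)
  expect_equal(annual_to_monthly_probability(1), 1)
  expect_equal(annual_to_monthly_probability(0.01), 0.000837,
               tolerance = 1e-3)
  grid <- seq(0, 0.999, length.out = 50)
  pm <- annual_to_monthly_probability(grid)
  # monotone, bounded by the annual probability, exact round trip
  expect_true(all(diff(pm) > 0))
  expect_true(all(pm <= grid))
  expect_equal(1 - (1 - pm)^12, grid, tolerance = 1e-12)
  expect_equal(annual_to_monthly_probability(0.12, "linear"), 0.01)
  expect_error(annual_to_monthly_probability(1.2),
               class = "opep_validation_error")
})

test_that("the fractional-range rule yields the published dispersion", {
  expect_equal(round(sd_from_fractional_range(13119, 0.20)), 1339)
  expect_equal(sd_from_fractional_range(0, 0.20), 0)
  expect_equal(sd_from_fractional_range(100, 0.196), 10)
  expect_error(sd_from_fractional_range(1, 0),
               class = "opep_validation_error")
})

test_that("parameter validation names the offending field", {
  expect_s3_class(model_params(), "opep_params")
  err <- tryCatch(model_params(p_exac_month1 = 1.3), condition = identity)
  expect_s3_class(err, "opep_validation_error")
  expect_equal(err$field, "p_exac_month1")
  expect_error(model_params(cost_severe = -1),
               class = "opep_validation_error")
  expect_error(model_params(rr_month1 = 0), class = "opep_validation_error")
  expect_error(model_params(decrement_severe = 0.05,
                            decrement_moderate = 0.12),
               class = "opep_validation_error")
  expect_error(model_params(n_cycles = 0), class = "opep_validation_error")
  p <- unclass(model_params())
  p$utility_copd <- NULL
  expect_error(validate_params(p), class = "opep_validation_error")
})

test_that("the shipped parameter document echoes the base case", {
  p <- base_case_params()
  expect_params_equal(p, model_params())
  expect_equal(attr(p, "currency"), "CAD2017")
  expect_equal(attr(p, "distributions")$cost_severe, "gamma")
})

test_that("composite inputs are re-derived when absent from the document", {
  doc <- yaml::read_yaml(system.file("extdata", "copd_base_case.yaml",
                                     package = "opepcua"))
  doc$params$utility_copd <- NULL
  doc$params$cost_no_exac <- NULL
  doc$params$decrement_severe <- NULL
  doc$params$decrement_moderate <- NULL
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, f)
  p <- load_params(f)
  expect_equal(p$utility_copd, 0.897, tolerance = 1e-12)
  expect_equal(p$cost_no_exac, 64.803, tolerance = 1e-9)
  expect_equal(p$decrement_severe, 0.504)
  expect_equal(p$decrement_moderate, 0.12)
})

test_that("a document with an out-of-range field fails with its name", {
  doc <- yaml::read_yaml(system.file("extdata", "copd_base_case.yaml",
                                     package = "opepcua"))
  doc$params$p_exac_month1 <- 1.3
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, f)
  err <- tryCatch(load_params(f), condition = identity)
  expect_s3_class(err, "opep_validation_error")
  expect_equal(err$field, "p_exac_month1")
})

test_that("serialising and re-loading a parameter set is bit-identical", {
  p <- generate_random_param_set(99)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, f)
  q <- load_params(f)
  expect_params_equal(p, q, tol = 0)
})
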