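# Cohort engine: transition rows, conservation, accrual accounting.

test_that("transition rows out of the exacerbation-free state split the
           hazard by arm and severity share", {
  p <- model_params()
  row <- build_transition_row(p, "control", "no_exac", 1)
  expect_equal(unname(row["severe_exac"]), 0.257 * 0.706)   # 0.181442
  expect_equal(unname(row["moderate_exac"]), 0.257 * 0.294) # 0.075558
  dev <- build_transition_row(p, "device", "no_exac", 1)
  expect_equal(unname(dev["severe_exac"] + dev["moderate_exac"]),
               0.257 * 0.72) # 0.18504
  later <- build_transition_row(p, "device", "no_exac", 5)
  expect_equal(unname(later["severe_exac"] + later["moderate_exac"]),
               0.059 * p$rr_later)
})

test_that("the dead state is absorbing and cycle bounds are enforced", {
  p <- model_params()
  expect_equal(unname(build_transition_row(p, "device", "dead", 3)),
               c(0, 0, 0, 1))
  expect_error(build_transition_row(p, "device", "no_exac", 0))
  expect_error(build_transition_row(p, "device", "no_exac", 13))
})

test_that("engine rows agree with an independent hand-built row
           construction across parameters, states and conventions", {
  for (i in 1:8) {
    p <- generate_random_param_set(300 + i)
    for (cv in convention_grid) {
      for (arm in c("device", "control")) {
        for (state in STATES) {
          for (cycle in c(1, 2, 12)) {
            got <- build_transition_row(p, arm, state, cycle, cv)
            want <- ref_transition_row(p, arm, state, cycle, cv)
            expect_equal(got, want, tolerance = 1e-12)
            expect_true(all(got >= 0))
            expect_equal(sum(got), 1, tolerance = 1e-12)
          }
        }
      }
    }
  }
})

test_that("an event-free cohort accrues the closed-form totals", {
  p <- model_params(p_exac_month1 = 0, p_exac_later = 0, p_death_annual = 0)
  for (cv in convention_grid) {
    res <- run_cohort(p, "control", cv)
    expect_equal(res$total_cost, 12 * 65, tolerance = 1e-12)
    expect_equal(res$total_qalys, 0.897, tolerance = 1e-12)
  }
  # the device arm additionally pays exactly the acquisition cost
  dev <- run_cohort(p, "device")
  expect_equal(dev$total_cost, 12 * 65 + 90, tolerance = 1e-12)
})

test_that("occupancy is conserved, bounded, and death is monotone", {
  for (i in 1:10) {
    p <- generate_random_param_set(500 + i)
    cv <- convention_grid[[1 + i %% length(convention_grid)]]
    for (arm in c("device", "control")) {
      tr <- run_cohort(p, arm, cv)$trace
      occ <- as.matrix(tr[, STATES])
      expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
      expect_true(all(occ >= 0 & occ <= 1))
      expect_true(all(diff(tr$dead) >= 0))
    }
  }
})

test_that("cohort totals respect the utility ceiling and start from a
           fully exacerbation-free cohort", {
  p <- model_params()
  res <- run_cohort(p, "control")
  expect_lte(res$total_qalys, p$utility_copd * p$n_cycles / 12)
  expect_equal(unlist(res$trace[1, STATES], use.names = FALSE),
               c(1, 0, 0, 0))
  # cycle-1 occupancy comes from the first-month hazard
  expect_equal(res$trace$severe_exac[2], 0.257 * 0.706)
})

test_that("arms are exchangeable when the device has no effect and no
           cost", {
  for (i in 1:5) {
    p <- generate_random_param_set(700 + i)
    p$rr_month1 <- 1
    p$rr_later <- 1
    p$frac_severe_device <- p$frac_severe_control
    p$cost_device <- 0
    for (cv in convention_grid[1:3]) {
      dev <- run_cohort(p, "device", cv)
      ctl <- run_cohort(p, "control", cv)
      expect_equal(dev$total_cost, ctl$total_cost, tolerance = 1e-12)
      expect_equal(dev$total_qalys, ctl$total_qalys, tolerance = 1e-12)
      expect_equal(dev$trace[, -1], ctl$trace[, -1], tolerance = 1e-12)
    }
  }
})

test_that("totals move monotonically with unit costs, the first-month
           hazard, and the decrements", {
  base <- model_params()
  eval_cost <- function(p) run_cohort(p, "control")$total_cost
  eval_qaly <- function(p) run_cohort(p, "control")$total_qalys
  for (f in c("cost_severe", "cost_moderate", "cost_no_exac",
              "p_exac_month1")) {
    p_hi <- base
    p_hi[[f]] <- base[[f]] * 1.05
    expect_gte(eval_cost(p_hi), eval_cost(base))
  }
  set.seed(11)
  for (i in 1:5) {
    p <- generate_random_param_set(800 + i)
    for (f in c("decrement_severe", "decrement_moderate")) {
      p_hi <- p
      p_hi[[f]] <- p[[f]] * 1.1
      if (p_hi$decrement_moderate > p_hi$decrement_severe)
        p_hi$decrement_severe <- p_hi$decrement_moderate
      expect_lte(eval_qaly(p_hi), eval_qaly(p))
    }
  }
})

test_that("the vectorised accrual used by the probabilistic analysis
           matches the scalar cohort run draw by draw", {
  base <- model_params()
  set.seed(21)
  draws <- draw_parameter_sets(base, n_draws = 15)
  for (cv in convention_grid[c(1, 2, 4)]) {
    pl <- lapply(unclass(base), as.numeric)
    for (f in names(draws)) pl[[f]] <- draws[[f]]
    vec <- opepcua:::cohort_accrue(pl, "device", cv)
    for (i in seq_len(nrow(draws))) {
      p <- base
      for (f in names(draws)) p[[f]] <- draws[[f]][i]
      if (p$decrement_severe < p$decrement_moderate) next
      res <- run_cohort(p, "device", cv)
      expect_equal(vec$cost[i], res$total_cost, tolerance = 1e-12)
      expect_equal(vec$qaly[i], res$total_qalys, tolerance = 1e-12)
    }
  }
})

test_that("a cohort trace round-trips through its CSV writer", {
  res <- run_cohort(model_params(), "device")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(res, f)
  back <- utils::read.csv(f)
  expect_equal(back, res$trace, tolerance = 1e-12)
})
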