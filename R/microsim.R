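# Patient-level microsimulation. Simulates individual disease paths with
# the same transition rows and reward rules as the cohort engine; by the
# law of large numbers its mean accruals must match the cohort totals, so
# it serves as an independent check of the deterministic recursion and of
# the reward accounting.

#' Microsimulate one strategy arm
#'
#' Simulates `n_patients` independent patient paths through the four-state
#' model and accrues per-patient costs and QALYs under exactly the reward
#' conventions of [run_cohort()]. Returns Monte-Carlo means with standard
#' errors; the cohort totals should lie within a few standard errors of
#' the means.
#'
#' @inheritParams build_transition_row
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `opep_microsim`: `arm`, `n_patients`,
#'   `total_cost` and `total_qalys` (per-patient means), `se_cost`,
#'   `se_qalys`, and the final `state_counts`.
#' @examples
#' ms <- microsimulate_arm(model_params(), "control", n_patients = 2000,
#'                         seed = 7)
#' ms$total_cost + c(-3, 3) * ms$se_cost
#' @export
microsimulate_arm <- function(params, arm = c("device", "control"),
                              n_patients = 10000L, seed = 1L,
                              conventions = NULL) {
  arm <- match.arg(arm)
  cv <- as_conventions(conventions)
  validate_params(params)
  stopifnot(n_patients >= 1)
  set.seed(as.integer(seed))
  n <- as.integer(n_patients)
  n_cycles <- params$n_cycles
  pl <- lapply(unclass(params), as.numeric)

  # states coded 1..4 in STATE_LABELS order; column m+1 = state after m
  # transitions
  states <- matrix(1L, n, n_cycles + 1)
  cur <- rep(1L, n)
  for (m in seq_len(n_cycles)) {
    rows <- row_components(pl, arm, m, cv)
    P <- rbind(rows$no[1, ], rows$mod[1, ], rows$sev[1, ], c(0, 0, 0, 1))
    cum <- t(apply(P, 1, cumsum))
    u <- stats::runif(n)
    nxt <- 1L + rowSums(u > cum[cur, , drop = FALSE])
    cur <- as.integer(pmin(nxt, 4L))
    states[, m + 1] <- cur
  }

  state_cost <- c(pl$cost_no_exac, pl$cost_moderate, pl$cost_severe, 0)
  q_no <- pl$utility_copd / 12
  state_qaly <- c(q_no, q_no - pl$decrement_moderate,
                  q_no - pl$decrement_severe, 0)

  # reward weight per patient-cycle; zero for exacerbation months ending
  # in death when decedents accrue nothing
  w <- matrix(1, n, n_cycles + 1)
  if (cv$decedent_accrual == "none") {
    for (m in seq_len(n_cycles - 1) + 1) {   # columns 2..n_cycles
      exac <- states[, m] %in% c(2L, 3L)
      w[exac & states[, m + 1] == 4L, m] <- 0
    }
  }
  rc <- matrix(state_cost[states], n) * w
  rq <- matrix(state_qaly[states], n) * w

  cost <- qaly <- numeric(n)
  for (m in seq_len(n_cycles)) {
    if (cv$half_cycle_correction) {
      cost <- cost + (rc[, m] + rc[, m + 1]) / 2
      qaly <- qaly + (rq[, m] + rq[, m + 1]) / 2
    } else {
      cost <- cost + rc[, m + 1]
      qaly <- qaly + rq[, m + 1]
    }
    if (arm == "device" && cv$device_cost_timing == "prorated")
      cost <- cost + pl$cost_device / n_cycles * (states[, m + 1] != 4L)
  }
  if (arm == "device" && cv$device_cost_timing == "entry")
    cost <- cost + pl$cost_device

  structure(list(
    arm = arm, n_patients = n,
    total_cost = mean(cost), total_qalys = mean(qaly),
    se_cost = stats::sd(cost) / sqrt(n),
    se_qalys = stats::sd(qaly) / sqrt(n),
    state_counts = table(factor(STATE_LABELS[states[, n_cycles + 1]],
                                levels = STATE_LABELS)),
    seed = as.integer(seed), conventions = cv
  ), class = "opep_microsim")
}

#' @export
print.opep_microsim <- function(x, ...) {
  cat(sprintf("Microsimulation (%s arm, %d patients, seed %d)\n",
              x$arm, x$n_patients, x$seed))
  cat(sprintf("  mean cost:  $%.2f (SE %.2f)\n", x$total_cost, x$se_cost))
  cat(sprintf("  mean QALYs: %.4f (SE %.4f)\n", x$total_qalys, x$se_qalys))
  invisible(x)
}
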