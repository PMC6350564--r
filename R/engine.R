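# Four-state discrete-time cohort engine. States: exacerbation-free,
# moderate exacerbation (ER visit), severe exacerbation (hospitalised),
# dead (absorbing). The whole cohort starts exacerbation-free; cycles are
# months. The engine is vectorised over parameter draws so the same code
# path serves the deterministic base case and the probabilistic analysis.

STATE_LABELS <- c("no_exac", "moderate_exac", "severe_exac", "dead")

# Per-draw transition-row components for one cycle. `pl` is a list of
# equal-length numeric vectors (one element per draw). Returns the rows
# out of the three alive states as n x 4 matrices.
row_components <- function(pl, arm, cycle, cv) {
  pdm <- annual_to_monthly_probability(pl$p_death_annual,
                                       cv$annual_prob_conversion)
  fs <- if (arm == "device") pl$frac_severe_device else pl$frac_severe_control
  p_base <- if (cycle == 1) pl$p_exac_month1 else pl$p_exac_later
  rr <- if (arm == "device") {
    if (cycle == 1) pl$rr_month1 else pl$rr_later
  } else 1
  pe <- pmin(p_base * rr, 1)
  if (cv$death_competition == "after_exac") {
    sev <- pe * fs
    mod <- pe * (1 - fs)
    dd <- (1 - pe) * pdm
  } else {
    dd <- pdm
    sev <- (1 - pdm) * pe * fs
    mod <- (1 - pdm) * pe * (1 - fs)
  }
  row_no <- unname(cbind(1 - sev - mod - dd, mod, sev, dd))
  if (cv$exac_survivor_routing == "composite") {
    # survivors re-enter the exacerbation-free process of this same cycle
    row_mod <- (1 - pdm) * row_no
    row_mod[, 4] <- row_mod[, 4] + pdm
    row_sev <- (1 - pl$p_death_severe) * row_no
    row_sev[, 4] <- row_sev[, 4] + pl$p_death_severe
  } else {
    zero <- rep(0, length(pe))
    row_mod <- unname(cbind(1 - pdm, zero, zero, pdm))
    row_sev <- unname(cbind(1 - pl$p_death_severe, zero, zero,
                            pl$p_death_severe))
  }
  list(no = row_no, mod = row_mod, sev = row_sev)
}

#' Transition probabilities out of one state
#'
#' Builds the row of the cycle-specific transition matrix for one health
#' state, arm and cycle under a given accounting convention. Rows are
#' non-negative and sum to one; the dead state is absorbing.
#'
#' @param params An `opep_params` object (see [model_params()]).
#' @param arm `"device"` or `"control"`.
#' @param state One of `"no_exac"`, `"moderate_exac"`, `"severe_exac"`,
#'   `"dead"`.
#' @param cycle Cycle index in `1:params$n_cycles`; the cycle-1 row uses
#'   the first-month exacerbation hazard and device relative risk.
#' @param conventions An `opep_conventions` object; `NULL` for the default.
#' @return Named numeric vector of transition probabilities over the four
#'   states.
#' @examples
#' build_transition_row(model_params(), "control", "no_exac", 1)
#' @export
build_transition_row <- function(params, arm = c("device", "control"),
                                 state = STATE_LABELS, cycle = 1,
                                 conventions = NULL) {
  arm <- match.arg(arm)
  state <- match.arg(state)
  cv <- as_conventions(conventions)
  validate_params(params)
  if (length(cycle) != 1 || cycle < 1 || cycle > params$n_cycles ||
      cycle != round(cycle))
    stop("'cycle' must be a single integer in 1..n_cycles")
  if (state == "dead") {
    row <- c(0, 0, 0, 1)
  } else {
    rows <- row_components(lapply(unclass(params), as.numeric),
                           arm, cycle, cv)
    row <- switch(state, no_exac = rows$no[1, ],
                  moderate_exac = rows$mod[1, ],
                  severe_exac = rows$sev[1, ])
  }
  stats::setNames(row, STATE_LABELS)
}

# Vectorised cohort accrual over parameter draws.
# `pl`: list of numeric vectors (length n or 1) with the fields of
# opep_params. Returns total cost and QALY vectors; when `trace = TRUE`
# (n must be 1) also the per-cycle trace matrix.
cohort_accrue <- function(pl, arm, cv, trace = FALSE) {
  n <- max(vapply(pl[VARYING_PARAMS], length, 1L))
  getv <- function(f) rep_len(as.numeric(pl[[f]]), n)
  for (f in c(VARYING_PARAMS, "cost_device")) pl[[f]] <- getv(f)
  n_cycles <- as.integer(pl$n_cycles[1])

  occ <- cbind(rep(1, n), 0, 0, 0)
  occs <- vector("list", n_cycles + 1)
  occs[[1]] <- occ
  exit_dead_mod <- exit_dead_sev <- vector("list", n_cycles)
  for (m in seq_len(n_cycles)) {
    rows <- row_components(pl, arm, m, cv)
    nxt <- occ[, 1] * rows$no + occ[, 2] * rows$mod + occ[, 3] * rows$sev
    nxt[, 4] <- nxt[, 4] + occ[, 4]
    exit_dead_mod[[m]] <- rows$mod[, 4]
    exit_dead_sev[[m]] <- rows$sev[, 4]
    occ <- nxt
    occs[[m + 1]] <- occ
  }

  # per-state monthly rewards
  q_no <- pl$utility_copd / 12
  q_mod <- q_no - pl$decrement_moderate
  q_sev <- q_no - pl$decrement_severe
  r_cost <- function(o) o[, 1] * pl$cost_no_exac +
    o[, 2] * pl$cost_moderate + o[, 3] * pl$cost_severe
  r_qaly <- function(o) o[, 1] * q_no + o[, 2] * q_mod + o[, 3] * q_sev

  # decedent accrual: under "none", occupancy of an exacerbation state
  # contributes nothing for the fraction that dies at the next transition
  weighted <- function(m) {
    o <- occs[[m + 1]]
    if (cv$decedent_accrual == "none" && m >= 1 && m < n_cycles) {
      o[, 2] <- o[, 2] * (1 - rep_len(exit_dead_mod[[m + 1]], n))
      o[, 3] <- o[, 3] * (1 - rep_len(exit_dead_sev[[m + 1]], n))
    }
    o
  }

  cost <- qaly <- numeric(n)
  cycle_cost <- cycle_qaly <- matrix(0, n, n_cycles)
  for (m in seq_len(n_cycles)) {
    o <- if (cv$half_cycle_correction)
      (weighted(m - 1) + weighted(m)) / 2 else weighted(m)
    cc <- r_cost(o)
    if (arm == "device" && cv$device_cost_timing == "prorated")
      cc <- cc + pl$cost_device / n_cycles * (1 - occs[[m + 1]][, 4])
    cq <- r_qaly(o)
    cycle_cost[, m] <- cc
    cycle_qaly[, m] <- cq
    cost <- cost + cc
    qaly <- qaly + cq
  }
  entry_cost <- if (arm == "device" && cv$device_cost_timing == "entry")
    pl$cost_device else numeric(n)
  cost <- cost + entry_cost

  out <- list(cost = cost, qaly = qaly)
  if (trace) {
    stopifnot(n == 1)
    occm <- do.call(rbind, occs)
    colnames(occm) <- STATE_LABELS
    tr <- data.frame(cycle = 0:n_cycles, occm,
                     cycle_cost = c(entry_cost[1], cycle_cost[1, ]),
                     cycle_qalys = c(0, cycle_qaly[1, ]))
    tr$cum_cost <- cumsum(tr$cycle_cost)
    tr$cum_qalys <- cumsum(tr$cycle_qalys)
    out$trace <- tr
  }
  out
}

#' Run the cohort model for one strategy arm
#'
#' Propagates a cohort that enters fully exacerbation-free through
#' `n_cycles` monthly transitions and accrues undiscounted costs and
#' quality-adjusted life years. Monthly cost is the occupancy-weighted sum
#' of the per-state monthly costs; monthly QALY accrual gives every alive
#' state one month of the baseline utility minus the state's utility
#' decrement (a severe month's contribution is negative at the base-case
#' inputs). The device arm is charged the acquisition cost according to
#' the convention's `device_cost_timing`.
#'
#' @inheritParams build_transition_row
#' @return An object of class `opep_arm_result`: a list with `arm`,
#'   `total_cost`, `total_qalys`, the per-cycle `trace` data frame
#'   (occupancy per state, per-cycle and cumulative accruals; cycle 0 is
#'   the entry row) and the `conventions` used.
#' @examples
#' res <- run_cohort(model_params(), "control")
#' res$total_cost
#' head(res$trace)
#' @export
run_cohort <- function(params, arm = c("device", "control"),
                       conventions = NULL) {
  arm <- match.arg(arm)
  cv <- as_conventions(conventions)
  validate_params(params)
  acc <- cohort_accrue(lapply(unclass(params), as.numeric), arm, cv,
                       trace = TRUE)
  structure(list(arm = arm, total_cost = acc$cost, total_qalys = acc$qaly,
                 trace = acc$trace, conventions = cv),
            class = "opep_arm_result")
}

#' @export
print.opep_arm_result <- function(x, ...) {
  cat(sprintf("Cohort arm result (%s arm, %d cycles)\n", x$arm,
              nrow(x$trace) - 1L))
  cat(sprintf("  total cost:  $%.2f\n  total QALYs: %.4f\n",
              x$total_cost, x$total_qalys))
  cat(sprintf("  survival at horizon: %.4f\n",
              1 - x$trace$dead[nrow(x$trace)]))
  invisible(x)
}

#' Write a cohort trace to CSV
#'
#' @param result An `opep_arm_result` from [run_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  stopifnot(inherits(result, "opep_arm_result"))
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
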