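# Strategy comparison: incremental cost and effect, dominance
# classification, and the one-way deterministic sensitivity analysis.

#' Compare the device and control arms
#'
#' Runs the cohort model for both strategy arms on one parameter set and
#' returns incremental results (device minus control). The comparison is
#' classified as `"dominant"` (cheaper and more effective), `"dominated"`
#' (costlier and less effective) or `"icer_reported"`, in which case the
#' incremental cost-effectiveness ratio is the cost difference per QALY
#' gained. When the QALY difference is exactly zero the ICER is undefined:
#' `icer` is `NA`, `icer_defined` is `FALSE`, and the label follows the
#' sign of the cost difference alone.
#'
#' @inheritParams build_transition_row
#' @return An object of class `opep_ce_result` with elements `delta_cost`,
#'   `delta_qalys`, `icer`, `icer_defined`, `classification`, and the two
#'   `opep_arm_result`s (`device`, `control`).
#' @examples
#' evaluate_strategy_pair(model_params())
#' @export
evaluate_strategy_pair <- function(params, conventions = NULL) {
  cv <- as_conventions(conventions)
  validate_params(params)
  dev <- run_cohort(params, "device", cv)
  ctl <- run_cohort(params, "control", cv)
  dc <- dev$total_cost - ctl$total_cost
  de <- dev$total_qalys - ctl$total_qalys
  icer_defined <- de != 0
  if (dc < 0 && de > 0) {
    cls <- "dominant"; icer <- NA_real_
  } else if (dc > 0 && de < 0) {
    cls <- "dominated"; icer <- NA_real_
  } else if (!icer_defined) {
    icer <- NA_real_
    cls <- if (dc > 0) "dominated" else if (dc < 0) "dominant" else "equivalent"
  } else {
    cls <- "icer_reported"; icer <- dc / de
  }
  structure(list(delta_cost = dc, delta_qalys = de, icer = icer,
                 icer_defined = icer_defined, classification = cls,
                 device = dev, control = ctl, conventions = cv),
            class = "opep_ce_result")
}

#' @export
print.opep_ce_result <- function(x, ...) {
  cat("Incremental cost-utility result (device vs control)\n")
  cat(sprintf("  cost:  device $%.2f, control $%.2f, incremental $%.2f\n",
              x$device$total_cost, x$control$total_cost, x$delta_cost))
  cat(sprintf("  QALYs: device %.4f, control %.4f, incremental %.4f\n",
              x$device$total_qalys, x$control$total_qalys, x$delta_qalys))
  if (x$classification == "icer_reported")
    cat(sprintf("  ICER: $%.0f per QALY\n", x$icer))
  else
    cat(sprintf("  classification: %s\n", x$classification))
  invisible(x)
}

#' Sustained-effect scenario
#'
#' Re-runs the strategy comparison assuming the device's effect on
#' exacerbations persists for the whole horizon: the later-cycle relative
#' risk is set equal to the first-month relative risk, all other inputs
#' unchanged.
#'
#' @inheritParams build_transition_row
#' @return An `opep_ce_result`, as [evaluate_strategy_pair()].
#' @examples
#' run_scenario(model_params())
#' @export
run_scenario <- function(params, conventions = NULL) {
  validate_params(params)
  params$rr_later <- params$rr_month1
  evaluate_strategy_pair(params, conventions)
}

#' Classify a point on the cost-effectiveness plane
#'
#' Labels an incremental (cost, QALY) pair and decides cost-effectiveness
#' at a willingness-to-pay threshold by the sign of the net monetary
#' benefit `delta_qalys * wtp - delta_cost`.
#'
#' @param delta_cost Incremental cost (device minus control), currency.
#' @param delta_qalys Incremental QALYs.
#' @param wtp Willingness to pay per QALY, non-negative (default 50,000).
#' @return A list with `label` (`"dominant"`, `"dominated"`,
#'   `"icer_reported"`, or `"equivalent"`), `icer` (`NA` under dominance),
#'   `nmb`, and logical `cost_effective`.
#' @examples
#' classify_dominance(-694.15, 0.04, 50000)
#' @export
classify_dominance <- function(delta_cost, delta_qalys, wtp = 50000) {
  stopifnot(wtp >= 0)
  nmb <- delta_qalys * wtp - delta_cost
  if (delta_cost < 0 && delta_qalys > 0) {
    label <- "dominant"; icer <- NA_real_
  } else if (delta_cost > 0 && delta_qalys < 0) {
    label <- "dominated"; icer <- NA_real_
  } else if (delta_qalys == 0) {
    icer <- NA_real_
    label <- if (delta_cost > 0) "dominated"
             else if (delta_cost < 0) "dominant" else "equivalent"
  } else {
    label <- "icer_reported"; icer <- delta_cost / delta_qalys
  }
  list(label = label, icer = icer, nmb = nmb, cost_effective = nmb > 0)
}

#' Low/high bounds for the sensitivity-analysis parameters
#'
#' Every model input with a published plausible range is varied over
#' mean -/+ `fraction` * mean. Bounds of probabilities, proportions and
#' the baseline utility are truncated to \[0, 1\].
#'
#' @param params An `opep_params` object.
#' @param fraction Half-width of the range as a fraction of the mean
#'   (default 0.20).
#' @return A data frame with columns `parameter`, `mean`, `low`, `high`.
#' @export
param_bounds <- function(params, fraction = 0.20) {
  validate_params(params)
  stopifnot(fraction > 0, fraction < 1)
  mean <- unlist(params[VARYING_PARAMS])
  low <- mean * (1 - fraction)
  high <- mean * (1 + fraction)
  unit <- VARYING_PARAMS %in% UNIT_INTERVAL_PARAMS
  low[unit] <- pmax(low[unit], 0)
  high[unit] <- pmin(high[unit], 1)
  data.frame(parameter = VARYING_PARAMS, mean = unname(mean),
             low = unname(low), high = unname(high))
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the strategy comparison with each sensitivity parameter in
#' turn set to its low and high bound (see [param_bounds()]), all others
#' held at the base case, and orders parameters by the width of the
#' incremental-cost range they induce (tornado ordering). Varying a severe
#' share moves the moderate share to its complement automatically, since
#' moderate exacerbations are modelled as the non-severe remainder.
#'
#' @inheritParams build_transition_row
#' @param fraction Fractional half-width of the ranges (default 0.20).
#' @return An object of class `opep_dsa`: a data frame with one row per
#'   parameter (`parameter`, `low`, `high`, incremental cost and QALYs at
#'   each bound, `cost_range`, `qaly_range`, `cost_rank`, `qaly_rank`),
#'   sorted by decreasing `cost_range`, with the base-case
#'   `opep_ce_result` attached as attribute `"base_case"`.
#' @examples
#' dsa <- one_way_dsa(model_params())
#' head(dsa[, c("parameter", "dcost_low", "dcost_high", "cost_range")])
#' @export
one_way_dsa <- function(params, fraction = 0.20, conventions = NULL) {
  cv <- as_conventions(conventions)
  validate_params(params)
  bounds <- param_bounds(params, fraction)
  base <- evaluate_strategy_pair(params, cv)
  eval_at <- function(name, value) {
    p <- params
    p[[name]] <- value
    evaluate_strategy_pair(p, cv)
  }
  rows <- lapply(seq_len(nrow(bounds)), function(i) {
    lo <- eval_at(bounds$parameter[i], bounds$low[i])
    hi <- eval_at(bounds$parameter[i], bounds$high[i])
    data.frame(parameter = bounds$parameter[i],
               low = bounds$low[i], high = bounds$high[i],
               dcost_low = lo$delta_cost, dcost_high = hi$delta_cost,
               dqaly_low = lo$delta_qalys, dqaly_high = hi$delta_qalys)
  })
  out <- do.call(rbind, rows)
  out$cost_range <- abs(out$dcost_high - out$dcost_low)
  out$qaly_range <- abs(out$dqaly_high - out$dqaly_low)
  out$cost_rank <- rank(-out$cost_range, ties.method = "first")
  out$qaly_rank <- rank(-out$qaly_range, ties.method = "first")
  out <- out[order(out$cost_rank), ]
  rownames(out) <- NULL
  attr(out, "base_case") <- base
  attr(out, "fraction") <- fraction
  class(out) <- c("opep_dsa", "data.frame")
  out
}
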