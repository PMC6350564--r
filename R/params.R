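# Model parameters: the complete input set driving both strategy arms.

# Parameters varied in sensitivity analyses (every input with a plausible
# range; the device acquisition cost is fixed).
VARYING_PARAMS <- c(
  "p_exac_month1", "p_exac_later", "p_death_severe", "p_death_annual",
  "rr_month1", "rr_later", "frac_severe_device", "frac_severe_control",
  "cost_severe", "cost_moderate", "cost_no_exac",
  "utility_copd", "decrement_severe", "decrement_moderate"
)

# Parameters constrained to [0,1] (probabilities, proportions, utility).
UNIT_INTERVAL_PARAMS <- c(
  "p_exac_month1", "p_exac_later", "p_death_severe", "p_death_annual",
  "frac_severe_device", "frac_severe_control", "utility_copd"
)

#' Construct the model parameter set
#'
#' Builds and validates the complete set of inputs for the two-arm Markov
#' cohort model. The defaults are the published base case for the Canadian
#' (Alberta) setting: post-exacerbation COPD patients followed over twelve
#' monthly cycles, comparing an oscillating positive expiratory pressure
#' (OPEP) device against no PEP/OPEP therapy. Costs are 2017 Canadian
#' dollars.
#'
#' @param p_exac_month1 Probability of a moderate-to-severe exacerbation in
#'   the first monthly cycle (untreated arm).
#' @param p_exac_later Monthly exacerbation probability in cycles 2 to
#'   `n_cycles` (untreated arm).
#' @param rr_month1 Relative risk of exacerbation in cycle 1 under the
#'   device.
#' @param rr_later Relative risk in cycles 2 onward; 1 in the base case
#'   (no sustained effect assumed), set equal to `rr_month1` in the
#'   sustained-effect scenario.
#' @param frac_severe_device,frac_severe_control Proportion of
#'   exacerbations that are severe (hospitalised) in each arm; the
#'   remainder are moderate (emergency visit only).
#' @param p_death_severe Case fatality of a severe exacerbation month.
#' @param p_death_annual Background annual mortality of COPD patients,
#'   applied to non-hospitalised states after conversion to a monthly
#'   probability (see [annual_to_monthly_probability()]).
#' @param cost_severe,cost_moderate,cost_no_exac Monthly healthcare cost
#'   (CAD 2017) of a severe exacerbation month, a moderate exacerbation
#'   month, and an exacerbation-free month.
#' @param cost_device Device acquisition cost per patient per year.
#' @param utility_copd Baseline annual utility of COPD patients.
#' @param decrement_severe,decrement_moderate Utility decrement applied to
#'   a month spent with a severe / moderate exacerbation.
#' @param n_cycles Number of monthly cycles (time horizon).
#'
#' @return A validated object of class `opep_params` (a named list).
#' @examples
#' p <- model_params()
#' p$p_exac_month1
#' @seealso [load_params()] to read a parameter set from a YAML document,
#'   [generate_random_param_set()] for random valid parameter sets.
#' @export
model_params <- function(p_exac_month1 = 0.257,
                         p_exac_later = 0.059,
                         rr_month1 = 0.72,
                         rr_later = 1.0,
                         frac_severe_device = 0.691,
                         frac_severe_control = 0.706,
                         p_death_severe = 0.110,
                         p_death_annual = 0.010,
                         cost_severe = 13119,
                         cost_moderate = 456,
                         cost_no_exac = 65,
                         cost_device = 90,
                         utility_copd = 0.897,
                         decrement_severe = 0.504,
                         decrement_moderate = 0.12,
                         n_cycles = 12L) {
  p <- list(
    p_exac_month1 = p_exac_month1, p_exac_later = p_exac_later,
    rr_month1 = rr_month1, rr_later = rr_later,
    frac_severe_device = frac_severe_device,
    frac_severe_control = frac_severe_control,
    p_death_severe = p_death_severe, p_death_annual = p_death_annual,
    cost_severe = cost_severe, cost_moderate = cost_moderate,
    cost_no_exac = cost_no_exac, cost_device = cost_device,
    utility_copd = utility_copd, decrement_severe = decrement_severe,
    decrement_moderate = decrement_moderate, n_cycles = as.integer(n_cycles)
  )
  class(p) <- "opep_params"
  validate_params(p)
}

stop_validation <- function(field, msg) {
  stop(structure(
    class = c("opep_validation_error", "error", "condition"),
    list(message = sprintf("invalid parameter '%s': %s", field, msg),
         call = NULL, field = field)
  ))
}

#' Validate a model parameter set
#'
#' Checks every invariant of the parameter set: probabilities, proportions
#' and the baseline utility in \[0, 1\]; costs non-negative; relative risks
#' positive; the severe decrement at least the moderate one; at least one
#' cycle. Violations raise a condition of class `opep_validation_error`
#' whose `field` element names the offending parameter.
#'
#' @param params An `opep_params` object or plain named list with the same
#'   fields.
#' @return `params`, invisibly classed as `opep_params`, if valid.
#' @export
validate_params <- function(params) {
  required <- c(VARYING_PARAMS, "cost_device", "n_cycles")
  missing <- setdiff(required, names(params))
  if (length(missing) > 0)
    stop_validation(missing[1], "missing from the parameter set")
  for (f in required) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop_validation(f, "must be a single finite number")
  }
  for (f in UNIT_INTERVAL_PARAMS) {
    v <- params[[f]]
    if (v < 0 || v > 1)
      stop_validation(f, sprintf("must lie in [0, 1], got %g", v))
  }
  for (f in c("cost_severe", "cost_moderate", "cost_no_exac", "cost_device",
              "decrement_severe", "decrement_moderate")) {
    if (params[[f]] < 0) stop_validation(f, "must be non-negative")
  }
  for (f in c("rr_month1", "rr_later")) {
    if (params[[f]] <= 0) stop_validation(f, "must be positive")
  }
  if (params$decrement_severe < params$decrement_moderate)
    stop_validation("decrement_severe",
                    "must be at least decrement_moderate")
  if (params$n_cycles < 1)
    stop_validation("n_cycles", "must be at least 1")
  if (!inherits(params, "opep_params")) class(params) <- "opep_params"
  invisible(params)
}

#' @export
print.opep_params <- function(x, ...) {
  cat("COPD cost-utility model parameters (CAD 2017,",
      x$n_cycles, "monthly cycles)\n")
  df <- data.frame(value = unlist(x[setdiff(names(x), "n_cycles")]))
  print(df, ...)
  invisible(x)
}

#' Severity-weighted baseline utility
#'
#' Aggregates per-severity utility scores into a single baseline utility
#' for the COPD population by taking the dot product with the severity
#' distribution (e.g. mild/moderate/severe/very severe shares).
#'
#' @param weights Proportions of the population per severity grade; must
#'   sum to 1.
#' @param utilities Utility score per grade, each in \[0, 1\].
#' @return The population-average utility.
#' @examples
#' derive_copd_utility(c(0.27, 0.55, 0.15, 0.03), c(0.97, 0.93, 0.72, 0.52))
#' @export
derive_copd_utility <- function(weights, utilities) {
  if (length(weights) != length(utilities))
    stop_validation("severity_weights",
                    "weights and utilities must have equal length")
  if (abs(sum(weights) - 1) > 1e-9)
    stop_validation("severity_weights",
                    sprintf("must sum to 1, got %.12g", sum(weights)))
  if (any(weights < 0))
    stop_validation("severity_weights", "must be non-negative")
  if (any(utilities < 0 | utilities > 1))
    stop_validation("severity_utilities", "must lie in [0, 1]")
  sum(weights * utilities)
}

#' Monthly outpatient follow-up cost
#'
#' The cost of an exacerbation-free month is the dot product of unit costs
#' for outpatient resources (physician visit, antibiotics, corticosteroids)
#' with their monthly utilisation frequencies.
#'
#' @param unit_costs Cost per use of each resource (CAD).
#' @param frequencies Uses per patient per month.
#' @return Expected cost per patient per month.
#' @examples
#' derive_no_exac_cost(c(78, 251, 101), c(0.131, 0.172, 0.113)) # 64.80
#' @export
derive_no_exac_cost <- function(unit_costs, frequencies) {
  if (length(unit_costs) != length(frequencies))
    stop_validation("outpatient_unit_costs",
                    "costs and frequencies must have equal length")
  if (any(unit_costs < 0))
    stop_validation("outpatient_unit_costs", "must be non-negative")
  if (any(frequencies < 0))
    stop_validation("outpatient_frequencies", "must be non-negative")
  sum(unit_costs * frequencies)
}

#' Monthly utility decrement from an annual decrement
#'
#' Converts a per-year utility decrement into the decrement applied to a
#' single month spent in the exacerbation state, by scaling with the number
#' of months per year (an exacerbation month concentrates the annual
#' quality-of-life loss into that month).
#'
#' @param annual_decrement Utility decrement per year, non-negative.
#' @return The per-event-month decrement, `12 * annual_decrement`.
#' @examples
#' derive_monthly_decrement(0.042) # 0.504
#' @export
derive_monthly_decrement <- function(annual_decrement) {
  if (any(annual_decrement < 0))
    stop_validation("annual_decrement", "must be non-negative")
  12 * annual_decrement
}

#' Annual to monthly probability conversion
#'
#' Converts an annual event probability to a monthly one under a constant
#' hazard: `1 - (1 - p)^(1/12)`. The naive division `p/12` is available
#' through the accounting-convention switch (see [convention_config()]);
#' the two differ by less than 1e-5 at the background mortality used here.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @param method `"hazard"` (constant-hazard, default) or `"linear"`
#'   (`p/12`).
#' @return Monthly probability in \[0, `p_annual`\].
#' @examples
#' annual_to_monthly_probability(0.01)
#' @export
annual_to_monthly_probability <- function(p_annual,
                                          method = c("hazard", "linear")) {
  method <- match.arg(method)
  if (any(p_annual < 0 | p_annual > 1))
    stop_validation("p_annual", "must lie in [0, 1]")
  if (method == "hazard") 1 - (1 - p_annual)^(1 / 12) else p_annual / 12
}

#' Standard deviation from a fractional range
#'
#' Treats the interval mean ± `fraction` * mean as a 95% confidence
#' interval of a normal distribution, so the implied standard deviation is
#' `|mean| * fraction / 1.96`. This is the rule used to equip every
#' sensitivity-analysis parameter with a dispersion when only a point
#' estimate is published.
#'
#' @param mean Point estimate.
#' @param fraction Half-width of the range as a fraction of the mean
#'   (default 0.20).
#' @return The implied standard deviation.
#' @examples
#' sd_from_fractional_range(13119) # 1338.67, printed rounded as ~$1,339
#' @export
sd_from_fractional_range <- function(mean, fraction = 0.20) {
  if (any(fraction <= 0))
    stop_validation("fraction", "must be positive")
  abs(mean) * fraction / 1.96
}
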