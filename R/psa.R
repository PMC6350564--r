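# Probabilistic sensitivity analysis: method-of-moments distribution
# fitting, independent parameter sampling, vectorised evaluation of both
# arms per draw, cost-effectiveness plane regions and the acceptability
# curve.

#' Fit a sampling distribution by the method of moments
#'
#' Fits the distribution family conventionally attached to each kind of
#' health-economic input — beta for probabilities, proportions and
#' utilities, gamma for costs and utility decrements, log-normal for
#' relative risks — so that the fitted distribution reproduces the given
#' mean and standard deviation exactly (log-normal on the natural scale).
#' A zero standard deviation yields a degenerate `"fixed"` spec.
#'
#' Method-of-moments parameterisations:
#' * beta: `k = m(1-m)/s^2 - 1`, `shape1 = m k`, `shape2 = (1-m) k`
#' * gamma: `shape = (m/s)^2`, `scale = s^2/m`
#' * log-normal: `sdlog^2 = log(1 + s^2/m^2)`,
#'   `meanlog = log(m) - sdlog^2/2`
#'
#' @param family `"beta"`, `"gamma"`, `"lognormal"` or `"fixed"`.
#' @param mean Target mean, inside the family's support.
#' @param sd Target standard deviation, non-negative.
#' @return An object of class `opep_dist_spec`: a list with `family`,
#'   `mean`, `sd` and the fitted parameters (`shape1`/`shape2`,
#'   `shape`/`scale`, or `meanlog`/`sdlog`).
#' @examples
#' fit_distribution("gamma", 13119, sd_from_fractional_range(13119))
#' fit_distribution("beta", 0.5, sqrt(1 / 12)) # the uniform distribution
#' @export
fit_distribution <- function(family = c("beta", "gamma", "lognormal", "fixed"),
                             mean, sd) {
  family <- match.arg(family)
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0)
  if (sd == 0) family <- "fixed"
  spec <- list(family = family, mean = mean, sd = sd)
  if (family == "beta") {
    if (mean <= 0 || mean >= 1)
      stop("beta requires mean strictly inside (0, 1)")
    if (sd^2 >= mean * (1 - mean))
      stop("beta requires sd^2 < mean * (1 - mean)")
    k <- mean * (1 - mean) / sd^2 - 1
    spec$shape1 <- mean * k
    spec$shape2 <- (1 - mean) * k
  } else if (family == "gamma") {
    if (mean <= 0) stop("gamma requires a positive mean")
    spec$shape <- (mean / sd)^2
    spec$scale <- sd^2 / mean
  } else if (family == "lognormal") {
    if (mean <= 0) stop("lognormal requires a positive mean")
    s2 <- log(1 + sd^2 / mean^2)
    spec$sdlog <- sqrt(s2)
    spec$meanlog <- log(mean) - s2 / 2
  }
  class(spec) <- "opep_dist_spec"
  spec
}

#' @export
print.opep_dist_spec <- function(x, ...) {
  pars <- setdiff(names(x), c("family", "mean", "sd"))
  cat(sprintf("%s(mean = %g, sd = %g)", x$family, x$mean, x$sd))
  if (length(pars))
    cat(" [", paste(sprintf("%s = %.6g", pars, unlist(x[pars])),
                    collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

# Draw n values from a fitted spec.
draw_from_spec <- function(spec, n) {
  switch(spec$family,
         fixed = rep(spec$mean, n),
         beta = stats::rbeta(n, spec$shape1, spec$shape2),
         gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
         lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog))
}

#' Default distribution assignments for the probabilistic analysis
#'
#' Builds the full table of sampling distributions: beta for event
#' probabilities, severity shares and the baseline utility; gamma for the
#' three state costs and the two utility decrements; log-normal for the
#' two relative risks. Every standard deviation comes from the fractional
#' range rule ([sd_from_fractional_range()]) applied to the parameter's
#' base-case mean; the device acquisition cost is not sampled. Family
#' overrides stored on the parameter object by [load_params()] (the
#' `distributions` block of the YAML document) are honoured.
#'
#' @param params An `opep_params` object.
#' @param fraction Fractional half-width treated as the 95% interval
#'   (default 0.20).
#' @return A named list of `opep_dist_spec` objects, one per sampled
#'   parameter.
#' @export
psa_spec_table <- function(params, fraction = 0.20) {
  validate_params(params)
  default_family <- function(name) {
    if (name %in% UNIT_INTERVAL_PARAMS) "beta"
    else if (name %in% c("rr_month1", "rr_later")) "lognormal"
    else "gamma"
  }
  overrides <- attr(params, "distributions")
  specs <- lapply(VARYING_PARAMS, function(name) {
    fam <- overrides[[name]] %||% default_family(name)
    m <- params[[name]]
    fit_distribution(fam, m, sd_from_fractional_range(m, fraction))
  })
  stats::setNames(specs, VARYING_PARAMS)
}

# Sample n parameter sets as a list of column vectors; unsampled fields
# (device cost, horizon) are carried over from the base set. Sampling
# order is the fixed column order of VARYING_PARAMS, so results are
# reproducible under a given RNG state.
draw_columns <- function(base, specs, n_draws) {
  missing <- setdiff(VARYING_PARAMS, names(specs))
  if (length(missing) > 0)
    stop("no distribution spec for parameter(s): ",
         paste(missing, collapse = ", "))
  pl <- lapply(unclass(base), as.numeric)
  for (f in VARYING_PARAMS) pl[[f]] <- draw_from_spec(specs[[f]], n_draws)
  pl
}

#' Draw one random parameter set for the probabilistic analysis
#'
#' Draws each sensitivity parameter independently from its fitted
#' distribution and returns a validated parameter set; unsampled fields
#' (the device cost and the horizon) keep their base-case values. The
#' chosen families respect each parameter's support, so no clipping is
#' required.
#'
#' @param base The base-case `opep_params`.
#' @param specs Named list of `opep_dist_spec`s, as from
#'   [psa_spec_table()].
#' @return A validated `opep_params` object.
#' @examples
#' set.seed(1)
#' draw_parameter_set(model_params(), psa_spec_table(model_params()))
#' @export
draw_parameter_set <- function(base, specs = psa_spec_table(base)) {
  validate_params(base)
  pl <- draw_columns(base, specs, 1L)
  p <- lapply(pl, function(v) v[1])
  p$n_cycles <- as.integer(base$n_cycles)
  class(p) <- "opep_params"
  validate_params(p)
}

#' Draw a table of random parameter sets
#'
#' Vectorised counterpart of [draw_parameter_set()]: returns `n_draws`
#' independent parameter sets as a data frame, one column per sampled
#' parameter.
#'
#' @inheritParams draw_parameter_set
#' @param n_draws Number of sets to draw.
#' @return A data frame with `n_draws` rows and one column per sampled
#'   parameter.
#' @export
draw_parameter_sets <- function(base, specs = psa_spec_table(base),
                                n_draws = 1000L) {
  validate_params(base)
  stopifnot(n_draws >= 1)
  as.data.frame(draw_columns(base, specs, as.integer(n_draws))[VARYING_PARAMS])
}

#' Willingness-to-pay grid
#'
#' @param min,max,step Grid limits and spacing in currency per QALY
#'   (defaults 0 to 100,000 by 1,000).
#' @return Strictly increasing numeric vector of thresholds.
#' @export
wtp_grid <- function(min = 0, max = 100000, step = 1000) {
  stopifnot(min >= 0, max > min, step > 0)
  seq(min, max, by = step)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter sets (all sensitivity parameters varying
#' independently), evaluates both strategy arms on each draw — the two
#' arms share the drawn set within a draw — and summarises the joint
#' distribution of incremental cost and effect: the proportion of draws
#' in each cost-effectiveness-plane region, the acceptability curve over
#' a willingness-to-pay grid, and the probability of cost-effectiveness
#' at a reference threshold.
#'
#' Plane regions partition the draws: `dominant` (cheaper, more
#' effective), `dominated` (costlier, less effective; boundary draws with
#' a zero difference fall here), `ne_below_wtp` and `ne_above_wtp`
#' (costlier and more effective, on either side of the reference
#' willingness-to-pay line), and `sw` (cheaper, less effective).
#' Cost-effectiveness at a threshold is defined by positive net monetary
#' benefit; the additive region count `dominant + ne_below_wtp` is
#' reported alongside (`prob_ce_additive`), the two differing only in the
#' treatment of the small `sw` region.
#'
#' @inheritParams draw_parameter_set
#' @param n_draws Number of Monte-Carlo draws (default 100,000).
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param wtp Willingness-to-pay grid for the acceptability curve.
#' @param region_wtp Reference threshold for the region split and the
#'   headline cost-effectiveness probability (default 50,000).
#' @param conventions An `opep_conventions` object; `NULL` for the default.
#' @param keep_samples If `TRUE`, the per-draw incremental results are
#'   returned in element `samples`.
#' @return An object of class `opep_psa`: `n_draws`, `seed`, `regions`
#'   (named proportions summing to 1), `prob_dominant`, `prob_dominated`,
#'   `prob_ce`, `prob_ce_additive`, `region_wtp`, `ceac` (data frame
#'   `wtp`, `prob_cost_effective`), mean incremental cost and QALYs, and
#'   optionally `samples`.
#' @examples
#' psa <- run_psa(model_params(), n_draws = 2000, seed = 1)
#' psa$regions
#' @export
run_psa <- function(base, specs = psa_spec_table(base), n_draws = 100000L,
                    seed = 1L, wtp = wtp_grid(), region_wtp = 50000,
                    conventions = NULL, keep_samples = FALSE) {
  cv <- as_conventions(conventions)
  validate_params(base)
  stopifnot(n_draws >= 1, region_wtp >= 0, all(diff(wtp) > 0), all(wtp >= 0))
  set.seed(as.integer(seed))
  pl <- draw_columns(base, specs, as.integer(n_draws))
  dev <- cohort_accrue(pl, "device", cv)
  ctl <- cohort_accrue(pl, "control", cv)
  dc <- dev$cost - ctl$cost
  de <- dev$qaly - ctl$qaly

  dominant <- dc < 0 & de > 0
  dominated <- dc >= 0 & de <= 0
  ne <- dc >= 0 & de > 0
  sw <- dc < 0 & de <= 0
  nmb_ref <- de * region_wtp - dc
  regions <- c(dominant = mean(dominant),
               ne_below_wtp = mean(ne & nmb_ref > 0),
               ne_above_wtp = mean(ne & nmb_ref <= 0),
               dominated = mean(dominated),
               sw = mean(sw))
  ceac <- vapply(wtp, function(l) mean(de * l - dc > 0), numeric(1))

  out <- list(
    n_draws = as.integer(n_draws), seed = as.integer(seed),
    regions = regions,
    prob_dominant = unname(regions["dominant"]),
    prob_dominated = unname(regions["dominated"]),
    prob_ce = mean(nmb_ref > 0),
    prob_ce_additive = unname(regions["dominant"] + regions["ne_below_wtp"]),
    region_wtp = region_wtp,
    ceac = data.frame(wtp = wtp, prob_cost_effective = ceac),
    mean_delta_cost = mean(dc), mean_delta_qalys = mean(de),
    conventions = cv
  )
  if (keep_samples)
    out$samples <- data.frame(draw = seq_len(n_draws), delta_cost = dc,
                              delta_qalys = de)
  class(out) <- "opep_psa"
  out
}

#' @export
print.opep_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis (%d draws, seed %d)\n",
              x$n_draws, x$seed))
  cat(sprintf("  mean incremental cost:  $%.2f\n", x$mean_delta_cost))
  cat(sprintf("  mean incremental QALYs: %.4f\n", x$mean_delta_qalys))
  cat("  cost-effectiveness plane regions:\n")
  for (r in names(x$regions))
    cat(sprintf("    %-14s %6.1f%%\n", r, 100 * x$regions[r]))
  cat(sprintf("  P(cost-effective at $%s/QALY): %.1f%% (NMB), %.1f%% (regions)\n",
              format(x$region_wtp, big.mark = ","), 100 * x$prob_ce,
              100 * x$prob_ce_additive))
  invisible(x)
}
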