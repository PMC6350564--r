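# YAML parameter documents: one human-editable file holds the full input
# table, the raw ingredients of the composite inputs, and the distribution
# family assigned to each parameter for probabilistic analysis.

#' Read and validate a model parameter document
#'
#' Loads a YAML parameter document (see
#' `system.file("extdata", "copd_base_case.yaml", package = "opepcua")`
#' for the base-case file). The document has a `params` block with the
#' fields of [model_params()], an optional `derivation` block with the raw
#' ingredients of the composite inputs, and an optional `distributions`
#' block naming the sampling family per parameter.
#'
#' Composite inputs missing from `params` (`utility_copd`, `cost_no_exac`,
#' `decrement_severe`, `decrement_moderate`) are computed from the
#' `derivation` block via [derive_copd_utility()], [derive_no_exac_cost()]
#' and [derive_monthly_decrement()].
#'
#' @param path Path to the YAML document.
#' @return An `opep_params` object. The derivation block, distribution
#'   assignments and currency tag travel along as attributes
#'   `"derivation"`, `"distributions"` and `"currency"`.
#' @export
load_params <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$params))
    stop_validation("params", "document has no 'params' block")
  p <- doc$params
  der <- doc$derivation
  if (is.null(p$utility_copd) && !is.null(der))
    p$utility_copd <- derive_copd_utility(unlist(der$severity_weights),
                                          unlist(der$severity_utilities))
  if (is.null(p$cost_no_exac) && !is.null(der))
    p$cost_no_exac <- derive_no_exac_cost(unlist(der$outpatient_unit_costs),
                                          unlist(der$outpatient_frequencies))
  if (is.null(p$decrement_severe) && !is.null(der))
    p$decrement_severe <- derive_monthly_decrement(der$annual_decrements$severe)
  if (is.null(p$decrement_moderate) && !is.null(der))
    p$decrement_moderate <- derive_monthly_decrement(der$annual_decrements$moderate)
  if (is.null(p$n_cycles)) p$n_cycles <- 12L
  p$n_cycles <- as.integer(p$n_cycles)
  class(p) <- "opep_params"
  validate_params(p)
  attr(p, "derivation") <- der
  attr(p, "distributions") <- doc$distributions
  attr(p, "currency") <- if (is.null(doc$currency)) "CAD2017" else doc$currency
  p
}

#' Write a model parameter document
#'
#' Serialises an `opep_params` object (and any derivation / distribution
#' attributes) back to YAML with full double precision, so that
#' `load_params(write_params(p, f))` reproduces every field bit-identically.
#'
#' @param params An `opep_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  doc <- list(currency = attr(params, "currency") %||% "CAD2017",
              params = unclass(params)[names(unclass(params))])
  attr(doc$params, "derivation") <- NULL
  if (!is.null(attr(params, "derivation")))
    doc$derivation <- attr(params, "derivation")
  if (!is.null(attr(params, "distributions")))
    doc$distributions <- attr(params, "distributions")
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The published base-case parameter document
#'
#' Convenience accessor for the parameter document shipped with the
#' package, holding the published Canadian base-case inputs.
#'
#' @return An `opep_params` object.
#' @export
base_case_params <- function() {
  load_params(system.file("extdata", "copd_base_case.yaml",
                          package = "opepcua", mustWork = TRUE))
}
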