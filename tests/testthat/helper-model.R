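# Shared fixtures and an independent, hand-coded transition-row builder
# used to guard the engine's row construction (dual implementation with
# different code paths).

STATES <- c("no_exac", "moderate_exac", "severe_exac", "dead")

# A convention grid covering every switch at least once.
convention_grid <- list(
  convention_config(),
  convention_config(exac_survivor_routing = "simple",
                    half_cycle_correction = FALSE),
  convention_config(death_competition = "before_exac",
                    device_cost_timing = "prorated"),
  convention_config(exac_survivor_routing = "simple",
                    decedent_accrual = "none",
                    annual_prob_conversion = "linear"),
  convention_config(decedent_accrual = "none")
)

# Reference row builder, written directly from the model description and
# deliberately structured differently from the package implementation:
# it assembles each row entry by entry.
ref_transition_row <- function(p, arm, state, cycle, cv) {
  mort <- if (cv$annual_prob_conversion == "linear") {
    p$p_death_annual / 12
  } else {
    1 - (1 - p$p_death_annual)^(1 / 12)
  }
  hazard <- if (cycle == 1) p$p_exac_month1 else p$p_exac_later
  if (arm == "device") {
    hazard <- hazard * (if (cycle == 1) p$rr_month1 else p$rr_later)
  }
  hazard <- min(hazard, 1)
  severe_share <- if (arm == "device") p$frac_severe_device else
    p$frac_severe_control
  # row out of the exacerbation-free state
  if (cv$death_competition == "before_exac") {
    p_die <- mort
    p_sev <- (1 - mort) * hazard * severe_share
    p_mod <- (1 - mort) * hazard * (1 - severe_share)
  } else {
    p_sev <- hazard * severe_share
    p_mod <- hazard * (1 - severe_share)
    p_die <- (1 - hazard) * mort
  }
  row_free <- c(1 - p_sev - p_mod - p_die, p_mod, p_sev, p_die)
  if (state == "no_exac") return(setNames(row_free, STATES))
  if (state == "dead") return(setNames(c(0, 0, 0, 1), STATES))
  exit_death <- if (state == "severe_exac") p$p_death_severe else mort
  if (cv$exac_survivor_routing == "composite") {
    row <- (1 - exit_death) * row_free
    row[4] <- row[4] + exit_death
  } else {
    row <- c(1 - exit_death, 0, 0, exit_death)
  }
  setNames(row, STATES)
}

expect_params_equal <- function(a, b, tol = 0) {
  for (f in names(unclass(a))) {
    expect_equal(a[[f]], b[[f]], tolerance = tol, info = f)
  }
}
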