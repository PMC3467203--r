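# shared fixtures, built in code

base_sc <- default_scenario()

# short horizon keeps per-test cohort runs fast where lifetime detail is
# not the point
short_sc <- override(base_sc, "horizon_years", 5)

# a scenario in which nothing ever happens: no events, no mortality
inert_scenario <- function(horizon_years = 2) {
  lt <- data.frame(age = 65:100, annual_mortality_probability = 0)
  sc <- default_scenario(life_table = lt)
  for (nm in c("rate_stroke_warfarin", "rate_ich_warfarin",
               "rate_ech_warfarin", "rate_minor_bleed_warfarin",
               "rate_mi_warfarin"))
    sc <- override(sc, nm, 0)
  override(sc, "horizon_years", horizon_years)
}

# collapse every sensitivity range to the base value (degenerate PSA)
degenerate_scenario <- function(sc = base_sc) {
  rng <- !is.na(sc$parameters$low) & !is.na(sc$parameters$high)
  sc$parameters$low[rng] <- sc$parameters$base[rng]
  sc$parameters$high[rng] <- sc$parameters$base[rng]
  validate_scenario(sc)
  sc
}

# a neutral scenario: apixaban indistinguishable from warfarin
symmetric_scenario <- function(horizon_years = 10) {
  sc <- override(base_sc, "horizon_years", horizon_years)
  for (nm in c("hr_stroke_apixaban", "hr_ich_apixaban", "hr_ech_apixaban",
               "rr_minor_bleed_apixaban", "hr_mi_apixaban"))
    sc <- override(sc, nm, 1)
  sc <- override(sc, "cost_apixaban_2wk", param_value(sc, "cost_warfarin_2wk"))
  override(sc, "u_apixaban", param_value(sc, "u_warfarin"))
}

well_state <- function(treatment = "warfarin") {
  list(treatment = treatment, stroke = "none", ich = "none", mi = 0L,
       alive = TRUE)
}
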