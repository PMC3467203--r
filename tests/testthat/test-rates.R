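test_that("annual rates convert to cycle probabilities by the exponential rule", {
  expect_identical(annual_rate_to_cycle_prob(0, 14), 0)
  # closed form evaluated independently, 12 decimal places
  expect_equal(annual_rate_to_cycle_prob(1.05, 14),
               1 - exp(-0.0105 * 14 / 365.25), tolerance = 1e-12)
  # saturation: huge rates approach 1 but never exceed it
  expect_lte(annual_rate_to_cycle_prob(1e6, 14), 1)
  expect_gt(annual_rate_to_cycle_prob(1e6, 14), 1 - 1e-10)
  expect_lt(annual_rate_to_cycle_prob(100, 14), 1)
  # monotone in the rate
  r <- seq(0, 50, by = 0.5)
  expect_true(all(diff(annual_rate_to_cycle_prob(r, 14)) > 0))
  expect_error(annual_rate_to_cycle_prob(-1, 14), "non-negative")
})

test_that("age adjustment applies the per-decade relative risk by decade", {
  expect_equal(age_adjust(1.05, 1.4, 65, 65), 1.05)
  expect_equal(age_adjust(1.05, 1.4, 75, 65), 1.05 * 1.4)  # = 1.47
  expect_equal(age_adjust(0.80, 1.97, 85, 65), 0.80 * 1.97^2)
  # steps: constant within a decade, jumps at its boundary
  expect_equal(age_adjust(1.05, 1.4, 74.9, 65), 1.05)
  expect_equal(age_adjust(1.05, 1.4, 75.0, 65), 1.47)
  # continuous alternative interpolates smoothly
  expect_equal(age_adjust(1.05, 1.4, 70, 65, method = "continuous"),
               1.05 * 1.4^0.5)
  expect_error(age_adjust(1, 1.4, 60, 65), ">= ref_age")
})

test_that("event mixing keeps one event per cycle with an explicit remainder", {
  expect_identical(event_mix(numeric(0)), c(no_event = 1))
  expect_equal(event_mix(c(stroke = 0.2)),
               c(stroke = 0.2, no_event = 0.8))
  expect_equal(event_mix(list(list("a", 0.1), list("b", 0.3))),
               c(a = 0.1, b = 0.3, no_event = 0.6))
  expect_error(event_mix(c(a = 0.6, b = 0.5)), "implausible")
  expect_error(event_mix(c(a = -0.1)), "\\[0, 1\\)")
})

test_that("a base-case cycle mixes independently converted per-event rates", {
  # the engine's first-cycle probabilities for warfarin must equal the
  # per-rate conversions done by hand here
  cp <- apixcea:::cycle_prob_matrix(base_sc, "warfarin")
  conv <- function(annual) 1 - exp(-(annual / 100) * 14 / 365.25)
  expect_equal(unname(cp[1, "stroke_drug"]), conv(1.05 * 0.72), tolerance = 1e-12)
  expect_equal(unname(cp[1, "tia_drug"]), conv(1.05 * 0.28), tolerance = 1e-12)
  expect_equal(unname(cp[1, "ich_drug"]), conv(0.80), tolerance = 1e-12)
  expect_equal(unname(cp[1, "ech_drug"]), conv(3.09), tolerance = 1e-12)
  expect_equal(unname(cp[1, "mb_drug"]), conv(2.55), tolerance = 1e-12)
  expect_equal(unname(cp[1, "mi_drug"]), conv(0.61), tolerance = 1e-12)
  # apixaban scales hemorrhage streams by its hazard ratios
  cpa <- apixcea:::cycle_prob_matrix(base_sc, "apixaban")
  expect_equal(unname(cpa[1, "ich_drug"]), conv(0.80 * 0.42), tolerance = 1e-12)
  expect_equal(unname(cpa[1, "ech_drug"]), conv(3.09 * 0.69), tolerance = 1e-12)
  # aspirin streams are shared between strategies
  expect_equal(unname(cp[1, "stroke_asp"]), conv(1.05 * 2.08 * 0.72), tolerance = 1e-12)
  expect_equal(unname(cpa[, "stroke_asp"]), unname(cp[, "stroke_asp"]))
})

test_that("stroke severity splits follow the treatment-specific distributions", {
  s <- split_stroke(1, "warfarin")
  expect_equal(unname(s), c(8.2, 40.2, 42.5, 9.1) / 100)
  expect_equal(names(s), c("fatal", "major", "minor", "rind"))
  expect_equal(sum(s), 1)
  expect_equal(split_stroke(1, "apixaban"), s)

  a <- split_stroke(1, "aspirin")
  # printed aspirin fractions sum to 99.9; the split renormalises
  expect_equal(unname(a), c(17.9, 30.0, 41.0, 11.0) / 99.9)
  expect_equal(sum(a), 1)

  expect_equal(unname(split_stroke(0, "warfarin")), rep(0, 4))

  bad <- af_parameters()
  bad$base[bad$name == "frac_stroke_fatal"] <- 30
  bad$base[bad$name == "frac_stroke_major"] <- 30
  bad$base[bad$name == "frac_stroke_minor"] <- 30
  bad$base[bad$name == "frac_stroke_rind"] <- 30
  expect_error(split_stroke(1, "warfarin", bad), "sum to 100")
})

test_that("ICH severity splits follow the Hylek distribution", {
  s <- split_ich(1)
  expect_equal(unname(s), c(36.4, 14.1, 49.5) / 100)
  expect_equal(unname(split_ich(0)), rep(0, 3))
  bad <- af_parameters()
  bad$base[bad$name == "frac_ich_fatal"] <- 30
  bad$base[bad$name == "frac_ich_major"] <- 30
  bad$base[bad$name == "frac_ich_minor"] <- 30
  expect_error(split_ich(1, bad), "sum to 100")
})

test_that("non-event death combines life-table hazard and excess-mortality ratios", {
  lt <- base_sc$life_table
  q65 <- lt$annual_mortality_probability[1]
  dt <- 14 / 365.25

  p_af <- nonevent_death_prob(65, "none", lt, 14)
  expect_equal(p_af, 1 - exp(log(1 - q65) * 1.3 * dt), tolerance = 1e-12)

  # default composition: 2.3 replaces 1.3 for ischemic stroke survivors
  p_stroke <- nonevent_death_prob(65, "major_stroke", lt, 14)
  expect_equal(p_stroke, 1 - exp(log(1 - q65) * 2.3 * dt), tolerance = 1e-12)
  # ICH-only survivors keep the AF ratio
  expect_equal(nonevent_death_prob(65, "major_ich", lt, 14), p_af)
  # multiplicative composition stacks the ratios
  expect_equal(nonevent_death_prob(65, "stroke_and_ich", lt, 14,
                                   composition = "multiplicative"),
               1 - exp(log(1 - q65) * 1.3 * 2.3 * dt), tolerance = 1e-12)

  # zero mortality stays zero; ages beyond the table clamp to its last row
  lt0 <- data.frame(age = 65:100, annual_mortality_probability = 0)
  expect_equal(nonevent_death_prob(70, "none", lt0, 14), 0)
  expect_equal(nonevent_death_prob(140, "none", lt, 14),
               nonevent_death_prob(100, "none", lt, 14))
})

test_that("discount factors follow 3% per annum compounding", {
  expect_identical(discount_factor(0, 14, 0.03), 1)
  # a full year of cycles discounts by exactly 1/1.03
  expect_equal(discount_factor(365.25 / 14, 14, 0.03), 1 / 1.03,
               tolerance = 1e-12)
  expect_equal(discount_factor(0:100, 14, 0), rep(1, 101))
  expect_true(all(diff(discount_factor(0:100, 14, 0.03)) < 0))
})
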