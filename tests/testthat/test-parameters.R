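test_that("the bundled scenario carries the published base values and ranges", {
  path <- system.file("extdata", "default_scenario.yaml", package = "apixcea")
  sc <- load_scenario(path)
  p <- sc$parameters
  row <- function(nm) p[match(nm, p$name), ]

  expect_equal(unlist(row("rate_stroke_warfarin")[c("base", "low", "high")],
                      use.names = FALSE), c(1.05, 0.92, 1.24))
  expect_equal(row("cost_apixaban_2wk")$base, 95)
  expect_equal(unlist(row("cost_apixaban_2wk")[c("low", "high")],
                      use.names = FALSE), c(51, 154))
  expect_equal(row("hr_ich_apixaban")$base, 0.42)
  expect_equal(row("frac_ich_fatal")$base, 36.4)
  expect_equal(row("rr_death_af_stroke")$base, 2.3)
  expect_equal(param_value(sc, "disc_rate_pct"), 3)
  expect_equal(sc$start_age, 65)
  expect_equal(sc$cycle_days, 14)
  expect_equal(sc$wtp, 50000)
  # matches the in-code constructor bit for bit
  expect_identical(sc$parameters, default_scenario()$parameters)
})

test_that("the cost-103 variant only changes the apixaban drug cost", {
  sc <- default_scenario("apixaban_cost_103")
  expect_equal(param_value(sc, "cost_apixaban_2wk"), 103)
  d <- default_scenario()
  same <- sc$parameters$name != "cost_apixaban_2wk"
  expect_identical(sc$parameters[same, ], d$parameters[same, ])
})

test_that("scenario files round-trip every value bit-exactly", {
  dir <- withr::local_tempdir()
  for (ext in c("yaml", "json")) {
    f <- file.path(dir, paste0("sc.", ext))
    write_scenario(base_sc, f)
    back <- load_scenario(f)
    expect_identical(back$parameters, base_sc$parameters)
    expect_equal(back$life_table, base_sc$life_table)
    expect_equal(back[scenario_fields <- c("start_age", "cycle_days",
                                           "horizon_years", "wtp")],
                 base_sc[scenario_fields])
  }
})

test_that("invalid scenarios are rejected with the offending key named", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.yaml")

  write_scenario(base_sc, f)
  y <- yaml::read_yaml(f)
  y$parameters$u_warfarin <- list(1.2, 0.94, 1)   # utility above 1
  yaml::write_yaml(y, f)
  expect_error(load_scenario(f), "u_warfarin")

  y$parameters$u_warfarin <- NULL                 # missing parameter
  yaml::write_yaml(y, f)
  expect_error(load_scenario(f), "missing.*u_warfarin")

  write_scenario(base_sc, f)
  y <- yaml::read_yaml(f)
  y$parameters$cost_event_ich <- list(41645, 50000, 71000)  # low > base
  yaml::write_yaml(y, f)
  expect_error(load_scenario(f), "cost_event_ich")

  expect_error(load_scenario(file.path(dir, "nope.yaml")), "not found")
})

test_that("override returns a modified copy and leaves the original alone", {
  sc <- base_sc
  sc2 <- override(sc, "hr_ich_apixaban", 0.42)   # identity value
  expect_identical(sc2$parameters, sc$parameters)
  expect_equal(run_base_case(override(short_sc, "hr_ich_apixaban", 0.42)),
               run_base_case(short_sc))

  sc3 <- override(sc, "cost_apixaban_2wk", 51)
  expect_equal(param_value(sc3, "cost_apixaban_2wk"), 51)
  expect_equal(param_value(sc, "cost_apixaban_2wk"), 95)

  # distinct keys commute
  a <- override(override(sc, "cost_apixaban_2wk", 60), "wtp", 10000)
  b <- override(override(sc, "wtp", 10000), "cost_apixaban_2wk", 60)
  expect_identical(a, b)

  expect_error(override(sc, "not_a_parameter", 1), "unknown parameter")
})

test_that("a parameter set stripped of a key fails fast at run time", {
  sc <- short_sc
  sc$parameters <- sc$parameters[sc$parameters$name != "cost_event_ich", ]
  expect_error(run_strategy(sc, "apixaban"), "cost_event_ich")
  expect_error(validate_scenario(sc), "missing.*cost_event_ich")
})

test_that("horizon and life-table coverage are enforced", {
  expect_equal(n_cycles(base_sc), 913L)  # 35y of 2-week cycles
  expect_error(override(base_sc, "horizon_years", 0.01), "whole cycle")
  lt <- data.frame(age = 65:80, annual_mortality_probability = 0.01)
  expect_error(default_scenario(life_table = lt), "life table must cover")
})

test_that("the bundled life table is a valid single-year table", {
  lt <- load_life_table()
  expect_equal(lt$age, 65:100)
  expect_true(all(diff(lt$annual_mortality_probability) > 0))
  expect_true(all(lt$annual_mortality_probability > 0 &
                  lt$annual_mortality_probability < 1))
})
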