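test_that("microsimulation is deterministic and stable under cohort growth", {
  sc <- override(base_sc, "horizon_years", 5)
  a <- simulate_patients(sc, "apixaban", n = 200, seed = 42)
  b <- simulate_patients(sc, "apixaban", n = 200, seed = 42)
  expect_identical(a$totals, b$totals)
  # per-patient RNG streams: the first 100 patients of a larger run are
  # exactly the 100 patients of a smaller one
  small <- simulate_patients(sc, "apixaban", n = 100, seed = 42)
  expect_identical(a$totals[1:100, ], small$totals)
  c <- simulate_patients(sc, "apixaban", n = 200, seed = 43)
  expect_false(identical(a$totals, c$totals))
})

test_that("an event-free patient survives the horizon and accrues it fully", {
  sc <- inert_scenario(horizon_years = 2)
  sim <- simulate_patients(sc, "warfarin", n = 1, seed = 1)
  nc <- n_cycles(sc)
  expect_equal(unname(sim$totals[1, "ly"]), nc * 14 / 365.25)
  expect_equal(unname(sim$totals[1, "ly_disc"]),
               sum(discount_factor(0:(nc - 1), 14, 0.03)) * 14 / 365.25)
})

test_that("microsimulation means agree with the cohort trace", {
  # the patient-level simulation consumes the same transition rows as the
  # cohort engine, so its sample means must estimate the trace totals
  n <- 30000
  for (s in c("apixaban", "warfarin")) {
    sim <- simulate_patients(base_sc, s, n = n, seed = 77)
    cohort <- run_cohort(base_sc, s, full_trace = FALSE)$totals
    for (q in c("cost_disc", "qaly_disc", "ly_disc")) {
      m <- sim$summary$mean[sim$summary$quantity == q]
      se <- sim$summary$se[sim$summary$quantity == q]
      expect_lt(abs(m - cohort[[q]]) / se, 3)
    }
  }
})

test_that("first-cycle event draws match the analytic event mix", {
  # chi-square goodness of fit of simulated first-cycle events against the
  # engine's own per-cycle probabilities
  one_cycle <- override(base_sc, "horizon_years", 14 / 365.25 * 1.01)
  expect_equal(n_cycles(one_cycle), 1L)
  n <- 100000
  sim <- simulate_patients(one_cycle, "warfarin", n = n, seed = 13,
                           keep_trajectories = TRUE)
  obs <- table(factor(sim$trajectories$event,
                      levels = c("none", apixcea:::.events)))

  inp <- apixcea:::engine_inputs(one_cycle, "warfarin")
  topo <- inp$topo
  mine <- topo$transitions$from == topo$start_state
  p <- inp$cp[1, topo$tr_rate[mine]] * inp$frac[topo$tr_frac[mine]]
  probs <- c(none = 1 - sum(p),
             stats::setNames(p, topo$transitions$event[mine]))
  probs <- probs[names(obs)]
  probs[is.na(probs)] <- 0
  keep <- probs > 0
  expect_equal(sum(obs[!keep]), 0)  # impossible events never drawn
  fit <- suppressWarnings(
    stats::chisq.test(obs[keep], p = probs[keep] / sum(probs[keep])))
  expect_gt(fit$p.value, 0.001)
})

test_that("event histories export in long format with consistent totals", {
  sc <- override(base_sc, "horizon_years", 3)
  sim <- simulate_patients(sc, "apixaban", n = 50, seed = 3,
                           keep_trajectories = TRUE)
  df <- export_event_histories(sim)
  expect_true(all(c("patient", "cycle", "age", "state", "event",
                    "cost_increment", "utility") %in% names(df)))
  # at most one event per cycle, cycles strictly ordered within patient
  expect_false(any(duplicated(df[, c("patient", "cycle")])))
  for (i in unique(df$patient))
    expect_true(!is.unsorted(df$cycle[df$patient == i], strictly = TRUE))
  # undiscounted per-patient cost sums equal the trajectory totals
  sums <- tapply(df$cost_increment, df$patient, sum)
  expect_equal(as.numeric(sums[as.character(1:50)]),
               as.numeric(sim$totals[, "cost"]))

  # writing to disk round-trips the table
  f <- withr::local_tempfile(fileext = ".csv")
  export_event_histories(sim, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(df))

  # an empty input gives a header-only table
  empty <- export_event_histories(NULL)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("patient", "event", "cost_increment") %in% names(empty)))

  expect_error(export_event_histories(simulate_patients(sc, "apixaban",
                                                        n = 2, seed = 1)),
               "keep_trajectories")
})

test_that("a single simulated stroke appears exactly once in the history", {
  # force a scenario where stroke is the only possible event and certain
  lt <- data.frame(age = 65:100, annual_mortality_probability = 0)
  sc <- default_scenario(life_table = lt)
  for (nm in c("rate_ich_warfarin", "rate_ech_warfarin",
               "rate_minor_bleed_warfarin", "rate_mi_warfarin"))
    sc <- override(sc, nm, 0)
  sc <- override(sc, "rate_stroke_warfarin", 5000)  # near-certain per cycle
  sc <- override(sc, "tia_fraction_pct", 0)
  sc <- override(sc, "frac_stroke_fatal", 100)
  for (nm in c("frac_stroke_major", "frac_stroke_minor", "frac_stroke_rind"))
    sc <- override(sc, nm, 0)
  sc <- override(sc, "horizon_years", 2)
  sim <- simulate_patients(sc, "warfarin", n = 20, seed = 8,
                           keep_trajectories = TRUE)
  df <- export_event_histories(sim)
  strokes <- df[df$event == "stroke_fatal", ]
  expect_equal(nrow(strokes), 20)          # one fatal stroke per patient
  expect_equal(as.integer(table(strokes$patient)), rep(1L, 20))
})
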