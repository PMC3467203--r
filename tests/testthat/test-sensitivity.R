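test_that("triangular sampling inverts the CDF over its support", {
  expect_equal(sample_triangular(2, 5, 10, 0), 2)
  expect_equal(sample_triangular(2, 5, 10, 1), 10)
  # u at the CDF of the mode returns the mode (closed-form CDF)
  expect_equal(sample_triangular(2, 5, 10, (5 - 2) / (10 - 2)), 5)
  expect_equal(sample_triangular(3, 3, 3, 0.42), 3)
  expect_error(sample_triangular(5, 2, 10, 0.5), "low <= mode <= high")
  expect_error(sample_triangular(2, 5, 10, 1.2), "u must lie")

  # sample mean matches the analytic (low+mode+high)/3 within 3 SE
  set.seed(7)
  n <- 1e5
  x <- sample_triangular(2, 5, 10, stats::runif(n))
  expect_true(all(x >= 2 & x <= 10))
  se <- stats::sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - (2 + 5 + 10) / 3), 3 * se)
})

test_that("sampled parameter sets stay in range with coherent splits", {
  set.seed(11)
  for (i in 1:50) {
    p <- psa_sample_parameters(base_sc)
    rng <- !is.na(p$low) & !is.na(p$high)
    free <- rng & !grepl("^frac_", p$name)  # splits are renormalised
    expect_true(all(p$base[free] >= p$low[free] &
                    p$base[free] <= p$high[free]))
    sum_of <- function(nms) sum(p$base[match(nms, p$name)])
    expect_equal(sum_of(c("frac_stroke_fatal", "frac_stroke_major",
                          "frac_stroke_minor", "frac_stroke_rind")), 100)
    expect_equal(sum_of(c("frac_ich_fatal", "frac_ich_major",
                          "frac_ich_minor")), 100)
  }
})

test_that("a degenerate PSA reproduces the deterministic base case", {
  sc <- override(degenerate_scenario(), "horizon_years", 5)
  psa <- run_psa(sc, n_iter = 3, seed = 99)
  det <- apixcea:::run_pair(sc)
  expect_equal(psa$plane$delta_cost, rep(det$delta_cost, 3), tolerance = 1e-9)
  expect_equal(psa$plane$delta_qaly, rep(det$delta_qaly, 3), tolerance = 1e-9)
})

test_that("the PSA is reproducible under a fixed seed", {
  sc <- override(base_sc, "horizon_years", 3)
  a <- run_psa(sc, n_iter = 5, seed = 123)
  b <- run_psa(sc, n_iter = 5, seed = 123)
  expect_identical(a$plane, b$plane)
  expect_identical(a$samples, b$samples)
  c <- run_psa(sc, n_iter = 5, seed = 124)
  expect_false(identical(a$plane, c$plane))
})

test_that("cost-effectiveness at WTP is monotone in the threshold", {
  sc <- override(base_sc, "horizon_years", 5)
  psa <- run_psa(sc, n_iter = 200, seed = 5)
  frac_ce <- vapply(c(0, 2e4, 5e4, 1e5, 1e6), function(w) {
    mean(w * psa$plane$delta_qaly - psa$plane$delta_cost > 0)
  }, numeric(1))
  expect_true(all(diff(frac_ce) >= 0))
  expect_gte(psa$frac_ce_at_wtp, psa$frac_dominant)
})

test_that("independent seeds agree within binomial error", {
  n <- 600
  a <- run_psa(base_sc, n_iter = n, seed = 101)
  b <- run_psa(base_sc, n_iter = n, seed = 202)
  for (stat in c("frac_dominant", "frac_ce_at_wtp")) {
    pa <- a[[stat]]; pb <- b[[stat]]
    pool <- (pa + pb) / 2
    se <- sqrt(2 * pool * (1 - pool) / n)
    expect_lt(abs(pa - pb), max(3 * se, 1e-9))
  }
})

test_that("one-way thresholds are genuine sign changes", {
  ow <- one_way(base_sc, "cost_apixaban_2wk", n_points = 5)
  expect_true(all(ow$grid$value >= 51 & ow$grid$value <= 154))
  thr <- ow$thresholds$dominance_boundary
  expect_false(is.na(thr))
  # re-evaluating at the threshold leaves essentially zero incremental cost
  at <- apixcea:::run_pair(override(base_sc, "cost_apixaban_2wk", thr))
  expect_lt(abs(at$delta_cost), 1)
  # dominance below the threshold, positive incremental cost above it
  below <- apixcea:::run_pair(override(base_sc, "cost_apixaban_2wk", thr - 5))
  above <- apixcea:::run_pair(override(base_sc, "cost_apixaban_2wk", thr + 5))
  expect_lt(below$delta_cost, 0)
  expect_gt(above$delta_cost, 0)
  expect_error(one_way(base_sc, "no_such_parameter"), "unknown parameter")
})

test_that("flat responses yield no threshold", {
  # the minor-bleed event cost cannot overturn dominance across its range
  ow <- one_way(base_sc, "cost_event_minor_bleed", n_points = 3)
  expect_true(is.na(ow$thresholds$dominance_boundary))
  expect_true(all(ow$grid$quadrant == "dominant"))
})

test_that("the horizon sweep reproduces the base case and improves with time", {
  hs <- horizon_sweep(base_sc, c(1, 5, 9, 20, 35))
  bc <- run_base_case(base_sc)
  expect_equal(hs$delta_cost[hs$years == 35], bc$comparison$delta_cost)
  expect_equal(hs$delta_qaly[hs$years == 35], bc$comparison$delta_qaly)
  # the ICER falls monotonically toward dominance as the horizon grows
  icer <- ifelse(hs$quadrant == "dominant", -Inf, hs$icer)
  expect_true(all(diff(icer) < 0))
  # one year of treatment is not cost-effective at $50k/QALY
  expect_false(hs$nmb[hs$years == 1] > 0)
  expect_equal(hs$quadrant[hs$years == 35], "dominant")
})

test_that("two-way grids agree with pointwise evaluation", {
  sc <- override(base_sc, "horizon_years", 5)
  # single-cell grid equals the one-off comparison at those values
  tw <- two_way(sc, "rate_stroke_warfarin", c(2, 2),
                "rate_ich_warfarin", c(0.7, 0.7), n = 1, m = 1)
  direct <- apixcea:::run_pair(
    override(override(sc, "rate_stroke_warfarin", 2),
             "rate_ich_warfarin", 0.7))
  expect_equal(tw$grid$delta_cost, direct$delta_cost)
  expect_equal(tw$grid$delta_qaly, direct$delta_qaly)

  # the base-case cell carries the base-case classification
  tw2 <- two_way(base_sc, "rate_stroke_warfarin", c(1.05, 1.05),
                 "rate_ich_warfarin", c(0.80, 0.80), n = 1, m = 1)
  expect_equal(tw2$grid$class, "dominant")
})
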