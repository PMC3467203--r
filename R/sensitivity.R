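#' Triangular-distribution quantile transform
#'
#' Inverse-CDF sampling for the triangular(low, mode, high) distribution
#' used for every ranged parameter in probabilistic sensitivity analysis.
#' Degenerate distributions (`low == high`) return the point mass.
#'
#' @param low,mode,high distribution support and likeliest value,
#'   `low <= mode <= high`.
#' @param u uniform(0,1) deviate(s).
#' @return sampled value(s), same length as `u`.
#' @export
sample_triangular <- function(low, mode, high, u) {
  if (!(low <= mode && mode <= high))
    stop("need low <= mode <= high, got (", low, ", ", mode, ", ", high, ")")
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  if (low == high) return(rep(low, length(u)))
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

ranged_parameters <- function(pars) {
  pars$name[!is.na(pars$low) & !is.na(pars$high)]
}

#' Sample one probabilistic parameter set
#'
#' Draws every ranged parameter independently from its
#' triangular(low, base, high) distribution.  Severity splits are then made
#' coherent: the four stroke severity fractions (per treatment class) are
#' renormalised to sum to 100%, and the minor-ICH fraction — which has no
#' published range — is set to the remainder after the sampled fatal and
#' major fractions.  Structural parameters without ranges are held at base.
#'
#' @param scenario an `af_scenario`.
#' @return a parameter data.frame with sampled `base` values.
#' @export
psa_sample_parameters <- function(scenario) {
  pars <- scenario$parameters
  nm <- ranged_parameters(pars)
  u <- stats::runif(length(nm))
  for (j in seq_along(nm)) {
    i <- match(nm[j], pars$name)
    pars$base[i] <- sample_triangular(pars$low[i], pars$base[i], pars$high[i],
                                      u[j])
  }
  renorm <- function(set) {
    i <- match(set, pars$name)
    pars$base[i] <<- pars$base[i] * 100 / sum(pars$base[i])
  }
  renorm(c("frac_stroke_fatal", "frac_stroke_major", "frac_stroke_minor",
           "frac_stroke_rind"))
  renorm(c("frac_stroke_asp_fatal", "frac_stroke_asp_major",
           "frac_stroke_asp_minor", "frac_stroke_asp_rind"))
  pars$base[match("frac_ich_minor", pars$name)] <-
    100 - pars$base[match("frac_ich_fatal", pars$name)] -
    pars$base[match("frac_ich_major", pars$name)]
  pars
}

run_pair <- function(scenario, pars = scenario$parameters) {
  res <- lapply(c("apixaban", "warfarin"), function(strat) {
    inp <- engine_inputs(scenario, strat, pars)
    topo <- inp$topo
    r <- cohort_run_cpp(nrow(topo$states), topo$dead_state, topo$start_state,
                        topo$tr_from, topo$tr_to, topo$tr_rate, topo$tr_frac,
                        topo$tr_event, inp$cp, inp$frac,
                        unname(inp$event$cost), unname(inp$event$du),
                        inp$state$cost, inp$state$util,
                        scenario$cycle_days, inp$disc,
                        isTRUE(scenario$half_cycle), FALSE)
    o <- as.list(r$totals[c("cost_disc", "qaly_disc", "ly_disc",
                            "cost", "qaly", "ly")])
    names(o) <- c("cost", "qaly", "ly", "cost_undisc", "qaly_undisc",
                  "ly_undisc")
    o$strategy <- strat
    class(o) <- "af_outcome"
    o
  })
  compare_strategies(res[[1]], res[[2]], scenario$wtp)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation over the joint parameter uncertainty: each
#' iteration draws a full parameter set ([psa_sample_parameters()]), runs
#' both strategies on the same draw, and records the incremental cost and
#' QALY point on the cost-effectiveness plane.  Summarised as the fraction
#' of draws in which apixaban is dominant (less costly, more effective) and
#' the fraction in which it is cost-effective at the willingness-to-pay
#' threshold (net monetary benefit > 0).
#'
#' @param scenario an `af_scenario`.
#' @param n_iter number of Monte Carlo iterations.
#' @param seed RNG seed (fixed for reproducibility).
#' @return an `af_psa` list: `n`, `frac_dominant`, `frac_ce_at_wtp`,
#'   `wtp`, `plane` (data.frame `draw`, `delta_cost`, `delta_qaly`),
#'   `samples` (matrix of sampled parameter values).
#' @export
run_psa <- function(scenario, n_iter = 10000, seed = 1) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  sampled_names <- ranged_parameters(scenario$parameters)
  samples <- matrix(NA_real_, n_iter, length(sampled_names),
                    dimnames = list(NULL, sampled_names))
  dc <- numeric(n_iter); dq <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    pars <- psa_sample_parameters(scenario)
    samples[i, ] <- pars$base[match(sampled_names, pars$name)]
    cmp <- run_pair(scenario, pars)
    dc[i] <- cmp$delta_cost; dq[i] <- cmp$delta_qaly
  }
  dominant <- dc < 0 & dq > 0
  ce <- scenario$wtp * dq - dc > 0
  stopifnot(all(ce[dominant]))  # dominant draws are always cost-effective
  out <- list(n = n_iter, frac_dominant = mean(dominant),
              frac_ce_at_wtp = mean(ce), wtp = scenario$wtp,
              plane = data.frame(draw = seq_len(n_iter), delta_cost = dc,
                                 delta_qaly = dq),
              samples = samples, seed = seed)
  class(out) <- "af_psa"
  out
}

#' @export
print.af_psa <- function(x, ...) {
  cat(sprintf("PSA (%d iterations): apixaban dominant in %.1f%%, cost-effective at $%s/QALY in %.1f%%\n",
              x$n, 100 * x$frac_dominant, format(x$wtp, big.mark = ","),
              100 * x$frac_ce_at_wtp))
  invisible(x)
}

bisect <- function(f, lo, hi, flo = f(lo), fhi = f(hi), tol) {
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (flo * fm < 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

#' One-way sensitivity analysis with threshold search
#'
#' Evaluates the apixaban-vs-warfarin comparison at `n_points` evenly
#' spaced values of one parameter across its plausible range, then locates
#' by bisection (tolerance `1e-6` of the range width) the threshold values
#' at which incremental cost crosses zero (loss of dominance) and at which
#' the ICER crosses the willingness-to-pay threshold (net monetary benefit
#' crosses zero), where the range brackets a sign change.
#'
#' @param scenario an `af_scenario`.
#' @param parameter a ranged parameter name.
#' @param n_points grid size.
#' @return an `af_oneway` list: `parameter`, `grid` (data.frame of value,
#'   incremental outcomes, quadrant), `thresholds` (named list
#'   `dominance_boundary`, `wtp_boundary`; `NA` when no crossing exists).
#' @export
one_way <- function(scenario, parameter, n_points = 11) {
  i <- match(parameter, scenario$parameters$name)
  if (is.na(i)) stop("unknown parameter: ", parameter)
  lo <- scenario$parameters$low[i]; hi <- scenario$parameters$high[i]
  if (is.na(lo) || is.na(hi))
    stop("parameter has no sensitivity range: ", parameter)
  eval_at <- function(v) run_pair(override(scenario, parameter, v))
  vals <- seq(lo, hi, length.out = n_points)
  cmps <- lapply(vals, eval_at)
  grid <- data.frame(
    value = vals,
    delta_cost = vapply(cmps, `[[`, numeric(1), "delta_cost"),
    delta_qaly = vapply(cmps, `[[`, numeric(1), "delta_qaly"),
    icer = vapply(cmps, `[[`, numeric(1), "icer"),
    nmb = vapply(cmps, `[[`, numeric(1), "nmb_at_wtp"),
    quadrant = vapply(cmps, `[[`, character(1), "quadrant"))
  tol <- 1e-6 * (hi - lo)
  thr_dom <- bisect(function(v) eval_at(v)$delta_cost, lo, hi,
                    grid$delta_cost[1], grid$delta_cost[n_points], tol)
  thr_wtp <- bisect(function(v) eval_at(v)$nmb_at_wtp, lo, hi,
                    grid$nmb[1], grid$nmb[n_points], tol)
  out <- list(parameter = parameter, grid = grid,
              thresholds = list(dominance_boundary = thr_dom,
                                wtp_boundary = thr_wtp))
  class(out) <- "af_oneway"
  out
}

#' One-way sensitivity analysis over all ranged parameters
#'
#' Runs [one_way()] for every parameter with a plausible range and returns
#' a tornado-style table: the comparison at each range end and any
#' dominance/WTP threshold inside the range.
#'
#' @param scenario an `af_scenario`.
#' @param n_points grid size per parameter.
#' @return data.frame with one row per parameter.
#' @export
owsa_all <- function(scenario, n_points = 3) {
  nms <- ranged_parameters(scenario$parameters)
  rows <- lapply(nms, function(nm) {
    ow <- one_way(scenario, nm, n_points = n_points)
    g <- ow$grid
    lab <- function(k) {
      if (g$quadrant[k] == "dominant") "Dominant"
      else if (g$quadrant[k] == "dominated") "Dominated"
      else format(round(g$icer[k]))
    }
    data.frame(parameter = nm, low = g$value[1], high = g$value[nrow(g)],
               result_at_low = lab(1), result_at_high = lab(nrow(g)),
               dominance_threshold = ow$thresholds$dominance_boundary,
               wtp_threshold = ow$thresholds$wtp_boundary,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Time-horizon sweep
#'
#' Re-runs the full comparison with the horizon truncated to each requested
#' number of years.
#'
#' @param scenario an `af_scenario`.
#' @param years numeric vector of horizons (years).
#' @return data.frame: `years`, incremental outcomes, `icer`, `quadrant`.
#' @export
horizon_sweep <- function(scenario, years = 1:35) {
  rows <- lapply(years, function(y) {
    cmp <- run_pair(override(scenario, "horizon_years", y))
    data.frame(years = y, delta_cost = cmp$delta_cost,
               delta_qaly = cmp$delta_qaly, icer = cmp$icer,
               nmb = cmp$nmb_at_wtp, quadrant = cmp$quadrant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-way sensitivity analysis
#'
#' Evaluates the comparison on an `n x m` grid over two parameter ranges
#' and classifies each cell as `"dominant"`, `"ce_at_wtp"` (positive ICER
#' below the willingness-to-pay threshold) or `"not_ce"`.
#'
#' @param scenario an `af_scenario`.
#' @param param_a,param_b parameter names.
#' @param range_a,range_b length-2 numeric ranges.
#' @param n,m grid dimensions.
#' @return an `af_twoway` list: `values_a`, `values_b`, `class` (n x m
#'   character matrix), `grid` (long data.frame incl. incremental results).
#' @export
two_way <- function(scenario, param_a, range_a, param_b, range_b,
                    n = 10, m = 10) {
  va <- seq(range_a[1], range_a[2], length.out = n)
  vb <- seq(range_b[1], range_b[2], length.out = m)
  cls <- matrix(NA_character_, n, m)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc <- override(override(scenario, param_a, va[i]), param_b, vb[j])
    cmp <- run_pair(sc)
    cls[i, j] <- if (cmp$quadrant == "dominant") "dominant"
      else if (cmp$cost_effective) "ce_at_wtp" else "not_ce"
    rows[[length(rows) + 1L]] <- data.frame(
      a = va[i], b = vb[j], delta_cost = cmp$delta_cost,
      delta_qaly = cmp$delta_qaly, icer = cmp$icer, class = cls[i, j],
      stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  names(grid)[1:2] <- c(param_a, param_b)
  out <- list(param_a = param_a, param_b = param_b, values_a = va,
              values_b = vb, class = cls, grid = grid)
  class(out) <- "af_twoway"
  out
}
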