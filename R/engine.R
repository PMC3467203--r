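# cached parameter-free topology
.apix_cache <- new.env(parent = emptyenv())

model_topology <- function() {
  if (is.null(.apix_cache$topology)) {
    states <- model_states()
    tr <- build_transitions(states)
    .apix_cache$topology <- list(
      states = states, transitions = tr,
      tr_from = tr$from, tr_to = tr$to,
      tr_rate = match(tr$rate_col, .rate_cols),
      tr_frac = match(tr$frac_id, .frac_ids),
      tr_event = match(tr$event, .events),
      dead_state = states$id[!states$alive],
      start_state = states$id[states$alive & states$treatment == "drug" &
                              states$stroke == "none" & states$ich == "none" &
                              states$mi == 0L][1])
  }
  .apix_cache$topology
}

#' Per-cycle event probabilities for every rate stream
#'
#' Builds the `n_cycles x 14` matrix of per-cycle probabilities feeding the
#' transition topology: ischemic stroke, TIA, ICH, ECH, minor bleeding and
#' MI for the strategy drug and for aspirin, and non-event death with and
#' without a prior ischemic stroke.  Stroke/TIA, ICH and MI rates step up
#' by their per-decade relative risks with each completed decade of life;
#' ECH and minor bleeding are age-constant.  The baseline ischemic-event
#' rate covers all ischemic neurologic events: 28% of it flows to the TIA
#' stream and 72% to the severity-split stroke stream.
#'
#' @param scenario an `af_scenario`.
#' @param strategy `"apixaban"` or `"warfarin"`.
#' @param pars parameter data.frame (defaults to the scenario's; PSA
#'   substitutes a sampled copy).
#' @param nc number of cycles (defaults to the scenario horizon).
#' @return numeric matrix, columns named as in `apixcea:::.rate_cols`.
#' @keywords internal
cycle_prob_matrix <- function(scenario, strategy, pars = scenario$parameters,
                              nc = n_cycles(scenario)) {
  pv <- function(nm) pget(pars, nm)
  dt_yr <- scenario$cycle_days / 365.25
  ages <- scenario$start_age + (seq_len(nc) - 1) * dt_yr
  ref <- scenario$start_age

  hr <- if (strategy == "apixaban") {
    c(stroke = pv("hr_stroke_apixaban"), ich = pv("hr_ich_apixaban"),
      ech = pv("hr_ech_apixaban"), mb = pv("rr_minor_bleed_apixaban"),
      mi = pv("hr_mi_apixaban"))
  } else if (strategy == "warfarin") {
    c(stroke = 1, ich = 1, ech = 1, mb = 1, mi = 1)
  } else stop("strategy must be 'apixaban' or 'warfarin'")
  rr_asp <- c(stroke = pv("rr_stroke_aspirin"), hem = pv("rr_hemorrhage_aspirin"),
              mi = pv("rr_mi_aspirin"))

  tia_mult <- pv("tia_fraction_pct") / 100
  stroke_mult <- 1 - tia_mult
  conv <- function(annual) annual_rate_to_cycle_prob(annual, scenario$cycle_days)

  stroke_base <- age_adjust(pv("rate_stroke_warfarin"), pv("rr_stroke_decade"),
                            ages, ref)
  ich_base <- age_adjust(pv("rate_ich_warfarin"), pv("rr_ich_decade"), ages, ref)
  mi_base <- age_adjust(pv("rate_mi_warfarin"), pv("rr_mi_decade"), ages, ref)
  ech_base <- rep(pv("rate_ech_warfarin"), nc)
  mb_base <- rep(pv("rate_minor_bleed_warfarin"), nc)

  comp <- scenario$stroke_mort_composition
  d_base <- nonevent_death_prob(ages, "none", scenario$life_table,
                                scenario$cycle_days, rr_af = pv("rr_death_af"),
                                rr_af_stroke = pv("rr_death_af_stroke"),
                                composition = comp)
  d_neuro <- nonevent_death_prob(ages, "stroke", scenario$life_table,
                                 scenario$cycle_days, rr_af = pv("rr_death_af"),
                                 rr_af_stroke = pv("rr_death_af_stroke"),
                                 composition = comp)

  cp <- cbind(
    stroke_drug = conv(stroke_base * hr["stroke"] * stroke_mult),
    stroke_asp = conv(stroke_base * rr_asp["stroke"] * stroke_mult),
    tia_drug = conv(stroke_base * hr["stroke"] * tia_mult),
    tia_asp = conv(stroke_base * rr_asp["stroke"] * tia_mult),
    ich_drug = conv(ich_base * hr["ich"]),
    ich_asp = conv(ich_base * rr_asp["hem"]),
    ech_drug = conv(ech_base * hr["ech"]),
    ech_asp = conv(ech_base * rr_asp["hem"]),
    mb_drug = conv(mb_base * hr["mb"]),
    mb_asp = conv(mb_base * rr_asp["hem"]),
    mi_drug = conv(mi_base * hr["mi"]),
    mi_asp = conv(mi_base * rr_asp["mi"]),
    death_base = d_base,
    death_neuro = d_neuro)
  colnames(cp) <- .rate_cols
  cp
}

# severity-split fractions and fatal-event fractions as probabilities,
# indexed by .frac_ids
frac_vector <- function(scenario, pars = scenario$parameters) {
  pv <- function(nm) pget(pars, nm)
  f <- c(one = 1,
         s_fatal = pv("frac_stroke_fatal"), s_major = pv("frac_stroke_major"),
         s_minor = pv("frac_stroke_minor"), s_rind = pv("frac_stroke_rind"),
         sa_fatal = pv("frac_stroke_asp_fatal"), sa_major = pv("frac_stroke_asp_major"),
         sa_minor = pv("frac_stroke_asp_minor"), sa_rind = pv("frac_stroke_asp_rind"),
         i_fatal = pv("frac_ich_fatal"), i_major = pv("frac_ich_major"),
         i_minor = pv("frac_ich_minor"))
  f[c("s_fatal", "s_major", "s_minor", "s_rind")] <-
    check_split_fractions(f[c("s_fatal", "s_major", "s_minor", "s_rind")],
                          "stroke")
  f[c("sa_fatal", "sa_major", "sa_minor", "sa_rind")] <-
    check_split_fractions(f[c("sa_fatal", "sa_major", "sa_minor", "sa_rind")],
                          "aspirin stroke")
  f[c("i_fatal", "i_major", "i_minor")] <-
    check_split_fractions(f[c("i_fatal", "i_major", "i_minor")], "ICH")
  f[-1] <- f[-1] / 100
  fe <- scenario$fatal_ech_fraction
  fm <- scenario$fatal_mi_fraction
  c(f, ech_fatal = fe, ech_nonfatal = 1 - fe,
    mi_fatal = fm, mi_nonfatal = 1 - fm)[.frac_ids]
}

# per-state bi-weekly cost and per-cycle utility, via the economics module
state_reward_vectors <- function(scenario, strategy, pars = scenario$parameters) {
  states <- model_topology()$states
  drug_name <- strategy
  n <- nrow(states)
  cost <- numeric(n); util <- numeric(n)
  for (i in seq_len(n)) {
    st <- state_row_to_list(states, i)
    if (st$alive && st$treatment == "drug") st$treatment <- drug_name
    cost[i] <- cycle_cost(st, NULL, pars)
    util[i] <- cycle_utility(st, NULL, pars,
                             combination = scenario$utility_combination,
                             cycle_days = scenario$cycle_days)
  }
  list(cost = cost, util = util)
}

# per-event one-time cost and full-cycle-equivalent utility decrement,
# indexed by .events
event_reward_vectors <- function(scenario, pars = scenario$parameters) {
  cost <- vapply(.events, function(e) pget(pars, event_cost_param[[e]]),
                 numeric(1))
  du <- stats::setNames(numeric(length(.events)), .events)
  du["ech"] <- pget(pars, "du_major_bleed")
  du["minor_bleed"] <- pget(pars, "du_minor_bleed") * 2 / scenario$cycle_days
  list(cost = cost, du = du)
}

engine_inputs <- function(scenario, strategy, pars = scenario$parameters) {
  topo <- model_topology()
  list(topo = topo,
       cp = cycle_prob_matrix(scenario, strategy, pars),
       frac = unname(frac_vector(scenario, pars)),
       state = state_reward_vectors(scenario, strategy, pars),
       event = event_reward_vectors(scenario, pars),
       disc = pget(pars, "disc_rate_pct") / 100)
}

#' Run the deterministic cohort trace for one strategy
#'
#' Iterates the whole cohort (starting in the well-with-AF state on the
#' strategy drug) through every cycle of the horizon, accumulating per-cycle
#' cost, QALY and life-year increments before and after discounting.
#'
#' @param scenario an `af_scenario`.
#' @param strategy `"apixaban"` or `"warfarin"`.
#' @param full_trace keep the full occupancy matrix and per-cycle
#'   increments (set `FALSE` for speed inside sensitivity loops).
#' @return an `af_trace` list: `totals` (named vector), and with
#'   `full_trace` also `occupancy` (cycles+1 x states, rows summing to 1)
#'   and `cycles` (per-cycle data.frame).
#' @export
run_cohort <- function(scenario, strategy = c("apixaban", "warfarin"),
                       full_trace = TRUE) {
  strategy <- match.arg(strategy)
  inp <- engine_inputs(scenario, strategy)
  topo <- inp$topo
  res <- cohort_run_cpp(nrow(topo$states), topo$dead_state, topo$start_state,
                        topo$tr_from, topo$tr_to, topo$tr_rate, topo$tr_frac,
                        topo$tr_event, inp$cp, inp$frac,
                        unname(inp$event$cost), unname(inp$event$du),
                        inp$state$cost, inp$state$util,
                        scenario$cycle_days, inp$disc,
                        isTRUE(scenario$half_cycle), full_trace)
  out <- list(strategy = strategy, totals = res$totals)
  if (full_trace) {
    colnames(res$occupancy) <- topo$states$label
    out$occupancy <- res$occupancy
    nc <- nrow(inp$cp)
    out$cycles <- data.frame(
      cycle = seq_len(nc) - 1L,
      age = scenario$start_age + (seq_len(nc) - 1) * scenario$cycle_days / 365.25,
      cost = res$increments[, 1], qaly = res$increments[, 2],
      ly = res$increments[, 3], cost_disc = res$increments[, 4],
      qaly_disc = res$increments[, 5], ly_disc = res$increments[, 6])
  }
  class(out) <- "af_trace"
  out
}

#' Lifetime outcomes for one strategy
#'
#' Convenience wrapper: cohort run followed by outcome aggregation.
#'
#' @inheritParams run_cohort
#' @return an `af_outcome`.
#' @export
run_strategy <- function(scenario, strategy = c("apixaban", "warfarin")) {
  strategy <- match.arg(strategy)
  strategy_outcome(run_cohort(scenario, strategy, full_trace = FALSE))
}

#' Run the base-case comparison
#'
#' Runs both strategies on the scenario and compares apixaban against
#' warfarin at the scenario's willingness-to-pay threshold.
#'
#' @param scenario an `af_scenario`.
#' @return list with `apixaban`, `warfarin` (`af_outcome`) and
#'   `comparison` (`af_comparison`).
#' @export
run_base_case <- function(scenario = default_scenario()) {
  apix <- run_strategy(scenario, "apixaban")
  warf <- run_strategy(scenario, "warfarin")
  out <- list(apixaban = apix, warfarin = warf,
              comparison = compare_strategies(apix, warf, scenario$wtp))
  class(out) <- "af_base_case"
  out
}

#' @export
print.af_base_case <- function(x, ...) {
  cat("Base-case cohort results (discounted)\n")
  for (s in c("warfarin", "apixaban"))
    cat(sprintf("  %-9s cost $%s  QALY %.3f  LY %.3f\n", s,
                format(round(x[[s]]$cost), big.mark = ","),
                x[[s]]$qaly, x[[s]]$ly))
  print(x$comparison)
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' Writes one row per cycle: cycle index, attained age, occupancy of every
#' enumerated state, and the (un)discounted cost/QALY/LY increments.
#'
#' @param trace an `af_trace` from [run_cohort()] with `full_trace = TRUE`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  if (is.null(trace$occupancy))
    stop("trace was run with full_trace = FALSE")
  df <- cbind(trace$cycles[, c("cycle", "age")],
              as.data.frame(trace$occupancy[seq_len(nrow(trace$cycles)), ,
                                            drop = FALSE]),
              trace$cycles[, c("cost", "qaly", "ly",
                               "cost_disc", "qaly_disc", "ly_disc")])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
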