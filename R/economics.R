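# Event -> one-time cost parameter.  Fatal strokes are charged the
# moderate-to-severe stroke admission cost; fatal ICH/ECH/MI the respective
# event cost; TIAs are costed as RIND events.
event_cost_param <- c(
  tia = "cost_event_rind", stroke_rind = "cost_event_rind",
  stroke_minor = "cost_event_minor_stroke",
  stroke_major = "cost_event_major_stroke",
  stroke_fatal = "cost_event_major_stroke",
  ich_fatal = "cost_event_ich", ich_major = "cost_event_ich",
  ich_minor = "cost_event_ich",
  ech = "cost_event_ech", ech_fatal = "cost_event_ech",
  minor_bleed = "cost_event_minor_bleed",
  mi = "cost_event_mi", mi_fatal = "cost_event_mi",
  nonevent_death = "cost_nonevent_death")

pget <- function(params, name) {
  if (inherits(params, "af_scenario")) params <- params$parameters
  i <- match(name, params$name)
  if (anyNA(i)) stop("unknown parameter: ", paste(name[is.na(i)], collapse = ", "))
  params$base[i]
}

sequela_utility <- function(level, params) {
  switch(level, none = 1,
         minor = pget(params, "u_minor_neuro"),
         major = pget(params, "u_major_neuro"))
}

#' Health-state utility for one cycle
#'
#' The cycle utility is the treatment utility (warfarin 0.987, apixaban
#' 0.994, aspirin 0.998 at base case) combined with the utilities of any
#' permanent sequelae (major neurological event 0.39, minor 0.75, MI
#' history 0.84).  Coexisting sequelae combine multiplicatively by default
#' (`combination = "minimum"` instead takes the worst sequela utility).
#' Transient bleeding events decrement the cycle: a non-fatal ECH (major
#' bleed) for the full cycle, a minor bleed for 2 days of it.  The result is
#' clamped to `[0, 1]`.
#'
#' @param state list with `treatment` (`"apixaban"`, `"warfarin"` or
#'   `"aspirin"`), `stroke`, `ich`, `mi`, `alive`.
#' @param transient optional transient event this cycle (`"ech"` or
#'   `"minor_bleed"`); other event labels contribute no transient decrement.
#' @param params parameter data.frame or scenario.
#' @param combination `"multiplicative"` or `"minimum"`.
#' @param cycle_days cycle length in days (the minor-bleed decrement covers
#'   2 days of it).
#' @return utility value in `[0, 1]` (0 when dead).
#' @export
cycle_utility <- function(state, transient = NULL, params = af_parameters(),
                          combination = c("multiplicative", "minimum"),
                          cycle_days = 14) {
  combination <- match.arg(combination)
  if (!isTRUE(state$alive)) return(0)
  u_trt <- pget(params, switch(state$treatment,
                               apixaban = "u_apixaban",
                               warfarin = "u_warfarin",
                               aspirin = "u_aspirin",
                               stop("unknown treatment: ", state$treatment)))
  seqs <- c(sequela_utility(state$stroke, params),
            sequela_utility(state$ich, params),
            if (state$mi == 1L) pget(params, "u_mi") else 1)
  u <- if (combination == "multiplicative") u_trt * prod(seqs)
       else u_trt * min(seqs)
  if (!is.null(transient)) {
    if (transient == "ech") u <- u + pget(params, "du_major_bleed")
    if (transient == "minor_bleed")
      u <- u + pget(params, "du_minor_bleed") * 2 / cycle_days
  }
  min(max(u, 0), 1)
}

#' Health-state cost for one cycle
#'
#' Bi-weekly drug cost (warfarin including INR monitoring) plus the
#' bi-weekly cost of chronic sequelae: minor stroke, moderate-to-severe
#' stroke, ICH, the combined stroke-and-ICH state (which replaces, not
#' adds to, the separate stroke and ICH costs), and MI history (additive).
#' When a `transient` event label is supplied its one-time event cost is
#' added.  The dead state accrues nothing.
#'
#' @inheritParams cycle_utility
#' @param transient optional event label this cycle (see
#'   [build_transitions()] for the event vocabulary).
#' @return cost in 2012 US$ for the cycle.
#' @export
cycle_cost <- function(state, transient = NULL, params = af_parameters()) {
  if (!isTRUE(state$alive)) {
    # a death *event* still carries its one-time cost in the cycle it occurs
    if (is.null(transient)) return(0)
    return(pget(params, event_cost_param[[transient]]))
  }
  drug <- pget(params, switch(state$treatment,
                              apixaban = "cost_apixaban_2wk",
                              warfarin = "cost_warfarin_2wk",
                              aspirin = "cost_aspirin_2wk",
                              stop("unknown treatment: ", state$treatment)))
  chronic <- if (state$stroke != "none" && state$ich != "none") {
    pget(params, "cost_biweekly_stroke_ich")
  } else if (state$ich != "none") {
    pget(params, "cost_biweekly_ich")
  } else if (state$stroke == "minor") {
    pget(params, "cost_biweekly_minor_stroke")
  } else if (state$stroke == "major") {
    pget(params, "cost_biweekly_major_stroke")
  } else 0
  mi <- if (state$mi == 1L) pget(params, "cost_biweekly_mi") else 0
  ev <- if (!is.null(transient)) pget(params, event_cost_param[[transient]]) else 0
  drug + chronic + mi + ev
}

#' Lifetime outcomes of one strategy
#'
#' Collects discounted and undiscounted total cost, QALYs and life-years
#' from a cohort trace into a `af_outcome` object.
#'
#' @param trace a cohort trace from [run_cohort()].
#' @return an `af_outcome` list.
#' @export
strategy_outcome <- function(trace) {
  out <- list(strategy = trace$strategy,
              cost = trace$totals["cost_disc"],
              qaly = trace$totals["qaly_disc"],
              ly = trace$totals["ly_disc"],
              cost_undisc = trace$totals["cost"],
              qaly_undisc = trace$totals["qaly"],
              ly_undisc = trace$totals["ly"])
  out <- lapply(out, unname)
  class(out) <- "af_outcome"
  out
}

#' Compare two strategy outcomes
#'
#' Computes incremental cost, QALYs and life-years (first strategy minus
#' comparator), classifies the cost-effectiveness-plane quadrant, reports
#' the ICER where the comparison is a trade-off (one strategy costlier and
#' more effective), and the net monetary benefit at the willingness-to-pay
#' threshold.  With zero incremental QALYs the ICER is undefined and `NA`.
#'
#' @param intervention,comparator `af_outcome` objects (conventionally
#'   apixaban vs warfarin).
#' @param wtp willingness-to-pay, $ per QALY.
#' @return an `af_comparison` list with `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer`, `quadrant` (`"dominant"`, `"dominated"`,
#'   `"tradeoff_ne"`, `"tradeoff_sw"`), `nmb_at_wtp`, `cost_effective`.
#' @export
compare_strategies <- function(intervention, comparator, wtp = 50000) {
  dc <- intervention$cost - comparator$cost
  dq <- intervention$qaly - comparator$qaly
  dl <- intervention$ly - comparator$ly
  quadrant <- if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else if (dq >= 0) "tradeoff_ne" else "tradeoff_sw"
  icer <- if (quadrant %in% c("tradeoff_ne", "tradeoff_sw") && dq != 0)
    dc / dq else NA_real_
  nmb <- wtp * dq - dc
  res <- list(delta_cost = dc, delta_qaly = dq, delta_ly = dl,
              icer = icer, quadrant = quadrant, nmb_at_wtp = nmb,
              wtp = wtp, cost_effective = nmb > 0)
  class(res) <- "af_comparison"
  res
}

#' @export
print.af_outcome <- function(x, ...) {
  cat(sprintf("<af_outcome> %s: cost $%s, %.3f QALY, %.3f LY (discounted)\n",
              x$strategy, format(round(x$cost), big.mark = ","),
              x$qaly, x$ly))
  invisible(x)
}

#' @export
print.af_comparison <- function(x, ...) {
  cat("<af_comparison>\n")
  cat(sprintf("  incremental: cost $%s, %.4f QALY, %.4f LY\n",
              format(round(x$delta_cost), big.mark = ","),
              x$delta_qaly, x$delta_ly))
  cat(sprintf("  quadrant: %s%s; NMB at $%s/QALY: $%s\n", x$quadrant,
              if (!is.na(x$icer))
                sprintf(" (ICER $%s/QALY)", format(round(x$icer), big.mark = ","))
              else "",
              format(x$wtp, big.mark = ","),
              format(round(x$nmb_at_wtp), big.mark = ",")))
  invisible(x)
}
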