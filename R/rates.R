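#' Convert an annual event rate to a per-cycle probability
#'
#' Uses the constant-hazard (exponential) transform
#' `p = 1 - exp(-(rate/100) * cycle_days / 365.25)`, the standard conversion
#' for state-transition models with short cycles.
#'
#' @param annual_pct event rate in percent per year (vectorised).
#' @param cycle_days cycle length in days.
#' @return per-cycle probability in `[0, 1)`.
#' @export
annual_rate_to_cycle_prob <- function(annual_pct, cycle_days) {
  if (any(annual_pct < 0)) stop("annual rate must be non-negative")
  1 - exp(-(annual_pct / 100) * cycle_days / 365.25)
}

#' Age-adjust an annual rate by a per-decade relative risk
#'
#' Applies the per-decade relative risk once for each completed decade of
#' life beyond the reference age:
#' `rate * rr_per_decade^floor((age - ref_age) / 10)` (the default), the
#' way a table-driven cohort model indexes risk by decade age band.
#' `method = "continuous"` instead applies the smooth exponent
#' `(age - ref_age) / 10`.
#'
#' @param annual_pct baseline annual rate (percent/year) at `ref_age`.
#' @param rr_per_decade relative risk per 10 years of life.
#' @param age attained age (years, vectorised).
#' @param ref_age reference age of the baseline rate.
#' @param method `"step"` (default) or `"continuous"`.
#' @return adjusted annual rate, percent/year.
#' @export
age_adjust <- function(annual_pct, rr_per_decade, age, ref_age,
                       method = c("step", "continuous")) {
  method <- match.arg(method)
  if (any(age < ref_age)) stop("age must be >= ref_age")
  expo <- if (method == "step") floor((age - ref_age) / 10)
          else (age - ref_age) / 10
  annual_pct * rr_per_decade^expo
}

#' Combine independent per-cycle event probabilities into a one-event mix
#'
#' A cycle admits at most one event.  Each competing event's per-cycle
#' probability is taken as converted; the remainder is "no event".  A
#' combined event probability of 1 or more signals an implausible parameter
#' combination and aborts.
#'
#' @param rate_events named numeric vector (or list of `(name, prob)`
#'   pairs) of per-cycle probabilities.
#' @return named vector of probabilities including `no_event`, summing to 1.
#' @export
event_mix <- function(rate_events) {
  if (is.list(rate_events)) {
    nm <- vapply(rate_events, function(x) as.character(x[[1]]), character(1))
    p <- vapply(rate_events, function(x) as.numeric(x[[2]]), numeric(1))
    rate_events <- stats::setNames(p, nm)
  }
  if (length(rate_events) == 0)
    return(c(no_event = 1))
  if (any(rate_events < 0) || any(rate_events >= 1))
    stop("each per-cycle probability must lie in [0, 1)")
  tot <- sum(rate_events)
  if (tot >= 1)
    stop("combined per-cycle event probability ", format(tot),
         " >= 1: implausible parameter combination")
  c(rate_events, no_event = 1 - tot)
}

# severity splits must sum to 100%; printed tables carry rounding, so up to
# half a percentage point of slack is absorbed by renormalisation
check_split_fractions <- function(frac_pct, what, tol = 0.5) {
  if (abs(sum(frac_pct) - 100) > tol)
    stop(what, " severity fractions must sum to 100%, got ",
         format(sum(frac_pct)))
  if (any(frac_pct < 0)) stop(what, " severity fractions must be >= 0")
  frac_pct * 100 / sum(frac_pct)
}

#' Split an ischemic stroke probability by severity
#'
#' Distributes a per-cycle ischemic stroke probability over fatal,
#' moderate-to-severe (major), mild (minor) and no-residual-deficit (RIND)
#' outcomes, using the anticoagulant or aspirin severity distribution.
#' Transient ischemic attacks are not part of this split; they are modelled
#' as a separate event stream (see [build_transitions()]).
#'
#' @param outcome_prob per-cycle stroke probability.
#' @param treatment `"apixaban"`, `"warfarin"` (same split) or `"aspirin"`.
#' @param params optional scenario or parameter data.frame supplying the
#'   split fractions; defaults to the base case.
#' @return named probabilities `c(fatal, major, minor, rind)`.
#' @export
split_stroke <- function(outcome_prob,
                         treatment = c("apixaban", "warfarin", "aspirin"),
                         params = af_parameters()) {
  treatment <- match.arg(treatment)
  if (inherits(params, "af_scenario")) params <- params$parameters
  pick <- function(nm) params$base[match(nm, params$name)]
  f <- if (treatment == "aspirin") {
    c(fatal = pick("frac_stroke_asp_fatal"), major = pick("frac_stroke_asp_major"),
      minor = pick("frac_stroke_asp_minor"), rind = pick("frac_stroke_asp_rind"))
  } else {
    c(fatal = pick("frac_stroke_fatal"), major = pick("frac_stroke_major"),
      minor = pick("frac_stroke_minor"), rind = pick("frac_stroke_rind"))
  }
  f <- check_split_fractions(f, "stroke")
  outcome_prob * f / 100
}

#' Split an intracranial hemorrhage probability by severity
#'
#' Uses the fatal/major/minor ICH outcome distribution (Hylek severity
#' classification), identical across treatments.
#'
#' @inheritParams split_stroke
#' @return named probabilities `c(fatal, major, minor)`.
#' @export
split_ich <- function(outcome_prob, params = af_parameters()) {
  if (inherits(params, "af_scenario")) params <- params$parameters
  pick <- function(nm) params$base[match(nm, params$name)]
  f <- c(fatal = pick("frac_ich_fatal"), major = pick("frac_ich_major"),
         minor = pick("frac_ich_minor"))
  f <- check_split_fractions(f, "ICH")
  outcome_prob * f / 100
}

#' Per-cycle probability of death from causes other than a modelled event
#'
#' Looks up the all-cause annual mortality probability at the attained
#' (floored) age, converts it to a hazard, multiplies by the excess
#' mortality ratio — 1.3 for atrial fibrillation, or 2.3 for AF patients
#' who have survived an ischemic stroke (the two ratios are alternative
#' multipliers of the same population baseline; `composition =
#' "multiplicative"` stacks them to 1.3 x 2.3 instead) — and converts back
#' to a per-cycle probability.  Working on the hazard scale keeps the
#' result a probability even when the multiplier times the annual
#' probability would exceed 1 at advanced ages.  Ages beyond the table are
#' clamped to its last row.
#'
#' @param age attained age in years (vectorised).
#' @param sequela sequela label: any value containing an ischemic stroke
#'   component (`"minor_stroke"`, `"major_stroke"`, `"stroke_and_ich"`, or
#'   the shorthand `"stroke"`) applies the post-stroke ratio; `"none"` and
#'   ICH-only sequelae (`"minor_ich"`, `"major_ich"`) apply the AF ratio.
#' @param life_table data.frame from [load_life_table()].
#' @param cycle_days cycle length in days.
#' @param rr_af excess mortality ratio for atrial fibrillation (default 1.3).
#' @param rr_af_stroke excess mortality ratio for AF with prior ischemic
#'   stroke (default 2.3).
#' @param composition `"replace"` (default: the post-stroke ratio replaces
#'   the AF ratio) or `"multiplicative"` (ratios stack).
#' @return per-cycle probability of non-event death.
#' @export
nonevent_death_prob <- function(age, sequela, life_table, cycle_days,
                                rr_af = 1.3, rr_af_stroke = 2.3,
                                composition = c("replace", "multiplicative")) {
  composition <- match.arg(composition)
  idx <- pmin(pmax(floor(age), min(life_table$age)), max(life_table$age)) -
    min(life_table$age) + 1
  q <- life_table$annual_mortality_probability[idx]
  post_stroke <- grepl("stroke", sequela)
  mult <- ifelse(post_stroke,
                 if (composition == "multiplicative") rr_af * rr_af_stroke
                 else rr_af_stroke,
                 rr_af)
  h <- -log(1 - q) * mult
  1 - exp(-h * cycle_days / 365.25)
}

#' Discount factor for a model cycle
#'
#' `(1 + annual_rate)^(-cycle_index * cycle_days / 365.25)`; cycle 0 is
#' undiscounted.
#'
#' @param cycle_index 0-based cycle index (vectorised).
#' @param cycle_days cycle length in days.
#' @param annual_rate annual discount rate as a fraction (0.03 for 3%).
#' @return discount factor in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, cycle_days, annual_rate) {
  (1 + annual_rate)^(-cycle_index * cycle_days / 365.25)
}
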