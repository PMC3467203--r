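#' Canonical model parameter table
#'
#' Returns the full base-case parameter set of the model: every cost,
#' utility, event rate, severity split and relative risk, together with the
#' low/high plausible range used in sensitivity analyses.  Rates are
#' expressed in percent per year, severity splits in percent, costs in 2012
#' US dollars.  Parameters whose range is `NA` are structural (held fixed in
#' probabilistic analyses).
#'
#' @return A data.frame with columns `name`, `base`, `low`, `high`,
#'   `units`, `role`.
#' @export
af_parameters <- function() {
  p <- function(name, base, low, high, units, role) {
    data.frame(name = name, base = base, low = low, high = high,
               units = units, role = role, stringsAsFactors = FALSE)
  }
  rbind(
    # -- costs (2012 US$) ---------------------------------------------------
    p("cost_warfarin_2wk",          18,    3,    28,   "$/2wk", "cost"),
    p("cost_apixaban_2wk",          95,    51,   154,  "$/2wk", "cost"),
    p("cost_aspirin_2wk",           0.3,   0.07, 2.8,  "$/2wk", "cost"),
    p("cost_event_rind",            6562,  3500, 13000, "$", "cost"),
    p("cost_event_minor_stroke",    9956,  4500, 18000, "$", "cost"),
    p("cost_event_major_stroke",    14783, 11000, 27500, "$", "cost"),
    p("cost_biweekly_minor_stroke", 1232,  500,  2000, "$/2wk", "cost"),
    p("cost_biweekly_major_stroke", 2683,  1000, 4500, "$/2wk", "cost"),
    p("cost_event_ich",             41645, 16500, 71000, "$", "cost"),
    p("cost_biweekly_ich",          2835,  1000, 4500, "$/2wk", "cost"),
    p("cost_biweekly_stroke_ich",   3595,  1600, 7000, "$/2wk", "cost"),
    p("cost_event_ech",             5830,  2000, 9000, "$", "cost"),
    p("cost_event_minor_bleed",     42,    0,    200,  "$", "cost"),
    p("cost_event_mi",              20357, 16500, 24000, "$", "cost"),
    p("cost_biweekly_mi",           152,   69,   300,  "$/2wk", "cost"),
    p("cost_nonevent_death",        5000,  0,    10000, "$", "cost"),
    p("disc_rate_pct",              3,     0,    5,    "%/yr", "structural"),
    # -- utilities ----------------------------------------------------------
    p("u_warfarin",      0.987, 0.940, 1, "utility", "utility"),
    p("u_apixaban",      0.994, 0.975, 1, "utility", "utility"),
    p("u_aspirin",       0.998, 0.994, 1, "utility", "utility"),
    p("u_major_neuro",   0.39,  0,     1, "utility", "utility"),
    p("u_minor_neuro",   0.75,  0,     1, "utility", "utility"),
    p("du_major_bleed", -0.16, -0.3,   0, "disutility", "utility"),
    p("du_minor_bleed", -0.16, -0.3,   0, "disutility", "utility"),
    p("u_mi",            0.84,  0.5,   1, "utility", "utility"),
    # -- event rates and relative effects -----------------------------------
    p("rate_stroke_warfarin",      1.05, 0.92, 1.24, "%/yr", "probability"),
    p("hr_stroke_apixaban",        1.0,  0.74, 1.13, "ratio", "hazard_ratio"),
    p("rr_stroke_aspirin",         2.08, 1.59, 2.70, "ratio", "relative_risk"),
    p("rr_stroke_decade",          1.4,  NA,   NA,   "ratio", "structural"),
    p("frac_stroke_fatal",         8.2,  8.2,  10.1, "%", "probability"),
    p("frac_stroke_major",         40.2, 40.2, 41.7, "%", "probability"),
    p("frac_stroke_minor",         42.5, 34.8, 42.5, "%", "probability"),
    p("frac_stroke_rind",          9.1,  9.1,  13.3, "%", "probability"),
    p("frac_stroke_asp_fatal",     17.9, 10.1, 17.9, "%", "probability"),
    p("frac_stroke_asp_major",     30.0, 30.0, 41.1, "%", "probability"),
    p("frac_stroke_asp_minor",     41.0, 34.8, 41.0, "%", "probability"),
    p("frac_stroke_asp_rind",      11.0, 11.0, 13.3, "%", "probability"),
    p("rate_ich_warfarin",         0.80, 0.63, 0.89, "%/yr", "probability"),
    p("hr_ich_apixaban",           0.42, 0.30, 0.58, "ratio", "hazard_ratio"),
    p("rr_ich_decade",             1.97, NA,   NA,   "ratio", "structural"),
    p("frac_ich_fatal",            36.4, 28.3, 45.2, "%", "probability"),
    p("frac_ich_major",            14.1, 9.0,  21.4, "%", "probability"),
    p("frac_ich_minor",            49.5, NA,   NA,   "%", "probability"),
    p("rate_ech_warfarin",         3.09, 2.59, 3.16, "%/yr", "probability"),
    p("hr_ech_apixaban",           0.69, 0.60, 0.80, "ratio", "hazard_ratio"),
    p("rate_minor_bleed_warfarin", 2.55, 2.32, 2.80, "%/yr", "probability"),
    p("rr_minor_bleed_apixaban",   0.69, 0.59, 0.80, "ratio", "relative_risk"),
    p("rr_hemorrhage_aspirin",     0.87, 0.59, 0.90, "ratio", "relative_risk"),
    p("rate_mi_warfarin",          0.61, 0.51, 0.76, "%/yr", "probability"),
    p("hr_mi_apixaban",            1.0,  0.66, 1.17, "ratio", "hazard_ratio"),
    p("rr_mi_aspirin",             1.42, 0.84, 2.39, "ratio", "relative_risk"),
    p("rr_mi_decade",              1.3,  NA,   NA,   "ratio", "structural"),
    p("rr_death_af",               1.3,  1.12, 1.62, "ratio", "relative_risk"),
    p("rr_death_af_stroke",        2.3,  1.3,  3.0,  "ratio", "relative_risk"),
    p("tia_fraction_pct",          28,   NA,   NA,   "%", "structural")
  )
}

#' Load the bundled life table
#'
#' Reads a two-column CSV (`age`, `annual_mortality_probability`).  The
#' bundled default is a synthetic single-year-of-age table, log-linearly
#' interpolated between published 2012-era US all-cause mortality anchor
#' values for ages 65-100; it stands in for the census-based table the model
#' calls for and can be replaced via the scenario file.
#'
#' @param path CSV file; default is the bundled synthetic table.
#' @return data.frame with integer `age` and `annual_mortality_probability`.
#' @export
load_life_table <- function(path = system.file("extdata",
                                               "life_table_us2012_synthetic.csv",
                                               package = "apixcea")) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "annual_mortality_probability")
  if (!all(need %in% names(lt)))
    stop("life table must have columns: ", paste(need, collapse = ", "))
  lt <- lt[order(lt$age), need]
  if (any(diff(lt$age) != 1))
    stop("life table ages must be consecutive single years")
  q <- lt$annual_mortality_probability
  if (any(!is.finite(q)) || any(q < 0) || any(q >= 1))
    stop("annual mortality probabilities must lie in [0, 1)")
  lt
}

scenario_field_defaults <- function() {
  list(start_age = 65, cycle_days = 14, horizon_years = 35, wtp = 50000,
       fatal_ech_fraction = 0, fatal_mi_fraction = 0,
       stroke_mort_composition = "replace",
       utility_combination = "multiplicative",
       half_cycle = FALSE)
}

#' Construct the default (base-case) scenario
#'
#' The base case: a 65-year-old cohort, 2-week cycles, a 35-year (lifetime)
#' horizon, 3 percent annual discounting, willingness-to-pay $50,000/QALY,
#' and every parameter at its Table-ledger base value.  The
#' `"apixaban_cost_103"` variant substitutes the $103 2-week apixaban cost
#' (the wholesale-acquisition-cost figure) for the default $95.
#'
#' @param variant `"base"` or `"apixaban_cost_103"`.
#' @param life_table optional replacement life table (data.frame as returned
#'   by [load_life_table()]).
#' @return An object of class `af_scenario`.
#' @export
default_scenario <- function(variant = c("base", "apixaban_cost_103"),
                             life_table = load_life_table()) {
  variant <- match.arg(variant)
  sc <- c(scenario_field_defaults(),
          list(parameters = af_parameters(), life_table = life_table))
  class(sc) <- "af_scenario"
  if (variant == "apixaban_cost_103")
    sc <- override(sc, "cost_apixaban_2wk", 103)
  validate_scenario(sc)
  sc
}

unit_bounds_ok <- function(units, x) {
  switch(units,
         "$" = , "$/2wk" = x >= 0,
         "utility" = x >= 0 & x <= 1,
         "disutility" = x >= -1 & x <= 0,
         "%" = x >= 0 & x <= 100,
         "%/yr" = x >= 0,
         "ratio" = x > 0,
         TRUE)
}

#' Validate a scenario
#'
#' Checks that every canonical parameter is present exactly once, that
#' `low <= base <= high` wherever a range exists, that each value respects
#' its unit's admissible domain (utilities in \[0,1\], disutilities in
#' \[-1,0\], costs and rates non-negative, ratios positive, percentages in
#' \[0,100\]), that the horizon yields at least one whole cycle, and that
#' the life table covers `[start_age, start_age + horizon]`.  Errors name
#' every offending key.
#'
#' @param scenario an `af_scenario`.
#' @return the scenario, invisibly, if valid.
#' @export
validate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "af_scenario"))
  pars <- scenario$parameters
  canon <- af_parameters()$name
  missing_p <- setdiff(canon, pars$name)
  extra_p <- setdiff(pars$name, canon)
  if (length(missing_p))
    stop("scenario is missing parameters: ", paste(missing_p, collapse = ", "))
  if (length(extra_p))
    stop("scenario has unknown parameters: ", paste(extra_p, collapse = ", "))
  if (anyDuplicated(pars$name))
    stop("duplicated parameters: ",
         paste(unique(pars$name[duplicated(pars$name)]), collapse = ", "))

  has_range <- !is.na(pars$low) & !is.na(pars$high)
  bad_order <- has_range & !(pars$low <= pars$base & pars$base <= pars$high)
  if (any(bad_order))
    stop("range violation (need low <= base <= high) for: ",
         paste(pars$name[bad_order], collapse = ", "))

  vals_ok <- mapply(function(u, b, l, h) {
    all(unit_bounds_ok(u, c(b, l[!is.na(l)], h[!is.na(h)])))
  }, pars$units, pars$base, pars$low, pars$high)
  if (any(!vals_ok))
    stop("value outside admissible domain for: ",
         paste(pars$name[!vals_ok], collapse = ", "))

  for (f in c("fatal_ech_fraction", "fatal_mi_fraction")) {
    v <- scenario[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  if (n_cycles(scenario) < 1)
    stop("horizon must contain at least one whole cycle")
  lt <- scenario$life_table
  if (min(lt$age) > scenario$start_age ||
      max(lt$age) < floor(scenario$start_age + scenario$horizon_years) - 1)
    stop("life table must cover ages ", scenario$start_age, " to ",
         floor(scenario$start_age + scenario$horizon_years))
  invisible(scenario)
}

#' Number of whole model cycles in the horizon
#' @param scenario an `af_scenario`.
#' @return integer cycle count (`floor(horizon / cycle length)`).
#' @export
n_cycles <- function(scenario) {
  as.integer(floor(scenario$horizon_years * 365.25 / scenario$cycle_days))
}

#' Look up a parameter's base value
#' @param scenario an `af_scenario`.
#' @param name parameter name.
#' @return the base value (scalar).
#' @export
param_value <- function(scenario, name) {
  i <- match(name, scenario$parameters$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  scenario$parameters$base[i]
}

scenario_scalar_fields <- c("start_age", "cycle_days", "horizon_years", "wtp",
                            "fatal_ech_fraction", "fatal_mi_fraction")

#' Override a parameter or scenario field
#'
#' Returns a new scenario differing only in the named quantity; the input is
#' untouched.  `name` may be any model parameter (its base value is
#' replaced) or one of the scalar scenario fields (`start_age`,
#' `cycle_days`, `horizon_years`, `wtp`, `fatal_ech_fraction`,
#' `fatal_mi_fraction`).
#'
#' @param scenario an `af_scenario`.
#' @param name parameter or field name.
#' @param value new numeric value.
#' @return a new validated `af_scenario`.
#' @export
override <- function(scenario, name, value) {
  stopifnot(inherits(scenario, "af_scenario"), is.numeric(value),
            length(value) == 1)
  if (name %in% scenario$parameters$name) {
    i <- match(name, scenario$parameters$name)
    scenario$parameters$base[i] <- value
    # keep low <= base <= high coherent when pushed outside the printed range
    if (!is.na(scenario$parameters$low[i]))
      scenario$parameters$low[i] <- min(scenario$parameters$low[i], value)
    if (!is.na(scenario$parameters$high[i]))
      scenario$parameters$high[i] <- max(scenario$parameters$high[i], value)
  } else if (name %in% scenario_scalar_fields) {
    scenario[[name]] <- value
  } else {
    stop("unknown parameter: ", name)
  }
  validate_scenario(scenario)
  scenario
}

#' Read a scenario file
#'
#' Scenario files are YAML (or JSON, chosen by extension) with top-level
#' keys `parameters` (a map `name: [base, low, high]`, `null` entries for
#' absent range bounds), the scalar fields of [default_scenario()], and
#' `life_table` (a path to a two-column CSV, resolved relative to the
#' scenario file; the literal `"bundled"` uses the packaged table).  Every
#' canonical parameter must be present: a missing parameter is an error,
#' never a silent default.
#'
#' @param path scenario file.
#' @return a validated `af_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  if (is.null(raw$parameters)) stop("scenario file has no 'parameters' block")

  canon <- af_parameters()
  given <- names(raw$parameters)
  missing_p <- setdiff(canon$name, given)
  if (length(missing_p))
    stop("scenario file is missing parameters: ",
         paste(missing_p, collapse = ", "))
  unknown_p <- setdiff(given, canon$name)
  if (length(unknown_p))
    stop("scenario file has unknown parameters: ",
         paste(unknown_p, collapse = ", "))

  pars <- canon
  for (nm in canon$name) {
    v <- raw$parameters[[nm]]
    v <- vapply(v, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
                numeric(1))
    if (length(v) == 1) v <- c(v, NA_real_, NA_real_)
    if (length(v) != 3)
      stop("parameter '", nm, "' must give [base, low, high]")
    i <- match(nm, pars$name)
    pars$base[i] <- v[1]; pars$low[i] <- v[2]; pars$high[i] <- v[3]
  }

  lt_spec <- raw$life_table
  lt <- if (is.null(lt_spec) || identical(lt_spec, "bundled")) {
    load_life_table()
  } else {
    lt_path <- if (file.exists(lt_spec)) lt_spec
               else file.path(dirname(path), lt_spec)
    load_life_table(lt_path)
  }

  sc <- scenario_field_defaults()
  for (f in names(sc)) if (!is.null(raw[[f]])) sc[[f]] <- raw[[f]]
  sc$parameters <- pars
  sc$life_table <- lt
  class(sc) <- "af_scenario"
  validate_scenario(sc)
  sc
}

#' Write a scenario file
#'
#' Serialises a scenario to YAML (or JSON by extension) in the format read
#' by [load_scenario()].  The life table is written alongside as
#' `<stem>_life_table.csv` and referenced by relative path, so that
#' `load_scenario(write_scenario(x, p))` round-trips every value.
#'
#' @param scenario an `af_scenario`.
#' @param path output file (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  validate_scenario(scenario)
  pars <- scenario$parameters
  plist <- stats::setNames(lapply(seq_len(nrow(pars)), function(i) {
    v <- c(pars$base[i], pars$low[i], pars$high[i])
    lapply(as.list(v), function(x) if (is.na(x)) NULL else x)
  }), pars$name)
  lt_name <- paste0(tools::file_path_sans_ext(basename(path)),
                    "_life_table.csv")
  utils::write.csv(scenario$life_table, file.path(dirname(path), lt_name),
                   row.names = FALSE, quote = FALSE)
  out <- c(scenario[scenario_scalar_fields],
           scenario[c("stroke_mort_composition", "utility_combination",
                      "half_cycle")],
           list(parameters = plist, life_table = lt_name))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' @export
print.af_scenario <- function(x, ...) {
  cat("<af_scenario>\n")
  cat(sprintf("  cohort start age %g, cycle %g days, horizon %g years (%d cycles)\n",
              x$start_age, x$cycle_days, x$horizon_years, n_cycles(x)))
  cat(sprintf("  WTP $%s/QALY, discount %g%%/yr\n",
              format(x$wtp, big.mark = ","), param_value(x, "disc_rate_pct")))
  cat(sprintf("  %d parameters (%d with sensitivity ranges)\n",
              nrow(x$parameters), sum(!is.na(x$parameters$low))))
  invisible(x)
}
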