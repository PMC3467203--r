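# Report assembly: every command writes its outputs plus a run manifest
# (scenario, command, seed, timestamp, package version, output files).
# The manifest is written even when the command fails, with the error.

round_money <- function(x) round(x)  # dollars kept to the cent internally

write_manifest <- function(out_dir, command, scenario_path, seed, outputs,
                           status = "ok", error = NULL) {
  man <- list(command = command,
              scenario = if (is.null(scenario_path)) "in-memory" else scenario_path,
              seed = seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package = "apixcea",
              version = as.character(utils::packageVersion("apixcea")),
              outputs = as.list(outputs), status = status)
  if (!is.null(error)) man$error <- error
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

with_manifest <- function(out_dir, command, scenario_path, seed, body) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  res <- tryCatch(body(function(f) outputs <<- c(outputs, f)),
                  error = function(e) e)
  if (inherits(res, "error")) {
    write_manifest(out_dir, command, scenario_path, seed, outputs,
                   status = "failed", error = conditionMessage(res))
    stop(res)
  }
  write_manifest(out_dir, command, scenario_path, seed, outputs)
  res
}

outcome_row <- function(o, discounted) {
  if (discounted)
    data.frame(strategy = o$strategy, discounted = TRUE,
               cost = round_money(o$cost), qaly = o$qaly, ly = o$ly)
  else
    data.frame(strategy = o$strategy, discounted = FALSE,
               cost = round_money(o$cost_undisc), qaly = o$qaly_undisc,
               ly = o$ly_undisc)
}

#' Base-case report
#'
#' Runs both strategies, writes the strategy outcomes and the incremental
#' comparison as JSON and CSV plus full per-cycle trace CSVs and a run
#' manifest.
#'
#' @param scenario an `af_scenario`.
#' @param out_dir output directory (created if needed).
#' @param scenario_path optional provenance string recorded in the manifest.
#' @return the [run_base_case()] result, invisibly.
#' @export
report_base_case <- function(scenario, out_dir, scenario_path = NULL) {
  with_manifest(out_dir, "base_case", scenario_path, NA, function(note) {
    bc <- run_base_case(scenario)
    tab <- rbind(outcome_row(bc$apixaban, TRUE), outcome_row(bc$warfarin, TRUE),
                 outcome_row(bc$apixaban, FALSE), outcome_row(bc$warfarin, FALSE))
    f <- file.path(out_dir, "outcomes.csv")
    utils::write.csv(tab, f, row.names = FALSE); note(f)
    cmp <- bc$comparison
    summ <- list(
      strategies = list(
        apixaban = bc$apixaban[c("cost", "qaly", "ly", "cost_undisc",
                                 "qaly_undisc", "ly_undisc")],
        warfarin = bc$warfarin[c("cost", "qaly", "ly", "cost_undisc",
                                 "qaly_undisc", "ly_undisc")]),
      comparison = list(delta_cost = round_money(cmp$delta_cost),
                        delta_qaly = cmp$delta_qaly, delta_ly = cmp$delta_ly,
                        icer = if (is.na(cmp$icer)) NULL else cmp$icer,
                        quadrant = cmp$quadrant,
                        nmb_at_wtp = round_money(cmp$nmb_at_wtp),
                        wtp = cmp$wtp,
                        cost_effective = cmp$cost_effective))
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE); note(f)
    for (s in c("apixaban", "warfarin")) {
      f <- file.path(out_dir, paste0("trace_", s, ".csv"))
      export_trace(run_cohort(scenario, s), f); note(f)
    }
    invisible(bc)
  })
}

#' One-way sensitivity report
#'
#' Writes the tornado-style table over all ranged parameters (result at
#' each range end, dominance and WTP thresholds) as CSV.
#'
#' @inheritParams report_base_case
#' @param n_points grid size per parameter.
#' @return the [owsa_all()] table, invisibly.
#' @export
report_owsa <- function(scenario, out_dir, n_points = 3,
                        scenario_path = NULL) {
  with_manifest(out_dir, "owsa", scenario_path, NA, function(note) {
    tab <- owsa_all(scenario, n_points = n_points)
    f <- file.path(out_dir, "owsa_tornado.csv")
    utils::write.csv(tab, f, row.names = FALSE); note(f)
    invisible(tab)
  })
}

#' Two-way sensitivity report
#'
#' Grid classification of the joint variation of two parameters (default:
#' baseline warfarin stroke rate over the Medicare-registry range 0.61-5.82
#' percent/year against the baseline warfarin ICH rate over its plausible
#' range), written as a long CSV.
#'
#' @inheritParams report_base_case
#' @param param_a,param_b,range_a,range_b,n,m see [two_way()].
#' @return the [two_way()] result, invisibly.
#' @export
report_twsa <- function(scenario, out_dir,
                        param_a = "rate_stroke_warfarin",
                        range_a = c(0.61, 5.82),
                        param_b = "rate_ich_warfarin",
                        range_b = c(0.63, 0.89),
                        n = 10, m = 10, scenario_path = NULL) {
  with_manifest(out_dir, "twsa", scenario_path, NA, function(note) {
    tw <- two_way(scenario, param_a, range_a, param_b, range_b, n, m)
    f <- file.path(out_dir, "twsa_grid.csv")
    utils::write.csv(tw$grid, f, row.names = FALSE); note(f)
    invisible(tw)
  })
}

#' Probabilistic sensitivity report
#'
#' Runs the Monte Carlo PSA and writes the cost-effectiveness plane points
#' (draw_id, delta_cost, delta_qaly) as CSV and the dominant/cost-effective
#' fractions as JSON.
#'
#' @inheritParams report_base_case
#' @param n_iter iterations.
#' @param seed RNG seed.
#' @return the [run_psa()] result, invisibly.
#' @export
report_psa <- function(scenario, out_dir, n_iter = 10000, seed = 1,
                       scenario_path = NULL) {
  with_manifest(out_dir, "psa", scenario_path, seed, function(note) {
    psa <- run_psa(scenario, n_iter = n_iter, seed = seed)
    plane <- data.frame(draw_id = psa$plane$draw,
                        delta_cost = psa$plane$delta_cost,
                        delta_qaly = psa$plane$delta_qaly)
    f <- file.path(out_dir, "ce_plane.csv")
    utils::write.csv(plane, f, row.names = FALSE); note(f)
    f <- file.path(out_dir, "psa_summary.json")
    jsonlite::write_json(list(n = psa$n, seed = seed, wtp = psa$wtp,
                              frac_dominant = psa$frac_dominant,
                              frac_ce_at_wtp = psa$frac_ce_at_wtp),
                         f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note(f)
    invisible(psa)
  })
}

#' Microsimulation report
#'
#' Simulates patient-level trajectories and writes the per-patient event
#' histories as CSV and the summary means/standard errors as JSON.
#'
#' @inheritParams report_base_case
#' @param strategy `"apixaban"` or `"warfarin"`.
#' @param n number of patients.
#' @param seed master seed.
#' @return the [simulate_patients()] result, invisibly.
#' @export
report_microsim <- function(scenario, out_dir, strategy = "apixaban",
                            n = 1000, seed = 1, scenario_path = NULL) {
  with_manifest(out_dir, "microsim", scenario_path, seed, function(note) {
    sim <- simulate_patients(scenario, strategy, n = n, seed = seed,
                             keep_trajectories = TRUE)
    f <- file.path(out_dir, "event_histories.csv")
    export_event_histories(sim, f); note(f)
    f <- file.path(out_dir, "microsim_summary.json")
    jsonlite::write_json(list(strategy = strategy, n = n, seed = seed,
                              summary = sim$summary),
                         f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note(f)
    invisible(sim)
  })
}

#' Command-line entry point
#'
#' Thin shell interface over the report functions, used by the
#' `inst/cli/apixcea.R` script:
#' `apixcea.R <base-case|owsa|twsa|psa|microsim> [options]`.
#' Options: `--scenario PATH` (default bundled base case),
#' `--override name=value[,name=value...]`, `--horizon YEARS`,
#' `--wtp DOLLARS`, `--n ITER`, `--seed INT`, `--out DIR`,
#' `--strategy NAME`.
#'
#' @param args character vector of command-line arguments.
#' @return 0 on success (invisibly); signals an error otherwise.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1)
    stop("usage: apixcea.R <base-case|owsa|twsa|psa|microsim> [options]")
  command <- args[1]
  if (!command %in% c("base-case", "owsa", "twsa", "psa", "microsim"))
    stop("unknown command: ", command)

  opts <- list(scenario = NULL, override = NULL, horizon = NULL, wtp = NULL,
               n = NULL, seed = 1, out = "apixcea_out", strategy = "apixaban")
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opts)) stop("unknown option: ", rest[i])
    if (i + 1 > length(rest)) stop("option --", key, " needs a value")
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }

  scenario <- if (is.null(opts$scenario)) default_scenario()
              else load_scenario(opts$scenario)
  if (!is.null(opts$override)) {
    for (ov in strsplit(opts$override, ",")[[1]]) {
      kv <- strsplit(ov, "=")[[1]]
      if (length(kv) != 2) stop("bad --override (need name=value): ", ov)
      scenario <- override(scenario, trimws(kv[1]), as.numeric(kv[2]))
    }
  }
  if (!is.null(opts$horizon))
    scenario <- override(scenario, "horizon_years", as.numeric(opts$horizon))
  if (!is.null(opts$wtp))
    scenario <- override(scenario, "wtp", as.numeric(opts$wtp))
  seed <- as.integer(opts$seed)
  out_dir <- opts$out

  switch(command,
    "base-case" = {
      bc <- report_base_case(scenario, out_dir, opts$scenario)
      print(bc)
    },
    "owsa" = report_owsa(scenario, out_dir, scenario_path = opts$scenario),
    "twsa" = report_twsa(scenario, out_dir, scenario_path = opts$scenario),
    "psa" = report_psa(scenario, out_dir,
                       n_iter = if (is.null(opts$n)) 10000 else as.integer(opts$n),
                       seed = seed, scenario_path = opts$scenario),
    "microsim" = report_microsim(scenario, out_dir, strategy = opts$strategy,
                                 n = if (is.null(opts$n)) 1000 else as.integer(opts$n),
                                 seed = seed, scenario_path = opts$scenario))
  invisible(0)
}
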