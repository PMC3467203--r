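# State space ----------------------------------------------------------------
#
# A living state is the composite (treatment, stroke sequela, ICH sequela,
# MI history).  Treatment is the strategy anticoagulant or aspirin (patients
# who suffer a major hemorrhage stop anticoagulation permanently and switch
# to aspirin).  Stroke sequela: none / minor / major; a second minor
# ischemic stroke escalates to major, a second major one to death.  ICH
# sequela: none / minor / major.  Death is a single absorbing state.

.stroke_levels <- c("none", "minor", "major")
.ich_levels <- c("none", "minor", "major")
.events <- c("tia", "stroke_fatal", "stroke_major", "stroke_minor",
             "stroke_rind", "ich_fatal", "ich_major", "ich_minor",
             "ech_fatal", "ech", "minor_bleed", "mi_fatal", "mi",
             "nonevent_death")
.rate_cols <- c("stroke_drug", "stroke_asp", "tia_drug", "tia_asp",
                "ich_drug", "ich_asp", "ech_drug", "ech_asp",
                "mb_drug", "mb_asp", "mi_drug", "mi_asp",
                "death_base", "death_neuro")
.frac_ids <- c("one", "s_fatal", "s_major", "s_minor", "s_rind",
               "sa_fatal", "sa_major", "sa_minor", "sa_rind",
               "i_fatal", "i_major", "i_minor",
               "ech_fatal", "ech_nonfatal", "mi_fatal", "mi_nonfatal")

#' Enumerate the model's health states
#'
#' Expands the composite attribute space into an explicit state list so the
#' cohort engine is a pure matrix-vector iteration.  `treatment = "drug"`
#' denotes the strategy anticoagulant (apixaban or warfarin depending on the
#' arm being run); the absorbing dead state is last.
#'
#' @return data.frame with columns `id`, `treatment`, `stroke`, `ich`,
#'   `mi`, `alive`, `label`.
#' @export
model_states <- function() {
  g <- expand.grid(mi = c(0L, 1L), ich = .ich_levels, stroke = .stroke_levels,
                   treatment = c("drug", "aspirin"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("treatment", "stroke", "ich", "mi")]
  g$alive <- TRUE
  g <- rbind(g, data.frame(treatment = "none", stroke = "none", ich = "none",
                           mi = 0L, alive = FALSE))
  g$id <- seq_len(nrow(g))
  g$label <- ifelse(g$alive,
                    paste0(g$treatment,
                           ifelse(g$stroke != "none",
                                  paste0("+", g$stroke, "_stroke"), ""),
                           ifelse(g$ich != "none",
                                  paste0("+", g$ich, "_ich"), ""),
                           ifelse(g$mi == 1L, "+mi", "")),
                    "dead")
  g[, c("id", "treatment", "stroke", "ich", "mi", "alive", "label")]
}

sev_max <- function(a, b) {
  lv <- c(none = 0L, minor = 1L, major = 2L)
  names(lv)[max(lv[a], lv[b]) + 1L]
}

#' Apply an event to a health state
#'
#' Deterministic successor-state rule.  Sequelae are monotone: a patient
#' never moves to a less severe neurological state.  A second minor ischemic
#' stroke yields the major-stroke state; a second major stroke is fatal.
#' Any intracranial hemorrhage or a (non-fatal) extracranial hemorrhage on
#' an anticoagulant triggers a permanent switch to aspirin.  TIA, RIND,
#' minor bleeding and non-fatal ECH are temporary: they leave the sequela
#' unchanged.  Non-fatal MI sets a permanent MI-history flag.
#'
#' @param state list with fields `treatment` (`"drug"`/`"aspirin"`),
#'   `stroke`, `ich` (`"none"`/`"minor"`/`"major"`), `mi` (0/1) and `alive`.
#' @param event one of `"tia"`, `"stroke_fatal"`, `"stroke_major"`,
#'   `"stroke_minor"`, `"stroke_rind"`, `"ich_fatal"`, `"ich_major"`,
#'   `"ich_minor"`, `"ech_fatal"`, `"ech"`, `"minor_bleed"`, `"mi_fatal"`,
#'   `"mi"`, `"nonevent_death"`.
#' @return the successor state (same structure).
#' @export
apply_event <- function(state, event) {
  if (!isTRUE(state$alive)) stop("cannot apply an event to the dead state")
  event <- match.arg(event, .events)
  s <- state
  to_aspirin <- function(s) { s$treatment <- "aspirin"; s }
  switch(event,
    tia = , stroke_rind = , minor_bleed = s,
    stroke_fatal = , ich_fatal = , ech_fatal = , mi_fatal = ,
    nonevent_death = {
      list(treatment = "none", stroke = "none", ich = "none", mi = 0L,
           alive = FALSE)
    },
    stroke_major = {
      if (s$stroke == "major")
        list(treatment = "none", stroke = "none", ich = "none", mi = 0L,
             alive = FALSE)
      else { s$stroke <- "major"; s }
    },
    stroke_minor = {
      s$stroke <- if (s$stroke == "none") "minor" else "major"
      s
    },
    ich_major = { s$ich <- "major"; to_aspirin(s) },
    ich_minor = { s$ich <- sev_max(s$ich, "minor"); to_aspirin(s) },
    ech = to_aspirin(s),
    mi = { s$mi <- 1L; s }
  )
}

state_row_to_list <- function(states, i) {
  list(treatment = states$treatment[i], stroke = states$stroke[i],
       ich = states$ich[i], mi = states$mi[i], alive = states$alive[i])
}

match_state <- function(states, s) {
  if (!s$alive) return(states$id[!states$alive])
  hit <- which(states$treatment == s$treatment & states$stroke == s$stroke &
               states$ich == s$ich & states$mi == s$mi & states$alive)
  stopifnot(length(hit) == 1)
  states$id[hit]
}

#' Build the event-level transition topology
#'
#' One row per (source state, event): the destination state, the annual
#' rate stream feeding the event's probability, and the severity-split
#' fraction multiplying it.  Both the cohort engine and the patient-level
#' microsimulation consume this same table, so they share transition
#' probabilities by construction.  The topology is parameter-free; per-cycle
#' probabilities attach at run time as
#' `prob = cycle_prob[cycle, rate_col] * frac[frac_id]`.
#'
#' @param states state table from [model_states()].
#' @return data.frame with columns `from`, `to`, `event`, `rate_col`,
#'   `frac_id`.
#' @export
build_transitions <- function(states = model_states()) {
  rows <- list()
  add <- function(from, event, rate_col, frac_id) {
    s <- apply_event(state_row_to_list(states, from), event)
    rows[[length(rows) + 1L]] <<- data.frame(
      from = states$id[from], to = match_state(states, s), event = event,
      rate_col = rate_col, frac_id = frac_id, stringsAsFactors = FALSE)
  }
  for (i in which(states$alive)) {
    asp <- states$treatment[i] == "aspirin"
    sfx <- if (asp) "asp" else "drug"
    sf <- if (asp) c("sa_fatal", "sa_major", "sa_minor", "sa_rind")
          else c("s_fatal", "s_major", "s_minor", "s_rind")
    rc <- function(stem) paste0(stem, "_", sfx)
    add(i, "tia", rc("tia"), "one")
    add(i, "stroke_fatal", rc("stroke"), sf[1])
    add(i, "stroke_major", rc("stroke"), sf[2])
    add(i, "stroke_minor", rc("stroke"), sf[3])
    add(i, "stroke_rind", rc("stroke"), sf[4])
    add(i, "ich_fatal", rc("ich"), "i_fatal")
    add(i, "ich_major", rc("ich"), "i_major")
    add(i, "ich_minor", rc("ich"), "i_minor")
    add(i, "ech_fatal", rc("ech"), "ech_fatal")
    add(i, "ech", rc("ech"), "ech_nonfatal")
    add(i, "minor_bleed", rc("mb"), "one")
    add(i, "mi_fatal", rc("mi"), "mi_fatal")
    add(i, "mi", rc("mi"), "mi_nonfatal")
    # the post-stroke mortality ratio attaches to ischemic stroke sequelae;
    # ICH-only survivors keep the AF baseline ratio
    post_stroke <- states$stroke[i] != "none"
    add(i, "nonevent_death",
        if (post_stroke) "death_neuro" else "death_base", "one")
  }
  tr <- do.call(rbind, rows)
  tr <- tr[order(tr$from), ]
  rownames(tr) <- NULL
  tr
}
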