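# Session builder: reconstruct per-question field visits and interview
# timelines from raw audit-trail events.
#
# The interviewing software presents one modal field at a time, so at most one
# visit is open per case.  Pairing rules:
#   * ENTER opens a visit; if another visit is still open it is closed at the
#     new ENTER's timestamp and marked synthetic_exit (a lost EXIT).
#   * the first subsequent EXIT carrying the open visit's question closes it
#     normally; any other EXIT is an orphan (discarded, counted).
#   * a visit still open at the end of the log closes at the last event
#     timestamp, marked synthetic_exit.
# At identical timestamps EXIT sorts before VALUE_SET before ENTER, so an
# abutting close/open at the same instant resolves in that order.

KIND_PRIORITY <- c(EXIT = 0L, KEYSTROKE = 1L, VALUE_SET = 1L, ENTER = 2L)

#' Reconstruct per-question field visits from audit events
#'
#' @param events audit-event table (one or many cases); must have the
#'   canonical `audit_events` columns.
#' @param catalog optional question catalog (unused in pairing; accepted for
#'   interface symmetry with the timeline builder).
#' @return data.table of visits: `case_id`, `interviewer_id`, `question_id`,
#'   `visit_index` (1-based per case x question, in enter order), `enter`,
#'   `exit`, `field_time_seconds`, `value_changed`, `synthetic_exit`.
#'   Attributes `orphan_exits` (count of discarded EXITs) and `n_events`.
#' @export
build_field_visits <- function(events, catalog = NULL) {
  ev <- as.data.table(events)
  if (nrow(ev) == 0L) {
    out <- data.table(case_id = character(), interviewer_id = character(),
                      question_id = character(), visit_index = integer(),
                      enter = as.POSIXct(character(), tz = "UTC"),
                      exit = as.POSIXct(character(), tz = "UTC"),
                      field_time_seconds = numeric(), value_changed = logical(),
                      synthetic_exit = logical())
    setattr(out, "orphan_exits", 0L)
    return(out)
  }
  ev <- ev[, .(event_id, case_id, interviewer_id, question_id, kind, timestamp)]
  ev[, prio := KIND_PRIORITY[kind]]
  setorder(ev, case_id, timestamp, prio, event_id)
  ev[, vnum := cumsum(kind == "ENTER"), by = case_id]
  ev[, pos := seq_len(.N), by = .(case_id, vnum)]
  # question owning each open visit = question of the ENTER heading the group
  ev[, vq := question_id[1L], by = .(case_id, vnum)]

  ev[, is_match_exit := vnum > 0L & kind == "EXIT" & question_id == vq]
  ev[, match_rank := cumsum(is_match_exit), by = .(case_id, vnum)]
  first_exit <- ev[is_match_exit & match_rank == 1L,
                   .(case_id, vnum, m_exit = timestamp, m_pos = pos)]

  visits <- ev[vnum > 0L & pos == 1L,
               .(case_id, vnum, interviewer_id, question_id, enter = timestamp)]
  visits <- first_exit[visits, on = c("case_id", "vnum")]
  visits[, next_enter := shift(enter, type = "lead"), by = case_id]
  last_ts <- ev[, .(last_ts = max(timestamp)), by = case_id]
  visits <- last_ts[visits, on = "case_id"]
  visits[, synthetic_exit := is.na(m_exit)]
  visits[, exit := fifelse(!synthetic_exit, m_exit,
                           fifelse(!is.na(next_enter), next_enter, last_ts))]

  # VALUE_SET for the visit's question before its close marks value_changed
  ev[first_exit, on = c("case_id", "vnum"), m_pos := i.m_pos]
  vs <- unique(ev[vnum > 0L & kind == "VALUE_SET" & question_id == vq &
                    (is.na(m_pos) | pos < m_pos), .(case_id, vnum)])
  visits[, value_changed := FALSE]
  visits[vs, on = c("case_id", "vnum"), value_changed := TRUE]

  n_orphan <- ev[kind == "EXIT", sum(vnum == 0L | !is_match_exit | match_rank > 1L)]

  setorder(visits, case_id, enter, vnum)
  visits[, visit_index := seq_len(.N), by = .(case_id, question_id)]
  visits[, field_time_seconds := as.numeric(exit) - as.numeric(enter)]
  out <- visits[, .(case_id, interviewer_id, question_id, visit_index, enter,
                    exit, field_time_seconds, value_changed, synthetic_exit)]
  setattr(out, "orphan_exits", as.integer(n_orphan))
  setattr(out, "n_events", nrow(ev))
  out
}

#' Count visits per case and question
#'
#' @param visits output of [build_field_visits()]
#' @return data.table `case_id`, `question_id`, `n_visits` (= the maximum
#'   `visit_index`, which equals the number of visits)
#' @export
count_question_visits <- function(visits) {
  if (nrow(visits) == 0L)
    return(data.table(case_id = character(), question_id = character(),
                      n_visits = integer()))
  visits[, .(n_visits = max(visit_index)), by = .(case_id, question_id)]
}

#' Timelines from an existing visit table
#'
#' Multi-case timeline computation separated from the event-level entry point,
#' so degenerate visit rows (e.g. negative durations from a corrupted clock)
#' can be fed straight in.
#'
#' @param visits visit table ([build_field_visits()] layout)
#' @param catalog question catalog
#' @param pause_threshold_seconds see [build_timelines()]
#' @return see [build_timelines()]
#' @export
timelines_from_visits <- function(visits, catalog, pause_threshold_seconds = 420) {
  if (nrow(visits) == 0L) {
    tl <- data.table(case_id = character(), interviewer_id = character(),
                     total_survey_seconds = numeric(),
                     adjusted_total_seconds = numeric(),
                     treatment_seconds = numeric(), timeout_bug = logical())
    setattr(tl, "module_seconds",
            data.table(case_id = character(), module = character(),
                       seconds = numeric()))
    return(tl)
  }
  v <- copy(as.data.table(visits))
  setorder(v, case_id, enter, exit)
  v[, gap_before := as.numeric(enter) - shift(as.numeric(exit)), by = case_id]
  v[is.na(gap_before) | gap_before < 0, gap_before := 0]

  tl <- v[, .(interviewer_id = interviewer_id[1L],
              total_survey_seconds = as.numeric(max(exit)) - as.numeric(min(enter)),
              excised = sum(gap_before[gap_before > pause_threshold_seconds]),
              span_bug = any(field_time_seconds < 0) ||
                any(field_time_seconds > as.numeric(max(exit)) - as.numeric(min(enter)))),
          by = case_id]
  tl[, adjusted_total_seconds := total_survey_seconds - excised]
  tl[, excised := NULL]

  mod <- as.data.table(catalog)[, .(question_id, module)]
  vm <- mod[v, on = "question_id"]
  vm[is.na(module), module := "unknown"]
  ms <- vm[, .(seconds = sum(pmax(field_time_seconds, 0))), by = .(case_id, module)]
  trt <- ms[module == "treatment", .(treatment_seconds = sum(seconds)), by = case_id]
  tl <- trt[tl, on = "case_id"]
  tl[is.na(treatment_seconds), treatment_seconds := 0]
  setnames(tl, "span_bug", "timeout_bug")
  out <- tl[, .(case_id, interviewer_id, total_survey_seconds,
                adjusted_total_seconds, treatment_seconds, timeout_bug)]
  setattr(out, "module_seconds", ms[])
  out
}

#' Build interview timelines for every case in an event table
#'
#' @param events audit events (any number of cases)
#' @param catalog question catalog (maps questions to modules; the module
#'   labelled `"treatment"` feeds `treatment_seconds`)
#' @param pause_threshold_seconds within-case gaps (time covered by no visit)
#'   longer than this are excised from `adjusted_total_seconds`; default 420 s,
#'   the 7-minute long-pause rule
#' @return data.table: `case_id`, `interviewer_id`, `total_survey_seconds`
#'   (first ENTER to last EXIT), `adjusted_total_seconds`,
#'   `treatment_seconds`, `timeout_bug` (TRUE when a visit duration is
#'   negative or exceeds the session span).  Per-module field-time totals in
#'   attribute `"module_seconds"` (`case_id`, `module`, `seconds`).
#' @export
build_timelines <- function(events, catalog, pause_threshold_seconds = 420) {
  visits <- build_field_visits(events, catalog)
  timelines_from_visits(visits, catalog, pause_threshold_seconds)
}

#' Build the timeline of a single case
#'
#' Single-case contract of [build_timelines()]: errors on an empty event set
#' and returns the timeline as a one-row list with `per_module_seconds` as a
#' named numeric vector.
#'
#' @inheritParams build_timelines
#' @return list with fields `case_id`, `total_survey_seconds`,
#'   `adjusted_total_seconds`, `treatment_seconds`, `per_module_seconds`,
#'   `timeout_bug`
#' @export
build_timeline <- function(events, catalog, pause_threshold_seconds = 420) {
  ev <- as.data.table(events)
  if (nrow(ev) == 0L) stop("no timeline: case has zero audit events", call. = FALSE)
  if (uniqueN(ev$case_id) != 1L)
    stop("build_timeline expects events of exactly one case", call. = FALSE)
  tl <- build_timelines(ev, catalog, pause_threshold_seconds)
  ms <- attr(tl, "module_seconds")
  list(case_id = tl$case_id,
       total_survey_seconds = tl$total_survey_seconds,
       adjusted_total_seconds = tl$adjusted_total_seconds,
       treatment_seconds = tl$treatment_seconds,
       per_module_seconds = setNames(ms$seconds, ms$module),
       timeout_bug = tl$timeout_bug)
}
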