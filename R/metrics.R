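# Verification metrics: the IT-team measures that sit beside the flags —
# monitoring coverage, calling time, productivity rates, reported-time
# discrepancies, and the per-case interview-time measures.

METRIC_NAMES <- c("MONITORED", "MONITORING_TIME_PER_CASE",
                  "MONITORING_TIME_PER_INTERVIEWER", "BLAISE_SURVEY_TIME",
                  "BLAISE_ADJUSTED_TOTAL_TIME", "BLAISE_TREATMENT_TIME",
                  "CISCO_CALLING_TIME", "AVG_AFTER_CALL_WORK_TIME",
                  "DIALS_PER_HOUR", "COMPLETES_PER_HOUR",
                  "ADJ_COMPLETES_PER_HOUR", "REPORTED_TIME_DISCREPANCY",
                  "ADT_SECTION_LENGTH", "TIMEOUT_BUG")

metric_row <- function(interviewer_id, metric, value, period,
                       case_id = NA_character_) {
  n <- max(length(interviewer_id), length(value), length(case_id))
  if (n == 0L || length(value) == 0L)
    return(data.table(interviewer_id = character(), metric = character(),
                      period_start = as.Date(character()),
                      period_end = as.Date(character()),
                      case_id = character(), value = numeric()))
  data.table(interviewer_id = interviewer_id, metric = metric,
             period_start = period[1], period_end = period[2],
             case_id = case_id, value = as.numeric(value))
}

#' Compute the verification metrics over a period
#'
#' Per interviewer over the half-open date period `[period[1], period[2])`:
#' * `CISCO_CALLING_TIME` — summed call durations, hours
#' * `DIALS_PER_HOUR` — dials per logged CALLING hour
#' * `COMPLETES_PER_HOUR` — completes per logged shift hour (all activities)
#' * `ADJ_COMPLETES_PER_HOUR` — completes per logged CALLING hour (the
#'   exposure-corrected rate)
#' * `AVG_AFTER_CALL_WORK_TIME` — mean seconds from a call's end to the same
#'   interviewer's next dial within one CALLING block
#' * `REPORTED_TIME_DISCREPANCY` — logged CALLING hours minus hours with
#'   observed activity (union of call and field-visit intervals); signed,
#'   positive = overreported
#' * `MONITORING_TIME_PER_INTERVIEWER` — merged monitored-interval minutes
#'
#' Per case (interviewer attached, `case_id` set):
#' `MONITORING_TIME_PER_CASE` and `MONITORED` (minutes; 1/0), and the
#' timeline lifts `BLAISE_SURVEY_TIME`, `BLAISE_ADJUSTED_TOTAL_TIME`,
#' `BLAISE_TREATMENT_TIME`, `ADT_SECTION_LENGTH` (total in-field time; all
#' minutes) and `TIMEOUT_BUG` (1/0).
#'
#' Interviewers present in the bundle but without activity in the period get
#' zero-valued interviewer-level metrics, not absent rows.
#'
#' @param bundle a `paradata_bundle`
#' @param visits output of [build_field_visits()] on the bundle's events
#' @param timelines output of [build_timelines()]
#' @param period length-2 `Date` vector, half-open
#' @return data.table `interviewer_id`, `metric`, `period_start`,
#'   `period_end`, `case_id`, `value`
#' @export
compute_metrics <- function(bundle, visits, timelines, period) {
  period <- as.Date(period)
  stopifnot(length(period) == 2L)
  in_period <- function(t) as.Date(t) >= period[1] & as.Date(t) < period[2]

  calls <- bundle$call_records[in_period(start)]
  logs <- bundle$time_logs[in_period(start)]
  cases <- bundle$case_records[in_period(call_start)]
  ids <- sort(unique(c(bundle$call_records$interviewer_id,
                       bundle$time_logs$interviewer_id,
                       bundle$case_records$interviewer_id)))
  base <- data.table(interviewer_id = ids)

  calling_h <- logs[activity == "CALLING",
                    .(calling_h = sum(as.numeric(end) - as.numeric(start)) / 3600),
                    by = interviewer_id]
  shift_h <- logs[, .(shift_h = sum(as.numeric(end) - as.numeric(start)) / 3600),
                  by = interviewer_id]
  call_h <- calls[, .(call_h = sum(as.numeric(end) - as.numeric(start)) / 3600,
                      dials = .N), by = interviewer_id]
  comp <- cases[disposition == "COMPLETE", .(completes = .N), by = interviewer_id]

  agg <- Reduce(function(a, b) merge(a, b, by = "interviewer_id", all.x = TRUE),
                list(base, calling_h, shift_h, call_h, comp))
  for (cl in c("calling_h", "shift_h", "call_h", "dials", "completes"))
    agg[is.na(get(cl)), (cl) := 0]

  # after-call work: gap to the next dial inside one CALLING block
  acw <- data.table(interviewer_id = character(), acw = numeric())
  if (nrow(calls) > 1L) {
    cl <- copy(calls); setorder(cl, interviewer_id, start, call_id)
    cl[, next_start := shift(start, type = "lead"), by = interviewer_id]
    pairs <- cl[!is.na(next_start) & next_start >= end,
                .(interviewer_id, t1 = end, t2 = next_start)]
    cblocks <- logs[activity == "CALLING", .(interviewer_id, bs = start, be = end)]
    if (nrow(pairs) && nrow(cblocks)) {
      hit <- cblocks[pairs, on = .(interviewer_id, bs <= t1, be >= t2), nomatch = NULL,
                     .(interviewer_id, gap = as.numeric(t2) - as.numeric(t1))]
      acw <- hit[, .(acw = mean(gap)), by = interviewer_id]
    }
  }
  agg <- merge(agg, acw, by = "interviewer_id", all.x = TRUE)
  agg[is.na(acw), acw := 0]

  # observed-activity hours: union of call intervals and field-visit intervals
  v <- as.data.table(visits)
  v <- if (nrow(v)) v[in_period(enter)] else v
  act <- rbind(calls[, .(interviewer_id, s = start, e = end)],
               if (nrow(v)) v[, .(interviewer_id, s = enter, e = exit)] else NULL)
  obs <- if (!is.null(act) && nrow(act))
    act[, .(obs_h = interval_union_seconds(s, e) / 3600), by = interviewer_id]
  else data.table(interviewer_id = character(), obs_h = numeric())
  agg <- merge(agg, obs, by = "interviewer_id", all.x = TRUE)
  agg[is.na(obs_h), obs_h := 0]

  mi <- parse_monitored_intervals(calls)
  mon_i <- if (nrow(mi))
    mi[, .(mon_min = interval_union_seconds(m_start, m_end) / 60), by = interviewer_id]
  else data.table(interviewer_id = character(), mon_min = numeric())
  agg <- merge(agg, mon_i, by = "interviewer_id", all.x = TRUE)
  agg[is.na(mon_min), mon_min := 0]

  rate <- function(num, den) fifelse(den > 0, num / den, 0)
  per_int <- rbind(
    metric_row(agg$interviewer_id, "CISCO_CALLING_TIME", agg$call_h, period),
    metric_row(agg$interviewer_id, "DIALS_PER_HOUR", rate(agg$dials, agg$calling_h), period),
    metric_row(agg$interviewer_id, "COMPLETES_PER_HOUR", rate(agg$completes, agg$shift_h), period),
    metric_row(agg$interviewer_id, "ADJ_COMPLETES_PER_HOUR", rate(agg$completes, agg$calling_h), period),
    metric_row(agg$interviewer_id, "AVG_AFTER_CALL_WORK_TIME", agg$acw, period),
    metric_row(agg$interviewer_id, "REPORTED_TIME_DISCREPANCY", agg$calling_h - agg$obs_h, period),
    metric_row(agg$interviewer_id, "MONITORING_TIME_PER_INTERVIEWER", agg$mon_min, period))

  # per-case block
  per_case <- NULL
  if (nrow(cases)) {
    cc <- cases[, .(case_id, interviewer_id)]
    mon_c <- if (nrow(mi))
      mi[, .(mon_min = interval_union_seconds(m_start, m_end) / 60), by = case_id]
    else data.table(case_id = character(), mon_min = numeric())
    cc <- merge(cc, mon_c, by = "case_id", all.x = TRUE)
    cc[is.na(mon_min), mon_min := 0]
    tl <- as.data.table(timelines)
    if (!"case_id" %in% names(tl))
      tl <- data.table(case_id = character(), total_survey_seconds = numeric(),
                       adjusted_total_seconds = numeric(),
                       treatment_seconds = numeric(), timeout_bug = logical())
    ms <- attr(timelines, "module_seconds")
    adt <- if (!is.null(ms) && nrow(ms))
      ms[, .(adt_min = sum(seconds) / 60), by = case_id]
    else data.table(case_id = character(), adt_min = numeric())
    cc <- merge(cc, tl[, .(case_id, total_survey_seconds, adjusted_total_seconds,
                           treatment_seconds, timeout_bug)],
                by = "case_id", all.x = TRUE)
    cc <- merge(cc, adt, by = "case_id", all.x = TRUE)
    for (cl in c("total_survey_seconds", "adjusted_total_seconds",
                 "treatment_seconds", "adt_min"))
      cc[is.na(get(cl)), (cl) := 0]
    cc[is.na(timeout_bug), timeout_bug := FALSE]
    per_case <- rbind(
      metric_row(cc$interviewer_id, "MONITORING_TIME_PER_CASE", cc$mon_min, period, cc$case_id),
      metric_row(cc$interviewer_id, "MONITORED", as.numeric(cc$mon_min > 0), period, cc$case_id),
      metric_row(cc$interviewer_id, "BLAISE_SURVEY_TIME", cc$total_survey_seconds / 60, period, cc$case_id),
      metric_row(cc$interviewer_id, "BLAISE_ADJUSTED_TOTAL_TIME", cc$adjusted_total_seconds / 60, period, cc$case_id),
      metric_row(cc$interviewer_id, "BLAISE_TREATMENT_TIME", cc$treatment_seconds / 60, period, cc$case_id),
      metric_row(cc$interviewer_id, "ADT_SECTION_LENGTH", cc$adt_min, period, cc$case_id),
      metric_row(cc$interviewer_id, "TIMEOUT_BUG", as.numeric(cc$timeout_bug), period, cc$case_id))
  }
  out <- rbind(per_int, per_case)
  setorder(out, metric, interviewer_id, case_id, na.last = FALSE)
  out[]
}
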