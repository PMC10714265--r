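# Reporting: flag summary (the fielded report's layout), monitoring coverage,
# investigation task queue, interviewer profiles, evaluation records.

# Flag type -> denominator population for the "cases flagged" percentage.
# Question-time and treatment flags are evaluated on every touched case; the
# remaining flags only on completed cases.
DENOM_KIND <- c(
  SHORT_QUESTION_TIME = "TOUCHED_CASES", SHORT_STEM_QUESTION_TIME = "TOUCHED_CASES",
  LONG_QUESTION_TIME = "TOUCHED_CASES", LONG_TREATMENT = "TOUCHED_CASES",
  HIGH_COMPLETES = "COMPLETED_CASES", HIGH_PCT_SHORT_TIME = "COMPLETED_CASES",
  SHORT_INTERVIEW = "COMPLETED_CASES", LONG_INTERVIEW = "COMPLETED_CASES",
  SHORT_AVG_INTERVIEW = "COMPLETED_CASES", HIGH_NEGATIVE_STEMS = "COMPLETED_CASES",
  MULTI_FIELD_VISITS = "COMPLETED_CASES", MULTI_STEM_FIELD_VISITS = "COMPLETED_CASES",
  PREVALENCE_RATE = "COMPLETED_CASES")

#' Summarize flags by type
#'
#' One row per flag type present: flag count, its share of all flags, the
#' number of distinct cases flagged and its share of the type's denominator
#' population (touched cases for question-time and treatment flags, completed
#' cases otherwise).
#'
#' Percentages are rounded at `digits` decimals; `rounding = "half-up"` is the
#' conventional rule, `"truncate"` reproduces reports that truncate toward
#' zero (as the fielded study's published table did).
#'
#' @param flags flag table
#' @param n_completed,n_touched denominator sizes (> 0)
#' @param flag_cases optional link table `flag_id`, `case_id` attributing
#'   cases to flags that carry no `case_id` themselves (window-level flags)
#' @param rounding `"half-up"` or `"truncate"`
#' @param digits decimals for the percentage columns
#' @return data.table `flag_type`, `n_flags`, `pct_of_total_flags`,
#'   `n_cases_flagged`, `pct_of_denominator`, `denominator_kind`,
#'   `denominator_n`
#' @export
flag_summary <- function(flags, n_completed, n_touched, flag_cases = NULL,
                         rounding = c("half-up", "truncate"), digits = 2) {
  rounding <- match.arg(rounding)
  rnd <- if (rounding == "half-up") round_half_up else trunc_at
  if (n_completed <= 0 || n_touched <= 0)
    stop("flag_summary: denominators must be positive", call. = FALSE)
  fl <- as.data.table(flags)
  if (nrow(fl) == 0L)
    return(data.table(flag_type = character(), n_flags = integer(),
                      pct_of_total_flags = numeric(), n_cases_flagged = integer(),
                      pct_of_denominator = numeric(), denominator_kind = character(),
                      denominator_n = integer()))
  links <- fl[!is.na(case_id), .(flag_type, case_id)]
  if (!is.null(flag_cases)) {
    fc <- as.data.table(flag_cases)
    links <- rbind(links,
                   fl[fc, on = "flag_id", nomatch = NULL, .(flag_type, case_id = i.case_id)])
  }
  out <- fl[, .(n_flags = .N), by = flag_type]
  cases <- links[, .(n_cases_flagged = uniqueN(case_id)), by = flag_type]
  out <- merge(out, cases, by = "flag_type", all.x = TRUE)
  out[is.na(n_cases_flagged), n_cases_flagged := 0L]
  total <- nrow(fl)
  out[, denominator_kind := DENOM_KIND[flag_type]]
  out[, denominator_n := fifelse(denominator_kind == "TOUCHED_CASES",
                                 as.integer(n_touched), as.integer(n_completed))]
  out[, pct_of_total_flags := rnd(100 * n_flags / total, digits)]
  out[, pct_of_denominator := rnd(100 * n_cases_flagged / denominator_n, digits)]
  setcolorder(out, c("flag_type", "n_flags", "pct_of_total_flags",
                     "n_cases_flagged", "pct_of_denominator", "denominator_kind",
                     "denominator_n"))
  setorder(out, flag_type)
  out[]
}

#' Monitoring-coverage report
#'
#' Overlapping monitoring sessions on a case are merged before any time is
#' summed, so double-covered minutes count once.
#'
#' @param call_records call-record table (monitored intervals serialized)
#' @param completed_case_ids character vector of completed cases
#' @param min_minutes coverage threshold per case (default 15)
#' @return list: `dial_hours`, `monitored_hours`, `pct_dial_time_monitored`,
#'   `n_completed`, `n_monitored_min` / `pct_monitored_min` (completed cases
#'   with merged monitored time >= `min_minutes`),
#'   `n_monitored_any` / `pct_monitored_any`
#' @export
monitoring_coverage <- function(call_records, completed_case_ids, min_minutes = 15) {
  cr <- as.data.table(call_records)
  dial_h <- if (nrow(cr)) sum(as.numeric(cr$end) - as.numeric(cr$start)) / 3600 else 0
  mi <- parse_monitored_intervals(cr)
  per_case <- if (nrow(mi))
    mi[, .(mon_min = interval_union_seconds(m_start, m_end) / 60), by = case_id]
  else data.table(case_id = character(), mon_min = numeric())
  mon_h <- sum(per_case$mon_min) / 60
  nc <- length(completed_case_ids)
  cmon <- per_case[case_id %in% completed_case_ids]
  n_min <- cmon[mon_min >= min_minutes, .N]
  n_any <- cmon[mon_min > 0, .N]
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den, 2) else 0
  list(dial_hours = dial_h,
       monitored_hours = mon_h,
       pct_dial_time_monitored = pct(mon_h, dial_h),
       n_completed = nc,
       n_monitored_min = n_min,
       pct_monitored_min = pct(n_min, nc),
       n_monitored_any = n_any,
       pct_monitored_any = pct(n_any, nc),
       min_minutes = min_minutes)
}

#' Build the prioritized investigation task queue
#'
#' Tasks are grouped per interviewer (not per flag — per-flag tasks proved
#' unmanageable in the field): one OPEN task per interviewer with at least one
#' flag in the period.  Priority is HIGH when the interviewer has any
#' window-level flag or at least `high_count` case flags, MEDIUM at
#' `med_count`, else LOW.  Flag ids are listed newest-first.
#'
#' @param flags flag table
#' @param period length-2 `Date` vector, half-open
#' @param rules list with `high_count` (default 10) and `med_count` (3)
#' @return data.table `task_id`, `interviewer_id`, `period_start`,
#'   `period_end`, `priority`, `status`, `n_flags`, `flag_ids`
#'   (semicolon-joined, newest first), `notes`
#' @export
build_task_queue <- function(flags, period,
                             rules = list(high_count = 10, med_count = 3)) {
  period <- as.Date(period)
  fl <- as.data.table(flags)[!is.na(interviewer_id) &
                               triggered_at >= period[1] & triggered_at < period[2]]
  if (nrow(fl) == 0L)
    return(data.table(task_id = character(), interviewer_id = character(),
                      period_start = as.Date(character()),
                      period_end = as.Date(character()), priority = character(),
                      status = character(), n_flags = integer(),
                      flag_ids = character(), notes = character()))
  setorder(fl, -triggered_at, flag_id)
  out <- fl[, .(n_flags = .N,
                n_case = sum(level == "CASE"),
                any_window = any(level == "INTERVIEWER_WINDOW"),
                flag_ids = paste(flag_id, collapse = ";")),
            by = interviewer_id]
  out[, priority := fifelse(any_window | n_case >= rules$high_count, "HIGH",
                            fifelse(n_case >= rules$med_count, "MEDIUM", "LOW"))]
  out[, `:=`(task_id = sprintf("T-%s-%s", format(period[1]), interviewer_id),
             period_start = period[1], period_end = period[2],
             status = "OPEN", notes = "")]
  out[, c("n_case", "any_window") := NULL]
  setcolorder(out, c("task_id", "interviewer_id", "period_start", "period_end",
                     "priority", "status", "n_flags", "flag_ids", "notes"))
  setorder(out, interviewer_id)
  out[]
}

TASK_TRANSITIONS <- list(OPEN = c("ASSIGNED_MONITORING", "RESOLVED"),
                         ASSIGNED_MONITORING = "RESOLVED",
                         RESOLVED = character(0))

#' Advance a task through its lifecycle
#'
#' Legal transitions: OPEN -> ASSIGNED_MONITORING -> RESOLVED, or OPEN ->
#' RESOLVED.  Notes are append-only with a timestamp.
#'
#' @param tasks task queue from [build_task_queue()]
#' @param task_id task to update
#' @param new_status target status
#' @param note optional text appended to the task's note log
#' @param at timestamp recorded with the note
#' @return the updated task table (a copy)
#' @export
update_task_status <- function(tasks, task_id, new_status, note = "",
                               at = as.POSIXct("1970-01-01", tz = "UTC")) {
  tk <- copy(as.data.table(tasks))
  i <- which(tk$task_id == task_id)
  if (length(i) != 1L) stop("unknown task: ", task_id, call. = FALSE)
  cur <- tk$status[i]
  if (!(new_status %in% TASK_TRANSITIONS[[cur]]))
    stop(sprintf("illegal task transition %s -> %s", cur, new_status), call. = FALSE)
  tk[i, status := new_status]
  if (nzchar(note))
    tk[i, notes := paste0(notes, if (nzchar(notes)) "\n", format_ts(at), " ", note)]
  tk[]
}

#' Aggregate one interviewer's engine outputs into a profile
#'
#' @param interviewer_id id to profile; must appear in `known_ids` (an
#'   interviewer with no output rows yields a profile of zeros)
#' @param flags,metrics,window_stats engine outputs
#' @param known_ids roster of valid ids; defaults to ids seen in the inputs
#' @param date_range optional length-2 `Date` filter (half-open) on flag dates
#' @param category optional flag-category filter (`"duration"`, `"cidi"`,
#'   `"operational"`)
#' @return list: `interviewer_id`, `n_flags`, `flags_by_type`,
#'   `flags_by_category`, `metrics` (metric -> value, interviewer level),
#'   `z_trajectory` (window, statistic, z)
#' @export
interviewer_profile <- function(interviewer_id, flags, metrics, window_stats,
                                known_ids = NULL, date_range = NULL,
                                category = NULL) {
  fl <- as.data.table(flags); mt <- as.data.table(metrics)
  ws <- as.data.table(window_stats)
  if (is.null(known_ids))
    known_ids <- unique(c(fl$interviewer_id, mt$interviewer_id, ws$interviewer_id))
  if (!interviewer_id %in% known_ids)
    stop("unknown interviewer: ", interviewer_id, call. = FALSE)
  f <- fl[interviewer_id, on = "interviewer_id", nomatch = NULL]
  if (!is.null(date_range))
    f <- f[triggered_at >= as.Date(date_range[1]) & triggered_at < as.Date(date_range[2])]
  cat_filter <- category
  f[, category := FLAG_CATEGORIES[flag_type]]
  if (!is.null(cat_filter)) f <- f[category %in% cat_filter]
  by_type <- if (nrow(f)) f[, .N, by = flag_type] else
    data.table(flag_type = character(), N = integer())
  by_cat <- if (nrow(f)) f[, .N, by = category] else
    data.table(category = character(), N = integer())
  m <- mt[interviewer_id, on = "interviewer_id", nomatch = NULL][is.na(case_id)]
  z <- ws[interviewer_id, on = "interviewer_id", nomatch = NULL,
          .(window_start, window_end, statistic, n_cases, value, z)]
  list(interviewer_id = interviewer_id,
       n_flags = nrow(f),
       flags_by_type = setNames(as.list(by_type$N), by_type$flag_type),
       flags_by_category = setNames(as.list(by_cat$N), by_cat$category),
       metrics = setNames(as.list(m$value), m$metric),
       z_trajectory = z)
}

EVAL_SKILLS <- c("probing", "objections_refusals", "persuasion", "typing_speed",
                 "project_knowledge", "verbatim_reading")

#' Record an interviewer skill evaluation
#'
#' Six fixed skills, each scored 0 (lowest) to 5 (highest).
#'
#' @param interviewer_id interviewer evaluated
#' @param date evaluation date
#' @param scores named integer vector/list covering exactly the six skills:
#'   probing, objections_refusals, persuasion, typing_speed,
#'   project_knowledge, verbatim_reading
#' @return one-row data.table (id, date, one column per skill)
#' @export
evaluation_record <- function(interviewer_id, date, scores) {
  scores <- unlist(scores)
  if (!setequal(names(scores), EVAL_SKILLS))
    stop("scores must cover exactly: ", paste(EVAL_SKILLS, collapse = ", "),
         call. = FALSE)
  scores <- scores[EVAL_SKILLS]
  if (any(scores != as.integer(scores)) || any(scores < 0) || any(scores > 5))
    stop("scores must be integers in 0..5", call. = FALSE)
  cbind(data.table(interviewer_id = interviewer_id, date = as.Date(date)),
        as.data.table(as.list(setNames(as.integer(scores), names(scores)))))
}
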