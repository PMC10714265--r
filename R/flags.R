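# Flag engine: case-level quality indicators evaluated against one threshold
# configuration.  All cutoff comparisons are strict (<, >) except the
# high-completes z rule which is >= per its own contract.

FLAG_TYPES <- c("HIGH_COMPLETES", "SHORT_QUESTION_TIME", "SHORT_STEM_QUESTION_TIME",
                "HIGH_PCT_SHORT_TIME", "SHORT_INTERVIEW", "LONG_INTERVIEW",
                "SHORT_AVG_INTERVIEW", "HIGH_NEGATIVE_STEMS", "MULTI_FIELD_VISITS",
                "MULTI_STEM_FIELD_VISITS", "PREVALENCE_RATE", "LONG_QUESTION_TIME",
                "LONG_TREATMENT")

# one emitting operation per flag type (checked by a registry test)
FLAG_REGISTRY <- list(
  flag_question_times  = c("SHORT_QUESTION_TIME", "SHORT_STEM_QUESTION_TIME",
                           "LONG_QUESTION_TIME"),
  flag_multiple_visits = c("MULTI_FIELD_VISITS", "MULTI_STEM_FIELD_VISITS"),
  flag_case_profiles   = c("HIGH_PCT_SHORT_TIME", "SHORT_INTERVIEW",
                           "LONG_INTERVIEW", "HIGH_NEGATIVE_STEMS", "LONG_TREATMENT"),
  flag_high_completes  = "HIGH_COMPLETES",
  emit_window_flags    = c("PREVALENCE_RATE", "SHORT_AVG_INTERVIEW"))

# Flag -> review-team category.  The fielded system named the categories but
# not the assignment; this shipped table is the package's declared mapping and
# can be overridden in reporting calls.
FLAG_CATEGORIES <- c(
  SHORT_QUESTION_TIME = "duration", SHORT_STEM_QUESTION_TIME = "duration",
  HIGH_PCT_SHORT_TIME = "duration", SHORT_INTERVIEW = "duration",
  LONG_INTERVIEW = "duration", SHORT_AVG_INTERVIEW = "duration",
  LONG_QUESTION_TIME = "duration", LONG_TREATMENT = "duration",
  HIGH_NEGATIVE_STEMS = "cidi", PREVALENCE_RATE = "cidi",
  MULTI_FIELD_VISITS = "cidi", MULTI_STEM_FIELD_VISITS = "cidi",
  HIGH_COMPLETES = "operational")

#' Flag type -> category mapping
#' @return named character vector (names are flag types; values are
#'   `"duration"`, `"cidi"` or `"operational"`)
#' @export
flag_categories <- function() FLAG_CATEGORIES

empty_flags <- function() {
  data.table(flag_type = character(), level = character(), case_id = character(),
             interviewer_id = character(), question_id = character(),
             window_start = as.Date(character()), window_end = as.Date(character()),
             observed_value = numeric(), threshold_value = numeric(),
             triggered_at = as.Date(character()), status = character(),
             notes = character())
}

make_flags <- function(flag_type, level, interviewer_id, observed_value,
                       threshold_value, triggered_at, case_id = NA_character_,
                       question_id = NA_character_, window_start = as.Date(NA),
                       window_end = as.Date(NA), notes = "") {
  n <- length(observed_value)
  if (n == 0L) return(empty_flags())
  data.table(flag_type = flag_type, level = level, case_id = case_id,
             interviewer_id = interviewer_id, question_id = question_id,
             window_start = as.Date(window_start), window_end = as.Date(window_end),
             observed_value = as.numeric(observed_value),
             threshold_value = as.numeric(threshold_value),
             triggered_at = as.Date(triggered_at), status = "OPEN", notes = notes)
}

bind_flags <- function(...) {
  parts <- lapply(list(...), function(x) {
    x <- as.data.table(x)
    if ("flag_id" %in% names(x)) x[, !"flag_id"] else x
  })
  out <- rbindlist(parts, use.names = TRUE)
  if (nrow(out) == 0L) return(empty_flags())
  setorder(out, triggered_at, flag_type, interviewer_id, case_id, question_id,
           na.last = TRUE)
  out[, flag_id := sprintf("F%06d", .I)]
  setcolorder(out, "flag_id")
  out[]
}

# join stem/exclusion info; error on questions missing from the catalog when
# required (stem status decides which flag applies)
join_catalog <- function(dt, catalog, require_known = FALSE, context = "") {
  cat_dt <- as.data.table(catalog)[, .(question_id, is_stem, exclude_from_short_flag)]
  out <- cat_dt[dt, on = "question_id"]
  if (require_known && anyNA(out$is_stem))
    stop(context, ": question_id absent from catalog: ",
         out[is.na(is_stem), question_id][1], call. = FALSE)
  out
}

#' Flag short and long question field times
#'
#' A visit on a non-excluded question shorter than the short cutoff (strict
#' `<`) flags `SHORT_QUESTION_TIME` (nonstem) or `SHORT_STEM_QUESTION_TIME`
#' (stem); a visit longer than the long cutoff (strict `>`, any question,
#' excluded or not) flags `LONG_QUESTION_TIME`.  One flag per offending visit.
#'
#' @param visits output of [build_field_visits()]
#' @param catalog question catalog (stem status and exclusion list)
#' @param cfg a [qc_config()]
#' @return flag table (one row per flag)
#' @export
flag_question_times <- function(visits, catalog, cfg) {
  if (nrow(visits) == 0L) return(bind_flags())
  v <- join_catalog(visits, catalog)
  v[is.na(is_stem), `:=`(is_stem = FALSE, exclude_from_short_flag = FALSE)]
  short <- v[field_time_seconds < cfg$short_question_seconds &
               exclude_from_short_flag == FALSE]
  long <- v[field_time_seconds > cfg$long_question_seconds]
  bind_flags(
    make_flags(fifelse(short$is_stem, "SHORT_STEM_QUESTION_TIME", "SHORT_QUESTION_TIME"),
               "CASE", short$interviewer_id, short$field_time_seconds,
               cfg$short_question_seconds, as.Date(short$enter),
               case_id = short$case_id, question_id = short$question_id),
    make_flags("LONG_QUESTION_TIME", "CASE", long$interviewer_id,
               long$field_time_seconds, cfg$long_question_seconds,
               as.Date(long$enter), case_id = long$case_id,
               question_id = long$question_id))
}

#' Flag questions visited more than the cutoff number of times
#'
#' @param visit_counts output of [count_question_visits()]
#' @param catalog question catalog; every counted question must appear in it
#' @param cfg a [qc_config()]
#' @param case_info optional table `case_id`, `interviewer_id`, `date` used to
#'   attribute flags; without it interviewer and date are `NA`.
#' @return flag table: `MULTI_STEM_FIELD_VISITS` where a stem count exceeds
#'   `stem_visit_cutoff` (strict `>`), `MULTI_FIELD_VISITS` where a nonstem
#'   count exceeds `nonstem_visit_cutoff`
#' @export
flag_multiple_visits <- function(visit_counts, catalog, cfg, case_info = NULL) {
  if (nrow(visit_counts) == 0L) return(bind_flags())
  vc <- join_catalog(visit_counts, catalog, require_known = TRUE,
                     context = "flag_multiple_visits")
  vc[, `:=`(interviewer_id = NA_character_, date = as.Date(NA))]
  if (!is.null(case_info)) {
    ci <- as.data.table(case_info)
    vc[ci, on = "case_id", `:=`(interviewer_id = i.interviewer_id, date = i.date)]
  }
  hit <- vc[(is_stem & n_visits > cfg$stem_visit_cutoff) |
              (!is_stem & n_visits > cfg$nonstem_visit_cutoff)]
  make_flags(fifelse(hit$is_stem, "MULTI_STEM_FIELD_VISITS", "MULTI_FIELD_VISITS"),
             "CASE", hit$interviewer_id, hit$n_visits,
             fifelse(hit$is_stem, cfg$stem_visit_cutoff, cfg$nonstem_visit_cutoff),
             hit$date, case_id = hit$case_id,
             question_id = hit$question_id) |> bind_flags()
}

#' Flag case profiles: short-time share, interview length, negative stems,
#' treatment length
#'
#' Length, stem and short-share rules apply to COMPLETE cases only; the
#' treatment-length rule applies to every case with a timeline.  A complete
#' case with zero short-eligible visits is skipped for the short-share rule
#' (no division by zero) and recorded in attribute `"skipped_pct_short"`.
#'
#' @param cases case-record table
#' @param timelines output of [build_timelines()]
#' @param visits output of [build_field_visits()]
#' @param catalog question catalog
#' @param cfg a [qc_config()]
#' @return flag table
#' @export
flag_case_profiles <- function(cases, timelines, visits, catalog, cfg) {
  cs <- as.data.table(cases)
  tl <- as.data.table(timelines)
  flags <- list()
  skipped <- character(0)
  if (nrow(cs)) {
    comp <- cs[disposition == "COMPLETE"]
    comp[, date := as.Date(call_start)]

    # interview length against version-specific cutoffs on adjusted minutes
    if (nrow(tl) && "case_id" %in% names(tl)) {
      ctl <- tl[comp, on = "case_id", nomatch = NULL]
      ctl[, adj_min := adjusted_total_seconds / 60]
      ctl[, short_cut := vapply(version, function(v) cfg$short_interview_minutes[[v]], 0)]
      ctl[, long_cut := vapply(version, function(v) cfg$long_interview_minutes[[v]], 0)]
      s <- ctl[adj_min < short_cut]
      l <- ctl[adj_min > long_cut]
      flags$short <- make_flags("SHORT_INTERVIEW", "CASE", s$interviewer_id,
                                s$adj_min, s$short_cut, s$date, case_id = s$case_id)
      flags$long <- make_flags("LONG_INTERVIEW", "CASE", l$interviewer_id,
                               l$adj_min, l$long_cut, l$date, case_id = l$case_id)
    }

    # share of short-eligible visits under the short cutoff
    if (NROW(visits) && "case_id" %in% names(visits)) {
      v <- join_catalog(visits, catalog)
      v <- v[is.na(exclude_from_short_flag) | exclude_from_short_flag == FALSE]
      agg <- v[case_id %in% comp$case_id,
               .(n_eligible = .N,
                 n_short = sum(field_time_seconds < cfg$short_question_seconds)),
               by = case_id]
      agg <- comp[, .(case_id, interviewer_id, date)][agg, on = "case_id"]
      hit <- agg[100 * n_short / n_eligible > cfg$short_field_pct]
      flags$pct <- make_flags("HIGH_PCT_SHORT_TIME", "CASE", hit$interviewer_id,
                              100 * hit$n_short / hit$n_eligible,
                              cfg$short_field_pct, hit$date, case_id = hit$case_id)
      skipped <- setdiff(comp$case_id, agg$case_id)
    } else skipped <- comp$case_id

    # negative stems among administered (non-missing) stem answers
    sa <- parse_stem_answers(comp)
    if (nrow(sa)) {
      st <- sa[answer != "MISSING",
               .(n_admin = .N, n_neg = sum(answer == "NEGATIVE")), by = case_id]
      st <- comp[, .(case_id, interviewer_id, date)][st, on = "case_id"]
      if (identical(cfg$negative_stem_rule, "all")) {
        hit <- st[n_admin >= cfg$negative_stem_min_administered & n_neg == n_admin]
        thr <- hit$n_admin
      } else {
        hit <- st[n_neg > cfg$negative_stem_rule]
        thr <- cfg$negative_stem_rule
      }
      flags$stems <- make_flags("HIGH_NEGATIVE_STEMS", "CASE", hit$interviewer_id,
                                hit$n_neg, thr, hit$date, case_id = hit$case_id)
    }
  }

  # treatment-module time, evaluated for every case with a timeline
  if (nrow(tl) && "case_id" %in% names(tl)) {
    ti <- cs[, .(case_id, date = as.Date(call_start))][tl, on = "case_id"]
    hit <- ti[treatment_seconds > cfg$treatment_length_minutes * 60]
    flags$treat <- make_flags("LONG_TREATMENT", "CASE", hit$interviewer_id,
                              hit$treatment_seconds / 60,
                              cfg$treatment_length_minutes, hit$date,
                              case_id = hit$case_id)
  }
  out <- do.call(bind_flags, flags)
  setattr(out, "skipped_pct_short", skipped)
  out
}

#' Single-case wrapper of [flag_case_profiles()]
#'
#' @param case one-row case-record table
#' @param timeline one-row timeline table for the same case
#' @param visits that case's visits
#' @param catalog question catalog
#' @param cfg a [qc_config()]
#' @return flag table
#' @export
flag_case_profile <- function(case, timeline, visits, catalog, cfg) {
  stopifnot(nrow(case) == 1L)
  flag_case_profiles(case, timeline, visits, catalog, cfg)
}

#' Per-interviewer daily completes and worked calling hours
#'
#' @param case_records case-record table
#' @param time_logs time-log table
#' @return data.table `interviewer_id`, `date`, `completes`,
#'   `worked_hours` (sum of CALLING activity, attributed to the entry's start
#'   date)
#' @export
daily_interviewer_stats <- function(case_records, time_logs) {
  comp <- as.data.table(case_records)[disposition == "COMPLETE",
                                      .(completes = .N),
                                      by = .(interviewer_id, date = as.Date(call_start))]
  hrs <- as.data.table(time_logs)[activity == "CALLING",
                                  .(worked_hours = sum(as.numeric(end) - as.numeric(start)) / 3600),
                                  by = .(interviewer_id, date = as.Date(start))]
  out <- merge(comp, hrs, by = c("interviewer_id", "date"), all = TRUE)
  out[is.na(completes), completes := 0L]
  out[is.na(worked_hours), worked_hours := 0]
  setorder(out, date, interviewer_id)
  out[]
}

#' Flag unusually high exposure-adjusted completion rates
#'
#' Raw completes mislead when interviewers work unequal hours, so the rate is
#' completes per worked CALLING hour; each interviewer-day is standardized
#' against all interviewer-days of the same calendar day and flagged when its
#' z score reaches `completes_zscore_cutoff` (`>=`).  Days where the
#' cross-interviewer sample SD is zero, or with fewer than two rates, produce
#' no flags.  Interviewer-days with completes but zero worked hours are
#' recorded in attribute `"inconsistencies"` and excluded from rates.
#'
#' @param day_stats output of [daily_interviewer_stats()]
#' @param cfg a [qc_config()]
#' @return flag table (level `INTERVIEWER_WINDOW`; the window is the single day)
#' @export
flag_high_completes <- function(day_stats, cfg) {
  ds <- as.data.table(day_stats)
  bad <- ds[worked_hours == 0 & completes > 0]
  ds <- ds[worked_hours > 0]
  if (nrow(ds)) {
    ds[, rate := completes / worked_hours]
    ds[, `:=`(mu = mean(rate), sdev = if (.N >= 2) sd(rate) else NA_real_, n = .N),
       by = date]
    hit <- ds[!is.na(sdev) & sdev > 0 &
                (rate - mu) / sdev >= cfg$completes_zscore_cutoff]
    out <- make_flags("HIGH_COMPLETES", "INTERVIEWER_WINDOW", hit$interviewer_id,
                      (hit$rate - hit$mu) / hit$sdev, cfg$completes_zscore_cutoff,
                      hit$date, window_start = hit$date, window_end = hit$date + 1,
                      notes = sprintf("rate %.3f completes/h over %.2f h",
                                      hit$rate, hit$worked_hours)) |> bind_flags()
  } else out <- bind_flags()
  setattr(out, "inconsistencies", bad[])
  out
}
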