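# Windowed interviewer statistics: tumbling two-week windows aligned to the
# study start, cross-interviewer z scores, and the two windowed flags
# (prevalence rate; short average interview length).

#' Partition a date range into tumbling windows
#'
#' Windows are `window_days` long, aligned to `study_start_date`, half-open on
#' dates (`[start, end)`): a case dated exactly on a boundary belongs to the
#' later window.
#'
#' @param study_start_date `Date`, the alignment anchor; must not be after the
#'   earliest date
#' @param dates `Date` vector of observed activity
#' @param window_days window width in days (default 14)
#' @return data.table `window_start`, `window_end`, consecutive and disjoint,
#'   jointly covering `dates`; empty for an empty date set
#' @export
partition_windows <- function(study_start_date, dates, window_days = 14) {
  start <- as.Date(study_start_date)
  dates <- as.Date(dates)
  if (length(dates) == 0L)
    return(data.table(window_start = as.Date(character()),
                      window_end = as.Date(character())))
  if (min(dates) < start)
    stop("study_start_date is after the earliest date", call. = FALSE)
  k <- floor(as.numeric(max(dates) - start) / window_days)
  ws <- start + (0:k) * window_days
  data.table(window_start = ws, window_end = ws + window_days)
}

# window start containing each date (half-open)
assign_window <- function(dates, study_start_date, window_days = 14) {
  start <- as.Date(study_start_date)
  start + floor(as.numeric(as.Date(dates) - start) / window_days) * window_days
}

empty_window_stats <- function() {
  data.table(interviewer_id = character(),
             window_start = as.Date(character()), window_end = as.Date(character()),
             statistic = character(), n_cases = integer(), value = numeric(),
             z = numeric())
}

#' Per-interviewer windowed disorder prevalence
#'
#' The fraction of an interviewer's completed cases in each window that screen
#' positive for any disorder.  Only COMPLETE cases (which must carry a
#' non-null `any_disorder`) enter.
#'
#' @param cases case-record table
#' @param study_start_date window alignment anchor (`Date`)
#' @param cfg a [qc_config()] (window width)
#' @return window-stat table: `interviewer_id`, `window_start`, `window_end`,
#'   `statistic = "PREVALENCE"`, `n_cases`, `value`, `z` (NA until
#'   [window_zscores()])
#' @export
prevalence_stat <- function(cases, study_start_date, cfg = qc_config()) {
  comp <- as.data.table(cases)[disposition == "COMPLETE"]
  if (nrow(comp) == 0L) return(empty_window_stats())
  comp[, window_start := assign_window(as.Date(call_start), study_start_date,
                                       cfg$window_days)]
  out <- comp[, .(n_cases = .N, value = mean(any_disorder)),
              by = .(interviewer_id, window_start)]
  out[, `:=`(window_end = window_start + cfg$window_days,
             statistic = "PREVALENCE", z = NA_real_)]
  setcolorder(out, c("interviewer_id", "window_start", "window_end", "statistic",
                     "n_cases", "value", "z"))
  setorder(out, window_start, interviewer_id)
  out[]
}

#' Per-interviewer windowed mean interview length
#'
#' Mean adjusted interview length (minutes) over an interviewer's completed
#' cases in each window.
#'
#' @param cases case-record table
#' @param timelines output of [build_timelines()]
#' @param study_start_date window alignment anchor (`Date`)
#' @param cfg a [qc_config()]
#' @return window-stat table with `statistic = "MEAN_INTERVIEW_MINUTES"`
#' @export
mean_interview_stat <- function(cases, timelines, study_start_date,
                                cfg = qc_config()) {
  comp <- as.data.table(cases)[disposition == "COMPLETE"]
  tl <- as.data.table(timelines)
  comp <- tl[, .(case_id, adjusted_total_seconds)][comp, on = "case_id", nomatch = NULL]
  if (nrow(comp) == 0L) return(empty_window_stats())
  comp[, window_start := assign_window(as.Date(call_start), study_start_date,
                                       cfg$window_days)]
  out <- comp[, .(n_cases = .N, value = mean(adjusted_total_seconds) / 60),
              by = .(interviewer_id, window_start)]
  out[, `:=`(window_end = window_start + cfg$window_days,
             statistic = "MEAN_INTERVIEW_MINUTES", z = NA_real_)]
  setcolorder(out, c("interviewer_id", "window_start", "window_end", "statistic",
                     "n_cases", "value", "z"))
  setorder(out, window_start, interviewer_id)
  out[]
}

#' Cross-interviewer z scores within each window
#'
#' Within each (window, statistic) group, interviewers with at least
#' `min_completes_per_window` cases form the standardization population;
#' `z = (value - mean) / sd` with the sample SD (n-1) over that population.
#' Ineligible interviewers, and every interviewer when the SD is zero or fewer
#' than two interviewers are eligible, get `z = NA`.
#'
#' @param stats window-stat table from [prevalence_stat()] /
#'   [mean_interview_stat()] (the two may be rbind-ed)
#' @param cfg a [qc_config()]
#' @return the same table with `z` filled in
#' @export
window_zscores <- function(stats, cfg = qc_config()) {
  st <- copy(as.data.table(stats))
  if (nrow(st) == 0L) return(st)
  st[, eligible := n_cases >= cfg$min_completes_per_window]
  st[, z := NA_real_]
  st[, `:=`(mu = mean(value[eligible]),
            sdev = if (sum(eligible) >= 2L) sd(value[eligible]) else NA_real_),
     by = .(window_start, statistic)]
  st[eligible & !is.na(sdev) & sdev > 0, z := (value - mu) / sdev]
  st[, c("eligible", "mu", "sdev") := NULL]
  st[]
}

#' Emit the windowed interviewer flags
#'
#' `PREVALENCE_RATE` fires when the prevalence z magnitude strictly exceeds
#' `prevalence_z_cutoff` (sign preserved in `observed_value`: positive and
#' negative prevalence outliers are both flagged); `SHORT_AVG_INTERVIEW` fires
#' when the mean-interview-length z is `<=` `short_avg_interview_z_cutoff`
#' (the operators follow each flag's fielded wording, hence differ).
#'
#' @param stats window-stat table with `z` computed ([window_zscores()])
#' @param cfg a [qc_config()]
#' @return flag table (level `INTERVIEWER_WINDOW`), `triggered_at` = window end
#' @export
emit_window_flags <- function(stats, cfg = qc_config()) {
  st <- as.data.table(stats)[!is.na(z)]
  prev <- st[statistic == "PREVALENCE" & abs(z) > cfg$prevalence_z_cutoff]
  shrt <- st[statistic == "MEAN_INTERVIEW_MINUTES" &
               z <= cfg$short_avg_interview_z_cutoff]
  bind_flags(
    make_flags("PREVALENCE_RATE", "INTERVIEWER_WINDOW", prev$interviewer_id,
               prev$z, cfg$prevalence_z_cutoff, prev$window_end,
               window_start = prev$window_start, window_end = prev$window_end,
               notes = sprintf("prevalence %.3f over %d completes",
                               prev$value, prev$n_cases)),
    make_flags("SHORT_AVG_INTERVIEW", "INTERVIEWER_WINDOW", shrt$interviewer_id,
               shrt$z, cfg$short_avg_interview_z_cutoff, shrt$window_end,
               window_start = shrt$window_start, window_end = shrt$window_end,
               notes = sprintf("mean interview %.1f min over %d completes",
                               shrt$value, shrt$n_cases)))
}
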