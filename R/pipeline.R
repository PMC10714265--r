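# End-to-end engine: bundle -> visits -> timelines -> flags -> window stats ->
# metrics -> reports, plus deterministic on-disk exports.

#' Run the full QC engine on a paradata bundle
#'
#' @param bundle a `paradata_bundle`
#' @param cfg a [qc_config()]
#' @return list: `visits`, `timelines`, `flags` (all levels, one table),
#'   `window_stats`, `metrics`, `summary`, `coverage`, `tasks`, `day_stats`,
#'   `n_completed`, `n_touched`, `period`
#' @export
run_qc <- function(bundle, cfg = qc_config()) {
  stopifnot(inherits(bundle, "paradata_bundle"))
  visits <- build_field_visits(bundle$audit_events, bundle$catalog)
  timelines <- timelines_from_visits(visits, bundle$catalog,
                                     cfg$pause_threshold_seconds)
  cases <- bundle$case_records
  case_info <- cases[, .(case_id, interviewer_id, date = as.Date(call_start))]

  f_time <- flag_question_times(visits, bundle$catalog, cfg)
  f_vis <- flag_multiple_visits(count_question_visits(visits), bundle$catalog,
                                cfg, case_info)
  f_prof <- flag_case_profiles(cases, timelines, visits, bundle$catalog, cfg)
  day_stats <- daily_interviewer_stats(cases, bundle$time_logs)
  f_hc <- flag_high_completes(day_stats, cfg)

  stats <- rbind(prevalence_stat(cases, bundle$study_start_date, cfg),
                 mean_interview_stat(cases, timelines, bundle$study_start_date, cfg))
  stats <- window_zscores(stats, cfg)
  f_win <- emit_window_flags(stats, cfg)

  flags <- bind_flags(f_time, f_vis, f_prof, f_hc, f_win)

  dates <- c(as.Date(cases$call_start), as.Date(bundle$time_logs$start),
             bundle$study_start_date)
  period <- c(bundle$study_start_date, max(dates) + 1)
  metrics <- compute_metrics(bundle, visits, timelines, period)

  completed_ids <- cases[disposition == "COMPLETE", case_id]
  n_completed <- length(completed_ids)
  n_touched <- uniqueN(cases$case_id)

  # attribute window-level z flags to the interviewer's completed cases in the
  # flagged window, mirroring how window flags touch many cases
  wf <- flags[level == "INTERVIEWER_WINDOW" & !is.na(window_start)]
  flag_cases <- if (nrow(wf)) {
    cc <- cases[disposition == "COMPLETE",
                .(case_id, interviewer_id, date = as.Date(call_start))]
    wf[, .(flag_id, interviewer_id, window_start, window_end)][
      cc, on = .(interviewer_id, window_start <= date, window_end > date),
      nomatch = NULL, .(flag_id, case_id = i.case_id)]
  } else NULL

  summary <- if (n_completed > 0 && n_touched > 0 && nrow(flags) > 0)
    flag_summary(flags, n_completed, n_touched, flag_cases = flag_cases)
  else flag_summary(empty_flags(), max(n_completed, 1L), max(n_touched, 1L))
  coverage <- monitoring_coverage(bundle$call_records, completed_ids)
  tasks <- build_task_queue(flags, period,
                            rules = list(high_count = cfg$task_high_count,
                                         med_count = cfg$task_med_count))

  list(visits = visits, timelines = timelines, flags = flags,
       window_stats = stats, metrics = metrics, summary = summary,
       coverage = coverage, tasks = tasks, day_stats = day_stats,
       n_completed = n_completed, n_touched = n_touched, period = period)
}

#' Write engine outputs to a report directory
#'
#' Produces `flags.csv`, `summary.csv`, `metrics.csv`, `window_stats.csv`,
#' `visits.csv`, `timelines.csv`, `coverage.json`, `tasks.json` and
#' `profiles/<id>.json`.  Output is deterministic: rerunning on the same
#' results yields byte-identical files.
#'
#' @param results output of [run_qc()]
#' @param dir output directory (created if absent)
#' @param bundle optional bundle; when given, profiles cover every interviewer
#'   in it (not only flagged ones)
#' @return `dir`, invisibly
#' @export
write_qc_outputs <- function(results, dir, bundle = NULL) {
  dir.create(file.path(dir, "profiles"), showWarnings = FALSE, recursive = TRUE)
  v <- copy(results$visits)
  v[, `:=`(enter = format_ts(enter), exit = format_ts(exit))]
  qc_fwrite(v, file.path(dir, "visits.csv"))
  qc_fwrite(results$timelines, file.path(dir, "timelines.csv"))
  qc_fwrite(results$flags, file.path(dir, "flags.csv"))
  qc_fwrite(results$summary, file.path(dir, "summary.csv"))
  qc_fwrite(results$metrics, file.path(dir, "metrics.csv"))
  qc_fwrite(results$window_stats, file.path(dir, "window_stats.csv"))
  jsonlite::write_json(results$coverage, file.path(dir, "coverage.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tk <- results$tasks
  jsonlite::write_json(tk, file.path(dir, "tasks.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  ids <- if (!is.null(bundle))
    sort(unique(c(bundle$case_records$interviewer_id,
                  bundle$time_logs$interviewer_id)))
  else sort(unique(results$flags$interviewer_id))
  ids <- ids[!is.na(ids)]
  for (id in ids) {
    p <- interviewer_profile(id, results$flags, results$metrics,
                             results$window_stats, known_ids = ids)
    jsonlite::write_json(p, file.path(dir, "profiles", paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(dir)
}
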