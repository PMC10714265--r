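# Threshold configuration: one structured object holding every cutoff the flag
# engine and window statistics use.  Field names are mirrored verbatim in the
# on-disk config file.

#' Build a threshold configuration
#'
#' All cutoffs used by the flag engine and the windowed z-score statistics live
#' in one object.  Defaults follow the fielded system where a cutoff was
#' published (3 s short-question rule, 7 min long-pause rule, 1 stem / 3
#' nonstem visit cutoffs, 30% short-field share, +/-1.5 prevalence z, -2
#' short-average-interview z, 2-week windows); interview-length and treatment
#' cutoffs were never published and default to declared values anchored to the
#' published mean lengths (94 min long version, 64 min short version).
#'
#' @param short_question_seconds a visit shorter than this (strict `<`) on a
#'   non-excluded question is a short-time flag; seconds.
#' @param long_question_seconds a visit longer than this (strict `>`) flags a
#'   long question field time; seconds.  Default 420 (the 7-minute break rule).
#' @param stem_visit_cutoff flag a stem question visited more than this many
#'   times.
#' @param nonstem_visit_cutoff flag a nonstem question visited more than this
#'   many times.
#' @param short_field_pct flag a completed case whose percentage of
#'   short-eligible visits under the short cutoff exceeds this (strict `>`).
#' @param short_interview_minutes,long_interview_minutes named lists
#'   (`LONG`, `SHORT`) of adjusted-length cutoffs in minutes.
#' @param negative_stem_rule `"all"` (flag when every administered stem is
#'   negative and at least `negative_stem_min_administered` stems were
#'   administered) or a positive count (flag when more than that many stems are
#'   negative).
#' @param negative_stem_min_administered see `negative_stem_rule`.
#' @param treatment_length_minutes flag when treatment-module field time
#'   exceeds this; minutes.
#' @param completes_zscore_cutoff same-day cross-interviewer z cutoff (`>=`)
#'   on the worked-hour-adjusted completes rate.
#' @param prevalence_z_cutoff magnitude cutoff (strict `>`) on the windowed
#'   prevalence z score.
#' @param short_avg_interview_z_cutoff signed cutoff (`<=`) on the windowed
#'   mean-interview-length z score.
#' @param window_days width of the tumbling interviewer windows; days.
#' @param min_completes_per_window interviewers with fewer completes in a
#'   window are excluded from standardization and get no z score.
#' @param pause_threshold_seconds within-case gaps longer than this are
#'   excised from the adjusted interview length; seconds.
#' @param task_high_count,task_med_count case-flag counts at which an
#'   investigation task is prioritized HIGH / MEDIUM.
#' @return an object of class `qc_config` (a validated named list)
#' @export
qc_config <- function(short_question_seconds = 3,
                      long_question_seconds = 420,
                      stem_visit_cutoff = 1,
                      nonstem_visit_cutoff = 3,
                      short_field_pct = 30,
                      short_interview_minutes = list(LONG = 47, SHORT = 32),
                      long_interview_minutes = list(LONG = 188, SHORT = 128),
                      negative_stem_rule = "all",
                      negative_stem_min_administered = 10,
                      treatment_length_minutes = 30,
                      completes_zscore_cutoff = 2,
                      prevalence_z_cutoff = 1.5,
                      short_avg_interview_z_cutoff = -2,
                      window_days = 14,
                      min_completes_per_window = 5,
                      pause_threshold_seconds = 420,
                      task_high_count = 10,
                      task_med_count = 3) {
  cfg <- list(short_question_seconds = as.numeric(short_question_seconds),
              long_question_seconds = as.numeric(long_question_seconds),
              stem_visit_cutoff = as.numeric(stem_visit_cutoff),
              nonstem_visit_cutoff = as.numeric(nonstem_visit_cutoff),
              short_field_pct = as.numeric(short_field_pct),
              short_interview_minutes = lapply(short_interview_minutes, as.numeric),
              long_interview_minutes = lapply(long_interview_minutes, as.numeric),
              negative_stem_rule = negative_stem_rule,
              negative_stem_min_administered = as.numeric(negative_stem_min_administered),
              treatment_length_minutes = as.numeric(treatment_length_minutes),
              completes_zscore_cutoff = as.numeric(completes_zscore_cutoff),
              prevalence_z_cutoff = as.numeric(prevalence_z_cutoff),
              short_avg_interview_z_cutoff = as.numeric(short_avg_interview_z_cutoff),
              window_days = as.numeric(window_days),
              min_completes_per_window = as.numeric(min_completes_per_window),
              pause_threshold_seconds = as.numeric(pause_threshold_seconds),
              task_high_count = as.numeric(task_high_count),
              task_med_count = as.numeric(task_med_count))
  validate_qc_config(cfg)
  structure(cfg, class = "qc_config")
}

validate_qc_config <- function(cfg) {
  pos <- c("short_question_seconds", "long_question_seconds", "stem_visit_cutoff",
           "nonstem_visit_cutoff", "short_field_pct", "treatment_length_minutes",
           "window_days", "min_completes_per_window", "pause_threshold_seconds",
           "task_high_count", "task_med_count", "negative_stem_min_administered")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(sprintf("config field '%s' must be a single positive number", f), call. = FALSE)
  if (cfg$window_days < 1) stop("window_days must be >= 1", call. = FALSE)
  for (f in c("short_interview_minutes", "long_interview_minutes")) {
    v <- cfg[[f]]
    if (!all(c("LONG", "SHORT") %in% names(v)))
      stop(sprintf("config field '%s' needs LONG and SHORT entries", f), call. = FALSE)
    if (any(unlist(v) <= 0))
      stop(sprintf("config field '%s' entries must be positive", f), call. = FALSE)
  }
  if (!(identical(cfg$negative_stem_rule, "all") ||
        (is.numeric(cfg$negative_stem_rule) && cfg$negative_stem_rule > 0)))
    stop("negative_stem_rule must be \"all\" or a positive count", call. = FALSE)
  invisible(cfg)
}

#' Write a threshold configuration to a structured text file
#'
#' The format is a flat indented `key: value` layout (a YAML subset) mirroring
#' the `qc_config()` field names exactly; the version-keyed interview-length
#' cutoffs are nested one level.
#'
#' @param cfg a `qc_config` object
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_qc_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "qc_config"))
  lines <- character(0)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (is.list(v)) {
      lines <- c(lines, paste0(nm, ":"))
      for (k in names(v)) lines <- c(lines, sprintf("  %s: %s", k, format(v[[k]])))
    } else {
      lines <- c(lines, sprintf("%s: %s", nm, format(v)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a threshold configuration file
#'
#' @param path file written by [write_qc_config()] (or by hand, same layout).
#'   Unknown keys are an error; missing keys keep their defaults.
#' @return a `qc_config` object
#' @export
read_qc_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  vals <- list()
  current <- NULL
  for (ln in lines) {
    indented <- grepl("^\\s+", ln)
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 0L) stop("unparseable config line: ", ln, call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    if (!indented && val == "") {
      current <- key
      vals[[current]] <- list()
    } else if (indented) {
      if (is.null(current)) stop("indented entry without a parent key: ", ln, call. = FALSE)
      vals[[current]][[key]] <- as.numeric(val)
    } else {
      current <- NULL
      num <- suppressWarnings(as.numeric(val))
      vals[[key]] <- if (is.na(num)) val else num
    }
  }
  known <- names(formals(qc_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(qc_config, vals)
}
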