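# Paradata bundle: the five input streams (audit events, call detail records,
# interviewer time logs, case records, question catalog) plus study metadata.
# Canonical dialect: UTF-8 CSV, quoted fields, mandatory header, ISO-8601
# timestamps with explicit UTC offset.  All intervals half-open [start, end).

AUDIT_KINDS   <- c("ENTER", "EXIT", "KEYSTROKE", "VALUE_SET")
ACTIVITIES    <- c("CALLING", "SHIFT_PREP", "TECH_SUPPORT", "BREAK")
DISPOSITIONS  <- c("COMPLETE", "PARTIAL", "REFUSAL", "NONCONTACT", "OTHER")
VERSIONS      <- c("LONG", "SHORT")

BUNDLE_FILES <- c(audit_events = "audit_events.csv",
                  call_records = "call_records.csv",
                  time_logs    = "time_logs.csv",
                  case_records = "case_records.csv",
                  catalog      = "catalog.csv")

empty_audit_events <- function() {
  data.table(event_id = character(), case_id = character(),
             interviewer_id = character(), session_id = character(),
             question_id = character(), kind = character(),
             timestamp = as.POSIXct(character(), tz = "UTC"),
             value = character())
}

empty_call_records <- function() {
  data.table(call_id = character(), interviewer_id = character(),
             case_id = character(),
             start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"),
             monitored_intervals = character())
}

empty_time_logs <- function() {
  data.table(interviewer_id = character(), activity = character(),
             start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"))
}

empty_case_records <- function() {
  data.table(case_id = character(), interviewer_id = character(),
             version = character(),
             call_start = as.POSIXct(character(), tz = "UTC"),
             call_end = as.POSIXct(character(), tz = "UTC"),
             disposition = character(), respondent_gender = character(),
             stem_answers = character(), any_disorder = logical(),
             attempt_number = integer())
}

empty_catalog <- function() {
  data.table(question_id = character(), module = character(),
             is_stem = logical(), baseline_read_seconds = numeric(),
             exclude_from_short_flag = logical())
}

#' Assemble a paradata bundle
#'
#' @param audit_events,call_records,time_logs,case_records,catalog data.tables
#'   in the canonical column layouts (see the stream constructors in
#'   `empty_*()`; any of them may be empty).
#' @param study_start_date `Date`; anchors the tumbling two-week windows.
#' @param provenance free-form character note stored in `bundle_meta.json`.
#' @param strict if `TRUE` (default) any invariant violation is an error; if
#'   `FALSE` offending rows are dropped and counted in the load report
#'   attached as attribute `"load_report"`.
#' @return an object of class `paradata_bundle`
#' @export
paradata_bundle <- function(audit_events = empty_audit_events(),
                            call_records = empty_call_records(),
                            time_logs = empty_time_logs(),
                            case_records = empty_case_records(),
                            catalog = empty_catalog(),
                            study_start_date,
                            provenance = "",
                            strict = TRUE) {
  b <- structure(list(audit_events = as.data.table(audit_events),
                      call_records = as.data.table(call_records),
                      time_logs = as.data.table(time_logs),
                      case_records = as.data.table(case_records),
                      catalog = as.data.table(catalog),
                      study_start_date = as.Date(study_start_date),
                      provenance = provenance),
                 class = "paradata_bundle")
  validate_bundle(b, strict = strict)
}

#' @export
print.paradata_bundle <- function(x, ...) {
  cat("<paradata_bundle> study start", format(x$study_start_date), "\n")
  for (nm in names(BUNDLE_FILES))
    cat(sprintf("  %-13s %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

# Apply all stream invariants.  strict: stop at the first violation with the
# offending stream and row numbers.  lenient: drop bad rows, record counts.
validate_bundle <- function(b, strict = TRUE) {
  report <- list()
  drop_or_die <- function(dt, bad, stream, why) {
    bad[is.na(bad)] <- TRUE
    if (any(bad) && strict)
      abort_row(sprintf("%s: %s (first at row %d of %d bad rows)",
                        stream, why, which(bad)[1], sum(bad)))
    dt[!bad]
  }

  # catalog first: duplicates are fatal in either mode (downstream joins
  # would silently multiply rows)
  cat_dt <- b$catalog
  if (anyDuplicated(cat_dt$question_id))
    stop("catalog: duplicate question_id '",
         cat_dt$question_id[duplicated(cat_dt$question_id)][1], "'", call. = FALSE)
  cat_dt <- drop_or_die(cat_dt, !is.finite(cat_dt$baseline_read_seconds) |
                          cat_dt$baseline_read_seconds < 0,
                        "catalog", "baseline_read_seconds must be >= 0")

  ae <- b$audit_events
  n0 <- nrow(ae)
  ae <- drop_or_die(ae, is.na(ae$timestamp), "audit_events", "unparseable timestamp")
  ae <- drop_or_die(ae, !(ae$kind %in% AUDIT_KINDS), "audit_events", "unknown kind")
  ae <- drop_or_die(ae, ae$kind == "VALUE_SET" & (is.na(ae$value) | ae$value == ""),
                    "audit_events", "VALUE_SET without a value")
  ae <- drop_or_die(ae, ae$kind %in% c("ENTER", "EXIT") & !is.na(ae$value) & ae$value != "",
                    "audit_events", "ENTER/EXIT must not carry a value")
  report$audit_events <- c(n0, nrow(ae))

  cr <- b$call_records
  n0 <- nrow(cr)
  cr <- drop_or_die(cr, is.na(cr$start) | is.na(cr$end), "call_records",
                    "unparseable timestamp")
  cr <- drop_or_die(cr, cr$end < cr$start, "call_records", "end < start")
  if (nrow(cr)) {
    mi <- parse_monitored_intervals(cr)
    if (nrow(mi)) {
      bad_calls <- mi[is.na(m_start) | is.na(m_end) | m_end < m_start |
                        m_start < start | m_end > end, unique(call_id)]
      cr <- drop_or_die(cr, cr$call_id %in% bad_calls, "call_records",
                        "monitored interval outside [start,end) or malformed")
    }
  }
  report$call_records <- c(n0, nrow(cr))

  tl <- b$time_logs
  n0 <- nrow(tl)
  tl <- drop_or_die(tl, is.na(tl$start) | is.na(tl$end), "time_logs",
                    "unparseable timestamp")
  tl <- drop_or_die(tl, tl$end < tl$start, "time_logs", "end < start")
  tl <- drop_or_die(tl, !(tl$activity %in% ACTIVITIES), "time_logs", "unknown activity")
  if (nrow(tl) > 1L) {
    setorder(tl, interviewer_id, start, end)
    prev_end <- tl[, shift(cummax(as.numeric(end))), by = interviewer_id]$V1
    overlap <- !is.na(prev_end) & as.numeric(tl$start) < prev_end
    tl <- drop_or_die(tl, overlap, "time_logs",
                      "overlapping entries for one interviewer")
  }
  report$time_logs <- c(n0, nrow(tl))

  cs <- b$case_records
  n0 <- nrow(cs)
  cs <- drop_or_die(cs, is.na(cs$call_start) | is.na(cs$call_end), "case_records",
                    "unparseable timestamp")
  cs <- drop_or_die(cs, cs$call_end < cs$call_start, "case_records", "end < start")
  cs <- drop_or_die(cs, !(cs$disposition %in% DISPOSITIONS), "case_records",
                    "unknown disposition")
  cs <- drop_or_die(cs, !(cs$version %in% VERSIONS), "case_records", "unknown version")
  cs <- drop_or_die(cs, cs$disposition == "COMPLETE" & is.na(cs$any_disorder),
                    "case_records", "COMPLETE case with null any_disorder")
  cs <- drop_or_die(cs, !is.finite(cs$attempt_number) | cs$attempt_number < 1,
                    "case_records", "attempt_number must be a positive integer")
  if (nrow(cs)) {
    sa <- parse_stem_answers(cs)
    if (nrow(sa)) {
      stems <- cat_dt[is_stem == TRUE, question_id]
      bad_cases <- sa[!(question_id %in% stems) |
                        !(answer %in% c("POSITIVE", "NEGATIVE", "MISSING")),
                      unique(case_id)]
      cs <- drop_or_die(cs, cs$case_id %in% bad_cases, "case_records",
                        "stem_answers key not a catalog stem question")
    }
  }
  report$case_records <- c(n0, nrow(cs))
  report$catalog <- c(nrow(b$catalog), nrow(cat_dt))

  b$audit_events <- ae; b$call_records <- cr; b$time_logs <- tl
  b$case_records <- cs; b$catalog <- cat_dt
  lr <- data.table(stream = names(report),
                   rows_in = vapply(report, `[`, 0, 1L),
                   rows_loaded = vapply(report, `[`, 0, 2L))
  lr[, rows_dropped := rows_in - rows_loaded]
  setattr(b, "load_report", lr[])
  b
}

#' Expand the serialized monitored intervals of call records
#'
#' @param call_records canonical call-record table; `monitored_intervals` holds
#'   semicolon-separated `"start|end"` ISO-8601 pairs (empty string for none).
#' @return data.table with one row per monitored interval: `call_id`,
#'   `case_id`, `interviewer_id`, `start`, `end` (of the call), `m_start`,
#'   `m_end`
#' @export
parse_monitored_intervals <- function(call_records) {
  cr <- call_records[!is.na(monitored_intervals) & monitored_intervals != ""]
  if (nrow(cr) == 0L)
    return(data.table(call_id = character(), case_id = character(),
                      interviewer_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      m_start = as.POSIXct(character(), tz = "UTC"),
                      m_end = as.POSIXct(character(), tz = "UTC")))
  pieces <- strsplit(cr$monitored_intervals, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(cr)), lengths(pieces))
  flat <- unlist(pieces)
  se <- strsplit(flat, "|", fixed = TRUE)
  out <- cr[idx, .(call_id, case_id, interviewer_id, start, end)]
  out[, m_start := parse_ts(vapply(se, `[`, "", 1L))]
  out[, m_end := parse_ts(vapply(se, function(x) x[2] %||% NA_character_, ""))]
  out[]
}

#' Expand the serialized stem answers of case records
#'
#' @param case_records canonical case-record table; `stem_answers` holds
#'   semicolon-separated `"question_id=POSITIVE|NEGATIVE|MISSING"` pairs.
#' @return data.table `case_id`, `question_id`, `answer`
#' @export
parse_stem_answers <- function(case_records) {
  cs <- case_records[!is.na(stem_answers) & stem_answers != ""]
  if (nrow(cs) == 0L)
    return(data.table(case_id = character(), question_id = character(),
                      answer = character()))
  pieces <- strsplit(cs$stem_answers, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(cs)), lengths(pieces))
  flat <- unlist(pieces)
  eq <- regmatches(flat, regexec("^([^=]+)=(.*)$", flat))
  data.table(case_id = cs$case_id[idx],
             question_id = vapply(eq, function(m) if (length(m)) m[2] else NA_character_, ""),
             answer = vapply(eq, function(m) if (length(m)) m[3] else NA_character_, ""))
}

# Serialize helpers (inverse of the parsers); used by the simulator and writer.
serialize_intervals <- function(m_start, m_end) {
  if (length(m_start) == 0L) return("")
  paste(paste(format_ts(m_start), format_ts(m_end), sep = "|"), collapse = ";")
}

#' Read a paradata bundle from a directory
#'
#' The directory must contain the five canonical files
#' (`audit_events.csv`, `call_records.csv`, `time_logs.csv`,
#' `case_records.csv`, `catalog.csv`) and `bundle_meta.json`.
#'
#' @param dir directory path
#' @param strict abort on any invariant violation (`TRUE`) or drop offending
#'   rows and count them in the attached `"load_report"` attribute (`FALSE`)
#' @return a `paradata_bundle`
#' @export
read_bundle <- function(dir, strict = TRUE) {
  for (f in c(BUNDLE_FILES, "bundle_meta.json"))
    if (!file.exists(file.path(dir, f)))
      stop("missing bundle file: ", f, call. = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "bundle_meta.json"))

  ae <- qc_fread(file.path(dir, "audit_events.csv"),
                 colClasses = list(character = c("event_id", "case_id",
                   "interviewer_id", "session_id", "question_id", "kind",
                   "timestamp", "value")))
  ae[, timestamp := parse_ts(timestamp)]
  if (nrow(ae) == 0L) ae <- empty_audit_events()

  cr <- qc_fread(file.path(dir, "call_records.csv"),
                 colClasses = list(character = c("call_id", "interviewer_id",
                   "case_id", "start", "end", "monitored_intervals")))
  cr[, `:=`(start = parse_ts(start), end = parse_ts(end))]
  cr[is.na(monitored_intervals), monitored_intervals := ""]
  if (nrow(cr) == 0L) cr <- empty_call_records()

  tl <- qc_fread(file.path(dir, "time_logs.csv"),
                 colClasses = list(character = c("interviewer_id", "activity",
                                                 "start", "end")))
  tl[, `:=`(start = parse_ts(start), end = parse_ts(end))]
  if (nrow(tl) == 0L) tl <- empty_time_logs()

  cs <- qc_fread(file.path(dir, "case_records.csv"),
                 colClasses = list(character = c("case_id", "interviewer_id",
                   "version", "call_start", "call_end", "disposition",
                   "respondent_gender", "stem_answers", "any_disorder"),
                   integer = "attempt_number"))
  cs[, `:=`(call_start = parse_ts(call_start), call_end = parse_ts(call_end))]
  cs[, any_disorder := as.logical(any_disorder)]
  cs[is.na(stem_answers), stem_answers := ""]
  if (nrow(cs) == 0L) cs <- empty_case_records()

  ct <- qc_fread(file.path(dir, "catalog.csv"),
                 colClasses = list(character = c("question_id", "module"),
                                   logical = c("is_stem", "exclude_from_short_flag"),
                                   numeric = "baseline_read_seconds"))
  if (nrow(ct) == 0L) ct <- empty_catalog()

  paradata_bundle(ae, cr, tl, cs, ct,
                  study_start_date = as.Date(meta$study_start_date),
                  provenance = meta$provenance %||% "",
                  strict = strict)
}

#' Write a paradata bundle to a directory
#'
#' Row order is canonical (primary timestamp, then id) so two writes of the
#' same bundle are byte-identical.
#'
#' @param bundle a `paradata_bundle`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "paradata_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  ae <- copy(bundle$audit_events); setorder(ae, timestamp, event_id)
  ae[, timestamp := format_ts(timestamp)]
  qc_fwrite(ae, file.path(dir, "audit_events.csv"))

  cr <- copy(bundle$call_records); setorder(cr, start, call_id)
  cr[, `:=`(start = format_ts(start), end = format_ts(end))]
  qc_fwrite(cr, file.path(dir, "call_records.csv"))

  tl <- copy(bundle$time_logs); setorder(tl, start, interviewer_id, activity)
  tl[, `:=`(start = format_ts(start), end = format_ts(end))]
  qc_fwrite(tl, file.path(dir, "time_logs.csv"))

  cs <- copy(bundle$case_records); setorder(cs, call_start, case_id)
  cs[, `:=`(call_start = format_ts(call_start), call_end = format_ts(call_end))]
  qc_fwrite(cs, file.path(dir, "case_records.csv"))

  ct <- copy(bundle$catalog); setorder(ct, question_id)
  qc_fwrite(ct, file.path(dir, "catalog.csv"))

  jsonlite::write_json(list(study_start_date = format(bundle$study_start_date),
                            provenance = bundle$provenance),
                       file.path(dir, "bundle_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Check a question catalog for issues
#'
#' Reports (without mutating the input): duplicated question ids, negative
#' baselines, stem questions marked excluded, and entries whose baseline read
#' time is under the short-question cutoff but are not excluded from the
#' short-time flag (the fielded procedure excluded questions that take under 3
#' seconds by design).
#'
#' @param catalog catalog table
#' @param short_question_seconds the short-question cutoff used for the
#'   should-exclude suggestion
#' @return data.table of issues: `question_id`, `issue`, `detail`
#' @export
validate_catalog <- function(catalog, short_question_seconds = 3) {
  issues <- list()
  dup <- unique(catalog$question_id[duplicated(catalog$question_id)])
  if (length(dup))
    issues$dup <- data.table(question_id = dup, issue = "duplicate",
                             detail = "question_id appears more than once")
  neg <- catalog[baseline_read_seconds < 0]
  if (nrow(neg))
    issues$neg <- data.table(question_id = neg$question_id, issue = "negative_baseline",
                             detail = sprintf("baseline %.3f s", neg$baseline_read_seconds))
  se <- catalog[is_stem == TRUE & exclude_from_short_flag == TRUE]
  if (nrow(se))
    issues$se <- data.table(question_id = se$question_id, issue = "stem_excluded",
                            detail = "stem question marked excluded from short flag")
  sugg <- catalog[baseline_read_seconds >= 0 &
                    baseline_read_seconds < short_question_seconds &
                    exclude_from_short_flag == FALSE]
  if (nrow(sugg))
    issues$sugg <- data.table(question_id = sugg$question_id, issue = "should_exclude",
                              detail = sprintf("baseline %.3f s is under the %.3g s cutoff",
                                               sugg$baseline_read_seconds,
                                               short_question_seconds))
  if (length(issues)) rbindlist(issues) else
    data.table(question_id = character(), issue = character(), detail = character())
}
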