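library(data.table)

TS0 <- as.POSIXct("2021-01-20 09:00:00", tz = "UTC")

ts <- function(sec) TS0 + sec

# quick audit-event builder: ev(5, "ENTER", "q1") at TS0+5s
mk_events <- function(kind, question, sec, case = "C1", iv = "I01", value = NA_character_) {
  n <- length(kind)
  data.table(event_id = sprintf("%s-E%03d", case, seq_len(n)), case_id = case,
             interviewer_id = iv, session_id = paste0(case, "-S1"),
             question_id = question, kind = kind, timestamp = ts(sec),
             value = fifelse(kind == "VALUE_SET",
                             fifelse(is.na(value), "1", value), NA_character_))
}

# a simple enter/exit pair per question with given durations and gaps
mk_interview <- function(questions, durations, gaps = 0, case = "C1", iv = "I01",
                         start = 0) {
  gaps <- rep_len(gaps, length(questions))
  enters <- start + cumsum(c(0, head(durations + gaps, -1)))
  exits <- enters + durations
  rbind(mk_events(rep("ENTER", length(questions)), questions, enters, case, iv),
        mk_events(rep("EXIT", length(questions)), questions, exits, case, iv))
}

mk_catalog <- function(qids, module = "health", is_stem = FALSE, baseline = 8,
                       exclude = FALSE) {
  data.table(question_id = qids, module = rep_len(module, length(qids)),
             is_stem = rep_len(is_stem, length(qids)),
             baseline_read_seconds = rep_len(baseline, length(qids)),
             exclude_from_short_flag = rep_len(exclude, length(qids)))
}

mk_case <- function(case = "C1", iv = "I01", disposition = "COMPLETE",
                    version = "LONG", start_sec = 0, end_sec = 3600,
                    stem_answers = "", any_disorder = FALSE, attempt = 1L) {
  out <- data.table(case_id = case, interviewer_id = iv, version = version,
                    call_start = ts(start_sec), call_end = ts(end_sec),
                    disposition = disposition, respondent_gender = "FEMALE",
                    stem_answers = stem_answers, any_disorder = any_disorder,
                    attempt_number = attempt)
  out[disposition != "COMPLETE", any_disorder := NA]
  out[]
}

small_sim <- function(seed = 7, n_interviewers = 4, n_days = 6, ...) {
  sim_config(n_interviewers = n_interviewers, n_days = n_days,
             dials_per_day = 8, seed = seed, ...)
}

# ---- independent oracles (naive implementations, deliberately loop-based) ----

# single-open-visit reconstruction, written as an explicit event walk
oracle_visits <- function(events) {
  ev <- as.data.frame(events)
  prio <- c(EXIT = 0, KEYSTROKE = 1, VALUE_SET = 1, ENTER = 2)
  ev <- ev[order(ev$case_id, ev$timestamp, prio[ev$kind], ev$event_id), ]
  out <- list(); orphans <- 0L
  for (cid in unique(ev$case_id)) {
    e <- ev[ev$case_id == cid, ]
    open <- NULL
    vis <- list()
    for (i in seq_len(nrow(e))) {
      k <- e$kind[i]; q <- e$question_id[i]; t <- e$timestamp[i]
      if (k == "ENTER") {
        if (!is.null(open)) {
          open$exit <- t; open$synthetic <- TRUE; vis[[length(vis) + 1L]] <- open
        }
        open <- list(q = q, enter = t, changed = FALSE)
      } else if (k == "EXIT") {
        if (!is.null(open) && open$q == q) {
          open$exit <- t; open$synthetic <- FALSE
          vis[[length(vis) + 1L]] <- open; open <- NULL
        } else orphans <- orphans + 1L
      } else if (k == "VALUE_SET") {
        if (!is.null(open) && open$q == q) open$changed <- TRUE
      }
    }
    if (!is.null(open)) {
      open$exit <- max(e$timestamp); open$synthetic <- TRUE
      vis[[length(vis) + 1L]] <- open
    }
    if (length(vis))
      out[[cid]] <- data.frame(case_id = cid,
                               question_id = vapply(vis, `[[`, "", "q"),
                               enter = do.call(c, lapply(vis, `[[`, "enter")),
                               exit = do.call(c, lapply(vis, `[[`, "exit")),
                               value_changed = vapply(vis, `[[`, TRUE, "changed"),
                               synthetic_exit = vapply(vis, `[[`, TRUE, "synthetic"))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(case_id = character(), question_id = character())
  attr(res, "orphans") <- orphans
  res
}

# union length of [s, e) intervals by naive pairwise sweep
oracle_union_seconds <- function(s, e) {
  s <- as.numeric(s); e <- as.numeric(e)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(0)
  o <- order(s)
  s <- s[o]; e <- e[o]
  total <- 0; cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > ce) { total <- total + (ce - cs); cs <- s[i]; ce <- e[i] }
    else ce <- max(ce, e[i])
  }
  total + (ce - cs)
}

# random event log over n questions, intentionally messy (orphans, lost exits)
random_event_log <- function(n_events, n_questions = 10, case = "C1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kinds <- sample(c("ENTER", "EXIT", "VALUE_SET"), n_events, replace = TRUE,
                  prob = c(0.4, 0.35, 0.25))
  mk_events(kinds, sprintf("q%02d", sample.int(n_questions, n_events, replace = TRUE)),
            sort(runif(n_events, 0, 3600)), case = case)
}
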