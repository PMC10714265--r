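# Synthetic paradata simulator.  Generates mutually consistent audit events,
# call records, time logs and case records for a roster of interviewers with
# configurable behavioral archetypes, so every flag and metric has positive
# and negative instances without any real data.
#
# Determinism: the question catalog and calibration constants come from a
# stream seeded by (seed, "catalog"); each interviewer's paradata comes from a
# stream seeded by (seed, interviewer_id).  Re-generating one interviewer
# (inject_archetype) therefore leaves everyone else's rows bit-identical.

ARCHETYPES <- c("COMPLIANT", "SPEEDER", "FABRICATOR", "REVISITER", "SLOWPOKE")

#' Describe an interviewer archetype
#'
#' @param name one of COMPLIANT, SPEEDER, FABRICATOR, REVISITER, SLOWPOKE
#' @param question_time_scale multiplier on question read time (SPEEDER 0.3:
#'   the rapid reader; SLOWPOKE 1.8)
#' @param answer_time_scale multiplier on the respondent-answer portion of a
#'   visit; 0 models an interviewer who records the option while still talking
#'   (the SPEEDER default)
#' @param stem_positive_prob_scale multiplier on the per-stem positive
#'   probability (FABRICATOR 0.1: steers answers negative to shorten the
#'   interview)
#' @param extra_revisit_prob probability a question gets a second visit
#'   (REVISITER 0.4)
#' @param pause_rate_per_interview expected within-question long pauses per
#'   interview
#' @param overreport_hours extra CALLING hours logged per day beyond actual
#'   activity (exercises the reported-time discrepancy metric)
#' @return an `archetype_config` list
#' @export
archetype_config <- function(name = "COMPLIANT",
                             question_time_scale = NULL,
                             answer_time_scale = NULL,
                             stem_positive_prob_scale = NULL,
                             extra_revisit_prob = NULL,
                             pause_rate_per_interview = NULL,
                             overreport_hours = NULL) {
  name <- match.arg(name, ARCHETYPES)
  def <- switch(name,
    COMPLIANT  = list(1.0, 1.0, 1.0, 0.08, 0.25, 0),
    SPEEDER    = list(0.3, 0.0, 1.0, 0.08, 0.10, 0),
    FABRICATOR = list(1.0, 1.0, 0.1, 0.08, 0.15, 0),
    REVISITER  = list(1.0, 1.0, 1.0, 0.40, 0.25, 0),
    SLOWPOKE   = list(1.8, 1.8, 1.0, 0.08, 0.30, 0))
  a <- list(name = name,
            question_time_scale = question_time_scale %||% def[[1]],
            answer_time_scale = answer_time_scale %||% def[[2]],
            stem_positive_prob_scale = stem_positive_prob_scale %||% def[[3]],
            extra_revisit_prob = extra_revisit_prob %||% def[[4]],
            pause_rate_per_interview = pause_rate_per_interview %||% def[[5]],
            overreport_hours = overreport_hours %||% def[[6]])
  if (a$question_time_scale <= 0) stop("question_time_scale must be > 0", call. = FALSE)
  if (a$answer_time_scale < 0) stop("answer_time_scale must be >= 0", call. = FALSE)
  for (f in c("stem_positive_prob_scale", "extra_revisit_prob"))
    if (a[[f]] < 0 || (f == "extra_revisit_prob" && a[[f]] > 1))
      stop(f, " out of range", call. = FALSE)
  if (a$overreport_hours < 0) stop("overreport_hours must be >= 0", call. = FALSE)
  structure(a, class = "archetype_config")
}

#' Build a simulation configuration
#'
#' Defaults state the emulated fielding conditions: two six-hour daily shifts,
#' 94 / 64 minute mean adjusted lengths for the long / short instrument, and a
#' per-stem positive probability calibrated so completed-case disorder
#' prevalence has cross-interviewer mean near 0.43 and SD near 0.11.
#'
#' @param n_interviewers roster size (default 20)
#' @param n_days fielding days (default 30)
#' @param study_start_date first fielding day (default `"2021-01-20"`)
#' @param shifts list of two `c(start_hour, end_hour)` daily blocks (UTC)
#' @param archetypes named list / character vector mapping interviewer ids
#'   (`"I01"`, ...) to archetype names or `archetype_config`s; unnamed
#'   interviewers are COMPLIANT
#' @param version_mix probability a case gets the LONG instrument
#' @param mean_interview_minutes named list of target mean adjusted lengths
#' @param n_questions,stem_share catalog size and share of stem questions
#' @param target_prevalence calibration target for completed-case disorder
#'   prevalence
#' @param interviewer_sd_log SD (log scale) of the per-interviewer disorder
#'   propensity multiplier; drives between-interviewer prevalence spread
#' @param disposition_probs dial outcome probabilities (complete, partial,
#'   refusal, noncontact, other)
#' @param dials_per_day expected dials per interviewer-day
#' @param monitoring_rate probability a long call carries a monitoring session
#' @param seed integer master seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_interviewers = 20, n_days = 30,
                       study_start_date = "2021-01-20",
                       shifts = list(c(9, 15), c(15, 21)),
                       archetypes = NULL,
                       version_mix = 0.5,
                       mean_interview_minutes = list(LONG = 94, SHORT = 64),
                       n_questions = 120, stem_share = 0.10,
                       target_prevalence = 0.43,
                       interviewer_sd_log = 0.20,
                       disposition_probs = c(COMPLETE = 0.08, PARTIAL = 0.05,
                                             REFUSAL = 0.12, NONCONTACT = 0.70,
                                             OTHER = 0.05),
                       dials_per_day = 15,
                       monitoring_rate = 0.08,
                       seed = 1L) {
  stopifnot(n_interviewers >= 0, n_days >= 0, version_mix >= 0, version_mix <= 1,
            n_questions >= 10, stem_share > 0, stem_share < 1,
            abs(sum(disposition_probs) - 1) < 1e-8,
            all(disposition_probs >= 0))
  ids <- sprintf("I%02d", seq_len(n_interviewers))
  amap <- setNames(rep("COMPLIANT", n_interviewers), ids)
  if (!is.null(archetypes)) {
    nm <- names(archetypes)
    if (is.null(nm) || any(nm == "")) stop("archetypes must be named by interviewer id", call. = FALSE)
    bad <- setdiff(nm, ids)
    if (length(bad)) stop("unknown interviewer in archetypes: ", bad[1], call. = FALSE)
    for (k in nm) amap[[k]] <- if (inherits(archetypes[[k]], "archetype_config"))
      archetypes[[k]]$name else match.arg(archetypes[[k]], ARCHETYPES)
  }
  structure(list(n_interviewers = n_interviewers, n_days = n_days,
                 study_start_date = as.Date(study_start_date), shifts = shifts,
                 archetypes = as.list(amap),
                 archetype_overrides = Filter(function(x) inherits(x, "archetype_config"),
                                              as.list(archetypes %||% list())),
                 version_mix = version_mix,
                 mean_interview_minutes = lapply(mean_interview_minutes, as.numeric),
                 n_questions = n_questions, stem_share = stem_share,
                 target_prevalence = target_prevalence,
                 interviewer_sd_log = interviewer_sd_log,
                 disposition_probs = disposition_probs,
                 dials_per_day = dials_per_day,
                 monitoring_rate = monitoring_rate,
                 seed = as.integer(seed),
                 read_sdlog = 0.4, answer_sdlog = 0.5,
                 gap_rate = 0.15),
            class = "sim_config")
}

interviewer_archetype <- function(sim, id) {
  ov <- sim$archetype_overrides[[id]]
  if (!is.null(ov)) ov else archetype_config(sim$archetypes[[id]] %||% "COMPLIANT")
}

# Deterministic catalog + calibration constants shared by all interviewers.
sim_context <- function(sim) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(sim$seed, "catalog"))

  nq <- sim$n_questions
  n_stem <- max(1L, round(sim$stem_share * nq))
  n_intro <- max(3L, round(0.05 * nq))
  n_treat <- max(3L, round(0.06 * nq))
  mods_mid <- c("depression", "worry_anxiety", "stressful_experiences", "health", "covid")
  mid_n <- nq - n_intro - n_treat
  module <- c(rep("intro", n_intro),
              rep(mods_mid, length.out = mid_n)[order(rep(seq_along(mods_mid),
                                                          length.out = mid_n))],
              rep("treatment", n_treat))
  question_id <- sprintf("Q%03d", seq_len(nq))
  # stems live in the diagnostic modules
  stem_pool <- which(module %in% c("depression", "worry_anxiety",
                                   "stressful_experiences"))
  is_stem <- rep(FALSE, nq)
  is_stem[sort(sample(stem_pool, min(n_stem, length(stem_pool))))] <- TRUE
  baseline <- rgamma(nq, shape = 16, rate = 2)          # mean 8 s reads
  short_q <- !is_stem & runif(nq) < 0.08                # sub-3 s by design
  baseline[short_q] <- runif(sum(short_q), 1.2, 2.5)
  catalog <- data.table(question_id = question_id, module = module,
                        is_stem = is_stem,
                        baseline_read_seconds = round(baseline, 3),
                        exclude_from_short_flag = baseline < 3)

  # short-version question set: stems, intro, treatment, plus leading nonstems
  # until the baseline mass reaches the short/long length ratio
  rf <- exp(sim$read_sdlog^2 / 2); af <- exp(sim$answer_sdlog^2 / 2)
  target_long <- sim$mean_interview_minutes$LONG * 60 - 120   # pauses budget
  S_long <- sum(catalog$baseline_read_seconds)
  base_rv <- 0.08  # compliant revisit probability, 0.3x duration
  # target = S*rf*(1 + rv*0.3) + r*S*af  =>  answer/read ratio r
  r_ans <- (target_long - S_long * rf * (1 + base_rv * 0.3)) / (S_long * af)
  if (r_ans <= 0) stop("infeasible config: interview target shorter than read time",
                       call. = FALSE)
  target_short <- sim$mean_interview_minutes$SHORT * 60 - 120
  S_short <- target_short / (rf * (1 + base_rv * 0.3) + r_ans * af)
  core <- which(catalog$is_stem | catalog$module %in% c("intro", "treatment"))
  extra <- setdiff(seq_len(nq), core)
  csum <- sum(catalog$baseline_read_seconds[core]) +
    cumsum(catalog$baseline_read_seconds[extra])
  take <- extra[seq_len(max(0L, findInterval(S_short, csum)))]
  short_set <- sort(c(core, take))

  n_stems_admin <- sum(catalog$is_stem)
  p_stem <- 1 - (1 - sim$target_prevalence)^(1 / n_stems_admin)

  shift_len_h <- vapply(sim$shifts, function(s) s[2] - s[1], 0)
  if (max(unlist(sim$mean_interview_minutes)) / 60 > min(shift_len_h) - 0.75)
    stop("infeasible config: interviews longer than a working shift", call. = FALSE)

  list(catalog = catalog, r_ans = r_ans, short_set = short_set, p_stem = p_stem)
}

# Generate every stream for one interviewer.  Returns a list of data.tables.
gen_interviewer <- function(sim, ctx, id, day_dates, shift_hours) {
  arch <- interviewer_archetype(sim, id)
  set.seed(derive_seed(sim$seed, id))
  prop <- exp(rnorm(1, 0, sim$interviewer_sd_log))
  p_pos <- min(1, ctx$p_stem * prop * arch$stem_positive_prob_scale)

  n_days <- length(day_dates)
  empty <- list(audit = empty_audit_events(), calls = empty_call_records(),
                logs = empty_time_logs(), cases = empty_case_records())
  if (n_days == 0L) return(empty)

  day_start <- as.POSIXct(paste0(format(day_dates), " 00:00:00"), tz = "UTC")
  s0 <- day_start + shift_hours[1] * 3600
  s1 <- day_start + shift_hours[2] * 3600
  # daily activity blocks: prep, main calling block, break, wrap-up calling
  logs <- rbind(
    data.table(interviewer_id = id, activity = "SHIFT_PREP", start = s0, end = s0 + 900),
    data.table(interviewer_id = id, activity = "CALLING", start = s0 + 900, end = s1 - 1800),
    data.table(interviewer_id = id, activity = "BREAK", start = s1 - 1800, end = s1 - 600),
    data.table(interviewer_id = id, activity = "CALLING", start = s1 - 600, end = s1))
  if (arch$overreport_hours > 0)
    logs <- rbind(logs, data.table(interviewer_id = id, activity = "CALLING",
                                   start = s1, end = s1 + arch$overreport_hours * 3600))
  setorder(logs, start, activity)

  n_dials <- rpois(n_days, sim$dials_per_day)
  N <- sum(n_dials)
  if (N == 0L) { empty$logs <- logs; return(empty) }
  dials <- data.table(day_idx = rep(seq_len(n_days), n_dials))
  dials[, dial_idx := seq_len(.N), by = day_idx]
  dials[, case_id := sprintf("%s-D%02d-%02d", id, day_idx, dial_idx)]
  dials[, disposition := sample(names(sim$disposition_probs), .N, replace = TRUE,
                                prob = sim$disposition_probs)]
  dials[, version := fifelse(runif(.N) < sim$version_mix, "LONG", "SHORT")]
  dials[, attempt_number := sample(1:3, .N, replace = TRUE, prob = c(0.7, 0.2, 0.1))]
  dials[, gender := sample(c("FEMALE", "MALE"), .N, replace = TRUE)]

  # ---- assemble interviews (completes and partials) at question level ----
  iv <- dials[disposition %in% c("COMPLETE", "PARTIAL")]
  visits <- NULL
  if (nrow(iv)) {
    iv[, n_avail := fifelse(version == "LONG", sim$n_questions,
                            length(ctx$short_set))]
    iv[, n_q := fifelse(disposition == "COMPLETE", n_avail,
                        pmax(2L, as.integer(ceiling(runif(.N, 0.1, 0.6) * n_avail))))]
    visits <- iv[rep(seq_len(.N), n_q),
                 .(case_id, version, disposition, day_idx)]
    visits[, qpos := sequence(iv$n_q)]
    long_set <- seq_len(sim$n_questions)
    visits[, qrow := fifelse(version == "LONG", long_set[qpos],
                             ctx$short_set[qpos])]
    visits[, question_id := ctx$catalog$question_id[qrow]]
    visits[, baseline := ctx$catalog$baseline_read_seconds[qrow]]
    visits[, is_stem := ctx$catalog$is_stem[qrow]]
    nv <- nrow(visits)
    visits[, dur := rlnorm(nv, log(baseline * arch$question_time_scale),
                           sim$read_sdlog) +
             (if (arch$answer_time_scale > 0)
               rlnorm(nv, log(baseline * ctx$r_ans * arch$answer_time_scale),
                      sim$answer_sdlog) else 0)]
    visits[, value_set := TRUE]
    visits[, visit_no := 1L]

    # second visits (question revisits)
    rv <- visits[runif(nv) < arch$extra_revisit_prob]
    if (nrow(rv)) {
      rv[, dur := rlnorm(.N, log(pmax(baseline, 0.5) * 0.3), sim$read_sdlog)]
      rv[, value_set := runif(.N) < 0.3]
      rv[, visit_no := 2L]
      visits <- rbind(visits, rv)
    }
    setorder(visits, case_id, qpos, visit_no)

    # within-question long pauses (respondent breaks) inflate a visit:
    # each first visit pauses with probability pause_rate / n_questions
    visits[, pause := 0]
    p_pause <- arch$pause_rate_per_interview / mean(iv$n_q)
    psel <- which(visits$visit_no == 1L & runif(nrow(visits)) < p_pause)
    if (length(psel)) {
      visits$pause[psel] <- rlnorm(length(psel), log(300), 0.7)
      visits[, dur := dur + pause]
    }

    # occasional between-question gaps (excisable pauses); never after the
    # last visit of a case (a trailing gap is not inside the interview)
    visits[, gap_after := 0]
    p_gap <- sim$gap_rate / mean(iv$n_q)
    gsel <- which(runif(nrow(visits)) < p_gap)
    if (length(gsel)) visits$gap_after[gsel] <- rlnorm(length(gsel), log(480), 0.6)
    visits[visits[, .I[.N], by = case_id]$V1, gap_after := 0]

    visits[, offset := cumsum(shift(dur + gap_after, fill = 0)), by = case_id]
    span <- visits[, .(span = sum(dur + gap_after)), by = case_id]
    iv <- span[iv, on = "case_id"]
  }

  # ---- call durations and daily packing ----
  dials[, call_dur := fcase(disposition == "REFUSAL", runif(.N, 40, 180),
                            disposition == "NONCONTACT", runif(.N, 15, 45),
                            disposition == "OTHER", runif(.N, 30, 120),
                            default = 0)]
  if (nrow(iv)) dials[iv, on = "case_id", call_dur := i.span + 50]
  dials[, gap_before := 30 + rexp(.N, 1 / 90)]
  dials[, start_off := cumsum(shift(call_dur + gap_before, fill = 0)) + gap_before,
        by = day_idx]
  calling_start <- s0 + 900; calling_end <- s1 - 1800
  dials[, start := floor_sec(calling_start[day_idx] + start_off)]
  dials[, end := floor_sec(start + call_dur)]
  keep <- dials$end <= (calling_end[dials$day_idx] + 1800) &
    dials$start < calling_end[dials$day_idx]
  dials <- dials[keep]
  if (nrow(dials) == 0L) { empty$logs <- logs; return(empty) }

  # ---- audit events for kept interview cases ----
  audit <- empty_audit_events()
  kept_iv <- if (!is.null(visits)) visits[case_id %in% dials$case_id] else NULL
  if (!is.null(kept_iv) && nrow(kept_iv)) {
    kept_iv[dials, on = "case_id", call_start := i.start]
    kept_iv[, enter_raw := as.numeric(call_start) + 30 + offset]
    kept_iv[, enter := floor_sec(enter_raw)]
    kept_iv[, exit := floor_sec(enter_raw + dur)]
    kept_iv[, vs_time := floor_sec(enter_raw + 0.8 * dur)]
    kept_iv[, vrow := seq_len(.N), by = case_id]
    ae <- rbind(
      kept_iv[, .(case_id, question_id, kind = "ENTER", timestamp = enter, vrow,
                  sub = 1L, value = NA_character_)],
      kept_iv[value_set == TRUE,
              .(case_id, question_id, kind = "VALUE_SET", timestamp = vs_time, vrow,
                sub = 2L, value = "1")],
      kept_iv[, .(case_id, question_id, kind = "EXIT", timestamp = exit, vrow,
                  sub = 3L, value = NA_character_)])
    setorder(ae, case_id, vrow, sub)
    ae[, event_id := sprintf("%s-E%04d", case_id, seq_len(.N)), by = case_id]
    ae[, `:=`(interviewer_id = id, session_id = paste0(case_id, "-S1"),
              vrow = NULL, sub = NULL)]
    setcolorder(ae, names(empty_audit_events()))
    audit <- ae
  }

  # dial end for interview cases must cover the audit span
  if (!is.null(kept_iv) && nrow(kept_iv)) {
    sp <- kept_iv[, .(last_exit = max(exit)), by = case_id]
    dials[sp, on = "case_id", end := i.last_exit + 20]
  }

  # ---- stem answers / disorders ----
  dials[, `:=`(stem_answers = "", any_disorder = NA)]
  if (!is.null(kept_iv) && nrow(kept_iv)) {
    st <- kept_iv[visit_no == 1L & is_stem == TRUE]
    if (nrow(st)) {
      st[, ans := fifelse(runif(.N) < 0.005, "MISSING",
                          fifelse(runif(.N) < p_pos, "POSITIVE", "NEGATIVE"))]
      sa <- st[, .(stem_answers = paste(paste0(question_id, "=", ans), collapse = ";"),
                   any_pos = any(ans == "POSITIVE")), by = case_id]
      dials[sa, on = "case_id", `:=`(stem_answers = i.stem_answers,
                                     any_disorder = i.any_pos)]
    }
  }
  dials[disposition != "COMPLETE", any_disorder := NA]
  dials[disposition == "COMPLETE" & is.na(any_disorder), any_disorder := FALSE]

  # ---- monitoring sessions on longer calls ----
  dials[, monitored_intervals := ""]
  dur_act <- as.numeric(dials$end) - as.numeric(dials$start)
  long_call <- which(dur_act > 600 & runif(nrow(dials)) < sim$monitoring_rate)
  if (length(long_call)) {
    ms <- floor_sec(dials$start[long_call] + runif(length(long_call), 0, 1) *
                      (dur_act[long_call] / 3))
    me <- floor_sec(pmin(ms + runif(length(long_call), 300, 1200),
                         dials$end[long_call]))
    dials$monitored_intervals[long_call] <-
      paste(format_ts(ms), format_ts(me), sep = "|")
  }

  calls <- dials[, .(call_id = paste0(case_id, "-K"), interviewer_id = id,
                     case_id, start, end, monitored_intervals)]
  cases <- dials[, .(case_id, interviewer_id = id, version,
                     call_start = start, call_end = end, disposition,
                     respondent_gender = gender, stem_answers,
                     any_disorder, attempt_number = as.integer(attempt_number))]
  list(audit = audit, calls = calls, logs = logs, cases = cases)
}

#' Generate a complete synthetic paradata bundle
#'
#' @param sim a [sim_config()]
#' @return a validated `paradata_bundle`; the configuration is attached as
#'   attribute `"sim"` so [inject_archetype()] and [truth_table()] can use it
#' @export
generate_bundle <- function(sim) {
  stopifnot(inherits(sim, "sim_config"))
  ctx <- sim_context(sim)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  ids <- names(sim$archetypes)
  day_dates <- if (sim$n_days > 0) sim$study_start_date + 0:(sim$n_days - 1) else
    as.Date(character())
  parts <- lapply(seq_along(ids), function(i) {
    shift <- sim$shifts[[(i - 1L) %% length(sim$shifts) + 1L]]
    gen_interviewer(sim, ctx, ids[i], day_dates, shift)
  })
  b <- paradata_bundle(
    audit_events = rbindlist(c(list(empty_audit_events()), lapply(parts, `[[`, "audit"))),
    call_records = rbindlist(c(list(empty_call_records()), lapply(parts, `[[`, "calls"))),
    time_logs = rbindlist(c(list(empty_time_logs()), lapply(parts, `[[`, "logs"))),
    case_records = rbindlist(c(list(empty_case_records()), lapply(parts, `[[`, "cases"))),
    catalog = ctx$catalog,
    study_start_date = sim$study_start_date,
    provenance = sprintf("synthetic bundle, seed %d", sim$seed),
    strict = TRUE)
  setattr(b, "sim", sim)
  b
}

#' Rewrite one interviewer's paradata under a different archetype
#'
#' Only the named interviewer's rows change: every interviewer draws from an
#' independent stream seeded by (seed, id), so the rest of the bundle is
#' bit-identical.  Injecting an interviewer's current archetype is an identity
#' operation.
#'
#' @param bundle a bundle produced by [generate_bundle()]
#' @param interviewer_id an id present in the generating configuration
#' @param archetype archetype name or [archetype_config()]
#' @return a new `paradata_bundle`
#' @export
inject_archetype <- function(bundle, interviewer_id, archetype) {
  sim <- attr(bundle, "sim")
  if (is.null(sim)) stop("bundle was not produced by generate_bundle()", call. = FALSE)
  if (!interviewer_id %in% names(sim$archetypes))
    stop("unknown interviewer: ", interviewer_id, call. = FALSE)
  if (inherits(archetype, "archetype_config")) {
    sim$archetype_overrides[[interviewer_id]] <- archetype
    sim$archetypes[[interviewer_id]] <- archetype$name
  } else {
    sim$archetype_overrides[[interviewer_id]] <- NULL
    sim$archetypes[[interviewer_id]] <- match.arg(archetype, ARCHETYPES)
  }
  generate_bundle(sim)
}

#' Ground-truth archetype assignment of a simulated bundle
#'
#' @param x a `sim_config` or a bundle from [generate_bundle()]
#' @return data.table `interviewer_id`, `archetype`
#' @export
truth_table <- function(x) {
  sim <- if (inherits(x, "sim_config")) x else attr(x, "sim")
  if (is.null(sim)) stop("no simulation configuration available", call. = FALSE)
  data.table(interviewer_id = names(sim$archetypes),
             archetype = unlist(sim$archetypes))
}
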