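# build a flag table carrying given per-type counts, cycling case ids so the
# distinct-case count is controlled independently of the flag count
mk_flag_fixture <- function(counts, case_counts, level = "CASE") {
  parts <- lapply(names(counts), function(ft) {
    n <- counts[[ft]]
    cid <- sprintf("%s-C%05d", ft, rep_len(seq_len(case_counts[[ft]]), n))
    data.table(flag_type = ft, level = level,
               case_id = if (level == "CASE") cid else NA_character_,
               interviewer_id = sprintf("I%02d", rep_len(1:20, n)),
               question_id = NA_character_, window_start = as.Date(NA),
               window_end = as.Date(NA), observed_value = 1,
               threshold_value = 0, triggered_at = as.Date("2021-02-01"),
               status = "OPEN", notes = "")
  })
  catiqc:::bind_flags(do.call(rbind, parts))
}

test_that("flag summary conserves counts and computes shares both ways", {
  fl <- mk_flag_fixture(list(MULTI_STEM_FIELD_VISITS = 4584, SHORT_QUESTION_TIME = 3224),
                        list(MULTI_STEM_FIELD_VISITS = 1902, SHORT_QUESTION_TIME = 1400))
  sm <- flag_summary(fl, n_completed = 4496, n_touched = 54850)
  expect_equal(sum(sm$n_flags), nrow(fl))
  r <- sm[flag_type == "MULTI_STEM_FIELD_VISITS"]
  expect_equal(r$pct_of_total_flags, round_half_up(100 * 4584 / 7808, 2))
  expect_equal(r$n_cases_flagged, 1902L)
  expect_equal(r$denominator_kind, "COMPLETED_CASES")
  expect_equal(sm[flag_type == "SHORT_QUESTION_TIME", denominator_kind], "TOUCHED_CASES")
  expect_equal(sm[flag_type == "SHORT_QUESTION_TIME", pct_of_denominator],
               round_half_up(100 * 1400 / 54850, 2))

  one <- flag_summary(mk_flag_fixture(list(LONG_INTERVIEW = 7), list(LONG_INTERVIEW = 7)),
                      100, 1000)
  expect_equal(one$pct_of_total_flags, 100)
  expect_error(flag_summary(fl, 0, 100), "positive")
})

test_that("window flags attribute cases through the link table", {
  fl <- mk_flag_fixture(list(PREVALENCE_RATE = 46), list(PREVALENCE_RATE = 1),
                        level = "INTERVIEWER_WINDOW")
  links <- data.table(flag_id = rep(fl$flag_id, each = 8),
                      case_id = sprintf("C%04d", rep_len(1:345, 46 * 8)))
  sm <- flag_summary(fl, 4496, 54850, flag_cases = links)
  expect_equal(sm$n_cases_flagged, 345L)
})

test_that("percentage rounding matches a half-up oracle over random counts", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample.int(5000, 1); den <- sample(n:60000, 1)
    x <- 100 * n / den
    # independent half-up oracle in integer arithmetic on the percentage scale
    want <- floor(x * 100 + 0.5) / 100
    expect_equal(round_half_up(x, 2), want)
  }
  expect_equal(round_half_up(0.125, 2), 0.13)   # where banker's rounding differs
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(catiqc:::trunc_at(29.2161, 2), 29.21)
  expect_equal(catiqc:::trunc_at(0.4169, 2), 0.41)
})

test_that("monitoring coverage merges intervals and honors thresholds", {
  empty <- monitoring_coverage(empty_cr <- data.table(
    call_id = character(), interviewer_id = character(), case_id = character(),
    start = ts(numeric(0)), end = ts(numeric(0)),
    monitored_intervals = character()), character(0))
  expect_equal(empty$dial_hours, 0)
  expect_equal(empty$pct_dial_time_monitored, 0)
  expect_equal(empty$n_monitored_min, 0L)

  # three calls; case C1 monitored 16 min via two overlapping sessions,
  # C2 monitored 5 min, C3 unmonitored
  mk_cr <- function(case, s, e, mi = "") data.table(
    call_id = paste0(case, "-K"), interviewer_id = "I01", case_id = case,
    start = ts(s), end = ts(e), monitored_intervals = mi)
  cr <- rbind(
    mk_cr("C1", 0, 3600, catiqc:::serialize_intervals(ts(c(0, 480)), ts(c(600, 960 + 480)))),
    mk_cr("C2", 4000, 7600, catiqc:::serialize_intervals(ts(4100), ts(4400))),
    mk_cr("C3", 8000, 9800))
  cov <- monitoring_coverage(cr, c("C1", "C2", "C3"), min_minutes = 15)
  expect_equal(cov$dial_hours, (3600 + 3600 + 1800) / 3600)
  expect_equal(cov$monitored_hours, (1440 + 300) / 3600)
  expect_equal(cov$n_monitored_min, 1L)   # only C1 reaches 15 merged minutes
  expect_equal(cov$n_monitored_any, 2L)
  expect_equal(cov$pct_monitored_any, round_half_up(100 * 2 / 3, 2))

  # union against the naive oracle on random monitored sets
  set.seed(11)
  for (i in 1:20) {
    k <- sample(1:6, 1)
    s <- sort(runif(k, 0, 3000)); e <- s + runif(k, 10, 900)
    e <- pmin(e, 3500)
    cr2 <- mk_cr("CX", 0, 3600, catiqc:::serialize_intervals(ts(s), ts(e)))
    cov2 <- monitoring_coverage(cr2, "CX", 0)
    expect_equal(cov2$monitored_hours * 3600,
                 oracle_union_seconds(floor(s), floor(e)), tolerance = 1e-9)
  }
})

test_that("task queue groups per interviewer with priority rules and totality", {
  expect_equal(nrow(build_task_queue(catiqc:::empty_flags(),
                                     as.Date(c("2021-01-20", "2021-03-01")))), 0L)

  fl <- catiqc:::bind_flags(rbind(
    mk_flag_fixture(list(SHORT_QUESTION_TIME = 12), list(SHORT_QUESTION_TIME = 12))[
      , interviewer_id := "I01"],
    mk_flag_fixture(list(SHORT_INTERVIEW = 4), list(SHORT_INTERVIEW = 4))[
      , interviewer_id := "I02"],
    mk_flag_fixture(list(LONG_INTERVIEW = 1), list(LONG_INTERVIEW = 1))[
      , interviewer_id := "I03"],
    mk_flag_fixture(list(PREVALENCE_RATE = 1), list(PREVALENCE_RATE = 1),
                    level = "INTERVIEWER_WINDOW")[, interviewer_id := "I04"],
    mk_flag_fixture(list(HIGH_COMPLETES = 2), list(HIGH_COMPLETES = 2))[
      , interviewer_id := "I05"]))
  q <- build_task_queue(fl, as.Date(c("2021-01-20", "2021-03-01")))
  expect_equal(nrow(q), 5L)           # one task per flagged interviewer
  pr <- setNames(q$priority, q$interviewer_id)
  expect_equal(pr[["I01"]], "HIGH")   # >= 10 case flags
  expect_equal(pr[["I02"]], "MEDIUM") # >= 3
  expect_equal(pr[["I03"]], "LOW")
  expect_equal(pr[["I04"]], "HIGH")   # window-level flag
  # totality: every flag id lands in exactly one task
  all_ids <- unlist(strsplit(q$flag_ids, ";"))
  expect_setequal(all_ids, fl$flag_id)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_true(all(q$status == "OPEN"))
})

test_that("task lifecycle transitions are enforced and notes append", {
  fl <- mk_flag_fixture(list(SHORT_INTERVIEW = 1), list(SHORT_INTERVIEW = 1))
  q <- build_task_queue(fl, as.Date(c("2021-01-20", "2021-03-01")))
  q2 <- update_task_status(q, q$task_id, "ASSIGNED_MONITORING", note = "watch calls")
  expect_equal(q2$status, "ASSIGNED_MONITORING")
  expect_match(q2$notes, "watch calls")
  q3 <- update_task_status(q2, q$task_id, "RESOLVED", note = "ok")
  expect_match(q3$notes, "watch calls.*\n.*ok")
  expect_error(update_task_status(q3, q$task_id, "OPEN"), "illegal task transition")
  expect_error(update_task_status(q, q$task_id, "BOGUS"), "illegal|invalid")
})

test_that("interviewer profiles aggregate and conserve flag counts", {
  res <- run_qc(generate_bundle(small_sim(seed = 14)))
  ids <- sprintf("I%02d", 1:4)
  for (id in ids) {
    p <- interviewer_profile(id, res$flags, res$metrics, res$window_stats,
                             known_ids = ids)
    expect_equal(p$n_flags, nrow(res$flags[interviewer_id == id]))
    expect_equal(sum(unlist(p$flags_by_type)), p$n_flags)
  }
  expect_error(interviewer_profile("I99", res$flags, res$metrics,
                                   res$window_stats, known_ids = ids),
               "unknown interviewer")
  # no-activity interviewer: all-zero profile
  p0 <- interviewer_profile("GHOST", res$flags, res$metrics, res$window_stats,
                            known_ids = c(ids, "GHOST"))
  expect_equal(p0$n_flags, 0L)
  expect_length(p0$flags_by_type, 0L)

  # a speeder's profile is dominated by duration-category flags
  rs <- run_qc(generate_bundle(small_sim(seed = 15,
                                         archetypes = list(I01 = "SPEEDER"))))
  ps <- interviewer_profile("I01", rs$flags, rs$metrics, rs$window_stats,
                            known_ids = ids)
  bc <- unlist(ps$flags_by_category)
  expect_gt(bc[["duration"]], sum(bc) - bc[["duration"]])
  # category filter is consistent with the full profile
  pd <- interviewer_profile("I01", rs$flags, rs$metrics, rs$window_stats,
                            known_ids = ids, category = "duration")
  expect_equal(pd$n_flags, unname(bc[["duration"]]))
})

test_that("evaluation records enforce the six skills and score range", {
  ok <- evaluation_record("I01", "2021-02-01",
                          c(probing = 4, objections_refusals = 3, persuasion = 5,
                            typing_speed = 2, project_knowledge = 4,
                            verbatim_reading = 5))
  expect_equal(ok$persuasion, 5L)
  expect_error(evaluation_record("I01", "2021-02-01",
                                 c(probing = 6, objections_refusals = 3, persuasion = 5,
                                   typing_speed = 2, project_knowledge = 4,
                                   verbatim_reading = 5)), "0..5")
  expect_error(evaluation_record("I01", "2021-02-01", c(probing = 4)), "exactly")
})
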