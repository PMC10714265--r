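cfg <- qc_config()

test_that("question-time flags respect cutoffs, exclusions and stem status", {
  cat1 <- data.table(question_id = c("q1", "q2", "s1", "x1"),
                     module = "health", is_stem = c(FALSE, FALSE, TRUE, FALSE),
                     baseline_read_seconds = c(8, 8, 8, 1.5),
                     exclude_from_short_flag = c(FALSE, FALSE, FALSE, TRUE))
  ev <- rbind(mk_interview("q1", 2.9),            # short nonstem -> flag
              mk_interview("q2", 3.0, start = 100),  # exactly at cutoff -> none
              mk_interview("s1", 1.0, start = 200),  # short stem -> stem flag
              mk_interview("x1", 1.0, start = 300),  # excluded -> none
              mk_interview("q1", 500, start = 400))  # long -> flag
  v <- build_field_visits(ev, cat1)
  fl <- flag_question_times(v, cat1, cfg)
  expect_equal(sort(fl$flag_type),
               sort(c("SHORT_QUESTION_TIME", "SHORT_STEM_QUESTION_TIME",
                      "LONG_QUESTION_TIME")))
  expect_equal(fl[flag_type == "SHORT_QUESTION_TIME", question_id], "q1")
  expect_equal(fl[flag_type == "SHORT_STEM_QUESTION_TIME", question_id], "s1")
  expect_equal(fl[flag_type == "LONG_QUESTION_TIME", observed_value], 500)
  # exactly 420 s does not flag (strict >)
  v420 <- build_field_visits(mk_interview("q1", 420), cat1)
  expect_equal(nrow(flag_question_times(v420, cat1, cfg)), 0L)
})

test_that("multiple-visit flags use the stem/nonstem cutoffs strictly", {
  cat1 <- data.table(question_id = c("s1", "q1"), module = "depression",
                     is_stem = c(TRUE, FALSE), baseline_read_seconds = 8,
                     exclude_from_short_flag = FALSE)
  vc <- data.table(case_id = "C1", question_id = c("s1", "q1"), n_visits = c(2L, 3L))
  fl <- flag_multiple_visits(vc, cat1, cfg)
  expect_equal(fl$flag_type, "MULTI_STEM_FIELD_VISITS")
  expect_equal(fl$observed_value, 2)
  expect_equal(fl$threshold_value, 1)

  vc2 <- data.table(case_id = "C1", question_id = "q1", n_visits = 4L)
  expect_equal(flag_multiple_visits(vc2, cat1, cfg)$flag_type, "MULTI_FIELD_VISITS")
  vc3 <- data.table(case_id = "C1", question_id = "q1", n_visits = 34L)
  expect_equal(flag_multiple_visits(vc3, cat1, cfg)$observed_value, 34)

  vc4 <- data.table(case_id = "C1", question_id = "nope", n_visits = 2L)
  expect_error(flag_multiple_visits(vc4, cat1, cfg), "absent from catalog")
})

test_that("case-profile flags: short-time share with strict boundary and skip rule", {
  cat1 <- mk_catalog(sprintf("q%02d", 1:10))
  mk_profile_case <- function(n_short, n_total = 10, case = "C1") {
    durs <- c(rep(2, n_short), rep(10, n_total - n_short))
    ev <- mk_interview(sprintf("q%02d", 1:n_total), durs, case = case)
    v <- build_field_visits(ev, cat1)
    tl <- timelines_from_visits(v, cat1)
    cs <- mk_case(case = case)
    flag_case_profiles(cs, tl, v, cat1, cfg)
  }
  f40 <- mk_profile_case(4)   # 40% > 30 -> flag
  expect_true("HIGH_PCT_SHORT_TIME" %in% f40$flag_type)
  expect_equal(f40[flag_type == "HIGH_PCT_SHORT_TIME", observed_value], 40)
  f30 <- mk_profile_case(3)   # exactly 30% -> none
  expect_false("HIGH_PCT_SHORT_TIME" %in% f30$flag_type)

  # all visits excluded -> rule skipped, recorded
  cat_ex <- mk_catalog(sprintf("q%02d", 1:10), exclude = TRUE)
  ev <- mk_interview(sprintf("q%02d", 1:10), rep(2, 10))
  v <- build_field_visits(ev, cat_ex)
  fl <- flag_case_profiles(mk_case(), timelines_from_visits(v, cat_ex), v, cat_ex, cfg)
  expect_false("HIGH_PCT_SHORT_TIME" %in% fl$flag_type)
  expect_equal(attr(fl, "skipped_pct_short"), "C1")
})

test_that("interview-length flags use version-specific cutoffs on adjusted time", {
  cat1 <- mk_catalog("q1")
  mk_len <- function(minutes, version) {
    v <- build_field_visits(mk_interview("q1", minutes * 60), cat1)
    tl <- timelines_from_visits(v, cat1)
    flag_case_profiles(mk_case(version = version), tl, v, cat1, cfg)
  }
  expect_true("SHORT_INTERVIEW" %in% mk_len(40, "LONG")$flag_type)    # < 47
  expect_false("SHORT_INTERVIEW" %in% mk_len(60, "LONG")$flag_type)
  expect_true("SHORT_INTERVIEW" %in% mk_len(30, "SHORT")$flag_type)   # < 32
  expect_false("SHORT_INTERVIEW" %in% mk_len(40, "SHORT")$flag_type)
  expect_true("LONG_INTERVIEW" %in% mk_len(190, "LONG")$flag_type)    # > 188
  expect_false("LONG_INTERVIEW" %in% mk_len(185, "LONG")$flag_type)
  # PARTIAL cases are not length-flagged
  v <- build_field_visits(mk_interview("q1", 40 * 60), cat1)
  tl <- timelines_from_visits(v, cat1)
  fl <- flag_case_profiles(mk_case(disposition = "PARTIAL"), tl, v, cat1, cfg)
  expect_false("SHORT_INTERVIEW" %in% fl$flag_type)
})

test_that("negative-stem and treatment-length rules", {
  all_neg <- paste(sprintf("s%02d=NEGATIVE", 1:12), collapse = ";")
  one_pos <- sub("s03=NEGATIVE", "s03=POSITIVE", all_neg)
  few_neg <- paste(sprintf("s%02d=NEGATIVE", 1:5), collapse = ";")
  fl <- flag_case_profiles(mk_case(stem_answers = all_neg), empty_tl <- data.table(),
                           data.table(), mk_catalog("q1"), cfg)
  expect_true("HIGH_NEGATIVE_STEMS" %in% fl$flag_type)
  expect_equal(fl[flag_type == "HIGH_NEGATIVE_STEMS", observed_value], 12)
  fl2 <- flag_case_profiles(mk_case(stem_answers = one_pos, any_disorder = TRUE),
                            data.table(), data.table(), mk_catalog("q1"), cfg)
  expect_false("HIGH_NEGATIVE_STEMS" %in% fl2$flag_type)
  # fewer than the minimum administered stems: not evaluated
  fl3 <- flag_case_profiles(mk_case(stem_answers = few_neg), data.table(),
                            data.table(), mk_catalog("q1"), cfg)
  expect_false("HIGH_NEGATIVE_STEMS" %in% fl3$flag_type)
  # fixed-count alternative rule
  cfg_n <- qc_config(negative_stem_rule = 4)
  fl4 <- flag_case_profiles(mk_case(stem_answers = few_neg), data.table(),
                            data.table(), mk_catalog("q1"), cfg_n)
  expect_true("HIGH_NEGATIVE_STEMS" %in% fl4$flag_type)

  # treatment time: > 30 min in the treatment module, any disposition
  cat_t <- mk_catalog("t1", module = "treatment")
  v <- build_field_visits(mk_interview("t1", 31 * 60), cat_t)
  tl <- timelines_from_visits(v, cat_t)
  fl5 <- flag_case_profiles(mk_case(disposition = "PARTIAL"), tl, v, cat_t, cfg)
  expect_true("LONG_TREATMENT" %in% fl5$flag_type)
})

test_that("high-completes flags standardize exposure-adjusted daily rates", {
  d <- as.Date("2021-01-25")
  # identical rates despite unequal completes: no flags
  ds_eq <- data.table(interviewer_id = sprintf("I%02d", 1:6), date = d,
                      completes = c(6, 6, 3, 3, 4, 4),
                      worked_hours = c(6, 6, 3, 3, 4, 4))
  expect_equal(nrow(flag_high_completes(ds_eq, cfg)), 0L)

  # 10 interviewer-days, one rate 3.0 among 1.0s: z = 1.8/sqrt(3.6/9) = 2.846
  ds <- data.table(interviewer_id = sprintf("I%02d", 1:10), date = d,
                   completes = c(3, rep(1, 9)), worked_hours = 1)
  fl <- flag_high_completes(ds, cfg)
  expect_equal(fl$interviewer_id, "I01")
  expect_equal(fl$observed_value, 2.846050, tolerance = 1e-6)
  expect_equal(fl$level, "INTERVIEWER_WINDOW")

  # 6 completes in 6 h is double the rate of 6 completes in 12 h
  ds2 <- data.table(interviewer_id = c("A", "B"), date = d,
                    completes = c(6, 6), worked_hours = c(6, 12))
  fl2 <- flag_high_completes(ds2, cfg)  # n=2, sd>0, z = +-0.707: none flagged
  expect_equal(nrow(fl2), 0L)

  # completes with zero worked hours: recorded inconsistency, no rate
  ds3 <- data.table(interviewer_id = c("A", "B"), date = d,
                    completes = c(2, 1), worked_hours = c(0, 5))
  fl3 <- flag_high_completes(ds3, cfg)
  expect_equal(attr(fl3, "inconsistencies")$interviewer_id, "A")
})

test_that("flag monotonicity in thresholds", {
  b <- generate_bundle(small_sim(seed = 9))
  v <- build_field_visits(b$audit_events, b$catalog)
  n_short <- function(cut) nrow(flag_question_times(
    v, b$catalog, qc_config(short_question_seconds = cut)))
  expect_true(all(diff(sapply(c(1, 2, 3, 5, 8), n_short)) >= 0))
  vc <- count_question_visits(v)
  ci <- b$case_records[, .(case_id, interviewer_id, date = as.Date(call_start))]
  n_multi <- function(cut) nrow(flag_multiple_visits(
    vc, b$catalog, qc_config(nonstem_visit_cutoff = cut), ci))
  expect_true(all(diff(sapply(1:4, n_multi)) <= 0))
})

test_that("flag registry covers the 13 types exactly once and levels are disciplined", {
  reg <- catiqc:::FLAG_REGISTRY
  expect_setequal(unlist(reg), catiqc:::FLAG_TYPES)
  expect_equal(anyDuplicated(unlist(reg)), 0L)
  expect_length(catiqc:::FLAG_TYPES, 13L)

  for (seed in c(4, 8)) {
    res <- run_qc(generate_bundle(small_sim(seed = seed)))
    fl <- res$flags
    expect_true(all(fl$flag_type %in% catiqc:::FLAG_TYPES))
    expect_true(fl[level == "CASE", all(!is.na(case_id))])
    expect_true(fl[level == "INTERVIEWER_WINDOW",
                   all(!is.na(window_start) & !is.na(window_end))])
    expect_equal(anyDuplicated(fl$flag_id), 0L)
  }
})

test_that("the engine is deterministic for a fixed bundle and config", {
  b <- generate_bundle(small_sim(seed = 12))
  r1 <- run_qc(b); r2 <- run_qc(b)
  expect_identical(as.data.frame(r1$flags), as.data.frame(r2$flags))
  expect_identical(as.data.frame(r1$summary), as.data.frame(r2$summary))
})
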