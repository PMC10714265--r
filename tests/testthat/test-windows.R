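cfg <- qc_config()

test_that("window partition is a disjoint aligned cover with half-open boundaries", {
  w <- partition_windows("2021-01-20", as.Date("2021-01-25"))
  expect_equal(nrow(w), 1L)
  expect_equal(w$window_start, as.Date("2021-01-20"))
  expect_equal(w$window_end, as.Date("2021-02-03"))

  # a case dated exactly on a boundary joins the later window
  expect_equal(assign_window <- catiqc:::assign_window(as.Date("2021-02-03"),
                                                       "2021-01-20"),
               as.Date("2021-02-03"))

  dates <- as.Date("2021-01-20") + 0:59
  w5 <- partition_windows("2021-01-20", dates)
  expect_equal(nrow(w5), 5L)
  expect_equal(w5$window_start[-1], w5$window_end[-5])  # consecutive, disjoint
  idx <- findInterval(as.numeric(dates), as.numeric(w5$window_start))
  expect_true(all(dates >= w5$window_start[idx] & dates < w5$window_end[idx]))

  expect_equal(nrow(partition_windows("2021-01-20", as.Date(character()))), 0L)
  expect_error(partition_windows("2021-01-20", as.Date("2021-01-10")),
               "after the earliest date")
})

test_that("window z scores: frozen hand computation, SD-zero and eligibility rules", {
  st <- data.table(interviewer_id = c("A", "B", "C"),
                   window_start = as.Date("2021-01-20"),
                   window_end = as.Date("2021-02-03"),
                   statistic = "MEAN_INTERVIEW_MINUTES",
                   n_cases = c(10L, 10L, 10L), value = c(60, 90, 90), z = NA_real_)
  z <- window_zscores(st, cfg)
  expect_equal(z[interviewer_id == "A", z], -1.154701, tolerance = 1e-6)
  expect_equal(z[, mean(z)], 0, tolerance = 1e-9)
  expect_equal(z[, sd(z)], 1, tolerance = 1e-9)

  st_eq <- copy(st)[, value := 80]
  expect_true(all(is.na(window_zscores(st_eq, cfg)$z)))

  st_small <- copy(st)[, n_cases := c(10L, 10L, 3L)]  # C below the minimum
  z2 <- window_zscores(st_small, cfg)
  expect_true(is.na(z2[interviewer_id == "C", z]))
  expect_equal(z2[interviewer_id == "A", z], -0.7071068, tolerance = 1e-6)

  # only one eligible interviewer: no z at all
  st_one <- copy(st)[, n_cases := c(10L, 2L, 2L)]
  expect_true(all(is.na(window_zscores(st_one, cfg)$z)))
})

test_that("prevalence and mean-length stats aggregate completed cases per window", {
  cs <- rbind(
    mk_case(sprintf("C%02d", 1:8), iv = "A", any_disorder = FALSE),
    mk_case(sprintf("D%02d", 1:10), iv = "B",
            any_disorder = rep(c(TRUE, FALSE), 5)),
    mk_case("E1", iv = "A", disposition = "REFUSAL"))
  ps <- prevalence_stat(cs, "2021-01-20", cfg)
  expect_equal(ps[interviewer_id == "A", value], 0)
  expect_equal(ps[interviewer_id == "A", n_cases], 8L)
  expect_equal(ps[interviewer_id == "B", value], 0.5)

  tl <- data.table(case_id = cs$case_id, interviewer_id = cs$interviewer_id,
                   total_survey_seconds = 6000, adjusted_total_seconds = 5400,
                   treatment_seconds = 0, timeout_bug = FALSE)
  ms <- mean_interview_stat(cs, tl, "2021-01-20", cfg)
  expect_equal(unique(ms$value), 90)
  expect_equal(ms[interviewer_id == "B", n_cases], 10L)
})

test_that("window flags follow each rule's own operator", {
  base <- data.table(interviewer_id = "A", window_start = as.Date("2021-01-20"),
                     window_end = as.Date("2021-02-03"), n_cases = 10L, value = 0.1)
  f <- function(stat, z) emit_window_flags(copy(base)[, `:=`(statistic = stat, z = z)], cfg)
  expect_equal(nrow(f("PREVALENCE", -1.5)), 0L)       # strict magnitude
  expect_equal(nrow(f("PREVALENCE", -1.51)), 1L)
  expect_equal(f("PREVALENCE", 2.47)$flag_type, "PREVALENCE_RATE")
  expect_equal(f("PREVALENCE", 2.47)$observed_value, 2.47)  # sign preserved
  expect_equal(nrow(f("MEAN_INTERVIEW_MINUTES", -2)), 1L)   # <= fires at -2
  expect_equal(nrow(f("MEAN_INTERVIEW_MINUTES", -1.99)), 0L)
  expect_equal(nrow(f("MEAN_INTERVIEW_MINUTES", 3)), 0L)    # one-sided
})

test_that("interval unions merge overlaps and match the oracle", {
  m <- merge_intervals(ts(c(0, 300)), ts(c(600, 1200)))
  expect_equal(nrow(m), 1L)
  expect_equal(interval_union_seconds <- catiqc:::interval_union_seconds(
    ts(c(0, 300)), ts(c(600, 1200))), 1200)

  set.seed(99)
  for (i in 1:40) {
    n <- sample(1:12, 1)
    s <- runif(n, 0, 1000); e <- s + runif(n, -50, 400)  # some reversed: dropped
    expect_equal(catiqc:::interval_union_seconds(s, e), oracle_union_seconds(s, e))
    # adding an interval never decreases the union
    expect_gte(catiqc:::interval_union_seconds(c(s, 500), c(e, 700)),
               catiqc:::interval_union_seconds(s, e))
  }
})

test_that("verification metrics: rates, discrepancy, monitoring merge, empty period", {
  d0 <- ts(0)
  logs <- data.table(interviewer_id = "A", activity = "CALLING",
                     start = d0, end = d0 + 5 * 3600)
  # 30 dials of 6 minutes in the 5-hour block
  starts <- d0 + (0:29) * 600
  calls <- data.table(call_id = sprintf("K%02d", 1:30), interviewer_id = "A",
                      case_id = sprintf("C%02d", 1:30), start = starts,
                      end = starts + 360, monitored_intervals = "")
  calls$monitored_intervals[1] <- paste0(
    catiqc:::serialize_intervals(d0 + c(0, 60), d0 + c(120, 240)))
  b <- paradata_bundle(call_records = calls, time_logs = logs,
                       study_start_date = "2021-01-20")
  mt <- compute_metrics(b, data.table(), data.table(),
                        as.Date(c("2021-01-20", "2021-01-21")))
  g <- function(m) mt[metric == m & interviewer_id == "A" & is.na(case_id), value]
  expect_equal(g("DIALS_PER_HOUR"), 6)
  expect_equal(g("CISCO_CALLING_TIME"), 3)
  # logged 5 h CALLING, observed 3 h of calls -> discrepancy +2 h
  expect_equal(g("REPORTED_TIME_DISCREPANCY"), 2)
  # overlapping monitoring [0,2) and [1,4) minutes merges to 4
  expect_equal(g("MONITORING_TIME_PER_INTERVIEWER"), 4)
  # after-call work: 4-minute gap between consecutive dials in one block
  expect_equal(g("AVG_AFTER_CALL_WORK_TIME"), 240)

  # period with no activity: zero-valued metrics, still present
  mt0 <- compute_metrics(b, data.table(), data.table(),
                         as.Date(c("2022-01-01", "2022-01-02")))
  expect_true(all(mt0[interviewer_id == "A", value] == 0))
  expect_true("ADJ_COMPLETES_PER_HOUR" %in% mt0$metric)
})

test_that("completes-per-hour uses shift hours, adjusted rate uses calling hours", {
  d0 <- ts(0)
  logs <- rbind(
    data.table(interviewer_id = "A", activity = "SHIFT_PREP", start = d0, end = d0 + 3600),
    data.table(interviewer_id = "A", activity = "CALLING", start = d0 + 3600,
               end = d0 + 3 * 3600))
  cases <- mk_case(c("C1", "C2"), iv = "A", any_disorder = FALSE)
  b <- paradata_bundle(case_records = cases, time_logs = logs,
                       study_start_date = "2021-01-20")
  mt <- compute_metrics(b, data.table(), data.table(),
                        as.Date(c("2021-01-20", "2021-01-21")))
  expect_equal(mt[metric == "COMPLETES_PER_HOUR", value], 2 / 3)
  expect_equal(mt[metric == "ADJ_COMPLETES_PER_HOUR", value], 1)
})

test_that("per-case metrics lift timeline fields and monitoring; 14 metric names", {
  expect_length(catiqc:::METRIC_NAMES, 14L)
  b <- generate_bundle(small_sim(seed = 6))
  v <- build_field_visits(b$audit_events, b$catalog)
  tl <- timelines_from_visits(v, b$catalog)
  mt <- compute_metrics(b, v, tl, c(b$study_start_date, b$study_start_date + 7))
  expect_true(all(mt$metric %in% catiqc:::METRIC_NAMES))
  one <- tl$case_id[1]
  expect_equal(mt[metric == "BLAISE_SURVEY_TIME" & case_id == one, value],
               tl[case_id == one, total_survey_seconds] / 60)
  expect_true(all(mt[metric == "MONITORED", value] %in% c(0, 1)))
})

test_that("z scores standardize to mean 0, sample SD 1 within eligible window sets", {
  b <- generate_bundle(small_sim(seed = 13, n_interviewers = 6))
  v <- build_field_visits(b$audit_events, b$catalog)
  tl <- timelines_from_visits(v, b$catalog)
  st <- window_zscores(rbind(prevalence_stat(b$case_records, b$study_start_date, cfg),
                             mean_interview_stat(b$case_records, tl,
                                                 b$study_start_date, cfg)), cfg)
  chk <- st[!is.na(z), .(m = mean(z), s = sd(z), n = .N),
            by = .(window_start, statistic)]
  expect_true(chk[n >= 2, all(abs(m) < 1e-9 & abs(s - 1) < 1e-9)])
})
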