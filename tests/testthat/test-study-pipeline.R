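small_cfg <- function(...) {
  sim_config(n_subjects = 4, study_days = 2, seed = 19, ...)
}

test_that("alternation arithmetic: full cohort yields balanced analyzed days", {
  cfg <- sim_config(n_subjects = 4, study_days = 6, seed = 2)
  rep <- run_study(cfg)
  acc <- rep$accounting
  expect_equal(acc$enrolled_days, 24)
  expect_equal(acc$analyzed_days, 24)
  expect_equal(unname(acc$analyzed_by_strategy[c("tight", "loose")]),
               c(12L, 12L))
  expect_true(acc$identity_ok)
})

test_that("subjects completing fewer than 2 days are excluded with a reason", {
  cfg <- sim_config(n_subjects = 8, study_days = 4, seed = 23,
                    early_exit_prob = 0.5)
  rep <- run_study(cfg)
  short <- rep$roster$subject_id[rep$roster$days_completed < 2]
  expect_gt(length(short), 0)  # this seed produces early exits
  ds <- rep$day_summaries
  expect_true(all(!ds$analyzed[ds$subject_id %in% short]))
  expect_true(all(ds$reason[ds$subject_id %in% short] ==
                    "subject completed fewer than 2 days"))
  # and they never enter the paired analysis
  expect_false(any(rep$pairs$subject_id %in% short))
  expect_true(rep$accounting$identity_ok)
})

test_that("mis-set alarm days are screened out as protocol violations", {
  tight <- strategy_from_target(target_range(), "tight")
  expect_true(screen_violations(tight, tight)$keep)
  off <- alarm_strategy(tight$low_alarm + 2, tight$high_alarm + 2, tight$delay)
  scr <- screen_violations(off, tight)
  expect_false(scr$keep)
  expect_match(scr$reason, "inconsistent")

  cfg <- sim_config(n_subjects = 4, study_days = 4, seed = 29,
                    violation_prob = 0.3)
  rep <- run_study(cfg)
  ds <- rep$day_summaries
  viol <- !ds$analyzed
  expect_gt(sum(viol), 0)
  # violating days really carry off-protocol recorded settings
  tight_ok <- ds$recorded_low == 87 & ds$recorded_high == 96 & ds$recorded_delay == 30
  loose_ok <- ds$recorded_low == 85 & ds$recorded_high == 98 & ds$recorded_delay == 90
  expect_true(all(!tight_ok[viol] | ds$strategy[viol] != "tight"))
  expect_true(all(xor(ds$analyzed, !(tight_ok & ds$strategy == "tight") &
                        !(loose_ok & ds$strategy == "loose"))))
  expect_true(rep$accounting$identity_ok)
})

test_that("the pipeline is deterministic given the seed", {
  cfg <- small_cfg(violation_prob = 0.2)
  a <- run_study(cfg)
  b <- run_study(cfg)
  expect_identical(a$day_summaries, b$day_summaries)
  expect_identical(a$comparisons, b$comparisons)
  expect_identical(a$fig1_histogram, b$fig1_histogram)
})

test_that("pooling concatenates days rather than averaging daily values", {
  # two analyzed days with very different valid denominators: the pooled
  # rate must be the ratio of sums, not the mean of daily rates
  base <- data.frame(
    subject_id = "S01", day = 1:2, strategy = c("tight", "loose"),
    recorded_low = 87, recorded_high = 96, recorded_delay = 30,
    analyzed = TRUE, reason = NA_character_,
    n_samples = c(17280, 17280), n_valid = c(17280, 8640),
    n_suppl = c(17280, 8640), n_hypox = 0, n_hyper = 0,
    n_in_suppl = c(17280, 8640), n_normox = c(17280, 8640),
    hypox_gt1 = 0, hypox_gt3 = 0, hyper_gt1 = 0, hyper_gt3 = 0,
    n_alarms = c(24, 12), audible_samples = 0, n_manual = 0,
    sum_hmed_spo2 = c(24, 24) * 92, sum_hmed_fio2 = c(24, 24) * 0.3,
    n_hours = 24
  )
  extra <- base
  extra$day <- 3:4
  extra$strategy <- c("loose", "tight")
  extra$n_valid[2] <- 17280
  extra$n_alarms <- c(6, 48)
  ds <- rbind(base, extra)
  pairs <- pool_by_strategy(ds)
  tight_rate <- pairs$value_tight[pairs$metric == "alarms_per_hour"]
  # tight: (24 + 48) alarms over 48 valid hours
  expect_equal(tight_rate, 72 / 48)
  loose_rate <- pairs$value_loose[pairs$metric == "alarms_per_hour"]
  # loose: (12 + 6) alarms over 12 + 24 valid hours
  expect_equal(loose_rate, 18 / 36)
})

test_that("single-strategy subjects drop out of pairing", {
  ds <- data.frame(
    subject_id = c("S01", "S01", "S02"), day = c(1, 2, 1),
    strategy = c("tight", "loose", "tight"),
    recorded_low = 87, recorded_high = 96, recorded_delay = 30,
    analyzed = TRUE, reason = NA_character_,
    n_samples = 17280, n_valid = 17280, n_suppl = 17280,
    n_hypox = 0, n_hyper = 0, n_in_suppl = 17280, n_normox = 17280,
    hypox_gt1 = 0, hypox_gt3 = 0, hyper_gt1 = 0, hyper_gt3 = 0,
    n_alarms = 10, audible_samples = 0, n_manual = 0,
    sum_hmed_spo2 = 24 * 92, sum_hmed_fio2 = 24 * 0.3, n_hours = 24
  )
  pairs <- pool_by_strategy(ds)
  expect_equal(unique(pairs$subject_id), "S01")
  # one day per strategy: pooled value equals that day's value
  expect_equal(pairs$value_tight[pairs$metric == "alarms_per_hour"], 10 / 24)
})

test_that("a no-event cohort runs end to end with degenerate statistics", {
  cfg <- sim_config(n_subjects = 4, study_days = 2, noise_sd = 0,
                    desat_rate = 0, hyper_rate = 0, dropout_rate = 0,
                    manual_adjustments_per_day = 0, seed = 31)
  rep <- run_study(cfg)
  expect_true(all(rep$day_summaries$n_alarms == 0))
  expect_true(all(rep$day_summaries$hypox_gt1 == 0))
  norm <- rep$pairs[rep$pairs$metric == "pct_normoxemia", ]
  expect_true(all(norm$value_tight == 100 & norm$value_loose == 100))
  degen <- rep$comparisons[rep$comparisons$metric == "alarms_per_hour", ]
  expect_equal(degen$p_value, 1)
})

test_that("the cohort histogram takes per-bin medians and quartiles", {
  hists <- data.frame(
    subject_id = rep(c("A", "B", "C"), each = 2),
    bin = rep(c(90, 91), 3),
    pct = c(60, 40, 70, 30, 80, 20)
  )
  ch <- cohort_histogram(hists)
  expect_equal(ch$median_pct[ch$bin == 90], 70)
  expect_equal(ch$q1_pct[ch$bin == 90], 65)
  expect_equal(ch$q3_pct[ch$bin == 90], 75)
  # a subject missing a bin contributes zero there
  hists2 <- rbind(hists, data.frame(subject_id = "A", bin = 92, pct = 5))
  ch2 <- cohort_histogram(hists2)
  expect_equal(ch2$median_pct[ch2$bin == 92], 0)
})

test_that("file-based and in-memory pipelines agree", {
  cfg <- small_cfg(violation_prob = 0.1, dropout_rate = 0.03)
  rep <- run_study(cfg)
  d <- tempfile()
  simulate_cohort(cfg, d)
  expect_true(file.exists(file.path(d, "schedule.csv")))
  expect_true(file.exists(file.path(d, "logs", "S01.csv")))
  an <- analyze_logs(d)
  expect_equal(an$day_summaries, rep$day_summaries, tolerance = 1e-9)
  rep2 <- report_from_summaries(an$day_summaries, an$hist_counts)
  expect_equal(rep2$comparisons, rep$comparisons, tolerance = 1e-9)
  unlink(d, recursive = TRUE)
})

test_that("report files are written and the accounting identity holds on disk", {
  cfg <- small_cfg()
  d <- tempfile()
  rep <- run_study(cfg, outdir = d)
  for (f in c("day_summaries.csv", "paired_comparisons.csv", "table3.csv",
              "table4.csv", "fig1_histogram.csv", "fig2_daily_alarm_rates.csv",
              "accounting.csv", "roster.csv")) {
    expect_true(file.exists(file.path(d, f)), info = f)
  }
  acc <- utils::read.csv(file.path(d, "accounting.csv"))
  v <- stats::setNames(acc$value, acc$item)
  expect_equal(v[["enrolled_days"]], v[["analyzed_days"]] + v[["excluded_days"]])
  expect_equal(v[["analyzed_days"]], v[["analyzed_tight"]] + v[["analyzed_loose"]])
  unlink(d, recursive = TRUE)
})

test_that("percent-reduction arithmetic and reference medians are coherent", {
  expect_equal(pct_reduction(4, 1), 75)
  expect_error(pct_reduction(0, 1), "zero")
  ref <- reference_outcomes()
  expect_true(all(c("spo2_alarms_per_hour", "pct_audible") %in% ref$metric))
  # the headline effect: fewer alarms under the loose strategy
  expect_lt(ref$loose[ref$metric == "spo2_alarms_per_hour"],
            ref$tight[ref$metric == "spo2_alarms_per_hour"])
})
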