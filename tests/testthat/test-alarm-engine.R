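tight <- strategy_from_target(target_range(), "tight")
loose <- strategy_from_target(target_range(), "loose")

test_that("strategies derive from the target range with fixed offsets", {
  expect_equal(tight[c("low_alarm", "high_alarm", "delay")],
               list(low_alarm = 87, high_alarm = 96, delay = 30))
  expect_equal(loose[c("low_alarm", "high_alarm", "delay")],
               list(low_alarm = 85, high_alarm = 98, delay = 90))
  s <- strategy_from_target(target_range(90, 94), "tight")
  expect_equal(s[c("low_alarm", "high_alarm", "delay")],
               list(low_alarm = 89, high_alarm = 95, delay = 30))
  expect_error(strategy_from_target(target_range(2, 98), "loose"),
               "outside")
  expect_error(alarm_strategy(90, 85, 30), "low_alarm")
  expect_error(alarm_strategy(85, 95, 12), "multiple of 5")
})

test_that("a series that never violates produces no alarms", {
  s <- make_series(rep(92, 720))
  expect_equal(nrow(detect_alarms(s, tight)), 0)
  expect_equal(nrow(detect_alarms(s, loose)), 0)
  expect_equal(alarm_rate(detect_alarms(s, tight), s), 0)
  expect_equal(audible_fraction(detect_alarms(s, tight), s), 0)
})

test_that("a 40-s desaturation run triggers the 30-s but not the 90-s delay", {
  spo2 <- rep(92, 40)
  spo2[11:18] <- 82  # 8 samples = 40 s below both thresholds
  s <- make_series(spo2)
  ev_t <- detect_alarms(s, tight)
  expect_equal(nrow(ev_t), 1)
  expect_equal(ev_t$kind, "low")
  expect_equal(ev_t$start, 16)           # 6th violating sample: 30 s held
  expect_equal(ev_t$end, 19)             # first in-range sample
  expect_equal(ev_t$duration_s, 15)
  expect_equal(nrow(detect_alarms(s, loose)), 0)
  # the brute-force scan agrees
  expect_equal(as.data.frame(ev_t)[c("start", "end")],
               oracle_alarms(s, tight)[c("start", "end")])
})

test_that("a violation run exactly equal to the delay yields one event with the post-delay residue", {
  spo2 <- rep(92, 30)
  spo2[11:16] <- 80  # exactly 6 samples = 30 s
  s <- make_series(spo2)
  ev <- detect_alarms(s, tight)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 16)
  expect_equal(ev$end, 17)
  expect_equal(ev$duration_s, 5)
  # one sample short of the delay: no event
  spo2[16] <- 92
  expect_equal(nrow(detect_alarms(make_series(spo2), tight)), 0)
})

test_that("an alarm active at the series end is closed at the boundary", {
  spo2 <- c(rep(92, 10), rep(70, 10))
  ev <- detect_alarms(make_series(spo2), tight)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end, 21)
})

test_that("invalid samples pause the persistence timer, or reset it on request", {
  spo2 <- c(rep(92, 5), rep(80, 3), rep(80, 2), rep(80, 3), rep(92, 5))
  valid <- rep(TRUE, 18)
  valid[9:10] <- FALSE  # dropout in the middle of the violation
  s <- make_series(spo2, valid = valid)
  # pause: 3 + 3 valid violating samples reach the 30-s (6-sample) delay
  ev <- detect_alarms(s, tight)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 13)
  # reset: neither 3-sample run alone satisfies the delay
  expect_equal(nrow(detect_alarms(s, tight, invalid_resets = TRUE)), 0)
})

test_that("run-length detection matches the per-sample state machine on random series", {
  set.seed(421)
  for (i in 1:300) {
    s <- random_series(n = sample(50:250, 1))
    strat <- alarm_strategy(sample(80:90, 1), sample(94:99, 1),
                            5 * sample(0:20, 1))
    inv <- i %% 2 == 0
    got <- as.data.frame(detect_alarms(s, strat, invalid_resets = inv))
    want <- oracle_alarms(s, strat, invalid_resets = inv)
    expect_equal(got[c("kind", "start", "end")], want,
                 info = sprintf("case %d", i))
  }
})

test_that("alarm events are disjoint within kind and never span an in-range valid sample", {
  set.seed(99)
  for (i in 1:50) {
    s <- random_series(250)
    ev <- detect_alarms(s, tight)
    for (k in c("low", "high")) {
      e <- ev[ev$kind == k, ]
      if (nrow(e) > 1) {
        expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
      }
      if (nrow(e)) {
        expect_true(all(e$start < e$end))
      }
    }
  }
})

test_that("increasing the delay never increases the event count", {
  set.seed(31)
  for (i in 1:50) {
    s <- random_series(300)
    counts <- vapply(c(0, 15, 30, 60, 90), function(delay) {
      nrow(detect_alarms(s, alarm_strategy(87, 96, delay)))
    }, 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("widening thresholds does not increase alarms on physiologic series", {
  cfg <- sim_config(n_subjects = 4, study_days = 1, seed = 8)
  for (i in 1:4) {
    s <- generate_subject(cfg, i)
    widths <- list(c(87, 96), c(86, 97), c(85, 98))
    counts <- vapply(widths, function(w) {
      nrow(detect_alarms(s, alarm_strategy(w[1], w[2], 30)))
    }, 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the loose strategy's audible burden never exceeds the tight one's", {
  # loose thresholds enclose tight and its delay is longer, so every
  # loose-audible sample is tight-audible
  set.seed(77)
  for (i in 1:40) {
    s <- random_series(400)
    expect_lte(audible_fraction(detect_alarms(s, loose), s),
               audible_fraction(detect_alarms(s, tight), s))
  }
  cfg <- sim_config(n_subjects = 2, study_days = 1, seed = 12)
  for (i in 1:2) {
    s <- generate_subject(cfg, i)
    expect_lt(alarm_rate(detect_alarms(s, loose), s),
              alarm_rate(detect_alarms(s, tight), s))
  }
})

test_that("alarm rate and audible fraction follow their definitions", {
  s <- make_series(rep(92, 17280))  # 24 h, all valid
  fake <- data.frame(kind = rep("low", 48), start = 1:48, end = 2:49,
                     duration_s = 5)
  expect_equal(alarm_rate(fake, s), 2)
  one <- data.frame(kind = "low", start = 1, end = 15, duration_s = 72)
  hour <- make_series(rep(92, 720))
  expect_equal(audible_fraction(one, hour), 2)
  expect_error(alarm_rate(fake, make_series(rep(92, 10), valid = FALSE)),
               "valid")
})

test_that("alarm events export with subject, day and timing columns", {
  cfg <- sim_config(n_subjects = 1, study_days = 2, seed = 21)
  s <- generate_subject(cfg, 1)
  ev <- detect_alarms(s, tight)
  f <- tempfile(fileext = ".csv")
  write_alarm_csv(ev, s, f)
  r <- utils::read.csv(f)
  expect_equal(names(r),
               c("subject_id", "day", "kind", "start_s", "end_s", "duration_s"))
  expect_equal(nrow(r), nrow(ev))
  expect_true(all(r$day %in% 1:2))
})
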