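## End-to-end simulated crossover study:
## generate -> schedule -> alarms -> metrics -> paired analysis -> report.
## The same analysis code runs either in memory (run_study) or over CSV
## logs on disk (simulate_cohort / analyze_logs / report_from_summaries).

TABLE4_METRICS <- c(
  "alarms_per_hour", "pct_audible",
  "pct_hypoxemia", "hypox_gt1min_per24h", "hypox_gt3min_per24h",
  "pct_hyperoxemia", "hyper_gt1min_per24h", "hyper_gt3min_per24h"
)
TABLE3_METRICS <- c(
  "mean_hourly_median_fio2", "mean_hourly_median_spo2",
  "pct_in_86_96_suppl_o2", "pct_normoxemia", "manual_adjustments_per_day"
)

## sufficient statistics of one subject-day; alarms are detected with the
## day's *recorded* device settings, as a bedside monitor would
day_stats <- function(series, recorded_strategy) {
  v <- series$valid
  hypo <- find_episodes(series, "hypoxemia")
  hyper <- find_episodes(series, "hyperoxemia")
  ev <- detect_alarms(series, recorded_strategy)
  hour <- (seq_len(nrow(series)) - 1L) %/% SAMPLES_PER_HOUR
  med_s <- tapply(series$spo2[v], hour[v], stats::median)
  med_f <- tapply(series$fio2[v], hour[v], stats::median)
  data.frame(
    n_samples = nrow(series),
    n_valid = sum(v),
    n_suppl = sum(v & suppl_o2(series)),
    n_hypox = sum(episode_predicate(series, "hypoxemia")),
    n_hyper = sum(episode_predicate(series, "hyperoxemia")),
    n_in_suppl = sum(v & suppl_o2(series) & series$spo2 >= 86 & series$spo2 <= 96),
    n_normox = sum(v & ((series$spo2 >= 86 & series$spo2 <= 96) |
                          (series$spo2 > 96 & room_air(series)))),
    hypox_gt1 = sum(hypo$duration_s > 60),
    hypox_gt3 = sum(hypo$duration_s > 180),
    hyper_gt1 = sum(hyper$duration_s > 60),
    hyper_gt3 = sum(hyper$duration_s > 180),
    n_alarms = nrow(ev),
    audible_samples = sum(ev$end - ev$start),
    n_manual = sum(series$manual_adjustment),
    sum_hmed_spo2 = sum(med_s),
    sum_hmed_fio2 = sum(med_f),
    n_hours = length(med_s)
  )
}

## derived outcome metrics from (pooled) sufficient statistics
derive_metrics <- function(g) {
  vh <- g$n_valid * 5 / 3600   # valid hours
  vd <- g$n_valid * 5 / 86400  # valid days
  data.frame(
    alarms_per_hour = g$n_alarms / vh,
    pct_audible = 100 * g$audible_samples / g$n_valid,
    pct_hypoxemia = 100 * g$n_hypox / g$n_valid,
    hypox_gt1min_per24h = g$hypox_gt1 / vd,
    hypox_gt3min_per24h = g$hypox_gt3 / vd,
    pct_hyperoxemia = 100 * g$n_hyper / g$n_valid,
    hyper_gt1min_per24h = g$hyper_gt1 / vd,
    hyper_gt3min_per24h = g$hyper_gt3 / vd,
    pct_in_86_96_suppl_o2 = ifelse(g$n_suppl > 0,
                                   100 * g$n_in_suppl / g$n_suppl, NA_real_),
    pct_normoxemia = 100 * g$n_normox / g$n_valid,
    mean_hourly_median_spo2 = g$sum_hmed_spo2 / g$n_hours,
    mean_hourly_median_fio2 = g$sum_hmed_fio2 / g$n_hours,
    manual_adjustments_per_day = g$n_manual / (g$n_samples * 5 / 86400)
  )
}

#' Screen a study day for protocol violations
#'
#' A day is excluded when the alarm settings recorded at the bedside
#' differ from the assigned strategy's settings (mis-set alarms).
#'
#' @param recorded,assigned [alarm_strategy()] objects: the settings found
#'   on the device and the settings the schedule assigned.
#' @return List with `keep` (logical) and `reason` (`NA` or a short
#'   description).
#' @export
screen_violations <- function(recorded, assigned) {
  same <- recorded$low_alarm == assigned$low_alarm &&
    recorded$high_alarm == assigned$high_alarm &&
    recorded$delay == assigned$delay
  if (same) {
    list(keep = TRUE, reason = NA_character_)
  } else {
    list(keep = FALSE, reason = "alarm settings inconsistent with assigned strategy")
  }
}

## a mis-set device: both thresholds shifted off either strategy's values
misset_strategy <- function(assigned) {
  shift <- sample(c(-2, 2), 1)
  alarm_strategy(assigned$low_alarm + shift, assigned$high_alarm + shift,
                 assigned$delay, name = "custom")
}

## Per-subject schedules with assigned and recorded device settings.
## Early exit and mis-set days are drawn from RNG streams separate from
## the signal generator so the two stay decoupled.
cohort_plan <- function(config) {
  first <- assign_first_day(config$n_subjects, config$seed)
  strat <- list(tight = strategy_from_target(config$target_range, "tight"),
                loose = strategy_from_target(config$target_range, "loose"))
  lapply(seq_len(config$n_subjects), function(s) {
    draws <- with_seed(subject_seed(config$seed, s, stream = 1L), {
      days_s <- config$study_days
      if (config$early_exit_prob > 0 && config$study_days > 1) {
        exits <- stats::runif(config$study_days - 1) < config$early_exit_prob
        if (any(exits)) days_s <- which(exits)[1]
      }
      list(days = days_s, viol = stats::runif(days_s) < config$violation_prob)
    })
    sched <- build_schedule(first[s], draws$days)
    rows <- lapply(seq_len(draws$days), function(d) {
      assigned <- strat[[sched[d]]]
      recorded <- if (draws$viol[d]) {
        with_seed(subject_seed(config$seed, s, stream = 2L + d),
                  misset_strategy(assigned))
      } else {
        assigned
      }
      data.frame(subject_id = sprintf("S%02d", s), day = d,
                 strategy = sched[d],
                 assigned_low = assigned$low_alarm,
                 assigned_high = assigned$high_alarm,
                 assigned_delay = assigned$delay,
                 recorded_low = recorded$low_alarm,
                 recorded_high = recorded$high_alarm,
                 recorded_delay = recorded$delay)
    })
    do.call(rbind, rows)
  })
}

## day summaries + per-subject histogram counts for one subject's series
summarize_subject <- function(series, sched) {
  day_list <- split_days(series)
  incomplete <- nrow(sched) < 2
  rows <- lapply(seq_len(nrow(sched)), function(d) {
    recorded <- alarm_strategy(sched$recorded_low[d], sched$recorded_high[d],
                               sched$recorded_delay[d])
    assigned <- alarm_strategy(sched$assigned_low[d], sched$assigned_high[d],
                               sched$assigned_delay[d])
    scr <- screen_violations(recorded, assigned)
    reason <- if (incomplete) "subject completed fewer than 2 days" else scr$reason
    cbind(
      data.frame(subject_id = sched$subject_id[d], day = d,
                 strategy = sched$strategy[d],
                 recorded_low = recorded$low_alarm,
                 recorded_high = recorded$high_alarm,
                 recorded_delay = recorded$delay,
                 analyzed = scr$keep && !incomplete, reason = reason),
      day_stats(day_list[[d]], recorded)
    )
  })
  summaries <- do.call(rbind, rows)
  hist_rows <- lapply(which(summaries$analyzed), function(d) {
    dl <- day_list[[d]]
    sel <- dl$valid & suppl_o2(dl)
    if (!any(sel)) return(NULL)
    h <- spo2_histogram(dl)
    data.frame(subject_id = sched$subject_id[1], bin = h$bin,
               count = tabulate(match(dl$spo2[sel], h$bin), nbins = nrow(h)))
  })
  list(summaries = summaries, hist = do.call(rbind, hist_rows))
}

#' Pool subject-days by strategy into paired per-subject values
#'
#' For each subject and strategy, every outcome is recomputed over the
#' concatenation of all that subject's analyzed days under that strategy
#' (sums of per-day counts and denominators, not means of daily values).
#' Subjects lacking analyzed days under either strategy are dropped from
#' pairing.
#'
#' @param day_summaries Data frame of per-day rows as produced by
#'   [run_study()] or [analyze_logs()] (columns `subject_id`, `strategy`,
#'   `analyzed` plus the sufficient-statistic columns).
#' @return Data frame with one row per subject x metric: `subject_id`,
#'   `metric`, `value_tight`, `value_loose`.
#' @export
pool_by_strategy <- function(day_summaries) {
  ds <- day_summaries[day_summaries$analyzed, , drop = FALSE]
  if (!nrow(ds)) stop("pool_by_strategy: no analyzed days", call. = FALSE)
  num_cols <- c("n_samples", "n_valid", "n_suppl", "n_hypox", "n_hyper",
                "n_in_suppl", "n_normox", "hypox_gt1", "hypox_gt3",
                "hyper_gt1", "hyper_gt3", "n_alarms", "audible_samples",
                "n_manual", "sum_hmed_spo2", "sum_hmed_fio2", "n_hours")
  agg <- stats::aggregate(ds[num_cols],
                          by = list(subject_id = ds$subject_id,
                                    strategy = ds$strategy),
                          FUN = sum)
  vals <- cbind(agg[c("subject_id", "strategy")], derive_metrics(agg))
  both <- intersect(vals$subject_id[vals$strategy == "tight"],
                    vals$subject_id[vals$strategy == "loose"])
  metrics <- setdiff(names(vals), c("subject_id", "strategy"))
  t_rows <- vals[vals$strategy == "tight", ]
  l_rows <- vals[vals$strategy == "loose", ]
  out <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(
      subject_id = both,
      metric = m,
      value_tight = t_rows[[m]][match(both, t_rows$subject_id)],
      value_loose = l_rows[[m]][match(both, l_rows$subject_id)]
    )
  }))
  rownames(out) <- NULL
  out
}

#' Paired analysis of all pooled metrics
#'
#' @param pairs Output of [pool_by_strategy()].
#' @param level Confidence level for the median-difference interval.
#' @param test Passed to [compare_paired()].
#' @return Data frame with one [compare_paired()] row per metric (metrics
#'   with fewer than 2 complete pairs are omitted). Warnings from
#'   degenerate (all-zero-difference) metrics are suppressed.
#' @export
analyze_pairs <- function(pairs, level = 0.95, test = "auto") {
  out <- do.call(rbind, lapply(split(pairs, pairs$metric), function(p) {
    keep <- !is.na(p$value_tight) & !is.na(p$value_loose)
    if (sum(keep) < 2) return(NULL)
    withCallingHandlers(
      compare_paired(p$value_tight[keep], p$value_loose[keep],
                     metric = p$metric[1], level = level, test = test),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }))
  rownames(out) <- NULL
  out
}

#' Cohort histogram: per-bin median and IQR
#'
#' @param hists Data frame of per-subject histograms in long format
#'   (`subject_id`, `bin`, `pct`); subjects missing a bin contribute 0
#'   there.
#' @return Data frame `bin`, `median_pct`, `q1_pct`, `q3_pct`.
#' @export
cohort_histogram <- function(hists) {
  bins <- sort(unique(hists$bin))
  subjects <- unique(hists$subject_id)
  mat <- matrix(0, length(subjects), length(bins),
                dimnames = list(subjects, bins))
  mat[cbind(match(hists$subject_id, subjects), match(hists$bin, bins))] <-
    hists$pct
  q <- apply(mat, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
  data.frame(bin = bins, median_pct = q[2, ], q1_pct = q[1, ],
             q3_pct = q[3, ], row.names = NULL)
}

#' Day accounting of a crossover study
#'
#' Verifies the accounting identity enrolled = analyzed + excluded over a
#' table of study days.
#'
#' @param day_status Data frame with columns `analyzed` (logical),
#'   `strategy` and `reason` (`NA` for analyzed days).
#' @return List with `enrolled_days`, `analyzed_days`,
#'   `analyzed_by_strategy` (named vector), `excluded_days`,
#'   `excluded_by_reason` (named vector) and `identity_ok`.
#' @export
study_accounting <- function(day_status) {
  analyzed <- day_status$analyzed
  by_strat <- table(factor(day_status$strategy[analyzed],
                           levels = c("tight", "loose")))
  by_reason <- table(day_status$reason[!analyzed], useNA = "no")
  out <- list(
    enrolled_days = nrow(day_status),
    analyzed_days = sum(analyzed),
    analyzed_by_strategy = c(by_strat),
    excluded_days = sum(!analyzed),
    excluded_by_reason = c(by_reason)
  )
  out$identity_ok <- out$enrolled_days == out$analyzed_days + out$excluded_days
  out
}

#' Percent reduction between two rates
#'
#' @param from Reference value (e.g. the tight-strategy median).
#' @param to Comparison value (e.g. the loose-strategy median).
#' @return `100 * (from - to) / from`.
#' @examples
#' pct_reduction(5.2, 1.6)   # 69% alarm-rate reduction
#' pct_reduction(11.7, 6.9)  # 41% audible-time reduction
#' @export
pct_reduction <- function(from, to) {
  if (any(from == 0)) stop("pct_reduction: reference value is zero", call. = FALSE)
  100 * (from - to) / from
}

#' Published outcome medians of the reference bedside evaluation
#'
#' Per-strategy outcome medians reported by the clinical crossover
#' evaluation of the two alarm strategies that this package's simulator is
#' calibrated against. Useful as calibration context and for worked-example
#' arithmetic such as [pct_reduction()]; the synthetic cohort reproduces
#' the structure of these outcomes, not their magnitudes.
#'
#' @return Data frame with columns `metric`, `loose`, `tight`.
#' @export
reference_outcomes <- function() {
  data.frame(
    metric = c("spo2_alarms_per_hour", "spo2_share_of_all_alarms_pct",
               "pct_audible", "pct_hypoxemia", "hypox_gt1min_per24h",
               "hypox_gt3min_per24h", "pct_hyperoxemia",
               "hyper_gt1min_per24h", "hyper_gt3min_per24h"),
    loose = c(1.6, 47, 6.9, 0.2, 1.2, 0, 0.2, 0.7, 0),
    tight = c(5.2, 75, 11.7, 0.3, 1.1, 0, 0.2, 0.5, 0)
  )
}

#' Run the full simulated crossover study
#'
#' Generates a cohort, randomizes first-day strategies in balanced blocks
#' of 4, alternates strategies every 24 h, detects alarms with each day's
#' recorded settings, screens protocol violations, excludes subjects who
#' complete fewer than 2 days, pools days by strategy within subject, and
#' performs the paired analyses. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; if given, all report components are
#'   written there (see [write_study_report()]).
#' @return A list of class `study_report`: `roster`, `day_summaries`,
#'   `pairs`, `comparisons`, `table3`, `table4`, `fig1_histogram`,
#'   `fig2_daily_alarm_rates`, `subject_histograms`, `accounting`,
#'   `config`.
#' @export
run_study <- function(config, outdir = NULL) {
  validate_sim_config(config)
  plan <- cohort_plan(config)
  pieces <- lapply(seq_along(plan), function(s) {
    series <- generate_subject(config, s, n_days = nrow(plan[[s]]))
    summarize_subject(series, plan[[s]])
  })
  day_summaries <- do.call(rbind, lapply(pieces, `[[`, "summaries"))
  rownames(day_summaries) <- NULL
  hist_counts <- do.call(rbind, lapply(pieces, `[[`, "hist"))
  roster <- data.frame(
    subject_id = vapply(plan, function(p) p$subject_id[1], ""),
    first_day = vapply(plan, function(p) p$strategy[1], ""),
    days_completed = vapply(plan, nrow, 0L),
    exited_early = vapply(plan, nrow, 0L) < config$study_days,
    excluded_incomplete = vapply(plan, nrow, 0L) < 2
  )
  report <- report_from_summaries(day_summaries, hist_counts)
  report$roster <- roster
  report$config <- config
  if (!is.null(outdir)) write_study_report(report, outdir)
  report
}

#' Assemble the study report from day summaries
#'
#' Performs pooling, paired analysis and the table/figure analogues; the
#' back end shared by [run_study()] and the file-based pipeline.
#'
#' @param day_summaries Per-day summary rows (see [analyze_logs()]).
#' @param hist_counts Per-subject-day SpO2 bin counts in long format
#'   (`subject_id`, `bin`, `count`), or `NULL`.
#' @return A `study_report` (without roster/config, which [run_study()]
#'   adds).
#' @export
report_from_summaries <- function(day_summaries, hist_counts = NULL) {
  pairs <- pool_by_strategy(day_summaries)
  comparisons <- analyze_pairs(pairs)

  subj_hist <- if (!is.null(hist_counts) && nrow(hist_counts)) {
    agg <- stats::aggregate(count ~ subject_id + bin, data = hist_counts,
                            FUN = sum)
    tot <- stats::aggregate(count ~ subject_id, data = agg, FUN = sum)
    agg$pct <- 100 * agg$count / tot$count[match(agg$subject_id, tot$subject_id)]
    agg[order(agg$subject_id, agg$bin), c("subject_id", "bin", "pct")]
  } else {
    data.frame(subject_id = character(), bin = integer(), pct = numeric())
  }
  fig1 <- if (nrow(subj_hist)) cohort_histogram(subj_hist) else
    data.frame(bin = integer(), median_pct = numeric(),
               q1_pct = numeric(), q3_pct = numeric())

  an <- day_summaries[day_summaries$analyzed, , drop = FALSE]
  fig2 <- data.frame(
    subject_id = an$subject_id, day = an$day, strategy = an$strategy,
    alarms_per_hour = an$n_alarms / (an$n_valid * 5 / 3600)
  )
  structure(list(
    day_summaries = day_summaries,
    pairs = pairs,
    comparisons = comparisons,
    table3 = strategy_table(pairs, comparisons, TABLE3_METRICS),
    table4 = strategy_table(pairs, comparisons, TABLE4_METRICS),
    fig1_histogram = fig1,
    fig2_daily_alarm_rates = fig2,
    subject_histograms = subj_hist,
    accounting = study_accounting(day_summaries)
  ), class = "study_report")
}

## median (IQR) per strategy + paired p, mirroring the published layout
strategy_table <- function(pairs, comparisons, metrics) {
  fmt <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
  }
  do.call(rbind, lapply(metrics, function(m) {
    p <- pairs[pairs$metric == m, ]
    cmp <- comparisons[comparisons$metric == m, ]
    data.frame(
      metric = m,
      loose = fmt(p$value_loose),
      tight = fmt(p$value_tight),
      p_value = if (nrow(cmp)) signif(cmp$p_value, 3) else NA_real_,
      test = if (nrow(cmp)) cmp$test_used else NA_character_
    )
  }))
}

#' Simulate a cohort to disk
#'
#' Writes per-subject monitoring logs (`logs/S01.csv`, ...), the strategy
#' schedule with assigned and recorded device settings (`schedule.csv`)
#' and the configuration (`config.yaml`) into `outdir`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
simulate_cohort <- function(config, outdir) {
  validate_sim_config(config)
  dir.create(file.path(outdir, "logs"), recursive = TRUE, showWarnings = FALSE)
  plan <- cohort_plan(config)
  for (s in seq_along(plan)) {
    series <- generate_subject(config, s, n_days = nrow(plan[[s]]))
    write_oxi_csv(series, file.path(outdir, "logs",
                                    paste0(plan[[s]]$subject_id[1], ".csv")))
  }
  utils::write.csv(do.call(rbind, plan), file.path(outdir, "schedule.csv"),
                   row.names = FALSE)
  write_sim_config(config, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' Analyze monitoring logs from disk
#'
#' Reads the per-subject CSV logs and the schedule written by
#' [simulate_cohort()] (or assembled from real device exports in the same
#' layout), screens protocol violations, and computes per-day summaries.
#'
#' @param dir Directory containing `logs/` and `schedule.csv`.
#' @return List with `day_summaries` and `hist_counts`, ready for
#'   [report_from_summaries()].
#' @export
analyze_logs <- function(dir) {
  sched <- utils::read.csv(file.path(dir, "schedule.csv"),
                           stringsAsFactors = FALSE)
  pieces <- lapply(split(sched, sched$subject_id), function(ss) {
    ss <- ss[order(ss$day), , drop = FALSE]
    series <- read_oxi_csv(file.path(dir, "logs", paste0(ss$subject_id[1], ".csv")),
                           subject_id = ss$subject_id[1])
    summarize_subject(series, ss)
  })
  day_summaries <- do.call(rbind, lapply(pieces, `[[`, "summaries"))
  rownames(day_summaries) <- NULL
  day_summaries <- day_summaries[order(day_summaries$subject_id,
                                       day_summaries$day), , drop = FALSE]
  rownames(day_summaries) <- NULL
  list(day_summaries = day_summaries,
       hist_counts = do.call(rbind, lapply(pieces, `[[`, "hist")))
}

#' @export
print.study_report <- function(x, ...) {
  acc <- x$accounting
  cat(sprintf(
    "<study_report> %d days enrolled = %d analyzed (%d tight / %d loose) + %d excluded\n",
    acc$enrolled_days, acc$analyzed_days,
    acc$analyzed_by_strategy[["tight"]], acc$analyzed_by_strategy[["loose"]],
    acc$excluded_days
  ))
  cat("Outcomes (median (IQR) by strategy):\n")
  print(x$table4, row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `roster.csv`, `day_summaries.csv`, `paired_comparisons.csv`,
#' `table3.csv`, `table4.csv`, `fig1_histogram.csv`,
#' `fig2_daily_alarm_rates.csv`, `subject_histograms.csv` and
#' `accounting.csv` into `outdir`; with `format = "json"` a single
#' `study_report.json` instead.
#'
#' @param report A `study_report` from [run_study()].
#' @param outdir Output directory (created if absent).
#' @param format `"csv"` or `"json"` (the latter needs the jsonlite
#'   package).
#' @return `outdir`, invisibly.
#' @export
write_study_report <- function(report, outdir, format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  parts <- list(
    day_summaries = report$day_summaries,
    paired_comparisons = report$comparisons,
    table3 = report$table3,
    table4 = report$table4,
    fig1_histogram = report$fig1_histogram,
    fig2_daily_alarm_rates = report$fig2_daily_alarm_rates,
    subject_histograms = report$subject_histograms,
    accounting = data.frame(
      item = c("enrolled_days", "analyzed_days", "analyzed_tight",
               "analyzed_loose", "excluded_days"),
      value = c(report$accounting$enrolled_days,
                report$accounting$analyzed_days,
                report$accounting$analyzed_by_strategy[["tight"]],
                report$accounting$analyzed_by_strategy[["loose"]],
                report$accounting$excluded_days)
    )
  )
  if (!is.null(report$roster)) parts$roster <- report$roster
  if (format == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("json output requires the jsonlite package", call. = FALSE)
    }
    jsonlite::write_json(parts, file.path(outdir, "study_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    for (nm in names(parts)) {
      utils::write.csv(parts[[nm]], file.path(outdir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(outdir)
}
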