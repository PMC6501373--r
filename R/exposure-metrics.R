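## Oxygenation-exposure outcomes on 5-second monitoring logs.
##
## Conventions: SpO2 is integer-valued (device resolution), so "> 98%"
## means spo2 >= 99 and comparisons are exact integer comparisons. All
## "% time" figures use valid monitored samples as denominator. Room-air
## detection (FiO2 = 0.21) uses a +/- 0.005 tolerance to absorb floating
## representation of 21%. Episodes interrupted by invalid samples are
## split: an invalid sample never extends an episode.

FIO2_TOL <- 0.005

suppl_o2 <- function(series) series$fio2 > 0.21 + FIO2_TOL
room_air <- function(series) abs(series$fio2 - 0.21) <= FIO2_TOL

## per-sample predicate for an episode kind
episode_predicate <- function(series, kind) {
  switch(kind,
    hypoxemia = series$valid & series$spo2 < 80,
    hyperoxemia = series$valid & series$spo2 > 98 & suppl_o2(series),
    stop(sprintf("unknown episode kind '%s'", kind), call. = FALSE)
  )
}

#' Find hypoxemia or hyperoxemia episodes
#'
#' Hypoxemia is SpO2 below 80%; hyperoxemia is SpO2 above 98% while on
#' supplemental oxygen (time at FiO2 = 0.21 is excluded). Episodes are
#' maximal consecutive runs of the predicate over valid samples.
#'
#' @param series An [oxi_series()].
#' @param kind `"hypoxemia"` or `"hyperoxemia"`.
#' @return Data frame with columns `kind`, `start`, `end` (half-open sample
#'   indices) and `duration_s = (end - start) * 5`.
#' @export
find_episodes <- function(series, kind = c("hypoxemia", "hyperoxemia")) {
  kind <- match.arg(kind)
  check_grid(series)
  pred <- episode_predicate(series, kind)
  r <- rle(pred)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values)
  out <- data.frame(
    kind = rep(kind, length(hit)),
    start = starts[hit],
    end = ends[hit] + 1L
  )
  out$duration_s <- (out$end - out$start) * 5
  out
}

#' Percent time at an SpO2 extreme
#'
#' @inheritParams find_episodes
#' @return Percent of valid monitored samples satisfying the predicate.
#' @export
prevalence <- function(series, kind = c("hypoxemia", "hyperoxemia")) {
  kind <- match.arg(kind)
  nv <- sum(series$valid)
  if (nv == 0) stop("prevalence: no valid samples", call. = FALSE)
  100 * sum(episode_predicate(series, kind)) / nv
}

#' Rate of prolonged episodes
#'
#' @param episodes Result of [find_episodes()].
#' @param series The series the episodes came from.
#' @param min_duration Threshold in seconds; episodes strictly longer are
#'   counted (60 for "> 1 min", 180 for "> 3 min").
#' @return Episodes per 24 h of valid monitored time.
#' @export
episode_rate <- function(episodes, series, min_duration = 60) {
  days <- valid_seconds(series) / 86400
  if (days <= 0) stop("episode_rate: no valid monitored time", call. = FALSE)
  sum(episodes$duration_s > min_duration) / days
}

#' Percent time in normoxemia
#'
#' Normoxemia is SpO2 between 86 and 96%, or above 96% while breathing
#' room air (FiO2 = 0.21).
#'
#' @param series An [oxi_series()].
#' @return Percent of valid monitored samples.
#' @export
normoxemia_pct <- function(series) {
  nv <- sum(series$valid)
  if (nv == 0) stop("normoxemia_pct: no valid samples", call. = FALSE)
  ok <- series$valid &
    ((series$spo2 >= 86 & series$spo2 <= 96) |
       (series$spo2 > 96 & room_air(series)))
  100 * sum(ok) / nv
}

#' Percent time with SpO2 86--96% during supplemental oxygen
#'
#' Restricted to valid samples with FiO2 above 0.21; `NA` if the subject
#' never received supplemental oxygen.
#'
#' @param series An [oxi_series()].
#' @return Percent of the supplemental-oxygen subset, or `NA_real_`.
#' @export
in_range_suppl_o2_pct <- function(series) {
  sel <- series$valid & suppl_o2(series)
  if (!any(sel)) return(NA_real_)
  100 * sum(sel & series$spo2 >= 86 & series$spo2 <= 96) / sum(sel)
}

#' Mean of hourly median SpO2 and FiO2
#'
#' The series is partitioned into consecutive wall-clock hours anchored at
#' the series start; per hour the median over valid samples is taken, and
#' the unweighted mean over hours with at least one valid sample is
#' reported.
#'
#' @param series An [oxi_series()].
#' @return Named numeric vector `c(spo2 = , fio2 = )`.
#' @export
hourly_median_summary <- function(series) {
  check_grid(series)
  hour <- (seq_len(nrow(series)) - 1L) %/% SAMPLES_PER_HOUR
  v <- series$valid
  if (!any(v)) stop("hourly_median_summary: no valid samples", call. = FALSE)
  med_s <- tapply(series$spo2[v], hour[v], stats::median)
  med_f <- tapply(series$fio2[v], hour[v], stats::median)
  c(spo2 = mean(med_s), fio2 = mean(med_f))
}

#' SpO2 histogram during supplemental oxygen
#'
#' Percent of time per 1%-wide integer SpO2 bin, restricted to valid
#' samples with FiO2 above 0.21.
#'
#' @param series An [oxi_series()].
#' @param bins Integer bin values to tabulate; defaults to the observed
#'   range.
#' @return Data frame with columns `bin` and `pct`; `pct` sums to 100 over
#'   the supplemental-oxygen subset (all rows 0 if that subset is empty).
#' @export
spo2_histogram <- function(series, bins = NULL) {
  sel <- series$valid & suppl_o2(series)
  x <- series$spo2[sel]
  if (is.null(bins)) {
    bins <- if (length(x)) seq(min(x), max(x)) else integer()
  }
  cnt <- tabulate(match(x, bins), nbins = length(bins))
  pct <- if (length(x)) 100 * cnt / length(x) else rep(0, length(bins))
  data.frame(bin = as.integer(bins), pct = pct)
}

#' Manual FiO2 adjustment frequency
#'
#' @param series An [oxi_series()].
#' @return Caregiver FiO2 adjustments per elapsed (wall-clock) day.
#' @export
manual_adjustment_count <- function(series) {
  days <- nrow(series) * 5 / 86400
  sum(series$manual_adjustment) / days
}

#' Summarize one monitoring series
#'
#' Computes every exposure outcome, optionally joined with the alarm
#' metrics for a strategy.
#'
#' @param series An [oxi_series()].
#' @param strategy Optional [alarm_strategy()]; if supplied, alarm rate and
#'   audible fraction are included.
#' @return One-row data frame with the exposure outcomes
#'   (`pct_hypoxemia`, `pct_hyperoxemia`, episode rates per 24 h,
#'   `pct_in_86_96_suppl_o2`, `pct_normoxemia`, means of hourly medians,
#'   `manual_adjustments_per_day`, `pct_invalid`, and if a strategy is
#'   given `alarms_per_hour` and `pct_audible`).
#' @export
exposure_summary <- function(series, strategy = NULL) {
  hypo <- find_episodes(series, "hypoxemia")
  hyper <- find_episodes(series, "hyperoxemia")
  hm <- hourly_median_summary(series)
  out <- data.frame(
    subject_id = attr(series, "subject_id") %||% NA_character_,
    pct_hypoxemia = prevalence(series, "hypoxemia"),
    pct_hyperoxemia = prevalence(series, "hyperoxemia"),
    hypox_gt1min_per24h = episode_rate(hypo, series, 60),
    hypox_gt3min_per24h = episode_rate(hypo, series, 180),
    hyper_gt1min_per24h = episode_rate(hyper, series, 60),
    hyper_gt3min_per24h = episode_rate(hyper, series, 180),
    pct_in_86_96_suppl_o2 = in_range_suppl_o2_pct(series),
    pct_normoxemia = normoxemia_pct(series),
    mean_hourly_median_spo2 = unname(hm["spo2"]),
    mean_hourly_median_fio2 = unname(hm["fio2"]),
    manual_adjustments_per_day = manual_adjustment_count(series),
    pct_invalid = 100 * mean(!series$valid)
  )
  if (!is.null(strategy)) {
    ev <- detect_alarms(series, strategy)
    out$alarms_per_hour <- alarm_rate(ev, series)
    out$pct_audible <- audible_fraction(ev, series)
  }
  out
}
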