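## Threshold-plus-persistence-delay alarm logic.
##
## An alarm activates at the first sample where the violation condition
## (valid AND spo2 below the low threshold, or valid AND spo2 above the high
## threshold) has held continuously for at least the strategy's delay, and
## deactivates at the first subsequent valid in-range sample. Invalid
## samples pause the persistence timer by default (they neither satisfy nor
## reset the condition); `invalid_resets = TRUE` makes them reset it.
## All intervals are half-open [start, end) in 1-based sample indices;
## durations are (end - start) * 5 seconds.

#' Define an alarm strategy
#'
#' A strategy is a (low threshold, high threshold, persistence delay)
#' triple governing when the SpO2 alarm sounds.
#'
#' @param low_alarm Low SpO2 alarm threshold (%); the alarm condition is
#'   `spo2 < low_alarm`.
#' @param high_alarm High SpO2 alarm threshold (%); condition
#'   `spo2 > high_alarm`.
#' @param delay Persistence delay in seconds; must be a nonnegative
#'   multiple of the 5-s sampling interval.
#' @param name Strategy label (`"tight"`, `"loose"` or `"custom"`).
#' @return A list of class `alarm_strategy`.
#' @export
alarm_strategy <- function(low_alarm, high_alarm, delay,
                           name = c("custom", "tight", "loose")) {
  name <- match.arg(name)
  if (!(low_alarm < high_alarm)) {
    stop("alarm_strategy: low_alarm must be below high_alarm", call. = FALSE)
  }
  if (delay < 0 || delay %% 5 != 0) {
    stop("alarm_strategy: delay must be a nonnegative multiple of 5 s",
         call. = FALSE)
  }
  structure(list(name = name, low_alarm = low_alarm, high_alarm = high_alarm,
                 delay = delay), class = "alarm_strategy")
}

#' @export
print.alarm_strategy <- function(x, ...) {
  cat(sprintf("<alarm_strategy> %s: low < %g%%, high > %g%%, delay %g s\n",
              x$name, x$low_alarm, x$high_alarm, x$delay))
  invisible(x)
}

#' Derive the tight or loose strategy from a target range
#'
#' The tight strategy triggers just outside the target range (1% beyond
#' each bound) with a 30-s delay; the loose strategy sets each threshold 2%
#' wider than tight (3% beyond the range) with a 90-s delay. With the
#' default 88--95% range this yields (87, 96, 30 s) and (85, 98, 90 s).
#'
#' @param range A [target_range()].
#' @param kind `"tight"` or `"loose"`.
#' @return An [alarm_strategy()].
#' @examples
#' strategy_from_target(target_range(), "tight")  # 87 / 96 / 30 s
#' strategy_from_target(target_range(), "loose")  # 85 / 98 / 90 s
#' @export
strategy_from_target <- function(range, kind = c("tight", "loose")) {
  kind <- match.arg(kind)
  if (!inherits(range, "target_range")) {
    stop("strategy_from_target: need a target_range", call. = FALSE)
  }
  off <- if (kind == "tight") 1 else 3
  delay <- if (kind == "tight") 30 else 90
  low <- range$low - off
  high <- range$high + off
  if (low < 1 || high > 100) {
    stop("strategy_from_target: thresholds outside [1, 100]", call. = FALSE)
  }
  alarm_strategy(low, high, delay, name = kind)
}

#' Detect SpO2 alarm events
#'
#' Scans a monitoring series for low and high threshold violations and
#' returns one event per alarm activation. A violation run shorter than the
#' persistence delay produces no event. Low and high alarms are tracked
#' independently.
#'
#' @param series An [oxi_series()] on a uniform 5-s grid.
#' @param strategy An [alarm_strategy()].
#' @param invalid_resets If `TRUE`, an invalid sample resets the
#'   persistence timer; by default the timer pauses across invalid runs.
#' @return A data frame of class `alarm_events` with columns `kind`
#'   (`"low"`/`"high"`), `start` (activation sample index, i.e. the sample
#'   at which the delay is satisfied), `end` (exclusive; the first
#'   subsequent valid in-range sample, or one past the series end) and
#'   `duration_s`.
#' @export
detect_alarms <- function(series, strategy, invalid_resets = FALSE) {
  check_grid(series)
  if (!inherits(strategy, "alarm_strategy")) {
    stop("detect_alarms: need an alarm_strategy", call. = FALSE)
  }
  low <- detect_kind(series$valid & series$spo2 < strategy$low_alarm,
                     series$valid, strategy$delay, invalid_resets)
  high <- detect_kind(series$valid & series$spo2 > strategy$high_alarm,
                      series$valid, strategy$delay, invalid_resets)
  ev <- rbind(
    if (nrow(low)) cbind(kind = "low", low) else NULL,
    if (nrow(high)) cbind(kind = "high", high) else NULL
  )
  if (is.null(ev)) {
    ev <- data.frame(kind = character(), start = integer(), end = integer())
  }
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  ev$duration_s <- (ev$end - ev$start) * 5
  class(ev) <- c("alarm_events", "data.frame")
  ev
}

## run-length detection for one alarm kind.
## viol: violation condition per sample (FALSE at invalid samples);
## delay seconds -> k = max(1, ceiling(delay/5)) consecutive condition
## samples required before activation.
detect_kind <- function(viol, valid, delay, invalid_resets) {
  k <- max(1L, as.integer(ceiling(delay / 5)))
  n <- length(viol)
  if (invalid_resets) {
    ## an invalid sample breaks the timer run, but deactivation still
    ## waits for a valid in-range sample, so events can bridge dropouts
    idx <- seq_len(n)
    cond <- viol
  } else {
    ## timer pauses: runs over the valid subsequence only
    idx <- which(valid)
    cond <- viol[idx]
  }
  if (!length(idx)) {
    return(data.frame(start = integer(), end = integer()))
  }
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) {
    return(data.frame(start = integer(), end = integer()))
  }
  act <- idx[starts[hit] + k - 1L]   # delay satisfied at this sample
  if (invalid_resets) {
    ## first valid in-range sample after each run end
    inrange <- which(valid & !viol)
    pos <- findInterval(idx[ends[hit]], inrange) + 1L
    dea <- ifelse(pos > length(inrange), n + 1L,
                  inrange[pmin(pos, length(inrange))])
    ## activations occurring while a previous event is still audible merge
    keep <- c(TRUE, act[-1] >= cummax(dea)[-length(dea)])
    act <- act[keep]
    dea <- dea[keep]
  } else {
    ## the next valid sample after a run is in-range by construction
    nxt <- ends[hit] + 1L
    dea <- ifelse(nxt > length(idx), n + 1L, idx[pmin(nxt, length(idx))])
  }
  data.frame(start = as.integer(act), end = as.integer(dea))
}

#' Alarm frequency
#'
#' @param events Result of [detect_alarms()] on `series`.
#' @param series The monitoring series the events came from.
#' @return Alarms per hour of valid monitored time.
#' @export
alarm_rate <- function(events, series) {
  hours <- valid_seconds(series) / 3600
  if (hours <= 0) stop("alarm_rate: no valid monitored time", call. = FALSE)
  nrow(events) / hours
}

#' Audible alarm burden
#'
#' Percentage of monitored time with the SpO2 alarm annunciating. An
#' event's audible interval starts at activation (end of the satisfied
#' delay) and ends at deactivation.
#'
#' @inheritParams alarm_rate
#' @return Percent of valid monitored time.
#' @export
audible_fraction <- function(events, series) {
  secs <- valid_seconds(series)
  if (secs <= 0) stop("audible_fraction: no valid monitored time", call. = FALSE)
  100 * sum(events$duration_s) / secs
}

#' Write alarm events to CSV
#'
#' Columns: `subject_id, day, kind, start_s, end_s, duration_s`; `day` is
#' the 1-based 24-h block containing the activation.
#'
#' @param events An `alarm_events` data frame.
#' @param series The series the events came from (for subject id).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alarm_csv <- function(events, series, path) {
  out <- data.frame(
    subject_id = rep(attr(series, "subject_id") %||% "S1", nrow(events)),
    day = (events$start - 1L) %/% SAMPLES_PER_DAY + 1L,
    kind = events$kind,
    start_s = (events$start - 1L) * 5,
    end_s = (events$end - 1L) * 5,
    duration_s = events$duration_s
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
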