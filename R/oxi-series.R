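#' SpO2 target range
#'
#' The clinician-set saturation interval that the closed-loop FiO2 controller
#' aims for. The prevailing setting in the unit this package models is
#' 88--95%.
#'
#' @param low,high Lower and upper bound of the target range, in % SpO2.
#' @return An object of class `target_range`: a list with elements `low`
#'   and `high`.
#' @examples
#' target_range()        # 88-95
#' target_range(90, 94)
#' @export
target_range <- function(low = 88, high = 95) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || is.na(low) || is.na(high)) {
    stop("target_range: 'low' and 'high' must be single numbers", call. = FALSE)
  }
  if (!(low > 0 && low < high && high <= 100)) {
    stop("target_range: need 0 < low < high <= 100", call. = FALSE)
  }
  structure(list(low = low, high = high), class = "target_range")
}

#' @export
print.target_range <- function(x, ...) {
  cat(sprintf("SpO2 target range: %g-%g%%\n", x$low, x$high))
  invisible(x)
}

#' Construct a monitoring series
#'
#' An `oxi_series` is a uniformly sampled (5-second) per-subject log of
#' pulse-oximetry saturation and inspired-oxygen fraction, the universal
#' input of all downstream computations. Invalid samples (signal dropout)
#' are present on the grid but flagged, so the grid has no gaps; their SpO2
#' column carries the last valid reading but they are excluded from every
#' metric and from alarm detection.
#'
#' @param spo2 Integer-valued SpO2 in percent (values are rounded to the
#'   device's 1% resolution).
#' @param fio2 Inspired oxygen fraction, in `[0.21, 1]`.
#' @param valid Logical vector flagging samples with a usable signal.
#' @param manual_adjustment Logical vector flagging samples at which a
#'   caregiver changed the baseline FiO2.
#' @param subject_id Subject identifier.
#' @param start_time Timestamp (seconds) of the first sample.
#' @param sample_interval Sampling interval in seconds; fixed at 5.
#' @return A data frame of class `oxi_series` with columns `timestamp_s`,
#'   `spo2`, `fio2`, `valid`, `manual_adjustment`.
#' @export
oxi_series <- function(spo2, fio2, valid = rep(TRUE, length(spo2)),
                       manual_adjustment = rep(FALSE, length(spo2)),
                       subject_id = "S1", start_time = 0,
                       sample_interval = 5) {
  n <- length(spo2)
  if (n == 0L) stop("oxi_series: empty series", call. = FALSE)
  if (sample_interval != 5) {
    stop("oxi_series: sample_interval must be 5 seconds", call. = FALSE)
  }
  if (length(fio2) != n || length(valid) != n || length(manual_adjustment) != n) {
    stop("oxi_series: all columns must have the same length", call. = FALSE)
  }
  spo2 <- as.integer(round(spo2))
  if (any(valid & (spo2 < 0 | spo2 > 100), na.rm = TRUE)) {
    stop("oxi_series: valid spo2 outside [0, 100]", call. = FALSE)
  }
  if (any(fio2 < 0.21 - 1e-9 | fio2 > 1 + 1e-9, na.rm = TRUE)) {
    stop("oxi_series: fio2 outside [0.21, 1.0]", call. = FALSE)
  }
  out <- data.frame(
    timestamp_s = start_time + sample_interval * (seq_len(n) - 1),
    spo2 = spo2,
    fio2 = fio2,
    valid = as.logical(valid),
    manual_adjustment = as.logical(manual_adjustment)
  )
  attr(out, "subject_id") <- subject_id
  attr(out, "sample_interval") <- sample_interval
  class(out) <- c("oxi_series", "data.frame")
  out
}

#' @export
print.oxi_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "<oxi_series> subject %s: %d samples (%.2f h), %.1f%% valid\n",
    attr(x, "subject_id"), n, n * 5 / 3600, 100 * mean(x$valid)
  ))
  invisible(x)
}

## stop unless the series sits on an unbroken 5-s grid
check_grid <- function(series) {
  if (!inherits(series, "oxi_series")) {
    stop("expected an 'oxi_series' object", call. = FALSE)
  }
  dt <- diff(series$timestamp_s)
  if (length(dt) && any(dt != 5)) {
    stop("series is not on a uniform 5-s grid", call. = FALSE)
  }
  invisible(series)
}

## seconds of valid monitoring
valid_seconds <- function(series) sum(series$valid) * 5

#' Split a series into consecutive 24-h days
#'
#' @param series An [oxi_series()].
#' @return A list of `oxi_series`, one per complete or partial 24-h block,
#'   anchored at the series start.
#' @export
split_days <- function(series) {
  check_grid(series)
  per_day <- 86400 / 5
  day <- (seq_len(nrow(series)) - 1) %/% per_day
  lapply(split(seq_len(nrow(series)), day), function(idx) {
    out <- series[idx, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "subject_id") <- attr(series, "subject_id")
    attr(out, "sample_interval") <- 5
    class(out) <- c("oxi_series", "data.frame")
    out
  })
}

#' Write a monitoring series to CSV
#'
#' Columns are `timestamp_s, spo2, fio2, valid, manual_adjustment` with a
#' mandatory header row; the SpO2 field of invalid samples is written empty.
#'
#' @param series An [oxi_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_oxi_csv <- function(series, path) {
  check_grid(series)
  out <- as.data.frame(series)
  out$spo2 <- ifelse(out$valid, out$spo2, NA_integer_)
  out$valid <- ifelse(out$valid, "TRUE", "FALSE")
  out$manual_adjustment <- ifelse(out$manual_adjustment, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a monitoring series from CSV
#'
#' Inverse of [write_oxi_csv()]. Missing SpO2 fields are treated as invalid
#' samples and filled with the last valid reading (they stay flagged and are
#' never counted in metrics).
#'
#' @param path CSV file path.
#' @param subject_id Subject identifier to attach; defaults to the file name.
#' @return An [oxi_series()].
#' @export
read_oxi_csv <- function(path, subject_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_s", "spo2", "fio2", "valid", "manual_adjustment")
  if (!all(need %in% names(df))) {
    stop("read_oxi_csv: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  valid <- as.logical(df$valid) & !is.na(df$spo2)
  spo2 <- locf(df$spo2)
  if (anyNA(spo2)) spo2[is.na(spo2)] <- 0L  # series opening with dropout
  if (is.null(subject_id)) {
    subject_id <- sub("\\.csv$", "", basename(path))
  }
  oxi_series(spo2, df$fio2, valid, as.logical(df$manual_adjustment),
             subject_id = subject_id, start_time = df$timestamp_s[1])
}

## last-observation-carried-forward for a numeric vector
locf <- function(x) {
  ok <- !is.na(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  out <- x
  has <- idx > 0L
  out[has] <- x[idx[has]]
  out
}
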