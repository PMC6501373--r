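# Fixture builders and brute-force oracles, deliberately independent of
# the package's run-length implementations.

make_series <- function(spo2, fio2 = 0.30, valid = TRUE, manual = FALSE,
                        id = "T1") {
  n <- length(spo2)
  oxi_series(spo2,
             fio2 = rep_len(fio2, n),
             valid = rep_len(valid, n),
             manual_adjustment = rep_len(manual, n),
             subject_id = id)
}

# a short random series: integer random-walk SpO2, occasional invalid
# samples, FiO2 mixing room air and supplemental oxygen
random_series <- function(n = 200, p_invalid = 0.1) {
  spo2 <- pmin(100, pmax(60, 92 + cumsum(sample(-3:3, n, replace = TRUE))))
  fio2 <- ifelse(runif(n) < 0.25, 0.21, round(runif(n, 0.25, 0.6), 2))
  valid <- runif(n) > p_invalid
  make_series(spo2, fio2 = fio2, valid = valid)
}

# per-sample state-machine alarm scan for one kind
oracle_alarms_kind <- function(viol, valid, delay_s, invalid_resets = FALSE) {
  k <- max(1, ceiling(delay_s / 5))
  events <- list()
  count <- 0
  active <- FALSE
  act <- NA_integer_
  for (i in seq_along(viol)) {
    if (!valid[i]) {
      if (invalid_resets) count <- 0
      next
    }
    if (viol[i]) {
      count <- count + 1
      if (!active && count >= k) {
        active <- TRUE
        act <- i
      }
    } else {
      count <- 0
      if (active) {
        events[[length(events) + 1]] <- c(act, i)
        active <- FALSE
      }
    }
  }
  if (active) events[[length(events) + 1]] <- c(act, length(viol) + 1)
  if (!length(events)) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- do.call(rbind, events)
  data.frame(start = m[, 1], end = m[, 2])
}

oracle_alarms <- function(series, strategy, invalid_resets = FALSE) {
  low <- oracle_alarms_kind(series$valid & series$spo2 < strategy$low_alarm,
                            series$valid, strategy$delay, invalid_resets)
  high <- oracle_alarms_kind(series$valid & series$spo2 > strategy$high_alarm,
                             series$valid, strategy$delay, invalid_resets)
  ev <- rbind(
    if (nrow(low)) cbind(kind = "low", low) else NULL,
    if (nrow(high)) cbind(kind = "high", high) else NULL
  )
  if (is.null(ev)) {
    return(data.frame(kind = character(), start = integer(), end = integer()))
  }
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# per-sample episode scan
oracle_episodes <- function(series, kind) {
  pred <- if (kind == "hypoxemia") {
    series$valid & series$spo2 < 80
  } else {
    series$valid & series$spo2 > 98 & series$fio2 > 0.215
  }
  events <- list()
  start <- NA_integer_
  for (i in seq_along(pred)) {
    if (pred[i] && is.na(start)) start <- i
    if (!pred[i] && !is.na(start)) {
      events[[length(events) + 1]] <- c(start, i)
      start <- NA_integer_
    }
  }
  if (!is.na(start)) events[[length(events) + 1]] <- c(start, length(pred) + 1)
  if (!length(events)) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- do.call(rbind, events)
  data.frame(start = m[, 1], end = m[, 2])
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  all_w <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[seq_len(n)]
    sum(r[signs == 1])
  }, numeric(1))
  min(1, 2 * min(mean(all_w <= w), mean(all_w >= w)))
}

# distribution-free Hodges-Lehmann interval by enumerating the signed-rank
# null distribution (independent of qsignrank)
oracle_hl_ci <- function(d, level = 0.95) {
  n <- length(d)
  w <- sort(as.vector(outer(d, d, "+"))[as.vector(upper.tri(matrix(0, n, n),
                                                            diag = TRUE))] / 2)
  m <- n * (n + 1) / 2
  all_v <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    sum(seq_len(n)[signs == 1])
  }, numeric(1))
  cdf <- function(k) mean(all_v <= k)
  alpha <- 1 - level
  k <- 0
  while (cdf(k) <= alpha / 2) k <- k + 1
  k <- max(1, k)  # largest k with P(V <= k-1) <= alpha/2
  c(estimate = stats::median(w), low = w[k], high = w[m - k + 1])
}
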