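## Synthetic monitoring-log generator.
##
## The SpO2 process is a constant baseline at the target-range midpoint plus
## AR(1) noise (the mean reversion of which emulates the controller's
## pull-back toward range), with superimposed desaturation dips and
## hyperoxemic drifts. Event arrivals are Poisson; each event deflects the
## signal along a half-sine profile so that onset, nadir and recovery are
## smooth. FiO2 is a linearly declining subject baseline plus a first-order
## controller response proportional to the smoothed SpO2 deficit.

SAMPLES_PER_DAY <- 86400L / 5L   # 17,280 five-second samples
SAMPLES_PER_HOUR <- 3600L / 5L

## per-subject RNG stream offsets (all derived seeds stay below 2^31)
subject_seed <- function(seed, subject_index, stream = 0L) {
  (as.integer(seed) + 9973L * as.integer(subject_index) + 131L * stream) %%
    2147483647L
}

#' Generate one subject's monitoring log
#'
#' Produces a deterministic (given `config$seed` and `subject_index`)
#' synthetic 5-second SpO2/FiO2 log with the statistical structure the
#' downstream analysis assumes: saturations mostly inside the target range,
#' Poisson desaturation events with mixture-distributed durations, rare
#' hyperoxemic drifts, flagged signal dropouts, and caregiver-adjustment
#' flags. The realized event list is attached as attribute `"events"`
#' (columns `kind`, `start`, `duration_s`) for validation of event rates.
#'
#' @param config A [sim_config()].
#' @param subject_index Subject number in `1:config$n_subjects`.
#' @param n_days Number of days to generate; defaults to `config$study_days`.
#' @return An [oxi_series()] of `n_days * 17280` samples.
#' @export
generate_subject <- function(config, subject_index, n_days = config$study_days) {
  validate_sim_config(config)
  if (subject_index < 1 || subject_index > config$n_subjects) {
    stop("generate_subject: subject_index out of range", call. = FALSE)
  }
  n <- as.integer(n_days) * SAMPLES_PER_DAY
  tr <- config$target_range
  mid <- (tr$low + tr$high) / 2

  with_seed(subject_seed(config$seed, subject_index), {
    ## baseline + AR(1) noise; phi from the controller time constant
    phi <- exp(-5 / config$controller_timeconstant)
    noise <- if (config$noise_sd > 0) {
      innov <- stats::rnorm(n, 0, config$noise_sd * sqrt(1 - phi^2))
      as.numeric(stats::filter(innov, phi, method = "recursive"))
    } else {
      numeric(n)
    }

    ## desaturation events
    desat <- place_events(n, config$desat_rate,
                          function(k) draw_desat_durations(k, config$desat_duration))
    defl_down <- event_deflection(n, desat,
                                  depth = stats::runif(nrow(desat),
                                                       max(0, config$desat_depth - 3),
                                                       config$desat_depth + 3))

    ## hyperoxemic drifts: lift the signal a little above the high bound
    hyper <- place_events(n, config$hyper_rate,
                          function(k) stats::rlnorm(k, log(25), 0.5))
    defl_up <- event_deflection(n, hyper,
                                depth = (tr$high - mid) +
                                  stats::runif(nrow(hyper), 3.5, 5.5))

    spo2_f <- mid + noise - defl_down + defl_up

    ## FiO2: linear baseline decline + first-order controller response
    traj <- config$baseline_fio2_trajectory
    f_start <- stats::runif(1, traj$start[1], traj$start[length(traj$start)])
    f_end <- stats::runif(1, traj$end[1], traj$end[length(traj$end)])
    base <- seq(f_start, f_end, length.out = n)
    alpha <- min(1, 5 / config$controller_timeconstant)
    deficit <- pmax(0, mid - spo2_f)
    resp <- as.numeric(stats::filter(alpha * deficit, 1 - alpha,
                                     method = "recursive"))
    fio2 <- pmin(1, pmax(0.21, base + config$controller_gain * resp))

    ## signal dropouts: Poisson run starts, geometric run lengths (mean 6)
    valid <- rep(TRUE, n)
    if (config$dropout_rate > 0) {
      starts <- which(stats::runif(n) < config$dropout_rate / 6)
      if (length(starts)) {
        lens <- 1L + stats::rgeom(length(starts), 1 / 6)
        for (j in seq_along(starts)) {
          valid[starts[j]:min(n, starts[j] + lens[j] - 1L)] <- FALSE
        }
      }
    }

    ## caregiver FiO2 adjustments: flags only, no feedback
    manual <- rep(FALSE, n)
    for (d in seq_len(n_days)) {
      cnt <- stats::rpois(1, config$manual_adjustments_per_day)
      if (cnt > 0) {
        at <- sample.int(SAMPLES_PER_DAY, min(cnt, SAMPLES_PER_DAY)) +
          (d - 1L) * SAMPLES_PER_DAY
        manual[at] <- TRUE
      }
    }

    spo2 <- as.integer(round(pmin(100, pmax(0, spo2_f))))
    spo2[!valid] <- locf(replace(spo2, !valid, NA_integer_))[!valid]
    spo2[is.na(spo2)] <- as.integer(round(mid))

    out <- oxi_series(spo2, fio2, valid, manual,
                      subject_id = sprintf("S%02d", subject_index))
    ev <- rbind(
      if (nrow(desat)) cbind(kind = "desaturation", desat) else NULL,
      if (nrow(hyper)) cbind(kind = "hyperoxemia", hyper) else NULL
    )
    attr(out, "events") <- if (is.null(ev)) {
      data.frame(kind = character(), start = integer(), duration_s = numeric())
    } else {
      ev[order(ev$start), , drop = FALSE]
    }
    out
  })
}

## Poisson event arrivals over n samples at `rate` per hour; durations in
## seconds from `dur_fun`. Overlapping events simply superimpose.
place_events <- function(n, rate, dur_fun) {
  hours <- n * 5 / 3600
  k <- stats::rpois(1, rate * hours)
  if (k == 0) {
    return(data.frame(start = integer(), duration_s = numeric()))
  }
  start <- sort(sample.int(n, k, replace = TRUE))
  data.frame(start = start, duration_s = dur_fun(k))
}

## additive deflection track: half-sine profile per event, peak = depth
event_deflection <- function(n, events, depth) {
  defl <- numeric(n)
  if (!nrow(events)) return(defl)
  len <- pmax(1L, as.integer(round(events$duration_s / 5)))
  for (j in seq_len(nrow(events))) {
    idx <- events$start[j]:min(n, events$start[j] + len[j] - 1L)
    defl[idx] <- defl[idx] +
      depth[j] * sin(pi * (seq_along(idx) - 0.5) / len[j])
  }
  defl
}

## duration mixture: log-normal body truncated at 60 s (inverse-CDF
## sampling) + exponential excess tail entered with prob tail_frac
draw_desat_durations <- function(k, dd) {
  tail <- stats::runif(k) < dd$tail_frac
  out <- numeric(k)
  if (any(!tail)) {
    p60 <- stats::plnorm(60, dd$meanlog, dd$sdlog)
    u <- stats::runif(sum(!tail)) * p60
    out[!tail] <- stats::qlnorm(u, dd$meanlog, dd$sdlog)
  }
  if (any(tail)) {
    out[tail] <- 60 + stats::rexp(sum(tail), 1 / dd$tail_scale)
  }
  out
}

#' Randomize first-day strategy assignments
#'
#' Assignment uses a balanced block table with blocks of 4: every complete
#' block contains exactly two `"tight"` and two `"loose"` labels in random
#' order; a trailing partial block is the truncated prefix of one more
#' balanced permutation.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; assignment is deterministic given the seed.
#' @return Character vector of length `n_subjects` with values `"tight"` or
#'   `"loose"`.
#' @export
assign_first_day <- function(n_subjects, seed) {
  if (n_subjects < 1) stop("assign_first_day: n_subjects >= 1", call. = FALSE)
  n_blocks <- ceiling(n_subjects / 4)
  with_seed(seed, {
    labels <- unlist(lapply(seq_len(n_blocks), function(i) {
      sample(c("tight", "tight", "loose", "loose"))
    }))
    labels[seq_len(n_subjects)]
  })
}

#' Build a subject's strategy schedule
#'
#' The two alarm strategies alternate in 24-h blocks starting from the
#' first-day assignment.
#'
#' @param first_day `"tight"` or `"loose"`.
#' @param study_days Number of 24-h blocks (>= 1).
#' @return Character vector of length `study_days`, one label per day.
#' @export
build_schedule <- function(first_day, study_days) {
  first_day <- match.arg(first_day, c("tight", "loose"))
  if (study_days < 1) stop("build_schedule: study_days >= 1", call. = FALSE)
  other <- if (first_day == "tight") "loose" else "tight"
  rep(c(first_day, other), length.out = study_days)
}
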