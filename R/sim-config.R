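#' Simulation configuration
#'
#' Parameters of the synthetic monitoring-log generator. Defaults describe a
#' cohort of intubated neonates in their first week of life managed with a
#' closed-loop FiO2 controller holding SpO2 in an 88--95% target range:
#' saturations mostly inside the range, sporadic desaturations a few times
#' per hour (most shorter than one minute), rare hyperoxemic drifts, a small
#' fraction of signal dropout, and supplemental oxygen between room air and
#' roughly 0.67.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param study_days Days of monitoring per subject (the study design caps
#'   participation at 6 days).
#' @param sample_interval Sampling interval in seconds; must be 5.
#' @param target_range A [target_range()].
#' @param noise_sd Stationary standard deviation (% SpO2) of the
#'   autocorrelated baseline noise; 0 turns noise off.
#' @param desat_rate Desaturation events per hour (Poisson arrivals).
#' @param desat_duration Mixture parameters of event durations in seconds:
#'   a log-normal body (`meanlog`, `sdlog`) truncated at 60 s, plus a heavy
#'   tail entered with probability `tail_frac` in which the excess over 60 s
#'   is exponential with mean `tail_scale`.
#' @param desat_depth Typical depth of a desaturation below the target-range
#'   lower bound, in % SpO2 (per-event depths are jittered +/- 3).
#' @param hyper_rate Hyperoxemic drift events per hour.
#' @param dropout_rate Fraction of samples lost to signal dropout, in
#'   `[0, 1)`.
#' @param controller_gain FiO2 response of the emulated controller, in
#'   fraction FiO2 per % SpO2 deficit below the target midpoint.
#' @param controller_timeconstant First-order time constant (seconds) of the
#'   emulated controller; it sets both the FiO2 response smoothing and the
#'   mean-reversion of the SpO2 baseline noise.
#' @param baseline_fio2_trajectory List with elements `start` and `end`,
#'   each a range (length-2 numeric) from which a subject's baseline FiO2 at
#'   study entry and exit is drawn; the baseline declines linearly between
#'   them as the infant is weaned.
#' @param manual_adjustments_per_day Mean of the Poisson count of caregiver
#'   FiO2 adjustments per day (flags only; they do not feed back).
#' @param violation_prob Probability that a day's recorded alarm settings
#'   are mis-set (a protocol violation screened out by the pipeline).
#' @param early_exit_prob Per-day probability that a subject leaves the
#'   study before the cap (e.g. weaned off respiratory support).
#' @param seed Integer seed; all generation is deterministic given the seed.
#' @return A list of class `sim_config`.
#' @seealso [generate_subject()], [run_study()]
#' @export
sim_config <- function(n_subjects = 21,
                       study_days = 6,
                       sample_interval = 5,
                       target_range = oxialarm::target_range(),
                       noise_sd = 1.5,
                       desat_rate = 5,
                       desat_duration = list(meanlog = log(30), sdlog = 0.6,
                                             tail_frac = 0.03, tail_scale = 90),
                       desat_depth = 11,
                       hyper_rate = 0.4,
                       dropout_rate = 0.02,
                       controller_gain = 0.012,
                       controller_timeconstant = 90,
                       baseline_fio2_trajectory = list(start = c(0.25, 0.55),
                                                       end = c(0.22, 0.32)),
                       manual_adjustments_per_day = 2,
                       violation_prob = 0,
                       early_exit_prob = 0,
                       seed = 1L) {
  cfg <- structure(list(
    n_subjects = n_subjects, study_days = study_days,
    sample_interval = sample_interval, target_range = target_range,
    noise_sd = noise_sd, desat_rate = desat_rate,
    desat_duration = desat_duration, desat_depth = desat_depth,
    hyper_rate = hyper_rate, dropout_rate = dropout_rate,
    controller_gain = controller_gain,
    controller_timeconstant = controller_timeconstant,
    baseline_fio2_trajectory = baseline_fio2_trajectory,
    manual_adjustments_per_day = manual_adjustments_per_day,
    violation_prob = violation_prob, early_exit_prob = early_exit_prob,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config A [sim_config()].
#' @return `config`, invisibly; otherwise an error naming the offending
#'   field.
#' @export
validate_sim_config <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("expected a 'sim_config' object", call. = FALSE)
  }
  bad <- function(field, why) {
    stop(sprintf("sim_config: invalid '%s' (%s)", field, why), call. = FALSE)
  }
  pos_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1
  if (!pos_count(config$n_subjects)) bad("n_subjects", "need a count >= 1")
  if (!pos_count(config$study_days)) bad("study_days", "need a count >= 1")
  if (config$sample_interval != 5) bad("sample_interval", "must be 5 seconds")
  if (!inherits(config$target_range, "target_range")) {
    bad("target_range", "need a target_range object")
  }
  nneg <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0
  for (f in c("noise_sd", "desat_rate", "desat_depth", "hyper_rate",
              "controller_gain", "manual_adjustments_per_day")) {
    if (!nneg(config[[f]])) bad(f, "must be a nonnegative number")
  }
  if (!nneg(config$dropout_rate) || config$dropout_rate >= 1) {
    bad("dropout_rate", "must be in [0, 1)")
  }
  if (!nneg(config$violation_prob) || config$violation_prob > 1) {
    bad("violation_prob", "must be in [0, 1]")
  }
  if (!nneg(config$early_exit_prob) || config$early_exit_prob > 1) {
    bad("early_exit_prob", "must be in [0, 1]")
  }
  if (!is.numeric(config$controller_timeconstant) ||
      config$controller_timeconstant <= 0) {
    bad("controller_timeconstant", "must be positive seconds")
  }
  dd <- config$desat_duration
  if (!is.list(dd) || !all(c("meanlog", "sdlog", "tail_frac", "tail_scale")
                           %in% names(dd))) {
    bad("desat_duration", "need meanlog, sdlog, tail_frac, tail_scale")
  }
  if (dd$tail_frac < 0 || dd$tail_frac > 1) {
    bad("desat_duration", "tail_frac must be in [0, 1]")
  }
  tr <- config$baseline_fio2_trajectory
  if (!is.list(tr) || !all(c("start", "end") %in% names(tr))) {
    bad("baseline_fio2_trajectory", "need 'start' and 'end' ranges")
  }
  vals <- c(tr$start, tr$end)
  if (any(vals < 0.21 - 1e-9) || any(vals > 1 + 1e-9)) {
    bad("baseline_fio2_trajectory", "FiO2 values must lie in [0.21, 1.0]")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1 || is.na(config$seed)) {
    bad("seed", "need a single integer")
  }
  invisible(config)
}

#' Read a simulation configuration from YAML
#'
#' The YAML keys mirror the [sim_config()] argument names exactly;
#' `target_range` is a mapping with `low` and `high`.
#'
#' @param path Path to a YAML file.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$target_range)) {
    args$target_range <- target_range(raw$target_range$low, raw$target_range$high)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) {
    stop("read_sim_config: unknown fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, args)
}

#' Write a simulation configuration to YAML
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  lst <- unclass(config)
  lst$target_range <- list(low = config$target_range$low,
                           high = config$target_range$high)
  yaml::write_yaml(lst, path)
  invisible(path)
}

## evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% 2147483647L)
  code
}
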