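#' Default descriptive calibration for the synthetic cohort
#'
#' Per-condition means and standard deviations used to calibrate the
#' synthetic-cohort generator: investment percentage, composite attitude,
#' frontal and parietal asymmetry (dB), and baseline-relative pupil change
#' (mm) for the short standard script ("S1") and the longer personalised
#' script ("S2").
#'
#' @return A data frame with columns `variable`, `condition`, `mean`, `sd`.
#' @export
#' @examples
#' default_calibration()
default_calibration <- function() {
  data.frame(
    variable  = rep(c("investment", "attitude", "faa", "paa", "pupil_change"),
                    each = 2),
    condition = rep(c("S1", "S2"), times = 5),
    mean = c(14.762, 32.143, 5.095, 6.095, -0.768, -0.095,
             0.650, 0.173, 0.283, 0.391),
    sd   = c(17.346, 31.81, 1.221, 1.375, 1.366, 1.740,
             1.749, 2.433, 0.333, 0.299),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic cohort
#'
#' A `cohort_spec` bundles every parameter of the synthetic-data generator:
#' recording geometry (sampling rates, baseline window, script durations),
#' the alpha-oscillation model (frequency, amplitudes, noise), the
#' Gaussian-copula coupling between the frontal asymmetry and behaviour, and
#' the per-condition descriptive calibration. Identical spec + seed yields
#' bit-identical cohorts.
#'
#' @param n_participants Number of participants (>= 2). Default 21.
#' @param conditions Condition labels; default `c("S1", "S2")`.
#' @param eeg_rate EEG sampling rate in samples/s. Default 250.
#' @param pupil_rate Pupil sampling rate in samples/s. Default 100.
#' @param baseline_window Baseline interval in ms relative to script onset,
#'   `c(start, end)` with `start < end < 0`. Default `c(-5000, -200)`.
#' @param script_durations Named numeric, script duration in seconds per
#'   condition. Default `c(S1 = 51, S2 = 87)`.
#' @param alpha_freq Alpha oscillation frequency in Hz. Default 10.
#' @param alpha_amplitude Baseline alpha amplitude in signal units
#'   (microvolt-like). Default 10.
#' @param channel_gains Optional explicit per-channel amplitudes: a list
#'   keyed by condition, each element a 4 x 2 matrix with rows
#'   `F3, F4, P3, P4` and columns `baseline, task`. When `NULL` (default)
#'   task amplitudes are derived per participant from the calibrated
#'   asymmetry draws.
#' @param noise_sd Additive white-noise SD of the EEG signal in signal
#'   units. Default 1.
#' @param target_tau Per-condition Kendall correlations between the frontal
#'   asymmetry score and each behavioural variable: a list keyed by
#'   condition, each a named vector with entries `attitude` and
#'   `investment`, all in (-1, 1). Defaults reproduce the observed
#'   correlation structure of the study conditions.
#' @param calibration Data frame as returned by [default_calibration()].
#' @param pupil_baseline Mean and SD (mm) of the per-participant baseline
#'   pupil level. Default `c(3.5, 0.4)`.
#' @param pupil_drift_amp Amplitude (mm) of the slow sinusoidal pupil drift.
#'   Default 0.05.
#' @param pupil_noise_sd Per-sample pupil measurement noise SD (mm).
#'   Default 0.005.
#' @param seed Integer seed governing all generator randomness. Default 1.
#'
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_participants = 4, seed = 42)
#' spec$script_durations
cohort_spec <- function(n_participants = 21,
                        conditions = c("S1", "S2"),
                        eeg_rate = 250,
                        pupil_rate = 100,
                        baseline_window = c(-5000, -200),
                        script_durations = c(S1 = 51, S2 = 87),
                        alpha_freq = 10,
                        alpha_amplitude = 10,
                        channel_gains = NULL,
                        noise_sd = 1,
                        target_tau = list(
                          S1 = c(attitude = 0.347, investment = 0.219),
                          S2 = c(attitude = -0.404, investment = -0.460)),
                        calibration = default_calibration(),
                        pupil_baseline = c(3.5, 0.4),
                        pupil_drift_amp = 0.05,
                        pupil_noise_sd = 0.005,
                        seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 2)
    stop("`n_participants` must be >= 2", call. = FALSE)
  if (length(conditions) < 1 || anyDuplicated(conditions))
    stop("`conditions` must be distinct labels", call. = FALSE)
  if (!(baseline_window[1] < baseline_window[2] && baseline_window[2] < 0))
    stop("`baseline_window` must satisfy start < end < 0", call. = FALSE)
  if (is.null(names(script_durations)) ||
      !all(conditions %in% names(script_durations)))
    stop("`script_durations` must be named by condition", call. = FALSE)
  if (any(script_durations <= 0))
    stop("script durations must be positive", call. = FALSE)
  if (alpha_freq <= 0 || eeg_rate <= 0 || pupil_rate <= 0)
    stop("rates and `alpha_freq` must be positive", call. = FALSE)
  if (alpha_amplitude <= 0)
    stop("`alpha_amplitude` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  for (cond in conditions) {
    tt <- target_tau[[cond]]
    if (is.null(tt) || !all(c("attitude", "investment") %in% names(tt)))
      stop("`target_tau` needs `attitude` and `investment` entries for ",
           cond, call. = FALSE)
    if (any(abs(tt) >= 1))
      stop("`target_tau` values must lie in (-1, 1)", call. = FALSE)
  }
  if (!is.null(channel_gains)) {
    for (cond in conditions) {
      g <- channel_gains[[cond]]
      if (is.null(g) || !is.matrix(g) || !identical(dim(g), c(4L, 2L)))
        stop("`channel_gains[[", cond, "]]` must be a 4 x 2 matrix",
             call. = FALSE)
      if (any(g <= 0))
        stop("channel gains must be positive", call. = FALSE)
    }
  }
  structure(list(
    n_participants = as.integer(n_participants),
    conditions = conditions,
    eeg_rate = eeg_rate,
    pupil_rate = pupil_rate,
    baseline_window = baseline_window,
    script_durations = script_durations,
    alpha_freq = alpha_freq,
    alpha_amplitude = alpha_amplitude,
    channel_gains = channel_gains,
    noise_sd = noise_sd,
    target_tau = target_tau,
    calibration = calibration,
    pupil_baseline = pupil_baseline,
    pupil_drift_amp = pupil_drift_amp,
    pupil_noise_sd = pupil_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  participants:", x$n_participants,
      " conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  EEG", x$eeg_rate, "Hz / pupil", x$pupil_rate, "Hz;",
      "alpha", x$alpha_freq, "Hz, amplitude", x$alpha_amplitude,
      ", noise SD", x$noise_sd, "\n")
  cat("  baseline window [", x$baseline_window[1], ",",
      x$baseline_window[2], "] ms; script durations:",
      paste(sprintf("%s=%gs", names(x$script_durations), x$script_durations),
            collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

cal_lookup <- function(spec, variable, condition) {
  cal <- spec$calibration
  row <- cal[cal$variable == variable & cal$condition == condition, ]
  if (nrow(row) != 1)
    stop("no calibration entry for ", variable, "/", condition, call. = FALSE)
  c(mean = row$mean, sd = row$sd)
}

# Deterministic sub-seed per (participant, condition, purpose); keeps every
# derived seed well below .Machine$integer.max for small base seeds.
derive_seed <- function(seed, participant, condition_index, purpose) {
  as.integer((abs(seed) * 797L + participant * 131L +
                condition_index * 17L + purpose) %% 2147483629L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Ground-truth participant effects implied by a cohort spec
#'
#' Draws (deterministically, from the spec seed) the per-participant true
#' frontal and parietal asymmetries (dB), pupil baseline level and pupil
#' change (mm) for one condition, from the spec's calibration.
#'
#' @param spec A [cohort_spec()].
#' @param participant Participant index in `1:n_participants`.
#' @param condition Condition label.
#' @return A list with elements `faa`, `paa`, `pupil_base`, `pupil_change`.
#' @export
participant_truth <- function(spec, participant, condition) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (participant < 1 || participant > spec$n_participants)
    stop("participant index out of range", call. = FALSE)
  ci <- match(condition, spec$conditions)
  if (is.na(ci)) stop("unknown condition: ", condition, call. = FALSE)
  faa_cal <- cal_lookup(spec, "faa", condition)
  paa_cal <- cal_lookup(spec, "paa", condition)
  pup_cal <- cal_lookup(spec, "pupil_change", condition)
  with_seed(derive_seed(spec$seed, participant, ci, 1L), {
    list(
      faa = rnorm(1, faa_cal["mean"], faa_cal["sd"]),
      paa = rnorm(1, paa_cal["mean"], paa_cal["sd"]),
      pupil_base = max(2, rnorm(1, spec$pupil_baseline[1],
                                spec$pupil_baseline[2])),
      pupil_change = rnorm(1, pup_cal["mean"], pup_cal["sd"])
    )
  })
}
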