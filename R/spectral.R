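#' Cut a recording segment into fixed-length epochs
#'
#' Tiles the requested segment of a recording with contiguous,
#' non-overlapping epochs of `epoch_len_ms`; a trailing partial window is
#' discarded. The baseline segment tiles `baseline_window` (relative to
#' script onset); the task segment tiles from script onset to script end.
#'
#' @param rec A `signal_recording` (see [generate_signals()]).
#' @param segment `"baseline"` or `"task"`.
#' @param epoch_len_ms Epoch length in ms (default 200).
#' @param baseline_window Baseline interval in ms relative to script onset.
#' @return An `epoch_set`: list with `epochs` (epoch x channel x sample
#'   array), `n_epochs`, `channels`, `rate`, `segment`, `epoch_len_ms`.
#' @export
#' @examples
#' spec <- cohort_spec(n_participants = 2, seed = 1)
#' es <- epoch_signal(generate_signals(spec, 1, "S1"), "baseline")
#' es$n_epochs  # 24 epochs of 200 ms tile [-5000, -200] ms
epoch_signal <- function(rec, segment = c("baseline", "task"),
                         epoch_len_ms = 200,
                         baseline_window = c(-5000, -200)) {
  stopifnot(inherits(rec, "signal_recording"))
  segment <- match.arg(segment)
  if (epoch_len_ms <= 0) stop("epoch length must be positive", call. = FALSE)
  ev <- function(lab) rec$events$onset_ms[rec$events$label == lab]
  window <- if (segment == "baseline") baseline_window
            else c(ev("script_onset"), ev("script_end"))
  n_samp <- epoch_len_ms * rec$rate / 1000
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("epoch length must be an integer number of samples", call. = FALSE)
  n_samp <- as.integer(round(n_samp))
  n_epochs <- floor((window[2] - window[1]) / epoch_len_ms)
  if (n_epochs < 1)
    stop("segment shorter than one epoch", call. = FALSE)
  i0 <- which(rec$time_ms >= window[1] - 1e-9)[1]
  # the segment is half-open: its last sample is one period before window[2]
  if (is.na(i0) || i0 + n_epochs * n_samp - 1L > ncol(rec$samples))
    stop("recording does not span the requested segment", call. = FALSE)
  nch <- length(rec$channels)
  epochs <- array(NA_real_, dim = c(n_epochs, nch, n_samp),
                  dimnames = list(NULL, rec$channels, NULL))
  for (e in seq_len(n_epochs)) {
    idx <- i0 + (e - 1L) * n_samp + seq_len(n_samp) - 1L
    epochs[e, , ] <- rec$samples[, idx]
  }
  structure(list(epochs = epochs, n_epochs = n_epochs,
                 channels = rec$channels, rate = rec$rate,
                 segment = segment, epoch_len_ms = epoch_len_ms),
            class = "epoch_set")
}

#' Remove the evoked (phase-locked) response from an epoch set
#'
#' Subtracts the across-epoch mean waveform, per channel and sample index,
#' from every epoch. This removes phase-locked activity and increases the
#' stationarity of the residual; the across-epoch mean of the result is
#' zero at every sample by construction. Note that a signal strictly
#' periodic in the epoch length is entirely phase-locked and is therefore
#' removed in full — see the package vignette for when to apply this step.
#'
#' @param es An `epoch_set`.
#' @return An `epoch_set` of residual epochs.
#' @export
remove_evoked <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  if (es$n_epochs < 2)
    stop("evoked-response removal needs at least 2 epochs", call. = FALSE)
  erp <- apply(es$epochs, c(2, 3), mean)            # channel x sample
  es$epochs <- sweep(es$epochs, c(2, 3), erp, "-")
  es
}

#' Alpha power at a fixed FFT bin
#'
#' Per-epoch magnitude-squared FFT coefficient at the requested frequency,
#' averaged across epochs (rectangular window, no taper). The frequency
#' must be an exact bin of the epoch — e.g. 10 Hz is bin 2 of a 50-sample
#' epoch at 250 Hz — otherwise an error is raised rather than silently
#' leaking power across bins.
#'
#' @param es An `epoch_set`.
#' @param channel Channel label.
#' @param freq Target frequency in Hz (default 10).
#' @return An `alpha_power`: list with `channel`, `segment`, `power`
#'   (signal-units squared), `freq`, `n_epochs`.
#' @export
alpha_power <- function(es, channel, freq = 10) {
  stopifnot(inherits(es, "epoch_set"))
  ch <- match(channel, es$channels)
  if (is.na(ch)) stop("unknown channel: ", channel, call. = FALSE)
  n_samp <- dim(es$epochs)[3]
  bin <- freq * n_samp / es$rate
  if (abs(bin - round(bin)) > 1e-9)
    stop(freq, " Hz is not an exact FFT bin for ", n_samp,
         "-sample epochs at ", es$rate, " Hz", call. = FALSE)
  bin <- as.integer(round(bin))
  if (bin < 0 || bin > floor(n_samp / 2))
    stop("frequency outside the resolvable range", call. = FALSE)
  mat <- matrix(es$epochs[, ch, ], nrow = es$n_epochs)
  coefs <- mvfft(t(mat))[bin + 1L, ]
  structure(list(channel = channel, segment = es$segment,
                 power = mean(Mod(coefs)^2), freq = freq,
                 n_epochs = es$n_epochs),
            class = "alpha_power")
}

#' Decibel baseline normalisation
#'
#' `10 * log10(task power / baseline power)`: the task-related change in
#' power expressed in dB relative to the pre-stimulus baseline, removing
#' trait power differences across participants.
#'
#' @param task,baseline `alpha_power` objects (or bare positive numbers)
#'   for the same channel.
#' @return The dB value (numeric scalar).
#' @export
#' @examples
#' db_normalize(2, 1)  # 10*log10(2) ~ 3.0103 dB
db_normalize <- function(task, baseline) {
  p_t <- if (inherits(task, "alpha_power")) task$power else task
  p_b <- if (inherits(baseline, "alpha_power")) baseline$power else baseline
  if (inherits(task, "alpha_power") && inherits(baseline, "alpha_power") &&
      !identical(task$channel, baseline$channel))
    stop("task and baseline powers are from different channels",
         call. = FALSE)
  if (!is.finite(p_t) || !is.finite(p_b) || p_t <= 0 || p_b <= 0)
    stop("powers must be positive and finite", call. = FALSE)
  10 * log10(p_t / p_b)
}

#' Hemispheric asymmetry index
#'
#' Right-minus-left difference of baseline-normalised power:
#' `db_right - db_left`. Applied to (F4, F3) this is the frontal alpha
#' asymmetry (FAA); applied to (P4, P3) the parietal control (PAA).
#' Positive values mean relatively more normalised alpha power over the
#' right hemisphere (conventionally read as approach motivation), negative
#' values more over the left (avoidance).
#'
#' @param db_right,db_left Finite dB values.
#' @return The dB difference.
#' @export
asymmetry_index <- function(db_right, db_left) {
  if (!is.finite(db_right) || !is.finite(db_left))
    stop("asymmetry inputs must be finite", call. = FALSE)
  db_right - db_left
}

#' Full spectral-asymmetry stage for one recording
#'
#' Epochs the baseline and task segments, optionally removes the evoked
#' response from each, computes the single-bin alpha power per channel
#' averaged across epochs, baseline-normalises it in dB, and forms the
#' frontal and parietal asymmetry indices.
#'
#' @param rec A `signal_recording`.
#' @param epoch_len_ms Epoch length in ms (default 200).
#' @param baseline_window Baseline interval in ms (default
#'   `c(-5000, -200)`).
#' @param alpha_freq Analysis frequency in Hz (default 10).
#' @param remove_evoked Subtract the across-epoch mean waveform before the
#'   FFT (default `FALSE`; see the vignette — strictly periodic synthetic
#'   oscillations are phase-locked to the epochs and would be cancelled).
#' @param frontal,parietal Channel label pairs `c(left, right)`.
#' @return One-row data frame: `participant`, `condition`, `db_F3`,
#'   `db_F4`, `db_P3`, `db_P4`, `FAA`, `PAA`.
#' @export
compute_asymmetry <- function(rec, epoch_len_ms = 200,
                              baseline_window = c(-5000, -200),
                              alpha_freq = 10,
                              remove_evoked = FALSE,
                              frontal = c("F3", "F4"),
                              parietal = c("P3", "P4")) {
  base <- epoch_signal(rec, "baseline", epoch_len_ms, baseline_window)
  task <- epoch_signal(rec, "task", epoch_len_ms, baseline_window)
  if (isTRUE(remove_evoked)) {
    base <- remove_evoked(base)
    task <- remove_evoked(task)
  }
  chans <- c(frontal, parietal)
  db <- vapply(chans, function(ch)
    db_normalize(alpha_power(task, ch, alpha_freq),
                 alpha_power(base, ch, alpha_freq)), 0)
  out <- data.frame(
    participant = if (is.null(rec$participant)) NA else rec$participant,
    condition = if (is.null(rec$condition)) NA else rec$condition,
    stringsAsFactors = FALSE)
  out[paste0("db_", chans)] <- as.list(db)
  out$FAA <- asymmetry_index(db[[frontal[2]]], db[[frontal[1]]])
  out$PAA <- asymmetry_index(db[[parietal[2]]], db[[parietal[1]]])
  out
}
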