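#' Generate a synthetic multi-channel EEG recording
#'
#' Emits a four-channel (F3, F4, P3, P4) recording containing an alpha
#' sinusoid at `spec$alpha_freq` plus additive white Gaussian noise. The
#' recording spans the rest phase (from the start of the baseline window)
#' through the end of the condition's script; amplitudes switch from their
#' baseline to their task value at script onset. When `spec$channel_gains`
#' is `NULL`, task amplitudes encode the participant's ground-truth
#' asymmetries: the right-hemisphere channel of each pair is scaled by
#' `10^(truth/20)` so that the downstream dB pipeline recovers `truth`
#' exactly in the noiseless case.
#'
#' @param spec A [cohort_spec()].
#' @param participant Participant index.
#' @param condition Condition label.
#' @return A `signal_recording`: list with `channels`, `rate`, `samples`
#'   (channel x time matrix), `time_ms`, and `events` (data frame of
#'   `label`, `onset_ms` for `rest_onset`, `script_onset`, `script_end`).
#' @export
#' @examples
#' spec <- cohort_spec(n_participants = 2, seed = 7)
#' rec <- generate_signals(spec, 1, "S1")
#' rec$events
generate_signals <- function(spec, participant, condition) {
  stopifnot(inherits(spec, "cohort_spec"))
  ci <- match(condition, spec$conditions)
  if (is.na(ci)) stop("unknown condition: ", condition, call. = FALSE)
  dur_ms <- spec$script_durations[[condition]] * 1000
  if (dur_ms <= 0) stop("script duration must be positive", call. = FALSE)
  channels <- c("F3", "F4", "P3", "P4")

  if (!is.null(spec$channel_gains)) {
    gains <- spec$channel_gains[[condition]]
    rownames(gains) <- channels
    colnames(gains) <- c("baseline", "task")
  } else {
    truth <- participant_truth(spec, participant, condition)
    a <- spec$alpha_amplitude
    gains <- cbind(
      baseline = rep(a, 4),
      task = c(a, a * 10^(truth$faa / 20), a, a * 10^(truth$paa / 20)))
    rownames(gains) <- channels
  }
  if (any(gains <= 0))
    stop("channel amplitudes must be positive", call. = FALSE)

  rate <- spec$eeg_rate
  start_ms <- spec$baseline_window[1]
  n <- round((dur_ms - start_ms) / 1000 * rate)
  t_ms <- start_ms + (seq_len(n) - 1) / rate * 1000
  task <- t_ms >= 0

  samples <- with_seed(derive_seed(spec$seed, participant, ci, 2L), {
    phases <- runif(4, 0, 2 * pi)
    out <- matrix(0, nrow = 4, ncol = n, dimnames = list(channels, NULL))
    for (k in seq_len(4)) {
      amp <- ifelse(task, gains[k, "task"], gains[k, "baseline"])
      x <- amp * sin(2 * pi * spec$alpha_freq * t_ms / 1000 + phases[k])
      if (spec$noise_sd > 0) x <- x + rnorm(n, 0, spec$noise_sd)
      out[k, ] <- x
    }
    out
  })

  structure(list(
    channels = channels,
    rate = rate,
    samples = samples,
    time_ms = t_ms,
    events = data.frame(
      label = c("rest_onset", "script_onset", "script_end"),
      onset_ms = c(start_ms, 0, dur_ms),
      stringsAsFactors = FALSE),
    participant = participant,
    condition = condition
  ), class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  cat("signal_recording:", length(x$channels), "channels at", x$rate, "Hz,",
      ncol(x$samples), "samples [",
      round(min(x$time_ms)), ",", round(max(x$time_ms)), "] ms\n")
  invisible(x)
}

# Pupil epoch index sets matching the processing pipeline: baseline and task
# windows split at their midpoint, odd sample to the initial half.
pupil_epoch_indices <- function(time_ms, baseline_window, task_window) {
  sel_b <- which(time_ms >= baseline_window[1] & time_ms < baseline_window[2])
  sel_t <- which(time_ms >= task_window[1] & time_ms < task_window[2])
  if (!length(sel_b) || !length(sel_t))
    stop("trace does not cover the requested windows", call. = FALSE)
  halves <- function(idx) {
    n1 <- ceiling(length(idx) / 2)
    list(initial = idx[seq_len(n1)], final = idx[-seq_len(n1)])
  }
  list(baseline = halves(sel_b), task = halves(sel_t))
}

#' Generate a synthetic binocular pupil trace
#'
#' Produces a smooth mm-scale trace (per-participant baseline level, a step
#' to `baseline + change` at script onset, a slow sinusoidal drift, bounded
#' measurement jitter) with injected blink gaps and isolated outlier
#' excursions. Blinks set both eyes to `NA` and flag the sample `blink`;
#' outliers are single samples displaced by 8 within-epoch standard
#' deviations, guaranteed to exceed the pipeline's 3-SD rejection rule. The
#' injected positions are attached as attributes for test assertions.
#'
#' @param spec A [cohort_spec()].
#' @param participant Participant index.
#' @param condition Condition label.
#' @param blink_count Number of blink gaps to inject (>= 0).
#' @param outlier_count Number of isolated outlier samples to inject (>= 0).
#' @return A `pupil_trace` data frame with columns `time_ms`, `left_mm`,
#'   `right_mm`, `validity`, and attributes `outlier_idx`, `blink_idx`,
#'   `true_change` (mm change of the clean trace under the pipeline's
#'   averaging) and `rate`.
#' @export
generate_pupil <- function(spec, participant, condition,
                           blink_count = 2, outlier_count = 2) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (blink_count < 0 || outlier_count < 0)
    stop("blink and outlier counts must be >= 0", call. = FALSE)
  ci <- match(condition, spec$conditions)
  if (is.na(ci)) stop("unknown condition: ", condition, call. = FALSE)
  dur_ms <- spec$script_durations[[condition]] * 1000
  rate <- spec$pupil_rate
  start_ms <- spec$baseline_window[1]
  n <- round((dur_ms - start_ms) / 1000 * rate)
  t_ms <- start_ms + (seq_len(n) - 1) / rate * 1000
  truth <- participant_truth(spec, participant, condition)

  blink_len <- round(0.12 * rate)          # ~120 ms closures
  if ((blink_count * (blink_len + 2) + 3 * outlier_count) > n / 2)
    stop("requested blinks/outliers exceed trace capacity", call. = FALSE)

  with_seed(derive_seed(spec$seed, participant, ci, 3L), {
    level <- ifelse(t_ms >= 0, truth$pupil_base + truth$pupil_change,
                    truth$pupil_base)
    ep <- pupil_epoch_indices(t_ms, spec$baseline_window, c(0, dur_ms))
    all_epochs <- c(ep$baseline, ep$task)

    # Draw the drift phase and the bounded (uniform) sensor jitter jointly
    # until no clean sample strays beyond 2.8 within-epoch SDs, so that
    # only injected spikes can cross the pipeline's 3-SD rejection rule
    # (a sinusoid segment covering an extremum asymmetrically can
    # otherwise standardise past 3 in a short epoch).
    a <- spec$pupil_noise_sd * sqrt(3)
    for (attempt in 1:50) {
      drift <- spec$pupil_drift_amp *
        sin(2 * pi * 0.1 * t_ms / 1000 + runif(1, 0, 2 * pi))
      clean <- level + drift
      left <- clean + runif(n, -a, a)
      right <- clean + runif(n, -a, a)
      merged <- (left + right) / 2
      zmax <- max(vapply(all_epochs, function(i) {
        x <- merged[i]
        s <- sd(x)
        if (s == 0) 0 else max(abs(x - mean(x)) / s)
      }, 0))
      if (zmax <= 2.8) break
      if (attempt == 50)
        stop("could not generate a trace free of spurious outliers",
             call. = FALSE)
    }

    true_change <- mean(vapply(ep$task, function(i) mean(clean[i]), 0)) -
      mean(vapply(ep$baseline, function(i) mean(clean[i]), 0))

    # blink gaps: non-overlapping runs away from the trace edges
    taken <- rep(FALSE, n)
    blink_idx <- integer(0)
    if (blink_count > 0) {
      for (b in seq_len(blink_count)) {
        ok <- FALSE
        for (try in 1:200) {
          s <- sample(seq(2, n - blink_len - 1), 1)
          run <- s:(s + blink_len - 1)
          if (!any(taken[c(run, run - 1, run + 1)])) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place blink gaps", call. = FALSE)
        taken[run] <- TRUE
        blink_idx <- c(blink_idx, run)
      }
    }

    # isolated outliers: 8 within-epoch SDs from the epoch mean (valid
    # samples only), so they survive the post-injection variance inflation
    outlier_idx <- integer(0)
    if (outlier_count > 0) {
      epoch_of <- integer(n)
      for (k in seq_along(all_epochs)) epoch_of[all_epochs[[k]]] <- k
      candidates <- which(!taken & epoch_of > 0)
      candidates <- candidates[candidates > 1 & candidates < n]
      for (o in seq_len(outlier_count)) {
        ok <- FALSE
        for (try in 1:200) {
          s <- sample(candidates, 1)
          if (!any(taken[c(s - 1, s, s + 1)])) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place outliers", call. = FALSE)
        taken[s] <- TRUE
        idx <- all_epochs[[epoch_of[s]]]
        valid <- setdiff(idx, blink_idx)
        s_sd <- sd(merged[valid])
        if (!is.finite(s_sd) || s_sd == 0)
          stop("cannot inject outliers into a constant epoch", call. = FALSE)
        spike <- mean(merged[valid]) + sample(c(-1, 1), 1) * 8 * s_sd
        left[s] <- right[s] <- spike
        outlier_idx <- c(outlier_idx, s)
      }
    }

    validity <- rep("valid", n)
    validity[blink_idx] <- "blink"
    left[blink_idx] <- NA_real_
    right[blink_idx] <- NA_real_

    structure(
      data.frame(time_ms = t_ms, left_mm = left, right_mm = right,
                 validity = validity, stringsAsFactors = FALSE),
      outlier_idx = sort(outlier_idx),
      blink_idx = sort(blink_idx),
      true_change = true_change,
      rate = rate,
      participant = participant,
      condition = condition,
      class = c("pupil_trace", "data.frame"))
  })
}

# Moments of a N(mu, sigma) variable clamped to [lo, hi].
censored_normal_moments <- function(mu, sigma, lo = 0, hi = 100) {
  mu <- unname(mu); sigma <- unname(sigma)
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  mk <- function(k) {
    lo^k * pnorm(a) + hi^k * (1 - pnorm(b)) +
      integrate(function(x) x^k * dnorm(x, mu, sigma), lo, hi,
                rel.tol = 1e-10)$value
  }
  m1 <- mk(1)
  c(mean = m1, sd = sqrt(max(mk(2) - m1^2, 0)))
}

# Latent normal parameters such that the [0, 100]-clamped variable has the
# requested mean and SD (moment matching by Nelder-Mead).
calibrate_censored_normal <- function(target_mean, target_sd) {
  target_mean <- unname(target_mean); target_sd <- unname(target_sd)
  obj <- function(p) {
    m <- censored_normal_moments(p[1], exp(p[2]))
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Generate behavioural responses coupled to the frontal asymmetry
#'
#' Uses a Gaussian copula: the rank transform of `faa_scores` is mapped to a
#' standard normal and each behavioural margin is generated from a latent
#' bivariate normal with Pearson correlation `rho = sin(pi * tau / 2)`,
#' where `tau` is the condition's target Kendall correlation. The attitude
#' margin thresholds the latent normal at equally spaced quantiles
#' (0.2, 0.4, 0.6, 0.8) to give four binary items in `{1, 2}`; the
#' investment margin is a latent normal moment-matched so that, after
#' clamping to `[0, 100]`, its mean and SD equal the condition's calibrated
#' values. Wallets are drawn uniformly from the winnings range of the
#' 15-bet gambling game (multiples of 1,000 up to 300,000 lire).
#'
#' @param spec A [cohort_spec()].
#' @param faa_scores Numeric vector of per-participant frontal asymmetry
#'   scores (length `n_participants`).
#' @param condition Condition label.
#' @return Data frame with columns `participant`, `condition`, `item_a` ..
#'   `item_d`, `wallet`, `invested`.
#' @export
generate_behavior <- function(spec, faa_scores, condition) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  if (length(faa_scores) != n)
    stop("`faa_scores` must have length n_participants", call. = FALSE)
  ci <- match(condition, spec$conditions)
  if (is.na(ci)) stop("unknown condition: ", condition, call. = FALSE)
  tt <- spec$target_tau[[condition]]
  if (any(abs(tt) >= 1))
    stop("target tau must lie in (-1, 1)", call. = FALSE)
  inv_cal <- cal_lookup(spec, "investment", condition)
  latent <- calibrate_censored_normal(inv_cal["mean"], inv_cal["sd"])

  with_seed(derive_seed(spec$seed, 0L, ci, 4L), {
    z_faa <- qnorm(rank(faa_scores, ties.method = "average") / (n + 1))
    couple <- function(tau) {
      rho <- sin(pi * tau / 2)
      rho * z_faa + sqrt(1 - rho^2) * rnorm(n)
    }
    u_att <- pnorm(couple(tt[["attitude"]]))
    items <- vapply(c(0.2, 0.4, 0.6, 0.8),
                    function(thr) 1L + (u_att > thr), integer(n))
    pct <- latent["mu"] + latent["sigma"] * couple(tt[["investment"]])
    pct <- round(pmin(pmax(pct, 0), 100), 1)
    wallet <- sample(seq(1000, 300000, by = 1000), n, replace = TRUE)
    invested <- round(wallet * pct / 100)
    data.frame(participant = seq_len(n), condition = condition,
               item_a = items[, 1], item_b = items[, 2],
               item_c = items[, 3], item_d = items[, 4],
               wallet = wallet, invested = invested,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Draws per-participant ground-truth effects, generates EEG recordings,
#' pupil traces and behavioural responses for every participant and
#' condition, and returns them together with the ground-truth table.
#'
#' @param spec A [cohort_spec()].
#' @param signals,pupil Logical; generate the corresponding modality
#'   (default `TRUE`). Skipping unneeded modalities speeds up large
#'   replicate simulations.
#' @param blink_count,outlier_count Injection counts passed to
#'   [generate_pupil()].
#' @return An object of class `cohort`: list with `spec`, `signals` (nested
#'   list `[[condition]][[participant]]`), `pupil` (same shape), `behavior`
#'   (data frame over all conditions) and `truth` (data frame of true
#'   per-participant effects).
#' @export
simulate_cohort <- function(spec, signals = TRUE, pupil = TRUE,
                            blink_count = 2, outlier_count = 2) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  truth <- do.call(rbind, lapply(spec$conditions, function(cond) {
    rows <- lapply(seq_len(n), function(p) {
      tr <- participant_truth(spec, p, cond)
      data.frame(participant = p, condition = cond, faa = tr$faa,
                 paa = tr$paa, pupil_base = tr$pupil_base,
                 pupil_change = tr$pupil_change, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  sig <- pup <- NULL
  if (signals)
    sig <- lapply(stats::setNames(spec$conditions, spec$conditions),
                  function(cond) lapply(seq_len(n), function(p)
                    generate_signals(spec, p, cond)))
  if (pupil)
    pup <- lapply(stats::setNames(spec$conditions, spec$conditions),
                  function(cond) lapply(seq_len(n), function(p)
                    generate_pupil(spec, p, cond, blink_count,
                                   outlier_count)))
  behavior <- do.call(rbind, lapply(spec$conditions, function(cond) {
    faa <- truth$faa[truth$condition == cond]
    generate_behavior(spec, faa, cond)
  }))
  structure(list(spec = spec, signals = sig, pupil = pup,
                 behavior = behavior, truth = truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$spec$n_participants, "participants x",
      length(x$spec$conditions), "conditions;",
      if (is.null(x$signals)) "no" else "with", "signals,",
      if (is.null(x$pupil)) "no" else "with", "pupil traces\n")
  invisible(x)
}
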