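# Independent oracles used across the suite; all are deliberately naive
# implementations that never share code with the package internals.

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Exhaustive pair-counting Kendall tau-b.
tau_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(x), 2))
  n2 <- sum(choose(table(y), 2))
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Monte-Carlo marginal likelihood for the JZS t-test Bayes factor:
# delta drawn from its Cauchy prior, noncentral-t density averaged.
jzs_bf_mc <- function(t, n, width, side = "two_sided", draws = 1e6) {
  delta <- rcauchy(draws, 0, width)
  if (side == "positive") delta <- abs(delta)
  if (side == "negative") delta <- -abs(delta)
  marg <- mean(suppressWarnings(dt(t, n - 1, ncp = delta * sqrt(n))))
  marg / dt(t, n - 1)
}

# Monte-Carlo Savage-Dickey Kendall Bayes factor: population tau drawn
# through the stretched-beta prior on rho.
kendall_bf_mc <- function(tau, n, kappa, draws = 1e6) {
  rho <- 2 * rbeta(draws, 1 / kappa, 1 / kappa) - 1
  tp <- (2 / pi) * asin(rho)
  z <- tau / sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  mean(dnorm(z, 1.5 * tp * sqrt(n), 1)) / dnorm(z, 0, 1)
}

# Hand-built recording for spectral unit tests: one channel per row of
# `samples`, spanning [-5000, dur_ms) like the generator's output.
make_rec <- function(samples, rate = 250, dur_ms = 1000,
                     channels = rownames(samples)) {
  structure(list(
    channels = channels, rate = rate, samples = samples,
    time_ms = -5000 + (seq_len(ncol(samples)) - 1) / rate * 1000,
    events = data.frame(label = c("rest_onset", "script_onset",
                                  "script_end"),
                        onset_ms = c(-5000, 0, dur_ms),
                        stringsAsFactors = FALSE),
    participant = 1, condition = "S1"), class = "signal_recording")
}

# Minimal pupil epoch for unit tests.
make_epoch <- function(samples, segment = "task", half = "initial") {
  structure(list(samples = samples, segment = segment, half = half),
            class = "pupil_epoch")
}

# Noiseless spec with explicit channel gains (baseline amplitude 10).
noiseless_spec <- function(f4_ratio = 1, f3_ratio = 1, p4_ratio = 1,
                           p3_ratio = 1, seed = 1, n = 2, ...) {
  gains <- function(r3, r4, q3, q4)
    cbind(rep(10, 4), 10 * c(r3, r4, q3, q4))
  cohort_spec(
    n_participants = n, noise_sd = 0, seed = seed,
    channel_gains = list(S1 = gains(f3_ratio, f4_ratio, p3_ratio, p4_ratio),
                         S2 = gains(f3_ratio, f4_ratio, p3_ratio, p4_ratio)),
    ...)
}
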