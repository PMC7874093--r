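test_that("epoching tiles the baseline and task segments exactly", {
  spec <- cohort_spec(n_participants = 2, seed = 1)
  rec <- generate_signals(spec, 1, "S1")
  base <- epoch_signal(rec, "baseline")
  expect_equal(base$n_epochs, 24)                # 4800 ms / 200 ms
  expect_equal(dim(base$epochs), c(24, 4, 50))   # 50 samples at 250 Hz
  task <- epoch_signal(rec, "task")
  expect_equal(task$n_epochs, 255)               # 51 s / 200 ms
  # trailing partial windows are discarded
  rec87 <- generate_signals(spec, 1, "S2")
  expect_equal(epoch_signal(rec87, "task", epoch_len_ms = 700)$n_epochs,
               floor(87000 / 700))
  expect_error(epoch_signal(rec, "baseline", epoch_len_ms = 6000),
               "shorter than one epoch")
  expect_error(epoch_signal(rec, "baseline", epoch_len_ms = 130),
               "integer number of samples")
})

test_that("epochs reproduce the raw samples they cover", {
  x <- matrix(seq_len(4 * 2500), nrow = 4,
              dimnames = list(c("F3", "F4", "P3", "P4"), NULL))
  rec <- make_rec(x, rate = 250, dur_ms = 5000)
  es <- epoch_signal(rec, "task")
  expect_equal(es$epochs[1, "F3", ], unname(x["F3", 1251:1300]))
  expect_equal(es$epochs[25, "P4", ], unname(x["P4", 2451:2500]))
})

test_that("evoked-response removal subtracts the across-epoch mean", {
  spec <- cohort_spec(n_participants = 2, seed = 2, noise_sd = 0)
  rec <- generate_signals(spec, 1, "S1")
  es <- epoch_signal(rec, "task")
  resid <- remove_evoked(es)
  # a strictly periodic oscillation is fully phase-locked: removed entirely
  expect_lt(max(abs(resid$epochs)), 1e-9)
  # common waveform + noise: residual has (a) zero across-epoch mean and
  # (b) variance close to the injected noise variance
  spec_n <- cohort_spec(n_participants = 2, seed = 3, noise_sd = 1)
  es_n <- epoch_signal(generate_signals(spec_n, 1, "S1"), "task")
  resid_n <- remove_evoked(es_n)
  expect_lt(max(abs(apply(resid_n$epochs, c(2, 3), mean))), 1e-10)
  expect_equal(sd(resid_n$epochs), 1, tolerance = 0.05)
  # single epoch cannot have its mean removed without zeroing the data
  one <- es
  one$epochs <- es$epochs[1, , , drop = FALSE]
  one$n_epochs <- 1L
  expect_error(remove_evoked(one), "at least 2 epochs")
})

test_that("single-bin power behaves like a calibrated spectral line", {
  t <- (0:49) / 250
  wave <- function(a, f) a * sin(2 * pi * f * t)
  as_es <- function(x) {
    # one-channel, one-epoch set built directly
    structure(list(epochs = array(x, c(1, 1, 50),
                                  dimnames = list(NULL, "F3", NULL)),
                   n_epochs = 1L, channels = "F3", rate = 250,
                   segment = "task", epoch_len_ms = 200),
              class = "epoch_set")
  }
  p1 <- alpha_power(as_es(wave(1, 10)), "F3")$power
  p2 <- alpha_power(as_es(wave(2, 10)), "F3")$power
  expect_equal(p2 / p1, 4)                     # power scales with amplitude^2
  expect_equal(alpha_power(as_es(rep(3, 50)), "F3")$power, 0)   # DC
  expect_lt(alpha_power(as_es(wave(1, 15)), "F3")$power / p1, 1e-20)
  expect_error(alpha_power(as_es(wave(1, 10)), "F3", freq = 7),
               "not an exact FFT bin")
  expect_error(alpha_power(as_es(wave(1, 10)), "Cz"), "unknown channel")
})

test_that("decibel normalization follows the power-ratio definition", {
  expect_equal(db_normalize(5, 5), 0)
  expect_equal(db_normalize(10, 1), 10)
  expect_equal(db_normalize(2, 1), 10 * log10(2))
  expect_error(db_normalize(0, 1), "positive")
  expect_error(db_normalize(1, -2), "positive")
})

test_that("asymmetry is the right-minus-left difference and antisymmetric", {
  expect_equal(asymmetry_index(2, 2), 0)
  expect_equal(asymmetry_index(2, 1), 1)
  expect_error(asymmetry_index(Inf, 0), "finite")
  spec <- cohort_spec(n_participants = 2, seed = 9)
  rec <- generate_signals(spec, 1, "S2")
  a <- compute_asymmetry(rec)
  swapped <- compute_asymmetry(rec, frontal = c("F4", "F3"),
                               parietal = c("P4", "P3"))
  expect_equal(swapped$FAA, -a$FAA)
  expect_equal(swapped$PAA, -a$PAA)
})

test_that("noiseless cohorts recover the configured asymmetries exactly", {
  # F4/F3 amplitude ratio 10^(1/2) -> 10 dB FAA; equal P channels -> 0 PAA
  spec <- noiseless_spec(f4_ratio = 10^(1 / 2))
  a <- compute_asymmetry(generate_signals(spec, 1, "S1"))
  expect_equal(a$FAA, 10, tolerance = 1e-6)
  expect_equal(a$PAA, 0, tolerance = 1e-6)
  expect_equal(a$db_F4, 10, tolerance = 1e-6)
  expect_equal(a$db_F3, 0, tolerance = 1e-6)
  # amplitude ratio sqrt(2) on F4 -> FAA = 10*log10(2)
  spec2 <- noiseless_spec(f4_ratio = sqrt(2), p4_ratio = 2, p3_ratio = 2)
  a2 <- compute_asymmetry(generate_signals(spec2, 1, "S2"))
  expect_equal(a2$FAA, 10 * log10(2), tolerance = 1e-6)
  expect_equal(a2$PAA, 0, tolerance = 1e-6)
})

test_that("noiseless asymmetry is invariant to the task duration", {
  for (dur in c(51, 102)) {
    spec <- noiseless_spec(f4_ratio = 2, seed = 5)
    spec$script_durations <- c(S1 = dur, S2 = 87)
    a <- compute_asymmetry(generate_signals(spec, 1, "S1"))
    if (dur == 51) faa51 <- a$FAA else expect_lt(abs(a$FAA - faa51), 1e-9)
  }
})

test_that("asymmetry estimates are unbiased under additive noise", {
  # signal-to-noise chosen so the additive noise floor at the analysis bin
  # is negligible against the sampling spread of the estimate
  true_faa <- 20 * log10(2)  # F4 amplitude ratio 2
  errs <- vapply(1:200, function(s) {
    spec <- noiseless_spec(f4_ratio = 2, seed = 1000 + s)
    spec$noise_sd <- 0.3
    compute_asymmetry(generate_signals(spec, 1, "S1"))$FAA - true_faa
  }, 0)
  expect_lt(abs(mean(errs)), 2 * sd(errs) / sqrt(length(errs)))
})
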