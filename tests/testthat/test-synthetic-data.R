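test_that("cohort specs are validated", {
  expect_error(cohort_spec(n_participants = 1), "n_participants")
  expect_error(cohort_spec(baseline_window = c(-200, -5000)), "baseline_window")
  expect_error(cohort_spec(baseline_window = c(-5000, 200)), "baseline_window")
  expect_error(cohort_spec(script_durations = c(S1 = -3, S2 = 87)),
               "positive")
  expect_error(cohort_spec(target_tau = list(
    S1 = c(attitude = 1.2, investment = 0), S2 = c(attitude = 0, investment = 0))),
    "target_tau")
  expect_error(cohort_spec(target_tau = list(
    S1 = c(investment = 0), S2 = c(attitude = 0, investment = 0))),
    "attitude")
  expect_error(cohort_spec(channel_gains = list(S1 = matrix(1, 2, 2),
                                                S2 = matrix(1, 4, 2))),
               "4 x 2")
  expect_error(cohort_spec(channel_gains = list(S1 = matrix(-1, 4, 2),
                                                S2 = matrix(1, 4, 2))),
               "positive")
})

test_that("identical spec and seed give bit-identical outputs", {
  spec <- cohort_spec(n_participants = 3, seed = 11)
  expect_identical(generate_signals(spec, 2, "S1"),
                   generate_signals(spec, 2, "S1"))
  expect_identical(generate_pupil(spec, 1, "S2", 2, 2),
                   generate_pupil(spec, 1, "S2", 2, 2))
  faa <- participant_truth(spec, 1, "S1")$faa
  expect_identical(generate_behavior(spec, rep(c(faa, 0), length.out = 3), "S1"),
                   generate_behavior(spec, rep(c(faa, 0), length.out = 3), "S1"))
  # different seed changes the data
  spec2 <- cohort_spec(n_participants = 3, seed = 12)
  expect_false(identical(generate_signals(spec, 1, "S1")$samples,
                         generate_signals(spec2, 1, "S1")$samples))
})

test_that("signal recordings have coherent geometry and events", {
  spec <- cohort_spec(n_participants = 2, seed = 4)
  rec <- generate_signals(spec, 1, "S1")
  expect_identical(rec$channels, c("F3", "F4", "P3", "P4"))
  expect_equal(nrow(rec$samples), 4)
  # 5 s rest + 51 s script at 250 Hz
  expect_equal(ncol(rec$samples), (5 + 51) * 250)
  expect_equal(rec$events$label, c("rest_onset", "script_onset", "script_end"))
  expect_true(!is.unsorted(rec$events$onset_ms, strictly = TRUE))
  expect_equal(diff(rec$time_ms[1:2]), 4)  # 250 Hz -> 4 ms
})

test_that("copula coupling recovers the target Kendall tau at scale", {
  n <- 5000
  faa <- with_seed_test(99, rnorm(n, -0.095, 1.74))
  for (target in c(-0.5, 0, 0.5)) {
    spec <- cohort_spec(
      n_participants = n, seed = 21,
      target_tau = list(S1 = c(attitude = 0, investment = 0),
                        S2 = c(attitude = 0.2, investment = target)))
    beh <- score_behavior(generate_behavior(spec, faa, "S2"))
    emp <- kendall_tau_b(faa, beh$investment_pct)
    tol <- if (target == 0) 0.03 else 0.05
    expect_lt(abs(emp - target), tol)
  }
})

test_that("attitude items are binary and composites span 4..8", {
  spec <- cohort_spec(n_participants = 2000, seed = 5)
  faa <- with_seed_test(7, rnorm(2000))
  beh <- generate_behavior(spec, faa, "S1")
  items <- as.matrix(beh[c("item_a", "item_b", "item_c", "item_d")])
  expect_true(all(items %in% c(1L, 2L)))
  att <- score_behavior(beh)$attitude
  expect_true(all(att == round(att)))
  expect_true(all(att >= 4 & att <= 8))
  expect_setequal(sort(unique(att)), 4:8)
  # items are a monotone unfolding of the composite: item_a flips first
  expect_true(all(beh$item_a >= beh$item_d))
})

test_that("investment margins reproduce the calibrated condition means", {
  n <- 5000
  faa <- with_seed_test(3, rnorm(n))
  spec <- cohort_spec(n_participants = n, seed = 31)
  for (cond in c("S1", "S2")) {
    cal <- default_calibration()
    m <- cal$mean[cal$variable == "investment" & cal$condition == cond]
    s <- cal$sd[cal$variable == "investment" & cal$condition == cond]
    pct <- score_behavior(generate_behavior(spec, faa, cond))$investment_pct
    expect_true(all(pct >= 0 & pct <= 100))
    expect_lt(abs(mean(pct) - m), 2 * s / sqrt(n))
  }
})

test_that("wallets are positive and invested never exceeds them", {
  spec <- cohort_spec(n_participants = 500, seed = 13)
  beh <- generate_behavior(spec, with_seed_test(1, rnorm(500)), "S2")
  expect_true(all(beh$wallet > 0))
  expect_true(all(beh$wallet <= 15 * 20000))
  expect_true(all(beh$invested >= 0 & beh$invested <= beh$wallet))
})

test_that("pupil traces carry exactly the injected artifacts", {
  for (seed in c(2, 8)) {
    spec <- cohort_spec(n_participants = 2, seed = seed)
    for (cond in c("S1", "S2")) {
      tr <- generate_pupil(spec, 1, cond, blink_count = 3, outlier_count = 2)
      expect_true(all(tr$validity[attr(tr, "blink_idx")] == "blink"))
      expect_true(all(is.na(tr$left_mm[attr(tr, "blink_idx")])))
      dur <- spec$script_durations[[cond]] * 1000
      eps <- split_pupil_epochs(merge_eyes(tr), tr$time_ms,
                                spec$baseline_window, c(0, dur))
      rejected <- unlist(lapply(eps, function(e) {
        r <- reject_outliers(e)
        sum(is.na(r$samples) & !is.na(e$samples))
      }))
      expect_identical(sum(rejected), length(attr(tr, "outlier_idx")))
    }
  }
})

test_that("artifact requests beyond trace capacity are rejected", {
  spec <- cohort_spec(n_participants = 2, seed = 1)
  expect_error(generate_pupil(spec, 1, "S1", blink_count = 1e4),
               "capacity")
  expect_error(generate_pupil(spec, 1, "S1", blink_count = -1), ">= 0")
})

test_that("cohorts round-trip through the plain-text serialization", {
  spec <- cohort_spec(n_participants = 2, seed = 17)
  cohort <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  manifest_path <- write_cohort(cohort, dir)
  manifest <- jsonlite::fromJSON(manifest_path)
  expect_equal(manifest$n_participants, 2)
  rec0 <- cohort$signals$S1[[1]]
  rec <- read_signal_csv(file.path(dir, manifest$recordings$p01_S1$signals),
                         file.path(dir, manifest$recordings$p01_S1$events))
  expect_equal(rec$samples, rec0$samples, ignore_attr = TRUE)
  expect_equal(rec$rate, rec0$rate)
  tr <- read_pupil_csv(file.path(dir, manifest$recordings$p01_S1$pupil))
  expect_equal(tr$left_mm, cohort$pupil$S1[[1]]$left_mm)
  # asymmetries recomputed from the serialized form match in-memory ones
  expect_equal(compute_asymmetry(rec)$FAA, compute_asymmetry(rec0)$FAA,
               tolerance = 1e-12)
})
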