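test_that("prior specifications are validated and canonicalized", {
  expect_error(prior_spec("cauchy", -1), "positive")
  expect_error(prior_spec("cauchy", c(1, 2)), "positive scalar")
  expect_equal(prior_spec("cauchy", 0.707)$width, sqrt(2) / 2)
  expect_equal(prior_spec("cauchy", 1.41)$width, sqrt(2))
  expect_equal(prior_spec("stretched_beta", 1.5)$width, 1.5)
  expect_error(jzs_ttest_bf(1, 10, prior_spec("stretched_beta", 1)),
               "Cauchy")
  expect_error(kendall_tau_bf(0.3, 10, prior_spec("cauchy", 1)),
               "stretched-beta")
})

test_that("the induced prior on the population tau integrates to one", {
  for (kappa in c(1, 1.5, 2)) {
    mass <- integrate(faabayes:::stretched_beta_tau_density, -1, 1,
                      kappa = kappa, rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8)
    half <- integrate(faabayes:::stretched_beta_tau_density, 0, 1,
                      kappa = kappa, side = "positive",
                      rel.tol = 1e-10)$value
    expect_equal(half, 1, tolerance = 1e-8)
  }
})

test_that("JZS t-test Bayes factors behave like a default Bayes test", {
  # null-concordant data favor H0; strong signal gives decisive evidence
  expect_lt(jzs_ttest_bf(0, 21)$bf10, 1)
  expect_gt(jzs_ttest_bf(6, 21)$bf10, 100)
  # two-sided symmetry in t
  for (t in c(0.5, 1.7, 3.2))
    expect_equal(jzs_ttest_bf(t, 21)$bf10, jzs_ttest_bf(-t, 21)$bf10,
                 tolerance = 1e-8)
  # one-sided halves average to the two-sided Bayes factor
  for (t in c(-1, 2.4)) {
    b2 <- jzs_ttest_bf(t, 21)$bf10
    bp <- jzs_ttest_bf(t, 21, prior_spec("cauchy", 0.707, "positive"))$bf10
    bn <- jzs_ttest_bf(t, 21, prior_spec("cauchy", 0.707, "negative"))$bf10
    expect_equal((bp + bn) / 2, b2, tolerance = 1e-6)
  }
  expect_error(jzs_ttest_bf(Inf, 21), "finite")
  expect_error(jzs_ttest_bf(1, 1), "at least 2")
})

test_that("JZS quadrature agrees with Monte-Carlo integration", {
  set.seed(71)
  for (i in 1:5) {
    t <- runif(1, -3, 3)
    n <- sample(8:40, 1)
    w <- sample(c(0.707, 1, 1.41), 1)
    bf <- jzs_ttest_bf(t, n, prior_spec("cauchy", w))$bf10
    mc <- jzs_bf_mc(t, n, faabayes:::canonical_width("cauchy", w),
                    draws = 2e5)
    expect_equal(bf, mc, tolerance = 0.02)
  }
})

test_that("Kendall Bayes factors are symmetric, monotone and consistent", {
  # two-sided symmetry in tau
  expect_equal(kendall_tau_bf(0.4, 21)$bf10, kendall_tau_bf(-0.4, 21)$bf10,
               tolerance = 1e-8)
  # null-concordant data favor H0
  expect_lt(kendall_tau_bf(0, 21)$bf10, 1)
  # monotone growth in |tau| at fixed n and width
  grid <- seq(0, 0.6, by = 0.1)
  bfs <- vapply(grid, function(tt) kendall_tau_bf(tt, 21)$bf10, 0)
  expect_true(all(diff(bfs) > 0))
  # consistency: evidence grows without bound in n at tau = 0.5
  bfn <- vapply(c(10, 50, 200, 1000),
                function(n) kendall_tau_bf(0.5, n)$bf10, 0)
  expect_true(all(diff(bfn) > 0))
  expect_gt(bfn[4] / bfn[1], 1e6)
  # one-sided halves average to the two-sided value
  b2 <- kendall_tau_bf(0.3, 21)$bf10
  bp <- kendall_tau_bf(0.3, 21, prior_spec("stretched_beta", 1, "positive"))$bf10
  bn <- kendall_tau_bf(0.3, 21, prior_spec("stretched_beta", 1, "negative"))$bf10
  expect_equal((bp + bn) / 2, b2, tolerance = 1e-6)
  expect_gt(bp, bn)  # the concordant direction carries the evidence
  expect_error(kendall_tau_bf(1, 21), "-1, 1")
  expect_error(kendall_tau_bf(0.2, 3), "at least 4")
})

test_that("Kendall quadrature agrees with Monte-Carlo integration", {
  set.seed(72)
  for (i in 1:5) {
    tau <- runif(1, -0.7, 0.7)
    n <- sample(8:40, 1)
    kappa <- sample(c(1, 1.5, 2), 1)
    bf <- kendall_tau_bf(tau, n, prior_spec("stretched_beta", kappa))$bf10
    mc <- kendall_bf_mc(tau, n, kappa, draws = 2e5)
    expect_equal(bf, mc, tolerance = 0.02)
  }
})

test_that("evidence bands follow the conventional ladder", {
  expect_equal(classify_bf(102.3), "extreme evidence for H1")
  expect_equal(classify_bf(1), "equal evidence for H1 and H0")
  expect_equal(classify_bf(0.2), "moderate evidence for H0")
  expect_equal(classify_bf(5), "moderate evidence for H1")
  expect_equal(classify_bf(13.7), "strong evidence for H1")
  expect_equal(classify_bf(45), "very strong evidence for H1")
  expect_equal(classify_bf(1.5), "anecdotal evidence for H1")
  expect_equal(classify_bf(0.8), "anecdotal evidence for H0")
  expect_equal(classify_bf(0.05), "strong evidence for H0")
  expect_equal(classify_bf(0.02), "very strong evidence for H0")
  expect_equal(classify_bf(0.005), "extreme evidence for H0")
  # boundaries go to the stronger band
  expect_equal(classify_bf(3), "moderate evidence for H1")
  expect_equal(classify_bf(100), "extreme evidence for H1")
  expect_equal(classify_bf(1 / 10), "strong evidence for H0")
  expect_error(classify_bf(0), "positive")
})

test_that("robustness analysis reports the modal band across widths", {
  rob <- bf_robustness("kendall", 0.559, 21)
  expect_equal(rownames(rob$table), c("default", "wide", "ultrawide"))
  expect_equal(rob$table$width, c(1, 1.5, 2))
  # anecdotal H0 under the default but moderate H0 under both wider
  # priors counts as mostly moderate
  rob2 <- bf_robustness("kendall", 0.120, 21)
  expect_equal(rob2$table$band[1], "anecdotal evidence for H0")
  expect_equal(rob2$table$band[2], "moderate evidence for H0")
  expect_equal(rob2$verdict, "moderate evidence for H0")
  expect_error(bf_robustness("kendall", 0.3, 21, widths = c(1, 1, 2)),
               "strictly increasing")
  # t-test route uses the Cauchy ladder
  robt <- bf_robustness("ttest", 2.8, 21)
  expect_equal(robt$table$width, c(0.707, 1, 1.41))
  expect_true(all(diff(robt$table$bf10) < 0))  # wider prior dilutes evidence
})
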