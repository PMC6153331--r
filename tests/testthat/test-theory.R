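# Closed-form SNR components and their constrained maximization.

test_that("v_max matches its closed form, the jitter-free limit, and a Monte-Carlo peak", {
  # frozen closed-form value at the P = 5 optimal geometry
  expect_equal(v_max(11, 3.2, 8.9), 0.62892, tolerance = 1e-4)

  # zero-jitter limit is the LIF charging curve, exactly
  tau <- c(3, 8.9, 25)
  expect_equal(v_max(tau, 0, tau), rep(1 - exp(-1), 3), tolerance = 1e-9)
  expect_equal(v_max(7, 0, 13), 1 - exp(-7 / 13), tolerance = 1e-9)
  # continuity across the small-T branch
  expect_equal(v_max(7, 1e-7, 13), 1 - exp(-7 / 13), tolerance = 1e-6)

  # long-subsection limit saturates at 1
  expect_equal(v_max(1e5, 3.2, 8.9), 1, tolerance = 1e-8)

  # Monte-Carlo oracle: threshold-free LIF driven by a dense spike packet
  # of duration dt with per-spike uniform jitter, peak normalized by the
  # steady state rho * tau
  set.seed(99)
  dt_w <- 11; T <- 3.2; tau1 <- 8.9; K <- 8000; reps <- 40
  peaks <- replicate(reps, {
    ts <- sort(runif(K, 0, dt_w) + runif(K, -T, T))
    d <- diff(c(ts[1], ts))
    V <- numeric(K); V[1] <- 1
    ef <- exp(-d / tau1)
    for (j in 2:K) V[j] <- V[j - 1] * ef[j] + 1
    max(V)
  })
  expect_equal(mean(peaks) / (K / dt_w * tau1), v_max(dt_w, T, tau1),
               tolerance = 0.02)
})

test_that("v_max is monotone in subsection duration and jitter, and bounded", {
  set.seed(1)
  for (i in 1:20) {
    tau <- runif(1, 1, 30)
    T <- runif(1, 0, 10)
    dts <- sort(runif(5, 0.5, 60))
    vals <- v_max(dts, T, tau)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_true(all(diff(vals) >= -1e-12))       # non-decreasing in dt
    Ts <- sort(runif(5, 0, 12))
    vT <- v_max(10, Ts, tau)
    expect_true(all(diff(vT) <= 1e-12))          # non-increasing in T
  }
  expect_error(v_max(-1, 3, 8), "positive")
  expect_error(v_max(5, 3, 0), "positive")
})

test_that("expected connected-afferent count follows the Poisson closed form", {
  p5 <- standard_params()
  expect_equal(expected_M(p5, 11), 1613.82, tolerance = 1e-5)
  expect_equal(signif(expected_M(p5, 11), 2), 1600)
  expect_equal(expected_M(p5, 0), 0)
  expect_error(expected_M(p5, 101), "L")

  p1 <- theory_params(1e4, 1, P = 1, L = 10)
  expect_equal(expected_M(p1, 2), 1e4 * (1 - exp(-0.002)), tolerance = 1e-9)
  expect_equal(expected_M(p1, 2), 19.98, tolerance = 1e-3)

  # monotone in dt and in P, bounded by N
  expect_true(all(diff(expected_M(p5, c(1, 5, 20, 100))) > 0))
  expect_lt(expected_M(p5, 100), p5$N)
  expect_gt(expected_M(theory_params(1e4, 3.2, 3.2, 10), 11),
            expected_M(p5, 11))

  # Monte-Carlo cross-check: afferents with >= 1 spike in any of P windows
  set.seed(5)
  N <- 500; f <- 10; dtw <- 2; P <- 2
  draws <- replicate(400, {
    k <- rpois(P, N * f / 1000 * dtw)
    length(unique(sample.int(N, sum(k), replace = TRUE)))
  })
  pm <- theory_params(N, f, P = P, L = 10)
  expect_lt(abs(mean(draws) - expected_M(pm, dtw)),
            3 * sd(draws) / sqrt(length(draws)))
})

test_that("expected input rate is f * N", {
  expect_equal(expected_r(standard_params()), 32000)
  expect_equal(expected_r(theory_params(1e4, 5, P = 1)), 50000)
})

test_that("noise-period potential moments match shot-noise theory and an Euler simulation", {
  expect_equal(noise_stats(8.9, 3.2, 0), c(mean = 0, sd = 0))
  ns <- noise_stats(8.9, 3.2, 1614)
  expect_equal(unname(ns["mean"]), 45.97, tolerance = 1e-3)
  expect_equal(unname(ns["sd"]), 4.79, tolerance = 1e-2)

  # doubling M doubles the mean and scales the sd by sqrt(2)
  n1 <- noise_stats(10, 5, 300); n2 <- noise_stats(10, 5, 600)
  expect_equal(unname(n2["mean"] / n1["mean"]), 2)
  expect_equal(unname(n2["sd"] / n1["sd"]), sqrt(2))

  # Euler-integration oracle with Poisson input
  set.seed(17)
  tau <- 10; f <- 20; M <- 50; dt <- 0.1; nb <- 4e5
  jumps <- rpois(nb, f / 1000 * M * dt)
  V <- as.numeric(stats::filter(jumps, 1 - dt / tau, method = "recursive"))
  V <- V[-(1:5000)]
  th <- noise_stats(tau, f, M)
  expect_equal(mean(V), unname(th["mean"]), tolerance = 0.03)
  expect_equal(sd(V), unname(th["sd"]), tolerance = 0.05)
})

test_that("expected SNR reproduces the published values at the published geometries", {
  for (i in seq_len(nrow(published_optima))) {
    row <- published_optima[i, ]
    p <- standard_params(row$P)
    comp <- expected_snr(p, detector_geometry(p, row$tau_opt, row$dt_opt))
    expect_equal(signif(comp$snr, 2), row$snr_opt,
                 info = paste("P =", row$P))
  }
})

test_that("expected SNR scales with the afferent count and degenerates safely", {
  p <- standard_params()
  g <- list(tau = 8.9, dt_window = 11)
  p2 <- theory_params(2e4, 3.2, 3.2, 5, 100)
  expect_gt(expected_snr(p2, detector_geometry(p2, 8.9, 11))$snr,
            expected_snr(p, detector_geometry(p, 8.9, 11))$snr)
  # dt -> 0: v_max and <M> vanish, SNR -> 0 (like sqrt(dt))
  tinies <- vapply(c(1e-4, 1e-6, 1e-8), function(d)
    expected_snr(p, detector_geometry(p, 8.9, d))$snr, 0)
  expect_true(all(diff(tinies) < 0))
  expect_lt(tinies[3], 0.01)
  expect_error(detector_geometry(p, 8.9, 0), "positive")
  expect_error(detector_geometry(p, 0, 11), "positive")
})

test_that("constrained SNR maximization agrees with a dense grid-search oracle", {
  for (P in c(5, 40)) {
    p <- standard_params(P)
    opt <- optimize_snr(p, enforce_dt_max = FALSE)
    taus <- exp(seq(log(1), log(60), length.out = 220))
    dts <- exp(seq(log(0.5), log(60), length.out = 220))
    grid <- outer(taus, dts, function(a, b) snr_surface(a, b, p))
    i <- which(grid == max(grid), arr.ind = TRUE)
    # the optimizer must beat (or tie) the grid and sit within one grid
    # step of the grid argmax
    expect_gte(opt$snr, max(grid) - 1e-9)
    expect_equal(log(opt$geometry$tau), log(taus[i[1]]),
                 tolerance = 1.1 * diff(log(taus))[1])
    expect_equal(log(opt$geometry$dt_window), log(dts[i[2]]),
                 tolerance = 1.1 * diff(log(dts))[1])
  }
})

test_that("optimal SNR decreases with the pattern count and with jitter", {
  tab <- table1_analytic(P = c(5, 10, 20, 40))
  expect_true(all(diff(tab$snr_opt) < 0))
  snrs <- vapply(c(1, 3.2, 6), function(T)
    optimize_snr(theory_params(1e4, 3.2, T, 5), enforce_dt_max = FALSE)$snr,
    0)
  expect_true(all(diff(snrs) < 0))
})

test_that("the mean-input constraint binds when tightened and infeasibility is signalled", {
  p <- standard_params()
  free <- optimize_snr(p, enforce_dt_max = FALSE)
  expect_false(free$constraint_active)
  tight <- optimize_snr(p, min_mean_inputs = 200, enforce_dt_max = FALSE)
  expect_true(tight$constraint_active)
  expect_equal(tight$geometry$tau * 3.2e-3 * tight$geometry$M_expected, 200,
               tolerance = 1e-3)
  expect_lt(tight$snr, free$snr)
  expect_error(optimize_snr(p, min_mean_inputs = 1e12), "infeasible")
})

test_that("reduced-SNR sampling is deterministic, concentrated, and matches the plug-in mean", {
  p <- theory_params(1e4, 1, P = 1, L = 10)
  a <- reduced_snr_sample(p, 2, n_draws = 50, seed = 7)
  b <- reduced_snr_sample(p, 2, n_draws = 50, seed = 7)
  expect_identical(a, b)
  one <- reduced_snr_sample(p, 2, n_draws = 1, seed = 3)
  expect_identical(one, reduced_snr_sample(p, 2, n_draws = 1, seed = 3))

  s <- reduced_snr_sample(p, 2, n_draws = 2e4, seed = 42)
  expect_equal(mean(s$snr_reduced) / s$plug_in, 1, tolerance = 0.02)
  expect_lt(sd(s$snr_reduced) / mean(s$snr_reduced), 0.2)

  # draws with no connected afferent are excluded and counted
  sparse <- reduced_snr_sample(theory_params(3, 0.5, P = 1, L = 10), 1,
                               n_draws = 200, seed = 1)
  expect_equal(length(sparse$snr_reduced) + sparse$n_excluded, 200)
  expect_gt(sparse$n_excluded, 0)
})
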