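# Validation experiments, learning runs, and detector evaluation.

# a minimal hand-built fit for exercising evaluate() arithmetic
fake_fit <- function(params, w, out_spikes, onsets, duration,
                     pattern_set) {
  structure(list(params = params, duration = duration,
                 w = w, w0 = 0.5, out_spikes = out_spikes,
                 annotation = list(period = 400, onsets = onsets),
                 convergence_index = data.frame(time = duration,
                                                value = convergence_index(w)),
                 pattern_set = pattern_set,
                 n_potentiated = sum(w > 0.5)),
            class = "stdp_fit")
}

test_that("the convergence index is the mean distance to binary weights", {
  expect_equal(convergence_index(c(0, 1, 1, 0)), 0)
  expect_equal(convergence_index(rep(0.5, 7)), 0.5)
  expect_equal(convergence_index(c(0.1, 0.9, 0.5, 1.0)), 0.175)
  expect_error(convergence_index(c(-0.1, 0.5)))
  expect_error(convergence_index(1.2))
})

test_that("evaluate scores hits, false alarms, and the optimality margins", {
  p <- theory_params(100, 3.2, 3.2, 2, 100)
  ps <- generate_pattern_set(p, seed = 2)
  geom <- detector_geometry(p, tau = 10, dt_window = 20)
  on <- data.frame(time = seq(150, 40000 - 250, by = 400),
                   pattern = rep(c(1L, 2L), 50))
  # potentiate exactly the afferents firing in the first 20 ms of either
  # pattern; spike once inside every presentation window
  conn <- unique(unlist(lapply(ps$patterns,
                               function(q) q$afferent[q$time < 20])))
  w <- numeric(100); w[conn] <- 1
  fit <- fake_fit(p, w, out_spikes = on$time + 50, onsets = on,
                  duration = 40000, pattern_set = ps)
  ev <- evaluate(fit, geometry_opt = geom, epoch_fraction = 1)
  expect_equal(ev$P_learned, 2)
  expect_equal(ev$hit_rate, 100)
  expect_equal(ev$false_alarm_rate, 0)
  expect_equal(ev$n_potentiated, length(conn))
  expect_true(all(ev$subsection_ok))

  # no output spikes: nothing learned, not optimal
  ev0 <- evaluate(fake_fit(p, w, numeric(0), on, 40000, ps),
                  geometry_opt = geom, epoch_fraction = 1)
  expect_equal(ev0$P_learned, 0)
  expect_false(ev0$optimal)
  expect_equal(ev0$hit_rate, 0)

  # a potentiated count 6% above the optimum violates the 5% margin
  M <- geom$M_expected
  w_over <- numeric(100)
  w_over[seq_len(min(100, round(1.06 * M)))] <- 1
  ev_over <- evaluate(fake_fit(p, w_over, on$time + 50, on, 40000, ps),
                      geometry_opt = geom, epoch_fraction = 1)
  expect_false(ev_over$optimal)

  # spikes outside every window are false alarms at the right rate
  fa_fit <- fake_fit(p, w, out_spikes = c(on$time + 50, 10, 30, 130),
                     onsets = on, duration = 40000, pattern_set = ps)
  ev_fa <- evaluate(fa_fit, geometry_opt = geom, epoch_fraction = 1)
  expect_equal(ev_fa$false_alarm_rate, 3 / 40, tolerance = 1e-9)
})

test_that("a zero-duration run returns the uniform initial state", {
  p <- theory_params(200, 3.2, 3.2, 2, 100)
  fit <- run_learning(p, neuron_config(tau = 13, theta0 = 5),
                      plasticity_config(w_out = -6e-3), duration = 0,
                      seed = 1)
  expect_true(all(fit$w == fit$w0))
  expect_length(fit$out_spikes, 0)
  expect_equal(fit$convergence_index$value, min(fit$w0, 1 - fit$w0))
})

test_that("the threshold-free simulator recovers the reduced peak in the zero-jitter limit", {
  # population large enough that the small upward bias of the
  # noisy-trajectory peak estimator stays below the tolerance
  p <- theory_params(2000, 20, T = 0, P = 1, L = 10)
  geom <- detector_geometry(p, tau = 10, dt_window = 10)
  mc <- validate_snr_montecarlo(p, geom, n_patterns = 5,
                                n_presentations = 60, seed = 5)
  # dt = tau: empirical v_max near 1 - exp(-1)
  expect_equal(mean(mc$v_max), 1 - exp(-1), tolerance = 0.05)
  expect_lt(abs(mc$mean - mc$theory), 3 * mc$sd)
})

test_that("without depression the weights saturate high and optimality fails", {
  p <- theory_params(400, 3.2, 3.2, 1, 100)
  opt <- optimize_snr(p, enforce_dt_max = FALSE)
  co <- opt$components
  vpk <- co$V_noise_mean + co$v_max * (co$V_inf - co$V_noise_mean)
  fit <- run_learning(p, neuron_config(tau = opt$geometry$tau,
                                       theta0 = 0.9 * vpk),
                      plasticity_config(w_out = -1e-6),
                      duration = 4e5, seed = 3)
  ev <- evaluate(fit, geometry_opt = opt$geometry)
  expect_gt(fit$n_potentiated, 1.2 * opt$geometry$M_expected)
  expect_false(ev$optimal)
})

test_that("an unreachable threshold yields no output spikes and no learning", {
  p <- theory_params(300, 3.2, 3.2, 1, 100)
  fit <- run_learning(p, neuron_config(tau = 13, theta0 = 1e6),
                      plasticity_config(w_out = -6e-3),
                      duration = 1e5, seed = 4)
  expect_length(fit$out_spikes, 0)
  expect_true(all(fit$w == fit$w0))
  expect_equal(evaluate(fit, geometry_opt =
                          optimize_snr(p)$geometry)$P_learned, 0)
})

test_that("geometric grids have the requested ratio and the search reports optimal fractions", {
  g <- geometric_grid(100, 5)
  expect_equal(g[3], 100)
  expect_equal(unique(round(g[-1] / g[-5], 10)), 1.025)

  p <- theory_params(300, 3.2, 3.2, 1, 100)
  opt <- optimize_snr(p, enforce_dt_max = FALSE)
  co <- opt$components
  vpk <- co$V_noise_mean + co$v_max * (co$V_inf - co$V_noise_mean)
  hs <- hyperparameter_search(p, theta0_grid = 0.9 * vpk,
                              w_out_grid = c(-6e-3, -1e-6),
                              duration = 2e5, n_repeats = 2, seed = 9,
                              geometry_opt = opt$geometry)
  expect_equal(nrow(hs$table), 2)
  expect_true(all(hs$table$p_optimal >= 0 & hs$table$p_optimal <= 1))
  expect_equal(nrow(hs$best), 1)
})

test_that("the full-scale protocol runner shrinks consistently with its scale factor", {
  tab <- run_table1_simulation(P = 5, scale = 0.04, seed = 6)
  expect_equal(nrow(tab), 1)
  expect_true(is.finite(tab$hit_rate))
  expect_true(tab$P_learned >= 0 && tab$P_learned <= 5)
  expect_gte(tab$false_alarm_rate, 0)
})
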