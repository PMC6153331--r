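# Analytic SNR theory for a multi-pattern coincidence detector.
#
# All public interfaces take times in ms and rates in Hz; internally every
# rate is converted to events/ms at the computation boundary so that all
# time-like quantities share one unit.

#' Problem parameters for the multi-pattern detection task
#'
#' Bundles the imposed variables of the detection problem: a population of
#' `N` afferents firing as homogeneous Poisson processes at rate `f`, from
#' which `P` frozen spike patterns of duration `L` are drawn and replayed
#' with per-spike uniform jitter on `[-T, T]`.
#'
#' @param N Number of afferent neurons (>= 1).
#' @param f Afferent firing rate in Hz (> 0).
#' @param T Maximal jitter half-width in ms (>= 0).
#' @param P Number of repeating patterns (>= 1).
#' @param L Pattern duration in ms (> 0).
#' @return An object of class `"theory_params"`: a list with fields
#'   `N`, `f`, `T`, `P`, `L`.
#' @examples
#' theory_params(N = 1e4, f = 3.2, T = 3.2, P = 5, L = 100)
#' @export
theory_params <- function(N, f, T = 0, P = 1, L = 100) {
  stopifnot(length(N) == 1, length(f) == 1, length(T) == 1,
            length(P) == 1, length(L) == 1)
  if (!is.finite(N) || N < 1 || N != round(N))
    stop("'N' must be a positive integer count of afferents")
  if (!is.finite(f) || f <= 0) stop("'f' must be a positive rate in Hz")
  if (!is.finite(T) || T < 0) stop("'T' must be a non-negative jitter in ms")
  if (!is.finite(P) || P < 1 || P != round(P))
    stop("'P' must be a positive integer count of patterns")
  if (!is.finite(L) || L <= 0) stop("'L' must be a positive duration in ms")
  structure(list(N = as.integer(N), f = f, T = T, P = as.integer(P), L = L),
            class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat(sprintf(
    "Detection problem: N = %d afferents at f = %g Hz, P = %d pattern(s) of L = %g ms, jitter T = %g ms\n",
    x$N, x$f, x$P, x$L, x$T))
  invisible(x)
}

#' Detector geometry: the free variables of the detector
#'
#' The detector is characterised by the membrane time constant `tau` and the
#' duration `dt_window` of the pattern subsection whose firing afferents are
#' connected. The derived quantities `M_expected` (expected number of
#' connected afferents) and `r_expected` (expected input rate during a
#' subsection, which equals `f * N`) are filled in from `params`.
#'
#' @param params A [theory_params()] object.
#' @param tau Membrane time constant in ms (> 0).
#' @param dt_window Subsection duration in ms, `0 < dt_window <= L`.
#' @return An object of class `"detector_geometry"` with fields `tau`,
#'   `dt_window`, `M_expected`, `r_expected` (Hz).
#' @examples
#' p <- theory_params(1e4, 3.2, 3.2, 5)
#' detector_geometry(p, tau = 8.9, dt_window = 11)
#' @export
detector_geometry <- function(params, tau, dt_window) {
  stopifnot(inherits(params, "theory_params"))
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be a positive time in ms")
  if (!is.finite(dt_window) || dt_window <= 0)
    stop("'dt_window' must be a positive duration in ms")
  if (dt_window > params$L)
    stop("'dt_window' must not exceed the pattern duration L")
  structure(list(tau = tau, dt_window = dt_window,
                 M_expected = expected_M(params, dt_window),
                 r_expected = expected_r(params)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "Detector geometry: tau = %g ms, dt_window = %g ms  (<M> = %.1f afferents, <r> = %g Hz)\n",
    x$tau, x$dt_window, x$M_expected, x$r_expected))
  invisible(x)
}

#' Reduced peak potential of the detector during a pattern subsection
#'
#' Closed form for the peak membrane potential reached during a jittered
#' pattern subsection, rescaled to `[0, 1]` between the mean noise-period
#' potential (0) and the steady state that an infinitely long subsection
#' would reach (1):
#' \deqn{v_{max} = \min(1, \Delta t / 2T) -
#'   \frac{\tau}{2T}\log\left(1 - e^{-\max(\Delta t, 2T)/\tau}
#'   + e^{-|\Delta t - 2T|/\tau}\right).}
#' In the zero-jitter limit this reduces to the LIF charging curve
#' `1 - exp(-dt_window/tau)`; below `T = 1e-6` ms the limit form is used to
#' avoid catastrophic cancellation.
#'
#' @param dt_window Subsection duration in ms (> 0). Vectorised.
#' @param T Jitter half-width in ms (>= 0).
#' @param tau Membrane time constant in ms (> 0). Vectorised.
#' @return Dimensionless reduced peak in `[0, 1]`, same length as the
#'   recycled arguments.
#' @examples
#' v_max(11, 3.2, 8.9)           # ~0.63
#' v_max(8.9, 0, 8.9)            # 1 - exp(-1)
#' @export
v_max <- function(dt_window, T, tau) {
  if (any(!is.finite(dt_window)) || any(dt_window <= 0))
    stop("'dt_window' must be positive")
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("'tau' must be positive")
  if (any(!is.finite(T)) || any(T < 0)) stop("'T' must be non-negative")
  n <- max(length(dt_window), length(T), length(tau))
  dt_window <- rep_len(dt_window, n)
  T <- rep_len(T, n)
  tau <- rep_len(tau, n)
  out <- numeric(n)
  small <- T < 1e-6
  out[small] <- 1 - exp(-dt_window[small] / tau[small])
  if (any(!small)) {
    d <- dt_window[!small]; tt <- T[!small]; tu <- tau[!small]
    out[!small] <- pmin(1, d / (2 * tt)) -
      tu / (2 * tt) *
        log(1 - exp(-pmax(d, 2 * tt) / tu) + exp(-abs(d - 2 * tt) / tu))
  }
  # clamp tiny negative round-off
  pmin(1, pmax(0, out))
}

#' Expected number of connected afferents
#'
#' An afferent is connected when it emits at least one spike in at least one
#' of the `P` independent pattern subsections of duration `dt_window`. With
#' Poisson firing the count is on average
#' `N * (1 - exp(-P * f * dt_window))` (`f` converted to events/ms).
#'
#' @param params A [theory_params()] object.
#' @param dt_window Subsection duration in ms, `0 < dt_window <= L`.
#'   `dt_window = 0` is allowed and returns 0. Vectorised.
#' @return Expected connected-afferent count, in `[0, N]`.
#' @examples
#' expected_M(theory_params(1e4, 3.2, 3.2, 5), 11)  # ~1614
#' @export
expected_M <- function(params, dt_window) {
  stopifnot(inherits(params, "theory_params"))
  if (any(!is.finite(dt_window)) || any(dt_window < 0))
    stop("'dt_window' must be non-negative")
  if (any(dt_window > params$L))
    stop("'dt_window' must not exceed the pattern duration L")
  f_ms <- params$f / 1000
  params$N * (1 - exp(-params$P * f_ms * dt_window))
}

#' Expected input rate during a pattern subsection
#'
#' The expected total number of spikes received during a subsection is
#' `f * N * dt_window`; divided by the subsection duration this gives the
#' expected input rate `f * N`, independent of the subsection.
#'
#' @param params A [theory_params()] object (with `N` possibly 0 allowed
#'   through direct field access for degenerate checks).
#' @return Expected rate in Hz.
#' @export
expected_r <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  params$f * params$N
}

#' Noise-period membrane potential moments
#'
#' During noise periods the LIF with `M` connected unitary synapses driven
#' by independent Poisson afferents at rate `f` is a shot-noise process:
#' mean potential `tau * f * M` and standard deviation
#' `sqrt(tau * f * M / 2)` (with `tau` and `1/f` in the same time unit; each
#' input spike causes a unit potential jump).
#'
#' @param tau Membrane time constant in ms.
#' @param f Afferent rate in Hz.
#' @param M Number of connected afferents (may be the expectation).
#' @return Named numeric vector `c(mean = , sd = )` in potential units.
#' @examples
#' noise_stats(8.9, 3.2, 1614)  # mean ~46.0, sd ~4.8
#' @export
noise_stats <- function(tau, f, M) {
  if (any(tau <= 0)) stop("'tau' must be positive")
  if (any(f < 0) || any(M < 0)) stop("'f' and 'M' must be non-negative")
  m <- tau / 1000 * f * M
  c(mean = m, sd = sqrt(m / 2))
}

#' Expected signal-to-noise ratio of the detector
#'
#' Computes the expected SNR of the threshold-free LIF detector across
#' Poisson pattern realizations,
#' \deqn{\langle SNR \rangle = v_{max}\,\sqrt{2\tau/f}\;
#'   \frac{\langle r\rangle - f\langle M\rangle}{\sqrt{\langle M\rangle}},}
#' together with all intermediate components. The SNR is the distance
#' between the peak potential reached during a pattern and the mean
#' noise-period potential, in units of the noise standard deviation.
#'
#' @param params A [theory_params()] object.
#' @param geometry A [detector_geometry()] object (or a list with `tau` and
#'   `dt_window`, from which one is built).
#' @return An object of class `"snr_components"`: list with `v_max`,
#'   `V_noise_mean`, `V_noise_sd`, `V_inf`, `snr_reduced` (events/ms
#'   units), and `snr`.
#' @examples
#' p <- theory_params(1e4, 3.2, 3.2, 5)
#' expected_snr(p, detector_geometry(p, 8.9, 11))$snr  # ~31
#' @export
expected_snr <- function(params, geometry) {
  stopifnot(inherits(params, "theory_params"))
  if (!inherits(geometry, "detector_geometry"))
    geometry <- detector_geometry(params, geometry$tau, geometry$dt_window)
  f_ms <- params$f / 1000
  M <- geometry$M_expected
  if (M <= 0)
    stop("degenerate geometry: expected number of connected afferents is 0")
  r_ms <- f_ms * params$N
  vm <- v_max(geometry$dt_window, params$T, geometry$tau)
  ns <- noise_stats(geometry$tau, params$f, M)
  snr_red <- (r_ms - f_ms * M) / sqrt(M)
  structure(list(
    v_max = vm,
    V_noise_mean = unname(ns["mean"]),
    V_noise_sd = unname(ns["sd"]),
    V_inf = geometry$tau * r_ms,
    snr_reduced = snr_red,
    snr = vm * sqrt(2 * geometry$tau / f_ms) * snr_red
  ), class = "snr_components")
}

#' @export
print.snr_components <- function(x, ...) {
  cat(sprintf("Expected SNR: %.4g\n", x$snr))
  cat(sprintf("  v_max = %.4f, V_noise = %.3f +/- %.3f, V_inf = %.3f, reduced snr = %.4f /ms\n",
              x$v_max, x$V_noise_mean, x$V_noise_sd, x$V_inf, x$snr_reduced))
  invisible(x)
}

# internal: SNR as a plain function of (tau, dt) in ms, f in /ms
.snr_value <- function(tau, dt_window, params) {
  f_ms <- params$f / 1000
  M <- params$N * (1 - exp(-params$P * f_ms * dt_window))
  if (M <= 0) return(0)
  vm <- v_max(dt_window, params$T, tau)
  vm * sqrt(2 * tau / f_ms) * (f_ms * params$N - f_ms * M) / sqrt(M)
}

#' Maximize the expected SNR over the detector geometry
#'
#' Finds the membrane time constant and subsection duration maximizing the
#' expected SNR, subject to a minimum mean synaptic input
#' `tau * f * <M> >= min_mean_inputs` (so that the noise-potential
#' distribution is approximately Gaussian rather than positively skewed)
#' and optionally `dt_window <= L`. The search runs multi-start bounded
#' quasi-Newton optimization in log coordinates, seeded from a coarse
#' log-spaced grid; the constraint is enforced by reparametrising
#' `tau = tau_min(dt_window) * exp(s)`, `s >= 0`.
#'
#' @param params A [theory_params()] object.
#' @param min_mean_inputs Lower bound on `tau * f * <M>` (dimensionless;
#'   default 10).
#' @param enforce_dt_max If `TRUE` (default) constrain `dt_window <= L`;
#'   set `FALSE` to reproduce the analytic setting where `L` is assumed
#'   large enough that the bound is inactive.
#' @param tau_max Upper bound on `tau` in ms used to detect infeasibility
#'   (default 1e5).
#' @return An object of class `"snr_optimum"`: list with `params`,
#'   `geometry` (the optimal [detector_geometry()]), `components`
#'   ([expected_snr()] at the optimum), `snr`, `constraint_active`, and
#'   `min_mean_inputs`.
#' @examples
#' opt <- optimize_snr(theory_params(1e4, 3.2, 3.2, 5))
#' coef(opt)          # tau ~8.9 ms, dt_window ~11 ms
#' opt$snr            # ~31
#' @export
optimize_snr <- function(params, min_mean_inputs = 10,
                         enforce_dt_max = TRUE, tau_max = 1e5) {
  stopifnot(inherits(params, "theory_params"))
  f_ms <- params$f / 1000
  dt_hi <- if (enforce_dt_max) params$L else 1e5
  # tau lower bound imposed by the mean-input constraint at a given dt
  tau_min_of <- function(dt) {
    M <- params$N * (1 - exp(-params$P * f_ms * dt))
    if (M <= 0) return(Inf)
    max(1e-9, min_mean_inputs / (f_ms * M))
  }
  if (tau_min_of(dt_hi) > tau_max)
    stop("infeasible constraint: no (tau, dt_window) with tau*f*<M> >= ",
         min_mean_inputs, " and tau <= ", tau_max)

  # objective in (s, log dt) with tau = tau_min(dt) * exp(s)
  neg_obj <- function(x) {
    dt <- exp(x[2])
    tau <- tau_min_of(dt) * exp(x[1])
    if (!is.finite(tau) || tau > tau_max) return(1e10)
    -.snr_value(tau, dt, params)
  }
  # coarse feasible multi-start grid
  dt_grid <- exp(seq(log(min(1e-2, dt_hi / 10)), log(dt_hi), length.out = 40))
  tau_grid <- exp(seq(log(1e-2), log(min(tau_max, 1e4)), length.out = 40))
  starts <- list()
  best_coarse <- -Inf
  for (dt in dt_grid) {
    tmin <- tau_min_of(dt)
    for (tau in tau_grid) {
      if (tau < tmin || tau > tau_max) next
      v <- .snr_value(tau, dt, params)
      if (v > best_coarse) {
        best_coarse <- v
        starts <- c(list(c(log(tau / tmin), log(dt))), starts)
      }
    }
    # also start exactly on the constraint boundary
    if (tmin <= tau_max) {
      v <- .snr_value(tmin, dt, params)
      if (v > best_coarse * 0.5)
        starts <- c(starts, list(c(0, log(dt))))
    }
  }
  starts <- unique(starts[seq_len(min(8, length(starts)))])
  best <- NULL
  for (s0 in starts) {
    fit <- stats::optim(s0, neg_obj, method = "L-BFGS-B",
                        lower = c(0, log(1e-6)), upper = c(40, log(dt_hi)),
                        control = list(factr = 10, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  dt_opt <- exp(best$par[2])
  tau_opt <- tau_min_of(dt_opt) * exp(best$par[1])
  geom <- detector_geometry(params, tau_opt, dt_opt)
  comp <- expected_snr(params, geom)
  active <- tau_opt * f_ms * geom$M_expected <= min_mean_inputs * (1 + 1e-6)
  structure(list(params = params, geometry = geom, components = comp,
                 snr = comp$snr, constraint_active = active,
                 min_mean_inputs = min_mean_inputs),
            class = "snr_optimum")
}

#' @export
print.snr_optimum <- function(x, ...) {
  print(x$params)
  cat(sprintf("Optimal geometry: tau = %.4g ms, dt_window = %.4g ms\n",
              x$geometry$tau, x$geometry$dt_window))
  cat(sprintf("  <M> = %.4g afferents, expected SNR = %.4g\n",
              x$geometry$M_expected, x$snr))
  cat(sprintf("  mean-input constraint tau*f*<M> >= %g: %s\n",
              x$min_mean_inputs,
              if (x$constraint_active) "ACTIVE at the optimum" else "inactive"))
  invisible(x)
}

#' @export
coef.snr_optimum <- function(object, ...) {
  c(tau = object$geometry$tau, dt_window = object$geometry$dt_window)
}

#' @export
summary.snr_optimum <- function(object, ...) {
  out <- c(coef(object),
           M_expected = object$geometry$M_expected,
           snr = object$snr,
           V_noise_mean = object$components$V_noise_mean,
           V_noise_sd = object$components$V_noise_sd,
           v_max = object$components$v_max)
  class(out) <- c("summary.snr_optimum", class(out))
  out
}

#' @export
print.summary.snr_optimum <- function(x, ...) {
  y <- unclass(x)
  print(round(y, 4))
  invisible(x)
}

#' Sample the reduced SNR across Poisson pattern realizations
#'
#' For each draw, realizes the `P` pattern subsections of duration
#' `dt_window` (as Poisson spike counts over `N` afferents), counts the
#' connected afferents `M` (at least one spike in at least one subsection)
#' and the realized input rate `r` (total spikes divided by total
#' subsection time), and returns the reduced SNR `(r - f M) / sqrt(M)` per
#' draw (events/ms units). Draws with `M = 0` are excluded and counted.
#'
#' @param params A [theory_params()] object.
#' @param dt_window Subsection duration in ms.
#' @param n_draws Number of independent pattern realizations (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `snr_reduced` (numeric vector, one per retained draw),
#'   `n_excluded` (draws with `M = 0`), and `plug_in`, the deterministic
#'   approximation `(<r> - f <M>) / sqrt(<M>)`.
#' @examples
#' s <- reduced_snr_sample(theory_params(1e4, 1, P = 1, L = 10), 2,
#'                         n_draws = 1000, seed = 1)
#' mean(s$snr_reduced) / s$plug_in  # close to 1
#' @export
reduced_snr_sample <- function(params, dt_window, n_draws, seed = NULL) {
  stopifnot(inherits(params, "theory_params"), n_draws >= 1)
  if (dt_window <= 0 || dt_window > params$L)
    stop("'dt_window' must be in (0, L]")
  if (!is.null(seed)) set.seed(seed)
  f_ms <- params$f / 1000
  N <- params$N
  lam <- N * f_ms * dt_window  # expected spikes per subsection
  tot_time <- params$P * dt_window
  K <- stats::rpois(n_draws * params$P, lam)
  dim(K) <- c(n_draws, params$P)
  snr <- numeric(n_draws)
  keep <- logical(n_draws)
  for (i in seq_len(n_draws)) {
    k <- sum(K[i, ])
    if (k == 0L) next
    aff <- sample.int(N, k, replace = TRUE)
    M <- length(unique(aff))
    r <- k / tot_time
    snr[i] <- (r - f_ms * M) / sqrt(M)
    keep[i] <- TRUE
  }
  Mbar <- expected_M(params, dt_window)
  list(snr_reduced = snr[keep],
       n_excluded = sum(!keep),
       plug_in = (f_ms * N - f_ms * Mbar) / sqrt(Mbar))
}
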