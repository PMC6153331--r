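# LIF neuron with adaptive threshold and multiplicative STDP.

#' Configuration of the LIF neuron
#'
#' @param tau Membrane time constant in ms.
#' @param theta0 Baseline firing threshold in potential units (a unit-weight
#'   input spike raises the potential by 1). Required when `thresholded`.
#' @param theta_jump_factor Threshold increment at each output spike, as a
#'   multiple of `theta0` (default 1.8).
#' @param tau_theta Threshold decay time constant toward `theta0`, ms
#'   (default 80).
#' @param dt_sim Forward-Euler integration bin in ms (default 0.1).
#' @param thresholded If `FALSE`, the neuron never fires: the threshold-free
#'   mode used by the analytic theory and its Monte-Carlo validation.
#' @param reset_on_spike Reset the potential to 0 after an output spike
#'   (default `TRUE`). The adaptive threshold, not the reset, is the
#'   mechanism discouraging repeated firing to one pattern, so both
#'   variants are available.
#' @return An object of class `"neuron_config"`.
#' @export
neuron_config <- function(tau, theta0 = NULL, theta_jump_factor = 1.8,
                          tau_theta = 80, dt_sim = 0.1,
                          thresholded = TRUE, reset_on_spike = TRUE) {
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be positive (ms)")
  if (dt_sim <= 0) stop("'dt_sim' must be positive (ms)")
  if (tau_theta <= 0) stop("'tau_theta' must be positive (ms)")
  if (thresholded) {
    if (is.null(theta0) || !is.finite(theta0) || theta0 <= 0)
      stop("'theta0' must be positive when the neuron is thresholded")
  } else theta0 <- Inf
  structure(list(tau = tau, theta0 = theta0,
                 theta_jump_factor = theta_jump_factor,
                 tau_theta = tau_theta, dt_sim = dt_sim,
                 thresholded = thresholded,
                 reset_on_spike = reset_on_spike),
            class = "neuron_config")
}

#' Configuration of the STDP rule
#'
#' All-to-all spike STDP: each presynaptic spike increments that synapse's
#' trace by `dA_pre`; the trace decays exponentially with `tau_pre`. At each
#' postsynaptic spike every synapse is potentiated by
#' `w * (1 - w) * A_pre` (LTP) and then depressed by `w * (1 - w) * w_out`
#' (homeostatic LTD, `w_out < 0`). The multiplicative soft-bound factor
#' `w * (1 - w)` keeps weights in `[0, 1]` and drives them to saturate at
#' the bounds after convergence.
#'
#' @param dA_pre Presynaptic trace increment (default 0.1).
#' @param tau_pre Trace decay time constant in ms (default 20).
#' @param w_out Homeostatic depression constant, strictly negative.
#' @return An object of class `"plasticity_config"`.
#' @export
plasticity_config <- function(dA_pre = 0.1, tau_pre = 20, w_out) {
  if (dA_pre <= 0) stop("'dA_pre' must be positive")
  if (tau_pre <= 0) stop("'tau_pre' must be positive (ms)")
  if (!is.finite(w_out) || w_out >= 0) stop("'w_out' must be negative")
  structure(list(dA_pre = dA_pre, tau_pre = tau_pre, w_out = w_out),
            class = "plasticity_config")
}

#' Soft-bound LTP applied at a postsynaptic spike
#'
#' `w <- w + w * (1 - w) * A_pre`. Weights 0 and 1 are fixed points.
#'
#' @param w Weight vector in `[0, 1]`.
#' @param A_pre Presynaptic trace vector (same length, >= 0).
#' @return Updated weights, clamped to `[0, 1]`.
#' @export
ltp_on_post <- function(w, A_pre) {
  pmin(1, pmax(0, w + w * (1 - w) * A_pre))
}

#' Soft-bound homeostatic LTD applied at a postsynaptic spike
#'
#' `w <- w + w * (1 - w) * w_out` with `w_out < 0`, applied to every
#' synapse.
#'
#' @param w Weight vector in `[0, 1]`.
#' @param w_out Negative depression constant.
#' @return Updated weights, clamped to `[0, 1]`.
#' @export
ltd_on_post <- function(w, w_out) {
  stopifnot(w_out < 0)
  pmin(1, pmax(0, w + w * (1 - w) * w_out))
}

#' Presynaptic trace value at a given time
#'
#' Exact all-to-all trace: `A(t) = sum_j dA_pre * exp(-(t - t_j)/tau_pre)`
#' over all presynaptic spikes `t_j <= t`. Increments accumulate; nothing
#' resets.
#'
#' @param t Evaluation time in ms.
#' @param pre_times Presynaptic spike times (ms) of one afferent.
#' @param dA_pre Trace increment per spike.
#' @param tau_pre Trace decay constant in ms.
#' @return Trace value at `t`.
#' @export
trace_at <- function(t, pre_times, dA_pre = 0.1, tau_pre = 20) {
  pre_times <- pre_times[pre_times <= t]
  sum(dA_pre * exp(-(t - pre_times) / tau_pre))
}

#' Initial uniform synaptic weight
#'
#' All `N` afferents start connected with one common weight `w0`, chosen so
#' that the mean noise-period potential sits one noise standard deviation
#' above the baseline threshold: `w0 * tau * f * N = theta0 +
#' w0 * sqrt(tau * f * N / 2)` (uniform-weight scaling of the shot-noise
#' moments). This puts the neuron just above its firing threshold on
#' average, giving a moderate initial output rate from which STDP can
#' bootstrap.
#'
#' @param params A [theory_params()] object.
#' @param neuron A [neuron_config()] object (uses `tau` and `theta0`).
#' @return Scalar initial weight, clipped to `[0, 1]`.
#' @examples
#' p <- theory_params(1e4, 3.2, 3.2, 5)
#' initial_weights(p, neuron_config(tau = 8.9, theta0 = 190))  # ~0.70
#' @export
initial_weights <- function(params, neuron) {
  stopifnot(inherits(params, "theory_params"),
            inherits(neuron, "neuron_config"))
  mu <- neuron$tau / 1000 * params$f * params$N   # tau*f*N, unit weights
  den <- mu - sqrt(mu / 2)
  if (den <= 0)
    stop("invalid configuration: tau*f*N too small to place the threshold ",
         "below the noise mean (denominator <= 0)")
  min(1, max(0, neuron$theta0 / den))
}

#' Run the clock-based LIF simulation over one spike stream
#'
#' Forward-Euler integration with bin `dt_sim`: per bin the potential leaks
#' by `(1 - dt/tau)`, each input spike on afferent `i` adds `w[i]`, then the
#' threshold is tested. At an output spike: LTP with the decayed
#' presynaptic traces, then homeostatic LTD, then potential reset and
#' threshold jump by `theta_jump_factor * theta0`; the threshold leaks back
#' toward `theta0` with `tau_theta` from the next bin on. Presynaptic
#' traces decay exactly between events.
#'
#' The simulator is resumable: pass the `state` of a previous call to
#' continue a long run chunk by chunk without keeping the whole stream in
#' memory.
#'
#' @param stream A [spike_data()] object (times need not start at 0).
#' @param neuron A [neuron_config()].
#' @param plasticity A [plasticity_config()], or `NULL` for fixed weights.
#' @param weights Initial weight vector (length `N`) or scalar recycled.
#' @param t_start,t_end Simulated window in ms; default the stream's
#'   nominal `[0, duration)`.
#' @param state Optional state list from a previous call (fields `V`,
#'   `theta`, `A_pre`, `t_A`, `w`, `t`); overrides `weights`.
#' @param record_V Record the potential at every bin (memory: one double
#'   per bin).
#' @param snapshot_interval Interval in ms at which the weight convergence
#'   index is recorded (default 1000; `0` disables).
#' @return List with final `state`, `out_spikes` (ms), `w` (final weights),
#'   `snapshot_times`, `convergence_index` series, and optionally
#'   `V_trace`.
#' @export
simulate_lif <- function(stream, neuron, plasticity = NULL, weights = 1,
                         t_start = NULL, t_end = NULL, state = NULL,
                         record_V = FALSE, snapshot_interval = 1000) {
  stopifnot(inherits(stream, "spike_data"), inherits(neuron, "neuron_config"))
  N <- attr(stream, "n_afferents")
  if (is.null(t_start)) t_start <- 0
  if (is.null(t_end)) t_end <- attr(stream, "duration")
  if (is.null(state)) {
    w <- rep_len(weights, N)
    state <- list(V = 0, theta = if (neuron$thresholded) neuron$theta0 else Inf,
                  A_pre = numeric(N), t_A = rep(t_start, N), w = w,
                  t = t_start)
  }
  plastic <- !is.null(plasticity) && neuron$thresholded
  res <- lif_run_cpp(
    stream$afferent, stream$time, N, t_start, t_end,
    neuron$tau, neuron$dt_sim,
    neuron$thresholded,
    if (neuron$thresholded) neuron$theta0 else Inf,
    if (neuron$thresholded) neuron$theta_jump_factor * neuron$theta0 else 0,
    neuron$tau_theta,
    plastic,
    if (plastic) plasticity$dA_pre else 0,
    if (plastic) plasticity$tau_pre else 1,
    if (plastic) plasticity$w_out else 0,
    state$w, state$V, state$theta, state$A_pre, state$t_A,
    neuron$reset_on_spike, record_V, snapshot_interval)
  out <- list(
    state = list(V = res$V, theta = res$theta, A_pre = res$A_pre,
                 t_A = res$t_A, w = res$w, t = res$t),
    out_spikes = res$out_spikes, w = res$w,
    snapshot_times = res$snapshot_times,
    convergence_index = res$convergence_index)
  if (record_V) out$V_trace <- res$V_trace
  out
}
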