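# Shared fixtures: the standard parameter set of the detection problem and
# the published optimal-geometry table used across tests.

standard_params <- function(P = 5) theory_params(1e4, 3.2, 3.2, P, 100)

# printed optimal-geometry rows (dt and tau in ms) and performance values
published_optima <- data.frame(
  P = c(5, 10, 20, 40),
  dt_opt = c(11, 8.1, 5.7, 3.7),
  tau_opt = c(8.9, 6.8, 5.6, 5.1),
  M_opt = c(1600, 2300, 3100, 3800),
  snr_opt = c(31, 20, 12, 6.7))

# unit in the last printed digit of a value given to 2 significant figures
printed_ulp <- function(x) 10^(floor(log10(abs(x))) - 1)

# vectorised expected SNR used as an independent oracle for the optimizer
snr_surface <- function(tau, dt, params) {
  f_ms <- params$f / 1000
  M <- params$N * (1 - exp(-params$P * f_ms * dt))
  v_max(dt, params$T, tau) * sqrt(2 * tau / f_ms) *
    (f_ms * params$N - f_ms * M) / sqrt(M)
}
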