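// Clock-based leaky integrate-and-fire core with adaptive threshold and
// multiplicative all-to-all STDP with homeostatic depression.
//
// Forward Euler on the membrane potential and the threshold with bin
// dt_sim; presynaptic traces use exact exponential decay between events
// (the trace ODE is linear, so exactness is free). Input spikes are
// quantized to bins on arrival; several spikes of one afferent in one bin
// simply sum.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List lif_run_cpp(IntegerVector aff, NumericVector tms,
                 int n_aff, double t_start, double t_end,
                 double tau, double dt_sim,
                 bool thresholded, double theta0, double theta_jump,
                 double tau_theta,
                 bool plastic, double dA_pre, double tau_pre, double w_out,
                 NumericVector w_init, double V_init, double theta_init,
                 NumericVector A_init, NumericVector tA_init,
                 bool reset_on_spike,
                 bool record_V, double snapshot_interval) {
  const R_xlen_t n_ev = aff.size();
  if (tms.size() != n_ev) stop("afferent/time length mismatch");
  const long long n_bins = (long long) std::llround((t_end - t_start) / dt_sim);

  std::vector<double> w(w_init.begin(), w_init.end());
  std::vector<double> A(A_init.begin(), A_init.end());
  std::vector<double> tA(tA_init.begin(), tA_init.end());
  if ((int) w.size() != n_aff || (int) A.size() != n_aff ||
      (int) tA.size() != n_aff)
    stop("state vectors must have length n_aff");

  double V = V_init;
  double theta = theta_init;
  const double decay_V = 1.0 - dt_sim / tau;
  const double decay_th = 1.0 - dt_sim / tau_theta;

  std::vector<double> out_spikes;
  std::vector<double> snap_t, snap_ci;
  NumericVector Vtrace(record_V ? (R_xlen_t) n_bins : 0);

  double next_snap = (snapshot_interval > 0) ? t_start : R_PosInf;
  R_xlen_t k = 0;
  while (k < n_ev && tms[k] < t_start) ++k;  // ignore events before window

  for (long long b = 0; b < n_bins; ++b) {
    const double t_next = t_start + (b + 1) * dt_sim;

    // membrane and threshold leak
    V *= decay_V;
    if (thresholded) theta = theta0 + (theta - theta0) * decay_th;

    // input spikes falling in this bin
    while (k < n_ev && tms[k] < t_next) {
      const int i = aff[k] - 1;  // 1-based afferent ids
      V += w[i];
      if (plastic) {
        A[i] = A[i] * std::exp(-(tms[k] - tA[i]) / tau_pre) + dA_pre;
        tA[i] = tms[k];
      }
      ++k;
    }

    // threshold crossing: LTP with the decayed presynaptic traces, then
    // homeostatic LTD of every synapse, then reset and threshold jump
    if (thresholded && V >= theta) {
      out_spikes.push_back(t_next);
      if (plastic) {
        for (int i = 0; i < n_aff; ++i) {
          double Ai = A[i] * std::exp(-(t_next - tA[i]) / tau_pre);
          A[i] = Ai;
          tA[i] = t_next;
          double wi = w[i] + w[i] * (1.0 - w[i]) * Ai;       // LTP
          wi = wi + wi * (1.0 - wi) * w_out;                 // LTD
          w[i] = (wi < 0.0) ? 0.0 : (wi > 1.0 ? 1.0 : wi);
        }
      }
      if (reset_on_spike) V = 0.0;
      theta += theta_jump;
    }

    if (record_V) Vtrace[(R_xlen_t) b] = V;

    if (t_next >= next_snap) {
      double ci = 0.0;
      for (int i = 0; i < n_aff; ++i)
        ci += (w[i] < 0.5) ? w[i] : 1.0 - w[i];
      snap_t.push_back(t_next);
      snap_ci.push_back(ci / n_aff);
      next_snap += snapshot_interval;
    }
  }

  List out = List::create(
    _["V"] = V, _["theta"] = theta,
    _["w"] = NumericVector(w.begin(), w.end()),
    _["A_pre"] = NumericVector(A.begin(), A.end()),
    _["t_A"] = NumericVector(tA.begin(), tA.end()),
    _["t"] = t_start + n_bins * dt_sim,
    _["out_spikes"] = NumericVector(out_spikes.begin(), out_spikes.end()),
    _["snapshot_times"] = NumericVector(snap_t.begin(), snap_t.end()),
    _["convergence_index"] = NumericVector(snap_ci.begin(), snap_ci.end()));
  if (record_V) out["V_trace"] = Vtrace;
  return out;
}
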