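# spikesnr

Optimal coincidence detection of repeating spatiotemporal spike patterns
by a single leaky integrate-and-fire (LIF) neuron — analytic theory,
Poisson spike-train simulation, and unsupervised STDP learning.

## The problem

`N` afferent neurons fire as homogeneous Poisson processes at rate `f`.
Hidden in this activity, `P` spike patterns of duration `L` repeat: each
pattern is a *frozen* Poisson realization, replayed with every spike
shifted by an independent uniform jitter on `[-T, T]` at each
presentation. The patterns have exactly the background firing statistics,
so only their coincidence structure gives them away. A LIF neuron
connected (with unit weights) to the `M` afferents that fire during a
chosen subsection of duration `Δt ≤ L` of at least one pattern will peak
whenever a pattern is presented.

The package is aimed at computational neuroscientists studying
coincidence detection, localist vs. distributed neural codes, and
STDP-based unsupervised learning of spike patterns.

## The theory

The detector's quality is its signal-to-noise ratio

    SNR = (V_max − V̄_noise) / σ_noise,

with shot-noise moments `V̄_noise = τfM`, `σ_noise = √(τfM/2)`. The
expected SNR across Poisson pattern realizations has the closed form

    ⟨SNR⟩ = v_max · √(2τ/f) · (⟨r⟩ − f⟨M⟩) / √⟨M⟩,

where `⟨M⟩ = N(1 − e^{−PfΔt})`, `⟨r⟩ = fN`, and `v_max` is the reduced
peak of a jittered subsection,

    v_max = min(1, Δt/2T) − (τ/2T)·log(1 − e^{−max(Δt,2T)/τ} + e^{−|Δt−2T|/τ}).

`optimize_snr()` maximizes `⟨SNR⟩` over the free variables `(τ, Δt)`
under the Gaussian-regime constraint `τf⟨M⟩ ≥ 10`. The package also
simulates the full protocol — frozen patterns, jitter, Poisson gaps, a
clock-based LIF with adaptive threshold and multiplicative all-to-all
STDP with homeostatic depression — and shows that the learned detector
approaches the theoretical optimum (`run_learning()`, `evaluate()`,
`hyperparameter_search()`).

## Worked example

```r
library(spikesnr)
params <- theory_params(N = 1e4, f = 3.2, T = 3.2, P = 5, L = 100)
opt <- optimize_snr(params, enforce_dt_max = FALSE)
opt
#> Detection problem: N = 10000 afferents at f = 3.2 Hz, P = 5 pattern(s) of L = 100 ms, jitter T = 3.2 ms
#> Optimal geometry: tau = 8.861 ms, dt_window = 11.12 ms
#>   <M> = 1630 afferents, expected SNR = 31.34
#>   mean-input constraint tau*f*<M> >= 10: inactive
```

A neuron detecting five 100 ms patterns among 10,000 afferents does best
with a short membrane time constant (τ ≈ 8.9 ms) reading an 11 ms
subsection of each pattern: it deliberately ignores ~90% of every
pattern, trading integration for temporal resolution. About 1,600
afferents end up connected and the expected peak stands 31 noise
standard deviations above the noise mean — patterns are essentially
never missed and false alarms are essentially impossible. Sweeping the
pattern count shows the SNR decays only slowly:

```r
table1_analytic()
#>    P    dt_opt  tau_opt    M_opt   snr_opt
#> 1  5 11.122942 8.861151 1630.300 31.335533
#> 2 10  8.067699 6.832486 2275.333 19.779094
#> 3 20  5.680321 5.631749 3047.895 11.876323
#> 4 40  3.699477 5.101148 3772.020  6.717248
```

Even 40 independent patterns leave an SNR near 7 — a single neuron can
code for tens of patterns (distributed coding). The STDP simulator
reaches this optimum without supervision; see the vignette
(`vignettes/detector-theory.Rmd`) for the learning protocol, its
evaluation criteria, and the scaled instances the test suite runs.

A thin command-line wrapper is installed with the package
(`inst/scripts/spikesnr`):

```sh
Rscript inst/scripts/spikesnr optimize --N 10000 --f 3.2 --T 3.2 --P 5 --L 100 --out results.json
Rscript inst/scripts/spikesnr learn --config cfg.yaml --seed 1 --out run/
```

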