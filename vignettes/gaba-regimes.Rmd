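---
title: "Inhibitory, non-monotonic and excitatory regimes of GABAergic input"
author: "gabaregimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inhibitory, non-monotonic and excitatory regimes of GABAergic input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(gabaregimes)
```

GABA is usually thought of as inhibitory, but whether a GABAergic conductance
raises or lowers a neuron's firing rate depends on where the GABA reversal
potential $E_{GABA}$ sits relative to the cell's operating range. This
package implements, end to end, the analysis of that question in
conductance-based integrate-and-fire models: closed-form theory for the
deterministic neuron, first-passage-time theory under input noise, a more
biophysical EIF-Kir neuron as a robustness check, and a striatal
microcircuit model in which the same single-cell mechanism produces
non-monotonic and heterogeneous population effects.

## The deterministic LIF theory

The membrane potential of the conductance-based LIF neuron obeys

$$\tau \frac{dv}{dt} = -(v - E_L) - g_{GABA}(v - E_{GABA})
  - g_{Glu}(v - E_{Glu}),$$

with conductances normalized by the leak, a hard threshold $E_{thr}$, reset
to $E_{reset}$ and no refractory period. Collecting terms gives relaxation
towards an effective reversal $E_{eff}$ (the conductance-weighted mean of
the reversal potentials) with effective conductance
$g_{eff} = 1 + g_{GABA} + g_{Glu}$ and time constant
$\tau_{eff} = \tau/g_{eff}$:

```{r}
p <- lif_params()   # tau 20 ms, E_L -80, E_thr -60, E_reset -70, E_Glu 0 mV
effective_input(p, synaptic_drive(g_Glu = 0.4, g_GABA = 0.5, E_GABA = -62))
```

When $E_{eff} > E_{thr}$ the neuron fires periodically at the closed-form
rate implemented by `deterministic_rate()`. GABA acts through two competing
channels: it *increases* $g_{eff}$ (shorter $\tau_{eff}$, faster approach to
threshold — excitatory) and it *moves* $E_{eff}$ towards $E_{GABA}$
(inhibitory whenever $E_{GABA} < E_{eff}$). The derivative of the rate with
respect to $g_{GABA}$ (`rate_slope_ggaba()`) makes the competition explicit,
and its root at $g_{GABA} = 0$ defines the critical reversal potential
`critical_egaba()` separating the inhibitory from the non-monotonic regime.
Two analytic anchors pin the phase diagram for the default parameters:

```{r}
glu_firing_onset(p)          # minimal g_Glu for firing: 1/3
critical_egaba(p, 1e4) - p$E_thr   # large-drive limit: -5 mV
```

so non-monotonicity is confined to a 5 mV band below threshold,
$(E_{reset}+E_{thr})/2 < E_{GABA} < E_{thr}$. `classify_regime()` labels any
point of the $(E_{GABA}, g_{Glu})$ plane as `SILENT`, `GABA_ACTIVATED`,
`INHIBITORY`, `NON_MONOTONIC` or `EXCITATORY`, and `build_phase_diagram()`
maps a grid:

```{r}
pd <- build_phase_diagram(p, E_GABA = seq(-70, -55, 0.25),
                          g_Glu = seq(0, 1.5, 0.05))
plot(pd)
```

Boundary ties are measure-zero on any grid but need a deterministic rule:
$E_{GABA} = E_{thr}$ in the firing region is classified `EXCITATORY`, and an
initial slope within $10^{-9}$ Hz of zero `INHIBITORY`. The
`regime_summary()` maximization uses a 512-point log-spaced coarse grid
(above $10^{-3}$) followed by bounded refinement to $10^{-6}$ on the
conductance; the rate curve is smooth and unimodal in the regimes where the
maximum is meaningful, and the default search interval, twice the silencing
conductance (or 50 when that is infinite), keeps the maximum interior.

## Noise and the Ricciardi rate

With Gaussian white input noise of amplitude $\sigma$ (mV), the stationary
firing rate is the inverse of the mean first-passage time,

$$\nu = \left[\tau_{eff}\sqrt{\pi}\int_{x_{min}}^{x_{max}}
  e^{x^2}(1+\operatorname{erf} x)\,dx\right]^{-1},\qquad
  x_{min,max} = \frac{E_{reset,thr} - E_{eff}}{\sigma_{eff}},$$

with $\sigma_{eff} = \sigma/\sqrt{g_{eff}}$. Naive evaluation of the
integrand overflows around $|x| \approx 26$; `ricciardi_rate()` evaluates it
through the scaled complementary error function, integrates the deep tail
$x < -10$ with its asymptotic series, and handles strongly sub-threshold
points ($x_{max} > 26$) in log space, so the rate is finite and continuous
over the whole parameter range. The initial slope of the noisy rate has no
printed closed form, so boundaries under noise use a centered difference
with step $10^{-4}$ in $g_{GABA}$ and bisection over $[E_{reset}, E_{thr}]$
to 0.01 mV (`boundary_egaba()`); theory bounds the deterministic boundary
above $(E_{reset}+E_{thr})/2$ and noise only lowers it, so failure to
bracket is signalled rather than silently extrapolated.

Noise expands the non-monotonic region: in the high-noise limit the rate
grows like $\sigma\sqrt{g_{eff}}$ (`high_noise_rate()`), so a small GABA
conductance is excitatory for *any* sub-threshold reversal. The closed form
approaches the integral slowly — the two agree to 5% only once $\sigma$ is
of order several hundred mV for the default 10 mV threshold-reset gap — so
it is used as a limit statement, not a numerical approximation.

Two noise models are provided. `noise_constant(sigma)` is additive and
parameter-independent. `noise_conductance(a)` follows from the diffusion
approximation of independent Poisson presynaptic firing: the variance is
$\sigma^2(v) = \sum_s a_s g_s (v - E_s)^2$, frozen at $v = E_{eff}$ (the
standard substitution that makes the noise additive; $E_{eff}$ does not
depend on $\sigma$, so no fixed-point iteration is needed). Because this
noise vanishes with the conductances, it expands the non-monotonic region
most where the drive is strong — the constant-noise expansion, by contrast,
collapses from about 0.9 mV at $g_{Glu} = 0.4$ to 0.05 mV at $g_{Glu} = 1.5$
(for $\sigma = 3$ mV) while the conductance-noise expansion stays at several
mV across that range.

## Simulators as oracles, and the EIF-Kir neuron

`simulate_lif()` integrates the same equation by Euler-Maruyama (white-noise
increment $\sigma\sqrt{dt/\tau}$ per step; spike registered at the first
step with $v \ge E_{thr}$, no interpolation — this changes rates by well
under 1% at the default step). The deterministic closed form and the
Ricciardi integral are checked against these simulations in the test suite;
default steps are 0.05 ms for the LIF (0.01-0.02 ms where rates are compared
quantitatively) and 0.01 ms for the EIF-Kir model, whose exponential term is
stiff near spikes. At these steps, halving $dt$ moves simulated rates by
less than 1%.

The EIF-Kir neuron (`eif_kir_params()`, `simulate_eif_kir()`) adds an
exponential spike-generating current $\Delta_T e^{(v-V_T)/\Delta_T}$ and an
inward-rectifier potassium current $-g_K f(v) (v - E_K)$ with sigmoidal
activation $f$ that shuts off with depolarization, reproducing the nonlinear
V-I curve of a spiny projection neuron (`vi_curve()`, `fi_curve()`). There
is no hard threshold; a spike is recorded when the voltage crosses a cutoff
(default $-30$ mV), beyond which the exponential current diverges within a
fraction of a step, and the voltage resets to $E_{reset} = -70$ mV (the
LIF value; the model tables do not state a separate reset). The
non-monotonic GABA effect survives in this model for $E_{GABA}$ near $V_T$,
and increasing $\Delta_T$ shifts the non-monotonic band to higher
$E_{GABA}$.

## The striatal microcircuit

`striatal_network()` builds the population model: $N = 1000$ LIF neurons,
2% fast-spiking interneurons (FSI), 49% direct- and 49% indirect-pathway
spiny projection neurons (dSPN, iSPN), connected by GABAergic synapses with
Bernoulli connectivity and block-constant strengths (`striatal_P()`,
`striatal_G()`; FSIs project to dSPNs more densely and the SPN-to-FSI blocks
are empty). Every neuron receives an independent 1000 Hz Poisson
glutamatergic drive filtered by a 5.6 ms exponential kernel — the synthetic
stand-in for total cortical input — and every GABAergic spike triggers a
difference-of-exponentials conductance (20 ms decay, 1.5 ms rise) in its
targets, using the reversal potential of the *postsynaptic* cell: $-80$ mV
in FSIs, and 1 mV below threshold in SPNs by default (both SPN types share
one $E_{GABA}$, as nothing distinguishes them in this respect). Synaptic
events are realized as per-bin Poisson counts (statistically identical to
event lists at these rates and steps, and O(1) per neuron-step) and the PSC
kernel as a two-state exponential filter, which is the exact discrete
update; no transmission delays are modelled (none are specified, and
conduction within the ~0.01 mm³ volume is sub-step). Initial voltages are
drawn uniformly on $[E_L, E_{thr}]$ to avoid spurious synchrony, and the
first 100 ms are discarded from every analysis.

`calibrate_drive()` tunes the per-population drive amplitudes so the
populations fire at in-vivo-like rates (FSI 10 Hz, SPN 1 Hz), by sequential
per-population bisection with 10 s evaluation runs repeated over up to three
sweeps — the population transfer is monotone in its own amplitude and the
recurrent coupling at ~1 Hz is weak, so this converges quickly and, because
all evaluation runs share one connectivity realization and seed, it is
deterministic. `fsi_rate_sweep()` emulates bidirectional FSI manipulation by
re-calibrating only the FSI drive (drive scaling is the minimal model of
optogenetic gain modulation and preserves FSI spike statistics), holding the
SPN drive at baseline.

What the generator does *not* emulate: weight heterogeneity within a
connection block (weights are binary, zero or $G_{ij}$), correlated cortical
input, other interneuron classes, SPN lateral glutamate, short-term
plasticity, and chloride dynamics that would make $E_{GABA}$
activity-dependent. Passing tests therefore certify the mechanism under
these idealizations, not quantitative agreement with recorded striatal data.

## Population statistics and an ambiguity worth documenting

`vm_distribution_sd()` fits a Gaussian (sample mean/SD) to the pooled SPN
membrane potentials, sampled every 1 ms after the transient and excluding
samples within 1 ms of a spike on either side, so the reset and the
threshold approach do not contaminate the sub-threshold distribution. At the
calibrated baseline this width is about 1.1-1.2 mV and the distribution is
nearly Gaussian (|skewness| < 0.5).

The width of the *rate* distribution across SPNs needs more care. Two
sources contribute: quenched heterogeneity (each SPN's FSI and collateral
in-degree) and finite-window counting noise, roughly $\sqrt{\nu/T}$ for a
window of length $T$. With FSIs silenced there is no FSI in-degree left to
vary, and in this model the remaining quenched width is only ~0.1 Hz; a
width of order 1 Hz at ~1 Hz mean is only obtained when per-neuron rates
are estimated in short windows. `pooled_rate_distribution()` therefore
implements the measurement as per-neuron rates in a 1 s window (after the
100 ms transient) pooled over 100 independent network realizations — the
window length matches the membrane-potential traces the network figures
display, and the realization count matches the stated number of independent
realizations. A single long run (`rate_distribution_sd()` on one
simulation) isolates the quenched component instead; both knobs are
exposed. Under the pooled measurement the widths computed here are about
0.85 Hz (FSI 0 Hz) and 1.0 Hz (FSI 25 Hz): the ordering and the
similar-means property are robust, but the magnitudes — in particular the
growth at 25 Hz — remain smaller than the reference values, because at this
operating point the per-neuron rate sensitivity to the FSI conductance
spread (mean ≈ 2.8, SD ≈ 0.5 on dSPNs at 25 Hz) is only about
$-0.16$ Hz per unit conductance. The mechanism itself is unambiguous:
at a fixed 25 Hz condition the per-dSPN rate correlates with FSI in-degree
at $r \approx -0.68$, and `delta_rate_vs_indegree()` shows the same
negative correlation for the rate *change* between the silenced and
over-driven conditions, with lightly innervated SPNs excited and heavily
innervated ones inhibited.

```{r, eval = FALSE}
net <- striatal_network()
cal <- calibrate_drive(net, c(FSI = 10, dSPN = 1, iSPN = 1),
                       config = sim_config(duration = 10000, seed = 1))
sim <- simulate_network(net, cal$amplitudes,
                        sim_config(duration = 10100, seed = 2),
                        conn = cal$conn, record_vm = TRUE)
vm_distribution_sd(sim)
```

## Reproduction driver and problem sizes

`run_experiment()` runs the figure-level experiments from a YAML/JSON config
or an R list (`phase_deterministic`, `phase_constant_noise`,
`phase_conductance_noise`, `eif_kir_sweep`, `network_baseline`,
`network_fsi_sweep`), writes CSV tables plus a JSON manifest (package
version, seed, config hash), and reruns bit-identically from the same
config and seed. The deterministic phase diagram uses the full
0.1 mV × 0.01 grid; noisy diagrams default to coarser grids since every
point costs two quadratures. The test suite runs the network modules at
$N = 300$ with seconds-long windows, and the acceptance-level checks run
the full $N = 1000$ model with a 10 s calibration window, a 10 s
baseline run for the membrane-potential width, 1 s × 40-100 realization
pools for the rate widths, 10 s × 5 realizations per point for the FSI
sweep, and paired 100 s fixed-realization runs for the in-degree analysis —
sizes at which the calibration tolerance (5%) and the counting noise are
small compared with the effects under test.

## Known limitations

* The quantitative width of the SPN rate distribution, and with it the
  strength of the heterogeneity at high FSI rates, depends on the operating
  point in ways the printed model parameters do not fully pin down (see
  above); this package reports what the stated parameters produce.
* The Ricciardi evaluation is for white noise; synaptic filtering
  corrections to the transfer function are out of scope, so the analytic
  rate is compared with simulations driven by white noise, not by the
  filtered Poisson drive of the network.
* The iSPN pathway, being less densely innervated by FSIs, peaks near the
  upper end of the tested FSI range; whether it is strictly inhibited at
  25 Hz relative to baseline is at the edge of resolution at the simulated
  durations.
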