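---
title: "Modelling odorant transduction and spike encoding in fly olfactory sensory neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling odorant transduction and spike encoding in fly olfactory sensory neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`flyosn` simulates a *Drosophila* olfactory sensory neuron (OSN) as a
two-stage cascade: an odorant transduction process (OTP) that converts a
concentration waveform into a transduction current, and a biophysical
spike generator (BSG) that samples that current into spike trains.

### Odorant transduction

An odorant is abstracted as a triple: a binding rate $b$
($(\mathrm{ppm\,s})^{-1}$), a dissociation rate $d$ ($\mathrm{s}^{-1}$),
and a concentration waveform $u(t)$ (ppm). The *affinity* $b/d$
(ppm$^{-1}$) positions the dose–response curve; $d$ alone sets the speed
of the transient response.

The cascade has four stages:

1. **Peri-receptor filtering.** Odorant molecules reach the dendrite
   through the sensillar lymph; we model this as a causal second-order
   low-pass filter with unit DC gain,
   $\ddot y + 2\beta_1\alpha_1\dot y + \alpha_1^2 y = \alpha_1^2 w(t)$,
   with natural frequency $\alpha_1$ (45 s$^{-1}$) and damping $\beta_1$
   (0.8). The exact second-order form is a modelling choice (the
   transfer function is documented here precisely so it can be swapped);
   only its low-pass character matters for the results. Because the
   filter is linear, the concentration and its gradient are filtered in
   one pass of $w = u + \gamma\,du/dt$.
2. **Concentration profile.** $v = \max(0, h*u + \gamma\, h*\dot u)$:
   the rectified weighted sum of filtered concentration and filtered
   concentration gradient, with weight $\gamma = 0.2105$ s. The gradient
   term is what makes the neuron phasic–tonic; setting $\gamma = 0$
   (`gradient_ablation()`) removes all gradient encoding.
3. **Bound-receptor kinetics.** With two receptor states (free/bound),
   the bound fraction obeys
   $\dot x_1 = b\,v\,(1 - x_1) - d\,x_1$, so in steady state
   $x_1^* = \frac{(b/d)\,v}{(b/d)\,v + 1}$ — only the product of
   affinity and concentration matters at equilibrium. This is the
   linchpin of the estimation module.
4. **Co-receptor channel with calcium feedback.** The channel gating
   variable $x_2$ is driven by $x_1$ and suppressed by a calcium
   variable $x_3$ through a fractional-power product:
   $\dot x_2 = \alpha_2 x_1 (1 - x_2) - \beta_2 x_2 -
   \kappa\, x_2^{2/3} x_3^{2/3}$, $\dot x_3 = \alpha_3 x_2 - \beta_3 x_3$.
   The exponent 2/3 (exposed as `feedback_power`) is what lets the
   cascade emphasise the concentration gradient; `power_sweep()`
   evaluates the alternatives $1/6, \dots, 1$. The transduction current
   is a Hill function, $I = x_2^p/(x_2^p + c^p)\,I_{max}$, which
   normalises a wide input range into $[0, I_{max}]$, $I_{max} = 62.13$
   pA.

The default parameter values (see `otp_params()`) are the fitted
acetone/Or59b set and are shared across receptors; identity enters only
through $(b, d)$.

**Numerical choices.** The five states (two filter states, $x_1, x_2,
x_3$) are integrated jointly by fixed-step RK4 at $\Delta t = 10^{-4}$
s; the calcium feedback with $\kappa \approx 8.8\times 10^3$ is the
stiffest term and sets the step. Fractional powers act on the
non-negative clamp of the state, and each step is projected back onto
the invariant set ($x_1, x_2 \in [0,1]$, $x_3 \ge 0$), which the exact
dynamics preserve but a discrete step can overshoot; pre-projection
excursions beyond $10^{-4}$ trigger a warning suggesting a smaller step.
`otp_steady_state()` solves the equilibrium by bracketed root finding
and serves as an independent oracle for the integrator's long-time
limit (they agree to $10^{-4}$ relative over randomised draws).

A useful exact symmetry: for a fixed $d$, scaling $b \mapsto k b$ and
$u \mapsto u/k$ leaves the trajectory unchanged, because $b$ and $u$
enter only through $b\,v$. The package exploits this for caching in the
population simulator and asserts it to $10^{-10}$ in the tests.

### Spike generation

The BSG is a Connor–Stevens point neuron — chosen for its type I
excitability: a continuous frequency–current curve rising from zero,
reaching more than 300 spikes/s — with an additive Brownian current
term. The conductances and rate functions are the canonical
Connor–Stevens set (temperature factor 3.8); the supplementary source
for the original BSG calibration is not available, so two constants
couple the neuron to the cascade and were calibrated once, then frozen:

* `current_gain = 3.0` (µA/cm² per pA) maps transduction current onto
  membrane current density. With this gain the f–I curve is continuous
  from zero (rheobase ≈ 2.8 pA), passes 300 spikes/s near 23 pA, and
  covers the range of currents the cascade can produce (the Hill stage
  saturates steady currents near 18 pA; transients stay below ~35 pA).
  Far above that operating range (≈ 52 pA and beyond) the
  Connor–Stevens neuron enters depolarisation block, as the canonical
  model does at very high current densities; the f–I monotonicity
  checks therefore run over the operationally reachable range.
* `sigma = 1.3` (µA/cm²·√ms) sets the Brownian term; the spontaneous
  rate at rest is ~0 spikes/s, at the low end of what such neurons
  show.

Integration is Euler–Maruyama on the membrane potential and exponential
Euler on the five gating variables at $\Delta t = 10^{-5}$ s (the
gating steady states and decay factors are read from a 0.02 mV lookup
table). Spikes are upward crossings of 0 mV with a 2 ms lockout. A
group of neurons expressing the same receptor shares one transduction
trajectory (rates are common within a group) and differs only in noise
sample paths; per-neuron seeds derive from the master seed as
`seed + neuron_index`. For fitting problems the noiseless generator is
used with a 0.02 ms step — target and candidate share the step, so the
loss at the generating parameters is exactly zero.

## Stimulus families

`wave_step()`, `wave_ramp()` and `wave_parabola()` implement the
standard pulse families supported on $[0.5, 2.5]$ s; `wave_staircase()`
the piecewise-constant protocol (default treads 0–100 ppm in 20-ppm
steps of 2 s); `wave_triangles()` the symmetric-triangle set whose
documented cardinality is 110 — only the count is documented, so the
default grid (10 peaks of 10–100 ppm × 11 durations of 0.3–2.3 s) is a
package choice. `wave_white_noise()` stands in for an unpublished
recorded waveform: Gaussian samples at the Nyquist spacing of the
requested bandwidth, spline-interpolated, rescaled and clipped at zero;
its mean/sd/bandwidth defaults (50 ppm / 15 ppm / 30 Hz) are free
parameters chosen to be plausible for such recordings.

For the piecewise-polynomial families the gradient column carries the
analytic slope; jump discontinuities are represented as one-sample
rectangular pulses whose area equals the jump (the sampled
distributional derivative). A finite-difference mode is available for
any waveform; the two agree except at jumps, where finite differences
smear the pulse over two samples.

## Rate estimation by inverse mapping

Because $x_1^*$ depends only on affinity × concentration, the settled
spike rate of a constant stimulus traces one sigmoid in that product.
`steady_rate_map()` tabulates it by full cascade simulation (5-s
constant stimuli, settled window 4–5 s, 25 noisy neurons per point) and
`estimate_affinity()` inverts it by monotone interpolation: the full
characterisation sweep uses affinities $10^{-2}$–$10^1$ at 0.01 log
steps; the package default covers $10^{-4}$–$10^1$ at 12 points per
decade, which resolves the inverse well below the simulation noise
floor at a fraction of the cost (the vignette-scale problem sizes
throughout were chosen so a complete analysis runs in minutes on one
CPU core). The dissociation rate is then estimated from the *peak* rate
of a step response: `peak_rate_map()` simulates the step family over a
dissociation grid at the estimated affinity (faster dissociation tracks
the transient overshoot of the concentration profile more closely,
giving a higher peak) and inverts the same way. Rates outside a map's
range raise errors naming the bracketing values; flat segments of the
monotone envelope invert to their upper edge, so sub-threshold entries
floor at the largest affinity still consistent with silence.

`estimate_affinity_matrix()` applies the settled-rate inverse entrywise
to a receptors × odorants spike-count table (counts are read as settled
rates at the stated amplitude — nominally 100 ppm; the source tables'
unit annotation is ambiguous, so the amplitude is a parameter), with
one shared map; sub-threshold and saturated entries are flagged.

The two worked examples the estimator is checked against — (87
spikes/s settled, 197 peak at 20 ppm) and (43 settled, 101 peak at 173
ppm) — deserve a caveat: under the shared transduction parameters the
173-ppm example has the *larger* settled current but the *lower*
printed rate, so no single monotone spike generator can reproduce all
four printed estimates exactly; the estimator is therefore judged on
order-of-magnitude agreement and, more stringently, on round-trip
self-consistency (simulating with the estimated pair must reproduce the
input rates within 10%, which it does within ~1%).

## Fitting

`fit_problem()` bundles (stimulus, target histogram) pairs split into a
transient set (white-noise-like stimuli) and a steady set (pulse-like
stimuli), with loss $L = L_1 + \lambda L_2$, $\lambda = 40$; each $L_i$
is the mean squared error between simulated and target PSTHs.
`fit_de()` is rand/1/bin differential evolution on the log scale of the
free parameters ($F = 0.6$, $CR = 0.9$, reflection at bounds, elitist
replacement), with bounds defaulting to 0.1×–10× of the reference
values. The full-scale setting (population 5000, 10000 iterations) is
preserved as documented constants; desk-scale recovery (population 60,
≤300 iterations, early stop at 1% of target variance) recovers
$\alpha_2, \beta_2, \kappa$ from noiseless synthetic targets to a few
percent. Because binned spike counts quantise the loss surface, the
final convergence is plateau-to-plateau; the early-stopping tolerance
is the natural stopping point. Whether all parameters should be refit
for each exponent in the fractional-power sweep is ambiguous; both
modes exist (`refit` flag), with the fixed-parameter sweep as default.

## Encoding manifold

`manifold_samples()` pools (concentration, gradient, rate) triples over
a waveform set; `manifold_fit()` fits rate $= f(u, \dot u)$ by ridge
regression on a tensor-product polynomial basis (total degree 4 by
default) with the penalty chosen by generalised cross-validation; the
intercept is unpenalised so the infinite-penalty limit is the sample
mean. The named method is simply "ridge"; the basis is a package
choice, kept polynomial so the surface and its monotonicity properties
are easy to probe. On triangle-set responses the fitted surface shows
the expected signatures: at low concentration the rate rises steeply
with even small positive gradients, and at high concentration the
concentration axis dominates.

## Population level

`population_spec()`/`population_simulate()` replicate the cascade over
receptor groups (default 50 groups × 25 neurons = 1250 OSNs; affinity
grid $2\times10^{-4}$–$10^{-2}$ in steps of $2\times10^{-4}$; shared
dissociation $10^2$ s$^{-1}$), each group one shared transduction solve
plus independent noisy generators. `rate_matrix_movie()` does the same
for a receptors × odorants affinity table (shared dissociation 132
s$^{-1}$ — an assumption, since count tables cannot constrain $d$) and
emits a rate matrix every histogram shift (10 ms). Whether neurons in a
group share one transduction trajectory or integrate it independently
is immaterial in law (the trajectory is deterministic given the
stimulus); the package shares it and caches solves across equal
affinities.

## What the synthetic data do and do not show

`synth_count_matrix()` draws ground-truth affinities log-uniformly
inside the sigmoid's invertible range and forward-maps them through the
tabulated steady map (optionally Poisson-perturbed); recovery tests on
it validate the inversion machinery, not the biology of real count
tables (which mix measurement techniques, drift, and receptors whose
parameters deviate from the shared set). `synth_fit_targets()` builds
noiseless fitting targets from known parameters; recovery shows the
optimiser and loss plumbing work, not that real recordings are fit
equally well — fitting to actual electrophysiology requires the
original recordings, which are outside this package's scope. PSTH
estimates use 20 ms windows sliding by 10 ms; edge windows are
truncated with their true length in the denominator, and peak detection
skips the first 10 ms after stimulus onset to avoid the one-sample
gradient pulse of analytic-gradient steps.

## Known limitations

* The peri-receptor filter form and the spike-generator calibration
  constants stand in for unavailable supplementary material; both are
  isolated behind parameters so they can be replaced.
* Sensillum geometry, odorant mixtures, and pheromone receptors are out
  of scope.
* Estimates from count tables constrain affinity only; dissociation
  needs temporal information (a peak rate at minimum).
* The Connor–Stevens neuron blocks at current densities far above the
  cascade's operating range; driving the generator directly with large
  constant currents will show this.
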