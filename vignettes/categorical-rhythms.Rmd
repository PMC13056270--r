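---
title: "Generative models of categorical rhythm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative models of categorical rhythm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(rhythmogen)
```

## The question the package addresses

Across human musical cultures, and increasingly in the vocal and acoustic
displays of other species, interval durations are not arbitrary: they cluster
into discrete categories, often related by small-integer ratios (1:1, 2:1,
3:2, ...). This package implements two deliberately minimal generative models
of rhythmic event production and asks whether — and under which parameter
regimes — such categorical structure emerges from their dynamics alone:

* a **leaky integrate-and-fire (LIF) neuron** with alpha-shaped excitatory
  post-synaptic currents, a minimal biophysical oscillator driven by external
  spike trains, and
* a **cricket stridulation model**, a behavioural abstraction in which a
  chirping oscillator adjusts its period through a Type II phase response
  curve (PRC) and relaxes back to its natural period at a tunable rate.

Both are one-way forced oscillators; both are analysed with the same
pipeline: inter-onset intervals `i_k`, rhythm ratios
`r_k = i_k / (i_k + i_{k+1})`, kernel density estimates of the ratio
distribution, weighted on-integer fractions at seven small-integer ratio
categories, and a spacing-based estimate of the differential entropy of the
ratio distribution.

## The neuron model

The membrane potential obeys

```
C_m dV/dt = -(C_m / tau_m) (V - E_L) + I_e + I_syn(t),
```

with a spike emitted (and `V` reset to `V_reset`, clamped for `t_ref`) when
`V` reaches `V_th`. Each input event contributes an alpha-shaped current
`w e (t / tau_syn) exp(-t / tau_syn)` whose peak is exactly the connection
weight `w` (pA) at `t = tau_syn`. Without input the neuron is an isochronous
oscillator with the closed-form period

```
T = t_ref + tau_m * log((Vinf - V_reset) / (Vinf - V_th)),   Vinf = E_L + tau_m I_e / C_m,
```

which `intrinsic_period()` exposes and `current_for_rate()` inverts exactly.
Because excitatory input can only advance the next spike, the model is a
Type I oscillator; 1:1 entrainment to an equal-frequency input is therefore
one-sided, and the fully synchronised region sits at input-frequency ratios
of 0.5 *and above*, as the sweep heatmaps show.

**Parameter defaults** (all overridable): `C_m = 250` pF, `tau_m = 10` ms,
`E_L = -70` mV, `V_th = -55` mV, `V_reset = -70` mV, `t_ref = 2` ms,
`tau_syn = 2` ms, `dt = 0.1` ms — the conventional defaults of the standard
LIF-with-alpha-currents simulator family. The sweep default connection
weight is `w = 1000` pA: a single input spike then delivers roughly 8–10 mV
of depolarisation against the 15 mV threshold gap, strong enough to entrain
but not so strong that every input fires the cell from rest.

**Numerics.** The subthreshold system (membrane plus the two-variable
alpha-current state) is linear, so it is propagated *exactly* on a fixed
grid of step `dt` with a precomputed exponential propagator matrix; the only
discretisation effects are the snapping of input events to the nearest grid
point and the reporting of spikes at the grid point where the threshold is
crossed (no sub-step interpolation). Consequently free-run inter-spike
intervals match the closed-form period to within `2 dt`, and halving `dt`
leaves free-run intervals unchanged to within one step. Under forcing,
near-tangent threshold crossings can slip by a whole step when the grid is
refined, and such slips accumulate along a run; step-refinement accuracy
should therefore be judged per interval (or in median displacement), not on
absolute spike times late in a long simulation. A related double-precision
limit: for very slow target rates (below roughly 8 Hz with the default
constants) `Vinf` approaches `V_th` closer than the representable resolution
of the potential, so `current_for_rate()` refuses unrepresentably slow rates
rather than returning an inaccurate current.

## The cricket model

The cricket chirps with a current period `T_cur`, initially the natural
period `T0`. A stimulus at phase `phi = (s - c) / T_cur` of the cycle that
started at chirp time `c` reschedules the cycle to `T_cur (1 + PRC(phi))`;
if several stimuli fall within one cycle, only the most recent matters. At
each chirp the period carried into the next cycle relaxes toward `T0`:

```
T_cur <- T_sched + rho * (T0 - T_sched),
```

where `T_sched` is the (possibly perturbed) period of the cycle just
completed. Applying relaxation at *every* chirp — not only after unperturbed
cycles — is a deliberate design choice: it is the only reading under which a
relaxation rate of 1 restores the natural period on the very first interval
after a perturbation, and a rate of 0.2 moves the period exactly 20% closer
to `T0` at each chirp, which is precisely the semantics the model is meant
to have. The resulting deviation decays geometrically,
`|T_k - T0| = (1 - rho)^k |T_pert - T0|`, which the tests verify to
floating-point accuracy.

**The PRC.** The empirical curve this model abstracts is only available as a
published figure, so the package ships two parameterised Type II stand-ins
(both marked clearly as qualitative):

* `prc_piecewise(a, b, phi_star)` — a continuous tent-shaped curve through
  `(0, 0) -> (phi_star/2, a) -> (phi_star, 0) -> (1, -b)`: stimuli early in
  the cycle lengthen the period (delay lobe peaking at `a`), stimuli late in
  the cycle shorten it (advance lobe reaching `-b`), with the zero crossing
  exactly at the breakpoint `phi_star`;
* `prc_sine(a, b, phi_star)` — a smooth two-lobe alternative with the same
  amplitudes and breakpoint.

Defaults `a = b = 0.5`, `phi_star = 0.6`. Both satisfy `PRC(0) = 0`, so a
stimulus coinciding with a chirp (attributed to the new cycle) is a no-op
and in-phase isochronous forcing reproduces the free run exactly. Optional
Gaussian PRC noise (`noise_sd`) is truncated below at -0.95 so the
perturbed period stays positive. Two guards cover pathological geometry: a
stimulus whose perturbation would schedule the chirp *before* the stimulus
itself instead triggers the chirp immediately after it, and phases of
stimuli arriving beyond the nominal period of an already-delayed cycle are
clamped just below 1. Because perturbations multiply the *current* period,
repeated early stimuli at low `rho` can transiently push intervals slightly
beyond the single-perturbation band `T0 (1 + [-b, a])`; at `rho = 1` the
band is exact. `T0` defaults to 2000 ms — the order of magnitude of slow
insect chirping — but all sweep results are expressed in dimensionless
frequency ratios, so its value is immaterial there.

## The quantification pipeline

* **Rhythm ratios** `r_k = i_k / (i_k + i_{k+1})` lie in (0, 1); 0.5 is
  isochrony, 2/3 a 2:1 long–short pair. Ratios of a Poisson train are
  Uniform(0, 1) (the ratio of two i.i.d. exponentials), which makes the
  Poisson input the maximally random reference.
* **KDE**: Gaussian kernel with Scott's-rule bandwidth `sd(x) n^{-1/5}`,
  matching the common default of reference implementations.
* **On-integer fractions**: for each of the seven categories
  1:3, 1:2, 2:3, 1:1, 3:2, 2:1, 3:1 (inverse ratios kept separate), the
  ratio axis between adjacent targets is split at midpoints; each target's
  on-bin is the central half of its segment and the remainder is off-bin;
  counts are weighted by inverse width and the fraction is
  `W_on / (W_on + W_off)`. The exact published bin boundaries this follows
  are not printed anywhere we can verify, so the construction is isolated
  behind `build_bins()` and chosen so that the on-width equals the combined
  off-width per segment — hence a uniform ratio distribution scores exactly
  0.5 and a sequence concentrated on the category scores 1. Ratios are not
  folded around 0.5, and ratios falling outside every segment (roughly
  outside [0.21, 0.79]) count toward no category: a sequence clustered at,
  say, 0.07/0.93 yields an undefined (`NA`) fraction rather than a
  misleading one.
* **Differential entropy**: the boundary-corrected (Ebrahimi-style) spacing
  estimator with window `m = floor(sqrt(n))`. On (0, 1) the maximum is 0
  nats (uniform); a Uniform(0, c) sample scores `log c`; both calibrations
  are tested at n = 10,000 within ±0.05. Degenerate samples — an isochronous
  sequence has all ratios identical — return `-Inf`, which the heatmaps clip
  to the minimum finite value so fully locked cells share the lowest colour.
  With more than half of the window spacings exactly zero the estimate is
  short-circuited to `-Inf`; isolated zero spacings reach the same value
  through `log(0)`.

## The three experiments

All sweeps share one design: a 2-D grid, one top-level seed, and per-cell
seeds derived deterministically from the seed and the grid indices, so
results are reproducible cell by cell. Sequence length is fixed by interval
count (default 150 per cell, comfortably above the 100-interval floor the
analysis assumes) rather than by duration, so every cell has the same sample
size; an optional `discard` drops initial intervals as lock-in transient
(default 0, i.e. strict full-sequence analysis; the locking-focused tests
use 20). Poisson inputs are length-matched by event count, not duration — an
open choice, made once, so that every grid cell sees the same number of
stimulus draws.

* **Experiment 1 (random input)**: Poisson forcing across input-frequency
  ratios `f_in / (f_in + f_model)` from 1/6 to 5/6 (input:model 1:5 to 5:1)
  against firing rate (neuron, default 10–100 Hz) or relaxation rate
  (cricket). Both models *reduce* entropy relative to their input and bias
  the ratio distribution toward 0.5, the more strongly the slower the input.
* **Experiment 2 (isochronous input)**: the same axes with perfectly
  periodic forcing. The first stimulus is placed half an input period after
  time zero so forcing at ratio 0.5 is not phase-degenerate (the initial
  phase is an undocumented free choice; it is configurable). Entropy minima
  appear at frequency ratios 1/2, 1/3 and 1/4 (the 1:1, 1:2 and 1:3
  tongues); just above the 1:2 tongue the output alternates two interval
  durations and the ratio distribution splits into two clusters flanking
  0.5.
* **Experiment 3 (connection strength, neuron only)**: isochronous input at
  exactly the intrinsic frequency, sweeping weight 500–10,000 pA against
  synaptic rise time 2–8 ms. Clustering at isochrony grows with both
  parameters in rank correlation, with ridge-like exceptions where strong,
  slow synapses spread an input's effect over several cycles and produce
  non-1:1 categories — at the shortest rise times the output can even leave
  the small-integer band entirely (the `NA` fractions above).

Default grids are 21×21; the routine test suite and the bundled
reproduction script run reduced 11×11 / 17×11 grids with 150 intervals per
cell, which keeps a full three-experiment pass in the tens of seconds while
preserving every qualitative feature listed above. PRC noise is off by
default in sweeps (the noise level used for the published cricket landscapes
is unknown); a `noise_sd` flag is available.

## What the synthetic inputs do and do not emulate

The generators produce exactly the two stimulus classes the experiments
need — homogeneous Poisson trains (maximal rhythmic randomness: uniform
ratio distribution, entropy ≈ 0) and perfectly isochronous trains (minimal:
degenerate ratios, entropy `-Inf`). Real animal signals and neural spike
trains live between these extremes and carry serial correlations, drift and
measurement jitter that neither class contains; passing tests therefore
certify the models' behaviour under the idealised study conditions, not
performance on empirical recordings. The metrics module, however, accepts
any strictly increasing event-time sequence (`read_events()` reads a plain
CSV), so empirical sequences can be analysed with the identical pipeline.

## Known limitations

* The PRC is a qualitative stand-in for the published empirical curve; all
  cricket results are therefore qualitative, and the cricket's
  entropy landscape is expected to be smoother than the neuron's rather
  than to match any exact published layout.
* The neuron's published sweep parameters (exact weights, grid resolutions,
  axis ranges) are not recoverable from the main text; defaults are declared
  here and configurable, so figure-level pixel replication is out of scope.
* One neuron, one cricket, one-way forcing only; no inhibitory sweeps, no
  conductance synapses, no mutual coupling.
* Spike times are grid-quantised; analyses that need sub-`dt` timing should
  lower `dt` (the integrator is exact for any step).
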