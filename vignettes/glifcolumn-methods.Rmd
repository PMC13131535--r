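---
title: "Methods: building, simulating and training a GLIF3 cortical column"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building, simulating and training a GLIF3 cortical column}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the model it implements: the
construction rules, the point-neuron and synapse dynamics, the training
objective and optimizer, the numerical choices that were genuinely open, and
what the synthetic fixtures do and do not establish about real cortical data.

## The model

`glifcolumn` builds a cylindrical cortical-column network of generalized
leaky integrate-and-fire point neurons with two after-spike currents
(GLIF3), connects it with biologically parameterized rules, simulates it
with forward Euler at a 1 ms step, and fits its recurrent and background
synaptic weights to physiological target statistics by backpropagation
through time (BPTT) with a surrogate spike derivative.

### Network construction

Neurons of each cell type are placed uniformly in the column cross-section
(lateral plane `(x, z)`, depth `y`), with counts set by volumetric density,
depth drawn from the type's laminar range, a preferred (tuning) angle
uniform on [0, 360), and a target in-degree — the neuron's total dendritic
input synapse count — drawn from a type-specific log-normal.  The central
200 um cylinder is the *core* (the high-fidelity readout region); the shell
out to 400 um is the *periphery*, present to absorb boundary artifacts.

Recurrent connectivity composes three rules on top of a distance-dependent
Gaussian with class parameters `p_max` and `sigma`:

1. **Orientation-dependent displacement.** The presynaptic ensemble centroid
   is displaced by `dR = 50 um` along the postsynaptic preferred
   orientation — toward it for inhibitory sources, away for excitatory
   sources, the excitatory profile additionally elongated by the anisotropy
   ratio `kappa = 1.5`.  The displacement applies only within 1.5 core radii
   of the column centre; outside, the profile is a centred isotropic
   Gaussian.
2. **Like-to-like modulation** (excitatory-to-excitatory only): probability
   is multiplied by `(2 / (1 + beta)) (1 - (1 - beta) * dphi / 90)` with the
   orientation difference `dphi` folded to [0, 90] degrees.  The factor
   averages to exactly one over uniform differences, so `p_max` is
   preserved.  `beta` is a configuration parameter; the fixtures use 0.6.
3. **Target-size modulation**: probability scales with the neuron's
   in-degree relative to its type mean, so larger dendritic arbors collect
   proportionally more connections.

Each ordered pair is then sampled as an independent Bernoulli draw.  The
original sampling scheme is not uniquely determined by published
descriptions of this class of model (per-pair Bernoulli versus
fixed-in-degree sampling); per-pair Bernoulli was chosen and is documented
here.  Probability products exceeding 1 are clipped, with the clip count
recorded.  Autapses are forbidden.  Delays are class constants rounded to
the nearest integer millisecond, minimum 1.

**Weights by the log-normal quotient rule.**  Per-connection weights must be
individually weaker on neurons with more inputs so that the population PSP
distribution matches paired-recording data.  Weights are drawn from
`LogNormal(mu_W, sigma_W)` with `sigma_W = sqrt(sigma_PSP^2 - sigma_N^2)`
and `mu_W = mu_PSP + mu_N - log(n_mean)`, then scaled by
`n_mean / n_target`; log-normal closure under quotients makes the resulting
population distribution exactly `LogNormal(mu_PSP, sigma_PSP)`.  When
`sigma_PSP <= sigma_N` the spread collapses onto a floor of 0.01 in log
space (the floor value is a package choice; only "small positive" is
determined).  Desired PSP amplitudes in mV are converted to simulator
current units by dividing by the *unitary PSP* — the peak deflection a
single unit-weight spike produces in the target cell model through the
receptor family's kernel, measured by simulating the model in isolation.

**Thalamic (LGN) input.**  Per-connection synapse counts follow the
Yule-Simon distribution `P(k) = rho B(k, rho + 1)` (power-law tail, mean
`rho / (rho - 1)`), so the number of distinct connections for a synapse
budget `N_syn` is `N_syn (rho - 1) / rho`.  Source units are drawn with
receptive-field-proximity weighting of width `sigma_LGN / n_syn`
(`sigma_LGN = 5` deg), so high-count connections come from precisely
aligned sources; weight is proportional to synapse count; the delay is a
fixed 1.7 ms (2 steps).  Direction selectivity arises by convergence:
transient-type sources are drawn toward a point offset along the preferred
direction, sustained-type sources toward the opposite offset.

**Background input.**  100 virtual Poisson units at 250 Hz; every neuron
receives exactly 4 distinct units at 1 ms delay.  Background weights are
calibrated per cell model by a log-scale bisection so that the isolated
network (recurrent weights removed, spontaneous LGN drive on) matches each
model's spontaneous-rate target.

With the full 19-type composition (six excitatory types, PV/SST/VIP in four
layers, L1 interneurons) the kinetic aggregation of inhibitory types across
layers yields 11 effective classes including the generic external
excitatory class, hence 121 directed receptor families.

### Dynamics

Voltages are normalized by each neuron's threshold distance
`dV = V_th - E_L`: reset at 0, threshold at 1, all weights and currents
divided by the target's `dV`.  The membrane update is
`v[n+1] = alpha v[n] + (1 - alpha) R i[n] - S[n]` with
`alpha = exp(-dt / tau_m)`; the spike indicator `S[n]` uses the pre-update
voltage and requires the refractory counter to be zero; the *soft reset*
subtracts one threshold distance inside the same update.  After-spike
currents decay every step (`exp(-k dt)`) and increment at the spike step.
The refractory counter reloads to `tau_ref / dt` (rounded) on a spike;
during the window the membrane keeps integrating and only emission is
disabled — the alternative (clamping) is not what the dynamics specify, and
the choice is recorded here.

Synaptic currents are double-alpha kernels
`A [(t/tau_f) e^{1 - t/tau_f} + lambda (t/tau_s) e^{1 - t/tau_s}]`,
realized by an equivalent linear-state recursion (two states per alpha
component) that avoids storing spike histories; the recursion is tested
against explicit convolution at relative 1e-9.  Delays are handled by a
per-source delay-lane buffer; event accumulation over the compressed
per-source synapse table is contracted to equal the dense delayed
matrix-vector product.  A shared *alpha basis* (global time constants, fit
jointly by an outer Nelder-Mead search over log-taus with inner linear
least squares, multi-start on log-spaced ladders) can replace the
receptor-wise kernels, shrinking PSC state memory from `4 x channels` to
`2 x n_basis` per neuron; per-family fit MSE and integrated-charge error
are recorded with the basis.  The basis time constants are data-dependent,
so the fixtures assert only the error criterion (MSE < 1e-3 over a 30 ms
horizon at 0.1 ms sampling on the synthetic kernel set), never specific tau
values.

### Training

The trainable parameters are the *positive magnitudes* of recurrent and
background weights; signs are fixed by presynaptic class (Dale's law) and
LGN weights are frozen.  The forward pass uses exact Heaviside spikes; the
backward pass substitutes the triangular surrogate
`gamma max(1 - |u|, 0)`, `gamma = 0.1`, where `u` is the normalized
distance to threshold.  The surrogate's support was taken as `|u| < 1`
(width 2); the one-sided reading is switchable.  The reverse pass is a
hand-written adjoint of every forward assignment, validated two ways:
against an independently coded dense reference recursion in the spiking
regime (relative 1e-9) and against central finite differences in a
hyperpolarized regime where no voltage enters the surrogate support, so
the dynamics are genuinely smooth in the weights (relative 1e-5).

**Exponentiated Adam.**  Adam first/second moments with bias correction,
applied multiplicatively: `a <- a exp(-eta m_hat / (sqrt(v_hat) + eps))`
with `eta = 5e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-11`.  Positivity —
and therefore every synaptic sign — is preserved by construction; a
`1e-12` magnitude floor prevents exponent underflow from locking a synapse
at exactly zero (the floor is a package choice).  Under a constant
gradient the update factor is exactly `e^{-eta}` per step, which the tests
assert as a closed form.

**Objective.**  `L_total = L_core + 0.1 L_peri + L_volt + L_w`, where the
core block carries spontaneous/evoked rate-distribution terms, evoked
crowd OSI/DSI, and spontaneous/evoked synchrony; the peripheral block
carries rate and OSI/DSI only.  Components:

- *Rate distributions* are matched rank-to-rank per cell type against a
  fixed target vector drawn once by inverse-CDF (linear quantile
  interpolation at midpoint probabilities) from the empirical samples, with
  an explicit 0 Hz sample appended to preserve the silent fraction, under a
  quantile-Huber penalty (`kappa = 0.002`, quantile `q/N_c`), coefficient
  `lambda_rate = 1e4`.  Rates enter in the simulator's native unit, spikes
  per millisecond — the scale on which `kappa` and `lambda_rate` are
  commensurate with the other terms.
- *Crowd-surrogate OSI/DSI*: within each type, preferred directions tile
  the circle uniformly by construction, so averaging normalized single-trial
  responses weighted by `cos(2 d)` / `cos(d)` over neurons approximates the
  average over stimulus directions of the type's mean aligned tuning
  curve.  Responses are normalized by an EMA of evoked rates
  (`beta = 0.95`, floor 0.5 Hz, initialized at the first observed trial and
  treated as a running statistic, not differentiated), and the denominator
  is the floored population mean.  The floor is applied to the normalized
  mean exactly as the definition is written, although the unit of that
  comparison is ambiguous in the source formulation; the choice is recorded
  here.  Matching is a population-weighted MSE, `lambda = 20`.
- *Synchrony*: multi-scale Fano factors of pooled excitatory core spike
  counts — 500 pools, sizes Gaussian(70, 30) clipped at 15, drawn by
  shuffle-and-slice so no neuron repeats within a pass; 20 log-spaced
  candidate widths on [1, 1000] ms with widths at or above half the 300 ms
  analysis window dropped (14 widths, up to ~113 ms); sample variance over
  non-overlapping bins; `lambda = 1.5`.  The pool RNG stream is independent
  of the network stream.
- *Voltage regularizer*: `mean((v - 1)^2)` exactly as printed,
  `lambda = 1`.  The printed form penalizes distance from threshold, which
  sits oddly with its stated purpose of discouraging excursions; a
  suprathreshold-hinge alternative is available behind a switch, but the
  printed form is the default and no guess about intent is baked in.
- *Weight regularizer*: Wasserstein-1 distance between current and initial
  recurrent weights per connection class (mean absolute difference of
  sorted weights), `lambda = 10`.

A training epoch starts from a 500 ms gray-screen warm-up of the zero
state; each update simulates one spontaneous and one evoked chunk (500 ms,
5 trials each; evoked gratings at 80% contrast, 0.04 cpd, 2 Hz, random
direction and phase per trial) and takes one optimizer step.  State carries
forward between updates within an epoch (the handoff between updates is not
fully pinned down by the published protocol; carry-forward was chosen).  A
mean-rate ceiling (default 100 Hz) aborts runaway runs with diagnostics.

### Stimulus generation and the surrogate LGN

Gratings are exact sinusoids in contrast units around gray 0, one pixel per
degree, one frame per millisecond, with optional gray padding.  The LGN
front end is a deliberately simple parametric surrogate for a full
spatiotemporal filter-bank model: difference-of-Gaussians spatial profiles
(sign-flipped for OFF subtypes), subtype-specific temporal kernels
(sustained: delayed low-pass; transient: biphasic, zero-DC), a rectifying
output nonlinearity around each unit's baseline, and Bernoulli spike
sampling with `p = 1 - exp(-r / 1000)` per 1 ms bin.  Gray input yields
exactly the baseline rates.  Its parameters are fixture choices tuned only
for order-of-magnitude plausibility (tens of Hz at a 2 Hz, 0.04 cpd, 80%
contrast grating); they are not derived from retinal or geniculate data and
must not be read as such.  Arbitrary luminance arrays are accepted, with a
documented contrast-multiplier option (doubling is the convention for
natural images).

### Analysis suite

Classical per-neuron OSI/DSI by vector summation; preferred direction from
the phase of the second circular moment, disambiguated by the sign of the
first moment's projection (the boundary case keeps the orientation branch),
with a 1 Hz peak-rate inclusion threshold; response sparsity
(selectivity); maximum participation ratio over 10/50/100 ms bins;
leave-one-out oracle correlation; distribution similarity as one minus the
two-sample Kolmogorov-Smirnov statistic; weight-versus-response-correlation
deltas with the signed-quotient convention that makes "positive =
like-to-like" hold for inhibitory weights too (within-layer restriction for
inhibitory pairs is the caller's responsibility; a relative 1e-6 floor on
the uncorrelated-bin mean marks the metric undefined — the floor is an
artifact decision); cosine-series fits of weight versus preferred-direction
difference with OLS t-tests (df = n - 3); per-type outgoing-weight tertile
cohorts restricted to core sources with deterministic id tie-breaks; and
silencing perturbations (-1000 pA constant injection for the stimulus
duration, matched seeds, targeted neurons excluded from all reported
metrics).  Monte Carlo matched resampling repeats a pairwise statistic on
experiment-sized subsamples to produce a p-value distribution under matched
power.

## Fixtures: what they emulate, and what passing does not show

The fixtures build 100-2000-neuron, four-type (L4 excitatory, PV, SST,
VIP), single-layer columns through exactly the construction path a
full-scale build would use, with every statistical ingredient active:
log-normal PSPs and in-degrees, like-to-like and target-size modulation,
Yule-Simon synapse counts, calibrated background.  Synthetic target sets
mimic curated in vivo references structurally: log-normal rate samples with
an appended 0 Hz entry, evoked above spontaneous, selectivity scalars in
[0, 1], supra-Poisson Fano curves with evoked above spontaneous at every
width.

What passing tests establish: the construction rules realize their stated
distributions; the simulator and its reverse pass are exact to their
oracles; the optimizer preserves signs and magnitudes; a perturbed network
is trainable back to reference rate statistics.  What they do not
establish: fidelity to any real cortical dataset — the fixture parameters
(densities, `p_max`/`sigma` tables, kinetic constants, LGN surrogate) are
plausible values, not fitted ones, and a four-type single-layer column
cannot exhibit the laminar and cell-type-specific phenomena a full
19-type model addresses.

## Numerical choices and problem sizes

- Forward Euler, `dt = 1` ms throughout; delays rounded to whole steps,
  minimum 1.
- The event/convolution equivalence is asserted at relative 1e-9 in double
  precision; the reverse-pass dual-implementation check at 1e-9, the
  finite-difference check at 1e-5.
- Yule-Simon sampling is inverse-CDF on a cumulative table grown until the
  tail mass is below 1e-12.
- The single-neuron unitary-PSP calibration runs 200 ms and rejects if the
  unit-weight deflection reaches threshold.
- Background calibration: 12 bisection iterations on a 2 s probe, one
  scale per cell model, tolerance warnings past 100% relative error.
- The test and acceptance runs use 120-300-neuron columns, 500 ms chunks,
  and a 50-update recovery experiment; these sizes were chosen so the whole
  statistical battery (1e5-draw KS checks included) completes comfortably
  on one CPU while every assertion retains its power.  The trainability
  experiment uses a mildly over-excited copy (background weights x1.15,
  excitatory recurrent x1.08) of a calibrated reference column: the
  multiplicative optimizer moves magnitudes by at most `e^{-eta u}`, so a
  50-update budget bounds the size of perturbation that can be undone, and
  the reference's spontaneous rates (6-12 Hz) sit well above the 2 Hz
  quantile-Huber knee so a 20% rate mismatch is resolvable by the loss.
  Reference statistics are measured under the training protocol itself
  (gray warm-up, carried state) — measuring from a cold zero state deflates
  rates by the onset transient and would bias the comparison.

## Known limitations

- The LGN surrogate is parametric and not data-derived; spatiotemporal
  tuning fidelity (e.g. subtype latency structure) is schematic.
- Training differentiates the rate, selectivity, synchrony, voltage and
  weight-regularizer terms; the refractory counter and the discrete spike
  reload are treated as non-differentiable, as is standard for
  surrogate-gradient BPTT.
- Chunk-boundary truncation: spikes whose delayed arrivals fall beyond the
  chunk end contribute no gradient (their forward effect is preserved via
  the carried delay buffer).
- The per-pair Bernoulli wiring scheme, the log-space weight floor, the
  clip-at-1 probability rule, the surrogate support width, and the
  inter-update state handoff are documented package decisions where the
  source formulation is silent or ambiguous.
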