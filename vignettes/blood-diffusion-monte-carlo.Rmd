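---
title: "Monte-Carlo modelling of water diffusion in blood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte-Carlo modelling of water diffusion in blood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodwalk)
```

## The problem

In intravoxel incoherent motion (IVIM) modelling of perfusion, the signal
contribution of flowing blood depends on the self-diffusion coefficient of
blood water, `D_b`. Blood is not a simple fluid: roughly 40% of its volume
is red blood cells (RBCs), whose membranes restrict and exchange water with
plasma. The apparent diffusion coefficient (ADC) measured in blood
therefore depends on hematocrit (HCT), on the diffusion time `T` of the
encoding waveform, and on whether the waveform is monopolar (MP) or
flow-compensated (FC). `bloodwalk` implements a two-compartment Monte-Carlo
model of this system together with the measurement-side analysis chain
(noise-floor correction, SNR gating, ADC/T2 fitting, blood-count
calibration).

## Geometry

The RBC is modelled as an oblate cylinder of reference diameter 8.00 um
and height 1.75 um, scaled isotropically so that its volume equals the
mean corpuscular volume (MCV). It sits centered in a periodic cuboid unit
cell sized so that the RBC volume fraction equals the hematocrit. Since
only "cuboid" is prescribed by the model, the aspect ratio is a free
choice; we use the *equal-gap* construction, the same plasma gap `g` on
all three axes:

$$(d + g)^2 (h + g) = \mathrm{MCV} / \mathrm{HCT}.$$

This cubic has exactly one positive root (one sign change) whenever
HCT < pi/4, the packing limit of a cylinder in a square; higher
hematocrits raise an infeasible-geometry error. The equal gap makes "the
shortest dimension (distance between neighboring RBCs)" unambiguous: it
is `g` on every axis. At HCT 0.43 and MCV 87.7 fL the gap is 0.857 um,
so a step of 1% of the gap is 8.57 nm, and the scaled RBC has a
surface-to-volume ratio of 1.64 um^-1 -- both match the reference
operating point of the model.

```{r geometry}
cell <- build_unit_cell(hct = 0.43, mcv = 87.7)
cell
```

## Compartment parameters

Defaults are literature values at 37 C: plasma diffusivity
`D_p = 2.75 um^2/ms`, erythrocyte diffusivity `D_e = 1.00 um^2/ms`,
free-water concentrations `c_p = 0.95` and `c_e = 0.70`, and an
intracellular pre-exchange lifetime `tau_e = 12 ms`. The membrane
permeability follows as `kappa_e = (V/S)/tau_e`, and stationarity of the
concentrations fixes the plasma-side value `kappa_p = kappa_e c_e/c_p`.
The fraction of blood water inside RBCs,

$$f = \frac{c_e \cdot \mathrm{HCT}}{c_e \cdot \mathrm{HCT} + c_p (1 - \mathrm{HCT})},$$

weights the particle initialization, so the simulated signal is
water-concentration weighted (f = 0.357 at HCT 0.43).

```{r params}
params <- compartment_params(cell)
params
```

## Gradient profiles

Both encodings are described by the switch times of the *effective*
waveform (sign-flipped after the refocusing pulse), centered on `TE/2`:
MP has two intervals (`t_k = TE/2 + (k-1) T/2`), FC has four
(`t_k = TE/2 + (T/4)\,\mathrm{sgn}(k-2)\,\sqrt{2}^{|k-2|}`). The FC
interval pattern nulls both the zeroth and first gradient moment, which
removes all phase from constant-velocity motion. The b-value obeys
`b = a γ² g² T³` with `a = 1/12` (MP) and `a = sqrt(2)/8 - 1/6 ≈ 0.010110`
(FC); the FC coefficient as typeset in the source material is ambiguous
("2/8 - 1/6"), and we fixed the radical by an independent piecewise
quadrature of the waveform, which also confirms exact M0/M1 nulling.
Because `a_FC` is ~8x smaller, FC needs ~2.87x the gradient amplitude of
MP for the same `b` at equal `T`.

```{r waveform}
fc <- switch_times("FC", T_ms = 70, TE_ms = 120)
fc
b_coefficient(fc)
gradient_moments(fc)
```

## The random walk

Particles take fixed-length steps in uniformly random directions with a
shared clock: the plasma step is a fraction (default 1%) of the gap,
`dt = ds_p^2/(6 D_p)`, and the intracellular step is `sqrt(6 D_e dt)`.
Reflecting walls would make the membrane impermeable; instead, a step
whose segment crosses the membrane is *transmitted* with probability

$$P = 2\, d_s\, \kappa_i / D_i,$$

where `d_s` is the distance from the particle's pre-step position to the
membrane and `(kappa_i, D_i)` belong to the source compartment. The
factor matters: averaging the attempt rate over all launch positions
within one step of a flat wall shows that this rule realizes a wall
permeability of exactly `kappa_i` for the fixed-step scheme. (Evaluating
`P` with the full step length instead of the instantaneous distance --
a plausible alternative reading -- triples the exchange rate; it is
ruled out by the consistency requirement that intracellular residence
times average `tau_e`. The walker tests check this directly: measured
mean residence is ~11.7 ms against the 12 ms target, and long-run
intracellular occupancy stays at `f`.) A failed transmission reflects
specularly at the crossing point; a successful one continues into the
other compartment with the residual path rescaled to the destination
step length.

Positions are wrapped into the periodic cell while an unwrapped copy
feeds, for every requested profile in the same pass, the per-interval
trajectory center of mass

$$x_{cm,k} = \frac{1}{\Delta t_k}\int_{t_{k-1}}^{t_k} x(t)\,dt,$$

accumulated by the rectangle rule with interval boundaries snapped to
step edges (error O(dt)). Under piecewise-constant gradients these K
vectors are a sufficient statistic for the accrued phase.

All randomness inside the walker comes from a xoshiro256++ generator
seeded by the user: identical seed and configuration replay the walk
bit-identically, independent of R's RNG state.

## Phases and estimators

For amplitude `g` along direction `u`,

$$\varphi = \varphi'\sqrt{b} = \gamma g \sum_k \Delta t_k\, (-1)^k\, x_{cm,k}\cdot u ,$$

and the normalized phase `phi'` is independent of the `b` used to set
`g`. From the ensemble over particles and (shared, seeded-random)
directions:

* `ADC_b = -(1/b) ln |<exp(i phi' sqrt(b))>|` -- what a two-point
  measurement at `b` and 0 would report;
* `ADC_0 = <phi'^2>/2` -- the Gaussian-phase small-b limit;
* `K_app = <phi'^4>/<phi'^2>^2 - 3` -- apparent excess kurtosis.

The three are linked by the cumulant expansion
`ADC_b = ADC_0 - (b/6) ADC_0^2 K_app + O(b^2)`;
`kurtosis_expansion_check()` verifies the relation and estimates the
next-order term from the sixth moment. The complex signal is averaged
jointly over particles and directions (the alternative -- averaging
magnitudes per direction first -- differs only beyond the isotropic
statistics we report); bootstrap standard errors resample particles
only, because shared directions are a variance-reduction device, not
independent samples.

## What the simulation sweep shows

`adc_sweep()` runs the chain over HCT x T x profile at fixed TE. At the
desk scales used in the tests (2000-3000 particles, step 5% of the gap,
2000-4000 directions; a few minutes per hematocrit on one core) the
sweep reproduces the study-scale behavior: ADC_400 falls with
hematocrit over 1.33-1.58 um^2/ms, `K_app > 0` everywhere with MP
kurtosis exceeding FC, and FC ADC_0 at or above the T-independent MP
plateau. Differences between FC and MP ADC_0 at long `T` are of order
0.01-0.05 um^2/ms and resolve only within Monte-Carlo standard errors
at these particle counts; the full-fidelity configuration of the study
(300,000 particles, 1% step, ~10^7 steps per particle) sharpens them
but runs for hours and is deliberately not part of any test. The 5%
step at desk scale slightly softens restriction (coarser membrane
interaction), which is why range checks carry Monte-Carlo SE slack.

The model deliberately omits: the biconcave RBC shape (the cylinder
changes S/V and hence the permeability scale), RBC orientation
dispersion, susceptibility gradients and relaxation inside the walk,
sedimentation, and any scanner/EPI physics. Passing tests therefore
validate the two-compartment exchange model, not those effects.

## Measurement-side chain

The analysis half mirrors how phantom measurements are processed:

* `noise_correct()`: `S_c = sqrt(S_m^2 - 6 sigma^2)` for six-channel
  sum-of-squares magnitudes (`n_factor` configurable; zero-floored
  values are flagged, never errors);
* `exclude_low_snr()`: an ADC measurement is dropped when the corrected
  b = 400 s/mm^2 signal falls below `sqrt(60) sigma`, i.e. SNR
  `< sqrt(10) ~ 3.2`;
* `fit_adc()`: unweighted OLS of `ln S_c` on all three b-values
  (0, 50, 400 s/mm^2), directions averaged first, both b = 0 scans
  averaged; with three b-values the weighted and unweighted estimators
  differ negligibly at the SNRs of interest, so the simpler estimator
  is used. The 95% CI comes from the residual t distribution (1 df);
  fixture round-trips put its actual coverage near 94%.
* `fit_t2()`: log-linear fit of the unweighted signal across TE. At a
  channel-SNR of 30 at the shortest echo, the unweighted estimator
  recovers T2 = 45 ms within 10% in ~88% of repeats -- reported as
  measured; weighting would improve it but is not part of the chain.
* `correlate_and_regress()`: Pearson r with the exact t transform
  (df = n - 2) and the gate `|r| > r_crit`; regression coefficients are
  only reported when the gate passes. No multiplicity correction across
  the three covariates (raw p-values are reported by design).
* `predict_Db()`: the blood-count calibrations
  `ADC_MP = 1.307 + (0.42 - HCT) * 2.846`,
  `ADC_FC = 1.545 + (0.42 - HCT) * 2.169` (and HGB analogues), with the
  profile-specific constants 1.30/1.54 um^2/ms as covariate-free
  fallbacks.

```{r analysis}
predict_Db("FC", hct = 0.42)
noise_correct(10, 1)
```

## Synthetic signal fixtures

`generate_signals()` emulates the acquisition at channel level: each of
six accessible channels (the lower three at half gain, gains normalized
to unit sum of squares) receives the attenuated complex signal plus
complex Gaussian noise of per-channel variance `sigma^2`, combined by
sum of squares. This makes the noise floor exactly `6 sigma^2`, the
value the correction assumes, and noise is never added to magnitudes
directly. Ground truth travels with the table as an attribute. The
fixtures emulate ROI-mean tables, not images: EPI artifacts, motion and
sedimentation drift are out of scope, so recovery tests speak to the
estimator chain, not to acquisition robustness.

## Numerical choices

* Interval boundaries snap to the nearest step edge; the O(dt) bias is
  negligible at <= 5% step fractions.
* Membrane crossings are located by 30 bisection steps of the
  compartment-membership predicate, giving sub-nanometer brackets; the
  reflected/transmitted point continues from the matching side of the
  bracket. Up to 10 crossing interactions are allowed per step (corner
  cases), after which the residual path is dropped.
* `ADC_0` uses the second-moment estimator directly, never a multi-b
  fit; multi-b kurtosis fitting is out of scope.
* Degenerate inputs prefer flags over failures where a study would
  continue (floored signals, flat T2 decays); impossible configurations
  (HCT beyond the packing limit, TE < T) raise errors.
* The `hct = 0.9` corner of an all-hematocrit validation grid is
  unreachable under the equal-gap construction (limit pi/4); the
  geometry tests cover 0.1-0.7 plus the error path beyond the limit.

## Reproducibility

Every stochastic entry point takes a seed. The walker's stream is
internal (xoshiro256++ seeded by splitmix64), so results are identical
across platforms and unaffected by the caller's R RNG state; sweep
sub-seeds are derived deterministically from the base seed per
hematocrit. Long-run checkpointing is intentionally absent: desk-scale
runs complete in minutes and are cheaper to replay than to checkpoint.
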