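---
title: "Models and methods behind cuedecide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cuedecide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cuedecide)
```

cuedecide implements the full computational workflow of a pharmacological
spatial-attention study of perceptual decision-making: balanced cued
orientation-discrimination designs and adaptive staircases, drift diffusion
modeling (simulation, exact likelihood, hierarchical Bayesian regression),
signal-detection summaries, EEG decision markers (CPP, lateralized ERPs,
surface-Laplacian CSD, Morlet time-frequency power, alpha lateralization),
cluster-corrected permutation statistics, and physiological derivations.
A synthetic-data generator produces complete study-shaped datasets so that
every stage is testable without any recordings. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and the places where a genuine design decision had to be made.

## Task design and staircase

A session consists of `n_blocks x trials_per_block` trials (reference
protocol: 2 x 280 = 560). Cue side, stimulus side and stimulus orientation
are each balanced to exactly 50%, and the spatial cue is valid on exactly
80% of trials. `generate_session_design()` enforces balance *exactly* by
building the full factorial cell list per validity stratum and shuffling it
with the seed: the printed proportions then hold at any admissible trial
count, and requests that cannot be satisfied exactly (e.g. 7 trials at 80%
validity) raise an error instead of approximating. Validity is balanced per
session; because the shuffle is uniform, blocks are near-balanced but not
forced to exact within-block balance -- the protocol specifies balance at
the session level only.

The difficulty staircase (`run_staircase()`) is a weighted up-down rule:
stimulus opacity rises by `step` (0.01) after every error and falls by
`step / ratio` (0.01/3) after every correct response, clipped to [0, 1].
A reversal is a change in the response sequence from correct to error or
vice versa; the run stops at 50 reversals and the threshold is the mean
opacity over reversal trials. The equilibrium accuracy solves
`p * step/ratio = (1 - p) * step`, i.e. `p = ratio / (1 + ratio)` = 0.75
for the 3:1 weighting (`staircase_equilibrium()`).

Two properties matter for interpreting the converged value. First, the
equilibrium statement is asymptotic: reversals recorded while the staircase
is still descending from its starting opacity pull the mean reversal opacity
upward. The intake protocol addresses this with two blocks -- the first
(from high opacity) is familiarization, the second starts at the first
block's output -- reproduced by `two_phase = TRUE`. Second, even at
stationarity the converged accuracy sits a point or two above the nominal
75% for shallow psychometric slopes, because the stationary opacity
distribution has finite width and the psychometric function is convex below
threshold. With the two-block protocol and a logistic observer of slope 16
per opacity unit (a realistic dynamic range of roughly 0.2 opacity between
60% and 90% correct for this stimulus class), the simulated observer's
accuracy at the converged opacity is 75-78%, within the tolerance used in
the acceptance checks.

## Drift diffusion model

The decision model is a two-boundary diffusion with unit diffusion
coefficient: evidence accumulates at mean rate `v` (evidence/s) between
absorbing boundaries 0 and `a`, starting at `z = a/2`; the first passage
time plus the non-decision time `t0` is the RT, and under accuracy coding
the upper boundary is the correct response. Trial-to-trial drift
variability is Normal(`v`, `sv`). The starting point is fixed at `a/2`
because accuracy coding makes bias inexpressible there; response bias is
analyzed separately through the signal-detection criterion.

Three independent routes to the same distribution are implemented and
cross-checked in the tests:

* `simulate_ddm()` -- Euler-Maruyama integration (default `dt` = 1 ms) with
  a per-step Brownian-bridge crossing correction: after each step the
  probability that the path crossed a boundary *inside* the step,
  `exp(-2 (b - x)(b - x') / dt)`, is evaluated and a crossing sampled
  accordingly. This removes the leading-order discretization bias, so
  millisecond steps already match the exact density to within Kolmogorov-
  Smirnov distance well below 0.01. The simulator uses its own
  xoshiro256++ RNG stream seeded from the `seed` argument, so very large
  simulations are cheap and bit-reproducible without touching R's RNG.
* `wfpt_density()` -- the exact first-passage density, computed from the
  classical small-time and large-time series expansions with an automatic
  switch at a truncation-error bound of 1e-7.
* `choice_probability()` -- the closed-form absorption probability
  `(1 - exp(-2 v z)) / (1 - exp(-2 v a))`, the analytic oracle for both.

Drift variability is handled *in closed form* rather than by quadrature:
the drift enters the first-passage density only through the factor
`exp(-v a w - v^2 t / 2)`, whose integral against a Normal(v, sv) drift is
a Gaussian integral with an explicit solution. This is exact and removes an
11-point quadrature from the likelihood's inner loop.

### Hierarchical Bayesian regression

`fit_hierarchical_ddm()` fits RT distributions of correct and incorrect
trials jointly for all subjects. Per trial,

```
v_i  = v_s  + X_i' beta_v
a_i  = a_s  + X_i' beta_a
t0_i = t0_s + X_i' beta_t0
```

where `X_i` contains the coded regressors drug (-1 placebo, +1 active
drug), cue validity (weighted effect coding: -0.8 invalid, +0.2 valid, so
the column has zero mean under the 80/20 proportions and the coefficient
equals the valid-minus-invalid difference), and their product. Subject
parameters are exchangeable draws from group Normal distributions. Models
are fitted separately per active drug (placebo + one drug), mirroring the
pairwise design.

Priors are weakly informative and stated explicitly because the original
analysis delegated them to an external package without reporting them:
Normal(0, 2) on regression coefficients and group means, half-Normal(1) on
group SDs and on `sv`; boundary and non-decision parameters are constrained
to their supports through the likelihood (any trial with `a_i <= 0` or
`rt_i <= t0_i` has zero likelihood). Sampling is Metropolis-within-Gibbs:
joint random-walk blocks per subject, random-walk blocks per coefficient
triplet and for `sv` (proposal scales adapted toward 25-40% acceptance
during burn-in, then frozen), conjugate Gibbs updates for the group means,
and log-scale random-walk updates for the group SDs. Split-Rhat is attached
to every parameter; any Rhat above 1.1 flags the fit as non-converged (a
warning and `converged = FALSE`, never a silent return). Defaults are 2
chains of 1000 kept draws after 500 burn-in iterations; the acceptance
checks use 1 chain with 500 kept draws after 400, which is sufficient for
interval coverage of the group coefficients at 8 subjects x 2 sessions.

`posterior_probability()` returns the fraction of posterior draws on the
opposite side of zero from the posterior mean -- the one-sided tail-mass
convention for reporting these regression effects -- bounded below by one
over the number of draws; a two-sided doubling is available by flag.

Two known approximations are documented rather than modeled: trials slower
than the 1.4 s response deadline are excluded and the likelihood is *not*
renormalized for that truncation (the convention of the workflow being
reproduced); this biases `sv` and, slightly, `a` downward while leaving the
drift-rate regression coefficients essentially unbiased, which is what the
recovery checks assert. And `sv` is group-level only by default (a
subject-level variant was considered and rejected as weakly identified at
560 trials per session).

## Behavioral summaries

`sdt_metrics()` computes `d' = z(H) - z(FA)` and criterion
`c = -(z(H) + z(FA)) / 2`, with clockwise targets as the "signal" class by
convention (d' is invariant to the labeling; the criterion flips sign).
Extreme rates are corrected log-linearly (0.5 added to every cell count, 1
to every denominator) so the statistics stay finite at observed rates of 0
or 1; the correction is applied uniformly, not only to extreme cells, so
comparisons across cells remain monotone. `condition_summary()` applies the
trial filters (missed trials and RTs above 1.4 s excluded) and summarises
d', criterion and RT per drug x validity cell. `bin_by_alpha()`
median-splits trials on a per-trial lateralized alpha score within subject
and drug session (matching the per-session EEG normalization); odd counts
put the extra trial in the low bin.

## EEG operators

Epochs live in a light container (trials x channels x samples plus times,
channel positions and trial metadata). `epoch_and_baseline()` re-locks
(cue onset is 300 ms cue + 1000 ms interval = 1.3 s before the stimulus;
response locking re-cuts each trial around its recorded RT, dropping trials
whose window leaves the recording), crops, downsamples (4th-order
Butterworth anti-alias low-pass at 80% of the target Nyquist, then integer
decimation), and subtracts the per-trial per-channel mean over the baseline
window (reference windows: -80 to 0 ms before cue or stimulus onset).

The surface-Laplacian CSD uses spherical splines with rigidity `m = 4`,
regularization `lambda = 1e-5` and a Legendre series to order 50 -- the
transform is named in the reference workflow but not parameterized, so
these standard values are exposed as arguments. The transform is linear,
maps a uniform topography to zero, and is reference-free; the tests assert
all three to numerical precision plus the spatial-sharpening property on a
synthetic focal source. Channel geometry is an idealized spherical 10-10
layout constructed from row/column arc angles (mirror-symmetric by
construction); it is a layout model, not digitized positions, which is
sufficient for CSD properties and all hemisphere logic here.

Contra/ipsi labeling (`assign_contra_ipsi()`) follows the crossing of cue
side and stimulus side: a hemisphere represents the contralateral
hemifield, so the hemisphere opposite the cue carries the *cued* location
and the hemisphere opposite the stimulus carries the *target*. CPP metrics
are the response-locked ROI average (CPz/CP1/CP2) at t = 0 (the "peak") and
the OLS slope over -250 to 0 ms (the build-up rate). The literal-sample
definition of the peak is used; a local-maximum variant was considered and
not adopted because the amplitude at the response is the stated definition.

`morlet_tfr()` convolves with unit-energy complex Morlet wavelets whose
cycle count is `f / 2` -- equivalently a fixed temporal Gaussian SD of
`1/(4 pi)` s at every frequency -- over 2-40 Hz in 2 Hz steps by default;
power is the squared magnitude. `db_normalize()` applies
`10 log10(signal / baseline)` with the baseline power averaged over -250 to
-50 ms pre-cue, per channel and frequency; condition-level maps use the
trial-average baseline and single-trial analyses the trial-wise baseline.
`alpha_lateralization()` band-averages 8-12 Hz per occipital hemisphere ROI
(O1/PO3/PO7 vs O2/PO4/PO8), maps hemispheres to contra/ipsi relative to the
cue and returns contra, ipsi and their difference per trial and time point.

Artifact handling is deliberately simple: `reject_artifacts()` drops trials
exceeding a configurable peak-to-peak amplitude on any channel. Consensus
bad-channel detection and ICA ocular correction are published third-party
algorithms and are out of scope; this is a departure from the full
preprocessing chain and is stated as such.

## Statistics

`rm_anova()` implements balanced fully within-subject ANOVA for 1-3
factors by direct projection: for each effect, cell means are collapsed
onto the effect's factors, centered along each of them (yielding the pure
interaction component per subject), and `F` is the ratio of the effect mean
square to the subject-by-effect mean square. Partial eta squared is
`SS_effect / (SS_effect + SS_error)`, and for t-tests
`eta_p^2 = t^2 / (t^2 + df)` (`eta_p_from_t()`). No sphericity correction
is applied by default (uncorrected dfs are the reporting convention here);
Greenhouse-Geisser is available behind a flag. The engine is verified
against `stats::aov` across 1-3 factor designs, against the paired-t
identity `F = t^2`, and against a hand-computed sums-of-squares oracle.
It exists as its own vectorized implementation because the cluster tests
below need thousands of samplewise F maps per permutation run, which is not
feasible through `aov`.

Cluster-corrected permutation tests threshold the samplewise statistic at
the parametric critical value at `cluster_alpha` (default 0.05), form
contiguous clusters (run-lengths over time; 4-connectivity over a
time-frequency grid), and compare each observed cluster's summed statistic
with the permutation distribution of the *maximal* cluster mass. For the
repeated-measures ANOVA the null is generated by re-shuffling condition
labels within subjects (preserving subject exchangeability); for the
one-sample test by random per-subject sign flips, with positive and
negative clusters formed separately. Permutation p-values are bounded below
by one over the number of permutations; identical seeds give bit-identical
results. For 2-cell designs and for the one-sample test an `exhaustive`
switch enumerates the full permutation group (2^subjects), giving exact
p-values that the tests compare against brute-force enumeration oracles.
Because the cluster-forming threshold is a quantile of the statistic's own
null distribution, cluster p-values are invariant to monotone rescaling of
the data, which is also asserted.

`bf01_approx()` is an explicitly labeled BIC approximation,
`BF01 = exp((BIC_alt - BIC_null)/2)` from nested linear models with subject
as a fixed blocking factor. Default-prior Bayesian ANOVA Bayes factors
depend on prior settings that are not reproducible from the reported
information; exact agreement with them is declared out of reach and not
asserted anywhere.

## Physiology and pupillometry

Mean arterial pressure is `dia + (sys - dia)/3`. The 16 visual-analogue
items aggregate into alertness (9 items), contentedness (5) and calmness
(2) by the standard assignment of this instrument; the exact item-to-
category map is shipped as an editable argument because item order varies
between translations, and categories are means (not sums) so that all three
stay on the centimeter scale. Drug effects on these panels are analyzed as
percent change from the pre-drug baseline.

`pupil_preprocess()` interpolates blinks linearly (with a 50 ms pad),
band-passes 0.01-10 Hz by zero-phase forward-backward Butterworth filtering
(reflection padding suppresses the filter's edge transients; for traces
shorter than one period of the low edge the high-pass reduces to mean
removal), and removes blink/saccade-evoked transients by least-squares FIR
deconvolution: event-aligned boxcar regressors at 50 ms resolution over a
0-6 s post-event window, fitted by OLS and subtracted. The kernel window
and resolution are configurable; the defaults cover the canonical pupil
response duration. `pupil_darkbright()` averages the final 5 s of the 15 s
dark and bright presentation windows to give maximal and minimal diameter.

## Synthetic data generator

The generator's defaults are the study conditions: 28 subjects, three
sessions (placebo, atomoxetine, donepezil), 560 trials per session at 80%
validity; group diffusion parameters (v = 0.8 +- 0.25, a = 1.4 +- 0.15,
t0 = 0.30 +- 0.05 s, sv = 0.3) chosen so simulated accuracy sits near the
staircased 75% and RTs fit the 1.4 s response window; condition effects
equal to the reported posterior means under the same weighted effect coding
the fitter uses -- validity to v: +0.17, atomoxetine to v: +0.15, their
interaction: +0.04, a small atomoxetine slowing of t0 (+0.02 per unit
code), and null donepezil effects (the reported donepezil effects were not
statistically reliable). Placebo and atomoxetine sessions follow the
pairwise regression model exactly, so the fitted coefficients' generating
values are the numbers above; donepezil sessions equal placebo plus
optional donepezil deltas (zero by default).

Synthetic EEG epochs (64 channels, 512 Hz, -2 to 2 s around the stimulus)
contain: spectrally shaped 1/f background noise (exponent 1) plus white
sensor noise; occipital alpha oscillators (10 Hz) whose contralateral-to-
cue amplitude ramps down from 120 ms after cue onset and plateaus from 600
ms after the cue at the configured power lateralization (-1 dB) until the
stimulus -- the plateau makes "injected lateralization" a well-defined
quantity that the analysis pipeline must recover within +-0.2 dB; a
centro-parietal ramp per trial rising from `t0` to the trial's RT with
build-up rate proportional to the trial's generative drift, then decaying;
and lateral occipito-temporal Gaussian deflections in the reported latency
windows (cued-hemifield modulation 70-336 ms, stimulus identity 352-500 ms,
drug 406-586 ms post-stimulus). EEG amplitudes are in arbitrary
microvolt-scale units: the absolute scales are free parameters of the
generator, chosen once for detectability at the study's sample size and
documented in `generative_config()`; real recordings differ in spectral
detail, artifact structure, and inter-subject variability, so passing
end-to-end tests demonstrates internal consistency of the pipeline, not
performance on real data. Every generator accepts `null_effects = TRUE`,
zeroing all condition effects for type-I calibration of the downstream
tests.

The physiological panel adds an atomoxetine effect at post-baseline
timepoints on heart rate (+8 bpm), blood pressure (+7/+4 mmHg) and pupil
diameter (+0.5 mm on both the dark and bright window), with no donepezil
or subjective (VAS) effects, matching the reported pattern.

## Problem sizes used in the checks

The test-suite sizes are the package's own choices for routine runs: the
million-trial simulator-versus-density comparison runs once; hierarchical
recovery uses 10 replicates of 8 subjects x 2 sessions x 560 trials with
single-chain reduced-draw fits plus 10 null-configuration fits;
permutation calibration uses 200 null datasets of 10 subjects x 2
conditions x 40 samples at 400 permutations; the end-to-end EEG check uses
12 subjects x 80 trials of one session with the full 64-channel generator,
restricting the time-frequency transform to the occipital ROI channels.
Larger sizes reproduce the same results more slowly and can be set through
the configuration objects.

## Known limitations

* The likelihood ignores the RT-deadline truncation (see above).
* The Bayes factors are BIC approximations, not default-prior Bayes
  factors.
* The CSD uses an idealized spherical layout, not digitized positions.
* The artifact rejector is amplitude-based only.
* The generator's EEG is a signal-plus-noise model; it does not emulate
  volume conduction from realistic sources, eye movements, or non-
  stationary noise.
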