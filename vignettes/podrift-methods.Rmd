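---
title: "Methods: orientation-tuning drift analysis and the Hebbian-volatility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation-tuning drift analysis and the Hebbian-volatility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`podrift` does two related jobs. First, it turns trial-structured two-photon
calcium-imaging fluorescence into per-session estimates of each neuron's
preferred orientation (PO) and quantifies how those estimates drift across
days — including drift *toward* an over-represented ("experienced")
orientation, the statistical signature of experience-dependent
representational drift. Second, it simulates a two-layer feedforward network
in which the same drift phenomenology emerges from the interplay of Hebbian
plasticity and activity-independent synaptic volatility. A seeded synthetic
data generator stands in for the mouse data, so every stage is testable with
known ground truth.

All orientations are degrees on the 180°-periodic orientation circle,
represented in [-90, 90). Circular arithmetic (`wrap_orientation()`,
`orientation_distance()`) doubles angles where needed so that, for example,
+89° and -89° are 2° apart.

## 1. From fluorescence to preferred orientation

**ΔF/F.** `compute_dff()` subtracts scaled neuropil contamination and
normalizes by a baseline:
F_corr(t) = F(t) − 0.7·(F_np(t) − median(F_np)); ΔF/F = (F_corr − F_b)/F_b,
where F_b is the median of F_corr over the concatenated 1-s pre-stimulus
windows of the session. We take the baseline from the *corrected* trace;
with the generator's contamination fixed at the same 0.7 this makes the
noiseless round trip exact. The contamination coefficient is exposed but
should stay at 0.7 to match the correction assumed by the generator.

**Responsiveness.** For each of the 12 grating directions, a two-sample
Wilcoxon rank-sum test (normal approximation, tie-corrected — `wilcox.test`)
compares stimulus-window means against pre-stimulus means across the ~32
repetitions. A neuron is *responsive* if any direction is significant at
α/n_stim (Bonferroni, α = 0.05) **and** its stimulus median exceeds the
pre-stimulus median. The one-sided median condition implements "responses
above baseline"; suppressed responses never count.

**Vector-sum PO.** With responses R and direction angles θ over all
direction × repetition entries,
X = mean(R·cos 2θ), Y = mean(R·sin 2θ), PO = ½·atan2(Y, X).
The two-argument arctangent keeps the quadrant; a plain arctan of Y/X would
fold the orientation circle. A resultant indistinguishable from zero at
floating precision (relative to the response scale) is reported as `NA`:
perfectly symmetric responses carry no orientation signal.

**Bootstrap CI and the tuned criterion.** `estimate_po()` resamples the
repetition indices with replacement (jointly across directions, the default;
independent per-direction resampling is available) `n_boot = 1000` times.
The point estimate is the circular mean of the bootstrap POs. For the 95%
interval the bootstrap angles are doubled, centred on the doubled circular
mean, percentiled at 2.5/97.5 and halved back — this avoids branch-cut
artifacts for neurons tuned near ±90°. A neuron is *tuned* when the interval
width is ≤ 90° (equivalently, a half-width of 45°); `analyze_tuning()`
additionally requires responsiveness, so `tuned` implies `responsive`.

Two numerical points deserve emphasis:

* *Pure noise is rejected by the joint criterion, not by CI width alone.*
  At zero signal the sample resultant is Rayleigh-distributed, and the
  bootstrap spread around a lucky large resultant is often narrow; roughly
  half of pure-noise neurons would pass a CI-width-only gate. The rank-sum
  responsiveness gate bounds that false-positive rate near the Bonferroni
  level, which is why the classification is the conjunction.
* *Direction-grid aliasing.* Sampling a tuning curve at 12 directions
  (6 orientations) aliases high circular harmonics into the estimate. For
  tuning widths ≳ 20° the resulting PO bias is ≪ 0.1°; for narrow curves
  (~15°) it can approach 1°. This is a property of the estimator on any
  finite direction grid, not of the implementation; the "noiseless recovery"
  test therefore asserts sub-degree rather than machine-precision agreement.

## 2. Drift, convergence, and shuffle nulls

`make_drift_records()` builds one record per *concurrently tuned* neuron
(responsive and tuned on both sessions of a pair): the signed PO change, the
drift magnitude |ΔPO| ∈ [0°, 90°], and a significance flag requiring each
day's PO to fall outside the other day's 95% CI, both tested circularly.
Given an experienced orientation, it adds rPO (distance from the experienced
orientation, in [0°, 90°]) and the convergence Δ|rPO| = rPO_pre − rPO_post
(positive = toward).

`convergence_summary()` reports the median with a percentile bootstrap CI
(default 10,000 resamples of records). `shuffle_test()` provides the two
nulls that dissociate magnitude from direction:

* `magnitude`: permute drift magnitudes across neurons, keep each neuron's
  toward/away direction. If convergence is carried by direction, the median
  is unchanged.
* `direction`: keep each neuron's magnitude, assign toward/away at random
  with equal probability (a sign-randomization null; permuting the observed
  signs is available as `direction_permute`). If convergence is carried by
  direction, the shuffled median collapses to zero.

After either shuffle, rPO_post is re-derived as
clip(rPO_pre − dir·magnitude, 0°, 90°); the clip respects the geometry of
the rPO range.

**Population-similarity decay.** `psc_matrix()` computes pairwise signal
correlations (Pearson correlation of trial-averaged 12-point tuning curves);
`psc_similarity_decay()` vectorizes the strict upper triangle of each day's
matrix, correlates day pairs, and fits y = a + b·e^(−c·x) to similarity vs
interval with Levenberg–Marquardt least squares (`minpack.lm::nlsLM`),
initialized at (min y, max y − min y, 0.1) with c ≥ 0. The strict upper
triangle excludes self-correlations, which would inflate similarity
uniformly.

**Behavioral filters.** `behavioral_modulation()` implements
corr(per-trial response amplitude, covariate) × mean across-session change
of the covariate, for running speed and pupil diameter;
`filter_by_modulation()` drops the most-modulated fraction of records
(ties broken deterministically by neuron id) so drift statistics can be
re-checked on the least state-confounded half of the data. The per-trial
amplitude is the stimulus-window mean; alternatives (preferred-stimulus
trials only) would only sub-select trials upstream of the same code path.

## 3. The synthetic imaging generator

`generate_experiment()` emulates the chronic protocol: 12 drifting-grating
directions, 5-s stimulus, 6-s inter-stimulus interval, 32 repetitions per
session, sessions on arbitrary day indices. Tuned neurons respond with a
circular Gaussian in orientation (width log-normal across neurons) on top of
a baseline fluorescence; traces include additive Gaussian frame noise and a
shared neuropil signal mixed at the 0.7 contamination fraction. Running
speed (log-normal across trials) multiplies response gain through
`exp(behavior_gain · z)`, which modulates amplitude but never the PO —
mirroring the premise that tuning preference is state-independent while
responsiveness is not. Pupil diameter is generated correlated with running.

Ground-truth POs evolve per day as a pure random walk, a biased walk toward
a target orientation (mean step = bias_strength × signed circular distance),
or not at all. A single seeded RNG stream drives the whole experiment;
identical configurations are bit-identical. What the generator deliberately
does *not* model: calcium indicator kinetics (responses are box-car),
motion/registration artifacts, ROI segmentation errors, and non-Gaussian
noise. Passing tests therefore validate the estimator and statistics
pipeline, not robustness to those real-data nuisances.

The test suite's "moderate SNR" condition is a peak response of 0.6 ΔF/F
against 0.2 ΔF/F frame noise (ratio 3), typical of good GCaMP6s somata.

## 4. The plasticity network model

N = 500 presynaptic neurons with Gaussian orientation tuning (centers tiling
[-90°, 90°)) drive N postsynaptic neurons linearly: v = Wᵀu. Per stimulus
presentation every weight updates as

Δw_ij = ε · ρ(w_ij) · (k·H_ij + ξ),  H_ij = u_j·v_i,  ξ ~ N(0, σ²),
ρ(w) = tanh(10·w),

with ε = 1e-4, σ = 1, and k ∈ [0, 1] scaling the Hebbian component. A
simulated day is N_θ = 43,200 presentations (one per second for 12 waking
hours); once per day each postsynaptic neuron's incoming weights are
divisively normalized to sum 1 — homeostatic scaling four orders of
magnitude slower than the per-stimulus updates. Weights are clipped at zero
after each update (exposed as `clip_negative`): ρ is odd, so a negative
weight would have self-amplifying volatility, and synaptic strengths are
non-negative quantities. Baseline vision is uniform random orientations;
orientation deprivation is a constant experienced orientation θ̂; the
interrupted variant inserts a block of uniformly drawn, plasticity-active
stimuli every 7 days. POs are measured with frozen weights by sweeping a
test grid (step 180°/N = 0.36°) and taking the argmax rate per neuron, ties
to the smaller angle. Every run starts with a 3-day baseline warm-up.

### Calibration

The learning-rule constants (ε, σ, the ρ gain, N_θ) are fixed. Four
quantities are not printed anywhere and had to be set; we anchored them, in
this order, to the two facts the model is explicitly built to reproduce —
the experimental baseline drift rate (~0.3°/day over 19–20-day intervals)
and comparable drift under baseline and deprivation:

1. **Hebbian/volatility balance.** With incoming sums fixed at 1, the only
   free scale of the Hebbian term is the presynaptic rate amplitude (offset
   fixed at 1/10 of amplitude). Equating the raw per-update magnitudes
   (mean|k·H| = mean|ξ|) makes the *directional* Hebbian term outweigh the
   *diffusive* volatility by √N_θ ≈ 208 per day, and the positive feedback
   through v = Wᵀu (the weights a stimulus strengthens increase the
   response that drives further strengthening) then diverges
   super-exponentially within a simulated day — at any desk scale, since
   the per-day exponent ε·N_θ is scale-invariant. The meaningful parity is
   between per-day accumulated contributions: N_θ·mean(H) against
   σ·√(2N_θ/π), i.e. mean(H) = σ·√(2/(π·N_θ)).
   `calibrate_hebbian_noise_parity()` solves this in closed form (H is
   quadratic in the rates). On top of this horizon we apply a balance
   factor of 1/8 to the rate scale, determined once by simulation as the
   point where the per-day convergence under deprivation matches the
   per-day diffusive drift under baseline — the observable-level statement
   of "both components matter comparably", and the regime in which
   deprivation convergence is gradual over weeks rather than immediate.
   `balance = 1` and the literal per-step horizon remain available for
   comparison.
2. **Presynaptic tuning width** σ_u = 20°, a V1-typical tuning scale.
3. **Postsynaptic weight-profile widths**, log-normal with sdlog 0.3
   (drift magnitudes are approximately log-normal across neurons, and a
   neuron's drift rate grows with its width, so the width spread produces
   the drift-magnitude spread). The median width (meanlog = log(54°)) is
   the value at which the calibrated model's 20-day baseline drift matches
   the experimental ~0.3°/day. The implied measured tuning curves are
   broader than classical single-unit V1 widths; within this learning rule
   the noise-to-PO transfer at ε = 1e-4 and σ = 1 is otherwise too weak to
   reproduce the observed drift rate, and we kept the printed learning-rule
   constants over the unprinted geometry.
4. **Parity reference.** The calibration targets `parity_sd` (default: the
   construction-time volatility sd, i.e. 1) rather than the possibly
   desk-rescaled `noise_sd`, so scaled-down runs keep the full-scale
   Hebbian strength, and ablations with `noise_sd = 0` calibrate against
   the default volatility — "remove one component, keep the other as it
   was".

With this calibration the model reproduces, without further adjustment:
near-zero volatility-only (k = 0) convergence under deprivation alongside
the largest baseline drift of the three conditions; positive Hebbian-only
(σ = 0) convergence alongside near-zero baseline drift; a weak positive
rank correlation between a neuron's initial distance from θ̂ and its
28-day drift magnitude (volatility masks the Hebbian signature on
experimental timescales); slower convergence when deprivation is
interrupted weekly; and incomplete recovery after input statistics return
to baseline.

### Desk-scale runs

`rescale_for_desk(config, c)` divides the stimuli per day by c, multiplies
ε by c and divides σ by √c, preserving both the per-day accumulated Hebbian
drift (∝ ε·N_θ) and the per-day diffusion scale (∝ ε·σ·√N_θ). Acceptance
runs use c = 100 (432 stimuli/day), 10-seed ensembles, 20-day baseline and
28-day deprivation windows — a few minutes each on one CPU; the unit-test
property runs use n = 100 and c = 1440. The rescaling is exact for the
diffusion and mean-drift statistics; it coarsens only the within-day
ordering of updates.

### Numerical implementation

The per-stimulus update touches N² weights, ~10⁷ evaluations per simulated
day at full scale, so `run_protocol()`'s default engine is a compiled day
loop: volatility is drawn with a Ziggurat sampler over xoshiro256++
(seeded from the run seed and the day index, giving deterministic,
reproducible streams independent of R's RNG), and ρ is evaluated through a
dense linear interpolation table of tanh on [0, 20] (2¹⁷ bins, max abs
error ~2.2e-9, saturated beyond). The pure-R reference engine
(`plasticity_step()`) uses exact `tanh` and R's RNG; the two are asserted
equal to 1e-9 on deterministic runs, and the kernel's noise stream is
distribution-tested against the standard normal. Non-finite weights abort
the run rather than being silently repaired; conservation after each daily
normalization is tracked and asserted to 1e-12.

## 5. Pipeline and reproducibility

`validate_config()` type- and range-checks a YAML configuration (sections
`imaging`, `analysis`, `drift`, `model`, `protocol`), rejects unknown keys,
and aggregates all violations into one report. `run_pipeline()` executes the
stages in dependency order, writes CSV tables and JSON summaries plus a
single `manifest.json` (command, config hash, seed, package version,
timestamp), and is byte-deterministic given config and seed. Angles are
serialized in degrees in [-90, 90); tables are RFC 4180 CSV with '.'
decimals. Trial tensors are persisted as RDS between stages; all
cross-package outputs are plain text.

## 6. Known limitations

* The generator's box-car responses ignore indicator kinetics; temporal
  deconvolution is out of scope.
* The bootstrap CI is percentile-based; at very low repetition counts
  (< ~10) its coverage degrades as for any percentile bootstrap.
* The model is purely feedforward and linear; recurrence, spiking, and
  receptor-level biophysics are out of scope, as is the pixel level of the
  imaging data (segmentation, registration, neuropil estimation).
* The model's measured tuning widths are broader than classical V1
  single-unit estimates (see Calibration above).
* Whether interruption stimuli should be plastic is ambiguous in the
  protocol description (measurement sweeps are weight-frozen); we simulate
  interruption exposure with plasticity active — frozen interruptions would
  be indistinguishable from uninterrupted deprivation.
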