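---
title: "Incremental SVM decoding under nonstationary brain activation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental SVM decoding under nonstationary brain activation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model behind the synthetic cohort, the real-time decoding pipeline, the
statistics, the numerical choices, and — importantly — what the synthetic
experiments do and do not establish about real data.

## The scientific setting

Closed-loop motor-imagery neurofeedback classifies each incoming fMRI volume
as rest or task (imagined left/right hand gripping and opening, LGO/RGO) and
feeds the result back — here as a robot arm raised 11° per correct task
classification, reset at every block end. The classifier is a linear
soft-margin SVM trained on a no-feedback scan (run 0). The phenomenon the
package is built around is *nonstationarity*: activation is widespread while
the skill is being learned and becomes focal once it is acquired, so a
static run-0 classifier degrades over feedback runs 1–3, while retraining
after each run on that run's data alone ("incremental strategy") tracks the
change.

## The protocol object

A run is 9 rest blocks bracketing 8 task blocks (4 LGO + 4 RGO), every block
30 s at TR 2 s: 255 volumes, 135 rest / 60 LGO / 60 RGO. Within-run task
order is not a scientifically constrained quantity here; the default is
strict alternation starting with LGO, with a seeded shuffle available for
robustness experiments. Volumes are assigned to blocks by 0-based index over
half-open time intervals `[onset, onset + duration)`.

`label_shift_volumes` delays per-volume labels to acknowledge hemodynamic
lag. The *default is 0*: task-volume counts then match the literal protocol
bookkeeping, which is what TPV denominators are defined on. A shift of 3
volumes (6 s, the canonical HRF peak delay) is used by the weight-recovery
analyses below, where pattern fidelity rather than literal scoring is the
aim.

## The generative model

Each voxel time series is

$$y_v(t) = \mu + \sum_r A_r\, s_r(v)\, (\mathrm{box}_{c(r)} \otimes h)(t)
  + \beta t + \varepsilon_v(t)$$

with baseline $\mu = 100$ (so amplitudes read as percent signal change),
spherical binary supports $s_r$, the canonical double-gamma HRF $h$
(response gamma shape 6 / scale 1 s, undershoot shape 16 / scale 1 s,
weighted 1/6, unit peak), linear drift $\beta$, and AR(1) Gaussian noise
with stationary sd $\sigma$ and lag-1 correlation 0.3.

Defaults, chosen once as a plausible regime where detrending matters and
decoding is neither trivial nor hopeless:

* grid 24 × 24 × 12 voxels at 3 mm isotropic (desk-scale, not whole-brain);
* two contralateral "hand-area" relevant regions (radius 4, amplitude 2.0,
  one LGO- and one RGO-selective), one medial SMA-like region responding to
  both tasks (radius 3, amplitude 1.5), and four transient bilateral regions
  (radius 3, amplitude 1.5) representing early widespread activity;
* noise sd 2.0, i.e. contrast-to-noise ≈ 1 at relevant-region cores before
  smoothing; drift slope 0.02 · σ per volume (≈10 units over a run — large
  enough that undetrended decoding fails);
* learning rate 0.4: per feedback run, transient amplitudes decay by
  $(1-\lambda)^{\text{run}}$ and relevant radii contract by
  $(1-\lambda/2)^{\text{run}}$ (floored at 1 voxel, amplitude unchanged).
  Run 0 always uses the full widespread topography.

A cohort draws subject `s` with seed `base_seed + s`; subject-level
variability is a deterministic ±10% amplitude jitter and ±0.1 learning-rate
jitter from the subject seed. Every run is bit-reproducible from
`(seed, run_index)`.

What the generator does *not* emulate: head motion and realignment,
physiological noise, spatially correlated noise beyond what smoothing
induces, magnitude information about the real activation decline (the
source literature localizes the change but does not quantify amplitudes),
and anatomical realism. Passing tests therefore establish that the
*pipeline* behaves as designed under the stated statistical structure — not
that effect sizes match any real cohort.

## The real-time pipeline

Per volume: Gaussian smoothing (8 mm FWHM, σ = FWHM/(2√(2 ln 2)·voxel) ≈
1.132 voxels at 3 mm; separable convolution with half-sample reflection
boundaries, which conserves total mass) → masking (all grid voxels by
default, standing in for a whole-brain mask) → streaming linear detrending →
decision value of the cue-matched model → causal drift correction of the
decision trace → thresholding at 0 → feedback. Smoothing uses only the
current volume, so the implementation smooths a run in one pass; detrending
and output correction are strictly causal.

**Streaming detrending.** Per voxel the state is the running sums
$(n, \Sigma t, \Sigma t^2, \Sigma y, \Sigma ty)$; the emitted residual at
step $n \ge 3$ is the step-$n$ residual of the OLS line through all $n$
samples (for $n \le 2$ a line fits exactly, so 0 is emitted). This is
algebraically identical to refitting from scratch — tested to 1e-8 relative
over 1000 random series — with constant memory.

An intrinsic consequence, worth stating because it shapes every TPV number
in the package: early in a run the cumulative line absorbs the first task
block's step response into its slope, attenuating (eventually inverting)
the residual signal of late first-block volumes. Even noise-free data
cannot be decoded perfectly in the first task–rest cycle; after one full
cycle the fit stabilizes and noise-free decoding is exact (this is the
property the tests assert). Combined with lag-free labels this puts
synthetic TPVs in the 40–60% range rather than the 70–80% of practiced
human participants; the strategy *contrast*, which is what the experiments
measure, is unaffected.

**Decision-trace drift correction.** The raw decision sequence is detrended
by the same cumulative fit, then the running mean is added back:
$\tilde d_n = d_n - (\hat a_n + \hat b_n n) + \bar d_n$, which removes only
the tilt around the running mean while preserving level (class separation
lives in the level). The first two positions pass through unchanged. A
consequence of preserving level is that the *accumulated* level of a drift
survives; the correction protects the sign of decisions against the tilt,
which is what re-thresholding at 0 needs. Ties at exactly 0 go to the rest
class: conservative feedback, no undeserved reward motion.

**Model assignment.** The real-time loop is cue-driven: during an LGO block
the R-vs-LGO model drives feedback, during RGO blocks R-vs-RGO. All models
are evaluated on every volume for logging and offline metrics. LGO raises
the left arm and RGO the right; a `mirror_arms` flag swaps the mapping,
since either convention is defensible.

## Training and the two strategies

Three binary contrasts are trained per run: R vs LGO and R vs RGO (each on
that run's rest volumes plus the task condition's volumes) and LGO vs RGO
(task volumes only). Training features are smoothed, masked and
*batch*-detrended (the offline analogue the streaming fit converges to);
labels come from the known block schedule. The SVM is the linear C-SVM of
LIBSVM (via `e1071`), cost fixed at 1 — the standard, robust choice for
this problem class — without feature scaling (features are already residuals
on a common scale). The primal `(w, b)` is extracted and stored under a
fixed convention: positive decision value ⇒ task (or LGO, in the pairwise
contrast).

* **Incremental:** run `r` (1–3) is classified by the model trained on run
  `r − 1` only; after classification the models are retrained on run `r`
  alone. Four generations per contrast exist after a session.
* **Static:** the run-0 models classify all three feedback runs.

Run 1 is therefore identical under both strategies, a useful built-in
control that the tests assert bit-exactly. Detrend states reset at run
boundaries (separate scans). No future run can influence earlier outputs;
the test suite verifies this by perturbing run 3 and comparing runs 1–2.

## Evaluation statistics

* **TPV** = 100 · (correct task volumes)/(task volumes), rest excluded —
  rest blocks are not monitored during feedback. **Pairwise accuracy** is
  the same over LGO+RGO volumes.
* **Repeated-measures ANOVA** across feedback runs: `aov` with an
  `Error(subject/condition)` stratum, sphericity assumed (no correction),
  df = (k−1, (k−1)(n−1)) — (2, 58) at n = 30. When the condition
  sum-of-squares is numerically zero the routine reports F = 0, p = 1
  rather than the 0/0 indeterminate. Post-hoc paired t-tests are two-sided
  and uncorrected; a zero-variance difference vector is flagged degenerate
  instead of producing an infinite statistic.
* **GLM activation maps:** per-voxel OLS on [intercept, linear drift,
  LGO regressor, RGO regressor], t = c′β̂ / √(σ̂² c′(X′X)⁻¹c),
  df = volumes − rank(X). The first 5 volumes are discarded by default
  (the usual guard against initial signal instability). OLS is not
  prewhitened, so null calibration holds for white noise (tested) but t
  statistics are mildly inflated under AR(1) noise — a known limitation
  shared with any unwhitened GLM.
* **Group t-maps:** one-sample t of subject maps against 0, df = n−1;
  zero-variance voxels are flagged. Thresholding is voxelwise p < 0.001
  two-sided with an optional 6-connected cluster-extent filter — a
  deliberate, simpler stand-in for random-field-theory FWE correction,
  which is out of scope.

## The weight-recovery analysis

Where does the classifier look? Per subject, run-0 model weights are
scattered into image space and a group one-sample t-map is thresholded at
p < 0.001. This analysis uses `label_shift_volumes = 3` and a higher-SNR
cohort (noise sd 1, CNR ≈ 2): with lag-free labels the SVM's hard samples
are the transition volumes at block edges, where the label says "task" but
the lagged BOLD signal is absent — the solver then leans on noise
directions and single-subject maps are diffuse. The 3-volume shift aligns
labels with the response, and the group test cancels the remaining
subject-specific noise loading. At the default scale the thresholded group
map overlaps the generative truth with Dice ≈ 0.75–0.83. Single-subject
top-|w| concentration is only guaranteed in the separable lag-free limit,
which is how the unit test constructs it.

## Problem sizes and runtime choices

The package's experiments are sized for a desk: the cohort experiment runs
30 subjects × 4 runs on the 24 × 24 × 12 grid (both strategies fitted with
shared preprocessing, ≈ 5 min single-threaded); weight-map recovery uses
n = 10; unit tests exercise the same code paths on a 10 × 10 × 8 grid.
Smoothing is implemented as three per-axis banded matrix multiplications,
and per-run preprocessing and model generations are computed once and
shared across strategies.

## Known limitations

* The early-run detrend transient (above) depresses absolute TPVs; a
  burn-in or rest-referenced detrend would avoid it but would depart from
  the cumulative-OLS definition used here.
* Whether a real acquisition's incremental detrend used cumulative or
  windowed fits is unknowable from the outside; the cumulative fit is exact
  and testable, which is why it is the default.
* Effect sizes of the widespread-to-focal shift are free parameters of the
  generator; only directional claims (decline under the static strategy,
  advantage of retraining) are meaningful, and only those are asserted.
* Real-data ingestion (4D NIfTI + events TSV) is provided, but realignment,
  normalization and segmentation are out of scope and must happen upstream.
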