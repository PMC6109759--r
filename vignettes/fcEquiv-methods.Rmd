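---
title: "Testing whether task-evoked BOLD responses alter ICA-derived connectivity networks"
author: "fcEquiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing whether task-evoked BOLD responses alter ICA-derived connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcEquiv)
```

## The question and the procedure

Functional-connectivity (FC) networks — most prominently the default mode
network (DMN) — are extracted from BOLD fMRI by spatial independent component
analysis (ICA) as sets of voxels sharing a coherent spontaneous fluctuation.
During a task, the same regions can also show task-locked BOLD responses:
positive in sensory cortex, negative (deactivation) in the DMN. Does that
task-locked response *alter* the network that ICA extracts, or does the
network's fluctuation ride on top of it unchanged?

fcEquiv implements a residualization-and-permutation procedure to answer this
on a per-subject basis:

1. **First-level GLM.** Each voxel's time series is regressed on
   canonical-HRF-convolved task regressors (visual, audio, motor response,
   plus an explicit intercept). The *residualized* dataset is the OLS
   residual plus the voxel's temporal mean — the data with all task-locked
   variance removed.
2. **Spatial ICA, twice.** The preprocessed data and the residualized data
   are each decomposed by spatial ICA. In each decomposition the visual
   network and the DMN are identified by spatial correlation against
   reference maps, with the ICA sign ambiguity fixed toward the reference.
3. **Similarity.** For each network, the decompositions before and after
   residualization are compared by the temporal Pearson correlation (Pcc) of
   the matched time-courses, the spatial Pcc of the matched maps, and the
   Dice overlap of the maps thresholded at z = 3.
4. **Equivalency interval.** Any reprocessing perturbs ICA a little, so the
   observed similarity drop is compared against a null: each subject is
   residualized with a *donor* subject's task timing (a random derangement —
   no subject keeps its own timing), which removes only task-irrelevant
   variance. A paired one-sided t test per network and metric decides whether
   the observed drop exceeds this natural variability ("altered") or stays
   inside it ("within_equivalency").

The verdict of interest is the dissociation: the visual network's time-course
is altered by removing task variance, while the DMN's is not, despite a
robust negative BOLD response inside DMN territory.

## The synthetic cohort

No suitable public dataset accompanies this design, so the package ships a
seeded generator (`generateCohort()`, `synthesizeSubject()`) whose defaults
define the study conditions:

* geometry: 20 × 20 × 10 voxels of 3 × 3 × 5.5 mm, TR 1 s, 360 volumes — a
  desk-scale abstract volume, not an anatomical template; the inference
  procedure is geometry-agnostic;
* events: 55 visual and 55 audio events per run with random onsets (mean
  inter-onset spacing 6.2 s, range 4–18 s) and durations (mean 1.2 s, range
  0.5–3.5 s), plus a 0.5 s motor response at each visual offset. Spacings are
  truncated-exponential and durations truncated-log-normal, rescaled to hit
  the target means: only the mean and range of the jitter are established,
  and these shapes reproduce the skewed look of event-related designs while
  honoring both. Since the maximum duration (3.5 s) is below the minimum
  spacing (4 s), events never overlap;
* per voxel: `baseline + Σ_templates map(v)·[coupling·(HRF ⊛ boxcar)(t) +
  spontaneous(t)] + loading(v)·drift(t) + white noise`, with baseline 100,
  noise SD 0.5, and a cosine drift (period 128 s, amplitude 0.5, random
  phase) whose loading is a smooth positive random field around 1 — scanner
  drift varies smoothly across the field of view, and a spatially uniform
  drift would moreover be a zero-spatial-variance ICA source whose z-scored
  map is pure amplified leakage;
* spontaneous fluctuations: Gaussian noise low-pass filtered at 0.1 Hz (the
  band where FC fluctuations concentrate), variance-normalized, scaled by the
  template amplitude (default 1.0), and redrawn (up to 100 times) until
  |r| < 0.1 against every task regressor. Resampling rather than
  orthogonalization preserves the fluctuation's spectrum.

### Why the DMN deactivation is its own source

The default scene plants three sources: a **visual network** (coupling +1.0
*and* a spontaneous fluctuation on one map), a **DMN** (spontaneous
fluctuation only), and a **DMN deactivation** (coupling −0.6, no spontaneous
signal) on a map that overlaps the DMN but with a distinct spatial profile.

This structure is forced by linear algebra, not convenience. If the
deactivation and the DMN fluctuation shared one map, the noise-free data
matrix would have rank two (one spatial pattern per region), and spatial ICA
would *necessarily* return a DMN component whose time-course contains the
−0.6-scaled task response — its correlation with the task would be ≈ 0.3 for
these event statistics. That contradicts the empirical picture the pipeline
is designed to probe: ICA-extracted DMN time-courses are reported to be
essentially uncorrelated with task timing even where the region robustly
deactivates, which is attributed to DMN nodes having hemodynamic responses
distinct from the network's shared fluctuation, so that spatial ICA separates
the deactivation from the FC component. Modeling the deactivation as an
overlapping-but-distinct source is the minimal generative structure with that
property: ICA then recovers a task component (spanning the activated visual
cortex and the deactivated DMN territory with opposite signs), a visual FC
component whose time-course *is* task-locked (positive BOLD and fluctuation
share the visual map and are mathematically inseparable — matching the
visual-network phenomenology), and a task-free DMN FC component.

Consequently the pairwise support-overlap bound (Dice < 0.05) is enforced
between *spontaneous-carrying* templates only — those are the near-disjoint
sources spatial ICA assumes — while a task-only template may overlap an FC
template: that overlap is the phenomenon under study. The −0.6 gain itself is
a modeling choice (the relative amplitude of negative BOLD is not
established); it is exposed in `defaultScene()`. A per-template HRF override
(`hrf` argument of `networkTemplate()`) allows non-canonical deactivation
responses but defaults to the canonical shape.

### What the generator does not emulate

White, Gaussian, spatially independent measurement noise (no motion,
physiological cycles, or scanner artifacts); a common grid for all subjects
(no spatial normalization errors, which are a real concern for group ICA on
real data); identical coupling strengths across subjects; exactly canonical
hemodynamics. Passing tests therefore demonstrate the *logic* of the
inference — calibration under the null and sensitivity under the stated
effect sizes — not robustness to real-scanner artifacts.

## Preprocessing

Fixed order: high-pass filter → 3D Gaussian smoothing (FWHM 5 mm) → global
intensity normalization to median 10⁴ (each stage can be skipped). The
high-pass filter is a Gaussian-weighted running-line detrend with sigma
`1/(2·cutoff·TR)` volumes (50 volumes at the default 0.01 Hz), the FSL
convention, with the voxel's temporal mean re-added. Note this filter's
roll-off is gentle: a 200 s-period cosine keeps ≈ 71 % of its amplitude (the
Gaussian window spans a full period, so the local line captures little of
it). A DCT-basis regression filter (`method = "dct"`, ≈ 30 % residual at
200 s) is available where a sharper stopband matters. Smoothing kernels are
renormalized at volume borders, so constants are preserved exactly and
nothing leaks out of the volume. The intensity-normalization median is
computed over all voxels by default — synthetic volumes have no anatomical
background to exclude — with an optional mask argument.

## GLM choices

* The default HRF is the double-gamma "canonical" form (peak-1, peak ≈ 5 s,
  undershoot ratio 1/6); the single-gamma Boynton variant is available as
  `hrf = "boynton"`. Regressors are built on a 0.1 s grid and sampled at
  acquisition times.
* Ordinary least squares, no prewhitening: the synthetic noise is white by
  construction, and this keeps the residual-orthogonality contract exact. On
  real (autocorrelated) data the z statistics would be optimistic; this is a
  documented limitation, not a calibration bug — the permutation null, not
  the GLM z map, carries the headline inference.
* An explicit constant column is included; condition regressors are not
  demeaned. The temporal mean volume is added back exactly once during
  residualization.
* Group maps are voxelwise one-sample t tests across subject betas converted
  to z (the cross-subject mixed-effects machinery of full fMRI suites is out
  of scope; group maps are illustrative, the inference is subject-wise).
  Degenerate zero-variance voxels are capped at |z| = 40, as are all
  t-derived z statistics in the package.

## Spatial ICA

Voxel time series are demeaned, the time dimension is PCA-reduced to k
components, and FastICA (deflation with Gram–Schmidt decorrelation, logcosh
contrast, tolerance 10⁻⁴, at most 1000 iterations shared across retries per
component) unmixes the voxel dimension so rows of the map matrix are
maximally non-Gaussian spatial sources. Deflation is used rather than the
symmetric update because forced low-order decompositions whiten near-Gaussian
noise-floor directions, on which a joint symmetric update drifts
indefinitely; one-unit iterations converge component by component, and a
component that oscillates between nearby extrema of the empirical contrast is
restarted from a fresh seed with progressive damping. Five seeded restarts of
the whole unmixing are run and the solution with the highest total negentropy
kept; a run that never converges raises an error carrying the iteration count
(downstream, the null builder records such rounds as missing rather than
aborting). Maps are
z-scored (the z = 3 thresholding convention applies to these maps); the
z-scoring offsets are stored so `reconstruct()` reproduces the PCA-reduced
data to 10⁻⁴. Components are ordered by explained variance. Matching against
a reference map maximizes |spatial Pcc| (ties to the lower index) and fixes
the sign ambiguity by flipping map and time-course together.

**Model order.** `estimateModelOrder()` implements the Laplace approximation
to the Bayesian evidence of the PCA rank (clamped to [2, n_volumes − 5]).
Its isotropic-noise assumption holds on unprocessed data, where it recovers
planted ranks exactly; after smoothing (which correlates the voxel samples)
and temporal filtering (which colors the spectrum) it runs to the clamp
ceiling at this problem size. The pipeline therefore estimates the order on
the *raw* series and applies it to the preprocessed data. An alternative
`method = "mp"` fits a Marchenko–Pastur noise bulk with a free effective
sample count and counts eigenvalues above the bulk edge; on preprocessed
desk-scale data it returns ≈ 20. Tests pin `nComponents` where bitwise
determinism is asserted.

## Similarity and the equivalence test

Spatial Pcc is computed over all in-mask voxels on unthresholded maps; Dice
uses the positive tail (map ≥ z threshold, default 3) since matched
components are sign-fixed positive toward their reference. Dice with two
empty supports is recorded as missing with a reason rather than 0/0.

The null distribution uses seeded uniform random derangements of the task
timings (a fixed point would remove a subject's *true* task variance and
contaminate the null). The default is a single permutation round; more rounds
tighten the null, and per-subject null values are averaged across rounds
before pairing. The paired t test is one-sided (observed < null), because the
hypothesis is a similarity *reduction*; the two-sided p value is reported
alongside. The verdict is "altered" only when the one-sided p falls below
alpha (default 0.05) *and* the observed mean is below the null mean. No
multiple-testing correction is applied across the 2 networks × 3 metrics
grid; all six p values are reported side by side.

## Numerical conventions and degenerate inputs

* t → z conversion goes through the t CDF on the log scale (stable in the
  tails) and is capped at |z| = 40; perfect fits and zero-variance paired
  differences hit the cap instead of producing infinities.
* Zero-variance input to a Pearson correlation is an error, not an NA.
* ICA sign ties (zero correlation with the reference) break toward +1;
  matching ties break toward the lower component index.
* Schedules are redrawn (up to 100 times) when a draw does not fit the scan;
  infeasible designs error out before sampling.

## Problem sizes used by the tests and the acceptance script

The test suite exercises the full default geometry (20 × 20 × 10, 360
volumes) with cohorts of 8 subjects and 20 seeded replicates for the
headline-dissociation and type-I-control properties; unit tests use a
reduced 12 × 12 × 6 / 160-volume scene. `scripts/acceptance.R` recomputes the
headline rates over 10 replicates of 8-subject studies plus the calibration,
group-map, task-correlation and source-recovery quantities. These sizes are
the package's chosen desk-scale study conditions; the cohort size of the
original design (30 subjects) remains the `studyConfig()` default.

One practical note on interpreting the verdict table: a paired t test across
subjects detects arbitrarily small similarity drops if they are consistent —
a systematic map change of order 10⁻³ in Pcc can reach significance at n = 8.
The effect sizes (`meanObserved` vs `meanNull`) should always be read
alongside the verdicts.

## Known limitations

* OLS without autocorrelation modeling (see above).
* Subject-wise ICA is the default inference path; group (temporally
  concatenated) ICA is provided for completeness but returns only group-level
  similarity records — the paired test needs per-subject values.
* Spatial ICA cannot, by construction, separate two sources sharing one
  spatial map; the visual network's task response and fluctuation are
  reported as one component, which is exactly the behavior under study.
* The equivalence verdict is the operational paired-test criterion, not a
  formal TOST equivalence margin.
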