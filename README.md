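# fcEquiv

Does a task-evoked BOLD response alter the functional-connectivity (FC)
network that overlaps it? fcEquiv implements a subject-wise pipeline to
answer that question for ICA-derived networks: remove all task-locked
variance from the data by first-level GLM **residualization**, re-extract the
networks by **spatial ICA**, measure how much each network changed
(**temporal and spatial Pearson correlation, Dice overlap at z ≥ 3**), and
test the change against a **cross-subject task-timing permutation null** —
the *equivalency interval*, the natural variability produced by removing
task-*irrelevant* variance. It is aimed at fMRI methods researchers studying
the relationship between task-evoked activity (including the negative BOLD
response of the default mode network, DMN) and intrinsic connectivity.

## The model

Per voxel `v` and volume `t`, the synthetic cohort generator plants

    y(v,t) = baseline + Σ_T map_T(v) · [ c_T x_T(t) + s_T(t) ] + d(t) + ε(v,t)

where `x_T = HRF ⊛ boxcar` is the convolved task regressor (double-gamma
canonical HRF, peak 1), `c_T` a signed coupling (+1.0 visual activation,
−0.6 DMN deactivation), `s_T` a spontaneous fluctuation (Gaussian noise
low-passed at 0.1 Hz, SD 1.0, decorrelated from the task by construction),
`d` a slow cosine drift and `ε` white noise (SD 0.5). The first-level GLM is
voxelwise OLS on the three convolved regressors (visual, audio, motor) plus
intercept; residualization returns `residual + temporal mean`. Spatial ICA is
PCA reduction followed by FastICA (logcosh, symmetric decorrelation) on the
voxel dimension, with the model order chosen by the Laplace evidence of the
PCA rank. The equivalence test is a paired one-sided Student t on per-subject
(observed − null) similarity differences, where the null residualizes each
subject with a donor subject's task timing (a derangement).

See `vignettes/fcEquiv-methods.Rmd` for the full account of the model,
parameter defaults, and design choices.

## Worked example

```r
library(fcEquiv)

cfg <- studyConfig(nSubjects = 8, seed = 1)   # default synthetic scene
res <- runStudy(cfg)
res$equivalence[, c("network", "metric", "tStat", "dof", "pValue",
                    "meanObserved", "meanNull", "verdict")]
```

```
  network      metric   tStat dof   pValue meanObserved meanNull            verdict
1  visual temporalPcc -7.5526   7 6.57e-05        0.886    0.979            altered
2  visual  spatialPcc  0.0486   7 5.19e-01        1.000    1.000 within_equivalency
3  visual        dice  0.6897   7 7.44e-01        0.995    0.994 within_equivalency
4     dmn temporalPcc  1.7446   7 9.38e-01        0.993    0.978 within_equivalency
5     dmn  spatialPcc  0.4114   7 6.53e-01        0.999    0.999 within_equivalency
6     dmn        dice  0.3272   7 6.23e-01        0.994    0.993 within_equivalency
```

Reading the headline rows: removing the subject's own task variance drops the
visual network's time-course similarity to 0.886, far below the null's 0.979
(one-sided paired t = −7.6, p ≈ 7e−5): the visual network's temporal
characteristics are **altered** by the task. The DMN's time-course similarity
(0.993) stays at — here slightly above — the null level: **within the
equivalency interval**, even though the same data contain a robust −0.6-gain
deactivation inside DMN territory. That is the dissociation the pipeline is
built to detect; the spatial metrics of both networks stay within the
interval on this scene.

Per-subject records are in `res$observed` and `res$null@records`; with
`cfg@outputDir` set, all tables are written as TSV with a provenance header
(package version, config hash, master seed), and reruns with an identical
configuration reproduce them bitwise.

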