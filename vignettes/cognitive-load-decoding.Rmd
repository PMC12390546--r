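---
title: "Decoding working-memory load from fNIRS: models, simulation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding working-memory load from fNIRS: models, simulation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
generative model behind the synthetic sessions, the preprocessing and
selection steps, the classifier, the cross-validation protocol, and — most
importantly — the choices that were genuinely open and how they were
resolved.

## 1. The problem

An n-back session produces a multichannel concentration-change time series
(HbO2 and HbR per measurement site, in µM) together with a per-sample
condition label in {rest, 0-back, 1-back, 2-back}. The task is to classify
the load level of short windows cut from the task blocks. Two protocol
dimensions are under study: the segmentation mode (overlapping windows
multiply the training set but correlate neighbours; non-overlapping windows
are independent but fewer) and the Adam learning rate (0.1 / 0.01 / 0.001).

## 2. The synthetic session generator

`sim_config()` + `simulate_session()` produce labelled recordings with the
statistical structure the analysis assumes. A note on dimensionality: a
"204-channel" prefrontal montage is interpreted here as 102 measurement
sites x 2 chromophores (HbO2, HbR) — chromophores are what selection later
contrasts — and both the site count and everything below are configurable:

* **Design.** A leading rest period, then `blocks_per_condition` (default 4)
  blocks per load level of `block_seconds` (30 s) separated by
  `rest_seconds` (15 s) of rest, in per-subject shuffled order. Block and
  rest lengths are not properties of any public protocol; 30 s task blocks
  with 15 s inter-block rest are typical of block-design n-back fNIRS
  studies and leave room for the haemodynamic response to develop and
  partially recover.
* **Activation.** A fraction `informative_fraction` (default 0.3) of sites
  carries task activation. The informative-site set is drawn once from the
  root seed, so it is common to all subjects. For an informative site, the
  HbO2 channel is an amplitude boxcar convolved with the canonical
  double-gamma HRF (`double_gamma_hrf()`, positive lobe peaking at 6 s,
  undershoot at 16 s with ratio 1/6; sampled argmax falls in the
  physiological 5–8 s range). The kernel is area-normalized inside the
  simulator so block plateaus approach the configured amplitudes:
  0.2 / 0.5 / 1.0 µM for 0/1/2-back, a monotone load gradation with µM-scale
  values typical of prefrontal n-back responses. The paired HbR channel is
  the task component scaled by `-hbr_ratio` (default 0.4), reflecting the
  smaller, inverted deoxy response.
* **Noise.** Sinusoidal cardiac (0.25 µM at 1.1 Hz), respiratory (0.25 µM at
  0.25 Hz) and Mayer-wave (0.3 µM at 0.1 Hz) components with random phase
  per channel; a slow drift (0.4 µM; a random-period 60–180 s sinusoid plus
  a random linear ramp); and white noise (σ = 0.3 µM). These are standard
  physiological magnitudes, set once as the package's study conditions.
* **Subjects.** A multiplicative response gain `1 + N(0, 0.25)` (floored at
  0.2) per subject. Per-subject RNG streams are derived from the root seed
  with `derive_seed()`, so adding subjects never perturbs earlier ones.

What the generator deliberately does **not** emulate: motion artifacts,
optical forward physics (photon transport), spatial correlation between
neighbouring sites, non-stationary task engagement, and — critically — the
kind of high-dimensional, heavy-tailed structure that makes real
physiological data hard to optimize on. Consequences of that last point are
discussed in section 7.

`mbll_forward()` / `mbll_invert()` implement the modified Beer–Lambert law
linking concentration changes to optical-density changes at 780/850 nm
(default extinction coefficients in mM⁻¹cm⁻¹, DPF 6, source–detector
distance 1.5 cm); the 2×2 system is solved exactly, and a singular
extinction matrix is rejected.

## 3. Preprocessing

* **Standardization** (`fit_scaler()` / `apply_scaler()`): per-channel
  z-scoring with the population (divide-by-n) convention. Zero-variance
  channels are an error naming the channel; an epsilon guard is available
  and is what the experiment grid uses (`eps = 1e-12`), since a dead channel
  should not abort a whole grid cell.
* **Windowing** (`seconds_to_samples()`, `segment_windows()`): seconds
  convert to samples by rounding half away from zero — the only convention
  consistent with 20 s × 8.138 Hz = 162.76 → 163. Windows are cut from
  maximal single-condition runs only (pure labels; windows never straddle a
  block boundary and never contain rest). Non-overlapping windows tile each
  run; overlapping windows advance by `step_seconds`. The step is not a
  published constant; the default is half the window, the most common
  convention, exposed as a parameter. A run of length L yields
  `floor((L − n)/stride) + 1` windows.

## 4. Channel selection

One observation per (window, channel) is obtained by a reducer over time —
the mean by default (median and mean-absolute-value are selectable); nothing
in the protocol dictates this reduction, so it is a documented choice.
Channels are ranked by the one-way ANOVA F statistic and the top K = 50 are
kept. Numerical conventions: zero within-group variance with distinct means
gives `F = Inf` (perfect separation, ranked first); zero within- and
between-group variance gives `F = 0`; rank ties break by ascending channel
index. Because F is invariant under per-channel affine maps, selection runs
on raw summaries and only the retained channels are standardized — an
equivalence the test suite asserts.

The Pearson correlation matrix of the selected features is diagnostic only:
no channel is dropped by correlation (no removal rule is part of the
protocol). `plot_correlation_heatmap()` draws it. On synthetic data the
top-50 is dominated by informative HbO2 channels, matching the physiological
expectation that oxy-haemoglobin tracks load more strongly than deoxy.

## 5. The classifier

`eegnet_config()` fixes the architecture per window length:

| window | samples | F1 | D | F2 | kernel1 | kernel2 |
|---|---|---|---|---|---|---|
| 10 s | 81 | 8 | 2 | 16 | 32 | 8 |
| 20 s | 163 | 16 | 2 | 32 | 64 | 16 |
| 30 s | 244 | 32 | 2 | 64 | 128 | 32 |

with dropout 0.25, mean pooling, ELU, and a classifier kernel spanning the
post-pooling time dimension exactly (`t2 = (n_samples %/% 4) %/% 8`,
computed automatically from the data shape). Off-grid window lengths use the
nearest row. Two conventions deserve note:

* **Separable kernel length.** The layer table pins the separable depthwise
  kernel at 16 while the hyperparameter table scales it 8/16/32; the scaled
  version is used (16 coincides with the 20 s instance), and
  `kernel2_fixed = TRUE` restores the constant.
* **Even kernels.** Same-padding with an even kernel produces one extra
  output column; the convention here is pad `k %/% 2` on both sides and
  crop the trailing extra column, preserving the tabulated shapes exactly.

The network is implemented from first principles — no deep-learning
framework. Layers reduce to 1-D convolutions along time (Rcpp kernels) and
BLAS matrix products; the backward pass is hand-derived and checked against
central finite differences on every tensor (tolerance 1e-4 relative on
random spot checks; observed agreement is ~1e-10).

Numerical/semantic choices:

* **Batch normalization** uses the statistics of the batch being processed
  in both training and evaluation (no running buffers). Evaluation is
  therefore a pure function of the weights and the evaluated batch, which
  keeps the null-step property exact: training with learning rate 0 leaves
  both the weights and all predictions bit-identical. The alternative
  (running statistics) was measured to change fold accuracy by only a few
  hundredths here, and breaks that exactness.
* One structural fact: the first batchnorm's shift parameter has an exactly
  zero gradient, because a per-map constant added before the linear spatial
  collapse is removed exactly by the following batchnorm. It is kept for
  architectural fidelity; the gradient-flow test asserts it is the only
  zero-gradient tensor.
* **Initialization** is Xavier-uniform with the convolution fan convention
  (`bound = sqrt(6/(fan_in + fan_out))`), batchnorm at (1, 0), classifier
  bias 0; deterministic given the seed.
* **Max-norm.** The depthwise spatial filters are re-projected onto the
  unit L2 ball after every Adam step (only filters exceeding the bound are
  rescaled).
* **Training.** Adam with library-default moments (0.9, 0.999, eps 1e-8, no
  weight decay), cross-entropy on log-softmax outputs, batch size 64
  (rather than the near-miss 63 sometimes quoted for this protocol), shuffled minibatches including
  the final partial batch, no early stopping or scheduling; the final-epoch
  model is evaluated. A non-finite loss marks the cell `diverged` instead
  of crashing the grid.

## 6. Cross-validation protocol

`run_experiment()` executes the full grid. Per (window, mode) the windows
are shuffled into 5 folds (sizes differing by at most one); the same
partition is reused for every learning rate in that cell so rates are
compared on identical data. Fold partitions cannot be shared across window
sizes — window counts differ — so sharing is per (window, mode) only.

Metrics are accuracy, macro-averaged recall/precision/F1 and macro
one-vs-rest AUC (Mann–Whitney with midranks). Macro averaging is a choice:
the source tables show recall duplicating accuracy and precision duplicating
F1, which no standard averaging reproduces simultaneously, so the standard
macro definitions are used and the discrepancy documented rather than
imitated. Classes absent from a test fold are skipped with a warning;
never-predicted classes contribute precision 0.

Two leakage-related switches exist, both off by default:

* `paper_mode = TRUE` fits standardization and channel selection once on the
  full dataset before fold splitting — the protocol of the original
  analysis, and a mild information leak. The default fits both per fold on
  training data only.
* `grouped_folds = TRUE` assigns whole subjects to folds. With overlapping
  windows, a window-level random split lets temporally adjacent windows of
  one subject straddle the train/test boundary; the grouped splitter removes
  that optimism, and the test suite checks directionally that grouped
  accuracy does not exceed the random-split accuracy.

## 7. What the shipped checks do and do not show

The test suite exercises the pipeline at deliberately small problem sizes —
sessions with 6–40 sites and 2–5 subjects for the unit and property tests,
and the full default (8 subjects, 102 sites) for the end-to-end checks: a
smoke experiment (10 s non-overlapping windows, learning rate 0.001, 30
epochs, 5-fold CV, 3 seeds) and a reduced-epoch interaction grid (10 s
windows, both modes, rates {0.1, 0.001}, 15 epochs, 3 seeds). The
acceptance script runs the same interaction grid at 30 epochs for one seed.
These sizes are the package's own protocol choices for routine checking;
nothing prevents running the full 10/20/30 s × 3-rate grid at 200 epochs
with `train_spec()` defaults.

Passing tests show that the machinery is correct (oracles, invariants,
gradients, determinism) and that the synthetic task is decodable far above
chance from selected channels. They do **not** show that conclusions about
real fNIRS transfer: in particular, on this generator's smooth, strongly
separable class structure, Adam at learning rate 0.1 converges stably and
can match or exceed rate 0.001 at reduced epochs — whereas destabilized
high-rate training is precisely the phenomenon reported on real data. The
interaction check in the acceptance suite therefore documents how the
synthetic world differs from real recordings: the overlap-vs-nonoverlap
ordering at the low rate reproduces, the high-rate degradation does not.
Reproducing the latter would require a generator with the optimization
pathologies of real physiological data (heavy tails, inter-site correlation,
non-stationarity), which is out of scope here.

## 8. Interchange formats and limitations

Recordings and window sets serialize to wide CSV (full `%.17g` precision;
write-then-read is bit-exact) with JSON sidecars for channel metadata,
sampling rate, labels and provenance; reports serialize to per-fold CSV,
aggregate CSV and a Markdown table. An HDF5-based format was not included
because the package intentionally keeps its dependency set to packages on
every scientific R stack; the CSV+JSON pair carries the same information.

Known limitations: the generator's realism gaps listed above; no motion
artifacts or short-channel regression (device-toolkit territory); no
multiple-testing correction on selection p-values (selection is rank-based,
p-values descriptive); single-CPU training only — the model sizes involved
(1.6k–27k parameters) do not warrant accelerators.
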