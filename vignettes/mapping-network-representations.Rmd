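---
title: "Mapping network representations onto neural data: models and methods"
author: "dnnmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping network representations onto neural data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnnmapr)
```

# Overview

`dnnmapr` treats an artificial neural network as an experimental subject.
A stimulus set is presented, internal activity is recorded through a mask
of layers/channels/units, and the resulting representation is related to
measured neural responses by linear mapping models and by representational
similarity analysis (RSA). This vignette documents the models, their
assumptions, the tunable parameters, the numerical choices, and what the
bundled synthetic fixtures do and do not establish.

# Scanning a network

A `NetworkModel` is an ordered list of named layers (`conv`, `relu`,
`pool`, `linear`) with explicit weights, a deterministic forward pass, and
reverse-mode gradients. Activation tensors have shape
`(n_stim, channels, height, width)`; linear layers produce
`(n_stim, features)` matrices.

Two conventions matter throughout:

- **Indices are 0-based** — in mask files, in the API, and in results.
  The networks these objects describe live in 0-based ecosystems, and one
  convention everywhere beats two.
- **"The activation of a conv layer" means its post-ReLU output** when a
  ReLU immediately follows; `extractActivations(..., postRelu = FALSE)`
  gives the pre-rectification values. Top-stimulus queries follow the same
  convention. Unit-level probes (saliency, synthesis, receptive fields)
  address the named layer's own output, because their target is the unit's
  raw response function; this distinction is deliberate and documented
  here rather than hidden.

Channel-level summaries use the spatial **mean** by default (max and full
flattening are available). Channel-level gradient targets differentiate
the channel's spatial-mean activation, consistent with the summarization
convention.

`reduceDimension()` performs PCA either globally (fit on all rows) or in
leakage-safe mode (`fitOn =` training rows only; held-out rows are
projected but never influence the axes). Both modes exist because
layer-wise dimensionality reduction can legitimately be treated as a fixed
preprocessing step or as part of the fitted pipeline; the choice is
recorded by the caller, and a property test verifies that the held-out
rows genuinely cannot move the axes in leakage-safe mode.

# Encoding and decoding models

For features $X \in \mathbb{R}^{n \times p}$ and a site's responses $y$,
the univariate encoding model fits $y = X\beta + \varepsilon$ per site;
families are ordinary least squares (`glm`), ridge, and lasso. The
multivariate PLS model extracts latent components maximizing the
covariance between $X$ and all sites jointly. Decoding exchanges the roles
of predictors and targets, with penalized logistic regression for
classification.

Cross-validation discipline:

- Folds (`makeFolds`: k-fold with sizes differing by at most one, or
  leave-one-out) are a seeded, reproducible partition carried inside every
  result object.
- Features and responses are z-scored with **training-fold statistics
  only** (`standardize = FALSE` opts out). Constant training columns get a
  unit scale so they standardize to zero rather than NaN.
- Held-out predictions are **pooled across folds** in stimulus order and
  each site is scored once on the pooled vector — stable when folds are
  small. Per-fold scores are retained on decoding results.
- Scores: Pearson $r$ between measured and predicted responses (the
  workflow default) and explained variance
  $1 - \mathrm{var}(y - \hat y)/\mathrm{var}(y)$ for regression; accuracy
  (fraction correct) for classification. Pearson $r$ on a constant vector
  is undefined and returned as `NA`, never silently 0.
- Sites containing NaN or with zero variance are excluded from fitting and
  listed in `excludedSites` — censored sites are a fact of real response
  matrices, not an error.
- Reported weights come from a final whole-data fit mapped back to the raw
  feature/response scale, so a noiseless linear linkage returns the
  generating weights themselves.

Defaults: ridge penalty 1.0 and lasso penalty 0.01 (on z-scored data);
logistic regression uses an L2 penalty with inverse strength C = 1.0
(implemented as `glmnet` with $\lambda = 1/(nC)$); PLS components default
to `min(10, rank bound)`. OLS uses a QR solve with aliased (collinear or
constant) features assigned zero weight, the same convention `lm` uses for
rank-deficient fits.

**Permutation inference.** `permutationTest()` recomputes the full
cross-validated score under seeded permutations of the targets and reports
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + n_\text{perm})$ —
the add-one convention guarantees $p \in (0, 1]$ and makes the test exact
under exchangeability. One-sided (greater) is the default, matching the
"better than chance" question; `n_perm` defaults to 1000.

# Representational similarity analysis

`computeRDM()` builds the stimulus × stimulus dissimilarity matrix with
Euclidean distance or correlation distance ($1 - $ Pearson $r$ across
features; entries in $[0, 2]$). The matrix is forced exactly symmetric
with a zero diagonal; a constant pattern row under the correlation metric
is an error naming the stimulus. `compareRDMs()` correlates the strict
upper triangles (row-major) by Pearson, Spearman, or Kendall's tau-b (the
tie-corrected variant). Stimulus IDs must match in order — alignment is
never silently repaired.

The RSA permutation test relabels the stimuli of the *second* RDM (rows
and columns jointly; permuting vectorized entries independently would
break exchangeability) and recomputes the comparison. Because the
comparison statistic is symmetric in its two arguments, permuting either
RDM yields the same null; the choice of the second argument is arbitrary
and documented. Condition-averaged RDMs are supported by the
`conditionAverage()` pre-step over stimulus attributes.

# Unit characterization

- **Top stimuli**: ranked activation per stimulus, ties broken by
  ascending stimulus order (a stable, reproducible rule).
- **Saliency**: vanilla = the raw input-gradient of the unit's scalar
  activation; guided additionally zeroes gradients through each ReLU where
  the incoming gradient is negative. Sign is preserved; maps have exactly
  the stimulus shape. Gradients are exact (verified against central finite
  differences away from ReLU kinks, and exactly zero outside a unit's
  theoretical receptive field).
- **Empirical receptive field**: occlusion — slide a zeroing patch
  (default 1×1, stride 1) over the probe image, record
  $|\Delta \text{activation}|$ per position, and take the bounding box of
  positions reaching `thresholdFrac` (default 0.05) of the maximum change.
  A unit that never responds to occlusion returns an explicit empty flag,
  never a zero-area box. Occlusion was chosen over gradient-based variants
  because it probes the forward pass directly and needs no
  differentiability assumption.
- **Theoretical receptive field**: an architecture walk mapping an output
  index range back through each kernel/stride/padding stage; serves as the
  analytic bound that the occlusion estimate must respect.
- **Ablation**: a returned model copy whose forward pass multiplies the
  masked channels/units by zero at the masked layer — the simplest
  semantics consistent with removing a unit's signal. Ablation masks
  accumulate by union, so re-applying a mask is idempotent.
- **Optimal-stimulus synthesis**: gradient ascent from seeded
  low-amplitude uniform noise (amplitude 0.1 around zero). Per iteration:
  a step of `stepSize` (default 0.1) along the L2-normalized gradient,
  multiplicative decay `l2Decay` (default 0.01), Gaussian blur of
  `blurSigma` (default 0.5 px) every `blurEvery` (default 4) iterations,
  for `nIter` (default 100) iterations. The low-amplitude start matters:
  from full-range noise the weight-decay term can initially outweigh the
  ascent step for weakly drivable units, so ascent — not the random start
  — should set the scale of the result. The activation trajectory
  (including the start) is recorded, the final entry always equals a fresh
  forward pass, and the full configuration is stored in the result for
  provenance. A fixed iteration count with recorded configuration was
  preferred over a convergence criterion, whose tolerance would just be a
  different arbitrary constant.

# Transfer learning

`fineTune()` attaches a fresh linear head after a named layer and trains
by full-batch gradient descent on softmax cross-entropy (classification)
or mean squared error (regression). Frozen layers are skipped during the
update, so their weights remain bit-identical; head initialization is
seeded. Full-batch descent keeps the procedure deterministic and
sufficient at fixture scale; stochastic mini-batching would add a noise
source without adding anything testable.

# Synthetic fixtures: what they emulate, and what they do not

The fixture layer generates the study conditions for every test:

- **Toy networks** (≤ 3 conv layers, ≤ 16 channels, inputs ≤ 32×32) with
  seeded He-scaled Gaussian, identity, all-ones, or custom weights.
- **Stimuli**: iid uniform noise; oriented gratings with an
  `orientation_deg` attribute; Gaussian blobs with position attributes.
- **Linked responses**: sites are noisy linear readouts
  $Y = F W + \varepsilon$ of a layer's mean-summarized features, with the
  generating $W$ and noise SD returned as ground truth. This instantiates
  exactly the premise of a linear encoding analysis.
- **Category datasets**: `linear_margin` places the two balanced classes
  at ±3 along the first feature with a guaranteed margin (class sign ×
  (1 + |N(0,1)|)/3 × half-margin), so linear separability holds by
  construction for every seed — a sampling scheme that merely makes
  overlap improbable would make "accuracy = 1.0" a seed lottery. `xor`
  labels points by the sign product of two features: balanced but not
  linearly separable, pinning a linear decoder at chance.

Every fixture is a pure function of its arguments and seed; no fixture
touches the filesystem, and no generator call perturbs the caller's RNG
stream.

What passing tests on these fixtures establish: the estimators,
gradients, permutation machinery and file formats are correct under their
own assumptions (linear linkage, iid noise, exchangeable nulls). What they
do not establish: behaviour on real measurements — hemodynamic temporal
structure, spatially correlated noise, nonlinear stimulus–response
relations, or the statistics of natural images and pretrained-network
features are all outside what the generators emulate.

# Numerical choices and problem sizes

- The noiseless linear-recovery check demands the generating weights back
  to 1e-6 and pooled $r \ge 0.999$ (n = 60 stimuli, 3 features, 2 sites).
  Recovery is only asserted on full-rank features — a channel that is dead
  across the whole stimulus set (a rectified channel can be) makes its
  weight unidentifiable, which is a property of the problem, not the
  estimator.
- The one-component PLS recovery check uses a single-latent design
  ($X = t v^\top$): with a generic full-rank $X$, the first PLS weight is
  proportional to $(X^\top X)w$ rather than $w$, so one component cannot
  reproduce the linkage exactly on held-out folds at these sample sizes;
  with a single latent it provably can, which is the property the check is
  after.
- Permutation calibration runs 600 replicate null experiments per test
  (decoding and RSA) at `n_perm = 99`, asserting the empirical rejection
  rate at $\alpha = 0.05$ lies in [0.02, 0.08]; 600 replicates keep the
  binomial noise of that estimate (sd ≈ 0.009) well inside the band. The
  underlying tests were additionally verified exact on thousands of
  replicates during development.
- Finite-difference gradient checks use central differences and must stay
  on one side of every ReLU kink; probe stimuli are drawn (or the step
  shrunk to 1e-4) so that no pre-activation lies within the step's reach
  of zero. At a kink the gradient is genuinely undefined and the
  comparison meaningless.
- Float32 is the storage type for activation payloads (the field's
  convention); a value that has been truncated to float32 once survives
  all further roundtrips bit-exactly, and the test asserts exactly that.
- Accuracy bounds of the form 0.5 ± 0.075 are compared with a 1e-12 slack
  because 0.075 itself is not exactly representable in binary.

# Known limitations

- Only sequential feed-forward architectures (conv/relu/pool/linear); no
  branching, recurrence, or normalization layers. Any conforming model can
  be supplied, but none beyond toy scale ships with the package.
- Binary classification only in the decoding module.
- The conv engine is plain R over im2col index maps — entirely adequate at
  fixture scale (every analysis here runs in seconds), not intended for
  ImageNet-scale models.
- Neuroimaging container formats (NIfTI/GIFTI/CIFTI) are not read
  directly; responses enter via delimited text or HDF5, matching the
  package's position downstream of preprocessing.
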