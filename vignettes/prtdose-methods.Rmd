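---
title: "Methods: progressive-refinement windowed-attention dose prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: progressive-refinement windowed-attention dose prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In postoperative radiotherapy planning for cervical cancer, surgeons
transposing ovaries out of the pelvic radiation field need to know, before
surgery, where the low-dose region of the eventual VMAT plan will lie.
`prtdose` implements an image-to-dose model for this task: given a CT
volume, binary masks for the planning target volume (PTV), nine organs at
risk and the body contour, it predicts the 3D absorbed-dose distribution of
a 45 Gy / 25-fraction VMAT plan, together with the preprocessing that feeds
the network and the dosimetric evaluation suite used to judge predictions
(body-masked error metrics, DVH statistics, gamma index, isodose overlap
and surface distances, plan-criteria checks).

The clinical cohort behind the method (104 patients) is not publicly
deposited. The package therefore ships a synthetic pelvic phantom generator
that reproduces the *structure* of such data — an elliptical body, a
central spherical PTV, surrounding organ-at-risk shapes, and a VMAT-like
dose field — so the whole pipeline is exercisable end-to-end at desk scale.

## Preprocessing

CT values are clipped to the [-1000, +400] HU window and rescaled linearly
to [0, 1]; the rescale (not stated by the window convention itself) is a
recorded normalisation decision for optimisation stability, and the
`windowed` flag makes the operation idempotent. Dose grids are resampled to
2.5 x 2.5 x 5.0 mm by trilinear interpolation with voxel centers at
`origin + index * spacing` (0-based); this coordinate convention is fixed
package-wide so resampling and surface distances are testable. In-plane
grids are zero-pad centred to a square (512 at clinical scale; tests and
the phantom work at 64 so a forward pass takes well under a second).

Each slice becomes an 11-channel superimposed map: windowed CT first, then
the ten masks in the fixed order PTV, bladder, femoral head left/right,
kidney left/right, marrow, rectum, spinal cord, body. Three consecutive
slices (boundary slices replicated at the volume edges) are concatenated
into a 33-channel triplet input. The regression target is the **center**
slice's dose — the symmetric choice of context — normalised by the
prescription so the network fits order-one values; the scale is recorded in
each sample and undone at prediction time.

## The network

The model is an encoder–decoder with four prediction branches:

* **Stem**: one 3x3 convolution at full resolution provides the skip for
  the final decoder stage.
* **Encoder** (four stages): patches of `P = 2` pixels are linearly
  embedded into `Ce = 32` dimensions (learnable position parameters, one
  table per attention window shared across windows, are added once at
  embedding). Each stage applies a constant-window attention block, a
  shifted-window attention block, and a convolutional block-attention
  module (CBAM). Between stages, 2x2 patch merging concatenates token
  quadruples and projects to double width, so stages run at token sides
  32/16/8/4 and widths 32/64/128/256.
* **Attention**: per head, `Q = x W_Q`, `K = x W_K`, `V = x W_V`, and the
  score matrix is `S = tanh(Q + K) W_alpha / sqrt(dk)` — note `W_alpha` is
  a *learnable* `dk x Nw` matrix, which forces a fixed token count per
  window; attention therefore operates on non-overlapping windows of
  `Nw = 16` tokens, with rows softmax-normalised and applied to `V`, and
  heads concatenated (no output projection beyond the concatenation, as
  the formulation specifies none). Shifted blocks displace the partition
  by half a window with cyclic wrap, masking attention across wrap
  boundaries; when a window covers the whole token grid the shift is a
  no-op and is disabled.
* **Decoder** (four stages): bilinear x2 upsampling, skip concatenation,
  then two (conv 3x3, batch norm, Mish) blocks at widths 64/32/16/8
  (coarse to fine; the clinical-scale configuration is 512/256/128/64).
* **Progressive refinement**: each decoder stage feeds a generation head
  (two conv–BN–Mish blocks and a single-channel 3x3 conv) emitting a dose
  map `phi_i` at side n/8, n/4, n/2, n. The pyramid is accumulated as
  `p_1 = phi_1` and `p_i = phi_i + U(p_{i-1})` with bilinear x2 upsampling
  `U` — cumulative coarse-to-fine correction. (The printed recursion mixes
  its indices; the cumulative form is the reading consistent with refining
  "from low to high resolution", and zeroing heads 2–4 makes `p_4` exactly
  the x8 upsampling of `p_1`, which the tests assert.)

Because no deep-learning framework is available in this R stack, the
package carries its own reverse-mode autodiff engine (`R/autodiff.R`):
a flat tape of coarse-grained ops (matrix multiply, im2col convolution,
windowed-attention application, layer/batch norm, pooling, sparse
resampling) whose backward rules are each verified against central finite
differences in the test suite. The two hot kernels — im2col/col2im and the
block-diagonal attention application — are compiled (Rcpp). BLAS is pinned
to one thread at load because the engine issues many small GEMMs for which
OpenBLAS thread synchronisation costs more than the arithmetic.

Unstated architectural constants were fixed as follows: transformer MLP
hidden ratio 2, CBAM channel reduction 4, window side 4 tokens, Xavier
initialisation, and a small (sd 0.01) initialisation of each head's final
convolution so an untrained network predicts near zero dose.

## The fused loss

Training minimises, on every pyramid level `i` against area-average
downsampled targets (an intensive quantity; PTV masks re-binarised at 0.5):

* `Lm = ||p - y||^2 / (2m)` — mean squared error;
* `Lp = lambda_k mean_PTV((p - y)^2)/2 + mu_i mean_nonPTV(max(p - y, 0)^2)/2`
  with `lambda_k = 0.7`, `mu_i = 0.3` — inside the PTV both directions are
  penalised; outside, only overshoot (the dose should fall off fast, so
  under-dosing normal tissue is free);
* `Lr` — a pairwise rank loss: pixels are sorted by the target (stable
  sort, so ties break deterministically), adjacent sorted pairs are scored
  `rho = logistic(p*(s+1) - p*(s))` with labels `omega = 1` (target strictly
  increases) or `1/2` (tie), and the negative mean pairwise log-likelihood
  is taken. The printed form of that likelihood contains `(1 - log rho)`
  where a log-likelihood requires `log(1 - rho)`; the corrected form is the
  default (`rank_variant = "log1m"`) and the literal form is kept behind
  `rank_variant = "as_printed"` for auditability.

Losses are computed over the full padded grid (only *evaluation* is
body-masked); a body-mask option for the losses exists but defaults off.
Branch weights default to 1 (equal deep supervision). Note `Lr` does not
vanish at `p = y`: adjacent sorted gaps are near zero, so each pair
contributes about `log 2`, giving a constant floor (about 1.37 for the
phantom slices) under which the `Lm`/`Lp` excess must be read.

## Training

Adam (lr 1e-4, weight decay 1e-4, batch 16, 100 epochs in the reference
configuration) with a constant learning rate; data order, initialisation
and hence entire metric logs are reproducible from the seed on CPU. Each
step runs one stacked forward pass for the whole minibatch — batch-norm
statistics are computed over the batch, as usual — while the losses are
evaluated per sample on slices of the stacked pyramid (the rank loss must
sort within a sample) and averaged. Inference defaults to the sample's own
batch statistics (`stats = "batch"`, deterministic and consistent with
optimisation); tracked running averages are available as an alternative. Checkpoints capture weights, batch-norm statistics and the
configuration; the best-validation checkpoint is kept when a validation
set is supplied (the selection rule is otherwise unstated, so validation
fused loss was chosen). The cohort split follows the 69/22/13 proportions
of the reference cohort of 104.

The test suite's end-to-end gate is an overfit probe: four noise-free
phantoms, one middle-slice sample each, full-batch Adam at lr 1e-3 with
weight decay 0 (no regularisation in a memorisation test) for 225 steps.
At these conditions the mean body-masked MAE is about 4.6% of the 45 Gy
prescription and the 4 Gy isodose DSC about 0.93–0.95. Two systematic
effects were characterised while fixing these conditions: (i) the one-sided
non-PTV loss plus the rank loss's indifference between near-tie orderings
turn residual fit wiggle into a small *underdose* bias, so the fused loss
plateaus above the pure-MSE fit quality; (ii) that plateau is rate
dependent — lr 1e-3 reaches a lower equilibrium than 3e-3, while a staged
rate drop merely freezes the bias, so the constant schedule is kept.

## The phantom generator

Defaults encode the study conditions: 45 Gy prescription, 2.5 x 2.5 x 5 mm
voxels, an elliptical body cylinder (semi-axes 70 x 75 mm), a 25 mm
spherical PTV, and eight spherical OAR stand-ins placed anatomically
(bladder anterior, rectum posterior, femoral heads lateral with bone-level
HU, kidneys, marrow, spinal cord posterior). The dose model is
`prescription * exp(-d / falloff)` in the distance `d` to the PTV sphere
surface, zero outside the body, plus optional Gaussian noise (default sd
1 Gy) inside the body; `falloff = 20 mm` puts the 4 Gy isodose just inside
the body edge so the low-dose bands 4–10/10–15/15–20 Gy are populated. The
exponential is a one-parameter, strictly monotone stand-in for VMAT
falloff — the reference data are never characterised statistically, so no
claim of dosimetric physics fidelity is made. Cohort generation jitters
body axes (±10%), PTV radius (±20%), falloff (±10%) and OAR centers
(±5 mm in-plane), all config-exposed.

What passing tests on phantoms do **not** show: performance on real
anatomy (deformable organs, heterogeneous HU, plan-specific modulation),
nor the reference study's clinical error statistics, which would require
the undeposited cohort and full-scale training.

## Evaluation conventions

All error metrics are computed inside the body contour only. DVH: `Vd`
uses `>=`; `Dq` on raw voxels is the ascending order statistic at position
`floor(m (1 - q/100))` (doses 1..100 Gy give D95 = 5 Gy), which guarantees
`V(Dq) >= q`; on a binned DVH curve the largest bin dose still covering q%
is returned (these differ by up to one dose gap by construction). Gamma
uses global normalisation (3% of the maximum truth dose), a 10%-of-max
low-dose threshold, and an exhaustive shift search over a disk/ball of
radius `3 * dta` at step `dta/10` with linear interpolation, visited in
order of increasing distance with early termination; for 3D grids the
z-search moves in whole slices (5 mm spacing versus a 6 mm radius) while
the in-plane search remains sub-voxel. Isodose overlap thresholds at
`>= level`, and Hausdorff/HD95 are symmetric, computed from face-connected
surface voxel centers in mm, HD95 as the 95th percentile (type-7 quantile)
of the pooled directed distances, so HD95 <= HD always. Plan criteria
follow the stated limits; the PTV D95-versus-prescription bound is treated
as inclusive at the exact boundary (relevant only for synthetic exact-dose
cases) and flagged as such in the documentation.

## Problem sizes

The shipped tests run the network at n = 64 with widths (64, 32, 16, 8),
four-phantom cohorts of three 64 x 64 slices, 24 x 24 gamma oracle slices,
and a 225-step probe — sizes chosen so the whole suite completes on one
CPU core in well under half an hour while still exercising every module at
full fidelity. The clinical-scale configuration (n = 512, widths
512/256/128/64, batch 16, 100 epochs) is reachable purely through
configuration but is not executed by the tests.

## Known limitations

* The engine is CPU-only and single-threaded; clinical-scale training is
  configurable but not practical in it.
* Exact architectural constants of the reference network (embedding dim,
  heads, depths, window size) are unpublished; the defaults here are
  self-consistent choices, so learned-weight compatibility is out of scope.
* The phantom's exponential falloff ignores beam geometry, heterogeneity
  and modulation; it exists to give the pipeline data with the right
  structure, not the right physics.
* DICOM-RT input/output and rigid registration of preoperative to planning
  CTs are out of scope; cases enter as NIfTI + JSON directories.
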