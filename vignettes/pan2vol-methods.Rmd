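---
title: "pan2vol: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pan2vol: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model it
implements, the choices made where the design was genuinely open, and
what its synthetic experiments can and cannot establish.

## The problem and the data model

A panoramic radiograph integrates X-ray attenuation along the depth
(buccolingual) axis of the dental arch. The clinically decisive fact
about a maxillary impacted canine — whether its crown lies buccal,
middle, or lingual — is exactly the information that projection
destroys. `pan2vol` implements the first stage of a two-stage
reconstruction: expanding the 2D panoramic into a *flattened* pseudo-3D
volume, before any bending along the real archform (the second stage,
out of scope here).

Data live on a fixed grid: a volume is indexed `(rl, ap, is)` with the
arch width `N` free, the AP and IS extents equal to the patch side `P`
(128 in the full-scale setting, smaller for CPU work), and voxel
spacing carried in mm (0.3 mm isotropic by default, the resolution of
typical CBCT protocols). A panoramic is `(rl, is)`. The buccal face is
`ap = 1`; this orientation is a storage convention, fixed once and used
consistently by the phantom, the classifiers, and the projection code.

Intensities are affinely normalized to `[-1, 1]` per image before
training. A constant image has no range to stretch and maps to 0, the
interval midpoint. Histogram matching to a template — used to align
synthetic panoramic distributions — is rank-based quantile mapping with
average ranks for ties; the variant was not prescribed, and average
ranks make the map deterministic and symmetric under relabeling of tied
voxels.

## Patching

Training and inference operate on cubic `P^3` patches sliding along the
arch. Patches start at every multiple of the stride `S` strictly below
`N`, so a volume contributes `ceiling(N / S)` patches; RL overhang
beyond the volume is zero-padded, and the padded columns are recorded so
reassembly can exclude them. This start rule was chosen because it
reproduces the worked patch count of the full-scale setting (a 320-wide
volume at stride 32 contributes 10 patches of side 128), where the
conventional "full patches only" rule `(N - P)/S + 1` would give 7.

Reassembly averages all in-bounds contributions per voxel. One numerical
subtlety: when every contribution to a voxel is bit-identical (the case
in an extract/reassemble round trip, where overlapping patches copy the
same source), the common value is returned verbatim instead of
`sum/count`, making the round trip exact rather than exact-up-to-FP
rounding. Contributions that genuinely differ (generator outputs) are
averaged normally.

## Networks

The generator follows the single-view encoder–decoder pattern: a 2D
convolutional encoder (3x3, stride 2, leaky ReLU, `n_levels` stages), a
depth-replication lift of each encoder feature map into 3D
("Connection-A": an `(rl, is, c)` map becomes `(rl, d, is, c)` by
copying along AP), and a 3D decoder (nearest-neighbour upsampling plus
3x3x3 convolutions) that adds the lifted features as skip links at
matching resolutions ("Connection-B"), ending in a tanh-bounded 3x3x3
output convolution. The discriminator is a least-squares patch critic:
`n_levels` strided 3D convolutions and a linear 1-channel head, so its
score grid is strictly coarser than the input and unbounded, as the
squared-deviation losses require.

The reference architecture is published only as a figure and a citation
to a single-view biplanar-CT framework; its exact layer inventory is not
recoverable. The package therefore fixes a *contract* — 2D encoder,
replication lift, skip-linked 3D decoder, bounded output, deterministic
initialization, configurable width/depth — and tests that contract
(shapes, bounds, determinism, receptive field, gradient correctness)
rather than a specific layer recipe. Width (`base_channels`, default 8)
and depth (`n_levels`, default 2) are sized so that a `P = 32` model
trains in minutes on one CPU; `P = 128` is supported by the same code.

Convolutions (forward and backward, 2D and 3D) are im2col + GEMM in
C++/Armadillo; everything else (activations, lifts, upsampling, Adam) is
R. All gradients are verified against central finite differences in the
test suite.

## Objective

The discriminator minimizes
`E_y[(D(y)-1)^2] + E_x[D(G(x))^2]`; the generator minimizes
`lambda1 * E_x[(D(G(x))-1)^2] + lambda2 * L_R + lambda3 * L_P`.
Three reading decisions were required:

* The printed generator objective names the discriminator's own loss in
  its adversarial slot; a generator cannot meaningfully minimize that in
  least-squares form, so the generator's adversarial loss (scores pushed
  to 1) is used.
* The squared-norm notation is realized as a *mean* squared error, which
  makes losses patch-size invariant and keeps voxel and projection terms
  commensurable. For the same reason, plane projections are means, not
  sums, along the projected axis.
* The expectation in the GAN losses is taken over both score-grid
  elements and batch (the empirical mean over everything available).

The weights `lambda1 = 0.1, lambda2 = 10, lambda3 = 10` are defaults in
the spirit of reconstruction GANs of this family, where the voxel and
projection regularizers dominate; the source work does not report its
values, and all three are configuration-overridable. With `lambda1 = 0`
the adversarial term is absent from the generator objective and the
discriminator cannot influence the result, so training skips the
discriminator updates entirely and reduces to supervised regression —
this is also the regime used by the training regression test, because it
has a monotone loss to assert against.

An always-true inequality worth knowing: the projection loss never
exceeds the voxel loss (projection is an average, and averaging
contracts squared error); the suite checks this on a thousand random
pairs as a regression guard.

## Training

Adam with `lr = 2e-4`, `beta = (0.5, 0.999)` by default — standard for
least-squares GANs; the source reports only "Adam". Each step samples
aligned 2D/3D patch pairs (same RL start) and alternates
`d_updates_per_g` discriminator updates with one generator update. All
randomness derives from one training seed, so runs are bit-identical on
a single-threaded BLAS; a zero learning rate is explicitly permitted as
a degenerate configuration and leaves parameters untouched. Training
aborts with a diagnostic naming the component and step if any loss
becomes non-finite.

Cross-validation follows the uneven-group scheme of the full-scale
experiment: impacted ids are shuffled deterministically and split into
`k` maximally even groups (74 ids at `k = 15` give fourteen 5s and one
4); every fold tests one group and trains on the rest *plus all
controls* — controls are read as training augmentation only, never held
out, which is how "kept as one group, each fold contained all the
training data" is interpreted here.

Full-width inference slides the generator across the panoramic at the
same starts as patch extraction and reassembles with overlap averaging,
excluding padded columns; with an oracle generator this inverts patch
extraction exactly at any stride, which the suite asserts.

## The phantom: what it emulates, and what it does not

The generator needs paired panoramics and volumes; the clinical pairs
are confidential. The phantom stands in with the simplest geometry that
preserves the *task structure*:

* discrete tissue intensities, strictly ordered air (0) < trabecular
  bone (0.35) < dentine (0.7) <= enamel (1.0) — arbitrary but ordered
  values on a unit scale, configurable in the phantom spec;
* a bone slab spanning the arch width in the middle band of depth;
* a row of erupted teeth (dentine capsules with enamel crown caps) at
  the middle depth, one of which — the canine slot, the tooth nearest a
  quarter of the arch width — is *removed* in impacted samples;
* one impacted canine: an enamel crown ellipsoid (with a dentine root)
  whose depth centroid falls in the requested third of the flattened
  depth — buccal `[0, 1/3)`, middle `[1/3, 2/3)`, lingual `[2/3, 1]` —
  with uniform jitter inside a band comfortably away from the
  boundaries (e.g. depth fraction 0.10–0.26 for buccal), and whose RL
  centroid is displaced 4–8% of the arch width toward (mesial) or away
  from (distal) the midline relative to the slot;
* an apical (upward) crown displacement of 2 mm by default — the
  vertical position is embedded in the data but, as in the clinical
  evaluation, never scored;
* additive Gaussian noise (sigma 0.05 on the unit tissue scale) applied
  independently to the volume and to the rendered panoramic.

The panoramic is the depth-axis mean projection of the clean volume,
normalized to `[-1, 1]`. Phantom generation is a pure function of its
spec (including the seed), and dataset generation fans one master seed
into per-sample seeds.

What the phantom does *not* emulate: real mandibular/maxillary anatomy,
the focal-trough blur of panoramic machines, beam hardening, soft
tissue, or the intensity statistics of CBCT-derived projections. A green
test therefore establishes that the pipeline's mechanics are correct —
patching, losses, optimization, metric arithmetic, and that position
information *can* flow from panoramic to volume at toy scale — not that
clinical-grade reconstruction accuracy is achievable; the full-scale
clinical accuracies cannot be reproduced without the withheld data and
GPU-scale training.

There is no numeric ground truth for how far buccally or lingually real
impactions sit; the displacement bands above are free parameters of the
stated synthetic world, chosen once so that the planted label is
unambiguous under the classifiers below, and not revisited.

## Evaluation

**SSIM.** Mean over all valid sliding windows (uniform 7^3 window) of
the luminance–contrast–structure product with `C1 = (0.01 L)^2`,
`C2 = (0.03 L)^2` and declared dynamic range `L = 2` for `[-1, 1]` data.
Local variance and covariance use the unbiased (`n-1`) estimator,
matching the de-facto standard implementation (verified against
scikit-image during development and against an independent per-window
oracle in the suite). Zero-variance windows reduce to the luminance term
via the stabilizers; identical inputs give exactly 1. The window and
constants are logged in every report.

**Position classification.** The clinical study localized crowns
visually; this package substitutes an explicit, testable rule. The crown
ROI is the ground-truth mask dilated by 2 voxels — evaluation measures
reconstruction fidelity at a known site, not detection. Within the ROI,
the intensity-weighted centroid (weights shifted by the ROI minimum, so
air contributes nothing) yields a depth fraction classified by equal
thirds with half-open boundaries (`f = 1/3` is middle), and an RL
coordinate classified mesial when at least as close to the arch midline
as the normal slot (exact ties are mesial; there is no middle class in
this direction, mirroring the clinical labeling).

**Accuracy arithmetic.** Per-class percentage correct is rounded
half-up to an integer — the only rounding rule that reproduces both
3/26 = 12% and 1/9 = 11% simultaneously — and overall accuracy is the
pooled fraction correct to two decimals. SSIM quartiles use the linear
interpolation (type 7) empirical quantile.

## Other numerical and interface choices

* NIfTI-1 I/O (float32, single-file `.nii`/`.nii.gz`, spacing in
  `pixdim`) is implemented in the package because the target environment
  has no NIfTI package; it is deliberately minimal. PNG export of
  panoramics is 8-bit and lossy, for previews; NIfTI is the lossless
  path.
* Checkpoints are single versioned RDS files (params + config +
  training seed). Dataset manifests are versioned JSON carrying each
  sample's labels, seed, slot position, file names, and full spec with
  an FNV-1a fingerprint (no hashing package is available, so the hash
  is implemented in R).
* All file outputs are written atomically (temp file + rename), so a
  failing command leaves no partial outputs.
* The command-line wrapper (`inst/cli/pan2vol`) fans a single master
  seed deterministically into simulation, initialization, batching, and
  fold shuffling.

## Known limitations

* The generator is a faithful *contract* implementation, not a
  replication of the reference layer inventory (which is not published
  in recoverable form).
* CPU-scale configurations (P = 16–32, base width 4–8) are the tested
  regime; `P = 128` runs but is not exercised by the default suite.
* The phantom's geometric simplicity makes the position task easier
  than the clinical one; accuracies on phantoms should be read as
  plumbing checks, not clinical estimates.
* SSIM between `[-1, 1]` images can be negative; the clinical quantity
  of interest (similarity of plausible reconstructions) lives in the
  upper part of the range, where the metric is well behaved.
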