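---
title: "Automatic cranial implant geometry: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic cranial implant geometry: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cranioplasty repairs a skull defect with an implant that must continue the
cranial vault's convex shape and meet the defect boundary precisely.
Mirror-based design fails when the defect crosses the mid-sagittal plane or
the skull is asymmetric, which motivates learning the spatial distribution
of intact upper crania and using it to complete a defective model. The
package implements that pipeline end to end on dense binary voxel grids:

1. **Acquire/synthesize** an intact cranial model — either by thresholding
   a CT intensity volume to bone (closed Hounsfield interval, default
   `[1200, 1817]`) and normalizing it to a 112 × 112 × 40 upper-cranium
   grid, or with the built-in shell phantom generator.
2. **Simulate a defect** by Boolean subtraction of a parametric 3D mask:
   `defective = intact AND NOT mask`. The removed part,
   `P = intact AND mask`, is the ideal implant.
3. **Complete** the defective model with a compact 3D autoencoder.
4. **Extract the implant**: `P* = completed AND NOT defective`, optionally
   post-processed at a 4×-finer plane resolution for printing.
5. **Score** with the volumetric error rate
   `r = 100 · ‖P − P*‖₁ / ‖P‖₁`, the 1-norm of the voxelwise difference
   relative to the ideal implant's volume. On binary grids the numerator
   is the symmetric-difference count, so overfill and underfill both
   count, and `r` can exceed 100 %.

## The network

The completion model (`cranionet_spec()`, `build_network()`) is a
12-conv-layer skip-connected autoencoder with a dilated bottleneck:

| stage | layers | channels | dilation | resolution |
|---|---|---|---|---|
| encoder | conv1, conv2 (pool after each) | 8, 8 | 1 | full → 1/2 → 1/4 |
| encoder | conv3, conv4 | 4, 4 | 1 | 1/4 |
| bottleneck | dil1–dil4, then pool | 4, 4, 4, 4 | 2, 4, 8, 16 | 1/4 → 1/8 |
| decoder | deconv1 (up), deconv2 (up), deconv3 (up) | 4, 8, 8 | 1 | 1/8 → full |
| output | conv12, sigmoid | 1 | 1 | full |

All kernels are 3 × 3 × 3 with stride 1 and zero "same" padding; every
activation is ReLU except the final sigmoid, and there is no dropout or
batch normalization, so a forward pass is fully deterministic. Each layer
carries `27·C_in·C_out + C_out` parameters — `(224, 1736, 868, 436, 436,
436, 436, 436, 436, 872, 1736, 217)`, 8 269 in total. The four dilated
layers give the bottleneck a wide field of view at constant cost: a
3 × 3 × 3 kernel at dilation `d` spans `2d + 1` voxels per axis
(`effective_receptive_field()`), up to 33 at dilation 16, while keeping
27 weights per channel pair.

Eight **additive** skip connections join (i) the two pooled encoder
tensors to the matching decoder outputs, (ii) conv3's output to the first
up-sampled decoder tensor, and (iii) five neighboring mid-layer pairs
(conv3→conv4 and along the dilation stack). Additive (rather than
concatenative) skips are forced by the parameter accounting: the printed
channel sequence reproduces the total of 8 269 only if skips add no input
channels — `build_network()` asserts shape and channel compatibility of
every edge at construction time. The source tensor is added after the
destination's activation; pre- versus post-activation addition changes
neither shapes nor parameter counts, and the post-activation form keeps
every named tensor equal to what its consumers see.

Up-sampling is parameter-free nearest-neighbour 2×: the "deconvolution"
layers carry ordinary 3 × 3 × 3 stride-1 kernels, so learned up-sampling
would break the parameter total. Pooling sits after conv1, conv2 and the
dilation stack — the placement consistent with the bottleneck feature-map
resolutions (quarter resolution entering the dilations, eighth leaving
them; 28 × 28 × 10 and 14 × 14 × 5 at the full working grid). Input
shapes must therefore be divisible by 8 along every axis.

## Training

`cranionet(pairs, spec, control)` minimizes voxelwise binary cross
entropy with the Adadelta optimizer, mini-batches of 10 pairs, and a
random 10 % validation split — returning the weights of the best
validation epoch. Adadelta's decay rate is 0.95 with conditioning
epsilon 1e-6 (the optimizer's canonical constants; Adadelta adapts its
own step sizes, which is why no learning rate appears anywhere).
Probabilities are clamped to `[1e-7, 1 − 1e-7]` before the logarithm.
Everything stochastic — weight initialization (Glorot-uniform with
`fan = 27·C`), the split, and per-epoch shuffling — derives from the
single control seed, so a fit is a pure function of (pairs, spec,
control); two runs with the same seed produce identical histories.

Two initialization details are the package's own choices where the
method description is silent:

* the output layer's bias starts at the empirical log-odds of voxel
  occupancy in the training targets (`calibrate_bias = TRUE`). With ~9 %
  foreground this removes the early epochs otherwise spent learning the
  base rate; it changes nothing about the converged model class.
* the Adadelta accumulator state is stored on the fitted object, so
  training resumed from a checkpoint continues with adapted step sizes
  instead of re-warming from zero.

Defect masks are fixed per pair by default (a pre-generated cohort);
re-sampling per epoch is possible by rebuilding pairs between calls,
since fits are resumable.

## The phantom generator

No cranial CT accessions are distributed, so every quantitative result in
the package is computed on synthetic upper-cranium shells
(`generate_phantom()`, `generate_cohort()`). A phantom is the difference
of two concentric ellipsoids — outer semi-axes drawn per subject,
constant per-axis thickness — optionally perturbed by a smooth degree-2
spherical-harmonic radial field (surface noise), rotated about the
vertical axis, tilted, and truncated at the grid's bottom face so only
the upper cranium remains (open bottom). Cohort variation (semi-axes,
thickness, pose, jitter, noise amplitude) scales with the grid:
at the full 112 × 112 × 40 profile, in-plane semi-axes of roughly 38–47
voxels, vertical semi-axis exceeding the grid depth (so the bottom cut
lands below the equator), and thickness of ~4.5–7.3 voxels, i.e. a few
millimetres at CT-like spacing. These ranges are a modelling choice — the
source cohort's statistics are not published — and are configuration, not
a claim of anthropometric fidelity.

What the phantoms share with real crania: closed convex-ish shells of
finite, smoothly varying thickness, inter-subject size/eccentricity/pose
variation, and an open base. What they lack: sutures, foramina, facial
bones, thickness inhomogeneity from diploë, and scanner artifacts.
Passing the synthetic benchmarks therefore demonstrates that the
implementation learns and completes smooth shell geometry under the
stated protocol — not clinical performance on patient data.

Working grids are named profiles (`resolve_grid()`): `"full"`
(112 × 112 × 40), `"reduced"` (56 × 56 × 16) and `"mini"` (32 × 32 × 8).
The reduced profile halves the full plane; its depth is 16 rather than a
half-scaled 20 because three 2× poolings require divisibility by 8.

## Defect families

Six mask families are implemented (`make_mask()`): symmetric ellipsoid
(equal in-plane semi-axes), ellipsoid, mixed ellipsoid (union of 2–3
overlapping ellipsoids), cylinder, elliptical cylinder, and mixed
elliptical cylinder. Cylinder-family boundaries are parallel to the axial
direction — identical in-plane cross-sections on every slice, spanning
the full grid depth — while ellipsoid-family boundaries are curved.
`sample_training_pair()` draws the family uniformly, centers a primitive
on a random occupied voxel in the upper part of the shell, and rescales
it (bounded retries, center resampled each retry) until the defect
fraction `|P| / |intact|` lands in the requested interval; masks crossing
the mid-sagittal plane are flagged, since such defects are exactly the
ones mirror-based design cannot handle. The "mixed" construction — unions
of overlapping primitives — follows the rendered compound outlines; no
formula is published for them.

## Numerical choices and degenerate inputs

* Resampling (plane downsampling, pose augmentation, post-processing
  up-sampling) is trilinear interpolation followed by 0.5 binarization;
  this preserves thin shells better than nearest-neighbour decimation.
  An augmentation variant losing more than a configured fraction of its
  occupancy at the grid boundary triggers a warning but is retained.
* The HU interval is treated as closed at both ends and configurable,
  since openness and rescale conventions are not fixed by the protocol.
* Binarization of the sigmoid output uses threshold 0.5 with the `>=`
  tie rule, exposed as a flag.
* Implant post-processing is up-sample → morphological closing (radius 1)
  → Gaussian (σ = 1 voxel) → 0.5 re-binarization → re-subtraction of the
  high-resolution defective model; re-subtraction is idempotent and the
  smoothing defaults are calibrated so a large solid's volume changes by
  < 5 %. If smoothing empties an implant the unsmoothed geometry is used,
  with a warning.
* Degenerate cases fail loudly: masks that miss the skull (no defect),
  empty ideal implants (undefined error rate), shells that violate the
  2-voxel grid margin, non-divisible input shapes, non-finite losses.
* The voxel-face STL mesh is watertight by construction and its enclosed
  volume equals the voxel count exactly; marching-cubes smoothing is out
  of scope since printing-oriented smoothing already happens in the voxel
  domain.

## Problem sizes used in the checks

The packaged benchmarks run at the reduced profile: a 230-shell training
cohort (207 train / 23 validation after the 0.1 split) with one defect
per shell at 5–20 % defect fraction, up to 70 training epochs with
early stopping on the validation-loss plateau (patience 20), and 24
held-out shells with independently sampled defects for evaluation; the
capability curve probes 5 %-wide fraction bins up to 50 % on held-out
shells. These sizes were chosen as the smallest cohort that exercises
the full protocol — augmentation-scale cohorts and the full
112 × 112 × 40 grid change memory and wall-clock, not code paths. Since
"satisfactory" repair is not numerically defined for the capability
study, the curve reports an explicit surrogate criterion (mean r ≤ 15 %
per bin) clearly labelled as an artifact-defined threshold.

It matters to be explicit about what this training scale can and cannot
show. A clinical-scale training regime runs more than a thousand epochs
over thousands of augmented samples — on the order of a hundred times
more optimizer updates than the packaged benchmark performs. Within the
packaged budget the network learns the completion task qualitatively
(defect regions are filled, validation loss falls smoothly), but the
completion is not yet voxel-sharp: a sub-voxel rind of misclassified
boundary voxels remains around the repaired patch, and because the
volumetric error rate divides by the ideal implant's volume — small at
5–20 % defect fractions on thin reduced-profile shells — that rind
dominates the measured rate at this scale. The error rate declines
steadily as the optimizer budget grows; the acceptance script reports
whatever the protocol genuinely measures rather than extrapolating.

## Known limitations

* Phantoms are smooth ellipsoid-derived shells; performance numbers on
  them do not transfer to clinical CT without retraining and validation.
* The finest skip connection lives at half resolution, so full-resolution
  boundary detail must be re-synthesized by the last two layers; on thin
  shells this is the dominant error source (a one-voxel halo around the
  shell costs several error-rate points on small defects).
* Training on a single CPU core with an 8 269-parameter model is
  feasible (minutes at the reduced profile) but the full-profile,
  augmentation-scale training regime of the clinical setting is not
  attempted here.
* DICOM series and NRRD are not read directly; intensity volumes enter
  as NIfTI.
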