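---
title: "Multiscale patch-based label fusion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale patch-based label fusion: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densefuse)
```

This vignette is the package's own account of the science it implements:
the segmentation model and its assumptions, the parameters that matter, what
the synthetic test bed does and does not emulate, and the choices made where
the design was genuinely open.

## The segmentation model

Non-local patch-based label fusion treats segmentation as weighted voting
over a library of co-registered labeled atlases. For a voxel $x_i$, every
position $j$ inside a cubic search volume $V_i$ of every library member $s$
contributes its label $y_{s,j}$ with weight

$$ w(x_i, x_{s,j}) = \exp\!\left(-\frac{D_{i,j,s}}{h^2}\right), \qquad
   D_{i,j,s} = \frac{1}{|P|}\sum_{p \in P} \left(P(x_i)_p - P(x_{s,j})_p\right)^2 , $$

and the per-voxel label probability is the normalized weight mass per label.
The model's central assumption is that the subject and the library share a
common geometric and intensity space: inputs must already be denoised,
bias-corrected, intensity-normalized (`normalize_intensity()` implements the
piecewise-linear tissue-median mapping as an optional pre-stage), and
affinely registered to the template grid. Under that assumption a small
search volume suffices, because anatomy is already coarsely aligned.

The bandwidth $h$ is not free: it is estimated per target voxel from the
minimum patch distance inside its search volume. We use $h^2 = D_{\min} +
\varepsilon$ with $\varepsilon = 10^{-6}$, which makes the best match's
weight exactly 1 when a perfect match exists ($D_{\min} = 0$) and about
$e^{-1}$ otherwise. $h$ is recomputed per scale and per voxel; sharing it
across scales would couple the two probability maps through an arbitrary
constant.

Robustness to white-matter lesions is achieved purely through library
content — lesion-bearing members carrying WML labels — with no
lesion-specific code path: a subject lesion finds its best matches among
lesion patches and inherits their label, while an intensity-only classifier
would call the same voxels gray matter.

## Acceleration: approximate nearest neighbor fields

The exhaustive sum is exact but quadratic in window volume;
`fuse_labels_exhaustive()` exists as the reference implementation and
oracle. The production path, `build_annf()`, keeps $k$ candidate
correspondences per voxel, initialized with each member's affinely aligned
position plus random window samples, then refined by (a) propagation of
shifted candidates from already-scanned raster neighbors (alternating scan
direction per iteration) and (b) random search around the current best
candidate with a radius halving per probe. Candidates stay sorted and unique
per (member, position); inserts only ever improve, so the mean best distance
is non-increasing across iterations, and the whole field is a pure function
of the seed (a self-contained xorshift64* stream, independent of R's RNG).

Votes are aggregated *patchwise* (each matched patch votes labels for every
masked voxel it covers), the late-aggregation scheme of the OPAL lineage;
central-voxel voting is also provided, and with $k$ covering the whole
candidate pool it reproduces the exhaustive probabilities to $10^{-12}$ —
that equivalence is tested, as is the degenerate-window case where the field
must equal the exhaustive best-$k$ exactly.

One honest limitation, quantified in the acceptance suite: on
piecewise-constant images, label boundaries *within* a tissue (e.g. the
left/right split of white matter) carry no intensity contrast, so the full
exhaustive sum decides them by a label-frequency prior over the window.
Any best-$k$ restriction flattens that prior; even the fully converged
best-$k$ field agrees with the exhaustive argmax at only about 93–94% of
ICC voxels on such phantoms. At the pipeline's operating point — two scales
mixed, patchwise voting, background excluded inside the ICC — agreement is
about 96%, and that is the comparison the acceptance suite makes, because it
is the form in which the acceleration is actually used. On textured real
data the gap shrinks, because patch distances are informative everywhere.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `patch_sizes` | 3, 5 | voxels | two scales: fine boundaries + broader context; mixed by `alpha` |
| `alpha` | 0.5 | — | no value is canonical; equal weighting, exposed as a knob |
| `search_radius` | 4 | voxels | 9³ window; justified by affine pre-alignment |
| `annf_k` | 8 | matches/voxel/scale | quality/cost balance of the accelerated path |
| `annf_iterations` | 4 | — | best distances plateau within a few sweeps |
| `h_epsilon` | 1e-6 | intensity² | stabilizer for $h^2 = D_{\min}+\varepsilon$ |

## Systematic-error correction

Fusion averages away random errors but not systematic ones; those are
learnable. The corrector (`pec_train()` / `pec_apply()`) maps, for voxels
within 2 voxels of a structure's automatic contour, a 112-feature vector —
3³ fully sampled and 7³ subsampled (offsets −3/0/+3) patches of the
intensity image and of the binary automatic segmentation, one
contour-distance-map value, and the three template-space world coordinates
(27+27+27+27+1+3 = 112) — to the 3³ binary membership patch of the structure
in the manual labels. The learner is an ensemble of ten 112×83×55×27
multilayer perceptrons (tanh hidden layers, sigmoid outputs, binary
cross-entropy, Adam), trained with a boosting scheme: each network sees a
fresh sample drawn with per-sample selection weights, and after each network
the weights of samples the running ensemble misclassifies (any of the 27
thresholded outputs wrong) are multiplied by $1+\beta$ ($\beta = 2$) and
renormalized. At application time overlapping patch predictions are
averaged per voxel and thresholded at 0.5; voxels pushed out of the
structure receive the runner-up fusion label when probability maps are
available, otherwise the nearest non-structure label.

Open points resolved as design choices: the 27-output head cannot one-hot a
full label set, so correctors are one-vs-rest per structure (the only
reading consistent with the topology); activation functions, epochs, loss,
the 2-voxel training band, $\beta$, and the overlap-averaging rule are
package choices, all exposed as arguments. Correction is local by
construction — only the contour band can change, which the tests assert.

## The phantom test bed

`make_phantom()` builds a brain-like nested geometry (ICC ellipsoid, CSF
shell, cortical ribbon over a WM core, two subcortical blobs per hemisphere,
cerebellum with GM/WM, brainstem cylinder), split at the midplane into
hemisphere-specific structures with flip pairs, with piecewise-constant
tissue intensities plus Gaussian noise. Defaults: 48³ grid, noise SD 2.5
(5% of the 50-unit cGM–cWM contrast), deformation amplitude 2 voxels.
WM lesions are spheres placed entirely inside cerebral WM with intensity
near the cGM mean — the classic misclassification trap.

`make_library()` warps the base anatomy by smooth random displacement
fields built as the **curl of a Gaussian-filtered random vector potential**.
The curl makes the field divergence-free, i.e. volume-preserving to first
order: plain smoothed noise at any smoothness carries enough divergence to
inflate or deflate small structures by far more than the 10–20% volume
variability real affine-registered cohorts show, which is also why the
smallest phantom structures are sized at radius 0.085 × grid — below that,
nearest-neighbor label warping alone perturbs volumes beyond that range.
Labels are warped nearest-neighbor (crisp labels), intensities trilinearly,
with per-member global intensity jitter (±5%) and fresh noise.

What the phantoms do **not** emulate: cortical folding, MR texture and
partial-volume gradients, Rician noise (Gaussian is adequate at phantom SNR
and simpler to reason about), non-linear registration residuals beyond the
smooth field, and realistic lesion spatial priors (lesions are merely
WM-restricted). Passing tests therefore demonstrate correctness of the
machinery and the direction of its behaviors (e.g. the corrector improves
every corrupted case) — not clinical-grade accuracy on real MRI.

## Numerical choices and degenerate inputs

* Voxel indexing is 0-based in the compiled kernels, 1-based at the R
  surface; patches and windows use half-open clamped index ranges; patches
  crossing the grid border are filled by edge replication, and search
  windows are clamped.
* Argmax ties break to the lowest label id — reproducible and
  scheme-independent. Inside the pipeline the background class is excluded
  from the argmax: the ICC mask already decides what is brain, so every
  intracranial voxel takes its best structure label, which also makes the
  tissue-scale volumes an exact integer partition of the ICC volume.
* Dice for a label absent from both volumes is reported `NA`, not 0, so
  averages run over present labels only.
* The left-right flip axis is the first voxel axis (template x); flipping
  twice is the identity, which is tested.
* Interface curation uses 6-connectivity; relabeled voxels take the nearest
  structure of the destination set (ties to the lowest id); partial-volume
  maps are regularized by non-local means *before* relabeling.
* Intensity normalization maps anchor medians bit-exactly (piecewise-linear
  with slope-extended end segments) and refuses non-monotone anchors.
* Problem sizes in the test suite: 48³ grids with 10-member libraries for
  the study-scale checks, 32³ with 3–6 members for functional tests, 8³–12³
  for the brute-force oracle comparisons — chosen so the whole suite and the
  acceptance script each run in minutes on one CPU.

## Known limitations

Exhaustive fusion is only feasible on small grids (it is the oracle, not
the product). The corrector is one-vs-rest per structure and is trained on
the phantom's error model when used in the test bed; transferring a trained
corrector to a different segmenter or protocol requires retraining. Native-
space volumes are obtained by scaling with the native-affine determinant
rather than inverse resampling — one interpolation fewer, but no
native-space label map is produced. Cortical thickness is consumed, never
computed; without a supplied thickness map the report simply omits those
columns.
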