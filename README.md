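# densefuse

Multiscale non-local patch-based multi-atlas segmentation of the whole brain,
with systematic-error correction and volumetric reporting — an R package for
researchers who need dense anatomical labeling (structures, tissues, lobes)
of T1-weighted MRI volumes that are already denoised, bias-corrected, and
affinely registered to a common template grid, together with a fully
synthetic phantom test bed for validating every stage.

## The method

**Label fusion.** Given a subject image and a library of `N` co-registered
atlases (intensity volume + expert label volume), every voxel `x_i` inside
the intracranial cavity (ICC) collects votes from all positions `j` in a
search volume `V_i` across all members `s`:

    v(x_i) = argmax_l  Σ_s Σ_{j∈V_i} w(x_i, x_{s,j}) · [y_{s,j} = l]
                       ─────────────────────────────────────────────
                       Σ_s Σ_{j∈V_i} w(x_i, x_{s,j})

with patch-similarity weights

    w(x_i, x_{s,j}) = exp( − ‖P(x_i) − P(x_{s,j})‖² / h² ),

where `‖·‖²` is the mean of squared intensity differences over the patch and
`h² = min D + ε` is estimated per voxel from the minimum patch distance in
its search volume, so the best match always receives the largest weight.

**Acceleration.** The exhaustive sum is quadratic in window volume.
`build_annf()` replaces it with an approximate nearest neighbor field
(PatchMatch-style): per voxel, `k` candidate matches are randomly
initialized (seeded with each member's affinely aligned position), then
improved by propagation from raster-scan neighbors and random search with a
geometrically decaying radius. Matched patches vote labels for every voxel
they cover (patchwise late aggregation). Probability maps are computed at
two patch scales (3³ and 5³) and mixed, `p(l) = α p₁(l) + (1−α) p₂(l)`.
The ICC mask itself is produced by the same two-scale engine run with a
binary library.

**Systematic-error correction (PEC).** A patch-based ensemble corrector
learns a segmenter's reproducible mistakes: for voxels near a structure's
contour, a 112-feature vector (3³ and subsampled 7³ patches of intensity and
of the binary automatic segmentation, a contour-distance value, and the
template-space coordinates) is mapped by a boosted ensemble of ten
112×83×55×27 multilayer perceptrons to the 3³ manual-membership patch;
overlapping predictions are averaged and thresholded at 0.5.

**Reporting.** Structure labels are grouped into eight tissue classes
(CSF, cGM, cWM, sGM, ceGM, ceWM, BS, WML) and cerebrum lobes; the report
lists template- and native-space volumes, percent of ICC, right–left
asymmetry `100·(R−L)/((R+L)/2)`, and per-region cortical thickness when a
thickness map is supplied.

**Phantoms.** `make_phantom()` / `make_library()` generate labeled
brain-like volumes (nested ellipsoids with hemisphere-split structures,
piecewise-constant tissue intensities, Gaussian noise, optional WM lesions
placed in white matter with gray-matter-like intensity) and deformed
libraries warped by divergence-free smooth random displacement fields —
the stand-in for a licensed manually labeled atlas library.

## Worked example

Generate a phantom library, segment the base subject against its deformed
members, and score the result:

```sh
Rscript inst/cli/densefuse.R phantom --out ph --shape 32 --members 3 --seed 4
Rscript inst/cli/densefuse.R run --subject ph/subject-t1.nii.gz \
    --library ph --scheme ph/scheme.csv --out ph/out --seed 9
Rscript inst/cli/densefuse.R dice --a ph/out/structures.nii.gz \
    --b ph/subject-truth.nii.gz
```

which prints

```
<densefuse_result> 16 structures over 9969 ICC voxels
  stages: icc 1.5s, fusion 0.5s, argmax 0.0s, grouping 0.0s, report 0.0s
mean dice: 0.9760041
```

`ph/out/` then holds `structures.nii.gz`, `tissues.nii.gz`, `lobes.nii.gz`,
`icc.nii.gz`, the 4-D probability stack with its label sidecar, `report.csv`
(one row per region at every scale), and `run_log.json` with parameters,
seed, and per-stage timings. The mean Dice of 0.976 says the fused labels
agree with the phantom's ground truth almost voxel-perfectly on this easy
instance; leave-one-out segmentation of a *deformed* member against the
remaining members (the harder, realistic protocol) lands near 0.93 — see
below.

The same workflow in R goes through `make_library()`, `run_pipeline()`, and
`dice()`; see `vignette("densefuse-methods")` for the full tour, including
corrector training with `pec_train()` / `pec_apply()`.

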