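---
title: "Methods: two-slide mask transfer and regional TIL quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-slide mask transfer and regional TIL quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilmask)
```

## The problem

Chromogenic multiplex IHC can visualize at most three antibodies plus a
hematoxylin counterstain on one slide. Quantifying tumor-infiltrating
immune cells (TILs) by subtype therefore takes two serial sections: slide-1
carries Pan-CK (epithelium, Fast Red) and CD45 (all leukocytes, DAB);
slide-2 carries CD4 (DAB), CD8 (purple) and CD68 (Fast Red). The tumor
mask is derived where Pan-CK is — on slide-1 — but the cells of interest
are phenotyped on slide-2, so the mask must be transferred across sections
by image co-registration. Because the two sections are different physical
slices of tissue, the transfer has an error that depends on how far apart
the sections were cut and on the tumor's growth pattern; `tilmask`
implements both the pipeline and the evaluation of that error.

## Stain model

Chromogens absorb light per Beer–Lambert, so concentrations combine
linearly in optical density, `OD_c = -log10(I_c / I_0)` per channel. For
RGB images, each chromogen has a unit-norm OD fingerprint; `tilmask` uses
DAB `[0.268, 0.570, 0.776]`, Fast Red `[0.214, 0.851, 0.478]` and
hematoxylin `[0.490, 0.769, 0.410]` (columns of `brightfield_stains()`),
and `deconvolve()` inverts the per-pixel 3×3 system exactly, clipping
negative concentrations to zero since concentrations are physical. The
`od_transform()` guard adds `eps = 1` intensity unit before the log
(standard practice for 8-bit images); passing `eps = 0` makes the
transform exactly invertible on floating-point renders, which is how the
round-trip tests achieve 1e-9 accuracy.

The purple chromogen used for CD8 has no published RGB fingerprint; the
`VPurple` vector shipped here is a synthetic placeholder (flagged by a
message) and should be replaced with a vector measured from a single-stain
control slide for real data.

For multispectral cubes, `unmix_cube()` solves a per-pixel nonnegative
least-squares problem against per-chromogen reference spectra. With at most
four references the NNLS optimum is found exactly by enumerating support
sets, which vectorizes over all pixels; the generic iterative solver is
used as an independent cross-check in the tests. Cubes carry 31 bands. The
acquisition they emulate is described as spanning 420–700 nm at 5 nm
resolution *and* as producing 31 images per cube; these are mutually
inconsistent (a 5 nm grid over that range has 57 points), so the package
pins the 31-band count and spaces the wavelengths evenly across 420–700 nm.
The shipped reference spectra are synthetic smooth curves peaked at
wavelengths characteristic of each chromogen's color — adequate for
validating the unmixing algebra and for simulation, not for real cubes,
which need spectra measured on the acquiring instrument.

## Tumor mask

`build_tumor_mask()` thresholds the Pan-CK concentration image with Otsu's
criterion over a 256-bin histogram, then applies morphological opening
(disk radius 2 px), removes 8-connected components smaller than 400 px
(100 µm² at 0.5 µm/px) and closes with a disk of radius 5 px to smooth the
boundary. The structuring-element sizes and minimum object area are not
prescribed by the method description this implements; the defaults are
scaled to lymphocyte and gland sizes at 0.5 µm/px and are all
configurable. Components use 8-connectivity throughout, pinned for
reproducibility.

## ROI selection

`density_map()` tiles the slide (default 256 px tiles; the pipeline default
is 128 px for its smaller synthetic fields) and counts segmented nuclei
under the mask per tile in counts/mm². `select_rois()` is deterministic
top-k selection with an optional Chebyshev separation constraint and a
documented (row, col) tie-break; a seeded softmax sampling mode is
available to emulate random selection among high-burden tiles, but the
deterministic mode is the default because reproducibility matters more
than fidelity to a manual selection step.

## Co-registration and mask transfer

`estimate_affine()` maximizes normalized cross-correlation between the two
hematoxylin concentration images over the six affine parameters. NCC is
used rather than intensity difference because staining intensity differs
between slides. Translation is initialized by FFT phase correlation; the
transform is then refined coarse-to-fine over a 3-level image pyramid with
Nelder–Mead. The linear part is parameterized about the image center so
rotation and scale decouple from translation, a small set of rotation
starts at the coarsest level guards against angular local optima, and a
simplex restart at full resolution polishes the solution. If the final NCC
falls below a floor (default 0.2, e.g. featureless crops) the identity is
returned flagged low-confidence, and the pipeline excludes that ROI from
pooled statistics while keeping it in the report. Masks are transferred
with `warp_mask()` by inverse-mapped nearest-neighbor resampling — masks
are sets, so no intensity interpolation. Registration recovers synthetic
transforms with |rotation| ≤ 5°, |shift| ≤ 20 px and scale 0.95–1.05 to
sub-pixel translation error; note that a shifted section images a
different field of view, so mask-overlap checks are made within the common
visible region.

The manual post-registration contour adjustment of the original workflow
is out of scope; an optional user-supplied correction transform
(`pipeline_config(correction = ...)`) can be composed after the estimated
one instead.

## Phenotyping

`segment_nuclei()` smooths the hematoxylin channel (Gaussian, σ = 0.5 px),
thresholds with Otsu, and splits touching nuclei by a distance-transform
watershed, keeping components of 20–400 px². The light smoothing default
preserves the waist between abutting nuclei (σ = 1 merges disks whose
centers are 6 px apart); σ is exposed for noisier material.
`cytoplasmic_ring()` dilates each segmented component by `expand_px` and
subtracts the nucleus, giving the annulus used for marker readout; the
dilation uses the actual component rather than a fitted circle, which
loses nothing for irregular nuclei (the equivalent radius is recorded for
reporting). The default `expand_px = 4` follows the half-the-mean-immune-
nucleus-radius convention at 0.5 µm/px; the exact value used originally is
not printed anywhere, so it is a config parameter.

`classify_cells()` scores each marker's mean concentration over the ring.
With `thresholds = "auto"` the per-marker threshold is Otsu's split of the
population of per-cell means, floored at 0.05 OD: without the floor, a
marker absent from a field would have its noise distribution bisected and
yield spurious positives. A cell takes the marker label maximizing
`mean − threshold` among markers above threshold, otherwise `negative`;
exact ties fall back to a configurable priority order and are logged
(multi-positive cells are not expected with non-overlapping chromogens).
Marker-negative nuclei under the transferred cancer mask are the tumor
reference population (`label_tumor_cells()`).

## Regions and counting

`partition()` defines three regions from the transferred mask: the mask
itself (intra-tumoral), the ring of outside pixels within 7 px of it
(border), and the next ring out to 7 + 50 px (extra-tumoral), using the
Euclidean distance transform, clipped at the image boundary. The source
description prints "7 pixels (3.5 µm)" and "50 pixels (35 µm)"; at
0.5 µm/px the second pair is internally inconsistent (50 px = 25 µm), so
the pixel widths are treated as authoritative and both are parameters.
The border ring lies strictly outside the mask: the intra region is the
mask by definition, and pooled "intra + border" counts
(`intra_plus_border()`) then lose no cells. Cells are assigned to regions
by nucleus centroid.

## Evaluation metrics

`overlap_ratio()` implements `Ov = #pixels(CMSK ∩ GT) / #pixels(GT)`.
This is deliberately *not* Dice or Jaccard — it normalizes by the ground
truth only, so transferred-mask false positives do not lower it; Dice and
Jaccard are provided alongside under their own names. `tumor_count_error()`
implements `TCe = |#cells(CMSK) − #cells(GT)| / #cells(GT)`, zero when the
counts agree and one when no tumor cells fall under the transferred mask.
The statistics layer provides Pearson correlation, Bland–Altman agreement
(mean difference, sd with n−1 denominator, limits of agreement at ±1.96 sd,
one-sided paired t-test with configurable direction; a zero-variance
difference vector yields p ∈ {0, 0.5, 1} by sign convention) and classic
one-way ANOVA with an explicit error on zero within-group variance.

## The synthetic-scene generator

No image data ships with the method, so `scene_spec()` /
`generate_section()` build paired pseudo-serial sections with complete
ground truth. What it emulates:

* **Tumor nests** — solid pattern: 3 large filled blobs (radius 45 ± 8 px),
  boundaries perturbed by a low-order Fourier series; glandular pattern:
  12 small annuli (radius 10 ± 2 px) with 45% hollow lumina. The 3–8×
  size ratio is what makes glands fragile under re-cutting.
* **Cells** — nuclei as disks (tumor ≈ 7 px, immune ≈ 4 px radius at
  0.5 µm/px), placed by dart throwing so nuclei never overlap; hematoxylin
  in every nucleus, marker chromogen in a 3-px cytoplasmic annulus around
  immune nuclei. Default densities: 4000 tumor nuclei/mm² of mask, 300
  immune cells/mm² per marker inside the mask and 800/mm² outside,
  matching the expectation that TILs concentrate peritumorally. Exact
  planted counts per label are available via `n_cells_per_label`.
* **Rendering** — per-pixel Beer–Lambert transmission over the chromogen
  fingerprints, Gaussian noise (default sd 0.02) added in OD space,
  intensities kept floating point until written to disk so that noise-free
  renders invert exactly.
* **Serial sections** — the second section reuses the first's nest
  geometry with center/boundary jitter of sd 0.8 px per unit of 4-µm
  re-cut distance and per-nest survival `exp(-(d/12)·(6/r))`, so small
  glands drop out first; nuclei persist with probability `exp(-d/4)` and
  are replaced by fresh ones of the same label and region class, keeping
  densities stationary while decorrelating distant sections. At distance 0
  the two sections are identical. RNG streams are split per object class,
  so adding immune cells does not move nest boundaries at a fixed seed.

Under these defaults the mean mask overlap across 20 seeds stays above the
glandular value at every distance 1–9 and declines with distance for both
patterns — the qualitative solid-vs-glandular contrast the evaluation is
designed to detect. The perturbation parameters are a stand-in chosen once
on biological plausibility, not calibrated to measured tissue deformation;
absolute overlap values from the generator should not be read as
predictions for real sections. Other things the generator does not model:
chromogen co-localization artifacts, section folds and tears, uneven
staining, out-of-focus blur, and DCIS/normal glands (whose exclusion was a
manual step; the pipeline accepts a user-supplied exclusion mask instead).
Passing tests on these scenes validate the algorithmic contracts — they do
not certify performance on clinical material.

## Problem sizes and determinism

The shipped tests run the full pipeline on 384×384 px fields (0.037 mm² at
0.5 µm/px) with 3 ROIs of 128 px tiles, registration recovery on 20 seeded
192×192 px pairs, and the serial-section study on 20 seeds × 9 distances ×
2 patterns at 256×256 px using the mask-only fast path. These sizes keep a
full run in a few minutes while leaving every contrast comfortably
resolved; all of them scale up through `scene_spec()` unchanged. Every
stochastic step draws from a seed derived from the scene seed, so any
reported number is reproducible bit-for-bit from the provenance block of a
pipeline report.
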