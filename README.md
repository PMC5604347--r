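# tilmask

Regional quantification of tumor-infiltrating immune cells (TILs) from
two-slide chromogenic immunohistochemistry, with explicit evaluation of the
error introduced by transferring the tumor mask between serial sections.

Brightfield multiplex IHC is limited to about three chromogens per slide,
so a practical TIL workup uses two serial sections: slide-1 stained with
Pan-CK (epithelium, Fast Red) + CD45 (leukocytes, DAB) + hematoxylin, and
slide-2 with CD4 (DAB) + CD8 (purple) + CD68 (Fast Red) + hematoxylin.
`tilmask` implements the complete pipeline:

1. **Stain separation** — color deconvolution of RGB images using unit-norm
   OD fingerprints (DAB `[0.268, 0.570, 0.776]`, Fast Red
   `[0.214, 0.851, 0.478]`, hematoxylin `[0.490, 0.769, 0.410]`), and exact
   per-pixel nonnegative least-squares unmixing of 31-band multispectral
   cubes.
2. **Tumor masking** — Otsu threshold of the Pan-CK concentration image,
   morphological opening, small-object removal (8-connected), closing.
3. **ROI selection** — tile-level tumor-nucleus density maps (counts/mm²)
   and deterministic top-k high-density ROI picking.
4. **Co-registration** — affine registration of the two hematoxylin
   channels (phase-correlation init, multi-resolution Nelder–Mead on
   normalized cross-correlation) and nearest-neighbor mask transfer.
5. **Phenotyping** — hematoxylin nuclear segmentation (Otsu +
   distance-transform watershed), cytoplasmic-ring marker readout, and
   per-marker Otsu auto-thresholds; marker-negative nuclei under the mask
   are the tumor-cell reference.
6. **Regional counting** — intra-tumoral / 7-px border ring / 50-px
   extra-tumoral ring (Euclidean distance transform), counts and densities
   per region × label.
7. **Evaluation** — the mask-transfer metrics

   `Ov = #px(CMSK ∩ GT) / #px(GT)`  and  `TCe = |#cells(CMSK) − #cells(GT)| / #cells(GT)`

   (note `Ov` normalizes by ground truth only — it is not Dice/Jaccard,
   which are provided separately), plus Pearson correlation, Bland–Altman
   limits of agreement and one-way ANOVA.

Because no image data are deposited with the method, the package includes a
first-class synthetic-scene generator (`scene_spec()`,
`generate_serial_pair()`, `generate_cube()`) producing paired
pseudo-serial sections — solid or glandular growth pattern, planted nuclei
with known marker labels, Beer–Lambert rendering from the printed
fingerprints, and a section-distance perturbation model — so every stage is
testable against planted ground truth. See the methods vignette
(`vignettes/tilmask-methods.Rmd`) for the model and its limitations.

## Worked example

Run the full two-slide pipeline on a synthetic serial pair cut 2 re-cut
units (8 µm) apart:

```r
library(tilmask)

cfg <- pipeline_config(scene = scene_spec(seed = 1), distance = 2,
                       n_rois = 3, tile_size_px = 128, seed = 1)
rep <- run_two_slide_pipeline(cfg)

for (r in rep$roi_results)
  cat(sprintf("ROI: metric %.3f  Ov %.3f  TCe %g\n",
              r$metric, r$agreement$Ov, r$agreement$TCe))
#> ROI: metric 0.760  Ov 0.973  TCe 0
#> ROI: metric 0.484  Ov 0.984  TCe 0
#> ROI: metric 0.532  Ov 0.860  TCe 0

head(rep$roi_results[[1]]$counts, 6)
#>   region label count   area_mm2 density_per_mm2
#> 1  intra   CD4     1 0.00181825        549.9794
#> 2 border   CD4     0 0.00046400          0.0000
#> 3  extra   CD4     1 0.00176000        568.1818
#> 4  intra  CD68     1 0.00181825        549.9794
#> 5 border  CD68     1 0.00046400       2155.1724
#> 6  extra  CD68     1 0.00176000        568.1818
```

Per ROI, `metric` is the final registration NCC on the hematoxylin
channels, `Ov` the overlap of the transferred mask with the generator's
ground-truth slide-2 mask, and `TCe` the relative tumor-cell count error
under the two masks (0 = identical counts). The counts table gives cells
and densities per region and label; `rep$summary` pools counts across ROIs
and adds intra+border vs extra Pearson correlations per label when at
least three well-registered ROIs are available. At `distance = 0` the
transfer is near-perfect (every `Ov ≥ 0.95`); it degrades with section
distance, and much faster for glandular than for solid growth patterns.

All pixel coordinates in exported tables are 0-based `(row, col)` with
half-open intervals; masks are PNG, tables CSV, reports JSON.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/tilmask.R simulate --seed 1 --pattern glandular --distance 2 --out sim/
Rscript inst/cli/tilmask.R run --seed 1 --distance 0 --rois 3 --out out/
Rscript inst/cli/tilmask.R evaluate --cmsk out/roi01_transferred_mask.png --gt sim/slide2_gt_mask.png
```

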