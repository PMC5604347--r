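Package: tilmask
Title: Two-Slide Chromogenic IHC Quantification of Tumor-Infiltrating Immune Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-slide brightfield immunohistochemistry pipeline
    for regional quantification of tumor-infiltrating immune cells. One slide
    carries an epithelial marker (Pan-CK) plus CD45 and hematoxylin; a second
    serial section carries CD4, CD8 and CD68. The package separates chromogens
    by color deconvolution (RGB) or linear spectral unmixing (31-band cubes),
    builds a tumor mask from the Pan-CK concentration image, transfers it to
    the second slide by affine co-registration of the hematoxylin channels,
    phenotypes immune cells from mean marker concentration in a cytoplasmic
    ring around each nucleus, tallies cells in intra-tumoral, border and
    extra-tumoral regions, and evaluates mask-transfer fidelity with the
    overlap ratio (Ov) and tumor cell count error (TCe) together with
    Pearson, Bland-Altman and one-way ANOVA summaries. A synthetic-scene
    generator produces paired pseudo-serial sections with full ground truth
    (solid and glandular growth patterns) so the whole pipeline is testable
    without clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    pracma,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
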