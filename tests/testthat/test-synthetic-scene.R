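test_that("an empty scene renders uniform white with empty ground truth", {
  spec <- scene_spec(seed = 1, height_px = 64, width_px = 64, n_nests = 0,
                     tumor_nucleus_density = 0, immune_density_intra = 0,
                     immune_density_extra = 0, noise_od_sd = 0)
  sec <- generate_section(spec)
  expect_equal(max(abs(sec$image - 255)), 0)
  expect_equal(nrow(sec$truth$cells), 0)
  expect_false(any(sec$truth$tumor_mask))
})

test_that("same spec and seed give bit-identical scenes", {
  spec <- scene_spec(seed = 42, height_px = 128, width_px = 128)
  a <- generate_section(spec)
  b <- generate_section(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  expect_false(identical(generate_section(scene_spec(seed = 43, height_px = 128,
                                                     width_px = 128))$image, a$image))
})

test_that("planted objects appear in ground truth with the right geometry", {
  spec <- scene_spec(seed = 9, height_px = 256, width_px = 256,
                     growth_pattern = "solid", n_nests = 1,
                     nest_radius_px = c(50, 0),
                     tumor_nucleus_density = 0,
                     n_cells_per_label = c(CD8 = 100),
                     marker_set = "CD8", noise_od_sd = 0)
  sec <- generate_section(spec)
  expect_equal(sum(sec$truth$cells$label == "CD8"), 100)
  expect_equal(nrow(sec$truth$cells), 100)
  area <- sum(sec$truth$tumor_mask)
  expect_lt(abs(area - pi * 50^2) / (pi * 50^2), 0.05)
  # conservation: every ground-truth cell has rendered hematoxylin at its centroid
  hema <- conc_channel(sec$conc, "Hematoxylin")
  at <- cbind(round(sec$truth$cells$row), round(sec$truth$cells$col))
  expect_true(all(hema[at] > 0))
  # all centroids inside bounds
  expect_true(all(sec$truth$cells$row >= 1 & sec$truth$cells$row <= 256))
  expect_true(all(sec$truth$cells$col >= 1 & sec$truth$cells$col <= 256))
})

test_that("noise-free rendering deconvolves back to planted concentrations", {
  spec <- scene_spec(seed = 4, height_px = 128, width_px = 128,
                     marker_set = c("PanCK", "CD45"), noise_od_sd = 0)
  sec <- generate_section(spec)
  od <- od_transform(sec$image, eps = 0)
  M <- brightfield_stains(c("FastRed", "DAB", "Hematoxylin"))
  cm <- deconvolve(od, M)
  chrom <- tilmask:::chromogen_concentrations(sec$conc$conc)
  for (s in c("FastRed", "DAB", "Hematoxylin"))
    expect_lt(max(abs(conc_channel(cm, s) - chrom[, , s])), 1e-6)
})

test_that("serial pairs are identical at distance zero and degrade with distance", {
  spec <- scene_spec(seed = 3, height_px = 192, width_px = 192)
  p0 <- generate_serial_pair(spec, distance = 0, render = FALSE)
  expect_identical(p0$first$truth$tumor_mask, p0$second$truth$tumor_mask)
  expect_equal(overlap_ratio(p0$second$truth$tumor_mask, p0$first$truth$tumor_mask), 1.0)
  expect_error(generate_serial_pair(spec, distance = -1), "nonnegative")
})

test_that("rendered pair at distance zero shares its cell population", {
  spec <- scene_spec(seed = 8, height_px = 128, width_px = 128)
  p <- generate_serial_pair(spec, distance = 0)
  expect_identical(p$first$truth$cells, p$second$truth$cells)
})

test_that("cube composition is linear in the reference spectra", {
  spec <- scene_spec(seed = 5, height_px = 64, width_px = 64, n_nests = 0,
                     tumor_nucleus_density = 0, immune_density_intra = 0,
                     immune_density_extra = 0, noise_od_sd = 0)
  cb <- generate_cube(spec)
  expect_equal(dim(cb$cube)[3], 31L)
  expect_true(all(diff(attr(cb$cube, "wavelengths")) > 0))
  expect_equal(max(abs(cb$cube)), 0)   # empty scene -> all-zero OD

  # compose-then-invert round trip on a populated scene
  spec2 <- scene_spec(seed = 6, height_px = 96, width_px = 96, noise_od_sd = 0,
                      n_cells_per_label = c(CD4 = 10, CD8 = 10, CD68 = 10))
  cb2 <- generate_cube(spec2)
  refs <- reference_spectra(c("DAB", "VPurple", "FastRed", "Hematoxylin"))
  cm <- unmix_cube(cb2$cube, refs)
  chrom <- tilmask:::chromogen_concentrations(cb2$conc$conc)
  for (s in colnames(refs$spectra))
    expect_lt(max(abs(conc_channel(cm, s) - chrom[, , s])), 1e-6)
})

test_that("spec validation rejects degenerate inputs", {
  expect_error(scene_spec(height_px = 0), "positive")
  expect_error(scene_spec(marker_set = character(0)), "empty")
  expect_error(scene_spec(lumen_fraction = 1), "lumen_fraction")
  expect_error(scene_spec(immune_density_intra = -1), "nonnegative")
})
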