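test_that("segmentation handles empty images and recovers planted nuclei", {
  empty <- segment_nuclei(matrix(0, 50, 50))
  expect_equal(nrow(empty), 0L)

  # 25 non-touching disks on a 5x5 grid
  hema <- matrix(0, 150, 150)
  centers <- as.matrix(expand.grid(seq(20, 140, by = 30), seq(20, 140, by = 30)))
  for (i in seq_len(nrow(centers)))
    hema[disk_mask(150, 150, centers[i, ], 4)] <- 0.8
  cells <- segment_nuclei(hema, min_area = 10, max_area = 200)
  expect_equal(nrow(cells), 25L)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((cells$row - centers[i, 1])^2 + (cells$col - centers[i, 2])^2)
    expect_lt(min(d), 1)
  }
  expect_equal(cells$equivalent_radius_px, sqrt(cells$area_px / pi))
})

test_that("watershed splits two overlapping nuclei", {
  hema <- matrix(0, 60, 60)
  hema[disk_mask(60, 60, c(30, 27), 4)] <- 0.8
  hema[disk_mask(60, 60, c(30, 33), 4)] <- 0.8
  cells <- segment_nuclei(hema, min_area = 10, max_area = 200)
  expect_equal(nrow(cells), 2L)
})

test_that("cytoplasmic ring equals the distance-transform annulus", {
  hema <- matrix(0, 40, 40)
  hema[disk_mask(40, 40, c(20, 20), 5)] <- 1
  cells <- segment_nuclei(hema, sigma = 0, threshold = 0.5, min_area = 10, max_area = 200)
  labels <- attr(cells, "labels")

  expect_length(cytoplasmic_ring(labels, cells$id[1], 0), 0)

  ring <- cytoplasmic_ring(labels, cells$id[1], 2)
  nucleus <- which(labels == cells$id[1])
  # brute-force oracle: pixels with 0 < d(p, nucleus) <= 2
  d <- brute_distance_to_mask(labels == cells$id[1])
  oracle <- which(d > 0 & d <= 2)
  expect_setequal(ring, oracle)
  expect_length(intersect(ring, nucleus), 0)
})

test_that("classification assigns labels by ring marker means", {
  # two nuclei; CD8-chromogen ring around the first only
  hema <- matrix(0, 80, 80)
  hema[disk_mask(80, 80, c(25, 25), 4)] <- 0.8
  hema[disk_mask(80, 80, c(55, 55), 4)] <- 0.8
  cd8 <- matrix(0, 80, 80)
  cd8[disk_mask(80, 80, c(25, 25), 8) & !disk_mask(80, 80, c(25, 25), 4)] <- 0.9
  cells <- segment_nuclei(hema, min_area = 10, max_area = 200)
  cmap <- tilmask:::concentration_map(
    array(c(cd8, hema), dim = c(80, 80, 2)), c("VPurple", "Hematoxylin"))
  cls <- classify_cells(cells, cmap, thresholds = c(VPurple = 0.1), expand_px = 4)
  got <- cls$label[order(cls$row)]
  expect_equal(got, c("VPurple", "negative"))

  # all-zero markers -> negative, and auto-threshold on constants errors
  zero <- tilmask:::concentration_map(
    array(c(cd8 * 0, hema), dim = c(80, 80, 2)), c("VPurple", "Hematoxylin"))
  cls0 <- classify_cells(cells, zero, thresholds = c(VPurple = 0.1))
  expect_true(all(cls0$label == "negative"))
  expect_error(classify_cells(cells, zero), "constant")
})

test_that("raising a marker threshold never increases its positive count", {
  spec <- scene_spec(seed = 21, n_nests = 0, height_px = 256, width_px = 256,
                     noise_od_sd = 0.02,
                     n_cells_per_label = c(CD8 = 40, negative = 40))
  cb <- generate_cube(spec)
  cm <- unmix_cube(cb$cube, reference_spectra(c("VPurple", "Hematoxylin")))
  cells <- segment_nuclei(conc_channel(cm, "Hematoxylin"))
  prev <- Inf
  for (thr in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    cls <- classify_cells(cells, cm, markers = "VPurple",
                          thresholds = c(VPurple = thr))
    n_pos <- sum(cls$label == "VPurple")
    expect_lte(n_pos, prev)
    prev <- n_pos
  }
})

test_that("planted phenotypes are recovered from an unmixed cube", {
  spec <- scene_spec(seed = 5, n_nests = 0, noise_od_sd = 0.02,
                     n_cells_per_label = c(CD4 = 50, CD8 = 50, CD68 = 50,
                                           negative = 50))
  cb <- generate_cube(spec)
  cm <- unmix_cube(cb$cube, reference_spectra(c("DAB", "VPurple", "FastRed",
                                                "Hematoxylin")))
  cells <- segment_nuclei(conc_channel(cm, "Hematoxylin"))
  cls <- classify_cells(cells, cm, markers = c("DAB", "VPurple", "FastRed"))
  back <- c(DAB = "CD4", VPurple = "CD8", FastRed = "CD68")
  cls$label <- ifelse(cls$label %in% names(back), back[cls$label], cls$label)
  res <- label_agreement(cls, cb$truth$cells)
  expect_gte(res["matched"], 180)
  expect_gte(res["agreement"], 0.9)
  # label count conservation
  expect_equal(sum(table(cls$label)), nrow(cls))
})

test_that("negative nuclei under the cancer mask become tumor cells", {
  cells <- data.frame(id = 1:3, row = c(10, 10, 30), col = c(10, 30, 30),
                      label = c("negative", "CD8", "negative"))
  mask <- matrix(FALSE, 40, 40); mask[1:20, 1:40] <- TRUE
  out <- label_tumor_cells(cells, mask)
  expect_equal(out$label, c("tumor", "CD8", "negative"))
})
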