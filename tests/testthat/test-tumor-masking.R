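test_that("histogram threshold separates a perfectly bimodal image", {
  x <- matrix(c(rep(0, 500), rep(0.9, 500)), 50, 20)
  thr <- histogram_threshold(x)
  expect_gt(thr, 0)
  expect_lt(thr, 0.9)
  expect_error(histogram_threshold(matrix(1, 5, 5)), "constant")
})

test_that("histogram threshold matches an exhaustive between-class-variance search", {
  set.seed(17)
  x <- c(rnorm(600, 0.2, 0.05), rnorm(400, 0.8, 0.08))
  x <- pmax(x, 0)
  # independent oracle: brute force over all 256 histogram bin boundaries,
  # between-class variance w1*w2*(m1 - m2)^2 computed per class directly
  rng <- range(x)
  bins <- pmin(256, 1 + floor((x - rng[1]) / diff(rng) * 256))
  best_k <- NA; best_v <- -Inf
  for (k in 1:255) {
    lo <- bins[bins <= k]; hi <- bins[bins > k]
    if (!length(lo) || !length(hi)) next
    v <- length(lo) * length(hi) / length(x)^2 * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_k <- k }
  }
  thr <- histogram_threshold(x)
  k_pkg <- ceiling((thr - rng[1]) / diff(rng) * 256)
  # the chosen boundary must attain the brute-force maximum criterion
  # (adjacent empty bins give exact ties in the partition)
  lo <- bins[bins <= k_pkg]; hi <- bins[bins > k_pkg]
  v_pkg <- length(lo) * length(hi) / length(x)^2 * (mean(lo) - mean(hi))^2
  expect_equal(v_pkg, best_v, tolerance = 1e-12)
})

test_that("mask cleanup preserves large objects and removes speckle", {
  img <- matrix(0, 200, 200)
  img[disk_mask(200, 200, c(100, 100), 40)] <- 1
  m <- build_tumor_mask(img, min_object_px = 50, open_radius_px = 2, close_radius_px = 3)
  expect_lt(abs(sum(m) - sum(disk_mask(200, 200, c(100, 100), 40))) /
              sum(disk_mask(200, 200, c(100, 100), 40)), 0.03)

  # speckles only -> empty mask
  sp <- matrix(0, 100, 100)
  sp[cbind(c(10, 50, 90), c(10, 50, 90))] <- 1
  sp[cbind(c(11, 51, 91), c(10, 50, 90))] <- 1
  expect_false(any(build_tumor_mask(sp, min_object_px = 50, open_radius_px = 0,
                                    close_radius_px = 0, threshold = 0.5)))
})

test_that("closing bridges a small gap between blobs", {
  img <- matrix(0, 100, 100)
  img[disk_mask(100, 100, c(50, 35), 12)] <- 1
  img[disk_mask(100, 100, c(50, 63), 12)] <- 1   # 2-px gap between disks
  m <- build_tumor_mask(img, min_object_px = 10, open_radius_px = 0,
                        close_radius_px = 3, threshold = 0.5)
  expect_equal(max(tilmask:::label_components(m)), 1L)
})

test_that("build_tumor_mask is idempotent and monotone in min_object_px", {
  spec <- scene_spec(seed = 12, height_px = 192, width_px = 192,
                     marker_set = c("PanCK", "CD45"), noise_od_sd = 0)
  sec <- generate_section(spec)
  panck <- tilmask:::chromogen_concentrations(sec$conc$conc)[, , "FastRed"]
  m <- build_tumor_mask(panck)
  m2 <- build_tumor_mask(m * 1, threshold = 0.5)
  expect_identical(m, m2)
  for (mo in c(0, 100, 400, 2000)) {
    mm <- build_tumor_mask(panck, min_object_px = mo)
    if (mo == 0) prev <- sum(mm)
    expect_lte(sum(mm), prev)
    prev <- sum(mm)
  }
})

test_that("mask recovers ground truth on noise-free scenes", {
  for (seed in c(2, 9)) {
    spec <- scene_spec(seed = seed, height_px = 256, width_px = 256,
                       marker_set = c("PanCK", "CD45"), noise_od_sd = 0)
    sec <- generate_section(spec)
    cm <- deconvolve(od_transform(sec$image, eps = 0),
                     brightfield_stains(c("FastRed", "DAB", "Hematoxylin")))
    m <- build_tumor_mask(conc_channel(cm, "FastRed"))
    expect_gte(overlap_ratio(m, sec$truth$tumor_mask), 0.95)
  }
})

test_that("8-connected labelling merges diagonal touches", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(tilmask:::label_components(m)), 1L)
  m[5, 5] <- TRUE
  expect_equal(max(tilmask:::label_components(m)), 2L)
})
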