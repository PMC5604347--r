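test_that("optical density transform behaves per Beer-Lambert", {
  img <- array(255, dim = c(2, 2, 3))
  expect_lt(max(abs(od_transform(img))), 2e-3)

  img[1, 1, 1] <- 25.5
  expect_equal(od_transform(img)[1, 1, 1], -log10(26.5 / 255), tolerance = 1e-12)
  expect_equal(od_transform(img)[1, 1, 1], 1.0, tolerance = 0.02)

  # monotone non-increasing in intensity, per channel
  v <- seq(0, 255, by = 5)
  od <- od_transform(array(v, dim = c(length(v), 1, 3)))[, 1, 1]
  expect_true(all(diff(od) < 0))
})

test_that("stain vectors validate norm and collinearity", {
  expect_error(stain_vector("x", c(1, 1, 1)), "unit norm")
  v <- stain_vector("a", c(0.268, 0.570, 0.776))
  expect_error(stain_matrix(list(v, v)), "duplicate")
  v2 <- stain_vector("b", c(0.268, 0.570, 0.776))
  expect_error(stain_matrix(list(v, v2)), "collinear")
})

test_that("deconvolution inverts known mixtures of the printed fingerprints", {
  M <- brightfield_stains(c("DAB", "FastRed", "Hematoxylin"))
  dab <- M[, "DAB"]; hema <- M[, "Hematoxylin"]

  # pure hematoxylin pixel
  od <- array(rep(hema, each = 1), dim = c(1, 1, 3))
  cm <- deconvolve(od, M)
  expect_equal(as.numeric(cm$conc[1, 1, ]), c(0, 0, 1), tolerance = 1e-9,
               ignore_attr = TRUE)

  # all-zero OD
  expect_equal(max(abs(deconvolve(array(0, c(2, 2, 3)), M)$conc)), 0)

  # 0.5 DAB + 0.3 hematoxylin, oracle: independent 3x3 solve
  mix <- 0.5 * dab + 0.3 * hema
  od <- array(mix, dim = c(1, 1, 3))
  oracle <- solve(unclass(M), mix)
  expect_equal(as.numeric(oracle), c(0.5, 0, 0.3), tolerance = 1e-9)
  expect_equal(as.numeric(deconvolve(od, M)$conc[1, 1, ]), c(0.5, 0, 0.3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("deconvolution is linear before clipping", {
  M <- brightfield_stains(c("DAB", "FastRed", "Hematoxylin"))
  set.seed(31)
  od1 <- array(runif(12, 0, 1), c(2, 2, 3))
  od2 <- array(runif(12, 0, 1), c(2, 2, 3))
  lhs <- deconvolve(2 * od1 + 3 * od2, M, clip = FALSE)$conc
  rhs <- 2 * deconvolve(od1, M, clip = FALSE)$conc + 3 * deconvolve(od2, M, clip = FALSE)$conc
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("recompose is the exact inverse of deconvolve on the stain span", {
  M <- brightfield_stains(c("DAB", "FastRed", "Hematoxylin"))
  set.seed(7)
  conc <- array(runif(3 * 8 * 8, 0, 2), c(8, 8, 3))
  cmap <- tilmask:::concentration_map(conc, colnames(M))
  od <- recompose(cmap, M)
  back <- deconvolve(od, M)
  expect_lt(max(abs(back$conc - conc)), 1e-9)
  expect_lt(max(abs(recompose(back, M) - od)), 1e-9)
  expect_equal(max(abs(recompose(tilmask:::concentration_map(conc * 0, colnames(M)), M))), 0)
})

test_that("cube unmixing recovers planted weights", {
  refs <- reference_spectra(c("DAB", "FastRed"))
  S <- refs$spectra
  # pure pixel at weight 2.0
  cube <- array(0, c(1, 2, 31))
  cube[1, 1, ] <- 2.0 * S[, "DAB"]
  cm <- unmix_cube(cube, refs)
  expect_equal(as.numeric(cm$conc[1, 1, ]), c(2, 0), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(as.numeric(cm$conc[1, 2, ]), c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)

  # mixed pixel vs exact normal-equations oracle
  cube[1, 2, ] <- 0.7 * S[, "DAB"] + 0.4 * S[, "FastRed"]
  cm <- unmix_cube(cube, refs)
  oracle <- solve(crossprod(S), crossprod(S, cube[1, 2, ]))
  expect_equal(as.numeric(cm$conc[1, 2, ]), as.numeric(oracle), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(max(cm$residual), 1e-9)

  # identical references must fail
  bad <- refs; bad$spectra <- cbind(S[, 1], S[, 1]); colnames(bad$spectra) <- c("a", "b")
  expect_error(unmix_cube(cube, bad), "ill-posed")
})

test_that("batch NNLS agrees with the reference NNLS solver", {
  refs <- reference_spectra()
  set.seed(123)
  B <- matrix(rnorm(50 * 31, 0, 0.3), 50, 31)
  fast <- tilmask:::nnls_enumerate(refs$spectra, B)
  slow <- t(apply(B, 1, function(b) pracma::lsqnonneg(refs$spectra, b)$x))
  expect_lt(max(abs(fast - slow)), 1e-10)
})
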