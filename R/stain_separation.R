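#' Stain fingerprints and stain matrices
#'
#' Chromogen concentrations combine linearly in optical density (OD), so an
#' RGB brightfield image of a 2- or 3-chromogen stain can be inverted
#' per pixel into single-chromogen concentration images once the unit-norm
#' OD "fingerprint" of each chromogen is known. `stain_vector()` builds one
#' fingerprint; `stain_matrix()` collects two or three of them;
#' `brightfield_stains()` returns the standard fingerprints used for the
#' Pan-CK/CD45/hematoxylin slide: DAB (brown), Fast Red and hematoxylin.
#'
#' The purple chromogen used for CD8 on triplex slides has no standard
#' published RGB fingerprint; `"VPurple"` ships a synthetic placeholder and a
#' message notes it should be replaced by a measured vector when available.
#'
#' @param name chromogen name.
#' @param rgb_od numeric length-3 nonnegative OD components `[R, G, B]`;
#'   must be unit Euclidean norm to within 1e-2.
#' @return `stain_vector()`: a named numeric vector of class `stain_vector`;
#'   `stain_matrix()`: a 3 x k matrix (rows R,G,B; columns stains) of class
#'   `stain_matrix`.
#' @examples
#' M <- brightfield_stains()
#' colnames(M)
#' @export
stain_vector <- function(name, rgb_od) {
  if (!is.character(name) || length(name) != 1L) stop("'name' must be a string")
  rgb_od <- as.numeric(rgb_od)
  if (length(rgb_od) != 3L || any(rgb_od < 0)) stop("'rgb_od' must be 3 nonnegative values")
  nrm <- sqrt(sum(rgb_od^2))
  if (abs(nrm - 1) > 1e-2)
    stop(sprintf("stain vector '%s' must be unit norm (got %.4f)", name, nrm))
  structure(rgb_od, names = c("R", "G", "B"), stain = name, class = "stain_vector")
}

# RGB OD fingerprints for the standard brightfield chromogens.
.FINGERPRINTS <- list(
  DAB         = c(0.268, 0.570, 0.776),
  FastRed     = c(0.214, 0.851, 0.478),
  Hematoxylin = c(0.490, 0.769, 0.410),
  # synthetic placeholder: no published fingerprint for the purple chromogen
  VPurple     = c(0.620, 0.712, 0.330)
)

#' @rdname stain_vector
#' @param vectors list of `stain_vector` objects (2 or 3).
#' @export
stain_matrix <- function(vectors) {
  if (length(vectors) < 2L || length(vectors) > 3L)
    stop("a stain matrix holds 2 or 3 stain vectors")
  M <- vapply(vectors, as.numeric, numeric(3))
  colnames(M) <- vapply(vectors, function(v) attr(v, "stain"), character(1))
  rownames(M) <- c("R", "G", "B")
  if (anyDuplicated(colnames(M))) stop("duplicate stain names")
  k <- kappa(M, exact = TRUE)
  if (!is.finite(k) || k > 1e6)
    stop(sprintf("stain vectors are collinear (condition number %.3g): %s",
                 k, paste(colnames(M), collapse = ", ")))
  structure(M, class = c("stain_matrix", "matrix"))
}

#' @rdname stain_vector
#' @param names chromogen names to look up among the built-in fingerprints
#'   (`DAB`, `FastRed`, `Hematoxylin`, `VPurple`).
#' @export
brightfield_stains <- function(names = c("FastRed", "DAB", "Hematoxylin")) {
  miss <- setdiff(names, names(.FINGERPRINTS))
  if (length(miss)) stop("unknown chromogen(s): ", paste(miss, collapse = ", "))
  if ("VPurple" %in% names)
    message("VPurple fingerprint is a synthetic placeholder; supply a measured vector if available")
  stain_matrix(lapply(names, function(n) stain_vector(n, .FINGERPRINTS[[n]])))
}

#' Optical density transform
#'
#' Converts 8-bit intensities to optical density per channel:
#' `OD_c = -log10((pixel_c + eps) / i0)`. The additive guard `eps` protects
#' `log(0)` at saturated black; set `eps = 0` for exact Beer-Lambert
#' round trips on floating-point renders that contain no zeros.
#'
#' @param image numeric array, `H x W x 3` (or any array/matrix of
#'   intensities in `[0, i0]`).
#' @param i0 incident (blank-field) intensity, default 255.
#' @param eps log guard added to every pixel, default 1 intensity unit.
#' @return array of the same shape holding OD values.
#' @export
od_transform <- function(image, i0 = 255, eps = 1) {
  stopifnot_scalar(i0, "i0")
  if (i0 <= 0) stop("'i0' must be positive")
  -log10((image + eps) / i0)
}

# Inverse of od_transform with eps = 0: intensity from OD.
od_to_intensity <- function(od, i0 = 255) i0 * 10^(-od)

#' Color deconvolution of an OD image
#'
#' Solves, per pixel, the linear system `OD = S c` where the columns of `S`
#' are the stain fingerprints, yielding one concentration image per stain.
#' For three stains this is the exact matrix inverse; for two it is the
#' least-squares solution. Negative concentrations are clipped to zero by
#' default (concentrations are physical quantities).
#'
#' @param od `H x W x 3` OD array (see [od_transform()]).
#' @param stains a [stain_matrix()].
#' @param clip clip negative solutions to zero (default `TRUE`).
#' @return a `concentration_map`: list with `conc` (`H x W x k` array, one
#'   slice per stain), `stains` (names) and `pixel_size_um` attribute passed
#'   through if present on `od`.
#' @export
deconvolve <- function(od, stains, clip = TRUE) {
  if (length(dim(od)) != 3L || dim(od)[3] != 3L) stop("'od' must be H x W x 3")
  S <- unclass(stains)
  inv <- tryCatch(solve(crossprod(S)) %*% t(S),
                  error = function(e) stop("singular stain matrix: ",
                                           paste(colnames(S), collapse = ", "), call. = FALSE))
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)            # N x 3
  conc <- flat %*% t(inv)                  # N x k
  if (clip) conc[conc < 0] <- 0
  out <- array(conc, dim = c(d[1], d[2], ncol(S)))
  concentration_map(out, colnames(S), attr(od, "pixel_size_um"))
}

concentration_map <- function(conc, stains, pixel_size_um = NULL) {
  dimnames(conc)[[3]] <- stains
  structure(list(conc = conc, stains = stains,
                 pixel_size_um = pixel_size_um %||% NA_real_),
            class = "concentration_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one stain channel from a concentration map
#' @param cmap a `concentration_map`.
#' @param stain stain name.
#' @return `H x W` numeric matrix.
#' @export
conc_channel <- function(cmap, stain) {
  if (!stain %in% cmap$stains) stop("no stain channel '", stain, "'")
  cmap$conc[, , stain]
}

#' Recompose an OD image from concentrations
#'
#' The linear forward model `OD = sum_i conc_i * S_i`; inverse of
#' [deconvolve()] on nonnegative concentrations within the stain span.
#'
#' @param cmap a `concentration_map` (or `H x W x k` array with stain names
#'   in the third dimnames).
#' @param stains a [stain_matrix()] whose column names match the map's stains.
#' @return `H x W x 3` OD array.
#' @export
recompose <- function(cmap, stains) {
  conc <- if (inherits(cmap, "concentration_map")) cmap$conc else cmap
  snames <- dimnames(conc)[[3]]
  S <- unclass(stains)
  if (!setequal(snames, colnames(S)))
    stop("stain names do not match: map has [", paste(snames, collapse = ", "),
         "], matrix has [", paste(colnames(S), collapse = ", "), "]")
  S <- S[, snames, drop = FALSE]
  d <- dim(conc)
  flat <- matrix(conc, ncol = d[3])
  od <- flat %*% t(S)
  array(od, dim = c(d[1], d[2], 3L))
}

#' Reference emission spectra for spectral unmixing
#'
#' Returns unit-normalized 31-band absorbance spectra (420-700 nm in 5 nm
#' steps) for the supported chromogens. Real reference spectra are measured
#' from single-stain control slides; the spectra shipped here are synthetic
#' smooth curves with absorbance peaks at wavelengths characteristic of each
#' chromogen's color, adequate for simulation and for validating the
#' unmixing algebra, not for analyzing real cubes.
#'
#' @param names chromogens: any of `Hematoxylin`, `DAB`, `FastRed`, `VPurple`.
#' @return list with `wavelengths` (length 31) and `spectra` (31 x k matrix,
#'   unit-norm columns).
#' @export
reference_spectra <- function(names = c("Hematoxylin", "DAB", "FastRed", "VPurple")) {
  # 31 bands spanning 420-700 nm (the acquisition description of a 5 nm
  # step would give 57; the 31-image cube count is taken as the contract)
  wl <- seq(420, 700, length.out = 31)
  shapes <- list(
    # center (nm), width (nm), optional secondary bump
    Hematoxylin = function(w) exp(-((w - 600)/45)^2),
    DAB         = function(w) exp(-((w - 460)/60)^2) + 0.55 * exp(-((w - 520)/50)^2),
    FastRed     = function(w) exp(-((w - 515)/35)^2),
    VPurple     = function(w) exp(-((w - 560)/30)^2) + 0.35 * exp(-((w - 440)/35)^2)
  )
  miss <- setdiff(names, names(shapes))
  if (length(miss)) stop("no reference spectrum for: ", paste(miss, collapse = ", "))
  S <- vapply(names, function(n) { s <- shapes[[n]](wl); s / sqrt(sum(s^2)) }, numeric(length(wl)))
  list(wavelengths = wl, spectra = S)
}

# Exact batch NNLS for few references by support-set enumeration: for every
# nonempty column subset, take the unconstrained LS solution on that support;
# among the feasible (all-nonnegative) candidates the one with the smallest
# residual is the NNLS optimum. O(2^k) solves, all vectorized over pixels.
nnls_enumerate <- function(S, B) {
  k <- ncol(S); n <- nrow(B)
  best_res <- rowSums(B^2)                 # empty-support residual
  best_x <- matrix(0, n, k)
  subsets <- lapply(seq_len(2^k - 1L), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0))
  for (J in subsets) {
    SJ <- S[, J, drop = FALSE]
    XJ <- B %*% SJ %*% solve(crossprod(SJ))          # n x |J|
    feas <- rowSums(XJ < -1e-12) == 0
    if (!any(feas)) next
    res <- rowSums((B[feas, , drop = FALSE] - XJ[feas, , drop = FALSE] %*% t(SJ))^2)
    idx <- which(feas)
    better <- res < best_res[idx] - 1e-15
    upd <- idx[better]
    if (length(upd)) {
      best_res[upd] <- res[better]
      best_x[upd, ] <- 0
      best_x[upd, J] <- XJ[feas, , drop = FALSE][better, , drop = FALSE]
    }
  }
  best_x
}

#' Linear spectral unmixing of a multiband cube
#'
#' Per-pixel nonnegative least squares of the 31-band OD spectrum against
#' the reference spectra. The unconstrained least-squares solution is used
#' wherever it is already nonnegative; pixels with any negative coordinate
#' are re-solved with NNLS ([pracma::lsqnonneg()]).
#'
#' @param cube `H x W x 31` OD array (see [generate_cube()]); a
#'   `wavelengths` attribute, if present, is checked against the references.
#' @param refs output of [reference_spectra()].
#' @return a `concentration_map` with an extra `residual` element
#'   (`H x W` matrix of per-pixel residual norms).
#' @export
unmix_cube <- function(cube, refs) {
  S <- refs$spectra
  if (ncol(S) < 1L) stop("need at least one reference spectrum")
  if (length(dim(cube)) != 3L || dim(cube)[3] != nrow(S))
    stop("cube band count (", dim(cube)[3], ") does not match reference spectra (", nrow(S), ")")
  wl <- attr(cube, "wavelengths")
  if (!is.null(wl) && !isTRUE(all.equal(wl, refs$wavelengths)))
    stop("cube wavelength grid does not match reference spectra")
  g <- crossprod(S)
  if (kappa(g, exact = TRUE) > 1e10) stop("reference spectra are (near-)identical; unmixing is ill-posed")
  d <- dim(cube)
  flat <- matrix(cube, ncol = d[3])               # N x 31
  conc <- flat %*% S %*% solve(g)                 # unconstrained LS, N x k
  neg <- which(rowSums(conc < -1e-12) > 0)
  if (length(neg)) {
    if (ncol(S) <= 4L) {
      conc[neg, ] <- nnls_enumerate(S, flat[neg, , drop = FALSE])
    } else {
      for (i in neg) conc[i, ] <- pracma::lsqnonneg(S, flat[i, ])$x
    }
  }
  conc[conc < 0] <- 0
  resid <- sqrt(rowSums((flat - conc %*% t(S))^2))
  out <- concentration_map(array(conc, dim = c(d[1], d[2], ncol(S))), colnames(S),
                           attr(cube, "pixel_size_um"))
  out$residual <- matrix(resid, d[1], d[2])
  out
}
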