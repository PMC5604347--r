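#' Affine transforms between slide coordinate frames
#'
#' An `affine_transform` is a 3 x 3 matrix with last row `(0, 0, 1)` mapping
#' homogeneous moving-image pixel coordinates `(row, col, 1)` (1-based) into
#' the fixed-image frame.
#'
#' @param matrix 3 x 3 numeric matrix.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix) {
  m <- unname(as.matrix(matrix))
  if (!all(dim(m) == c(3L, 3L))) stop("affine matrix must be 3 x 3")
  if (max(abs(m[3, ] - c(0, 0, 1))) > 1e-9) stop("last row must be (0, 0, 1)")
  if (abs(det(m[1:2, 1:2])) <= 1e-12) stop("affine transform is singular")
  structure(m, class = c("affine_transform", "matrix"))
}

#' @rdname affine_transform
#' @param rotation_deg rotation angle (degrees, about `center`).
#' @param scale isotropic scale factor.
#' @param translation length-2 `(row, col)` shift in px.
#' @param center rotation/scaling center `(row, col)`; default origin.
#' @export
affine_from_params <- function(rotation_deg = 0, scale = 1,
                               translation = c(0, 0), center = c(0, 0)) {
  th <- rotation_deg * pi / 180
  A <- scale * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  t0 <- center - A %*% center + translation
  affine_transform(rbind(cbind(A, t0), c(0, 0, 1)))
}

#' @rdname affine_transform
#' @param t an `affine_transform`.
#' @export
affine_invert <- function(t) affine_transform(solve(unclass(t)))

#' @rdname affine_transform
#' @param t2,t1 transforms; the result applies `t1` first.
#' @export
affine_compose <- function(t2, t1) affine_transform(unclass(t2) %*% unclass(t1))

# Sample `img` at fixed-frame coordinates mapped back through t^{-1}.
# interp: "bilinear" for intensities, "nearest" for masks. Out of bounds -> fill.
warp_image <- function(img, t, out_shape = dim(img),
                       interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  inv <- solve(unclass(t))
  H <- out_shape[1]; W <- out_shape[2]
  rr <- rep(seq_len(H), W); cc <- rep(seq_len(W), each = H)
  src_r <- inv[1, 1] * rr + inv[1, 2] * cc + inv[1, 3]
  src_c <- inv[2, 1] * rr + inv[2, 2] * cc + inv[2, 3]
  out <- rep(fill, H * W)
  if (interp == "nearest") {
    ri <- round(src_r); ci <- round(src_c)
    ok <- ri >= 1 & ri <= nrow(img) & ci >= 1 & ci <= ncol(img)
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(src_r); c0 <- floor(src_c)
    ok <- r0 >= 1 & r0 + 1 <= nrow(img) & c0 >= 1 & c0 + 1 <= ncol(img)
    fr <- src_r[ok] - r0[ok]; fc <- src_c[ok] - c0[ok]
    i00 <- img[cbind(r0[ok], c0[ok])];     i01 <- img[cbind(r0[ok], c0[ok] + 1)]
    i10 <- img[cbind(r0[ok] + 1, c0[ok])]; i11 <- img[cbind(r0[ok] + 1, c0[ok] + 1)]
    out[ok] <- i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
               i01 * (1 - fr) * fc + i11 * fr * fc
  }
  matrix(out, H, W)
}

#' Transfer a binary mask through an affine transform
#'
#' Inverse-mapped nearest-neighbor resampling into the fixed frame;
#' out-of-bounds pixels become `FALSE`. Masks are sets, so no intensity
#' interpolation is performed.
#'
#' @param mask logical matrix (moving frame).
#' @param t an [affine_transform()] mapping moving to fixed coordinates.
#' @param out_shape output `(H, W)`; default the mask's own shape.
#' @return logical matrix in the fixed frame.
#' @export
warp_mask <- function(mask, t, out_shape = dim(mask)) {
  warp_image(mask * 1, t, out_shape, interp = "nearest", fill = 0) > 0.5
}

# Normalized cross-correlation over pixels valid in both images.
ncc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

# 2x block-average downscale (pads odd edges by truncation).
downscale2 <- function(img) {
  H <- 2L * (nrow(img) %/% 2L); W <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(H), seq_len(W)]
  0.25 * (img[seq(1, H, 2), seq(1, W, 2)] + img[seq(2, H, 2), seq(1, W, 2)] +
          img[seq(1, H, 2), seq(2, W, 2)] + img[seq(2, H, 2), seq(2, W, 2)])
}

# Integer translation estimate by phase correlation (FFT cross-power peak).
phase_correlation <- function(fixed, moving) {
  H <- min(nrow(fixed), nrow(moving)); W <- min(ncol(fixed), ncol(moving))
  f <- stats::fft(fixed[seq_len(H), seq_len(W)])
  g <- stats::fft(moving[seq_len(H), seq_len(W)])
  cp <- f * Conj(g)
  mag <- Mod(cp); mag[mag < 1e-12] <- 1e-12
  corr <- Re(stats::fft(cp / mag, inverse = TRUE))
  idx <- which.max(corr)
  dr <- (idx - 1L) %% H
  dc <- (idx - 1L) %/% H
  if (dr > H / 2) dr <- dr - H
  if (dc > W / 2) dc <- dc - W
  c(dr, dc)
}

#' Estimate the slide-1 to slide-2 affine transform
#'
#' Registers the moving hematoxylin image onto the fixed one by maximizing
#' normalized cross-correlation (NCC) over the 6 affine parameters.
#' Translation is initialized by phase correlation; the full transform is
#' then refined with Nelder-Mead over a multi-resolution pyramid
#' (coarse to fine). If the final NCC falls below `metric_floor` the
#' identity transform is returned with a warning and the result is flagged
#' low-confidence.
#'
#' @param fixed_hema,moving_hema `H x W` hematoxylin concentration images.
#' @param pyramid_levels number of pyramid levels (default 3).
#' @param max_iter Nelder-Mead iteration cap per level.
#' @param metric_floor minimum acceptable final NCC (default 0.2).
#' @return an [affine_transform()] with attributes `metric` (final NCC) and
#'   `low_confidence` (logical).
#' @export
estimate_affine <- function(fixed_hema, moving_hema, pyramid_levels = 3L,
                            max_iter = 300L, metric_floor = 0.2) {
  if (!length(fixed_hema) || !length(moving_hema)) stop("images must be nonempty")
  # pyramids, level 1 = full resolution
  pf <- list(fixed_hema); pm <- list(moving_hema)
  for (l in seq_len(pyramid_levels - 1L)) {
    if (min(dim(pf[[l]])) < 32L) break
    pf[[l + 1L]] <- downscale2(pf[[l]]); pm[[l + 1L]] <- downscale2(pm[[l]])
  }
  L <- length(pf)
  sh <- phase_correlation(pf[[L]], pm[[L]])
  # params: (a11-1, a12, a21, a22-1, t_row, t_col); the linear part acts
  # about the image center so rotation/scale decouple from translation
  par <- c(0, 0, 0, 0, sh[1], sh[2])
  matrix_from_par <- function(p, ctr) {
    A <- rbind(c(1 + p[1], p[2]), c(p[3], 1 + p[4]))
    rbind(cbind(A, ctr - A %*% ctr + p[5:6]), c(0, 0, 1))
  }
  for (l in rev(seq_len(L))) {
    fx <- pf[[l]]; mv <- pm[[l]]
    ctr <- dim(fx) / 2
    objective <- function(p) {
      m <- matrix_from_par(p, ctr)
      if (abs(det(m[1:2, 1:2])) < 1e-6) return(2)
      w <- warp_image(mv, structure(m, class = c("affine_transform", "matrix")),
                      out_shape = dim(fx))
      -ncc(fx, w)
    }
    ctl <- list(maxit = max_iter, reltol = 1e-9,
                parscale = c(0.02, 0.02, 0.02, 0.02, 2, 2))
    if (l == L) {
      # multi-start over initial rotations at the coarsest level: phase
      # correlation only initializes translation, and NCC is multi-modal in
      # angle once nests rotate past their own width
      starts <- lapply(c(-6, -3, 0, 3, 6) * pi / 180, function(th)
        c(cos(th) - 1, -sin(th), sin(th), cos(th) - 1, par[5], par[6]))
      vals <- vapply(starts, objective, numeric(1))
      par <- starts[[which.min(vals)]]
    }
    opt <- stats::optim(par, objective, method = "Nelder-Mead", control = ctl)
    if (l == 1L) {  # restart re-initializes the simplex and polishes
      ctl$parscale <- ctl$parscale / 4
      opt <- stats::optim(opt$par, objective, method = "Nelder-Mead", control = ctl)
    }
    par <- opt$par
    if (l > 1L) par[5:6] <- par[5:6] * 2   # translations scale with resolution
  }
  m <- matrix_from_par(par, dim(fixed_hema) / 2)
  metric <- -opt$value
  if (metric < metric_floor) {
    warning(sprintf("registration metric %.3f below floor %.3f; returning identity",
                    metric, metric_floor))
    t <- affine_transform(diag(3))
    attr(t, "metric") <- metric; attr(t, "low_confidence") <- TRUE
    return(t)
  }
  t <- affine_transform(m)
  attr(t, "metric") <- metric; attr(t, "low_confidence") <- FALSE
  t
}
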