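#' Automated histogram threshold (Otsu)
#'
#' Threshold maximizing the between-class variance over a 256-bin histogram
#' of the input values — the automated histogram thresholding step used to
#' binarize the Pan-CK concentration image.
#'
#' @param channel nonnegative numeric matrix or vector with at least two
#'   distinct values.
#' @param levels number of histogram bins (default 256).
#' @return scalar threshold on the scale of `channel`.
#' @export
histogram_threshold <- function(channel, levels = 256L) {
  x <- as.numeric(channel)
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("cannot threshold a constant image")
  h <- tabulate(pmin(levels, 1L + floor((x - rng[1]) / diff(rng) * levels)), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)          # first bin index maximizing criterion
  rng[1] + k / levels * diff(rng)  # upper edge of bin k
}

#' Build the cancer-cell mask from a Pan-CK concentration image
#'
#' Otsu threshold, morphological opening (disk), removal of small connected
#' components (8-connectivity), then morphological closing to smoothen the
#' mask boundary.
#'
#' @param panck `H x W` nonnegative Pan-CK concentration matrix.
#' @param min_object_px minimum connected-component area kept, in px
#'   (default 400 = 100 um^2 at 0.5 um/px).
#' @param open_radius_px,close_radius_px disk radii for opening / closing.
#' @param threshold numeric threshold, or `"auto"` for [histogram_threshold()].
#' @return logical `H x W` matrix (the binary mask).
#' @export
build_tumor_mask <- function(panck, min_object_px = 400L, open_radius_px = 2L,
                             close_radius_px = 5L, threshold = "auto") {
  if (any(c(min_object_px, open_radius_px, close_radius_px) < 0))
    stop("morphology parameters must be nonnegative")
  thr <- if (identical(threshold, "auto")) histogram_threshold(panck) else threshold
  m <- panck > thr
  if (open_radius_px > 0)
    m <- EBImage::opening(m * 1, EBImage::makeBrush(2L * open_radius_px + 1L, "disc")) > 0.5
  if (min_object_px > 0 && any(m)) {
    lab <- label_components(m)
    keep <- which(tabulate(lab[lab > 0L]) >= min_object_px)
    m <- matrix(lab %in% keep, nrow = nrow(m))
  }
  if (close_radius_px > 0)
    m <- EBImage::closing(m * 1, EBImage::makeBrush(2L * close_radius_px + 1L, "disc")) > 0.5
  m
}
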