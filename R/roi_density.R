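#' Tile-level tumor cell density map
#'
#' Tiles the image with square tiles and counts nucleus centroids that fall
#' on mask-true pixels in each tile, expressed as counts per mm^2 of tile
#' area. Tiles at the right/bottom edge may be partial; their density uses
#' the full tile area, matching a fixed-tile acquisition grid.
#'
#' @param nuclei_centroids two-column matrix or data.frame of `(row, col)`
#'   centroid positions (1-based pixel coordinates).
#' @param mask logical tumor mask (provides the grid extent).
#' @param tile_size_px tile side in px (default 256).
#' @param pixel_size_um physical pixel size.
#' @return object of class `density_map`: list with `grid` (R x C matrix of
#'   counts/mm^2), `counts` (raw per-tile counts), `tile_size_px`,
#'   `pixel_size_um`.
#' @export
density_map <- function(nuclei_centroids, mask, tile_size_px = 256L,
                        pixel_size_um = 0.5) {
  if (tile_size_px < 1) stop("'tile_size_px' must be >= 1")
  H <- nrow(mask); W <- ncol(mask)
  nr <- ceiling(H / tile_size_px); nc <- ceiling(W / tile_size_px)
  counts <- matrix(0L, nr, nc)
  pts <- as.matrix(nuclei_centroids)[, 1:2, drop = FALSE]
  if (nrow(pts)) {
    ri <- round(pts[, 1]); ci <- round(pts[, 2])
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    ri <- ri[ok]; ci <- ci[ok]
    under <- mask[cbind(ri, ci)]
    ri <- ri[under]; ci <- ci[under]
    if (length(ri)) {
      tr <- 1L + (ri - 1L) %/% tile_size_px
      tc <- 1L + (ci - 1L) %/% tile_size_px
      for (i in seq_along(tr)) counts[tr[i], tc[i]] <- counts[tr[i], tc[i]] + 1L
    }
  }
  tile_area_mm2 <- tile_size_px^2 * px_area_mm2(pixel_size_um)
  structure(list(grid = counts / tile_area_mm2, counts = counts,
                 tile_size_px = as.integer(tile_size_px),
                 pixel_size_um = pixel_size_um,
                 image_dim = c(H, W)),
            class = "density_map")
}

#' Select high-density regions of interest
#'
#' Greedy top-k selection of tiles by descending density, skipping tiles
#' within `min_separation_tiles` (Chebyshev distance) of an already chosen
#' tile. Exact ties are broken by (row, col) order, or sampled uniformly
#' among tied tiles when `jitter_ties = TRUE` (seeded). A softmax sampling
#' mode (`mode = "sample"`) draws tiles with probability proportional to
#' `exp(density / temperature)`, emulating random selection among
#' high-burden regions.
#'
#' @param dmap a [density_map()].
#' @param k number of ROIs requested.
#' @param min_separation_tiles minimum Chebyshev tile distance between
#'   selected tiles (0 = no constraint).
#' @param seed RNG seed used by the stochastic modes.
#' @param mode `"top"` (deterministic, default) or `"sample"`.
#' @param jitter_ties sample uniformly among exactly tied tiles.
#' @param temperature softmax temperature for `mode = "sample"`.
#' @return data.frame of class `roi_set` with 1-based `tile_row`, `tile_col`,
#'   0-based pixel `top_left_row`/`top_left_col`, `height_px`, `width_px`,
#'   `density`; fewer than `k` rows (with a warning) if the separation
#'   constraint cannot be met.
#' @export
select_rois <- function(dmap, k, min_separation_tiles = 0L, seed = 1L,
                        mode = c("top", "sample"), jitter_ties = FALSE,
                        temperature = NULL) {
  mode <- match.arg(mode)
  g <- dmap$grid
  if (k < 1 || k > length(g)) stop("'k' must be between 1 and the number of tiles")
  ord <- order(-as.vector(g),
               rep(seq_len(nrow(g)), ncol(g)),
               rep(seq_len(ncol(g)), each = nrow(g)))
  if (jitter_ties || mode == "sample") {
    ord <- with_seed(seed, {
      if (mode == "sample") {
        tau <- temperature %||% max(stats::sd(g), 1e-9)
        w <- exp((as.vector(g) - max(g)) / tau)
        sample(seq_along(g), length(g), prob = w)
      } else {
        # random order within exact-tie groups
        order(-as.vector(g), runif(length(g)))
      }
    })
  }
  chosen <- matrix(integer(0), ncol = 2)
  for (idx in ord) {
    tr <- (idx - 1L) %% nrow(g) + 1L
    tc <- (idx - 1L) %/% nrow(g) + 1L
    if (nrow(chosen) && min_separation_tiles > 0 &&
        any(pmax(abs(chosen[, 1] - tr), abs(chosen[, 2] - tc)) <= min_separation_tiles))
      next
    chosen <- rbind(chosen, c(tr, tc))
    if (nrow(chosen) == k) break
  }
  if (nrow(chosen) < k)
    warning(sprintf("separation constraint allows only %d of %d requested ROIs",
                    nrow(chosen), k))
  ts <- dmap$tile_size_px
  H <- dmap$image_dim[1]; W <- dmap$image_dim[2]
  out <- data.frame(
    tile_row = chosen[, 1], tile_col = chosen[, 2],
    top_left_row = (chosen[, 1] - 1L) * ts,          # 0-based pixel coords
    top_left_col = (chosen[, 2] - 1L) * ts,
    height_px = pmin(ts, H - (chosen[, 1] - 1L) * ts),
    width_px = pmin(ts, W - (chosen[, 2] - 1L) * ts),
    density = g[chosen]
  )
  class(out) <- c("roi_set", "data.frame")
  out
}
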