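#' Intra-tumoral / border / extra-tumoral partition
#'
#' Splits the frame into three regions from the (transferred) tumor mask:
#' the intra-tumoral region is the mask itself; the tumor border is the ring
#' of outside pixels within Euclidean distance `border_px` (default 7 px =
#' 3.5 um at 0.5 um/px) of the mask; the extra-tumoral region is the second
#' ring out to `border_px + extra_px` (default extra width 50 px). Distances
#' come from the Euclidean distance transform and are clipped at the image
#' boundary.
#'
#' @param tumor_mask logical matrix.
#' @param border_px border-ring width in px (default 7).
#' @param extra_px extra-tumoral ring width in px (default 50).
#' @param pixel_size_um physical pixel size, stored for area computations.
#' @return object of class `region_partition`: list of logical masks
#'   `intra`, `border`, `extra` (pairwise disjoint) plus the widths and
#'   pixel size.
#' @export
partition <- function(tumor_mask, border_px = 7L, extra_px = 50L,
                      pixel_size_um = 0.5) {
  if (border_px < 1 || extra_px < 1) stop("ring widths must be >= 1")
  mask <- tumor_mask != 0
  if (!any(mask)) {
    warning("empty tumor mask; all regions empty")
    empty <- matrix(FALSE, nrow(mask), ncol(mask))
    return(structure(list(intra = empty, border = empty, extra = empty,
                          border_px = border_px, extra_px = extra_px,
                          pixel_size_um = pixel_size_um),
                     class = "region_partition"))
  }
  d <- as.matrix(EBImage::distmap((!mask) * 1))   # outside px: distance to mask
  structure(list(intra = mask,
                 border = !mask & d <= border_px,
                 extra = !mask & d > border_px & d <= border_px + extra_px,
                 border_px = border_px, extra_px = extra_px,
                 pixel_size_um = pixel_size_um),
            class = "region_partition")
}

#' Count classified cells per region
#'
#' Region membership is decided by the nucleus centroid. Cells falling
#' outside all three regions are excluded from the tallies and reported in
#' the `excluded` attribute. Densities divide counts by region area in mm^2.
#'
#' @param cells a classified cell table with `row`, `col`, `label`.
#' @param parts a [partition()] result.
#' @return data.frame of class `region_counts` with columns `region`,
#'   `label`, `count`, `area_mm2`, `density_per_mm2`, one row per
#'   region x label present.
#' @export
assign_and_count <- function(cells, parts) {
  H <- nrow(parts$intra); W <- ncol(parts$intra)
  ri <- pmin(pmax(round(cells$row), 1L), H)
  ci <- pmin(pmax(round(cells$col), 1L), W)
  at <- cbind(ri, ci)
  region <- rep(NA_character_, nrow(cells))
  region[parts$extra[at]] <- "extra"
  region[parts$border[at]] <- "border"
  region[parts$intra[at]] <- "intra"
  areas <- c(intra = sum(parts$intra), border = sum(parts$border),
             extra = sum(parts$extra)) * px_area_mm2(parts$pixel_size_um)
  labels <- sort(unique(cells$label))
  grid <- expand.grid(region = c("intra", "border", "extra"), label = labels,
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(rg, lb) sum(region == rg & cells$label == lb, na.rm = TRUE),
                       grid$region, grid$label)
  grid$area_mm2 <- areas[grid$region]
  grid$density_per_mm2 <- ifelse(grid$area_mm2 > 0, grid$count / grid$area_mm2, 0)
  rownames(grid) <- NULL
  class(grid) <- c("region_counts", "data.frame")
  attr(grid, "excluded") <- sum(is.na(region))
  grid
}

#' Intra-tumoral plus border count for one label
#'
#' The pooled "within tumor nest plus at the border" count used as the
#' x-axis variable of the intra/extra correlation analysis.
#'
#' @param counts a [assign_and_count()] table.
#' @param label cell label.
#' @return integer count.
#' @export
intra_plus_border <- function(counts, label) {
  if (!label %in% counts$label) stop("unknown label '", label, "'")
  sum(counts$count[counts$label == label & counts$region %in% c("intra", "border")])
}
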