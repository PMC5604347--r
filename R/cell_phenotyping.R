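#' Segment nuclei on the hematoxylin channel
#'
#' Gaussian smoothing, Otsu threshold, then a distance-transform watershed
#' to split touching nuclei, followed by an area filter. One record per
#' retained component, with centroid and equivalent radius `sqrt(area/pi)`.
#'
#' @param hema `H x W` hematoxylin concentration matrix.
#' @param sigma Gaussian smoothing sd in px (default 0.5).
#' @param min_area,max_area inclusive component-area bounds in px^2
#'   (defaults 20 and 400, sized for nuclei at 0.5 um/px).
#' @param threshold numeric or `"auto"` (Otsu).
#' @return data.frame of class `cell_table` with columns `id`, `row`, `col`
#'   (centroid), `area_px`, `equivalent_radius_px`; the watershed label
#'   image is attached as attribute `"labels"`.
#' @export
segment_nuclei <- function(hema, sigma = 0.5, min_area = 20L, max_area = 400L,
                           threshold = "auto") {
  if (!length(hema)) stop("empty image")
  empty <- data.frame(id = integer(), row = numeric(), col = numeric(),
                      area_px = integer(), equivalent_radius_px = numeric())
  sm <- if (sigma > 0)
    as.matrix(EBImage::gblur(EBImage::Image(hema), sigma = sigma)) else hema
  if (diff(range(sm)) == 0) { attr(empty, "labels") <- matrix(0L, nrow(hema), ncol(hema)); return(empty) }
  thr <- if (identical(threshold, "auto")) histogram_threshold(sm) else threshold
  bin <- sm > thr
  if (!any(bin)) { attr(empty, "labels") <- matrix(0L, nrow(hema), ncol(hema)); return(empty) }
  dm <- EBImage::distmap(bin * 1)
  lab <- EBImage::watershed(dm, tolerance = 1)
  lab <- matrix(as.integer(lab), nrow = nrow(hema))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area & areas <= max_area)
  if (!length(keep)) { attr(empty, "labels") <- matrix(0L, nrow(hema), ncol(hema)); return(empty) }
  relab <- integer(max(lab)); relab[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  lab2[lab > 0L] <- relab[lab[lab > 0L]]
  idx <- which(lab2 > 0L)
  comp <- lab2[idx]
  rows <- (idx - 1L) %% nrow(lab2) + 1L
  cols <- (idx - 1L) %/% nrow(lab2) + 1L
  area <- tabulate(comp)
  out <- data.frame(id = seq_along(keep),
                    row = tapply(rows, comp, mean),
                    col = tapply(cols, comp, mean),
                    area_px = area,
                    equivalent_radius_px = sqrt(area / pi),
                    row.names = NULL)
  class(out) <- c("cell_table", "data.frame")
  attr(out, "labels") <- lab2
  out
}

#' Cytoplasmic ring around a nucleus
#'
#' The segmented nuclear component is expanded by `expand_px` (half the mean
#' immune-nucleus radius by convention) and the nucleus itself subtracted;
#' the inter-contour annulus is the cytoplasmic mask used for marker
#' readout. Pixels are those at Euclidean distance in `(0, expand_px]` from
#' the component.
#'
#' @param labels integer label image (attribute of [segment_nuclei()] output).
#' @param cell_id component id.
#' @param expand_px ring width in px (default 4).
#' @return integer vector of linear pixel indices into the image.
#' @export
cytoplasmic_ring <- function(labels, cell_id, expand_px = 4L) {
  if (expand_px < 0) stop("'expand_px' must be nonnegative")
  if (expand_px == 0) return(integer(0))
  H <- nrow(labels); W <- ncol(labels)
  idx <- which(labels == cell_id)
  if (!length(idx)) stop("no component with id ", cell_id)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  pad <- ceiling(expand_px) + 1L
  r0 <- max(1L, min(rows) - pad); r1 <- min(H, max(rows) + pad)
  c0 <- max(1L, min(cols) - pad); c1 <- min(W, max(cols) + pad)
  comp <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
  comp[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1
  d <- EBImage::distmap(1 - comp)     # distance of outside pixels to component
  sel <- which(d > 0 & d <= expand_px)
  sr <- (sel - 1L) %% nrow(comp) + r0
  sc <- (sel - 1L) %/% nrow(comp) + c0
  as.integer((sc - 1L) * H + sr)
}

#' Classify cells by mean marker concentration in the cytoplasmic ring
#'
#' For each cell the mean concentration of every marker over its ring pixels
#' is computed. With `thresholds = "auto"` each marker's threshold is the
#' Otsu split of the population of per-cell means. A cell is labeled with
#' the marker maximizing `mean - threshold` among markers whose mean exceeds
#' the threshold; otherwise `negative`. Exact ties fall back to
#' `marker_priority` order.
#'
#' @param cells a [segment_nuclei()] table (its `"labels"` attribute is used).
#' @param marker_concs a `concentration_map` holding the marker channels.
#' @param markers marker channel names to score; default all non-hematoxylin
#'   channels of `marker_concs`.
#' @param thresholds `"auto"`, or a named numeric vector per marker.
#' @param expand_px ring width (see [cytoplasmic_ring()]).
#' @param marker_priority tie-break order; default the order of `markers`.
#' @param min_threshold floor applied to auto thresholds (OD units, default
#'   0.05): when a marker is absent from the field, the Otsu split of its
#'   ring means would otherwise bisect pure noise and create spurious
#'   positives.
#' @return the input table with one `mean_<marker>` column per marker and a
#'   `label` column.
#' @export
classify_cells <- function(cells, marker_concs, markers = NULL,
                           thresholds = "auto", expand_px = 4L,
                           marker_priority = NULL, min_threshold = 0.05) {
  labels_img <- attr(cells, "labels")
  if (is.null(labels_img)) stop("'cells' must carry the label image from segment_nuclei()")
  if (is.null(markers)) markers <- setdiff(marker_concs$stains, "Hematoxylin")
  if (!length(markers)) stop("no marker channels to classify on")
  marker_priority <- marker_priority %||% markers
  n <- nrow(cells)
  means <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  rings <- vector("list", n)
  for (i in seq_len(n)) {
    ring <- cytoplasmic_ring(labels_img, cells$id[i], expand_px)
    rings[[i]] <- ring
    for (m in markers) {
      ch <- conc_channel(marker_concs, m)
      means[i, m] <- if (length(ring)) mean(ch[ring]) else 0
    }
  }
  if (identical(thresholds, "auto")) {
    thresholds <- vapply(markers, function(m) {
      v <- means[, m]
      if (length(unique(round(v, 12))) < 2L)
        stop("marker '", m, "' has a constant ring-mean population; supply an explicit threshold")
      max(histogram_threshold(v), min_threshold)
    }, numeric(1))
  } else {
    if (!all(markers %in% names(thresholds)))
      stop("thresholds missing for: ",
           paste(setdiff(markers, names(thresholds)), collapse = ", "))
    thresholds <- thresholds[markers]
  }
  lab <- rep("negative", n)
  for (i in seq_len(n)) {
    excess <- means[i, ] - thresholds
    pos <- which(excess > 0)
    if (length(pos)) {
      best <- pos[excess[pos] == max(excess[pos])]
      if (length(best) > 1L) {
        best <- best[order(match(markers[best], marker_priority))][1]
        message("tie between markers for cell ", cells$id[i], "; using priority order")
      }
      lab[i] <- markers[best[1]]
    }
  }
  out <- cells
  for (m in markers) out[[paste0("mean_", m)]] <- means[, m]
  out$label <- lab
  attr(out, "labels") <- labels_img
  attr(out, "thresholds") <- thresholds
  attr(out, "rings") <- rings
  out
}

#' Label marker-negative nuclei under the cancer mask as tumor cells
#'
#' Nuclei under the (transferred) cancer mask that are positive for no
#' immune marker are the tumor-cell reference population.
#'
#' @param cells a classified [classify_cells()] table.
#' @param mask logical cancer mask.
#' @return the table with `negative` cells under the mask relabeled `tumor`.
#' @export
label_tumor_cells <- function(cells, mask) {
  under <- mask[cbind(pmin(pmax(round(cells$row), 1L), nrow(mask)),
                      pmin(pmax(round(cells$col), 1L), ncol(mask)))]
  cells$label[under & cells$label == "negative"] <- "tumor"
  cells
}
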