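#' Configure the two-slide pipeline
#'
#' Collects every stage parameter for [run_two_slide_pipeline()]. Input is
#' either synthetic (`scene` + `distance`: the generator produces the
#' Pan-CK/CD45 slide and the CD4/CD8/CD68 serial section internally) or
#' file-based (`slide1_rgb` path plus `slide2_cube` multi-page TIFF path).
#' The config round-trips through YAML via [write_pipeline_config()].
#'
#' @param scene a [scene_spec()] for synthetic input, or `NULL`.
#' @param distance re-cut distance between the two synthetic sections.
#' @param slide1_rgb,slide2_cube input file paths (file mode).
#' @param pixel_size_um physical pixel size for file inputs.
#' @param n_rois ROIs to select; `tile_size_px` the density-map tile.
#' @param min_separation_tiles ROI separation constraint.
#' @param mask_params list passed to [build_tumor_mask()].
#' @param seg_params list passed to [segment_nuclei()].
#' @param expand_px cytoplasmic ring width.
#' @param border_px,extra_px region ring widths.
#' @param registration list: `pyramid_levels`, `max_iter`, `metric_floor`.
#' @param correction optional user-supplied [affine_transform()] composed
#'   after the estimated one (replaces interactive mask adjustment).
#' @param output_dir directory for intermediates, or `NULL` to skip writing.
#' @param seed RNG seed for ROI selection.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = NULL, distance = 0L,
                            slide1_rgb = NULL, slide2_cube = NULL,
                            pixel_size_um = 0.5,
                            n_rois = 3L, tile_size_px = 128L,
                            min_separation_tiles = 0L,
                            mask_params = list(),
                            seg_params = list(),
                            expand_px = 4L, border_px = 7L, extra_px = 50L,
                            registration = list(),
                            correction = NULL,
                            output_dir = NULL, seed = 1L) {
  if (is.null(scene) && (is.null(slide1_rgb) || is.null(slide2_cube)))
    stop("provide either a synthetic 'scene' or both input paths")
  structure(list(scene = scene, distance = as.integer(distance),
                 slide1_rgb = slide1_rgb, slide2_cube = slide2_cube,
                 pixel_size_um = pixel_size_um,
                 n_rois = as.integer(n_rois), tile_size_px = as.integer(tile_size_px),
                 min_separation_tiles = as.integer(min_separation_tiles),
                 mask_params = mask_params, seg_params = seg_params,
                 expand_px = as.integer(expand_px),
                 border_px = as.integer(border_px), extra_px = as.integer(extra_px),
                 registration = registration, correction = correction,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

crop_to_roi <- function(img, roi) {
  rows <- (roi$top_left_row + 1L):(roi$top_left_row + roi$height_px)
  cols <- (roi$top_left_col + 1L):(roi$top_left_col + roi$width_px)
  if (length(dim(img)) == 3L) img[rows, cols, , drop = FALSE] else img[rows, cols, drop = FALSE]
}

# Load / generate the two slides, returning concentration channels and any
# ground truth available.
prepare_slides <- function(config) {
  if (!is.null(config$scene)) {
    # Latent immune subtypes (CD4/CD8/CD68) are shared between sections:
    # slide-1 renders them into its CD45 channel, slide-2 into the triplex.
    spec_t <- config$scene
    spec_t$marker_set <- c("CD4", "CD8", "CD68")
    nests1 <- draw_nests(spec_t)
    mask1t <- rasterize_nests(nests1, spec_t$height_px, spec_t$width_px)
    cells1 <- place_cells(spec_t, mask1t, sub_seed(spec_t$seed, 2L))
    nests2 <- perturb_nests(nests1, config$distance,
                            sub_seed(spec_t$seed, 50L + config$distance))
    mask2t <- rasterize_nests(nests2, spec_t$height_px, spec_t$width_px)
    cells2 <- perturb_cells(cells1, mask2t, config$distance,
                            sub_seed(spec_t$seed, 70L + config$distance))
    spec1 <- config$scene
    spec1$marker_set <- c("PanCK", "CD45")
    s1 <- generate_section(spec1, nests = nests1, cells = cells1)
    cube2 <- generate_cube(spec_t, nests = nests2, cells = cells2,
                           cell_seed_stream = 3L)
    stains1 <- brightfield_stains(c("FastRed", "DAB", "Hematoxylin"))
    od1 <- od_transform(s1$image, eps = 0)
    cmap1 <- deconvolve(od1, stains1)
    cmap2 <- unmix_cube(cube2$cube, reference_spectra(c("DAB", "VPurple", "FastRed", "Hematoxylin")))
    list(panck = conc_channel(cmap1, "FastRed"),
         hema1 = conc_channel(cmap1, "Hematoxylin"),
         hema2 = conc_channel(cmap2, "Hematoxylin"),
         markers2 = cmap2,
         marker_names = c(CD4 = "DAB", CD8 = "VPurple", CD68 = "FastRed"),
         gt_mask1 = s1$truth$tumor_mask, gt_mask2 = cube2$truth$tumor_mask,
         gt_cells2 = cube2$truth$cells,
         pixel_size_um = spec1$pixel_size_um)
  } else {
    img1 <- read_rgb_image(config$slide1_rgb, config$pixel_size_um)
    cube2 <- read_cube(config$slide2_cube)
    stains1 <- brightfield_stains(c("FastRed", "DAB", "Hematoxylin"))
    cmap1 <- deconvolve(od_transform(img1), stains1)
    cmap2 <- unmix_cube(cube2, reference_spectra(c("DAB", "VPurple", "FastRed", "Hematoxylin")))
    list(panck = conc_channel(cmap1, "FastRed"),
         hema1 = conc_channel(cmap1, "Hematoxylin"),
         hema2 = conc_channel(cmap2, "Hematoxylin"),
         markers2 = cmap2,
         marker_names = c(CD4 = "DAB", CD8 = "VPurple", CD68 = "FastRed"),
         gt_mask1 = NULL, gt_mask2 = NULL, gt_cells2 = NULL,
         pixel_size_um = config$pixel_size_um)
  }
}

process_roi <- function(roi, slides, mask1, config, use_mask = NULL) {
  reg <- config$registration
  h1 <- crop_to_roi(slides$hema1, roi)
  h2 <- crop_to_roi(slides$hema2, roi)
  m1 <- crop_to_roi(mask1, roi)
  if (is.null(use_mask)) {
    t <- estimate_affine(h2, h1,
                         pyramid_levels = reg$pyramid_levels %||% 3L,
                         max_iter = reg$max_iter %||% 300L,
                         metric_floor = reg$metric_floor %||% 0.2)
    if (!is.null(config$correction)) t <- affine_compose(config$correction, t)
    cmsk <- warp_mask(m1, t, out_shape = dim(h2))
    low_conf <- isTRUE(attr(t, "low_confidence"))
    metric <- attr(t, "metric")
  } else {
    t <- NULL; cmsk <- crop_to_roi(use_mask, roi); low_conf <- FALSE; metric <- NA_real_
  }
  parts <- partition(cmsk, config$border_px, config$extra_px, slides$pixel_size_um)
  seg <- do.call(segment_nuclei, c(list(hema = h2), config$seg_params))
  counts <- NULL; cells <- seg; agreement <- NULL
  if (nrow(seg)) {
    # per-ROI marker channels
    roi_conc <- concentration_map(
      array(vapply(slides$markers2$stains,
                   function(s) crop_to_roi(conc_channel(slides$markers2, s), roi),
                   numeric(roi$height_px * roi$width_px)),
            dim = c(roi$height_px, roi$width_px, length(slides$markers2$stains))),
      slides$markers2$stains, slides$pixel_size_um)
    chrom_of <- slides$marker_names
    cells <- tryCatch(
      classify_cells(seg, roi_conc, markers = unname(chrom_of), expand_px = config$expand_px),
      error = function(e) { seg$label <- "negative"; seg })
    # report marker names, not chromogen names
    back <- setNames(names(chrom_of), chrom_of)
    cells$label <- ifelse(cells$label %in% names(back), back[cells$label], cells$label)
    cells <- label_tumor_cells(cells, cmsk)
    counts <- assign_and_count(cells, parts)
  }
  if (!is.null(slides$gt_mask2)) {
    gt2 <- crop_to_roi(slides$gt_mask2, roi)
    agreement <- if (sum(gt2) > 0) mask_agreement(cmsk, gt2, cells) else NULL
  }
  list(roi = roi, transform = t, metric = metric, low_confidence = low_conf,
       mask = cmsk, partition = parts, cells = cells, counts = counts,
       agreement = agreement)
}

#' Run the two-slide TIL quantification pipeline
#'
#' Executes the full workflow: stain separation of slide-1, tumor mask from
#' Pan-CK, tile density map and ROI selection, per-ROI affine registration
#' of the hematoxylin channels, mask transfer, regional partition, nuclear
#' segmentation and ring-based phenotyping on slide-2, regional counting,
#' and mask-agreement statistics where ground truth is available.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`: `rois` (selected ROI table),
#'   `roi_results` (per-ROI list: counts, mask agreement, registration
#'   metric), `summary` (pooled per-label counts and, with >= 3 ROIs,
#'   intra+border vs extra Pearson correlations), `provenance`.
#' @export
run_two_slide_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  slides <- prepare_slides(config)
  mask1 <- do.call(build_tumor_mask, c(list(panck = slides$panck), config$mask_params))
  nuc1 <- segment_nuclei(slides$hema1)
  dmap <- density_map(nuc1[, c("row", "col")], mask1,
                      tile_size_px = config$tile_size_px,
                      pixel_size_um = slides$pixel_size_um)
  rois <- select_rois(dmap, k = config$n_rois,
                      min_separation_tiles = config$min_separation_tiles,
                      seed = config$seed)
  roi_results <- lapply(seq_len(nrow(rois)), function(i)
    process_roi(rois[i, ], slides, mask1, config))
  report <- build_report(config, slides, mask1, dmap, rois, roi_results)
  if (!is.null(config$output_dir)) write_report(report, slides, mask1, config$output_dir)
  report
}

#' Run the pipeline with a user-supplied ground-truth slide-2 mask
#'
#' Identical counting pipeline, but the provided mask replaces the
#' transferred one (the hand-delineated ground-truth arm of the workflow);
#' used for transferred-vs-ground-truth comparisons.
#'
#' @param config a [pipeline_config()].
#' @param gt_mask logical slide-2 mask; for synthetic scenes defaults to the
#'   generator's ground truth.
#' @return a `pipeline_report`.
#' @export
run_ground_truth_mode <- function(config, gt_mask = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  slides <- prepare_slides(config)
  gt_mask <- gt_mask %||% slides$gt_mask2
  if (is.null(gt_mask)) stop("ground-truth mode needs a slide-2 mask")
  if (!all(dim(gt_mask) == dim(slides$hema2))) stop("ground-truth mask shape mismatch")
  mask1 <- do.call(build_tumor_mask, c(list(panck = slides$panck), config$mask_params))
  nuc1 <- segment_nuclei(slides$hema1)
  dmap <- density_map(nuc1[, c("row", "col")], mask1,
                      tile_size_px = config$tile_size_px,
                      pixel_size_um = slides$pixel_size_um)
  rois <- select_rois(dmap, k = config$n_rois,
                      min_separation_tiles = config$min_separation_tiles,
                      seed = config$seed)
  roi_results <- lapply(seq_len(nrow(rois)), function(i)
    process_roi(rois[i, ], slides, mask1, config, use_mask = gt_mask))
  report <- build_report(config, slides, mask1, dmap, rois, roi_results)
  if (!is.null(config$output_dir)) write_report(report, slides, mask1, config$output_dir)
  report
}

build_report <- function(config, slides, mask1, dmap, rois, roi_results) {
  all_counts <- do.call(rbind, lapply(seq_along(roi_results), function(i) {
    cc <- roi_results[[i]]$counts
    if (is.null(cc)) return(NULL)
    cc$roi <- i; cc
  }))
  summary <- list()
  if (!is.null(all_counts)) {
    pooled <- stats::aggregate(count ~ region + label, all_counts, sum)
    summary$pooled_counts <- pooled
    ok <- which(!vapply(roi_results, function(r) r$low_confidence || is.null(r$counts), logical(1)))
    if (length(ok) >= 3L) {
      labs <- setdiff(unique(all_counts$label), "tumor")
      cors <- vapply(labs, function(lb) {
        xi <- vapply(ok, function(i) {
          cc <- roi_results[[i]]$counts
          if (lb %in% cc$label) intra_plus_border(cc, lb) else 0
        }, numeric(1))
        ye <- vapply(ok, function(i) {
          cc <- roi_results[[i]]$counts
          sum(cc$count[cc$label == lb & cc$region == "extra"])
        }, numeric(1))
        tryCatch(pearson(xi, ye), error = function(e) NA_real_)
      }, numeric(1))
      summary$intra_extra_pearson <- cors
    }
    ags <- Filter(Negate(is.null), lapply(roi_results, `[[`, "agreement"))
    if (length(ags)) {
      summary$mean_Ov <- mean(vapply(ags, `[[`, numeric(1), "Ov"))
      tces <- vapply(ags, `[[`, numeric(1), "TCe")
      summary$median_TCe <- stats::median(tces[!is.na(tces)])
    }
  }
  structure(list(rois = rois, density_map = dmap, roi_results = roi_results,
                 summary = summary,
                 provenance = list(seed = config$seed,
                                   package_version = as.character(utils::packageVersion("tilmask")),
                                   timestamp = NULL,   # kept NULL for reproducible reports
                                   config = config[setdiff(names(config),
                                                           c("scene", "correction", "output_dir"))])),
            class = "pipeline_report")
}

write_report <- function(report, slides, mask1, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mask(mask1, file.path(dir, "slide1_tumor_mask.png"))
  utils::write.csv(report$rois, file.path(dir, "rois.csv"), row.names = FALSE)
  utils::write.csv(data.frame(density = as.vector(report$density_map$grid)),
                   file.path(dir, "density_map.csv"), row.names = FALSE)
  for (i in seq_along(report$roi_results)) {
    r <- report$roi_results[[i]]
    write_mask(r$mask, file.path(dir, sprintf("roi%02d_transferred_mask.png", i)))
    if (!is.null(r$cells) && nrow(r$cells))
      utils::write.csv(as.data.frame(r$cells), file.path(dir, sprintf("roi%02d_cells.csv", i)),
                       row.names = FALSE)
    if (!is.null(r$counts))
      utils::write.csv(as.data.frame(r$counts), file.path(dir, sprintf("roi%02d_counts.csv", i)),
                       row.names = FALSE)
  }
  json <- list(summary = report$summary, provenance = report$provenance,
               agreements = lapply(report$roi_results, function(r)
                 if (is.null(r$agreement)) NULL else unclass(r$agreement)))
  jsonlite::write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(dir)
}
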