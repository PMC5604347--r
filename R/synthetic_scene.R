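#' Specify a synthetic IHC scene
#'
#' Builds the parameter object for the pseudo-serial-section generator. The
#' generator emulates a chromogenic IHC field of view: tumor nests (solid
#' sheets or small hollow glands) on a clear background, hematoxylin-stained
#' nuclei everywhere, an epithelial chromogen across the tumor nests, and an
#' immune-marker chromogen in a cytoplasmic annulus around each immune
#' nucleus. Every generated object is recorded in a ground-truth table so
#' downstream stages (masking, registration, phenotyping, counting) can be
#' validated against planted truth.
#'
#' Densities are in cells per mm^2 and apply per marker label. With the
#' default 0.5 um pixels a 384 x 384 field covers 0.037 mm^2.
#'
#' @param seed integer seed; identical spec + seed gives bit-identical scenes.
#' @param height_px,width_px image size in pixels.
#' @param pixel_size_um physical pixel size (default 0.5 um/px).
#' @param growth_pattern `"solid"` (large filled nests) or `"glandular"`
#'   (small annular glands with hollow lumina).
#' @param n_nests number of tumor nests; default 3 solid / 12 glandular.
#' @param nest_radius_px length-2 `c(mean, sd)` of nest radius in px;
#'   defaults 45 +/- 8 (solid), 10 +/- 2 (glandular).
#' @param lumen_fraction fraction of gland area that is hollow (glandular
#'   only), in `[0, 1)`.
#' @param tumor_nucleus_density tumor nuclei per mm^2 of tumor mask.
#' @param immune_density_intra,immune_density_extra immune cells per mm^2
#'   (per marker label) inside / outside the tumor mask.
#' @param marker_set immune/epithelial markers to render; subset of
#'   `PanCK`, `CD45`, `CD4`, `CD8`, `CD68`.
#' @param n_cells_per_label optional named integer vector of exact planted
#'   cell counts per label (labels from `marker_set` plus `"negative"`);
#'   overrides the density-based placement when given.
#' @param noise_od_sd sd of Gaussian noise added in OD space.
#' @param section_distance default re-cut distance for [generate_serial_pair()],
#'   in units of one 4-um re-cut.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(seed = 1L,
                       height_px = 384L, width_px = 384L,
                       pixel_size_um = 0.5,
                       growth_pattern = c("solid", "glandular"),
                       n_nests = NULL,
                       nest_radius_px = NULL,
                       lumen_fraction = 0.45,
                       tumor_nucleus_density = 4000,
                       immune_density_intra = 300,
                       immune_density_extra = 800,
                       marker_set = c("CD4", "CD8", "CD68"),
                       n_cells_per_label = NULL,
                       noise_od_sd = 0.02,
                       section_distance = 0L) {
  growth_pattern <- match.arg(growth_pattern)
  if (is.null(n_nests)) n_nests <- if (growth_pattern == "solid") 3L else 12L
  if (is.null(nest_radius_px))
    nest_radius_px <- if (growth_pattern == "solid") c(45, 8) else c(10, 2)
  if (height_px < 1 || width_px < 1) stop("image dimensions must be positive")
  if (lumen_fraction < 0 || lumen_fraction >= 1) stop("'lumen_fraction' must be in [0, 1)")
  if (any(c(tumor_nucleus_density, immune_density_intra, immune_density_extra) < 0))
    stop("densities must be nonnegative")
  known <- c("PanCK", "CD45", "CD4", "CD8", "CD68")
  if (length(marker_set) == 0L) stop("'marker_set' must not be empty")
  if (!all(marker_set %in% known))
    stop("unknown markers: ", paste(setdiff(marker_set, known), collapse = ", "))
  if (!is.null(n_cells_per_label)) {
    ok <- c(marker_set, "negative")
    if (is.null(names(n_cells_per_label)) || !all(names(n_cells_per_label) %in% ok))
      stop("'n_cells_per_label' names must be in marker_set or 'negative'")
  }
  if (noise_od_sd < 0) stop("'noise_od_sd' must be nonnegative")
  if (section_distance < 0) stop("'section_distance' must be nonnegative")
  structure(list(seed = as.integer(seed), height_px = as.integer(height_px),
                 width_px = as.integer(width_px), pixel_size_um = pixel_size_um,
                 growth_pattern = growth_pattern, n_nests = as.integer(n_nests),
                 nest_radius_px = nest_radius_px, lumen_fraction = lumen_fraction,
                 tumor_nucleus_density = tumor_nucleus_density,
                 immune_density_intra = immune_density_intra,
                 immune_density_extra = immune_density_extra,
                 marker_set = marker_set, n_cells_per_label = n_cells_per_label,
                 noise_od_sd = noise_od_sd,
                 section_distance = as.integer(section_distance)),
            class = "scene_spec")
}

# Chromogen used to visualize each marker (slide-1: Pan-CK Fast Red +
# CD45 DAB; slide-2 triplex: CD4 DAB, CD8 purple, CD68 Fast Red).
.MARKER_CHROMOGEN <- c(PanCK = "FastRed", CD45 = "DAB",
                       CD4 = "DAB", CD8 = "VPurple", CD68 = "FastRed")

# --- nest geometry ---------------------------------------------------------

# Draw nest parameters: center, base radius, smooth radial perturbation as a
# low-order Fourier series (order 4, coefficient sd 0.06).
draw_nests <- function(spec) {
  with_seed(sub_seed(spec$seed, 1L), {
    n <- spec$n_nests
    if (n == 0L) return(list())
    lapply(seq_len(n), function(i) {
      list(id = i,
           center = c(runif(1, 0.15, 0.85) * spec$height_px,
                      runif(1, 0.15, 0.85) * spec$width_px),
           radius = max(3, rnorm(1, spec$nest_radius_px[1], spec$nest_radius_px[2])),
           fa = rnorm(4, 0, 0.06), fb = rnorm(4, 0, 0.06),
           lumen = if (spec$growth_pattern == "glandular") spec$lumen_fraction else 0)
    })
  })
}

# Rasterize nests to a logical tumor mask (union of nest bodies minus lumina).
rasterize_nests <- function(nests, height, width) {
  solid <- matrix(FALSE, height, width)
  lumen <- matrix(FALSE, height, width)
  for (nest in nests) {
    R <- nest$radius
    rmax <- R * 1.5
    r0 <- max(1L, floor(nest$center[1] - rmax)); r1 <- min(height, ceiling(nest$center[1] + rmax))
    c0 <- max(1L, floor(nest$center[2] - rmax)); c1 <- min(width, ceiling(nest$center[2] + rmax))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    dy <- outer(rr - nest$center[1], rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - nest$center[2])
    rho <- sqrt(dy^2 + dx^2)
    th <- atan2(dx, dy)
    pert <- 1
    for (k in 1:4) pert <- pert + nest$fa[k] * cos(k * th) + nest$fb[k] * sin(k * th)
    rb <- R * pmax(pert, 0.2)
    inside <- rho <= rb
    solid[rr, cc] <- solid[rr, cc] | inside
    if (nest$lumen > 0)
      lumen[rr, cc] <- lumen[rr, cc] | (rho <= sqrt(nest$lumen) * rb)
  }
  solid & !lumen
}

# Perturb nest geometry to emulate a re-cut `distance` sections away:
# boundary/center jitter with sd 0.8 px per unit distance, and per-nest
# survival exp(-(d/tau) * (r_ref/r)) so small glands drop out first.
perturb_nests <- function(nests, distance, seed, tau = 12, r_ref = 6) {
  if (distance == 0 || length(nests) == 0L) return(nests)
  with_seed(seed, {
    out <- list()
    for (nest in nests) {
      if (runif(1) > exp(-(distance / tau) * (r_ref / nest$radius))) next
      nest$center <- nest$center + rnorm(2, 0, 0.8 * distance)
      nest$fa <- nest$fa + rnorm(4, 0, 0.012 * distance)
      nest$fb <- nest$fb + rnorm(4, 0, 0.012 * distance)
      nest$radius <- nest$radius * exp(rnorm(1, 0, 0.01 * distance))
      out[[length(out) + 1L]] <- nest
    }
    out
  })
}

# --- cell placement --------------------------------------------------------

# Dart-throwing placement of non-overlapping nuclei; returns a data.frame.
place_cells <- function(spec, mask, seed) {
  H <- spec$height_px; W <- spec$width_px
  area_px <- px_area_mm2(spec$pixel_size_um)
  intra_area <- sum(mask) * area_px
  extra_area <- sum(!mask) * area_px
  markers <- setdiff(spec$marker_set, "PanCK")   # PanCK marks epithelium, not cells
  want <- list()
  if (!is.null(spec$n_cells_per_label)) {
    for (lab in names(spec$n_cells_per_label))
      want[[length(want) + 1L]] <- list(label = lab, n = spec$n_cells_per_label[[lab]],
                                        region = "any")
  } else {
    n_t <- round(spec$tumor_nucleus_density * intra_area)
    if (n_t > 0) want[[length(want) + 1L]] <- list(label = "tumor", n = n_t, region = "intra")
    for (lab in markers) {
      ni <- round(spec$immune_density_intra * intra_area)
      ne <- round(spec$immune_density_extra * extra_area)
      if (ni > 0) want[[length(want) + 1L]] <- list(label = lab, n = ni, region = "intra")
      if (ne > 0) want[[length(want) + 1L]] <- list(label = lab, n = ne, region = "extra")
    }
  }
  cols <- c("id", "row", "col", "radius_px", "label", "region")
  empty <- data.frame(id = integer(), row = numeric(), col = numeric(),
                      radius_px = numeric(), label = character(), region = character(),
                      stringsAsFactors = FALSE)
  if (length(want) == 0L) return(empty)
  with_seed(seed, {
    rows <- numeric(0); cols_ <- numeric(0); rads <- numeric(0)
    labs <- character(0); regs <- character(0)
    for (w in want) {
      placed <- 0L; tries <- 0L
      radius_mu <- if (w$label == "tumor") 7 else 4
      while (placed < w$n && tries < w$n * 200L) {
        tries <- tries + 1L
        r <- runif(1, 6, H - 5); c <- runif(1, 6, W - 5)
        under <- mask[round(r), round(c)]
        if (w$region == "intra" && !under) next
        if (w$region == "extra" && under) next
        rad <- max(2.5, rnorm(1, radius_mu, 0.4))
        if (length(rows)) {
          d2 <- (rows - r)^2 + (cols_ - c)^2
          if (any(d2 < (rads + rad + 2)^2)) next
        }
        rows <- c(rows, r); cols_ <- c(cols_, c); rads <- c(rads, rad)
        labs <- c(labs, w$label)
        regs <- c(regs, if (under) "intra" else "extra")
        placed <- placed + 1L
      }
      if (placed < w$n)
        warning(sprintf("placed %d of %d requested '%s' cells (field too crowded)",
                        placed, w$n, w$label))
    }
    if (!length(rows)) return(empty)
    data.frame(id = seq_along(rows), row = rows, col = cols_, radius_px = rads,
               label = labs, region = regs, stringsAsFactors = FALSE)
  })
}

# Derive the cell population of a re-cut `distance` units away: each nucleus
# survives with probability exp(-distance/4) (nuclei are ~8 um across, two
# re-cut units), survivors jitter by N(0, 0.3*distance) px, and dropped cells
# are replaced by fresh nuclei of the same label in the same region class so
# per-region densities are preserved.
perturb_cells <- function(cells, mask2, distance, seed) {
  if (distance == 0 || is.null(cells) || nrow(cells) == 0L) return(cells)
  H <- nrow(mask2); W <- ncol(mask2)
  with_seed(seed, {
    keep <- runif(nrow(cells)) < exp(-distance / 4)
    surv <- cells[keep, , drop = FALSE]
    if (nrow(surv)) {
      surv$row <- surv$row + rnorm(nrow(surv), 0, 0.3 * distance)
      surv$col <- surv$col + rnorm(nrow(surv), 0, 0.3 * distance)
      inb <- surv$row >= 4 & surv$row <= H - 3 & surv$col >= 4 & surv$col <= W - 3
      surv <- surv[inb, , drop = FALSE]
      surv$region <- ifelse(mask2[cbind(round(surv$row), round(surv$col))], "intra", "extra")
    }
    dropped <- cells[!keep, , drop = FALSE]
    rows <- surv$row; cols_ <- surv$col; rads <- surv$radius_px
    if (nrow(dropped)) {
      new_rows <- numeric(0); new_cols <- numeric(0); new_rads <- numeric(0)
      new_labs <- character(0); new_regs <- character(0)
      for (i in seq_len(nrow(dropped))) {
        want_intra <- dropped$region[i] == "intra"
        for (try in 1:200) {
          r <- runif(1, 6, H - 5); c <- runif(1, 6, W - 5)
          if (mask2[round(r), round(c)] != want_intra) next
          rad <- dropped$radius_px[i]
          d2 <- (c(rows, new_rows) - r)^2 + (c(cols_, new_cols) - c)^2
          if (length(d2) && any(d2 < (c(rads, new_rads) + rad + 2)^2)) next
          new_rows <- c(new_rows, r); new_cols <- c(new_cols, c); new_rads <- c(new_rads, rad)
          new_labs <- c(new_labs, dropped$label[i])
          new_regs <- c(new_regs, if (want_intra) "intra" else "extra")
          break
        }
      }
      if (length(new_rows))
        surv <- rbind(surv, data.frame(id = 0L, row = new_rows, col = new_cols,
                                       radius_px = new_rads, label = new_labs,
                                       region = new_regs, stringsAsFactors = FALSE))
    }
    if (nrow(surv)) surv$id <- seq_len(nrow(surv))
    rownames(surv) <- NULL
    surv
  })
}

# --- rendering -------------------------------------------------------------

# Stamp a filled disk into matrix `m` (value `v`, max-combined).
stamp_disk <- function(m, r0, c0, radius, v) {
  H <- nrow(m); W <- ncol(m)
  ra <- max(1L, floor(r0 - radius)):min(H, ceiling(r0 + radius))
  ca <- max(1L, floor(c0 - radius)):min(W, ceiling(c0 + radius))
  d2 <- outer((ra - r0)^2, rep(1, length(ca))) + outer(rep(1, length(ra)), (ca - c0)^2)
  sub <- m[ra, ca]
  sub[d2 <= radius^2] <- pmax(sub[d2 <= radius^2], v)
  m[ra, ca] <- sub
  m
}

# Stamp an annulus (inner < d <= outer) around a disk nucleus.
stamp_annulus <- function(m, r0, c0, inner, outer_r, v) {
  H <- nrow(m); W <- ncol(m)
  ra <- max(1L, floor(r0 - outer_r)):min(H, ceiling(r0 + outer_r))
  ca <- max(1L, floor(c0 - outer_r)):min(W, ceiling(c0 + outer_r))
  d2 <- outer((ra - r0)^2, rep(1, length(ca))) + outer(rep(1, length(ra)), (ca - c0)^2)
  sel <- d2 > inner^2 & d2 <= outer_r^2
  sub <- m[ra, ca]
  sub[sel] <- pmax(sub[sel], v)
  m[ra, ca] <- sub
  m
}

# Per-marker (plus hematoxylin) concentration images for a scene.
render_concentrations <- function(spec, mask, cells) {
  H <- spec$height_px; W <- spec$width_px
  chans <- c(spec$marker_set, "Hematoxylin")
  conc <- array(0, dim = c(H, W, length(chans)), dimnames = list(NULL, NULL, chans))
  if ("PanCK" %in% chans) {
    p <- matrix(0, H, W); p[mask] <- 0.5
    conc[, , "PanCK"] <- p
  }
  hema <- matrix(0, H, W)
  if (nrow(cells)) {
    for (i in seq_len(nrow(cells)))
      hema <- stamp_disk(hema, cells$row[i], cells$col[i], cells$radius_px[i], 0.75)
    imm <- cells[!(cells$label %in% c("tumor", "negative")), , drop = FALSE]
    for (i in seq_len(nrow(imm))) {
      lab <- imm$label[i]
      # CD45 marks all leukocytes: on a Pan-CK/CD45 slide, immune cells of
      # any latent subtype are rendered into the CD45 channel
      if (!lab %in% chans && "CD45" %in% chans) lab <- "CD45"
      if (!lab %in% chans) next
      ch <- conc[, , lab]
      ch <- stamp_annulus(ch, imm$row[i], imm$col[i],
                          imm$radius_px[i], imm$radius_px[i] + 3, 0.8)
      conc[, , lab] <- ch
    }
  }
  conc[, , "Hematoxylin"] <- hema
  conc
}

# Sum per-marker concentrations into per-chromogen concentrations.
chromogen_concentrations <- function(conc) {
  chans <- dimnames(conc)[[3]]
  chrom <- vapply(chans, function(ch)
    if (ch == "Hematoxylin") "Hematoxylin" else .MARKER_CHROMOGEN[[ch]], character(1))
  out_names <- unique(chrom)
  out <- array(0, dim = c(dim(conc)[1], dim(conc)[2], length(out_names)),
               dimnames = list(NULL, NULL, out_names))
  for (i in seq_along(chans)) out[, , chrom[i]] <- out[, , chrom[i]] + conc[, , chans[i]]
  out
}

#' Generate one synthetic IHC section
#'
#' Renders the scene described by a [scene_spec()]: the per-pixel RGB image
#' follows Beer-Lambert transmission,
#' `I_c = 255 * 10^(-sum_i conc_i * S_ic)` over the chromogens present, with
#' optional Gaussian noise of sd `noise_od_sd` added in OD space and clipped
#' to `[0, 255]`. Intensities are kept as floating point; quantization to
#' 8 bits happens only when writing to disk.
#'
#' @param spec a [scene_spec()].
#' @param nests optional pre-drawn nest geometry (internal use by
#'   [generate_serial_pair()]).
#' @param cells optional pre-placed cell table (internal use by
#'   [generate_serial_pair()], which derives the second section's cells from
#'   the first's); placed fresh when `NULL`.
#' @param cell_seed_stream RNG stream index for cell placement.
#' @param render if `FALSE`, skip cells and rendering and return only the
#'   ground-truth tumor mask (fast path for mask-overlap simulations).
#' @return list of class `ihc_section`:
#'   `image` (H x W x 3 float intensities, or `NULL` when `render = FALSE`),
#'   `truth` (list: `tumor_mask` logical matrix, `cells` data.frame with
#'   id, row, col, radius_px, label, region),
#'   `conc` (noise-free per-marker `concentration_map`), `spec`.
#' @export
generate_section <- function(spec, nests = NULL, cells = NULL,
                             cell_seed_stream = 2L, render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(nests)) nests <- draw_nests(spec)
  mask <- rasterize_nests(nests, spec$height_px, spec$width_px)
  if (!render) {
    return(structure(list(image = NULL,
                          truth = list(tumor_mask = mask, cells = NULL),
                          conc = NULL, spec = spec), class = "ihc_section"))
  }
  if (is.null(cells))
    cells <- place_cells(spec, mask, sub_seed(spec$seed, cell_seed_stream))
  conc <- render_concentrations(spec, mask, cells)
  chrom <- chromogen_concentrations(conc)
  # Beer-Lambert composition works for any number of chromogens (a 3x3
  # deconvolution of a 4-chromogen render is of course not exact).
  S <- vapply(dimnames(chrom)[[3]], function(n) .FINGERPRINTS[[n]], numeric(3))
  d <- dim(chrom)
  od <- array(matrix(chrom, ncol = d[3]) %*% t(S), dim = c(d[1], d[2], 3L))
  if (spec$noise_od_sd > 0) {
    od <- od + with_seed(sub_seed(spec$seed, cell_seed_stream + 100L),
                         array(rnorm(length(od), 0, spec$noise_od_sd), dim = dim(od)))
  }
  img <- od_to_intensity(od)
  img[img < 0] <- 0; img[img > 255] <- 255
  attr(img, "pixel_size_um") <- spec$pixel_size_um
  structure(list(image = img,
                 truth = list(tumor_mask = mask, cells = cells),
                 conc = concentration_map(conc, dimnames(conc)[[3]], spec$pixel_size_um),
                 spec = spec),
            class = "ihc_section")
}

#' Generate a pseudo-serial section pair
#'
#' The second section reuses the first section's nest geometry, perturbed to
#' emulate the tissue change between re-cuts a given number of 4-um sections
#' apart: nest centers and boundaries jitter with Gaussian sd
#' `0.8 * distance` px, and each nest survives with probability
#' `exp(-(distance/tau) * (r_ref/r))`, so small glands disappear more readily
#' than large solid nests. At `distance = 0` the two sections are identical.
#' Cells persist between sections with probability `exp(-distance/4)` and
#' jitter with the cut distance, so adjacent sections share most of their
#' hematoxylin pattern (which is what makes serial-section co-registration
#' possible) while distant ones share little.
#'
#' @param spec a [scene_spec()].
#' @param distance nonnegative re-cut distance (defaults to
#'   `spec$section_distance`).
#' @param render passed to [generate_section()].
#' @return list with elements `first` and `second`, each an `ihc_section`.
#' @export
generate_serial_pair <- function(spec, distance = spec$section_distance, render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (distance < 0) stop("'distance' must be nonnegative")
  nests1 <- draw_nests(spec)
  nests2 <- perturb_nests(nests1, distance, sub_seed(spec$seed, 50L + distance))
  first <- generate_section(spec, nests = nests1, cell_seed_stream = 2L, render = render)
  cells2 <- if (render)
    perturb_cells(first$truth$cells,
                  rasterize_nests(nests2, spec$height_px, spec$width_px),
                  distance, sub_seed(spec$seed, 70L + distance)) else NULL
  list(first  = first,
       second = generate_section(spec, nests = nests2, cells = cells2,
                                 cell_seed_stream = 3L, render = render))
}

#' Generate a multispectral cube for a scene
#'
#' Composes a 31-band OD cube (420-700 nm, 5 nm steps) linearly from the
#' scene's per-chromogen concentrations and the [reference_spectra()],
#' mirroring multispectral acquisition of the triplex slide.
#'
#' @param spec a [scene_spec()].
#' @param nests,cells,cell_seed_stream as in [generate_section()].
#' @return list: `cube` (H x W x 31 OD array with `wavelengths` attribute),
#'   `truth`, `conc`, `spec` as in [generate_section()].
#' @export
generate_cube <- function(spec, nests = NULL, cells = NULL, cell_seed_stream = 2L) {
  sec <- generate_section(spec, nests = nests, cells = cells,
                          cell_seed_stream = cell_seed_stream)
  chrom <- chromogen_concentrations(sec$conc$conc)
  refs <- reference_spectra(dimnames(chrom)[[3]])
  d <- dim(chrom)
  flat <- matrix(chrom, ncol = d[3])
  cube <- array(flat %*% t(refs$spectra), dim = c(d[1], d[2], 31L))
  if (spec$noise_od_sd > 0) {
    cube <- cube + with_seed(sub_seed(spec$seed, cell_seed_stream + 200L),
                             array(rnorm(length(cube), 0, spec$noise_od_sd), dim = dim(cube)))
    cube[cube < 0] <- 0
  }
  attr(cube, "wavelengths") <- refs$wavelengths
  attr(cube, "pixel_size_um") <- spec$pixel_size_um
  list(cube = cube, truth = sec$truth, conc = sec$conc, spec = spec)
}
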