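# Shared fixtures built in code.

disk_mask <- function(h, w, center, radius) {
  d2 <- outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, `+`)
  d2 <= radius^2
}

# Brute-force Euclidean distance from every pixel to the nearest TRUE pixel.
brute_distance_to_mask <- function(mask) {
  idx <- which(mask)
  mr <- (idx - 1L) %% nrow(mask) + 1L
  mc <- (idx - 1L) %/% nrow(mask) + 1L
  d <- matrix(Inf, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask)))
    for (c in seq_len(ncol(mask)))
      d[r, c] <- sqrt(min((mr - r)^2 + (mc - c)^2))
  d
}

# A smooth deterministic "hematoxylin-like" field with enough texture for
# registration experiments.
texture_field <- function(seed, h = 192, w = 192) {
  spec <- scene_spec(seed = seed, height_px = h, width_px = w,
                     marker_set = c("PanCK", "CD45"), noise_od_sd = 0)
  sec <- generate_section(spec)
  conc_channel(sec$conc, "Hematoxylin")
}

# Match each detected cell to the nearest planted cell within `tol` px and
# return the fraction of matches with agreeing labels.
label_agreement <- function(detected, truth, tol = 3) {
  agree <- 0L; matched <- 0L
  for (i in seq_len(nrow(detected))) {
    d2 <- (truth$row - detected$row[i])^2 + (truth$col - detected$col[i])^2
    j <- which.min(d2)
    if (d2[j] <= tol^2) {
      matched <- matched + 1L
      if (truth$label[j] == detected$label[i]) agree <- agree + 1L
    }
  }
  c(agreement = if (matched) agree / matched else 0, matched = matched)
}

# Deterministic affine-perturbation parameters for registration experiments:
# |rotation| <= 5 deg, |shift| <= 20 px, scale in [0.95, 1.05].
with_seed_params <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed * 1000 + 17)
  list(rot = runif(1, -5, 5),
       scale = runif(1, 0.95, 1.05),
       shift = runif(2, -20, 20))
}

# Overlap of the two ground-truth masks of a serial pair (mask-only render).
pair_overlap <- function(pattern, distance, seed, size = 256) {
  p <- generate_serial_pair(
    scene_spec(seed = seed, growth_pattern = pattern,
               height_px = size, width_px = size),
    distance = distance, render = FALSE)
  overlap_ratio(p$second$truth$tumor_mask, p$first$truth$tumor_mask)
}
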