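#' @importFrom stats rnorm runif setNames
#' @importFrom graphics plot
#' @importFrom utils write.csv read.csv
NULL

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
# All randomness in the package flows through this so that independent stages
# (nest geometry, cell placement, noise) draw from separate streams.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derived sub-seed for an independent stream; keeps values < 2^31.
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 97 + stream * 7919) %% 2147483629
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected; merge
# labels that touch diagonally so connectivity matches the mask contract.
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.numeric(mask != 0), nrow = nrow(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow = nrow(lab))
  if (connectivity == 4 || max(lab) < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]),  as.vector(lab[-nr, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Pixel area in mm^2 for a given pixel size in micrometres.
px_area_mm2 <- function(pixel_size_um) (pixel_size_um^2) * 1e-6
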