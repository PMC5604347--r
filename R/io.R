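#' Image and table I/O
#'
#' Thin wrappers over the `png` and `tiff` readers keeping the package's
#' `H x W x 3` intensity-in-`[0, 255]` convention, plus mask, cube and
#' config serialization. Cubes are written as multi-page 32-bit float TIFF,
#' one page per band in ascending wavelength.
#'
#' @param path file path (`.png`, `.tif`/`.tiff` by extension).
#' @param image `H x W x 3` array of intensities in `[0, 255]`.
#' @param pixel_size_um physical pixel size recorded on read.
#' @return `read_rgb_image()` returns the intensity array with a
#'   `pixel_size_um` attribute.
#' @name image_io
NULL

#' @rdname image_io
#' @export
write_rgb_image <- function(image, path) {
  arr <- pmin(pmax(image / 255, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(arr, path)
  else tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname image_io
#' @export
read_rgb_image <- function(path, pixel_size_um = 0.5) {
  arr <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else tiff::readTIFF(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), dim = c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3]
  out <- arr * 255
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

#' @rdname image_io
#' @param mask logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask)), path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_mask <- function(path) png::readPNG(path) > 0.5

#' @rdname image_io
#' @param cube `H x W x 31` OD array with a `wavelengths` attribute.
#' @export
write_cube <- function(cube, path) {
  pages <- lapply(seq_len(dim(cube)[3]), function(b) cube[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname image_io
#' @export
read_cube <- function(path, wavelengths = seq(420, 700, length.out = 31)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  cube <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  attr(cube, "wavelengths") <- wavelengths
  cube
}

#' @rdname image_io
#' @param stains a `stain_matrix`.
#' @export
write_stain_matrix <- function(stains, path) {
  S <- unclass(stains)
  yaml::write_yaml(setNames(lapply(seq_len(ncol(S)), function(i) as.numeric(S[, i])),
                            colnames(S)), path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_stain_matrix <- function(path) {
  lst <- yaml::read_yaml(path)
  stain_matrix(lapply(names(lst), function(n) stain_vector(n, as.numeric(lst[[n]]))))
}

#' @rdname image_io
#' @param t an `affine_transform`.
#' @export
write_affine <- function(t, path) {
  jsonlite::write_json(list(matrix = as.vector(t(unclass(t)))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname image_io
#' @export
read_affine <- function(path) {
  affine_transform(matrix(unlist(jsonlite::read_json(path)$matrix), 3, 3, byrow = TRUE))
}
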