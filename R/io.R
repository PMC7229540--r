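# Raster input/output.  PNG and TIFF only; both readers return intensities
# in [0, 1].  Color images are collapsed to luma with the Rec. 601 weights.

#' Load a grayscale image from PNG or TIFF
#'
#' 8/16-bit gray or color rasters; color is collapsed to luma
#' (0.299 R + 0.587 G + 0.114 B), alpha is ignored.  Values are scaled to
#' `[0, 1]`.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return a numeric image matrix.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop(sprintf("unsupported format '%s' (use PNG or TIFF): %s",
                           ext, path), call. = FALSE))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] >= 3L) {
      x <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    } else {
      x <- x[, , 1L]             # gray + alpha
    }
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = dim(x)[1L])
  x
}

#' Save a grayscale image as PNG or TIFF
#'
#' Values are clamped to `[0, 1]`.  TIFF output is written at the requested
#' bit depth (default 16); PNG at 8 bits.
#'
#' @param image numeric matrix with values (nominally) in `[0, 1]`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits bits per sample for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path, bits = 16L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix", call. = FALSE)
  x <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(x, path),
         tif = ,
         tiff = tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits)),
         stop(sprintf("unsupported format '%s' (use PNG or TIFF): %s",
                      ext, path), call. = FALSE))
  invisible(path)
}
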