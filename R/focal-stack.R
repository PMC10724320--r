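#' Calibrated multi-focal-plane image stack
#'
#' Container for one epithelial field photographed at several focus
#' levels. Planes are numeric arrays on \[0, 1\], either greyscale
#' (H x W) or RGB (H x W x 3, channel order red, green, blue), all with
#' identical dimensions.
#'
#' @param planes list of image arrays (ordered by focus level).
#' @param um_per_pixel spatial calibration, micrometres per pixel.
#' @return object of class `focal_stack`.
#' @export
focal_stack <- function(planes, um_per_pixel) {
  if (!is.list(planes) || length(planes) < 1)
    stop("`planes` must be a nonempty list of images")
  d1 <- dim(planes[[1]])
  for (p in planes) {
    if (!is.numeric(p) || is.null(dim(p)))
      stop("each plane must be a numeric array")
    if (!identical(dim(p), d1))
      stop("all planes must have identical dimensions")
  }
  if (!is.numeric(um_per_pixel) || um_per_pixel <= 0)
    stop("um_per_pixel must be positive")
  structure(list(planes = planes, um_per_pixel = um_per_pixel),
            class = "focal_stack")
}

#' @export
print.focal_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("Focal stack: %d plane(s), %d x %d%s, %g um/pixel\n",
              length(x$planes), d[1], d[2],
              if (length(d) == 3) " x 3 (RGB)" else " (grey)",
              x$um_per_pixel))
  invisible(x)
}

#' Read a focal stack from a multi-page TIFF
#'
#' @param path TIFF file, one page per focus level.
#' @param um_per_pixel calibration to attach.
#' @return a [focal_stack()].
#' @export
read_stack <- function(path, um_per_pixel) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # drop an alpha channel if present
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3 && dim(p)[3] == 4) p[, , 1:3, drop = FALSE] else p
  })
  focal_stack(pages, um_per_pixel)
}

#' Write a focal stack to a multi-page TIFF
#'
#' @param stack a [focal_stack()].
#' @param path output file.
#' @param bits bits per sample (8 keeps files small; 16 for higher
#'   fidelity).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 8L) {
  stopifnot(inherits(stack, "focal_stack"))
  tiff::writeTIFF(stack$planes, path, bits.per.sample = bits)
  invisible(path)
}
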