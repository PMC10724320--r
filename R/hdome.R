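#' Greyscale reconstruction by dilation
#'
#' Morphological reconstruction of `mask` from `marker` under
#' 8-connectivity: the result is the largest image below `mask` reachable
#' from `marker` by repeated geodesic dilation. Implemented with the
#' fast-hybrid raster/queue algorithm.
#'
#' @param marker numeric matrix, elementwise `<= mask` (values above the
#'   mask are clipped down before reconstruction).
#' @param mask numeric matrix, same dimensions as `marker`.
#' @return numeric matrix of the reconstructed image.
#' @seealso [hdome()]
#' @export
reconstruct_dilate <- function(marker, mask) {
  stopifnot(is.matrix(marker), is.matrix(mask),
            all(dim(marker) == dim(mask)))
  marker <- pmin(marker, mask)
  .reconstruct_dilate_cpp(marker, mask)
}

#' h-dome transform
#'
#' Extracts the image "domes": connected peak regions whose height above
#' their surroundings is at most `h`. Defined as
#' `image - reconstruct_dilate(image - h, image)`; the output is bounded
#' by `[0, h]` and is invariant to adding a constant to the input. Used
#' here to isolate bright vessel ridges after high-pass filtering.
#'
#' @param image numeric matrix (greyscale).
#' @param h positive dome height, in the intensity units of `image`.
#' @return numeric matrix of dome heights, same dimensions as `image`.
#' @examples
#' m <- matrix(0, 16, 16)
#' m[6:10, 6:10] <- 100          # plateau of height 100
#' d <- hdome(m, 30)
#' range(d[6:10, 6:10])          # 30 on the plateau
#' @export
hdome <- function(image, h) {
  stopifnot(is.matrix(image))
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("`h` must be a single positive number")
  image - .reconstruct_dilate_cpp(image - h, image)
}
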