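# Focus stacking: collapse a focal stack into one all-in-focus image by
# per-pixel plane selection on a local sharpness score.

.lap_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)

ebi_filter2 <- function(x, f) {
  as.matrix(EBImage::imageData(EBImage::filter2(x, f, boundary = "replicate")))
}

# Per-pixel variance of the Laplacian response in a w x w window.
laplacian_variance <- function(gray, window) {
  lap <- ebi_filter2(gray, .lap_kernel)
  box <- matrix(1 / window^2, window, window)
  m1 <- ebi_filter2(lap, box)
  m2 <- ebi_filter2(lap * lap, box)
  pmax(m2 - m1 * m1, 0)
}

to_gray <- function(plane) {
  if (length(dim(plane)) == 3)
    0.299 * plane[, , 1] + 0.587 * plane[, , 2] + 0.114 * plane[, , 3]
  else plane
}

#' Fuse a focal stack into one all-in-focus image
#'
#' For every pixel, selects the focus plane with the highest local
#' sharpness — the variance of the 3x3 Laplacian response within a
#' `window` x `window` neighbourhood — and copies that plane's value.
#' Pure selection (no blending) preserves granule contrast: every fused
#' pixel value exists at the same coordinate in some input plane. Ties
#' resolve to the lowest plane index; the chosen plane per pixel is
#' returned as the provenance index map.
#'
#' @param stack a [focal_stack()].
#' @param window odd window side length (pixels) for the local sharpness
#'   score; default 9.
#' @return object of class `fused_image`: list with `image`,
#'   `um_per_pixel`, `index_map` (1-based plane choice per pixel) and
#'   `window`.
#' @export
fuse_stack <- function(stack, window = 9L) {
  stopifnot(inherits(stack, "focal_stack"))
  if (window < 3 || window %% 2 != 1)
    stop("`window` must be an odd integer >= 3")
  n <- length(stack$planes)
  d <- dim(stack$planes[[1]])
  h <- d[1]; w <- d[2]

  idx <- matrix(1L, h, w)
  best <- laplacian_variance(to_gray(stack$planes[[1]]), window)
  if (n > 1) for (p in 2:n) {
    s <- laplacian_variance(to_gray(stack$planes[[p]]), window)
    upd <- s > best            # strict: ties keep the lower plane index
    idx[upd] <- p
    best[upd] <- s[upd]
  }

  image <- stack$planes[[1]]
  if (n > 1) {
    if (length(d) == 3) {
      for (p in 2:n) {
        sel <- idx == p
        for (ch in 1:3) {
          tmp <- image[, , ch]
          src <- stack$planes[[p]][, , ch]
          tmp[sel] <- src[sel]
          image[, , ch] <- tmp
        }
      }
    } else {
      for (p in 2:n) {
        sel <- idx == p
        image[sel] <- stack$planes[[p]][sel]
      }
    }
  }
  structure(list(image = image, um_per_pixel = stack$um_per_pixel,
                 index_map = idx, window = as.integer(window)),
            class = "fused_image")
}

#' @export
print.fused_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Fused image %d x %d%s, %g um/pixel (window %d); planes used: %s\n",
              d[1], d[2], if (length(d) == 3) " x 3" else "",
              x$um_per_pixel, x$window,
              paste(sort(unique(as.vector(x$index_map))), collapse = ", ")))
  invisible(x)
}

#' Write a fused image and its plane-index map
#'
#' The fused image is written as TIFF; the index map, rescaled to
#' grey levels, as PNG via EBImage.
#'
#' @param fused a `fused_image`.
#' @param image_path TIFF output for the fused image.
#' @param index_path optional PNG output for the index map.
#' @return `image_path`, invisibly.
#' @export
write_fused <- function(fused, image_path, index_path = NULL) {
  stopifnot(inherits(fused, "fused_image"))
  tiff::writeTIFF(fused$image, image_path, bits.per.sample = 8L)
  if (!is.null(index_path)) {
    n <- max(fused$index_map)
    EBImage::writeImage(EBImage::Image((fused$index_map - 1) / max(1, n - 1)),
                        index_path, type = "png")
  }
  invisible(image_path)
}
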