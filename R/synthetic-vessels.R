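# Synthetic slit-lamp-style vessel photographs with a known vessel-pixel
# fraction.

.vessel_pal <- list(
  background = c(0.96, 0.93, 0.91),
  vessel     = c(0.72, 0.18, 0.20),
  alpha      = 0.92,
  noise_sd   = 0.01
)

#' Generate a synthetic vessel photograph with known vessel fraction
#'
#' Draws red curvilinear vessel strokes (jittered random-walk polylines
#' stamped with a round brush) on a pale background until the vessel
#' mask covers the requested fraction of the ROI; stroke stamping stops
#' pixel-by-pixel once the target is reached, so the realized fraction
#' matches the target to well within +/- 2 percentage points. The binary
#' vessel mask is returned as ground truth.
#'
#' @param width,height image size in pixels.
#' @param target_fraction requested vessel-pixel fraction of the ROI, in
#'   \[0, 0.6\]; denser targets are refused as unreachable with
#'   non-self-intersecting stroke coverage.
#' @param roi_mask logical matrix; defaults to the full image.
#' @param seed integer seed; output is deterministic in it.
#' @param stroke_width_px range of vessel stroke widths in pixels.
#' @return list with `image` (RGB array), `truth` (list with
#'   `vessel_mask` and realized `vessel_fraction`) and `roi`.
#' @examples
#' v <- generate_vessel_image(128, 128, target_fraction = 0.2, seed = 1)
#' v$truth$vessel_fraction
#' @export
generate_vessel_image <- function(width = 256L, height = 256L,
                                  target_fraction, roi_mask = NULL,
                                  seed = 1L, stroke_width_px = c(3, 6)) {
  if (!is.numeric(target_fraction) || target_fraction < 0 ||
      target_fraction > 1)
    stop("target_fraction must lie in [0, 1]")
  if (target_fraction > 0.6)
    stop("target_fraction above 0.6 is unreachable with curvilinear ",
         "stroke coverage; lower the target")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, height, width)
  stopifnot(is.logical(roi_mask), nrow(roi_mask) == height,
            ncol(roi_mask) == width, sum(roi_mask) > 0)
  n_roi <- sum(roi_mask)

  with_seed(seed, {
    mask <- matrix(FALSE, height, width)
    n_in <- 0L
    roi_px <- which(roi_mask)
    target_px <- round(target_fraction * n_roi)
    strokes <- 0L
    while (n_in < target_px && strokes < 5000L) {
      strokes <- strokes + 1L
      start <- roi_px[sample.int(length(roi_px), 1)]
      y <- (start - 1) %% height + 1
      x <- (start - 1) %/% height + 1
      ang <- runif(1, 0, 2 * pi)
      w <- runif(1, stroke_width_px[1], stroke_width_px[2])
      r <- w / 2
      for (step in seq_len(80L)) {
        patch <- disk_coverage(c(height, width), x, y, r, ss = 2L)
        if (!is.null(patch)) {
          sel <- patch$cov >= 0.5
          rows <- rep(patch$rows, times = ncol(patch$cov))[as.vector(sel)]
          cols <- rep(patch$cols, each = nrow(patch$cov))[as.vector(sel)]
          idx <- (cols - 1L) * height + rows
          new <- idx[!mask[idx]]
          if (length(new)) {
            gain <- new[roi_mask[new]]
            if (n_in + length(gain) > target_px) {
              # stamp only as many ROI pixels as still needed
              need <- target_px - n_in
              keep_roi <- gain[seq_len(need)]
              mask[keep_roi] <- TRUE
              n_in <- target_px
              break
            }
            mask[new] <- TRUE
            n_in <- n_in + length(gain)
          }
        }
        ang <- ang + rnorm(1, 0, 0.18)
        x <- x + 1.5 * cos(ang)
        y <- y + 1.5 * sin(ang)
        if (x < 1 || x > width || y < 1 || y > height) break
      }
    }
    realized <- n_in / n_roi
    if (abs(realized - target_fraction) > 0.02)
      stop(sprintf("could not reach target fraction %.3f (realized %.3f)",
                   target_fraction, realized))

    img <- array(rep(.vessel_pal$background, each = height * width),
                 dim = c(height, width, 3))
    if (any(mask)) {
      feather <- as.matrix(EBImage::gblur(mask * 1, sigma = 0.6))
      a <- pmin(feather * 1.15, 1) * .vessel_pal$alpha
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - a) + .vessel_pal$vessel[ch] * a
    }
    img <- clamp(img + array(rnorm(length(img), 0, .vessel_pal$noise_sd),
                             dim = dim(img)), 0, 1)
    list(image = img,
         truth = list(vessel_mask = mask & roi_mask,
                      vessel_fraction = realized),
         roi = roi_mask)
  })
}
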