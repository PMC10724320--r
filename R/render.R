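# Internal rendering primitives for the synthetic-image generator.
# Images are numeric arrays H x W x 3 on [0, 1], pixel centres at integer
# (row, col) coordinates.

# Anti-aliased disk coverage via 4x4 supersampling. Returns NULL when the
# disk misses the canvas, else rows/cols of the bounding box and a
# fractional coverage matrix.
disk_coverage <- function(dims, cx, cy, r, ss = 4L) {
  x0 <- max(1L, floor(cx - r - 1)); x1 <- min(dims[2], ceiling(cx + r + 1))
  y0 <- max(1L, floor(cy - r - 1)); y1 <- min(dims[1], ceiling(cy + r + 1))
  if (x1 < x0 || y1 < y0) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  offs <- (seq_len(ss) - 0.5) / ss - 0.5
  cov <- matrix(0, length(ys), length(xs))
  for (oy in offs) {
    dy2 <- (ys + oy - cy)^2
    for (ox in offs) {
      dx2 <- (xs + ox - cx)^2
      cov <- cov + (outer(dy2, dx2, "+") <= r^2)
    }
  }
  list(rows = ys, cols = xs, cov = cov / ss^2)
}

# Alpha-blend a colour into an RGB canvas using a coverage patch.
blend_patch <- function(img, patch, color, alpha = 1) {
  if (is.null(patch)) return(img)
  a <- patch$cov * alpha
  for (ch in 1:3) {
    old <- img[patch$rows, patch$cols, ch]
    img[patch$rows, patch$cols, ch] <- old * (1 - a) + color[ch] * a
  }
  img
}

# Accumulate a coverage patch onto a single-channel canvas.
add_patch <- function(canvas, patch) {
  if (is.null(patch)) return(canvas)
  canvas[patch$rows, patch$cols] <-
    canvas[patch$rows, patch$cols] + patch$cov
  canvas
}

# Linear pixel indices of a disk (coverage >= 0.5), used for truth masks.
disk_mask_indices <- function(dims, cx, cy, r) {
  p <- disk_coverage(dims, cx, cy, r)
  if (is.null(p)) return(integer(0))
  sel <- which(p$cov >= 0.5, arr.ind = TRUE)
  (p$cols[sel[, 2]] - 1L) * dims[1] + p$rows[sel[, 1]]
}

# Sequential dart-throwing placement of n disks with per-disk radii and a
# pairwise centre-distance constraint. Returns a data.frame (possibly
# with fewer than n rows if space runs out).
place_disks <- function(n, radii, lo_x, hi_x, lo_y, hi_y, gap, max_tries = 400L) {
  xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      x <- runif(1, lo_x, hi_x); y <- runif(1, lo_y, hi_y)
      if (length(xs) == 0 ||
          all((xs - x)^2 + (ys - y)^2 >= (rs + radii[i] + gap)^2)) {
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, radii[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  data.frame(x = xs, y = ys, r = rs)
}

# Place granule centres inside a nucleus disk: uniform in the allowed
# inner disk, minimum pairwise centre distance r_i + r_j + gap.
place_granules_in_nucleus <- function(n, grad_px, nucleus_r_px, gap,
                                      max_tries = 300L) {
  xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
  for (i in seq_len(n)) {
    rmax <- nucleus_r_px - grad_px[i] - 1.5
    if (rmax <= 0) break
    for (t in seq_len(max_tries)) {
      a <- runif(1, 0, 2 * pi); rr <- rmax * sqrt(runif(1))
      x <- rr * cos(a); y <- rr * sin(a)
      if (length(xs) == 0 ||
          all((xs - x)^2 + (ys - y)^2 >= (rs + grad_px[i] + gap)^2)) {
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, grad_px[i])
        break
      }
    }
    if (length(xs) < i) break
  }
  data.frame(dx = xs, dy = ys, r_px = rs)
}
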