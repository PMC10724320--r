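# Independent oracles used to validate the package implementations.
# Each is written against the rule statements directly, not against the
# package code paths it checks.

# --- morphological reconstruction: iterative geodesic dilation to fixpoint
dilate3x3_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m); out <- m
  shift <- function(dr, dc) {
    r1 <- max(1, 1 + dr):min(nr, nr + dr); r0 <- r1 - dr
    c1 <- max(1, 1 + dc):min(nc, nc + dc); c0 <- c1 - dc
    x <- matrix(-Inf, nr, nc); x[r1, c1] <- m[r0, c0]; x
  }
  for (dr in -1:1) for (dc in -1:1) if (dr != 0 || dc != 0)
    out <- pmax(out, shift(dr, dc))
  out
}

reconstruct_oracle <- function(marker, mask) {
  m <- pmin(marker, mask)
  repeat {
    m2 <- pmin(dilate3x3_oracle(m), mask)
    if (all(m2 == m)) return(m)
    m <- m2
  }
}

hdome_oracle <- function(image, h) image - reconstruct_oracle(image - h, image)

# --- pattern rule: literal transcription of the five-way taxonomy
pattern_oracle <- function(n_small, n_large, few_max = 4L) {
  if (n_large > 0) {
    if (n_large <= few_max) 3L else 4L
  } else if (n_small > 0) {
    if (n_small <= few_max) 1L else 2L
  } else 5L
}

category_oracle <- function(pattern) {
  if (pattern %in% c(5L, 1L)) 1L else pattern
}

# --- Welch t + Sidak all-pairs oracle built on stats::t.test
tamhane_oracle <- function(groups, alpha = 0.05) {
  k <- length(groups)
  m <- k * (k - 1) / 2
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tt <- t.test(groups[[i]], groups[[j]], var.equal = FALSE)
    p_adj <- min(1, 1 - (1 - tt$p.value)^m)
    out[[length(out) + 1L]] <- data.frame(
      i = i, j = j, t = unname(tt$statistic),
      df = unname(tt$parameter), p_raw = tt$p.value, p_adj = p_adj,
      significant = p_adj < alpha)
  }
  do.call(rbind, out)
}

# --- truncated-normal moments on [lo, hi] (closed form)
truncnorm_moments <- function(mean, sd, lo = 0, hi = 100) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mu <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                 ((dnorm(a) - dnorm(b)) / z)^2)
  list(mean = mu, sd = sqrt(v))
}

# --- brute-force per-pixel sharpest-plane selection with an explicit
# sliding window (independent of the package's convolution route)
fuse_oracle_index <- function(planes, window) {
  gray <- lapply(planes, function(p)
    if (length(dim(p)) == 3)
      0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3] else p)
  lap <- lapply(gray, function(g) {
    nr <- nrow(g); nc <- ncol(g)
    out <- matrix(0, nr, nc)
    ci <- function(v, n) min(max(v, 1), n)    # replicate boundary
    for (r in 1:nr) for (c in 1:nc)
      out[r, c] <- g[ci(r - 1, nr), c] + g[ci(r + 1, nr), c] +
        g[r, ci(c - 1, nc)] + g[r, ci(c + 1, nc)] - 4 * g[r, c]
    out
  })
  half <- (window - 1) / 2
  nr <- nrow(lap[[1]]); nc <- ncol(lap[[1]])
  idx <- matrix(1L, nr, nc)
  clampi <- function(v, n) pmin(pmax(v, 1), n)
  for (r in 1:nr) for (c in 1:nc) {
    rs <- clampi((r - half):(r + half), nr)
    cs <- clampi((c - half):(c + half), nc)
    best <- -Inf
    for (p in seq_along(lap)) {
      w <- lap[[p]][rs, cs]          # replicate boundary via clamped index
      v <- mean(w^2) - mean(w)^2
      if (v > best + 1e-15) { best <- v; idx[r, c] <- p }
    }
  }
  idx
}

# --- matching detected nuclei to ground truth by centre distance
match_detections <- function(truth_nuclei, info, max_dist_px = 10) {
  vapply(truth_nuclei, function(n) {
    if (nrow(info) == 0) return(NA_integer_)
    d2 <- (info$x - n$x)^2 + (info$y - n$y)^2
    j <- which.min(d2)
    if (d2[j] <= max_dist_px^2) as.integer(j) else NA_integer_
  }, integer(1))
}

iou <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small cheap cohort spec used across tests
small_spec <- function(...) {
  cohort_spec(groups = data.frame(label = c("primary", "recurrent", "control"),
                                  n_specimens = c(3L, 2L, 2L)),
              nuclei_per_field = c(8L, 10L), field_px = 192L, ...)
}
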