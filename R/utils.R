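# Internal helpers: seeded RNG scoping, truncated normal, image utilities.

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# stream. Used so generators are deterministic in (seed, index) while a
# surrounding simulation keeps its own stream intact.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-specimen sub-seed; kept inside 32-bit integer range.
specimen_seed <- function(seed, index) {
  v <- ((as.numeric(seed) %% 94906265) * 22695477 + index * 2654435761) %% 2147483399
  as.integer(v) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Truncated normal on [lo, hi] via inverse-CDF sampling. sd = 0 collapses
# to a (clamped) point mass.
r_truncnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd <= 0) return(rep(clamp(mean, lo, hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Analytic mean of the truncated normal: the reference value that seeded
# cohorts should recover (truncation shifts the mean away from the nominal
# location parameter, so recovery is judged against this, not `mean`).
truncnorm_mean <- function(mean, sd, lo = 0, hi = 100) {
  if (sd <= 0) return(clamp(mean, lo, hi))
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}

# Linear contrast stretch of a numeric array onto [0, 1]; constant input
# maps to all zeros.
stretch01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] - r[1] <= .Machine$double.eps) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

# Otsu threshold computed from an arbitrary pixel subset (EBImage::otsu
# works on whole images only). 256-bin histogram on [0, 1] values.
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  stopifnot(length(values) > 0)
  h <- tabulate(pmin(pmax(floor(values * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L
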