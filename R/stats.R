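# Group summaries, Tamhane's T2 all-pairs comparison, and the reporting
# arithmetic (rounded positive fractions, two-significant-figure ratios).

#' Summarise one group of specimen positivity values
#'
#' @param values numeric vector of per-specimen positivity percentages.
#' @param label group label.
#' @return object of class `group_sample`: label, n, values, mean and
#'   sample standard deviation (n - 1 denominator).
#' @examples
#' group_summary(c(0, 100))   # mean 50, sd ~70.71
#' @export
group_summary <- function(values, label = NA_character_) {
  if (length(values) == 0) stop("group_summary needs at least one value")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numbers")
  structure(list(label = label, n = length(values), values = values,
                 mean = mean(values),
                 sd = if (length(values) > 1) sd(values) else 0),
            class = "group_sample")
}

#' @export
print.group_sample <- function(x, ...) {
  cat(sprintf("%s: n=%d, %s%% +/- %s%%\n",
              if (is.na(x$label)) "group" else x$label, x$n,
              signif(x$mean, 2), signif(x$sd, 2)))
  invisible(x)
}

#' Tamhane's T2 all-pairs comparison
#'
#' All-pairs multiple comparison for normally distributed data with
#' unequal sample sizes and unequal variances: for each of the
#' m = k(k-1)/2 group pairs a Welch t statistic
#' t = (mean_i - mean_j) / sqrt(s_i^2/n_i + s_j^2/n_j) with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value, then
#' the Sidak family-wise adjustment p_adj = 1 - (1 - p)^m (capped at 1),
#' which is what distinguishes T2 from a Bonferroni-style procedure.
#' A pair with zero standard error is degenerate: equal means give
#' p = 1, unequal means p = 0.
#'
#' @param groups either a named list of numeric vectors of per-specimen
#'   values, or a list of [group_summary()] objects. Every group needs
#'   n >= 2.
#' @param alpha family-wise significance level; the `significant` flag is
#'   strict, `p_adj < alpha`.
#' @return object of class `tamhane_t2`: a data.frame with one row per
#'   pair (group_a, group_b, mean_diff, t, df, p_raw, p_adj,
#'   significant) plus attributes `alpha`, `m` and `groups`.
#' @examples
#' x <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(8, 9, 10))
#' tamhane_t2(x)
#' @export
tamhane_t2 <- function(groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (length(groups) < 2) stop("need at least two groups")
  gs <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (inherits(g, "group_sample")) g
    else group_summary(g, label = if (!is.null(names(groups)))
      names(groups)[i] else paste0("group", i))
  })
  ns <- vapply(gs, `[[`, 0, "n")
  if (any(ns < 2)) stop("every group needs n >= 2 for inference")
  k <- length(gs)
  m <- k * (k - 1) / 2
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- gs[[i]]; b <- gs[[j]]
    vi <- a$sd^2 / a$n; vj <- b$sd^2 / b$n
    diff <- a$mean - b$mean
    se <- sqrt(vi + vj)
    if (se == 0) {
      tt <- if (diff == 0) 0 else sign(diff) * Inf
      df <- NA_real_
      p <- if (diff == 0) 1 else 0
    } else {
      tt <- diff / se
      df <- (vi + vj)^2 / (vi^2 / (a$n - 1) + vj^2 / (b$n - 1))
      p <- 2 * pt(-abs(tt), df)
    }
    p_adj <- min(1, 1 - (1 - p)^m)
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = a$label, group_b = b$label, mean_diff = diff,
      t = tt, df = df, p_raw = p, p_adj = p_adj,
      significant = p_adj < alpha)
  }
  out <- do.call(rbind, rows)
  structure(out, alpha = alpha, m = m, groups = gs,
            class = c("tamhane_t2", "data.frame"))
}

#' @export
print.tamhane_t2 <- function(x, digits = 4, ...) {
  cat(sprintf("Tamhane T2 all-pairs comparison (%d pairs, Sidak-adjusted, alpha = %g)\n",
              attr(x, "m"), attr(x, "alpha")))
  df <- as.data.frame(x)
  df$t <- signif(df$t, digits); df$df <- signif(df$df, digits)
  df$p_raw <- signif(df$p_raw, digits); df$p_adj <- signif(df$p_adj, digits)
  df$mean_diff <- signif(df$mean_diff, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.tamhane_t2 <- function(object, ...) {
  cat("Groups:\n")
  for (g in attr(object, "groups")) print(g)
  print(object)
  invisible(object)
}

#' Positive-specimen percentage, rounded to the nearest integer
#'
#' Reporting convention for "x of n specimens (p%)" statements: the
#' percentage is rounded half-up to an integer.
#'
#' @param n_positive,n_total nonnegative counts, `n_positive <= n_total`,
#'   `n_total > 0`.
#' @return integer percent.
#' @examples
#' positive_fraction(28, 55)   # 51
#' positive_fraction(20, 20)   # 100
#' @export
positive_fraction <- function(n_positive, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_positive < 0) || any(n_positive > n_total))
    stop("need 0 <= n_positive <= n_total")
  as.integer(floor(100 * n_positive / n_total + 0.5))
}

#' Ratio of two group means at two significant figures
#'
#' Reporting convention for marker ratios (e.g. HIF2a:HIF1a): the ratio
#' of the printed group means, rounded to two significant figures.
#'
#' @param mean_numerator,mean_denominator group means (percent);
#'   denominator must be positive.
#' @return ratio at two significant figures.
#' @examples
#' mean_ratio(38, 11)     # 3.5
#' mean_ratio(4.5, 0.12)  # 38
#' @export
mean_ratio <- function(mean_numerator, mean_denominator) {
  if (any(mean_denominator <= 0)) stop("denominator mean must be positive")
  signif(mean_numerator / mean_denominator, 2)
}

#' Correlation between two immunoreactivity measures
#'
#' Pearson and Spearman correlations with p values, for checks such as
#' within-specimen HIF1a vs HIF2a positivity or positivity vs vessel
#' density (null results expected in this application).
#'
#' @param x,y numeric vectors of equal length (pairs with missing values
#'   are dropped).
#' @return data.frame with method, estimate, p_value, n.
#' @export
marker_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  pe <- cor.test(x, y, method = "pearson")
  sp <- cor.test(x, y, method = "spearman", exact = FALSE)
  data.frame(method = c("pearson", "spearman"),
             estimate = c(unname(pe$estimate), unname(sp$estimate)),
             p_value = c(pe$p.value, sp$p.value),
             n = length(x))
}
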