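# Granule size classes, the five-way nucleus pattern taxonomy and the
# four-category positivity scheme.

#' Classify a granule diameter into a size class
#'
#' Chromogen granules with an equivalent circular diameter of 1.2-1.6 um
#' are "small" and those above 1.6 up to 2.2 um are "large" (the 1.6 um
#' boundary itself counts as small). Diameters below 1.2 um are treated
#' as sub-threshold noise and those above 2.2 um as out of range; both
#' are ignored by the pattern classifier by default.
#'
#' @param diameter equivalent circular diameter in micrometres (vector
#'   allowed; all values must be positive).
#' @return character vector with levels `sub_threshold`, `small`,
#'   `large`, `over_range`.
#' @examples
#' classify_granule_size(c(1.4, 1.6, 1.601, 2.2, 2.5, 0.8))
#' @export
classify_granule_size <- function(diameter) {
  if (!is.numeric(diameter) || any(!is.finite(diameter)) || any(diameter <= 0))
    stop("granule diameters must be positive finite numbers")
  out <- character(length(diameter))
  out[diameter < 1.2] <- "sub_threshold"
  out[diameter >= 1.2 & diameter <= 1.6] <- "small"
  out[diameter > 1.6 & diameter <= 2.2] <- "large"
  out[diameter > 2.2] <- "over_range"
  out
}

#' Classify a nucleus into one of the five granule patterns
#'
#' Pattern taxonomy: 1 = few small granules, 2 = numerous small,
#' 3 = few large, 4 = numerous large, 5 = no granules (negative).
#' "Few" means at most `few_max` granules. Only small and large granules
#' participate; sub-threshold and (by default) over-range granules are
#' ignored. A nucleus containing any large granule is classified by its
#' large granules (large dominates), since the taxonomy defines pure
#' patterns only.
#'
#' @param granules either a numeric vector of granule diameters (um), or
#'   a data.frame with a `size_class` column (as from
#'   [detect_granules()]), or with a `diameter_um` column.
#' @param few_max largest count still "few" (default 4).
#' @param over_range_as_large count over-range granules as large instead
#'   of ignoring them.
#' @return integer pattern in 1..5.
#' @examples
#' classify_nucleus_pattern(numeric(0))        # 5: negative
#' classify_nucleus_pattern(c(1.4, 1.5))       # 1: few small
#' classify_nucleus_pattern(rep(1.4, 7))       # 2: numerous small
#' classify_nucleus_pattern(c(1.4, 1.9))       # 3: large dominates
#' @export
classify_nucleus_pattern <- function(granules, few_max = 4L,
                                     over_range_as_large = FALSE) {
  if (few_max < 1) stop("few_max must be >= 1")
  cls <- granule_size_classes(granules)
  n_large <- sum(cls == "large") +
    if (over_range_as_large) sum(cls == "over_range") else 0L
  n_small <- sum(cls == "small")
  if (n_large > 0L) {
    if (n_large <= few_max) 3L else 4L
  } else if (n_small > 0L) {
    if (n_small <= few_max) 1L else 2L
  } else 5L
}

granule_size_classes <- function(granules) {
  if (is.data.frame(granules)) {
    if ("size_class" %in% names(granules)) return(granules$size_class)
    if ("diameter_um" %in% names(granules)) granules <- granules$diameter_um
    else stop("granule data.frame needs a size_class or diameter_um column")
  }
  if (length(granules) == 0) return(character(0))
  classify_granule_size(granules)
}

#' Map a granule pattern to its positivity category
#'
#' Negative nuclei (pattern 5) and nuclei with few small granules
#' (pattern 1) share category 1; numerous small granules (pattern 2) is
#' category 2, few large (pattern 3) category 3, numerous large
#' (pattern 4) category 4. Nuclei in categories 2-4 count as positively
#' stained.
#'
#' @param pattern integer vector of patterns in 1..5.
#' @return integer vector of categories in 1..4.
#' @examples
#' pattern_category(1:5)   # 1 2 3 4 1
#' @export
pattern_category <- function(pattern) {
  if (!all(pattern %in% 1:5)) stop("pattern must be in 1..5")
  c(1L, 2L, 3L, 4L, 1L)[pattern]
}

#' Per-specimen immunoreactivity from nucleus records
#'
#' Counts the non-goblet nuclei and those among them in categories 2-4
#' ("positively stained") and reports their percentage. Goblet cells are
#' excluded from both numerator and denominator; occasional goblet-cell
#' staining does not enter the analysis.
#'
#' @param records data.frame with logical `goblet` and integer `category`
#'   columns (one row per nucleus), as built by [score_specimen()].
#' @param specimen_id,group,marker labels carried into the summary.
#' @return object of class `specimen_summary`: list with `n_counted`,
#'   `n_positive`, `positivity` (exact percent) and `positivity_int`
#'   (nearest-integer reporting convention, via [positive_fraction()]).
#' @export
specimen_immunoreactivity <- function(records, specimen_id = NA_character_,
                                      group = NA_character_,
                                      marker = NA_character_) {
  stopifnot(is.data.frame(records),
            all(c("goblet", "category") %in% names(records)))
  counted <- records[!records$goblet, , drop = FALSE]
  if (nrow(counted) == 0)
    stop("no non-goblet nuclei: specimen positivity is undefined")
  n_pos <- sum(counted$category >= 2L)
  structure(list(
    specimen_id = specimen_id, group = group, marker = marker,
    n_counted = nrow(counted), n_positive = n_pos,
    positivity = 100 * n_pos / nrow(counted),
    positivity_int = positive_fraction(n_pos, nrow(counted))),
    class = "specimen_summary")
}

#' @export
print.specimen_summary <- function(x, ...) {
  cat(sprintf("Specimen %s [%s, %s]: %d of %d nuclei positive (%d%%)\n",
              x$specimen_id, x$group, x$marker,
              x$n_positive, x$n_counted, x$positivity_int))
  invisible(x)
}
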