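#' Cohort specification for the synthetic-data generator
#'
#' Describes a simulated immunohistochemistry cohort: group sizes, the
#' per-group distribution of true specimen positivity, field geometry and
#' staining/rendering parameters. Defaults mirror the study conditions the
#' pipeline was designed around: three groups (primary pterygium,
#' recurrent pterygium, healthy conjunctiva controls) with 55/6/20
#' specimens and mean positivity 11/18/46 percent (SD 20/36/30) for the
#' HIF1a marker, imaged at 0.25 um/pixel (about 400x magnification) over
#' three focus levels.
#'
#' @param groups data.frame with columns `label` and `n_specimens`.
#' @param marker marker label, e.g. `"HIF1a"` or `"HIF2a"`.
#' @param true_mean_positivity named numeric, per-group mean positivity in
#'   percent (location parameter of the truncated normal on \[0, 100\]).
#' @param positivity_dispersion named numeric, per-group spread (SD
#'   parameter of the truncated normal); 0 gives a point mass.
#' @param nuclei_per_field integer range, epithelial cells rendered per
#'   field (one field per specimen).
#' @param granule_diameter_small,granule_diameter_large numeric intervals
#'   (um) from which true granule diameters are drawn. Defaults sit
#'   inside the small (1.2-1.6 um) and large (>1.6-2.2 um) classes with a
#'   margin against pixel-quantisation error at the default calibration.
#' @param few_max largest granule count still called "few"; counts above
#'   it are "numerous".
#' @param goblet_fraction probability that a rendered cell is a goblet
#'   cell (granule-free, faint mucin staining, excluded from counting).
#' @param um_per_pixel spatial calibration in micrometres per pixel.
#' @param n_planes number of focus levels per field.
#' @param noise_sd additive Gaussian pixel noise (intensity units, images
#'   are on \[0, 1\]).
#' @param field_px field side length in pixels.
#' @param nucleus_radius_um base range of nucleus radii (um); nuclei that
#'   must hold "numerous" granules are drawn towards the upper end.
#' @param seed integer seed; all generator output is deterministic in
#'   (seed, specimen index).
#' @return object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec()
#' spec
#' @export
cohort_spec <- function(groups = data.frame(
                          label = c("primary", "recurrent", "control"),
                          n_specimens = c(55L, 6L, 20L)),
                        marker = "HIF1a",
                        true_mean_positivity = c(primary = 11, recurrent = 18, control = 46),
                        positivity_dispersion = c(primary = 20, recurrent = 36, control = 30),
                        nuclei_per_field = c(25L, 35L),
                        granule_diameter_small = c(1.25, 1.55),
                        granule_diameter_large = c(1.7, 2.2),
                        few_max = 4L,
                        goblet_fraction = 0.1,
                        um_per_pixel = 0.25,
                        n_planes = 3L,
                        noise_sd = 0.02,
                        field_px = 320L,
                        nucleus_radius_um = c(3.0, 5.2),
                        seed = 1L) {
  spec <- structure(list(
    groups = groups, marker = marker,
    true_mean_positivity = true_mean_positivity,
    positivity_dispersion = positivity_dispersion,
    nuclei_per_field = as.integer(nuclei_per_field),
    granule_diameter_small = granule_diameter_small,
    granule_diameter_large = granule_diameter_large,
    few_max = as.integer(few_max),
    goblet_fraction = goblet_fraction,
    um_per_pixel = um_per_pixel,
    n_planes = as.integer(n_planes),
    noise_sd = noise_sd,
    field_px = as.integer(field_px),
    nucleus_radius_um = nucleus_radius_um,
    seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  g <- spec$groups
  if (!is.data.frame(g) || !all(c("label", "n_specimens") %in% names(g)))
    stop("`groups` must be a data.frame with columns label, n_specimens")
  if (any(g$n_specimens < 0)) stop("group sizes must be nonnegative")
  for (lab in g$label) {
    if (is.na(spec$true_mean_positivity[lab]))
      stop("missing true_mean_positivity for group ", lab)
    if (is.na(spec$positivity_dispersion[lab]))
      stop("missing positivity_dispersion for group ", lab)
  }
  if (any(spec$true_mean_positivity < 0 | spec$true_mean_positivity > 100))
    stop("true_mean_positivity must lie in [0, 100]")
  if (any(spec$positivity_dispersion < 0))
    stop("positivity_dispersion must be nonnegative")
  if (spec$goblet_fraction < 0 || spec$goblet_fraction > 1)
    stop("goblet_fraction must lie in [0, 1]")
  if (spec$um_per_pixel <= 0) stop("um_per_pixel must be positive")
  if (spec$n_planes < 1) stop("n_planes must be >= 1")
  if (spec$few_max < 1) stop("few_max must be >= 1")
  if (diff(spec$granule_diameter_small) < 0 || diff(spec$granule_diameter_large) < 0)
    stop("granule diameter intervals must be nonempty")
  if (diff(range(spec$nuclei_per_field)) < 0 || min(spec$nuclei_per_field) < 1)
    stop("nuclei_per_field must be a positive range")
  d_max <- max(spec$granule_diameter_small, spec$granule_diameter_large)
  if (d_max > 0.9 * 2 * min(spec$nucleus_radius_um))
    stop("granule diameter interval exceeds the nucleus size; ",
         "enlarge nucleus_radius_um or shrink the granule intervals")
  if (min(spec$granule_diameter_small) < 2 * spec$um_per_pixel)
    stop("granules smaller than two pixels at this calibration cannot be ",
         "rendered; decrease um_per_pixel")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic IHC cohort specification\n")
  cat("  marker:", x$marker, " seed:", x$seed, "\n")
  for (i in seq_len(nrow(x$groups))) {
    lab <- x$groups$label[i]
    cat(sprintf("  %-10s n=%-3d positivity ~ truncN(%g, %g) on [0,100]\n",
                lab, x$groups$n_specimens[i],
                x$true_mean_positivity[[lab]], x$positivity_dispersion[[lab]]))
  }
  cat(sprintf("  field %dpx @ %g um/px, %d focus planes, %d-%d cells/field, goblet %.0f%%\n",
              x$field_px, x$um_per_pixel, x$n_planes,
              min(x$nuclei_per_field), max(x$nuclei_per_field),
              100 * x$goblet_fraction))
  invisible(x)
}

total_specimens <- function(spec) sum(spec$groups$n_specimens)

# Map a 1-based specimen index to its group label (groups in order).
specimen_group <- function(spec, index) {
  cs <- cumsum(spec$groups$n_specimens)
  if (index < 1 || index > cs[length(cs)])
    stop("specimen_index out of range")
  spec$groups$label[which(index <= cs)[1]]
}
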