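# Synthetic epithelial-field generator with per-nucleus ground truth.

# Rendering palette (RGB on [0,1]). AEC chromogen is red-brown and
# hematoxylin counterstain blue-violet; values chosen so the chromogen
# score (R - B) and counterstain score (B - R) separate cleanly.
.pal <- list(
  background = c(0.94, 0.93, 0.92),
  nucleus    = c(0.45, 0.45, 0.72),
  chromogen  = c(0.55, 0.20, 0.16),
  wash_alpha = 0.04,     # faint cytoplasmic background staining
  nucleus_alpha = 0.85,
  granule_alpha = 0.95,
  goblet_counterstain_alpha = 0.12,
  goblet_chromogen_alpha    = 0.06,
  blur_per_plane_px = 2.5  # defocus blur sigma per focus-plane step
)

#' Generate one synthetic specimen field with ground truth
#'
#' Renders a multi-focal-plane field of AEC-stained epithelium: nuclei as
#' counterstained blobs, intranuclear chromogen granules as red-dominant
#' disks sharp in exactly one focus plane and defocus-blurred in the
#' others, goblet cells as large faint granule-free blobs, plus a faint
#' uniform cytoplasmic wash and Gaussian pixel noise. Every rendered
#' object is recorded in the returned ground truth.
#'
#' Each cell is a goblet cell with probability `goblet_fraction`;
#' each non-goblet nucleus is positive with probability equal to the
#' specimen's drawn true positivity, in which case it receives a
#' "numerous small", "few large" or "numerous large" granule load
#' (patterns 2-4), otherwise "few small" or no granules (patterns 1/5).
#' The stored true pattern and category are recomputed from the granules
#' actually placed, so truth is consistent with the classification rules
#' by construction.
#'
#' @param spec a [cohort_spec()].
#' @param specimen_index 1-based index into the cohort (groups in order);
#'   output is deterministic in `(spec$seed, specimen_index)`.
#' @return list with elements `stack` (a [focal_stack()]) and `truth`
#'   (per-nucleus centres, masks, goblet flags, granule lists, patterns,
#'   categories; per-specimen target and realized positivity).
#' @examples
#' spec <- cohort_spec(field_px = 160L, nuclei_per_field = c(8L, 10L))
#' s <- generate_specimen_stack(spec, 1)
#' s$truth$positivity
#' @export
generate_specimen_stack <- function(spec, specimen_index) {
  validate_cohort_spec(spec)
  group <- specimen_group(spec, specimen_index)
  with_seed(specimen_seed(spec$seed, specimen_index), {
    target <- r_truncnorm(1, spec$true_mean_positivity[[group]],
                          spec$positivity_dispersion[[group]])
    render_specimen(spec, specimen_index, group, target)
  })
}

# Worker running inside the specimen's RNG scope.
render_specimen <- function(spec, specimen_index, group, target) {
  fp <- spec$field_px
  umpp <- spec$um_per_pixel
  dims <- c(fp, fp)
  n_cells <- if (spec$nuclei_per_field[1] == spec$nuclei_per_field[2])
    spec$nuclei_per_field[1] else
    sample(spec$nuclei_per_field[1]:spec$nuclei_per_field[2], 1)

  goblet <- runif(n_cells) < spec$goblet_fraction
  if (all(goblet)) goblet[1] <- FALSE   # positivity needs >= 1 counted cell
  positive <- !goblet & (runif(n_cells) < target / 100)
  pattern_intent <- integer(n_cells)
  pattern_intent[positive] <- sample(2:4, sum(positive), replace = TRUE)
  pattern_intent[!positive & !goblet] <-
    sample(c(1L, 5L), sum(!positive & !goblet), replace = TRUE)

  # nucleus radii (um): nuclei that must hold "numerous" granules are
  # drawn from the upper part of the configured range
  r_lo <- spec$nucleus_radius_um[1]; r_hi <- spec$nucleus_radius_um[2]
  rad_um <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    rad_um[i] <- if (goblet[i]) runif(1, 4.5, 5.5)
    else switch(pattern_intent[i],
                runif(1, r_lo, r_lo + 0.8),                   # 1
                runif(1, r_lo + 0.6, r_lo + 1.3),             # 2
                runif(1, r_lo + 0.2, r_lo + 1.0),             # 3
                runif(1, r_hi - 0.6, r_hi),                   # 4
                runif(1, r_lo, r_lo + 0.8))                   # 5
  }
  rad_px <- rad_um / umpp
  pos <- place_disks(n_cells, rad_px,
                     lo_x = max(rad_px) + 2, hi_x = fp - max(rad_px) - 2,
                     lo_y = max(rad_px) + 2, hi_y = fp - max(rad_px) - 2,
                     gap = 4)
  n_placed <- nrow(pos)
  if (n_placed < n_cells) {        # field saturated; keep what fits
    goblet <- goblet[seq_len(n_placed)]
    pattern_intent <- pattern_intent[seq_len(n_placed)]
    rad_um <- rad_um[seq_len(n_placed)]
    rad_px <- rad_px[seq_len(n_placed)]
  }
  n_cells <- n_placed

  few <- spec$few_max
  canvases <- replicate(spec$n_planes, matrix(0, fp, fp), simplify = FALSE)
  nuclei <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    granules <- data.frame(x = numeric(0), y = numeric(0),
                           diameter_um = numeric(0), plane = integer(0))
    if (!goblet[i] && pattern_intent[i] != 5L) {
      small <- pattern_intent[i] %in% c(1L, 2L)
      n_g <- switch(pattern_intent[i],
                    sample(few, 1),                    # few small
                    few + sample(2L, 1),               # numerous small
                    sample(few, 1),                    # few large
                    few + sample(2L, 1))               # numerous large
      d_um <- if (small)
        runif(n_g, spec$granule_diameter_small[1], spec$granule_diameter_small[2])
      else
        runif(n_g, spec$granule_diameter_large[1], spec$granule_diameter_large[2])
      gap <- if (n_g <= few) 3 else 1   # "few" nuclei get wide separation
      pl <- place_granules_in_nucleus(n_g, d_um / 2 / umpp, rad_px[i], gap)
      if (nrow(pl) > 0) {
        keep <- seq_len(nrow(pl))
        granules <- data.frame(
          x = pos$x[i] + pl$dx, y = pos$y[i] + pl$dy,
          diameter_um = d_um[keep],
          plane = sample(spec$n_planes, nrow(pl), replace = TRUE))
        for (g in seq_len(nrow(granules)))
          canvases[[granules$plane[g]]] <- add_patch(
            canvases[[granules$plane[g]]],
            disk_coverage(dims, granules$x[g], granules$y[g], pl$r_px[g]))
      }
    }
    pattern <- if (goblet[i]) NA_integer_ else
      classify_nucleus_pattern(granules$diameter_um, few_max = few)
    nuclei[[i]] <- list(
      id = i, x = pos$x[i], y = pos$y[i],
      radius_um = rad_um[i], goblet = goblet[i],
      mask = disk_mask_indices(dims, pos$x[i], pos$y[i], rad_px[i]),
      granules = granules,
      pattern = pattern,
      category = if (is.na(pattern)) NA_integer_ else pattern_category(pattern))
  }

  # static base layer: background, wash, nuclei, goblet cells
  base <- array(rep(.pal$background, each = fp * fp), dim = c(fp, fp, 3))
  wash <- matrix(.pal$wash_alpha, fp, fp)
  for (ch in 1:3)
    base[, , ch] <- base[, , ch] * (1 - wash) + .pal$chromogen[ch] * wash
  for (i in seq_len(n_cells)) {
    patch <- disk_coverage(dims, pos$x[i], pos$y[i], rad_px[i])
    if (goblet[i]) {
      base <- blend_patch(base, patch, .pal$nucleus, .pal$goblet_counterstain_alpha)
      base <- blend_patch(base, patch, .pal$chromogen, .pal$goblet_chromogen_alpha)
    } else {
      base <- blend_patch(base, patch, .pal$nucleus, .pal$nucleus_alpha)
    }
  }

  planes <- vector("list", spec$n_planes)
  for (p in seq_len(spec$n_planes)) {
    img <- base
    for (g in seq_len(spec$n_planes)) {
      lay <- canvases[[g]]
      if (all(lay == 0)) next
      sigma <- .pal$blur_per_plane_px * abs(p - g)
      if (sigma > 0)
        lay <- as.matrix(EBImage::gblur(lay, sigma = sigma))
      a <- pmin(lay, 1) * .pal$granule_alpha
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - a) + .pal$chromogen[ch] * a
    }
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    planes[[p]] <- clamp(img, 0, 1)
  }

  counted <- !goblet
  cats <- vapply(nuclei, function(n) if (is.na(n$category)) 0L else n$category, 0L)
  truth <- list(
    specimen_index = specimen_index,
    group = group, marker = spec$marker,
    target_positivity = target,
    positivity = 100 * sum(cats >= 2L & counted) / sum(counted),
    n_nuclei = n_cells, n_goblet = sum(goblet),
    nuclei = nuclei)
  list(stack = focal_stack(planes, um_per_pixel = umpp), truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Calls [generate_specimen_stack()] for every specimen of every group in
#' `spec$groups` (in order). Per-specimen true positivity is drawn from
#' the group's truncated-normal distribution on \[0, 100\]; the whole
#' cohort is reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `ihc_cohort`: list with `spec` and
#'   `specimens`, each specimen a list of `specimen_id`, `group`,
#'   `stack`, `truth`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- total_specimens(spec)
  specimens <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_specimen_stack(spec, i)
    specimens[[i]] <- list(
      specimen_id = sprintf("S%03d", i),
      group = s$truth$group,
      stack = s$stack,
      truth = s$truth)
  }
  structure(list(spec = spec, specimens = specimens), class = "ihc_cohort")
}

#' @export
print.ihc_cohort <- function(x, ...) {
  cat("Synthetic IHC cohort:", length(x$specimens), "specimens, marker",
      x$spec$marker, "\n")
  tab <- table(vapply(x$specimens, `[[`, "", "group"))
  for (g in names(tab)) cat(sprintf("  %-10s %d\n", g, tab[[g]]))
  invisible(x)
}

#' True positivity table of a synthetic cohort
#'
#' @param cohort an `ihc_cohort`.
#' @return data.frame with specimen_id, group, target (drawn) and
#'   realized true positivity.
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "ihc_cohort"))
  do.call(rbind, lapply(cohort$specimens, function(s) data.frame(
    specimen_id = s$specimen_id, group = s$group,
    target_positivity = s$truth$target_positivity,
    positivity = s$truth$positivity)))
}

#' Write a synthetic cohort to disk
#'
#' Writes each specimen's focal stack as a multi-page TIFF, its ground
#' truth as a JSON sidecar, and a cohort manifest CSV with columns
#' specimen_id, group, marker, image, truth.
#'
#' @param cohort an `ihc_cohort`.
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ihc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$specimens, function(s) {
    img <- file.path(dir, paste0(s$specimen_id, ".tif"))
    tru <- file.path(dir, paste0(s$specimen_id, "_truth.json"))
    write_stack(s$stack, img)
    truth <- s$truth
    truth$nuclei <- lapply(truth$nuclei, function(n) {
      n$mask <- as.integer(n$mask); n
    })
    jsonlite::write_json(truth, tru, auto_unbox = TRUE, digits = NA)
    data.frame(specimen_id = s$specimen_id, group = s$group,
               marker = cohort$spec$marker, image = img, truth = tru)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
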