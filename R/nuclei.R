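# Nucleus and granule detection on the fused image.

ebi_matrix <- function(x) as.matrix(EBImage::imageData(x))

#' Detect counterstained nuclei in a fused image
#'
#' Thresholds the hematoxylin counterstain score (blue minus red
#' channel), fills granule-induced holes, removes speckle by
#' morphological opening, then separates touching nuclei by a watershed
#' on the distance map of the binary mask. Objects outside the
#' configured area bounds are discarded; goblet cells, whose mucin body
#' takes almost no counterstain, fall below the threshold and are not
#' detected.
#'
#' @param fused a `fused_image` (RGB).
#' @param counterstain_threshold counterstain score above which a pixel
#'   is nuclear.
#' @param area_um2 admissible nucleus area range in square micrometres.
#' @param open_size diameter (pixels) of the disc brush used for opening.
#' @param watershed_tolerance minimum distance-map depth between two
#'   objects for the watershed to keep them separate (pixels).
#' @return list with `masks` (list of linear pixel-index vectors, one per
#'   nucleus) and `info` (data.frame id, x, y, area_px, area_um2). A
#'   blank image yields zero nuclei, not an error.
#' @export
detect_nuclei <- function(fused, counterstain_threshold = 0.12,
                          area_um2 = c(15, 120), open_size = 5L,
                          watershed_tolerance = 2) {
  stopifnot(inherits(fused, "fused_image"))
  img <- fused$image
  if (!is_rgb_array(img)) stop("detect_nuclei needs an RGB fused image")
  umpp <- fused$um_per_pixel
  score <- img[, , 3] - img[, , 1]
  bw <- score > counterstain_threshold
  bw <- ebi_matrix(EBImage::fillHull(EBImage::Image(bw * 1)))
  bw <- ebi_matrix(EBImage::opening(bw, EBImage::makeBrush(open_size, "disc")))
  if (!any(bw > 0))
    return(list(masks = list(),
                info = data.frame(id = integer(0), x = numeric(0),
                                  y = numeric(0), area_px = integer(0),
                                  area_um2 = numeric(0))))
  lab <- ebi_matrix(EBImage::watershed(EBImage::distmap(bw),
                                       tolerance = watershed_tolerance,
                                       ext = 1))
  n_lab <- max(lab)
  px_area <- umpp^2
  min_px <- area_um2[1] / px_area
  max_px <- area_um2[2] / px_area

  masks <- list()
  for (l in seq_len(n_lab)) {
    idx <- which(lab == l)
    if (length(idx) >= min_px && length(idx) <= max_px)
      masks[[length(masks) + 1L]] <- idx
  }
  h <- dim(img)[1]
  info <- do.call(rbind, lapply(seq_along(masks), function(i) {
    idx <- masks[[i]]
    data.frame(id = i,
               x = mean((idx - 1) %/% h + 1),
               y = mean((idx - 1) %% h + 1),
               area_px = length(idx),
               area_um2 = length(idx) * px_area)
  }))
  if (is.null(info))
    info <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                       area_px = integer(0), area_um2 = numeric(0))
  list(masks = masks, info = info)
}

#' Detect chromogen granules within a nucleus mask
#'
#' Thresholds the chromogen score (red minus blue channel) inside the
#' nucleus mask, labels connected components, and reports each
#' component's centre, pixel area, equivalent circular diameter
#' (2 sqrt(area/pi) in um) and size class. The faint cytoplasmic wash
#' stays well below the chromogen threshold and yields no granules.
#'
#' @param fused a `fused_image` (RGB).
#' @param nucleus_mask linear pixel indices of one nucleus.
#' @param chromogen_threshold chromogen score above which a pixel belongs
#'   to a granule.
#' @param min_diameter_um components with smaller equivalent diameter are
#'   discarded as pixel noise before size classification.
#' @return data.frame with x, y, area_px, diameter_um, size_class (empty
#'   if the nucleus carries no granules).
#' @export
detect_granules <- function(fused, nucleus_mask, chromogen_threshold = 0.06,
                            min_diameter_um = 0.6) {
  stopifnot(inherits(fused, "fused_image"))
  img <- fused$image
  if (!is_rgb_array(img)) stop("detect_granules needs an RGB fused image")
  h <- dim(img)[1]; w <- dim(img)[2]
  if (length(nucleus_mask) == 0 || min(nucleus_mask) < 1 ||
      max(nucleus_mask) > h * w)
    stop("nucleus_mask must index pixels of the fused image")
  umpp <- fused$um_per_pixel
  score <- img[, , 1] - img[, , 3]
  bin <- matrix(FALSE, h, w)
  bin[nucleus_mask] <- score[nucleus_mask] > chromogen_threshold
  lab <- ebi_matrix(EBImage::bwlabel(bin))
  n_lab <- max(lab)
  empty <- data.frame(x = numeric(0), y = numeric(0), area_px = integer(0),
                      diameter_um = numeric(0), size_class = character(0))
  if (n_lab == 0) return(empty)
  out <- lapply(seq_len(n_lab), function(l) {
    idx <- which(lab == l)
    d <- 2 * sqrt(length(idx) / pi) * umpp
    data.frame(x = mean((idx - 1) %/% h + 1),
               y = mean((idx - 1) %% h + 1),
               area_px = length(idx), diameter_um = d,
               size_class = classify_granule_size(d))
  })
  out <- do.call(rbind, out)
  out <- out[out$diameter_um >= min_diameter_um, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score one specimen end to end
#'
#' Runs the full per-specimen chain: fuse the focal stack, detect nuclei,
#' detect and size-classify granules per nucleus, assign each nucleus its
#' pattern and category, and summarise positivity. An optional annotation
#' table can mark detected nuclei as goblet cells (matched by nearest
#' centre), overriding the default assumption that detected
#' counterstained nuclei are countable epithelium.
#'
#' @param stack a [focal_stack()] (or an already fused `fused_image`).
#' @param specimen_id,group,marker labels carried into the summary.
#' @param few_max "few" vs "numerous" cut for the pattern classifier.
#' @param fusion_window sharpness window for [fuse_stack()].
#' @param counterstain_threshold,area_um2 passed to [detect_nuclei()].
#' @param chromogen_threshold,min_diameter_um passed to
#'   [detect_granules()].
#' @param over_range_as_large passed to [classify_nucleus_pattern()].
#' @param annotations optional data.frame (x, y, goblet) of nucleus
#'   annotations; a detected nucleus within `match_radius_um` of an
#'   annotated centre inherits its goblet flag.
#' @param match_radius_um matching radius for annotations, in um.
#' @return list with `summary` (a `specimen_summary`), `records`
#'   (per-nucleus data.frame: id, x, y, n_small, n_large, pattern,
#'   category, goblet) and `fused` (the fused image).
#' @export
score_specimen <- function(stack, specimen_id = NA_character_,
                           group = NA_character_, marker = NA_character_,
                           few_max = 4L, fusion_window = 9L,
                           counterstain_threshold = 0.12,
                           area_um2 = c(15, 120),
                           chromogen_threshold = 0.06,
                           min_diameter_um = 0.6,
                           over_range_as_large = FALSE,
                           annotations = NULL,
                           match_radius_um = 3) {
  fused <- if (inherits(stack, "fused_image")) stack
           else fuse_stack(stack, window = fusion_window)
  nuc <- detect_nuclei(fused, counterstain_threshold, area_um2)
  n <- length(nuc$masks)
  goblet <- rep(FALSE, n)
  if (!is.null(annotations) && n > 0) {
    stopifnot(all(c("x", "y", "goblet") %in% names(annotations)))
    r <- match_radius_um / fused$um_per_pixel
    for (i in seq_len(n)) {
      d2 <- (annotations$x - nuc$info$x[i])^2 + (annotations$y - nuc$info$y[i])^2
      j <- which.min(d2)
      if (length(j) && d2[j] <= r^2) goblet[i] <- isTRUE(annotations$goblet[j])
    }
  }
  records <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        n_small = integer(0), n_large = integer(0),
                        pattern = integer(0), category = integer(0),
                        goblet = logical(0))
  for (i in seq_len(n)) {
    gr <- detect_granules(fused, nuc$masks[[i]], chromogen_threshold,
                          min_diameter_um)
    pat <- classify_nucleus_pattern(gr, few_max = few_max,
                                    over_range_as_large = over_range_as_large)
    records <- rbind(records, data.frame(
      id = i, x = nuc$info$x[i], y = nuc$info$y[i],
      n_small = sum(gr$size_class == "small"),
      n_large = sum(gr$size_class == "large"),
      pattern = pat, category = pattern_category(pat),
      goblet = goblet[i]))
  }
  summary <- specimen_immunoreactivity(records, specimen_id, group, marker)
  list(summary = summary, records = records, fused = fused)
}
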