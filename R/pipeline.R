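# Configuration and the end-to-end pipeline: fuse -> score -> summarise
# -> compare, driven by a cohort manifest.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis in one validated
#' list, so sensitivity analyses are single-field changes. The four
#' granule size thresholds (um) are, in increasing order: the pixel-noise
#' floor below which components are discarded, the lower small-granule
#' bound, the small/large boundary, and the upper large-granule bound.
#'
#' @param um_per_pixel spatial calibration (um/pixel).
#' @param fusion_window sharpness window for [fuse_stack()].
#' @param few_max "few" vs "numerous" granule-count cut.
#' @param size_thresholds_um strictly increasing vector of the four
#'   granule diameter boundaries.
#' @param nucleus_area_um2 admissible nucleus area range.
#' @param counterstain_threshold,chromogen_threshold detection score
#'   thresholds.
#' @param over_range_as_large count over-range granules as large.
#' @param vessel_sigma,vessel_h,vessel_min_contrast vessel-density
#'   parameters (see [compute_vessel_density()]).
#' @param alpha family-wise significance level in (0, 1).
#' @param seed integer seed recorded in the run log.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(um_per_pixel = 0.25,
                            fusion_window = 9L,
                            few_max = 4L,
                            size_thresholds_um = c(0.6, 1.2, 1.6, 2.2),
                            nucleus_area_um2 = c(15, 120),
                            counterstain_threshold = 0.12,
                            chromogen_threshold = 0.06,
                            over_range_as_large = FALSE,
                            vessel_sigma = 20,
                            vessel_h = 0.5,
                            vessel_min_contrast = 0.15,
                            alpha = 0.05,
                            seed = 1L) {
  cfg <- structure(list(
    um_per_pixel = um_per_pixel, fusion_window = as.integer(fusion_window),
    few_max = as.integer(few_max),
    size_thresholds_um = size_thresholds_um,
    nucleus_area_um2 = nucleus_area_um2,
    counterstain_threshold = counterstain_threshold,
    chromogen_threshold = chromogen_threshold,
    over_range_as_large = over_range_as_large,
    vessel_sigma = vessel_sigma, vessel_h = vessel_h,
    vessel_min_contrast = vessel_min_contrast,
    alpha = alpha, seed = as.integer(seed)), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$um_per_pixel <= 0) stop("um_per_pixel must be positive")
  if (cfg$fusion_window < 3 || cfg$fusion_window %% 2 != 1)
    stop("fusion_window must be odd and >= 3")
  if (length(cfg$size_thresholds_um) != 4 ||
      any(diff(cfg$size_thresholds_um) <= 0))
    stop("size_thresholds_um must be four strictly increasing values")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$few_max < 1) stop("few_max must be >= 1")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file keep their [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  base <- pipeline_config()
  known <- names(base)
  unknown <- setdiff(names(user), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg <- base
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg$fusion_window <- as.integer(cfg$fusion_window)
  cfg$few_max <- as.integer(cfg$few_max)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

# FNV-1a 32-bit hash of the deparsed config, for the run log.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full scoring pipeline over a cohort manifest
#'
#' For every manifest row: read the focal stack, fuse it, detect nuclei
#' and granules, classify patterns and categories, and summarise
#' specimen positivity. Rows that fail (missing or unreadable images,
#' schema violations) are recorded in an error table with their row
#' identifier and the run continues; partial results are flagged in the
#' log. Group summaries and Tamhane T2 comparisons are computed per
#' marker across groups with at least two specimens.
#'
#' @param config a `pipeline_config` (or path to a YAML config).
#' @param manifest data.frame or CSV path with columns specimen_id,
#'   group, marker, image (and optionally truth, ignored here).
#' @param out_dir report directory; receives specimens.csv, summary.csv,
#'   comparisons.csv, errors.csv (if any) and run_log.txt.
#' @return invisibly, a list with `specimens`, `summary`, `comparisons`
#'   and `errors` data.frames.
#' @export
run_pipeline <- function(config, manifest, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(manifest)) manifest <- read.csv(manifest)
  need <- c("specimen_id", "group", "marker", "image")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  spec_rows <- list(); err_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      stack <- read_stack(row$image, um_per_pixel = config$um_per_pixel)
      sc <- score_specimen(
        stack, specimen_id = row$specimen_id, group = row$group,
        marker = row$marker, few_max = config$few_max,
        fusion_window = config$fusion_window,
        counterstain_threshold = config$counterstain_threshold,
        area_um2 = config$nucleus_area_um2,
        chromogen_threshold = config$chromogen_threshold,
        min_diameter_um = config$size_thresholds_um[1],
        over_range_as_large = config$over_range_as_large)
      s <- sc$summary
      data.frame(specimen_id = s$specimen_id, group = s$group,
                 marker = s$marker, n_counted = s$n_counted,
                 n_positive = s$n_positive, positivity = s$positivity)
    }, error = function(e) e)
    if (inherits(res, "error"))
      err_rows[[length(err_rows) + 1L]] <- data.frame(
        specimen_id = row$specimen_id, image = row$image,
        message = conditionMessage(res))
    else spec_rows[[length(spec_rows) + 1L]] <- res
  }
  specimens <- if (length(spec_rows)) do.call(rbind, spec_rows) else
    data.frame(specimen_id = character(0), group = character(0),
               marker = character(0), n_counted = integer(0),
               n_positive = integer(0), positivity = numeric(0))
  errors <- if (length(err_rows)) do.call(rbind, err_rows) else
    data.frame(specimen_id = character(0), image = character(0),
               message = character(0))

  summary_rows <- list(); comp_rows <- list()
  for (mk in unique(specimens$marker)) {
    sub <- specimens[specimens$marker == mk, ]
    groups <- split(sub$positivity, sub$group)
    for (g in names(groups)) {
      gs <- group_summary(groups[[g]], label = g)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        marker = mk, group = g, n = gs$n, mean = gs$mean, sd = gs$sd)
    }
    usable <- groups[vapply(groups, length, 0L) >= 2]
    if (length(usable) >= 2) {
      tt <- tamhane_t2(usable, alpha = config$alpha)
      tt <- as.data.frame(tt)
      tt$marker <- mk
      comp_rows[[length(comp_rows) + 1L]] <- tt
    }
  }
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame(marker = character(0), group = character(0), n = integer(0),
               mean = numeric(0), sd = numeric(0))
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(group_a = character(0), group_b = character(0),
               mean_diff = numeric(0), t = numeric(0), df = numeric(0),
               p_raw = numeric(0), p_adj = numeric(0),
               significant = logical(0), marker = character(0))

  write.csv(specimens, file.path(out_dir, "specimens.csv"), row.names = FALSE)
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
            row.names = FALSE)
  if (nrow(errors))
    write.csv(errors, file.path(out_dir, "errors.csv"), row.names = FALSE)
  log <- c(
    paste0("ihcscore version: ", as.character(packageVersion("ihcscore"))),
    paste0("config hash: ", config_hash(config)),
    paste0("seed: ", config$seed),
    paste0("specimens scored: ", nrow(specimens), " of ", nrow(manifest)),
    if (nrow(errors)) paste0("PARTIAL RESULTS: ", nrow(errors),
                             " row(s) failed; see errors.csv"),
    "config:",
    strsplit(yaml::as.yaml(unclass(config)), "\n")[[1]])
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(specimens = specimens, summary = summary,
                 comparisons = comparisons, errors = errors))
}
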