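# Granule size classes, pattern/category classification and specimen
# positivity, including detection on rendered fixtures.

test_that("granule size classes respect the printed diameter boundaries", {
  expect_equal(classify_granule_size(1.4), "small")
  expect_equal(classify_granule_size(1.2), "small")    # closed lower bound
  expect_equal(classify_granule_size(1.6), "small")    # 1.6 still small
  expect_equal(classify_granule_size(1.601), "large")  # strictly above 1.6
  expect_equal(classify_granule_size(2.2), "large")
  expect_equal(classify_granule_size(2.5), "over_range")
  expect_equal(classify_granule_size(1.19), "sub_threshold")
  expect_equal(classify_granule_size(c(1.4, 1.9, 0.5, 3)),
               c("small", "large", "sub_threshold", "over_range"))
  expect_error(classify_granule_size(0), "positive")
  expect_error(classify_granule_size(-1.4), "positive")
})

test_that("pattern classification matches the rule taxonomy on examples", {
  expect_equal(classify_nucleus_pattern(numeric(0)), 5L)
  expect_equal(classify_nucleus_pattern(c(1.4, 1.5), few_max = 4), 1L)
  expect_equal(classify_nucleus_pattern(rep(1.4, 7), few_max = 4), 2L)
  expect_equal(classify_nucleus_pattern(c(1.8, 1.9), few_max = 4), 3L)
  expect_equal(classify_nucleus_pattern(rep(1.8, 6), few_max = 4), 4L)
  # large dominates mixed nuclei
  expect_equal(classify_nucleus_pattern(c(rep(1.4, 7), 1.9), few_max = 4), 3L)
  # sub-threshold and over-range granules are ignored by default
  expect_equal(classify_nucleus_pattern(c(0.8, 2.5)), 5L)
  expect_equal(classify_nucleus_pattern(c(0.8, 2.5), over_range_as_large = TRUE), 3L)
  expect_error(classify_nucleus_pattern(c(1.4), few_max = 0), "few_max")
})

test_that("pattern and category agree with brute-force enumeration", {
  for (few_max in c(2L, 4L, 6L)) {
    for (ns in 0:10) for (nl in 0:10) {
      diams <- c(rep(1.4, ns), rep(1.9, nl))
      p <- classify_nucleus_pattern(diams, few_max = few_max)
      expect_identical(p, pattern_oracle(ns, nl, few_max))
      expect_identical(pattern_category(p), category_oracle(p))
    }
  }
})

test_that("pattern-to-category mapping follows the four-category scheme", {
  expect_identical(pattern_category(1:5), c(1L, 2L, 3L, 4L, 1L))
  expect_error(pattern_category(0L), "1..5")
  expect_error(pattern_category(6L), "1..5")
})

test_that("specimen positivity counts categories 2-4 and excludes goblets", {
  rec <- data.frame(goblet = rep(FALSE, 5), category = c(1L, 2L, 3L, 4L, 1L))
  s <- specimen_immunoreactivity(rec)
  expect_equal(s$positivity, 60)
  expect_equal(s$n_counted, 5L)
  expect_equal(s$n_positive, 3L)

  all_neg <- data.frame(goblet = rep(FALSE, 4), category = rep(1L, 4))
  expect_equal(specimen_immunoreactivity(all_neg)$positivity, 0)

  # goblet rows leave numerator and denominator
  withg <- rbind(rec, data.frame(goblet = TRUE, category = 4L))
  expect_equal(specimen_immunoreactivity(withg)$positivity, 60)

  expect_error(specimen_immunoreactivity(
    data.frame(goblet = TRUE, category = 1L)), "undefined")

  # integer reporting convention at specimen level
  big <- data.frame(goblet = rep(FALSE, 55),
                    category = c(rep(2L, 28), rep(1L, 27)))
  expect_equal(specimen_immunoreactivity(big)$positivity_int, 51L)
})

test_that("positivity never decreases when a category-4 nucleus is added", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    rec <- data.frame(goblet = FALSE, category = sample(1:4, n, replace = TRUE))
    p0 <- specimen_immunoreactivity(rec)$positivity
    p1 <- specimen_immunoreactivity(
      rbind(rec, data.frame(goblet = FALSE, category = 4L)))$positivity
    expect_gte(p1, p0)
  }
})

# --- detection on rendered fixtures -----------------------------------

# Render a single-nucleus RGB field with granules at given offsets (px)
# and diameters (um), using the generator's own palette conventions.
render_nucleus_fixture <- function(diams_um, offsets, umpp = 0.25,
                                   size_px = 96, nucleus_r_um = 6,
                                   wash = TRUE) {
  pal <- ihcscore:::.pal
  dims <- c(size_px, size_px)
  ctr <- (size_px + 1) / 2
  img <- array(rep(pal$background, each = size_px^2), dim = c(dims, 3))
  if (wash) {
    a <- pal$wash_alpha
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - a) + pal$chromogen[ch] * a
  }
  np <- ihcscore:::disk_coverage(dims, ctr, ctr, nucleus_r_um / umpp)
  img <- ihcscore:::blend_patch(img, np, pal$nucleus, pal$nucleus_alpha)
  for (i in seq_along(diams_um)) {
    gp <- ihcscore:::disk_coverage(dims, ctr + offsets[i, 1], ctr + offsets[i, 2],
                                   diams_um[i] / 2 / umpp)
    img <- ihcscore:::blend_patch(img, gp, pal$chromogen, pal$granule_alpha)
  }
  fused <- structure(list(image = img, um_per_pixel = umpp,
                          index_map = matrix(1L, size_px, size_px),
                          window = 9L), class = "fused_image")
  mask <- ihcscore:::disk_mask_indices(dims, ctr, ctr, nucleus_r_um / umpp)
  list(fused = fused, mask = mask)
}

test_that("granule detection recovers count and diameter on clean nuclei", {
  offs <- rbind(c(-10, -10), c(10, -10), c(-10, 10), c(10, 10), c(0, 0))
  for (d in c(1.3, 1.4, 1.9)) {
    k <- 4
    fx <- render_nucleus_fixture(rep(d, k), offs[1:k, , drop = FALSE])
    gr <- detect_granules(fx$fused, fx$mask)
    expect_equal(nrow(gr), k)
    expect_true(all(abs(gr$diameter_um - d) <= 0.2))
  }
})

test_that("a granule-free nucleus with cytoplasmic wash yields no granules", {
  fx <- render_nucleus_fixture(numeric(0), matrix(0, 0, 2))
  expect_equal(nrow(detect_granules(fx$fused, fx$mask)), 0L)
})

test_that("nucleus detection finds all truth nuclei with IoU >= 0.5", {
  spec <- cohort_spec(groups = data.frame(label = "primary", n_specimens = 1L),
                      true_mean_positivity = c(primary = 50),
                      positivity_dispersion = c(primary = 0),
                      nuclei_per_field = c(30L, 30L), goblet_fraction = 0,
                      field_px = 384L, seed = 99L)
  s <- generate_specimen_stack(spec, 1)
  fused <- fuse_stack(s$stack)
  det <- detect_nuclei(fused)
  expect_equal(length(det$masks), 30L)
  m <- match_detections(s$truth$nuclei, det$info)
  expect_false(anyNA(m))
  ious <- vapply(seq_along(m), function(i)
    iou(s$truth$nuclei[[i]]$mask, det$masks[[m[i]]]), 0)
  expect_true(all(ious >= 0.5))
})

test_that("a blank image yields zero nuclei, not an error", {
  img <- array(rep(c(0.94, 0.93, 0.92), each = 64 * 64), dim = c(64, 64, 3))
  fused <- structure(list(image = img, um_per_pixel = 0.25,
                          index_map = matrix(1L, 64, 64), window = 9L),
                     class = "fused_image")
  det <- detect_nuclei(fused)
  expect_equal(length(det$masks), 0L)
  expect_equal(nrow(det$info), 0L)
})

test_that("two touching nuclei are split by the watershed", {
  pal <- ihcscore:::.pal
  size <- 128
  img <- array(rep(pal$background, each = size^2), dim = c(size, size, 3))
  r <- 3.4 / 0.25
  for (cx in c(54, 76)) {   # centres 22 px apart, radii 13.6 px: touching
    p <- ihcscore:::disk_coverage(c(size, size), cx, 64, r)
    img <- ihcscore:::blend_patch(img, p, pal$nucleus, pal$nucleus_alpha)
  }
  fused <- structure(list(image = img, um_per_pixel = 0.25,
                          index_map = matrix(1L, size, size), window = 9L),
                     class = "fused_image")
  det <- detect_nuclei(fused)
  expect_equal(length(det$masks), 2L)
  expect_equal(sort(round(det$info$x)), c(54, 76), tolerance = 0.05)
})

test_that("annotation override excludes goblet-flagged nuclei from counting", {
  spec <- cohort_spec(groups = data.frame(label = "control", n_specimens = 1L),
                      true_mean_positivity = c(control = 40),
                      positivity_dispersion = c(control = 0),
                      nuclei_per_field = c(10L, 10L), goblet_fraction = 0,
                      field_px = 224L, seed = 7L)
  s <- generate_specimen_stack(spec, 1)
  base <- score_specimen(s$stack)
  # flag the first detected nucleus as goblet via annotations
  ann <- data.frame(x = base$records$x[1], y = base$records$y[1], goblet = TRUE)
  ann_sc <- score_specimen(s$stack, annotations = ann)
  expect_equal(ann_sc$summary$n_counted, base$summary$n_counted - 1L)
})
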