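# Ground-truthed synthetic cohort and vessel-image generators.

test_that("specimen generation is deterministic in (seed, index)", {
  spec <- small_spec(seed = 3L)
  a <- generate_specimen_stack(spec, 2)
  b <- generate_specimen_stack(spec, 2)
  expect_identical(a$stack$planes, b$stack$planes)
  expect_identical(a$truth, b$truth)
  c <- generate_specimen_stack(spec, 3)
  expect_false(identical(a$stack$planes, c$stack$planes))
})

test_that("zero positivity with zero dispersion gives only negative nuclei", {
  spec <- cohort_spec(groups = data.frame(label = "primary", n_specimens = 2L),
                      true_mean_positivity = c(primary = 0),
                      positivity_dispersion = c(primary = 0),
                      nuclei_per_field = c(8L, 10L), field_px = 192L,
                      seed = 5L)
  for (i in 1:2) {
    s <- generate_specimen_stack(spec, i)
    pats <- vapply(s$truth$nuclei, function(n)
      if (is.na(n$pattern)) -1L else n$pattern, 0L)
    expect_true(all(pats[pats > 0] %in% c(1L, 5L)))
    cats <- vapply(s$truth$nuclei, function(n)
      if (is.na(n$category)) -1L else n$category, 0L)
    expect_true(all(cats[cats > 0] == 1L))
    expect_equal(s$truth$positivity, 0)
  }
})

test_that("goblet counts follow the Bernoulli sampling rule", {
  # 60 fields x 10 cells at goblet_fraction 0.1: total is Binomial(600, .1);
  # 99% interval computed from the binomial quantiles directly
  spec <- cohort_spec(groups = data.frame(label = "primary", n_specimens = 60L),
                      true_mean_positivity = c(primary = 20),
                      positivity_dispersion = c(primary = 10),
                      nuclei_per_field = c(10L, 10L), goblet_fraction = 0.1,
                      field_px = 192L, n_planes = 1L, seed = 11L)
  tot_cells <- 0L; tot_goblet <- 0L
  for (i in 1:60) {
    s <- generate_specimen_stack(spec, i)
    tot_cells <- tot_cells + s$truth$n_nuclei
    tot_goblet <- tot_goblet + s$truth$n_goblet
  }
  lo <- qbinom(0.005, tot_cells, 0.1)
  hi <- qbinom(0.995, tot_cells, 0.1)
  expect_gte(tot_goblet, lo)
  expect_lte(tot_goblet, hi)
})

test_that("stored truth is consistent with the classification rules", {
  spec <- small_spec(seed = 21L)
  for (i in c(1, 4, 6)) {
    s <- generate_specimen_stack(spec, i)
    for (n in s$truth$nuclei) {
      if (n$goblet) {
        expect_true(is.na(n$pattern))
        next
      }
      expect_identical(n$pattern,
                       classify_nucleus_pattern(n$granules$diameter_um,
                                                few_max = spec$few_max))
      expect_identical(n$category, pattern_category(n$pattern))
    }
    # positivity bookkeeping is exact
    counted <- Filter(function(n) !n$goblet, s$truth$nuclei)
    n_pos <- sum(vapply(counted, function(n) n$category >= 2L, TRUE))
    expect_equal(s$truth$positivity, 100 * n_pos / length(counted))
  }
})

test_that("cohort structure matches the group table and seed reproduces", {
  spec <- small_spec(seed = 8L)
  coh <- generate_cohort(spec)
  expect_s3_class(coh, "ihc_cohort")
  expect_length(coh$specimens, 7L)
  labs <- vapply(coh$specimens, `[[`, "", "group")
  expect_identical(sum(labs == "primary"), 3L)
  expect_identical(sum(labs == "recurrent"), 2L)
  expect_identical(sum(labs == "control"), 2L)
  tr <- cohort_truth(coh)
  expect_identical(tr$group, labs)
  tr2 <- cohort_truth(generate_cohort(spec))
  expect_identical(tr, tr2)

  empty <- cohort_spec(groups = data.frame(label = character(0),
                                           n_specimens = integer(0)))
  expect_length(generate_cohort(empty)$specimens, 0L)
})

test_that("drawn positivity follows the truncated-normal distribution", {
  # distribution-level check at reduced cohort scale: group means of the
  # drawn (target) positivity within 3 CLT standard errors of the
  # analytic truncated-normal mean
  spec <- cohort_spec(groups = data.frame(label = c("primary", "control"),
                                          n_specimens = c(40L, 30L)),
                      true_mean_positivity = c(primary = 11, control = 46),
                      positivity_dispersion = c(primary = 20, control = 30),
                      nuclei_per_field = c(6L, 6L), field_px = 160L,
                      n_planes = 1L, seed = 13L)
  tr <- cohort_truth(generate_cohort(spec))
  for (g in c("primary", "control")) {
    mom <- truncnorm_moments(spec$true_mean_positivity[[g]],
                             spec$positivity_dispersion[[g]])
    vals <- tr$target_positivity[tr$group == g]
    expect_lt(abs(mean(vals) - mom$mean), 3 * mom$sd / sqrt(length(vals)))
  }
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(true_mean_positivity = c(primary = 120,
                                                    recurrent = 18,
                                                    control = 46)),
               "\\[0, 100\\]")
  expect_error(cohort_spec(goblet_fraction = 1.5), "goblet_fraction")
  expect_error(cohort_spec(n_planes = 0L), "n_planes")
  expect_error(cohort_spec(um_per_pixel = 0), "um_per_pixel")
  # granules that cannot fit the nucleus at the given geometry
  expect_error(cohort_spec(granule_diameter_large = c(1.7, 8),
                           nucleus_radius_um = c(3, 4)),
               "exceeds the nucleus size")
  # calibration too coarse to render a granule
  expect_error(cohort_spec(um_per_pixel = 1), "calibration")
  expect_error(generate_specimen_stack(small_spec(), 99), "out of range")
})

test_that("vessel images hit their target fraction with a consistent mask", {
  v <- generate_vessel_image(192, 192, target_fraction = 0.24, seed = 4)
  expect_gte(v$truth$vessel_fraction, 0.22)
  expect_lte(v$truth$vessel_fraction, 0.26)
  # independent pixel count of the returned mask equals the reported value
  expect_equal(sum(v$truth$vessel_mask & v$roi) / sum(v$roi),
               v$truth$vessel_fraction)
  # deterministic in the seed
  v2 <- generate_vessel_image(192, 192, target_fraction = 0.24, seed = 4)
  expect_identical(v$image, v2$image)

  z <- generate_vessel_image(128, 128, target_fraction = 0, seed = 1)
  expect_false(any(z$truth$vessel_mask))
  expect_equal(z$truth$vessel_fraction, 0)

  expect_error(generate_vessel_image(64, 64, target_fraction = 0.9, seed = 1),
               "unreachable")
})

test_that("vessel targets respect a non-trivial ROI", {
  roi <- matrix(FALSE, 160, 160)
  roi[40:120, 40:120] <- TRUE
  v <- generate_vessel_image(160, 160, target_fraction = 0.2, roi_mask = roi,
                             seed = 9)
  expect_equal(sum(v$truth$vessel_mask & roi) / sum(roi),
               v$truth$vessel_fraction)
  expect_gte(v$truth$vessel_fraction, 0.18)
  expect_lte(v$truth$vessel_fraction, 0.22)
})
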