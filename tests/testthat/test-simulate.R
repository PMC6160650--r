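test_that("the same seed reproduces the cohort bitwise", {
  cfg <- small_config(lesion_spec = list(n_lesions = 2L, radius_mm = 2,
                                         offset = -0.3))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$images, b$images)
  expect_identical(a$covariates, b$covariates)
  c2 <- generate_cohort(small_config(seed = 2L,
    lesion_spec = list(n_lesions = 2L, radius_mm = 2, offset = -0.3)))
  expect_false(identical(a$images, c2$images))
})

test_that("a zero-effect, zero-variance cohort is identical across arms", {
  cfg <- small_config(noise_sd = 0, subject_sd = 0, site_bias_sd = 0,
                      rate_sd = 0, rate_field_sd = 0,
                      atrophy_rate_treated = 0.015,
                      atrophy_rate_placebo = 0.015,
                      effect_regions = list(),
                      eloquent_region = list(center = c(13L, 22L, 13L),
                                             radius_mm = 6))
  co <- generate_cohort(cfg)
  cov <- co$covariates
  tr12 <- which(cov$group == "treated" & cov$month == 12)
  pl12 <- which(cov$group == "placebo" & cov$month == 12)
  expect_identical(co$images[, , , tr12[1]], co$images[, , , pl12[1]])
})

test_that("the placebo arm loses GM at the configured rate (Monte Carlo)", {
  # pooled subjects across two replicate cohorts; tolerance +/-10% of the
  # configured 1.5%/year
  ann <- unlist(lapply(1:2, function(s) {
    co <- generate_cohort(small_config(
      n_per_group = c(treated = 5L, placebo = 60L), seed = s))
    wb <- region_volume_series(co, co$brain_mask)
    wb$subjects$annualized_pct[wb$subjects$group == "placebo"]
  }))
  expect_gt(length(ann), 100)
  expect_lt(abs(mean(-ann) / 100 - 0.015), 0.1 * 0.015)
})

test_that("ground-truth spheres match brute-force enumeration", {
  cfg <- small_config()
  gt <- ground_truth_masks(cfg)
  er <- cfg$effect_regions[[1]]
  # exhaustive scan over all voxels
  d <- cfg$grid_shape
  ijk <- arrayInd(seq_len(prod(d)), d)
  d2 <- colSums((t(ijk) - er$center)^2) * 1.5^2
  expect_identical(which(gt$effect_1$data == 1L), which(d2 <= er$radius_mm^2))

  # radius 0: exactly the centre voxel
  cfg0 <- small_config(effect_regions = list(list(center = c(13L, 22L, 13L),
                                                  radius_mm = 0,
                                                  sparing = 0.01)))
  gt0 <- ground_truth_masks(cfg0)
  expect_equal(sum(gt0$effect_1$data), 1)
  expect_equal(which(gt0$effect_1$data == 1L),
               13L + (22L - 1L) * 24L + (13L - 1L) * 24L * 28L)

  # two disjoint spheres give disjoint masks
  cfg2 <- small_config(effect_regions = list(
    list(center = c(9L, 14L, 13L), radius_mm = 4, sparing = 0.02),
    list(center = c(17L, 22L, 13L), radius_mm = 4, sparing = 0.02)))
  gt2 <- ground_truth_masks(cfg2)
  expect_equal(sum(gt2$effect_1$data & gt2$effect_2$data), 0)
})

test_that("configs violating the invariants are rejected", {
  expect_error(simulation_config(grid_shape = c(0, 10, 10)), "positive")
  expect_error(simulation_config(timepoints = c(12, 0)), "increasing")
  expect_error(simulation_config(atrophy_rate_placebo = 1.2), "rates")
  expect_error(small_config(effect_regions = list(
    list(center = c(1L, 1L, 1L), radius_mm = 6, sparing = 0.02))),
    "outside the brain mask")
})

test_that("generated GM stays in [0,1] with a small clipping fraction", {
  co <- generate_cohort(small_config(seed = 4L))
  expect_gte(min(co$images), 0)
  expect_lte(max(co$images), 1)
  expect_lt(co$clip_fraction, 0.01)
})

test_that("under the null the arms' voxelwise changes are distribution-identical", {
  # iid-noise configuration so the two-sample KS test is exact in spirit
  cfg <- null_config(subject_sd = 0, site_bias_sd = 0, rate_sd = 0,
                     rate_field_sd = 0, seed = 9L,
                     n_per_group = c(treated = 10L, placebo = 10L))
  co <- generate_cohort(cfg)
  cov <- co$covariates
  idx <- which(co$brain_mask$data == 1L)
  n_scan <- nrow(cov)
  mat <- matrix(co$images, ncol = n_scan)[idx, ]
  delta <- function(g) {
    s0 <- which(cov$group == g & cov$month == 0)
    s1 <- which(cov$group == g & cov$month == 12)
    as.numeric(mat[, s1] - mat[, s0])
  }
  withr::with_seed(10, {
    a <- sample(delta("treated"), 4000)
    b <- sample(delta("placebo"), 4000)
  })
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})

test_that("the clinical coupling slope is recoverable by regression", {
  # ceiling-free baseline so instrument clipping does not attenuate the fit
  co <- generate_cohort(small_config(
    n_per_group = c(treated = 60L, placebo = 60L),
    pasat2_baseline = c(40, 4), seed = 12L))
  cov <- co$covariates
  ch <- tapply(cov$pasat2, cov$subject, function(x) x[2] - x[1])
  tr <- tapply(cov$eloquent_true_change, cov$subject,
               function(x) x[2] - x[1])
  fit <- summary(stats::lm(ch ~ tr[names(ch)]))$coefficients
  expect_lt(abs(fit[2, "Estimate"] - 600), 3 * fit[2, "Std. Error"])
})

test_that("cohorts round-trip through disk", {
  co <- generate_cohort(small_config(
    n_per_group = c(treated = 2L, placebo = 2L)))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(dim(back$images), dim(co$images))
  expect_lt(max(abs(back$images - co$images)), 1e-6)
  expect_identical(back$brain_mask$data, co$brain_mask$data)
  expect_equal(back$covariates$pasat2, co$covariates$pasat2,
               tolerance = 1e-6)
  expect_identical(back$ground_truth$effect_1$data,
                   co$ground_truth$effect_1$data)
})
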