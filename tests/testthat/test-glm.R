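test_that("a 2-subject 2-timepoint design has the documented columns and rank", {
  cov <- data.frame(subject = rep(c("A", "B"), each = 2),
                    group = rep(c("treated", "placebo"), each = 2),
                    site = 1L, month = rep(c(0, 12), 2))
  expect_warning(d <- build_design(cov), "single-site")
  expect_equal(colnames(d$X),
               c("subj_A", "subj_B", "time_years", "group_time"))
  expect_equal(d$rank, 4)
  expect_equal(unname(d$X[, "group_time"]), c(0, 1, 0, 0))
})

test_that("degenerate and confounded designs are rejected with names", {
  cov <- toy_covariates()
  cov$group <- "treated"
  expect_error(build_design(cov), "two groups")
  # a score column collinear with time is named in the error
  cov2 <- toy_covariates()
  cov2$dup <- cov2$month / 12
  expect_error(build_design(cov2, score_column = "dup"), "dup")
  expect_error(build_design(toy_covariates(), score_column = "nope"),
               "not found")
  cov3 <- toy_covariates()
  cov3$flat <- 1
  expect_error(build_design(cov3, score_column = "flat"), "constant")
})

test_that("voxelwise t-maps match a brute-force lm oracle", {
  # 12 scans (3 subjects per arm x 2 timepoints), 2 sites, tiny grid,
  # interaction and score regressors both checked to 1e-8 relative
  cov <- toy_covariates(n_per_arm = 3L, n_sites = 2L)
  withr::with_seed(21, {
    d <- c(3, 3, 2)
    images <- array(stats::rnorm(prod(d) * nrow(cov), 0.5, 0.1),
                    c(d, nrow(cov)))
    cov$pasat2 <- stats::rnorm(nrow(cov), 40, 5)
  })
  ds <- toy_dataset(images, cov)
  design <- build_design(cov, score_column = "pasat2")
  fit <- fit_voxelwise(ds, design)
  tmap <- contrast_t(fit, c(group_time = 1))
  smap <- contrast_t(fit, "pasat2")
  for (vx in seq_len(prod(d))) {
    y <- matrix(images, ncol = nrow(cov))[vx, ]
    t_or <- lm_t_oracle(y, design$X, "group_time")
    expect_equal(tmap$t[vx], t_or, tolerance = 1e-8)
    t_sc <- lm_t_oracle(y, design$X, "pasat2")
    expect_equal(smap$t[vx], t_sc, tolerance = 1e-8)
  }
  # single-voxel betas against an explicit normal-equations solve on a
  # full-rank (single-site) design
  cov1 <- cov; cov1$site <- 1L
  suppressWarnings(design1 <- build_design(cov1, score_column = "pasat2"))
  fit1 <- fit_voxelwise(ds, design1)
  y1 <- matrix(images, ncol = nrow(cov))[1, ]
  X1 <- design1$X
  beta_or <- solve(crossprod(X1), crossprod(X1, y1))
  expect_equal(unname(fit1$beta[, 1]), as.numeric(beta_or), tolerance = 1e-8)
})

test_that("subject-constant shifts do not move the interaction t-map", {
  cov <- toy_covariates(n_per_arm = 3L, n_sites = 2L)
  withr::with_seed(22, images <- array(stats::rnorm(8 * nrow(cov), 0.5, 0.1),
                                       c(2, 2, 2, nrow(cov))))
  ds <- toy_dataset(images, cov)
  design <- build_design(cov)
  t1 <- contrast_t(fit_voxelwise(ds, design), c(group_time = 1))
  ds2 <- ds
  ds2$images <- ds$images + 0.17   # global constant: absorbed by subjects
  t2 <- contrast_t(fit_voxelwise(ds2, design), c(group_time = 1))
  expect_equal(t1$t, t2$t, tolerance = 1e-8)
  # per-subject constant field
  ds3 <- ds
  shift <- stats::setNames(seq_along(unique(cov$subject)) * 0.01,
                           unique(cov$subject))
  for (i in seq_len(nrow(cov)))
    ds3$images[, , , i] <- ds3$images[, , , i] + shift[cov$subject[i]]
  t3 <- contrast_t(fit_voxelwise(ds3, design), c(group_time = 1))
  expect_equal(t1$t, t3$t, tolerance = 1e-7)
})

test_that("row permutation of scans leaves the t-map invariant", {
  cov <- toy_covariates(n_per_arm = 3L, n_sites = 2L)
  withr::with_seed(23, images <- array(stats::rnorm(4 * nrow(cov), 0.5, 0.1),
                                       c(2, 2, 1, nrow(cov))))
  ds <- toy_dataset(images, cov)
  t1 <- contrast_t(fit_voxelwise(ds, build_design(cov)), c(group_time = 1))
  perm <- rev(seq_len(nrow(cov)))
  ds2 <- toy_dataset(images[, , , perm, drop = FALSE],
                     cov[perm, , drop = FALSE])
  t2 <- contrast_t(fit_voxelwise(ds2, build_design(cov[perm, ])),
                   c(group_time = 1))
  expect_equal(t1$t, t2$t, tolerance = 1e-9)
})

test_that("a noise-free cohort with model-spanned structure fits perfectly", {
  cfg <- small_config(noise_sd = 0, rate_field_sd = 0, subject_sd = 0,
                      seed = 3L)
  co <- generate_cohort(cfg)
  cov <- co$covariates
  cov$gm_global <- colMeans(matrix(co$images,
    ncol = nrow(cov))[which(co$brain_mask$data == 1L), ])
  design <- build_design(cov, global_column = "gm_global")
  fit <- fit_voxelwise(co, design)
  expect_lt(max(fit$sigma2), 1e-10)
})

test_that("contrast handling enforces the documented contracts", {
  cov <- toy_covariates()
  withr::with_seed(24, images <- array(stats::rnorm(2 * nrow(cov), 0.5, 0.1),
                                       c(2, 1, 1, nrow(cov))))
  fit <- fit_voxelwise(toy_dataset(images, cov), build_design(cov))
  expect_error(contrast_t(fit, c(group_time = 0)), "zero")
  expect_error(contrast_t(fit, rep(0, length(fit$colnames))), "zero")
  # a single subject column is not estimable (subject/site redundancy)
  tneg <- contrast_t(fit, c(group_time = -1))
  tpos <- contrast_t(fit, c(group_time = 1))
  expect_equal(tneg$t, -tpos$t)
  expect_equal(tneg$z[!is.na(tneg$z)], -tpos$z[!is.na(tpos$z)],
               tolerance = 1e-9)
})

test_that("z equals the normal quantile of the one-sided p", {
  cov <- toy_covariates(n_per_arm = 4L)
  withr::with_seed(25, images <- array(stats::rnorm(4 * nrow(cov), 0.5, 0.1),
                                       c(2, 2, 1, nrow(cov))))
  sm <- contrast_t(fit_voxelwise(toy_dataset(images, cov),
                                 build_design(cov)), c(group_time = 1))
  ok <- !is.na(sm$p)
  expect_equal(sm$z[ok], stats::qnorm(1 - sm$p[ok]), tolerance = 1e-6)
  expect_true(all(sm$p[ok] > 0 & sm$p[ok] <= 1))
})

test_that("the score partial correlation approaches 1 in the noiseless limit", {
  cov <- toy_covariates(n_per_arm = 6L, n_sites = 2L)
  d <- c(3, 3, 3)
  withr::with_seed(26, {
    images <- array(stats::rnorm(prod(d) * nrow(cov), 0.5, 0.05),
                    c(d, nrow(cov)))
  })
  # score equals the centre voxel's GM exactly
  cov$score <- images[2, 2, 2, ]
  ds <- toy_dataset(images, cov)
  sm <- correlation_map(ds, "score", global_normalization = FALSE)
  expect_gt(sm$r[2, 2, 2], 0.999)
})

test_that("an image-independent score yields calibrated p-values", {
  # fraction of in-mask voxels with p < 0.05 is ~0.05, and the one-sided
  # p-values are uniform (KS) under an unsmoothed iid null; iid residuals
  # are the regime in which the OLS t reference distribution is exact
  cfg <- null_config(seed = 31L, noise_sd = 0.02, subject_sd = 0,
                     site_bias_sd = 0, rate_sd = 0, rate_field_sd = 0,
                     grid_shape = c(30L, 36L, 30L),
                     n_per_group = c(treated = 12L, placebo = 12L))
  co <- generate_cohort(cfg)
  sm <- correlation_map(co, "pasat2", global_normalization = FALSE)
  pv <- sm$p[sm$mask_idx]
  pv <- pv[!is.na(pv)]
  expect_gt(length(pv), 1e4)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.01)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("exchangeable whitening agrees with OLS when residuals are iid", {
  cov <- toy_covariates(n_per_arm = 5L, n_sites = 2L)
  withr::with_seed(27, images <- array(stats::rnorm(8 * nrow(cov), 0.5, 0.1),
                                       c(2, 2, 2, nrow(cov))))
  ds <- toy_dataset(images, cov)
  design <- build_design(cov)
  t_id <- contrast_t(fit_voxelwise(ds, design, scheme = "identity"),
                     c(group_time = 1))
  t_ex <- contrast_t(fit_voxelwise(ds, design, scheme = "exchangeable"),
                     c(group_time = 1))
  ok <- !is.na(t_id$t)
  expect_true(all(is.finite(t_ex$t[ok])))
  # iid residuals: the estimated within-subject correlation is near zero
  # and the whitened t-map stays close to OLS
  expect_gt(stats::cor(t_id$t[ok], t_ex$t[ok]), 0.95)
})
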