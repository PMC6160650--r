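# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately naive (dense loops, closed forms, stats::lm) and never reuse
# the package's own code paths.

# Brute-force Benjamini-Hochberg: exhaustive scan over k.
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  kmax <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
  if (kmax == 0L) return(rep(FALSE, m))
  p <= ps[kmax]
}

# Direct 3D convolution with the full (non-separable) truncated Gaussian
# kernel and reflect padding, accumulated tap by tap over the whole grid.
dense_gauss_oracle <- function(x, sigma_vox) {
  d <- dim(x)
  r <- sapply(sigma_vox, function(s) max(1L, ceiling(4 * s)))
  k1 <- lapply(1:3, function(a) {
    w <- exp(-(seq(-r[a], r[a]))^2 / (2 * sigma_vox[a]^2)); w / sum(w)
  })
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 2L - i, i)
    pmin(pmax(ifelse(i > n, 2L * n - i, i), 1L), n)
  }
  ix <- lapply(1:3, function(a)
    lapply(-r[a]:r[a], function(o) refl(seq_len(d[a]) + o, d[a])))
  out <- array(0, d)
  for (di in -r[1]:r[1]) for (dj in -r[2]:r[2]) for (dk in -r[3]:r[3]) {
    w3 <- k1[[1]][di + r[1] + 1] * k1[[2]][dj + r[2] + 1] *
      k1[[3]][dk + r[3] + 1]
    out <- out + w3 * x[ix[[1]][[di + r[1] + 1]],
                        ix[[2]][[dj + r[2] + 1]],
                        ix[[3]][[dk + r[3] + 1]]]
  }
  out
}

# Per-voxel OLS through stats::lm on an explicit design data.frame,
# returning the t statistic for one coefficient.
lm_t_oracle <- function(y, X, coef_name) {
  df <- as.data.frame(X)
  df$y <- y
  fit <- stats::lm(y ~ 0 + ., data = df)
  ct <- summary(fit)$coefficients
  nm <- make.names(coef_name)
  rn <- make.names(rownames(ct))
  unname(ct[match(nm, rn), "t value"])
}

# Small covariate table: n subjects per arm x 2 timepoints across n_sites.
toy_covariates <- function(n_per_arm = 3L, n_sites = 2L, months = c(0, 12)) {
  n <- 2L * n_per_arm
  data.frame(
    subject = rep(sprintf("S%02d", seq_len(n)), each = length(months)),
    group = rep(rep(c("treated", "placebo"), each = n_per_arm),
                each = length(months)),
    site = rep(rep_len(seq_len(n_sites), n), each = length(months)),
    month = rep(months, times = n),
    stringsAsFactors = FALSE)
}

# A small cohort_dataset built directly from arrays (bypassing the
# generator) for GLM-level tests.
toy_dataset <- function(images, covariates, mask = NULL,
                        voxel_size_mm = c(1.5, 1.5, 1.5)) {
  d <- dim(images)[1:3]
  aff <- diag(c(voxel_size_mm, 1))
  aff[1:3, 4] <- -voxel_size_mm * (d - 1) / 2
  if (is.null(mask)) mask <- array(1L, d)
  structure(list(images = images, covariates = covariates,
                 brain_mask = region_mask(mask, "brain", aff, voxel_size_mm),
                 ground_truth = NULL, affine = aff,
                 voxel_size_mm = voxel_size_mm, lesion_masks = NULL,
                 clip_fraction = 0, config = NULL),
            class = "cohort_dataset")
}

# Reduced-size simulation for tests that need the full generator but not
# the full grid. Overrides replace fields wholesale (no recursive merging,
# so list-valued fields like effect_regions behave as expected).
small_config <- function(...) {
  args <- list(grid_shape = c(24L, 28L, 24L),
               n_per_group = c(treated = 8L, placebo = 8L),
               n_sites = 3L,
               effect_regions = list(list(center = c(13L, 22L, 13L),
                                          radius_mm = 6, sparing = 0.02)),
               seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# A fully null configuration: equal arm rates, no effect regions, score
# decoupled from the images.
null_config <- function(...) {
  args <- list(atrophy_rate_treated = 0.015,
               atrophy_rate_placebo = 0.015,
               effect_regions = list(),
               eloquent_region = list(center = c(13L, 22L, 13L),
                                      radius_mm = 6),
               score_slope = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(small_config, args)
}

# A small cohort with a strong, well-resolved sparing sphere for recovery
# smoke tests (the acceptance suite runs the full-size protocol).
strong_config <- function(...) {
  small_config(effect_regions = list(list(center = c(13L, 18L, 13L),
                                          radius_mm = 8, sparing = 0.05)),
               score_noise_sd = 0.1, pasat2_baseline = c(35, 5), ...)
}
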