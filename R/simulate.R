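# Synthetic longitudinal GM cohorts with known effect geometry.
#
# The generator emulates a two-arm neuroprotection trial after all image
# preprocessing has happened: each scan is a modulated gray-matter map
# already in a common space. Per voxel v, subject s, time t (months):
#
#   GM(s,v,t) = T(v) * (1 + a_s) * (1 - r_s(v) t/12 + spare(v) t/12)
#               + site(s) + eps(s,v,t)
#
# where T is a fixed procedural template, a_s a multiplicative subject
# anatomy effect, and r_s(v) the subject's annualized atrophy-rate field:
# the arm's mean rate plus a global per-subject deviation plus a spatially
# smooth per-subject field. spare(v) is nonzero only inside the configured
# effect regions and only for the treated arm. The atrophy-rate variance is
# split into a small global and a larger spatially local component so that
# the localized sparing signal, not the arm-wide rate difference, dominates
# the voxelwise interaction map, and so that a clinical score coupled to one
# region correlates with GM change locally rather than brain-wide.

#' Simulation configuration for a synthetic longitudinal GM cohort
#'
#' Defaults describe a two-arm trial: 62 treated vs 49 placebo subjects over
#' 13 sites, scans at months 0 and 12, arm-level annualized GM loss 0.5%
#' (treated) vs 1.5% (placebo), and one 10 mm sphere of extra treatment
#' sparing (2% per year) that is also the "eloquent" region driving a
#' PASAT-like clinical score.
#'
#' @param grid_shape voxels per axis.
#' @param voxel_size_mm isotropic voxel edge length (mm).
#' @param n_per_group subjects per arm, named c(treated=, placebo=).
#' @param n_sites number of scan sites.
#' @param timepoints scan months, strictly increasing, first is baseline.
#' @param subject_sd SD of the multiplicative subject anatomy effect.
#' @param site_bias_sd SD of the additive per-site intensity bias.
#' @param atrophy_rate_treated,atrophy_rate_placebo arm-level fractional GM
#'   loss per 12 months.
#' @param rate_sd SD of the global per-subject atrophy-rate deviation
#'   (fraction/year).
#' @param rate_field_sd SD of the spatially smooth per-subject atrophy-rate
#'   field (fraction/year).
#' @param rate_field_fwhm_mm correlation length (FWHM) of that field.
#' @param effect_regions list of spheres `list(center=, radius_mm=,
#'   sparing=)`: extra annualized sparing fraction for the treated arm.
#'   Centres are 1-based voxel indices.
#' @param eloquent_region sphere spec whose GM change drives the clinical
#'   score; NULL couples it to the first effect region.
#' @param score_slope clinical-score points per unit mean GM change in the
#'   eloquent region.
#' @param score_noise_sd per-visit score measurement noise (points).
#' @param pasat2_baseline,pasat3_baseline c(mean, sd) of the subject-level
#'   baseline score draws.
#' @param score_range instrument range; generated scores are clipped to it.
#' @param noise_sd voxelwise measurement noise SD.
#' @param lesion_spec list(n_lesions=, radius_mm=, offset=) for white-matter
#'   lesion blobs; default none.
#' @param seed integer; fixed seed gives bitwise-identical cohorts.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(grid_shape = c(48L, 56L, 48L),
                              voxel_size_mm = 1.5,
                              n_per_group = c(treated = 62L, placebo = 49L),
                              n_sites = 13L,
                              timepoints = c(0, 12),
                              subject_sd = 0.1,
                              site_bias_sd = 0.01,
                              atrophy_rate_treated = 0.005,
                              atrophy_rate_placebo = 0.015,
                              rate_sd = 0.02,
                              rate_field_sd = 0.012,
                              rate_field_fwhm_mm = 12,
                              effect_regions = list(list(center = c(25L, 44L, 25L),
                                                         radius_mm = 10,
                                                         sparing = 0.02)),
                              eloquent_region = NULL,
                              score_slope = 600,
                              score_noise_sd = 0.5,
                              pasat2_baseline = c(42, 12),
                              pasat3_baseline = c(51, 9),
                              score_range = c(0, 60),
                              noise_sd = 0.02,
                              lesion_spec = list(n_lesions = 0L),
                              seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
              n_per_group = n_per_group, n_sites = as.integer(n_sites),
              timepoints = as.numeric(timepoints),
              subject_sd = subject_sd, site_bias_sd = site_bias_sd,
              atrophy_rate_treated = atrophy_rate_treated,
              atrophy_rate_placebo = atrophy_rate_placebo,
              rate_sd = rate_sd, rate_field_sd = rate_field_sd,
              rate_field_fwhm_mm = rate_field_fwhm_mm,
              effect_regions = effect_regions,
              eloquent_region = eloquent_region,
              score_slope = score_slope, score_noise_sd = score_noise_sd,
              pasat2_baseline = pasat2_baseline,
              pasat3_baseline = pasat3_baseline,
              score_range = as.numeric(score_range),
              noise_sd = noise_sd, lesion_spec = lesion_spec,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape <= 0L))
    stop("grid_shape must be three positive integers")
  if (length(cfg$n_per_group) != 2L || any(cfg$n_per_group < 1L))
    stop("n_per_group must give two positive arm sizes")
  if (length(cfg$timepoints) < 2L || any(diff(cfg$timepoints) <= 0))
    stop("timepoints must be strictly increasing with at least two entries")
  rates <- c(cfg$atrophy_rate_treated, cfg$atrophy_rate_placebo)
  if (any(rates < 0) || any(rates >= 1))
    stop("atrophy rates must lie in [0, 1)")
  for (er in cfg$effect_regions) {
    if (er$sparing < 0 || er$sparing >= 1)
      stop("sparing fractions must lie in [0, 1)")
  }
  mask <- brain_template(cfg)$mask
  regions <- cfg$effect_regions
  if (!is.null(cfg$eloquent_region)) regions <- c(regions, list(cfg$eloquent_region))
  for (er in regions) {
    sph <- sphere_mask_array(cfg$grid_shape, er$center, er$radius_mm,
                             cfg$voxel_size_mm)
    if (any(sph == 1L & mask == 0L))
      stop("effect region at (", paste(er$center, collapse = ","),
           ") extends outside the brain mask")
  }
  invisible(cfg)
}

#' Procedural brain template
#'
#' A deterministic smooth GM field in [0,1] on the configured grid: an
#' ellipsoidal "brain" with a cortex-like shell of high GM probability and a
#' deep-GM core, plus the brain mask (the ellipsoid's interior).
#'
#' @param config a `simulation_config`.
#' @return list(template = 3D array, mask = 3D 0/1 array).
#' @export
brain_template <- function(config) {
  d <- config$grid_shape
  ctr <- (d + 1) / 2
  semi <- (d - 1) / 2 * 0.92
  ijk <- arrayInd(seq_len(prod(d)), d)
  rho <- sqrt(((ijk[, 1] - ctr[1]) / semi[1])^2 +
              ((ijk[, 2] - ctr[2]) / semi[2])^2 +
              ((ijk[, 3] - ctr[3]) / semi[3])^2)
  shell <- 0.65 * exp(-((rho - 0.72) / 0.28)^2)
  core <- 0.30 * exp(-(rho / 0.35)^2)
  tmpl <- pmin(shell + core, 1)
  tmpl[rho > 1] <- 0
  list(template = array(tmpl, d), mask = array(as.integer(rho <= 1), d))
}

#' Ground-truth region masks for a simulation configuration
#'
#' Binary masks (voxel centre within radius) for every configured effect
#' region and for the eloquent region, on the cohort grid.
#'
#' @param config a `simulation_config`.
#' @return Named list of `region_mask` objects (`effect_1`, ...,
#'   `eloquent`).
#' @export
ground_truth_masks <- function(config) {
  validate_config(config)
  aff <- default_affine(config$grid_shape, config$voxel_size_mm)
  out <- list()
  for (i in seq_along(config$effect_regions)) {
    er <- config$effect_regions[[i]]
    out[[paste0("effect_", i)]] <-
      region_mask(sphere_mask_array(config$grid_shape, er$center,
                                    er$radius_mm, config$voxel_size_mm),
                  paste0("effect_", i), aff, config$voxel_size_mm)
  }
  el <- config$eloquent_region
  if (is.null(el) && length(config$effect_regions)) el <- config$effect_regions[[1]]
  if (!is.null(el)) {
    out$eloquent <-
      region_mask(sphere_mask_array(config$grid_shape, el$center,
                                    el$radius_mm, config$voxel_size_mm),
                  "eloquent", aff, config$voxel_size_mm)
  }
  out
}

# One global seed split into fixed per-stage substreams so e.g. turning
# lesions on does not perturb the anatomy draws.
stage_seeds <- function(seed) {
  s <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 5L))
  names(s) <- c("anatomy", "noise", "lesions", "scores", "outcomes")
  s
}

#' Generate a synthetic longitudinal GM cohort
#'
#' @param config a `simulation_config`.
#' @return A `cohort_dataset`: 4D image array (x,y,z,scan), a covariate
#'   table with one row per scan (subject, group, site, month, PASAT-like
#'   scores, outcome analogues, and the noise-free eloquent-region GM change
#'   used to couple the score), the brain mask, ground-truth masks, and the
#'   fraction of generated values clipped to [0,1].
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  d <- config$grid_shape
  vox <- config$voxel_size_mm
  aff <- default_affine(d, vox)
  bt <- brain_template(config)
  tmpl <- bt$template
  mask <- bt$mask
  mask_idx <- which(mask == 1L)
  seeds <- stage_seeds(config$seed)

  n_tr <- config$n_per_group[[1]]
  n_pl <- config$n_per_group[[2]]
  n_subj <- n_tr + n_pl
  # alternate arms along the subject list so the round-robin site assignment
  # puts both arms at (almost) every site
  group <- c(rep(c("treated", "placebo"), times = min(n_tr, n_pl)),
             rep(if (n_tr > n_pl) "treated" else "placebo", abs(n_tr - n_pl)))
  subj_id <- sprintf("S%03d", seq_len(n_subj))
  site <- rep_len(seq_len(config$n_sites), n_subj)

  months <- config$timepoints
  n_tp <- length(months)
  n_scan <- n_subj * n_tp

  # sparing field: annualized extra-sparing fraction inside effect regions
  spare <- array(0, d)
  for (er in config$effect_regions) {
    sph <- sphere_mask_array(d, er$center, er$radius_mm, vox)
    spare[sph == 1L] <- er$sparing
  }
  truth <- ground_truth_masks(config)
  eloq_idx <- if (is.null(truth$eloquent)) integer(0) else
    which(truth$eloquent$data == 1L)

  sigma_field_vox <- fwhm_to_sigma(config$rate_field_fwhm_mm) / vox

  # anatomy: subject amplitudes, rate deviations, smooth rate fields, sites
  anat <- withr::with_seed(seeds[["anatomy"]], {
    list(a = stats::rnorm(n_subj, 0, config$subject_sd),
         g = stats::rnorm(n_subj, 0, config$rate_sd),
         site_bias = stats::rnorm(config$n_sites, 0, config$site_bias_sd),
         field_noise_seeds = sample.int(.Machine$integer.max - 1L, n_subj))
  })

  images <- array(0, c(d, n_scan))
  covariates <- data.frame(
    subject = rep(subj_id, each = n_tp),
    group = rep(group, each = n_tp),
    site = rep(site, each = n_tp),
    month = rep(months, times = n_subj),
    stringsAsFactors = FALSE)
  eloq_change <- numeric(n_scan)

  noise_seeds <- withr::with_seed(seeds[["noise"]],
    sample.int(.Machine$integer.max - 1L, n_scan))

  n_clip <- 0
  scan <- 0L
  for (s in seq_len(n_subj)) {
    base_s <- tmpl * (1 + anat$a[s])
    rate_base <- if (group[s] == "treated") config$atrophy_rate_treated
                 else config$atrophy_rate_placebo
    if (config$rate_field_sd > 0) {
      f <- withr::with_seed(anat$field_noise_seeds[s],
                            array(stats::rnorm(prod(d)), d))
      f <- smooth_array(f, sigma_field_vox)
      f <- f / stats::sd(f[mask_idx]) * config$rate_field_sd
    } else f <- array(0, d)
    rate_s <- rate_base + anat$g[s] + f
    slope_v <- base_s * (-rate_s + if (group[s] == "treated") spare else 0)
    for (tp in seq_len(n_tp)) {
      scan <- scan + 1L
      ty <- months[tp] / 12
      img <- base_s + slope_v * ty + anat$site_bias[site[s]]
      if (config$noise_sd > 0)
        img <- img + withr::with_seed(noise_seeds[scan],
                 array(stats::rnorm(prod(d), 0, config$noise_sd), d))
      img[mask == 0L] <- 0
      n_clip <- n_clip + sum(img[mask_idx] < 0 | img[mask_idx] > 1)
      img[img < 0] <- 0
      img[img > 1] <- 1
      images[, , , scan] <- img
      eloq_change[scan] <- if (length(eloq_idx)) mean(slope_v[eloq_idx]) * ty
                           else 0
    }
  }
  clip_fraction <- n_clip / (length(mask_idx) * n_scan)

  covariates$eloquent_true_change <- eloq_change
  gm_ml <- apply(matrix(images, prod(d), n_scan)[mask_idx, , drop = FALSE],
                 2, sum) * prod(vox) / 1000
  covariates$gm_ml <- gm_ml

  covariates <- add_scores(covariates, config, seeds[["scores"]])
  covariates <- add_outcome_analogues(covariates, config, seeds[["outcomes"]])

  lesion_masks <- NULL
  if ((config$lesion_spec$n_lesions %||% 0L) > 0L) {
    bm <- region_mask(mask, "brain", aff, vox)
    lesion_masks <- vector("list", n_scan)
    les_seeds <- withr::with_seed(seeds[["lesions"]],
      sample.int(.Machine$integer.max - 1L, n_subj))
    for (s in seq_len(n_subj)) {
      rows <- which(covariates$subject == subj_id[s])
      for (i in rows) {
        v <- gm_volume(images[, , , i], aff, vox)
        # chronic lesions: same placement at every timepoint of a subject
        li <- implant_lesions(v, config$lesion_spec, bm, seed = les_seeds[s])
        images[, , , i] <- li$volume$data
        lesion_masks[[i]] <- li$lesion_mask
      }
    }
  }

  structure(list(images = images,
                 covariates = covariates,
                 brain_mask = region_mask(mask, "brain", aff, vox),
                 ground_truth = truth,
                 template = tmpl,
                 affine = aff,
                 voxel_size_mm = vox,
                 lesion_masks = lesion_masks,
                 clip_fraction = clip_fraction,
                 config = config),
            class = "cohort_dataset")
}

# PASAT-like scores: baseline draw per subject, plus the configured linear
# coupling to the noise-free eloquent-region GM change, plus per-visit
# measurement noise. PASAT2 has the wider baseline spread; PASAT3 gets half
# the coupling. Scores are clipped to the instrument range [0, 60].
add_scores <- function(covariates, config, seed) {
  n_subj <- length(unique(covariates$subject))
  n <- nrow(covariates)
  rng <- config$score_range
  clipfun <- function(x) pmin(pmax(x, rng[1]), rng[2])
  withr::with_seed(seed, {
    p2_base <- clipfun(stats::rnorm(n_subj, config$pasat2_baseline[1],
                                    config$pasat2_baseline[2]))
    p3_base <- clipfun(stats::rnorm(n_subj, config$pasat3_baseline[1],
                                    config$pasat3_baseline[2]))
    names(p2_base) <- names(p3_base) <- unique(covariates$subject)
    e2 <- stats::rnorm(n, 0, config$score_noise_sd)
    e3 <- stats::rnorm(n, 0, config$score_noise_sd)
    covariates$pasat2 <- clipfun(
      p2_base[covariates$subject] +
        config$score_slope * covariates$eloquent_true_change + e2)
    covariates$pasat3 <- clipfun(
      p3_base[covariates$subject] +
        0.5 * config$score_slope * covariates$eloquent_true_change + e3)
  })
  covariates
}

# Scalar outcome analogues per scan (ml or instrument units). WM drifts
# freely; CSF expands to fill the space the (image-derived) whole GM loses;
# motor measures and EDSS are uncoupled noise around trial-typical values.
add_outcome_analogues <- function(covariates, config, seed) {
  subj <- unique(covariates$subject)
  n_subj <- length(subj)
  ty <- covariates$month / 12
  base_gm <- stats::ave(covariates$gm_ml, covariates$subject,
                        FUN = function(x) x[1])
  gm_change <- covariates$gm_ml - base_gm
  withr::with_seed(seed, {
    draw <- function(mean, sd) {
      x <- stats::rnorm(n_subj, mean, sd); names(x) <- subj; x[covariates$subject]
    }
    wm0 <- draw(493, 65); wm_slope <- draw(0, 8)
    csf0 <- draw(234, 49)
    gd0 <- pmax(draw(0.07, 0.15), 0); gd_slope <- draw(-0.05, 0.2)
    fl0 <- pmax(draw(5.7, 5), 0.1); fl_slope <- draw(1.3, 2)
    hp0 <- draw(19.4, 3.5); hp_slope <- draw(-0.5, 2)
    tw0 <- draw(4.8, 1.2); tw_slope <- draw(0, 0.8)
    ms0 <- draw(0.15, 0.7); ms_slope <- draw(0.13, 0.4)
    ed0 <- pmin(pmax(round(draw(2.2, 1.1) * 2) / 2, 0), 7)
    ed_slope <- draw(-0.18, 0.7)
    covariates$wm_ml <- wm0 + wm_slope * ty
    covariates$csf_ml <- csf0 - gm_change +
      stats::rnorm(nrow(covariates), 0, 0.5) * ty
    covariates$gd_ml <- pmax(gd0 + gd_slope * ty, 0)
    covariates$flair_ml <- pmax(fl0 + fl_slope * ty, 0)
    covariates$hpt9 <- hp0 + hp_slope * ty
    covariates$t25fw <- tw0 + tw_slope * ty
    covariates$msfc <- ms0 + ms_slope * ty
    covariates$edss <- pmin(pmax(ed0 + ed_slope * ty, 0), 10)
  })
  covariates
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset:", length(unique(x$covariates$subject)), "subjects,",
      nrow(x$covariates), "scans on a",
      paste(dim(x$images)[1:3], collapse = "x"), "grid\n")
  cat("  arms:", paste(names(table(x$covariates$group)),
                       table(x$covariates$group) /
                         length(unique(x$covariates$month)), collapse = ", "),
      "| clip fraction", signif(x$clip_fraction, 3), "\n")
  invisible(x)
}

#' Extract one scan of a cohort as a `gm_volume`
#'
#' @param cohort a `cohort_dataset`.
#' @param i scan index (row of the covariate table).
#' @return A `gm_volume`.
#' @export
cohort_volume <- function(cohort, i) {
  gm_volume(cohort$images[, , , i], cohort$affine, cohort$voxel_size_mm)
}

#' Smooth every scan of a cohort
#'
#' @param cohort a `cohort_dataset`.
#' @param fwhm_mm Gaussian kernel FWHM in mm (the conventional VBM choice is
#'   8 mm).
#' @return The cohort with smoothed images.
#' @export
smooth_cohort <- function(cohort, fwhm_mm = 8) {
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / cohort$voxel_size_mm
  n_scan <- dim(cohort$images)[4]
  for (i in seq_len(n_scan))
    cohort$images[, , , i] <- smooth_array(cohort$images[, , , i], sigma_vox)
  cohort$smoothed_fwhm_mm <- fwhm_mm
  cohort
}

#' In-paint lesions across a cohort
#'
#' Fills each scan's lesion mask from the distribution of normal-appearing
#' in-mask tissue (brain mask minus lesions). No-op when the cohort has no
#' lesions.
#'
#' @param cohort a `cohort_dataset`.
#' @param seed integer seed for the fill draws.
#' @return The cohort with in-painted images.
#' @export
inpaint_cohort <- function(cohort, seed = 1L) {
  if (is.null(cohort$lesion_masks)) return(cohort)
  n_scan <- dim(cohort$images)[4]
  fill_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_scan))
  for (i in seq_len(n_scan)) {
    lm <- cohort$lesion_masks[[i]]
    if (sum(lm$data) == 0L) next
    ref <- cohort$brain_mask$data
    ref[lm$data == 1L] <- 0L
    v <- inpaint_lesions(cohort_volume(cohort, i), lm,
                         region_mask(ref, "reference", cohort$affine,
                                     cohort$voxel_size_mm),
                         seed = fill_seeds[i])
    cohort$images[, , , i] <- v$data
  }
  cohort
}

#' Write a cohort to disk
#'
#' One NIfTI volume per scan (`sub-<id>_month-<m>_gm.nii.gz`), the brain
#' mask and ground-truth masks as NIfTI, and the covariate table as
#' `covariates.csv`.
#'
#' @param cohort a `cohort_dataset`.
#' @param dir output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_len(nrow(cohort$covariates))) {
    f <- file.path(dir, sprintf("sub-%s_month-%02d_gm.nii.gz",
                                cohort$covariates$subject[i],
                                cohort$covariates$month[i]))
    write_volume(cohort_volume(cohort, i), f)
    paths <- c(paths, f)
  }
  f <- file.path(dir, "brain_mask.nii.gz")
  write_volume(cohort$brain_mask, f); paths <- c(paths, f)
  for (nm in names(cohort$ground_truth)) {
    f <- file.path(dir, paste0("truth_", nm, ".nii.gz"))
    write_volume(cohort$ground_truth[[nm]], f); paths <- c(paths, f)
  }
  f <- file.path(dir, "covariates.csv")
  utils::write.csv(cohort$covariates, f, row.names = FALSE)
  paths <- c(paths, f)
  invisible(paths)
}
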