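# The three headline constructs: the treatment-induced-sparing region (TIS),
# the longitudinal cognitive disability-specific atlas (DSA), and their
# overlap, plus per-subject GM volumes integrated over a region.

#' Compute the treatment-induced-sparing (TIS) region
#'
#' Fits the group x time GLM on the (smoothed) cohort, tests the interaction
#' one-sided in the sparing direction (treated arm loses less GM than
#' placebo), controls the FDR over in-mask voxels, and clusters the
#' survivors; the TIS is the union of those clusters. The reverse direction
#' (placebo spared relative to treated) is carried through its own FDR and
#' clustering and reported alongside.
#'
#' @param dataset a smoothed `cohort_dataset`.
#' @param q FDR level (default 0.05).
#' @param connectivity cluster connectivity (default 26).
#' @param scheme residual covariance scheme for [fit_voxelwise()].
#' @param global_normalization include the per-scan in-mask mean GM as an
#'   ANCOVA nuisance covariate, so the interaction map reflects sparing
#'   beyond any brain-wide difference in atrophy rate.
#' @return list of class `tis_result`: `mask` (TIS `region_mask`),
#'   `clusters` (`cluster_table`), `stat_map` (sparing-direction map),
#'   `reverse_clusters`, `reverse_mask`, `fdr_threshold`.
#' @export
compute_tis <- function(dataset, q = 0.05, connectivity = 26L,
                        scheme = c("identity", "exchangeable"),
                        global_normalization = TRUE) {
  scheme <- match.arg(scheme)
  cov <- dataset$covariates
  gcol <- NULL
  if (global_normalization) {
    cov$gm_global <- scan_global_means(dataset)
    gcol <- "gm_global"
  }
  design <- build_design(cov, interaction = TRUE, global_column = gcol)
  fit <- fit_voxelwise(dataset, design, scheme = scheme)
  # interaction coefficient = treated minus placebo annualized GM change;
  # sparing direction is positive
  fwd <- contrast_t(fit, c(group_time = 1))
  rev <- contrast_t(fit, c(group_time = -1))
  fwd_out <- threshold_and_cluster(fwd, q, connectivity, "TIS")
  rev_out <- threshold_and_cluster(rev, q, connectivity, "TIS_reverse")
  structure(list(mask = fwd_out$mask, clusters = fwd_out$clusters,
                 stat_map = fwd, fdr_threshold = fwd_out$threshold,
                 reverse_mask = rev_out$mask,
                 reverse_clusters = rev_out$clusters),
            class = "tis_result")
}

threshold_and_cluster <- function(stat_map, q, connectivity, name) {
  pv <- stat_map$p[stat_map$mask_idx]
  usable <- !is.na(pv)
  sig <- rep(FALSE, length(pv))
  thr <- 0
  if (any(usable)) {
    bh <- fdr_bh(pv[usable], q)
    sig[usable] <- bh$significant
    thr <- bh$threshold
  }
  m <- array(0L, stat_map$grid)
  m[stat_map$mask_idx[sig]] <- 1L
  mask <- region_mask(m, name, stat_map$affine, stat_map$voxel_size_mm)
  list(mask = mask, clusters = extract_clusters(mask, stat_map, connectivity),
       threshold = thr)
}

#' Compute the longitudinal cognitive disability-specific atlas (DSA)
#'
#' Voxelwise partial correlation between GM and a clinical score,
#' controlling subject, site, time and the group x time trend; the DSA is
#' the union of clusters surviving FDR in the positive direction (less GM
#' goes with a worse score).
#'
#' @param dataset a smoothed `cohort_dataset`.
#' @param score_column score column name (default "pasat2", the score with
#'   the broader disability continuum).
#' @inheritParams compute_tis
#' @return list of class `dsa_result`: `mask`, `clusters`, `stat_map`
#'   (with partial-correlation array `r`), `fdr_threshold`.
#' @export
compute_dsa <- function(dataset, score_column = "pasat2", q = 0.05,
                        connectivity = 26L,
                        scheme = c("identity", "exchangeable"),
                        global_normalization = TRUE) {
  scheme <- match.arg(scheme)
  sm <- correlation_map(dataset, score_column, scheme = scheme,
                        global_normalization = global_normalization)
  out <- threshold_and_cluster(sm, q, connectivity, "DSA")
  structure(list(mask = out$mask, clusters = out$clusters, stat_map = sm,
                 fdr_threshold = out$threshold),
            class = "dsa_result")
}

#' Overlap of the TIS and DSA regions
#'
#' Voxelwise intersection, clustered with peaks taken from the TIS z-map.
#'
#' @param tis a `tis_result` (or TIS `region_mask` plus `z_map`).
#' @param dsa a `dsa_result` (or DSA `region_mask`).
#' @param connectivity cluster connectivity.
#' @return list: `mask` (intersection `region_mask`), `clusters`.
#' @export
tis_dsa_overlap <- function(tis, dsa, connectivity = 26L) {
  tis_mask <- if (inherits(tis, "tis_result")) tis$mask else tis
  dsa_mask <- if (inherits(dsa, "dsa_result")) dsa$mask else dsa
  z_map <- if (inherits(tis, "tis_result")) tis$stat_map else
    stop("need a tis_result to locate overlap peaks")
  ov <- region_overlap(tis_mask, dsa_mask)
  list(mask = ov, clusters = extract_clusters(ov, z_map, connectivity))
}

#' Per-subject GM volume inside a region, over time
#'
#' Integrates the modulated GM over the region mask for every scan
#' (sum of voxel values times voxel volume, in ml), then derives per-subject
#' change from baseline to the last timepoint, percent change relative to
#' baseline, and annualized percent change. Subjects missing the baseline or
#' final scan are excluded (with a message).
#'
#' @param dataset a `cohort_dataset` (typically unsmoothed, so volumes are
#'   physical).
#' @param mask a `region_mask` on the cohort grid.
#' @return list of class `region_volume_series`: `scans` (per-scan volumes),
#'   `subjects` (per-subject changes), `group_diff` (difference between
#'   group means of percent change, with standard error, treated minus
#'   placebo, plus the annualized version).
#' @export
region_volume_series <- function(dataset, mask) {
  stopifnot(inherits(dataset, "cohort_dataset"), inherits(mask, "region_mask"))
  if (!all(dim(mask$data) == dim(dataset$images)[1:3]))
    stop("mask is not on the cohort grid")
  idx <- which(mask$data == 1L)
  n_scan <- dim(dataset$images)[4]
  vol_ml <- if (length(idx) == 0L) rep(0, n_scan) else
    colSums(matrix(dataset$images, ncol = n_scan)[idx, , drop = FALSE]) *
      prod(dataset$voxel_size_mm) / 1000
  scans <- cbind(dataset$covariates[c("subject", "group", "site", "month")],
                 volume_ml = vol_ml)

  months <- sort(unique(scans$month))
  m0 <- months[1]; m1 <- months[length(months)]
  span_years <- (m1 - m0) / 12
  subjects <- do.call(rbind, lapply(split(scans, scans$subject), function(df) {
    has0 <- any(df$month == m0); has1 <- any(df$month == m1)
    if (!has0 || !has1) return(NULL)
    v0 <- df$volume_ml[df$month == m0][1]
    v1 <- df$volume_ml[df$month == m1][1]
    pct <- if (v0 > 0) 100 * (v1 - v0) / v0 else NA_real_
    data.frame(subject = df$subject[1], group = df$group[1],
               baseline_ml = v0, final_ml = v1, change_ml = v1 - v0,
               pct_change = pct, annualized_pct = pct / span_years)
  }))
  dropped <- setdiff(unique(scans$subject), subjects$subject)
  if (length(dropped))
    message("excluded ", length(dropped), " subject(s) without both endpoints")
  rownames(subjects) <- NULL

  groups <- sort(unique(subjects$group))
  gd <- NULL
  if (length(groups) == 2L) {
    # treated arm is the non-reference (second sorted) level by convention
    tr <- subjects$pct_change[subjects$group == groups[2]]
    pl <- subjects$pct_change[subjects$group == groups[1]]
    se <- sqrt(stats::var(tr) / length(tr) + stats::var(pl) / length(pl))
    gd <- list(treated_level = groups[2],
               estimate_pct = mean(tr) - mean(pl), se_pct = se,
               estimate_annualized_pct = (mean(tr) - mean(pl)) / span_years,
               se_annualized_pct = se / span_years)
  }
  structure(list(scans = scans, subjects = subjects, group_diff = gd,
                 region = mask$name),
            class = "region_volume_series")
}
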