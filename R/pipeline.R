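# One-config orchestration: simulate (or load) -> in-paint -> smooth ->
# TIS -> DSA -> overlap -> region volumes -> clinical statistics, with a
# JSON manifest of every artifact and its checksum.

#' Read a pipeline configuration from YAML (or take a list)
#'
#' Recognised fields: `out_dir`, `input_dir` (pre-existing cohort) or `sim`
#' (overrides for [simulation_config()]), `fwhm_mm` (default 8), `q`
#' (default 0.05), `connectivity` (default 26), `score_column` (default
#' "pasat2"), `scheme` ("identity"), `seed`, `write_nifti`.
#'
#' @param config list or path to a YAML file.
#' @return Normalized configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(out_dir = "results", input_dir = NULL, sim = list(),
                   fwhm_mm = 8, q = 0.05, connectivity = 26L,
                   score_column = "pasat2", scheme = "identity",
                   seed = 1L, write_nifti = TRUE)
  cfg <- utils::modifyList(defaults, config)
  if (cfg$fwhm_mm <= 0) stop("fwhm_mm must be positive")
  if (cfg$q <= 0 || cfg$q >= 1) stop("q must lie in (0,1)")
  cfg
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing `covariates.csv`, per-scan NIfTI volumes
#'   and `brain_mask.nii.gz`.
#' @return A `cohort_dataset` (without ground-truth masks unless present as
#'   `truth_*.nii.gz`).
#' @export
read_cohort <- function(dir) {
  cov <- utils::read.csv(file.path(dir, "covariates.csv"),
                         stringsAsFactors = FALSE)
  mask_vol <- read_volume(file.path(dir, "brain_mask.nii.gz"))
  d <- dim(mask_vol$data)
  n_scan <- nrow(cov)
  images <- array(0, c(d, n_scan))
  for (i in seq_len(n_scan)) {
    f <- file.path(dir, sprintf("sub-%s_month-%02d_gm.nii.gz",
                                cov$subject[i], cov$month[i]))
    v <- read_volume(f)
    if (!all(dim(v$data) == d)) stop("scan ", f, " is not on the cohort grid")
    images[, , , i] <- v$data
  }
  truth_files <- list.files(dir, pattern = "^truth_.*\\.nii\\.gz$",
                            full.names = TRUE)
  truth <- NULL
  if (length(truth_files)) {
    truth <- lapply(truth_files, function(f) {
      v <- read_volume(f)
      nm <- sub("^truth_(.*)\\.nii\\.gz$", "\\1", basename(f))
      region_mask(round(v$data), nm, v$affine, v$voxel_size_mm)
    })
    names(truth) <- sub("^truth_(.*)\\.nii\\.gz$", "\\1",
                        basename(truth_files))
  }
  structure(list(images = images, covariates = cov,
                 brain_mask = region_mask(round(mask_vol$data), "brain",
                                          mask_vol$affine,
                                          mask_vol$voxel_size_mm),
                 ground_truth = truth, affine = mask_vol$affine,
                 voxel_size_mm = mask_vol$voxel_size_mm,
                 lesion_masks = NULL, clip_fraction = NA_real_,
                 config = NULL),
            class = "cohort_dataset")
}

#' Run the full sparing analysis pipeline
#'
#' Executes the stages in fixed order -- simulate (or load) the cohort,
#' in-paint lesions, smooth, TIS, DSA, TIS/DSA overlap, per-subject region
#' volumes, clinical statistics and heat map -- writing every artifact under
#' `out_dir` and recording it in `manifest.json` with an md5 checksum, the
#' seed and the parameters. A stage failure aborts with the stage name after
#' persisting the partial manifest.
#'
#' @param config list or YAML path, see [pipeline_config()].
#' @return The manifest, invisibly; artifacts are on disk.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = cfg[c("fwhm_mm", "q", "connectivity",
                                      "score_column", "scheme", "seed")],
                   version = as.character(utils::packageVersion("vbmsparing")),
                   artifacts = list())
  add <- function(path, what) {
    manifest$artifacts[[what]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      save_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(cfg$input_dir)) read_cohort(cfg$input_dir)
    else {
      sim <- cfg$sim
      sim$seed <- sim$seed %||% cfg$seed
      generate_cohort(do.call(simulation_config, sim))
    }
  })
  cov_path <- file.path(cfg$out_dir, "covariates.csv")
  utils::write.csv(cohort$covariates, cov_path, row.names = FALSE)
  add(cov_path, "covariates")

  cohort <- stage("inpaint", inpaint_cohort(cohort, seed = cfg$seed))
  raw_cohort <- cohort  # physical (unsmoothed) volumes for region integrals
  cohort <- stage("smooth", smooth_cohort(cohort, cfg$fwhm_mm))

  tis <- stage("tis", compute_tis(cohort, q = cfg$q,
                                  connectivity = cfg$connectivity,
                                  scheme = cfg$scheme))
  dsa <- stage("dsa", compute_dsa(cohort, score_column = cfg$score_column,
                                  q = cfg$q, connectivity = cfg$connectivity,
                                  scheme = cfg$scheme))
  ov <- stage("overlap", tis_dsa_overlap(tis, dsa, cfg$connectivity))

  if (isTRUE(cfg$write_nifti)) {
    for (it in list(list(tis$mask, "tis_mask"), list(dsa$mask, "dsa_mask"),
                    list(ov$mask, "overlap_mask"))) {
      f <- file.path(cfg$out_dir, paste0(it[[2]], ".nii.gz"))
      write_volume(it[[1]], f); add(f, it[[2]])
    }
  }
  for (it in list(list(tis$clusters, "tis_clusters"),
                  list(tis$reverse_clusters, "tis_reverse_clusters"),
                  list(dsa$clusters, "dsa_clusters"),
                  list(ov$clusters, "overlap_clusters"))) {
    f <- file.path(cfg$out_dir, paste0(it[[2]], ".csv"))
    utils::write.csv(it[[1]]$table, f, row.names = FALSE); add(f, it[[2]])
  }

  vols <- stage("volumes", region_volume_series(raw_cohort, tis$mask))
  f <- file.path(cfg$out_dir, "tis_volumes.csv")
  utils::write.csv(vols$subjects, f, row.names = FALSE); add(f, "tis_volumes")

  stats_out <- stage("stats", {
    outcomes <- outcome_table(raw_cohort, vols)
    list(outcomes = outcomes,
         changes = change_table(outcomes),
         correlations = pearson_matrix(outcomes, by_group = TRUE))
  })
  f <- file.path(cfg$out_dir, "outcomes.csv")
  utils::write.csv(stats_out$outcomes, f, row.names = FALSE); add(f, "outcomes")
  f <- file.path(cfg$out_dir, "change_table.csv")
  utils::write.csv(stats_out$changes, f, row.names = FALSE); add(f, "change_table")
  for (g in names(stats_out$correlations)) {
    f <- file.path(cfg$out_dir, paste0("correlations_", g, ".csv"))
    utils::write.csv(stats_out$correlations[[g]]$r, f)
    add(f, paste0("correlations_", g))
    f <- file.path(cfg$out_dir, paste0("heatmap_", g, ".png"))
    stage("heatmap", correlation_heatmap(stats_out$correlations[[g]], f,
                                         paste("changes,", g)))
    add(f, paste0("heatmap_", g))
  }

  save_manifest()
  add_summary <- list(tis_voxels = sum(tis$mask$data),
                      dsa_voxels = sum(dsa$mask$data),
                      overlap_voxels = sum(ov$mask$data))
  manifest$summary <- add_summary
  save_manifest()
  invisible(manifest)
}
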