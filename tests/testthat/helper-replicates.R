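# Replicate protocols for the acceptance checks. Results are cached within
# a session so several test blocks can share one set of simulations.

# n=30/arm cohorts at the default grid and effect geometry: TIS recovery,
# reverse-direction clusters, and treated-arm correlation signs.
tis_replicates <- local({
  cache <- NULL
  function(n_rep = 20L) {
    if (!is.null(cache)) return(cache)
    res <- lapply(seq_len(n_rep), function(i) {
      cfg <- simulation_config(n_per_group = c(treated = 30L, placebo = 30L),
                               seed = 100L + i)
      co <- generate_cohort(cfg)
      cos <- smooth_cohort(co, 8)
      tis <- compute_tis(cos)
      vols <- region_volume_series(co, tis$mask)
      out <- outcome_table(co, vols)
      tr <- out[out$group == "treated", ]
      list(dice = dice(tis$mask, co$ground_truth$effect_1),
           reverse_voxels = sum(tis$reverse_mask$data),
           cor_score = stats::cor(tr$tis_ml_change, tr$pasat2_change),
           cor_csf = stats::cor(tr$tis_ml_change, tr$csf_ml_change))
    })
    cache <<- res
    res
  }
})

# n=60/arm cohorts with the score coupled to the spared sphere: TIS/DSA
# overlap recovery.
overlap_replicates <- local({
  cache <- NULL
  function(n_rep = 10L) {
    if (!is.null(cache)) return(cache)
    res <- lapply(seq_len(n_rep), function(i) {
      cfg <- simulation_config(n_per_group = c(treated = 60L, placebo = 60L),
                               seed = 200L + i)
      co <- generate_cohort(cfg)
      cos <- smooth_cohort(co, 8)
      tis <- compute_tis(cos)
      dsa <- compute_dsa(cos)
      ov <- tis_dsa_overlap(tis, dsa)
      list(dice_overlap = dice(ov$mask, co$ground_truth$effect_1),
           overlap_voxels = sum(ov$mask$data))
    })
    cache <<- res
    res
  }
})
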