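# vbmsparing

Voxel-based morphometry (VBM) of treatment-induced gray-matter sparing in
a two-arm longitudinal trial, as a tested R package plus a numbered
analysis workflow.

## The problem

Gray-matter (GM) atrophy in relapsing-remitting multiple sclerosis tracks
cognitive decline. When a candidate neuroprotective treatment slows GM
loss, the interesting question is *where*: does it spare the cortex that
serves the cognitive function that improved? This package implements the
statistical pipeline for that question on longitudinal modulated GM maps
in a common space:

- **TIS** (treatment-induced sparing): at every in-brain voxel, fit the
  GLM `GM ~ subject + site + time + group x time (+ global GM)`, test the
  interaction one-sided in the sparing direction, control the false
  discovery rate (Benjamini-Hochberg, q = 0.05) over the ~50k in-mask
  voxels, and take the union of the surviving 26-connected clusters. The
  interaction coefficient is the annualized difference in GM change
  between arms; the global-GM covariate (ANCOVA-style global
  normalization, standard for modulated VBM) makes the map read "sparing
  beyond the brain-wide arm difference".
- **DSA** (disability-specific atlas): the same model with a PASAT-like
  cognitive score as the regressor of interest; the partial correlation
  r = t/sqrt(t^2 + df) per voxel, positive-direction FDR, clusters.
- **Overlap**: the voxelwise intersection TIS ∩ DSA — cortex that the
  treatment spared *and* whose preservation tracks cognition.
- Downstream: per-subject GM volume inside any region (ml), change
  tables, group-difference regressions, Pearson correlation matrices with
  average-linkage heat maps, Wilcoxon/chi-square baseline comparisons.

Because no subject-level trial data are public, the package ships a
first-class synthetic cohort generator (`simulation_config()`,
`generate_cohort()`) that emulates the trial — 62 treated vs 49 placebo
subjects across 13 sites, scans at months 0 and 12, annualized GM loss
0.5 %/yr (treated) vs 1.5 %/yr (placebo), one 10 mm sphere of extra
sparing coupled to the cognitive score — with known ground truth, so
every stage is validated by recovery rather than by fiat. The methods
vignette (`vignettes/sparing-methods.Rmd`) documents the model, the
generator's variance components, and every numerical choice.

## Worked example

The numbered scripts under `analysis/` run the whole study; each is a thin
driver over package functions and writes under `results/`:

```sh
Rscript analysis/01_simulate.R       # cohort -> results/cohort/
Rscript analysis/02_preprocess.R     # in-paint + 8mm smooth -> results/smoothed/
Rscript analysis/03_sparing_maps.R   # TIS, DSA, overlap -> results/maps/
Rscript analysis/04_clinical_stats.R # volumes, tables, heat maps -> results/stats/
```

Output of stages 3-4 on the default cohort (seed 20260929):

```
TIS: 1724 voxels in 2 cluster(s); reverse direction: 0 voxels
  label   x_mm  y_mm   z_mm size_voxels size_ml peak_z
1         3.75  24.8   0.75        1722 5.81175   9.04
2       -12.75 -27.8 -17.25           2 0.00675   2.93
DSA: 2596 voxels
TIS/DSA overlap: 1610 voxels
Dice(TIS, implanted sphere): 0.805
Dice(overlap, implanted sphere): 0.814

TIS GM volume percent-change difference (treated - placebo): 2.31 +/- 0.37 %
annualized whole-GM loss: treated 0.51 %, placebo 1.33 %
treated arm: corr(TIS change, PASAT2 change) = 0.86; corr(TIS change, CSF change) = -0.87
```

Reading this: the sparing-direction map recovers the implanted 10 mm
sphere (Dice 0.81) as one dominant cluster of 5.8 ml peaking at Z = 9.0,
with nothing in the reverse (placebo-spared) direction; the score-linked
DSA overlaps it almost entirely; GM inside the derived TIS declines ~2.3
percentage points less in the treated arm; and in the treated arm,
subjects whose TIS volume was preserved improved more on the PASAT2 and
expanded less in CSF — the sign structure the construct is meant to
exhibit.

The same run is available as a single call:

```r
library(vbmsparing)
run_pipeline(list(out_dir = "results/run", seed = 20260929,
                  sim = list()))   # defaults; writes a JSON manifest
```

Or step by step:

```r
cohort <- generate_cohort(simulation_config(seed = 1))
smoothed <- smooth_cohort(cohort, fwhm_mm = 8)
tis <- compute_tis(smoothed, q = 0.05)
dsa <- compute_dsa(smoothed, score_column = "pasat2")
ov  <- tis_dsa_overlap(tis, dsa)
dice(tis$mask, cohort$ground_truth$effect_1)
```

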