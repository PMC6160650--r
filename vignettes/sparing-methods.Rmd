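---
title: "Localizing treatment-induced gray-matter sparing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing treatment-induced gray-matter sparing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In relapsing-remitting multiple sclerosis, gray matter (GM) atrophies
progressively and the loss correlates with cognitive decline. A
neuroprotective treatment should slow that loss, and — if cognition is
served by particular cortex — slow it *where it matters*. Voxel-based
morphometry (VBM) makes this testable: tissue-volume ("modulated") GM maps
from all subjects and visits live on a common voxel grid, and a
mass-univariate model at every voxel asks whether the treated arm loses
less GM there than the placebo arm.

`vbmsparing` implements the statistical half of such a trial analysis as a
reusable, fully tested pipeline:

1. a **synthetic cohort generator** producing longitudinal modulated GM
   maps with known effect geometry and a clinical score coupled to a chosen
   region — so every downstream stage can be validated against ground
   truth;
2. **image operations**: NIfTI I/O, Gaussian smoothing, white-matter-lesion
   in-painting, voxel/ml/world-coordinate conversions;
3. a **voxelwise general linear model** with subject, site and global-GM
   nuisance terms, contrast t/Z/p maps;
4. **inference**: Benjamini-Hochberg FDR over in-mask voxels, 3D
   connected-component cluster tables, region overlap;
5. the **headline constructs**: the treatment-induced-sparing region (TIS),
   the longitudinal cognitive disability-specific atlas (DSA), their
   overlap, and per-subject region-volume series;
6. **clinical statistics**: change tables, group-difference regressions,
   Pearson matrices with average-linkage heat-map ordering, baseline
   comparisons.

Tissue segmentation, bias correction and nonlinear registration are out of
scope: the generator emits data as they stand *after* that preprocessing.

# The voxelwise model

For scan $i$ (subject $s(i)$, site $k(i)$, time $t_i$ in years) and voxel
$v$, the default design is

$$ y_{iv} \;=\; \sum_s \alpha_{sv}\,[s(i)=s] \;+\; \sum_k \gamma_{kv}\,[k(i)=k]
\;+\; \tau_v\, t_i \;+\; \beta_v\, t_i\,[\text{treated}] \;+\; \eta_v\, g_i
\;+\; \varepsilon_{iv}, $$

with intercept-free subject indicators (absorbing anatomy, age, group
membership — anything subject-constant), reference-coded site indicators,
a common time trend $\tau_v$, the group-by-time interaction $\beta_v$ —
the annualized difference in GM change between arms, the effect of
interest — and $g_i$, the scan's mean GM over the brain mask.

Because site is constant within subject, the site columns lie in the span
of the subject columns; the fit uses the Moore-Penrose pseudoinverse (thin
SVD), the numerical rank sets the residual degrees of freedom
$\nu = n_{\text{scans}} - \mathrm{rank}(X)$, and every contrast is checked
for estimability against the design's row space. One-sided contrasts are
carried in both directions (sparing and its reverse), each through its own
FDR family, because the scientific claim is directional.

## Global normalization

The global covariate $g_i$ is the ANCOVA form of global normalization that
is standard practice for modulated VBM data. It matters here for a
structural reason: the two arms differ in their *brain-wide* atrophy rate
(0.5 vs 1.5 %/year under the generator defaults), so without $g_i$ every
voxel carries a small arm-difference signal. An adaptive step-up procedure
over ~50,000 voxels then cascades: once the genuinely spared cluster is
declared, the threshold relaxes and the near-threshold brain-wide
background floods the map (we observed exactly this during development —
no homoscedastic heterogeneity level separates a 3 %/yr sphere from a
1 %/yr uniform background under step-up FDR). With $g_i$ in the model the
interaction map reads "sparing *beyond* the brain-wide difference", the
background mean sits at zero, and the localized effect is recovered
cleanly. The covariate is on by default in `compute_tis()`/`compute_dsa()`
and can be disabled (`global_normalization = FALSE`); `build_design()`
also accepts the plain subject+site design.

## Nonsphericity

Longitudinal residuals are correlated within subject. The default scheme
is ordinary least squares with classical $\nu = n - \mathrm{rank}$, which
is exact when residuals are iid and approximate otherwise; an optional
`scheme = "exchangeable"` estimates a single global within-subject
correlation by pooled method of moments over in-mask voxels and whitens
both sides of the model. Full restricted-maximum-likelihood covariance
components estimation (as in SPM) is deliberately not implemented: the
transparent schemes keep the inference auditable, and the validation suite
runs under the default. The p-uniformity test in the suite uses an iid
null for exactly this reason.

# Inference

**FDR.** `fdr_bh()` is a direct implementation of the step-up rule: over
the $m$ in-mask p-values, find the largest $k$ with
$p_{(k)} \le k\,q/m$ and declare everything at or below $p_{(k)}$. It is
cross-checked in the tests against `stats::p.adjust` and an independent
exhaustive-scan oracle. Smoothed maps are positively dependent, the regime
in which step-up control is known to hold.

**Clusters.** Significant voxels are grouped by 26-connectivity by default
(faces, edges, corners — the SPM-like convention; 6 and 18 are available).
Each cluster is reported with voxel count, volume in ml
(`voxels_to_ml`: count x voxel volume / 1000; 3.375 mm³ per voxel at the
1.5 mm grid), the world (mm) coordinate of its peak Z, and the peak Z.
Peak ties break at the smallest linear index. Cluster tables are sorted by
size, mirroring the conventional trial report.

**Constructs.** The TIS is the union of sparing-direction clusters; the
DSA is the union of positive-direction clusters of the score partial
correlation $r = t/\sqrt{t^2+\nu}$ (positive = more GM goes with a better
score); the overlap is their voxelwise intersection, clustered with peaks
from the TIS map. GM volume inside any mask is integrated per scan on the
*unsmoothed* cohort so volumes are physical; per-subject change, percent
change and annualized percent change are all emitted (the distinction
matters only for designs longer than 12 months, but both are reported
since trial write-ups are ambiguous about which is printed).

Deriving the TIS on a cohort and then measuring per-subject volumes in
that same TIS is circular by construction — the selected voxels are those
where the arms differ most, so the group difference measured inside the
mask is biased away from zero. The trial design this mirrors has the same
property. The synthetic tests therefore also report volumes in the
*ground-truth* mask, which quantifies that bias (about +0.1 to +0.5
percentage points under defaults, depending on how far the derived mask
extends beyond the true sphere).

# The synthetic cohort

Per voxel $v$, subject $s$, month $t$:

$$ \mathrm{GM}(s,v,t) = T(v)\,(1+a_s)\Big(1 - r_s(v)\tfrac{t}{12} +
\mathrm{spare}(v)\,[\text{treated}]\tfrac{t}{12}\Big) + b_{k(s)} +
\varepsilon_{svt}, $$

clipped to $[0,1]$ (the clipping fraction is recorded and is ~0 under
defaults). $T$ is a deterministic ellipsoidal template with a cortex-like
shell and deep-GM core; the brain mask is the ellipsoid interior
(~49,600 voxels, ~167 ml at 1.5 mm — a deliberately small desk-scale
brain). $a_s \sim N(0, 0.1^2)$ scales anatomy multiplicatively;
$b_k \sim N(0, 0.01^2)$ is an additive site bias; $\varepsilon$ is iid
voxel noise (SD 0.02).

The atrophy-rate field decomposes as

$$ r_s(v) = r_{\text{arm}} + g_s + f_s(v), $$

with arm rates 0.015/0.005 per year (placebo/treated), a global
per-subject deviation $g_s \sim N(0, 0.02^2)$, and a spatially smooth
per-subject field $f_s$ (SD 0.012/yr, correlation FWHM 12 mm, generated by
smoothing white noise and rescaling over the mask). This split is the
load-bearing modeling choice, made once during design:

* the **global** component makes the whole-GM arm comparison borderline at
  trial size — the regime such trials actually sit in — without inflating
  any single voxel's evidence;
* the **local** component gives each subject regionally idiosyncratic
  atrophy, which is what lets a clinical score coupled to one region
  correlate with GM change *there* rather than brain-wide, and is what
  makes the DSA localizable at all.

Sparing is a binary sphere (default: 10 mm radius, 0.02/yr extra sparing
for the treated arm), so the true arm difference inside it is 3 %/yr
(1 % global + 2 % local), matching the scale of the percent-difference
headline such a trial prints.

Clinical scores: each subject draws a PASAT2-like baseline
($N(42, 12^2)$, the published trial's distribution) and a PASAT3-like
baseline ($N(51, 9^2)$); at each visit the score is baseline +
slope x (noise-free mean GM change in the eloquent region) + visit noise,
clipped to the instrument range $[0, 60]$. Defaults: slope 600 points per
unit fractional GM change, visit noise SD 0.5. The eloquent region
defaults to the sparing sphere (the coupled scenario); pointing it at a
disjoint sphere produces the decoupled scenario in which the TIS/DSA
overlap is empty. The ceiling matters: subjects near 60 compress, which
attenuates naive slope regression — the slope-recovery test uses a
ceiling-free baseline, and the generator exposes the baseline parameters
precisely because the variance components are order-of-magnitude choices,
not published quantities.

Outcome analogues (WM, CSF, lesion volumes, 9HPT, T25FW, MSFC, EDSS) are
scalar series at trial-typical means; CSF expands to fill what whole GM
loses (volume conservation), the rest are uncoupled noise. They exist so
the change-table and correlation-matrix machinery runs on realistic
columns; only the GM-coupled signs are scientifically meaningful.

One global seed is split into fixed per-stage substreams (anatomy, noise,
lesions, scores, outcomes), so enabling lesions does not perturb anatomy
draws, and a fixed seed reproduces the cohort bitwise.

**What the generator does not emulate:** scanner physics (bias fields,
k-space noise), registration error, segmentation failure, longitudinal
dropout, non-Gaussian atrophy heterogeneity, practice effects on
cognition. Passing recovery tests on this generator therefore shows the
*statistical machinery* is sound — it does not certify performance on real
multi-site MRI.

# Image operations

Smoothing is separable Gaussian convolution with
$\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$ per axis in voxel units, reflect
padding at the boundary (avoids edge dimming; the impulse response and a
dense full-kernel convolution oracle pin it down in the tests), kernels
truncated at $4\sigma$. Axis-aligned affines only — sheared grids are
rejected rather than mishandled.

Lesion in-painting is the distributional fill: each lesion voxel is
replaced by a draw from a Gaussian fitted to the normal-appearing
reference tissue (mean and SD of the reference voxels), deterministic
under its seed, touching nothing outside the lesion mask. The pipeline
order is fixed as in-paint, then smooth — in-painting exists to keep
lesion intensities from contaminating the statistics, so it must precede
the operation that spreads them.

Volumes are written as NIfTI-1 (float32; masks uint8) with the affine in
the sform; on read, a header pixdim that disagrees with the affine's
column norms by more than 1e-3 mm draws a warning and the affine wins.
Voxel indices are 0-based in world-coordinate arithmetic (world = affine
x [i-1, j-1, k-1, 1] from R's 1-based arrays), so reported peaks are
signed mm coordinates in the usual convention.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `fwhm_mm` | 8 | mm | the conventional VBM smoothing kernel |
| `q` | 0.05 | — | FDR level used throughout |
| `connectivity` | 26 | — | SPM-like cluster adjacency |
| `score_column` | `pasat2` | — | the score with the broader disability continuum |
| `atrophy_rate_placebo/treated` | 0.015 / 0.005 | fraction/yr | arm-level annualized GM loss |
| sparing | 0.02 | fraction/yr | extra treated-arm sparing in the effect sphere |
| `rate_sd` | 0.02 | fraction/yr | global per-subject rate heterogeneity |
| `rate_field_sd`, `rate_field_fwhm_mm` | 0.012, 12 | fraction/yr, mm | local rate heterogeneity and its correlation length |
| `score_slope`, `score_noise_sd` | 600, 0.5 | pts per unit change, pts | clinical coupling strength and visit noise |
| `noise_sd` | 0.02 | GM units | voxelwise measurement noise |

# Validation protocol and problem sizes

The test suite checks every operation against an independent oracle
(per-voxel `lm`, exhaustive BH scan, dense convolution, closed forms,
hand-computed 2x2 chi-square) and runs recovery protocols sized for a
single desk CPU:

* TIS recovery: 20 replicate trials at n=30/arm on the default grid —
  Dice against the implanted sphere ≥ 0.5 in ≥ 80 % of replicates, reverse
  direction empty in the median;
* TIS/DSA overlap: 10 replicates at n=60/arm (the DSA needs the larger
  cohort; its information is the within-arm local heterogeneity after
  global partialling) — overlap Dice ≥ 0.5 in ≥ 70 %; plus decoupled
  replicates with a disjoint eloquent region, median overlap 0;
* FDR validity: 200 fully-null replicate cohorts (equal rates, no effect
  regions, decoupled score) on a reduced 24x28x24 grid at n=8/arm — mean
  false-discovery proportion ≤ q within twice the Monte-Carlo SE;
* sign structure: treated-arm correlation of TIS-volume change with PASAT2
  change positive, and with CSF change negative, in ≥ 90 % of replicates.

Module tests use further-reduced cohorts (stronger spheres, smaller
grids); the sizes above are the package's validation design, chosen to
make each check statistically meaningful at interactive runtimes.

# Numerical choices and degenerate inputs

* Rank-deficient designs from site-within-subject nesting are expected and
  handled by pseudoinverse; any *other* deficiency (e.g. a score collinear
  with time) is an error naming the offending columns.
* Zero-variance voxels are flagged and excluded from inference (their maps
  are NA).
* Z is computed from the one-sided p on the log scale, so extreme t keeps
  a finite, accurate Z.
* `fdr_bh` on an all-ones p-vector declares nothing; an empty mask is an
  error, an empty significance mask yields an empty cluster table.
* A constant image smooths to itself exactly; interior-supported mass is
  conserved to 1e-6.
* Scores clipped at the instrument range; generated GM clipped to [0,1]
  with the fraction reported.
* Subjects missing either endpoint are excluded from volume-change series
  with a message.

# Known limitations

* OLS p-values are approximate under within-subject correlation and
  random atrophy slopes; the exchangeable scheme is a first-order remedy,
  not a substitute for full covariance-component estimation.
* The DSA is underpowered at n=30/arm under default coupling — a real
  effect of the design, not a bug; the overlap construct (gated by the
  TIS) remains recoverable there.
* With global normalization, "sparing" is relative to the brain-wide arm
  difference; a treatment that spared the whole brain uniformly would, by
  construction, produce an empty TIS. On small grids with strong localized
  effects the reverse contrast can show a mild anti-sparing halo for the
  same reason.
* Anatomic labels in cluster tables are free text; no atlas is bundled.
* Whole-GM group comparisons on the synthetic cohort are somewhat more
  significant than in a real trial of this size, because the generator's
  heterogeneity is Gaussian and its brain is small; the voxelwise regime
  is calibrated, the scalar summaries are caricatures.
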