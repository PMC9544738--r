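# seedprint

Seed-based resting-state connectivity fingerprinting of task-defined
brain regions, with a fully synthetic fMRI cohort generator for
ground-truth validation.

## The problem

Resting-state functional connectivity can show that a seed region — here
the dorsal anterior cingulate cortex (dACC) — is coupled to frontoparietal
cortex in the neighbourhood of the regions recruited for intuitive
physical inference. The sharper question is whether the seed's strongest
connections *precisely target* those regions: do they track the
individual-specific positioning of physics-related activity, subject by
subject? `seedprint` implements the full analysis chain for that
question:

- **Volume/atlas plumbing** — NIfTI-1 IO (via RNifti), parcel atlases with
  functional roles, motion tables, ROI timeseries extraction.
- **Rest preprocessing** — Gaussian smoothing, zero-phase Butterworth
  band-pass (0.009–0.08 Hz), framewise-displacement censoring, motion +
  white-matter + ventricle nuisance regression, removal of the ACC
  parcels' common variance.
- **Seed connectivity** — voxelwise Pearson `r` with the dACC mean series,
  Fisher z-transform `z = atanh(r)`, group one-sample t-tests, Monte-Carlo
  cluster-extent correction with self-consistent smoothness matching.
- **Task GLM** — 23-block palindromic physics/colour design, gamma HRF
  `h(t) = (t/pq)^p e^(p − t/q)` peaking at 4.7 s, voxelwise OLS, the
  physics−colour contrast.
- **The two bespoke analyses** — the percentile-threshold overlap curve
  (99.00–99.95 in 0.05 steps, 20 levels) and the within/between-subject
  spatial-correlation MVPA,
  `within_i = atanh r(conn_i, contrast_i)` vs
  `between_i = mean_{j≠i} atanh r(conn_i, contrast_j)`,
  tested with a repeated-measures ANOVA, plus split-half reliability and a
  motion-confound check.
- **A synthetic cohort generator** whose subjects carry a planted,
  subject-specific displacement of their physics-responsive voxels shared
  between rest connectivity and task activation — known ground truth for
  every stage.

Results come back as tibbles that pipe into dplyr/ggplot2 (`autoplot()`
methods for curves and fingerprint tables, `tidy()`/`glance()` for fitted
objects).

## Worked example

```r
library(seedprint)

cohort <- make_cohort(cohort_params(master_seed = 42L))
result <- fingerprint_pipeline(cohort)
result
#> <fingerprint_result> 8 subjects x 4 regions; mean within-between gap 0.520 (z)
#> <rm_anova>
#>   condition            F(1, 7) = 383.179, p = 2.267e-07
#>   region               F(3, 21) = 3.713, p = 0.02751
#>   condition:region     F(3, 21) = 1.286, p = 0.3052

identification_rate(result)
#> [1] 1
result$motion_check$r
#> [1] 0.1583459
```

Each subject's resting dACC connectivity correlates far better with their
*own* task contrast (mean within-z 0.566) than with other subjects'
contrasts (mean between-z 0.046): the condition effect F(1, 7) = 383 says
the planted connectivity fingerprint was recovered, and every subject is
identifiable from their connectivity map alone (identification rate 1.0).
The motion check (r = 0.16 across 8 subjects) shows the gap does not
track head motion. `autoplot(result$table)` draws the paired
within/between points per region;
`autoplot(group_overlap_analysis(cohort))` draws the percentile-overlap
curve.

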