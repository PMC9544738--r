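---
title: "Connectivity fingerprinting of task-defined regions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity fingerprinting of task-defined regions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedprint)
```

## The scientific question

Seed-based resting-state functional connectivity asks which voxels'
spontaneous BOLD fluctuations track a seed region's mean timeseries. This
package implements a specific, stronger form of that analysis: a
*connectivity fingerprint* test. The seed is the dorsal anterior cingulate
cortex (dACC), and the question is whether its strongest resting
connections do not merely land in the neighbourhood of the frontoparietal
regions recruited for intuitive physical inference, but precisely target
each individual's own physics-responsive voxels. Three analyses carry that
claim:

1. **Percentile-overlap curve.** The group connectivity map is thresholded
   at increasingly stringent percentiles (99.00 to 99.95 in steps of 0.05,
   20 levels) within a frontoparietal search mask, and the proportion of
   suprathreshold voxels falling inside the task-defined physics parcels is
   recorded per level. Precise targeting predicts the proportion rises with
   stringency, approaching 100%.
2. **Within/between-subject spatial-correlation MVPA.** For each subject,
   the spatial (across-voxel) correlation between their dACC connectivity
   map and their own task contrast (*within*) is compared with the average
   correlation against every other subject's contrast (*between*),
   region by region. A repeated-measures ANOVA on Fisher-z values tests the
   condition (within vs between) effect.
3. **Split-half reliability.** Individual differences are only meaningful
   if they are stable: each subject's rest run is split in half, and the
   agreement between a subject's two half-run connectivity maps (within) is
   compared to the agreement with other subjects' maps (between), per
   hemisphere.

Real resting-state cohorts for this design are not freely available, so
the package ships a synthetic cohort generator with planted ground truth:
every stage is verifiable by parameter recovery at desk scale.

## The generative model

`make_cohort()` draws, per subject $i$, a rigid integer-voxel displacement
$d_i \sim \mathcal{N}(0, \sigma_d^2 I_3)$ (rounded to voxels, clamped to
the parcel margins). The *same* $d_i$ determines where that subject's
physics-responsive voxels sit in rest and in task — this shared placement
is the planted fingerprint the pipeline must recover.

Rest runs: every voxel carries stationary AR(1) noise,
$\varepsilon_t = \phi\,\varepsilon_{t-1} + \eta_t$ with
$\eta_t \sim \mathcal{N}(0, \sigma^2)$, so the stationary SD is
$\sigma_\mathrm{eff} = \sigma/\sqrt{1-\phi^2}$. The dACC voxels share a
unit-variance latent $s(t)$; the displaced physics cores carry
$a\,s(t)$; white-matter and ventricle compartments carry their own shared
confounds, leaking with weight $0.2a$ into all brain voxels (large enough
that skipping nuisance regression measurably biases the correlations,
small enough not to swamp the fingerprint). At a planted voxel the
population correlation with the seed is

$$ r = \frac{a}{\sqrt{a^2 + \sigma_\mathrm{eff}^2}}, $$

which the test suite and acceptance script verify empirically to within
±0.03 at $T = 10^4$.

Task runs: a 23-block palindromic design (three rest blocks at positions
1, 12 and 23; ten physics and ten colour blocks of 18 s, each holding two
1-s cue / 6-s movie / 2-s response repetitions; 414 s, 207 volumes at TR
2 s). The displaced cores respond with amplitude $\beta$ to the
HRF-convolved physics-cue regressor; a fixed disjoint control set responds
to the colour cue.

Default conditions: 8 subjects, a $20^3$ grid at $3 \times 3 \times
3.5$ mm, two 150-volume rest runs (5 min at TR 2 s) and two task runs per
subject, $a = 0.5$, $\beta = 1$, $\sigma = 1$, $\phi = 0.3$,
$\sigma_d = 6$ mm, motion-spike rate 0.01/volume. The rest-run length is
inferred from the 5-minute duration and the 2-s TR. $\phi = 0.3$ mimics
fMRI temporal autocorrelation at TR 2 s. Displacements are rigid
integer-voxel shifts without interpolation so the planted ground truth
stays exact.

What the generator does *not* emulate: haemodynamic nonlinearity,
physiological noise, susceptibility artefacts, imperfect alignment
(volumes are generated pre-aligned on one grid; there is no resampling,
and grid mismatches are errors), per-subject atlas variability, or image
artefacts of head motion (motion enters only through the parameter tables
and censoring logic). Passing recovery tests therefore shows the
*analysis* is correct and well calibrated, not that it would survive all
the failure modes of real scanner data.

## Preprocessing

The rest chain (defaults in `preproc_config()`): 4-mm FWHM Gaussian
smoothing; zero-phase order-2 Butterworth band-pass, 0.009–0.08 Hz;
censoring of volumes with framewise displacement above 2 mm (3 mm for
task); nuisance regression of the six motion parameters, their backward
differences, and the white-matter and ventricle mean series; and removal
of the ACC parcels' common variance so each parcel's connectivity reflects
its unique signal.

Choices that a verbal description of such a pipeline leaves open, and
what this package does:

* **The censoring metric.** "Millimetres of movement" is not by itself a
  defined scalar; we use framewise displacement with rotations converted
  to arc length on a 50-mm sphere — standard practice, monotone in all
  six parameters.
* **Censoring vs filtering order.** Censoring after filtering (the
  default) preserves the regular sampling the temporal filter assumes;
  `censor_first = TRUE` provides the other order. The nuisance regressors
  are band-passed with the same filter and censored with the same index,
  so regression cannot reintroduce filtered frequencies.
* **"Common variance" of the ACC parcels** is the mean of the eight
  parcel-mean series (simplest shared component); a first-principal-
  component variant is available via `method = "pc1"`.
* **HRF form.** The haemodynamic response is specified only by its 4.7-s
  peak; we use the gamma variate $h(t) = (t/pq)^p e^{p - t/q}$ with
  $p = 8.6$, $q = 0.547$, whose peak value 1 falls at $pq = 4.70$ s.
* **Cue-only regressors.** Condition regressors model the 1-s cue events
  only (the literal reading of the task description); movie and response
  variance stays in the residual. Because the second cue of each block
  starts 9 s into an 18-s block, it falls off the 2-s TR grid, so boxcars
  are sampled by fractional overlap of each TR interval — exact for
  on-grid events.
* **Prewhitening** is omitted: OLS point estimates are unbiased under AR
  noise, and the fingerprint analysis uses contrast estimates, not their
  standard errors.

## Group inference and cluster correction

Per-subject correlation maps are Fisher-z transformed (|r| clipped to
$1 - 10^{-7}$) and combined with voxelwise one-sample t-tests. Cluster
correction is Monte-Carlo: null white-noise fields are smoothed, masked,
standardized and thresholded exactly like the data, and the $(1-\alpha)$
quantile of their maximum cluster sizes (6-connectivity; positive and
negative clusters separate, since the primary threshold is two-sided)
sets the minimum surviving extent.

Smoothness is estimated by the derivative-variance (Forman-type)
estimator, $\mathrm{FWHM} = \Delta\sqrt{4\ln 2\,\hat\sigma^2 /
\widehat{\mathrm{var}}(\nabla)}$, per axis. On a discrete grid this
estimator is biased upward at small kernel widths, so `cluster_correct()`
inverts the estimator's own expectation (through the discrete sampled-
kernel autocorrelation) when choosing the simulation smoothing width: the
null fields then match the *measured* smoothness of the data, making the
correction self-consistent. The familywise error calibration experiment
(`cluster_fwe_experiment()`) uses a $16^3$ grid with 8-mm effective
smoothness (about 2.5 voxels, a realistic effective smoothness for
4-mm-smoothed data riding on intrinsic spatial correlation); at much
smaller smoothness the null maximum-cluster distribution on a small grid
is so discrete that no extent threshold attains a level near 0.05.

Two further choices: the primary threshold is two-sided (connectivity maps
carry meaningful negative correlations), and the percentile sweep runs
99.00–99.95 — a sweep through the 100th percentile would give 21 levels
whose last retains at most one voxel, while 20 levels keeps every level
nonempty and matches the stated number of datasets.

**Group overlap statistic.** The percentile sweep operates on the group
*mean Fisher-z* map rather than the group t map. At small n the extreme
upper tail of a t map is dominated by voxels whose between-subject
variance happens to be tiny, not by strong connectivity, which destroys
the interpretability (and monotonicity) of the most stringent levels; the
mean-z map is the faithful group summary of connectivity strength. The t
map remains available via `statistic = "t"`.

## The fingerprint analyses

`within_between_table()` computes, for subject $i$ and region $R$,

$$ \mathrm{within}_{iR} = \operatorname{atanh} r\!\left(c_i, k_i; R\right),
\qquad
\mathrm{between}_{iR} = \frac{1}{n-1}\sum_{j \ne i}
  \operatorname{atanh} r\!\left(c_i, k_j; R\right), $$

where $c_i$ is the connectivity z-map, $k_j$ a contrast map, and $r(\cdot)$
the Pearson correlation across voxels in $R$. Correlations are Fisher-z
transformed *before* averaging, uniformly across both the MVPA and the
split-half analysis. The four regions are the task-defined physics voxels
(group t, positive tail, $p < 0.001$) intersected with the four physics
parcels; when an intersection is smaller than 10 voxels the whole parcel
is used instead (recorded in an attribute) — with purely subject-specific
planted activation at $n = 8$ the group map is often sparse, and the MVPA
conclusion does not depend on the restriction.

`rm_anova()` fits the classical subject-as-random-block decomposition via
`stats::aov` with an `Error(subject/(condition*region))` stratum; each
effect is tested against its own subject-interaction error term. The
reported degrees of freedom follow from this layout (condition:
$F_{1,n-1}$); the test suite checks the F statistics against an
independent brute-force sums-of-squares decomposition. A stronger
identity claim — each subject's connectivity map best matches their *own*
contrast (argmax over subjects) — is reported by `identification_rate()`.

The motion-confound check correlates per-subject mean framewise
displacement with the per-subject mean fingerprint gap
($\mathrm{within} - \mathrm{between}$); planted coupling drives this
correlation above 0.9 in tests, while the default generator (motion
independent of identity) keeps it near zero.

## Numerical choices and degenerate inputs

* Non-finite voxels are rejected at read/construction time rather than
  propagated; every downstream statistic assumes finite data.
* Constant voxel series map to $r = 0$ with a logged count; a constant
  *seed* is an error.
* Zero-variance voxels in a group t-test get sentinels (signed infinity,
  or NaN when all values are zero) and are excluded from clusters.
* The band-pass operator removes the DC component exactly before
  filtering, so constant series map to zero without edge transients; the
  zero-phase (forward–backward) filter is applied as a cached $T \times T$
  operator, letting whole volumes filter as one matrix product.
* Percentile thresholds use the default quantile definition (type 7), so
  1000 distinct values thresholded at the 99th percentile retain exactly
  the top 10.
* All randomness flows from explicit seeds: cohorts are bit-reproducible
  from `master_seed`, and per-run seeds are recorded in the cohort
  manifest.

## Problem sizes

The replicated experiments use 20 cohorts of 8 subjects on a $20^3$ grid
(recovery and null calibration), 20 cohorts of 10 subjects with one rest
run for the split-half power analogue, and 200 null studies of 200
Monte-Carlo simulations each for the familywise-error calibration; these
sizes give binomial confidence intervals tight enough to distinguish the
claimed rates while keeping a full run on a laptop in the tens of
minutes.

## Known limitations

* The toy atlas is shared across subjects; mapping a real parcellation to
  individual anatomy (and everything upstream: despiking, slice-time
  correction, coregistration, template warping) is out of scope — the
  hooks are no-ops and volumes must arrive pre-aligned.
* Monte-Carlo cluster correction assumes Gaussian-shaped spatial
  autocorrelation; heavy-tailed spatial ACFs in real data are known to
  make such corrections optimistic, and no ACF-based model is provided.
* With purely subject-specific activation and small n, task-region
  definition by group significance is conservative (see the fallback
  above).
* Absolute F ratios, overlap percentages and suprathreshold voxel counts
  measured on real cohorts depend on the data themselves and are not
  reproduction targets; the package's claims are structural — recovery,
  calibration, and the design constants.
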