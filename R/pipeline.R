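#' Seed connectivity map(s) for one subject's rest runs
#'
#' Runs the full rest preprocessing chain on each run, extracts the dACC
#' seed series (union of the left and right dACC parcels by default, or a
#' single hemisphere), correlates it with every voxel, Fisher-transforms,
#' and averages the z maps across runs.
#'
#' @param subject One element of a [make_cohort()]'s `subjects` list.
#' @param atlas The cohort atlas.
#' @param config A [preproc_config()].
#' @param hemisphere `"both"`, `"L"`, or `"R"`.
#' @return List: `zmap` (`stat_map` kind `z`), `mean_fd_mm`, `n_censored`.
#' @export
subject_connectivity <- function(subject, atlas, config = preproc_config(),
                                 hemisphere = "both") {
  dacc <- dacc_labels(atlas)
  ids <- switch(hemisphere, both = dacc, L = dacc["L"], R = dacc["R"])
  per_run <- lapply(subject$rest, function(run) {
    pp <- preprocess_rest(run$vol, run$motion, atlas, config)
    seed <- rowMeans(vapply(ids, function(id) {
      roi_mean_timeseries(pp$vol, atlas, id)
    }, numeric(n_volumes(pp$vol))))
    rmap <- seed_connectivity(pp$vol, seed, source = subject$profile$subject_id)
    list(z = fisher_z(rmap), fd = mean(pp$fd), n_censored = pp$n_censored)
  })
  list(
    zmap = average_stat_maps(lapply(per_run, `[[`, "z")),
    mean_fd_mm = mean(vapply(per_run, `[[`, numeric(1), "fd")),
    n_censored = sum(vapply(per_run, `[[`, numeric(1), "n_censored"))
  )
}

#' Physics-minus-colour contrast for one subject
#'
#' Fits each task run separately (condition cue regressors plus motion
#' nuisance columns, motion-censored at the task threshold) and averages
#' the two runs' contrast maps.
#'
#' @param subject One element of a cohort's `subjects` list.
#' @param design The cohort [build_block_design()].
#' @param censor_threshold_mm Task censoring threshold (3 mm).
#' @param concatenate Fit one GLM on the concatenated runs instead of
#'   averaging per-run contrasts.
#' @return A `stat_map` of kind `contrast`.
#' @export
subject_contrast <- function(subject, design, censor_threshold_mm = 3,
                             concatenate = FALSE) {
  runs <- subject$task
  prep <- lapply(runs, function(run) {
    X <- cbind(convolve_design(design),
               motion_regressors(run$motion, derivatives = TRUE))
    fd <- framewise_displacement(run$motion)
    cen <- censor_volumes(run$vol, fd, censor_threshold_mm)
    list(vol = cen$vol, X = X[cen$kept, , drop = FALSE])
  })
  if (concatenate) {
    mats <- lapply(prep, function(p) volume_matrix(p$vol))
    vol <- matrix_volume(do.call(rbind, mats), prep[[1]]$vol)
    X <- do.call(rbind, lapply(prep, `[[`, "X"))
    fit <- fit_glm(vol, X, source = subject$profile$subject_id)
    return(physics_minus_colour(fit))
  }
  maps <- lapply(prep, function(p) {
    physics_minus_colour(fit_glm(p$vol, p$X,
                                 source = subject$profile$subject_id))
  })
  average_stat_maps(maps)
}

#' Task-defined region masks
#'
#' The group-significant physics voxels (one-sample t over subjects'
#' contrast maps, positive tail at the primary threshold) intersected with
#' each of the four physics parcels. A parcel whose intersection has fewer
#' than `min_voxels` voxels falls back to the whole parcel (recorded in the
#' `fallback` attribute) so the spatial correlations stay defined.
#'
#' @param contrast_maps List of per-subject contrast `stat_map`s.
#' @param atlas The cohort atlas.
#' @param voxel_p Primary threshold for the group t (one-sided).
#' @param min_voxels Minimum usable region size.
#' @return Named list of 3D logical masks
#'   (`frontal_L`, `frontal_R`, `parietal_L`, `parietal_R`).
#' @export
physics_region_masks <- function(contrast_maps, atlas, voxel_p = 0.001,
                                 min_voxels = 10) {
  tmap <- group_ttest(contrast_maps)
  tthr <- qt(1 - voxel_p, tmap$df)
  tv <- tmap$data
  tv[is.nan(tv)] <- 0
  sig <- tv >= tthr
  phys <- atlas$table[atlas$table$role == "physics", ]
  fallback <- character(0)
  masks <- lapply(seq_len(nrow(phys)), function(i) {
    parcel <- atlas$labels == phys$label_id[i]
    m <- sig & parcel
    if (sum(m) < min_voxels) {
      fallback <<- c(fallback, phys$name[i])
      m <- parcel
    }
    m
  })
  names(masks) <- sub("^physics_", "", phys$name)
  attr(masks, "fallback") <- fallback
  masks
}

#' Full connectivity-fingerprint pipeline on a cohort
#'
#' Per subject: rest preprocessing and dACC seed connectivity (z maps
#' averaged over runs) and the task physics-minus-colour contrast (averaged
#' over runs). Group level: task-defined region masks, the
#' within/between-subject fingerprint table, its repeated-measures ANOVA
#' (condition x region), and the motion-confound correlation.
#'
#' @param cohort A [make_cohort()] result.
#' @param config A [preproc_config()].
#' @param region_p Primary threshold defining the task regions.
#' @return List of class `fingerprint_result`: `table`
#'   (`fingerprint_table`), `anova` (`rm_anova`), `motion_check`,
#'   `conn_maps`, `contrast_maps`, `region_masks`.
#' @export
fingerprint_pipeline <- function(cohort, config = preproc_config(),
                                 region_p = 0.001) {
  ids <- vapply(cohort$subjects, function(s) s$profile$subject_id, character(1))
  conn <- lapply(cohort$subjects, subject_connectivity, atlas = cohort$atlas,
                 config = config)
  conn_maps <- setNames(lapply(conn, `[[`, "zmap"), ids)
  mean_fd <- setNames(vapply(conn, `[[`, numeric(1), "mean_fd_mm"), ids)
  contrast_maps <- setNames(
    lapply(cohort$subjects, subject_contrast, design = cohort$design),
    ids
  )
  region_masks <- physics_region_masks(contrast_maps, cohort$atlas,
                                       voxel_p = region_p)
  table <- within_between_table(conn_maps, contrast_maps, region_masks,
                                mean_fd = mean_fd)
  structure(
    list(
      table = table,
      anova = rm_anova(table),
      motion_check = motion_confound_check(table),
      conn_maps = conn_maps,
      contrast_maps = contrast_maps,
      region_masks = region_masks
    ),
    class = "fingerprint_result"
  )
}

#' @export
print.fingerprint_result <- function(x, ...) {
  gap <- mean(x$table$within_z) - mean(x$table$between_z)
  cat(sprintf("<fingerprint_result> %d subjects x %d regions; mean within-between gap %.3f (z)\n",
              length(unique(x$table$subject)),
              length(unique(x$table$region)), gap))
  print(x$anova)
  invisible(x)
}

#' Subject identification rate
#'
#' The fraction of subjects whose own contrast map is the best spatial
#' match (argmax over candidate subjects) for their connectivity map,
#' averaged over regions — a stronger form of the within > between claim.
#'
#' @param result A [fingerprint_pipeline()] result.
#' @return Proportion in [0, 1].
#' @export
identification_rate <- function(result) {
  subjects <- names(result$conn_maps)
  hits <- 0
  total <- 0
  for (rg in names(result$region_masks)) {
    mask <- result$region_masks[[rg]]
    for (i in subjects) {
      rs <- vapply(subjects, function(j) {
        spatial_correlation(result$conn_maps[[i]],
                            result$contrast_maps[[j]], mask)
      }, numeric(1))
      hits <- hits + (names(which.max(rs)) == i)
      total <- total + 1
    }
  }
  hits / total
}

#' Split-half reliability of dACC connectivity patterns
#'
#' Mirrors the independent power check: each subject's preprocessed rest
#' data are split into halves; left- and right-dACC connectivity maps are
#' computed per half; `within` is the Fisher-z spatial correlation of a
#' subject's first- and second-half maps, `between` the mean Fisher-z
#' correlation of their first half with every other subject's first half,
#' both within the physics-parcel mask; a repeated-measures ANOVA with
#' factors condition (within/between) x hemisphere tests for reliable
#' individual differences.
#'
#' @param cohort A [make_cohort()] result (first rest run of each subject
#'   is used).
#' @param config A [preproc_config()].
#' @return List of class `split_half_result`: `table` (long tibble),
#'   `anova` (`rm_anova`).
#' @export
split_half_reliability <- function(cohort, config = preproc_config()) {
  atlas <- cohort$atlas
  dacc <- dacc_labels(atlas)
  roi <- atlas_mask(atlas, roles = "physics")
  ids <- vapply(cohort$subjects, function(s) s$profile$subject_id, character(1))

  half_maps <- lapply(cohort$subjects, function(sub) {
    run <- sub$rest[[1]]
    pp <- preprocess_rest(run$vol, run$motion, atlas, config)
    n_t <- n_volumes(pp$vol)
    if (n_t < 32) stop("run too short to split", call. = FALSE)
    halves <- list(seq_len(floor(n_t / 2)), (floor(n_t / 2) + 1):n_t)
    lapply(c(L = "L", R = "R"), function(h) {
      lapply(halves, function(idx) {
        part <- matrix_volume(volume_matrix(pp$vol)[idx, , drop = FALSE], pp$vol)
        seed <- roi_mean_timeseries(part, atlas, dacc[[h]])
        fisher_z(seed_connectivity(part, seed, source = sub$profile$subject_id))
      })
    })
  })
  names(half_maps) <- ids

  rows <- purrr::map_dfr(c("L", "R"), function(h) {
    purrr::map_dfr(ids, function(i) {
      within <- fisher_z(spatial_correlation(half_maps[[i]][[h]][[1]],
                                             half_maps[[i]][[h]][[2]], roi))
      others <- setdiff(ids, i)
      between <- mean(vapply(others, function(j) {
        fisher_z(spatial_correlation(half_maps[[i]][[h]][[1]],
                                     half_maps[[j]][[h]][[1]], roi))
      }, numeric(1)))
      tibble::tibble(subject = i, hemisphere = h,
                     within_z = within, between_z = between)
    })
  })
  long <- tidyr::pivot_longer(rows, c("within_z", "between_z"),
                              names_to = "condition", values_to = "z")
  long$condition <- sub("_z$", "", long$condition)
  structure(
    list(table = rows,
         anova = rm_anova(long, value = "z", subject = "subject",
                          factors = c("condition", "hemisphere"))),
    class = "split_half_result"
  )
}

#' Replicated fingerprint-recovery experiment
#'
#' Generates `n_cohorts` independent synthetic cohorts and runs the full
#' pipeline on each, recording the mean within- and between-subject
#' Fisher-z correlations, the condition-effect p, and the identification
#' rate. With `displacement_sd_mm = 0` this is the null calibration: no
#' individual differences are planted, so the condition effect should be
#' rejected at roughly the nominal rate.
#'
#' @param n_cohorts Number of replicate cohorts.
#' @param params Base [cohort_params()] (its `master_seed` is offset per
#'   cohort).
#' @param seed Experiment seed.
#' @param config A [preproc_config()].
#' @return Tibble: `cohort`, `mean_within_z`, `mean_between_z`, `gap`,
#'   `p_condition`, `identification_rate`, `motion_r`.
#' @export
fingerprint_recovery_experiment <- function(n_cohorts = 20,
                                            params = cohort_params(),
                                            seed = 1L,
                                            config = preproc_config()) {
  purrr::map_dfr(seq_len(n_cohorts), function(k) {
    p <- params
    p$master_seed <- (seed * 10007L + k * 131L) %% 2000000000L
    res <- fingerprint_pipeline(make_cohort(p), config)
    cond <- res$anova[res$anova$effect == "condition", ]
    tibble::tibble(
      cohort = k,
      mean_within_z = mean(res$table$within_z),
      mean_between_z = mean(res$table$between_z),
      gap = mean(res$table$within_z) - mean(res$table$between_z),
      p_condition = cond$p,
      identification_rate = identification_rate(res),
      motion_r = res$motion_check$r
    )
  })
}

#' Replicated split-half power experiment
#'
#' Runs [split_half_reliability()] on `n_cohorts` independent cohorts
#' (default 10 subjects with a single rest run each, mirroring the
#' split-half power check design) and records the condition-effect p per
#' cohort.
#'
#' @param n_cohorts Number of replicate cohorts.
#' @param params Base [cohort_params()].
#' @param seed Experiment seed.
#' @param config A [preproc_config()].
#' @return Tibble: `cohort`, `mean_within_z`, `mean_between_z`,
#'   `p_condition`.
#' @export
split_half_experiment <- function(n_cohorts = 20,
                                  params = cohort_params(n_subjects = 10,
                                                         rest_runs_per_subject = 1),
                                  seed = 1L,
                                  config = preproc_config()) {
  purrr::map_dfr(seq_len(n_cohorts), function(k) {
    p <- params
    p$master_seed <- (seed * 20011L + k * 197L) %% 2000000000L
    res <- split_half_reliability(make_cohort(p, tasks = FALSE), config)
    cond <- res$anova[res$anova$effect == "condition", ]
    tibble::tibble(
      cohort = k,
      mean_within_z = mean(res$table$within_z),
      mean_between_z = mean(res$table$between_z),
      p_condition = cond$p
    )
  })
}

#' Group-level overlap analysis
#'
#' Per-subject dACC connectivity z maps are combined in a voxelwise group
#' t-test, and the resulting group map is swept through the percentile
#' thresholds within the fronto-parietal search mask: the proportion of the
#' most strongly connected voxels falling inside the physics parcels, per
#' threshold level.
#'
#' @param cohort A [make_cohort()] result.
#' @param config A [preproc_config()].
#' @param statistic Group map to sweep: the mean Fisher-z connectivity
#'   (default — percentiles of the correlation results themselves) or the
#'   one-sample `t` map. At small n the extreme tail of a t map is
#'   dominated by voxels with tiny between-subject variance rather than
#'   strong connectivity, so the mean-z sweep is the faithful group
#'   summary of connectivity strength.
#' @param ... Passed to [overlap_curve()] (sweep definition).
#' @return An [overlap_curve()] tibble.
#' @export
group_overlap_analysis <- function(cohort, config = preproc_config(),
                                   statistic = c("mean_z", "t"), ...) {
  statistic <- match.arg(statistic)
  conn <- lapply(cohort$subjects, subject_connectivity, atlas = cohort$atlas,
                 config = config)
  zmaps <- lapply(conn, `[[`, "zmap")
  gmap <- if (statistic == "mean_z") average_stat_maps(zmaps) else
    group_ttest(zmaps)
  overlap_curve(gmap, cohort$atlas, seed_label = "dACC", hemisphere = "both", ...)
}

#' Familywise-error calibration of the cluster correction
#'
#' Generates independent null studies — a standardized smooth Gaussian
#' field on a small grid, analysed as a high-df t map with its smoothness
#' estimated from the field itself — and records, per study, whether any
#' cluster survives Monte-Carlo cluster-extent correction. On null data the
#' rejection rate should match the nominal cluster-level alpha.
#'
#' @param n_studies Number of null studies.
#' @param fwhm_mm True smoothing applied to the null fields (8 mm default:
#'   a realistic effective smoothness for smoothed fMRI data).
#' @param grid_dims Field grid.
#' @param voxel_size_mm Voxel size.
#' @param cfg A [cluster_config()].
#' @param seed RNG seed.
#' @return List: `fwe` (rejection rate), `n_studies`, `rejections`.
#' @export
cluster_fwe_experiment <- function(n_studies = 200, fwhm_mm = 8,
                                   grid_dims = c(16, 16, 16),
                                   voxel_size_mm = c(3, 3, 3.5),
                                   cfg = cluster_config(n_sims = 200),
                                   seed = 1L) {
  mask <- array(TRUE, grid_dims)
  rej <- withr_seed(seed, {
    vapply(seq_len(n_studies), function(s) {
      v <- volume_series(array(rnorm(prod(grid_dims)), dim = c(grid_dims, 1)),
                         voxel_size_mm = voxel_size_mm, tr_s = 1)
      x <- smooth_gaussian(v, fwhm_mm)$data[, , , 1]
      x <- (x - mean(x)) / sd(x)
      fw <- estimate_smoothness(x, voxel_size_mm)
      tmap <- stat_map(x, kind = "t", df = 400L)
      cc <- cluster_correct(tmap, mask, cfg, fw, voxel_size_mm)
      nrow(cc$table) > 0
    }, logical(1))
  })
  list(fwe = mean(rej), n_studies = n_studies, rejections = rej)
}
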