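test_that("the toy atlas has the expected parcel structure", {
  atlas <- default_atlas()
  expect_equal(sum(atlas$table$role == "acc_dacc"), 2L)   # one dACC per hemisphere
  expect_equal(sum(atlas$table$role == "acc_other"), 6L)  # 3 more per hemisphere
  expect_equal(sum(atlas$table$role == "physics"), 4L)
  phys <- atlas_mask(atlas, roles = "physics")
  search <- atlas_mask(atlas, roles = "searchmask")
  expect_true(all(search[phys]))                          # physics inside search mask
  for (id in atlas$table$label_id[atlas$table$role == "physics"]) {
    expect_gte(sum(atlas$labels == id), 200)
  }
  # parcels are mutually disjoint by construction of a single label field
  expect_equal(sum(atlas_mask(atlas, roles = "wm") &
                     atlas_mask(atlas, roles = "ventricle")), 0L)
  expect_error(make_atlas(cohort_params(grid_dims = c(12, 12, 12))), "too small")
})

test_that("cohorts are bit-reproducible and seeds differentiate them", {
  p <- quick_params()
  a <- make_cohort(p, tasks = FALSE)
  b <- make_cohort(p, tasks = FALSE)
  expect_identical(a$subjects[[2]]$rest[[1]]$vol$data,
                   b$subjects[[2]]$rest[[1]]$vol$data)
  expect_identical(a$subjects[[1]]$profile$displacement_vox,
                   b$subjects[[1]]$profile$displacement_vox)
  # different master seeds give different displacement draws
  disps <- vapply(1:10, function(s) {
    co <- make_cohort(quick_params(n_subjects = 2, n_rest_volumes = 20,
                                   master_seed = s), tasks = FALSE)
    paste(vapply(co$subjects,
                 function(x) paste(x$profile$displacement_vox, collapse = ","),
                 character(1)), collapse = ";")
  }, character(1))
  expect_gt(length(unique(disps)), 6)
  c0 <- make_cohort(quick_params(displacement_sd_mm = 0), tasks = FALSE)
  for (s in c0$subjects) expect_equal(s$profile$displacement_vox, c(0L, 0L, 0L))
})

test_that("displacements stay inside the physics parcels", {
  p <- cohort_params(n_subjects = 12, displacement_sd_mm = 30, master_seed = 5L)
  co <- make_cohort(p, tasks = FALSE)
  atlas <- co$atlas
  phys <- atlas_mask(atlas, roles = "physics")
  for (s in co$subjects) {
    planted <- seedprint:::planted_voxels(atlas, s$profile$displacement_vox)
    expect_true(all(phys[planted]))
  }
})

test_that("uncoupled physics voxels respect the independence sampling bound", {
  p <- quick_params(seed_coupling = 0, n_rest_volumes = 150)
  atlas <- make_atlas(p)
  prof <- seedprint:::subject_profile("s1", c(0, 0, 0), 31L, 33L)
  run <- simulate_rest_run(prof, atlas, p)
  # with a = 0 the confound leak (weight 0.2a) vanishes too, so the raw
  # dACC series and physics voxels are exactly independent
  dacc <- roi_mean_timeseries(run$vol, atlas, dacc_labels(atlas)[["L"]])
  planted <- which(seedprint:::planted_voxels(atlas, c(0L, 0L, 0L)))
  mat <- t(matrix(run$vol$data, nrow = prod(dim(atlas$labels))))
  rs <- cor(dacc, mat[, planted[seq(1, length(planted), by = 4)]])
  expect_lt(mean(abs(rs)), 2 / sqrt(n_volumes(run$vol)))
})

test_that("planted rest correlation matches the closed form at long T", {
  # independent oracle: r = a / sqrt(a^2 + sigma_eff^2) for y = a*s + AR(1) noise
  set.seed(12)
  a <- 0.5; sigma <- 1; phi <- 0.3
  n_t <- 1e4
  s <- seedprint:::ar1_latent(n_t, phi)
  eps <- seedprint:::ar1_matrix(n_t, 100, phi, innov_sd = sigma)
  vol <- volume_series(array(t(a * s + eps), dim = c(5, 5, 4, n_t)), tr_s = 2)
  rmap <- seed_connectivity(vol, s)
  expected <- a / sqrt(a^2 + ar1_stationary_sd(sigma, phi)^2)
  expect_lt(abs(mean(rmap$data) - expected), 0.03)
})

test_that("motion obeys the spike rate and censoring threshold", {
  p <- quick_params(motion_spike_rate = 0)
  atlas <- make_atlas(p)
  prof <- seedprint:::subject_profile("s1", c(0, 0, 0), 77L, 78L)
  run <- simulate_rest_run(prof, atlas, p)
  expect_true(all(framewise_displacement(run$motion) < 2))
  p2 <- quick_params(motion_spike_rate = 0.1)
  run2 <- simulate_rest_run(seedprint:::subject_profile("s2", c(0, 0, 0), 79L, 80L),
                            make_atlas(p2), p2)
  expect_gt(sum(framewise_displacement(run2$motion) > 2), 0)
})

test_that("task runs have the designed length and recover beta exactly without noise", {
  p <- quick_params()
  atlas <- make_atlas(p)
  design <- build_block_design(2L)
  prof <- seedprint:::subject_profile("s1", c(1, 1, 0), 41L, c(42L, 43L))
  run <- simulate_task_run(prof, atlas, design, p)
  expect_equal(n_volumes(run$vol), 207L)

  # noiseless least squares is exact: plant beta * regressor directly
  X <- convolve_design(design)
  d <- dim(atlas$labels)
  y <- matrix(0, nrow = nrow(X), ncol = prod(d))
  planted <- which(seedprint:::planted_voxels(atlas, c(1L, 1L, 0L)))
  y[, planted] <- X[, "physics_cue"]
  vol <- volume_series(array(t(y), dim = c(d, nrow(X))), tr_s = 2)
  fit <- fit_glm(vol, X)
  expect_equal(max(abs(fit$betas$physics_cue$data[planted] - 1)), 0,
               tolerance = 1e-6)

  # null recovery: beta = 0 gives contrasts within 2 SE of zero on average
  p0 <- quick_params(activation_beta = 0)
  run0 <- simulate_task_run(prof, make_atlas(p0), design, p0)
  fit0 <- fit_glm(run0$vol, X)
  con0 <- physics_minus_colour(fit0)$data[planted]
  expect_lt(abs(mean(con0)), 2 * sd(con0) / sqrt(length(con0)))

  bad <- design; bad$total_duration_s <- 415
  expect_error(simulate_task_run(prof, atlas, bad, p), "whole number")
})

test_that("a written cohort can be read back from disk", {
  skip_if_not_installed("yaml")
  dir <- withr::local_tempdir()
  co <- make_cohort(cohort_params(n_subjects = 2, n_rest_volumes = 20,
                                  rest_runs_per_subject = 1, master_seed = 2L),
                    tasks = FALSE)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- read_volume(file.path(dir, "sub01_rest1.nii.gz"))
  expect_equal(back$data, co$subjects[[1]]$rest[[1]]$vol$data, tolerance = 1e-6)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$subjects$sub01$displacement_vox,
               as.integer(co$subjects[[1]]$profile$displacement_vox))
})
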