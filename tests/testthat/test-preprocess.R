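test_that("framewise displacement matches the arc-length formula", {
  m <- as.data.frame(matrix(0, 6, 6))
  names(m) <- c("roll", "pitch", "yaw", "dS", "dP", "dL")
  m$dS[3:6] <- 2            # one 2-mm translation step at volume 3
  m$roll[5:6] <- 1          # one 1-degree rotation step at volume 5
  fd <- framewise_displacement(motion_table(m))
  expect_equal(fd[1], 0)
  expect_equal(fd[3], 2)
  expect_equal(fd[5], 50 * pi / 180, tolerance = 1e-10)  # ~0.8727 mm
  expect_equal(fd[c(2, 4, 6)], rep(0, 3))
  expect_equal(framewise_displacement(still_motion(10)), rep(0, 10))
})

test_that("censoring removes only suprathreshold volumes and maps indices", {
  vol <- tiny_volume(n_t = 10)
  fd <- rep(0, 10); fd[4] <- 2.5
  out2 <- censor_volumes(vol, fd, threshold_mm = 2)
  expect_equal(n_volumes(out2$vol), 9L)
  expect_equal(out2$kept, setdiff(1:10, 4))
  expect_equal(out2$vol$data[, , , 4], vol$data[, , , 5])
  # the task threshold keeps the same series intact
  out3 <- censor_volumes(vol, fd, threshold_mm = 3)
  expect_equal(n_volumes(out3$vol), 10L)
  expect_error(censor_volumes(vol, rep(9, 10), 2), "all volumes")
})

test_that("band-pass rejects DC, passes the band, attenuates the stopband", {
  tt <- seq(0, by = 2, length.out = 600)
  const <- rep(3, 600)
  expect_lt(max(abs(bandpass(const, tr_s = 2))), 1e-8 * 3)
  inband <- sin(2 * pi * 0.04 * tt)
  out <- bandpass(inband, tr_s = 2)
  amp <- max(abs(out[100:500]))
  expect_gt(amp, 0.9); expect_lt(amp, 1.1)
  stopband <- sin(2 * pi * 0.2 * tt)
  expect_lt(max(abs(bandpass(stopband, tr_s = 2)[100:500])), 0.15)
  expect_error(bandpass(inband, tr_s = 2, low_hz = 0.01, high_hz = 0.3),
               "Nyquist")
  expect_error(bandpass(rnorm(10), tr_s = 2), "too short")
})

test_that("nuisance regression projects out regressors and is idempotent", {
  set.seed(8)
  n_t <- 60
  wm <- rnorm(n_t)
  u <- rnorm(n_t)
  d <- c(3, 3, 2)
  base <- array(rnorm(prod(d) * n_t, sd = 1e-3), dim = c(d, n_t))
  base[1, 1, 1, ] <- wm                   # equals a regressor
  base[2, 1, 1, ] <- 2 * wm + u           # planted mixture
  vol <- volume_series(base, tr_s = 2)
  res <- nuisance_regress(vol, cbind(wm = wm))
  expect_lt(max(abs(res$data[1, 1, 1, ])), 1e-8 * sd(wm))
  expect_gt(cor(res$data[2, 1, 1, ], u), 0.99)
  # orthogonal series only loses its mean
  res_u <- nuisance_regress(volume_series(base, tr_s = 2),
                            cbind(w = wm - mean(wm)))
  v_orth <- base[3, 1, 1, ]
  proj <- v_orth - mean(v_orth) -
    (wm - mean(wm)) * sum((v_orth - mean(v_orth)) * (wm - mean(wm))) /
      sum((wm - mean(wm))^2)
  expect_equal(res_u$data[3, 1, 1, ], proj, tolerance = 1e-10)
  # idempotence
  res2 <- nuisance_regress(res, cbind(wm = wm))
  expect_equal(res2$data, res$data, tolerance = 1e-10)
  expect_error(nuisance_regress(vol, cbind(a = wm, b = 2 * wm)), "collinear")
})

test_that("common ROI variance removal orthogonalizes and preserves structure", {
  atlas <- default_atlas()
  params <- cohort_params()
  set.seed(21)
  n_t <- 60
  d <- params$grid_dims
  g <- rnorm(n_t)
  base <- array(rnorm(prod(d) * n_t), dim = c(d, n_t))
  acc_ids <- atlas$table$label_id[atlas$table$role %in% c("acc_dacc", "acc_other")]
  mat <- t(matrix(base, nrow = prod(d)))
  for (id in acc_ids) mat[, which(atlas$labels == id)] <-
    mat[, which(atlas$labels == id)] + 5 * g
  vol <- volume_series(array(t(mat), dim = c(d, n_t)), tr_s = 2)

  pre_var <- var(roi_mean_timeseries(vol, atlas, acc_ids[1]))
  out <- regress_common_roi_variance(vol, atlas)
  # every voxel orthogonal to the removed common series
  common <- rowMeans(vapply(acc_ids, function(id) roi_mean_timeseries(vol, atlas, id),
                            numeric(n_t)))
  post <- roi_mean_timeseries(out, atlas, acc_ids[1])
  expect_lt(abs(cor(post, common)), 1e-6)
  # the shared component is essentially gone from each parcel mean
  expect_lt(var(post) / pre_var, 0.01)
})

test_that("input with no common component only loses its mean", {
  atlas <- default_atlas()
  d <- dim(atlas$labels)
  set.seed(3)
  n_t <- 40
  vol <- volume_series(array(rnorm(prod(d) * n_t), dim = c(d, n_t)), tr_s = 2)
  out <- regress_common_roi_variance(vol, atlas)
  v_in <- vol$data[1, 1, 1, ]
  expect_equal(out$data[1, 1, 1, ], v_in - mean(v_in), tolerance = 0.15)
})

test_that("Gaussian smoothing preserves mass and matches the kernel peak", {
  d <- c(15, 15, 15)
  x <- array(0, dim = c(d, 1))
  x[8, 8, 8, 1] <- 1
  vol <- volume_series(x, voxel_size_mm = c(3, 3, 3), tr_s = 1)
  expect_identical(smooth_gaussian(vol, 0)$data, vol$data)
  sm <- smooth_gaussian(vol, 4)
  expect_equal(sum(sm$data), 1, tolerance = 1e-3)
  # peak matches the analytic 3D Gaussian density at the centre x voxel volume
  sig_mm <- 4 / (2 * sqrt(2 * log(2)))
  analytic <- (2 * pi * sig_mm^2)^(-3 / 2) * 27
  expect_equal(sm$data[8, 8, 8, 1], analytic, tolerance = 0.02)
})

test_that("the full rest chain runs, censors spikes, and removes confounds", {
  params <- quick_params(motion_spike_rate = 0.05)
  atlas <- make_atlas(params)
  prof <- seedprint:::subject_profile("s1", c(1, 0, 0), c(5L, 6L), c(7L, 8L))
  run <- simulate_rest_run(prof, atlas, params)
  fd <- framewise_displacement(run$motion)
  pp <- preprocess_rest(run$vol, run$motion, atlas)
  expect_equal(pp$n_censored, sum(fd > 2))
  expect_equal(n_volumes(pp$vol), length(pp$kept))
  # residuals orthogonal to the wm confound series that was regressed out
  wm <- seedprint:::roi_mean_timeseries_raw(pp$vol, atlas, "wm", pp$kept)
  expect_lt(max(abs(wm)), 1e-6)
})
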