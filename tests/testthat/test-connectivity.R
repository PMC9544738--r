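test_that("seed connectivity hits the exact correlation anchors", {
  set.seed(6)
  seed <- rnorm(30)
  d <- c(3, 2, 2)
  y <- matrix(rnorm(30 * prod(d)), 30, prod(d))
  y[, 1] <- seed
  y[, 2] <- -seed
  y[, 3] <- 5                                    # constant voxel
  vol <- volume_series(array(t(y), dim = c(d, 30)), tr_s = 2)
  rmap <- seed_connectivity(vol, seed)
  expect_equal(rmap$data[1, 1, 1], 1)
  expect_equal(rmap$data[2, 1, 1], -1)
  expect_equal(rmap$data[3, 1, 1], 0)            # flagged constant
  expect_equal(attr(rmap, "n_constant_voxels"), 1L)
  expect_error(seed_connectivity(vol, rep(1, 30)), "constant")
})

test_that("connectivity is invariant to positive affine rescaling", {
  set.seed(7)
  vol <- tiny_volume(n_t = 40)
  seed <- rnorm(40)
  r1 <- seed_connectivity(vol, seed)
  scaled <- volume_series(3.7 * vol$data + 11, tr_s = 2)
  r2 <- seed_connectivity(scaled, seed)
  expect_equal(r2$data, r1$data, tolerance = 1e-12)
})

test_that("fisher z matches atanh and inverts through tanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306144, tolerance = 1e-8)
  r <- seq(-0.999, 0.999, length.out = 101)
  expect_equal(fisher_z(r), -fisher_z(-r))        # odd symmetry
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  # boundary is clipped, not infinite
  expect_true(is.finite(fisher_z(1)))
})

test_that("group t-test matches the hand-computed statistic", {
  d <- c(2, 2, 1)
  vals <- list(1, 2, 3)
  maps <- lapply(vals, function(v) stat_map(array(v, dim = d), kind = "z"))
  tmap <- group_ttest(maps)
  expect_equal(tmap$data[1, 1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-10) # 3.4641
  expect_equal(tmap$df, 2L)
  # sign-flipping all maps flips t exactly
  neg <- lapply(maps, function(m) stat_map(-m$data, kind = "z"))
  expect_equal(group_ttest(neg)$data, -tmap$data)
  # all-zero voxels get a flagged sentinel
  zero <- lapply(1:3, function(i) stat_map(array(0, dim = d), kind = "z"))
  tz <- group_ttest(zero)
  expect_true(all(is.nan(tz$data)))
  expect_equal(attr(tz, "n_degenerate_voxels"), prod(d))
})

test_that("smoothness estimator recovers white-noise and smoothed fields", {
  set.seed(10)
  d <- c(20, 20, 20)
  vox <- c(3, 3, 3.5)
  white <- array(rnorm(prod(d)), dim = d)
  fw_white <- estimate_smoothness(white, vox)
  expect_true(all(abs(fw_white - vox) / vox < 0.25))
  sm <- smooth_gaussian(volume_series(array(white, dim = c(d, 1)),
                                      voxel_size_mm = vox, tr_s = 1), 4)
  fw_sm <- estimate_smoothness(sm$data[, , , 1], vox)
  expect_true(all(fw_sm > 3.2 & fw_sm < 4.8))
  # doubling the voxel size doubles the reported mm FWHM for the same field
  expect_equal(estimate_smoothness(white, 2 * vox), 2 * fw_white)
  expect_error(estimate_smoothness(array(1, dim = d), vox), "constant")
})

test_that("cluster correction keeps a strong planted effect and drops noise", {
  set.seed(14)
  d <- c(16, 16, 16)
  vox <- c(3, 3, 3.5)
  mask <- array(TRUE, d)
  cfg <- cluster_config(n_sims = 200)
  # planted 100-voxel block with t ~ 8 on a smooth-noise background
  n_sub <- 12
  effect <- array(0, dim = d)
  effect[6:10, 6:10, 6:9] <- 8 / sqrt(n_sub)     # 5x5x4 = 100 voxels
  maps <- lapply(seq_len(n_sub), function(i) {
    noise <- smooth_gaussian(volume_series(array(rnorm(prod(d)), dim = c(d, 1)),
                                           voxel_size_mm = vox, tr_s = 1), 6)$data[, , , 1]
    stat_map(effect + noise / sd(noise), kind = "z", source = paste0("s", i))
  })
  tmap <- group_ttest(maps)
  fw <- estimate_smoothness(maps, vox)
  cc <- cluster_correct(tmap, mask, cfg, fw, vox)
  expect_lt(cc$critical_size, 100)
  expect_gt(nrow(cc$table), 0)
  big <- cc$table[cc$table$sign == "positive", ]
  expect_gte(max(big$n_voxels), 50)
  planted_kept <- sum(cc$mask_map$data[6:10, 6:10, 6:9] > 0)
  expect_gt(planted_kept / 100, 0.5)

  # an empty suprathreshold set yields an empty result
  flat <- stat_map(array(rnorm(prod(d), sd = 0.01), dim = d), kind = "t", df = 11L)
  cc0 <- cluster_correct(flat, mask, cfg, fw, vox)
  expect_equal(nrow(cc0$table), 0L)
  expect_equal(sum(cc0$mask_map$data), 0)
  expect_error(cluster_correct(tmap, array(FALSE, d), cfg, fw, vox), "empty")
})

test_that("cluster labelling uses face adjacency only", {
  m <- array(FALSE, dim = c(4, 4, 1))
  m[1, 1, 1] <- TRUE
  m[2, 2, 1] <- TRUE   # diagonal neighbour: separate cluster under NN1
  m[2, 1, 1] <- FALSE
  lab <- seedprint:::label_clusters(m)
  expect_equal(max(lab), 2L)
  m[2, 1, 1] <- TRUE   # face bridge joins them
  expect_equal(max(seedprint:::label_clusters(m)), 1L)
})
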