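test_that("spatial correlation hits its exact anchors", {
  set.seed(5)
  d <- c(5, 5, 4)
  roi <- array(TRUE, d)
  a <- array(rnorm(prod(d)), dim = d)
  expect_equal(spatial_correlation(a, a, roi), 1)
  expect_equal(spatial_correlation(a, -a, roi), -1)
  # explicit orthogonal construction after demeaning within the ROI
  b <- array(0, dim = d)
  b[1] <- 1; b[2] <- -1
  a2 <- array(0, dim = d)
  a2[3] <- 1; a2[4] <- -1
  expect_lt(abs(spatial_correlation(a2, b, roi)), 1e-10)
  small <- array(FALSE, d); small[1:5] <- TRUE
  expect_error(spatial_correlation(a, a, small), "fewer than 10")
  expect_error(spatial_correlation(array(1, d), a, roi), "constant")
})

test_that("within equals between when all subjects share one map", {
  set.seed(6)
  d <- c(6, 6, 4)
  shared <- stat_map(array(rnorm(prod(d)), dim = d), kind = "z")
  conn <- list(s1 = shared, s2 = shared, s3 = shared)
  contrast <- lapply(conn, function(m) stat_map(m$data, kind = "contrast"))
  masks <- list(roi = array(TRUE, d))
  tab <- within_between_table(conn, contrast, masks)
  expect_equal(tab$within_z, tab$between_z)
})

test_that("two-subject between is a single correlation, not an average", {
  set.seed(8)
  d <- c(5, 5, 4)
  mk <- function() stat_map(array(rnorm(prod(d)), dim = d), kind = "z")
  conn <- list(s1 = mk(), s2 = mk())
  contrast <- list(s1 = mk(), s2 = mk())
  roi <- array(TRUE, d)
  tab <- within_between_table(conn, contrast, list(roi = roi))
  direct <- fisher_z(spatial_correlation(conn$s1, contrast$s2, roi))
  expect_equal(tab$between_z[tab$subject == "s1"], direct)
  expect_error(within_between_table(conn["s1"], contrast["s1"], list(roi = roi)),
               "at least 2")
})

test_that("rm_anova matches the brute-force decomposition on a 12-cell table", {
  set.seed(11)
  df <- expand.grid(subject = paste0("s", 1:3),
                    condition = c("within", "between"),
                    region = c("front", "pari"),
                    stringsAsFactors = FALSE)
  df$z <- c(2.1, 1.7, 1.9, 0.8, 0.6, 1.1, 2.4, 1.5, 2.0, 1.0, 0.9, 0.7)
  out <- rm_anova(df, value = "z", subject = "subject",
                  factors = c("condition", "region"))
  oracle <- brute_force_rm_anova(df, "z", "subject", "condition", "region")
  expect_equal(out$F[out$effect == "condition"], oracle$F1, tolerance = 1e-10)
  expect_equal(out$F[out$effect == "region"], oracle$F2, tolerance = 1e-10)
  expect_equal(out$F[out$effect == "condition:region"], oracle$F12,
               tolerance = 1e-10)
  expect_equal(out$df_num[out$effect == "condition"], oracle$df[1])
  expect_equal(out$df_den[out$effect == "condition"], oracle$df[2])
  expect_error(rm_anova(df[-1, ], value = "z", subject = "subject",
                        factors = c("condition", "region")), "incomplete")
})

test_that("an all-equal table reports F = 0 with a note", {
  df <- expand.grid(subject = paste0("s", 1:3),
                    condition = c("within", "between"),
                    region = c("front", "pari"), stringsAsFactors = FALSE)
  df$z <- 1
  out <- rm_anova(df, value = "z", subject = "subject",
                  factors = c("condition", "region"))
  expect_equal(out$F, rep(0, 3))
  expect_match(attr(out, "note"), "all cells equal")
})

test_that("the condition-effect p is uniform under the exchangeable null", {
  set.seed(19)
  ps <- replicate(400, {
    df <- expand.grid(subject = paste0("s", 1:6),
                      condition = c("within", "between"),
                      region = paste0("r", 1:4), stringsAsFactors = FALSE)
    df$z <- rnorm(nrow(df))
    out <- rm_anova(df, value = "z", subject = "subject",
                    factors = c("condition", "region"))
    out$p[out$effect == "condition"]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})

test_that("motion confound check responds to planted coupling only", {
  set.seed(23)
  base <- expand.grid(subject = paste0("s", 1:8),
                      region = c("a", "b"), stringsAsFactors = FALSE)
  gap <- rep(rnorm(8, 1, 0.5), 2)
  tab <- tibble::tibble(subject = base$subject, region = base$region,
                        within_z = gap, between_z = 0,
                        mean_fd_mm = rep(0.1, 16))
  class(tab) <- c("fingerprint_table", class(tab))
  expect_error(motion_confound_check(tab), "zero variance")
  tab$mean_fd_mm <- gap * 0.3 + rnorm(16, sd = 1e-3)  # FD tracks the gap
  out <- motion_confound_check(tab)
  expect_gt(out$r, 0.9)
  # independent motion: |r| small on average over replicates
  rs <- replicate(30, {
    t2 <- tab
    t2$within_z <- rep(rnorm(8, 1, 0.5), 2)
    t2$mean_fd_mm <- rep(abs(rnorm(8, 0.2, 0.05)), 2)
    motion_confound_check(t2)$r
  })
  expect_lt(mean(abs(rs)), 2 / sqrt(8))
})

test_that("fingerprint tables plot and tidiers return tibbles", {
  set.seed(2)
  d <- c(5, 5, 4)
  mk <- function() stat_map(array(rnorm(prod(d)), dim = d), kind = "z")
  conn <- list(s1 = mk(), s2 = mk(), s3 = mk())
  contrast <- list(s1 = mk(), s2 = mk(), s3 = mk())
  roi_a <- array(FALSE, d); roi_a[, , 1:2] <- TRUE
  roi_b <- array(FALSE, d); roi_b[, , 3:4] <- TRUE
  tab <- within_between_table(conn, contrast, list(a = roi_a, b = roi_b))
  expect_s3_class(autoplot(tab), "ggplot")
  an <- rm_anova(tab, factors = c("condition", "region"))
  expect_s3_class(tidy(an), "tbl_df")
  expect_equal(nrow(glance(an)), 1L)
})
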