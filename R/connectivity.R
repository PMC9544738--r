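#' Seed-based voxelwise connectivity
#'
#' Pearson correlation of every voxel's timeseries with a seed series.
#' Constant voxels get r = 0; their count is attached as the
#' `n_constant_voxels` attribute. The result is invariant to positive affine
#' rescaling of the voxel series.
#'
#' @param vol A preprocessed `volume_series` (T >= 10).
#' @param seed_series Numeric seed timeseries of length T; must not be
#'   constant.
#' @param source Subject id recorded on the resulting map.
#' @return A `stat_map` of kind `r`.
#' @export
seed_connectivity <- function(vol, seed_series, source = "subject") {
  stopifnot(inherits(vol, "volume_series"))
  n <- n_volumes(vol)
  if (length(seed_series) != n) stop("seed length must equal T", call. = FALSE)
  if (n < 10) stop("need at least 10 volumes", call. = FALSE)
  s <- seed_series - mean(seed_series)
  ss <- sqrt(sum(s^2))
  if (ss == 0) stop("seed series is constant", call. = FALSE)
  Y <- volume_matrix(vol)
  Yc <- sweep(Y, 2, colMeans(Y))
  denom <- sqrt(colSums(Yc^2)) * ss
  num <- drop(crossprod(Yc, s))
  r <- ifelse(denom > 0, num / denom, 0)
  n_const <- sum(denom == 0)
  r <- pmin(1, pmax(-1, r))
  out <- stat_map(array(r, dim = dim(vol$data)[1:3]), kind = "r", source = source)
  attr(out, "n_constant_voxels") <- n_const
  out
}

#' Fisher z-transform of a correlation map
#'
#' `z = atanh(r)` with |r| clipped to `1 - 1e-7` first so the transform stays
#' finite at the boundary.
#'
#' @param x A `stat_map` of kind `r`, or a numeric vector of correlations.
#' @return A `stat_map` of kind `z` (or numeric vector).
#' @export
fisher_z <- function(x) {
  clip <- function(r) {
    r[r > 1 - 1e-7] <- 1 - 1e-7
    r[r < -(1 - 1e-7)] <- -(1 - 1e-7)
    r
  }
  if (inherits(x, "stat_map")) {
    stopifnot(x$kind == "r")
    return(stat_map(atanh(clip(x$data)), kind = "z", source = x$source))
  }
  atanh(clip(x))
}

#' Voxelwise one-sample t-test across maps
#'
#' Per voxel, `t = mean / (sd / sqrt(n))` over the supplied maps (df =
#' n - 1). Voxels with zero variance get a sentinel: signed infinity when
#' the mean is nonzero, NaN when all values are zero; their count is the
#' `n_degenerate_voxels` attribute.
#'
#' @param maps List of >= 2 `stat_map`s on a common grid (typically kind
#'   `z` or `contrast`).
#' @return A `stat_map` of kind `t` with `df = n - 1`.
#' @export
group_ttest <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 2)
  for (m in maps[-1]) check_same_grid(maps[[1]], m)
  arr <- vapply(maps, function(m) as.vector(m$data),
                numeric(length(maps[[1]]$data)))
  n <- length(maps)
  mu <- rowMeans(arr)
  s <- sqrt(rowSums((arr - mu)^2) / (n - 1))
  t <- ifelse(s > 0, mu / (s / sqrt(n)),
              ifelse(mu == 0, NaN, sign(mu) * Inf))
  out <- stat_map(array(t, dim = dim(maps[[1]]$data)), kind = "t",
                  df = n - 1L, source = "group")
  attr(out, "n_degenerate_voxels") <- sum(s == 0)
  out
}

#' Gaussian-equivalent spatial smoothness of residual maps
#'
#' Per-axis FWHM estimated from the variance of spatial first differences:
#' `FWHM = delta * sqrt(4*log(2) * var(field) / var(diff))`, the classic
#' derivative-variance estimator, which recovers the kernel FWHM of
#' Gaussian-smoothed white noise in the continuum limit and reports roughly
#' one voxel for unsmoothed white noise. Axes are averaged across maps.
#'
#' @param maps A `stat_map`/3D array or list of them.
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return Length-3 numeric, FWHM in mm per axis.
#' @export
estimate_smoothness <- function(maps, voxel_size_mm = c(3, 3, 3.5)) {
  if (!is.list(maps) || inherits(maps, "stat_map")) maps <- list(maps)
  per_map <- vapply(maps, function(m) {
    x <- if (inherits(m, "stat_map")) m$data else m
    v <- var(as.vector(x))
    if (v == 0) stop("cannot estimate smoothness of a constant map", call. = FALSE)
    vapply(1:3, function(ax) {
      dv <- var(as.vector(apply(x, setdiff(1:3, ax), diff)))
      voxel_size_mm[ax] * sqrt(4 * log(2) * v / dv)
    }, numeric(1))
  }, numeric(3))
  rowMeans(per_map)
}

# lag-1 autocorrelation of white noise smoothed with the discrete sampled
# Gaussian kernel used by smooth_gaussian, at a given FWHM (in voxels * delta)
discrete_kernel_acf1 <- function(fwhm_mm, delta_mm) {
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / delta_mm
  k <- gaussian_kernel(sig)
  if (length(k) == 1) return(0)
  sum(k[-length(k)] * k[-1]) / sum(k^2)
}

# FWHM at which smooth_gaussian-ed white noise reproduces the measured
# smoothness under the derivative-variance estimator (self-consistent
# inversion, so Monte-Carlo nulls match the data's estimated smoothness)
invert_smoothness <- function(fwhm_est, delta_mm) {
  vapply(seq_along(fwhm_est), function(ax) {
    target_rho <- 1 - 2 * log(2) * delta_mm[ax]^2 / fwhm_est[ax]^2
    if (target_rho <= 0) return(0)
    f <- function(fw) discrete_kernel_acf1(fw, delta_mm[ax]) - target_rho
    upper <- 10 * delta_mm[ax]
    if (f(upper) < 0) return(upper)
    stats::uniroot(f, c(1e-3, upper))$root
  }, numeric(1))
}

#' Cluster-extent correction configuration
#'
#' @param voxel_p Primary uncorrected voxelwise threshold (two-sided by
#'   default, matching maps that carry both positive and negative effects).
#' @param alpha Cluster-level familywise error rate.
#' @param n_sims Number of Monte-Carlo null fields.
#' @param two_sided Threshold |t| (default) or positive tail only.
#' @return A list of class `cluster_config`. Clusters use face adjacency
#'   (6-neighbour connectivity).
#' @export
cluster_config <- function(voxel_p = 0.001, alpha = 0.05, n_sims = 1000,
                           two_sided = TRUE) {
  stopifnot(voxel_p > 0, voxel_p < 1, n_sims >= 100)
  structure(list(voxel_p = voxel_p, alpha = alpha, n_sims = n_sims,
                 two_sided = two_sided, connectivity = 6L),
            class = "cluster_config")
}

# connected components of a logical 3D array under 6-connectivity
label_clusters <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  coord <- arrayInd(idx, d)
  strides <- c(1L, d[1], d[1] * d[2])
  in_mask <- array(FALSE, d)
  in_mask[idx] <- TRUE
  current <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(v, d)
      for (ax in 1:3) {
        for (dir in c(-1L, 1L)) {
          cj <- ci[ax] + dir
          if (cj < 1 || cj > d[ax]) next
          w <- v + dir * strides[ax]
          if (in_mask[w] && lab[w] == 0L) {
            lab[w] <- current
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  lab
}

# max suprathreshold cluster size of one simulated smooth null field
null_max_cluster <- function(d, mask_idx, fwhm_sim, voxel_size_mm, zthr,
                             two_sided, mask) {
  field <- volume_series(array(rnorm(prod(d)), dim = c(d, 1)),
                         voxel_size_mm = voxel_size_mm, tr_s = 1)
  if (any(fwhm_sim > 0)) {
    # anisotropic: smooth at the per-axis widths via one pass
    field <- smooth_aniso(field, fwhm_sim)
  }
  x <- field$data[, , , 1][mask_idx]
  x <- (x - mean(x)) / sd(x)
  z <- array(0, dim = d)
  z[mask_idx] <- x
  supra <- if (two_sided) abs(z) >= zthr else z >= zthr
  supra <- supra & mask
  if (!any(supra)) return(0L)
  if (two_sided) {
    pos <- label_clusters(supra & z > 0)
    neg <- label_clusters(supra & z < 0)
    max(c(tabulate(pos[pos > 0]), tabulate(neg[neg > 0]), 0L))
  } else {
    lab <- label_clusters(supra)
    max(tabulate(lab[lab > 0]))
  }
}

# per-axis anisotropic Gaussian smoothing (fwhm vector, mm)
smooth_aniso <- function(vol, fwhm_mm_vec) {
  d <- dim(vol$data)
  x <- vol$data
  for (ax in 1:3) {
    sig <- fwhm_mm_vec[ax] / (2 * sqrt(2 * log(2))) / vol$voxel_size_mm[ax]
    k <- gaussian_kernel(sig)
    if (length(k) == 1) next
    K <- kernel_matrix(d[ax], k)
    perm <- c(ax, setdiff(1:4, ax))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xp <- K %*% matrix(xp, nrow = dp[1])
    dim(xp) <- dp
    x <- aperm(xp, order(perm))
  }
  volume_series(x, voxel_size_mm = vol$voxel_size_mm, tr_s = vol$tr_s)
}

#' Monte-Carlo cluster-extent correction
#'
#' Thresholds a t-map at the primary voxelwise p, then retains only clusters
#' (6-connectivity, positive and negative clusters labelled separately when
#' two-sided) at least as large as the critical extent obtained from
#' Monte-Carlo simulation: white-noise fields are smoothed so that their
#' measured smoothness matches `fwhm_est`, standardized within the mask,
#' thresholded identically, and the (1 - alpha) quantile of their maximum
#' cluster sizes sets the critical size.
#'
#' @param tmap A `stat_map` of kind `t` with known `df`.
#' @param mask 3D logical analysis mask.
#' @param cfg A [cluster_config()].
#' @param fwhm_est Length-3 estimated smoothness in mm (see
#'   [estimate_smoothness()]).
#' @param voxel_size_mm Voxel size in mm.
#' @return List: `mask_map` (binary `stat_map` of surviving voxels),
#'   `table` (tibble: cluster_id, n_voxels, peak_t, x, y, z, sign),
#'   `critical_size`, `t_threshold`.
#' @export
cluster_correct <- function(tmap, mask, cfg = cluster_config(), fwhm_est,
                            voxel_size_mm = c(3, 3, 3.5)) {
  stopifnot(inherits(tmap, "stat_map"), tmap$kind == "t")
  if (is.null(tmap$df)) stop("t map must carry df", call. = FALSE)
  if (!any(mask)) stop("analysis mask is empty", call. = FALSE)
  d <- dim(tmap$data)
  stopifnot(identical(dim(mask), d))

  tthr <- if (cfg$two_sided) qt(1 - cfg$voxel_p / 2, tmap$df) else
    qt(1 - cfg$voxel_p, tmap$df)
  zthr <- if (cfg$two_sided) qnorm(1 - cfg$voxel_p / 2) else
    qnorm(1 - cfg$voxel_p)

  fwhm_sim <- invert_smoothness(fwhm_est, voxel_size_mm)
  mask_idx <- which(mask)
  maxes <- vapply(seq_len(cfg$n_sims), function(i) {
    null_max_cluster(d, mask_idx, fwhm_sim, voxel_size_mm, zthr,
                     cfg$two_sided, mask)
  }, integer(1))
  # smallest extent whose null exceedance probability is at most alpha
  critical <- 1L
  while (mean(maxes >= critical) > cfg$alpha) critical <- critical + 1L

  tv <- tmap$data
  tv[!mask] <- 0
  tv[is.nan(tv)] <- 0  # degenerate-voxel sentinels never enter clusters
  supra <- if (cfg$two_sided) abs(tv) >= tthr else tv >= tthr
  supra <- supra & mask

  collect <- function(sub, sgn) {
    lab <- label_clusters(sub)
    if (max(lab) == 0) return(NULL)
    purrr::map_dfr(seq_len(max(lab)), function(k) {
      vox <- which(lab == k)
      sizes <- length(vox)
      peak <- vox[which.max(abs(tv[vox]))]
      pc <- arrayInd(peak, d)
      tibble::tibble(n_voxels = sizes, peak_t = tv[peak],
                     x = pc[1], y = pc[2], z = pc[3], sign = sgn)
    })
  }
  tab <- dplyr::bind_rows(
    if (cfg$two_sided) collect(supra & tv > 0, "positive") else collect(supra, "positive"),
    if (cfg$two_sided) collect(supra & tv < 0, "negative") else NULL
  )
  keep <- array(FALSE, dim = d)
  if (!is.null(tab) && nrow(tab) > 0) {
    tab <- tab[tab$n_voxels >= critical, , drop = FALSE]
    if (nrow(tab) > 0) {
      for (sgn in unique(tab$sign)) {
        sub <- if (sgn == "positive") supra & tv > 0 else supra & tv < 0
        lab <- label_clusters(sub)
        sizes <- tabulate(lab[lab > 0])
        ok <- which(sizes >= critical)
        keep[lab %in% ok & sub] <- TRUE
      }
      tab <- dplyr::arrange(tab, dplyr::desc(.data$n_voxels))
      tab$cluster_id <- seq_len(nrow(tab))
      tab <- tab[, c("cluster_id", "n_voxels", "peak_t", "x", "y", "z", "sign")]
    }
  }
  if (is.null(tab)) tab <- tibble::tibble(
    cluster_id = integer(), n_voxels = integer(), peak_t = numeric(),
    x = integer(), y = integer(), z = integer(), sign = character())
  list(
    mask_map = stat_map(array(as.numeric(keep), dim = d), kind = "t",
                        df = tmap$df, source = tmap$source),
    table = tab,
    critical_size = critical,
    t_threshold = tthr
  )
}
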