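#' Preprocessing configuration
#'
#' Defaults follow standard resting-state practice: 4-mm FWHM spatial
#' smoothing, 0.009--0.08 Hz band-pass, motion censoring at 2 mm framewise
#' displacement for rest (3 mm for task), motion parameters plus their first
#' backward differences as nuisance regressors.
#'
#' @param fwhm_mm Gaussian smoothing kernel FWHM in mm (>= 0; 0 disables).
#' @param band_low_hz,band_high_hz Band-pass edges in Hz; must satisfy
#'   `0 < low < high < 1/(2*tr_s)`.
#' @param censor_threshold_mm Framewise-displacement censoring threshold.
#' @param include_motion_derivatives Include backward differences of the six
#'   motion parameters as extra nuisance columns.
#' @param censor_first If `TRUE`, censor before smoothing/filtering instead
#'   of after (the default censors after filtering, preserving the regular
#'   sampling the temporal filter assumes).
#' @return A list of class `preproc_config`.
#' @export
preproc_config <- function(fwhm_mm = 4, band_low_hz = 0.009,
                           band_high_hz = 0.08, censor_threshold_mm = 2,
                           include_motion_derivatives = TRUE,
                           censor_first = FALSE) {
  stopifnot(fwhm_mm >= 0, band_low_hz > 0, band_high_hz > band_low_hz)
  structure(
    list(
      fwhm_mm = fwhm_mm,
      band_low_hz = band_low_hz,
      band_high_hz = band_high_hz,
      censor_threshold_mm = censor_threshold_mm,
      include_motion_derivatives = include_motion_derivatives,
      censor_first = censor_first
    ),
    class = "preproc_config"
  )
}

#' Framewise displacement
#'
#' Per-volume scalar head-motion summary: the sum of absolute backward
#' differences of the three translations (mm) plus the three rotations
#' converted to arc length on a 50-mm sphere. `FD(1) = 0`.
#'
#' @param motion A [motion_table()].
#' @param radius_mm Sphere radius for the rotation-to-mm conversion.
#' @return Numeric vector of length T, mm.
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  m <- as.matrix(as.data.frame(motion))
  if (nrow(m) < 2) stop("need at least 2 volumes", call. = FALSE)
  d <- abs(diff(m))
  rot <- d[, c("roll", "pitch", "yaw"), drop = FALSE] * pi / 180 * radius_mm
  tra <- d[, c("dS", "dP", "dL"), drop = FALSE]
  c(0, rowSums(rot) + rowSums(tra))
}

#' Censor high-motion volumes
#'
#' Removes volumes whose framewise displacement exceeds the threshold and
#' returns the mapping from retained to original positions, which must also
#' be applied to any regressor matrix used downstream.
#'
#' @param vol A `volume_series`.
#' @param fd Framewise displacement, length T.
#' @param threshold_mm Censoring threshold in mm.
#' @return List with `vol` (censored series) and `kept` (integer index,
#'   new -> old).
#' @export
censor_volumes <- function(vol, fd, threshold_mm) {
  stopifnot(inherits(vol, "volume_series"), length(fd) == n_volumes(vol))
  kept <- which(fd <= threshold_mm)
  if (length(kept) == 0) {
    stop("all volumes exceed the censoring threshold", call. = FALSE)
  }
  if (length(kept) == n_volumes(vol)) {
    return(list(vol = vol, kept = kept))
  }
  list(vol = matrix_volume(volume_matrix(vol)[kept, , drop = FALSE], vol),
       kept = kept)
}

# zero-phase band-pass operator (T x T), cached: filtfilt applied to the
# identity basis, so a whole T x V matrix filters as one matrix product
bandpass_operator <- function(n, tr_s, low_hz, high_hz) {
  nyq <- 1 / (2 * tr_s)
  if (!(low_hz > 0 && high_hz < nyq)) {
    stop(sprintf("band (%g, %g) Hz outside (0, Nyquist = %g)", low_hz, high_hz, nyq),
         call. = FALSE)
  }
  key <- sprintf("bp_%d_%g_%g_%g", n, tr_s, low_hz, high_hz)
  cached <- .seedprint_cache[[key]]
  if (!is.null(cached)) return(cached)
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  op <- apply(diag(n), 2, function(e) signal::filtfilt(bf, e))
  # remove DC exactly before filtering, so constants map to zero with no
  # edge transient
  op <- op - rowMeans(op) %o% rep(1, n)
  .seedprint_cache[[key]] <- op
  op
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-2 Butterworth applied forward and backward (zero phase, squared
#' magnitude response); removes DC exactly in the pass definition.
#'
#' @param x Numeric vector (length T), a T x V matrix, or a
#'   `volume_series`.
#' @param tr_s Sampling interval in seconds (taken from the object for
#'   volumes).
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @return Filtered object of the same shape.
#' @export
bandpass <- function(x, tr_s = NULL, low_hz = 0.009, high_hz = 0.08) {
  if (inherits(x, "volume_series")) {
    mat <- volume_matrix(x)
    op <- bandpass_operator(nrow(mat), x$tr_s, low_hz, high_hz)
    return(matrix_volume(op %*% mat, x))
  }
  stopifnot(!is.null(tr_s))
  if (is.matrix(x)) {
    if (nrow(x) < 16) stop("series too short to filter (need >= 16)", call. = FALSE)
    return(bandpass_operator(nrow(x), tr_s, low_hz, high_hz) %*% x)
  }
  if (length(x) < 16) stop("series too short to filter (need >= 16)", call. = FALSE)
  drop(bandpass_operator(length(x), tr_s, low_hz, high_hz) %*% cbind(x))
}

#' Motion nuisance regressors
#'
#' The six rigid-body parameters and (optionally) their first backward
#' differences, first row zero.
#'
#' @param motion A `motion_table`.
#' @param derivatives Include backward differences.
#' @return T x 6 or T x 12 matrix with named columns.
#' @export
motion_regressors <- function(motion, derivatives = TRUE) {
  m <- as.matrix(as.data.frame(motion))
  if (!derivatives) return(m)
  d <- rbind(0, diff(m))
  colnames(d) <- paste0("d_", colnames(m))
  cbind(m, d)
}

#' Regress nuisance signals out of every voxel
#'
#' Per voxel, the residual of an ordinary least-squares fit of the voxel
#' series on an intercept plus the supplied regressors. Residuals are
#' orthogonal to the regressors, so the operation is idempotent.
#'
#' @param vol A `volume_series`.
#' @param regressors T x K numeric matrix (without intercept).
#' @return A `volume_series` of residuals.
#' @export
nuisance_regress <- function(vol, regressors) {
  stopifnot(inherits(vol, "volume_series"))
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != n_volumes(vol)) {
    stop("regressor rows must equal the number of volumes", call. = FALSE)
  }
  X <- cbind(intercept = 1, regressors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  Y <- volume_matrix(vol)
  matrix_volume(Y - X %*% qr.coef(qrX, Y), vol)
}

#' Remove the ACC parcels' common variance
#'
#' Computes the mean timeseries of each of the 8 ACC parcels (roles
#' `acc_dacc` and `acc_other`), takes their shared component and regresses
#' it out of every voxel, so each parcel's subsequent connectivity reflects
#' its unique variance. The shared component is the mean of the parcel-mean
#' series by default; `method = "pc1"` uses their first principal component
#' instead.
#'
#' @param vol A `volume_series`.
#' @param atlas A `parcel_atlas` containing the ACC parcels.
#' @param method `"mean"` (default) or `"pc1"`.
#' @return A `volume_series` of residuals.
#' @export
regress_common_roi_variance <- function(vol, atlas, method = c("mean", "pc1")) {
  method <- match.arg(method)
  acc <- atlas$table$label_id[atlas$table$role %in% c("acc_dacc", "acc_other")]
  if (length(acc) == 0) stop("atlas has no ACC parcels", call. = FALSE)
  series <- vapply(acc, function(id) roi_mean_timeseries(vol, atlas, id),
                   numeric(n_volumes(vol)))
  common <- if (method == "mean") {
    rowMeans(series)
  } else {
    s <- scale(series, center = TRUE, scale = FALSE)
    drop(s %*% svd(s, nu = 0, nv = 1)$v)
  }
  nuisance_regress(vol, cbind(acc_common = common))
}

# discrete sampled Gaussian kernel, normalized to sum 1
gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# banded convolution matrix for a symmetric kernel along an axis of length n
kernel_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1) / 2
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - r):(j + r)
    ok <- idx >= 1 & idx <= n
    K[idx[ok], j] <- kernel[ok]
  }
  t(K)
}

#' Spatial Gaussian smoothing
#'
#' Separable 3D Gaussian smoothing of every volume, with per-axis
#' `sigma_vox = fwhm_mm / (2*sqrt(2*log(2))) / voxel_size_mm`. The kernel is
#' normalized, so an interior impulse keeps its total mass; `fwhm_mm = 0` is
#' the identity.
#'
#' @param vol A `volume_series`.
#' @param fwhm_mm Kernel FWHM in mm.
#' @return Smoothed `volume_series`.
#' @export
smooth_gaussian <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "volume_series"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  d <- dim(vol$data)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_size_mm
  x <- vol$data
  for (ax in 1:3) {
    k <- gaussian_kernel(sig[ax])
    if (length(k) == 1) next
    K <- kernel_matrix(d[ax], k)
    perm <- c(ax, setdiff(1:4, ax))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xp <- K %*% matrix(xp, nrow = dp[1])
    dim(xp) <- dp
    x <- aperm(xp, order(perm))
  }
  volume_series(x, voxel_size_mm = vol$voxel_size_mm, tr_s = vol$tr_s,
                affine = vol$affine)
}

#' Full rest-run preprocessing chain
#'
#' Default order: spatial smoothing, band-pass filtering, motion censoring,
#' nuisance regression (motion parameters and derivatives plus white-matter
#' and ventricular mean series, all band-passed and censored with the same
#' index), then removal of the ACC parcels' common variance. Setting
#' `config$censor_first` censors before the filter instead.
#'
#' @param vol Rest run (`volume_series`).
#' @param motion Its `motion_table`.
#' @param atlas A `parcel_atlas` with ACC, wm and ventricle parcels.
#' @param config A [preproc_config()].
#' @param common_variance Remove the ACC common component (disable for runs
#'   where the atlas lacks ACC parcels).
#' @return List: `vol` (residual series), `kept` (retained volume indices),
#'   `fd` (framewise displacement, full length), `n_censored`.
#' @export
preprocess_rest <- function(vol, motion, atlas, config = preproc_config(),
                            common_variance = TRUE) {
  stopifnot(nrow(motion) == n_volumes(vol))
  fd <- framewise_displacement(motion)
  keep_all <- seq_len(n_volumes(vol))

  if (config$censor_first) {
    cen <- censor_volumes(vol, fd, config$censor_threshold_mm)
    vol <- cen$vol
    kept <- cen$kept
  } else {
    kept <- keep_all
  }

  vol <- smooth_gaussian(vol, config$fwhm_mm)
  vol <- bandpass(vol, low_hz = config$band_low_hz, high_hz = config$band_high_hz)

  if (!config$censor_first) {
    cen <- censor_volumes(vol, fd, config$censor_threshold_mm)
    vol <- cen$vol
    kept <- cen$kept
  }

  reg <- motion_regressors(motion, config$include_motion_derivatives)
  wm <- roi_mean_timeseries_raw(vol, atlas, "wm", kept)
  vent <- roi_mean_timeseries_raw(vol, atlas, "ventricle", kept)
  reg <- bandpass(reg, tr_s = vol$tr_s, low_hz = config$band_low_hz,
                  high_hz = config$band_high_hz)
  reg <- cbind(reg[kept, , drop = FALSE], wm = wm, vent = vent)
  vol <- nuisance_regress(vol, reg)
  if (common_variance) vol <- regress_common_roi_variance(vol, atlas)

  out <- list(vol = vol, kept = kept, fd = fd,
              n_censored = length(keep_all) - length(kept))
  attr(out, "config") <- config
  attr(out, "order") <- if (config$censor_first) {
    "censor>smooth>bandpass>nuisance>roi_common"
  } else {
    "smooth>bandpass>censor>nuisance>roi_common"
  }
  out
}

# mean series of a role's voxels from an already-censored volume
roi_mean_timeseries_raw <- function(vol, atlas, role, kept) {
  ids <- atlas$table$label_id[atlas$table$role == role]
  if (length(ids) == 0) stop(sprintf("atlas has no '%s' parcel", role), call. = FALSE)
  sel <- which(atlas$labels %in% ids)
  rowMeans(volume_matrix(vol)[, sel, drop = FALSE])
}
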