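#' Fit a voxelwise GLM
#'
#' Ordinary least squares of every voxel series on an intercept plus the
#' supplied design columns (condition regressors of interest and motion
#' columns of no interest). Residuals are orthogonal to the design.
#' Prewhitening is not performed: at TR 2 s the mild AR noise inflates
#' standard errors but leaves the contrast point estimates the fingerprint
#' analysis uses unbiased.
#'
#' @param vol A `volume_series` (already censored if applicable).
#' @param X T x K design matrix with named columns; an intercept is added.
#' @param source Subject id recorded on the beta maps.
#' @return An object of class `glm_fit`: `betas` (named list of `stat_map`
#'   kind `beta`), `residuals` (a `volume_series`), `condition_number`.
#' @export
fit_glm <- function(vol, X, source = "subject") {
  stopifnot(inherits(vol, "volume_series"))
  X <- as.matrix(X)
  if (nrow(X) != n_volumes(vol)) {
    stop("design rows must equal the number of volumes", call. = FALSE)
  }
  Xi <- cbind(intercept = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qrX$pivot[(qrX$rank + 1):ncol(Xi)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  Y <- volume_matrix(vol)
  B <- qr.coef(qrX, Y)
  resid <- Y - Xi %*% B
  d3 <- dim(vol$data)[1:3]
  betas <- lapply(seq_len(nrow(B)), function(k) {
    stat_map(array(B[k, ], dim = d3), kind = "beta", source = source)
  })
  names(betas) <- colnames(Xi)
  sv <- svd(Xi, nu = 0, nv = 0)$d
  structure(
    list(betas = betas,
         residuals = matrix_volume(resid, vol),
         condition_number = sv[1] / sv[length(sv)],
         source = source),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit source=%s> %d beta maps, condition number %.3g\n",
              x$source, length(x$betas), x$condition_number))
  invisible(x)
}

#' Physics minus colour contrast
#'
#' Voxelwise difference of the physics-cue and colour-cue betas; swapping
#' the condition labels negates the map exactly.
#'
#' @param fit A [fit_glm()] result containing `physics_cue` and
#'   `colour_cue` betas.
#' @return A `stat_map` of kind `contrast`.
#' @export
physics_minus_colour <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!all(c("physics_cue", "colour_cue") %in% names(fit$betas))) {
    stop("fit lacks physics_cue / colour_cue betas", call. = FALSE)
  }
  stat_map(fit$betas$physics_cue$data - fit$betas$colour_cue$data,
           kind = "contrast", source = fit$source)
}

#' Average stat maps voxelwise
#' @param maps List of `stat_map`s of a common kind and grid.
#' @return A `stat_map`.
#' @export
average_stat_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  for (m in maps[-1]) check_same_grid(maps[[1]], m)
  acc <- Reduce(`+`, lapply(maps, function(m) m$data)) / length(maps)
  stat_map(acc, kind = maps[[1]]$kind, source = maps[[1]]$source)
}

#' Group-level one-sample t-test on contrast maps
#'
#' Per-voxel one-sample t over subjects' contrast images, optionally
#' restricted to an ROI mask, with the count of voxels exceeding a t
#' threshold — after Monte-Carlo cluster correction when a
#' [cluster_config()] is supplied, uncorrected otherwise.
#'
#' @param contrast_maps List of per-subject `stat_map`s (kind `contrast`).
#' @param roi_mask Optional 3D logical mask restricting the report.
#' @param threshold_t Voxel t threshold for the suprathreshold count.
#' @param cluster_cfg Optional [cluster_config()] to cluster-correct before
#'   counting.
#' @param fwhm_est Smoothness for the cluster correction (estimated from the
#'   contrast maps when omitted).
#' @param voxel_size_mm Voxel size in mm.
#' @return List: `tmap` (`stat_map` kind `t`), `n_suprathreshold`,
#'   `suprathreshold` (3D logical), and `clusters` (tibble or NULL).
#' @export
group_contrast_ttest <- function(contrast_maps, roi_mask = NULL,
                                 threshold_t = 3.3, cluster_cfg = NULL,
                                 fwhm_est = NULL,
                                 voxel_size_mm = c(3, 3, 3.5)) {
  tmap <- group_ttest(contrast_maps)
  d <- dim(tmap$data)
  if (is.null(roi_mask)) roi_mask <- array(TRUE, dim = d)
  tv <- tmap$data
  tv[is.nan(tv)] <- 0
  supra <- tv >= threshold_t & roi_mask
  clusters <- NULL
  if (!is.null(cluster_cfg)) {
    if (is.null(fwhm_est)) {
      fwhm_est <- estimate_smoothness(contrast_maps, voxel_size_mm)
    }
    cc <- cluster_correct(tmap, roi_mask, cluster_cfg, fwhm_est, voxel_size_mm)
    supra <- supra & (cc$mask_map$data > 0)
    clusters <- cc$table
  }
  list(tmap = tmap, n_suprathreshold = sum(supra), suprathreshold = supra,
       clusters = clusters)
}
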