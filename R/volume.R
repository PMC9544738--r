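#' 4D volume timeseries
#'
#' The universal carrier for rest and task runs and their residuals: a 4D
#' scalar field (X x Y x Z x T) together with its voxel size in mm, its
#' repetition time (TR) in seconds, and a 4x4 affine mapping 0-based voxel
#' indices to world coordinates in mm (NIfTI convention).
#'
#' @param data A 3D or 4D numeric array. 3D input is promoted to a single
#'   volume (T = 1). Must be finite throughout: downstream statistics assume
#'   finite data, so NaN/Inf are rejected at construction rather than
#'   propagated.
#' @param voxel_size_mm Length-3 positive numeric, voxel edge lengths in mm.
#' @param tr_s Repetition time in seconds (> 0).
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling by
#'   `voxel_size_mm`.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_size_mm = c(3, 3, 3.5), tr_s = 2,
                          affine = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L))) {
    stop("`data` must be a 3D or 4D array", call. = FALSE)
  }
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  bad <- which(!is.finite(data))
  if (length(bad) > 0) {
    idx <- arrayInd(bad[1], dim(data))
    stop(sprintf(
      "non-finite voxel value at index [%s]",
      paste(idx, collapse = ", ")
    ), call. = FALSE)
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  stopifnot(is.numeric(tr_s), length(tr_s) == 1, tr_s > 0)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  structure(
    list(
      data = data,
      voxel_size_mm = voxel_size_mm,
      tr_s = tr_s,
      affine = affine
    ),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_series> %d x %d x %d voxels, T = %d (TR %.3g s, voxel %s mm)\n",
    d[1], d[2], d[3], d[4],
    x$tr_s, paste(format(x$voxel_size_mm), collapse = " x ")
  ))
  invisible(x)
}

#' @export
dim.volume_series <- function(x) dim(x$data)

#' Number of volumes (time points) in a series
#' @param vol A `volume_series`.
#' @return Integer T.
#' @export
n_volumes <- function(vol) dim(vol$data)[4]

spatial_dim <- function(x) {
  if (inherits(x, "volume_series")) return(dim(x$data)[1:3])
  if (inherits(x, "stat_map")) return(dim(x$data))
  if (inherits(x, "parcel_atlas")) return(dim(x$labels))
  if (is.array(x)) return(dim(x)[1:3])
  stop("cannot determine spatial grid of object", call. = FALSE)
}

check_same_grid <- function(a, b) {
  da <- spatial_dim(a)
  db <- spatial_dim(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop(sprintf(
      "grid mismatch: %s vs %s (volumes are assumed pre-aligned; no resampling is performed)",
      paste(da, collapse = "x"), paste(db, collapse = "x")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D or 4D NIfTI-1 file into a [volume_series()]. 3D files are
#' promoted to T = 1. TR is taken from the header (`pixdim[4]`) unless
#' overridden; a missing/zero header TR falls back to `tr_s`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param tr_s Optional TR override in seconds.
#' @return A `volume_series`.
#' @export
read_volume <- function(path, tr_s = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (!(length(d) %in% c(3L, 4L))) {
    stop(sprintf("expected a 3D or 4D NIfTI file, got %d dimensions", length(d)),
         call. = FALSE)
  }
  pd <- RNifti::pixdim(img)
  header_tr <- if (length(pd) >= 4) pd[4] else 0
  tr <- if (!is.null(tr_s)) tr_s else if (is.finite(header_tr) && header_tr > 0) header_tr else 2
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  volume_series(
    data = array(as.numeric(img), dim = d),
    voxel_size_mm = pd[1:3],
    tr_s = tr,
    affine = affine
  )
}

#' Write a volume series to NIfTI-1
#'
#' Header voxel sizes, TR and the qform affine are taken from the object.
#' A T = 1 series is written as a 3D file.
#'
#' @param vol A `volume_series`.
#' @param path Destination path (`.nii` or `.nii.gz`); parent must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_series"))
  if (!dir.exists(dirname(path))) {
    stop(sprintf("parent directory does not exist: %s", dirname(path)), call. = FALSE)
  }
  data <- vol$data
  if (dim(data)[4] == 1L) dim(data) <- dim(data)[1:3]
  img <- RNifti::asNifti(data)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::pixdim(img) <- c(vol$voxel_size_mm, vol$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Statistic map
#'
#' A 3D map of a single voxelwise statistic with metadata: the statistic kind
#' (`r` correlation, `z` Fisher-z, `beta` GLM coefficient, `contrast`,
#' `t`), optional degrees of freedom, and its source (a subject id or
#' `"group"`).
#'
#' @param data 3D numeric array.
#' @param kind One of `"r"`, `"z"`, `"beta"`, `"contrast"`, `"t"`.
#' @param df Optional integer degrees of freedom (required for `t` maps used
#'   in thresholding).
#' @param source Subject id or `"group"`.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(data, kind = c("r", "z", "beta", "contrast", "t"),
                     df = NULL, source = "group") {
  kind <- match.arg(kind)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (kind == "r") {
    finite <- data[is.finite(data)]
    if (length(finite) != length(data) || any(abs(finite) > 1 + 1e-12)) {
      stop("a correlation map must be finite with |r| <= 1", call. = FALSE)
    }
    data[data > 1] <- 1
    data[data < -1] <- -1
  }
  structure(
    list(data = data, kind = kind, df = df, source = source),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<stat_map kind=%s source=%s%s> %d x %d x %d\n",
    x$kind, x$source,
    if (!is.null(x$df)) sprintf(" df=%d", x$df) else "",
    d[1], d[2], d[3]
  ))
  invisible(x)
}

#' Mean timeseries over a labelled region
#'
#' Element t is the unweighted mean over all voxels carrying `label_id` at
#' volume t. The extraction is linear in the volume.
#'
#' @param vol A `volume_series`.
#' @param atlas A [parcel_atlas()] on the same grid.
#' @param label_id A label present in the atlas.
#' @return Numeric vector of length T.
#' @export
roi_mean_timeseries <- function(vol, atlas, label_id) {
  stopifnot(inherits(vol, "volume_series"), inherits(atlas, "parcel_atlas"))
  check_same_grid(vol, atlas)
  sel <- which(atlas$labels == label_id)
  if (length(sel) == 0) {
    stop(sprintf("ROI with label %s is empty", label_id), call. = FALSE)
  }
  mat <- volume_matrix(vol)  # T x V
  if (length(sel) == 1L) return(mat[, sel])
  rowMeans(mat[, sel, drop = FALSE])
}

# T x V view of a volume_series (voxels in array order)
volume_matrix <- function(vol) {
  d <- dim(vol$data)
  t(matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4]))
}

# rebuild a volume_series from a T x V matrix on the grid of `like`
matrix_volume <- function(mat, like) {
  d <- dim(like$data)
  stopifnot(ncol(mat) == prod(d[1:3]))
  volume_series(
    array(t(mat), dim = c(d[1:3], nrow(mat))),
    voxel_size_mm = like$voxel_size_mm,
    tr_s = like$tr_s,
    affine = like$affine
  )
}
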