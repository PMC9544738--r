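#' Parcel atlas
#'
#' A 3D integer label field on the cohort grid plus a label table giving each
#' parcel an id, a name and a functional role. Label 0 is background. Roles:
#' `acc_dacc` (the dorsal anterior cingulate seed, exactly one per
#' hemisphere), `acc_other` (remaining ACC subdivisions), `physics`
#' (task-localizer parcels), `searchmask` (fronto-parietal search region),
#' `wm` and `ventricle` (nuisance-signal compartments).
#'
#' The search mask geometrically contains the physics parcels; because a
#' single label field cannot overlap, search-mask voxels that also belong to
#' a physics parcel carry the physics label, and [atlas_mask()] re-unions
#' them when the `searchmask` role is requested.
#'
#' @param labels 3D integer array; 0 = background.
#' @param table Data frame with columns `label_id` (positive integer),
#'   `name` (string; dACC names must end in `_L`/`_R` to identify the
#'   hemisphere), `role` (one of the roles above).
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return An object of class `parcel_atlas`.
#' @export
parcel_atlas <- function(labels, table, voxel_size_mm = c(3, 3, 3.5)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  labels <- array(as.integer(labels), dim = dim(labels))
  table <- tibble::as_tibble(table)
  stopifnot(all(c("label_id", "name", "role") %in% names(table)))
  roles <- c("acc_dacc", "acc_other", "physics", "searchmask", "wm", "ventricle")
  if (!all(table$role %in% roles)) {
    stop("unknown parcel role(s): ",
         paste(setdiff(table$role, roles), collapse = ", "), call. = FALSE)
  }
  if (any(table$label_id <= 0)) stop("label ids must be positive", call. = FALSE)
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, table$label_id)
  if (length(missing) > 0) {
    stop("labels present in the volume but missing from the table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dacc <- table[table$role == "acc_dacc", ]
  hemi <- vapply(dacc$name, function(nm) {
    if (grepl("_L$", nm)) "L" else if (grepl("_R$", nm)) "R" else NA_character_
  }, character(1))
  if (nrow(dacc) != 2 || anyNA(hemi) || length(unique(hemi)) != 2) {
    stop("expected exactly one acc_dacc label per hemisphere (names ending _L and _R)",
         call. = FALSE)
  }
  structure(
    list(labels = labels, table = table, voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "parcel_atlas"
  )
}

#' @export
print.parcel_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<parcel_atlas> %d x %d x %d, %d parcels\n",
              d[1], d[2], d[3], nrow(x$table)))
  print(dplyr::count(x$table, .data$role))
  invisible(x)
}

#' Logical mask for atlas labels or roles
#'
#' @param atlas A `parcel_atlas`.
#' @param roles Character vector of roles to include (the `searchmask` role
#'   implicitly unions the physics parcels it contains).
#' @param label_ids Integer label ids to include (alternative to `roles`).
#' @return 3D logical array.
#' @export
atlas_mask <- function(atlas, roles = NULL, label_ids = NULL) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  if (is.null(roles) && is.null(label_ids)) {
    stop("supply `roles` or `label_ids`", call. = FALSE)
  }
  ids <- integer(0)
  if (!is.null(roles)) {
    eff <- roles
    if ("searchmask" %in% roles) eff <- union(eff, "physics")
    ids <- c(ids, atlas$table$label_id[atlas$table$role %in% eff])
  }
  ids <- union(ids, as.integer(label_ids %||% integer(0)))
  if (length(ids) == 0) stop("no matching labels", call. = FALSE)
  array(atlas$labels %in% ids, dim = dim(atlas$labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label ids of the dACC seed parcels
#' @param atlas A `parcel_atlas`.
#' @return Named integer vector with elements `L` and `R`.
#' @export
dacc_labels <- function(atlas) {
  dacc <- atlas$table[atlas$table$role == "acc_dacc", ]
  hemi <- ifelse(grepl("_L$", dacc$name), "L", "R")
  setNames(as.integer(dacc$label_id), hemi)[c("L", "R")]
}

#' Write / read an atlas as NIfTI + label-table TSV
#'
#' The label volume goes to `<path>.nii.gz` and the table to `<path>.tsv`
#' with columns `label_id name role`.
#'
#' @param atlas A `parcel_atlas`.
#' @param path Path stem (no extension).
#' @return `write_atlas()`: the stem, invisibly; `read_atlas()`: a
#'   `parcel_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  vol <- volume_series(array(as.numeric(atlas$labels), dim = dim(atlas$labels)),
                       voxel_size_mm = atlas$voxel_size_mm, tr_s = 1)
  write_volume(vol, paste0(path, ".nii.gz"))
  write.table(atlas$table[, c("label_id", "name", "role")],
              paste0(path, ".tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  vol <- read_volume(paste0(path, ".nii.gz"))
  tab <- read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  labels <- array(as.integer(round(vol$data[, , , 1])), dim = dim(vol$data)[1:3])
  parcel_atlas(labels, tab, voxel_size_mm = vol$voxel_size_mm)
}

#' Motion parameter table
#'
#' Per-volume rigid-body motion estimates: three rotations (roll, pitch,
#' yaw; degrees) and three translations (dS, dP, dL; mm).
#'
#' @param x Data frame or matrix with columns
#'   `roll, pitch, yaw, dS, dP, dL`, one row per volume.
#' @return A tibble of class `motion_table`.
#' @export
motion_table <- function(x) {
  cols <- c("roll", "pitch", "yaw", "dS", "dP", "dL")
  x <- tibble::as_tibble(as.data.frame(x))
  stopifnot(all(cols %in% names(x)))
  x <- x[, cols]
  if (!all(vapply(x, function(c) all(is.finite(c)), logical(1)))) {
    stop("motion parameters must be finite", call. = FALSE)
  }
  class(x) <- c("motion_table", class(x))
  x
}

#' Read / write a motion table as whitespace-delimited text
#'
#' @param path File path; header line `roll pitch yaw dS dP dL`.
#' @param motion A `motion_table`.
#' @return `read_motion()`: a `motion_table`; `write_motion()`: `path`,
#'   invisibly.
#' @export
read_motion <- function(path) {
  motion_table(read.table(path, header = TRUE))
}

#' @rdname read_motion
#' @export
write_motion <- function(motion, path) {
  write.table(as.data.frame(motion), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
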