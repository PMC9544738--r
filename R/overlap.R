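#' Percentile-threshold sweep of a connectivity map
#'
#' Computes percentile thresholds of the map's values within the search
#' mask and, per level, the mask of voxels at or above that threshold.
#' The default sweep runs from the 99th percentile upward in steps of 0.05
#' for 20 levels (99.00--99.95): a sweep through the 100th percentile would
#' give 21 levels whose last retains at most one voxel, so the final level
#' stops one step short. Masks are nested (each level's mask contains the
#' next).
#'
#' @param zmap A `stat_map` (kind `z` or `t`) or 3D numeric array.
#' @param search_mask 3D logical mask; percentiles are computed within it.
#' @param start_pct,end_pct,step_pct Sweep definition in percent.
#' @return Tibble with columns `percentile`, `threshold`, `n_voxels`, and a
#'   list-column `mask` of 3D logical arrays.
#' @export
percentile_sweep <- function(zmap, search_mask, start_pct = 99,
                             end_pct = 99.95, step_pct = 0.05) {
  x <- if (inherits(zmap, "stat_map")) zmap$data else zmap
  stopifnot(is.array(x), identical(dim(x), dim(search_mask)))
  if (!any(search_mask)) stop("search mask is empty", call. = FALSE)
  vals <- x[search_mask]
  if (max(vals) == min(vals)) {
    stop("map is constant within the search mask", call. = FALSE)
  }
  pct <- seq(start_pct, end_pct, by = step_pct)
  thr <- quantile(vals, probs = pct / 100, names = FALSE)
  masks <- lapply(thr, function(q) (x >= q) & search_mask)
  tibble::tibble(
    percentile = pct,
    threshold = thr,
    n_voxels = vapply(masks, sum, integer(1)),
    mask = masks
  )
}

#' Fraction of suprathreshold voxels inside the physics parcels
#'
#' `|suprathreshold & physics & search| / |suprathreshold & search|`.
#'
#' @param suprathreshold_mask 3D logical.
#' @param physics_mask 3D logical (the task-defined parcels).
#' @param search_mask 3D logical.
#' @return Proportion in [0, 1]; `NA` (flagged via warning) when no
#'   suprathreshold voxel falls in the search mask.
#' @export
overlap_fraction <- function(suprathreshold_mask, physics_mask, search_mask) {
  denom <- sum(suprathreshold_mask & search_mask)
  if (denom == 0) {
    warning("no suprathreshold voxels inside the search mask")
    return(NA_real_)
  }
  sum(suprathreshold_mask & physics_mask & search_mask) / denom
}

#' Percentile-overlap curve
#'
#' Composes [percentile_sweep()] and [overlap_fraction()]: the proportion of
#' the most strongly seed-connected voxels that fall inside the
#' task-defined physics parcels, as a function of threshold stringency.
#'
#' @param zmap A `stat_map` or 3D array of connectivity strength.
#' @param atlas A `parcel_atlas` (roles `physics` and `searchmask`), or
#'   `NULL` when masks are given directly.
#' @param physics_mask,search_mask Explicit 3D logical masks (default from
#'   the atlas).
#' @param seed_label Label recorded on the curve (e.g. `"dACC"`).
#' @param hemisphere Recorded hemisphere tag.
#' @param start_pct,end_pct,step_pct Sweep definition.
#' @return A tibble of class `overlap_curve` with columns `percentile`,
#'   `threshold`, `n_voxels`, `proportion`.
#' @export
overlap_curve <- function(zmap, atlas = NULL, physics_mask = NULL,
                          search_mask = NULL, seed_label = "dACC",
                          hemisphere = "both", start_pct = 99,
                          end_pct = 99.95, step_pct = 0.05) {
  if (is.null(physics_mask)) physics_mask <- atlas_mask(atlas, roles = "physics")
  if (is.null(search_mask)) search_mask <- atlas_mask(atlas, roles = "searchmask")
  sweep <- percentile_sweep(zmap, search_mask, start_pct, end_pct, step_pct)
  out <- tibble::tibble(
    percentile = sweep$percentile,
    threshold = sweep$threshold,
    n_voxels = sweep$n_voxels,
    proportion = vapply(sweep$mask, overlap_fraction, numeric(1),
                        physics_mask = physics_mask, search_mask = search_mask)
  )
  class(out) <- c("overlap_curve", class(out))
  attr(out, "seed_label") <- seed_label
  attr(out, "hemisphere") <- hemisphere
  out
}

#' Write an overlap curve as TSV
#' @param curve An [overlap_curve()] tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_overlap_curve <- function(curve, path) {
  write.table(as.data.frame(curve[, c("percentile", "n_voxels", "proportion")]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
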