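#' Spatial correlation of two maps within an ROI
#'
#' Pearson correlation across voxels (not time) of two statistic maps
#' restricted to an ROI mask.
#'
#' @param map_a,map_b `stat_map`s or 3D arrays on a common grid.
#' @param roi_mask 3D logical mask with >= 10 voxels.
#' @return Correlation `r`.
#' @export
spatial_correlation <- function(map_a, map_b, roi_mask) {
  a <- if (inherits(map_a, "stat_map")) map_a$data else map_a
  b <- if (inherits(map_b, "stat_map")) map_b$data else map_b
  stopifnot(identical(dim(a), dim(b)), identical(dim(a), dim(roi_mask)))
  if (sum(roi_mask) < 10) stop("ROI has fewer than 10 voxels", call. = FALSE)
  av <- a[roi_mask]
  bv <- b[roi_mask]
  if (sd(av) == 0 || sd(bv) == 0) {
    stop("map constant within the ROI", call. = FALSE)
  }
  cor(av, bv)
}

#' Within- versus between-subject fingerprint table
#'
#' For each subject and each task-defined region: `within_z` is the
#' Fisher-z spatial correlation of the subject's seed-connectivity map with
#' their own task contrast; `between_z` is the mean over all other subjects
#' j of the Fisher-z correlation with subject j's contrast (correlations
#' are z-transformed before averaging). Per-subject mean framewise
#' displacement is carried along for the motion-confound check.
#'
#' @param conn_maps Named list of per-subject connectivity maps
#'   (`stat_map`, kind `z`).
#' @param contrast_maps Named list (same names) of per-subject contrast
#'   maps.
#' @param region_masks Named list of 3D logical region masks (typically the
#'   group-significant physics voxels intersected with each parcel).
#' @param mean_fd Optional named numeric of per-subject mean framewise
#'   displacement (mm).
#' @return A tibble of class `fingerprint_table` with columns `subject`,
#'   `region`, `within_z`, `between_z`, `mean_fd_mm`.
#' @export
within_between_table <- function(conn_maps, contrast_maps, region_masks,
                                 mean_fd = NULL) {
  subjects <- names(conn_maps)
  if (is.null(subjects) || !setequal(subjects, names(contrast_maps))) {
    stop("conn_maps and contrast_maps must be named lists over the same subjects",
         call. = FALSE)
  }
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  out <- purrr::map_dfr(names(region_masks), function(rg) {
    mask <- region_masks[[rg]]
    z <- outer(subjects, subjects,
               Vectorize(function(i, j) {
                 fisher_z(spatial_correlation(conn_maps[[i]],
                                              contrast_maps[[j]], mask))
               }))
    dimnames(z) <- list(subjects, subjects)
    purrr::map_dfr(subjects, function(i) {
      tibble::tibble(
        subject = i,
        region = rg,
        within_z = z[i, i],
        between_z = mean(z[i, setdiff(subjects, i)]),
        mean_fd_mm = if (is.null(mean_fd)) NA_real_ else unname(mean_fd[i])
      )
    })
  })
  class(out) <- c("fingerprint_table", class(out))
  out
}

#' Repeated-measures ANOVA on a fingerprint table
#'
#' Classical subject-as-random-block repeated-measures decomposition with
#' two within-subject factors (by default condition = within/between and
#' region), each effect tested against its own subject-by-effect
#' interaction error stratum, fitted via `stats::aov` with an
#' `Error(subject/...)` term. A degenerate table in which every cell is
#' equal yields all-zero sums of squares; F is then reported as 0 with a
#' note.
#'
#' @param table A [within_between_table()] result, or any long data frame.
#' @param value,subject,factors Column names (strings) when supplying a
#'   generic long table; the default reshapes a `fingerprint_table` to long
#'   format with factors `condition` (within/between) and `region`.
#' @return A tibble of class `rm_anova` with columns `effect`, `F`,
#'   `df_num`, `df_den`, `p`.
#' @export
rm_anova <- function(table, value = "z", subject = "subject",
                     factors = c("condition", "region")) {
  if (inherits(table, "fingerprint_table") && !(value %in% names(table))) {
    table <- tidyr::pivot_longer(tibble::as_tibble(table),
                                 c("within_z", "between_z"),
                                 names_to = "condition", values_to = "z")
    table$condition <- sub("_z$", "", table$condition)
  }
  df <- as.data.frame(table)
  stopifnot(all(c(value, subject, factors) %in% names(df)))
  df[[subject]] <- factor(df[[subject]])
  for (f in factors) df[[f]] <- factor(df[[f]])
  n_cells <- prod(vapply(df[factors], nlevels, integer(1))) *
    nlevels(df[[subject]])
  if (nrow(df) != n_cells) {
    stop("incomplete repeated-measures layout: expected one observation per subject x cell",
         call. = FALSE)
  }
  fml <- stats::as.formula(sprintf(
    "%s ~ %s + Error(%s/(%s))",
    value, paste(factors, collapse = "*"), subject,
    paste(factors, collapse = "*")
  ))
  fit <- aov(fml, data = df)
  sm <- summary(fit)
  rows <- purrr::map_dfr(sm, function(stratum) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    keep <- eff != "Residuals"
    if (!any(keep)) return(NULL)
    err <- tab[eff == "Residuals", , drop = FALSE]
    tibble::tibble(
      effect = eff[keep],
      ss = tab[keep, "Sum Sq"],
      df_num = tab[keep, "Df"],
      ss_err = err[1, "Sum Sq"],
      df_den = err[1, "Df"]
    )
  })
  rows <- rows[rows$effect %in% c(factors, paste(factors, collapse = ":")), ]
  degenerate <- rows$ss < 1e-24 & rows$ss_err < 1e-24
  ms <- rows$ss / rows$df_num
  mse <- rows$ss_err / rows$df_den
  Fv <- ifelse(degenerate, 0, ms / mse)
  out <- tibble::tibble(
    effect = rows$effect,
    F = Fv,
    df_num = as.integer(rows$df_num),
    df_den = as.integer(rows$df_den),
    p = ifelse(degenerate, NA_real_, pf(Fv, rows$df_num, rows$df_den,
                                        lower.tail = FALSE))
  )
  class(out) <- c("rm_anova", class(out))
  if (any(degenerate)) {
    attr(out, "note") <- "all cells equal in one or more strata; F reported as 0"
  }
  out
}

#' Motion-confound check
#'
#' Pearson correlation across subjects between mean framewise displacement
#' and the mean fingerprint gap (within_z - between_z averaged over
#' regions). A large correlation would indicate that apparent
#' subject-specific coupling merely tracks head motion.
#'
#' @param table A [within_between_table()] with `mean_fd_mm` filled in.
#' @return List: `r`, `n_subjects`, and the per-subject summary tibble.
#' @export
motion_confound_check <- function(table) {
  per <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table), .data$subject),
    gap = mean(.data$within_z - .data$between_z),
    fd = mean(.data$mean_fd_mm),
    .groups = "drop"
  )
  if (nrow(per) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (anyNA(per$fd)) stop("mean_fd_mm missing", call. = FALSE)
  if (sd(per$fd) == 0 || sd(per$gap) == 0) {
    stop("zero variance in motion or fingerprint gap", call. = FALSE)
  }
  list(r = cor(per$fd, per$gap), n_subjects = nrow(per), table = per)
}
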