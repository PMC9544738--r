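#' Plot an overlap curve
#'
#' Proportion of the most strongly seed-connected voxels falling inside the
#' task-defined physics parcels, against threshold stringency.
#'
#' @param object An [overlap_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$percentile, y = .data$proportion)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(colour = "#2c7fb8") +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x) 100 * x) +
    ggplot2::labs(
      x = "connectivity percentile threshold",
      y = "% of suprathreshold voxels inside physics parcels",
      title = sprintf("Seed %s (%s hemisphere)",
                      attr(object, "seed_label") %||% "seed",
                      attr(object, "hemisphere") %||% "both")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fingerprint table
#'
#' Paired within- versus between-subject Fisher-z spatial correlations per
#' region, one line per subject.
#'
#' @param object A [within_between_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fingerprint_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("within_z", "between_z"),
                              names_to = "condition", values_to = "z")
  long$condition <- factor(sub("_z$", "", long$condition),
                           levels = c("within", "between"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$z,
                                     group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = NULL, y = "spatial correlation (Fisher z)") +
    ggplot2::theme_minimal()
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova>\n")
  df <- tibble::as_tibble(x)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-20s F(%d, %d) = %.3f, p = %.4g\n",
                df$effect[i], df$df_num[i], df$df_den[i], df$F[i], df$p[i]))
  }
  if (!is.null(attr(x, "note"))) cat("  note:", attr(x, "note"), "\n")
  invisible(x)
}

#' Tidy a repeated-measures ANOVA
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return Tibble with one row per effect: term, statistic, df, df.residual,
#'   p.value.
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(
    term = x$effect,
    statistic = x$F,
    df = x$df_num,
    df.residual = x$df_den,
    p.value = x$p
  )
}

#' One-row summary of a repeated-measures ANOVA (the condition effect)
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return One-row tibble: statistic, df, df.residual, p.value.
#' @export
glance.rm_anova <- function(x, ...) {
  i <- match("condition", x$effect)
  if (is.na(i)) i <- 1L
  tibble::tibble(
    statistic = x$F[i], df = x$df_num[i],
    df.residual = x$df_den[i], p.value = x$p[i]
  )
}

#' Tidy a voxelwise GLM fit
#' @param x A `glm_fit`.
#' @param ... Unused.
#' @return Tibble with per-regressor summary statistics of the beta maps.
#' @export
tidy.glm_fit <- function(x, ...) {
  purrr::map_dfr(names(x$betas), function(nm) {
    b <- x$betas[[nm]]$data
    tibble::tibble(
      term = nm,
      mean_beta = mean(b),
      sd_beta = sd(as.vector(b)),
      max_abs_beta = max(abs(b))
    )
  })
}

#' One-row summary of a voxelwise GLM fit
#' @param x A `glm_fit`.
#' @param ... Unused.
#' @return One-row tibble: n_regressors, n_voxels, T, condition_number,
#'   residual_sd.
#' @export
glance.glm_fit <- function(x, ...) {
  d <- dim(x$residuals$data)
  tibble::tibble(
    n_regressors = length(x$betas) - 1L,
    n_voxels = prod(d[1:3]),
    n_volumes = d[4],
    condition_number = x$condition_number,
    residual_sd = sd(as.vector(x$residuals$data))
  )
}
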