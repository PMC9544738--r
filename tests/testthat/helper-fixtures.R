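# small deterministic fixtures shared across test files

tiny_volume <- function(dims = c(4, 4, 3), n_t = 20, seed = 1,
                        voxel = c(3, 3, 3.5), tr = 2) {
  set.seed(seed)
  volume_series(array(rnorm(prod(dims) * n_t), dim = c(dims, n_t)),
                voxel_size_mm = voxel, tr_s = tr)
}

# quick cohort parameters: full 20^3 grid but shorter rest runs, for unit
# tests that only need the pipeline to run end to end
quick_params <- function(...) {
  args <- list(n_subjects = 4, n_rest_volumes = 80,
               rest_runs_per_subject = 1, master_seed = 7L)
  do.call(cohort_params, utils::modifyList(args, list(...)))
}

# an atlas on the default grid, built once per test run
default_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_atlas(cohort_params())
    cache
  }
})

# AR(1) helpers mirrored from the package internals for oracle use
ar1_stationary_sd <- function(sigma, phi) sigma / sqrt(1 - phi^2)

still_motion <- function(n_t) {
  motion_table(matrix(0, n_t, 6,
                      dimnames = list(NULL,
                                      c("roll", "pitch", "yaw", "dS", "dP", "dL"))))
}

# independent oracle: classical repeated-measures sums-of-squares decomposition
brute_force_rm_anova <- function(df, value, subject, f1, f2) {
  y <- df[[value]]
  g <- mean(y)
  m_s <- tapply(y, df[[subject]], mean)
  m_1 <- tapply(y, df[[f1]], mean)
  m_2 <- tapply(y, df[[f2]], mean)
  m_12 <- tapply(y, list(df[[f1]], df[[f2]]), mean)
  m_1s <- tapply(y, list(df[[f1]], df[[subject]]), mean)
  m_2s <- tapply(y, list(df[[f2]], df[[subject]]), mean)
  a <- nlevels(factor(df[[f1]])); b <- nlevels(factor(df[[f2]]))
  s <- nlevels(factor(df[[subject]]))
  ss_1 <- s * b * sum((m_1 - g)^2)
  ss_2 <- s * a * sum((m_2 - g)^2)
  ss_12 <- s * sum((m_12 - outer(m_1 - g, m_2 - g, `+`) - g)^2)
  ss_1s <- b * sum((m_1s - outer(m_1 - g, m_s - g, `+`) - g)^2)
  ss_2s <- a * sum((m_2s - outer(m_2 - g, m_s - g, `+`) - g)^2)
  fitted <- g +
    (m_1[df[[f1]]] - g) + (m_2[df[[f2]]] - g) + (m_s[df[[subject]]] - g) +
    (m_12[cbind(df[[f1]], df[[f2]])] - m_1[df[[f1]]] - m_2[df[[f2]]] + g) +
    (m_1s[cbind(df[[f1]], df[[subject]])] - m_1[df[[f1]]] - m_s[df[[subject]]] + g) +
    (m_2s[cbind(df[[f2]], df[[subject]])] - m_2[df[[f2]]] - m_s[df[[subject]]] + g)
  ss_12s <- sum((y - fitted)^2)
  list(
    F1 = (ss_1 / (a - 1)) / (ss_1s / ((a - 1) * (s - 1))),
    F2 = (ss_2 / (b - 1)) / (ss_2s / ((b - 1) * (s - 1))),
    F12 = (ss_12 / ((a - 1) * (b - 1))) / (ss_12s / ((a - 1) * (b - 1) * (s - 1))),
    df = c(a - 1, (a - 1) * (s - 1), b - 1, (b - 1) * (s - 1))
  )
}
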