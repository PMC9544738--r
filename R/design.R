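#' Build the palindromic block design of the physics/colour localizer
#'
#' One run is 23 contiguous 18-s blocks (414 s, 207 volumes at TR 2 s):
#' 10 physical-judgement blocks, 10 colour-judgement blocks and 3 rest
#' blocks fixed at positions 1, 12 and 23. The 20 task blocks are arranged
#' in a pseudorandom palindrome — the second half mirrors the first — so the
#' pairwise ordering of block types is balanced within a run. Each task
#' block contains two repetitions of (1-s text cue, 6-s movie, 2-s
#' response).
#'
#' @param seed Integer seed for the pseudorandom first half.
#' @param tr_s TR in seconds.
#' @param block_s Block duration in seconds.
#' @return An object of class `block_design`: `blocks` (tibble: index, type,
#'   onset_s, duration_s), `events` (tibble: type, onset_s, duration_s),
#'   `tr_s`, `total_duration_s`.
#' @export
build_block_design <- function(seed = 1L, tr_s = 2, block_s = 18) {
  half <- withr_seed(seed, sample(rep(c("physics", "colour"), each = 5)))
  task_types <- c(half, rev(half))          # palindrome over 20 task blocks
  types <- character(23)
  types[c(1, 12, 23)] <- "rest"
  types[types == ""] <- task_types
  blocks <- tibble::tibble(
    index = 1:23,
    type = types,
    onset_s = (0:22) * block_s,
    duration_s = block_s
  )
  events <- purrr::map_dfr(which(types != "rest"), function(i) {
    t0 <- blocks$onset_s[i]
    cue <- paste0("cue_", types[i])
    tibble::tibble(
      type = c(cue, "movie", "response", cue, "movie", "response"),
      onset_s = t0 + c(0, 1, 7, 9, 10, 16),
      duration_s = c(1, 6, 2, 1, 6, 2)
    )
  })
  events <- events[order(events$onset_s), ]
  structure(
    list(
      blocks = blocks,
      events = events,
      tr_s = tr_s,
      total_duration_s = sum(blocks$duration_s)
    ),
    class = "block_design"
  )
}

# evaluate `expr` under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design> %d blocks, %g s total (TR %g s, %d volumes)\n",
              nrow(x$blocks), x$total_duration_s, x$tr_s,
              as.integer(round(x$total_duration_s / x$tr_s))))
  cat(paste(substr(x$blocks$type, 1, 1), collapse = " "), "\n")
  invisible(x)
}

#' Gamma-variate haemodynamic response function
#'
#' `h(t) = (t/(p*q))^p * exp(p - t/q)`, a gamma-variate normalized to peak
#' value 1 at `t = p*q`. The defaults `p = 8.6`, `q = 0.547` put the peak at
#' 4.70 s.
#'
#' @param t_s Time since event onset, seconds (>= 0).
#' @param p,q Shape and scale parameters.
#' @return Unitless response values.
#' @export
hrf_gamma <- function(t_s, p = 8.6, q = 0.547) {
  if (any(t_s < 0)) stop("hrf_gamma is defined for t >= 0", call. = FALSE)
  (t_s / (p * q))^p * exp(p - t_s / q)
}

#' Convolve a block design into condition regressors
#'
#' For each condition a boxcar over that condition's cue intervals is sampled
#' on the TR grid as the fractional overlap of each TR interval with the cue
#' intervals (exact for on-grid events; the second cue of each block starts
#' 9 s into the block and so falls off the 2-s grid), then discretely
#' convolved with the HRF sampled at 0, TR, 2*TR, ... and truncated to T.
#'
#' @param design A [build_block_design()] result.
#' @param hrf HRF function of time in seconds.
#' @param conditions Which cue conditions to build columns for.
#' @return T x K numeric matrix with columns `physics_cue`, `colour_cue`.
#' @export
convolve_design <- function(design, hrf = hrf_gamma,
                            conditions = c("physics", "colour")) {
  tr <- design$tr_s
  n_vol <- as.integer(round(design$total_duration_s / tr))
  hrf_s <- hrf(seq(0, by = tr, length.out = n_vol))
  cols <- lapply(conditions, function(cond) {
    ev <- design$events[design$events$type == paste0("cue_", cond), ]
    box <- boxcar_tr(ev$onset_s, ev$duration_s, tr, n_vol)
    convolve_discrete(box, hrf_s)[seq_len(n_vol)]
  })
  x <- do.call(cbind, cols)
  colnames(x) <- paste0(conditions, "_cue")
  x
}

# fraction of each TR interval [t, t+tr) covered by the given event intervals
boxcar_tr <- function(onsets, durations, tr, n_vol) {
  box <- numeric(n_vol)
  starts <- (seq_len(n_vol) - 1) * tr
  for (k in seq_along(onsets)) {
    lo <- pmax(starts, onsets[k])
    hi <- pmin(starts + tr, onsets[k] + durations[k])
    box <- box + pmax(0, hi - lo) / tr
  }
  box
}

convolve_discrete <- function(x, h) {
  n <- length(x) + length(h) - 1
  Re(fft(fft(c(x, numeric(n - length(x)))) *
           fft(c(h, numeric(n - length(h)))), inverse = TRUE)) / n
}

#' Export a design as a 3-column events table
#' @param design A `block_design`.
#' @param path TSV destination (columns onset, duration, condition).
#' @return `path`, invisibly.
#' @export
write_design_events <- function(design, path) {
  tab <- data.frame(
    onset = design$blocks$onset_s,
    duration = design$blocks$duration_s,
    condition = design$blocks$type
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
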