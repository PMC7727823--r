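#' Summary statistics with block-averaged uncertainty
#'
#' Frames extracted from a molecular-dynamics trajectory are autocorrelated,
#' so the naive standard error of the mean is too small. The block-averaging
#' estimator splits the series into contiguous blocks, averages within each
#' block, and reports the standard error of the block means. The trailing
#' partial block, if any, is dropped from the block means (never from the
#' overall mean or sd).
#'
#' @param values Numeric vector (one series, e.g. a bond length or one
#'   atom's instantaneous shift).
#' @param block_size Frames per block; `1` recovers the naive SEM. With the
#'   default 200 fs snapshot spacing the default of 10 frames spans 2 ps.
#' @param label Optional label recorded in the output.
#'
#' @return One-row tibble: `label`, `mean`, `sem`, `sd`, `min`, `max`,
#'   `n_frames`, `block_size`. `sem` is `NA` when fewer than two complete
#'   blocks exist.
#' @examples
#' summarize_series(c(1, 2, 3, 4), block_size = 1)
#' @export
summarize_series <- function(values, block_size = 10, label = NA_character_) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1) abort("need at least one value")
  if (block_size < 1) abort("block_size must be >= 1")
  if (block_size > n)
    abort(paste0("block_size (", block_size, ") exceeds series length (", n, ")"))
  n_blocks <- n %/% block_size
  block_means <- vapply(seq_len(n_blocks), function(b)
    mean(values[((b - 1) * block_size + 1):(b * block_size)]), numeric(1))
  sem <- if (n_blocks >= 2) stats::sd(block_means) / sqrt(n_blocks) else NA_real_
  tibble(label = label,
         mean = mean(values),
         sem = sem,
         sd = if (n >= 2) stats::sd(values) else NA_real_,
         min = min(values),
         max = max(values),
         n_frames = n,
         block_size = as.integer(block_size))
}

#' Summarise every column of a wide series table
#'
#' @param series Wide series tibble (`time_fs` + one column per label).
#' @inheritParams summarize_series
#' @return A tibble with one [summarize_series()] row per label.
#' @export
summarize_series_table <- function(series, block_size = 10) {
  series <- as_tibble(series)
  purrr::map_dfr(series_labels(series), function(lab)
    summarize_series(series[[lab]], block_size = block_size, label = lab))
}

#' Fluctuation range of a series
#'
#' @param values Numeric vector.
#' @return One-row tibble with `min`, `max` and `span = max - min`. For an
#'   instantaneous shift series the span is the quantity usually quoted as
#'   the fluctuation amplitude (tens of ppm for conjugated carbons at 300 K).
#' @export
fluctuation_range <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) abort("need at least one value")
  tibble(min = min(values), max = max(values), span = max(values) - min(values))
}

#' Compare a computed shift pattern with a reference pattern
#'
#' Matches labels shared between the two maps (e.g. computed trajectory
#' averages vs reported MAS-NMR values) and reports the root-mean-square
#' deviation, the Pearson correlation of the patterns and per-label
#' residuals (computed minus reference).
#'
#' @param computed,reference Named numeric vectors (names are atom labels),
#'   or two-column data frames `(label, value)`.
#' @return A `pattern_comparison` object; see [tidy.pattern_comparison()]
#'   and [glance.pattern_comparison()].
#' @examples
#' compare_shift_patterns(c(C13 = 150, C14 = 130), c(C13 = 155, C14 = 135))
#' @export
compare_shift_patterns <- function(computed, reference) {
  computed <- as_label_map(computed)
  reference <- as_label_map(reference)
  shared <- intersect(names(computed), names(reference))
  if (length(shared) < 2)
    abort("need at least 2 shared labels to compare patterns")
  resid <- computed[shared] - reference[shared]
  structure(list(
    residuals = tibble(label = shared,
                       computed = unname(computed[shared]),
                       reference = unname(reference[shared]),
                       residual = unname(resid)),
    rmsd = sqrt(mean(resid^2)),
    pearson_r = stats::cor(computed[shared], reference[shared]),
    n = length(shared)
  ), class = "pattern_comparison")
}

as_label_map <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    return(setNames(as.numeric(x[[2]]), as.character(x[[1]])))
  }
  if (is.null(names(x))) abort("pattern must be named or a (label, value) frame")
  setNames(as.numeric(x), names(x))
}

#' @export
print.pattern_comparison <- function(x, ...) {
  cat(sprintf("<pattern_comparison> %d shared labels, rmsd %.4g, r %.4f\n",
              x$n, x$rmsd, x$pearson_r))
  print(x$residuals)
  invisible(x)
}

#' @rdname compare_shift_patterns
#' @param x A `pattern_comparison`.
#' @param ... Unused.
#' @method tidy pattern_comparison
#' @export
tidy.pattern_comparison <- function(x, ...) x$residuals

#' @rdname compare_shift_patterns
#' @method glance pattern_comparison
#' @export
glance.pattern_comparison <- function(x, ...) {
  tibble(rmsd = x$rmsd, pearson_r = x$pearson_r, n = x$n)
}
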