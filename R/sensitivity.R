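#' Ordinary least squares of one shift on one bond length
#'
#' Regresses instantaneous chemical shift (ppm) on instantaneous bond length
#' (Angstrom) and reports the slope with both the classical standard error
#' and a block (batch-means) standard error that accounts for the
#' autocorrelation of trajectory frames. The block p-value drives the
#' significance mask in [build_sensitivity_matrix()].
#'
#' When the shift is constant the slope, correlation and p-value are set by
#' convention to 0, 0 and 1. A constant bond length is an error: the
#' regressor carries no information.
#'
#' @param delta Numeric vector of instantaneous shifts (ppm).
#' @param d Numeric vector of instantaneous bond lengths (Angstrom).
#' @param block_size Frames per block for the batch-means standard error.
#'
#' @return One-row tibble: `slope_ppm_per_A`, `intercept_ppm`,
#'   `stderr_slope`, `p_value` (classical t test), `stderr_block`,
#'   `p_block` (batch-means t test, df = n_blocks - 1), `pearson_r`, `n`.
#' @examples
#' d <- c(1.40, 1.42, 1.44, 1.46, 1.48)
#' pairwise_regression(150 + 100 * (d - 1.4), d, block_size = 1)
#' @export
pairwise_regression <- function(delta, d, block_size = 10) {
  delta <- as.numeric(delta); d <- as.numeric(d)
  n <- length(d)
  if (length(delta) != n) abort("delta and d must have equal length")
  if (n < 3) abort("need at least 3 frames")
  sxx <- sum((d - mean(d))^2)
  if (sxx == 0) abort("bond length series has zero variance")

  if (stats::var(delta) == 0) {
    return(tibble(slope_ppm_per_A = 0, intercept_ppm = mean(delta),
                  stderr_slope = 0, p_value = 1,
                  stderr_block = 0, p_block = 1,
                  pearson_r = 0, n = n))
  }

  xc <- d - mean(d)
  slope <- sum(xc * delta) / sxx
  intercept <- mean(delta) - slope * mean(d)
  e <- delta - intercept - slope * d
  s2 <- sum(e^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- if (se > 0) slope / se else sign(slope) * Inf
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  r <- stats::cor(d, delta)

  # batch-means SE via the slope's influence values; residuals rescaled for
  # the fitted degrees of freedom (HC1-style) so the test stays calibrated
  psi <- n * xc * (e * sqrt(n / (n - 2))) / sxx
  n_blocks <- n %/% block_size
  if (n_blocks >= 2) {
    bm <- vapply(seq_len(n_blocks), function(b)
      mean(psi[((b - 1) * block_size + 1):(b * block_size)]), numeric(1))
    se_b <- stats::sd(bm) / sqrt(n_blocks)
    tb <- if (se_b > 0) slope / se_b else sign(slope) * Inf
    p_b <- 2 * stats::pt(abs(tb), df = n_blocks - 1, lower.tail = FALSE)
  } else {
    se_b <- se; p_b <- p
  }

  tibble(slope_ppm_per_A = slope, intercept_ppm = intercept,
         stderr_slope = se, p_value = p,
         stderr_block = se_b, p_block = p_b,
         pearson_r = r, n = n)
}

#' Build the significance-filtered shift/bond sensitivity matrix
#'
#' The central object of the analysis: the matrix M of slopes (ppm/Angstrom)
#' relating instantaneous 13C shifts (rows, atoms) to instantaneous C-C
#' bond lengths (columns, bonds), with entries whose block-corrected
#' p-value fails the multiplicity-adjusted significance test set to exactly
#' zero. The surviving entries typically form an alternating-sign double
#' diagonal mirroring the conjugated system.
#'
#' Two estimators are available. The default, `method = "joint"`, fits one
#' multivariate OLS per atom (shift on all bond lengths together), so each
#' entry is the partial slope holding the other bonds fixed — the matrix in
#' the linear relation shift-change = M x bond-change, and the estimator
#' that recovers an exactly linear map without omitted-variable bias.
#' `method = "pairwise"` uses one simple regression per (atom, bond) pair
#' ([pairwise_regression()]); its slopes are marginal and coincide with the
#' joint ones only when bond fluctuations are uncorrelated. Per-pair
#' Pearson correlations are always the marginal ones.
#'
#' @param shifts Wide shift series (`time_fs` + atom columns, ppm).
#' @param bonds Wide bond series (`time_fs` + bond columns, Angstrom),
#'   row-aligned with `shifts` (see [align_series()]).
#' @param alpha Significance level for the mask; `0` blanks the matrix.
#' @param correction Multiplicity correction across all (atom, bond) pairs:
#'   Benjamini-Hochberg (default), Bonferroni, or none.
#' @param block_size Frames per block for the autocorrelation-robust
#'   batch-means standard error.
#' @param method Slope estimator, `"joint"` (partial slopes, default) or
#'   `"pairwise"` (marginal slopes).
#' @param atoms,bond_labels Optional subsets of the series columns.
#'
#' @return A `sensitivity_matrix` object: masked `slopes` and raw
#'   `slopes_raw` matrices (atoms x bonds, ppm/A), Pearson `r` matrix,
#'   logical `mask`, the per-pair regression table `pairs`, and the
#'   filtering settings.
#' @seealso [sign_pattern()], [asymmetry_report()], [pseudoinverse_predict()]
#' @export
build_sensitivity_matrix <- function(shifts, bonds, alpha = 0.05,
                                     correction = c("bh", "bonferroni", "none"),
                                     block_size = 10,
                                     method = c("joint", "pairwise"),
                                     atoms = NULL, bond_labels = NULL) {
  correction <- match.arg(correction)
  method <- match.arg(method)
  shifts <- as_tibble(shifts); bonds <- as_tibble(bonds)
  if (nrow(shifts) != nrow(bonds))
    abort(paste0("misaligned series: ", nrow(shifts), " shift frames vs ",
                 nrow(bonds), " bond frames"))
  atoms <- atoms %||% series_labels(shifts)
  bond_labels <- bond_labels %||% series_labels(bonds)
  stopifnot(all(atoms %in% names(shifts)), all(bond_labels %in% names(bonds)))

  pairs <- tidyr::expand_grid(atom = atoms, bond = bond_labels)
  if (method == "pairwise") {
    pairs <- dplyr::bind_cols(pairs, purrr::map2_dfr(
      pairs$atom, pairs$bond,
      function(a, b) pairwise_regression(shifts[[a]], bonds[[b]],
                                         block_size = block_size)))
  } else {
    X <- as.matrix(bonds[bond_labels])
    pairs <- dplyr::bind_cols(pairs, purrr::map_dfr(
      atoms, function(a) joint_regression(shifts[[a]], X, block_size)))
    pairs$pearson_r <- purrr::map2_dbl(pairs$atom, pairs$bond, function(a, b) {
      if (stats::var(shifts[[a]]) == 0) 0 else stats::cor(bonds[[b]], shifts[[a]])
    })
  }
  adj <- c(bh = "BH", bonferroni = "bonferroni", none = "none")[[correction]]
  pairs$p_adj <- stats::p.adjust(pairs$p_block, method = adj)
  pairs$significant <- alpha > 0 & pairs$p_adj <= alpha

  shape <- function(v) matrix(v, nrow = length(atoms), byrow = TRUE,
                              dimnames = list(atoms, bond_labels))
  slopes_raw <- shape(pairs$slope_ppm_per_A)
  mask <- shape(pairs$significant)
  slopes <- slopes_raw
  slopes[!mask] <- 0

  structure(list(slopes = slopes, slopes_raw = slopes_raw,
                 r = shape(pairs$pearson_r),
                 stderr_block = shape(pairs$stderr_block),
                 mask = mask, pairs = pairs,
                 alpha = alpha, correction = correction,
                 block_size = block_size, method = method,
                 n_frames = nrow(shifts)),
            class = "sensitivity_matrix")
}

# per-atom multivariate OLS of shift on all bond lengths; one row per bond
joint_regression <- function(y, X, block_size) {
  n <- nrow(X); nb <- ncol(X)
  if (n < nb + 3) abort("need at least n_bonds + 3 frames for joint slopes")
  if (any(apply(X, 2, stats::var) == 0))
    abort(paste0("bond length series has zero variance: ",
                 colnames(X)[which(apply(X, 2, stats::var) == 0)[1]]))
  if (stats::var(y) == 0) {
    return(tibble(slope_ppm_per_A = rep(0, nb), intercept_ppm = mean(y),
                  stderr_slope = 0, p_value = 1,
                  stderr_block = 0, p_block = 1, n = n))
  }
  W <- cbind(`(Intercept)` = 1, X)
  WtW <- crossprod(W)
  beta <- solve(WtW, crossprod(W, y))
  e <- drop(y - W %*% beta)
  s2 <- sum(e^2) / (n - nb - 1)
  Vinv <- solve(WtW)
  se <- sqrt(pmax(s2 * diag(Vinv)[-1], 0))
  slope <- beta[-1]
  tstat <- ifelse(se > 0, slope / se, sign(slope) * Inf)
  p <- 2 * stats::pt(abs(tstat), df = n - nb - 1, lower.tail = FALSE)

  # batch-means SE from the coefficient influence values; residuals
  # rescaled for the fitted degrees of freedom (HC1-style)
  e_adj <- e * sqrt(n / (n - nb - 1))
  Psi <- n * (W %*% t(Vinv))[, -1, drop = FALSE] * e_adj   # n x nb
  n_blocks <- n %/% block_size
  if (n_blocks >= 2) {
    grp <- rep(seq_len(n_blocks), each = block_size)
    bm <- apply(Psi[seq_len(n_blocks * block_size), , drop = FALSE], 2,
                function(v) tapply(v, grp, mean))
    se_b <- apply(bm, 2, stats::sd) / sqrt(n_blocks)
    tb <- ifelse(se_b > 0, slope / se_b, sign(slope) * Inf)
    p_b <- 2 * stats::pt(abs(tb), df = n_blocks - 1, lower.tail = FALSE)
    p_b[slope == 0] <- 1
  } else {
    se_b <- se; p_b <- p
  }
  p[slope == 0 & se == 0] <- 1
  tibble(slope_ppm_per_A = unname(slope), intercept_ppm = beta[1],
         stderr_slope = unname(se), p_value = unname(p),
         stderr_block = unname(se_b), p_block = unname(p_b), n = n)
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("<sensitivity_matrix> %d atoms x %d bonds, %d/%d significant (alpha %.3g, %s)\n",
              nrow(x$slopes), ncol(x$slopes), sum(x$mask), length(x$mask),
              x$alpha, x$correction))
  print(round(x$slopes, 2))
  invisible(x)
}

#' @rdname build_sensitivity_matrix
#' @param x A `sensitivity_matrix`.
#' @param ... Unused.
#' @method tidy sensitivity_matrix
#' @export
tidy.sensitivity_matrix <- function(x, ...) x$pairs

#' @rdname build_sensitivity_matrix
#' @method glance sensitivity_matrix
#' @export
glance.sensitivity_matrix <- function(x, ...) {
  tibble(n_atoms = nrow(x$slopes), n_bonds = ncol(x$slopes),
         n_significant = sum(x$mask), alpha = x$alpha,
         correction = x$correction, n_frames = x$n_frames)
}

#' Sign pattern of a sensitivity matrix
#'
#' Labels every (atom, bond) entry `positive`, `negative` or `none`
#' (not significant) — the red/blue bullet representation of the
#' alternating-sign band.
#'
#' @param m A `sensitivity_matrix`.
#' @return Long tibble with columns `atom`, `bond`, `sign`.
#' @export
sign_pattern <- function(m) {
  stopifnot(inherits(m, "sensitivity_matrix"))
  dplyr::mutate(m$pairs[c("atom", "bond")],
                sign = dplyr::case_when(
                  m$pairs$significant & m$pairs$slope_ppm_per_A > 0 ~ "positive",
                  m$pairs$significant & m$pairs$slope_ppm_per_A < 0 ~ "negative",
                  TRUE ~ "none"))
}

#' Preferred bond per atom from a sensitivity matrix
#'
#' The symmetry of the geometric sensitivity is typically disturbed: some
#' nuclei correlate far more strongly with one bond than any other (their
#' "preferred" bond), and some are independent of the whole bond set.
#'
#' @param m A `sensitivity_matrix`.
#' @return Tibble with one row per atom: `preferred_bond` (bond with the
#'   largest absolute significant slope, `NA` if none), `max_abs_slope`,
#'   `ratio` of largest to second-largest absolute significant slope
#'   (`Inf` when only one entry is significant), and `independent`
#'   (no significant entry at all).
#' @export
asymmetry_report <- function(m) {
  stopifnot(inherits(m, "sensitivity_matrix"))
  purrr::map_dfr(rownames(m$slopes), function(a) {
    row <- m$slopes[a, ]
    sig <- row[m$mask[a, ]]
    if (!length(sig))
      return(tibble(atom = a, preferred_bond = NA_character_,
                    max_abs_slope = NA_real_, ratio = NA_real_,
                    independent = TRUE))
    ord <- order(abs(sig), decreasing = TRUE)
    ratio <- if (length(sig) >= 2) abs(sig[ord[1]]) / abs(sig[ord[2]]) else Inf
    tibble(atom = a, preferred_bond = names(sig)[ord[1]],
           max_abs_slope = abs(sig[ord[1]]), ratio = ratio,
           independent = FALSE)
  })
}

#' Write a sensitivity matrix to CSV / JSON
#'
#' `write_sensitivity_matrix()` writes the atoms x bonds slope grid as CSV
#' and, alongside it (same stem, `.json`), the mask and filter metadata.
#'
#' @param m A `sensitivity_matrix`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_matrix <- function(m, path) {
  stopifnot(inherits(m, "sensitivity_matrix"))
  grid <- as_tibble(m$slopes, rownames = "atom")
  readr::write_csv(grid, path)
  meta <- list(alpha = m$alpha, correction = m$correction,
               block_size = m$block_size, n_frames = m$n_frames,
               mask = as_tibble(m$mask, rownames = "atom"))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Heatmap of a sensitivity matrix
#'
#' Tile plot of the masked slopes with significant entries marked by
#' sign-coloured bullets, the usual rendering of the shift/bond correlation
#' band.
#'
#' @param object A `sensitivity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sensitivity_matrix
#' @export
autoplot.sensitivity_matrix <- function(object, ...) {
  df <- tidy(object)
  df$sign <- sign_pattern(object)$sign
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bond, y = .data$atom)) +
    ggplot2::geom_tile(ggplot2::aes(
      fill = ifelse(.data$significant, .data$slope_ppm_per_A, 0)),
      colour = "grey80") +
    ggplot2::geom_point(data = df[df$sign != "none", ],
                        ggplot2::aes(colour = .data$sign), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "slope (ppm/Å)") +
    ggplot2::scale_colour_manual(values = c(positive = "#b2182b",
                                            negative = "#2166ac")) +
    ggplot2::labs(x = "C-C bond", y = "carbon atom") +
    ggplot2::theme_minimal()
}
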