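#' Principal component analysis of shift fluctuations
#'
#' Centred, unscaled PCA of the per-frame isotropic shifts of the selected
#' atoms. No dimensionality reduction is performed: the number of components
#' equals the number of atoms, so the PCA is a pure rotation that weights
#' directions by their fluctuation variance before the multivariate
#' regression of [fit_inverse_model()].
#'
#' @param shifts Wide shift series (`time_fs` + atom columns, ppm).
#' @param atoms Atom labels to use as features (default: all shift columns;
#'   for phycocyanobilin ring C/D work the conventional set is C13-C18).
#'
#' @return A `shift_pca` object: `feature_labels`, `feature_means` (ppm),
#'   `loadings` (components x features, orthonormal rows), and
#'   `explained_variance` per component (ppm^2, decreasing).
#' @export
fit_shift_pca <- function(shifts, atoms = NULL) {
  shifts <- as_tibble(shifts)
  atoms <- atoms %||% series_labels(shifts)
  stopifnot(all(atoms %in% names(shifts)))
  X <- as.matrix(shifts[atoms])
  if (nrow(X) <= length(atoms))
    abort("need more frames than features for a full-rank PCA")
  v <- apply(X, 2, stats::var)
  if (any(v == 0))
    abort(paste0("constant shift column: ", atoms[which(v == 0)[1]]))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < length(atoms) || min(pc$sdev) <= 0)
    abort("rank-deficient shift data: PCA did not return a full rotation")
  structure(list(feature_labels = atoms,
                 feature_means = pc$center,
                 loadings = t(pc$rotation),      # components x features
                 explained_variance = pc$sdev^2,
                 n_components = length(atoms)),
            class = "shift_pca")
}

#' @export
print.shift_pca <- function(x, ...) {
  cat(sprintf("<shift_pca> %d components over %s\n", x$n_components,
              paste(x$feature_labels, collapse = " ")))
  cat("explained variance (ppm^2):",
      paste(signif(x$explained_variance, 4), collapse = " "), "\n")
  invisible(x)
}

#' @rdname fit_shift_pca
#' @param x A `shift_pca`.
#' @param ... Unused.
#' @method tidy shift_pca
#' @export
tidy.shift_pca <- function(x, ...) {
  as_tibble(x$loadings, rownames = NULL) |>
    mutate(component = seq_len(nrow(x$loadings)),
           explained_variance = x$explained_variance) |>
    tidyr::pivot_longer(all_of(x$feature_labels),
                        names_to = "atom", values_to = "loading") |>
    select("component", "atom", "loading", "explained_variance")
}

# scores of a shift table in an existing PCA basis (centred with fit means)
pca_scores <- function(pca, shifts) {
  X <- as.matrix(as_tibble(shifts)[pca$feature_labels])
  sweep(X, 2, pca$feature_means) %*% t(pca$loadings)
}

identity_pca <- function(shifts, atoms) {
  X <- as.matrix(as_tibble(shifts)[atoms])
  structure(list(feature_labels = atoms,
                 feature_means = colMeans(X),
                 loadings = diag(length(atoms)),
                 explained_variance = apply(X, 2, stats::var),
                 n_components = length(atoms)),
            class = "shift_pca")
}

#' Fit the inverse structure-property model
#'
#' Regresses each bond length on the full set of shift principal-component
#' scores (ordinary least squares, one regression per bond). Because the
#' PCA is a rotation, the fitted values are identical to a direct regression
#' on the centred shifts; the component basis is kept because it exposes the
#' fluctuation structure of the features. The model maps a shift-change
#' vector to a bond-length-change vector via [predict_bond_deltas()].
#'
#' @param pca A [fit_shift_pca()] object, or `NULL` to regress directly on
#'   centred shifts (identity rotation) — the two give identical
#'   predictions.
#' @param shifts Wide shift series aligned with `bonds` (same frames).
#' @param bonds Wide bond series (`time_fs` + bond columns, Angstrom).
#' @param bond_labels Bonds to model (default: all bond columns).
#'
#' @return An `inverse_model`: `coefficients` (bonds x components, Angstrom
#'   per score unit), `intercepts` (Angstrom), per-bond residual standard
#'   deviation `sigma`, and the training scores/lengths needed for
#'   bootstrap refits.
#' @export
fit_inverse_model <- function(pca, shifts, bonds, bond_labels = NULL) {
  shifts <- as_tibble(shifts); bonds <- as_tibble(bonds)
  if (nrow(shifts) != nrow(bonds))
    abort("shift and bond series must be frame-aligned")
  if (is.null(pca))
    pca <- identity_pca(shifts, series_labels(shifts))
  stopifnot(inherits(pca, "shift_pca"))
  bond_labels <- bond_labels %||% series_labels(bonds)
  k <- pca$n_components
  n <- nrow(shifts)
  if (n <= k + 1)
    abort("need n_frames > n_components + 1 to fit the inverse model")

  Z <- pca_scores(pca, shifts)                  # n x k
  D <- as.matrix(bonds[bond_labels])            # n x bonds
  W <- cbind(1, Z)
  WtW <- crossprod(W)
  if (rcond_safe(WtW) < 1e-12)
    abort("collinear component scores: design matrix is singular")
  WtW_inv <- solve(WtW)
  B <- WtW_inv %*% crossprod(W, D)              # (k+1) x bonds
  fitted <- W %*% B
  resid <- D - fitted
  sigma <- sqrt(colSums(resid^2) / (n - k - 1))

  structure(list(pca = pca,
                 bond_labels = bond_labels,
                 coefficients = t(B[-1, , drop = FALSE]),  # bonds x components
                 intercepts = setNames(B[1, ], bond_labels),
                 sigma = setNames(sigma, bond_labels),
                 WtW_inv = WtW_inv,
                 scores = Z, lengths = D,
                 n_frames = n),
            class = "inverse_model")
}

rcond_safe <- function(m) tryCatch(1 / kappa(m, exact = FALSE), error = function(e) 0)

#' @export
print.inverse_model <- function(x, ...) {
  cat(sprintf("<inverse_model> %d bonds on %d shift components, %d frames\n",
              length(x$bond_labels), x$pca$n_components, x$n_frames))
  cat("residual sd (A):", paste(signif(x$sigma, 3), collapse = " "), "\n")
  invisible(x)
}

#' @rdname fit_inverse_model
#' @param x An `inverse_model`.
#' @param ... Unused.
#' @method tidy inverse_model
#' @export
tidy.inverse_model <- function(x, ...) {
  as_tibble(x$coefficients, rownames = "bond") |>
    tidyr::pivot_longer(-"bond", names_to = "component",
                        values_to = "coefficient_A")
}

#' @rdname fit_inverse_model
#' @method glance inverse_model
#' @export
glance.inverse_model <- function(x, ...) {
  ss_tot <- colSums(scale(x$lengths, scale = FALSE)^2)
  ss_res <- (x$n_frames - x$pca$n_components - 1) * x$sigma^2
  tibble(n_frames = x$n_frames, n_components = x$pca$n_components,
         n_bonds = length(x$bond_labels),
         r_squared_min = min(1 - ss_res / ss_tot),
         r_squared_max = max(1 - ss_res / ss_tot))
}

#' Construct / read an experimental shift-change vector
#'
#' The experimental input to the inversion: per-atom changes in the 13C
#' chemical shift between two photostates (e.g. dark state to photoproduct).
#'
#' @param transition Transition name, e.g. `"Pr->Pg"`.
#' @param atoms Character vector of atom labels.
#' @param delta_ppm Numeric shift changes (ppm), same length as `atoms`.
#' @param source Optional provenance note.
#' @return A tibble with columns `transition`, `atom`, `delta_ppm`, `source`.
#' @export
shift_delta <- function(transition, atoms, delta_ppm, source = NA_character_) {
  stopifnot(length(atoms) == length(delta_ppm))
  if (anyDuplicated(atoms)) abort("duplicate atom labels in shift delta")
  if (any(!is.finite(delta_ppm))) abort("shift delta values must be finite")
  tibble(transition = transition, atom = as.character(atoms),
         delta_ppm = as.numeric(delta_ppm), source = source)
}

#' @rdname shift_delta
#' @param path CSV (columns `transition`, `atom`, `delta_ppm`) or JSON file.
#' @export
read_shift_delta <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    return(shift_delta(x$transition, names(x$delta_ppm),
                       unlist(x$delta_ppm), x$source %||% NA_character_))
  }
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("transition", "atom", "delta_ppm") %in% names(x)))
  shift_delta(x$transition[1], x$atom, x$delta_ppm,
              if ("source" %in% names(x)) x$source[1] else NA_character_)
}

delta_vector <- function(delta, atoms) {
  delta <- as_tibble(delta)
  missing <- setdiff(atoms, delta$atom)
  if (length(missing))
    abort(paste0("shift delta missing atoms: ", paste(missing, collapse = ", ")))
  setNames(delta$delta_ppm[match(atoms, delta$atom)], atoms)
}

new_prediction <- function(transition, bonds, delta_pm, uncertainty_pm, method) {
  structure(tibble(transition = transition, bond = bonds,
                   delta_pm = unname(delta_pm),
                   uncertainty_pm = unname(uncertainty_pm),
                   method = method),
            class = c("bond_delta_prediction", "tbl_df", "tbl", "data.frame"))
}

#' Predict bond-length changes from a shift-change vector
#'
#' Projects the shift-change vector onto the component basis (no mean
#' subtraction — it is already a difference), maps it through the fitted
#' regression coefficients and converts Angstrom to picometre. Uncertainty
#' is, by default, the standard deviation of the prediction over seeded
#' block-bootstrap refits of the regression (contiguous frame blocks,
#' sampled with replacement); with `n_boot = 0` the analytic OLS prediction
#' standard error is reported instead.
#'
#' @param model An [fit_inverse_model()] object.
#' @param delta A [shift_delta()] covering all model features.
#' @param n_boot Number of bootstrap refits (0 for analytic standard error).
#' @param seed Integer seed for the bootstrap.
#' @param block_size Frames per bootstrap block.
#'
#' @return A `bond_delta_prediction` tibble: `transition`, `bond`,
#'   `delta_pm`, `uncertainty_pm`, `method = "pc_regression"`.
#' @export
predict_bond_deltas <- function(model, delta, n_boot = 200, seed = 1,
                                block_size = 10) {
  stopifnot(inherits(model, "inverse_model"))
  dv <- delta_vector(delta, model$pca$feature_labels)
  z <- drop(model$pca$loadings %*% dv)          # component-space delta
  pred_A <- drop(model$coefficients %*% z)
  delta_pm <- 100 * pred_A

  if (n_boot > 0) {
    n <- model$n_frames
    n_blocks_avail <- max(1L, n %/% block_size)
    starts <- (seq_len(n_blocks_avail) - 1L) * block_size + 1L
    need <- ceiling(n / block_size)
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- unlist(lapply(sample(starts, need, replace = TRUE),
                             function(s) s:min(s + block_size - 1L, n)))
        idx <- idx[seq_len(min(length(idx), n))]
        Zb <- model$scores[idx, , drop = FALSE]
        Db <- model$lengths[idx, , drop = FALSE]
        Wb <- cbind(1, Zb)
        Bb <- tryCatch(solve(crossprod(Wb), crossprod(Wb, Db)),
                       error = function(e) matrix(NA_real_, ncol(Wb), ncol(Db)))
        drop(t(Bb[-1, , drop = FALSE]) %*% z)
      }, numeric(length(model$bond_labels)))
    })
    unc_pm <- 100 * apply(matrix(boots, nrow = length(model$bond_labels)),
                          1, stats::sd, na.rm = TRUE)
  } else {
    # analytic: var(c_b' z) = sigma_b^2 * z' (W'W)^{-1}[scores] z
    V <- model$WtW_inv[-1, -1, drop = FALSE]
    q <- drop(t(z) %*% V %*% z)
    unc_pm <- 100 * model$sigma * sqrt(q)
  }
  new_prediction(delta$transition[1], model$bond_labels, delta_pm, unc_pm,
                 "pc_regression")
}

#' Minimum-norm pseudoinverse prediction
#'
#' The cross-check route: applies the Moore-Penrose pseudoinverse of the
#' significance-masked sensitivity matrix directly to the shift-change
#' vector, returning the minimum-norm least-squares bond-change pattern.
#' With a square, full-rank matrix this solves the linear system exactly
#' and agrees with [predict_bond_deltas()] on noiseless data; with more
#' bonds than shift features only the minimum-norm solution is identified.
#'
#' Uncertainty is estimated by seeded parametric resampling of the
#' significant matrix entries from their block standard errors
#' (`n_draws = 0` reports `NA`).
#'
#' @param m A [build_sensitivity_matrix()] object with at least one
#'   significant entry.
#' @param delta A [shift_delta()] covering the matrix's atoms.
#' @param n_draws Resampling draws for the uncertainty.
#' @param seed Integer seed.
#' @return A `bond_delta_prediction` tibble with `method = "pseudoinverse"`.
#' @export
pseudoinverse_predict <- function(m, delta, n_draws = 200, seed = 1) {
  stopifnot(inherits(m, "sensitivity_matrix"))
  if (!any(m$mask)) abort("sensitivity matrix has no significant entries")
  dv <- delta_vector(delta, rownames(m$slopes))
  pinv <- MASS::ginv(m$slopes)
  delta_pm <- 100 * drop(pinv %*% dv)

  unc_pm <- rep(NA_real_, ncol(m$slopes))
  if (n_draws > 0) {
    draws <- withr::with_seed(seed, {
      vapply(seq_len(n_draws), function(i) {
        Mi <- m$slopes
        Mi[m$mask] <- stats::rnorm(sum(m$mask), m$slopes[m$mask],
                                   m$stderr_block[m$mask])
        100 * drop(MASS::ginv(Mi) %*% dv)
      }, numeric(ncol(m$slopes)))
    })
    unc_pm <- apply(matrix(draws, nrow = ncol(m$slopes)), 1, stats::sd)
  }
  new_prediction(delta$transition[1], colnames(m$slopes), delta_pm, unc_pm,
                 "pseudoinverse")
}

#' @export
print.bond_delta_prediction <- function(x, ...) {
  cat(sprintf("<bond_delta_prediction> %s (%s)\n",
              x$transition[1], x$method[1]))
  NextMethod()
}

#' Bar chart of predicted bond-length changes
#'
#' @param object A `bond_delta_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bond_delta_prediction
#' @export
autoplot.bond_delta_prediction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bond, y = .data$delta_pm)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$delta_pm > 0),
                      show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$delta_pm - .data$uncertainty_pm,
                                        ymax = .data$delta_pm + .data$uncertainty_pm),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "#2166ac")) +
    ggplot2::labs(x = "C-C bond", y = expression(Delta * d ~ "(pm)"),
                  title = object$transition[1]) +
    ggplot2::theme_minimal()
}
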