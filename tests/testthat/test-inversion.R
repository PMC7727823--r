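test_that("PCA of collinear two-feature data recovers the known geometry", {
  set.seed(11)
  x <- rnorm(100)
  shifts <- tibble::tibble(time_fs = seq_along(x) * 200,
                           C13 = 10 + x, C14 = 5 + x + rnorm(100, sd = 1e-6))
  pca <- fit_shift_pca(shifts)
  expect_equal(abs(pca$loadings[1, ]), c(C13 = 1, C14 = 1) / sqrt(2),
               tolerance = 1e-3)
  expect_lt(pca$explained_variance[2] / pca$explained_variance[1], 1e-6)
})

test_that("explained variances sum to total variance; loadings orthonormal", {
  spec <- square_spec(seed = 12, sigma_shift_ppm = 0.5)
  tr <- simulate_trajectory(spec, 200)
  pca <- fit_shift_pca(tr$shifts)
  X <- as.matrix(tr$shifts[spec$atoms])
  expect_equal(sum(pca$explained_variance), sum(apply(X, 2, var)))
  expect_equal(pca$loadings %*% t(pca$loadings), diag(6),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("loadings match an independent covariance eigendecomposition", {
  spec <- square_spec(seed = 13, sigma_shift_ppm = 0.5)
  tr <- simulate_trajectory(spec, 300)
  pca <- fit_shift_pca(tr$shifts)
  X <- as.matrix(tr$shifts[spec$atoms])
  eig <- eigen(cov(X), symmetric = TRUE)
  expect_equal(pca$explained_variance, eig$values, tolerance = 1e-10)
  for (k in 1:6) {
    v <- eig$vectors[, k]
    w <- pca$loadings[k, ]
    expect_equal(abs(sum(v * w)), 1, tolerance = 1e-8)  # equal up to sign
  }
})

test_that("constant shift columns are refused by name", {
  shifts <- tibble::tibble(time_fs = 1:10 * 200., C13 = rnorm(10), C14 = 7)
  expect_error(fit_shift_pca(shifts), "C14")
})

test_that("noiseless linear data give exact in-sample reconstruction", {
  spec <- square_spec(seed = 14)
  tr <- simulate_trajectory(spec, 500)
  model <- fit_inverse_model(fit_shift_pca(tr$shifts), tr$shifts, tr$bonds)
  Z <- cbind(1, model$scores)
  fitted <- Z %*% rbind(model$intercepts, t(model$coefficients))
  expect_equal(fitted, as.matrix(tr$bonds[spec$bonds]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(model$sigma < 1e-10))
})

test_that("the model is invariant to frame order", {
  spec <- square_spec(seed = 15, sigma_shift_ppm = 0.5)
  tr <- simulate_trajectory(spec, 200)
  perm <- withr::with_seed(1, sample(200))
  m1 <- fit_inverse_model(fit_shift_pca(tr$shifts), tr$shifts, tr$bonds)
  m2 <- fit_inverse_model(fit_shift_pca(tr$shifts[perm, ]),
                          tr$shifts[perm, ], tr$bonds[perm, ])
  d1 <- predict_bond_deltas(m1, shift_delta("t", spec$atoms, rep(1, 6)),
                            n_boot = 0)
  d2 <- predict_bond_deltas(m2, shift_delta("t", spec$atoms, rep(1, 6)),
                            n_boot = 0)
  expect_equal(d1$delta_pm, d2$delta_pm, tolerance = 1e-8)
})

test_that("prediction is linear: zero in, zero out; doubling doubles", {
  spec <- square_spec(seed = 16, sigma_shift_ppm = 0.5)
  tr <- simulate_trajectory(spec, 300)
  model <- fit_inverse_model(fit_shift_pca(tr$shifts), tr$shifts, tr$bonds)
  z <- predict_bond_deltas(model, shift_delta("t", spec$atoms, rep(0, 6)),
                           n_boot = 0)
  expect_equal(z$delta_pm, rep(0, 6))
  dl <- shift_delta("t", spec$atoms, c(1, -2, 0.5, 3, -1, 2))
  dl2 <- shift_delta("t", spec$atoms, 2 * c(1, -2, 0.5, 3, -1, 2))
  p1 <- predict_bond_deltas(model, dl, n_boot = 0)
  p2 <- predict_bond_deltas(model, dl2, n_boot = 0)
  expect_equal(p2$delta_pm, 2 * p1$delta_pm, tolerance = 1e-8)
  expect_error(
    predict_bond_deltas(model, shift_delta("t", spec$atoms[-1], rep(1, 5))),
    "missing atoms")
})

test_that("PCA is a pure rotation: identical predictions without it", {
  spec <- square_spec(seed = 17, sigma_shift_ppm = 0.5)
  pair <- simulate_state_pair(spec, truth_dd(spec), 400, noise_ppm = 0.5)
  tr <- pair$trajectory
  with_pca <- fit_inverse_model(fit_shift_pca(tr$shifts), tr$shifts, tr$bonds)
  without <- fit_inverse_model(NULL, tr$shifts, tr$bonds)
  p1 <- predict_bond_deltas(with_pca, pair$observed_delta, n_boot = 0)
  p2 <- predict_bond_deltas(without, pair$observed_delta, n_boot = 0)
  expect_equal(p1$delta_pm, p2$delta_pm, tolerance = 1e-8)
})

test_that("pseudoinverse predict handles identity and square systems", {
  # identity map in ppm/A: a 1 ppm change inverts to 1 A = 100 pm
  spec <- synthetic_spec(M_true = diag(1, 6), sigma_shift_ppm = 0.2, seed = 18)
  tr <- simulate_trajectory(spec, 500)
  m <- build_sensitivity_matrix(tr$shifts, tr$bonds, alpha = 0.05,
                                correction = "bonferroni")
  # substitute the exact identity map/mask for the unit-conversion check
  dl <- shift_delta("t", spec$atoms, rep(1, 6))
  m$slopes <- diag(1, 6); dimnames(m$slopes) <- dimnames(spec$M_true)
  m$mask <- diag(6) == 1; dimnames(m$mask) <- dimnames(spec$M_true)
  p <- pseudoinverse_predict(m, dl, n_draws = 0)
  expect_equal(p$delta_pm, rep(100, 6))

  # square invertible map: pinv solves the system exactly
  spec2 <- square_spec(seed = 19)
  pair <- simulate_state_pair(spec2, truth_dd(spec2), 500)
  tr2 <- pair$trajectory
  m2 <- build_sensitivity_matrix(tr2$shifts, tr2$bonds)
  p2 <- pseudoinverse_predict(m2, pair$observed_delta, n_draws = 0)
  expect_equal(p2$delta_pm, unname(pair$delta_d_true_pm), tolerance = 1e-6)
  expect_equal(drop(m2$slopes %*% (p2$delta_pm / 100)),
               with(pair$observed_delta, setNames(delta_ppm, atom)),
               tolerance = 1e-6)
})

test_that("both inversion routes agree on noiseless square fixtures", {
  for (seed in c(23, 24, 25)) {
    spec <- square_spec(seed = seed)
    pair <- simulate_state_pair(spec, truth_dd(spec), 400)
    tr <- pair$trajectory
    model <- fit_inverse_model(fit_shift_pca(tr$shifts), tr$shifts, tr$bonds)
    m <- build_sensitivity_matrix(tr$shifts, tr$bonds)
    p1 <- predict_bond_deltas(model, pair$observed_delta, n_boot = 0)
    p2 <- pseudoinverse_predict(m, pair$observed_delta, n_draws = 0)
    expect_lt(max(abs(p1$delta_pm - p2$delta_pm)), 0.1)
  }
})

test_that("recovery error is monotone in shift noise", {
  mean_err <- function(sigma) {
    errs <- vapply(1:20, function(s) {
      spec <- square_spec(seed = 400 + s, sigma_shift_ppm = sigma)
      pair <- simulate_state_pair(spec, truth_dd(spec), 300,
                                  noise_ppm = sigma)
      tr <- pair$trajectory
      model <- fit_inverse_model(fit_shift_pca(tr$shifts),
                                 tr$shifts, tr$bonds)
      p <- predict_bond_deltas(model, pair$observed_delta, n_boot = 0)
      mean(abs(p$delta_pm - pair$delta_d_true_pm))
    }, numeric(1))
    mean(errs)
  }
  e <- vapply(c(0.1, 0.5, 2.0), mean_err, numeric(1))
  expect_true(all(diff(e) >= 0))
})

test_that("bootstrap uncertainty shrinks with trajectory length", {
  unc <- function(n) {
    spec <- square_spec(seed = 26, sigma_shift_ppm = 0.5)
    pair <- simulate_state_pair(spec, truth_dd(spec), n)
    tr <- pair$trajectory
    model <- fit_inverse_model(fit_shift_pca(tr$shifts), tr$shifts, tr$bonds)
    mean(predict_bond_deltas(model, pair$observed_delta,
                             n_boot = 60, seed = 5)$uncertainty_pm)
  }
  expect_gt(unc(1000), unc(4000))
})

test_that("shift delta files round-trip through CSV and JSON", {
  dl <- shift_delta("Pr->Pg", paste0("C", 13:18),
                    c(2.1, -3.2, 9.8, 0.4, -1.1, 5.6), source = "test")
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dl, csv)
  expect_equal(read_shift_delta(csv)$delta_ppm, dl$delta_ppm)
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(transition = "Pr->Pg",
                            delta_ppm = as.list(setNames(dl$delta_ppm, dl$atom))),
                       js, auto_unbox = TRUE)
  back <- read_shift_delta(js)
  expect_equal(back$delta_ppm, dl$delta_ppm)
  expect_equal(back$atom, dl$atom)
})
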