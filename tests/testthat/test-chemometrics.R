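test_that("PLSR solves the exact single-predictor case at one factor", {
  set.seed(1)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x1"))
  y <- drop(2 * x)
  m <- fit_plsr(x, 1, y = y)
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-8)
  expect_equal(sum(m$explained_y_variance_per_factor), 100,
               tolerance = 1e-8)
  expect_equal(predict(m, x), y, tolerance = 1e-8)
})

test_that("NIPALS factor scores are mutually orthogonal", {
  p <- random_problem(2, n = 30, P = 8)
  m <- fit_plsr(p$X, 5, y = p$y)
  G <- crossprod(m$scores)
  offdiag <- G[upper.tri(G)]
  expect_lt(max(abs(offdiag)), 1e-8 * max(diag(G)))
})

test_that("full-rank PLSR at maximal factors reproduces OLS", {
  p <- random_problem(3, n = 25, P = 4)
  m <- fit_plsr(p$X, 4, y = p$y)
  ols <- lm(p$y ~ p$X)
  expect_equal(unname(m$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-6)
  expect_equal(m$intercept, unname(coef(ols)[1]), tolerance = 1e-6)
  expect_equal(predict(m, p$X), unname(fitted(ols)), tolerance = 1e-6)
})

test_that("prediction respects centering and feature labels, not column order", {
  p <- random_problem(4, n = 20, P = 5)
  m <- fit_plsr(p$X, 3, y = p$y)
  expect_equal(unname(predict(m, matrix(m$x_mean, 1,
                                        dimnames = list(NULL, names(m$coefficients))))),
               m$y_mean, tolerance = 1e-10)
  perm <- sample(ncol(p$X))
  expect_equal(predict(m, p$X[, perm]), predict(m, p$X), tolerance = 1e-12)
  expect_error(predict(m, p$X[, 1:3]), "lacks model features")
})

test_that("LOOCV holds each plant out once and rewards the exact model", {
  set.seed(5)
  x <- matrix(rnorm(15), 15, 1, dimnames = list(NULL, "x1"))
  y <- drop(3 * x) + 1
  cv <- loocv_plsr(x, 1, y = y)
  expect_equal(cv$r2_val, 1, tolerance = 1e-8)
  expect_equal(cv$optimal_factors, 1)
  expect_equal(nrow(cv$loocv_predictions), 15)
  expect_true(all(is.finite(cv$loocv_predictions)))

  p <- random_problem(6, n = 18, P = 4)
  cv1 <- loocv_plsr(p$X, 3, y = p$y)
  perm <- sample(18)
  cv2 <- loocv_plsr(p$X[perm, ], 3, y = p$y[perm])
  expect_equal(cv1$r2_val, cv2$r2_val, tolerance = 1e-10)
  expect_equal(cv1$loocv_predictions[perm, ], cv2$loocv_predictions,
               tolerance = 1e-10)
  expect_warning(loocv_plsr(p$X, 10, y = p$y), "capped")
})

test_that("explained-variance curves are monotone and reach 100% at rank", {
  set.seed(7)
  X <- matrix(rnorm(30 * 7), 30, 7)
  y <- drop(X %*% rnorm(7))     # exact linear: rank-7 model is perfect
  ev <- explained_variance_curves(X, 7, y = y)
  expect_true(all(diff(ev$explained_cal) >= -1e-8))
  expect_equal(ev$explained_cal[7], 100, tolerance = 1e-6)
})

test_that("an overfit-prone calibration shows a wider train/validation gap", {
  set.seed(8)
  X <- matrix(rnorm(12 * 30), 12, 30)
  y <- drop(X[, 1] * 2) + rnorm(12)
  ev <- explained_variance_curves(X, 8, y = y)
  gap <- ev$explained_cal - ev$explained_val
  cv <- loocv_plsr(X, 8, y = y)
  expect_gt(gap[8], gap[cv$optimal_factors])
})

test_that("VIP scores satisfy the normalisation identity on random models", {
  for (s in 1:50) {
    p <- random_problem(100 + s, n = 20, P = 6)
    m <- fit_plsr(p$X, 3, y = p$y)
    v <- vip_scores(m)
    expect_equal(sum(v$scores^2), 6, tolerance = 1e-8)
    expect_true(all(v$scores >= 0))
    expect_setequal(v$retained_labels, names(v$scores)[v$scores >= 1])
  }
})

test_that("a single informative feature takes the whole VIP budget", {
  set.seed(21)
  X <- cbind(x1 = rnorm(20), x2 = rep(1, 20), x3 = rep(2, 20),
             x4 = rep(3, 20))
  y <- drop(3 * X[, 1])
  m <- fit_plsr(X, 1, y = y)
  v <- vip_scores(m)
  expect_equal(unname(v$scores["x1"]), 2, tolerance = 1e-8)  # sqrt(P) = 2
  expect_equal(unname(v$scores[c("x2", "x3", "x4")]), rep(0, 3))
  expect_equal(v$retained_labels, "x1")
})

test_that("degenerate PLSR inputs raise errors", {
  set.seed(9)
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_plsr(X, 1, y = rep(5, 10)), "zero-variance")
  expect_error(fit_plsr(X, 5, y = rnorm(10)), "n_factors")
})

test_that("peak detection finds planted well-separated bands", {
  flat <- raman_spectrum(1:100, rep(3, 100))
  expect_length(detect_peaks(flat), 0)

  wn <- seq(500, 1700, by = 1)
  bands <- tiny_band_library()
  sp <- raman_spectrum(wn, band_sum(wn, bands))
  found <- detect_peaks(sp, 0.02)
  expect_length(found, nrow(bands))
  expect_true(all(abs(found - bands$center) <= 2))
  # prominence threshold suppresses minor bumps
  tiny_bump <- band_sum(wn, bands) + 2 / (1 + ((wn - 600) / 5)^2)
  expect_length(detect_peaks(raman_spectrum(wn, tiny_bump), 0.02),
                nrow(bands))
})

test_that("peak features are windowed maxima with preserved labels", {
  wn <- seq(500, 1700, by = 1)
  bands <- tiny_band_library()
  set.seed(12)
  n_plants <- 6
  scale <- runif(n_plants, 0.8, 1.2)
  mat <- t(vapply(scale, function(s) band_sum(wn, bands, s),
                  numeric(length(wn))))
  rownames(mat) <- paste0("p", 1:n_plants)
  ps <- plant_samples(wn, mat,
                      data.frame(plant_id = rownames(mat),
                                 set_label = "fixing", nitrogen_mM = 2,
                                 n_measurements = 1))
  fm <- extract_peak_features(ps, bands$center, window_cm1 = 4)
  expect_equal(dim(fm$values), c(n_plants, nrow(bands)))
  expect_equal(fm$feature_wavenumbers, bands$center)
  # isolated bands: feature close to scaled amplitude
  expect_equal(fm$values[, 2], scale * bands$base_amplitude[2],
               tolerance = 0.05, ignore_attr = TRUE)
  # degenerate case: every grid point with zero window is the spectrum
  fm_all <- extract_peak_features(ps, wn, window_cm1 = 0)
  expect_equal(unname(fm_all$values), unname(mat))
  expect_error(extract_peak_features(ps, 2000, 4), "outside grid")
})
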