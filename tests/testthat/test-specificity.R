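test_that("elastic-net penalty arithmetic", {
  b <- c(1, -2)
  expect_equal(enet_penalty(b, 0.5), 2.75)
  expect_equal(enet_penalty(b, 1), 3)
  expect_equal(enet_penalty(b, 0), 2.5)
  expect_equal(enet_penalty(numeric(3), 0.5), 0)
  expect_error(enet_penalty(b, 1.2), "alpha")
})

test_that("the cost function matches its closed-form special cases", {
  p <- random_problem(1, n = 30, P = 3)
  ols <- lm(p$y ~ p$X)
  expect_equal(enet_cost(p$X, p$y, coef(ols)[1], coef(ols)[-1], 0),
               sum(resid(ols)^2) / (2 * 30))
  # null model: J = population variance / 2
  expect_equal(enet_cost(p$X, p$y, mean(p$y), rep(0, 3), 5, 0.5),
               mean((p$y - mean(p$y))^2) / 2)
  fit <- fit_enet(p$X, p$y, lambda = 2, alpha = 0.5)
  expect_lte(fit$objective_value,
             enet_cost(p$X, p$y, mean(p$y), rep(0, 3), 2, 0.5))
  # the literal inside-bracket form is a lambda rescaling
  expect_equal(enet_cost(p$X, p$y, 1, c(1, 2, 3), 4, 0.5,
                         lambda_inside_bracket = TRUE),
               enet_cost(p$X, p$y, 1, c(1, 2, 3), 4 / (2 * 30), 0.5))
})

test_that("coordinate descent reproduces OLS at lambda = 0", {
  for (s in 1:5) {
    p <- random_problem(s, n = 50, P = 5)
    f <- fit_enet(p$X, p$y, lambda = 0)
    ols <- lm(p$y ~ p$X)
    expect_equal(unname(f$beta), unname(coef(ols)[-1]), tolerance = 1e-6)
    expect_equal(f$beta0, unname(coef(ols)[1]), tolerance = 1e-6)
  }
})

test_that("extreme penalties shrink every coefficient exactly to zero", {
  p <- random_problem(2, n = 40, P = 4)
  lam_big <- 1e6 * max(abs(crossprod(p$X, p$y))) / 40
  f <- fit_enet(p$X, p$y, lambda = lam_big, alpha = 0.5)
  expect_identical(unname(f$beta), rep(0, 4))
  expect_equal(f$beta0, mean(p$y))
})

test_that("coordinate descent beats a brute-force grid on two features", {
  set.seed(3)
  X <- matrix(rnorm(30 * 2), 30)
  y <- drop(X %*% c(1.5, -2)) + rnorm(30)
  f <- fit_enet(X, y, lambda = 1, alpha = 0.5)
  g <- as.matrix(expand.grid(b1 = seq(-5, 5, length.out = 201),
                             b2 = seq(-5, 5, length.out = 201)))
  obj <- apply(g, 1, function(b)
    enet_cost(X, y, mean(y - X %*% b), b, 1, 0.5))
  expect_lte(f$objective_value, min(obj) + 1e-12)
})

test_that("coordinate descent agrees with an independent convex solver", {
  skip_if_not_installed("glmnet")
  # y scaled to unit *population* variance so glmnet's internal response
  # standardisation is the identity and the two objectives coincide
  for (s in 1:20) {
    set.seed(s)
    n <- 40
    X <- matrix(rnorm(n * 6), n)
    y <- drop(X %*% rnorm(6)) + rnorm(n)
    y <- y / (sd(y) * sqrt((n - 1) / n))
    lams <- c(0.5, 0.1, 0.02)
    g <- glmnet::glmnet(X, y, alpha = 0.5, lambda = lams,
                        standardize = FALSE, thresh = 1e-14, maxit = 1e7)
    for (l in lams) {
      f <- fit_enet(X, y, lambda = l, alpha = 0.5, tol = 1e-10)
      b <- as.numeric(coef(g, s = l))
      expect_equal(unname(f$beta), b[-1], tolerance = 1e-5)
      expect_equal(f$beta0, b[1], tolerance = 1e-5)
    }
  }
})

test_that("non-convergence raises a condition carrying the last iterate", {
  p <- random_problem(4, n = 30, P = 5)
  err <- tryCatch(fit_enet(p$X, p$y, lambda = 0.01, tol = 1e-12,
                           max_sweeps = 1),
                  condition = function(e) e)
  expect_s3_class(err, "ramanbnf_enet_nonconvergence")
  expect_length(err$beta, 5)
})

test_that("the regularisation path is consistent and increasingly sparse", {
  p <- random_problem(5, n = 30, P = 5)
  Xnf <- random_problem(6, n = 15, P = 5)$X
  path <- regularisation_path(p$X, Xnf, alpha = 0.5, y = p$y)
  expect_equal(path$lambda_grid[1], 0)
  f0 <- fit_enet(p$X, p$y, lambda = 0)
  expect_equal(unname(path$coefficients[1, ]), unname(f0$beta),
               tolerance = 1e-7)
  G <- length(path$lambda_grid)
  # full shrinkage at the top of the grid: control output is the mean
  expect_equal(unname(path$coefficients[G, ]), rep(0, 5))
  expect_equal(path$mean_nonfixing_prediction[G], mean(p$y),
               tolerance = 1e-8)
  # penalty value at the optimum is non-increasing in lambda
  pen <- apply(path$coefficients, 1, enet_penalty, alpha = 0.5)
  expect_true(all(diff(pen) <= 1e-8))
  # L1 sparsity: all-zero solutions appear at finite lambda
  expect_true(any(rowSums(path$coefficients != 0) == 0))
  expect_equal(path$mean_nonfixing_prediction[
    match(path$lambda_star, path$lambda_grid)],
    min(path$mean_nonfixing_prediction))
  colnames(Xnf) <- paste0("z", 1:5)
  expect_error(regularisation_path(p$X, Xnf, y = p$y), "labels differ")
  expect_error(regularisation_path(p$X, random_problem(6, n = 15, P = 5)$X,
                                   lambda_grid = c(1, 2), y = p$y),
               "include 0")
})

test_that("lambda selection minimises the control output with small-lambda ties", {
  mk <- function(lams, nf) structure(
    list(lambda_grid = lams, mean_nonfixing_prediction = nf),
    class = "enet_path")
  expect_equal(select_lambda(mk(c(0, 1, 2, 4), c(9, 7, 5, 3))), 4)
  expect_equal(select_lambda(mk(c(0, 1, 2, 4), c(9, 3, 5, 8))), 1)
  expect_equal(select_lambda(mk(c(0, 1, 2, 4), c(9, 3, 3, 8))), 1)
})

test_that("key-wavenumber criteria apply the coefficient and reduction rules", {
  unreg <- c(a = 1.0, b = 0.5, c = 0.05, d = 0.8, e = 0)
  reg <- c(a = 0.85, b = 0.6, c = 0.04, d = 0.75, e = 0.2)
  sel <- select_key_wavenumbers(unreg, reg)
  # a: 0.85 > 0.1 and 15% reduction -> selected
  # b: grew (0.5 -> 0.6) -> excluded by the literal rule
  # c: below the magnitude threshold; d: only 6.25% reduction
  # e: zero unregularised coefficient -> excluded
  expect_equal(sel$selected_wavenumbers, "a")
  sel2 <- select_key_wavenumbers(unreg, reg, include_increases = TRUE)
  expect_setequal(sel2$selected_wavenumbers, c("a", "b", "e"))
  # all-zero regularised coefficients select nothing
  expect_length(select_key_wavenumbers(unreg, reg * 0)$selected_wavenumbers,
                0)
  expect_error(select_key_wavenumbers(unreg, c(x = 1)), "share labels")
})

test_that("bundled band assignments cover the influential peak table", {
  tab <- band_assignments()
  expect_equal(nrow(tab), 15)
  expect_named(tab, c("band_cm1", "vibrational_mode", "assignment"))
  expect_true(674 %in% tab$band_cm1 && 1426 %in% tab$band_cm1)
})
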