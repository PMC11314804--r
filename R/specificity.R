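#' Elastic-net penalty
#'
#' `P_alpha(beta) = (1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1`;
#' `alpha = 1` is the lasso, `alpha = 0` ridge.
#'
#' @param beta Coefficient vector.
#' @param alpha Mixing weight in `[0, 1]`.
#' @return Non-negative scalar, zero iff `beta = 0`.
#' @export
enet_penalty <- function(beta, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  (1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta))
}

#' Elastic-net cost function
#'
#' `J = (1/(2N)) * sum_i (y_i - beta0 - x_i' beta)^2 + lambda * P_alpha(beta)`.
#' With `lambda_inside_bracket = TRUE` the penalty term is placed inside
#' the `1/(2N)` bracket instead (`J = (1/(2N)) (RSS + lambda P_alpha)`),
#' which is the same family reparametrised by `lambda / (2N)`.
#'
#' @param X Feature matrix (rows are samples).
#' @param y Response vector.
#' @param beta0 Intercept.
#' @param beta Coefficient vector.
#' @param lambda Penalty strength, `>= 0`.
#' @param alpha Mixing weight in `[0, 1]`.
#' @param lambda_inside_bracket Penalty placement convention (see above).
#' @return Scalar cost `J`.
#' @export
enet_cost <- function(X, y, beta0, beta, lambda, alpha = 0.5,
                      lambda_inside_bracket = FALSE) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N == 0) stop("empty problem", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  r <- y - beta0 - drop(X %*% beta)
  lam <- if (lambda_inside_bracket) lambda / (2 * N) else lambda
  sum(r^2) / (2 * N) + lam * enet_penalty(beta, alpha)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Fit an elastic-net regression by cyclic coordinate descent
#'
#' Minimises [enet_cost()] with an unpenalised intercept. Features and
#' response are centred internally (no standardisation: raw Raman peak
#' intensities keep their scale); each sweep updates coefficients in fixed
#' cyclic order by soft-thresholding, so the fit is deterministic.
#' Convergence when the largest coefficient change in a sweep falls below
#' `tol`; non-convergence after `max_sweeps` raises an error condition
#' (class `ramanbnf_enet_nonconvergence`) carrying the last iterate.
#'
#' @param X Feature matrix or [feature_matrix()] (rows are samples).
#' @param y Response; defaults to the feature matrix response.
#' @param lambda Penalty strength `>= 0`.
#' @param alpha Mixing weight in `[0, 1]` (default 0.5, equal L1/L2
#'   balance).
#' @param lambda_inside_bracket See [enet_cost()].
#' @param beta_init Optional warm-start coefficients.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_sweeps Sweep budget.
#' @return Object of class `enet_model`: `beta0`, `beta` (named), `alpha`,
#'   `lambda`, `objective_value`, `n_sweeps`.
#' @export
fit_enet <- function(X, y = NULL, lambda, alpha = 0.5,
                     lambda_inside_bracket = FALSE, beta_init = NULL,
                     tol = 1e-8, max_sweeps = 1e5) {
  if (inherits(X, "feature_matrix")) {
    y <- y %||% X$response
    X <- X$values
  } else X <- as.matrix(X)
  if (is.null(y)) stop("response required", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  N <- nrow(X); P <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(P))
  lam <- if (lambda_inside_bracket) lambda / (2 * N) else lambda
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  z <- colSums(Xc^2) / N
  beta <- if (is.null(beta_init)) numeric(P) else as.numeric(beta_init)
  r <- yc - drop(Xc %*% beta)
  l1 <- lam * alpha
  l2 <- lam * (1 - alpha)
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    delta_max <- 0
    for (j in seq_len(P)) {
      if (z[j] < 1e-14) { # zero-variance feature: coefficient pinned at 0
        if (beta[j] != 0) { r <- r + Xc[, j] * beta[j]; beta[j] <- 0 }
        next
      }
      rho <- sum(Xc[, j] * r) / N + z[j] * beta[j]
      bj <- soft_threshold(rho, l1) / (z[j] + l2)
      d <- bj - beta[j]
      if (d != 0) {
        r <- r - Xc[, j] * d
        beta[j] <- bj
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(errorCondition(
      sprintf("elastic net did not converge in %d sweeps (last max change %g)",
              max_sweeps, delta_max),
      class = "ramanbnf_enet_nonconvergence",
      beta = beta, tol_reached = delta_max))
  beta0 <- y_mean - sum(x_mean * beta)
  structure(
    list(beta0 = beta0, beta = stats::setNames(beta, colnames(X)),
         alpha = alpha, lambda = lambda,
         lambda_inside_bracket = lambda_inside_bracket,
         objective_value = enet_cost(X, y, beta0, beta, lambda, alpha,
                                     lambda_inside_bracket),
         n_sweeps = sweeps),
    class = "enet_model")
}

#' @export
print.enet_model <- function(x, ...) {
  cat(sprintf(
    "<enet_model> alpha %.2f lambda %.4g | %d/%d nonzero | J = %.4g\n",
    x$alpha, x$lambda, sum(x$beta != 0), length(x$beta), x$objective_value))
  invisible(x)
}

#' @export
predict.enet_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$values else
    as.matrix(newdata)
  if (!is.null(colnames(X))) {
    missing <- setdiff(names(object$beta), colnames(X))
    if (length(missing))
      stop("newdata lacks model features: ",
           paste(missing, collapse = ", "), call. = FALSE)
    X <- X[, names(object$beta), drop = FALSE]
  }
  drop(object$beta0 + X %*% object$beta)
}

# Smallest lambda at which every coefficient is zero (standard convention).
lambda_max_enet <- function(X, y, alpha) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  max(abs(crossprod(Xc, yc))) / (nrow(X) * max(alpha, 1e-3))
}

default_lambda_grid <- function(X, y, alpha, length_out = 40) {
  lmax <- lambda_max_enet(X, y, alpha)
  c(0, exp(seq(log(lmax * 1e-3), log(lmax), length.out = length_out)))
}

#' Regularisation path targeted at the non-fixing control set
#'
#' For each penalty strength in `lambda_grid` (ascending, warm-started),
#' fits the elastic net on the fixing set and records the coefficient
#' vector, the calibration R^2 on the fixing set, and the mean predicted
#' %BNF of the non-fixing control set. Since non-fixing plants truly fix
#' no nitrogen, the penalty strength is later chosen to minimise that mean
#' ([select_lambda()]), trading calibration fit for specificity to
#' fixation. Non-fixing predictions are not clipped at zero here (clipping
#' would flatten the selection objective); clip only when reporting.
#'
#' @param X A [feature_matrix()] (fixing set) with response.
#' @param X_nonfixing A [feature_matrix()] of the control set sharing the
#'   same feature labels.
#' @param lambda_grid Ascending grid including 0; default 0 plus 40
#'   log-spaced values up to the full-shrinkage lambda.
#' @param alpha Mixing weight (default 0.5).
#' @param y Response when `X` is a plain matrix.
#' @param lambda_inside_bracket See [enet_cost()].
#' @return Object of class `enet_path`: `lambda_grid`, `coefficients`
#'   (grid x P), `intercepts`, `mean_nonfixing_prediction`, `fixing_r2`,
#'   `lambda_star`.
#' @export
regularisation_path <- function(X, X_nonfixing, lambda_grid = NULL,
                                alpha = 0.5, y = NULL,
                                lambda_inside_bracket = FALSE) {
  if (inherits(X, "feature_matrix")) {
    y <- y %||% X$response
    Xf <- X$values
  } else Xf <- as.matrix(X)
  Xn <- if (inherits(X_nonfixing, "feature_matrix")) X_nonfixing$values else
    as.matrix(X_nonfixing)
  if (!is.null(colnames(Xf)) && !is.null(colnames(Xn))) {
    if (!setequal(colnames(Xf), colnames(Xn)))
      stop("fixing and non-fixing feature labels differ", call. = FALSE)
    Xn <- Xn[, colnames(Xf), drop = FALSE]
  } else if (ncol(Xn) != ncol(Xf))
    stop("fixing and non-fixing feature counts differ", call. = FALSE)
  if (is.null(lambda_grid))
    lambda_grid <- default_lambda_grid(Xf, y, alpha)
  lambda_grid <- sort(as.numeric(lambda_grid))
  if (min(lambda_grid) > 0)
    stop("lambda grid must include 0 (the unregularised model)",
         call. = FALSE)
  G <- length(lambda_grid)
  coefs <- matrix(0, G, ncol(Xf), dimnames = list(NULL, colnames(Xf)))
  b0 <- mean_nf <- r2 <- numeric(G)
  sst <- sum((y - mean(y))^2)
  warm <- NULL
  for (g in seq_len(G)) {
    fit <- fit_enet(Xf, y, lambda = lambda_grid[g], alpha = alpha,
                    lambda_inside_bracket = lambda_inside_bracket,
                    beta_init = warm)
    warm <- fit$beta
    coefs[g, ] <- fit$beta
    b0[g] <- fit$beta0
    yhat <- drop(fit$beta0 + Xf %*% fit$beta)
    r2[g] <- 1 - sum((y - yhat)^2) / sst
    mean_nf[g] <- mean(fit$beta0 + Xn %*% fit$beta)
  }
  path <- structure(
    list(lambda_grid = lambda_grid, coefficients = coefs, intercepts = b0,
         mean_nonfixing_prediction = mean_nf, fixing_r2 = r2,
         alpha = alpha, lambda_star = NA_real_),
    class = "enet_path")
  path$lambda_star <- select_lambda(path)
  path
}

#' @export
print.enet_path <- function(x, ...) {
  i <- match(x$lambda_star, x$lambda_grid)
  cat(sprintf(
    "<enet_path> %d lambdas | lambda* = %.4g (mean non-fixing %.2f%%, fixing R2 %.3f)\n",
    length(x$lambda_grid), x$lambda_star,
    x$mean_nonfixing_prediction[i], x$fixing_r2[i]))
  invisible(x)
}

#' Select the penalty minimising the control-set output
#'
#' `lambda*` is the grid value at which the mean predicted %BNF of the
#' non-fixing control set is smallest; exact ties are broken toward the
#' smaller lambda (least intervention).
#'
#' @param path An `enet_path`.
#' @return Selected lambda.
#' @export
select_lambda <- function(path) {
  if (!length(path$lambda_grid)) stop("empty path", call. = FALSE)
  # grid is ascending, which.min returns the first (smallest-lambda) tie
  path$lambda_grid[which.min(path$mean_nonfixing_prediction)]
}

#' Select key BNF-related wavenumbers
#'
#' A feature is a key wavenumber when (1) its regularised coefficient
#' magnitude exceeds `coef_threshold` and (2) regularisation reduced the
#' coefficient magnitude by more than `reduction_threshold` relative to
#' the unregularised model. Features with a zero unregularised coefficient
#' are excluded. The literal rule discards features whose coefficient
#' *grew* under regularisation; set `include_increases = TRUE` to also
#' retain grown coefficients above the magnitude threshold.
#'
#' @param coef_unregularised Named coefficient vector at `lambda = 0`.
#' @param coef_regularised Named coefficient vector at `lambda*` (same
#'   labels).
#' @param coef_threshold Magnitude threshold (default 0.1).
#' @param reduction_threshold Relative reduction threshold (default 0.10).
#' @param include_increases Also keep coefficient-increase cases.
#' @return List with `selected_wavenumbers` (labels) and `table` (per
#'   feature: both coefficients, relative reduction, selection flag).
#' @export
select_key_wavenumbers <- function(coef_unregularised, coef_regularised,
                                   coef_threshold = 0.1,
                                   reduction_threshold = 0.10,
                                   include_increases = FALSE) {
  labs <- names(coef_unregularised)
  if (is.null(labs) || is.null(names(coef_regularised)) ||
      !setequal(labs, names(coef_regularised)))
    stop("coefficient vectors must share labels", call. = FALSE)
  coef_regularised <- coef_regularised[labs]
  au <- abs(coef_unregularised); ar <- abs(coef_regularised)
  reduction <- ifelse(au > 0, (au - ar) / au, NA_real_)
  sel <- ar > coef_threshold & !is.na(reduction) &
    reduction > reduction_threshold
  if (include_increases)
    sel <- sel | (ar > coef_threshold & ar > au)
  list(selected_wavenumbers = labs[sel],
       table = data.frame(
         label = labs,
         coef_unregularised = as.numeric(coef_unregularised),
         coef_regularised = as.numeric(coef_regularised),
         reduction = as.numeric(reduction),
         selected = sel, row.names = NULL))
}

#' Literature band assignments
#'
#' Reference table of vibrational-band assignments for the influential
#' soybean leaf Raman peaks (band centre, vibrational mode, candidate
#' biochemical), bundled as package data.
#'
#' @return Data frame with columns `band_cm1`, `vibrational_mode`,
#'   `assignment`.
#' @export
band_assignments <- function() {
  path <- system.file("extdata", "band_assignments.csv",
                      package = "ramanbnf", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Nearest-band assignment strings for a set of peak wavenumbers.
assign_bands <- function(wavenumbers, max_distance_cm1 = 6) {
  tab <- band_assignments()
  vapply(wavenumbers, function(w) {
    d <- abs(tab$band_cm1 - w)
    i <- which.min(d)
    if (d[i] <= max_distance_cm1) tab$assignment[i] else NA_character_
  }, character(1))
}
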