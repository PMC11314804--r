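#' Feature matrix of peak intensities
#'
#' Samples x features container used by the PLSR and elastic-net stages.
#' Columns are labelled by the wavenumber (cm^-1) of the peak they
#' represent.
#'
#' @param values Numeric matrix, `n_samples x P`, no missing values.
#' @param feature_wavenumbers Numeric vector of length `P`.
#' @param sample_ids Character vector of row identifiers.
#' @param response Optional numeric response (%BNF) per sample.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_wavenumbers, sample_ids,
                           response = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature matrix must have no missing values",
                          call. = FALSE)
  if (ncol(values) < 1) stop("feature matrix needs at least one feature",
                             call. = FALSE)
  if (length(feature_wavenumbers) != ncol(values))
    stop("feature_wavenumbers length must equal feature count",
         call. = FALSE)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length must equal sample count", call. = FALSE)
  if (!is.null(response) && length(response) != nrow(values))
    stop("response length must equal sample count", call. = FALSE)
  colnames(values) <- format_wn(feature_wavenumbers)
  rownames(values) <- sample_ids
  structure(list(values = values,
                 feature_wavenumbers = as.numeric(feature_wavenumbers),
                 sample_ids = as.character(sample_ids),
                 response = response),
            class = "feature_matrix")
}

format_wn <- function(x) sprintf("wn_%.2f", x)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$response)) "" else " (+response)"))
  invisible(x)
}

#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares regression of a single response on mean-centred
#' features (no unit-variance scaling: absolute Raman intensities are
#' informative). The NIPALS sequence extracts factors maximising the
#' covariance between feature scores and the response; deflation makes the
#' factor scores mutually orthogonal. Requested factors beyond the
#' effective rank of the centred feature matrix are dropped with a
#' warning.
#'
#' @param X A [feature_matrix()] with a response, or a plain matrix.
#' @param n_factors Number of latent factors to extract.
#' @param y Response vector (ignored when `X` carries one).
#' @return Object of class `plsr_model` with weights, loadings, scores,
#'   regression coefficients, intercept and per-factor explained Y
#'   variance (%).
#' @export
fit_plsr <- function(X, n_factors, y = NULL) {
  if (inherits(X, "feature_matrix")) {
    y <- y %||% X$response
    wns <- X$feature_wavenumbers
    X <- X$values
  } else {
    X <- as.matrix(X)
    wns <- seq_len(ncol(X))
    if (is.null(colnames(X))) colnames(X) <- paste0("x", wns)
  }
  if (is.null(y)) stop("response required to fit PLSR", call. = FALSE)
  n <- nrow(X); P <- ncol(X)
  if (stats::var(y) == 0)
    stop("zero-variance response", call. = FALSE)
  if (n_factors < 1 || n_factors > min(n - 1, P))
    stop("n_factors must lie in [1, min(n_samples - 1, P)]", call. = FALSE)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  sst <- sum(yc^2)
  W <- Pl <- matrix(0, P, n_factors)
  Tm <- matrix(0, n, n_factors)
  q <- ssy <- numeric(n_factors)
  A <- 0L
  for (a in seq_len(n_factors)) {
    w <- crossprod(Xc, yc)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sst)) break
    w <- w / nw
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p <- crossprod(Xc, t_)[, 1] / tt
    qa <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p)
    yc <- yc - t_[, 1] * qa
    A <- a
    W[, a] <- w; Pl[, a] <- p; Tm[, a] <- t_; q[a] <- qa
    ssy[a] <- qa^2 * tt
  }
  if (A == 0L) stop("no covariance between features and response",
                    call. = FALSE)
  if (A < n_factors)
    warning(sprintf("requested %d factors, rank supports %d", n_factors, A))
  W <- W[, seq_len(A), drop = FALSE]
  Pl <- Pl[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]; ssy <- ssy[seq_len(A)]
  b <- plsr_coefficients(W, Pl, q, A)
  model <- structure(
    list(n_factors = A, x_mean = x_mean, y_mean = y_mean,
         weights = W, x_loadings = Pl, y_loadings = q, scores = Tm,
         coefficients = stats::setNames(b, colnames(X)),
         intercept = y_mean - sum(x_mean * b),
         explained_y_variance_per_factor = 100 * ssy / sst,
         feature_wavenumbers = wns, feature_labels = colnames(X)),
    class = "plsr_model")
  model
}

# Regression coefficients of the a-factor PLS1 model: b = W (Pl' W)^-1 q.
plsr_coefficients <- function(W, Pl, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- Pl[, seq_len(a), drop = FALSE]
  (Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))[, 1]
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d factors, %d features\n",
              x$n_factors, length(x$coefficients)))
  cat(sprintf("  cumulative explained Y variance: %.1f%%\n",
              sum(x$explained_y_variance_per_factor)))
  invisible(x)
}

#' Predict %BNF from a fitted PLSR model
#'
#' Columns of the new data are aligned to the model's feature labels, so
#' predictions are invariant to feature order. Unknown or missing labels
#' raise an error naming the offending wavenumbers.
#'
#' @param object A `plsr_model`.
#' @param newdata A [feature_matrix()] or labelled matrix.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$values else
    as.matrix(newdata)
  labs <- colnames(X)
  if (is.null(labs)) {
    if (ncol(X) != length(object$feature_labels))
      stop("unlabelled newdata with wrong number of columns", call. = FALSE)
    labs <- object$feature_labels
    colnames(X) <- labs
  }
  missing <- setdiff(object$feature_labels, labs)
  if (length(missing))
    stop("newdata lacks model features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- X[, object$feature_labels, drop = FALSE]
  drop(object$intercept + X %*% object$coefficients)
}

#' Leave-one-out cross-validation of a PLSR calibration
#'
#' Each sample (plant) is held out in turn; the model is refitted from
#' scratch on the remainder and the held-out %BNF predicted, for every
#' factor count up to `max_factors`. The optimal factor count is the
#' smallest whose validation R^2 is within `parsimony_tol` of the maximum.
#'
#' @param X A [feature_matrix()] with response, or matrix.
#' @param max_factors Largest factor count to evaluate; capped at the
#'   per-fold rank with a warning.
#' @param y Response when `X` is a plain matrix.
#' @param parsimony_tol Tolerance of the parsimony rule (R^2 units).
#' @return Object of class `plsr_cv` with calibration/validation R^2 and
#'   RMSE per factor count, per-sample LOOCV predictions and
#'   `optimal_factors`.
#' @export
loocv_plsr <- function(X, max_factors, y = NULL, parsimony_tol = 0.01) {
  if (inherits(X, "feature_matrix")) {
    y <- y %||% X$response
    Xm <- X$values
  } else Xm <- as.matrix(X)
  n <- nrow(Xm)
  if (n < 3) stop("LOOCV needs at least 3 samples", call. = FALSE)
  cap <- min(max_factors, n - 2, ncol(Xm))
  if (cap < max_factors)
    warning(sprintf("max_factors capped at %d by fold rank", cap))
  preds <- matrix(NA_real_, n, cap)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      fit_plsr(Xm[-i, , drop = FALSE], cap, y = y[-i]))
    for (a in seq_len(cap)) {
      aa <- min(a, fit$n_factors)
      b <- plsr_coefficients(fit$weights, fit$x_loadings, fit$y_loadings, aa)
      preds[i, a] <- fit$y_mean + sum((Xm[i, ] - fit$x_mean) * b)
    }
  }
  sst <- sum((y - mean(y))^2)
  full <- suppressWarnings(fit_plsr(Xm, cap, y = y))
  cal <- vapply(seq_len(cap), function(a) {
    aa <- min(a, full$n_factors)
    b <- plsr_coefficients(full$weights, full$x_loadings, full$y_loadings, aa)
    drop(full$y_mean + sweep(Xm, 2, full$x_mean) %*% b)
  }, numeric(n))
  r2_cal <- 1 - colSums((cal - y)^2) / sst
  rmse_cal <- sqrt(colMeans((cal - y)^2))
  r2_val <- 1 - colSums((preds - y)^2) / sst
  rmse_val <- sqrt(colMeans((preds - y)^2))
  best <- max(r2_val)
  optimal <- min(which(r2_val >= best - parsimony_tol))
  structure(
    list(factors = seq_len(cap),
         r2_cal = r2_cal, rmse_cal = rmse_cal,
         r2_val = r2_val, rmse_val = rmse_val,
         loocv_predictions = preds,
         optimal_factors = optimal),
    class = "plsr_cv")
}

#' @export
print.plsr_cv <- function(x, ...) {
  cat(sprintf("<plsr_cv> optimal factors: %d (R2_val %.3f, RMSE_val %.2f)\n",
              x$optimal_factors, x$r2_val[x$optimal_factors],
              x$rmse_val[x$optimal_factors]))
  invisible(x)
}

#' Training vs cross-validated explained-variance curves
#'
#' Cumulative percentage of response variance explained on the training
#' data and the corresponding LOOCV value (100 x validation R^2) per
#' factor count. A widening train/validation gap diagnoses overfitting.
#'
#' @inheritParams loocv_plsr
#' @return Data frame with columns `factors`, `explained_cal`,
#'   `explained_val`.
#' @export
explained_variance_curves <- function(X, max_factors, y = NULL) {
  cv <- loocv_plsr(X, max_factors, y = y)
  data.frame(factors = cv$factors,
             explained_cal = 100 * cv$r2_cal,
             explained_val = 100 * cv$r2_val)
}

#' Variable importance in projection scores
#'
#' `VIP_j = sqrt(P * sum_a ssy_a * w_ja^2 / sum_a ssy_a)` with normalised
#' weight vectors `w_a` and `ssy_a` the response variance explained by
#' factor `a`. Mean squared VIP is 1 by construction, so scores above 1
#' mark features of above-average influence.
#'
#' @param model A fitted `plsr_model`.
#' @param threshold Retention threshold (default 1): features scoring
#'   below it are excluded from the retained set.
#' @return List with `scores` (named), `threshold` and
#'   `retained_wavenumbers` (numeric cm^-1 of features with
#'   `score >= threshold`).
#' @export
vip_scores <- function(model, threshold = 1) {
  ssy <- model$explained_y_variance_per_factor
  if (sum(ssy) <= 0) stop("model explains no response variance",
                          call. = FALSE)
  W2 <- model$weights^2   # columns already unit norm
  P <- nrow(W2)
  vip <- sqrt(P * drop(W2 %*% ssy) / sum(ssy))
  names(vip) <- model$feature_labels
  keep <- vip >= threshold
  list(scores = vip, threshold = threshold,
       retained_wavenumbers = model$feature_wavenumbers[keep],
       retained_labels = model$feature_labels[keep])
}

#' Detect peaks in a mean corrected spectrum
#'
#' Local maxima whose topographic prominence is at least
#' `prominence_fraction` of the spectrum maximum. Prominence of a peak is
#' its height above the higher of the two minima separating it from
#' higher terrain on either side (or from the spectrum edge).
#'
#' @param spec A baseline-corrected [raman_spectrum()] (or a list with
#'   `wavenumber`/`intensity`).
#' @param prominence_fraction Fraction of the maximum intensity.
#' @return Numeric vector of peak wavenumbers, ascending (possibly empty).
#' @export
detect_peaks <- function(spec, prominence_fraction = 0.05) {
  y <- spec$intensity
  n <- length(y)
  if (n < 3) return(numeric(0))
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                    y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(is_max)) return(numeric(0))
  prom <- vapply(is_max, function(i) {
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    higher_l <- which(left > y[i])
    base_l <- if (length(higher_l)) min(left[(max(higher_l) + 1):(i - 1)])
      else min(left)
    higher_r <- which(right > y[i])
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)])
      else min(right)
    y[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= prominence_fraction * max(y)
  sort(spec$wavenumber[is_max[keep]])
}

#' Extract windowed peak-intensity features
#'
#' Feature `j` of each plant is the maximum corrected intensity within
#' `window_cm1 / 2` of peak centre `j`; the window tolerates small
#' peak-position shifts between plants.
#'
#' @param samples A [plant_samples()] object.
#' @param peaks Numeric vector of peak centres (cm^-1), all within the
#'   grid.
#' @param window_cm1 Full window width in cm^-1 (default 4).
#' @return A [feature_matrix()]; the response column is filled from
#'   `samples$info$bnf_percent` when present.
#' @export
extract_peak_features <- function(samples, peaks, window_cm1 = 4) {
  wn <- samples$wavenumber
  step <- spectrum_step(wn)
  vals <- matrix(NA_real_, nrow(samples$intensities), length(peaks))
  for (j in seq_along(peaks)) {
    sel <- which(abs(wn - peaks[j]) <= window_cm1 / 2 + 1e-6 * step)
    if (!length(sel))
      stop(sprintf("peak %.2f cm^-1 outside grid or window too narrow",
                   peaks[j]), call. = FALSE)
    vals[, j] <- apply(samples$intensities[, sel, drop = FALSE], 1, max)
  }
  feature_matrix(vals, peaks, rownames(samples$intensities),
                 response = samples$info$bnf_percent)
}
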