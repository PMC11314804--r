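#' Preprocessing configuration
#'
#' Parameters of the despike -> smooth -> baseline -> crop -> average
#' chain. Defaults follow common practice for 785 nm leaf spectra:
#' Savitzky-Golay polynomial order 13 with a 51-point frame, and an
#' iterative moving-average fluorescence baseline with a 50 cm^-1 kernel
#' run for 50 iterations. The analysis window is 600-1770 cm^-1.
#'
#' @param sg_poly_order Savitzky-Golay polynomial order.
#' @param sg_frame_length Savitzky-Golay frame length in grid points; odd
#'   and greater than `sg_poly_order`.
#' @param baseline_kernel_cm1 Moving-average kernel width in cm^-1
#'   (converted to an odd number of grid points).
#' @param baseline_iterations Number of min/moving-average iterations.
#' @param despike_window Rolling-median window (points, odd).
#' @param despike_z_threshold Robust z-score above which a point is
#'   treated as a cosmic-ray spike.
#' @param crop_range Analysis window in cm^-1 (closed interval).
#' @param average_before_baseline If `TRUE`, replicate measurements are
#'   averaged before baseline subtraction instead of after (sensitivity
#'   analysis); default `FALSE`.
#' @param normalisation One of `"none"` (default), `"snv"`, `"area"`.
#'   Off by default: absolute intensities carry calibration information,
#'   and normalising discards it.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_poly_order = 13, sg_frame_length = 51,
                              baseline_kernel_cm1 = 50,
                              baseline_iterations = 50,
                              despike_window = 7, despike_z_threshold = 8,
                              crop_range = c(600, 1770),
                              average_before_baseline = FALSE,
                              normalisation = c("none", "snv", "area")) {
  cfg <- structure(
    list(sg_poly_order = as.integer(sg_poly_order),
         sg_frame_length = as.integer(sg_frame_length),
         baseline_kernel_cm1 = baseline_kernel_cm1,
         baseline_iterations = as.integer(baseline_iterations),
         despike_window = as.integer(despike_window),
         despike_z_threshold = despike_z_threshold,
         crop_range = as.numeric(crop_range),
         average_before_baseline = isTRUE(average_before_baseline),
         normalisation = match.arg(normalisation)),
    class = "preprocess_config")
  if (cfg$sg_frame_length %% 2 == 0)
    stop("sg_frame_length must be odd", call. = FALSE)
  if (cfg$sg_frame_length <= cfg$sg_poly_order)
    stop("sg_frame_length must exceed sg_poly_order", call. = FALSE)
  if (cfg$baseline_iterations < 1)
    stop("baseline_iterations must be >= 1", call. = FALSE)
  if (cfg$despike_window %% 2 == 0 || cfg$despike_window < 3)
    stop("despike_window must be odd and >= 3", call. = FALSE)
  if (length(cfg$crop_range) != 2 || diff(cfg$crop_range) <= 0)
    stop("crop_range must be an increasing pair", call. = FALSE)
  cfg
}

# Rolling median (and median absolute deviation) over centred windows that
# shrink at the boundaries. Windows include the point itself.
rolling_median_mad <- function(y, window) {
  n <- length(y)
  h <- window %/% 2
  med <- mad_ <- numeric(n)
  for (i in seq_len(n)) {
    w <- y[max(1, i - h):min(n, i + h)]
    m <- stats::median(w)
    med[i] <- m
    mad_[i] <- stats::median(abs(w - m))
  }
  list(median = med, mad = mad_)
}

#' Remove single-point cosmic-ray spikes
#'
#' Each point is compared with the median of its `despike_window`
#' neighbourhood; points whose positive deviation exceeds
#' `despike_z_threshold` robust standard deviations (1.4826 x rolling MAD)
#' are replaced by the rolling median. Replacement and re-screening repeat
#' until no point is flagged (a handful of passes at most), so the
#' operation is idempotent: its output is a fixed point. Only positive
#' deviations are flagged: cosmic rays are additive.
#'
#' @param spec A [raman_spectrum()] (or numeric vector).
#' @param cfg A [preprocess_config()]; or pass `window`/`z_threshold`.
#' @param window,z_threshold Overrides for the config values.
#' @return Despiked spectrum of the same type as the input.
#' @export
despike <- function(spec, cfg = preprocess_config(),
                    window = cfg$despike_window,
                    z_threshold = cfg$despike_z_threshold) {
  y <- if (inherits(spec, "raman_spectrum")) spec$intensity else spec
  if (window > length(y))
    stop("despike window larger than spectrum", call. = FALSE)
  out <- y
  for (pass in 1:10) {
    rm_ <- rolling_median_mad(out, window)
    dev <- out - rm_$median
    scale <- 1.4826 * rm_$mad
    z <- ifelse(dev <= 0, 0, ifelse(scale > 0, dev / scale, Inf))
    flagged <- z > z_threshold
    if (!any(flagged)) break
    out[flagged] <- rm_$median[flagged]
  }
  if (inherits(spec, "raman_spectrum")) {
    spec$intensity <- out
    spec
  } else out
}

# Projection matrix of a least-squares polynomial fit of degree p on n
# equally spaced points. Built from an orthogonal polynomial basis
# (stats::poly on scaled offsets), so it stays numerically exact at the
# high orders (e.g. 13) where a raw-monomial Vandermonde breaks down.
sgolay_projection <- function(poly_order, frame_length) {
  x <- seq(-1, 1, length.out = frame_length)
  A <- cbind(1, stats::poly(x, degree = poly_order))
  Q <- qr.Q(qr(A))
  tcrossprod(Q)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing: each point is replaced by the
#' value of a degree-`sg_poly_order` polynomial fitted to its
#' `sg_frame_length`-point window. Polynomial signals of degree up to the
#' order are reproduced exactly. The first and last half-frames are
#' smoothed with the polynomial fitted to the first/last full frame,
#' evaluated at the edge offsets, so output length equals input length.
#' The fit uses an orthogonal-polynomial basis and is numerically stable
#' at high orders.
#'
#' @inheritParams despike
#' @param poly_order,frame_length Overrides for the config values.
#' @return Smoothed spectrum of the same type as the input.
#' @export
savgol_smooth <- function(spec, cfg = preprocess_config(),
                          poly_order = cfg$sg_poly_order,
                          frame_length = cfg$sg_frame_length) {
  y <- if (inherits(spec, "raman_spectrum")) spec$intensity else spec
  if (frame_length %% 2 == 0)
    stop("frame_length must be odd", call. = FALSE)
  if (frame_length <= poly_order)
    stop("frame_length must exceed poly_order", call. = FALSE)
  if (frame_length > length(y))
    stop("frame_length exceeds spectrum length", call. = FALSE)
  n <- length(y)
  h <- frame_length %/% 2
  H <- sgolay_projection(poly_order, frame_length)
  centre <- H[h + 1, ]
  out <- as.numeric(stats::filter(y, centre, sides = 2))
  out[seq_len(h)] <- drop(H[seq_len(h), ] %*% y[seq_len(frame_length)])
  out[(n - h + 1):n] <-
    drop(H[(h + 2):frame_length, ] %*% y[(n - frame_length + 1):n])
  if (inherits(spec, "raman_spectrum")) {
    spec$intensity <- out
    spec
  } else out
}

# Centred moving average with boundary windows shrunk (no padding), via
# cumulative sums.
moving_average <- function(y, half_window) {
  n <- length(y)
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half_window)
  hi <- pmin(n, idx + half_window)
  cs <- c(0, cumsum(y))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Iterative moving-average fluorescence baseline
#'
#' Estimates the broad fluorescence background under sharp Raman bands.
#' Starting from the spectrum itself, each iteration replaces the current
#' baseline estimate by the pointwise minimum of itself and its centred
#' moving average (kernel `baseline_kernel_cm1`, converted to an odd
#' number of grid points). Smooth broad structure survives the averaging
#' almost unchanged, while narrow peaks are progressively planed off, so
#' the estimate converges onto the background. The baseline never exceeds
#' the input and is pointwise non-increasing across iterations.
#'
#' @inheritParams despike
#' @param kernel_cm1,iterations Overrides for the config values.
#' @return List with `baseline` and `corrected` (input minus baseline),
#'   each of the same type as the input.
#' @export
baseline_ima <- function(spec, cfg = preprocess_config(),
                         kernel_cm1 = cfg$baseline_kernel_cm1,
                         iterations = cfg$baseline_iterations) {
  is_spec <- inherits(spec, "raman_spectrum")
  if (!is_spec)
    stop("baseline_ima needs a raman_spectrum (kernel is in cm^-1)",
         call. = FALSE)
  step <- spectrum_step(spec$wavenumber)
  w <- round(kernel_cm1 / step)
  if (w %% 2 == 0) w <- w + 1
  if (w < 3) stop("baseline kernel below 3 grid points", call. = FALSE)
  h <- w %/% 2
  b <- spec$intensity
  for (t in seq_len(iterations)) b <- pmin(b, moving_average(b, h))
  baseline <- spec
  baseline$intensity <- b
  corrected <- spec
  corrected$intensity <- spec$intensity - b
  list(baseline = baseline, corrected = corrected)
}

#' Average repeated measurements of one plant
#'
#' Pointwise arithmetic mean of spectra sharing one wavenumber grid and one
#' plant. Metadata records the plant id and the number of averaged
#' acquisitions.
#'
#' @param specs List of [raman_spectrum()] objects.
#' @return A [raman_spectrum()].
#' @export
average_measurements <- function(specs) {
  if (length(specs) == 0) stop("no spectra to average", call. = FALSE)
  wn <- specs[[1]]$wavenumber
  pid <- specs[[1]]$meta$plant_id
  for (s in specs) {
    if (length(s$wavenumber) != length(wn) ||
        max(abs(s$wavenumber - wn)) > 1e-9 * max(abs(wn)))
      stop("alignment error: spectra do not share one grid", call. = FALSE)
    if (!is.null(pid) && !is.null(s$meta$plant_id) &&
        !identical(s$meta$plant_id, pid))
      stop("spectra belong to different plants", call. = FALSE)
  }
  m <- rowMeans(vapply(specs, function(s) s$intensity,
                       numeric(length(wn))))
  raman_spectrum(wn, m,
                 meta = list(plant_id = pid, n_measurements = length(specs)),
                 validate = FALSE)
}

#' Crop a spectrum to a wavenumber window
#'
#' Retains grid points with `range[1] <= wavenumber <= range[2]` (closed
#' interval, with a small numeric tolerance on the bounds).
#'
#' @param spec A [raman_spectrum()].
#' @param range Length-2 numeric window in cm^-1.
#' @return Cropped [raman_spectrum()].
#' @export
crop_spectrum <- function(spec, range = c(600, 1770)) {
  step <- spectrum_step(spec$wavenumber)
  tol <- 1e-6 * step
  keep <- spec$wavenumber >= range[1] - tol & spec$wavenumber <= range[2] + tol
  if (!any(keep)) stop("crop range retains no grid points", call. = FALSE)
  spec$wavenumber <- spec$wavenumber[keep]
  spec$intensity <- spec$intensity[keep]
  spec
}

crop_indices <- function(wavenumber, range) {
  step <- spectrum_step(wavenumber)
  tol <- 1e-6 * step
  which(wavenumber >= range[1] - tol & wavenumber <= range[2] + tol)
}

apply_normalisation <- function(y, method) {
  switch(method,
         none = y,
         snv = (y - mean(y)) / stats::sd(y),
         area = y / sum(abs(y)))
}

#' Full preprocessing pipeline
#'
#' Per acquisition: despike, Savitzky-Golay smooth, iterative
#' moving-average baseline subtraction, crop to the analysis window; then
#' the corrected spectra of each plant are averaged (averaging can instead
#' precede baseline subtraction via `cfg$average_before_baseline`).
#' Ground-truth %BNF, when supplied, is joined onto the per-plant output.
#'
#' @param set A [spectra_set()].
#' @param cfg A [preprocess_config()].
#' @param truth Optional ground-truth data frame with `plant_id` and
#'   `bnf_percent`.
#' @return A [plant_samples()] object (one corrected spectrum per plant).
#' @export
preprocess_pipeline <- function(set, cfg = preprocess_config(),
                                truth = NULL) {
  man <- set$manifest
  plants <- unique(man$plant_id)
  if (!is.null(truth)) {
    missing <- setdiff(truth$plant_id, plants)
    if (length(missing))
      stop("plants with zero spectra: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  keep <- crop_indices(set$wavenumber, cfg$crop_range)
  wn_crop <- set$wavenumber[keep]

  per_spectrum <- function(y) {
    y <- despike(y, cfg)
    y <- savgol_smooth(y, cfg)
    y
  }
  correct <- function(y) {
    spec <- raman_spectrum(set$wavenumber, y, validate = FALSE)
    baseline_ima(spec, cfg)$corrected$intensity[keep]
  }

  out <- matrix(NA_real_, length(plants), length(wn_crop))
  info <- data.frame(plant_id = plants, set_label = NA_character_,
                     nitrogen_mM = NA_real_, n_measurements = NA_integer_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(plants)) {
    rows <- which(man$plant_id == plants[i])
    smoothed <- t(apply(set$intensities[rows, , drop = FALSE], 1,
                        per_spectrum))
    if (cfg$average_before_baseline) {
      corr <- correct(colMeans(smoothed))
    } else {
      corr <- colMeans(t(apply(smoothed, 1, correct)))
    }
    out[i, ] <- apply_normalisation(corr, cfg$normalisation)
    info$set_label[i] <- man$set_label[rows[1]]
    info$nitrogen_mM[i] <- man$nitrogen_mM[rows[1]]
    info$n_measurements[i] <- length(rows)
  }
  rownames(out) <- plants
  if (!is.null(truth))
    info$bnf_percent <- truth$bnf_percent[match(plants, truth$plant_id)]
  plant_samples(wn_crop, out, info)
}
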