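#' Construct a single Raman spectrum
#'
#' A `raman_spectrum` holds one acquisition: a strictly increasing, uniform
#' wavenumber grid (cm^-1), the measured intensities (detector counts) and a
#' list of acquisition metadata (spectrum id, plant linkage, measurement
#' index, processing stage).
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing on a uniform grid.
#' @param intensity Numeric vector of intensities, same length as
#'   `wavenumber`, all finite.
#' @param meta Named list of metadata fields.
#' @param validate If `TRUE` (default) the grid and intensities are checked.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list(),
                           validate = TRUE) {
  spec <- structure(
    list(wavenumber = as.numeric(wavenumber),
         intensity = as.numeric(intensity),
         meta = meta),
    class = "raman_spectrum")
  if (validate) validate_spectrum(spec)
  spec
}

validate_spectrum <- function(spec) {
  if (length(spec$wavenumber) != length(spec$intensity))
    stop("wavenumber and intensity must have the same length", call. = FALSE)
  if (!all(is.finite(spec$intensity)))
    stop("intensities must all be finite", call. = FALSE)
  spectrum_step(spec$wavenumber)
  invisible(spec)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  if (!is.null(x$meta$spectrum_id))
    cat("  spectrum_id:", x$meta$spectrum_id, "\n")
  invisible(x)
}

# Grid step of a uniform wavenumber axis; errors if the axis is not strictly
# increasing or departs from uniformity by more than `tol` (relative).
spectrum_step <- function(wavenumber, tol = 1e-6) {
  if (length(wavenumber) < 2)
    stop("spectrum grid needs at least two points", call. = FALSE)
  d <- diff(wavenumber)
  if (any(d <= 0))
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  step <- mean(d)
  if (max(abs(d - step)) > tol * step)
    stop("wavenumber grid is not uniform", call. = FALSE)
  step
}

#' Construct a set of spectra sharing one wavenumber grid
#'
#' A `spectra_set` stores many acquisitions as an intensity matrix (one row
#' per spectrum) plus a manifest linking each spectrum to its plant,
#' treatment set, nitrogen level, replicate and measurement index.
#'
#' @param wavenumber Shared wavenumber grid (cm^-1).
#' @param intensities Numeric matrix, `n_spectra x n_wavenumbers`, with
#'   rownames equal to `manifest$spectrum_id`.
#' @param manifest Data frame with columns `spectrum_id`, `plant_id`,
#'   `set_label`, `nitrogen_mM`, `replicate`, `measurement_index`.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumber, intensities, manifest) {
  intensities <- as.matrix(intensities)
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  required <- c("spectrum_id", "plant_id", "set_label", "nitrogen_mM",
                "replicate", "measurement_index")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols))
    stop("manifest is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(manifest$spectrum_id))
    stop("duplicate spectrum_id in manifest: ",
         paste(unique(manifest$spectrum_id[duplicated(manifest$spectrum_id)]),
               collapse = ", "), call. = FALSE)
  if (nrow(intensities) != nrow(manifest))
    stop("intensity matrix and manifest disagree on spectrum count",
         call. = FALSE)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- manifest$spectrum_id
  if (!identical(rownames(intensities), as.character(manifest$spectrum_id)))
    stop("intensity rownames must match manifest spectrum_id order",
         call. = FALSE)
  if (ncol(intensities) != length(wavenumber))
    stop("intensity matrix width must match wavenumber grid", call. = FALSE)
  spectrum_step(wavenumber)
  if (!all(is.finite(intensities)))
    stop("intensities must all be finite", call. = FALSE)
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensities = intensities,
                 manifest = manifest),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d points, %.1f-%.1f cm-1\n",
              nrow(x$intensities), length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  cat(sprintf("  plants: %d  sets: %s\n",
              length(unique(x$manifest$plant_id)),
              paste(sort(unique(x$manifest$set_label)), collapse = ", ")))
  invisible(x)
}

# Extract one spectrum (by row index or spectrum_id) as a raman_spectrum.
#' @export
`[[.spectra_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$manifest$spectrum_id)
  raman_spectrum(x$wavenumber, x$intensities[i, ],
                 meta = as.list(x$manifest[i, ]), validate = FALSE)
}

#' Per-plant preprocessed spectra with treatment information
#'
#' A `plant_samples` object holds one averaged, baseline-corrected spectrum
#' per plant (rows of `intensities`) together with treatment metadata and,
#' when available, the isotope-dilution ground-truth %BNF.
#'
#' @param wavenumber Shared wavenumber grid (cm^-1).
#' @param intensities Matrix `n_plants x n_wavenumbers`, rownames plant ids.
#' @param info Data frame with columns `plant_id`, `set_label`,
#'   `nitrogen_mM`, `n_measurements` and optionally `bnf_percent`.
#' @return An object of class `plant_samples`.
#' @export
plant_samples <- function(wavenumber, intensities, info) {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == nrow(info))
  if (is.null(rownames(intensities)))
    rownames(intensities) <- info$plant_id
  spectrum_step(wavenumber)
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensities = intensities,
                 info = as.data.frame(info, stringsAsFactors = FALSE)),
            class = "plant_samples")
}

#' @export
print.plant_samples <- function(x, ...) {
  cat(sprintf("<plant_samples> %d plants x %d points\n",
              nrow(x$intensities), length(x$wavenumber)))
  invisible(x)
}

# Subset plants by a logical/integer index, keeping grid and info aligned.
subset_plants <- function(ps, idx) {
  plant_samples(ps$wavenumber, ps$intensities[idx, , drop = FALSE],
                ps$info[idx, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
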