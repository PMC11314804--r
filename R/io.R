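#' Write a spectra set to long-format CSV plus manifest
#'
#' Spectra CSV columns: `spectrum_id`, `wavenumber_cm1`, `intensity`;
#' manifest CSV columns: `spectrum_id`, `plant_id`, `set_label`,
#' `nitrogen_mM`, `replicate`, `measurement_index`. UTF-8, header row,
#' '.' decimal, no row names.
#'
#' @param set A [spectra_set()].
#' @param spectra_path,manifest_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_spectra <- function(set, spectra_path, manifest_path) {
  man <- set$manifest
  long <- data.frame(
    spectrum_id = rep(man$spectrum_id, each = length(set$wavenumber)),
    wavenumber_cm1 = rep(set$wavenumber, times = nrow(man)),
    intensity = as.vector(t(set$intensities)))
  utils::write.csv(long, spectra_path, row.names = FALSE)
  utils::write.csv(man, manifest_path, row.names = FALSE)
  invisible(c(spectra_path, manifest_path))
}

#' Read a spectra set from long-format CSV plus manifest
#'
#' Validates that every spectrum id appears in the manifest and vice
#' versa, that ids are unique, that all spectra share one strictly
#' increasing uniform grid. Row order in either file is irrelevant.
#'
#' @param spectra_path,manifest_path CSV paths as written by
#'   [write_spectra()].
#' @return A [spectra_set()].
#' @export
read_spectra <- function(spectra_path, manifest_path) {
  long <- utils::read.csv(spectra_path, stringsAsFactors = FALSE)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "wavenumber_cm1", "intensity")
  if (!all(need %in% names(long)))
    stop("spectra CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(man$spectrum_id))
    stop("duplicate spectrum_id in manifest: ",
         paste(unique(man$spectrum_id[duplicated(man$spectrum_id)]),
               collapse = ", "), call. = FALSE)
  ids_data <- unique(long$spectrum_id)
  orphan <- setdiff(ids_data, man$spectrum_id)
  if (length(orphan))
    stop("spectra missing from manifest: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(man$spectrum_id, ids_data)
  if (length(absent))
    stop("manifest rows without spectra: ", paste(absent, collapse = ", "),
         call. = FALSE)
  man <- man[order(man$spectrum_id), , drop = FALSE]
  rownames(man) <- NULL
  long <- long[order(long$spectrum_id, long$wavenumber_cm1), , drop = FALSE]
  counts <- table(long$spectrum_id)
  if (length(unique(counts)) != 1)
    stop("spectra have differing numbers of grid points", call. = FALSE)
  n_wn <- as.integer(counts[1])
  wn <- long$wavenumber_cm1[seq_len(n_wn)]
  spectrum_step(wn)   # strictly increasing uniform grid
  grids <- matrix(long$wavenumber_cm1, nrow = n_wn)
  if (max(abs(grids - wn)) > 1e-9 * max(abs(wn)))
    stop("spectra do not share one wavenumber grid", call. = FALSE)
  intens <- t(matrix(long$intensity, nrow = n_wn))
  rownames(intens) <- unique(long$spectrum_id)
  spectra_set(wn, intens, man)
}

#' Write / read per-plant ground truth
#'
#' CSV columns `plant_id`, `set_label`, `nitrogen_mM`, `replicate`,
#' `bnf_percent`.
#'
#' @param truth Ground-truth data frame.
#' @param path CSV path.
#' @return `write_ground_truth`: the path, invisibly;
#'   `read_ground_truth`: the data frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  truth <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("plant_id", "bnf_percent") %in% names(truth)))
    stop("ground truth needs plant_id and bnf_percent columns",
         call. = FALSE)
  truth
}

#' Write preprocessed per-plant spectra
#'
#' Same long CSV dialect as [write_spectra()], with a `stage` column
#' marking the processing state.
#'
#' @param samples A [plant_samples()] object.
#' @param path CSV path.
#' @param stage Stage label (default `"preprocessed"`).
#' @return The path, invisibly.
#' @export
write_plant_spectra <- function(samples, path, stage = "preprocessed") {
  long <- data.frame(
    spectrum_id = rep(rownames(samples$intensities),
                      each = length(samples$wavenumber)),
    wavenumber_cm1 = rep(samples$wavenumber,
                         times = nrow(samples$intensities)),
    intensity = as.vector(t(samples$intensities)),
    stage = stage)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `spectra.csv`, `manifest.csv` and `ground_truth.csv`.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("spectra.csv", "manifest.csv",
                            "ground_truth.csv"))
  write_spectra(dataset$spectra, paths[1], paths[2])
  write_ground_truth(dataset$truth, paths[3])
  invisible(paths)
}

#' Serialise / deserialise a PLSR model as JSON
#'
#' Round-trips every numeric field to full double precision and metadata
#' bit-exactly.
#'
#' @param model A `plsr_model`.
#' @param path JSON path.
#' @return `write_plsr_model`: the path, invisibly; `read_plsr_model`: the
#'   model.
#' @export
write_plsr_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_plsr_model
#' @export
read_plsr_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- raw
  # column-major serialisation: columns arrive as inner arrays
  for (f in c("weights", "x_loadings", "scores"))
    model[[f]] <- t(as.matrix(raw[[f]]))
  model$coefficients <- stats::setNames(as.numeric(raw$coefficients),
                                        raw$feature_labels)
  model$x_mean <- stats::setNames(as.numeric(raw$x_mean),
                                  raw$feature_labels)
  structure(model, class = "plsr_model")
}

#' Write a regularisation path as CSV
#'
#' Columns: `lambda`, one column per feature coefficient,
#' `mean_nonfixing_prediction`, `fixing_r2`.
#'
#' @param path_obj An `enet_path`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_enet_path <- function(path_obj, path) {
  df <- data.frame(lambda = path_obj$lambda_grid,
                   path_obj$coefficients, check.names = FALSE)
  df$mean_nonfixing_prediction <- path_obj$mean_nonfixing_prediction
  df$fixing_r2 <- path_obj$fixing_r2
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
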