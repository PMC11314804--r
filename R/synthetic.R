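#' Default spectral band library for soybean leaf spectra
#'
#' Literature band assignments used by the simulator. The fifteen
#' `bnf_linked` bands (674-1426 cm^-1) correspond to metabolites whose
#' abundance tracks biological nitrogen fixation (amino acids, glycerol,
#' nucleobases, cell-wall carbohydrates); the three `nitrogen_linked` bands
#' are the strong pectin/carotenoid features (747, 1160, 1525 cm^-1) that
#' respond to plant nitrogen status regardless of its source.
#'
#' @param bnf_amplitude Base amplitudes (counts) for the 15 BNF-linked
#'   bands, recycled if scalar.
#' @param nitrogen_amplitude Base amplitudes for the 3 nitrogen-status
#'   bands.
#' @return Data frame with columns `center`, `width` (HWHM, cm^-1),
#'   `base_amplitude`, `role`.
#' @export
default_band_library <- function(bnf_amplitude = NULL,
                                 nitrogen_amplitude = NULL) {
  bnf_centers <- c(674, 695, 704, 713, 726, 859, 952, 976, 1019, 1114,
                   1211, 1345, 1400, 1414, 1426)
  if (is.null(bnf_amplitude))
    bnf_amplitude <- c(160, 120, 110, 150, 140, 170, 180, 140, 130, 200,
                       220, 240, 200, 180, 190)
  bnf_amplitude <- rep_len(bnf_amplitude, length(bnf_centers))
  n_centers <- c(747, 1160, 1525)
  if (is.null(nitrogen_amplitude)) nitrogen_amplitude <- c(420, 900, 1100)
  nitrogen_amplitude <- rep_len(nitrogen_amplitude, length(n_centers))
  rbind(
    data.frame(center = bnf_centers, width = 8,
               base_amplitude = bnf_amplitude, role = "bnf_linked"),
    data.frame(center = n_centers, width = 10,
               base_amplitude = nitrogen_amplitude, role = "nitrogen_linked")
  )
}

#' Configuration of the synthetic greenhouse experiment
#'
#' Describes the simulated two-set design: fixing (inoculated) and
#' non-fixing (sterile) soybean plants grown at four nitrogen levels with
#' five replicates, three Raman acquisitions per plant. Spectra are a broad
#' fluorescence background plus Lorentzian bands whose amplitudes respond
#' either to the plant's %BNF (`bnf_linked` bands) or to its nitrogen
#' status (`nitrogen_linked` bands), with additive Gaussian noise and
#' optional cosmic-ray spikes.
#'
#' The wavenumber grid is anchored at 600 cm^-1 with the default step
#' `(1770 - 600)/1096` so that the standard 600-1770 cm^-1 analysis window
#' contains exactly 1097 channels; the grid is extended outwards to cover
#' `grid_min`-`grid_max`.
#'
#' @param nitrogen_levels_mM Nitrogen treatments (mM ammonium nitrate).
#' @param replicates_per_level Plants per set x nitrogen level.
#' @param measurements_per_plant Raman acquisitions per plant.
#' @param grid_min,grid_max Acquisition range, cm^-1.
#' @param grid_step Grid spacing, cm^-1.
#' @param band_library Data frame as from [default_band_library()].
#' @param bnf_response Named numeric vector mapping nitrogen level (mM) to
#'   the expected %BNF of fixing plants; must be non-increasing in nitrogen.
#' @param bnf_jitter_sd Between-plant SD of %BNF around the treatment mean.
#' @param bnf_effect_size Fractional amplitude change of `bnf_linked` bands
#'   per %BNF unit.
#' @param nitrogen_effect_size Fractional amplitude change of
#'   `nitrogen_linked` bands per mM of effective nitrogen status.
#' @param band_jitter_sd Relative SD of independent per-plant, per-band
#'   amplitude variability (biological metabolite variation not linked to
#'   BNF or nitrogen).
#' @param scatter_jitter_sd Relative SD of a per-plant common amplitude
#'   factor applied to all bands (leaf thickness / scattering efficiency);
#'   this is the dominant source of inter-feature correlation.
#' @param fixing_nitrogen_status Nitrogen status of fixing plants at
#'   sampling. `"residual"` (default): the symbiosis has largely levelled
#'   nitrogen status across treatments but a fraction
#'   `residual_nitrogen_fraction` of the treatment difference persists
#'   (residual effect of early-growth nitrogen deficiency);
#'   `"saturated"`: status fully uniform at `fixing_saturation_mM`;
#'   `"tracking"`: status follows the treatment exactly, as in the
#'   non-fixing set (robustness scenario).
#' @param residual_nitrogen_fraction Fraction (0-1) of the treatment
#'   difference retained by fixing plants under `"residual"`; 0 is
#'   `"saturated"`, 1 is `"tracking"`.
#' @param fixing_saturation_mM Effective nitrogen status (mM equivalent) of
#'   fully supplied fixing plants. Deliberately below the highest
#'   fertiliser treatment: symbiosis meets demand without the luxury
#'   nitrogen accumulation of heavily fertilised sterile plants.
#' @param fixation_overshoot_mM Extra nitrogen status (mM equivalent, per
#'   100 %BNF) of strongly fixing plants: plants deriving more nitrogen
#'   from fixation run a slightly richer nitrogen budget. This couples the
#'   nitrogen-status bands weakly and positively to %BNF in the fixing
#'   set, the leakage that control-set-targeted regularisation is meant to
#'   remove.
#' @param fluorescence_params List: `amplitude`, `center`, `width` of the
#'   Gaussian fluorescence hump; `ramp_high`, `ramp_low` of the linear ramp
#'   (counts at `grid_min` and `grid_max`); `jitter` relative per-spectrum
#'   amplitude variation.
#' @param noise_sd SD of additive Gaussian detector noise (counts).
#' @param cosmic_ray_rate Expected cosmic-ray spikes per spectrum.
#' @param cosmic_ray_amplitude Range (counts) of spike heights.
#' @param seed Root seed; per-plant child seeds are derived from it.
#' @return Validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(nitrogen_levels_mM = c(2, 6, 10, 14),
                             replicates_per_level = 5,
                             measurements_per_plant = 3,
                             grid_min = 400, grid_max = 1800,
                             grid_step = (1770 - 600) / 1096,
                             band_library = default_band_library(),
                             bnf_response = c("2" = 85, "6" = 60,
                                              "10" = 35, "14" = 15),
                             bnf_jitter_sd = 5,
                             bnf_effect_size = 0.02,
                             nitrogen_effect_size = 0.04,
                             band_jitter_sd = 0.04,
                             scatter_jitter_sd = 0.06,
                             fixing_nitrogen_status = c("saturated",
                                                        "residual",
                                                        "tracking"),
                             residual_nitrogen_fraction = 0.3,
                             fixing_saturation_mM = 14,
                             fixation_overshoot_mM = 0,
                             fluorescence_params = list(
                               amplitude = 6000, center = 1300, width = 500,
                               ramp_high = 3000, ramp_low = 1000,
                               jitter = 0.1),
                             noise_sd = 25,
                             cosmic_ray_rate = 0.2,
                             cosmic_ray_amplitude = c(500, 5000),
                             seed = 0L) {
  cfg <- structure(
    list(nitrogen_levels_mM = as.numeric(nitrogen_levels_mM),
         replicates_per_level = as.integer(replicates_per_level),
         measurements_per_plant = as.integer(measurements_per_plant),
         grid_min = grid_min, grid_max = grid_max, grid_step = grid_step,
         band_library = band_library,
         bnf_response = bnf_response,
         bnf_jitter_sd = bnf_jitter_sd,
         bnf_effect_size = bnf_effect_size,
         nitrogen_effect_size = nitrogen_effect_size,
         band_jitter_sd = band_jitter_sd,
         scatter_jitter_sd = scatter_jitter_sd,
         fixing_nitrogen_status = match.arg(fixing_nitrogen_status),
         residual_nitrogen_fraction = residual_nitrogen_fraction,
         fixing_saturation_mM = fixing_saturation_mM,
         fixation_overshoot_mM = fixation_overshoot_mM,
         fluorescence_params = fluorescence_params,
         noise_sd = noise_sd,
         cosmic_ray_rate = cosmic_ray_rate,
         cosmic_ray_amplitude = as.numeric(cosmic_ray_amplitude),
         seed = as.integer(seed)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (!(grid_min < grid_max)) stop("grid_min must be < grid_max",
                                     call. = FALSE)
    if (!(grid_step > 0)) stop("grid_step must be > 0", call. = FALSE)
    if (replicates_per_level < 1 || measurements_per_plant < 1 ||
        length(nitrogen_levels_mM) < 1)
      stop("all design counts must be >= 1", call. = FALSE)
    if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
    if (band_jitter_sd < 0 || scatter_jitter_sd < 0)
      stop("jitter SDs must be >= 0", call. = FALSE)
    if (residual_nitrogen_fraction < 0 || residual_nitrogen_fraction > 1)
      stop("residual_nitrogen_fraction must lie in [0, 1]", call. = FALSE)
    if (cosmic_ray_rate < 0) stop("cosmic_ray_rate must be >= 0",
                                  call. = FALSE)
    if (any(cosmic_ray_amplitude < 0))
      stop("cosmic_ray_amplitude bounds must be >= 0", call. = FALSE)
    need <- as.character(nitrogen_levels_mM)
    if (!all(need %in% names(bnf_response)))
      stop("bnf_response must name every nitrogen level", call. = FALSE)
    resp <- bnf_response[need]
    if (any(resp < 0 | resp > 100))
      stop("bnf_response values must lie in [0, 100]", call. = FALSE)
    if (is.unsorted(rev(resp[order(nitrogen_levels_mM)])))
      stop("bnf_response must be non-increasing in nitrogen level",
           call. = FALSE)
    if (!all(c("center", "width", "base_amplitude", "role") %in%
             names(band_library)))
      stop("band_library needs columns center, width, base_amplitude, role",
           call. = FALSE)
    if (any(band_library$width <= 0))
      stop("band widths must be > 0", call. = FALSE)
    if (any(band_library$base_amplitude < 0))
      stop("band amplitudes must be >= 0", call. = FALSE)
    if (any(band_library$center < grid_min | band_library$center > grid_max))
      stop("band center outside the wavenumber grid", call. = FALSE)
  })
  cfg
}

# Wavenumber grid anchored at 600 cm^-1 (when covered) so the 600-1770
# crop has exactly (1770-600)/grid_step + 1 channels.
synthetic_grid <- function(cfg) {
  s <- cfg$grid_step
  anchor <- if (cfg$grid_min <= 600 && cfg$grid_max >= 600) 600 else
    cfg$grid_min
  k_lo <- -floor((anchor - cfg$grid_min) / s + 1e-9)
  k_hi <- floor((cfg$grid_max - anchor) / s + 1e-9)
  anchor + s * (k_lo:k_hi)
}

#' %BNF from a 15N isotope-dilution measurement
#'
#' Standard isotope dilution: plants fed 15N-enriched fertiliser dilute the
#' label with unenriched atmospheric N2 in proportion to the fraction of
#' nitrogen derived from fixation, so
#' `%BNF = (1 - AE_sample / AE_reference) * 100`, where AE is atom percent
#' 15N excess and the reference is a non-fixing plant under the same
#' fertilisation. The result is clipped to [0, 100].
#'
#' @param ae_sample Atom % 15N excess of the (potentially fixing) sample;
#'   must be >= 0.
#' @param ae_reference Atom % 15N excess of the non-fixing reference; must
#'   be > 0.
#' @return %BNF in [0, 100]; vectorised over `ae_sample`.
#' @export
ndfa_from_isotope <- function(ae_sample, ae_reference) {
  if (any(ae_reference <= 0))
    stop("invalid reference: atom % excess of the non-fixing reference ",
         "must be > 0", call. = FALSE)
  if (any(ae_sample < 0))
    stop("sample atom % excess must be >= 0", call. = FALSE)
  pmin(100, pmax(0, (1 - ae_sample / ae_reference) * 100))
}

# Lorentzian profile with half-width-at-half-maximum `w`, peak value `A`.
lorentzian <- function(x, center, w, A) A / (1 + ((x - center) / w)^2)

# Smooth fluorescence background: Gaussian hump + linear ramp, all >= 0.
fluorescence_background <- function(wn, cfg, amp_scale = 1) {
  fp <- cfg$fluorescence_params
  span <- cfg$grid_max - cfg$grid_min
  ramp <- fp$ramp_high + (fp$ramp_low - fp$ramp_high) *
    (wn - cfg$grid_min) / span
  amp_scale * (fp$amplitude * exp(-(wn - fp$center)^2 / (2 * fp$width^2)) +
                 pmax(ramp, 0))
}

# Effective nitrogen status (mM equivalent) of one plant.
nitrogen_status <- function(set_label, nitrogen_mM, cfg, bnf_percent = 0) {
  if (set_label == "non_fixing") return(nitrogen_mM)
  base <- switch(cfg$fixing_nitrogen_status,
                 saturated = cfg$fixing_saturation_mM,
                 tracking = nitrogen_mM,
                 residual = cfg$fixing_saturation_mM -
                   cfg$residual_nitrogen_fraction *
                   (cfg$fixing_saturation_mM - nitrogen_mM))
  base + cfg$fixation_overshoot_mM * bnf_percent / 100
}

#' Simulate one Raman acquisition
#'
#' Builds a spectrum as fluorescence background + sum of Lorentzian bands +
#' Gaussian noise. `bnf_linked` band amplitudes scale as
#' `base * (1 + bnf_effect_size * bnf_percent)`; `nitrogen_linked` bands as
#' `base * (1 + nitrogen_effect_size * status)` where the status of fixing
#' plants is governed by `cfg$fixing_nitrogen_status`. Deterministic given
#' `seed`.
#'
#' @param truth One-row data frame (or list) with `plant_id`, `set_label`,
#'   `nitrogen_mM`, `bnf_percent`.
#' @param cfg A [synthetic_config()].
#' @param measurement_index Acquisition number within the plant.
#' @param seed Integer seed for this acquisition's noise draws.
#' @param plant_effects Optional plant-level state as drawn by
#'   [generate_dataset()]: list with `scatter` (common amplitude factor)
#'   and `band_multiplier` (per-band factors). `NULL` means no
#'   between-plant amplitude variability.
#' @return A [raman_spectrum()].
#' @export
simulate_spectrum <- function(truth, cfg, measurement_index = 1L,
                              seed = cfg$seed, plant_effects = NULL) {
  wn <- synthetic_grid(cfg)
  bl <- cfg$band_library
  if (any(bl$center < min(wn) | bl$center > max(wn)))
    stop("band center outside the wavenumber grid", call. = FALSE)
  status <- nitrogen_status(truth$set_label, truth$nitrogen_mM, cfg,
                            truth$bnf_percent)
  amp <- bl$base_amplitude
  is_bnf <- bl$role == "bnf_linked"
  is_nit <- bl$role == "nitrogen_linked"
  amp[is_bnf] <- amp[is_bnf] * (1 + cfg$bnf_effect_size * truth$bnf_percent)
  amp[is_nit] <- amp[is_nit] * (1 + cfg$nitrogen_effect_size * status)
  if (!is.null(plant_effects))
    amp <- amp * plant_effects$scatter * plant_effects$band_multiplier
  set.seed(as.integer(seed))
  fl_scale <- 1 + cfg$fluorescence_params$jitter * stats::runif(1, -1, 1)
  intensity <- fluorescence_background(wn, cfg, fl_scale)
  for (b in seq_len(nrow(bl)))
    intensity <- intensity + lorentzian(wn, bl$center[b], bl$width[b], amp[b])
  if (cfg$noise_sd > 0)
    intensity <- intensity + stats::rnorm(length(wn), 0, cfg$noise_sd)
  raman_spectrum(
    wn, intensity,
    meta = list(spectrum_id = paste0(truth$plant_id, "_m", measurement_index),
                plant_id = truth$plant_id, set_label = truth$set_label,
                nitrogen_mM = truth$nitrogen_mM,
                measurement_index = measurement_index),
    validate = FALSE)
}

#' Add cosmic-ray spikes to a spectrum
#'
#' Draws `k ~ Poisson(rate)` (or a forced `k`) distinct grid positions and
#' adds a positive single-point spike at each, emulating detector
#' cosmic-ray events that the despiking stage must remove.
#'
#' @param spec A [raman_spectrum()].
#' @param rate Expected number of spikes; >= 0.
#' @param amplitude_range Length-2 positive range of spike heights (counts).
#' @param seed Integer seed.
#' @param k Optional forced spike count (overrides the Poisson draw).
#' @return List with `spectrum` (spiked copy) and `positions` (sorted grid
#'   indices of the spikes).
#' @export
inject_cosmic_rays <- function(spec, rate, amplitude_range = c(500, 5000),
                               seed = 0L, k = NULL) {
  if (rate < 0) stop("cosmic ray rate must be >= 0", call. = FALSE)
  if (any(amplitude_range < 0) || diff(amplitude_range) < 0)
    stop("amplitude_range must be an increasing pair of non-negative values",
         call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(k)) k <- stats::rpois(1, rate)
  if (k == 0) return(list(spectrum = spec, positions = integer(0)))
  pos <- sort(sample.int(length(spec$intensity), k))
  delta <- stats::runif(k, amplitude_range[1], amplitude_range[2])
  out <- spec
  out$intensity[pos] <- out$intensity[pos] + delta
  list(spectrum = out, positions = pos)
}

# Deterministic per-plant child seed below 2^31.
plant_seed <- function(root_seed, plant_index) {
  (as.integer(root_seed) %% 1048576L) * 1024L + as.integer(plant_index)
}

#' Generate a full synthetic fixing/non-fixing dataset
#'
#' Crosses the two treatment sets with every nitrogen level and replicate,
#' draws each fixing plant's %BNF around the treatment mean
#' (`cfg$bnf_response`, truncated to [0, 100]), simulates
#' `measurements_per_plant` acquisitions per plant and injects cosmic rays
#' at `cfg$cosmic_ray_rate`. Non-fixing plants always have
#' `bnf_percent = 0`. Fully deterministic given `cfg` (including its seed):
#' each plant owns a child seed so the dataset is reproducible and
#' extensible plant by plant.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `spectra` (a [spectra_set()]) and `truth` (data frame
#'   `plant_id`, `set_label`, `nitrogen_mM`, `replicate`, `bnf_percent`).
#' @export
generate_dataset <- function(cfg) {
  validate_synthetic_config(cfg)
  design <- expand.grid(replicate = seq_len(cfg$replicates_per_level),
                        nitrogen_mM = cfg$nitrogen_levels_mM,
                        set_label = c("fixing", "non_fixing"),
                        stringsAsFactors = FALSE)
  design$plant_id <- sprintf("%s_%02.0fmM_r%d",
                             ifelse(design$set_label == "fixing", "F", "NF"),
                             design$nitrogen_mM, design$replicate)
  wn <- synthetic_grid(cfg)
  n_spec <- nrow(design) * cfg$measurements_per_plant
  intens <- matrix(NA_real_, n_spec, length(wn))
  manifest <- vector("list", n_spec)
  truth <- design[, c("plant_id", "set_label", "nitrogen_mM", "replicate")]
  truth$bnf_percent <- 0
  row <- 0L
  for (i in seq_len(nrow(design))) {
    pseed <- plant_seed(cfg$seed, i)
    set.seed(pseed)
    # draw consumed by both sets so the downstream stream stays aligned
    mu <- cfg$bnf_response[[as.character(design$nitrogen_mM[i])]]
    bnf_draw <- stats::rnorm(1, mu, cfg$bnf_jitter_sd)
    if (design$set_label[i] == "fixing")
      truth$bnf_percent[i] <- min(100, max(0, bnf_draw))
    effects <- list(
      scatter = max(0.2, 1 + stats::rnorm(1, 0, cfg$scatter_jitter_sd)),
      band_multiplier = pmax(
        0.2, 1 + stats::rnorm(nrow(cfg$band_library), 0,
                              cfg$band_jitter_sd)))
    for (m in seq_len(cfg$measurements_per_plant)) {
      mseed <- pseed + 7919L * m
      spec <- simulate_spectrum(truth[i, ], cfg, m, seed = mseed,
                                plant_effects = effects)
      if (cfg$cosmic_ray_rate > 0)
        spec <- inject_cosmic_rays(spec, cfg$cosmic_ray_rate,
                                   cfg$cosmic_ray_amplitude,
                                   seed = mseed + 1L)$spectrum
      row <- row + 1L
      intens[row, ] <- spec$intensity
      manifest[[row]] <- data.frame(
        spectrum_id = spec$meta$spectrum_id, plant_id = design$plant_id[i],
        set_label = design$set_label[i],
        nitrogen_mM = design$nitrogen_mM[i],
        replicate = design$replicate[i], measurement_index = m,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(intens) <- manifest$spectrum_id
  list(spectra = spectra_set(wn, intens, manifest), truth = truth)
}
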