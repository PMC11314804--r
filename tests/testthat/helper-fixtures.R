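# Small synthetic configurations and random problems shared across tests.

# Unit-step grid (550-1800 cm^-1) so band centres land exactly on grid
# points; a handful of well-separated bands.
tiny_band_library <- function() {
  data.frame(center = c(700, 900, 1100, 1300),
             width = 8,
             base_amplitude = c(200, 300, 250, 350),
             role = c("bnf_linked", "bnf_linked", "bnf_linked",
                      "nitrogen_linked"))
}

tiny_config <- function(...) {
  args <- list(grid_min = 550, grid_max = 1800, grid_step = 1,
               replicates_per_level = 2, measurements_per_plant = 2,
               band_library = tiny_band_library())
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

# Fully deterministic tiny config: no noise, no jitter, no cosmic rays.
noiseless_config <- function(...) {
  args <- list(noise_sd = 0, band_jitter_sd = 0, scatter_jitter_sd = 0,
               cosmic_ray_rate = 0,
               fluorescence_params = list(amplitude = 4000, center = 1200,
                                          width = 500, ramp_high = 2000,
                                          ramp_low = 800, jitter = 0))
  override <- list(...)
  args[names(override)] <- override
  do.call(tiny_config, args)
}

# Random regression problem with named feature columns.
random_problem <- function(seed, n = 40, P = 6, noise = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * P), n, P,
              dimnames = list(NULL, paste0("x", seq_len(P))))
  beta <- stats::rnorm(P)
  y <- drop(X %*% beta) + noise * stats::rnorm(n)
  list(X = X, y = y, beta = beta)
}

# Analytic sum of Lorentzian bands on a grid.
band_sum <- function(wn, bands, amp_scale = 1) {
  out <- rep(0, length(wn))
  for (b in seq_len(nrow(bands)))
    out <- out + amp_scale * bands$base_amplitude[b] /
      (1 + ((wn - bands$center[b]) / bands$width[b])^2)
  out
}
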