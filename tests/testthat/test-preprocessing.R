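test_that("despike leaves clean spectra alone and repairs spikes", {
  wn <- seq(400, 1400, by = 1)
  smooth <- 500 + 2000 * exp(-(wn - 900)^2 / (2 * 300^2)) +
    band_sum(wn, tiny_band_library())
  expect_identical(despike(smooth), smooth)

  set.seed(1)
  noisy <- smooth + rnorm(length(wn), 0, 5)
  spiked <- noisy
  spiked[500] <- spiked[500] + 50 * 5
  fixed <- despike(spiked)
  expect_lt(abs(fixed[500] - noisy[500]), 3 * 5)
  expect_identical(fixed[-500], spiked[-500])
})

test_that("despike is idempotent and rarely touches clean noisy spectra", {
  altered <- 0L
  n <- 600
  for (s in 1:100) {
    set.seed(s)
    y <- 1000 + 50 * sin(seq(0, 6, length.out = n)) + rnorm(n, 0, 10)
    d1 <- despike(y)
    altered <- altered + sum(d1 != y)
    expect_identical(despike(d1), d1)
  }
  expect_lt(altered / (100 * n), 0.01)
})

test_that("Savitzky-Golay reproduces polynomials and smooths noise", {
  # constants are degree-0 polynomials
  expect_equal(savgol_smooth(rep(7, 200)), rep(7, 200), tolerance = 1e-10)
  # exact reproduction of a degree-13 polynomial signal
  x <- seq(-1, 1, length.out = 300)
  y <- rowSums(outer(x, 0:13, `^`))
  out <- savgol_smooth(y, poly_order = 13, frame_length = 51)
  expect_equal(out, y, tolerance = 1e-8)
  # white-noise variance reduction below 0.5
  vr <- vapply(1:100, function(s) {
    set.seed(s)
    e <- rnorm(500)
    var(savgol_smooth(e)[26:475])
  }, numeric(1))
  expect_lt(mean(vr), 0.5)
  # parameter validation
  expect_error(savgol_smooth(rnorm(100), frame_length = 50), "odd")
  expect_error(savgol_smooth(rnorm(100), poly_order = 51,
                             frame_length = 51), "exceed")
  expect_error(savgol_smooth(rnorm(10)), "length")
})

test_that("Savitzky-Golay matches an independent implementation at low order", {
  skip_if_not_installed("signal")
  set.seed(4)
  y <- cumsum(rnorm(300))
  ours <- savgol_smooth(y, poly_order = 3, frame_length = 11)
  ref <- signal::sgolayfilt(y, p = 3, n = 11)
  expect_equal(ours[6:295], ref[6:295], tolerance = 1e-9)
})

test_that("iterative moving-average baseline stays below the input and shrinks", {
  set.seed(2)
  wn <- seq(500, 1700, by = 1)
  bg <- 4000 * exp(-(wn - 1000)^2 / (2 * 450^2)) + 1500
  y <- bg + band_sum(wn, tiny_band_library()) + rnorm(length(wn), 0, 5)
  sp <- raman_spectrum(wn, y)
  r <- baseline_ima(sp)
  expect_true(all(r$baseline$intensity <= sp$intensity + 1e-9))
  expect_equal(r$corrected$intensity,
               sp$intensity - r$baseline$intensity)
  # baseline is pointwise non-increasing across iterations
  b_prev <- baseline_ima(sp, iterations = 5)$baseline$intensity
  for (it in c(10, 25, 50)) {
    b <- baseline_ima(sp, iterations = it)$baseline$intensity
    expect_true(all(b <= b_prev + 1e-9))
    b_prev <- b
  }
  expect_error(baseline_ima(raman_spectrum(c(1, 2, 4, 8), rep(1, 4))),
               "uniform")
})

test_that("baseline recovers a known background under narrow peaks", {
  wn <- seq(500, 1700, by = 1)
  bg <- 5000 * exp(-(wn - 1000)^2 / (2 * 600^2)) + 2000 - wn / 2
  # pure smooth broad hump: residual under 2% of amplitude
  r0 <- baseline_ima(raman_spectrum(wn, bg))
  expect_lt(max(abs(r0$corrected$intensity)), 0.02 * 5000)
  # narrow Lorentzian on a zero baseline keeps >= 90% of its height
  pk <- 800 / (1 + ((wn - 1100) / 5)^2)
  r1 <- baseline_ima(raman_spectrum(wn, pk))
  expect_gte(r1$corrected$intensity[wn == 1100], 0.9 * 800)
})

test_that("averaging replicate measurements is an arithmetic mean", {
  wn <- 1:50
  mk <- function(v, pid = "p") raman_spectrum(wn, v, meta = list(plant_id = pid))
  s <- mk(rnorm(50))
  expect_equal(average_measurements(list(s, s, s))$intensity, s$intensity)
  abc <- lapply(1:3, function(k) mk(rep(k, 50)))
  expect_equal(average_measurements(abc)$intensity, rep(2, 50))
  # mean of means equals grand mean for equal group sizes
  set.seed(9)
  six <- lapply(1:6, function(k) mk(rnorm(50)))
  g1 <- average_measurements(six[1:3])
  g2 <- average_measurements(six[4:6])
  expect_equal(average_measurements(list(g1, g2))$intensity,
               average_measurements(six)$intensity, tolerance = 1e-12)
  expect_error(average_measurements(list()), "no spectra")
  expect_error(average_measurements(list(s, raman_spectrum(2:51, rnorm(50),
                                                           meta = list(plant_id = "p")))),
               "alignment")
  expect_error(average_measurements(list(s, mk(rnorm(50), "q"))),
               "different plants")
})

test_that("cropping keeps the closed wavenumber window", {
  cfg <- synthetic_config()
  sp <- simulate_spectrum(list(plant_id = "p", set_label = "non_fixing",
                               nitrogen_mM = 2, bnf_percent = 0), cfg,
                          seed = 1)
  cr <- crop_spectrum(sp, c(600, 1770))
  expect_length(cr$wavenumber, 1097)
  expect_true(all(cr$wavenumber >= 600 - 1e-6 & cr$wavenumber <= 1770 + 1e-6))
  full <- crop_spectrum(sp, range(sp$wavenumber))
  expect_identical(full$intensity, sp$intensity)
  expect_error(crop_spectrum(sp, c(3000, 4000)), "no grid points")
})

test_that("the preprocessing pipeline returns one corrected spectrum per plant", {
  cfg <- tiny_config(seed = 11)
  d <- generate_dataset(cfg)
  ps <- preprocess_pipeline(d$spectra, preprocess_config(), d$truth)
  expect_s3_class(ps, "plant_samples")
  expect_equal(nrow(ps$intensities), nrow(d$truth))
  expect_setequal(rownames(ps$intensities), d$truth$plant_id)
  expect_true(all(ps$info$n_measurements == cfg$measurements_per_plant))
  expect_true(all(ps$wavenumber >= 600 & ps$wavenumber <= 1770))
  # ground truth joined
  expect_equal(ps$info$bnf_percent,
               d$truth$bnf_percent[match(ps$info$plant_id,
                                         d$truth$plant_id)])
  # plants in truth but absent from the spectra are an error
  truth_bad <- rbind(d$truth,
                     data.frame(plant_id = "ghost", set_label = "fixing",
                                nitrogen_mM = 2, replicate = 9,
                                bnf_percent = 50))
  expect_error(preprocess_pipeline(d$spectra, preprocess_config(),
                                   truth_bad), "ghost")
})

test_that("a background-free noiseless dataset passes through almost unchanged", {
  cfg <- noiseless_config(seed = 1)
  cfg$fluorescence_params <- list(amplitude = 0, center = 1200, width = 500,
                                  ramp_high = 0, ramp_low = 0, jitter = 0)
  d <- generate_dataset(cfg)
  ps <- preprocess_pipeline(d$spectra, preprocess_config(), d$truth)
  # compare corrected intensities at band centres against the analytic sum
  bands <- cfg$band_library
  for (p in seq_len(nrow(ps$intensities))) {
    info <- ps$info[p, ]
    status <- if (info$set_label == "non_fixing") info$nitrogen_mM else
      cfg$fixing_saturation_mM
    amps <- bands$base_amplitude *
      ifelse(bands$role == "bnf_linked",
             1 + cfg$bnf_effect_size * info$bnf_percent,
             1 + cfg$nitrogen_effect_size * status)
    truth_bands <- bands
    truth_bands$base_amplitude <- amps
    expected <- band_sum(ps$wavenumber, truth_bands)
    idx <- match(bands$center, ps$wavenumber)
    # combined smoothing + baseline distortion stays under 5% at centres
    expect_equal(ps$intensities[p, idx], expected[idx],
                 tolerance = 0.05, ignore_attr = TRUE)
  }
})
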