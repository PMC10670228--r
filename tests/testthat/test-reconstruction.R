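# k-linearization, A-scan/B-scan reconstruction and closed-form system
# parameters.

test_that("an already-uniform-in-k grid maps to the identity", {
  n <- 256
  k <- seq(2 * pi / 760, 2 * pi / 920, length.out = n)   # uniform in k
  lambda <- 2 * pi / k                                   # increasing
  map <- build_calibration_map(lambda)
  expect_equal(map$resampling_indices, seq_len(n), tolerance = 1e-9)
})

test_that("a uniform-in-wavelength grid needs increasingly wide resampling steps", {
  map <- small_map()
  spacing <- diff(map$resampling_indices)
  expect_true(all(diff(spacing) > 0))   # curvature of k = 2*pi/lambda
  expect_true(all(spacing > 0))
  # no extrapolation: indices stay inside the source grid
  expect_gte(min(map$resampling_indices), 1)
  expect_lte(max(map$resampling_indices), length(map$source_wavelength_grid))
  # target grid strictly uniform in k
  expect_lt(diff(range(diff(map$target_wavenumber_grid))), 1e-15)
})

test_that("calibration rejects invalid wavelength grids", {
  expect_error(build_calibration_map(seq(900, 760, length.out = 64)),
               "increasing")
  expect_error(build_calibration_map(c(760, 780, 770, 800, 820, 840, 860, 880)),
               "monotonic")
  expect_error(build_calibration_map(1:4), "8 samples")
})

test_that("a single reflector reconstructs at its physical depth", {
  src <- paper_source()
  g <- scan_geometry(lines_per_bscan = 1)
  map <- build_calibration_map(src$wavelength_grid)
  ph <- single_reflector_phantom(0.2, 0.3, g)
  fr <- simulate_interferogram(ph, src, g)
  ref <- simulate_interferogram(empty_phantom(g), src, g)
  a <- reconstruct_ascan(fr$samples[, 1], map, window = "hann",
                         dc = ref$samples[, 1])
  expect_true(all(a$magnitude >= 0))
  peak_um <- ascan_depths(a)[which.max(a$magnitude)]
  expect_lt(abs(peak_um - 200), a$depth_pitch)

  # a reflector-free line reconstructs to numerical residue only
  a0 <- reconstruct_ascan(ref$samples[, 1], map, window = "hann",
                          dc = ref$samples[, 1])
  expect_lt(max(a0$magnitude), 0.01 * max(a$magnitude))

  expect_error(reconstruct_ascan(fr$samples[1:100, 1], map), "length")
})

test_that("round trip recovers reflector depths across the usable range", {
  src <- small_source()
  g <- scan_geometry(lines_per_bscan = 1, depth_range = 0.4)
  map <- build_calibration_map(src$wavelength_grid)
  ref <- simulate_interferogram(empty_phantom(g), src, g)$samples[, 1]
  for (z in seq(0.04, 0.36, by = 0.04)) {           # 10%..90% of range
    fr <- simulate_interferogram(single_reflector_phantom(z, 0.3, g), src, g)
    a <- reconstruct_ascan(fr$samples[, 1], map, window = "hann", dc = ref)
    peak_um <- ascan_depths(a)[which.max(a$magnitude)]
    expect_lt(abs(peak_um - z * 1000), a$depth_pitch)
  }
})

test_that("adding a reflector never decreases total A-scan energy", {
  src <- small_source()
  g <- scan_geometry(lines_per_bscan = 1, depth_range = 0.5)
  map <- build_calibration_map(src$wavelength_grid)
  ref <- simulate_interferogram(empty_phantom(g), src, g)$samples[, 1]
  ph1 <- single_reflector_phantom(0.12, 0.2, g)
  ph2 <- ph1
  ph2$scatterers <- rbind(ph2$scatterers,
                          data.frame(depth = 0.33, lateral_cell = 1L,
                                     reflectivity = 0.25, phase = 0))
  energy <- function(ph) {
    fr <- simulate_interferogram(ph, src, g)
    sum(reconstruct_ascan(fr$samples[, 1], map, dc = ref)$magnitude^2)
  }
  expect_gte(energy(ph2), energy(ph1))
})

test_that("apodization lowers the far sidelobe level", {
  src <- small_source()
  g <- scan_geometry(lines_per_bscan = 1, depth_range = 0.4)
  map <- build_calibration_map(src$wavelength_grid)
  ref <- simulate_interferogram(empty_phantom(g), src, g)$samples[, 1]
  fr <- simulate_interferogram(single_reflector_phantom(0.2, 0.3, g), src, g)
  sidelobe <- function(window) {
    a <- reconstruct_ascan(fr$samples[, 1], map, window = window, dc = ref)
    d <- ascan_depths(a)
    pk <- which.max(a$magnitude)
    away <- abs(d - d[pk]) > 25          # um, well outside the main lobe
    max(a$magnitude[away]) / a$magnitude[pk]
  }
  expect_lt(sidelobe("hann"), sidelobe("none"))
})

test_that("B-scan reconstruction is column-deterministic and 0 dB referenced", {
  src <- small_source()
  g <- scan_geometry(lines_per_bscan = 8, depth_range = 0.4)
  map <- build_calibration_map(src$wavelength_grid)
  fr <- simulate_interferogram(single_reflector_phantom(0.2, 0.3, g), src, g)
  # identical lines (flat reflector) -> identical columns, max of 0 dB
  b <- reconstruct_bscan(fr, map, dc = "none")
  expect_equal(max(b$image), 0)
  expect_true(all(apply(b$image, 1, function(r) diff(range(r)) == 0)))
  expect_error(reconstruct_bscan(
    structure(list(samples = matrix(numeric(0), 0, 0)),
              class = "oct_spectral_frame"), map), "empty")
})

test_that("a tilted reflector reconstructs with the phantom's tilt", {
  src <- small_source()
  g <- scan_geometry(lines_per_bscan = 64, depth_range = 0.5)
  map <- build_calibration_map(src$wavelength_grid)
  tilt <- 0.12   # mm across the full width
  ph <- single_reflector_phantom(0.25, 0.3, g, tilt = tilt)
  fr <- simulate_interferogram(ph, src, g)
  b <- reconstruct_bscan(fr, map, dc = "mean")
  peaks_um <- apply(b$image, 2, which.max) * b$depth_pitch
  fit <- stats::lm(peaks_um ~ seq_along(peaks_um))
  fitted_tilt_mm <- unname(coef(fit)[2]) * ncol(b$image) / 1000
  expect_equal(fitted_tilt_mm, tilt, tolerance = 0.05)
})

test_that("the point-spread function matches the coherence-length prediction", {
  # same physics at 512 pixels as the full-resolution acceptance check
  src <- small_source()
  f <- psf_fwhm(src, scan_geometry(depth_range = 0.5), depth = 0.25)
  expect_equal(f, axial_resolution(840, 51.2), tolerance = 0.03)
})

test_that("axial resolution follows the Gaussian coherence-length closed form", {
  expect_equal(axial_resolution(840, 102.4),
               axial_resolution(840, 51.2) / 2, tolerance = 1e-12)
  # independent evaluation of the closed form for a 1300 nm source
  expect_equal(axial_resolution(1300, 100), 0.44 * 1300^2 / 100 / 1000,
               tolerance = 1e-12)
  expect_equal(axial_resolution(1300, 100, prefactor = 2 * log(2) / pi),
               2 * log(2) / pi * 1300^2 / 100 / 1000, tolerance = 1e-12)
  expect_error(axial_resolution(840, 0), "positive")
})

test_that("sensitivity is the dB sum of SNR and ND attenuation", {
  expect_equal(sensitivity_from_snr(33.5, 20), 53.5)
  expect_equal(sensitivity_from_snr(17, 0), 17)
  expect_error(sensitivity_from_snr(NA, 10), "number")
})

test_that("scan timing arithmetic covers degenerate and scaled cases", {
  st <- scan_timing(10000, 500, 0.05)
  expect_equal(st$bscan_duration, 0.05)
  expect_equal(st$volume_duration, 20)
  expect_equal(st$bscans_per_volume, 400L)
  st1 <- scan_timing(1234, 1234, 1)
  expect_equal(st1$bscan_duration, 1)
  expect_equal(st1$bscans_per_volume, 1L)
  expect_error(scan_timing(0, 100, 1), "positive")
})
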