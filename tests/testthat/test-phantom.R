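# Synthetic source, phantoms, spectral forward model and dataset plumbing.

test_that("source envelope peaks at the centre wavelength with the stated FWHM", {
  src <- paper_source()
  expect_equal(src$wavelength_grid[which.max(src$power_envelope)], 840,
               tolerance = 1e-6)
  step <- diff(src$wavelength_grid[1:2])
  expect_lt(abs(measure_fwhm(src$wavelength_grid, src$power_envelope) - 51.2),
            step)
  # half-maximum value at centre +/- FWHM/2 (interpolated off-grid)
  half_pt <- approx(src$wavelength_grid, src$power_envelope,
                    xout = 840 + 51.2 / 2)$y
  expect_equal(half_pt, max(src$power_envelope) / 2, tolerance = 1e-4)
  expect_true(all(src$power_envelope >= 0))
})

test_that("half-maximum separation tracks the requested bandwidth on other sources", {
  src <- make_source_spectrum(1300, 100, 1024)
  step <- diff(src$wavelength_grid[1:2])
  expect_lt(abs(measure_fwhm(src$wavelength_grid, src$power_envelope) - 100),
            step)
})

test_that("source construction validates its inputs", {
  expect_error(make_source_spectrum(-840, 51.2), "positive")
  expect_error(make_source_spectrum(840, 0), "positive")
  expect_error(make_source_spectrum(840, 900), "smaller")
  expect_error(make_source_spectrum(840, Inf), "finite")
})

test_that("phantom generation is a pure function of its seed", {
  a <- generate_phantom("IA", small_geometry(), seed = 1)
  b <- generate_phantom("IA", small_geometry(), seed = 1)
  expect_identical(a$scatterers, b$scatterers)
  expect_identical(a$mu, b$mu)
  c <- generate_phantom("IA", small_geometry(), seed = 2)
  expect_false(identical(a$scatterers, c$scatterers))
})

test_that("phantom textures realize their class motifs", {
  g <- small_geometry()
  nor <- generate_phantom("NOR", g, seed = 1)
  expect_gt(nrow(nor$spots), 0)
  expect_gte(mean(nor$spots$depth <= 0.25 * g$depth_range), 0.95)

  # MIA attenuation is laterally smooth; IA is interrupted
  ia <- generate_phantom("IA", g, seed = 2)
  mia <- generate_phantom("MIA", g, seed = 2)
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(mia$mu), cv(ia$mu))
  expect_gt(max(abs(diff(ia$mu))), 0.5)       # at least one hard jump
  expect_lt(max(abs(diff(mia$mu))), 0.1)      # no jump anywhere

  expect_error(generate_phantom("XXX", g), "class label")
})

test_that("phantom invariants hold across classes and seeds", {
  g <- small_geometry()
  for (cl in grade_levels()) {
    for (seed in 1:3) {
      ph <- generate_phantom(cl, g, seed = seed)
      expect_true(all(ph$scatterers$depth >= 0 &
                        ph$scatterers$depth <= g$depth_range))
      expect_true(all(ph$scatterers$reflectivity > 0 &
                        ph$scatterers$reflectivity <= 1))
    }
  }
})

test_that("empty-phantom interferogram is proportional to the source envelope", {
  src <- small_source()
  g <- small_geometry()
  fr <- simulate_interferogram(empty_phantom(g), src, g)
  ratio <- fr$samples / src$power_envelope
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
})

test_that("spectral forward model is linear in the reflector set", {
  src <- small_source()
  g <- scan_geometry(lines_per_bscan = 4, depth_range = 0.5)
  p1 <- single_reflector_phantom(0.12, 0.3, g)
  p2 <- single_reflector_phantom(0.31, 0.2, g)
  union <- p1
  union$scatterers <- rbind(p1$scatterers, p2$scatterers)
  f1 <- simulate_interferogram(p1, src, g)$samples
  f2 <- simulate_interferogram(p2, src, g)$samples
  f0 <- simulate_interferogram(empty_phantom(g), src, g)$samples
  fu <- simulate_interferogram(union, src, g)$samples
  # union frame = sum of individual fringe terms plus a single source term
  expect_equal(fu, f1 + f2 - f0, tolerance = 1e-9)
})

test_that("fringe period in k equals pi over the reflector depth", {
  src <- small_source()
  g <- scan_geometry(lines_per_bscan = 1, depth_range = 0.5)
  z_mm <- 0.3
  ph <- single_reflector_phantom(z_mm, 0.3, g)
  fr <- simulate_interferogram(ph, src, g)
  ref <- simulate_interferogram(empty_phantom(g), src, g)
  map <- build_calibration_map(src$wavelength_grid)
  line <- fr$samples[, 1] - ref$samples[, 1]
  resampled <- spline(seq_along(line), line,
                      xout = map$resampling_indices)$y / src$power_envelope
  crossings <- sum(diff(sign(resampled)) != 0)
  dk_total <- abs(diff(range(map$target_wavenumber_grid)))
  expected_crossings <- 2 * dk_total / (pi / (z_mm * 1e6))
  expect_equal(crossings, expected_crossings, tolerance = 0.02)
})

test_that("depths beyond the unambiguous range are rejected", {
  src <- small_source()   # 512 px -> shallow unambiguous depth
  g <- scan_geometry(lines_per_bscan = 1)
  ph <- single_reflector_phantom(1.2, 0.3, g)
  expect_error(simulate_interferogram(ph, src, g), "unambiguous")
})

test_that("interferogram noise has the requested variance", {
  src <- make_source_spectrum(n_pixels = 128)
  g <- scan_geometry(lines_per_bscan = 2, depth_range = 0.2)
  ph <- single_reflector_phantom(0.05, 0.3, g)
  clean <- simulate_interferogram(ph, src, g, noise_std = 0)$samples
  sd_target <- 0.8
  withr::with_seed(42, {
    resid <- replicate(200, {
      noisy <- simulate_interferogram(ph, src, g, noise_std = sd_target)$samples
      noisy - clean
    })
  })
  expect_equal(var(as.numeric(resid)), sd_target^2, tolerance = 0.1)
  expect_identical(simulate_interferogram(ph, src, g)$samples, clean)
})

test_that("rendered B-scans separate the classes with two linear features", {
  skip_if_not_installed("MASS")
  g <- small_geometry()
  n_per <- 20
  feats <- NULL; labels <- character(0)
  for (cl in grade_levels()) {
    for (i in seq_len(n_per)) {
      ph <- generate_phantom(cl, g, seed = 500 + i)
      b <- render_bscan(ph, n_depth = 64, n_width = 110, seed = 900 + i)
      feats <- rbind(feats, phantom_features(b))
      labels <- c(labels, cl)
    }
  }
  fit <- MASS::lda(feats, grouping = factor(labels))
  acc <- mean(predict(fit, feats)$class == labels)
  expect_gt(acc, 0.9)
})

test_that("dataset generation writes a patient-disjoint, reproducible manifest", {
  g <- small_geometry()
  dir1 <- withr::local_tempdir()
  man <- generate_dataset(2, g, file.path(dir1, "a"), seed = 7,
                          frames_per_volume = 2, dim = c(32L, 54L))
  expect_equal(nrow(man), 6)
  expect_equal(length(list.files(file.path(dir1, "a", "volumes"),
                                 pattern = "\\.rds$")), 6)
  generate_dataset(2, g, file.path(dir1, "b"), seed = 7,
                   frames_per_volume = 2, dim = c(32L, 54L))
  expect_identical(readBin(file.path(dir1, "a", "manifest.csv"), "raw", 1e5),
                   readBin(file.path(dir1, "b", "manifest.csv"), "raw", 1e5))
  expect_error(
    generate_dataset(2, g, file.path(dir1, "a"), seed = 7,
                     frames_per_volume = 2, dim = c(32L, 54L)),
    "overwrite")

  man4 <- generate_dataset(4, g, file.path(dir1, "c"), seed = 3,
                           frames_per_volume = 1, train_frac = 0.75,
                           dim = c(32L, 54L))
  expect_silent(assert_patient_disjoint(man4$patient_id, man4$split))
  expect_setequal(unique(man4$split), c("train", "test"))
})
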