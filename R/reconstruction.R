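# Spectral-domain reconstruction: k-linearization, DC removal, apodization,
# FFT, log compression, plus the closed-form system parameters.

#' Build a k-linearization calibration map
#'
#' Spectrometer pixels sample uniformly in wavelength; the FFT needs samples
#' uniform in wavenumber `k = 2*pi/lambda`. The map holds the target uniform
#' k grid (same length and orientation as the source grid, so an
#' already-uniform-in-k input maps to the identity) and the fractional
#' source-pixel positions each target sample interpolates from.
#'
#' @param wavelength_grid Strictly monotonic wavelength grid in nm.
#' @return Object of class `oct_calibration` with `source_wavelength_grid`,
#'   `source_wavenumber_grid`, `target_wavenumber_grid` (strictly uniform)
#'   and `resampling_indices` (monotone fractional indices, no
#'   extrapolation).
#' @export
#' @examples
#' m <- build_calibration_map(make_source_spectrum(n_pixels = 256)$wavelength_grid)
#' head(m$resampling_indices)
build_calibration_map <- function(wavelength_grid) {
  if (!is.numeric(wavelength_grid) || length(wavelength_grid) < 8) {
    oct_abort("`wavelength_grid` must be a numeric vector (>= 8 samples)")
  }
  d <- diff(wavelength_grid)
  if (!(all(d > 0) || all(d < 0))) {
    oct_abort("`wavelength_grid` must be strictly monotonic")
  }
  if (any(d < 0)) {
    oct_abort("`wavelength_grid` must be increasing (camera pixel order)")
  }
  n <- length(wavelength_grid)
  k_src <- 2 * pi / wavelength_grid             # strictly decreasing
  k_tgt <- seq(k_src[1], k_src[n], length.out = n)
  idx <- approx(x = rev(k_src), y = rev(seq_len(n)), xout = rev(k_tgt))$y
  idx <- rev(idx)
  structure(
    list(source_wavelength_grid = wavelength_grid,
         source_wavenumber_grid = k_src,
         target_wavenumber_grid = k_tgt,
         resampling_indices = idx),
    class = "oct_calibration"
  )
}

apodization_window <- function(n, kind = c("hann", "hamming", "none")) {
  kind <- match.arg(kind)
  switch(kind,
         hann = signal::hanning(n),
         hamming = signal::hamming(n),
         none = rep(1, n))
}

#' Reconstruct a single A-scan from one spectral line
#'
#' Applies the standard SD-OCT inverse: cubic resampling onto the uniform-k
#' grid of the calibration map, DC (background spectrum) subtraction,
#' apodization, FFT and one-sided magnitude. The depth pitch follows from
#' the total resampled wavenumber span: `dz = pi / (N * dk)` (in air).
#'
#' @param line Numeric vector of detector counts (length matching the map).
#' @param map An [build_calibration_map()] object.
#' @param window Apodization window: `"hann"` (default), `"hamming"` or
#'   `"none"` (keeps the source's own Gaussian envelope as apodization, the
#'   right choice for point-spread-function measurements).
#' @param dc Optional background spectrum (same length, source sampling) to
#'   subtract; `NULL` subtracts nothing.
#' @param zero_pad Integer zero-padding factor (>= 1) for finer depth
#'   sampling of the transform.
#' @return Object of class `oct_ascan`: `magnitude` (non-negative, length
#'   `zero_pad * n / 2`), `depth_pitch` (um per sample, in air).
#' @export
reconstruct_ascan <- function(line, map, window = "hann", dc = NULL,
                              zero_pad = 1L) {
  stopifnot(inherits(map, "oct_calibration"))
  n <- length(map$source_wavelength_grid)
  if (!is.numeric(line) || length(line) != n) {
    oct_abort("`line` length must match the calibration map")
  }
  if (!is.null(dc)) {
    if (length(dc) != n) oct_abort("`dc` length must match the calibration map")
    line <- line - dc
  }
  zero_pad <- check_count(zero_pad, "zero_pad")
  # cubic resampling at the fractional source-pixel positions
  resampled <- spline(x = seq_len(n), y = line,
                      xout = map$resampling_indices, method = "fmm")$y
  w <- apodization_window(n, window)
  apodized <- resampled * w
  padded <- c(apodized, rep(0, (zero_pad - 1L) * n))
  spec <- fft(padded)
  m <- floor(length(padded) / 2)
  magnitude <- Mod(spec)[seq_len(m)]
  dk <- abs(diff(map$target_wavenumber_grid[1:2]))
  depth_pitch_um <- pi / (length(padded) * dk) * 1e-3   # k in 1/nm -> um
  structure(
    list(magnitude = magnitude, depth_pitch = depth_pitch_um,
         zero_pad = zero_pad, window = window),
    class = "oct_ascan"
  )
}

#' Depth axis of an A-scan
#' @param ascan An `oct_ascan`.
#' @return Depths in um (in air), one per magnitude sample.
#' @export
ascan_depths <- function(ascan) {
  (seq_along(ascan$magnitude) - 1) * ascan$depth_pitch
}

#' Reconstruct a B-scan from a spectral frame
#'
#' Column-wise [reconstruct_ascan()] followed by log compression referenced
#' to the frame maximum (0 dB) with a floor at `db_floor`. By default the
#' background spectrum subtracted from every line is the mean line of the
#' frame (the usual SD-OCT DC estimate).
#'
#' @param frame An `oct_spectral_frame`.
#' @param map An [build_calibration_map()] object.
#' @param window Apodization window, see [reconstruct_ascan()].
#' @param dc `"mean"` (default; subtract the frame-average spectrum),
#'   `"none"`, or a numeric background spectrum.
#' @param db_floor Log floor in dB (default -60).
#' @param depth_crop Optional depth crop in mm (e.g. 1.4) applied to the top
#'   of the image before return.
#' @param lateral_range Lateral scan range in mm used to set the lateral
#'   pitch (default `NA`).
#' @param volume_id,frame_index Provenance, stored on the B-scan.
#' @return An [new_bscan()] object.
#' @export
reconstruct_bscan <- function(frame, map, window = "hann", dc = "mean",
                              db_floor = -60, depth_crop = NULL,
                              lateral_range = NA_real_,
                              volume_id = NA_character_,
                              frame_index = NA_integer_) {
  stopifnot(inherits(frame, "oct_spectral_frame"),
            inherits(map, "oct_calibration"))
  samples <- frame$samples
  if (length(samples) == 0 || ncol(samples) == 0) {
    oct_abort("empty spectral frame")
  }
  dc_vec <- if (is.character(dc)) {
    switch(match.arg(dc, c("mean", "none")),
           mean = rowMeans(samples),
           none = NULL)
  } else dc
  cols <- lapply(seq_len(ncol(samples)), function(j) {
    reconstruct_ascan(samples[, j], map, window = window, dc = dc_vec)
  })
  mag <- vapply(cols, `[[`, numeric(length(cols[[1]]$magnitude)), "magnitude")
  depth_pitch <- cols[[1]]$depth_pitch
  if (!is.null(depth_crop)) {
    keep <- ascan_depths(cols[[1]]) <= depth_crop * 1000
    mag <- mag[keep, , drop = FALSE]
  }
  peak <- max(mag)
  if (peak <= 0) peak <- 1
  img <- 20 * log10(pmax(mag / peak, 10^(db_floor / 20)))
  lat_pitch <- if (is.na(lateral_range)) NA_real_ else lateral_range * 1000 / ncol(img)
  b <- new_bscan(img, depth_pitch = depth_pitch,
                 lateral_pitch = if (is.na(lat_pitch)) depth_pitch else lat_pitch,
                 volume_id = volume_id, frame_index = frame_index)
  b$lateral_pitch <- lat_pitch
  b
}

#' Theoretical axial resolution of a Gaussian source
#'
#' Gaussian coherence-length formula `prefactor * lambda_c^2 / d_lambda`.
#' The default prefactor 0.44 is the rounded constant conventionally used to
#' quote OCT axial resolution; the exact Gaussian value is
#' `2 * log(2) / pi` (about 0.4413) and can be passed instead. For the
#' default 840 nm / 51.2 nm source the conventional constant gives 6.06 um
#' in air.
#'
#' @param center_wavelength Centre wavelength in nm.
#' @param fwhm_bandwidth Source power FWHM in nm.
#' @param prefactor Coherence-length prefactor (default 0.44).
#' @return Axial resolution in um (in air).
#' @export
#' @examples
#' axial_resolution(840, 51.2)
axial_resolution <- function(center_wavelength, fwhm_bandwidth,
                             prefactor = 0.44) {
  check_number(center_wavelength, "center_wavelength")
  check_number(fwhm_bandwidth, "fwhm_bandwidth")
  check_number(prefactor, "prefactor")
  prefactor * center_wavelength^2 / fwhm_bandwidth * 1e-3
}

#' System sensitivity from an attenuated SNR measurement
#'
#' With a calibrated neutral-density filter of round-trip attenuation
#' `nd_attenuation_db` in front of a mirror, the sensitivity is the measured
#' SNR plus the attenuation (both in dB).
#'
#' @param measured_snr_db Measured signal-to-noise ratio in dB.
#' @param nd_attenuation_db ND-filter attenuation in dB.
#' @return Sensitivity in dB.
#' @export
#' @examples
#' sensitivity_from_snr(40, 50)  # 90
sensitivity_from_snr <- function(measured_snr_db, nd_attenuation_db) {
  check_number(measured_snr_db, "measured_snr_db", positive = FALSE)
  check_number(nd_attenuation_db, "nd_attenuation_db", positive = FALSE)
  measured_snr_db + nd_attenuation_db
}

#' Scan timing arithmetic
#'
#' B-scan duration = lines / A-line rate; volume duration = one slow-axis
#' period; B-scans per volume = their rounded ratio.
#'
#' @param aline_rate A-line rate in Hz.
#' @param lines_per_bscan A-lines per B-scan.
#' @param slow_axis_freq Slow-axis frequency in Hz.
#' @return Object of class `oct_scan_timing`: `bscan_duration` (s),
#'   `volume_duration` (s), `bscans_per_volume`.
#' @export
#' @examples
#' scan_timing(20000, 2000, 0.025)  # 0.1 s, 40 s, 400
scan_timing <- function(aline_rate, lines_per_bscan, slow_axis_freq) {
  check_number(aline_rate, "aline_rate")
  lines_per_bscan <- check_count(lines_per_bscan, "lines_per_bscan")
  check_number(slow_axis_freq, "slow_axis_freq")
  bd <- lines_per_bscan / aline_rate
  vd <- 1 / slow_axis_freq
  structure(
    list(bscan_duration = bd,
         volume_duration = vd,
         bscans_per_volume = as.integer(round(vd / bd))),
    class = "oct_scan_timing"
  )
}

#' @export
print.oct_scan_timing <- function(x, ...) {
  cat(sprintf("<oct_scan_timing> %.4g s/B-scan, %.4g s/volume, %d B-scans/volume\n",
              x$bscan_duration, x$volume_duration, x$bscans_per_volume))
  invisible(x)
}

#' Measure the reconstructed point-spread function FWHM
#'
#' Simulates a noise-free interferogram of a single reflector, reconstructs
#' it without extra apodization (the Gaussian source envelope is the natural
#' window), zero-pads the transform for fine depth sampling and measures the
#' magnitude peak's full width at half maximum in um via [measure_fwhm()].
#'
#' @param source An [make_source_spectrum()] object.
#' @param depth Reflector depth in mm (default mid-depth of the geometry).
#' @param geometry Scan geometry (a single line is simulated).
#' @param zero_pad Zero-padding factor (default 8).
#' @return FWHM of the point-spread function in um (in air).
#' @export
psf_fwhm <- function(source = make_source_spectrum(),
                     geometry = scan_geometry(),
                     depth = geometry$depth_range / 2,
                     zero_pad = 8L) {
  g1 <- scan_geometry(aline_rate = geometry$aline_rate,
                      lines_per_bscan = 1L,
                      slow_axis_freq = geometry$slow_axis_freq,
                      lateral_range = geometry$lateral_range,
                      depth_range = geometry$depth_range)
  ph <- single_reflector_phantom(depth, reflectivity = 0.2, geometry = g1)
  frame <- simulate_interferogram(ph, source, g1, noise_std = 0)
  ref <- simulate_interferogram(empty_phantom(g1), source, g1, noise_std = 0)
  map <- build_calibration_map(source$wavelength_grid)
  a <- reconstruct_ascan(frame$samples[, 1], map, window = "none",
                         dc = ref$samples[, 1], zero_pad = zero_pad)
  depths <- ascan_depths(a)
  # restrict to a window around the expected peak, away from residual DC
  keep <- depths > depth * 1000 * 0.5 & depths < depth * 1000 * 1.5
  measure_fwhm(depths[keep], a$magnitude[keep])
}
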