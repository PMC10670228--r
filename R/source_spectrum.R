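#' Gaussian broadband source spectrum on a spectrometer pixel grid
#'
#' Models the power envelope of a superluminescent-diode source as sampled by
#' a line-scan spectrometer: a Gaussian power spectral density centred at
#' `center_wavelength` with the stated full width at half maximum, evaluated
#' on a uniform wavelength grid. The grid is uniform in wavelength (not
#' wavenumber), which is what makes k-linearization a real step downstream.
#'
#' The grid spans `span_factor * fwhm_bandwidth` (default 3.2x), wide enough
#' to contain the envelope tails while keeping the post-FFT depth range above
#' 1.4 mm for the default 840 nm / 51.2 nm source on 2048 pixels.
#'
#' @param center_wavelength Centre wavelength in nm (default 840).
#' @param fwhm_bandwidth Full width at half maximum of the power envelope in
#'   nm (default 51.2).
#' @param n_pixels Number of spectrometer pixels (default 2048).
#' @param span_factor Width of the wavelength grid in units of the FWHM
#'   (default 3.2, must be >= 3).
#' @return An object of class `oct_source` with fields `center_wavelength`,
#'   `fwhm_bandwidth`, `n_pixels`, `wavelength_grid` (nm) and
#'   `power_envelope` (unit peak).
#' @export
#' @examples
#' src <- make_source_spectrum(840, 51.2, 2048)
#' src$wavelength_grid[which.max(src$power_envelope)]  # 840
make_source_spectrum <- function(center_wavelength = 840,
                                 fwhm_bandwidth = 51.2,
                                 n_pixels = 2048,
                                 span_factor = 3.2) {
  check_number(center_wavelength, "center_wavelength")
  check_number(fwhm_bandwidth, "fwhm_bandwidth")
  n_pixels <- check_count(n_pixels, "n_pixels", min = 16L)
  check_number(span_factor, "span_factor")
  if (fwhm_bandwidth >= center_wavelength) {
    oct_abort("`fwhm_bandwidth` must be smaller than `center_wavelength`")
  }
  if (span_factor < 3) {
    oct_abort("`span_factor` must be at least 3 so the envelope tails fit")
  }
  span <- span_factor * fwhm_bandwidth
  # align the pixel grid so the centre wavelength falls exactly on a sample
  step <- span / (n_pixels - 1)
  grid <- center_wavelength + (seq_len(n_pixels) - 1L - floor(n_pixels / 2)) * step
  envelope <- exp(-4 * log(2) * ((grid - center_wavelength) / fwhm_bandwidth)^2)
  structure(
    list(center_wavelength = center_wavelength,
         fwhm_bandwidth = fwhm_bandwidth,
         n_pixels = n_pixels,
         wavelength_grid = grid,
         power_envelope = envelope),
    class = "oct_source"
  )
}

#' @export
print.oct_source <- function(x, ...) {
  cat(sprintf("<oct_source> %g nm centre, %g nm FWHM, %d pixels (%.1f-%.1f nm)\n",
              x$center_wavelength, x$fwhm_bandwidth, x$n_pixels,
              min(x$wavelength_grid), max(x$wavelength_grid)))
  invisible(x)
}

#' Raster scan geometry of the OCT system
#'
#' Bundles the scanning parameters: A-line (depth profile) rate, lines per
#' B-scan, slow-axis galvanometer frequency and the physical field of view.
#' Defaults reproduce a 20 kHz system acquiring 2000-line B-scans over a
#' 2.4 mm x 2.4 mm area with a 0.025 Hz slow axis, i.e. 400 B-scans per
#' 40 s volume.
#'
#' @param aline_rate A-line rate in Hz (default 20000).
#' @param lines_per_bscan A-lines per B-scan (default 2000).
#' @param slow_axis_freq Slow-axis scan frequency in Hz (default 0.025).
#' @param lateral_range Lateral scan range in mm (default 2.4).
#' @param depth_range Imaging depth kept after reconstruction, mm (default 1.4).
#' @return An object of class `oct_geometry`.
#' @export
#' @examples
#' scan_geometry()
scan_geometry <- function(aline_rate = 20000,
                          lines_per_bscan = 2000,
                          slow_axis_freq = 0.025,
                          lateral_range = 2.4,
                          depth_range = 1.4) {
  check_number(aline_rate, "aline_rate")
  lines_per_bscan <- check_count(lines_per_bscan, "lines_per_bscan")
  check_number(slow_axis_freq, "slow_axis_freq")
  check_number(lateral_range, "lateral_range")
  check_number(depth_range, "depth_range")
  structure(
    list(aline_rate = aline_rate,
         lines_per_bscan = lines_per_bscan,
         slow_axis_freq = slow_axis_freq,
         lateral_range = lateral_range,
         depth_range = depth_range),
    class = "oct_geometry"
  )
}

#' @export
print.oct_geometry <- function(x, ...) {
  cat(sprintf(
    "<oct_geometry> %g Hz A-line rate, %d lines/B-scan, %g Hz slow axis, %g x %g mm\n",
    x$aline_rate, x$lines_per_bscan, x$slow_axis_freq,
    x$lateral_range, x$depth_range))
  invisible(x)
}

#' Full width at half maximum of a sampled unimodal curve
#'
#' Locates the global peak of `y` and the two half-maximum crossings on
#' either side by linear interpolation between samples. Used to measure both
#' spectral bandwidths and reconstructed point-spread functions.
#'
#' @param x Ordinate (monotone increasing).
#' @param y Curve values, same length as `x`.
#' @return The width `x_right - x_left` between the half-maximum crossings.
#' @export
#' @examples
#' g <- seq(-5, 5, length.out = 1001)
#' measure_fwhm(g, exp(-4 * log(2) * g^2))  # ~1
measure_fwhm <- function(x, y) {
  if (length(x) != length(y) || length(x) < 5) {
    oct_abort("`x` and `y` must be equal-length vectors (>= 5 samples)")
  }
  ipk <- which.max(y)
  if (ipk == 1L || ipk == length(y)) {
    oct_abort("peak lies on the boundary; cannot measure FWHM")
  }
  half <- y[ipk] / 2
  cross <- function(idx_range, from_left) {
    yy <- y[idx_range]
    below <- which(yy < half)
    if (length(below) == 0) oct_abort("curve never falls below half maximum")
    if (from_left) {
      i <- max(below)                      # last sample below half, left side
      i0 <- idx_range[i]; i1 <- idx_range[i] + 1L
    } else {
      i <- min(below)                      # first sample below half, right side
      i0 <- idx_range[i] - 1L; i1 <- idx_range[i]
    }
    # linear interpolation between the bracketing samples
    x[i0] + (half - y[i0]) * (x[i1] - x[i0]) / (y[i1] - y[i0])
  }
  left <- cross(seq_len(ipk - 1L), from_left = TRUE)
  right <- cross(seq(ipk + 1L, length(y)), from_left = FALSE)
  right - left
}
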