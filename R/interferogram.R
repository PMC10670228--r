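#' Simulate a raw spectral interferogram frame
#'
#' Standard SD-OCT forward model for an unbalanced Michelson interferometer:
#' for every A-line the detected spectrum is
#' \deqn{I(k) = S(k)\,[R_{ref} + \sum_n R_n + \sum_n 2\sqrt{R_{ref} R_n}
#'   \cos(2 k z_n + \phi_n)] + \epsilon(k)}
#' with \eqn{k = 2\pi/\lambda}, per-scatterer effective reflectivities
#' \eqn{R_n} (phantom reflectivity attenuated by the round-trip Beer-Lambert
#' factor) and speckle phases \eqn{\phi_n} frozen in the phantom.
#' Scatterer-scatterer autocorrelation terms are neglected. The output is
#' linear in the reflector set and deterministic when `noise_std = 0`.
#'
#' @param phantom An `oct_phantom`.
#' @param source An [make_source_spectrum()] object.
#' @param geometry Scan geometry; defaults to the phantom's.
#' @param noise_std Standard deviation of additive detector noise (same
#'   arbitrary units as the source envelope).
#' @param r_ref Reference-arm reflectivity (default 1).
#' @return An object of class `oct_spectral_frame`: list with `samples`
#'   (`n_pixels` x `lines_per_bscan` matrix of non-negative detector counts)
#'   and `wavelength_grid` (nm).
#' @export
#' @examples
#' fr <- simulate_interferogram(single_reflector_phantom(0.2),
#'                              make_source_spectrum(n_pixels = 512),
#'                              scan_geometry(lines_per_bscan = 4))
#' dim(fr$samples)
simulate_interferogram <- function(phantom, source,
                                   geometry = phantom$geometry,
                                   noise_std = 0, r_ref = 1) {
  stopifnot(inherits(phantom, "oct_phantom"), inherits(source, "oct_source"))
  check_number(noise_std, "noise_std", positive = FALSE)
  if (noise_std < 0) oct_abort("`noise_std` must be >= 0")
  check_number(r_ref, "r_ref")

  k <- 2 * pi / source$wavelength_grid          # 1/nm, decreasing with lambda
  S <- source$power_envelope
  n_pix <- source$n_pixels
  lines <- geometry$lines_per_bscan

  # unambiguous-depth limit from the coarsest local k sampling
  dk_max <- max(abs(diff(k)))
  z_nyq_mm <- pi / (2 * dk_max) * 1e-6
  sc <- phantom$scatterers
  if (nrow(sc) > 0 && max(sc$depth) >= z_nyq_mm) {
    oct_abort(sprintf(
      "scatterer depth %.3f mm exceeds the unambiguous depth %.3f mm",
      max(sc$depth), z_nyq_mm))
  }

  # map acquisition lines onto phantom texture cells
  cell_of_line <- pmin(phantom$n_cells,
                       pmax(1L, ceiling(seq_len(lines) / lines * phantom$n_cells)))
  samples <- matrix(0, nrow = n_pix, ncol = lines)
  for (cell in unique(cell_of_line)) {
    idx <- sc$lateral_cell == cell
    if (any(idx)) {
      depth_below <- pmax(sc$depth[idx] - phantom$surface[cell], 0)
      r_eff <- sc$reflectivity[idx] * exp(-2 * phantom$mu[cell] * depth_below)
      z_nm <- sc$depth[idx] * 1e6
      fringe <- cos(outer(2 * k, z_nm) +
                      matrix(sc$phase[idx], n_pix, length(z_nm), byrow = TRUE))
      line <- S * (r_ref + sum(r_eff)) +
        S * as.numeric(fringe %*% (2 * sqrt(r_ref * r_eff)))
    } else {
      line <- S * r_ref
    }
    samples[, cell_of_line == cell] <- line
  }
  if (noise_std > 0) {
    samples <- samples + matrix(rnorm(length(samples), 0, noise_std),
                                nrow = n_pix)
  }
  structure(
    list(samples = samples, wavelength_grid = source$wavelength_grid),
    class = "oct_spectral_frame"
  )
}

#' @export
print.oct_spectral_frame <- function(x, ...) {
  cat(sprintf("<oct_spectral_frame> %d spectral pixels x %d lines\n",
              nrow(x$samples), ncol(x$samples)))
  invisible(x)
}
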