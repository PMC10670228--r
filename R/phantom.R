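# Tissue phantoms with class-specific textures.
#
# The three grades are told apart by texture motifs reported for lung OCT:
#   IA  - laterally interrupted attenuation with discontinuous reflection
#         (piecewise-constant attenuation/reflectivity segments with jumps),
#   MIA - formless, spatially homogeneous reflectivity,
#   NOR - dense bright spots confined to the superficial quartile of depth.
# Texture parameterization is this package's own construction; amplitudes are
# chosen so inter-class differences exceed the speckle noise by well over 3x
# in the two summary features computed by phantom_features().

# gaussian-smoothed standard normal noise, used for gentle lateral variation
smooth_noise <- function(n, width) {
  half <- max(3L, ceiling(3 * width))
  kern <- exp(-0.5 * (seq(-half, half) / width)^2)
  kern <- kern / sum(kern)
  raw <- rnorm(n + 2 * half)
  as.numeric(stats::filter(raw, kern, sides = 2))[(half + 1):(half + n)]
}

#' Default texture parameters for a tumour grade
#'
#' Returns the parameter list controlling the class-specific texture of a
#' [generate_phantom()] call. Attenuation coefficients are round-trip
#' single-sided values in 1/mm; reflectivities are relative (0, 1].
#'
#' @param class_label One of `"IA"`, `"MIA"`, `"NOR"`.
#' @return Named list of texture parameters.
#' @export
#' @examples
#' phantom_texture("NOR")$n_spots
phantom_texture <- function(class_label) {
  check_class_label(class_label)
  base <- list(
    surface_depth = 0.10,     # mm of air gap above the tissue surface
    surface_wobble = 0.015,   # mm, slow per-column wobble of the surface
    scatterers_per_line = 12, # discrete scatterers per A-line (spectral sim)
    refl_base = 0.40,
    mu_base = 1.5             # attenuation coefficient, 1/mm
  )
  extra <- switch(class_label,
    IA = list(
      n_boundaries = c(2L, 4L),  # range; actual count drawn per phantom
      mu_levels = c(0.9, 3.2),   # alternating attenuation levels
      refl_levels = c(0.65, 0.22),
      level_jitter = 0.06
    ),
    MIA = list(
      smooth_amplitude = 0.05,   # relative amplitude of the smooth variation
      smooth_width = 30          # lateral correlation width in cells
    ),
    NOR = list(
      n_spots = 30L,
      spot_radius = 0.02,        # mm
      spot_refl = 1.0,           # bright superficial spots at full reflectivity
      spot_depth_frac = 0.25,    # spots confined above this fraction of depth
      smooth_amplitude = 0.05,
      smooth_width = 30
    )
  )
  c(base, extra)
}

#' Generate a synthetic tissue phantom
#'
#' Builds a scatterer field with the texture motif of the requested grade:
#' per-column attenuation coefficients and reflectivity levels, superficial
#' bright spots (NOR), lateral attenuation discontinuities (IA) or smooth
#' homogeneity (MIA), plus the discrete scatterers (with speckle amplitudes
#' and phases) used by the spectral forward model. Deterministic for a fixed
#' seed.
#'
#' @param class_label `"IA"`, `"MIA"` or `"NOR"`.
#' @param geometry An [scan_geometry()] object.
#' @param texture_params Parameter list as returned by [phantom_texture()];
#'   defaults to the class defaults.
#' @param seed Integer seed; the phantom is a pure function of
#'   (arguments, seed).
#' @param n_cells Number of lateral texture cells (default 218).
#' @return An object of class `oct_phantom` with fields `class_label`,
#'   `geometry`, `mu` (per-cell attenuation, 1/mm), `refl` (per-cell
#'   reflectivity), `surface` (per-cell surface depth, mm), `spots`
#'   (data frame), `scatterers` (data frame with `depth`, `lateral_cell`,
#'   `reflectivity`, `phase`), `texture_params` and `seed`.
#' @export
#' @examples
#' ph <- generate_phantom("NOR", scan_geometry(), seed = 1)
#' range(ph$spots$depth)
generate_phantom <- function(class_label,
                             geometry = scan_geometry(),
                             texture_params = NULL,
                             seed = 1L,
                             n_cells = 218L) {
  check_class_label(class_label)
  stopifnot(inherits(geometry, "oct_geometry"))
  n_cells <- check_count(n_cells, "n_cells", min = 8L)
  tp <- texture_params %||% phantom_texture(class_label)
  depth_range <- geometry$depth_range

  with_seed(seed, {
    surface <- pmax(0.01, tp$surface_depth +
                      tp$surface_wobble * smooth_noise(n_cells, 40))
    spots <- data.frame(depth = numeric(0), lateral_cell = integer(0),
                        radius = numeric(0), reflectivity = numeric(0))

    if (class_label == "IA") {
      nb <- if (length(tp$n_boundaries) > 1) {
        sample(seq(tp$n_boundaries[1], tp$n_boundaries[2]), 1L)
      } else tp$n_boundaries
      # boundaries with a minimum segment width of ~8% of the scan
      repeat {
        bpos <- sort(sample(seq(10L, n_cells - 10L), nb))
        if (nb < 2L || min(diff(bpos)) >= ceiling(0.08 * n_cells)) break
      }
      seg <- findInterval(seq_len(n_cells), bpos) %% 2L + 1L
      jit <- function(v) v * (1 + tp$level_jitter * rnorm(1))
      mu_lv <- vapply(tp$mu_levels, jit, numeric(1))
      re_lv <- vapply(tp$refl_levels, jit, numeric(1))
      mu <- mu_lv[seg]
      refl <- re_lv[seg]
    } else {
      mu <- tp$mu_base * (1 + tp$smooth_amplitude * smooth_noise(n_cells, tp$smooth_width))
      refl <- tp$refl_base * (1 + tp$smooth_amplitude * smooth_noise(n_cells, tp$smooth_width))
    }
    mu <- pmax(mu, 0.05)
    refl <- pmin(pmax(refl, 0.02), 1)

    if (class_label == "NOR") {
      ns <- tp$n_spots
      zmax_spot <- tp$spot_depth_frac * depth_range - 2 * tp$spot_radius
      cells <- sample(seq_len(n_cells), ns, replace = TRUE)
      spots <- data.frame(
        depth = runif(ns, pmin(surface[cells] + 0.01, zmax_spot - 0.01), zmax_spot),
        lateral_cell = cells,
        radius = tp$spot_radius * runif(ns, 0.7, 1.4),
        reflectivity = tp$spot_refl * runif(ns, 0.8, 1.0)
      )
    }

    # discrete scatterers for the spectral forward model; speckle enters as a
    # per-scatterer complex-Gaussian amplitude (exponential intensity, uniform
    # phase), frozen into the phantom so noise-free simulation is deterministic
    per_line <- pmax(1L, rpois(n_cells, tp$scatterers_per_line))
    cell_id <- rep(seq_len(n_cells), per_line)
    nsc <- length(cell_id)
    sc <- data.frame(
      depth = runif(nsc, surface[cell_id] + 0.005, 0.95 * depth_range),
      lateral_cell = cell_id,
      reflectivity = pmin(pmax(refl[cell_id] * rexp(nsc) / 2, 1e-6), 1),
      phase = runif(nsc, 0, 2 * pi)
    )
    if (nrow(spots) > 0) {
      sp <- data.frame(
        depth = spots$depth,
        lateral_cell = spots$lateral_cell,
        reflectivity = pmin(spots$reflectivity, 1),
        phase = runif(nrow(spots), 0, 2 * pi)
      )
      sc <- rbind(sc, sp)
    }

    structure(
      list(class_label = class_label,
           geometry = geometry,
           n_cells = n_cells,
           mu = mu,
           refl = refl,
           surface = surface,
           spots = spots,
           scatterers = sc,
           texture_params = tp,
           seed = seed),
      class = "oct_phantom"
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.oct_phantom <- function(x, ...) {
  cat(sprintf("<oct_phantom> class %s, %d lateral cells, %d scatterers, %d spots (seed %s)\n",
              x$class_label, x$n_cells, nrow(x$scatterers), nrow(x$spots),
              as.character(x$seed)))
  invisible(x)
}

#' Single point-reflector phantom
#'
#' Calibration-style phantom holding one mirror-like reflector at a given
#' depth, used to measure the reconstructed point-spread function. No
#' attenuation, no speckle phase, no tissue surface.
#'
#' @param depth Reflector depth in mm.
#' @param reflectivity Reflectivity in (0, 1].
#' @param geometry An [scan_geometry()] object.
#' @param tilt Optional lateral tilt in mm of depth change across the full
#'   scan width (the reflector becomes a tilted plane).
#' @return An `oct_phantom` with `class_label = NA` (not a tissue class).
#' @export
single_reflector_phantom <- function(depth, reflectivity = 0.2,
                                     geometry = scan_geometry(), tilt = 0) {
  check_number(depth, "depth")
  check_number(reflectivity, "reflectivity")
  if (reflectivity > 1) oct_abort("`reflectivity` must be in (0, 1]")
  n_cells <- 218L
  zs <- depth + tilt * (seq_len(n_cells) - (n_cells + 1) / 2) / n_cells
  structure(
    list(class_label = NA_character_,
         geometry = geometry,
         n_cells = n_cells,
         mu = rep(0, n_cells),
         refl = rep(reflectivity, n_cells),
         surface = rep(0, n_cells),
         spots = data.frame(),
         scatterers = data.frame(depth = zs,
                                 lateral_cell = seq_len(n_cells),
                                 reflectivity = reflectivity,
                                 phase = 0),
         texture_params = list(),
         seed = NA_integer_),
    class = "oct_phantom"
  )
}

#' Empty phantom (reference arm only)
#'
#' A phantom with no scatterers; its simulated interferogram contains only
#' the source term and serves as the DC/background reference.
#'
#' @param geometry An [scan_geometry()] object.
#' @return An `oct_phantom` with zero scatterers.
#' @export
empty_phantom <- function(geometry = scan_geometry()) {
  structure(
    list(class_label = NA_character_,
         geometry = geometry,
         n_cells = 218L,
         mu = rep(0, 218L),
         refl = rep(0, 218L),
         surface = rep(0, 218L),
         spots = data.frame(),
         scatterers = data.frame(depth = numeric(0),
                                 lateral_cell = integer(0),
                                 reflectivity = numeric(0),
                                 phase = numeric(0)),
         texture_params = list(),
         seed = NA_integer_),
    class = "oct_phantom"
  )
}

#' Render a phantom directly to a log-intensity B-scan
#'
#' Image-domain shortcut around the spectral forward model: evaluates the
#' attenuation/reflectivity field on a pixel grid, stamps in superficial
#' spots, applies fully developed multiplicative speckle (exponentially
#' distributed intensity from a complex-Gaussian field) plus additive
#' detector noise, and log-compresses. This is the path used to build
#' classifier-scale datasets; the spectral route exists for physics-level
#' validation.
#'
#' @param phantom An `oct_phantom`.
#' @param n_depth,n_width Output image size in pixels (default 128 x 218).
#' @param speckle Apply multiplicative speckle (default `TRUE`).
#' @param noise_sd Additive detector noise standard deviation on the linear
#'   intensity scale (relative to a unit-reflectivity return).
#' @param seed Optional seed controlling the speckle/noise realization.
#' @param db_floor Log-compression floor in dB (default -60).
#' @return An [new_bscan()] object (dB image, 0 dB at the frame maximum).
#' @export
#' @examples
#' b <- render_bscan(generate_phantom("IA", seed = 3), seed = 1)
#' dim(b$image)
render_bscan <- function(phantom, n_depth = 128L, n_width = 218L,
                         speckle = TRUE, noise_sd = 0.005, seed = NULL,
                         db_floor = -60) {
  stopifnot(inherits(phantom, "oct_phantom"))
  n_depth <- check_count(n_depth, "n_depth", min = 8L)
  n_width <- check_count(n_width, "n_width", min = 8L)
  g <- phantom$geometry
  z <- g$depth_range * (seq_len(n_depth) - 0.5) / n_depth
  # map output columns onto phantom texture cells
  cell <- pmin(phantom$n_cells,
               pmax(1L, ceiling(seq_len(n_width) / n_width * phantom$n_cells)))
  mu <- phantom$mu[cell]
  refl <- phantom$refl[cell]
  zs <- phantom$surface[cell]

  depth_below <- outer(z, zs, `-`)              # n_depth x n_width
  inside <- depth_below >= 0
  intensity <- t(t(pmax(depth_below, 0)) * (-2 * mu))
  intensity <- exp(intensity)
  intensity <- t(t(intensity) * refl) * inside

  if (nrow(phantom$spots) > 0) {
    xs_mm <- g$lateral_range * (seq_len(n_width) - 0.5) / n_width
    spot_x <- g$lateral_range * (phantom$spots$lateral_cell - 0.5) / phantom$n_cells
    for (s in seq_len(nrow(phantom$spots))) {
      dz2 <- (z - phantom$spots$depth[s])^2
      dx2 <- (xs_mm - spot_x[s])^2
      blob <- phantom$spots$reflectivity[s] *
        exp(-(outer(dz2, dx2, `+`)) / (2 * phantom$spots$radius[s]^2))
      intensity <- intensity + blob * inside
    }
  }

  with_seed(seed, {
    if (speckle) {
      intensity <- intensity * matrix(rexp(length(intensity)), nrow = n_depth)
    }
    if (noise_sd > 0) {
      intensity <- intensity + abs(rnorm(length(intensity), 0, noise_sd))
    }
  })
  peak <- max(intensity)
  if (peak <= 0) peak <- 1
  img <- 10 * log10(pmax(intensity / peak, 10^(db_floor / 10)))
  new_bscan(img,
            depth_pitch = g$depth_range * 1000 / n_depth,
            lateral_pitch = g$lateral_range * 1000 / n_width,
            volume_id = NA_character_, frame_index = NA_integer_)
}

#' Handcrafted summary features separating the three grades
#'
#' Two scalar features designed around the class texture motifs:
#' `spot_density`, the fraction of bright pixels (above the 99th percentile
#' of the image) lying in the superficial quartile of depth, and
#' `discontinuity`, the largest jump between adjacent lateral-bin mean
#' intensities, capturing interrupted attenuation. A linear classifier on
#' these two features separates synthetic phantoms almost perfectly, which
#' is what makes the synthetic dataset learnable by construction.
#'
#' @param image An `oct_bscan`, model image, or numeric matrix
#'   (depth x width, any monotone intensity scale).
#' @param n_bins Number of lateral bins for the discontinuity score.
#' @return Named numeric vector `c(spot_density, discontinuity)`.
#' @export
phantom_features <- function(image, n_bins = 24L) {
  x <- bscan_matrix(image)
  rng <- range(x)
  if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
  top <- x[seq_len(max(1L, floor(nrow(x) / 4))), , drop = FALSE]
  thr <- quantile(x, 0.99)
  bright_total <- sum(x >= thr)
  spot_density <- if (bright_total == 0) 0 else sum(top >= thr) / bright_total
  colprof <- colMeans(x)
  bin <- cut(seq_along(colprof), breaks = n_bins, labels = FALSE)
  binmeans <- tapply(colprof, bin, mean)
  discontinuity <- max(abs(diff(binmeans)))
  c(spot_density = unname(spot_density), discontinuity = unname(discontinuity))
}
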