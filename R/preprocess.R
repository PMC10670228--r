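# Despeckling (registered adjacent-frame averaging), model-input resizing
# and data augmentation.

#' Estimate the integer translation between two B-scans
#'
#' Maximizes the normalized cross-correlation of the mean-subtracted images
#' over integer shifts, restricted to +/- 10 percent of the image size in
#' each axis (adjacent frames move little). Computed via FFT.
#'
#' @param reference,moving B-scans (`oct_bscan` or matrices) of equal shape.
#' @param max_shift_frac Search bound as a fraction of the image size
#'   (default 0.1).
#' @return Integer vector `c(row_shift, col_shift)` such that `moving` is
#'   the reference displaced by that amount (positive = down / right).
#' @export
#' @examples
#' img <- matrix(rnorm(400), 20)
#' register_translation(img, img)  # c(0, 0)
register_translation <- function(reference, moving, max_shift_frac = 0.1) {
  r <- bscan_matrix(reference)
  m <- bscan_matrix(moving)
  if (!all(dim(r) == dim(m))) oct_abort("images must have the same shape")
  r0 <- r - mean(r)
  m0 <- m - mean(m)
  # circular cross-correlation: peak at the displacement of `moving`
  cc <- Re(fft(fft(m0) * Conj(fft(r0)), inverse = TRUE))
  nr <- nrow(r); nc <- ncol(r)
  max_r <- floor(max_shift_frac * nr)
  max_c <- floor(max_shift_frac * nc)
  shifts_r <- c(0:max_r, if (max_r > 0) (nr - max_r):(nr - 1))
  shifts_c <- c(0:max_c, if (max_c > 0) (nc - max_c):(nc - 1))
  sub <- cc[shifts_r + 1, shifts_c + 1, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  to_signed <- function(s, n) if (s > n / 2) s - n else s
  c(row_shift = to_signed(shifts_r[pk[1]], nr),
    col_shift = to_signed(shifts_c[pk[2]], nc))
}

# integer translation with edge replication (no wrap-around artefacts)
shift_image <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  src_r <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  src_c <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  x[src_r, src_c, drop = FALSE]
}

#' Despeckle by averaging registered adjacent frames
#'
#' Speckle decorrelates between adjacent B-scans while structure persists,
#' so the per-pixel mean over a window of translation-registered frames
#' suppresses speckle roughly by the square root of the window size. Each
#' frame is registered to the centre frame with [register_translation()]
#' before averaging.
#'
#' @param frames List of exactly `window` B-scans (`oct_bscan` or matrices)
#'   of identical shape.
#' @param window Required number of frames (default 7).
#' @param register Register frames before averaging (default `TRUE`).
#' @return Despeckled frame of the same type as the centre input; for
#'   `oct_bscan` input the provenance `volume_id` is preserved and the
#'   averaged frame window is recorded in `frame_window`.
#' @export
despeckle <- function(frames, window = 7L, register = TRUE) {
  window <- check_count(window, "window", min = 1L)
  if (!is.list(frames) || length(frames) != window) {
    oct_abort(sprintf("`frames` must be a list of exactly %d B-scans", window))
  }
  mats <- lapply(frames, bscan_matrix)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    oct_abort("all frames must have the same shape")
  }
  centre <- (window + 1L) %/% 2L
  ref <- mats[[centre]]
  aligned <- lapply(seq_along(mats), function(i) {
    if (!register || i == centre) return(mats[[i]])
    s <- register_translation(ref, mats[[i]])
    shift_image(mats[[i]], -s[1], -s[2])
  })
  out <- Reduce(`+`, aligned) / window
  mid <- frames[[centre]]
  if (inherits(mid, "oct_bscan")) {
    res <- new_bscan(out, depth_pitch = mid$depth_pitch,
                     lateral_pitch = if (is.na(mid$lateral_pitch)) mid$depth_pitch else mid$lateral_pitch,
                     volume_id = mid$volume_id, frame_index = mid$frame_index)
    res$lateral_pitch <- mid$lateral_pitch
    idx <- vapply(frames, function(f) {
      if (inherits(f, "oct_bscan")) f$frame_index else NA_integer_
    }, integer(1))
    res$frame_window <- idx
    res
  } else {
    out
  }
}

#' Resize and normalize a B-scan to the model input format
#'
#' Bilinearly resizes to 128 (depth) x 218 (width) pixels and min-max
#' rescales to \[0, 1\]. A constant image maps to all zeros. When the input
#' already has the target shape the resampling step is skipped, making the
#' operation exactly idempotent.
#'
#' @param image B-scan (`oct_bscan` or numeric matrix), at least 2 x 2.
#' @param dim Target `c(depth, width)` (default `c(128, 218)`).
#' @param label Optional class label attached to the result.
#' @return A `model_image`: numeric `dim[1] x dim[2]` matrix in \[0, 1\]
#'   with attributes `label`, `volume_id` and `frame_window`.
#' @export
resize_normalize <- function(image, dim = c(128L, 218L), label = NULL) {
  x <- bscan_matrix(image)
  if (nrow(x) < 2 || ncol(x) < 2) {
    oct_abort("degenerate input: need at least a 2 x 2 image")
  }
  if (!is.null(label)) check_class_label(label)
  if (!all(base::dim(x) == dim)) {
    x <- EBImage::imageData(EBImage::resize(EBImage::Image(x), w = dim[1],
                                            h = dim[2], filter = "bilinear"))
  }
  rng <- range(x)
  x <- if (diff(rng) == 0) matrix(0, dim[1], dim[2]) else (x - rng[1]) / diff(rng)
  structure(x,
            label = label,
            volume_id = if (inherits(image, "oct_bscan")) image$volume_id else NA_character_,
            frame_window = if (inherits(image, "oct_bscan")) image$frame_window else NULL,
            class = c("model_image", "matrix", "array"))
}

#' Augmentation configuration
#'
#' Random-augmentation parameters: width/height shift as fractions of the
#' image size, shear and zoom ratios (both default 0.1, deliberately
#' conservative so tissue morphology is preserved) and horizontal flipping.
#'
#' @param width_shift,height_shift Maximum shift fractions (default 0.1).
#' @param shear_ratio,zoom_ratio Shear / zoom ratios (default 0.1).
#' @param horizontal_flip Allow random horizontal flips (default `TRUE`).
#' @param seed Optional integer seed for deterministic draws.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(width_shift = 0.1, height_shift = 0.1,
                           shear_ratio = 0.1, zoom_ratio = 0.1,
                           horizontal_flip = TRUE, seed = NULL) {
  for (nm in c("width_shift", "height_shift", "shear_ratio", "zoom_ratio")) {
    v <- get(nm)
    check_number(v, nm, positive = FALSE)
    if (v < 0 || v > 0.5) oct_abort(sprintf("`%s` must be in [0, 0.5]", nm))
  }
  structure(list(width_shift = width_shift, height_shift = height_shift,
                 shear_ratio = shear_ratio, zoom_ratio = zoom_ratio,
                 horizontal_flip = isTRUE(horizontal_flip), seed = seed),
            class = "augment_config")
}

#' Flip a model image horizontally
#' @param image A `model_image` or matrix.
#' @return The image mirrored along the lateral axis; an involution.
#' @export
flip_horizontal <- function(image) {
  out <- image[, rev(seq_len(ncol(image))), drop = FALSE]
  attributes(out) <- attributes(image)
  out
}

# bilinear sampling of x at (possibly fractional) coordinates, 0 outside
bilinear_sample <- function(x, rr, cc) {
  nr <- nrow(x); nc <- ncol(x)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- numeric(length(ri))
    out[ok] <- x[cbind(ri[ok], ci[ok])]
    out
  }
  val(r0, c0) * (1 - fr) * (1 - fc) +
    val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc +
    val(r0 + 1, c0 + 1) * fr * fc
}

#' Randomly augment a model image
#'
#' Draws a random combination of width/height shift, shear, zoom and
#' (optionally) a horizontal flip from the configuration and applies it as
#' one affine resampling about the image centre (bilinear, zero fill).
#' Output is clipped to \[0, 1\]; the class label is preserved. With all
#' ratios zero and flipping off the image is returned unchanged.
#'
#' @param image A `model_image` (matrix in \[0, 1\]).
#' @param cfg An [augment_config()].
#' @return Augmented `model_image`, same shape and attributes.
#' @export
augment <- function(image, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  x <- unclass(image)
  if (!is.matrix(x)) oct_abort("`image` must be a matrix")
  if (min(x) < -1e-8 || max(x) > 1 + 1e-8) {
    oct_abort("`image` must be scaled to [0, 1]")
  }
  identity_cfg <- cfg$width_shift == 0 && cfg$height_shift == 0 &&
    cfg$shear_ratio == 0 && cfg$zoom_ratio == 0 && !cfg$horizontal_flip
  if (identity_cfg) return(image)

  nr <- nrow(x); nc <- ncol(x)
  with_seed(cfg$seed, {
    dr <- runif(1, -cfg$height_shift, cfg$height_shift) * nr
    dc <- runif(1, -cfg$width_shift, cfg$width_shift) * nc
    sh <- runif(1, -cfg$shear_ratio, cfg$shear_ratio)
    zm <- runif(1, 1 - cfg$zoom_ratio, 1 + cfg$zoom_ratio)
    flip <- cfg$horizontal_flip && runif(1) < 0.5
  })
  if (flip) x <- x[, rev(seq_len(nc)), drop = FALSE]
  # inverse mapping: for each target pixel find the source coordinate
  ctr_r <- (nr + 1) / 2; ctr_c <- (nc + 1) / 2
  tg <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  u <- tg$r - ctr_r - dr
  v <- tg$c - ctr_c - dc
  src_r <- (u - sh * v) / zm + ctr_r
  src_c <- v / zm + ctr_c
  out <- matrix(pmin(pmax(bilinear_sample(x, src_r, src_c), 0), 1), nr, nc)
  attributes(out) <- attributes(image)
  out
}
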