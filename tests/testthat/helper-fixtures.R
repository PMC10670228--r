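# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small spectrometer + geometry keep spectral tests fast
small_source <- function() fixture("small_source", function() {
  make_source_spectrum(840, 51.2, n_pixels = 512)
})

small_geometry <- function() fixture("small_geometry", function() {
  scan_geometry(lines_per_bscan = 64)
})

small_map <- function() fixture("small_map", function() {
  build_calibration_map(small_source()$wavelength_grid)
})

paper_source <- function() fixture("paper_source", function() {
  make_source_spectrum(840, 51.2, 2048)
})

# a tiny trained-ish model configuration for fast forward passes
tiny_config <- function(seed = 7) {
  model_config(input_dim = c(16L, 22L), filters = c(2L, 3L, 4L),
               attention_filters = c(3L, 4L), seed = seed)
}

tiny_images <- function(n, seed = 1) {
  withr::with_seed(seed, array(runif(16 * 22 * n), c(16, 22, n)))
}

# numeric loss for finite-difference oracles
model_loss_at <- function(model, x, onehot) {
  fw <- octgrade:::model_forward(model, x)
  octgrade:::crossentropy_loss(fw$probs, onehot)
}
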