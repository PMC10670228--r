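# Small input-validation helpers shared across modules.

oct_abort <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    oct_abort(sprintf("`%s` must be a single number", name))
  }
  if (finite && !is.finite(x)) {
    oct_abort(sprintf("`%s` must be finite", name))
  }
  if (positive && x <= 0) {
    oct_abort(sprintf("`%s` must be positive", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, positive = FALSE)
  if (x < min || x != round(x)) {
    oct_abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

check_class_label <- function(x) {
  if (!is.character(x) || length(x) != 1L || !(x %in% GRADE_LEVELS)) {
    oct_abort("class label must be one of ", paste(GRADE_LEVELS, collapse = ", "))
  }
  x
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    oct_abort(sprintf("`%s` must be a numeric matrix", name))
  }
  invisible(x)
}

# Seeded evaluation that does not disturb the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}
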