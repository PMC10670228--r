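# Inspection-session layer: one record per embedded point, joining the
# t-SNE coordinates, patient metadata, class probabilities and the paths to
# the OCT image and grad-CAM map. The interface is headless and read-only;
# an interactive viewer is a thin plotting shim over lookup_point().

SESSION_SCHEMA_VERSION <- "1.0"

METADATA_FIELDS <- c("name", "chart_number", "gender", "sample_number",
                     "volume_number", "n_bscans")

#' Build an inspection session from pipeline outputs
#'
#' Joins, by image id, the embedding points, the prediction table, the
#' patient metadata and the image/CAM references into one record per
#' embedded point. Missing metadata fields are kept as explicit `NA`
#' markers; a prediction or metadata row referring to no embedding point
#' (or an embedding point without prediction) is an error naming the
#' offending ids.
#'
#' @param embedding An `oct_embedding` (or its `points` data frame with
#'   columns `id`, `x`, `y`, optionally `split`, `label`).
#' @param predictions Data frame with `id` and probability columns
#'   `IA`, `MIA`, `NOR` (rows summing to 1) plus optional
#'   `predicted_class`.
#' @param metadata Data frame with `id` and any of the patient fields
#'   `name`, `chart_number`, `gender`, `sample_number`, `volume_number`,
#'   `n_bscans`.
#' @param image_refs,cam_refs Optional named character vectors (names =
#'   ids) pointing at image / grad-CAM files within the session directory.
#' @return Object of class `oct_session`: `records` (named list of
#'   inspection records), `embedding` (data frame), `model_info`,
#'   `created`, `schema_version`.
#' @export
build_session <- function(embedding, predictions, metadata = NULL,
                          image_refs = NULL, cam_refs = NULL,
                          model_info = list()) {
  pts <- if (inherits(embedding, "oct_embedding")) embedding$points else embedding
  if (!all(c("id", "x", "y") %in% names(pts))) {
    oct_abort("embedding must have columns id, x, y")
  }
  if (!all(c("id", GRADE_LEVELS) %in% names(predictions))) {
    oct_abort("predictions must have columns id, IA, MIA, NOR")
  }
  ids <- as.character(pts$id)
  if (anyDuplicated(ids)) oct_abort("embedding ids must be unique")
  missing_pred <- setdiff(ids, as.character(predictions$id))
  if (length(missing_pred) > 0) {
    oct_abort("no prediction for embedding id(s): ",
              paste(missing_pred, collapse = ", "))
  }
  dangling <- setdiff(as.character(predictions$id), ids)
  if (length(dangling) > 0) {
    oct_abort("prediction refers to unknown embedding id(s): ",
              paste(dangling, collapse = ", "))
  }
  psums <- rowSums(predictions[, GRADE_LEVELS])
  if (any(abs(psums - 1) > 1e-6)) {
    oct_abort("probability triples must sum to 1")
  }
  meta_by_id <- if (!is.null(metadata)) {
    split(metadata, as.character(metadata$id))
  } else list()
  pred_by_id <- split(predictions, as.character(predictions$id))

  records <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    pr <- pred_by_id[[id]][1, ]
    probs <- setNames(as.numeric(pr[GRADE_LEVELS]), GRADE_LEVELS)
    meta <- setNames(as.list(rep(NA, length(METADATA_FIELDS))), METADATA_FIELDS)
    if (!is.null(meta_by_id[[id]])) {
      row <- meta_by_id[[id]][1, ]
      for (f in intersect(METADATA_FIELDS, names(row))) meta[[f]] <- row[[f]]
    }
    structure(
      list(id = id,
           metadata = meta,
           probabilities = probs,
           predicted_class = GRADE_LEVELS[which.max(probs)],
           image_ref = unname(image_refs[id]) %||% NA_character_,
           cam_ref = unname(cam_refs[id]) %||% NA_character_,
           embedding = list(x = pts$x[i], y = pts$y[i],
                            split = if ("split" %in% names(pts)) pts$split[i] else NA_character_,
                            label = if ("label" %in% names(pts)) pts$label[i] else NA_character_)),
      class = "inspection_record")
  })
  names(records) <- ids
  structure(
    list(records = records,
         embedding = pts,
         model_info = model_info,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         schema_version = SESSION_SCHEMA_VERSION),
    class = "oct_session")
}

#' @export
print.oct_session <- function(x, ...) {
  cat(sprintf("<oct_session> %d records (schema %s, created %s)\n",
              length(x$records), x$schema_version, x$created))
  invisible(x)
}

#' Display formatting of a probability triple
#'
#' Formats the non-negligible class probabilities the way the inspection
#' panel displays them, e.g. `"IA: 66.04% and NOR: 33.96%"` (two decimals;
#' classes below 0.005% omitted; ordered by probability).
#'
#' @param probabilities Named probability triple summing to 1.
#' @return A single display string.
#' @export
format_probabilities <- function(probabilities) {
  p <- probabilities[order(-probabilities)]
  p <- p[p >= 5e-5]
  paste(sprintf("%s: %.2f%%", names(p), 100 * p), collapse = " and ")
}

#' @export
print.inspection_record <- function(x, ...) {
  cat(sprintf("<inspection_record> %s -> %s (%s)\n", x$id, x$predicted_class,
              format_probabilities(x$probabilities)))
  invisible(x)
}

#' Retrieve the inspection record for a point
#'
#' Exact-id lookup, or nearest-point lookup from clicked coordinates
#' (Euclidean distance in the embedding plane; exact ties break towards the
#' earlier id in the session's id order).
#'
#' @param session An `oct_session`.
#' @param id Point identifier (exact lookup).
#' @param at Numeric `c(x, y)` (nearest-point lookup); exactly one of `id`
#'   and `at` must be given.
#' @return The matching `inspection_record`.
#' @export
lookup_point <- function(session, id = NULL, at = NULL) {
  stopifnot(inherits(session, "oct_session"))
  if (length(session$records) == 0) oct_abort("session has no records")
  if (is.null(id) == is.null(at)) {
    oct_abort("supply exactly one of `id` or `at`")
  }
  if (!is.null(id)) {
    rec <- session$records[[as.character(id)]]
    if (is.null(rec)) oct_abort("no record with id '", id, "'")
    return(rec)
  }
  stopifnot(length(at) == 2)
  d2 <- (session$embedding$x - at[1])^2 + (session$embedding$y - at[2])^2
  session$records[[which.min(d2)]]   # which.min takes the first (id-order) tie
}

#' Export a session to a JSON bundle
#'
#' Writes a schema-versioned JSON manifest (`session.json`) into `path`.
#' Image and CAM files referenced by the records are expected to live next
#' to it; the manifest itself is self-contained and diffable.
#'
#' @param session An `oct_session`.
#' @param path Directory to write into (created if needed).
#' @return Invisibly, the manifest path.
#' @export
export_session <- function(session, path) {
  stopifnot(inherits(session, "oct_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(path, "session.json")
  payload <- list(
    schema_version = session$schema_version,
    created = session$created,
    model_info = session$model_info,
    embedding = session$embedding,
    records = lapply(unname(session$records), function(r) {
      r <- unclass(r)
      r$probabilities <- as.list(r$probabilities)  # keep names in JSON
      r
    })
  )
  jsonlite::write_json(payload, manifest, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Import a session bundle
#'
#' Reads a bundle written by [export_session()]. A schema-version mismatch
#' is an explicit migration error; a corrupted manifest is a parse error
#' and never yields a partial session.
#'
#' @param path Directory containing `session.json` (or the manifest path).
#' @return The reconstructed `oct_session`.
#' @export
import_session <- function(path) {
  manifest <- if (dir.exists(path)) file.path(path, "session.json") else path
  if (!file.exists(manifest)) oct_abort("no session manifest at '", path, "'")
  payload <- tryCatch(
    jsonlite::read_json(manifest, simplifyVector = FALSE),
    error = function(e) oct_abort("corrupt session manifest: ", conditionMessage(e)))
  if (!identical(payload$schema_version, SESSION_SCHEMA_VERSION)) {
    oct_abort(sprintf(
      "session schema %s cannot be read by this version (expects %s); migrate first",
      payload$schema_version %||% "<missing>", SESSION_SCHEMA_VERSION))
  }
  emb <- do.call(rbind, lapply(payload$embedding, function(row) {
    as.data.frame(lapply(row, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  records <- lapply(payload$records, function(r) {
    r$metadata <- lapply(r$metadata, function(v) if (is.null(v)) NA else v)
    r$probabilities <- unlist(r$probabilities)[GRADE_LEVELS]
    r$image_ref <- r$image_ref %||% NA_character_
    r$cam_ref <- r$cam_ref %||% NA_character_
    r$embedding <- lapply(r$embedding, function(v) if (is.null(v)) NA else v)
    structure(r, class = "inspection_record")
  })
  names(records) <- vapply(records, `[[`, character(1), "id")
  structure(
    list(records = records,
         embedding = emb,
         model_info = payload$model_info,
         created = payload$created,
         schema_version = payload$schema_version),
    class = "oct_session")
}

#' Interactive session viewer
#'
#' Plots the embedding colour-coded by class (training points lighter,
#' test points darker) and, on interactive devices, lets the user click a
#' point to print its inspection record ([lookup_point()] with the clicked
#' coordinates). On non-interactive devices it draws the map and returns.
#'
#' @param session An `oct_session`.
#' @param n_clicks Maximum number of clicks to serve (default 1).
#' @return Invisibly, the last record inspected (or `NULL`).
#' @export
view_session <- function(session, n_clicks = 1L) {
  stopifnot(inherits(session, "oct_session"))
  emb <- session$embedding
  cls <- factor(if ("label" %in% names(emb)) emb$label else "point")
  shade <- if ("split" %in% names(emb)) ifelse(emb$split == "train", 0.35, 1) else 1
  base_cols <- grDevices::hcl.colors(max(3L, nlevels(cls)), "Dark 3")
  cols <- grDevices::adjustcolor(base_cols[as.integer(cls)], alpha.f = 1)
  cols <- ifelse(shade < 1, grDevices::adjustcolor(cols, alpha.f = 0.35), cols)
  graphics::plot(emb$x, emb$y, col = cols, pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = "inspection session")
  last <- NULL
  if (interactive()) {
    for (i in seq_len(n_clicks)) {
      pt <- graphics::locator(1)
      if (is.null(pt)) break
      last <- lookup_point(session, at = c(pt$x, pt$y))
      print(last)
    }
  }
  invisible(last)
}
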