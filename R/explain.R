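# Grad-CAM saliency and penultimate-feature extraction.

#' Gradient-weighted class activation map
#'
#' Computes the gradient of the target-class logit with respect to the last
#' convolutional feature maps (the post-attention output of the final
#' stage), averages it spatially into per-channel weights, forms the
#' rectified weighted sum of the feature maps, bilinearly upsamples it to
#' the model input size and min-max normalizes to \[0, 1\] (an all-zero map
#' stays zero).
#'
#' @param model An `oct_model`.
#' @param image A single model image (matrix of the model's input size).
#' @param target_class Class whose logit is explained (`IA`/`MIA`/`NOR`).
#' @param stage Convolutional stage whose feature maps are explained;
#'   `NULL` (default) uses the last stage. Earlier stages trade semantic
#'   depth for finer spatial localization (their receptive fields are
#'   smaller), which matters in this compact architecture whose final maps
#'   are only a few cells tall.
#' @return An object of class `oct_heatmap`: `values` (input-size matrix in
#'   \[0, 1\]), `target_class`, `raw` (pre-upsampling rectified map).
#' @export
grad_cam <- function(model, image, target_class, stage = NULL) {
  stopifnot(inherits(model, "oct_model"))
  target_class <- check_class_label(target_class)
  n_stages <- length(model$cfg$filters)
  stage <- if (is.null(stage)) n_stages else check_count(stage, "stage")
  if (stage > n_stages) oct_abort("model has only ", n_stages, " stages")
  x <- as_batch4(unclass(image))
  if (dim(x)[4] != 1) oct_abort("`image` must be a single image")
  fw <- model_forward(model, x, keep_cache = TRUE)
  if (stage == n_stages) {
    dF <- cam_feature_gradient(model, fw$cache, target_class)
    Fmap <- fw$cache$features        # (H, W, C, 1)
  } else {
    k <- match(target_class, GRADE_LEVELS)
    dlogits <- matrix(0, model$cfg$n_classes, 1)
    dlogits[k, 1] <- 1
    gr <- model_backward(model, fw$cache, dlogits, collect_stage_grads = TRUE)
    dF <- attr(gr, "stage_grads")[[sprintf("stage%d", stage)]]
    Fmap <- stage_activation(model, fw$cache, stage)
  }
  d <- dim(Fmap)
  w <- colMeans(matrix(dF, d[1] * d[2], d[3]))          # spatial mean per channel
  cam <- matrix(matrix(Fmap, d[1] * d[2], d[3]) %*% w, d[1], d[2])
  cam <- pmax(cam, 0)
  up <- EBImage::imageData(EBImage::resize(EBImage::Image(cam),
                                           w = model$cfg$input_dim[1],
                                           h = model$cfg$input_dim[2],
                                           filter = "bilinear"))
  up <- pmax(up, 0)
  mx <- max(up)
  if (mx > 0) up <- up / mx
  structure(list(values = up, target_class = target_class, raw = cam),
            class = "oct_heatmap")
}

# gradient of the target logit w.r.t. the CAM feature maps (head backward)
cam_feature_gradient <- function(model, cache, target_class) {
  k <- match(target_class, GRADE_LEVELS)
  dlogits <- matrix(0, model$cfg$n_classes, 1)
  dlogits[k, 1] <- 1
  dg <- t(model$params[["dense.w"]]) %*% dlogits
  global_avg_pool_bwd(dg, dim(cache$features))
}

# forward pass of the classification head from a given feature map;
# independent re-route used by finite-difference tests
head_logits <- function(model, features) {
  g <- global_avg_pool(as_batch4(features))
  model$params[["dense.w"]] %*% g + model$params[["dense.b"]]
}

#' @export
print.oct_heatmap <- function(x, ...) {
  cat(sprintf("<oct_heatmap> %d x %d, target %s, max %.3f\n",
              nrow(x$values), ncol(x$values), x$target_class, max(x$values)))
  invisible(x)
}

#' Depth centre of mass of a heatmap
#'
#' Fraction of the image depth at which the heatmap mass is centred
#' (0 = surface, 1 = bottom). Used to verify that normal-tissue saliency
#' concentrates in the superficial region.
#'
#' @param heatmap An `oct_heatmap` or matrix.
#' @return Scalar in \[0, 1\].
#' @export
heatmap_depth_com <- function(heatmap) {
  v <- if (inherits(heatmap, "oct_heatmap")) heatmap$values else heatmap
  rowmass <- rowSums(v)
  if (sum(rowmass) == 0) return(NA_real_)
  sum(rowmass * (seq_len(nrow(v)) - 0.5)) / sum(rowmass) / nrow(v)
}

#' Extract penultimate-layer features
#'
#' Returns the global-average-pooled activations entering the dense head
#' (one fixed-length vector per image); these are the features embedded by
#' [tsne_embed()]. Deterministic; batch order preserved. A warning is
#' raised for untrained models (features are then random projections).
#'
#' @param model An `oct_model`.
#' @param images Image matrix or H x W x N / H x W x 1 x N array.
#' @return Numeric matrix, one row per image.
#' @export
extract_features <- function(model, images) {
  stopifnot(inherits(model, "oct_model"))
  if (!isTRUE(model$trained)) {
    warning("extracting features from an untrained model", call. = FALSE)
  }
  x <- as_batch4(images)
  n <- dim(x)[4]
  chunk <- 64L
  out <- NULL
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    fw <- model_forward(model, x[, , , idx, drop = FALSE], keep_cache = TRUE)
    out <- rbind(out, t(fw$cache$g))
  }
  out
}
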