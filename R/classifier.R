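# Attention-gated residual network: construction, forward/backward pass,
# SGD training with early stopping, prediction.

#' Model configuration for the attention residual network
#'
#' The network counts 14 weight-bearing layers on its main path: one input
#' convolution, two 3x3 convolutions in each of six residual blocks, and the
#' final dense layer. The six blocks form three stages with filter counts
#' `filters` (default 16 -> 32 -> 64); each stage halves the spatial
#' resolution. Attention gates sit at the stages whose filter counts appear
#' in `attention_filters` (default 32 and 64): the gate produces a
#' same-shape mask `M = sigmoid(conv1x1(F))` in (0, 1) and re-enters the
#' main path as `F + alpha * (F * M)` with `alpha` a learnable scalar
#' initialized at `alpha_init`. With `alpha_init = 0` the gated state is the
#' starting point, so attention can fade out during training if it does not
#' help. Shortcut projections and the 1x1 gate convolutions are counted as
#' plumbing, not weight layers; this counting convention is configurable
#' through `blocks_per_stage`/`filters`.
#'
#' @param input_dim Input image size `c(depth, width)` (default 128 x 218).
#' @param filters Filter counts of the three stages.
#' @param blocks_per_stage Residual blocks per stage (default 2, so 6 total).
#' @param attention_filters Filter counts of the stages that carry an
#'   attention gate.
#' @param leaky_relu_slope Negative-side slope of the activation (0.01).
#' @param l2_weight L2 penalty weight on convolution/dense kernels (0.05).
#' @param n_classes Number of output classes (3).
#' @param alpha_init Initial value of the attention gain alpha (0).
#' @param seed Seed for weight initialization.
#' @return An object of class `oct_model_config`.
#' @export
model_config <- function(input_dim = c(128L, 218L),
                         filters = c(16L, 32L, 64L),
                         blocks_per_stage = 2L,
                         attention_filters = c(32L, 64L),
                         leaky_relu_slope = 0.01,
                         l2_weight = 0.05,
                         n_classes = 3L,
                         alpha_init = 0,
                         seed = 42L) {
  stopifnot(length(input_dim) == 2, length(filters) >= 1)
  blocks_per_stage <- check_count(blocks_per_stage, "blocks_per_stage")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  check_number(leaky_relu_slope, "leaky_relu_slope")
  if (leaky_relu_slope >= 1) oct_abort("`leaky_relu_slope` must be in (0, 1)")
  check_number(l2_weight, "l2_weight", positive = FALSE)
  if (!all(attention_filters %in% filters)) {
    oct_abort("`attention_filters` must be a subset of `filters`")
  }
  n_blocks <- length(filters) * blocks_per_stage
  structure(
    list(input_dim = as.integer(input_dim),
         filters = as.integer(filters),
         blocks_per_stage = blocks_per_stage,
         attention_filters = as.integer(attention_filters),
         n_residual_blocks = n_blocks,
         n_weight_layers = 2L * n_blocks + 2L,
         leaky_relu_slope = leaky_relu_slope,
         l2_weight = l2_weight,
         n_classes = as.integer(n_classes),
         alpha_init = alpha_init,
         seed = seed),
    class = "oct_model_config"
  )
}

he_init <- function(kh, kw, ci, co) {
  array(rnorm(kh * kw * ci * co, 0, sqrt(2 / (kh * kw * ci))),
        dim = c(kh, kw, ci, co))
}

#' Build the attention residual network
#'
#' Instantiates the architecture described in [model_config()]: a stride-2
#' 3x3 input convolution and 2x2 max pooling, three stages of residual
#' blocks (each block two 3x3 convolutions with leaky-ReLU activations and
#' an identity or 1x1-projection shortcut; the first block of every stage
#' downsamples by 2), attention gates at the configured stages, global
#' average pooling and a dense softmax head. Weights use He initialization;
#' construction is deterministic given `cfg$seed`.
#'
#' @param cfg An [model_config()] object.
#' @param attention Set `FALSE` to build the identical network without
#'   attention gates (used to verify the alpha = 0 gating contract).
#' @return An object of class `oct_model`.
#' @export
#' @examples
#' m <- build_model(model_config())
#' count_weight_layers(m)  # 14
build_model <- function(cfg = model_config(), attention = TRUE) {
  stopifnot(inherits(cfg, "oct_model_config"))
  if (cfg$n_weight_layers != 2L * cfg$n_residual_blocks + 2L) {
    oct_abort("inconsistent layer counts in configuration")
  }
  params <- list()
  with_seed(cfg$seed, {
    f1 <- cfg$filters[1]
    params[["conv1.w"]] <- he_init(3, 3, 1, f1)
    params[["conv1.b"]] <- numeric(f1)
    cin <- f1
    for (s in seq_along(cfg$filters)) {
      co <- cfg$filters[s]
      for (b in seq_len(cfg$blocks_per_stage)) {
        nm <- sprintf("s%db%d", s, b)
        stride <- if (b == 1L) 2L else 1L
        params[[paste0(nm, ".wa")]] <- he_init(3, 3, cin, co)
        params[[paste0(nm, ".ba")]] <- numeric(co)
        params[[paste0(nm, ".wb")]] <- he_init(3, 3, co, co)
        params[[paste0(nm, ".bb")]] <- numeric(co)
        if (stride != 1L || cin != co) {
          params[[paste0(nm, ".wp")]] <- he_init(1, 1, cin, co)
          params[[paste0(nm, ".bp")]] <- numeric(co)
        }
        cin <- co
      }
      if (attention && co %in% cfg$attention_filters) {
        nm <- sprintf("att%d", s)
        params[[paste0(nm, ".w")]] <- array(rnorm(co * co, 0, 0.01),
                                            dim = c(1, 1, co, co))
        params[[paste0(nm, ".b")]] <- numeric(co)
        params[[paste0(nm, ".alpha")]] <- cfg$alpha_init
      }
    }
    ctop <- cfg$filters[length(cfg$filters)]
    params[["dense.w"]] <- matrix(rnorm(cfg$n_classes * ctop, 0, sqrt(2 / ctop)),
                                  cfg$n_classes, ctop)
    params[["dense.b"]] <- numeric(cfg$n_classes)
  })
  structure(list(cfg = cfg, params = params, attention = attention,
                 trained = FALSE),
            class = "oct_model")
}

#' @export
print.oct_model <- function(x, ...) {
  cat(sprintf(
    "<oct_model> %d weight layers, %d residual blocks, attention at %s filters, %s\n",
    count_weight_layers(x), count_residual_blocks(x),
    paste(x$cfg$attention_filters, collapse = "/"),
    if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

#' Count weight-bearing layers on the main path
#'
#' Counts the input convolution, the two convolutions of every residual
#' block and the final dense layer. Shortcut projections and attention-gate
#' convolutions are plumbing and excluded by convention.
#'
#' @param model An `oct_model`.
#' @return Integer layer count (14 for the default configuration).
#' @export
count_weight_layers <- function(model) {
  nms <- names(model$params)
  sum(grepl("^conv1\\.w$", nms)) + sum(grepl("\\.wa$", nms)) +
    sum(grepl("\\.wb$", nms)) + sum(grepl("^dense\\.w$", nms))
}

#' Count residual blocks
#' @param model An `oct_model`.
#' @return Integer block count (6 for the default configuration).
#' @export
count_residual_blocks <- function(model) {
  sum(grepl("\\.wa$", names(model$params)))
}

#' Stages carrying an attention gate
#' @param model An `oct_model`.
#' @return Integer vector of filter counts of the attention-gated stages.
#' @export
attention_stages <- function(model) {
  nms <- names(model$params)
  s <- as.integer(sub("^att(\\d+)\\.alpha$", "\\1", grep("^att\\d+\\.alpha$", nms, value = TRUE)))
  model$cfg$filters[sort(s)]
}

# ---- forward / backward -----------------------------------------------------

model_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  cfg <- model$cfg
  slope <- cfg$leaky_relu_slope
  x <- as_batch4(x)
  if (!all(dim(x)[1:2] == cfg$input_dim)) {
    oct_abort(sprintf("input must be %d x %d (got %d x %d)",
                      cfg$input_dim[1], cfg$input_dim[2], dim(x)[1], dim(x)[2]))
  }
  # fixed input standardization: model images arrive in [0, 1]; mapping them
  # to an approximately zero-mean, unit-variance range keeps He-initialized
  # layers in their intended regime
  x <- (x - 0.5) * 4
  cache <- if (keep_cache) list(x = x) else NULL

  c1 <- conv_fwd(x, p[["conv1.w"]], p[["conv1.b"]], stride = 2L, pad = 1L)
  a1 <- lrelu(c1, slope)
  pool <- maxpool_fwd(a1, 2L, 2L)
  h <- pool$y
  if (keep_cache) cache$conv1 <- list(c1 = c1, a1 = a1, idx = pool$idx,
                                      a1dim = dim(a1))
  for (s in seq_along(cfg$filters)) {
    for (b in seq_len(cfg$blocks_per_stage)) {
      nm <- sprintf("s%db%d", s, b)
      stride <- if (b == 1L) 2L else 1L
      xin <- h
      cA <- conv_fwd(xin, p[[paste0(nm, ".wa")]], p[[paste0(nm, ".ba")]],
                     stride = stride, pad = 1L)
      aA <- lrelu(cA, slope)
      cB <- conv_fwd(aA, p[[paste0(nm, ".wb")]], p[[paste0(nm, ".bb")]],
                     stride = 1L, pad = 1L)
      proj <- !is.null(p[[paste0(nm, ".wp")]])
      sc <- if (proj) {
        conv_fwd(xin, p[[paste0(nm, ".wp")]], p[[paste0(nm, ".bp")]],
                 stride = stride, pad = 0L)
      } else xin
      z <- cB + sc
      h <- lrelu(z, slope)
      if (keep_cache) cache[[nm]] <- list(xin = xin, cA = cA, aA = aA, z = z,
                                          stride = stride, proj = proj)
    }
    anm <- sprintf("att%d", s)
    if (!is.null(p[[paste0(anm, ".alpha")]])) {
      Fmap <- h
      pre <- conv_fwd(Fmap, p[[paste0(anm, ".w")]], p[[paste0(anm, ".b")]],
                      stride = 1L, pad = 0L)
      M <- sigmoid(pre)
      h <- Fmap + p[[paste0(anm, ".alpha")]] * (Fmap * M)
      if (keep_cache) cache[[anm]] <- list(Fmap = Fmap, M = M)
    }
  }
  features <- h                       # (H, W, C, N) entering the head
  g <- global_avg_pool(features)      # C x N
  logits <- p[["dense.w"]] %*% g + p[["dense.b"]]
  probs <- softmax_probs(logits)
  if (keep_cache) {
    cache$features <- features
    cache$g <- g
  }
  list(logits = logits, probs = probs, cache = cache)
}

model_backward <- function(model, cache, dlogits, collect_stage_grads = FALSE) {
  p <- model$params
  cfg <- model$cfg
  slope <- cfg$leaky_relu_slope
  grads <- list()
  stage_grads <- list()

  dg <- t(p[["dense.w"]]) %*% dlogits
  grads[["dense.w"]] <- dlogits %*% t(cache$g)
  grads[["dense.b"]] <- rowSums(dlogits)
  dh <- global_avg_pool_bwd(dg, dim(cache$features))

  for (s in rev(seq_along(cfg$filters))) {
    if (collect_stage_grads) stage_grads[[sprintf("stage%d", s)]] <- dh
    anm <- sprintf("att%d", s)
    if (!is.null(p[[paste0(anm, ".alpha")]])) {
      ca <- cache[[anm]]
      alpha <- p[[paste0(anm, ".alpha")]]
      grads[[paste0(anm, ".alpha")]] <- sum(dh * ca$Fmap * ca$M)
      dM <- dh * alpha * ca$Fmap
      dpre <- dM * ca$M * (1 - ca$M)
      bwA <- conv_bwd(ca$Fmap, p[[paste0(anm, ".w")]], dpre,
                      stride = 1L, pad = 0L)
      grads[[paste0(anm, ".w")]] <- bwA$dw
      grads[[paste0(anm, ".b")]] <- bwA$db
      dh <- dh * (1 + alpha * ca$M) + bwA$dx
    }
    for (b in rev(seq_len(cfg$blocks_per_stage))) {
      nm <- sprintf("s%db%d", s, b)
      cb <- cache[[nm]]
      dz <- dh * lrelu_grad(cb$z, slope)
      bwB <- conv_bwd(cb$aA, p[[paste0(nm, ".wb")]], dz, stride = 1L, pad = 1L)
      grads[[paste0(nm, ".wb")]] <- bwB$dw
      grads[[paste0(nm, ".bb")]] <- bwB$db
      dcA <- bwB$dx * lrelu_grad(cb$cA, slope)
      bwA <- conv_bwd(cb$xin, p[[paste0(nm, ".wa")]], dcA,
                      stride = cb$stride, pad = 1L)
      grads[[paste0(nm, ".wa")]] <- bwA$dw
      grads[[paste0(nm, ".ba")]] <- bwA$db
      if (cb$proj) {
        bwP <- conv_bwd(cb$xin, p[[paste0(nm, ".wp")]], dz,
                        stride = cb$stride, pad = 0L)
        grads[[paste0(nm, ".wp")]] <- bwP$dw
        grads[[paste0(nm, ".bp")]] <- bwP$db
        dh <- bwA$dx + bwP$dx
      } else {
        dh <- bwA$dx + dz
      }
    }
  }
  da1 <- maxpool_bwd(dh, cache$conv1$idx, cache$conv1$a1dim)
  dc1 <- da1 * lrelu_grad(cache$conv1$c1, slope)
  bw1 <- conv_bwd(cache$x, p[["conv1.w"]], dc1, stride = 2L, pad = 1L)
  grads[["conv1.w"]] <- bw1$dw
  grads[["conv1.b"]] <- bw1$db
  if (collect_stage_grads) attr(grads, "stage_grads") <- stage_grads
  grads
}

# activation entering the backward hook of stage `s` (its post-attention
# output): the final stage's features, otherwise the next stage's input
stage_activation <- function(model, cache, s) {
  if (s == length(model$cfg$filters)) return(cache$features)
  cache[[sprintf("s%db1", s + 1L)]]$xin
}

is_kernel_param <- function(nm) grepl("\\.w[abp]?$", nm)

l2_penalty <- function(model) {
  nms <- names(model$params)
  kernels <- nms[is_kernel_param(nms)]
  model$cfg$l2_weight * sum(vapply(kernels, function(n) sum(model$params[[n]]^2),
                                   numeric(1)))
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the reference protocol: minibatches of 16 images,
#' stochastic gradient descent with learning rate 1e-4 and momentum 0.9,
#' categorical cross-entropy (plus the model's L2 penalty), and early
#' stopping when the validation loss has not decreased for 15 consecutive
#' epochs.
#'
#' @param batch_size Minibatch size (16).
#' @param learning_rate SGD learning rate (1e-4).
#' @param momentum SGD momentum (0.9).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (15).
#' @param max_epochs Hard epoch cap (default 60).
#' @param seed Seed controlling shuffling (and hence the whole run).
#' @return An object of class `oct_train_config`.
#' @export
train_config <- function(batch_size = 16L, learning_rate = 1e-4,
                         momentum = 0.9, early_stop_patience = 15L,
                         max_epochs = 60L, seed = 1L) {
  structure(
    list(batch_size = check_count(batch_size, "batch_size"),
         learning_rate = check_number(learning_rate, "learning_rate",
                                      positive = FALSE),
         momentum = check_number(momentum, "momentum", positive = FALSE),
         early_stop_patience = check_count(early_stop_patience, "early_stop_patience"),
         max_epochs = check_count(max_epochs, "max_epochs"),
         seed = seed),
    class = "oct_train_config"
  )
}

prepare_set <- function(set, name, n_classes) {
  if (!is.list(set) || is.null(set$x) || is.null(set$y)) {
    oct_abort(sprintf("`%s` must be a list with elements `x` and `y`", name))
  }
  x <- as_batch4(set$x)
  y <- as.character(set$y)
  if (dim(x)[4] == 0 || length(y) == 0) {
    oct_abort(sprintf("`%s` split is empty", name))
  }
  if (dim(x)[4] != length(y)) {
    oct_abort(sprintf("`%s`: image count and label count differ", name))
  }
  list(x = x, y = y, onehot = one_hot(y), patients = set$patients)
}

# mean categorical cross-entropy (data loss, no penalty) and accuracy
eval_loss_acc <- function(model, set, chunk = 64L) {
  n <- dim(set$x)[4]
  loss <- 0; correct <- 0
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    fw <- model_forward(model, set$x[, , , idx, drop = FALSE])
    loss <- loss + crossentropy_loss(fw$probs, set$onehot[, idx, drop = FALSE]) * length(idx)
    pred <- GRADE_LEVELS[apply(fw$probs, 2, which.max)]
    correct <- correct + sum(pred == set$y[idx])
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train the attention residual network
#'
#' Minibatch SGD with momentum on categorical cross-entropy plus the L2
#' kernel penalty, with early stopping on the validation data loss
#' (cross-entropy; the L2 term shapes the gradients but would mask
#' plateaus if monitored): training ends once the validation loss has not
#' improved for `cfg$early_stop_patience` consecutive epochs (or at
#' `max_epochs`), and the weights from the best validation epoch are
#' returned. The run is deterministic for a fixed seed under
#' single-threaded BLAS. Reported curve losses are data losses.
#'
#' Patient-level hygiene is enforced: if both splits carry `patients`
#' vectors, any patient appearing in both is an error.
#'
#' @param model An untrained (or pre-trained) `oct_model`.
#' @param train,val Lists with `x` (images: H x W x N or H x W x 1 x N
#'   array), `y` (labels in `IA`/`MIA`/`NOR`) and optionally `patients`.
#' @param cfg An [train_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `oct_training`: `model` (best weights, marked
#'   trained), `curve` (data frame: epoch, train_loss, train_acc, val_loss,
#'   val_acc), `best_epoch`, `stopped_epoch`.
#' @export
train_model <- function(model, train, val, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "oct_model"), inherits(cfg, "oct_train_config"))
  train <- prepare_set(train, "train", model$cfg$n_classes)
  val <- prepare_set(val, "val", model$cfg$n_classes)
  if (!is.null(train$patients) && !is.null(val$patients)) {
    overlap <- intersect(unique(train$patients), unique(val$patients))
    if (length(overlap) > 0) {
      oct_abort("patients present in both splits: ",
                paste(overlap, collapse = ", "))
    }
  }
  p <- model$params
  vel <- lapply(p, function(w) w * 0)
  l2 <- model$cfg$l2_weight
  n <- dim(train$x)[4]
  curve <- data.frame()
  best_loss <- Inf; best_params <- p; best_epoch <- 0L; wait <- 0L
  stopped <- cfg$max_epochs

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        xb <- train$x[, , , idx, drop = FALSE]
        yb <- train$onehot[, idx, drop = FALSE]
        model$params <- p
        fw <- model_forward(model, xb, keep_cache = TRUE)
        loss <- crossentropy_loss(fw$probs, yb)
        grads <- model_backward(model, fw$cache, crossentropy_grad(fw$probs, yb))
        for (nm in names(p)) {
          g <- grads[[nm]]
          if (is.null(g)) next
          if (l2 > 0 && is_kernel_param(nm)) g <- g + 2 * l2 * p[[nm]]
          vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * g
          p[[nm]] <- p[[nm]] + vel[[nm]]
        }
        ep_loss <- ep_loss + loss * length(idx)
        pred <- GRADE_LEVELS[apply(fw$probs, 2, which.max)]
        ep_correct <- ep_correct + sum(pred == train$y[idx])
      }
      model$params <- p
      tr_loss <- ep_loss / n
      vl <- eval_loss_acc(model, val)
      curve <- rbind(curve, data.frame(
        epoch = epoch, train_loss = tr_loss, train_acc = ep_correct / n,
        val_loss = unname(vl["loss"]), val_acc = unname(vl["acc"])))
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f",
                        epoch, tr_loss, ep_correct / n, vl["loss"], vl["acc"]))
      }
      if (vl["loss"] < best_loss - 1e-12) {
        best_loss <- vl["loss"]; best_params <- p
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) { stopped <- epoch; break }
      }
      stopped <- epoch
    }
  })
  model$params <- best_params
  model$trained <- TRUE
  structure(list(model = model, curve = curve,
                 best_epoch = best_epoch, stopped_epoch = stopped),
            class = "oct_training")
}

#' @export
print.oct_training <- function(x, ...) {
  last <- tail(x$curve, 1)
  cat(sprintf(
    "<oct_training> %d epochs (best %d): val loss %.4f, val acc %.3f\n",
    x$stopped_epoch, x$best_epoch, last$val_loss, last$val_acc))
  invisible(x)
}

#' Predict class probabilities for model images
#'
#' Softmax probability triples in the canonical order (IA, MIA, NOR) and
#' the argmax grade (ties broken in that order). Batch order is preserved.
#'
#' @param object An `oct_model`.
#' @param images A single image matrix or an H x W x N / H x W x 1 x N
#'   array.
#' @param ... Unused.
#' @return Data frame with columns `IA`, `MIA`, `NOR` (each row summing to
#'   1) and `predicted_class`.
#' @export
predict.oct_model <- function(object, images, ...) {
  x <- as_batch4(images)
  n <- dim(x)[4]
  out <- matrix(NA_real_, n, length(GRADE_LEVELS),
                dimnames = list(NULL, GRADE_LEVELS))
  chunk <- 64L
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    fw <- model_forward(object, x[, , , idx, drop = FALSE])
    out[idx, ] <- t(fw$probs)
  }
  pred <- GRADE_LEVELS[apply(out, 1, which.max)]
  data.frame(out, predicted_class = pred, stringsAsFactors = FALSE)
}
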