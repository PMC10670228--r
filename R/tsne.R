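# Exact (dense) t-distributed stochastic neighbor embedding.
#
# High-dimensional similarities are Gaussian with per-point bandwidths
# calibrated to a common perplexity; low-dimensional similarities follow a
# Student t distribution with one degree of freedom; the embedding minimizes
# the Kullback-Leibler divergence KL(P || Q) by gradient descent with
# momentum, adaptive gains and early exaggeration. The final 10% of the
# iterations switch to backtracking plain descent so the recorded KLD is
# non-increasing over that window. O(n^2) memory/time: intended for the
# desk-scale inspection sets this package produces (hundreds to a few
# thousand points).

#' t-SNE configuration
#'
#' @param perplexity Target perplexity of the conditional Gaussians
#'   (default 35); must satisfy `n_points > 3 * perplexity`.
#' @param n_iter Total gradient iterations (default 600).
#' @param learning_rate Step size (default 200).
#' @param seed Seed for the initial layout.
#' @param early_exaggeration Factor multiplying P during the opening phase
#'   (default 12, first quarter of the iterations).
#' @return An object of class `tsne_config`.
#' @export
tsne_config <- function(perplexity = 35, n_iter = 600L, learning_rate = 200,
                        seed = 1L, early_exaggeration = 12) {
  structure(
    list(perplexity = check_number(perplexity, "perplexity"),
         n_iter = check_count(n_iter, "n_iter", min = 50L),
         learning_rate = check_number(learning_rate, "learning_rate"),
         seed = seed,
         early_exaggeration = check_number(early_exaggeration, "early_exaggeration")),
    class = "tsne_config"
  )
}

# conditional Gaussian affinities at a fixed perplexity (binary search on
# the precision beta of every point), then symmetrized and normalized
tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  D <- outer(sq, sq, `+`) - 2 * tcrossprod(x)
  D[D < 0] <- 0
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { entropy <- 0 } else {
        pij <- w / sw
        entropy <- -sum(pij[pij > 0] * log(pij[pij > 0]))
      }
      if (abs(entropy - target) < 1e-5) break
      if (entropy > target) {          # too flat: increase precision
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta + beta_lo) / 2
      }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_q <- function(y) {
  sq <- rowSums(y^2)
  num <- 1 / (1 + outer(sq, sq, `+`) - 2 * tcrossprod(y))
  diag(num) <- 0
  list(num = num, Q = pmax(num / sum(num), 1e-12))
}

tsne_kld <- function(P, Q) sum(P * (log(P) - log(Q)))

tsne_gradient <- function(P, Q, num, y) {
  L <- (P - Q) * num
  4 * (diag(rowSums(L)) - L) %*% y
}

#' Embed feature vectors with t-SNE
#'
#' @param features Numeric matrix, one row per observation.
#' @param cfg A [tsne_config()] (default: perplexity 35).
#' @param ids Optional observation identifiers.
#' @param split Optional train/test tag per observation.
#' @param labels Optional class label per observation.
#' @return An object of class `oct_embedding`: `points` (data frame with
#'   `id`, `x`, `y`, and any `split`/`label` provided), `kld` (per-iteration
#'   Kullback-Leibler divergence), `cfg`.
#' @export
#' @examples
#' set.seed(1)
#' f <- rbind(matrix(rnorm(300), 50), matrix(rnorm(300, 6), 50))
#' emb <- tsne_embed(f, tsne_config(perplexity = 10, n_iter = 120))
tsne_embed <- function(features, cfg = tsne_config(), ids = NULL,
                       split = NULL, labels = NULL) {
  stopifnot(inherits(cfg, "tsne_config"))
  features <- as.matrix(features)
  n <- nrow(features)
  if (n <= 3 * cfg$perplexity) {
    oct_abort(sprintf(
      "perplexity %g too large: need n_points > %g, got %d",
      cfg$perplexity, 3 * cfg$perplexity, n))
  }
  P <- tsne_affinities(features, cfg$perplexity)
  exag_until <- floor(cfg$n_iter / 4)
  final_from <- cfg$n_iter - floor(cfg$n_iter / 10) + 1L

  with_seed(cfg$seed, {
    y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  })
  vel <- y * 0
  gains <- y * 0 + 1
  eta <- cfg$learning_rate
  kld <- numeric(cfg$n_iter)

  for (it in seq_len(cfg$n_iter)) {
    Pit <- if (it <= exag_until) P * cfg$early_exaggeration else P
    qq <- tsne_q(y)
    grad <- tsne_gradient(Pit, qq$Q, qq$num, y)
    kld[it] <- tsne_kld(P, qq$Q)

    if (it < final_from) {
      mom <- if (it <= exag_until) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(vel), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      vel <- mom * vel - eta * gains * grad
      y <- y + vel
      y <- sweep(y, 2, colMeans(y))
    } else {
      # closing phase: plain descent with backtracking so KLD cannot rise
      step <- eta
      accepted <- FALSE
      repeat {
        y_new <- y - step * gains * grad
        k_new <- tsne_kld(P, tsne_q(y_new)$Q)
        if (k_new <= kld[it]) { accepted <- TRUE; break }
        if (step < 1e-8) break
        step <- step / 2
      }
      if (accepted) {
        y <- sweep(y_new, 2, colMeans(y_new))
        kld[it] <- k_new
      }
    }
  }
  pts <- data.frame(id = ids %||% seq_len(n), x = y[, 1], y = y[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(split)) pts$split <- split
  if (!is.null(labels)) pts$label <- labels
  structure(list(points = pts, kld = kld, cfg = cfg),
            class = "oct_embedding")
}

#' @export
print.oct_embedding <- function(x, ...) {
  cat(sprintf("<oct_embedding> %d points, final KLD %.4f (perplexity %g)\n",
              nrow(x$points), tail(x$kld, 1), x$cfg$perplexity))
  invisible(x)
}
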