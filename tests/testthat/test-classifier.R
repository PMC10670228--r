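# Architecture audit, gating contract, training behaviour and prediction.

test_that("the default architecture counts 14 weight layers and 6 blocks", {
  m <- build_model(model_config())
  expect_equal(count_weight_layers(m), 14L)
  expect_equal(count_residual_blocks(m), 6L)
  expect_equal(attention_stages(m), c(32L, 64L))
  expect_error(model_config(attention_filters = c(5L)), "subset")
})

test_that("with alpha = 0 the network equals its attention-free twin", {
  cfg <- tiny_config(seed = 13)
  m_att <- build_model(cfg)                      # alphas initialized at 0
  m_plain <- build_model(cfg, attention = FALSE)
  shared <- intersect(names(m_plain$params), names(m_att$params))
  m_plain$params[shared] <- m_att$params[shared]
  x <- tiny_images(3, seed = 2)
  expect_equal(octgrade:::model_forward(m_att, x)$logits,
               octgrade:::model_forward(m_plain, x)$logits,
               tolerance = 1e-12)
  # a non-zero alpha makes the gate act
  m_att$params[["att3.alpha"]] <- 0.5
  expect_false(isTRUE(all.equal(octgrade:::model_forward(m_att, x)$logits,
                                octgrade:::model_forward(m_plain, x)$logits)))
})

test_that("probability triples are a softmax and obey the argmax rule", {
  m <- build_model(tiny_config())
  x <- tiny_images(5, seed = 3)
  pr <- predict(m, x)
  expect_equal(rowSums(pr[, grade_levels()]), rep(1, 5), tolerance = 1e-9)
  expect_equal(pr$predicted_class,
               grade_levels()[max.col(pr[, grade_levels()], "first")])

  # uniform logits give the uniform triple
  m0 <- m
  m0$params[["dense.w"]][] <- 0
  m0$params[["dense.b"]][] <- 0
  pr0 <- predict(m0, x)
  expect_equal(as.numeric(as.matrix(pr0[, grade_levels()])),
               rep(1 / 3, 15), tolerance = 1e-12)
  # ties break in canonical class order
  expect_equal(unique(pr0$predicted_class), "IA")
})

test_that("prediction is stateless: permuting the batch permutes the output", {
  m <- build_model(tiny_config())
  x <- tiny_images(6, seed = 4)
  perm <- c(4, 1, 6, 2, 5, 3)
  pr <- predict(m, x)
  pr_perm <- predict(m, x[, , perm])
  expect_equal(as.matrix(pr_perm[, grade_levels()]),
               as.matrix(pr[perm, grade_levels()]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(predict(m, matrix(0, 4, 4)), "input must be")
})

test_that("training reduces the loss on a separable toy problem", {
  # two texture archetypes: energy at the top vs bottom of the image
  make_toy <- function(n, seed) {
    withr::with_seed(seed, {
      x <- array(runif(16 * 22 * n, 0, 0.2), c(16, 22, n))
      y <- rep(c("IA", "NOR"), length.out = n)
      for (i in seq_len(n)) {
        rows <- if (y[i] == "IA") 1:6 else 11:16
        x[rows, , i] <- x[rows, , i] + 0.7
      }
      list(x = pmin(x, 1), y = y)
    })
  }
  tr <- make_toy(24, 1)
  te <- make_toy(8, 2)
  m <- build_model(tiny_config(seed = 3))
  res <- train_model(m, tr, te, train_config(max_epochs = 25, seed = 5))
  expect_lt(tail(res$curve$train_loss, 1), res$curve$train_loss[1])
  expect_equal(nrow(res$curve), res$stopped_epoch)
  expect_true(res$model$trained)
})

test_that("a frozen model early-stops after exactly the patience window", {
  tr <- list(x = tiny_images(8, 1), y = rep(c("IA", "MIA"), 4))
  te <- list(x = tiny_images(4, 2), y = rep(c("IA", "MIA"), 2))
  m <- build_model(tiny_config(seed = 5))
  cfg <- train_config(learning_rate = 0, early_stop_patience = 15, max_epochs = 60,
                      seed = 1)
  res <- train_model(m, tr, te, cfg)
  # epoch 1 sets the best loss; 15 flat epochs then stop
  expect_equal(res$best_epoch, 1L)
  expect_equal(res$stopped_epoch, 16L)
  expect_equal(nrow(res$curve), 16L)
})

test_that("training is deterministic for a fixed seed", {
  tr <- list(x = tiny_images(12, 6), y = rep(grade_levels(), 4))
  te <- list(x = tiny_images(6, 7), y = rep(grade_levels(), 2))
  run <- function() {
    train_model(build_model(tiny_config(seed = 2)), tr, te,
                train_config(max_epochs = 3, seed = 9))
  }
  r1 <- run(); r2 <- run()
  expect_identical(tail(r1$curve$val_loss, 1), tail(r2$curve$val_loss, 1))
  expect_identical(r1$model$params, r2$model$params)
})

test_that("the training objective includes the L2 kernel penalty", {
  m <- build_model(tiny_config())
  # penalty is positive for any non-zero kernels, so objective > data loss
  expect_gt(octgrade:::l2_penalty(m), 0)
  m0 <- m; m0$cfg$l2_weight <- 0
  expect_equal(octgrade:::l2_penalty(m0), 0)
  # and it shapes the gradient: one SGD step shrinks kernels faster with L2
  tr <- list(x = tiny_images(8, 1), y = rep(c("IA", "MIA"), 4))
  te <- list(x = tiny_images(4, 2), y = rep(c("IA", "MIA"), 2))
  norm_after <- function(model) {
    res <- train_model(model, tr, te,
                       train_config(max_epochs = 2, seed = 4))
    sum(res$model$params[["s1b1.wa"]]^2)
  }
  expect_lt(norm_after(m), norm_after(m0))
})

test_that("training refuses invalid splits", {
  x <- tiny_images(4, 1); y <- rep(c("IA", "NOR"), 2)
  m <- build_model(tiny_config())
  expect_error(
    train_model(m, list(x = x, y = y, patients = c("A", "A", "B", "B")),
                list(x = x, y = y, patients = c("B", "B", "C", "C")),
                train_config(max_epochs = 1)),
    "patients present in both")
  expect_error(
    train_model(m, list(x = x, y = character(0)), list(x = x, y = y),
                train_config(max_epochs = 1)),
    "differ|empty")
})
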