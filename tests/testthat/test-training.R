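# Training machinery: class weights, the weighted smoothed cross-entropy
# against term-by-term evaluation, schedules, clipping, and determinism /
# gradient-norm / leakage properties of the loop on a scaled-down model.

test_that("class weights are inverse-frequency with count-weighted mean one", {
  expect_equal(compute_class_weights(rep(1:3, each = 10)), rep(1, 3))
  w <- compute_class_weights(rep(c(1L, 2L), times = c(75, 25)))
  expect_equal(w, c(100 / 150, 100 / 50), tolerance = 1e-12)
  set.seed(1)
  y <- sample(1:4, 200, replace = TRUE)
  w2 <- compute_class_weights(y)
  expect_equal(sum(w2 * tabulate(y)) / length(y), 1, tolerance = 1e-12)
  expect_error(compute_class_weights(c(1L, 1L, 3L), n_classes = 3),
               "class 2")
})

test_that("the loss matches hand evaluation and reduces to plain CE", {
  # uniform binary prediction, no weighting or smoothing -> ln 2
  expect_equal(weighted_smoothed_ce(matrix(0.5, 1, 2), 1L), log(2),
               tolerance = 1e-12)
  # perfect one-hot prediction -> 0 (up to the log floor)
  expect_equal(weighted_smoothed_ce(matrix(c(1, 0), 1, 2), 1L), 0,
               tolerance = 1e-10)
  # term-by-term scalar oracle: C = 3, w = (1,2,1), eps = 0.1
  p <- matrix(c(0.7, 0.2, 0.1), 1, 3)
  w <- c(1, 2, 1)
  tgt <- c(0.9 + 0.1 / 3, 0.1 / 3, 0.1 / 3)
  manual <- -(w[1] * tgt[1] * log(0.7) + w[2] * tgt[2] * log(0.2) +
                w[3] * tgt[3] * log(0.1))
  expect_equal(weighted_smoothed_ce(p, 1L, w, 0.1), manual, tolerance = 1e-6)
  # equivalence with unweighted CE at w = 1, eps = 0, on random batches
  set.seed(2)
  for (r in 1:20) {
    probs <- matrix(rexp(5 * 4), 5, 4)
    probs <- probs / rowSums(probs)
    y <- sample(1:4, 5, replace = TRUE)
    plain <- -mean(log(probs[cbind(1:5, y)]))
    expect_equal(weighted_smoothed_ce(probs, y), plain, tolerance = 1e-12)
    # batch permutation invariance
    o <- sample(5)
    expect_equal(weighted_smoothed_ce(probs[o, ], y[o], label_smoothing = 0.1),
                 weighted_smoothed_ce(probs, y, label_smoothing = 0.1),
                 tolerance = 1e-12)
    # linear scaling in a uniform weight multiplier
    expect_equal(weighted_smoothed_ce(probs, y, rep(2.5, 4)),
                 2.5 * weighted_smoothed_ce(probs, y), tolerance = 1e-12)
  }
  # the logits-space loss used in training agrees with the probability form
  logits <- matrix(rnorm(12), 4, 3)
  probs <- exp(logits) / rowSums(exp(logits))
  y <- c(1L, 3L, 2L, 2L)
  w3 <- c(0.8, 1.1, 1.4)
  node <- tanet:::ad_wsce_logits(NULL, tanet:::ad_leaf(logits), y, w3, 0.1)
  expect_equal(tanet:::ad_val(node),
               weighted_smoothed_ce(probs, y, w3, 0.1), tolerance = 1e-10)
})

test_that("learning-rate schedules hit their endpoints and midpoints", {
  expect_equal(lr_schedule(0, 100, "cosine", lr0 = 0.002), 0.002)
  expect_equal(lr_schedule(100, 100, "cosine", lr0 = 0.002), 0)
  expect_equal(lr_schedule(50, 100, "cosine", lr0 = 0.002), 0.001,
               tolerance = 1e-12)
  expect_equal(lr_schedule(30, 100, "one_cycle", lr0 = 0.002), 0.002)
  expect_equal(lr_schedule(100, 100, "one_cycle", lr0 = 0.002), 0.002 / 100)
  expect_lt(lr_schedule(0, 100, "one_cycle", lr0 = 0.002), 0.002)
})

test_that("gradient clipping bounds the global norm", {
  g <- list(a = matrix(3, 2, 2), b = rep(4, 5))
  clipped <- clip_global_norm(g, 1)
  nrm <- sqrt(sum(unlist(clipped)^2))
  expect_lte(nrm, 1 + 1e-9)
  expect_gt(attr(clipped, "norm"), 1)
  small <- clip_global_norm(list(a = 0.1), 1)
  expect_equal(small$a, 0.1)
})

test_that("training is deterministic and respects the clip bound", {
  cfg <- tiny_config()
  d <- c(24, cfg$n_bands, cfg$eeg_channels, cfg$windows)
  set.seed(3)
  de <- array(rnorm(prod(d)), d)
  psd <- array(rnorm(prod(d)), d)
  y <- rep(1:3, 8)
  trn <- list(de = de[1:18, , , , drop = FALSE],
              psd = psd[1:18, , , , drop = FALSE], labels = y[1:18])
  val <- list(de = de[19:24, , , , drop = FALSE],
              psd = psd[19:24, , , , drop = FALSE], labels = y[19:24])
  tc <- train_config("seed_like", epochs = 3L, batch_size = 8L, seed = 11)
  f1 <- tanet_train(tanet_model(cfg, seed = 4), trn, val, tc)
  f2 <- tanet_train(tanet_model(cfg, seed = 4), trn, val, tc)
  expect_identical(f1$history, f2$history)
  expect_true(all(f1$history$max_grad_norm_postclip <= 1 + 1e-6))
  expect_equal(nrow(f1$history), 3)
})

test_that("no label signal leaks through the training loop at zero effect", {
  cfg <- tiny_config()
  d0 <- generate_feature_dataset("seed_like", n_per_class = 30,
                                 effect_size = 0, seed = 21)
  # shrink to the tiny geometry by slicing channels/bands/windows
  cut <- function(a) array(a[, 1:2, 1:4, 1:6], c(dim(a)[1], 2, 4, 6))
  dtest <- generate_feature_dataset("seed_like", n_per_class = 50,
                                    effect_size = 0, seed = 22)
  fit <- tanet_train(tanet_model(cfg, seed = 5),
                     list(de = cut(d0$de), psd = cut(d0$psd),
                          labels = d0$labels),
                     list(de = cut(dtest$de)[1:30, , , , drop = FALSE],
                          psd = cut(dtest$psd)[1:30, , , , drop = FALSE],
                          labels = dtest$labels[1:30]),
                     train_config("seed_like", epochs = 4L, batch_size = 32L,
                                  seed = 12))
  probs <- tanet:::predict_probs(fit$model, cut(dtest$de), cut(dtest$psd))
  acc <- mean(max.col(probs, ties.method = "first") == dtest$labels)
  chance_sd <- sqrt((1 / 3) * (2 / 3) / length(dtest$labels))
  expect_lt(abs(acc - 1 / 3), 3 * chance_sd)
})

test_that("a non-finite loss aborts with a diagnostic", {
  cfg <- tiny_config()
  m <- tanet_model(cfg, seed = 6)
  m$params$cls.b3[] <- NaN   # poison the logits
  inp <- tiny_inputs(cfg, B = 6L)
  expect_error(
    tanet_train(m, list(de = inp$de[1:4, , , , drop = FALSE],
                        psd = inp$psd[1:4, , , , drop = FALSE],
                        labels = c(1L, 2L, 3L, 1L)),
                list(de = inp$de[5:6, , , , drop = FALSE],
                     psd = inp$psd[5:6, , , , drop = FALSE],
                     labels = c(2L, 3L)),
                train_config(epochs = 1L, batch_size = 4L, seed = 1)),
    "non-finite")
})
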