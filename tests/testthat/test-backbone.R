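# Backbone assembly: convolution against explicit arithmetic, adaptive
# pooling semantics, projection fan-in, Conformer sub-modules and residual
# identities, classifier normalisation, the layer-by-layer dimension ledger
# and the trainable-parameter total.

test_that("conv2d matches the explicit convolution sum", {
  kern <- array(0, c(1, 1, 3, 3))
  set.seed(1)
  kern[1, 1, , ] <- matrix(rnorm(9), 3, 3)
  bias <- 0.7
  x <- array(rnorm(9), c(1, 1, 3, 3))
  out <- conv2d(x, kern, bias)
  pad <- matrix(0, 5, 5)
  pad[2:4, 2:4] <- x[1, 1, , ]
  manual <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    manual[i, j] <- sum(kern[1, 1, , ] * pad[i:(i + 2), j:(j + 2)]) + bias
  }
  expect_equal(out[1, 1, , ], manual, tolerance = 1e-6)
})

test_that("conv block maps 5 band channels to 64 and rejects mismatches", {
  m <- tanet_model(tanet_config(), seed = 1)
  set.seed(2)
  x <- array(rnorm(2 * 5 * 62 * 10), c(2, 5, 62, 10))
  out <- conv_block(x, m)
  expect_equal(dim(out), c(2, 64, 62, 10))
  expect_error(conv_block(x[, 1:3, , ], m), "input channels")
  # 1 x 1 spatial input is defined thanks to padding
  cfg <- tiny_config()
  mt <- tanet_model(cfg, seed = 2)
  y <- conv_block(array(1, c(1, 2, 1, 1)), mt)
  expect_equal(dim(y), c(1, 5, 1, 1))
  expect_true(all(is.finite(y)))
})

test_that("adaptive pooling fixes (31, 10) from above and from below", {
  set.seed(3)
  x <- array(rnorm(2 * 64 * 62 * 10), c(2, 64, 62, 10))
  p <- adaptive_average_pool(x)
  expect_equal(dim(p), c(2, 64, 31, 10))
  # 62 -> 31: each output is the mean of its 2 x 1 bin
  expect_equal(p[1, 1, 1, 1], mean(x[1, 1, 1:2, 1]), tolerance = 1e-12)
  expect_equal(p[2, 5, 31, 7], mean(x[2, 5, 61:62, 7]), tolerance = 1e-12)
  # constant input -> constant output
  expect_equal(adaptive_average_pool(array(3.3, c(1, 2, 5, 4))),
               array(3.3, c(1, 2, 31, 10)), tolerance = 1e-12)
  # DEAP case: (32, 3) is up-sampled to (31, 10)
  expect_equal(dim(adaptive_average_pool(array(rnorm(64 * 32 * 3),
                                               c(1, 64, 32, 3)))),
               c(1, 64, 31, 10))
})

test_that("sequence projection flattens 64 x 31 = 1984 per token", {
  m <- tanet_model(tanet_config(), seed = 4)
  set.seed(4)
  x <- array(rnorm(2 * 64 * 31 * 10), c(2, 64, 31, 10))
  S <- sequence_projection(x, m)
  expect_equal(dim(S), c(2, 10, 256))
  expect_equal(nrow(m$params$proj.W), 1984)
  expect_error(sequence_projection(array(0, c(1, 64, 30, 10)), m), "fan-in")
  # layer-norm identity: pre-affine rows have mean 0, variance 1
  m$params$proj.ln.gamma[] <- 1
  m$params$proj.ln.beta[] <- 0
  S2 <- sequence_projection(x, m)
  mus <- apply(S2, c(1, 2), mean)
  vars <- apply(S2, c(1, 2), function(v) mean((v - mean(v))^2))
  expect_true(all(abs(mus) < 1e-8))
  expect_true(all(abs(vars - 1) < 1e-3))
})

test_that("feed-forward module: shape, zero weights, scalar oracle", {
  cfg <- tiny_config(conformer_dropout = 0)
  m <- tanet_model(cfg, seed = 5)
  set.seed(5)
  x <- array(rnorm(2 * 6 * 8), c(2, 6, 8))
  expect_equal(dim(conformer_ffn(x, m)), dim(x))
  z <- tanet_model(cfg, seed = 5)
  for (nm in grep("^conf1\\.ffn1", ls(z$params), value = TRUE)) {
    z$params[[nm]][] <- 0
  }
  expect_equal(conformer_ffn(x, z, block = 1, which = 1),
               array(0, dim(x)), tolerance = 1e-12)
  # d_model = 2, expansion 2, one token: hand-computed GELU arithmetic
  cfg2 <- tiny_config(d_model = 2L, n_heads = 1L, ffn_expansion = 2L,
                      conformer_dropout = 0)
  m2 <- tanet_model(cfg2, seed = 6)
  W1 <- matrix(c(0.5, -0.3, 0.2, 0.8, -0.6, 0.1, 0.4, -0.2), 2, 4)
  b1 <- c(0.1, 0, -0.1, 0.2)
  W2 <- matrix(seq(-0.4, 0.3, 0.1), 4, 2)
  b2 <- c(0.05, -0.05)
  m2$params$conf1.ffn1.W1 <- W1
  m2$params$conf1.ffn1.b1 <- b1
  m2$params$conf1.ffn1.W2 <- W2
  m2$params$conf1.ffn1.b2 <- b2
  m2$params$conf1.ffn1.ln.gamma <- c(1.5, 0.5)
  m2$params$conf1.ffn1.ln.beta <- c(0.2, -0.2)
  xv <- array(c(0.3, -1.1), c(1, 1, 2))
  out <- conformer_ffn(xv, m2)
  v <- c(0.3, -1.1)
  xhat <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  h <- xhat * c(1.5, 0.5) + c(0.2, -0.2)
  a <- as.vector(h %*% W1) + b1
  g <- a * pnorm(a)
  manual <- as.vector(g %*% W2) + b2
  expect_equal(as.vector(out), manual, tolerance = 1e-6)
})

test_that("conv module: delta kernel and identity pointwise give identity", {
  cfg <- tiny_config(conformer_dropout = 0)
  m <- tanet_model(cfg, seed = 7)
  # identity LayerNorm and BatchNorm are impossible in general, so make the
  # whole module transparent: LN off via gamma/beta trick is not available;
  # instead check Eq-level pieces through hand-set weights on a raw matrix.
  D <- cfg$d_model
  m$params$conf1.conv.dw.W[] <- 0
  m$params$conf1.conv.dw.W[2, ] <- 1  # centre tap (kernel length 3)
  m$params$conf1.conv.pw.W <- diag(D)
  m$params$conf1.conv.pw.b[] <- 0
  set.seed(7)
  x <- matrix(rnorm(6 * 2 * D), 6 * 2, D)
  lv <- tanet:::wrap_leaves(m$params)
  # depthwise with the delta kernel reproduces its input exactly
  z <- tanet:::ad_depthwise_tokens(NULL, tanet:::ad_leaf(x),
                                   lv$conf1.conv.dw.W, 6L, 2L)
  expect_equal(tanet:::ad_val(z), x, tolerance = 1e-12)
  # pointwise with the identity matrix reproduces its input exactly
  pw <- tanet:::ad_linear(NULL, tanet:::ad_leaf(x), lv$conf1.conv.pw.W,
                          lv$conf1.conv.pw.b)
  expect_equal(tanet:::ad_val(pw), x, tolerance = 1e-12)
  # 1 channel, length 5, kernel (1, 2, 3, 2, 1): manual 1-D convolution
  w5 <- matrix(c(1, 2, 3, 2, 1), 5, 1)
  xs <- matrix(c(0.5, -1, 2, 0.3, -0.7), 5, 1)
  z5 <- tanet:::ad_val(tanet:::ad_depthwise_tokens(NULL, tanet:::ad_leaf(xs),
                                                   tanet:::ad_leaf(w5), 5L, 1L))
  xp <- c(0, 0, xs[, 1], 0, 0)
  manual <- vapply(1:5, function(t) sum(w5[, 1] * xp[t:(t + 4)]), numeric(1))
  expect_equal(as.vector(z5), manual, tolerance = 1e-12)
  # and the assembled module preserves shape
  xa <- array(rnorm(2 * 6 * D), c(2, 6, D))
  expect_equal(dim(conformer_conv_module(xa, m)), dim(xa))
})

test_that("zeroed submodules reduce a Conformer block to LayerNorm", {
  cfg <- tiny_config(conformer_dropout = 0)
  m <- tanet_model(cfg, seed = 8)
  for (nm in grep("^conf1\\.", ls(m$params), value = TRUE)) {
    if (!grepl("final_ln", nm)) m$params[[nm]][] <- 0
  }
  m$params$conf1.final_ln.gamma[] <- 1
  m$params$conf1.final_ln.beta[] <- 0
  set.seed(8)
  x <- array(rnorm(2 * 6 * 8), c(2, 6, 8))
  out <- conformer_block(x, m, block = 1)
  manual <- x
  for (b in 1:2) for (t in 1:6) {
    v <- x[b, t, ]
    manual[b, t, ] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  }
  expect_equal(out, manual, tolerance = 1e-10)
})

test_that("self-attention rows sum to one for every head and sample", {
  cfg <- tiny_config()
  m <- tanet_model(cfg, seed = 9)
  set.seed(9)
  x <- array(rnorm(3 * 6 * 8), c(3, 6, 8))
  out <- conformer_block(x, m, keep_attn = TRUE)
  attn <- attr(out, "attn")
  expect_length(attn, 3 * cfg$n_heads)
  for (p in attn) {
    expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-10)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("classifier produces normalised probabilities", {
  m <- tanet_model(tanet_config(), seed = 10)
  set.seed(10)
  x <- matrix(rnorm(4 * 256), 4, 256)
  p <- classifier_head(x, m)
  expect_equal(dim(p), c(4, 3))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-9)
  m$params$cls.W3[] <- 0
  m$params$cls.b3[] <- 0
  expect_equal(classifier_head(x, m), matrix(1 / 3, 4, 3), tolerance = 1e-12)
  md <- tanet_model(tanet_config("deap_like"), seed = 10)
  expect_equal(ncol(classifier_head(x, md)), 2)
})

test_that("the dimension ledger is reproduced row for row", {
  m <- tanet_model(tanet_config(), seed = 11)
  inp <- list(de = array(rnorm(2 * 5 * 62 * 10), c(2, 5, 62, 10)),
              psd = array(rnorm(2 * 5 * 62 * 10), c(2, 5, 62, 10)))
  tr <- tanet_shape_trace(m, inp$de, inp$psd)
  B <- 2L
  expect_equal(tr$mca_band, c(B, 62L, 10L))
  expect_equal(tr$fused, c(B, 5L, 62L, 10L))
  expect_equal(tr$cbam, c(B, 5L, 62L, 10L))
  expect_equal(tr$conv1, c(B, 32L, 62L, 10L))
  expect_equal(tr$conv2, c(B, 64L, 62L, 10L))
  expect_equal(tr$pool, c(B, 64L, 31L, 10L))
  expect_equal(tr$tokens, c(B, 10L, 1984L))
  expect_equal(tr$projected, c(B, 10L, 256L))
  expect_equal(tr$conformer1, c(B, 10L, 256L))
  expect_equal(tr$conformer2, c(B, 10L, 256L))
  expect_equal(tr$pooled, c(B, 256L))
  expect_equal(tr$cls1, c(B, 128L))
  expect_equal(tr$cls2, c(B, 64L))
  expect_equal(tr$logits, c(B, 3L))
})

test_that("global average pooling of a constant sequence returns the constant", {
  cfg <- tiny_config()
  x <- matrix(5.5, 6 * 2, 8)
  out <- tanet:::ad_val(tanet:::ad_mean_tokens(NULL, tanet:::ad_leaf(x), 6L, 2L))
  expect_equal(out, matrix(5.5, 2, 8), tolerance = 1e-12)
})

test_that("parameter accounting: totals, single layers, freezing", {
  m <- tanet_model(tanet_config(), seed = 12)
  total <- count_trainable_parameters(m)
  expect_equal(round(total / 1e6, 2), 3.34)
  # a single 256 -> 128 linear layer with bias
  expect_equal(length(m$params$cls.W1) + length(m$params$cls.b1), 32896)
  frozen <- count_trainable_parameters(m, freeze = "cls.")
  cls_total <- sum(vapply(grep("^cls\\.", ls(m$params), value = TRUE),
                          function(n) length(m$params[[n]]), numeric(1)))
  expect_equal(total - frozen, cls_total)
})

test_that("full forward yields (B, 3) probabilities deterministically", {
  m <- tanet_model(tanet_config(), seed = 13)
  set.seed(13)
  de <- array(rnorm(2 * 5 * 62 * 10), c(2, 5, 62, 10))
  psd <- array(rnorm(2 * 5 * 62 * 10), c(2, 5, 62, 10))
  p1 <- tanet_forward(m, de, psd)
  expect_equal(dim(p1), c(2, 3))
  expect_equal(rowSums(p1), rep(1, 2), tolerance = 1e-9)
  expect_identical(p1, tanet_forward(m, de, psd))
  expect_error(tanet_forward(m, de[, 1:3, , ], psd[, 1:3, , ]), "bands")
})
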