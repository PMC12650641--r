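# Shared fixtures: a scaled-down network configuration for fast structural
# and gradient tests, random feature pairs, and small independent oracles.

tiny_config <- function(...) {
  base <- list(n_bands = 2L, eeg_channels = 4L, windows = 6L, n_classes = 3L,
               att_dim = 3L, mca_dropout = 0.2, cbam_reduction = 2L,
               cbam_kernel = 3L, conv_channels = c(3L, 5L),
               pool_target = c(3L, 4L), d_model = 8L, n_heads = 2L,
               conformer_kernel = 3L, ffn_expansion = 2L, n_blocks = 2L,
               conformer_dropout = 0.1, classifier_dims = c(6L, 5L),
               dropout_cls = c(0.1, 0.1))
  over <- list(...)
  base[names(over)] <- over
  do.call(tanet_config, base)
}

tiny_inputs <- function(cfg, B = 3L, seed = 42L) {
  set.seed(seed)
  d <- c(B, cfg$n_bands, cfg$eeg_channels, cfg$windows)
  list(de = array(rnorm(prod(d)), d), psd = array(rnorm(prod(d)), d))
}

# set every trainable parameter of a model to zero
zero_all_params <- function(model) {
  for (nm in ls(model$params)) model$params[[nm]][] <- 0
  invisible(model)
}

# single Hann-windowed periodogram, written independently of welch_psd
periodogram_oracle <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  p <- Mod(fft(x * w))^2 / sum(w^2)
  nf <- n %/% 2 + 1
  p <- p[1:nf]
  scale <- rep(2, nf)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / n, psd = p * scale)
}

# nearest-class-centroid classifier on flattened tensors: the brute-force
# linear-discriminant (identity covariance) separability check
centroid_accuracy <- function(x, labels, train_frac = 0.7, seed = 1) {
  set.seed(seed)
  X <- matrix(x, dim(x)[1])
  n <- nrow(X)
  tr <- sample.int(n, round(train_frac * n))
  te <- setdiff(seq_len(n), tr)
  cls <- sort(unique(labels))
  cent <- t(vapply(cls, function(k) colMeans(X[intersect(tr, which(labels == k)), ,
                                               drop = FALSE]),
                   numeric(ncol(X))))
  d2 <- vapply(seq_len(nrow(cent)), function(k) {
    rowSums(sweep(X[te, , drop = FALSE], 2, cent[k, ])^2)
  }, numeric(length(te)))
  pred <- cls[max.col(-d2, ties.method = "first")]
  mean(pred == labels[te])
}
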