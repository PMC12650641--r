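# Public module-level operations. These run the same internal code paths as
# the assembled network, in evaluation mode, on user-facing batch-first
# arrays, taking their weights from a `tanet_model` so tests and users can
# hand-set individual tensors via `model$params`.

# batch-first (B, C, H, W) <-> internal batch-last (C, H, W, B)
pub_to_chwb <- function(x) aperm(x, c(2, 3, 4, 1))
chwb_to_pub <- function(x) aperm(x, c(4, 1, 2, 3))

# batch-first (B, T, D) <-> internal (T*B, D) token-fastest matrix
seq_to_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(2, 1, 3)), d[2] * d[1], d[3])
}
mat_to_seq <- function(m, Tn, B) {
  aperm(array(m, c(Tn, B, ncol(m))), c(2, 1, 3))
}

# (B, C, T) <-> per-band internal (C*B, T) channel-fastest matrix
bct_to_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(2, 1, 3)), d[2] * d[1], d[3])
}
mat_to_bct <- function(m, C, B) {
  aperm(array(m, c(C, B, ncol(m))), c(2, 1, 3))
}

#' Scaled dot-product attention
#'
#' The standard attention primitive
#' \eqn{\mathrm{softmax}(QK^\top/\sqrt{d_k})\,V}.
#'
#' @param Q query matrix (m x dk).
#' @param K key matrix (n x dk).
#' @param V value matrix (n x dv).
#' @param dk scaling dimension; defaults to `ncol(Q)`.
#' @return The (m x dv) attention output, with the (m x n) attention-weight
#'   matrix attached as attribute `"weights"` (rows sum to one).
#' @export
scaled_dot_attention <- function(Q, K, V, dk = ncol(Q)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share the inner dimension")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  Wt <- softmax_rows(tcrossprod(Q, K) / sqrt(dk))
  out <- Wt %*% V
  attr(out, "weights") <- Wt
  out
}

mca_check <- function(de, psd) {
  if (!identical(dim(de), dim(psd))) {
    stop("DE and PSD feature maps must have identical shapes")
  }
}

#' Unidirectional cross-modal attention fusion
#'
#' Queries are projected from the DE modality, keys and values from the PSD
#' modality; attention runs over channel tokens and the result is projected
#' back to the window dimension, so the output shape equals the input shape.
#'
#' @param de,psd (batch, channels, windows) arrays for one frequency band.
#' @param model a `tanet_model` supplying the projection weights.
#' @param band which band's weights to use.
#' @param training logical; apply dropout.
#' @return Fused (batch, channels, windows) array.
#' @export
mca_unidirectional <- function(de, psd, model, band = 1L, training = FALSE) {
  mca_check(de, psd)
  B <- dim(de)[1]; C <- dim(de)[2]
  cfg <- model$config
  cfg$bidirectional <- FALSE
  lv <- wrap_leaves(model$params)
  out <- fwd_mca_band(NULL, lv, cfg, band, ad_leaf(bct_to_mat(de)),
                      ad_leaf(bct_to_mat(psd)), B, training)
  mat_to_bct(ad_val(out), C, B)
}

#' Bidirectional (mutual) cross-modal attention fusion
#'
#' Sum of the two directed attention outputs: DE querying PSD plus PSD
#' querying DE, each with its own projections.
#'
#' @inheritParams mca_unidirectional
#' @return Fused (batch, channels, windows) array.
#' @export
mca_bidirectional <- function(de, psd, model, band = 1L, training = FALSE) {
  mca_check(de, psd)
  if (!model$config$bidirectional) {
    stop("model was not configured with bidirectional cross-modal attention")
  }
  B <- dim(de)[1]; C <- dim(de)[2]
  lv <- wrap_leaves(model$params)
  out <- fwd_mca_band(NULL, lv, model$config, band, ad_leaf(bct_to_mat(de)),
                      ad_leaf(bct_to_mat(psd)), B, training)
  mat_to_bct(ad_val(out), C, B)
}

#' Fuse all frequency bands with per-band cross-modal attention
#'
#' Applies one independent cross-modal attention per band and stacks the
#' outputs: band-first (batch, bands, channels, windows) for the SEED-style
#' layout, channel-first (batch, channels, bands, windows) for the DEAP-style
#' layout.
#'
#' @param de4d,psd4d (batch, bands, channels, windows) tensors.
#' @param model a `tanet_model`; its layout decides the stacking order and
#'   whether fusion is bidirectional.
#' @param training logical; apply dropout.
#' @return The stacked fused tensor.
#' @export
fuse_all_bands <- function(de4d, psd4d, model, training = FALSE) {
  if (!identical(dim(de4d), dim(psd4d))) stop("modality shapes differ")
  cfg <- model$config
  if (dim(de4d)[2] != cfg$n_bands) {
    stop("band count mismatch: model expects ", cfg$n_bands)
  }
  B <- dim(de4d)[1]; C <- dim(de4d)[3]; Tn <- dim(de4d)[4]
  lv <- wrap_leaves(model$params)
  de_b <- split_bands(de4d)
  psd_b <- split_bands(psd4d)
  out <- array(0, dim(de4d))
  for (f in seq_len(cfg$n_bands)) {
    m <- fwd_mca_band(NULL, lv, cfg, f, ad_leaf(de_b[[f]]),
                      ad_leaf(psd_b[[f]]), B, training)
    out[, f, , ] <- mat_to_bct(ad_val(m), C, B)
  }
  if (cfg$layout == "deap_like") aperm(out, c(1, 3, 2, 4)) else out
}

#' CBAM channel attention
#'
#' Global average- and max-pooled channel descriptors pass through a shared
#' two-layer MLP; the element-wise sum goes through a sigmoid.
#'
#' @param F4 input feature map (batch, channels, height, width).
#' @param model a `tanet_model` supplying the MLP weights.
#' @return Channel gates of shape (batch, channels, 1, 1), all in (0, 1).
#' @export
channel_attention <- function(F4, model) {
  lv <- wrap_leaves(model$params)
  mc <- ad_val(fwd_cbam_mc(NULL, lv, model$config, ad_leaf(pub_to_chwb(F4))))
  array(t(mc), c(dim(F4)[1], dim(F4)[2], 1, 1))
}

#' CBAM spatial attention
#'
#' Channel-wise mean and max maps are stacked and convolved with a k x k
#' kernel ("same" padding), then passed through a sigmoid.
#'
#' @param F4 input feature map (batch, channels, height, width).
#' @param model a `tanet_model` supplying the convolution kernel.
#' @return Spatial gates of shape (batch, 1, height, width), all in (0, 1).
#' @export
spatial_attention <- function(F4, model) {
  lv <- wrap_leaves(model$params)
  ms <- ad_val(fwd_cbam_ms(NULL, lv, model$config, ad_leaf(pub_to_chwb(F4))))
  d <- dim(F4)
  array(aperm(ms, c(3, 1, 2)), c(d[1], 1, d[3], d[4]))
}

#' CBAM refinement: channel then spatial gating
#'
#' @param F4 input feature map (batch, channels, height, width).
#' @param model a `tanet_model`.
#' @return Refined feature map of the same shape; because both gates lie in
#'   (0, 1) the output never exceeds the input in magnitude.
#' @export
cbam_refine <- function(F4, model) {
  lv <- wrap_leaves(model$params)
  out <- fwd_cbam(NULL, lv, model$config, ad_leaf(pub_to_chwb(F4)),
                  dim(F4)[1], FALSE)
  chwb_to_pub(ad_val(out))
}

#' Plain 2-D convolution (stride 1, "same" zero padding)
#'
#' @param x input (batch, in_channels, height, width).
#' @param kernel (out_channels, in_channels, kh, kw) weight array; odd kh, kw.
#' @param bias optional per-output-channel bias.
#' @return Output (batch, out_channels, height, width).
#' @export
conv2d <- function(x, kernel, bias = NULL) {
  kd <- dim(kernel)
  if (kd[2] != dim(x)[2]) stop("kernel input channels do not match input")
  Wm <- matrix(kernel, kd[1], kd[2] * kd[3] * kd[4])
  out <- ad_conv2d(NULL, ad_leaf(pub_to_chwb(x)), ad_leaf(Wm),
                   if (is.null(bias)) NULL else ad_leaf(bias),
                   kd[3], kd[4])
  chwb_to_pub(ad_val(out))
}

#' Two-stage convolutional feature extractor
#'
#' Two (convolution, batch-normalisation, GELU) stages with 3 x 3 kernels and
#' "same" padding; channel counts follow the model configuration
#' (bands -> 32 -> 64 by default).
#'
#' @param x input (batch, bands, height, width).
#' @param model a `tanet_model`.
#' @param training logical; batch statistics vs running statistics.
#' @return Output (batch, conv_channels[2], height, width).
#' @export
conv_block <- function(x, model, training = FALSE) {
  if (dim(x)[2] != model$config$n_bands) {
    stop("expected ", model$config$n_bands, " input channels")
  }
  lv <- wrap_leaves(model$params)
  out <- fwd_conv_block(NULL, lv, model$config, model$state,
                        ad_leaf(pub_to_chwb(x)), training)
  chwb_to_pub(ad_val(out))
}

#' Adaptive average pooling to a fixed spatial size
#'
#' Partitions each spatial axis into `output_size` near-equal bins and
#' averages within each bin; an axis shorter than its target is upsampled by
#' bin replication.
#'
#' @param x input (batch, channels, height, width).
#' @param output_size integer pair, default (31, 10).
#' @return Output (batch, channels, output_size[1], output_size[2]).
#' @export
adaptive_average_pool <- function(x, output_size = c(31L, 10L)) {
  out <- ad_adaptive_pool(NULL, ad_leaf(pub_to_chwb(x)),
                          output_size[1], output_size[2])
  chwb_to_pub(ad_val(out))
}

#' Project pooled CNN features to the Conformer sequence
#'
#' The time axis becomes the token axis; per-token features (channels x
#' height, 1984 in the default configuration) are linearly mapped to
#' `d_model` and layer-normalised.
#'
#' @param x input (batch, channels, height, windows) from the pooling stage.
#' @param model a `tanet_model`.
#' @return Sequence tensor (batch, windows, d_model).
#' @export
sequence_projection <- function(x, model) {
  d <- dim(x)
  fan_in <- d[2] * d[3]
  if (fan_in != nrow(model$params$proj.W)) {
    stop("flattened per-token size ", fan_in, " does not match projection fan-in ",
         nrow(model$params$proj.W))
  }
  lv <- wrap_leaves(model$params)
  xi <- pub_to_chwb(x)                       # (C, H, W, B)
  S <- matrix(aperm(array(xi, c(fan_in, d[4], d[1])), c(2, 3, 1)),
              d[4] * d[1], fan_in)
  S <- ad_linear(NULL, ad_leaf(S), lv$proj.W, lv$proj.b)
  S <- ad_layernorm(NULL, S, lv$proj.ln.gamma, lv$proj.ln.beta)
  mat_to_seq(ad_val(S), d[4], d[1])
}

#' Conformer feed-forward module
#'
#' Pre-layer-norm two-layer MLP with GELU and dropout:
#' `Dropout(Linear2(GELU(Linear1(LayerNorm(x)))))`.
#'
#' @param x sequence tensor (batch, tokens, d_model).
#' @param model a `tanet_model`.
#' @param block Conformer block index.
#' @param which 1 for the leading, 2 for the trailing feed-forward module.
#' @param training logical; apply dropout.
#' @return Same-shaped tensor.
#' @export
conformer_ffn <- function(x, model, block = 1L, which = 1L, training = FALSE) {
  lv <- wrap_leaves(model$params)
  prefix <- sprintf("conf%d.ffn%d.", block, which)
  out <- fwd_ffn(NULL, lv, model$config, prefix, ad_leaf(seq_to_mat(x)),
                 training)
  mat_to_seq(ad_val(out), dim(x)[2], dim(x)[1])
}

#' Conformer convolution module
#'
#' LayerNorm, depthwise 1-D convolution along tokens (zero padded),
#' BatchNorm, GELU, pointwise (1 x 1) convolution, dropout.
#'
#' @inheritParams conformer_ffn
#' @return Same-shaped tensor.
#' @export
conformer_conv_module <- function(x, model, block = 1L, training = FALSE) {
  lv <- wrap_leaves(model$params)
  out <- fwd_conv_module(NULL, lv, model$config, model$state,
                         sprintf("conf%d.", block), ad_leaf(seq_to_mat(x)),
                         dim(x)[2], dim(x)[1], training)
  mat_to_seq(ad_val(out), dim(x)[2], dim(x)[1])
}

#' One full Conformer block
#'
#' Half-step feed-forward, multi-head self-attention, convolution module and
#' a second half-step feed-forward, each pre-layer-normalised with residual
#' connections, followed by a final layer normalisation.
#'
#' @inheritParams conformer_ffn
#' @param keep_attn logical; attach the per-(sample, head) self-attention
#'   matrices as attribute `"attn"`.
#' @return Same-shaped tensor.
#' @export
conformer_block <- function(x, model, block = 1L, training = FALSE,
                            keep_attn = FALSE) {
  lv <- wrap_leaves(model$params)
  out <- fwd_conformer_block(NULL, lv, model$config, model$state, block,
                             ad_leaf(seq_to_mat(x)), dim(x)[2], dim(x)[1],
                             training, keep_attn = keep_attn)
  res <- mat_to_seq(ad_val(out), dim(x)[2], dim(x)[1])
  if (keep_attn) attr(res, "attn") <- attr(out, "attn")
  res
}

#' Classification head
#'
#' Three fully connected layers (GELU and dropout on the first two) followed
#' by a softmax.
#'
#' @param x pooled features (batch, d_model).
#' @param model a `tanet_model`.
#' @param training logical; apply dropout.
#' @return (batch, n_classes) probability matrix; rows sum to one.
#' @export
classifier_head <- function(x, model, training = FALSE) {
  lv <- wrap_leaves(model$params)
  logits <- fwd_classifier(NULL, lv, model$config, ad_leaf(as.matrix(x)),
                           training)
  softmax_rows(ad_val(logits))
}

#' Trace the shape of every pipeline stage
#'
#' Runs a forward pass and records the batch-first shape after each named
#' stage, for checking the layer-by-layer dimension ledger.
#'
#' @param model a `tanet_model`.
#' @param de,psd input tensors (batch, bands, channels, windows).
#' @return Named list of integer shape vectors (batch dimension first).
#' @export
tanet_shape_trace <- function(model, de, psd) {
  out <- tanet_forward_core(model, de, psd, training = FALSE, trace = TRUE)
  sh <- out$shapes
  B <- out$batch
  conv <- function(nm, d) {
    switch(nm,
      mca_band = c(B, d[1] / B),                     # (C*B, T) -> (B, C, T)
      fused = , cbam = , conv1 = , conv2 = , pool = c(B, d[-length(d)]),
      tokens = , projected = , conformer1 = , conformer2 =
        c(B, d[1] / B, d[2]),                        # (T*B, D) -> (B, T, D)
      d)
  }
  res <- list()
  for (nm in names(sh)) {
    d <- sh[[nm]]
    r <- conv(nm, d)
    if (nm == "mca_band") r <- c(r[1], r[2], model$config$windows)
    res[[nm]] <- as.integer(r)
  }
  res
}
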