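# Model configuration, parameter initialisation, and the end-to-end forward
# pass of the triple-attention network (cross-modal attention fusion, CBAM
# refinement, CNN feature extraction, Conformer temporal modelling,
# MLP classifier).
#
# Convention notes. Query/key/value projections (in both the cross-modal
# attention and the multi-head self-attention) carry no bias, following the
# original-Transformer convention; convolutions immediately followed by batch
# normalisation are also bias-free, since the normalisation supplies the
# shift. Under these conventions the default SEED-style configuration counts
# 3,344,019 trainable parameters (3.34 M at two decimals).

#' Model configuration
#'
#' Builds the full architectural hyperparameter set of the triple-attention
#' network. Defaults reproduce the SEED-style configuration: 5 frequency
#' bands, 62 EEG channels, 10 time windows, 3 emotion classes. Use
#' `layout = "deap_like"` for the 32-channel binary-classification variant
#' with bidirectional cross-modal attention.
#'
#' @param layout `"seed_like"` or `"deap_like"`.
#' @param n_bands number of frequency bands (feature-map channels entering
#'   the CNN).
#' @param eeg_channels number of EEG electrodes (spatial height).
#' @param windows number of time windows (token/sequence length after
#'   projection for the seed layout).
#' @param n_classes number of emotion classes.
#' @param att_dim cross-modal attention dimension \eqn{d_k}.
#' @param mca_dropout dropout rate on the attention fusion output.
#' @param bidirectional logical; mutual (two-direction, summed) cross-modal
#'   attention as used for the DEAP-style layout.
#' @param cbam_reduction channel-attention MLP reduction ratio.
#' @param cbam_kernel spatial-attention convolution kernel size (odd).
#' @param cbam_bias logical; keep biases in the CBAM MLP and convolution.
#' @param conv_channels two CNN output channel counts.
#' @param pool_target adaptive average-pooling output size (H, W).
#' @param d_model Conformer embedding width.
#' @param n_heads self-attention heads (must divide `d_model`).
#' @param conformer_kernel depthwise convolution kernel length.
#' @param ffn_expansion feed-forward hidden width multiplier.
#' @param n_blocks number of Conformer blocks.
#' @param conformer_dropout internal Conformer dropout rate.
#' @param classifier_dims hidden widths of the classifier head.
#' @param dropout_cls dropout rates of the two hidden classifier layers.
#' @param use_mca,use_cbam,use_conformer module switches for ablation: a
#'   disabled MCA is replaced by the element-wise mean of the two
#'   modalities, a disabled CBAM by the identity, and a disabled Conformer
#'   by direct global average pooling of the projected tokens.
#' @return A list of class `"tanet_config"`.
#' @export
tanet_config <- function(layout = c("seed_like", "deap_like"),
                         n_bands = 5L,
                         eeg_channels = NULL,
                         windows = NULL,
                         n_classes = NULL,
                         att_dim = 32L,
                         mca_dropout = 0.3,
                         bidirectional = NULL,
                         cbam_reduction = 4L,
                         cbam_kernel = 7L,
                         cbam_bias = TRUE,
                         conv_channels = c(32L, 64L),
                         pool_target = c(31L, 10L),
                         d_model = 256L,
                         n_heads = 8L,
                         conformer_kernel = 5L,
                         ffn_expansion = 4L,
                         n_blocks = 2L,
                         conformer_dropout = 0.1,
                         classifier_dims = c(128L, 64L),
                         dropout_cls = c(0.3, 0.2),
                         use_mca = TRUE,
                         use_cbam = TRUE,
                         use_conformer = TRUE) {
  layout <- match.arg(layout)
  if (is.null(eeg_channels)) eeg_channels <- if (layout == "seed_like") 62L else 32L
  if (is.null(windows)) windows <- if (layout == "seed_like") 10L else 3L
  if (is.null(n_classes)) n_classes <- if (layout == "seed_like") 3L else 2L
  if (is.null(bidirectional)) bidirectional <- layout == "deap_like"
  stopifnot(d_model %% n_heads == 0,
            cbam_kernel %% 2 == 1,
            length(conv_channels) == 2,
            length(classifier_dims) == 2)
  cfg <- list(layout = layout, n_bands = as.integer(n_bands),
              eeg_channels = as.integer(eeg_channels),
              windows = as.integer(windows),
              n_classes = as.integer(n_classes),
              att_dim = as.integer(att_dim), mca_dropout = mca_dropout,
              bidirectional = bidirectional,
              cbam_reduction = as.integer(cbam_reduction),
              cbam_kernel = as.integer(cbam_kernel), cbam_bias = cbam_bias,
              conv_channels = as.integer(conv_channels),
              pool_target = as.integer(pool_target),
              d_model = as.integer(d_model), n_heads = as.integer(n_heads),
              conformer_kernel = as.integer(conformer_kernel),
              ffn_expansion = as.integer(ffn_expansion),
              n_blocks = as.integer(n_blocks),
              conformer_dropout = conformer_dropout,
              classifier_dims = as.integer(classifier_dims),
              dropout_cls = dropout_cls,
              use_mca = use_mca, use_cbam = use_cbam,
              use_conformer = use_conformer)
  class(cfg) <- "tanet_config"
  cfg
}

# package-local shape tracer used by tanet_shape_trace()
trace_env <- new.env(parent = emptyenv())
trace_env$active <- FALSE

trace_note <- function(nm, v) {
  if (trace_env$active) {
    d <- dim(ad_val(v))
    if (is.null(d)) d <- length(ad_val(v))
    trace_env$shapes[[nm]] <- d
  }
  invisible(NULL)
}

# uniform init over (-1/sqrt(fan_in), 1/sqrt(fan_in))
init_mat <- function(nr, nc, fan_in) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

init_vec <- function(n, fan_in) {
  b <- 1 / sqrt(fan_in)
  stats::runif(n, -b, b)
}

mca_param_names <- function(cfg, band) {
  p <- sprintf("mca.b%d.", band)
  base <- paste0(p, c("Wq", "Wk", "Wv", "Wo", "bo"))
  if (cfg$bidirectional) c(base, paste0(p, c("Wq2", "Wk2", "Wv2", "Wo2", "bo2")))
  else base
}

init_mca_band <- function(params, cfg, band) {
  Tn <- cfg$windows; A <- cfg$att_dim
  p <- sprintf("mca.b%d.", band)
  params[[paste0(p, "Wq")]] <- init_mat(Tn, A, Tn)
  params[[paste0(p, "Wk")]] <- init_mat(Tn, A, Tn)
  params[[paste0(p, "Wv")]] <- init_mat(Tn, A, Tn)
  params[[paste0(p, "Wo")]] <- init_mat(A, Tn, A)
  params[[paste0(p, "bo")]] <- init_vec(Tn, A)
  if (cfg$bidirectional) {
    params[[paste0(p, "Wq2")]] <- init_mat(Tn, A, Tn)
    params[[paste0(p, "Wk2")]] <- init_mat(Tn, A, Tn)
    params[[paste0(p, "Wv2")]] <- init_mat(Tn, A, Tn)
    params[[paste0(p, "Wo2")]] <- init_mat(A, Tn, A)
    params[[paste0(p, "bo2")]] <- init_vec(Tn, A)
  }
}

#' Assemble an untrained model
#'
#' Creates all trainable parameters (seeded) and the batch-normalisation
#' running statistics for a given configuration.
#'
#' @param config a [tanet_config()] object.
#' @param seed integer RNG seed for the parameter initialisation.
#' @return A list of class `"tanet_model"` with elements `config`, `params`
#'   (an environment of named arrays) and `state` (running statistics).
#' @export
tanet_model <- function(config = tanet_config(), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cfg <- config
  params <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())

  if (cfg$use_mca) {
    for (f in seq_len(cfg$n_bands)) init_mca_band(params, cfg, f)
  }

  if (cfg$use_cbam) {
    Cb <- cfg$n_bands
    hid <- max(1L, as.integer(ceiling(Cb / cfg$cbam_reduction)))
    params$cbam.mlp1.W <- init_mat(Cb, hid, Cb)
    params$cbam.mlp2.W <- init_mat(hid, Cb, hid)
    k <- cfg$cbam_kernel
    params$cbam.conv.W <- init_mat(1, 2 * k * k, 2 * k * k)
    if (cfg$cbam_bias) {
      params$cbam.mlp1.b <- init_vec(hid, Cb)
      params$cbam.mlp2.b <- init_vec(Cb, hid)
      params$cbam.conv.b <- init_vec(1, 2 * k * k)
    }
  }

  c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
  params$cnn.conv1.W <- init_mat(c1, cfg$n_bands * 9L, cfg$n_bands * 9L)
  params$cnn.bn1.gamma <- rep(1, c1)
  params$cnn.bn1.beta <- rep(0, c1)
  params$cnn.conv2.W <- init_mat(c2, c1 * 9L, c1 * 9L)
  params$cnn.bn2.gamma <- rep(1, c2)
  params$cnn.bn2.beta <- rep(0, c2)
  state$cnn.bn1 <- list(mean = rep(0, c1), var = rep(1, c1))
  state$cnn.bn2 <- list(mean = rep(0, c2), var = rep(1, c2))

  fan_in <- c2 * cfg$pool_target[1]
  D <- cfg$d_model
  params$proj.W <- init_mat(fan_in, D, fan_in)
  params$proj.b <- init_vec(D, fan_in)
  params$proj.ln.gamma <- rep(1, D)
  params$proj.ln.beta <- rep(0, D)

  if (cfg$use_conformer) {
    hidden <- D * cfg$ffn_expansion
    for (i in seq_len(cfg$n_blocks)) {
      p <- sprintf("conf%d.", i)
      for (f in c("ffn1.", "ffn2.")) {
        params[[paste0(p, f, "ln.gamma")]] <- rep(1, D)
        params[[paste0(p, f, "ln.beta")]] <- rep(0, D)
        params[[paste0(p, f, "W1")]] <- init_mat(D, hidden, D)
        params[[paste0(p, f, "b1")]] <- init_vec(hidden, D)
        params[[paste0(p, f, "W2")]] <- init_mat(hidden, D, hidden)
        params[[paste0(p, f, "b2")]] <- init_vec(D, hidden)
      }
      params[[paste0(p, "mhsa.ln.gamma")]] <- rep(1, D)
      params[[paste0(p, "mhsa.ln.beta")]] <- rep(0, D)
      params[[paste0(p, "mhsa.Wq")]] <- init_mat(D, D, D)
      params[[paste0(p, "mhsa.Wk")]] <- init_mat(D, D, D)
      params[[paste0(p, "mhsa.Wv")]] <- init_mat(D, D, D)
      params[[paste0(p, "mhsa.Wo")]] <- init_mat(D, D, D)
      params[[paste0(p, "mhsa.bo")]] <- init_vec(D, D)
      params[[paste0(p, "conv.ln.gamma")]] <- rep(1, D)
      params[[paste0(p, "conv.ln.beta")]] <- rep(0, D)
      params[[paste0(p, "conv.dw.W")]] <- init_mat(cfg$conformer_kernel, D,
                                                   cfg$conformer_kernel)
      params[[paste0(p, "conv.bn.gamma")]] <- rep(1, D)
      params[[paste0(p, "conv.bn.beta")]] <- rep(0, D)
      params[[paste0(p, "conv.pw.W")]] <- init_mat(D, D, D)
      params[[paste0(p, "conv.pw.b")]] <- init_vec(D, D)
      params[[paste0(p, "final_ln.gamma")]] <- rep(1, D)
      params[[paste0(p, "final_ln.beta")]] <- rep(0, D)
      state[[paste0(p, "bn")]] <- list(mean = rep(0, D), var = rep(1, D))
    }
  }

  h1 <- cfg$classifier_dims[1]; h2 <- cfg$classifier_dims[2]
  params$cls.W1 <- init_mat(D, h1, D)
  params$cls.b1 <- init_vec(h1, D)
  params$cls.W2 <- init_mat(h1, h2, h1)
  params$cls.b2 <- init_vec(h2, h1)
  params$cls.W3 <- init_mat(h2, cfg$n_classes, h2)
  params$cls.b3 <- init_vec(cfg$n_classes, h2)

  model <- list(config = cfg, params = params, state = state)
  class(model) <- "tanet_model"
  model
}

#' Count trainable parameters
#'
#' @param model a `tanet_model`.
#' @param freeze character vector of name prefixes to exclude from the count
#'   (e.g. `"cls."` to freeze the classifier head).
#' @return Integer total of trainable tensor elements.
#' @export
count_trainable_parameters <- function(model, freeze = character()) {
  nms <- ls(model$params)
  for (p in freeze) nms <- nms[!startsWith(nms, p)]
  sum(vapply(nms, function(n) length(model$params[[n]]), numeric(1)))
}

# wrap every parameter as a leaf node for one forward/backward pass
wrap_leaves <- function(params) {
  nms <- ls(params)
  lv <- new.env(parent = emptyenv())
  for (n in nms) lv[[n]] <- ad_leaf(params[[n]])
  lv
}

# ---- forward-pass building blocks (internal layouts) -------------------
# Per-band modality slices are (channels*batch, windows) matrices with rows
# ordered channel-fastest; 4-D feature maps are (C, H, W, B) arrays with the
# batch last; sequence tensors are (tokens*batch, d_model) matrices with rows
# ordered token-fastest.

fwd_mca_band <- function(tape, lv, cfg, band, de_m, psd_m, batch, training) {
  C <- nrow(ad_val(de_m)) / batch
  p <- sprintf("mca.b%d.", band)
  att1 <- ad_attention(tape,
                       ad_linear(tape, de_m, lv[[paste0(p, "Wq")]]),
                       ad_linear(tape, psd_m, lv[[paste0(p, "Wk")]]),
                       ad_linear(tape, psd_m, lv[[paste0(p, "Wv")]]),
                       tokens = C, batch = batch, nheads = 1L)
  out <- ad_linear(tape, att1, lv[[paste0(p, "Wo")]], lv[[paste0(p, "bo")]])
  if (cfg$bidirectional) {
    att2 <- ad_attention(tape,
                         ad_linear(tape, psd_m, lv[[paste0(p, "Wq2")]]),
                         ad_linear(tape, de_m, lv[[paste0(p, "Wk2")]]),
                         ad_linear(tape, de_m, lv[[paste0(p, "Wv2")]]),
                         tokens = C, batch = batch, nheads = 1L)
    out2 <- ad_linear(tape, att2, lv[[paste0(p, "Wo2")]], lv[[paste0(p, "bo2")]])
    out <- ad_add(tape, out, out2)
  }
  ad_dropout(tape, out, cfg$mca_dropout, training)
}

# channel-attention gate: (C, B) sigmoid weights from shared two-layer MLP
fwd_cbam_mc <- function(tape, lv, cfg, Fm) {
  b1 <- if (cfg$cbam_bias) lv$cbam.mlp1.b else NULL
  b2 <- if (cfg$cbam_bias) lv$cbam.mlp2.b else NULL
  mlp <- function(x) {
    ad_linear(tape, ad_relu(tape, ad_linear(tape, x, lv$cbam.mlp1.W, b1)),
              lv$cbam.mlp2.W, b2)
  }
  avg <- ad_aperm(tape, ad_mean_hw(tape, Fm), c(2, 1))
  mx <- ad_aperm(tape, ad_max_hw(tape, Fm), c(2, 1))
  mc <- ad_sigmoid(tape, ad_add(tape, mlp(avg), mlp(mx)))
  ad_aperm(tape, mc, c(2, 1))
}

# spatial-attention map: (H, W, B) sigmoid weights from a k x k convolution
# over the stacked channel-mean and channel-max maps
fwd_cbam_ms <- function(tape, lv, cfg, Fp) {
  sp <- ad_stack_first(tape, list(ad_mean_c(tape, Fp), ad_max_c(tape, Fp)))
  k <- cfg$cbam_kernel
  cb <- if (cfg$cbam_bias) lv$cbam.conv.b else NULL
  ms <- ad_sigmoid(tape, ad_conv2d(tape, sp, lv$cbam.conv.W, cb, k, k))
  d <- dim(ad_val(ms))
  ad_reshape(tape, ms, d[2:4])
}

fwd_cbam <- function(tape, lv, cfg, Fm, batch, training) {
  Fp <- ad_gate_channel(tape, Fm, fwd_cbam_mc(tape, lv, cfg, Fm))
  ad_gate_spatial(tape, Fp, fwd_cbam_ms(tape, lv, cfg, Fp))
}

fwd_conv_block <- function(tape, lv, cfg, state, x, training) {
  d <- dim(ad_val(x))
  bn_apply <- function(h, key, gamma, beta) {
    dh <- dim(ad_val(h))
    hm <- ad_reshape(tape, ad_aperm(tape, h, c(2, 3, 4, 1)),
                     c(prod(dh[2:4]), dh[1]))
    hm <- ad_batchnorm(tape, hm, gamma, beta, state, key, training)
    ad_aperm(tape, ad_reshape(tape, hm, c(dh[2], dh[3], dh[4], dh[1])),
             c(4, 1, 2, 3))
  }
  h <- ad_conv2d(tape, x, lv$cnn.conv1.W, NULL, 3L, 3L)
  h <- ad_gelu(tape, bn_apply(h, "cnn.bn1", lv$cnn.bn1.gamma, lv$cnn.bn1.beta))
  trace_note("conv1", h)
  h <- ad_conv2d(tape, h, lv$cnn.conv2.W, NULL, 3L, 3L)
  h <- ad_gelu(tape, bn_apply(h, "cnn.bn2", lv$cnn.bn2.gamma, lv$cnn.bn2.beta))
  trace_note("conv2", h)
  h
}

fwd_ffn <- function(tape, lv, cfg, prefix, x, training) {
  h <- ad_layernorm(tape, x, lv[[paste0(prefix, "ln.gamma")]],
                    lv[[paste0(prefix, "ln.beta")]])
  h <- ad_gelu(tape, ad_linear(tape, h, lv[[paste0(prefix, "W1")]],
                               lv[[paste0(prefix, "b1")]]))
  h <- ad_linear(tape, h, lv[[paste0(prefix, "W2")]], lv[[paste0(prefix, "b2")]])
  ad_dropout(tape, h, cfg$conformer_dropout, training)
}

fwd_conv_module <- function(tape, lv, cfg, state, prefix, x, tokens, batch,
                            training) {
  h <- ad_layernorm(tape, x, lv[[paste0(prefix, "conv.ln.gamma")]],
                    lv[[paste0(prefix, "conv.ln.beta")]])
  h <- ad_depthwise_tokens(tape, h, lv[[paste0(prefix, "conv.dw.W")]],
                           tokens, batch)
  h <- ad_batchnorm(tape, h, lv[[paste0(prefix, "conv.bn.gamma")]],
                    lv[[paste0(prefix, "conv.bn.beta")]], state,
                    paste0(prefix, "bn"), training)
  h <- ad_gelu(tape, h)
  h <- ad_linear(tape, h, lv[[paste0(prefix, "conv.pw.W")]],
                 lv[[paste0(prefix, "conv.pw.b")]])
  ad_dropout(tape, h, cfg$conformer_dropout, training)
}

fwd_conformer_block <- function(tape, lv, cfg, state, i, x, tokens, batch,
                                training, keep_attn = FALSE) {
  p <- sprintf("conf%d.", i)
  x <- ad_add(tape, x, ad_scale(tape, fwd_ffn(tape, lv, cfg, paste0(p, "ffn1."),
                                              x, training), 0.5))
  h <- ad_layernorm(tape, x, lv[[paste0(p, "mhsa.ln.gamma")]],
                    lv[[paste0(p, "mhsa.ln.beta")]])
  att <- ad_attention(tape,
                      ad_linear(tape, h, lv[[paste0(p, "mhsa.Wq")]]),
                      ad_linear(tape, h, lv[[paste0(p, "mhsa.Wk")]]),
                      ad_linear(tape, h, lv[[paste0(p, "mhsa.Wv")]]),
                      tokens = tokens, batch = batch, nheads = cfg$n_heads,
                      keep_weights = keep_attn)
  attn_w <- attr(att, "attn")
  o <- ad_linear(tape, att, lv[[paste0(p, "mhsa.Wo")]], lv[[paste0(p, "mhsa.bo")]])
  x <- ad_add(tape, x, ad_dropout(tape, o, cfg$conformer_dropout, training))
  x <- ad_add(tape, x, fwd_conv_module(tape, lv, cfg, state, p, x, tokens,
                                       batch, training))
  x <- ad_add(tape, x, ad_scale(tape, fwd_ffn(tape, lv, cfg, paste0(p, "ffn2."),
                                              x, training), 0.5))
  out <- ad_layernorm(tape, x, lv[[paste0(p, "final_ln.gamma")]],
                      lv[[paste0(p, "final_ln.beta")]])
  if (keep_attn) attr(out, "attn") <- attn_w
  out
}

fwd_classifier <- function(tape, lv, cfg, x, training) {
  h <- ad_gelu(tape, ad_linear(tape, x, lv$cls.W1, lv$cls.b1))
  h <- ad_dropout(tape, h, cfg$dropout_cls[1], training)
  trace_note("cls1", h)
  h <- ad_gelu(tape, ad_linear(tape, h, lv$cls.W2, lv$cls.b2))
  h <- ad_dropout(tape, h, cfg$dropout_cls[2], training)
  trace_note("cls2", h)
  ad_linear(tape, h, lv$cls.W3, lv$cls.b3)
}

# split a public (B, F, C, T) array into per-band (C*B, T) matrices
split_bands <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[2]), function(f) {
    sl <- array(x[, f, , ], c(d[1], d[3], d[4]))
    matrix(aperm(sl, c(2, 1, 3)), d[1] * d[3], d[4])
  })
}

# rebuild (C, T, B) from a (C*B, T) matrix
band_to_ctb <- function(tape, m, C, B, Tn) {
  ad_aperm(tape, ad_reshape(tape, m, c(C, B, Tn)), c(1, 3, 2))
}

# Full forward pass. de/psd: public (B, F, C, T) arrays, or `fused` a public
# (B, F, C, T) pre-fused tensor (DEAP segment path). Returns logits node plus
# the leaf environment and an optional shape trace.
tanet_forward_core <- function(model, de = NULL, psd = NULL, fused = NULL,
                               training = FALSE, tape = NULL, trace = FALSE,
                               keep_attn = FALSE) {
  cfg <- model$config
  lv <- wrap_leaves(model$params)
  if (trace) {
    trace_env$active <- TRUE
    trace_env$shapes <- list()
    on.exit(trace_env$active <- FALSE)
  }
  note <- trace_note

  if (is.null(fused)) {
    stopifnot(length(dim(de)) == 4, identical(dim(de), dim(psd)))
    B <- dim(de)[1]
    Fb <- dim(de)[2]
    C <- dim(de)[3]
    Tn <- dim(de)[4]
    if (Fb != cfg$n_bands) {
      stop("expected ", cfg$n_bands, " bands, got ", Fb)
    }
    de_b <- split_bands(de)
    psd_b <- split_bands(psd)
    fused_b <- vector("list", Fb)
    for (f in seq_len(Fb)) {
      de_l <- ad_leaf(de_b[[f]])
      psd_l <- ad_leaf(psd_b[[f]])
      if (cfg$use_mca) {
        fused_b[[f]] <- fwd_mca_band(tape, lv, cfg, f, de_l, psd_l, B, training)
      } else {
        fused_b[[f]] <- ad_scale(tape, ad_add(tape, de_l, psd_l), 0.5)
      }
      if (f == 1L) note("mca_band", fused_b[[f]])
    }
    Fm <- ad_stack_first(tape, lapply(fused_b, band_to_ctb, tape = tape,
                                      C = C, B = B, Tn = Tn))
  } else {
    stopifnot(length(dim(fused)) == 4)
    B <- dim(fused)[1]
    C <- dim(fused)[3]
    Tn <- dim(fused)[4]
    Fm <- ad_leaf(aperm(fused, c(2, 3, 4, 1)))
  }
  note("fused", Fm)                                   # (F, C, T, B)

  if (cfg$use_cbam) Fm <- fwd_cbam(tape, lv, cfg, Fm, B, training)
  note("cbam", Fm)

  h <- fwd_conv_block(tape, lv, cfg, model$state, Fm, training)
  h <- ad_adaptive_pool(tape, h, cfg$pool_target[1], cfg$pool_target[2])
  note("pool", h)                                     # (64, 31, 10, B)

  d <- dim(ad_val(h))
  Tseq <- d[3]
  fan_in <- d[1] * d[2]
  h <- ad_reshape(tape, h, c(fan_in, Tseq, B))
  h <- ad_aperm(tape, h, c(2, 3, 1))                  # (T, B, fan_in)
  S <- ad_reshape(tape, h, c(Tseq * B, fan_in))
  note("tokens", S)
  S <- ad_linear(tape, S, lv$proj.W, lv$proj.b)
  S <- ad_layernorm(tape, S, lv$proj.ln.gamma, lv$proj.ln.beta)
  note("projected", S)                                # (T*B, 256)

  attn_w <- NULL
  if (cfg$use_conformer) {
    for (i in seq_len(cfg$n_blocks)) {
      S <- fwd_conformer_block(tape, lv, cfg, model$state, i, S, Tseq, B,
                               training, keep_attn = keep_attn)
      if (keep_attn && i == 1L) attn_w <- attr(S, "attn")
      note(sprintf("conformer%d", i), S)
    }
  }
  pooled <- ad_mean_tokens(tape, S, Tseq, B)
  note("pooled", pooled)                              # (B, 256)
  logits <- fwd_classifier(tape, lv, cfg, pooled, training)
  note("logits", logits)

  list(logits = logits, leaves = lv,
       shapes = if (trace) trace_env$shapes else NULL,
       batch = B, fan_in = fan_in, attn = attn_w)
}

#' Forward pass to class probabilities
#'
#' Runs the assembled network in evaluation mode (dropout off,
#' batch-normalisation running statistics) and returns softmax class
#' probabilities.
#'
#' @param model a `tanet_model`.
#' @param de,psd feature tensors of shape (batch, bands, channels, windows);
#'   both required unless `fused` is given.
#' @param fused optional pre-fused tensor of the same 4-D shape, used for the
#'   DEAP segment pipeline where cross-modal fusion happens upstream.
#' @return A (batch, n_classes) matrix of probabilities; rows sum to one.
#' @export
tanet_forward <- function(model, de = NULL, psd = NULL, fused = NULL) {
  out <- tanet_forward_core(model, de, psd, fused, training = FALSE)
  softmax_rows(ad_val(out$logits))
}
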