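# Reverse-mode automatic differentiation on a dynamic tape.
#
# Nodes are environments holding a value and (in training mode) a backward
# closure; the tape records nodes in creation order, which is a valid
# topological order for the feed-forward graphs built here. With a NULL tape
# the same op functions run in inference mode: values only, no graph.

#' Create a fresh autodiff tape
#'
#' @return An environment that records computation nodes for a single
#'   forward/backward pass.
#' @keywords internal
ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$n <- 0L
  e
}

ad_node_new <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (!is.null(tape) && !is.null(backward)) {
    nd$backward <- backward
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      length(tape$nodes) <- 2L * length(tape$nodes)
    }
    tape$nodes[[tape$n]] <- nd
  }
  class(nd) <- "ad_node"
  nd
}

#' Wrap a plain array as a leaf node (parameter or input)
#' @keywords internal
ad_leaf <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  class(nd) <- "ad_node"
  nd
}

ad_val <- function(x) if (inherits(x, "ad_node")) x$value else x

ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run the backward pass from a scalar loss node
#' @keywords internal
ad_backward <- function(tape, node, seed = 1) {
  node$grad <- seed
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# broadcast a length-d vector across the rows of an (n, d) matrix
rowb <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# ---- elementwise and linear ops ----------------------------------------

ad_add <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_node_new(tape, av + bv, backward = function(g) {
    if (inherits(a, "ad_node")) ad_accum(a, g)
    if (inherits(b, "ad_node")) ad_accum(b, g)
  })
}

ad_mul <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_node_new(tape, av * bv, backward = function(g) {
    if (inherits(a, "ad_node")) ad_accum(a, g * bv)
    if (inherits(b, "ad_node")) ad_accum(b, g * av)
  })
}

ad_scale <- function(tape, a, s) {
  av <- ad_val(a)
  ad_node_new(tape, av * s, backward = function(g) ad_accum(a, g * s))
}

# x: (n, din) matrix node; W: (din, dout); b: length-dout bias or NULL
ad_linear <- function(tape, x, W, b = NULL) {
  xv <- ad_val(x); Wv <- ad_val(W)
  y <- xv %*% Wv
  if (!is.null(b)) y <- y + rowb(ad_val(b), nrow(y))
  ad_node_new(tape, y, backward = function(g) {
    if (inherits(x, "ad_node")) ad_accum(x, g %*% t(Wv))
    ad_accum(W, crossprod(xv, g))
    if (!is.null(b)) ad_accum(b, colSums(g))
  })
}

ad_gelu <- function(tape, x) {
  xv <- ad_val(x)
  ph <- stats::pnorm(xv)
  ad_node_new(tape, xv * ph, backward = function(g) {
    ad_accum(x, g * (ph + xv * stats::dnorm(xv)))
  })
}

ad_relu <- function(tape, x) {
  xv <- ad_val(x)
  m <- xv > 0
  ad_node_new(tape, xv * m, backward = function(g) ad_accum(x, g * m))
}

ad_sigmoid <- function(tape, x) {
  xv <- ad_val(x)
  s <- stats::plogis(xv)
  ad_node_new(tape, s, backward = function(g) ad_accum(x, g * s * (1 - s)))
}

ad_reshape <- function(tape, x, dims) {
  xv <- ad_val(x)
  olddims <- if (is.null(dim(xv))) length(xv) else dim(xv)
  ad_node_new(tape, array(xv, dims), backward = function(g) {
    ad_accum(x, array(g, olddims))
  })
}

ad_aperm <- function(tape, x, perm) {
  xv <- ad_val(x)
  ad_node_new(tape, aperm(xv, perm), backward = function(g) {
    ad_accum(x, aperm(g, order(perm)))
  })
}

ad_dropout <- function(tape, x, p, training) {
  if (!training || p <= 0) return(x)
  xv <- ad_val(x)
  mask <- (stats::runif(length(xv)) >= p) / (1 - p)
  dim(mask) <- dim(xv)
  ad_node_new(tape, xv * mask, backward = function(g) ad_accum(x, g * mask))
}

# ---- normalisation -----------------------------------------------------

# row-wise layer norm of an (n, d) matrix; biased variance, eps inside sqrt
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- ad_val(x)
  n <- nrow(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  gv <- ad_val(gamma)
  y <- xhat * rowb(gv, n) + rowb(ad_val(beta), n)
  ad_node_new(tape, y, backward = function(g) {
    ad_accum(beta, colSums(g))
    ad_accum(gamma, colSums(g * xhat))
    dxh <- g * rowb(gv, n)
    if (inherits(x, "ad_node")) {
      ad_accum(x, (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * inv)
    }
  })
}

# batch norm over the rows of an (n, C) matrix (channels in columns).
# state is an environment; key indexes running statistics.
ad_batchnorm <- function(tape, x, gamma, beta, state, key, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- ad_val(x)
  n <- nrow(xv)
  gv <- ad_val(gamma)
  if (training) {
    mu <- colMeans(xv)
    xc <- xv - rowb(mu, n)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * rowb(inv, n)
    rs <- state[[key]]
    ub <- if (n > 1) v * n / (n - 1) else v
    state[[key]] <- list(mean = (1 - momentum) * rs$mean + momentum * mu,
                         var = (1 - momentum) * rs$var + momentum * ub)
    y <- xhat * rowb(gv, n) + rowb(ad_val(beta), n)
    ad_node_new(tape, y, backward = function(g) {
      ad_accum(beta, colSums(g))
      ad_accum(gamma, colSums(g * xhat))
      dxh <- g * rowb(gv, n)
      dx <- (dxh - rowb(colMeans(dxh), n) -
               xhat * rowb(colMeans(dxh * xhat), n)) * rowb(inv, n)
      if (inherits(x, "ad_node")) ad_accum(x, dx)
    })
  } else {
    rs <- state[[key]]
    inv <- 1 / sqrt(rs$var + eps)
    xhat <- (xv - rowb(rs$mean, n)) * rowb(inv, n)
    y <- xhat * rowb(gv, n) + rowb(ad_val(beta), n)
    ad_node_new(tape, y, backward = function(g) {
      ad_accum(beta, colSums(g))
      ad_accum(gamma, colSums(g * xhat))
      if (inherits(x, "ad_node")) ad_accum(x, g * rowb(gv * inv, n))
    })
  }
}

# ---- softmax / attention ----------------------------------------------

softmax_rows <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}

ad_softmax_rows <- function(tape, x) {
  p <- softmax_rows(ad_val(x))
  ad_node_new(tape, p, backward = function(g) {
    ad_accum(x, (g - rowSums(g * p)) * p)
  })
}

# Multi-head scaled dot-product attention over token rows.
# Q, K, V: (tokens*batch, d) matrices, rows ordered token-fastest then batch;
# d must divide by nheads. Returns an output node of the same shape; the
# per-(batch, head) attention matrices are attached as attr "attn" on request.
ad_attention <- function(tape, Q, K, V, tokens, batch, nheads,
                         keep_weights = FALSE) {
  Qv <- ad_val(Q); Kv <- ad_val(K); Vv <- ad_val(V)
  d <- ncol(Qv)
  dh <- d %/% nheads
  sc <- 1 / sqrt(dh)
  out <- matrix(0, nrow(Qv), d)
  P <- vector("list", batch * nheads)
  for (b in seq_len(batch)) {
    r <- (b - 1L) * tokens + seq_len(tokens)
    for (h in seq_len(nheads)) {
      cc <- (h - 1L) * dh + seq_len(dh)
      q <- Qv[r, cc, drop = FALSE]
      k <- Kv[r, cc, drop = FALSE]
      p <- softmax_rows(tcrossprod(q, k) * sc)
      P[[(b - 1L) * nheads + h]] <- p
      out[r, cc] <- p %*% Vv[r, cc, drop = FALSE]
    }
  }
  nd <- ad_node_new(tape, out, backward = function(g) {
    dQ <- matrix(0, nrow(Qv), d); dK <- dQ; dV <- dQ
    for (b in seq_len(batch)) {
      r <- (b - 1L) * tokens + seq_len(tokens)
      for (h in seq_len(nheads)) {
        cc <- (h - 1L) * dh + seq_len(dh)
        p <- P[[(b - 1L) * nheads + h]]
        go <- g[r, cc, drop = FALSE]
        v <- Vv[r, cc, drop = FALSE]
        dV[r, cc] <- crossprod(p, go)
        dp <- tcrossprod(go, v)
        ds <- ((dp - rowSums(dp * p)) * p) * sc
        dQ[r, cc] <- ds %*% Kv[r, cc, drop = FALSE]
        dK[r, cc] <- crossprod(ds, Qv[r, cc, drop = FALSE])
      }
    }
    if (inherits(Q, "ad_node")) ad_accum(Q, dQ)
    if (inherits(K, "ad_node")) ad_accum(K, dK)
    if (inherits(V, "ad_node")) ad_accum(V, dV)
  })
  if (keep_weights) attr(nd, "attn") <- P
  nd
}

# ---- 2-D convolution (stride 1, "same" padding, odd kernels) -----------

conv_idx_cache <- new.env(parent = emptyenv())

conv2d_index <- function(C, H, W, kh, kw) {
  key <- paste(C, H, W, kh, kw, sep = "_")
  got <- conv_idx_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + kh - 1L
  ci <- rep(seq_len(C), times = kh * kw)
  di <- rep(rep(0:(kh - 1L), each = C), times = kw)
  dj <- rep(0:(kw - 1L), each = C * kh)
  ii <- rep(seq_len(H), times = W)
  jj <- rep(seq_len(W), each = H)
  rterm <- ci + C * di + C * Hp * dj
  oterm <- C * (ii - 1L) + C * Hp * (jj - 1L)
  idx <- as.integer(outer(rterm, oterm, "+"))
  conv_idx_cache[[key]] <- idx
  idx
}

# x: (C, H, W, B) array node; Wm: (Cout, C*kh*kw) weight node; bias optional
ad_conv2d <- function(tape, x, Wm, bias = NULL, kh, kw) {
  xv <- ad_val(x)
  d <- dim(xv)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  Wv <- ad_val(Wm)
  Cout <- nrow(Wv)
  xp <- array(0, c(C, Hp, Wp, B))
  xp[, ph + seq_len(H), pw + seq_len(W), ] <- xv
  xpf <- matrix(xp, C * Hp * Wp, B)
  idx <- conv2d_index(C, H, W, kh, kw)
  P <- xpf[idx, , drop = FALSE]
  dim(P) <- c(C * kh * kw, H * W * B)
  Y <- Wv %*% P
  if (!is.null(bias)) Y <- Y + ad_val(bias)
  dim(Y) <- c(Cout, H, W, B)
  ad_node_new(tape, Y, backward = function(g) {
    dim(g) <- c(Cout, H * W * B)
    ad_accum(Wm, tcrossprod(g, P))
    if (!is.null(bias)) ad_accum(bias, rowSums(g))
    if (inherits(x, "ad_node")) {
      dP <- crossprod(Wv, g)
      dim(dP) <- c(C * kh * kw * H * W, B)
      agg <- rowsum(dP, group = idx)
      dxp <- matrix(0, C * Hp * Wp, B)
      dxp[as.integer(rownames(agg)), ] <- agg
      dim(dxp) <- c(C, Hp, Wp, B)
      ad_accum(x, dxp[, ph + seq_len(H), pw + seq_len(W), , drop = FALSE])
    }
  })
}

# ---- pooling -----------------------------------------------------------

adaptive_bins <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    s <- floor((i - 1) * n_in / n_out) + 1L
    e <- ceiling(i * n_in / n_out)
    M[i, s:e] <- 1 / (e - s + 1L)
  }
  M
}

apply_axis2 <- function(x, M) {
  # multiply axis 2 of (C, H, W, B) by M (oh x H)
  d <- dim(x)
  y <- M %*% matrix(aperm(x, c(2, 1, 3, 4)), d[2], d[1] * d[3] * d[4])
  aperm(array(y, c(nrow(M), d[1], d[3], d[4])), c(2, 1, 3, 4))
}

apply_axis3 <- function(x, M) {
  d <- dim(x)
  y <- M %*% matrix(aperm(x, c(3, 1, 2, 4)), d[3], d[1] * d[2] * d[4])
  aperm(array(y, c(nrow(M), d[1], d[2], d[4])), c(2, 3, 1, 4))
}

# adaptive average pooling of (C, H, W, B) to (C, oh, ow, B)
ad_adaptive_pool <- function(tape, x, oh, ow) {
  xv <- ad_val(x)
  d <- dim(xv)
  Mh <- adaptive_bins(d[2], oh)
  Mw <- adaptive_bins(d[3], ow)
  y <- apply_axis3(apply_axis2(xv, Mh), Mw)
  ad_node_new(tape, y, backward = function(g) {
    ad_accum(x, apply_axis2(apply_axis3(g, t(Mw)), t(Mh)))
  })
}

# mean over (H, W) of (C, H, W, B) -> (C, B)
ad_mean_hw <- function(tape, x) {
  xv <- ad_val(x)
  d <- dim(xv)
  Xm <- matrix(aperm(xv, c(2, 3, 1, 4)), d[2] * d[3], d[1] * d[4])
  v <- matrix(colMeans(Xm), d[1], d[4])
  ad_node_new(tape, v, backward = function(g) {
    gex <- aperm(array(g / (d[2] * d[3]), c(d[1], d[4], d[2], d[3])),
                 c(1, 3, 4, 2))
    ad_accum(x, gex)
  })
}

# max over (H, W) of (C, H, W, B) -> (C, B); gradient routed to first argmax
ad_max_hw <- function(tape, x) {
  xv <- ad_val(x)
  d <- dim(xv)
  tXm <- t(matrix(aperm(xv, c(2, 3, 1, 4)), d[2] * d[3], d[1] * d[4]))
  am <- max.col(tXm, ties.method = "first")
  v <- matrix(tXm[cbind(seq_len(nrow(tXm)), am)], d[1], d[4])
  ad_node_new(tape, v, backward = function(g) {
    dXm <- matrix(0, d[2] * d[3], d[1] * d[4])
    dXm[cbind(am, seq_len(ncol(dXm)))] <- as.vector(g)
    ad_accum(x, aperm(array(dXm, c(d[2], d[3], d[1], d[4])), c(3, 1, 2, 4)))
  })
}

# mean over channels (axis 1) of (C, H, W, B) -> (H, W, B)
ad_mean_c <- function(tape, x) {
  xv <- ad_val(x)
  d <- dim(xv)
  v <- colMeans(xv, dims = 1)
  ad_node_new(tape, v, backward = function(g) {
    gex <- array(rep(as.vector(g) / d[1], each = d[1]), d)
    ad_accum(x, gex)
  })
}

# max over channels (axis 1) of (C, H, W, B) -> (H, W, B)
ad_max_c <- function(tape, x) {
  xv <- ad_val(x)
  d <- dim(xv)
  Xc <- matrix(xv, d[1], d[2] * d[3] * d[4])
  am <- max.col(t(Xc), ties.method = "first")
  v <- array(Xc[cbind(am, seq_len(ncol(Xc)))], d[2:4])
  ad_node_new(tape, v, backward = function(g) {
    dXc <- matrix(0, d[1], length(am))
    dXc[cbind(am, seq_along(am))] <- as.vector(g)
    dim(dXc) <- d
    ad_accum(x, dXc)
  })
}

# stack k same-shaped (H, W, B) nodes into (k, H, W, B)
ad_stack_first <- function(tape, xs) {
  vs <- lapply(xs, ad_val)
  d <- dim(vs[[1]])
  k <- length(xs)
  y <- array(0, c(k, d))
  for (i in seq_len(k)) y[i, , , ] <- vs[[i]]
  ad_node_new(tape, y, backward = function(g) {
    for (i in seq_len(k)) {
      if (inherits(xs[[i]], "ad_node")) {
        ad_accum(xs[[i]], array(g[i, , , ], d))
      }
    }
  })
}

# gate (C, H, W, B) by per-channel weights (C, B)
ad_gate_channel <- function(tape, x, g) {
  xv <- ad_val(x); gv <- ad_val(g)
  d <- dim(xv)
  gex <- aperm(array(gv, c(d[1], d[4], d[2], d[3])), c(1, 3, 4, 2))
  ad_node_new(tape, xv * gex, backward = function(gr) {
    if (inherits(x, "ad_node")) ad_accum(x, gr * gex)
    dg <- gr * xv
    dg <- matrix(aperm(dg, c(2, 3, 1, 4)), d[2] * d[3], d[1] * d[4])
    ad_accum(g, matrix(colSums(dg), d[1], d[4]))
  })
}

# gate (C, H, W, B) by a spatial map (H, W, B)
ad_gate_spatial <- function(tape, x, s) {
  xv <- ad_val(x); sv <- ad_val(s)
  d <- dim(xv)
  sex <- aperm(array(sv, c(d[2], d[3], d[4], d[1])), c(4, 1, 2, 3))
  ad_node_new(tape, xv * sex, backward = function(gr) {
    if (inherits(x, "ad_node")) ad_accum(x, gr * sex)
    ad_accum(s, colSums(gr * xv, dims = 1))
  })
}

# ---- token-axis ops for sequence tensors stored as (T*B, d) ------------

# depthwise 1-D convolution along the token axis, zero padded; w: (k, d)
ad_depthwise_tokens <- function(tape, x, w, tokens, batch) {
  xv <- ad_val(x); wv <- ad_val(w)
  k <- nrow(wv)
  K <- (k - 1L) %/% 2L
  n <- tokens * batch
  d <- ncol(xv)
  zrow <- n + 1L
  xa <- rbind(xv, 0)
  tt <- rep(seq_len(tokens), times = batch)
  bb <- rep(seq_len(batch), each = tokens)
  idx_for <- function(o) {
    s <- tt + o
    out <- (bb - 1L) * tokens + s
    out[s < 1L | s > tokens] <- zrow
    out
  }
  idxs <- lapply(seq_len(k), function(m) idx_for(m - K - 1L))
  Z <- matrix(0, n, d)
  for (m in seq_len(k)) {
    Z <- Z + xa[idxs[[m]], , drop = FALSE] * rowb(wv[m, ], n)
  }
  ad_node_new(tape, Z, backward = function(g) {
    ga <- rbind(g, 0)
    dw <- matrix(0, k, d)
    dx <- matrix(0, n, d)
    for (m in seq_len(k)) {
      dw[m, ] <- colSums(xa[idxs[[m]], , drop = FALSE] * g)
      # inverse shift: source index offset -(m - K - 1)
      inv <- idx_for(-(m - K - 1L))
      dx <- dx + ga[inv, , drop = FALSE] * rowb(wv[m, ], n)
    }
    ad_accum(w, dw)
    if (inherits(x, "ad_node")) ad_accum(x, dx)
  })
}

# mean over the token axis of (T*B, d) -> (B, d)
ad_mean_tokens <- function(tape, x, tokens, batch) {
  xv <- ad_val(x)
  d <- ncol(xv)
  v <- colMeans(array(xv, c(tokens, batch, d)), dims = 1)
  ad_node_new(tape, v, backward = function(g) {
    ad_accum(x, g[rep(seq_len(batch), each = tokens), , drop = FALSE] / tokens)
  })
}

# ---- loss --------------------------------------------------------------

# class-weighted, label-smoothed cross-entropy on logits, batch-averaged.
# y: integer class labels in 1..C; w: per-class weights; eps: smoothing.
ad_wsce_logits <- function(tape, logits, y, w, eps) {
  zv <- ad_val(logits)
  B <- nrow(zv); C <- ncol(zv)
  m <- zv[cbind(seq_len(B), max.col(zv, ties.method = "first"))]
  lse <- m + log(rowSums(exp(zv - m)))
  logp <- zv - lse
  tm <- matrix(eps / C, B, C)
  tm[cbind(seq_len(B), y)] <- tm[cbind(seq_len(B), y)] + (1 - eps)
  WT <- tm * rowb(w, B)
  loss <- -sum(WT * logp) / B
  ad_node_new(tape, loss, backward = function(g) {
    p <- exp(logp)
    ad_accum(logits, (p * rowSums(WT) - WT) * (g / B))
  })
}
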