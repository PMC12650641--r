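# Training: class-weighted label-smoothed cross-entropy, learning-rate
# schedules, AdamW with decoupled weight decay, gradient clipping and
# accumulation, early stopping. Fully seeded and deterministic.

#' Inverse-frequency class weights
#'
#' \eqn{w_i = N / (C \, n_i)}: inversely proportional to the class counts,
#' normalised so the count-weighted mean weight is one.
#'
#' @param labels integer class labels in 1..n_classes.
#' @param n_classes number of classes; defaults to `max(labels)`.
#' @return Numeric weight vector of length `n_classes`.
#' @export
compute_class_weights <- function(labels, n_classes = max(labels)) {
  cnt <- tabulate(labels, nbins = n_classes)
  if (any(cnt == 0)) {
    stop("degenerate fold: class ", which(cnt == 0)[1], " has no samples")
  }
  length(labels) / (n_classes * cnt)
}

#' Class-weighted, label-smoothed cross-entropy
#'
#' \eqn{L = -\sum_i w_i \left[(1-\epsilon) y_i + \epsilon / C\right]
#' \log \hat y_i}, averaged over the batch. Reduces to the plain
#' cross-entropy when all weights are one and \eqn{\epsilon = 0}.
#'
#' @param pred_probs (batch, C) matrix of predicted probabilities.
#' @param y integer labels (1..C) or a one-hot matrix.
#' @param class_weights per-class positive weights (default all one).
#' @param label_smoothing smoothing coefficient \eqn{\epsilon \in [0, 1)}.
#' @return Scalar loss. Zero predicted probabilities on a smoothed target
#'   are floored at 1e-12 before the log.
#' @export
weighted_smoothed_ce <- function(pred_probs, y,
                                 class_weights = rep(1, ncol(pred_probs)),
                                 label_smoothing = 0) {
  p <- as.matrix(pred_probs)
  C <- ncol(p)
  stopifnot(all(class_weights > 0), label_smoothing >= 0, label_smoothing < 1)
  if (is.matrix(y)) y <- max.col(y, ties.method = "first")
  B <- nrow(p)
  tm <- matrix(label_smoothing / C, B, C)
  tm[cbind(seq_len(B), y)] <- tm[cbind(seq_len(B), y)] + (1 - label_smoothing)
  lp <- log(pmax(p, 1e-12))
  -sum(tm * rowb(class_weights, B) * lp) / B
}

#' Learning-rate schedule
#'
#' `cosine`: half-cosine decay from `lr0` at step 0 to 0 at `total_steps`.
#' `one_cycle`: linear warm-up from `lr0/25` to the peak `lr0` over
#' `warmup_frac` of the run, then cosine annealing down to `lr0/100`.
#'
#' @param step current optimiser step (0..total_steps).
#' @param total_steps schedule horizon.
#' @param kind `"cosine"` or `"one_cycle"`.
#' @param lr0 initial (cosine) or peak (one-cycle) learning rate.
#' @param warmup_frac one-cycle warm-up fraction.
#' @return Learning rate at `step`.
#' @export
lr_schedule <- function(step, total_steps, kind = c("cosine", "one_cycle"),
                        lr0, warmup_frac = 0.3) {
  kind <- match.arg(kind)
  stopifnot(step >= 0, step <= total_steps)
  if (kind == "cosine") {
    lr0 * (1 + cos(pi * step / total_steps)) / 2
  } else {
    peak_at <- warmup_frac * total_steps
    if (step <= peak_at) {
      start <- lr0 / 25
      start + (lr0 - start) * (if (peak_at > 0) step / peak_at else 1)
    } else {
      final <- lr0 / 100
      frac <- (step - peak_at) / (total_steps - peak_at)
      final + (lr0 - final) * (1 + cos(pi * frac)) / 2
    }
  }
}

#' Training configuration
#'
#' Defaults follow the two published recipes: SEED-style (lr 0.002, weight
#' decay 1e-4, batch 96, one-cycle schedule) and DEAP-style (lr 0.0005,
#' weight decay 1e-3, batch 32, cosine annealing); both clip the global
#' gradient norm at 1.0 and accumulate gradients over 2 micro-batches.
#'
#' @param layout `"seed_like"` or `"deap_like"` (sets the defaults).
#' @param lr,weight_decay,batch_size,epochs optimiser hyperparameters.
#' @param grad_clip_norm maximum global gradient norm.
#' @param accum_steps micro-batches whose averaged loss forms one update.
#' @param scheduler `"cosine"` or `"one_cycle"`.
#' @param label_smoothing smoothing coefficient of the loss.
#' @param early_stop_patience epochs without validation-accuracy improvement
#'   before stopping (best weights restored).
#' @param val_acc_stop optional validation accuracy at which training stops
#'   early (convergence shortcut).
#' @param seed RNG seed controlling shuffling, dropout and initial state.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(layout = c("seed_like", "deap_like"),
                         lr = NULL, weight_decay = NULL, batch_size = NULL,
                         epochs = 100L, grad_clip_norm = 1.0,
                         accum_steps = 2L, scheduler = NULL,
                         label_smoothing = 0.1,
                         early_stop_patience = 15L,
                         val_acc_stop = NULL, seed = 1L) {
  layout <- match.arg(layout)
  if (is.null(lr)) lr <- if (layout == "seed_like") 0.002 else 0.0005
  if (is.null(weight_decay)) {
    weight_decay <- if (layout == "seed_like") 1e-4 else 1e-3
  }
  if (is.null(batch_size)) batch_size <- if (layout == "seed_like") 96L else 32L
  if (is.null(scheduler)) {
    scheduler <- if (layout == "seed_like") "one_cycle" else "cosine"
  }
  stopifnot(epochs >= 1, grad_clip_norm > 0, accum_steps >= 1)
  cfg <- list(layout = layout, lr = lr, weight_decay = weight_decay,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              grad_clip_norm = grad_clip_norm,
              accum_steps = as.integer(accum_steps), scheduler = scheduler,
              label_smoothing = label_smoothing,
              early_stop_patience = as.integer(early_stop_patience),
              val_acc_stop = val_acc_stop, seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

#' Clip gradients to a maximum global norm
#'
#' @param grads named list of gradient arrays.
#' @param max_norm maximum Euclidean norm of the concatenated gradients.
#' @return The (possibly rescaled) gradient list, with the pre-clipping
#'   norm attached as attribute `"norm"`.
#' @export
clip_global_norm <- function(grads, max_norm) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  }
  attr(grads, "norm") <- nrm
  grads
}

adamw_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(as.list(params), function(p) {
    z <- p
    z[] <- 0
    z
  })
  st$v <- st$m
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(params, grads, st, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    upd <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    params[[nm]][] <- params[[nm]] * (1 - lr * weight_decay) - lr * upd
  }
  invisible(NULL)
}

# batched eval-mode prediction (limits per-pass memory)
predict_probs <- function(model, de = NULL, psd = NULL, fused = NULL,
                          batch = 128L) {
  n <- dim(if (is.null(fused)) de else fused)[1]
  out <- NULL
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(n, s + batch - 1L)
    sub <- function(a) {
      if (is.null(a)) NULL else array(a[idx, , , , drop = FALSE], c(length(idx), dim(a)[-1]))
    }
    p <- tanet_forward(model, sub(de), sub(psd), sub(fused))
    out <- rbind(out, p)
  }
  out
}

snapshot_params <- function(model) {
  list(params = as.list(model$params), state = as.list(model$state))
}

restore_params <- function(model, snap) {
  for (nm in names(snap$params)) model$params[[nm]] <- snap$params[[nm]]
  for (nm in names(snap$state)) model$state[[nm]] <- snap$state[[nm]]
  invisible(NULL)
}

#' Train the network
#'
#' AdamW (beta1 = 0.9, beta2 = 0.999) with decoupled weight decay on the
#' class-weighted label-smoothed cross-entropy; gradients are averaged over
#' `accum_steps` micro-batches, clipped to a global norm, and the scheduler
#' advances once per optimiser step across the whole run. Class weights are
#' computed from the training labels. The best-validation-accuracy weights
#' are restored at the end.
#'
#' @param model a `tanet_model` (modified in place and returned).
#' @param train_data,val_data lists with `labels` plus either `de` and `psd`
#'   tensors (batch, bands, channels, windows) or a pre-fused `fused` tensor.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (best weights) and `history` (per-epoch
#'   data.frame: epoch, lr, train_loss, train_acc, val_loss, val_acc,
#'   max_grad_norm_postclip).
#' @export
tanet_train <- function(model, train_data, val_data, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "tanet_model"), inherits(config, "train_config"))
  set.seed(config$seed)
  y <- as.integer(train_data$labels)
  n <- length(y)
  C <- model$config$n_classes
  w <- compute_class_weights(y, C)
  opt <- adamw_init(model$params)
  nb <- ceiling(n / config$batch_size)
  total_steps <- config$epochs * ceiling(nb / config$accum_steps)
  hist <- list()
  best_acc <- -Inf
  best_snap <- NULL
  stall <- 0L
  accum <- NULL
  accum_k <- 0L

  take <- function(data, idx) {
    sub <- function(a) {
      if (is.null(a)) NULL else array(a[idx, , , , drop = FALSE],
                                      c(length(idx), dim(a)[-1]))
    }
    list(de = sub(data$de), psd = sub(data$psd), fused = sub(data$fused))
  }

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0L
    max_post <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n)]
      batch <- take(train_data, idx)
      tape <- ad_tape()
      out <- tanet_forward_core(model, batch$de, batch$psd, batch$fused,
                                training = TRUE, tape = tape)
      loss <- ad_wsce_logits(tape, out$logits, y[idx], w,
                             config$label_smoothing)
      lval <- ad_val(loss)
      if (!is.finite(lval)) {
        stop("non-finite training loss at epoch ", ep, ", batch ", bi,
             " (loss = ", lval, "); aborting")
      }
      ep_loss <- ep_loss + lval * length(idx)
      pred <- max.col(ad_val(out$logits), ties.method = "first")
      ep_correct <- ep_correct + sum(pred == y[idx])
      ad_backward(tape, loss)
      gr <- list()
      for (nm in ls(out$leaves)) {
        g <- out$leaves[[nm]]$grad
        if (!is.null(g)) gr[[nm]] <- g / config$accum_steps
      }
      if (is.null(accum)) accum <- gr
      else for (nm in names(gr)) accum[[nm]] <- accum[[nm]] + gr[[nm]]
      accum_k <- accum_k + 1L
      if (accum_k == config$accum_steps || bi == nb) {
        lr <- lr_schedule(opt$t, total_steps, config$scheduler, config$lr)
        accum <- clip_global_norm(accum, config$grad_clip_norm)
        max_post <- max(max_post,
                        min(attr(accum, "norm"), config$grad_clip_norm))
        adamw_step(model$params, accum, opt, lr, config$weight_decay)
        accum <- NULL
        accum_k <- 0L
      }
    }
    vp <- predict_probs(model, val_data$de, val_data$psd, val_data$fused)
    vy <- as.integer(val_data$labels)
    val_loss <- weighted_smoothed_ce(vp, vy, w, config$label_smoothing)
    val_acc <- mean(max.col(vp, ties.method = "first") == vy)
    hist[[ep]] <- data.frame(
      epoch = ep, lr = lr_schedule(opt$t, total_steps, config$scheduler,
                                   config$lr),
      train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = val_loss, val_acc = val_acc,
      max_grad_norm_postclip = max_post)
    if (verbose) {
      cat(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f\n", ep,
                  ep_loss / n, ep_correct / n, val_loss, val_acc))
    }
    if (val_acc > best_acc) {
      best_acc <- val_acc
      best_snap <- snapshot_params(model)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (!is.null(config$val_acc_stop) && val_acc >= config$val_acc_stop) break
    if (stall >= config$early_stop_patience) break
  }
  if (!is.null(best_snap)) restore_params(model, best_snap)
  list(model = model, history = do.call(rbind, hist))
}
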