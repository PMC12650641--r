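# Evaluation protocols: subject-specific stratified cross-validation with
# leakage-free standardisation, the DEAP-style fuse -> scale -> segment ->
# binarise -> stratified-split pipeline, leave-one-subject-out splitting,
# and the ablation harness.

#' Leakage-free per-fold standardisation
#'
#' Z-scores every (band, channel, window) cell using statistics fitted on
#' the training tensor only; the validation tensor is transformed with the
#' training statistics. PSD features are square-root transformed first to
#' compress their range. Cells with zero training variance are centred only.
#'
#' @param train,val feature tensors (n, bands, channels, windows); `val`
#'   may be NULL.
#' @param modality `"DE"` or `"PSD"` (PSD triggers the sqrt transform).
#' @return list with `train`, `val`, and `scaler` (the fitted statistics:
#'   `mean`, `sd` arrays, `n_fit`, `modality`, `degenerate_cells`).
#' @export
seed_standardize <- function(train, val = NULL, modality = c("DE", "PSD")) {
  modality <- match.arg(modality)
  if (modality == "PSD") {
    if (any(train < 0)) stop("PSD features must be non-negative")
    train <- sqrt(train)
    if (!is.null(val)) val <- sqrt(pmax(val, 0))
  }
  d <- dim(train)
  mu <- apply(train, 2:4, mean)
  sd_ <- apply(train, 2:4, stats::sd)
  degen <- sum(sd_ == 0)
  if (degen > 0) {
    message(degen, " feature cells had zero training variance; centred only")
  }
  sd_safe <- ifelse(sd_ == 0, 1, sd_)
  scale_one <- function(x) {
    n <- dim(x)[1]
    mu_e <- aperm(array(mu, c(d[2:4], n)), c(4, 1, 2, 3))
    sd_e <- aperm(array(sd_safe, c(d[2:4], n)), c(4, 1, 2, 3))
    (x - mu_e) / sd_e
  }
  list(train = scale_one(train),
       val = if (is.null(val)) NULL else scale_one(val),
       scaler = list(mean = mu, sd = sd_, n_fit = d[1], modality = modality,
                     degenerate_cells = degen))
}

# per-class round-robin assignment to k folds after a seeded shuffle
stratified_kfold <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Subject-specific stratified k-fold plan
#'
#' Partitions each subject's samples independently into k stratified folds,
#' so the model is always trained and validated on distinct subsets of the
#' same subject's data.
#'
#' @param labels integer class labels.
#' @param subject_ids per-sample subject identifiers.
#' @param k number of folds (default 5).
#' @param seed RNG seed; the same seed reproduces the same plan.
#' @return list of class `"fold_plan"`: `assignments` (data.frame with
#'   sample, subject, fold), `k`, `seed`.
#' @export
subject_cv_folds <- function(labels, subject_ids, k = 5L, seed = 1L) {
  stopifnot(length(labels) == length(subject_ids))
  fold <- integer(length(labels))
  for (s in sort(unique(subject_ids))) {
    idx <- which(subject_ids == s)
    cnt <- table(labels[idx])
    if (any(cnt < k)) {
      stop("subject ", s, " has a class with fewer than k = ", k,
           " samples; cannot stratify")
    }
    fold[idx] <- stratified_kfold(labels[idx], k,
                                  seed = seed + as.integer(s))
  }
  plan <- list(assignments = data.frame(sample = seq_along(labels),
                                        subject = subject_ids, fold = fold),
               k = as.integer(k), seed = as.integer(seed))
  class(plan) <- "fold_plan"
  plan
}

#' Extend the DEAP time axis from 58 to 60 steps
#'
#' Collapses the trailing 4-segment axis by its mean, then appends two time
#' steps, each equal to the mean of the last four time steps.
#'
#' @param x feature tensor (n, channels, bands, 58, 4).
#' @return Tensor (n, channels, bands, 60).
#' @export
deap_time_extend <- function(x) {
  d <- dim(x)
  if (length(d) != 5 || d[5] != 4) {
    stop("expected a 5-D tensor (n, channels, bands, time, 4)")
  }
  m <- colMeans(aperm(x, c(5, 1, 2, 3, 4)), dims = 1)
  Tn <- d[4]
  tail_mean <- apply(m[, , , (Tn - 3):Tn, drop = FALSE], 1:3, mean)
  out <- array(0, c(d[1:3], Tn + 2L))
  out[, , , seq_len(Tn)] <- m
  out[, , , Tn + 1L] <- tail_mean
  out[, , , Tn + 2L] <- tail_mean
  out
}

#' Binarise 1-9 affect ratings at 5
#'
#' @param scores numeric valence/arousal ratings.
#' @return Integer labels: scores below 5 give 0, scores of 5 or above 1.
#' @export
binarize_labels <- function(scores) {
  as.integer(scores >= 5)
}

#' DEAP-style pipeline: fuse, scale, segment, binarise
#'
#' Fuses DE and PSD per frequency band with bidirectional cross-modal
#' attention (untrained, fixed-seed projections applied in preprocessing),
#' min-max scales the fused tensor to [0, 1], cuts the 60-step time axis
#' into non-overlapping `segment_len`-step windows, and repeats each trial's
#' binarised label once per segment.
#'
#' The default reproduces the benchmark "slice-first, then divide" workflow
#' with holistic (whole-tensor) normalisation; `leakage_safe = TRUE` fits
#' the min-max statistics on `train_idx` trials only.
#'
#' @param de,psd feature tensors (n, channels, bands, 60).
#' @param scores per-trial 1-9 ratings (or already-binary 0/1 labels).
#' @param fusion_model optional `tanet_model` with a deap-like bidirectional
#'   configuration supplying the fusion weights; created from `fusion_seed`
#'   when NULL.
#' @param fusion_seed seed for the fusion projections.
#' @param segment_len segment length in time steps (default 3).
#' @param leakage_safe fit min-max scaling on training trials only.
#' @param train_idx trial indices treated as training data when
#'   `leakage_safe` is TRUE.
#' @return list of class `"deap_segments"`: `segments`
#'   (n*T/segment_len, channels, bands, segment_len), `labels` (0/1, one per
#'   segment), `provenance` (segment -> trial, window), `scale` (min, max,
#'   fit).
#' @export
deap_build_segments <- function(de, psd, scores, fusion_model = NULL,
                                fusion_seed = 0L, segment_len = 3L,
                                leakage_safe = FALSE, train_idx = NULL) {
  d <- dim(de)
  stopifnot(length(d) == 4, identical(d, dim(psd)))
  n <- d[1]; Ch <- d[2]; Fb <- d[3]; Tn <- d[4]
  if (Tn %% segment_len != 0) {
    stop("time axis (", Tn, ") is not divisible by segment_len (",
         segment_len, ")")
  }
  if (is.null(fusion_model)) {
    fusion_model <- tanet_model(
      tanet_config("deap_like", eeg_channels = Ch, windows = Tn,
                   n_bands = Fb, bidirectional = TRUE),
      seed = fusion_seed)
  }
  fused <- array(0, d)
  for (f in seq_len(Fb)) {
    de_f <- array(de[, , f, ], c(n, Ch, Tn))
    psd_f <- array(psd[, , f, ], c(n, Ch, Tn))
    fused[, , f, ] <- mca_bidirectional(de_f, psd_f, fusion_model, band = f)
  }
  fit <- fused
  fit_tag <- "all"
  if (leakage_safe) {
    if (is.null(train_idx)) stop("leakage_safe = TRUE requires train_idx")
    fit <- fused[train_idx, , , , drop = FALSE]
    fit_tag <- "train"
  }
  mn <- min(fit); mx <- max(fit)
  if (mn == mx) stop("degenerate min-max scaling: constant fused tensor")
  fused <- (fused - mn) / (mx - mn)
  n_seg <- Tn %/% segment_len
  segments <- array(0, c(n * n_seg, Ch, Fb, segment_len))
  lab01 <- binarize_labels(scores)
  seg_labels <- integer(n * n_seg)
  trial_of <- integer(n * n_seg)
  window_of <- integer(n * n_seg)
  for (i in seq_len(n)) {
    for (s in seq_len(n_seg)) {
      r <- (i - 1L) * n_seg + s
      tt <- ((s - 1L) * segment_len + 1L):(s * segment_len)
      segments[r, , , ] <- fused[i, , , tt]
      seg_labels[r] <- lab01[i]
      trial_of[r] <- i
      window_of[r] <- s
    }
  }
  out <- list(segments = segments, labels = seg_labels,
              provenance = data.frame(segment = seq_len(n * n_seg),
                                      trial = trial_of, window = window_of),
              scale = list(min = mn, max = mx, fit = fit_tag))
  class(out) <- "deap_segments"
  out
}

#' Stratified train/test split
#'
#' Per class, a seeded shuffle assigns `round((1 - ratio) * n_class)`
#' samples to the test set, preserving class proportions within one sample.
#'
#' @param labels class labels.
#' @param ratio training fraction (default 0.9).
#' @param seed RNG seed; different seeds give different reproducible splits.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, ratio = 0.9, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  test <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_test <- round(length(idx) * (1 - ratio))
      if (n_test < 1 || n_test >= length(idx)) {
        stop("class ", cl, " too small to stratify at ratio ", ratio)
      }
      test <- c(test, idx[sample.int(length(idx))][seq_len(n_test)])
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Leave-one-subject-out splits
#'
#' Each subject in turn forms the entire test set.
#'
#' @param subject_ids per-sample subject identifiers.
#' @return list (one element per subject) of lists with `subject`,
#'   `train` and `test` index vectors.
#' @export
loso_split <- function(subject_ids) {
  subs <- sort(unique(subject_ids))
  if (length(subs) < 2) stop("leave-one-subject-out requires >= 2 subjects")
  lapply(subs, function(s) {
    list(subject = s, train = which(subject_ids != s),
         test = which(subject_ids == s))
  })
}

#' Ablation harness
#'
#' Trains the full model and its three ablated variants (cross-modal
#' attention replaced by the element-wise modality mean; CBAM replaced by
#' the identity; the Conformer replaced by direct global average pooling of
#' the projected tokens) on identical stratified folds and seeds, and
#' compares each variant to the full model with a paired test on the
#' per-fold accuracies.
#'
#' @param de,psd feature tensors (n, bands, channels, windows).
#' @param labels integer class labels 1..C.
#' @param model_config base [tanet_config()].
#' @param train_cfg a [train_config()] (typically with reduced epochs).
#' @param k number of folds.
#' @param seed fold/initialisation seed shared by all variants.
#' @param method paired test: `"t"` or `"wilcoxon"`.
#' @param include_self also compare the full model against itself (p = 1
#'   sanity row).
#' @return list with `table` (columns variant, accuracy, CI, F1, kappa, p),
#'   `raw` (numeric per-variant summary), `per_fold` (accuracy matrix).
#' @export
ablation_harness <- function(de, psd, labels, model_config = tanet_config(),
                             train_cfg = train_config(epochs = 10L),
                             k = 3L, seed = 1L, method = "t",
                             include_self = FALSE) {
  labels <- as.integer(labels)
  folds <- stratified_kfold(labels, k, seed)
  variants <- list(
    "Conformer + CBAM" = list(use_mca = FALSE),
    "Conformer + MCA" = list(use_cbam = FALSE),
    "CBAM + MCA" = list(use_conformer = FALSE),
    "Conformer + CBAM + MCA" = list())
  sub4 <- function(a, idx) array(a[idx, , , , drop = FALSE],
                                 c(length(idx), dim(a)[-1]))
  run_variant <- function(flags) {
    cfg <- model_config
    for (nm in names(flags)) cfg[[nm]] <- flags[[nm]]
    reports <- vector("list", k)
    for (j in seq_len(k)) {
      tr <- which(folds != j)
      va <- which(folds == j)
      model <- tanet_model(cfg, seed = seed)
      fit <- tanet_train(model,
                         list(de = sub4(de, tr), psd = sub4(psd, tr),
                              labels = labels[tr]),
                         list(de = sub4(de, va), psd = sub4(psd, va),
                              labels = labels[va]),
                         train_cfg)
      probs <- predict_probs(fit$model, sub4(de, va), sub4(psd, va))
      reports[[j]] <- evaluation_report(probs, labels[va])
    }
    reports
  }
  all_reports <- lapply(variants, run_variant)
  aggs <- lapply(all_reports, aggregate_runs)
  acc <- vapply(all_reports, function(rs) {
    vapply(rs, `[[`, numeric(1), "accuracy")
  }, numeric(k))
  full <- "Conformer + CBAM + MCA"
  rows <- names(variants)
  if (include_self) rows <- c(rows, "Full vs itself")
  tab <- data.frame(variant = rows, accuracy = NA_character_,
                    CI = NA_character_, F1 = NA_character_,
                    kappa = NA_character_, p = NA_real_,
                    stringsAsFactors = FALSE)
  raw <- NULL
  for (i in seq_along(rows)) {
    nm <- if (rows[i] == "Full vs itself") full else rows[i]
    a <- aggs[[nm]]
    pv <- if (rows[i] == full) {
      NA_real_
    } else if (rows[i] == "Full vs itself") {
      paired_comparison(acc[, full], acc[, full], method)$p_value
    } else {
      paired_comparison(acc[, full], acc[, nm], method)$p_value
    }
    tab$accuracy[i] <- sprintf("%.2f ± %.2f", 100 * a$mean["accuracy"],
                               100 * a$sd["accuracy"])
    tab$CI[i] <- sprintf("[%.2f, %.2f]", 100 * a$ci95[1], 100 * a$ci95[2])
    tab$F1[i] <- sprintf("%.3f ± %.3f", a$mean["f1"], a$sd["f1"])
    tab$kappa[i] <- sprintf("%.3f ± %.3f", a$mean["kappa"], a$sd["kappa"])
    tab$p[i] <- pv
    raw <- rbind(raw, data.frame(variant = rows[i],
                                 accuracy_mean = a$mean["accuracy"],
                                 accuracy_sd = a$sd["accuracy"],
                                 f1_mean = a$mean["f1"],
                                 kappa_mean = a$mean["kappa"],
                                 p = pv, row.names = NULL))
  }
  list(table = tab, raw = raw, per_fold = acc)
}
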