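# Protocols: leakage-free standardisation, fold plans as stratified
# partitions, the DEAP fuse/scale/segment pipeline, stratified splitting,
# and leave-one-subject-out semantics.

test_that("standardisation fits on training data only", {
  set.seed(1)
  tr <- array(rnorm(20 * 2 * 3 * 4, mean = 5, sd = 2), c(20, 2, 3, 4))
  va <- array(rnorm(8 * 2 * 3 * 4, mean = 5, sd = 2), c(8, 2, 3, 4))
  sc <- seed_standardize(tr, va, "DE")
  expect_equal(mean(sc$train), 0, tolerance = 1e-10)
  expect_true(max(abs(apply(sc$train, 2:4, mean))) < 1e-10)
  expect_true(max(abs(apply(sc$train, 2:4, sd) - 1)) < 1e-10)
  # shifting the validation set must not change the fitted statistics
  sc2 <- seed_standardize(tr, va + 100, "DE")
  expect_identical(sc2$scaler$mean, sc$scaler$mean)
  expect_identical(sc2$scaler$sd, sc$scaler$sd)
  expect_identical(sc2$train, sc$train)
  expect_equal(sc2$val, sc$val + 100 / aperm(array(sc$scaler$sd, c(2, 3, 4, 8)),
                                             c(4, 1, 2, 3)),
               tolerance = 1e-10)
})

test_that("PSD standardisation takes the square root first", {
  tr <- array(1, c(5, 1, 1, 1))
  tr[1:5, 1, 1, 1] <- c(0.25, 0.5625, 1, 1.5625, 2.25)  # sqrt: .5 .75 1 1.25 1.5
  va <- array(4, c(1, 1, 1, 1))
  sc <- seed_standardize(tr, va, "PSD")
  mu <- mean(sqrt(tr))
  sdv <- sd(sqrt(tr))
  expect_equal(as.vector(sc$val), (2 - mu) / sdv, tolerance = 1e-12)
  expect_error(seed_standardize(tr - 10, va, "PSD"), "non-negative")
})

test_that("zero-variance cells are centred only, with a message", {
  tr <- array(rnorm(40), c(10, 1, 2, 2))
  tr[, 1, 1, 1] <- 7
  expect_message(sc <- seed_standardize(tr, NULL, "DE"), "zero training variance")
  expect_equal(sc$scaler$degenerate_cells, 1)
  expect_true(all(sc$train[, 1, 1, 1] == 0))
})

test_that("subject-specific folds are stratified partitions", {
  set.seed(2)
  labels <- rep(rep(1:3, each = 10), times = 2)
  subjects <- rep(1:2, each = 30)
  plan <- subject_cv_folds(labels, subjects, k = 5, seed = 3)
  a <- plan$assignments
  expect_setequal(a$sample, seq_along(labels))
  for (s in 1:2) {
    f <- a$fold[a$subject == s]
    expect_equal(unname(as.vector(table(f))), rep(6, 5))
    for (j in 1:5) {
      cls <- table(labels[a$subject == s & a$fold == j])
      expect_true(max(cls) - min(cls) <= 1)
    }
  }
  expect_identical(plan$assignments,
                   subject_cv_folds(labels, subjects, k = 5, seed = 3)$assignments)
  expect_error(subject_cv_folds(c(1, 1, 2), c(1, 1, 1), k = 5), "fewer than k")
})

test_that("the time axis extends 58 -> 60 by tail averaging", {
  set.seed(3)
  x <- array(rnorm(2 * 3 * 2 * 58 * 4), c(2, 3, 2, 58, 4))
  out <- deap_time_extend(x)
  expect_equal(dim(out), c(2, 3, 2, 60))
  m <- apply(x, 1:4, mean)
  expect_equal(out[, , , 1:58], m, tolerance = 1e-12)
  tail_mean <- apply(m[, , , 55:58, drop = FALSE], 1:3, mean)
  expect_equal(out[, , , 59], tail_mean, tolerance = 1e-12)
  expect_equal(out[, , , 60], tail_mean, tolerance = 1e-12)
  cst <- deap_time_extend(array(4.2, c(1, 2, 2, 58, 4)))
  expect_equal(as.vector(cst), rep(4.2, 1 * 2 * 2 * 60))
  expect_error(deap_time_extend(array(0, c(2, 3, 2, 58))), "5-D")
})

test_that("segment building: counts, binarisation, provenance, scaling", {
  set.seed(4)
  n <- 8
  de <- array(rnorm(n * 6 * 2 * 12), c(n, 6, 2, 12))
  psd <- array(rnorm(n * 6 * 2 * 12), c(n, 6, 2, 12))
  scores <- c(1, 4.99, 5, 9, 3, 7, 5.01, 4)
  fm <- tanet_model(tanet_config("deap_like", eeg_channels = 6L,
                                 windows = 12L, n_bands = 2L, att_dim = 3L),
                    seed = 1)
  seg <- deap_build_segments(de, psd, scores, fusion_model = fm,
                             segment_len = 3L)
  expect_equal(dim(seg$segments), c(n * 4, 6, 2, 3))
  expect_equal(range(seg$segments), c(0, 1))
  # label binarisation at 5 and 20x-style repetition per trial
  expect_equal(seg$labels[seg$provenance$trial == 2], rep(0L, 4))
  expect_equal(seg$labels[seg$provenance$trial == 3], rep(1L, 4))
  for (i in seq_len(n)) {
    expect_equal(unique(seg$labels[seg$provenance$trial == i]),
                 as.integer(scores[i] >= 5))
  }
  # provenance is a bijection segment -> (trial, window)
  expect_equal(nrow(unique(seg$provenance[, c("trial", "window")])), n * 4)
  # leakage-safe mode fits min-max on the training trials only
  seg_ls <- deap_build_segments(de, psd, scores, fusion_model = fm,
                                segment_len = 3L, leakage_safe = TRUE,
                                train_idx = 1:6)
  expect_equal(seg_ls$scale$fit, "train")
  expect_false(identical(seg_ls$scale$min, seg$scale$min) &&
                 identical(seg_ls$scale$max, seg$scale$max))
  expect_error(deap_build_segments(de, psd, scores, fusion_model = fm,
                                   segment_len = 5L), "divisible")
})

test_that("stratified splits preserve class proportions and differ by seed", {
  labels <- rep(1:2, times = c(15000, 10600))  # 25,600 imitated segments
  sp <- stratified_split(labels, ratio = 0.9, seed = 1)
  expect_length(sp$train, 23040)
  expect_length(sp$test, 2560)
  expect_length(intersect(sp$train, sp$test), 0)
  ratio_all <- mean(labels == 1)
  ratio_test <- mean(labels[sp$test] == 1)
  expect_lt(abs(ratio_test - ratio_all), 1 / length(sp$test) + 1e-9)
  seeds <- lapply(0:9, function(s) stratified_split(labels, seed = s)$test)
  expect_equal(length(unique(seeds)), 10)
  expect_identical(stratified_split(labels, seed = 4),
                   stratified_split(labels, seed = 4))
  expect_error(stratified_split(c(1, 1, 1, 2), ratio = 0.9), "too small")
})

test_that("LOSO splits tile the subject set without leakage", {
  subjects <- rep(1:4, times = c(5, 6, 7, 8))
  sp <- loso_split(subjects)
  expect_length(sp, 4)
  tests <- unlist(lapply(sp, `[[`, "test"))
  expect_setequal(tests, seq_along(subjects))
  expect_equal(length(tests), length(subjects))  # disjoint and exhaustive
  for (s in sp) {
    expect_length(intersect(s$train, s$test), 0)
    expect_true(all(subjects[s$test] == s$subject))
    expect_true(all(subjects[s$train] != s$subject))
  }
  expect_error(loso_split(rep(1, 5)), "2 subjects")
})

test_that("cross-subject generalisation is no easier than within-subject", {
  # the discriminative dimensions vary between subjects (a mild form of the
  # inter-individual variability that motivates subject-specific protocols);
  # a nearest-centroid oracle classifier probes the two protocols
  set.seed(5)
  n_sub <- 4; per <- 30
  x <- NULL; y <- NULL; sub <- NULL
  for (s in 1:n_sub) {
    base_dim <- 2 * (s %% 2)   # subjects alternate between dims 1:2 and 3:4
    for (k in 1:2) {
      xs <- matrix(rnorm(per / 2 * 10), per / 2, 10)
      xs[, base_dim + k] <- xs[, base_dim + k] + 2
      x <- rbind(x, xs)
      y <- c(y, rep(k, per / 2))
      sub <- c(sub, rep(s, per / 2))
    }
  }
  centroid_pred <- function(tr, te) {
    cent <- rbind(colMeans(x[tr, ][y[tr] == 1, ]), colMeans(x[tr, ][y[tr] == 2, ]))
    d2 <- cbind(rowSums(sweep(x[te, ], 2, cent[1, ])^2),
                rowSums(sweep(x[te, ], 2, cent[2, ])^2))
    mean((3 - max.col(d2, ties.method = "first")) == y[te])
  }
  loso_acc <- mean(vapply(loso_split(sub), function(s) {
    centroid_pred(s$train, s$test)
  }, numeric(1)))
  # subject-specific protocol: train and test within each subject's own data
  plan <- subject_cv_folds(y, sub, k = 5, seed = 6)
  a <- plan$assignments
  within_acc <- mean(vapply(1:n_sub, function(s) {
    mean(vapply(1:5, function(j) {
      centroid_pred(a$sample[a$subject == s & a$fold != j],
                    a$sample[a$subject == s & a$fold == j])
    }, numeric(1)))
  }, numeric(1)))
  expect_lte(loso_acc, within_acc + 0.02)
})
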