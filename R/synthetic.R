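# Synthetic EEG generator: class-conditional band-power structure for
# exercising the full pipeline without external recordings. Each trial is a
# sum of band-limited oscillations (one per canonical band, amplitude scaled
# by a per-class gain) plus correlated Gaussian noise across channels.

#' Canonical EEG frequency bands
#'
#' Delta 1-4, Theta 4-8, Alpha 8-14, Beta 14-31, Gamma 31-50 Hz (the common
#' SEED-style convention).
#'
#' @return data.frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             f_lo = c(1, 4, 8, 14, 31),
             f_hi = c(4, 8, 14, 31, 50))
}

#' Specification for the synthetic raw-EEG generator
#'
#' @param n_trials_per_class trials per emotion class (>= 1).
#' @param n_channels number of EEG channels.
#' @param fs sampling rate in Hz; must exceed twice the highest band edge.
#' @param duration trial length in seconds.
#' @param bands data.frame of band definitions (name, f_lo, f_hi).
#' @param class_band_gain matrix (classes x bands) of dimensionless amplitude
#'   multipliers, all positive; row count sets the number of classes.
#' @param base_amplitude oscillation base amplitude in microvolts.
#' @param noise_sd additive Gaussian noise standard deviation (microvolts).
#' @param channel_corr inter-channel noise correlation in [0, 1], realised by
#'   mixing a shared noise component into every channel.
#' @param n_subjects number of synthetic subjects; trials are assigned
#'   round-robin within class.
#' @param seed RNG seed.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_trials_per_class = 10L,
                           n_channels = 8L,
                           fs = 200,
                           duration = 6,
                           bands = eeg_bands(),
                           class_band_gain = rbind(c(1, 1, 1, 1, 1),
                                                   c(1, 1, 2, 1, 1),
                                                   c(1, 2, 1, 1, 1)),
                           base_amplitude = 10,
                           noise_sd = 5,
                           channel_corr = 0.2,
                           n_subjects = 1L,
                           seed = 1L) {
  class_band_gain <- as.matrix(class_band_gain)
  stopifnot(n_trials_per_class >= 1, n_channels >= 1, duration > 0,
            ncol(class_band_gain) == nrow(bands),
            all(class_band_gain > 0),
            channel_corr >= 0, channel_corr <= 1,
            noise_sd >= 0, n_subjects >= 1)
  worst <- which.max(bands$f_hi)
  if (fs <= 2 * bands$f_hi[worst]) {
    stop("sampling rate ", fs, " Hz is too low for band '",
         bands$name[worst], "' (upper edge ", bands$f_hi[worst],
         " Hz); need fs > ", 2 * bands$f_hi[worst], " Hz")
  }
  spec <- list(n_trials_per_class = as.integer(n_trials_per_class),
               n_channels = as.integer(n_channels), fs = fs,
               duration = duration, bands = bands,
               class_band_gain = class_band_gain,
               base_amplitude = base_amplitude, noise_sd = noise_sd,
               channel_corr = channel_corr,
               n_subjects = as.integer(n_subjects), seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic raw EEG dataset
#'
#' Each trial of class k is a sum over bands of a sinusoid with amplitude
#' `base_amplitude * class_band_gain[k, band]`, a frequency drawn uniformly
#' within the band, and an independent random phase per channel, plus
#' Gaussian noise correlated across channels. Reproducible given the spec's
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `"raw_eeg_dataset"` with elements `signals`
#'   (trials x channels x samples, microvolts), `fs`, `labels` (integer
#'   classes 1..K), `subject_ids`.
#' @export
generate_raw_eeg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    K <- nrow(spec$class_band_gain)
    n <- spec$n_trials_per_class * K
    ns <- round(spec$fs * spec$duration)
    ch <- spec$n_channels
    tt <- (seq_len(ns) - 1) / spec$fs
    labels <- rep(seq_len(K), each = spec$n_trials_per_class)
    subjects <- rep(rep_len(seq_len(spec$n_subjects), spec$n_trials_per_class),
                    times = K)
    sig <- array(0, c(n, ch, ns))
    for (i in seq_len(n)) {
      k <- labels[i]
      x <- matrix(0, ch, ns)
      for (b in seq_len(nrow(spec$bands))) {
        f <- stats::runif(1, spec$bands$f_lo[b], spec$bands$f_hi[b])
        amp <- spec$base_amplitude * spec$class_band_gain[k, b]
        ph <- stats::runif(ch, 0, 2 * pi)
        x <- x + amp * sin(outer(ph, 2 * pi * f * tt, "+"))
      }
      if (spec$noise_sd > 0) {
        rho <- spec$channel_corr
        eps <- matrix(stats::rnorm(ch * ns), ch, ns)
        if (rho > 0) {
          shared <- matrix(stats::rnorm(ns), 1, ns)
          eps <- sqrt(1 - rho) * eps +
            sqrt(rho) * shared[rep(1, ch), , drop = FALSE]
        }
        x <- x + spec$noise_sd * eps
      }
      sig[i, , ] <- x
    }
    out <- list(signals = sig, fs = spec$fs, labels = labels,
                subject_ids = subjects)
    class(out) <- "raw_eeg_dataset"
    out
  })
}

#' @export
print.raw_eeg_dataset <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("raw EEG dataset: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("classes:", paste(sprintf("%d (n=%d)", sort(unique(x$labels)),
                                tabulate(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a pre-extracted feature dataset with class structure
#'
#' Draws standard-Gaussian DE and PSD feature tensors and shifts, for class
#' k, every cell of frequency band `((k - 1) mod bands) + 1` by
#' `effect_size` standard deviations in both modalities. Layouts follow the
#' two documented conventions: `seed_like` gives (n, 5 bands, 62 channels,
#' 10 windows) with 3 classes, `deap_like` gives (n, 32 channels, 5 bands,
#' 60 steps) with 2 classes.
#'
#' @param layout `"seed_like"` or `"deap_like"`.
#' @param n_per_class trials per class.
#' @param effect_size class-mean separation in units of the feature standard
#'   deviation (>= 0).
#' @param seed RNG seed.
#' @param n_classes optionally override the layout's class count.
#' @param n_subjects synthetic subjects, assigned round-robin within class.
#' @return list with elements `de`, `psd` (equal-shaped arrays), `labels`
#'   (integer 1..K, balanced), `subject_ids`, `layout`.
#' @export
generate_feature_dataset <- function(layout = c("seed_like", "deap_like"),
                                     n_per_class = 10L,
                                     effect_size = 1,
                                     seed = 1L,
                                     n_classes = NULL,
                                     n_subjects = 1L) {
  layout <- match.arg(layout)
  stopifnot(n_per_class >= 1, effect_size >= 0)
  if (is.null(n_classes)) n_classes <- if (layout == "seed_like") 3L else 2L
  n <- n_per_class * n_classes
  dims <- if (layout == "seed_like") c(n, 5L, 62L, 10L) else c(n, 32L, 5L, 60L)
  band_axis <- if (layout == "seed_like") 2L else 3L
  n_bands <- dims[band_axis]
  with_seed(seed, {
    labels <- rep(seq_len(n_classes), each = n_per_class)
    perm <- sample.int(n)
    labels <- labels[perm]
    subjects <- rep(rep_len(seq_len(n_subjects), n_per_class),
                    times = n_classes)[perm]
    make <- function() {
      x <- array(stats::rnorm(prod(dims)), dims)
      for (k in seq_len(n_classes)) {
        b <- (k - 1L) %% n_bands + 1L
        idx <- which(labels == k)
        if (band_axis == 2L) {
          x[idx, b, , ] <- x[idx, b, , ] + effect_size
        } else {
          x[idx, , b, ] <- x[idx, , b, ] + effect_size
        }
      }
      x
    }
    list(de = make(), psd = make(), labels = labels,
         subject_ids = subjects, layout = layout)
  })
}
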