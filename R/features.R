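# Band-limited feature extraction: zero-phase Butterworth filter bank,
# differential entropy per sliding window, and Welch power spectral density
# pooled into canonical bands.

check_bands <- function(bands, fs) {
  stopifnot(is.data.frame(bands), all(c("name", "f_lo", "f_hi") %in% names(bands)))
  bad <- which(bands$f_hi >= fs / 2)
  if (length(bad)) {
    stop("band '", bands$name[bad[1]], "' (", bands$f_lo[bad[1]], "-",
         bands$f_hi[bad[1]], " Hz) reaches the Nyquist frequency at fs = ",
         fs, " Hz")
  }
  stopifnot(all(bands$f_lo > 0), all(bands$f_lo < bands$f_hi))
}

#' Decompose a signal into frequency bands
#'
#' Zero-phase band-pass filtering: a 4th-order Butterworth band-pass design
#' applied forward and backward (`signal::filtfilt`), one filter per band.
#'
#' @param x numeric signal (one channel).
#' @param bands band definition data.frame (see [eeg_bands()]).
#' @param fs sampling rate in Hz.
#' @return Matrix (length(x) x bands), one filtered copy per column.
#' @export
bandpass_decompose <- function(x, bands = eeg_bands(), fs) {
  check_bands(bands, fs)
  if (length(x) < 24) stop("signal too short to filter reliably")
  out <- matrix(0, length(x), nrow(bands))
  colnames(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    flt <- signal::butter(2, c(bands$f_lo[b], bands$f_hi[b]) / (fs / 2),
                          type = "pass")
    out[, b] <- signal::filtfilt(flt, x)
  }
  out
}

#' Differential entropy of a band-limited window
#'
#' Under the Gaussian approximation for a band-limited EEG window, the
#' differential entropy is \eqn{\tfrac12 \ln(2\pi e \sigma^2)} (natural log,
#' nats), with \eqn{\sigma^2} the window's sample variance.
#'
#' @param x numeric window (length >= 2, non-constant).
#' @return Differential entropy in nats.
#' @export
differential_entropy <- function(x) {
  if (length(x) < 2) stop("window must contain at least two samples")
  s2 <- stats::var(x)
  if (s2 == 0) stop("degenerate window: zero variance, entropy undefined")
  0.5 * log(2 * pi * exp(1) * s2)
}

#' Welch power spectral density
#'
#' Splits the signal into Hann-windowed segments, computes each segment's
#' periodogram normalised by the window energy \eqn{W = \sum_n w_n^2}, and
#' averages over all segments. One-sided: interior bins are doubled.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param segment_s segment duration in seconds (default 2).
#' @param overlap_frac fractional overlap between segments in [0, 1).
#' @return list with `freq` (Hz) and `psd` (non-negative power density).
#' @export
welch_psd <- function(x, fs, segment_s = 2, overlap_frac = 0.5) {
  nseg <- round(segment_s * fs)
  stopifnot(nseg >= 8, overlap_frac >= 0, overlap_frac < 1)
  if (length(x) < nseg) {
    stop("signal (", length(x), " samples) is shorter than one segment (",
         nseg, " samples)")
  }
  hop <- max(1L, round(nseg * (1 - overlap_frac)))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / nseg))
  W <- sum(w^2)
  nf <- nseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / W
    p <- p[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist for even lengths)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1) * fs / nseg, psd = acc / length(starts))
}

#' Extract band features from raw EEG
#'
#' Produces a (trials, bands, channels, windows) feature tensor. For
#' differential entropy, each channel is band-pass filtered once per band
#' and the closed form is evaluated on each non-overlapping sliding window.
#' For power spectral density, Welch's estimate (2-s Hann segments, 50%
#' overlap) is computed per window and averaged over each band's frequency
#' range. Trailing samples that do not fill a window are dropped.
#'
#' @param raw a `raw_eeg_dataset`.
#' @param bands band definitions.
#' @param window_s window length in seconds.
#' @param modality `"DE"` or `"PSD"`.
#' @param welch_segment_s Welch segment length for the PSD modality.
#' @return A list of class `"band_feature_tensor"`: `values`
#'   (n, bands, channels, windows), `modality`, `layout`, `window_s`,
#'   `band_names`.
#' @export
extract_features <- function(raw, bands = eeg_bands(), window_s = 6,
                             modality = c("DE", "PSD"),
                             welch_segment_s = 2) {
  modality <- match.arg(modality)
  stopifnot(inherits(raw, "raw_eeg_dataset"))
  check_bands(bands, raw$fs)
  d <- dim(raw$signals)
  wlen <- round(window_s * raw$fs)
  if (wlen > d[3]) stop("window (", window_s, " s) longer than trial")
  n_win <- d[3] %/% wlen
  dropped <- d[3] - n_win * wlen
  if (dropped > 0) {
    message("dropping ", dropped, " trailing samples per trial (",
            n_win, " full windows of ", window_s, " s)")
  }
  nb <- nrow(bands)
  out <- array(0, c(d[1], nb, d[2], n_win))
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- raw$signals[i, ch, ]
      if (modality == "DE") {
        xb <- bandpass_decompose(x, bands, raw$fs)
        for (wdx in seq_len(n_win)) {
          rows <- ((wdx - 1L) * wlen + 1L):(wdx * wlen)
          for (b in seq_len(nb)) {
            out[i, b, ch, wdx] <- differential_entropy(xb[rows, b])
          }
        }
      } else {
        for (wdx in seq_len(n_win)) {
          rows <- ((wdx - 1L) * wlen + 1L):(wdx * wlen)
          ps <- welch_psd(x[rows], raw$fs, segment_s = welch_segment_s)
          for (b in seq_len(nb)) {
            sel <- ps$freq >= bands$f_lo[b] & ps$freq <= bands$f_hi[b]
            out[i, b, ch, wdx] <- mean(ps$psd[sel])
          }
        }
      }
    }
  }
  res <- list(values = out, modality = modality, layout = "seed_like",
              window_s = window_s, band_names = bands$name)
  class(res) <- "band_feature_tensor"
  res
}
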