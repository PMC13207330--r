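#' Welch power spectral density
#'
#' Welch's averaged-periodogram estimator with Hann windows. The default
#' 2 s window with 50% overlap gives 0.5 Hz resolution. Densities are
#' one-sided in power units per Hz (microvolt^2/Hz for microvolt input)
#' and Parseval-consistent: integrating the density over frequency
#' recovers the signal variance up to windowing loss.
#'
#' @param recording A `recording`, or a numeric matrix (time x channel)
#'   with `fs` supplied.
#' @param window_length Segment length in seconds (default 2).
#' @param overlap Fractional overlap in `[0, 0.9]` (default 0.5).
#' @param fs Sampling rate, required when `recording` is a bare matrix.
#' @return An object of class `power_spectrum`: `freqs` (Hz), `power`
#'   (freq x channel matrix), `window_length`, `overlap`, `fs`.
#' @export
compute_psd <- function(recording, window_length = 2, overlap = 0.5,
                        fs = NULL) {
  if (inherits(recording, "recording")) {
    x <- recording$samples
    fs <- recording$montage$sampling_rate
  } else {
    x <- as.matrix(recording)
    if (is.null(fs)) stop("fs must be supplied for a bare matrix")
  }
  if (overlap < 0 || overlap > 0.9) stop("overlap must be in [0, 0.9]")
  nper <- round(window_length * fs)
  if (nrow(x) < nper) stop("recording shorter than one PSD window")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, nrow(x) - nper + 1L, by = step)
  w <- signal::hanning(nper)
  u <- sum(w^2)
  n_freq <- floor(nper / 2)
  freqs <- seq_len(n_freq) * fs / nper
  scale <- 2 / (fs * u)

  pow <- matrix(0, nrow = n_freq, ncol = ncol(x),
                dimnames = list(NULL, colnames(x)))
  for (s in starts) {
    seg <- x[s:(s + nper - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))           # detrend (mean removal)
    X <- stats::mvfft(seg * w)
    pw <- Mod(X[2:(n_freq + 1L), , drop = FALSE])^2 * scale
    if (nper %% 2L == 0L) pw[n_freq, ] <- pw[n_freq, ] / 2   # Nyquist bin
    pow <- pow + pw
  }
  pow <- pow / length(starts)

  structure(
    list(freqs = freqs, power = pow, window_length = window_length,
         overlap = overlap, fs = fs, n_segments = length(starts)),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins (%.3g-%.3g Hz), %d channel(s), %d Welch segment(s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$power),
              x$n_segments))
  invisible(x)
}

#' Band-averaged magnitude-squared coherence
#'
#' Welch cross-spectral coherence between two channels, averaged over the
#' frequency bins of a band. Values lie in `[0, 1]` and are symmetric in
#' channel order.
#'
#' @param recording A `recording`.
#' @param ch_a,ch_b Distinct channel labels.
#' @param band Numeric `c(lo, hi)` in Hz.
#' @param window_length,overlap Welch parameters as in [compute_psd()].
#' @return Scalar coherence in `[0, 1]`.
#' @export
coherence <- function(recording, ch_a, ch_b, band = c(8, 13),
                      window_length = 2, overlap = 0.5) {
  stopifnot(inherits(recording, "recording"))
  if (identical(ch_a, ch_b)) {
    stop("coherence requires two distinct channel labels")
  }
  x <- recording$samples
  stopifnot(ch_a %in% colnames(x), ch_b %in% colnames(x))
  fs <- recording$montage$sampling_rate
  nper <- round(window_length * fs)
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, nrow(x) - nper + 1L, by = step)
  w <- signal::hanning(nper)
  n_freq <- floor(nper / 2)
  freqs <- seq_len(n_freq) * fs / nper

  sxx <- syy <- numeric(n_freq)
  sxy <- complex(length.out = n_freq)
  for (s in starts) {
    a <- x[s:(s + nper - 1L), ch_a]; a <- (a - mean(a)) * w
    b <- x[s:(s + nper - 1L), ch_b]; b <- (b - mean(b)) * w
    A <- fft(a)[2:(n_freq + 1L)]
    B <- fft(b)[2:(n_freq + 1L)]
    sxx <- sxx + Mod(A)^2
    syy <- syy + Mod(B)^2
    sxy <- sxy + A * Conj(B)
  }
  msc <- Mod(sxy)^2 / (sxx * syy)
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  mean(msc[sel])
}

#' Triple-channel coherence over the sensorimotor strip
#'
#' Mean of the three pairwise band coherences among `C3`, `C4` and `Cz`,
#' the training statistic of coherence-based sensorimotor protocols.
#'
#' @param recording A `recording` containing the three channels.
#' @param band Numeric `c(lo, hi)` in Hz (default the 8-13 Hz mu band).
#' @param channels Three channel labels (default `C3`, `C4`, `Cz`).
#' @param ... Passed to [coherence()].
#' @return Scalar mean coherence in `[0, 1]`.
#' @export
triple_coherence <- function(recording, band = c(8, 13),
                             channels = c("C3", "C4", "Cz"), ...) {
  stopifnot(length(channels) == 3L)
  pairs <- utils::combn(channels, 2)
  mean(apply(pairs, 2, function(p) {
    coherence(recording, p[1], p[2], band = band, ...)
  }))
}
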