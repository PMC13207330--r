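#' Synthesize a multichannel EEG recording from spectral models
#'
#' Generates per-channel time series whose expected one-sided power spectral
#' density equals [evaluate_model_psd()] of the corresponding model.
#' Synthesis is by spectral shaping of complex Gaussian noise in the
#' frequency domain (inverse FFT), which yields realistic random phases
#' rather than a sum of sinusoids.
#'
#' @param models A single [spectral_model()] (recycled over channels) or a
#'   list of one model per channel, optionally named by channel label.
#' @param montage A [montage()].
#' @param duration Recording length in seconds; at least 4 s so that a
#'   Welch estimate with the default 2 s window has multiple segments.
#' @param seed Integer seed; identical inputs give bitwise-identical
#'   samples.
#' @return An object of class `recording`: a list with `montage`,
#'   `duration`, `samples` (time x channel matrix, microvolt scale),
#'   `truth` (list of per-channel models) and `seed`.
#' @examples
#' rec <- synthesize_recording(mci_model(), montage(c("O1", "O2")), 8, seed = 1)
#' dim(rec$samples)
#' @export
synthesize_recording <- function(models, montage, duration, seed) {
  stopifnot(inherits(montage, "montage"))
  stopifnot(is.numeric(duration), length(duration) == 1L)
  if (duration < 4) stop("duration must be at least 4 s (needs multiple PSD windows)")
  stopifnot(is.numeric(seed), length(seed) == 1L)
  labels <- montage$channel_labels
  n_ch <- length(labels)
  if (inherits(models, "spectral_model")) {
    models <- rep(list(models), n_ch)
  }
  stopifnot(length(models) == n_ch)
  if (!is.null(names(models))) models <- models[labels]
  names(models) <- labels

  fs <- montage$sampling_rate
  n <- round(duration * fs)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  samples <- matrix(0, nrow = n, ncol = n_ch, dimnames = list(NULL, labels))
  for (j in seq_len(n_ch)) {
    samples[, j] <- .shape_noise(models[[j]], n, fs)
  }

  structure(
    list(montage = montage, duration = duration, samples = samples,
         truth = models, seed = seed),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels, %.4g s @ %g Hz (seed %s)\n",
              ncol(x$samples), x$duration, x$montage$sampling_rate,
              format(x$seed)))
  invisible(x)
}

# One channel of spectrally shaped Gaussian noise, drawn from the CURRENT
# RNG stream: |X_k|^2 expectation = S_k * fs * n / 2 so the one-sided
# periodogram matches the target density S.
.shape_noise <- function(model, n, fs) {
  freqs <- seq_len(floor(n / 2)) * fs / n
  n_pos <- length(freqs)
  has_nyquist <- (n %% 2L == 0L)
  target <- evaluate_model_psd(model, freqs)
  amp <- sqrt(target * fs * n / 2)
  z <- complex(real = rnorm(n_pos), imaginary = rnorm(n_pos)) / sqrt(2)
  xk <- amp * z
  if (has_nyquist) {
    # Nyquist bin must be real for a real signal.
    xk[n_pos] <- amp[n_pos] * Re(z[n_pos]) * sqrt(2)
  }
  spec <- complex(length.out = n)
  spec[1] <- 0
  spec[2:(n_pos + 1L)] <- xk
  if (has_nyquist) {
    spec[(n_pos + 2L):n] <- Conj(rev(xk[-n_pos]))
  } else {
    spec[(n_pos + 2L):n] <- Conj(rev(xk))
  }
  Re(fft(spec, inverse = TRUE)) / n
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
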