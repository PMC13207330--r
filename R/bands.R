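#' Frequency band schemes
#'
#' The default clinical band scheme. Bands are `[lo, hi)` half-open
#' intervals in intent; [band_power()] integrates the density over the
#' closed interval on the discrete grid.
#'
#' @return A data.frame with columns `name`, `lo`, `hi`.
#' @export
band_scheme <- function() {
  data.frame(
    name = c("Delta", "Theta", "Alpha1", "Alpha2", "Beta1", "Beta2",
             "Gamma", "Mu"),
    lo = c(1, 4, 8, 10, 13, 20, 30, 8),
    hi = c(4, 8, 10, 13, 20, 30, 45, 13),
    stringsAsFactors = FALSE
  )
}

#' Band definition
#'
#' @param name Band name.
#' @param lo,hi Band edges in Hz with `0 < lo < hi`.
#' @return A one-row band data.frame.
#' @export
band_definition <- function(name, lo, hi) {
  stopifnot(lo > 0, hi > lo)
  data.frame(name = name, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

#' Absolute band power
#'
#' Trapezoidal integral of the power spectral density over a band.
#'
#' @param spectrum A `power_spectrum`.
#' @param band Either a `c(lo, hi)` numeric pair or a one-row band
#'   data.frame from [band_definition()]/[band_scheme()].
#' @return Named numeric vector: integrated power per channel.
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (is.data.frame(band)) band <- c(band$lo[1], band$hi[1])
  stopifnot(length(band) == 2L, band[2] > band[1])
  if (band[1] < min(spectrum$freqs) || band[2] > max(spectrum$freqs)) {
    stop("band extends beyond the spectrum support")
  }
  interior <- spectrum$freqs > band[1] & spectrum$freqs < band[2]
  # integration nodes: interpolated band edges plus interior grid points,
  # so bands narrower than the grid spacing still integrate correctly
  f <- c(band[1], spectrum$freqs[interior], band[2])
  apply(spectrum$power, 2, function(p) {
    pv <- c(approx(spectrum$freqs, p, xout = band[1])$y,
            p[interior],
            approx(spectrum$freqs, p, xout = band[2])$y)
    sum(diff(f) * (pv[-1] + pv[-length(pv)]) / 2)
  })
}

#' Band power ratio
#'
#' The controller's feedback signal `y` in ratio mode, e.g. Theta/Alpha.
#'
#' @param spectrum A `power_spectrum`.
#' @param numerator_band,denominator_band Bands as in [band_power()].
#' @return Named numeric vector of per-channel ratios.
#' @export
power_ratio <- function(spectrum, numerator_band, denominator_band) {
  num <- band_power(spectrum, numerator_band)
  den <- band_power(spectrum, denominator_band)
  if (any(den <= 0)) stop("denominator band power must be positive")
  num / den
}
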