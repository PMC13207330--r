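#' Fit the aperiodic (1/f) component of a power spectrum
#'
#' Robust log-log linear fit of power against frequency with iterative
#' masking of oscillatory peaks: bins whose log-power residual exceeds 2.5
#' standard deviations above the running fit are excluded and the fit
#' repeated until the mask stabilizes. This yields the aperiodic offset `k`
#' and exponent `x` of the model `P(f) = L + k f^(-x)`. A non-zero noise
#' floor `L` is then estimated by a constrained nonlinear refinement on the
#' unmasked bins and retained only when the Bayesian information criterion
#' favors the three-parameter model; otherwise `L = 0`.
#'
#' @param spectrum A `power_spectrum`.
#' @param fit_range Numeric `c(lo, hi)` in Hz with `lo > 0`; default 1-40.
#' @param channel Channel index or label (default first channel).
#' @return An object of class `aperiodic_fit`: `noise_floor`, `offset`,
#'   `exponent`, `fit_range`, `goodness` (R^2 of the log-log fit on
#'   unmasked bins), `masked` (logical per bin in range), `freqs`.
#' @export
fit_aperiodic <- function(spectrum, fit_range = c(1, 40), channel = 1L) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  stopifnot(fit_range[1] > 0, fit_range[2] > fit_range[1])
  p_all <- spectrum$power[, channel]
  sel <- spectrum$freqs >= fit_range[1] & spectrum$freqs <= fit_range[2]
  f <- spectrum$freqs[sel]
  p <- p_all[sel]
  if (any(p <= 0)) {
    # Zero bins carry no 1/f information; exclude from the log fit.
    keep <- p > 0
    f <- f[keep]; p <- p[keep]
  }
  lf <- log10(f)
  lp <- log10(p)

  mask <- rep(FALSE, length(f))
  fit <- NULL
  for (it in 1:10) {
    fit <- lm(lp[!mask] ~ lf[!mask])
    resid_all <- lp - (coef(fit)[1] + coef(fit)[2] * lf)
    s <- sd(resid_all[!mask])
    if (!is.finite(s) || s < 1e-10) break    # numerically exact fit
    new_mask <- resid_all > 2.5 * s
    if (sum(!new_mask) < 10L) {
      stop("fewer than 10 usable bins after peak masking")
    }
    if (identical(new_mask, mask)) break
    mask <- new_mask
  }
  if (sum(!mask) < 10L) stop("fewer than 10 usable bins after peak masking")
  k <- 10^coef(fit)[[1]]
  x <- -coef(fit)[[2]]

  # Optional white-noise floor: refit P = L + k f^-x on unmasked bins and
  # keep L > 0 only if BIC (on log residuals) improves.
  noise_floor <- 0
  fu <- f[!mask]; pu <- p[!mask]
  ll_resid <- function(Lv, kv, xv) log10(pmax(Lv + kv * fu^(-xv), 1e-300)) - log10(pu)
  bic <- function(r, npar) length(r) * log(mean(r^2)) + npar * log(length(r))
  bic2 <- bic(ll_resid(0, k, x), 2L)
  refined <- tryCatch(
    minpack.lm::nlsLM(
      lpu ~ log10(L + kk * fu^(-xx)),
      data = list(lpu = log10(pu), fu = fu),
      start = list(L = min(pu) / 2, kk = k, xx = max(x, 0.01)),
      lower = c(0, 1e-12, 0), upper = c(max(pu), Inf, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(refined)) {
    cf <- coef(refined)
    bic3 <- bic(ll_resid(cf[["L"]], cf[["kk"]], cf[["xx"]]), 3L)
    if (bic3 < bic2 - 2) {      # require clear evidence for the extra term
      noise_floor <- cf[["L"]]
      k <- cf[["kk"]]
      x <- cf[["xx"]]
    }
  }

  pred <- log10(pmax(noise_floor + k * fu^(-x), 1e-300))
  ss_res <- sum((log10(pu) - pred)^2)
  ss_tot <- sum((log10(pu) - mean(log10(pu)))^2)
  goodness <- if (ss_tot <= .Machine$double.eps) 1 else max(0, min(1, 1 - ss_res / ss_tot))

  structure(
    list(noise_floor = noise_floor, offset = k, exponent = x,
         fit_range = fit_range, goodness = goodness,
         freqs = f, masked = mask, channel = channel),
    class = "aperiodic_fit"
  )
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> L=%.4g, k=%.4g, x=%.3f, R^2=%.3f (%g-%g Hz)\n",
              x$noise_floor, x$offset, x$exponent, x$goodness,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Aperiodic model evaluated on a grid
#'
#' @param fit An `aperiodic_fit`.
#' @param freqs Frequencies in Hz.
#' @return Power values `L + k f^(-x)`.
#' @export
aperiodic_psd <- function(fit, freqs) {
  stopifnot(inherits(fit, "aperiodic_fit"), all(freqs > 0))
  fit$noise_floor + fit$offset * freqs^(-fit$exponent)
}

#' Flatten a spectrum by removing its aperiodic component
#'
#' @param spectrum A `power_spectrum`.
#' @param fit An `aperiodic_fit` for the chosen channel.
#' @param floor_at_zero Clip negative residuals to 0 (default TRUE).
#' @return List with `freqs` (restricted to the fit range) and `power`
#'   (residual oscillatory power).
#' @export
flatten_spectrum <- function(spectrum, fit, floor_at_zero = TRUE) {
  stopifnot(inherits(spectrum, "power_spectrum"), inherits(fit, "aperiodic_fit"))
  sel <- spectrum$freqs >= fit$fit_range[1] & spectrum$freqs <= fit$fit_range[2]
  f <- spectrum$freqs[sel]
  resid <- spectrum$power[sel, fit$channel] - aperiodic_psd(fit, f)
  if (floor_at_zero) resid <- pmax(resid, 0)
  list(freqs = f, power = resid)
}
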