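#' Standardized deviation (z-score) against a normative entry
#'
#' `z = (observed - mean) / sd`, with the clinical flag convention:
#' `normative` for `|z| <= 1.5`, `target` for `|z| > 1.5` (primary
#' neuroregulation targets), `pathological` for `|z| > 2.0` (strict
#' inequality; `z = 2.0` exactly is flagged `target`).
#'
#' @param observed Observed metric value.
#' @param mean Normative mean.
#' @param sd Normative standard deviation; must be positive.
#' @return List with `z` and `flag`.
#' @export
zscore <- function(observed, mean, sd) {
  if (!is.finite(sd) || sd <= 0) stop("normative sd must be positive")
  z <- (observed - mean) / sd
  flag <- if (abs(z) > 2.0) "pathological" else if (abs(z) > 1.5) "target" else "normative"
  list(z = z, flag = flag)
}

#' Build a z-score map from observed metrics and a normative database
#'
#' @param observed Data.frame with columns `channel`, `band`, `metric`,
#'   `value`.
#' @param db A `normative_db` (already stratum-matched, or supply `age`).
#' @param age Optional age in years; when given, [match_stratum()] is
#'   applied first.
#' @return A data.frame of class `zscore_map` with columns `channel`,
#'   `band`, `metric`, `value`, `mean`, `sd`, `z`, `flag`.
#' @export
zscore_map <- function(observed, db, age = NULL) {
  stopifnot(is.data.frame(observed),
            all(c("channel", "band", "metric", "value") %in% names(observed)))
  if (!is.null(age)) db <- match_stratum(db, age)
  m <- merge(observed, as.data.frame(db)[, c("channel", "band", "metric", "mean", "sd")],
             by = c("channel", "band", "metric"), sort = FALSE)
  if (nrow(m) == 0L) stop("no observed metric matches a normative entry")
  zs <- mapply(function(v, mu, s) zscore(v, mu, s),
               m$value, m$mean, m$sd, SIMPLIFY = FALSE)
  m$z <- vapply(zs, `[[`, numeric(1), "z")
  m$flag <- vapply(zs, `[[`, character(1), "flag")
  class(m) <- c("zscore_map", "data.frame")
  m
}

#' Euclidean Clinical Deviation Index
#'
#' The aggregate deviation `sqrt(sum(z_i^2))` over the (optionally
#' filtered) entries of a z-score map - a norm on the standardized metric
#' vector, zero iff every entry sits at its normative mean.
#'
#' @param zmap A `zscore_map` (or data.frame with a `z` column).
#' @param selection Optional logical/integer index or a character vector of
#'   channel labels restricting the entries (e.g. Precuneus-mapped
#'   channels).
#' @return Non-negative scalar.
#' @export
cdi_euclidean <- function(zmap, selection = NULL) {
  stopifnot("z" %in% names(zmap))
  z <- zmap$z
  if (!is.null(selection)) {
    if (is.character(selection)) {
      z <- z[zmap$channel %in% selection]
    } else {
      z <- z[selection]
    }
  }
  if (length(z) == 0L) stop("empty selection for CDI")
  sqrt(sum(z^2))
}

#' CDI as percentage deviation of the i-APF from the normative centre
#'
#' `(center - iapf) / center * 100`, signed: negative when the individual
#' alpha peak exceeds the normative centre. Full precision is returned;
#' clinical reports print two decimals (see [format_cdi_percent()]).
#'
#' @param iapf Individual alpha peak frequency in Hz.
#' @param normative_center Normative alpha centre frequency in Hz
#'   (default 10.25; population-dependent, hence a parameter).
#' @return Signed percentage (full precision).
#' @examples
#' cdi_percent(9.78)        # about 4.585 (prints as 4.58)
#' @export
cdi_percent <- function(iapf, normative_center = 10.25) {
  stopifnot(is.numeric(iapf), is.numeric(normative_center),
            normative_center > 0)
  (normative_center - iapf) / normative_center * 100
}

#' Two-decimal clinical report form of CDI%
#'
#' Truncates toward zero at two decimals, the convention of the clinical
#' worked example (0.47/10.25 x 100 reported as 4.58%).
#'
#' @param x CDI percentage (full precision).
#' @return Numeric truncated to two decimals.
#' @export
format_cdi_percent <- function(x) {
  trunc(x * 100) / 100
}

#' Spider-map deviation vector
#'
#' Radar-chart representation of a z-score map: one axis per (channel,
#' band, metric) triple, radius `|z|`, centre meaning z = 0 (the normative
#' mean). Axis order is stable across sessions so longitudinal difference
#' vectors are well defined.
#'
#' @param zmap A `zscore_map`.
#' @param axis_order Optional character vector of `channel.band.metric`
#'   axis keys fixing the order (e.g. from a first session); must match the
#'   map's axes exactly.
#' @return A data.frame of class `spider_map` with `axis`, `radius`,
#'   `flag`.
#' @export
spider_map <- function(zmap, axis_order = NULL) {
  stopifnot(inherits(zmap, "zscore_map") || all(c("z", "flag") %in% names(zmap)))
  axes <- paste(zmap$channel, zmap$band, zmap$metric, sep = ".")
  out <- data.frame(axis = axes, radius = abs(zmap$z), flag = zmap$flag,
                    stringsAsFactors = FALSE)
  if (!is.null(axis_order)) {
    if (!setequal(axis_order, axes) || anyDuplicated(axis_order)) {
      stop("axis_order does not match the axes of this map")
    }
    out <- out[match(axis_order, out$axis), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- out[order(out$axis), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("spider_map", "data.frame")
  out
}

#' Longitudinal spider-map difference
#'
#' Elementwise radius difference `session_b - session_a` on identical axis
#' sets; all-negative differences are the graphical "CDI subtraction"
#' (radii shrinking toward the normative centre).
#'
#' @param a,b `spider_map` objects over the same axes.
#' @return Data.frame with `axis` and `delta_radius`.
#' @export
spider_diff <- function(a, b) {
  stopifnot(inherits(a, "spider_map"), inherits(b, "spider_map"))
  if (!identical(a$axis, b$axis)) {
    b <- b[match(a$axis, b$axis), , drop = FALSE]
    if (anyNA(b$axis)) stop("axis mismatch between sessions")
  }
  data.frame(axis = a$axis, delta_radius = b$radius - a$radius,
             stringsAsFactors = FALSE)
}
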