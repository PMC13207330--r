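#' Offline analysis of a recording
#'
#' The full measurement pipeline without a controller: Welch spectrum,
#' per-channel aperiodic fit and peak extraction, i-APF by both rules
#' (three-highest-posterior-peak average and centre of gravity), deviation
#' from the normative alpha centre, z-score map and Euclidean CDI against
#' a normative database, spider map, and (optionally, for full 19-channel
#' montages) a standardized source map with DMN ROI powers.
#'
#' @param x A `recording`, or a path to an EDF file.
#' @param normative_db Optional `normative_db` (default the packaged
#'   synthetic one). `NULL` disables z-score outputs.
#' @param normative_center Normative alpha centre in Hz (default 10.25).
#' @param age Age in years for stratum matching (default 76).
#' @param alpha_band Alpha search band in Hz.
#' @param posterior_nodes Channels used by the top-3 i-APF rule.
#' @param iapf_method `"auto"` (top-3 posterior peak average, falling back
#'   to centre of gravity), `"pooled_peak"` (joint full-model fit on the
#'   channel-averaged spectrum - the lowest-variance choice when all
#'   channels share one generator, as in synthetic precision checks), or
#'   `"cog"` (mean per-channel centre of gravity).
#' @param window_length Welch window in seconds (default 2; longer windows
#'   reduce leakage bias for precision work).
#' @param sloreta Compute a standardized source map from alpha band powers
#'   (needs the full 19-channel montage; default FALSE).
#' @return An object of class `analysis_report` with elements `iapf`
#'   (primary estimate, Hz), `iapf_method`, `iapf_cog`, `per_channel_peaks`,
#'   `deviation_hz` (signed `center - iapf`), `deviation_abs_hz`,
#'   `cdi_percent` (full precision), `cdi_percent_reported` (two-decimal
#'   clinical form), `cdi_euclidean`, `zmap`, `spider`, `aperiodic`
#'   (per-channel exponents), `source_map`, `roi_powers`.
#' @export
analyze_recording <- function(x, normative_db = NULL,
                              normative_center = 10.25, age = 76,
                              alpha_band = c(7, 13),
                              posterior_nodes = c("O1", "O2", "Oz", "P3",
                                                  "P4", "Pz"),
                              iapf_method = c("auto", "pooled_peak", "cog"),
                              window_length = 2, sloreta = FALSE) {
  iapf_method <- match.arg(iapf_method)
  rec <- if (is.character(x)) read_edf(x) else x
  stopifnot(inherits(rec, "recording"))
  labels <- rec$montage$channel_labels
  psd <- compute_psd(rec, window_length = window_length)

  peak_freqs <- setNames(rep(NA_real_, length(labels)), labels)
  cogs <- setNames(rep(NA_real_, length(labels)), labels)
  exponents <- setNames(rep(NA_real_, length(labels)), labels)
  for (j in seq_along(labels)) {
    ap <- tryCatch(fit_aperiodic(psd, channel = j), error = function(e) NULL)
    if (is.null(ap)) next
    exponents[j] <- ap$exponent
    ps <- extract_peaks(psd, ap)
    peak_freqs[j] <- peak_in_band(ps, alpha_band)
    cogs[j] <- tryCatch(iapf_center_of_gravity(ps, alpha_band)$value,
                        error = function(e) NA_real_)
  }

  node_peaks <- peak_freqs[names(peak_freqs) %in% posterior_nodes]
  iapf_cog <- mean(cogs[!is.na(cogs)])

  if (iapf_method == "pooled_peak") {
    pooled <- pool_channels(psd)
    jm <- fit_spectral_model(pooled)
    iapf_val <- model_peak_in_band(jm, alpha_band)
    if (is.na(iapf_val)) stop("no alpha peak in the pooled spectrum")
    iapf_method <- "pooled_peak(joint fit)"
  } else if (iapf_method == "cog") {
    if (!is.finite(iapf_cog)) stop("no alpha power detectable on any channel")
    iapf_val <- iapf_cog
    iapf_method <- "center_of_gravity(mean over channels)"
  } else {
    top3 <- tryCatch(iapf_top3_average(peak_freqs, nodes = posterior_nodes,
                                       band = alpha_band),
                     error = function(e) NULL)
    if (!is.null(top3)) {
      iapf_val <- top3$value
      iapf_method <- "top3_average"
    } else {
      usable <- peak_freqs[!is.na(peak_freqs)]
      if (length(usable)) {
        iapf_val <- mean(sort(usable, decreasing = TRUE)[seq_len(min(3L, length(usable)))])
        iapf_method <- "top3_average(all channels)"
      } else {
        usable_cog <- cogs[!is.na(cogs)]
        if (!length(usable_cog)) stop("no alpha peak detectable on any channel")
        iapf_val <- mean(usable_cog)
        iapf_method <- "center_of_gravity(mean over channels)"
      }
    }
  }

  deviation <- normative_center - iapf_val
  pct <- cdi_percent(iapf_val, normative_center)

  zmap <- NULL; spider <- NULL; cdi_euc <- NA_real_
  if (!identical(normative_db, FALSE)) {
    if (is.null(normative_db)) {
      normative_db <- tryCatch(read_normative_db(synthetic_normative_path()),
                               error = function(e) NULL)
    }
    if (!is.null(normative_db)) {
      db <- tryCatch(match_stratum(normative_db, age), error = function(e) NULL)
      if (!is.null(db)) {
        obs <- .observed_band_powers(psd, labels)
        zmap <- tryCatch(zscore_map(obs, db), error = function(e) NULL)
        if (!is.null(zmap) && nrow(zmap) > 0L) {
          cdi_euc <- cdi_euclidean(zmap)
          spider <- spider_map(zmap)
        }
      }
    }
  }

  source_map <- NULL; roi_powers <- NULL
  if (isTRUE(sloreta)) {
    if (!all(standard_1020_labels() %in% labels)) {
      stop("sLORETA mapping needs the full 19-channel 10-20 montage; ",
           "recording has: ", paste(labels, collapse = ", "))
    }
    lf <- build_toy_headmodel()
    alpha_bp <- band_power(psd, alpha_band)[standard_1020_labels()]
    V <- sqrt(alpha_bp)            # amplitude-scale scalp vector
    J <- inverse_minimum_norm(V, lf)
    source_map <- sloreta_standardize(J, lf)
    roi_powers <- c(Precuneus = roi_power(source_map, "Precuneus"),
                    PCC = roi_power(source_map, "PCC"),
                    other = roi_power(source_map, "other"))
  }

  structure(
    list(iapf = iapf_val, iapf_method = iapf_method, iapf_cog = iapf_cog,
         per_channel_peaks = peak_freqs, node_peaks = node_peaks,
         deviation_hz = deviation, deviation_abs_hz = abs(deviation),
         cdi_percent = pct, cdi_percent_reported = format_cdi_percent(pct),
         cdi_euclidean = cdi_euc, zmap = zmap, spider = spider,
         aperiodic = exponents, source_map = source_map,
         roi_powers = roi_powers, normative_center = normative_center),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> i-APF %.3f Hz (%s)\n", x$iapf, x$iapf_method))
  cat(sprintf("  deviation from %.2f Hz centre: %.2f Hz; CDI%% = %.2f\n",
              x$normative_center, x$deviation_abs_hz, x$cdi_percent_reported))
  if (is.finite(x$cdi_euclidean)) {
    cat(sprintf("  Euclidean CDI over %d metrics: %.2f\n",
                nrow(x$zmap), x$cdi_euclidean))
  }
  invisible(x)
}

#' Write a report to JSON or CSV
#'
#' JSON keeps the scalar endpoints and tables; CSV writes the epoch table
#' (session reports), trajectory (program reports) or spider map/z-map
#' (analysis reports).
#'
#' @param report A `session_report`, `program_report` or
#'   `analysis_report`.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- if (inherits(report, "session_report")) report$epochs
    else if (inherits(report, "program_report")) report$trajectory
    else if (inherits(report, "analysis_report")) {
      if (!is.null(report$spider)) report$spider else
        data.frame(iapf = report$iapf, cdi_percent = report$cdi_percent)
    } else stop("unsupported report type")
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(path))
  }
  obj <- .report_as_list(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path JSON path written by [write_report()].
#' @return A plain list mirroring the report's scalar fields and tables.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.report_as_list <- function(report) {
  if (inherits(report, "session_report")) {
    list(type = "session",
         seed = report$config$seed,
         n_epochs = nrow(report$epochs),
         success_rate = report$success_rate,
         start_iapf = report$start_iapf, end_iapf = report$end_iapf,
         start_cdi = report$start_cdi, end_cdi = report$end_cdi,
         tier = report$tier$tier,
         epochs = report$epochs)
  } else if (inherits(report, "program_report")) {
    list(type = "program",
         seed = report$config$seed,
         n_sessions = nrow(report$trajectory),
         cdi_subtraction = report$cdi_subtraction,
         trajectory = report$trajectory)
  } else if (inherits(report, "analysis_report")) {
    list(type = "analysis",
         iapf = report$iapf, iapf_method = report$iapf_method,
         iapf_cog = report$iapf_cog,
         deviation_hz = report$deviation_hz,
         deviation_abs_hz = report$deviation_abs_hz,
         cdi_percent = report$cdi_percent,
         cdi_percent_reported = report$cdi_percent_reported,
         cdi_euclidean = report$cdi_euclidean,
         aperiodic = as.list(report$aperiodic),
         roi_powers = as.list(report$roi_powers))
  } else stop("unsupported report type")
}
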