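#' Read a normative qEEG database
#'
#' CSV schema: `channel, band, metric, age_lo, age_hi, mean, sd` (an
#' optional `sex` column is accepted and carried through, reserved for
#' future stratification). Rows with `sd <= 0` are rejected with their row
#' number; overlapping age strata for the same (channel, band, metric) are
#' rejected.
#'
#' @param path CSV file path.
#' @param known_channels Optional character vector; rows with channels
#'   outside it are rejected. Defaults to the 19-channel 10-20 labels plus
#'   `Oz` and the ROI labels `Precuneus`/`PCC`.
#' @return A data.frame of class `normative_db`.
#' @export
read_normative_db <- function(path,
                              known_channels = c(standard_1020_labels(),
                                                 "Oz", "Precuneus", "PCC")) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("channel", "band", "metric", "age_lo", "age_hi", "mean", "sd")
  missing_cols <- setdiff(required, names(db))
  if (length(missing_cols)) {
    stop("normative database missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_sd <- which(!is.finite(db$sd) | db$sd <= 0)
  if (length(bad_sd)) {
    stop("normative database rows with sd <= 0 (rows ",
         paste(bad_sd, collapse = ", "), ")")
  }
  bad_ch <- which(!db$channel %in% known_channels)
  if (length(bad_ch)) {
    stop("unknown channel label(s) in rows ", paste(bad_ch, collapse = ", "),
         ": ", paste(unique(db$channel[bad_ch]), collapse = ", "))
  }
  key <- interaction(db$channel, db$band, db$metric, drop = TRUE)
  for (k in levels(key)) {
    rows <- db[key == k, , drop = FALSE]
    if (nrow(rows) > 1L) {
      o <- order(rows$age_lo)
      lo <- rows$age_lo[o]; hi <- rows$age_hi[o]
      if (any(lo[-1] <= hi[-length(hi)])) {
        stop("overlapping age strata for ", k)
      }
    }
  }
  class(db) <- c("normative_db", "data.frame")
  db
}

#' Select the age stratum covering an age
#'
#' Strata are closed intervals `[age_lo, age_hi]`; age 76 against strata
#' 60-75 and 76-120 selects the second.
#'
#' @param db A `normative_db`.
#' @param age Age in years.
#' @return The rows of `db` whose stratum covers `age`.
#' @export
match_stratum <- function(db, age) {
  stopifnot(inherits(db, "normative_db"))
  hit <- db$age_lo <= age & age <= db$age_hi
  if (!any(hit)) stop("no normative stratum covers age ", age)
  out <- db[hit, , drop = FALSE]
  class(out) <- class(db)
  out
}

#' Path to the packaged synthetic normative database
#'
#' A small synthetic normative table (plausible alpha/theta means and
#' standard deviations, two age strata: 60-75 and 76-120) used by the
#' examples and tests. Synthetic, for software validation only - not
#' clinical reference data.
#'
#' @return File path of the CSV inside the installed package.
#' @export
synthetic_normative_path <- function() {
  system.file("extdata", "normative_synthetic.csv", package = "alphaloop",
              mustWork = TRUE)
}
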