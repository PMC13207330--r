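#' Write a recording to EDF
#'
#' Minimal European Data Format writer: 16-bit samples, physical units
#' microvolts, one-second data records. A JSON sidecar with the ground-truth
#' spectral models can be written alongside.
#'
#' @param recording A `recording` from [synthesize_recording()] (or the
#'   same structure from [read_edf()]).
#' @param path Output path (conventionally `.edf`).
#' @param truth_sidecar If `TRUE` (default when `recording$truth` is
#'   non-null), write `<path>.json` with the per-channel model parameters.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, truth_sidecar = !is.null(recording$truth)) {
  stopifnot(inherits(recording, "recording") || is.list(recording))
  x <- recording$samples
  fs <- recording$montage$sampling_rate
  labels <- recording$montage$channel_labels
  n_ch <- ncol(x)
  stopifnot(length(labels) == n_ch)
  spr <- as.integer(round(fs))             # samples per 1 s record
  n_rec <- floor(nrow(x) / spr)
  if (n_rec < 1) stop("recording shorter than one 1 s data record")

  pmin_ <- apply(x, 2, min)
  pmax_ <- apply(x, 2, max)
  # Guard degenerate flat channels.
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L
  dmax <- 32767L

  pad <- function(s, w) {
    s <- substr(as.character(s), 1L, w)
    formatC(s, width = w, flag = "-")
  }
  num <- function(v, w) vapply(v, function(z) pad(formatC(z, format = "g", digits = 8), w), "")

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(pad("0", 8), con, eos = NULL)
  writeChar(pad("synthetic subject", 80), con, eos = NULL)
  writeChar(pad("synthetic recording", 80), con, eos = NULL)
  writeChar(pad("01.01.00", 8), con, eos = NULL)       # start date
  writeChar(pad("00.00.00", 8), con, eos = NULL)       # start time
  writeChar(pad(as.character(256L + 256L * n_ch), 8), con, eos = NULL)
  writeChar(pad("", 44), con, eos = NULL)
  writeChar(pad(as.character(n_rec), 8), con, eos = NULL)
  writeChar(pad("1", 8), con, eos = NULL)              # record duration s
  writeChar(pad(as.character(n_ch), 4), con, eos = NULL)
  for (s in pad(labels, 16)) writeChar(s, con, eos = NULL)
  for (s in rep(pad("synthetic EEG", 80), n_ch)) writeChar(s, con, eos = NULL)
  for (s in rep(pad("uV", 8), n_ch)) writeChar(s, con, eos = NULL)
  for (s in num(pmin_, 8)) writeChar(s, con, eos = NULL)
  for (s in num(pmax_, 8)) writeChar(s, con, eos = NULL)
  for (s in rep(pad(dmin, 8), n_ch)) writeChar(s, con, eos = NULL)
  for (s in rep(pad(dmax, 8), n_ch)) writeChar(s, con, eos = NULL)
  for (s in rep(pad("", 80), n_ch)) writeChar(s, con, eos = NULL)  # prefilter
  for (s in rep(pad(spr, 8), n_ch)) writeChar(s, con, eos = NULL)
  for (s in rep(pad("", 32), n_ch)) writeChar(s, con, eos = NULL)  # reserved

  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (j in seq_len(n_ch)) {
      dig <- as.integer(round((x[rows, j] - pmin_[j]) / gain[j]) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }

  if (isTRUE(truth_sidecar) && !is.null(recording$truth)) {
    side <- lapply(recording$truth, function(m) {
      list(noise_floor = m$noise_floor, aperiodic_offset = m$aperiodic_offset,
           aperiodic_exponent = m$aperiodic_exponent,
           peaks = lapply(m$peaks, function(p) {
             list(center_freq = p$center_freq, amplitude = p$amplitude,
                  bandwidth_sd = p$bandwidth_sd)
           }))
    })
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Minimal EDF reader for continuous 16-bit recordings with a uniform
#' sampling rate across channels (the layout [write_edf()] produces and the
#' common clinical export). If a `<path>.json` truth sidecar exists it is
#' loaded into `$truth`.
#'
#' @param path Path to an EDF file.
#' @return A `recording` (see [synthesize_recording()]); `truth` is `NULL`
#'   when no sidecar is present.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), "")
  for (i in seq_len(n_ch)) rd(80)
  units <- vapply(seq_len(n_ch), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  for (i in seq_len(n_ch)) rd(80)
  spr <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), ""))
  for (i in seq_len(n_ch)) rd(32)
  stopifnot(header_bytes == 256L + 256L * n_ch)
  if (length(unique(spr)) != 1L) {
    stop("read_edf supports a uniform sampling rate across channels")
  }
  fs <- spr[1] / rec_dur

  gain <- (pmax_ - pmin_) / (dmax - dmin)
  samples <- matrix(0, nrow = n_rec * spr[1], ncol = n_ch,
                    dimnames = list(NULL, labels))
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (j in seq_len(n_ch)) {
      dig <- readBin(con, what = "integer", n = spr[j], size = 2L,
                     endian = "little", signed = TRUE)
      samples[rows, j] <- pmin_[j] + (dig - dmin[j]) * gain[j]
    }
  }

  truth <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    raw <- jsonlite::read_json(sidecar)
    truth <- lapply(raw, function(m) {
      spectral_model(m$noise_floor, m$aperiodic_offset, m$aperiodic_exponent,
                     lapply(m$peaks, function(p) {
                       gaussian_peak(p$center_freq, p$amplitude, p$bandwidth_sd)
                     }))
    })
    names(truth) <- labels
  }

  structure(
    list(montage = montage(labels, fs), duration = n_rec * rec_dur,
         samples = samples, truth = truth, seed = NA_integer_),
    class = "recording"
  )
}
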