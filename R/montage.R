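#' EEG montage
#'
#' A set of unique 10-20 channel labels plus a sampling rate. The clinical
#' minimum sampling rate for this framework is 250 Hz.
#'
#' @param channel_labels Character vector of unique channel labels.
#' @param sampling_rate Sampling rate in Hz, at least 250.
#' @return An object of class `montage`.
#' @examples
#' montage(c("O1", "O2", "Pz"), 250)
#' @export
montage <- function(channel_labels = standard_1020_labels(),
                    sampling_rate = 250) {
  stopifnot(is.character(channel_labels), length(channel_labels) >= 1L)
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1L)
  if (sampling_rate < 250) {
    stop("sampling_rate must be at least 250 Hz")
  }
  structure(list(channel_labels = channel_labels,
                 sampling_rate = sampling_rate),
            class = "montage")
}

#' Standard 19-channel 10-20 labels
#'
#' @return Character vector of the 19 classic 10-20 electrode names.
#' @export
standard_1020_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Idealized unit-sphere positions for the 19-channel 10-20 montage
#'
#' Electrodes are placed on the unit sphere: the outer ring at the equator
#' every 36 degrees, intermediate sites at 45-50 degree inclination, Cz at
#' the vertex. Coordinates are (x right, y anterior, z superior). This is
#' the sensor geometry of the toy spherical head model.
#'
#' @return A 19 x 3 matrix with rownames = channel labels.
#' @export
standard_1020_positions <- function() {
  deg <- pi / 180
  sph <- function(incl, az) {
    c(sin(incl * deg) * cos(az * deg),
      sin(incl * deg) * sin(az * deg),
      cos(incl * deg))
  }
  pos <- rbind(
    Fp1 = sph(90, 108), Fp2 = sph(90, 72),
    F7  = sph(90, 144), F8  = sph(90, 36),
    T3  = sph(90, 180), T4  = sph(90, 0),
    T5  = sph(90, 216), T6  = sph(90, 324),
    O1  = sph(90, 252), O2  = sph(90, 288),
    F3  = sph(50, 120), F4  = sph(50, 60),
    C3  = sph(45, 180), C4  = sph(45, 0),
    P3  = sph(50, 240), P4  = sph(50, 300),
    Fz  = sph(45, 90),  Pz  = sph(45, 270),
    Cz  = sph(0, 0)
  )
  colnames(pos) <- c("x", "y", "z")
  pos[standard_1020_labels(), , drop = FALSE]
}
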