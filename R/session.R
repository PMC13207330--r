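#' Session configuration
#'
#' Everything one closed-loop neurofeedback session needs: the virtual
#' subject, the controller, the feedback signal definition and the
#' simulated autonomic stream. Defaults encode the clinical protocol:
#' 1 s epochs, Theta/Alpha suppression feedback from the sensorimotor
#' channels C3/C4/Cz, the 9.78-10.25 Hz high-precision training sub-band,
#' and the 70% operating point.
#'
#' @param subject A [virtual_subject()] (default: MCI-prior draw from
#'   `seed`).
#' @param controller A [bdws_posterior()].
#' @param n_epochs Number of 1 s epochs in the session (default 180).
#' @param epoch_length Epoch length in seconds (default 1).
#' @param buffer_epochs Sliding spectral-integration buffer in epochs
#'   (default 30).
#' @param direction `"suppress"` (y = Theta/Alpha ratio) or `"enhance"`
#'   (y = training-band power).
#' @param training_band High-precision alpha sub-band in Hz (default
#'   `c(9.78, 10.25)`).
#' @param target_channels Feedback channels (default C3, C4, Cz).
#' @param theta_band,alpha_band Bands for the ratio signal.
#' @param normative_center Normative alpha centre in Hz (default 10.25).
#' @param normative_db Optional `normative_db` for Euclidean CDI; default
#'   the packaged synthetic database.
#' @param age Subject age in years for stratum matching (default 76).
#' @param sampling_rate Hz (default 250).
#' @param hrv_baseline,hrv_phi,hrv_sd AR(1) parameters of the simulated
#'   HRV stream (ms).
#' @param hrv_drop_epochs Integer epochs at which an induced HRV drop
#'   (to 60% of baseline) exercises the gate; empty by default.
#' @param seed Master seed for all randomness in the session.
#' @return An object of class `session_config`.
#' @export
session_config <- function(subject = NULL, controller = NULL,
                           n_epochs = 180L, epoch_length = 1,
                           buffer_epochs = 30L,
                           direction = c("suppress", "enhance"),
                           training_band = c(9.78, 10.25),
                           target_channels = c("C3", "C4", "Cz"),
                           theta_band = c(4, 8), alpha_band = c(8, 13),
                           normative_center = 10.25, normative_db = NULL,
                           age = 76, sampling_rate = 250,
                           hrv_baseline = 42, hrv_phi = 0.95, hrv_sd = 0.8,
                           hrv_drop_epochs = integer(0), seed = 1L) {
  direction <- match.arg(direction)
  if (is.null(subject)) subject <- draw_mci_subject(seed)
  if (is.null(controller)) {
    controller <- bdws_posterior(rho_star = operating_point(),
                                 direction = direction)
  }
  if (is.null(normative_db)) {
    path <- synthetic_normative_path()
    normative_db <- read_normative_db(path)
  }
  stopifnot(inherits(subject, "virtual_subject"),
            inherits(controller, "bdws_posterior"),
            n_epochs >= buffer_epochs,
            training_band[1] >= alpha_band[1],
            training_band[2] <= alpha_band[2])
  structure(
    list(subject = subject, controller = controller,
         n_epochs = as.integer(n_epochs), epoch_length = epoch_length,
         buffer_epochs = as.integer(buffer_epochs), direction = direction,
         training_band = training_band, target_channels = target_channels,
         theta_band = theta_band, alpha_band = alpha_band,
         normative_center = normative_center, normative_db = normative_db,
         age = age, sampling_rate = sampling_rate,
         hrv_baseline = hrv_baseline, hrv_phi = hrv_phi, hrv_sd = hrv_sd,
         hrv_drop_epochs = as.integer(hrv_drop_epochs),
         seed = as.integer(seed)),
    class = "session_config"
  )
}

#' Run one closed-loop session
#'
#' Per epoch: the virtual subject's current spectral model generates 1 s
#' of EEG on the target channels; the sliding buffer's Welch spectrum
#' yields the feedback signal `y`; the controller rewards against its
#' current threshold and then updates the posterior; the subject takes a
#' plasticity step; the simulated HRV stream gates difficulty. i-APF and
#' CDI are measured from the buffer at the first full buffer and at the
#' session end. Fully deterministic under the config seed.
#'
#' @param config A [session_config()].
#' @return An object of class `session_report`: `epochs` (audit-trail
#'   data.frame), `start_iapf`, `end_iapf`, `start_cdi`, `end_cdi` (each a
#'   list with `percent` and `euclidean`), `start_spider`, `end_spider`,
#'   `controller`, `subject`, `success_rate`, `tier`, `config`.
#' @export
run_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  fs <- config$sampling_rate
  n_ep <- config$n_epochs
  n_samp <- round(config$epoch_length * fs)
  chans <- config$target_channels
  buf_rows <- config$buffer_epochs * n_samp
  buffer <- matrix(0, 0, length(chans), dimnames = list(NULL, chans))

  state <- config$subject
  ctrl <- config$controller
  min_buffer_s <- 8                      # need a few Welch segments
  hrv <- config$hrv_baseline

  rows <- vector("list", n_ep)
  start_metrics <- NULL

  for (ep in seq_len(n_ep)) {
    model <- subject_model(state)
    epoch <- vapply(chans, function(ch) .shape_noise(model, n_samp, fs),
                    numeric(n_samp))
    buffer <- rbind(buffer, epoch)
    if (nrow(buffer) > buf_rows) {
      buffer <- buffer[(nrow(buffer) - buf_rows + 1L):nrow(buffer), ,
                       drop = FALSE]
    }

    # Simulated autonomic stream (AR(1) around baseline, optional drops).
    hrv <- config$hrv_baseline +
      config$hrv_phi * (hrv - config$hrv_baseline) +
      rnorm(1, sd = config$hrv_sd)
    if (ep %in% config$hrv_drop_epochs) hrv <- 0.6 * config$hrv_baseline

    y <- NA_real_
    rewarded <- FALSE
    if (nrow(buffer) >= min_buffer_s * fs) {
      psd <- compute_psd(buffer, fs = fs)
      y <- if (config$direction == "suppress") {
        mean(power_ratio(psd, config$theta_band, config$alpha_band))
      } else {
        mean(band_power(psd, config$training_band))
      }
      rewarded <- reward_decision(y, ctrl$theta, ctrl$direction)
      ctrl <- update_posterior(ctrl, y)
      ctrl <- hrv_gate(hrv_state(hrv, config$hrv_baseline), ctrl)
      state <- subject_step(state, rewarded)
      if (is.null(start_metrics) && nrow(buffer) >= buf_rows) {
        start_metrics <- .session_metrics(buffer, fs, config)
      }
    }

    rows[[ep]] <- data.frame(
      epoch = ep, y = y,
      theta = if (is.na(ctrl$theta)) NA_real_ else ctrl$theta,
      rewarded = rewarded, iapf_true = state$iapf, hrv = hrv,
      rho_effective = ctrl$rho_effective)
  }

  epochs <- do.call(rbind, rows)
  active <- !is.na(epochs$y)
  sr <- if (any(active)) mean(epochs$rewarded[active]) else NA_real_
  end_metrics <- .session_metrics(buffer, fs, config)
  if (is.null(start_metrics)) start_metrics <- end_metrics

  structure(
    list(epochs = epochs,
         start_iapf = start_metrics$iapf, end_iapf = end_metrics$iapf,
         start_cdi = start_metrics$cdi, end_cdi = end_metrics$cdi,
         start_spider = start_metrics$spider, end_spider = end_metrics$spider,
         controller = ctrl, subject = state, success_rate = sr,
         tier = assign_tier(min(100, max(0, 100 * ifelse(is.na(sr), 0, sr)))),
         config = config),
    class = "session_report"
  )
}

# Buffer -> (i-APF estimate, CDI in both forms, spider map).
.session_metrics <- function(buffer, fs, config) {
  psd <- compute_psd(buffer, fs = fs)
  peak_freqs <- numeric(0)
  cogs <- numeric(0)
  for (j in seq_len(ncol(buffer))) {
    ap <- tryCatch(fit_aperiodic(psd, channel = j), error = function(e) NULL)
    if (is.null(ap)) next
    ps <- extract_peaks(psd, ap)
    pf <- peak_in_band(ps, config$alpha_band)
    if (!is.na(pf)) peak_freqs[colnames(buffer)[j]] <- pf
    cg <- tryCatch(iapf_center_of_gravity(ps, config$alpha_band)$value,
                   error = function(e) NA_real_)
    if (!is.na(cg)) cogs <- c(cogs, cg)
  }
  iapf_val <- if (length(peak_freqs) >= 1L) {
    mean(sort(peak_freqs, decreasing = TRUE)[seq_len(min(3L, length(peak_freqs)))])
  } else if (length(cogs)) {
    mean(cogs)
  } else NA_real_

  cdi_pct <- if (is.na(iapf_val)) NA_real_ else
    cdi_percent(iapf_val, config$normative_center)

  cdi_euc <- NA_real_
  spider <- NULL
  db <- tryCatch(match_stratum(config$normative_db, config$age),
                 error = function(e) NULL)
  if (!is.null(db)) {
    obs <- .observed_band_powers(psd, colnames(buffer))
    zm <- tryCatch(zscore_map(obs, db), error = function(e) NULL)
    if (!is.null(zm) && nrow(zm) > 0L) {
      cdi_euc <- cdi_euclidean(zm)
      spider <- spider_map(zm)
    }
  }
  list(iapf = iapf_val, cdi = list(percent = cdi_pct, euclidean = cdi_euc),
       spider = spider)
}

.observed_band_powers <- function(psd, channels,
                                  bands = c("Theta", "Alpha1", "Alpha2")) {
  scheme <- band_scheme()
  out <- list()
  for (b in bands) {
    bp <- band_power(psd, scheme[scheme$name == b, ])
    out[[b]] <- data.frame(channel = channels, band = b,
                           metric = "absolute_power", value = unname(bp),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf(
    "<session_report> %d epochs, success %.1f%%, i-APF %.2f -> %.2f Hz, CDI%% %.2f -> %.2f\n",
    nrow(x$epochs), 100 * x$success_rate, x$start_iapf, x$end_iapf,
    x$start_cdi$percent, x$end_cdi$percent))
  invisible(x)
}

#' Run a longitudinal training program
#'
#' Chains sessions with carried-over subject state (session `i + 1` starts
#' from session `i`'s end state). The program-level "CDI subtraction"
#' criterion is: median end-of-session CDI% over the last three sessions
#' below the median over the first three.
#'
#' @param config A [session_config()] for the first session.
#' @param n_sessions Number of sessions (>= 1).
#' @return An object of class `program_report`: `sessions` (list of
#'   session reports), `trajectory` (data.frame of per-session endpoints),
#'   `cdi_subtraction` (logical, NA when n_sessions < 6).
#' @export
run_longitudinal <- function(config, n_sessions) {
  stopifnot(inherits(config, "session_config"), n_sessions >= 1)
  sessions <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1L) * 1000L
    if (i > 1L) cfg$subject <- sessions[[i - 1L]]$subject
    sessions[[i]] <- run_session(cfg)
  }
  traj <- do.call(rbind, lapply(seq_len(n_sessions), function(i) {
    s <- sessions[[i]]
    data.frame(session = i, start_iapf = s$start_iapf, end_iapf = s$end_iapf,
               cdi_percent = s$end_cdi$percent,
               cdi_euclidean = s$end_cdi$euclidean,
               success_rate = s$success_rate)
  }))
  subtraction <- if (n_sessions >= 6) {
    median(tail(traj$cdi_percent, 3)) < median(head(traj$cdi_percent, 3))
  } else NA
  structure(list(sessions = sessions, trajectory = traj,
                 cdi_subtraction = subtraction, config = config),
            class = "program_report")
}

#' @export
print.program_report <- function(x, ...) {
  cat(sprintf("<program_report> %d sessions, CDI subtraction: %s\n",
              nrow(x$trajectory), format(x$cdi_subtraction)))
  print(x$trajectory, row.names = FALSE)
  invisible(x)
}
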