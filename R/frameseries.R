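# Series-level features and the analyze() front end that produces a
# FrameSeries: one row per 12.5 ms frame, missing (NA) values carrying the
# explicit unvoiced/absent semantics downstream summaries rely on.

#' Per-frame amplitude envelope and envelope modulation frequency
#'
#' The envelope is the per-frame RMS amplitude; its modulation frequency is
#' the location of the strongest non-DC peak of the envelope's power
#' spectrum, reported only when that peak is at least 3 times the median
#' spectral power (otherwise `NA`, e.g. for constant amplitude).
#'
#' @param envelope numeric vector of per-frame RMS values (>= 0).
#' @param frame_rate envelope sampling rate in frames per second
#'   (`1 / hop_s`).
#' @return list with `envelope` (unchanged) and `envelope_frequency` (Hz,
#'   or `NA` when fewer than 8 frames or no prominent peak).
#' @export
amplitude_envelope <- function(envelope, frame_rate) {
  out <- list(envelope = envelope, envelope_frequency = NA_real_)
  n <- length(envelope)
  if (n < 8) return(out)
  x <- envelope - mean(envelope)
  ps <- abs(fft(x))^2
  nb <- n %/% 2
  if (nb < 2) return(out)
  band <- ps[2:(nb + 1)]
  k <- which.max(band)
  if (band[k] >= 3 * median(band) && band[k] > 0)
    out$envelope_frequency <- k * frame_rate / n
  out
}

gaussian_checkerboard <- function(size) {
  half <- size / 2
  u <- seq_len(size) - half - 0.5
  g <- exp(-(u / (half / 2))^2)
  sgn <- outer(sign(u), sign(u))
  (g %o% g) * sgn
}

#' Spectral novelty curve of a frame sequence
#'
#' A cosine self-similarity matrix of the per-frame power spectra is
#' correlated along its diagonal with a Gaussian-tapered checkerboard
#' kernel; the rectified correlation is the novelty. Peaks mark frames
#' where the local spectral content changes.
#'
#' @param ps `bins x frames` power-spectrum matrix (or any non-negative
#'   frame-feature matrix).
#' @param kernel kernel size in frames (even; default 16).
#' @return non-negative numeric vector, one value per frame (zeros when
#'   the series is shorter than the kernel).
#' @export
spectral_novelty <- function(ps, kernel = 16) {
  n <- ncol(ps)
  nov <- numeric(n)
  if (n < kernel) return(nov)
  norms <- sqrt(colSums(ps^2))
  u <- ps / rep(pmax(norms, 1e-300), each = nrow(ps))
  u[, norms <= 0] <- 0
  ssm <- crossprod(u)
  K <- gaussian_checkerboard(kernel)
  half <- kernel %/% 2
  for (i in seq(half + 1L, n - half)) {
    idx <- (i - half):(i + half - 1L)
    nov[i] <- sum(ssm[idx, idx] * K)
  }
  pmax(nov, 0)
}

#' Run an analyzer profile over a recording
#'
#' Slices the audio into frames and runs every estimator in the profile's
#' `feature_set`: pitch (cepstral or autocorrelation variant per profile)
#' with voicing and hyperphonation flags, linear-prediction formants on
#' voiced frames, band energies, RMS amplitude, fricative score, spectral
#' entropy and spectral novelty. Missing values are explicit: unvoiced
#' frames carry `NA` f0 and formants.
#'
#' @param audio an [audio_segment()].
#' @param profile an [analyzer_profile()].
#' @return a `frame_series`: a data.frame with one row per frame
#'   (`frame_time`, `voiced`, and the profile's feature columns), with
#'   attributes `analyzer_id`, `sample_rate`, `hop_s` and `profile`.
#' @export
analyze <- function(audio, profile) {
  stopifnot(inherits(audio, "audio_segment"),
            inherits(profile, "analyzer_profile"))
  frames <- frame_signal(audio, profile)
  raw <- attr(frames, "raw")
  times <- attr(frames, "times")
  sr <- attr(frames, "sample_rate")
  hop_s <- attr(frames, "hop_len") / sr
  nf <- ncol(frames)
  fs <- profile$feature_set
  out <- data.frame(frame_time = times)

  ps <- if (nf > 0) power_spectrum_mat(frames) else
    matrix(0, max(1, nrow(frames) %/% 2), 0)

  pitch <- if (nf == 0) list(f0 = numeric(0), voiced = logical(0))
  else pitch_track_mat(raw, sr, profile)
  out$voiced <- pitch$voiced
  if ("f0" %in% fs) out$f0 <- pitch$f0
  if ("hyperphonation" %in% fs)
    out$hyperphonation <- !is.na(pitch$f0) &
      pitch$f0 > profile$hyperphonation_threshold

  if ("formants" %in% fs) {
    F1 <- F2 <- rep(NA_real_, nf)
    for (j in which(pitch$voiced)) {
      fm <- estimate_formants(raw[, j], profile, sr)
      F1[j] <- fm$F1
      F2[j] <- fm$F2
    }
    out$F1 <- F1
    out$F2 <- F2
  }
  if ("energy" %in% fs) {
    e <- frame_energy_mat(ps, sr, profile)
    out$energy_total <- e$total
    out$energy_low <- e$low
    out$energy_high <- e$high
  } else {
    # segmentation needs total energy regardless of feature set
    out$energy_total <- frame_energy_mat(ps, sr, profile)$total
  }
  if ("amplitude" %in% fs)
    out$amplitude <- if (nf > 0) sqrt(colMeans(raw^2)) else numeric(0)
  if ("spectral_entropy" %in% fs) out$spectral_entropy <- spectral_entropy_mat(ps)
  if ("fricative" %in% fs)
    out$fricative <- if (nf > 0)
      fricative_score_mat(ps, raw, sr, profile) else numeric(0)
  if ("novelty" %in% fs)
    out$novelty <- spectral_novelty(ps, profile$novelty_kernel)

  structure(out, analyzer_id = profile$analyzer_id, sample_rate = sr,
            hop_s = hop_s, frame_len_s = attr(frames, "frame_len") / sr,
            profile = profile, class = c("frame_series", "data.frame"))
}

#' Write a frame series as CSV with a JSON profile sidecar
#'
#' One row per frame, missing values as empty cells; the analyzer profile
#' parameters go to `<path>.json`.
#'
#' @param series a [analyze()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_frame_series <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE, na = "")
  prof <- attr(series, "profile")
  jsonlite::write_json(prof[setdiff(names(prof), "window")] ,
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
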