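# Source-filter cry synthesis: a glottal impulse train following a pitch
# contour, filtered through cascaded second-order formant resonators, with
# optional fricative (band-limited noise) stretches and additive background
# noise. The generator exists to provide ground truth (f0, formants,
# utterance boundaries, group effects) for every downstream stage.

#' Construct an audio segment
#'
#' @param samples numeric amplitude vector in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz.
#' @param infant_id,recording_id identifiers carried through the pipeline.
#' @return an object of class `audio_segment`.
#' @export
audio_segment <- function(samples, sample_rate, infant_id = "unknown",
                          recording_id = "r1") {
  if (length(samples) == 0) stop_invalid("audio segment must be non-empty")
  if (any(!is.finite(samples))) stop_invalid("audio samples must be finite")
  check_positive(sample_rate, "sample_rate")
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 infant_id = infant_id, recording_id = recording_id),
            class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment> infant %s / %s: %.2f s @ %d Hz\n",
              x$infant_id, x$recording_id,
              length(x$samples) / x$sample_rate, as.integer(x$sample_rate)))
  invisible(x)
}

#' Cry synthesis parameters
#'
#' Controls the source-filter generator. Defaults describe a typical newborn
#' cry: fundamental near 450 Hz with a rise-fall contour, occasional
#' hyperphonation episodes above 1 kHz, first two formants near 1100 and
#' 3300 Hz, utterances of 250-900 ms separated by 200-600 ms inspiratory
#' gaps.
#'
#' @param f0_base baseline fundamental frequency, Hz.
#' @param f0_contour list of `(time fraction, multiplier)` pairs describing
#'   the within-utterance pitch contour (linearly interpolated).
#' @param hyperphonation_prob probability that an utterance is produced in
#'   hyperphonation (f0 jumps to `hyperphonation_f0`).
#' @param hyperphonation_f0 hyperphonation fundamental, Hz (> 1000).
#' @param formants list of `(center Hz, bandwidth Hz)` pairs for F1, F2
#'   (optionally F3); centers must be strictly increasing.
#' @param fricative_prob probability that an utterance contains a fricative
#'   (turbulence-noise) stretch.
#' @param aspiration amplitude of aspiration noise mixed into the glottal
#'   source relative to the unit pulse train (newborn cries are breathy;
#'   this also gives the spectrum the inter-harmonic support that
#'   linear-prediction formant tracking relies on).
#' @param utterance_dur_range_ms,gap_dur_range_ms,n_utterances_range
#'   `(min, max)` sampling ranges for utterance durations, inter-utterance
#'   gaps and utterance counts per recording.
#' @param noise_snr_db background-noise signal-to-noise ratio in dB
#'   (`Inf` disables noise).
#' @param sample_rate sampling rate, Hz (>= 8000). Default 22050 Hz: infant
#'   cry energy lies below ~11 kHz.
#' @return an object of class `cry_synth_params`.
#' @export
cry_synth_params <- function(f0_base = 450,
                             f0_contour = list(c(0, 0.9), c(0.25, 1.1),
                                               c(0.6, 1.05), c(1, 0.8)),
                             hyperphonation_prob = 0.1,
                             hyperphonation_f0 = 1400,
                             formants = list(c(1100, 150), c(3300, 300)),
                             fricative_prob = 0.1,
                             aspiration = 0.15,
                             utterance_dur_range_ms = c(250, 900),
                             gap_dur_range_ms = c(200, 600),
                             n_utterances_range = c(3, 8),
                             noise_snr_db = 25,
                             sample_rate = 22050) {
  check_positive(f0_base, "f0_base")
  check_prob(hyperphonation_prob, "hyperphonation_prob")
  check_prob(fricative_prob, "fricative_prob")
  if (hyperphonation_f0 <= 1000)
    stop_invalid("'hyperphonation_f0' must exceed 1000 Hz")
  if (sample_rate < 8000) stop_invalid("'sample_rate' must be >= 8000 Hz")
  centers <- vapply(formants, `[`, numeric(1), 1)
  if (any(diff(centers) <= 0))
    stop_invalid("formant centers must be strictly increasing")
  if (any(centers >= sample_rate / 2))
    stop_invalid("formant centers must lie below the Nyquist frequency")
  for (r in list(utterance_dur_range_ms, gap_dur_range_ms)) {
    check_positive(r, "duration range")
    if (r[2] < r[1]) stop_invalid("duration range must be (min, max)")
  }
  if (any(n_utterances_range < 0) ||
      n_utterances_range[2] < n_utterances_range[1])
    stop_invalid("'n_utterances_range' must be a non-negative (min, max)")
  structure(list(f0_base = f0_base, f0_contour = f0_contour,
                 hyperphonation_prob = hyperphonation_prob,
                 hyperphonation_f0 = hyperphonation_f0,
                 formants = formants, fricative_prob = fricative_prob,
                 aspiration = aspiration,
                 utterance_dur_range_ms = utterance_dur_range_ms,
                 gap_dur_range_ms = gap_dur_range_ms,
                 n_utterances_range = n_utterances_range,
                 noise_snr_db = noise_snr_db, sample_rate = sample_rate),
            class = "cry_synth_params")
}

# cascade of two-pole resonators; gain renormalized afterwards
apply_formants <- function(x, formants, sr) {
  for (f in formants) {
    r <- exp(-pi * f[2] / sr)
    theta <- 2 * pi * f[1] / sr
    x <- as.numeric(stats::filter(x, c(2 * r * cos(theta), -r^2),
                                  method = "recursive"))
  }
  x
}

#' Synthesize one cry utterance
#'
#' A glottal impulse train at the (possibly hyperphonated) pitch contour is
#' filtered through the formant resonators; with probability
#' `fricative_prob` a stretch of the utterance is replaced by band-limited
#' turbulence noise. Peak amplitude is normalized to 0.9.
#'
#' @param params a [cry_synth_params()] object.
#' @param duration_ms utterance duration in milliseconds (> 0).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param hyperphonation `NA` to draw from `hyperphonation_prob`, or
#'   `TRUE`/`FALSE` to force.
#' @param fricative `NA` to draw from `fricative_prob`, or `TRUE`/`FALSE`.
#' @return an [audio_segment()] with attributes `f0_track` (per-sample true
#'   f0) and `hyperphonation`/`fricative` flags.
#' @export
synthesize_utterance <- function(params, duration_ms, seed = NULL,
                                 hyperphonation = NA, fricative = NA) {
  stopifnot(inherits(params, "cry_synth_params"))
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop_invalid("'duration_ms' must be positive")
  if (!is.null(seed)) set.seed(seed)
  sr <- params$sample_rate
  n <- max(2L, as.integer(round(duration_ms * sr / 1000)))
  hyper <- if (is.na(hyperphonation))
    runif(1) < params$hyperphonation_prob else isTRUE(hyperphonation)
  fric <- if (is.na(fricative))
    runif(1) < params$fricative_prob else isTRUE(fricative)

  base <- if (hyper) params$hyperphonation_f0 else params$f0_base
  cpts <- do.call(rbind, params$f0_contour)
  mult <- approx(cpts[, 1], cpts[, 2], xout = (seq_len(n) - 1) / (n - 1),
                 rule = 2)$y
  # hyperphonation is produced with a flattened contour (falsetto-like)
  if (hyper) mult <- 1 + 0.15 * (mult - 1)
  f0_track <- base * mult

  phase <- cumsum(f0_track) / sr
  src <- numeric(n)
  src[c(TRUE, diff(floor(phase)) >= 1)] <- 1
  src <- src + params$aspiration * rnorm(n)
  y <- apply_formants(src, params$formants, sr)

  if (fric) {
    len <- as.integer(n * runif(1, 0.3, 0.6))
    start <- as.integer(runif(1, 1, n - len))
    noise <- rnorm(len)
    bp <- signal::butter(4, c(2500, min(8000, sr / 2 - 100)) / (sr / 2),
                         type = "pass")
    noise <- signal::filtfilt(bp, noise)
    seg <- start:(start + len - 1)
    rms_y <- sqrt(mean(y[seg]^2))
    y[seg] <- noise / max(sqrt(mean(noise^2)), 1e-12) * rms_y
    f0_track[seg] <- NA  # unvoiced stretch
  }

  # 15 ms raised-cosine onset/offset ramps
  ramp <- min(as.integer(0.015 * sr), n %/% 2)
  if (ramp > 1) {
    w <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    y[seq_len(ramp)] <- y[seq_len(ramp)] * w
    y[(n - ramp + 1):n] <- y[(n - ramp + 1):n] * rev(w)
  }

  if (is.finite(params$noise_snr_db)) {
    sig_rms <- max(sqrt(mean(y^2)), 1e-12)
    y <- y + rnorm(n, sd = sig_rms * 10^(-params$noise_snr_db / 20))
  }
  y <- y / max(abs(y)) * 0.9
  out <- audio_segment(y, sr)
  attr(out, "f0_track") <- f0_track
  attr(out, "hyperphonation") <- hyper
  attr(out, "fricative") <- fric
  out
}

#' Synthesize a multi-utterance cry recording with ground-truth boundaries
#'
#' Utterances separated by silence gaps are concatenated; the background
#' noise floor (from `noise_snr_db`) covers gaps as well as utterances, so
#' segmentation thresholds are exercised realistically.
#'
#' @param params a [cry_synth_params()] object.
#' @param n_utterances number of utterances (>= 0); `NULL` draws from
#'   `params$n_utterances_range`.
#' @param seed integer seed.
#' @param infant_id,recording_id identifiers attached to the output.
#' @return list with `audio` (an [audio_segment()]) and `boundaries`
#'   (data.frame of `start_s`, `end_s`, `hyperphonation`, `fricative`).
#' @export
synthesize_recording <- function(params, n_utterances = NULL, seed = NULL,
                                 infant_id = "unknown", recording_id = "r1") {
  stopifnot(inherits(params, "cry_synth_params"))
  if (!is.null(seed)) set.seed(seed)
  sr <- params$sample_rate
  if (is.null(n_utterances)) {
    r <- params$n_utterances_range
    n_utterances <- as.integer(round(runif(1, r[1], r[2])))
  }
  if (n_utterances < 0) stop_invalid("'n_utterances' must be >= 0")

  lead <- as.integer(runif(1, 0.2, 0.4) * sr)
  pieces <- list(numeric(lead))
  bounds <- list()
  pos <- lead
  quiet <- params
  quiet$noise_snr_db <- Inf  # noise added once, recording-wide
  for (i in seq_len(n_utterances)) {
    dur <- runif(1, params$utterance_dur_range_ms[1],
                 params$utterance_dur_range_ms[2])
    u <- synthesize_utterance(quiet, dur)
    bounds[[i]] <- data.frame(
      start_s = pos / sr, end_s = (pos + length(u$samples)) / sr,
      hyperphonation = attr(u, "hyperphonation"),
      fricative = attr(u, "fricative"))
    pieces[[length(pieces) + 1L]] <- u$samples
    pos <- pos + length(u$samples)
    gap <- as.integer(runif(1, params$gap_dur_range_ms[1],
                            params$gap_dur_range_ms[2]) / 1000 * sr)
    pieces[[length(pieces) + 1L]] <- numeric(gap)
    pos <- pos + gap
  }
  y <- unlist(pieces)
  if (length(y) < sr %/% 10) y <- c(y, numeric(sr %/% 10 - length(y)))
  if (is.finite(params$noise_snr_db)) {
    ref <- if (n_utterances > 0) 0.9 / sqrt(2) else 0.05
    y <- y + rnorm(length(y), sd = ref * 10^(-params$noise_snr_db / 20))
    y <- y / max(abs(y)) * 0.9
  }
  boundaries <- if (length(bounds)) do.call(rbind, bounds) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               hyperphonation = logical(0), fricative = logical(0))
  list(audio = audio_segment(y, sr, infant_id, recording_id),
       boundaries = boundaries)
}

#' Apply the pharmacological-treatment trigger rule to a FNAST series
#'
#' Treatment is indicated when the score is 8 or higher on two consecutive
#' assessments, or 12 or higher on any single assessment.
#'
#' @param scores integer vector of FNAST scores (0-46).
#' @return logical flag.
#' @export
fnast_treated <- function(scores) {
  if (any(scores < 0 | scores > 46)) stop_invalid("FNAST scores lie in 0-46")
  any(scores >= 12) ||
    (length(scores) >= 2 && any(scores[-1] >= 8 & scores[-length(scores)] >= 8))
}

#' Simulate a FNAST assessment series from a latent withdrawal severity
#'
#' Scores at 3-hour intervals follow a noisy AR(1) process around a mean
#' that increases with severity, clamped to the 0-46 instrument range. The
#' treatment flag applies the trigger rule exactly; this provides an
#' optional labelling path in which treatment derives from simulated
#' bedside scoring rather than group membership.
#'
#' @param withdrawal_severity finite latent scalar (0 = typical healthy
#'   neonate; ~2 = marked withdrawal).
#' @param seed integer seed.
#' @param n_assessments number of 3-hourly assessments (default 16 = 48 h).
#' @param infant_id identifier.
#' @return list with `infant_id`, `scores`, `hours` and `treated`.
#' @export
simulate_fnast_series <- function(withdrawal_severity, seed = NULL,
                                  n_assessments = 16, infant_id = "unknown") {
  if (!is.finite(withdrawal_severity))
    stop_invalid("'withdrawal_severity' must be finite")
  if (!is.null(seed)) set.seed(seed)
  mu <- 2.5 + 3.5 * withdrawal_severity
  e <- as.numeric(stats::filter(rnorm(n_assessments, sd = 2), 0.5,
                                method = "recursive"))
  scores <- as.integer(pmin(46, pmax(0, round(mu + e))))
  list(infant_id = infant_id, scores = scores,
       hours = 3 * (seq_len(n_assessments) - 1),
       treated = fnast_treated(scores))
}
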