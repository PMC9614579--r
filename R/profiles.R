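# Analyzer profiles. Two built-in profiles stand in for the two analysis
# systems whose outputs are stacked: a "cepstral" profile (cepstral pitch
# tracking, band energies, fricative scoring) and a "spectral" profile
# (autocorrelation-on-spectrum pitch variant, spectral entropy, novelty,
# amplitude envelope). They share the frame geometry (12.5 ms frames,
# half-frame hop, Hann taper) but differ in estimators and feature sets.

#' Built-in analyzer profiles
#'
#' @param name `"cepstral"` or `"spectral"`.
#' @param ... named overrides for any profile field (e.g. `frame_ms`,
#'   `f0_range`, `feature_set`).
#' @return an object of class `analyzer_profile` with fields `analyzer_id`,
#'   `frame_ms` (default 12.5), `hop_ms` (default half frame), `window`,
#'   `f0_range` (Hz), `f0_method`, `hyperphonation_threshold` (Hz, default
#'   1000), `voicing_threshold`, `lpc_order`, `formant_sr`, `preemphasis`,
#'   `band_split` (Hz), `novelty_kernel` (frames) and `feature_set`.
#' @export
analyzer_profile <- function(name = c("cepstral", "spectral"), ...) {
  name <- match.arg(name)
  p <- list(
    analyzer_id = name,
    frame_ms = 12.5,
    hop_ms = 6.25,
    window = "hann",
    f0_range = c(150, 2500),
    f0_method = if (name == "cepstral") "cepstral" else "autocorr",
    hyperphonation_threshold = 1000,
    # cepstral: peak >= k x median band level; autocorr: normalized r >= k
    voicing_threshold = if (name == "cepstral") 3 else 0.30,
    lpc_order = 12,
    formant_sr = 10000,
    preemphasis = 0.97,
    band_split = 2500,
    novelty_kernel = 16,
    feature_set = if (name == "cepstral")
      c("f0", "hyperphonation", "formants", "energy", "fricative",
        "amplitude")
    else
      c("f0", "hyperphonation", "formants", "energy", "amplitude",
        "spectral_entropy", "novelty"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop_invalid("unknown profile fields: %s", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (p$frame_ms <= 0 || p$hop_ms <= 0)
    stop_invalid("'frame_ms' and 'hop_ms' must be positive")
  if (p$f0_range[1] >= p$f0_range[2])
    stop_invalid("'f0_range' must be (min, max)")
  structure(p, class = "analyzer_profile")
}

#' Slice an audio segment into tapered analysis frames
#'
#' Frames of `round(frame_ms * sr / 1000)` samples at `hop_ms` spacing,
#' so frame count is `floor((N - frame_len) / hop_len) + 1`. Audio shorter
#' than one frame yields an empty frame matrix, not an error.
#'
#' @param audio an [audio_segment()].
#' @param profile an [analyzer_profile()].
#' @return a `frame_len x n_frames` matrix of windowed frames, with
#'   attributes `times` (frame centers, s), `raw` (unwindowed frames),
#'   `frame_len`, `hop_len` and `sample_rate`.
#' @export
frame_signal <- function(audio, profile) {
  stopifnot(inherits(audio, "audio_segment"),
            inherits(profile, "analyzer_profile"))
  sr <- audio$sample_rate
  frame_len <- max(2L, as.integer(round(profile$frame_ms * sr / 1000)))
  hop_len <- max(1L, as.integer(round(profile$hop_ms * sr / 1000)))
  n <- length(audio$samples)
  n_frames <- if (n < frame_len) 0L else (n - frame_len) %/% hop_len + 1L
  idx <- outer(seq_len(frame_len), (seq_len(n_frames) - 1L) * hop_len, `+`)
  raw <- matrix(audio$samples[idx], nrow = frame_len)
  w <- switch(profile$window,
              hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(frame_len) - 1) /
                                       (frame_len - 1)),
              hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(frame_len) - 1) /
                                            (frame_len - 1)),
              rect = rep(1, frame_len),
              stop_invalid("unknown window '%s'", profile$window))
  frames <- raw * w
  attr(frames, "raw") <- raw
  attr(frames, "times") <- ((seq_len(n_frames) - 1L) * hop_len +
                              frame_len / 2) / sr
  attr(frames, "frame_len") <- frame_len
  attr(frames, "hop_len") <- hop_len
  attr(frames, "sample_rate") <- sr
  frames
}
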