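# Frame-level estimators. The matrix variants (suffix _mat) operate on all
# frames at once via mvfft and are what analyze() uses; the exported
# single-frame functions wrap them for direct use and testing.

power_spectrum_mat <- function(frames) {
  n <- nrow(frames)
  nb <- n %/% 2
  S <- mvfft(frames)
  ps <- abs(S[seq_len(nb), , drop = FALSE])^2 / n^2
  attr(ps, "freqs") <- (seq_len(nb) - 1)
  ps
}

# --- pitch tracking -------------------------------------------------------
# Two-stage per-frame tracker shared by both profiles. Stage 1 (common):
# the frame is spectrally whitened by linear-prediction inverse filtering
# (removing the formant envelope that otherwise captures the period
# search at high fundamentals), the whitened signal's autocorrelation is
# searched in the lag band for f0_range, and the raw peak is corrected
# for subharmonic (rahmonic) errors by checking integer divisors of the
# peak lag. Stage 2 differs by profile: the cepstral profile refines the
# period on the real cepstrum of the whitened frame and gates voicing on
# cepstral peak prominence; the spectral profile refines on the
# autocorrelation itself and gates voicing on the normalized
# autocorrelation peak.

# quadratic (parabolic) peak interpolation on a curve indexed by lag + 1
refine_peak <- function(curve, L) {
  if (L < 2 || L + 2 > length(curve)) return(L)
  a <- curve[L]
  b <- curve[L + 1]
  cc <- curve[L + 2]
  den <- a - 2 * b + cc
  if (den >= 0) L else L + 0.5 * (a - cc) / den
}

# prefer a divisor of the peak lag whose own peak is comparable: corrects
# period-multiple (subharmonic) picks caused by grid quantization
divisor_correct <- function(curve, L, lag_lo, frac = 0.5) {
  pv <- curve[L + 1]
  for (k in 4:2) {
    Lk <- L / k
    if (Lk < lag_lo) next
    i <- unique(c(floor(Lk), ceiling(Lk)))
    i <- i[i >= lag_lo]
    if (!length(i)) next
    if (max(curve[i + 1]) >= frac * pv) return(i[which.max(curve[i + 1])])
  }
  L
}

lpc_whiten <- function(x, order = 14) {
  fit <- tryCatch(ar.yw(x, aic = FALSE, order.max = order, demean = TRUE),
                  error = function(e) NULL)
  if (is.null(fit)) return(x)
  r <- fit$resid
  r[is.na(r)] <- 0
  if (sd(r) == 0) x else r
}

fft_acf <- function(x) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  a <- Re(fft(abs(fft(c(x, numeric(nfft - n))))^2, inverse = TRUE))
  if (a[1] <= 0) return(rep(0, n))
  a[seq_len(n)] / a[1]
}

# periodicity statistic: tapered-signal ACF maximum in the lag band,
# rescaled for the triangular taper decay; ~0.15-0.2 on white noise
acf_periodicity <- function(x, lag_lo, lag_hi) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  a <- fft_acf((x - mean(x)) * w)
  lags <- lag_lo:lag_hi
  max(a[lags + 1] / (1 - lags / n))
}

ACF_GATE <- 0.30  # shared periodicity gate for voicing

pitch_frame <- function(x, sr, profile) {
  n <- length(x)
  lag_lo <- max(2L, as.integer(ceiling(sr / profile$f0_range[2])))
  lag_hi <- min(n - 2L, as.integer(floor(sr / profile$f0_range[1])))
  if (lag_hi <= lag_lo || sd(x) == 0)
    return(list(f0 = NA_real_, voiced = FALSE))
  res <- lpc_whiten(x)
  a <- fft_acf(res)
  band <- a[(lag_lo + 1L):(lag_hi + 1L)]
  L <- lag_lo + which.max(band) - 1L
  L <- divisor_correct(a, L, lag_lo)
  vstat <- acf_periodicity(x, lag_lo, lag_hi)
  if (profile$f0_method == "cepstral") {
    nfft <- 2048L
    if (nfft < 2 * n) nfft <- 2^ceiling(log2(2 * n))
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    lm <- log(abs(fft(c(res * w, numeric(nfft - n)))) + 1e-12)
    lm <- lm - mean(lm)
    ceps <- Re(fft(lm, inverse = TRUE)) / nfft
    win <- max(lag_lo, L - 2L):min(lag_hi, L + 2L)
    q <- win[which.max(ceps[win + 1L])]
    prom <- ceps[q + 1L] /
      median(abs(ceps[(lag_lo + 1L):(lag_hi + 1L)]))
    voiced <- is.finite(prom) && prom >= profile$voicing_threshold &&
      vstat >= ACF_GATE
    list(f0 = if (voiced) sr / refine_peak(ceps, q) else NA_real_,
         voiced = voiced)
  } else {
    voiced <- vstat >= profile$voicing_threshold
    list(f0 = if (voiced) sr / refine_peak(a, L) else NA_real_,
         voiced = voiced)
  }
}

pitch_track_mat <- function(raw_frames, sr, profile) {
  nf <- ncol(raw_frames)
  f0 <- rep(NA_real_, nf)
  voiced <- logical(nf)
  for (j in seq_len(nf)) {
    p <- pitch_frame(raw_frames[, j], sr, profile)
    f0[j] <- p$f0
    voiced[j] <- p$voiced
  }
  list(f0 = f0, voiced = voiced)
}

#' Cepstral fundamental-frequency estimate for one frame
#'
#' The frame is whitened by linear-prediction inverse filtering, an
#' autocorrelation period candidate is found in the lag band for
#' `profile$f0_range` (with subharmonic correction), and the period is
#' refined on the real cepstrum. The frame is voiced when the cepstral
#' peak is at least `voicing_threshold` times the median cepstrum level in
#' the band and the signal shows band periodicity; then
#' `f0 = sr / quefrency`.
#'
#' @param frame numeric vector of samples (one analysis frame).
#' @param profile an [analyzer_profile()].
#' @param sample_rate sampling rate in Hz.
#' @return list with `f0` (Hz, or `NA` when unvoiced) and `voiced`.
#' @export
estimate_f0_cepstral <- function(frame, profile, sample_rate) {
  if (profile$f0_method != "cepstral")
    profile$f0_method <- "cepstral"
  pitch_frame(frame, sample_rate, profile)
}

#' Autocorrelation fundamental-frequency estimate for one frame
#'
#' Variant pitch tracker used by the spectral profile: the period is
#' found and refined on the autocorrelation of the whitened frame; the
#' frame is voiced when the normalized tapered-signal autocorrelation
#' peak in the band reaches `voicing_threshold`.
#'
#' @inheritParams estimate_f0_cepstral
#' @return list with `f0` (Hz, or `NA`) and `voiced`.
#' @export
estimate_f0_autocorr <- function(frame, profile, sample_rate) {
  if (profile$f0_method != "autocorr")
    profile$f0_method <- "autocorr"
  pitch_frame(frame, sample_rate, profile)
}

# anti-aliasing low-pass filters cached per (sample_rate, formant_sr)
.aa_cache <- new.env(parent = emptyenv())

antialias_filter <- function(sr, fsr) {
  key <- paste(sr, fsr)
  if (is.null(.aa_cache[[key]]))
    .aa_cache[[key]] <- signal::butter(6, 0.9 * (fsr / 2) / (sr / 2))
  .aa_cache[[key]]
}

#' Linear-prediction formant estimates for one voiced frame
#'
#' The frame is pre-emphasized, low-pass filtered and resampled to
#' `profile$formant_sr`, and fit with a Yule-Walker autoregressive model of
#' order `profile$lpc_order`. Poles with bandwidth < 400 Hz and frequency
#' in (200, 5000) Hz are candidate resonances; with the short frames and
#' high fundamentals of newborn cries a single resonance is often modelled
#' by two nearby poles, so qualifying poles closer than 450 Hz are merged
#' by bandwidth-weighted averaging, and the two lowest merged candidates
#' are F1 and F2.
#'
#' @inheritParams estimate_f0_cepstral
#' @return list with `F1` and `F2` in Hz (`NA` when fewer than 1 or 2
#'   qualifying resonances).
#' @export
estimate_formants <- function(frame, profile, sample_rate) {
  out <- list(F1 = NA_real_, F2 = NA_real_)
  n <- length(frame)
  if (n < 8 || sd(frame) == 0) return(out)
  x <- frame - c(0, profile$preemphasis * frame[-n])
  fsr <- profile$formant_sr
  if (sample_rate > fsr) {
    x <- signal::filtfilt(antialias_filter(sample_rate, fsr), x)
    m <- max(profile$lpc_order + 4L, as.integer(round(n * fsr / sample_rate)))
    x <- approx(seq_len(n), x, xout = seq(1, n, length.out = m))$y
  } else fsr <- sample_rate
  m <- length(x)
  x <- x * (0.54 - 0.46 * cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
  fit <- tryCatch(ar.yw(x, aic = FALSE, order.max = profile$lpc_order,
                        demean = TRUE),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(out)
  poles <- 1 / polyroot(c(1, -fit$ar))
  poles <- poles[Im(poles) > 0]
  freq <- Arg(poles) / (2 * pi) * fsr
  bw <- -fsr / pi * log(pmin(Mod(poles), 1 - 1e-9))
  ok <- freq > 200 & freq < 5000 & bw < 400
  freq <- freq[ok]
  bw <- bw[ok]
  o <- order(freq)
  freq <- freq[o]
  bw <- bw[o]
  cand <- numeric(0)
  i <- 1L
  while (i <= length(freq)) {
    j <- i
    while (j < length(freq) && freq[j + 1] - freq[j] < 450) j <- j + 1L
    w <- 1 / pmax(bw[i:j], 20)
    cand <- c(cand, sum(freq[i:j] * w) / sum(w))
    i <- j + 1L
  }
  if (length(cand) >= 1) out$F1 <- cand[1]
  if (length(cand) >= 2) out$F2 <- cand[2]
  out
}

frame_energy_mat <- function(ps, sr, profile) {
  nb <- nrow(ps)
  freqs <- (seq_len(nb) - 1) * sr / (2 * nb)
  lo <- freqs < profile$band_split
  list(total = db_floor(colSums(ps)),
       low = db_floor(colSums(ps[lo, , drop = FALSE])),
       high = db_floor(colSums(ps[!lo, , drop = FALSE])))
}

#' Frame energies in decibels
#'
#' Total, low-band and high-band energy (10 log10 of summed spectral
#' power, split at `profile$band_split` Hz), floored at -120 dB.
#'
#' @inheritParams estimate_f0_cepstral
#' @return list with `energy_total`, `energy_low`, `energy_high` (dB).
#' @export
frame_energy <- function(frame, profile, sample_rate) {
  e <- frame_energy_mat(power_spectrum_mat(matrix(frame, ncol = 1)),
                        sample_rate, profile)
  list(energy_total = e$total[1], energy_low = e$low[1],
       energy_high = e$high[1])
}

spectral_entropy_mat <- function(ps) {
  tot <- colSums(ps)
  nb <- nrow(ps)
  p <- ps / rep(pmax(tot, 1e-300), each = nb)
  h <- -colSums(ifelse(p > 0, p * log(p), 0)) / log(nb)
  h[tot <= 0] <- NA_real_
  pmin(pmax(h, 0), 1)
}

#' Spectral entropy of one frame
#'
#' Shannon entropy of the normalized power spectrum divided by
#' `log(n_bins)`: near 1 for noise-like frames, near 0 for tonal frames;
#' `NA` for an all-zero frame.
#'
#' @param frame numeric vector of samples.
#' @return value in `[0, 1]`, or `NA`.
#' @export
spectral_entropy <- function(frame) {
  spectral_entropy_mat(power_spectrum_mat(matrix(frame, ncol = 1)))[1]
}

fricative_score_mat <- function(ps, raw_frames, sr, profile) {
  e <- frame_energy_mat(ps, sr, profile)
  ratio <- 10^(e$high / 10) / pmax(10^(e$total / 10), 1e-300)
  n <- nrow(raw_frames)
  s <- sign(raw_frames)
  zcr <- colSums(abs(diff(s)) > 0) / (n - 1)
  stats::plogis(8 * (ratio - 0.5) + 6 * (zcr - 0.3))
}

#' Fricative (turbulence) score of one frame
#'
#' Logistic combination of the high-band energy ratio and the zero-crossing
#' rate, monotone nondecreasing in both; near 1 for high-frequency noise,
#' near 0 for low-pitched voiced frames.
#'
#' @inheritParams estimate_f0_cepstral
#' @return value in `[0, 1]`.
#' @export
fricative_score <- function(frame, profile, sample_rate) {
  m <- matrix(frame, ncol = 1)
  fricative_score_mat(power_spectrum_mat(m), m, sample_rate, profile)[1]
}
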