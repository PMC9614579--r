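# Frame-level estimators: frame geometry, pitch trackers, formants, band
# energies, spectral entropy, fricative scoring.

test_that("frame slicing follows the documented arithmetic", {
  a <- audio_segment(rnorm(22050), 22050)
  f <- frame_signal(a, analyzer_profile("cepstral"))
  expect_equal(attr(f, "frame_len"), 276)  # round(12.5 * 22050 / 1000)
  expect_equal(attr(f, "hop_len"), 138)
  expect_equal(ncol(f), (22050 - 276) %/% 138 + 1)  # 158
  expect_equal(ncol(f), 158)

  one <- audio_segment(rnorm(276), 22050)
  expect_equal(ncol(frame_signal(one, analyzer_profile("cepstral"))), 1)
  short <- audio_segment(rnorm(100), 22050)
  expect_equal(ncol(frame_signal(short, analyzer_profile("cepstral"))), 0)

  # 12.5 ms frames regardless of rate
  a16 <- audio_segment(rnorm(16000), 16000)
  f16 <- frame_signal(a16, analyzer_profile("cepstral"))
  expect_equal(attr(f16, "frame_len") / 16000, 0.0125)
})

test_that("pitch trackers recover a pulse train and reject noise", {
  sr <- 22050
  prof_c <- analyzer_profile("cepstral")
  prof_s <- analyzer_profile("spectral")
  u <- synthesize_utterance(flat_params(400), 400, seed = 1,
                            hyperphonation = FALSE, fricative = FALSE)
  fr <- attr(frame_signal(u, prof_c), "raw")
  mid <- fr[, ncol(fr) %/% 2]
  rc <- estimate_f0_cepstral(mid, prof_c, sr)
  ra <- estimate_f0_autocorr(mid, prof_s, sr)
  # within one quefrency bin of 400 Hz: sr/54..sr/56
  expect_true(rc$voiced)
  expect_gte(rc$f0, sr / 56)
  expect_lte(rc$f0, sr / 54)
  expect_true(ra$voiced)
  expect_gte(ra$f0, sr / 56)
  expect_lte(ra$f0, sr / 54)

  set.seed(9)
  noise <- rnorm(276)
  expect_false(estimate_f0_cepstral(noise, prof_c, sr)$voiced)
  expect_false(estimate_f0_autocorr(noise, prof_s, sr)$voiced)
  expect_true(is.na(estimate_f0_cepstral(noise, prof_c, sr)$f0))
})

test_that("a 1200 Hz train trips the hyperphonation flag in analyze()", {
  u <- synthesize_utterance(flat_params(1200), 500, seed = 3,
                            hyperphonation = FALSE, fricative = FALSE)
  fs <- analyze(u, analyzer_profile("cepstral"))
  # octave slips on a 1200 Hz train leave a minority of frames unflagged
  expect_gt(mean(fs$hyperphonation[fs$voiced]), 0.6)
  expect_lt(abs(median(fs$f0, na.rm = TRUE) - 1200) / 1200, 0.05)
})

test_that("formant estimates land on the synthetic resonances", {
  prof <- analyzer_profile("cepstral")
  u <- synthesize_utterance(
    flat_params(400, formants = list(c(1100, 150), c(3300, 300))),
    1300, seed = 4, hyperphonation = FALSE, fricative = FALSE)
  fs <- analyze(u, prof)
  expect_gte(sum(!is.na(fs$F1)), 100)
  expect_lt(abs(median(fs$F1, na.rm = TRUE) - 1100), 100)
  expect_lt(abs(median(fs$F2, na.rm = TRUE) - 3300), 150)
  both <- !is.na(fs$F1) & !is.na(fs$F2)
  expect_true(all(fs$F1[both] < fs$F2[both]))

  # unvoiced frame yields missing formants
  expect_true(is.na(estimate_formants(numeric(276), prof, 22050)$F1))
})

test_that("band energies behave like decibel power sums", {
  prof <- analyzer_profile("cepstral")
  z <- frame_energy(numeric(276), prof, 22050)
  expect_equal(z$energy_total, -120)
  expect_equal(z$energy_high, -120)

  s <- sin(2 * pi * 500 * (0:275) / 22050)
  e <- frame_energy(s, prof, 22050)
  expect_lt(abs(e$energy_low - e$energy_total), 0.1)
  expect_lt(e$energy_high, e$energy_total - 20)

  e2 <- frame_energy(2 * s, prof, 22050)
  expect_equal(e2$energy_total - e$energy_total, 20 * log10(2),
               tolerance = 1e-6)
  expect_equal(e2$energy_low - e$energy_low, 20 * log10(2),
               tolerance = 1e-6)
})

test_that("spectral entropy separates noise from tone and stays in [0,1]", {
  set.seed(42)
  vals <- replicate(300, spectral_entropy(rnorm(276)))
  # expected normalized entropy of an exponential periodogram at 138 bins:
  # 1 - (1 - gamma)/log(138) ~ 0.914
  expect_gt(mean(vals), 0.89)
  expect_lt(mean(vals), 0.94)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_lt(spectral_entropy(sin(2 * pi * 500 * (0:275) / 22050)), 0.3)
  expect_true(is.na(spectral_entropy(numeric(276))))
})

test_that("fricative score is high for high-band noise, low for tone", {
  prof <- analyzer_profile("cepstral")
  set.seed(2)
  bp <- signal::butter(4, c(3000, 9000) / 11025, type = "pass")
  hf <- signal::filtfilt(bp, rnorm(2000))[500:775]
  expect_gte(fricative_score(hf, prof, 22050), 0.8)
  lp <- sin(2 * pi * 300 * (0:275) / 22050)
  expect_lte(fricative_score(lp, prof, 22050), 0.2)

  # monotone in the high-band mixing proportion at fixed frames
  set.seed(3)
  lo_part <- sin(2 * pi * 300 * (0:275) / 22050)
  hi_part <- signal::filtfilt(bp, rnorm(2000))[500:775]
  hi_part <- hi_part / sd(hi_part) * sd(lo_part)
  scores <- vapply(seq(0, 1, by = 0.25), function(w)
    fricative_score((1 - w) * lo_part + w * hi_part, prof, 22050),
    numeric(1))
  expect_true(all(diff(scores) >= -1e-8))
})
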