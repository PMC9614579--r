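# Segmentation, stratification and the two-level summarization.

test_that("stratum classification splits exactly at 500 ms", {
  expect_equal(classify_stratum(499), "short")
  expect_equal(classify_stratum(500), "long")
  expect_equal(classify_stratum(501), "long")
  expect_error(classify_stratum(0), "positive")
  expect_error(classify_stratum(-10), "positive")
})

test_that("segmentation merges close bursts and drops silence", {
  # 200 ms burst, 30 ms gap, 200 ms burst on a -60 dB floor (6.25 ms hop)
  burst <- function(ms) rep(-10, round(ms / 6.25))
  quiet <- function(ms) rep(-60, round(ms / 6.25))
  e <- c(quiet(200), burst(200), quiet(30), burst(200), quiet(200))
  fs <- make_frame_series(e, voiced = e > -30)
  utts <- segment_utterances(fs, seg_config(merge_gap_ms = 50))
  expect_equal(nrow(utts), 1)
  expect_gt(utts$duration_ms, 400)

  # gap wider than merge_gap stays split
  e2 <- c(quiet(200), burst(200), quiet(80), burst(200), quiet(200))
  fs2 <- make_frame_series(e2, voiced = e2 > -30)
  expect_equal(nrow(segment_utterances(fs2, seg_config(merge_gap_ms = 50))),
               2)

  silence <- make_frame_series(rep(-60, 200), voiced = rep(FALSE, 200))
  expect_equal(nrow(segment_utterances(silence)), 0)

  # unvoiced bursts are not utterances
  e3 <- c(quiet(200), burst(300), quiet(200))
  fs3 <- make_frame_series(e3, voiced = rep(FALSE, length(e3)))
  expect_equal(nrow(segment_utterances(fs3)), 0)
})

test_that("segmentation recovers synthetic ground truth", {
  hits <- total <- 0
  segged <- list()
  for (s in 1:3) {
    rec <- synthesize_recording(cry_synth_params(), 5, seed = 40 + s)
    fs <- analyze(rec$audio, analyzer_profile("cepstral"))
    utts <- segment_utterances(fs)
    segged[[s]] <- utts
    for (i in seq_len(nrow(rec$boundaries))) {
      total <- total + 1
      iou <- vapply(seq_len(nrow(utts)), function(j) {
        inter <- max(0, min(rec$boundaries$end_s[i], utts$end_s[j]) -
                       max(rec$boundaries$start_s[i], utts$start_s[j]))
        inter / (max(rec$boundaries$end_s[i], utts$end_s[j]) -
                   min(rec$boundaries$start_s[i], utts$start_s[j]))
      }, numeric(1))
      if (any(iou > 0.5)) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
  # partition: no frame belongs to two utterances
  for (utts in segged)
    if (nrow(utts) > 1)
      expect_true(all(utts$start_frame[-1] > utts$end_frame[-nrow(utts)]))
})

test_that("utterance summaries average observed frames and track missing", {
  e <- rep(-10, 3)
  fs <- make_frame_series(e, voiced = c(TRUE, FALSE, TRUE),
                          extra = list(f0 = c(400, NA, 420),
                                       F1 = c(NA, NA, NA),
                                       amplitude = c(0.5, 0.5, 0.5)))
  utt <- data.frame(start_s = 0, end_s = 0.02, duration_ms = 20,
                    stratum = "short", start_frame = 1, end_frame = 3)
  row <- summarize_utterance(fs, utt)
  expect_equal(row$f0_mean, 410)
  expect_equal(row$f0_missing_rate, 1 / 3)
  expect_true(is.na(row$f1_mean))
  expect_equal(row$f1_missing_rate, 1)
  expect_equal(row$amplitude_mean, 0.5)
  expect_equal(row$amplitude_missing_rate, 0)

  bad <- utt
  bad$end_frame <- 10
  expect_error(summarize_utterance(fs, bad), "range")
})

test_that("infant aggregation is the unweighted mean over utterances", {
  rows <- data.frame(duration_ms = c(300, 600, 900),
                     stratum = c("short", "long", "long"),
                     f0_mean = c(400, 500, 600),
                     f0_missing_rate = c(0, 0.5, 1))
  agg <- aggregate_infant(rows, "i1", "long", "cepstral")
  expect_equal(agg$utterance_count, 3)
  expect_equal(agg$f0_mean, 500)
  expect_equal(agg$f0_missing_rate, 0.5)

  empty <- aggregate_infant(NULL, "i2", "short", "cepstral",
                            feature_names = names(rows))
  expect_equal(empty$utterance_count, 0)
  expect_true(is.na(empty$f0_mean))
})

test_that("aggregation is linear in the frame features", {
  e <- rep(-10, 40)
  base_f0 <- runif(40, 380, 420)
  fs1 <- make_frame_series(e, voiced = rep(TRUE, 40),
                           extra = list(f0 = base_f0))
  fs2 <- make_frame_series(e, voiced = rep(TRUE, 40),
                           extra = list(f0 = 3 * base_f0))
  utt <- data.frame(start_s = 0, end_s = 0.25, duration_ms = 250,
                    stratum = "short", start_frame = 1, end_frame = 40)
  r1 <- summarize_utterance(fs1, utt)
  r2 <- summarize_utterance(fs2, utt)
  expect_equal(r2$f0_mean, 3 * r1$f0_mean)
  expect_equal(r2$f0_missing_rate, r1$f0_missing_rate)
})

test_that("feature tables preserve utterance counts and strata", {
  coh <- generate_cohort(cohort_spec(n_nows = 2, n_exposed_no_nows = 1,
                                     n_unexposed = 2, seed = 19,
                                     mode = "audio"))
  tabs <- build_feature_tables(coh)
  expect_setequal(names(tabs),
                  c("cepstral.short", "cepstral.long",
                    "spectral.short", "spectral.long"))
  for (tab in tabs) {
    expect_equal(nrow(tab), 5)
    expect_true(all(c("infant_id", "label", "subgroup",
                      "utterance_count") %in% names(tab)))
  }
  # count conservation: per analyzer, strata counts sum to all segmented
  for (analyzer in c("cepstral", "spectral")) {
    total_by_table <- sum(tabs[[paste0(analyzer, ".short")]]$utterance_count) +
      sum(tabs[[paste0(analyzer, ".long")]]$utterance_count)
    recount <- sum(vapply(coh$manifest$infant_id, function(id) {
      fs <- analyze(coh$recordings[[id]]$audio, analyzer_profile(analyzer))
      nrow(segment_utterances(fs))
    }, numeric(1)))
    expect_equal(total_by_table, recount)
  }
})

test_that("an infant producing only long utterances has a zero short count", {
  long_only <- cry_synth_params(utterance_dur_range_ms = c(700, 900),
                                fricative_prob = 0)
  rec <- synthesize_recording(long_only, 3, seed = 23, infant_id = "solo")
  coh <- structure(list(mode = "audio",
                        manifest = data.frame(infant_id = "solo",
                                              subgroup = "nows", label = 1L),
                        recordings = list(solo = rec)),
                   class = "cry_cohort")
  tabs <- build_feature_tables(coh)
  expect_equal(tabs[["cepstral.short"]]$utterance_count, 0)
  expect_gt(tabs[["cepstral.long"]]$utterance_count, 0)
  expect_true(is.na(tabs[["cepstral.short"]]$f0_mean))
})
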