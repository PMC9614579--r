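# Utterance segmentation and two-level summarization (frames -> utterance
# -> infant). An utterance is a maximal run of frames above the noise floor
# with a sufficient voiced fraction -- an energy/voicing approximation to
# "cry during one expiratory phase" (inspiratory sounds are mostly unvoiced
# and short). Utterances are stratified at 500 ms into short and long.

#' Segmentation configuration
#'
#' @param threshold_db activity threshold above the noise floor (the
#'   `noise_quantile` quantile of frame energy), dB.
#' @param min_dur_ms minimum utterance duration, ms.
#' @param merge_gap_ms runs closer than this are merged, ms.
#' @param min_voiced_fraction minimum fraction of voiced frames in a run.
#' @param noise_quantile quantile of frame energy taken as the noise floor.
#' @return a list of class `seg_config`.
#' @export
seg_config <- function(threshold_db = 15, min_dur_ms = 50, merge_gap_ms = 50,
                       min_voiced_fraction = 0.3, noise_quantile = 0.10) {
  check_positive(threshold_db, "threshold_db")
  check_positive(min_dur_ms, "min_dur_ms")
  check_prob(min_voiced_fraction, "min_voiced_fraction")
  structure(list(threshold_db = threshold_db, min_dur_ms = min_dur_ms,
                 merge_gap_ms = merge_gap_ms,
                 min_voiced_fraction = min_voiced_fraction,
                 noise_quantile = noise_quantile), class = "seg_config")
}

#' Classify an utterance duration into the short/long stratum
#'
#' @param duration_ms utterance duration in milliseconds (> 0).
#' @return `"short"` when `duration_ms < 500`, `"long"` when `>= 500`.
#' @export
classify_stratum <- function(duration_ms) {
  if (any(!is.finite(duration_ms) | duration_ms <= 0))
    stop_invalid("'duration_ms' must be positive")
  ifelse(duration_ms < 500, "short", "long")
}

#' Segment cry utterances from a frame series
#'
#' Maximal runs of frames whose total energy exceeds the noise floor by
#' `threshold_db`; runs separated by less than `merge_gap_ms` are merged,
#' then runs shorter than `min_dur_ms` or with fewer than
#' `min_voiced_fraction` voiced frames are dropped. Silence yields an
#' empty result.
#'
#' @param series a [analyze()] frame series.
#' @param cfg a [seg_config()].
#' @return data.frame of non-overlapping, time-ordered utterances:
#'   `start_s`, `end_s`, `duration_ms`, `stratum`, `start_frame`,
#'   `end_frame`.
#' @export
segment_utterances <- function(series, cfg = seg_config()) {
  stopifnot(inherits(series, "frame_series"))
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_ms = numeric(0), stratum = character(0),
                      start_frame = integer(0), end_frame = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(series) == 0) return(empty)
  hop_s <- attr(series, "hop_s")
  half_frame_s <- attr(series, "frame_len_s") / 2
  e <- series$energy_total
  floor_db <- quantile(e[is.finite(e)], cfg$noise_quantile, names = FALSE)
  active <- is.finite(e) & e > floor_db + cfg$threshold_db
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0) return(empty)
  # merge runs separated by short gaps
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    gap_ms <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * hop_s * 1000
    if (gap_ms < cfg$merge_gap_ms)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  start_s <- series$frame_time[merged$start] - half_frame_s
  end_s <- series$frame_time[merged$end] + half_frame_s
  duration_ms <- (end_s - start_s) * 1000
  voiced_frac <- mapply(function(a, b) mean(series$voiced[a:b]),
                        merged$start, merged$end)
  keep <- duration_ms >= cfg$min_dur_ms &
    voiced_frac >= cfg$min_voiced_fraction
  if (!any(keep)) return(empty)
  data.frame(start_s = start_s[keep], end_s = end_s[keep],
             duration_ms = duration_ms[keep],
             stratum = classify_stratum(duration_ms[keep]),
             start_frame = merged$start[keep], end_frame = merged$end[keep],
             stringsAsFactors = FALSE)
}

# frame columns summarized to utterance level, with their table base names
utterance_feature_columns <- function(series) {
  map <- c(f0 = "f0", F1 = "f1", F2 = "f2", energy_total = "energy_total",
           energy_low = "energy_low", energy_high = "energy_high",
           amplitude = "amplitude", spectral_entropy = "entropy",
           fricative = "fricative", novelty = "novelty")
  map[names(map) %in% names(series)]
}

#' Summarize one utterance's frames into a feature row
#'
#' Per feature: the mean over non-missing frames and the missing-data rate
#' (missing frames / total frames). Adds the hyperphonation rate, the
#' voiced fraction, and the utterance's amplitude-envelope modulation
#' frequency where the amplitude track is available.
#'
#' @param series a [analyze()] frame series.
#' @param utt one row of [segment_utterances()] output.
#' @return one-row data.frame of utterance features.
#' @export
summarize_utterance <- function(series, utt) {
  stopifnot(inherits(series, "frame_series"))
  idx <- utt$start_frame:utt$end_frame
  if (length(idx) == 0 || utt$start_frame < 1 || utt$end_frame > nrow(series))
    stop_invalid("utterance frame range outside the series")
  row <- data.frame(duration_ms = utt$duration_ms,
                    stratum = unname(classify_stratum(utt$duration_ms)),
                    stringsAsFactors = FALSE)
  cols <- utterance_feature_columns(series)
  for (k in seq_along(cols)) {
    v <- series[[names(cols)[k]]][idx]
    miss <- mean(is.na(v))
    row[[paste0(cols[k], "_mean")]] <-
      if (miss == 1) NA_real_ else mean(v, na.rm = TRUE)
    row[[paste0(cols[k], "_missing_rate")]] <- miss
  }
  if ("hyperphonation" %in% names(series))
    row$hyperphonation_rate <- mean(series$hyperphonation[idx], na.rm = TRUE)
  row$voiced_rate <- mean(series$voiced[idx])
  if ("amplitude" %in% names(series)) {
    env <- amplitude_envelope(series$amplitude[idx], 1 / attr(series, "hop_s"))
    row$envelope_freq <- env$envelope_frequency
  }
  row
}

#' Aggregate utterance rows into one infant-level row
#'
#' Unweighted mean over utterances of each utterance mean, mean of the
#' utterance missing rates, and the utterance count. An empty input yields
#' a row with `utterance_count = 0` and all features missing.
#'
#' @param rows data.frame of [summarize_utterance()] rows (same infant,
#'   stratum and analyzer).
#' @param infant_id,stratum,analyzer_id identifiers for the output row.
#' @param feature_names optional character vector fixing the feature
#'   columns (needed for empty inputs).
#' @return one-row data.frame.
#' @export
aggregate_infant <- function(rows, infant_id, stratum, analyzer_id,
                             feature_names = NULL) {
  if (is.null(feature_names) && (is.null(rows) || nrow(rows) == 0))
    stop_invalid("'feature_names' is required when 'rows' is empty")
  if (is.null(feature_names))
    feature_names <- setdiff(names(rows), c("stratum"))
  out <- data.frame(infant_id = infant_id, stratum = stratum,
                    analyzer_id = analyzer_id,
                    utterance_count = if (is.null(rows)) 0L else nrow(rows),
                    stringsAsFactors = FALSE)
  for (f in setdiff(feature_names, c("stratum", "duration_ms"))) {
    v <- if (is.null(rows) || nrow(rows) == 0) NA_real_ else rows[[f]]
    m <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    out[[f]] <- m
  }
  out
}

#' Build the four infant-level feature tables from a cohort
#'
#' For an audio-mode cohort, runs both analyzer profiles over every
#' recording, segments utterances, summarizes them and aggregates per
#' infant and stratum, yielding four tables keyed `analyzer.stratum` and
#' aligned on `infant_id`, with labels and subgroups attached from the
#' manifest. A feature-table-mode cohort returns its tables directly.
#'
#' @param cohort a [generate_cohort()] result (or a list with `recordings`
#'   and `manifest` of the same shape).
#' @param profiles list of [analyzer_profile()] objects (default both
#'   built-ins).
#' @param cfg a [seg_config()].
#' @return named list of four data.frames keyed
#'   `{cepstral,spectral}.{short,long}`.
#' @export
build_feature_tables <- function(cohort,
                                 profiles = list(analyzer_profile("cepstral"),
                                                 analyzer_profile("spectral")),
                                 cfg = seg_config()) {
  if (identical(cohort$mode, "feature_table")) return(cohort$tables)
  manifest <- cohort$manifest
  missing_ids <- setdiff(names(cohort$recordings), manifest$infant_id)
  if (length(missing_ids))
    stop_invalid("infants missing from manifest: %s",
                 paste(missing_ids, collapse = ", "))
  tables <- list()
  for (profile in profiles) {
    per_infant <- list()
    for (id in manifest$infant_id) {
      rec <- cohort$recordings[[id]]
      if (is.null(rec)) stop_invalid("no recording for infant '%s'", id)
      series <- analyze(rec$audio, profile)
      utts <- segment_utterances(series, cfg)
      rows <- if (nrow(utts)) do.call(rbind, lapply(
        seq_len(nrow(utts)),
        function(i) summarize_utterance(series, utts[i, ]))) else NULL
      per_infant[[id]] <- rows
    }
    feat_names <- NULL
    for (rows in per_infant)
      if (!is.null(rows)) { feat_names <- names(rows); break }
    if (is.null(feat_names))
      stop_invalid("no utterances segmented for any infant (profile '%s')",
                   profile$analyzer_id)
    for (stratum in c("short", "long")) {
      tab <- do.call(rbind, lapply(manifest$infant_id, function(id) {
        rows <- per_infant[[id]]
        sel <- if (is.null(rows)) NULL else rows[rows$stratum == stratum, ]
        if (!is.null(sel) && nrow(sel) == 0) sel <- NULL
        aggregate_infant(sel, id, stratum, profile$analyzer_id, feat_names)
      }))
      tab <- merge(manifest, tab, by = "infant_id", sort = FALSE)
      tab$stratum <- NULL
      tab$analyzer_id <- NULL
      attr(tab, "analyzer") <- profile$analyzer_id
      attr(tab, "stratum") <- stratum
      tables[[paste(profile$analyzer_id, stratum, sep = ".")]] <- tab
    }
  }
  tables
}
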