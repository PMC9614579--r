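# Synthetic cohort generation. The cohort mirrors the study structure the
# downstream analysis assumes: 19 neonates treated for NOWS, 7 opioid-exposed
# neonates who did not develop NOWS, and 39 unexposed neonates (65 total),
# with group-level effects applied to the acoustic feature families found
# discriminative (hyperphonation, f0, F1/F2, energy, fricatives, utterance
# counts, entropy, novelty).

#' Default standardized group effects per feature family
#'
#' Standardized (Cohen d) shifts applied to the treated-for-NOWS group.
#' No clinical dataset pins these; they are generator settings chosen once
#' to produce a separable but imperfect cohort, concentrated on the feature
#' families reported as most discriminative.
#' @return named numeric vector of standardized shifts.
#' @export
default_effect_map <- function() {
  c(hyperphonation = 1.2, f0 = 0.8, f1 = 1.0, f2 = 0.6, energy = 0.8,
    n_utterances = 1.0, fricative = 0.6, entropy = 0.5, novelty = 0.5,
    envelope = 0.3)
}

#' Cohort specification
#'
#' @param n_nows,n_exposed_no_nows,n_unexposed subgroup sizes; defaults
#'   `(19, 7, 39)` mirror the study cohort of 65 neonates.
#' @param effect_map named vector of standardized group shifts per feature
#'   family (see [default_effect_map()]); the treated group mean is shifted
#'   by `d` pooled standard deviations.
#' @param seed integer seed; fully determines the generated cohort.
#' @param mode `"feature_table"` generates infant-level feature tables
#'   directly; `"audio"` synthesizes cry recordings per infant.
#' @param n_noise_features number of uninformative feature columns added to
#'   every table in `feature_table` mode.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_nows = 19, n_exposed_no_nows = 7, n_unexposed = 39,
                        effect_map = default_effect_map(), seed = 1,
                        mode = c("feature_table", "audio"),
                        n_noise_features = 4) {
  mode <- match.arg(mode)
  counts <- c(n_nows, n_exposed_no_nows, n_unexposed)
  if (any(counts < 0)) stop_invalid("subgroup counts must be >= 0")
  if (sum(counts) == 0) stop_invalid("at least one subgroup must be non-empty")
  if (is.null(names(effect_map)) && length(effect_map) > 0)
    stop_invalid("'effect_map' must be a named vector (family -> shift)")
  structure(list(n_nows = n_nows, n_exposed_no_nows = n_exposed_no_nows,
                 n_unexposed = n_unexposed, effect_map = effect_map,
                 seed = as.integer(seed), mode = mode,
                 n_noise_features = n_noise_features),
            class = "cohort_spec")
}

cohort_manifest <- function(spec) {
  subgroup <- rep(c("nows", "exposed_no_nows", "unexposed"),
                  c(spec$n_nows, spec$n_exposed_no_nows, spec$n_unexposed))
  data.frame(infant_id = sprintf("inf%03d", seq_along(subgroup)),
             subgroup = subgroup,
             label = as.integer(subgroup == "nows"),
             stringsAsFactors = FALSE)
}

# family -> representative column, baseline mean and sd, per analyzer
feature_family_layout <- function(analyzer) {
  base <- data.frame(
    family = c("f0", "hyperphonation", "f1", "f2", "energy", "energy2",
               "energy3", "fricative", "amplitude", "entropy", "novelty",
               "envelope", "n_utterances"),
    column = c("f0_mean", "hyperphonation_rate", "f1_mean", "f2_mean",
               "energy_total_mean", "energy_low_mean", "energy_high_mean",
               "fricative_mean", "amplitude_mean", "entropy_mean",
               "novelty_mean", "envelope_freq_mean", "utterance_count"),
    mean = c(450, 0.12, 1100, 3300, -25, -28, -33, 0.20, 0.30, 0.50, 1.2,
             4.0, 12),
    sd = c(50, 0.06, 120, 250, 4, 4, 5, 0.08, 0.08, 0.10, 0.3, 1.2, 4),
    stringsAsFactors = FALSE)
  keep <- if (analyzer == "cepstral")
    c("f0", "hyperphonation", "f1", "f2", "energy", "energy2", "energy3",
      "fricative", "amplitude", "n_utterances")
  else
    c("f0", "hyperphonation", "f1", "f2", "energy", "amplitude", "entropy",
      "novelty", "envelope", "n_utterances")
  base[base$family %in% keep, ]
}

generate_feature_table <- function(spec, manifest, analyzer, stratum, seed) {
  set.seed(seed)
  layout <- feature_family_layout(analyzer)
  n <- nrow(manifest)
  shift <- manifest$label  # treated group only
  tab <- manifest
  informative <- numeric(0)
  for (i in seq_len(nrow(layout))) {
    fam <- layout$family[i]
    d <- if (fam %in% names(spec$effect_map)) spec$effect_map[[fam]] else 0
    mu <- layout$mean[i] + shift * d * layout$sd[i]
    v <- rnorm(n, mu, layout$sd[i])
    if (layout$column[i] %in% c("hyperphonation_rate", "fricative_mean",
                                "amplitude_mean", "entropy_mean"))
      v <- pmin(pmax(v, 0), 1)
    if (layout$column[i] == "utterance_count")
      v <- pmax(0L, as.integer(round(v)))
    tab[[layout$column[i]]] <- v
    if (d != 0) informative[layout$column[i]] <- d
  }
  for (j in seq_len(spec$n_noise_features))
    tab[[sprintf("noise_%02d", j)]] <- rnorm(n)
  attr(tab, "analyzer") <- analyzer
  attr(tab, "stratum") <- stratum
  attr(tab, "informative") <- informative
  tab
}

# per-infant synthesis parameters with group effects on the param scale
infant_synth_params <- function(spec, label) {
  em <- function(fam) if (label == 1 && fam %in% names(spec$effect_map))
    spec$effect_map[[fam]] else 0
  f0 <- rnorm(1, 450 + em("f0") * 40, 40)
  hp <- min(0.9, max(0, rnorm(1, 0.08 + em("hyperphonation") * 0.06, 0.04)))
  f1 <- rnorm(1, 1100 + em("f1") * 100, 80)
  f2 <- max(f1 + 500, rnorm(1, 3300 + em("f2") * 200, 150))
  fr <- min(0.9, max(0, rnorm(1, 0.12 + em("fricative") * 0.07, 0.05)))
  n_mid <- max(1, 5.5 + em("n_utterances") * 2)
  cry_synth_params(
    f0_base = max(250, f0), hyperphonation_prob = hp,
    formants = list(c(max(500, f1), 150), c(f2, 300)),
    fricative_prob = fr,
    n_utterances_range = c(max(1, round(n_mid - 2)), round(n_mid + 2)))
}

#' Generate a synthetic cohort
#'
#' In `feature_table` mode, four infant-level feature tables (two analyzers
#' x two utterance strata) are drawn directly, with the treated group's
#' mean shifted by `effect_map` standard deviations on the designated
#' informative columns. In `audio` mode, each infant receives synthesis
#' parameters shifted per `effect_map` and a multi-utterance cry recording
#' with ground-truth boundaries.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `cry_cohort`: a list with `mode`, `spec`,
#'   `manifest` and, depending on mode, `tables` (named
#'   `analyzer.stratum` list) or `recordings` (per-infant list with
#'   `audio`, `boundaries`, `params`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  manifest <- cohort_manifest(spec)
  out <- list(mode = spec$mode, spec = spec, manifest = manifest)
  if (spec$mode == "feature_table") {
    tables <- list()
    for (analyzer in c("cepstral", "spectral"))
      for (stratum in c("short", "long"))
        tables[[paste(analyzer, stratum, sep = ".")]] <-
          generate_feature_table(
            spec, manifest, analyzer, stratum,
            derive_seed(spec$seed, paste("table", analyzer, stratum)))
    out$tables <- tables
  } else {
    recs <- vector("list", nrow(manifest))
    names(recs) <- manifest$infant_id
    for (i in seq_len(nrow(manifest))) {
      set.seed(derive_seed(spec$seed, paste0("params.", manifest$infant_id[i])))
      params <- infant_synth_params(spec, manifest$label[i])
      rec <- synthesize_recording(
        params, seed = derive_seed(spec$seed,
                                   paste0("audio.", manifest$infant_id[i])),
        infant_id = manifest$infant_id[i])
      recs[[i]] <- list(audio = rec$audio, boundaries = rec$boundaries,
                        params = params)
    }
    out$recordings <- recs
  }
  structure(out, class = "cry_cohort")
}

#' @export
print.cry_cohort <- function(x, ...) {
  cat(sprintf("<cry_cohort> %d infants (%d NOWS / %d exposed / %d unexposed), mode=%s\n",
              nrow(x$manifest), x$spec$n_nows, x$spec$n_exposed_no_nows,
              x$spec$n_unexposed, x$mode))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Audio mode writes one 16-bit PCM WAV per infant plus a manifest CSV
#' (`infant_id`, `subgroup`, `label`, `wav`) and a ground-truth boundaries
#' CSV; feature-table mode writes the four infant-level tables and the
#' manifest.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cry_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  if (cohort$mode == "audio") {
    manifest$wav <- file.path(dir, paste0(manifest$infant_id, ".wav"))
    bounds <- list()
    for (i in seq_len(nrow(manifest))) {
      rec <- cohort$recordings[[manifest$infant_id[i]]]
      write_wav(rec$audio$samples, rec$audio$sample_rate, manifest$wav[i])
      if (nrow(rec$boundaries))
        bounds[[i]] <- cbind(infant_id = manifest$infant_id[i],
                             rec$boundaries)
    }
    write.csv(do.call(rbind, bounds), file.path(dir, "boundaries.csv"),
              row.names = FALSE)
  } else {
    for (key in names(cohort$tables))
      write.csv(cohort$tables[[key]],
                file.path(dir, paste0("table_", key, ".csv")),
                row.names = FALSE, na = "")
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
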