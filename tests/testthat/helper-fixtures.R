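# Shared fixtures: flat-pitch synthesis parameters, an autocorrelation f0
# oracle independent of the package's trackers, a hand-built frame series
# constructor, and reduced-size model configurations for simulation tests.

flat_params <- function(f0, ...) {
  cry_synth_params(f0_base = f0, f0_contour = list(c(0, 1), c(1, 1)),
                   noise_snr_db = Inf, hyperphonation_prob = 0,
                   fricative_prob = 0, ...)
}

# fully periodic variant (no aspiration noise) for waveform-ACF oracles:
# the oracle peak sits at the true period only when the signal repeats
# exactly, so oracle fixtures use a noiseless source and an on-grid period
flat_periodic <- function(f0, ...) flat_params(f0, aspiration = 0, ...)

# independent f0 oracle: global autocorrelation peak of the waveform
oracle_f0_acf <- function(samples, sr, f0_range = c(150, 2500)) {
  x <- samples - mean(samples)
  lag_max <- floor(sr / f0_range[1])
  r <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  lo <- ceiling(sr / f0_range[2])
  lag <- lo + which.max(r[(lo + 1):(lag_max + 1)]) - 1
  sr / lag
}

# frame series built by hand (no audio), for segmentation/summary units
make_frame_series <- function(energy, voiced, hop_s = 0.00625,
                              frame_len_s = 0.0125, extra = list()) {
  n <- length(energy)
  df <- data.frame(frame_time = frame_len_s / 2 + (seq_len(n) - 1) * hop_s,
                   voiced = voiced, energy_total = energy)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  structure(df, analyzer_id = "cepstral", sample_rate = 22050,
            hop_s = hop_s, frame_len_s = frame_len_s,
            profile = analyzer_profile("cepstral"),
            class = c("frame_series", "data.frame"))
}

# reduced-size configurations for simulation work (defaults stay faithful)
fast_config <- function(master_seed, n_trees = 500, n_runs = 2,
                        retain_threshold = 0, selection_trees = 50,
                        selection_max_iter = 14) {
  model_config(n_trees = n_trees, n_runs = n_runs,
               retain_threshold = retain_threshold,
               selection_trees = selection_trees,
               selection_max_iter = selection_max_iter,
               master_seed = master_seed)
}

strong_effect_map <- function(d = 1.5) {
  c(hyperphonation = d, f1 = d, energy = d, n_utterances = d, fricative = d)
}

null_effect_map <- function() setNames(numeric(0), character(0))

stacked_auc <- function(fit) {
  ok <- !is.na(fit$predictions$p_stacked)
  roc_curve(fit$predictions$p_stacked[ok], fit$predictions$label[ok])$auc
}

# brute-force AUC oracle: concordant-pair fraction with ties counted 1/2
auc_bruteforce <- function(prob, label) {
  pos <- prob[label == 1]
  neg <- prob[label == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
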