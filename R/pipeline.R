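# End-to-end orchestration: synthesis (or WAV ingest) -> two analyzer
# profiles -> segmentation/summarization -> feature filtering -> LOOCV with
# per-fold selection and stacking -> diagnostic reports (primary + both
# subgroup exclusions). A single master seed fans out to every stage.

default_run_config <- function() {
  list(
    cohort = list(n_nows = 19, n_exposed_no_nows = 7, n_unexposed = 39,
                  mode = "feature_table", effect_map = default_effect_map(),
                  manifest = NULL),
    frontend = list(frame_ms = 12.5, hop_ms = 6.25,
                    hyperphonation_threshold = 1000),
    segmentation = list(threshold_db = 15, min_dur_ms = 50,
                        merge_gap_ms = 50, min_voiced_fraction = 0.3),
    filters = list(max_missing = 0.60, freq_ratio = 19, unique_pct = 10,
                   cutoff = 0.75, within_folds = FALSE),
    selection = list(n_runs = 100, retain_threshold = 5, alpha = 0.01,
                     selection_trees = 300, selection_max_iter = 100),
    model = list(n_trees = 10000, min_node_size = 10),
    evaluation = list(level = 0.95),
    out_dir = NULL,
    master_seed = 1)
}

#' Validate and complete a run configuration
#'
#' Fills the faithful defaults (12.5 ms frames, 500 ms stratum split,
#' 0.60/0.75 filter cutoffs, 100 selection runs with the >5 retention
#' rule, 10 000 trees) into a partial configuration and applies
#' cross-field checks. Unknown keys and out-of-range values raise
#' descriptive errors.
#'
#' @param raw named list (possibly nested, possibly empty) of overrides,
#'   or a path to a JSON configuration file.
#' @return a completed list of class `run_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw)) raw <- jsonlite::read_json(raw, simplifyVector = TRUE)
  if (inherits(raw, "run_config")) raw <- unclass(raw)
  cfg <- default_run_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop_invalid("unknown config keys: %s", paste(unknown, collapse = ", "))
  for (k in names(raw)) {
    if (is.list(cfg[[k]]) && is.list(raw[[k]])) {
      bad <- setdiff(names(raw[[k]]), names(cfg[[k]]))
      if (length(bad))
        stop_invalid("unknown config keys under '%s': %s", k,
                     paste(bad, collapse = ", "))
      cfg[[k]][names(raw[[k]])] <- raw[[k]]
    } else cfg[[k]] <- raw[[k]]
  }
  if (cfg$frontend$frame_ms <= 0 || cfg$frontend$hop_ms <= 0)
    stop_invalid("'frame_ms' and 'hop_ms' must be positive")
  if (cfg$selection$retain_threshold >= cfg$selection$n_runs)
    stop_invalid("'retain_threshold' (%s) must be below 'n_runs' (%s)",
                 cfg$selection$retain_threshold, cfg$selection$n_runs)
  check_prob(cfg$filters$max_missing, "max_missing")
  check_prob(cfg$filters$cutoff, "cutoff")
  if (cfg$model$n_trees < 1) stop_invalid("'n_trees' must be >= 1")
  structure(cfg, class = "run_config")
}

read_cohort_manifest <- function(path) {
  if (!file.exists(path))
    stop_invalid("stage ingest: manifest '%s' does not exist", path)
  manifest <- read.csv(path, stringsAsFactors = FALSE)
  recs <- list()
  for (i in seq_len(nrow(manifest))) {
    wav <- manifest$wav[i]
    if (!file.exists(wav))
      stop_invalid("stage ingest: WAV '%s' (infant %s) does not exist",
                   wav, manifest$infant_id[i])
    w <- read_wav(wav)
    recs[[manifest$infant_id[i]]] <-
      list(audio = audio_segment(w$samples, w$sample_rate,
                                 manifest$infant_id[i]))
  }
  structure(list(mode = "audio", manifest = manifest, recordings = recs),
            class = "cry_cohort")
}

#' Run the full analysis pipeline
#'
#' Executes synthesis (or WAV ingest) through both analyzer profiles,
#' segmentation and summarization, feature filtering, LOOCV with per-fold
#' ensemble selection and stacking, and evaluation with both subgroup
#' sensitivity variants. All artifacts (tables, stability profiles,
#' predictions, reports, a manifest with configuration and stage
#' checksums, and a JSONL log) are written to the output directory.
#'
#' @param config a [validate_config()] result or raw override list.
#' @return (invisibly) a list with the run directory, the `loocv_stack`
#'   fit, the reports and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir %||% tempfile("crywatch_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  log_line <- function(stage, ...) {
    rec <- c(list(stage = stage, time = format(Sys.time(), "%H:%M:%OS2")),
             list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cohort <- stage("ingest", {
    if (!is.null(cfg$cohort$manifest))
      read_cohort_manifest(cfg$cohort$manifest)
    else generate_cohort(cohort_spec(
      n_nows = cfg$cohort$n_nows,
      n_exposed_no_nows = cfg$cohort$n_exposed_no_nows,
      n_unexposed = cfg$cohort$n_unexposed,
      effect_map = unlist(cfg$cohort$effect_map),
      seed = derive_seed(cfg$master_seed, "cohort"),
      mode = cfg$cohort$mode))
  })
  log_line("ingest", n_infants = nrow(cohort$manifest), mode = cohort$mode)

  tables <- stage("extract", {
    profiles <- list(
      analyzer_profile("cepstral", frame_ms = cfg$frontend$frame_ms,
                       hop_ms = cfg$frontend$hop_ms,
                       hyperphonation_threshold =
                         cfg$frontend$hyperphonation_threshold),
      analyzer_profile("spectral", frame_ms = cfg$frontend$frame_ms,
                       hop_ms = cfg$frontend$hop_ms,
                       hyperphonation_threshold =
                         cfg$frontend$hyperphonation_threshold))
    build_feature_tables(cohort, profiles, seg_config(
      threshold_db = cfg$segmentation$threshold_db,
      min_dur_ms = cfg$segmentation$min_dur_ms,
      merge_gap_ms = cfg$segmentation$merge_gap_ms,
      min_voiced_fraction = cfg$segmentation$min_voiced_fraction))
  })
  for (key in names(tables))
    write.csv(tables[[key]],
              file.path(out_dir, paste0("table_", key, ".csv")),
              row.names = FALSE, na = "")
  log_line("extract", tables = names(tables),
           rows = nrow(tables[[1]]))

  fcfg <- cfg$filters[c("max_missing", "freq_ratio", "unique_pct", "cutoff")]
  filter_reports <- NULL
  if (!isTRUE(cfg$filters$within_folds)) {
    filtered <- stage("filter", lapply(tables, function(tab)
      do.call(filter_features, c(list(tab), fcfg))))
    filter_reports <- lapply(filtered, `[[`, "report")
    tables <- lapply(filtered, `[[`, "table")
    for (key in names(filter_reports))
      jsonlite::write_json(
        list(kept = filter_reports[[key]]$kept,
             removed = filter_reports[[key]]$removed),
        file.path(out_dir, paste0("filter_", key, ".json")),
        auto_unbox = TRUE, digits = NA)
    log_line("filter", kept = vapply(filter_reports,
                                     function(r) length(r$kept), numeric(1)))
  }

  fit <- stage("train-eval", loocv_stack(
    tables,
    config = model_config(
      n_trees = cfg$model$n_trees,
      min_node_size = cfg$model$min_node_size,
      n_runs = cfg$selection$n_runs,
      retain_threshold = cfg$selection$retain_threshold,
      selection_trees = cfg$selection$selection_trees,
      selection_max_iter = cfg$selection$selection_max_iter,
      alpha = cfg$selection$alpha,
      master_seed = derive_seed(cfg$master_seed, "loocv")),
    filter_cfg = if (isTRUE(cfg$filters$within_folds)) fcfg else NULL))
  pred_path <- file.path(out_dir, "predictions.csv")
  write.csv(fit$predictions, pred_path, row.names = FALSE, na = "")
  for (key in names(fit$stability))
    write.csv(as.data.frame(fit$stability[[key]]),
              file.path(out_dir, paste0("stability_", key, ".csv")),
              row.names = FALSE, na = "")
  log_line("train-eval", n_predictions = nrow(fit$predictions),
           skipped_models = unname(fit$skipped))

  reports <- stage("report", {
    variants <- list(primary = NULL)
    for (ex in c("unexposed", "exposed_no_nows")) {
      left <- fit$predictions[fit$predictions$subgroup != ex, ]
      if (length(unique(left$label[!is.na(left$p_stacked)])) == 2)
        variants[[paste0("excluding_", ex)]] <- ex
    }
    lapply(variants, function(ex)
      subgroup_analysis(fit$predictions, exclude = ex,
                        level = cfg$evaluation$level))
  })
  for (nm in names(reports))
    jsonlite::write_json(as.data.frame(reports[[nm]]),
                         file.path(out_dir, paste0("report_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  log_line("report", variants = names(reports))

  outputs <- list.files(out_dir, pattern = "\\.(csv|json)$")
  manifest <- list(
    master_seed = cfg$master_seed,
    config = unclass(cfg),
    checksums = setNames(
      lapply(outputs, function(f) file_checksum(file.path(out_dir, f))),
      outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(dir = out_dir, fit = fit, reports = reports,
                 tables = tables, filter_reports = filter_reports,
                 manifest = manifest))
}
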