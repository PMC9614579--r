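# Stacked random-forest classification under leave-one-out cross-validation.
# Each fold: per feature table (analyzer x utterance stratum), ensemble
# Boruta selection on the training rows only, a probability forest on the
# retained features, median imputation from training rows; the held-out
# infant's prediction is the unweighted mean of the available per-table
# class probabilities.

#' Model configuration for the stacked classifier
#'
#' Defaults are the faithful analysis settings: 10 000-tree probability
#' forests with `mtry = floor(sqrt(p))` (the forest default), minimum node
#' size 10, and the 100-repetition Boruta ensemble with the ">5 of 100"
#' retention rule. Simulation work typically lowers `n_trees`, `n_runs`
#' and `selection_max_iter`.
#'
#' @param n_trees trees in each final probability forest (default 10000).
#' @param min_node_size minimum node size for probability trees (default
#'   10).
#' @param n_runs,retain_threshold ensemble-selection repetitions and
#'   strict retention bound (defaults 100 and 5).
#' @param selection_trees,selection_max_iter,alpha Boruta internals
#'   (defaults 300 trees, 100 iterations, 0.01).
#' @param master_seed master seed; all fold/run seeds derive from it.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_trees = 10000, min_node_size = 10, n_runs = 100,
                         retain_threshold = 5, selection_trees = 300,
                         selection_max_iter = 100, alpha = 0.01,
                         master_seed = 1) {
  if (n_trees < 1) stop_invalid("'n_trees' must be >= 1")
  if (retain_threshold >= n_runs)
    stop_invalid("'retain_threshold' must be below 'n_runs'")
  check_prob(alpha, "alpha")
  structure(list(n_trees = n_trees, min_node_size = min_node_size,
                 n_runs = n_runs, retain_threshold = retain_threshold,
                 selection_trees = selection_trees,
                 selection_max_iter = selection_max_iter, alpha = alpha,
                 master_seed = as.integer(master_seed)),
            class = "model_config")
}

usable_row <- function(row) {
  !is.null(row) && nrow(row) == 1 &&
    (is.null(row$utterance_count) || row$utterance_count > 0)
}

training_medians <- function(x) {
  vapply(x, function(v) median(v, na.rm = TRUE), numeric(1))
}

impute_with <- function(x, medians) {
  for (f in names(medians))
    x[[f]][is.na(x[[f]])] <- medians[[f]]
  x
}

#' Fit one cross-validation fold of the stacked model
#'
#' Per table: median imputation statistics and ensemble Boruta selection
#' are computed from the training rows only, then a probability forest is
#' fit on the retained features. A table whose ensemble retains no feature
#' contributes no model to this fold (stacking averages the rest).
#'
#' @param train_tables named list of infant-level feature tables
#'   (training rows only; both classes present in each).
#' @param config a [model_config()].
#' @param fold_seed integer seed for this fold.
#' @return an object of class `stack_fold`: per-table `models`,
#'   `retained`, `medians` and `selection` ([ensemble_select()] results).
#' @export
fit_fold <- function(train_tables, config, fold_seed) {
  models <- retained <- medians <- selection <-
    setNames(vector("list", length(train_tables)), names(train_tables))
  for (key in names(train_tables)) {
    tab <- train_tables[[key]]
    y <- factor(tab$label, levels = c(0, 1))
    if (nlevels(droplevels(y)) != 2)
      stop_invalid("training rows for table '%s' lack a class", key)
    x <- tab[, feature_columns(tab), drop = FALSE]
    x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
    med <- training_medians(x)
    med <- med[is.finite(med)]        # drop all-missing features
    x <- impute_with(x[, names(med), drop = FALSE], med)
    sel <- ensemble_select(
      x, y, n_runs = config$n_runs,
      retain_threshold = config$retain_threshold,
      seed = derive_seed(fold_seed, paste0("sel.", key)),
      max_iter = config$selection_max_iter, alpha = config$alpha,
      num_trees = config$selection_trees)
    selection[[key]] <- sel
    medians[[key]] <- med
    retained[[key]] <- sel$retained
    if (length(sel$retained) == 0) next  # model skipped for this fold
    d <- x[, sel$retained, drop = FALSE]
    d$.y <- y
    models[[key]] <- ranger::ranger(
      dependent.variable.name = ".y", data = d, probability = TRUE,
      num.trees = config$n_trees, min.node.size = config$min_node_size,
      seed = derive_seed(fold_seed, paste0("rf.", key)), num.threads = 1)
  }
  structure(list(models = models, retained = retained, medians = medians,
                 selection = selection), class = "stack_fold")
}

#' Predict a held-out infant from a fitted fold
#'
#' Per available model (the infant has a usable row in that table and the
#' fold kept a model for it), the class-1 probability; the stacked
#' prediction is the unweighted mean of the available probabilities. An
#' infant with usable rows but no available model receives the
#' uninformative probability 0.5; an infant with no usable rows in any
#' table yields `NA` (excluded downstream).
#'
#' @param fold a [fit_fold()] result.
#' @param heldout_rows named list of one-row tables for the held-out
#'   infant (keys matching the fold's tables; `NULL` where absent).
#' @return one-row data.frame with per-model probabilities (`p_<key>`),
#'   `p_stacked` and `n_models`.
#' @export
predict_heldout <- function(fold, heldout_rows) {
  keys <- names(fold$models)
  probs <- setNames(rep(NA_real_, length(keys)), keys)
  any_usable <- FALSE
  for (key in keys) {
    row <- heldout_rows[[key]]
    if (!usable_row(row)) next
    any_usable <- TRUE
    if (is.null(fold$models[[key]])) next
    med <- fold$medians[[key]]
    x <- impute_with(row[, names(med), drop = FALSE], med)
    pr <- predict(fold$models[[key]],
                  data = x[, fold$retained[[key]], drop = FALSE],
                  num.threads = 1)$predictions
    probs[key] <- pr[1, "1"]
  }
  avail <- !is.na(probs)
  stacked <- if (any(avail)) mean(probs[avail])
  else if (any_usable) 0.5 else NA_real_
  out <- as.data.frame(as.list(setNames(probs, paste0("p_", keys))))
  out$p_stacked <- stacked
  out$n_models <- sum(avail)
  out
}

#' Stacked random-forest classification under leave-one-out
#' cross-validation
#'
#' The core fitting routine: for every infant, the full modelling
#' procedure (per-table ensemble Boruta feature selection, probability
#' forests, median imputation) is repeated on all other infants, and the
#' held-out infant receives the stacked (mean) probability. Per-fold
#' retained feature sets are kept for stability profiling.
#'
#' @param tables named list of infant-level feature tables (typically the
#'   four `analyzer.stratum` tables), aligned on `infant_id` and carrying
#'   `label` and `subgroup` columns.
#' @param config a [model_config()].
#' @param filter_cfg optional list of [filter_features()] thresholds; when
#'   supplied, the filter chain is applied inside every fold to the
#'   training rows only (instead of once up front).
#' @return an object of class `loocv_stack` with `predictions` (one row
#'   per infant), `fold_selection`, `stability` (per-table
#'   [stability_profile()]s), `skipped` counts and `config`.
#' @export
loocv_stack <- function(tables, config = model_config(), filter_cfg = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1)
  ids <- tables[[1]]$infant_id
  for (tab in tables) {
    if (!all(c("infant_id", "label") %in% names(tab)))
      stop_invalid("every table needs 'infant_id' and 'label' columns")
    if (!identical(sort(tab$infant_id), sort(ids)))
      stop_invalid("tables are not aligned on infant_id")
  }
  labels <- tables[[1]]$label[match(ids, tables[[1]]$infant_id)]
  if (min(table(factor(labels, levels = c(0, 1)))) < 2)
    stop_invalid("LOOCV needs at least 2 infants per class")
  subgroups <- if ("subgroup" %in% names(tables[[1]]))
    tables[[1]]$subgroup[match(ids, tables[[1]]$infant_id)]
  else rep(NA_character_, length(ids))

  preds <- vector("list", length(ids))
  fold_selection <- vector("list", length(ids))
  names(fold_selection) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    fold_seed <- derive_seed(config$master_seed, paste0("fold.", id))
    train <- lapply(tables, function(tab) tab[tab$infant_id != id, ])
    heldout <- lapply(tables, function(tab) {
      r <- tab[tab$infant_id == id, ]
      if (nrow(r) == 1) r else NULL
    })
    if (!is.null(filter_cfg)) {
      for (key in names(train)) {
        ft <- do.call(filter_features, c(list(train[[key]]), filter_cfg))
        train[[key]] <- ft$table
        if (!is.null(heldout[[key]]))
          heldout[[key]] <- heldout[[key]][, names(ft$table), drop = FALSE]
      }
    }
    fold <- fit_fold(train, config, fold_seed)
    fold_selection[[id]] <- fold$selection
    p <- predict_heldout(fold, heldout)
    preds[[i]] <- cbind(data.frame(infant_id = id, label = labels[i],
                                   subgroup = subgroups[i],
                                   stringsAsFactors = FALSE), p)
  }
  predictions <- do.call(rbind, preds)
  stability <- lapply(setNames(names(tables), names(tables)), function(key)
    stability_profile(lapply(fold_selection, function(s) s[[key]])))
  skipped <- vapply(names(tables), function(key)
    sum(vapply(fold_selection,
               function(s) length(s[[key]]$retained) == 0, logical(1))),
    numeric(1))
  structure(list(predictions = predictions, fold_selection = fold_selection,
                 stability = stability, skipped = skipped, config = config,
                 call = match.call()),
            class = "loocv_stack")
}

#' @export
print.loocv_stack <- function(x, ...) {
  ok <- !is.na(x$predictions$p_stacked)
  cat(sprintf("<loocv_stack> %d infants (%d with predictions), %d tables\n",
              nrow(x$predictions), sum(ok), length(x$stability)))
  if (sum(ok) > 3 && length(unique(x$predictions$label[ok])) == 2) {
    roc <- roc_curve(x$predictions$p_stacked[ok], x$predictions$label[ok])
    cat(sprintf("  stacked LOOCV AUC %.3f (95%% CI %.3f-%.3f)\n",
                roc$auc, roc$auc_ci[1], roc$auc_ci[2]))
  }
  invisible(x)
}

#' @rdname loocv_stack
#' @param object a `loocv_stack`.
#' @param exclude optional subgroup to exclude before evaluation
#'   (`"unexposed"` or `"exposed_no_nows"`).
#' @param ... unused.
#' @export
summary.loocv_stack <- function(object, exclude = NULL, ...) {
  subgroup_analysis(object$predictions, exclude = exclude)
}

#' @rdname loocv_stack
#' @param x a `loocv_stack`.
#' @export
plot.loocv_stack <- function(x, ...) {
  ok <- !is.na(x$predictions$p_stacked)
  roc <- roc_curve(x$predictions$p_stacked[ok], x$predictions$label[ok])
  plot(roc, ...)
  invisible(x)
}

#' @export
as.data.frame.loocv_stack <- function(x, ...) x$predictions
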