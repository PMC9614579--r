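# Native Boruta: all-relevant feature selection by comparison against
# permuted shadow features, plus the 100-repetition retention ensemble
# (variables selected in more than `retain_threshold` of `n_runs`
# repetitions are retained) and per-fold stability profiling.

#' Run the Boruta shadow-feature selection algorithm
#'
#' Each iteration appends a permuted shadow copy of every still-active
#' feature (padded to at least five shadows), fits a random forest and
#' records permutation importances. A feature scores a hit when its
#' importance exceeds the maximum shadow importance; cumulative hits are
#' tested against Binomial(iterations, 1/2) two-sided at level `alpha`
#' with Bonferroni correction over features. Significantly many hits
#' confirm a feature, significantly few reject it (rejected features are
#' dropped from subsequent forests); features still undecided after
#' `max_iter` iterations stay `tentative`.
#'
#' @param x data.frame or matrix of numeric features (complete cases).
#' @param y binary outcome (factor or 0/1 vector); both classes required.
#' @param seed integer seed (iteration seeds are derived from it).
#' @param max_iter maximum number of iterations (default 100).
#' @param alpha significance level of the hit test (default 0.01).
#' @param num_trees trees per internal forest (default 300).
#' @return an object of class `boruta_result`: `decision` (named factor
#'   with levels confirmed/tentative/rejected), `hits`, `iterations`,
#'   `importance_history` (iterations x features) and `mean_importance`.
#' @export
boruta_run <- function(x, y, seed = 1, max_iter = 100, alpha = 0.01,
                       num_trees = 300) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop_invalid("Boruta needs at least 2 features")
  y <- factor(y)
  if (nlevels(droplevels(y)) != 2)
    stop_invalid("'y' must contain both classes")
  y <- droplevels(y)
  p <- ncol(x)
  feats <- names(x)
  decision <- rep("tentative", p)
  names(decision) <- feats
  hits <- setNames(rep(0L, p), feats)
  tested <- setNames(rep(0L, p), feats)
  history <- matrix(NA_real_, max_iter, p, dimnames = list(NULL, feats))
  thr <- alpha / (2 * p)  # two-sided, Bonferroni over features
  iter <- 0L
  for (t in seq_len(max_iter)) {
    iter <- t
    active <- decision != "rejected"
    undecided <- decision == "tentative"
    if (!any(undecided)) { iter <- t - 1L; break }
    Xa <- x[, active, drop = FALSE]
    set.seed(derive_seed(seed, paste0("perm", t)))
    sh_src <- rep(seq_len(ncol(Xa)), length.out = max(5L, ncol(Xa)))
    shadows <- as.data.frame(lapply(sh_src, function(j) sample(Xa[[j]])))
    names(shadows) <- paste0("shadow_", seq_along(sh_src))
    d <- cbind(Xa, shadows)
    d$.y <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = d,
      num.trees = num_trees, importance = "permutation",
      seed = derive_seed(seed, paste0("rf", t)), num.threads = 1)
    imp <- fit$variable.importance
    shadow_max <- max(imp[names(shadows)])
    real_imp <- imp[names(Xa)]
    history[t, names(Xa)] <- real_imp
    hit_now <- names(Xa)[real_imp > shadow_max]
    hit_now <- intersect(hit_now, feats[undecided])
    hits[hit_now] <- hits[hit_now] + 1L
    tested[undecided] <- tested[undecided] + 1L
    for (f in feats[undecided]) {
      p_hi <- pbinom(hits[[f]] - 1L, tested[[f]], 0.5, lower.tail = FALSE)
      p_lo <- pbinom(hits[[f]], tested[[f]], 0.5)
      if (p_hi < thr) decision[f] <- "confirmed"
      else if (p_lo < thr) decision[f] <- "rejected"
    }
  }
  history <- history[seq_len(max(iter, 1L)), , drop = FALSE]
  structure(list(
    decision = factor(decision, levels = c("confirmed", "tentative",
                                           "rejected")),
    hits = hits, iterations = iter,
    importance_history = history,
    mean_importance = colMeans(history, na.rm = TRUE)),
    class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  cat(sprintf("<boruta_result> %d iterations: %d confirmed, %d tentative, %d rejected\n",
              x$iterations, tab[["confirmed"]], tab[["tentative"]],
              tab[["rejected"]]))
  invisible(x)
}

#' Ensemble Boruta selection with a retention threshold
#'
#' Repeats [boruta_run()] `n_runs` times with derived seeds; a feature's
#' selection count is the number of runs in which it was confirmed
#' (tentative does not count), and it is retained when the count strictly
#' exceeds `retain_threshold` (the ">5 of 100" rule at the defaults).
#'
#' @inheritParams boruta_run
#' @param n_runs number of Boruta repetitions (default 100).
#' @param retain_threshold strict lower bound on the selection count for
#'   retention (default 5).
#' @param ... passed to [boruta_run()] (`max_iter`, `alpha`, `num_trees`).
#' @return an object of class `ensemble_selection`: data.frame `summary`
#'   (`feature`, `selection_count`, `retained`, `mean_importance`) plus
#'   `retained` (character), `n_runs` and `retain_threshold`.
#' @export
ensemble_select <- function(x, y, n_runs = 100, retain_threshold = 5,
                            seed = 1, ...) {
  if (retain_threshold >= n_runs)
    stop_invalid("'retain_threshold' must be below 'n_runs'")
  x <- as.data.frame(x)
  feats <- names(x)
  counts <- setNames(rep(0L, length(feats)), feats)
  imp <- matrix(NA_real_, n_runs, length(feats),
                dimnames = list(NULL, feats))
  for (r in seq_len(n_runs)) {
    b <- boruta_run(x, y, seed = derive_seed(seed, paste0("run", r)), ...)
    sel <- names(b$decision)[b$decision == "confirmed"]
    counts[sel] <- counts[sel] + 1L
    imp[r, ] <- b$mean_importance[feats]
  }
  summary <- data.frame(
    feature = feats, selection_count = unname(counts),
    retained = unname(counts > retain_threshold),
    mean_importance = unname(colMeans(imp, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  structure(list(summary = summary,
                 retained = feats[counts > retain_threshold],
                 n_runs = n_runs, retain_threshold = retain_threshold),
            class = "ensemble_selection")
}

#' @export
print.ensemble_selection <- function(x, ...) {
  cat(sprintf("<ensemble_selection> %d/%d features retained (count > %d of %d runs)\n",
              length(x$retained), nrow(x$summary), x$retain_threshold,
              x$n_runs))
  invisible(x)
}

#' Feature stability and mean importance across cross-validation folds
#'
#' Stability is the percentage of folds in which a feature was retained by
#' the ensemble selector (100% = retained in every fold); importance is
#' averaged over the folds where it was computed.
#'
#' @param fold_results list of [ensemble_select()] results (one per fold).
#' @return an object of class `stability_profile`: a data.frame with
#'   `feature`, `stability` (%), `mean_importance` and `n_folds`.
#' @export
stability_profile <- function(fold_results) {
  if (length(fold_results) == 0)
    stop_invalid("at least one fold result is required")
  feats <- unique(unlist(lapply(fold_results,
                                function(r) r$summary$feature)))
  n_folds <- length(fold_results)
  ret <- sapply(fold_results, function(r)
    feats %in% r$retained)
  imp <- sapply(fold_results, function(r)
    r$summary$mean_importance[match(feats, r$summary$feature)])
  ret <- matrix(ret, nrow = length(feats))
  imp <- matrix(imp, nrow = length(feats))
  mi <- rowMeans(imp, na.rm = TRUE)
  mi[!is.finite(mi)] <- NA_real_
  mi[rowSums(ret) == 0] <- NA_real_  # never retained: no importance reported
  out <- data.frame(feature = feats,
                    stability = 100 * rowMeans(ret),
                    mean_importance = mi,
                    n_folds = n_folds, stringsAsFactors = FALSE)
  out <- out[order(-out$stability, -rank(out$mean_importance,
                                         na.last = FALSE)), ]
  rownames(out) <- NULL
  structure(out, class = c("stability_profile", "data.frame"))
}

#' Plot feature stability against mean importance
#'
#' The diagnostic view used to identify important variables: features with
#' both high stability (retained in most folds) and high mean importance.
#'
#' @param x a [stability_profile()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.stability_profile <- function(x, ...) {
  graphics::plot(x$stability, x$mean_importance,
                 xlab = "Stability (% of folds retained)",
                 ylab = "Mean permutation importance",
                 pch = 19, col = "#2c7fb8", ...)
  top <- x$stability > 90 & !is.na(x$mean_importance)
  if (any(top))
    graphics::text(x$stability[top], x$mean_importance[top],
                   labels = x$feature[top], pos = 2, cex = 0.7)
  graphics::abline(v = 90, lty = 3)
  invisible(x)
}
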