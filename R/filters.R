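# Pre-selection feature filtering: drop features with >60% missing data,
# near-zero variance, or excessive intercorrelation (|r| > 0.75), in that
# order. Thresholds and the greedy mean-absolute-correlation removal follow
# the common machine-learning preprocessing convention.

meta_columns <- c("infant_id", "subgroup", "label")

#' Feature columns of an infant-level table
#' @param table infant-level feature table.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), meta_columns)
}

new_filter_report <- function(table, removed, thresholds) {
  feats <- feature_columns(table)
  kept <- setdiff(feats, removed$feature)
  structure(list(removed = removed, kept = kept, thresholds = thresholds,
                 table = table[, c(intersect(meta_columns, names(table)),
                                   kept), drop = FALSE]),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d kept, %d removed\n",
              length(x$kept), nrow(x$removed)))
  if (nrow(x$removed)) print(x$removed, row.names = FALSE)
  invisible(x)
}

empty_removed <- function() {
  data.frame(feature = character(0), reason = character(0),
             statistic = numeric(0), stringsAsFactors = FALSE)
}

#' Remove features with a high missing-data rate
#'
#' Features whose fraction of missing infant-level values is strictly
#' greater than `max_missing` are removed.
#'
#' @param table infant-level feature table.
#' @param max_missing missingness threshold (default 0.60).
#' @return a `filter_report` with `removed`, `kept`, `thresholds` and the
#'   filtered `table`.
#' @export
missingness_filter <- function(table, max_missing = 0.60) {
  if (nrow(table) == 0) stop_invalid("'table' must be non-empty")
  feats <- feature_columns(table)
  rate <- vapply(feats, function(f) mean(is.na(table[[f]])), numeric(1))
  bad <- rate > max_missing
  removed <- data.frame(feature = feats[bad],
                        reason = rep("missingness", sum(bad)),
                        statistic = unname(rate[bad]),
                        stringsAsFactors = FALSE)
  new_filter_report(table, removed, list(max_missing = max_missing))
}

#' Remove near-zero-variance features
#'
#' A feature is removed when the ratio of the most common value's count to
#' the second most common value's count is at least `freq_ratio` and the
#' number of distinct values is below `unique_pct` percent of the sample
#' size. Constant features are always removed.
#'
#' @param table infant-level feature table.
#' @param freq_ratio frequency-ratio threshold (default 19, i.e. 95/5).
#' @param unique_pct distinct-value percentage threshold (default 10).
#' @return a `filter_report`.
#' @export
near_zero_variance_filter <- function(table, freq_ratio = 19,
                                      unique_pct = 10) {
  if (nrow(table) == 0) stop_invalid("'table' must be non-empty")
  feats <- feature_columns(table)
  removed <- empty_removed()
  for (f in feats) {
    v <- table[[f]][!is.na(table[[f]])]
    if (length(v) == 0) next
    counts <- sort(table(v), decreasing = TRUE)
    if (length(counts) == 1) {
      removed <- rbind(removed, data.frame(
        feature = f, reason = "near_zero_variance", statistic = Inf,
        stringsAsFactors = FALSE))
      next
    }
    fr <- counts[1] / counts[2]
    pu <- 100 * length(counts) / length(v)
    if (fr >= freq_ratio && pu < unique_pct)
      removed <- rbind(removed, data.frame(
        feature = f, reason = "near_zero_variance", statistic = unname(fr),
        stringsAsFactors = FALSE))
  }
  new_filter_report(table, removed,
                    list(freq_ratio = freq_ratio, unique_pct = unique_pct))
}

#' Remove excessively intercorrelated features
#'
#' Pairwise-complete absolute Pearson correlations; while any pair exceeds
#' `cutoff` (strictly), the member of the worst pair with the larger mean
#' absolute correlation to the remaining features is removed, ties going to
#' the earlier column. Deterministic.
#'
#' @param table infant-level feature table.
#' @param cutoff absolute correlation cutoff (default 0.75).
#' @return a `filter_report`.
#' @export
correlation_filter <- function(table, cutoff = 0.75) {
  feats <- feature_columns(table)
  removed <- empty_removed()
  keep <- feats[vapply(feats, function(f) is.numeric(table[[f]]) &&
                         sum(!is.na(table[[f]])) >= 3 &&
                         sd(table[[f]], na.rm = TRUE) > 0, logical(1))]
  if (length(keep) >= 2) {
    cm <- abs(suppressWarnings(
      stats::cor(table[, keep, drop = FALSE],
                 use = "pairwise.complete.obs")))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    repeat {
      worst <- max(cm)
      if (worst <= cutoff) break
      ij <- which(cm == worst, arr.ind = TRUE)[1, ]
      mac <- rowMeans(cm, na.rm = TRUE)
      drop_i <- if (mac[ij[1]] > mac[ij[2]]) ij[1]
      else if (mac[ij[2]] > mac[ij[1]]) ij[2]
      else min(ij)
      removed <- rbind(removed, data.frame(
        feature = rownames(cm)[drop_i], reason = "correlation",
        statistic = worst, stringsAsFactors = FALSE))
      cm <- cm[-drop_i, -drop_i, drop = FALSE]
      if (nrow(cm) < 2) break
    }
  }
  new_filter_report(table, removed, list(cutoff = cutoff))
}

#' Apply the full data-reduction filter chain
#'
#' Missingness, then near-zero variance, then intercorrelation, each
#' applied to the survivors of the previous step; the combined report
#' records each removal once with the reason from the first filter that
#' triggered.
#'
#' @param table infant-level feature table.
#' @param max_missing,freq_ratio,unique_pct,cutoff filter thresholds.
#' @return list with `table` (filtered) and `report` (a `filter_report`).
#' @export
filter_features <- function(table, max_missing = 0.60, freq_ratio = 19,
                            unique_pct = 10, cutoff = 0.75) {
  r1 <- missingness_filter(table, max_missing)
  r2 <- near_zero_variance_filter(r1$table, freq_ratio, unique_pct)
  r3 <- correlation_filter(r2$table, cutoff)
  removed <- rbind(r1$removed, r2$removed, r3$removed)
  if (length(r3$kept) == 0)
    stop_invalid("all %d features removed by filtering; nothing to select",
                 length(feature_columns(table)))
  report <- new_filter_report(table, removed, list(
    max_missing = max_missing, freq_ratio = freq_ratio,
    unique_pct = unique_pct, cutoff = cutoff))
  list(table = report$table, report = report)
}
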