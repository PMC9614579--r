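# Diagnostic evaluation of the stacked LOOCV probabilities: ROC/AUC with
# the DeLong rank-based variance, the distance-to-perfect-prediction
# cutpoint, standard diagnostic accuracy estimates with exact
# (Clopper-Pearson) binomial intervals, Cohen's kappa with its asymptotic
# interval, subgroup sensitivity analyses, and Table-1-style group
# comparisons.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile interval; the lower bound is exactly 0 when
#' `successes = 0` and the upper exactly 1 when `successes = n`.
#'
#' @param successes,n counts with `0 <= successes <= n`, `n > 0`.
#' @param level confidence level (default 0.95).
#' @return numeric `(lower, upper)`.
#' @export
exact_binomial_ci <- function(successes, n, level = 0.95) {
  if (!is.finite(successes) || !is.finite(n) || n <= 0 ||
      successes < 0 || successes > n)
    stop_invalid("need 0 <= successes <= n with n > 0")
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else qbeta(a, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - a, successes + 1,
                                            n - successes)
  c(lower, upper)
}

#' Receiver operating characteristic curve with AUC
#'
#' Thresholds at the distinct predicted probabilities (predict positive
#' when `prob >= threshold`); AUC is the Mann-Whitney concordance with
#' ties counted one half, and its confidence interval uses the DeLong
#' placement-variance estimate.
#'
#' @param prob numeric predicted probabilities.
#' @param label binary truth (0/1); both classes required.
#' @param level confidence level for the AUC interval.
#' @return an object of class `roc_curve`: `points` (threshold, fpr, tpr),
#'   `auc`, `auc_ci`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(prob, label, level = 0.95) {
  ok <- !is.na(prob) & !is.na(label)
  prob <- prob[ok]
  label <- as.integer(label[ok])
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0)
    stop_invalid("both classes are required for a ROC curve")
  thr <- c(Inf, sort(unique(prob), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(prob >= t & label == 1) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(prob >= t & label == 0) / n0,
                numeric(1))
  r <- rank(prob)
  auc <- (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pos <- prob[label == 1]
  neg <- prob[label == 0]
  v10 <- vapply(pos, function(p) (sum(p > neg) + 0.5 * sum(p == neg)) / n0,
                numeric(1))
  v01 <- vapply(neg, function(p) (sum(pos > p) + 0.5 * sum(pos == p)) / n1,
                numeric(1))
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, auc_ci = ci, n_pos = n1, n_neg = n0,
                 prob = prob, label = label),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "1 - Specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  cp <- select_cutpoint(x)
  i <- which(x$points$threshold == cp)
  graphics::points(x$points$fpr[i], x$points$tpr[i], pch = 17, col = "red")
  invisible(x)
}

#' Select the cutpoint closest to perfect prediction
#'
#' The threshold minimizing the Euclidean distance
#' `sqrt((1 - sensitivity)^2 + (1 - specificity)^2)` to the perfect
#' corner; ties resolve to the lower threshold (higher sensitivity).
#'
#' @param roc a [roc_curve()].
#' @return the selected probability threshold.
#' @export
select_cutpoint <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  pts <- roc$points[is.finite(roc$points$threshold), ]
  d <- sqrt((1 - pts$tpr)^2 + pts$fpr^2)
  best <- which(d == min(d))
  min_thr <- min(pts$threshold[best])
  min_thr
}

#' Confusion matrix at a probability cutpoint
#'
#' @param prob,label predictions and binary truth.
#' @param cutpoint predict positive when `prob >= cutpoint`.
#' @return list of class `confusion_matrix` with `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_matrix <- function(prob, label, cutpoint) {
  ok <- !is.na(prob) & !is.na(label)
  pred <- prob[ok] >= cutpoint
  truth <- as.integer(label[ok]) == 1
  structure(list(tp = sum(pred & truth), fn = sum(!pred & truth),
                 fp = sum(pred & !truth), tn = sum(!pred & !truth)),
            class = "confusion_matrix")
}

kappa_statistic <- function(tp, fn, fp, tn, level = 0.95) {
  n <- tp + fn + fp + tn
  p0 <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
  if (pe == 1) return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_)))
  k <- (p0 - pe) / (1 - pe)
  se <- sqrt(p0 * (1 - p0) / (n * (1 - pe)^2))
  z <- qnorm(1 - (1 - level) / 2)
  list(estimate = k, ci = pmax(pmin(k + c(-1, 1) * z * se, 1), -1))
}

#' Standard diagnostic accuracy estimates from a confusion matrix
#'
#' Accuracy, sensitivity, specificity, positive and negative predictive
#' values, each with an exact (Clopper-Pearson) binomial confidence
#' interval, plus Cohen's kappa with its asymptotic interval. Ratios with
#' zero denominators are reported missing.
#'
#' @param cm a [confusion_matrix()] (or list with `tp`, `fn`, `fp`, `tn`).
#' @param level confidence level (default 0.95).
#' @return an object of class `diagnostic_report` (AUC fields empty; see
#'   [evaluate_predictions()] for the full report).
#' @export
diagnostics <- function(cm, level = 0.95) {
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n <= 0) stop_invalid("empty confusion matrix")
  prop <- function(num, den) {
    if (den == 0) return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_)))
    list(estimate = num / den, ci = exact_binomial_ci(num, den, level))
  }
  structure(list(
    confusion = cm, n = n, level = level,
    accuracy = prop(cm$tp + cm$tn, n),
    sensitivity = prop(cm$tp, cm$tp + cm$fn),
    specificity = prop(cm$tn, cm$tn + cm$fp),
    ppv = prop(cm$tp, cm$tp + cm$fp),
    npv = prop(cm$tn, cm$tn + cm$fn),
    kappa = kappa_statistic(cm$tp, cm$fn, cm$fp, cm$tn, level),
    auc = NULL, cutpoint = NULL, variant = "confusion-matrix"),
    class = "diagnostic_report")
}

#' Full diagnostic evaluation of stacked predictions
#'
#' ROC and AUC (DeLong interval), distance-to-perfect cutpoint, the
#' resulting confusion matrix and all diagnostic accuracy estimates.
#'
#' @param predictions data.frame with `p_stacked` and `label` columns
#'   (rows with missing predictions are excluded, mirroring infants with
#'   no usable cries).
#' @param level confidence level.
#' @param variant tag recorded in the report (e.g. the subgroup variant).
#' @return a `diagnostic_report`.
#' @export
evaluate_predictions <- function(predictions, level = 0.95,
                                 variant = "primary") {
  ok <- !is.na(predictions$p_stacked)
  prob <- predictions$p_stacked[ok]
  label <- predictions$label[ok]
  roc <- roc_curve(prob, label, level)
  cp <- select_cutpoint(roc)
  cm <- confusion_matrix(prob, label, cp)
  rep <- diagnostics(cm, level)
  rep$auc <- list(estimate = roc$auc, ci = roc$auc_ci)
  rep$roc <- roc
  rep$cutpoint <- cp
  rep$variant <- variant
  rep
}

#' Recompute the diagnostic report after excluding a subgroup
#'
#' Sensitivity analysis on the stacked LOOCV probabilities: the named
#' subgroup is removed and the ROC, cutpoint and all diagnostics are
#' recomputed on the retained predictions (no refitting).
#'
#' @param predictions stacked prediction data.frame (with `subgroup`).
#' @param exclude subgroup to exclude (`"unexposed"`,
#'   `"exposed_no_nows"`, or `NULL` for the primary analysis).
#' @param level confidence level.
#' @return a `diagnostic_report`.
#' @export
subgroup_analysis <- function(predictions, exclude = NULL, level = 0.95) {
  keep <- predictions
  variant <- "primary"
  if (!is.null(exclude) && !identical(exclude, "none")) {
    keep <- predictions[predictions$subgroup != exclude, ]
    variant <- paste0("excluding_", exclude)
  }
  if (length(unique(keep$label[!is.na(keep$p_stacked)])) < 2)
    stop_invalid("exclusion leaves a single class")
  evaluate_predictions(keep, level, variant)
}

#' @export
print.diagnostic_report <- function(x, ...) {
  fmt <- function(s) {
    if (is.null(s) || is.na(s$estimate)) return("   --")
    sprintf("%.2f (95%% CI, %.2f-%.2f)", s$estimate, s$ci[1], s$ci[2])
  }
  cat(sprintf("<diagnostic_report> [%s] n = %d\n", x$variant, x$n))
  if (!is.null(x$auc)) cat("  AUC         ", fmt(x$auc), "\n")
  cat("  Accuracy    ", fmt(x$accuracy), "\n")
  cat("  Kappa       ", fmt(x$kappa), "\n")
  cat("  Sensitivity ", fmt(x$sensitivity), "\n")
  cat("  Specificity ", fmt(x$specificity), "\n")
  cat("  PPV         ", fmt(x$ppv), "\n")
  cat("  NPV         ", fmt(x$npv), "\n")
  cm <- x$confusion
  cat(sprintf("  Confusion: TP %d / FN %d / FP %d / TN %d",
              cm$tp, cm$fn, cm$fp, cm$tn))
  if (!is.null(x$cutpoint)) cat(sprintf("  (cutpoint %.3f)", x$cutpoint))
  cat("\n")
  invisible(x)
}

#' Convert a diagnostic report to a flat data.frame
#' @param x a `diagnostic_report`.
#' @param ... unused.
#' @export
as.data.frame.diagnostic_report <- function(x, ...) {
  row <- function(name, s) data.frame(
    metric = name, estimate = s$estimate, ci_lower = s$ci[1],
    ci_upper = s$ci[2], stringsAsFactors = FALSE)
  out <- rbind(
    if (!is.null(x$auc)) row("auc", x$auc),
    row("accuracy", x$accuracy), row("kappa", x$kappa),
    row("sensitivity", x$sensitivity), row("specificity", x$specificity),
    row("ppv", x$ppv), row("npv", x$npv))
  out$variant <- x$variant
  out
}

#' Group comparisons for cohort covariates
#'
#' Numeric covariates: Welch two-sample t test (Satterthwaite degrees of
#' freedom) and pooled-SD Cohen's d (reported as a magnitude). Categorical
#' covariates: Pearson chi-squared (with continuity correction on 2x2
#' tables, R's default).
#'
#' @param data data.frame of covariates plus a binary group column.
#' @param group name of the binary group column (default `"label"`).
#' @param covariates character vector of covariate columns (default: all
#'   except the group and identifier columns).
#' @return data.frame with `covariate`, `test`, `statistic`, `df`,
#'   `p_value`, `cohen_d`.
#' @export
compare_groups <- function(data, group = "label", covariates = NULL) {
  g <- factor(data[[group]])
  if (nlevels(droplevels(g)) != 2)
    stop_invalid("'%s' must define two non-empty groups", group)
  if (is.null(covariates))
    covariates <- setdiff(names(data), c(group, "infant_id", "subgroup"))
  rows <- lapply(covariates, function(cv) {
    v <- data[[cv]]
    if (is.numeric(v)) {
      tt <- t.test(v ~ g)
      sp <- split(v, g)
      n1 <- sum(!is.na(sp[[1]])); n2 <- sum(!is.na(sp[[2]]))
      pooled <- sqrt(((n1 - 1) * var(sp[[1]], na.rm = TRUE) +
                        (n2 - 1) * var(sp[[2]], na.rm = TRUE)) /
                       (n1 + n2 - 2))
      d <- abs(mean(sp[[1]], na.rm = TRUE) - mean(sp[[2]], na.rm = TRUE)) /
        pooled
      data.frame(covariate = cv, test = "welch_t",
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 cohen_d = d, stringsAsFactors = FALSE)
    } else {
      ct <- suppressWarnings(chisq.test(table(v, g)))
      data.frame(covariate = cv, test = "chi_squared",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 cohen_d = NA_real_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
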