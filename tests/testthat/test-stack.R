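# Stacked LOOCV: fold fitting, held-out prediction, stacking arithmetic,
# leakage protection and reproducibility.

small_cohort <- function(seed, effect = strong_effect_map(), n1 = 6,
                         n0 = 8) {
  generate_cohort(cohort_spec(n_nows = n1, n_exposed_no_nows = 0,
                              n_unexposed = n0, effect_map = effect,
                              seed = seed, n_noise_features = 2))
}

test_that("a fitted fold has per-table models on retained features", {
  coh <- small_cohort(501)
  train <- lapply(coh$tables, function(t) t[t$infant_id != "inf001", ])
  fold <- fit_fold(train, fast_config(3), fold_seed = 77)
  expect_named(fold$models, names(coh$tables))
  for (key in names(fold$models)) {
    expect_true(all(fold$retained[[key]] %in%
                      feature_columns(coh$tables[[key]])))
    if (!is.null(fold$models[[key]]))
      expect_s3_class(fold$models[[key]], "ranger")
    expect_true(all(is.finite(fold$medians[[key]])))
  }
})

test_that("stacked probability is the mean of available models", {
  coh <- small_cohort(502)
  fit <- loocv_stack(coh$tables, fast_config(11))
  p <- fit$predictions
  pm <- as.matrix(p[, paste0("p_", names(coh$tables))])
  manual <- rowMeans(pm, na.rm = TRUE)
  ok <- p$n_models > 0
  expect_equal(p$p_stacked[ok], manual[ok])
  expect_true(all(p$p_stacked >= 0 & p$p_stacked <= 1, na.rm = TRUE))
  expect_equal(nrow(p), 14)  # one prediction per infant
})

test_that("an infant without usable rows in a stratum is averaged over the rest", {
  coh <- small_cohort(503, effect = strong_effect_map(2), n1 = 10, n0 = 12)
  coh$tables[["cepstral.short"]]$utterance_count[3] <- 0L
  fit <- loocv_stack(coh$tables, fast_config(12))
  row <- fit$predictions[3, ]
  expect_true(is.na(row$p_cepstral.short))
  expect_equal(row$n_models, 3)
  expect_equal(row$p_stacked,
               mean(unlist(row[c("p_cepstral.long", "p_spectral.short",
                                 "p_spectral.long")])))
})

test_that("folds never see the held-out infant", {
  coh <- small_cohort(504)
  cfg <- fast_config(21, n_runs = 1)
  fit <- loocv_stack(coh$tables, cfg)
  # recompute one fold's selection from training rows only; it must match
  id <- coh$tables[[1]]$infant_id[5]
  key <- "cepstral.short"
  tab <- coh$tables[[key]]
  train <- tab[tab$infant_id != id, ]
  x <- train[, feature_columns(train)]
  med <- vapply(x, function(v) median(v, na.rm = TRUE), numeric(1))
  for (f in names(med)) x[[f]][is.na(x[[f]])] <- med[[f]]
  fold_seed <- derive_seed(cfg$master_seed, paste0("fold.", id))
  sel <- ensemble_select(x, factor(train$label, levels = c(0, 1)),
                         n_runs = cfg$n_runs,
                         retain_threshold = cfg$retain_threshold,
                         seed = derive_seed(fold_seed, paste0("sel.", key)),
                         max_iter = cfg$selection_max_iter,
                         alpha = cfg$alpha,
                         num_trees = cfg$selection_trees)
  expect_identical(fit$fold_selection[[id]][[key]]$summary, sel$summary)
})

test_that("LOOCV output is bit-identical under a fixed master seed", {
  coh <- small_cohort(505, n1 = 4, n0 = 5)
  cfg <- fast_config(31, n_runs = 1, n_trees = 200)
  f1 <- loocv_stack(coh$tables, cfg)
  f2 <- loocv_stack(coh$tables, cfg)
  expect_identical(f1$predictions, f2$predictions)
})

test_that("LOOCV refuses degenerate class structure", {
  coh <- small_cohort(506, n1 = 1, n0 = 8)
  expect_error(loocv_stack(coh$tables, fast_config(1)), "2 infants")
  t2 <- generate_cohort(cohort_spec(n_nows = 3, n_exposed_no_nows = 0,
                                    n_unexposed = 3, seed = 9))$tables
  t2[[2]] <- t2[[2]][1:5, ]  # one infant missing from one table
  expect_error(loocv_stack(t2, fast_config(1)), "aligned")
})

test_that("tree count beyond a few hundred barely moves the AUC", {
  coh <- generate_cohort(cohort_spec(n_nows = 80, n_exposed_no_nows = 0,
                                     n_unexposed = 120,
                                     effect_map = strong_effect_map(1.0),
                                     seed = 507))
  tab <- coh$tables[["cepstral.short"]]
  test_idx <- seq(1, 200, by = 2)  # stratified by construction
  train <- tab[-test_idx, ]
  test <- tab[test_idx, ]
  aucs <- vapply(c(500, 5000), function(nt) {
    d <- train[, feature_columns(train)]
    d$.y <- factor(train$label)
    m <- ranger::ranger(dependent.variable.name = ".y", data = d,
                        probability = TRUE, num.trees = nt, seed = 42,
                        num.threads = 1, min.node.size = 10)
    p <- predict(m, data = test[, feature_columns(test)],
                 num.threads = 1)$predictions[, "1"]
    roc_curve(p, test$label)$auc
  }, numeric(1))
  expect_lt(abs(aucs[1] - aucs[2]), 0.02)
})
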