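# ROC/AUC, cutpoint, diagnostic accuracy, exact intervals, kappa,
# subgroup analyses and group comparisons.

test_that("AUC matches brute-force pair counting in all tie regimes", {
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_equal(roc_curve(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(c(0.9, 0.7, 0.8, 0.1), c(1, 1, 0, 0))$auc, 0.75)

  set.seed(20)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    prob <- round(runif(n), 2)  # induce ties
    label <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_curve(prob, label)$auc, auc_bruteforce(prob, label))
  }
  expect_error(roc_curve(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC endpoints and monotonicity hold", {
  set.seed(21)
  r <- roc_curve(runif(30), rbinom(30, 1, 0.4))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_true(r$auc_ci[1] <= r$auc && r$auc <= r$auc_ci[2])
})

test_that("DeLong interval agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  prob <- runif(60)
  label <- rbinom(60, 1, 0.4)
  prob[label == 1] <- prob[label == 1] + 0.3
  r <- roc_curve(prob, label)
  ref <- pROC::ci.auc(pROC::roc(label, prob, quiet = TRUE), method = "delong")
  expect_equal(r$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(r$auc_ci[1], as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(r$auc_ci[2], as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("the cutpoint minimizes distance to perfect prediction", {
  set.seed(23)
  prob <- runif(40)
  label <- rbinom(40, 1, 0.5)
  r <- roc_curve(prob, label)
  cp <- select_cutpoint(r)
  pts <- r$points[is.finite(r$points$threshold), ]
  d <- sqrt((1 - pts$tpr)^2 + pts$fpr^2)
  expect_equal(min(d), d[pts$threshold == cp])
  # exhaustive: no point strictly closer
  expect_true(all(d >= d[pts$threshold == cp] - 1e-12))

  # perfect point is always selected; a (sens .89, spec .83) style point
  # sits at distance sqrt(.0121 + .0289)
  expect_equal(sqrt((1 - 0.89)^2 + (1 - 0.83)^2), 0.2025, tolerance = 1e-4)
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  cp2 <- select_cutpoint(perfect)
  cm <- confusion_matrix(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), cp2)
  expect_equal(cm$fn + cm$fp, 0)

  # tie resolves to the lower threshold (more sensitive): thresholds 0.9
  # and 0.4 both sit at distance 0.5, so 0.4 wins
  tie <- roc_curve(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0))
  expect_equal(select_cutpoint(tie), 0.4)
})

test_that("diagnostic estimates reproduce textbook arithmetic", {
  cm <- list(tp = 19, fn = 0, fp = 0, tn = 46)
  rep <- diagnostics(cm)
  for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv"))
    expect_equal(rep[[m]]$estimate, 1)
  expect_equal(rep$kappa$estimate, 1)

  # chance-level classifier has kappa near zero
  set.seed(24)
  truth <- rbinom(4000, 1, 0.3)
  pred <- rbinom(4000, 1, 0.6)
  cm2 <- list(tp = sum(pred & truth), fn = sum(!pred & truth),
              fp = sum(pred & !truth), tn = sum(!pred & !truth))
  expect_lt(abs(diagnostics(cm2)$kappa$estimate), 0.05)

  # kappa is invariant to swapping both labels
  cm3 <- list(tp = 17, fn = 2, fp = 8, tn = 38)
  cm3_swapped <- list(tp = 38, fn = 8, fp = 2, tn = 17)
  expect_equal(diagnostics(cm3)$kappa$estimate,
               diagnostics(cm3_swapped)$kappa$estimate)

  # zero denominators are reported missing
  rep0 <- diagnostics(list(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_true(is.na(rep0$sensitivity$estimate))  # no positives: 0/0
  expect_equal(rep0$ppv$estimate, 0)
  rep1 <- diagnostics(list(tp = 0, fn = 2, fp = 0, tn = 8))
  expect_true(is.na(rep1$ppv$estimate))          # no predicted positives
})

test_that("Clopper-Pearson intervals hit the printed bounds and edges", {
  ci <- exact_binomial_ci(17, 19)
  expect_equal(round(ci, 2), c(0.67, 0.99))
  expect_equal(exact_binomial_ci(0, 10)[1], 0)
  expect_equal(exact_binomial_ci(10, 10)[2], 1)
  expect_equal(round(exact_binomial_ci(38, 40)[1], 2), 0.83)
  expect_error(exact_binomial_ci(5, 4), "successes")
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(25)
  for (p in c(0.1, 0.5, 0.9)) {
    x <- rbinom(2000, 50, p)
    covered <- vapply(x, function(k) {
      ci <- exact_binomial_ci(k, 50)
      ci[1] <= p && p <= ci[2]
    }, logical(1))
    expect_gte(mean(covered), 0.945)
  }
})

test_that("subgroup exclusion recomputes reports on the retained infants", {
  set.seed(26)
  preds <- data.frame(
    infant_id = sprintf("i%02d", 1:65),
    label = rep(c(1, 0, 0), c(19, 7, 39)),
    subgroup = rep(c("nows", "exposed_no_nows", "unexposed"), c(19, 7, 39)),
    p_stacked = c(runif(19, 0.4, 1), runif(7, 0, 0.6), runif(39, 0, 0.6)))
  primary <- subgroup_analysis(preds)
  expect_equal(primary$n, 65)
  no_unexposed <- subgroup_analysis(preds, exclude = "unexposed")
  expect_equal(no_unexposed$n, 26)
  no_exposed <- subgroup_analysis(preds, exclude = "exposed_no_nows")
  expect_equal(no_exposed$n, 58)
  identity <- subgroup_analysis(preds, exclude = NULL)
  expect_equal(identity$auc$estimate, primary$auc$estimate)
  expect_identical(as.data.frame(identity)[, -5],
                   as.data.frame(primary)[, -5])

  one_class <- preds[preds$subgroup == "nows" | preds$subgroup == "unexposed", ]
  one_class$label[one_class$subgroup == "unexposed"] <- 1
  expect_error(subgroup_analysis(one_class, exclude = "nows"),
               "single class")
})

test_that("group comparisons compute Welch t and pooled-SD Cohen d", {
  # vectors with exact sample moments: mean 3.1/3.4, sd 0.4, n 19/46
  mk <- function(n, m, s, seed) {
    set.seed(seed)
    x <- rnorm(n)
    m + s * (x - mean(x)) / sd(x)
  }
  dat <- data.frame(
    label = rep(c(1, 0), c(19, 46)),
    birth_weight = c(mk(19, 3.1, 0.4, 1), mk(46, 3.4, 0.4, 2)),
    sex = factor(rep(c("f", "m"), length.out = 65)))
  out <- compare_groups(dat, covariates = c("birth_weight", "sex"))
  bw <- out[out$covariate == "birth_weight", ]
  expect_equal(round(bw$cohen_d, 2), 0.75)
  expect_equal(bw$test, "welch_t")
  expect_gt(abs(bw$statistic), 2)
  expect_equal(out[out$covariate == "sex", "test"], "chi_squared")

  same <- data.frame(label = rep(c(1, 0), each = 10), v = rep(1:10, 2))
  r <- compare_groups(same, covariates = "v")
  expect_equal(r$statistic, 0)
  expect_equal(r$cohen_d, 0)
  expect_error(compare_groups(data.frame(label = rep(1, 5), v = 1:5),
                              covariates = "v"), "two")
})
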