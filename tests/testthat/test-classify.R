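# Feature selection, SVM evaluation, confusion/ROC metrics, bootstrap AUC
# comparison and the modality likelihood-ratio test.

sep_data <- function(n_per = 20, margin = 3, noise = 0.3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("control", "patient"), each = n_per))
  X <- data.frame(
    f1 = ifelse(y == "patient", margin, 0) + rnorm(2 * n_per, sd = noise),
    f2 = ifelse(y == "patient", -margin, 0) + rnorm(2 * n_per, sd = noise),
    n1 = rnorm(2 * n_per), n2 = rnorm(2 * n_per), n3 = rnorm(2 * n_per))
  list(X = X, y = y)
}

test_that("ANOVA selection keeps a planted feature and scores importance", {
  d <- sep_data(margin = 5, noise = 1, seed = 2)
  sel <- select_features_anova(d$X, d$y)
  expect_true(all(c("f1", "f2") %in% sel$feature[sel$selected]))
  expect_equal(sel$importance, -log10(sel$p_adj))
  # excluded (e.g. ASM-associated) features are never tested
  sel2 <- select_features_anova(d$X, d$y, exclude = c("f1"))
  expect_false("f1" %in% sel2$feature)
  # zero-variance features are skipped with a warning
  d$X$flat <- 1
  expect_warning(select_features_anova(d$X, d$y), "zero-variance")
})

test_that("all-noise features are selected at about the FDR rate", {
  set.seed(3)
  any_sel <- replicate(200, {
    X <- as.data.frame(matrix(rnorm(30 * 5), 30, 5))
    y <- rep(c("a", "b"), each = 15)
    any(select_features_anova(X, y)$selected)
  })
  expect_lte(mean(any_sel), 0.12)        # BH at q = 0.05 over 5 null features
})

test_that("confusion metrics follow their defining formulas", {
  m <- confusion_metrics(9, 8, 2, 1)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 9 / 11)
  expect_equal(m$npv, 8 / 9)
  expect_equal(m$accuracy, 0.85)
  perfect <- confusion_metrics(5, 7, 0, 0)
  expect_true(all(unlist(perfect) == 1))
  expect_true(is.na(confusion_metrics(0, 5, 0, 3)$ppv))
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
  # invariance to scaling all counts
  m4 <- confusion_metrics(36, 32, 8, 4)
  expect_equal(unlist(m), unlist(m4))
})

test_that("threshold-sweep AUC equals the concordance statistic", {
  r <- roc_auc(c(1, 2, 3, 10, 11, 12), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(r$youden$j, 1)
  tied <- roc_auc(rep(4, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(tied$auc, 0.5)
  set.seed(4)
  for (i in 1:50) {
    s <- rnorm(30)
    p <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (!any(p) || all(p)) next
    expect_equal(roc_auc(s, p)$auc, oracle_auc(s, p), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(5)
  s <- rnorm(60)
  p <- rbinom(60, 1, plogis(s))
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(p, s, quiet = TRUE)))
    expect_equal(roc_auc(s, p == 1)$auc, ref, tolerance = 1e-10)
  } else {
    expect_equal(roc_auc(s, p == 1)$auc, oracle_auc(s, p == 1), tolerance = 1e-12)
  }
})

test_that("chi-squared independence matches the Pearson formula", {
  r <- chi2_independence(matrix(c(50, 0, 0, 50), 2, 2))
  expect_equal(r$statistic, 100)
  expect_lt(r$p, 1e-20)
  ind <- chi2_independence(matrix(c(25, 25, 25, 25), 2, 2))
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p, 1)
  set.seed(6)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    expect_equal(chi2_independence(tab)$statistic, oracle_chi2(tab),
                 tolerance = 1e-10)
  }
  expect_error(chi2_independence(matrix(c(0, 0, 3, 4), 2, 2)), "marginal")
})

test_that("separable features yield near-perfect SVM performance", {
  d <- sep_data(seed = 7)
  rep_ <- train_eval_svm(d$X[c("f1", "f2")], d$y, n_splits = 50, seed = 8)
  expect_gte(rep_$metrics$mean[rep_$metrics$metric == "accuracy"], 0.95)
  expect_gte(rep_$metrics$mean[rep_$metrics$metric == "auc"], 0.98)
  expect_gte(rep_$cv$metrics$accuracy, 0.95)
})

test_that("label-shuffled features classify at chance", {
  d <- sep_data(seed = 9)
  set.seed(10)
  ysh <- sample(d$y)
  rep_ <- train_eval_svm(d$X[c("f1", "f2")], ysh, n_splits = 50, seed = 11)
  acc <- rep_$metrics$mean[rep_$metrics$metric == "accuracy"]
  expect_gt(acc, 0.3)
  expect_lt(acc, 0.7)
})

test_that("SVM evaluation is deterministic given a seed", {
  d <- sep_data(seed = 12)
  r1 <- train_eval_svm(d$X, d$y, n_splits = 10, seed = 13)
  r2 <- train_eval_svm(d$X, d$y, n_splits = 10, seed = 13)
  expect_identical(r1$splits, r2$splits)
  expect_identical(r1$metrics, r2$metrics)
})

test_that("bootstrap AUC comparison separates what should be separated", {
  set.seed(14)
  pool <- 0.8 + rnorm(200, sd = 0.05)
  self <- bootstrap_auc_compare(pool, pool, n_boot = 2000, seed = 15)
  expect_gte(self$p, 0.9)
  shifted <- bootstrap_auc_compare(pool + 0.2, pool, n_boot = 2000, seed = 16)
  expect_lte(shifted$p, 0.001)
  # resolution is 2/n_boot-granular at tiny n_boot
  tiny <- bootstrap_auc_compare(rnorm(20), rnorm(20), n_boot = 10, seed = 17)
  expect_equal(tiny$p %% 0.1, 0, tolerance = 1e-12)
})

test_that("the modality LRT sees no gain from a duplicated feature", {
  set.seed(18)
  base <- matrix(rnorm(80 * 2), 80, 2)
  y <- factor(ifelse(plogis(base[, 1]) > runif(80), "patient", "control"))
  dup <- lrt_modality(base, base[, 1, drop = FALSE], y)
  expect_lt(dup$delta_deviance, 1e-6)
  expect_equal(dup$df, 1)
})

test_that("a strongly predictive added feature is detected by the LRT", {
  set.seed(19)
  hits <- replicate(20, {
    base <- matrix(rnorm(80), 80, 1)
    extra <- rnorm(80)
    y <- factor(ifelse(plogis(0.3 * base[, 1] + 2 * extra) > runif(80),
                       "patient", "control"))
    lrt_modality(base, cbind(extra), y)$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})
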