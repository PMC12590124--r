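# Classification of patients vs controls from normalized oscillation
# features: ANOVA feature selection with FDR, RBF-kernel SVM (C = 10)
# evaluated by stratified 10-fold CV and repeated stratified 80/20 splits,
# confusion/ROC metrics, chi-squared independence of predicted vs actual
# labels, bootstrap AUC comparison between models, and a likelihood-ratio
# test for the added value of a second modality.

#' ANOVA feature selection with FDR correction
#'
#' One-way ANOVA F test per feature against the class labels; p values are
#' Benjamini-Hochberg adjusted across features and features with adjusted
#' p < `q` are retained. Importance is `-log10(adjusted p)`. Features listed
#' in `exclude` (e.g. those associated with anti-seizure medication use) are
#' removed before testing; zero-variance features are skipped with a
#' warning.
#'
#' @param features data.frame or matrix (subjects x features, named columns).
#' @param labels Factor or vector of class labels (2+ per class).
#' @param q FDR level (default 0.05).
#' @param exclude Character vector of feature names to drop beforehand.
#' @return data.frame per tested feature: `feature`, `F`, `p`, `p_adj`,
#'   `selected`, `importance`.
#' @export
select_features_anova <- function(features, labels, q = 0.05,
                                  exclude = character()) {
  features <- as.data.frame(features)
  labels <- factor(labels)
  if (min(table(labels)) < 2) stop_arg("need >= 2 subjects per class")
  features <- features[, setdiff(names(features), exclude), drop = FALSE]
  keep <- vapply(features, function(x) stats::sd(x) > 0, logical(1))
  if (any(!keep))
    warning(sprintf("zero-variance feature(s) skipped: %s",
                    paste(names(features)[!keep], collapse = ", ")))
  features <- features[, keep, drop = FALSE]
  res <- lapply(names(features), function(nm) {
    av <- stats::anova(stats::lm(features[[nm]] ~ labels))
    data.frame(feature = nm, F = av$`F value`[1], p = av$`Pr(>F)`[1])
  })
  out <- do.call(rbind, res)
  adj <- fdr_bh(out$p, q = q)
  out$p_adj <- adj$p_adjusted
  out$selected <- adj$rejected
  out$importance <- -log10(out$p_adj)
  out
}

#' Confusion-matrix metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN), accuracy (TP+TN)/total. Ratios with a zero denominator
#' are reported as `NA`, not zero.
#'
#' @param tp,tn,fp,fn Non-negative counts (total > 0).
#' @return Named list of the five metrics.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop_arg("counts must be non-negative")
  if (sum(counts) == 0) stop_arg("total count must be positive")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = rat(tp, tp + fn), specificity = rat(tn, tn + fp),
       ppv = rat(tp, tp + fp), npv = rat(tn, tn + fn),
       accuracy = (tp + tn) / sum(counts))
}

#' ROC curve, AUC and Youden operating point
#'
#' Threshold sweep over the unique scores (higher score = more likely
#' positive); AUC by the trapezoidal rule, which equals the Mann-Whitney
#' concordance probability. The Youden point maximizes
#' sensitivity + specificity - 1.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical/0-1/factor labels; the positive class is `TRUE`,
#'   `1`, or the second factor level.
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `youden` (list `threshold`, `sensitivity`, `specificity`, `j`).
#' @export
roc_auc <- function(scores, labels) {
  if (!all(is.finite(scores))) stop_arg("scores must be finite")
  pos <- if (is.logical(labels)) labels
         else if (is.factor(labels)) labels == levels(labels)[2]
         else labels == 1
  nP <- sum(pos)
  nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop_arg("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) sum(scores >= th & pos) / nP, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & !pos) / nN, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  best <- which.max(j)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc,
       youden = list(threshold = thr[best], sensitivity = tpr[best],
                     specificity = 1 - fpr[best], j = j[best]))
}

#' Chi-squared independence of predicted vs actual classification
#'
#' Pearson chi-squared with 1 df on the pooled 2x2 confusion table;
#' continuity correction is off by default.
#'
#' @param confusion 2x2 matrix (rows = actual, cols = predicted), or the
#'   four counts `c(tp, fn, fp, tn)`.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List with `statistic`, `p`, `df`.
#' @export
chi2_independence <- function(confusion, correct = FALSE) {
  if (!is.matrix(confusion)) confusion <- matrix(confusion, 2, 2, byrow = TRUE)
  if (any(rowSums(confusion) == 0) || any(colSums(confusion) == 0))
    stop_arg("all table marginals must be positive")
  ct <- suppressWarnings(stats::chisq.test(confusion, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter))
}

# stratified index sample: `frac` of each class (at least 1 per class)
.stratified_sample <- function(labels, frac) {
  unlist(lapply(levels(labels), function(lv) {
    idx <- which(labels == lv)
    sample(idx, max(1L, round(frac * length(idx))))
  }), use.names = FALSE)
}

# min-max scaling fit on a training matrix; constant columns map to 0
.fit_minmax <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}
.apply_minmax <- function(X, sc) sweep(sweep(X, 2L, sc$lo, "-"), 2L, sc$rng, "/")

# median-heuristic RBF bandwidth: gamma = 1 / (2 * median pairwise sq dist)
.median_gamma <- function(X) {
  d2 <- as.numeric(stats::dist(X))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med == 0) 1 / ncol(X) else 1 / (2 * med)
}

#' Train and evaluate an RBF-kernel SVM
#'
#' Two evaluation regimes, reported side by side: (a) stratified `n_folds`
#' cross-validation on the full data set; (b) `n_splits` stratified
#' train-test splits (default 80/20), which provide the per-iteration metric
#' distributions, the pooled ROC and the per-iteration AUC pool. The
#' regularization parameter defaults to C = 10; the RBF bandwidth is set by
#' the median heuristic on the training data unless given. Min-max feature
#' scaling is fit on the training portion of each split by default
#' (`scale_mode = "train"`, leakage-safe); `"global"` fits it once on all
#' data. A split whose test set misses a class is re-drawn (logged).
#'
#' @param features data.frame/matrix (subjects x features).
#' @param labels Class labels; the positive class ("patient") must be the
#'   second factor level (default alphabetical order does this for
#'   control/patient).
#' @param C Regularization parameter (default 10).
#' @param gamma RBF bandwidth; `NULL` (default) = median heuristic.
#' @param n_folds Folds for the CV regime (default 10).
#' @param n_splits Number of random stratified splits (default 1000).
#' @param train_frac Training fraction per split (default 0.8).
#' @param scale_mode `"train"` (default) or `"global"`.
#' @param seed Seed for fold assignment and splits.
#' @return List of class `classification_report`: `cv` (pooled CV confusion +
#'   metrics), `splits` (per-iteration data.frame), `metrics` (mean and SD
#'   over splits), `pooled_confusion`, `chi2`, `roc` (pooled), `auc_pool`,
#'   `youden`, `gamma`, `redraws`.
#' @export
train_eval_svm <- function(features, labels, C = 10, gamma = NULL,
                           n_folds = 10, n_splits = 1000, train_frac = 0.8,
                           scale_mode = c("train", "global"), seed = NULL) {
  scale_mode <- match.arg(scale_mode)
  X <- as.matrix(as.data.frame(features))
  y <- factor(labels)
  if (nlevels(y) != 2) stop_arg("labels must have exactly two classes")
  pos <- levels(y)[2]
  if (min(table(y)) < 2) stop_arg("need >= 2 subjects per class")
  gl_sc <- .fit_minmax(X)

  fit_predict <- function(tr_idx, te_idx) {
    sc <- if (scale_mode == "train") .fit_minmax(X[tr_idx, , drop = FALSE]) else gl_sc
    Xtr <- .apply_minmax(X[tr_idx, , drop = FALSE], sc)
    Xte <- .apply_minmax(X[te_idx, , drop = FALSE], sc)
    g <- if (is.null(gamma)) .median_gamma(Xtr) else gamma
    fit <- e1071::svm(Xtr, y[tr_idx], type = "C-classification",
                      kernel = "radial", cost = C, gamma = g, scale = FALSE)
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    # orient decision values so larger = more likely positive class
    if (!startsWith(colnames(attr(pr, "decision.values"))[1], pos)) dv <- -dv
    list(pred = pr, score = dv, gamma = g)
  }

  with_seed(seed, {
    ## (a) stratified k-fold CV
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    cv_pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
    for (f in seq_len(n_folds)) {
      te <- which(fold == f)
      if (!length(te)) next
      cv_pred[te] <- fit_predict(which(fold != f), te)$pred
    }
    cv_tab <- table(actual = y, predicted = cv_pred)
    cv_conf <- c(tp = cv_tab[2, 2], tn = cv_tab[1, 1],
                 fp = cv_tab[1, 2], fn = cv_tab[2, 1])
    cv <- list(confusion = cv_conf,
               metrics = do.call(confusion_metrics, as.list(cv_conf)))

    ## (b) repeated stratified train/test splits
    rows <- vector("list", n_splits)
    scores_pool <- list()
    labels_pool <- list()
    gammas <- numeric(n_splits)
    redraws <- 0L
    for (s in seq_len(n_splits)) {
      repeat {
        tr <- .stratified_sample(y, train_frac)
        te <- setdiff(seq_along(y), tr)
        if (nlevels(droplevels(y[te])) == 2 && nlevels(droplevels(y[tr])) == 2)
          break
        redraws <- redraws + 1L
      }
      fp_ <- fit_predict(tr, te)
      gammas[s] <- fp_$gamma
      tab <- table(actual = y[te], predicted = fp_$pred)
      tp <- tab[2, 2]; tn <- tab[1, 1]; fp <- tab[1, 2]; fn <- tab[2, 1]
      met <- confusion_metrics(tp, tn, fp, fn)
      auc_s <- tryCatch(roc_auc(fp_$score, y[te] == pos)$auc,
                        error = function(e) NA_real_)
      rows[[s]] <- data.frame(split = s, tp = tp, tn = tn, fp = fp, fn = fn,
                              sensitivity = met$sensitivity,
                              specificity = met$specificity,
                              ppv = met$ppv, npv = met$npv,
                              accuracy = met$accuracy, auc = auc_s)
      scores_pool[[s]] <- fp_$score
      labels_pool[[s]] <- y[te] == pos
    }
    splits <- do.call(rbind, rows)
    pooled <- c(tp = sum(splits$tp), tn = sum(splits$tn),
                fp = sum(splits$fp), fn = sum(splits$fn))
    metric_names <- c("sensitivity", "specificity", "ppv", "npv", "accuracy", "auc")
    metrics <- data.frame(
      metric = metric_names,
      mean = vapply(metric_names, function(m) mean(splits[[m]], na.rm = TRUE), numeric(1)),
      sd = vapply(metric_names, function(m) stats::sd(splits[[m]], na.rm = TRUE), numeric(1)),
      row.names = NULL)
    pooled_roc <- roc_auc(unlist(scores_pool), unlist(labels_pool))
    structure(list(cv = cv, splits = splits, metrics = metrics,
                   pooled_confusion = pooled,
                   chi2 = chi2_independence(matrix(pooled[c("tp", "fn", "fp", "tn")], 2, 2,
                                                   byrow = TRUE)),
                   roc = pooled_roc$roc, pooled_auc = pooled_roc$auc,
                   youden = pooled_roc$youden, auc_pool = splits$auc,
                   gamma = stats::median(gammas), redraws = redraws,
                   params = list(C = C, n_folds = n_folds, n_splits = n_splits,
                                 train_frac = train_frac,
                                 scale_mode = scale_mode)),
              class = "classification_report")
  })
}

#' @export
print.classification_report <- function(x, ...) {
  acc <- x$metrics[x$metrics$metric == "accuracy", ]
  auc <- x$metrics[x$metrics$metric == "auc", ]
  cat(sprintf("<classification_report> %d splits: accuracy %.2f +/- %.2f, AUC %.2f +/- %.2f; CV accuracy %.2f\n",
              x$params$n_splits, acc$mean, acc$sd, auc$mean, auc$sd,
              x$cv$metrics$accuracy))
  invisible(x)
}

#' Bootstrap comparison of two AUC pools
#'
#' Draws `n_boot` bootstrap resamples from each pool of per-iteration AUC
#' values, records the difference in resampled means, and reports the
#' two-sided empirical p value `min(1, 2 * min(P(diff <= 0), P(diff >= 0)))`.
#'
#' @param pool_a,pool_b Numeric AUC pools (non-empty).
#' @param n_boot Bootstrap draws (default 10000).
#' @param seed Optional seed.
#' @return List with `p`, `observed_diff`, `boot_diff` (the resampled
#'   difference distribution).
#' @export
bootstrap_auc_compare <- function(pool_a, pool_b, n_boot = 10000, seed = NULL) {
  pool_a <- pool_a[is.finite(pool_a)]
  pool_b <- pool_b[is.finite(pool_b)]
  if (!length(pool_a) || !length(pool_b)) stop_arg("pools must be non-empty")
  with_seed(seed, {
    d <- vapply(seq_len(n_boot), function(i)
      mean(sample(pool_a, replace = TRUE)) - mean(sample(pool_b, replace = TRUE)),
      numeric(1))
    p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
    list(p = p, observed_diff = mean(pool_a) - mean(pool_b), boot_diff = d)
  })
}

# logistic deviance via glm; flags likely separation / non-convergence and
# falls back to a lightly ridge-penalized fit (deviance evaluated at the
# penalized estimate)
.logistic_deviance <- function(X, y01) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y01, family = stats::binomial()),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  dev <- fit$deviance
  if (sep || !fit$converged) {
    nll <- function(b) {
      eta <- as.numeric(cbind(1, X) %*% b)
      sum(log1p(exp(-(2 * y01 - 1) * eta))) + 1e-4 * sum(b[-1]^2)
    }
    opt <- stats::optim(rep(0, ncol(X) + 1), nll, method = "BFGS")
    eta <- as.numeric(cbind(1, X) %*% opt$par)
    dev <- 2 * sum(log1p(exp(-(2 * y01 - 1) * eta)))
  }
  list(deviance = dev, separation = sep || !fit$converged)
}

#' Likelihood-ratio test for the added value of extra features
#'
#' Fits maximum-likelihood logistic regressions with the base features alone
#' and with the base plus added features, and compares deviances:
#' `Ddeviance = deviance_base - deviance_full`, referred to the chi-squared
#' distribution with df = number of added features. Separation-induced
#' non-convergence is flagged and handled with a lightly penalized fit.
#'
#' @param base_features data.frame/matrix of the base model's features.
#' @param added_features data.frame/matrix of the candidate extra features.
#' @param labels Two-class labels (positive = second level).
#' @return List of class `modality_comparison`: `deviance_base`,
#'   `deviance_full`, `delta_deviance`, `df`, `p`, `separation_flag`.
#' @export
lrt_modality <- function(base_features, added_features, labels) {
  Xb <- as.matrix(as.data.frame(base_features))
  Xa <- as.matrix(as.data.frame(added_features))
  y <- factor(labels)
  if (nlevels(y) != 2) stop_arg("labels must have exactly two classes")
  y01 <- as.numeric(y == levels(y)[2])
  base <- .logistic_deviance(Xb, y01)
  full <- .logistic_deviance(cbind(Xb, Xa), y01)
  dd <- max(0, base$deviance - full$deviance)
  df <- ncol(Xa)
  structure(list(deviance_base = base$deviance,
                 deviance_full = full$deviance, delta_deviance = dd, df = df,
                 p = stats::pchisq(dd, df, lower.tail = FALSE),
                 separation_flag = base$separation || full$separation),
            class = "modality_comparison")
}

#' @export
print.modality_comparison <- function(x, ...) {
  cat(sprintf("<modality_comparison> delta deviance = %.3f, df = %d, p = %.4g%s\n",
              x$delta_deviance, x$df, x$p,
              if (x$separation_flag) " (penalized fallback used)" else ""))
  invisible(x)
}
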