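# Classifier fitting and full evaluation: ROC/AUC, calibration +
# Hosmer-Lemeshow, decision-curve analysis, stratified cross-validation.

#' Classifier specification
#'
#' @param algorithm one of `"logistic_regression"`, `"random_forest"`,
#'   `"extra_trees"`, `"xgboost"`.
#' @param params named list of hyperparameter overrides (library defaults
#'   otherwise).
#' @param seed RNG seed pinning the fit.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("logistic_regression", "random_forest",
                                     "extra_trees", "xgboost"),
                       params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, params = params,
                 seed = as.integer(seed)), class = "model_spec")
}

as_binary <- function(y) {
  if (is.factor(y) || is.character(y)) {
    lv <- sort(unique(as.character(y)))
    if (length(lv) > 2L) stop("y must be binary")
    y <- as.integer(as.character(y) == lv[length(lv)])
  }
  as.integer(y)
}

#' Fit a classifier and return probability scores
#'
#' Fits the specified model on the training data and returns predicted
#' class-1 probabilities on the evaluation rows. Deterministic under the
#' spec's seed (tree methods are seeded, xgboost runs single-threaded).
#'
#' @param spec a [model_spec()].
#' @param X_train,X_eval numeric matrices with identical columns.
#' @param y_train binary training outcome.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
fit_predict <- function(spec, X_train, y_train, X_eval) {
  stopifnot(inherits(spec, "model_spec"))
  X_train <- as.matrix(X_train); X_eval <- as.matrix(X_eval)
  if (!identical(colnames(X_train), colnames(X_eval))) {
    stop("train and eval columns must be identical")
  }
  if (anyNA(X_train) || anyNA(X_eval)) stop("missing values in features")
  y <- as_binary(y_train)
  if (length(unique(y)) < 2L) stop("single-class y_train")
  p <- spec$params
  set.seed(spec$seed)
  scores <- switch(spec$algorithm,
    logistic_regression = {
      df <- as.data.frame(X_train)
      names(df) <- paste0("f", seq_len(ncol(X_train)))
      df$.y <- y
      fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      de <- as.data.frame(X_eval)
      names(de) <- paste0("f", seq_len(ncol(X_eval)))
      unname(predict(fit, de, type = "response"))
    },
    random_forest = {
      df <- data.frame(X_train)
      df$.y <- factor(y, levels = c(0, 1))
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df, probability = TRUE,
        num.trees = p$num.trees %||% 500L, seed = spec$seed,
        num.threads = 1L)
      predict(fit, data.frame(X_eval), num.threads = 1L)$predictions[, "1"]
    },
    extra_trees = {
      df <- data.frame(X_train)
      df$.y <- factor(y, levels = c(0, 1))
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df, probability = TRUE,
        num.trees = p$num.trees %||% 500L, splitrule = "extratrees",
        seed = spec$seed, num.threads = 1L)
      predict(fit, data.frame(X_eval), num.threads = 1L)$predictions[, "1"]
    },
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(X_train, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = p$max_depth %||% 3L,
                      eta = p$eta %||% 0.1, nthread = 1L,
                      seed = spec$seed),
        data = dtr, nrounds = p$nrounds %||% 100L, verbose = 0)
      predict(fit, xgboost::xgb.DMatrix(X_eval))
    })
  pmin(pmax(as.numeric(scores), 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROC AUC with optional bootstrap CI
#'
#' AUC computed as the Mann-Whitney probability that a random positive
#' outranks a random negative, ties counted one half (midranks).
#'
#' @param scores predicted probabilities or risk scores.
#' @param labels binary labels.
#' @param ci compute a percentile bootstrap CI?
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return `list(auc = , ci = )`; `ci` is `NULL` unless requested.
#' @export
roc_auc <- function(scores, labels, ci = FALSE, n_boot = 500L, conf = 0.95,
                    seed = 1L) {
  y <- as_binary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  auc_of <- function(s, yy) {
    r <- rank(s, ties.method = "average")
    (sum(r[yy == 1]) - sum(yy == 1) * (sum(yy == 1) + 1) / 2) /
      (sum(yy == 1) * sum(yy == 0))
  }
  a <- auc_of(scores, y)
  ci_out <- NULL
  if (ci) {
    set.seed(seed)
    bs <- replicate(n_boot, {
      i <- sample(length(y), replace = TRUE)
      if (length(unique(y[i])) < 2L) return(NA_real_)
      auc_of(scores[i], y[i])
    })
    ci_out <- unname(quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                              na.rm = TRUE))
  }
  list(auc = a, ci = ci_out)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return `data.frame(threshold = , fpr = , tpr = )` over all observed
#'   score cutpoints.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[y == 0] >= t), 0),
    tpr = vapply(th, function(t) mean(scores[y == 1] >= t), 0))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk binning; within each bin g with n_g subjects, observed
#' events O_g and expected E_g, the statistic sums
#' (O_g - E_g)^2 / (E_g (1 - E_g / n_g)), with df = bins - 2. Bins whose
#' expected count degenerates are merged into their neighbor (df adjusted,
#' logged).
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels binary outcomes.
#' @param n_bins number of risk bins (default 10).
#' @return `list(statistic = , df = , p = , bins = )` where `bins` tabulates
#'   n, observed and expected per bin (the calibration-curve points).
#' @export
hosmer_lemeshow <- function(probs, labels, n_bins = 10L) {
  y <- as_binary(labels)
  n <- length(y)
  stopifnot(length(probs) == n, n >= n_bins)
  br <- unique(quantile(probs, seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3L) br <- c(min(probs) - 1e-9, mean(range(probs)),
                               max(probs) + 1e-9)
  bin <- cut(probs, br, include.lowest = TRUE, labels = FALSE)
  tab <- data.frame(
    n = as.vector(tapply(y, bin, length)),
    obs = as.vector(tapply(y, bin, sum)),
    exp = as.vector(tapply(probs, bin, sum)),
    mean_pred = as.vector(tapply(probs, bin, mean)))
  # merge degenerate bins (expected 0 or n) into the previous one
  degen <- which(tab$exp <= 1e-12 | tab$exp >= tab$n - 1e-12)
  if (length(degen)) {
    message("hosmer_lemeshow: merging ", length(degen), " degenerate bin(s)")
    for (i in rev(degen)) {
      j <- if (i > 1) i - 1 else i + 1
      if (j > nrow(tab)) next
      tab$n[j] <- tab$n[j] + tab$n[i]
      tab$obs[j] <- tab$obs[j] + tab$obs[i]
      tab$exp[j] <- tab$exp[j] + tab$exp[i]
      tab <- tab[-i, , drop = FALSE]
    }
    tab$mean_pred <- tab$exp / tab$n
  }
  g <- nrow(tab)
  stat <- sum((tab$obs - tab$exp)^2 / (tab$exp * (1 - tab$exp / tab$n)))
  df <- max(1L, g - 2L)
  tab$obs_rate <- tab$obs / tab$n
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE), bins = tab)
}

#' Decision curve analysis
#'
#' Net benefit of acting on the model at threshold probability p_t:
#' NB(p_t) = TP/n - (FP/n) p_t / (1 - p_t), with treat-all and treat-none
#' (identically zero) reference policies.
#'
#' @param probs predicted probabilities.
#' @param labels binary outcomes.
#' @param thresholds threshold grid in (0, 1); default 0.01 to 0.99 by 0.01.
#' @return `data.frame(threshold = , net_benefit = , treat_all = ,
#'   treat_none = )`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  y <- as_binary(labels)
  n <- length(y)
  stopifnot(all(thresholds > 0 & thresholds < 1))
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    pos <- probs >= pt
    tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
    tp / n - (fp / n) * pt / (1 - pt)
  }, 0)
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, net_benefit = nb, treat_all = ta,
             treat_none = 0)
}

#' Full evaluation report for one score vector
#'
#' Bundles AUC (with bootstrap CI), ROC points, calibration bins with the
#' Hosmer-Lemeshow test, the decision curve, and the 0.5-threshold confusion
#' counts.
#'
#' @inheritParams roc_auc
#' @param tag dataset tag (e.g. `"test"`, `"fold_3"`).
#' @param algorithm optional model name carried into the report.
#' @return An object of class `eval_report`.
#' @export
evaluate_scores <- function(scores, labels, tag = "test", algorithm = NA,
                            seed = 1L) {
  y <- as_binary(labels)
  ra <- roc_auc(scores, y, ci = TRUE, seed = seed)
  hl <- if (length(y) >= 10L) hosmer_lemeshow(pmin(pmax(scores, 1e-9),
                                                   1 - 1e-9), y) else NULL
  pos <- scores >= 0.5
  conf <- c(tp = sum(pos & y == 1), fp = sum(pos & y == 0),
            fn = sum(!pos & y == 1), tn = sum(!pos & y == 0))
  structure(list(tag = tag, algorithm = algorithm, auc = ra$auc,
                 auc_ci = ra$ci, roc = roc_points(scores, y),
                 hosmer_lemeshow = hl,
                 dca = decision_curve(scores, y), confusion = conf,
                 n = length(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s%s  AUC %.3f", x$tag,
              if (!is.na(x$algorithm)) paste0(" [", x$algorithm, "]") else "",
              x$auc))
  if (!is.null(x$auc_ci)) {
    cat(sprintf(" (%.3f-%.3f)", x$auc_ci[1], x$auc_ci[2]))
  }
  if (!is.null(x$hosmer_lemeshow)) {
    cat(sprintf("  HL p = %.3f", x$hosmer_lemeshow$p))
  }
  cat("\n")
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Stratified folds, one [evaluate_scores()] report per held-out fold, and
#' the mean and sd of the fold AUCs — the model-stability check.
#'
#' @param spec a [model_spec()].
#' @param X feature matrix.
#' @param y binary outcome.
#' @param n_folds folds (default 5).
#' @param seed fold-assignment seed.
#' @return `list(folds = , auc_mean = , auc_sd = , fold_auc = )`.
#' @export
crossvalidate <- function(spec, X, y, n_folds = 5L, seed = 1L) {
  y <- as_binary(y)
  X <- as.matrix(X)
  if (min(table(y)) < n_folds && n_folds < length(y)) {
    stop("stratification impossible: a class has fewer members than folds")
  }
  fold <- if (n_folds >= length(y)) seq_along(y) else
    stratified_folds(y, n_folds, seed)
  reports <- list()
  pooled <- numeric(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) stop("single-class training fold")
    sc <- fit_predict(spec, X[tr, , drop = FALSE], y[tr],
                      X[!tr, , drop = FALSE])
    pooled[!tr] <- sc
    reports[[f]] <- if (length(unique(y[!tr])) == 2L) {
      evaluate_scores(sc, y[!tr], tag = paste0("fold_", f),
                      algorithm = spec$algorithm)
    } else {
      structure(list(tag = paste0("fold_", f), algorithm = spec$algorithm,
                     auc = NA_real_, n = sum(!tr)), class = "eval_report")
    }
  }
  aucs <- vapply(reports, `[[`, 0, "auc")
  auc_pooled <- roc_auc(pooled, y)$auc
  # single-observation folds (LOO) carry no per-fold AUC; fall back to the
  # AUC of the pooled out-of-fold predictions
  auc_mean <- if (all(is.na(aucs))) auc_pooled else mean(aucs, na.rm = TRUE)
  list(folds = reports, auc_mean = auc_mean,
       auc_sd = sd(aucs[!is.na(aucs)]), fold_auc = aucs,
       auc_pooled = auc_pooled)
}

#' Rank models by evaluation AUC
#'
#' @param reports list of `eval_report`s on the same evaluation split.
#' @return `data.frame` sorted by AUC (descending; ties by algorithm name),
#'   with the best model flagged.
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 2L)
  df <- data.frame(
    algorithm = vapply(reports, function(r) as.character(r$algorithm), ""),
    tag = vapply(reports, function(r) as.character(r$tag), ""),
    auc = vapply(reports, `[[`, 0, "auc"))
  df <- df[order(-df$auc, df$algorithm), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$best <- df$rank == 1L
  rownames(df) <- NULL
  df
}
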