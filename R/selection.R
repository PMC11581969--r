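# Staged feature reduction: ICC robustness, distribution screen, Pearson
# pruning, and L1-penalized (LASSO) selection with 10-fold cross-validation.

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' standard variance decomposition, the usual robustness measure for
#' radiomic features under re-segmentation (test-retest) or between raters.
#'
#' @param ratings numeric matrix, subjects x raters/occasions (complete
#'   layout, >= 2 subjects, >= 2 raters).
#' @return ICC value in \[-1, 1\], or `NA` (with a warning) when the total
#'   variance is zero and the ICC is undefined.
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  if (anyNA(ratings)) stop("complete two-way layout required")
  if (var(as.vector(ratings)) == 0) {
    warning("zero total variance; ICC undefined")
    return(NA_real_)
  }
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' ICC robustness filter
#'
#' A feature survives iff its ICC is at least `threshold` in every supplied
#' design (e.g. both test-retest and inter-rater); undefined ICCs fail.
#'
#' @param designs named list of designs; each design is a list of two
#'   subjects-x-features matrices (the two occasions/raters) with identical
#'   column names.
#' @param threshold robustness cutoff (default 0.85).
#' @return `list(survivors = , icc = )` where `icc` is a feature x design
#'   matrix of ICC values.
#' @export
icc_filter <- function(designs, threshold = 0.85) {
  stopifnot(length(designs) >= 1L)
  feats <- colnames(designs[[1]][[1]])
  vals <- sapply(designs, function(d) {
    stopifnot(identical(colnames(d[[1]]), feats),
              identical(colnames(d[[2]]), feats))
    vapply(feats, function(f) {
      suppressWarnings(icc(cbind(d[[1]][, f], d[[2]][, f])))
    }, 0)
  })
  vals <- matrix(vals, nrow = length(feats),
                 dimnames = list(feats, names(designs)))
  minv <- apply(vals, 1, function(x) if (anyNA(x)) NA_real_ else min(x))
  survivors <- feats[!is.na(minv) & minv >= threshold]
  list(survivors = survivors, icc = vals)
}

#' Distribution screen
#'
#' Parametric-suitability screen applied per feature. The default method is a
#' Shapiro-Wilk normality test (a feature survives when p >= alpha); the
#' alternative `"t_fit"` method fits a location-scale Student-t by maximum
#' likelihood and keeps features a Kolmogorov-Smirnov test does not reject.
#' Constant (degenerate) features always fail and are logged.
#'
#' @param table patients x features numeric matrix.
#' @param alpha screen level (default 0.05); `alpha = 0` keeps every
#'   non-degenerate feature.
#' @param method `"normality"` or `"t_fit"`.
#' @return `list(survivors = , p_values = )`.
#' @export
distribution_filter <- function(table, alpha = 0.05,
                                method = c("normality", "t_fit")) {
  method <- match.arg(method)
  stopifnot(nrow(table) >= 8L)
  pv <- vapply(colnames(table), function(f) {
    x <- table[, f]
    if (sd(x) == 0) return(NA_real_)
    if (method == "normality") {
      shapiro.test(x)$p.value
    } else {
      # location-scale Student-t ML fit (own optimizer: the df -> Inf
      # boundary makes Hessian-based fitters fail on near-normal data)
      z <- scale(x)[, 1]
      nll <- function(par) {
        m <- par[1]; s <- exp(par[2]); df <- min(exp(par[3]), 1e6)
        -sum(stats::dt((z - m) / s, df, log = TRUE) - log(s))
      }
      fit <- tryCatch(
        stats::optim(c(0, 0, log(5)), nll, method = "Nelder-Mead",
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      m <- fit$par[1]; s <- exp(fit$par[2]); df <- min(exp(fit$par[3]), 1e6)
      suppressWarnings(stats::ks.test((z - m) / s, "pt", df)$p.value)
    }
  }, 0)
  degen <- names(pv)[is.na(pv)]
  if (length(degen)) {
    message("distribution_filter: degenerate feature(s) removed: ",
            paste(head(degen, 5), collapse = ", "),
            if (length(degen) > 5) " ..." else "")
  }
  list(survivors = colnames(table)[!is.na(pv) & pv >= alpha], p_values = pv)
}

#' Pearson correlation pruning
#'
#' While any surviving pair exceeds `|r| > r_threshold`, the member of the
#' most correlated pair with the larger mean absolute correlation to all
#' other survivors is dropped (ties broken by lexicographic feature name).
#' No surviving pair exceeds the threshold on return.
#'
#' @param table patients x features numeric matrix (>= 3 rows).
#' @param r_threshold absolute-correlation threshold (default 0.9).
#' @return `list(survivors = , dropped = )`; `dropped` records each removed
#'   feature with the |r| that triggered it.
#' @export
pearson_prune <- function(table, r_threshold = 0.9) {
  stopifnot(nrow(table) >= 3L)
  feats <- colnames(table)
  cm <- suppressWarnings(abs(cor(table)))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  alive <- setNames(rep(TRUE, length(feats)), feats)
  dropped <- data.frame(feature = character(), r = numeric())
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    if (max(sub) <= r_threshold) break
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- c(rownames(sub)[w[1]], colnames(sub)[w[2]])
    mac <- rowMeans(sub[pair, , drop = FALSE])
    victim <- if (abs(mac[1] - mac[2]) > 1e-12) {
      pair[which.max(mac)]
    } else sort(pair)[2]
    alive[victim] <- FALSE
    dropped <- rbind(dropped, data.frame(feature = victim, r = max(sub)))
  }
  list(survivors = feats[alive], dropped = dropped)
}

#' LASSO selection with cross-validated lambda
#'
#' L1-penalized logistic regression along a log-spaced lambda grid;
#' 10-fold cross-validation chooses the lambda with the lowest mean CV error
#' (binomial deviance), and the nonzero-coefficient features at that lambda
#' are the selected signature. `rule = "1se"` selects the sparsest lambda
#' within one standard error of the minimum instead.
#'
#' @param X numeric matrix (rows = patients); standardized internally.
#' @param y binary outcome coded 0/1 (or a two-level factor).
#' @param n_folds CV folds (default 10).
#' @param lambda optional lambda grid; defaults to glmnet's.
#' @param seed RNG seed for the fold assignment.
#' @param rule `"min"` or `"1se"`.
#' @return `list(selected = , coefficients = , lambda = , lambda_grid = ,
#'   cv_mean = , cv_sd = )`.
#' @export
lasso_select <- function(X, y, n_folds = 10L, lambda = NULL, seed = 1L,
                         rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) y <- as.integer(as.factor(y)) - 1L
  stopifnot(all(y %in% c(0, 1)))
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) stop("all features are constant; nothing to select")
  X <- X[, sds > 0, drop = FALSE]
  Xs <- scale(X)
  foldid <- stratified_folds(y, n_folds, seed)
  cv <- glmnet::cv.glmnet(Xs, y, family = "binomial", lambda = lambda,
                          foldid = foldid, standardize = FALSE)
  lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  co <- coef(cv, s = lam)
  nz <- which(co[-1, 1] != 0)
  list(selected = rownames(co)[-1][nz],
       coefficients = setNames(co[-1, 1][nz], rownames(co)[-1][nz]),
       lambda = lam, lambda_grid = cv$lambda,
       cv_mean = cv$cvm, cv_sd = cv$cvsd)
}

#' Staged feature selection
#'
#' Runs the staged reduction — optional ICC robustness filter, distribution
#' screen, Pearson pruning, LASSO — and returns a selection report whose
#' per-stage survivor sets are strictly nested. The ICC stage runs only when
#' re-segmentation designs are supplied (habitat signatures conventionally
#' skip it).
#'
#' @param table patients x features matrix.
#' @param y binary outcome aligned with rows.
#' @param icc_designs optional designs for [icc_filter()].
#' @param icc_threshold,alpha,r_threshold,n_folds,seed,rule stage parameters.
#' @param use_distribution_filter set `FALSE` to disable the screen.
#' @param dist_method distribution-screen method; the staged pipeline
#'   defaults to the Student-t fit (`"t_fit"`), which tolerates the
#'   heavy-tailed and class-mixed features informative signatures rely on
#'   while still rejecting degenerate ones; `"normality"` applies the
#'   stricter Shapiro-Wilk screen.
#' @return An object of class `selection_report`: per-stage survivors,
#'   statistics, and the LASSO path with the chosen lambda.
#' @export
select_features <- function(table, y, icc_designs = NULL,
                            icc_threshold = 0.85, alpha = 0.05,
                            use_distribution_filter = TRUE,
                            dist_method = "t_fit",
                            r_threshold = 0.9, n_folds = 10L, seed = 1L,
                            rule = "min") {
  stages <- list(input = colnames(table))
  tab <- table
  icc_res <- NULL
  if (!is.null(icc_designs)) {
    icc_res <- icc_filter(icc_designs, icc_threshold)
    keep <- intersect(colnames(tab), icc_res$survivors)
    tab <- tab[, keep, drop = FALSE]
    stages$icc <- keep
  }
  dist_res <- NULL
  if (use_distribution_filter) {
    dist_res <- distribution_filter(tab, alpha, method = dist_method)
    tab <- tab[, dist_res$survivors, drop = FALSE]
    stages$distribution <- dist_res$survivors
  }
  pr <- pearson_prune(tab, r_threshold)
  tab <- tab[, pr$survivors, drop = FALSE]
  stages$pearson <- pr$survivors
  if (ncol(tab) == 0L) stop("no features survive the screening stages")
  la <- lasso_select(tab, y, n_folds = n_folds, seed = seed, rule = rule)
  stages$lasso <- la$selected
  structure(list(stages = stages, icc = icc_res, distribution = dist_res,
                 pearson = pr, lasso = la),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %-12s %d features\n", s, length(x$stages[[s]])))
  }
  if (!is.null(x$lasso)) {
    cat(sprintf("  lambda = %.5g\n", x$lasso$lambda))
  }
  invisible(x)
}
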