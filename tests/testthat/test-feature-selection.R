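# ICC, distribution screen, Pearson pruning, LASSO, and stage nesting.

test_that("icc equals a direct ANOVA mean-squares oracle on a 6x2 table", {
  ratings <- cbind(c(9, 2, 5, 8, 6, 7), c(2, 1, 8, 6, 5, 7))
  # oracle: hand-expanded two-way ANOVA sums of squares
  n <- 6; k <- 2
  grand <- mean(ratings)
  msr <- k * sum((rowMeans(ratings) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(ratings) - grand)^2) / (k - 1)
  mse <- (sum((ratings - grand)^2) - (n - 1) * msr - (k - 1) * msc) /
    ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc(ratings), oracle, tolerance = 1e-9)
})

test_that("icc is 1 for perfect agreement, ~0 under permutation, NA when
           degenerate", {
  x <- rnorm(30)
  expect_equal(icc(cbind(x, x)), 1, tolerance = 1e-12)
  set.seed(4)
  y <- rnorm(1000)
  expect_lt(abs(icc(cbind(y, sample(y)))), 0.1)
  expect_warning(v <- icc(cbind(rep(1, 5), rep(1, 5))), "undefined")
  expect_true(is.na(v))
})

test_that("icc_filter applies the min rule across designs and is monotone", {
  set.seed(7)
  n <- 30
  base <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  # a: near-perfect both designs; b: good retest, poor inter-rater; c: noise
  retest <- list(base, base + cbind(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05),
                                    rnorm(n, 0, 2)))
  inter <- list(base, base + cbind(rnorm(n, 0, 0.05), rnorm(n, 0, 1.5),
                                   rnorm(n, 0, 2)))
  res <- icc_filter(list(retest = retest, interrater = inter), 0.85)
  expect_identical(res$survivors, "a")
  expect_lt(min(res$icc["b", ]), 0.85)   # min rule removed b
  # vacuous threshold keeps everything; raising it never adds survivors
  all_surv <- icc_filter(list(retest = retest, interrater = inter), -1)
  expect_setequal(all_surv$survivors, c("a", "b", "c"))
  for (th in c(0, 0.5, 0.9, 0.99)) {
    s <- icc_filter(list(retest = retest, interrater = inter), th)$survivors
    expect_true(all(s %in% all_surv$survivors))
    all_surv$survivors <- s
  }
})

test_that("distribution screen: type-I close to alpha, high power on
           log-normal, alpha = 0 keeps non-degenerate features", {
  set.seed(11)
  reps <- 500
  normal_pass <- logical(reps)
  skew_fail <- logical(reps)
  for (i in seq_len(reps)) {
    tab <- cbind(g = rnorm(100), s = exp(rnorm(100)))
    out <- distribution_filter(tab, alpha = 0.05)
    normal_pass[i] <- "g" %in% out$survivors
    skew_fail[i] <- !("s" %in% out$survivors)
  }
  expect_lt(abs(mean(normal_pass) - 0.95), 0.03)
  expect_gte(mean(skew_fail), 0.95)
  tab <- cbind(a = rnorm(20), b = exp(rnorm(20)), k = rep(1, 20))
  out0 <- suppressMessages(distribution_filter(tab, alpha = 0))
  expect_setequal(out0$survivors, c("a", "b"))   # constant feature fails
})

test_that("the t-fit screen retains class-mixture features that the
           normality screen deletes", {
  kept <- t(vapply(1:10, function(s) {
    set.seed(s * 7)
    n <- 100
    mix <- c(rnorm(n / 2, -1.5), rnorm(n / 2, 1.5))   # two-class mixture
    tab <- cbind(mix = mix, flat = rep(1, n), g = rnorm(n))
    nrm <- suppressMessages(distribution_filter(tab, method = "normality"))
    tft <- suppressMessages(distribution_filter(tab, method = "t_fit"))
    c(norm = "mix" %in% nrm$survivors, tfit = "mix" %in% tft$survivors,
      flat = "flat" %in% tft$survivors, g = "g" %in% tft$survivors)
  }, logical(4)))
  expect_gte(sum(kept[, "tfit"]), 9L)     # t fit tolerates the mixture
  expect_lte(sum(kept[, "norm"]), 6L)     # normality screen mostly deletes it
  expect_equal(sum(kept[, "flat"]), 0L)   # degenerate features always fail
  expect_gte(sum(kept[, "g"]), 9L)        # well-behaved features survive
})

test_that("pearson_prune drops duplicates, keeps orthogonal sets, matches a
           brute-force oracle", {
  set.seed(5)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  dup <- cbind(x, a2 = x[, "a"])
  res <- pearson_prune(dup, 0.9)
  expect_equal(sum(c("a", "a2") %in% res$survivors), 1L)
  # mutually orthogonal features all survive
  q <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  colnames(q) <- paste0("f", 1:5)
  expect_setequal(pearson_prune(q, 0.9)$survivors, colnames(q))
  # known correlation structure vs an independent re-implementation
  set.seed(6)
  z <- rnorm(60)
  tab <- cbind(a = z, b = z + rnorm(60, 0, 0.1), c = z + rnorm(60, 0, 0.12),
               d = rnorm(60), e = rnorm(60))
  oracle_prune <- function(m, thr) {
    alive <- colnames(m)
    repeat {
      cm <- abs(cor(m[, alive, drop = FALSE])); diag(cm) <- 0
      if (max(cm) <= thr) break
      w <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- c(rownames(cm)[w[1]], colnames(cm)[w[2]])
      mac <- rowMeans(cm[pair, , drop = FALSE])
      victim <- if (abs(diff(mac)) > 1e-12) pair[which.max(mac)] else
        sort(pair)[2]
      alive <- setdiff(alive, victim)
    }
    alive
  }
  expect_setequal(pearson_prune(tab, 0.8)$survivors, oracle_prune(tab, 0.8))
  # no surviving pair exceeds the threshold
  surv <- pearson_prune(tab, 0.8)$survivors
  cm <- abs(cor(tab[, surv])); diag(cm) <- 0
  expect_lte(max(cm), 0.8)
})

test_that("lasso_select finds an exact linear signal and shrinks to zero at
           large lambda", {
  set.seed(8)
  X <- matrix(rnorm(120 * 10), 120, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.integer(X[, 1] > 0)   # y depends on feature 1 only
  res <- lasso_select(X, y, seed = 1)
  expect_true("f1" %in% res$selected)
  expect_gt(res$coefficients["f1"], 0)
  expect_true(res$lambda %in% res$lambda_grid)
  # at the top of the grid (strongest penalty) nothing is selected
  fit <- glmnet::glmnet(scale(X), y, family = "binomial",
                        lambda = max(res$lambda_grid) * 2)
  expect_equal(sum(coef(fit)[-1] != 0), 0)
  expect_error(lasso_select(matrix(1, 20, 3), rep(0:1, 10)), "constant")
})

test_that("lasso CV curve and chosen lambda are reproducible and invariant
           to feature order", {
  set.seed(12)
  X <- matrix(rnorm(100 * 20), 100, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  y <- rbinom(100, 1, plogis(X[, 3] - X[, 7]))
  r1 <- lasso_select(X, y, seed = 5)
  r2 <- lasso_select(X, y, seed = 5)
  expect_equal(r1$lambda, r2$lambda)
  expect_equal(r1$cv_mean, r2$cv_mean)
  perm <- sample(ncol(X))
  r3 <- lasso_select(X[, perm], y, seed = 5)
  expect_equal(r3$lambda, r1$lambda, tolerance = 1e-10)
  expect_setequal(r3$selected, r1$selected)
})

test_that("staged selection produces strictly nested survivor sets", {
  set.seed(13)
  n <- 60
  z <- rnorm(n)
  tab <- cbind(sig = z + rnorm(n, 0, 0.5), dup = z + rnorm(n, 0, 0.05),
               skewed = exp(rnorm(n)),
               matrix(rnorm(n * 6), n, 6,
                      dimnames = list(NULL, paste0("n", 1:6))))
  colnames(tab)[1:3] <- c("sig", "dup", "skewed")
  y <- as.integer(z + rnorm(n, 0, 0.8) > 0)
  rep <- suppressMessages(select_features(tab, y, n_folds = 5, seed = 2,
                                          dist_method = "normality"))
  st <- rep$stages
  for (i in seq_len(length(st) - 1)) {
    expect_true(all(st[[i + 1]] %in% st[[i]]))
  }
  expect_true("skewed" %in% setdiff(st$input, st$distribution))
})
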