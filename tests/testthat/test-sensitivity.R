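test_that("drop_missing_drugs applies the strict 20% rule", {
  m <- matrix(runif(100 * 3, 12, 40), 100, 3,
              dimnames = list(sprintf("L%03d", 1:100), c("d21", "d20", "d0")))
  m[1:21, "d21"] <- NA   # 21% missing: dropped
  m[1:20, "d20"] <- NA   # exactly 20%: kept
  out <- drop_missing_drugs(m, 0.20)
  expect_equal(colnames(out), c("d20", "d0"))
  full <- matrix(1, 4, 2, dimnames = list(letters[1:4], c("a", "b")))
  expect_equal(drop_missing_drugs(full, 0.2), full)
})

test_that("knn_impute fills from nearest neighbours and clamps to range", {
  # two identical rows; the twin's value fills the gap at k = 1
  m <- rbind(L1 = c(1, 2, 3, 4), L2 = c(1, 2, 3, NA), L3 = c(30, 40, 50, 60))
  colnames(m) <- paste0("d", 1:4)
  out <- knn_impute(m, k = 1)
  expect_equal(out["L2", "d4"], 4)
  expect_false(anyNA(out))
  # complete matrix returned unchanged
  expect_equal(knn_impute(out, k = 2), out)
  # imputed values stay inside the drug's observed range
  set.seed(61)
  big <- matrix(runif(20 * 6, 1, 100), 20, 6,
                dimnames = list(sprintf("L%02d", 1:20), paste0("d", 1:6)))
  holes <- big; holes[sample(length(holes), 15)] <- NA
  filled <- knn_impute(holes, k = 5)
  for (j in seq_len(ncol(big))) {
    rng <- range(holes[, j], na.rm = TRUE)
    expect_true(all(filled[, j] >= rng[1] & filled[, j] <= rng[2]))
  }
  # a drug nobody observes cannot be imputed
  none <- m; none[, 2] <- NA
  expect_error(knn_impute(none, k = 1), "observes")
})

test_that("knn imputation beats column-mean imputation on rank-1 matrices", {
  set.seed(67)
  wins <- replicate(100, {
    row_eff <- runif(25, 0.5, 2)
    col_eff <- runif(12, 5, 50)
    truth <- outer(row_eff, col_eff)
    dimnames(truth) <- list(sprintf("L%02d", 1:25), sprintf("d%02d", 1:12))
    holes <- truth
    idx <- sample(length(truth), round(0.1 * length(truth)))
    holes[idx] <- NA
    knn <- knn_impute(holes, k = 5)
    colmean <- holes
    for (j in seq_len(ncol(holes))) {
      mu <- mean(holes[, j], na.rm = TRUE)
      colmean[is.na(colmean[, j]), j] <- mu
    }
    rmse <- function(est) sqrt(mean((est[idx] - truth[idx])^2))
    rmse(knn) < rmse(colmean)
  })
  expect_gte(sum(wins), 95)
})

test_that("ridge_fit equals OLS at lambda 0 and shrinks to the mean", {
  set.seed(71)
  X <- matrix(rnorm(5 * 2), 5, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(5)
  fit0 <- ridge_fit(X, y, lambda = 0)
  ols <- lm(y ~ X)
  expect_equal(unname(fit0$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-8)
  expect_equal(fit0$intercept, unname(coef(ols)[1]), tolerance = 1e-8)

  big <- ridge_fit(X, y, lambda = 1e12)
  expect_equal(unname(big$coefficients), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(predict(big, X)), rep(mean(y), 5), tolerance = 1e-4)

  const <- ridge_fit(X, rep(2, 5))
  expect_equal(unname(const$coefficients), c(0, 0))
  expect_equal(const$intercept, 2)
  expect_error(ridge_fit(X, y, lambda = -1), ">= 0")
})

test_that("GCV ridge recovers coefficients in a dense simulation", {
  set.seed(73)
  n <- 200; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, 0, 0.1)
  fit <- ridge_fit(X, y)
  err <- sqrt(sum((fit$coefficients - beta)^2)) / sqrt(sum(beta^2))
  expect_lt(err, 0.1)
  # prediction invariant to feature reordering
  perm <- sample(p)
  fit2 <- ridge_fit(X[, perm], y)
  expect_equal(predict(fit2, X[1:5, perm]), predict(fit, X[1:5, ]),
               tolerance = 1e-6)
})

test_that("predict_sensitivity works on the log scale and back-transforms", {
  set.seed(79)
  genes <- 6; train <- 40
  expr <- matrix(rnorm(genes * train), genes, train,
                 dimnames = list(paste0("g", 1:genes), NULL))
  beta <- rnorm(genes, 0, 0.5)
  ic50 <- exp(1.5 + drop(t(expr) %*% beta) + rnorm(train, 0, 0.05))
  pred <- predict_sensitivity(expr, ic50, expr)
  expect_true(all(pred > 0))
  expect_lt(sqrt(mean((log(pred) - log(ic50))^2)), 0.2)
  expect_error(predict_sensitivity(expr, c(-1, ic50[-1]), expr), "positive")
})

test_that("sensitive_drugs enforces the strict 10 uM rule and co-occurrence", {
  p1 <- cbind(navitoclax = rep(7.65, 4), borderline = rep(10, 4),
              only1 = rep(5, 4), high = rep(40, 4))
  p2 <- cbind(navitoclax = rep(7.65, 4), borderline = rep(9, 4),
              only1 = rep(50, 4), high = rep(40, 4))
  out <- sensitive_drugs(list(screen1 = p1, screen2 = p2), threshold_um = 10)
  expect_equal(as.character(out), "navitoclax")
  per <- attr(out, "per_screen")
  expect_equal(per$screen1, c("navitoclax", "only1"))  # 10 exactly excluded
  expect_equal(per$screen2, c("borderline", "navitoclax"))
  expect_error(sensitive_drugs(list(p1), 10), "two screens")
  # monotone: lowering the threshold never adds drugs
  lower <- sensitive_drugs(list(screen1 = p1, screen2 = p2), threshold_um = 5)
  expect_true(all(lower %in% out))
})

test_that("compare_groups matches the exact permutation distribution", {
  same <- c(1.2, 3.4, 5.6, 7.8)
  out <- compare_groups(same, same)
  expect_gt(out$p, 0.99)

  set.seed(83)
  a <- rnorm(6); b <- rnorm(6, 1)
  got <- compare_groups(a, b)
  expect_equal(got$p, wilcox_perm_oracle(a, b), tolerance = 1e-12)

  sep <- compare_groups(1:10, 101:110)
  expect_equal(sep$p, wilcox_perm_oracle(1:10, 101:110), tolerance = 1e-12)
  expect_error(compare_groups(1:2, 1:5), "3")
})

test_that("compare_groups has power against a 2-sigma shift", {
  set.seed(89)
  rejections <- replicate(200, {
    a <- rnorm(20, 0, 1); b <- rnorm(20, 2, 1)
    compare_groups(a, b)$p < 0.05
  })
  expect_gt(mean(rejections), 0.9)
})
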