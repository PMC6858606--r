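test_that("upsampling balances classes without touching majority rows", {
  set.seed(60)
  X <- matrix(rnorm(144 * 3), 144, 3)
  y <- rep(c("normal", "tumor"), c(9, 135))
  up <- upsample_balance(X, y, seed = 1)
  expect_equal(as.vector(table(up$y)), c(135L, 135L))
  # every majority row appears exactly once
  maj <- X[y == "tumor", 1]
  expect_true(all(sort(up$X[up$y == "tumor", 1]) == sort(maj)))
  # minority rows are drawn from the original minority pool
  expect_true(all(up$X[up$y == "normal", 1] %in% X[y == "normal", 1]))
  # (1, 4) case
  up2 <- upsample_balance(X[1:5, ], rep(c("a", "b"), c(1, 4)), seed = 2)
  expect_equal(as.vector(table(up2$y)), c(4L, 4L))
  expect_error(upsample_balance(X, rep("a", 144)), "two classes")
  # already balanced: identity up to shuffle
  up3 <- upsample_balance(X[1:10, ], rep(c("a", "b"), 5), seed = 3)
  expect_equal(dim(up3$X), c(10L, 3L))
})

test_that("LASSO selection finds an informative probe among noise", {
  set.seed(61)
  n <- 120
  X <- matrix(rnorm(n * 20), n, 20)
  colnames(X) <- paste0("P", 1:20)
  y <- rep(c("a", "b"), each = n / 2)
  X[, 7] <- X[, 7] + ifelse(y == "b", 3, 0)
  sel <- l1_logistic_select(X, y, seed = 5)
  expect_true("P7" %in% sel$selected)
  expect_lt(length(sel$selected), 10)
  # at lambda_max every coefficient is zero by definition
  cf_max <- as.matrix(glmnet::coef.glmnet(sel$fit$glmnet.fit,
                                          s = max(sel$fit$lambda)))[, 1]
  expect_true(all(cf_max[names(cf_max) != "(Intercept)"] == 0))
})

test_that("stability selection separates signal from a pure-noise panel", {
  set.seed(62)
  n <- 100
  X <- matrix(rnorm(n * 20), n, 20)
  colnames(X) <- paste0("P", 1:20)
  y <- rep(c("a", "b"), each = n / 2)
  ss_null <- stability_select(X, y, B = 60, seed = 7)
  expect_lt(max(ss_null$probabilities), 0.5)
  expect_equal(length(ss_null$retained), 0)
  # retained is exactly the strict-threshold set
  expect_identical(ss_null$retained,
                   names(ss_null$probabilities)[
                     ss_null$probabilities > ss_null$threshold])
  # planted signal
  X2 <- X
  X2[, c(2, 9)] <- X2[, c(2, 9)] + ifelse(y == "b", 2.5, 0)
  ss <- stability_select(X2, y, B = 60, seed = 7)
  expect_true(all(c("P2", "P9") %in% ss$retained))
  expect_lte(length(setdiff(ss$retained, c("P2", "P9"))), 1)
  expect_warning(stability_select(X2, y, B = 20, seed = 1), "unstable")
})

test_that("LogitBoost separates separable data and ties break low", {
  X <- matrix(1:10, 10, 1)
  y <- rep(c("a", "b"), each = 5)
  m <- logitboost(X, y, max_iters = 10, tune = "none")
  expect_equal(mean(predict(m, X, type = "class") == y), 1)
  expect_lte(nrow(m$stumps), 10)
  # duplicating a feature leaves predictions unchanged (lowest index wins)
  set.seed(63)
  X2 <- matrix(rnorm(80), 40, 2)
  y2 <- factor(ifelse(X2[, 1] + rnorm(40, 0, 0.5) > 0, "b", "a"))
  m1 <- logitboost(X2, y2, max_iters = 20, tune = "none")
  m2 <- logitboost(cbind(X2[, 1], X2), y2, max_iters = 20, tune = "none")
  p1 <- predict(m1, X2)
  p2 <- predict(m2, cbind(X2[, 1], X2))
  expect_equal(p1, p2)
  expect_error(logitboost(X, rep("a", 10)), "constant")
})

test_that("LOOCV accuracy is chance-level on label-free data", {
  set.seed(64)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep(c("a", "b"), each = 30)
  m <- logitboost(X, y, max_iters = 40, tune = "loocv")
  acc <- m$loocv_accuracy[m$n_iter]
  expect_gte(acc, 0.35 - 1e-9)
  expect_lte(acc, 0.65 + 1e-9)
})

test_that("ROC/AUC matches the pairwise Mann-Whitney oracle", {
  r1 <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$auc, 1)
  r2 <- roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(r2$auc, 0.5)
  pairwise_auc <- function(s, l) {
    pos <- s[l]
    neg <- s[!l]
    mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
  }
  set.seed(65)
  for (i in 1:50) {
    s <- round(rnorm(40), 1) # rounding forces ties
    l <- runif(40) > 0.4
    if (!any(l) || all(l)) next
    expect_equal(roc_auc(s, l)$auc, pairwise_auc(s, l),
                 tolerance = 1e-12)
  }
  # cross-check against pROC on one instance
  set.seed(66)
  s <- rnorm(100)
  l <- runif(100) > 0.5
  expect_equal(roc_auc(s, l)$auc,
               as.numeric(pROC::auc(pROC::roc(
                 factor(l, c(FALSE, TRUE)), s, quiet = TRUE,
                 direction = "<"))),
               tolerance = 1e-10)
})

test_that("repeated evaluation is stratified, leak-free and calibrated", {
  set.seed(67)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- paste0("P", 1:5)
  y <- rep(c("a", "b"), c(40, 80))
  X[y == "b", 1:3] <- X[y == "b", 1:3] + 1.8
  ev <- evaluate_repeated(X, y, paste0("P", 1:3), n_splits = 10,
                          seed = 2, max_iters = 30, keep_splits = TRUE)
  expect_gt(ev$mean_auc, 0.85)
  for (sp in ev$splits) {
    expect_equal(length(intersect(sp$train, sp$test)), 0)
    expect_equal(sort(c(sp$train, sp$test)), 1:n)
    # stratification preserves the label ratio in the training part
    expect_equal(sum(y[sp$train] == "a"), 28)
  }
  # permuted labels: chance-level
  set.seed(68)
  yp <- sample(y)
  evp <- evaluate_repeated(X, yp, paste0("P", 1:3), n_splits = 10,
                           seed = 2, max_iters = 30)
  expect_gte(evp$mean_auc, 0.3)
  expect_lte(evp$mean_auc, 0.7)
  # degenerate split count reports zero SD
  ev1 <- evaluate_repeated(X, y, "P1", n_splits = 1, seed = 1,
                           max_iters = 10, tune = "none")
  expect_equal(ev1$sd_auc, 0)
})
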