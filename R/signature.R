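#' Upsample the minority class to balance a two-class dataset
#'
#' The minority class is resampled with replacement (seeded) until both
#' classes have equal counts; majority rows are untouched; the row order
#' of the result is shuffled deterministically.
#'
#' @param X numeric matrix or data.frame, samples in rows.
#' @param y two-class labels parallel to the rows.
#' @param seed optional integer seed.
#' @return list(X, y) with balanced classes.
#' @export
upsample_balance <- function(X, y, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L)
    stop("need exactly two classes with members")
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  extra <- max(tab) - min(tab)
  idx <- seq_along(y)
  if (extra > 0L) {
    pool <- which(y == minority)
    idx <- c(idx, sample(pool, extra, replace = TRUE))
  }
  idx <- sample(idx)
  list(X = X[idx, , drop = FALSE], y = droplevels(y[idx]))
}

#' LASSO-penalized logistic probe selection
#'
#' Cross-validated L1 logistic regression (glmnet): internally
#' standardized predictors, a 100-value lambda path down to 1e-3 of the
#' smallest all-zero lambda, binomial deviance cross-validation, and the
#' 1-SE rule by default. The selected set is the probes with nonzero
#' coefficients at the chosen lambda.
#'
#' @param X numeric matrix (samples x probes).
#' @param y two-class labels.
#' @param n_lambda lambda path length.
#' @param cv_folds number of cross-validation folds.
#' @param rule `"1se"` (default) or `"min"`.
#' @param seed optional seed for fold assignment.
#' @return an `l1_selection`: list(selected, coefficients, lambda, fit).
#' @export
l1_logistic_select <- function(X, y, n_lambda = 100, cv_folds = 10,
                               rule = c("1se", "min"), seed = NULL) {
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("y must be binary")
  fit <- cv.glmnet(X, y, family = "binomial", nlambda = n_lambda,
                   lambda.min.ratio = 1e-3, nfolds = cv_folds,
                   type.measure = "deviance", standardize = TRUE)
  lam <- if (rule == "1se") fit$lambda.1se else fit$lambda.min
  cf <- as.matrix(coef(fit, s = lam))[, 1L]
  selected <- names(cf)[cf != 0 & names(cf) != "(Intercept)"]
  structure(list(selected = selected, coefficients = cf, lambda = lam,
                 fit = fit), class = "l1_selection")
}

#' @export
print.l1_selection <- function(x, ...) {
  cat("l1_selection: lambda =", signif(x$lambda, 4), "->",
      length(x$selected), "probes:",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Stability selection over subsampled LASSO fits
#'
#' For each of B seeded subsamples (a fraction of the rows without
#' replacement, then minority upsampling), an L1 logistic selection is
#' run; each probe's selection probability is the fraction of runs that
#' kept it, and the retained set is the probes with probability strictly
#' above the threshold.
#'
#' @param X numeric matrix (samples x probes).
#' @param y two-class labels.
#' @param B number of subsample runs (default 2000).
#' @param subsample row fraction per run.
#' @param threshold retention threshold on the selection probability
#'   (strict `>`).
#' @param seed integer seed.
#' @param ... passed to [l1_logistic_select()].
#' @return a `stability_selection`: list(probabilities, retained, B,
#'   threshold).
#' @export
stability_select <- function(X, y, B = 2000, subsample = 0.5,
                             threshold = 0.5, seed = 1, ...) {
  if (B < 50) warning("B < 50 gives unstable probability estimates")
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  probes <- colnames(X) %||% as.character(seq_len(ncol(X)))
  colnames(X) <- probes
  hits <- setNames(numeric(length(probes)), probes)
  for (b in seq_len(B)) {
    set.seed(seed + b)
    repeat {
      rows <- sample.int(n, max(4L, floor(subsample * n)))
      if (min(table(y[rows])) >= 2L) break
    }
    up <- upsample_balance(X[rows, , drop = FALSE], y[rows])
    sel <- l1_logistic_select(up$X, up$y, ...)
    hits[sel$selected] <- hits[sel$selected] + 1
  }
  prob <- hits / B
  structure(list(probabilities = prob,
                 retained = probes[prob > threshold],
                 B = B, threshold = threshold),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat("stability_selection over", x$B, "subsamples (threshold >",
      paste0(x$threshold, "):"), length(x$retained), "probes retained\n")
  top <- sort(x$probabilities, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(10, sum(x$probabilities > 0)))]
  if (length(top))
    cat(paste(sprintf("  %s: %.3f", names(top), top), collapse = "\n"),
        "\n")
  invisible(x)
}

#' Boosted logistic regression with decision stumps
#'
#' Two-class LogitBoost: the additive score F is grown by weighted
#' least-squares threshold stumps on the working response
#' z = (y - p)/(p(1-p)) with p = 1/(1+exp(-2F)), p clipped to
#' [1e-5, 1-1e-5] and z to +/-4, each stump contributing half its fitted
#' value. With `tune = "loocv"` the iteration count is chosen from
#' 1..max_iters by leave-one-out accuracy on the training set, ties
#' resolved toward fewer iterations. Stump ties go to the lowest feature
#' index, then the lowest threshold.
#'
#' @param X numeric matrix (samples x features).
#' @param y two-class labels; the second factor level is the positive
#'   class.
#' @param max_iters maximum boosting iterations (default 100).
#' @param tune `"loocv"` (default) or `"none"` (use max_iters).
#' @return a `logitboost` model: stumps, n_iter, levels, and the LOOCV
#'   accuracy path when tuned.
#' @export
logitboost <- function(X, y, max_iters = 100, tune = c("loocv", "none")) {
  tune <- match.arg(tune)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("constant labels: nothing to boost")
  if (nlevels(y) != 2L) stop("y must be binary")
  y01 <- as.integer(y) - 1L
  loocv_acc <- NULL
  n_iter <- max_iters
  if (tune == "loocv") {
    loocv_acc <- cpp_logitboost_loocv(X, y01, as.integer(max_iters))
    n_iter <- which.max(loocv_acc) # first max = fewest iterations
  }
  stumps <- cpp_logitboost_fit(X, y01, as.integer(n_iter))
  structure(list(stumps = stumps, n_iter = n_iter, levels = levels(y),
                 loocv_accuracy = loocv_acc,
                 features = colnames(X)),
            class = "logitboost")
}

#' @export
print.logitboost <- function(x, ...) {
  cat("logitboost:", x$n_iter, "stumps over",
      length(unique(x$stumps$feature)), "features; classes",
      paste(x$levels, collapse = " vs "), "\n")
  invisible(x)
}

#' @rdname logitboost
#' @param object a `logitboost` model.
#' @param newdata numeric matrix with the training columns.
#' @param type `"score"` (additive F), `"prob"` (P(second level)) or
#'   `"class"`.
#' @param ... unused.
#' @export
predict.logitboost <- function(object, newdata,
                               type = c("score", "prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata)) &&
      all(object$features %in% colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  f <- cpp_logitboost_predict(newdata, object$stumps$feature,
                              object$stumps$threshold,
                              object$stumps$left, object$stumps$right,
                              as.integer(object$n_iter))[, 1L]
  if (type == "score") return(f)
  p <- 1 / (1 + exp(-2 * f))
  if (type == "prob") return(p)
  factor(object$levels[(f > 0) + 1L], levels = object$levels)
}

#' ROC curve and AUC with tie handling
#'
#' AUC is the Mann-Whitney U statistic with half credit for score ties,
#' divided by n1*n2; the curve is traced over the sorted score
#' thresholds.
#'
#' @param scores numeric classifier scores (larger = more positive).
#' @param labels two-class labels; the second factor level (or TRUE/1) is
#'   positive.
#' @return list(auc, curve = data.frame(fpr, tpr)).
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- factor(labels, c(FALSE, TRUE))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("both classes must be present")
  pos <- labels == levels(labels)[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, 0)
  list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
}

# step-function interpolation of a ROC curve on an FPR grid
interp_tpr <- function(curve, grid) {
  o <- order(curve$fpr, curve$tpr)
  stats::approx(curve$fpr[o], curve$tpr[o], xout = grid,
                method = "constant", f = 1, ties = max, rule = 2)$y
}

#' Repeated stratified-split evaluation of a probe signature
#'
#' For each of `n_splits` seeded splits: a stratified 70/30 train/test
#' partition, minority upsampling of the training rows, a LogitBoost
#' classifier (LOOCV-tuned iteration count) fitted on the signature
#' columns, and ROC/AUC on the held-out rows. Reports the per-split AUCs,
#' their mean and SD, and the vertically averaged ROC on a fixed
#' 101-point FPR grid.
#'
#' @param X numeric matrix (samples x probes).
#' @param y two-class labels.
#' @param signature character vector of probe columns to use.
#' @param n_splits number of repeated splits (default 100).
#' @param train_fraction training fraction (default 0.7).
#' @param seed integer seed.
#' @param max_iters,tune passed to [logitboost()].
#' @param keep_splits record the train/test row indices of every split.
#' @return an `eval_report`: list(auc, mean_auc, sd_auc, fpr_grid,
#'   mean_tpr, n_splits) plus `splits` when requested.
#' @export
evaluate_repeated <- function(X, y, signature, n_splits = 100,
                              train_fraction = 0.7, seed = 1,
                              max_iters = 100, tune = "loocv",
                              keep_splits = FALSE) {
  X <- as.matrix(X)
  if (!all(signature %in% colnames(X)))
    stop("signature probes missing from X")
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("y must be binary")
  if (any(table(y) < 2L))
    stop("stratification impossible: a class has fewer than 2 samples")
  Xs <- X[, signature, drop = FALSE]
  grid <- seq(0, 1, length.out = 101)
  aucs <- numeric(n_splits)
  tprs <- matrix(0, n_splits, length(grid))
  splits <- if (keep_splits) vector("list", n_splits) else NULL
  for (s in seq_len(n_splits)) {
    set.seed(seed + s)
    train <- unlist(lapply(levels(y), function(lv) {
      i <- which(y == lv)
      sample(i, max(1L, round(train_fraction * length(i))))
    }))
    test <- setdiff(seq_len(nrow(Xs)), train)
    if (length(unique(y[test])) < 2L || length(unique(y[train])) < 2L)
      stop("degenerate split: a class is absent from train or test")
    up <- upsample_balance(Xs[train, , drop = FALSE], y[train])
    model <- logitboost(up$X, up$y, max_iters = max_iters, tune = tune)
    sc <- predict(model, Xs[test, , drop = FALSE], type = "score")
    roc <- roc_auc(sc, y[test])
    aucs[s] <- roc$auc
    tprs[s, ] <- interp_tpr(roc$curve, grid)
    if (keep_splits) splits[[s]] <- list(train = sort(train), test = test)
  }
  structure(list(auc = aucs, mean_auc = mean(aucs),
                 sd_auc = if (n_splits > 1) sd(aucs) else 0,
                 fpr_grid = grid, mean_tpr = colMeans(tprs),
                 n_splits = n_splits, signature = signature,
                 splits = splits),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:", x$n_splits, "stratified splits,",
      length(x$signature), "probes\n")
  cat(sprintf("  mean AUC %.3f (SD %.3f), range [%.3f, %.3f]\n",
              x$mean_auc, x$sd_auc, min(x$auc), max(x$auc)))
  invisible(x)
}

#' @export
plot.eval_report <- function(x, ...) {
  plot(x$fpr_grid, x$mean_tpr, type = "l", lwd = 2,
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("Averaged ROC (mean AUC %.3f)", x$mean_auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Fit a probe signature model (selection + classifier)
#'
#' Convenience wrapper tying the module together: minority upsampling,
#' stability-selected LASSO probe selection (or a single cross-validated
#' LASSO), and a LogitBoost classifier refitted on the selected probes.
#'
#' @param X numeric matrix (samples x probes).
#' @param y two-class labels.
#' @param selection `"stability"` (default) or `"lasso_cv"`.
#' @param B,subsample,threshold stability-selection parameters.
#' @param seed integer seed.
#' @param max_iters,tune LogitBoost parameters.
#' @return a `signature_model`: list(selected_probes, selection,
#'   classifier).
#' @export
fit_signature <- function(X, y, selection = c("stability", "lasso_cv"),
                          B = 2000, subsample = 0.5, threshold = 0.5,
                          seed = 1, max_iters = 100, tune = "loocv") {
  selection <- match.arg(selection)
  X <- as.matrix(X)
  if (selection == "stability") {
    sel <- stability_select(X, y, B = B, subsample = subsample,
                            threshold = threshold, seed = seed)
    probes <- sel$retained
  } else {
    set.seed(seed)
    up <- upsample_balance(X, y)
    sel <- l1_logistic_select(up$X, up$y)
    probes <- sel$selected
  }
  if (!length(probes))
    stop("selection retained no probes")
  set.seed(seed)
  up <- upsample_balance(X[, probes, drop = FALSE], y)
  clf <- logitboost(up$X, up$y, max_iters = max_iters, tune = tune)
  structure(list(selected_probes = probes, selection = sel,
                 classifier = clf, selection_mode = selection),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("signature_model (", x$selection_mode, "): ",
      length(x$selected_probes), " probes: ",
      paste(x$selected_probes, collapse = ", "), "\n", sep = "")
  print(x$classifier)
  invisible(x)
}

#' @export
predict.signature_model <- function(object, newdata, type = "prob", ...) {
  predict(object$classifier,
          as.matrix(newdata)[, object$selected_probes, drop = FALSE],
          type = type, ...)
}

#' Serialize a signature model to JSON
#'
#' @param model a `signature_model` or `logitboost`.
#' @param path output JSON path.
#' @export
write_signature_json <- function(model, path) {
  if (inherits(model, "signature_model")) {
    payload <- list(selected_probes = model$selected_probes,
                    selection_mode = model$selection_mode,
                    probabilities =
                      if (inherits(model$selection, "stability_selection"))
                        as.list(model$selection$probabilities) else NULL,
                    stumps = model$classifier$stumps,
                    n_iter = model$classifier$n_iter,
                    levels = model$classifier$levels)
  } else {
    payload <- list(stumps = model$stumps, n_iter = model$n_iter,
                    levels = model$levels)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
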