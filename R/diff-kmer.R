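#' Median-of-ratios size factors
#'
#' Computes per-sample scaling constants against a pseudo-reference of
#' per-row geometric means. By default only rows with all-positive counts
#' contribute to the reference; with `zero_policy = "positive-geomean"`
#' geometric means are taken over the positive entries of each row
#' instead, for matrices without any zero-free row.
#'
#' @param mat counts matrix (features x samples) or a `joined_kmers`.
#' @param zero_policy `"strict"` (error when no zero-free row exists) or
#'   `"positive-geomean"`.
#' @return numeric vector of positive size factors, one per sample.
#' @export
median_of_ratios <- function(mat, zero_policy = c("strict",
                                                  "positive-geomean")) {
  zero_policy <- match.arg(zero_policy)
  if (inherits(mat, "joined_kmers")) mat <- mat$counts
  mat <- as.matrix(mat)
  if (ncol(mat) < 1L || nrow(mat) < 1L) stop("empty count matrix")
  if (zero_policy == "strict") {
    ok <- rowSums(mat <= 0) == 0L
    if (!any(ok))
      stop("no zero-free rows for the median-of-ratios reference; ",
           "use zero_policy = \"positive-geomean\"")
    lg <- log(mat[ok, , drop = FALSE])
    ref <- rowMeans(lg)
    # median taken on the log scale (geometric interpolation between the
    # two central ratios when the row count is even)
    sf <- exp(apply(lg - ref, 2L, median))
  } else {
    lg <- suppressWarnings(log(mat))
    lg[!is.finite(lg)] <- NA
    ref <- rowMeans(lg, na.rm = TRUE)
    ok <- is.finite(ref)
    if (!any(ok)) stop("no rows with positive geometric mean")
    sf <- exp(apply(lg[ok, , drop = FALSE] - ref[ok], 2L, median,
                    na.rm = TRUE))
  }
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor; check for empty samples")
  unname(sf)
}

#' Per-row negative-binomial Wald test between two conditions
#'
#' A desk-scale two-group test on size-factor-normalized counts: per row,
#' the dispersion is estimated by method of moments on the normalized
#' counts (floored at 1e-8), the log2 fold change uses a pseudocount on
#' the group means, and a Wald statistic with negative-binomial variance
#' of the group means is referred to the normal distribution (two-sided).
#' This is deliberately not a reimplementation of DESeq2's shrinkage
#' machinery; a Welch t-test on log2(normalized + 1) is available as an
#' alternative mode.
#'
#' @param mat counts matrix (features x samples) or `joined_kmers`.
#' @param condition factor/character of length ncol with exactly two
#'   levels; the first level is the reference (A).
#' @param size_factors optional; computed by [median_of_ratios()] when
#'   missing.
#' @param pseudocount added to group means in the fold change only (never
#'   to tested counts).
#' @param method `"nb_wald"` (default) or `"welch"`.
#' @return data.frame: feature, mean_a, mean_b, log2_fold_change, p_value,
#'   adjusted_p (Benjamini-Hochberg).
#' @export
nb_wald_test <- function(mat, condition, size_factors = NULL,
                         pseudocount = 0.5,
                         method = c("nb_wald", "welch")) {
  method <- match.arg(method)
  if (inherits(mat, "joined_kmers")) mat <- mat$counts
  mat <- as.matrix(mat)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("`condition` must have exactly two levels")
  if (length(condition) != ncol(mat))
    stop("`condition` length must match the number of samples")
  if (any(table(condition) < 2L))
    stop("need at least two samples per condition")
  if (is.null(size_factors))
    size_factors <- tryCatch(median_of_ratios(mat),
                             error = function(e)
                               median_of_ratios(mat, "positive-geomean"))
  if (any(size_factors <= 0)) stop("size factors must be positive")
  q <- sweep(mat, 2L, size_factors, "/")
  a <- condition == levels(condition)[1]
  b <- !a
  nA <- sum(a); nB <- sum(b)
  mA <- rowMeans(q[, a, drop = FALSE])
  mB <- rowMeans(q[, b, drop = FALSE])
  lfc <- log2((mB + pseudocount) / (mA + pseudocount))

  if (method == "welch") {
    lq <- log2(q + 1)
    vA <- apply(lq[, a, drop = FALSE], 1L, var)
    vB <- apply(lq[, b, drop = FALSE], 1L, var)
    se2 <- vA / nA + vB / nB
    tt <- (rowMeans(lq[, b, drop = FALSE]) -
             rowMeans(lq[, a, drop = FALSE])) / sqrt(se2)
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    p <- 2 * stats::pt(-abs(tt), df)
  } else {
    vA <- apply(q[, a, drop = FALSE], 1L, var)
    vB <- apply(q[, b, drop = FALSE], 1L, var)
    # method-of-moments dispersion per condition; the larger estimate is
    # kept, which guards against understating the NB variance at small n
    aA <- ifelse(mA > 0, (vA - mA) / mA^2, 0)
    aB <- ifelse(mB > 0, (vB - mB) / mB^2, 0)
    alpha <- pmax(aA, aB, 1e-8)
    varA <- (mA + alpha * mA^2) / nA
    varB <- (mB + alpha * mB^2) / nB
    se <- sqrt(varA / (mA + pseudocount)^2 + varB / (mB + pseudocount)^2) /
      log(2)
    z <- lfc / se
    p <- 2 * pnorm(-abs(z))
  }
  # degenerate rows: a condition pair with zero mean and zero variance
  # everywhere yields p = 1, not an exception
  degen <- !is.finite(p) | (mA == 0 & mB == 0)
  p[degen] <- 1
  lfc[mA == 0 & mB == 0] <- 0
  res <- data.frame(feature = rownames(mat) %||%
                      as.character(seq_len(nrow(mat))),
                    mean_a = mA, mean_b = mB, log2_fold_change = lfc,
                    p_value = p, stringsAsFactors = FALSE,
                    row.names = NULL)
  res$adjusted_p <- benjamini_hochberg(res$p_value)
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment,
#' `adj_i = min_{j >= rank(i)} (m / rank(j)) p_(j)` capped at 1
#' (delegated to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Select differentially abundant k-mers
#'
#' Retains rows with adjusted p strictly below the threshold; with
#' `direction = "up"` additionally requires log2 fold change > 0 (B over
#' A), `"down"` the opposite.
#'
#' @param results data.frame from [nb_wald_test()].
#' @param p_threshold adjusted-p threshold (strict `<`).
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return the retained subset of `results`.
#' @export
select_de_kmers <- function(results, p_threshold = 0.05,
                            direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- results$adjusted_p < p_threshold
  if (direction == "up") keep <- keep & results$log2_fold_change > 0
  if (direction == "down") keep <- keep & results$log2_fold_change < 0
  results[keep, , drop = FALSE]
}

#' Write a DE k-mer results table as TSV
#' @param results data.frame from [nb_wald_test()].
#' @param path output path.
#' @export
write_de_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
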