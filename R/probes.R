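#' Normalize a NanoString-style probe count table
#'
#' Three-step scheme: (1) lane scaling — each sample is scaled by the
#' ratio of the across-sample geometric mean of positive-control geometric
#' means to the sample's own positive-control geometric mean; (2)
#' background — the per-sample mean of the negative controls is
#' subtracted from assay rows and values are floored at 0.5; (3) content —
#' target and benchmark rows are divided by the arithmetic mean of the
#' sample's housekeeping values after steps 1-2.
#'
#' @param pm a `probe_matrix` (see [make_probe_table()]) or a list with
#'   `values`, `roles`, `samples`.
#' @param housekeeping_ids optional subset of housekeeping row names to
#'   use for step 3 (default: all rows with role `housekeeping`).
#' @return the `probe_matrix` with `values` replaced by normalized values
#'   and a `normalized = TRUE` flag.
#' @export
normalize_probe_table <- function(pm, housekeeping_ids = NULL) {
  v <- pm$values
  roles <- pm$roles
  pos <- v[roles == "positive_control", , drop = FALSE]
  neg <- v[roles == "negative_control", , drop = FALSE]
  hk_ids <- housekeeping_ids %||%
    rownames(v)[roles == "housekeeping"]
  if (!length(hk_ids) || !all(hk_ids %in% rownames(v)))
    stop("missing housekeeping row(s)")
  if (nrow(pos) == 0L) stop("no positive-control rows")
  gm <- function(x) exp(mean(log(x)))
  lane_gm <- apply(pos, 2L, gm)
  if (any(lane_gm <= 0)) stop("zero positive-control geometric mean")
  lane_factor <- gm(lane_gm) / lane_gm
  v <- sweep(v, 2L, lane_factor, "*")

  assay <- roles %in% c("target", "benchmark", "housekeeping")
  bg <- if (nrow(neg)) colMeans(v[roles == "negative_control", ,
                                  drop = FALSE]) else rep(0, ncol(v))
  v[assay, ] <- pmax(sweep(v[assay, , drop = FALSE], 2L, bg, "-"), 0.5)

  hk_mean <- colMeans(v[hk_ids, , drop = FALSE])
  tb <- roles %in% c("target", "benchmark")
  v[tb, ] <- sweep(v[tb, , drop = FALSE], 2L, hk_mean, "/")

  pm$values <- v
  pm$normalized <- TRUE
  pm
}

# two-sided Mann-Whitney p from the tie-corrected normal approximation
# with continuity correction and an Edgeworth (kurtosis) term; the
# kurtosis uses the tie-free closed form, which is exact without ties and
# a close approximation under mild ties
wilcox_approx_p <- function(y, x) {
  m <- length(x)
  n <- length(y)
  r <- rank(c(y, x))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  N <- m + n
  ties <- table(r)
  mu <- m * n / 2
  s2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (s2 <= 0) return(1)
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(s2)
  g2 <- -1.2 * (m^2 + n^2 + m * n + m + n) / (m * n * (N + 1))
  P <- pnorm(z) - dnorm(z) * (z^3 - 3 * z) * g2 / 24
  P <- min(max(P, 0), 1)
  min(1, 2 * min(P, 1 - P))
}

#' Wilcoxon rank-sum tests and fold changes per probe
#'
#' Two-sided Wilcoxon rank-sum test of each probe between two sample
#' groups: exact enumeration when both groups have at most 8 samples and
#' no ties, otherwise a tie-corrected normal approximation carrying
#' continuity and Edgeworth (kurtosis) corrections. The fold change is
#' the ratio of group means, with a 0.5 pseudocount on the means when a
#' mean is zero.
#'
#' @param pm a normalized `probe_matrix`.
#' @param contrast two group labels, `c(reference, interest)`; the fold
#'   change is interest over reference.
#' @param group_var metadata column holding the labels (default
#'   `"condition"`).
#' @param roles probe roles to test.
#' @param exact `"auto"` (exact when both groups <= 8 and tie-free),
#'   `"always"`, or `"never"` (tie-corrected normal approximation).
#' @return data.frame: probe_id, role, mean_1, mean_2, fold_change,
#'   wilcoxon_p.
#' @export
wilcoxon_fc <- function(pm, contrast = c("normal", "tumor"),
                        group_var = "condition",
                        roles = c("target", "benchmark"),
                        exact = c("auto", "always", "never")) {
  exact <- match.arg(exact)
  g <- pm$samples[[group_var]]
  i1 <- which(g == contrast[1])
  i2 <- which(g == contrast[2])
  if (!length(i1) || !length(i2))
    stop("a contrast group is empty")
  rows <- which(pm$roles %in% roles)
  res <- lapply(rows, function(r) {
    x <- pm$values[r, i1]
    y <- pm$values[r, i2]
    use_exact <- switch(exact,
                        auto = length(x) <= 8 && length(y) <= 8 &&
                          !anyDuplicated(c(x, y)),
                        always = TRUE, never = FALSE)
    p <- if (use_exact)
      suppressWarnings(wilcox.test(y, x, exact = TRUE)$p.value)
    else wilcox_approx_p(y, x)
    m1 <- mean(x); m2 <- mean(y)
    fc <- if (m1 == 0 || m2 == 0) (m2 + 0.5) / (m1 + 0.5) else m2 / m1
    data.frame(probe_id = rownames(pm$values)[r], role = pm$roles[r],
               mean_1 = m1, mean_2 = m2, fold_change = fc,
               wilcoxon_p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Rank probes and flag them against a benchmark
#'
#' Probes are sorted by ascending p-value (ties by descending fold
#' change); each is flagged `significant` (p strictly below `p_cut` and,
#' when given, fold change strictly above `fc_cut`) and
#' `better_than_benchmark` (ranked above the benchmark probe).
#'
#' @param results data.frame from [wilcoxon_fc()].
#' @param benchmark_id probe_id of the benchmark.
#' @param p_cut significance threshold (strict).
#' @param fc_cut optional fold-change threshold (strict).
#' @return `results` sorted, with `rank`, `significant`,
#'   `better_than_benchmark` columns.
#' @export
rank_and_flag <- function(results, benchmark_id, p_cut = 0.01,
                          fc_cut = NULL) {
  if (!benchmark_id %in% results$probe_id)
    stop("unknown benchmark_id: ", benchmark_id)
  o <- order(results$wilcoxon_p, -results$fold_change)
  out <- results[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$significant <- out$wilcoxon_p < p_cut
  if (!is.null(fc_cut))
    out$significant <- out$significant & out$fold_change > fc_cut
  bench_rank <- out$rank[out$probe_id == benchmark_id]
  out$better_than_benchmark <- out$rank < bench_rank
  rownames(out) <- NULL
  out
}

stage_order <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c",
                 "T3a", "T3b", "T4")

parse_stage <- function(x) {
  x <- toupper(trimws(x))
  x[x == ""] <- NA
  idx <- match(x, toupper(stage_order))
  bad <- !is.na(x) & is.na(idx)
  if (any(bad)) {
    warning("unparseable stage string(s): ",
            paste(unique(x[bad]), collapse = ", "))
  }
  idx
}

#' Gleason/TNM risk stratification
#'
#' Assigns low / intermediate / high-risk labels from Gleason score and
#' clinical T stage alone (a PSA-free simplification of the D'Amico
#' scheme). Rules are data: a table scanned in order, first match wins;
#' the packaged default is Gleason <= 6 and stage <= T2a giving LR,
#' Gleason >= 8 or stage >= T2c giving HR, and IR otherwise. Missing
#' fields give NA; unparseable stages give NA with a warning.
#'
#' @param metadata data.frame with `gleason` and `t_stage` columns.
#' @param rule_table optional rules data.frame (columns label,
#'   gleason_min, gleason_max, stage_min, stage_max; NA = unbounded); the
#'   default is read from the package's `extdata/risk_rules.tsv`.
#' @return character vector of labels in `{LR, IR, HR, NA}`.
#' @export
stratify_risk <- function(metadata, rule_table = NULL) {
  if (is.null(rule_table)) {
    path <- system.file("extdata", "risk_rules.tsv", package = "kmsig")
    rule_table <- read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  gl <- metadata$gleason
  st <- parse_stage(metadata$t_stage)
  r_smin <- match(rule_table$stage_min, stage_order)
  r_smax <- match(rule_table$stage_max, stage_order)
  out <- rep(NA_character_, nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    if (is.na(gl[i]) || is.na(st[i])) next
    for (r in seq_len(nrow(rule_table))) {
      ok <- TRUE
      if (!is.na(rule_table$gleason_min[r]))
        ok <- ok && gl[i] >= rule_table$gleason_min[r]
      if (!is.na(rule_table$gleason_max[r]))
        ok <- ok && gl[i] <= rule_table$gleason_max[r]
      if (!is.na(r_smin[r])) ok <- ok && st[i] >= r_smin[r]
      if (!is.na(r_smax[r])) ok <- ok && st[i] <= r_smax[r]
      if (ok) {
        out[i] <- rule_table$label[r]
        break
      }
    }
  }
  out
}
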