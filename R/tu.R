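#' Read paired alignments for transcription-unit assembly
#'
#' Accepts a SAM or BAM path; SAM is converted (and coordinate-sorted) on
#' the fly. Only proper pairs passing the mapping-quality filter are
#' kept — the uniquely-mapped-read convention of coverage-based TU
#' assembly. Pair strand follows the dUTP convention (strand of the pair
#' is the strand of mate 2), matching reverse-stranded counting.
#'
#' @param path SAM or BAM file.
#' @param min_mapq minimum mapping quality (default 50).
#' @return a `GAlignmentPairs` with `strandMode = 2`.
#' @export
read_alignments <- function(path, min_mapq = 50) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
  }
  param <- ScanBamParam(mapqFilter = min_mapq)
  readGAlignmentPairs(path, param = param, strandMode = 2)
}

#' Strand-specific covered intervals with read support
#'
#' Computes maximal intervals of nonzero same-strand read coverage merged
#' across samples (union) and retains intervals supported by at least
#' `min_reads` reads (mates) in at least one single sample.
#'
#' @param aln_list list of `GAlignmentPairs`, one per sample.
#' @param min_reads support threshold (default 10).
#' @return stranded GRanges of retained covered intervals, with an
#'   `max_support` metadata column.
#' @export
coverage_segments <- function(aln_list, min_reads = 10) {
  if (!length(aln_list)) stop("no alignment samples supplied")
  read_grs <- lapply(aln_list, function(galp) {
    bl <- unlist(grglist(galp), use.names = FALSE)
    bl
  })
  covered <- reduce(do.call(c, read_grs), ignore.strand = FALSE)
  # per-sample mate-level support over the candidate intervals
  support <- sapply(seq_along(aln_list), function(s) {
    galp <- aln_list[[s]]
    reads <- c(granges(first(galp, real.strand = FALSE)),
               granges(last(galp, real.strand = FALSE)))
    strand(reads) <- rep(strand(galp), 2L)
    countOverlaps(covered, reads, ignore.strand = FALSE)
  })
  support <- matrix(support, nrow = length(covered))
  keep <- apply(support, 1L, max) >= min_reads
  out <- covered[keep]
  out$max_support <- apply(support, 1L, max)[keep]
  out
}

#' Merge same-strand segments separated by small gaps
#'
#' Consecutive same-strand intervals separated by fewer than `max_gap`
#' bases are merged transitively; the output is disjoint with pairwise
#' gaps of at least `max_gap`. Opposite strands never merge.
#'
#' @param segments stranded GRanges.
#' @param max_gap strict gap bound in bases (default 100: gaps of up to
#'   99 bases merge).
#' @return merged GRanges.
#' @export
merge_segments <- function(segments, max_gap = 100) {
  reduce(segments, min.gapwidth = max_gap, ignore.strand = FALSE)
}

#' Classify transcription units by genomic context
#'
#' Segments overlapping a same-strand annotated gene are `sense_overlap`
#' (excluded from the lncRNA catalog); otherwise `antisense` when they
#' overlap a gene on the opposite strand, else `intergenic`. Only
#' segments strictly longer than `min_length` are retained in the
#' catalog.
#'
#' @param segments merged stranded GRanges.
#' @param annotation GRanges annotation with `type` and gene rows.
#' @param min_length strict length bound (nt, default 200).
#' @return GRanges with mcols `tu_id`, `context`, `retained`.
#' @export
classify_tu <- function(segments, annotation, min_length = 200) {
  genes <- annotation[annotation$type == "gene"]
  sense <- overlapsAny(segments, genes, ignore.strand = FALSE)
  anti <- overlapsAny(invertStrand(segments), genes, ignore.strand = FALSE)
  context <- ifelse(sense, "sense_overlap",
                    ifelse(anti, "antisense", "intergenic"))
  out <- segments
  mcols(out) <- NULL
  out$tu_id <- sprintf("TU_%05d", seq_along(out))
  out$context <- context
  out$retained <- context != "sense_overlap" & width(out) > min_length
  out
}

#' Count fragments in features (reverse-stranded, overlap-tolerant)
#'
#' Fragments (pairs), not mates, are counted; a fragment is assigned to
#' every feature it overlaps on the protocol-consistent strand
#' (reverse strandedness: the fragment strand is the opposite of the
#' mate-1 alignment strand, i.e. the pair strand under `strandMode = 2`).
#' With `multi_overlap = FALSE`, fragments overlapping more than one
#' feature are discarded instead.
#'
#' @param aln_list list of `GAlignmentPairs` per sample.
#' @param features GRanges of features.
#' @param multi_overlap count a fragment in all overlapped features.
#' @param sample_ids optional column names.
#' @return integer matrix, features x samples.
#' @export
count_in_features <- function(aln_list, features, multi_overlap = TRUE,
                              sample_ids = NULL) {
  if (!length(features)) stop("no features supplied")
  counts <- vapply(aln_list, function(galp) {
    frag <- granges(galp)
    h <- findOverlaps(features, frag, ignore.strand = FALSE)
    if (!multi_overlap) {
      amb <- subjectHits(h)[duplicated(subjectHits(h))]
      h <- h[!(subjectHits(h) %in% amb)]
    }
    tabulate(queryHits(h), nbins = length(features))
  }, integer(length(features)))
  counts <- matrix(counts, nrow = length(features))
  colnames(counts) <- sample_ids %||% names(aln_list) %||%
    paste0("S", seq_along(aln_list))
  rownames(counts) <- if (!is.null(features$tu_id)) features$tu_id else
    if (!is.null(names(features))) names(features) else NULL
  counts
}

#' Reads per kilobase per million mapped reads
#'
#' @param count read/fragment count (vectorized).
#' @param feature_length_bp feature length in bp.
#' @param library_total total mapped reads of the library.
#' @return `count * 1e9 / (feature_length_bp * library_total)`.
#' @export
rpkm <- function(count, feature_length_bp, library_total) {
  if (any(feature_length_bp <= 0)) stop("feature length must be positive")
  if (any(library_total <= 0)) stop("library total must be positive")
  count * 1e9 / (feature_length_bp * library_total)
}

#' Extract splice junctions from gapped alignments
#'
#' Junctions are the N-gap introns of the alignment records, oriented by
#' the pair strand, with read support counts accumulated over samples.
#'
#' @param aln_list list of `GAlignmentPairs`.
#' @return GRanges of intron intervals with `n_reads` support.
#' @export
extract_junctions <- function(aln_list) {
  per <- lapply(aln_list, function(galp) {
    j <- junctions(galp)
    out <- unlist(j, use.names = FALSE)
    if (length(out))
      strand(out) <- rep(strand(galp), lengths(j))
    out
  })
  all <- do.call(c, per)
  if (!length(all)) return(GRanges(n_reads = integer()))
  u <- unique(all)
  u$n_reads <- countMatches(u, all)
  u
}

#' Assign expression classes to transcription units
#'
#' A TU is Class 2 when its condition-level expression (mean RPKM over
#' the condition's samples by default) exceeds the 20th percentile of
#' the per-condition mRNA mean RPKM distribution in at least one
#' condition; Class 1 additionally requires at least one junction with
#' both ends inside the TU on its strand and at least one spliced EST
#' overlapping the TU; everything else is `below_threshold`.
#'
#' @param tus GRanges from [classify_tu()].
#' @param tu_rpkm matrix of TU RPKM (TUs x samples).
#' @param mrna_rpkm matrix of mRNA RPKM (reference distribution).
#' @param condition per-sample condition labels (both matrices).
#' @param junctions GRanges from [extract_junctions()].
#' @param ests GRangesList of spliced EST blocks.
#' @param quantile_cut mRNA quantile defining the threshold (default 0.2).
#' @param summary condition summary: `"mean"` (default) or `"max"`.
#' @return `tus` with mcols `class`, `junction_count`, `est_count`.
#' @export
assign_classes <- function(tus, tu_rpkm, mrna_rpkm, condition,
                           junctions = NULL, ests = NULL,
                           quantile_cut = 0.2,
                           summary = c("mean", "max")) {
  summary <- match.arg(summary)
  if (is.null(dim(mrna_rpkm)) || nrow(mrna_rpkm) == 0L)
    stop("empty mRNA reference set: expression threshold undefined")
  condition <- as.factor(condition)
  agg <- function(m, f)
    vapply(levels(condition), function(lv)
      apply(m[, condition == lv, drop = FALSE], 1L, f),
      numeric(nrow(m)))
  f <- if (summary == "mean") mean else max
  tu_expr <- agg(tu_rpkm, f)
  mrna_expr <- agg(mrna_rpkm, mean)
  thr <- apply(mrna_expr, 2L, quantile, probs = quantile_cut, type = 7)
  above <- sweep(tu_expr, 2L, thr, ">")
  class2 <- apply(above, 1L, any)

  jc <- integer(length(tus))
  if (!is.null(junctions) && length(junctions)) {
    h <- findOverlaps(junctions, tus, type = "within",
                      ignore.strand = FALSE)
    jc <- tabulate(subjectHits(h), length(tus))
  }
  ec <- integer(length(tus))
  if (!is.null(ests) && length(ests)) {
    est_span <- unlist(range(ests))
    ec <- countOverlaps(tus, est_span, ignore.strand = FALSE)
  }
  cls <- ifelse(!class2, "below_threshold",
                ifelse(jc >= 1L & ec >= 1L, "class1", "class2"))
  tus$class <- cls
  tus$junction_count <- jc
  tus$est_count <- ec
  tus
}

#' Reference-based transcription-unit assembly from stranded coverage
#'
#' Orchestrates the coverage arm: covered-interval extraction with the
#' 10-read support rule, sub-100-nt gap merging, context classification,
#' fragment counting, RPKM, junction/EST evidence and Class 1/2
#' assignment against the mRNA expression distribution.
#'
#' @param aln_files SAM/BAM paths, one per sample.
#' @param annotation GRanges annotation (type, biotype).
#' @param condition per-sample condition labels.
#' @param ests GRangesList of spliced ESTs.
#' @param min_reads,max_gap,min_length,quantile_cut rule parameters.
#' @param min_mapq mapping-quality filter.
#' @return list(tus, catalog, tu_rpkm, junctions): all classified TUs, the
#'   antisense/intergenic catalog, RPKM matrix and the junction set.
#' @export
assemble_tus <- function(aln_files, annotation, condition, ests = NULL,
                         min_reads = 10, max_gap = 100, min_length = 200,
                         quantile_cut = 0.2, min_mapq = 50) {
  aln <- lapply(aln_files, read_alignments, min_mapq = min_mapq)
  segs <- coverage_segments(aln, min_reads = min_reads)
  merged <- merge_segments(segs, max_gap = max_gap)
  tus <- classify_tu(merged, annotation, min_length = min_length)
  totals <- vapply(aln, function(g) 2L * length(g), 0L)

  tu_counts <- count_in_features(aln, tus)
  tu_rpkm <- rpkm(tu_counts, width(tus),
                  matrix(rep(totals, each = length(tus)),
                         nrow = length(tus)))

  genes <- annotation[annotation$type == "gene"]
  mrna <- genes[genes$biotype == "protein_coding"]
  if (!length(mrna)) stop("annotation holds no protein-coding genes")
  mrna_counts <- count_in_features(aln, mrna)
  mrna_rpkm <- rpkm(mrna_counts, width(mrna),
                    matrix(rep(totals, each = length(mrna)),
                           nrow = length(mrna)))

  jx <- extract_junctions(aln)
  tus <- assign_classes(tus, tu_rpkm, mrna_rpkm, condition,
                        junctions = jx, ests = ests,
                        quantile_cut = quantile_cut)
  list(tus = tus, catalog = tus[tus$retained],
       tu_rpkm = tu_rpkm, junctions = jx)
}
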