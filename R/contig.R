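#' Assemble DE k-mers into contigs (unitigs)
#'
#' Builds maximal non-branching paths in the graph linking k-mers whose
#' (k-1)-suffix equals another k-mer's (k-1)-prefix; extension stops at
#' branches, so every DE k-mer belongs to exactly one contig (singletons
#' become length-k contigs). Each contig inherits the adjusted p-value and
#' fold change of its representative k-mer: the member with the smallest
#' adjusted p, ties broken lexicographically.
#'
#' @param de_kmers data.frame with columns `feature` (the k-mer),
#'   `adjusted_p` and `log2_fold_change` (as from [select_de_kmers()]), or
#'   a bare character vector of k-mers.
#' @param k k-mer length.
#' @return a `contig_catalog` data.frame: contig_id, sequence, length,
#'   n_kmers, representative_kmer, adjusted_p, log2_fold_change, with the
#'   member k-mers in a list column `members`.
#' @export
assemble_contigs <- function(de_kmers, k) {
  if (is.character(de_kmers))
    de_kmers <- data.frame(feature = de_kmers, adjusted_p = NA_real_,
                           log2_fold_change = NA_real_,
                           stringsAsFactors = FALSE)
  kmers <- de_kmers$feature
  if (anyDuplicated(kmers)) stop("k-mers must be distinct")
  if (length(kmers) == 0L) {
    out <- data.frame(contig_id = character(), sequence = character(),
                      length = integer(), n_kmers = integer(),
                      representative_kmer = character(),
                      adjusted_p = numeric(), log2_fold_change = numeric(),
                      stringsAsFactors = FALSE)
    out$members <- list()
    class(out) <- c("contig_catalog", "data.frame")
    return(out)
  }
  if (any(nchar(kmers) != k)) stop("all k-mers must have length k")
  asm <- cpp_assemble_unitigs(kmers, as.integer(k))
  n <- length(asm$sequence)
  rep_k <- character(n)
  padj <- numeric(n)
  lfc <- numeric(n)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- asm$members[[i]]
    members[[i]] <- kmers[idx]
    pv <- de_kmers$adjusted_p[idx]
    if (all(is.na(pv))) {
      best <- idx[order(kmers[idx])][1]
    } else {
      o <- order(pv, kmers[idx], na.last = TRUE)
      best <- idx[o[1]]
    }
    rep_k[i] <- kmers[best]
    padj[i] <- de_kmers$adjusted_p[best]
    lfc[i] <- de_kmers$log2_fold_change[best]
  }
  out <- data.frame(contig_id = sprintf("ctg_%05d", seq_len(n)),
                    sequence = asm$sequence,
                    length = nchar(asm$sequence),
                    n_kmers = lengths(asm$members),
                    representative_kmer = rep_k, adjusted_p = padj,
                    log2_fold_change = lfc, stringsAsFactors = FALSE)
  out$members <- members
  class(out) <- c("contig_catalog", "data.frame")
  out
}

# longest exact extension of `s` (from its start) at genomic position `pos`
match_extension <- function(s, gseq, pos) {
  L <- nchar(s)
  g <- substring(gseq, pos, pos + L - 1L)
  if (g == s) return(L)
  a <- utf8ToInt(g)
  b <- utf8ToInt(substring(s, 1L, nchar(g)))
  d <- which(a != b)
  if (length(d) == 0L) return(nchar(g))
  d[1L] - 1L
}

# full-length exact occurrences of `target` on the + strand of all chroms
full_sites <- function(target, genome) {
  hits <- vmatchPattern(target, genome)
  res <- NULL
  for (ci in seq_along(hits)) {
    h <- hits[[ci]]
    if (length(h))
      res <- rbind(res, data.frame(chrom = names(genome)[ci],
                                   start = start(h), end = end(h),
                                   stringsAsFactors = FALSE))
  }
  res
}

# attempt a two-block (spliced) placement of `target` (sense, + strand):
# longest exact prefix + longest exact suffix, same chrom, gap <= max_gap,
# both blocks >= min_block, jointly covering the whole sequence
split_site <- function(target, genome, min_block, max_gap) {
  L <- nchar(target)
  if (L < 2L * min_block) return(NULL)
  seedp <- substring(target, 1L, min_block)
  seeds <- substring(target, L - min_block + 1L, L)
  rc <- function(x) as.character(reverseComplement(DNAString(x)))
  best <- NULL
  for (ci in seq_along(genome)) {
    gseq <- as.character(genome[[ci]])
    ph <- start(matchPattern(seedp, genome[[ci]]))
    sh <- start(matchPattern(seeds, genome[[ci]]))
    if (length(ph) == 0L || length(sh) == 0L) next
    pre <- vapply(ph, function(p) match_extension(target, gseq, p), 0)
    # suffix: longest exact match ending at the end of the hit; extend the
    # reversed sequences instead
    rt <- paste(rev(strsplit(target, "")[[1]]), collapse = "")
    rg <- paste(rev(strsplit(gseq, "")[[1]]), collapse = "")
    glen <- nchar(gseq)
    suf_end <- sh + min_block - 1L
    suf <- vapply(suf_end, function(e)
      match_extension(rt, rg, glen - e + 1L), 0)
    for (i in seq_along(ph)) {
      for (j in seq_along(sh)) {
        a <- pre[i]; b <- suf[j]
        if (a + b < L) next
        b_use <- min(b, L - min_block)
        a_use <- L - b_use
        if (a_use > a || a_use < min_block || b_use < min_block) next
        e1 <- ph[i] + a_use - 1L
        s2 <- suf_end[j] - b_use + 1L
        gap <- s2 - e1 - 1L
        if (gap <= 0L || gap > max_gap) next
        cand <- list(chrom = names(genome)[ci],
                     starts = c(ph[i], s2), ends = c(e1, suf_end[j]),
                     gap = gap)
        if (is.null(best) || cand$gap < best$gap) best <- cand
      }
    }
  }
  best
}

#' Align contigs to a genome
#'
#' Internal exact mode finds all exact occurrences of each contig and of
#' its reverse complement (the alignment strand is recorded so that the
#' contig sequence is sense to the transcript). When no full-length site
#' exists, a two-block split is attempted: longest exact prefix plus
#' longest exact suffix on the same chromosome and strand, blocks at
#' least `k`, gap up to `max_gap`, reported as a spliced alignment.
#' External mode attaches alignments from a BED12 file keyed by
#' contig_id. All occurrence sites are retained for multiplicity
#' assessment.
#'
#' @param catalog a `contig_catalog` from [assemble_contigs()].
#' @param genome DNAStringSet (internal mode).
#' @param mode `"exact_internal"` or `"external_bed12"`.
#' @param bed12 path to a BED12 file (external mode), names = contig ids.
#' @param k minimum block length for the split (the assembly k).
#' @param max_gap maximum intron size for the two-block split (bp).
#' @return the catalog with columns n_sites, chrom, start, end, strand,
#'   n_blocks (primary site) and a `blocks` GRangesList attribute.
#' @export
align_contigs <- function(catalog, genome = NULL,
                          mode = c("exact_internal", "external_bed12"),
                          bed12 = NULL, k = 31, max_gap = 3e5) {
  mode <- match.arg(mode)
  if (any(catalog$length < k)) stop("contig shorter than k")
  n <- nrow(catalog)
  n_sites <- integer(n)
  chrom <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  start <- rep(NA_integer_, n)
  end <- rep(NA_integer_, n)
  n_blocks <- rep(NA_integer_, n)
  blocks <- setNames(vector("list", n), catalog$contig_id)

  if (mode == "external_bed12") {
    if (is.null(bed12)) stop("external mode requires a BED12 path")
    bed <- rtracklayer::import(bed12, format = "bed")
    for (i in seq_len(n)) {
      hits <- bed[bed$name == catalog$contig_id[i]]
      n_sites[i] <- length(hits)
      if (length(hits)) {
        h <- hits[1]
        chrom[i] <- as.character(seqnames(h))
        strand[i] <- as.character(strand(h))
        start[i] <- GenomicRanges::start(h)
        end[i] <- GenomicRanges::end(h)
        bl <- h$blocks[[1]]
        n_blocks[i] <- length(bl)
        blocks[[i]] <- GRanges(chrom[i],
                               shift(bl, GenomicRanges::start(h) - 1L),
                               strand = strand[i])
      }
    }
  } else {
    if (is.null(genome)) stop("internal mode requires a genome")
    if (!is(genome, "DNAStringSet")) genome <- readDNAStringSet(genome)
    for (i in seq_len(n)) {
      seq <- catalog$sequence[i]
      sites <- NULL
      fwd <- full_sites(seq, genome)
      if (!is.null(fwd)) { fwd$strand <- "+"; sites <- rbind(sites, fwd) }
      rev <- full_sites(revcomp(seq), genome)
      if (!is.null(rev)) { rev$strand <- "-"; sites <- rbind(sites, rev) }
      if (is.null(sites)) {
        # spliced attempt, both strands
        sp <- split_site(seq, genome, k, max_gap)
        st <- "+"
        if (is.null(sp)) {
          sp <- split_site(revcomp(seq), genome, k, max_gap)
          st <- "-"
        }
        if (!is.null(sp)) {
          n_sites[i] <- 1L
          chrom[i] <- sp$chrom
          strand[i] <- st
          start[i] <- sp$starts[1]
          end[i] <- sp$ends[2]
          n_blocks[i] <- 2L
          blocks[[i]] <- GRanges(sp$chrom, IRanges(sp$starts, sp$ends),
                                 strand = st)
        }
        next
      }
      sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
      n_sites[i] <- nrow(sites)
      chrom[i] <- sites$chrom[1]
      strand[i] <- sites$strand[1]
      start[i] <- sites$start[1]
      end[i] <- sites$end[1]
      n_blocks[i] <- 1L
      blocks[[i]] <- GRanges(sites$chrom[1],
                             IRanges(sites$start[1], sites$end[1]),
                             strand = sites$strand[1])
    }
  }
  catalog$n_sites <- n_sites
  catalog$chrom <- chrom
  catalog$start <- start
  catalog$end <- end
  catalog$strand <- strand
  catalog$n_blocks <- n_blocks
  empty <- GRanges()
  attr(catalog, "blocks") <-
    GRangesList(lapply(blocks, function(b) b %||% empty))
  catalog
}

#' Categorize contig alignments
#'
#' `unmapped` when no site exists; `repeat` when more than one genomic
#' occurrence (multiplicity takes precedence over splicing); `spliced`
#' for a single multi-block site; `contiguous` otherwise.
#'
#' @param catalog output of [align_contigs()].
#' @return the catalog with a `category` column.
#' @export
categorize_alignment <- function(catalog) {
  stopifnot(!is.null(catalog$n_sites))
  cat <- ifelse(catalog$n_sites == 0L, "unmapped",
                ifelse(catalog$n_sites > 1L, "repeat",
                       ifelse(catalog$n_blocks >= 2L, "spliced",
                              "contiguous")))
  catalog$category <- cat
  catalog
}

#' Classify the genomic context of mapped contigs
#'
#' Precedence: `coding` for a same-strand overlap with a protein-coding
#' exon; `OL` for a same-strand overlap with a lncRNA gene; `AS` for an
#' opposite-strand overlap with any gene; `Inter` otherwise. Gene extent
#' (not just exons) drives OL/AS/Inter; exon-level overlap is used only
#' for the coding exclusion. Repeat and unmapped contigs are
#' `unassigned`.
#'
#' @param catalog categorized catalog from [categorize_alignment()].
#' @param annotation GRanges with `type` (gene/exon) and `biotype`.
#' @return the catalog with a `location` column.
#' @export
classify_location <- function(catalog, annotation) {
  loc <- rep("unassigned", nrow(catalog))
  mapped <- which(catalog$category %in% c("contiguous", "spliced"))
  if (length(mapped)) {
    gr <- GRanges(catalog$chrom[mapped],
                  IRanges(catalog$start[mapped], catalog$end[mapped]),
                  strand = catalog$strand[mapped])
    genes <- annotation[annotation$type == "gene"]
    cod_ex <- annotation[annotation$type == "exon" &
                           annotation$biotype == "protein_coding"]
    lnc_genes <- genes[genes$biotype == "lncRNA"]
    same_cod <- overlapsAny(gr, cod_ex, ignore.strand = FALSE)
    same_lnc <- overlapsAny(gr, lnc_genes, ignore.strand = FALSE)
    anti_any <- overlapsAny(invertStrand(gr), genes, ignore.strand = FALSE)
    loc[mapped] <- ifelse(same_cod, "coding",
                          ifelse(same_lnc, "OL",
                                 ifelse(anti_any, "AS", "Inter")))
  }
  catalog$location <- loc
  catalog
}

#' Apply the catalog filters
#'
#' Contiguous/spliced contigs are retained iff length strictly above
#' `min_length`, adjusted p strictly below `max_adjusted_p`, and location
#' among `keep_locations` (coding is excluded by default). Repeat and
#' unmapped contigs pass the same length and p filters and are retained
#' iff their category is in `keep_categories`.
#'
#' @param catalog classified catalog.
#' @param min_length strict lower length bound (nt).
#' @param max_adjusted_p strict upper adjusted-p bound.
#' @param keep_locations locations retained for mapped contigs.
#' @param keep_categories categories retained.
#' @return the filtered catalog.
#' @export
filter_catalog <- function(catalog, min_length = 200,
                           max_adjusted_p = 0.01,
                           keep_locations = c("Inter", "OL", "AS"),
                           keep_categories = c("contiguous", "spliced",
                                               "repeat", "unmapped")) {
  keep <- catalog$length > min_length &
    !is.na(catalog$adjusted_p) & catalog$adjusted_p < max_adjusted_p &
    catalog$category %in% keep_categories
  mapped <- catalog$category %in% c("contiguous", "spliced")
  keep[mapped] <- keep[mapped] &
    catalog$location[mapped] %in% keep_locations
  out <- catalog[keep, , drop = FALSE]
  bl <- attr(catalog, "blocks")
  if (!is.null(bl)) attr(out, "blocks") <- bl[out$contig_id]
  out
}

#' Deduplicate contigs within genomic windows
#'
#' Mapped contigs are clustered by single linkage: two contigs join a
#' cluster when their alignment spans on the same chromosome are at most
#' `window` bp apart. Only the contig with the lowest adjusted p-value
#' survives per cluster (ties by lexicographic contig_id). Unmapped
#' contigs pass through.
#'
#' @param catalog filtered catalog.
#' @param window clustering distance in bp.
#' @return the reduced catalog.
#' @export
window_dedup <- function(catalog, window = 5000) {
  mapped <- which(!is.na(catalog$chrom))
  keep <- rep(TRUE, nrow(catalog))
  if (length(mapped) > 1L) {
    df <- catalog[mapped, ]
    for (ch in unique(df$chrom)) {
      idx <- mapped[df$chrom == ch]
      o <- idx[order(catalog$start[idx])]
      cl <- integer(length(o))
      cl[1] <- 1L
      max_end <- catalog$end[o[1]]
      for (i in seq_along(o)[-1]) {
        gap <- catalog$start[o[i]] - max_end - 1L
        cl[i] <- if (gap <= window) cl[i - 1L] else cl[i - 1L] + 1L
        max_end <- max(max_end, catalog$end[o[i]])
        if (cl[i] != cl[i - 1L]) max_end <- catalog$end[o[i]]
      }
      for (c0 in unique(cl)) {
        members <- o[cl == c0]
        if (length(members) > 1L) {
          best <- members[order(catalog$adjusted_p[members],
                                catalog$contig_id[members])][1]
          keep[setdiff(members, best)] <- FALSE
        }
      }
    }
  }
  out <- catalog[keep, , drop = FALSE]
  bl <- attr(catalog, "blocks")
  if (!is.null(bl)) attr(out, "blocks") <- bl[out$contig_id]
  out
}

#' Interval pairs exceeding an overlap fraction
#'
#' Reports pairs (x, y) whose overlap length is at least `fraction` of
#' the query x (one-directional; `reciprocal = TRUE` additionally
#' requires the fraction of y). Strand-aware when both sets carry
#' strands.
#'
#' @param a,b GRanges (query, subject).
#' @param fraction minimum overlap fraction (boundary inclusive).
#' @param reciprocal require the fraction on both sides.
#' @param ignore_strand override the strand-awareness default.
#' @return data.frame: query, subject (indices), overlap_bp, frac_query,
#'   frac_subject.
#' @export
overlap_fraction <- function(a, b, fraction = 0.5, reciprocal = FALSE,
                             ignore_strand = NULL) {
  if (is.null(ignore_strand))
    ignore_strand <- all(strand(a) == "*") || all(strand(b) == "*")
  h <- findOverlaps(a, b, ignore.strand = ignore_strand)
  if (length(h) == 0L)
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer(), frac_query = numeric(),
                      frac_subject = numeric()))
  ov <- width(pintersect(a[queryHits(h)], b[subjectHits(h)],
                         ignore.strand = TRUE))
  fq <- ov / width(a[queryHits(h)])
  fs <- ov / width(b[subjectHits(h)])
  keep <- fq >= fraction
  if (reciprocal) keep <- keep & fs >= fraction
  data.frame(query = queryHits(h)[keep], subject = subjectHits(h)[keep],
             overlap_bp = ov[keep], frac_query = fq[keep],
             frac_subject = fs[keep])
}

#' Write a contig catalog as TSV (and optional BED12)
#'
#' @param catalog a classified/filtered catalog.
#' @param tsv output TSV path.
#' @param bed12 optional BED12 path; one record per mapped contig,
#'   blocks = alignment blocks.
#' @export
write_catalog <- function(catalog, tsv, bed12 = NULL) {
  df <- catalog[, setdiff(names(catalog), "members")]
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed12)) {
    bl <- attr(catalog, "blocks")
    mapped <- catalog$contig_id[!is.na(catalog$chrom)]
    grl <- bl[mapped]
    rtracklayer::export(grl, bed12, format = "bed")
  }
  invisible(tsv)
}

#' End-to-end reference-free contig discovery
#'
#' Runs the whole reference-free arm on per-sample FASTQ pairs: k-mer
#' counting, annotation masking, recurrence-filtered joining, NB Wald
#' testing, DE selection, unitig assembly, alignment, categorization,
#' location classification, catalog filtering and 5-kb window
#' deduplication.
#'
#' @param design data.frame with sample_id, condition, fastq_1, fastq_2.
#' @param transcripts annotated transcript sequences (mask source).
#' @param genome DNAStringSet for alignment.
#' @param annotation GRanges annotation (type/biotype).
#' @param k k-mer length.
#' @param protocol library protocol for [count_kmers()].
#' @param min_recurrence,min_recurrence_abundance joining filter.
#' @param p_threshold DE selection threshold (adjusted p, strict).
#' @param direction DE direction filter.
#' @param min_length,max_adjusted_p,window catalog filters.
#' @return list(catalog, results, joined): the deduplicated catalog plus
#'   the per-k-mer DE table and joined matrix.
#' @export
discover_contigs <- function(design, transcripts, genome, annotation,
                             k = 31, protocol = "fr-firststrand",
                             min_recurrence = 6,
                             min_recurrence_abundance = 5,
                             p_threshold = 0.05, direction = "up",
                             min_length = 200, max_adjusted_p = 0.01,
                             window = 5000) {
  mask <- build_mask(transcripts, k)
  pre_mask_total <- numeric(nrow(design))
  tables <- lapply(seq_len(nrow(design)), function(i) {
    tb <- count_kmers(design$fastq_1[i], design$fastq_2[i], k = k,
                      protocol = protocol,
                      sample_id = design$sample_id[i])
    pre_mask_total[i] <<- sum(tb$counts)
    apply_mask(tb, mask)
  })
  joined <- join_samples(tables, min_recurrence, min_recurrence_abundance)
  # size factors from library k-mer totals, not from the joined matrix:
  # the masked/joined rows are dominated by condition-specific novel
  # k-mers, whose fold change must not be absorbed into the normalization
  totals <- design$total_reads %||% pre_mask_total
  sf <- totals / exp(mean(log(totals)))
  res <- nb_wald_test(joined, design$condition, size_factors = sf)
  de <- select_de_kmers(res, p_threshold, direction)
  contigs <- assemble_contigs(de, k)
  if (nrow(contigs)) {
    contigs <- align_contigs(contigs, genome, k = k)
    contigs <- categorize_alignment(contigs)
    contigs <- classify_location(contigs, annotation)
    catalog <- filter_catalog(contigs, min_length = min_length,
                              max_adjusted_p = max_adjusted_p)
    catalog <- window_dedup(catalog, window = window)
  } else catalog <- contigs
  list(catalog = catalog, results = res, joined = joined,
       contigs = contigs)
}
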