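#' Build a k-mer occurrence index over a transcript reference
#'
#' Counts every k-mer occurrence across the reference transcript set,
#' strand-specifically. Used to decide which contig k-mers are unique in
#' the reference (occurrence <= 1: zero occurrences mean novel, one means
#' unambiguous).
#'
#' @param transcripts reference transcript sequences (FASTA path,
#'   DNAStringSet or character).
#' @param k k-mer length.
#' @return a `kmer_index`: list(k, counts) with named occurrence counts.
#' @export
build_reference_index <- function(transcripts, k = 31) {
  seqs <- read_seqs(transcripts)
  res <- cpp_count_kmers(seqs, as.integer(k))
  structure(list(k = as.integer(k),
                 counts = setNames(res$count, res$kmer)),
            class = "kmer_index")
}

#' Contig k-mers unique in a transcript reference
#'
#' Returns the contig's k-mers that are unique in the reference,
#' preserving their 5'-to-3' order along the contig. Under the default
#' `"novel_or_unique"` reading a k-mer passes when its reference
#' occurrence count is at most 1 (zero = novel, one = unambiguous);
#' `"unique_only"` requires exactly one occurrence, excluding novel
#' k-mers.
#'
#' @param contig contig sequence (single string).
#' @param index a `kmer_index` from [build_reference_index()].
#' @param mode uniqueness reading (see above).
#' @return ordered character vector of k-mers.
#' @export
unique_contig_kmers <- function(contig, index,
                                mode = c("novel_or_unique",
                                         "unique_only")) {
  mode <- match.arg(mode)
  k <- index$k
  L <- nchar(contig)
  if (L < k) stop("contig shorter than k")
  kmers <- substring(contig, seq_len(L - k + 1L),
                     seq_len(L - k + 1L) + k - 1L)
  occ <- index$counts[kmers]
  occ[is.na(occ)] <- 0
  if (mode == "unique_only") kmers[occ == 1] else kmers[occ <= 1]
}

#' Regularly spaced deterministic sampling of a k-mer list
#'
#' For a list of length L, base positions are
#' `round(start (L-1) + i (end-start) (L-1) / (n-1))` for i = 0..n-1
#' (0-based), i.e. n picks from the first to the last 10 percent of the
#' list by default. Replicate r shifts every index by r positions,
#' clamped to the valid range with duplicates collapsed. Fully
#' deterministic; short lists yield fewer picks.
#'
#' @param kmer_list ordered character vector.
#' @param n picks per replicate (default 10).
#' @param start_fraction,end_fraction sampled span of the list.
#' @param replicate_offsets number of shifted replicates (default 4).
#' @return list of `replicate_offsets` character vectors.
#' @export
regular_sample <- function(kmer_list, n = 10, start_fraction = 0.10,
                           end_fraction = 0.90, replicate_offsets = 4) {
  L <- length(kmer_list)
  if (L == 0L) stop("empty k-mer list")
  if (L <= n)
    return(rep(list(kmer_list), replicate_offsets))
  base <- round(start_fraction * (L - 1) +
                  (seq_len(n) - 1) * (end_fraction - start_fraction) *
                  (L - 1) / (n - 1))
  lo <- round(start_fraction * (L - 1))
  hi <- round(end_fraction * (L - 1))
  lapply(seq_len(replicate_offsets) - 1L, function(r) {
    # shifted replicates stay clamped inside the sampled span
    idx <- pmin(pmax(base + r, lo), hi)
    kmer_list[unique(idx) + 1L]
  })
}

#' Stream-count query k-mers in a sequencing library
#'
#' Single pass over the library: for each query k-mer, the number of
#' occurrences across all reads (several occurrences in one read all
#' count). For unstranded libraries a window matching the query's
#' reverse complement also counts; stranded mode counts sense matches
#' only.
#'
#' @param files FASTQ/FASTA path(s) (e.g. both mates), DNAStringSet or
#'   character reads.
#' @param query_kmers character vector of query k-mers (one length).
#' @param mode `"unstranded"` (default) or `"stranded"`.
#' @return list(raw = named counts, total_reads = number of reads seen).
#' @export
stream_count <- function(files, query_kmers,
                         mode = c("unstranded", "stranded")) {
  mode <- match.arg(mode)
  if (!length(query_kmers)) stop("empty query set")
  seqs <- read_seqs(files)
  raw <- cpp_stream_count(seqs, query_kmers, mode == "unstranded")
  list(raw = setNames(raw, query_kmers), total_reads = length(seqs))
}

#' Counts per million reads
#'
#' @param raw raw counts.
#' @param library_total_reads total reads of the library (> 0).
#' @return `raw * 1e6 / library_total_reads`.
#' @export
normalize_counts <- function(raw, library_total_reads) {
  if (any(library_total_reads <= 0))
    stop("library total must be positive")
  raw * 1e6 / library_total_reads
}

#' Build probe k-mer sets for a contig catalog
#'
#' For each contig: its representative k-mer plus the reference-unique
#' k-mers sampled regularly along the contig in four shifted replicates.
#'
#' @param catalog a `contig_catalog` with `sequence` and
#'   `representative_kmer` columns.
#' @param index a `kmer_index` over the reference transcripts.
#' @param n,start_fraction,end_fraction,replicate_offsets see
#'   [regular_sample()].
#' @param mode uniqueness reading, see [unique_contig_kmers()].
#' @return data.frame: contig_id, kmer, role (`representative`,
#'   `sampled_r0` .. `sampled_r3`).
#' @export
probe_kmer_sets <- function(catalog, index, n = 10, start_fraction = 0.10,
                            end_fraction = 0.90, replicate_offsets = 4,
                            mode = "novel_or_unique") {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    uk <- unique_contig_kmers(catalog$sequence[i], index, mode)
    out <- data.frame(contig_id = catalog$contig_id[i],
                      kmer = catalog$representative_kmer[i],
                      role = "representative", stringsAsFactors = FALSE)
    if (length(uk)) {
      reps <- regular_sample(uk, n, start_fraction, end_fraction,
                             replicate_offsets)
      for (r in seq_along(reps))
        out <- rbind(out, data.frame(contig_id = catalog$contig_id[i],
                                     kmer = reps[[r]],
                                     role = sprintf("sampled_r%d", r - 1L),
                                     stringsAsFactors = FALSE))
    }
    out
  })
  do.call(rbind, rows)
}

#' Quantify probe k-mer sets across libraries
#'
#' Streams every library once, then aggregates per contig: the raw and
#' CPM-normalized representative count, and the mean count of the first
#' sampled replicate (further replicates are returned too).
#'
#' @param libraries list of per-library inputs (each a path vector or
#'   reads; e.g. `list(S1 = c(r1, r2), ...)`).
#' @param probes data.frame from [probe_kmer_sets()].
#' @param mode strand handling for [stream_count()].
#' @return list(raw, cpm, representative, sampled_mean, totals): matrices
#'   keyed by contig/k-mer and library.
#' @export
quantify_libraries <- function(libraries,
                               probes, mode = c("unstranded", "stranded")) {
  mode <- match.arg(mode)
  qk <- unique(probes$kmer)
  libs <- names(libraries) %||% paste0("L", seq_along(libraries))
  raw <- matrix(0, length(qk), length(libraries),
                dimnames = list(qk, libs))
  totals <- setNames(numeric(length(libraries)), libs)
  for (j in seq_along(libraries)) {
    sc <- stream_count(libraries[[j]], qk, mode)
    raw[, j] <- sc$raw
    totals[j] <- sc$total_reads
  }
  cpm <- sweep(raw, 2L, totals, function(x, t) x * 1e6 / t)
  ctg <- unique(probes$contig_id)
  rep_cpm <- t(vapply(ctg, function(cid) {
    km <- probes$kmer[probes$contig_id == cid &
                        probes$role == "representative"][1]
    cpm[km, ]
  }, numeric(length(libs))))
  samp_cpm <- lapply(sprintf("sampled_r%d", 0:3), function(role) {
    t(vapply(ctg, function(cid) {
      km <- probes$kmer[probes$contig_id == cid & probes$role == role]
      if (!length(km)) return(rep(NA_real_, length(libs)))
      colMeans(cpm[km, , drop = FALSE])
    }, numeric(length(libs))))
  })
  list(raw = raw, cpm = cpm, totals = totals,
       representative = rep_cpm, sampled_mean = samp_cpm[[1]],
       sampled_replicates = samp_cpm)
}

#' Representative-vs-sampled concordance per contig
#'
#' Pearson correlation, across libraries, of the representative k-mer
#' counts against the mean counts of the sampled k-mers. Contigs with a
#' zero-variance vector get `NA`.
#'
#' @param representative matrix contigs x libraries.
#' @param sampled_mean matrix contigs x libraries.
#' @return named numeric vector of Pearson r per contig.
#' @export
concordance <- function(representative, sampled_mean) {
  if (!all(dim(representative) == dim(sampled_mean)))
    stop("matrix dimensions differ")
  if (ncol(representative) < 3L)
    stop("need at least 3 libraries for a correlation")
  r <- vapply(seq_len(nrow(representative)), function(i) {
    x <- representative[i, ]
    y <- sampled_mean[i, ]
    if (sd(x) == 0 || sd(y) == 0 || anyNA(c(x, y))) return(NA_real_)
    cor(x, y)
  }, 0)
  names(r) <- rownames(representative)
  r
}
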