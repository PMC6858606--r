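#' Count k-mers from stranded read pairs
#'
#' Decomposes reads into k-mers in transcript orientation. Under the
#' `fr-firststrand` (dUTP) protocol mate-1 sequences are reverse-complemented
#' and mate-2 sequences taken as-is before decomposition; `fr-secondstrand`
#' is the mirror image; `unstranded` uses both mates as-is. Windows
#' containing non-ACGT characters are skipped.
#'
#' @param mate1 mate-1 reads: FASTQ/FASTA path, DNAStringSet, or character.
#' @param mate2 optional mate-2 reads (same forms).
#' @param k k-mer length, in \[2, 63\]; discovery runs use 31.
#' @param protocol library protocol.
#' @param sample_id label attached to the table.
#' @return a `kmer_counts` object: list(k, sample_id, counts) where
#'   `counts` is a named numeric vector of occurrence counts (>= 1).
#' @export
count_kmers <- function(mate1, mate2 = NULL, k = 31,
                        protocol = c("fr-firststrand", "fr-secondstrand",
                                     "unstranded"),
                        sample_id = "sample") {
  protocol <- match.arg(protocol)
  if (k < 2 || k > 63) stop("k must be in [2, 63]")
  r1 <- read_seqs(mate1)
  r2 <- if (!is.null(mate2)) read_seqs(mate2) else character()
  if (protocol == "fr-firststrand") {
    seqs <- c(revcomp(r1), r2)
  } else if (protocol == "fr-secondstrand") {
    seqs <- c(r1, if (length(r2)) revcomp(r2) else character())
  } else {
    seqs <- c(r1, r2)
  }
  res <- cpp_count_kmers(seqs, as.integer(k))
  counts <- setNames(res$count, res$kmer)
  structure(list(k = as.integer(k), sample_id = sample_id, counts = counts),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("kmer_counts [", x$sample_id, "]: ", length(x$counts),
      " distinct ", x$k, "-mers, total ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' Build a strand-specific k-mer mask from transcript sequences
#'
#' The mask contains exactly the k-mers of the given transcript (sense)
#' sequences. Reverse complements are NOT added: masking is
#' strand-specific, so antisense k-mers of annotated transcripts survive
#' masking and remain discoverable.
#'
#' @param transcripts transcript sequences (FASTA path, DNAStringSet or
#'   character), sense orientation.
#' @param k k-mer length.
#' @return a `kmer_set`: list(k, members).
#' @export
build_mask <- function(transcripts, k = 31) {
  seqs <- read_seqs(transcripts)
  if (length(seqs) == 0 || all(nchar(seqs) < k)) {
    warning("empty transcript input: mask is empty")
    return(structure(list(k = as.integer(k), members = character()),
                     class = "kmer_set"))
  }
  res <- cpp_count_kmers(seqs, as.integer(k))
  structure(list(k = as.integer(k), members = res$kmer), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("kmer_set:", length(x$members), "distinct", paste0(x$k, "-mers"), "\n")
  invisible(x)
}

#' Remove masked k-mers from a count table
#'
#' @param table a `kmer_counts`.
#' @param mask a `kmer_set` with the same k.
#' @return the filtered `kmer_counts`; counts of surviving keys unchanged.
#' @export
apply_mask <- function(table, mask) {
  stopifnot(inherits(table, "kmer_counts"), inherits(mask, "kmer_set"))
  if (table$k != mask$k) stop("k mismatch: table k=", table$k,
                              ", mask k=", mask$k)
  if (length(mask$members))
    table$counts <- table$counts[!(names(table$counts) %in% mask$members)]
  table
}

#' Join per-sample k-mer tables under a recurrence filter
#'
#' A k-mer is retained iff its count is at least
#' `min_recurrence_abundance` in at least `min_recurrence` samples,
#' counted jointly over all samples of both conditions. Absent entries are
#' zero. Defaults follow the discovery run settings (6 samples at count
#' >= 5, k = 31).
#'
#' @param tables list of `kmer_counts` sharing one k, with distinct
#'   sample ids.
#' @param min_recurrence minimum number of samples.
#' @param min_recurrence_abundance minimum per-sample count.
#' @return a `joined_kmers` object: list(k, sample_ids, counts) with
#'   `counts` an integer matrix (k-mers x samples).
#' @export
join_samples <- function(tables, min_recurrence = 6,
                         min_recurrence_abundance = 5) {
  ks <- vapply(tables, `[[`, 0L, "k")
  if (length(unique(ks)) != 1L) stop("tables disagree on k")
  ids <- vapply(tables, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_id in tables")
  if (min_recurrence > length(tables))
    stop("min_recurrence exceeds the number of samples")
  dt <- rbindlist(lapply(tables, function(t)
    data.table(kmer = names(t$counts), sample = t$sample_id,
               count = as.numeric(t$counts))))
  pass <- dt[, list(n = sum(count >= min_recurrence_abundance)),
             by = "kmer"][n >= min_recurrence, kmer]
  if (length(pass) == 0L) {
    mat <- matrix(0, 0, length(ids), dimnames = list(NULL, ids))
    return(structure(list(k = ks[1], sample_ids = ids, counts = mat),
                     class = "joined_kmers"))
  }
  dt <- dt[dt$kmer %in% pass]
  wide <- dcast.data.table(dt, kmer ~ sample, value.var = "count", fill = 0)
  mat <- as.matrix(wide, rownames = "kmer")
  missing_cols <- setdiff(ids, colnames(mat))
  if (length(missing_cols)) {
    zero <- matrix(0, nrow(mat), length(missing_cols),
                   dimnames = list(rownames(mat), missing_cols))
    mat <- cbind(mat, zero)
  }
  mat <- mat[, ids, drop = FALSE]
  structure(list(k = ks[1], sample_ids = ids, counts = mat),
            class = "joined_kmers")
}

#' @export
print.joined_kmers <- function(x, ...) {
  cat("joined_kmers:", nrow(x$counts), "k-mers x", length(x$sample_ids),
      "samples (k =", paste0(x$k, ")"), "\n")
  invisible(x)
}

#' Write a joined k-mer matrix as TSV (kmer column + one column per sample)
#' @param joined a `joined_kmers`.
#' @param path output path.
#' @export
write_joined_tsv <- function(joined, path) {
  df <- data.frame(kmer = rownames(joined$counts), joined$counts,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
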