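# shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of character sequences
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# Accept a DNAStringSet, a character vector of sequences, or a FASTA/FASTQ
# file path, and return a character vector of sequences.
read_seqs <- function(x) {
  if (is(x, "DNAStringSet")) return(as.character(x))
  if (is(x, "XStringSet")) return(as.character(x))
  if (is.character(x) && length(x) >= 1 && all(file.exists(x))) {
    seqs <- unlist(lapply(x, function(f) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", f, ignore.case = TRUE))
        "fastq" else "fasta"
      if (fmt == "fastq") check_fastq(f)
      as.character(readDNAStringSet(f, format = fmt))
    }))
    return(unname(seqs))
  }
  if (is.character(x)) return(unname(x))
  stop("cannot interpret sequences: supply a DNAStringSet, a character ",
       "vector, or FASTA/FASTQ file path(s)")
}

# Minimal structural validation of a FASTQ file; reports the index of the
# first malformed record.
check_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  i <- 0L
  repeat {
    block <- readLines(con, n = 4000L)
    if (length(block) == 0L) break
    hdr <- block[seq(1L, length(block), by = 4L)]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad))
      stop("malformed FASTQ record ", i + bad[1L], " in ", path)
    if (length(block) %% 4L != 0L)
      stop("truncated FASTQ record ", i + length(hdr), " in ", path)
    i <- i + length(hdr)
  }
  invisible(TRUE)
}

# Write paired (or single) reads as plain 4-line FASTQ with constant quality.
write_fastq <- function(reads, path, ids = NULL) {
  ids <- ids %||% paste0("read", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
  writeLines(rbind(paste0("@", ids), reads, "+", qual), path)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("`", name, "` must be a single number")
  if (positive && x <= 0) stop("`", name, "` must be positive")
  invisible(x)
}
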