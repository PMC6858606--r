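# Shared small synthetic cohort, built once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixtures <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    cfg <- sim_config(genome_length = 2e5, n_genes = 40, n_events = 6,
                      n_per_group = c(4L, 6L), seed = 7,
                      mean_expression = 40)
    ref <- make_reference(cfg)
    truth <- plant_events(ref, cfg)
    sim <- simulate_reads(ref, truth, cfg, emit = c("fastq", "sam"))
    .fixtures$cohort <- list(cfg = cfg, ref = ref, truth = truth,
                             sim = sim)
  }
  .fixtures$cohort
}

# hand-written SAM with fully controlled proper pairs.
# reads: data.frame(qname, chrom, pos1, cigar1, minus1, pos2, cigar2, minus2)
# where mate 1 carries flag 0x40 and mate 2 flag 0x80.
write_test_sam <- function(reads, chrom_len = 100000L,
                           path = tempfile(fileext = ".sam"),
                           mapq = 60L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", reads$chrom[1], "\tLN:", chrom_len))
  f1 <- 1L + 2L + 64L + ifelse(reads$minus1, 16L, 0L) +
    ifelse(reads$minus2, 32L, 0L)
  f2 <- 1L + 2L + 128L + ifelse(reads$minus2, 16L, 0L) +
    ifelse(reads$minus1, 32L, 0L)
  l1 <- paste(reads$qname, f1, reads$chrom, reads$pos1, mapq, reads$cigar1,
              "=", reads$pos2, 0L, "*", "*", sep = "\t")
  l2 <- paste(reads$qname, f2, reads$chrom, reads$pos2, mapq, reads$cigar2,
              "=", reads$pos1, 0L, "*", "*", sep = "\t")
  body <- c(l1, l2)[order(c(reads$pos1, reads$pos2))]
  writeLines(c(hdr, body), path)
  path
}

# proper pair on the transcript (plus) strand under the dUTP convention:
# mate 1 on the minus strand, mate 2 on the plus strand
plus_pair <- function(qname, chrom, start, read_len = 50L, frag_len = 150L,
                      cigar = NULL) {
  cg <- cigar %||% paste0(read_len, "M")
  data.frame(qname = qname, chrom = chrom,
             pos1 = start + frag_len - read_len, cigar1 = cg,
             minus1 = TRUE,
             pos2 = start, cigar2 = cg, minus2 = FALSE,
             stringsAsFactors = FALSE)
}

random_kmer <- function(n, k) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
          collapse = ""), "")
}
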