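test_that("unitig assembly merges overlapping k-mers and guards self-loops", {
  c1 <- assemble_contigs(c("ACGTA", "CGTAC"), k = 5)
  expect_equal(c1$sequence, "ACGTAC")
  expect_equal(c1$n_kmers, 2)
  # homopolymer self-loop: no infinite extension
  c2 <- assemble_contigs("AAAAA", k = 5)
  expect_equal(c2$sequence, "AAAAA")
  # branch stops extension: AAC has two successors ACA and ACG
  c3 <- assemble_contigs(c("AAC", "ACA", "ACG"), k = 3)
  expect_equal(sort(c3$sequence), c("AAC", "ACA", "ACG"))
})

test_that("representative k-mer carries the smallest adjusted p, ties lexicographic", {
  de <- data.frame(feature = c("ACGTA", "CGTAC", "GTACG"),
                   adjusted_p = c(0.01, 0.001, 0.001),
                   log2_fold_change = c(1, 2, 3))
  ctg <- assemble_contigs(de, k = 5)
  expect_equal(ctg$sequence, "ACGTACG")
  expect_equal(ctg$representative_kmer, "CGTAC")
  expect_equal(ctg$adjusted_p, 0.001)
  expect_equal(ctg$log2_fold_change, 2)
})

test_that("decompose-and-reassemble round-trips random sequences", {
  set.seed(20)
  k <- 31
  seqs <- random_kmer(50, 0) # placeholder, rebuilt below
  seqs <- vapply(sample(60:300, 50, replace = TRUE), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""), "")
  kmers <- unique(unlist(lapply(seqs, function(s)
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))))
  ctg <- assemble_contigs(kmers, k)
  expect_setequal(ctg$sequence, seqs)
  # partition invariant: every DE k-mer in exactly one contig
  expect_equal(sum(ctg$n_kmers), length(kmers))
  expect_equal(anyDuplicated(unlist(ctg$members)), 0)
})

test_that("alignment finds strands, splices and absences", {
  set.seed(21)
  intron <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                  collapse = "")
  left <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                collapse = "")
  exon1 <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                 collapse = "")
  exon2 <- paste(sample(c("A", "C", "G", "T"), 70, replace = TRUE),
                 collapse = "")
  minus_ctg <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                     collapse = "")
  genome <- DNAStringSet(setNames(paste0(
    left, exon1, intron, exon2, revcomp(minus_ctg),
    paste(rep("T", 200), collapse = "")), "chrT"))
  catalog <- data.frame(
    contig_id = c("c_minus", "c_spliced", "c_absent"),
    sequence = c(minus_ctg, paste0(exon1, exon2),
                 paste(rep(c("A", "C"), 60), collapse = "")),
    length = c(120, 150, 120),
    adjusted_p = 1e-4, log2_fold_change = 3,
    stringsAsFactors = FALSE)
  al <- align_contigs(catalog, genome, k = 31)
  al <- categorize_alignment(al)
  expect_equal(al$strand[1], "-")
  expect_equal(al$category[1], "contiguous")
  expect_equal(al$category[2], "spliced")
  expect_equal(al$n_blocks[2], 2)
  bl <- attr(al, "blocks")[["c_spliced"]]
  expect_equal(start(bl[2]) - end(bl[1]) - 1, 500) # gap = intron length
  expect_equal(al$category[3], "unmapped")
  expect_equal(al$n_sites[3], 0)
})

test_that("multiplicity takes precedence over splicing", {
  set.seed(22)
  ctg <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                  replace = TRUE), collapse = "")
  genome <- DNAStringSet(setNames(paste0(pad(200), ctg, pad(300), ctg,
                                         pad(100)), "chrT"))
  catalog <- data.frame(contig_id = "dup", sequence = ctg, length = 100,
                        adjusted_p = 1e-3, log2_fold_change = 2,
                        stringsAsFactors = FALSE)
  al <- categorize_alignment(align_contigs(catalog, genome, k = 31))
  expect_equal(al$n_sites, 2)
  expect_equal(al$category, "repeat")
})

test_that("location classification follows the coding > OL > AS > Inter precedence", {
  ann <- GRanges("chr1",
                 IRanges(c(1000, 1000, 5000, 5000, 9000, 9000),
                         c(3000, 1500, 7000, 5500, 9400, 9200)),
                 strand = c("+", "+", "+", "+", "-", "-"),
                 type = rep(c("gene", "exon"), 3),
                 biotype = c("protein_coding", "protein_coding",
                             "lncRNA", "lncRNA", "protein_coding",
                             "protein_coding"))
  catalog <- data.frame(
    contig_id = paste0("c", 1:5),
    length = 300, adjusted_p = 1e-4, log2_fold_change = 2,
    chrom = "chr1",
    start = c(1200, 2000, 6000, 9100, 20000),
    end = c(1400, 2200, 6200, 9300, 20300),
    strand = c("+", "-", "+", "+", "+"),
    n_sites = 1L, n_blocks = 1L,
    category = "contiguous", stringsAsFactors = FALSE)
  out <- classify_location(catalog, ann)
  # same-strand protein-coding exon; antisense over gene extent; lncRNA
  # intron overlap is OL by gene extent; opposite-strand over coding; none
  expect_equal(out$location, c("coding", "AS", "OL", "AS", "Inter"))
})

test_that("location labels agree with a brute-force all-pairs scan", {
  set.seed(23)
  n_genes <- 60
  gs <- sort(sample(seq(1, 2e5, by = 2500), n_genes))
  genes <- GRanges("chr1", IRanges(gs, width = sample(500:2000, n_genes,
                                                      replace = TRUE)),
                   strand = sample(c("+", "-"), n_genes, TRUE),
                   type = "gene",
                   biotype = sample(c("protein_coding", "lncRNA"),
                                    n_genes, TRUE))
  exons <- genes
  exons$type <- "exon"
  ann <- c(genes, exons)
  m <- 150
  catalog <- data.frame(
    contig_id = paste0("c", seq_len(m)), length = 250,
    adjusted_p = 1e-4, log2_fold_change = 1, chrom = "chr1",
    start = sample(1:2.1e5, m), strand = sample(c("+", "-"), m, TRUE),
    n_sites = 1L, n_blocks = 1L, category = "contiguous",
    stringsAsFactors = FALSE)
  catalog$end <- catalog$start + 249L
  got <- classify_location(catalog, ann)$location
  gdf <- as.data.frame(genes)
  want <- vapply(seq_len(m), function(i) {
    hit <- catalog$start[i] <= gdf$end & gdf$start <= catalog$end[i]
    same <- hit & gdf$strand == catalog$strand[i]
    if (any(same & gdf$biotype == "protein_coding")) return("coding")
    if (any(same & gdf$biotype == "lncRNA")) return("OL")
    if (any(hit & gdf$strand != catalog$strand[i])) return("AS")
    "Inter"
  }, "")
  expect_equal(got, want)
})

test_that("catalog filters apply strict boundaries and drop coding", {
  catalog <- data.frame(
    contig_id = paste0("c", 1:5),
    length = c(200, 250, 250, 250, 250),
    adjusted_p = c(0.001, 0.009, 0.01, 0.001, 0.001),
    log2_fold_change = 2, chrom = "chr1", start = 1, end = 2,
    strand = "+", n_sites = 1L, n_blocks = 1L,
    category = c("contiguous", "contiguous", "contiguous", "contiguous",
                 "unmapped"),
    location = c("Inter", "Inter", "Inter", "coding", "unassigned"),
    stringsAsFactors = FALSE)
  out <- filter_catalog(catalog)
  # length exactly 200 excluded; padj exactly 0.01 excluded; coding out;
  # unmapped kept by category
  expect_setequal(out$contig_id, c("c2", "c5"))
  out2 <- filter_catalog(catalog, keep_categories = c("contiguous",
                                                      "spliced"))
  expect_setequal(out2$contig_id, "c2")
})

test_that("window deduplication is single-linkage with lowest-p survivors", {
  mk <- function(id, start, end, p)
    data.frame(contig_id = id, length = 300, adjusted_p = p,
               log2_fold_change = 2, chrom = "chr1", start = start,
               end = end, strand = "+", n_sites = 1L, n_blocks = 1L,
               category = "contiguous", location = "Inter",
               stringsAsFactors = FALSE)
  # 3 kb apart: one survivor (the lower p)
  cat1 <- rbind(mk("a", 1000, 1200, 1e-5), mk("b", 4200, 4400, 1e-3))
  expect_equal(window_dedup(cat1, 5000)$contig_id, "a")
  # 6 kb apart: both survive
  cat2 <- rbind(mk("a", 1000, 1200, 1e-5), mk("b", 7200, 7400, 1e-3))
  expect_equal(window_dedup(cat2, 5000)$contig_id, c("a", "b"))
  # chain a-b 4 kb, b-c 4 kb, a-c 8 kb: single linkage keeps one
  cat3 <- rbind(mk("a", 1000, 1200, 1e-3), mk("b", 5200, 5400, 1e-6),
                mk("c", 9400, 9600, 1e-4))
  expect_equal(window_dedup(cat3, 5000)$contig_id, "b")
  # unmapped contigs pass through
  un <- mk("u", NA, NA, 1e-3)
  un$chrom <- NA
  un$category <- "unmapped"
  cat4 <- rbind(cat1, un)
  expect_true("u" %in% window_dedup(cat4, 5000)$contig_id)
})

test_that("overlap fractions are one-directional unless reciprocal", {
  # half-open [0,100) and [50,200) in 1-based closed coordinates
  x <- GRanges("chr1", IRanges(1, 100))
  y <- GRanges("chr1", IRanges(51, 200))
  hit <- overlap_fraction(x, y, fraction = 0.5)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$overlap_bp, 50)
  # overlap 40: query fraction 0.4 passes alone but reciprocal fails
  # because the subject fraction is 40/140
  x2 <- GRanges("chr1", IRanges(1, 100))
  y2 <- GRanges("chr1", IRanges(61, 200))
  expect_equal(nrow(overlap_fraction(x2, y2, 0.5)), 0)
  expect_equal(nrow(overlap_fraction(x2, y2, 0.4)), 1)
  expect_equal(nrow(overlap_fraction(x2, y2, 0.4, reciprocal = TRUE)), 0)
  # disjoint
  expect_equal(nrow(overlap_fraction(
    GRanges("chr1", IRanges(1, 10)),
    GRanges("chr1", IRanges(50, 60)), 0.1)), 0)
  # strand-aware when both stranded
  xs <- GRanges("chr1", IRanges(1, 100), strand = "+")
  ys <- GRanges("chr1", IRanges(1, 100), strand = "-")
  expect_equal(nrow(overlap_fraction(xs, ys, 0.5)), 0)
})
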