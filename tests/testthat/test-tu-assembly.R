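test_that("segment merging respects the strict sub-100-nt gap rule", {
  # half-open [100,300)+[399,600): gap 99 -> merged
  g1 <- GRanges("chr1", IRanges(c(101, 400), c(300, 599)), strand = "+")
  m1 <- merge_segments(g1, 100)
  expect_equal(length(m1), 1)
  expect_equal(start(m1), 101)
  expect_equal(end(m1), 599)
  # gap 100 -> not merged
  g2 <- GRanges("chr1", IRanges(c(101, 401), c(300, 599)), strand = "+")
  expect_equal(length(merge_segments(g2, 100)), 2)
  # opposite strands never merge, even at gap 0
  g3 <- GRanges("chr1", IRanges(c(101, 301), c(300, 500)),
                strand = c("+", "-"))
  expect_equal(length(merge_segments(g3, 100)), 2)
})

test_that("segment merging is idempotent and equals brute-force merging", {
  set.seed(30)
  n <- 2000
  st <- sample(1:5e5, n, replace = TRUE)
  gr <- GRanges("chr1", IRanges(st, width = sample(50:400, n, TRUE)),
                strand = sample(c("+", "-"), n, TRUE))
  m <- merge_segments(gr, 100)
  expect_identical(merge_segments(m, 100), m)
  # brute force per strand: sort, chain while gap < 100
  for (s in c("+", "-")) {
    iv <- as.data.frame(sort(gr[strand(gr) == s]))
    merged <- list()
    cs <- iv$start[1]; ce <- iv$end[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] - ce - 1 < 100) ce <- max(ce, iv$end[i])
      else { merged[[length(merged) + 1]] <- c(cs, ce)
             cs <- iv$start[i]; ce <- iv$end[i] }
    }
    merged[[length(merged) + 1]] <- c(cs, ce)
    bf <- do.call(rbind, merged)
    ms <- m[strand(m) == s]
    expect_equal(start(ms), bf[, 1])
    expect_equal(end(ms), bf[, 2])
  }
})

test_that("covered intervals require 10 supporting reads in one sample", {
  # 6 stacked pairs (12 reads) at locus A; 4 pairs (8 reads) at locus B
  reads_a <- do.call(rbind, lapply(1:6, function(i)
    plus_pair(paste0("a", i), "chr1", 1001, frag_len = 60)))
  reads_b <- do.call(rbind, lapply(1:4, function(i)
    plus_pair(paste0("b", i), "chr1", 5001, frag_len = 60)))
  sam <- write_test_sam(rbind(reads_a, reads_b))
  aln <- read_alignments(sam, min_mapq = 50)
  segs <- coverage_segments(list(aln), min_reads = 10)
  expect_equal(length(segs), 1)
  expect_equal(start(segs), 1001)
  expect_equal(segs$max_support, 12)
  # adjacent spans from two samples form a single union interval
  sam2 <- write_test_sam(do.call(rbind, lapply(1:6, function(i)
    plus_pair(paste0("c", i), "chr1", 1031, frag_len = 60))))
  aln2 <- read_alignments(sam2)
  segs2 <- coverage_segments(list(aln, aln2), min_reads = 10)
  expect_equal(length(segs2), 1)
  expect_equal(c(start(segs2), end(segs2)), c(1001, 1090))
})

test_that("TU contexts and the strict 200-nt rule classify segments", {
  ann <- GRanges("chr1", IRanges(c(2000, 9000), c(4000, 9500)),
                 strand = c("+", "+"), type = "gene",
                 biotype = c("protein_coding", "protein_coding"))
  segs <- GRanges("chr1",
                  IRanges(c(2500, 2500, 6000, 6000), width = c(500, 500,
                                                               150, 500)),
                  strand = c("-", "+", "+", "+"))
  tu <- classify_tu(segs, ann)
  expect_equal(tu$context, c("antisense", "sense_overlap", "intergenic",
                             "intergenic"))
  expect_equal(tu$retained, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("fragment counting follows -p -s 2 -O semantics", {
  feats <- GRanges("chr1", IRanges(c(1000, 1100, 5000), c(1200, 1300,
                                                          5400)),
                   strand = c("+", "+", "+"))
  # one proper plus-strand pair inside feature 1+2 overlap region
  pr <- plus_pair("p1", "chr1", 1101, frag_len = 80)
  # an antisense fragment (pair strand -) in feature 3
  anti <- data.frame(qname = "m1", chrom = "chr1",
                     pos1 = 5100, cigar1 = "50M", minus1 = FALSE,
                     pos2 = 5200, cigar2 = "50M", minus2 = TRUE,
                     stringsAsFactors = FALSE)
  sam <- write_test_sam(rbind(pr, anti))
  aln <- read_alignments(sam)
  cm <- count_in_features(list(s1 = aln), feats)
  # fragments (not mates) are counted, in every overlapped feature
  expect_equal(unname(cm[, 1]), c(1, 1, 0))
  # multi_overlap = FALSE drops ambiguous fragments
  cm2 <- count_in_features(list(s1 = aln), feats, multi_overlap = FALSE)
  expect_equal(unname(cm2[, 1]), c(0, 0, 0))
})

test_that("RPKM follows its unit definition", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(10, 1000, 2e6), 5)
  expect_error(rpkm(1, 0, 10), "positive")
})

test_that("junctions come from gapped alignments with pair strands", {
  pr <- plus_pair("j1", "chr1", 1001, frag_len = 150)
  pr$cigar2 <- "20M100N30M"
  sam <- write_test_sam(pr)
  aln <- read_alignments(sam)
  jx <- extract_junctions(list(aln))
  expect_equal(length(jx), 1)
  expect_equal(start(jx), 1021)
  expect_equal(end(jx), 1120)
  expect_equal(as.character(strand(jx)), "+")
  expect_equal(jx$n_reads, 1)
})

test_that("expression classes combine the quantile rule with evidence", {
  tus <- GRanges("chr1", IRanges(c(1000, 3000, 5000), width = 400),
                 strand = "+", tu_id = paste0("TU", 1:3),
                 context = "intergenic", retained = TRUE)
  cond <- c("A", "A", "B", "B")
  mrna <- matrix(rep(c(1, 2, 5, 10, 20), 4), 5, 4) # mRNA RPKM reference
  tu_rpkm <- rbind(c(50, 50, 50, 50),   # far above threshold
                   c(50, 50, 50, 50),
                   c(0.1, 0.1, 0.1, 0.1)) # below
  jx <- GRanges("chr1", IRanges(1100, 1300), strand = "+", n_reads = 3)
  ests <- GRangesList(e1 = GRanges("chr1", IRanges(c(1000, 1250),
                                                   c(1100, 1380)),
                                   strand = "+"))
  out <- assign_classes(tus, tu_rpkm, mrna, cond, junctions = jx,
                        ests = ests)
  expect_equal(out$class, c("class1", "class2", "below_threshold"))
  expect_error(assign_classes(tus, tu_rpkm, mrna[0, ], cond),
               "mRNA")
})

test_that("planted transcripts reappear as strand-matched TUs", {
  co <- small_cohort()
  tu <- assemble_tus(co$sim$design$sam, co$ref$annotation,
                     co$sim$design$condition, ests = co$ref$ests)
  truth <- co$truth
  tg <- GRanges(truth$chrom, IRanges(truth$start, truth$end),
                strand = truth$strand)
  ov <- overlap_fraction(tg, tu$catalog, fraction = 0.8)
  expect_equal(length(unique(ov$query)), nrow(truth))
})
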