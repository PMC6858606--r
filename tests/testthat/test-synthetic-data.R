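test_that("reference generation is deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 5e4, n_genes = 10, n_events = 2,
                    seed = 3)
  r1 <- make_reference(cfg)
  r2 <- make_reference(cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(as.character(r1$transcripts),
                   as.character(r2$transcripts))
  expect_equal(sum(r1$annotation$type == "gene"), 10)
})

test_that("different seeds change the genome but not the dimensions", {
  c1 <- sim_config(genome_length = 5e4, n_genes = 10, seed = 1)
  c2 <- sim_config(genome_length = 5e4, n_genes = 10, seed = 2)
  r1 <- make_reference(c1)
  r2 <- make_reference(c2)
  expect_false(as.character(r1$genome[[1]]) == as.character(r2$genome[[1]]))
  expect_equal(length(r1$transcripts), length(r2$transcripts))
  expect_equal(sum(r1$annotation$type == "gene"),
               sum(r2$annotation$type == "gene"))
})

test_that("zero genes yields an empty annotation but a genome", {
  cfg <- sim_config(genome_length = 2e4, n_genes = 0, n_events = 0,
                    seed = 1)
  ref <- make_reference(cfg)
  expect_equal(length(ref$annotation), 0)
  expect_equal(sum(BiocGenerics::width(ref$genome)), 2e4)
})

test_that("a genome too short for the requested genes errors", {
  cfg <- sim_config(genome_length = 5e3, n_genes = 50, seed = 1)
  expect_error(make_reference(cfg), "too short")
})

test_that("planted events satisfy their class definitions (independent scan)", {
  co <- small_cohort()
  truth <- co$truth
  ann <- as.data.frame(co$ref$annotation)
  genes <- ann[ann$type == "gene", ]
  # brute-force interval overlap, no GenomicRanges
  overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
  for (i in seq_len(nrow(truth))) {
    hit <- overlaps(truth$start[i], truth$end[i], genes$start, genes$end)
    if (truth$type[i] == "intergenic_lnc") {
      expect_false(any(hit), label = truth$event_id[i])
    } else if (truth$type[i] == "antisense_lnc") {
      expect_true(any(hit & genes$strand != truth$strand[i]))
      expect_false(any(hit & genes$strand == truth$strand[i]))
    }
  }
})

test_that("planted fold changes respect the configured floor", {
  co <- small_cohort()
  expect_true(all(2^co$truth$log2_effect >= co$cfg$effect_floor))
})

test_that("true counts, emitted reads and library totals agree", {
  co <- small_cohort()
  sim <- co$sim
  for (s in seq_len(nrow(sim$design))) {
    nfrag <- sum(sim$counts[, s])
    expect_equal(sim$design$total_reads[s], 2 * nfrag)
    n_lines <- length(readLines(sim$design$fastq_1[s]))
    expect_equal(n_lines, 4 * nfrag)
  }
})

test_that("fr-firststrand pairs are oriented mate-2 sense, mate-1 antisense", {
  cfg <- sim_config(genome_length = 4e4, n_genes = 6, n_events = 1,
                    n_per_group = c(1L, 1L), substitution_rate = 0,
                    seed = 13, mean_expression = 20)
  ref <- make_reference(cfg)
  truth <- plant_events(ref, cfg)
  sim <- simulate_reads(ref, truth, cfg, emit = "fastq")
  tx <- as.character(sim$transcripts)
  r2 <- as.character(readDNAStringSet(sim$design$fastq_2[1],
                                      format = "fastq"))
  r1 <- as.character(readDNAStringSet(sim$design$fastq_1[1],
                                      format = "fastq"))
  in_tx <- function(reads) vapply(reads, function(r)
    any(vapply(tx, function(t) grepl(r, t, fixed = TRUE), TRUE)), TRUE)
  expect_true(all(in_tx(sample(r2, min(50, length(r2))))))
  expect_true(all(in_tx(revcomp(sample(r1, min(50, length(r1)))))))
})

test_that("planted effects shift group means by about 2^log2_effect", {
  # fixed 8-fold effect, tight dispersion, averaged over 10+10 samples
  cfg <- sim_config(genome_length = 1e5, n_genes = 10, n_events = 3,
                    n_per_group = c(10L, 10L), nb_dispersion = 0.02,
                    effect_floor = 8, effect_max = 8, seed = 21,
                    mean_expression = 30)
  ref <- make_reference(cfg)
  truth <- plant_events(ref, cfg)
  sim <- simulate_reads(ref, truth, cfg, emit = "fastq")
  ev <- sim$counts[sim$tx_info$is_event, , drop = FALSE]
  grpA <- sim$design$condition == "A"
  ratio <- rowMeans(ev[, !grpA]) / rowMeans(ev[, grpA])
  expect_true(all(abs(ratio - 8) / 8 < 0.25))
})

test_that("Poisson limit holds when dispersion is zero", {
  cfg <- sim_config(genome_length = 5e4, n_genes = 8, n_events = 0,
                    n_per_group = c(15L, 15L), nb_dispersion = 0,
                    seed = 4, mean_expression = 50)
  ref <- make_reference(cfg)
  sim <- simulate_reads(ref, NULL, cfg, emit = "fastq")
  vm <- apply(sim$counts, 1, var) / rowMeans(sim$counts)
  # variance-to-mean ratio concentrates near 1
  expect_lt(median(vm), 2)
  expect_gt(median(vm), 0.5)
})

test_that("fragment length below read length is a configuration error", {
  cfg <- sim_config(genome_length = 5e4, n_genes = 5, n_events = 0,
                    fragment_mean = 50, read_length = 75, seed = 1)
  ref <- make_reference(cfg)
  expect_error(simulate_reads(ref, NULL, cfg), "configuration error")
})

test_that("probe tables carry controls, effects and labels as configured", {
  pm <- make_probe_table(n_targets = 23, n_per_class = c(9, 135),
                         target_fc = 6, seed = 2)
  expect_equal(sum(pm$roles == "target"), 23)
  expect_equal(sum(pm$roles == "housekeeping"), 6)
  expect_equal(sum(pm$roles == "benchmark"), 1)
  expect_true(all(c("positive_control", "negative_control") %in% pm$roles))
  tum <- pm$samples$condition == "tumor"
  # housekeeping: no class effect
  hk <- pm$values[pm$roles == "housekeeping", , drop = FALSE]
  hk_ratio <- rowMeans(hk[, tum]) / rowMeans(hk[, !tum])
  expect_true(all(hk_ratio > 0.7 & hk_ratio < 1.4))
  # targets at FC 6: empirical FC within [4, 9]
  tg <- pm$values[pm$roles == "target", , drop = FALSE]
  fc <- rowMeans(tg[, tum]) / rowMeans(tg[, !tum])
  expect_true(all(fc > 4 & fc < 9))
})

test_that("a 29-row assay request yields 29 assay rows plus controls", {
  pm <- make_probe_table(n_targets = 22, n_housekeeping = 6, seed = 1)
  assay <- pm$roles %in% c("target", "housekeeping", "benchmark")
  expect_equal(sum(assay), 29)
  expect_gt(sum(!assay), 0)
})

test_that("zero samples in a class errors", {
  expect_error(make_probe_table(n_per_class = c(0, 10)), "class")
})
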