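#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic stranded RNA-seq
#' cohort generator. Defaults describe a desk-scale two-condition cohort:
#' a 1-Mb single-chromosome genome carrying 200 multi-exon genes, 20 planted
#' novel noncoding transcripts with at least a six-fold up-shift in the
#' second condition, and 8 vs 16 libraries of 75-nt paired-end reads from a
#' dUTP-type (fr-firststrand) protocol with negative-binomial count noise.
#'
#' @param genome_length genome size in bp.
#' @param n_genes number of annotated genes to place.
#' @param n_events number of novel transcripts to plant.
#' @param n_per_group integer pair: samples in condition A (e.g. normal) and
#'   condition B (e.g. tumor).
#' @param read_length read length in bp.
#' @param fragment_mean,fragment_sd fragment length distribution in bp.
#' @param substitution_rate per-base substitution error rate, in \[0, 0.1\].
#' @param nb_dispersion negative-binomial dispersion of per-transcript
#'   fragment counts (0 gives Poisson counts).
#' @param protocol one of `"fr-firststrand"`, `"fr-secondstrand"`,
#'   `"unstranded"`.
#' @param seed integer seed; all generator stages derive their streams from
#'   it, so a fixed seed reproduces the cohort exactly.
#' @param mean_expression median background expression (mean fragments per
#'   annotated transcript and sample).
#' @param event_types event classes to cycle through when planting; any of
#'   `"intergenic_lnc"`, `"antisense_lnc"`, `"exon_extension"`,
#'   `"splice_variant"`.
#' @param effect_floor,effect_max bounds of the planted fold change
#'   (uniform on the log2 scale).
#' @param baseline_mean_range range of the condition-A mean fragment count
#'   of planted transcripts.
#' @param event_length_range planted transcript length range in bp.
#' @param event_spacing minimum genomic distance between planted events
#'   (bp); events model distinct loci, so they are kept farther apart
#'   than the catalog's deduplication window.
#' @param est_fraction fraction of multi-exon transcripts that receive a
#'   matching spliced EST record.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6, n_genes = 200, n_events = 20,
                       n_per_group = c(8L, 16L), read_length = 75,
                       fragment_mean = 250, fragment_sd = 40,
                       substitution_rate = 0.005, nb_dispersion = 0.2,
                       protocol = c("fr-firststrand", "fr-secondstrand",
                                    "unstranded"),
                       seed = 1L, mean_expression = 80,
                       event_types = c("intergenic_lnc", "antisense_lnc"),
                       effect_floor = 6, effect_max = 12,
                       baseline_mean_range = c(30, 80),
                       event_length_range = c(300, 800),
                       event_spacing = 6000, est_fraction = 0.7) {
  protocol <- match.arg(protocol)
  stopifnot_scalar(genome_length, "genome_length")
  if (n_genes < 0 || n_events < 0) stop("counts must be non-negative")
  if (length(n_per_group) != 2L || any(n_per_group < 1))
    stop("`n_per_group` must be two positive counts")
  stopifnot_scalar(read_length, "read_length")
  stopifnot_scalar(fragment_mean, "fragment_mean")
  if (substitution_rate < 0 || substitution_rate > 0.1)
    stop("`substitution_rate` must be in [0, 0.1]")
  if (nb_dispersion < 0) stop("`nb_dispersion` must be >= 0")
  if (effect_floor < 1 || effect_max < effect_floor)
    stop("effect bounds must satisfy 1 <= effect_floor <= effect_max")
  cfg <- list(genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes), n_events = as.integer(n_events),
              n_per_group = as.integer(n_per_group),
              read_length = as.integer(read_length),
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              substitution_rate = substitution_rate,
              nb_dispersion = nb_dispersion, protocol = protocol,
              seed = as.integer(seed), mean_expression = mean_expression,
              event_types = event_types, effect_floor = effect_floor,
              effect_max = effect_max,
              baseline_mean_range = baseline_mean_range,
              event_length_range = as.integer(event_length_range),
              event_spacing = as.integer(event_spacing),
              est_fraction = est_fraction)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [sim_config()].
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to read YAML configurations")
  do.call(sim_config, yaml::read_yaml(path))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome, annotation and transcript set
#'
#' Places `n_genes` non-overlapping multi-exon gene models (protein-coding
#' and lncRNA, both strands) on a random genome, derives their spliced
#' transcript sequences, and emits spliced EST records for a configurable
#' fraction of multi-exon transcripts.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_reference` list with elements `genome` (DNAStringSet),
#'   `annotation` (GRanges with `type` gene/exon, `gene_id`, `biotype`),
#'   `transcripts` (DNAStringSet, sense orientation), `exons` (GRangesList
#'   per gene, genomic order), and `ests` (GRangesList of spliced EST
#'   blocks).
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom <- "chr1"
  genome <- DNAStringSet(setNames(random_dna(cfg$genome_length), chrom))

  if (cfg$n_genes == 0L) {
    ann <- GRanges(seqinfo = Seqinfo(chrom, cfg$genome_length))
    mcols(ann) <- DataFrame(type = character(), gene_id = character(),
                            biotype = character())
    out <- list(genome = genome, annotation = ann,
                transcripts = DNAStringSet(),
                exons = GRangesList(),
                ests = GRangesList(), cfg = cfg)
    class(out) <- "sim_reference"
    return(out)
  }

  n <- cfg$n_genes
  n_ex <- sample(1:4, n, replace = TRUE)
  struct <- lapply(n_ex, function(ne) {
    ex <- sample(120:400, ne, replace = TRUE)
    it <- if (ne > 1) sample(200:1200, ne - 1, replace = TRUE) else integer()
    list(ex = ex, it = it, span = sum(ex) + sum(it))
  })
  spans <- vapply(struct, `[[`, 0, "span")
  min_gap <- 400L
  need <- sum(spans) + (n + 1L) * min_gap
  if (need > cfg$genome_length)
    stop("genome too short to place ", n, " genes: need >= ", need, " bp")
  w <- runif(n + 1L)
  gaps <- min_gap + floor((cfg$genome_length - need) * w / sum(w))
  starts <- cumsum(gaps)[seq_len(n)] + c(0, cumsum(spans))[seq_len(n)] + 1L

  gene_id <- sprintf("G%03d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  biotype <- sample(c("protein_coding", "lncRNA"), n, replace = TRUE,
                    prob = c(0.75, 0.25))

  gene_rows <- GRanges(chrom, IRanges(starts, width = spans), strand = strand,
                       type = "gene", gene_id = gene_id, biotype = biotype)
  exon_list <- vector("list", n)
  for (i in seq_len(n)) {
    st <- struct[[i]]
    es <- starts[i] + c(0L, cumsum(st$ex + c(st$it, 0L)))[seq_along(st$ex)]
    exon_list[[i]] <- GRanges(chrom, IRanges(es, width = st$ex),
                              strand = strand[i], type = "exon",
                              gene_id = gene_id[i], biotype = biotype[i])
  }
  exons <- GRangesList(setNames(exon_list, gene_id))
  ann <- sort(c(gene_rows, unlist(exons, use.names = FALSE)),
              ignore.strand = TRUE)
  seqinfo(ann) <- Seqinfo(chrom, cfg$genome_length)

  gseq <- as.character(genome[[1]])
  tx <- vapply(seq_len(n), function(i) {
    ex <- exon_list[[i]]
    s <- paste(substring(gseq, start(ex), end(ex)), collapse = "")
    if (strand[i] == "-") s <- revcomp(s)
    s
  }, "")
  transcripts <- DNAStringSet(setNames(tx, gene_id))

  multi <- which(n_ex > 1)
  est_sel <- multi[runif(length(multi)) < cfg$est_fraction]
  ests <- GRangesList(setNames(exon_list[est_sel],
                               paste0("EST_", gene_id[est_sel])))

  out <- list(genome = genome, annotation = ann, transcripts = transcripts,
              exons = exons, ests = ests, cfg = cfg)
  class(out) <- "sim_reference"
  out
}

# sample one interval of width `len` avoiding `occupied` (IRanges, strand
# agnostic); returns NA when no gap fits
sample_free_interval <- function(len, occupied, genome_length, buffer = 100L) {
  free <- setdiff(IRanges(1L, genome_length),
                  resize(occupied, width(occupied) + 2L * buffer, fix = "center"))
  free <- free[width(free) >= len]
  if (length(free) == 0L) return(NULL)
  g <- free[sample.int(length(free), 1L)]
  s <- start(g) + sample.int(width(g) - len + 1L, 1L) - 1L
  IRanges(s, width = len)
}

#' Plant novel transcription events on a synthetic reference
#'
#' Places `cfg$n_events` novel transcripts of the requested classes and
#' draws their tumor effect sizes. Intergenic events overlap no annotated
#' gene on either strand; antisense events overlap a gene only on the
#' opposite strand; exon extensions prolong a terminal exon into gene-free
#' sequence; splice variants join two exons by a novel junction. Fold
#' changes are uniform on the log2 scale between `effect_floor` and
#' `effect_max`, so every event is up-shifted by at least the floor.
#'
#' @param ref a `sim_reference` from [make_reference()].
#' @param cfg the [sim_config()] used to build `ref`.
#' @return a `truth_manifest` data.frame (event_id, type, chrom, start, end,
#'   strand, log2_effect, baseline_mean) with attributes `event_seq`
#'   (named character, sense sequences) and `event_blocks` (GRangesList of
#'   genomic alignment blocks per event).
#' @export
plant_events <- function(ref, cfg) {
  stopifnot(inherits(ref, "sim_reference"))
  set.seed(cfg$seed + 1000L)
  n <- cfg$n_events
  genes <- ref$annotation[ref$annotation$type == "gene"]
  chrom <- names(ref$genome)[1]
  gseq <- as.character(ref$genome[[1]])
  types <- rep(cfg$event_types, length.out = n)

  occupied <- ranges(genes)      # gene footprints, both strands
  taken <- IRanges()             # event footprints
  spacing <- cfg$event_spacing %||% 6000L
  too_close <- function(span)
    length(taken) > 0L &&
      length(findOverlaps(span + spacing, taken)) > 0L

  rows <- vector("list", n)
  seqs <- character(n)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(seq(cfg$event_length_range[1], cfg$event_length_range[2]), 1L)
    ty <- types[i]
    placed <- FALSE
    for (try in 1:200) {
      if (ty == "intergenic_lnc") {
        iv <- sample_free_interval(len, c(occupied, taken),
                                   cfg$genome_length)
        if (is.null(iv)) break
        if (too_close(iv)) next
        strand <- sample(c("+", "-"), 1L)
        ev <- GRanges(chrom, iv, strand = strand)
        bl <- ev
        sq <- substring(gseq, start(iv), end(iv))
        if (strand == "-") sq <- revcomp(sq)
      } else if (ty == "antisense_lnc") {
        cand <- genes[width(genes) >= len + 40L]
        if (length(cand) == 0L) break
        g <- cand[sample.int(length(cand), 1L)]
        s <- start(g) + sample.int(width(g) - len + 1L, 1L) - 1L
        strand <- if (as.character(strand(g)) == "+") "-" else "+"
        ev <- GRanges(chrom, IRanges(s, width = len), strand = strand)
        # must not touch any gene on the event's own strand
        same <- genes[strand(genes) == strand]
        if (length(findOverlaps(ev, same, ignore.strand = FALSE)) > 0) next
        if (too_close(ranges(ev))) next
        bl <- ev
        sq <- substring(gseq, s, s + len - 1L)
        if (strand == "-") sq <- revcomp(sq)
      } else if (ty == "exon_extension") {
        cand <- genes
        g <- cand[sample.int(length(cand), 1L)]
        gs <- as.character(strand(g))
        ex <- ref$exons[[g$gene_id]]
        if (gs == "+") {
          term <- ex[which.max(end(ex))]
          reg <- IRanges(end(g) + 1L, width = len)
        } else {
          term <- ex[which.min(start(ex))]
          reg <- IRanges(start(g) - len, width = len)
        }
        if (start(reg) < 1L || end(reg) > cfg$genome_length) next
        if (length(findOverlaps(IRanges(start(reg), end(reg)),
                                c(occupied, taken))) > 0) next
        if (too_close(IRanges(start(reg), end(reg)))) next
        ev <- GRanges(chrom, reg, strand = gs)
        bl <- reduce(GRanges(chrom, c(ranges(term), reg), strand = gs))
        sq <- paste(substring(gseq, start(bl), end(bl)), collapse = "")
        if (gs == "-") sq <- revcomp(sq)
      } else if (ty == "splice_variant") {
        cand <- genes[vapply(genes$gene_id,
                             function(g) length(ref$exons[[g]]) >= 3L, TRUE)]
        if (length(cand) == 0L) break
        g <- cand[sample.int(length(cand), 1L)]
        ex <- sort(ref$exons[[g$gene_id]])
        gs <- as.character(strand(g))
        pair <- if (gs == "+") c(1L, 3L) else c(length(ex) - 2L, length(ex))
        bl <- GRanges(chrom, ranges(ex[pair]), strand = gs)
        ev <- GRanges(chrom, IRanges(min(start(bl)), max(end(bl))),
                      strand = gs)
        if (too_close(ranges(ev))) next
        sq <- paste(substring(gseq, start(bl), end(bl)), collapse = "")
        if (gs == "-") sq <- revcomp(sq)
      } else stop("unknown event type: ", ty)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("placement error: no free space for event ", i, " (", ty, ")")
    taken <- c(taken, IRanges(min(start(bl)), max(end(bl))))
    rows[[i]] <- data.frame(
      event_id = sprintf("EV%02d", i), type = ty, chrom = chrom,
      start = start(ev), end = end(ev),
      strand = as.character(strand(ev)),
      stringsAsFactors = FALSE)
    seqs[i] <- sq
    blocks[[i]] <- bl
  }

  truth <- do.call(rbind, rows)
  truth$log2_effect <- runif(n, log2(cfg$effect_floor), log2(cfg$effect_max))
  truth$baseline_mean <- runif(n, cfg$baseline_mean_range[1],
                               cfg$baseline_mean_range[2])
  names(seqs) <- truth$event_id
  attr(truth, "event_seq") <- seqs
  attr(truth, "event_blocks") <- GRangesList(setNames(blocks, truth$event_id))
  class(truth) <- c("truth_manifest", "data.frame")
  truth
}

#' Write / read a truth manifest as TSV
#' @param truth a `truth_manifest`.
#' @param path output TSV path.
#' @export
write_truth_manifest <- function(truth, path) {
  write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# substitution errors: mutate `reads` in place at per-base rate `rate`
add_substitutions <- function(reads, rate) {
  if (rate <= 0) return(reads)
  wid <- nchar(reads)
  nsub <- rbinom(length(reads), wid, rate)
  idx <- which(nsub > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(wid[i], nsub[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  reads
}

# map transcript-coordinate intervals [a, b] onto genomic blocks of one
# transcript; returns per-interval list(starts, ends) plus CIGAR
map_mate_blocks <- function(a, b, bs, be, minus, Lt) {
  wid <- be - bs + 1L
  cum <- cumsum(wid)
  c0 <- c(0L, cum)
  nb <- length(bs)
  nfrag <- length(a)
  if (minus) {
    tmp <- Lt - b + 1L
    b <- Lt - a + 1L
    a <- tmp
  }
  pos <- integer(nfrag)
  cigar <- character(nfrag)
  endg <- integer(nfrag)
  if (nb == 1L) {
    pos <- bs + a - 1L
    endg <- bs + b - 1L
    cigar <- paste0(b - a + 1L, "M")
    return(list(pos = pos, end = endg, cigar = cigar))
  }
  j1 <- findInterval(a - 1L, cum) + 1L
  j2 <- findInterval(b - 1L, cum) + 1L
  same <- j1 == j2
  pos[same] <- bs[j1[same]] + (a[same] - c0[j1[same]] - 1L)
  endg[same] <- bs[j2[same]] + (b[same] - c0[j2[same]] - 1L)
  cigar[same] <- paste0(b[same] - a[same] + 1L, "M")
  for (f in which(!same)) {
    js <- j1[f]:j2[f]
    gs <- pmax(bs[js], bs[j1[f]] + (a[f] - c0[j1[f]] - 1L))
    ge <- pmin(be[js], bs[j2[f]] + (b[f] - c0[j2[f]] - 1L))
    gs[1] <- bs[j1[f]] + (a[f] - c0[j1[f]] - 1L)
    ge[length(js)] <- bs[j2[f]] + (b[f] - c0[j2[f]] - 1L)
    gs[-1] <- bs[js[-1]]
    ge[-length(js)] <- be[js[-length(js)]]
    m <- ge - gs + 1L
    gaps <- gs[-1] - ge[-length(gs)] - 1L
    cigar[f] <- paste0(paste0(m[-length(m)], "M", gaps, "N", collapse = ""),
                       m[length(m)], "M")
    pos[f] <- gs[1]
    endg[f] <- ge[length(ge)]
  }
  list(pos = pos, end = endg, cigar = cigar)
}

#' Simulate stranded paired-end reads and alignments from planted truth
#'
#' Draws per-transcript fragment counts negative-binomially around
#' condition means (planted events up-shifted in condition B by
#' `2^log2_effect`), cuts fragments uniformly along each transcript,
#' emits protocol-consistent mate pairs with substitution errors, and
#' writes per-sample FASTQ pairs plus SAM alignments computed directly
#' from the known fragment positions (no aligner involved).
#'
#' @param ref a `sim_reference`.
#' @param truth a `truth_manifest` from [plant_events()] (or `NULL` for a
#'   background-only cohort).
#' @param cfg the shared [sim_config()].
#' @param out_dir output directory for FASTQ/SAM files (default: a fresh
#'   temporary directory).
#' @param emit which per-sample files to write: `"fastq"`, `"sam"`, or both.
#' @return a `sim_reads` list: `design` (sample_id, condition, file paths,
#'   total_reads), `counts` (true fragment counts, transcripts x samples),
#'   `transcripts` (DNAStringSet incl. event transcripts), `tx_info`, and
#'   the inputs `truth` and `cfg`.
#' @export
simulate_reads <- function(ref, truth, cfg, out_dir = NULL,
                           emit = c("fastq", "sam")) {
  stopifnot(inherits(ref, "sim_reference"))
  if (cfg$fragment_mean < cfg$read_length)
    stop("configuration error: fragment_mean < read_length")
  emit <- match.arg(emit, several.ok = TRUE)
  out_dir <- out_dir %||% tempfile("simreads")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 2000L)

  chrom <- names(ref$genome)[1]
  # transcript table: annotated background + planted events
  tx_seq <- as.character(ref$transcripts)
  tx_blocks <- lapply(as.list(ref$exons), function(g) {
    list(bs = start(g), be = end(g),
         minus = as.character(strand(g))[1] == "-")
  })
  n_bg <- length(tx_seq)
  mean_bg <- rlnorm(n_bg, log(cfg$mean_expression), 0.6)
  meanA <- mean_bg
  meanB <- mean_bg
  is_event <- rep(FALSE, n_bg)
  if (!is.null(truth) && nrow(truth) > 0) {
    ev_seq <- attr(truth, "event_seq")
    ev_blocks <- attr(truth, "event_blocks")
    tx_seq <- c(tx_seq, ev_seq)
    tx_blocks <- c(tx_blocks, lapply(as.list(ev_blocks), function(g) {
      g <- sort(g)
      list(bs = start(g), be = end(g),
           minus = as.character(strand(g))[1] == "-")
    }))
    meanA <- c(meanA, truth$baseline_mean)
    meanB <- c(meanB, truth$baseline_mean * 2^truth$log2_effect)
    is_event <- c(is_event, rep(TRUE, nrow(truth)))
  }
  tx_id <- names(tx_seq)
  Lt <- nchar(tx_seq)
  keep <- Lt >= cfg$read_length
  if (!all(keep)) {
    tx_seq <- tx_seq[keep]; tx_blocks <- tx_blocks[keep]
    meanA <- meanA[keep]; meanB <- meanB[keep]
    is_event <- is_event[keep]; tx_id <- tx_id[keep]; Lt <- Lt[keep]
  }
  ntx <- length(tx_seq)

  nA <- cfg$n_per_group[1]; nB <- cfg$n_per_group[2]
  sample_id <- sprintf("S%02d", seq_len(nA + nB))
  condition <- rep(c("A", "B"), c(nA, nB))
  counts <- matrix(0L, ntx, nA + nB, dimnames = list(tx_id, sample_id))
  design <- data.frame(sample_id = sample_id, condition = condition,
                       fastq_1 = NA_character_, fastq_2 = NA_character_,
                       sam = NA_character_, total_reads = 0L,
                       stringsAsFactors = FALSE)
  rl <- cfg$read_length

  for (s in seq_along(sample_id)) {
    mu <- if (condition[s] == "A") meanA else meanB
    cnt <- if (cfg$nb_dispersion > 0)
      rnbinom(ntx, mu = mu, size = 1 / cfg$nb_dispersion)
    else rpois(ntx, mu)
    counts[, s] <- cnt
    ti <- rep.int(seq_len(ntx), cnt)
    nf <- length(ti)
    ltv <- Lt[ti]
    fl <- pmin(pmax(as.integer(round(rnorm(nf, cfg$fragment_mean,
                                           cfg$fragment_sd))), rl), ltv)
    fs <- as.integer(floor(runif(nf) * (ltv - fl + 1))) + 1L
    fe <- fs + fl - 1L
    txs <- tx_seq[ti]
    sense <- substring(txs, fs, fs + rl - 1L)
    anti <- revcomp(substring(txs, fe - rl + 1L, fe))
    sense <- add_substitutions(sense, cfg$substitution_rate)
    anti <- add_substitutions(anti, cfg$substitution_rate)
    if (cfg$protocol == "fr-firststrand") {
      r1 <- anti; r2 <- sense
    } else if (cfg$protocol == "fr-secondstrand") {
      r1 <- sense; r2 <- anti
    } else {
      flip <- runif(nf) < 0.5
      r1 <- ifelse(flip, sense, anti)
      r2 <- ifelse(flip, anti, sense)
    }
    ids <- sprintf("%s_f%06d", sample_id[s], seq_len(nf))
    if ("fastq" %in% emit) {
      f1 <- file.path(out_dir, paste0(sample_id[s], "_1.fastq"))
      f2 <- file.path(out_dir, paste0(sample_id[s], "_2.fastq"))
      write_fastq(r1, f1, ids = paste0(ids, "/1"))
      write_fastq(r2, f2, ids = paste0(ids, "/2"))
      design$fastq_1[s] <- f1
      design$fastq_2[s] <- f2
    }
    if ("sam" %in% emit) {
      design$sam[s] <- write_sim_sam(
        file.path(out_dir, paste0(sample_id[s], ".sam")),
        chrom, width(ref$genome)[1], ids, ti, fs, fe, rl,
        tx_blocks, Lt, cfg$protocol)
    }
    design$total_reads[s] <- 2L * nf
  }

  out <- list(design = design, counts = counts,
              transcripts = DNAStringSet(tx_seq),
              tx_info = data.frame(tx_id = tx_id, length = Lt,
                                   is_event = is_event,
                                   stringsAsFactors = FALSE),
              truth = truth, cfg = cfg, out_dir = out_dir)
  class(out) <- "sim_reads"
  out
}

# emit one sample's alignments as coordinate-sorted SAM computed from the
# known fragment positions
write_sim_sam <- function(path, chrom, chrom_len, ids, ti, fs, fe, rl,
                          tx_blocks, Lt, protocol) {
  nf <- length(ti)
  pos1 <- integer(nf); pos2 <- integer(nf)
  end1 <- integer(nf); end2 <- integer(nf)
  cig1 <- character(nf); cig2 <- character(nf)
  minus_tx <- logical(nf)
  for (t in unique(ti)) {
    w <- which(ti == t)
    bl <- tx_blocks[[t]]
    sense <- map_mate_blocks(fs[w], fs[w] + rl - 1L, bl$bs, bl$be,
                             bl$minus, Lt[t])
    anti <- map_mate_blocks(fe[w] - rl + 1L, fe[w], bl$bs, bl$be,
                            bl$minus, Lt[t])
    # sense mate aligns on the transcript strand, anti mate on the opposite
    pos1[w] <- sense$pos; end1[w] <- sense$end; cig1[w] <- sense$cigar
    pos2[w] <- anti$pos; end2[w] <- anti$end; cig2[w] <- anti$cigar
    minus_tx[w] <- bl$minus
  }
  # genome strand of each mate
  sense_minus <- minus_tx
  anti_minus <- !minus_tx
  if (protocol == "fr-firststrand") {
    # R1 = anti mate, R2 = sense mate
    p1 <- pos2; e1 <- end2; c1 <- cig2; m1 <- anti_minus
    p2 <- pos1; e2 <- end1; c2 <- cig1; m2 <- sense_minus
  } else if (protocol == "fr-secondstrand") {
    p1 <- pos1; e1 <- end1; c1 <- cig1; m1 <- sense_minus
    p2 <- pos2; e2 <- end2; c2 <- cig2; m2 <- anti_minus
  } else {
    flip <- runif(nf) < 0.5
    p1 <- ifelse(flip, pos1, pos2); e1 <- ifelse(flip, end1, end2)
    c1 <- ifelse(flip, cig1, cig2)
    m1 <- ifelse(flip, sense_minus, anti_minus)
    p2 <- ifelse(flip, pos2, pos1); e2 <- ifelse(flip, end2, end1)
    c2 <- ifelse(flip, cig2, cig1)
    m2 <- ifelse(flip, anti_minus, sense_minus)
  }
  span_l <- pmin(p1, p2)
  span_r <- pmax(e1, e2)
  tlen1 <- ifelse(p1 <= p2, span_r - span_l + 1L, -(span_r - span_l + 1L))
  flag1 <- 1L + 2L + 64L + ifelse(m1, 16L, 0L) + ifelse(m2, 32L, 0L)
  flag2 <- 1L + 2L + 128L + ifelse(m2, 16L, 0L) + ifelse(m1, 32L, 0L)
  lines1 <- paste(ids, flag1, chrom, p1, 60L, c1, "=", p2, tlen1,
                  "*", "*", sep = "\t")
  lines2 <- paste(ids, flag2, chrom, p2, 60L, c2, "=", p1, -tlen1,
                  "*", "*", sep = "\t")
  all_pos <- c(p1, p2)
  ord <- order(all_pos)
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len),
               c(lines1, lines2)[ord]), path)
  path
}

#' Simulate a NanoString-style probe count table with clinical labels
#'
#' Emulates a multiplexed probe assay: positive-control rows on a fixed
#' concentration ladder, negative-control background rows, housekeeping
#' rows with no class effect, target probe rows with configured
#' tumor/normal fold changes, and one benchmark probe. Per-lane scaling
#' factors and log-normal measurement noise are applied to every row, so
#' control-based normalization is exercised end to end. Tumor samples also
#' receive Gleason scores, TNM stages drawn jointly with a latent risk
#' level, and recurrence labels.
#'
#' @param n_targets number of target probe rows.
#' @param n_per_class samples per class, `c(normal, tumor)`.
#' @param target_fc fold change (tumor over normal) per target probe;
#'   recycled to `n_targets`.
#' @param n_housekeeping housekeeping probe rows (no class effect).
#' @param benchmark_fc fold change of the single benchmark probe.
#' @param noise_sdlog log-normal measurement noise (sdlog).
#' @param lane_sdlog log-normal spread of per-lane scaling factors.
#' @param seed integer seed.
#' @return a `probe_matrix`: list with `values` (probes x samples, raw),
#'   `roles` (per-row role), and `samples` (sample metadata: condition,
#'   gleason, t_stage, recurrence).
#' @export
make_probe_table <- function(n_targets = 23, n_per_class = c(9L, 135L),
                             target_fc = 6, n_housekeeping = 6,
                             benchmark_fc = 2.5, noise_sdlog = 0.35,
                             lane_sdlog = 0.10, seed = 1L) {
  if (length(n_per_class) < 2L || any(n_per_class < 1))
    stop("need at least one sample in each of two classes")
  set.seed(seed)
  nN <- n_per_class[1]; nT <- n_per_class[2]
  n_samp <- nN + nT
  condition <- rep(c("normal", "tumor"), c(nN, nT))
  sample_id <- sprintf("P%03d", seq_len(n_samp))
  target_fc <- rep_len(target_fc, n_targets)

  pos_ladder <- c(128, 512, 2048, 8192, 32768, 0.125 * 1024)
  lane <- rlnorm(n_samp, 0, lane_sdlog)

  mk_rows <- function(base, fc, n_rows, prefix) {
    base_m <- matrix(rep(base, n_samp), n_rows, n_samp)
    eff <- matrix(rep(ifelse(condition == "tumor", 1, 0), each = n_rows),
                  n_rows, n_samp)
    fcm <- matrix(rep(fc, n_samp), n_rows, n_samp)
    v <- base_m * fcm^eff *
      matrix(rlnorm(n_rows * n_samp, 0, noise_sdlog), n_rows, n_samp) *
      matrix(rep(lane, each = n_rows), n_rows, n_samp)
    rownames(v) <- sprintf("%s%02d", prefix, seq_len(n_rows))
    v
  }

  pos <- mk_rows(pos_ladder, 1, length(pos_ladder), "POS_")
  neg <- mk_rows(rep(15, 8), 1, 8, "NEG_")
  hk <- mk_rows(rlnorm(n_housekeeping, log(800), 0.4), 1, n_housekeeping,
                "HK_")
  tg <- mk_rows(rlnorm(n_targets, log(120), 0.8), target_fc, n_targets,
                "TGT_")
  bm <- mk_rows(5000, benchmark_fc, 1, "BENCH_")

  values <- rbind(pos, neg, hk, tg, bm)
  roles <- rep(c("positive_control", "negative_control", "housekeeping",
                 "target", "benchmark"),
               c(nrow(pos), nrow(neg), nrow(hk), nrow(tg), nrow(bm)))

  gleason <- rep(NA_integer_, n_samp)
  t_stage <- rep(NA_character_, n_samp)
  recurrence <- rep(NA_character_, n_samp)
  tum <- which(condition == "tumor")
  risk_latent <- sample(c("LR", "IR", "HR"), length(tum), replace = TRUE,
                        prob = c(0.3, 0.4, 0.3))
  for (i in seq_along(tum)) {
    if (risk_latent[i] == "LR") {
      gleason[tum[i]] <- 6L
      t_stage[tum[i]] <- sample(c("T1c", "T2a"), 1)
    } else if (risk_latent[i] == "HR") {
      if (runif(1) < 0.5) {
        gleason[tum[i]] <- sample(8:10, 1)
        t_stage[tum[i]] <- sample(c("T1c", "T2a", "T2b", "T2c", "T3a"), 1)
      } else {
        gleason[tum[i]] <- sample(6:7, 1)
        t_stage[tum[i]] <- sample(c("T2c", "T3a", "T3b"), 1)
      }
    } else {
      gleason[tum[i]] <- 7L
      t_stage[tum[i]] <- sample(c("T1c", "T2a", "T2b"), 1)
    }
    recurrence[tum[i]] <- sample(c("yes", "no"), 1, prob = c(0.25, 0.75))
  }

  out <- list(values = values, roles = roles,
              samples = data.frame(sample_id = sample_id,
                                   condition = condition, gleason = gleason,
                                   t_stage = t_stage,
                                   recurrence = recurrence,
                                   stringsAsFactors = FALSE))
  colnames(out$values) <- sample_id
  class(out) <- "probe_matrix"
  out
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat("probe_matrix:", nrow(x$values), "rows x", ncol(x$values), "samples\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$roles)),
                                table(x$roles)), collapse = ", "), "\n")
  cat("  conditions:",
      paste(sprintf("%s=%d", names(table(x$samples$condition)),
                    table(x$samples$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.sim_reference <- function(x, ...) {
  genes <- sum(x$annotation$type == "gene")
  cat("sim_reference:", sum(width(x$genome)), "bp genome,",
      genes, "genes,", length(x$ests), "spliced ESTs\n")
  invisible(x)
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", nrow(x$design), "samples (",
      paste(sprintf("%s=%d", names(table(x$design$condition)),
                    table(x$design$condition)), collapse = ", "),
      "),", nrow(x$counts), "transcripts\n")
  cat("  total fragments:", sum(x$design$total_reads) / 2, "\n")
  invisible(x)
}
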