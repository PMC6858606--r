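---
title: "Reference-free k-mer contig discovery and RNA signature evaluation"
author: "kmsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free k-mer contig discovery and RNA signature evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Biomarker discovery pipelines that count reads over annotated genes are
blind to transcripts missing from the annotation: unannotated intergenic
or antisense long noncoding RNAs (lncRNAs), exon extensions, and novel
splice forms. `kmsig` implements a reference-free alternative for
stranded RNA-seq: fixed-length subsequences (k-mers) are counted
directly from reads, k-mers exactly matching annotated transcripts are
masked away, the remainder is tested for differential abundance between
two conditions, and differentially expressed (DE) k-mers are assembled
into contigs that are then aligned, classified against the annotation
and filtered into a catalog of candidate novel transcript fragments.
Around this core the package carries the full downstream workflow: a
coverage-based transcription-unit assembler for the complementary
reference-based view, streaming k-mer quantification of catalog contigs
in independent libraries, normalization and testing of multiplexed
probe-count tables, and multiplex signature inference with
repeated-split ROC evaluation.

# The discovery model

## k-mer counting and masking

Reads are decomposed into k-mers of length $k$ (default 31) in
*transcript orientation*: under the dUTP `fr-firststrand` protocol,
mate 1 is reverse-complemented and mate 2 taken as-is. Windows
containing non-ACGT characters are skipped. Masking removes k-mers
exactly matching the annotated transcript set, *same strand only*:
adding reverse complements to the mask would annihilate the antisense
contig class, which is one of the main discovery targets.

## Recurrence filtering and testing

Per-sample tables are joined; a k-mer is kept when its count reaches
`min_recurrence_abundance` (default 5) in at least `min_recurrence`
(default 6) samples, evaluated jointly over both conditions — the
single-parameter semantics of the original run configuration. Absent
entries are zeros.

Counts are normalized by size factors. Two estimators are exposed:

* `median_of_ratios()` — the median-of-ratios estimator against a
  per-row geometric-mean pseudo-reference, computed on the log scale
  (so an even number of reference rows interpolates geometrically; this
  makes the implementation agree exactly with the standard
  Bioconductor estimator). Note that scaling one library by $c$
  rescales the pseudo-reference by $c^{1/n}$, so the invariant quantity
  is the *ratio* of size factors, which picks up exactly $c$.
* library k-mer totals — used by the end-to-end driver
  `discover_contigs()`, because after masking and recurrence filtering
  the joined matrix is dominated by condition-specific novel k-mers;
  computing median-of-ratios on that biased submatrix would absorb the
  very fold changes the test is after. Totals are taken over all
  counted k-mers per library, before masking.

Each k-mer row is tested with a per-row negative-binomial Wald test:
normalized group means $m_A, m_B$, method-of-moments dispersion
$\alpha = \max(\alpha_A, \alpha_B, 10^{-8})$ with
$\alpha_g = (v_g - m_g)/m_g^2$, Wald statistic on
$\log_2((m_B + 0.5)/(m_A + 0.5))$ with variance
$\mathrm{Var}(m_g) = (m_g + \alpha m_g^2)/n_g$, two-sided p-value from
the normal reference and Benjamini–Hochberg adjustment. Taking the
larger of the two per-group dispersion estimates guards against
understating the NB variance at small $n$; under the null simulation
used in the tests (2,000 rows, 8 vs 16 samples, $\mu = 50$,
$\alpha = 0.2$) the empirical type-I error at nominal 0.05 lands inside
[0.03, 0.07]. This is deliberately *not* a reimplementation of DESeq2's
shared-dispersion shrinkage or outlier handling — the workflow needs a
calibrated two-group test at the k-mer level, not DESeq2's internals. A
Welch t-test on $\log_2(\text{normalized} + 1)$ is available as an
alternative mode. All p-value thresholds in the pipeline are strict
(`<`), matching "below 0.05 / below 0.01" semantics.

## Contig assembly and annotation

DE k-mers are assembled as unitigs: maximal non-branching paths in the
graph linking k-mers whose $(k{-}1)$-suffix equals another's
$(k{-}1)$-prefix. Extension stops at any branch, self-loops are
guarded, and cycles are broken at the lowest input index, so every DE
k-mer lands in exactly one contig and assembly is deterministic. Each
contig inherits the statistics of its *representative k-mer* — the
member with the smallest adjusted p, ties broken lexicographically.

The internal aligner is exact-match only: all occurrences of the contig
and of its reverse complement are collected; if none exist, a two-block
split (longest exact prefix + longest exact suffix, same chromosome and
strand, blocks at least $k$, gap up to 300 kb) is attempted and
reported as a spliced alignment. Real-genome workflows would instead
attach external BED12 alignments (`mode = "external_bed12"`). Contigs
are categorized as `unmapped` (no site), `repeat` (more than one site —
multiplicity takes precedence over splicing, because multiple sites
invalidate the unique-fragment interpretation), `spliced` (single
multi-block site) or `contiguous`.

Location classes follow the precedence coding > OL > AS > Inter: a
same-strand overlap with a protein-coding *exon* excludes the contig as
`coding`; a same-strand overlap with a lncRNA *gene* makes it `OL`; an
opposite-strand overlap with any gene makes it `AS` (antisense);
otherwise it is `Inter` (intergenic). Gene extent rather than exon
structure drives OL/AS/Inter because novel fragments of annotated
lncRNA loci frequently sit in introns; exon-level overlap is reserved
for the protein-coding exclusion.

The catalog keeps contigs longer than 200 nt with adjusted p below
0.01, excluding `coding`. Finally contigs within the same genomic
neighborhood are deduplicated: alignment spans on one chromosome are
clustered by single linkage at a 5-kb distance and only the
lowest-adjusted-p contig survives per cluster. Single linkage (rather
than fixed tiling windows) was chosen because the deduplication rule
speaks of contigs "within the same region", which is a property of
pairwise distance, not of arbitrary window boundaries.

# The reference-based arm

`assemble_tus()` is a deliberately simple coverage assembler for
stranded libraries: maximal intervals of same-strand read coverage,
merged across samples, are retained when at least 10 reads support them
in at least one sample, then merged when separated by *fewer than* 100
bases (a 99-base gap merges, a 100-base gap does not). Segments
overlapping a same-strand gene are set aside as `sense_overlap`;
antisense and intergenic segments longer than 200 nt form the TU
catalog. TUs are single-interval objects — the protocol merges
coverage, it does not infer exon chains.

Fragments are counted into features with reverse-stranded,
overlap-tolerant semantics (pairs counted once, assigned to every
feature they overlap on the protocol-consistent strand) and converted
to RPKM ($c \cdot 10^9 / (L \cdot N)$). A TU is **Class 2** when its
condition-level mean RPKM exceeds the 20th percentile (type-7 quantile;
the only single-threshold reading of "0.2 quartile") of the
per-condition mRNA mean RPKM in at least one condition, and **Class 1**
when it additionally contains at least one splice junction (extracted
from gapped alignments with N operations — no external junction caller)
on its strand and overlaps at least one spliced EST. Condition-level
expression defaults to the mean over the condition's samples; `max` is
available. Whether the 10-read rule means any single sample or a
condition pool is ambiguous; any single sample is used.

# Quantification in independent libraries

For each catalog contig, quantification probes are its representative
k-mer plus k-mers *unique in the reference transcriptome*. Uniqueness
defaults to occurrence $\le 1$ — novel (0 occurrences) or unambiguous
(1) — because novel contigs have zero reference occurrences and must
not lose all their k-mers; the stricter "occurs exactly once" reading
is switchable. From the ordered unique-k-mer list of length $L$, 10
regularly spaced k-mers are drawn at 0-based indices
$\mathrm{round}(0.1(L{-}1) + i \cdot 0.8 (L{-}1)/9)$, $i = 0..9$, and
the draw is repeated four times with start offsets 0–3, clamped inside
the 10–90 % span; lists with $L \le 10$ are used whole. The procedure
is deterministic — no seeds. Libraries are streamed once; in
unstranded mode a window matching a query's reverse complement counts
toward that query. Counts are normalized per million reads, and
per-contig concordance between representative counts and mean sampled
counts across libraries is summarized by Pearson correlation.

# Probe tables and signatures

Probe-count tables (multiplexed hybridization counters) are normalized
in three steps: lane scaling by positive-control geometric means,
background subtraction of the mean negative control floored at 0.5,
and division by the arithmetic mean of the housekeeping rows. The
vendor's exact control normalization is not public; this fixed scheme
reproduces its documented intent and is invariant (up to the floor) to
per-lane scaling. Probes are tested with a two-sided Wilcoxon rank-sum
test — exact enumeration when both groups have at most 8 tie-free
samples, otherwise a tie-corrected normal approximation with
continuity *and* Edgeworth (kurtosis) corrections. The plain corrected
normal deviates from exact enumeration by up to 0.011 at group sizes
(8, 8) — a fixed property of the discrete support — while the
Edgeworth term (closed-form excess kurtosis
$-1.2\,(m^2{+}n^2{+}mn{+}m{+}n)/(mn(m{+}n{+}1))$, exact for tie-free
data) brings the worst case below $10^{-3}$. Fold changes are ratios
of group means with a 0.5 pseudocount only when a mean is zero.
Risk stratification (low/intermediate/high) is driven by a data file of
Gleason/T-stage rules, not code, because published threshold tables
vary; the packaged default is a PSA-free simplification of the D'Amico
scheme.

Signature inference uses L1-penalized logistic regression (glmnet) on
minority-upsampled data: a 100-value lambda path down to
$10^{-3}\lambda_{\max}$, 10-fold cross-validated binomial deviance and
the 1-SE rule (conventional for parsimonious selection; the rule is
configurable). Stability selection repeats this on 2,000 seeded
half-subsamples and retains probes selected in strictly more than half
of the runs. A caveat the synthetic tests make explicit: several
*mutually redundant* informative probes split their selection
probability under the L1 penalty, so a panel of many interchangeable
strong probes can dilute each below the 0.5 threshold; the recovery
checks therefore plant an identifiable five-probe signature.

Classification uses LogitBoost with decision stumps: working response
$z = (y - p)/(p(1-p))$ with $p$ clipped to $[10^{-5}, 1-10^{-5}]$ and
$z$ to $\pm 4$, weighted least-squares stumps (ties to the lowest
feature index, then lowest threshold) and half-steps on the additive
score. The iteration count (up to 100) is picked by leave-one-out
accuracy on the training set, ties toward fewer iterations; the staged
LOO path is computed in C++ because it refits the boosting path once
per training row. Evaluation repeats 100 stratified 70/30 splits with
upsampling on the training side only, reports per-split AUC (Mann-
Whitney U with half credit for ties), their mean and SD, and a
vertically averaged ROC on a 101-point FPR grid. Classifiers are refit
inside every training split; selection-set coefficients are never
transferred to validation data.

# The synthetic-data generator

Every stage is testable without external data through a seeded
generator that emulates: a random genome with non-overlapping
multi-exon gene models on both strands (protein-coding and lncRNA
biotypes), spliced transcript sequences, spliced-EST records for a
fraction of multi-exon transcripts, planted novel events (intergenic,
antisense, exon-extension, splice-variant), negative-binomial
per-transcript fragment counts with a configurable tumor up-shift of at
least six-fold, protocol-faithful mate orientation, substitution-only
sequencing errors, and SAM alignments emitted directly from the known
fragment coordinates — exercising BAM parsing without an aligner.
Planted events are kept at least 6 kb apart: they model distinct loci,
and spacing them beyond the 5-kb deduplication window keeps the truth
set identifiable by construction.

What the generator does *not* emulate — indels, quality-score
structure, coverage bias along transcripts, multi-chromosome genomes,
fusion or circular RNA, batch effects — bounds what the passing tests
show: the pipeline's rules and statistics behave as specified under
clean NB-noise conditions, not that discovery power or calibration
transfers to any particular real cohort.

Default study conditions used by the acceptance checks: a 1-Mb genome
with 200 genes, 20 planted intergenic/antisense events at 6–12 fold,
8 vs 16 libraries of 75-nt pairs (~0.65 M fragments in total), probe
cohorts of 144 (9 normal / 135 tumor) and 557 (52 / 505) samples with
24 candidate probes, stability selection over 2,000 subsamples and 100
evaluation splits. These sizes keep the full suite in the
ten-minute range on a single core while preserving the workflow's
dimensional structure (sample imbalance, probe count, split design).

# Numerical choices and edge cases

* Degenerate DE rows (both groups all zero) yield $p = 1$ and
  log2FC 0 rather than an error.
* `median_of_ratios()` errors when no zero-free row exists, and offers
  a positive-geomean fallback that excludes zeros row-wise.
* Assembly of a duplicate-free k-mer set is required; duplicated input
  k-mers are an error, homopolymer self-loops terminate.
* Alignment ties (several full-length sites) keep all sites for the
  multiplicity call; the primary site (lowest chromosome, start) is
  used for span-based operations.
* Window deduplication ties break by lexicographic contig id.
* `regular_sample()` clamps shifted replicates into the sampled span
  and collapses duplicates, so short lists yield fewer picks.
* Upsampling, subsampling, fold assignment, splits: every stochastic
  step takes an explicit seed, and the generator is fully reproducible
  from `sim_config(seed = ...)`.

# Limitations

The internal aligner tolerates no mismatches, so contig alignment on
real genomes should come from an external aligner via BED12. The NB
Wald test is per-row and unshrunken: at very small $n$ it is noisier
than information-sharing estimators, which the recurrence filter
partially offsets. TU assembly infers no isoform structure. The
LogitBoost LOO tuner assumes exchangeable training rows; with heavy
upsampling the duplicated minority rows make LOO optimistic, which is
acceptable here because the iteration count, not the reported
performance, is tuned with it.
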