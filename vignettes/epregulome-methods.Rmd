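---
title: "Mapping a motif-anchored enhancer-promoter regulome from HiChIP loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a motif-anchored enhancer-promoter regulome from HiChIP loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Oncogenic fusion transcription factors can rewire gene regulation through
long-range enhancer-promoter (E-P) contacts that a linear genome browser view
cannot reveal. Protein-directed conformation capture (HiChIP) yields the
factor's chromatin loops directly: pairs of fixed-width genomic bins
("anchors") with a contact count and a loop-calling significance (a q-value,
as produced by FitHiChIP-style callers at 5-kb bins over a 50 kb - 3 Mb
range). This package turns such loop calls, together with ordinary 1D inputs
(a genome, gene models, ChIP peaks, signal tracks, a knockout
differential-expression table, an expression compendium), into a ranked table
of candidate direct target genes of the factor.

The pipeline mirrors how a regulatory-genomics group would assemble the
analysis by hand, with each stage exposed as a tested function:

1. **Loop filtering** (`filter_loops()`): keep intra-chromosomal loops with
   q <= 0.01 at distances 50 kb - 3 Mb.
2. **Anchor classification** (`classify_anchors()`): an anchor overlapping
   any TSS +/- 10 kb window is a promoter anchor (`P`); a non-promoter anchor
   carrying both a motif match and a 1D factor peak is a motif-bearing
   enhancer-side anchor (`I_HLF` in the HLF-like naming used throughout);
   promoter status takes precedence so each anchor gets exactly one class,
   while the motif flag is retained for the both-anchor-motif statistic.
3. **Pairing** (`build_ep_pairs()`): every filtered loop joining an `I_HLF`
   anchor to a `P` anchor becomes a candidate E-P pair; the promoter window's
   genes become the pair's genes.
4. **Per-gene aggregation** (`ep_gene_table()`): for each gene, the number of
   pairs, the **sumCC** statistic (the sum of contact counts over all of its
   significant pairs - a cumulative interaction-frequency measure), and the
   best pair q-value. Genes are ranked by best q, then descending sumCC.
5. **Integration**: knockout DE direction at adjusted p < 0.05 (the
   significant subset are the *E-P genes*, `ep_genes()`), ROSE-style
   enhancer class of the motif anchors, chromatin-state cluster of the motif
   site, transcription-factor membership, and subtype specificity.

## Motif scanning

Anchors are scanned with a position weight matrix in log2-odds form,
`log2(((counts + pseudocount) / rowsum) / background)`, on both strands; the
reverse strand is scored against the reverse-complemented matrix, which is
identical to scoring the reverse complement of each window. A hit requires a
relative score (score divided by the matrix's maximal attainable score) of at
least 0.8. A relative-score threshold was chosen over a p-value threshold
because it is deterministic, background-free, and reproducible bit for bit;
the pseudocount defaults to 0.1 with a uniform background. Windows containing
N are never hits, which lets `flag_motif_regions()` scan the concatenation of
all regions of a chromosome (N-spacered) in one pass. The enrichment test
(`motif_enrichment()`) is a one-sided Fisher's exact test on the 2x2
motif-by-set table, with a Haldane +0.5 correction for the odds ratio when a
cell is zero.

The shipped `hlf_like_pwm()` is a synthetic 8-mer consensus matrix around a
PAR-bZIP-like core (TTACGCAA). It is a generator fixture, not a claim about
the biological motif, and is deliberately sharp: at the default pseudocount
only exact consensus matches reach relative score 0.8, which makes planted
motif truth in the synthetic data exact.

## Promoter windows: two distinct scales

Two promoter definitions coexist deliberately. Feature annotation
(`annotate_intervals()`) uses a narrow, HOMER-like window of -1000/+100 bp
around the TSS for midpoint-based categorisation (promoter > 5' UTR > 3' UTR >
exon > intron > intergenic; midpoint assignment gives every region exactly
one category, and ties between genes resolve to the nearest TSS, then the
lexicographically smaller gene id). Loop-anchor pairing uses TSS +/- 10 kb,
matching the resolution of 5-kb loop bins. Conflating the two scales would
distort both the annotation breakdown and the pair catalogue; both are
configurable.

## ROSE-style enhancer calling

H3K27ac peaks are gap-stitched (peaks within 12,500 bp merged transitively,
the published ROSE default; TSS exclusion defaults to 0 and is available when
gene models are supplied). Stitched regions are scored by the area under the
signal track (control-subtracted when given, floored at zero) - areas rather
than read counts keep the module alignment-free. The super-enhancer cutoff is
the classic hockey stick: with ascending rank and signal both scaled to
[0, 1], the cutoff is the signal at the point where the curve's slope first
reaches 1; regions above it are super-enhancers. The geometric alternative
(the point of maximum distance below the diagonal) is used as an independent
cross-check in the tests and must agree within one rank on a clear elbow.
Profiles without a usable elbow (all-equal signals, or a quasi-linear profile
where most regions would land above the cutoff) are treated as degenerate:
no super-enhancers, with a warning.

## Chromatin states at motif sites

`build_signal_matrix()` computes per-bin mean coverage of each track in a
+/- 2 kb window (50-bp bins) around each motif center, strand-flipped for
minus-strand motifs. The span and bin width are conventional
computeMatrix-scale defaults; the source data do not pin them down, so both
are arguments. The top 75% of regions by the factor's own occupancy are kept
(`select_top_enriched()`), then k-means with k = 3 clusters the concatenated
track profiles, after standardising each bin column within each track so a
deep track cannot dominate the distance. Ten restarts under a fixed seed make
the assignment deterministic; clusters are relabelled by descending mean of
the active mark (H3K27ac when present) so that "cluster 1 = most active" is
stable across runs. Per-cluster comparisons use an RPKM-style density (window
sum per kb per million units of track total - invariant to rescaling a
track), Welch t-tests for every cluster pair and track, and Benjamini-
Hochberg adjustment across the whole family. Within-cluster association of
accessibility and factor occupancy is a per-region-sum Pearson correlation
with its t-distribution p-value.

## Signature scoring

`module_score()` follows the canonical single-cell module-score scheme
(24 equal-frequency bins of mean expression; 100 control genes per module
gene sampled with replacement from the module gene's bin; score = mean module
expression minus mean pooled-control expression per cell). The score is
invariant under adding a constant to the whole matrix and reproducible under
a fixed seed. Control pools are drawn from the full bin, so a module that
dominates the extreme expression bins will partially control against itself;
the synthetic generator therefore plants its module among mid-range genes
(see below).

`preranked_gsea()` is a weighted Kolmogorov-Smirnov-style statistic on a
ranked gene list: hit steps `|metric|^p / sum |metric|^p` (p = 1), miss steps
`1/(N - m)`, enrichment score (ES) = the signed maximum deviation of the
running sum, evaluated exactly at hit boundaries. Because a preranked list
has no sample labels, the null is gene-set permutation: random same-size
sets, shared across sets of equal size. NES divides ES by the mean |ES| of
same-sign null scores; the permutation p-value is
`(1 + #{same-sign null at least as extreme}) / (1 + #same-sign null)`, BH-
adjusted across sets. The default ranking metric produced from a DE table is
`-log10(adjusted p) * sign(log2FC)`; the upstream analyses this package
emulates did not state their metric, so it is an explicit, configurable
choice. One published figure legend filtered the module genes at
"adj. P value > 0.05", almost certainly a typo for "< 0.05"; the pipeline
uses `<`.

## Replicate reproducibility (SCC)

`scc()` implements the stratum-adjusted correlation coefficient for two
contact matrices: both are mean-filtered with a (2h+1) x (2h+1) window
(h = 3 by default; edge-truncated, no padding - mean-filter variants differ
here, so the choice is stated), then for each diagonal stratum within the
0 - 3 Mb distance band the Pearson correlation of paired entries is combined
with weights N_k * sd1_k * sd2_k. Identical non-constant matrices give
exactly 1; zero-variance strata are skipped and all-constant input is an
error.

One calibration subtlety: on independent 100 x 100 Poisson matrices, the
default h = 3 window leaves roughly n/7 effective samples per stratum, which
inflates the spread of the null SCC (measured sd about 0.09) without biasing
it. The package's null-calibration checks therefore run unsmoothed (h = 0,
where the statistic is a pure stratified correlation and |SCC| < 0.1 holds in
essentially all seeds), while range and self-identity properties are asserted
at h = 3. On real replicate-scale matrices (thousands of bins per
chromosome) this small-matrix effect is negligible.

## The synthetic study conditions

`simulate_regulome()` generates every input the pipeline consumes, with the
planted truth serialized next to the data. The defaults are the package's
study conditions and echo the magnitudes of the motivating study design:
5-kb bins, q = 0.01 loop threshold, 3 chromatin archetypes, 24 expression
subtypes with a 22-gene specific set, adjusted-p 0.05 DE threshold. Sizes
(3 chromosomes x 5 Mb, 200 genes, 2000 loops, 30 planted E-P genes, 300
motif regions, 500 cells x 1000 genes) are chosen so a full run takes on the
order of a minute on one core while every statistic still has comfortable
power; the vignette states them here as the package's chosen problem sizes.

Ground truth is exact by construction, which separates correctness tests
from sensitivity studies:

* all chance occurrences of the motif consensus (both strands) are scrubbed
  from the random genome before planted instances are inserted, and the
  consensus is sharp enough that only exact matches clear the 0.8 threshold;
* planted loops draw q from 1e-6 - 1e-3 (the designated top gene: ~1e-8 with
  the largest contact counts) and background loops from (0.01, 1], so the
  significant set equals the planted set; a `hard_mode` flag overlaps the two
  q distributions for power studies;
* planted genes have isolated TSSs (no other TSS within 25 kb) and planted
  motif anchors avoid every TSS +/- 10 kb window, so recovered gene sets
  contain no bystanders;
* promoter-side motifs for the both-anchor-motif fraction are planted at
  genes with a single loop (a gene's pairs share its promoter anchor, so
  planting there marks all of them at once);
* subtype-specific genes are deterministically scaled to 3.5x the maximum
  other-subtype median, and every other gene is capped at 2.5x, so the 3x
  rule recovers exactly the planted set;
* the expression module is planted among mid-range baseline genes (mean
  log-expression <= 2 of a 0.5 - 3 range) so that, after the +1 shift in the
  labelled half of the cells, bin-matched controls remain representative of
  the background - planting in the extreme bins would make the module its
  own control and shrink the recovered score contrast.

Chromatin tracks realise three archetypes at motif centers - active (high
H3K27ac/H3K4me1/accessibility), primed (H3K4me1-high, H3K27ac-low, with a
mild planted see-saw between accessibility and factor occupancy), and
repressed-yet-accessible (H3K27me3-high with elevated accessibility and
strong occupancy) - as Gaussian bumps with multiplicative log-normal noise
(sigma = 0.1). Genes whose motif anchors fall in the active archetype are
planted to be knocked down in ~70% of cases, reproducing the
activation-biased direction structure of cluster 1.

What the generator does **not** emulate: read-level noise, alignment and
peak-calling artefacts, copy-number and mappability biases, overlapping
genes and alternative TSSs, the loop caller's background model, and
unbalanced subtype sizes. Passing the planted-truth suite therefore
demonstrates the correctness of the integration logic under its stated
contracts, not robustness to upstream noise; `hard_mode` is the entry point
for the latter kind of study.

## Subtype specificity

"k-fold higher median expression than all other subtypes" admits two
readings; the strict per-subtype rule (median in the target subtype at least
`fold` times the median of *every* other subtype) is the default because it
is the more conservative reading, and a pooled-others comparison is available
via `comparison = "pooled"`. Subtypes without samples are excluded with a
warning.

## Aggregation rules that were genuinely open

* A gene touched by several motif anchors takes the *modal* chromatin
  cluster (ties to the lowest, i.e. most active, cluster number) and the
  *highest-precedence* enhancer class (SE > TE > external-only > none):
  least-surprising aggregates, stated here because the upstream analyses do
  not specify them.
* Ranking uses best q first and sumCC as the secondary key, mirroring the
  presentation of interaction significance as primary with contact mass as a
  magnitude annotation.
* Loop q-values absent from an input BEDPE are treated as 0 (pre-filtered
  exports); anchors of retained inter-chromosomal loops survive I/O but are
  excluded from filtering and pairing.
* `run_pipeline()` derives each stage's RNG stream from the master seed with
  fixed per-stage offsets, so adding a stage never perturbs earlier stages,
  and writes an md5 manifest - determinism is checkable by hash equality.

## Known limitations

* One TSS per gene; alternative transcripts are out of scope.
* The annotation module does not reproduce HOMER's finer subcategories
  (TTS, CpG classes).
* The GSEA p-value is plain permutation (resolution limited by `n_perm`),
  not an adaptive multilevel estimate; at desk scale this is sufficient and
  exact cross-checks against the reference statistic are part of the tests.
* FIMO-style p-value calibration of motif scores is not implemented; match
  thresholds are relative scores.
* The ROSE gene-mapping step is intentionally absent: target assignment is
  the loop catalogue's job here.
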