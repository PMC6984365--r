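---
title: "Methods: comparative lncRNA identification and expression evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative lncRNA identification and expression evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and overview

`lncevo` implements the computational machinery of a comparative
transcriptomics study of long noncoding RNA (lncRNA) evolution across
species, organs and developmental stages: identification and filtering of
lncRNA loci from assembled transcripts, coding-potential scoring,
alignment-guided orthology prediction, expression normalization, and
cross-species sequence- and expression-conservation statistics. Wet-lab
steps and heavyweight externals (read alignment, transcript assembly, BLAST,
PhastCons, whole-genome aligners) are out of scope; their outputs are the
pipeline's inputs, consumed through standard formats (GTF, UCSC chain,
bedGraph, BED, BLAST tabular, TSV matrices).

Because the original study's headline numbers depend on full-size genomes
and sequencing data, the package ships a deterministic multi-species
simulator with planted ground truth. Every pipeline stage is exercised end
to end on synthetic data whose generating process is documented below; the
tests and `scripts/acceptance.R` measure recovery of the planted truth.

# Data model and coordinates

Internally all intervals are 0-based, half-open; GTF I/O converts to and
from the 1-based inclusive convention, while BED, bedGraph and chain files
are natively 0-based. A `gene_model` groups one or more `transcript_model`
isoforms on a single chromosome and strand; derived regions are:

* **exon blocks** — the union of exon coordinates across all isoforms, the
  unit projected between genomes;
* **promoters** — 400 bp upstream of the gene's transcription start site
  (TSS), the 5'-most isoform start on the gene strand. One promoter per
  gene: when isoforms disagree, the 5'-most TSS wins. Promoters truncate at
  the chromosome edge and carry a `truncated` flag;
* **splice sites** — the first and last two bases of each intron.

A promoter is called *bidirectional* when another gene's TSS sits on the
opposite strand within a window of the gene's TSS. No window length is
canonical; the default is 1 kb (configurable), a common promoter-pairing
convention, and protein-coding partners take precedence over noncoding
ones when both occur.

# Coding potential

The codon substitution frequency (CSF) score asks whether an aligned
sequence window evolves like coding sequence. A `csf_model` holds the
frequencies of ordered codon pairs (reference codon, aligned codon)
estimated from in-frame alignments of coding sequence and from neutrally
evolving alignments, with additive smoothing (default pseudocount 0.5; the
training corpus and smoothing are free parameters, set here to the
simulator's training output). The three stop codons are pooled into a
single state to avoid sparse cells; codon pairs containing gaps or
ambiguity codes contribute nothing, since substitution patterns are only
defined on aligned codons.

A scan slides 75 bp windows in 3 bp steps; each window's score on a strand
is the maximum over that strand's three reading frames of the summed
log-ratios `log(f_coding / f_noncoding)`, and the minus strand is scored on
the reverse complement and reported in input coordinates. Windows that
would extend past the alignment are omitted, so an alignment of length `L`
yields `(L - 75)/3 + 1` windows per strand.

A transcript is classified protein-coding when its exonic bases lying under
at least one strictly positive window on its own strand total at least
150 bp, after masking exonic regions of other genes (positive CSF signal
leaks onto antisense strands through the partial strand symmetry of the
genetic code). The similarity route classifies a transcript coding when
BLAST-like hits with e-value ≤ 1e-3 and identity ≥ 40% cover ≥ 150 bp of
the transcript. A gene is protein-coding if any isoform is flagged by
either route. The package scores pairwise alignments (one informant);
several informants can be summed, which preserves the scan mechanics at
desk scale.

# The lncRNA filter cascade

Candidate noncoding loci — novel genes negative on both coding-potential
routes, plus reference genes with noncoding biotypes (`lincRNA`,
`processed_transcript`, `antisense`, `TEC`, `macro_lncRNA`,
`bidirectional_promoter_lncRNA`, `sense_intronic`) — pass through
independent filters, each recorded as pass/fail/NA in a per-gene audit:

| filter | rule | applies to |
|---|---|---|
| exonic length | ≥ 200 bp (multiexonic), ≥ 500 bp (monoexonic) | novel |
| unmappable | ≤ 5% of exonic length | novel |
| intergenic | no exonic overlap with protein-coding genes (either strand) and ≥ 5 kb from same-strand protein-coding spans | novel |
| junction support | all introns supported with correct strand | novel multiexonic |
| retrogene | < 50% of locus length | all |
| tRNA | no overlap | all |
| RNA repeats | < 25% of locus length | all |
| read support | ≥ 10 unique reads in total | all |
| sense/antisense | ratio ≥ 1% in ≥ 1 sample | all |
| concordance | Spearman rho ≥ 0.9 between full and overlap-free expression estimates | loci with antisense overlap |

Thresholds are strict or inclusive exactly as listed. Overlap fractions use
exonic length for the unmappable filter and locus (span) length for the
retrogene and repeat filters — the two readings of "their length" differ
between filters and both are configurable. "Intergenic" distance is
measured between gene spans. The sense/antisense ratio is evaluated on
unique read counts; coverage-based evaluation would need per-base depth the
pipeline does not otherwise require. Filters are evaluated independently,
so the audit is invariant to evaluation order, and a missing region set
degrades that one filter to NA rather than aborting the run. A locus is
called lncRNA only when every applicable filter passes.

# Orthology through chain maps

Exon blocks are projected through UCSC chain alignments. Per block, the
projection uses the highest-scoring chain covering at least 10% of the
block's bases. A block is `ambiguous` when two or more qualifying chains
reach distinct target loci — operationalized as different chromosomes or
projections more than 1 Mb apart, since recent duplications are the case
this guard exists for — and `split` when no single chain qualifies but
chains on distinct loci jointly do. Projected blocks must have a
target/reference span ratio within [0.33, 3] for rodent-like pairs
([0.2, 5] for more distant comparisons); the ratio uses spans rather than
summed block lengths, matching the notion of a projected *region*. The 10%
remap threshold applies per exon block, the finest unit the chain can
resolve.

Per gene, the consensus target chromosome and strand is the one carrying
the majority of projected bases (ties discard the gene; no principled
tie-break exists). Blocks off-consensus are dropped; the survivors' target
midpoints must then be monotone in reference order, orientation-corrected
for minus-strand chains — midpoints are robust to small block overlaps. If
exactly one block breaks monotonicity it is dropped (the first such block
when several single removals would work); otherwise the gene is eliminated.
The implementation agrees with an exhaustive oracle over all single-block
removals, which the tests check for every gene with ≤ 8 blocks.

Projected genes and target annotations are clustered by single-link on
≥ 1 bp strand-aware exonic overlap. Within a cluster, each
reference–target pair is globally aligned (affine-gap Needleman–Wunsch on
concatenated exon-block sequences via Biostrings; the aligner is a
pluggable function, so an external aligner can be swapped in). Percent
identity and percent aligned-without-gaps are reported relative to the
*reference* exonic length; the asymmetry is intentional, as both directions
are computed independently. A reference gene's best hit must beat the
runner-up's identity by a ratio > 1.1, otherwise no hit is called;
reciprocal best hits are the 1-to-1 orthologs. Multi-species families are
single-link components over pairwise 1-to-1 edges, discarding components
with two genes from one species. All filters are monotone: relaxing the
remap threshold or the size bounds never removes a reported pair.

Each reference gene receives an ordered conservation class — unprojected,
projected, projected with detected transcription (≥ 10 unique reads over
the projected locus), 1-to-1 ortholog, ortholog of the same gene class —
the highest class it satisfies.

# Expression

**Scaling normalization.** Genes are ranked within each sample; the 100
genes with the smallest across-sample rank variance, among genes whose mean
expression lies in the across-gene interquartile range, become the
reference set (ties in rank variance break by gene id for determinism;
within-sample rank ties use average ranks). Each sample is rescaled so the
median expression of the reference genes is identical across samples. The
selection statistics and the target median are computed on a copy of the
matrix whose columns are standardized to a fixed common total (10^6, the
TPM convention); the coefficients then apply to the original values. This
design makes the procedure exactly idempotent and exactly equivariant to
per-sample rescaling — properties the tests assert at 1e-9 — and is a
no-op standardization for genuine TPM input, where the raw and
standardized computations coincide. The common target is the mean of the
per-sample standardized medians; with fewer than 100 IQR candidates all of
them are used with a warning, and a zero median in any sample is an error
rather than a silent division by zero.

**Transforms and summaries.** Expression is analyzed as log2(TPM + 1).
Condition means average replicates per organ × stage per species. The
maximum-expression condition breaks exact ties by the fixed condition order
(brain, kidney, liver, testes, then ascending stage) and flags them.
Mitochondrial genes can be excluded via a configurable chromosome/biotype
list before any of this.

**Depth homogenization.** To compare detection across conditions, counts
are down-sampled without replacement (multivariate hypergeometric over all
gene × replicate cells of a condition) to the shallowest condition's total
within each species; detection then counts genes with ≥ 10 reads per
sample and class. Sampling without replacement guarantees exact totals,
preserves zeros, and preserves expected gene shares.

**Class depth matching.** For DE comparisons between classes of very
different abundance, protein-coding counts are thinned per sample by
`r = mean(lnc)/mean(pc)`. The default keeps each read independently with
probability `r` (binomial thinning), which maps a negative-binomial count
distribution with mean `mu` and dispersion `a` exactly onto one with mean
`r*mu` and unchanged dispersion — after matching, the two classes share
their full count distribution, not just their means, so any remaining
detection difference reflects the data and not the depth. A deterministic
proportional mode (scale and stochastically round) is available when exact
per-gene proportionality matters more than distributional matching.

**Markers.** Cross-species markers are ortholog pairs with specificity
τ = Σ(1 − x_i/x_max)/(n − 1) at least 0.8 in both species and the same
argmax condition in both. τ is the standard tissue-specificity index; the
0.8 default encodes "narrow expression distribution" and is configurable,
as no canonical cutoff exists.

# Developmental-stage differential expression

The DE engine is a deliberate stand-in for heavier machinery, built to be
fast, transparent and calibrated. Counts are modeled as negative binomial
with per-gene dispersion estimated by method of moments from the
full-model (per-stage) residuals with degree-of-freedom correction,
falling back to a Poisson likelihood when the moment estimate is
non-positive. With the dispersion fixed, the maximum-likelihood mean of
each group is its sample mean, so the likelihood ratio between the
per-stage model and the homogeneous model is available in closed form.
The statistic divided by its degrees of freedom is referenced to
F(k − 1, n − k) rather than chi-square(k − 1): with few replicates the
plug-in dispersion makes the chi-square reference visibly anticonservative
(about 12% type-I error at nominal 5% with three stages and three
replicates in our null simulations), while the F reference — the standard
small-sample treatment of an estimated scale — restores calibration, which
the acceptance tests verify against a binomial confidence band.
Consecutive stages are compared with a Wald test on the log mean ratio
using a delta-method standard error under the same variance model; it is
exactly antisymmetric in the group labels. FDR control is
Benjamini–Hochberg across tested genes; all-zero genes are untested.
Externally computed DE tables can be substituted wherever a DE result is
consumed (shared-DE intersection, concordance, clustering), which take
plain data frames.

Shared DE pairs are 1-to-1 orthologs with FDR < 0.01 in both species.
Stage concordance cross-tabulates the two species' maximum-expression
stages over shared-DE pairs, rows normalized to 100%. For clustering, each
pair's per-species stage profiles are divided by their maxima, concatenated
and clustered by Euclidean K-means — best of 50 k-means++-style seeded
restarts by within-cluster sum of squares, deterministic given the seed.
Genes with zero expression in a species have no relative profile and are
excluded.

# Conservation and divergence

**Sequence conservation** of a gene region is the mean per-base track score
over region bases that are not masked (exonic regions of other genes) and
have a defined score; genes with no scoreable bases are missing rather
than zero. Group summaries report the median per condition over genes
expressed above noise (mean TPM ≥ 1) with a percentile bootstrap 95%
interval over genes; groups under 10 genes are flagged unstable.

**Expression conservation index.** For one organ/stage condition,
`ec = rho_between / rho_within` on log2(TPM+1) over a gene category:
`rho_between` averages Spearman correlations over cross-species replicate
pairs and `rho_within` over within-species replicate pairs, both species
pooled. Cross-species pairs with matching replicate indices are excluded
from the between average: replicate labels carry no cross-species meaning,
the exclusion discards only n of n² pairs, and it gives the index an exact
calibration point — comparing a species against a copy of itself yields
ec = 1 identically, which the tests assert. The bootstrap resamples gene
pairs (the quantity whose sampling noise the envelope should reflect) 100
times and reports the min–max envelope. `rho_within ≤ 0` leaves the index
undefined with a flag. An alternative pairing that correlates
replicate-averaged profiles is available behind a flag.

**Expression divergence** between two species' sum-normalized relative
profiles (condition means divided by their total) is the Euclidean
distance; it is symmetric and zero iff the profiles agree. Because the
squared distance is a sum over conditions, `(p_A − p_B)²/d²` is the unique
per-condition decomposition whose shares sum to 1; genes with d = 0 are
excluded from contribution averages. Divergence increases at low
expression for purely statistical reasons, so an ordinary least-squares
regression of d on average log2 expression provides residual divergence;
the slope and intercept match the closed-form normal equations.

**Species-specific loci** are loci with ≥ 100 unique reads in one species
and exactly zero reads over the resolved projected region in the other;
unprojectable loci are excluded rather than miscounted as specific.

# The synthetic study and what it shows

`sim_config()` fixes the study conditions: two species, two chromosomes of
roughly 0.5 Mb each, 110 clean protein-coding and 110 clean lncRNA ortholog
families plus planted events (10 duplications, 6 translocated exon blocks,
4 double rearrangements, 6 deletions, 3 large insertions, 3 cross-chromosome
exon relocations, 4 + 4 species-specific insertions, 5 + 5
expression-species-specific loci), 5% nucleotide divergence, and a
4 organ × 3 stage × 3 replicate design with negative-binomial replicate
noise (dispersion 0.05), log-normal organ effects, lncRNAs expressed about
eightfold below protein-coding genes, half of lncRNAs testis-biased
(fourfold), 30% of genes stage-DE with monotone or peaked profiles, and
log-normal between-species divergence (sd 0.3 on the log scale). Chain
files are emitted directly from the true homology map — indels are confined
to intergenic spacers so ortholog exon blocks project exactly — because the
tests target pipeline logic, not aligner quality. Conservation tracks are
piecewise constant: a baseline of 0.1 with boosts of +0.6/+0.4/+0.8 on the
exons, promoters and splice sites of constrained genes, covering every base
exactly once. CSF training data evolve coding pairs under a
frame-preserving, synonymous-biased codon process that never introduces
in-frame stops, and noncoding pairs under uniform substitution. Everything
is reproducible bit for bit from the seed.

Each planted event type maps onto exactly one projection failure mode, so
recovery statistics are interpretable: duplications must become `ambiguous`
(never 1-to-1), double rearrangements `order_fail`, large insertions
`size_fail`, deletions `unmapped`. Ortholog recall on the default fixture
is therefore bounded near (246 − 7)/246 ≈ 0.97 by construction: the order-
and size-failure genes are true orthologs the method deliberately
discards.

What passing does **not** show about real data: the simulator has clean
single-isoform gene models, exactly consistent chains, no assembly noise,
no alignment error, no GC or mappability structure, and expression noise
exactly matching the DE engine's assumed family. The calibration results
(type-I error, EC gradient, depth-matching equivalence) are statements
about the method's internal consistency under its own model, not about
robustness to model misspecification.

# Numerical choices and degenerate inputs

Problem sizes in the default test and acceptance runs — ~270 gene families,
36 samples per species, 2,000-gene null DE simulations, 100-replicate
bootstraps, 1,000 random profile pairs — were chosen so the full suite
completes in a few minutes on one CPU while keeping binomial confidence
bands tight enough to detect miscalibration. Other conventions: "positive
CSF score" means strictly greater than zero; boundary thresholds follow
their quoted inclusivity exactly (e.g. 150 bp coding overlap is ≥, the
0.9 concordance cut is a strict < for failure); Spearman correlations on
constant vectors are undefined and fail the filter that needed them;
all-zero genes are excluded from profiles, markers and DE rather than
propagating NaN; the K-means restart loop is seeded once so results are a
pure function of (seed, restarts).

# Known limitations

* One informant per CSF scan; multi-species alignments must be reduced to
  pairwise informants first.
* The chain projector resolves ambiguity by chain score and a 1 Mb locus
  heuristic; real liftOver chains with nested/overlapping chain structure
  may need the external tool.
* The DE stand-in shares no code with DESeq2 and will not reproduce its
  numerics; it accepts external DE tables for that purpose.
* The EC index's bootstrap envelope is a min–max over 100 replicates, not a
  confidence interval with coverage guarantees.
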