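---
title: "Methods: U12 intron classification, retention calling, and the viability model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: U12 intron classification, retention calling, and the viability model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u12retain)
library(dplyr)
```

This vignette is the package's account of its models and the choices behind
them: what is computed, under which assumptions, with which defaults, and
what the synthetic benchmarks do and do not demonstrate.

## Intron catalogs

`extract_introns()` enumerates the inter-exon gaps of every multi-exon
transcript. Coordinates are 0-based half-open internally (GTF's 1-based
inclusive coordinates are converted on read; BED output needs no
conversion). Every intron sequence is stored in *transcript orientation* —
minus-strand introns are reverse-complemented — so the donor site is always
the 5' end of the stored sequence and one set of position weight matrices
serves both strands. Ranks run 1..k from the transcript 5' end.

Transcripts of the same gene often share introns. `dedup_introns()`
collapses the catalog to one record per distinct genomic intron per gene
and assigns gene-level ranks; classification and the adjacency statistic
work on this deduplicated set, because "the U2 intron immediately next to a
U12 intron" is a gene-level, not transcript-level, notion. Whether to
deduplicate before enrichment counting is genuinely open; we deduplicate
and say so here, since double-counting an intron shared by five transcripts
would otherwise inflate both the numerator and denominator of every
proportion.

Degenerate inputs: single-exon transcripts contribute nothing; a
transcript with overlapping exons is an error (the gap structure is
undefined); a chromosome missing from the genome is an error naming the
chromosome; abutting exons (zero-length gap) contribute no intron.

## Splice-site scoring

`build_pwm()` turns an alignment of equal-length site sequences into
per-position log2-odds against a background composition:

$$\mathrm{logodds}[i,b] = \log_2 \frac{(c_{ib} + \kappa\,\pi_b)/(n+\kappa)}{\pi_b}$$

with pseudocount mass $\kappa$ (default 1) distributed across bases by the
background $\pi$ (default uniform; a genome-derived mononucleotide
composition can be supplied). `N` characters contribute 0.25 of a count to
each base when training and score 0 when scanning — no evidence either
way. Log base 2 throughout, so scores are in bits.

Window geometry (the published analysis defers these to its U12-database
references, so they are package defaults, all configurable):

* **donor**: intronic positions +1..+12 (width 12);
* **branch point**: width 9, scanned near the 3' end;
* **U2 acceptor**: intronic positions −14..−1 (width 14).

The branch scan indexes a placement by the offset of its 3'-most base from
the intron end; the default search range is −40..−8, i.e. the branch
window ends between 8 and 40 nt upstream of the acceptor, where U12 branch
points concentrate. A placement must fit entirely inside the intron, so
introns shorter than window + 8 = 17 nt have no feasible placement and
receive a −Inf sentinel: they can never be called U12. Score ties are
broken toward the 3' end, the biologically typical branch position. The
U2 branch site is deliberately not scored — it is too degenerate to carry
information at this training-set size — so the U2 composite is donor +
acceptor only.

## Classification and the margin threshold

For each intron, `classify_intron()` computes a composite score per U12
subtype (donor + best branch placement) and the U2 composite (donor +
acceptor). The *margin* is the best U12 composite minus the U2 composite.
An intron is assigned `U12-ATAC` or `U12-GTAG` only when

1. the margin exceeds `margin_threshold`, **and**
2. its terminal dinucleotides match the winning subtype (AT..AC or
   GT..AG).

Everything else is U2 — the correct default, since U2 introns outnumber
U12 introns ~250:1. Sequences over 50% `N` are assigned U2 with a warning.
A composite tie between subtypes goes to the one whose termini match, then
to GT-AG (the commoner subtype in real genomes).

**Why the default margin threshold is 15 bits, not 0.** Zero would be the
Bayes rule if the two composites were calibrated likelihood ratios over
the same positions. They are not: the U12 side takes a maximum over ~33
branch placements, and the terminal dinucleotides enter both composites
asymmetrically. In particular, an AT..AC intron with *no* motif support
gains roughly 8 bits of margin from its termini alone, because AT and AC
are heavily penalized by the near-invariant GT/AG columns of the U2
matrices. Measured on the fixture matrices, genuine U12 sites score
margins of +30..+60 bits while termini-only impostors centre near 0 with a
long right tail. The default of 15 bits — about half the typical composite
advantage of a real site — keeps sensitivity on genuine sites at 1.0 in
the plant-and-recover benchmarks while rejecting >90% of termini-only
impostors. The threshold is an explicit argument everywhere; users
retraining matrices on their own alignments should re-examine it.

**Fixture matrices.** `default_pwm_set()` builds its six matrices from
small hand-curated training alignments shipped in the package (no external
motif database needed): U12 donors with the canonical RTATCCTT block
nearly invariant and positions +9..+12 variable, the TTCCTTRAC branch
motif with the branch adenosine invariant, U2 donors with invariant GT and
a moderately conserved AAGT core, and U2 acceptors whose polypyrimidine
tract is genuinely low-information (every base occurs at every tract
position) with a strongly conserved YAG end. These widths and conservation
patterns mirror real minor/major intron site statistics; users with
organism-specific alignments should call `build_pwm()` on them instead.

## PSI and differential calling

PSI is the plain read ratio `100 * inclusion / (inclusion + exclusion)`.
Splicing tools apply internal corrections on top of this ratio; those are
deliberately out of scope — the ratio is the documented, testable contract
here, and the synthetic generator produces counts that satisfy it exactly.
A sample with zero reads has undefined PSI and makes its event
low-coverage rather than raising an error.

Group means are unweighted arithmetic means across samples (matching
"average inclusion levels"), not pooled counts, so a deep sample cannot
dominate a replicate group. ΔPSI = mean(MU) − mean(WT). Calls use a
*strict* inequality at the 10% default threshold — an event at exactly
ΔPSI = 10 is `unchanged` — and the coverage filter requires
`inclusion + exclusion >= min_reads` (default 10) in *every* sample.
Low-coverage events are never called, in either direction.

For intron-retention events the table format makes the counting explicit:
inclusion reads support the retained intron, exclusion reads are
spliced-junction reads. No alignment step is needed or provided.

## Enrichment and adjacency statistics

`u12_ir_enrichment()` counts U12-classified introns among the IR events
called up in the mutant and computes an exact binomial upper-tail p-value
against an expected fraction — exact rather than chi-square because the
expected counts under a ~0.04% null are far below the chi-square comfort
zone. The default expected fraction is 0.0004, the genome-wide proportion
of U12 introns; **on synthetic catalogs the null must be the realized
catalog U12 fraction instead** (the generator deliberately over-represents
U12 genes at 3% to keep catalogs small — see below).

`adjacency_to_u12()` measures, for each affected U2 intron in a
U12-containing gene, the gene-level rank distance to the nearest U12
intron; distance 1 is "immediately upstream or downstream". Events in
genes with no U12 intron are excluded with a warning and reported
separately rather than silently dropped.

`two_proportion_ztest()` is the pooled-proportion z with a two-sided
normal p (whether the original comparisons were one- or two-sided is
unstated; two-sided is the conservative reading). A pooled proportion of
0 or 1 makes the statistic undefined; the function returns p = 1 with a
degenerate flag rather than NaN. `consensus_de_intersection()` accepts a
gene only when both input analyses call it at adjusted p < 0.01 *and*
agree on the direction of change; direction concordance is not in the
published rule, but "agreement" between two programs that disagree on the
sign would be meaningless. Per-class enrichment p-values are adjusted
across event classes with Benjamini–Hochberg.

## The viability model

Three biological facts drive the genetics: Zrsr1 is autosomal and
maternally imprinted (only the paternal allele is expressed); Zrsr2 is
X-linked and, because X inactivation is imprinted in the early embryo (the
paternal X is silenced until the blastocyst), only the maternal allele is
expressed before implantation; a male's single X is maternal anyway. An
early embryo is viable iff its expressed paternal Zrsr1 **or** expressed
maternal Zrsr2 is wild type.

`enumerate_offspring()` does the Mendelian bookkeeping exactly: the
autosomal locus segregates independently in each parent, the X-linked
locus rides the maternal X gametes, and offspring sex follows the paternal
X/Y gamete at 1:1. Both silencings are modeled as complete — no leaky
expression parameter — because the observed litter outcomes are
all-or-none and a leakiness parameter would be unidentifiable from them.
Viability is assessed at the early-embryo stage only; later failures of
rescued embryos are outside the model, and the observed ~20% of double
mutants that reach morula before arresting is left to the user's
`litter_consistency_test()` rather than folded into the viability rule.
That test is an exact multinomial (binomial for two categories)
goodness-of-fit: the p-value sums the probability of all outcomes no more
probable than the observed one; a category predicted impossible but
observed gives p = 0 immediately.

The model reproduces the defining asymmetry: a Zrsr2^mu/mu dam crossed to
a Zrsr1^mu/mu sire has viable fraction 0 (every embryo expresses mutant
copies of both genes), while the reciprocal cross has viable fraction 1;
and no surviving pup of a Zrsr2^WT/mu dam and Zrsr1^mu/mu sire can carry
the mutant Zrsr2 on its maternal X.

## The synthetic-data generator

`simulate_intron_catalog()` emulates the data regime the analysis assumes:
gene models on alternating strands, each a chain of exons and introns;
3% of genes carry exactly one U12 intron (30% AT-AC, 70% GT-AG) among U2
introns; splice-site blocks are sampled position-wise from the class's
matrices (donor at the 5' end, branch at a random feasible offset, U2
acceptor at the 3' end), terminal dinucleotides are forced canonical, and
interior sequence is uniform random. `simulate_event_counts()` draws
`inclusion ~ Binomial(depth, PSI/100)` per sample: baseline PSI 5 in both
groups, +25 in the mutant group for the 20 planted events, which land on
U12 introns with probability 0.5 (`planted_u12_bias = NA` plants uniformly
— the null used for type-I checks). Everything is deterministic given the
config seed.

Defaults (500 genes × 5 introns, depth 100, 3 replicates per group,
baseline PSI 5, effect +25) were chosen once as a realistic two-condition
embryo RNA-seq regime at desk scale: the U12 gene fraction of 3% is
deliberately ~8× the genomic gene-level rate so that a 2,500-intron
catalog still contains ~15 U12 introns, and effect size and depth match
what a ΔPSI > 10 threshold is meant to detect. The benchmark problem
sizes (one 500-gene catalog for classifier recovery, 5 × 2,500 events for
direction recovery, 100 seeded runs each for enrichment power and type-I
rate) are the package's standard report.

What the generator does **not** emulate, and hence what passing benchmarks
do not show about real data: overdispersed counts (the binomial has no
biological variance component), non-uniform intron background composition,
degenerate or non-canonical splice sites, alternative event classes beyond
intron retention, mappability or positional coverage bias, and any
dependence between events in the same gene. The benchmarks demonstrate
that the machinery is correct under its stated model, not that the default
thresholds are optimal for any particular organism or library type.

## Numerical conventions

All scores are log2; probabilities re-derived from a PWM renormalize
within 1e−9. PSI is in percent, ΔPSI in percentage points, bounded by
[−100, 100] by construction. Exact tests are used wherever the expected
counts are small (binomial enrichment, multinomial litter test up to ~10^6
compositions, beyond which a chi-square approximation is used with a
warning). Seeded generators restore the caller's RNG state
(`withr::local_seed`), and derived seeds stay within 32-bit integer range.

## Known limitations

* The classifier scores mononucleotide matrices only; dinucleotide or
  higher-order dependencies at splice sites are not modeled.
* The PSI contract is the raw read ratio; tool-specific corrections
  (mappability, event-complexity normalization) are out of scope, as is
  any statistical test on PSI beyond the ΔPSI threshold.
* The fixture matrices are consensus-derived teaching/testing sets, not a
  species-specific resource; serious use requires retraining on a curated
  alignment set.
* The viability model ignores post-implantation effects, mosaic X
  reactivation at the blastocyst, strain background, and partial escape.
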