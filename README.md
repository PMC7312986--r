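# u12retain

Minor-spliceosome intron classification and retention analysis for
two-condition transcriptome experiments.

## The problem

Fewer than 0.4% of introns are U12-type ("minor") introns, spliced by the
U12-dependent spliceosome. When minor-splicing factors fail — the motivating
case is mouse embryos carrying mutations in the Zrsr1/Zrsr2 paralogs, which
arrest at the 2-cell stage during zygotic genome activation — the signature
in RNA-seq is retention of U12 introns far in excess of their genomic
frequency. Asking "is my perturbation a minor-splicing defect?" requires
four pieces of machinery that this package provides as composable,
tibble-in/tibble-out functions:

1. **Intron catalogs** (`extract_introns()`): strand-aware enumeration of
   introns from a genome (FASTA) and annotation (GTF), with transcript
   ranks and terminal dinucleotides.
2. **U2/U12 classification** (`build_pwm()`, `classify_catalog()`):
   position weight matrices for donor, branch-point and acceptor sites.
   An intron is called `U12-ATAC` or `U12-GTAG` when its donor + best
   branch-point log2-odds beat the U2 donor + acceptor composite by more
   than a margin threshold *and* its terminal dinucleotides match the
   subtype.
3. **Differential splicing** (`call_differential()`): per-sample percent
   spliced-in, `PSI = 100 * inclusion / (inclusion + exclusion)`; events
   with `|ΔPSI| = |mean PSI(MU) − mean PSI(WT)| > 10` that pass a
   per-sample coverage filter are called up or down.
4. **Statistics** (`u12_ir_enrichment()`, `adjacency_to_u12()`,
   `two_proportion_ztest()`, `consensus_de_intersection()`): exact binomial
   enrichment of U12 introns among retained events, rank adjacency of
   affected U2 introns to U12 introns in the same gene, pooled
   two-proportion z-tests, and the two-program consensus rule for
   differential expression.

Two companion modules round this out: a genetics model
(`enumerate_offspring()`) for the imprinting/X-inactivation viability rules
of Zrsr1 × Zrsr2 crosses (Zrsr1 is expressed only from the paternal allele;
the paternal X — hence paternal Zrsr2 — is silenced in the early embryo, so
an embryo survives iff paternal Zrsr1 or maternal Zrsr2 is wild type), and
comparative-CT qPCR fold changes (`delta_delta_ct()`, the 2^−ΔΔCT method).
A seeded synthetic-data generator (`sim_config()`,
`simulate_intron_catalog()`, `simulate_event_counts()`) produces genomes,
annotations and count tables with known ground truth, so the whole pipeline
is testable without any external data.

## Worked example

Simulate a 100-gene catalog with planted U12 introns, classify it, call
differential retention, and test U12 enrichment:

```r
library(u12retain)
library(dplyr)

cfg  <- sim_config(n_genes = 100, seed = 42)
sim  <- simulate_intron_catalog(cfg)
cat_ <- extract_introns(sim$genome, sim$annotation)
cls  <- classify_catalog(cat_, default_pwm_set())
cls$summary
#> # A tibble: 2 x 2
#>   assigned_class     n
#>   <chr>          <int>
#> 1 U12-GTAG           3
#> 2 U2               497

ec    <- simulate_event_counts(sim$truth, cfg)
calls <- call_differential(ec$counts, threshold_percent = 10, min_reads = 10)
p0    <- mean(startsWith(cls$classifications$assigned_class, "U12"))
u12_ir_enrichment(calls, cls$classifications, expected_fraction = p0)
#> U12 enrichment: 3/20 (15.00%) vs 0.6000% expected; fold 25.0, p = 0.000228
```

All three planted U12 introns are recovered (497/500 introns are U2, as
planted), the 20 planted retention events are all called `up_in_MU`, and
the U12 share among the called events — 15%, capped here by the three U12
introns the small catalog contains — is 25-fold enriched over the
catalog-wide U12 fraction of 0.6%. This is the same logic as the published
comparison of 53/710 retained U12 events against the ~0.04% genomic
expectation:

```r
enrichment_binomial(53, 710, 4e-4)
#> U12 enrichment: 53/710 (7.46%) vs 0.0400% expected; fold 186.6, p = 2.62e-100
```

The genetics model reproduces the cross outcomes structurally:

```r
lethal <- enumerate_offspring(
  parent_genotype("female", c("mu", "mu"), c("mu", "mu")),  # Zrsr2^mu/mu dam
  parent_genotype("male",   c("mu", "mu"), "WT")            # Zrsr1^mu/mu sire
)
lethal$viable_fraction
#> [1] 0
```

Every result object has `tidy()`/`glance()` methods and an `autoplot()` or
`plot_*()` companion.

## Documentation

The methods vignette (`vignettes/u12retain-methods.Rmd`) describes the
scoring model, the classification margin and its calibration, the PSI
contract, the viability model's assumptions, and what the synthetic
generator does and does not emulate.
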