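# condelscreen

Comparative genomic screening for **CONDELs** — conserved sequence
deletions: genomic intervals that are well conserved across species with a
complete ancestral trait (*outgroups*) but missing, deleted or too diverged
to align, in multiple independent lineages with the reduced trait
(*targets*). Recurrent deletion of a conserved element across unrelated
trait-reduced clades is strong evidence that the element matters for the
trait, and the screen was designed for exactly that genotype-to-phenotype
question in large panels of fish genomes, where fin loss has evolved many
times independently.

The package takes UCSC pairwise alignment **chains** of many query genomes
against one reference, plus gene models and a species phenotype table, and
reports candidate intervals with linked genes, per-clade deletion support,
conservation support, genotype-phenotype violations, and genomic context.

## The screen in brief

For each reference gene with orthology-confident chains in at least 17
outgroups and 5 targets, the window `TSS ± 200 kb` (400,001 bp unclipped)
around the canonical isoform's transcription start site is scanned for
bases where

* at least ⌈2/3⌉ of the mapped members of **every** screened target clade
  show a chain gap (sequence missing from that query genome), with gaps
  within 100 bp of an assembly N-run discarded as assembly artifacts and
  gaps merged within 20 bp per chain; and
* conserved elements of at least 17 outgroups cover the base, where each
  species' conserved elements are its top sliding-window identity segments
  (10/25/50/100 bp windows pooled) up to a merged coverage of 5% of the
  non-N reference, with ties at the cutoff included.

Intersections of at least 20 bp are merged within 20 bp; pieces of at least
50 bp that show a gap in at most one *scorable* outgroup become CONDELs,
unified across calling genes and classified as coding-exon,
genic-noncoding, or intergenic.

Downstream statistics included: one-sided exact binomial term enrichment
with Benjamini–Hochberg FDR over a user-supplied gene→term table,
Boschloo's exact unconditional 2×2 test (two-tailed, nuisance parameter
maximized over a refined grid), and the two-tailed Mann–Whitney U test.

A first-class synthetic data generator (`simulate_study()`) builds a
complete miniature study — reference, genes, per-species chains and query
FASTA, phenotypes, and a truth set of true CONDELs plus decoys that each
violate exactly one screen criterion — so the whole pipeline is testable
without downloading genomes.

## Worked example

```r
library(condelscreen)

bundle <- simulate_study(simulation_config())   # 1 Mb, 30 species, ~10 s
result <- run_condel_screen(bundle)             # a few minutes on one core
result$candidates[, c("condel_id", "start", "end", "length",
                      "conserved_support", "violations", "context")]
#>   condel_id  start    end length conserved_support violations         context
#> 1  CONDEL.1 150413 150641    229                20          0      intergenic
#> 2  CONDEL.2 173048 173256    209                20          0 genic-noncoding
#> 3  CONDEL.3 343650 343746     97                20          0      intergenic
#> 4  CONDEL.4 410815 411017    203                20          0      intergenic
#> 5  CONDEL.5 546381 546483    103                20          0      intergenic
#> 6  CONDEL.6 667312 667443    132                20          0      intergenic
#> 7  CONDEL.7 778342 778528    187                20          0 genic-noncoding
#> 8  CONDEL.8 913898 914047    150                20          0      intergenic

evaluate_recovery(result$candidates, bundle$truth)[c("recall", "precision")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1
```

All eight engineered true CONDELs are recovered (every candidate covers its
truth interval; `conserved_support` is the number of outgroups whose
conserved elements cover every candidate base; `violations` counts scorable
outgroups contradicting the conserved genotype), and none of the sixteen
decoys — quorum failures, diverged regions, assembly-gap artifacts, and
outgroup-violation traps — produce a candidate.

The exact test used for the genome-editing outcome tables:

```r
boschloo_two_tailed(14, 15, 161, 396)
#> [1] 3.549890e-05
```

A thin CLI over the same functions ships in `inst/exec/condel`
(`condel simulate`, `condel screen`, `condel enrich`, `condel boschloo`).

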