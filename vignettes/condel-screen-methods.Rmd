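---
title: "Methods: screening whole-genome alignments for recurrently deleted conserved sequences"
author: "condelscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening whole-genome alignments for recurrently deleted conserved sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condelscreen)
```

## The problem and the model

Traits that are repeatedly lost in independent lineages offer a route from
phenotype to genotype: a genomic element that is well conserved in every
species carrying the ancestral, complete trait, yet missing from several
unrelated lineages with the reduced trait, is a strong candidate for a
regulatory or coding sequence whose loss contributes to the trait change.
`condelscreen` implements this comparative screen over UCSC pairwise
alignment chains of many query genomes against a single reference.

The screen treats every species as one of three roles. The *reference*
supplies the coordinate system and gene models. *Outgroups* carry the
complete trait and define conservation. *Targets* carry the reduced trait
and are organised into clades; deletions must recur in a quorum of each
screened clade so that a single assembly artifact or lineage-specific loss
cannot drive a call. A CONDEL (conserved sequence deletion) is an interval
that simultaneously satisfies, at every base, a deletion quorum in each
screened target clade and a conservation quorum across outgroups, and that
survives length, merging and genotype-phenotype-violation filters.

## From chains to evidence

**Orthologous chains.** Alignment chains are accepted per gene through two
inclusive ratio criteria with threshold 10: the winner (most aligned bases
inside the gene's canonical span; ties by header score, then smaller chain
id) must align at least ten times as many in-gene bases as the runner-up
chain, and must carry at least ten times as many aligned bases genome-wide
as inside the gene. The second criterion encodes "gene in synteny": a chain
that aligns little beyond the gene is a poor orthology witness. The exact
formulation of these two criteria in the lineage of tools this package
follows is not fully published, so the package documents this pair of
base-count ratios as its own explicit interpretation and keeps both
thresholds configurable; all downstream behaviour depends only on which
chain is accepted.

**Chain gaps.** Every inter-block separator with reference-side length
`dt > 0` is recorded as sequence missing from the query: *single-sided*
when the query is contiguous (`dq = 0`), *double-sided* when the query has
unaligned sequence (`dq > 0`). Both kinds enter the screen identically;
sidedness is retained for reporting. A gap whose query context lies within
100 bp (inclusive, measured from the context edges — the conservative
choice for double-sided gaps) of an assembly N-run longer than 5 bases is
discarded as a likely assembly artifact. Proximity is measured in query
coordinates because the suspect N-run lives in the query assembly.
Surviving gaps are merged within 20 bp *per chain* before per-species gap
sets are unioned across chains.

**Conserved elements.** For each outgroup chain, percent identity is
computed in sliding windows of 10, 25, 50 and 100 bases laid inside
ungapped alignment blocks (windows never span a block boundary, so no gap
columns arise; matching is case-insensitive and N never matches). The
window step defaults to 1 — maximally sensitive and affordable at the
problem sizes this package targets — and is configurable for large
genomes. All window sizes are pooled into one ranked list per species,
sorted by identity; windows are accumulated until their merged coverage
first reaches 5% of the reference's non-N length, all windows tying the
stopping window's identity are added, and the result is merged within
20 bp. Because the tie cohort always enters whole, the selection reduces
to an identity threshold and is independent of how ties are ordered;
internally the threshold is located by binary search over distinct
identity levels and coverage is computed with a linear sweep over
start-sorted windows, which is exactly equivalent to the accumulation
description above. The non-N quota basis was the open design choice here:
N-runs cannot align, so quoting coverage against alignable sequence keeps
the quota meaningful for fragmented assemblies; the basis is a plain
function argument for users who prefer full assembly length.

**The gene-centric scan.** A gene is eligible when it has accepted
orthology calls from at least 17 outgroups and 5 targets. Its window spans
200 kb on both sides of the canonical (longest-span) transcript's
strand-aware TSS — 400,001 bases when unclipped. Within the window, the
target-deletion mask keeps bases where at least ⌈2/3 × mapped clade
members⌉ of **every** screened clade show a gap; screened clades default to
those with at least two mapped members, so single-representative lineages
are reported but never gate candidacy. Quorum denominators count mapped
members only: a target with no accepted chain for the gene can neither
support nor dilute the quorum. The deletion mask is intersected with bases
covered by conserved elements of at least 17 outgroups (the reference is
never counted); intersections of at least 20 bp are merged within 20 bp,
and pieces of at least 50 bp are kept. Finally, a candidate is discarded
if more than one *scorable* outgroup — an outgroup whose accepted chain's
reference span fully contains the candidate — shows a gap overlapping it;
non-scorable outgroups neither support nor violate. Candidates produced
under different genes that overlap by at least one base are unified, with
the union of calling genes as `linked_genes`, and classified as
`coding-exon`, `genic-noncoding` or `intergenic` in that precedence order.

## Statistics

Gene-set enrichment uses the one-sided exact binomial over-representation
test: for a term with `K` of `N` background genes and `k` of `s` study
genes, `p = P(X >= k)` with `X ~ Binomial(s, K/N)`, corrected across terms
by Benjamini-Hochberg FDR. Under-representation is deliberately not
computed; the screen only interprets enrichment folds above 1.

Editing-outcome tables are compared with Boschloo's exact unconditional
test: the one-sided statistic is Fisher's exact one-sided p of the
observed table, and the p-value maximises the rejection probability over
the common success proportion, scanned on a 999-point open grid with local
refinement around the maximum (doubling the grid moves the reported values
by far less than one part in 10^6). The two-tailed value is twice the
smaller one-sided value, capped at 1 — the doubling convention of the
statistics library used in the original analyses. One subtlety deserves a
warning: unconditional tests are *not* invariant to transposing the 2x2
table, because transposition changes which margin is conditioned on. The
worked reproduction in `scripts/acceptance.R` therefore states explicitly
which margins are fixed. Reporter-assay comparisons use the two-tailed
Mann-Whitney U test, exact for small untied samples and otherwise the
tie- and continuity-corrected normal approximation.

## The synthetic study generator

`simulate_study()` builds a complete miniature study so that every stage of
the pipeline can be validated against a known truth set without any
genome downloads. Its defaults are the package's study conditions: a 1 Mb
single-chromosome reference; 40 genes with 2-5 exons and one or two
transcripts; 20 outgroups at 2% substitution divergence; two screened
target clades of 4 and 3 species at 5% divergence, plus two
single-representative targets; 8 true CONDELs of 60-300 bp; four decoys of
each decoy class; and four benign N-runs per target assembly. Chains are
derived *analytically* from each species' edit script rather than by
running an aligner: a deletion of length L yields a separator with
`dt = L` and `dq = 0`, or `dq > 0` when a query insertion is co-placed at
the breakpoint, so both gap sidednesses occur; roughly a third of species
are emitted on the query minus strand to exercise strand bookkeeping. This
removes aligner nondeterminism and external binaries, and makes chain
invariants hold by construction.

Each decoy class violates exactly one screen criterion: `single_clade`
deletions reach quorum in only one clade; `low_conservation` deletions sit
in regions diverged every 6 bases in all outgroups, so no identity-1
window survives there; `assembly_gap` deletions carry an injected N-run
20 bp from the query gap edge, inside the 100 bp masking proximity; and
`outgroup_violation` deletions recur in two outgroups, one more than the
violation cap. True CONDELs (and their flanks) are kept substitution-free
in non-deleting species — an extension of the breakpoint buffer that makes
window identities interpretable — so that their conservation support and
recovery are guaranteed by construction, which is what a recall-of-1
acceptance check requires. Decoy deletions receive no breakpoint jitter:
jittered edges of, say, a low-conservation decoy would leak sub-50 bp
boundary fragments that are then rejected by the length filter rather
than by the criterion the decoy was built to violate.

What the generator deliberately does not emulate: realistic indel and
substitution processes (divergence is uniform outside engineered regions),
rearrangements and inversions, repeat families, paralogy (one chain per
species, which makes the orthology criteria pass trivially — those
criteria are exercised by constructed multi-chain unit fixtures instead),
and assembly fragmentation beyond injected N-runs. Passing the end-to-end
checks therefore demonstrates the screen's bookkeeping and thresholds, not
robustness to alignment noise in real genomes.

## Numerical choices and degenerate inputs

* Intervals are held as `GRanges` (1-based, closed), the convention of the
  genomics stack this package builds on; chain and BED files keep their
  native 0-based half-open convention on disk and are converted at the I/O
  boundary. "Within 20 bp" merges at separation ≤ 20; "within 100 bp"
  masks at distance ≤ 100; both boundaries are inclusive and tested.
* `clade_quorum()` computes `ceiling(fraction * size - 1e-9)`: 2/3 × 3
  evaluates to 2.0000000000000004 in doubles, and the small slack restores
  the intended rational arithmetic.
* Window identities are exact rationals stored as doubles; equal fractions
  from different window sizes (9/10 and 90/100) round to the identical
  double under IEEE division, so tie detection is exact.
* An empty interval set, a single-block chain (no separators), a gene with
  no aligned bases, and a screened clade with zero mapped members all
  short-circuit to empty results rather than erroring; a window extending
  past a chromosome end is clipped.
* The conservation quota falling short of supply selects all windows; a
  nuisance grid of 999 points with one `optimize()` refinement bounds the
  Boschloo maximisation error well below the three significant figures the
  reproductions require.

## Problem sizes and runtime

The default synthetic study (1 Mb reference, 29 aligned species) runs the
full pipeline in a few minutes on a single core, dominated by the ~4
million identity windows per outgroup; unit fixtures are all under 10 kb
so that brute-force per-base oracles stay exact and fast. The generator's
defaults were chosen once as the package's study conditions and are not
tuned per machine.

## Known limitations

* The orthology criteria are an explicit interpretation (documented above)
  and may differ from the unpublished originals; they are isolated behind
  `map_gene_to_chain()`.
* Deletion versus extreme divergence cannot be distinguished beyond the
  chain evidence itself; the screen inherits whatever the chaining step
  decided.
* Conservation is plain percent identity, not a phylogenetically weighted
  score; closely related outgroups therefore contribute correlated
  support.
* With low divergence and many perfect windows, the 5% quota stops inside
  the identity-1.0 tie cohort, and conserved elements can legitimately
  cover far more than 5% of the reference. This is the documented
  behaviour of the tie rule, and it is the regime the default generator
  operates in.
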