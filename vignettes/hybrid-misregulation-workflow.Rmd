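---
title: "Detecting misregulated allele-specific expression in hybrid embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting misregulated allele-specific expression in hybrid embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridase)
```

## The scientific problem

Interspecific F1 hybrids between chicken-like and quail-like parents carry
one haploid genome from each species in every cell. When such embryos
arrest before gastrulation, one candidate mechanism is *regulatory
misregulation*: genes that must be switched on between the early blastoderm
stage (stage X) and the preprimitive-streak stage (stage XIII/XIV) fail to
respond in the hybrid nuclear environment, on either parental allele.

Testing this requires three measurements per gene:

1. the stage contrast in each pure parental species (series Q and G),
2. the same contrast for each parental *allele* inside the hybrid,
   measured by allele-specific expression (series HQ and HG), and
3. a comparison of the *directions* of change (up / down / unaltered)
   across the four series.

A gene upregulated between stages in **both** parents whose hybrid shows
upregulation of **neither** allele is called *pattern D* — the
misregulation signature. `hybridase` implements this entire analysis as
testable components, together with a synthetic-data generator that plants
known regulatory programs so every stage of the pipeline can be validated
against ground truth.

## Allele-specific counting by competitive dual-genome mapping

Hybrid reads cannot be assigned to an allele by position alone; assignment
relies on fixed sequence differences between the parental genomes. Each
read pair is aligned competitively against *both* parental transcript sets:

- an exact k-mer index (default `k = 31`) proposes candidate locations on
  both strands; every candidate is verified by a full-length ungapped
  (Hamming) comparison, and locations with more than `max_mismatches`
  (default 2) per mate are rejected;
- a pair is *concordant* in a genome if the mates hit the same gene on
  opposite strands in FR orientation with a fragment span inside
  `fragment_window` (default 150–350 nt);
- within a genome only the best-mismatch concordant location is kept; more
  than one distinct best location discards the pair as multi-mapped;
- pairs concordant in exactly one genome are *species-specific* and feed
  the allele-level counts; pairs concordant in both genomes are *common*
  and are removed before counting, because they carry no allelic
  information; remaining pairs are discarded as unmapped, orphan (one mate
  only), or discordant.

The per-mate mismatch budget trades sensitivity against specificity: with
no mismatches allowed, sequencing errors and divergent sites discard many
truly assignable pairs; with a large budget, reads begin to align to both
genomes and become common. On synthetic data at 7% divergence the
species-specific fraction peaks at 2 allowed mismatches and the common
fraction increases monotonically with the budget — `mismatch_sweep()`
reproduces this directly.

Because the generator diverges the genomes by substitution only (no
indels), coordinates are shared between genomes and ungapped verification
is exact. This is a deliberate simplification: the mismatch filter, not
gapped alignment, is the operative rule being studied. Seed sensitivity is
the one caveat — a location can be missed only if the read's mismatches
break every k-length window. For 100 bp mates with 2 mismatches, `k = 15`
guarantees an intact seed (`ceiling(100 / 3) >= 15`); the test suite
proves the seeded search equivalent to a brute-force scan of every window
under both `k = 31` (with seed-compatible mismatch placement) and
`k = 15` (unconditionally).

## The stage-contrast model

Counts for gene *i* in sample *j* are modelled as negative binomial with
mean `s_j * q_{stage(j)}` and variance `mu + alpha * mu^2`:

- **Size factors** `s_j` come from median-of-ratios normalization: the
  reference is each gene's geometric mean across samples (over genes
  positive everywhere), and `s_j` is the median ratio of sample *j* to the
  reference.
- **Dispersion** `alpha_i` is estimated by method of moments on normalized
  counts with stage means removed, floored at `1e-8`. With three
  replicates per stage the per-gene moment estimate is noisy, and genes
  whose dispersion is underestimated by chance inflate the Wald statistic
  well beyond the inflation of the test itself (the test suite checks the
  empirical null rate directly). We therefore floor each gene's estimate
  at the **common dispersion** (the
  across-gene median of the raw moment values). This shares information
  across genes without imposing a mean–dispersion trend; for Poisson-like
  data the common floor collapses to `1e-8` and the estimator is
  unchanged. `common_floor = FALSE` restores the plain estimator.
- **Wald test**: stage means are fitted per gene by one-dimensional
  likelihood maximization at fixed dispersion; the effect is
  `log2fc = log2(q_XIII/XIV / q_X)` (later over earlier stage, so
  developmental induction is positive), its standard error comes from the
  observed information on the log scale, and `z = log2fc / se` is referred
  to the standard normal. If one stage has all-zero counts its fitted mean
  is floored at `0.5 / mean(s_j)` and the gene is flagged.
- **Multiplicity**: Benjamini–Hochberg within each (series, sex)
  comparison.

This is intentionally a transparent analogue of the standard
negative-binomial Wald workflow, without dispersion-trend shrinkage,
log-fold-change shrinkage, outlier replacement, or independent filtering.
The downstream claims ride on the *direction call*, which is deliberately
coarse:

- **up**: FDR < 0.05 **and** FC > 2;
- **down**: FDR < 0.05 **and** FC < 0.5;
- **unaltered**: otherwise (FDR ≥ 0.05, or 0.5 ≤ FC ≤ 2).

All inequalities are strict as written: a gene at exactly FC = 2 or
FDR = 0.05 is unaltered.

Before testing, genes with a count below 1 in any sample of the comparison
are excluded (`filter_low_counts()`). The filter is applied per
(series, sex) matrix because each stage contrast is run per series; the
gene universe for cross-series work is the intersection of the per-series
retained lists (`common_universe()`), computed per sex.

## Pattern classification and misregulated sets

For each sex, every gene in the universe receives a 4-tuple of direction
calls over (Q, G, HQ, HG) and a four-digit code (1 = up, 2 = down,
0 = unaltered, in that series order; the digit map is cosmetic output
only). Genes upregulated in both parents are *eligible*; among them:

| pattern | HQ  | HG  | reading |
|---------|-----|-----|---------|
| A | up | up | both alleles respond |
| B | not up | up | chicken-derived allele only |
| C | up | not up | quail-derived allele only |
| D | not up | not up | misregulated |

"Not up" includes both down and unaltered. `misregulated_sets()` then
applies the study's union/intersection logic across sexes: eligibility in
at least one sex, pattern D in at least one sex (the misregulated set),
and pattern D in both sexes (the consistent core).

`concordance()` summarizes any two series over the shared universe with a
3×3 direction table, the percent of genes on the diagonal, and the Pearson
correlation of the paired log2 fold changes. On data simulated under the
default program, parent-vs-own-allele comparisons (Q vs HQ, G vs HG) show
both higher correlation and a higher same-direction percentage than the
between-parent comparison (Q vs G) — the hybrid alleles retain their
parental regulatory behaviour except at the planted misregulated genes.

## Overrepresentation of the misregulated set

`fisher_overrep()` is a one-sided Fisher (hypergeometric upper-tail) test
of a study set against a population, per annotation term, with BH
adjustment and a strict FDR < 0.05 reporting cutoff. The population
defaults to the analyzed-gene universe (the union of the two per-sex
universes, matching the "male and/or female" eligibility convention), not
the full annotation: testing against all annotated genes would confound
expression-level detectability with biology. Terms with no annotated
population genes are untestable and skipped. No ontology-graph
propagation is performed; annotations are taken as supplied.

## What the generator emulates — and what it does not

The synthetic model plants every quantity the pipeline later estimates:

- **References**: one transcript per gene, independent per-site
  substitution at rate 0.07 (a chicken–quail-like coding divergence),
  identical ortholog lengths, 1:1 orthology.
- **Program**: a fraction (default 10%) of genes upregulated in both
  parents with |log2FC| = 2; half of those misregulated in the hybrid
  (both allelic fold changes zeroed — pattern D), the rest concordant
  (pattern A). Other genes draw parental directions independently from
  `direction_mix` (default 15% up, 15% down, 70% unaltered, conditioned on
  not being up in both so the planted class stays exactly binomial), and
  their hybrid alleles track the conspecific parent. Patterns B and C are
  never planted; they arise only as call noise, which keeps planted truth
  unambiguous.
- **Design**: 3 replicates per (series, stage, sex) cell — 36 samples —
  with log-normal library-size factors (sdlog 0.15). The baseline mean is
  a constant 200 normalized counts; a constant baseline isolates the
  regulatory signal from expression-level heterogeneity, and a sampler can
  be supplied where that heterogeneity matters.
- **Counts**: negative binomial with dispersion 0.05; hybrid samples
  produce two allele-level matrices at half the series mean each
  (symmetric allele usage; within-stage allelic imbalance is out of
  scope).
- **Reads**: 100 bp FR pairs, fragment length 250 ± 25 (normal, clamped),
  uniform starts, fragment mass proportional to expression × length,
  per-base error 0.001, constant "I" qualities (qualities are never used).

Real libraries violate several of these assumptions: GC and positional
bias, PCR duplicates, splice structure, indel divergence, cis-regulatory
allelic imbalance, and mapping-efficiency asymmetries between genomes are
all absent. Passing the recovery tests therefore shows the *inference
machinery* is correct under its stated model, not that real chicken–quail
libraries would yield these accuracies. In particular, between-genome
mapping-efficiency differences are why the original design never compares
expression *levels* across species — only within-series stage contrasts —
and the package keeps that restriction.

## Numerical choices and degenerate inputs

- Stage-mean fitting brackets the log-mean root at ±30 around the
  count-based starting value; all-zero stages take the pseudo-mean floor.
- `estimate_size_factors()` errors when no gene is positive in all samples
  (advice: lower the filter threshold) rather than silently returning
  unusable factors.
- Zero-variance log2FC vectors make the Pearson correlation undefined; it
  is reported as `NA` with a warning, never as 0.
- An empty series intersection yields an empty universe with a warning and
  empty downstream sets.
- BH ties and order: adjustment is computed on the full vector and
  returned in input order; term reports break p-value ties by term id so
  output order is reproducible.
- Reproducibility: one global seed; each pipeline stage derives a fixed
  child seed from it, so stages can be rerun in isolation and a full rerun
  is byte-identical. Derived seeds stay below 2^31.

## Problem sizes

The shipped defaults (1,000 genes, 20,000 read pairs per sample, 36
samples) run the full read-level pipeline in a few minutes on one core.
The statistical validation suite uses counts-level simulation at the same
gene scale — read simulation and mapping are validated separately at
smaller scale (tens of genes, thousands of pairs), where the brute-force
mapping oracle is affordable — chosen as the smallest sizes at which the
binomial/moment oracles have useful resolution.

## Known limitations

- Ungapped, transcript-level mapping only; no splicing, indels, or
  base-quality model. The mapper is a desk-scale stand-in for a spliced
  aligner, built to make the mismatch-filter rules exact and testable.
- The Wald test is the plain asymptotic one; with 3 replicates per stage
  its raw p-values are only approximately calibrated (the suite checks
  the empirical null rate stays within a documented band).
- Direction calls are threshold rules, so genes near FC = 2 or FDR = 0.05
  flip between adjacent categories under resampling; concordance
  percentages inherit that variance.
- The four-digit pattern code is display output; the digit assignment for
  down vs unaltered is a package convention.
- No figures are produced; every result is a TSV table designed to be
  diffable and assertable in tests.
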