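---
title: "Rare SV discovery with pangenome controls: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare SV discovery with pangenome controls: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svsieve)
```

## The problem

Long-read sequencing and assembly make structural variants (SVs, >= 50 bp)
callable in repetitive regions that short reads cannot resolve, but a single
family cohort produces tens of thousands of validated SVs per child — far
too many to evaluate clinically. The decisive step is *population
filtering*: comparing each family's SVs against panels of haplotype-resolved
control genomes ("pangenome controls") so that only variants private to the
families remain. svsieve implements that workflow end to end — multi-caller
validation, cohort-wide collapsing, control filtering, Mendelian and origin
classification, evidence-based curation of discordant calls, regulatory
annotation and candidate ranking, burden statistics, panel-scaling analyses,
sex-chromosome contiguity scoring and X-inactivation (XCI) skew — together
with a synthetic cohort generator that records ground truth, so every stage
is testable without access-controlled data.

## SV matching and collapsing

Two records match when all enabled criteria hold:

* same type and chromosome;
* breakpoint distance `|start_a - start_b| <= refdist` (default 500 bp);
* size similarity `min(l_a, l_b) / max(l_a, l_b) >= pctsize` (default 0.90);
* sequence similarity `1 - editdist / max(l_a, l_b) >= pctseq`
  (default 0.90; 0 disables);
* when reciprocal overlap is enabled (`pctovl`, used for relaxed
  cross-platform comparisons at 0/0.5/0.5), the spans must overlap
  reciprocally; insertions are points and satisfy overlap whenever their
  breakpoints are within `refdist`.

Design choices that the published tooling leaves unspecified, decided here:

* **Sequence similarity** is normalized Levenshtein similarity over the
  inserted (or deleted) sequences. It is a transparent, symmetric stand-in
  for whatever alignment heuristic a collapsing tool uses internally;
  equivalence is claimed only for this definition. Records lacking sequence
  fall back to size-plus-position matching.
* **Inversions** never use sequence similarity — comparing an inverted
  segment to itself is ill-defined — and match on size, position and
  overlap only.
* **Collapse is exact connected components** under the match relation,
  restricted to edges whose starts lie within `refdist`, not an
  order-dependent greedy sweep. This makes the partition reproducible and
  checkable against a brute-force all-pairs union–find oracle (the test
  suite does exactly that). The `keep` policy only selects the
  representative row: `common` (allele seen in most samples), `maxqual`, or
  `first`, with ties broken leftmost then lexicographically.
* **Two heterozygous calls of the same sample** are never connected by a
  direct edge (they are evidence of two distinct alleles), except when they
  are byte-identical records. Transitive merges through other samples'
  records remain possible; genotype conflicts arising in a merged row
  resolve to the highest-quality non-missing constituent and are counted in
  the collapse log.

## Control filtering and classification

A collapsed row is *rare* when at least one child carries it and no control
does. On chrX and chrY the control comparison is sex-matched: a carrier
child is compared only against controls of the same sex, because hemizygous
male genotypes and diploid female genotypes are not exchangeable evidence.
PAR intervals are configurable and treated as autosomal (diploid in males).

Each retained (SV, child) pair receives exactly one of six zygosity
categories — autosomal het/hom, X het/hom (females), X/Y hemizygous
(males) — and a Mendelian confidence: HC when the child genotype is
producible from the parental genotypes under sex-aware transmission (sons
receive the maternal X and paternal Y), LC otherwise or when a parent is
missing.

Variant origin is resolved per pair:

* `DENOVO`: the child carries and both parents are confidently absent. This
  pattern is *itself* Mendelian-discordant, so it is deliberately labeled
  after the LC handling: a clean de novo pattern is classified directly,
  while all other LC rows become `UNRESOLVED` and enter the curation
  cascade. At a genotyping error rate of zero this recovers injected de
  novo events with sensitivity and precision 1; with errors, false
  apparent de novo calls appear (a child flip at a locus absent everywhere
  mimics one) and are exactly what the cascade re-examines. A homozygous
  child with two absent parents is not labeled de novo (two independent
  mutations are implausible); it stays unresolved.
* `PRIVATE_INHERITED`: the transmitting parental allele occurs in exactly
  one parent across the entire parental population. The transmitting parent
  is counted — the published definition ("observed only once in the
  parental population") does not state whether it is, and counting it keeps
  the definition monotone under panel growth.
* `PRIVATE_BIALLELIC_HOM`: child homozygous, inherited from two
  heterozygous parents, family-unique among all parents, and never
  homozygous in any control.
* everything else inherited: `INHERITED_OTHER`.

Missing control genotypes never count as carriers.

## The curation cascade

Mendelian-discordant calls are resolved by ordered, transparent evidence
steps; the first decisive step wins:

1. **Parental raw-callset match** (relaxed 0.9/0.9 matching against
   pre-validation parental calls): a hit rescues the call as transmitted —
   the parent allele existed but was dropped by callerset validation.
2. **Re-genotype consistency**: re-genotyped family calls are fed back
   through the Mendelian rules; consistent transmission confirms
   inheritance, confident parental absence with a carrier child confirms de
   novo status. A child that re-genotypes as a non-carrier is a spurious
   call and is left for manual review rather than confirmed either way.
3. **Parental read support**: supported when at least `min_reads` (default
   1) read observations fall within a 50% size-deviation cap, evaluated in
   a window dynamic in the SV size (`max(svlen, 500)` bp — the published
   description says the window is size-dependent without giving the
   function, so the package fixes this one).
4. **TR expansion outliers**: a child allele length is an outlier when it
   exceeds the population mean by >= 3 SD *and* every other sample's
   alleles (the transmitting parent excepted); its origin is the parent
   carrying a matching long allele. The z + maximum rule is this package's
   formalization — the source workflow reports outliers without a formula.
   Loci with under 20 genotyped samples or zero variance are skipped.

Undecided rows end as `UNRESOLVED_MANUAL`, the terminal state that a visual
inspection step would consume. Two invariants are enforced by construction
and tested: a de novo verdict is never issued while a parental raw match
exists, and disabling all steps leaves every row unresolved. The trained
machine-learning quality model used by the original workflow is out of
scope; the rule-based read-support step covers its role, and a per-SV
quality column can be supplied by users who have one.

## Annotation and prioritization

Track intersection uses any-overlap (>= 1 bp) semantics; insertions are
intersected as 1 bp points at the insertion coordinate (the inserted
sequence does not occupy reference space). Functional categories partition
every SV set with precedence EXON (any exon or UTR overlap) > INTRON
(inside a gene span) > INTER. Constraint scores attach as the maximum over
overlapped intervals.

Candidates rank under three rule groups: (A) de novo and either exonic in
an NDD-flagged gene or regulatory/TF-cluster overlap near a risk gene; (B)
private biallelic homozygous in or near a SFARI-flagged gene or regulatory
DNA; (C) any rare SV combining a constraint maximum >= 4 with a promoter
overlap. "Near" means within the gene span or a 50 kbp flank — the source
analysis links intergenic regulatory SVs to named genes without stating a
distance, so the flank is explicit and configurable here. Prioritization is
monotone: adding a flag never removes a candidate.

## Burden statistics

The chi-square comparison builds, per group, the 2x2 table (event count,
sample count) — i.e. events against group-size slots. The published
analyses print chi-square p-values and odds ratios without printing the
table; this construction reproduces their direction and magnitudes (21 de
novo events in 51 probands versus 15 in 36 siblings gives OR 0.99 and a
Yates-corrected p of 1) and is stated prominently as an interpretation.
Yates continuity correction is on by default (small counts; toggleable);
odds ratios use the Haldane–Anscombe 0.5 correction when a cell is zero;
"adjusted p" is Bonferroni, the simplest family correction consistent with
a nominal 0.29 capping at 1. The Mann–Whitney comparison reports the
tie-corrected normal Z (positive when probands are higher) without
continuity correction — matching the convention in which Z = -0.23 pairs
with p = 0.82 — and switches to the exact permutation distribution when the
smaller group has at most 8 samples.

One calibration note: the type-I-error calibration test (500 null
replicates, rejection rate within 99% binomial bounds of 0.05) is run on
the Mann–Whitney test of per-sample counts. The events-versus-slots
chi-square construction compares a Poisson-distributed count against a
fixed denominator, which inflates the implied variance by roughly (1 +
lambda) relative to binomial sampling and is therefore intrinsically
conservative under the null; calibrating it to 0.05 would contradict its
own definition. Its correctness is instead verified against the closed-form
sum((O - E)^2 / E) oracle.

## The synthetic cohort generator

The generator defines the study conditions; its defaults are fixed once:

* **Size spectrum**: a mixture of two lognormal components centred at
  300 bp (sd 0.15 on the log scale) and 6 kbp (sd 0.12) — the Alu and LINE
  retrotransposition modes of the human SV spectrum — plus a 25% log-uniform
  tail on 50 bp–20 kbp, truncated at the 50 bp SV definition. Histograms of
  10,000 draws show local maxima in the 250–350 bp and 5–7 kbp bins.
* **Allele frequencies** per locus are independent Beta draws per ancestry
  stratum: Beta(0.35, 2.5) for AFR, Beta(0.2, 4.0) for non-AFR. The higher
  AFR mean reflects greater African genomic diversity and makes AFR
  discovery curves dominate non-AFR ones, as seen in real panels.
* **Founders** (parents and controls) draw Hardy–Weinberg genotypes at
  their stratum frequency; males are hemizygous on non-PAR chrX and chrY.
  Children receive one allele per parent; sons receive the maternal X and
  the paternal Y. PAR boundaries ship as a package default on the
  synthetic genome and are configurable.
* **De novo events** are fresh loci (never in the pool) placed at least
  1 kbp from every existing locus so that truth recovery is unambiguous;
  counts are Poisson per child. The default rate of 0.4 per child matches
  the order of magnitude implied by published family LRS studies (a few
  dozen validated de novo SVs per ~90 children); it is a free parameter,
  not a measured constant.
* **Genotyping errors** flip between adjacent zygosity states only
  (hom <-> het, het <-> absent, hemi <-> absent), mimicking real caller
  error modes; every flip is recorded in the truth set.
* **TR allele lengths** vary by whole motif copies within a bounded ±2-unit
  range, as for stable TRs; under this bounded support a z >= 3 outlier
  cannot arise by chance, so planted expansions (+300 bp, inherited from a
  carrier mother) are recovered exactly.
* **Methylation**: `skew` is the fraction of cells with the maternal X
  inactive. Each CpG's methylated count is Binomial(coverage, p) with
  p = skew * 0.85 + (1 - skew) * 0.15 on the maternal haplotype and the
  mirror on the paternal one, giving the closed-form expected skew index
  (2 * skew - 1) * 0.70; recovery over 889 islands at coverage 20 is
  accurate to within 0.02.
* **Alignment gaps** for contiguity scoring remove a chosen fraction of
  1 Mbp windows and emit one contig per intact run, so the qualified-window
  fraction has a constructed truth.

What the generator does **not** emulate: real repeat sequence content
(sequences are uniform random DNA, so edit-similarity behaviour in VNTRs is
idealized), read-level artifacts, assembly errors, breakpoint imprecision
correlated with repeat context, and linkage between loci. Passing tests
demonstrate the pipeline's logic is correct under its stated model, not
that caller-specific artifacts of real data are handled.

## Numerical and degenerate-input conventions

Internal coordinates are 0-based half-open; VCF emission is 1-based with
`END = POS` for insertions and `POS + svlen` for deletions, SVLEN negative
for deletions. Rounding of reported percentages is half-up (97% from
20,716 vs 663; 99% from 20,716 vs 202; 45% from 6171/13,773). Zero-variance
TR loci yield no outlier calls; empty blacklists and empty callsets are
identities; a fully masked chromosome yields an undefined (NA) coverage
fraction; folding caps MAF at 0.5 with hemizygous samples contributing one
allele. Ties in representative selection break leftmost, then by
identifier, making collapse deterministic.

## Problem sizes used by the test and acceptance runs

The packaged checks run on deliberately compact instances chosen to keep
the full suite interactive while leaving the statistics well-powered: de
novo recovery on a 20,000-locus pool with 5 quads and 100 controls;
filtering monotonicity on nested 20/100/400-control panels over a
5,000-locus pool across three seeds; oracle equivalence on 100-record
callsets over 50 trials; 500-replicate null calibration; XCI skew recovery
over the full 889 islands at coverage 20; contiguity scoring over 100
windows. The analysis drivers under `analysis/` use a 5-family, 60-control,
8,000-locus cohort.

## Known limitations

BND/translocation records, copy-number genotypes and multi-allelic TR
genotyping are out of scope; the collapse criterion is the package's own
transparent definition rather than a re-implementation of any specific
tool's internals; the curation cascade replaces a trained quality model
with rules and therefore has no learned notion of callable-region quality;
and all empirical results shipped with the package are computed on
synthetic cohorts whose generating model is described above.
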