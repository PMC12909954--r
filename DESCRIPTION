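Package: svsieve
Title: Rare Structural-Variant Discovery in Family Cohorts with Pangenome Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for rare structural-variant (SV) discovery in
    family cohorts sequenced with long reads: multi-caller validation of
    assembly-based callsets, cohort-wide SV collapsing into a nonredundant
    genotype table, filtering against pangenome control panels (sex-matched on
    the sex chromosomes), Mendelian-transmission classification and a rule-based
    curation cascade for discordant calls, zygosity and variant-origin
    categories, interval-based regulatory annotation and candidate
    prioritization, proband-versus-sibling burden statistics, control-panel
    scaling analyses (discovery curves, MAF capture), sex-chromosome
    assembly-contiguity scoring from alignment intervals, and X-inactivation
    skew from haplotype-resolved CpG-island methylation. A synthetic cohort
    generator with recorded ground truth stands in for access-controlled study
    data so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    withr,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
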