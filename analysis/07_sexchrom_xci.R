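#!/usr/bin/env Rscript
# Sex-chromosome assembly contiguity (1 Mbp window qualification from PAF
# alignment intervals) and X-inactivation skew from haplotype-resolved
# CpG-island methylation for the female children.

source(file.path("analysis", "00_common.R"))

cohort <- study_cohort()
ped <- cohort$ped
children <- ped$sample[ped$role %in% c("proband", "sibling")]

# per-child chrX contiguity with child-specific assembly gaps
rows <- lapply(seq_along(children), function(i) {
  pf <- simulate_paf(100e6, chrom = "chrX", window = 1e6,
                     gap_frac = runif(1, 0.02, 0.15), seed = SEED + i)
  wq <- window_qualification(pf$paf, "chrX", 100e6)
  data.frame(sample = children[i], qualified = sum(wq$windows$qualified),
             windows = nrow(wq$windows), fraction = wq$fraction)
})
contig <- withr::with_seed(SEED, do.call(rbind, rows))
cat(sprintf("mean chrX window coverage: %.2f\n", mean(contig$fraction)))
data.table::fwrite(contig, file.path(results_dir, "chrX_contiguity.tsv"),
                   sep = "\t")

# XCI skew: one balanced, one moderately and one extremely skewed female
females <- children[ped$sex[match(children, ped$sample)] == "F"]
skews <- setNames(rep(c(0.5, 0.8, 0.95), length.out = length(females)), females)
sk_rows <- lapply(names(skews), function(s) {
  m <- simulate_methylation(n_islands = 889, coverage = 20, skew = skews[[s]],
                            seed = SEED + match(s, names(skews)))
  xci_skew(m$mat, m$pat, m$islands, sample = s)$skew
})
sk <- do.call(rbind, sk_rows)
sk$true_skew <- unname(skews)
print(sk[, c("sample", "true_skew", "hap_mean_mat", "hap_mean_pat",
             "skew_index", "classification")], digits = 3)
data.table::fwrite(sk, file.path(results_dir, "xci_skew.tsv"), sep = "\t")
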