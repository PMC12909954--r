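#!/usr/bin/env Rscript
# Generates the synthetic study cohort: a population SV pool with the
# bimodal (Alu/LINE) size spectrum and ancestry-stratified allele
# frequencies, family + control genotypes with injected de novo events and
# genotyping errors, and the full fixture set (VCFs, caller replicates,
# annotation tracks, evidence tables, methylation). Everything downstream
# reads these files or regenerates them from the same seed.

source(file.path("analysis", "00_common.R"))

cohort <- study_cohort()
sim <- cohort$sim

out <- file.path(results_dir, "sim")
write_cohort(sim, out, dropout = c(pbsv = 0.3, sniffles = 0.3), seed = SEED)
simulate_tracks_and_evidence(sim, file.path(out, "evidence"),
                             gap_frac = 0.3, seed = SEED)

data.table::fwrite(cohort$ped, file.path(out, "pedigree.tsv"), sep = "\t")
data.table::fwrite(sim$truth$denovo, file.path(out, "truth_denovo.tsv"), sep = "\t")
data.table::fwrite(sim$truth$errors, file.path(out, "truth_errors.tsv"), sep = "\t")

cat(sprintf("cohort: %d samples (%d children), %d pool loci, %d de novo events, %d genotype errors\n",
            nrow(cohort$ped),
            sum(cohort$ped$role %in% c("proband", "sibling")),
            nrow(sim$pool), nrow(sim$truth$denovo), nrow(sim$truth$errors)))
len <- sim$pool$svlen[sim$pool$svtype == "INS"]
cat(sprintf("INS size spectrum: median %d bp; %.0f%% in 200-400 bp, %.0f%% in 5-7 kbp\n",
            median(len), 100 * mean(len >= 200 & len <= 400),
            100 * mean(len >= 5000 & len <= 7000)))
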