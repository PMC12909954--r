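#!/usr/bin/env Rscript
# Control-panel scaling: cumulative discovery curves per ancestry stratum,
# per-child rare-SV counts under nested control panels, the filtering
# efficiency each panel achieves, and the fraction of the full panel's SVs
# captured by a smaller panel per MAF bin.

source(file.path("analysis", "00_common.R"))

cohort <- study_cohort()
ped <- cohort$ped
tab <- cohort_table_from_sim(cohort$sim)
controls <- ped$sample[ped$role == "control"]
children <- ped$sample[ped$role %in% c("proband", "sibling")]

strata <- setNames(ped$population[match(controls, ped$sample)], controls)
dc <- discovery_curve(tab, strata, n_perm = 10, seed = SEED)
data.table::fwrite(dc, file.path(results_dir, "discovery_curves.tsv"), sep = "\t")
for (str in unique(dc$stratum)) {
  last <- dc[dc$stratum == str, ]
  last <- last[which.max(last$n_samples), ]
  cat(sprintf("%s: %d samples discover %.0f nonredundant SVs (band %d-%d)\n",
              str, last$n_samples, last$mean, last$min, last$max))
}

# nested panels: per-child rare counts and filtering efficiency
validated_per_child <- mean(colSums(
  matrix(tab$gt[, children] %in% c("het", "hom", "hemi"), nrow(tab$svs))))
for (k in c(15, 30, 60)) {
  ped_k <- ped[ped$role != "control" | ped$sample %in% controls[seq_len(k)], ]
  rare_k <- pangenome_filter(tab, ped_k)
  per_child <- nrow(rare_k) / length(children)
  eff <- filtering_efficiency_report(validated_per_child, per_child)
  cat(sprintf("%3d controls: %.1f rare SVs per child, %d%% filtered\n",
              k, per_child, eff$percent_excluded))
}

# MAF capture: the 15-control panel against the full 60-control panel
sexes <- setNames(ped$sex, ped$sample)
maf <- compute_maf(tab, sexes)
carried_small <- rowSums(matrix(
  tab$gt[, controls[1:15]] %in% c("het", "hom", "hemi"), nrow(tab$svs))) > 0
mc <- maf_capture(tab$svs[carried_small, ], tab$svs, maf,
                  breaks = c(0, 0.01, 0.05, 0.1, 0.5))
print(mc)
data.table::fwrite(mc, file.path(results_dir, "maf_capture.tsv"), sep = "\t")
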