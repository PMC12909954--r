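#!/usr/bin/env Rscript
# Proband-versus-sibling burden comparison: per-sample count matrix over
# burden categories, chi-square tests on events vs sample slots (with
# Bonferroni adjustment) and the Mann-Whitney comparison of per-sample
# counts.

source(file.path("analysis", "00_common.R"))

st <- study_rare_table()
rare <- st$rare
tracks <- simulate_tracks(st$sim$pool, seed = SEED)
flags <- intersect_tracks(rare, list(reg = tracks$reg, brainreg = tracks$brainreg))
rare <- cbind(rare, flags[, -1])
rare$functional_class <- functional_category(rare, tracks)
# transmission is resolvable when exactly one parent carries the allele
fa_c <- rare$father_gt %in% c("het", "hom", "hemi")
mo_c <- rare$mother_gt %in% c("het", "hom", "hemi")
rare$transmission <- ifelse(fa_c & !mo_c, "paternal",
                     ifelse(mo_c & !fa_c, "maternal", NA))

ped <- st$ped
probands <- ped$sample[ped$role == "proband"]
siblings <- ped$sample[ped$role == "sibling"]
cm <- per_sample_counts(rare, c(probands, siblings))

rows <- lapply(colnames(cm), function(cat) {
  ep <- sum(cm[probands, cat]); es <- sum(cm[siblings, cat])
  x2 <- chi2_burden(ep, length(probands), es, length(siblings))
  mw <- mwu_burden(cm[probands, cat], cm[siblings, cat])
  data.frame(category = cat, n_proband = length(probands),
             n_sibling = length(siblings), events_proband = ep,
             events_sibling = es, chi2 = x2$chi2, odds_ratio = x2$or,
             p_nominal = x2$p, z_mwu = mw$z, p_mwu = mw$p)
})
burden <- do.call(rbind, rows)
burden$p_adjusted <- adjust_pvalues(burden$p_nominal)

print(burden[, c("category", "events_proband", "events_sibling",
                 "odds_ratio", "p_nominal", "p_adjusted", "z_mwu", "p_mwu")],
      digits = 3)
sig <- burden$category[!is.na(burden$p_adjusted) & burden$p_adjusted < 0.05]
cat(if (length(sig)) sprintf("categories below 0.05 after adjustment: %s\n",
                             paste(sig, collapse = ", "))
    else "no burden category is significant after adjustment\n")

data.table::fwrite(burden, file.path(results_dir, "burden_tests.tsv"), sep = "\t")
data.table::fwrite(data.frame(sample = rownames(cm), cm),
                   file.path(results_dir, "per_sample_counts.tsv"), sep = "\t")
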