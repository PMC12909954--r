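#!/usr/bin/env Rscript
# Collapses per-sample calls into the nonredundant cohort table, filters it
# against the control panel (sex-matched on chrX/chrY), classifies zygosity
# categories, Mendelian confidence and variant origin, and writes the rare
# SV table.

source(file.path("analysis", "00_common.R"))

st <- study_rare_table()
rare <- st$rare

cat(sprintf("cohort table: %d nonredundant SVs x %d samples\n",
            nrow(st$tab$svs), ncol(st$tab$gt)))
flog <- attr(pangenome_filter(st$tab, st$ped), "log")
cat(sprintf("control filtering removed %d autosomal and %d sex-chromosome carrier pairs\n",
            flog$n_pairs_removed_auto, flog$n_pairs_removed_sex))
children <- st$ped$sample[st$ped$role %in% c("proband", "sibling")]
cat(sprintf("rare SVs: %d (SV x child) pairs, %.1f per child\n",
            nrow(rare), nrow(rare) / length(children)))
cat(sprintf("Mendelian concordance: %.3f\n", attr(rare, "concordance")))
cat("zygosity categories (per occurrence):\n")
print(attr(classify_zygosity_categories(rare), "counts")$per_occurrence)
cat("origins:\n")
print(table(rare$origin))

data.table::fwrite(rare, file.path(results_dir, "rare_svs.tsv"), sep = "\t")
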