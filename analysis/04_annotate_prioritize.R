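#!/usr/bin/env Rscript
# Annotates rare SVs with regulatory/constraint tracks and the gene model,
# measures the regulatory-annotation gain from the brain-derived tracks,
# and ranks candidate pathogenic SVs under the three rule groups.

source(file.path("analysis", "00_common.R"))

st <- study_rare_table()
rare <- st$rare
tracks <- simulate_tracks(st$sim$pool, seed = SEED)

flags <- intersect_tracks(rare, list(reg = tracks$reg,
                                     brainreg = tracks$brainreg,
                                     tf = tracks$tf,
                                     promoters = tracks$promoters,
                                     tr = tracks$tr_catalog,
                                     gnocchi = tracks$gnocchi))
rare <- cbind(rare, flags[, -1])
names(rare)[names(rare) == "gnocchi_max"] <- "gnocchi_max"
rare$functional_class <- functional_category(rare, tracks)

cat("functional classes:\n"); print(table(rare$functional_class))
g <- annotation_gain(rare, "reg", "brainreg")
cat(sprintf("brain-regulatory annotation gain: %d SVs beyond %d (= %d%%)\n",
            g$n_added_only, g$n_base, g$percent_increase))

cand <- prioritize(rare, tracks)
cat(sprintf("candidates: %d (rules: %s)\n", nrow(cand),
            paste(sort(unique(cand$rules)), collapse = "; ")))
cols <- c("family", "child", "sex", "sv_id", "chrom", "start", "svtype",
          "svlen", "origin", "functional_class", "rules", "genes")
data.table::fwrite(cand[, cols], file.path(results_dir, "candidates.tsv"),
                   sep = "\t")
data.table::fwrite(rare, file.path(results_dir, "rare_svs_annotated.tsv"),
                   sep = "\t")
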