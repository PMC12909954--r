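# Shared study configuration for the analysis drivers. Every driver sources
# this file and regenerates the cohort deterministically, so each script can
# be run on its own.

suppressMessages(library(svsieve))

SEED <- 2026
N_QUADS <- 3
N_TRIOS <- 2
N_CONTROLS <- 60
N_LOCI <- 8000
DENOVO_RATE <- 0.4
ERROR_RATE <- 0.01

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE)

study_cohort <- function() {
  ped <- simulate_pedigree(n_quads = N_QUADS, n_trios = N_TRIOS,
                           n_controls = N_CONTROLS, seed = SEED)
  pool <- simulate_sv_pool(N_LOCI, seed = SEED)
  sim <- simulate_cohort(pool, ped, denovo_rate = DENOVO_RATE,
                         error_rate = ERROR_RATE, seed = SEED)
  list(ped = ped, sim = sim)
}

study_rare_table <- function(cohort = study_cohort()) {
  tab <- cohort_table_from_sim(cohort$sim)
  rare <- classify_variant_origin(
    add_mendelian_confidence(
      classify_zygosity_categories(pangenome_filter(tab, cohort$ped))),
    tab, cohort$ped)
  list(ped = cohort$ped, sim = cohort$sim, tab = tab, rare = rare)
}
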