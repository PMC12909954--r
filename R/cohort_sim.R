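#' Default chromosome lengths of the simulated genome
#'
#' A compact genome (three autosomes plus chrX and chrY) keeps simulated
#' cohorts fast while exercising every chromosome class the pipeline
#' distinguishes.
#'
#' @return named numeric vector of lengths in bp.
#' @export
sim_chrom_lengths <- function() {
  c(chr1 = 10e6, chr2 = 8e6, chr3 = 6e6, chrX = 5e6, chrY = 2.5e6)
}

#' Default pseudoautosomal intervals of the simulated genome
#'
#' PAR loci behave diploid in males; the real PAR1/PAR2 boundaries are
#' reference-specific, so these are configurable.
#'
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
sim_par_regions <- function() {
  data.frame(chrom = c("chrX", "chrX", "chrY", "chrY"),
             start = c(0, 4.85e6, 0, 2.35e6),
             end   = c(150e3, 5e6, 150e3, 2.5e6))
}

#' Default SV size mixture
#'
#' Two lognormal components centred near 300 bp and 6 kbp (the Alu and LINE
#' retrotransposition modes of the human SV size spectrum) plus a log-uniform
#' tail; all draws are truncated at the 50 bp SV definition.
#'
#' @return list with `weights`, `meanlog`, `sdlog`, `tail_range`.
#' @export
sim_size_mix <- function() {
  list(weights = c(alu = 0.50, line = 0.25, tail = 0.25),
       meanlog = c(alu = log(300), line = log(6000)),
       sdlog = c(alu = 0.15, line = 0.12),
       tail_range = c(50, 20000))
}

#' Default per-stratum allele-frequency model
#'
#' Beta distributions per ancestry stratum; the AFR stratum is more diverse
#' (higher mean frequency), which reproduces the dominance of African
#' discovery curves over non-African ones.
#'
#' @return list of `c(shape1, shape2)` per stratum.
#' @export
sim_af_model <- function() {
  list(AFR = c(shape1 = 0.35, shape2 = 2.5),
       nonAFR = c(shape1 = 0.20, shape2 = 4.0))
}

.draw_sizes <- function(n, mix) {
  if (n == 0) return(integer(0))
  comp <- sample(names(mix$weights), n, replace = TRUE, prob = mix$weights)
  len <- numeric(n)
  for (cc in c("alu", "line")) {
    k <- comp == cc
    len[k] <- rlnorm(sum(k), mix$meanlog[cc], mix$sdlog[cc])
  }
  k <- comp == "tail"
  len[k] <- exp(runif(sum(k), log(mix$tail_range[1]), log(mix$tail_range[2])))
  pmax(50L, as.integer(round(len)))
}

#' Simulate a population SV pool
#'
#' Draws SV loci with positions uniform over the genome, sizes from the
#' bimodal mixture, types INS/DEL/INV, sequences for INS/DEL, and independent
#' per-stratum allele frequencies. Loci are returned sorted by (chrom, pos)
#' and the draw is deterministic under `seed`.
#'
#' @param n_loci number of loci (>= 0).
#' @param size_mix size mixture spec, see [sim_size_mix()].
#' @param af_model per-stratum Beta parameters, see [sim_af_model()].
#' @param chrom_lengths named vector of chromosome lengths.
#' @param type_probs sampling probabilities for INS/DEL/INV.
#' @param seed integer seed.
#' @return data.frame: `locus_id`, `chrom`, `pos` (0-based), `svtype`,
#'   `svlen`, `seq`, `af_afr`, `af_nonafr`.
#' @export
simulate_sv_pool <- function(n_loci, size_mix = sim_size_mix(),
                             af_model = sim_af_model(),
                             chrom_lengths = sim_chrom_lengths(),
                             type_probs = c(INS = 0.5, DEL = 0.45, INV = 0.05),
                             seed = 1) {
  if (n_loci < 0) stop("n_loci must be >= 0")
  if (!length(chrom_lengths) || any(chrom_lengths <= 0))
    stop("chromosome map must be nonempty with positive lengths")
  withr::with_seed(seed, {
    if (n_loci == 0) {
      return(data.frame(locus_id = character(0), chrom = character(0),
                        pos = integer(0), svtype = character(0),
                        svlen = integer(0), seq = character(0),
                        af_afr = numeric(0), af_nonafr = numeric(0)))
    }
    chrom <- sample(names(chrom_lengths), n_loci, replace = TRUE,
                    prob = chrom_lengths / sum(chrom_lengths))
    pos <- as.integer(floor(runif(n_loci) * (chrom_lengths[chrom] - 1e4)))
    svtype <- sample(names(type_probs), n_loci, replace = TRUE, prob = type_probs)
    svlen <- .draw_sizes(n_loci, size_mix)
    seqs <- rep(NA_character_, n_loci)
    withseq <- svtype != "INV"
    # sequence length capped for memory; similarity comparisons only need
    # enough bases to discriminate alleles
    seqs[withseq] <- random_dna(pmin(svlen[withseq], 2000L))
    af_afr <- rbeta(n_loci, af_model$AFR["shape1"], af_model$AFR["shape2"])
    af_nonafr <- rbeta(n_loci, af_model$nonAFR["shape1"], af_model$nonAFR["shape2"])
    o <- order(chrom, pos)
    data.frame(locus_id = sprintf("sv%06d", seq_len(n_loci)),
               chrom = chrom[o], pos = pos[o], svtype = svtype[o],
               svlen = svlen[o], seq = seqs[o],
               af_afr = af_afr[o], af_nonafr = af_nonafr[o],
               row.names = NULL)
  })
}

#' Simulate a pedigree specification
#'
#' Families are trios or quads (exactly one father, one mother); unrelated
#' controls carry no family id. Proband sex defaults to mostly female,
#' mirroring family-cohort designs enriched for affected daughters.
#'
#' @param n_quads,n_trios family counts.
#' @param n_controls unrelated control count.
#' @param p_afr probability a family/control is of AFR ancestry.
#' @param p_proband_female probability the proband is female.
#' @param seed integer seed.
#' @return data.frame: `sample`, `family` (NA for controls), `role`
#'   (father/mother/proband/sibling/control), `sex`, `population`.
#' @export
simulate_pedigree <- function(n_quads = 3, n_trios = 2, n_controls = 20,
                              p_afr = 0.25, p_proband_female = 0.8, seed = 1) {
  withr::with_seed(seed, {
    fams <- vector("list", 0)
    for (f in seq_len(n_quads + n_trios)) {
      fid <- sprintf("fam%03d", f)
      pop <- if (runif(1) < p_afr) "AFR" else "nonAFR"
      mem <- data.frame(
        sample = paste0(fid, c("_fa", "_mo", "_p1")),
        family = fid, role = c("father", "mother", "proband"),
        sex = c("M", "F", if (runif(1) < p_proband_female) "F" else "M"),
        population = pop)
      if (f <= n_quads) {
        mem <- rbind(mem, data.frame(sample = paste0(fid, "_s1"), family = fid,
                                     role = "sibling",
                                     sex = sample(c("F", "M"), 1),
                                     population = pop))
      }
      fams[[f]] <- mem
    }
    ctrl <- if (n_controls > 0) data.frame(
      sample = sprintf("ctrl%04d", seq_len(n_controls)),
      family = NA_character_, role = "control",
      sex = sample(c("F", "M"), n_controls, replace = TRUE),
      population = ifelse(runif(n_controls) < p_afr, "AFR", "nonAFR"))
    else NULL
    out <- rbind(do.call(rbind, fams), ctrl)
    rownames(out) <- NULL
    out
  })
}

# Draw one transmitted allele (0/1) from a parent genotype code.
.transmit <- function(gt) {
  n <- length(gt)
  u <- runif(n)
  out <- integer(n)
  out[gt == "hom" | gt == "hemi"] <- 1L
  out[gt == "het"] <- as.integer(u[gt == "het"] < 0.5)
  out[gt == "hemi"] <- 1L
  out
}

.gt_from_alleles <- function(a1, a2) c("absent", "het", "hom")[a1 + a2 + 1L]

#' Simulate cohort genotypes with recorded ground truth
#'
#' Founders (parents and controls) receive Hardy-Weinberg genotypes at each
#' pool locus using their stratum's allele frequency; males are hemizygous on
#' non-PAR chrX and on chrY. Children inherit one allele from each parent
#' (sons: maternal X only, paternal Y). De novo events are fresh loci added
#' per child at `Poisson(denovo_rate)`, placed at least 1 kbp from existing
#' loci. Genotyping errors flip emitted genotypes between adjacent zygosity
#' states at rate `error_rate`; every flip is recorded.
#'
#' @param pool SV pool from [simulate_sv_pool()].
#' @param ped pedigree from [simulate_pedigree()].
#' @param denovo_rate expected de novo events per child (>= 0).
#' @param error_rate per-genotype flip probability in \[0,1\].
#' @param par PAR intervals (data.frame) or NULL.
#' @param chrom_lengths named vector (for de novo placement).
#' @param seed integer seed.
#' @return list: `gt` (emitted genotype matrix loci x samples), `true_gt`,
#'   `pool` (input pool plus de novo loci, `is_denovo` flag), `truth` (list
#'   with `denovo`, `errors`, `transmission` data.frames), `ped`.
#' @export
simulate_cohort <- function(pool, ped, denovo_rate = 0.4, error_rate = 0,
                            par = sim_par_regions(),
                            chrom_lengths = sim_chrom_lengths(), seed = 1) {
  if (denovo_rate < 0) stop("denovo_rate must be >= 0")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0,1]")
  if (nrow(ped) > 0 && nrow(pool) == 0) stop("pool must be nonempty")
  withr::with_seed(seed, {
    samples <- ped$sample
    nl <- nrow(pool)
    af <- cbind(AFR = pool$af_afr, nonAFR = pool$af_nonafr)
    gt <- matrix("absent", nl, length(samples), dimnames = list(pool$locus_id, samples))

    ploidy_of <- function(sex) locus_ploidy_class(pool$chrom, pool$pos, sex, par)
    founders <- ped$role %in% c("father", "mother", "control")
    for (s in which(founders)) {
      a <- af[, ped$population[s]]
      pc <- ploidy_of(ped$sex[s])
      g <- rep("absent", nl)
      dip <- pc == "diploid"
      g[dip] <- .gt_from_alleles(rbinom(sum(dip), 1, a[dip]),
                                 rbinom(sum(dip), 1, a[dip]))
      hap <- pc == "haploid"
      g[hap] <- ifelse(rbinom(sum(hap), 1, a[hap]) == 1L, "hemi", "absent")
      gt[, s] <- g
    }

    transmission <- vector("list", 0)
    children <- which(ped$role %in% c("proband", "sibling"))
    for (s in children) {
      fa <- ped$sample[ped$family == ped$family[s] & ped$role == "father"]
      mo <- ped$sample[ped$family == ped$family[s] & ped$role == "mother"]
      pc <- ploidy_of(ped$sex[s])
      a_fa <- .transmit(gt[, fa])
      a_mo <- .transmit(gt[, mo])
      g <- rep("absent", nl)
      dip <- pc == "diploid"
      g[dip] <- .gt_from_alleles(a_fa[dip], a_mo[dip])
      hap <- pc == "haploid"
      onX <- hap & pool$chrom == "chrX"
      onY <- hap & pool$chrom == "chrY"
      g[onX] <- ifelse(a_mo[onX] == 1L, "hemi", "absent")  # sons: maternal X
      g[onY] <- ifelse(a_fa[onY] == 1L, "hemi", "absent")  # sons: paternal Y
      none <- pc == "none"
      g[none] <- "absent"
      gt[, s] <- g
      het <- which(g == "het")
      if (length(het)) {
        transmission[[length(transmission) + 1L]] <- data.frame(
          child = ped$sample[s], locus_id = pool$locus_id[het],
          origin = ifelse(a_fa[het] == 1L & a_mo[het] == 0L, "paternal",
                   ifelse(a_mo[het] == 1L & a_fa[het] == 0L, "maternal", "either")))
      }
    }

    # de novo events: fresh loci >= 1 kbp away from every existing locus
    dn_records <- vector("list", 0)
    dn_pool <- vector("list", 0)
    n_dn_total <- 0L
    mix <- sim_size_mix()
    auto_chroms <- names(chrom_lengths)[names(chrom_lengths) != "chrY"]
    for (s in children) {
      k <- rpois(1, denovo_rate)
      if (k == 0) next
      for (e in seq_len(k)) {
        n_dn_total <- n_dn_total + 1L
        repeat {
          ch <- sample(auto_chroms, 1,
                       prob = chrom_lengths[auto_chroms] / sum(chrom_lengths[auto_chroms]))
          p0 <- as.integer(floor(runif(1) * (chrom_lengths[ch] - 1e4)))
          near <- pool$chrom == ch & abs(pool$pos - p0) < 1000
          prev <- if (length(dn_pool))
            vapply(dn_pool, function(d) d$chrom == ch && abs(d$pos - p0) < 1000, logical(1))
            else logical(0)
          if (!any(near) && !any(prev)) break
        }
        ty <- sample(c("INS", "DEL"), 1)
        ln <- .draw_sizes(1, mix)
        id <- sprintf("dn%05d", n_dn_total)
        dn_pool[[length(dn_pool) + 1L]] <- data.frame(
          locus_id = id, chrom = ch, pos = p0, svtype = ty, svlen = ln,
          seq = random_dna(min(ln, 2000L)), af_afr = 0, af_nonafr = 0)
        gcode <- if (ch == "chrX" && ped$sex[s] == "M" &&
                     !in_par(ch, p0, par)) "hemi" else "het"
        dn_records[[length(dn_records) + 1L]] <- data.frame(
          sample = ped$sample[s], locus_id = id, gt = gcode)
      }
    }
    pool_out <- pool
    pool_out$is_denovo <- FALSE
    if (length(dn_pool)) {
      dn_df <- do.call(rbind, dn_pool)
      dn_df$is_denovo <- TRUE
      pool_out <- rbind(pool_out, dn_df)
      o <- order(pool_out$chrom, pool_out$pos)
      pool_out <- pool_out[o, , drop = FALSE]
      rownames(pool_out) <- NULL
      gt2 <- matrix("absent", nrow(pool_out), length(samples),
                    dimnames = list(pool_out$locus_id, samples))
      gt2[rownames(gt), ] <- gt
      dn_rec <- do.call(rbind, dn_records)
      gt2[cbind(match(dn_rec$locus_id, rownames(gt2)),
                match(dn_rec$sample, samples))] <- dn_rec$gt
      gt <- gt2
    }
    true_gt <- gt

    errors <- data.frame(sample = character(0), locus_id = character(0),
                         true_gt = character(0), emitted_gt = character(0))
    if (error_rate > 0) {
      flip <- which(matrix(runif(length(gt)) < error_rate, nrow(gt)))
      if (length(flip)) {
        old <- gt[flip]
        u <- runif(length(flip))
        new <- ifelse(old == "hom", "het",
               ifelse(old == "het", ifelse(u < 0.5, "absent", "hom"),
               ifelse(old == "absent", "het",
               ifelse(old == "hemi", "absent", old))))
        # absent on haploid loci flips to hemi, not het
        ridx <- (flip - 1L) %% nrow(gt) + 1L
        cidx <- (flip - 1L) %/% nrow(gt) + 1L
        pc <- locus_ploidy_class(pool_out$chrom[ridx], pool_out$pos[ridx],
                                 ped$sex[cidx], par)
        new[old == "absent" & pc == "haploid"] <- "hemi"
        keepflip <- new != old & pc != "none"
        flip <- flip[keepflip]; old <- old[keepflip]; new <- new[keepflip]
        ridx <- ridx[keepflip]; cidx <- cidx[keepflip]
        gt[flip] <- new
        errors <- data.frame(sample = samples[cidx],
                             locus_id = pool_out$locus_id[ridx],
                             true_gt = old, emitted_gt = new)
      }
    }
    denovo <- if (length(dn_records))
      do.call(rbind, dn_records)[, c("sample", "locus_id")]
    else data.frame(sample = character(0), locus_id = character(0))
    transmission <- if (length(transmission)) do.call(rbind, transmission)
      else data.frame(child = character(0), locus_id = character(0), origin = character(0))
    list(gt = gt, true_gt = true_gt, pool = pool_out,
         truth = list(denovo = denovo, errors = errors, transmission = transmission),
         ped = ped)
  })
}

# SV table view of a set of pool loci; qual drawn deterministically from id
# hash so representative selection is stable.
pool_to_sv_table <- function(pool) {
  sv_table(sv_id = pool$locus_id, chrom = pool$chrom, start = pool$pos,
           svtype = pool$svtype, svlen = pool$svlen, seq = pool$seq,
           qual = 30)
}

#' Build a cohort table directly from a simulation
#'
#' Converts the emitted genotype matrix into the long per-sample call format
#' and runs [collapse_cohort()], yielding the nonredundant table the
#' downstream filters operate on.
#'
#' @param sim result of [simulate_cohort()].
#' @param p matching parameters.
#' @param keep representative policy.
#' @return a `cohort_sv_table` over all pedigree samples.
#' @export
cohort_table_from_sim <- function(sim, p = match_params(), keep = "common") {
  carrier <- which(matrix(sim$gt %in% c("het", "hom", "hemi"),
                          nrow(sim$gt)), arr.ind = TRUE)
  pool <- sim$pool
  calls <- data.frame(
    sv_id = pool$locus_id[carrier[, 1]],
    chrom = pool$chrom[carrier[, 1]],
    start = pool$pos[carrier[, 1]],
    end = ifelse(pool$svtype[carrier[, 1]] == "INS", pool$pos[carrier[, 1]],
                 pool$pos[carrier[, 1]] + pool$svlen[carrier[, 1]]),
    svtype = pool$svtype[carrier[, 1]],
    svlen = pool$svlen[carrier[, 1]],
    seq = pool$seq[carrier[, 1]],
    qual = 30,
    caller = "assembly",
    sample = colnames(sim$gt)[carrier[, 2]],
    gt = sim$gt[carrier])
  collapse_cohort(calls, p = p, keep = keep, samples = colnames(sim$gt))
}

#' Write a simulated cohort as VCF files
#'
#' Emits one multi-sample VCF per family, one for the control batch, and
#' per-sample "caller replicate" VCFs: the primary assembly callset plus
#' supporting callsets downsampled at the given per-caller dropout
#' probabilities, exercising callerset validation.
#'
#' @param sim result of [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @param dropout named numeric vector: per supporting caller probability of
#'   dropping each true call.
#' @param callset_samples samples for which per-caller replicate VCFs are
#'   written (default: all children); `character(0)` disables them.
#' @param seed integer seed for the dropout resampling.
#' @return invisible list of written paths.
#' @export
write_cohort <- function(sim, out_dir, dropout = c(pbsv = 0.3, sniffles = 0.3),
                         callset_samples = NULL, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  ped <- sim$ped
  pool <- sim$pool
  svs <- pool_to_sv_table(pool)
  paths <- list()
  emit <- function(samples, path) {
    g <- sim$gt[, samples, drop = FALSE]
    keep <- rowSums(g != "absent") > 0
    write_sv_vcf(svs[keep, , drop = FALSE], path, gt = g[keep, , drop = FALSE])
    path
  }
  for (f in unique(stats::na.omit(ped$family))) {
    paths[[paste0("family_", f)]] <-
      emit(ped$sample[!is.na(ped$family) & ped$family == f],
           file.path(out_dir, paste0("family_", f, ".vcf")))
  }
  ctrl <- ped$sample[ped$role == "control"]
  if (length(ctrl))
    paths$controls <- emit(ctrl, file.path(out_dir, "controls.vcf"))
  if (is.null(callset_samples))
    callset_samples <- ped$sample[ped$role %in% c("proband", "sibling")]
  if (length(callset_samples)) {
    cs_dir <- file.path(out_dir, "callsets")
    dir.create(cs_dir, showWarnings = FALSE)
    withr::with_seed(seed, {
      for (s in callset_samples) {
        carried <- which(sim$gt[, s] != "absent")
        tab <- svs[carried, , drop = FALSE]
        g <- matrix(sim$gt[carried, s], ncol = 1, dimnames = list(NULL, s))
        p0 <- file.path(cs_dir, paste0(s, "_assembly.vcf"))
        write_sv_vcf(tab, p0, gt = g)
        paths[[paste0(s, "_assembly")]] <- p0
        for (cl in names(dropout)) {
          keep <- runif(nrow(tab)) >= dropout[[cl]]
          pc <- file.path(cs_dir, paste0(s, "_", cl, ".vcf"))
          write_sv_vcf(tab[keep, , drop = FALSE], pc,
                       gt = g[keep, , drop = FALSE])
          paths[[paste0(s, "_", cl)]] <- pc
        }
      }
    })
  }
  invisible(paths)
}
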