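#' Filter a cohort table against control genotypes
#'
#' Retains rows carried by at least one child and by zero controls. On chrX
#' and chrY the control comparison is sex-matched: a carrier child's
#' genotype is compared only against controls of the same sex. The result is
#' a long table with one row per retained (SV, carrier child) pair, joined
#' with the child's parental genotypes.
#'
#' @param table a `cohort_sv_table` whose columns include the children and
#'   controls.
#' @param ped pedigree data.frame (`sample`, `family`, `role`, `sex`,
#'   `population`); children are roles proband/sibling, controls role
#'   control.
#' @param par PAR intervals; PAR loci are treated as autosomal.
#' @return data.frame (one row per SV x carrier child) with SV columns,
#'   `child`, `sex`, `role`, `family`, `gt`, `father_gt`, `mother_gt`;
#'   removal counts per chromosome class in `attr(, "log")`.
#' @export
pangenome_filter <- function(table, ped, par = sim_par_regions()) {
  children <- ped$sample[ped$role %in% c("proband", "sibling")]
  controls <- ped$sample[ped$role == "control"]
  miss <- setdiff(children, colnames(table$gt))
  if (length(miss)) stop("child not present in table: ", paste(miss, collapse = ", "))
  controls <- intersect(controls, colnames(table$gt))
  svs <- table$svs
  gt <- table$gt
  sexchrom <- svs$chrom %in% c("chrX", "chrY") & !in_par(svs$chrom, svs$start, par)
  child_sex <- ped$sex[match(children, ped$sample)]
  ctrl_sex <- ped$sex[match(controls, ped$sample)]

  carr_child <- matrix(gt_carrier(gt[, children, drop = FALSE]),
                       nrow = nrow(svs), dimnames = list(NULL, children))
  if (length(controls)) {
    carr_ctrl <- matrix(gt_carrier(gt[, controls, drop = FALSE]), nrow = nrow(svs))
    any_ctrl <- rowSums(carr_ctrl) > 0
    ctrl_f <- rowSums(carr_ctrl[, ctrl_sex == "F", drop = FALSE]) > 0
    ctrl_m <- rowSums(carr_ctrl[, ctrl_sex == "M", drop = FALSE]) > 0
  } else {
    any_ctrl <- ctrl_f <- ctrl_m <- rep(FALSE, nrow(svs))
  }
  keep_pair <- carr_child
  for (j in seq_along(children)) {
    seen <- ifelse(sexchrom,
                   if (child_sex[j] == "F") ctrl_f else ctrl_m,
                   any_ctrl)
    keep_pair[, j] <- carr_child[, j] & !seen
  }
  pairs <- which(keep_pair, arr.ind = TRUE)
  log <- list(
    n_rows_in = nrow(svs),
    n_pairs_carrier = sum(carr_child),
    n_pairs_removed_auto = sum(carr_child[!sexchrom, , drop = FALSE]) -
      sum(keep_pair[!sexchrom, , drop = FALSE]),
    n_pairs_removed_sex = sum(carr_child[sexchrom, , drop = FALSE]) -
      sum(keep_pair[sexchrom, , drop = FALSE]))
  if (nrow(pairs) == 0) {
    out <- cbind(svs[0, , drop = FALSE],
                 data.frame(child = character(0), sex = character(0),
                            role = character(0), family = character(0),
                            gt = character(0), father_gt = character(0),
                            mother_gt = character(0)))
    attr(out, "log") <- log
    return(out)
  }
  ri <- pairs[, 1]
  ch <- children[pairs[, 2]]
  fam <- ped$family[match(ch, ped$sample)]
  parent_gt <- function(role) {
    ps <- ped$sample[match(paste0(fam, role), paste0(ped$family, ped$role))]
    out <- rep("missing", length(ps))
    ok <- !is.na(ps) & ps %in% colnames(gt)
    out[ok] <- gt[cbind(ri[ok], match(ps[ok], colnames(gt)))]
    out
  }
  out <- cbind(svs[ri, , drop = FALSE],
               data.frame(child = ch,
                          sex = ped$sex[match(ch, ped$sample)],
                          role = ped$role[match(ch, ped$sample)],
                          family = fam,
                          gt = gt[cbind(ri, match(ch, colnames(gt)))],
                          father_gt = parent_gt("father"),
                          mother_gt = parent_gt("mother")))
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}

#' Assign the six zygosity categories
#'
#' Each (SV, child) pair receives exactly one of AUTO_HET, AUTO_HOM, X_HET,
#' X_HOM, X_HEMI, Y_HEMI. Males on non-PAR chrX/chrY are always hemizygous;
#' PAR loci are treated as autosomal. A homozygous call on non-PAR chrX in a
#' male is flagged inconsistent (and categorized X_HEMI) rather than
#' raising an error.
#'
#' @param rare long rare-SV table from [pangenome_filter()].
#' @param par PAR intervals.
#' @return `rare` with `category` and `zygosity_flag` columns; category
#'   tallies (both per occurrence and per unique SV) in `attr(, "counts")`.
#' @export
classify_zygosity_categories <- function(rare, par = sim_par_regions()) {
  if (nrow(rare) == 0) {
    rare$category <- character(0)
    rare$zygosity_flag <- character(0)
    return(rare)
  }
  sexchrom <- rare$chrom %in% c("chrX", "chrY") & !in_par(rare$chrom, rare$start, par)
  male <- rare$sex == "M"
  cat <- ifelse(!sexchrom,
                ifelse(rare$gt == "hom", "AUTO_HOM", "AUTO_HET"),
         ifelse(rare$chrom == "chrY", "Y_HEMI",
         ifelse(male, "X_HEMI",
                ifelse(rare$gt == "hom", "X_HOM", "X_HET"))))
  flag <- ifelse(sexchrom & male & rare$gt %in% c("het", "hom"),
                 "male_diploid_on_haploid_locus", "")
  rare$category <- cat
  rare$zygosity_flag <- flag
  per_occ <- table(factor(cat, levels = c("AUTO_HET", "AUTO_HOM", "X_HET",
                                          "X_HOM", "X_HEMI", "Y_HEMI")))
  first <- !duplicated(rare$sv_id)
  per_sv <- table(factor(cat[first], levels = names(per_occ)))
  attr(rare, "counts") <- list(per_occurrence = per_occ, per_sv = per_sv)
  rare
}

# Which alleles can a parent genotype transmit? Returns two logical vectors.
.can_transmit <- function(gt) {
  list(a0 = gt %in% c("absent", "het"),
       a1 = gt %in% c("het", "hom", "hemi"),
       known = gt != "missing")
}

#' Mendelian-consistency classification
#'
#' A child genotype is high confidence (HC) when it is producible from the
#' parental genotypes under sex-aware Mendelian transmission (sons receive
#' the maternal X and the paternal Y; PAR loci segregate as autosomal), and
#' low confidence (LC) otherwise or when a required parent is missing.
#'
#' @param child_gt,father_gt,mother_gt genotype-code vectors.
#' @param chrom,pos locus coordinates (vectors).
#' @param child_sex "F"/"M" vector.
#' @param par PAR intervals.
#' @return character vector of "HC"/"LC".
#' @export
mendelian_classify <- function(child_gt, father_gt, mother_gt, chrom, pos,
                               child_sex, par = sim_par_regions()) {
  n <- length(child_gt)
  fa <- .can_transmit(father_gt)
  mo <- .can_transmit(mother_gt)
  pc <- locus_ploidy_class(chrom, pos, child_sex, par)
  hc <- rep(FALSE, n)
  dip <- pc == "diploid"
  hc[dip & child_gt == "absent"] <- (fa$a0 & mo$a0)[dip & child_gt == "absent"]
  hc[dip & child_gt == "het"] <- ((fa$a1 & mo$a0) | (fa$a0 & mo$a1))[dip & child_gt == "het"]
  hc[dip & child_gt == "hom"] <- (fa$a1 & mo$a1)[dip & child_gt == "hom"]
  isX <- pc == "haploid" & chrom == "chrX"
  isY <- pc == "haploid" & chrom == "chrY"
  hc[isX & child_gt == "hemi"] <- mo$a1[isX & child_gt == "hemi"]
  hc[isX & child_gt == "absent"] <- mo$a0[isX & child_gt == "absent"]
  hc[isY & child_gt == "hemi"] <- fa$a1[isY & child_gt == "hemi"]
  hc[isY & child_gt == "absent"] <- fa$a0[isY & child_gt == "absent"]
  # a missing required parent, or a missing child call, is never HC
  need_fa <- dip | isY
  need_mo <- dip | isX
  hc[(need_fa & !fa$known) | (need_mo & !mo$known) | child_gt == "missing"] <- FALSE
  ifelse(hc, "HC", "LC")
}

#' Add Mendelian confidence to a rare-SV table
#'
#' @param rare long rare-SV table.
#' @param par PAR intervals.
#' @return `rare` with a `confidence` column; the cohort concordance rate
#'   HC/(HC+LC) in `attr(, "concordance")`.
#' @export
add_mendelian_confidence <- function(rare, par = sim_par_regions()) {
  rare$confidence <- if (nrow(rare)) {
    mendelian_classify(rare$gt, rare$father_gt, rare$mother_gt,
                       rare$chrom, rare$start, rare$sex, par)
  } else character(0)
  attr(rare, "concordance") <-
    if (nrow(rare)) mean(rare$confidence == "HC") else NA_real_
  rare
}

#' Classify variant origin for rare SVs
#'
#' Labels, per (SV, child) pair: `DENOVO` (child carries, both parents
#' confidently absent; the control panel was already excluded upstream),
#' `PRIVATE_INHERITED` (the transmitting parental allele is observed in
#' exactly one parent across the whole parental population),
#' `PRIVATE_BIALLELIC_HOM` (child homozygous, inherited from two
#' heterozygous parents, family-unique among all parents and never
#' homozygous in any control), otherwise `INHERITED_OTHER`. Low-confidence
#' rows are `UNRESOLVED` and handed to the curation cascade.
#'
#' @param rare rare-SV table with `confidence` (see
#'   [add_mendelian_confidence()]).
#' @param table the cohort table the rare rows came from (for
#'   parental-population and control lookups).
#' @param ped pedigree data.frame.
#' @return `rare` with an `origin` column.
#' @export
classify_variant_origin <- function(rare, table, ped) {
  if (nrow(rare) == 0) {
    rare$origin <- character(0)
    return(rare)
  }
  parents <- intersect(ped$sample[ped$role %in% c("father", "mother")],
                       colnames(table$gt))
  controls <- intersect(ped$sample[ped$role == "control"], colnames(table$gt))
  ri <- match(rare$sv_id, table$svs$sv_id)
  pgt <- table$gt[ri, parents, drop = FALSE]
  n_parent_carriers <- rowSums(matrix(gt_carrier(pgt), nrow = length(ri)))
  n_ctrl_hom <- if (length(controls))
    rowSums(table$gt[ri, controls, drop = FALSE] == "hom") else rep(0L, length(ri))

  fa1 <- .can_transmit(rare$father_gt)$a1 & rare$father_gt != "missing"
  mo1 <- .can_transmit(rare$mother_gt)$a1 & rare$mother_gt != "missing"
  both_absent <- rare$father_gt == "absent" & rare$mother_gt == "absent"
  # transmitting parent is identifiable for het (single carrier parent) and
  # hemizygous (sex-determined) calls
  single_parent <- (rare$gt == "het" & (fa1 + mo1 == 1)) |
    (rare$gt == "hemi" & rare$chrom == "chrX" & mo1) |
    (rare$gt == "hemi" & rare$chrom == "chrY" & fa1)

  origin <- rep("INHERITED_OTHER", nrow(rare))
  origin[single_parent & n_parent_carriers == 1] <- "PRIVATE_INHERITED"
  origin[rare$gt == "hom" & rare$father_gt == "het" & rare$mother_gt == "het" &
           n_parent_carriers == 2 & n_ctrl_hom == 0] <- "PRIVATE_BIALLELIC_HOM"
  # remaining Mendelian-discordant rows go to the curation cascade; the
  # clean de novo pattern is itself non-Mendelian, so it is labeled after
  # the LC override
  if ("confidence" %in% names(rare)) origin[rare$confidence == "LC"] <- "UNRESOLVED"
  denovo <- gt_carrier(rare$gt) & both_absent &
    !(rare$gt == "hom")  # a hom child with two absent parents is implausible
  origin[denovo] <- "DENOVO"
  rare$origin <- origin
  rare
}

#' Folded minor allele frequencies over a cohort table
#'
#' Allele counts sum genotype dosages; hemizygous samples contribute one
#' allele to the allele number, diploid samples two, missing calls none.
#' Frequencies are folded to at most 0.5.
#'
#' @param table a `cohort_sv_table`.
#' @param sexes named vector sample -> "F"/"M".
#' @param par PAR intervals.
#' @return data.frame: `sv_id`, `ac`, `an`, `maf`.
#' @export
compute_maf <- function(table, sexes, par = sim_par_regions()) {
  svs <- table$svs
  gt <- table$gt
  n <- nrow(svs)
  ac <- integer(n); an <- integer(n)
  for (s in colnames(gt)) {
    pc <- locus_ploidy_class(svs$chrom, svs$start, sexes[[s]], par)
    g <- gt[, s]
    dose <- gt_dosage(g)
    dose[is.na(dose)] <- 0L
    ploid <- ifelse(g == "missing", 0L, ifelse(pc == "haploid", 1L,
                    ifelse(pc == "none", 0L, 2L)))
    ac <- ac + dose
    an <- an + ploid
  }
  af <- ifelse(an > 0, ac / an, NA_real_)
  data.frame(sv_id = svs$sv_id, ac = ac, an = an,
             maf = pmin(af, 1 - af))
}

#' Cumulative SV discovery curves with permutation bands
#'
#' For each ancestry stratum, samples are added in random order and the
#' cumulative count of distinct (collapsed) SV rows carried so far is
#' recorded; the mean and min-max band over permutations is returned.
#'
#' @param table a `cohort_sv_table` containing the panel samples.
#' @param strata named vector sample -> stratum label (e.g. AFR/nonAFR).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return data.frame: `stratum`, `n_samples`, `mean`, `min`, `max`.
#' @export
discovery_curve <- function(table, strata, n_perm = 10, seed = 1) {
  stopifnot(n_perm >= 1)
  samples <- intersect(names(strata), colnames(table$gt))
  carried <- lapply(samples, function(s) which(gt_carrier(table$gt[, s])))
  names(carried) <- samples
  withr::with_seed(seed, {
    out <- vector("list", 0)
    for (st in unique(strata[samples])) {
      mem <- samples[strata[samples] == st]
      counts <- matrix(0L, n_perm, length(mem))
      for (p in seq_len(n_perm)) {
        ord <- sample(mem)
        seen <- logical(nrow(table$svs))
        for (k in seq_along(ord)) {
          seen[carried[[ord[k]]]] <- TRUE
          counts[p, k] <- sum(seen)
        }
      }
      out[[st]] <- data.frame(stratum = st, n_samples = seq_along(mem),
                              mean = colMeans(counts),
                              min = apply(counts, 2, min),
                              max = apply(counts, 2, max))
    }
    do.call(rbind, out)
  })
}

#' Fraction of a large panel's SVs captured by a smaller panel, by MAF bin
#'
#' @param small_svs,large_svs SV tables (rows of the respective collapsed
#'   panels).
#' @param large_maf data.frame with `sv_id` and `maf` for the large panel
#'   (see [compute_maf()]).
#' @param breaks MAF bin breakpoints (passed to [cut()]).
#' @param p matching parameters for the cross-panel comparison.
#' @return data.frame: `bin`, `n`, `n_captured`, `capture`.
#' @export
maf_capture <- function(small_svs, large_svs, large_maf,
                        breaks = c(0, 0.001, 0.01, 0.05, 0.1, 0.5),
                        p = match_params(pctseq = 0, pctsize = 0.5, pctovl = 0.5)) {
  captured <- rep(FALSE, nrow(large_svs))
  if (nrow(small_svs) > 0 && nrow(large_svs) > 0) {
    hits <- match_any(large_svs, small_svs, p)
    captured[unique(hits$qi)] <- TRUE
  }
  maf <- large_maf$maf[match(large_svs$sv_id, large_maf$sv_id)]
  bin <- cut(maf, breaks = breaks, include.lowest = TRUE)
  agg <- data.frame(bin = levels(bin),
                    n = as.integer(table(bin)),
                    n_captured = as.integer(tapply(captured, bin, sum, default = 0)))
  agg$capture <- ifelse(agg$n > 0, agg$n_captured / agg$n, NA_real_)
  agg
}
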