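# A tiny hand-built cohort table for rule-level fixtures.
fixture_table <- function(chrom = "chr1", pos = 1000L, gts) {
  svs <- sv_table("svA", chrom, pos, svtype = "DEL", svlen = 100L,
                  seq = strrep("AT", 50))
  gt <- matrix(gts, nrow = 1, dimnames = list("svA", names(gts)))
  structure(list(svs = svs, gt = gt,
                 support = data.frame(), params = match_params(), keep = "common",
                 log = list()), class = "cohort_sv_table")
}

fixture_ped <- function() {
  data.frame(
    sample = c("fa", "mo", "p1", "c1", "c2"),
    family = c("f1", "f1", "f1", NA, NA),
    role = c("father", "mother", "proband", "control", "control"),
    sex = c("M", "F", "F", "M", "F"),
    population = "nonAFR")
}

test_that("pangenome filter keeps child-only SVs and applies sex matching", {
  ped <- fixture_ped()
  # carried by child only -> retained
  t1 <- fixture_table(gts = c(fa = "absent", mo = "absent", p1 = "het",
                              c1 = "absent", c2 = "absent"))
  expect_equal(nrow(pangenome_filter(t1, ped)), 1L)
  # carried by one autosomal control -> removed
  t2 <- fixture_table(gts = c(fa = "absent", mo = "absent", p1 = "het",
                              c1 = "het", c2 = "absent"))
  expect_equal(nrow(pangenome_filter(t2, ped)), 0L)
  # X-linked SV in a female child carried only by a male control -> retained
  t3 <- fixture_table(chrom = "chrX", pos = 2e6,
                      gts = c(fa = "absent", mo = "absent", p1 = "het",
                              c1 = "hemi", c2 = "absent"))
  expect_equal(nrow(pangenome_filter(t3, ped)), 1L)
  # same but a female control carries -> removed
  t4 <- fixture_table(chrom = "chrX", pos = 2e6,
                      gts = c(fa = "absent", mo = "absent", p1 = "het",
                              c1 = "absent", c2 = "het"))
  expect_equal(nrow(pangenome_filter(t4, ped)), 0L)
  # unknown child errors
  bad <- ped; bad$sample[3] <- "nope"
  expect_error(pangenome_filter(t1, bad), "child not present")
})

test_that("zygosity categories partition carriers and respect hemizygosity", {
  fx <- small_quad_sim(n_loci = 1200, denovo_rate = 0, seed = 31)
  tab <- cohort_table_from_sim(fx$sim)
  rare <- classify_zygosity_categories(pangenome_filter(tab, fx$ped))
  counts <- attr(rare, "counts")
  expect_equal(sum(counts$per_occurrence), nrow(rare))
  # category consistent with truth recomputed from genotype + locus class
  par <- sim_par_regions()
  sexchrom <- rare$chrom %in% c("chrX", "chrY") & !in_par(rare$chrom, rare$start, par)
  expect_true(all(rare$category[!sexchrom & rare$gt == "het"] == "AUTO_HET"))
  expect_true(all(rare$category[!sexchrom & rare$gt == "hom"] == "AUTO_HOM"))
  expect_true(all(rare$category[rare$chrom == "chrY" & sexchrom] == "Y_HEMI"))
  expect_true(all(rare$category[sexchrom & rare$chrom == "chrX" &
                                  rare$sex == "M"] == "X_HEMI"))
  expect_true(all(rare$category[sexchrom & rare$chrom == "chrX" &
                                  rare$sex == "F" & rare$gt == "het"] == "X_HET"))
  expect_true(all(rare$zygosity_flag == ""))
})

test_that("Mendelian classification follows sex-aware transmission rules", {
  # child het, father het, mother absent -> HC
  expect_equal(mendelian_classify("het", "het", "absent", "chr1", 1000, "F"), "HC")
  # child hom, both parents absent -> LC
  expect_equal(mendelian_classify("hom", "absent", "absent", "chr1", 1000, "F"), "LC")
  # missing parent -> LC even if compatible
  expect_equal(mendelian_classify("het", "missing", "het", "chr1", 1000, "F"), "LC")
  # son's non-PAR X comes from the mother
  expect_equal(mendelian_classify("hemi", "absent", "het", "chrX", 2e6, "M"), "HC")
  expect_equal(mendelian_classify("hemi", "hemi", "absent", "chrX", 2e6, "M"), "LC")
  # son's Y comes from the father
  expect_equal(mendelian_classify("hemi", "hemi", "absent", "chrY", 2e6, "M"), "HC")
  # PAR X behaves autosomally in males
  expect_equal(mendelian_classify("het", "het", "absent", "chrX", 1000, "M"), "HC")
})

test_that("variant origin labels are exclusive and match constructed fixtures", {
  ped <- fixture_ped()
  # de novo: child carries, both parents absent, no controls
  t1 <- fixture_table(gts = c(fa = "absent", mo = "absent", p1 = "het",
                              c1 = "absent", c2 = "absent"))
  r1 <- classify_variant_origin(add_mendelian_confidence(pangenome_filter(t1, ped)),
                                t1, ped)
  expect_equal(r1$origin, "DENOVO")
  # private biallelic hom: child hom, both parents het, family-unique
  t2 <- fixture_table(gts = c(fa = "het", mo = "het", p1 = "hom",
                              c1 = "absent", c2 = "absent"))
  r2 <- classify_variant_origin(add_mendelian_confidence(pangenome_filter(t2, ped)),
                                t2, ped)
  expect_equal(r2$origin, "PRIVATE_BIALLELIC_HOM")
  # private inherited: transmitting father is the only carrier parent
  t3 <- fixture_table(gts = c(fa = "het", mo = "absent", p1 = "het",
                              c1 = "absent", c2 = "absent"))
  r3 <- classify_variant_origin(add_mendelian_confidence(pangenome_filter(t3, ped)),
                                t3, ped)
  expect_equal(r3$origin, "PRIVATE_INHERITED")
  # each resolved pair gets exactly one label (simulated cohort)
  fx <- small_quad_sim(n_loci = 1000, denovo_rate = 0.5, seed = 37)
  tab <- cohort_table_from_sim(fx$sim)
  rare <- classify_variant_origin(
    add_mendelian_confidence(pangenome_filter(tab, fx$ped)), tab, fx$ped)
  expect_true(all(rare$origin %in% c("DENOVO", "PRIVATE_INHERITED",
                                     "PRIVATE_BIALLELIC_HOM", "INHERITED_OTHER",
                                     "UNRESOLVED")))
})

test_that("MAF equals the brute-force allele tally and folds correctly", {
  # 1 het among 50 diploid samples -> 1/100
  gts <- setNames(c("het", rep("absent", 49)), sprintf("s%02d", 1:50))
  tab <- fixture_table(gts = gts)
  sexes <- setNames(rep("F", 50), names(gts))
  maf <- compute_maf(tab, sexes)
  expect_equal(maf$maf, 0.01)
  expect_equal(maf$an, 100L)
  # all hom folds to 0
  tab2 <- fixture_table(gts = setNames(rep("hom", 10), sprintf("s%02d", 1:10)))
  expect_equal(compute_maf(tab2, setNames(rep("F", 10), sprintf("s%02d", 1:10)))$maf, 0)
  # random matrix vs direct tally (mixed sexes, X locus)
  fx <- small_quad_sim(n_loci = 600, denovo_rate = 0, seed = 41)
  tabs <- cohort_table_from_sim(fx$sim)
  sexes <- setNames(fx$ped$sex, fx$ped$sample)
  maf <- compute_maf(tabs, sexes)
  par <- sim_par_regions()
  for (i in sample.int(nrow(tabs$svs), 25)) {
    ac <- an <- 0
    for (s in colnames(tabs$gt)) {
      g <- tabs$gt[i, s]
      pc <- locus_ploidy_class(tabs$svs$chrom[i], tabs$svs$start[i], sexes[[s]], par)
      if (pc == "none" || g == "missing") next
      ac <- ac + switch(g, absent = 0, het = 1, hom = 2, hemi = 1)
      an <- an + if (pc == "haploid") 1 else 2
    }
    expect_equal(maf$ac[i], ac)
    expect_equal(maf$an[i], an)
    expect_equal(maf$maf[i], min(ac / an, 1 - ac / an))
  }
})

test_that("discovery curves are nondecreasing with correct degenerate forms", {
  # identical callsets: flat after the first sample
  gts <- c(a = "het", b = "het", c = "het")
  tab <- fixture_table(gts = gts)
  strata <- setNames(rep("AFR", 3), names(gts))
  dc <- discovery_curve(tab, strata, n_perm = 3, seed = 1)
  expect_equal(dc$mean, c(1, 1, 1))
  # disjoint callsets: running sum of set sizes
  svs <- sv_table(sprintf("v%d", 1:3), "chr1", c(1000L, 50000L, 90000L),
                  svtype = "DEL", svlen = 100L, seq = strrep("AT", 50))
  gt <- matrix("absent", 3, 3, dimnames = list(svs$sv_id, c("a", "b", "c")))
  diag(gt) <- "het"
  tab2 <- structure(list(svs = svs, gt = gt, params = match_params()),
                    class = "cohort_sv_table")
  dc2 <- discovery_curve(tab2, strata, n_perm = 4, seed = 2)
  expect_equal(dc2$mean, c(1, 2, 3))
  expect_true(all(dc2$min <= dc2$mean & dc2$mean <= dc2$max))
})

test_that("the AFR discovery curve dominates the non-AFR curve", {
  ped <- data.frame(sample = sprintf("c%03d", 1:30), family = NA,
                    role = "control", sex = "F",
                    population = rep(c("AFR", "nonAFR"), each = 15))
  pool <- simulate_sv_pool(2000, seed = 43)
  sim <- simulate_cohort(pool, ped, denovo_rate = 0, seed = 43)
  tab <- cohort_table_from_sim(sim)
  dc <- discovery_curve(tab, setNames(ped$population, ped$sample),
                        n_perm = 5, seed = 3)
  afr <- dc$mean[dc$stratum == "AFR"]
  naf <- dc$mean[dc$stratum == "nonAFR"]
  expect_true(all(afr > naf))
  expect_true(all(diff(afr) >= 0))
})

test_that("MAF capture has correct limits and tracks panel subsampling", {
  fx <- small_quad_sim(n_loci = 800, n_controls = 40, denovo_rate = 0, seed = 47)
  tab <- cohort_table_from_sim(fx$sim)
  sexes <- setNames(fx$ped$sex, fx$ped$sample)
  maf <- compute_maf(tab, sexes)
  # small == large -> all bins 1; empty small -> all bins 0
  full <- maf_capture(tab$svs, tab$svs, maf)
  expect_true(all(full$capture[full$n > 0] == 1))
  none <- maf_capture(tab$svs[0, ], tab$svs, maf)
  expect_true(all(none$capture[none$n > 0] == 0))
  # a 20% sample subset captures common SVs near 1, rare ones near 0.2
  ctrl <- fx$ped$sample[fx$ped$role == "control"]
  sub <- ctrl[seq(1, length(ctrl), by = 5)]
  carried <- rowSums(matrix(tab$gt[, sub] %in% c("het", "hom", "hemi"),
                            nrow(tab$svs))) > 0
  mc <- maf_capture(tab$svs[carried, ], tab$svs, maf,
                    breaks = c(0, 0.05, 0.2, 0.5))
  expect_true(mc$capture[3] > mc$capture[1])
  expect_gt(mc$capture[3], 0.8)
})
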