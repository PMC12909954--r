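mk_sv <- function(id = "svA", start = 1000L, chrom = "chr1") {
  sv_table(id, chrom, start, svtype = "DEL", svlen = 100L, seq = strrep("AT", 50))
}

test_that("parental raw-callset matching rescues dropped parent calls", {
  child <- mk_sv()
  # identical record in the father's raw callset -> hit
  hit <- parental_support_match(child, list(father = mk_sv("raw1"),
                                            mother = mk_sv("raw2", start = 90000L)))
  expect_equal(hit, "father")
  # nothing within refdist -> empty
  none <- parental_support_match(child, list(father = mk_sv("raw1", start = 50000L)))
  expect_length(none, 0)
})

test_that("re-genotype consistency reuses the Mendelian rules", {
  expect_equal(regenotype_consistency("het", "het", "absent", "chr1", 1000, "F"),
               "consistent")
  expect_equal(regenotype_consistency("het", "absent", "absent", "chr1", 1000, "F"),
               "denovo_support")
  expect_equal(regenotype_consistency("hom", "absent", "het", "chr1", 1000, "F"),
               "inconsistent")
  expect_true(is.na(regenotype_consistency("het", NA, "het", "chr1", 1000, "F")))
  # random fixtures agree with mendelian_classify (carrier children)
  set.seed(5)
  for (i in 1:50) {
    cg <- sample(c("het", "hom"), 1)
    fg <- sample(c("absent", "het", "hom"), 1)
    mg <- sample(c("absent", "het", "hom"), 1)
    v <- regenotype_consistency(cg, fg, mg, "chr1", 1000, "F")
    m <- mendelian_classify(cg, fg, mg, "chr1", 1000, "F")
    if (v == "consistent") expect_equal(m, "HC")
    if (v == "inconsistent") expect_equal(m, "LC")
  }
})

test_that("read support applies the deviation and min-read rules", {
  rs <- data.frame(sample = c("fa", "fa", "mo"), sv_id = "svA",
                   dev_frac = c(0.0, 0.6, 0.6), n_reads = c(1L, 5L, 5L))
  expect_true(read_support_check("svA", "fa", rs))
  # reads only beyond the 50% deviation cap are not support
  expect_false(read_support_check("svA", "mo", rs))
  expect_false(read_support_check("svB", "fa", rs))
  expect_false(read_support_check("svA", "fa", rs, min_reads = 2))
})

test_that("simulated read support reflects true parental carriers", {
  fx <- small_quad_sim(n_loci = 600, denovo_rate = 0, seed = 53)
  rs <- simulate_read_support(fx$sim, noise = 0, seed = 53)
  parents <- fx$ped$sample[fx$ped$role %in% c("father", "mother")]
  set.seed(1)
  for (s in sample(parents, 3)) {
    carried <- rownames(fx$sim$true_gt)[fx$sim$true_gt[, s] %in% c("het", "hom", "hemi")]
    for (sv in sample(carried, 10))
      expect_true(read_support_check(sv, s, rs))
    absent <- rownames(fx$sim$true_gt)[fx$sim$true_gt[, s] == "absent"]
    for (sv in sample(absent, 10))
      expect_false(read_support_check(sv, s, rs))
  }
})

test_that("TR outlier scan flags planted expansions with parental origin", {
  ped <- simulate_pedigree(n_quads = 8, n_trios = 0, n_controls = 30, seed = 59)
  tr <- simulate_tr_cohort(ped, n_loci = 50, n_expansions = 3, seed = 59)
  hits <- suppressWarnings(tr_outlier_scan(tr$alleles, ped))
  expect_equal(nrow(hits), 3L)
  expect_setequal(paste(hits$locus, hits$child),
                  paste(tr$truth$locus, tr$truth$child))
  expect_true(all(hits$origin == "maternal"))
  # all-equal alleles: zero variance handled as no call
  flat <- data.frame(sample = rep(ped$sample, 2), locus = "trX",
                     al1 = 100, al2 = 100)
  expect_equal(nrow(suppressWarnings(tr_outlier_scan(flat, ped))), 0L)
  # fewer than 20 samples: locus skipped with a warning
  few <- data.frame(sample = ped$sample[1:5], locus = "trY",
                    al1 = c(100, 100, 100, 100, 500), al2 = 100)
  expect_warning(tr_outlier_scan(few, ped), "fewer than")
})

test_that("the cascade short-circuits, resolves truth, and can be disabled", {
  fx <- small_quad_sim(n_loci = 2000, denovo_rate = 1, error_rate = 0.05, seed = 61)
  tab <- cohort_table_from_sim(fx$sim)
  rare <- classify_variant_origin(
    add_mendelian_confidence(pangenome_filter(tab, fx$ped)), tab, fx$ped)
  lc <- rare[rare$origin == "UNRESOLVED", , drop = FALSE]
  expect_gt(nrow(lc), 0)
  # zero-noise evidence: re-genotypes are the true genotypes
  tg <- fx$sim$true_gt
  rg <- data.frame(sample = rep(colnames(tg), each = nrow(tg)),
                   sv_id = rep(rownames(tg), ncol(tg)), gt = as.vector(tg))
  rs <- simulate_read_support(fx$sim, seed = 61)
  v <- curate(lc, evidence = list(regenotype = rg, read_support = rs), fx$ped)
  expect_identical(v$status == "UNRESOLVED_MANUAL", v$deciding_step == "none")
  # verdicts agree with the simulation truth
  fa <- fx$ped$sample[match(paste(lc$family, "father"),
                            paste(fx$ped$family, fx$ped$role))]
  mo <- fx$ped$sample[match(paste(lc$family, "mother"),
                            paste(fx$ped$family, fx$ped$role))]
  truly_trans <- vapply(seq_len(nrow(lc)), function(i)
    any(tg[lc$sv_id[i], c(fa[i], mo[i])] %in% c("het", "hom", "hemi")), logical(1))
  child_carrier <- tg[cbind(match(lc$sv_id, rownames(tg)),
                            match(lc$child, colnames(tg)))] %in%
    c("het", "hom", "hemi")
  ok <- (v$status == "TRANSMITTED_CONFIRMED" & truly_trans) |
    (v$status == "DENOVO_CONFIRMED" & child_carrier & !truly_trans) |
    (v$status == "UNRESOLVED_MANUAL" & !child_carrier)
  expect_true(all(ok))
  # determinism
  v2 <- curate(lc, evidence = list(regenotype = rg, read_support = rs), fx$ped)
  expect_identical(v, v2)
  # decisive step 1 wins without consulting later steps
  one <- lc[1, , drop = FALSE]
  svcols <- c("sv_id", "chrom", "start", "end", "svtype", "svlen", "seq")
  raw <- setNames(list(list(father = one[, svcols],
                            mother = mk_sv("far", start = 9e5))), one$child)
  v3 <- curate(one, evidence = list(parental_raw = raw, regenotype = rg), fx$ped)
  expect_equal(v3$deciding_step, "parental_match")
  expect_equal(v3$status, "TRANSMITTED_CONFIRMED")
  # all evidence absent / steps disabled -> everything manual
  v0 <- curate(lc, evidence = list(), fx$ped)
  expect_true(all(v0$status == "UNRESOLVED_MANUAL"))
  v00 <- curate(lc, evidence = list(regenotype = rg), fx$ped, steps = character(0))
  expect_true(all(v00$status == "UNRESOLVED_MANUAL" & v00$deciding_step == "none"))
})

test_that("a de novo verdict is never issued against raw parental evidence", {
  fx <- small_quad_sim(n_loci = 800, denovo_rate = 0, error_rate = 0.08, seed = 67)
  tab <- cohort_table_from_sim(fx$sim)
  rare <- classify_variant_origin(
    add_mendelian_confidence(pangenome_filter(tab, fx$ped)), tab, fx$ped)
  lc <- rare[rare$origin == "UNRESOLVED", , drop = FALSE]
  # raw parental callsets from the true genotypes; regenotype claims de novo
  pool <- fx$sim$pool
  raws <- list()
  for (i in seq_len(nrow(lc))) {
    fid <- lc$family[i]
    get_raw <- function(role) {
      ps <- fx$ped$sample[fx$ped$family == fid & fx$ped$role == role]
      carried <- rownames(fx$sim$true_gt)[
        fx$sim$true_gt[, ps] %in% c("het", "hom", "hemi")]
      pi <- match(carried, pool$locus_id)
      sv_table(carried, pool$chrom[pi], pool$pos[pi], svtype = pool$svtype[pi],
               svlen = pool$svlen[pi], seq = pool$seq[pi])
    }
    raws[[lc$child[i]]] <- list(father = get_raw("father"),
                                mother = get_raw("mother"))
  }
  wrong_rg <- data.frame(
    sample = rep(colnames(fx$sim$gt), each = nrow(fx$sim$gt)),
    sv_id = rep(rownames(fx$sim$gt), ncol(fx$sim$gt)),
    gt = "absent")
  wrong_rg$gt[wrong_rg$sample %in% lc$child] <- "het"
  v <- curate(lc, evidence = list(parental_raw = raws, regenotype = wrong_rg),
              fx$ped, steps = c("regenotype"))
  truly_trans <- vapply(seq_len(nrow(lc)), function(i) {
    fid <- lc$family[i]
    ps <- fx$ped$sample[fx$ped$family == fid & fx$ped$role %in% c("father", "mother")]
    any(fx$sim$true_gt[lc$sv_id[i], ps] %in% c("het", "hom", "hemi"))
  }, logical(1))
  expect_false(any(v$status == "DENOVO_CONFIRMED" & truly_trans))
})
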