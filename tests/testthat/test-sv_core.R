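test_that("VCF coordinates follow the 0-based convention and round-trip", {
  d <- withr::local_tempdir()
  svs <- sv_table(sv_id = "ins1", chrom = "chr1", start = 999L,
                  svtype = "INS", svlen = 300L,
                  seq = paste(rep("ACGT", 75), collapse = ""), qual = 40)
  gt <- matrix("het", 1, 1, dimnames = list(NULL, "sampleA"))
  path <- file.path(d, "one.vcf")
  write_sv_vcf(svs, path, gt = gt)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(as.integer(strsplit(body, "\t")[[1]][2]), 1000L)  # POS 1-based
  rt <- read_sv_vcf(path)
  expect_equal(rt$svs$start, 999L)
  expect_equal(rt$svs$end, 999L)
  expect_equal(rt$svs$svlen, 300L)
  expect_equal(unname(rt$gt[1, 1]), "het")
})

test_that("multiallelic VCF records split into biallelic SV records", {
  d <- withr::local_tempdir()
  path <- file.path(d, "multi.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=.,Type=String,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"l\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    paste("chr1", "500", "mv", "N", paste0("N", strrep("AC", 50), ",N", strrep("AG", 60)),
          "30", "PASS", "SVTYPE=INS,INS;SVLEN=100,120", "GT", "1/2", sep = "\t")),
    path)
  rt <- read_sv_vcf(path)
  expect_equal(nrow(rt$svs), 2L)
  expect_equal(rt$svs$svlen, c(100L, 120L))
  expect_equal(unname(rt$gt[, 1]), c("het", "het"))
})

test_that("a written 100-record genotyped table reads back identically", {
  d <- withr::local_tempdir()
  set.seed(7)
  n <- 100
  svs <- sv_table(sprintf("sv%03d", 1:n), sample(c("chr1", "chr2"), n, TRUE),
                  start = sort(sample.int(1e6, n)),
                  svtype = sample(c("INS", "DEL", "INV"), n, TRUE),
                  svlen = sample(50:2000, n), qual = round(runif(n, 1, 60), 1))
  has_seq <- svs$svtype != "INV"
  svs$seq[has_seq] <- vapply(svs$svlen[has_seq], function(k)
    paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""), character(1))
  svs$end <- ifelse(svs$svtype == "INS", svs$start, svs$start + svs$svlen)
  gt <- matrix(sample(c("absent", "het", "hom", "missing"), n * 3, TRUE), n, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  path <- file.path(d, "tab.vcf")
  write_sv_vcf(svs, path, gt = gt)
  rt <- read_sv_vcf(path)
  o <- match(svs$sv_id, rt$svs$sv_id)
  expect_equal(rt$svs$start[o], svs$start)
  expect_equal(rt$svs$svlen[o], svs$svlen)
  expect_equal(rt$svs$seq[o][has_seq], svs$seq[has_seq])
  expect_equal(unname(rt$gt[o, ]), unname(gt))
})

test_that("sv_match honours identity, type, size ratio and symmetry", {
  p <- match_params()
  a <- sv_table("a", "chr1", 1000L, svtype = "INS", svlen = 300L,
                seq = strrep("ACGT", 75))
  ident <- sv_match(a, a, p)
  expect_true(ident$matched)
  expect_equal(ident$sizesim, 1.0)
  expect_equal(ident$seqsim, 1.0)

  b <- sv_table("b", "chr1", 1000L, svtype = "DEL", svlen = 300L,
                seq = strrep("ACGT", 75))
  expect_false(sv_match(a, b, p)$matched)

  # 260/300 = 0.867 < 0.9 fails on size alone
  set.seed(1)
  c1 <- sv_table("c1", "chr1", 1000L, svtype = "INS", svlen = 260L,
                 seq = paste(sample(c("A", "C", "G", "T"), 260, TRUE), collapse = ""))
  c2 <- sv_table("c2", "chr1", 1100L, svtype = "INS", svlen = 300L,
                 seq = paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))
  m <- sv_match(c1, c2, p)
  expect_false(m$matched)
  expect_equal(m$sizesim, 260 / 300, tolerance = 1e-12)

  # symmetry over random pairs
  set.seed(2)
  recs <- random_calls(30)
  for (k in 1:40) {
    ij <- sample.int(30, 2)
    expect_equal(sv_match(recs[ij[1], ], recs[ij[2], ], p)$matched,
                 sv_match(recs[ij[2], ], recs[ij[1], ], p)$matched)
  }
})

test_that("matches are monotone in refdist", {
  set.seed(3)
  recs <- random_calls(60, max_pos = 2000)
  p1 <- match_params(pctseq = 0, refdist = 100)
  p2 <- match_params(pctseq = 0, refdist = 500)
  h1 <- match_any(recs, recs, p1)
  h2 <- match_any(recs, recs, p2)
  k1 <- paste(h1$qi, h1$si)
  k2 <- paste(h2$qi, h2$si)
  expect_true(all(k1 %in% k2))
})

test_that("callerset validation equals the all-pairs oracle", {
  p <- match_params(pctseq = 0)
  set.seed(4)
  primary <- random_calls(120, n_samples = 1)
  sup1 <- primary[sample.int(120, 60), , drop = FALSE]
  sup2 <- primary[sample.int(120, 60), , drop = FALSE]
  # jitter supporting callsets so matching is not purely identity
  sup1$start <- sup1$start + sample(-80:80, 60, TRUE)
  val <- validate_callersets(primary, list(a = sup1, b = sup2), p)
  orc <- oracle_match_any(primary, sup1, p) | oracle_match_any(primary, sup2, p)
  expect_setequal(val$sv_id, primary$sv_id[orc])

  expect_equal(nrow(validate_callersets(primary, list(a = primary[0, ]), p)), 0L)
  all_val <- validate_callersets(primary, list(a = primary), p)
  expect_setequal(all_val$sv_id, primary$sv_id)
})

test_that("blacklist exclusion equals the naive intersection oracle", {
  set.seed(5)
  svs <- random_calls(1000, max_pos = 1e6)
  bl <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                   start = s <- sample.int(1e6, 40),
                   end = s + sample(1000:50000, 40, TRUE))
  out <- exclude_blacklist(svs, bl)
  hit <- oracle_intersect(svs, bl)
  expect_setequal(out$sv_id, svs$sv_id[!hit])
  expect_equal(attr(out, "n_removed"), sum(hit))
  # empty blacklist is the identity
  out0 <- exclude_blacklist(svs, bl[0, ])
  expect_equal(nrow(out0), nrow(svs))
})

test_that("collapse merges shared alleles and keeps single samples intact", {
  p <- match_params()
  # one 300 bp INS in 5 samples within 50 bp -> one row, 5 genotypes
  seqv <- strrep("ACGT", 75)
  calls <- data.frame(sv_id = sprintf("v%d", 1:5), chrom = "chr1",
                      start = c(1000L, 1010L, 1020L, 1030L, 1050L),
                      svtype = "INS", svlen = 300L, seq = seqv, qual = 30,
                      caller = "assembly", sample = sprintf("s%d", 1:5),
                      gt = "het")
  calls$end <- calls$start
  tab <- collapse_cohort(calls, p)
  expect_equal(nrow(tab$svs), 1L)
  expect_equal(sum(tab$gt != "absent"), 5L)
  # single sample, already nonredundant: unchanged
  set.seed(6)
  one <- random_calls(20, n_samples = 1, max_pos = 1e6)
  t1 <- collapse_cohort(one, p)
  expect_equal(nrow(t1$svs), nrow(one))
  # unknown sample errors
  expect_error(collapse_cohort(one, p, samples = "other"), "unknown sample")
})

test_that("collapse partition equals the brute-force union-find oracle", {
  p <- match_params(pctseq = 0, pctsize = 0.9, refdist = 200)
  set.seed(7)
  for (trial in 1:8) {
    calls <- random_calls(100)
    tab <- collapse_cohort(calls, p)
    comp <- oracle_partition(calls, p)
    got <- unname(lapply(split(tab$members$sv_id, tab$members$row_id), sort))
    want <- unname(lapply(split(calls$sv_id, comp), sort))
    expect_setequal(got, want)
  }
})

test_that("collapse is idempotent and its output nonredundant", {
  p <- match_params(pctseq = 0, refdist = 300)
  set.seed(8)
  calls <- random_calls(200)
  tab <- collapse_cohort(calls, p)
  expect_true(is_nonredundant(tab))
  re <- tab$svs
  re$sample <- "s1"; re$gt <- "het"; re$qual <- 30; re$caller <- "x"
  tab2 <- collapse_cohort(re, p)
  expect_equal(nrow(tab2$svs), nrow(tab$svs))
  expect_equal(tab2$svs$start, tab$svs$start)
})
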