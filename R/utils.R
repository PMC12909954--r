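#' @importFrom stats rbinom rpois rbeta rlnorm runif rnorm setNames
#' @importFrom utils adist head tail
NULL

.datatable.aware <- TRUE

# data.table non-standard evaluation columns
utils::globalVariables(c("grp", "comp", "gt", "qual", "caller", "row",
                         ".N", "sample"))

# Genotype vocabulary used throughout: one call per (SV row, sample).
# "hemi" is the single-copy state of males on non-PAR chrX and on chrY.
GT_LEVELS <- c("absent", "het", "hom", "hemi", "missing")

#' Allele dosage of a genotype code
#'
#' @param gt character vector of genotype codes (`absent`, `het`, `hom`,
#'   `hemi`, `missing`).
#' @return integer dosage (0/1/2); `NA` for `missing`.
#' @export
gt_dosage <- function(gt) {
  d <- c(absent = 0L, het = 1L, hom = 2L, hemi = 1L, missing = NA_integer_)
  unname(d[gt])
}

#' Ploidy (allele number contributed) of a genotype code
#'
#' Hemizygous calls contribute one allele to allele-number tallies, diploid
#' calls two, missing calls none.
#'
#' @inheritParams gt_dosage
#' @return integer 0/1/2.
#' @export
gt_ploidy <- function(gt) {
  p <- c(absent = 2L, het = 2L, hom = 2L, hemi = 1L, missing = 0L)
  unname(p[gt])
}

gt_carrier <- function(gt) !is.na(gt) & gt %in% c("het", "hom", "hemi")

assert_gt <- function(gt) {
  bad <- setdiff(unique(gt), GT_LEVELS)
  if (length(bad)) stop("unknown genotype code(s): ", paste(bad, collapse = ", "))
  invisible(gt)
}

# round-half-up at `digits`; base round() is round-half-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

random_dna <- function(n) {
  vapply(n, function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                              collapse = ""), character(1))
}

#' Is a locus inside a pseudoautosomal region?
#'
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @param par data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), e.g. [sim_par_regions()].
#' @return logical vector.
#' @export
in_par <- function(chrom, pos, par) {
  if (is.null(par) || nrow(par) == 0) return(rep(FALSE, length(chrom)))
  out <- rep(FALSE, length(chrom))
  for (i in seq_len(nrow(par))) {
    out <- out | (chrom == par$chrom[i] & pos >= par$start[i] & pos < par$end[i])
  }
  out
}

#' Ploidy context of a locus for a given sex
#'
#' Returns "diploid", "haploid" (male non-PAR chrX/chrY) or "none" (chrY in
#' females). PAR loci are diploid in both sexes.
#'
#' @inheritParams in_par
#' @param sex "F"/"M" (scalar or vector).
#' @return character vector.
#' @export
locus_ploidy_class <- function(chrom, pos, sex, par = sim_par_regions()) {
  par_hit <- in_par(chrom, pos, par)
  ifelse(chrom == "chrX" & !par_hit & sex == "M", "haploid",
  ifelse(chrom == "chrY" & !par_hit, ifelse(sex == "M", "haploid", "none"),
         "diploid"))
}
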