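#' Per-sample burden count matrix
#'
#' Tallies rare-SV counts per child across burden categories: ALL, the SV
#' types DEL/INS, the functional classes EXON/INTRON/INTER, regulatory
#' flags REG/brainREG, NDD-gene proximity, and parental origin PAT/MAT
#' (requires resolved transmission). Categories whose source column is
#' absent from `rare` are filled with zeros.
#'
#' @param rare annotated long rare-SV table (one row per SV x child); uses
#'   columns `svtype`, `functional_class`, `reg`, `brainreg`, `near_ndd`,
#'   `transmission` when present.
#' @param samples children to report (rows of the matrix); zero rows are
#'   kept for children without rare SVs.
#' @return integer matrix samples x categories.
#' @export
per_sample_counts <- function(rare, samples) {
  cats <- c("ALL", "DEL", "INS", "EXON", "INTRON", "INTER", "REG",
            "brainREG", "NDD", "PAT", "MAT")
  m <- matrix(0L, length(samples), length(cats),
              dimnames = list(samples, cats))
  if (nrow(rare) == 0) return(m)
  tally <- function(mask) {
    t <- table(factor(rare$child[mask], levels = samples))
    as.integer(t)
  }
  m[, "ALL"] <- tally(rep(TRUE, nrow(rare)))
  m[, "DEL"] <- tally(rare$svtype == "DEL")
  m[, "INS"] <- tally(rare$svtype == "INS")
  if ("functional_class" %in% names(rare)) {
    for (fc in c("EXON", "INTRON", "INTER"))
      m[, fc] <- tally(rare$functional_class == fc)
  }
  if ("reg" %in% names(rare)) m[, "REG"] <- tally(rare$reg)
  if ("brainreg" %in% names(rare)) m[, "brainREG"] <- tally(rare$brainreg)
  if ("near_ndd" %in% names(rare)) m[, "NDD"] <- tally(rare$near_ndd)
  if ("transmission" %in% names(rare)) {
    m[, "PAT"] <- tally(!is.na(rare$transmission) & rare$transmission == "paternal")
    m[, "MAT"] <- tally(!is.na(rare$transmission) & rare$transmission == "maternal")
  }
  m
}

#' Chi-square burden comparison between two groups
#'
#' Builds the 2x2 table (events, sample slots) per group - i.e. rows
#' (events_a, n_a) and (events_b, n_b) - and applies the chi-square test
#' with optional Yates continuity correction. The odds ratio is
#' (a*d)/(b*c) with the Haldane-Anscombe 0.5 correction when any cell is
#' zero.
#'
#' @param events_a,n_a event count and sample count, group A (probands).
#' @param events_b,n_b likewise for group B (siblings).
#' @param yates apply the continuity correction (default TRUE).
#' @return list: `chi2`, `or`, `p`, `table`, `undefined`.
#' @export
chi2_burden <- function(events_a, n_a, events_b, n_b, yates = TRUE) {
  stopifnot(events_a >= 0, events_b >= 0, n_a >= 0, n_b >= 0)
  tab <- matrix(c(events_a, n_a, events_b, n_b), nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("events", "slots")))
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = NA_real_, or = NA_real_, p = NA_real_, table = tab,
                undefined = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  t2 <- tab
  if (any(t2 == 0)) t2 <- t2 + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(chi2 = unname(ct$statistic), or = unname(or),
       p = unname(ct$p.value), table = tab, undefined = FALSE)
}

# Mann-Whitney U of x over y with average ranks.
.mwu_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U burden comparison
#'
#' Normal-approximation Z with tie correction (Z > 0 means the first group
#' has higher counts) and the two-sided p. For small samples
#' (min(n) <= `exact_max`) the exact permutation p over all group
#' assignments is reported instead.
#'
#' @param x,y per-sample counts for the two groups (each nonempty).
#' @param exact_max exact enumeration threshold (default 8).
#' @return list: `z`, `p`, `u`, `exact` (whether p is the enumeration p).
#' @export
mwu_burden <- function(x, y, exact_max = 8) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  u <- .mwu_u(x, y)
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
  p_norm <- min(1, 2 * stats::pnorm(-abs(z)))
  if (min(n1, n2) <= exact_max && N <= 24) {
    v <- c(x, y)
    idx <- utils::combn(N, n1)
    obs <- abs(u - mu)
    us <- apply(idx, 2, function(k) .mwu_u(v[k], v[-k]))
    p_ex <- mean(abs(us - mu) >= obs - 1e-9)
    return(list(z = z, p = p_ex, u = u, exact = TRUE))
  }
  list(z = z, p = p_norm, u = u, exact = FALSE)
}

#' Multiple-testing adjustment
#'
#' @param p vector of p-values in \[0,1\].
#' @param method adjustment method (default Bonferroni: `min(1, m * p)`).
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = "bonferroni") {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = method)
}

#' Filtering-efficiency summary
#'
#' Percent of validated SVs per child excluded by control filtering:
#' `100 * (1 - rare / validated)`, rounded half-up to the nearest integer.
#'
#' @param per_child_validated_mean mean validated SVs per child.
#' @param per_child_rare_mean mean rare SVs per child after filtering.
#' @return list: `percent_excluded` (integer), `ratio` (rare/validated).
#' @export
filtering_efficiency_report <- function(per_child_validated_mean,
                                        per_child_rare_mean) {
  stopifnot(per_child_validated_mean > 0)
  ratio <- per_child_rare_mean / per_child_validated_mean
  list(percent_excluded = as.integer(round_half_up(100 * (1 - ratio))),
       ratio = ratio)
}

#' k-of-n percentage at fixed precision
#'
#' Generic ratio reporter for yields and overlap fractions.
#'
#' @param k numerator.
#' @param n denominator (> 0).
#' @param digits decimal places (default 1).
#' @return numeric percentage rounded half-up.
#' @export
ratio_pct <- function(k, n, digits = 1) {
  stopifnot(n > 0)
  round_half_up(100 * k / n, digits)
}
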