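#' Read alignment intervals from a PAF file
#'
#' Parses the 12 mandatory PAF columns; optional tags are ignored.
#'
#' @param path PAF file.
#' @return data.frame: `qname`, `qlen`, `qstart`, `qend`, `strand`,
#'   `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`.
#' @export
read_paf <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          select = 1:12, data.table = FALSE)
  names(df) <- c("qname", "qlen", "qstart", "qend", "strand", "tname",
                 "tlen", "tstart", "tend", "nmatch", "alen", "mapq")
  df
}

#' Window-based assembly contiguity scoring
#'
#' Tiles the chromosome into fixed windows, drops windows overlapping any
#' mask interval (PAR, centromere, heterochromatin), and qualifies a window
#' when the union of alignment blocks covers at least `min_overlap` of it
#' AND at most `max_contigs` distinct contigs overlap it. The coverage
#' fraction is qualified / total unmasked windows.
#'
#' @param alignments data.frame with `tname`, `tstart`, `tend`, `qname`
#'   (e.g. from [read_paf()]); secondary alignments are assumed removed.
#' @param chrom target chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param window window size in bp (default 1 Mbp).
#' @param min_overlap minimum covered fraction of a window (default 0.95).
#' @param max_contigs maximum distinct contigs overlapping a window
#'   (default 3).
#' @param masks optional data.frame (`chrom`, `start`, `end`) of excluded
#'   regions.
#' @return list: `windows` (per-window table: `start`, `end`, `masked`,
#'   `covered_frac`, `n_contigs`, `qualified`) and `fraction` (NA when no
#'   window survives masking).
#' @export
window_qualification <- function(alignments, chrom, chrom_length,
                                 window = 1e6, min_overlap = 0.95,
                                 max_contigs = 3, masks = NULL) {
  stopifnot(window > 0)
  n_win <- max(1L, floor(chrom_length / window))
  ws <- (seq_len(n_win) - 1) * window
  we <- pmin(ws + window, chrom_length)
  wr <- IRanges::IRanges(ws + 1L, we)
  masked <- rep(FALSE, n_win)
  if (!is.null(masks) && nrow(masks)) {
    mk <- masks[masks$chrom == chrom, , drop = FALSE]
    if (nrow(mk)) {
      masked <- IRanges::overlapsAny(wr, IRanges::IRanges(mk$start + 1L, mk$end))
    }
  }
  aln <- alignments[alignments$tname == chrom, , drop = FALSE]
  covered_frac <- numeric(n_win)
  n_contigs <- integer(n_win)
  if (nrow(aln)) {
    ar <- IRanges::IRanges(aln$tstart + 1L, aln$tend)
    hits <- IRanges::findOverlaps(wr, ar)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      pairs <- unique(data.frame(w = qh, q = aln$qname[sh]))
      n_contigs <- as.integer(table(factor(pairs$w, levels = seq_len(n_win))))
      for (w in unique(qh)) {
        blocks <- IRanges::restrict(ar[sh[qh == w]],
                                    start = ws[w] + 1L, end = we[w])
        covered_frac[w] <- sum(IRanges::width(IRanges::reduce(blocks))) /
          (we[w] - ws[w])
      }
    }
  }
  qualified <- !masked & covered_frac >= min_overlap & n_contigs <= max_contigs
  windows <- data.frame(start = ws, end = we, masked = masked,
                        covered_frac = covered_frac, n_contigs = n_contigs,
                        qualified = qualified)
  n_unmasked <- sum(!masked)
  fraction <- if (n_unmasked == 0) NA_real_ else sum(qualified) / n_unmasked
  list(windows = windows, fraction = fraction)
}

#' Read a bedMethyl-like methylation table
#'
#' Accepts either the minimal 5-column layout (`chrom`, `start`, `end`,
#' `coverage`, `pct`) or the 18-column modkit pileup layout (coverage in
#' column 10, percent methylated in column 11). The percent column is
#' auto-detected as 0-1 versus 0-100 and returned on the 0-1 scale.
#'
#' @param path bedMethyl file.
#' @return data.frame: `chrom`, `start`, `end`, `coverage`, `meth` (0-1).
#' @export
read_bedmethyl <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(df) >= 11) {
    out <- df[, c(1, 2, 3, 10, 11)]
  } else if (ncol(df) >= 5) {
    out <- df[, 1:5]
  } else stop("unrecognized bedMethyl layout: ", ncol(df), " columns")
  names(out) <- c("chrom", "start", "end", "coverage", "meth")
  if (max(out$meth, na.rm = TRUE) > 1) out$meth <- out$meth / 100
  out
}

#' X-inactivation skew from haplotype-resolved CpG-island methylation
#'
#' For every CpG island (extended by `flank` on each side), computes the
#' mean methylation per haplotype over CpGs with coverage >= `min_cov`;
#' aggregates to a genome-wide haplotype mean (unweighted over islands with
#' usable CpGs on both haplotypes) and reports the skew index
#' `hap_mean_mat - hap_mean_pat`. A positive index (maternal haplotype more
#' methylated) indicates preferential inactivation of the maternal X.
#'
#' @param meth_mat,meth_pat methylation tables (data.frames as returned by
#'   [read_bedmethyl()], or paths).
#' @param islands data.frame (`chrom`, `start`, `end`) of CpG islands.
#' @param flank flanking bp added on both sides (default 5000).
#' @param min_cov minimum CpG coverage (default 5).
#' @param skew_threshold |skew index| at or above which the sample is
#'   called skewed (default 0.20).
#' @param sample optional sample label.
#' @return list: `per_island` (data.frame with per-haplotype means and CpG
#'   counts) and `skew` (one-row data.frame: `sample`, `islands_used`,
#'   `hap_mean_mat`, `hap_mean_pat`, `skew_index`, `classification`,
#'   `islands_excluded`).
#' @export
xci_skew <- function(meth_mat, meth_pat, islands, flank = 5000, min_cov = 5,
                     skew_threshold = 0.20, sample = NA_character_) {
  norm_meth <- function(x) {
    if (is.character(x)) return(read_bedmethyl(x))
    if (!"meth" %in% names(x) && "pct" %in% names(x)) x$meth <- x$pct
    if (max(x$meth, na.rm = TRUE) > 1) x$meth <- x$meth / 100
    x
  }
  meth_mat <- norm_meth(meth_mat)
  meth_pat <- norm_meth(meth_pat)
  ir <- IRanges::IRanges(pmax(0, islands$start - flank) + 1L,
                         islands$end + flank)
  island_means <- function(meth) {
    m <- meth[meth$coverage >= min_cov, , drop = FALSE]
    mr <- IRanges::IRanges(m$start + 1L, m$end)
    hits <- IRanges::findOverlaps(ir, mr)
    qh <- S4Vectors::queryHits(hits)
    val <- m$meth[S4Vectors::subjectHits(hits)]
    mean_v <- tapply(val, factor(qh, levels = seq_len(nrow(islands))), mean)
    n_v <- tapply(val, factor(qh, levels = seq_len(nrow(islands))), length)
    list(mean = as.numeric(mean_v), n = ifelse(is.na(n_v), 0L, as.integer(n_v)))
  }
  mm <- island_means(meth_mat)
  pp <- island_means(meth_pat)
  per_island <- data.frame(chrom = islands$chrom, start = islands$start,
                           end = islands$end,
                           mean_meth_maternal = mm$mean,
                           mean_meth_paternal = pp$mean,
                           n_cpg_mat = mm$n, n_cpg_pat = pp$n)
  used <- per_island$n_cpg_mat > 0 & per_island$n_cpg_pat > 0
  hm <- mean(per_island$mean_meth_maternal[used])
  hp <- mean(per_island$mean_meth_paternal[used])
  skew_index <- hm - hp
  classification <- if (!sum(used)) NA_character_
    else if (skew_index >= skew_threshold) "skewed_maternal_inactive"
    else if (skew_index <= -skew_threshold) "skewed_paternal_inactive"
    else "balanced"
  list(per_island = per_island,
       skew = data.frame(sample = sample, islands_used = sum(used),
                         hap_mean_mat = hm, hap_mean_pat = hp,
                         skew_index = skew_index,
                         classification = classification,
                         islands_excluded = sum(!used)))
}
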