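.sv_granges <- function(svs) {
  # insertions are intersected as 1 bp points at the insertion coordinate
  GenomicRanges::GRanges(svs$chrom,
    IRanges::IRanges(svs$start + 1L, pmax(svs$end, svs$start + 1L)))
}

.track_granges <- function(track) {
  GenomicRanges::GRanges(track$chrom, IRanges::IRanges(track$start + 1L, track$end))
}

#' Intersect SVs with annotation tracks
#'
#' Any-overlap (>= 1 bp) semantics; insertions count as points at the
#' insertion coordinate. For a track carrying a `value` column (constraint
#' scores), the maximum value over overlapped intervals is reported.
#'
#' @param svs SV table.
#' @param tracks named list of interval data.frames (`chrom`, `start`,
#'   `end`, optional `value`).
#' @return data.frame: `sv_id`, one logical flag column per track, and
#'   `<name>_max` for tracks with values.
#' @export
intersect_tracks <- function(svs, tracks) {
  out <- data.frame(sv_id = svs$sv_id, stringsAsFactors = FALSE)
  if (nrow(svs) == 0) {
    for (nm in names(tracks)) out[[nm]] <- logical(0)
    return(out)
  }
  g <- .sv_granges(svs)
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    if (is.null(tr) || nrow(tr) == 0) {
      out[[nm]] <- rep(FALSE, nrow(svs))
      next
    }
    tg <- .track_granges(tr)
    # disjoint chromosome sets between SVs and a track are routine, not an
    # anomaly worth a seqlevel warning
    out[[nm]] <- suppressWarnings(IRanges::overlapsAny(g, tg))
    if ("value" %in% names(tr)) {
      hits <- suppressWarnings(GenomicRanges::findOverlaps(g, tg))
      mx <- rep(NA_real_, nrow(svs))
      if (length(hits)) {
        agg <- tapply(tr$value[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits), max)
        mx[as.integer(names(agg))] <- as.numeric(agg)
      }
      out[[paste0(nm, "_max")]] <- mx
    }
  }
  out
}

#' Functional category of each SV relative to a gene model
#'
#' `EXON` when overlapping any exon or UTR interval, else `INTRON` when
#' inside a gene span, else `INTER`; precedence EXON > INTRON > INTER (an SV
#' intronic in one gene but exonic in another is EXON).
#'
#' @param svs SV table.
#' @param gene_model list with `genes` (spans + flags) and `exons`
#'   data.frames; an optional `utrs` data.frame is treated like exons.
#' @return character vector of categories, one per SV.
#' @export
functional_category <- function(svs, gene_model) {
  if (nrow(svs) == 0) return(character(0))
  g <- .sv_granges(svs)
  ex <- gene_model$exons
  if (!is.null(gene_model$utrs)) {
    ex <- rbind(ex[, c("chrom", "start", "end")],
                gene_model$utrs[, c("chrom", "start", "end")])
  }
  exonic <- suppressWarnings(IRanges::overlapsAny(g, .track_granges(ex)))
  genic <- suppressWarnings(IRanges::overlapsAny(g, .track_granges(gene_model$genes)))
  ifelse(exonic, "EXON", ifelse(genic, "INTRON", "INTER"))
}

#' Gain in annotated SVs from adding a second annotation source
#'
#' @param flags data.frame of logical flag columns (from
#'   [intersect_tracks()]).
#' @param base_class,added_class column names.
#' @return list: `n_base` (SVs flagged by the base source), `n_added_only`
#'   (flagged by the added source but not the base), `percent_increase`
#'   (100 * n_added_only / n_base, rounded to the nearest integer).
#' @export
annotation_gain <- function(flags, base_class, added_class) {
  base <- flags[[base_class]]
  added <- flags[[added_class]]
  n_base <- sum(base)
  n_added_only <- sum(added & !base)
  list(n_base = n_base, n_added_only = n_added_only,
       percent_increase = as.integer(round_half_up(100 * n_added_only / n_base)))
}

# Genes whose span (plus flank) an SV touches.
.genes_near <- function(svs, genes, flank = 0) {
  g <- .sv_granges(svs)
  gg <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(pmax(0L, genes$start - flank) + 1L, genes$end + flank))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(g, gg))
  split(genes$gene[S4Vectors::subjectHits(hits)],
        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(svs))))
}

#' Rank candidate pathogenic SVs
#'
#' Applies three rule groups to an annotated rare-SV table:
#' \itemize{
#'   \item A: de novo AND (exonic in an NDD-flagged gene OR regulatory /
#'     brain-regulatory / TF-cluster overlap near a risk gene);
#'   \item B: private biallelic homozygous AND (in/near a SFARI-flagged gene
#'     OR regulatory / brain-regulatory overlap);
#'   \item C: any rare SV with constraint-score maximum >= `gnocchi_min`
#'     AND a promoter overlap.
#' }
#' "Near" means within the gene span or `flank` bp of it.
#'
#' @param rare annotated rare-SV table: origin plus flag columns `reg`,
#'   `brainreg`, `tf`, `promoters`, `gnocchi_max`, and `functional_class`.
#' @param gene_model gene model list (`genes` with `ndd`, `sfari` flags).
#' @param flank risk-gene linking distance in bp (default 50 kbp).
#' @param gnocchi_min constraint threshold for rule C (default 4).
#' @return subset of `rare` with `rules` (comma-separated rule trail) and
#'   `genes` columns, ordered A < B < C by strongest rule.
#' @export
prioritize <- function(rare, gene_model, flank = 5e4, gnocchi_min = 4) {
  if (nrow(rare) == 0) {
    rare$rules <- character(0); rare$genes <- character(0)
    return(rare)
  }
  genes <- gene_model$genes
  near <- .genes_near(rare, genes, flank)
  ndd_genes <- genes$gene[genes$ndd]
  sfari_genes <- genes$gene[!is.na(genes$sfari)]
  near_ndd <- vapply(near, function(g) any(g %in% ndd_genes), logical(1))
  near_sfari <- vapply(near, function(g) any(g %in% sfari_genes), logical(1))
  reg_any <- rare$reg | rare$brainreg
  ruleA <- rare$origin == "DENOVO" &
    ((rare$functional_class == "EXON" & near_ndd) |
       ((reg_any | rare$tf) & (near_ndd | near_sfari)))
  ruleB <- rare$origin == "PRIVATE_BIALLELIC_HOM" & (near_sfari | reg_any)
  gmax <- rare$gnocchi_max
  ruleC <- !is.na(gmax) & gmax >= gnocchi_min & rare$promoters
  any_rule <- ruleA | ruleB | ruleC
  out <- rare[any_rule, , drop = FALSE]
  trail <- cbind(A = ruleA, B = ruleB, C = ruleC)[any_rule, , drop = FALSE]
  out$rules <- apply(trail, 1, function(z) paste(colnames(trail)[z], collapse = ","))
  out$genes <- vapply(near[any_rule], paste, character(1), collapse = ",")
  out <- out[order(out$rules), , drop = FALSE]
  rownames(out) <- NULL
  out
}
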