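#' Construct matching parameters for SV comparison
#'
#' The defaults reproduce the stringent intra-cohort collapse settings
#' (sequence similarity 0.90, size similarity 0.90, breakpoint distance
#' 500 bp). The relaxed cross-platform comparison corresponds to
#' `match_params(pctseq = 0, pctsize = 0.5, pctovl = 0.5)`.
#'
#' @param pctseq minimum normalized sequence similarity in \[0,1\]; 0 disables
#'   sequence comparison.
#' @param pctsize minimum size similarity `min(svlen)/max(svlen)`.
#' @param refdist maximum breakpoint (start) distance in bp.
#' @param pctovl minimum reciprocal overlap of the reference spans, or `NULL`
#'   to disable. Insertions are treated as satisfying overlap when their
#'   breakpoints are within `refdist`.
#' @param sizemin,sizemax SV length bounds; records outside are not compared.
#' @return list of class `match_params`.
#' @export
match_params <- function(pctseq = 0.9, pctsize = 0.9, refdist = 500,
                         pctovl = NULL, sizemin = 50, sizemax = 1e6) {
  stopifnot(pctseq >= 0, pctseq <= 1, pctsize >= 0, pctsize <= 1,
            refdist >= 0, sizemin <= sizemax)
  if (!is.null(pctovl)) stopifnot(pctovl >= 0, pctovl <= 1)
  structure(list(pctseq = pctseq, pctsize = pctsize, refdist = refdist,
                 pctovl = pctovl, sizemin = sizemin, sizemax = sizemax),
            class = "match_params")
}

#' Construct and validate a table of SV records
#'
#' Coordinates are 0-based half-open; `end == start` for insertions;
#' `end - start == svlen` for deletions and inversions. `seq` holds the
#' inserted sequence (INS) or the deleted reference sequence (DEL) and may be
#' `NA` (symbolic records).
#'
#' @param sv_id,chrom,start,end,svtype,svlen,seq,qual,caller column vectors;
#'   recycled where length 1.
#' @return data.frame with one row per SV.
#' @export
sv_table <- function(sv_id, chrom, start, end = NULL, svtype, svlen,
                     seq = NA_character_, qual = NA_real_, caller = NA_character_) {
  n <- length(sv_id)
  chrom <- rep_len(chrom, n)
  start <- rep_len(start, n)
  svtype <- rep_len(svtype, n)
  svlen <- rep_len(svlen, n)
  if (is.null(end)) end <- ifelse(svtype == "INS", start, start + svlen)
  df <- data.frame(sv_id = as.character(sv_id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   svtype = as.character(svtype), svlen = as.integer(svlen),
                   seq = rep_len(as.character(seq), n),
                   qual = rep_len(as.numeric(qual), n),
                   caller = rep_len(as.character(caller), n),
                   stringsAsFactors = FALSE)
  validate_sv_table(df)
}

#' @rdname sv_table
#' @param df data.frame to validate.
#' @export
validate_sv_table <- function(df) {
  need <- c("sv_id", "chrom", "start", "end", "svtype", "svlen")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sv table missing column(s): ", paste(miss, collapse = ", "))
  if (!"seq" %in% names(df)) df$seq <- NA_character_
  if (!"qual" %in% names(df)) df$qual <- NA_real_
  if (!"caller" %in% names(df)) df$caller <- NA_character_
  if (nrow(df) == 0) return(df)
  if (any(!df$svtype %in% c("INS", "DEL", "INV")))
    stop("svtype must be one of INS, DEL, INV")
  if (any(df$end < df$start)) stop("end < start")
  if (any(df$svlen < 1)) stop("svlen must be positive")
  span <- df$svtype != "INS"
  if (any(df$end[span] - df$start[span] != df$svlen[span]))
    stop("DEL/INV records must satisfy end - start == svlen")
  df
}

# Normalized Levenshtein similarity: 1 - editdist / max(length).
seq_similarity <- function(a, b) {
  ifelse(is.na(a) | is.na(b), NA_real_,
         ifelse(a == b, 1,
                1 - mapply(function(x, y) adist(x, y)[1, 1], a, b) /
                  pmax(nchar(a), nchar(b))))
}

# Vectorized match evaluation for index pairs (i, j) into `df`.
# Returns a data.frame of the decision components per pair.
.match_eval <- function(df, i, j, p) {
  n <- length(i)
  if (n == 0) {
    return(data.frame(matched = logical(0), sizesim = numeric(0),
                      seqsim = numeric(0), dist = integer(0), ovl = numeric(0)))
  }
  dist <- abs(df$start[i] - df$start[j])
  sizesim <- pmin(df$svlen[i], df$svlen[j]) / pmax(df$svlen[i], df$svlen[j])
  ok <- df$svtype[i] == df$svtype[j] & df$chrom[i] == df$chrom[j] &
    dist <= p$refdist & sizesim >= p$pctsize
  ovl <- rep(NA_real_, n)
  if (!is.null(p$pctovl)) {
    ins <- df$svtype[i] == "INS"
    shared <- pmax(0, pmin(df$end[i], df$end[j]) - pmax(df$start[i], df$start[j]))
    w <- pmax(df$end[i] - df$start[i], df$end[j] - df$start[j])
    ovl <- ifelse(ins, ifelse(dist <= p$refdist, 1, 0),
                  ifelse(w > 0, shared / w, 0))
    ok <- ok & ovl >= p$pctovl
  }
  seqsim <- rep(NA_real_, n)
  if (p$pctseq > 0) {
    # sequence comparison applies to INS/DEL only; inverted-sequence
    # comparison is undefined, so INV records match on size + position alone
    cand <- which(ok & df$svtype[i] != "INV")
    if (length(cand)) {
      s <- seq_similarity(df$seq[i[cand]], df$seq[j[cand]])
      seqsim[cand] <- s
      # records lacking sequence fall back to size-only matching
      fail <- !is.na(s) & s < p$pctseq
      ok[cand[fail]] <- FALSE
    }
  }
  data.frame(matched = ok, sizesim = sizesim, seqsim = seqsim,
             dist = dist, ovl = ovl)
}

#' Pairwise SV match decision
#'
#' Two records match when they share `svtype` and `chrom`, their start
#' positions are within `refdist`, their size similarity reaches `pctsize`,
#' their sequence similarity reaches `pctseq` (when enabled and both
#' sequences are present; inversions and sequence-less records fall back to
#' size-only matching) and, when `pctovl` is enabled, their reference spans
#' reciprocally overlap by at least `pctovl`. The decision is symmetric.
#'
#' @param a,b one-row data.frames as produced by [sv_table()].
#' @param p a [match_params()] object.
#' @return list with `matched`, `sizesim`, `seqsim`, `dist`, `ovl`.
#' @export
sv_match <- function(a, b, p = match_params()) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  df <- rbind(a[, c("sv_id", "chrom", "start", "end", "svtype", "svlen", "seq")],
              b[, c("sv_id", "chrom", "start", "end", "svtype", "svlen", "seq")])
  if (any(df$svlen < p$sizemin | df$svlen > p$sizemax))
    return(list(matched = FALSE, sizesim = NA_real_, seqsim = NA_real_,
                dist = NA_integer_, ovl = NA_real_))
  as.list(.match_eval(df, 1L, 2L, p))
}

#' Find all matches of query records in a subject callset
#'
#' @param query,subject SV tables.
#' @param p a [match_params()] object.
#' @return data.frame with columns `qi`, `si`: row indices of matched pairs.
#' @export
match_any <- function(query, subject, p = match_params()) {
  no <- data.frame(qi = integer(0), si = integer(0))
  qok <- which(query$svlen >= p$sizemin & query$svlen <= p$sizemax)
  sok <- which(subject$svlen >= p$sizemin & subject$svlen <= p$sizemax)
  if (!length(qok) || !length(sok)) return(no)
  out <- vector("list", 0)
  for (ch in intersect(unique(query$chrom[qok]), unique(subject$chrom[sok]))) {
    qi <- qok[query$chrom[qok] == ch]
    si <- sok[subject$chrom[sok] == ch]
    si <- si[order(subject$start[si])]
    ss <- subject$start[si]
    lo <- findInterval(query$start[qi] - p$refdist - 0.5, ss) + 1L
    hi <- findInterval(query$start[qi] + p$refdist + 0.5, ss)
    keep <- which(hi >= lo)
    if (!length(keep)) next
    reps <- hi[keep] - lo[keep] + 1L
    qq <- rep(qi[keep], reps)
    jj <- si[unlist(mapply(seq, lo[keep], hi[keep], SIMPLIFY = FALSE))]
    both <- rbind(query[, c("sv_id", "chrom", "start", "end", "svtype", "svlen", "seq")],
                  subject[, c("sv_id", "chrom", "start", "end", "svtype", "svlen", "seq")])
    ev <- .match_eval(both, match(qq, seq_len(nrow(query))),
                      nrow(query) + jj, p)
    hit <- ev$matched
    if (any(hit)) out[[length(out) + 1L]] <- data.frame(qi = qq[hit], si = jj[hit])
  }
  if (!length(out)) return(no)
  unique(do.call(rbind, out))
}

#' Validate a primary callset against supporting callsets
#'
#' A primary (assembly-based) record is validated when at least one record in
#' at least one supporting (alignment-based) callset matches it under `p`.
#'
#' @param primary SV table from the primary caller.
#' @param supporting named list of SV tables from supporting callers.
#' @param p a [match_params()] object.
#' @return the validated subset of `primary` with a `support` column listing
#'   the supporting caller names (comma-separated).
#' @export
validate_callersets <- function(primary, supporting, p = match_params()) {
  if (!length(supporting)) stop("at least one supporting callset is required")
  if (is.null(names(supporting)))
    names(supporting) <- paste0("caller", seq_along(supporting))
  if (nrow(primary) == 0) {
    primary$support <- character(0)
    return(primary)
  }
  sup <- matrix(FALSE, nrow(primary), length(supporting),
                dimnames = list(NULL, names(supporting)))
  for (k in seq_along(supporting)) {
    hits <- match_any(primary, supporting[[k]], p)
    sup[unique(hits$qi), k] <- TRUE
  }
  keep <- rowSums(sup) > 0
  out <- primary[keep, , drop = FALSE]
  out$support <- apply(sup[keep, , drop = FALSE], 1,
                       function(z) paste(colnames(sup)[z], collapse = ","))
  rownames(out) <- NULL
  out
}

#' Remove SVs intersecting blacklisted regions
#'
#' Drops any SV whose reference footprint `[start, max(end, start + 1))`
#' (insertions count as 1 bp points) overlaps a blacklist interval such as
#' assembly gaps, telomeres or centromeres.
#'
#' @param svs SV table.
#' @param blacklist data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return filtered SV table; the number of removals is available as
#'   `attr(, "n_removed")`.
#' @export
exclude_blacklist <- function(svs, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0 || nrow(svs) == 0) {
    attr(svs, "n_removed") <- 0L
    return(svs)
  }
  g <- GenomicRanges::GRanges(svs$chrom,
    IRanges::IRanges(svs$start + 1L, pmax(svs$end, svs$start + 1L)))
  b <- GenomicRanges::GRanges(blacklist$chrom,
    IRanges::IRanges(blacklist$start + 1L, blacklist$end))
  hit <- suppressWarnings(IRanges::overlapsAny(g, b))
  out <- svs[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  out
}

# --- cohort-wide collapse -------------------------------------------------

# Minimal iterative union-find.
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}
.uf_union <- function(parent, a, b) {
  ra <- .uf_find(parent, a); rb <- .uf_find(parent, b)
  if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  parent
}

# Edges between sorted-by-start record indices within refdist, evaluated
# under the match criteria; returns data.frame(i, j) of matched pairs.
.collapse_edges <- function(df, p, het_rule = TRUE, sample = NULL, gt = NULL) {
  out <- vector("list", 0)
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    idx <- idx[order(df$start[idx])]
    st <- df$start[idx]
    hi <- findInterval(st + p$refdist + 0.5, st)
    k <- which(hi > seq_along(idx))
    if (!length(k)) next
    reps <- hi[k] - k
    ii <- rep(k, reps)
    jj <- unlist(mapply(function(a, b) seq(a + 1L, b), k, hi[k], SIMPLIFY = FALSE))
    ev <- .match_eval(df, idx[ii], idx[jj], p)
    hit <- ev$matched
    if (het_rule && !is.null(sample) && any(hit)) {
      # never merge two heterozygous calls of the same sample directly
      a <- idx[ii][hit]; b <- idx[jj][hit]
      forbid <- sample[a] == sample[b] & gt[a] == "het" & gt[b] == "het"
      keep <- which(hit)[!forbid]
      hit <- rep(FALSE, length(hit)); hit[keep] <- TRUE
    }
    if (any(hit)) out[[length(out) + 1L]] <- data.frame(i = idx[ii][hit], j = idx[jj][hit])
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0)))
  do.call(rbind, out)
}

#' Collapse per-sample callsets into a nonredundant cohort table
#'
#' All records are partitioned into connected components under the pairwise
#' match relation (edges restricted to records whose starts lie within
#' `refdist`); each component is reported as one representative row with a
#' genotype matrix over all declared samples. Exact duplicate alleles (same
#' chrom/start/type/length/sequence) are grouped before pairwise evaluation;
#' this does not change the partition because identical records always match.
#'
#' @param calls data.frame of per-sample calls: SV columns as in [sv_table()]
#'   plus `sample` and `gt` (genotype codes).
#' @param p a [match_params()] object.
#' @param keep representative choice: `"common"` (allele observed in most
#'   samples), `"maxqual"` (highest qual) or `"first"` (leftmost); ties break
#'   leftmost then lexicographic `sv_id`.
#' @param samples declared sample set (columns of the genotype matrix);
#'   defaults to the samples present in `calls`. Unknown samples in `calls`
#'   are an error.
#' @return object of class `cohort_sv_table`: list with `svs` (representative
#'   rows, sorted), `gt` (rows x samples genotype matrix), `support` (long
#'   data.frame of per-cell caller support), `members` (input record to
#'   output row mapping), `params`, `log`.
#' @export
collapse_cohort <- function(calls, p = match_params(), keep = c("common", "maxqual", "first"),
                            samples = NULL) {
  keep <- match.arg(keep)
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  bad <- setdiff(unique(calls$sample), samples)
  if (length(bad)) stop("unknown sample(s) in callset: ", paste(bad, collapse = ", "))
  calls <- validate_sv_table(as.data.frame(calls))
  if (!"gt" %in% names(calls)) calls$gt <- "het"
  assert_gt(calls$gt)
  calls <- calls[calls$svlen >= p$sizemin & calls$svlen <= p$sizemax, , drop = FALSE]
  if (nrow(calls) == 0) {
    gt <- matrix(character(0), 0, length(samples), dimnames = list(NULL, samples))
    return(structure(list(svs = calls, gt = gt,
                          support = data.frame(row_id = character(0), sample = character(0),
                                               callers = character(0)),
                          params = p, keep = keep, log = list(n_gt_conflicts = 0L)),
                     class = "cohort_sv_table"))
  }
  key <- paste(calls$chrom, calls$start, calls$svtype, calls$svlen,
               ifelse(is.na(calls$seq), "", calls$seq), sep = "\r")
  grp <- match(key, unique(key))
  first_of <- match(seq_len(max(grp)), grp)
  ua <- calls[first_of, c("sv_id", "chrom", "start", "end", "svtype", "svlen", "seq"), drop = FALSE]

  # group-level het-only bookkeeping for the same-sample het/het edge rule
  gdt <- data.table::data.table(grp = grp, sample = calls$sample, gt = calls$gt)
  ginfo <- gdt[, list(n_samp = data.table::uniqueN(sample),
                      one_samp = sample[1L],
                      all_het = all(gt == "het")), by = "grp"]
  data.table::setkey(ginfo, grp)
  edges <- .collapse_edges(ua, p, het_rule = FALSE)
  if (nrow(edges)) {
    a <- ginfo[edges$i]; b <- ginfo[edges$j]
    forbid <- a$n_samp == 1L & b$n_samp == 1L & a$one_samp == b$one_samp &
      a$all_het & b$all_het
    edges <- edges[!forbid, , drop = FALSE]
  }
  parent <- .uf_new(nrow(ua))
  for (e in seq_len(nrow(edges))) parent <- .uf_union(parent, edges$i[e], edges$j[e])
  root <- vapply(seq_len(nrow(ua)), function(x) .uf_find(parent, x), integer(1))
  comp <- match(root, unique(root))           # component id per allele group
  rec_comp <- comp[grp]                        # per record

  # representative per component
  dt <- data.table::data.table(rec = seq_len(nrow(calls)), comp = rec_comp, grp = grp,
                               sample = calls$sample, gt = calls$gt,
                               qual = calls$qual, start = calls$start,
                               sv_id = calls$sv_id, caller = calls$caller)
  n_samp_grp <- gdt[, list(ns = data.table::uniqueN(sample)), by = "grp"]$ns
  rep_grp <- integer(max(comp))
  for (cid in seq_len(max(comp))) {
    gs <- which(comp == cid)
    if (keep == "common") {
      sc <- n_samp_grp[gs]
      gs2 <- gs[sc == max(sc)]
    } else if (keep == "maxqual") {
      q <- vapply(gs, function(g) {
        qq <- calls$qual[grp == g]
        if (all(is.na(qq))) -Inf else max(qq, na.rm = TRUE)
      }, numeric(1))
      gs2 <- gs[q == max(q)]
    } else gs2 <- gs
    o <- order(ua$start[gs2], ua$sv_id[gs2])
    rep_grp[cid] <- gs2[o[1L]]
  }
  svs <- ua[rep_grp, , drop = FALSE]
  svs$sv_id <- make.unique(svs$sv_id, sep = "_dup")
  ord <- order(svs$chrom, svs$start, svs$sv_id)
  svs <- svs[ord, , drop = FALSE]
  row_of_comp <- match(seq_len(max(comp)), ord)  # component id -> output row
  rownames(svs) <- NULL

  # genotype matrix: per (component, sample) the non-missing genotype of the
  # highest-qual constituent; differing non-missing genotypes are logged
  dt[, row := row_of_comp[comp]]
  cell <- dt[, {
    g <- gt[gt != "missing"]
    q <- qual[gt != "missing"]
    if (!length(g)) list(gt = "missing", conflict = FALSE)
    else {
      o <- order(-ifelse(is.na(q), -Inf, q))
      list(gt = g[o[1L]], conflict = length(unique(g)) > 1L)
    }
  }, by = c("row", "sample")]
  gt <- matrix("absent", nrow(svs), length(samples),
               dimnames = list(svs$sv_id, samples))
  gt[cbind(cell$row, match(cell$sample, samples))] <- cell$gt
  supp <- dt[!is.na(caller),
             list(callers = paste(sort(unique(caller)), collapse = ",")),
             by = c("row", "sample")]
  support <- data.frame(row_id = svs$sv_id[supp$row], sample = supp$sample,
                        callers = supp$callers, stringsAsFactors = FALSE)
  members <- data.frame(row_id = svs$sv_id[dt$row], sv_id = dt$sv_id,
                        sample = dt$sample, stringsAsFactors = FALSE)
  structure(list(svs = svs, gt = gt, support = support, members = members,
                 params = p, keep = keep,
                 log = list(n_gt_conflicts = sum(cell$conflict))),
            class = "cohort_sv_table")
}

#' @export
print.cohort_sv_table <- function(x, ...) {
  cat("cohort_sv_table:", nrow(x$svs), "nonredundant SVs x",
      ncol(x$gt), "samples\n")
  invisible(x)
}

#' Verify that no two rows of a cohort table match
#'
#' @param table a `cohort_sv_table`.
#' @param p matching parameters; defaults to the table's own.
#' @return TRUE/FALSE.
#' @export
is_nonredundant <- function(table, p = table$params) {
  # the same-sample het/het edge exclusion means two het calls of one sample
  # may legitimately remain as matching rows; check the unconstrained pairs
  df <- table$svs
  if (nrow(df) < 2) return(TRUE)
  edges <- .collapse_edges(df, p, het_rule = FALSE)
  if (nrow(edges) == 0) return(TRUE)
  gtm <- table$gt
  ok <- vapply(seq_len(nrow(edges)), function(e) {
    gi <- gtm[edges$i[e], ]; gj <- gtm[edges$j[e], ]
    any(gi == "het" & gj == "het")
  }, logical(1))
  all(ok)
}

# --- VCF I/O --------------------------------------------------------------

.parse_info <- function(info) {
  out <- list()
  for (kv in strsplit(info, ";", fixed = TRUE)[[1]]) {
    p <- strsplit(kv, "=", fixed = TRUE)[[1]]
    out[[p[1]]] <- if (length(p) > 1) p[2] else TRUE
  }
  out
}

.gt_from_string <- function(g, allele) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
  al <- strsplit(g, "[/|]")[[1]]
  if (any(al == ".")) return("missing")
  k <- sum(al == as.character(allele))
  if (length(al) == 1L) return(if (k == 1L) "hemi" else "absent")
  c("absent", "het", "hom")[k + 1L]
}

#' Read SVs from a VCF file
#'
#' Parses SVTYPE/SVLEN/END from INFO (or reconstructs them from REF/ALT),
#' splits multiallelic records into biallelic rows and converts coordinates
#' to the package's 0-based convention (`start = POS - 1`). Records with
#' neither an SVLEN nor an ALT/REF sequence are skipped with a warning.
#'
#' @param path VCF file (plain or bgzipped).
#' @param caller optional caller label stored in the `caller` column.
#' @return list with `svs` (SV table) and `gt` (genotype matrix rows x
#'   samples, or NULL when the VCF has no sample columns); the number of
#'   skipped records is in `attr(, "n_skipped")`.
#' @export
read_sv_vcf <- function(path, caller = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gtm_raw <- if (ncol(v@gt) > 1) vcfR::extract.gt(v, element = "GT") else NULL
  rows <- vector("list", 0)
  gts <- vector("list", 0)
  n_skipped <- 0L
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    info <- .parse_info(v@fix[r, "INFO"])
    svtypes <- if (!is.null(info$SVTYPE)) strsplit(info$SVTYPE, ",")[[1]] else NULL
    svlens <- if (!is.null(info$SVLEN)) as.integer(strsplit(info$SVLEN, ",")[[1]]) else NULL
    ref <- fix[r, "REF"]
    pos <- as.integer(fix[r, "POS"])
    for (k in seq_along(alts)) {
      alt <- alts[k]
      symbolic <- grepl("^<", alt)
      svtype <- if (!is.null(svtypes)) svtypes[min(k, length(svtypes))] else NULL
      svlen <- if (!is.null(svlens)) abs(svlens[min(k, length(svlens))]) else NULL
      seqs <- NA_character_
      if (symbolic) {
        if (is.null(svtype)) svtype <- gsub("[<>]", "", alt)
        if (is.null(svlen)) { n_skipped <- n_skipped + 1L; next }
      } else {
        if (nchar(alt) > nchar(ref)) {
          if (is.null(svtype)) svtype <- "INS"
          seqs <- substring(alt, nchar(ref) + 1L)
        } else if (nchar(ref) > nchar(alt)) {
          if (is.null(svtype)) svtype <- "DEL"
          seqs <- substring(ref, nchar(alt) + 1L)
        } else {
          n_skipped <- n_skipped + 1L; next
        }
        if (is.null(svlen)) svlen <- abs(nchar(alt) - nchar(ref))
      }
      start <- pos - 1L
      end <- if (svtype == "INS") start else start + svlen
      rows[[length(rows) + 1L]] <- data.frame(
        sv_id = if (!is.na(fix[r, "ID"]) && fix[r, "ID"] != ".")
          paste0(fix[r, "ID"], if (length(alts) > 1) paste0("_", k) else "")
        else sprintf("%s_%d_%s", fix[r, "CHROM"], pos, svtype),
        chrom = fix[r, "CHROM"], start = start, end = end, svtype = svtype,
        svlen = svlen, seq = seqs,
        qual = suppressWarnings(as.numeric(fix[r, "QUAL"])),
        caller = caller, stringsAsFactors = FALSE)
      if (!is.null(gtm_raw)) {
        gts[[length(gts) + 1L]] <-
          vapply(gtm_raw[r, ], .gt_from_string, character(1), allele = k)
      }
    }
  }
  if (n_skipped > 0)
    warning(n_skipped, " record(s) without SVLEN or sequence skipped")
  svs <- if (length(rows)) do.call(rbind, rows) else
    sv_table(character(0), character(0), integer(0), integer(0),
             character(0), integer(0))
  rownames(svs) <- NULL
  gt <- if (length(gts)) do.call(rbind, gts) else NULL
  if (!is.null(gt)) rownames(gt) <- svs$sv_id
  out <- list(svs = svs, gt = gt)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write SVs (optionally with genotypes) to a VCF file
#'
#' Emits VCF 4.2 with SVTYPE/SVLEN/END INFO fields and GT genotypes. Records
#' carrying sequence are written with explicit REF/ALT alleles over an `N`
#' padding base (`POS = start + 1`); sequence-less records and inversions use
#' symbolic ALTs. SVLEN is negative for deletions.
#'
#' @param svs SV table.
#' @param path output path (plain text `.vcf`).
#' @param gt optional genotype matrix (rows matching `svs`, columns samples).
#' @export
write_sv_vcf <- function(svs, path, gt = NULL) {
  o <- order(svs$chrom, svs$start, svs$sv_id)
  svs <- svs[o, , drop = FALSE]
  if (!is.null(gt)) gt <- gt[o, , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length (negative for DEL)\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
           "##ALT=<ID=INS,Description=\"Insertion\">",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=INV,Description=\"Inversion\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(gt)) cols <- c(cols, "FORMAT", colnames(gt))
  n <- nrow(svs)
  if (n > 0) {
    has_seq <- !is.na(svs$seq) & svs$svtype != "INV"
    ref <- ifelse(has_seq & svs$svtype == "DEL", paste0("N", svs$seq), "N")
    alt <- ifelse(has_seq & svs$svtype == "INS", paste0("N", svs$seq),
                  ifelse(has_seq & svs$svtype == "DEL", "N",
                         paste0("<", svs$svtype, ">")))
    svlen_out <- ifelse(svs$svtype == "DEL", -svs$svlen, svs$svlen)
    pos <- svs$start + 1L
    end <- ifelse(svs$svtype == "INS", pos, pos + svs$svlen)
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", svs$svtype, svlen_out, end)
    qual <- ifelse(is.na(svs$qual), ".", format(svs$qual, trim = TRUE))
    body <- paste(svs$chrom, pos, svs$sv_id, ref, alt, qual, "PASS", info, sep = "\t")
    if (!is.null(gt)) {
      code <- c(absent = "0/0", het = "0/1", hom = "1/1", hemi = "1", missing = "./.")
      gts <- matrix(code[gt], nrow = n)
      body <- paste(body, "GT", apply(gts, 1, paste, collapse = "\t"), sep = "\t")
    }
  } else body <- character(0)
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}
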