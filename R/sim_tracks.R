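#' Simulate annotation tracks for a synthetic genome
#'
#' Generates gene models (spans, exons, promoters, NDD / SFARI flags),
#' regulatory tracks (an ENCODE-like set and a brain-derived set), TF
#' clusters, a tandem-repeat catalog anchored on a subset of pool loci, a
#' constraint-score (Gnocchi-like) tiling, and a small blacklist. Interval
#' content is random; only the structural properties matter for testing.
#'
#' @param pool SV pool (used to anchor the TR catalog so TR-overlapping SVs
#'   exist).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param seed integer seed.
#' @return named list of data.frames; `genes`/`exons` form the gene model,
#'   the rest are interval tracks (`chrom`, `start`, `end`, optional `value`).
#' @export
simulate_tracks <- function(pool, chrom_lengths = sim_chrom_lengths(), seed = 1) {
  withr::with_seed(seed, {
    genes <- vector("list", 0)
    exons <- vector("list", 0)
    gi <- 0L
    for (ch in names(chrom_lengths)) {
      n_gene <- max(1L, floor(chrom_lengths[ch] / 150e3))
      for (k in seq_len(n_gene)) {
        gi <- gi + 1L
        span <- round(runif(1, 2e4, 8e4))
        start <- floor(runif(1, 0, chrom_lengths[ch] - span))
        name <- sprintf("GENE%04d", gi)
        genes[[gi]] <- data.frame(
          gene = name, chrom = ch, start = start, end = start + span,
          ndd = runif(1) < 0.10,
          sfari = if (runif(1) < 0.08) sample(1:3, 1) else NA_integer_)
        n_ex <- sample(3:8, 1)
        ex_start <- sort(floor(runif(n_ex, start, start + span - 400)))
        exons[[gi]] <- data.frame(gene = name, chrom = ch, start = ex_start,
                                  end = ex_start + round(runif(n_ex, 150, 300)))
      }
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    promoters <- data.frame(chrom = genes$chrom,
                            start = pmax(0, genes$start - 2000),
                            end = genes$start, gene = genes$gene)
    rand_track <- function(n_per_mb, width_range) {
      out <- vector("list", 0)
      for (ch in names(chrom_lengths)) {
        n <- max(1L, round(chrom_lengths[ch] / 1e6 * n_per_mb))
        w <- round(runif(n, width_range[1], width_range[2]))
        s <- floor(runif(n, 0, chrom_lengths[ch] - w))
        out[[ch]] <- data.frame(chrom = ch, start = sort(s), end = sort(s) + w)
      }
      do.call(rbind, out)
    }
    reg <- rand_track(30, c(200, 2000))
    brainreg <- rand_track(20, c(200, 2000))
    tf <- rand_track(10, c(100, 500))
    # TR catalog anchored on ~15% of pool loci plus random intervals
    anchor <- pool[runif(nrow(pool)) < 0.15, , drop = FALSE]
    tr <- rbind(data.frame(chrom = anchor$chrom,
                           start = pmax(0, anchor$pos - 50),
                           end = anchor$pos + pmax(anchor$svlen, 50) + 50),
                rand_track(5, c(100, 1000))[, c("chrom", "start", "end")])
    tr <- tr[order(tr$chrom, tr$start), ]
    gn <- vector("list", 0)
    for (ch in names(chrom_lengths)) {
      s <- seq(0, chrom_lengths[ch] - 1e5, by = 1e5)
      gn[[ch]] <- data.frame(chrom = ch, start = s, end = s + 1e5,
                             value = round(rnorm(length(s), 1, 1.6), 2))
    }
    gnocchi <- do.call(rbind, gn)
    blacklist <- rand_track(0.5, c(5e3, 5e4))
    rownames(genes) <- rownames(exons) <- NULL
    list(genes = genes, exons = exons, promoters = promoters, reg = reg,
         brainreg = brainreg, tf = tf, tr_catalog = tr, gnocchi = gnocchi,
         blacklist = blacklist)
  })
}

#' Simulate parental read-support tables from true genotypes
#'
#' For every parent truly carrying a pool locus, emits read observations with
#' small size deviation; with `noise > 0`, carrier entries may be dropped and
#' spurious high-deviation entries appear for non-carriers.
#'
#' @param sim result of [simulate_cohort()].
#' @param noise probability of corrupting an entry.
#' @param seed integer seed.
#' @return data.frame: `sample`, `sv_id`, `dev_frac`, `n_reads`.
#' @export
simulate_read_support <- function(sim, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    ped <- sim$ped
    parents <- ped$sample[ped$role %in% c("father", "mother")]
    out <- vector("list", 0)
    for (s in parents) {
      carried <- which(sim$true_gt[, s] %in% c("het", "hom", "hemi"))
      drop <- runif(length(carried)) < noise
      keep <- carried[!drop]
      if (length(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          sample = s, sv_id = rownames(sim$true_gt)[keep],
          dev_frac = abs(rnorm(length(keep), 0, 0.05)),
          n_reads = sample(1:6, length(keep), replace = TRUE))
      }
      if (noise > 0) {
        absent <- which(sim$true_gt[, s] == "absent")
        spur <- absent[runif(length(absent)) < noise * 0.1]
        if (length(spur)) {
          out[[length(out) + 1L]] <- data.frame(
            sample = s, sv_id = rownames(sim$true_gt)[spur],
            dev_frac = runif(length(spur), 0.6, 1.5),
            n_reads = 1L)
        }
      }
    }
    if (!length(out)) return(data.frame(sample = character(0), sv_id = character(0),
                                        dev_frac = numeric(0), n_reads = integer(0)))
    do.call(rbind, out)
  })
}

#' Simulate a tandem-repeat allele-length cohort with planted expansions
#'
#' Population allele lengths vary by whole motif copies around a per-locus
#' baseline, within a narrow bounded range (+/- 2 units), as typical for
#' stable TRs; planted expansions give one child a long allele far above the
#' population and above every other sample's alleles, inherited from a
#' carrier mother.
#'
#' @param ped pedigree data.frame.
#' @param n_loci number of TR loci.
#' @param n_expansions number of planted (child, locus) expansions.
#' @param expansion_bp length added to the expanded allele.
#' @param unit_bp motif length; population alleles differ by whole units.
#' @param seed integer seed.
#' @return list: `alleles` (data.frame `sample`, `locus`, `al1`, `al2`) and
#'   `truth` (data.frame `locus`, `child`, `parent`).
#' @export
simulate_tr_cohort <- function(ped, n_loci = 30, n_expansions = 3,
                               expansion_bp = 300, unit_bp = 5, seed = 1) {
  withr::with_seed(seed, {
    loci <- sprintf("tr%03d", seq_len(n_loci))
    base <- round(runif(n_loci, 100, 500))
    al <- expand.grid(sample = ped$sample, locus = loci,
                      stringsAsFactors = FALSE)
    li <- match(al$locus, loci)
    units <- function(n) sample(-2:2, n, replace = TRUE,
                                prob = c(0.05, 0.2, 0.5, 0.2, 0.05))
    al$al1 <- base[li] + unit_bp * units(nrow(al))
    al$al2 <- base[li] + unit_bp * units(nrow(al))
    children <- ped$sample[ped$role %in% c("proband", "sibling")]
    pick <- data.frame(child = sample(children, n_expansions, replace = FALSE),
                       locus = sample(loci, n_expansions, replace = FALSE))
    pick$parent <- vapply(pick$child, function(cd) {
      fid <- ped$family[ped$sample == cd]
      ped$sample[ped$family == fid & ped$role == "mother"][1]
    }, character(1))
    for (i in seq_len(n_expansions)) {
      long <- base[match(pick$locus[i], loci)] + expansion_bp
      al$al1[al$sample == pick$child[i] & al$locus == pick$locus[i]] <- long
      al$al1[al$sample == pick$parent[i] & al$locus == pick$locus[i]] <- long
    }
    list(alleles = al, truth = pick[, c("locus", "child", "parent")])
  })
}

#' Simulate assembly-to-reference alignment intervals with gapped windows
#'
#' Tiles a chromosome into windows, marks a chosen fraction (or explicit
#' index set) as assembly gaps, and emits one alignment block per maximal
#' run of intact windows, each from its own contig.
#'
#' @param chrom_length chromosome length in bp.
#' @param chrom target name.
#' @param window window size in bp.
#' @param gap_frac fraction of windows to leave uncovered (ignored when
#'   `gap_windows` given).
#' @param gap_windows explicit 1-based window indices to gap.
#' @param seed integer seed.
#' @return list: `paf` (data.frame in PAF column order) and `gap_windows`.
#' @export
simulate_paf <- function(chrom_length, chrom = "chrX", window = 1e6,
                         gap_frac = 0.3, gap_windows = NULL, seed = 1) {
  n_win <- floor(chrom_length / window)
  withr::with_seed(seed, {
    if (is.null(gap_windows)) {
      k <- round(gap_frac * n_win)
      gap_windows <- if (k > 0) sort(sample(n_win, k)) else integer(0)
    }
    intact <- setdiff(seq_len(n_win), gap_windows)
    runs <- split(intact, cumsum(c(1, diff(intact) != 1)))
    paf <- do.call(rbind, lapply(seq_along(runs), function(i) {
      r <- runs[[i]]
      ts <- (min(r) - 1) * window
      te <- max(r) * window
      data.frame(qname = sprintf("contig%03d", i), qlen = te - ts,
                 qstart = 0, qend = te - ts, strand = "+",
                 tname = chrom, tlen = chrom_length,
                 tstart = ts, tend = te,
                 nmatch = te - ts, alen = te - ts, mapq = 60)
    }))
    list(paf = paf, gap_windows = gap_windows)
  })
}

#' Simulate haplotype-resolved CpG-island methylation under XCI skew
#'
#' `skew` is the fraction of cells in which the maternal X is inactive
#' (hence methylated at CpG islands). Each CpG's methylated-read count is
#' Binomial(coverage, p) with p = `skew * meth_high + (1-skew) * meth_low`
#' on the maternal haplotype and the mirror on the paternal one, so the
#' expected haplotype-mean difference is `(2*skew - 1) * (meth_high -
#' meth_low)`.
#'
#' @param n_islands number of CpG islands.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param cpg_per_island mean CpG count per island (Poisson, min 1).
#' @param coverage read coverage per CpG.
#' @param skew maternal-inactive cell fraction in \[0,1\].
#' @param meth_high,meth_low methylation levels of inactive/active copies.
#' @param seed integer seed.
#' @return list: `islands` (BED-like data.frame) and `mat`, `pat`
#'   (bedMethyl-like data.frames: `chrom`, `start`, `end`, `coverage`, `pct`).
#' @export
simulate_methylation <- function(n_islands = 889, chrom = "chrX",
                                 chrom_length = sim_chrom_lengths()[["chrX"]],
                                 cpg_per_island = 12, coverage = 20,
                                 skew = 0.5, meth_high = 0.85, meth_low = 0.15,
                                 seed = 1) {
  stopifnot(skew >= 0, skew <= 1)
  withr::with_seed(seed, {
    span <- 800
    gap <- floor((chrom_length - 20000) / n_islands)
    start <- 10000 + (seq_len(n_islands) - 1) * gap
    islands <- data.frame(chrom = chrom, start = start, end = start + span)
    n_cpg <- pmax(1L, rpois(n_islands, cpg_per_island))
    isl_idx <- rep(seq_len(n_islands), n_cpg)
    cpg_pos <- floor(islands$start[isl_idx] +
                       runif(sum(n_cpg)) * (span - 2))
    p_mat <- skew * meth_high + (1 - skew) * meth_low
    p_pat <- (1 - skew) * meth_high + skew * meth_low
    mk <- function(p) {
      m <- rbinom(length(cpg_pos), coverage, p)
      data.frame(chrom = chrom, start = cpg_pos, end = cpg_pos + 2,
                 coverage = coverage, pct = 100 * m / coverage)
    }
    list(islands = islands, mat = mk(p_mat), pat = mk(p_pat))
  })
}

#' Write a BED-like data.frame as tab-separated text
#'
#' @param df data.frame starting with `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write PAF alignment intervals
#'
#' @param paf data.frame in PAF column order (12 columns).
#' @param path output path.
#' @export
write_paf <- function(paf, path) {
  data.table::fwrite(paf, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Emit the full fixture set for annotation, curation and XCI analyses
#'
#' Writes BED tracks, parental read-support and TR allele-length tables,
#' per-child PAF alignments for chrX, and per-female CpG-island bedMethyl
#' pairs under `out_dir`. Deterministic under `seed`.
#'
#' @param sim result of [simulate_cohort()].
#' @param out_dir output directory.
#' @param skew named vector: maternal-inactive fraction per female child
#'   (defaults to 0.5 for all female children).
#' @param gap_frac fraction of chrX windows gapped in the PAF fixtures.
#' @param seed integer seed.
#' @return invisible list of the in-memory objects and written paths.
#' @export
simulate_tracks_and_evidence <- function(sim, out_dir, skew = NULL,
                                         gap_frac = 0.3, seed = 1) {
  if (!is.null(skew)) stopifnot(all(skew >= 0 & skew <= 1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ped <- sim$ped
  tracks <- simulate_tracks(sim$pool, seed = seed)
  for (nm in names(tracks)) {
    write_bed(tracks[[nm]][, intersect(c("chrom", "start", "end", "value", "gene",
                                         "ndd", "sfari"), names(tracks[[nm]]))],
              file.path(out_dir, paste0(nm, ".bed")))
  }
  rs <- simulate_read_support(sim, seed = seed + 1)
  data.table::fwrite(rs, file.path(out_dir, "read_support.tsv"), sep = "\t")
  tr <- simulate_tr_cohort(ped, seed = seed + 2)
  data.table::fwrite(tr$alleles, file.path(out_dir, "allele_lengths.tsv"), sep = "\t")
  children <- ped$sample[ped$role %in% c("proband", "sibling")]
  for (i in seq_along(children)) {
    pf <- simulate_paf(sim_chrom_lengths()[["chrX"]], gap_frac = gap_frac,
                       seed = seed + 10 + i)
    write_paf(pf$paf, file.path(out_dir, paste0(children[i], "_chrX.paf")))
  }
  females <- children[ped$sex[match(children, ped$sample)] == "F"]
  if (is.null(skew)) skew <- setNames(rep(0.5, length(females)), females)
  meth <- list()
  for (s in names(skew)) {
    m <- simulate_methylation(skew = skew[[s]], seed = seed + 100 + match(s, names(skew)))
    write_bed(m$mat, file.path(out_dir, paste0(s, "_mat.bedmethyl")))
    write_bed(m$pat, file.path(out_dir, paste0(s, "_pat.bedmethyl")))
    meth[[s]] <- m
  }
  if (length(meth))
    write_bed(meth[[1]]$islands, file.path(out_dir, "cpg_islands.bed"))
  invisible(list(tracks = tracks, read_support = rs, tr = tr, meth = meth,
                 dir = out_dir))
}
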