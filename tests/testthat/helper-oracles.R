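# Brute-force oracles and fixture builders shared across tests.
# Oracles are written independently of the package's windowed/grouped
# implementations: plain loops over all pairs.

# All-pairs match oracle: logical vector, query record i matched by any
# subject record.
oracle_match_any <- function(query, subject, p) {
  vapply(seq_len(nrow(query)), function(i) {
    any(vapply(seq_len(nrow(subject)), function(j) {
      sv_match(query[i, , drop = FALSE], subject[j, , drop = FALSE], p)$matched
    }, logical(1)))
  }, logical(1))
}

# All-pairs union-find partition oracle over sv_match edges, with the
# same-sample het/het exclusion (exact-identical records excepted, since
# they are indistinguishable duplicates).
oracle_partition <- function(calls, p) {
  n <- nrow(calls)
  prnt <- seq_len(n)
  find <- function(x) { while (prnt[x] != x) x <- prnt[x]; x }
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m <- sv_match(calls[i, , drop = FALSE], calls[j, , drop = FALSE], p)$matched
      if (!m) next
      identical_rec <- calls$chrom[i] == calls$chrom[j] &&
        calls$start[i] == calls$start[j] && calls$svtype[i] == calls$svtype[j] &&
        calls$svlen[i] == calls$svlen[j] &&
        identical(calls$seq[i], calls$seq[j])
      forbid <- !identical_rec && calls$sample[i] == calls$sample[j] &&
        calls$gt[i] == "het" && calls$gt[j] == "het"
      if (!forbid) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) prnt[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Random per-sample call set for collapse tests.
random_calls <- function(n, n_samples = 5, chroms = c("chr1", "chr2"),
                         max_pos = 5000, refseq = FALSE) {
  calls <- data.frame(
    sv_id = sprintf("r%04d", seq_len(n)),
    chrom = sample(chroms, n, TRUE),
    start = sample.int(max_pos, n, TRUE),
    svtype = sample(c("INS", "DEL"), n, TRUE),
    svlen = sample(c(100L, 105L, 110L, 300L, 310L, 1000L), n, TRUE),
    seq = NA_character_,
    qual = round(runif(n, 1, 60), 1),
    caller = "sim",
    sample = sample(sprintf("s%d", seq_len(n_samples)), n, TRUE),
    gt = sample(c("het", "hom"), n, TRUE, prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE)
  calls$end <- ifelse(calls$svtype == "INS", calls$start, calls$start + calls$svlen)
  calls
}

# Interval-intersection oracle (O(n*m) loop); SVs as points for INS.
oracle_intersect <- function(svs, track) {
  vapply(seq_len(nrow(svs)), function(i) {
    a <- svs$start[i]; b <- max(svs$end[i], svs$start[i] + 1)
    any(track$chrom == svs$chrom[i] & track$start < b & track$end > a)
  }, logical(1))
}

# Small deterministic quad cohort used by several modules.
small_quad_sim <- function(n_loci = 1500, n_quads = 3, n_controls = 25,
                           denovo_rate = 0.5, error_rate = 0, seed = 11) {
  ped <- simulate_pedigree(n_quads = n_quads, n_trios = 0,
                           n_controls = n_controls, seed = seed)
  pool <- simulate_sv_pool(n_loci, seed = seed)
  sim <- simulate_cohort(pool, ped, denovo_rate = denovo_rate,
                         error_rate = error_rate, seed = seed)
  list(ped = ped, sim = sim)
}
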