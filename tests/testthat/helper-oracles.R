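# Independent brute-force oracles used to check the statistical layer and
# the screening logic. These deliberately avoid the code paths under test:
# hypergeometric probabilities come from choose(), the Mann-Whitney null
# distribution from explicit enumeration of group assignments.

# Two-sided Fisher p by enumerating all tables with the observed margins;
# probability-mass method with a small relative tolerance on the comparison.
oracle_fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + rel_tol)])
}

# Exact two-sided Mann-Whitney p from the enumerated U distribution:
# 2 * min(P(U <= u), P(U >= u)), capped at 1.
oracle_mw_dist <- function(n, n_a) {
  splits <- utils::combn(n, n_a)
  ranks <- seq_len(n)
  apply(splits, 2L, function(ix) sum(ranks[ix]) - n_a * (n_a + 1) / 2)
}

oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n_a <- length(x)
  u_obs <- sum(rank(pooled)[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  dist <- oracle_mw_dist(length(pooled), n_a)
  min(1, 2 * min(mean(dist <= u_obs), mean(dist >= u_obs)))
}

# Confusion-matrix enumeration for the outlier screen.
oracle_screen <- function(flagged, confirmed, threshold) {
  tp <- fp <- fn <- 0L
  for (s in names(confirmed)) {
    f <- s %in% flagged
    pos <- confirmed[[s]] >= threshold
    if (f && pos) tp <- tp + 1L
    if (f && !pos) fp <- fp + 1L
    if (!f && pos) fn <- fn + 1L
  }
  list(TP = tp, FP = fp, FN = fn)
}

# Noise-free, error-free simulation spec: every read is an exact copy of
# the allele amplicon (up to strand).
clean_sim_spec <- function(alleles, n_reads = 60L, seed = 1L, ...) {
  sample_sim_spec(alleles = alleles, n_reads = n_reads,
                  mosaicism_sd_triplets = 0, error_rate_sub = 0,
                  error_rate_indel = 0, aac_streak_rate = 0,
                  seed = seed, ...)
}

reverse_complement_reads <- function(reads) {
  data.frame(
    read_id = reads$read_id,
    seq = as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads$seq))),
    qual = vapply(strsplit(reads$qual, ""), function(q) {
      paste(rev(q), collapse = "")
    }, ""),
    stringsAsFactors = FALSE
  )
}
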