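mk_calls <- function(counts, flank = "GTG", pre = "", motif = "AAG",
                     seg_len = NULL) {
  n <- length(counts)
  if (is.null(seg_len)) seg_len <- 9L + 3L * counts
  data.frame(read_id = sprintf("r%03d", seq_len(n)),
             segment_len = seg_len,
             flank_class = rep(flank, length.out = n),
             flank_novel = FALSE,
             pre_repeat = rep(pre, length.out = n),
             tract_start_offset = 9L,
             main_motif = rep(motif, length.out = n),
             triplet_count = as.integer(counts),
             remainder = 0L,
             stringsAsFactors = FALSE)
}

test_that("allele summaries use the lower median and n-1 standard deviation", {
  s1 <- summarize_allele(mk_calls(c(10, 10, 10)))
  expect_identical(s1$median_triplets, 10L)
  expect_identical(s1$sd_triplets, 0)

  s2 <- summarize_allele(mk_calls(c(100, 200, 300, 400)))
  expect_identical(s2$median_triplets, 200L) # lower median for even n
  expect_equal(s2$sd_triplets, sqrt(50000 / 3), tolerance = 1e-12)

  # retained-segment median 554 bp maps to a 700 bp fragment equivalent
  s3 <- summarize_allele(mk_calls(rep(180L, 5), seg_len = rep(554L, 5)))
  expect_identical(s3$fragment_equivalent_bp, 700L)
})

test_that("signature differences separate alleles regardless of size", {
  calls <- rbind(mk_calls(rep(30L, 20), flank = "GTG"),
                 mk_calls(rep(32L, 20), flank = "GTTAGTCATAGTACCCC"))
  calls$read_id <- sprintf("r%03d", seq_len(nrow(calls)))
  part <- partition_reads(calls)
  expect_identical(nrow(part$groups), 2L)
  expect_setequal(part$groups$n_reads, c(20L, 20L))
})

test_that("size clustering splits well-separated counts and keeps unimodal groups whole", {
  set.seed(42)
  two <- mk_calls(c(round(rnorm(60, 204, 4)), round(rnorm(60, 311, 6))))
  part2 <- partition_reads(two)
  expect_identical(nrow(part2$groups), 2L)
  expect_equal(sort(part2$groups$median_triplets), c(204, 311), tolerance = 0.01)

  one <- mk_calls(round(rnorm(120, 300, 8)))
  part1 <- partition_reads(one)
  expect_identical(nrow(part1$groups), 1L)

  expect_error(partition_reads(mk_calls(rep(50L, 5))),
               "insufficient_coverage")
})

test_that("allele labels are size-ranked and stable under read shuffling", {
  set.seed(7)
  calls <- rbind(mk_calls(round(rnorm(40, 30, 1))),
                 mk_calls(round(rnorm(40, 200, 4)), pre = "AAGAG"))
  calls$read_id <- sprintf("r%03d", seq_len(nrow(calls)))
  shuffled <- calls[sample.int(nrow(calls)), , drop = FALSE]
  p1 <- partition_reads(calls)
  p2 <- partition_reads(shuffled)
  key <- function(p) p$groups[order(p$groups$median_triplets),
                              c("n_reads", "median_triplets")]
  expect_equal(key(p1), key(p2), ignore_attr = TRUE)

  expect_identical(repeatscope:::assign_allele_labels(c(100, 30)),
                   c("a2", "a1"))
  expect_identical(repeatscope:::assign_allele_labels(c(300, 30, 270)),
                   c("a2", "a1", "a3"))
})

test_that("genotype classification follows the threshold and motif rules", {
  th <- classification_thresholds()
  row <- function(m, motif = "AAG") {
    data.frame(median_triplets = m, main_motif = motif, flank_class = "GTG",
               pre_repeat = "", stringsAsFactors = FALSE)
  }
  expect_identical(classify_genotype(row(254), th)$class, "incomplete_250_299")
  expect_identical(classify_genotype(row(400, "AAGGAG"), th)$class,
                   "nonpathogenic_motif")
  expect_identical(classify_genotype(rbind(row(684), row(498)), th)$class,
                   "biallelic_expansion")
  expect_identical(classify_genotype(row(191), th)$class,
                   "intermediate_180_249")
  expect_identical(classify_genotype(row(120), th)$class, "normal")
  expect_identical(classify_genotype(rbind(row(30), row(310)), th)$class,
                   "pathogenic_300_plus")
  # a huge hexamer allele never drives a pathogenic class
  expect_identical(classify_genotype(rbind(row(30), row(500, "AAGGAG")), th)$class,
                   "nonpathogenic_motif")
})

test_that("instability correlation handles the degenerate and error cases", {
  expect_error(instability_correlation(c(1, 2, 3), c(0, 0, 0)), "zero variance")
  two <- instability_correlation(c(100, 300), c(2, 8))
  expect_identical(two$r_squared, 1)
  set.seed(11)
  m <- runif(50, 9, 400)
  prop <- instability_correlation(m, 0.05 * m + rnorm(50, 0, 0.5))
  expect_gt(prop$r, 0.9)
  null <- instability_correlation(m, 5 + rnorm(50, 0, 0.5))
  expect_lt(abs(null$r), 0.3)
})
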