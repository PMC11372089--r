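test_that("segments parse into invariable motif, flank, pre-repeat and tract", {
  arch <- default_architecture()
  p1 <- parse_segment(paste0("CTTTCT", "GTG", strrep("AAG", 36)), arch)
  expect_true(p1$invariable_found)
  expect_identical(p1$flank_class, "GTG")
  expect_identical(p1$pre_repeat, "")
  expect_identical(nchar(p1$tract), 108L)
  expect_identical(p1$tract_start_offset, 9L)

  p2 <- parse_segment(paste0("CTTTCT", "GTG", "AAGAAAGAG",
                             strrep("AAG", 250)), arch)
  expect_identical(p2$flank_class, "GTG")
  expect_identical(p2$pre_repeat, "AAGAAAGAG")

  p3 <- parse_segment(paste0("CTTTCT", "GTTAGTCATAGTACCCC",
                             strrep("AAG", 9)), arch)
  expect_identical(p3$flank_class, "GTTAGTCATAGTACCCC")

  # novel variable region kept verbatim, flagged
  p4 <- parse_segment(paste0("CTTTCT", "TTACT", strrep("AAG", 20)), arch)
  expect_true(p4$flank_novel)
  expect_identical(p4$flank_class, "TTACT")

  # no invariable motif: read excluded from allele calling
  p5 <- parse_segment(paste0("GGGGGG", strrep("AAG", 20)), arch)
  expect_false(p5$invariable_found)
  expect_true(is.na(p5$tract))
})

test_that("triplet decomposition counts in a fixed frame with resync", {
  cls <- decompose_triplets("AAGAAGAAG")
  expect_identical(as.character(cls), c("AAG", "AAG", "AAG"))
  expect_identical(attr(cls, "remainder"), 0L)

  # hexamer with AAG leader: 12 triplets, alternating after the leader
  hx <- paste0("AAGAAG", strrep("AAGGAG", 5))
  cls_hx <- decompose_triplets(hx)
  expect_length(cls_hx, 12L)
  expect_identical(as.character(cls_hx)[3:12], rep(c("AAG", "GAG"), 5))

  mid <- paste0(strrep("AAG", 10), "ACG", strrep("AAG", 10))
  cls_mid <- decompose_triplets(mid)
  expect_length(cls_mid, 21L)
  expect_identical(which(as.character(cls_mid) == "ACG"), 11L)

  # frame anchoring: prepending the first triplet adds exactly one
  tract <- paste0(strrep("AAG", 7), "GAG", strrep("AAG", 3))
  expect_length(decompose_triplets(paste0("AAG", tract)),
                length(decompose_triplets(tract)) + 1L)

  # remainder is reported, not counted
  cls_rem <- decompose_triplets("AAGAAGAA")
  expect_length(cls_rem, 2L)
  expect_identical(attr(cls_rem, "remainder"), 2L)
})

test_that("resync confines an indel to one position instead of the whole suffix", {
  clean <- strrep("AAG", 40)
  # delete one base at position 50: downstream frame shifts by one
  mutated <- paste0(substr(clean, 1, 49), substr(clean, 51, nchar(clean)))
  cls <- decompose_triplets(mutated)
  expect_lte(abs(length(cls) - 40L), 1L)
  expect_lte(sum(cls != "AAG"), 1L)
  # without resync the suffix decodes as garbage
  cls_fixed <- decompose_triplets(mutated, resync = FALSE)
  expect_gt(sum(cls_fixed != "AAG"), 10L)
})

test_that("main-motif calling favors the triplet motif at the tie", {
  expect_identical(call_main_motif(rep("AAG", 50)), "AAG")
  expect_identical(call_main_motif(c("AAG", "AAG", rep(c("AAG", "GAG"), 200))),
                   "AAGGAG")
  # exactly half the adjacent pairs alternate: tie goes to AAG
  half <- c(rep(c("AAG", "GAG"), 25), rep("AAG", 51))
  frac <- mean((half[-length(half)] == "AAG" & half[-1] == "GAG") |
                 (half[-length(half)] == "GAG" & half[-1] == "AAG"))
  expect_identical(frac, 0.5)
  expect_identical(call_main_motif(half), "AAG")
  expect_error(call_main_motif(character(0)), "empty")
})

test_that("interruption typing separates reproducible variants from random error", {
  arch <- default_architecture()
  run_alleles <- function(spec, n_reads = 40L, seed = 31L, ...) {
    sim <- simulate_sample(
      sample_sim_spec(spec, n_reads = n_reads, mosaicism_sd_triplets = 0,
                      error_rate_sub = 0, error_rate_indel = 0,
                      seed = seed, ...), arch)
    gt <- call_sample(sim$reads, "t", run_config())
    gt$genotype
  }

  # middle ACG block, present in every read
  g_mid <- run_alleles(allele_spec(
    "GTG", 60, interruptions = data.frame(position_triplet = 30L,
                                          motif = "ACG",
                                          length_triplets = 2L)),
    aac_streak_rate = 0)
  expect_identical(g_mid$interruption_class, "middle")

  # GAG run within the first 5% of a 300-triplet tract: 5' edge
  g_edge <- run_alleles(allele_spec(
    "GTG", 300, interruptions = data.frame(position_triplet = 6L,
                                           motif = "GAG",
                                           length_triplets = 5L)),
    aac_streak_rate = 0)
  expect_identical(g_edge$interruption_class, "edge_5p")

  # random AAC streaks in ~10% of reads do not reach consensus support
  g_aac <- run_alleles(allele_spec("GTG", 200), aac_streak_rate = 0.10,
                       n_reads = 60L)
  expect_identical(g_aac$interruption_class, "pure")

  # single-read alleles cannot be assessed
  rc <- data.frame(read_id = "r1", triplet_count = 50L, main_motif = "AAG",
                   stringsAsFactors = FALSE)
  expect_identical(
    classify_interruptions(rc, data.frame(read_id = character(0),
                                          run_start = integer(0),
                                          run_end = integer(0),
                                          run_len = integer(0),
                                          motif = character(0))),
    "unassessable")
})

test_that("decomposition is deterministic", {
  seg <- paste0("CTTTCT", "GTG", strrep("AAG", 25), "ACG", strrep("AAG", 10))
  a <- parse_segment(seg)
  b <- parse_segment(seg)
  expect_identical(a, b)
  expect_identical(decompose_triplets(a$tract), decompose_triplets(b$tract))
})
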