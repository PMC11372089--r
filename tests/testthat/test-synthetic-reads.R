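test_that("allele sequences concatenate the documented parts", {
  arch <- default_architecture()
  s <- build_allele_sequence(allele_spec("GTG", 10), arch)
  expect_true(grepl(paste0("CTTTCT", "GTG", strrep("AAG", 10)), s, fixed = TRUE))

  # small-allele flank with 12 repeats: tract is 36 nt
  s2 <- build_allele_sequence(allele_spec("GTTAGTCATAGTACCCC", 12), arch)
  seg2 <- sub(paste0(".*", arch$upstream_anchor), "", s2)
  seg2 <- sub(paste0(arch$downstream_anchor, ".*"), "", seg2)
  expect_identical(nchar(seg2), 6L + 17L + 36L)

  # component lengths add up: CTTTCT + GTG + 9 nt pre-repeat + 300 triplets
  s3 <- build_allele_sequence(
    allele_spec("GTG", 300, pre_repeat = "AAGAAAGAG"), arch)
  seg3 <- sub(paste0(".*", arch$upstream_anchor), "", s3)
  seg3 <- sub(paste0(arch$downstream_anchor, ".*"), "", seg3)
  expect_identical(nchar(seg3), 6L + 3L + 9L + 900L)

  # both anchors occur exactly once
  count_hits <- function(p, s) {
    sum(gregexpr(p, s, fixed = TRUE)[[1]] > 0)
  }
  expect_identical(count_hits(arch$upstream_anchor, s3), 1L)
  expect_identical(count_hits(arch$downstream_anchor, s3), 1L)

  expect_error(build_allele_sequence(allele_spec("NOPE?", 10), arch),
               "unknown flank class")
})

test_that("allele_spec validates its grammar", {
  expect_error(allele_spec("GTG", 1), "AAGAAG gate")
  expect_error(allele_spec("GTG", 10, pre_repeat = "ACT"), "AG-only")
  expect_error(
    allele_spec("GTG", 10,
                interruptions = data.frame(position_triplet = 12L,
                                           motif = "ACG",
                                           length_triplets = 1L)),
    "positions")
})

test_that("noise-free simulation is a lossless round trip through the pipeline", {
  arch <- default_architecture()
  specs <- list(
    allele_spec("GTG", 37, pre_repeat = "AAGAG"),
    allele_spec("GTTAGTCATAGTACCCC", 15),
    allele_spec("GTG", 120, main_motif = "AAGGAG"),
    allele_spec("GTG", 80,
                interruptions = data.frame(position_triplet = 40L,
                                           motif = "ACG",
                                           length_triplets = 3L))
  )
  for (al in specs) {
    sim <- simulate_sample(clean_sim_spec(al, n_reads = 20L, seed = 3L), arch)
    lt <- locate_and_trim(sim$reads, arch)
    expect_identical(nrow(lt$segments), 20L)
    ps <- parse_segment(lt$segments$segment, arch)
    expect_true(all(ps$invariable_found))
    expect_true(all(ps$flank_class == al$flank_class))
    expect_true(all(ps$pre_repeat == al$pre_repeat))
    counts <- vapply(ps$tract, function(tr) length(decompose_triplets(tr)), 1L)
    expect_true(all(counts == al$repeat_triplets))
  }
})

test_that("a fixed seed fixes the FASTQ bytes", {
  spec <- sample_sim_spec(allele_spec("GTG", 60), n_reads = 40L, seed = 11L)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_sample(spec)$reads, f1)
  write_fastq(simulate_sample(spec)$reads, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("FASTQ writer and reader round-trip, including gzip", {
  sim <- simulate_sample(sample_sim_spec(allele_spec("GTG", 30),
                                         n_reads = 15L, seed = 5L))
  for (ext in c(".fastq", ".fastq.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_fastq(sim$reads, f)
    back <- read_fastq(f)
    expect_identical(back, sim$reads)
  }
})

test_that("ground-truth mosaic spread converges to the requested sd", {
  sd_target <- 10
  spec <- sample_sim_spec(allele_spec("GTG", 300), n_reads = 2000L,
                          mosaicism_sd_triplets = sd_target,
                          error_rate_sub = 0, error_rate_indel = 0,
                          aac_streak_rate = 0, short_fragment_bias = 0,
                          seed = 21L)
  sim <- simulate_sample(spec)
  se <- sd_target / sqrt(2 * 2000)
  expect_lt(abs(sd(sim$truth$true_triplets) - sd_target), 2 * se)
})

test_that("strand mix does not change pipeline segments (same seed)", {
  mk <- function(frac) {
    sample_sim_spec(allele_spec("GTG", 50), n_reads = 30L,
                    minus_strand_fraction = frac, seed = 9L)
  }
  seg <- function(frac) {
    locate_and_trim(simulate_sample(mk(frac))$reads)$segments$segment
  }
  expect_identical(seg(1.0), seg(0.0))
})
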