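mk_read <- function(seq, q = 30L, id = "r1") {
  data.frame(read_id = id, seq = seq,
             qual = strrep(rawToChar(as.raw(33L + q)), nchar(seq)),
             stringsAsFactors = FALSE)
}

test_that("quality filter applies the length and mean-quality gates", {
  short <- mk_read(strrep("ACGT", 38), q = 20L) # 152 bp
  res <- quality_filter(short)
  expect_identical(nrow(res$kept), 0L)
  expect_identical(res$rejected$reason, "too_short")

  # ends fine, interior drags the mean below 10
  n <- 300L
  qv <- c(rep(30L, 10L), rep(5L, n - 20L), rep(30L, 10L))
  lowq <- data.frame(read_id = "r1", seq = strrep("A", n),
                     qual = rawToChar(as.raw(33L + qv)),
                     stringsAsFactors = FALSE)
  res <- quality_filter(lowq)
  expect_identical(res$rejected$reason, "low_mean_q")

  good <- mk_read(strrep("ACGT", 75), q = 30L)
  res <- quality_filter(good)
  expect_identical(res$kept, good)

  long <- mk_read(strrep("A", 500L), q = 30L)
  res <- quality_filter(long, qc_params(max_len = 400L))
  expect_identical(res$rejected$reason, "too_long")
})

test_that("quality filter trims low-quality ends and is idempotent", {
  n <- 260L
  qv <- c(rep(2L, 30L), rep(30L, n - 60L), rep(2L, 30L))
  r <- data.frame(read_id = "r1", seq = paste(rep("ACGT", 65), collapse = ""),
                  qual = rawToChar(as.raw(33L + qv)), stringsAsFactors = FALSE)
  once <- quality_filter(r)
  expect_identical(nchar(once$kept$seq), n - 60L)
  twice <- quality_filter(once$kept)
  expect_identical(twice$kept, once$kept)
  expect_identical(nrow(twice$rejected), 0L)
})

test_that("double-flank anchoring extracts the segment on both strands", {
  arch <- default_architecture()
  seg_true <- paste0("CTTTCTGTG", strrep("AAG", 50))
  read <- paste0("TTTTCCCCGGGG", arch$upstream_anchor, seg_true,
                 arch$downstream_anchor, "ACACACACAC")
  res <- locate_and_trim(mk_read(read), arch)
  expect_identical(res$segments$segment, seg_true)
  expect_identical(res$segments$strand_source, "+")
  expect_identical(res$segments$up_edits, 0L)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  res_rc <- locate_and_trim(mk_read(rc), arch)
  expect_identical(res_rc$segments$segment, seg_true)
  expect_identical(res_rc$segments$strand_source, "-")
})

test_that("anchor edit tolerance is enforced at 2 edits", {
  arch <- default_architecture()
  seg_true <- paste0("CTTTCTGTG", strrep("AAG", 40))
  mutate_at <- function(s, at) {
    for (p in at) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  up2 <- mutate_at(arch$upstream_anchor, c(3L, 17L))
  read2 <- paste0("GGTT", up2, seg_true, arch$downstream_anchor, "CCAA")
  res2 <- locate_and_trim(mk_read(read2), arch)
  expect_identical(res2$segments$segment, seg_true)
  expect_identical(res2$segments$up_edits, 2L)

  up3 <- mutate_at(arch$upstream_anchor, c(3L, 10L, 18L))
  read3 <- paste0("GGTT", up3, seg_true, arch$downstream_anchor, "CCAA")
  res3 <- locate_and_trim(mk_read(read3), arch)
  expect_identical(nrow(res3$segments), 0L)
  expect_identical(res3$rejected$reason, "missing_anchor")
})

test_that("concatemers and discordant anchor layouts are rejected with reasons", {
  arch <- default_architecture()
  amp <- build_allele_sequence(allele_spec("GTG", 30), arch)
  res <- locate_and_trim(mk_read(paste0(amp, amp)), arch)
  expect_identical(nrow(res$segments), 0L)
  expect_identical(res$rejected$reason, "chimeric")

  wrong_order <- paste0("TTTT", arch$downstream_anchor, strrep("AAG", 30),
                        arch$upstream_anchor, "GGGG")
  res2 <- locate_and_trim(mk_read(wrong_order), arch)
  expect_identical(res2$rejected$reason, "discordant_anchors")

  no_anchor <- mk_read(strrep("ACGT", 100))
  res3 <- locate_and_trim(no_anchor, arch)
  expect_identical(res3$rejected$reason, "missing_anchor")
})

test_that("the AAGAAG gate admits triplet junctions only", {
  expect_true(aag_gate("CTTTCTGTGAAGAAG"))
  expect_false(aag_gate(paste0("CTTTCTGTG", strrep("AAGGAG", 20))))
  expect_false(aag_gate(""))
  # hexamer override accepts two consecutive hexamer units
  expect_true(aag_gate(paste0("CTTTCTGTG", strrep("AAGGAG", 20)),
                       allow_hexamer = TRUE))
})

test_that("on error-free reads the gate acceptance rate equals the AAGAAG fraction", {
  arch <- default_architecture()
  # one AAG allele (passes) and one leaderless pure hexamer (never AAGAAG)
  spec <- clean_sim_spec(
    list(allele_spec("GTG", 40),
         allele_spec("GTG", 60, main_motif = "AAGGAG",
                     hexamer_leader = FALSE)),
    n_reads = 80L, seed = 13L)
  sim <- simulate_sample(spec, arch)
  lt <- locate_and_trim(sim$reads, arch)
  gate <- aag_gate(lt$segments$segment)
  truth_pass <- sim$truth$allele_index == 1L
  expect_identical(sum(gate), sum(truth_pass))
  expect_identical(sort(lt$segments$read_id[gate]),
                   sort(sim$truth$read_id[truth_pass]))
})
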