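# Nanopore-like amplicon read simulator with known ground truth. Emulates
# the processes the real assay exhibits: size-dependent somatic mosaicism,
# per-base substitution and indel errors, systematic AAG->AAC runs in a
# minority of reads, preferential sampling of short fragments, and a mix of
# read orientations. It does not model pore-level signal or basecaller
# behavior beyond these processes.

#' Simulation settings for one sample
#'
#' @param alleles List of 1-3 [allele_spec()] objects.
#' @param n_reads Number of reads to emit.
#' @param dosage Per-allele dosage weights (default equal); normalized to
#'   sum to 1.
#' @param mosaicism_sd_triplets Per-allele standard deviation (in triplets)
#'   of the per-read repeat count. `NULL` (default) uses
#'   `0.02 * repeat_triplets`, reflecting the positive size-instability
#'   correlation seen in real expansions; the coefficient is a modeling
#'   choice, not a measured value.
#' @param error_rate_sub Per-base substitution probability (default 0.01).
#' @param error_rate_indel Per-base indel probability, split evenly between
#'   insertions and deletions (default 0.005).
#' @param aac_streak_rate Per-read probability of a systematic AAG->AAC run
#'   (default 0.05).
#' @param aac_streak_mean Mean length (triplets, geometric) of an AAC run
#'   (default 8).
#' @param short_fragment_bias Exponent b >= 0: sampling weight is
#'   proportional to `length^(-b)` (default 0.5, mild preferential sampling
#'   of short fragments).
#' @param minus_strand_fraction Probability a read is emitted as the reverse
#'   complement (default 0.5).
#' @param mean_q Constant Phred quality emitted per base (default 20).
#' @param seed Integer seed; fixes the output byte-exactly.
#' @return An object of class `sample_sim_spec`.
#' @export
sample_sim_spec <- function(alleles, n_reads,
                            dosage = NULL,
                            mosaicism_sd_triplets = NULL,
                            error_rate_sub = 0.01,
                            error_rate_indel = 0.005,
                            aac_streak_rate = 0.05,
                            aac_streak_mean = 8,
                            short_fragment_bias = 0.5,
                            minus_strand_fraction = 0.5,
                            mean_q = 20L,
                            seed = 1L) {
  if (inherits(alleles, "allele_spec")) alleles <- list(alleles)
  stopifnot(length(alleles) >= 1L, length(alleles) <= 3L,
            all(vapply(alleles, inherits, TRUE, "allele_spec")),
            n_reads > 0L)
  k <- length(alleles)
  if (is.null(dosage)) dosage <- rep(1 / k, k)
  stopifnot(length(dosage) == k, all(dosage >= 0), sum(dosage) > 0)
  dosage <- dosage / sum(dosage)
  if (is.null(mosaicism_sd_triplets)) {
    mosaicism_sd_triplets <-
      0.02 * vapply(alleles, function(a) a$repeat_triplets, 1)
  }
  if (length(mosaicism_sd_triplets) == 1L) {
    mosaicism_sd_triplets <- rep(mosaicism_sd_triplets, k)
  }
  probs <- c(error_rate_sub, error_rate_indel, aac_streak_rate,
             minus_strand_fraction)
  stopifnot(all(probs >= 0), all(probs <= 1),
            all(mosaicism_sd_triplets >= 0), short_fragment_bias >= 0)
  structure(list(
    alleles = alleles, n_reads = as.integer(n_reads), dosage = dosage,
    mosaicism_sd_triplets = mosaicism_sd_triplets,
    error_rate_sub = error_rate_sub, error_rate_indel = error_rate_indel,
    aac_streak_rate = aac_streak_rate, aac_streak_mean = aac_streak_mean,
    short_fragment_bias = short_fragment_bias,
    minus_strand_fraction = minus_strand_fraction,
    mean_q = as.integer(mean_q), seed = as.integer(seed)
  ), class = "sample_sim_spec")
}

.BASES <- c("A", "C", "G", "T")

# Substitutions then indels on one sequence, as a character vector job.
apply_read_errors <- function(seq, sub_rate, indel_rate) {
  if (sub_rate <= 0 && indel_rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(v)
  nsub <- stats::rbinom(1L, L, sub_rate)
  if (nsub > 0L) {
    pos <- sample.int(L, nsub)
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(.BASES, b), 1L), "")
  }
  ndel <- stats::rbinom(1L, L, indel_rate / 2)
  nins <- stats::rbinom(1L, L, indel_rate / 2)
  if (ndel > 0L) v <- v[-sample.int(length(v), min(ndel, length(v) - 1L))]
  if (nins > 0L) {
    at <- stats::runif(nins, 0, length(v)) # fractional positions interleave
    v <- c(v, sample(.BASES, nins, replace = TRUE))[
      order(c(seq_len(length(v)), at))]
  }
  paste(v, collapse = "")
}

#' Simulate a sample's nanopore-like amplicon reads
#'
#' Draws reads per allele (dosage times a `length^(-b)` short-fragment
#' weight), jitters each read's repeat count by a rounded Gaussian truncated
#' at 2 triplets (somatic mosaicism), optionally rewrites a contiguous run
#' of AAG triplets to AAC (systematic sequencing error), applies per-base
#' substitution and indel errors, reverse-complements minus-strand reads,
#' and emits constant-quality Phred+33 records. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [sample_sim_spec()].
#' @param arch An [default_architecture()].
#' @param id_prefix Prefix for read identifiers.
#' @return A list with `reads` (data.frame: `read_id`, `seq`, `qual`) and
#'   `truth` (data.frame: `read_id`, `allele_index`, `true_triplets`,
#'   `strand`).
#' @export
simulate_sample <- function(spec, arch = default_architecture(),
                            id_prefix = "sim") {
  stopifnot(inherits(spec, "sample_sim_spec"))
  withr::with_seed(spec$seed, simulate_sample_impl(spec, arch, id_prefix))
}

simulate_sample_impl <- function(spec, arch, id_prefix) {
  k <- length(spec$alleles)
  # per-allele fixed parts
  flanks <- vapply(spec$alleles, function(a) resolve_flank(a$flank_class, arch), "")
  prefix <- paste0(arch$primer_pad_5p, arch$upstream_anchor,
                   arch$invariable_motif, flanks,
                   vapply(spec$alleles, function(a) a$pre_repeat, ""))
  suffix <- paste0(arch$downstream_anchor, arch$primer_pad_3p)
  nominal <- vapply(spec$alleles, function(a) a$repeat_triplets, 1L)
  amp_len <- nchar(prefix) + 3L * nominal + nchar(suffix)
  w <- spec$dosage * amp_len^(-spec$short_fragment_bias)
  allele_idx <- sample.int(k, spec$n_reads, replace = TRUE, prob = w / sum(w))

  n <- spec$n_reads
  # Per-read mosaic repeat count: discretized Gaussian around the nominal
  # count, truncated at 2, reweighted by fragment length^(-b) so that
  # preferential sampling of short fragments also acts within an allele
  # (shorter mosaic variants of an expansion are over-sampled, biasing the
  # median down -- the behavior the median aggregation is meant to resist).
  tri <- integer(n)
  fixed_len <- nchar(prefix) + nchar(suffix)
  for (ai in seq_len(k)) {
    idx <- which(allele_idx == ai)
    if (length(idx) == 0L) next
    sd_i <- spec$mosaicism_sd_triplets[ai]
    if (sd_i > 0) {
      grid <- seq.int(max(2L, nominal[ai] - ceiling(6 * sd_i)),
                      nominal[ai] + ceiling(6 * sd_i))
      w_g <- stats::dnorm(grid, nominal[ai], sd_i) *
        (fixed_len[ai] + 3 * grid)^(-spec$short_fragment_bias)
      tri[idx] <- sample(grid, length(idx), replace = TRUE, prob = w_g)
    } else {
      tri[idx] <- nominal[ai]
    }
  }
  seqs <- character(n)
  minus <- stats::runif(n) < spec$minus_strand_fraction
  for (i in seq_len(n)) {
    ai <- allele_idx[i]
    al <- spec$alleles[[ai]]
    t_i <- tri[i]
    tr <- build_tract_triplets(al, t_i)
    if (al$main_motif == "AAG" && spec$aac_streak_rate > 0 &&
        stats::runif(1L) < spec$aac_streak_rate) {
      len <- stats::rgeom(1L, 1 / spec$aac_streak_mean) + 1L
      start <- sample.int(t_i, 1L)
      idx <- start:min(t_i, start + len - 1L)
      idx <- idx[tr[idx] == "AAG"]
      tr[idx] <- "AAC"
    }
    read <- paste0(prefix[ai], paste(tr, collapse = ""), suffix)
    seqs[i] <- apply_read_errors(read, spec$error_rate_sub, spec$error_rate_indel)
  }
  if (any(minus)) {
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus])))
  }
  qchar <- rawToChar(as.raw(33L + spec$mean_q))
  reads <- data.frame(
    read_id = sprintf("%s_%05d", id_prefix, seq_len(n)),
    seq = seqs,
    qual = strrep(qchar, nchar(seqs)),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    read_id = reads$read_id,
    allele_index = allele_idx,
    true_triplets = tri,
    strand = ifelse(minus, "-", "+"),
    stringsAsFactors = FALSE
  )
  list(reads = reads, truth = truth)
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads Data.frame with `read_id`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix writes gzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", reads$qual),
             con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' Transparently handles gzip. Malformed records (length mismatch between
#' sequence and quality) are reported with their read id and dropped;
#' processing continues.
#'
#' @param path FASTQ path (`.gz` allowed).
#' @return Data.frame with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on conversion
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  reads <- data.frame(
    read_id = sub("\\s.*$", "", names(x)),
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE
  )
  bad <- nchar(reads$seq) != nchar(reads$qual)
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed FASTQ record(s): ",
            paste(utils::head(reads$read_id[bad], 5L), collapse = ", "),
            call. = FALSE)
    reads <- reads[!bad, , drop = FALSE]
  }
  rownames(reads) <- NULL
  reads
}

#' Write a ground-truth table as TSV
#'
#' @param truth Truth data.frame from [simulate_sample()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
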