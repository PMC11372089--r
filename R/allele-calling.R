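# Allele partitioning, per-allele summaries and genotype classification.
#
# Reads are first grouped by structural signature (flank class, pre-repeat,
# main motif); sequencing errors corrupt the variable region of a minority
# of reads, so rare signatures are re-assigned to the closest major
# signature by edit distance rather than being treated as alleles of their
# own. Within a signature, repeat counts are split by an explicit 1-D
# two-means criterion: a split is accepted iff the cluster medians differ by
# more than max(10 triplets, 3 x pooled within-cluster MAD) and both sides
# retain at least min_support reads. The paper's authors separated alleles
# visually; this rule is the package's reproducible replacement, and its
# resolution (same-signature alleles closer than ~max(10, 3 sigma) triplets
# merge) is documented behavior.

# Lower median: the lower of the two central order statistics for even n,
# matching integer-valued printed repeat numbers.
median_lower <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

# Optimal 1-D two-means split by scanning all cut points of the sorted
# values (O(n) with cumulative sums). Returns NULL or list(left, right).
best_split <- function(x, min_support) {
  n <- length(x)
  if (n < 2L * min_support) return(NULL)
  xs <- sort(x)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  i <- seq(min_support, n - min_support)
  ssw <- (cs2[i] - cs[i]^2 / i) +
    ((cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i))
  cut <- i[which.min(ssw)]
  list(left = xs[seq_len(cut)], right = xs[(cut + 1L):n])
}

split_accepted <- function(left, right, gap_min, mad_mult) {
  m1 <- stats::median(left)
  m2 <- stats::median(right)
  pooled_mad <- stats::mad(c(left - m1, right - m2), center = 0)
  (m2 - m1) > max(gap_min, mad_mult * pooled_mad)
}

# Recursive size clustering of triplet counts; returns integer cluster ids.
cluster_sizes <- function(counts, min_support, gap_min = 10, mad_mult = 3,
                          max_clusters = 3L) {
  assign_rec <- function(idx, depth) {
    sp <- best_split(counts[idx], min_support)
    if (is.null(sp) || depth >= max_clusters - 1L ||
        !split_accepted(sp$left, sp$right, gap_min, mad_mult)) {
      return(list(idx))
    }
    thr <- max(sp$left)
    left_idx <- idx[counts[idx] <= thr]
    # ties at the boundary all go left; guard support
    right_idx <- setdiff(idx, left_idx)
    if (length(left_idx) < min_support || length(right_idx) < min_support) {
      return(list(idx))
    }
    c(assign_rec(left_idx, depth + 1L), assign_rec(right_idx, depth + 1L))
  }
  groups <- assign_rec(seq_along(counts), 0L)
  ids <- integer(length(counts))
  for (g in seq_along(groups)) ids[groups[[g]]] <- g
  ids
}

#' Partition a sample's read calls into allele groups
#'
#' First splits by exact structural signature (flank class, pre-repeat, main
#' motif), re-assigning reads with minor signatures (fewer than
#' `major_fraction` of reads) to the closest major signature by edit
#' distance of the variable region; then, within each signature, clusters
#' triplet counts with the documented two-means split rule. At most three
#' groups are retained (ranked by read support); surplus groups are flagged
#' in the output, not silently dropped.
#'
#' @param read_calls Data.frame of per-read calls (needs `read_id`,
#'   `flank_class`, `pre_repeat`, `main_motif`, `triplet_count`).
#' @param min_support Minimum reads per allele (default 10).
#' @param gap_min,mad_mult Split-rule constants: accept a split iff the
#'   cluster medians differ by more than `max(gap_min, mad_mult * pooled
#'   within-cluster MAD)`.
#' @param major_fraction Signature share below which reads are re-assigned
#'   (default 0.10).
#' @return List with `assignment` (integer group id per read, NA for reads
#'   in surplus groups beyond three) and `groups` (data.frame: `group_id`,
#'   `signature`, `n_reads`, `median_triplets`, `surplus`).
#' @export
partition_reads <- function(read_calls, min_support = 10L,
                            gap_min = 10, mad_mult = 3,
                            major_fraction = 0.10) {
  n <- nrow(read_calls)
  if (n < min_support) {
    stop(structure(class = c("insufficient_coverage", "error", "condition"),
                   list(message = sprintf(
                     "insufficient_coverage: %d reads < min_support %d",
                     n, min_support), call = NULL)))
  }
  vr <- paste0(ifelse(is.na(read_calls$flank_class), "",
                      read_calls$flank_class),
               ifelse(is.na(read_calls$pre_repeat), "",
                      read_calls$pre_repeat))
  sig <- paste(read_calls$flank_class, read_calls$pre_repeat,
               read_calls$main_motif, sep = "|")
  tab <- table(sig)
  major <- names(tab)[tab >= max(min_support, major_fraction * n)]
  if (length(major) == 0L) {
    sig_assigned <- rep("pooled", n)
  } else {
    sig_assigned <- sig
    minor <- !(sig %in% major)
    if (any(minor)) {
      # A corrupted read carries two signals: its (damaged) variable region
      # and its (nearly intact) repeat count. Reads whose errors delay the
      # tract-start junction absorb mutated tract bases into the variable
      # region, which can leave them closer in edit distance to an
      # unrelated, longer signature; the size term resolves this.
      rep_vr <- vapply(major, function(s) vr[match(s, sig)], "")
      med_cnt <- vapply(major, function(s) {
        stats::median(read_calls$triplet_count[sig == s])
      }, 1)
      d <- utils::adist(vr[minor], rep_vr) +
        0.25 * abs(outer(read_calls$triplet_count[minor], med_cnt, "-"))
      sig_assigned[minor] <- major[max.col(-d, ties.method = "first")]
    }
  }
  assignment <- integer(n)
  next_id <- 1L
  for (s in unique(sig_assigned)) {
    idx <- which(sig_assigned == s)
    ids <- cluster_sizes(read_calls$triplet_count[idx], min_support,
                         gap_min, mad_mult)
    assignment[idx] <- ids + next_id - 1L
    next_id <- next_id + max(ids)
  }
  groups <- do.call(rbind, lapply(sort(unique(assignment)), function(g) {
    sel <- assignment == g
    data.frame(group_id = g,
               signature = names(sort(-table(sig_assigned[sel])))[1L],
               n_reads = sum(sel),
               median_triplets = median_lower(read_calls$triplet_count[sel]),
               stringsAsFactors = FALSE)
  }))
  groups$surplus <- FALSE
  if (nrow(groups) > 3L) {
    keep <- order(-groups$n_reads)[1:3]
    groups$surplus <- !(groups$group_id %in% groups$group_id[keep])
    assignment[assignment %in% groups$group_id[groups$surplus]] <- NA_integer_
  }
  list(assignment = assignment, groups = groups)
}

# Modal (most frequent) value of a character vector, NA-safe.
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  names(sort(-table(x)))[1L]
}

#' Summarize one allele's read group
#'
#' The repeat number is the lower median of the per-read triplet counts (the
#' median, not the mean, is robust to the preferential sequencing of shorter
#' mosaic fragments); its spread is the sample standard deviation (n-1
#' denominator), a readout of somatic mosaicism. The fragment-equivalent
#' size adds the trimmed 146 bp back to the median retained-segment length
#' for direct comparison with fragment-analysis sizing.
#'
#' @param read_calls Data.frame of the group's per-read calls (needs
#'   `triplet_count`, `segment_len`, `flank_class`, `pre_repeat`,
#'   `main_motif`).
#' @param arch An [default_architecture()].
#' @param runs Optional non-canonical run table for interruption typing.
#' @param ... Passed to [classify_interruptions()].
#' @return One-row data.frame (an allele summary, label unset).
#' @export
summarize_allele <- function(read_calls, arch = default_architecture(),
                             runs = NULL, ...) {
  stopifnot(nrow(read_calls) > 0L)
  interruption <- if (is.null(runs)) {
    NA_character_
  } else {
    classify_interruptions(read_calls, runs, ...)
  }
  data.frame(
    label = NA_character_,
    n_reads = nrow(read_calls),
    median_triplets = median_lower(read_calls$triplet_count),
    sd_triplets = stats::sd(read_calls$triplet_count),
    median_retained_bp = median_lower(read_calls$segment_len),
    fragment_equivalent_bp =
      median_lower(read_calls$segment_len) + arch$trim_offset_bp,
    flank_class = modal_value(read_calls$flank_class),
    pre_repeat = modal_value(read_calls$pre_repeat),
    main_motif = modal_value(read_calls$main_motif),
    interruption_class = interruption,
    stringsAsFactors = FALSE
  )
}

# a1 = smallest, a2 = largest, a3 = intermediate (mosaic cases).
assign_allele_labels <- function(medians) {
  k <- length(medians)
  labels <- character(k)
  ord <- order(medians)
  if (k == 1L) {
    labels[ord] <- "a1"
  } else if (k == 2L) {
    labels[ord] <- c("a1", "a2")
  } else {
    labels[ord] <- c("a1", "a3", "a2")
  }
  labels
}

#' Classify a sample genotype from its allele summaries
#'
#' The largest AAG-motif allele drives the class; hexamer (`AAGGAG`) alleles
#' never contribute to pathogenic classes regardless of size. Boundaries:
#' `[180, 250)` intermediate, `[250, 300)` incomplete penetrance, `>= 300`
#' full penetrance. A sample with two or more AAG alleles at or above the
#' pathogenic threshold is a biallelic expansion. Samples whose only
#' expanded allele (>= 180 triplets) is hexameric are `nonpathogenic_motif`.
#'
#' @param summaries Data.frame of allele summaries (one row per allele).
#' @param thresholds A [classification_thresholds()] list.
#' @return List of class `sample_genotype_class` with `class` and
#'   `mosaic_flag`.
#' @export
classify_genotype <- function(summaries, thresholds = classification_thresholds()) {
  stopifnot(nrow(summaries) >= 1L)
  aag <- summaries$main_motif == "AAG"
  n_path_aag <- sum(aag & summaries$median_triplets >= thresholds$pathogenic_min)
  max_aag <- if (any(aag)) max(summaries$median_triplets[aag]) else -Inf
  max_other <- if (any(!aag)) max(summaries$median_triplets[!aag]) else -Inf
  cls <- if (n_path_aag >= 2L) {
    "biallelic_expansion"
  } else if (max_aag >= thresholds$full_penetrance_min) {
    "pathogenic_300_plus"
  } else if (max_aag >= thresholds$pathogenic_min) {
    "incomplete_250_299"
  } else if (max_aag >= thresholds$intermediate_min) {
    "intermediate_180_249"
  } else if (max_other >= thresholds$intermediate_min) {
    "nonpathogenic_motif"
  } else {
    "normal"
  }
  mosaic <- nrow(summaries) == 3L &&
    anyDuplicated(paste(summaries$flank_class, summaries$pre_repeat,
                        summaries$main_motif)) > 0L
  list(class = cls, mosaic_flag = mosaic)
}

#' Correlate somatic instability with expansion size
#'
#' Pearson correlation of per-allele repeat-count standard deviation against
#' median repeat number across alleles, the readout of size-dependent
#' somatic mosaicism.
#'
#' @param medians,sds Numeric vectors (one entry per allele).
#' @return List with `r`, `r_squared`, `p_value`, `conf_int` (95%, Fisher z)
#'   and `n`.
#' @export
instability_correlation <- function(medians, sds) {
  stopifnot(length(medians) == length(sds))
  if (length(medians) < 2L) stop("need at least 2 alleles", call. = FALSE)
  if (stats::sd(medians) == 0 || stats::sd(sds) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  if (length(medians) == 2L) {
    # degenerate perfect fit through two points
    r <- unname(stats::cor(medians, sds))
    return(list(r = r, r_squared = r^2, p_value = NA_real_,
                conf_int = c(NA_real_, NA_real_), n = 2L))
  }
  ct <- stats::cor.test(medians, sds, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, conf_int = as.numeric(ct$conf.int),
       n = length(medians))
}
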