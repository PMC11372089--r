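# Read-level gatekeeping: quality trim/filter, double-flank anchoring with
# edit-tolerant 25-mer matching, strand resolution, and the AAGAAG gate.
#
# Anchor matching uses unit-cost Levenshtein edit distance (indels dominate
# nanopore error), searched as a d = 0, 1, ..., max_edits cascade so each
# read is assigned its lowest-edit hit. Ties between equal-edit hits are
# broken leftmost for the upstream anchor and rightmost for the downstream
# anchor, which maximizes the retained segment (conservative toward keeping
# the full repeat tract).

#' Quality-control parameters
#'
#' Defaults mirror standard amplicon QC: Phred+33, end-trimming at Q10,
#' length gate 200-100000 bp, minimum mean quality 10 computed on post-trim
#' bases as the arithmetic mean of Phred scores.
#'
#' @param min_len,max_len Length gate after trimming.
#' @param trim_q Ends are trimmed until base quality >= `trim_q`.
#' @param min_mean_q Minimum post-trim mean Phred quality.
#' @param qual_offset ASCII offset of the quality encoding (33).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_len = 200L, max_len = 100000L, trim_q = 10L,
                      min_mean_q = 10L, qual_offset = 33L) {
  stopifnot(min_len > 0L, min_len <= max_len)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 trim_q = as.integer(trim_q), min_mean_q = min_mean_q,
                 qual_offset = as.integer(qual_offset)),
            class = "qc_params")
}

#' Quality-trim and filter reads
#'
#' Trims both ends until the base quality reaches `trim_q`, then keeps reads
#' whose trimmed length lies in `[min_len, max_len]` and whose mean Phred
#' quality is at least `min_mean_q`. Idempotent: applying it twice equals
#' applying it once.
#'
#' @param reads Data.frame with `read_id`, `seq`, `qual`.
#' @param params A [qc_params()] object.
#' @return List with `kept` (trimmed reads data.frame) and `rejected`
#'   (data.frame: `read_id`, `reason`).
#' @export
quality_filter <- function(reads, params = qc_params()) {
  n <- nrow(reads)
  keep <- logical(n)
  reason <- character(n)
  seqs <- reads$seq
  quals <- reads$qual
  for (i in seq_len(n)) {
    q <- as.integer(charToRaw(quals[i])) - params$qual_offset
    ok <- which(q >= params$trim_q)
    if (length(ok) == 0L) {
      reason[i] <- "too_short"
      next
    }
    a <- ok[1L]; b <- ok[length(ok)]
    len <- b - a + 1L
    if (len < params$min_len) { reason[i] <- "too_short"; next }
    if (len > params$max_len) { reason[i] <- "too_long"; next }
    if (mean(q[a:b]) < params$min_mean_q) { reason[i] <- "low_mean_q"; next }
    keep[i] <- TRUE
    if (a > 1L || b < length(q)) {
      seqs[i] <- substr(seqs[i], a, b)
      quals[i] <- substr(quals[i], a, b)
    }
  }
  kept <- data.frame(read_id = reads$read_id[keep], seq = seqs[keep],
                     qual = quals[keep], stringsAsFactors = FALSE)
  rejected <- data.frame(read_id = reads$read_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

# Lowest-edit leftmost hit of `pattern` in each of `texts`. Returns a
# data.frame(start, end, edits) with NA where no hit at <= max_edits.
best_left_hit <- function(texts, pattern, max_edits) {
  n <- length(texts)
  start <- end <- edits <- rep(NA_integer_, n)
  todo <- seq_len(n)
  for (d in 0:max_edits) {
    if (length(todo) == 0L) break
    m <- aregexec(pattern, texts[todo], max.distance = d, fixed = TRUE)
    pos <- vapply(m, function(x) x[1L], 1L)
    len <- vapply(m, function(x) attr(x, "match.length")[1L], 1L)
    hit <- pos > 0L
    idx <- todo[hit]
    start[idx] <- pos[hit]
    end[idx] <- pos[hit] + len[hit] - 1L
    edits[idx] <- d
    todo <- todo[!hit]
  }
  data.frame(start = start, end = end, edits = edits)
}

# Lowest-edit rightmost hit: search the reversed strings (edit distance is
# invariant under joint reversal), then map coordinates back.
best_right_hit <- function(texts, pattern, max_edits) {
  rev_str <- function(s) as.character(
    Biostrings::reverse(Biostrings::BStringSet(s)))
  h <- best_left_hit(rev_str(texts), rev_str(pattern), max_edits)
  L <- nchar(texts)
  data.frame(start = L - h$end + 1L, end = L - h$start + 1L, edits = h$edits)
}

# TRUE where a second hit at <= `edits` exists outside the found span
# (amplicon concatemer check). Only reads with a primary hit are examined.
has_second_hit <- function(texts, pattern, span_start, span_end, edits) {
  n <- length(texts)
  out <- logical(n)
  found <- which(!is.na(span_start))
  if (length(found) == 0L) return(out)
  after <- substr(texts[found], span_end[found] + 1L, nchar(texts[found]))
  before <- substr(texts[found], 1L, pmax(0L, span_start[found] - 1L))
  for (side in list(after, before)) {
    long_enough <- nchar(side) >= nchar(pattern) - edits[found]
    if (!any(long_enough)) next
    sub_idx <- which(long_enough)
    # group by edit level to reuse the vectorized matcher
    for (d in unique(edits[found][sub_idx])) {
      ii <- sub_idx[edits[found][sub_idx] == d]
      m <- aregexec(pattern, side[ii], max.distance = d, fixed = TRUE)
      hit <- vapply(m, function(x) x[1L], 1L) > 0L
      out[found[ii][hit]] <- TRUE
    }
  }
  out
}

# Both anchors, one orientation. Returns per-read hit table plus validity.
anchor_pair <- function(texts, arch) {
  up <- best_left_hit(texts, arch$upstream_anchor, arch$max_anchor_edits)
  down <- best_right_hit(texts, arch$downstream_anchor, arch$max_anchor_edits)
  ok_order <- !is.na(up$end) & !is.na(down$start) & up$end < down$start - 1L
  chim <- has_second_hit(texts, arch$upstream_anchor, up$start, up$end,
                         up$edits) |
    has_second_hit(texts, arch$downstream_anchor, down$start, down$end,
                   down$edits)
  list(up = up, down = down, valid = ok_order & !chim,
       chimeric = ok_order & chim,
       found_any = !is.na(up$start) | !is.na(down$start))
}

#' Locate both flanking anchors and extract the repeat-containing segment
#'
#' Finds the lowest-edit occurrence of each 25-mer anchor (edit distance
#' <= `arch$max_anchor_edits`) on the plus strand; reads where both anchors
#' are instead found on the reverse-complement orientation are
#' reverse-complemented before extraction. Reads are accepted only when both
#' anchors are found in one consistent orientation with the upstream anchor
#' before the downstream anchor; the anchors themselves are trimmed off.
#' Reads with an extra non-overlapping anchor hit at equal edit cost are
#' rejected as chimeric.
#'
#' @param reads Data.frame with `read_id`, `seq` (post-QC).
#' @param arch An [default_architecture()].
#' @return List with `segments` (data.frame: `read_id`, `segment`,
#'   `strand_source`, `up_edits`, `down_edits`) and `rejected` (data.frame:
#'   `read_id`, `reason` in `missing_anchor`, `discordant_anchors`,
#'   `chimeric`).
#' @export
locate_and_trim <- function(reads, arch = default_architecture()) {
  n <- nrow(reads)
  seqs <- reads$seq
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  plus <- anchor_pair(seqs, arch)
  minus <- anchor_pair(rc, arch)

  use_plus <- plus$valid & !minus$valid
  use_minus <- minus$valid & !plus$valid
  accepted <- use_plus | use_minus

  reason <- rep(NA_character_, n)
  reason[plus$valid & minus$valid] <- "discordant_anchors"
  reason[!accepted & is.na(reason) & (plus$chimeric | minus$chimeric)] <- "chimeric"
  both_found_one_orient <-
    (!is.na(plus$up$start) & !is.na(plus$down$start)) |
    (!is.na(minus$up$start) & !is.na(minus$down$start))
  mixed_orient <-
    (!is.na(plus$up$start) & !is.na(minus$down$start)) |
    (!is.na(minus$up$start) & !is.na(plus$down$start))
  reason[!accepted & is.na(reason) &
           (both_found_one_orient | mixed_orient)] <- "discordant_anchors"
  reason[!accepted & is.na(reason)] <- "missing_anchor"

  oriented <- ifelse(use_minus, rc, seqs)
  up <- plus$up; down <- plus$down
  up[use_minus, ] <- minus$up[use_minus, ]
  down[use_minus, ] <- minus$down[use_minus, ]
  seg <- rep(NA_character_, n)
  seg[accepted] <- substr(oriented[accepted], up$end[accepted] + 1L,
                          down$start[accepted] - 1L)
  empty <- accepted & !nzchar(seg)
  if (any(empty)) {
    accepted[empty] <- FALSE
    reason[empty] <- "empty_segment"
  }

  segments <- data.frame(
    read_id = reads$read_id[accepted],
    segment = seg[accepted],
    strand_source = ifelse(use_minus[accepted], "-", "+"),
    up_edits = up$edits[accepted],
    down_edits = down$edits[accepted],
    stringsAsFactors = FALSE
  )
  rejected <- data.frame(read_id = reads$read_id[!accepted],
                         reason = reason[!accepted], stringsAsFactors = FALSE)
  rownames(segments) <- rownames(rejected) <- NULL
  list(segments = segments, rejected = rejected)
}

#' The AAGAAG read gate
#'
#' A segment passes iff it contains the sequence `AAGAAG` (two consecutive
#' AAG repeats). Pure hexamer (`AAGGAG`) tracts never contain `AAGAAG`; the
#' optional `allow_hexamer` override also accepts segments containing
#' `AAGGAGAAGGAG`, for hexamer alleles lacking an AAG leader.
#'
#' @param segment Character vector of anchored segments.
#' @param allow_hexamer Also accept two consecutive `AAGGAG` units.
#' @return Logical vector.
#' @examples
#' aag_gate("CTTTCTGTGAAGAAG") # TRUE
#' aag_gate(strrep("AAGGAG", 20)) # FALSE
#' @export
aag_gate <- function(segment, allow_hexamer = FALSE) {
  ok <- grepl("AAGAAG", segment, fixed = TRUE)
  if (allow_hexamer) {
    ok <- ok | grepl("AAGGAGAAGGAG", segment, fixed = TRUE)
  }
  ok & nzchar(segment) & !is.na(segment)
}
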