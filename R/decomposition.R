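# Segment parsing and triplet decomposition. Each anchored segment is split
# into invariable motif, 5'-flank class, pre-repeat and repeat tract; the
# tract is read as non-overlapping 3-mers in a fixed frame anchored at the
# first AAGAAG (the expansion conventionally starts with an AAG motif after
# the pre-repeat).

.TRIPLET_CLASSES <- c("AAG", "GAG", "AGG", "ACG", "AAC")

#' Parse an anchored segment into its structural parts
#'
#' Locates the invariable `CTTTCT` motif (at most 1 edit) near the segment
#' start; the span between its end and the tract start is matched against
#' the flank catalog (exact prefix, longest match first), with an AG-only
#' residue classified as pre-repeat; a non-AG residue (or no catalog match)
#' makes the whole variable region a novel flank class, retained verbatim.
#' The tract starts at the first `AAGAAG` (or, under the hexamer override,
#' the first `AAGGAGAAGGAG` when no `AAGAAG` exists) and runs to the segment
#' end.
#'
#' @param segment Character vector of anchored segments.
#' @param arch An [default_architecture()].
#' @param allow_hexamer Accept hexamer tract starts for segments without an
#'   `AAGAAG` junction.
#' @param search_window Number of leading bases searched for the invariable
#'   motif (default 20).
#' @return Data.frame with one row per segment: `invariable_found`,
#'   `flank_class`, `flank_novel`, `pre_repeat`, `tract_start_offset`
#'   (0-based offset of the tract within the segment; NA if no tract) and
#'   `tract`.
#' @export
parse_segment <- function(segment, arch = default_architecture(),
                          allow_hexamer = FALSE, search_window = 20L) {
  n <- length(segment)
  inv <- arch$invariable_motif
  catalog <- arch$flank_catalog[order(-nchar(arch$flank_catalog))]
  out <- data.frame(
    invariable_found = logical(n), flank_class = NA_character_,
    flank_novel = FALSE, pre_repeat = NA_character_,
    tract_start_offset = NA_integer_, tract = NA_character_,
    stringsAsFactors = FALSE
  )
  heads <- substr(segment, 1L, search_window)
  hit0 <- regexpr(inv, heads, fixed = TRUE)
  for (i in seq_len(n)) {
    pos <- hit0[i]
    len <- nchar(inv)
    if (pos < 0L) {
      m <- aregexec(inv, heads[i], max.distance = 1L, fixed = TRUE)[[1L]]
      if (m[1L] < 0L) next # no_invariable
      pos <- m[1L]
      len <- attr(m, "match.length")[1L]
    }
    out$invariable_found[i] <- TRUE
    rest_start <- pos + len # 1-based start of the variable region
    ts <- regexpr("AAGAAG", substr(segment[i], rest_start, nchar(segment[i])),
                  fixed = TRUE)
    if (ts < 0L && allow_hexamer) {
      ts <- regexpr("AAGGAGAAGGAG",
                    substr(segment[i], rest_start, nchar(segment[i])),
                    fixed = TRUE)
    }
    if (ts < 0L) next # invariable found but no tract
    tract_at <- rest_start + ts - 1L # 1-based within segment
    vr <- substr(segment[i], rest_start, tract_at - 1L)
    fc <- vr
    novel <- TRUE
    pre <- ""
    for (j in seq_along(catalog)) {
      f <- catalog[[j]]
      if (startsWith(vr, f)) {
        residue <- substr(vr, nchar(f) + 1L, nchar(vr))
        if (!grepl("[^AG]", residue)) {
          fc <- names(catalog)[j]
          pre <- residue
          novel <- FALSE
          break
        }
      }
    }
    out$flank_class[i] <- fc
    out$flank_novel[i] <- novel
    out$pre_repeat[i] <- pre
    out$tract_start_offset[i] <- tract_at - 1L # 0-based
    out$tract[i] <- substr(segment[i], tract_at, nchar(segment[i]))
  }
  out
}

#' Decompose a repeat tract into classified triplets
#'
#' Reads non-overlapping 3-mers in a fixed frame from the tract start,
#' classifying each into `AAG`, `GAG`, `AGG`, `ACG`, `AAC` or `OTHER`. When
#' an unclassifiable 3-mer is met the frame is re-anchored at the next
#' `AAGAAG`/`AAGGAG` junction and the skipped bases are emitted as `OTHER`
#' triplets (rounded to the nearest whole triplet), so that a single indel
#' sequencing error desynchronizes at most one position instead of the
#' whole downstream tract. With `resync = FALSE` the frame is fixed
#' throughout. A trailing 1-2 nt remainder is reported but not counted.
#'
#' @param tract A single tract string (frame anchored at its first base).
#' @param resync Re-anchor the frame after unclassifiable triplets
#'   (default `TRUE`).
#' @return Character vector of triplet classes with attribute `remainder`
#'   (0, 1 or 2 leftover nucleotides).
#' @examples
#' decompose_triplets("AAGAAGAAG")
#' @export
decompose_triplets <- function(tract, resync = TRUE) {
  L <- nchar(tract)
  if (L < 3L) {
    return(structure(character(0), remainder = L))
  }
  fixed_frame <- function(s) {
    k <- nchar(s) %/% 3L
    if (k == 0L) return(character(0))
    at <- seq.int(1L, by = 3L, length.out = k)
    trip <- substring(s, at, at + 2L)
    ifelse(trip %in% .TRIPLET_CLASSES, trip, "OTHER")
  }
  if (!resync) {
    return(structure(fixed_frame(tract), remainder = L %% 3L))
  }
  out <- character(0)
  i <- 1L
  while (i + 2L <= L) {
    rest <- substr(tract, i, L)
    cls <- fixed_frame(rest)
    bad <- which(cls == "OTHER")
    if (length(bad) == 0L) {
      out <- c(out, cls)
      i <- i + 3L * length(cls)
      break
    }
    k <- bad[1L]
    out <- c(out, cls[seq_len(k - 1L)])
    p <- i + 3L * (k - 1L) # absolute start of the unclassifiable 3-mer
    m <- regexpr("AAG(AAG|GAG)", substr(tract, p + 1L, min(L, p + 60L)))
    if (m < 0L) { # no junction ahead: emit the tail as OTHER and stop
      out <- c(out, rep("OTHER", (L - p + 1L) %/% 3L))
      i <- L + 1L
      break
    }
    j <- p + as.integer(m) # absolute resync position
    out <- c(out, rep("OTHER", max(0L, as.integer(round((j - p) / 3)))))
    i <- j
  }
  structure(out, remainder = max(0L, L - i + 1L))
}

#' Call the main repeat motif of a read
#'
#' Returns `"AAGGAG"` iff the fraction of adjacent triplet pairs in perfect
#' `AAG`/`GAG` alternation exceeds one half of the pairable positions;
#' otherwise `"AAG"` (ties favor the triplet motif).
#'
#' @param triplet_string Character vector of triplet classes from
#'   [decompose_triplets()].
#' @return `"AAG"` or `"AAGGAG"`.
#' @export
call_main_motif <- function(triplet_string) {
  n <- length(triplet_string)
  if (n == 0L) stop("empty triplet string", call. = FALSE)
  if (n == 1L) return("AAG")
  a <- triplet_string[-n]
  b <- triplet_string[-1L]
  alt <- (a == "AAG" & b == "GAG") | (a == "GAG" & b == "AAG")
  if (mean(alt) > 0.5) "AAGGAG" else "AAG"
}

# Runs of non-canonical triplets in one classified tract. canonical is
# c("AAG") for triplet alleles, c("AAG","GAG") for hexamer alleles.
noncanonical_runs <- function(cls, canonical = "AAG") {
  r <- rle(!(cls %in% canonical))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) {
    return(data.frame(run_start = integer(0), run_end = integer(0),
                      run_len = integer(0), motif = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- starts[keep]; ends <- ends[keep]
  motif <- mapply(function(a, b) {
    tb <- table(cls[a:b])
    names(tb)[which.max(tb)]
  }, starts, ends)
  data.frame(run_start = starts, run_end = ends,
             run_len = ends - starts + 1L, motif = as.character(motif),
             stringsAsFactors = FALSE)
}

#' Classify the interruption pattern of one allele
#'
#' A non-canonical triplet run is a candidate interruption when it occurs at
#' a consistent position (within +/- `position_tol` triplets, measured from
#' the 5' end for runs in the first half of the tract and from the 3' end
#' otherwise) in at least `support_fraction` of the allele's reads.
#' Supported candidates wholly inside the first or last
#' `edge_fraction` of the tract (minimum 3 triplets) give an edge class;
#' any supported candidate elsewhere gives `middle`; no supported candidate
#' gives `pure`. Random sequencing-error runs (e.g. AAC streaks) fail the
#' support requirement because their positions are not reproducible across
#' reads.
#'
#' @param read_calls Data.frame of the allele's per-read calls (needs
#'   `triplet_count` and `main_motif`).
#' @param runs Data.frame of non-canonical runs for those reads (columns
#'   `read_id`, `run_start`, `run_end`, `run_len`, `motif`), as produced by
#'   the pipeline.
#' @param edge_fraction Edge window as a fraction of the tract (default 0.10).
#' @param support_fraction Minimum fraction of reads supporting a candidate
#'   (default 0.5).
#' @param position_tol Position tolerance in triplets (default 2).
#' @return One of `"pure"`, `"middle"`, `"edge_5p"`, `"edge_3p"`,
#'   `"edge_both"`, `"unassessable"`.
#' @export
classify_interruptions <- function(read_calls, runs, edge_fraction = 0.10,
                                   support_fraction = 0.5,
                                   position_tol = 2L) {
  n_reads <- nrow(read_calls)
  if (n_reads < 2L) return("unassessable")
  med_count <- stats::median(read_calls$triplet_count)
  if (nrow(runs) == 0L) return("pure")
  counts <- stats::setNames(read_calls$triplet_count, read_calls$read_id)
  runs <- runs[runs$read_id %in% names(counts), , drop = FALSE]
  if (nrow(runs) == 0L) return("pure")
  rc <- counts[runs$read_id]
  # anchor each run to its nearer tract end so mosaicism does not smear
  # positions; 5'-anchored runs keyed by start, 3'-anchored by distance of
  # the start from the tract end
  mid <- (runs$run_start + runs$run_end) / 2
  from_3p <- mid > rc / 2
  key <- ifelse(from_3p, rc - runs$run_start + 1L, runs$run_start)
  classes <- character(0)
  w <- max(3L, ceiling(edge_fraction * med_count))
  for (side in c(FALSE, TRUE)) {
    sel_side <- which(from_3p == side)
    if (length(sel_side) == 0L) next
    # one vote per read per key: a candidate interruption needs a run at a
    # reproducible position (+/- position_tol) in >= support_fraction of reads
    votes <- unique(data.frame(read = runs$read_id[sel_side],
                               key = key[sel_side]))
    tab <- table(votes$key)
    ks <- as.integer(names(tab))
    counts_at <- as.integer(tab)
    window_support <- vapply(ks, function(p) {
      idx <- abs(votes$key - p) <= position_tol
      length(unique(votes$read[idx]))
    }, 1L)
    active <- ks[window_support / n_reads >= support_fraction]
    # non-maximum suppression: collapse neighboring candidate centers
    while (length(active) > 0L) {
      ws <- window_support[match(active, ks)]
      p <- active[which.max(ws)]
      sel <- sel_side[abs(key[sel_side] - p) <= position_tol]
      e <- stats::median(runs$run_end[sel])
      # distance of the run start from the 3' end, in triplets (1 = last)
      d3 <- stats::median(rc[sel] - runs$run_start[sel] + 1L)
      if (e <= w) classes <- c(classes, "edge_5p")
      else if (d3 <= w) classes <- c(classes, "edge_3p")
      else classes <- c(classes, "middle")
      active <- active[abs(active - p) > 2L * position_tol]
    }
  }
  if (length(classes) == 0L) return("pure")
  if ("middle" %in% classes) return("middle")
  has5 <- "edge_5p" %in% classes
  has3 <- "edge_3p" %in% classes
  if (has5 && has3) "edge_both" else if (has5) "edge_5p" else "edge_3p"
}
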