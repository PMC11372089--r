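# Ground-truth allele grammar: 5'-flank class, optional AG-rich pre-repeat,
# main motif (AAG triplet or AAGGAG hexamer, counted in triplets either
# way), and interruption blocks placed at fixed triplet positions.

#' Describe a ground-truth repeat allele
#'
#' An allele is described by its 5'-flank class (a name from the
#' architecture's flank catalog, or a novel sequence given verbatim), an
#' optional AG-rich pre-repeat, the main repeat motif and the total triplet
#' count. Hexamer (`AAGGAG`) alleles carry a two-triplet `AAG` leader by
#' default so that they contain the `AAGAAG` junction required by the read
#' gate; this can be disabled.
#'
#' @param flank_class Name of a cataloged flank class, or a novel DNA
#'   sequence used verbatim.
#' @param repeat_triplets Total number of triplets in the repeat tract
#'   (leader and interruptions included). Must be >= 2 for `AAG` alleles.
#' @param pre_repeat Optional AG-only pre-repeat sequence (default "").
#' @param main_motif `"AAG"` or `"AAGGAG"`.
#' @param interruptions `NULL` or a data.frame with columns
#'   `position_triplet` (0-based triplet index into the tract), `motif`
#'   (a triplet) and `length_triplets`.
#' @param hexamer_leader For `AAGGAG` alleles, prepend a 2-triplet `AAG`
#'   leader (default `TRUE`).
#' @return An object of class `allele_spec`.
#' @examples
#' allele_spec("GTG", 300)
#' allele_spec("GTG", 120, main_motif = "AAGGAG")
#' @export
allele_spec <- function(flank_class, repeat_triplets, pre_repeat = "",
                        main_motif = c("AAG", "AAGGAG"),
                        interruptions = NULL, hexamer_leader = TRUE) {
  main_motif <- match.arg(main_motif)
  repeat_triplets <- as.integer(repeat_triplets)
  if (main_motif == "AAG" && repeat_triplets < 2L) {
    stop("AAG alleles need repeat_triplets >= 2 (the AAGAAG gate)", call. = FALSE)
  }
  if (repeat_triplets < 1L) stop("repeat_triplets must be positive", call. = FALSE)
  if (nchar(pre_repeat) > 0L && grepl("[^AG]", pre_repeat)) {
    stop("pre_repeat must be AG-only", call. = FALSE)
  }
  if (!is.null(interruptions)) {
    stopifnot(is.data.frame(interruptions),
              all(c("position_triplet", "motif", "length_triplets") %in%
                    names(interruptions)))
    if (any(interruptions$position_triplet < 0L) ||
        any(interruptions$position_triplet >= repeat_triplets)) {
      stop("interruption positions must lie in [0, repeat_triplets)", call. = FALSE)
    }
    if (any(nchar(interruptions$motif) != 3L)) {
      stop("interruption motifs must be triplets", call. = FALSE)
    }
  }
  structure(list(
    flank_class = flank_class,
    pre_repeat = pre_repeat,
    main_motif = main_motif,
    repeat_triplets = repeat_triplets,
    interruptions = interruptions,
    hexamer_leader = isTRUE(hexamer_leader)
  ), class = "allele_spec")
}

# Resolve a flank class against the catalog; novel sequences pass through
# verbatim but must be DNA.
resolve_flank <- function(flank_class, arch) {
  if (is.null(flank_class) || is.na(flank_class) || !nzchar(flank_class)) {
    stop("unknown flank class: provide a catalog name or an explicit novel sequence",
         call. = FALSE)
  }
  if (flank_class %in% names(arch$flank_catalog)) {
    return(unname(arch$flank_catalog[[flank_class]]))
  }
  if (grepl("[^ACGT]", flank_class)) {
    stop("unknown flank class '", flank_class,
         "': not in the catalog and not a DNA sequence", call. = FALSE)
  }
  flank_class
}

# Triplet vector of the repeat tract at a given (possibly mosaic) total
# count. Interruption blocks keep their absolute 0-based positions and are
# clipped to the realized length.
build_tract_triplets <- function(spec, triplets = spec$repeat_triplets) {
  n <- as.integer(triplets)
  if (spec$main_motif == "AAG") {
    tr <- rep("AAG", n)
  } else {
    lead <- if (spec$hexamer_leader) 2L else 0L
    body_n <- n - lead
    body <- rep(c("AAG", "GAG"), length.out = max(0L, body_n))
    tr <- c(rep("AAG", lead), body)[seq_len(n)]
  }
  if (!is.null(spec$interruptions) && nrow(spec$interruptions) > 0L) {
    for (i in seq_len(nrow(spec$interruptions))) {
      p0 <- spec$interruptions$position_triplet[i] # 0-based
      len <- spec$interruptions$length_triplets[i]
      idx <- (p0 + 1L):(p0 + len) # 1-based
      idx <- idx[idx <= n]
      tr[idx] <- spec$interruptions$motif[i]
    }
  }
  tr
}

#' Build the full plus-strand amplicon sequence of an allele
#'
#' Concatenates primer-proximal padding, the upstream anchor, the invariable
#' motif, the flank-class sequence, the pre-repeat, the repeat tract (with
#' interruptions placed at their stated triplet positions), the downstream
#' anchor, and the 3' padding. Both 25-mer anchors occur exactly once.
#'
#' @param spec An [allele_spec()].
#' @param arch An [default_architecture()].
#' @return A single DNA string (plus strand).
#' @examples
#' nchar(build_allele_sequence(allele_spec("GTG", 10)))
#' @export
build_allele_sequence <- function(spec, arch = default_architecture()) {
  stopifnot(inherits(spec, "allele_spec"))
  flank <- resolve_flank(spec$flank_class, arch)
  tract <- paste(build_tract_triplets(spec), collapse = "")
  paste0(arch$primer_pad_5p, arch$upstream_anchor,
         arch$invariable_motif, flank, spec$pre_repeat, tract,
         arch$downstream_anchor, arch$primer_pad_3p)
}
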