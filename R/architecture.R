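# Locus constants and coordinate conventions for the FGF14 intron-1 STR
# amplicon. Genomic coordinates are 1-based inclusive (hg38, as printed in
# the field's catalogs); all internal string offsets are 0-based half-open
# at module boundaries and 1-based inclusive inside R code (substr
# semantics), documented at each conversion.

# Fixed primer-proximal padding so that the non-segment part of a simulated
# amplicon is exactly trim_offset_bp = 146 bp: 48 bp pad + 25 bp anchor on
# each side (48 + 25 + 25 + 48 = 146). Pads start with the published LR-PCR
# primer sequences; fillers are fixed arbitrary sequences free of the
# anchors, of CTTTCT and of AAGAAG.
.PAD_5P <- "AGCAATCGTCAGTCAGTGTAAGCTGACTGCATGTTCGACTGACTTGCA"
.PAD_3P <- "TCACTGGATGTTCAGCTTGACCATGCAGCTCTATGTGGGCAGGAACTG"

#' Default FGF14 amplicon architecture
#'
#' Returns the locus constants for the FGF14 intron-1 AAG short tandem
#' repeat: the two 25-nt flanking anchor sequences used to select and orient
#' reads, the invariable `CTTTCT` motif that precedes the variable 5' region,
#' the catalog of known 5'-flank classes, the maximum edit distance tolerated
#' per anchor, and the two length offsets used for size conversion.
#'
#' Two distinct offsets coexist by design. `trim_offset_bp` (146 bp) is the
#' amplicon length removed by anchor trimming (primer-proximal padding plus
#' both anchors) and is added back to the median retained-segment length when
#' reporting a fragment-equivalent size. `nonrepeat_amplicon_bp` (160 bp) is
#' the implied non-repeat length of a whole LR-PCR fragment, obtained by
#' solving the published conversion pairs (700 bp, 180 repeats) and
#' (670 bp, 170 repeats) for a 3 bp/triplet slope; it decomposes as
#' 146 + 6 (`CTTTCT`) + ~8 bp typical variable-region/pre-repeat allowance.
#' The 8 bp allowance is a reconciliation, not a measured constant, and is
#' used only for whole-fragment conversion.
#'
#' @param flank_catalog Named character vector of known 5'-flank sequences.
#'   Defaults to the five published classes.
#' @param max_anchor_edits Maximum Levenshtein edit distance per anchor
#'   (default 2).
#' @return An object of class `amplicon_architecture` (a list).
#' @examples
#' arch <- default_architecture()
#' arch$upstream_anchor
#' @export
default_architecture <- function(flank_catalog = c(
                                   GTG = "GTG",
                                   GG = "GG",
                                   GGG = "GGG",
                                   GTTAGTCATAGTACCCC = "GTTAGTCATAGTACCCC",
                                   GTTAGTCATAGTACCAG = "GTTAGTCATAGTACCAG"
                                 ),
                                 max_anchor_edits = 2L) {
  arch <- structure(list(
    upstream_anchor   = "ATATCAATATTCTCTATGCAACCAA",
    downstream_anchor = "TAGAAATGTGTTTAAGAATTCCTCA",
    invariable_motif  = "CTTTCT",
    flank_catalog     = flank_catalog,
    max_anchor_edits  = as.integer(max_anchor_edits),
    trim_offset_bp    = 146L,
    nonrepeat_amplicon_bp = 160L,
    reference_region  = list(chrom = "chr13", start = 102161576L, end = 102161726L),
    primer_pad_5p     = .PAD_5P,
    primer_pad_3p     = .PAD_3P
  ), class = "amplicon_architecture")
  validate_architecture(arch)
}

validate_architecture <- function(arch) {
  stopifnot(inherits(arch, "amplicon_architecture"))
  for (a in c(arch$upstream_anchor, arch$downstream_anchor)) {
    if (nchar(a) != 25L || grepl("[^ACGT]", a)) {
      stop("anchors must be 25 nt over {A,C,G,T}", call. = FALSE)
    }
  }
  if (arch$max_anchor_edits < 0L) stop("max_anchor_edits must be >= 0", call. = FALSE)
  if (nchar(arch$primer_pad_5p) + nchar(arch$primer_pad_3p) + 50L !=
      arch$trim_offset_bp) {
    stop("primer pads plus anchors must sum to trim_offset_bp", call. = FALSE)
  }
  arch
}

#' @export
print.amplicon_architecture <- function(x, ...) {
  cat("Amplicon architecture (", x$reference_region$chrom, ":",
      x$reference_region$start, "-", x$reference_region$end, ")\n", sep = "")
  cat("  anchors      :", x$upstream_anchor, "/", x$downstream_anchor, "\n")
  cat("  invariable   :", x$invariable_motif, "\n")
  cat("  flank classes:", paste(names(x$flank_catalog), collapse = ", "), "\n")
  cat("  max edits/anchor:", x$max_anchor_edits,
      " trim offset:", x$trim_offset_bp, "bp",
      " non-repeat fragment:", x$nonrepeat_amplicon_bp, "bp\n")
  invisible(x)
}

#' Convert LR-PCR fragment size to a triplet repeat number
#'
#' Applies the linear conversion implied by the published anchor pairs
#' (700 bp, 180 repeats) and (670 bp, 170 repeats): 3 bp per triplet after
#' subtracting the fixed non-repeat amplicon length, floored to an integer.
#'
#' @param fragment_bp Integer vector of fragment sizes in bp; each must be at
#'   least `arch$nonrepeat_amplicon_bp`.
#' @param arch An [default_architecture()] object.
#' @return Integer vector of triplet repeat numbers.
#' @examples
#' fragment_to_repeats(700) # 180
#' fragment_to_repeats(670) # 170
#' @export
fragment_to_repeats <- function(fragment_bp, arch = default_architecture()) {
  if (any(!is.finite(fragment_bp))) stop("fragment_bp must be finite", call. = FALSE)
  if (any(fragment_bp < arch$nonrepeat_amplicon_bp)) {
    stop("fragment below the non-repeat amplicon length (",
         arch$nonrepeat_amplicon_bp, " bp): no repeat content representable",
         call. = FALSE)
  }
  as.integer(floor((fragment_bp - arch$nonrepeat_amplicon_bp) / 3))
}

#' Convert a triplet repeat number to an LR-PCR fragment size
#'
#' Exact inverse of [fragment_to_repeats()]: `3 * triplets +
#' nonrepeat_amplicon_bp`.
#'
#' @param triplets Non-negative integer vector of repeat numbers.
#' @inheritParams fragment_to_repeats
#' @return Integer vector of fragment sizes in bp.
#' @examples
#' repeats_to_fragment(180) # 700
#' @export
repeats_to_fragment <- function(triplets, arch = default_architecture()) {
  if (any(!is.finite(triplets)) || any(triplets < 0)) {
    stop("triplets must be non-negative", call. = FALSE)
  }
  as.integer(3L * as.integer(triplets) + arch$nonrepeat_amplicon_bp)
}

#' Pathogenicity classification thresholds
#'
#' Repeat-number thresholds used for genotype classification: 180 repeats
#' (intermediate, matching the 700 bp fragment cutoff under the size
#' conversion), 250 (pathogenic with incomplete penetrance) and 300 (full
#' penetrance).
#'
#' @return A list with fields `intermediate_min`, `pathogenic_min`,
#'   `full_penetrance_min`, `fragment_intermediate_bp`.
#' @export
classification_thresholds <- function() {
  th <- list(
    intermediate_min = 180L,
    pathogenic_min = 250L,
    full_penetrance_min = 300L,
    fragment_intermediate_bp = 700L
  )
  stopifnot(th$intermediate_min < th$pathogenic_min,
            th$pathogenic_min < th$full_penetrance_min)
  th
}

#' Serialize an architecture to JSON
#'
#' @param arch An architecture object.
#' @param path File path to write; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_architecture <- function(arch, path = NULL) {
  x <- unclass(arch)
  x$flank_catalog <- as.list(x$flank_catalog) # keep names through JSON
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read an architecture from JSON
#'
#' @param path File written by [write_architecture()].
#' @return An `amplicon_architecture` object.
#' @export
read_architecture <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$flank_catalog <- unlist(x$flank_catalog)
  x$max_anchor_edits <- as.integer(x$max_anchor_edits)
  x$trim_offset_bp <- as.integer(x$trim_offset_bp)
  x$nonrepeat_amplicon_bp <- as.integer(x$nonrepeat_amplicon_bp)
  validate_architecture(structure(x, class = "amplicon_architecture"))
}

#' Write an ExpansionHunter-style variant catalog for the locus
#'
#' Convenience writer producing a single-locus catalog JSON usable with
#' short-read STR genotypers.
#'
#' @param path Output JSON path.
#' @param arch An architecture object.
#' @param locus_id Locus identifier (default "FGF14").
#' @param motif Repeat motif (default "AAG").
#' @return `path`, invisibly.
#' @export
write_variant_catalog <- function(path, arch = default_architecture(),
                                  locus_id = "FGF14", motif = "AAG") {
  rr <- sprintf("%s:%d-%d", arch$reference_region$chrom,
                arch$reference_region$start, arch$reference_region$end)
  catalog <- list(list(
    LocusId = locus_id,
    LocusStructure = sprintf("(%s)*", motif),
    ReferenceRegion = rr,
    VariantType = "Repeat"
  ))
  writeLines(jsonlite::toJSON(catalog, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}
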