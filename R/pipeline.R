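# End-to-end orchestration: FASTQ -> QC -> anchoring -> gate -> parsing ->
# allele partition -> genotype, with gate counts recorded at every stage and
# per-read failures logged, never fatal.

#' Pipeline run configuration
#'
#' Bundles every tunable of the read-to-genotype chain so a run is
#' reproducible from (config, inputs). Serializable to JSON.
#'
#' @param arch An [default_architecture()].
#' @param qc A [qc_params()].
#' @param thresholds A [classification_thresholds()].
#' @param min_support Minimum reads per allele (default 10).
#' @param gap_min,mad_mult Allele split-rule constants (see
#'   [partition_reads()]).
#' @param edge_fraction,support_fraction Interruption-typing parameters (see
#'   [classify_interruptions()]).
#' @param allow_hexamer Accept hexamer-only reads at the gate and in tract
#'   anchoring.
#' @param seed Seed for the run's randomness (waterfall subsampling).
#' @return A list of class `run_config`.
#' @export
run_config <- function(arch = default_architecture(), qc = qc_params(),
                       thresholds = classification_thresholds(),
                       min_support = 10L, gap_min = 10, mad_mult = 3,
                       edge_fraction = 0.10, support_fraction = 0.5,
                       allow_hexamer = FALSE, seed = 1L) {
  structure(list(arch = arch, qc = qc, thresholds = thresholds,
                 min_support = as.integer(min_support), gap_min = gap_min,
                 mad_mult = mad_mult, edge_fraction = edge_fraction,
                 support_fraction = support_fraction,
                 allow_hexamer = isTRUE(allow_hexamer),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON path.
#' @return `path` (writer) or a `run_config` (reader).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$arch <- unclass(x$arch)
  x$arch$flank_catalog <- as.list(x$arch$flank_catalog)
  x$qc <- unclass(x$qc)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$arch$flank_catalog <- unlist(x$arch$flank_catalog)
  arch <- validate_architecture(structure(
    lapply(x$arch, function(v) v), class = "amplicon_architecture"))
  arch$max_anchor_edits <- as.integer(arch$max_anchor_edits)
  arch$trim_offset_bp <- as.integer(arch$trim_offset_bp)
  arch$nonrepeat_amplicon_bp <- as.integer(arch$nonrepeat_amplicon_bp)
  run_config(arch = arch,
             qc = do.call(qc_params, x$qc[c("min_len", "max_len", "trim_q",
                                            "min_mean_q", "qual_offset")]),
             min_support = x$min_support, gap_min = x$gap_min,
             mad_mult = x$mad_mult, edge_fraction = x$edge_fraction,
             support_fraction = x$support_fraction,
             allow_hexamer = x$allow_hexamer, seed = x$seed)
}

# Per-read structural calls for anchored segments. Returns read_calls (one
# row per parsable read), runs (non-canonical triplet runs, long) and a
# rejection table for unparsable reads.
call_reads <- function(segments, arch = default_architecture(),
                       allow_hexamer = FALSE) {
  ps <- parse_segment(segments$segment, arch, allow_hexamer = allow_hexamer)
  parsable <- ps$invariable_found & !is.na(ps$tract)
  reason <- ifelse(!ps$invariable_found, "no_invariable", "no_tract")
  rejected <- data.frame(read_id = segments$read_id[!parsable],
                         reason = reason[!parsable], stringsAsFactors = FALSE)
  idx <- which(parsable)
  n <- length(idx)
  calls <- data.frame(
    read_id = segments$read_id[idx],
    segment_len = nchar(segments$segment[idx]),
    flank_class = ps$flank_class[idx],
    flank_novel = ps$flank_novel[idx],
    pre_repeat = ps$pre_repeat[idx],
    tract_start_offset = ps$tract_start_offset[idx],
    main_motif = NA_character_,
    triplet_count = NA_integer_,
    remainder = NA_integer_,
    stringsAsFactors = FALSE
  )
  runs_list <- vector("list", n)
  for (j in seq_len(n)) {
    cls <- decompose_triplets(ps$tract[idx[j]])
    calls$triplet_count[j] <- length(cls)
    calls$remainder[j] <- attr(cls, "remainder")
    mm <- call_main_motif(cls)
    calls$main_motif[j] <- mm
    canon <- if (mm == "AAGGAG") c("AAG", "GAG") else "AAG"
    rr <- noncanonical_runs(cls, canon)
    if (nrow(rr) > 0L) {
      rr$read_id <- calls$read_id[j]
      runs_list[[j]] <- rr
    }
  }
  runs <- do.call(rbind, runs_list)
  if (is.null(runs)) {
    runs <- data.frame(run_start = integer(0), run_end = integer(0),
                       run_len = integer(0), motif = character(0),
                       read_id = character(0), stringsAsFactors = FALSE)
  }
  list(read_calls = calls, runs = runs, rejected = rejected)
}

#' Call the genotype of one sample from its reads
#'
#' Runs the full read-level chain (quality filter, double-flank anchoring
#' and trimming, AAGAAG gate, segment parsing) and the allele-level chain
#' (signature/size partition, per-allele summaries, interruption typing,
#' genotype classification). Per-read failures are recorded with reason
#' codes; only a sample-wide lack of usable reads aborts the call.
#'
#' @param reads Data.frame with `read_id`, `seq`, `qual` (e.g. from
#'   [read_fastq()] or [simulate_sample()]).
#' @param sample_id Sample identifier carried into outputs.
#' @param config A [run_config()].
#' @return List of class `sample_genotype`: `genotype` (one row per allele,
#'   plus sample-level class), `read_calls` (with allele assignment),
#'   `runs`, `rejected`, `gate_counts`.
#' @export
call_sample <- function(reads, sample_id = "sample", config = run_config()) {
  arch <- config$arch
  qf <- quality_filter(reads, config$qc)
  lt <- locate_and_trim(qf$kept, arch)
  gate_ok <- aag_gate(lt$segments$segment, allow_hexamer = config$allow_hexamer)
  gated <- lt$segments[gate_ok, , drop = FALSE]
  gate_rej <- data.frame(read_id = lt$segments$read_id[!gate_ok],
                         reason = rep("no_aagaag", sum(!gate_ok)),
                         stringsAsFactors = FALSE)
  cr <- call_reads(gated, arch, allow_hexamer = config$allow_hexamer)
  rejected <- rbind(qf$rejected, lt$rejected, gate_rej, cr$rejected)
  rownames(rejected) <- NULL
  read_calls <- cr$read_calls

  gate_counts <- data.frame(
    stage = c("input", "qc_pass", "anchored", "gate_pass", "parsed"),
    n = c(nrow(reads), nrow(qf$kept), nrow(lt$segments), nrow(gated),
          nrow(read_calls)),
    stringsAsFactors = FALSE
  )

  part <- tryCatch(
    partition_reads(read_calls, min_support = config$min_support,
                    gap_min = config$gap_min, mad_mult = config$mad_mult),
    insufficient_coverage = function(e) e
  )
  if (inherits(part, "condition")) {
    genotype <- data.frame(sample_id = sample_id, label = NA_character_,
                           class = "insufficient_coverage",
                           stringsAsFactors = FALSE)
    out <- list(genotype = genotype, read_calls = read_calls,
                runs = cr$runs, rejected = rejected,
                gate_counts = gate_counts)
    class(out) <- "sample_genotype"
    return(out)
  }
  read_calls$allele_group <- part$assignment

  live <- part$groups$group_id[!part$groups$surplus]
  summaries <- do.call(rbind, lapply(live, function(g) {
    sel <- !is.na(read_calls$allele_group) & read_calls$allele_group == g
    grp <- read_calls[sel, , drop = FALSE]
    # robust trim: stray mis-decoded reads too few to cluster on their own
    # would otherwise pollute the allele's mosaicism readout
    dev <- abs(grp$triplet_count - stats::median(grp$triplet_count))
    cut <- max(10, 5 * stats::mad(grp$triplet_count))
    if (sum(dev <= cut) >= config$min_support) {
      grp <- grp[dev <= cut, , drop = FALSE]
    }
    summarize_allele(grp, arch,
                     runs = cr$runs[cr$runs$read_id %in% grp$read_id, ,
                                    drop = FALSE],
                     edge_fraction = config$edge_fraction,
                     support_fraction = config$support_fraction)
  }))
  summaries$label <- assign_allele_labels(summaries$median_triplets)
  summaries <- summaries[order(summaries$label), , drop = FALSE]
  gcls <- classify_genotype(summaries, config$thresholds)
  genotype <- cbind(sample_id = sample_id, summaries,
                    class = gcls$class, mosaic_flag = gcls$mosaic_flag,
                    note = if (nrow(summaries) == 1L) {
                      "single_allele_group; possible homozygosity or allele dropout"
                    } else "",
                    stringsAsFactors = FALSE)
  rownames(genotype) <- NULL
  out <- list(genotype = genotype, read_calls = read_calls, runs = cr$runs,
              rejected = rejected, gate_counts = gate_counts,
              surplus_groups = part$groups[part$groups$surplus, , drop = FALSE])
  class(out) <- "sample_genotype"
  out
}

#' @export
print.sample_genotype <- function(x, ...) {
  cat("Sample genotype:", unique(x$genotype$sample_id), "\n")
  if ("median_triplets" %in% names(x$genotype)) {
    for (i in seq_len(nrow(x$genotype))) {
      g <- x$genotype[i, ]
      cat(sprintf("  %s: %d triplets (sd %.1f, %d reads, %s%s%s, %s)\n",
                  g$label, g$median_triplets, g$sd_triplets, g$n_reads,
                  g$flank_class,
                  ifelse(nzchar(g$pre_repeat), paste0("+", g$pre_repeat), ""),
                  paste0(", ", g$main_motif), g$interruption_class))
    }
  }
  cat("  class:", x$genotype$class[1L], "\n")
  invisible(x)
}

#' Run the pipeline over one or more FASTQ files
#'
#' @param fastq Named character vector of FASTQ paths (names = sample ids)
#'   or a named list of read data.frames.
#' @param config A [run_config()].
#' @param out_prefix If non-`NULL`, writes `<prefix>_genotypes.tsv`,
#'   `<prefix>_read_calls.tsv`, `<prefix>_rejected.tsv` and
#'   `<prefix>_gate_counts.tsv`.
#' @return List with `genotypes`, `read_calls`, `rejected`, `gate_counts`
#'   (all samples bound together) and `samples` (per-sample
#'   [call_sample()] results).
#' @export
run_pipeline <- function(fastq, config = run_config(), out_prefix = NULL) {
  if (is.null(names(fastq)) || any(!nzchar(names(fastq)))) {
    stop("fastq inputs must be named by sample id", call. = FALSE)
  }
  samples <- lapply(names(fastq), function(sid) {
    reads <- if (is.character(fastq)) {
      if (!file.exists(fastq[[sid]])) {
        stop("unreadable input: ", fastq[[sid]], call. = FALSE)
      }
      read_fastq(fastq[[sid]])
    } else {
      fastq[[sid]]
    }
    call_sample(reads, sample_id = sid, config = config)
  })
  names(samples) <- names(fastq)
  bind <- function(field) {
    do.call(rbind, lapply(names(samples), function(sid) {
      x <- samples[[sid]][[field]]
      if (is.null(x) || nrow(x) == 0L) return(NULL)
      if (!"sample_id" %in% names(x)) x <- cbind(sample_id = sid, x)
      x
    }))
  }
  out <- list(genotypes = bind("genotype"), read_calls = bind("read_calls"),
              rejected = bind("rejected"), gate_counts = bind("gate_counts"),
              samples = samples)
  if (!is.null(out_prefix)) {
    for (nm in c("genotypes", "read_calls", "rejected", "gate_counts")) {
      utils::write.table(out[[nm]], paste0(out_prefix, "_", nm, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' Waterfall export: per-read triplet classes for one allele
#'
#' Produces the long-format matrix behind a waterfall plot: one row per
#' (read, triplet position) with its class. At most `max_reads` reads are
#' sampled (seeded) per call.
#'
#' @param segments Data.frame with `read_id`, `segment` (one allele's
#'   reads).
#' @param arch An [default_architecture()].
#' @param max_reads Maximum reads displayed (default 300).
#' @param seed Sampling seed.
#' @param allow_hexamer Passed to [parse_segment()].
#' @return Data.frame with `read_id`, `row`, `triplet_index`, `class`.
#' @export
export_waterfall <- function(segments, arch = default_architecture(),
                             max_reads = 300L, seed = 1L,
                             allow_hexamer = FALSE) {
  if (nrow(segments) > max_reads) {
    keep <- withr::with_seed(seed, sample.int(nrow(segments), max_reads))
    segments <- segments[sort(keep), , drop = FALSE]
  }
  ps <- parse_segment(segments$segment, arch, allow_hexamer = allow_hexamer)
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    if (is.na(ps$tract[i])) return(NULL)
    cls <- decompose_triplets(ps$tract[i])
    if (length(cls) == 0L) return(NULL)
    data.frame(read_id = segments$read_id[i], row = i,
               triplet_index = seq_along(cls), class = as.character(cls),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # order rows by read length, longest on top, as waterfall plots are drawn
  if (!is.null(out)) {
    len <- tapply(out$triplet_index, out$read_id, max)
    out$row <- match(out$read_id, names(sort(len, decreasing = TRUE)))
  }
  out
}

.WATERFALL_COLORS <- c(AAG = "#2166ac", GAG = "#ffd92f", AGG = "#d73027",
                       ACG = "#1a9850", AAC = "#f781bf", OTHER = "#000000")

#' Plot a waterfall matrix
#'
#' Renders the classic per-read color-strip plot: AAG blue, GAG yellow, AGG
#' red, ACG green, AAC pink, other black.
#'
#' @param wf Long data.frame from [export_waterfall()].
#' @param main Plot title.
#' @return Invisibly, the class-indexed matrix drawn.
#' @export
plot_waterfall <- function(wf, main = "") {
  classes <- names(.WATERFALL_COLORS)
  nr <- max(wf$row)
  nc <- max(wf$triplet_index)
  m <- matrix(NA_integer_, nrow = nr, ncol = nc)
  m[cbind(wf$row, wf$triplet_index)] <- match(wf$class, classes)
  graphics::image(t(m[rev(seq_len(nr)), , drop = FALSE]),
                  col = .WATERFALL_COLORS, zlim = c(1, length(classes)),
                  axes = FALSE, main = main,
                  xlab = "triplet index", ylab = "reads")
  invisible(m)
}

# ---- fixture registry -------------------------------------------------

.FIXTURES <- list(
  biallelic_204_311 = function(arch) {
    sample_sim_spec(
      alleles = list(allele_spec("GTG", 204), allele_spec("GTG", 311)),
      n_reads = 160L, seed = 104L)
  },
  hexamer = function(arch) {
    sample_sim_spec(
      alleles = list(allele_spec("GTG", 25),
                     allele_spec("GTG", 150, main_motif = "AAGGAG")),
      n_reads = 160L, seed = 105L)
  },
  mosaic_trimodal = function(arch) {
    sample_sim_spec(
      alleles = list(allele_spec("GTG", 30), allele_spec("GTG", 270),
                     allele_spec("GTG", 330)),
      n_reads = 240L, seed = 106L)
  },
  interrupted_acg = function(arch) {
    sample_sim_spec(
      alleles = list(
        allele_spec("GTG", 25),
        allele_spec("GTG", 100,
                    interruptions = data.frame(position_triplet = 50L,
                                               motif = "ACG",
                                               length_triplets = 3L))),
      n_reads = 160L, seed = 107L)
  }
)

#' Generate a named test fixture
#'
#' Small simulated samples with known structure, generated on demand with
#' fixed seeds: `biallelic_204_311` (two AAG alleles separated by size),
#' `hexamer` (an AAGGAG expansion with AAG leader plus a small AAG allele),
#' `mosaic_trimodal` (three same-signature size clusters), and
#' `interrupted_acg` (a middle ACG block).
#'
#' @param name Fixture name.
#' @param arch An [default_architecture()].
#' @return List with `reads`, `truth` and the `sim_spec` used.
#' @export
make_fixture <- function(name, arch = default_architecture()) {
  if (!name %in% names(.FIXTURES)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.FIXTURES), collapse = ", "), call. = FALSE)
  }
  spec <- .FIXTURES[[name]](arch)
  sim <- simulate_sample(spec, arch, id_prefix = name)
  list(reads = sim$reads, truth = sim$truth, sim_spec = spec)
}
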