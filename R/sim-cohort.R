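# Cohort-level generators: diploid validation samples with realistic
# flank/size association, case-control larger-allele size distributions,
# and an age-at-onset model calibrated to a target R^2. These encode the
# study conditions the read-level simulator is exercised under; parameter
# choices are documented in the methods vignette.

# Flank class by allele size, following the observed size association:
# GTTAGTCATAGTACCCC only in small alleles (<= 21), GTG across the mid
# range, GG/GGG only in large expansions (>= 326).
flank_for_size <- function(triplets) {
  if (triplets <= 21L) return("GTTAGTCATAGTACCCC")
  if (triplets < 326L) return("GTG")
  sample(c("GTG", "GG", "GGG"), 1L)
}

# Pre-repeats are strongly enriched in larger alleles.
pre_for_size <- function(triplets) {
  p <- if (triplets >= 180L) 0.6 else 0.1
  if (stats::runif(1L) < p) sample(c("AAGAG", "AAGAAAGAG"), 1L) else ""
}

#' Simulate a diploid validation sample with known allele sizes
#'
#' Builds a two-allele sample: `a1` drawn from the common small-allele range
#' (9-50 triplets) and `a2` across the full spectrum (9-400 by default),
#' re-drawn until the two differ by at least `min_separation` triplets
#' (heterozygous validation design: sizing accuracy is assessed on
#' resolvable alleles). Flank classes and pre-repeats follow the observed
#' size associations; all error processes use the generator defaults.
#'
#' @param seed Integer seed (also seeds the read simulation).
#' @param n_reads Reads per sample (default 500).
#' @param a2_range Size range of the variable allele (default `c(9, 400)`).
#' @param min_separation Minimum |a2 - a1| in triplets (default 30).
#' @param ... Overrides passed to [sample_sim_spec()].
#' @return List with `sim_spec`, `truth_triplets` (length 2) and the
#'   simulated `reads`/`truth` tables.
#' @export
sim_validation_sample <- function(seed, n_reads = 500L,
                                  a2_range = c(9L, 400L),
                                  min_separation = 30L, ...) {
  draws <- withr::with_seed(seed, {
    a1 <- sample(9:50, 1L)
    repeat {
      a2 <- sample(a2_range[1]:a2_range[2], 1L)
      if (abs(a2 - a1) >= min_separation) break
    }
    list(a1 = a1, a2 = a2,
         f1 = flank_for_size(a1), f2 = flank_for_size(a2),
         p1 = pre_for_size(a1), p2 = pre_for_size(a2))
  })
  spec <- sample_sim_spec(
    alleles = list(
      allele_spec(draws$f1, draws$a1, pre_repeat = draws$p1),
      allele_spec(draws$f2, draws$a2, pre_repeat = draws$p2)
    ),
    n_reads = n_reads, seed = seed, ...
  )
  sim <- simulate_sample(spec, id_prefix = sprintf("s%d", seed))
  list(sim_spec = spec, truth_triplets = c(draws$a1, draws$a2),
       reads = sim$reads, truth = sim$truth)
}

#' Simulate a case-control cohort of larger-allele sizes
#'
#' Draws the larger-allele repeat number per subject from a long-tailed
#' baseline (log-normal around the common small-allele mode) plus, in
#' cases, an expansion component with probability `case_expansion_rate`.
#' With `shift = 0` and `case_expansion_rate = 0` the two groups are
#' exchangeable (null cohort).
#'
#' @param n_cases,n_controls Group sizes (defaults 148 and 802, typical
#'   index-patient and population-control cohort sizes).
#' @param case_expansion_rate Probability a case carries an expanded larger
#'   allele (default 0.3).
#' @param expansion_range Expanded-allele size range (default
#'   `c(180, 500)`).
#' @param shift Additive shift of the case baseline (default 0).
#' @param seed Integer seed.
#' @return Data.frame with `sample_id`, `group`, `larger_allele_triplets`.
#' @export
sim_size_cohort <- function(n_cases = 148L, n_controls = 802L,
                            case_expansion_rate = 0.3,
                            expansion_range = c(180, 500),
                            shift = 0, seed = 1L) {
  withr::with_seed(seed, {
    base <- function(n) pmax(9, round(stats::rlnorm(n, log(25), 0.45)))
    ctrl <- base(n_controls)
    cas <- base(n_cases) + shift
    expanded <- stats::runif(n_cases) < case_expansion_rate
    cas[expanded] <- round(stats::runif(sum(expanded),
                                        expansion_range[1],
                                        expansion_range[2]))
    data.frame(
      sample_id = sprintf("s%04d", seq_len(n_cases + n_controls)),
      group = rep(c("case", "control"), c(n_cases, n_controls)),
      larger_allele_triplets = c(cas, ctrl),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate age at onset with a calibrated repeat-size effect
#'
#' `AAO = intercept - slope * repeats + noise`, with the noise variance set
#' so the population R^2 equals `r_squared` given the realized spread of
#' repeat sizes. Used to test that the correlation machinery recovers a
#' known coefficient of determination.
#'
#' @param n Number of patients (default 42).
#' @param repeats_range Repeat sizes drawn uniformly from this range
#'   (default `c(254, 937)`).
#' @param r_squared Target population R^2 (default 0.27).
#' @param intercept,slope Linear model parameters (defaults 75 years and
#'   0.04 years per repeat).
#' @param seed Integer seed.
#' @return Data.frame with `repeats` and `aao`.
#' @export
sim_aao_cohort <- function(n = 42L, repeats_range = c(254, 937),
                           r_squared = 0.27, intercept = 75, slope = 0.04,
                           seed = 1L) {
  stopifnot(r_squared > 0, r_squared < 1)
  withr::with_seed(seed, {
    reps <- stats::runif(n, repeats_range[1], repeats_range[2])
    signal_var <- slope^2 * stats::var(reps)
    noise_sd <- sqrt(signal_var * (1 - r_squared) / r_squared)
    aao <- intercept - slope * reps + stats::rnorm(n, 0, noise_sd)
    data.frame(repeats = reps, aao = aao)
  })
}
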