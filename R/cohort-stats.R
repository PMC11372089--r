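# Cohort-level statistical layer: 2x2 association tests with log2 odds
# ratios, size-bin enrichment with Bonferroni correction, group comparisons
# by Mann-Whitney with Holm correction, Pearson correlation with Fisher-z
# intervals, and the qPCR relative-abundance formula. Exact tests come from
# base R (fisher.test, wilcox.test); the odds ratio is the cross-product
# (a d)/(b c), not the conditional MLE, with a Haldane-Anscombe 0.5
# correction for zero cells.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p sums all hypergeometric tables whose probability does not
#' exceed that of the observed table (probability-mass method). The returned
#' odds ratio is the sample cross-product `(a*d)/(b*c)`.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are the factor of
#'   interest (e.g. in-bin / out-of-bin), columns the groups.
#' @param correct Apply the Haldane-Anscombe 0.5 correction to the OR when
#'   any cell is zero (default `TRUE`); the p-value is never corrected.
#' @return List with `OR`, `log2_OR`, `p_value`, and `zero_corrected`.
#' @examples
#' fisher_exact_2x2(2, 1, 1, 2)$OR # 4
#' @export
fisher_exact_2x2 <- function(a, b, c, d, correct = TRUE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("all-zero table", call. = FALSE)
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE))$p.value
  zero <- any(cells == 0)
  or <- if (zero && correct) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(OR = or, log2_OR = log2(or), p_value = p,
       zero_corrected = zero && correct)
}

#' Size-bin enrichment of larger alleles in cases versus controls
#'
#' For each repeat-number bin (half-open intervals), builds the 2x2 table
#' (cases in bin, cases out of bin, controls in bin, controls out of bin),
#' computes the cross-product odds ratio (log2-transformed; positive =
#' enrichment in cases, negative = depletion), a two-sided Fisher p, and a
#' Bonferroni-adjusted p over the number of bins.
#'
#' @param cohort Data.frame with `group` (`"case"`/`"control"`) and
#'   `larger_allele_triplets`.
#' @param edges Bin edges; bin i is `[edges[i], edges[i+1])`. Default:
#'   width-20 bins over `[0, 360)` plus `[360, Inf)`.
#' @param m Multiplicity for the Bonferroni correction (default: number of
#'   bins).
#' @return Data.frame with one row per bin: `bin_lo`, `bin_hi`, `a`, `b`,
#'   `c`, `d`, `OR`, `log2_OR`, `p_raw`, `p_adj`, `direction`,
#'   `zero_corrected`.
#' @export
bin_enrichment <- function(cohort, edges = c(seq(0, 360, by = 20), Inf),
                           m = NULL) {
  stopifnot(all(c("group", "larger_allele_triplets") %in% names(cohort)))
  x_case <- cohort$larger_allele_triplets[cohort$group == "case"]
  x_ctrl <- cohort$larger_allele_triplets[cohort$group == "control"]
  if (length(x_case) == 0L || length(x_ctrl) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  edges <- sort(edges)
  nb <- length(edges) - 1L
  if (is.null(m)) m <- nb
  out <- vector("list", nb)
  for (i in seq_len(nb)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    a <- sum(x_case >= lo & x_case < hi)
    b <- length(x_case) - a
    cc <- sum(x_ctrl >= lo & x_ctrl < hi)
    d <- length(x_ctrl) - cc
    ft <- fisher_exact_2x2(a, b, cc, d)
    out[[i]] <- data.frame(
      bin_lo = lo, bin_hi = hi, a = a, b = b, c = cc, d = d,
      OR = ft$OR, log2_OR = ft$log2_OR, p_raw = ft$p_value,
      p_adj = min(1, m * ft$p_value),
      direction = if (ft$log2_OR >= 0) "enrichment" else "depletion",
      zero_corrected = ft$zero_corrected,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p by enumeration when the pooled sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. U is the statistic for the first group.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Pooled size up to which the exact distribution is used
#'   (default 12).
#' @return List with `U` and `p_value`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Holm step-down adjustment
#'
#' Step-down Holm correction with monotonicity enforcement, capped at 1.
#' Dominates Bonferroni element-wise.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Pearson correlation with confidence interval
#'
#' @param x,y Numeric vectors, `n >= 3`, both with positive variance.
#' @return List with `r`, `r_squared`, `p_value`, `conf_int` (95%,
#'   Fisher z) and `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, conf_int = as.numeric(ct$conf.int),
       n = length(x))
}

#' qPCR relative abundance, r = 2^(-ddCt)
#'
#' Per-sample `dCt = Ct(target) - Ct(control region)`; the default
#' normalization divides by the mean control-cohort dCt (the ratio form as
#' used for this locus), with the conventional subtractive form available
#' via `method = "difference"`. The ratio form is undefined for a zero
#' control mean.
#'
#' @param ct_target,ct_control Numeric vectors of Ct values for the tested
#'   individuals.
#' @param reference_dct Mean dCt of the control individuals (a scalar), or a
#'   vector of control dCt values whose mean is taken.
#' @param method `"ratio"` (default) or `"difference"`.
#' @return List with `ddct` and `r` (per-sample relative abundance).
#' @examples
#' ddct_relative_abundance(10, 9, 1)$r # ddCt = 1 -> r = 0.5
#' @export
ddct_relative_abundance <- function(ct_target, ct_control, reference_dct,
                                    method = c("ratio", "difference")) {
  method <- match.arg(method)
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_control)),
            all(is.finite(reference_dct)))
  dct <- ct_target - ct_control
  ref <- mean(reference_dct)
  ddct <- if (method == "ratio") {
    if (ref == 0) {
      stop("control-mean dCt is zero: the ratio form is undefined; ",
           "use method = \"difference\"", call. = FALSE)
    }
    dct / ref
  } else {
    dct - ref
  }
  list(ddct = ddct, r = 2^(-ddct))
}
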