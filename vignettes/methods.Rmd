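---
title: "Methods: repeat-expansion genotyping from targeted long-read amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-expansion genotyping from targeted long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscope)
```

## The problem and the model

The *FGF14* intron-1 short tandem repeat is highly polymorphic: alleles
range from a handful of triplets to nearly a thousand, the repeat motif can
be the pathogenic AAG triplet or the benign AAGGAG hexamer, and the tract is
embedded in a structured context — an invariable `CTTTCT` motif, a variable
5'-flank sequence, an optional AG-rich pre-repeat, and possible interruption
blocks. Expanded alleles are somatically unstable, so a single individual's
amplicon reads form a distribution of repeat counts rather than a point.
`repeatscope` models one LR-PCR amplicon spanning this locus and treats each
sequencing read as a noisy observation of one of 1–3 underlying alleles.

Key structural assumptions:

* both 25-nt flanking anchors are present on a usable read, in a single
  orientation, within 2 edits (unit-cost Levenshtein; indels dominate
  nanopore error, so Hamming matching would discard good reads);
* the repeat tract begins at the first `AAGAAG` junction after the
  invariable motif — the expansion conventionally starts with an AAG unit
  after the pre-repeat, and the `AAGAAG` gate mirrors the read-filtering
  convention for this locus;
* per-allele repeat counts are summarized by the *median*, because
  preferential sequencing of shorter fragments and length-dependent
  mosaicism skew the mean downward.

## Two length offsets, on purpose

The architecture stores two constants that look redundant but are not:

* `trim_offset_bp = 146` — the amplicon length removed by anchor trimming
  (primer-proximal padding plus both 25-mers). It is added back to the
  median retained-segment length to report a fragment-equivalent size
  comparable with capillary fragment analysis.
* `nonrepeat_amplicon_bp = 160` — the implied non-repeat length of a whole
  LR-PCR fragment, obtained by solving the published conversion anchor
  pairs (700 bp, 180 repeats) and (670 bp, 170 repeats) with a 3 bp/triplet
  slope. It decomposes as 146 + 6 (`CTTTCT`) + ~8 bp of typical
  variable-region/pre-repeat content. The 8 bp allowance is a
  reconciliation of the two published constants, not a measured value; it
  is used only for whole-fragment conversion, never per read.

## Read-level processing

Quality control follows standard amplicon practice: Phred+33, both ends
trimmed to Q10, post-trim length within 200–100000 bp, post-trim
arithmetic-mean quality at least 10.

Anchor search runs a d = 0, 1, 2 cascade of approximate matching so each
read gets its lowest-edit hit; ties are broken leftmost for the upstream
anchor and rightmost for the downstream anchor, maximizing the retained
segment (conservative toward keeping the whole tract). A second
non-overlapping hit of either anchor at the same edit cost marks the read
as an amplicon concatemer and rejects it (`chimeric`). Reads whose anchors
appear in mixed orientations, in the wrong order, or not at all are
rejected with distinct reason codes; nothing is dropped silently.

### Frame resynchronization

Triplet decomposition reads non-overlapping 3-mers in a fixed frame. A raw
fixed frame is brittle under nanopore indel rates: one deletion shifts the
frame and the entire downstream tract decodes as noise, which both destroys
interruption calls (support collapses below consensus) and corrupts
main-motif calls for hexamer alleles. `decompose_triplets()` therefore
re-anchors at the next `AAG(AAG|GAG)` junction whenever it meets an
unclassifiable 3-mer, emitting the skipped bases as `OTHER` triplets
rounded to the nearest whole triplet. One indel then costs at most one
misclassified position while the count stays calibrated. The no-error
behavior is unchanged (exact round trip of simulated alleles), and
`resync = FALSE` restores the strict fixed frame.

## Allele partitioning

Reads are first grouped by exact structural signature (flank class,
pre-repeat, main motif). Sequencing errors corrupt the short variable
region in a sizeable minority of reads, so signatures holding fewer than
10% of reads are re-assigned to the closest major signature using the sum
of (a) the edit distance between variable regions and (b) 0.25 × the
difference between the read's triplet count and the signature's median
count. The size term matters: errors that delay the tract-start junction
absorb mutated tract bases into the variable region, which can leave a
corrupted read *closer in edit distance* to an unrelated, longer signature;
its nearly intact repeat count resolves the ambiguity. The 0.25 weight
makes a 4-triplet size difference as costly as one edit — strong enough to
fix junction artifacts, weak enough that genuinely different structures at
similar sizes still separate on sequence.

Within a signature, counts are split by an explicit two-means criterion: a
candidate split (optimal 1-D two-means cut) is accepted iff the cluster
medians differ by more than `max(10, 3 × pooled within-cluster MAD)` and
both sides keep at least `min_support = 10` reads. The MAD is the scaled
estimator (`stats::mad`, consistent for a Gaussian sigma). The scaling is
load-bearing: with the raw MAD, the threshold for a wide unimodal cluster
(about `1.23 sigma`) falls *below* the median separation its own halves
produce when cut (about `1.35 sigma`), so mosaic alleles with sd above ~7
triplets would self-split; with the scaled MAD the unimodal cut threshold
(`1.82 sigma`) clears that with a 35% margin, while two alleles separated
by more than about `max(10, 3 sigma)` still split. That quantity is the
caller's documented resolution: same-signature alleles closer than it merge
and are reported as one allele with a note (possible homozygosity).
Within each final group, reads deviating from the group median by more than
`max(10, 5 × MAD)` are trimmed before summarizing — stray mis-decoded reads
too few to cluster on their own would otherwise inflate the mosaicism
readout.

At most three groups are kept (a1 smallest, a2 largest, a3 intermediate —
the mosaic pattern); surplus groups are flagged, never silently dropped.
The genotype class is driven by the largest AAG allele ([180, 250)
intermediate, [250, 300) incomplete penetrance, ≥ 300 full penetrance);
hexamer alleles never drive a pathogenic class; two AAG alleles ≥ 250 make
a biallelic expansion.

## Interruption typing

A non-canonical triplet run is a *candidate* interruption only if it occurs
at a reproducible position — within ±2 triplets, measured from the nearer
tract end — in at least half of the allele's reads. This consensus rule is
what separates true variants (present in many reads at one position) from
sequencing error (random positions in single reads), including the
systematic AAG→AAC streaks that nanopore basecalling produces in long
expanded reads. Supported candidates wholly inside the first or last 10% of
the tract (minimum 3 triplets) give the 5'/3'-edge classes; anything else
is a middle interruption. The 10% window and 50% support are explicit,
tunable defaults; the corresponding published categorization did not state
numeric values, so these are this package's formalization.

## The synthetic generator

`simulate_sample()` emulates the processes the real assay exhibits, with
known ground truth per read:

* **mosaicism** — per-read count drawn from a discretized Gaussian around
  the nominal count, truncated at 2 triplets; the default sd is
  `0.02 × repeat count`, reflecting the positive size–instability
  correlation (the coefficient itself is unreported; it is a modeling
  choice, stated as such);
* **errors** — substitutions at 0.01/base and indels at 0.005/base
  (nanopore R9-class amplicon error scale), plus a systematic AAG→AAC run
  in 5% of reads with geometric length (mean 8 triplets);
* **short-fragment bias** — sampling weight `length^(-0.5)` applied both
  between alleles and within an allele's mosaic variants, so removing the
  bias can only raise the called median (the behavior median aggregation is
  meant to resist);
* **strand** — half of the reads are emitted as reverse complements;
  qualities are a constant Q20.

None of the error magnitudes are measurements of the real runs, which do
not publish them; they are defaults a nanopore amplicon dataset of this
class could plausibly show, and every rate is a parameter. The generator
does not model pore-level signal, basecaller-specific artifacts beyond the
AAC streaks, adapter/barcode structure, or coverage heterogeneity between
amplicons — so passing tests demonstrate algorithmic correctness under the
stated error model, not performance guarantees on any particular real run.

Validation cohorts (`sim_validation_sample()`) draw diploid samples with a1
in the common small-allele range (9–50 triplets) and a2 across 9–400, with
flank classes and pre-repeat frequencies following the observed size
associations (the 17-mer flank only in small alleles, GG/GGG only in large
ones, pre-repeats enriched above 180). A minimum separation of 30 triplets
between the two alleles makes every validation sample resolvable by the
caller's stated resolution; the recovery property targets sizing and
allele-count accuracy on heterozygous samples, not homozygote
deconvolution.

## Statistical layer

Exact 2×2 tests use the probability-mass two-sided Fisher convention; the
reported odds ratio is the cross-product `(ad)/(bc)` with a
Haldane–Anscombe 0.5 correction (flagged) when a cell is zero, so sparse
enrichment bins keep finite log2 odds. Size-bin enrichment defaults to
width-20 bins over [0, 360) plus a top bin, Bonferroni-corrected over the
number of bins; the bin edges are configurable because the published
analysis does not print its own. Mann-Whitney tests are exact (enumeration)
up to a pooled n of 12 without ties, otherwise normal-approximated with tie
and continuity corrections; multiple group comparisons use Holm. The qPCR
relative abundance implements `r = 2^(−ΔΔCt)` with ΔΔCt formed as the
*ratio* of the sample's ΔCt to the control-mean ΔCt — the form printed for
this locus, unusual relative to the conventional subtraction, which is
available behind `method = "difference"`; the ratio form errors on a zero
control mean.

The test suite cross-checks both exact tests against brute-force
enumeration oracles (all 2×2 tables with n ≤ 10; all group splits with
pooled n ≤ 10) that are implemented independently of the package code.

## Problem sizes and numerical choices

The heavy properties run at sizes chosen to finish comfortably on a single
CPU while keeping statistical power: parameter recovery uses 50 diploid
samples × 500 reads; the mosaicism correlation uses 50 single-allele
samples × 150 reads per arm (proportional-sd arm at `0.05 × size`, the
calibrated setting; constant-sd null at 8 triplets); enrichment type-I
control uses 200 null replicates of a 148/802 cohort; the age-at-onset
recovery uses 20 seeds at n = 42 calibrated to R² = 0.27, asserted on the
across-seed mean because a single draw of R̂² at n = 42 has a sampling sd
near 0.11. Quantiles for outlier screening are the linear-interpolation
(type 7) definition with a strict `>` at the boundary. All randomness is
routed through explicit integer seeds; a fixed seed fixes the FASTQ bytes
and every downstream TSV.

## Known limitations

* Same-signature alleles closer than `max(10, 3 sigma)` triplets merge by
  design; resolving near-homozygous genotypes needs orthogonal information.
* The flank catalog ships the five published classes; additional rare
  classes surface as verbatim novel flanks rather than named classes.
* Interruption typing assumes interruptions are positionally stable
  relative to the nearer tract end; an interruption drifting with mosaic
  length would lose support.
* Triplet counts are per-read with median aggregation; no consensus
  polishing of the tract sequence is attempted.
* Pathogenicity classes implement fixed thresholds (180/250/300); they are
  parameters, and the biallelic class requires both alleles at or above the
  250-repeat threshold.
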