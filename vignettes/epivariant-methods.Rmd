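---
title: "Detecting individual-specific chromatin outliers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting individual-specific chromatin outliers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epivariant)
```

## The problem

In a case–control cohort profiled for a promoter-associated histone mark
(H3K4me3 ChIP-seq), group-mean differential tests can come up empty while
individual samples still carry striking private alterations: a promoter
peak several-fold higher or lower in one case than in *every* control.
`epivariant` treats each case sample as its own test unit against the full
control panel, which matches the biology of rare, individual-specific
epigenetic variation ("epi-mutations") better than any group contrast.

## Normalization model

Sequencing depth differs between libraries, and total-read scaling is
distorted when large signal regions differ between samples. The package
instead anchors normalization on promoter regions, where the mark
concentrates in every sample: windows of ±2,000 bp (4 kbp total) are placed
around all annotated TSSs and merged into maximal disjoint regions
(`build_promoter_set()`); the per-sample count of reads mapped into these
regions, divided by $10^7$, is the scale factor $s$
(`normalization_factor()`). The normalized coverage of peak $i$ in sample
$j$ is

$$ q_{ij} = \frac{1}{s_j}\sum_{b \in \text{peak } i} \text{cov}_j(b). $$

Two conventions needed fixing where reasonable people could differ:

* **Read membership.** A read counts toward the promoter tally when its 5′
  mapped position lies inside the merged regions (`promoter_read_tally()`).
  This is order-independent and reproducible from a position list alone;
  users with a different convention can supply a precomputed tally.
* **Window clipping.** Windows are clipped at the chromosome start; no
  clipping at chromosome ends is attempted unless the user supplies
  lengths, which keeps the function free of any genome-build dependency.

The key invariant — verified by property tests — is that multiplying one
sample's raw coverage *and* its promoter tally by any $c > 0$ leaves its
$q$ column unchanged to within 1e-9 relative and changes no downstream
call.

## Outlier model and thresholds

For each testable peak and case sample, with $C$ the control coverages:

* **up**: $q \ge 5$, $q \ge 1.5\,q_c\ \forall c \in C$, and
  $P(X \ge q) < 0.01$ for $X \sim N(\hat\mu, \hat\sigma)$ fitted to $C$;
* **down**: $q_c \ge 5\ \forall c$, $q \le 0.5\,q_c\ \forall c$, and
  $P(X \le q) < 0.01$.

Parameters, units and defaults (`detection_thresholds()`):

| parameter | default | meaning |
|---|---|---|
| `up_fold` / `down_fold` | 1.5 / 0.5 | worst-case fold vs. every control |
| `min_case_cov_up` | 5 (normalized units) | floor on the case signal for up calls |
| `min_ctrl_cov_down` | 5 | floor on every control for down calls (a loss needs something to be lost from) |
| `nominal_p_max` | 0.01 | one-tailed normal-model p cutoff |
| `low_cov_exclude` | 2.5 | cohort-mean coverage below which a locus is untestable |
| `mapq_frac_exclude` | 0.75 | pooled low-MAPQ (< 10) read fraction at which a locus is treated as a mappability artifact |
| `gene_link_dist` | 2000 bp | strict peak-to-TSS linkage distance |

Numerical and boundary decisions:

* All threshold comparisons are **exact and inclusive** ("at least 1.5-fold"
  means `>=`); no epsilon is applied anywhere, so a fold of exactly 1.5
  calls and a MAPQ fraction of exactly 0.75 excludes.
* $\hat\sigma$ is the unbiased $n-1$ standard deviation. When the controls
  are identical ($\hat\sigma = 0$) the fitted model is a point mass and the
  tail probability degenerates to 0 when the case value lies strictly on
  the tested side of $\hat\mu$ and 1 otherwise; this keeps noiseless
  fixtures and near-constant loci callable without special-casing callers.
* The p-value is one-tailed in the direction of the candidate call, since
  up and down candidates are selected separately.
* For up calls a control at 0 satisfies the fold clause trivially (and the
  worst-case fold is reported as `Inf`); for down calls the every-control
  ≥ 5 clause guarantees no division by zero.
* The low-coverage filter is applied to the **cohort mean** of $q$ over all
  samples. Applying it to the case sample or the control mean alone would
  couple eligibility to the quantity being tested; the cohort mean is the
  most symmetric reading, and the per-peak exclusion reason is emitted
  (`exclusion_reasons()`) so users can audit the choice.
* MAPQ fractions are pooled across all cohort samples: low mappability is a
  property of the locus, not of a library. Peaks with no MAPQ information
  (or no reads) are never excluded by this rule — absence of evidence of
  bad mappability is not evidence of it.

Requiring the fold change against *every* control deliberately suppresses
the false-positive rate at the cost of sensitivity; missed signals are
expected, and the package's operating characteristics under its own
generative model are recomputed, not assumed (see the acceptance script).

## Recurrence and subgroup structure

`summarize_recurrence()` groups calls by (locus, direction) and reports the
singleton fraction — the share of altered loci seen in exactly one case.
Because a locus up in one sample and down in another could be counted
either way, the per-locus any-direction grouping is emitted as a secondary
view rather than silently chosen.

`sample_correlation()` computes genome-wide Pearson correlations between
samples. `flag_subgroups()` then flags case clusters whose members
correlate with each other at least `delta` (default 0.05) above each
member's mean correlation to all samples outside the cluster. The
implementation builds a graph of qualifying pairs, takes connected
components, and verifies every internal pair of a component against the
outside-cluster means; components failing verification stay unflagged.
This is deterministic and reproduces the intended behavior on the
motivating pattern (two mutually similar, globally divergent cases) without
committing to a full clustering model. Flagged subgroups are then analyzed
as separate case sets against the full control panel (`groups` in the run
config).

## Enrichment stage

* **Category linkage.** A TSS links to a peak when its distance to the peak
  interval is strictly below 2,000 bp (0 inside the peak). A peak linked to
  both protein-coding and non-coding transcripts is categorized
  `protein_coding`: a dominance rule is needed for the three categories to
  partition the catalog, and coding dominance is the conservative choice
  when the scientific claim of interest is non-coding enrichment.
* **Fisher tests.** All enrichment p-values are one-tailed hypergeometric
  upper tails (`fisher_one_tailed()`, via `phyper`); the test suite checks
  them against exhaustive log-binomial enumeration for every 2×2 table with
  total up to 200. Bonferroni for the category table uses m = number of
  rows actually tested (4 by default) and is logged; BH-FDR is used for
  gene-list batteries and ORA.
* **GWAS region sets.** Variants passing a p threshold are extended ±100 kb
  and merged. The overlap test restricts the peak universe to peaks
  overlapping regions built from *all* tested variants with the same flank
  — the wording "the whole variant set as a background" is ambiguous
  between this peak-universe restriction and a variant-level background;
  the peak-universe reading was chosen because it keeps the unit of testing
  (peaks) fixed across numerator and denominator. Whole-genome backgrounds
  (for CNV-style tests) are expressed by passing chromosome-spanning
  regions from `read_chrom_sizes()`.
* **ORA.** A local Fisher + BH over-representation test over user-supplied
  GMT sets replaces web-service enrichment tools, so results are
  reproducible offline with a pinned gene universe.

One published-table caveat: for the annotation-category table, the two
depleted rows (annotated and protein-coding) are exactly recoverable from
their printed margins and reproduce an adjusted p of 1.0; the printed
adjusted p-values of the two *enriched* rows are not recoverable from any
peak-count-background Fisher computation on the printed counts, and the
same claim is given a different adjusted p in running text. The package
therefore treats only the two robust rows as reproduction targets and
leaves the enriched-row p-values to its own computation.

## Coordinates

Coordinates are handled by GenomicRanges/IRanges and are therefore 1-based
inclusive internally; BED and bedGraph inputs are converted at the boundary
and reports print publication-style 1-based `chrom:start-end` labels. This
buys all interval algebra (merge, overlap, nearest) from a mature library
instead of a bespoke 0-based layer; the BED reader/writer pair round-trips
exactly. Chromosome names are matched verbatim — mixed Ensembl/UCSC naming
must be resolved upstream, and peaks on chromosomes absent from a coverage
track quantify to 0 with a warning rather than an error.

## The synthetic cohort generator

`simulate_cohort()` draws
$q_{ij} = \text{baseline}_i \times \text{noise}_{ij} \times \text{spike}_{ij}$ with

* per-peak baseline $\sim$ LogNormal(meanlog = log 20, sdlog = 1) —
  a right-skewed promoter-coverage distribution spanning the detection
  floor (a realistic fraction of peaks falls below the 2.5 eligibility
  cutoff);
* multiplicative noise LogNormal with CV 0.15, mean 1 — the within-locus
  between-sample variability regime in which a 1.5-fold-vs-every-control
  rule is stringent but attainable;
* defaults of 16 cases + 16 controls and 5,000 peaks, peak width 1,500 bp;
* spikes: configured (peak, case, direction, fold) multipliers, recorded as
  ground truth;
* library factors uniform on [0.5, 2] applied jointly to raw tracks and
  promoter tallies — they exist to *cancel*, and a property test asserts
  end-to-end that changing their range changes nothing downstream;
* 1% of non-spiked peaks become mappability artifacts with low-MAPQ
  fractions in [0.75, 0.98].

Two constructive details matter for validation. Down-spiked rows are
rescaled upward when needed so every control stays ≥ 5.5: without this the
every-control-≥-5 clause silently voids down-recovery tests on low-baseline
peaks. And one seeded RNG stream per bundle is used with a fixed draw order
(matrix randomness first, library factors last), which makes bundles
byte-reproducible and keeps the library-factor invariance exact; per-sample
stream splitting was considered and rejected as needless machinery at this
scale.

The generator emulates the *statistical* structure the detector assumes —
not read-level data, peak shapes, genomic sequence, GC or fragment-length
artifacts, or correlated biological programs across loci. Passing recovery
tests therefore demonstrate that the implementation honors its own model;
they do not certify performance on real chromatin data, where the normal
control model and independence across loci are approximations.

## Validation problem sizes

The test suite validates each operation against independent oracles:
per-base masks for interval algebra, literal four-clause loops for the
caller (50 random matrices in the unit suite and 1,000 random 200-peak,
4-case/8-control matrices in the acceptance suite), exhaustive
hypergeometric enumeration for all 2×2 tables with N ≤ 200, numeric
integration for normal tails, and the textbook BH formula. Recovery and
null calibration run on 16+16 cohorts of 5,000 peaks (10 and 20 replicates
respectively) — sizes chosen so the full suite completes in a few minutes
while keeping Monte-Carlo error well inside the asserted margins.

## Known limitations

* The nominal p is a ranking heuristic, not a calibrated error rate: 16
  controls estimate $\hat\sigma$ noisily, coverages are non-negative and
  right-skewed, and no multiple-testing correction is applied at the call
  stage (by design, mirroring the stringent fold rule).
* Covariates (age, sex) are carried as metadata only; no adjustment is
  performed.
* BAM ingestion is out of scope: per-peak coverage, promoter tallies and
  MAPQ summaries arrive as tracks/TSVs produced by standard upstream tools.
* `flag_subgroups()` is a rule, not an inference: it will not discover
  overlapping subgroups, and `delta` trades sensitivity against spurious
  flags with no significance statement attached.
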