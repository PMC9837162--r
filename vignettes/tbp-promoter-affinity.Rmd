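---
title: "Estimating TBP-promoter binding affinity and comparing promoter groups"
author: "tbpAffinity authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating TBP-promoter binding affinity and comparing promoter groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbpAffinity)
```

## The scientific problem

The TATA-binding protein (TBP) initiates assembly of the transcription
preinitiation complex by binding the TATA box of the core promoter,
typically between positions −70 and −20 relative to the transcription start
site. The equilibrium dissociation constant $K_D$ of the TBP-promoter
complex is a proxy for a promoter's basal strength: the lower $K_D$, the
tighter the binding and the higher the expected expression. Given cohorts
of 90 bp proximal promoter sequences labelled by species, gene family and
group, this package estimates a per-promoter $K_D$ from sequence and asks
whether the group means differ.

## The binding model and its assumptions

$K_D$ estimation follows a three-step conception of TBP-promoter binding:

1. **Nonspecific sliding.** TBP first associates with any DNA and diffuses
   along it. This step is sequence-independent and defines the affinity
   *ceiling*: a promoter with no recognizable site is assigned
   $K_D^{ns} = 10^{-5}$ M, the characteristic nonspecific affinity of TBP
   for double-stranded DNA.
2. **Site recognition.** TBP halts on a TATA-like element. We model
   recognition with a position probability matrix of width $w$: every
   window of width $w$ on the forward strand and on the reverse complement
   is scored by the log-odds
   $S = \sum_{j=1}^{w} \ln\!\big(p_j(b_j)/q(b_j)\big)$
   against the background $q$, and the best window's score is normalized by
   the consensus score, $s^* = \max(0,\, S/S_{\max}) \in [0,1]$.
3. **Complex stabilization.** Bending of the DNA axis stabilizes the bound
   complex. We do not model the bending energetics explicitly; together
   with recognition it is absorbed into a log-linear calibration between
   the ceiling and the affinity *floor* $K_D^{sp} = 10^{-9}$ M, the
   characteristic affinity of TBP for a perfect site:
   $$\ln K_D = \ln K_D^{ns} + s^*\,(\ln K_D^{sp} - \ln K_D^{ns}).$$

This surrogate intentionally trades structural detail for two exact,
experimentally motivated anchor points and a monotone, bounded map from
recognition score to affinity. Consequences worth keeping in mind:

* Every estimate lies in $[10^{-9}, 10^{-5}]$ M by construction; the model
  cannot extrapolate to super-consensus sites or to unusually sticky
  nonspecific DNA.
* The promoter's $K_D$ is set by its **single best window** (the
  maximum-occupancy site). We rejected an additive partition-function
  aggregation over all windows: with ~150 windows per promoter the
  nonspecific mass would dominate and the calibration anchors would no
  longer be attainable.
* Both strands are scanned because TBP binding to the double helix is
  orientation-ambiguous. Determinism requires a tie rule: equal scores are
  resolved toward the forward strand, then the smaller start position
  (reverse-strand windows are reported by the forward-strand coordinate of
  their leftmost base).
* Absolute $K_D$ values depend on the matrix and the two anchors; the
  downstream group statistics are invariant to any monotone recalibration,
  so the comparisons are more robust than the absolute numbers.

## Parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `kd_nonspecific` | mol/L | 1e-5 | nonspecific TBP-DNA affinity (ceiling) |
| `kd_specific` | mol/L | 1e-9 | affinity for a perfect site (floor) |
| matrix width | bp | 15 | TATAWAWR core (8) plus flanking context |
| `pseudocount` | counts | 0.25 | keeps all probabilities positive on count input |
| background | probabilities | uniform 0.25 | neutral log-odds reference |

The default matrix (shipped as `inst/extdata/tata_pfm.txt`) encodes the
canonical TATAWAWR consensus: consensus base probability 0.85 and
off-consensus 0.05 at fixed positions, the two W positions split A/T at
0.45 and the R position splits A/G at 0.45, flanked by near-uniform columns
(A 0.28, C/G/T 0.24). It is deterministic, documented and swappable via
`loadTataMatrix()`; the slight A-preference of the flanks gives the matrix
a unique consensus window. No claim is made that it equals any particular
experimentally fitted matrix — users with a better plant TBP model should
supply it.

## Group statistics

Per-promoter $K_D$ values (reported in nM) are aggregated per species and
per group into $N$, the arithmetic mean $M_0$ and the standard error of the
mean $\Delta$ (sample SD with the $n-1$ denominator over $\sqrt n$). Food
and non-food groups are compared per gene family with the
difference-of-means Z-test
$Z = |M_0^{(1)} - M_0^{(2)}| / \sqrt{\Delta_1^2 + \Delta_2^2}$, two-sided
against the standard normal. Design choices:

* **Promoter-level pooling.** Group means average promoters, not species
  means, so the group $N$ is the promoter count; `species_weighted = TRUE`
  switches to averaging species means for users worried about species
  imbalance.
* **Direction as a flag.** $Z$ is reported as an absolute value; the sign
  of the difference travels separately, which keeps the reporting
  convention of positive $Z$ values.
* **No multiplicity correction by default.** The three gene families are
  reported as three uncorrected tests; `bonferroni = TRUE` multiplies the
  p-values by the number of computable tests.
* **Degenerate inputs.** A single-promoter set gets SEM 0 with a warning;
  two groups with both SEMs zero raise an error when the means are equal
  and report $Z = \infty$, $p = 0$ with a warning when they differ. A
  family observed in only one group is reported with its test marked not
  computable instead of failing the run.

## The synthetic cohort generator

Real promoter cohorts come from sequence databases and cannot be bundled;
the generator produces cohorts with the statistical structure the analysis
assumes, so the entire pipeline is testable offline:

* Each record is an i.i.d. background sequence (GC fraction 0.40 by
  default, a typical plant promoter composition) with **one** planted
  TATA-like site. One site suffices because the model only consumes the
  best window.
* The planted site is the consensus window degraded by greedy single-base
  substitutions to a strength drawn from a truncated normal on $[0,1]$;
  because scores move on a discrete substitution lattice, the achieved
  strength lands within one lattice step of the target (the flank columns
  provide steps of ~0.013 in normalized score, so targets are hit closely).
* The site start is uniform on 21..56 (width 15), placing the element
  within positions 21..70 of the 90-mer — the −70..−20 region relative to
  the transcription start site at the 3' end.
* Defaults mirror the reference validation conditions: 50 promoters per
  group, strengths 0.8 (food) versus 0.4 (non-food), SD 0.1. Five species
  labels per group and all three gene families, assigned round-robin, give
  realistically unbalanced per-species counts without dominating any
  label. Identical spec and seed reproduce the cohort byte-identically
  (Mersenne-Twister, seed recorded in the cohort provenance and the run
  manifest).

What the generator does **not** emulate: dinucleotide or phylogenetic
structure in the background, indels, multiple or overlapping sites, and
the unknown real distribution of site strengths (the truncated normal is a
modelling convenience). Tests passing on synthetic cohorts therefore
validate the machinery — scanning, calibration, aggregation, error rates —
not the biological realism of any particular cohort. One visible
consequence of the i.i.d. background: when the planted site is weak
(strength below roughly 0.5), a chance background window occasionally
out-scores it, biasing the best-window score upward; this affects both
groups equally and leaves the null calibration of the Z-test intact, as
the type-I simulations confirm.

## Numerical choices

* **Exact anchors.** Normalized scores at or above 1 (a perfect site) are
  pinned to `kd_specific`, and at or below 0 to `kd_nonspecific`, so the
  anchors are reproduced exactly rather than to within rounding.
* **Consistent accumulation.** Window scores in the vectorized scanner are
  built by repeated double-precision additions; the consensus score used
  for normalization is accumulated the same way (not with `sum()`, which
  may use extended precision), so a planted consensus site normalizes to
  exactly 1 on every platform.
* **Ambiguity codes.** Sequences with IUPAC ambiguity codes are excluded
  by `filterAmbiguous()` before scoring, mirroring standard practice for
  this analysis; a non-IUPAC character is a hard validation error, not a
  filter case.
* **Orientation convention.** Sequences are stored 5'→3' on the annotated
  strand with position 90 adjacent to the transcription start site;
  coordinates are 1-based inclusive. The provided 90-mer is treated as
  authoritative and is not re-anchored.
* **Degenerate matrices.** A matrix whose consensus log-odds score is not
  positive (e.g. uniform) cannot normalize scores and is rejected with a
  configuration error.

## Validation problem sizes

The shipped test suite exercises the scanner against an exhaustive
brute-force oracle on 200 random 90-mers (width-6 matrix), checks strand
symmetry on 500 random sequences, estimates the type-I error of the full
generate→score→test pipeline on 2000 null cohorts of 50+50 promoters
(nominal 5%, accepted within the 99% binomial band), and measures power on
200 cohorts under the default planted effect (requiring ≥95% rejections at
p < 0.01). The acceptance script repeats the type-I measurement at 1000
cohorts and the power measurement at 200; these sizes give binomial
standard errors below one percentage point while keeping a laptop run in
the low minutes.

## Known limitations

* The affinity surrogate is calibrated, not fitted: absolute $K_D$ values
  from other predictors or from binding assays will differ; only the
  ordering and the group-level contrasts are expected to transfer.
* A single generic plant TBP matrix is used; no ortholog-specific models.
* The Z-test assumes large-sample normality of the group means; with very
  small groups (a handful of promoters) a t-based or resampling test would
  be more appropriate than the normal reference used here.
* No phylogenetic correction: promoters from related species are treated
  as independent observations, as in the promoter-level pooling
  convention.
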