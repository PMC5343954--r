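---
title: "Predicting CpG methylation status from composition and sequence complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CpG methylation status from composition and sequence complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsc)
```

## The problem

Bisulfite sequencing assays report a methylation level β ∈ [0, 1] per CpG
site, but cover only a fraction of the genome's CpGs. Sites that are
*stably* methylated or unmethylated across developmental stages are,
however, strongly determined by their local sequence context: unmethylated
CpGs cluster in GC-rich, CpG-dense islands near promoters, while the
methylated bulk of the genome is AT-richer and more repetitive. `methsc`
exploits this to classify any CpG site from the reference sequence of a
window centred on it.

## The feature model

A window ω of length L is encoded as exactly 72 numbers, in a fixed order
that is serialized with every trained model:

1. **Trinucleotide frequencies (64).** Overlapping 3-mers counted on the
   plus strand, each normalized by L − 2. The encoding is deliberately
   strand-specific: no reverse-complement symmetrization is applied, and
   `encode(revcomp(s)) != encode(s)` in general. Windows are extracted
   from the plus strand of the reference, so train- and predict-time
   conventions agree by construction.
2. **GC content (1).** (G + C)/L.
3. **Sequence complexity (7).** The subword complexity function
   p_ω(n) counts distinct length-n subwords. For a finite window it rises
   steeply (near 4^n) and then decays linearly to 1 at n = L. Its
   asymptotic growth rate — the topological entropy — cannot be read off a
   finite window directly, so the informative region is located
   empirically: after two discrete difference operations on p_ω, the
   longest contiguous run of non-zero second differences marks the
   *exponentially increasing part* (EIP), where the curve is still
   genuinely bending. The seven SC features are p_ω at seven consecutive
   points ending at the calibrated last EIP point.

### Numerical conventions in the complexity module

- The second difference attached to point k is
  d2[k] = p(k+2) − 2p(k+1) + p(k); runs are reported in p-point indices.
  This convention reproduces the published location of the EIP (points
  1–7) for the reference 100-bp example.
- The non-zero test is exact integer inequality — p is integer-valued, so
  no tolerance is appropriate — and an interior zero breaks a run.
- Equal-length runs are resolved toward the earliest run.
- A profile whose second differences are all zero (homopolymers, short
  period repeats) is flagged degenerate and reports the trivial run (1, 1).
- Subwords containing N are never counted; the dataset module rejects any
  window containing N upstream, so the complexity code only ever sees pure
  A/C/G/T.
- `complexity_table()` profiles sequences to
  n_max = min(L, 64); feature extraction itself only evaluates p up to the
  largest SC point, so kilobase windows never incur O(L²) hashing.

### Entropy point and the fixed SC table

The entropy point n₀ of a window of length L is the unique integer with
4^n₀ + n₀ − 1 < L ≤ 4^(n₀+1) + (n₀+1) − 1; `entropy_point()` solves this
inequality directly and the test suite verifies the solution by
substitution. The shipped SC-point table is

| window | n₀ (inequality) | SC points |
|---|---|---|
| 100 | 3 | 1–7 |
| 200 | 3 | 2–8 |
| 300 | 4 | 2–8 |
| 400 | 4 | 3–9 |
| 500 | 4 | 4–10 |
| 600 | 4 | 4–10 |
| 700 | 4 | 4–10 |
| 800 | 4 | 4–10 |
| 900 | 4 | 5–11 |

One documentation caveat: the published calibration table this reproduces
prints n₀ = 5 for 600–900 bp windows, although the defining inequality
gives 4 for every L ≤ 1028. The SC-point intervals (the column actually
used for features) are internally consistent with the EIP calibration, so
`sc_spec()` follows the interval column exactly, while `entropy_point()`
follows the inequality; the discrepancy is surfaced here rather than
silently resolved. For window sizes outside the table, `sc_spec(mode =
"dynamic")` recalibrates: it records the last EIP point over a calibration
corpus (~100 windows is ample; ties in the median round down) and takes
the seven points ending at the median.

### Topological entropy estimators

Two finite-window estimators are provided. The single-point estimator is
log₄ p(n₀)/n₀. The averaged estimator takes the mean of log₄ p(i)/i over
the k points ending at n₀ (default k = 3, i.e. i = n₀−2, n₀−1, n₀). The
literature formula for the latter is printed with summation limits
n₀−k … n₀ and prefactor 1/k, which is internally inconsistent (k+1 terms,
and values can exceed 1); the accompanying worked narrative, which uses
exactly the three points 1–3 for a 100-bp window (n₀ = 3, k = 3), pins
down the intended reading, and that is what is implemented. Both
estimators are guaranteed to lie in [0, 1], reaching 1 on de-Bruijn-like
windows and 0 on homopolymers.

## Dataset construction

- **Coordinates** are 0-based half-open throughout; a bedGraph `start` is
  the CpG cytosine coordinate. The ENCODE RRBS dialect reads percent
  methylation from column 11 and rescales to [0, 1].
- **Labelling** uses strict intersection semantics: positive iff present
  in *every* stage with β ≥ 0.7 everywhere, negative iff present in every
  stage with β ≤ 0.01 everywhere, everything else dropped. Both
  thresholds are parameters; the defaults are the stable-class values
  (a looser β ≤ 0.1 definition of "unmethylated" exists for descriptive
  purposes, but labelling defaults to the strict 0.01).
- **Window extraction** places the CpG astride the centre: for even L the
  window is [c − (L/2 − 1), c + L/2 + 1), so C sits at offset L/2 − 1.
  The even-window convention is a package choice (nothing in the source
  material defines it) and is serialized in the model bundle so that
  features are reproducible. Windows off chromosome ends, containing N,
  or whose centre is not CG in the reference are skipped and counted.
- **Redundancy reduction** mimics CD-HIT-EST with a greedy
  representative scan in input order: a window joins a cluster if its
  ungapped, same-position identity with the representative reaches 0.8,
  else it founds a new cluster; a shared-8-mer prescreen limits the
  quadratic comparisons. This surrogate is deterministic given input
  order and is documented as an approximation of CD-HIT (which uses
  alignment); an external `cd-hit-est` binary can be supplied for
  fidelity runs. Positive and negative subsets are reduced independently.

## Classifier and evaluation

- Min-max scaling to [0, 1] is fitted on training data only (standard
  LibSVM practice; prevents leakage in cross-validation, where it is
  refitted per fold) and stored in the bundle.
- Linear-kernel C-SVM with C = 1 by default and no grid search; C is
  exposed. No class weighting by default; `subsample_balanced()`
  reproduces matched training/independent-test protocols.
- The decision threshold is fixed at 0 (signed distance); ROC curves and
  the rank-method AUC are built from continuous decision values. The
  rank AUC equals trapezoidal integration of the ROC points to 1e−9,
  which the suite asserts.
- MCC with a zero denominator is reported as 0 and flagged — the standard
  convention for degenerate confusion matrices. Confusion-matrix terms
  follow the universal definitions (FP = unmethylated predicted
  methylated), which is what the metric formulas themselves encode.
- Feature importance is the bootstrap mean ± sd of |w_j|/Σ|w_j| over 30
  resamples by default; absolute (not signed) coefficients are used.

## The synthetic generator

`synthetic_spec()` defaults define the study conditions used throughout
the tests: a 120 kb chromosome, ~25% island tracts (≈0.8–1.6 kb) in a
background of ≈2.4–4.8 kb tracts; island GC 0.65 with 0.05 planted CpG/bp,
background GC 0.40 with 0.01 CpG/bp; 8 stages; β ~ clipped
Normal(0, 0.01) at island CpGs and Normal(0.95, 0.01) at background CpGs;
60% of CpGs assayed; 30% of background tracts built as 20–50 bp tandem
repeats. Rationale for the less obvious choices:

- **Island β mean 0 with clipping** masses draws at exactly 0, the way
  RRBS negatives behave. Under 8-stage intersection labelling only ~25%
  of island CpGs survive as negatives — deliberately harsh, qualitatively
  matching the small stable fractions (a few percent to ~12%) seen in
  real multi-stage intersections.
- **Repeat seeding** plants a complexity contrast: a tandem-repeated
  window has p(n) capped near the unit length, shifting SC features while
  leaving class-mean trinucleotide and GC expectations untouched (the
  repeat unit is random per tract). Setting island and background GC and
  CpG densities equal and the repeat bias to 1 yields datasets whose
  *only* class signal is repeat structure — the configuration used to
  show that SC features then dominate the importance ranking.
- **Region annotations are tract bodies ± 300 bp.** Real chromatin-state
  segmentations do not align exactly with methylation domains; the flank
  makes every region a mixture of both CpG classes. This matters for the
  region-level consistency test: the assayed mean is a β-weighted mixture
  and the predicted mean a binary-prediction mixture of the same
  proportions, so a sound model produces overlapping distributions
  (Wilcoxon p > 0.01) while an inverted model separates them. Without
  the mixture, a perfect binary classifier would be trivially
  distinguishable from continuous β means and the test could never pass.
- β noise is Gaussian and clipped; real β distributions are bimodal
  beta-binomial mixtures with coverage-dependent variance. The generator
  reproduces bimodality through the two class means only. Passing tests
  therefore demonstrate pipeline correctness and signal recovery, not
  real-genome accuracy: real data add boundary CpGs, partially methylated
  domains, coverage noise and genuine biological exceptions that this
  generator does not emulate.

## Problem sizes and determinism

The shipped tests run the full pipeline at the default 120 kb/600 bp
conditions (≈2,700 windows after redundancy reduction), the importance
recovery at 60 kb/200 bp over 10 seeds, and the region consistency test on
the default conditions — sizes chosen so the whole suite completes in a
few minutes on one core while keeping several hundred windows per class.
All randomness flows through explicit seeds: the generator's spec seed,
and the fold/bootstrap seeds of the model functions. Identical spec + seed
gives byte-identical synthetic output.

## Known limitations

- The greedy identity surrogate is not CD-HIT: it uses same-position
  (ungapped, unshifted) identity, so overlapping windows of nearby CpGs
  are *not* collapsed, only genuine near-duplicates are.
- Minus-strand CpG calls are assumed to be given at the plus-strand C
  coordinate; dialects that encode strand are mapped, others are taken
  as-is.
- `predict()` yields binary status or a signed margin, not a calibrated
  probability; region profiles use binary predictions.
- States with fewer than 2 regions cannot be tested; states below the
  1000-region reporting threshold are flagged `small_n` rather than
  dropped, since desk-scale data never reach that count.
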