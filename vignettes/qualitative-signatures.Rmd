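---
title: "Qualitative transcriptional signatures from relative expression orderings"
author: "reosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative transcriptional signatures from relative expression orderings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
```

## The model

For two genes A and B measured in one sample, the *relative expression
ordering* (REO) is the order relation A > B or A < B between their
measurements. An REO is a within-sample quantity: it is invariant under any
strictly increasing transformation of that sample's expression vector, and
therefore under the per-sample scale, offset, and power-law effects that
make absolute intensities incomparable across batches, scanners, and
platforms. Everything in this package is built from REOs, which is why a
signature trained on pooled public cohorts can be applied to a single new
profile with no normalization step.

The discovery procedure, stage by stage:

* **Stable pairs.** Within one phenotype, a pair (A, B) is *stable* when
  one direction holds in at least a threshold fraction of samples (default
  90%, inclusive, i.e. "at least"). Exactly tied values count as neither
  direction but stay in the denominator, so ties can only erode support,
  never inflate it. Thresholds at or below 0.5 are rejected because the
  two directions would no longer be mutually exclusive.
* **Reversal pairs.** A pair stable in both phenotypes with *opposite*
  directions. These are the only pairs carrying phenotype information that
  survives any monotone batch distortion.
* **Cross-platform consistency.** Reversal sets discovered independently
  on several platforms are intersected, keeping a pair only when its
  orientation agrees in every set — a pair reversed one way on one
  platform and the other way on another is contradictory evidence, not
  replication.
* **Reference-cohort filter.** Surviving candidates must show their
  reference-phenotype direction in *more than* the threshold fraction
  (default 90%, strict) of an independent reference cohort. The
  deliberately different boundary semantics of the two stages ("at least"
  for discovery, "more than" for the filter) are both exposed through an
  explicit inclusive/strict flag and tested at their boundaries.
* **Scoring.** For a sample with m signature pairs evaluable (both genes
  measured, not tied) of which n show the case-characteristic ordering,
  the incidence-risk score is n/m. Unevaluable pairs leave both numerator
  and denominator, and the evaluable fraction is reported as *coverage*;
  scoring refuses to proceed below a coverage floor (default 0.5) rather
  than return a score built on a sliver of the signature. Classification
  is a majority vote: case-like iff score > 0.5, with exact ties resolved
  to the reference class (the conservative choice).

Downstream, pair-level stage analysis correlates each pair's 0/1
case-ordering indicator with an ordinal severity label by Spearman rank
correlation under Benjamini–Hochberg FDR control, list overlaps and
pathway memberships are tested with the upper hypergeometric tail
P(X ≥ k), and the treatment-reversal analysis counts, per disease-model
gene, the treatment protocols whose treatment-vs-model Student t p-value
falls strictly below each of a ladder of thresholds.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| stability threshold | 0.90, inclusive | minimum support for a stable pair within a phenotype |
| consistency threshold | 0.90, strict | minimum reference-cohort support in the filter stage |
| coverage floor | 0.5 | minimum evaluable fraction of the signature per scored sample |
| classification cutoff | 0.5 | majority-vote boundary; ties go to the reference class |
| FDR level | 0.05 | BH control for stage-correlated pairs and enrichment |
| Wilcoxon exact limit | 20 | combined n at or below which the exact rank-sum null is used (tie-free data) |

All thresholds are arguments, never constants, and every boundary
(inclusive vs strict) is testable independently.

## What the synthetic generator emulates — and what it does not

`simulateCaseControl()` produces the structure the analysis assumes: two
phenotypes differing only in a set of planted reversal pairs, several
"platforms" measuring overlapping gene subsets with their own independent
samples, and per-sample strictly monotone batch distortions
(x → a·x^b + c with a, b > 0, c ≥ 0) emulating scanner and scale effects.

Two generator design choices deserve explanation:

* **Reserved pair bands.** Gene means live on a latent log-like scale on
  which each planted pair occupies its own band of width `logGap`, bands
  are separated by guard zones, and all non-planted genes fall in guard
  zones. This is not cosmetic: if a bystander gene's mean lay inside a
  pair's band, the probability that the bystander exceeds the planted gene
  would cross 1/2 when the pair's levels swap, so the bystander would
  *necessarily* be stably reversed against the pair members as well, and
  "the planted truth" would no longer be the complete set of true
  reversals. Reserving the bands is what makes recall and contamination
  against the planted list well-defined, at the cost of a latent mean
  range that grows with the number of planted pairs and a marginal
  intensity distribution that is not log-normal. Because every downstream
  statistic is rank-based, the marginal family is immaterial; values are
  emitted through a softplus map (strictly increasing, hence REO-neutral)
  to guarantee positive intensities without numeric overflow under the
  power-law distortion.
* **Noise decomposition.** Per-sample noise of total standard deviation
  `noiseSd` splits into an array-level shift common to all genes of a
  sample and an independent gene-level residual, with equal variance. The
  shared shift is the dominant technical effect in real array data and is
  itself strictly monotone, so only the residual can flip an ordering: a
  planted pair flips in a given sample with probability
  pnorm(−logGap/noiseSd) (≈ 0.023 at the default gap 2, noise 1). Under
  this model the two-platform build with a strict filter at 50 samples
  per group recovers planted pairs with expected recall ≈ 0.98, which the
  cohort-scale tests assert as ≥ 0.95.

Consequently, passing tests demonstrate correct *mechanics* (counting,
intersection, filtering, scoring, invariance, calibration) under a
favorably structured truth. They do not demonstrate that real tissue
cohorts contain comparably clean reversal structure; on real data,
gene–gene correlation, partial reversals, and genes sitting inside other
pairs' dynamic ranges all blur the planted/bystander distinction that the
generator makes sharp. The generator also simulates gene-level data only
(no probe effects) and no gene–gene correlation beyond the planted pairs.

The stage-cohort generator imposes each pair's drawn orientation exactly
(the Bernoulli indicator at the stage's flip probability is the ground
truth by construction), so FDR calibration checks are exact-null by
design. The treatment-study generator uses plain iid residual noise: a
shared array shift there would correlate the per-gene t statistics and
invalidate the type-I calibration check that relies on approximate
independence across genes. With the same seed, the case/control and
stage generators assign gene roles identically, so a signature built on
the former aligns with the latter's planted pairs.

Problem sizes in the shipped tests were chosen to exercise each claim at
the smallest scale where it is statistically meaningful: oracle
equivalence on all-pairs scans up to 50 genes × 20 samples, invariance
over 100 random distortions, parameter recovery at 1000 genes / 200
planted pairs / 50 samples per group on two discovery platforms plus a
filter cohort, and null calibrations at 2000 genes (type-I) and ~100
pairs (FDR).

## Numerical choices

* The all-pairs scan runs in compiled code over row blocks, holding at
  most one block of the G × G pair space, and is required by test to be
  bit-identical to the naive triple loop.
* Canonical pair orientation is lexicographic (C collation) on gene id;
  the direction code carries the biology. This makes set intersection and
  union well-defined regardless of discovery order.
* The hypergeometric tail is evaluated in log space (log-binomial terms
  combined by log-sum-exp) and cross-checked against both exhaustive
  draw enumeration (small universes) and the distribution function in
  base R.
* Spearman p-values for pair indicators use an exact permutation null
  when fewer than 12 samples are evaluable — feasible because a binary
  indicator has only choose(n, #ones) distinct arrangements, each equally
  likely — and the t approximation with tie-corrected rho otherwise;
  constant indicators have no defined correlation and are excluded with a
  reported count.
* The Wilcoxon comparison switches from the exact null to the
  tie-corrected normal approximation above a combined n of 20 (or in the
  presence of ties); the switch point is an argument.
* The AUC confidence interval is a seeded percentile bootstrap (default
  2000 resamples) stratified by class; the point estimate is the
  normalized Mann–Whitney statistic with ties counted 1/2.
* Degenerate inputs fail loudly and specifically: zero pooled variance
  yields NA statistics with a message (never a silent p of 0), probes
  absent from the probe map and genes absent from a treatment comparison
  are hard errors naming the offender, and an empty consistency-filter
  result reports the candidate count and the best support seen.

## Design choices that were genuinely open

* **Ties** are counted as neither direction while remaining in the
  denominator — the conservative reading; support can only be eroded by
  ties.
* **Cross-platform consistency** requires orientation agreement, not mere
  co-occurrence, since opposite orientations are disconfirming.
* **Treatment reversal** is judged on the p-value alone by default; the
  published frequency counts are reproducible by pure threshold counting,
  so no effect-direction requirement is imposed. A direction-checked mode
  (treatment effect opposite in sign to the model effect) is available
  behind a flag.
* **Ortholog mapping** keeps strict 1:1 translations only; zero-target
  and multi-target genes are counted and reported, not guessed.
* **Probe collapsing** unions a probe's gene assignments across rows
  before applying the zero/multi-gene discard rule, and averages the
  uniquely mapped probes per gene.
* The stability threshold is applied to the pooled samples of each
  platform (matching pooled cohort counts in multi-cohort discovery); a
  per-dataset variant is a matter of slicing the input matrices, which
  the interfaces leave to the caller.
* The pipeline has no shell entry point: this is an R analysis package
  and `runPipeline()` plus the exported stage functions are its
  interface; all result tables carry '#' metadata headers sufficient to
  re-derive how they were produced.

## Known limitations

* Stage correlation on a combined multi-platform indicator matrix assumes
  the REO indicator is portable across the platforms being combined; this
  holds by construction for monotone distortions but not for platforms
  that fail to measure a pair at all (such pairs are dropped per cohort
  with a count).
* The sensitivity/specificity operating point assumes the majority-vote
  cutoff of 0.5; no cutoff tuning or calibration machinery is provided.
* Signature discovery is threshold-based stability only; discriminative
  score-ranked pair selection (top-scoring-pair style) is out of scope.
* The enrichment universe N must be supplied explicitly (it is a platform
  property); it is never inferred from the gene-set collection.
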