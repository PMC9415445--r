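# reosig

Rank-based (qualitative) transcriptional signatures for single-sample
disease-risk scoring, built from **relative expression orderings (REOs)**:
the within-sample order relation between two genes' measurements. Because
an REO is unchanged by any strictly increasing transformation of one
sample's profile, REO-based signatures survive batch effects, scanner
scale, and normalization differences, and can be applied to one sample at
a time — the setting where quantitative signatures break down.

The package implements the full discovery-to-application pipeline used to
build a lung-cancer incidence-risk signature for COPD patients from public
microarray cohorts, plus a seeded synthetic-data generator so every stage
is testable without any external download:

1. **Stable pairs** — all gene pairs whose ordering (A > B or A < B) is
   identical in at least 90% of one phenotype's samples
   (`stablePairs()`, compiled blocked scan, bit-identical to the naive
   counting loop).
2. **Reversal pairs** — pairs stable in both phenotypes with opposite
   orderings (`reversalPairs()`).
3. **Cross-platform signature** — reversal sets from several discovery
   platforms are intersected requiring consistent orientation, then
   filtered on an independent reference cohort at a strict >90% threshold
   (`intersectReversalSets()`, `consistencyFilter()`, or the one-call
   `buildSignature()`).
4. **Incidence-risk score** — for one sample, with m signature pairs
   evaluable and n of them showing the cancer-characteristic ordering, the
   score is **n/m** (`riskScore()`, `scoreCohort()`); classification is by
   majority vote (score > 0.5), with `rocAuc()` and
   `compareScoreGroups()` (Wilcoxon rank-sum) for cohort evaluation.
5. **Stage analysis & enrichment** — Spearman correlation of each pair's
   cancer-ordering indicator with ordinal disease stage with BH-FDR
   control (`stageCorrelatedPairs()`), hypergeometric list-overlap and
   pathway enrichment via the upper tail
   P(X ≥ k) = 1 − Σᵢ₌₀^{k−1} C(m,i)·C(N−m,n−i)/C(N,n)
   (`hypergeometricTail()`, `overlapSignificance()`,
   `pathwayEnrichment()`).
6. **Treatment reversal** — pooled-variance Student t statistics
   (`twoGroupStats()`), ortholog mapping (`mapOrthologs()`), and per-gene
   counts of treatment protocols reversing a disease-model gene below p
   thresholds (`treatmentReversalTable()`).

## Worked example

```r
library(reosig)

cfg <- simConfig(nGenes = 300, nPlantedPairs = 50, nSamplesPerGroup = 30,
                 logGap = 2, noiseSd = 1, platforms = c(1, 1, 1), seed = 1)
cc  <- simulateCaseControl(cfg)

sig <- buildSignature(cc$platforms[1:2], cc$platforms[[3]]$normal)
sig
#> PairSignature: 46 pairs, 92 unique genes
#>   build: n_consistent=48 | n_dropped_unmeasured=0 | n_signature=46

holdout <- cc$platforms[[3]]
sc  <- scoreCohort(cbind(holdout$normal, holdout$cancer), sig)
lab <- rep(c("normal", "cancer"), each = 30)
rocAuc(sc$score, lab, positive = "cancer", seed = 1)$auc
#> [1] 1
```

The build report mirrors the staged bookkeeping of a real multi-platform
discovery (stable pairs per phenotype per platform, consistent reversal
pairs, final filtered signature), and the held-out AUC of 1 reflects the
planted two-unit ordering gap at unit noise. Scoring a graded stage
cohort (`simulateStageCohort()`, cancer-like ordering probability 0.2 in
moderate vs 0.8 in severe samples) gives severe-vs-moderate Wilcoxon
p-values far below 0.01:

```r
st  <- simulateStageCohort(cfg, flipProb = c(0.2, 0.8))
ssc <- scoreCohort(st$matrix, sig, coverageFloor = 0.1)
compareScoreGroups(ssc$score[st$stages == "severe"],
                   ssc$score[st$stages == "moderate"])$p_value
#> [1] 5.878341e-18
```

`runPipeline()` chains all of the above from one config (list or YAML)
and writes TSV artifacts plus a JSON manifest.

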