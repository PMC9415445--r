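Bundled plain-text reference tables used by the worked examples and tests:

- `copd_rat_model_de.tsv` — per-gene two-group statistics (fold-change as
  ratio of group means, pooled-variance Student t, two-sided p at df = 10)
  for the 16 genes significantly dysregulated in a six-vs-six COPD rat
  model versus control comparison.
- `copd_rat_treatment_pvalues.tsv` — for the same 16 genes, the
  treatment-vs-model two-sided p-values under four treatment protocols
  (BYF, BJF, YZF, APL) and the published reversal-frequency counts at the
  p < .05 / .1 / .2 thresholds.
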