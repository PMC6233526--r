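# cpligand

Ligand-based target profiling with valid confidence: per-target binary
activity models that return **two conformal p-values** (active /
non-active) for a query molecule instead of a bare point prediction.

Intended users: cheminformaticians and safety pharmacologists who want a
panel of QSAR binding models (one per gene symbol) whose error rates are
controlled at a chosen confidence level, plus the full preparation,
tuning, validation and profiling pipeline around them.

## Method core

- **Signature descriptors.** For every heavy atom and height
  h ∈ {1,2,3}, the canonical string of the induced subgraph of atoms
  within distance h of the root (exact lexicographic-minimum DFS
  serialization, computed in C++). A molecule's features are sparse
  signature counts; per height, counts sum to the heavy-atom count.
- **Mondrian aggregated conformal prediction.** Per target, 10 inductive
  conformal predictors are trained on independent proper/calibration
  splits (stratified 20% calibration per class). Nonconformity is the
  signed distance to a linear SVM decision surface (α = −d for class A,
  +d for class N); the per-class p-value is the rank statistic
  (#{α_j ≥ α} + 1)/(n + 1); per-ICP p-values are mean-aggregated. The
  prediction set at significance ε is {c : p_c > ε}; the confidence of a
  prediction is 1 − min(p_A, p_N).
- **Preparation rules** for activity tables: drop every (target, SMILES)
  key with conflicting labels; deduplicate on (target, SMILES, activity);
  include targets with ≥100 actives and ≥100 non-actives; top up
  data-poor targets (<10,000 known non-actives) with *assumed
  non-actives* to a 1:2 active:non-active ratio — used for SVM training
  only, never for calibration.
- **Evaluation.** Observed fuzziness OF (mean wrong-class p-value),
  class-averaged OF, the M criterion (fraction of multi-label sets),
  calibration curves (accuracy vs confidence, 0.05–0.95), and 2×4
  label-set confusion tables at confidence 0.8 / 0.9. The SVM cost is
  selected from {1, 10, 100} by pooled 10-fold cross-validated OF.
- **Synthetic activity tables** with a known motif-based
  structure–activity signal, label noise, and ledgered injected
  duplicates/conflicts, so the whole pipeline is testable offline.

## Worked example

```r
library(cpligand)

# two synthetic targets; T1's activity motif is a carboxylic acid
spec <- synthetic_spec(n_targets = 2, n_active = 30, n_nonactive = 30,
                       label_noise = 0.1, seed = 3)
records <- deduplicate(remove_conflicts(generate_activity_table(spec)$records))
sel <- select_targets(records, prep_config(min_actives = 20, min_nonactives = 20))
models <- lapply(sel$datasets, function(ds)
  acp_train(ds, train_config(cost = 1), split_config(n_icp = 2, seed = 3)))

predict_profile(models, "CCCCC(=O)O", confidence = 0.8)
#> <target_profile> query CCCCC(=O)O (2 targets, set confidence 0.80)
#>  target   p_A   p_N set confidence error
#>      T1 0.357 0.143   A      0.857  <NA>
#>      T2 0.143 0.571   N      0.857  <NA>
```

The carboxylic-acid query is predicted active for T1 (p_A = 0.357 clears
significance 0.2; p_N = 0.143 does not) and non-active for T2; each row's
confidence is 1 − min(p_A, p_N). `atom_contributions(models$T1, smiles)`
decomposes the averaged linear decision value onto atoms (positive =
toward the larger-p class) for fragment-level coloring.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/cpligand-cli.R all --out run1 --config cfg.yaml
Rscript inst/scripts/cpligand-cli.R predict --out run1 --smiles "CCCCC(=O)O" --confidence 0.8
```

Each stage appends to `run1/manifest.jsonl` (parameters, seeds, output
digests), and stage outputs are byte-reproducible under a fixed seed.

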