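---
title: "Conformal target profiling with signature descriptors: models, choices, limits"
author: "cpligand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformal target profiling with signature descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ligand-based target profiling asks, for a query molecule and a panel of
protein targets, "does this compound bind each target?" — with one binary
QSAR model per target. Point classifications are of limited use in early
hazard assessment because they carry no statement of reliability. `cpligand`
therefore wraps every per-target classifier in a *Mondrian conformal
predictor*: for each query and each target it reports two p-values, one per
class (`A` = active, `N` = non-active). At a chosen significance
$\varepsilon$ the prediction *set* is $\{c : p_c > \varepsilon\}$, which may
be a single label, both labels ("Both"), or empty ("Null"). Under
exchangeability of calibration and test data, the set misses the true label
with probability at most $\varepsilon$, and the Mondrian (per-class)
construction gives that guarantee class-conditionally, which is what makes
heavily imbalanced activity data workable without resampling tricks.

## The model stack

**Descriptors.** A molecule is a heavy-atom graph (element, aromaticity,
formal charge on vertices; single/double/triple/aromatic bonds). For every
atom and every height $h \in \{1,2,3\}$ we generate the *signature*: a
canonical string encoding of the induced subgraph of all atoms within graph
distance $h$ of the root. The canonical form is defined as the
lexicographic minimum over all depth-first serializations of that subgraph
(branches parenthesised, ring closures as numbered back-references to DFS
visit indices), computed exactly by branch-and-bound in compiled code. The
feature vector of a molecule is the sparse count map of its signatures;
each height contributes exactly one signature per atom, so per-height
counts always sum to the heavy-atom count — a cheap invariant that the test
suite exercises relentlessly. Signatures are tagged with their height, so
equal strings arising at different heights stay distinct columns.
Chemistry perception (validity, aromaticity, canonical SMILES) is
delegated to Open Babel; the package tokenizes Open Babel's canonical
aromatic SMILES, which means kekulized and aromatic spellings of a molecule
featurize identically. Stereochemistry, isotopes and explicit hydrogen
counts are deliberately ignored (the descriptor is 2-D).

**Nonconformity.** Per target, a linear SVM (libsvm, linear kernel, cost
$C$, uniform class weights, no feature scaling) is fitted on the *proper
training set*. The signed distance $d$ from the decision surface (oriented
so positive means active) scores strangeness: $\alpha = -d$ for class A,
$\alpha = +d$ for class N.

**Calibration.** Each inductive conformal predictor (ICP) sets aside a
stratified 20% of each class as a calibration set. The p-value of a test
score $\alpha$ against its class's calibration scores
$\alpha_1,\dots,\alpha_n$ is the rank statistic
$p = (\#\{j : \alpha_j \ge \alpha\} + 1)/(n+1)$, deterministic and slightly
conservative; a tie-randomized (smoothed) variant exists behind a flag for
exact-validity experiments but is off by default so that every pipeline
output is reproducible byte for byte.

**Aggregation.** Ten ICPs are trained on independent proper/calibration
splits (assumed non-actives — see below — always join the proper set) and
their p-values are combined by the arithmetic mean (median available).

## Data preparation rules

Activity tables (target gene symbol, original entry id, SMILES, A/N flag)
are cleaned in a fixed order: (1) every (target, SMILES) key that carries
both an A and an N record is dropped entirely — no majority voting; (2)
duplicates on (target, SMILES, activity) collapse to the first-seen entry
id; (3) targets need at least 100 actives and 100 non-actives (both minima
inclusive) — excluded targets are reported with their counts. SMILES are
compared by backend-canonical form by default (a raw-string switch exists),
because the same structure frequently appears under different SMILES
spellings and identical structures must never straddle a
calibration/test boundary.

Targets with fewer than 10,000 known non-actives are topped up with
*assumed non-actives*: compounds sampled uniformly without replacement from
the remaining pool that are (i) not reported active for the target and
(ii) not already in its dataset, until non-actives total twice the actives
($\max(0, \lceil 2 n_A \rceil - n_N)$ additions; ceiling so the ratio is
met even for odd counts). Assumed non-actives are used *only* to train the
underlying SVM — never for calibration, never in cross-validation test
folds — so untypical chemistry in the presumed negatives cannot distort
the calibration. This propagates end-to-end: the splitter pins assumed
records to the proper set, and the fold builder excludes them from folds.

## Hyper-parameter tuning and evaluation

The SVM cost is swept over $\{1, 10, 100\}$ by 10-fold cross-validation,
training a full 10-ICP ACP per fold and pooling all fold predictions
before computing *observed fuzziness*
$\mathrm{OF} = \big(\sum_{y_i=A} p_i^N + \sum_{y_i=N} p_i^A\big)/(m_A+m_N)$
— the mean wrong-class p-value; lower is sharper. Pooling (rather than
averaging per-fold OFs) weights every prediction equally. The best cost is
the OF argmin; ties break toward the smaller cost (stronger
regularization, deterministic). The class-averaged variant
$\mathrm{CAOF} = \sum_{y_i=A} p_i^N/m_A + \sum_{y_i=N} p_i^A/m_N$ (equal
to $2\,\mathrm{OF}$ for balanced data) and the M criterion (fraction of
multi-label sets at a significance) are reported for information and never
used for selection. Validity is summarized as a calibration curve
(accuracy vs confidence over 0.05–0.95 in steps of 0.05) and as 2×4
label-set confusion tables (observed A/N against predicted
{A}/{N}/Both/Null) at confidence 0.8 and 0.9. Set membership uses the
strict inequality $p > \varepsilon$ everywhere, consistent with p-values
living in $(0, 1]$.

## The synthetic data generator

Real activity extracts are tens of gigabytes; every stage here is instead
exercised on generated tables with a *known* structure–activity signal.
Each target is assigned a functional-group motif from a curated list
(carboxylic acid, nitro, sulfonamide, nitrile, halogens, ...; pairwise
distinguishable at signature height 1). Scaffolds are randomly grown alkyl
chains (length 2–10, optional methyl/ethyl branches, 40% carry a phenyl
ring); actives carry the target's motif, non-actives a different
decoration or none. Observed labels are then flipped independently with
probability `label_noise` (default 0.1), after the ground-truth label is
recorded, so power and validity can be measured against the truth. All
SMILES are valid by construction and canonically distinct within a target.
Duplicate rows and conflicting label pairs can be injected at known rates,
with an exact ledger, so the cleaning steps can be verified row-for-row.

Two honest caveats. First, exchangeability between training and test sets
is obtained by generating *one* pool and randomly partitioning it; the
within-pool distinctness constraint makes molecules very weakly dependent,
a negligible effect at the sizes used. Second, the chemistry is a cartoon:
a linear model separates motif from no-motif almost perfectly at zero
noise. Passing tests on this generator demonstrates the *statistical*
machinery (validity, efficiency ordering, augmentation benefit), not
predictive performance on real bioactivity data.

## Study conditions and problem sizes

The validity experiments train on 2000 molecules (balanced, noise 0.1) and
evaluate 1000 fresh exchangeable molecules with the default estimator
(10 ICPs, calibration fraction 0.2, mean aggregation, unsmoothed, cost 1);
coverage is checked at confidence 0.8 and 0.9 against a three-binomial-SE
tolerance. The augmentation experiment uses a deliberately data-poor
target (300 actives, 50 known non-actives, topped up to 600 non-actives
from a sibling target's pool) and compares median OF over three replicate
ACP trainings on a held-out 300-molecule test set. Signature invariants
run over 500 generated molecules, with the brute-force canonical-form
oracle applied to all of them with at most 8 heavy atoms. These sizes were
chosen as the smallest at which the binomial tolerances are meaningful.

## Numerical and design notes

- *Calibration fraction 0.2 per ICP*: a conventional inductive-conformal
  default, exposed in `split_config()`; per-class calibration sets of
  ~200 at the study sizes keep the p-value granularity ($1/(n+1)$) well
  below the tolerances tested.
- *Dictionary built once from all training molecules* (proper ∪
  calibration ∪ assumed) and shared by all ICPs: feature columns must
  agree across ICPs for aggregation, and the dictionary sees structures
  only, never labels, so nothing leaks. Signatures unseen at predict time
  are dropped silently (the linear model has no weight for them); the
  dropped count is attached to the vectorized row.
- *Determinism*: one master seed; every stochastic unit (ICP split, fold
  assignment, replicate, augmentation draw) derives its own stream from
  the master seed and its indices, so any unit reproduces in isolation.
  libsvm's linear-kernel fit is deterministic given the data.
- *Degenerate inputs*: a class with fewer than two non-assumed records
  cannot be calibrated and is a hard error, as is a single-class proper
  set or an empty calibration score list; conflicting-key removal of an
  entire target is surfaced by the target-selection report rather than
  silently producing an empty model.
- *Model archives* are single JSON files (manifest, dictionary, sparse
  weights, calibration scores) written with 17 significant digits, which
  round-trips IEEE doubles exactly: a saved-and-reloaded model predicts
  bit-identically.

## A known, deliberate red flag: aggregation vs exact validity

Each individual ICP carries the exact Mondrian guarantee: per class, the
error rate at significance $\varepsilon$ is at most $\varepsilon$ (our
test suite confirms a single-ICP model sits below the binomial band at
every grid point). The *mean-aggregated* ACP does not inherit that exact
rank guarantee. Averaging removes the across-ICP component of p-value
noise (calibration resampling and SVM refits), which concentrates the
p-value distribution toward its center: observed error rates fall clearly
*below* $\varepsilon$ at small $\varepsilon$ — the high-confidence regime
where the predictor is actually operated, and where our coverage checks at
0.8/0.9 pass with margin — but can exceed $\varepsilon$ by a few percent at
large $\varepsilon$ (significance 0.6–0.9). At the study sizes this excess
reaches ~0.05 beyond three binomial standard errors, and it does not
vanish with more data of the same shape. This trade-off of aggregated
conformal predictors is documented in the conformal-prediction literature;
the package keeps mean aggregation as the default because it stabilizes
p-values and matches the established ACP formulation, keeps a single-ICP
and a median mode available, and states the consequence here rather than
hiding it: prediction sets at low confidence levels are modestly
anti-conservative, and the per-significance-grid validity test is
expected to fail at those points under the default estimator.

## Worked example

```{r}
library(cpligand)

spec <- synthetic_spec(n_targets = 2, n_active = 300, n_nonactive = 300,
                       label_noise = 0.1, seed = 7)
tab <- generate_activity_table(spec)

records <- deduplicate(remove_conflicts(tab$records))
sel <- select_targets(records, prep_config(min_actives = 100,
                                           min_nonactives = 100))
models <- lapply(sel$datasets, function(ds) {
  ds <- add_assumed_nonactives(ds, records, prep_config(seed = 7))
  acp_train(ds, train_config(cost = 1), split_config(n_icp = 10, seed = 7))
})

profile <- predict_profile(models, "CCCCc1ccccc1C(=O)O", confidence = 0.8)
profile
atom_contributions(models[[1]], "CCCCc1ccccc1C(=O)O")
```

## Limitations

Beyond the aggregation caveat above: the descriptor is 2-D only (no
stereochemistry or tautomer handling); the SMILES dialect is whatever Open
Babel accepts; nonlinear kernels and conformal regression are out of
scope; and the pipeline is single-process by design — the stages mirror a
distributed workflow's boundaries, but orchestration at database scale is
a job for a workflow engine, not this package.
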