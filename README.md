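# DisorderBench

Assessment toolkit for per-residue predictors of protein intrinsic
disorder and of disordered binding regions.

Intrinsically disordered proteins and regions (IDPs/IDRs) do not adopt a
stable fold, and many methods predict disorder — a score and/or a binary
state per residue. Benchmarking such methods is mostly a problem of
*conventions*: how negatives and unknown residues are defined, how scores
are rounded and thresholds resolved, and how degenerate confusion
matrices are scored. DisorderBench implements that machinery end to end
for assessors and method developers:

* **Reference construction** (`buildReference()`): three residue-level
  reference modes from interval annotations — disorder with all-negative
  complement (`disprot`), disorder vs observed structure with masking of
  unknown residues (`disprot_pdb`, where disorder always overwrites
  structure), and binding (`binding`, retaining all-negative targets).
* **Prediction conventions** (`readPredictions()`, `roundScores()`,
  `resolveThreshold()`): half-up rounding to 3 decimals, states-as-scores
  fallback, threshold inference from states (minimum state-positive
  score) with declared/0.5 fallbacks, `score >= threshold`
  classification.
* **Metrics** (`pointMetrics()`, `computeCurves()`,
  `bootstrapMetric()`, `compareMethods()`): F-beta/MCC/rates with
  explicit zero-denominator conventions (MCC = 0 whenever any marginal is
  0); F_max = max F1 over the fixed 0.001-step threshold grid; ROC AUC by
  trapezoid with (0,0)/(1,1) endpoints; dataset (concatenated residues)
  vs target (unweighted per-protein mean) strategies; 1000-replicate
  residue-level bootstrap with Student-t intervals; paired two-tailed
  t-tests between methods.
* **Baselines**: `randomBaseline()` (uniform scores, threshold 0.5),
  `shuffledBaseline()` (global label permutation — preserves the dataset
  positive count exactly), `conservationBaseline()` (base-2
  Jensen–Shannon divergence of per-position frequency profiles against
  BLOSUM62 background, positive above 0.4, with an inversion flag), and
  `structureComplementBaseline()` (everything not covered by structure is
  disordered).
* **Challenges** (`runChallenge()`, `idpChallenge()`,
  `subsetEvaluation()`): full ranking reports with curves, bootstrap CIs
  and pairwise p-values, and the protein-level fully-disordered-protein
  challenge (a protein is an IDP when ≥95% of residues are annotated or
  predicted disordered), ranked by F1.
* **Synthetic fixtures** (`fixtureSpec()`, `generateDataset()`,
  `generatePredictions()`, `aucOracle()`, `generateProfiles()`): complete
  benchmarks with exact bookkeeping and predictors whose expected AUC is
  known analytically.

See `vignettes/assessing-disorder-predictors.Rmd` for the full account of
the models and conventions.

## Worked example

```r
library(DisorderBench)

d   <- generateDataset(fixtureSpec(nTargets = 100, seed = 42))
ref <- buildReference(d$targets, d$annotations, "disprot")
ref
#> ReferenceSet (mode=disprot): 100 targets, 36464 residues
#>   positives 10979 | negatives 25485 | masked 0

preds <- list(
  generatePredictions(d, noisyPredictorSpec(4, 2, 2, 4), seed = 1,
                      methodName = "NoisyA"),
  randomBaseline(d$targets, seed = 2),
  shuffledBaseline(ref, seed = 3))

rep <- runChallenge(ref, preds, nReplicates = 1000, seed = 7)
rep$ranking[, c("method", "f_max", "auc", "f1", "mcc", "bac",
                "ci_low", "ci_high")]
#>     method f_max   auc    f1     mcc   bac ci_low ci_high
#> 1   NoisyA 0.731 0.896 0.724 0.59341 0.813  0.717   0.730
#> 2   Random 0.463 0.501 0.378 0.00314 0.502  0.370   0.385
#> 3 Shuffled 0.463 0.506 0.310 0.01229 0.506  0.301   0.317
```

The synthetic "NoisyA" predictor draws scores from Beta(4, 2) at
disordered residues and Beta(2, 4) elsewhere; its measured AUC (0.896)
matches the analytic expectation `aucOracle(noisyPredictorSpec(4, 2, 2,
4))` = 0.8968. The two randomization baselines sit at AUC ≈ 0.5, and
their F_max ≈ 0.463 equals the F1 of calling everything disordered at
this prevalence (2p/(1+p) with p ≈ 0.30) — the floor any informative
method must beat. The bootstrap CI bounds are residue-level
1000-replicate Student-t intervals on F1 at each method's resolved
threshold.

Protein-level IDP challenge (≥95% disordered), same objects:

```r
idpChallenge(ref, preds)$ranking[, c("method", "tn", "fp", "fn", "tp",
                                     "f1", "bac")]
#>     method tn fp fn tp f1 bac
#> 1   NoisyA 94  0  6  0  0 0.5
#> 2   Random 94  0  6  0  0 0.5
#> 3 Shuffled 94  0  6  0  0 0.5
```

None of these per-residue predictors calls ≥95% of any protein
disordered, so all three miss the 6 synthetic IDPs — the zero-denominator
conventions (MCC = F1 = 0, BAC = 0.5) score them identically, exactly as
an all-negative protein-level predictor is scored in published
assessments (`idpBenchmarkTable()` ships 34 published confusion-matrix
rows as worked examples).

A thin command-line front end over the same functions is provided at
`inst/scripts/disorderbench.R` (subcommands `fixtures`, `build-ref`,
`evaluate`, `idp`).

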