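---
title: "Assessing intrinsic disorder predictors: reference construction, metrics and baselines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing intrinsic disorder predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DisorderBench)
```

## The assessment problem

Intrinsically disordered proteins and regions (IDPs/IDRs) lack a stable
three-dimensional fold under physiological conditions. Dozens of methods
predict, per residue, whether a protein position is disordered, and many
additionally predict which disordered residues mediate binding. Comparing
such methods fairly requires (i) residue-level reference sets built from
curated annotations with explicit rules for negatives and for residues
whose status is unknown, (ii) a single evaluation convention for scores,
states and thresholds, and (iii) naive baselines that expose how much of a
method's apparent skill is explained by trivial signals. DisorderBench
implements that assessment machinery as a reusable toolkit, together with
a synthetic data generator so that every component can be exercised, and
its statistical behaviour verified, without any external download.

## Reference sets

A reference assigns each residue of each target one of three labels:
positive (disordered, or binding in the binding challenge), negative, or
masked. Three modes are built by `buildReference()`:

* **disprot** — positives are residues inside curated disorder intervals;
  every other residue is negative. No residue is masked. This treats
  un-annotated residues as ordered, which is pessimistic for incompletely
  curated targets.
* **disprot_pdb** — positives as above; negatives are residues observed in
  an experimental structure and *not* annotated as disordered; all other
  residues are masked and excluded from every metric. Disorder always
  overwrites structure: a residue both disorder-annotated and
  structure-observed is positive. No further filtering of disordered
  residues inside deposited structures is applied.
* **binding** — positives are residues inside binding intervals; all other
  residues are negative. Targets with no binding annotation are retained
  as all-negative entries: in a realistic benchmark the majority of
  targets contribute only negatives, and dropping them would inflate
  precision.

Interval annotations are 1-based inclusive at every interface. Within one
class, overlapping or adjacent intervals are merged silently
(`GenomicRanges::reduce`); across classes only the precedence rule above
applies. Targets without any annotation are retained (all-negative, or
all-masked in `disprot_pdb` mode). The builder asserts the partition
invariant — positives + negatives + masked = target length — on every
build, and moving from `disprot` to `disprot_pdb` can only turn negatives
into masked residues, never touch a positive.

## Prediction conventions

Predictors emit a score in [0, 1] per residue and optionally a binary
state. The conventions, applied in `roundScores()` and
`resolveThreshold()`, are:

* scores are rounded **half-up to three decimals**, so there are 1001
  representable values and the fixed grid 0.000–1.000 (step 0.001) is an
  exhaustive threshold scan;
* missing scores: states are copied into scores verbatim;
* missing states: derived from scores at the resolved threshold;
* threshold precedence: inferred from states (the minimum score among
  state-positive residues), else the author-declared value, else 0.5;
* classification is `score >= threshold`. The non-strict rule makes a 0.5
  threshold split uniform random scores evenly in expectation, and the
  inferred minimum-positive-score threshold reproduce the provided
  states exactly whenever those states came from any threshold rule.
  Residues whose stated label disagrees with the re-derived one are
  counted and reported, never silently ignored.

## Metrics and degenerate-denominator conventions

`pointMetrics()` computes F-beta (0.5, 1, 2), MCC, TPR, TNR, PPV, FPR and
balanced accuracy from a confusion matrix. Conventions: F-beta is 0 when
its denominator is 0; MCC is 0 whenever any of the four marginals
(predicted positives/negatives, reference positives/negatives) is 0 —
which is why fully disordered targets, or targets predicted fully one
class, contribute MCC 0 under the target strategy; simple rates are 0 on
a zero denominator. Every fired convention is recorded in an attribute.

`computeCurves()` evaluates the full grid. Under the **dataset** strategy
all targets' residues are concatenated and one confusion matrix per
threshold is computed; under the **target** strategy metrics are computed
per target and their unweighted mean is taken per threshold (no length
weighting — a choice that treats each protein, not each residue, as the
experimental unit). F_max is the maximum F1 over the grid, reported with
the lowest threshold attaining it (at equal F1 the lower threshold has
equal or higher recall, and a deterministic tie-break is needed for
reporting). AUC is the trapezoidal area under the ROC points, always
augmented with (0, 0) and (1, 1) so degenerate score distributions still
integrate to a defined area; on the grid this equals the rank-statistic
(Mann–Whitney, ties counted half) AUC exactly, which the test suite
asserts. Whether AUC is taken over the grid or over all distinct raw
scores is immaterial after rounding, since every rounded score lies on
the grid.

## Bootstrap and method comparison

`bootstrapMetric()` resamples the concatenated (label, score) residue
pairs with replacement 1000 times and recomputes the metric per
replicate. Internally the resample is drawn as one multinomial over the
2 × 1001 distinct (label, rounded-score) cells — distributionally
identical to resampling individual residues, and O(cells) per replicate.
The confidence interval is the replicate mean ± t(0.975, B−1) × replicate
standard deviation. Because the replicate standard deviation shrinks as
1/sqrt(n) with dataset size, duplicating a dataset k-fold shrinks the
interval width by about 1/sqrt(k); the acceptance suite measures exactly
that at k = 1, 4, 16.

`compareMethods()` is a two-tailed paired t-test. Pairing can be over
bootstrap replicates or over per-target values; the package defaults to
paired-over-replicates because every method is always evaluated on the
same resampled residues, giving a common variance structure even when
per-target values are dominated by the MCC-zero convention. Zero-variance
differences yield p = 1 (equal means) or a flagged degenerate 0.

## Baselines

* **Random** — i.i.d. uniform scores, threshold 0.5. Its AUC is 0.5 up to
  sampling error; the acceptance suite bounds the deviation at 0.01 on a
  dataset of more than 10^5 residues.
* **Shuffled** — a global permutation of the unmasked reference labels
  used as scores. Preserves the dataset-level positive count exactly (an
  invariant asserted on every run), but not per-target counts; its
  expected precision and recall both equal the prevalence.
* **Conservation** — per-position base-2 Jensen–Shannon divergence
  between the position's amino-acid frequency profile (e.g. PSSM-derived)
  and the BLOSUM62 background frequencies; values lie in [0, 1] and a
  score strictly above 0.4 is called disordered. The package implements
  this literal rule as the default and exposes `invert = TRUE`
  (1 − JSD), since the motivating rationale — disordered regions are on
  average less conserved — would point the signal the other way; the
  toolkit takes no position on which direction a given profile set
  warrants. Base-2 logarithms keep the [0, 1] bound without extra
  normalisation, and 0·log 0 = 0.
* **Structure complement** — score 1.0 outside every structure-coverage
  interval, 0.0 inside, threshold 0.5; a target with no coverage at all
  is called fully disordered. Observed/close-homolog/remote-homolog/
  domain-prediction variants differ only in the provenance of the input
  coverage, which this package consumes as precomputed interval files
  (homology searches are out of scope).

## Challenges

`runChallenge()` orchestrates an evaluation: per method it computes both
strategies' curves, point metrics at the resolved threshold, a bootstrap
CI, and across methods a pairwise p-value matrix; methods are ranked by
dataset F_max with rank keys rounded to three decimals and ties broken by
method name, so equal-looking reports order deterministically.
`idpChallenge()` is the protein-level challenge: a target is a fully
disordered protein when at least 95% of its residues are annotated —
respectively predicted, from binary states at the method's resolved
threshold — as disordered; methods are ranked by F1. The 95% cut-off is
configurable because published sensitivity analyses report that nearby
thresholds do not substantially change rankings. `subsetEvaluation()`
reruns the identical machinery on any target subset (e.g. a taxonomic
partition supplied by the user; taxonomy assignment itself is out of
scope).

## The synthetic generator

`generateDataset()` draws a complete benchmark from `fixtureSpec()`.
Defaults emulate the composition of a curated 646-target disorder
benchmark: 40 of 646 targets fully disordered, 232 of 646 carrying a
binding region, disorder intervals at least 10 residues long, binding
regions always inside disorder. Sequence lengths are log-normal with
median 300 and log-SD 0.6 (bounded to [30, 2000]) — a deliberately loose
imitation of curated-database length scales, with no claim of matching
any real length distribution. Non-IDP targets receive disorder intervals
by rejection-sampled placement with a hard attempt cap (an infeasible
density errors out rather than silently under-filling, which would break
the bookkeeping guarantee); structure intervals cover a configurable
fraction of each ordered segment and occasionally overhang into disorder
to exercise the precedence rule. All bookkeeping is recomputed from the
final canonical annotations, so it equals an independent recount of the
emitted files by construction — and the tests recount anyway.

`generatePredictions()` draws scores from two Beta distributions (one per
class). The expected AUC of such a predictor is `P(S+ > S−) + P(S+ =
S−)/2`, which `aucOracle()` evaluates exactly on the 1001 rounding bins;
the acceptance suite requires the measured AUC on >10^5 residues to land
within 0.01 of this oracle. `generateProfiles()` mixes the background
with a point mass on the position's own residue at a tunable contrast, so
the conservation baseline's separation ranges from none (contrast 0, AUC
0.5) to complete.

What the generator does *not* emulate: real amino-acid composition biases
of IDRs, sequence-identity structure among targets, taxonomy, or
annotation noise. Passing tests therefore certify the correctness and
calibration of the assessment machinery, not the real-world accuracy of
any predictor.

## Numerical choices and problem sizes

Half-up decimal rounding (not IEEE half-even) matches the three-decimal
reporting convention; an epsilon of 1e-9 absorbs binary representation
error in both rounding and threshold comparison. The test and acceptance
runs use 330-target datasets (~1.2 × 10^5 residues) for the stochastic
calibration checks, 100 random fixtures of up to 10^3 residues for the
exhaustive F_max oracle, and 1000-replicate bootstraps — sizes chosen so
each statistical bound is comfortably tighter than its tolerance.

## Known limitations

* The toolkit consumes precomputed interval and profile files; it does not
  run homology searches, map structures onto sequences, or curate
  annotations, and partial structure mappings are assumed to be already
  expressed in target coordinates.
* Per-residue bootstrap ignores within-protein correlation of labels;
  intervals are therefore anti-conservative for clustered errors, a
  property inherited from the convention it implements.
* The conservation baseline's direction ambiguity is exposed, not
  resolved.
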