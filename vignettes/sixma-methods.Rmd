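---
title: "Predicting DNA N6-methyladenine sites with a two-layer ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA N6-methyladenine sites with a two-layer ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sixma)
```

## The problem

N6-methyladenine (6mA) is a DNA modification that, in plant genomes such as
rice, concentrates at characteristic sequence contexts (notably GAGG
motifs). Experimental detection (e.g. SMRT sequencing) is expensive, so a
common strategy is to train a classifier that decides, for a 41-nt window
centered on an adenine, whether that adenine is methylated. `sixma`
implements such a predictor as a two-layer ensemble over heterogeneous
sequence representations, together with everything needed to validate it:
feature optimization, stratified cross-validation, metric and
significance-test machinery, and a synthetic benchmark generator.

All windows are 41 nt long with the queried adenine at position 21 (1-based,
20 nt of flank on each side). Only the forward strand is considered: windows
are never reverse-complemented, which is a deliberate, flag-free limitation
of the tool.

## Sequence encodings

Five encodings are used by the default model; two more (`DBE` alone and
`KMER`) are available in the registry.

* **NUM** (40 values) maps bases alphabetically to 0.25 (A), 0.50 (C),
  0.75 (G), 1.0 (T). The central adenine is constant by construction and is
  omitted.
* **MBE** (164 values) is the positionwise one-hot code over base order
  A, C, G, T for all 41 positions.
* **DBE_LPF** (200 values) concatenates two views of the 40 overlapping
  dinucleotides. The binary part (160 values) writes each dinucleotide as
  the 4-bit code of its index under letter order A, T, C, G — the unique
  order consistent with the reference codes AA = (0,0,0,0),
  AT = (0,0,0,1), AC = (0,0,1,0) — so GG = (1,1,1,1). The local frequency
  part (40 values) gives, for each position j = 2..41, the number of
  occurrences of the dinucleotide ending at j within the length-j prefix,
  divided by j; for poly-A this is (1/2, 2/3, ..., 40/41).
* **RFHC** (164 values) encodes each base by three chemical indicator bits
  (ring count: purine vs pyrimidine; hydrogen bonding: weak vs strong;
  functional group: amino vs keto), giving A = (1,1,1), C = (0,0,1),
  G = (1,0,0), T = (0,1,0), plus the prefix density of the current base
  (its count in positions 1..i divided by i).
* **KNN** (7 values) measures similarity to labeled training windows with a
  +2 (match) / −1 (mismatch) positionwise score, and reports the fraction
  of positives among the n nearest references for
  n = 2, 4, 8, 16, 32, 64, 128. Ties in similarity are broken by reference
  insertion order, which makes the encoding deterministic. The per-n
  feature is the *positive fraction*: the sources describing this family of
  predictors do not pin down the exact functional form, and the fraction is
  the standard convention; this is the encoding we consider the main
  reproduction risk.
* **KMER** (1364 values) is the concatenation of normalized k-mer frequency
  blocks for k = 1..5. It is provided for completeness but is not part of
  the default model, where it underperforms the five encodings above.

Because the KNN encoding looks up the training set itself, it is the one
encoding that can silently leak labels. Two guards are built in and tested:
inside any cross-validation the reference is rebuilt from the training
folds only, and when a record being encoded is itself part of the reference
its exact-identity match is removed before ranking (`exclude_self`, on by
default). An injected leak (self-match allowed) drives null-data accuracy
far above chance, which is exactly what the guard test checks.

## Feature optimization

For each non-KNN encoding (KNN's 7 features are exempt) features are first
ranked by the F-score

$$F(i) = \frac{(\bar{x}^{+}_i - \bar{x}_i)^2 + (\bar{x}^{-}_i - \bar{x}_i)^2}
{\frac{1}{n^+ - 1}\sum_j (x^{+}_{i,j} - \bar{x}^{+}_i)^2 +
 \frac{1}{n^- - 1}\sum_j (x^{-}_{i,j} - \bar{x}^{-}_i)^2},$$

then a sequential forward search grows prefixes of the ranked list
(starting from the top two features) and scores each prefix by stratified
k-fold CV accuracy of the classifier; the accuracy-maximizing prefix is the
optimal feature set, with ties resolved toward the smaller prefix. Folds
are fixed by the seed and shared across prefix sizes so the accuracy curve
is internally comparable. Hyperparameters are tuned once on the full
feature set and frozen during the search; re-tuning at every prefix size
would multiply the cost by the grid size for, in our experience, no
qualitative change in the selected dimension, though it can in principle
shift the optimum.

`sfs_step` strides the prefix sizes (the full dimension is always
evaluated). The per-dimension curve corresponds to `sfs_step = 1`; the
validation runs shipped with the package use a stride of 16 to keep the
search affordable, which coarsens — but does not bias — the choice of k.

## Classifiers

* **SVM** with RBF kernel $K(x_i, x_j) = \exp(-\gamma \lVert x_i - x_j
  \rVert^2)$ (e1071/libsvm). The full search grid is
  $C \in \{2^{-5}, 2^{-3}, \ldots, 2^{15}\}$ and
  $\gamma \in \{2^{-15}, 2^{-14}, \ldots, 2^{-5}\}$ (11 × 11); the reduced
  grid is a 5 × 5 subset of the same ranges. Inputs are min-max scaled with
  parameters learned from the training data. Probabilities come from a
  Platt sigmoid fitted by the package on the training decision values with
  the usual regularized targets; this is deterministic, unlike libsvm's
  internal cross-validated calibration, and the exact calibration affects
  only the probability scale, not the ranking.
* **ERT** — extremely randomized trees (ranger, `splitrule =
  "extratrees"`, one random split per candidate feature, no bagging:
  every tree sees all training rows). The full grid is ntree 50..2000
  (step 25), mtry 1..15, nsplit 1..12, where nsplit — the minimum number of
  samples required to split a node — is mapped to ranger's `min.node.size`,
  the closest control that implementation exposes.
* **RF** and **XGB** are available behind the same interface with
  library-default single-row grids. They are flagged experimental: their
  tuning ranges are not part of this package's validated configuration.

Grid search is exhaustive, maximizes mean CV accuracy under a shared
stratified fold assignment, and breaks ties toward the first grid row, so
tuning is reproducible bit-for-bit from the seed.

## The two-layer ensemble

Within each classifier (layer 1), the five per-encoding probability
streams are combined as $p = \sum_k w_k p_k$ with $w_k \ge 0$,
$\sum_k w_k = 1$. The weights are found by exhaustively scoring every
point of a simplex grid (step 0.1 by default, 1001 points for five
streams; 0.05 available) by accuracy at the 0.5 threshold. Because the
grid contains the corners, the optimized ensemble can never score below
its best single stream on the data used for the search. The weights are
fitted on out-of-fold probabilities from the same stratified split used
throughout training — never on resubstitution probabilities, which would
reward overfit streams.

Layer 2 averages the per-classifier ensemble scores with equal weights
(default classifier set: SVM + ERT) and thresholds at 0.5. A score exactly
equal to the threshold is called positive; this boundary convention is
documented and tested. Restricting the model to one classifier and one-hot
weights reproduces the corresponding single-encoding model exactly, which
is one of the package's invariant tests.

## Evaluation

Performance is reported as sensitivity, specificity, accuracy, the
Matthews correlation coefficient, and AUC. Cross-validation is stratified:
every fold carries equal (±1) numbers of positives and negatives.
`cross_validate()` retrains the entire pipeline per fold — KNN references,
feature subsets, hyperparameters and layer-1 weights are all fold-internal
— and pools the out-of-fold predictions into a single confusion table
(micro-averaging). Pooling is the default because MCC on small per-fold
tables is unstable; the macro average of per-fold accuracies is available
via `macro = TRUE`. AUC uses the rank (Mann–Whitney) formulation with
tie-averaging, which equals trapezoidal integration of the ROC curve.

Two predictors are compared with McNemar's chi-square on the discordant
pairs, $(b - c)^2/(b + c)$ with 1 df and no continuity correction
(`exact = TRUE` switches to the exact binomial version, recommended when
$b + c < 25$). Robustness between cross-validation and an independent
evaluation is summarized as ΔACC, the absolute accuracy difference in
percentage points.

## The synthetic benchmark

Real 6mA benchmarks are external downloads; the generator in
`simulate_dataset()` reproduces their *structure* so the pipeline can be
validated end-to-end offline: 41-nt windows with a central adenine,
balanced classes, a GAGG motif implanted in positives at a high rate and
in negatives at a background rate (negatives in the real benchmarks are
GAGG-containing coding sequence, so the motif must not be a giveaway on
its own), and a positional bias that enriches an extended GAGG-flavoured
consensus around the center of positives (A/G alternation over positions
17–25, each favored base with probability 0.8). The implant offset is
sampled so the motif never overwrites the central adenine — which also
means the implanted motif is only weakly visible to positionwise encoders;
the positional bias is the main recoverable signal, and its strength was
chosen once from a binomial tail computation (Bayes accuracy of the bias
channel alone ≈ 0.96) so that a competent pipeline should recover the
planted signal almost completely. The bias is a simulation device and
carries no biological claim.

The default configuration is the strong-signal study used by the tests and
the acceptance script: 400/400 training windows, 200/200 held-out windows,
implant rates 0.9 vs 0.1. `null_dataset()` applies the identical generative
process to both classes (uniform background, no motif, no bias), giving the
chance-level control used for leakage and type-I-error checks.

What passing these tests shows is that the implementation recovers a known
planted signal and stays honest on a signal-free one. It does not show
field performance on real rice data: real benchmarks have sequence
redundancy structure, composition biases and experimental label noise the
generator does not emulate.

## Numerical and design choices

* All randomness (fold shuffles, simulation draws, tree construction)
  derives from explicit integer seeds; training twice with the same seed
  yields identical models, and simulation output is byte-identical.
* Degenerate cases are defined rather than left to chance: a feature
  constant within both classes has F-score 0 (with a warning); a zero MCC
  denominator yields MCC 0 (with a warning); equal-accuracy ties go to the
  smallest prefix (SFS), the first grid row (tuning), or the
  lexicographically first simplex point (weights).
* Windows containing `N` or with a non-adenine center are rejected at the
  boundary (`validate_window`) with a reason code, so encoders can assume
  clean input. During genome scanning, adenines closer than 20 nt to a
  contig edge are dropped rather than padded.
* The validation runs shipped with the package (tests and
  `scripts/acceptance.R`) use 3-fold CV, SFS stride 16 and the reduced
  grids; these are the package's chosen problem sizes for the synthetic
  study, and the same code scales to 10 folds, stride 1 and the full grids
  via `run_config()`.

## Known limitations

* Forward-strand only; no reverse-complement calling.
* The exact KNN feature definition and the original probability
  calibration are conventions chosen here (documented above); validation
  therefore relies on properties and planted-signal recovery, not on
  reproducing third-party probability values.
* RF/XGB plug-ins are untuned by design.
* The generator does not emulate SMRT kinetics, ModQV score filtering,
  redundancy reduction, or genome-wide 6mA distribution.
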