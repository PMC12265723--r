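---
title: "Hyperdimensional classification of microbial profiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperdimensional classification of microbial profiles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdclassify)
```

## The model

`hdclassify` implements an associative-memory classifier for quantitative
microbial profiles built on hyperdimensional computing (HDC) with the
Multiply–Add–Permute (MAP) vector algebra. Every piece of information lives in
a `D`-dimensional space (default `D = 10,000`) as a *hypervector*. Three
operations combine them:

* **bundling** (`hv_bundle`) — element-wise addition. The superposition stays
  similar to each summand, which is what lets one vector represent a set of
  samples.
* **binding** (`hv_bind`) — element-wise multiplication. For bipolar
  (±1) vectors it is exactly self-inverse and quasi-orthogonalizes its inputs.
* **permutation** (`hv_permute`) — circular coordinate rotation, used to mark
  *position*: the same abundance value at taxon 3 and taxon 7 contributes two
  quasi-orthogonal patterns.

We use the bipolar (−1/+1) representation throughout, not the binary (0/1)
variant: self-inverse binding and cosine similarity are only exact in the
bipolar system, and nothing in the pipeline needs the binary form.

### Encoding abundances

Numeric values are quantized onto an ordered family of *level hypervectors*
(`build_level_vectors`). Level 1 is a fresh random bipolar vector; walking up
the `m` levels flips a cumulative total of `floor(D/2)` coordinate signs,
spread evenly over the `m − 1` steps, with flip positions drawn once without
replacement. Because a bipolar pair differing in `f` coordinates has cosine
exactly `(D − 2f)/D`, this construction gives

* a linear similarity gradient — adjacent levels nearly identical, similarity
  decaying with level distance; and
* quasi-orthogonal endpoints — `cos(L_1, L_m) = 0` exactly for even `D`.

A cruder construction that flips half the bits *between each pair of adjacent
levels* would make every level quasi-orthogonal to every other and destroy the
gradient; the cumulative-budget scheme is the standard level-encoding choice
and the one consistent with both requirements at once.

A sample with abundances `x_1 … x_M` becomes

$$S \;=\; \sum_{j=1}^{M} \rho^{\,j-1} \, L(x_j),$$

the bundle of its level vectors, each rotated by its feature position
(`encode_sample`, `encode_profiles`). Encoding is exact integer arithmetic and
independent of evaluation order.

### Training, prediction, retraining

Training (`hdc_fit`) bundles each class's encoded samples into one class
hypervector, `C_c = Σ_{i: y_i = c} S_i`. Prediction (`predict`) encodes a
query and returns the class with the highest cosine similarity. Exact
similarity ties go to the first label in ascending sort order — a documented
canonical rule rather than an incidental iteration order.

Bundling many samples accumulates crosstalk, so `hdc_retrain` runs
perceptron-style correction passes: every misclassified training encoding is
added to its true class vector and subtracted from the wrongly predicted one,
until the training error reaches zero or stops decreasing (or a safety cap of
100 passes). Because a correction pass is applied *before* the error that
judges it is measured, a literal implementation can terminate one step after
the error worsened and return the degraded model; `hdc_retrain` instead
snapshots every iterate and returns the lowest-error one, so retraining can
never hand back a model worse than its input. The full error history and the
accepted pass index are stored on the model.

Class vectors keep full integer entries — no thresholding or clipping after
bundling — because the retraining subtractions must be exactly reversible.
Cosine with an all-zero vector is defined as 0 (maximally non-matching): a
class vector can pass through zero transiently during retraining.

## Feature selection

`backward_eliminate` wraps any classifier honoring the `fit`/`predict`
contract. From the surviving set `F` it scores one candidate model per
feature (trained on `F` minus that feature), keeps all candidates within a
tie tolerance (default `1e-9`, i.e. exact ties up to float noise) of the best
score, and takes the intersection of the best candidates' feature sets as the
next `F`. At least one feature disappears per iteration, so the procedure
terminates in at most `M − 1` iterations. A feature's importance is the
iteration at which it was discarded — the later, the more the model depended
on it; never-discarded survivors rank above everything else.

Two rules are deliberate design choices. The per-candidate evaluator defaults
to mean F1 over stratified 5-fold cross-validation, matching the package's
global evaluation protocol; it is configurable. And the *final* selected set
(`select_features`) is the surviving set produced by the iteration with the
best score, ties broken toward the smallest set — a parsimony rule chosen
because elimination itself only defines the trajectory, not a stopping point.
Elimination stops when a single feature remains (`min_features = 1`), since a
zero-feature model cannot be evaluated.

The wrapper is `O(M²)` in model evaluations; the command-line layer warns
above `M = 2,000` features.

### A fast, exact cross-validation path

When the quantization range is fixed (rather than resolved from the training
data), a sample's encoding does not depend on which fold it falls in. The HDC
classifier therefore exposes a fast cross-validation route that encodes every
sample once and assembles each fold's class vectors by row sums. The fold
assignment, scores, and results are bit-identical to the generic
fit-per-fold loop (asserted by test); it is an optimization, not an
approximation. Retraining or data-resolved ranges fall back to the generic
loop.

## Evaluation protocol

* **F1** (`f1_score`): binary F1 on a designated positive label (default: the
  lexicographically larger label — the averaging mode matters little for the
  balanced-to-moderately-imbalanced datasets the filters admit); macro-F1 for
  more than two classes.
* **Cross-validation** (`cross_validate`): stratified k-fold (default 5),
  deterministic given a seed. Stratification is required by the imbalanced
  datasets this tool targets.
* **Balance filtering** (`balance_score`, `assemble_datasets`): a binary
  dataset's raw balance is its minority fraction; scores are min-max
  normalized *across all candidate datasets* before any retention decision,
  and a study is kept when it has at least 100 samples (strictly fewer is
  dropped) and its normalized score lies in the inclusive window
  `[0.6, 1.0]`. The window comparison carries `1e-9` float slack so exact
  boundary candidates are not lost to the binary representation of ratios.
* **Four-way comparison** (`categorize_comparison`), margin `τ = 0.05`:
  *violet* when HDC beats every baseline by more than `τ`; else *black* when
  any baseline beats HDC by more than `τ`; else *red* when HDC beats at least
  one; else *blue*. The definitions of red ("beats at least one, comparable to
  the rest") and black ("beaten by at least one") overlap when both happen;
  black is given precedence as the conservative reading against HDC.
* **Significant-feature fraction** (`significant_feature_fraction`): the
  percentage of listed taxa whose two-sample Wilcoxon rank-sum test separates
  the classes at `α = 0.05`. The tie-corrected normal approximation is used
  throughout because abundance data carries many tied zeros; the groups are
  unpaired (class sizes differ), so no paired variant is meaningful here.

Baselines (logistic regression, decision tree, SVM, random forest) are thin
adapters over `stats::glm`, `rpart`, `e1071` and `ranger` with library-default
hyperparameters, recorded on the adapter for provenance. The random forest is
run single-threaded with a fixed seed so cross-validation is reproducible.

## The synthetic generator

`generate_profiles` emulates the structure of relative-abundance tables:
log-normal per-taxon abundances (`sdlog` = dispersion, default 1.0), a
log-scale mean shift (default 2.0) on a seed-fixed random subset of
informative taxa in the first class, independent zero-inflation (default
rate 0.3), and closure of each row to a constant total (default 100, the
percentage scale). Closure runs after zero-inflation so zeros stay exact.
Defaults — 100 samples per class, 50 taxa of which 10 informative — are the
package's reference study conditions: large enough for stratified 5-fold
cross-validation and wrapper selection to be meaningful, small enough for the
full elimination harness to run in minutes.

Two properties of the generator deserve attention when interpreting results:

* **Compositional spillover.** Closure redistributes the informative shift:
  when informative taxa grow in one class, every other relative abundance in
  that class shrinks. Non-informative taxa in a spiked dataset therefore show
  real class differences — exactly as in real compositional data. Null-rate
  calibration of the significance utility must use a fully null generator
  (`n_informative = 0`), which the tests do.
* **What it does not model.** No phylogenetic or co-occurrence correlation
  between taxa, no batch effects, no longitudinal structure, and no claim of
  matching any real profiler's marginal distributions. Passing tests on this
  generator demonstrate the machinery's correctness and its behavior under
  known ground truth, not performance on any particular real cohort.

## Numerical and design choices

* Hypervector entries are exact integers end to end; similarity computations
  promote to double precision (exact for all magnitudes reached here).
* Rotation direction (toward higher indices) is fixed and documented; only
  self-consistency matters.
* Quantization clamps out-of-range test values to the boundary bins with a
  warning — unseen samples may exceed the training range and should not
  abort a prediction run.
* The default quantization range is resolved from the training data and
  stored in the model, so test data are always quantized on the training
  scale. For relative abundances a fixed `[0, 100]` range is the natural
  choice and enables the fast cross-validation path.
* `m = 100` levels by default — unit-wide bins on the percentage scale; the
  level count is otherwise a free parameter.
* One global seed fans out to per-component child seeds through a
  deterministic label hash (`derive_seed`), so adding a pipeline stage never
  shifts another stage's random stream.
* Validation problem sizes: the heavy harnesses (retraining contract,
  elimination recovery) run the reference study conditions with `D = 1,000`
  encodings, while geometry and headline cross-validation checks use the full
  `D = 10,000`. The elimination inner loop scores ~1,300 candidate models;
  `D = 1,000` keeps each candidate's 5-fold evaluation fast while staying two
  orders of magnitude above the feature count, which is the regime the
  method's quasi-orthogonality arguments require.

## Known limitations

* Binary (0/1) hypervectors and Hamming-distance prediction are not
  implemented — the bipolar system subsumes them for every operation used
  here.
* Backward elimination on strongly redundant informative sets can discard
  redundant signal taxa in early tie groups; importance ranks are most
  interpretable in the late (small-set) iterations.
* Per-class similarity scores exposed by `predict(..., similarities = TRUE)`
  are raw cosines, not calibrated probabilities.
* Multiclass problems are handled by the same argmax machinery (with
  macro-F1), but the evaluation protocol and filters target binary
  contrasts.

## Worked example

```{r example, eval = FALSE}
library(hdclassify)

syn <- generate_profiles(synthetic_spec(seed = 7))
enc <- encoding_config(value_min = 0, value_max = 100, seed = 7)

model <- hdc_fit(syn$profiles, enc)
hdc_error_rate(model, syn$profiles)

cv <- cross_validate(syn$profiles, hdc_classifier(enc), k = 5, seed = 7)
cv$mean

trace <- backward_eliminate(
  syn$profiles,
  selection_config(classifier = hdc_classifier(
    encoding_config(1000, 100, value_min = 0, value_max = 100, seed = 7))))
head(feature_importance(trace), 12)
```
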