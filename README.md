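# hdclassify

Hyperdimensional computing (HDC) classification for high-dimensional
quantitative microbial profiles, with an HDC-tailored backward
variable-elimination feature selection and the full evaluation protocol
(stratified cross-validated F1, balance-score dataset filtering, four-way
classifier comparison).

## The problem and the approach

Relative-abundance profiles from shotgun metagenomics are wide (hundreds to
thousands of taxa), sparse, compositional, and often class-imbalanced.
`hdclassify` classifies such profiles with a brain-inspired associative
memory built on the Multiply–Add–Permute (MAP) vector algebra:

1. **Encoding.** A numeric range is quantized onto `m` *level hypervectors*
   (default `m = 100` levels, `D = 10,000` dimensions, bipolar ±1 entries).
   Level 1 is random; successive levels flip a cumulative `D/2` coordinate
   budget so that nearby abundances map to similar vectors and distant ones
   to quasi-orthogonal vectors. A sample is encoded as the bundle of its
   position-permuted level vectors:

   S = Σⱼ ρ^(j−1) L(xⱼ),  j = 1 … M taxa.

2. **Training.** Each class hypervector is the exact integer bundle of its
   training encodings: C_c = Σ_{i : yᵢ = c} Sᵢ.

3. **Prediction.** A query is encoded and assigned the class with the highest
   cosine similarity.

4. **Retraining.** Misclassified training encodings are added to their true
   class vector and subtracted from the wrongly predicted one, iterating
   until the training error stops decreasing; the best snapshot is returned.

5. **Feature selection.** Backward variable elimination scores one
   leave-one-out candidate model per surviving taxon (default evaluator:
   mean F1 over stratified 5-fold CV), intersects the tied-best candidates'
   feature sets, and stamps each taxon's importance with its discard
   iteration.

Classical baselines (logistic regression, decision tree, SVM, random forest)
are available behind the same fit/predict contract, and classifier
comparisons are color-categorized (violet / red / blue / black at margin
τ = 0.05). A synthetic generator produces sparse compositional profiles with
known ground-truth informative taxa so the whole pipeline is testable
without external data.

## Worked example

```r
library(hdclassify)

syn <- generate_profiles(synthetic_spec(seed = 7))
syn
#> <labeled_profiles> 200 samples x 50 features
#>   classes: case (100), control (100)
#>   informative: taxon_002, taxon_003, taxon_008, taxon_015, taxon_019,
#>     taxon_026, taxon_028, taxon_031, taxon_039, taxon_042

enc <- encoding_config(value_min = 0, value_max = 100, seed = 7)
model <- hdc_fit(syn$profiles, enc)
hdc_error_rate(model, syn$profiles)
#> [1] 0.03

cross_validate(syn$profiles, hdc_classifier(enc), k = 5, seed = 7)
#> <cv_result> HDC, 5-fold: mean F1 = 0.9618 (folds: 0.909, 0.976, 0.976, 0.974, 0.974)

categorize_comparison(0.69, c(LRC = 0.55, DTC = 0.49, SVC = 0.50, RFC = 0.60))
#> <comparison_outcome> violet: HDC 0.690 vs LRC 0.550, DTC 0.490, SVC 0.500, RFC 0.600 (tau = 0.05)
```

The training error of 0.03 says the bundled class memories recall 97% of
their own samples before retraining; the 5-fold mean F1 of 0.96 is held-out
performance on the synthetic study conditions (10 of 50 taxa informative,
log-scale effect 2.0, 30% zeros); the comparison call reproduces the
four-way color rule — violet because HDC exceeds every baseline by more than
the 0.05 margin.

Feature selection and its importance ranking:

```r
trace <- backward_eliminate(
  syn$profiles,
  selection_config(classifier = hdc_classifier(
    encoding_config(1000, 100, value_min = 0, value_max = 100, seed = 7))))
head(feature_importance(trace), 3)   # last-discarded taxa = most important
select_features(trace)               # best-scoring iteration's survivors
```

A command-line wrapper is installed with the package
(`system.file("scripts", "hdc", package = "hdclassify")`) exposing
`simulate`, `train`, `predict`, `retrain`, `crossval`, `select-features`,
`compare` and `catalog` subcommands; run it with `--help` for the flag list.

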