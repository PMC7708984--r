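---
title: "Methods: sequence encodings, imbalance-aware evaluation, and attribution for ac4C site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence encodings, imbalance-aware evaluation, and attribution for ac4C site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ac4cpred)
```

## The problem and its shape

N4-acetylcytidine (ac4C) is deposited on mRNA cytidines by NAT10 and
influences transcript stability and translation. The classification task
this package addresses takes pre-extracted candidate windows — fixed-width
sequences, conventionally 415 nt, centered on a candidate cytidine and
carrying five consecutive CXX motifs (C followed by any two bases) around
the center — and decides whether the central cytidine is acetylated.
Experimentally mapped benchmarks for this task are strongly imbalanced,
about one site per nine non-sites, and that imbalance shapes every design
choice below: the loss reweighting in the classifier, the stratified
cross-validation protocol, and the emphasis on the precision–recall area
over the ROC area.

The package assumes its inputs are already windowed: there is no genome
arithmetic, transcript extraction, or strand handling here. Sequences are
normalized to the DNA alphabet (uppercase, U mapped to T); IUPAC ambiguity
codes are rejected rather than imputed, because none of the encodings
defines a value for them.

### The central-motif convention

Benchmark windows have five consecutive CXX motifs "in the center", which
leaves the exact register unstated: the central C could be the C of the
first motif or of the third. We place the central position at
c = (L+1)/2 for odd L and require C at positions {c−6, c−3, c, c+3, c+6},
i.e. the central cytidine is the C of the *third* motif. This is the only
register that puts a C at the exact center — the candidate modified
cytidine itself — which is what the window is centered on in the first
place. The check is advisory by default (a warning) because the
constraint belongs to dataset construction, not to prediction-time
inputs; `check_central_motif(strict = TRUE)` and the CLI `--strict` flag
upgrade it to an error, and `has_central_cxx_block(offset =)` lets a user
shift the register if their data uses a different one. All user-facing
coordinates are 1-based.

## Feature encodings

Six encodings are implemented; their closed-form dimensions for a
length-L window are fixed and property-tested (one-hot 4L, NCP 3L, ND L,
NCP+ND 4L, k-mer 84, EIIP L, PseEIIP 64, EIIP+PseEIIP L+64; for L = 415
that is 1660, 1245, 415, 1660, 84, 415, 64 and 479).

Two conventions deserve a note:

* **Nucleotide density.** The density at position i is defined here as
  the count of the resident base within the prefix 1..i divided by i.
  A variant sometimes seen in print sums the indicator over the whole
  sequence while dividing by the prefix length; that variant makes the
  value independent of where the position sits, which defeats the
  encoding's purpose of carrying positional information. The prefix form
  is the one used in the nucleotide-density literature and is adopted
  throughout; the invariant "d_i · i is an integer" is tested.
* **Frequency normalization.** k-mer blocks and the PseEIIP trinucleotide
  frequencies are counts over the (L−k+1) overlapping windows divided by
  the window count, so each block sums to one and blocks of different k
  are commensurate. Each PseEIIP entry is (EIIP_x + EIIP_y + EIIP_z) ·
  f_xyz; since the weights are bounded by 3 · 0.134 = 0.402, the vector's
  sum is bounded by 0.402 — also tested.

One-hot channels follow the order (A, T, G, C) — a printed-definition
convention, kept bit-exactly rather than alphabetized. k-mers and
trinucleotides are ordered lexicographically over (A, C, G, T)
everywhere. Feature names are deterministic ("N198" for position 198 of
the EIIP block, "N12_x" for an NCP channel, "EIIP_GGC" for a PseEIIP
entry) so attribution reports are readable. EIIP constants are used at
full precision with no rounding.

## The classifier

The model is a gradient-boosted decision-tree ensemble with the
binary-logistic objective, trained via the xgboost library. The default
configuration (`ac4c_config()`) is the tuned set for the 415-nt, 1:9
benchmark:

| parameter | default | role |
|---|---|---|
| n_estimators | 1200 | boosting rounds; with eta 0.01 the effective learning budget |
| learning_rate | 0.01 | shrinkage per round |
| max_depth | 5 | tree depth; interaction order of the learned rules |
| min_child_weight | 5 | minimum hessian per leaf, a leaf-size floor |
| gamma | 5 | minimum loss reduction to split; strong pruning |
| subsample / colsample_bytree | 0.8 / 0.8 | stochastic row/column sampling per tree |
| scale_pos_weight | 6 | positive-class gradient multiplier against the 1:9 imbalance |
| seed | 42 | booster RNG (subsampling) |

Imbalance is handled by `scale_pos_weight`, never by resampling, so the
negative distribution the model sees is the one it will face at
prediction time. Training is deterministic given the data and seed: the
booster's own `seed` parameter governs its subsampling RNG,
independently of R's RNG, and training defaults to a single thread.
Model bundles are saved with the booster serialized to raw bytes plus
scheme, feature names, configuration and training class counts, so a
reloaded model validates input compatibility and reproduces predictions
bit-identically.

Baselines for the comparison harness (logistic regression, Gaussian naive
Bayes, AdaBoost on depth-1 stumps, random forest) run with library
defaults and a pinned seed; their rows in `compare_all()` output are
untuned reference points, not tuned competitors. The AdaBoost baseline is
an in-package discrete AdaBoost over `rpart` stumps (50 rounds,
half-log-odds alpha), exposing the same probability contract through a
logistic link on the additive margin. Grid search (`grid_search()`)
scores the full Cartesian product by mean cross-validated metric,
defaulting to AUPRC — the metric that actually ranks models under heavy
imbalance — with ties broken toward the earlier grid position; no default
search space is invented, the caller supplies the grid.

## Evaluation

Threshold metrics use the four-count parameterization: N⁺ and N⁻ are the
class sizes, N₋⁺ the false negatives, N₊⁻ the false positives. With these
identifications ACC, SN and SP take their universal meanings. The
four-count MCC is computed with the numerator 1 − (N₋⁺/N⁺ + N₊⁻/N⁻),
which is algebraically identical to the standard
(TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)) form — an identity the
test suite verifies exhaustively for all class sizes up to 20. The
four-count MCC occasionally appears in print with an accuracy-style
numerator, 1 − (N₋⁺+N₊⁻)/(N⁺+N⁻); that form does not equal the standard
MCC (a 60/100 example with ten errors of each kind gives 0.875 against
the true 0.733), so the equivalent form is the one implemented.

AUROC is computed as the Mann–Whitney statistic (ties at one half),
equivalent to trapezoidal ROC integration with tied scores grouped at
one threshold. AUPRC uses non-interpolated step summation
(average-precision style); linear PR interpolation is deliberately
avoided because it inflates areas exactly in the imbalanced regime this
package targets. The classification threshold for the label metrics is
0.5 on predicted probability and is configurable.

Degenerate situations raise a typed condition
(`ac4c_undefined_metric`) rather than returning a sentinel: sensitivity
without positives, AUROC with one class, MCC with an empty prediction
column. Inside cross-validation a label metric that is undefined on a
fold (e.g. MCC when the model calls every held-out example negative —
routine for a chance-level model at threshold 0.5 under 1:9 imbalance)
is recorded as NA for that fold and excluded from the mean, so the
threshold-free metrics of a shuffled-label control remain reportable;
AUROC/AUPRC still signal if a fold degenerates to one class.
Cross-validation is stratified (within-class shuffle, round-robin deal),
which reproduces the benchmark's exactly proportional per-fold counts —
232 sites and 2171 non-sites per fold for an 1160/10855 training set —
and is seeded; the seed is recorded in every report.

## Attribution

Global attributions are exact Shapley values computed from the tree
ensemble's structure, on the margin (log-odds) scale — the scale on which
the ensemble is additive, so the local-accuracy identity (attributions
plus base value equal the margin output) holds to numerical tolerance on
every sample and is asserted in the tests. Features are ranked by mean
absolute attribution; the report also gives the correlation between each
top feature's value and its attribution, the numeric counterpart of the
red/blue gradient in beeswarm summary plots. Constant features receive
exactly zero attribution, and duplicating a column preserves the pair's
total attribution — the property that distinguishes additive attributions
from gain-style importances, and the reason gain is not used here.

The local explainer is this package's own implementation of the standard
local-surrogate recipe: features are discretized into quartile bins
computed on the training matrix (stored in the fitted model);
perturbations redraw each feature's bin uniformly and sample a value
uniformly within the bin; samples are weighted by exp(−d²/w²) on the
Hamming distance d between bin patterns, with kernel width w = 0.75·√p;
and a weighted ridge regression (penalty 10⁻³, intercept unpenalized) of
the model's predicted probability on the same-bin indicators yields
signed weights. Positive weight means the feature's current value range
supports the ac4C call. Defaults — quartile discretization, 5000
perturbations — are conventions, configurable, and seeded: the same seed
gives the identical explanation. Constant features are left unperturbed
and absorb into the intercept.

## The synthetic benchmark generator

`simulate_ac4c()` exists so every pipeline stage is testable without
external downloads. It emulates the benchmark's *structure*: 415-nt
windows (any odd length ≥ 15), the five forced central C anchors, the 1:9
imbalance, and positives enriched in the GGG/CGG/GGC/CCC trinucleotides.
Enrichment is a position-wise first-order composition bias — after an A
or T the C/G sampling weight is √w, after a C or G it is w — so G/C runs
form and the discriminative signal is *distributed along the window*,
the kind of global composition shift that PseEIIP features detect,
rather than a pasted motif at a fixed offset. At w = 1 positives and
negatives are drawn from the identical process, giving a null control
whose trinucleotide distributions are statistically indistinguishable
(verified by a chi-square check at 500/500) and on which cross-validated
AUROC sits at chance.

What the generator does *not* emulate: real transcript context, codon
structure, positional motif grammar around the acetylated cytidine, or
the negative-sampling procedure of any experimental benchmark. Passing
the end-to-end tests therefore demonstrates that the pipeline is wired
correctly and can recover a planted composition signal under 1:9
imbalance — it does not certify performance on real ac4C data, which has
weaker and differently structured signal. On the default fixture the
tuned model separates nearly perfectly; published cross-validation
figures on the real benchmark are far lower, and reproducing them
requires obtaining that dataset (the `paces_import` path converts its
paired-FASTA layout; nothing is downloaded).

Generation is a pure function of its arguments under a fixed named RNG
(Mersenne-Twister, inversion, rejection sampling), run inside a
state-restoring wrapper so library calls never perturb the caller's RNG
stream.

## Problem sizes and numerical choices

The test suite runs the full 415-nt, 120/1080 default fixture for the
end-to-end checks and smaller windows (15–51 nt, tens of sequences) for
unit-level properties; encoder oracles use 200 random sequences of
length 3–60, and the MCC identity is swept exhaustively (~44k cases).
These sizes were chosen as the smallest that exercise each property
convincingly. All floating arithmetic is double precision; k-mer block
sums are asserted to 10⁻¹²; Shapley additivity to 10⁻⁵ on the margin
scale (single-precision accumulation inside the booster bounds this);
fold assignment uses 1-based ids. Ties in grid search resolve to the
earlier candidate, ties in scores to threshold grouping.

## Known limitations

* The near-perfect fixture results say nothing quantitative about real
  benchmarks; the generator is a structural, not distributional, emulation.
* Baselines are untuned by design; their comparison rows measure "library
  defaults", not each algorithm's ceiling.
* No confidence intervals or paired tests accompany the metrics — the
  evaluation contract is point metrics under a fixed protocol.
* The local surrogate inherits the usual caveats of perturbation-based
  explanations: weights depend on the discretization and kernel width,
  and independent per-feature perturbation ignores feature correlation.
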