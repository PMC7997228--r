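---
title: "Methods: multi-encoder deep-learning prediction of m6A sites"
author: "m6aFuse Developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-encoder deep-learning prediction of m6A sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6aFuse)
```

## The problem and the model

N6-methyladenosine deposition is sequence-contextual: the bases flanking a
candidate adenosine carry most of the predictable signal. `m6aFuse`
therefore treats m6A calling as supervised binary classification of
fixed-length windows — by convention 41 nt with the candidate A at
position 21 — and stacks three ideas: a *fused multi-view representation*
of the window, *sparse feature selection*, and a *small feed-forward
network* with tuned hyper-parameters.

### Feature encoders

Each encoder captures a different statistical view; all are deterministic
given their inputs.

| Encoder | Dimension (L = 41) | View |
|---|---|---|
| BE | 4L = 164 | exact base identity per position |
| KSNPF | 16(K_max+1) = 96 | ordered base pairs K apart, K = 0..5 |
| ENAC | 4(L−w+1) = 148 | local composition in sliding windows (w = 5) |
| NCP | 3L = 123 | ring / functional group / H-bond class per position |
| PseDNC | 16+λ = 46 | dinucleotide composition + λ tier correlations |
| TNC | 64 | global trimer composition |
| PSNP | L = 41 | per-position base enrichment between classes |
| PSDP | L−1 = 40 | per-position dinucleotide enrichment |

PSNP/PSDP are the only label-dependent views: entry (i, j) of their lookup
matrix is the frequency of symbol i at position j among positives minus
the same frequency among negatives, so each column sums to zero and
entries live in [−1, 1]. **Fitting these on data that later serves as a
test fold leaks labels**; `cross_validate()` therefore refits them (and
the feature selection) inside every training fold. A `fold_safe = FALSE`
switch reproduces the optimistic whole-dataset protocol for comparison
only — published pipelines are often silent on this point, and the
difference can be large at small n.

PseDNC's tier-j correlation averages, over positions i, the mean squared
difference between the six standardized physicochemical index values
(Rise, Roll, Shift, Slide, Tilt, Twist) of the dinucleotides at i and
i + j. The index table ships as a plain CSV and is standardized to mean
0/variance 1 per index, which makes the correlation terms scale-free; any
affine transformation of the raw table leaves results unchanged. The
dinucleotide frequencies use the overlapping convention (L − 1 dinucleotides)
of the pseudo-composition lineage; `overlapping = FALSE` exposes the
literal non-overlapping reading for comparison.

### Tunable parameters that matter

* `k_max` (KSNPF spacing, default 5, grid 1–5): larger values add longer-
  range pair statistics and noise in equal measure.
* `lambda` (PseDNC tiers, default 30, grid {10, 20, 30}) and `w` (weight
  factor, default 0.5, grid 0.1–0.9): trade composition against
  sequence-order information. `sweep_encoder_params()` grid-evaluates both
  by CV accuracy of the reference network on that encoder alone.
* `alpha` (elastic-net penalty, grid 0.01–0.1) and `beta` (L1/L2 mix,
  default 0.5): `alpha` controls how hard the fused matrix is pruned. The
  upstream description sweeps only `alpha`; `beta = 0.5` is the neutral
  equal-mix default and is exposed in every interface.
* DNN hyper-parameters: see `default_search_space()` — layer count {2, 3},
  widths (100–800 / 50–700 / 25–600), seven activations, seven optimizers,
  learning rate 0.001–0.09 (searched in log space), seven initializers,
  dropout 0.1–0.6, epochs 10–100 (step 10), batch size 40–80 (step 10).

### Feature selection

`fit_elastic_net()` minimizes

$$\frac{1}{2n}\lVert y - Xw\rVert_2^2 + \alpha\beta\lVert w\rVert_1
  + \frac{\alpha(1-\beta)}{2}\lVert w\rVert_2^2$$

on the 0/1 labels as a continuous response — deliberately the regression
form, not a logistic variant, because selection (not calibrated
probability) is its job here. Cyclic coordinate descent in covariance form
converges when no coefficient moves more than 1e-6 in a sweep; the
objective is provably non-increasing per update, which the test suite
checks. Features are standardized internally with population moments and
the centers/scales are stored in the model for test-time reuse; constant
columns are left at coefficient zero. Two closed-form oracles pin the
implementation down: at `beta = 0` the ridge solution
$(X^\top X + n\alpha I)^{-1}X^\top y$, and at `beta = 1` on an orthonormal
design the soft-thresholded univariate projections.

If a penalty kills every feature, `apply_selection()` refuses with advice
to lower `alpha`; `cross_validate()` instead scores that fold at chance
(0.5) with a warning, so a null-signal dataset degrades gracefully rather
than erroring.

### Classifier

The network is `input → hidden₁ → dropout → hidden₂ → dropout
[→ hidden₃ → dropout] → 1 sigmoid unit`, trained by minibatch gradient
descent on mean binary cross-entropy. Because no deep-learning framework
is assumed, the seven optimizers (SGD, Adam, Adamax, Nadam, RMSprop,
Adadelta, Adagrad) and seven initializers are implemented natively with
their conventional default moments (ε = 1e-7, Adam β₁ = 0.9, β₂ = 0.999,
RMSprop/Adadelta ρ = 0.9/0.95); dropout is inverted (activations rescaled
by 1/keep at train time, inference untouched). One seed drives
initialization, epoch shuffling and dropout masks, giving bit-identical
retraining on the same platform; across BLAS builds we promise metric
agreement to ~1e-3 rather than bit equality.

### Hyper-parameter optimization

`tpe_optimize()` is a native tree-structured Parzen estimator. After 10
random startup trials the history is split at the γ = 0.25 quantile of
observed losses (ties resolved by taking the ⌈γn⌉ best in trial order, so
an all-identical history still works); each dimension gets a "good" and a
"bad" density — truncated-Gaussian mixtures with neighbor-spacing
bandwidths plus one uniform prior component for numeric dimensions,
Laplace-smoothed counts for categoricals; 24 candidates are drawn from the
good model and the one maximizing log l − log g (equivalent to maximizing
expected improvement) is evaluated. The conditional `hidden_3` dimension
enters the densities only through trials where `layers = 3` — the tree
structure. The loss is 1 − mean CV accuracy. Failed objective evaluations
are recorded with infinite loss and the search continues. γ, the startup
count, the candidate count and the trial budget (default 100) are all
configurable because the upstream method fixes none of them.

### Metrics

Sn, Sp, ACC from the confusion matrix at threshold 0.5 (the threshold is
exposed everywhere); MCC in the standard four-factor square-root form,
defined as 0 whenever a margin is empty — the printed formula in the
source description omits the square root, which cannot be a correlation
coefficient, so the standard form is used; AUC by mid-rank Mann–Whitney,
which equals trapezoidal ROC integration and handles ties exactly.
Cross-validation reports fold-mean metrics by default (counts summed,
rates averaged) with pooled-prediction metrics also returned, since the
literature rarely states which of the two it prints.

## The synthetic world

`generate_synthetic()` emulates the structure of the public m6A benchmark
sets: balanced classes, 41-nt windows, central A. Positives carry
position-specific enrichment — at the eight positions flanking the center
the designated base (default G) is drawn with probability
`0.25 + 0.75·motif_strength` instead of 0.25; negatives are uniform.
Defaults (1000/class, strength 0.6) were fixed once as the package's
stated world. This is a position-weight world: it is exactly what
PSNP/BE/NCP can represent, which makes parameter recovery quantifiable
(CV AUC ≥ 0.9 at strength 0.6; chance at strength 0). What it does *not*
contain: k-mer/consensus motifs with interactions, composition or
secondary-structure biases, homology between records, class imbalance, or
label noise. A green recovery test therefore establishes that the pipeline
is wired correctly and leak-free — not that it reaches any particular
accuracy on real tissues, which depends on downloading the published
benchmarks.

At `motif_strength = 0` the two classes are one distribution; the test
suite verifies this over 100 seeds with per-position chi-square tests at a
Bonferroni-corrected 0.01 family level (41 raw-level tests would reject a
third of null seeds by construction, so the family-wise reading is the
meaningful one).

## Numerical choices and edge cases

* Alphabet is strictly {A, C, G, U} after uppercasing and T→U; ambiguity
  codes are rejected because every encoder denominator assumes 4 symbols.
* Positions are 1-based in user-facing messages, 0-based never exposed.
* Coordinate-descent tolerance 1e-6 on the max coefficient change;
  elastic-net ties in `sweep_alpha()` break toward the smaller selected
  dimension, then the smaller `alpha`. Encoder-parameter sweep ties break
  toward the smaller parameter.
* KSNPF uses the denominator L − K − 1, the exact count of K-spaced pairs,
  so each K layer sums to 1; TNC, ENAC blocks and PseDNC likewise
  normalize to 1 within 1e-9 (tested).
* Training aborts with the epoch index on a non-finite loss; `epochs = 0`
  is a valid no-op returning the initial weights.
* The loss trace's near-monotonicity is asserted on amplitude (no uptick
  exceeds 5% of the total descent at near-zero dropout) rather than on the
  count of upticks, which minibatch shuffling makes arbitrary near
  convergence.
* Degenerate metric inputs (single-class truth) yield NaN for the
  undefined quantities with a warning rather than an error.

## Limitations

* Inputs are pre-windowed samples; there is no transcript-scanning mode
  and no redundancy reduction (CD-HIT-style) — both belong upstream.
* The elastic net is the only selector; comparison selectors (mRMR, LLE,
  spectral embedding, SVD) are out of scope.
* The DNN is a plain MLP by design; no convolutional/recurrent variants
  and no early stopping (epochs are a tuned hyper-parameter instead).
* Published per-tissue accuracies are not asserted anywhere: they require
  the external benchmark downloads, and the package's own empirical claims
  are limited to what its tests and acceptance script compute on the
  synthetic world.
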