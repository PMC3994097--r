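---
title: "Hybrid associative classification with one-hot output coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid associative classification with one-hot output coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chatohm)
```

## The model family

Associative memories relate input patterns to output patterns through a
matrix **M** built from a *fundamental set* of p associations
\((x^\mu, y^\mu)\). Two classical constructions anchor the package:

The **Lernmatrix** takes binary inputs \(x \in \{0,1\}^n\) and one-hot
class outputs of length m. Starting from zero, each association updates
\(m_{ij}\) by \(+\varepsilon\) if \(y_i = 1, x_j = 1\), by
\(-\varepsilon\) if \(y_i = 1, x_j = 0\), and not at all if
\(y_i = 0\). Recall flags the class rows with maximal score
\(\langle M_{i\cdot}, x\rangle\) — possibly several, when scores tie.
\(\varepsilon\) is any positive constant; it scales all scores equally,
so predictions do not depend on it (a property the tests verify). The
default is 1.

The **Linear Associator** takes real patterns and sums outer products,
\(M = \sum_\mu y^\mu (x^\mu)^T\); recall is the bare product \(Mx\).
When inputs are mutually orthonormal the cross terms vanish and every
fundamental output is recalled exactly.

**CHA** combines Linear-Associator learning (class one-hot outputs) with
Lernmatrix recall. **CHAT** first translates all patterns so the origin
sits at the centroid \(\bar{x}\) of the training inputs — the
translation makes inner-product scores measure geometry relative to the
data cloud rather than to an arbitrary origin. The score of class k for
query x is \(\langle \sum_{\mu \in k}(x^\mu - \bar{x}),\; x -
\bar{x}\rangle\): a class is represented only by the *sum* of its
translated patterns, which is what limits CHAT on classes with
multimodal or unbalanced geometry.

**CHAT-OHM** removes that bottleneck by giving each *training pattern*
its own one-hot output of length p. The outer-product sum then reduces
exactly to stacking the translated training patterns as rows (the
package materializes the stack directly; a unit test asserts equality
with literal outer-product accumulation rather than paying the
\(O(p^2 n)\) cost on every fit). Recall yields a length-p binary vector
\(\tilde{y}\) flagging every training pattern whose centered inner
product with the query is maximal; an *extract* step is then needed to
map patterns back to classes. Per class k, a masking vector \(c^k\)
marks that class's training positions, the counting vector
\(t^k = \tilde{y} \wedge c^k\) is summed into a vote, and the class with
most votes wins. When the maximal score is unique — the generic case on
real-valued data — this is exactly nearest-pattern classification by
centered inner product, and the tests pin the equivalence against an
independent oracle. The voting machinery matters on the tie set, which
symmetric fixtures (`make_tie_fixture()`) exercise deliberately.

## Numerical choices

Scores are floating point, so "maximal" needs a tolerance: a score
belongs to the arg-max set iff
\(\max(u) - u_i \le 10^{-9}\max(1, |\max(u)|)\). Exact ties occur in
symmetric constructions, and strict float equality would make the voting
machinery untestable; the sign-aware relative form keeps the test
meaningful near zero. Lernmatrix scores are integer multiples of
\(\varepsilon\), so there the maximum is compared exactly. Two further
deterministic tie rules, chosen here because the underlying procedure
leaves them open: tied class scores in CHA/CHAT and tied vote counts in
CHAT-OHM both go to the smallest class index (label-map order). The
Lernmatrix recall vector with 1s at all maxima remains available
(`chat_scores()`, `chat_ohm_recover()`); the single-label collapse
exists because the evaluation protocol scores single-label accuracy.

Class labels of any type are mapped to internal indices `1..m` in
`sort(unique(labels))` order and restored on output; models never emit
labels absent from training.

## Preprocessing stages

*Normalization* is the population z-score: per attribute, subtract the
mean and divide by the divide-by-N standard deviation. Constant columns
(σ = 0) map to zeros rather than erroring — a constant attribute is
uninformative, and real clinical files do contain them. Statistics are
fit (`zscore_fit()`) separately from application (`zscore_apply()`), so
the same scaling can be reused on held-out data.

*Wilson editing* is the classic edited-nearest-neighbour rule: each
pattern's k = 3 nearest neighbours (Euclidean) vote, and patterns whose
own label differs from a unique plurality are discarded. The pass is
simultaneous — every pattern is judged against the original set and
failures are removed together — because sequential removal would make
the result order-dependent. Distance ties at the k-th neighbour prefer
the lower row index; plurality ties (impossible for k = 3 with two
classes, possible otherwise) conservatively keep the pattern.

*Missing values* are either deleted row-wise (`drop_missing_rows()`,
appropriate when incomplete records are rare) or imputed
class-conditionally (`impute_class_conditional()`): class mean for
continuous attributes, class mode for categorical ones, with mode ties
resolved to the smallest coded value. Imputation errors, naming the
pair, when a class × attribute cell has no observed value at all.

By default the configured stages run once on the full dataset *before*
cross-validation, mirroring pipelines that condition a dataset and then
validate on it; this leaks test-fold information into the fit. A
leakage-free mode (`per_fold = TRUE`) instead fits z-score statistics on
the training folds only and Wilson-edits training rows only.
Imputation and row deletion always run globally: test instances carry no
label at predict time, and success rates are only comparable on a fixed
instance set. The stage *order* is the user's: `"normalize"` before
`"wilson_edit"` edits in normalized space, the reverse edits raw space —
both orders are expressible because either choice is defensible and the
procedure itself does not fix one.

## The validation protocol

`cross_validate()` implements repeated stratified k-fold
cross-validation, default 10 × 10. Within each class the (shuffled)
instances are dealt round-robin to folds, so per-class per-fold counts
differ by at most one and remainders land in the lowest-indexed folds.
Each fold in turn is held out, the classifier trains on the rest, and
the success rate — the percentage of correctly classified test
instances — is recorded. The grand mean averages all repeats × folds
rates; with equal-size folds this equals the mean of per-repeat means,
and that equivalence is the reason the simpler convention was adopted.

Each repeat reshuffles with a derived seed,
`(seed mod 44488) * 48271 + 31 * r  (mod 2^31 − 1)`, so any single
repeat is reproducible in isolation and the whole result is a pure
function of the master seed. Identical seeds give bit-identical results;
the suite asserts this.

```{r cv-example}
fs <- make_blobs(blob_spec(means = rbind(c(-2, 0), c(2, 0)), sigma = 1.5,
                           counts = c(60, 40), seed = 42))
cross_validate(fs, "chat-ohm", cv_config(folds = 10, repeats = 2, seed = 1))
```

## What the synthetic generators emulate — and what they do not

`make_blobs()` draws each class from an isotropic Gaussian around its
mean. Separable (≥ 10σ between means) and overlapping (≈ 2σ) regimes
cover the two situations the classifiers face; richer covariances would
not exercise any additional code path, since every operator here depends
on the data only through inner products and Euclidean distances.
`corrupt()` plants two kinds of defects with ground truth returned:
missing markers (one `NA` cell in each chosen row) and label-flipped
outliers, each placed beside a *distinct* uncorrupted foreign-class row
with jitter at 10⁻³ of the feature scale, so a planted outlier's entire
neighbourhood carries the foreign label and the edited-nearest-neighbour
rule is guaranteed (up to negligible-probability distance coincidences)
to condemn it. `make_tie_fixture()` builds exactly symmetric two- and
three-class sets whose centered scores tie at the query, reaching the
voting paths unique maxima never touch.

Real clinical tables differ from these fixtures in ways that matter:
correlated and heavy-tailed attributes, label noise, class imbalance
beyond what the blob counts express, and categorical attributes whose
integer coding imposes an artificial metric. Passing tests therefore
demonstrate that the operators implement their definitions, not that the
classifier will reach any particular accuracy on a given clinical
dataset. Benchmark protocol sizes used throughout the tests and the
acceptance script — 100-instance blob sets, 10 × 10-fold validation, 50
random datasets per oracle comparison, 200 random Lernmatrix instances
with p, n ≤ 8 and m ≤ 4 — were chosen as the smallest sizes at which
every contract is exercised with comfortable statistical margin.

## Limitations

- CHAT-OHM stores every translated training pattern: memory and recall
  cost grow linearly in p, unlike CHAT's fixed m × n matrix.
- Equal-magnitude inner-product scores from patterns on opposite sides
  of the centroid are a structural ambiguity of the similarity; the tie
  rules make the outcome deterministic but not symmetric between
  classes (the smallest index is favoured).
- The Lernmatrix accepts only strictly binary inputs, by design; no
  implicit thresholding of real data is performed, so real-valued
  datasets must be binarized explicitly before using it.
- Integer-coded categorical attributes enter Euclidean distances (Wilson
  editing) and inner products as if they were ordinal; for nominal
  attributes with more than two levels this is a known distortion the
  pipeline does not attempt to correct.
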