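---
title: "Restoring missing labels before multilabel classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring missing labels before multilabel classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlrestore)
```

## The incompleteness model

`mlrestore` targets training sets where label *omission* is the only
annotation error: every assigned label is correct, but any document may be
missing some of its true labels. Three assumptions drive everything:

1. many training documents have incomplete label sets;
2. annotators do not assign wrong labels (false positives do not occur);
3. the compactness hypothesis: documents that are close in feature space
   tend to share categories.

Assumption 2 is why the package never removes an expert label — both
restoration algorithms only *propose additional* pairs, and the "del"
modification only shrinks the *negative* side of a per-label training
problem. Assumption 3 is why proposals come from feature-space
neighbourhoods, and it is the property the synthetic generator is built to
emulate.

## The two restorers

Both operate on the same substrate: the directed k-nearest-neighbour graph
with cosine-similarity edge weights `w_ij = sim(x_i, x_j)` for
`j ∈ K(i)`. Feature vectors are nonnegative and L2-normalized (the BM25
text path produces exactly this geometry), so all similarities lie in
[0, 1].

**WkNN voting.** The score of label `cl` for document `d` is the
weight-normalized fraction of `d`'s k nearest training documents that
carry `cl`. Every unlabeled cell with score at least `T` becomes a
proposal. The score is a convex combination of memberships, so
`T ∈ [0, 1]` is directly interpretable as a neighbourhood "vote share".
One reading note: weighted kNN is sometimes formulated with a distance
function ρ used multiplicatively as the vote weight, which taken literally
would up-weight *far* neighbours. We weight by cosine *similarity* (the
behaviour the weighted-kNN literature intends and the graph weights
already use); `weight = "inverse-distance"` gives a distance-reciprocal
alternative.

**SoftSL.** Each document carries a class distribution `p_i`; expert
information enters as a reference distribution `r_i`, uniform over the
document's assigned labels. The misalignment objective

$$C_1(p) = \sum_i \mathrm{KL}(r_i \,\|\, p_i)
  + \mu \sum_i \sum_{j \in K(i)} \omega_{ij}\, \mathrm{KL}(p_i \,\|\, p_j)
  - \nu \sum_i H(p_i)$$

balances fidelity to the experts, smoothness along the similarity graph,
and (optionally) entropy regularization. The middle term is occasionally
written as a bare cross-entropy `Σ p_i log p_j`; we use the standard KL
divergence throughout, which is the quantity actually meant by
"Kullback-Leibler distance" and keeps every term nonnegative in the sense
required for a monotone minimization contract. Unlabeled cells whose
optimized probability reaches `T` are proposed.

### Minimization

The implementation defines the optimizer by its contract: iterates
stay row-stochastic and the objective trace is monotone non-increasing.
The scheme is projected multiplicative (exponentiated-gradient) descent —
`p ← normalize(p · exp(−η ∇C₁))` — with backtracking: a step is accepted
only if it strictly decreases the objective, otherwise η is halved; the
step doubles again after success (capped at 10). Gradients are clipped to
±50 before exponentiation to avoid overflow; probabilities are floored at
`eps = 1e-10` so no logarithm sees zero. Convergence is declared when the
relative decrease falls below `tol = 1e-6`, with a cap of 200 iterations
and a `converged` flag on the result. Initialization is `p = r`: for
`μ = ν = 0` this start is already the global minimum (objective exactly
0), which makes the decoupled limit a useful exactness check.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 10 (grid 5–20) | neighbourhood size; larger k smooths votes, smaller k tracks local structure |
| `T` (WkNN) | 0.3 (grid 0.05–0.5) | vote share needed to propose a pair; lower T = more, riskier proposals |
| `T` (SoftSL) | 0.005 | probability threshold; tiny because mass spreads across m classes |
| `μ` | 0.5 | weight of graph smoothness vs expert fidelity |
| `ν` | 0 | entropy term; unnecessary when every document has some label |
| `C` | 1 | linear base-learner cost; the no-tuning protocol uses C = 1, b_l = 0 |
| `p` | 0.1–0.6 | simulated fraction of deleted labels per class |
| BM25 `k1`, `b` | 1.2, 0.75 | classic Okapi constants; the exact variant is recorded in output metadata |

The default grids for `(k, T)` bracket the optima typically selected in
practice (k around 10–15; T from 0.05 under heavy corruption up to 0.3
under light corruption), so the dev-set search has room on both sides.

## Deterministic tie-breaking and degenerate inputs

* Neighbour ties (equal similarity) break toward the ascending document
  index, making graphs reproducible across platforms. A consequence worth
  knowing: two duplicated documents are *not* perfectly symmetric in the
  graph when `k < n − 1`, because tied third parties route their edge to
  the lower index. Exact duplicate symmetry holds on the complete graph.
* Self-edges are excluded — a document never votes for its own labels.
* A document whose neighbours all have zero weight gets score 0 (warned).
* Labels with no positive training documents yield an always-negative
  scorer (logged); empty training sets are rejected.
* In the ROC sweep, instances with tied scores move together; the CROC
  AUC is the trapezoid area between realized sweep points on the
  *rescaled* axis, anchored at (0,0) and (1,1). With all scores tied this
  convention yields 0.5 (the rescaled chord), not the area of the
  continuous diagonal — the integration rule is deliberately attached to
  the realized polyline and recorded in the curve object.
* BM25 idf is floored at zero. This keeps weights nonnegative (the graph
  weights require cosine ∈ [0, 1]) at a known cost: terms occurring in at
  least half the corpus get zero weight, and a one-document corpus
  vectorizes to zero (warned). Inputs are token-count tables; term
  extraction is out of scope.
* Label deletion visits classes in seeded random order and samples
  candidates uniformly; a deletion that would empty a document's label
  set is skipped and reported as a shortfall, never redistributed to
  another class — preserving the per-class label distribution as nearly
  as the row constraint allows. `round(p·n_cl)` uses half-up rounding by
  default; `floor`/`ceiling` are selectable for studies that need a
  different rounding convention.

## What the synthetic generator does and does not emulate

Each label owns a cluster center (a dedicated block of features plus a
weak shared background, L2-normalized). A document draws a primary label
uniformly, adds each of the `q = 5` geometrically nearest other labels
with probability `co_label_rate`, and sits at the normalized mean of its
labels' centers plus nonnegative isotropic noise (`spread`). Defaults
(600 docs, 8 labels, 50 features, `co_label_rate = 0.6`) give
`1 + 5 × 0.6 = 4` expected labels per document — the density of the
classic gene-function benchmark this protocol was validated on — and
co-occurring labels are geometrically adjacent, which is precisely the
regime the compactness assumption describes.

Placing a multi-label document at the *mean* of its labels' clusters
(rather than sampling one component) is a deliberate choice: it is what
makes co-labels recoverable from geometry at all. The generator does not
attempt token-level realism — no Zipfian vocabularies, no length
variation, no label hierarchies, no annotator-specific missingness. Tests
passing on this generator therefore demonstrate that the algorithms
exploit compactness correctly, not that they will match any particular
real corpus's numbers.

For the label-recovery benchmark (p = 0.3) the fixture uses
`co_label_rate = 0.2` (~2 labels/doc). At the default density of 4/8
labels per document, half of all cells are positive, and a counting
argument shows the recovery lift over the random-pair baseline is capped
at `|unlabeled| / |deleted|` ≈ 4.3 regardless of method — too low a
ceiling to distinguish a good restorer from a perfect one. At ~2
labels/doc the ceiling is ≈ 11, making the ≥ 5× lift check meaningful.

## Experiment protocol

`run_experiment()` implements the full evaluation design: a held-out test set
(1/3 of documents) keeps its complete labels; the training portion is
corrupted at each `p`; a dev split (20% of the training portion,
*corrupted* labels — no oracle leakage) drives the `(k, T)` grid search;
restoration votes for dev-stage scoring come only from train-minus-dev
documents; the winning configuration is re-run on the whole training
portion and the classifier retrained before test evaluation. Grid ties
break toward smaller `k`, then larger `T` (fewer speculative additions).
A `p = 0` reference row (clean labels, no modification) is always
included. The default problem size — 600 documents, 8 labels, 50 features
— is the package's standard benchmark scale: big enough for stable micro
metrics on a 200-document test set, small enough that the full two-arm
sweep runs in well under a minute.

The linear base learner is a standard linear-kernel large-margin solver
behind a stable interface; the bespoke content of the classification
module is the Binary-Relevance orchestration, the del-mode negative
masking, and the threshold tuning. The tuner scans each label's `b_l`
over that label's distinct dev scores (greedy per-label maximization,
then the aggregate metric selects `C`); a joint scan over all labels'
thresholds would be exponential, and the per-category sequential scan is
the standard procedure.

## Known limitations

* Restoration is transductive within the training set; truly unlabeled
  documents (the `D_u` of the semi-supervised setting) are representable
  but not exercised by any experiment here.
* Single-round modification only by default: restore once, modify once.
  Iterating invites semantic drift and was not evaluated in the source
  protocol.
* Exact O(n²) neighbour search; fine for thousands of documents, not for
  millions.
* The "del" mode cannot help a label whose positives were *all* deleted —
  there is nothing left to vote for it; such labels train as
  always-negative.
* Micro metrics computed against an incomplete *test* set understate true
  performance; the synthetic protocol avoids this by keeping test labels
  complete, but real deployments should expect it.
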