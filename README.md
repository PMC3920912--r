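# mlrestore

Multilabel classification with missing-label restoration.

## The problem

In multilabel corpora — grant abstracts filed under a topic taxonomy, genes
annotated with functional classes — training labels are routinely
*incomplete*: annotators assign some correct categories and miss others.
A document that truly belongs to class *A* but lacks the label becomes a
false negative for *A*'s classifier, distorting every per-label decision
rule. The failure mode is asymmetric: annotators rarely assign *wrong*
labels, they omit right ones.

`mlrestore` implements a pre-training repair step for this regime. Under the
compactness hypothesis — similar objects tend to share categories — missing
(document, label) pairs can be inferred from each document's neighbourhood
in feature space, and the training set modified before an ordinary
multilabel classifier is fit. The package is aimed at text-mining and
functional-genomics practitioners who train per-category classifiers on
imperfectly curated collections, and at anyone who wants a controlled
benchmark for label-noise-of-omission methods.

## Methods in brief

Two restoration algorithms score every unlabeled (document *d*, class *cl*)
cell and propose the pairs PC = {(d, cl) : score ≥ T}:

* **WkNN** — weighted k-nearest-neighbour voting:

      S(d, cl) = Σ_{d′ ∈ kNN(d)} w(d, d′) · I(d′, cl) / Σ_{d′ ∈ kNN(d)} w(d, d′)

  with cosine-similarity weights over the k nearest training documents;
  S is a convex combination of the neighbours' memberships, so S ∈ [0, 1].

* **SoftSL** — soft supervised learning on the kNN similarity graph
  (edge weights ω_ij = sim(x_i, x_j)): per-document class distributions
  p_i are found by minimizing the misalignment functional

      C₁(p) = Σ_i KL(r_i ∥ p_i) + μ Σ_i Σ_{j ∈ K(i)} ω_ij KL(p_i ∥ p_j) − ν Σ_i H(p_i)

  where r_i is uniform over document i's expert labels. Minimization is a
  projected multiplicative descent with a monotone non-increasing
  objective; a pair is proposed when p_i^cl ≥ T (default T = 0.005, ν = 0).

Proposals feed one of two training-set modifications:

* **add** — include PC as new positives;
* **del** — leave the labels unchanged but exclude each proposed document
  from that label's *negatives* during per-label training.

Classification is Binary Relevance: one binary rule per label
(`w_l·x ≥ b_l` for the linear large-margin base, or a 30-tree random
forest with √f split candidates), with optional tuning of the shared cost
C and the per-label thresholds b_l on a development split. Evaluation is
micro-averaged precision/recall/F1 plus CROC curves — ROC with the
false-positive axis rescaled by `x_new(x) = (1 − e^{−αx})/(1 − e^{−α})`,
α = 7, to magnify the early-retrieval region.

The package also ships the two simulation tools that make the protocol
self-contained: a corruption simulator (`delete_labels()`) that removes a
per-class fraction `p` of labels while preserving the class-size
distribution and never emptying a document's label set, and a synthetic
generator (`generate_multilabel()`) producing label-compact Gaussian
cluster data with a controllable labels-per-document density.

## Worked example

```r
library(mlrestore)

# a compact synthetic benchmark: 300 docs, 8 labels, ~4 labels/doc
ds <- generate_multilabel(synthetic_spec(n_docs = 300, seed = 7))
label_stats(ds)
#>   n_docs n_labels n_positives labels_per_doc docs_per_label
#> 1    300        8        1230            4.1           154.

# simulate incomplete annotation: drop 40% of each class's labels
corr <- delete_labels(ds$Y, p = 0.4, seed = 7)
nrow(corr$deleted)   # 492 of 1230 labels removed

# propose missing labels by weighted kNN voting
pc <- restore_wknn(ds$X, corr$Y_incomplete, k = 10, T = 0.1)
pc
#> # A tibble: 1,105 × 3
#>     doc label score
#> 1    14     2 0.901
#> ...
# 472 of the 492 deleted labels are among the proposals
# (precision 0.43, recall 0.96)

# train Binary-Relevance classifiers on raw vs add-modified labels
fit_raw <- train_br(ds$X, corr$Y_incomplete)
fit_add <- train_br(ds$X, apply_add(corr$Y_incomplete, pc))
dplyr::bind_rows(raw      = micro_prf(ds$Y, predict(fit_raw, ds$X)),
                 modified = micro_prf(ds$Y, predict(fit_add, ds$X)),
                 .id = "training")
#>   training    tp    fp    fn precision recall    f1
#> 1 raw        440     3   790     0.993  0.358 0.526
#> 2 modified  1190   655    40     0.645  0.967 0.774
```

Reading the numbers: training on the corrupted labels leaves 40% of the
true labels acting as negative examples, so the raw classifiers are
precise but blind (recall 0.36). Adding the restored pairs trades a
little precision for a large recall gain, lifting micro-F1 from 0.53 to
0.77. The full protocol — corruption, dev-set grid search over (k, T),
final test-set evaluation, p = 0 reference — is one call:

```r
res <- run_experiment(experiment_config(synthetic_spec(seed = 42),
                                        p_grid = c(0.2, 0.4, 0.6),
                                        restorer = "wknn", mode = "add",
                                        seed = 42))
autoplot(res)
```

## File formats

`read_multilabel()` / `write_multilabel()` support three dialects:

* **mulan-arff** — dense ARFF whose trailing nominal `{0,1}` attributes
  are labels, plus a companion `.xml` (`<labels><label name="..."/>`)
  naming the label attributes (Mulan convention).
* **pair-tsv+mtx** — MatrixMarket feature matrix plus
  `<stem>.pairs.tsv` (`doc_id<TAB>label_id`, 0-based) and
  `<stem>.labels.tsv` (persisted label order).
* **dense-tsv** — dense TSV features with the same two sidecars.

A thin CLI over the same functions lives at `inst/cli/mlrestore.R`
(subcommands `simulate`, `corrupt`, `restore`, `modify`, `experiment`).

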