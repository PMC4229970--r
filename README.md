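# mechknn

Multi-label nearest-neighbour prediction of enzyme catalytic mechanism from
sequence-derived attributes.

## The problem

Enzyme function is usually annotated at the level of the overall reaction
(EC numbers), but two enzymes catalysing the same reaction can use entirely
different chemical mechanisms — different catalytic residues, cofactors and
intermediate steps. Curated mechanism databases label a protein chain with a
mechanism identifier (`M` + 4 digits, optionally refined with the chain's
role in the enzyme complex, e.g. `M0314_component_I`). Few proteins carry
such labels, so the question is whether cheap, sequence-only attributes carry
enough signal to transfer mechanism annotations to unannotated sequences.

`mechknn` answers this with a multi-label formulation. An instance is a
protein with a sparse attribute vector and a label set
(x_i, Y_i), Y_i ⊆ L; a predictor h emits a set Z_i = h(x_i) which may be
empty (a non-enzyme). The attributes are:

* **binary signature presence** — one 0/1 column per sequence signature
  (InterPro-style domain/family signatures, catalytic-site sequence matches);
* **per-mechanism profiles** — for a protein p, the vector
  a = (a_m), a_m = min over carriers p_m of m of the Euclidean distance
  between the signature vectors of p and p_m, and
  b = (b_m), b_m = max over carriers p_m of the global Needleman-Wunsch
  sequence identity between p and p_m (BLOSUM62, gap open 10, gap extend
  0.5, identity = identical positions / alignment length).

Predictors:

* **BRkNN** — binary-relevance k-nearest-neighbour (default k = 1) under
  Euclidean or Jaccard distance. The neighbourhood is the whole "closest
  ring" (every trainer tied with the k-th distance) and a label is predicted
  when it appears on at least half of the ring.
* **direct transfer** — a test protein receives the union of label sets of
  all training proteins with *exactly* its signature set; no exact twin, no
  prediction.
* **line separator** — a pair of proteins is called "same mechanism" iff
  `euclid ≤ slope × identity` in the identity-distance plane.

Evaluation: subset accuracy
`(1/|D|) Σ I(Z_i = Y_i)` (an exact-set match criterion), micro- and
macro-averaged precision/recall/specificity from per-label confusion counts,
leave-one-out, seeded k-fold and train/test drivers, and the binomial
standard deviation `100·sqrt(P(1−P)/N)` for significance bands.

Data I/O follows the Mulan multi-label convention: a Weka ARFF file (sparse
or dense body) holding attribute and label columns plus an XML file naming
the label columns. A deterministic synthetic protein-family generator
(`synth_generate()`) produces signature matrices, sequences with controlled
within-family identity, subunit-split complexes, confounder family pairs and
non-enzyme negatives, so the whole pipeline is testable offline.

## Worked example

```r
library(mechknn)

## five families x three orthologs, ten negatives, two empty anchors
sd <- synth_generate(synth_config(seed = 42))
sd
#> synth_data: 15 labeled + 10 negative instances (+2 anchors), 5 mechanisms, seed 42

leave_one_out(sd$dataset)   # BRkNN, k = 1, Euclidean
#> ml_eval_report over 25 instances
#>   subset accuracy : 1.0000
#>   micro P/R/Sp    : 1.0000 / 1.0000 / 1.0000
#>   macro P/R/Sp    : 1.0000 / 1.0000 / 1.0000
#>   FP: 0, FN: 0, mispredicted instances: 0
```

Every ortholog finds a same-family neighbour (small signature distance),
every negative resolves to an empty anchor and is correctly left unlabeled.
Introduce a confounder pair — two families with identical signature sets but
different mechanisms — and exactly those instances break:

```r
sdc <- synth_generate(synth_config(seed = 42, n_confounder_pairs = 1))
r <- leave_one_out(sdc$dataset)
r$mispredictions
#>        id true_labels predicted_labels fp_labels fn_labels
#> 1 P_F01_1       M0001            M0002     M0002     M0001
#> 2 P_F01_2       M0001            M0002     M0002     M0001
#> ...                      (all six confounded orthologs, nothing else)
```

This is the signature-sharing failure mode of annotation transfer: when two
protein families are indistinguishable in signature space, nearest-neighbour
voting crosses family lines. The analytic significance helper puts observed
accuracies in context:

```r
binomial_sigma(0.963, 250)
#> [1] 1.193834     # percentage points; 2-sigma band 93.9 .. 98.7
```

A command-line layer wraps the same functions (`synth`, `build-attrs`,
`pairs`, `predict`, `evaluate`, `sigma`); see `inst/cli/mechknn`.

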