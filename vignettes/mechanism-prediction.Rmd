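---
title: "Predicting enzyme mechanism with multi-label nearest neighbours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enzyme mechanism with multi-label nearest neighbours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechknn)
```

## The model

An enzyme's *mechanism* — which residues and cofactors do the chemistry, in
which order — is a finer annotation than its reaction class. `mechknn` treats
mechanism assignment as multi-label classification over protein sequences:
instance i is a pair (x_i, Y_i) with x_i a sparse attribute vector and
Y_i ⊆ L a (possibly empty) set of mechanism labels. Multi-label rather than
multi-class, because real multi-domain proteins can host several active
sites, and because a chain's label may be refined with its role in an enzyme
complex (`M0314_component_I`); `split_labels()` applies such refinements per
protein and `truncate_labels()` undoes them by keeping the first five
characters of each label.

The working hypothesis is *local similarity*: proteins carrying the same
mechanism cluster tightly in signature space. The default predictor is
therefore binary-relevance k-nearest-neighbour with k = 1: the model is the
training data, and a query receives the label set voted by its closest ring
of neighbours. Two baselines bracket it — exact-signature direct transfer
(maximally conservative) and a one-parameter line separator in the
identity-vs-distance plane (maximally crude).

## Attributes and distances

**Binary signatures.** One 0/1 column per signature (domain/family signature
or catalytic-site sequence match). On such vectors the Euclidean distance is
`sqrt(x)` for x differing signatures, so identical signature sets are at
distance 0 and a single signature difference costs 1. The Jaccard distance
(1 − shared/pooled active signatures) is available as an alternative;
both-empty vectors are at Jaccard distance 0 by convention.

**Profile attributes.** For a query p, `min_euclidean_profile()` computes
a_m = min over training carriers p_m of mechanism m of the Euclidean
distance, and `max_identity_profile()` computes b_m = max over carriers of
the global alignment identity. `profile_dataset()` assembles these into a
|M|-wide numeric attribute set, *leaving each instance out* of its own
profile so that later cross-validation never reads an instance's trivial
a_m = 0 / b_m = 1 entry. Profile values are used raw: identities live in
[0, 1] and distances are unbounded, and no normalisation rule is imposed —
a deliberate choice, since any rescaling would bake an arbitrary trade-off
between the two scales into the model (a known open point; `brknn()`
operates on whatever attribute scale it is given).

**Sequence identity.** `pairwise_identity()` is an end-to-end global
alignment (Needleman-Wunsch, affine gaps) under the bundled BLOSUM62 matrix
with gap opening 10 and extension 0.5 — a gap of length L costs
10 + 0.5·L — and identity is identical aligned positions divided by the
full alignment length, gap columns included. That denominator convention
matters: it makes identity symmetric and bounded by the longer sequence, and
it is the convention of the classic EMBOSS global aligner whose parameter
defaults these are. The implementation was checked against an independent
reference aligner on a fixed sequence pair (score 3.5, identity 3/10) and
the value is frozen in the test suite. Unknown residue letters are scored
through the matrix's `X` wildcard row.

## Edge policies

* **No-carrier sentinel.** Under leave-one-out a mechanism with two carriers
  can lose its only remaining carrier from a fold. Then a_m is set to a
  large finite constant (10^6, exported as `NO_CARRIER_DISTANCE`) and b_m to
  0, so an uncarried mechanism can never win a nearest-neighbour
  comparison yet the files remain finite and serialisable.
* **Empty anchors.** A query sharing no attribute with any training instance
  would otherwise gravitate to the trainer with the fewest attributes.
  `add_empty_instances()` appends all-zero, label-free instances (reserved
  ids `__EMPTY_*`) that sit at distance `sqrt(q)` from a q-attribute query
  and vote for the empty label set. Anchors always train and are never
  evaluated: they are excluded from test folds and metric denominators.
* **Ties.** The BRkNN neighbourhood is expanded to *all* trainers tied with
  the k-th smallest distance (tolerance 10^-9), and a label needs at least
  half of the neighbourhood (inclusive at exactly half). This makes
  predictions invariant to training-set order — verified by a property test —
  and makes 1-NN with several distance-0 trainers coincide with the
  direct-transfer union vote. The voting variant is this package's contract;
  other nearest-neighbour libraries resolve ties differently.
* **Macro 0/0.** A label never predicted and never true in a fold has an
  undefined per-label metric; `macro_metric()` scores it `empty_value = 1`
  (the label was handled perfectly) before averaging. The choice is
  explicit and switchable.
* **Unseen truth in train/test.** Attribute spaces are aligned to their
  union (absent columns 0). A test protein whose true labels do not exist in
  the training label space cannot produce a false negative; its predictions
  still count as false positives, and the report flags `fn_total = NA`
  ("n/a").

## The synthetic generator

`synth_generate()` emulates the population structure the method assumes,
without any database access:

* Each family is one mechanism with a private signature pool (Poisson-sized,
  mean `signatures_per_family`, floor 4) and a random ancestor sequence
  (uniform over the 20 standard residues, length in `length_band`, default
  250–400 residues).
* Orthologs are mutated copies of the ancestor with target identities drawn
  from `identity_band` (default 0.4–0.9, the bulk of the observed
  same-mechanism identity range). Substitution positions are *nested* across
  the lineage, so the pairwise identity of two orthologs is about the
  smaller of their two targets and every same-family pair stays inside the
  band — checked empirically via `pairwise_identity()`.
* Each ortholog loses at most one signature (probability
  `signature_dropout × pool size`), keeping same-family distances in
  [0, sqrt(2)]: small but nonzero, like the observed same-mechanism band.
  The cap is structural: it keeps every within-family distance strictly
  below the distance to an empty anchor (≥ sqrt(3)) and to other families
  (disjoint pools), which is exactly the regime in which clean 1-NN recovery
  is provable — and the default fixture (5 families × 3 orthologs + 10
  negatives + 2 anchors) indeed evaluates to subset accuracy 1.0 for every
  seed.
* Negatives carry one signature drawn from the family pools plus two private
  ones and no labels; their nearest neighbour is always an anchor, so a
  correct method leaves them unlabeled.
* A confounder pair (`n_confounder_pairs`) gives two families identical
  signature pools with dropout disabled, reproducing the situation where two
  enzymes with *exactly* the same signatures carry different mechanisms;
  1-NN then votes across the pair and precisely the confounded instances
  are mispredicted. With `shared_signature_overlap < 1` the overlap is
  partial and the failure becomes probabilistic.
* Complex families (`n_complex_families`) emit per-subunit lineages plus a
  split map, exercising the label refinement machinery.

What the generator does *not* model: realistic residue frequencies and the
~18% chance-identity floor of real alignments, signature length/position
semantics (signatures are opaque tokens), and the long-tailed label
distribution of curated mechanism data. Passing tests therefore demonstrate
algorithmic correctness and the claimed failure modes, not performance on
curated enzyme sets; the test block that reproduces published-scale metrics
runs only when the corresponding curated ARFF/XML files are deposited under
`inst/extdata/paper/`.

## Numerical and design choices

* Sparse matrices (`Matrix::dgCMatrix`) hold the attribute data end to end;
  all-pair distances are computed by cross-products, clamped at 0 before the
  square root.
* ARFF sparse rows are 0-based index-value pairs; label columns are appended
  after attribute columns as binary `{0,1}` attributes and the XML file is
  the sole authority on which columns are labels. A leading `protein_id`
  string attribute carries instance identifiers through the format.
* `k_fold()` derives its partition from a single integer seed recorded in
  the report and restores the session RNG state afterwards; `folds = n`
  reduces exactly to `leave_one_out()`.
* Problem sizes in the shipped tests and in `scripts/acceptance.R` are kept
  deliberately modest (tens of instances, sequences of 60–400 residues,
  hundreds of alignments) — large enough to exercise every code path and
  tie case, small enough that the whole suite re-runs in a few minutes on a
  single core.

## Known limitations

Identity computation is quadratic in the number of sequences, so
identity-profile attributes on tens of thousands of proteins are expensive
by construction; the signature representation is the scalable path. The
1-NN rule has no confidence output. And as with any annotation-transfer
scheme, families indistinguishable in attribute space are irreducibly
confusable — the confounder fixture exists precisely to keep that failure
mode visible.
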