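---
title: "Gene-sequence natural vectors for interaction and non-interaction prediction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-sequence natural vectors for interaction and non-interaction prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvdt)
```

## The problem

Most proteins never interact: experimentally supported *non*-interacting
pairs (PPNIs) are scarce but are as important as interactions (PPIs) for
training unbiased classifiers and for reasoning about multi-protein
complexes. This package predicts both classes from the *coding nucleotide
sequence* (CDS) of each protein rather than from the amino-acid sequence.
The motivation is that synonymous-codon choice — codon usage bias — and
dinucleotide composition carry information that is erased by translation,
and that this signal correlates with interaction propensity.

## The feature model

Let $S = s_1 s_2 \cdots s_N$, $s_i \in \{A, C, G, T\}$, be a CDS of length
$N$. For each nucleotide $k$ define:

* the count $n_k = \#\{i : s_i = k\}$;
* the mean position $\mu_k = \frac{1}{n_k}\sum_{i:\,s_i = k} i$ (1-based;
  the first nucleotide is the origin at position 1);
* the second normalized central moment
  $D_2^k = \sum_{i:\,s_i = k} \frac{(i - \mu_k)^2}{n_k N}$.

The twelve numbers $(n_A,\dots,n_T,\mu_A,\dots,\mu_T,D_2^A,\dots,D_2^T)$
form the classic natural vector, which is in one-to-one correspondence with
the sequence when all central moments are retained; the second moment alone
is sufficient for stable classification, so higher moments are not
computed. We extend it with the 16 overlapping dinucleotide counts and the
64 overlapping trinucleotide counts (stride 1, lexicographic order
$A<C<G<T$), giving the 92-dimensional NVDT vector. Trinucleotide windows at
codon scale make the vector sensitive to codon-usage bias even though the
windows are not frame-aligned. Feature-subset variants are available as
`NV` (12), `NVD` (28), `NVT` (76) and `NVDT` (92) for ablation.

Two interpretation points where the defining formulas are ambiguous, and
the conventions adopted:

* The position sum runs over all sequence positions with an indicator
  weight (the standard natural-vector reading), so `mean_positions("ACGT")`
  is $(1,2,3,4)$.
* A nucleotide that does not occur gets $\mu_k = D_2^k = 0$. This avoids
  division by zero and keeps the vector finite and totally ordered; the
  alternative (dropping entries) would make the dimension data-dependent.
* k-mer features are raw counts, not frequencies — Z-score standardization
  later removes the scale anyway. `kmer_normalize = TRUE` divides by the
  window count $N-k+1$ for sensitivity analysis.

A worked example, computed here, for `"AATA"`:

```{r worked-example}
natural_vector("AATA", variant = "NV")
kmer_counts("AATA", 2)[c("AA", "AT", "TA")]
```

## Pair encoding (Cod1–Cod5)

A protein pair $(A, B)$ with per-protein vectors $A, B \in \mathbb{R}^{92}$
is encoded under one of five schemes: elementwise absolute difference
(Cod1), sum (Cod2), their concatenation (Cod3), elementwise product (Cod4),
or the juxtaposition $(A, B)$ (Cod5, 184 dimensions, the default — it
retains the most information and performed best in the original
evaluations). Cod1/2/4 are symmetric in the inputs by construction. Cod5 is
not, so the package orders the two ids lexicographically (C locale) before
encoding; this makes the feature deterministic run-to-run. The claim that
an RBF-SVM is invariant to the order of the two halves is heuristic, not a
theorem, so the package additionally offers `augment_orders = TRUE`, which
adds both orders to the *training* set only; a test asserts empirical
prediction agreement between $(A,B)$ and $(B,A)$, it does not assert exact
invariance.

## Standardization

Pair features are Z-scored: $d'(l) = (d(l) - \mu(l))/\sigma(l)$ with
$\mu(l)$ the training-set mean and $\sigma(l)$ the training-set
**population** (1/n) standard deviation — the 1/n form is followed exactly
as defined, rather than the sample (n−1) form. The state is fitted on
training pairs only and applied unchanged to held-out pairs; the
cross-validation driver refits it inside every fold, and the fitted
statistics are exposed (`fold_standardizers`) so leakage can be audited.
Zero-variance columns (possible for rare k-mers in small sets) transform to
0 rather than raising.

## Classifiers and evaluation

Two model families are supported behind one interface: an RBF-kernel SVM
(via libsvm) and a random forest. Hyperparameters are chosen by an internal
stratified 3-fold grid search on the training rows, selecting the best mean
held-out accuracy with ties broken to the first grid point (deterministic
given the seed). Default grids: SVM cost $2^{-5}\dots2^{15}$, kernel width
$\gamma = 2^{-15}\dots2^{3}$ in steps of $4\times$ (the original work used
library defaults without printing its grid, so these are this package's
choices); RF trees $\{50, 100, 150, 200\}$, $\sqrt{d}$ features per split,
minimum leaf 1.

SVM scores are the logistic transform of the (orientation-corrected)
decision value, so a score of 0.5 coincides with the decision boundary and
the default 0.5 cutoff reproduces the SVM's own labeling. This mapping is
used instead of libsvm's Platt-scaling probabilities because the latter are
calibrated with an internal random resampling that is not reproducible from
R's seed; the logistic map is deterministic and monotone in the margin, and
the 0.5-cutoff semantics are unchanged. RF scores are the positive-class
vote fraction. A score exactly at the cutoff predicts positive (a side must
be chosen; documented).

Evaluation reports accuracy, precision, sensitivity, specificity, MCC and
F1 from the confusion counts, and AUC by the trapezoidal rule over the ROC
(with tied scores grouped, this equals the Mann–Whitney pairwise-ordering
statistic; a test asserts the equivalence). Ratios with zero denominators
are reported as 0 and flagged, keeping tabular output stable. k-fold
results are summarised as mean ± sample (n−1) standard deviation, the
conventional k-fold report.

## Dataset construction

`filter_short()` drops CDS under $3 \times 50$ nt (the coding equivalent of
the 50-amino-acid minimum; boundary inclusive). `filter_redundant()`
greedily removes sequences over 40% pairwise identity to an already-kept
one; the identity callback is pluggable because no specific tool is
mandated — the built-in default (global alignment, match 1, mismatch 0,
linear gap, matches/alignment-length) is a stand-in suitable for small
inputs, and production users should inject a CD-HIT-style callback.
`sample_negatives()` draws balanced uniform random non-positive pairs
(optionally restricted to localization-disjoint pairs, reflecting the
assumption that proteins confined to different compartments tend not to
interact); self-pairs are excluded by default. `split_pairs()` implements
the 5:1 train:test split, stratified by label by default (stratification is
this package's choice where the original protocol is silent), and
`kfold_pairs()` produces label-stratified folds whose sizes differ by at
most one.

## The synthetic generator

Real curated PPI/PPNI datasets require database downloads, so the package
ships a generator that plants a *codon-usage* signal: latent codon profiles
are drawn from a symmetric Dirichlet over the 64 codons; the two sequences
of an interacting pair are sampled codon-by-codon from the same profile,
the two sequences of a non-interacting pair from two distinct profiles
(truly independent profile draws would let a fraction of "non-interacting"
pairs share a profile and be indistinguishable from interacting ones by
construction, destroying the ground truth the benchmark needs). Each
sampling distribution is `effect * profile + (1 - effect) * uniform`, so
`effect = 0` is an exact null and `effect = 1` the full contrast. Sequences
start with ATG and in-frame stop codons are excluded by renormalizing over
the 61 sense codons. The generator records which profile produced each
sequence (`profile_of`), which is how ground-truth non-interaction networks
are constructed for the network-prediction checks.

The signal is planted in codon usage deliberately: the trinucleotide block
of NVDT is exactly codon-composition-sensitive, so recovery of the planted
effect is a sharp end-to-end test of the feature math. What the construct
does **not** emulate: homology and phylogenetic correlation, interface-
residue structure, length variation, shared proteins across pairs, and the
extreme class imbalance of real interactomes. Passing these benchmarks
therefore validates the pipeline's mechanics and statistics, not biological
accuracy on real data.

Default study conditions: 300 pairs per class, 900 nt (300 codons), 2
profiles, concentration 1, effect 1. With those settings five-fold
cross-validated accuracy is expected well above 90%; with `effect = 0` the
held-out AUC sits at chance.

## Network prediction

A PPNI network is a set of candidate edges over curated nodes (roles
`core`/`satellite` come from annotation, never inference). `predict_network()`
is by contract the pointwise application of the trained classifier to each
edge's pair feature, and `network_accuracy()` is simply correct/total with
a per-edge correctness table (the gray/red classes of the usual figures).
`augment_and_retrain()` emulates incremental experimental knowledge: a
seeded uniform fraction (e.g. 10/30/40%) of each core protein's edges moves
from evaluation into training, the model is retrained and the remainder
re-evaluated; moved edges never re-enter the evaluated set. Train/evaluate
manifests are explicit throughout to avoid leakage between network edges
and training pairs. `export_pajek()` writes the standard Pajek `.net`
format with correctness encoded in the edge-value column (1 correct, 2
false, 0 unknown).

## Numerical and scale choices

* All randomness flows through explicit integer seeds; RNG state is saved
  and restored around every seeded operation, so library calls do not
  perturb user RNG state and identical configs are byte-identical.
* Test and example problem sizes are desk scale by design: the
  planted-signal recovery check runs the full study conditions (300
  pairs/class, 900 nt, five-fold); the effect-monotonicity sweep uses 100
  pairs/class, 600 nt, three folds with fixed SVM hyperparameters
  (cost 1, $\gamma = 1/184$); pipeline checks use a reduced SVM grid
  (cost $\{1, 10\}$, $\gamma \{1/184, 0.01\}$) because the planted
  contrast is insensitive to the grid — the full default grid is available
  and used identically through the same interface.
* Oracle tolerances: feature and metric implementations are required to
  match naive brute-force reimplementations to $10^{-12}$; standardization
  contracts to $10^{-9}$.

## Known limitations

* The redundancy filter's default identity function is a naive global
  aligner: quadratic time, suitable for tests and small curation jobs only.
* The one-to-one sequence/vector correspondence is checked only as a
  collision smoke test (10,000 random equal-length draws), not asserted as
  a theorem by the package.
* Real-data protocol elements that require external databases (DIP,
  Negatome, NCBI downloads, species curation) are out of scope; the
  dataset builders operate on whatever FASTA/TSV inputs the user supplies.
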