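---
title: "Predicting protein subcellular localization with N-to-1 convolutional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein subcellular localization with N-to-1 convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scloc)
```

## The problem

The compartment a eukaryotic protein is sorted to — cytoplasm, nucleus,
mitochondrion, membrane, the secretory pathway, and so on — constrains its
function, its interaction partners and its accessibility to drugs.
Experimental localization is slow and costly, so sequence-based predictors
matter. `scloc` implements an *ab initio* predictor: nothing but the amino
acid sequence (optionally enriched with evolutionary information from a
multiple sequence alignment) is used to assign one of eight classes:
Other, Cytoplasm, Golgi apparatus, Membrane, Mitochondrion, Nucleus,
Plastid, Secreted. The class order is frozen; it fixes the order of network
output units, of probability columns in every file, and the tie-break rule
(lowest index wins).

Single-label prediction is a deliberate restriction. Proteins that shuttle
between compartments or carry multiple annotations are excluded at dataset
construction time: allowing them would blur the class boundaries the model
is asked to learn, and the evaluation metrics below all assume one label
per protein.

## The model

An N-to-1 network maps a sequence of arbitrary length N to one fixed-size
output without first compressing it into hand-picked descriptors such as
k-mer counts. The composition is:

1. **Input kernel.** At every position i the window of `2c + 1` residue
   encodings (positions i − c … i + c, zero vectors beyond the ends) is fed
   through a two-layer feed-forward block: a windowed layer followed by a
   "kernel of size 1", each followed by a sigmoid. This yields a state
   vector per position.
2. **Hidden kernels.** Each of the `k` hidden-to-hidden kernels reads a
   window of `2γ + 1` consecutive state vectors and produces a new state
   vector per position, again as a two-layer sigmoid block. Weights are
   shared across positions (convolution) but not across kernels.
3. **Average pooling.** The last kernel's per-position outputs are averaged
   element-wise into a single vector — this is what makes the network
   length-agnostic.
4. **Classifier.** A fully connected sigmoid hidden layer and a softmax
   output turn the pooled vector into eight class probabilities.

Counting hidden layers: two in the input kernel plus the fully connected
hidden layer gives 3 with no hidden-to-hidden kernel; each extra kernel
adds 2, i.e. `3 + 2k` in total. All internal non-linearities are sigmoids —
not rectified linear units — and the loss is the relative entropy between
the one-hot target and the softmax output, which reduces to the
cross-entropy `-log p[target]`.

Training is stochastic gradient descent with exact analytic gradients
(`n1nn_backward()` is verified against central finite differences to
`1e-5` in the test suite). Every `checkpoint_every` epochs the model is
scored on a validation set and snapshotted; a 5000-epoch run at the default
cadence of 10 yields 500 checkpoints, of which the 6 best by validation
accuracy are kept per configuration. The deployed predictor is an ensemble
— canonically 6 best × 4 configurations = 24 members — whose class
probabilities are averaged unweighted (majority voting is available as an
option; the combination rule is a package choice, since ensembling is
described only as a stabilizer).

## Encodings

Two per-position encodings are supported:

* **One-hot**: 21 bits per residue — the 20 standard amino acids plus `X`,
  to which every ambiguity code (`B`, `Z`, `J`, `U`, `O`, `*`) is
  collapsed. How ambiguous residues should be encoded is not externally
  fixed; folding them into a single 21st symbol keeps the input width
  constant and is this package's convention.
* **Clipped MSA profile**: 22 values per query position — the frequency of
  each of the 21 symbols plus the gap frequency, computed over all rows of
  an alignment of homologs, after which the column of the query's own
  residue is set ("clipped") to 1. Nothing else is renormalized: clipping
  guarantees the query signal while leaving homolog information intact,
  the minimal reading of the clipping rule. Columns where the query itself
  has a gap (insertions in homologs) are dropped so the profile has exactly
  the query's length. Profiles are used alone, not concatenated with
  one-hot: after clipping, the profile already contains the one-hot
  pattern.

When a dataset mixes records with and without alignments, one-hot matrices
are padded with a zero gap column to width 22 so a single network serves
both.

## Dataset construction

The protocol mirrors standard practice for localization benchmarks:

1. **Validity and length filter** — keep labeled sequences of ≥ 30
   residues (shorter chains are peptides with different organizing rules);
   removals are reported per reason.
2. **Redundancy reduction** — a greedy sweep in input order: each surviving
   sequence removes every *later* sequence similar to it at e-value ≤
   0.001, exact duplicates included. The scan order is fixed to input
   order; this makes the reduction deterministic. The output provably
   contains no retained pair at or below the threshold, which the tests
   verify by exhaustive all-pairs audit.
3. **Interleaved 3:1:1 split** — positions 1–3 of every cycle of five go to
   training, position 4 to test, position 5 to validation. For 11,825
   records this yields 7095/2365/2365. Interleaving spreads listing biases
   of the source file evenly across partitions.

Similarity is delegated to a pluggable backend. The built-in backend
computes a Smith–Waterman local alignment (BLOSUM62, gap open/extend 11/1
via `Biostrings::pairwiseAlignment`) and converts the score to a
Karlin–Altschul e-value `E = K·m·n·exp(−λS)` with the published gapped
BLOSUM62(11,1) constants λ = 0.267, K = 0.041, where m is the query length
and n a database-size term (set size × mean length). This is a desk-scale
stand-in for a full BLAST search — adequate for datasets of hundreds of
sequences; for real corpora the `blast-tab` backend ingests tabular output
of an external BLAST run instead. A 5-fold interleaved fold driver
(`make_folds()`) is provided for cross-validation orchestration.

## The synthetic data generator

Real localization corpora require UniProt snapshots and PSI-BLAST runs
against UniRef90, so the package ships a generator that emulates *labeled
sequence sets with class-discriminative motif signal*: each class is
defined by a short residue motif (default: disjoint 5-mers) planted at a
random position in an otherwise background-sampled sequence (default:
uniform over the 20 standard residues, lengths 30–50 — long enough to be
protein-like under the ≥ 30 filter, short enough to keep desk-scale
training fast). A per-position substitution probability ε corrupts the
motif; mock MSAs mutate homolog rows at rate μ and gap them at μ/4; planted
near-duplicates exercise redundancy reduction against a known ground
truth. A single master seed drives every sub-generator through derived
child streams, so each artifact is reproducible independently of
generation order.

The signal is positional by design, not compositional: a contiguous motif
can only be recognized by a model that reads windows, which is what lets
tests discriminate context-bearing architectures (γ ≥ 1, c ≥ 1) from
context-free ones. What the generator does *not* emulate is real protein
evolution: no domain structure, no compositional class bias, no length
distribution tails, no homology families. Tests passing on this data show
that the machinery — encodings, gradients, training loop, selection,
ensembling, metrics — works end to end; they say nothing about accuracy on
real proteomes.

## Numerical choices

* **Initialization.** Weights are uniform in `[−r, r]`,
  `r = sqrt(6/(fan_in + fan_out))`, biases zero. For the input kernel's
  windowed layer the fan-in is taken as the number of *simultaneously
  active* inputs, `2c + 1`: one-hot and clipped-profile rows put unit mass
  on essentially one of their 22 columns, so the nominal `(2c+1)·22`
  fan-in overstates the input scale by a factor of ~22 and leaves
  first-layer pre-activations an order of magnitude too small — empirically
  the network then sits at chance for hundreds of epochs before any
  learning begins. With the effective fan-in the same problems escape the
  initial plateau in tens of epochs.
* **Padding.** Windows extending past either sequence end read zero
  vectors, so every one of the N true positions produces a state and
  pooling averages over exactly N vectors — padded positions are never
  pooled.
* **Loss clamping.** `-log p` is clamped at `p = 1e-12`; a package-level
  counter records how often, instead of silently producing infinities.
* **Degenerate metrics.** Any per-class metric with a zero denominator is
  defined as 0 and flagged, including MCC.
* **Tie-breaks.** Argmax ties resolve to the lowest class index everywhere
  (single models, ensembles, prediction files).
* **Checkpoint ties.** Equal validation accuracies are broken in favor of
  the earlier epoch — the cheaper, less overfit model.
* **Model files.** Serialized with R's native format plus an explicit
  format/version tag, because the round-trip contract is bit-exactness of
  every weight, which text formats cannot guarantee.

## Evaluation metrics

From the 8 × 8 confusion matrix `Z` (rows observed, columns predicted),
each class i is scored one-vs-rest with `TP = Z[i,i]`,
`FP = Σ_{j≠i} Z[j,i]`, `FN = Σ_{j≠i} Z[i,j]`, TN the remainder. The
reported quantities are `Spec = TP/(TP+FP)`, `Sens = TP/(TP+FN)`,
`Acc = (TP+TN)/total`, the Matthews correlation coefficient, and
`F1 = 2·Spec·Sens/(Spec+Sens)`. Note that `Spec` as conventionally
reported in this line of work is the positive predictive value
(precision), *not* textbook specificity; the formulas are implemented
exactly as the field reports them, and textbook specificity
`TN/(TN+FP)` is additionally published under the separate, unambiguous
column name `TrueSpec`. The overall accuracy `Q` is the trace of `Z` over
its grand total.

## Desk-scale study sizes

The test suite and the acceptance script run everything at sizes a single
CPU handles in minutes, as the package's own reference workloads: the
checkpoint-arithmetic run trains a 3-2-3-unit network on a 10-sequence toy
set for the full 5000 epochs; the learnability study uses 4 classes × 50
sequences (split 120/40/40) and eight single-kernel training runs — input
semi-contexts 2–5, 32 kernel units, 16 state units, under two minibatch
regimes (learning rate 0.3 / batch 20 and 0.5 / batch 40, momentum 0.9) —
for 200 epochs each, whose 6 best checkpoints apiece form a 48-member
ensemble; redundancy audits use 50-sequence sets. With per-example SGD at
the reference defaults (learning rate 0.015, batch 1) the same networks
learn the same data, only over many more epochs; the minibatch-momentum
regime is the package's choice for fast demonstration runs.

## Known limitations

* The built-in similarity backend is a pairwise aligner with fixed
  Karlin–Altschul constants, not BLAST; e-values agree in order of
  magnitude, not digit-for-digit, and its cost is quadratic in set size.
* Training is plain (optionally minibatched/momentum) SGD with a constant
  learning rate, faithful to the described procedure; no adaptive
  optimizers. Sigmoid saturation plus average pooling makes early learning
  slow — pooled features at initialization vary on the order of 1e-3
  between sequences — which is why desk-scale demonstrations use the
  minibatch-momentum regime above. On the reference motif workload the
  48-member ensemble reaches 80% accuracy on the validation partition and
  90% on the test partition (the quantities `scripts/acceptance.R`
  recomputes); perfect motif detection would need far longer training (the
  reference protocol trains 5000 epochs) or more than the 120 training
  sequences of the reference workload.
* Multi-label localization is out of scope by design.
* The annotation-to-class mapping for real UniProt records is exposed as a
  user-editable keyword table (`read_labels()` accepts any of the eight
  canonical names); the package does not attempt to parse free-text
  subcellular-location fields.

## A worked example

```{r example, eval = FALSE}
spec <- generator_spec(n_classes = 4, n_per_class = 50, epsilon = 0,
                       seed = 11)
recs <- generate_dataset(spec)
split <- interleaved_split(recs)
train <- encode_labeled(split$train)
valid <- encode_labeled(split$validation)

cfg <- n1nn_config(c = 3, gamma = 0, k = 0, kernel_hidden_units = 32,
                   state_units = 16, fc_hidden_units = 16)
tc <- train_config(learning_rate = 1, total_epochs = 200,
                   checkpoint_every = 10, seed = 301, momentum = 0.8,
                   batch_size = length(train$x))
checkpoints <- sgd_train(cfg, tc, train, valid)
best <- select_best(checkpoints, 6)
ensemble <- build_ensemble(list(config = cfg, checkpoints = best))

pred <- ensemble_predict_all(ensemble, valid$x)
Z <- confusion(pred$class, split$validation$label)
metrics_report(Z)
overall_Q(Z)
```
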