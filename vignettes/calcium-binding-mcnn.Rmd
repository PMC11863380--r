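---
title: "Multi-window convolutional scanning for calcium-binding site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-window convolutional scanning for calcium-binding site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cabindr)
```

## The problem

Calcium ions coordinate with a handful of residues in ion channels and
transporters (voltage-gated calcium channels, sodium–calcium
exchangers), and knowing which residues those are matters both for
understanding permeation and for calcium-channel-blocker target work.
Experimentally validated binding residues are scarce: curated corpora
contain on the order of a hundred binding residues against tens of
thousands of non-binding ones, i.e. a positive rate near 1:190. The
predictor must therefore (a) work per residue, (b) exploit sequence
context rather than single-residue features, and (c) survive extreme
class imbalance.

`cabindr` treats the problem as window classification over per-residue
protein-language-model (PLM) embeddings. PLM embeddings (ProtT5-XL-
UniRef50, ESM-2, TAPE) assign each residue a d-dimensional vector
carrying contextual and structural information; the package consumes
them as *precomputed* L×d matrices through a keyed store, because live
PLM inference needs multi-gigabyte weights and adds nothing to the
modelling questions studied here. A seeded synthetic generator stands
in for real embeddings in all tests.

## The model and its assumptions

For a residue at position *i* the model sees the context window of
`2L + 1` rows centred on *i*, zero-padded where the window crosses a
terminus. Two interpretations of a "window length" parameter circulate
for models of this shape; `cabindr` reads L as a **half-width**
(L = 6 → 13-row context). The reason is internal consistency: the
default convolution kernels span up to 12 residues, and a 12-row
kernel cannot scan a 6-row context but fits a 13-row one. This
half-width reading is a design decision of this package, documented
here because nothing in the architecture forces it.

The scanner applies, for every window size w ∈ {6, 8, 10, 12}, a 1-D
convolution with F filters over the residue axis. Kernels span the
full embedding depth (`w × d` weights per filter), in valid mode: a
13-row context yields `13 − w + 1` positions. ReLU and *global*
max-pooling reduce each filter to one number; pooled features from all
window sizes are concatenated (length `|W| · F`) and classified by one
dense ReLU layer with dropout and a sigmoid unit. Multiple kernel
sizes see the same context at different scales; max-pooling makes each
filter a detector for "this pattern occurs somewhere in the window",
while the largest kernels — whose output length is only 2–3 — retain
coarse position information. Both properties matter below.

Training hyperparameters are deliberately exposed as ordinary
configuration because the underlying study design leaves them open:
cross-entropy loss, Adam at learning rate 1e-3 (optionally
cosine-annealed), decoupled weight decay 1e-4, batch 256, up to 50
epochs with early stopping on a stratified 10% validation split
(patience 5), one dense layer of 128 units, dropout 0.2. All defaults
are package choices, not claims about the original training runs.

## Windowing, coordinates and degenerate inputs

Internally all residue indices are 0-based half-open; every file
format (annotation TSV, prediction TSV) is 1-based inclusive, and the
conversion happens exactly once at the I/O boundary. Termini are
zero-padded; a zero row is distinguishable from a real residue only
through the learned filters. `extract_window()` errors on approaching
an out-of-range centre rather than truncating, and pairing records
with an embedding store fails fast whenever a matrix row count
disagrees with the sequence length — silent off-by-ones between
annotations and embeddings are the most dangerous failure mode of this
kind of pipeline. Unknown residues are kept as `X` and embedded like
any other residue.

## Imbalance handling

Random oversampling, SMOTE and ADASYN act on the flattened
`(2L+1)·d` window vectors of the *training* partition only, after the
validation split, never on evaluation data. Both SMOTE and ADASYN are
implemented to their original definitions (k = 5 neighbours by
default; equidistant neighbours break ties by index order): SMOTE
draws each synthetic point uniformly on a segment between a minority
point and one of its k minority neighbours; ADASYN allocates the
synthetic budget per minority point proportionally to the fraction of
majority samples among its k nearest neighbours in the full training
set. Originals are always preserved as a prefix of the resampled
matrix, and a fixed seed reproduces the output bit-for-bit.

## Evaluation

`confusion()` thresholds scores at t (default 0.5; scores equal to t
count as positive), and `compute_metrics()` derives sensitivity,
specificity, accuracy and MCC exactly, rounding only at presentation
time (reports print 4 decimals). When an MCC denominator factor is
zero the MCC is reported as 0 with a warning. AUC is computed exactly
via the midrank Mann–Whitney statistic; the (fpr, tpr) curve is
returned for plotting and its trapezoidal area equals the rank
statistic by construction. An optional Youden-J threshold chosen on
validation data is provided but never the default, since the default
operating threshold of the original tables is unreported.

The ablation runner re-trains over one configuration axis (single
windows, greedy window combinations ranked by single-window AUC,
filter counts, context half-width, imbalance method, PCA dimension,
or classifier) and emits one tidy metrics row per grid point.
Baseline classifiers (KNN, SVM, random forest, gradient boosting)
share the train/predict surface through thin wrappers over `class`,
`e1071`, `randomForest` and `xgboost`.

## PCA and feature fusion

`pca_fit()` (built on `stats::prcomp`) is fitted **only** on
training-partition residue vectors and then applied unchanged to
validation/test matrices. The original description does not say
whether its reduction was fitted with or without the held-out
sequences; fitting on the training partition is the leakage-safe
choice and is enforced by the ablation runner. `merge_features()`
concatenates embedding sets column-wise (ProtT5 + ESM-2-650M:
1024 + 1280 = 2304), preserving input order.

## The synthetic generator

`generate_synthetic()` draws uniform random amino-acid sequences,
Bernoulli(binding_rate) binding positions (rejected within h of the
termini), standard-normal embeddings, and adds `effect_size · v` to
every residue within h of a binding position, where v is one fixed
random unit direction per corpus. Overlapping sites shift each row
once (set-union semantics). The localized ±h footprint (h = 2 by
default) gives multi-window convolutions a genuinely multiscale
pattern; a point signal would make all kernel sizes equivalent. The
default binding rate of 0.005 matches the ~1:190 imbalance of the
curated corpora.

What the generator does *not* emulate: real PLM embedding geometry
(anisotropic, heavy-tailed, position-correlated), sequence motifs
(EF-hands and the like), or annotation noise. Passing the synthetic
tests therefore demonstrates that the machinery — windowing, training,
imbalance handling, evaluation — recovers a known signal under known
conditions; it is not evidence about accuracy on real proteins.

A subtlety worth knowing when interpreting synthetic AUCs: residues
*next to* a binding site carry the same shifted rows in their windows
but are labelled negative. A purely translation-invariant detector
cannot distinguish a centred signal block from one shifted by a few
rows, which caps its AUC at roughly `1 − 4·rate`. Beating that ceiling
requires the position-sensitive large kernels, which is precisely what
the multi-window design provides — the synthetic benchmark exercises
this distinction deliberately.

## Experiment design choices

The signal-recovery and null experiments
(`signal_recovery_experiment()`) fix their corpus once: 24 sequences
of 50–100 residues, d = 32, binding rate 0.02, h = 2, and the scanner
at W = {6, 8, 10, 12}, F = 16, L = 6. The rate is higher than the
generator default because at 1:190 a desk-scale corpus leaves ~0–3
held-out positives, making AUC estimates unusable; 0.02 keeps strong
imbalance (~1:50) with ~5–12 held-out positives per seed. Training
uses SMOTE, 60 cosine-annealed epochs, dropout 0.5 and no validation
hold-out: with a few dozen positives, a stratified validation split is
too small to monitor reliably, and interpolated oversampling
generalizes visibly better than duplicating two dozen positive
windows.

With effect size δ = 3 the scanner reaches held-out AUC ≥ 0.95 on
every seed tested; with δ = 0, or with labels shuffled in both
partitions, there is nothing to learn. Because a single seed's test
partition holds only ~5–12 positives, a per-seed null AUC has a
standard deviation near 0.1, so the chance-band check `[0.4, 0.6]` is
applied to the *mean* AUC over the five seeds; applying it per seed
would reject a perfectly null model a third of the time. The split
helper deterministically advances to the next seeded permutation when
a partition contains no positive residues, since AUC is undefined
there — an evaluation-validity requirement, not a data filter.

These problem sizes keep the full experiment suite to a few minutes
of CPU; they are stated here so that anyone scaling the corpus up
knows which numbers were choices rather than constraints of the
method.

## Numerical and tie-breaking conventions

* Sequence-level splits take `floor(ratio · n)` training sequences of
  a seeded permutation (27 sequences at 80:20 → 21/6).
* Score ties at the decision threshold count as positive; AUC counts
  score ties between classes as one half.
* kNN neighbour ties (SMOTE/ADASYN) break by ascending index.
* The max-pool argmax takes the first maximizing position; gradients
  flow only through it, and only where the pooled value is positive.
* All randomness (initialization, shuffling, dropout, resampling,
  generation) flows through explicit integer seeds; reruns are
  bit-identical, and every stochastic routine restores the caller's
  RNG state.

## Known limitations

* Live PLM adapters are not bundled; the supported path for real
  embeddings is the precomputed store. Parity with any particular
  upstream embedding run (precision, special-token handling) is
  therefore out of scope.
* The mCNN trains on CPU in pure R; it is sized for corpora of tens
  of sequences, not proteome scale.
* LSTM/Transformer baselines are not implemented; the classifier
  contract covers KNN/SVM/RF/gradient boosting.
* CD-HIT-style redundancy reduction is expected to have happened
  upstream; the package accepts pre-clustered input.
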