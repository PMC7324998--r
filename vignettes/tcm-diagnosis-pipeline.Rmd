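---
title: "An assistive diagnostic pipeline for traditional Chinese medicine notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An assistive diagnostic pipeline for traditional Chinese medicine notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In traditional Chinese medicine (TCM) a clinical encounter produces two
linked judgements: the *disease* and the *syndrome* — an abstraction of the
patient's signs and symptoms that summarizes the stage, location and
etiology of the condition. The two are related many-to-many: one disease
presents as several syndromes and the same syndrome occurs under several
diseases. An assistive diagnostic system therefore has to read a freestyle
electronic health record (EHR) note, recognize the clinically meaningful
entities in it, rank candidate diseases, and then — conditioned on the
disease — predict the syndrome.

`tcmdx` implements that system as four cooperating stages plus the
data-handling around them:

1. **Preprocessing** — width normalization, non-text stripping, section
   splitting, quality control, class rebalancing, stratified partitioning.
2. **Named-entity recognition (NER)** — a bidirectional recurrent encoder
   with a linear-chain conditional random field (CRF) output layer, decoded
   with Viterbi, producing entity spans that are assembled into structured
   records (with symptom–duration pairing).
3. **Feature extraction** — dictionary standardization, cross-section
   merging, symptom–time expansion, a linear time-decay weighting, and
   vectorization against a frozen feature index.
4. **Diagnosis** — a text-convolution network ranks diseases (top-k output),
   and a per-disease *integrated model* — a majority-rule vote over four
   heterogeneous base learners (back-propagation MLP, support vector
   classifier, random forest, extreme gradient boosting) — predicts the
   syndrome.

Because real hospital corpora are private, the package ships a first-class
synthetic-corpus generator whose output has the statistical structure the
pipeline assumes, so every stage is trainable and testable offline.

## The synthetic corpus: what it emulates and what it does not

`generateCorpus()` produces fully annotated notes with:

* the predefined section inventory (chief complaint, present illness,
  medical/family history, physical exam, tongue, pulse, admission and
  discharge pages);
* a standard chief complaint pattern of symptoms each qualified by a
  duration ("`sym_D01_1 3-days ...`"), plus durations in the present
  illness;
* gold entity spans (0-based, half-open character offsets per section) for
  five entity types: symptom, duration, tongue-quality, pulse, history;
* a disease label and exactly one syndrome label drawn from a many-to-many
  ontology;
* synonym surface variants (emulating different physicians' wording),
  mixed full-width/half-width characters (simulated by mapping ASCII to the
  Unicode full-width block, so normalization is exercised without requiring
  Chinese text), and optional non-text placeholders;
* planted quality-control violations of exactly the three screened kinds:
  missing admission/discharge page, admission–discharge field inconsistency,
  and a non-standard chief complaint.

Separability is an explicit dial: with `noiseProb = 0` each disease draws
from its own disjoint symptom lexicon and each syndrome has its own marker
symptoms, so a correct implementation must recover the labels almost
perfectly. That is what the end-to-end tests assert — and it is also what
they do *not* show: synthetic notes are token sequences from a generated
lexicon, not clinical prose. Passing at noise 0 demonstrates that the
machinery (spans, offsets, feature index, gating) is correct, not that the
published accuracies transfer to real Chinese EHR text. The published
corpus-scale numbers (22,984 notes, 187 diseases, 466 syndromes) are
documented context, not targets, because that corpus is private.

Defaults that mirror the documented corpus statistics: the severe class
imbalance example (2180/1913/109/584 notes per class), a QC pass that takes
23,719 generated notes to 22,984 by discarding 735 planted violations, and
the 8:1:1 partition in which one tenth of 22,984 is 2,298 validation notes.
These appear as test fixtures generated in code, never as stored data.

## Models and numerical choices

### Linear-chain CRF

For emissions $e \in \mathbb{R}^{T\times K}$ and transitions $A$ (with
virtual START/STOP states; transitions into START and out of STOP are
$-\infty$), a path $y$ scores

$$s(y) = A_{\text{START},y_1} + \sum_t e_{t,y_t} + \sum_t A_{y_t,y_{t+1}}
       + A_{y_T,\text{STOP}}.$$

`crfLogPartition()` is the forward algorithm in log space;
`crfViterbi()` decodes the argmax path with ties broken toward the lowest
tag index (a determinism choice — any fixed rule would do, this one makes
`which.max` the implementation). Training minimizes
$\log Z - s(y^{\text{gold}})$; gradients are the classical
forward–backward sufficient statistics (tag marginals and expected
transition counts minus their gold counterparts). All of this is validated
against brute-force enumeration over all $K^T$ paths at small sizes.

### NER encoder

The emissions come from a bidirectional recurrent (tanh) encoder over token
embeddings — 16-dimensional embeddings and 16 hidden units per direction by
default — trained jointly with the CRF by Adam, one section-sequence at a
time, with backpropagation through time written out by hand. This is the
same architecture family as the standard BiLSTM-CRF tagger, sized for a
synthetic lexicon where per-token evidence is strong; character-level
features and gated (LSTM) units are not needed at this scale and are not
implemented. Early stopping monitors span-level F1 on the validation notes
and keeps the best parameters. BIO decoding repairs an orphan `I-t` to
`B-t`. A duration entity attaches to the nearest *preceding* symptom in the
same section; a duration with no preceding symptom is logged and left
unpaired.

### Time-decay feature weights

Weights follow the recurrence `weight(n+1) = weight(n) + 1/N` with
`weight(0) = 0` over `N` total time units, i.e. `weight(k) = k/N`. The
recurrence indexes weights abstractly; the package fixes the recency
reading — an occurrence at time distance $n$ (in days) receives
`weight(N - n) = (N - n)/N`, so "now" weighs 1 and the edge of the window
weighs 0. Undated occurrences weigh 1. Units: days, with month = 30 and
year = 365; the default window is `N = 1095` days (three years), chosen to
cover the longest duration the generator emits so no clamping occurs on
synthetic data; distances beyond the window are clamped to weight 0 with a
log entry. A symptom with a duration yields both its bare term and the
compound `symptom#duration` term (the worked chief complaint with two dated
symptoms yields four feature terms). The selection threshold `tau` defaults
to 0 — every observed feature is kept — because the selection rule is
specified but no cutoff is published.

### Disease classifier

The text-convolution network embeds the entity token sequence (length-`L`,
zero-padded, pad row fixed at zero) and convolves with `nFilters` kernels
per height, each spanning the full embedding width, so a height-`h` kernel
yields an `(L-h+1)`-row feature surface; max-pooling reduces each surface
to a scalar, and the concatenated pooled vector feeds a softmax over
diseases. `textCnnConfig()` defaults to the published geometry — 100-dim
embeddings, 256 kernels at heights `L-1`, `L-2`, `L-3` (the 2×1, 3×1, 4×1
surfaces) — which is unusual (nearly global kernels) but unambiguous; the
classic small heights 2/3/4 remain available through `kernelHeights`. The
nonlinearity is ReLU (a standard choice; nothing is published about it).
Training is cross-entropy with Adam, early-stopped on validation top-1
accuracy; `cnnGridSearch()` provides the small configurable hyperparameter
search. Ranked output breaks probability ties by class index so top-k lists
are reproducible prefixes of each other.

The desk-scale pipeline default (`pipelineConfig()`: `L = 24`, `d = 48`,
64 filters) reflects the input actually seen on synthetic data — entity
token sequences of roughly 10–20 tokens — while keeping the published
geometry as the documented full-scale default of `textCnnConfig()` itself.

### Integrated syndrome model

One model per disease, gated by the disease prediction. Each model fits the
four base learners on the same class-balanced records (balancing via
uniform downsampling and synthetic minority oversampling: interpolants
$x + u(x' - x)$, $u \sim U(0,1)$, $x'$ among the $k=5$ within-class nearest
neighbours — $k$ is a conventional default, nothing is published). The
prediction is the majority vote; because four voters can tie 2–2 or
1–1–1–1, the tie-break chain is fixed as: vote count, then mean confidence
of the tied label's voters, then lexicographic label order. Confidence is
the learner's predicted-class probability (Platt-scaled for the SVC). No
stacking weights are trained — the vote itself is the combination rule. A
disease observed with a single syndrome gets a degenerate constant
predictor, logged. `evaluateModels()` reports stratified 5-fold
cross-validated accuracy per base learner and for the integrated vote,
reducing the fold count with a warning when a syndrome has fewer records
than folds. An optional small hyperparameter search
(`fitIntegrated(tune = TRUE)`) selects per-learner settings by k-fold
cross-validation with bootstrap resampling of each training part.

### Evaluation

`topkAccuracy()` is the fraction of cases whose gold label is in the first
`k` ranked predictions. System-level accuracy demands disease *and*
syndrome simultaneously correct; for `k > 1` the gold disease's syndrome
model is consulted only when the gold disease appears in the top-k, which
makes system top-k ≤ disease top-k provable rather than merely observed.
Both invariants (monotonicity in k, system ≤ disease) are asserted on every
evaluated corpus.

## Design choices made where the design was open

* **What feeds what**: the weighted feature vectors feed the syndrome
  ensembles; the disease classifier consumes the entity token sequence
  (entities and their relationships), since its convolutional input is a
  token matrix, not a bag of weights.
* **Balancing is applied to vectorized training records only**, never to
  raw text and never to validation/test folds: interpolating text is
  ill-defined, and leaking synthetic minority points into held-out folds
  would inflate accuracy.
* **Partitioning is stratified by disease** with floor-based sizes
  (validation and test each get `floor(N/10)`, remainder to training) —
  this reproduces 2,298 of 22,984 exactly.
* **Admission/discharge consistency** is checked on a configurable field
  list (default: disease, sex, age).
* **Classifier training uses gold annotations** (the training corpus is
  annotated); end-to-end evaluation always runs the NER front end, so the
  reported system numbers include NER errors.
* **Entity inventory**: symptom, duration, tongue-quality, pulse, history —
  a minimal reconstruction of the documented annotation examples; the
  relation set is symptom–duration pairing only (no negation, no other
  relations).

## Problem sizes used in the test suite

The end-to-end recovery fixture uses 8 diseases, ~20 syndromes, 200 notes
per disease at noise 0 — large enough that every stage has a real train/
validation/test split and every disease has enough syndrome records for
5-fold cross-validation, small enough to run on a single CPU in minutes.
CRF correctness is checked on 200 random instances with `T ≤ 4`, `K ≤ 3`
against exhaustive enumeration at tolerance 1e-8; the majority-vote
tie-break chain is checked exhaustively over all 4-vote patterns on up to 4
labels.

## Known limitations

* Tokenization is whitespace/offset based; Chinese word segmentation is out
  of scope (the generator is language-neutral by design).
* The NER encoder is a simple tanh recurrence, not a gated LSTM, and has no
  character-level features; both matter on real text with rare words.
* Pretrained word embeddings (the published system used a 149,076-word
  vocabulary trained on external hospital text) are supported only as a
  configuration point; synthetic runs train embeddings from scratch.
* Syndrome prediction is single-label per note; multi-label syndrome sets
  and learned gating/stacking are non-goals.
* The published absolute accuracies were measured on a private hospital
  corpus and are not reproducible here; nothing in this package's tests or
  documentation claims otherwise.

## A worked example

```{r, eval = FALSE}
library(tcmdx)

ont <- buildOntology(4, 8, 2, seed = 1)
lex <- makeLexicon(ont)
notes <- generateCorpus(genConfig(
  ont, c(D01 = 80, D02 = 80, D03 = 80, D04 = 80), seed = 2, noiseProb = 0))

models <- trainPipeline(notes, lex, pipelineConfig(seed = 3))
ids <- vapply(notes, `[[`, "", "note_id")
res <- runPipeline(notes[ids %in% models$split$test], models)
res$report
```

The report prints disease and system top-1/3/5 accuracies and the mean
per-disease syndrome accuracy; on this separable fixture all of them are at
or near 1, and the invariants top-5 ≥ top-3 ≥ top-1 and system ≤ disease
hold by construction.
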