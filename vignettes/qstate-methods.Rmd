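---
title: "Predicting homomeric quaternary state from pooled embeddings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting homomeric quaternary state from pooled embeddings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The quaternary state (qs) of a homomer — how many copies of one
polypeptide assemble into the functional unit — is annotated only for
proteins with solved structures, and it is notoriously brittle under
homology transfer: within a single structural family, members can
adopt different assembly states, and single point mutations can switch
one state to another. `qstate` implements a sequence-only predictor
built on protein-language-model (pLM) embeddings, together with the
baselines, data hygiene and confidence analyses needed to evaluate it
honestly.

## Model

**Pooling.** A pLM backend maps a sequence of length $L$ to a matrix
$M \in \mathbb{R}^{L \times D}$, one row per residue ($D = 1280$ for
the ESM-2 adapter, $D = 1024$ for ProtBERT). `mean_pool()` averages
over the residue dimension, $v_j = \frac{1}{L}\sum_i M_{ij}$, giving
one length-$D$ vector per protein regardless of length. Special
tokens (BOS/EOS/padding) emitted by live models are excluded from the
rows before pooling; whether the original tuning included them is not
observable from outside, and excluding them keeps the contract "exactly
$L$ rows" exact. Live backends are optional adapters; the package's
tests run entirely on a deterministic mock backend, so nothing here
requires model downloads.

**Classifier.** `train_mlp()` fits a single-hidden-layer perceptron
on pooled vectors: softmax cross-entropy, L2 penalty
$\frac{\alpha}{2n}\sum \lVert W \rVert^2$, minibatch adam. The tuned
defaults (`mlp_config()`) are: 120 hidden units, *identity*
activation, adam, adaptive learning-rate schedule starting at 0.01,
at most 1000 epochs, early stopping with patience 20 at tolerance
$10^{-3}$, $\alpha = 5\cdot 10^{-4}$, batch size 250, seed 22.
With identity activation the network is effectively a linear softmax
model with an over-parameterized factorization; the other activations
remain configurable, and `hyperparameter_search()` samples
configurations uniformly from a user-given space, scoring each by mean
*adjusted* balanced accuracy over grouped cross-validation folds.
Reports always print plain balanced accuracy; the chance-corrected
version $(\mathrm{BA} - 1/C)/(1 - 1/C)$ is used for model selection
only, where it makes scores comparable across fold compositions.

**Early-stopping semantics.** An epoch whose full-data loss fails to
improve the best seen by more than `tol` counts as stalled. After
`patience` stalled epochs the adaptive schedule divides the learning
rate by 5 and resets the counter; training stops once the rate falls
below $10^{-6}$ (non-adaptive schedules stop at the first stall-out).
If an epoch produces a non-finite loss (possible under absurd search
configurations), the epoch is rolled back and training stops — the
model stays usable and simply scores poorly.

**Annotation transfer.** `transfer_embedding()` assigns each query
the label of its maximum-cosine reference; `transfer_sequence()` the
label of its best local-alignment hit, with identity defined as
matches / alignment length and a qualifying hit requiring identity
≥ 0.30 *and* coverage of the shorter sequence ≥ 0.30. Queries without
a qualifying hit stay unpredicted (the "0-predicted" bin) and count as
errors in every metric. "Without homolog information" is
operationalized by masking all references in the query's ≥30%-identity
cluster — the same threshold that defines the data split, so "homolog"
means one thing throughout. Ties in similarity resolve to the
lexicographically smallest reference id, for determinism.

## Homology-aware evaluation

Records are clustered at 30% identity with ≥30% coverage.  When an
`mmseqs` binary is on the PATH it is used with the matching
parameters; otherwise a built-in greedy centroid clusterer visits
sequences longest-first and joins each to the best admissible existing
representative. The built-in path screens candidate representatives
by shared 5-mers — containment $C$ of the shorter sequence's k-mers
inverts to an identity estimate $C^{1/k}$ — and then decides
membership by an actual local BLOSUM62 alignment. The screen alone is
not trustworthy near the threshold: a single chance-shared 5-mer
between unrelated sequences already inverts to ≈0.37 "identity", and
at 20% per-site divergence the few surviving k-mers can cluster into
one short run that mimics a short shared segment. Requiring ≥3 shared
k-mers to become a candidate and delegating the decision to the
aligner fixes both failure modes while keeping the clusterer free of
external binaries.

`make_holdout_split()` and `make_cv_folds()` assign whole clusters,
never records: clusters are visited largest-first (ties shuffled by
the seed) and greedily placed in the partition or fold that most
reduces a chi-square-style deviation of per-label counts from their
targets (10% hold-out share; folds of $1/k$ each). This is
deterministic given the seed, invariant to input record order (records
are sorted by id, cluster ids are named after representatives), and
near-stratified: exact stratification is impossible under group
atomicity, so fold sizes can deviate by up to the largest cluster. A
cluster larger than the hold-out target triggers a warning and the
hold-out may overshoot.

Training data are rebalanced with `downsample_classes()`: monomers and
dimers (the two dominant classes) are reduced to
$\lfloor n/3 \rfloor$ members drawn uniformly without replacement.
`floor`, not `round`: "reduced to a third" is treated as an upper
bound. Down-sampling is applied once per training partition, before
fold construction, and re-drawn per seed. Classes with fewer than
`min_count` (default 10) training members are excluded from the
trainable set by `drop_rare_classes()` but retained for evaluation,
where they are scored as never-correct — mirroring a truth space wider
than the predictor's class list.

## Confidence analyses

For each actual class, `confidence_separation()` (transfer
similarities) and `probability_confidence()` (MLP top probabilities)
run a one-sided "greater" rank-sum test of correct vs. incorrect
predictions through a shared core, `rank_sum_test()`. The test uses
midranks, the normal approximation with tie correction and no
continuity correction; for combined samples of at most 12 the p-value
comes from exhaustive enumeration of rank assignments instead. Note
an asymmetry of the exact path: for two identical samples it returns
$P(W \ge w_{obs}) > 0.5$, which is what enumeration dictates, while
the asymptotic path returns exactly 0.5 at $z = 0$. Per-class
p-values are reported uncorrected for multiple testing (flagged in the
output); classes lacking correct or incorrect members are reported as
skipped rather than silently dropped.

`family_diversity()` summarizes assembly-state heterogeneity within
families: per family the number of distinct actual and predicted
states, and per record a subgroup — member of a single-qs family,
carrier of the dominant qs of a multi-qs family (ties to the smaller
qs), or carrier of a rare qs — with per-qs accuracies for each
subgroup. Single-member families and records without a family id are
tabulated separately, never dropped.

## Data curation

`read_label_table()` reads QSbio-style annotation exports with a
configurable column schema. `filter_qsbio()` keeps high-confidence
homomers: `is_homomer`, `corrected_nsub == nsub` (annotation unchanged
by internal validation), `best_bu == 1`, and error probability
*strictly* below 15. `deduplicate()` collapses identical sequences to
the entry with the lowest error probability — "highest confidence" is
interpreted as exactly that field; ties keep the first-encountered
entry, and the best-biological-unit rank does not participate (the
provenance of such a secondary criterion would be unclear).
Non-standard residues (B, Z, U, O, J) are mapped to X with a warning;
empty sequences are rejected.

## The synthetic world

`generate_dataset()` draws, per family $f$, an isotropic Gaussian
center $c_f$ (scale $\sigma_b$) and a consensus sequence; each member
carries vector $x = c_f + s\,u_{y} + \varepsilon$, with $u_y$ a fixed
orthonormal direction per qs class, $\varepsilon$ isotropic noise of
scale $\sigma_w$, and a sequence mutated from the consensus at an
independent per-site rate. A fraction of families harbours a second,
rare state on about a quarter of their members. Everything is
deterministic in the seed.

Default values, chosen once by upfront design analysis and frozen:

| parameter | default | rationale |
|---|---|---|
| families × members | 800 × (2–4) | ≈2,400 records; many small families make family memorization unrewarding, as in real sequence space |
| classes | 12 states (1,2,3,4,5,6,7,8,10,12,14,24) | the trainable-class regime of real homomer surveys |
| proportions | 0.24, 0.18, 0.09, 0.12, 0.045, 0.08, 0.04, 0.06, 0.04, 0.04, 0.035, 0.03 | monomers > dimers > tetramers > trimers ≈ hexamers > rare, with the rarest at 2–3% so every class keeps ≈50+ examples and remains learnable at this n |
| $D$ | 16 | just above the class count, so orthonormal class directions exist; real pLM dimensions are three orders larger but the pipeline is dimension-agnostic |
| $s = 3\sigma_w$ | 3 vs. 1 | class signal three times within-class noise: strong but not trivial separability (the construction's Bayes ceiling is ≈0.89 for 12 classes) |
| $\sigma_b$ | 0.25 | family structure present but subordinate to class signal — the regime in which embeddings carry assembly-state information across family boundaries, which is the premise of the whole approach |
| multi-qs fraction | 0.15 | most families single-state, a visible minority mixed |
| mutation rate | 0.05 | members ≈90% pairwise identity: clusterable families, realistic within-family divergence |

Design analysis behind the geometry: with 12 classes on orthonormal
directions the margin $s$ competes against the maximum of 11 Gaussian
competitor scores with per-direction noise
$\sqrt{\sigma_b^2 + \sigma_w^2}$, and a *trained* model additionally
pays for estimating rare-class directions and for over-fitting family
centers. Larger $\sigma_b$ or harsher skews push the achievable
cluster-held-out balanced accuracy of the tuned configuration below
what the construction is supposed to demonstrate (rare classes with a
dozen members are unlearnable at any geometry); the frozen values put
the tuned model comfortably in the 0.80+ range while keeping all the
qualitative structure. `label_shuffle()` permutes the
sequence-to-record mapping, destroying sequence signal while vectors
and labels stay fixed — the device used to show that embedding-based
prediction survives where homology transfer collapses to chance.

What the generator does *not* emulate: true pLM geometry (anisotropy,
length effects, the 1280-dimensional scale), unequal family divergence,
annotation noise, or any correlation between sequence and vector given
the class. A green test suite therefore establishes that the
machinery is correct and that the method recovers signal *of the
assumed form* — it says nothing about accuracy on real proteomes.

## Numerical choices and degenerate inputs

* Cosine similarity errors on zero-norm vectors rather than returning 0.
* Probability vectors are softmax-normalized with max-subtraction;
  rows sum to 1 within $10^{-9}$.
* All stochastic steps (splits, folds, down-sampling, initialization,
  batch order, simulation) run in private RNG streams restored
  afterwards, so package calls never perturb a user's RNG state.
* Duplicate training points never change the class list; single-class
  training data and non-finite vectors are errors.
* Metric edge cases: a class never observed and never predicted has
  undefined (NA) precision/recall; a class predicted but never
  observed contributes F1 = 0; empty inputs error. Confusion matrices
  carry an explicit final "none" column for absent predictions, and
  row frequencies of empty rows stay zero.

## Limitations

* The live ESM-2 / ProtBERT adapters require an external runtime and
  are reported as unavailable rather than approximated; production use
  feeds precomputed embedding caches (TSV: id + D columns).
* The built-in clusterer is a fixture-scale stand-in for a dedicated
  clustering tool and is quadratic in the worst case; at database
  scale, install `mmseqs`.
* Probabilities are raw softmax outputs; no calibration
  post-processing is applied.
* The predictor treats qs as a flat label set; ordinal or
  multi-label structure among assembly states is not modelled.
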