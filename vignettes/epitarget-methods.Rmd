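---
title: "Multi-target epigenetic bioactivity prediction: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-target epigenetic bioactivity prediction: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions they make, the parameters that matter, what the
synthetic benchmark does and does not show, and the places where the design
was genuinely open and a choice had to be made.

## 1. The task

Given a compound's SMILES string and a registry of epigenetic protein targets
(HDAC, HMT, HDM, HAT, DNMT families), predict for every target whether the
compound is active — operationally, whether its potency (IC50/EC50/Ki/Kd) is
at or below 10 µM. Activity values at exactly 10 µM are active; anything
strictly above is inactive (`binarize_activity()`). A target enters the
modelling panel only if it has at least 30 active **and** 30 inactive
compounds (`filter_targets()`); below that, a per-target binary classifier is
not meaningfully trainable or evaluable. A stated label that contradicts a
stated potency under the 10 µM rule is treated as a data error, and duplicate
(compound, target) rows with conflicting labels are rejected rather than
resolved by voting, because no resolution rule is defensible without assay
metadata.

## 2. Molecular graphs

`smiles_to_graph()` quantizes a molecule into:

* per-atom features (dimension 28 by default): one-hot element over
  {C, N, O, S, F, Cl, Br, I, P} + other; one-hot degree 0–5; formal charge
  (scalar); one-hot implicit-H count 0–4; aromaticity flag; one-hot
  hybridization {sp, sp2, sp3, other}; ring-membership flag;
* per-bond features (dimension 6): one-hot order {single, double, triple,
  aromatic}; conjugation flag; ring flag;
* a directed-edge structure: each chemical bond contributes two directed
  edges; `reverse_index` is a fixed-point-free involution pairing them.

Hydrogens are implicit — a count feature, never a node — which keeps graphs
small and matches standard practice for message passing on molecules.
Multi-fragment inputs (salts) keep the largest fragment and record the event.
Parsing is delegated to OpenBabel; ring perception and aromaticity come from
the ring decomposition, formal charges from the molblock's charge records.
Two featurization details are computed by rule rather than read from the
parser: hybridization (triple bond or two double bonds ⇒ sp; any double or
aromatic bond ⇒ sp2; else sp3; halogens "other") and conjugation (aromatic
bond, or both endpoint atoms sp/sp2). These are deliberate, documented
approximations: they are self-consistent across a dataset, which is what the
downstream encoder needs; they are not a substitute for a full valence-model
assignment and will differ from other toolkits on exotic chemistry (e.g.
amide nitrogen is sp3 under this rule).

## 3. The three encoders

All three implement `T` rounds of the node update `h_i^t = U(h_i^{t-1},
m_i^t)` with sum aggregation of neighbor messages, a readout over atoms, and
a logistic head, trained end-to-end with Adam on binary cross-entropy.
Forward and backward passes are written analytically in R (with small C++
kernels for gather/scatter aggregation); the test suite verifies every
gradient against central finite differences at 1e-4 relative tolerance.

* **GCN**: `U = ReLU(W_self h + W_msg m + b)`, per-step (untied) weights.
* **GGNN**: `U = GRU(h, m)` with tied weights across steps — update gate
  `z = σ(W_z m' + U_z h + b_z)`, reset gate `r`, candidate
  `c = tanh(W_c m' + U_c (r∘h) + b_c)`, `h' = (1−z)∘h + z∘c`, where `m'` is a
  learned linear map of the aggregated message.
* **DMPNN**: states live on directed bonds. The initial state of edge `v→w`
  is `ReLU(W_i [x_v ; e_vw])`; each step sets
  `h_{v→w} ← ReLU(h⁰_{v→w} + W_m Σ_{k∈N(v)\{w}} h_{k→v})` — the reverse edge
  is excluded, so information never immediately bounces back — and the final
  atom state is `ReLU(W_a [x_v ; Σ_incoming h_e])`. This is the standard
  directed-bond formulation with a skip connection to the initial state.

**Feature extraction point.** The molecule embedding handed to the boosting
stage is the penultimate vector — the readout output before the logistic
head. The head is kept in the model (its training probability is available
via `embed(..., head = TRUE)`) but plays no role downstream.

**Defaults and why.** `hidden_dim = 128`, `depth T = 3`, `epochs = 30`,
`learning_rate = 1e-3` (Adam), `batch_size = 50`, `dropout = 0`, sum
readout, one encoder per target. These are ordinary message-passing defaults
sized for CPU training. `T = 3` matches the detectability radius of the
planted motifs (section 6), so the benchmark is neither trivially easy nor
impossible for the architecture. No early stopping and no class reweighting:
a fixed epoch budget keeps runs bit-reproducible from the seed, and class
imbalance is reported rather than corrected, since the evaluation metrics
are imbalance-aware. The test suite and the acceptance script use a
desk-scale configuration (`hidden_dim = 32`, `epochs = 15`) sized so that a
full five-fold, five-target study with repeats trains in minutes on one CPU.

**Minibatching.** A batch is the disjoint union of its molecular graphs, so
one gather/aggregate pass performs message passing for the whole batch. The
batch partition is drawn once from the seed and reused across epochs (batch
*order* is reshuffled every epoch); this trades a little stochasticity for
exactly reproducible, cheaper training.

## 4. Boosting, assembly, significance

The classification stage is delegated to xgboost with the logistic objective
plus per-tree L1/L2 penalties — precisely the regularized objective the
hybrid architecture calls for — at `n_trees = 200`, `max_depth = 6`,
`eta = 0.1`, `λ = 1`, `α = 0`, single-thread for determinism. The behavioral
contract (increasing λ never improves training fit; probabilities respect
the 0.5 decision threshold, exposed as configuration) is asserted in tests.
Adam applies only to the encoder stage; trees are not gradient-descent
trained.

`fit_multitarget()` trains one encoder + booster per registry target and
assembles them; `predict_multitarget()` output is bitwise identical to
invoking each single-target classifier, by construction and by test.

Per compound, `polypharmacology_report()` computes for each object group the
exact upper-tail hypergeometric probability of seeing `k` of the compound's
`n` predicted-active targets fall in a group of size `K` out of `N`
registered targets (population = registered targets, draws = the compound's
predicted-active targets — the only parametrization consistent with
per-target binary calls). `stats::phyper` supplies the exact tail; tests
verify it against brute-force subset enumeration for all N ≤ 12. P-values
are raw by default with `α = 0.05` (a Bonferroni option across groups is
exposed but off), matching the convention of flagging families at raw
p < 0.05. Compounds with no active call report p = 1 everywhere.

## 5. Evaluation protocol

* **Folds** are stratified by label and seed-controlled; each fold retrains
  the encoder *and* the booster on the training split only, so held-out
  molecules never influence the learned features (the per-fold hash of
  training compounds is stored and asserted in tests).
* **Metrics**: MCC, F1, BA, precision, recall from the fold confusion
  counts; ROC AUC by the midrank Mann–Whitney formula. Any metric with a
  zero denominator is `NA` ("undefined"), never silently 0.
* **Summaries** are reported as mean ± sd across folds; with several targets
  per family, sd across targets within a family is available from the
  per-target table — both views are emitted since either convention is
  common.
* **Multi-target validation** pools (compound, target) pairs with known
  labels over compounds having ≥ 2 known active targets, excludes unknown
  labels from every count, and reports TPR, NPV, FDR. Pairs are pooled (not
  averaged per compound); the pooled choice weights compounds by their
  evidence.
* **External test split**: `train_test_split()` defaults to a stratified
  80/20 with a declared seed.

## 6. The synthetic benchmark

`generate_dataset()` assembles drug-like SMILES from a valence-safe fragment
grammar (alkyl chains, branched carbons, benzene/phenylene units) and plants
one substructure motif per target: amide, ester, sulfonamide, nitrile,
aromatic nitrogen. The label is active iff the final molecule matches the
motif's SMARTS pattern — matching is done on the assembled molecule, so the
label is honest even if fragments interact — then flipped with probability
`label_noise` (default 0.1). Potency values are drawn consistently with the
final label on either side of 10 µM. Inner fragments are deliberately free
of N/O heteroatoms and each motif is followed by a carbon spacer, so no
motif can arise or be destroyed by fragment adjacency; achieved prevalence
therefore tracks `active_fraction` (0.5) to binomial accuracy. Motifs are
planted independently per target, so multi-target actives occur naturally;
`make_multilabel_fixture()` additionally controls the overlap rate directly
and masks a fraction of labels as unknown (always leaving two known active
labels on multi-target actives, so the pooled-validation eligibility set
cannot be silently emptied by masking).

All motifs are detectable within 3 bond hops — matched to the default
`T = 3` so that passing the benchmark demonstrates the architecture can
represent its receptive field, not that it can exceed it.

**What passing does and does not show.** The benchmark exercises every
pipeline stage — parsing, featurization, propagation, training dynamics,
classification, assembly, the statistics — under a *known* ground truth. It
does not emulate real chemistry: chemical space coverage is narrow, the
structure–activity rule is a single substructure rather than a
pharmacophore, prevalences are balanced rather than skewed, and assay noise
is label-flip rather than potency-dependent. Scores on it say nothing
quantitative about performance on curated bioactivity extractions; published
panel-scale numbers depend on datasets that are not redistributable, which
is why acceptance here is property-based at desk scale (1,000 molecules,
five targets, five-fold CV over five seeds) rather than a reproduction of
panel values.

## 7. Numerical choices and degenerate inputs

* Glorot-uniform initialization; Adam with β₁ = 0.9, β₂ = 0.999, ε = 1e-8.
* A non-finite training loss aborts with the epoch and learning rate named.
* Single-atom molecules (no bonds) are legal: messages are zero, the DMPNN
  edge set is empty, and atom states reduce to functions of the atom's own
  features.
* Single-class training sets, unparseable SMILES, conflicting labels,
  feature-dimension mismatches, and inconsistent hypergeometric counts are
  all hard errors, never silent repairs; batch parsing records per-molecule
  failures and continues.
* Embeddings are computed in inference mode (dropout off) in chunks of 256
  molecules; values are independent of chunking, and invariance of
  embeddings to atom relabelling holds to 1e-6 (floating-point summation
  order is the only source of discrepancy).
* Ties in ROC scores are handled by midranks (ties count one half).

## 8. Known limitations

* Hybridization/conjugation are rule-based (section 2), and stereochemistry
  is ignored entirely.
* The grammar-based generator cannot stand in for real chemical diversity;
  see section 6.
* Encoder training is CPU-oriented; panel-scale datasets (tens of thousands
  of molecules, dozens of targets) are feasible but slow in this
  implementation — the design premium is on auditability (analytic
  gradients, finite-difference tests) rather than throughput.
* The hypergeometric test treats per-target calls as exchangeable draws; it
  ignores correlation between related targets within a family, so its
  p-values are enrichment scores, not calibrated error rates.
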