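# epitarget

Multi-target bioactivity prediction for epigenetic drug discovery: graph
neural network molecular features + gradient-boosted classification, with a
hypergeometric polypharmacology test.

## The problem

Epigenetic cancer therapy increasingly looks for compounds that inhibit
*several* chromatin-modifying proteins at once — histone deacetylases (HDAC),
histone methyltransferases (HMT) and demethylases (HDM), histone
acetyltransferases (HAT), and DNA methyltransferases (DNMT). Screening a
molecule against dozens of such targets experimentally is slow and expensive,
so ligand-based models that predict a compound's full activity profile from
its structure alone are a practical first filter. `epitarget` is aimed at
computational chemists and method developers who want that pipeline as a
tested, scriptable R package.

## The method

1. **Quantized molecular graphs.** A SMILES string is parsed (OpenBabel via
   ChemmineR/ChemmineOB) into a graph of heavy atoms with per-atom features
   (element, degree, formal charge, implicit H count, aromaticity,
   hybridization, ring membership) and per-bond features (order, conjugation,
   ring flag). Each chemical bond contributes two directed edges.

2. **Message-passing encoders.** Node states are updated for `T` steps as

   `h_i^t = U(h_i^{t-1}, m_i^t)`,

   where `m_i^t` aggregates the states of `i`'s neighbors. Three update rules
   are implemented from scratch (forward and analytic backward passes,
   trained with Adam under binary cross-entropy):

   * **GCN** — `U = ReLU(W_self h + W_msg m + b)`;
   * **GGNN** — `U` is a gated recurrent unit driven by the message;
   * **DMPNN** — hidden states live on *directed bonds*; the message into
     bond `v→w` sums incoming bonds `k→v` *excluding the reverse* `w→v`, with
     a skip connection to the initial bond state.

   An order-invariant readout (sum/mean over atoms) gives the molecule
   embedding; the penultimate vector (before the logistic head) is the
   learned feature representation.

3. **Boosted classification.** Per target, the embeddings feed a gradient
   boosted tree ensemble (xgboost) minimizing logistic loss plus the per-tree
   penalty `Σ_k Ω(f_k)`. A Morgan/ECFP4 fingerprint baseline runs through the
   identical protocol for comparison.

4. **Multi-target assembly + polypharmacology.** The per-target classifiers
   are combined into one multi-target predictor (assembly adds no coupling).
   For each compound, enrichment of predicted-active targets inside a protein
   family is scored with the exact upper-tail hypergeometric probability

   `P(X ≥ k) = Σ_{j≥k} C(K,j) C(N−K, n−j) / C(N,n)`

   (`N` registered targets, `K` in the family, `n` predicted active, `k` of
   them in the family); families with `p < 0.05` are flagged.

5. **Evaluation.** Stratified five-fold cross-validation with per-fold
   encoder retraining (no leakage), imbalance-aware metrics (MCC, F1,
   balanced accuracy, precision/recall, ROC AUC), and a pooled multi-target
   protocol (TPR / NPV / FDR over (compound, target) pairs with known labels,
   restricted to compounds with ≥ 2 known active targets).

Because the public bioactivity extractions behind the original study are not
shipped anywhere, the package includes a synthetic-data module that plants
substructure activity rules (amide, ester, sulfonamide, nitrile, aromatic-N
motifs) into valence-safe generated SMILES — every stage of the pipeline is
testable offline, end to end.

## Worked example

```r
library(epitarget)
library(dplyr)

# a 2-target dataset with planted motifs (amide -> T1, ester -> T2)
ds <- generate_dataset(synth_spec(n_molecules = 300, label_noise = 0.05,
                                  targets = list(T1 = "amide", T2 = "ester"),
                                  seed = 7))

# cross-validated performance of the DMPNN pipeline on target T1
d1 <- filter(ds$records, target_id == "T1")
cv <- crossvalidate(d1,
                    encoder_config("dmpnn", hidden_dim = 32, epochs = 15, seed = 1),
                    booster_config(seed = 1), n_folds = 5, seed = 1)
print(cv)
#> <epi_cv> 5 folds | featurizer: DMPNN
#>   mcc       0.741 +/- 0.135
#>   f1        0.858 +/- 0.073
#>   ba        0.866 +/- 0.069
#>   precision 0.880 +/- 0.090
#>   recall    0.848 +/- 0.121
#>   auc       0.932 +/- 0.027
```

Held-out MCC ≈ 0.74 and AUC ≈ 0.93 say the encoder recovered the planted
amide rule well despite the 5% label noise (which alone caps achievable
accuracy near 0.95 on 300 molecules); balanced accuracy ≈ 0.87 means both
classes are predicted well, not just the majority one.

```r
# assemble the multi-target model and profile new molecules
mt <- fit_multitarget(ds$records, ds$registry,
                      encoder_config("dmpnn", hidden_dim = 32, epochs = 15),
                      booster_config())
polypharmacology_report(mt, tibble::tibble(
  compound_id = "query1", smiles = "CCC(=O)NCCCC(=O)OC")) |> print()
#> # A tibble: 2 × 8
#>   compound_id object_group     k     K     n     N p_value significant
#>   <chr>       <chr>        <int> <int> <int> <int>   <dbl> <lgl>
#> 1 query1      HDAC             1     1     2     2       1 FALSE
#> 2 query1      HMT              1     1     2     2       1 FALSE
```

The query contains both motifs, so both targets are called active (`k = 1`
in each single-target family, `n = 2` calls overall). With only `N = 2`
registered targets the hypergeometric tail is 1 — family enrichment only
becomes informative on larger panels, e.g. a compound hitting all 10 HDAC
targets of a 24-target registry scores
`hypergeom_pvalue(24, 10, 10, 10)` ≈ 5.1e-7.

`tidy()`, `glance()`, and `autoplot()` methods are available for fitted
models, cross-validation results, and polypharmacology reports; a thin
command-line wrapper lives in `inst/cli/epitarget.R`
(`synth / featurize / train / evaluate / predict / polypharm`).

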