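# mgdta

Drug–target binding affinity (DTA) prediction from multi-scale graph
representations, in pure R.

Virtual screening needs fast, accurate estimates of how strongly a small
molecule binds a protein. `mgdta` frames this as regression of a continuous
affinity label (pKd for Davis-style data, KIBA scores otherwise) from three
graph views of a drug–protein pair:

* a **drug atom-level graph** — heavy atoms as nodes (78-dim one-hot
  descriptors: symbol, degree, hydrogen count, implicit valence, aromatic
  flag), chemical bonds as edges;
* a **drug motif-level graph** — perceived rings and non-ring bonds (with
  their atom pairs) as coarse nodes (92-dim descriptors), adjacent when they
  share atoms, so ring systems enter the model as units rather than as bags
  of atoms;
* a **weighted protein graph** — residues as nodes (33-dim physicochemical
  descriptors), with an edge wherever a predicted residue–residue contact
  probability reaches 0.5, weighted by that probability. Sequences longer
  than the contact predictor's context are handled by predicting overlapping
  windows (width 1000, step 500) and splicing them along the diagonal,
  averaging doubly covered cells.

Each graph is encoded by three graph-convolution layers (GCN, or GAT with
softmax neighbourhood attention) sized N → 4N → 4N → 4N. A **gated
skip-connection**

    z = σ(U₁ H⁽ˡ⁺¹⁾ + U₂ H⁽ˡ⁾ + b),   H ← z ⊙ H⁽ˡ⁺¹⁾ + (1 − z) ⊙ H⁽ˡ⁾

interpolates each hidden layer with its predecessor so depth does not wash
out early-scale features. Max (or mean) pooling and two fully connected
stages give one 128-dim embedding per branch. The three embeddings Z_d,
Z_m, Z_p are fused by a softmax **attention** over shared-parameter scores
w_i = W₂·tanh(W₁ Z_i),

    α = softmax(w_d, w_m, w_p),   Z_c = [α_d Z_d ‖ α_m Z_m ‖ α_p Z_p],

and a 384 → 1024 → 512 → 1 head predicts the affinity. Training minimises
MSE with Adam; evaluation reports MSE, concordance index (CI), Pearson r
and rm². Ablation switches reproduce the no-attention, no-motif and no-skip
variants.

All of this — including backpropagation through the GNNs, gate, attention
fusion and head — is implemented in base R + Matrix, with the chemistry
(SMILES parsing, ring perception) delegated to ChemmineR/OpenBabel. A
seeded synthetic generator produces valid fragment-assembled SMILES, random
sequences, deterministic stub contact predictors and affinity labels with a
known dependence on graph-visible features, so the whole pipeline is
testable offline; the real contact predictor (e.g. a protein language
model) plugs in through a one-function contract.

## Worked example

```r
library(mgdta)

# a self-contained synthetic benchmark: 64 drug-protein pairs whose
# affinity is a known function of ring count, sequence length and a
# drug-protein composition statistic, plus N(0, 0.1) noise
cfg   <- synthetic_config(seq_len_range = c(40, 120), noise_sd = 0.1,
                          seed = 5)
ds    <- gen_dataset(cfg)
store <- prepare_graphs(ds$records)          # graphs built once per entity

split <- make_split(nrow(ds$records), n_parts = 6, seed = 5)
idx   <- split_indices(split)                # part 1 held out

model <- dta_model(conv = "gcn", pooling = "max", seed = 5)
fit   <- fit_dta(model, ds$records[idx$train, ], store,
                 epochs = 200, lr = 0.01, seed = 5)

ev <- evaluate_dta(fit$model, ds$records[idx$test, ], store)
str(ev$metrics)
#> List of 4
#>  $ mse    : num 0.0157
#>  $ ci     : num 0.927
#>  $ rm2    : num 0.934
#>  $ pearson: num 0.987
```

Held-out MSE 0.016 is close to the injected noise floor (σ² = 0.01 plus
model error), CI 0.93 means 93% of affinity-ordered test pairs are ranked
correctly, and Pearson r 0.99 confirms the recovered signal; a label
permutation control sits at CI ≈ 0.5. Single pairs go through
`predict_dta(model, smiles, sequence)`; `cmd_synth` / `cmd_prepare` /
`cmd_train` / `cmd_evaluate` / `cmd_predict` (and the
`inst/scripts/dta.R` dispatcher) wire the same steps into shell runs.

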