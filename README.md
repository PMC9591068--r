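# dticross

Interpretable cross-attention networks for drug-target interaction (DTI)
prediction, in pure R.

A drug (SMILES string) and a target protein (amino-acid sequence) are
tokenised, embedded, and passed through a multi-head cross-attention encoder
in which protein positions attend over drug positions (and/or vice versa); a
1D-CNN head turns the attended context into an interaction probability. The
attention weights are not discarded: they are expanded to residue-by-atom
resolution and tested against annotated binding sites with a permutation
z-score, so the model's predictions come with a statistical statement about
*where* it looked.

## Features

* **Tokenisation** — character, SELFIES (built-in encoder/decoder with
  robustness guarantees) and frequent-consecutive-subsequence (byte-pair
  style) vocabularies mined from the training corpus with deterministic
  tie-breaking.
* **Model** — seven architectures (`CA_DP`, `CA2_DP`, `CA3_DP`, `CA_DP_FCL`,
  `SA_DP`, `CA_D`, `CA_P`) built from masked multi-head cross/self-attention
  with residual contexts, CNN or fully connected output heads, trained with
  mini-batch Adam; gradients are analytic and verified against finite
  differences.
* **Protocol** — 7:1:2 positive split with training-negative balancing,
  validation-PRAUC checkpointing, six evaluation metrics (SN, SP, PR, F1,
  ROCAUC, PRAUC) and multi-seed averaging.
* **Interpretability** — top-k attention sites, consistency numbers against
  binding annotations, 10,000-iteration permutation null with closed-form
  mean `k*b/L`, z-scores, top-k sensitivity sweeps and residue-shift curves.
* **Synthetic benchmark** — planted-motif generator with validity-checked
  SMILES and ground-truth binding sites, so every stage is testable offline.
* **I/O + CLI** — delimited DTI tables, binding-site annotations, FASTA
  joins, YAML run configurations, JSON metric reports, and an `Rscript` CLI
  (`simulate` / `mine-vocab` / `train` / `evaluate` / `predict` /
  `interpret`).

## Quick start

```r
library(dticross)

# a fully controlled benchmark: positives carry a planted protein motif
# AND a reactive drug substructure; motif positions are the binding sites
spec <- synthetic_spec(n_pairs = 2000L, rho = 0.05)
ds <- split_dataset(synthetic_dataset(spec, seed = 1L), seed = 1L)

ck <- train_dti(ds, arch = "CA_P", scheme = "smiles_embed",
                max_len_drug = 50L, max_len_protein = 120L,
                hidden = 96L, heads = 4L, epochs = 10L, batch_size = 32L,
                seed = 1L)

evaluate_dti(ck, ds, split = "test")
#>        SN        SP        PR        F1    ROCAUC     PRAUC
#> 0.9313725 0.9195402 0.9313725 0.9313725 0.9412046 0.9280864

rows <- which(ds$split == "test" & ds$label == 1 & !is.na(ds$binding_sites))
attention_site_analysis(ck, ds, rows = rows, k = 30L,
                        iterations = 10000L, seed = 1L)
#> <attention_analysis> 194 DTIs, top-30 sites
#>   observed consistency 5.335 | null 2.423 (sd 0.139) | z = 20.969
```

The z-score compares the observed mean consistency (top-30 attention sites
falling on true binding residues) to a null in which binding sites are placed
uniformly at random; values far above 2 mean the attention is genuinely
localised on the planted motif.

See the vignette (`vignettes/attention-dti.Rmd`) for the methods and design
decisions, and `scripts/acceptance.R` for the end-to-end reproduction script:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
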