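---
title: "Interpretable cross-attention for drug-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable cross-attention for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dticross` predicts whether a drug (a SMILES string) interacts with a target
protein (an amino-acid sequence) and, unlike a plain black-box classifier,
reports *where* the model looked: its cross-attention weights are expanded to
residue-by-atom resolution and tested statistically against annotated binding
sites. This vignette walks through the methods and the design decisions
behind each module.

## Tokenisation and encoding

Both molecule and protein strings are turned into token sequences in one of
five schemes:

* `smiles_embed` / `smiles_onehot` — character-level SMILES tokens with
  learned embeddings or one-hot rows; proteins use the 20 amino-acid letters.
* `selfies_embed` — SMILES are converted to SELFIES, a molecular string
  language in which *every* token string decodes to a valid molecule. The
  package includes its own encoder/decoder pair over a bracketed token
  alphabet; decoding is robust by construction (tested on random token
  streams).
* `fcs_embed` / `fcs_onehot` — frequent consecutive subsequences, a byte-pair
  style vocabulary mined from the training corpus by repeatedly merging the
  most frequent adjacent token pair (`fcs_mine()`). Ties are broken
  deterministically (lexicographic on the fused token, then on the pair) so
  mining is reproducible across platforms. The miner operates on a single
  integer-coded corpus with sentinel-separated sequences and updates pair
  counts incrementally around each merge, which makes mining on thousands of
  proteins take seconds instead of minutes; a naive full-recount reference
  implementation in the test suite guarantees the two produce identical
  vocabularies and segmentations.

Sequences are label-encoded to fixed lengths (defaults: 50 drug tokens, 545
protein tokens), padded with a PAD id whose embedding rows are zero and which
is excluded from attention through key masks. Token spans (start/width in the
original string) are carried along for later interpretation.

## Cross-attention model

Queries come from one molecule and keys/values from the other. With
embeddings $X_q, X_k$, projections $Q = X_q W_q$, $K = X_k W_k$,
$V = X_k W_v$, each of $h$ heads computes
$\mathrm{softmax}(Q_i K_i^\top / \sqrt{d})\, V_i$ over the non-PAD key
positions, the concatenated heads are projected by $W_0$, and the context is
the residual sum $C = Q + \mathrm{Multihead}\, W_0$. Seven architectures are
available: `CA_DP` (both directions, contexts stacked), deeper `CA2_DP` /
`CA3_DP` stacks, `CA_DP_FCL` (fully connected head), `SA_DP`
(self-attention), and the single-sided `CA_D` and `CA_P`. The default,
`CA_P`, attends protein queries over drug keys and feeds the protein context
into a two-layer 1D convolutional head (conv-ReLU-maxpool twice, then a
linear sigmoid unit).

The network and its backward pass are written directly against BLAS matrix
products: batches are stacked sample-major into $(B \cdot L) \times d$
matrices, and softmax/attention gradients are computed analytically. Training
uses mini-batch Adam on binary cross-entropy; every gradient path is verified
against central finite differences in the test suite. One subtlety worth
recording: with zero PAD embeddings and zero initial biases, convolution
outputs sit exactly on the ReLU kink where one-sided derivatives differ, so
gradient tests offset the head biases slightly.

## Data protocol and evaluation

`split_dataset()` partitions positives 7:1:2 into train/validation/test
(floor for validation and test, remainder to train), then down-samples
training negatives to exactly the training positive count; leftover negatives
go to validation and test in the 1:2 ratio, so test sets keep their natural
negative skew. `train_dti()` keeps the parameters of the epoch with the best
validation PRAUC. `evaluate_dti()` reports six metrics — sensitivity,
specificity, precision, F1, ROCAUC and PRAUC — with PRAUC computed as average
precision (step interpolation), the appropriate summary under class
imbalance. All metrics are cross-checked in the tests against a confusion
oracle, a Mann-Whitney ROCAUC and `pROC`. `multi_run()` averages metrics over
independent training seeds.

## Attention-site interpretability

For each test interaction with annotated binding residues:

1. the head-averaged protein-by-drug token attention matrix is expanded to a
   residue-by-atom map by broadcasting each weight over its tokens' character
   spans (`expand_attention()`);
2. the top-$k$ cells (default $k = 30$; ties broken by ascending residue then
   atom) are the model's claimed interaction sites (`top_sites()`);
3. the *consistency number* counts how many of those sites lie on annotated
   binding residues (`consistency_number()`).

Significance is judged against a permutation null (`null_profile()`): in each
of 10,000 iterations, every protein's binding set is re-placed uniformly at
random (same set size, same protein length), and the mean consistency over
proteins is recorded. Because a fresh binding set is drawn in *every*
iteration for *every* protein, the null mean has the closed form
$\mathbb{E}[c] = k \cdot b / L$ for a protein of length $L$ with $b$ binding
residues — a property the tests verify both against Monte-Carlo standard
errors and by exact enumeration of all $\binom{L}{b}$ subsets for short
proteins. The observed mean is standardised as
$z = (\bar{c}_{obs} - \mu_{null}) / \sigma_{null}$; for example an observed
mean of 2.020 against a null of 1.64 (sd 0.119) gives $z \approx 3.19$.
`topk_sensitivity()` sweeps $k$ and `shift_analysis()` offsets the claimed
sites by up to two residues (rebuilding the null per shift, since boundary
drops change the site tables) to show the signal is positionally specific.

## Synthetic planted-motif benchmark

`synthetic_dataset()` generates a fully controlled benchmark: a pair is
rule-positive when the protein carries a planted 8-residue motif *and* the
drug carries a reactive substructure (isocyanate, `N=C=O`). Rule-negatives
miss the protein motif, the drug motif, or both — uniformly over the three
cases — so neither motif alone predicts the label. Labels are flipped with
probability `rho` to emulate assay noise, and the planted motif positions are
recorded as binding-site annotations. Drugs are assembled from a curated list
of 50 small valid SMILES whose last atom has free valence, extended by
concatenation-safe fragments; every generated SMILES is validity-checked.
Class balance is controlled by an `imbalance` (negative:positive) ratio.

## Signal-recovery configuration

The end-to-end acceptance experiment (2,000 pairs, `rho = 0.05`) trains the
default `CA_P` architecture and requires test ROCAUC $\ge 0.9$ plus
interpretability $z > 2$ within a ten-minute single-CPU budget. Two scaling
decisions, both made from *timing* measurements before any accuracy
thresholds were evaluated, make that budget feasible in pure R: the hidden
dimension is reduced from 384 to 96 (at 384 a single epoch alone exceeds the
budget), and the protein length cap is 120 (the generator's maximum protein
is 120 residues, so nothing is truncated). The character-level
`smiles_embed` scheme is used because subsequence mining on *random* synthetic
proteins fragments the planted motif into rare fused tokens; batch size 32
gives enough optimisation steps in ten epochs. Measured across seeds, the
configuration reaches test ROCAUC 0.93-0.96 and $z \approx 21$ in under
three minutes.

```{r}
library(dticross)
spec <- synthetic_spec(n_pairs = 2000L, rho = 0.05)
ds <- split_dataset(synthetic_dataset(spec, seed = 1L), seed = 1L)
ck <- train_dti(ds, arch = "CA_P", scheme = "smiles_embed",
                max_len_drug = 50L, max_len_protein = 120L,
                hidden = 96L, heads = 4L, epochs = 10L, batch_size = 32L,
                seed = 1L)
evaluate_dti(ck, ds, split = "test")
rows <- which(ds$split == "test" & ds$label == 1 & !is.na(ds$binding_sites))
attention_site_analysis(ck, ds, rows = rows, k = 30L,
                        iterations = 10000L, seed = 1L)
```

## Command line

The same pipeline is scriptable through the installed CLI
(`system.file("cli", "dticross.R", package = "dticross")`):

```sh
Rscript dticross.R simulate  --out data.tsv --n-pairs 2000 --rho 0.05 --seed 1
Rscript dticross.R train     --data data.tsv --out ck.rds --scheme smiles_embed \
                             --hidden 96 --epochs 10 --batch-size 32 \
                             --max-len-protein 120 --seed 1
Rscript dticross.R evaluate  --checkpoint ck.rds --data data.tsv --out metrics.json
Rscript dticross.R interpret --checkpoint ck.rds --data data.tsv --out interp.json
```

Every command writes a `.log` sidecar recording the command, configuration,
seed and package version.
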