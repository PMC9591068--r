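# Multi-head scaled dot-product attention: cross- and self-attention with a
# residual context output. Heads are column blocks of combined projection
# matrices, so concat(Q_1..Q_h) is simply the full-width query matrix; the
# context is C = Q + concat(head_1..head_h) %*% W0.

#' Create multi-head projection parameters
#'
#' Weight matrices for one attention direction. Heads share a combined matrix
#' (`input_dim x hidden`) whose column blocks are the per-head projections;
#' `W0` is square (`hidden x hidden`). Initialisation is uniform scaled by the
#' input dimension.
#'
#' @param input_dim_q Feature width of the query-side embedding.
#' @param input_dim_kv Feature width of the key/value-side embedding.
#' @param hidden Model hidden size `h * d` (default 384).
#' @param heads Head count `h` (default 4).
#' @return List of class `attn_params` with `Wq`, `Wk`, `Wv`, `W0`, `heads`,
#'   `d` (per-head column dimension).
#' @export
attention_params <- function(input_dim_q, input_dim_kv = input_dim_q,
                             hidden = 384L, heads = 4L) {
  stopifnot(heads >= 1L, hidden %% heads == 0L)
  init <- function(nr, nc) matrix(stats::runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
  structure(list(
    Wq = init(input_dim_q, hidden), Wk = init(input_dim_kv, hidden),
    Wv = init(input_dim_kv, hidden), W0 = init(hidden, hidden),
    heads = as.integer(heads), d = as.integer(hidden / heads)
  ), class = "attn_params")
}

head_cols <- function(params, i) ((i - 1L) * params$d + 1L):(i * params$d)

#' Project an embedding matrix into per-head query/key/value matrices
#'
#' @param embedding Numeric matrix (rows = token positions).
#' @param params An `attn_params` object.
#' @param role `"Q"`, `"K"` or `"V"`.
#' @return List of `heads` matrices, each `nrow(embedding) x d`.
#' @export
project_heads <- function(embedding, params, role = c("Q", "K", "V")) {
  role <- match.arg(role)
  W <- params[[paste0("W", tolower(role))]]
  if (ncol(embedding) != nrow(W)) stop("embedding width does not match projection")
  full <- embedding %*% W
  lapply(seq_len(params$heads), function(i) full[, head_cols(params, i), drop = FALSE])
}

#' Scaled dot-product attention weights for one head
#'
#' Row-wise softmax of `Q K' / sqrt(d)` (or `/ d` when `scale = "d"`), with
#' masked key positions excluded via additive `-Inf` before the softmax.
#'
#' @param Qi Query matrix (`n_q x d`).
#' @param Ki Key matrix (`n_k x d`).
#' @param d Per-head column dimension used in the scaling.
#' @param key_mask Logical vector of length `n_k`; `FALSE` keys are excluded.
#' @param scale `"sqrt_d"` (default) or `"d"`.
#' @return Row-stochastic `n_q x n_k` matrix.
#' @export
attention_weights <- function(Qi, Ki, d = ncol(Qi), key_mask = NULL,
                              scale = c("sqrt_d", "d")) {
  scale <- match.arg(scale)
  if (ncol(Qi) != ncol(Ki)) stop("query/key dimension mismatch")
  denom <- if (scale == "sqrt_d") sqrt(d) else d
  S <- tcrossprod(Qi, Ki) / denom
  if (!is.null(key_mask)) {
    if (!any(key_mask)) stop("no attendable positions")
    S[, !key_mask] <- -Inf
  }
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Apply attention weights to a value matrix
#'
#' @param weights Attention weight matrix (`n_q x n_k`).
#' @param Vi Value matrix (`n_k x d`).
#' @return Head matrix `n_q x d`.
#' @export
attend <- function(weights, Vi) {
  if (ncol(weights) != nrow(Vi)) stop("weights/value shape mismatch")
  weights %*% Vi
}

attention_forward <- function(query_emb, kv_emb, params, scale = "sqrt_d",
                              mask_keys = TRUE) {
  qmask <- attr(query_emb, "mask")
  kmask <- attr(kv_emb, "mask")
  Q <- project_heads(query_emb, params, "Q")
  K <- project_heads(kv_emb, params, "K")
  V <- project_heads(kv_emb, params, "V")
  km <- if (mask_keys && !is.null(kmask)) kmask else NULL
  weights <- lapply(seq_len(params$heads), function(i) {
    attention_weights(Q[[i]], K[[i]], params$d, key_mask = km, scale = scale)
  })
  heads <- lapply(seq_len(params$heads), function(i) attend(weights[[i]], V[[i]]))
  H <- do.call(cbind, heads)
  Qfull <- do.call(cbind, Q)
  context <- Qfull + H %*% params$W0
  if (!is.null(qmask)) context[!qmask, ] <- 0
  structure(list(weights = weights, heads = heads, context = context,
                 query_mask = qmask, key_mask = kmask),
            class = "attention_bundle")
}

#' Cross-attention context of one entity conditioned on the other
#'
#' Queries come from `query_emb`, keys and values from `kv_emb`. The context
#' is the residual sum of the concatenated per-head queries and the projected
#' multi-head output. With protein queries against drug keys/values this is
#' the drug-conditioned protein context `C^P`; swapping roles gives `C^D`.
#'
#' @param query_emb,kv_emb Embedding matrices (optionally carrying a `mask`
#'   attribute marking real rows).
#' @param params An `attn_params` object.
#' @param scale Softmax scaling, `"sqrt_d"` (default) or `"d"`.
#' @param mask_keys Exclude PAD key positions from the softmax (default TRUE).
#' @return An `attention_bundle`: per-head `weights` and `heads`, the
#'   `context` matrix (query rows x hidden), and the masks used.
#' @export
cross_context <- function(query_emb, kv_emb, params, scale = "sqrt_d",
                          mask_keys = TRUE) {
  attention_forward(query_emb, kv_emb, params, scale, mask_keys)
}

#' Self-attention context
#'
#' Equivalent to [cross_context()] with query, key and value all drawn from
#' the same embedding.
#'
#' @inheritParams cross_context
#' @param emb Embedding matrix.
#' @return An `attention_bundle`.
#' @export
self_context <- function(emb, params, scale = "sqrt_d", mask_keys = TRUE) {
  attention_forward(emb, emb, params, scale, mask_keys)
}

#' Stack cross-attention layers
#'
#' Layer `k` consumes layer `k-1`'s context matrices as its embeddings: the
#' protein context becomes the protein-side input and the drug context the
#' drug-side input. Depth 1 is a single [cross_context()] pair.
#'
#' @param drug_emb,protein_emb Input embedding matrices (with `mask`
#'   attributes).
#' @param layer_params List of per-layer parameter pairs, each a list with
#'   elements `P` (protein-query direction) and `D` (drug-query direction) of
#'   class `attn_params`.
#' @param scale,mask_keys Passed to each layer.
#' @return List with `P` and `D` attention bundles of the final layer.
#' @export
stack_layers <- function(drug_emb, protein_emb, layer_params,
                         scale = "sqrt_d", mask_keys = TRUE) {
  depth <- length(layer_params)
  if (!depth %in% 1:3) stop("unsupported depth: ", depth)
  xd <- drug_emb; xp <- protein_emb
  bundleP <- bundleD <- NULL
  for (k in seq_len(depth)) {
    bundleP <- cross_context(xp, xd, layer_params[[k]]$P, scale, mask_keys)
    bundleD <- cross_context(xd, xp, layer_params[[k]]$D, scale, mask_keys)
    new_xp <- structure(bundleP$context, mask = attr(protein_emb, "mask"))
    new_xd <- structure(bundleD$context, mask = attr(drug_emb, "mask"))
    xp <- new_xp; xd <- new_xd
  }
  list(P = bundleP, D = bundleD)
}
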