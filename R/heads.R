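# Output heads: decode a context matrix into a DTI probability.
# The CNN head slides 1D convolutions along the sequence axis with features as
# channels; the FCL head is a two-layer perceptron on the flattened context.
# Dropout is active only during training (the batched trainer); these
# reference implementations run at inference, so dropout layers are identity.

conv_out_len <- function(L, kernel) L - kernel + 1L
pool_out_len <- function(L, pool) L %/% pool

#' Default CNN head parameters
#'
#' Two 1D convolution blocks (conv, ReLU, max-pool, dropout) and a final
#' linear layer with sigmoid. Channel sizes 384 -> 64 -> 32, kernel width 3,
#' pool width 2, dropout 0.1; all configurable and not taken from any
#' reference network.
#'
#' @param context_len Number of context rows the head will consume.
#' @param in_channels Context feature width (default 384).
#' @param channels Two conv output channel sizes.
#' @param kernel Convolution kernel width.
#' @param pool Max-pool width (= stride).
#' @param dropout Dropout rate used during training.
#' @return List of class `cnn_head_params`.
#' @export
cnn_head_params <- function(context_len, in_channels = 384L,
                            channels = c(64L, 32L), kernel = 3L, pool = 2L,
                            dropout = 0.1) {
  init <- function(nr, nc) matrix(stats::runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
  L1 <- pool_out_len(conv_out_len(context_len, kernel), pool)
  L2 <- pool_out_len(conv_out_len(L1, kernel), pool)
  if (L2 < 1L) stop("context too short for the CNN head configuration")
  structure(list(
    W1 = init(kernel * in_channels, channels[1L]), b1 = numeric(channels[1L]),
    W2 = init(kernel * channels[1L], channels[2L]), b2 = numeric(channels[2L]),
    Wl = init(L2 * channels[2L], 1L), bl = 0,
    kernel = as.integer(kernel), pool = as.integer(pool), dropout = dropout,
    context_len = as.integer(context_len), in_channels = as.integer(in_channels),
    channels = as.integer(channels)
  ), class = "cnn_head_params")
}

#' Default fully-connected head parameters
#'
#' Two linear+ReLU(+dropout) blocks on the flattened context followed by a
#' linear layer with sigmoid. Hidden sizes default to 64 and 32.
#'
#' @inheritParams cnn_head_params
#' @param hidden Two hidden layer sizes.
#' @return List of class `fcl_head_params`.
#' @export
fcl_head_params <- function(context_len, in_channels = 384L,
                            hidden = c(64L, 32L), dropout = 0.1) {
  init <- function(nr, nc) matrix(stats::runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
  flat <- context_len * in_channels
  structure(list(
    W1 = init(flat, hidden[1L]), b1 = numeric(hidden[1L]),
    W2 = init(hidden[1L], hidden[2L]), b2 = numeric(hidden[2L]),
    Wl = init(hidden[2L], 1L), bl = 0,
    dropout = dropout, context_len = as.integer(context_len),
    in_channels = as.integer(in_channels), hidden = as.integer(hidden)
  ), class = "fcl_head_params")
}

#' Select and combine context matrices for the output head
#'
#' @param bundleP Protein-context `attention_bundle` (or `NULL`).
#' @param bundleD Drug-context `attention_bundle` (or `NULL`).
#' @param selection `"dp"` (drug rows stacked above protein rows), `"d"`, or
#'   `"p"`.
#' @return Context matrix for the head.
#' @export
select_context <- function(bundleP, bundleD, selection = c("dp", "d", "p")) {
  selection <- match.arg(selection)
  ctx_of <- function(b, what) {
    if (is.null(b)) stop("missing ", what, " context bundle for selection")
    b$context
  }
  switch(selection,
    dp = rbind(ctx_of(bundleD, "drug"), ctx_of(bundleP, "protein")),
    d = ctx_of(bundleD, "drug"),
    p = ctx_of(bundleP, "protein")
  )
}

# valid-convolution unfold: row t of the result is rows t..t+k-1 concatenated
unfold_rows <- function(X, kernel) {
  L <- nrow(X)
  n_out <- conv_out_len(L, kernel)
  do.call(cbind, lapply(seq_len(kernel) - 1L, function(off) {
    X[seq_len(n_out) + off, , drop = FALSE]
  }))
}

maxpool_rows <- function(X, pool) {
  n_out <- pool_out_len(nrow(X), pool)
  idx <- (seq_len(n_out) - 1L) * pool
  out <- X[idx + 1L, , drop = FALSE]
  for (j in 2:pool) out <- pmax(out, X[idx + j, , drop = FALSE])
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' CNN head: context matrix to interaction probability
#'
#' @param context Numeric context matrix (`context_len x in_channels`).
#' @param params A `cnn_head_params` object.
#' @return Probability scalar in (0, 1).
#' @export
cnn_head <- function(context, params) {
  stopifnot(inherits(params, "cnn_head_params"))
  if (nrow(context) != params$context_len || ncol(context) != params$in_channels)
    stop("context dimensions do not match the head configuration")
  z1 <- pmax(sweep(unfold_rows(context, params$kernel) %*% params$W1, 2L,
                   params$b1, "+"), 0)
  p1 <- maxpool_rows(z1, params$pool)
  z2 <- pmax(sweep(unfold_rows(p1, params$kernel) %*% params$W2, 2L,
                   params$b2, "+"), 0)
  p2 <- maxpool_rows(z2, params$pool)
  flat <- as.vector(t(p2))
  sigmoid(sum(flat * params$Wl) + params$bl)
}

#' Fully-connected head: flattened context to interaction probability
#'
#' @param context Numeric context matrix.
#' @param params An `fcl_head_params` object.
#' @return Probability scalar in (0, 1).
#' @export
fcl_head <- function(context, params) {
  stopifnot(inherits(params, "fcl_head_params"))
  flat <- as.vector(t(context))
  if (length(flat) != nrow(params$W1))
    stop("context dimensions do not match the head configuration")
  h1 <- pmax(drop(flat %*% params$W1) + params$b1, 0)
  h2 <- pmax(drop(h1 %*% params$W2) + params$b2, 0)
  sigmoid(sum(h2 * params$Wl) + params$bl)
}
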