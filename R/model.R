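# Batched trainable cross-attention model.
#
# The single-sample functions in attention.R and heads.R are the readable
# reference; this file implements the same computation over sample-major
# batched matrices ((batch * seq_len) x features) with hand-written
# backpropagation and an Adam optimizer. Agreement between the two paths is
# enforced by tests. Parameters live in a flat named list so the optimizer can
# walk them generically.

ARCHITECTURES <- c("CA_DP", "CA2_DP", "CA3_DP", "CA_DP_FCL", "SA_DP", "CA_D", "CA_P")

#' Architecture grid lookup
#'
#' @param name One of `CA_DP`, `CA2_DP`, `CA3_DP`, `CA_DP_FCL`, `SA_DP`,
#'   `CA_D`, `CA_P` (the default model).
#' @return List with `attn` ("cross"/"self"), `depth`, `context`
#'   ("dp"/"d"/"p"), `head` ("cnn"/"fcl").
#' @export
arch_spec <- function(name) {
  name <- match.arg(name, ARCHITECTURES)
  switch(name,
    CA_DP = list(attn = "cross", depth = 1L, context = "dp", head = "cnn"),
    CA2_DP = list(attn = "cross", depth = 2L, context = "dp", head = "cnn"),
    CA3_DP = list(attn = "cross", depth = 3L, context = "dp", head = "cnn"),
    CA_DP_FCL = list(attn = "cross", depth = 1L, context = "dp", head = "fcl"),
    SA_DP = list(attn = "self", depth = 1L, context = "dp", head = "cnn"),
    CA_D = list(attn = "cross", depth = 1L, context = "d", head = "cnn"),
    CA_P = list(attn = "cross", depth = 1L, context = "p", head = "cnn")
  )
}

need_directions <- function(spec) {
  if (spec$context == "dp" || spec$depth > 1L) c("P", "D")
  else if (spec$context == "p") "P" else "D"
}

uinit <- function(nr, nc) matrix(stats::runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)

#' Construct a DTI prediction model
#'
#' Builds embedding tables, per-layer attention projections and the output
#' head for one of the Table-2 style architectures. Weight initialisation
#' draws from the current RNG state; seed it for reproducibility.
#'
#' @param vocab_drug,vocab_protein `dti_vocab` objects for the two entities.
#' @param arch Architecture name (see [arch_spec()]); default `"CA_P"`.
#' @param scheme Encoding scheme name (see `ENCODING_SCHEMES`).
#' @param max_len_drug,max_len_protein Fixed sequence lengths (defaults 50 and
#'   545).
#' @param hidden Model hidden size (default 384).
#' @param heads Attention head count (default 4).
#' @param scale Attention scaling (`"sqrt_d"` or `"d"`).
#' @param mask_keys Exclude PAD keys from attention (default TRUE).
#' @param positional Add learned positional embeddings (default TRUE for
#'   learned-embedding schemes, FALSE for one-hot).
#' @param head_opts Optional list overriding head defaults (`channels`,
#'   `kernel`, `pool`, `dropout`, `hidden`).
#' @return An object of class `dti_model`.
#' @export
dti_model <- function(vocab_drug, vocab_protein, arch = "CA_P",
                      scheme = "fcs_embed", max_len_drug = 50L,
                      max_len_protein = 545L, hidden = 384L, heads = 4L,
                      scale = "sqrt_d", mask_keys = TRUE, positional = NULL,
                      head_opts = list()) {
  arch <- match.arg(arch, ARCHITECTURES)
  scheme <- match.arg(scheme, ENCODING_SCHEMES)
  spec <- arch_spec(arch)
  onehot <- grepl("onehot", scheme)
  if (is.null(positional)) positional <- !onehot
  wd <- if (onehot) vocab_size(vocab_drug) else hidden
  wp <- if (onehot) vocab_size(vocab_protein) else hidden
  params <- list()
  if (!onehot) {
    max_lab_d <- max(unname(vocab_drug$label_of))
    max_lab_p <- max(unname(vocab_protein$label_of))
    params[["emb.drug_tok"]] <- embedding_init(max_lab_d + 1L, hidden)
    params[["emb.prot_tok"]] <- embedding_init(max_lab_p + 1L, hidden)
    if (positional) {
      params[["emb.drug_pos"]] <- embedding_init(max_len_drug, hidden)
      params[["emb.prot_pos"]] <- embedding_init(max_len_protein, hidden)
    }
  }
  dirs <- need_directions(spec)
  for (k in seq_len(spec$depth)) {
    in_p <- if (k == 1L) wp else hidden
    in_d <- if (k == 1L) wd else hidden
    for (dir in dirs) {
      qw <- if (dir == "P") in_p else in_d
      kw <- if (spec$attn == "self") qw else if (dir == "P") in_d else in_p
      pre <- sprintf("L%d.%s.", k, dir)
      params[[paste0(pre, "Wq")]] <- uinit(qw, hidden)
      params[[paste0(pre, "Wk")]] <- uinit(kw, hidden)
      params[[paste0(pre, "Wv")]] <- uinit(kw, hidden)
      params[[paste0(pre, "W0")]] <- uinit(hidden, hidden)
    }
  }
  Lc <- switch(spec$context, dp = max_len_drug + max_len_protein,
               d = max_len_drug, p = max_len_protein)
  if (spec$head == "cnn") {
    hp <- do.call(cnn_head_params, c(list(context_len = Lc, in_channels = hidden),
                                     head_opts))
  } else {
    hp <- do.call(fcl_head_params, c(list(context_len = Lc, in_channels = hidden),
                                     head_opts))
  }
  for (nm in c("W1", "b1", "W2", "b2", "Wl", "bl")) params[[paste0("head.", nm)]] <- hp[[nm]]
  head_cfg <- hp[setdiff(names(hp), c("W1", "b1", "W2", "b2", "Wl", "bl"))]
  head_cfg$kind <- spec$head
  structure(list(
    arch = arch, spec = spec, scheme = scheme, onehot = onehot,
    positional = positional, scale = scale, mask_keys = mask_keys,
    dims = list(Ld = as.integer(max_len_drug), Lp = as.integer(max_len_protein),
                wd = wd, wp = wp, hidden = as.integer(hidden),
                heads = as.integer(heads), d = as.integer(hidden / heads)),
    params = params, head_cfg = head_cfg,
    vocab = list(drug = vocab_drug, protein = vocab_protein)
  ), class = "dti_model")
}

#' @export
print.dti_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<dti_model> %s (%s), hidden %d, heads %d, %s head, %d parameters\n",
              x$arch, x$scheme, x$dims$hidden, x$dims$heads, x$head_cfg$kind, np))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `dti_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, 0L))

#' Tokenize and label-encode a set of DTI samples for a model
#'
#' @param model A `dti_model`.
#' @param drug_smiles,protein_seqs Character vectors (parallel).
#' @return Encoding object with per-entity label matrices, true lengths and
#'   token character spans.
#' @export
model_encode <- function(model, drug_smiles, protein_seqs) {
  tk <- scheme_tokenizers(model$scheme)
  list(
    drug = encode_label_matrix(drug_smiles, model$vocab$drug, model$dims$Ld, tk$drug),
    protein = encode_label_matrix(protein_seqs, model$vocab$protein, model$dims$Lp,
                                  tk$protein)
  )
}

# Build batched input matrices ((B*L) x width, sample-major) for sample idx.
encode_batch_inputs <- function(model, enc, idx) {
  B <- length(idx)
  d <- model$dims
  labd <- enc$drug$labels[idx, , drop = FALSE]
  labp <- enc$protein$labels[idx, , drop = FALSE]
  vd <- as.vector(t(labd)); vp <- as.vector(t(labp))
  maskd <- vd != PAD_LABEL; maskp <- vp != PAD_LABEL
  if (model$onehot) {
    onehot_mat <- function(v, vocab, width) {
      all_labels <- sort(unname(vocab$label_of))
      X <- matrix(0, length(v), width)
      col <- match(v, all_labels)
      hit <- which(!is.na(col) & v != PAD_LABEL)
      X[cbind(hit, col[hit])] <- 1
      X
    }
    Xd <- onehot_mat(vd, model$vocab$drug, d$wd)
    Xp <- onehot_mat(vp, model$vocab$protein, d$wp)
  } else {
    Xd <- model$params[["emb.drug_tok"]][vd + 1L, , drop = FALSE]
    Xp <- model$params[["emb.prot_tok"]][vp + 1L, , drop = FALSE]
    if (model$positional) {
      Xd <- Xd + model$params[["emb.drug_pos"]][rep(seq_len(d$Ld), B), , drop = FALSE]
      Xp <- Xp + model$params[["emb.prot_pos"]][rep(seq_len(d$Lp), B), , drop = FALSE]
    }
  }
  list(Xd = Xd, Xp = Xp, maskd = maskd, maskp = maskp, B = B,
       vd = vd, vp = vp)
}

# Batched attention forward for one direction.
batt_forward <- function(Xq, Xk, B, Lq, Lk, qmask, kmask, par, heads, dph,
                         scale, mask_keys, keep_A = TRUE) {
  Q <- Xq %*% par$Wq; K <- Xk %*% par$Wk; V <- Xk %*% par$Wv
  hidden <- ncol(Q)
  denom <- if (scale == "sqrt_d") sqrt(dph) else dph
  H <- matrix(0, nrow(Q), hidden)
  A <- if (keep_A) vector("list", B) else NULL
  for (b in seq_len(B)) {
    rq <- ((b - 1L) * Lq + 1L):(b * Lq)
    rk <- ((b - 1L) * Lk + 1L):(b * Lk)
    km <- kmask[rk]
    Ab <- array(0, c(Lq, Lk, heads))
    Qb <- Q[rq, , drop = FALSE]; Kb <- K[rk, , drop = FALSE]
    Vb <- V[rk, , drop = FALSE]
    for (i in seq_len(heads)) {
      ci <- ((i - 1L) * dph + 1L):(i * dph)
      S <- tcrossprod(Qb[, ci, drop = FALSE], Kb[, ci, drop = FALSE]) / denom
      if (mask_keys) S[, !km] <- -Inf
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      Ai <- E / rowSums(E)
      Ab[, , i] <- Ai
      H[rq, ci] <- Ai %*% Vb[, ci, drop = FALSE]
    }
    if (keep_A) A[[b]] <- Ab
  }
  ctx <- Q + H %*% par$W0
  ctx[!qmask, ] <- 0
  list(ctx = ctx, Q = Q, K = K, V = V, H = H, A = A,
       B = B, Lq = Lq, Lk = Lk, qmask = qmask, kmask = kmask, denom = denom)
}

batt_backward <- function(dctx, cache, par) {
  dctx[!cache$qmask, ] <- 0
  dQ <- dctx
  dH <- dctx %*% t(par$W0)
  gW0 <- crossprod(cache$H, dctx)
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  heads <- dim(cache$A[[1L]])[3L]
  dph <- ncol(cache$Q) / heads
  for (b in seq_len(cache$B)) {
    rq <- ((b - 1L) * cache$Lq + 1L):(b * cache$Lq)
    rk <- ((b - 1L) * cache$Lk + 1L):(b * cache$Lk)
    Ab <- cache$A[[b]]
    for (i in seq_len(heads)) {
      ci <- ((i - 1L) * dph + 1L):(i * dph)
      Ai <- Ab[, , i]
      dHi <- dH[rq, ci, drop = FALSE]
      Vi <- cache$V[rk, ci, drop = FALSE]
      dA <- tcrossprod(dHi, Vi)
      dV[rk, ci] <- dV[rk, ci] + crossprod(Ai, dHi)
      dS <- Ai * (dA - rowSums(Ai * dA))
      dS <- dS / cache$denom
      dQ[rq, ci] <- dQ[rq, ci] + dS %*% cache$K[rk, ci, drop = FALSE]
      dK[rk, ci] <- dK[rk, ci] + crossprod(dS, cache$Q[rq, ci, drop = FALSE])
    }
  }
  list(dXq = dQ %*% t(par$Wq), dXk = dK %*% t(par$Wk) + dV %*% t(par$Wv),
       dQ = dQ, dK = dK, dV = dV, gW0 = gW0)
}

# ---- batched heads ----

cnn_forward_batch <- function(Ctx, B, Lc, model, train, par) {
  hc <- model$head_cfg
  kern <- hc$kernel; pool <- hc$pool
  unfold_idx <- function(L) {
    n_out <- L - kern + 1L
    list(n_out = n_out,
         starts = as.vector(outer(seq_len(n_out), (seq_len(B) - 1L) * L, `+`)))
  }
  pool_idx <- function(L) {
    p <- L %/% pool
    i1 <- as.vector(outer(seq(1L, by = pool, length.out = p), (seq_len(B) - 1L) * L, `+`))
    list(p = p, i1 = i1)
  }
  conv_block <- function(X, L, W, bvec) {
    u <- unfold_idx(L)
    Xu <- do.call(cbind, lapply(seq_len(kern) - 1L, function(off) {
      X[u$starts + off, , drop = FALSE]
    }))
    Zpre <- sweep(Xu %*% W, 2L, bvec, "+")
    R <- Zpre > 0
    Z <- Zpre * R
    pidx <- pool_idx(u$n_out)
    P <- Z[pidx$i1, , drop = FALSE]
    M <- matrix(1L, nrow(P), ncol(P))  # argmax slot within each pool window
    for (j in 2:pool) {
      other <- Z[pidx$i1 + (j - 1L), , drop = FALSE]
      upd <- other > P
      P[upd] <- other[upd]
      M[upd] <- j
    }
    drop_mask <- NULL
    if (train && hc$dropout > 0) {
      drop_mask <- matrix(stats::rbinom(length(P), 1L, 1 - hc$dropout) /
                            (1 - hc$dropout), nrow(P), ncol(P))
      P <- P * drop_mask
    }
    list(P = P, cache = list(Xu = Xu, R = R, u = u, pidx = pidx, L = L,
                             drop = drop_mask, M = M))
  }
  b1 <- conv_block(Ctx, Lc, par$W1, par$b1)
  b2 <- conv_block(b1$P, b1$cache$pidx$p, par$W2, par$b2)
  p2 <- b2$cache$pidx$p
  c2 <- ncol(b2$P)
  Fmat <- matrix(as.vector(t(b2$P)), nrow = B, byrow = TRUE)
  logits <- drop(Fmat %*% par$Wl) + par$bl
  list(prob = sigmoid(logits), logits = logits,
       cache = list(b1 = b1$cache, b2 = b2$cache, Fmat = Fmat, P1 = b1$P,
                    p2 = p2, c2 = c2, B = B, Lc = Lc))
}

cnn_backward_batch <- function(dlogits, fw, model, par) {
  hc <- model$head_cfg
  kern <- hc$kernel; pool <- hc$pool
  ca <- fw$cache
  gWl <- crossprod(ca$Fmat, dlogits)
  gbl <- sum(dlogits)
  dF <- outer(dlogits, drop(par$Wl))  # B x flat
  dP2 <- matrix(as.vector(t(dF)), ncol = ca$c2, byrow = TRUE)
  conv_block_back <- function(dP, cache, W, X_in) {
    if (!is.null(cache$drop)) dP <- dP * cache$drop
    n_out <- cache$u$n_out
    dZ <- matrix(0, n_out * ca$B, ncol(dP))
    i1 <- cache$pidx$i1
    for (j in seq_len(pool)) {
      dZ[i1 + (j - 1L), ] <- dZ[i1 + (j - 1L), ] + dP * (cache$M == j)
    }
    dZ <- dZ * cache$R
    gW <- crossprod(cache$Xu, dZ)
    gb <- colSums(dZ)
    dXu <- tcrossprod(dZ, W)
    Cin <- ncol(dXu) / kern
    dX <- matrix(0, cache$L * ca$B, Cin)
    for (off in seq_len(kern) - 1L) {
      cols <- (off * Cin + 1L):((off + 1L) * Cin)
      rows <- cache$u$starts + off
      dX[rows, ] <- dX[rows, ] + dXu[, cols, drop = FALSE]
    }
    list(dX = dX, gW = gW, gb = gb)
  }
  bk2 <- conv_block_back(dP2, ca$b2, par$W2, fw$cache$P1)
  bk1 <- conv_block_back(bk2$dX, ca$b1, par$W1, NULL)
  list(dCtx = bk1$dX,
       grads = list(W1 = bk1$gW, b1 = bk1$gb, W2 = bk2$gW, b2 = bk2$gb,
                    Wl = gWl, bl = gbl))
}

fcl_forward_batch <- function(Ctx, B, Lc, model, train, par) {
  hc <- model$head_cfg
  F0 <- matrix(as.vector(t(Ctx)), nrow = B, byrow = TRUE)
  dense_block <- function(X, W, bvec) {
    Zpre <- sweep(X %*% W, 2L, bvec, "+")
    R <- Zpre > 0
    Z <- Zpre * R
    drop_mask <- NULL
    if (train && hc$dropout > 0) {
      drop_mask <- matrix(stats::rbinom(length(Z), 1L, 1 - hc$dropout) /
                            (1 - hc$dropout), nrow(Z), ncol(Z))
      Z <- Z * drop_mask
    }
    list(Z = Z, R = R, drop = drop_mask)
  }
  d1 <- dense_block(F0, par$W1, par$b1)
  d2 <- dense_block(d1$Z, par$W2, par$b2)
  logits <- drop(d2$Z %*% par$Wl) + par$bl
  list(prob = sigmoid(logits), logits = logits,
       cache = list(F0 = F0, d1 = d1, d2 = d2, B = B, Lc = Lc))
}

fcl_backward_batch <- function(dlogits, fw, model, par) {
  ca <- fw$cache
  gWl <- crossprod(ca$d2$Z, dlogits)
  gbl <- sum(dlogits)
  dZ2 <- outer(dlogits, drop(par$Wl))
  if (!is.null(ca$d2$drop)) dZ2 <- dZ2 * ca$d2$drop
  dZ2 <- dZ2 * ca$d2$R
  gW2 <- crossprod(ca$d1$Z, dZ2); gb2 <- colSums(dZ2)
  dZ1 <- tcrossprod(dZ2, par$W2)
  if (!is.null(ca$d1$drop)) dZ1 <- dZ1 * ca$d1$drop
  dZ1 <- dZ1 * ca$d1$R
  gW1 <- crossprod(ca$F0, dZ1); gb1 <- colSums(dZ1)
  dF0 <- tcrossprod(dZ1, par$W1)
  list(dF0 = dF0, grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                               Wl = gWl, bl = gbl))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- full model forward/backward ----

par_slice <- function(params, prefix) {
  nm <- names(params)[startsWith(names(params), prefix)]
  out <- params[nm]
  names(out) <- substring(nm, nchar(prefix) + 1L)
  out
}

#' Batched model forward pass
#'
#' @param model A `dti_model`.
#' @param batch Batch inputs from the internal encoder (see [model_encode()]).
#' @param train Logical; enables dropout.
#' @param keep_cache Keep intermediate values for backpropagation.
#' @return List with `prob` (length-B vector) and caches.
#' @keywords internal
model_forward <- function(model, batch, train = FALSE, keep_cache = TRUE) {
  d <- model$dims
  spec <- model$spec
  dirs <- need_directions(spec)
  xp <- batch$Xp; xd <- batch$Xd
  layer_caches <- vector("list", spec$depth)
  for (k in seq_len(spec$depth)) {
    pk <- list()
    if ("P" %in% dirs) {
      par <- par_slice(model$params, sprintf("L%d.P.", k))
      kv <- if (spec$attn == "self") list(x = xp, L = d$Lp, m = batch$maskp)
            else list(x = xd, L = d$Ld, m = batch$maskd)
      pk$P <- batt_forward(xp, kv$x, batch$B, d$Lp, kv$L, batch$maskp, kv$m,
                           par, d$heads, d$d, model$scale, model$mask_keys)
    }
    if ("D" %in% dirs) {
      par <- par_slice(model$params, sprintf("L%d.D.", k))
      kv <- if (spec$attn == "self") list(x = xd, L = d$Ld, m = batch$maskd)
            else list(x = xp, L = d$Lp, m = batch$maskp)
      pk$D <- batt_forward(xd, kv$x, batch$B, d$Ld, kv$L, batch$maskd, kv$m,
                           par, d$heads, d$d, model$scale, model$mask_keys)
    }
    layer_caches[[k]] <- pk
    if (k < spec$depth) { xp <- pk$P$ctx; xd <- pk$D$ctx }
  }
  last <- layer_caches[[spec$depth]]
  # context assembly (sample-major row blocks; for "dp", drug rows above protein)
  if (spec$context == "dp") {
    Lc <- d$Ld + d$Lp
    idxD <- as.vector(outer(seq_len(d$Ld), (seq_len(batch$B) - 1L) * Lc, `+`))
    idxP <- as.vector(outer(seq_len(d$Lp) + d$Ld, (seq_len(batch$B) - 1L) * Lc, `+`))
    Ctx <- matrix(0, batch$B * Lc, d$hidden)
    Ctx[idxD, ] <- last$D$ctx
    Ctx[idxP, ] <- last$P$ctx
    ctx_idx <- list(D = idxD, P = idxP)
  } else if (spec$context == "p") {
    Lc <- d$Lp; Ctx <- last$P$ctx; ctx_idx <- NULL
  } else {
    Lc <- d$Ld; Ctx <- last$D$ctx; ctx_idx <- NULL
  }
  hpar <- par_slice(model$params, "head.")
  hf <- if (model$head_cfg$kind == "cnn") {
    cnn_forward_batch(Ctx, batch$B, Lc, model, train, hpar)
  } else {
    fcl_forward_batch(Ctx, batch$B, Lc, model, train, hpar)
  }
  list(prob = hf$prob, head = hf, layers = layer_caches, ctx_idx = ctx_idx,
       Lc = Lc, batch = batch)
}

# Backward pass for mean binary cross-entropy; returns flat named grads.
model_backward <- function(model, fw, y) {
  d <- model$dims
  spec <- model$spec
  dirs <- need_directions(spec)
  B <- fw$batch$B
  dlogits <- (fw$prob - y) / B
  hpar <- par_slice(model$params, "head.")
  if (model$head_cfg$kind == "cnn") {
    hb <- cnn_backward_batch(dlogits, fw$head, model, hpar)
    dCtx <- hb$dCtx
  } else {
    hb <- fcl_backward_batch(dlogits, fw$head, model, hpar)
    dCtx <- matrix(as.vector(t(hb$dF0)), ncol = d$hidden, byrow = TRUE)
  }
  grads <- list()
  for (nm in names(hb$grads)) grads[[paste0("head.", nm)]] <- hb$grads[[nm]]
  if (spec$context == "dp") {
    dctxD <- dCtx[fw$ctx_idx$D, , drop = FALSE]
    dctxP <- dCtx[fw$ctx_idx$P, , drop = FALSE]
  } else if (spec$context == "p") {
    dctxP <- dCtx; dctxD <- NULL
  } else {
    dctxD <- dCtx; dctxP <- NULL
  }
  dXp <- matrix(0, nrow(fw$batch$Xp), ncol(fw$batch$Xp))
  dXd <- matrix(0, nrow(fw$batch$Xd), ncol(fw$batch$Xd))
  for (k in rev(seq_len(spec$depth))) {
    lay <- fw$layers[[k]]
    ndP <- ndD <- NULL
    if ("P" %in% dirs && !is.null(dctxP)) {
      par <- par_slice(model$params, sprintf("L%d.P.", k))
      bk <- batt_backward(dctxP, lay$P, par)
      # input gradients
      xq_in <- if (k == 1L) fw$batch$Xp else fw$layers[[k - 1L]]$P$ctx
      xk_in <- if (spec$attn == "self") xq_in
               else if (k == 1L) fw$batch$Xd else fw$layers[[k - 1L]]$D$ctx
      grads[[sprintf("L%d.P.Wq", k)]] <- crossprod(xq_in, bk$dQ)
      grads[[sprintf("L%d.P.Wk", k)]] <- crossprod(xk_in, bk$dK)
      grads[[sprintf("L%d.P.Wv", k)]] <- crossprod(xk_in, bk$dV)
      grads[[sprintf("L%d.P.W0", k)]] <- bk$gW0
      if (spec$attn == "self") { ndP <- bk$dXq + bk$dXk }
      else { ndP <- bk$dXq; ndD <- bk$dXk }
    }
    if ("D" %in% dirs && !is.null(dctxD)) {
      par <- par_slice(model$params, sprintf("L%d.D.", k))
      bk <- batt_backward(dctxD, lay$D, par)
      xq_in <- if (k == 1L) fw$batch$Xd else fw$layers[[k - 1L]]$D$ctx
      xk_in <- if (spec$attn == "self") xq_in
               else if (k == 1L) fw$batch$Xp else fw$layers[[k - 1L]]$P$ctx
      grads[[sprintf("L%d.D.Wq", k)]] <- crossprod(xq_in, bk$dQ)
      grads[[sprintf("L%d.D.Wk", k)]] <- crossprod(xk_in, bk$dK)
      grads[[sprintf("L%d.D.Wv", k)]] <- crossprod(xk_in, bk$dV)
      grads[[sprintf("L%d.D.W0", k)]] <- bk$gW0
      if (spec$attn == "self") {
        ndD <- (ndD %||% 0) + bk$dXq + bk$dXk
      } else {
        ndD <- (ndD %||% 0) + bk$dXq
        ndP <- (ndP %||% 0) + bk$dXk
      }
    }
    if (k > 1L) {
      dctxP <- if (is.null(ndP)) NULL else ndP
      dctxD <- if (is.null(ndD)) NULL else ndD
    } else {
      if (!is.null(ndP)) dXp <- dXp + ndP
      if (!is.null(ndD)) dXd <- dXd + ndD
    }
  }
  if (!model$onehot) {
    grads[["emb.drug_tok"]] <- scatter_rows(dXd, fw$batch$vd + 1L,
                                            nrow(model$params[["emb.drug_tok"]]))
    grads[["emb.prot_tok"]] <- scatter_rows(dXp, fw$batch$vp + 1L,
                                            nrow(model$params[["emb.prot_tok"]]))
    if (model$positional) {
      grads[["emb.drug_pos"]] <- scatter_rows(dXd, rep(seq_len(d$Ld), B), d$Ld)
      grads[["emb.prot_pos"]] <- scatter_rows(dXp, rep(seq_len(d$Lp), B), d$Lp)
    }
  }
  grads
}

scatter_rows <- function(dX, groups, n_rows) {
  agg <- rowsum(dX, group = groups)
  out <- matrix(0, n_rows, ncol(dX))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

bce_loss <- function(prob, y, eps = 1e-12) {
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

# ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Predict interaction probabilities
#'
#' @param object A `dti_model`.
#' @param drug_smiles,protein_seqs Parallel character vectors, or `NULL` if
#'   `enc`/`idx` are given.
#' @param enc Pre-computed encoding from [model_encode()].
#' @param idx Sample indices into `enc` (default all).
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.dti_model <- function(object, drug_smiles = NULL, protein_seqs = NULL,
                              enc = NULL, idx = NULL, batch_size = 64L, ...) {
  if (is.null(enc)) enc <- model_encode(object, drug_smiles, protein_seqs)
  if (is.null(idx)) idx <- seq_len(nrow(enc$drug$labels))
  out <- numeric(length(idx))
  for (s in split(seq_along(idx), ceiling(seq_along(idx) / batch_size))) {
    batch <- encode_batch_inputs(object, enc, idx[s])
    fw <- model_forward(object, batch, train = FALSE)
    out[s] <- fw$prob
  }
  out
}

#' Extract head-averaged cross-attention weights for single samples
#'
#' Runs the model on one sample and returns the protein-query attention weight
#' matrix of the final layer, averaged over heads, restricted to real (non-PAD)
#' positions, together with the token spans needed for sequence-axis expansion.
#'
#' @param model A trained `dti_model` whose architecture includes the
#'   protein-query direction (any except `CA_D`).
#' @param enc Encoding from [model_encode()].
#' @param i Sample index.
#' @return List with `weights` (protein tokens x drug tokens), `prot_spans`,
#'   `drug_spans` (token start/width in sequence coordinates), and the per-head
#'   array `per_head`.
#' @export
attention_map <- function(model, enc, i) {
  if (!"P" %in% need_directions(model$spec))
    stop("architecture ", model$arch, " has no protein-query attention")
  batch <- encode_batch_inputs(model, enc, i)
  fw <- model_forward(model, batch, train = FALSE)
  lay <- fw$layers[[model$spec$depth]]$P
  A <- lay$A[[1L]]  # Lp x Lk x heads
  tp <- enc$protein$true_len[i]
  td <- enc$drug$true_len[i]
  if (model$spec$attn == "self") stop("self-attention maps are not drug-conditioned")
  avg <- apply(A, c(1L, 2L), mean)
  list(weights = avg[seq_len(tp), seq_len(td), drop = FALSE],
       per_head = A[seq_len(tp), seq_len(td), , drop = FALSE],
       prot_spans = enc$protein$spans[[i]],
       drug_spans = enc$drug$spans[[i]],
       prob = fw$prob[1L])
}
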