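# Independent reference implementations used as oracles. Deliberately naive
# and written differently from the package code.

# Frequent-consecutive-subsequence mining by full recount each iteration.
naive_fcs_mine <- function(sequences, kind, min_freq = 5L, max_vocab = 100L) {
  alphabet_kind <- if (kind == "drug") "fcs_drug" else "fcs_protein"
  tokenize <- if (kind == "drug") dticross::tokenize_smiles_chars else
    dticross::tokenize_protein
  seqs <- lapply(sequences, tokenize)
  base <- sort(setdiff(unique(unlist(seqs)), "<unk>"))
  if (kind == "protein")
    base <- sort(union(base, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  naive_apply <- function(tok, left, right) {
    out <- character(0)
    i <- 1L
    while (i <= length(tok)) {
      if (i < length(tok) && tok[i] == left && tok[i + 1L] == right) {
        out <- c(out, paste0(left, right)); i <- i + 2L
      } else {
        out <- c(out, tok[i]); i <- i + 1L
      }
    }
    out
  }
  tokens <- base; merges <- list()
  repeat {
    if (length(tokens) + 1L >= max_vocab) break
    pairs <- unlist(lapply(seqs, function(tok) {
      n <- length(tok)
      if (n < 2L) return(character(0))
      paste(tok[-n], tok[-1L], sep = "\x1f")
    }))
    pairs <- pairs[!grepl("<unk>", pairs, fixed = TRUE)]
    if (length(pairs) == 0L) break
    cnt <- table(pairs)
    if (max(cnt) < min_freq) break
    cand <- sort(names(cnt)[cnt == max(cnt)], method = "radix")
    fused <- vapply(strsplit(cand, "\x1f", fixed = TRUE), paste0, "",
                    collapse = "")
    pick <- order(fused, cand, method = "radix")[1L]
    pair <- strsplit(cand[pick], "\x1f", fixed = TRUE)[[1]]
    merges[[length(merges) + 1L]] <- pair
    seqs <- lapply(seqs, naive_apply, left = pair[1L], right = pair[2L])
    if (!fused[pick] %in% tokens) tokens <- c(tokens, fused[pick])
  }
  list(tokens = tokens, merges = merges, segmented = seqs)
}

# Multi-head attention by an explicit per-head loop with per-element softmax.
brute_multihead <- function(Xq, Xk, Wq, Wk, Wv, W0, heads, scale = "sqrt_d") {
  hidden <- ncol(Wq)
  d <- hidden / heads
  Q <- Xq %*% Wq; K <- Xk %*% Wk; V <- Xk %*% Wv
  H <- matrix(0, nrow(Xq), hidden)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * d + 1):(h * d)
    S <- matrix(0, nrow(Xq), nrow(Xk))
    for (i in seq_len(nrow(Xq)))
      for (j in seq_len(nrow(Xk)))
        S[i, j] <- sum(Q[i, cols] * K[j, cols]) /
          (if (scale == "sqrt_d") sqrt(d) else d)
    A <- matrix(0, nrow(S), ncol(S))
    for (i in seq_len(nrow(S))) A[i, ] <- exp(S[i, ]) / sum(exp(S[i, ]))
    H[, cols] <- A %*% V[, cols]
  }
  Q + H %*% W0
}

# Confusion-table metrics from first principles.
oracle_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- ifelse(scores >= threshold, 1, 0)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sn <- tp / (tp + fn); sp <- tn / (tn + fp); pr <- tp / (tp + fp)
  c(SN = sn, SP = sp, PR = pr, F1 = 2 * pr * sn / (pr + sn))
}

# Mann-Whitney formulation of ROCAUC (ties count half).
oracle_rocauc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# small reproducible DTI dataset for pipeline tests
tiny_dti <- function(n = 60L, seed = 5L) {
  sp <- dticross::synthetic_spec(n_pairs = n, rho = 0,
                                 protein_len = c(30L, 40L),
                                 protein_motif = "WYKF")
  dticross::synthetic_dataset(sp, seed = seed)
}
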