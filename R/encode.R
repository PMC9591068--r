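# Token encoding: label vectors and embedding matrices.
#
# Five schemes are supported, differing in the drug/protein token units and in
# whether labels go through a learned embedding table or one-hot indicators:
#   fcs_embed      - mined subsequence tokens, learned embedding (default)
#   smiles_embed   - SMILES characters / AA letters, learned embedding
#   selfies_embed  - SELFIES words / AA letters, learned embedding
#   smiles_onehot  - SMILES characters / AA letters, one-hot
#   selfies_onehot - SELFIES words / AA letters, one-hot

ENCODING_SCHEMES <- c("fcs_embed", "smiles_embed", "selfies_embed",
                      "smiles_onehot", "selfies_onehot")

#' Tokenize a SMILES string into SELFIES words
#'
#' Convenience wrapper around [selfies_encode()]: the drug token unit of the
#' SELFIES encoding schemes.
#'
#' @inheritParams selfies_encode
#' @return Character vector of bracketed SELFIES word tokens.
#' @export
tokenize_selfies <- function(smiles) selfies_encode(smiles)

#' Map a token list to a fixed-length integer label vector
#'
#' Tokens are looked up in the vocabulary in order; sequences longer than
#' `max_len` keep their prefix, shorter ones are right-padded with the PAD
#' label 0.
#'
#' @param tokens Character vector of tokens (may be empty).
#' @param vocab A `dti_vocab`.
#' @param max_len Fixed output length (drug default 50, protein default 545).
#' @return An object of class `dti_labelvec`: integer vector of length
#'   `max_len` with attribute `true_len`.
#' @export
label_encode <- function(tokens, vocab, max_len) {
  stopifnot(max_len >= 1L)
  lab <- if (length(tokens)) vocab_labels(tokens, vocab) else integer(0)
  true_len <- min(length(lab), max_len)
  out <- rep(PAD_LABEL, max_len)
  if (true_len > 0L) out[seq_len(true_len)] <- lab[seq_len(true_len)]
  structure(as.integer(out), true_len = as.integer(true_len), class = "dti_labelvec")
}

label_mask <- function(lv) {
  seq_along(unclass(lv)) <= attr(lv, "true_len")
}

#' Initialise a learned embedding table
#'
#' Uniform initialisation scaled by the feature dimension, the same scheme
#' used for all weight matrices in the model.
#'
#' @param n_rows Number of rows (labels or positions covered).
#' @param dim Feature dimension (default 384).
#' @return Numeric matrix `n_rows x dim`.
#' @export
embedding_init <- function(n_rows, dim = 384L) {
  r <- 1 / sqrt(dim)
  matrix(stats::runif(n_rows * dim, -r, r), n_rows, dim)
}

#' Learned (table-lookup) embedding with positional addition
#'
#' Row `i` of the result is `token_table[label_i] + pos_table[i]`. PAD
#' positions (label 0) receive the table's PAD row plus position embedding but
#' are flagged by the mask and excluded from attention downstream.
#'
#' @param lv A `dti_labelvec`.
#' @param token_table Numeric matrix whose rows 2.. index labels 1.. (row 1 is
#'   the PAD row for label 0).
#' @param pos_table Numeric matrix with at least `length(lv)` rows, or `NULL`
#'   to disable positional embedding.
#' @return Numeric matrix `length(lv) x ncol(token_table)` with attribute
#'   `mask` (logical, TRUE on real positions).
#' @export
embed_learned <- function(lv, token_table, pos_table = NULL) {
  labels <- unclass(lv)
  if (max(labels) + 1L > nrow(token_table)) stop("label out of embedding table range")
  out <- token_table[labels + 1L, , drop = FALSE]
  if (!is.null(pos_table)) {
    if (nrow(pos_table) < length(labels)) stop("pos_table has too few rows")
    out <- out + pos_table[seq_along(labels), , drop = FALSE]
  }
  structure(out, mask = label_mask(lv))
}

#' One-hot embedding
#'
#' Row `i` is the indicator vector of label `i` over the vocabulary's label
#' set; PAD rows are all-zero. Width equals the vocabulary size.
#'
#' @param lv A `dti_labelvec`.
#' @param vocab The `dti_vocab` the labels came from.
#' @return Numeric matrix `length(lv) x vocab size` with attribute `mask`.
#' @export
embed_onehot <- function(lv, vocab) {
  labels <- unclass(lv)
  all_labels <- sort(unname(vocab$label_of))
  out <- matrix(0, length(labels), length(all_labels))
  col <- match(labels, all_labels)
  hit <- which(!is.na(col) & labels != PAD_LABEL)
  out[cbind(hit, col[hit])] <- 1
  structure(out, mask = label_mask(lv))
}

# Tokenizer pair for a scheme; FCS vocabularies are mined upstream and passed in.
scheme_tokenizers <- function(scheme) {
  scheme <- match.arg(scheme, ENCODING_SCHEMES)
  drug_tok <- switch(scheme,
    fcs_embed = function(s, vocab) vocab_segment(tokenize_smiles_chars(s), vocab),
    smiles_embed = ,
    smiles_onehot = function(s, vocab) tokenize_smiles_chars(s),
    selfies_embed = ,
    selfies_onehot = function(s, vocab) selfies_encode(s)
  )
  prot_tok <- switch(scheme,
    fcs_embed = function(s, vocab) vocab_segment(tokenize_protein(s), vocab),
    function(s, vocab) tokenize_protein(s)
  )
  list(drug = drug_tok, protein = prot_tok, onehot = grepl("onehot", scheme))
}

#' Build drug and protein vocabularies for an encoding scheme
#'
#' FCS schemes mine subsequence vocabularies on the supplied (training)
#' corpora; character/word schemes enumerate the observed token set.
#'
#' @param drug_smiles Character vector of training SMILES.
#' @param protein_seqs Character vector of training protein sequences.
#' @param scheme One of the five encoding scheme names.
#' @param min_freq,max_vocab_drug,max_vocab_protein FCS mining controls.
#' @return List with elements `drug` and `protein`, each a `dti_vocab`.
#' @export
build_vocabularies <- function(drug_smiles, protein_seqs,
                               scheme = "fcs_embed", min_freq = 5L,
                               max_vocab_drug = 2000L, max_vocab_protein = 10000L) {
  scheme <- match.arg(scheme, ENCODING_SCHEMES)
  if (scheme == "fcs_embed") {
    return(list(
      drug = fcs_mine(drug_smiles, "drug", min_freq, max_vocab_drug),
      protein = fcs_mine(protein_seqs, "protein", min_freq, max_vocab_protein)
    ))
  }
  drug_tokens <- if (grepl("selfies", scheme)) {
    sort(unique(unlist(lapply(drug_smiles, function(s) {
      tryCatch(selfies_encode(s), error = function(e) character(0))
    }))))
  } else {
    sort(unique(unlist(lapply(drug_smiles, tokenize_smiles_chars))))
  }
  drug_kind <- if (grepl("selfies", scheme)) "selfies_word" else "smiles_char"
  list(
    drug = vocabulary(drug_tokens, drug_kind),
    protein = vocabulary(AA_STANDARD, "aa_letter")
  )
}

# Encode a dataset (character vectors) into label matrices n x max_len.
# Returns list(labels, true_len, spans) where spans give per-sample token
# character spans (used by attention expansion).
encode_label_matrix <- function(seqs, vocab, max_len, tokenizer) {
  n <- length(seqs)
  labels <- matrix(PAD_LABEL, n, max_len)
  true_len <- integer(n)
  spans <- vector("list", n)
  toks <- NULL
  if (n > 1L && startsWith(vocab$alphabet_kind, "fcs_")) {
    # corpus-level merge replay; identical to per-sequence segmentation
    toks <- segment_corpus(base_tokens_for(seqs, vocab$alphabet_kind), vocab)
  }
  for (i in seq_len(n)) {
    tok <- if (is.null(toks)) tokenizer(seqs[i], vocab) else toks[[i]]
    lv <- label_encode(tok, vocab, max_len)
    labels[i, ] <- unclass(lv)
    true_len[i] <- attr(lv, "true_len")
    kept <- tok[seq_len(true_len[i])]
    w <- nchar(kept)
    spans[[i]] <- cbind(start = cumsum(c(1L, utils::head(w, -1L))), width = w)
  }
  list(labels = labels, true_len = true_len, spans = spans)
}
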