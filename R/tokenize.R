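# Reserved labels shared by every vocabulary: PAD is always 0, UNK defaults to 1.
PAD_LABEL <- 0L
UNK_TOKEN <- "<unk>"

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Split a SMILES string into single-character tokens
#'
#' Character-level tokenization treats every letter or symbol as one token, so
#' two-letter atom symbols such as `Cl` split into `C`, `l`. This is the
#' deliberate behaviour of the character encoding scheme (a "character" is a
#' letter or a symbol); chemically-aware multi-character tokenization is out of
#' scope.
#'
#' @param smiles Non-empty SMILES string.
#' @return Character vector with one token per character.
#' @examples
#' tokenize_smiles_chars("CN=C=O")
#' @export
tokenize_smiles_chars <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || nchar(smiles) == 0L) stop("empty sequence")
  strsplit(smiles, "", fixed = TRUE)[[1]]
}

#' Split a protein sequence into amino-acid letter tokens
#'
#' One token per residue; letters outside the 20 standard amino acids map to
#' the UNK token.
#'
#' @param seq Non-empty amino-acid string.
#' @return Character vector of residue tokens (`<unk>` for non-standard letters).
#' @export
tokenize_protein <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (is.na(seq) || nchar(seq) == 0L) stop("empty sequence")
  tok <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  tok[!tok %in% AA_STANDARD] <- UNK_TOKEN
  tok
}

#' Construct a token vocabulary
#'
#' A vocabulary maps tokens to positive integer labels and carries the ordered
#' list of merge rules produced by frequent-consecutive-subsequence mining
#' (empty for plain character/word vocabularies). Label 0 is reserved for
#' padding; the UNK token always has a label.
#'
#' @param tokens Character vector of tokens (must not contain duplicates or the
#'   UNK token; it is added automatically).
#' @param alphabet_kind One of `"smiles_char"`, `"selfies_word"`, `"aa_letter"`,
#'   `"fcs_drug"`, `"fcs_protein"`.
#' @param merges List of length-2 character vectors, in mining order.
#' @param labels Optional integer vector of labels parallel to `tokens`
#'   (defaults to contiguous labels starting at 2, after PAD = 0 and UNK = 1).
#' @param unk_label Label of the UNK token (default 1).
#' @return An object of class `dti_vocab`.
#' @export
vocabulary <- function(tokens, alphabet_kind, merges = list(), labels = NULL,
                       unk_label = 1L) {
  tokens <- as.character(tokens)
  tokens <- tokens[tokens != UNK_TOKEN]
  if (anyDuplicated(tokens)) stop("duplicate tokens in vocabulary")
  if (is.null(labels)) {
    labels <- seq_along(tokens) + 1L
  } else {
    labels <- as.integer(labels)
    stopifnot(length(labels) == length(tokens))
  }
  if (any(labels <= 0L)) stop("token labels must be positive (0 is PAD)")
  if (unk_label %in% labels) stop("unk_label collides with a token label")
  all_tokens <- c(UNK_TOKEN, tokens)
  all_labels <- c(as.integer(unk_label), labels)
  if (anyDuplicated(all_labels)) stop("duplicate labels")
  structure(
    list(
      tokens = all_tokens,
      label_of = stats::setNames(all_labels, all_tokens),
      merges = merges,
      pad_label = PAD_LABEL,
      unk_label = as.integer(unk_label),
      alphabet_kind = match.arg(alphabet_kind, c(
        "smiles_char", "selfies_word", "aa_letter", "fcs_drug", "fcs_protein"
      ))
    ),
    class = "dti_vocab"
  )
}

#' @export
print.dti_vocab <- function(x, ...) {
  cat(sprintf(
    "<dti_vocab> %s: %d tokens, %d merges (PAD=%d, UNK=%d)\n",
    x$alphabet_kind, length(x$tokens), length(x$merges), x$pad_label, x$unk_label
  ))
  invisible(x)
}

#' @export
length.dti_vocab <- function(x) length(x$tokens)

vocab_size <- function(vocab) length(vocab$tokens)

base_tokens_for <- function(sequences, alphabet_kind) {
  if (alphabet_kind %in% c("aa_letter", "fcs_protein")) {
    lapply(sequences, tokenize_protein)
  } else {
    lapply(sequences, tokenize_smiles_chars)
  }
}

# Count every adjacent token pair across the corpus ("AAA" contributes AA twice).
count_pairs <- function(token_seqs) {
  pairs <- unlist(lapply(token_seqs, function(tok) {
    n <- length(tok)
    if (n < 2L) return(character(0))
    paste(tok[-n], tok[-1L], sep = "\x1f")
  }))
  if (length(pairs) == 0L) return(integer(0))
  tab <- table(pairs)
  stats::setNames(as.integer(tab), names(tab))
}

# Greedy left-to-right selection among (possibly overlapping) pair positions:
# within each run of consecutive positions, accept every other one starting
# with the first ("AAAA" with rule A+A merges at positions 1 and 3).
greedy_keep <- function(hit) {
  if (length(hit) < 2L) return(hit)
  run_id <- cumsum(c(TRUE, diff(hit) != 1L))
  first <- match(run_id, run_id)  # index of each run's first element
  hit[(seq_along(hit) - first) %% 2L == 0L]
}

# Greedy left-to-right, non-overlapping application of one merge rule.
apply_merge <- function(tok, left, right) {
  n <- length(tok)
  if (n < 2L) return(tok)
  hit <- which(tok[-n] == left & tok[-1L] == right)
  if (length(hit) == 0L) return(tok)
  keep <- greedy_keep(hit)
  tok[keep] <- paste0(left, right)
  tok[-(keep + 1L)]
}

BOUNDARY_SENTINEL <- "\x1e"

#' Mine a frequent-consecutive-subsequence vocabulary
#'
#' Byte-pair-style mining: repeatedly find the most frequent adjacent token
#' pair in the corpus and fuse it into a single token, recording the merge.
#' Mining stops when the best pair occurs fewer than `min_freq` times or the
#' vocabulary reaches `max_vocab` tokens. Frequency ties are broken by
#' lexicographic order of the fused token, making the result deterministic.
#'
#' The corpus is held as one flat token vector with sequence-boundary
#' sentinels, and pair counts are updated incrementally around the positions a
#' merge touches, so each iteration costs far less than a full recount.
#'
#' @param sequences Character vector of training sequences (SMILES or protein).
#' @param kind `"drug"` or `"protein"`.
#' @param min_freq Minimum corpus frequency for a pair to be fused (>= 2).
#' @param max_vocab Vocabulary size cap (base alphabet + merged tokens + UNK).
#' @return A `dti_vocab` with `alphabet_kind` `"fcs_drug"` or `"fcs_protein"`.
#' @export
fcs_mine <- function(sequences, kind = c("drug", "protein"),
                     min_freq = 5L, max_vocab = if (kind == "drug") 2000L else 10000L) {
  kind <- match.arg(kind)
  if (length(sequences) == 0L) stop("empty corpus")
  stopifnot(min_freq >= 2L)
  alphabet_kind <- if (kind == "drug") "fcs_drug" else "fcs_protein"
  seqs <- base_tokens_for(sequences, alphabet_kind)
  base <- sort(setdiff(unique(unlist(seqs)), UNK_TOKEN))
  if (kind == "protein") base <- sort(union(base, AA_STANDARD))
  if (max_vocab <= length(base)) stop("max_vocab must exceed the base alphabet size")
  # integer-coded corpus: id 0 = boundary sentinel, strings live in `universe`
  universe <- sort(unique(c(unlist(seqs), UNK_TOKEN)))
  unk_id <- match(UNK_TOKEN, universe)
  tok <- unlist(lapply(seqs, function(s) c(match(s, universe), 0L)),
                use.names = FALSE)
  KEY <- 1e6  # pair key l*KEY + r; token ids stay far below KEY
  pair_ok <- function(l, r) l > 0L & r > 0L & l != unk_id & r != unk_id
  count_at <- function(adj) {
    # pair counts at the given adjacency indices (token i next to token i+1)
    adj <- adj[adj >= 1L & adj <= length(tok) - 1L]
    l <- tok[adj]; r <- tok[adj + 1L]
    ok <- pair_ok(l, r)
    if (!any(ok)) return(numeric(0))
    tab <- table(l[ok] * KEY + r[ok])
    stats::setNames(as.numeric(tab), names(tab))
  }
  n <- length(tok)
  cnt <- count_at(seq_len(n - 1L))
  tokens <- base
  merges <- list()
  repeat {
    if (length(tokens) + 1L >= max_vocab) break  # +1 accounts for UNK
    if (length(cnt) == 0L) break
    best_freq <- max(cnt)
    if (best_freq < min_freq) break
    keys <- as.numeric(names(cnt)[cnt == best_freq])
    lids <- as.integer(keys %/% KEY); rids <- as.integer(keys %% KEY)
    fused <- paste0(universe[lids], universe[rids])
    pick <- order(fused, universe[lids], universe[rids], method = "radix")[1L]
    merges[[length(merges) + 1L]] <- c(universe[lids[pick]], universe[rids[pick]])
    f_id <- match(fused[pick], universe)
    if (is.na(f_id)) { universe <- c(universe, fused[pick]); f_id <- length(universe) }
    n <- length(tok)
    hit <- which(tok[-n] == lids[pick] & tok[-1L] == rids[pick])
    keep <- greedy_keep(hit)
    sub <- count_at(unique(c(keep - 1L, keep, keep + 1L)))
    cnt[match(names(sub), names(cnt))] <-
      cnt[match(names(sub), names(cnt))] - sub
    tok[keep] <- f_id
    tok <- tok[-(keep + 1L)]
    np <- keep - (seq_along(keep) - 1L)  # fused-token positions after removal
    add <- count_at(unique(c(np - 1L, np)))
    if (length(add)) {
      m <- match(names(add), names(cnt))
      old <- !is.na(m)
      cnt[m[old]] <- cnt[m[old]] + add[old]
      if (any(!old)) cnt <- c(cnt, add[!old])
    }
    cnt <- cnt[cnt > 0L]
    if (!fused[pick] %in% tokens) tokens <- c(tokens, fused[pick])
  }
  vocabulary(tokens, alphabet_kind, merges = merges)
}

#' Segment a base-token sequence with a mined vocabulary
#'
#' Replays the vocabulary's merge rules, in mining order, over a base-alphabet
#' token list. The concatenation of the output equals the concatenation of the
#' input; characters unseen at mining time become UNK.
#'
#' @param tokens Character vector of base tokens (or a raw string, which is
#'   tokenized according to the vocabulary's alphabet kind).
#' @param vocab A `dti_vocab`.
#' @return Character vector of (possibly fused) tokens.
#' @export
vocab_segment <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "dti_vocab"))
  if (length(tokens) == 1L && !tokens %in% vocab$tokens && nchar(tokens) > 1L) {
    tokens <- base_tokens_for(tokens, vocab$alphabet_kind)[[1]]
  }
  for (m in vocab$merges) tokens <- apply_merge(tokens, m[1L], m[2L])
  known <- tokens %in% vocab$tokens
  tokens[!known] <- UNK_TOKEN
  tokens
}

# Segment many base-token sequences at once: the corpus is flattened with
# boundary sentinels and each merge is replayed in one vectorized pass.
# Result is identical to per-sequence vocab_segment (sentinels block
# cross-sequence pairs).
segment_corpus <- function(token_seqs, vocab) {
  stopifnot(inherits(vocab, "dti_vocab"))
  # integer-coded replay: id 0 = boundary sentinel
  merge_fused <- vapply(vocab$merges, paste0, "", collapse = "")
  universe <- unique(c(unlist(token_seqs, use.names = FALSE),
                       unlist(vocab$merges, use.names = FALSE), merge_fused))
  tok <- unlist(lapply(token_seqs, function(s) c(match(s, universe), 0L)),
                use.names = FALSE)
  for (k in seq_along(vocab$merges)) {
    l <- match(vocab$merges[[k]][1L], universe)
    r <- match(vocab$merges[[k]][2L], universe)
    f <- match(merge_fused[k], universe)
    n <- length(tok)
    hit <- which(tok[-n] == l & tok[-1L] == r)
    if (length(hit) == 0L) next
    keep <- greedy_keep(hit)
    tok[keep] <- f
    tok <- tok[-(keep + 1L)]
  }
  b <- tok == 0L
  out <- c(BOUNDARY_SENTINEL, universe)[tok + 1L]
  out[!b & !out %in% vocab$tokens] <- UNK_TOKEN
  seq_id <- cumsum(b) + 1L
  unname(split(out[!b], factor(seq_id[!b], levels = seq_along(token_seqs))))
}

#' Look up integer labels for tokens
#'
#' @param tokens Character vector of tokens.
#' @param vocab A `dti_vocab`.
#' @return Integer labels; unknown tokens get the UNK label.
#' @export
vocab_labels <- function(tokens, vocab) {
  lab <- unname(vocab$label_of[tokens])
  lab[is.na(lab)] <- vocab$unk_label
  as.integer(lab)
}

#' Write a vocabulary to a delimited text file
#'
#' Two sections: a `token<TAB>label` table and an ordered `left<TAB>right`
#' merge list, separated by a `#merges` marker line.
#'
#' @param vocab A `dti_vocab`.
#' @param path Output file path.
#' @export
write_vocab <- function(vocab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#dti_vocab\t%s\tunk=%d", vocab$alphabet_kind, vocab$unk_label), con)
  writeLines(sprintf("%s\t%d", vocab$tokens, unname(vocab$label_of[vocab$tokens])), con)
  writeLines("#merges", con)
  for (m in vocab$merges) writeLines(sprintf("%s\t%s", m[1L], m[2L]), con)
  invisible(path)
}

#' Read a vocabulary written by [write_vocab()]
#'
#' @param path File path.
#' @return A `dti_vocab`.
#' @export
read_vocab <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (hdr[1L] != "#dti_vocab") stop("not a vocabulary file: ", path)
  unk_label <- as.integer(sub("unk=", "", hdr[3L], fixed = TRUE))
  sep <- which(lines == "#merges")
  tok_lines <- lines[2:(sep - 1L)]
  parts <- strsplit(tok_lines, "\t", fixed = TRUE)
  tokens <- vapply(parts, `[`, "", 1L)
  labels <- as.integer(vapply(parts, `[`, "", 2L))
  merges <- list()
  if (sep < length(lines)) {
    merges <- lapply(strsplit(lines[(sep + 1L):length(lines)], "\t", fixed = TRUE), identity)
  }
  keep <- tokens != UNK_TOKEN
  vocabulary(tokens[keep], hdr[2L], merges = merges, labels = labels[keep],
             unk_label = unk_label)
}
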