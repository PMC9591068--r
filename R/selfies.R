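# SELFIES-style molecular string codec.
#
# Every token is a bracketed word: atom tokens ([C], [=O], [#N], aromatic [c],
# bracket atoms carried verbatim as e.g. [NH3+]), branch tokens ([Branch1]
# [=Branch1] [#Branch1] / [Branch2] ...) followed by index tokens giving the
# branch length in tokens, and ring tokens ([Ring1], [=Ring1], ...) followed by
# index tokens giving the distance (in atoms) back to the ring partner. Index
# values are encoded in a fixed 16-token alphabet, least significant digit
# last, with BranchN/RingN announcing N index tokens. Decoding caps bond
# orders by the remaining valence of both endpoints and drops infeasible ring
# or branch instructions, so any token string yields a structurally sound
# molecule; encoding covers the organic-subset SMILES grammar and raises
# "SELFIES conversion failed" outside it (stereo-free, connected inputs only).

SELFIES_INDEX_ALPHABET <- c(
  "[C]", "[Ring1]", "[Ring2]", "[Branch1]", "[=Branch1]", "[#Branch1]",
  "[Branch2]", "[=Branch2]", "[#Branch2]", "[O]", "[N]", "[=N]", "[=C]",
  "[#C]", "[S]", "[P]"
)

selfies_index_tokens <- function(value, n_tokens) {
  digits <- integer(n_tokens)
  for (i in seq_len(n_tokens)) {
    digits[n_tokens - i + 1L] <- value %% 16L
    value <- value %/% 16L
  }
  if (value > 0L) stop("index overflow in SELFIES encoding")
  SELFIES_INDEX_ALPHABET[digits + 1L]
}

selfies_index_value <- function(tokens) {
  digits <- match(tokens, SELFIES_INDEX_ALPHABET) - 1L
  digits[is.na(digits)] <- 0L
  Reduce(function(acc, d) acc * 16L + d, digits, 0L)
}

bond_prefix <- function(order) switch(as.character(order), "2" = "=", "3" = "#", "")

#' Split a SELFIES string into its bracketed word tokens
#'
#' @param selfies A SELFIES string (concatenated `[...]` words).
#' @return Character vector of tokens, each starting with `[` and ending `]`.
#' @export
selfies_split <- function(selfies) {
  stopifnot(is.character(selfies), length(selfies) == 1L)
  if (is.na(selfies) || nchar(selfies) == 0L) stop("empty sequence")
  toks <- regmatches(selfies, gregexpr("\\[[^][]*\\]", selfies))[[1]]
  if (sum(nchar(toks)) != nchar(selfies)) stop("malformed SELFIES string")
  toks
}

#' Encode a SMILES string as SELFIES tokens
#'
#' Translates the organic-subset SMILES grammar (atoms, bonds, nested branches,
#' rings, aromatics, bracket atoms) into a token list in which every word is a
#' chemically meaningful unit. SMILES outside the supported grammar (stereo
#' bond marks survive as single bonds; disconnected molecules do not) raise
#' `"SELFIES conversion failed"`.
#'
#' @param smiles SMILES string.
#' @return Character vector of SELFIES tokens.
#' @examples
#' selfies_encode("CO")
#' @export
selfies_encode <- function(smiles) {
  mol <- tryCatch(parse_smiles(smiles), error = function(e) NULL)
  if (is.null(mol) || !smiles_is_valid(smiles)) stop("SELFIES conversion failed")
  n <- length(mol$atoms)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      adj[[mol$bonds$from[k]]] <- c(adj[[mol$bonds$from[k]]], k)
      adj[[mol$bonds$to[k]]] <- c(adj[[mol$bonds$to[k]]], k)
    }
  }
  visited <- logical(n)
  tree_edge <- logical(nrow(mol$bonds))
  emit_order <- integer(0)  # atom index -> position in emission order
  span <- function(a) {
    visited[a] <<- TRUE
    for (k in adj[[a]]) {
      other <- if (mol$bonds$from[k] == a) mol$bonds$to[k] else mol$bonds$from[k]
      if (!visited[other]) { tree_edge[k] <<- TRUE; span(other) }
    }
  }
  span(1L)
  if (!all(visited)) stop("SELFIES conversion failed")  # disconnected molecule
  atom_token <- function(a, order) {
    at <- mol$atoms[[a]]
    if (!is.na(at$bracket)) return(paste0("[", bond_prefix(order), at$bracket, "]"))
    sym <- if (at$aromatic) tolower(at$symbol) else at$symbol
    paste0("[", bond_prefix(order), sym, "]")
  }
  pos <- integer(n)       # atom -> 1-based emission position
  counter <- 0L
  visited <- logical(n)
  ring_done <- logical(nrow(mol$bonds))
  encode_atom <- function(a, in_order) {
    visited[a] <<- TRUE
    counter <<- counter + 1L
    pos[a] <<- counter
    out <- atom_token(a, in_order)
    # ring closures whose both endpoints are now emitted
    for (k in adj[[a]]) {
      if (tree_edge[k] || ring_done[k]) next
      other <- if (mol$bonds$from[k] == a) mol$bonds$to[k] else mol$bonds$from[k]
      if (!visited[other]) next
      ring_done[k] <<- TRUE
      ord <- mol$bonds$order[k]
      dist <- pos[a] - pos[other] - 1L
      nidx <- if (dist < 16L) 1L else if (dist < 256L) 2L else 3L
      ring_word <- paste0("[", bond_prefix(if (mol$bonds$aromatic[k]) 1 else ord),
                          "Ring", nidx, "]")
      out <- c(out, ring_word, selfies_index_tokens(dist, nidx))
    }
    kids <- integer(0)
    for (k in adj[[a]]) {
      if (!tree_edge[k]) next
      other <- if (mol$bonds$from[k] == a) mol$bonds$to[k] else mol$bonds$from[k]
      if (!visited[other]) kids <- c(kids, k)
    }
    for (i in seq_along(kids)) {
      k <- kids[i]
      other <- if (mol$bonds$from[k] == a) mol$bonds$to[k] else mol$bonds$from[k]
      ord <- if (mol$bonds$aromatic[k]) 1 else mol$bonds$order[k]
      sub <- encode_atom(other, ord)
      if (i < length(kids)) {
        len <- length(sub)
        nidx <- if (len <= 16L) 1L else if (len <= 256L) 2L else 3L
        out <- c(out,
                 paste0("[", bond_prefix(ord), "Branch", nidx, "]"),
                 selfies_index_tokens(len - 1L, nidx),
                 sub)
      } else {
        out <- c(out, sub)
      }
    }
    out
  }
  encode_atom(1L, 1)
}

# remaining valence capacity of an atom in a partially built graph
remaining_valence <- function(mol, sums, a) {
  at <- mol$atoms[[a]]
  base <- if (!is.na(at$bracket)) 8  # bracket atoms: permissive
          else unname(MAX_VALENCE[at$symbol])
  if (is.na(base)) base <- 8  # symbols outside the table (decode pseudo-atoms)
  base - sums[a]
}

#' Decode SELFIES tokens back to a molecule
#'
#' Robust decoding: bond orders are capped by the remaining valence of both
#' endpoints, rings whose partner does not exist are dropped, and branch
#' lengths are clipped to the remaining token stream, so every token sequence
#' decodes to a structurally sound molecule.
#'
#' @param tokens Character vector of SELFIES tokens (or a single SELFIES
#'   string, which is split first).
#' @return A SMILES string for the decoded molecule.
#' @export
selfies_decode <- function(tokens) {
  if (length(tokens) == 1L && !grepl("^\\[[^][]*\\]$", tokens)) {
    tokens <- selfies_split(tokens)
  }
  mol <- list(atoms = list(),
              bonds = data.frame(from = integer(0), to = integer(0),
                                 order = numeric(0), aromatic = logical(0)))
  sums <- numeric(0)
  add_atom <- function(tok) {
    body <- sub("^\\[", "", sub("\\]$", "", tok))
    ord <- 1
    if (startsWith(body, "=")) { ord <- 2; body <- substring(body, 2L) }
    else if (startsWith(body, "#")) { ord <- 3; body <- substring(body, 2L) }
    if (nchar(body) == 0L) return(NULL)
    if (body %in% c(ORGANIC_ATOMS, AROMATIC_ATOMS)) {
      arom <- body %in% AROMATIC_ATOMS
      at <- atom_record(if (arom) toupper(body) else body, arom)
    } else {
      sym <- regmatches(body, regexpr("^[0-9]*([A-Z][a-z]?|[a-z])", body))
      sym <- sub("^[0-9]*", "", sym)
      if (length(sym) == 0L || nchar(sym) == 0L) return(NULL)
      at <- atom_record(if (sym %in% AROMATIC_ATOMS) toupper(sym) else sym,
                        sym %in% AROMATIC_ATOMS, bracket = body)
    }
    mol$atoms[[length(mol$atoms) + 1L]] <<- at
    sums <<- c(sums, 0)
    list(idx = length(mol$atoms), order = ord)
  }
  connect <- function(i, j, ord, aromatic = FALSE) {
    cap <- min(remaining_valence(mol, sums, i), remaining_valence(mol, sums, j))
    ord <- min(ord, max(cap, 0))
    if (ord < 1) return(FALSE)
    mol$bonds <<- rbind(mol$bonds, data.frame(from = i, to = j, order = ord,
                                              aromatic = aromatic && ord == 1))
    sums[i] <<- sums[i] + ord; sums[j] <<- sums[j] + ord
    TRUE
  }
  # decode `tokens[pos..]` for up to `budget` tokens starting from atom `anchor`
  decode_stream <- function(pos, budget, anchor) {
    used <- 0L
    current <- anchor
    while (used < budget && pos <= length(tokens)) {
      tok <- tokens[pos]
      m <- regmatches(tok, regexec("^\\[(=|#)?(Branch|Ring)([1-3])\\]$", tok))[[1]]
      if (length(m) > 0L && current > 0L) {
        ord <- switch(m[2], "=" = 2, "#" = 3, 1)
        nidx <- as.integer(m[4])
        idx_tokens <- tokens[seq.int(pos + 1L, length.out = min(nidx, length(tokens) - pos))]
        value <- selfies_index_value(idx_tokens)
        consumed <- 1L + length(idx_tokens)
        pos <- pos + consumed; used <- used + consumed
        if (m[3] == "Ring") {
          partner <- current - value - 1L
          if (partner >= 1L) {
            arom <- mol$atoms[[current]]$aromatic && mol$atoms[[partner]]$aromatic
            connect(current, partner, if (arom) 1 else ord, aromatic = arom)
          }
        } else {
          blen <- min(value + 1L, budget - used, length(tokens) - pos + 1L)
          if (blen > 0L) {
            res <- decode_stream(pos, blen, -current)  # negative: branch from current with stated order
            # branch's first bond order is carried via attr below
            pos <- pos + res$used; used <- used + res$used
          }
        }
        next
      }
      res <- add_atom(tok)
      pos <- pos + 1L; used <- used + 1L
      if (is.null(res)) next
      if (current != 0L) {
        anchor_atom <- abs(current)
        ok <- connect(anchor_atom, res$idx, res$order,
                      aromatic = mol$atoms[[anchor_atom]]$aromatic &&
                        mol$atoms[[res$idx]]$aromatic && res$order == 1)
        if (!ok && length(mol$atoms) > 1L) {
          # no capacity: drop the atom we just added
          mol$atoms[[res$idx]] <<- NULL
          sums <<- sums[-res$idx]
          next
        }
      }
      current <- res$idx
    }
    list(used = used)
  }
  decode_stream(1L, length(tokens), 0L)
  if (length(mol$atoms) == 0L) stop("SELFIES decoded to an empty molecule")
  write_smiles(mol)
}
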