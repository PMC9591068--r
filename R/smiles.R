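# Minimal molecular-graph SMILES parser/writer for the organic subset.
# Powers SMILES validity filtering and the SELFIES codec. Not a general
# cheminformatics toolkit: stereo bond marks (/ \) are read as single bonds,
# bracket-atom bodies are carried verbatim, and disconnected structures (.)
# are parsed but rejected by the SELFIES encoder.

ORGANIC_ATOMS <- c("Br", "Cl", "B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_ATOMS <- c("b", "c", "n", "o", "p", "s")

# Default valences used for sanity checks and decode-time capping.
MAX_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 5, S = 6,
                 F = 1, Cl = 1, Br = 1, I = 1)

atom_record <- function(symbol, aromatic, bracket = NA_character_) {
  list(symbol = symbol, aromatic = aromatic, bracket = bracket)
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (bare atoms B C N O P S F Cl Br I and their
#' aromatic forms), bracket atoms (body kept verbatim), single/double/triple/
#' aromatic bonds, nested branches, and ring-closure digits including `%nn`.
#'
#' @param smiles SMILES string.
#' @return A list with `atoms` (list of atom records in written order) and
#'   `bonds` (data frame `from`, `to`, `order`, `aromatic`), or an error if the
#'   string is not parseable.
#' @keywords internal
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || nchar(smiles) == 0L) stop("empty SMILES")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list(from = integer(0), to = integer(0), order = numeric(0),
                aromatic = logical(0))
  add_bond <- function(i, j, order, aromatic) {
    bonds$from <<- c(bonds$from, i); bonds$to <<- c(bonds$to, j)
    bonds$order <<- c(bonds$order, order); bonds$aromatic <<- c(bonds$aromatic, aromatic)
  }
  prev <- 0L           # atom the next bond attaches to (0 = none yet)
  stack <- integer(0)  # branch stack
  pending_bond <- NA_real_
  ring_open <- list()  # digit -> c(atom, bond order)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (ch == "(") {
      if (prev == 0L) stop("branch before any atom")
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "/", "\\", "=", "#", ":")) {
      if (!is.na(pending_bond)) stop("consecutive bond symbols")
      pending_bond <- switch(ch, "=" = 2, "#" = 3, ":" = 1.5, 1)
      i <- i + 1L; next
    }
    if (ch == ".") {
      if (!is.na(pending_bond)) stop("bond before '.'")
      prev <- 0L; i <- i + 1L; next
    }
    if (grepl("^[0-9]$", ch) || ch == "%") {
      if (prev == 0L) stop("ring closure before any atom")
      if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
          stop("malformed %nn ring closure")
        digit <- paste0("%", chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { digit <- ch; i <- i + 1L }
      if (!is.null(ring_open[[digit]])) {
        op <- ring_open[[digit]]
        if (op[[1]] == prev) stop("self ring closure")
        ord <- if (!is.na(pending_bond)) pending_bond else op[[2]]
        arom <- atoms[[prev]]$aromatic && atoms[[op[[1]]]]$aromatic && ord == 1
        add_bond(op[[1]], prev, if (arom) 1.5 else ord, arom)
        ring_open[[digit]] <- NULL
      } else {
        ring_open[[digit]] <- list(prev, if (is.na(pending_bond)) 1 else pending_bond)
      }
      pending_bond <- NA_real_
      next
    }
    if (ch == "[") {
      close <- NA_integer_
      for (j in (i + 1L):n) if (chars[j] == "]") { close <- j; break }
      if (is.na(close)) stop("unterminated bracket atom")
      body <- paste0(chars[(i + 1L):(close - 1L)], collapse = "")
      if (nchar(body) == 0L) stop("empty bracket atom")
      sym <- regmatches(body, regexpr("^[0-9]*([A-Z][a-z]?|[a-z])", body))
      sym <- sub("^[0-9]*", "", sym)
      if (length(sym) == 0L || nchar(sym) == 0L) stop("bad bracket atom: [", body, "]")
      arom <- sym %in% AROMATIC_ATOMS
      atoms[[length(atoms) + 1L]] <- atom_record(
        if (arom) toupper(sym) else sym, arom, bracket = body)
      idx <- length(atoms)
      if (prev > 0L) {
        ord <- if (is.na(pending_bond)) 1 else pending_bond
        ar <- arom && atoms[[prev]]$aromatic && ord == 1
        add_bond(prev, idx, if (ar) 1.5 else ord, ar)
      }
      prev <- idx; pending_bond <- NA_real_; i <- close + 1L; next
    }
    sym <- if (two %in% ORGANIC_ATOMS) two else if (ch %in% c(ORGANIC_ATOMS, AROMATIC_ATOMS)) ch else NULL
    if (is.null(sym)) stop("unexpected character '", ch, "' in SMILES")
    arom <- sym %in% AROMATIC_ATOMS
    atoms[[length(atoms) + 1L]] <- atom_record(if (arom) toupper(sym) else sym, arom)
    idx <- length(atoms)
    if (prev > 0L) {
      ord <- if (is.na(pending_bond)) 1 else pending_bond
      ar <- arom && atoms[[prev]]$aromatic && ord == 1
      add_bond(prev, idx, if (ar) 1.5 else ord, ar)
    }
    prev <- idx; pending_bond <- NA_real_
    i <- i + nchar(sym)
  }
  if (length(stack) > 0L) stop("unbalanced '('")
  if (length(ring_open) > 0L) stop("unclosed ring bond")
  if (!is.na(pending_bond)) stop("dangling bond symbol")
  if (length(atoms) == 0L) stop("no atoms in SMILES")
  list(atoms = atoms,
       bonds = data.frame(from = bonds$from, to = bonds$to,
                          order = bonds$order, aromatic = bonds$aromatic))
}

# Sum of bond orders incident to each atom (aromatic bonds as 1.5).
atom_bond_sums <- function(mol) {
  s <- numeric(length(mol$atoms))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$from[k]] <- s[mol$bonds$from[k]] + mol$bonds$order[k]
      s[mol$bonds$to[k]] <- s[mol$bonds$to[k]] + mol$bonds$order[k]
    }
  }
  s
}

#' Check whether a string is a parseable, valence-sane SMILES
#'
#' Syntax is checked by the organic-subset parser; bare (non-bracket) atoms are
#' additionally checked against standard maximum valences. Bracket atoms carry
#' explicit hydrogen/charge information and are trusted syntactically.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector.
#' @examples
#' smiles_is_valid(c("CCO", "not_a_smiles"))
#' @export
smiles_is_valid <- function(smiles) {
  vapply(smiles, function(s) {
    mol <- tryCatch(parse_smiles(s), error = function(e) NULL)
    if (is.null(mol)) return(FALSE)
    sums <- atom_bond_sums(mol)
    for (a in seq_along(mol$atoms)) {
      at <- mol$atoms[[a]]
      if (!is.na(at$bracket)) next
      if (sums[a] > MAX_VALENCE[[at$symbol]] + 1e-9) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# Write a molecular graph back to a SMILES string. DFS in atom-creation order;
# non-tree (back) edges become ring-closure digits planted at both endpoints.
write_smiles <- function(mol) {
  n <- length(mol$atoms)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      f <- mol$bonds$from[k]; t <- mol$bonds$to[k]
      adj[[f]] <- c(adj[[f]], k); adj[[t]] <- c(adj[[t]], k)
    }
  }
  bond_sym <- function(k) {
    b <- mol$bonds[k, ]
    if (b$aromatic) return("")
    switch(as.character(b$order), "1" = "", "2" = "=", "3" = "#", "1.5" = ":", "")
  }
  atom_str <- function(a) {
    at <- mol$atoms[[a]]
    if (!is.na(at$bracket)) return(paste0("[", at$bracket, "]"))
    if (at$aromatic) tolower(at$symbol) else at$symbol
  }
  # spanning forest: classify edges as tree/back
  visited <- logical(n)
  tree_edge <- logical(nrow(mol$bonds))
  span <- function(a) {
    visited[a] <<- TRUE
    for (k in adj[[a]]) {
      b <- mol$bonds[k, ]
      other <- if (b$from == a) b$to else b$from
      if (!visited[other]) { tree_edge[k] <<- TRUE; span(other) }
    }
  }
  roots <- integer(0)
  for (a in seq_len(n)) if (!visited[a]) { roots <- c(roots, a); span(a) }
  back <- which(!tree_edge)
  ring_digit <- integer(nrow(mol$bonds))
  ring_digit[back] <- seq_along(back)
  digit_opened <- logical(nrow(mol$bonds))
  digit_str <- function(d) if (d <= 9L) as.character(d) else sprintf("%%%02d", d)
  visited <- logical(n)
  write_atom <- function(a, in_edge) {
    visited[a] <<- TRUE
    s <- if (is.na(in_edge)) "" else bond_sym(in_edge)
    s <- paste0(s, atom_str(a))
    for (k in adj[[a]]) {
      if (tree_edge[k]) next
      if (!digit_opened[k]) {
        digit_opened[k] <<- TRUE
        s <- paste0(s, bond_sym(k), digit_str(ring_digit[k]))
      } else {
        s <- paste0(s, digit_str(ring_digit[k]))
      }
    }
    kids <- integer(0)
    for (k in adj[[a]]) {
      if (!tree_edge[k]) next
      b <- mol$bonds[k, ]
      other <- if (b$from == a) b$to else b$from
      if (!visited[other]) kids <- c(kids, k)
    }
    for (i in seq_along(kids)) {
      b <- mol$bonds[kids[i], ]
      other <- if (b$from == a) b$to else b$from
      child <- write_atom(other, kids[i])
      s <- if (i < length(kids)) paste0(s, "(", child, ")") else paste0(s, child)
    }
    s
  }
  paste(vapply(roots, function(r) write_atom(r, NA_integer_), ""), collapse = ".")
}

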