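test_that("character and residue tokenization", {
  expect_identical(tokenize_smiles_chars("CN=C=O"),
                   c("C", "N", "=", "C", "=", "O"))
  expect_identical(tokenize_smiles_chars("Cl"), c("C", "l"))
  expect_identical(tokenize_protein("MKVX"), c("M", "K", "V", "<unk>"))
  expect_error(tokenize_smiles_chars(""), "empty")
  expect_error(tokenize_protein(""), "empty")
})

test_that("vocabulary construction and lookup", {
  v <- vocabulary(c("C", "N", "O"), "smiles_char")
  expect_s3_class(v, "dti_vocab")
  expect_identical(v$pad_label, 0L)
  expect_identical(unname(v$label_of["<unk>"]), 1L)
  expect_identical(vocab_labels(c("C", "O", "Zz"), v),
                   c(unname(v$label_of["C"]), unname(v$label_of["O"]), 1L))
  expect_error(vocabulary(c("C", "C"), "smiles_char"), "duplicate")
})

test_that("pair counting counts every adjacent occurrence", {
  seqs <- lapply(c("ABAB", "ABAB", "ABCD"), function(s) strsplit(s, "")[[1]])
  cnt <- dticross:::count_pairs(seqs)
  expect_identical(unname(cnt[paste("A", "B", sep = "\x1f")]), 5L)
  expect_identical(unname(cnt[paste("B", "A", sep = "\x1f")]), 2L)
  # "AAA" contributes the AA pair twice
  cnt2 <- dticross:::count_pairs(list(c("A", "A", "A")))
  expect_identical(unname(cnt2[paste("A", "A", sep = "\x1f")]), 2L)
})

test_that("merge application is greedy left-to-right non-overlapping", {
  expect_identical(dticross:::apply_merge(c("A", "A", "A"), "A", "A"),
                   c("AA", "A"))
  expect_identical(dticross:::apply_merge(c("A", "A", "A", "A"), "A", "A"),
                   c("AA", "AA"))
  expect_identical(dticross:::apply_merge(c("C", "N", "C", "N"), "C", "N"),
                   c("CN", "CN"))
  expect_identical(dticross:::apply_merge(c("X"), "A", "B"), "X")
})

test_that("incremental miner matches the naive full-recount oracle", {
  set.seed(42)
  for (trial in 1:6) {
    n <- sample(5:30, 1)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "D", "E", "G", "K"), sample(4:50, 1),
                   replace = TRUE), collapse = "")
    }, "")
    got <- fcs_mine(seqs, "protein", min_freq = 2L, max_vocab = 60L)
    ref <- naive_fcs_mine(seqs, "protein", min_freq = 2L, max_vocab = 60L)
    expect_identical(setdiff(got$tokens, "<unk>"), ref$tokens)
    expect_identical(got$merges, ref$merges)
    # segmentation by merge replay reproduces the mined corpus state
    seg <- lapply(seqs, function(s) vocab_segment(tokenize_protein(s), got))
    expect_identical(seg, ref$segmented)
  }
})

test_that("mining respects min_freq and max_vocab", {
  seqs <- rep("MKMKMK", 4)  # MK occurs 12 times
  v <- fcs_mine(seqs, "protein", min_freq = 13L, max_vocab = 100L)
  expect_length(v$merges, 0)
  v2 <- fcs_mine(seqs, "protein", min_freq = 2L, max_vocab = 22L)
  expect_lte(length(v2$tokens), 22L)
  expect_error(fcs_mine(seqs, "protein", min_freq = 2L, max_vocab = 10L),
               "max_vocab")
})

test_that("protein base alphabet always covers the 20 standard residues", {
  v <- fcs_mine(c("MMMM", "KKKK"), "protein", min_freq = 2L, max_vocab = 30L)
  expect_true(all(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]] %in% v$tokens))
})

test_that("segmentation concatenation invariant and UNK fallback", {
  seqs <- c("CCOCCO", "CCNCCN", "CCOCCN", "COCCOC")
  v <- fcs_mine(seqs, "drug", min_freq = 2L, max_vocab = 40L)
  for (s in c(seqs, "CCOCC")) {
    seg <- vocab_segment(tokenize_smiles_chars(s), v)
    expect_identical(paste(seg, collapse = ""), s)
  }
  # a character unseen at mining time becomes UNK
  seg <- vocab_segment(tokenize_smiles_chars("CCS"), v)
  expect_true("<unk>" %in% seg)
})

test_that("corpus-level segmentation equals per-sequence replay", {
  set.seed(7)
  seqs <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(3:40, 1), replace = TRUE),
          collapse = "")
  }, "")
  v <- fcs_mine(seqs, "protein", min_freq = 2L, max_vocab = 50L)
  base <- lapply(seqs, tokenize_protein)
  got <- dticross:::segment_corpus(base, v)
  ref <- lapply(base, vocab_segment, vocab = v)
  expect_identical(got, ref)
})

test_that("vocabulary files round-trip", {
  v <- fcs_mine(c("CCOCCO", "CCNCCN"), "drug", min_freq = 2L, max_vocab = 30L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vocab(v, path)
  v2 <- read_vocab(path)
  expect_identical(v2$tokens, v$tokens)
  expect_identical(v2$label_of, v$label_of)
  expect_identical(v2$merges, v$merges)
  expect_identical(v2$alphabet_kind, v$alphabet_kind)
})
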