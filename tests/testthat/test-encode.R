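test_that("label encoding pads and truncates at fixed length", {
  v <- vocabulary(c("C", "N", "O"), "smiles_char")
  lv <- label_encode(c("C", "N"), v, 5L)
  expect_length(unclass(lv), 5L)
  expect_identical(attr(lv, "true_len"), 2L)
  expect_identical(unclass(lv)[3:5], rep(0L, 3))
  long <- label_encode(rep("C", 9), v, 4L)
  expect_identical(attr(long, "true_len"), 4L)
  expect_length(unclass(long), 4L)
})

test_that("learned embedding adds token and positional rows", {
  set.seed(1)
  v <- vocabulary(c("C", "N"), "smiles_char")
  tokt <- embedding_init(4L, 6L)
  post <- embedding_init(3L, 6L)
  lv <- label_encode(c("C", "N"), v, 3L)
  E <- embed_learned(lv, tokt, post)
  labs <- unclass(lv)
  for (i in 1:3)
    expect_equal(E[i, ], tokt[labs[i] + 1L, ] + post[i, ], ignore_attr = TRUE)
  expect_identical(attr(E, "mask"), c(TRUE, TRUE, FALSE))
})

test_that("one-hot embedding has unit rows on real positions, zero on PAD", {
  v <- vocabulary(c("C", "N", "O"), "smiles_char")
  lv <- label_encode(c("O", "C"), v, 4L)
  E <- embed_onehot(lv, v)
  expect_identical(dim(E), c(4L, 4L))  # 3 tokens + UNK
  expect_equal(rowSums(E), c(1, 1, 0, 0), ignore_attr = TRUE)
  expect_equal(sum(E[1, ] * E[2, ]), 0)
})

test_that("vocabulary builders cover all five schemes", {
  smiles <- c("CCO", "CN=C=O", "CCNCC")
  prots <- c("MKVLAA", "ACDEFGH")
  for (scheme in c("smiles_embed", "smiles_onehot")) {
    vb <- build_vocabularies(smiles, prots, scheme)
    expect_true(all(c("C", "N", "O", "=") %in% vb$drug$tokens))
    expect_identical(vb$protein$alphabet_kind, "aa_letter")
  }
  vb <- build_vocabularies(smiles, prots, "selfies_embed")
  expect_true(all(grepl("^\\[.+\\]$", setdiff(vb$drug$tokens, "<unk>"))))
  vb <- build_vocabularies(smiles, prots, "fcs_embed", min_freq = 2L)
  expect_identical(vb$drug$alphabet_kind, "fcs_drug")
  expect_identical(vb$protein$alphabet_kind, "fcs_protein")
})

test_that("encode_label_matrix records true lengths and covering spans", {
  v <- fcs_mine(c("CCOCCO", "CCNCCO"), "drug", min_freq = 2L, max_vocab = 30L)
  tk <- dticross:::scheme_tokenizers("fcs_embed")
  enc <- dticross:::encode_label_matrix(c("CCOCCO", "CCN"), v, 8L, tk$drug)
  expect_identical(dim(enc$labels), c(2L, 8L))
  for (i in 1:2) {
    sp <- enc$spans[[i]]
    expect_identical(unname(sp[1, "start"]), 1L)
    # spans tile the encoded prefix without gaps
    expect_identical(unname(sp[, "start"]),
                     unname(cumsum(c(1L, utils::head(sp[, "width"], -1L)))))
  }
  expect_identical(sum(enc$spans[[2]][, "width"]), 3L)
})
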