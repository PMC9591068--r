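test_that("the generator is byte-identical under a fixed seed", {
  sp <- synthetic_spec(n_pairs = 40L, rho = 0.1)
  d1 <- synthetic_dataset(sp, seed = 11L)
  d2 <- synthetic_dataset(sp, seed = 11L)
  expect_identical(d1, d2)
  d3 <- synthetic_dataset(sp, seed = 12L)
  expect_false(identical(d1$sequence, d3$sequence))
})

test_that("class counts follow the imbalance ratio", {
  d <- synthetic_dataset(synthetic_spec(n_pairs = 100L, rho = 0), seed = 2L)
  expect_identical(sum(d$rule_label == 1), 50L)
  d20 <- synthetic_dataset(synthetic_spec(n_pairs = 105L, rho = 0,
                                          imbalance = 20), seed = 2L)
  expect_identical(sum(d20$rule_label == 1), 5L)
  expect_identical(sum(d20$rule_label == 0), 100L)
})

test_that("every generated SMILES is chemically parseable", {
  d <- synthetic_dataset(synthetic_spec(n_pairs = 80L), seed = 3L)
  expect_true(all(smiles_is_valid(d$smiles)))
})

test_that("lengths respect the configured ranges", {
  sp <- synthetic_spec(n_pairs = 60L, protein_len = c(50L, 70L),
                       drug_len = c(8L, 30L))
  d <- synthetic_dataset(sp, seed = 4L)
  expect_true(all(nchar(d$sequence) >= 50 & nchar(d$sequence) <= 70))
  expect_true(all(nchar(d$smiles) <= 30))
})

test_that("with rho = 0 the labels equal the rule labels", {
  d <- synthetic_dataset(synthetic_spec(n_pairs = 60L, rho = 0), seed = 5L)
  expect_identical(d$label, d$rule_label)
})

test_that("rho flips roughly the expected fraction of labels", {
  d <- synthetic_dataset(synthetic_spec(n_pairs = 1000L, rho = 0.3), seed = 6L)
  expect_lt(abs(mean(d$label != d$rule_label) - 0.3), 0.05)
})

test_that("the rule requires both motifs; negatives cover all miss cases", {
  sp <- synthetic_spec(n_pairs = 120L, rho = 0)
  d <- synthetic_dataset(sp, seed = 7L)
  prot_has <- grepl(sp$protein_motif, d$sequence, fixed = TRUE)
  drug_has <- grepl(sp$drug_motif, d$smiles, fixed = TRUE)
  expect_true(all(prot_has[d$rule_label == 1]))
  expect_true(all(drug_has[d$rule_label == 1]))
  expect_true(all(!(prot_has & drug_has)[d$rule_label == 0]))
  # neither motif alone determines the label
  expect_gt(sum(prot_has & d$rule_label == 0), 0L)
  expect_gt(sum(drug_has & d$rule_label == 0), 0L)
  expect_gt(sum(!prot_has & !drug_has & d$rule_label == 0), 0L)
})

test_that("binding sites point exactly at the planted motif", {
  sp <- synthetic_spec(n_pairs = 60L, rho = 0)
  d <- synthetic_dataset(sp, seed = 8L)
  m <- nchar(sp$protein_motif)
  has <- !is.na(d$binding_sites)
  expect_true(all(has == grepl(sp$protein_motif, d$sequence, fixed = TRUE)))
  for (i in which(has)) {
    pos <- as.integer(strsplit(d$binding_sites[i], ",")[[1]])
    expect_length(pos, m)
    expect_identical(pos, seq.int(pos[1], pos[1] + m - 1L))
    expect_identical(substr(d$sequence[i], pos[1], pos[m]), sp$protein_motif)
  }
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(protein_motif = "HKWCYFDE",
                              protein_len = c(5L, 20L)),
               "motif longer")
  expect_error(synthetic_spec(drug_motif = "N=C=O", drug_len = c(2L, 6L)),
               "does not fit")
  expect_error(synthetic_spec(rho = 0.5), "rho")
  expect_error(synthetic_spec(protein_motif = "HKB2"))
})
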