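test_that("expand_attention broadcasts token weights over character spans", {
  W <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)  # protein tokens x drug tokens
  prot_spans <- cbind(start = c(1L, 3L), width = c(2L, 1L))
  drug_spans <- cbind(start = c(1L, 2L), width = c(1L, 2L))
  M <- expand_attention(W, prot_spans, drug_spans)
  expect_identical(dim(M), c(3L, 3L))
  # residues 1-2 come from protein token 1, residue 3 from token 2;
  # atom 1 from drug token 1, atoms 2-3 from drug token 2
  expect_equal(unclass(M),
               matrix(c(0.1, 0.1, 0.3, 0.2, 0.2, 0.4, 0.2, 0.2, 0.4), 3, 3),
               ignore_attr = TRUE)
  expect_error(expand_attention(W, prot_spans[1, , drop = FALSE], drug_spans),
               "inconsistent")
})

test_that("top_sites ranks by weight with (residue, atom) tie-breaking", {
  M <- matrix(c(0.5, 0.5, 0.2, 0.5), 2, 2)
  s <- top_sites(M, k = 4L)
  expect_identical(s$residue, c(1L, 2L, 2L, 1L))
  expect_identical(s$atom, c(1L, 1L, 2L, 2L))
  expect_equal(s$weight, c(0.5, 0.5, 0.5, 0.2))
  expect_warning(top_sites(M, k = 10L), "exceeds")
})

test_that("consistency_number counts sites on binding residues", {
  sites <- data.frame(residue = c(3L, 7L, 3L, 9L), atom = 1:4,
                      weight = c(0.4, 0.3, 0.2, 0.1))
  expect_identical(consistency_number(sites, c(3L, 9L)), 3L)
  expect_identical(consistency_number(sites, integer(0)), 0L)
})

test_that("the permutation null mean matches k*b/L within 3 MC standard errors", {
  set.seed(41)
  L <- c(40L, 50L, 60L); b <- c(5L, 8L, 10L); k <- 30L
  sites <- lapply(L, function(l) {
    data.frame(residue = sample.int(l, k, replace = TRUE),
               atom = seq_len(k), weight = runif(k))
  })
  prof <- null_profile(sites, L, b, iterations = 4000L, seed = 2L)
  expected <- mean(k * b / L)
  se <- stats::sd(prof$draws) / sqrt(length(prof$draws))
  expect_lt(abs(prof$mean - expected), 3 * se + 1e-12)
})

test_that("the null matches exact enumeration for a short protein", {
  set.seed(42)
  L <- 8L; b <- 3L
  sites <- data.frame(residue = c(1L, 1L, 2L, 5L, 5L, 5L, 8L),
                      atom = 1:7, weight = runif(7))
  cnt <- tabulate(sites$residue, nbins = L)
  combos <- utils::combn(L, b)
  exact <- apply(combos, 2, function(s) sum(cnt[s]))
  expect_equal(mean(exact), nrow(sites) * b / L, tolerance = 1e-12)
  prof <- null_profile(list(sites), L, b, iterations = 6000L, seed = 3L)
  se <- stats::sd(prof$draws) / sqrt(length(prof$draws))
  expect_lt(abs(prof$mean - mean(exact)), 3 * se + 1e-12)
  # uniform sampling: the null sd approaches the enumeration sd
  expect_lt(abs(prof$sd - stats::sd(exact)), 0.15)
})

test_that("a full binding set makes the null degenerate", {
  sites <- data.frame(residue = c(1L, 2L, 2L), atom = 1:3, weight = c(3, 2, 1))
  prof <- null_profile(list(sites), 2L, 2L, iterations = 50L, seed = 1L)
  expect_identical(prof$sd, 0)
  expect_equal(prof$mean, 3)
  expect_error(z_score(3, prof), "zero spread")
})

test_that("z_score is the standardised distance and reproduces the worked example", {
  expect_equal(z_score(5, list(mean = 3, sd = 2)), 1)
  # observed mean 2.020 against null mean 1.64, sd 0.119
  expect_equal(z_score(2.020, list(mean = 1.64, sd = 0.119)), 3.186,
               tolerance = 0.005)
})

test_that("null_profile validates its inputs and is seed-reproducible", {
  sites <- data.frame(residue = c(1L, 3L), atom = 1:2, weight = c(2, 1))
  expect_error(null_profile(list(sites), 4L, 6L), "exceeds protein length")
  p1 <- null_profile(list(sites), 6L, 2L, iterations = 200L, seed = 7L)
  p2 <- null_profile(list(sites), 6L, 2L, iterations = 200L, seed = 7L)
  expect_identical(p1$draws, p2$draws)
})

test_that("the end-to-end analysis, top-k sweep and shift analysis cohere", {
  ds <- split_dataset(tiny_dti(), seed = 2L)
  ck <- train_dti(ds, arch = "CA_P", scheme = "smiles_embed",
                  max_len_drug = 12L, max_len_protein = 40L, hidden = 8L,
                  heads = 2L, epochs = 1L, batch_size = 16L, seed = 4L,
                  head_opts = list(channels = c(5L, 4L)))
  an <- attention_site_analysis(ck, ds, k = 10L, iterations = 200L, seed = 5L)
  expect_s3_class(an, "attention_analysis")
  expect_length(an$consistency,
                sum(!is.na(ds$binding_sites) & nzchar(ds$binding_sites)))
  expect_equal(an$observed_mean, mean(an$consistency))
  expect_equal(an$z, (an$observed_mean - an$null$mean) / an$null$sd)
  tk <- topk_sensitivity(an, k_values = c(5L, 10L), iterations = 200L, seed = 5L)
  expect_identical(tk$k, c(5L, 10L))
  # consistency cannot decrease as more sites are admitted
  expect_true(all(diff(tk$consistency) >= 0))
  expect_equal(tk$consistency[tk$k == 10L], an$observed_mean)
  sh <- shift_analysis(an, shifts = -1:1, iterations = 200L, seed = 5L)
  expect_identical(sh$shift, -1:1)
  expect_equal(sh$consistency[sh$shift == 0L], an$observed_mean)
  expect_true(all(is.finite(sh$z)))
})

test_that("binding residues beyond the encoded prefix are excluded with a message", {
  ds <- split_dataset(tiny_dti(), seed = 2L)
  ck <- train_dti(ds, arch = "CA_P", scheme = "smiles_embed",
                  max_len_drug = 12L, max_len_protein = 15L, hidden = 8L,
                  heads = 2L, epochs = 1L, batch_size = 16L, seed = 4L,
                  head_opts = list(channels = c(5L, 4L)))
  expect_message(
    dticross:::collect_attention_maps(ck, ds),
    "beyond the encoded protein prefix"
  )
})

test_that("parse_positions handles both separators and blanks", {
  expect_identical(dticross:::parse_positions("3,5,9"), c(3L, 5L, 9L))
  expect_identical(dticross:::parse_positions("3;5"), c(3L, 5L))
  expect_identical(dticross:::parse_positions(NA_character_), integer(0))
  expect_identical(dticross:::parse_positions(""), integer(0))
})
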