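make_small_model <- function(arch, heads = 2L, head_opts = list(channels = c(5L, 4L)),
                             scheme = "smiles_embed", seed = 7L) {
  set.seed(seed)
  vd <- vocabulary(c("C", "N", "O", "="), "smiles_char")
  vp <- vocabulary(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "aa_letter")
  dti_model(vd, vp, arch = arch, scheme = scheme, max_len_drug = 8L,
            max_len_protein = 12L, hidden = 8L, heads = heads,
            head_opts = head_opts)
}

test_that("CNN head computes conv/pool/linear shapes and a probability", {
  set.seed(21)
  hp <- cnn_head_params(20L, in_channels = 6L, channels = c(5L, 4L))
  ctx <- matrix(rnorm(20 * 6), 20, 6)
  p <- cnn_head(ctx, hp)
  expect_gt(p, 0); expect_lt(p, 1)
  expect_error(cnn_head(ctx[1:5, ], hp), "dimensions")
  expect_error(cnn_head_params(4L, in_channels = 6L), "too short")
})

test_that("FCL head computes a probability from the flattened context", {
  set.seed(22)
  hp <- fcl_head_params(10L, in_channels = 6L, hidden = c(7L, 3L))
  ctx <- matrix(rnorm(10 * 6), 10, 6)
  p <- fcl_head(ctx, hp)
  expect_gt(p, 0); expect_lt(p, 1)
  expect_error(fcl_head(ctx[1:3, ], hp), "dimensions")
})

test_that("select_context stacks drug rows above protein rows", {
  bP <- list(context = matrix(1, 3, 2))
  bD <- list(context = matrix(2, 2, 2))
  expect_identical(select_context(bP, bD, "dp"),
                   rbind(matrix(2, 2, 2), matrix(1, 3, 2)))
  expect_identical(select_context(bP, NULL, "p"), bP$context)
  expect_error(select_context(NULL, NULL, "p"), "missing")
})

test_that("the architecture grid builds and predicts for all 7 entries", {
  drugs <- c("CN=C=O", "CCOC", "NCO")
  prots <- c("MKVLAA", "ACDEFGHIKL", "WYV")
  for (arch in c("CA_DP", "CA2_DP", "CA3_DP", "CA_DP_FCL", "SA_DP", "CA_D", "CA_P")) {
    ho <- if (arch == "CA_DP_FCL") list(hidden = c(6L, 4L))
          else if (arch == "CA_D") list(channels = c(5L, 4L), kernel = 2L)
          else list(channels = c(5L, 4L))
    m <- make_small_model(arch, head_opts = ho)
    p <- predict(m, drugs, prots)
    expect_length(p, 3L)
    expect_true(all(p > 0 & p < 1), label = arch)
  }
})

test_that("batched forward agrees with the single-sample reference path", {
  m <- make_small_model("CA_P")
  enc <- dticross:::model_encode(m, "CN=C=O", "MKVLAA")
  batch <- dticross:::encode_batch_inputs(m, enc, 1L)
  fw <- dticross:::model_forward(m, batch)
  lv_p <- structure(enc$protein$labels[1, ], true_len = enc$protein$true_len[1],
                    class = "dti_labelvec")
  lv_d <- structure(enc$drug$labels[1, ], true_len = enc$drug$true_len[1],
                    class = "dti_labelvec")
  ep <- embed_learned(lv_p, m$params[["emb.prot_tok"]], m$params[["emb.prot_pos"]])
  ed <- embed_learned(lv_d, m$params[["emb.drug_tok"]], m$params[["emb.drug_pos"]])
  ap <- structure(c(dticross:::par_slice(m$params, "L1.P."),
                    list(heads = 2L, d = 4L)), class = "attn_params")
  bP <- cross_context(ep, ed, ap)
  expect_equal(max(abs(bP$context - fw$layers[[1]]$P$ctx)), 0, tolerance = 1e-12)
  hp <- structure(c(dticross:::par_slice(m$params, "head."), m$head_cfg),
                  class = "cnn_head_params")
  expect_equal(cnn_head(bP$context, hp), fw$prob, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("analytic gradients match finite differences", {
  for (arch in c("CA_P", "CA_DP", "SA_DP", "CA_DP_FCL")) {
    ho <- if (arch == "CA_DP_FCL") list(hidden = c(6L, 4L))
          else list(channels = c(5L, 4L))
    m <- make_small_model(arch, head_opts = ho,
                          seed = match(arch, dticross:::ARCHITECTURES))
    # move biases off zero: zeroed PAD rows otherwise sit exactly on the ReLU
    # kink where one-sided derivatives differ
    for (nm in grep("head\\.b", names(m$params), value = TRUE))
      m$params[[nm]] <- m$params[[nm]] + 0.05
    drugs <- c("CN=C=O", "CCOC"); prots <- c("MKVLAA", "ACDEFGHIKL")
    y <- c(1, 0)
    enc <- dticross:::model_encode(m, drugs, prots)
    batch <- dticross:::encode_batch_inputs(m, enc, 1:2)
    fw <- dticross:::model_forward(m, batch, train = FALSE)
    gr <- dticross:::model_backward(m, fw, y)
    loss_at <- function(params) {
      m2 <- m; m2$params <- params
      b2 <- dticross:::encode_batch_inputs(m2, enc, 1:2)
      f2 <- dticross:::model_forward(m2, b2, train = FALSE)
      dticross:::bce_loss(f2$prob, y)
    }
    eps <- 1e-6
    set.seed(99)
    for (nm in sample(names(gr), 6L)) {
      ii <- sample(length(m$params[[nm]]), 1L)
      pp <- m$params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
      pm <- m$params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(gr[[nm]][ii], num, tolerance = 1e-4,
                   label = paste(arch, nm))
    }
  }
})

test_that("Adam training reduces the loss on a separable toy problem", {
  m <- make_small_model("CA_P", seed = 3L)
  drugs <- rep(c("CN=C=O", "CCOC"), 8)
  prots <- rep(c("MKVLAA", "ACDEFG"), 8)
  y <- rep(c(1, 0), 8)
  enc <- dticross:::model_encode(m, drugs, prots)
  state <- dticross:::adam_init(m$params)
  losses <- numeric(30)
  for (it in 1:30) {
    batch <- dticross:::encode_batch_inputs(m, enc, 1:16)
    fw <- dticross:::model_forward(m, batch, train = FALSE)
    losses[it] <- dticross:::bce_loss(fw$prob, y)
    gr <- dticross:::model_backward(m, fw, y)
    upd <- dticross:::adam_step(m$params, gr, state, lr = 0.01)
    m$params <- upd$params; state <- upd$state
  }
  expect_lt(losses[30], losses[1] * 0.5)
})

test_that("PAD masking makes predictions independent of padding amount", {
  m1 <- make_small_model("CA_P", seed = 12L)
  set.seed(12)
  vd <- vocabulary(c("C", "N", "O", "="), "smiles_char")
  vp <- vocabulary(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "aa_letter")
  m2 <- dti_model(vd, vp, arch = "CA_P", scheme = "smiles_embed",
                  max_len_drug = 8L, max_len_protein = 20L, hidden = 8L,
                  heads = 2L, head_opts = list(channels = c(5L, 4L)),
                  positional = FALSE)
  m1$params[["emb.drug_pos"]] <- NULL  # compare without positional tables
  m1$positional <- FALSE
  m1$params[["emb.prot_pos"]] <- NULL
  m2$params[["emb.drug_tok"]] <- m1$params[["emb.drug_tok"]]
  m2$params[["emb.prot_tok"]] <- m1$params[["emb.prot_tok"]]
  for (nm in grep("^L1|^head", names(m1$params), value = TRUE)) {
    if (nm == "head.Wl") next  # flat layer width depends on context length
    m2$params[[nm]] <- m1$params[[nm]]
  }
  # attention contexts at real positions must agree despite extra padding
  enc1 <- dticross:::model_encode(m1, "CN=C=O", "MKVLAA")
  enc2 <- dticross:::model_encode(m2, "CN=C=O", "MKVLAA")
  f1 <- dticross:::model_forward(m1, dticross:::encode_batch_inputs(m1, enc1, 1L))
  f2 <- dticross:::model_forward(m2, dticross:::encode_batch_inputs(m2, enc2, 1L))
  expect_equal(f1$layers[[1]]$P$ctx[1:6, ], f2$layers[[1]]$P$ctx[1:6, ],
               tolerance = 1e-12)
})
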