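test_that("multi-head output equals a brute-force per-head loop", {
  set.seed(11)
  Xq <- matrix(rnorm(5 * 8), 5, 8)
  Xk <- matrix(rnorm(7 * 8), 7, 8)
  p <- attention_params(8L, 8L, hidden = 8L, heads = 2L)
  got <- cross_context(Xq, Xk, p)$context
  ref <- brute_multihead(Xq, Xk, p$Wq, p$Wk, p$Wv, p$W0, heads = 2L)
  expect_equal(got, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("attention weight rows sum to one", {
  set.seed(2)
  Qi <- matrix(rnorm(6 * 4), 6, 4)
  Ki <- matrix(rnorm(9 * 4), 9, 4)
  A <- attention_weights(Qi, Ki)
  expect_equal(rowSums(A), rep(1, 6))
  expect_true(all(A >= 0))
})

test_that("both scaling variants are honoured", {
  set.seed(3)
  Qi <- matrix(rnorm(4 * 4), 4, 4)
  Ki <- matrix(rnorm(4 * 4), 4, 4)
  S <- tcrossprod(Qi, Ki)
  soft <- function(M) t(apply(M, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(attention_weights(Qi, Ki, scale = "sqrt_d"), soft(S / 2),
               tolerance = 1e-12)
  expect_equal(attention_weights(Qi, Ki, scale = "d"), soft(S / 4),
               tolerance = 1e-12)
})

test_that("masked keys get exactly zero weight", {
  set.seed(4)
  Qi <- matrix(rnorm(3 * 4), 3, 4)
  Ki <- matrix(rnorm(5 * 4), 5, 4)
  mask <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  A <- attention_weights(Qi, Ki, key_mask = mask)
  expect_true(all(A[, !mask] == 0))
  expect_equal(rowSums(A), rep(1, 3))
  expect_error(attention_weights(Qi, Ki, key_mask = rep(FALSE, 5)),
               "no attendable positions")
})

test_that("context is the residual sum of queries and projected heads", {
  set.seed(5)
  Xq <- matrix(rnorm(4 * 6), 4, 6)
  Xk <- matrix(rnorm(5 * 6), 5, 6)
  p <- attention_params(6L, 6L, hidden = 6L, heads = 3L)
  b <- cross_context(Xq, Xk, p)
  H <- do.call(cbind, b$heads)
  expect_equal(b$context, Xq %*% p$Wq + H %*% p$W0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_length(b$weights, 3L)
  expect_identical(dim(b$weights[[1]]), c(4L, 5L))
})

test_that("self-attention equals cross-attention with itself", {
  set.seed(6)
  X <- matrix(rnorm(4 * 6), 4, 6)
  p <- attention_params(6L, 6L, hidden = 6L, heads = 2L)
  expect_equal(self_context(X, p)$context, cross_context(X, X, p)$context,
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("stacked layers feed contexts forward", {
  set.seed(7)
  Xd <- structure(matrix(rnorm(3 * 6), 3, 6), mask = rep(TRUE, 3))
  Xp <- structure(matrix(rnorm(5 * 6), 5, 6), mask = rep(TRUE, 5))
  lp <- lapply(1:2, function(k) list(P = attention_params(6L, 6L, 6L, 2L),
                                     D = attention_params(6L, 6L, 6L, 2L)))
  out <- stack_layers(Xd, Xp, lp)
  expect_identical(dim(out$P$context), c(5L, 6L))
  expect_identical(dim(out$D$context), c(3L, 6L))
  # manual two-layer composition
  b1P <- cross_context(Xp, Xd, lp[[1]]$P)
  b1D <- cross_context(Xd, Xp, lp[[1]]$D)
  b2P <- cross_context(structure(b1P$context, mask = attr(Xp, "mask")),
                       structure(b1D$context, mask = attr(Xd, "mask")),
                       lp[[2]]$P)
  expect_equal(out$P$context, b2P$context, tolerance = 1e-12, ignore_attr = TRUE)
})
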