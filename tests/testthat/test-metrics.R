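test_that("threshold metrics match the confusion-table oracle on 20 vectors", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    scores <- runif(n)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    got <- dti_metrics(scores, labels)
    ref <- oracle_metrics(scores, labels)
    expect_equal(got[c("SN", "SP", "PR", "F1")], ref, tolerance = 1e-12)
    expect_equal(got[["ROCAUC"]], oracle_rocauc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROCAUC agrees with pROC including tied scores", {
  set.seed(15)
  for (i in 1:5) {
    scores <- sample(seq(0, 1, by = 0.1), 40, replace = TRUE)  # many ties
    labels <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-10)
  }
})

test_that("PRAUC step form equals average precision computed by hand", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  labels <- c(1, 0, 1, 1, 0)
  # precision at each positive hit: 1/1, 2/3, 3/4 ; AP = mean over recall steps
  expect_equal(pr_auc(scores, labels), (1 + 2 / 3 + 3 / 4) / 3,
               tolerance = 1e-12)
  expect_gte(pr_auc(scores, labels), pr_auc(scores, labels, "trapezoid") - 0.2)
})

test_that("perfect and inverted rankings bound the AUCs", {
  labels <- c(1, 1, 0, 0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), labels), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), labels), 0)
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), labels), 1)
})

test_that("random scores give ROCAUC near one half", {
  set.seed(16)
  scores <- runif(4000)
  labels <- rep(c(0, 1), 2000)
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.03)
})

test_that("scores equal to the threshold count as positive predictions", {
  cc <- confusion_counts(c(0.5, 0.5, 0.4), c(1, 0, 0), threshold = 0.5)
  expect_identical(unname(cc["TP"]), 1L)
  expect_identical(unname(cc["FP"]), 1L)
  expect_identical(unname(cc["TN"]), 1L)
})

test_that("single-class inputs raise errors for AUCs", {
  expect_error(roc_auc(runif(5), rep(1, 5)), "single class")
  expect_error(pr_auc(runif(5), rep(0, 5)), "single class")
})
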