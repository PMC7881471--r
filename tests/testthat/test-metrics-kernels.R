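test_that("metrics match hand arithmetic on a 10-subject confusion table", {
  truth <- c(rep("high", 5), rep("low", 5))
  pred <- c("high", "high", "high", "low", "low",
            "low", "low", "low", "low", "high")
  # TP = 3, FN = 2, TN = 4, FP = 1
  m <- compute_metrics(truth, pred)
  expect_equal(m$ACC, 0.7)
  expect_equal(m$SEN, 3 / 5)
  expect_equal(m$SPE, 4 / 5)
  expect_equal(m$Y, 3 / 5 + 4 / 5 - 1)
  expect_equal(m$BAC, (3 / 5 + 4 / 5) / 2)
  expect_equal(m$F, 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))
  expect_true(is.na(m$AUC))
})

test_that("metric edge cases behave as defined", {
  perfect <- compute_metrics(c("high", "low"), c("high", "low"), c(1, -1))
  expect_equal(unlist(perfect), c(ACC = 1, SEN = 1, SPE = 1, AUC = 1,
                                  Y = 1, F = 1, BAC = 1))
  all_pos <- compute_metrics(rep(c("high", "low"), 5), rep("high", 10))
  expect_equal(all_pos$ACC, 0.5)
  expect_equal(all_pos$SEN, 1)
  expect_equal(all_pos$SPE, 0)
  expect_equal(all_pos$Y, 0)
  expect_equal(all_pos$BAC, 0.5)
  expect_warning(one <- compute_metrics(rep("high", 4), rep("high", 4)),
                 "single-class")
  expect_true(is.nan(one$SPE))
})

test_that("metric identities hold over random prediction sets", {
  set.seed(12)
  for (i in 1:20) {
    truth <- sample(c("high", "low"), 20, replace = TRUE)
    if (length(unique(truth)) < 2) next
    pred <- sample(c("high", "low"), 20, replace = TRUE)
    s <- rnorm(20)
    m <- compute_metrics(truth, pred, s)
    expect_equal(m$Y, m$SEN + m$SPE - 1)
    expect_equal(m$BAC, (m$SEN + m$SPE) / 2)
    expect_true(m$AUC >= 0 && m$AUC <= 1)
  }
})

test_that("rank AUC agrees with pROC and ignores monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(13)
  truth <- sample(c("high", "low"), 40, replace = TRUE)
  scores <- rnorm(40) + (truth == "high")
  pred <- ifelse(scores > 0, "high", "low")
  m <- compute_metrics(truth, pred, scores)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("low", "high"),
    direction = "<", quiet = TRUE)))
  expect_equal(m$AUC, ref)
  m2 <- compute_metrics(truth, pred, exp(3 * scores))
  expect_equal(m2$AUC, m$AUC)
})

test_that("RBF kernel matches hand-computed distances and limits", {
  x <- rbind(a = c(0, 0), b = c(1, 0), c = c(1, 2))
  k <- rbf_kernel(x, gamma = 0.5)
  expect_equal(unname(diag(k)), rep(1, 3))
  expect_equal(k["a", "b"], exp(-0.5 * 1))
  expect_equal(k["a", "c"], exp(-0.5 * 5))
  expect_equal(k["b", "c"], exp(-0.5 * 4))
  expect_true(isSymmetric(k))
  # gamma -> 0 sends every entry to 1; identical subjects give exactly 1
  expect_equal(unname(rbf_kernel(x, 0)), matrix(1, 3, 3))
  expect_equal(rbf_kernel(rbind(x, a2 = c(0, 0)), 0.7)["a", "a2"], 1)
  # positive semi-definite
  set.seed(14)
  z <- matrix(rnorm(60), 10, 6)
  ev <- eigen(rbf_kernel(z, 0.3), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  # cross-kernel block
  kx <- rbf_kernel(x[1:2, ], 0.5, x)
  expect_equal(dim(kx), c(2, 3))
  expect_equal(kx[1, 3], k["a", "c"])
  expect_error(rbf_kernel(rbind(c(1, NA))), "non-finite",
               class = "hiernet_kernel_error")
})

test_that("kernel fusion is the convex combination with exact endpoints", {
  k1 <- matrix(c(1, 0.2, 0.2, 1), 2)
  k2 <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_identical(fuse_kernels(k1, k2, 1), k1)
  expect_identical(fuse_kernels(k1, k2, 0), k2)
  expect_equal(fuse_kernels(k1, k2, 0.5), (k1 + k2) / 2)
  expect_error(fuse_kernels(k1, matrix(1, 3, 3), 0.5), "dimensions",
               class = "hiernet_kernel_error")
  expect_error(fuse_kernels(k1, k2, 1.2), "beta", class = "hiernet_kernel_error")
})
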