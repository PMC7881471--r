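make_xy <- function(n_per_group = 10, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_group * p), 2 * n_per_group, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  y <- factor(rep(c("low", "high"), each = n_per_group),
              levels = c("low", "high"))
  list(x = x, y = y)
}

test_that("t-test screen matches the textbook two-sample computation", {
  d <- make_xy(3, 4, seed = 2)
  res <- ttest_filter(d$x, d$y, alpha = 0.05)
  for (j in seq_len(ncol(d$x))) {
    ref <- t.test(d$x[d$y == "low", j], d$x[d$y == "high", j],
                  var.equal = TRUE)
    expect_equal(res$stats$statistic[j], unname(ref$statistic))
    expect_equal(res$stats$p_value[j], ref$p.value)
  }
})

test_that("t-test screen keeps separated features, drops flat ones", {
  set.seed(3)
  x <- cbind(
    flat = rep(1, 20),
    sep = c(rnorm(10, 0), rnorm(10, 10)),  # 10 pooled SDs apart
    noise = rnorm(20)
  )
  y <- factor(rep(c("low", "high"), each = 10))
  res <- ttest_filter(x, y, alpha = 0.05)
  expect_true("sep" %in% res$kept)
  expect_false("flat" %in% res$kept)
  expect_equal(res$stats$p_value[res$stats$feature == "flat"], 1)
  expect_true(res$stats$zero_variance[res$stats$feature == "flat"])
})

test_that("mRMR ranks a redundant duplicate below an independent feature", {
  set.seed(4)
  y <- factor(rep(c("low", "high"), each = 15))
  sig <- as.numeric(y == "high") * 2 + rnorm(30, sd = 0.4)
  ind <- as.numeric(y == "high") * 2 + rnorm(30, sd = 0.4)
  x <- cbind(a_sig = sig, b_dup = sig, c_ind = ind)
  r <- mrmr_rank(x, y, keep = 3)
  dup_pos <- match(c("a_sig", "b_dup"), r$kept)
  expect_equal(sort(r$kept[1:2]), c("a_sig", "c_ind"))
  expect_equal(max(dup_pos), 3)
  # single candidate is trivially ranked first
  r1 <- mrmr_rank(x[, "a_sig", drop = FALSE], y, keep = 1)
  expect_equal(r1$kept, "a_sig")
  expect_warning(mrmr_rank(x, y, keep = 10), "keeping all")
})

test_that("greedy mRMR equals the exhaustive MID oracle", {
  set.seed(5)
  for (trial in 1:4) {
    x <- matrix(sample(0:3, 48, replace = TRUE) + rnorm(48, sd = 0.01),
                12, 4, dimnames = list(NULL, paste0("v", 1:4)))
    y <- factor(sample(rep(c("low", "high"), 6)))
    expect_equal(mrmr_rank(x, y, keep = 4)$kept, oracle_mrmr(x, y, 4))
  }
})

test_that("SVM-RFE keeps a perfect separator and matches the step oracle", {
  set.seed(6)
  y <- factor(rep(c("low", "high"), each = 10))
  x <- cbind(matrix(rnorm(80), 20, 4), perfect = as.numeric(y == "high") * 4)
  colnames(x) <- c(paste0("n", 1:4), "perfect")
  xs <- scale(x)
  r <- svm_rfe(xs, y, keep = 1, step = 1)
  expect_equal(r$kept, "perfect")
  oracle <- oracle_rfe_order(xs, y, keep = 1)
  expect_equal(r$elimination, oracle$elimination)
  expect_equal(r$kept, oracle$kept)
  # keep = input size is the identity
  r_id <- svm_rfe(xs, y, keep = 5)
  expect_equal(r_id$kept, colnames(xs))
  expect_length(r_id$elimination, 0)
})

test_that("the cascade output is nested through its stages", {
  co <- simulate_cohort(
    sim_config(n_per_group = 12,
               roi_effects = data.frame(roi = 1:2, measure = "gm", d = 2)),
    toy_atlas(), seed = 7)
  fb <- assemble_blocks(co, toy_atlas(), blocks = "roi_L4")
  set.seed(11)
  res <- run_cascade(fb$blocks$roi_L4, fb$labels,
                     selection_config(rfe_keep = 3))
  surv <- res$trace$survivors
  expect_true(all(res$selected %in% surv$mrmr))
  expect_true(all(surv$mrmr %in% surv$ttest))
  expect_true(all(surv$ttest %in% colnames(fb$blocks$roi_L4)))
  expect_length(res$selected, 3)
  # planted volume features dominate the final subset
  expect_true(any(c("roi01_gm", "roi02_gm") %in% res$selected))
})

test_that("the cascade is deterministic and fails cleanly on pure noise", {
  d <- make_xy(8, 30, seed = 9)
  cfg <- selection_config(t_alpha = 0.5, rfe_keep = 2)
  set.seed(1); a <- run_cascade(d$x, d$y, cfg)
  set.seed(1); b <- run_cascade(d$x, d$y, cfg)
  expect_identical(a$selected, b$selected)
  expect_identical(a$trace$rfe_elimination, b$trace$rfe_elimination)
  expect_error(run_cascade(d$x, d$y, selection_config(t_alpha = 1e-12)),
               "larger t_alpha", class = "hiernet_selection_error")
})

test_that("the cascade depends only on the training rows it is given", {
  d <- make_xy(10, 12, seed = 10)
  train <- rep(c(TRUE, FALSE), 10)
  x_other <- d$x
  x_other[!train, ] <- x_other[!train, ] + 100  # perturb held-out rows only
  cfg <- selection_config(t_alpha = 0.5, rfe_keep = 3)
  set.seed(2)
  a <- run_cascade(d$x[train, ], d$y[train], cfg)
  set.seed(2)
  b <- run_cascade(x_other[train, ], d$y[train], cfg)
  expect_identical(a$selected, b$selected)
})
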