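# permissive screen: the 8-edge toy network block must keep features even
# when only the regional block carries signal
toy_cv <- function(...) {
  cv_config(..., selection = selection_config(t_alpha = 0.9))
}

toy_signal_cohort <- function(n = 12, d = 2.5, seed = 17) {
  cfg <- sim_config(n_per_group = n,
                    roi_effects = data.frame(roi = c(1, 2), measure = "gm",
                                             d = d))
  simulate_cohort(cfg, toy_atlas(), seed = seed)
}

test_that("nested CV is reproducible and its counts are bounded", {
  fb <- assemble_blocks(toy_signal_cohort(), toy_atlas())
  cfg <- toy_cv(repetitions = 2)
  a <- nested_cv(fb, cfg, seed = 7)
  b <- nested_cv(fb, cfg, seed = 7)
  expect_equal(a$per_rep, b$per_rep)
  expect_equal(a$frequencies, b$frequencies)
  expect_equal(a$n_fits, 4)
  expect_true(all(a$frequencies$frequency <= a$n_fits))
  expect_true(all(a$frequencies$frequency >= 1))
  # metric identities hold on every repetition row
  expect_equal(a$per_rep$Y, a$per_rep$SEN + a$per_rep$SPE - 1)
  expect_equal(a$per_rep$BAC, (a$per_rep$SEN + a$per_rep$SPE) / 2)
  c <- nested_cv(fb, cfg, seed = 8)
  expect_false(identical(a$per_rep$ACC, c$per_rep$ACC))
})

test_that("beta endpoints reproduce single-kernel classification", {
  fb <- assemble_blocks(toy_signal_cohort(), toy_atlas())
  roi_only <- nested_cv(fb, toy_cv(repetitions = 2, net_block = NULL),
                        seed = 9)
  pinned1 <- nested_cv(fb, toy_cv(repetitions = 2, beta_grid = 1), seed = 9)
  expect_equal(pinned1$per_rep, roi_only$per_rep)
  net_only <- nested_cv(fb, toy_cv(repetitions = 2, roi_block = NULL),
                        seed = 9)
  pinned0 <- nested_cv(fb, toy_cv(repetitions = 2, beta_grid = 0), seed = 9)
  expect_equal(pinned0$per_rep, net_only$per_rep)
})

test_that("a clearly separable cohort is classified near-perfectly", {
  fb <- assemble_blocks(toy_signal_cohort(d = 8), toy_atlas())
  rep <- nested_cv(fb, toy_cv(repetitions = 2), seed = 5)
  expect_gte(rep$summary$mean[rep$summary$metric == "ACC"], 0.95)
})

test_that("permuted labels bring accuracy back to chance", {
  co <- simulate_cohort(
    sim_config(n_per_group = 10,
               roi_effects = data.frame(roi = 1, measure = "gm", d = 3)),
    seed = 19)
  # permute subject labels, keeping the group sizes
  subj <- unique(co$subject_id)
  perm <- withr::with_seed(20, setNames(
    sample(rep(c("high", "low"), each = 10)), subj))
  co$label <- perm[co$subject_id]
  fb <- assemble_blocks(co)
  rep <- nested_cv(fb, cv_config(repetitions = 2), seed = 21)
  acc <- rep$summary$mean[rep$summary$metric == "ACC"]
  expect_gte(acc, 0.2)
  expect_lte(acc, 0.8)
})

test_that("frequency tables are deterministic, annotated and cappable", {
  fb <- assemble_blocks(toy_signal_cohort(), toy_atlas())
  rep <- nested_cv(fb, toy_cv(repetitions = 2), seed = 7)
  t1 <- frequency_table(rep, "roi", top_k = 3)
  expect_equal(nrow(t1), 3)
  expect_equal(t1$rank, 1:3)
  expect_true(all(diff(t1$frequency) <= 0))
  expect_true(all(!is.na(t1$roi_i_name)))
  # top_k beyond the number of ever-selected features returns everything
  t_all <- frequency_table(rep, "roi", top_k = 1e6)
  expect_equal(nrow(t_all),
               sum(rep$frequencies$block == rep$config$roi_block))
  t2 <- frequency_table(nested_cv(fb, toy_cv(repetitions = 2), seed = 7),
                        "roi", top_k = 3)
  expect_equal(t1, t2)
})

test_that("a one-point weight sweep equals the pinned nested CV run", {
  fb <- assemble_blocks(toy_signal_cohort(), toy_atlas())
  cfg <- toy_cv(repetitions = 2)
  sw <- weight_sweep(fb, 0.5, cfg, seed = 11)
  direct <- nested_cv(fb, toy_cv(repetitions = 2, beta_grid = 0.5),
                      seed = 11)
  expect_equal(sw$ACC, direct$summary$mean[direct$summary$metric == "ACC"])
  expect_equal(nrow(sw), 1)
  expect_s3_class(sw, "weight_sweep")
})

test_that("baseline classifiers handle separable data and single requests", {
  fb <- assemble_blocks(toy_signal_cohort(n = 16, d = 8), toy_atlas())
  tab <- baseline_classifiers(fb, toy_cv(repetitions = 2), seed = 13)
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$accuracy >= 0.9))
  one <- baseline_classifiers(fb, toy_cv(repetitions = 2),
                              classifiers = "knn", seed = 13)
  expect_equal(nrow(one), 1)
  expect_equal(one$classifier, "knn")
})

test_that("tidiers and plots expose the report", {
  fb <- assemble_blocks(toy_signal_cohort(), toy_atlas())
  rep <- nested_cv(fb, toy_cv(repetitions = 2), seed = 7)
  td <- tidy(rep)
  expect_equal(nrow(td), 2)
  gl <- glance(rep)
  expect_equal(gl$repetitions, 2)
  expect_equal(gl$ACC, mean(td$ACC))
  expect_s3_class(autoplot(rep), "ggplot")
  sw <- weight_sweep(fb, c(0.2, 0.8), toy_cv(repetitions = 2), seed = 7)
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(plot_frequencies(frequency_table(rep, "roi", 3)), "ggplot")
})
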