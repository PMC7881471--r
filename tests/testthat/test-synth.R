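test_that("simulation is seed-deterministic with positive measures", {
  cfg <- sim_config(n_per_group = 5)
  a <- simulate_cohort(cfg, seed = 41)
  b <- simulate_cohort(cfg, seed = 41)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_cohort(cfg, seed = 42)
  expect_false(identical(a$thickness_mean, c$thickness_mean))
  for (m in c("gm_volume", "wm_volume", "csf_volume", "thickness_mean",
              "thickness_sd", "surface_area", "tiv", "mean_thickness",
              "total_area")) {
    expect_true(all(a[[m]] > 0), label = paste("positive", m))
  }
  expect_equal(as.integer(table(cohort_labels(a))), c(5L, 5L))
})

test_that("subject globals are consistent with the regional values", {
  co <- simulate_cohort(sim_config(n_per_group = 3), seed = 43)
  per <- dplyr::summarise(
    dplyr::group_by(co, subject_id, tiv, mean_thickness, total_area),
    s_tiv = sum(gm_volume + wm_volume + csf_volume),
    s_thk = mean(thickness_mean), s_area = sum(surface_area),
    .groups = "drop")
  expect_equal(per$tiv, per$s_tiv)
  expect_equal(per$mean_thickness, per$s_thk)
  expect_equal(per$total_area, per$s_area)
})

test_that("planted d = 2 regional effects are detectable at study size", {
  eff <- data.frame(roi = c(3, 11, 25, 40, 61),
                    measure = c("gm", "wm", "csf", "thk", "area"), d = 2)
  cfg <- sim_config(roi_effects = eff)
  hits <- 0L; total <- 0L
  seeds <- withr::with_seed(44, sample.int(1e6, 100))
  for (s in seeds) {
    co <- normalize_cohort(simulate_cohort(cfg, seed = s))
    y <- co$label[co$roi_index == 1]
    for (r in seq_len(nrow(eff))) {
      v <- co[[block_measures[[eff$measure[r]]]]][co$roi_index == eff$roi[r]]
      p <- t.test(v[y == "high"], v[y == "low"], var.equal = TRUE)$p.value
      total <- total + 1L
      hits <- hits + (p < 0.05)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("without planted effects the groups are exchangeable", {
  co <- simulate_cohort(sim_config(), seed = 45)
  fb <- assemble_blocks(co, blocks = "roi_L4")
  tt <- ttest_filter(fb$blocks$roi_L4, fb$labels, alpha = 0.05)
  # false-positive rate of the screen stays near its nominal level
  expect_lte(length(tt$kept) / ncol(fb$blocks$roi_L4), 0.12)
  expect_equal(nrow(attr(co, "ground_truth")$roi_effects), 0)
})

test_that("edge coupling shifts the similarity of the planted pair", {
  cfg <- sim_config(edge_effects = data.frame(roi_i = 5, roi_j = 50,
                                              coupling = 0.95))
  co <- simulate_cohort(cfg, seed = 46)
  fb <- assemble_blocks(co, blocks = "net_L4")
  v <- fb$blocks$net_L4[, "L4_e05_50"]
  y <- fb$labels
  p <- t.test(v[y == "high"], v[y == "low"])$p.value
  expect_lt(p, 0.01)
  expect_gt(mean(v[y == "high"]), mean(v[y == "low"]))
})

test_that("classification accuracy is monotone in planted effect size", {
  acc <- vapply(c(0, 1, 2), function(d) {
    eff <- if (d > 0) {
      data.frame(roi = c(3, 11, 61), measure = c("gm", "wm", "area"), d = d)
    } else NULL
    co <- simulate_cohort(sim_config(n_per_group = 17, roi_effects = eff),
                          seed = 47)
    fb <- assemble_blocks(co, blocks = c("roi_L4", "net_all"))
    rep <- nested_cv(fb, cv_config(repetitions = 2), seed = 48)
    rep$summary$mean[rep$summary$metric == "ACC"]
  }, numeric(1))
  expect_gte(acc[2], acc[1] - 0.1)
  expect_gte(acc[3], acc[2] - 0.1)
  expect_gt(acc[3], acc[1])
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_per_group = 1), "n_per_group",
               class = "hiernet_sim_error")
  expect_error(sim_config(roi_effects = data.frame(roi = 1, measure = "xx",
                                                   d = 1)),
               "unknown measure", class = "hiernet_sim_error")
  expect_error(sim_config(edge_effects = data.frame(roi_i = 1, roi_j = 2,
                                                    coupling = 1.5)),
               "couplings", class = "hiernet_sim_error")
  # overlapping couplings that cannot form a correlation matrix
  bad <- sim_config(edge_effects = data.frame(roi_i = c(1, 1), roi_j = c(2, 3),
                                              coupling = 0.95))
  expect_error(simulate_cohort(bad, toy_atlas(), seed = 1),
               "positive-definite", class = "hiernet_sim_error")
  out <- sim_config(roi_effects = data.frame(roi = 99, measure = "gm", d = 1))
  expect_error(simulate_cohort(out, toy_atlas(), seed = 1), "ROI index",
               class = "hiernet_sim_error")
})
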