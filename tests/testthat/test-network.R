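test_that("edge similarity matches its closed form", {
  expect_equal(edge_similarity(2.5, 0.3, 2.5, 0.4), 1)
  # |t_i - t_j| = sqrt(sigma_i^2 + sigma_j^2) gives exp(-1/2)
  expect_equal(edge_similarity(2.5 + 0.5, 0.3, 2.5, 0.4), exp(-0.5))
  expect_equal(edge_similarity(2.8, 0.3, 2.2, 0.4),
               exp(-(2.8 - 2.2)^2 / (2 * (0.3^2 + 0.4^2))))
  expect_equal(edge_similarity(2.8, 0.3, 2.2, 0.4), exp(-0.72))
})

test_that("edge similarity is symmetric, bounded and monotone", {
  set.seed(1)
  t1 <- runif(50, 2, 3); t2 <- runif(50, 2, 3)
  s1 <- runif(50, 0.1, 0.5); s2 <- runif(50, 0.1, 0.5)
  a <- edge_similarity(t1, s1, t2, s2)
  b <- edge_similarity(t2, s2, t1, s1)
  expect_equal(a, b)
  expect_true(all(a > 0 & a <= 1))
  # strictly decreasing in |t_i - t_j| at fixed sigmas
  d <- seq(0, 2, by = 0.1)
  v <- edge_similarity(2.5 + d, 0.3, 2.5, 0.3)
  expect_true(all(diff(v) < 0))
})

test_that("degenerate dispersion is rejected unless thickness agrees", {
  expect_equal(edge_similarity(2.5, 0, 2.5, 0), 1)
  expect_error(edge_similarity(2.5, 0, 2.6, 0), "degenerate",
               class = "hiernet_network_error")
  expect_error(edge_similarity(2.5, -0.1, 2.6, 0.3), "non-negative",
               class = "hiernet_network_error")
})

test_that("compound ROI statistics average their constituents", {
  toy <- toy_atlas()
  co <- toy_cohort(list(A = toy_measures(thk = c(2.0, 2.0, 3.0, 4.0),
                                         thk_sd = c(0.2, 0.3, 0.4, 0.5)),
                        B = toy_measures(rep(2, 4), label = "low")))
  # toy merge: layer-3 ROI 1 = {1, 3}, ROI 2 = {2, 4}
  st <- merge_thickness_stats(co[co$subject_id == "A", ], toy, 3)
  expect_equal(st$t, c(mean(c(2, 3)), mean(c(2, 4))))
  expect_equal(st$sigma, c(mean(c(0.2, 0.4)), mean(c(0.3, 0.5))))
  pooled <- merge_thickness_stats(co[co$subject_id == "A", ], toy, 3,
                                  sigma_method = "pooled")
  expect_equal(pooled$sigma, c(sqrt(mean(c(0.2, 0.4)^2)),
                               sqrt(mean(c(0.3, 0.5)^2))))
  # layer 1 averages over every ROI
  st1 <- merge_thickness_stats(co[co$subject_id == "A", ], toy, 1)
  expect_equal(st1$t, mean(c(2, 2, 3, 4)))
  expect_equal(st1$sigma, mean(c(0.2, 0.3, 0.4, 0.5)))
})

test_that("layer networks are symmetric with unit diagonal in (0, 1]", {
  co <- simulate_cohort(sim_config(n_per_group = 2), seed = 9)
  for (l in c(4, 3, 2)) {
    for (id in unique(co$subject_id)[1:2]) {
      net <- build_layer_network(co, layer = l, subject_id = id)
      expect_equal(dim(net), rep(c(78, 36, 14)[c(4, 3, 2) == l], 2))
      expect_true(isSymmetric(unclass(net)))
      expect_equal(unname(diag(net)), rep(1, nrow(net)))
      expect_true(all(net > 0 & net <= 1))
    }
  }
  net1 <- build_layer_network(co, layer = 1, subject_id = "S001")
  expect_equal(unclass(net1)[1, 1], 1)
  expect_equal(dim(net1), c(1, 1))
})

test_that("identical thickness everywhere yields the all-ones network", {
  toy <- toy_atlas()
  co <- toy_cohort(list(A = toy_measures(rep(2.5, 4)),
                        B = toy_measures(rep(2, 4), label = "low")))
  net <- build_layer_network(co, toy, 4, subject_id = "A")
  expect_equal(unclass(net), matrix(1, 4, 4), ignore_attr = TRUE)
})

test_that("a uniform thickness shift leaves the network unchanged", {
  toy <- toy_atlas()
  co <- toy_cohort(list(A = toy_measures(c(2.1, 2.5, 2.9, 2.3)),
                        B = toy_measures(rep(2, 4), label = "low")))
  shifted <- dplyr::mutate(co, thickness_mean = thickness_mean + 0.7)
  n1 <- build_layer_network(co, toy, 4, subject_id = "A", normalize = FALSE)
  n2 <- build_layer_network(shifted, toy, 4, subject_id = "A",
                            normalize = FALSE)
  expect_equal(unclass(n1), unclass(n2))
})

test_that("vectorization takes the strict upper triangle row-major", {
  toy <- toy_atlas()
  co <- toy_cohort(list(A = toy_measures(c(2.1, 2.5, 2.9, 2.3)),
                        B = toy_measures(rep(2, 4), label = "low")))
  net <- build_layer_network(co, toy, 4, subject_id = "A")
  v <- vectorize_network(net)
  expect_length(v, 6)
  expect_named(v, c("L4_e01_02", "L4_e01_03", "L4_e01_04",
                    "L4_e02_03", "L4_e02_04", "L4_e03_04"))
  expect_equal(unname(v),
               unclass(net)[cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4))])
  net1 <- build_layer_network(co, toy, 1, subject_id = "A")
  expect_length(vectorize_network(net1), 0)
})

test_that("edge-vector length is n(n-1)/2 at every layer", {
  co <- simulate_cohort(sim_config(n_per_group = 2), seed = 2)
  lens <- vapply(1:4, function(l) {
    length(vectorize_network(build_layer_network(co, layer = l,
                                                 subject_id = "S001")))
  }, integer(1))
  expect_equal(lens, c(0L, 91L, 630L, 3003L))
})
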