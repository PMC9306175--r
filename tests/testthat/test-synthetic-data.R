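test_that("scenario presets carry the study parameter settings", {
  presets <- scenario_presets()
  expect_named(presets, c("2d", "small_n_large_p", "irrelevant_features"))

  s <- presets[["2d"]]
  expect_equal(s$n_items, 100L)
  expect_equal(s$n_relevant, 2L)
  expect_equal(s$n_irrelevant, 0L)
  expect_equal(s$n_clusters, 5L)
  expect_equal(s$delta_mu, 3)

  s <- presets[["small_n_large_p"]]
  expect_equal(s$n_items, 50L)
  expect_equal(s$n_relevant, 500L)
  expect_equal(s$n_clusters, 5L)
  expect_equal(s$delta_mu, 1)

  s <- presets[["irrelevant_features"]]
  expect_equal(s$n_items, 200L)
  expect_equal(s$n_relevant, 20L)
  expect_equal(s$n_irrelevant, 100L)
  expect_equal(s$n_clusters, 5L)
  expect_equal(s$delta_mu, 1)

  for (s in presets) {
    expect_equal(s$weights, rep(1 / 5, 5))
    expect_equal(s$variance, 1)
  }
})

test_that("scenario validation names the violated invariant", {
  expect_error(mixture_scenario(0, 2, 0, 5, 1), "n_items")
  expect_error(mixture_scenario(10, 2, 0, 5, -1), "delta_mu")
  expect_error(mixture_scenario(10, 2, 0, 5, 1, variance = 0), "variance")
  expect_error(mixture_scenario(10, 2, 0, 5, 1, weights = c(0.6, 0.6)),
               "n_clusters|weights")
  expect_error(mixture_scenario(10, 2, 0, 2, 1, weights = c(0.7, 0.4)),
               "sum to 1")
  expect_error(mixture_scenario(10, 2, 0, 2, 1, weights = c(1.2, -0.2)),
               "positive")
  expect_error(mixture_scenario(10, 0, 0, 2, 1), "feature count")
})

test_that("generation is reproducible and respects shapes and masks", {
  ds1 <- simulate_mixture("2d", seed = 11)
  ds2 <- simulate_mixture("2d", seed = 11)
  expect_identical(ds1, ds2)

  expect_equal(dim(ds1$data), c(100L, 2L))
  expect_true(all(ds1$labels %in% 1:5))
  expect_equal(sum(ds1$relevance), 2L)

  ds3 <- simulate_mixture("irrelevant_features", seed = 4)
  expect_equal(dim(ds3$data), c(200L, 120L))
  expect_equal(sum(ds3$relevance), 20L)
  expect_equal(sum(!ds3$relevance), 100L)

  ds4 <- simulate_mixture("2d", seed = 12)
  expect_false(identical(ds1$data, ds4$data))
})

test_that("features are standardised by default, raw when asked", {
  ds <- simulate_mixture("2d", seed = 5)
  expect_equal(unname(colMeans(ds$data)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(ds$data, 2, sd)), c(1, 1), tolerance = 1e-12)

  raw <- simulate_mixture("2d", seed = 5, standardise = FALSE)
  expect_gt(max(apply(raw$data, 2, sd)), 1.5)
  # standardisation is an affine per-column map of the same draws
  expect_equal(cor(raw$data[, 1], ds$data[, 1]), 1, tolerance = 1e-12)
})

test_that("cluster proportions follow the mixture weights", {
  pvals <- vapply(1:100, function(s) {
    ds <- simulate_mixture("2d", seed = s)
    counts <- tabulate(ds$labels, nbins = 5)
    suppressWarnings(stats::chisq.test(counts, p = rep(1 / 5, 5))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals >= 0.01), 0.95)
})

test_that("within-cluster variance matches the generating variance", {
  scn <- mixture_scenario(n_items = 3000, n_relevant = 3, n_irrelevant = 0,
                          n_clusters = 2, delta_mu = 4, variance = 1.7)
  ds <- simulate_mixture(scn, seed = 8, standardise = FALSE)
  for (k in 1:2) {
    v <- apply(ds$data[ds$labels == k, ], 2, var)
    expect_lt(max(abs(v - 1.7) / 1.7), 0.1)
  }
})

test_that("irrelevant features carry no clustering signal", {
  mean_abs_cor <- vapply(1:50, function(s) {
    ds <- simulate_mixture("irrelevant_features", seed = s)
    noise <- ds$data[, !ds$relevance, drop = FALSE]
    mean(abs(cor(noise, ds$labels)))
  }, numeric(1))
  expect_lt(mean(mean_abs_cor), 0.1)
})

test_that("zero separation removes all recoverable signal", {
  scn <- mixture_scenario(n_items = 300, n_relevant = 5, n_irrelevant = 0,
                          n_clusters = 5, delta_mu = 0)
  ds <- simulate_mixture(scn, seed = 1)
  set.seed(99)
  km <- stats::kmeans(ds$data, centers = 5, nstart = 5)
  expect_lt(abs(ari(km$cluster, ds$labels)), 0.1)
})

test_that("collinear arrangement places identical ordered means in every feature", {
  scn <- mixture_scenario(n_items = 2000, n_relevant = 2, n_irrelevant = 0,
                          n_clusters = 4, delta_mu = 5,
                          arrangement = "collinear")
  ds <- simulate_mixture(scn, seed = 2, standardise = FALSE)
  expect_equal(ds$means, matrix(c(0, 5, 10, 15), 4, 2))
  for (q in 1:2) {
    emp <- vapply(1:4, function(k) mean(ds$data[ds$labels == k, q]), numeric(1))
    expect_equal(emp, c(0, 5, 10, 15), tolerance = 0.3)
  }
})

test_that("permuted arrangement keeps the within-feature mean grid", {
  ds <- simulate_mixture("2d", seed = 3, standardise = FALSE)
  for (q in 1:2) {
    expect_setequal(ds$means[, q], (0:4) * 3)
    emp <- vapply(1:5, function(k) mean(ds$data[ds$labels == k, q]), numeric(1))
    expect_equal(emp, ds$means[, q], tolerance = 0.8)
  }
})

test_that("tidy() gives one row per data cell with labels attached", {
  ds <- simulate_mixture("2d", seed = 1)
  td <- tidy(ds)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 200L)
  expect_equal(sum(td$relevant), 200L)
  expect_equal(td$value[1], ds$data[1, 1])
})
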