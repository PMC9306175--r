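test_that("prior partition draws match the Dirichlet-multinomial closed form", {
  hy <- mixture_hyperparameters(k_max = 2, dirichlet_alpha = 1)
  set.seed(1)
  expect_length(sample_prior_partition(1, hy), 1)

  draws <- replicate(20000, {
    p <- sample_prior_partition(2, hy)
    p[1] == p[2]
  })
  p_true <- (1 + 1) / (2 * 1 + 1)  # (alpha + 1) / (k alpha + 1)
  expect_lt(abs(mean(draws) - p_true), 4 * sqrt(p_true * (1 - p_true) / 20000))

  # large alpha: weights concentrate at uniform, P(co-cluster) -> 1/k
  hy_flat <- mixture_hyperparameters(k_max = 4, dirichlet_alpha = 1e6)
  set.seed(2)
  draws <- replicate(20000, {
    p <- sample_prior_partition(2, hy_flat)
    p[1] == p[2]
  })
  expect_lt(abs(mean(draws) - 1 / 4), 0.015)
})

test_that("chains are deterministic given their seed and have the right shape", {
  toy <- toy_clustered_data()
  hy <- mixture_hyperparameters(k_max = 10)
  ch1 <- run_chain(toy$data, depth = 50, seed = 7, hyper = hy)
  ch2 <- run_chain(toy$data, depth = 50, seed = 7, hyper = hy)
  expect_identical(ch1$partitions, ch2$partitions)
  expect_identical(ch1$loglik, ch2$loglik)

  expect_equal(nrow(ch1$partitions), 50L)
  expect_length(ch1$loglik, 50L)
  expect_true(all(ch1$partitions >= 1 & ch1$partitions <= 10))

  ch3 <- run_chain(toy$data, depth = 1, seed = 7, hyper = hy)
  expect_equal(nrow(ch3$partitions), 1L)

  thin <- run_chain(toy$data, depth = 50, seed = 7, hyper = hy, thin = 10)
  expect_equal(thin$recorded_iterations, c(10L, 20L, 30L, 40L, 50L))
  expect_identical(thin$partitions[5, ], ch1$partitions[50, ])
})

test_that("sweeps preserve the mixture-state invariants", {
  toy <- toy_clustered_data()
  hy <- mixture_hyperparameters(k_max = 8)
  hyr <- ccbayes:::resolve_hyperparameters(hy, toy$data)
  set.seed(5)
  state <- ccbayes:::draw_prior_state(toy$data, hyr, "gaussian")
  for (i in 1:5) {
    state <- gibbs_sweep(state, toy$data, hy)
    expect_equal(sum(state$weights), 1, tolerance = 1e-10)
    expect_true(all(state$partition >= 1 & state$partition <= 8))
    expect_true(all(state$variances > 0))
    expect_equal(state$log_likelihood, log_likelihood(state, toy$data),
                 tolerance = 1e-8)
  }
})

test_that("a single-item dataset is handled end to end", {
  x <- matrix(c(0.3, -0.2), nrow = 1)
  hy <- mixture_hyperparameters(k_max = 3, prior_mean = 0, prior_rate = 0.5)
  ch <- run_chain(x, depth = 10, seed = 1, hyper = hy)
  expect_true(all(ch$partitions %in% 1:3))
  expect_true(all(is.finite(ch$loglik)))
})

test_that("log-likelihood matches closed forms and a naive oracle", {
  state <- structure(
    list(partition = 1L, weights = 1, means = matrix(0, 1, 1),
         variances = matrix(1, 1, 1), model = "gaussian"),
    class = "mixture_state"
  )
  expect_equal(log_likelihood(state, matrix(0)), -0.5 * log(2 * pi),
               tolerance = 1e-12)

  set.seed(4)
  x <- matrix(rnorm(12), 4, 3)
  state <- structure(
    list(partition = rep(1L, 4), weights = c(0.2, 0.5, 0.3),
         means = matrix(rnorm(9), 3, 3),
         variances = matrix(rgamma(9, 3, 2), 3, 3), model = "gaussian"),
    class = "mixture_state"
  )
  expect_equal(log_likelihood(state, x), naive_log_likelihood(state, x),
               tolerance = 1e-10)

  perm <- c(3, 1, 2)
  permuted <- state
  permuted$weights <- state$weights[perm]
  permuted$means <- state$means[perm, ]
  permuted$variances <- state$variances[perm, ]
  expect_equal(log_likelihood(permuted, x), log_likelihood(state, x),
               tolerance = 1e-12)
})

test_that("invalid data is rejected with informative errors", {
  hy <- mixture_hyperparameters(k_max = 2)
  x <- matrix(c(1, NA, 0, 1), 2)
  expect_error(run_chain(x, depth = 2, seed = 1, hyper = hy), "non-finite")
  xb <- matrix(c(0, 1, 2, 0), 2)
  expect_error(run_chain(xb, depth = 2, seed = 1, model = "bernoulli",
                         hyper = hy), "\\{0, 1\\}")
})

test_that("posterior enumeration handles edge cases and refusals", {
  hy <- mixture_hyperparameters(k_max = 2, prior_mean = 0, prior_rate = 0.5)
  expect_equal(enumerate_posterior_coclustering(matrix(1.2), hy),
               matrix(1, 1, 1))

  # identical observations co-cluster more than under the prior alone
  x <- matrix(c(0.7, 0.7), ncol = 1)
  co <- enumerate_posterior_coclustering(x, hy)
  prior_co <- (hy$dirichlet_alpha + 1) / (2 * hy$dirichlet_alpha + 1)
  expect_gt(co[1, 2], prior_co)

  # widely separated pairs resolve to near 0/1
  x <- matrix(c(-5, -5, 5, 5), ncol = 1)
  hy1 <- mixture_hyperparameters(k_max = 2, dirichlet_alpha = 1,
                                 prior_mean = 0, prior_rate = 0.5)
  co <- enumerate_posterior_coclustering(x, hy1)
  expect_gt(min(co[1, 2], co[3, 4]), 0.95)
  expect_lt(max(co[1, 3], co[1, 4], co[2, 3], co[2, 4]), 0.05)

  big <- matrix(rnorm(30), ncol = 1)
  expect_error(enumerate_posterior_coclustering(big, hy), "bound")
})

test_that("enumeration is exactly equivariant under item permutation", {
  set.seed(10)
  x <- matrix(rnorm(10), 5, 2)
  hy <- mixture_hyperparameters(k_max = 2, prior_mean = 0, prior_rate = 0.4)
  co <- enumerate_posterior_coclustering(x, hy)
  perm <- c(4, 1, 5, 2, 3)
  co_perm <- enumerate_posterior_coclustering(x[perm, ], hy)
  expect_equal(co_perm, co[perm, perm], tolerance = 1e-12)
})

test_that("Gibbs co-clustering frequencies track the exact posterior", {
  set.seed(7)
  x <- matrix(rnorm(4), ncol = 1)
  hy <- mixture_hyperparameters(k_max = 2, dirichlet_alpha = 0.5,
                                prior_mean = 0, prior_rate = 0.5)
  enum <- enumerate_posterior_coclustering(x, hy)
  ch <- run_chain(x, depth = 2e4, seed = 11, hyper = hy)
  keep <- ch$recorded_iterations > 2e3
  emp <- unclass(consensus_matrix(ch$partitions[keep, ]))
  expect_lt(max(abs(emp - enum)), 0.05)
})

test_that("Bernoulli sampler agrees with its collapsed enumeration", {
  xb <- rbind(c(1, 1, 1), c(1, 1, 0), c(0, 0, 0), c(0, 1, 0))
  hy <- mixture_hyperparameters(k_max = 2, dirichlet_alpha = 0.5)
  enum <- enumerate_posterior_coclustering(xb, hy, model = "bernoulli")
  ch <- run_chain(xb, depth = 3e4, seed = 21, model = "bernoulli", hyper = hy)
  keep <- ch$recorded_iterations > 3e3
  emp <- unclass(consensus_matrix(ch$partitions[keep, ]))
  expect_lt(max(abs(emp - enum)), 0.05)
})

test_that("overfitted mixtures empty their surplus components", {
  toy <- toy_clustered_data(n_per = 20, k = 3, sep = 6)
  hy <- mixture_hyperparameters(k_max = 20)
  ch <- run_chain(toy$data, depth = 2000, seed = 4, hyper = hy)
  occ <- apply(ch$partitions[ch$recorded_iterations > 1000, ], 1,
               function(p) length(unique(p)))
  expect_equal(as.integer(names(which.max(table(occ)))), 3L)
  expect_gte(mean(occ <= 5), 0.9)
})

test_that("chain log-likelihood rises from its prior start to a plateau", {
  ds <- simulate_mixture("2d", seed = 1)
  ok <- vapply(1:5, function(s) {
    ch <- run_chain(ds, depth = 300, seed = s)
    mean(tail(ch$loglik, 100)) > ch$loglik[1]
  }, logical(1))
  expect_true(all(ok))
})
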