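test_that("pear matches its definition and a naive double-loop oracle", {
  p <- c(1, 1, 2, 2, 3)
  sim <- outer(p, p, function(a, b) (a == b) * 1)
  diag(sim) <- 1
  expect_equal(pear(p, sim), 1)

  # constant off-diagonal similarity: expected agreement cancels exactly
  q <- 0.37
  sim_q <- matrix(q, 5, 5)
  diag(sim_q) <- 1
  expect_equal(pear(c(1, 1, 2, 3, 3), sim_q), 0, tolerance = 1e-12)

  set.seed(30)
  for (i in 1:20) {
    sim <- random_similarity(5)
    cand <- random_partition(5, 3)
    expect_equal(pear(cand, sim), naive_pear(cand, sim), tolerance = 1e-12)
  }
})

test_that("pear is invariant to candidate relabelling and errors when degenerate", {
  set.seed(31)
  sim <- random_similarity(6)
  cand <- c(2, 1, 1, 3, 2, 1)
  relab <- c(7, 4, 4, 2, 7, 4)
  expect_equal(pear(cand, sim), pear(relab, sim), tolerance = 1e-14)

  ones <- matrix(1, 4, 4)
  expect_error(pear(rep(1, 4), ones), "degenerate")
  expect_error(pear(1:3, random_similarity(4)), "length")
})

test_that("max_pear recovers exact block structure and the identity edge case", {
  p <- rep(1:3, times = c(4, 3, 3))
  sim <- outer(p, p, function(a, b) (a == b) * 1)
  diag(sim) <- 1
  mp <- max_pear(sim)
  expect_equal(ari(mp$partition, p), 1)
  expect_equal(mp$pear, 1)

  id <- diag(10)
  mp <- max_pear(id)
  expect_equal(mp$pear, 0)
  ex <- exhaustive_max_pear(diag(6))
  expect_equal(ex$pear, 0)
})

test_that("exhaustive search enumerates all partitions and maximises", {
  sim <- rbind(c(1, .9, .1), c(.9, 1, .1), c(.1, .1, 1))
  ex <- exhaustive_max_pear(sim)
  expect_equal(ex$partition, c(1L, 1L, 2L))

  set.seed(32)
  sim <- random_similarity(5)
  ex <- exhaustive_max_pear(sim)
  for (p in ccbayes:::all_set_partitions(5)) {
    expect_gte(ex$pear + 1e-12, ccbayes:::pear_partition(sim, p))
  }

  expect_equal(exhaustive_max_pear(matrix(1, 1, 1)),
               list(partition = 1L, pear = 1))
  expect_error(exhaustive_max_pear(random_similarity(11)), "N > 10")
})

test_that("max_pear tracks the exhaustive optimum on random similarities", {
  set.seed(33)
  n_match <- 0
  for (i in 1:25) {
    n <- sample(5:8, 1)
    sim <- random_similarity(n)
    mp <- max_pear(sim)
    ex <- exhaustive_max_pear(sim)
    expect_gte(mp$pear, ex$pear - 0.02)
    if (abs(mp$pear - ex$pear) < 1e-9) n_match <- n_match + 1
  }
  expect_gte(n_match, 20)
})

test_that("merging blocks with mutual similarity one never lowers pear", {
  set.seed(34)
  # blocks 1 and 2 are identical in the similarity (all cross entries 1)
  n <- 9
  blocks <- rep(1:3, each = 3)
  sim <- matrix(runif(n * n, 0, 0.3), n, n)
  sim <- (sim + t(sim)) / 2
  sim[blocks %in% 1:2, blocks %in% 1:2] <- 1
  diag(sim) <- 1
  split_val <- ccbayes:::pear_partition(sim, blocks)
  merged <- ifelse(blocks == 2, 1, blocks)
  expect_gte(ccbayes:::pear_partition(sim, merged), split_val)
})

test_that("similarity validation rejects malformed matrices", {
  m <- random_similarity(4)
  m[1, 2] <- m[1, 2] + 1e-6
  expect_error(max_pear(m), "symmetric")
  m <- random_similarity(4)
  diag(m)[2] <- 0.9
  expect_error(max_pear(m), "unit diagonal")
  m <- random_similarity(4)
  m[1, 2] <- m[2, 1] <- 1.4
  expect_error(max_pear(m), "\\[0, 1\\]")
})
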