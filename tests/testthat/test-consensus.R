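test_that("consensus matrix counts co-clustering proportions", {
  cm <- consensus_matrix(list(c(1, 1, 2), c(1, 2, 2)))
  expect_equal(cm[1, 2], 0.5)
  expect_equal(cm[1, 3], 0)
  expect_equal(cm[2, 3], 0.5)
  expect_equal(diag(cm), rep(1, 3))

  p <- c(2, 2, 1, 3)
  cm <- consensus_matrix(list(p, p, p))
  expect_equal(unclass(cm), outer(p, p, function(a, b) (a == b) * 1),
               ignore_attr = TRUE)
})

test_that("consensus matrices are symmetric, unit-diagonal rationals of 1/W", {
  set.seed(20)
  for (w in c(3, 7, 10)) {
    parts <- lapply(seq_len(w), function(i) random_partition(12, 4))
    cm <- consensus_matrix(parts)
    expect_equal(unclass(cm), t(unclass(cm)))
    expect_equal(diag(cm), rep(1, 12))
    expect_true(all(cm >= 0 & cm <= 1))
    expect_equal(cm * w, round(cm * w), tolerance = 1e-12)
  }
  expect_error(consensus_matrix(list(c(1, 2), c(1, 2, 3))), "same length")
  expect_error(consensus_matrix(list()), "no partitions")
})

test_that("ensembles are deterministic and validate their configuration", {
  toy <- toy_clustered_data()
  hy <- mixture_hyperparameters(k_max = 6)
  e1 <- run_ensemble(toy$data, width = 4, depth = 20, seeds = 5, hyper = hy)
  e2 <- run_ensemble(toy$data, width = 4, depth = 20, seeds = 5, hyper = hy)
  expect_identical(e1$final, e2$final)
  expect_equal(dim(e1$final), c(4L, nrow(toy$data)))

  e3 <- run_ensemble(toy$data, width = 1, depth = 1, seeds = 9, hyper = hy)
  expect_equal(dim(e3$final), c(1L, nrow(toy$data)))

  expect_error(run_ensemble(toy$data, width = 3, depth = 5,
                            seeds = c(1, 1, 2), hyper = hy), "distinct")
  expect_error(run_ensemble(toy$data, width = 2, depth = 5, seeds = 1:3,
                            hyper = hy), "one seed per chain")
  expect_error(run_ensemble(toy$data, width = 2, depth = 5, seeds = 1:2,
                            hyper = hy, checkpoints = c(2, 4)),
               "end at `depth`")
})

test_that("grid cells equal fresh ensembles run at that depth and width", {
  toy <- toy_clustered_data(n_per = 8, k = 2, sep = 8, seed = 6)
  hy <- mixture_hyperparameters(k_max = 5)
  grid <- consensus_grid(toy$data, depth_grid = c(5, 15), width_grid = c(2, 4),
                         seeds = 3, hyper = hy)
  for (i in 1:2) {
    for (j in 1:2) {
      d <- grid$depth_grid[i]
      w <- grid$width_grid[j]
      fresh <- run_ensemble(toy$data, width = w, depth = d, seeds = 3,
                            hyper = hy)
      expect_equal(unclass(grid$cms[[i, j]]),
                   unclass(consensus_matrix(fresh$final)),
                   ignore_attr = TRUE)
    }
  }
  # nested widths reuse chain prefixes: narrow grid cells match wide ones
  expect_equal(attr(grid$cms[[1, 1]], "width_used"), 2L)
  expect_equal(attr(grid$cms[[2, 2]], "width_used"), 4L)
})

test_that("stability curves measure sequential consensus-matrix change", {
  cm <- function(m) ccbayes:::new_consensus_matrix(m, width_used = 10)
  base <- random_similarity(6)
  shifted <- base
  shifted[upper.tri(shifted)] <- pmin(shifted[upper.tri(shifted)] + 0.1, Inf)
  shifted[lower.tri(shifted)] <- t(shifted)[lower.tri(shifted)]

  cms <- vector("list", 2)
  dim(cms) <- c(2, 1)
  cms[[1, 1]] <- cm(base)
  cms[[2, 1]] <- cm(base)
  grid <- structure(list(cms = cms, depth_grid = c(10L, 20L),
                         width_grid = 5L, seeds = 1L, model = "gaussian"),
                    class = "consensus_grid")
  sc <- stability_curves(grid)
  expect_equal(sc$mad, 0)
  expect_true(all(sc$stable))

  cms[[2, 1]] <- cm(shifted)
  grid$cms <- cms
  sc <- stability_curves(grid)
  expect_equal(sc$mad, 0.1, tolerance = 1e-12)
  expect_false(any(sc$stable))

  singleton <- grid
  singleton$cms <- cms[1, 1, drop = FALSE]
  singleton$depth_grid <- 10L
  expect_error(stability_curves(singleton), "at least two")
})

test_that("consensus_clustering wires ensemble, matrix and point estimate", {
  toy <- toy_clustered_data(n_per = 10, k = 3, sep = 8, seed = 2)
  hy <- mixture_hyperparameters(k_max = 8)
  cc <- consensus_clustering(toy$data, width = 30, depth = 100, seeds = 1,
                             hyper = hy)
  expect_s3_class(cc, "consensus_clustering")
  expect_equal(ari(cc$point_estimate, toy$labels), 1)
  expect_gt(cc$pear, 0.9)

  g <- glance(cc)
  expect_equal(g$width, 30L)
  expect_equal(g$n_clusters, 3L)
  td <- tidy(cc)
  expect_equal(nrow(td), choose(30, 2))
  expect_true(all(td$proportion >= 0 & td$proportion <= 1))
})
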