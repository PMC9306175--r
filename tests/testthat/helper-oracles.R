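# Naive reference implementations used as independent oracles. These are
# deliberately written as explicit pair loops, independent of the package's
# vectorised code paths.

naive_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  btot <- n11 + n00 + n10 + n01
  index <- n11
  expd <- (n11 + n10) * (n11 + n01) / btot
  mx <- ((n11 + n10) + (n11 + n01)) / 2
  if (abs(mx - expd) < 1e-300) return(1)
  (index - expd) / (mx - expd)
}

naive_pear <- function(partition, sim) {
  n <- length(partition)
  s1 <- s2 <- s3 <- 0
  b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same <- partition[i] == partition[j]
      if (same) {
        s1 <- s1 + sim[i, j]
        s2 <- s2 + 1
      }
      s3 <- s3 + sim[i, j]
      b <- b + 1
    }
  }
  (s1 - s2 * s3 / b) / (0.5 * (s2 + s3) - s2 * s3 / b)
}

naive_log_likelihood <- function(state, data) {
  total <- 0
  for (i in seq_len(nrow(data))) {
    acc <- 0
    for (k in seq_along(state$weights)) {
      dens <- 1
      for (p in seq_len(ncol(data))) {
        dens <- dens * stats::dnorm(data[i, p], state$means[k, p],
                                    sqrt(state$variances[k, p]))
      }
      acc <- acc + state$weights[k] * dens
    }
    total <- total + log(acc)
  }
  total
}

random_partition <- function(n, kmax) {
  sample.int(kmax, n, replace = TRUE)
}

random_similarity <- function(n) {
  s <- matrix(stats::runif(n * n), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

# A small, clearly clustered Gaussian dataset for sampler tests; centres are
# deterministic and pairwise distinct.
toy_clustered_data <- function(n_per = 20, k = 3, sep = 6, p = 2, seed = 3) {
  set.seed(seed)
  centers <- sep * sapply(seq_len(p), function(q) (seq_len(k) - 1 + q) %% k)
  centers <- matrix(centers, k, p)
  x <- matrix(stats::rnorm(n_per * k * p), n_per * k, p)
  labels <- rep(seq_len(k), each = n_per)
  for (q in seq_len(p)) x[, q] <- x[, q] + centers[labels, q]
  list(data = scale(x), labels = labels)
}

# Minimal mcmc_chain stub for diagnostics tests.
fake_chain <- function(partitions, iterations = seq_len(nrow(partitions)),
                       loglik = rep(0, max(iterations))) {
  structure(
    list(partitions = partitions, recorded_iterations = as.integer(iterations),
         loglik = loglik, depth = max(iterations), seed = 0L,
         model = "gaussian"),
    class = "mcmc_chain"
  )
}
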