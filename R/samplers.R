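#' @title MCMC samplers for overfitted Bayesian mixtures
#' @description Uncollapsed ("parameters-and-allocations") Gibbs samplers for
#'   finite mixtures with diagonal-Gaussian or Bernoulli components, the
#'   prior-partition initialiser used by the consensus ensemble, and an exact
#'   enumeration oracle for small instances.
#' @name samplers
NULL

# Coerce user input to a plain numeric matrix. Accepts a labelled_dataset, a
# numeric matrix, or a data frame whose first non-numeric column (if any) is
# taken as item identifiers.
as_data_matrix <- function(data, model = c("gaussian", "bernoulli")) {
  model <- match.arg(model)
  if (inherits(data, "labelled_dataset")) data <- data$data
  if (is.data.frame(data)) {
    num <- vapply(data, is.numeric, logical(1))
    ids <- NULL
    if (!all(num)) {
      idcol <- which(!num)[1]
      ids <- as.character(data[[idcol]])
    }
    x <- as.matrix(data[num])
    if (!is.null(ids)) rownames(x) <- ids
    data <- x
  }
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix, data frame or labelled_dataset",
         call. = FALSE)
  }
  if (any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite data entry at row %d, column %d", bad[1], bad[2]),
         call. = FALSE)
  }
  if (model == "bernoulli" && !all(data %in% c(0, 1))) {
    stop("binary model requires all data entries in {0, 1}", call. = FALSE)
  }
  data
}

#' Draw a partition from the uninformative prior
#'
#' Draws mixture weights from `Dirichlet(alpha, ..., alpha)` over `k_max`
#' components and then allocates each item independently from those weights.
#' This is the random initialisation used for every ensemble chain; the
#' marginal probability that two items share a component is
#' `(alpha + 1) / (k_max * alpha + 1)`.
#'
#' @param n_items Number of items.
#' @param hyper A [mixture_hyperparameters] object (only `k_max` and
#'   `dirichlet_alpha` are used).
#' @return Integer vector of length `n_items` with values in `1..k_max`.
#' @export
sample_prior_partition <- function(n_items, hyper = mixture_hyperparameters()) {
  stopifnot(is_count(n_items), n_items >= 1)
  w <- rgamma(hyper$k_max, shape = hyper$dirichlet_alpha)
  w <- pmax(w, 1e-300)
  sample.int(hyper$k_max, n_items, replace = TRUE, prob = w / sum(w))
}

# Draw a full mixture state (partition, weights, component parameters) from
# the prior. Consumes the current RNG stream in a fixed order so chains are
# reproducible from a single seed.
draw_prior_state <- function(data, hyper, model = c("gaussian", "bernoulli")) {
  model <- match.arg(model)
  n <- nrow(data)
  p <- ncol(data)
  k <- hyper$k_max
  g <- pmax(rgamma(k, shape = hyper$dirichlet_alpha), 1e-300)
  weights <- g / sum(g)
  partition <- sample.int(k, n, replace = TRUE, prob = weights)
  state <- list(partition = partition, weights = weights, model = model)
  if (model == "gaussian") {
    gam <- matrix(rgamma(k * p, shape = hyper$prior_shape), k, p)
    vars <- sweep(1 / gam, 2, hyper$prior_rate, "*")
    means <- sweep(matrix(rnorm(k * p), k, p) * sqrt(vars / hyper$prior_shrinkage),
                   2, hyper$prior_mean, "+")
    state$means <- means
    state$variances <- vars
  } else {
    state$rates <- matrix(stats::rbeta(k * p, hyper$beta_a, hyper$beta_b), k, p)
  }
  state$log_likelihood <- log_likelihood(state, data)
  class(state) <- "mixture_state"
  state
}

#' Mixture model log-likelihood
#'
#' Observed-data log-likelihood `sum_i log sum_k pi_k p(x_i | theta_k)` of a
#' mixture state, evaluated stably in log space.
#'
#' @param state A `mixture_state` (as produced by [gibbs_sweep()] or stored in
#'   a chain's `final_state`).
#' @param data Numeric data matrix matching the state's dimensions.
#' @return A single finite number.
#' @export
log_likelihood <- function(state, data) {
  data <- as_data_matrix(data, state$model %||% "gaussian")
  lp <- component_log_densities(state, data)
  lp <- sweep(lp, 2, log(state$weights), "+")
  m <- apply(lp, 1, max)
  ll_i <- m + log(rowSums(exp(lp - m)))
  if (any(!is.finite(ll_i))) {
    stop("non-finite log-likelihood for item ", which(!is.finite(ll_i))[1],
         call. = FALSE)
  }
  sum(ll_i)
}

# N x K matrix of log p(x_i | theta_k).
component_log_densities <- function(state, data) {
  if (!is.null(state$means)) {
    v <- state$variances
    b2 <- state$means / v
    ck <- rowSums(state$means * b2 / 2 + 0.5 * log(2 * pi * v))
    lp <- data %*% t(b2) - (data^2) %*% t(0.5 / v)
    sweep(lp, 2, ck, "-")
  } else {
    th <- pmin(pmax(state$rates, 1e-12), 1 - 1e-12)
    lp <- data %*% t(log(th) - log1p(-th))
    sweep(lp, 2, rowSums(log1p(-th)), "+")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One full Gibbs sweep
#'
#' Performs a single sweep of the uncollapsed Gibbs sampler: (i) reallocate
#' every item from its full conditional given the current weights and
#' component parameters, (ii) redraw the weights from their Dirichlet full
#' conditional, (iii) redraw every component's parameters from the conjugate
#' posterior given its members (empty components draw from the prior).
#'
#' @param state A `mixture_state`.
#' @param data Data matrix (or data frame / labelled_dataset).
#' @param hyper A [mixture_hyperparameters].
#' @return The updated `mixture_state`, with `log_likelihood` recomputed.
#' @export
gibbs_sweep <- function(state, data, hyper = mixture_hyperparameters()) {
  model <- state$model %||% "gaussian"
  data <- as_data_matrix(data, model)
  hyper <- resolve_hyperparameters(hyper, data)
  res <- run_sweeps(state, data, hyper, nsweeps = 1L, checkpoints = 1L)
  res$state
}

# Shared wrapper around the compiled sweep kernels.
run_sweeps <- function(state, data, hyper, nsweeps, checkpoints) {
  model <- state$model %||% "gaussian"
  cps <- as.integer(checkpoints)
  if (model == "gaussian") {
    out <- gaussian_sweeps_cpp(
      data, as.integer(state$partition) - 1L, state$weights,
      state$means, state$variances,
      hyper$dirichlet_alpha, hyper$prior_mean, hyper$prior_shrinkage,
      hyper$prior_shape, hyper$prior_rate, as.integer(nsweeps), cps
    )
    new_state <- structure(
      list(partition = out$labels + 1L, weights = as.numeric(out$weights),
           means = out$means, variances = out$vars,
           log_likelihood = out$loglik[nsweeps], model = "gaussian"),
      class = "mixture_state"
    )
  } else {
    out <- bernoulli_sweeps_cpp(
      data, as.integer(state$partition) - 1L, state$weights, state$rates,
      hyper$dirichlet_alpha, hyper$beta_a, hyper$beta_b,
      as.integer(nsweeps), cps
    )
    new_state <- structure(
      list(partition = out$labels + 1L, weights = as.numeric(out$weights),
           rates = out$rates,
           log_likelihood = out$loglik[nsweeps], model = model),
      class = "mixture_state"
    )
  }
  list(state = new_state,
       loglik = as.numeric(out$loglik),
       partitions = out$partitions + 1L)
}

#' Run one MCMC chain
#'
#' Initialises from a prior draw (partition, weights and component
#' parameters), then performs `depth` Gibbs sweeps, recording the
#' log-likelihood at every sweep and the partition at every `thin`-th sweep.
#' The chain is fully determined by `seed`.
#'
#' @param data Data matrix, data frame or [simulate_mixture()] output.
#' @param depth Number of sweeps `D` (at least 1).
#' @param seed Integer seed for this chain.
#' @param model `"gaussian"` or `"bernoulli"`.
#' @param hyper A [mixture_hyperparameters].
#' @param thin Partition recording interval (1 = every sweep).
#' @return An object of class `mcmc_chain`: recorded `partitions` (one row
#'   per recorded sweep), `recorded_iterations`, per-sweep `loglik`, the
#'   `final_state`, and the run metadata (`depth`, `seed`, `model`).
#' @export
run_chain <- function(data, depth, seed, model = c("gaussian", "bernoulli"),
                      hyper = mixture_hyperparameters(), thin = 1L) {
  model <- match.arg(model)
  stopifnot(is_count(depth), depth >= 1, is_count(thin), thin >= 1)
  data <- as_data_matrix(data, model)
  hyper <- resolve_hyperparameters(hyper, data)
  set.seed(as.integer(seed))
  state <- draw_prior_state(data, hyper, model)
  rec <- unique(c(seq(thin, depth, by = thin), depth))
  res <- run_sweeps(state, data, hyper, nsweeps = depth, checkpoints = rec)
  partitions <- res$partitions
  storage.mode(partitions) <- "integer"
  colnames(partitions) <- rownames(data)
  structure(
    list(
      partitions = partitions,
      recorded_iterations = as.integer(rec),
      loglik = res$loglik,
      final_state = res$state,
      depth = as.integer(depth),
      seed = as.integer(seed),
      model = model,
      hyper = hyper
    ),
    class = "mcmc_chain"
  )
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("<mcmc_chain> %s model, depth %d, seed %d, %d recorded partitions\n",
              x$model, x$depth, x$seed, nrow(x$partitions)))
  invisible(x)
}

#' @rdname run_chain
#' @param x An `mcmc_chain`.
#' @param ... Unused.
#' @return `tidy()` returns a tibble with one row per sweep (`iteration`,
#'   `loglik`).
#' @export
tidy.mcmc_chain <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$loglik), loglik = x$loglik)
}

#' Exact posterior co-clustering by enumeration
#'
#' Test oracle for small instances: enumerates all `k_max^N` labelled
#' allocations, weighting each by its collapsed marginal likelihood
#' (component parameters integrated out under the conjugate priors) times the
#' Dirichlet-multinomial prior on allocation counts, and returns the exact
#' posterior probability that each pair of items co-clusters. The Gibbs
#' sampler targets the same partition posterior, which the correctness tests
#' exploit.
#'
#' @inheritParams run_chain
#' @param max_states Refusal bound on `k_max^N` (default `1e6`).
#' @return Symmetric N x N matrix of co-clustering probabilities, unit
#'   diagonal.
#' @export
enumerate_posterior_coclustering <- function(data, hyper = mixture_hyperparameters(),
                                             model = c("gaussian", "bernoulli"),
                                             max_states = 1e6) {
  model <- match.arg(model)
  data <- as_data_matrix(data, model)
  hyper <- resolve_hyperparameters(hyper, data)
  n <- nrow(data)
  k <- hyper$k_max
  n_states <- k^n
  if (n_states > max_states) {
    stop(sprintf("instance too large: k_max^N = %g exceeds the bound %g",
                 n_states, max_states), call. = FALSE)
  }
  if (n == 1L) return(matrix(1, 1, 1))

  alpha <- hyper$dirichlet_alpha
  allocs <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  logw <- apply(allocs, 1, function(cc) {
    counts <- tabulate(cc, nbins = k)
    lp <- sum(lgamma(counts + alpha)) - k * lgamma(alpha) +
      lgamma(k * alpha) - lgamma(n + k * alpha)
    for (comp in which(counts > 0)) {
      xs <- data[cc == comp, , drop = FALSE]
      lp <- lp + log_marginal_component(xs, hyper, model)
    }
    lp
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  cocl <- matrix(0, n, n)
  for (r in seq_along(w)) {
    cc <- allocs[r, ]
    cocl <- cocl + w[r] * outer(cc, cc, "==")
  }
  diag(cocl) <- 1
  unname(cocl)
}

# Collapsed marginal likelihood of one component's members (independent
# features; Normal-Inverse-Gamma or Beta-Bernoulli conjugacy).
log_marginal_component <- function(xs, hyper, model) {
  m <- nrow(xs)
  if (model == "gaussian") {
    kap <- hyper$prior_shrinkage
    a0 <- hyper$prior_shape
    b0 <- hyper$prior_rate
    m0 <- hyper$prior_mean
    xbar <- colMeans(xs)
    ssd <- colSums(xs^2) - m * xbar^2
    ssd[ssd < 0] <- 0
    bn <- b0 + 0.5 * ssd + 0.5 * kap * m * (xbar - m0)^2 / (kap + m)
    sum(-0.5 * m * log(2 * pi) + 0.5 * (log(kap) - log(kap + m)) +
          lgamma(a0 + m / 2) - lgamma(a0) + a0 * log(b0) -
          (a0 + m / 2) * log(bn))
  } else {
    s <- colSums(xs)
    sum(lbeta(hyper$beta_a + s, hyper$beta_b + m - s) -
          lbeta(hyper$beta_a, hyper$beta_b))
  }
}
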