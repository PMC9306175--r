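#' Hyperparameters for the overfitted Bayesian mixture
#'
#' The shipped sampler targets an overfitted finite mixture: many more
#' components (`k_max`) than clusters are expected, with a small symmetric
#' Dirichlet concentration (`dirichlet_alpha`, default `1 / k_max`) so that
#' surplus components empty out. Component parameters carry conjugate priors:
#' per feature a Normal-Inverse-Gamma prior on `(mean, variance)` for the
#' Gaussian model, and a Beta prior on the rate for the Bernoulli model.
#'
#' `prior_mean` and `prior_rate` may be left `NULL`, in which case they are
#' resolved per dataset: the prior mean defaults to the feature means, and
#' the Inverse-Gamma rate to `0.1` times the feature variances (so `0.1` for
#' standardised data). Centring the component-variance prior well below the
#' marginal feature variance matters: when clusters are present, most of the
#' marginal variance is between-cluster, and an Inverse-Gamma rate on the
#' marginal scale effectively excludes the small within-cluster variances
#' that genuine components need (its density vanishes exponentially below
#' the rate), which biases the sampler towards merged components. With
#' `prior_shape = 2` the prior keeps infinite variance, so it remains weakly
#' informative.
#'
#' @param k_max Number of mixture components (at least 2).
#' @param dirichlet_alpha Per-component Dirichlet concentration.
#' @param prior_mean Prior mean of each feature's component means (scalar or
#'   per-feature vector), or `NULL` to use the feature means.
#' @param prior_shrinkage Prior shrinkage `kappa`: the prior on a component
#'   mean has variance `sigma2 / kappa`.
#' @param prior_shape Inverse-Gamma shape `a0` on component variances.
#' @param prior_rate Inverse-Gamma rate `b0` (scalar or per-feature), or
#'   `NULL` to use `0.1` times the feature variances.
#' @param beta_a,beta_b Beta prior parameters on Bernoulli rates.
#'
#' @return An object of class `mixture_hyperparameters`.
#' @export
mixture_hyperparameters <- function(k_max = 50,
                                    dirichlet_alpha = 1 / k_max,
                                    prior_mean = NULL,
                                    prior_shrinkage = 0.01,
                                    prior_shape = 2,
                                    prior_rate = NULL,
                                    beta_a = 1,
                                    beta_b = 1) {
  if (!is_count(k_max) || k_max < 2) {
    stop("`k_max` must be an integer >= 2", call. = FALSE)
  }
  for (nm in c("dirichlet_alpha", "prior_shrinkage", "prior_shape",
               "beta_a", "beta_b")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a positive scalar", call. = FALSE)
    }
  }
  if (!is.null(prior_rate) && any(prior_rate <= 0)) {
    stop("`prior_rate` must be positive", call. = FALSE)
  }
  structure(
    list(
      k_max = as.integer(k_max),
      dirichlet_alpha = dirichlet_alpha,
      prior_mean = prior_mean,
      prior_shrinkage = prior_shrinkage,
      prior_shape = prior_shape,
      prior_rate = prior_rate,
      beta_a = beta_a,
      beta_b = beta_b
    ),
    class = "mixture_hyperparameters"
  )
}

#' @export
print.mixture_hyperparameters <- function(x, ...) {
  cat(sprintf(
    "<mixture_hyperparameters> k_max = %d, alpha = %g, kappa = %g, a0 = %g\n",
    x$k_max, x$dirichlet_alpha, x$prior_shrinkage, x$prior_shape
  ))
  invisible(x)
}

# Fill data-dependent prior fields (per-feature mean and rate) against a
# concrete matrix. Idempotent.
resolve_hyperparameters <- function(hyper, data) {
  p <- ncol(data)
  m0 <- hyper$prior_mean
  if (is.null(m0)) m0 <- colMeans(data)
  if (length(m0) == 1L) m0 <- rep(m0, p)
  b0 <- hyper$prior_rate
  if (is.null(b0)) {
    v <- apply(data, 2, var)
    v[v <= 0 | !is.finite(v)] <- 1
    b0 <- 0.1 * v
  }
  if (length(b0) == 1L) b0 <- rep(b0, p)
  if (length(m0) != p || length(b0) != p) {
    stop("per-feature prior vectors must have length ncol(data)", call. = FALSE)
  }
  hyper$prior_mean <- as.numeric(m0)
  hyper$prior_rate <- as.numeric(b0)
  hyper
}
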