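#' Define a finite-mixture simulation scenario
#'
#' A scenario bundles the parameters of the generating model used throughout
#' the simulation machinery: a finite mixture of `n_clusters` Gaussian
#' components with independent features, of which the first `n_relevant`
#' features carry the clustering signal (cluster-specific means, equally
#' spaced `delta_mu` apart) and the remaining `n_irrelevant` features are
#' drawn from a single global distribution regardless of cluster membership.
#'
#' @param n_items Number of items (rows) to generate.
#' @param n_relevant Number of clustering-relevant features.
#' @param n_irrelevant Number of irrelevant (pure-noise) features.
#' @param n_clusters Number of generating clusters.
#' @param delta_mu Distance between neighbouring cluster means within a
#'   single relevant feature: each relevant feature's component means are the
#'   equally spaced grid `0, delta_mu, ..., (K - 1) * delta_mu`.
#' @param variance Shared within-component variance of every feature.
#' @param weights Mixture weights; defaults to equal weights.
#' @param name Optional scenario label.
#' @param arrangement How the grid of means is assigned to clusters across
#'   relevant features: `"permuted"` (default) draws an independent random
#'   assignment per feature, so clusters that are neighbours in one feature
#'   are typically well separated in another; `"collinear"` uses the
#'   identity assignment in every feature, placing all clusters on a single
#'   line (the hardest geometry, where even the Bayes-optimal classifier
#'   confuses neighbouring clusters).
#'
#' @return An object of class `mixture_scenario`.
#' @seealso [scenario_presets()], [simulate_mixture()]
#' @export
mixture_scenario <- function(n_items, n_relevant, n_irrelevant = 0,
                             n_clusters, delta_mu, variance = 1,
                             weights = NULL, name = NULL,
                             arrangement = c("permuted", "collinear")) {
  arrangement <- match.arg(arrangement)
  if (!is_count(n_items) || n_items < 1) {
    stop("invalid scenario: `n_items` must be a positive integer", call. = FALSE)
  }
  if (!is_count(n_relevant) || n_relevant < 0) {
    stop("invalid scenario: `n_relevant` must be a nonnegative integer", call. = FALSE)
  }
  if (!is_count(n_irrelevant) || n_irrelevant < 0) {
    stop("invalid scenario: `n_irrelevant` must be a nonnegative integer", call. = FALSE)
  }
  if (n_relevant + n_irrelevant < 1) {
    stop("invalid scenario: total feature count must be at least 1", call. = FALSE)
  }
  if (!is_count(n_clusters) || n_clusters < 1) {
    stop("invalid scenario: `n_clusters` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(delta_mu) || length(delta_mu) != 1L || delta_mu < 0) {
    stop("invalid scenario: `delta_mu` must be a nonnegative scalar", call. = FALSE)
  }
  if (!is.numeric(variance) || length(variance) != 1L || variance <= 0) {
    stop("invalid scenario: `variance` must be a positive scalar", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1 / n_clusters, n_clusters)
  if (length(weights) != n_clusters) {
    stop("invalid scenario: `weights` must have length `n_clusters`", call. = FALSE)
  }
  if (any(weights <= 0)) {
    stop("invalid scenario: all `weights` must be positive", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("invalid scenario: `weights` must sum to 1 (within 1e-12)", call. = FALSE)
  }
  structure(
    list(
      n_items = as.integer(n_items),
      n_relevant = as.integer(n_relevant),
      n_irrelevant = as.integer(n_irrelevant),
      n_clusters = as.integer(n_clusters),
      delta_mu = as.numeric(delta_mu),
      variance = as.numeric(variance),
      weights = as.numeric(weights),
      name = name,
      arrangement = arrangement
    ),
    class = "mixture_scenario"
  )
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

#' @export
print.mixture_scenario <- function(x, ...) {
  cat(sprintf(
    "<mixture_scenario%s> N = %d, relevant = %d, irrelevant = %d, K = %d, delta_mu = %g, variance = %g\n",
    if (is.null(x$name)) "" else paste0(": ", x$name),
    x$n_items, x$n_relevant, x$n_irrelevant, x$n_clusters, x$delta_mu, x$variance
  ))
  invisible(x)
}

#' Preset simulation scenarios
#'
#' The three study scenarios: a two-feature, well-separated problem (`"2d"`);
#' a high-dimension, low-sample problem (`"small_n_large_p"`) where single
#' chains tend to get stuck; and a problem dominated by noise features
#' (`"irrelevant_features"`). All use five equally weighted clusters with
#' unit within-component variance.
#'
#' @return Named list of [mixture_scenario] objects with names `"2d"`,
#'   `"small_n_large_p"` and `"irrelevant_features"`.
#' @export
scenario_presets <- function() {
  list(
    "2d" = mixture_scenario(
      n_items = 100, n_relevant = 2, n_irrelevant = 0, n_clusters = 5,
      delta_mu = 3, variance = 1, name = "2d"
    ),
    "small_n_large_p" = mixture_scenario(
      n_items = 50, n_relevant = 500, n_irrelevant = 0, n_clusters = 5,
      delta_mu = 1, variance = 1, name = "small_n_large_p"
    ),
    "irrelevant_features" = mixture_scenario(
      n_items = 200, n_relevant = 20, n_irrelevant = 100, n_clusters = 5,
      delta_mu = 1, variance = 1, name = "irrelevant_features"
    )
  )
}

#' Simulate a labelled dataset from a mixture scenario
#'
#' Draws cluster labels i.i.d. from the scenario weights, then generates each
#' relevant feature from a Gaussian whose mean is the cluster's position on
#' that feature's mean grid (`0, delta_mu, ..., (K - 1) * delta_mu`, assigned
#' to clusters per the scenario's `arrangement`), and each irrelevant feature
#' from `Normal(0, variance)` independently of the label. By default every
#' feature is then standardised to zero mean and unit variance, which makes
#' the scale-free hyperparameter defaults of the samplers appropriate
#' without tuning.
#'
#' @param scenario A [mixture_scenario], or the name of a preset from
#'   [scenario_presets()].
#' @param seed Integer seed; identical `(scenario, seed)` pairs give
#'   bit-identical output.
#' @param standardise Standardise each feature after generation? Default `TRUE`.
#'
#' @return An object of class `labelled_dataset`: a list with `data` (an
#'   `n_items` x P numeric matrix with item and feature names), `labels`
#'   (integer generating allocation in `1..n_clusters`), `relevance`
#'   (logical length-P mask, `TRUE` for signal features), `means` (the
#'   K x `n_relevant` matrix of generating cluster means, pre-
#'   standardisation), plus the scenario and seed used.
#' @export
simulate_mixture <- function(scenario, seed, standardise = TRUE) {
  if (is.character(scenario)) {
    presets <- scenario_presets()
    if (!scenario %in% names(presets)) {
      stop("unknown preset '", scenario, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    scenario <- presets[[scenario]]
  }
  stopifnot(inherits(scenario, "mixture_scenario"))
  n <- scenario$n_items
  k <- scenario$n_clusters
  p_rel <- scenario$n_relevant
  p_irr <- scenario$n_irrelevant
  p <- p_rel + p_irr

  set.seed(as.integer(seed))
  labels <- sample.int(k, n, replace = TRUE, prob = scenario$weights)
  grid <- (seq_len(k) - 1) * scenario$delta_mu
  mu <- if (p_rel > 0) {
    if (identical(scenario$arrangement %||% "permuted", "collinear")) {
      matrix(grid, k, p_rel)
    } else {
      sapply(seq_len(p_rel), function(ignored) grid[sample.int(k)])
    }
  } else {
    matrix(numeric(0), k, 0)
  }
  mu <- matrix(mu, nrow = k)
  sdv <- sqrt(scenario$variance)
  x <- matrix(rnorm(n * p, sd = sdv), nrow = n, ncol = p)
  for (q in seq_len(p_rel)) {
    x[, q] <- x[, q] + mu[labels, q]
  }
  if (standardise) {
    x <- scale_features(x)
  }
  rownames(x) <- sprintf("item_%03d", seq_len(n))
  colnames(x) <- c(
    if (p_rel > 0) sprintf("signal_%03d", seq_len(p_rel)),
    if (p_irr > 0) sprintf("noise_%03d", seq_len(p_irr))
  )
  structure(
    list(
      data = x,
      labels = as.integer(labels),
      relevance = c(rep(TRUE, p_rel), rep(FALSE, p_irr)),
      means = mu,
      scenario = scenario,
      seed = as.integer(seed),
      standardised = standardise
    ),
    class = "labelled_dataset"
  )
}

# Column-wise standardisation; zero-variance columns are centred only.
scale_features <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, s, "/")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf(
    "<labelled_dataset> %d items x %d features (%d signal, %d noise), %d clusters, seed %d\n",
    nrow(x$data), ncol(x$data), sum(x$relevance), sum(!x$relevance),
    x$scenario$n_clusters, x$seed
  ))
  invisible(x)
}

#' @rdname simulate_mixture
#' @param x A `labelled_dataset`.
#' @param ... Unused.
#' @return `tidy()` returns a long tibble with one row per item/feature cell
#'   (`item`, `feature`, `value`, `label`, `relevant`).
#' @export
tidy.labelled_dataset <- function(x, ...) {
  tibble::tibble(
    item = rep(rownames(x$data), times = ncol(x$data)),
    feature = rep(colnames(x$data), each = nrow(x$data)),
    value = as.vector(x$data),
    label = rep(x$labels, times = ncol(x$data)),
    relevant = rep(x$relevance, each = nrow(x$data))
  )
}
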