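#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions
#' (Hubert-Arabie form). Equals 1 iff the partitions coincide up to
#' relabelling and has expectation approximately 0 for independent random
#' partitions. Symmetric and invariant to label permutations.
#'
#' @param a,b Equal-length cluster label vectors.
#' @return A single number, at most 1.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) {
    stop("partitions must have the same length", call. = FALSE)
  }
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  b2 <- choose(n, 2)
  expd <- sa * sb / b2
  mx <- (sa + sb) / 2
  if (abs(mx - expd) < 1e-300) return(1)
  (sij - expd) / (mx - expd)
}

#' Gaussian mixture baseline by EM with BIC model selection
#'
#' The maximum-likelihood comparator: for every `k` in `k_range` and every
#' covariance family, a Gaussian mixture is fitted by EM initialised from an
#' agglomerative hierarchical clustering of the data cut at `k` clusters,
#' and the model maximising `BIC = 2 loglik - n_params log N` is selected.
#' The families are per-component spherical, diagonal or full covariance — a
#' deliberately reduced version of the full model taxonomy of dedicated GMM
#' packages, sufficient for the qualitative comparisons made here.
#'
#' The default initialisation is mclust's model-based agglomeration
#' (unconstrained-covariance criterion on an SVD transformation of the
#' data), the initialisation the reference GMM tool itself uses. This choice
#' is behaviourally important in noisy high-dimensional data: model-based
#' agglomeration there tends to shave off single outlying items rather than
#' split the bulk, so EM never receives a genuine split to refine and BIC
#' falls back to one component — the characteristic collapse of
#' maximum-likelihood mixtures in the presence of many irrelevant features.
#' A Ward-linkage initialisation (`init = "ward"`) is offered as a stronger
#' alternative that frequently escapes this failure mode.
#'
#' Components whose variance collapses (or whose covariance loses rank) are
#' pruned with a warning and the fit continues with the remainder; a fit
#' with no viable components is recorded as failed (`NA` BIC).
#'
#' @param data Numeric matrix or data frame (items in rows).
#' @param k_range Numbers of components to try; should include 1.
#' @param families Subset of `c("diagonal", "full", "spherical")`.
#' @param init `"model"` (mclust's model-based agglomeration, the default)
#'   or `"ward"` (Ward-linkage `hclust`).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations per fit.
#' @return An object of class `gmm_bic`: `partition` (hard assignment of the
#'   best model), `k` (its effective number of components), `family`,
#'   `bic`, `loglik` and `bic_table` (a tibble over all fits).
#' @export
em_gmm_bic <- function(data, k_range = 1:9,
                       families = c("diagonal", "full", "spherical"),
                       init = c("model", "ward"),
                       tol = 1e-6, max_iter = 500L) {
  data <- as_data_matrix(data, "gaussian")
  families <- match.arg(families, several.ok = TRUE)
  init <- match.arg(init)
  n <- nrow(data)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1) || any(k_range > n)) {
    stop("`k_range` must lie in 1..N", call. = FALSE)
  }
  cut_at <- hierarchical_cutter(data, init)

  rows <- list()
  best <- NULL
  for (family in families) {
    for (k in k_range) {
      start <- if (k == 1L) rep(1L, n) else cut_at(k)
      fit <- em_fit(data, k, family, start, tol = tol, max_iter = max_iter)
      bic <- if (fit$failed) NA_real_
             else 2 * fit$loglik - fit$n_params * log(n)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family = family, k = k,
        k_effective = if (fit$failed) NA_integer_ else fit$k_effective,
        loglik = if (fit$failed) NA_real_ else fit$loglik,
        n_params = if (fit$failed) NA_integer_ else fit$n_params,
        bic = bic,
        converged = if (fit$failed) NA else fit$converged
      )
      if (!fit$failed && (is.null(best) || bic > best$bic)) {
        best <- list(fit = fit, bic = bic, family = family, k = k)
      }
    }
  }
  if (is.null(best)) stop("no model could be fitted", call. = FALSE)
  structure(
    list(
      partition = best$fit$partition,
      k = best$fit$k_effective,
      family = best$family,
      bic = best$bic,
      loglik = best$fit$loglik,
      bic_table = dplyr::bind_rows(rows)
    ),
    class = "gmm_bic"
  )
}

# Returns a function k -> hard assignment from a single agglomerative run.
hierarchical_cutter <- function(data, init) {
  n <- nrow(data)
  if (n == 1L) return(function(k) 1L)
  if (init == "model") {
    # mclust's default pipeline: standardise, whiten via SVD, then
    # unconstrained-covariance model-based agglomeration
    z <- scale(data)
    z <- z[, apply(z, 2, function(col) all(is.finite(col))), drop = FALSE]
    sv <- svd(z, nu = 0)
    p <- min(dim(z))
    z <- z %*% sv$v %*% diag(1 / sqrt(sv$d), p, p)
    hcm <- mclust::hcVVV(z)
    function(k) as.integer(mclust::hclass(hcm, k))
  } else {
    hcw <- hclust(dist(data), method = "ward.D2")
    function(k) cutree(hcw, k = k)
  }
}

# One EM fit. `init` is a hard assignment used to form the initial
# responsibilities.
em_fit <- function(x, k, family, init, tol, max_iter) {
  n <- nrow(x)
  p <- ncol(x)
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), init)] <- 1
  x2 <- x^2
  varfloor <- 1e-10 * mean(apply(x, 2, var) + 1e-300)
  ll_prev <- -Inf
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    # ---- M-step
    wk <- colSums(resp)
    drop_empty <- wk < n * 1e-10
    if (any(drop_empty)) {
      if (all(drop_empty)) return(list(failed = TRUE))
      warning("pruning ", sum(drop_empty), " empty component(s)",
              call. = FALSE)
      resp <- resp[, !drop_empty, drop = FALSE]
      resp <- resp / rowSums(resp)
      wk <- colSums(resp)
      k <- ncol(resp)
      ll_prev <- -Inf
    }
    weights <- wk / n
    means <- crossprod(resp, x) / wk                     # k x p
    params <- list()
    degenerate <- logical(k)
    if (family %in% c("diagonal", "spherical")) {
      vars <- crossprod(resp, x2) / wk - means^2
      vars[vars < 0] <- 0
      if (family == "spherical") {
        vars <- matrix(rowMeans(vars), k, p)
      }
      degenerate <- apply(vars, 1, min) < varfloor
      params$vars <- vars
    } else {
      chols <- vector("list", k)
      for (g in seq_len(k)) {
        xc <- sweep(x, 2, means[g, ], "-")
        sig <- crossprod(xc * resp[, g], xc) / wk[g]
        ch <- tryCatch(chol(sig), error = function(e) NULL)
        if (is.null(ch) || min(diag(ch))^2 < varfloor) {
          degenerate[g] <- TRUE
        } else {
          chols[[g]] <- ch
        }
      }
      params$chols <- chols
    }
    if (any(degenerate)) {
      if (all(degenerate)) return(list(failed = TRUE))
      warning("pruning ", sum(degenerate),
              " degenerate component(s) (vanishing variance)", call. = FALSE)
      resp <- resp[, !degenerate, drop = FALSE]
      rs <- rowSums(resp)
      rs[rs == 0] <- 1
      resp <- resp / rs
      k <- ncol(resp)
      ll_prev <- -Inf
      next
    }

    # ---- E-step
    lp <- matrix(0, n, k)
    if (family %in% c("diagonal", "spherical")) {
      v <- params$vars
      b2 <- means / v
      ck <- rowSums(means * b2 / 2 + 0.5 * log(2 * pi * v))
      lp <- x %*% t(b2) - x2 %*% t(0.5 / v)
      lp <- sweep(lp, 2, ck, "-")
    } else {
      for (g in seq_len(k)) {
        ch <- params$chols[[g]]
        xc <- sweep(x, 2, means[g, ], "-")
        z <- backsolve(ch, t(xc), transpose = TRUE)
        lp[, g] <- -0.5 * colSums(z^2) - sum(log(diag(ch))) -
          0.5 * p * log(2 * pi)
      }
    }
    lp <- sweep(lp, 2, log(weights), "+")
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    if (is.finite(ll_prev) && ll < ll_prev - 1e-6 * max(1, abs(ll_prev))) {
      stop("internal error: EM log-likelihood decreased", call. = FALSE)
    }
    resp <- exp(lp - lse)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      ll_prev <- ll
      break
    }
    ll_prev <- ll
  }

  n_params <- switch(family,
    spherical = (k - 1) + k * p + k,
    diagonal  = (k - 1) + 2 * k * p,
    full      = (k - 1) + k * p + k * p * (p + 1) / 2
  )
  list(
    failed = FALSE,
    loglik = ll_prev,
    n_params = as.integer(n_params),
    k_effective = k,
    converged = converged,
    partition = canonical_labels(max.col(resp, ties.method = "first"))
  )
}

#' @export
print.gmm_bic <- function(x, ...) {
  cat(sprintf("<gmm_bic> selected k = %d (%s covariance), BIC = %.2f\n",
              x$k, x$family, x$bic))
  invisible(x)
}

#' @rdname em_gmm_bic
#' @param x A `gmm_bic`.
#' @param ... Unused.
#' @export
tidy.gmm_bic <- function(x, ...) x$bic_table

#' @rdname em_gmm_bic
#' @export
glance.gmm_bic <- function(x, ...) {
  tibble::tibble(k = x$k, family = x$family, bic = x$bic, loglik = x$loglik)
}
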