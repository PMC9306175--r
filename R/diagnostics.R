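#' @title Long-chain convergence diagnostics
#' @description Geweke Z-scores with Shapiro-Wilk screening, classic and
#'   rank-normalised split R-hat, and pooled posterior similarity matrices —
#'   the machinery used to assess (and salvage) conventional long-chain
#'   Bayesian inference for comparison with the consensus ensemble.
#' @name diagnostics
NULL

# Spectral density at frequency zero via a smoothed, tapered periodogram.
# R's spec.pgram scaling makes a white-noise spectrum flat at var(x), so the
# squared standard error of the segment mean is spectrum0(x) / length(x).
spectrum0 <- function(x, taper = 0.04) {
  n <- length(x)
  if (n < 8) return(var(x))
  span <- max(3L, 2L * floor(sqrt(n) / 2) + 1L)
  sp <- spec.pgram(x, taper = taper, spans = span, detrend = TRUE,
                   plot = FALSE)
  sp$spec[1]
}

#' Geweke Z-scores for a scalar MCMC trace
#'
#' Compares the mean of early segments of the trace to the mean of its final
#' portion, scaled by spectral-density-at-zero standard errors. The late
#' window is the last `last_frac` of the trace; `n_windows` early windows of
#' length `first_frac * length(trace)` slide across the remainder. Under
#' stationarity each Z-score is approximately standard normal.
#'
#' @param trace Numeric vector (e.g. a chain's per-iteration
#'   log-likelihood), or an `mcmc_chain` whose `loglik` is used.
#' @param first_frac Early-window length as a fraction of the trace
#'   (default 0.1).
#' @param last_frac Late-window fraction (default 0.5).
#' @param n_windows Number of sliding early windows (default 10).
#' @param burn_in Iterations discarded before computing anything.
#' @param taper Taper passed to the periodogram estimator.
#' @return Numeric vector of `n_windows` Z-scores.
#' @export
geweke_z <- function(trace, first_frac = 0.1, last_frac = 0.5,
                     n_windows = 10L, burn_in = 0L, taper = 0.04) {
  if (inherits(trace, "mcmc_chain")) trace <- trace$loglik
  stopifnot(is.numeric(trace))
  if (burn_in > 0) trace <- trace[-seq_len(burn_in)]
  n <- length(trace)
  if (first_frac <= 0 || last_frac <= 0 || first_frac + last_frac > 1) {
    stop("need first_frac > 0, last_frac > 0 and first_frac + last_frac <= 1",
         call. = FALSE)
  }
  if (var(trace) == 0) {
    stop("degenerate trace: zero variance", call. = FALSE)
  }
  late <- trace[(n - floor(last_frac * n) + 1):n]
  if (var(late) == 0) {
    stop("degenerate trace: zero variance in the late window", call. = FALSE)
  }
  se2_late <- spectrum0(late, taper) / length(late)
  len <- max(2L, floor(first_frac * n))
  last_start <- n - floor(last_frac * n) - len + 1L
  if (last_start < 1) stop("trace too short for the requested windows",
                           call. = FALSE)
  starts <- unique(round(seq(1, last_start, length.out = n_windows)))
  vapply(starts, function(s) {
    early <- trace[s:(s + len - 1L)]
    if (var(early) == 0) {
      stop("degenerate trace: zero variance in an early window", call. = FALSE)
    }
    se2_early <- spectrum0(early, taper) / len
    (mean(early) - mean(late)) / sqrt(se2_early + se2_late)
  }, numeric(1))
}

# Split each chain in half and compute the between/within variance ratio.
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    m <- floor(length(ch) / 2)
    if (m < 2) return(NA_real_)
    halves[[length(halves) + 1L]] <- ch[seq_len(m)]
    halves[[length(halves) + 1L]] <- ch[(length(ch) - m + 1L):length(ch)]
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  w <- mean(vars)
  b <- n * var(means)
  if (w == 0) return(NaN)
  sqrt((n - 1) / n + b / (n * w))
}

# Rank-normalise the pooled draws (fractional offset 3/8), then split R-hat.
rank_normalised_rhat <- function(chains) {
  pooled <- unlist(chains)
  s <- length(pooled)
  z <- qnorm((rank(pooled, ties.method = "average") - 3 / 8) / (s + 1 / 4))
  idx <- rep(seq_along(chains), lengths(chains))
  split_rhat(split(z, idx))
}

#' Screen chains by Geweke normality and compute R-hat
#'
#' Applies [geweke_z()] to every chain's scalar trace and tests the resulting
#' Z-score sequence for normality with a Shapiro-Wilk test; a chain whose
#' p-value falls below `alpha` is presumed non-stationary and dropped. Both
#' the classic and the rank-normalised split forms of R-hat are then computed
#' across the kept chains' traces (a single kept chain is split in half).
#'
#' @param traces List of numeric vectors or `mcmc_chain` objects.
#' @param alpha Screening level (default 0.05).
#' @param burn_in Iterations discarded from each trace.
#' @param ... Passed on to [geweke_z()].
#' @return An object of class `chain_screen`: per-chain tibble (`chain`,
#'   `shapiro_p`, `kept`), the Z-score sequences, and `rhat` /
#'   `rhat_rank_normalised` over the kept chains (`NA` if none kept).
#' @export
screen_chains <- function(traces, alpha = 0.05, burn_in = 0L, ...) {
  stopifnot(length(traces) >= 1)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  traces <- lapply(traces, function(tr) {
    if (inherits(tr, "mcmc_chain")) tr <- tr$loglik
    if (burn_in > 0) tr <- tr[-seq_len(burn_in)]
    tr
  })
  zs <- lapply(traces, geweke_z, ...)
  pvals <- vapply(zs, function(z) shapiro.test(z)$p.value, numeric(1))
  kept <- pvals >= alpha
  kept_traces <- traces[kept]
  rhat <- if (length(kept_traces) >= 1) split_rhat(kept_traces) else NA_real_
  rhat_rn <- if (length(kept_traces) >= 1) rank_normalised_rhat(kept_traces)
             else NA_real_
  structure(
    list(
      summary = tibble::tibble(
        chain = seq_along(traces),
        shapiro_p = pvals,
        kept = kept
      ),
      geweke = zs,
      alpha = alpha,
      rhat = rhat,
      rhat_rank_normalised = rhat_rn
    ),
    class = "chain_screen"
  )
}

#' @export
print.chain_screen <- function(x, ...) {
  cat(sprintf("<chain_screen> %d/%d chains kept (alpha = %g); rhat = %.4f, rank-normalised = %.4f\n",
              sum(x$summary$kept), nrow(x$summary), x$alpha,
              x$rhat, x$rhat_rank_normalised))
  invisible(x)
}

#' @rdname screen_chains
#' @param x A `chain_screen`.
#' @export
tidy.chain_screen <- function(x, ...) x$summary

#' @rdname screen_chains
#' @export
glance.chain_screen <- function(x, ...) {
  tibble::tibble(
    n_chains = nrow(x$summary),
    n_kept = sum(x$summary$kept),
    rhat = x$rhat,
    rhat_rank_normalised = x$rhat_rank_normalised
  )
}

#' Pooled posterior similarity matrix
#'
#' Co-clustering proportions across all post-burn-in recorded partitions of
#' the supplied chains pooled together — the long-chain analogue of the
#' consensus matrix. A chain stuck in a single mode yields a pure 0/1 matrix
#' on its own; disagreeing stuck chains show up as intermediate pooled
#' entries.
#'
#' @param chains List of `mcmc_chain` objects (or a single one).
#' @param burn_in Iterations discarded from the start of each chain.
#' @return A [consensus_matrix] whose `width_used` is the total number of
#'   pooled samples.
#' @export
pooled_psm <- function(chains, burn_in = 0L) {
  if (inherits(chains, "mcmc_chain")) chains <- list(chains)
  parts <- lapply(chains, function(ch) {
    stopifnot(inherits(ch, "mcmc_chain"))
    keep <- ch$recorded_iterations > burn_in
    ch$partitions[keep, , drop = FALSE]
  })
  total <- sum(vapply(parts, nrow, integer(1)))
  if (total == 0) stop("no recorded samples after burn-in", call. = FALSE)
  consensus_matrix(do.call(rbind, parts))
}
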