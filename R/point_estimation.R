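#' @title Point estimation from a similarity matrix
#' @description Derive a point clustering from a consensus or posterior
#'   similarity matrix by maximising the posterior expected adjusted Rand
#'   index (PEAR) over a candidate set, with an exhaustive oracle for small N.
#' @name point_estimation
NULL

validate_similarity <- function(sim) {
  if (inherits(sim, "consensus_matrix")) sim <- unclass(sim)
  if (!is.matrix(sim) || !is.numeric(sim) || nrow(sim) != ncol(sim)) {
    stop("similarity must be a square numeric matrix", call. = FALSE)
  }
  if (max(abs(sim - t(sim))) > 1e-12) {
    stop("similarity matrix must be symmetric (within 1e-12)", call. = FALSE)
  }
  if (any(abs(diag(sim) - 1) > 1e-12)) {
    stop("similarity matrix must have unit diagonal", call. = FALSE)
  }
  if (min(sim) < -1e-12 || max(sim) > 1 + 1e-12) {
    stop("similarity entries must lie in [0, 1]", call. = FALSE)
  }
  unname(sim)
}

# Relabel by first occurrence: canonical form 1, 2, ... in order of appearance.
canonical_labels <- function(p) {
  as.integer(match(p, unique(p)))
}

pear_from_sums <- function(s1, s2, s3, b, degenerate = c("error", "zero")) {
  degenerate <- match.arg(degenerate)
  expd <- s2 * s3 / b
  den <- 0.5 * (s2 + s3) - expd
  if (abs(den) < 1e-300) {
    if (degenerate == "error") {
      stop("degenerate input: PEAR denominator is zero", call. = FALSE)
    }
    return(0)
  }
  (s1 - expd) / den
}

#' Posterior expected adjusted Rand index
#'
#' PEAR of a candidate partition against a similarity matrix `s`: with
#' `I_ij = 1` when items i and j share a cluster, over the `B = N(N-1)/2`
#' unordered pairs,
#' `PEAR = (sum I s - sum I sum s / B) / ((sum I + sum s)/2 - sum I sum s / B)`.
#' When the similarity matrix holds exact posterior co-clustering
#' probabilities this is the posterior expectation of the adjusted Rand
#' index between the candidate and the true clustering; for a consensus
#' matrix it is used as the same score heuristically.
#'
#' @param partition Integer cluster labels.
#' @param sim Similarity matrix ([consensus_matrix] or plain symmetric
#'   matrix with unit diagonal).
#' @return A single number, 1 for perfect agreement. A zero denominator
#'   (e.g. an all-ones similarity scored against itself) is an error.
#' @export
pear <- function(partition, sim) {
  sim <- validate_similarity(sim)
  n <- nrow(sim)
  if (length(partition) != n) {
    stop("partition length must match similarity dimension", call. = FALSE)
  }
  ut <- upper.tri(sim)
  I <- outer(partition, partition, "==")[ut]
  s <- sim[ut]
  pear_from_sums(sum(s[I]), sum(I), sum(s), n * (n - 1) / 2,
                 degenerate = "error")
}

#' Maximise PEAR over a candidate set
#'
#' Candidates are generated by hierarchical clustering of the dissimilarity
#' `1 - s` under several linkages (average, complete, Ward and single by
#' default), each cut at every `k` in `1..max_clusters`; every cut is then
#' refined by greedy item-wise reassignment until no single move improves
#' PEAR. Running the greedy refinement from several structurally different
#' dendrograms is what keeps the search out of the local optima any single
#' linkage occasionally produces. Ties are broken towards fewer clusters,
#' then towards the lexicographically smaller canonical labelling.
#' Candidates with an undefined (0/0) PEAR score 0.
#'
#' @inheritParams pear
#' @param max_clusters Largest number of clusters among the hierarchical
#'   cuts; default `min(30, ceiling(N / 2))`, capped at N.
#' @param greedy Apply the local-move refinement? Default `TRUE`.
#' @param linkage Character vector of linkages for candidate generation.
#' @return A list with `partition` (canonical labels of the maximiser) and
#'   `pear` (its score).
#' @export
max_pear <- function(sim, max_clusters = NULL, greedy = TRUE,
                     linkage = c("average", "complete", "ward.D2", "single")) {
  sim <- validate_similarity(sim)
  n <- nrow(sim)
  if (n == 1L) return(list(partition = 1L, pear = 1))
  if (is.null(max_clusters)) max_clusters <- min(30L, ceiling(n / 2))
  max_clusters <- min(as.integer(max_clusters), n)
  if (max_clusters < 1) stop("`max_clusters` must be at least 1", call. = FALSE)

  d <- stats::as.dist(1 - sim)
  best <- NULL
  for (meth in linkage) {
    hc <- hclust(d, method = meth)
    for (k in seq_len(max_clusters)) {
      p <- canonical_labels(cutree(hc, k = k))
      if (greedy) p <- greedy_pear_moves(sim, p)
      v <- pear_partition(sim, p)
      best <- better_candidate(best, list(partition = p, pear = v))
    }
  }
  best
}

# Score a partition against a similarity matrix, 0/0 treated as 0.
pear_partition <- function(sim, partition) {
  n <- nrow(sim)
  ut <- upper.tri(sim)
  I <- outer(partition, partition, "==")[ut]
  s <- sim[ut]
  pear_from_sums(sum(s[I]), sum(I), sum(s), n * (n - 1) / 2,
                 degenerate = "zero")
}

better_candidate <- function(best, cand) {
  cand$partition <- canonical_labels(cand$partition)
  if (is.null(best)) return(cand)
  if (cand$pear > best$pear + 1e-12) return(cand)
  if (cand$pear < best$pear - 1e-12) return(best)
  ka <- max(cand$partition)
  kb <- max(best$partition)
  if (ka < kb) return(cand)
  if (ka > kb) return(best)
  cmp <- cand$partition - best$partition
  nz <- which(cmp != 0)
  if (length(nz) > 0 && cmp[nz[1]] < 0) return(cand)
  best
}

# Greedy single-item moves maximising PEAR, using O(1) score updates from the
# pair-sum decomposition (per-item cluster similarity sums maintained).
greedy_pear_moves <- function(sim, partition, max_passes = 20L) {
  n <- nrow(sim)
  s <- sim
  diag(s) <- 0
  part <- canonical_labels(partition)
  k <- max(part)
  memb <- matrix(0, n, k)
  memb[cbind(seq_len(n), part)] <- 1
  cs <- s %*% memb                      # cs[i, g] = sum of s[i, j] over j in g
  sizes <- colSums(memb)
  b <- n * (n - 1) / 2
  s3 <- sum(s) / 2
  s2 <- sum(sizes * (sizes - 1) / 2)
  s1 <- sum(cs[cbind(seq_len(n), part)]) / 2

  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      a <- part[i]
      s1r <- s1 - cs[i, a]
      s2r <- s2 - (sizes[a] - 1)
      cur <- pear_from_sums(s1, s2, s3, b, degenerate = "zero")
      # candidate targets: every other non-empty cluster, plus a new
      # singleton when i is not already one
      targets <- which(sizes > 0)
      targets <- targets[targets != a]
      vals <- vapply(targets, function(g) {
        pear_from_sums(s1r + cs[i, g], s2r + sizes[g], s3, b,
                       degenerate = "zero")
      }, numeric(1))
      if (sizes[a] > 1) {
        targets <- c(targets, 0L)       # 0 marks "new singleton cluster"
        vals <- c(vals, pear_from_sums(s1r, s2r, s3, b, degenerate = "zero"))
      }
      if (length(vals) == 0) next
      jbest <- which.max(vals)
      if (vals[jbest] > cur + 1e-12) {
        g <- targets[jbest]
        if (g == 0L) {
          k <- k + 1L
          cs <- cbind(cs, 0)
          sizes <- c(sizes, 0)
          g <- k
        }
        s1 <- if (g <= ncol(cs)) s1r + cs[i, g] else s1r
        s2 <- s2r + sizes[g]
        cs[, a] <- cs[, a] - s[, i]
        cs[, g] <- cs[, g] + s[, i]
        sizes[a] <- sizes[a] - 1
        sizes[g] <- sizes[g] + 1
        part[i] <- g
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  canonical_labels(part)
}

# All set partitions of n items as restricted-growth label vectors.
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(labels, maxl) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) rec(c(labels, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  out
}

#' Exhaustive PEAR maximisation (test oracle)
#'
#' Enumerates every set partition of the items (Bell-number enumeration,
#' refused above `N = 10`) and returns the global PEAR maximiser under the
#' same scoring and tie-break rules as [max_pear()].
#'
#' @inheritParams pear
#' @return A list with `partition` and `pear`.
#' @export
exhaustive_max_pear <- function(sim) {
  sim <- validate_similarity(sim)
  n <- nrow(sim)
  if (n > 10L) {
    stop("exhaustive search refused for N > 10 (Bell-number enumeration)",
         call. = FALSE)
  }
  if (n == 1L) return(list(partition = 1L, pear = 1))
  best <- NULL
  for (p in all_set_partitions(n)) {
    best <- better_candidate(best, list(partition = p,
                                        pear = pear_partition(sim, p)))
  }
  best
}
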