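#' Run an ensemble of short chains
#'
#' The core consensus procedure: `width` independent chains are initialised
#' from prior draws on partitions and each run for `depth` Gibbs sweeps; the
#' partition at sweep `depth` (and at any intermediate `checkpoints`) is
#' collected from every chain. Chains depend only on their own seed, so the
#' result is identical whether the chains are run serially or in parallel.
#'
#' @param data Data matrix, data frame or [simulate_mixture()] output.
#' @param width Ensemble width `W` (number of chains).
#' @param depth Chain depth `D` (sweeps per chain).
#' @param seeds Integer vector of `width` distinct chain seeds; a single
#'   value `s` is expanded to `s, s + 1, ..., s + width - 1`.
#' @param model `"gaussian"` or `"bernoulli"`.
#' @param hyper A [mixture_hyperparameters].
#' @param checkpoints Optional ascending sweep indices at which partitions
#'   are additionally retained (must end at `depth`).
#' @param verbose Emit a progress line per 10% of chains completed.
#' @return A list with `final` (`width` x N integer matrix of final
#'   partitions, one row per chain) and, when `checkpoints` is set,
#'   `checkpoint_partitions` (a named list mapping each checkpoint depth to a
#'   `width` x N matrix).
#' @seealso [consensus_clustering()] for the one-call wrapper that also
#'   builds the consensus matrix.
#' @export
run_ensemble <- function(data, width, depth, seeds = 1L,
                         model = c("gaussian", "bernoulli"),
                         hyper = mixture_hyperparameters(),
                         checkpoints = NULL, verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(is_count(width), width >= 1, is_count(depth), depth >= 1)
  data <- as_data_matrix(data, model)
  hyper <- resolve_hyperparameters(hyper, data)
  if (length(seeds) == 1L) seeds <- seeds + seq_len(width) - 1L
  if (length(seeds) != width) {
    stop("`seeds` must supply one seed per chain", call. = FALSE)
  }
  if (anyDuplicated(seeds)) stop("`seeds` must be distinct", call. = FALSE)
  if (is.null(checkpoints)) {
    cps <- depth
  } else {
    cps <- as.integer(checkpoints)
    if (is.unsorted(cps, strictly = TRUE) || any(cps < 1) ||
        cps[length(cps)] != depth) {
      stop("`checkpoints` must be strictly ascending and end at `depth`",
           call. = FALSE)
    }
  }

  n <- nrow(data)
  snaps <- lapply(cps, function(d) matrix(NA_integer_, width, n))
  progress_at <- unique(ceiling(width * seq(0.1, 1, by = 0.1)))
  for (j in seq_len(width)) {
    set.seed(as.integer(seeds[j]))
    state <- draw_prior_state(data, hyper, model)
    res <- tryCatch(
      run_sweeps(state, data, hyper, nsweeps = depth, checkpoints = cps),
      error = function(e) {
        stop(sprintf("chain %d (seed %d) failed: %s", j, seeds[j],
                     conditionMessage(e)), call. = FALSE)
      }
    )
    for (i in seq_along(cps)) snaps[[i]][j, ] <- res$partitions[i, ]
    if (verbose && j %in% progress_at) {
      message(sprintf("ccbayes: %d/%d chains done", j, width))
    }
  }
  names(snaps) <- as.character(cps)
  out <- list(final = snaps[[length(snaps)]], seeds = as.integer(seeds),
              depth = as.integer(depth), width = as.integer(width),
              model = model)
  if (!is.null(checkpoints)) out$checkpoint_partitions <- snaps
  out
}

#' Build a consensus matrix from partitions
#'
#' Entry (i, j) is the proportion of partitions in which items i and j share
#' a cluster; the diagonal is exactly 1 and every entry is an integer
#' multiple of `1 / W`.
#'
#' @param partitions A list of equal-length integer partitions, or a matrix
#'   with one partition per row.
#' @return An object of class `consensus_matrix`: the numeric N x N matrix
#'   with attributes `width_used` and `depth_used` (the latter `NA` when
#'   unknown).
#' @export
consensus_matrix <- function(partitions) {
  if (is.list(partitions)) {
    lens <- lengths(partitions)
    if (length(partitions) == 0L) stop("no partitions supplied", call. = FALSE)
    if (length(unique(lens)) != 1L) {
      stop("all partitions must have the same length", call. = FALSE)
    }
    partitions <- do.call(rbind, partitions)
  }
  if (!is.matrix(partitions)) partitions <- matrix(partitions, nrow = 1)
  w <- nrow(partitions)
  n <- ncol(partitions)
  counts <- matrix(0, n, n)
  for (j in seq_len(w)) {
    p <- partitions[j, ]
    counts <- counts + outer(p, p, "==")
  }
  cm <- counts / w
  diag(cm) <- 1
  new_consensus_matrix(unname(cm), width_used = w, depth_used = NA_integer_,
                       item_names = colnames(partitions))
}

new_consensus_matrix <- function(values, width_used, depth_used = NA_integer_,
                                 item_names = NULL) {
  if (!is.null(item_names)) dimnames(values) <- list(item_names, item_names)
  structure(values, width_used = as.integer(width_used),
            depth_used = as.integer(depth_used),
            class = c("consensus_matrix", "matrix", "array"))
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("<consensus_matrix> %d items, built from %d partitions%s\n",
              nrow(x), attr(x, "width_used"),
              if (is.na(attr(x, "depth_used"))) ""
              else sprintf(" at depth %d", attr(x, "depth_used"))))
  invisible(x)
}

#' Consensus clustering in one call
#'
#' Runs the ensemble, builds the consensus matrix and (optionally) derives
#' the point clustering by PEAR maximisation.
#'
#' @inheritParams run_ensemble
#' @param point_estimate Also run [max_pear()] on the consensus matrix?
#' @param max_clusters Passed to [max_pear()].
#' @return An object of class `consensus_clustering` with elements
#'   `consensus` (a `consensus_matrix`), `partitions` (the chain finals),
#'   `point_estimate` (integer partition or `NULL`), `pear` (its PEAR value)
#'   and the run configuration.
#' @export
consensus_clustering <- function(data, width = 100, depth = 1000, seeds = 1L,
                                 model = c("gaussian", "bernoulli"),
                                 hyper = mixture_hyperparameters(),
                                 point_estimate = TRUE, max_clusters = NULL,
                                 verbose = FALSE) {
  model <- match.arg(model)
  ens <- run_ensemble(data, width, depth, seeds, model, hyper,
                      verbose = verbose)
  cm <- consensus_matrix(ens$final)
  attr(cm, "depth_used") <- ens$depth
  pe <- NULL
  pv <- NA_real_
  if (point_estimate) {
    mp <- max_pear(cm, max_clusters = max_clusters)
    pe <- mp$partition
    pv <- mp$pear
  }
  structure(
    list(consensus = cm, partitions = ens$final, point_estimate = pe,
         pear = pv, width = ens$width, depth = ens$depth, seeds = ens$seeds,
         model = model, hyper = resolve_hyperparameters(hyper, as_data_matrix(data, model))),
    class = "consensus_clustering"
  )
}

#' @export
print.consensus_clustering <- function(x, ...) {
  cat(sprintf("<consensus_clustering> W = %d chains, D = %d sweeps, %d items\n",
              x$width, x$depth, ncol(x$partitions)))
  if (!is.null(x$point_estimate)) {
    cat(sprintf("  point estimate: %d clusters (PEAR %.3f)\n",
                length(unique(x$point_estimate)), x$pear))
  }
  invisible(x)
}

#' @rdname consensus_clustering
#' @param x A `consensus_clustering`.
#' @param ... Unused.
#' @return `tidy()` returns one row per unordered item pair with the
#'   co-clustering proportion; `glance()` a one-row run summary.
#' @export
tidy.consensus_clustering <- function(x, ...) {
  cm <- x$consensus
  n <- nrow(cm)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  items <- rownames(cm) %||% as.character(seq_len(n))
  tibble::tibble(
    item_a = items[idx[, 1]],
    item_b = items[idx[, 2]],
    proportion = cm[idx]
  )
}

#' @rdname consensus_clustering
#' @export
glance.consensus_clustering <- function(x, ...) {
  tibble::tibble(
    n_items = ncol(x$partitions),
    width = x$width,
    depth = x$depth,
    n_clusters = if (is.null(x$point_estimate)) NA_integer_
                 else length(unique(x$point_estimate)),
    pear = x$pear
  )
}

#' Consensus matrices over a depth x width grid
#'
#' Runs `max(width_grid)` chains once to `max(depth_grid)`, snapshotting the
#' partition at every depth in `depth_grid`, and assembles the consensus
#' matrix `CM(d, w)` for every grid cell from the first `w` chains'
#' snapshots at depth `d` (nested chain prefixes; nothing is recomputed).
#'
#' @inheritParams run_ensemble
#' @param depth_grid,width_grid Strictly ascending positive integers.
#' @return An object of class `consensus_grid`: a list-matrix of
#'   `consensus_matrix` objects indexed `[[depth, width]]` plus the grids.
#' @seealso [stability_curves()]
#' @export
consensus_grid <- function(data, depth_grid, width_grid, seeds = 1L,
                           model = c("gaussian", "bernoulli"),
                           hyper = mixture_hyperparameters(), verbose = FALSE) {
  model <- match.arg(model)
  depth_grid <- as.integer(depth_grid)
  width_grid <- as.integer(width_grid)
  if (is.unsorted(depth_grid, strictly = TRUE) ||
      is.unsorted(width_grid, strictly = TRUE)) {
    stop("grids must be strictly ascending", call. = FALSE)
  }
  wmax <- max(width_grid)
  ens <- run_ensemble(data, width = wmax, depth = max(depth_grid),
                      seeds = seeds, model = model, hyper = hyper,
                      checkpoints = depth_grid, verbose = verbose)
  cms <- vector("list", length(depth_grid) * length(width_grid))
  dim(cms) <- c(length(depth_grid), length(width_grid))
  for (i in seq_along(depth_grid)) {
    snap <- ens$checkpoint_partitions[[as.character(depth_grid[i])]]
    for (j in seq_along(width_grid)) {
      cm <- consensus_matrix(snap[seq_len(width_grid[j]), , drop = FALSE])
      attr(cm, "depth_used") <- depth_grid[i]
      cms[[i, j]] <- cm
    }
  }
  structure(
    list(cms = cms, depth_grid = depth_grid, width_grid = width_grid,
         seeds = ens$seeds, model = model),
    class = "consensus_grid"
  )
}

#' @export
print.consensus_grid <- function(x, ...) {
  cat(sprintf("<consensus_grid> depths {%s} x widths {%s}\n",
              paste(x$depth_grid, collapse = ", "),
              paste(x$width_grid, collapse = ", ")))
  invisible(x)
}

# Mean absolute difference over the strictly upper triangle (the diagonal is
# identically 1 and would dilute the signal).
mean_abs_diff <- function(a, b) {
  ut <- upper.tri(a)
  mean(abs(a[ut] - b[ut]))
}

#' Ensemble stability curves
#'
#' The scree-plot-style stopping heuristic for sizing the ensemble: for each
#' width, the mean absolute difference between consensus matrices at
#' consecutive depths, and for each depth, the analogue across consecutive
#' widths. Differences are averaged over the N(N-1)/2 strictly
#' upper-triangular entries. As depth and width grow these sequential
#' changes shrink; an elbow suggests the ensemble is stable. The `stable`
#' flag (difference below `epsilon`) is advisory only.
#'
#' @param grid A [consensus_grid()].
#' @param epsilon Advisory stability threshold (default 0.01).
#' @return A tibble with columns `curve` (`"depth"` or `"width"`), `depth`,
#'   `width`, `from_depth`/`from_width` (the previous grid point), `mad`
#'   (the mean absolute difference) and `stable`.
#' @export
stability_curves <- function(grid, epsilon = 0.01) {
  stopifnot(inherits(grid, "consensus_grid"))
  nd <- length(grid$depth_grid)
  nw <- length(grid$width_grid)
  if (nd < 2 && nw < 2) {
    stop("grid must have at least two depths or two widths", call. = FALSE)
  }
  rows <- list()
  if (nd >= 2) {
    for (j in seq_len(nw)) {
      for (i in 2:nd) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          curve = "depth",
          depth = grid$depth_grid[i],
          width = grid$width_grid[j],
          from_depth = grid$depth_grid[i - 1],
          from_width = grid$width_grid[j],
          mad = mean_abs_diff(grid$cms[[i, j]], grid$cms[[i - 1, j]])
        )
      }
    }
  }
  if (nw >= 2) {
    for (i in seq_len(nd)) {
      for (j in 2:nw) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          curve = "width",
          depth = grid$depth_grid[i],
          width = grid$width_grid[j],
          from_depth = grid$depth_grid[i],
          from_width = grid$width_grid[j - 1],
          mad = mean_abs_diff(grid$cms[[i, j]], grid$cms[[i, j - 1]])
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$stable <- out$mad < epsilon
  out
}

#' @rdname stability_curves
#' @param x A `consensus_grid`.
#' @param ... Unused.
#' @export
tidy.consensus_grid <- function(x, ...) stability_curves(x)
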