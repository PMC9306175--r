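#' @title Delimited-text readers and writers
#' @description All tabular artifacts use one dialect: comma-separated values
#'   with a header row and a leading column of item identifiers. Matrices at
#'   the sizes handled here (hundreds of items) need no sparse formats.
#' @name io
NULL

#' Read an item-by-feature matrix from delimited text
#'
#' Expects a header row of feature names and a first column of item
#' identifiers. Parse failures report the offending line (and column where
#' applicable).
#'
#' @param path File path.
#' @param flavor `"continuous"` or `"binary"`; the binary flavor rejects
#'   entries outside `{0, 1}`.
#' @return Numeric matrix with row and column names.
#' @export
read_data_matrix <- function(path, flavor = c("continuous", "binary")) {
  flavor <- match.arg(flavor)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    stop("parse error: '", path, "' has no data rows", call. = FALSE)
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  ncols <- length(fields[[1]])
  feature_names <- trimws(fields[[1]][-1])
  n <- length(lines) - 1L
  x <- matrix(NA_real_, n, ncols - 1L)
  ids <- character(n)
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    if (length(row) != ncols) {
      stop(sprintf("parse error: line %d has %d fields, expected %d",
                   i + 1L, length(row), ncols), call. = FALSE)
    }
    ids[i] <- trimws(row[1])
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      stop(sprintf("parse error: non-numeric cell at line %d, column %d ('%s')",
                   i + 1L, j + 1L, row[j + 1L]), call. = FALSE)
    }
    x[i, ] <- vals
  }
  if (flavor == "binary" && !all(x %in% c(0, 1))) {
    bad <- which(!(x %in% c(0, 1)))[1]
    stop("binary matrix contains a value outside {0, 1} at data row ",
         (bad - 1L) %% n + 1L, call. = FALSE)
  }
  dimnames(x) <- list(ids, feature_names)
  x
}

#' Write an item-by-feature matrix as delimited text
#'
#' @param x Numeric matrix (or [simulate_mixture()] output, in which case a
#'   companion `<path base>_labels.csv` file of generating labels is written
#'   too).
#' @param path Output file path.
#' @param digits Significant digits (default 12).
#' @return `path`, invisibly.
#' @export
write_data_matrix <- function(x, path, digits = 12) {
  labels <- NULL
  if (inherits(x, "labelled_dataset")) {
    labels <- x$labels
    x <- x$data
  }
  ids <- rownames(x) %||% sprintf("item_%03d", seq_len(nrow(x)))
  feats <- colnames(x) %||% sprintf("feature_%03d", seq_len(ncol(x)))
  header <- paste(c("item_id", feats), collapse = ",")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(ids[i], formatC(x[i, ], digits = digits, format = "g")),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  if (!is.null(labels)) {
    lab_path <- sub("(\\.[^.]+)?$", "_labels.csv", path)
    # avoid doubling when path has no extension
    lab_path <- if (identical(lab_path, path)) paste0(path, "_labels.csv")
                else lab_path
    write_partition(labels, lab_path, items = ids)
  }
  invisible(path)
}

#' Read and write partitions as two-column delimited text
#'
#' @param partition Integer cluster labels.
#' @param path File path.
#' @param items Item identifiers (defaults to `item_001`, ...).
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   returns a named integer vector.
#' @export
write_partition <- function(partition, path, items = NULL) {
  if (is.null(items)) items <- sprintf("item_%03d", seq_along(partition))
  writeLines(c("item_id,label",
               paste(items, partition, sep = ",")), path)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item_id", "label") %in% names(df))) {
    stop("partition file must have columns item_id,label", call. = FALSE)
  }
  stats::setNames(as.integer(df$label), df$item_id)
}

#' A serialisable run configuration
#'
#' Bundles everything needed to reproduce a consensus run; round-trips
#' losslessly through JSON via [write_run_config()] / [read_run_config()].
#'
#' @param model `"gaussian"` or `"bernoulli"`.
#' @param width,depth Ensemble width and chain depth.
#' @param seeds Chain seeds (a single base seed is kept as such).
#' @param hyper A [mixture_hyperparameters].
#' @param scenario Optional [mixture_scenario] name or object.
#' @param prefix Output prefix.
#' @param verbose Verbosity flag.
#' @return An object of class `run_config`.
#' @export
run_config <- function(model = "gaussian", width = 100L, depth = 1000L,
                       seeds = 1L, hyper = mixture_hyperparameters(),
                       scenario = NULL, prefix = "ccbayes", verbose = FALSE) {
  stopifnot(model %in% c("gaussian", "bernoulli"))
  structure(
    list(
      model = model,
      width = as.integer(width),
      depth = as.integer(depth),
      seeds = as.integer(seeds),
      hyper = unclass(hyper),
      scenario = if (inherits(scenario, "mixture_scenario")) unclass(scenario)
                 else scenario,
      prefix = prefix,
      verbose = isTRUE(verbose)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  hy <- raw$hyper
  hyper <- mixture_hyperparameters(
    k_max = hy$k_max, dirichlet_alpha = hy$dirichlet_alpha,
    prior_mean = hy$prior_mean, prior_shrinkage = hy$prior_shrinkage,
    prior_shape = hy$prior_shape, prior_rate = hy$prior_rate,
    beta_a = hy$beta_a, beta_b = hy$beta_b
  )
  scenario <- raw$scenario
  if (is.list(scenario)) {
    scenario <- mixture_scenario(
      n_items = scenario$n_items, n_relevant = scenario$n_relevant,
      n_irrelevant = scenario$n_irrelevant, n_clusters = scenario$n_clusters,
      delta_mu = scenario$delta_mu, variance = scenario$variance,
      weights = scenario$weights, name = scenario$name,
      arrangement = scenario$arrangement %||% "permuted"
    )
  }
  run_config(model = raw$model, width = raw$width, depth = raw$depth,
             seeds = raw$seeds, hyper = hyper, scenario = scenario,
             prefix = raw$prefix, verbose = raw$verbose)
}

#' Write the artifacts of a consensus run
#'
#' Emits `<prefix>_cm.csv` (the consensus matrix), `<prefix>_partitions.csv`
#' (one row per chain), `<prefix>_pointest.csv` (when a point estimate is
#' present), optionally `<prefix>_stability.csv`, and always
#' `<prefix>_meta.json` with seeds, configuration and package version.
#'
#' @param result A [consensus_clustering()] object.
#' @param prefix Output path prefix.
#' @param stability Optional [stability_curves()] tibble.
#' @return Named character vector of the files written, invisibly.
#' @export
write_consensus_results <- function(result, prefix, stability = NULL) {
  stopifnot(inherits(result, "consensus_clustering"))
  cm <- result$consensus
  items <- rownames(cm) %||% sprintf("item_%03d", seq_len(nrow(cm)))
  files <- c(cm = paste0(prefix, "_cm.csv"))
  writeLines(
    c(paste(c("item_id", items), collapse = ","),
      vapply(seq_len(nrow(cm)), function(i) {
        paste(c(items[i], formatC(cm[i, ], digits = 12, format = "g")),
              collapse = ",")
      }, character(1))),
    files["cm"]
  )
  files["partitions"] <- paste0(prefix, "_partitions.csv")
  writeLines(
    c(paste(c("chain", items), collapse = ","),
      vapply(seq_len(nrow(result$partitions)), function(j) {
        paste(c(j, result$partitions[j, ]), collapse = ",")
      }, character(1))),
    files["partitions"]
  )
  if (!is.null(result$point_estimate)) {
    files["pointest"] <- paste0(prefix, "_pointest.csv")
    write_partition(result$point_estimate, files["pointest"], items = items)
  }
  if (!is.null(stability)) {
    files["stability"] <- paste0(prefix, "_stability.csv")
    utils::write.csv(stability, files["stability"], row.names = FALSE)
  }
  files["meta"] <- paste0(prefix, "_meta.json")
  cfg <- run_config(model = result$model, width = result$width,
                    depth = result$depth, seeds = result$seeds,
                    prefix = prefix)
  cfg$hyper <- unclass(result$hyper)
  meta <- c(unclass(cfg), list(package_version = as.character(packageVersion("ccbayes"))))
  jsonlite::write_json(meta, files["meta"], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(files)
}

#' Write an MCMC chain trace as delimited text with a JSON sidecar
#'
#' Emits `<prefix>_trace.csv` with one row per recorded sweep (`iteration`,
#' `loglik`, then one column per item holding the sampled cluster label) and
#' `<prefix>_meta.json` with the seed, depth, model and hyperparameters.
#'
#' @param chain An `mcmc_chain` from [run_chain()].
#' @param prefix Output path prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_chain_trace <- function(chain, prefix) {
  stopifnot(inherits(chain, "mcmc_chain"))
  items <- colnames(chain$partitions) %||%
    sprintf("item_%03d", seq_len(ncol(chain$partitions)))
  files <- c(trace = paste0(prefix, "_trace.csv"),
             meta = paste0(prefix, "_meta.json"))
  rows <- vapply(seq_along(chain$recorded_iterations), function(r) {
    it <- chain$recorded_iterations[r]
    paste(c(it, formatC(chain$loglik[it], digits = 12, format = "g"),
            chain$partitions[r, ]), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("iteration", "loglik", items), collapse = ","), rows),
             files["trace"])
  meta <- list(seed = chain$seed, depth = chain$depth, model = chain$model,
               hyper = unclass(chain$hyper),
               package_version = as.character(packageVersion("ccbayes")))
  jsonlite::write_json(meta, files["meta"], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(files)
}

#' Read a consensus or similarity matrix from delimited text
#'
#' @param path File written by [write_consensus_results()] (the `_cm.csv`
#'   artifact) or any square matrix in the same dialect.
#' @return A [consensus_matrix].
#' @export
read_consensus_matrix <- function(path) {
  x <- read_data_matrix(path)
  if (nrow(x) != ncol(x)) stop("consensus matrix file must be square",
                               call. = FALSE)
  new_consensus_matrix(unname(x), width_used = NA_integer_,
                       item_names = rownames(x))
}
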