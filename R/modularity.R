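#' Bipartite (Barber) modularity of a module assignment
#'
#' Evaluates the bipartite version of the Newman-Girvan modularity,
#' `M = (1/F) * sum_ij [ a_ij - k_i d_j / F ] * 1[module(i) == module(j)]`,
#' summing over all insect-host pairs, where `k_i` and `d_j` are the insect
#' and host degrees and `F` the total interaction count.  `M` is 0 for the
#' all-in-one-module partition and approaches 1 for many well-separated
#' modules.
#'
#' @param net a [bipartite_network()] with at least one interaction.
#' @param assignment named integer vector mapping every insect and host
#'   label of `net` to a module id, or a `module_partition` whose
#'   assignment is used.
#' @return The modularity value `M` (numeric scalar).
#' @examples
#' blocks <- bipartite_network(rbind(c(1,1,0,0), c(1,1,0,0),
#'                                   c(0,0,1,1), c(0,0,1,1)))
#' g <- c(1,1,2,2, 1,1,2,2)
#' names(g) <- c(blocks$insect_labels, blocks$host_labels)
#' bipartite_modularity(blocks, g)  # 0.5
#' @export
bipartite_modularity <- function(net, assignment) {
  stopifnot(inherits(net, "bipartite_network"))
  if (inherits(assignment, "module_partition"))
    assignment <- assignment$assignment
  labs <- c(net$insect_labels, net$host_labels)
  if (is.null(names(assignment)) || !all(labs %in% names(assignment)))
    stop("assignment must cover every insect and host label")
  a <- net$adjacency
  F <- sum(a)
  if (F == 0)
    stop("modularity is undefined for a network without interactions")
  gi <- assignment[net$insect_labels]
  gh <- assignment[net$host_labels]
  k <- rowSums(a); d <- colSums(a)
  same <- outer(gi, gh, "==")
  sum((a - outer(k, d) / F)[same]) / F
}

#' Simulated-annealing settings for the modularity optimiser
#'
#' @param initial_temperature starting temperature; `NULL` (default)
#'   calibrates it from a pre-pass so that about half of the early
#'   modularity-decreasing moves are accepted.
#' @param cooling_factor multiplicative cooling per temperature level, in
#'   (0,1); default 0.95.
#' @param steps_per_temperature proposed moves per temperature level;
#'   `NULL` (default) uses `steps_factor * n_nodes`.
#' @param steps_factor multiplier used when `steps_per_temperature` is
#'   `NULL`; default 10.
#' @param stall_limit stop after this many consecutive temperature levels
#'   without improvement of the best modularity; default 50.
#' @param n_runs independent annealing chains; the best final partition is
#'   returned (default 10, the standard protocol).
#' @param seed integer seed; chain `r` uses `seed + r - 1`.  `NULL` draws a
#'   seed from the current RNG stream.
#' @return A list of class `anneal_settings`.
#' @export
anneal_settings <- function(initial_temperature = NULL, cooling_factor = 0.95,
                            steps_per_temperature = NULL, steps_factor = 10,
                            stall_limit = 50, n_runs = 10, seed = NULL) {
  stopifnot(cooling_factor > 0, cooling_factor < 1, steps_factor > 0,
            stall_limit >= 1, n_runs >= 1)
  structure(list(initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 steps_per_temperature = steps_per_temperature,
                 steps_factor = steps_factor,
                 stall_limit = stall_limit,
                 n_runs = n_runs, seed = seed),
            class = "anneal_settings")
}

# canonical form: relabel modules by first appearance along the node order
canonical_assignment <- function(g) {
  u <- unique(g)
  match(g, u) - 1L
}

#' Find the maximum-modularity partition by simulated annealing
#'
#' Runs `n_runs` independent annealing chains (moves: single-node
#' reassignment, module merge, module split; Metropolis acceptance) and
#' returns the best partition found.  Chains that tie on `M` are resolved
#' deterministically in favour of the lexicographically smallest canonical
#' relabelling.  Nodes without any interaction are placed in singleton
#' modules (they cannot affect `M`).  The number of modules is an outcome
#' of the optimisation, never an input.
#'
#' @param net a [bipartite_network()] with at least one interaction.
#' @param settings an [anneal_settings()].
#' @return An object of class `module_partition`: list with `assignment`
#'   (named integer vector, module ids `0..n_modules-1` numbered by
#'   decreasing module size), `modularity` (recomputed with
#'   [bipartite_modularity()] from the returned assignment), `n_modules`,
#'   `inter_module_fraction` (share of interactions joining different
#'   modules), `module_sizes`, and `per_run_M` (final `M` of every chain,
#'   exposed because run-to-run variation is informative for networks with
#'   many between-module interactions).
#' @examples
#' net <- bipartite_network(rbind(c(1,1,0,0), c(1,1,0,0),
#'                                c(0,0,1,1), c(0,0,1,1)))
#' p <- optimize_partition(net, anneal_settings(seed = 1))
#' p$modularity  # 0.5
#' @export
optimize_partition <- function(net, settings = anneal_settings()) {
  stopifnot(inherits(net, "bipartite_network"),
            inherits(settings, "anneal_settings"))
  a <- net$adjacency
  if (sum(a) == 0)
    stop("modularity is undefined for a network without interactions")
  N <- nrow(a) + ncol(a)
  steps <- settings$steps_per_temperature
  if (is.null(steps)) steps <- as.integer(ceiling(settings$steps_factor * N))
  t0 <- if (is.null(settings$initial_temperature)) -1 else
    settings$initial_temperature
  seed <- settings$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 64L, 1)
  init <- seq_len(N) - 1L            # start from singletons
  best <- NULL
  per_run <- numeric(settings$n_runs)
  for (r in seq_len(settings$n_runs)) {
    res <- .anneal_chain(a, init, t0, settings$cooling_factor,
                         steps, settings$stall_limit,
                         (seed + r - 1L) %% .Machine$integer.max)
    res$assignment <- canonical_assignment(res$assignment)
    per_run[r] <- res$M
    if (is.null(best) || res$M > best$M + 1e-12 ||
        (abs(res$M - best$M) <= 1e-12 &&
         lex_smaller(res$assignment, best$assignment)))
      best <- res
  }
  partition_from_vector(net, best$assignment, per_run_M = per_run,
                        settings = settings)
}

lex_smaller <- function(x, y) {
  d <- x - y
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

# build a module_partition from a 0/1-based id vector in node order
# (insects then hosts); renumbers modules by decreasing size
partition_from_vector <- function(net, g, per_run_M = numeric(0),
                                  settings = NULL) {
  labs <- c(net$insect_labels, net$host_labels)
  stopifnot(length(g) == length(labs))
  sizes <- table(g)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  g <- relab[as.character(g)]
  assignment <- stats::setNames(as.integer(g), labs)
  m <- bipartite_modularity(net, assignment)
  structure(list(assignment = assignment,
                 modularity = m,
                 n_modules = length(unique(assignment)),
                 inter_module_fraction = inter_module_fraction(net, assignment),
                 module_sizes = as.integer(table(assignment)),
                 per_run_M = per_run_M,
                 settings = settings),
            class = "module_partition")
}

#' Coerce a labelled module assignment to a `module_partition`
#'
#' @param net the [bipartite_network()] the assignment refers to.
#' @param assignment named vector mapping every node label to a module id.
#' @return A `module_partition` (module ids renumbered by decreasing size).
#' @export
as_module_partition <- function(net, assignment) {
  labs <- c(net$insect_labels, net$host_labels)
  if (is.null(names(assignment)) || !all(labs %in% names(assignment)))
    stop("assignment must cover every insect and host label")
  ids <- match(assignment[labs], unique(assignment[labs])) - 1L
  partition_from_vector(net, ids)
}

#' Fraction of interactions that join different modules
#'
#' @param net a [bipartite_network()].
#' @param assignment named module-id vector or `module_partition`.
#' @return Fraction in `[0,1]`; its complement is the within-module share.
#' @export
inter_module_fraction <- function(net, assignment) {
  if (inherits(assignment, "module_partition"))
    assignment <- assignment$assignment
  a <- net$adjacency
  gi <- assignment[net$insect_labels]
  gh <- assignment[net$host_labels]
  cross <- outer(gi, gh, "!=")
  sum(a[cross]) / sum(a)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules, M = %.4f, %.1f%% of interactions between modules\n",
              x$n_modules, x$modularity, 100 * x$inter_module_fraction))
  cat("module sizes:", paste(x$module_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.module_partition <- function(object, ...) {
  g <- object$assignment
  df <- data.frame(node = names(g), module = as.integer(g),
                   row.names = NULL, stringsAsFactors = FALSE)
  cat(sprintf("%d modules, M = %.4f", object$n_modules, object$modularity))
  if (length(object$per_run_M) > 1)
    cat(sprintf(" (per-run M: %s)",
                paste(sprintf("%.4f", object$per_run_M), collapse = ", ")))
  cat("\n")
  invisible(df)
}

#' Export a module partition as two-column text
#'
#' Writes one `node<TAB>module` line per network node; module ids are
#' `0..n_modules-1` in decreasing module-size order.
#'
#' @param partition a `module_partition`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  g <- partition$assignment
  utils::write.table(data.frame(node = names(g), module = as.integer(g)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
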