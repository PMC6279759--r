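#' Nestedness by overlap and decreasing fill (NODF)
#'
#' Computes the NODF nestedness metric of a binary bipartite network.  For
#' every unordered pair of rows the pair scores
#' `100 * overlap / fill_smaller` when the two fills strictly decrease and
#' the smaller fill is positive, and 0 otherwise (equal fills and empty
#' partners score 0); likewise for columns.  The network NODF is the mean
#' over all row pairs and column pairs, so it lies in `[0, 100]` and is
#' invariant under any row/column permutation.
#'
#' @param net a [bipartite_network()] with at least 2 rows and 2 columns.
#' @param strict_empty drop zero-degree rows/columns from the pair count
#'   instead of letting them score 0 against every partner?  Default
#'   `FALSE`, the published convention, which keeps the denominator defined
#'   for null matrices containing empty rows.
#' @return An object of class `nodf`: list with `nodf_total`, `nodf_rows`,
#'   `nodf_cols` (each in `[0,100]`), `n_row_pairs` and `n_col_pairs`.
#'   `nodf_total` is the pooled mean
#'   `(sum row scores + sum col scores) / (n_row_pairs + n_col_pairs)`.
#' @examples
#' a <- rbind(c(1, 1, 1, 0), c(1, 0, 0, 1))
#' nodf(bipartite_network(a))$nodf_total  # 50
#' @export
nodf <- function(net, strict_empty = FALSE) {
  stopifnot(inherits(net, "bipartite_network"))
  a <- net$adjacency
  if (nrow(a) < 2 || ncol(a) < 2)
    stop("NODF needs at least 2 rows and 2 columns")
  if (strict_empty) {
    a <- a[rowSums(a) > 0, colSums(a) > 0, drop = FALSE]
    if (nrow(a) < 2 || ncol(a) < 2)
      stop("NODF needs at least 2 non-empty rows and 2 non-empty columns")
  }
  rows <- nodf_axis(a)
  cols <- nodf_axis(t(a))
  structure(list(
    nodf_total = (rows$sum + cols$sum) / (rows$n_pairs + cols$n_pairs),
    nodf_rows = if (rows$n_pairs > 0) rows$sum / rows$n_pairs else 0,
    nodf_cols = if (cols$n_pairs > 0) cols$sum / cols$n_pairs else 0,
    n_row_pairs = rows$n_pairs, n_col_pairs = cols$n_pairs),
    class = "nodf")
}

# vectorised pair scores along the rows of a
nodf_axis <- function(a) {
  f <- rowSums(a)
  n <- nrow(a)
  ov <- a %*% t(a)               # shared partners for each row pair
  fi <- matrix(f, n, n)          # fill of row i (by row)
  fj <- t(fi)                    # fill of row j
  # score for ordered (i, j): fills strictly decrease, j non-empty
  sc <- ifelse(fi > fj & fj > 0, 100 * ov / pmax(fj, 1), 0)
  # each unordered pair contributes once (the decreasing-fill direction)
  list(sum = sum(sc[upper.tri(sc)]) + sum(sc[lower.tri(sc)]),
       n_pairs = n * (n - 1) / 2)
}

#' @export
print.nodf <- function(x, ...) {
  cat(sprintf("NODF = %.2f (rows %.2f over %d pairs, columns %.2f over %d pairs)\n",
              x$nodf_total, x$nodf_rows, x$n_row_pairs,
              x$nodf_cols, x$n_col_pairs))
  invisible(x)
}

#' NODF of the interactions inside one module
#'
#' Applies [nodf()] to the submatrix spanned by a module's own insects and
#' hosts; interactions reaching other modules are excluded.  This is how
#' within-module nestedness is scored when modules found by the optimiser
#' are probed for internal structure.
#'
#' @param net a [bipartite_network()].
#' @param partition a [module_partition] covering `net`.
#' @param module_id id of the module to test; it must contain at least 2
#'   insects and 2 hosts.
#' @inheritParams nodf
#' @return A `nodf` object for the module submatrix.
#' @export
nodf_within_module <- function(net, partition, module_id, strict_empty = FALSE) {
  stopifnot(inherits(net, "bipartite_network"),
            inherits(partition, "module_partition"))
  g <- partition$assignment
  ins <- net$insect_labels[g[net$insect_labels] == module_id]
  hos <- net$host_labels[g[net$host_labels] == module_id]
  if (length(ins) < 2 || length(hos) < 2)
    stop("module must contain at least 2 insects and 2 hosts")
  sub <- bipartite_network(net$adjacency[ins, hos, drop = FALSE])
  nodf(sub, strict_empty = strict_empty)
}
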