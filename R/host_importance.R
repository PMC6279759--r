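#' Pairwise host-removal importance scan
#'
#' Recomputes a structural metric after deleting every unordered pair of
#' host taxa (C(n_hosts, 2) deletions; insect rows emptied by a deletion
#' are pruned, since a taxon without interactions carries no network
#' information).  The scan underlies the importance score of
#' [removal_zscore()]: hosts whose removal depresses nestedness the most
#' are the ones that generate it (ancestral, widely re-used hosts), and
#' hosts whose removal depresses modularity anchor modules (hosts of
#' radiations).
#'
#' For `metric = "M"` each deletion is re-optimised with the standard
#' multi-run annealer, seeded deterministically from `seed` and the pair
#' index so the scan is reproducible.
#'
#' @param net a [bipartite_network()] with at least 3 hosts.
#' @param metric `"NODF"` or `"M"`.
#' @param settings [anneal_settings()] for `metric = "M"`.
#' @param seed integer seed for the per-pair annealing seed schedule.
#' @return An object of class `removal_scan`: data frame `rows` with
#'   columns `host_a`, `host_b`, `value` (the metric after removing the
#'   pair; `NA` when the remainder was degenerate, i.e. fewer than 2 rows
#'   or columns), plus fields `metric_name`, `n_pairs`, `n_computable` and
#'   `n_degenerate`.
#' @export
pairwise_removal_scan <- function(net, metric = c("NODF", "M"),
                                  settings = anneal_settings(), seed = 1L) {
  stopifnot(inherits(net, "bipartite_network"))
  metric <- match.arg(metric)
  hosts <- net$host_labels
  if (length(hosts) < 3) stop("removal scan needs at least 3 hosts")
  pairs <- utils::combn(hosts, 2)
  vals <- rep(NA_real_, ncol(pairs))
  for (ix in seq_len(ncol(pairs))) {
    sub <- remove_hosts(net, pairs[, ix], prune_empty = TRUE)
    if (nrow(sub$adjacency) < 2 || ncol(sub$adjacency) < 2 ||
        sum(sub$adjacency) == 0) next
    vals[ix] <- if (metric == "NODF") nodf(sub)$nodf_total else {
      s <- settings
      s$seed <- (seed + 131L * ix) %% .Machine$integer.max
      optimize_partition(sub, s)$modularity
    }
  }
  rows <- data.frame(host_a = pairs[1, ], host_b = pairs[2, ],
                     value = vals, stringsAsFactors = FALSE)
  structure(list(metric_name = metric, rows = rows,
                 n_pairs = ncol(pairs),
                 n_computable = sum(!is.na(vals)),
                 n_degenerate = sum(is.na(vals))),
            class = "removal_scan")
}

#' @export
print.removal_scan <- function(x, ...) {
  cat(sprintf("Host-pair removal scan (%s): %d pairs, %d computable, %d degenerate\n",
              x$metric_name, x$n_pairs, x$n_computable, x$n_degenerate))
  invisible(x)
}

scan_pair_index <- function(scan, pair) {
  pair <- as.character(pair)
  stopifnot(length(pair) == 2)
  hit <- (scan$rows$host_a == pair[1] & scan$rows$host_b == pair[2]) |
         (scan$rows$host_a == pair[2] & scan$rows$host_b == pair[1])
  ix <- which(hit)
  if (length(ix) != 1) stop("host pair not found in scan")
  ix
}

#' Removal z-score of one host pair
#'
#' Standardises the metric value obtained without the focal host pair
#' against the distribution over all other computable pairs:
#' `z = (value_pair - mean_others) / sd_others` (the focal pair is excluded
#' from the reference moments).  Strongly negative z flags pairs whose
#' joint removal depresses the metric the most.
#'
#' @param scan a [pairwise_removal_scan()] result.
#' @param pair character vector of two host labels.
#' @return Numeric z (with a warning and `NA` when the reference SD is 0).
#' @export
removal_zscore <- function(scan, pair) {
  stopifnot(inherits(scan, "removal_scan"))
  ix <- scan_pair_index(scan, pair)
  v <- scan$rows$value[ix]
  if (is.na(v)) stop("focal pair was not computable")
  others <- scan$rows$value[-ix]
  others <- others[!is.na(others)]
  sdv <- stats::sd(others)
  if (is.na(sdv) || sdv == 0) {
    warning("all other removals give the same value; z undefined")
    return(NA_real_)
  }
  (v - mean(others)) / sdv
}

#' Rank-based empirical p-value of one host pair
#'
#' `p = (1 + #[other pairs with value <= focal]) / n_computable` for the
#' lower tail (metric depressed more than by any other pair); the upper
#' tail swaps the inequality.  This is the only distribution the scan
#' itself provides, so no parametric assumption is made.
#'
#' @param scan a [pairwise_removal_scan()] result.
#' @param pair character vector of two host labels.
#' @param tail `"lower"` (default; depression claims) or `"upper"`
#'   (elevation claims).
#' @return Empirical p in (0, 1].
#' @export
removal_pvalue <- function(scan, pair, tail = c("lower", "upper")) {
  stopifnot(inherits(scan, "removal_scan"))
  tail <- match.arg(tail)
  ix <- scan_pair_index(scan, pair)
  v <- scan$rows$value[ix]
  others <- scan$rows$value[-ix]
  others <- others[!is.na(others)]
  hits <- if (tail == "lower") sum(others <= v) else sum(others >= v)
  (1 + hits) / scan$n_computable
}

#' Write a removal scan as TSV
#'
#' One row per computable host pair, columns `host_a`, `host_b`, `value`,
#' `z`, `p`, sorted by z ascending.
#'
#' @param scan a [pairwise_removal_scan()] result.
#' @param path output file.
#' @param tail passed to [removal_pvalue()].
#' @return `path`, invisibly.
#' @export
write_removal_table <- function(scan, path, tail = "lower") {
  utils::write.table(removal_table(scan, tail), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Full removal-scan table with z and p per pair
#'
#' @param scan a [pairwise_removal_scan()] result.
#' @param tail passed to [removal_pvalue()].
#' @return Data frame sorted by z ascending (most depressing pairs first),
#'   columns `host_a`, `host_b`, `value`, `z`, `p`.
#' @export
removal_table <- function(scan, tail = "lower") {
  rows <- scan$rows
  ok <- which(!is.na(rows$value))
  z <- rep(NA_real_, nrow(rows)); p <- rep(NA_real_, nrow(rows))
  for (ix in ok) {
    pair <- c(rows$host_a[ix], rows$host_b[ix])
    z[ix] <- suppressWarnings(removal_zscore(scan, pair))
    p[ix] <- removal_pvalue(scan, pair, tail)
  }
  out <- cbind(rows, z = z, p = p)
  out[order(out$z), ]
}
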