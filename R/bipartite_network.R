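#' Binary bipartite interaction network
#'
#' Construct a validated binary bipartite network from an incidence matrix
#' with insect (consumer) taxa in rows and host taxa in columns.  This is the
#' central data container of the package: every metric, null model and
#' simulation operates on it.
#'
#' @param adjacency numeric or integer matrix of 0/1 cells, rows = insect
#'   taxa, columns = host taxa.  Row and column names are used as taxon
#'   labels; if absent, labels `I1..In` / `H1..Hm` are generated.
#' @param insect_labels,host_labels optional character vectors overriding the
#'   dimnames of `adjacency`.
#' @param meta optional list of free-form provenance notes (e.g. the
#'   simulation seed and scenario that produced the network).
#'
#' @return An object of class `bipartite_network`: a list with elements
#'   `adjacency` (integer matrix with dimnames), `insect_labels`,
#'   `host_labels` and `meta`.
#'
#' @details Only presence/absence interaction records are supported.  Any
#'   cell other than exactly 0 or 1 (including `NA`) is rejected with an
#'   error naming the offending cell; quantitative networks are not coerced.
#'
#' @examples
#' a <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("gen1", "gen2"), c("Rosales", "Poales")))
#' net <- bipartite_network(a)
#' n_interactions(net)
#' @export
bipartite_network <- function(adjacency, insect_labels = NULL,
                              host_labels = NULL, meta = list()) {
  if (!is.matrix(adjacency))
    adjacency <- as.matrix(adjacency)
  if (is.null(insect_labels))
    insect_labels <- rownames(adjacency)
  if (is.null(host_labels))
    host_labels <- colnames(adjacency)
  if (is.null(insect_labels))
    insect_labels <- paste0("I", seq_len(nrow(adjacency)))
  if (is.null(host_labels))
    host_labels <- paste0("H", seq_len(ncol(adjacency)))
  insect_labels <- as.character(insect_labels)
  host_labels <- as.character(host_labels)
  if (length(insect_labels) != nrow(adjacency) ||
      length(host_labels) != ncol(adjacency))
    stop("label lengths do not match adjacency dimensions")
  if (anyDuplicated(insect_labels))
    stop("duplicate insect labels: ",
         paste(unique(insect_labels[duplicated(insect_labels)]), collapse = ", "))
  if (anyDuplicated(host_labels))
    stop("duplicate host labels: ",
         paste(unique(host_labels[duplicated(host_labels)]), collapse = ", "))
  bad <- which(is.na(adjacency) | !(adjacency == 0 | adjacency == 1),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("non-binary cell at row '%s', column '%s': %s",
                 insect_labels[i], host_labels[j],
                 format(adjacency[i, j])))
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(insect_labels, host_labels)
  structure(list(adjacency = adjacency,
                 insect_labels = insect_labels,
                 host_labels = host_labels,
                 meta = meta),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("Bipartite network: %d insect taxa x %d host taxa, %d interactions (connectance %.3f)\n",
              nrow(x$adjacency), ncol(x$adjacency), n_interactions(x),
              n_interactions(x) / max(1L, length(x$adjacency))))
  if (!is.null(x$meta$scenario))
    cat("  scenario:", x$meta$scenario,
        if (!is.null(x$meta$seed)) paste0("(seed ", x$meta$seed, ")"), "\n")
  invisible(x)
}

#' Total number of interactions in a network
#'
#' @param net a [bipartite_network()].
#' @return Integer count of 1-cells (the network's total interaction count).
#' @export
n_interactions <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  sum(net$adjacency)
}

#' Read a bipartite network from delimited text
#'
#' Two dialects are supported.  `"matrix"`: one header row of host labels,
#' one leading column of insect labels, cells 0/1, comma- or tab-delimited
#' (auto-detected unless `sep` is given).  `"edge_list"`: two columns
#' (insect, host), one interaction per line, optional header; duplicate
#' edges collapse to a single 1.
#'
#' @param path file to read.
#' @param dialect `"matrix"` or `"edge_list"`.
#' @param sep field separator; `NULL` auto-detects tab vs comma from the
#'   first line.
#' @param header for the edge-list dialect only: does the file carry a
#'   header line?  Default `FALSE`.
#' @return A validated [bipartite_network()].
#' @seealso [write_network()]
#' @examples
#' f <- system.file("extdata", "synthetic_example_matrix.tsv",
#'                  package = "hostnet")
#' net <- read_network(f, "matrix")
#' summary(net)
#' @export
read_network <- function(path, dialect = c("matrix", "edge_list"),
                         sep = NULL, header = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  if (dialect == "matrix") {
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            row.names = 1, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m))
      stop("matrix dialect: non-numeric cells found; malformed header or body")
    bipartite_network(m, meta = list(source = path))
  } else {
    df <- utils::read.table(path, sep = sep, header = header,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2)
      stop("edge-list dialect needs two columns (insect, host)")
    edge_list_network(df[[1]], df[[2]], meta = list(source = path))
  }
}

#' Build a network from an edge list
#'
#' @param insects,hosts equal-length vectors naming the endpoints of each
#'   interaction.  Duplicated pairs collapse to a single interaction.
#' @param meta provenance list.
#' @return A [bipartite_network()] whose rows/columns follow first appearance
#'   order in the input.
#' @export
edge_list_network <- function(insects, hosts, meta = list()) {
  insects <- as.character(insects); hosts <- as.character(hosts)
  if (length(insects) != length(hosts))
    stop("insect and host vectors differ in length")
  il <- unique(insects); hl <- unique(hosts)
  a <- matrix(0L, length(il), length(hl), dimnames = list(il, hl))
  a[cbind(match(insects, il), match(hosts, hl))] <- 1L
  bipartite_network(a, meta = meta)
}

#' Write a bipartite network to delimited text
#'
#' Inverse of [read_network()]; `read_network(write_network(net, f), dialect)`
#' round-trips exactly.
#'
#' @param net a [bipartite_network()].
#' @param path output file.
#' @param dialect `"matrix"` or `"edge_list"`.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("matrix", "edge_list"),
                          sep = "\t") {
  stopifnot(inherits(net, "bipartite_network"))
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    df <- as.data.frame(net$adjacency, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       col.names = NA, row.names = TRUE)
  } else {
    idx <- which(net$adjacency == 1L, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    df <- data.frame(insect = net$insect_labels[idx[, 1]],
                     host = net$host_labels[idx[, 2]])
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       col.names = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Remove host taxa from a network
#'
#' Deletes the named host columns, optionally pruning insect rows left with
#' no interactions.  Used by the pairwise host-removal importance scan.
#' The input network is never modified.
#'
#' @param net a [bipartite_network()].
#' @param hosts character vector of host labels to delete (may be empty).
#' @param prune_empty drop insect rows whose degree falls to zero after the
#'   deletion?  Default `FALSE`; the removal scan turns it on because a taxon
#'   without interactions carries no network information.
#' @return A new [bipartite_network()].
#' @export
remove_hosts <- function(net, hosts, prune_empty = FALSE) {
  stopifnot(inherits(net, "bipartite_network"))
  hosts <- as.character(hosts)
  unknown <- setdiff(hosts, net$host_labels)
  if (length(unknown) > 0)
    stop("unknown host label(s): ", paste(unknown, collapse = ", "))
  keep <- !(net$host_labels %in% hosts)
  a <- net$adjacency[, keep, drop = FALSE]
  if (prune_empty) {
    nz <- rowSums(a) > 0
    a <- a[nz, , drop = FALSE]
  }
  bipartite_network(a, meta = net$meta)
}

#' Reduce a network to its interacting taxa
#'
#' Drops insect rows and host columns without any interaction.  Structural
#' analyses operate on the network of realised interactions — empirical
#' interaction matrices contain interacting taxa only by construction, and
#' a taxon with no interactions carries no structural information — so
#' [analyze_network()] and [scenario_study()] apply this before measuring.
#' Simulated studies, by contrast, keep zero-degree tips in their network
#' so that insect labels always match the guide-tree tips.
#'
#' @param net a [bipartite_network()].
#' @return A [bipartite_network()] without empty rows or columns.
#' @export
prune_network <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  a <- net$adjacency
  bipartite_network(a[rowSums(a) > 0, colSums(a) > 0, drop = FALSE],
                    meta = net$meta)
}

#' Summarise a bipartite network
#'
#' @param object a [bipartite_network()].
#' @param ... ignored.
#' @return An object of class `network_summary` with components `n_insects`,
#'   `n_hosts`, `n_interactions`, `connectance` (fill fraction) and
#'   `host_range_histogram`, a named integer vector mapping host-range
#'   (insect degree, including 0) to the number of insect taxa with that
#'   degree.  Histogram counts always sum to `n_insects`.
#' @export
summary.bipartite_network <- function(object, ...) {
  a <- object$adjacency
  deg <- rowSums(a)
  hist <- table(factor(deg, levels = sort(unique(deg))))
  hist <- stats::setNames(as.integer(hist), names(hist))
  structure(list(n_insects = nrow(a),
                 n_hosts = ncol(a),
                 n_interactions = sum(a),
                 connectance = if (length(a) > 0) sum(a) / length(a) else 0,
                 host_range_histogram = hist),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("%d insects, %d hosts, %d interactions, connectance %.4f\n",
              x$n_insects, x$n_hosts, x$n_interactions, x$connectance))
  cat("host-range histogram (hosts used : n insects):\n")
  print(x$host_range_histogram)
  invisible(x)
}

#' Incidence-matrix plot of a bipartite network
#'
#' Draws the 0/1 incidence matrix, optionally colouring cells by the module
#' of the interaction (an interaction is coloured when its insect and host
#' share a module, grey when it crosses modules).
#'
#' @param x a [bipartite_network()].
#' @param partition optional [module_partition] used to colour cells.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.bipartite_network <- function(x, partition = NULL, ...) {
  a <- x$adjacency
  z <- a * 1
  if (!is.null(partition)) {
    gi <- partition$assignment[x$insect_labels]
    gh <- partition$assignment[x$host_labels]
    same <- outer(gi, gh, "==")
    sel <- a == 1 & same
    z[sel] <- 2 + gi[row(a)[sel]]   # module ids are 0-based
  }
  cols <- c("white", "grey60",
            grDevices::hcl.colors(max(1, max(z) - 1), "Dark 3"))
  graphics::image(t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                  col = cols[seq_len(max(z) + 1)], axes = FALSE, ...)
  graphics::box()
  invisible(x)
}
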