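#' Parse a rooted phylogeny from a newick file or string
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' phylogenetic-diversity functions rely on: unique tip labels, collapsed
#' unifurcations, and branch lengths (missing lengths become 0 with a
#' warning).
#'
#' @param path path to a newick file, or (with `text`) a newick string.
#' @param text optional newick string used instead of `path`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_tree <- function(path = NULL, text = NULL) {
  phy <- if (!is.null(text)) ape::read.tree(text = text) else {
    if (!file.exists(path)) stop("file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(phy)) stop("could not parse newick input")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  phy <- ape::collapse.singles(phy)
  if (is.null(phy$edge.length)) {
    warning("newick has no branch lengths; all set to 0")
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    warning("missing branch lengths set to 0")
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  phy
}

#' Faith's phylogenetic diversity of a tip sample
#'
#' Sum of the branch lengths of the minimal subtree spanning the sampled
#' tips.  The path to the root is included (so a single tip has PD equal to
#' its root-to-tip distance, and the full tip set returns the total branch
#' length of the tree); set `include_root = FALSE` for the crown-only
#' variant.
#'
#' @param tree a `phylo` object (see [parse_tree()]).
#' @param tips non-empty character vector of tip labels.
#' @param include_root include the branches from the sample's subtree to
#'   the root (default `TRUE`).
#' @return PD in branch-length units.
#' @examples
#' tr <- parse_tree(text = "((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B", "C"))  # 5
#' faith_pd(tr, "A")               # 2
#' @export
faith_pd <- function(tree, tips, include_root = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  tips <- as.character(tips)
  if (length(tips) == 0) stop("tip sample is empty")
  ix <- match(tips, tree$tip.label)
  if (anyNA(ix))
    stop("unknown tip(s): ", paste(tips[is.na(ix)], collapse = ", "))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_edge <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2])
  used <- logical(nrow(tree$edge))
  for (v in ix) {
    while (v != root) {
      e <- parent_edge[v]
      if (used[e]) break
      used[e] <- TRUE
      v <- tree$edge[e, 1]
    }
  }
  if (!include_root && length(unique(ix)) >= 1) {
    mrca <- if (length(unique(ix)) == 1) ix[1] else
      ape::getMRCA(tree, unique(ix))
    v <- mrca
    while (v != root) {
      e <- parent_edge[v]
      used[e] <- FALSE
      v <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[used])
}

#' Phylogenetic diversity of every module, with a tip-shuffle null
#'
#' For each module and guild, computes Faith's PD of the module's members
#' on the corresponding tree, the percentage of the guild's total PD it
#' represents, and a permutation p-value from a null model that shuffles
#' taxon labels across the guild's tips while keeping every module's size
#' fixed: `p_lower = (1 + #[null PD <= observed]) / (n_shuffles + 1)`.
#' Modules whose observed PD is significantly low (`p_lower < alpha`)
#' contain phylogenetically clustered taxa — for insects, the signature of
#' closely related butterflies diversifying inside one module.  Modules
#' with fewer than 2 taxa of a guild get no p-value.
#'
#' @param net a [bipartite_network()].
#' @param partition a `module_partition` covering `net`.
#' @param insect_tree,host_tree `phylo` trees whose tips include the
#'   network's insect and host labels (either may be `NULL` to skip that
#'   guild).
#' @param n_shuffles number of label permutations (default 999).
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05).
#' @param seed integer seed or `NULL`.
#' @return Data frame of class `module_pd` with columns `module`, `guild`,
#'   `n_taxa`, `pd_raw`, `pd_percent` (100 x pd_raw / PD of all network
#'   taxa of the guild), `p_lower` (`NA` when `n_taxa < 2`) and
#'   `significant`.
#' @export
module_pd_test <- function(net, partition, insect_tree = NULL,
                           host_tree = NULL, n_shuffles = 999,
                           alpha = 0.05, seed = NULL) {
  stopifnot(inherits(net, "bipartite_network"),
            inherits(partition, "module_partition"))
  with_seed(seed, {
    out <- list()
    guilds <- list(insect = list(tree = insect_tree, labs = net$insect_labels),
                   host = list(tree = host_tree, labs = net$host_labels))
    for (gname in names(guilds)) {
      tree <- guilds[[gname]]$tree
      if (is.null(tree)) next
      labs <- guilds[[gname]]$labs
      missing <- setdiff(labs, tree$tip.label)
      if (length(missing) > 0)
        stop(gname, " tree lacks tip(s): ", paste(missing, collapse = ", "))
      g <- partition$assignment[labs]
      mods <- sort(unique(as.integer(partition$assignment)))
      total_pd <- faith_pd(tree, labs)
      members <- split(labs, factor(as.integer(g), levels = mods))
      sizes <- lengths(members)
      obs <- vapply(members, function(mm)
        if (length(mm) == 0) NA_real_ else faith_pd(tree, mm), 0.0)
      # null: permute labels over the guild's network tips, keep sizes
      hits <- integer(length(mods))
      grp <- rep(seq_along(mods), sizes)        # module of each shuffled slot
      for (s in seq_len(n_shuffles)) {
        perm <- sample(labs)
        null_members <- split(perm, grp)
        stopifnot(lengths(null_members) == sizes[sizes > 0])
        npd <- vapply(null_members, function(mm) faith_pd(tree, mm), 0.0)
        hits[sizes > 0] <- hits[sizes > 0] + (npd <= obs[sizes > 0] + 1e-12)
      }
      p <- ifelse(sizes >= 2, (1 + hits) / (n_shuffles + 1), NA_real_)
      out[[gname]] <- data.frame(
        module = mods, guild = gname, n_taxa = as.integer(sizes),
        pd_raw = obs, pd_percent = 100 * obs / total_pd,
        p_lower = p, significant = !is.na(p) & p < alpha,
        row.names = NULL, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    res <- res[res$n_taxa > 0, ]
    rownames(res) <- NULL
    class(res) <- c("module_pd", "data.frame")
    res
  })
}

#' Write a module-PD report as TSV
#'
#' @param report a [module_pd_test()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_module_pd <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
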