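#' Fixed guide phylogeny for the diversification simulations
#'
#' Builds the balanced, ultrametric guide tree on which every generative
#' scenario runs: `n_pairs` pairs of sister subclades, each pair holding one
#' low-diversity subclade (`small` tips) and one high-diversity subclade
#' (`large` tips).  With the defaults the tree has 100 terminal taxa in 10
#' subclades, so the diversity contrast within each pair is what the
#' simulated diversification process has to explain.
#'
#' Topology is deterministic: subclades are balanced binary trees, pairs are
#' joined on a ladder backbone.  Internal branches have length 1 and terminal
#' branches are padded so every tip sits at the same depth (the tree is
#' ultrametric).
#'
#' @param n_pairs number of subclade pairs (default 5).
#' @param small,large tip counts of the low- and high-diversity subclade of
#'   each pair (defaults 5 and 15).
#' @return An object of class `guide_tree`: list with `phylo` (an
#'   [ape::read.tree()] tree), `pairs` (per pair, the character vectors
#'   `low` and `high` of tip labels), and the call parameters.
#' @examples
#' gt <- build_guide_tree()
#' length(gt$phylo$tip.label)  # 100
#' @export
build_guide_tree <- function(n_pairs = 5, small = 5, large = 15) {
  stopifnot(n_pairs >= 1, small >= 1, large >= 1)
  bal <- function(labels) {
    n <- length(labels)
    if (n == 1) return(sprintf("%s:1", labels))
    k <- ceiling(n / 2)
    sprintf("(%s,%s):1", bal(labels[seq_len(k)]), bal(labels[-seq_len(k)]))
  }
  pairs <- vector("list", n_pairs)
  pair_nwk <- character(n_pairs)
  for (p in seq_len(n_pairs)) {
    low <- sprintf("p%dl%02d", p, seq_len(small))
    high <- sprintf("p%dh%02d", p, seq_len(large))
    pairs[[p]] <- list(low = low, high = high)
    pair_nwk[p] <- sprintf("(%s,%s):1", bal(low), bal(high))
  }
  nwk <- pair_nwk[1]
  if (n_pairs > 1)
    for (p in 2:n_pairs) nwk <- sprintf("(%s,%s):1", nwk, pair_nwk[p])
  phy <- ape::read.tree(text = paste0(sub(":1$", "", nwk), ";"))
  # pad terminal branches so all tips reach the maximum root-to-tip depth
  depth <- ape::node.depth.edgelength(phy)
  tipd <- depth[seq_along(phy$tip.label)]
  pad <- max(tipd) - tipd
  term <- match(seq_along(phy$tip.label), phy$edge[, 2])
  phy$edge.length[term] <- phy$edge.length[term] + pad
  structure(list(phylo = phy, pairs = pairs,
                 n_pairs = n_pairs, small = small, large = large),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat(sprintf("Guide tree: %d tips, %d subclade pairs (sizes %d + %d)\n",
              length(x$phylo$tip.label), x$n_pairs, x$small, x$large))
  invisible(x)
}

# tips of every subclade, in pair order
guide_tree_tips <- function(gt) unlist(lapply(gt$pairs, unlist), use.names = FALSE)
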