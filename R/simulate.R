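#' Configuration of a diversification-scenario simulation
#'
#' Bundles every constant of the generative rules.  The defaults are the
#' study conditions used throughout the package: a 40-host pool, a 10-host
#' ancestral fundamental repertoire, 10 extra hosts gained by each
#' high-diversity variability clade, 2 ancestral hosts under radiation,
#' 2 realised hosts per low-diversity tip, 80% removal of possible
#' interactions in high-diversity variability clades, and 20% random fill
#' where interactions are sampled at random.
#'
#' @param pair_scenarios character vector, one tag per subclade pair, each
#'   `"radiation"` or `"variability"`; e.g. `c("radiation", "radiation",
#'   "variability", "variability", "variability")` is the mixed scenario
#'   R2V3.  Radiation rules are applied to the listed pairs in tree order.
#' @param host_pool_size total number of host taxa available (default 40).
#' @param ancestral_fundamental size of the ancestor's fundamental host
#'   repertoire (default 10; under radiation only
#'   `radiation_ancestral_hosts` of these are used).
#' @param expansion_per_pair hosts added to the fundamental repertoire of a
#'   high-diversity variability clade (default 10).
#' @param radiation_ancestral_hosts hosts used by the ancestor under the
#'   radiation rules (default 2).
#' @param low_clade_realised hosts realised by each low-diversity tip
#'   (default 2).
#' @param high_clade_removal_fraction fraction of the possible tip-by-host
#'   interactions of a high-diversity variability clade that is deleted
#'   (default 0.80).
#' @param random_fill fraction of possible interactions realised in the
#'   random and uniform-evolution scenarios (default 0.20).
#' @param turnover number of fundamental-repertoire hosts replaced on each
#'   backbone branch in the uniform-evolution scenario (default 3, which
#'   uses 10 + 8*3 = 34 of the 40 pool hosts on the default backbone — the
#'   largest turnover the pool can sustain).
#' @param bernoulli_removal if `TRUE`, the 80% deletion is per-cell
#'   Bernoulli rather than an exact count (default `FALSE`: exactly
#'   `floor(fraction * n_cells)` deletions).
#' @param resample_empty if `TRUE`, tips left without any realised host are
#'   redrawn; default `FALSE` keeps them as empty rows.
#' @param seed integer seed making the simulation reproducible (`NULL` uses
#'   the current RNG stream).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(pair_scenarios = rep("variability", 5),
                            host_pool_size = 40,
                            ancestral_fundamental = 10,
                            expansion_per_pair = 10,
                            radiation_ancestral_hosts = 2,
                            low_clade_realised = 2,
                            high_clade_removal_fraction = 0.80,
                            random_fill = 0.20,
                            turnover = 3,
                            bernoulli_removal = FALSE,
                            resample_empty = FALSE,
                            seed = NULL) {
  pair_scenarios <- match.arg(pair_scenarios,
                              c("radiation", "variability"),
                              several.ok = TRUE)
  stopifnot(host_pool_size >= 1, ancestral_fundamental >= 1,
            expansion_per_pair >= 0, radiation_ancestral_hosts >= 1,
            low_clade_realised >= 1,
            high_clade_removal_fraction > 0, high_clade_removal_fraction < 1,
            random_fill > 0, random_fill < 1, turnover >= 0)
  if (ancestral_fundamental + expansion_per_pair > host_pool_size)
    stop("ancestral repertoire plus expansion exceeds the host pool")
  structure(list(pair_scenarios = pair_scenarios,
                 host_pool_size = host_pool_size,
                 ancestral_fundamental = ancestral_fundamental,
                 expansion_per_pair = expansion_per_pair,
                 radiation_ancestral_hosts = radiation_ancestral_hosts,
                 low_clade_realised = low_clade_realised,
                 high_clade_removal_fraction = high_clade_removal_fraction,
                 random_fill = random_fill,
                 turnover = turnover,
                 bernoulli_removal = bernoulli_removal,
                 resample_empty = resample_empty,
                 seed = seed),
            class = "scenario_config")
}

# run expr under set.seed(seed) without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

host_labels_for <- function(pool) sprintf("h%02d", seq_len(pool))

# assemble a simulated_study from a full insect x pool adjacency
finish_study <- function(adj, gt, cfg, fundamental, scenario) {
  used <- colSums(adj) > 0
  net <- bipartite_network(adj[, used, drop = FALSE],
                           meta = list(scenario = scenario, seed = cfg$seed))
  structure(list(network = net, tree = gt, config = cfg,
                 fundamental_repertoires = fundamental,
                 scenario = scenario),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated study, scenario %s\n", x$scenario))
  print(x$network)
  invisible(x)
}

#' Simulate a network under the radiation/variability scenario rules
#'
#' Each subclade pair of the guide tree diversifies under one of two
#' generative rule sets.  Radiation: the ancestor of all clades uses two
#' hosts; low-diversity subclade tips keep exactly those two ancestral
#' hosts; every tip of the high-diversity subclade uses a single novel host
#' unique to that subclade (the host whose colonisation allowed the
#' radiation).  Variability: the ancestor's fundamental repertoire holds 10
#' hosts shared by all pairs; the high-diversity subclade gains 10 further
#' hosts after branching; low-diversity tips realise
#' `low_clade_realised` hosts drawn at random from the ancestral repertoire;
#' in the high-diversity subclade 80% of the possible tip-by-repertoire
#' interactions are deleted at random, producing a specialist-generalist
#' gradient.
#'
#' Host bookkeeping uses one global pool `h01..h40`: radiation ancestral
#' hosts are `h01`,`h02`; the variability ancestral repertoire is
#' `h01..h10`; radiation novel hosts are taken from the top of the pool
#' (`h40` downwards) and excluded from expansion draws so they stay unique;
#' each expansion draws from the remaining `h11..h40` (expansions of
#' different pairs may overlap).  Hosts with no realised interaction are
#' dropped from the returned network.
#'
#' @param cfg a [scenario_config()]; `cfg$pair_scenarios` must have one tag
#'   per pair of `tree`.
#' @param tree a [build_guide_tree()] guide tree.
#' @return A `simulated_study`: list with the realised `network`
#'   ([bipartite_network]), the guide `tree`, `config`, and
#'   `fundamental_repertoires` (per tip, the character vector of hosts it
#'   could use).  Realised hosts are always a subset of the fundamental
#'   repertoire.
#' @export
simulate_scenario <- function(cfg = scenario_config(), tree = build_guide_tree()) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(tree, "guide_tree"))
  if (length(cfg$pair_scenarios) != tree$n_pairs)
    stop("pair_scenarios must name one scenario per subclade pair")
  with_seed(cfg$seed, {
    pool <- cfg$host_pool_size
    hl <- host_labels_for(pool)
    tips <- guide_tree_tips(tree)
    adj <- matrix(0L, length(tips), pool, dimnames = list(tips, hl))
    fund <- stats::setNames(vector("list", length(tips)), tips)
    anc_rad <- seq_len(cfg$radiation_ancestral_hosts)
    anc_var <- seq_len(cfg$ancestral_fundamental)
    n_rad <- sum(cfg$pair_scenarios == "radiation")
    rad_unique <- if (n_rad > 0) pool - seq_len(n_rad) + 1L else integer(0)
    if (n_rad > 0 && min(rad_unique) <= max(anc_var))
      stop("host pool too small for unique radiation hosts")
    expansion_pool <- setdiff(seq(cfg$ancestral_fundamental + 1L, pool), rad_unique)
    if (cfg$expansion_per_pair > length(expansion_pool))
      stop("host pool exhausted: expansion larger than remaining pool")
    r_seen <- 0L
    for (p in seq_len(tree$n_pairs)) {
      low <- tree$pairs[[p]]$low; high <- tree$pairs[[p]]$high
      if (cfg$pair_scenarios[p] == "radiation") {
        r_seen <- r_seen + 1L
        u <- rad_unique[r_seen]
        for (tp in low) { fund[[tp]] <- anc_rad; adj[tp, anc_rad] <- 1L }
        for (tp in high) { fund[[tp]] <- u; adj[tp, u] <- 1L }
      } else {
        for (tp in low) {
          fund[[tp]] <- anc_var
          adj[tp, sample(anc_var, cfg$low_clade_realised)] <- 1L
        }
        expansion <- sample(expansion_pool, cfg$expansion_per_pair)
        rep_high <- c(anc_var, expansion)
        nh <- length(high); nr <- length(rep_high)
        repeat {
          block <- matrix(1L, nh, nr)
          if (cfg$bernoulli_removal) {
            block[stats::runif(nh * nr) < cfg$high_clade_removal_fraction] <- 0L
          } else {
            drop <- sample(nh * nr,
                           floor(cfg$high_clade_removal_fraction * nh * nr))
            block[drop] <- 0L
          }
          if (!cfg$resample_empty || all(rowSums(block) > 0)) break
        }
        for (i in seq_len(nh)) {
          fund[[high[i]]] <- rep_high
          adj[high[i], rep_high] <- block[i, ]
        }
      }
    }
    fund <- lapply(fund, function(ix) hl[sort(ix)])
    finish_study(adj, tree, cfg, fund, scenario_tag(cfg$pair_scenarios))
  })
}

scenario_tag <- function(pair_scenarios) {
  sprintf("R%dV%d", sum(pair_scenarios == "radiation"),
          sum(pair_scenarios == "variability"))
}

#' Simulate a random (neutral) network
#'
#' Every tip's fundamental repertoire is the whole host pool and exactly
#' `round(fill * n_insects * host_pool)` interactions are drawn uniformly
#' without replacement over all insect-by-host cells; host-repertoire
#' evolution plays no role.  With the defaults this realises exactly 800 of
#' the 100 x 40 cells (20% connectance).  The per-insect host range is then
#' close to Binomial(`host_pool`, `fill`).
#'
#' @param n_insects number of insect taxa (default 100; when it matches the
#'   guide tree's tip count the tree's tip labels are used).
#' @param host_pool number of host taxa (default 40).
#' @param fill fraction of cells realised, in (0,1] (default 0.20).
#' @param seed integer seed or `NULL`.
#' @param tree guide tree supplying insect labels (default
#'   [build_guide_tree()]).
#' @return A `simulated_study` (see [simulate_scenario()]).
#' @export
simulate_random <- function(n_insects = 100, host_pool = 40, fill = 0.20,
                            seed = NULL, tree = build_guide_tree()) {
  stopifnot(fill > 0, fill <= 1)
  cfg <- scenario_config(random_fill = min(fill, 1 - 1e-9), seed = seed)
  cfg$host_pool_size <- host_pool
  use_tree <- inherits(tree, "guide_tree") &&
    length(tree$phylo$tip.label) == n_insects
  tips <- if (use_tree) guide_tree_tips(tree) else
    sprintf("t%03d", seq_len(n_insects))
  with_seed(seed, {
    hl <- host_labels_for(host_pool)
    adj <- matrix(0L, n_insects, host_pool, dimnames = list(tips, hl))
    k <- round(fill * n_insects * host_pool)
    adj[sample(n_insects * host_pool, k)] <- 1L
    fund <- stats::setNames(rep(list(hl), n_insects), tips)
    finish_study(adj, if (use_tree) tree else NULL, cfg, fund, "random")
  })
}

#' Simulate the uniform-evolution scenario
#'
#' Host repertoires evolve by gradual turnover along the backbone of the
#' guide tree, with no link between host use and diversification.  The root
#' carries a fundamental repertoire of `ancestral_fundamental` hosts; on
#' every backbone branch (root to each pair ancestor) `turnover` hosts are
#' replaced by hosts never used before, keeping the repertoire size
#' constant.  Below the pair split nothing changes, so the low- and
#' high-diversity subclades of each pair inherit identical fundamental
#' repertoires of identical size, closely related pairs share more hosts,
#' and basal pairs carry more unique hosts.  Realised interactions are a
#' uniform random draw of `random_fill` of all (tip, fundamental host)
#' cells.
#'
#' @inheritParams simulate_scenario
#' @return A `simulated_study` (see [simulate_scenario()]).
#' @export
simulate_uniform_evolution <- function(cfg = scenario_config(),
                                       tree = build_guide_tree()) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(tree, "guide_tree"))
  with_seed(cfg$seed, {
    phy <- tree$phylo
    pool <- cfg$host_pool_size
    hl <- host_labels_for(pool)
    ntip <- length(phy$tip.label)
    root <- ntip + 1L
    parent <- integer(ntip + phy$Nnode)
    parent[phy$edge[, 2]] <- phy$edge[, 1]
    mrcas <- vapply(tree$pairs,
                    function(p) ape::getMRCA(phy, c(p$low, p$high)), 0L)
    # backbone = all nodes on the root -> pair-ancestor paths (root excluded)
    backbone <- integer(0)
    for (m in mrcas) {
      v <- m
      while (v != root) { backbone <- c(backbone, v); v <- parent[v] }
    }
    backbone <- unique(backbone)
    backbone <- backbone[order(ape::node.depth.edgelength(phy)[backbone])]
    rep_at <- vector("list", ntip + phy$Nnode)
    rep_at[[root]] <- seq_len(cfg$ancestral_fundamental)
    unused <- setdiff(seq_len(pool), rep_at[[root]])
    for (v in backbone) {
      r <- rep_at[[parent[v]]]
      t_n <- min(cfg$turnover, length(r))
      if (t_n > length(unused))
        stop("host pool exhausted: reduce turnover or enlarge the pool")
      if (t_n > 0) {
        out <- sample(length(r), t_n)
        gain <- unused[sample.int(length(unused), t_n)]
        r[out] <- gain
        unused <- setdiff(unused, gain)
      }
      rep_at[[v]] <- r
    }
    tips <- guide_tree_tips(tree)
    fund_ix <- stats::setNames(vector("list", length(tips)), tips)
    for (p in seq_along(tree$pairs)) {
      r <- rep_at[[mrcas[p]]]
      for (tp in unlist(tree$pairs[[p]])) fund_ix[[tp]] <- r
    }
    cells <- do.call(rbind, lapply(seq_along(tips), function(i)
      cbind(i, fund_ix[[i]])))
    k <- round(cfg$random_fill * nrow(cells))
    chosen <- cells[sample(nrow(cells), k), , drop = FALSE]
    adj <- matrix(0L, length(tips), pool, dimnames = list(tips, hl))
    adj[chosen] <- 1L
    fund <- lapply(fund_ix, function(ix) hl[sort(ix)])
    finish_study(adj, tree, cfg, fund, "uniform")
  })
}
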