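#' Simulate a network for a named scenario
#'
#' One entry point for all eight generative scenarios: `"R5V0"` ...
#' `"R0V5"` (x pairs radiating, y pairs varying, radiation pairs first in
#' tree order), `"random"`, and `"uniform"` (uniform evolution).
#'
#' @param scenario scenario tag.
#' @param seed integer seed.
#' @param tree guide tree (default [build_guide_tree()]).
#' @param cfg base [scenario_config()]; its `pair_scenarios` and `seed` are
#'   overridden from `scenario` and `seed`.
#' @return A `simulated_study` (see [simulate_scenario()]).
#' @examples
#' st <- simulate_network("R5V0", seed = 1)
#' n_interactions(st$network)  # 125
#' @export
simulate_network <- function(scenario, seed = NULL,
                             tree = build_guide_tree(),
                             cfg = scenario_config()) {
  scenario <- as.character(scenario)[1]
  cfg$seed <- seed
  if (scenario == "random") {
    return(simulate_random(length(tree$phylo$tip.label), cfg$host_pool_size,
                           cfg$random_fill, seed = seed, tree = tree))
  }
  if (scenario == "uniform") {
    return(simulate_uniform_evolution(cfg, tree))
  }
  m <- regmatches(scenario, regexec("^R([0-9]+)V([0-9]+)$", scenario))[[1]]
  if (length(m) == 3) {
    r <- as.integer(m[2]); v <- as.integer(m[3])
    if (r + v != tree$n_pairs)
      stop(sprintf("scenario '%s' needs %d pairs but the tree has %d",
                   scenario, r + v, tree$n_pairs))
    cfg$pair_scenarios <- rep(c("radiation", "variability"), c(r, v))
    return(simulate_scenario(cfg, tree))
  }
  stop("unknown scenario tag: '", scenario,
       "' (expected RxVy, 'random' or 'uniform')")
}

#' Write a simulated study to disk
#'
#' Emits three files under `prefix`: `<prefix>_network.tsv` (matrix
#' dialect), `<prefix>_tree.nwk` (newick guide tree) and
#' `<prefix>_config.json` (scenario, seed and every generator constant), so
#' a run can be regenerated exactly from its sidecar.
#'
#' @param study a `simulated_study`.
#' @param prefix output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_study <- function(study, prefix) {
  stopifnot(inherits(study, "simulated_study"))
  files <- c(network = paste0(prefix, "_network.tsv"),
             tree = paste0(prefix, "_tree.nwk"),
             config = paste0(prefix, "_config.json"))
  write_network(study$network, files["network"], dialect = "matrix")
  if (!is.null(study$tree))
    ape::write.tree(study$tree$phylo, files["tree"])
  else
    files <- files[c("network", "config")]
  cfg <- study$config
  cfg$scenario <- study$scenario
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       files["config"], auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Full structural analysis of one network
#'
#' Bundles the core pipeline: NODF and modularity tests against the
#' degree-proportional null model, the best module partition, taxon roles,
#' and optionally the host-pair removal scan and the module
#' phylogenetic-diversity tests.
#'
#' @param net a [bipartite_network()].
#' @param n_null_nodf,n_null_m null matrices for the NODF and the `M` test
#'   (defaults 1000 and 200; the `M` default is lower because every null
#'   matrix is re-optimised).
#' @param alpha one-tailed (upper) significance level for the verdicts
#'   (default 0.05).
#' @param settings [anneal_settings()] for the observed network.
#' @param null_runs annealing chains per null matrix (default 3).
#' @param removal_scan also run [pairwise_removal_scan()] (for both
#'   metrics)?  Default `FALSE`; quadratic in host count.
#' @param prune_empty analyse the network of interacting taxa only
#'   (default `TRUE`; see [prune_network()]).
#' @param insect_tree,host_tree optional trees enabling [module_pd_test()].
#' @param seed integer seed driving every stochastic step.
#' @return An object of class `network_analysis`: list with `nodf_test`,
#'   `m_test` (class `metric_test`), `partition`, `roles`, `summary`,
#'   verdicts `nested_significant` / `modular_significant`, and if
#'   requested `removal` (per metric) and `module_pd`.
#' @export
analyze_network <- function(net, n_null_nodf = 1000, n_null_m = 200,
                            alpha = 0.05, settings = anneal_settings(),
                            null_runs = 3, removal_scan = FALSE,
                            insect_tree = NULL, host_tree = NULL,
                            prune_empty = TRUE, seed = NULL) {
  stopifnot(inherits(net, "bipartite_network"))
  if (prune_empty) net <- prune_network(net)
  with_seed(seed, {
    if (is.null(settings$seed))
      settings$seed <- sample.int(.Machine$integer.max - 64L, 1)
    partition <- optimize_partition(net, settings)
    nodf_test <- structure_test(net, "NODF", n_null = n_null_nodf)
    m_test <- structure_test(net, "M", n_null = n_null_m,
                             settings = settings, null_runs = null_runs,
                             partition = partition)
    roles <- compute_roles(net, partition)
    removal <- NULL
    if (removal_scan)
      removal <- list(NODF = pairwise_removal_scan(net, "NODF"),
                      M = pairwise_removal_scan(net, "M", settings = settings,
                                                seed = settings$seed))
    mpd <- NULL
    if (!is.null(insect_tree) || !is.null(host_tree))
      mpd <- module_pd_test(net, partition, insect_tree, host_tree)
    structure(list(summary = summary(net),
                   nodf_test = nodf_test, m_test = m_test,
                   partition = partition, roles = roles,
                   removal = removal, module_pd = mpd,
                   alpha = alpha,
                   nested_significant = nodf_test$p_upper < alpha,
                   modular_significant = m_test$p_upper < alpha,
                   seed = seed),
              class = "network_analysis")
  })
}

#' @export
print.network_analysis <- function(x, ...) {
  print(x$summary)
  print(x$nodf_test)
  print(x$m_test)
  cat(sprintf("verdict at alpha = %.2f: %snested, %smodular\n", x$alpha,
              if (x$nested_significant) "" else "not ",
              if (x$modular_significant) "" else "not "))
  invisible(x)
}

#' Run the full simulation study across scenarios
#'
#' Simulates every requested scenario, tests NODF and `M` of each realised
#' network against the degree-proportional null model, and tabulates
#' observed values, z-scores, permutation p-values and significance
#' verdicts — the simulation experiment that shows radiation-built networks
#' to be modular, variability-built networks to be nested, and random
#' networks to be neither.  With `replicates > 1`, per-scenario means and
#' SDs over replicate seeds are appended.
#'
#' @param scenarios character vector of scenario tags (default all eight).
#' @param seed master integer seed; replicate `r` of scenario `s` derives
#'   its seed deterministically from it.
#' @param n_null_nodf,n_null_m null-side sample sizes (see
#'   [analyze_network()]).
#' @param alpha significance level for verdicts (default 0.05, upper tail).
#' @param replicates replicate simulations per scenario (default 1).
#' @param settings [anneal_settings()] for observed networks.
#' @param null_runs annealing chains per null matrix (default 3).
#' @param tree guide tree.
#' @param cfg base [scenario_config()].
#' @return An object of class `scenario_study`: `results`, a data frame
#'   with one row per scenario x replicate (columns scenario, replicate,
#'   seed, n_insects, n_hosts, n_interactions, nodf, nodf_z, nodf_p, m,
#'   m_z, m_p, n_modules, nested_significant, modular_significant), and
#'   `summary_by_scenario` when `replicates > 1`.
#' @export
scenario_study <- function(scenarios = c("R5V0", "R4V1", "R3V2", "R2V3",
                                         "R1V4", "R0V5", "random", "uniform"),
                           seed = 1L, n_null_nodf = 1000, n_null_m = 200,
                           alpha = 0.05, replicates = 1,
                           settings = anneal_settings(), null_runs = 3,
                           tree = build_guide_tree(), cfg = scenario_config()) {
  rows <- list()
  for (si in seq_along(scenarios)) {
    for (r in seq_len(replicates)) {
      rseed <- (seed + 7919L * (si - 1L) + 104729L * (r - 1L)) %%
        .Machine$integer.max
      st <- simulate_network(scenarios[si], seed = rseed, tree = tree, cfg = cfg)
      an <- analyze_network(st$network, n_null_nodf = n_null_nodf,
                            n_null_m = n_null_m, alpha = alpha,
                            settings = settings, null_runs = null_runs,
                            seed = rseed + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scenarios[si], replicate = r, seed = rseed,
        n_insects = an$summary$n_insects, n_hosts = an$summary$n_hosts,
        n_interactions = an$summary$n_interactions,
        nodf = an$nodf_test$observed, nodf_z = an$nodf_test$z,
        nodf_p = an$nodf_test$p_upper,
        m = an$m_test$observed, m_z = an$m_test$z, m_p = an$m_test$p_upper,
        n_modules = an$partition$n_modules,
        nested_significant = an$nested_significant,
        modular_significant = an$modular_significant,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  summ <- NULL
  if (replicates > 1) {
    summ <- do.call(rbind, lapply(split(results, results$scenario), function(d)
      data.frame(scenario = d$scenario[1], replicates = nrow(d),
                 nodf_mean = mean(d$nodf), nodf_sd = stats::sd(d$nodf),
                 m_mean = mean(d$m), m_sd = stats::sd(d$m),
                 nodf_z_mean = mean(d$nodf_z), m_z_mean = mean(d$m_z),
                 prop_nested = mean(d$nested_significant),
                 prop_modular = mean(d$modular_significant),
                 stringsAsFactors = FALSE)))
    rownames(summ) <- NULL
    summ <- summ[match(unique(results$scenario), summ$scenario), ]
  }
  structure(list(results = results, summary_by_scenario = summ,
                 seed = seed, alpha = alpha,
                 n_null_nodf = n_null_nodf, n_null_m = n_null_m),
            class = "scenario_study")
}

#' @export
print.scenario_study <- function(x, ...) {
  cat(sprintf("Scenario study (master seed %d, %d NODF / %d M nulls, alpha %.2f)\n",
              x$seed, x$n_null_nodf, x$n_null_m, x$alpha))
  print(x$results, digits = 3)
  if (!is.null(x$summary_by_scenario)) {
    cat("\nPer-scenario summaries:\n")
    print(x$summary_by_scenario, digits = 3)
  }
  invisible(x)
}

#' Write a scenario study as TSV and JSON
#'
#' Emits `<prefix>_study.tsv` (the per-scenario/replicate results table)
#' and `<prefix>_study.json` (results, per-scenario summaries when present,
#' and the settings needed to regenerate the study).
#'
#' @param study a [scenario_study()] result.
#' @param prefix output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_scenario_study <- function(study, prefix) {
  stopifnot(inherits(study, "scenario_study"))
  files <- c(tsv = paste0(prefix, "_study.tsv"),
             json = paste0(prefix, "_study.json"))
  utils::write.table(study$results, files["tsv"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$seed, alpha = study$alpha,
         n_null_nodf = study$n_null_nodf, n_null_m = study$n_null_m,
         results = study$results,
         summary_by_scenario = study$summary_by_scenario),
    files["json"], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(files)
}

#' z-score chart of a scenario study
#'
#' Plots the NODF and `M` z-scores per scenario with the upper-tail
#' significance threshold as a dashed line, mirroring the usual summary
#' figure of such simulation studies.
#'
#' @param x a [scenario_study()] result.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.scenario_study <- function(x, ...) {
  d <- x$results
  agg <- do.call(rbind, lapply(split(d, d$scenario), function(s)
    data.frame(scenario = s$scenario[1], nodf_z = mean(s$nodf_z),
               m_z = mean(s$m_z))))
  agg <- agg[match(unique(d$scenario), agg$scenario), ]
  graphics::matplot(seq_len(nrow(agg)), cbind(agg$nodf_z, agg$m_z),
                    type = "b", pch = c(1, 19), lty = 1,
                    col = c("steelblue", "firebrick"),
                    xaxt = "n", xlab = "scenario", ylab = "z-score", ...)
  graphics::axis(1, at = seq_len(nrow(agg)), labels = agg$scenario)
  graphics::abline(h = stats::qnorm(1 - x$alpha), lty = 2)
  graphics::legend("topright", legend = c("NODF", "M"), pch = c(1, 19),
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
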