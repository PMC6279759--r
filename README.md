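# hostnet

Does the structure of an insect-by-host-plant interaction network carry
the signature of the diversification process that built it?  `hostnet`
implements the network–phylogenetic toolkit for that question: it
simulates binary butterfly–plant networks on a fixed guide phylogeny
under competing generative rules, and measures any binary bipartite
network with the statistics those rules discriminate.

Two hypothesised drivers of herbivore diversification make opposite
structural predictions.  **Adaptive radiation** — a lineage shifts
completely onto a novel host and radiates there — produces a **modular**
network: blocks of related insects tied to "their" host.  **Variability
in host use** — lineages keep a fundamental host repertoire wider than
the hosts they currently use and oscillate over it — produces a
**nested** network: specialists use subsets of the hosts of related
generalists.

The package provides:

* **Generative scenarios** on a 100-tip guide tree (five pairs of
  5-tip and 15-tip sister subclades): pure radiation `R5V0` through pure
  variability `R0V5`, a `random` 20%-fill control, and a `uniform`
  host-turnover scenario that isolates the effect of phylogenetically
  conserved repertoires (`simulate_network()`, `scenario_config()`).
* **Nestedness** by NODF, network-wide and within modules (`nodf()`,
  `nodf_within_module()`).
* **Bipartite (Barber) modularity**
  `M = (1/F) Σ_ij [a_ij − k_i d_j / F] δ(g_i, g_j)`, maximised by a
  seeded 10-run simulated-annealing optimiser with greedy polishing
  (`bipartite_modularity()`, `optimize_partition()`).
* **Degree-proportional null model** `p_ij = (k_i/m + d_j/n)/2` with
  add-one permutation p-values and the z-score
  `(X_obs − X_exp)/SD_exp` (`structure_test()`).
* **Taxon roles** from standardised within-module degree and
  among-module connectivity, with hub classification
  (`compute_roles()`).
* **Host-pair importance**: re-measure the network after deleting every
  pair of host taxa and standardise each pair against the rest
  (`pairwise_removal_scan()`, `removal_zscore()`).
* **Phylogenetic composition of modules** by root-inclusive Faith's PD
  against a size-preserving tip-label-shuffle null (`faith_pd()`,
  `module_pd_test()`).
* One-call orchestration: `analyze_network()` for a single matrix
  (delimited text via `read_network()`, matrix or edge-list dialect),
  `scenario_study()` for the full simulation experiment.

## Worked example

```r
library(hostnet)

st <- simulate_network("R5V0", seed = 1)   # pure radiation
st$network
#> Bipartite network: 100 insect taxa x 7 host taxa, 125 interactions (connectance 0.179)

an <- analyze_network(st$network, n_null_nodf = 100, n_null_m = 100, seed = 1)
an
#> 100 insects, 7 hosts, 125 interactions, connectance 0.1786
#> host-range histogram (hosts used : n insects):
#>  1  2
#> 75 25
#> NODF = 0 vs 100 degree-proportional nulls: mean 12.74, sd 1.98, z = -6.43
#>   p(upper) = 1, p(lower) = 0.009901
#> M = 0.768 vs 100 degree-proportional nulls: mean 0.4672, sd 0.0301, z = 9.99
#>   p(upper) = 0.009901, p(lower) = 1
#> verdict at alpha = 0.05: not nested, modular
```

The pure-radiation network is maximally un-nested (its specialists
share no hosts with each other, NODF = 0) and far more modular than the
degree-proportional expectation (z ≈ 10): the optimiser isolates each
radiating clade with its unique host.  Running the same pipeline on an
`"R0V5"` simulation flips both verdicts, and `"random"` yields neither.
`scenario_study()` tabulates this across all eight scenarios, with
per-replicate seeds recorded so any row can be regenerated exactly.

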