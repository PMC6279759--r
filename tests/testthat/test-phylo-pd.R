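test_that("newick parsing enforces the tree invariants", {
  tr <- parse_tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(length(tr$tip.label), 3)
  expect_equal(sum(tr$edge.length), 5)

  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  expect_equal(sum(parse_tree(f)$edge.length), 5)

  expect_warning(t0 <- parse_tree(text = "((A,B),C);"), "branch length")
  expect_true(all(t0$edge.length == 0))

  expect_error(parse_tree(text = "((A:1,A:1):1,C:2);"), "duplicate tip")
  expect_error(suppressWarnings(parse_tree(text = "((A:1,B:1:1,C:2);")))
})

test_that("Faith's PD sums the root-inclusive spanning subtree", {
  tr <- parse_tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(faith_pd(tr, c("A", "B", "C")), 5)
  expect_equal(faith_pd(tr, "A"), 2)          # tip branch + stem to root
  expect_equal(faith_pd(tr, c("A", "B")), 3)
  expect_equal(faith_pd(tr, c("A", "C")), 4)
  # crown-only variant drops the root path
  expect_equal(faith_pd(tr, c("A", "B"), include_root = FALSE), 2)
  expect_error(faith_pd(tr, "Z"), "unknown tip")
  expect_error(faith_pd(tr, character(0)), "empty")
})

test_that("PD agrees with picante on random subsets of the guide tree", {
  skip_if_not_installed("picante")
  withr::local_seed(17)
  gt <- build_guide_tree()
  tips <- gt$phylo$tip.label
  for (rep in 1:5) {
    s <- sample(tips, sample(2:30, 1))
    comm <- matrix(as.integer(tips %in% s), 1, dimnames = list("m", tips))
    expect_equal(faith_pd(gt$phylo, s),
                 picante::pd(comm, gt$phylo, include.root = TRUE)$PD)
  }
})

test_that("PD is monotone under adding tips", {
  withr::local_seed(18)
  gt <- build_guide_tree(n_pairs = 2, small = 3, large = 5)
  tips <- gt$phylo$tip.label
  s <- sample(tips, 3)
  base <- faith_pd(gt$phylo, s)
  for (extra in setdiff(tips, s))
    expect_gte(faith_pd(gt$phylo, c(s, extra)), base)
})

test_that("module PD test matches exhaustive enumeration on a 4-tip tree", {
  # two cherries: (A,B) sisters, (C,D) sisters, deep split
  tr <- parse_tree(text = "((A:1,B:1):5,(C:1,D:1):5);")
  a <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  dimnames(a) <- list(c("A", "B", "C", "D"), c("h1", "h2"))
  net <- bipartite_network(a)
  g <- setNames(c(0, 0, 1, 1, 0, 1), c("A", "B", "C", "D", "h1", "h2"))
  part <- as_module_partition(net, g)

  rep <- module_pd_test(net, part, insect_tree = tr, n_shuffles = 999,
                        seed = 3)
  ins <- rep[rep$guild == "insect", ]
  # exact null: of the C(4,2)=6 pairs, 2 are cherries with PD 7, 4 mix
  # clades with PD 12+...; observed cherry PD is the minimum, p = 2/6 exact
  expect_equal(ins$pd_raw, c(7, 7))
  exact_p <- 2 / 6
  expect_equal(ins$p_lower[1], exact_p, tolerance = 0.1)
  expect_equal(ins$p_lower[2], exact_p, tolerance = 0.1)

  # sister-tip module has lower PD (and lower p) than a clade-spanning one
  g2 <- setNames(c(0, 1, 0, 1, 0, 1), c("A", "B", "C", "D", "h1", "h2"))
  a2 <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  dimnames(a2) <- dimnames(a)
  net2 <- bipartite_network(a2)
  rep2 <- module_pd_test(net2, as_module_partition(net2, g2),
                         insect_tree = tr, n_shuffles = 999, seed = 3)
  ins2 <- rep2[rep2$guild == "insect", ]
  expect_true(all(ins$pd_raw < ins2$pd_raw))
  expect_true(all(ins$p_lower < ins2$p_lower))
})

test_that("saturated, single-taxon and absent-guild modules are handled", {
  gt <- build_guide_tree(n_pairs = 1, small = 2, large = 3)
  tips <- gt$phylo$tip.label
  a <- matrix(1L, 5, 3, dimnames = list(tips, c("x", "y", "z")))
  a[1, 2:3] <- 0L
  net <- bipartite_network(a)
  # module 0: all insects and host x; module 1: hosts y, z only
  g <- setNames(c(rep(0, 5), 0, 1, 1), c(tips, "x", "y", "z"))
  part <- as_module_partition(net, g)
  rep <- module_pd_test(net, part, insect_tree = gt$phylo,
                        n_shuffles = 99, seed = 1)
  ins <- rep[rep$guild == "insect", ]
  expect_equal(nrow(ins), 1)                   # no insects in module 1
  expect_equal(ins$pd_percent, 100)            # module holds the whole guild
  expect_equal(ins$p_lower, 1)

  # single-taxon module: PD reported, p not applicable
  g2 <- g; g2[tips[1]] <- 1
  rep2 <- module_pd_test(net, as_module_partition(net, g2),
                         insect_tree = gt$phylo, n_shuffles = 99, seed = 1)
  ins2 <- rep2[rep2$guild == "insect", ]
  single <- ins2[ins2$n_taxa == 1, ]
  expect_equal(nrow(single), 1)
  expect_gt(single$pd_raw, 0)
  expect_true(is.na(single$p_lower))

  expect_error(module_pd_test(net, part, insect_tree = ape::rtree(4)),
               "lacks tip")
})

test_that("label shuffles preserve module sizes and approximate picante's null", {
  skip_if_not_installed("picante")
  withr::local_seed(41)
  gt <- build_guide_tree(n_pairs = 2, small = 3, large = 5)
  tips <- gt$phylo$tip.label
  a <- random_filled_matrix(length(tips), 6, 0.3)
  dimnames(a) <- list(tips, paste0("h", 1:6))
  net <- bipartite_network(a)
  p <- optimize_partition(net, anneal_settings(seed = 2, n_runs = 3))
  rep <- module_pd_test(net, p, insect_tree = gt$phylo, n_shuffles = 499,
                        seed = 9)
  ins <- rep[rep$guild == "insect", ]
  expect_equal(sum(ins$n_taxa), length(tips))

  # cross-check the observed PDs against picante::ses.pd's observed column
  comm <- do.call(rbind, lapply(split(names(p$assignment[tips]),
                                      p$assignment[tips]), function(mm)
    as.integer(tips %in% mm)))
  colnames(comm) <- tips
  ses <- picante::ses.pd(comm, gt$phylo, null.model = "taxa.labels",
                         runs = 199, include.root = TRUE)
  expect_equal(ins$pd_raw[match(rownames(comm), ins$module)], ses$pd.obs)
})
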