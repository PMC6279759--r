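test_that("guide tree has the prescribed shape and is deterministic", {
  gt <- build_guide_tree()
  expect_equal(length(gt$phylo$tip.label), 100)
  expect_length(gt$pairs, 5)
  for (p in gt$pairs) {
    expect_length(p$low, 5)
    expect_length(p$high, 15)
    expect_true(ape::is.monophyletic(gt$phylo, p$low))
    expect_true(ape::is.monophyletic(gt$phylo, p$high))
  }
  expect_true(ape::is.ultrametric(gt$phylo))
  # subclades are pairwise disjoint and cover the tree
  all_tips <- unlist(lapply(gt$pairs, unlist), use.names = FALSE)
  expect_equal(sort(all_tips), sort(gt$phylo$tip.label))

  expect_identical(ape::write.tree(build_guide_tree()$phylo),
                   ape::write.tree(gt$phylo))

  small <- build_guide_tree(n_pairs = 1, small = 2, large = 3)
  expect_equal(length(small$phylo$tip.label), 5)
  expect_length(small$pairs, 1)
})

test_that("pure radiation yields the deterministic block network", {
  st <- simulate_network("R5V0", seed = 1)
  a <- st$network$adjacency
  expect_equal(ncol(a), 7)                       # 2 ancestral + 5 unique
  expect_equal(sum(a), 125)                      # 5 * (5*2 + 15*1)
  for (p in st$tree$pairs) {
    # low-diversity tips: exactly the two global ancestral hosts
    expect_true(all(a[p$low, c("h01", "h02")] == 1))
    expect_equal(unname(rowSums(a[p$low, ])), rep(2, 5))
    # high-diversity tips: one host, shared within the clade, unique to it
    expect_equal(unname(rowSums(a[p$high, ])), rep(1, 15))
    host <- names(which(colSums(a[p$high, , drop = FALSE]) > 0))
    expect_length(host, 1)
    expect_equal(sum(a[, host]), 15)             # used by no one else
  }
  # fully deterministic: independent of seed
  expect_identical(simulate_network("R5V0", seed = 999)$network$adjacency, a)
})

test_that("variability rules give degree-2 low clades and exact 80% removal", {
  st <- simulate_network("R0V5", seed = 3)
  a <- st$network$adjacency
  for (p in st$tree$pairs) {
    expect_equal(unname(rowSums(a[p$low, ])), rep(2, 5))
    # low tips draw from the shared ancestral ten
    expect_true(all(a[p$low, setdiff(colnames(a), sprintf("h%02d", 1:10))] == 0))
    # high clade keeps exactly 20 * 15 - 240 = 60 interactions
    expect_equal(sum(a[p$high, ]), 15 * 20 - floor(0.8 * 15 * 20))
    # high-clade fundamental repertoire is ancestral ten plus ten more
    reps <- unique(st$fundamental_repertoires[p$high])
    expect_length(reps, 1)
    expect_length(reps[[1]], 20)
    expect_true(all(sprintf("h%02d", 1:10) %in% reps[[1]]))
  }
})

test_that("every realised interaction lies within the fundamental repertoire", {
  for (tag in c("R5V0", "R2V3", "R0V5", "random", "uniform")) {
    st <- simulate_network(tag, seed = 17)
    a <- st$network$adjacency
    for (tip in rownames(a)) {
      used <- colnames(a)[a[tip, ] == 1]
      expect_true(all(used %in% st$fundamental_repertoires[[tip]]),
                  info = paste(tag, tip))
    }
    expect_setequal(rownames(a), st$tree$phylo$tip.label)
  }
})

test_that("simulations are reproducible from their seed", {
  for (tag in c("R3V2", "random", "uniform")) {
    a1 <- simulate_network(tag, seed = 21)$network$adjacency
    a2 <- simulate_network(tag, seed = 21)$network$adjacency
    expect_identical(a1, a2, info = tag)
    a3 <- simulate_network(tag, seed = 22)$network$adjacency
    expect_false(identical(a1, a3), info = tag)
  }
})

test_that("random scenario realises the exact interaction count", {
  st <- simulate_random(seed = 9)
  expect_equal(n_interactions(st$network), 800)  # 0.2 * 100 * 40
  expect_equal(nrow(st$network$adjacency), 100)

  sat <- simulate_random(6, 5, fill = 1, seed = 1)
  expect_equal(summary(sat$network)$connectance, 1)
})

test_that("random host ranges follow a binomial distribution across replicates", {
  degs <- unlist(lapply(1:30, function(i)
    rowSums(simulate_random(seed = 300 + i)$network$adjacency)))
  expect_equal(mean(degs), 40 * 0.2, tolerance = 0.02)
  # chi-square of pooled histogram against Binomial(40, 0.2)
  ks <- 0:40
  expected <- dbinom(ks, 40, 0.2) * length(degs)
  obs <- tabulate(degs + 1L, nbins = 41)
  keep <- expected > 5
  stat <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_lt(stat, qchisq(0.999, df = sum(keep) - 1))
})

test_that("uniform evolution keeps repertoire size constant and pair-identical", {
  st <- simulate_network("uniform", seed = 5)
  sizes <- lengths(st$fundamental_repertoires)
  expect_true(all(sizes == sizes[1]))
  expect_equal(unname(sizes[1]), 10)
  for (p in st$tree$pairs) {
    reps <- unique(st$fundamental_repertoires[c(p$low, p$high)])
    expect_length(reps, 1)
  }
  expect_equal(n_interactions(st$network), round(0.2 * 100 * 10))
})

test_that("closer pairs share more fundamental hosts than distant ones", {
  # averaged over seeds: sister pairs (1,2) overlap more than pairs (1,5)
  ov <- function(st, i, j) {
    ri <- st$fundamental_repertoires[[st$tree$pairs[[i]]$low[1]]]
    rj <- st$fundamental_repertoires[[st$tree$pairs[[j]]$low[1]]]
    length(intersect(ri, rj))
  }
  sis <- far <- numeric(20)
  for (s in 1:20) {
    st <- simulate_network("uniform", seed = 400 + s)
    sis[s] <- ov(st, 1, 2)
    far[s] <- ov(st, 1, 5)
  }
  expect_gt(mean(sis), mean(far))
})

test_that("zero turnover collapses to a shared-repertoire random fill", {
  cfg <- scenario_config(turnover = 0, seed = 2)
  st <- simulate_uniform_evolution(cfg)
  reps <- unique(st$fundamental_repertoires)
  expect_length(reps, 1)
  expect_setequal(reps[[1]], sprintf("h%02d", 1:10))
})

test_that("impossible configurations raise capacity errors", {
  expect_error(scenario_config(ancestral_fundamental = 35,
                               expansion_per_pair = 10),
               "exceeds the host pool")
  cfg <- scenario_config(turnover = 31, seed = 1)
  expect_error(simulate_uniform_evolution(cfg), "exhausted")
  expect_error(simulate_network("R9V9", seed = 1), "unknown scenario|needs")
  expect_error(simulate_network("banana", seed = 1), "unknown scenario")
})

test_that("a simulated study writes and regenerates byte-identically", {
  st <- simulate_network("R3V2", seed = 7)
  dir <- withr::local_tempdir()
  f1 <- write_study(st, file.path(dir, "a"))
  st2 <- simulate_network("R3V2", seed = 7)
  f2 <- write_study(st2, file.path(dir, "b"))
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]), info = k)
  back <- read_network(f1[["network"]], "matrix")
  expect_identical(back$adjacency, st$network$adjacency)
})
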