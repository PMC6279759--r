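test_that("constructor validates shapes, labels and binary cells", {
  a <- matrix(c(1, 0, 0, 1), 2, 2)
  net <- bipartite_network(a)
  expect_s3_class(net, "bipartite_network")
  expect_equal(n_interactions(net), 2)

  expect_error(bipartite_network(matrix(c(1, 2, 0, 1), 2, 2)), "non-binary")
  expect_error(bipartite_network(matrix(c(1, NA, 0, 1), 2, 2)), "non-binary")
  b <- matrix(1, 2, 2, dimnames = list(c("x", "x"), c("h1", "h2")))
  expect_error(bipartite_network(b), "duplicate insect")
})

test_that("matrix and edge-list files round-trip bit-identically", {
  withr::local_seed(7)
  a <- random_filled_matrix(9, 6)
  dimnames(a) <- list(paste0("gen", 1:9), paste0("ord", 1:6))
  net <- bipartite_network(a)
  for (dialect in c("matrix", "edge_list")) {
    f <- withr::local_tempfile(fileext = ".tsv")
    write_network(net, f, dialect = dialect)
    back <- read_network(f, dialect = dialect)
    # edge-list order follows first appearance; compare on common label order
    expect_setequal(back$insect_labels, net$insect_labels)
    expect_setequal(back$host_labels, net$host_labels)
    expect_identical(back$adjacency[net$insect_labels, net$host_labels],
                     net$adjacency)
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_network(back, f2, dialect = dialect)
    back2 <- read_network(f2, dialect = dialect)
    expect_identical(back2$adjacency, back$adjacency)
  }
})

test_that("edge lists collapse duplicate interactions", {
  net <- edge_list_network(c("A", "A", "B"), c("p1", "p1", "p2"))
  expect_equal(n_interactions(net), 2)
  f <- withr::local_tempfile()
  writeLines(c("A\tp1", "A\tp1", "B\tp2"), f)
  expect_equal(n_interactions(read_network(f, "edge_list")), 2)
})

test_that("reading a matrix with a non-binary cell fails, naming the cell", {
  f <- withr::local_tempfile()
  writeLines(c("\th1\th2", "i1\t1\t0", "i2\t2\t1"), f)
  expect_error(read_network(f, "matrix"), "i2.*h1")
})

test_that("remove_hosts deletes columns, optionally pruning emptied rows", {
  a <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 1))
  dimnames(a) <- list(c("specialist", "mid", "gen"), c("hA", "hB", "hC"))
  net <- bipartite_network(a)

  expect_identical(remove_hosts(net, character(0))$adjacency, net$adjacency)
  expect_equal(ncol(remove_hosts(net, c("hA", "hB"))$adjacency), 1)
  expect_error(remove_hosts(net, "nope"), "unknown host")

  # 'specialist' only uses hA: pruning after removing hA drops that row
  pruned <- remove_hosts(net, "hA", prune_empty = TRUE)
  expect_false("specialist" %in% pruned$insect_labels)
  kept <- remove_hosts(net, "hA", prune_empty = FALSE)
  expect_true("specialist" %in% kept$insect_labels)
  # the input is untouched
  expect_equal(ncol(net$adjacency), 3)
})

test_that("sequential removals compose like removing the union", {
  withr::local_seed(42)
  for (rep in 1:5) {
    a <- random_filled_matrix(8, 7)
    net <- bipartite_network(a)
    S <- sample(net$host_labels, 2)
    T2 <- sample(setdiff(net$host_labels, S), 2)
    step <- remove_hosts(remove_hosts(net, S), T2)
    once <- remove_hosts(net, c(S, T2))
    expect_identical(step$adjacency, once$adjacency)
  }
})

test_that("summary reports connectance and a consistent host-range histogram", {
  withr::local_seed(1)
  st <- simulate_random(100, 40, 0.2, seed = 5)
  s <- summary(st$network)
  expect_equal(s$n_interactions, 800)
  expect_equal(s$connectance, 800 / (100 * 40))
  expect_equal(sum(s$host_range_histogram), s$n_insects)

  # empty network: all mass at degree 0
  empty <- bipartite_network(matrix(0L, 3, 2))
  se <- summary(empty)
  expect_equal(se$connectance, 0)
  expect_equal(se$host_range_histogram, c("0" = 3L))

  # constant-degree network
  cd <- mk_net(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  expect_equal(summary(cd)$host_range_histogram, c("2" = 3L))

  # n_interactions always recomputable from the adjacency
  for (rep in 1:5) {
    a <- random_filled_matrix(6, 5)
    expect_equal(summary(bipartite_network(a))$n_interactions, sum(a))
  }
})

test_that("the bundled synthetic example file loads as documented", {
  f <- system.file("extdata", "synthetic_example_matrix.tsv",
                   package = "hostnet")
  net <- read_network(f, "matrix")
  expect_equal(dim(net$adjacency), c(12, 5))
  expect_equal(net$host_labels[1], "Rosales")
  expect_equal(n_interactions(net), sum(net$adjacency))
})

test_that("prune_network keeps exactly the interacting taxa", {
  a <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  net <- bipartite_network(a)
  p <- prune_network(net)
  expect_equal(dim(p$adjacency), c(2, 2))
  expect_equal(n_interactions(p), n_interactions(net))
})
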