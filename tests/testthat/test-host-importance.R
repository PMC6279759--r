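test_that("the scan enumerates every unordered host pair exactly once", {
  withr::local_seed(21)
  net <- bipartite_network(random_filled_matrix(8, 4, 0.5))
  scan <- pairwise_removal_scan(net, "NODF")
  expect_equal(scan$n_pairs, choose(4, 2))
  key <- apply(scan$rows[, 1:2], 1, function(r) paste(sort(r), collapse = "|"))
  expect_equal(anyDuplicated(key), 0)

  # a 34-host network yields the 561 pairs of the pierid-sized scan
  big <- simulate_random(40, 34, 0.25, seed = 2)$network
  scan34 <- pairwise_removal_scan(big, "NODF")
  expect_equal(scan34$n_pairs, 561)
  expect_equal(scan34$n_computable + scan34$n_degenerate, 561)

  expect_error(pairwise_removal_scan(
    bipartite_network(matrix(1L, 3, 2)), "NODF"), "at least 3")
})

test_that("scan values are independent of host order", {
  withr::local_seed(22)
  a <- random_filled_matrix(7, 5, 0.5)
  dimnames(a) <- list(paste0("i", 1:7), paste0("host", 1:5))
  net <- bipartite_network(a)
  scan <- pairwise_removal_scan(net, "NODF")
  perm <- sample(ncol(a))
  scan_p <- pairwise_removal_scan(
    bipartite_network(a[, perm, drop = FALSE]), "NODF")
  key <- function(s) {
    k <- apply(s$rows[, 1:2], 1, function(r) paste(sort(r), collapse = "|"))
    setNames(s$rows$value, k)
  }
  v1 <- key(scan); v2 <- key(scan_p)
  expect_equal(v2[names(v1)], v1)
})

test_that("removal z-scores standardise against all other pairs", {
  scan <- structure(list(
    metric_name = "NODF",
    rows = data.frame(host_a = c("A", "B", "C", "D", "E", "F", "G"),
                      host_b = letters[1:7],
                      value = c(1, 3, 3, 3, 5, 5, 5)),
    n_pairs = 7, n_computable = 7, n_degenerate = 0),
    class = "removal_scan")
  z <- removal_zscore(scan, c("A", "a"))
  expect_equal(z, (1 - 4) / sd(c(3, 3, 3, 5, 5, 5)))
  expect_equal(removal_pvalue(scan, c("A", "a"), "lower"), 1 / 7)

  same <- scan
  same$rows$value <- rep(2, 7)
  expect_warning(zz <- removal_zscore(same, c("A", "a")), "undefined")
  expect_true(is.na(zz))
})

test_that("leave-one-out z-scores centre near zero across the scan", {
  withr::local_seed(25)
  net <- bipartite_network(random_filled_matrix(12, 8, 0.4))
  tab <- removal_table(pairwise_removal_scan(net, "NODF"))
  expect_lt(abs(mean(tab$z, na.rm = TRUE)), 0.05)
  # p reproducible from the stored scan without recomputation
  scan <- pairwise_removal_scan(net, "NODF")
  pair <- c(tab$host_a[1], tab$host_b[1])
  expect_equal(removal_pvalue(scan, pair), tab$p[1])
})

test_that("removing redundant hosts can leave a perfectly nested remainder at 100", {
  # staircase with fills 6,4,2,1; deleting hosts 4 and 6 keeps the fills
  # strictly decreasing (4,3,2,1) so the remainder is still perfectly nested
  a <- rbind(c(1, 1, 1, 1, 1, 1), c(1, 1, 1, 1, 0, 0),
             c(1, 1, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0))
  net <- bipartite_network(a)
  expect_lt(nodf(net)$nodf_total, 100)  # tied column fills score 0
  scan <- pairwise_removal_scan(net, "NODF")
  ix <- hostnet:::scan_pair_index(scan, c(net$host_labels[4], net$host_labels[6]))
  expect_equal(scan$rows$value[ix], 100)
})

test_that("a planted generalist host pair attains the minimum removal z", {
  # two ancestral generalists h1,h2 used by everyone create the nestedness;
  # the other hosts are clade-specific specialists
  n <- 24
  a <- cbind(rep(1L, n), rep(1L, n), matrix(0L, n, 6))
  for (b in 1:6) a[(4 * b - 3):(4 * b), 2 + b] <- 1L
  net <- bipartite_network(a)
  scan <- pairwise_removal_scan(net, "NODF")
  tab <- removal_table(scan)
  focal <- sort(c(net$host_labels[1], net$host_labels[2]))
  expect_equal(sort(c(tab$host_a[1], tab$host_b[1])), focal)
  expect_equal(min(tab$z, na.rm = TRUE),
               removal_zscore(scan, focal))
  expect_lt(removal_zscore(scan, focal), 0)
})

test_that("degenerate removals are excluded but counted", {
  # 3 hosts; removing the two that support everyone leaves one column
  a <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1))
  net <- bipartite_network(a)
  scan <- pairwise_removal_scan(net, "NODF")
  expect_equal(scan$n_pairs, 3)
  expect_gte(scan$n_degenerate, 1)
  expect_equal(scan$n_computable + scan$n_degenerate, 3)
})

test_that("modularity scans are reproducible through the seed schedule", {
  withr::local_seed(29)
  big <- matrix(0L, 8, 6)
  big[1:4, 1:3] <- 1L; big[5:8, 4:6] <- 1L
  net <- bipartite_network(big)
  s <- anneal_settings(n_runs = 2)
  scan1 <- pairwise_removal_scan(net, "M", settings = s, seed = 5)
  scan2 <- pairwise_removal_scan(net, "M", settings = s, seed = 5)
  expect_equal(scan1$rows$value, scan2$rows$value)
})
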