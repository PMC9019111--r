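test_that("pairwise Hamming distances are exact and match a naive oracle", {
  g <- cbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L))
  expect_equal(unname(pairwise_hamming(toy_haps(g))[1, 2]), 0L)
  g2 <- cbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L))
  expect_equal(unname(pairwise_hamming(toy_haps(g2))[1, 2]), 2L)
  set.seed(12)
  for (rep in 1:10) {
    g3 <- matrix(rbinom(30 * 8, 1, 0.4), 30, 8)
    d <- pairwise_hamming(toy_haps(g3))
    expect_equal(unname(d), hamming_oracle(g3), ignore_attr = TRUE)
    expect_true(all(d == t(d)))
    expect_true(all(diag(d) == 0L))
  }
})

test_that("window and biallelic filters restrict the sites used", {
  g <- rbind(c(0L, 1L), c(0L, 2L), c(0L, 1L))
  h <- haplotype_matrix(
    g, data.frame(chrom = "chr", pos = c(10L, 20L, 30L), ref = "A",
                  alts = c("T", "T,G", "T")),
    data.frame(hap_id = c("h1", "h2"), sample_id = "s1",
               population = "p", species = "sp", year = 2000))
  d <- pairwise_hamming(h)             # multi-allelic site 2 dropped
  expect_equal(unname(d[1, 2]), 2L)
  d2 <- pairwise_hamming(h, window = c(1, 15))
  expect_equal(unname(d2[1, 2]), 1L)
  d3 <- pairwise_hamming(h, biallelic_only = FALSE)
  expect_equal(unname(d3[1, 2]), 3L)
})

test_that("hierarchical grouping separates distant blocks and labels by focal content", {
  # all identical: one group
  h <- toy_haps(matrix(0L, 10, 6))
  lab <- hierarchical_groups(pairwise_hamming(h),
                             list(F = rep(TRUE, 6)), cut_height = 5)
  expect_equal(unname(lab), rep("F1", 6), ignore_attr = TRUE)

  # two internally identical blocks 50 SNPs apart, cut at 5: two groups
  g <- cbind(matrix(0L, 50, 5), matrix(1L, 50, 5))
  focal <- list(F = c(rep(TRUE, 5), rep(FALSE, 5)),
                S = c(rep(FALSE, 5), rep(TRUE, 5)))
  lab2 <- hierarchical_groups(pairwise_hamming(toy_haps(g)), focal,
                              cut_height = 5)
  expect_equal(unname(lab2), c(rep("F1", 5), rep("S1", 5)),
               ignore_attr = TRUE)
  expect_error(hierarchical_groups(pairwise_hamming(toy_haps(g)), focal,
                                   cut_height = -1), "cut_height")
})

test_that("group labels go only to focal carriers; small clusters fall back to OR/wt", {
  g <- cbind(matrix(0L, 20, 6), matrix(1L, 20, 2))
  # cluster 1 holds 4 F carriers + 2 non-carriers; cluster 2 is 2 S carriers
  focal <- list(F = c(rep(TRUE, 4), rep(FALSE, 4)),
                S = c(rep(FALSE, 6), TRUE, TRUE))
  lab <- hierarchical_groups(pairwise_hamming(toy_haps(g)), focal,
                             cut_height = 2, min_group_size = 3)
  expect_equal(unname(lab), c(rep("F1", 4), "wt", "wt", "OR", "OR"),
               ignore_attr = TRUE)
})

test_that("median-joining network infers the Steiner median of a star triple", {
  h <- toy_haps(matrix(c(0, 0, 0, 0, 1, 1, 1, 1, 0), nrow = 3))
  net <- median_joining_network(h)
  expect_equal(nrow(net$nodes), 4L)
  med <- net$nodes[!net$nodes$observed, ]
  expect_equal(med$seq, "010")
  expect_equal(med$multiplicity, 0L)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$dist == 1L))
  # total length 3 < the 4 of the MST on observed nodes alone
  expect_equal(sum(net$edges$dist), 3)
})

test_that("edge pruning at the maximum edge distance splits components", {
  g <- matrix(c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 0), nrow = 4)
  net <- median_joining_network(toy_haps(g), max_edge_dist = 2L)
  comp <- net$nodes$component[match(c("0000", "0001", "1110"),
                                    net$nodes$seq)]
  expect_equal(comp[1], comp[2])
  expect_false(comp[1] == comp[3])
  # with no pruning the network stays connected
  net_inf <- median_joining_network(toy_haps(g), max_edge_dist = Inf)
  expect_equal(length(unique(net_inf$nodes$component)), 1L)
})

test_that("single haplotype gives a single node and no edges; multi-allelic errors", {
  h <- toy_haps(matrix(c(0L, 1L, 0L), 3, 1))
  net <- median_joining_network(h)
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(nrow(net$edges), 0L)
  h2 <- haplotype_matrix(
    matrix(c(0L, 2L), 1, 2),
    data.frame(chrom = "chr", pos = 5L, ref = "A", alts = "T,G"),
    data.frame(hap_id = c("a", "b"), sample_id = "s",
               population = "p", species = "sp", year = 2000))
  expect_error(median_joining_network(h2), "biallelic")
})

test_that("without homoplasy the network spans all observed haplotypes as a tree", {
  # unique-site mutations along a radiating genealogy
  set.seed(8)
  for (rep in 1:5) {
    n_sites <- 12
    haps <- list(rep(0L, n_sites))
    for (s in seq_len(n_sites)) {
      parent <- haps[[sample(length(haps), 1)]]
      child <- parent
      child[s] <- 1L          # each site mutates exactly once
      haps[[length(haps) + 1L]] <- child
    }
    g <- do.call(cbind, haps)
    net <- median_joining_network(toy_haps(g), max_edge_dist = Inf)
    n_nodes <- nrow(net$nodes)
    expect_equal(length(unique(net$nodes$component)), 1L)
    expect_equal(nrow(net$edges), n_nodes - 1L)   # tree
    expect_true(all(table(net$membership) >= 1))
  }
})

test_that("network components are invariant to haplotype input order", {
  set.seed(40)
  g <- matrix(rbinom(15 * 10, 1, 0.3), 15, 10)
  h <- toy_haps(g)
  net1 <- median_joining_network(h, max_edge_dist = 2L)
  perm <- sample(10)
  net2 <- median_joining_network(toy_haps(g[, perm]), max_edge_dist = 2L)
  # same node sequences in the same components up to component renaming
  m1 <- split(net1$nodes$seq, net1$nodes$component)
  m2 <- split(net2$nodes$seq, net2$nodes$component)
  norm <- function(m) sort(vapply(m, function(x)
    paste(sort(x), collapse = "|"), character(1)))
  expect_equal(unname(norm(m1)), unname(norm(m2)))
})

test_that("median nodes never lengthen the spanning structure", {
  set.seed(9)
  for (rep in 1:5) {
    g <- matrix(rbinom(10 * 7, 1, 0.4), 10, 7)
    h <- toy_haps(g)
    net <- median_joining_network(h, max_edge_dist = Inf)
    node_mat <- vapply(strsplit(net$nodes$seq, ""), as.integer,
                       integer(nchar(net$nodes$seq[1])))
    d_all <- kdrhap:::.hamming_mat(node_mat)
    d_obs <- kdrhap:::.hamming_mat(g[, !duplicated(t(g)), drop = FALSE])
    expect_lte(kdrhap:::.mst_length(d_all), kdrhap:::.mst_length(d_obs))
  }
})

test_that("non-synonymous edges are flagged with their codon changes", {
  ref <- toy_reference("ATGCTTTAA", offset = 100L)
  m <- gene_model("tx", "chr", "+", data.frame(start = 101, end = 109))
  # sites: intronic at 50, missense C>T at 104
  g <- rbind(c(0L, 1L, 0L), c(0L, 0L, 1L))
  h <- toy_haps(g, pos = c(50L, 104L))
  h$sites$ref <- c("A", "C"); h$sites$alts <- c("T", "T")
  eff <- annotate_all_sites(h, m, ref)
  net <- median_joining_network(h, max_edge_dist = Inf)
  net <- annotate_nonsynonymous_edges(net, eff)
  for (k in seq_len(nrow(net$edges))) {
    sites <- net$edges$sites[[k]]
    if (2L %in% sites) {
      expect_true(net$edges$nonsyn[k])
      expect_match(net$edges$codon_changes[k], "L2F")
    } else {
      expect_false(net$edges$nonsyn[k])
    }
  }
})

test_that("concordance uses the best one-to-one label matching", {
  a <- c(rep("F1", 5), rep("S1", 5))
  expect_equal(as.numeric(concordance(a, a)), 1)
  b <- c(rep("grp7", 5), rep("grp2", 5))    # pure relabelling
  expect_equal(as.numeric(concordance(a, b)), 1)
  # constructed confusion: 90 of 100 co-assigned under the best matching
  a2 <- c(rep("x", 50), rep("y", 50))
  b2 <- c(rep("q", 45), rep("r", 55))
  expect_equal(as.numeric(concordance(a2, b2)), 0.95)
  a3 <- rep(c("x", "y"), each = 50)
  b3 <- c(rep("q", 40), rep("r", 10), rep("r", 40), rep("q", 10))
  expect_equal(as.numeric(concordance(a3, b3)), 0.8)
})

test_that("the Hungarian matching solves small assignment problems exactly", {
  cost <- rbind(c(4, 1, 3), c(2, 0, 5), c(3, 2, 2))
  assign <- kdrhap:::.hungarian(cost)
  best <- Inf
  for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1)))
    best <- min(best, sum(cost[cbind(1:3, p)]))
  expect_equal(sum(cost[cbind(1:3, assign)]), best)
  set.seed(2)
  for (rep in 1:10) {
    cost <- matrix(sample(0:9, 16, replace = TRUE), 4, 4)
    assign <- kdrhap:::.hungarian(cost)
    perms <- expand.grid(rep(list(1:4), 4))
    perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
    best <- min(apply(perms, 1, function(p) sum(cost[cbind(1:4, p)])))
    expect_equal(sum(cost[cbind(1:4, assign)]), best)
  }
})

test_that("population group tables cross-tabulate labels", {
  labels <- c("F1", "F1", "wt", "S1")
  pops <- c("p1", "p1", "p1", "p2")
  tab <- population_group_table(labels, pops)
  expect_equal(unname(tab$counts["p1", "F1"]), 2)
  expect_equal(unname(rowSums(tab$freq)), c(1, 1))
})
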