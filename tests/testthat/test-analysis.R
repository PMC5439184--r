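test_that("Fisher's discriminant ratio matches hand-computed cases", {
  # classes {1,2} vs {3,4}: between-class scatter 2, within-class 1
  expect_equal(fisher_discriminant_ratio(c(1, 2, 3, 4), c("a", "a", "b", "b")),
               2)
  # identical class means give zero
  expect_equal(fisher_discriminant_ratio(c(1, 3, 1, 3), c("a", "a", "b", "b")),
               0)
  # zero within-class scatter with separation: large sentinel
  expect_equal(fisher_discriminant_ratio(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               1e6)
  # degenerate: all identical
  expect_equal(fisher_discriminant_ratio(rep(2, 4), c("a", "a", "b", "b")), 0)
  expect_error(fisher_discriminant_ratio(1:4, rep("a", 4)), "two classes")
  expect_error(fisher_discriminant_ratio(1:4, factor(c("a","a","b","b"),
                                                     levels = c("a","b","c"))),
               "nonempty")
})

test_that("FDR is shift-invariant and scales as a ratio", {
  set.seed(1)
  counts <- c(rnorm(5, 10), rnorm(5, 14))
  labels <- rep(c("I", "II"), each = 5)
  j0 <- fisher_discriminant_ratio(counts, labels)
  expect_equal(fisher_discriminant_ratio(counts + 7, labels), j0)
  expect_equal(fisher_discriminant_ratio(counts * 3, labels), j0)
})

test_that("true labels beat label permutations on separable counts", {
  set.seed(42)
  counts <- c(rnorm(10, 20, 1), rnorm(10, 30, 1))
  labels <- rep(c("I", "II"), each = 10)
  j_true <- fisher_discriminant_ratio(counts, labels)
  j_perm <- vapply(1:200, function(k) {
    fisher_discriminant_ratio(counts, sample(labels))
  }, 0)
  expect_gt(j_true, quantile(j_perm, 0.99))
})

test_that("network FDR sums per-bin values and ranks neurons deterministically", {
  set.seed(3)
  mk <- function(rate) {
    n <- rpois(1, rate * 20)
    spike_record(sample.int(4, n, replace = TRUE), sort(runif(n, 0, 1)),
                 n_neurons = 4, duration = 1, dt = 2e-4)
  }
  recs <- c(lapply(1:2, function(i) mk(40)), lapply(1:4, function(i) mk(10)))
  fdr <- network_fdr(recs, class1 = 1:2, bin = 0.1)
  expect_equal(fdr$network_fdr, sum(fdr$per_bin))
  expect_true(all(fdr$per_bin >= 0))
  expect_length(fdr$neuronal, 4)

  rk <- neuronal_fdr_ranking(fdr)
  expect_setequal(rk, 1:4)
  # ties broken by neuron index: identical FDRs keep index order
  fdr2 <- fdr; fdr2$neuronal <- rep(1, 4)
  expect_equal(neuronal_fdr_ranking(fdr2), 1:4)

  # identical responses for every stimulus give all-zero FDRs
  rec0 <- spike_record(c(1L, 2L), c(0.1, 0.5), 4, 1, 2e-4)
  same <- list(rec0, rec0, rec0)
  f0 <- network_fdr(same, class1 = 1, bin = 0.25)
  expect_true(all(f0$per_bin == 0))
  expect_equal(f0$network_fdr, 0)

  expect_error(network_fdr(same, 1, bin = 5), "bin")
})

test_that("subnetwork extraction applies the weight-change threshold", {
  net <- build_network(network_config(dims = c(4, 4, 2), seed = 5))
  w0 <- net$synapses$weight
  w1 <- w0
  w1[1] <- w0[1] + 2e-8
  w1[2] <- w0[2] - 2e-8
  w1[3] <- w0[3] + 5e-9
  sub <- extract_subnetwork(net, w0, w1, threshold = 1e-8)
  expect_equal(sub$potentiated, 1L)
  expect_equal(sub$depressed, 2L)
  # node classification partitions the node set
  expect_equal(sum(sub$node_class == "pre_only") +
               sum(sub$node_class == "post_only") +
               sum(sub$node_class == "both"), length(sub$nodes))
  expect_setequal(sub$nodes, c(net$synapses$pre[1], net$synapses$post[1]))

  # no learning: both sets empty
  sub0 <- extract_subnetwork(net, w0, w0)
  expect_length(sub0$potentiated, 0)
  expect_length(sub0$depressed, 0)

  expect_error(extract_subnetwork(net, w0[-1], w1), "match")
})

test_that("clustering coefficient matches closed forms and G(n,p)", {
  triangle <- cbind(c(1, 2, 3), c(2, 3, 1))
  expect_equal(clustering_coefficient(triangle), 1)
  star <- cbind(c(1, 1, 1), c(2, 3, 4))
  expect_equal(clustering_coefficient(star), 0)
  expect_error(clustering_coefficient(cbind(integer(0), integer(0))), "empty")

  # Erdos-Renyi: mean local clustering approaches p
  set.seed(7)
  p <- 0.2; n <- 80
  cc <- vapply(1:10, function(k) {
    adj <- matrix(runif(n * n) < p, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    clustering_coefficient(which(adj, arr.ind = TRUE))
  }, 0)
  expect_equal(mean(cc), p, tolerance = 0.15)
})

test_that("critical-neuron overlap counts and chance expectation agree with resampling", {
  sub <- structure(list(nodes = 1:40,
                        node_class = rep(c("pre_only", "post_only", "both"),
                                         length.out = 40)),
                   class = "subnetwork_graph")
  ranking <- 1:200
  ov <- critical_neuron_overlap(ranking, sub, k = 50, n_neurons = 200)
  expect_equal(ov$overlap, 40)            # all subnetwork nodes in the top 50
  expect_equal(ov$chance, 50 * 40 / 200)

  # chance expectation equals the mean overlap of random draws
  set.seed(9)
  draws <- vapply(1:2000, function(i) {
    sum(sample.int(200, 50) %in% sub$nodes)
  }, 0)
  expect_equal(mean(draws), ov$chance, tolerance = 0.05)

  # disjoint sets give zero
  sub2 <- structure(list(nodes = 300:310, node_class = rep("both", 11)),
                    class = "subnetwork_graph")
  expect_equal(critical_neuron_overlap(ranking, sub2, k = 50,
                                       n_neurons = 400)$overlap, 0)
  expect_error(critical_neuron_overlap(1:10, sub, k = 50), "exceeds")
})

test_that("subnetworks export as GraphML", {
  sub <- structure(list(edges = data.frame(pre = c(1, 2), post = c(2, 3),
                                           dw = c(2e-8, 3e-8))),
                   class = "subnetwork_graph")
  f <- tempfile(fileext = ".graphml")
  export_graphml(sub, f)
  expect_true(file.exists(f))
  expect_gt(file.info(f)$size, 0)
  unlink(f)
})
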