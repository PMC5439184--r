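#' Fisher's discriminant ratio on spike counts
#'
#' Between-class scatter over within-class scatter,
#' \deqn{J = \sum_C (\mu_C - \mu)^2 / \sum_C \sum_{i \in C} (S_i - \mu_C)^2,}
#' where \eqn{\mu} is the mean of the class means. Larger J means better
#' discrimination. When the within-class scatter is zero but the
#' between-class scatter is positive, a large sentinel value (1e6) is
#' returned; when both are zero, J = 0.
#'
#' @param counts numeric vector of spike counts (one per trial/stimulus)
#' @param labels class labels (>= 2 classes, each nonempty)
#' @return J (non-negative)
#' @export
fisher_discriminant_ratio <- function(counts, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("at least two classes are required")
  if (any(tabulate(labels, nbins = nlevels(labels)) == 0))
    stop("every class must be nonempty")
  mu_c <- tapply(counts, labels, mean)
  mu <- mean(mu_c)
  between <- sum((mu_c - mu)^2)
  within <- sum((counts - mu_c[labels])^2)
  if (within == 0) {
    if (between == 0) 0 else 1e6
  } else {
    between / within
  }
}

#' Network and neuronal FDR for a set of stimulus responses
#'
#' Network FDR: population spike counts are binned (default 10 ms); the
#' FDR between the designated class and the rest is computed per bin and
#' summed over bins. Neuronal FDR: for each neuron, the FDR of its total
#' spike count over the whole recording across stimuli. Bins where both
#' scatters vanish contribute 0.
#'
#' @param records list of \code{spike_record}s, one per stimulus, on a
#'   common time grid
#' @param class1 indices of the stimuli forming class I (e.g. the familiar
#'   stimulus); the rest form class II
#' @param bin time bin (s)
#' @return object of class \code{fdr_result}: \code{per_bin},
#'   \code{network_fdr} (sum over bins), \code{neuronal} (per-neuron FDR),
#'   \code{class1}
#' @export
network_fdr <- function(records, class1, bin = 0.010) {
  n <- length(records)
  durs <- vapply(records, function(r) r$duration, 0)
  if (max(durs) - min(durs) > 1e-9) stop("records must share a common time grid")
  if (bin > durs[1]) stop("bin larger than the record")
  labels <- factor(ifelse(seq_len(n) %in% class1, "I", "II"),
                   levels = c("I", "II"))
  counts <- vapply(records, binned_counts, numeric(ceiling(durs[1] / bin - 1e-9)),
                   bin = bin)
  # counts: bins x stimuli
  per_bin <- apply(counts, 1, function(s) {
    if (all(s == s[1])) 0 else fisher_discriminant_ratio(s, labels)
  })
  nn <- records[[1]]$n_neurons
  neuron_counts <- vapply(records, spike_counts, numeric(nn))
  neuronal <- apply(neuron_counts, 1, function(s) {
    if (all(s == s[1])) 0 else fisher_discriminant_ratio(s, labels)
  })
  structure(list(per_bin = per_bin, network_fdr = sum(per_bin),
                 neuronal = neuronal, class1 = class1, bin = bin),
            class = "fdr_result")
}

#' Rank neurons by their neuronal FDR
#'
#' Deterministic ranking (ties broken by neuron index).
#'
#' @param fdr \code{fdr_result}
#' @return integer vector of neuron ids, most discriminative first
#' @export
neuronal_fdr_ranking <- function(fdr) {
  order(-fdr$neuronal, seq_along(fdr$neuronal))
}

#' Extract the potentiated/depressed subnetwork
#'
#' Synapses whose weight change after learning exceeds \code{threshold}
#' (potentiated) or falls below \code{-threshold} (depressed). The node
#' set of the subnetwork is the endpoints of the potentiated synapses,
#' classified as presynaptic-only, postsynaptic-only, or both.
#'
#' @param network \code{lsm_network} (provides the synapse table)
#' @param weights_before,weights_after matched weight vectors
#' @param threshold weight-change threshold (default 1e-8)
#' @return object of class \code{subnetwork_graph}: \code{potentiated},
#'   \code{depressed} (synapse indices), \code{nodes}, \code{node_class},
#'   \code{threshold}
#' @export
extract_subnetwork <- function(network, weights_before, weights_after,
                               threshold = 1e-8) {
  syn <- network$synapses
  if (length(weights_before) != nrow(syn) ||
      length(weights_after) != nrow(syn))
    stop("weight vectors do not match the synapse table")
  dw <- weights_after - weights_before
  pot <- which(dw > threshold)
  dep <- which(dw < -threshold)
  pre_n <- unique(syn$pre[pot])
  post_n <- unique(syn$post[pot])
  nodes <- sort(unique(c(pre_n, post_n)))
  node_class <- ifelse(nodes %in% pre_n & nodes %in% post_n, "both",
                       ifelse(nodes %in% pre_n, "pre_only", "post_only"))
  structure(list(potentiated = pot, depressed = dep, nodes = nodes,
                 node_class = node_class, threshold = threshold,
                 edges = data.frame(pre = syn$pre[pot], post = syn$post[pot],
                                    dw = dw[pot])),
            class = "subnetwork_graph")
}

#' @export
print.subnetwork_graph <- function(x, ...) {
  cat(sprintf("subnetwork: %d potentiated, %d depressed synapses (|dW| > %g)\n",
              length(x$potentiated), length(x$depressed), x$threshold))
  cat(sprintf("  %d nodes (%d pre-only, %d post-only, %d both)\n",
              length(x$nodes), sum(x$node_class == "pre_only"),
              sum(x$node_class == "post_only"), sum(x$node_class == "both")))
  invisible(x)
}

#' Average clustering coefficient of a subnetwork
#'
#' Watts-Strogatz average of the per-node clustering coefficients on the
#' undirected simple projection of the potentiated edge set; isolated and
#' degree-1 nodes contribute 0.
#'
#' @param subnetwork \code{subnetwork_graph}, or a two-column edge matrix
#' @return mean clustering coefficient
#' @export
clustering_coefficient <- function(subnetwork) {
  edges <- if (inherits(subnetwork, "subnetwork_graph")) {
    as.matrix(subnetwork$edges[, c("pre", "post")])
  } else as.matrix(subnetwork)
  if (nrow(edges) == 0) stop("empty graph")
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(cc)
}

#' Overlap between top-FDR critical neurons and the subnetwork
#'
#' Counts how many of the k top-ranking neurons (by neuronal FDR) belong
#' to the potentiated subnetwork, alongside the chance expectation
#' \eqn{k |S| / N} for k neurons drawn at random from the whole reservoir.
#'
#' @param ranking neuron ids ordered by decreasing FDR
#'   (\code{\link{neuronal_fdr_ranking}})
#' @param subnetwork \code{subnetwork_graph}
#' @param k number of critical neurons (default 200)
#' @param n_neurons reservoir size (defaults to the length of the ranking)
#' @return list: \code{overlap}, \code{chance}, \code{k},
#'   \code{by_class} (overlap split by node classification)
#' @export
critical_neuron_overlap <- function(ranking, subnetwork, k = 200,
                                    n_neurons = length(ranking)) {
  if (k > length(ranking)) stop("k exceeds the number of ranked neurons")
  top <- ranking[seq_len(k)]
  inside <- top %in% subnetwork$nodes
  cls <- subnetwork$node_class[match(top[inside], subnetwork$nodes)]
  list(overlap = sum(inside),
       chance = k * length(subnetwork$nodes) / n_neurons,
       k = k,
       by_class = table(factor(cls, levels = c("pre_only", "post_only", "both"))))
}

#' Export a subnetwork as GraphML
#' @param subnetwork \code{subnetwork_graph}
#' @param path output file
#' @return invisibly, the path
#' @export
export_graphml <- function(subnetwork, path) {
  g <- igraph::graph_from_data_frame(subnetwork$edges, directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
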