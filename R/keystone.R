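#' Detect network modules by greedy modularity maximization
#'
#' Agglomerative fast-greedy optimization of Newman's Q on the unweighted
#' graph; deterministic for a given graph.
#'
#' @param net a [CooccurrenceNetwork-class] or `igraph`.
#' @return list: `membership` (named integer vector), `modularity` (Q),
#'   `n_modules`.
#' @export
detectModules <- function(net) {
  g <- if (is(net, "CooccurrenceNetwork")) networkGraph(net) else net
  if (igraph::vcount(g) == 0) stop("network is empty")
  # order vertices lexicographically so agglomerative tie-breaks are stable
  g <- igraph::permute(g, match(igraph::V(g)$name,
                                sort(igraph::V(g)$name)))
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  # pick the dendrogram cut with maximal recomputed Q ourselves: the cut
  # reported by membership() can drift below the single-community Q = 0
  # through accumulated floating-point error on dense graphs
  n <- igraph::vcount(g)
  n_merges <- if (is.null(cl$merges)) 0L else nrow(cl$merges)
  best_q <- -Inf
  best_mem <- NULL
  for (k in seq(n - n_merges, n)) {
    memk <- igraph::cut_at(cl, no = k)
    q <- igraph::modularity(g, memk)
    if (q > best_q + 1e-12) {  # ties resolve to the coarser partition
      best_q <- q
      best_mem <- memk
    }
  }
  mem <- as.integer(factor(best_mem, levels = unique(best_mem)))
  list(membership = stats::setNames(mem, igraph::V(g)$name),
       modularity = best_q,
       n_modules = length(unique(mem)))
}

#' Zi-Pi node roles and keystone classification
#'
#' Zi is the within-module degree z-score (population SD over the node's
#' module); Pi = 1 - sum_s (k_is / k_i)^2 is the among-module participation
#' coefficient. Nodes are classified with the four-quadrant rule: peripheral
#' (Zi <= zi_cut, Pi <= pi_cut), connector (Zi <= zi_cut, Pi > pi_cut),
#' module hub (Zi > zi_cut, Pi <= pi_cut), network hub (both exceeded).
#' Connectors, module hubs and network hubs together form the keystone set.
#' Threshold equality is assigned to the lower class.
#'
#' @param net a [CooccurrenceNetwork-class] or `igraph`.
#' @param modules named membership vector covering all nodes (e.g. from
#'   [detectModules()]`$membership`); detected automatically when missing.
#' @param zi_cut,pi_cut classification thresholds (defaults 2.5 and 0.62).
#' @return data.frame: taxon, module, degree, Zi, Pi, role, keystone.
#' @export
nodeRoles <- function(net, modules = NULL, zi_cut = 2.5, pi_cut = 0.62) {
  g <- if (is(net, "CooccurrenceNetwork")) networkGraph(net) else net
  if (is.null(modules)) modules <- detectModules(g)$membership
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(modules)))
    stop("module partition does not cover all nodes")
  mem <- modules[nodes]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(adj)
  mods <- sort(unique(mem))
  # k_is: links from node i into module s
  kis <- vapply(mods, function(s) rowSums(adj[, mem == s, drop = FALSE]),
                numeric(length(nodes)))
  if (length(nodes) == 1L) kis <- matrix(kis, nrow = 1)
  # within-module degree z-score with population SD
  zi <- numeric(length(nodes))
  for (s in mods) {
    in_s <- mem == s
    kw <- kis[in_s, which(mods == s)]
    mu <- mean(kw)
    sdev <- sqrt(mean((kw - mu)^2))
    zi[in_s] <- if (sdev == 0) 0 else (kw - mu) / sdev
  }
  pi_c <- ifelse(k == 0, 0, 1 - rowSums((kis / pmax(k, 1))^2))
  role <- ifelse(zi > zi_cut & pi_c > pi_cut, "network_hub",
                 ifelse(zi > zi_cut, "module_hub",
                        ifelse(pi_c > pi_cut, "connector", "peripheral")))
  data.frame(taxon = nodes, module = as.integer(mem), degree = as.integer(k),
             Zi = zi, Pi = pi_c, role = role,
             keystone = role != "peripheral", stringsAsFactors = FALSE)
}
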