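#' Abundance/prevalence filtering before network construction
#'
#' Keeps taxa whose overall relative abundance (taxon total over grand total)
#' strictly exceeds `rel_abund_cut` and that are detected in at least
#' `ceiling(prevalence_cut * n_samples)` samples.
#'
#' @param table an [AbundanceTable-class].
#' @param rel_abund_cut overall relative-abundance threshold (strict >),
#'   default 1e-4 (0.01%).
#' @param prevalence_cut minimum detection fraction (inclusive), default 0.10.
#' @return The filtered [AbundanceTable-class].
#' @export
filterTaxa <- function(table, rel_abund_cut = 1e-4, prevalence_cut = 0.10) {
  stopifnot(is(table, "AbundanceTable"))
  if (rel_abund_cut < 0 || rel_abund_cut >= 1 ||
      prevalence_cut < 0 || prevalence_cut >= 1)
    stop("cuts must lie in [0, 1)")
  x <- counts(table)
  rel <- colSums(x) / sum(x)
  prev <- colSums(x > 0)
  keep <- rel > rel_abund_cut & prev >= ceiling(prevalence_cut * nrow(x))
  if (!any(keep)) stop("all taxa removed by the abundance/prevalence filter")
  table[, keep]
}

# Vectorized Spearman correlations and t-approximation p-values for all
# column pairs of a samples x taxa matrix. Returns list(r, p) of S x S
# matrices; constant columns yield NA.
spearmanMatrix <- function(x) {
  n <- nrow(x)
  ranks <- apply(x, 2, rank)
  sds <- apply(ranks, 2, stats::sd)
  r <- suppressWarnings(stats::cor(ranks))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(p) <- NA
  list(r = r, p = p)
}

#' Build a thresholded Spearman co-occurrence network
#'
#' Computes Spearman correlations between all taxon pairs on per-sample
#' relative abundances, adjusts the p-values jointly over all pairs by
#' Benjamini-Hochberg, and keeps edges with |r| > `corr_cut` and adjusted
#' p < `fdr_cut`. Isolated taxa are excluded from the node set.
#'
#' @param table a pre-filtered [AbundanceTable-class] with >= 4 samples.
#' @param corr_cut correlation-magnitude threshold (strict), default 0.6.
#' @param fdr_cut adjusted-p threshold (strict), default 0.01.
#' @param use_relative correlate relative abundances (default) or raw counts.
#' @return A [CooccurrenceNetwork-class].
#' @export
buildNetwork <- function(table, corr_cut = 0.6, fdr_cut = 0.01,
                         use_relative = TRUE) {
  stopifnot(is(table, "AbundanceTable"))
  x <- counts(table)
  if (nrow(x) < 4) stop("need at least 4 samples for meaningful correlations")
  if (use_relative) x <- relAbundance(table)
  sp <- spearmanMatrix(x)
  S <- ncol(x)
  ut <- which(upper.tri(sp$r), arr.ind = TRUE)
  r <- sp$r[ut]; p <- sp$p[ut]
  valid <- !is.na(r)
  if (any(!valid)) warning(sum(!valid), " taxon pair(s) with a constant taxon skipped")
  p_adj <- rep(NA_real_, length(p))
  p_adj[valid] <- stats::p.adjust(p[valid], method = "BH")
  sel <- valid & abs(r) > corr_cut & p_adj < fdr_cut
  edges <- data.frame(from = colnames(x)[ut[sel, 1]],
                      to = colnames(x)[ut[sel, 2]],
                      r = r[sel], p_adj = p_adj[sel], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  new("CooccurrenceNetwork", graph = g, corr_cut = corr_cut,
      fdr_cut = fdr_cut, n_samples = nrow(x))
}

emptyTopologyRecord <- function() {
  data.frame(nodes_num = 0L, edges_num = 0L, avg_degree = 0,
             degree_centralization = 0, graph_density = 0,
             avg_path_length = NA_real_, clustering_coefficient = 0,
             modularity = NA_real_, betweenness_centralization = 0,
             edge_node_ratio = 0, flag = "empty", stringsAsFactors = FALSE)
}

topologyOfGraph <- function(g, modules = NULL) {
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  if (n == 0) return(emptyTopologyRecord())
  if (n < 3) {
    warning("fewer than 3 nodes; centralizations reported as 0")
    cd <- 0; cb <- 0
  } else {
    cd <- igraph::centr_degree(g, loops = FALSE)$centralization
    cb <- igraph::centr_betw(g)$centralization
  }
  if (is.null(modules)) {
    mod_q <- if (e > 0)
      igraph::modularity(g, igraph::membership(igraph::cluster_fast_greedy(g, weights = NULL)))
    else NA_real_
  } else {
    mod_q <- igraph::modularity(g, modules[igraph::V(g)$name])
  }
  apl <- if (e > 0) igraph::mean_distance(g, directed = FALSE) else NA_real_
  cc <- igraph::transitivity(g, type = "global")
  data.frame(nodes_num = n, edges_num = e, avg_degree = 2 * e / n,
             degree_centralization = cd,
             graph_density = igraph::edge_density(g),
             avg_path_length = apl,
             clustering_coefficient = if (is.nan(cc)) 0 else cc,
             modularity = mod_q,
             betweenness_centralization = cb,
             edge_node_ratio = e / n, flag = "ok", stringsAsFactors = FALSE)
}

#' Topological characterization of a co-occurrence network
#'
#' Reports node and edge numbers, average degree, Freeman degree and
#' betweenness centralizations, graph density, average path length over
#' connected pairs, global clustering coefficient (transitivity), Newman
#' modularity Q of the supplied (or freshly detected) partition, and the
#' edge/node ratio.
#'
#' @param net a [CooccurrenceNetwork-class] (or raw `igraph`).
#' @param modules optional named module membership vector; when missing,
#'   modules are detected with [detectModules()].
#' @return A one-row data.frame.
#' @export
networkTopology <- function(net, modules = NULL) {
  g <- if (is(net, "CooccurrenceNetwork")) networkGraph(net) else net
  if (igraph::vcount(g) == 0) stop("network is empty")
  topologyOfGraph(g, modules)
}

#' Ordinary least-squares power-law fit to the degree distribution
#'
#' Regresses log(frequency) on log(degree) over the observed positive
#' degrees (zero-frequency degrees are absent by construction).
#'
#' @param net a [CooccurrenceNetwork-class] or `igraph`.
#' @return list: `exponent` (the OLS slope), `r_squared`, `n_points`.
#' @export
powerlawFit <- function(net) {
  g <- if (is(net, "CooccurrenceNetwork")) networkGraph(net) else net
  deg <- igraph::degree(g)
  deg <- deg[deg > 0]
  tab <- table(deg)
  if (length(tab) < 3) stop("need at least 3 distinct positive degree values")
  k <- as.numeric(names(tab))
  freq <- as.numeric(tab) / length(deg)
  fit <- stats::lm(log(freq) ~ log(k))
  list(exponent = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       n_points = length(k))
}

#' Per-sample subnetwork topology
#'
#' Induces the subgraph of the network on the taxa present (count > 0) in one
#' sample and reports the same topology record as [networkTopology()]. An
#' empty induced graph yields an all-zero record flagged `"empty"`.
#'
#' @param net a [CooccurrenceNetwork-class].
#' @param table the [AbundanceTable-class] the network was built from.
#' @param sample a sample id present in `table`.
#' @return A one-row data.frame (column `sample` prepended).
#' @export
sampleSubnetwork <- function(net, table, sample) {
  stopifnot(is(net, "CooccurrenceNetwork"), is(table, "AbundanceTable"))
  if (!sample %in% sampleIDs(table)) stop("unknown sample: ", sample)
  x <- counts(table)[sample, ]
  present <- names(x)[x > 0]
  g <- networkGraph(net)
  nodes <- intersect(igraph::V(g)$name, present)
  rec <- if (!length(nodes)) emptyTopologyRecord()
  else topologyOfGraph(igraph::induced_subgraph(g, nodes))
  cbind(data.frame(sample = sample, stringsAsFactors = FALSE), rec)
}
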