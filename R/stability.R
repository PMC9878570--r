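#' Network robustness under random node removal
#'
#' Per repetition, `floor(removal_fraction * n)` nodes are removed uniformly
#' at random, then survivors left with degree 0 are pruned iteratively
#' (secondary extinction). Robustness is the surviving proportion of the
#' original node set, averaged over repetitions.
#'
#' @param net a [CooccurrenceNetwork-class] or `igraph`.
#' @param removal_fraction fraction of nodes removed, in (0, 1).
#' @param n_reps number of repetitions (default 100).
#' @param seed integer master seed (substream `"robustness"`).
#' @return list of class `StabilityRecord`: `robustness_mean`,
#'   `robustness_reps`, `removal_fraction`, `n_reps`.
#' @export
robustness <- function(net, removal_fraction = 0.5, n_reps = 100L, seed = 1L) {
  g <- if (is(net, "CooccurrenceNetwork")) networkGraph(net) else net
  n <- igraph::vcount(g)
  if (n == 0) stop("network is empty")
  if (removal_fraction <= 0 || removal_fraction >= 1)
    stop("removal_fraction must lie strictly inside (0, 1)")
  if (n_reps < 1) stop("n_reps must be >= 1")
  n_remove <- floor(removal_fraction * n)
  reps <- withSubstream(seed, "robustness", {
    vapply(seq_len(n_reps), function(i) {
      keep <- sample.int(n, n - n_remove)
      sub <- igraph::induced_subgraph(g, keep)
      # iterative pruning of isolated survivors; removing a degree-0 node
      # never lowers another node's degree, but loop until fixed point anyway
      repeat {
        iso <- which(igraph::degree(sub) == 0)
        if (!length(iso)) break
        sub <- igraph::delete_vertices(sub, iso)
      }
      igraph::vcount(sub) / n
    }, numeric(1))
  })
  structure(list(robustness_mean = mean(reps), robustness_reps = reps,
                 removal_fraction = removal_fraction,
                 n_reps = as.integer(n_reps)),
            class = "StabilityRecord")
}

# Global efficiency: mean over ordered vertex pairs of 1/d(i,j),
# with 1/d = 0 for disconnected pairs.
globalEfficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Network vulnerability (maximum node vulnerability)
#'
#' Node vulnerability V_i = (E - E_-i) / E, where E is the global efficiency
#' (mean inverse shortest-path length over ordered pairs, 0 for disconnected
#' pairs) and E_-i the efficiency of the graph with node i deleted. The
#' network vulnerability is max_i V_i, floored at 0.
#'
#' @param net a [CooccurrenceNetwork-class] or `igraph` with >= 3 nodes.
#' @return list of class `StabilityRecord`: `vulnerability`,
#'   `node_vulnerability` (named vector), `efficiency`.
#' @export
vulnerability <- function(net) {
  g <- if (is(net, "CooccurrenceNetwork")) networkGraph(net) else net
  n <- igraph::vcount(g)
  if (n < 3) stop("vulnerability needs at least 3 nodes")
  E <- globalEfficiency(g)
  if (E == 0) {
    warning("edgeless network; vulnerability defined as 0")
    v <- stats::setNames(rep(0, n), igraph::V(g)$name)
    return(structure(list(vulnerability = 0, node_vulnerability = v,
                          efficiency = 0), class = "StabilityRecord"))
  }
  v <- vapply(seq_len(n), function(i) {
    (E - globalEfficiency(igraph::delete_vertices(g, i))) / E
  }, numeric(1))
  names(v) <- igraph::V(g)$name
  structure(list(vulnerability = max(0, max(v)), node_vulnerability = v,
                 efficiency = E), class = "StabilityRecord")
}

#' @export
print.StabilityRecord <- function(x, ...) {
  cat("StabilityRecord\n")
  if (!is.null(x$robustness_mean))
    cat(sprintf("  robustness: %.4f (mean of %d reps, %.0f%% removal)\n",
                x$robustness_mean, x$n_reps, 100 * x$removal_fraction))
  if (!is.null(x$vulnerability))
    cat(sprintf("  vulnerability: %.4f (global efficiency %.4f)\n",
                x$vulnerability, x$efficiency))
  invisible(x)
}
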