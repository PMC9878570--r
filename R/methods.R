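#' @rdname AbundanceTable-class
#' @export
setMethod("counts", "AbundanceTable", function(x) x@counts)

#' @rdname AbundanceTable-class
#' @export
setMethod("sampleIDs", "AbundanceTable", function(x) rownames(x@counts))

#' @rdname AbundanceTable-class
#' @export
setMethod("taxonIDs", "AbundanceTable", function(x) colnames(x@counts))

#' @rdname AbundanceTable-class
#' @export
setMethod("nSamples", "AbundanceTable", function(x) nrow(x@counts))

#' @rdname AbundanceTable-class
#' @export
setMethod("nTaxa", "AbundanceTable", function(x) ncol(x@counts))

#' @rdname AbundanceTable-class
#' @export
setMethod("relAbundance", "AbundanceTable", function(x) {
  tot <- rowSums(x@counts)
  if (any(tot == 0)) stop("cannot compute relative abundances: all-zero sample(s): ",
                          paste(rownames(x@counts)[tot == 0], collapse = ", "))
  sweep(x@counts, 1, tot, "/")
})

#' Subset an AbundanceTable by samples (i) and taxa (j)
#'
#' @param x an [AbundanceTable-class].
#' @param i,j sample and taxon indices (numeric, logical or names).
#' @param ... ignored.
#' @param drop ignored; subsetting always returns an AbundanceTable.
#' @export
setMethod("[", "AbundanceTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@counts))
  if (missing(j)) j <- seq_len(ncol(x@counts))
  AbundanceTable(x@counts[i, j, drop = FALSE])
})

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d samples x %d taxa\n",
              nrow(object@counts), ncol(object@counts)))
  cat(sprintf("  total reads: %s; median depth: %s\n",
              format(sum(object@counts), big.mark = ","),
              format(stats::median(rowSums(object@counts)), big.mark = ",")))
})

setMethod("show", "NCMFit", function(object) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  m = %.4g, N = %.6g, Nm = %.6g, R2 = %.4g\n",
              object@m, object@N, object@Nm, object@r_squared))
  tab <- table(factor(object@taxa$partition, c("below", "within", "above")))
  cat(sprintf("  taxa: %d (below %d / within %d / above %d the 95%% envelope)\n",
              nrow(object@taxa), tab[["below"]], tab[["within"]], tab[["above"]]))
})

setMethod("show", "PNSTResult", function(object) {
  cat(sprintf("pNST result (%d null randomizations)\n", object@n_null))
  for (k in seq_len(nrow(object@groups)))
    cat(sprintf("  group %s: pNST = %.4f over %d within-group pairs\n",
                object@groups$group[k], object@groups$pNST[k],
                object@groups$n_pairs[k]))
})

#' @rdname network-accessors
#' @export
setMethod("networkGraph", "CooccurrenceNetwork", function(x) x@graph)

#' @rdname network-accessors
#' @export
setMethod("networkEdges", "CooccurrenceNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0)
    return(data.frame(taxon_a = character(), taxon_b = character(),
                      r = numeric(), p_adj = numeric()))
  el <- igraph::as_edgelist(g)
  data.frame(taxon_a = el[, 1], taxon_b = el[, 2],
             r = igraph::E(g)$r, p_adj = igraph::E(g)$p_adj)
})

#' @rdname network-accessors
#' @export
setMethod("networkNodes", "CooccurrenceNetwork",
          function(x) igraph::V(x@graph)$name)

setMethod("show", "CooccurrenceNetwork", function(object) {
  g <- object@graph
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (|r| > %g, FDR < %g, n = %d samples)\n",
              igraph::vcount(g), igraph::ecount(g),
              object@corr_cut, object@fdr_cut, object@n_samples))
  if (igraph::ecount(g) > 0) {
    r <- igraph::E(g)$r
    cat(sprintf("  positive edges: %d, negative edges: %d\n",
                sum(r > 0), sum(r < 0)))
  }
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  for (s in slotNames(object))
    cat(sprintf("  %s: %s\n", s, format(slot(object, s))))
})
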