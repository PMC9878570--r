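#' Rarefy an abundance table to even depth
#'
#' Subsamples each sample's reads without replacement down to `depth`.
#' Samples whose total is below `depth` are dropped (and reported via a
#' message and the `"dropped"` attribute); samples exactly at `depth` are
#' returned unchanged.
#'
#' @param table an [AbundanceTable-class].
#' @param depth positive integer target depth.
#' @param seed integer seed (substream `"rarefy"` of the master seed).
#' @return A rarefied [AbundanceTable-class]; attribute `dropped` lists the
#'   ids of removed samples.
#' @export
rarefyTable <- function(table, depth, seed = 1L) {
  stopifnot(is(table, "AbundanceTable"), depth >= 1)
  depth <- as.integer(depth)
  tot <- rowSums(counts(table))
  keep <- tot >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth ", depth)
  dropped <- sampleIDs(table)[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " sample(s) below depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  x <- counts(table)[keep, , drop = FALSE]
  out <- withSubstream(seed, "rarefy", {
    rar <- x
    for (i in seq_len(nrow(x))) {
      if (tot[keep][i] == depth) next  # exhaustive draw: unchanged
      # rrarefy warns whenever the smallest nonzero count exceeds 1, which
      # is routine for real count tables; silence only that heuristic
      rar[i, ] <- withCallingHandlers(
        vegan::rrarefy(x[i, , drop = FALSE], depth),
        warning = function(w) {
          if (grepl("observed counts", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    }
    rar
  })
  res <- AbundanceTable(out)
  attr(res, "dropped") <- dropped
  res
}

#' Alpha diversity: richness, Shannon entropy and Faith's PD
#'
#' Richness counts taxa with positive counts; Shannon uses natural logarithms;
#' Faith's phylogenetic diversity is the total branch length of the minimal
#' subtree spanning the observed tips and the root (the `picante::pd`
#' rooted convention; set `include_root = FALSE` for the unrooted variant).
#'
#' @param table an [AbundanceTable-class].
#' @param tree optional `phylo`; required for `faith_pd`.
#' @param include_root logical, include the path to the root in PD.
#' @return data.frame with columns sample, richness, shannon and (with a
#'   tree) faith_pd.
#' @export
alphaDiversity <- function(table, tree = NULL, include_root = TRUE) {
  stopifnot(is(table, "AbundanceTable"))
  x <- counts(table)
  rich <- rowSums(x > 0)
  shan <- as.numeric(vegan::diversity(x, index = "shannon"))
  out <- data.frame(sample = rownames(x), richness = as.integer(rich),
                    shannon = shan, stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    observed <- colnames(x)[colSums(x) > 0]
    missing <- setdiff(observed, tree$tip.label)
    if (length(missing))
      stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
    pruned <- if (length(setdiff(tree$tip.label, colnames(x))))
      ape::keep.tip(tree, intersect(tree$tip.label, colnames(x))) else tree
    # pd(include.root = TRUE) needs a rooted binary tree; resolving basal
    # polytomies with zero-length branches leaves every PD value unchanged
    if (include_root && !ape::is.rooted(pruned))
      pruned <- ape::multi2di(pruned)
    pdtab <- picante::pd(x[, pruned$tip.label, drop = FALSE], pruned,
                         include.root = include_root)
    out$faith_pd <- pdtab$PD[match(rownames(x), rownames(pdtab))]
    out$faith_pd[rich == 0] <- 0
  }
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), in [0, 1].
#'
#' @param table an [AbundanceTable-class] with no all-zero sample.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = sample ids.
#' @export
brayCurtis <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  x <- counts(table)
  if (any(rowSums(x) == 0))
    stop("Bray-Curtis is undefined for all-zero sample(s): ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  as.matrix(vegan::vegdist(x, method = "bray"))
}
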