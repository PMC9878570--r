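# Shared machinery: betaMNTD from a relative-abundance matrix (samples x taxa)
# and a patristic tip-tip distance matrix over the same taxa (same column
# order). For each sample j, minDist_j[k] = min over taxa present in j of the
# patristic distance from taxon k; then
#   D(i, j) = 1/2 * (f_i . minDist_j + f_j . minDist_i).
betaMNTDcore <- function(F, delta) {
  n <- nrow(F)
  S <- ncol(F)
  minD <- matrix(0, n, S)
  for (j in seq_len(n)) {
    pres <- which(F[j, ] > 0)
    if (!length(pres)) stop("empty community in row ", j)
    minD[j, ] <- do.call(pmin, lapply(pres, function(l) delta[, l]))
  }
  A <- F %*% t(minD)           # A[i, j] = f_i . minDist_j
  D <- (A + t(A)) / 2
  diag(D) <- 0
  dimnames(D) <- list(rownames(F), rownames(F))
  D
}

#' Abundance-weighted betaMNTD between all sample pairs
#'
#' The between-community mean nearest-taxon distance: for each taxon in one
#' community, the patristic distance to its closest relative in the other
#' community, averaged with relative-abundance weights and symmetrized.
#' Distances are normalized by the maximum patristic distance of the tree so
#' that results lie in \[0, 1\].
#'
#' @param table an [AbundanceTable-class]; every present taxon must be a tip.
#' @param tree a rooted `phylo` with branch lengths.
#' @param normalize divide by the tree's maximum patristic distance (default).
#' @return Symmetric matrix of dissimilarities with zero diagonal.
#' @export
betaMNTD <- function(table, tree, normalize = TRUE) {
  stopifnot(is(table, "AbundanceTable"), inherits(tree, "phylo"))
  x <- counts(table)
  if (any(rowSums(x) == 0)) stop("empty communities: ",
                                 paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  observed <- colnames(x)[colSums(x) > 0]
  missing <- setdiff(observed, tree$tip.label)
  if (length(missing))
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  keep <- intersect(colnames(x), tree$tip.label)
  x <- x[, keep, drop = FALSE]
  delta <- ape::cophenetic.phylo(tree)[keep, keep]
  dmax <- max(ape::cophenetic.phylo(tree))
  F <- sweep(x, 1, rowSums(x), "/")
  D <- betaMNTDcore(F, delta)
  if (normalize && dmax > 0) D <- D / dmax
  D
}

#' Tip-shuffle null ensemble of betaMNTD dissimilarities
#'
#' Each null draw shuffles the assignment of taxa to phylogeny tips uniformly
#' at random and recomputes betaMNTD for every sample pair; abundances (and
#' hence richness and depth) are untouched. Equivalent to permuting the rows
#' and columns of the patristic distance matrix.
#'
#' @param table an [AbundanceTable-class].
#' @param tree a `phylo` covering the table's present taxa.
#' @param n_null number of randomizations (a warning below 100).
#' @param seed integer master seed (substream `"pnst_null"`).
#' @return list: `observed` (matrix), `null_mean` (matrix of E_ij),
#'   `null_draws` (array n x n x n_null), `n_null`.
#' @export
nullDissimilarity <- function(table, tree, n_null = 1000L, seed = 1L) {
  if (n_null < 100) warning("n_null < 100; null means may be unstable")
  x <- counts(table)
  observed_taxa <- colnames(x)[colSums(x) > 0]
  missing <- setdiff(observed_taxa, tree$tip.label)
  if (length(missing))
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  keep <- intersect(colnames(x), tree$tip.label)
  x <- x[, keep, drop = FALSE]
  coph <- ape::cophenetic.phylo(tree)
  dmax <- max(coph)
  delta <- coph[keep, keep] / dmax
  F <- sweep(x, 1, rowSums(x), "/")
  obs <- betaMNTDcore(F, delta)
  n <- nrow(F); S <- ncol(F)
  draws <- array(NA_real_, c(n, n, n_null))
  withSubstream(seed, "pnst_null", {
    for (b in seq_len(n_null)) {
      perm <- sample.int(S)
      # shuffling tip labels == permuting which taxon sits at which tip;
      # realized as a column permutation of the abundance matrix
      draws[, , b] <- betaMNTDcore(F[, perm, drop = FALSE], delta)
    }
  })
  null_mean <- apply(draws, c(1, 2), mean)
  dimnames(null_mean) <- dimnames(obs)
  list(observed = obs, null_mean = null_mean, null_draws = draws,
       n_null = as.integer(n_null))
}

#' Phylogenetic normalized stochasticity ratio (pNST)
#'
#' For each sample pair, with C the observed normalized dissimilarity, E the
#' null-mean dissimilarity and the maximum attainable dissimilarity 1:
#' NST_ij = (1 - C)/(1 - E) when C >= E, and C/E when C < E. NST is 1 when
#' observed dissimilarity equals the null expectation (pure stochasticity)
#' and falls toward 0 as observations diverge from it in either direction.
#' The group pNST is the mean NST over within-group pairs; values above 0.5
#' are read as stochasticity-dominated assembly, below 0.5 as
#' determinism-dominated.
#'
#' @param null a list as returned by [nullDissimilarity()] (or a list with
#'   elements `observed`, `null_mean`, `n_null`).
#' @param groups group labels, one per sample (a single label for one group).
#' @return A [PNSTResult-class].
#' @export
pNST <- function(null, groups) {
  obs <- null$observed
  E <- null$null_mean
  n <- nrow(obs)
  if (length(groups) == 1L) groups <- rep(groups, n)
  if (length(groups) != n) stop("groups length must match the sample count")
  groups <- as.character(groups)
  idx <- which(upper.tri(obs), arr.ind = TRUE)
  C <- obs[idx]; Em <- E[idx]
  nst <- numeric(nrow(idx))
  st <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    c_k <- min(1, C[k]); e_k <- min(1, Em[k])
    if (c_k >= e_k) {
      nst[k] <- if (1 - e_k <= 0) 1 else (1 - c_k) / (1 - e_k)  # 0/0 -> 1
      st[k] <- if (c_k <= 0) 1 else e_k / c_k
    } else {
      nst[k] <- if (e_k <= 0) 1 else c_k / e_k
      st[k] <- if (1 - c_k <= 0) 1 else (1 - e_k) / (1 - c_k)
    }
  }
  g_i <- groups[idx[, 1]]; g_j <- groups[idx[, 2]]
  pair_group <- ifelse(g_i == g_j, g_i, NA_character_)
  pairs <- data.frame(sample_i = rownames(obs)[idx[, 1]],
                      sample_j = rownames(obs)[idx[, 2]],
                      group = pair_group, observed = C, null_mean = Em,
                      NST = nst, ST = st, stringsAsFactors = FALSE)
  lev <- unique(groups)
  gtab <- do.call(rbind, lapply(lev, function(g) {
    sel <- !is.na(pair_group) & pair_group == g
    data.frame(group = g, pNST = if (any(sel)) mean(nst[sel]) else NA_real_,
               n_pairs = sum(sel), stringsAsFactors = FALSE)
  }))
  new("PNSTResult", pairs = pairs, groups = gtab,
      n_null = as.integer(null$n_null))
}
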