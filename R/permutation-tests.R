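# One-way distance-based pseudo-F from a squared-distance matrix.
# SS_total = sum_{i<j} d^2 / N; SS_within = sum_g sum_{i<j in g} d^2 / n_g.
permanovaF <- function(d2, groups) {
  N <- nrow(d2)
  lev <- unique(groups)
  k <- length(lev)
  ss_tot <- sum(d2[upper.tri(d2)]) / N
  ss_w <- 0
  for (g in lev) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      dg <- d2[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(dg[upper.tri(dg)]) / length(idx)
    }
  }
  ss_b <- ss_tot - ss_w
  (ss_b / (k - 1)) / (ss_w / (N - k))
}

checkDistGroups <- function(dm, groups) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (length(groups) != nrow(dm))
    stop("groups length must match the distance matrix")
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  list(dm = dm, groups = groups)
}

#' One-way PERMANOVA (permutational multivariate analysis of variance)
#'
#' Partitions the total sum of squared dissimilarities into within- and
#' between-group components and tests the pseudo-F statistic by permuting
#' sample labels. The p-value uses the add-one convention
#' p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1), so p >= 1/(n_perm + 1).
#' With `exhaustive = TRUE` all distinct label permutations are enumerated
#' and p is the exact proportion with F >= F_obs (the identity included).
#'
#' @param dm distance matrix (matrix or `dist`).
#' @param groups group labels, one per sample.
#' @param n_perm number of random permutations (ignored when exhaustive).
#' @param seed integer seed (substream `"permanova"`).
#' @param exhaustive enumerate all permutations (only for small n).
#' @return data.frame: statistic (pseudo-F), p_value, method, n_permutations.
#' @export
permanovaTest <- function(dm, groups, n_perm = 999L, seed = 1L,
                          exhaustive = FALSE) {
  cg <- checkDistGroups(dm, groups)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  d2 <- cg$dm^2
  f_obs <- permanovaF(d2, cg$groups)
  if (exhaustive) {
    perms <- allLabelPermutations(cg$groups)
    f_perm <- vapply(perms, function(g) permanovaF(d2, g), numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    f_perm <- withSubstream(seed, "permanova", {
      vapply(seq_len(n_perm),
             function(i) permanovaF(d2, sample(cg$groups)), numeric(1))
    })
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  data.frame(statistic = f_obs, p_value = p, method = "permanova",
             n_permutations = n_used, stringsAsFactors = FALSE)
}

# ANOSIM R from the rank matrix of the n(n-1)/2 dissimilarities.
anosimR <- function(rk, within) {
  M <- length(rk)
  (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}

#' ANOSIM (analysis of similarities)
#'
#' R = (mean between-group rank - mean within-group rank) / (M/2) with
#' M = n(n-1)/2 ranked dissimilarities; the p-value is permutational with the
#' add-one convention (or exact under `exhaustive = TRUE`).
#'
#' @inheritParams permanovaTest
#' @return data.frame: statistic (R), p_value, method, n_permutations.
#' @export
anosimTest <- function(dm, groups, n_perm = 999L, seed = 1L,
                       exhaustive = FALSE) {
  cg <- checkDistGroups(dm, groups)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(cg$dm)
  ut <- upper.tri(cg$dm)
  rk <- rank(cg$dm[ut])
  pair_i <- row(cg$dm)[ut]; pair_j <- col(cg$dm)[ut]
  stat_for <- function(g) anosimR(rk, g[pair_i] == g[pair_j])
  r_obs <- stat_for(cg$groups)
  if (exhaustive) {
    perms <- allLabelPermutations(cg$groups)
    r_perm <- vapply(perms, stat_for, numeric(1))
    p <- mean(r_perm >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    r_perm <- withSubstream(seed, "anosim", {
      vapply(seq_len(n_perm), function(i) stat_for(sample(cg$groups)),
             numeric(1))
    })
    p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  data.frame(statistic = r_obs, p_value = p, method = "anosim",
             n_permutations = n_used, stringsAsFactors = FALSE)
}

# All distinct assignments of the multiset of labels to positions.
allLabelPermutations <- function(groups) {
  n <- length(groups)
  if (n > 10) stop("exhaustive enumeration is limited to n <= 10 samples")
  perms <- permutationsOf(seq_len(n))
  out <- unique(lapply(perms, function(p) groups[p]))
  out
}

permutationsOf <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutationsOf(v[-i]), function(p) c(v[i], p)))
  out
}
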