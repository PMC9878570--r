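# Fixture builders shared across the suite. All fixtures are constructed in
# code; nothing is read from disk except round-trip temp files.

withr_local_tempdir <- function(env = parent.frame()) {
  dir <- tempfile("anet")
  dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  dir
}

toyCounts <- function() {
  matrix(c(5, 0, 3, 2,
           1, 4, 0, 2,
           2, 2, 2, 2), nrow = 3, byrow = TRUE,
         dimnames = list(c("s1", "s2", "s3"), c("otuA", "otuB", "otuC", "otuD")))
}

toyTable <- function() AbundanceTable(toyCounts())

# 4-tip tree with hand-computable patristic distances:
# d(A,B) = 3, d(A,C) = d(A,D) = 5, d(B,C) = d(B,D) = 6, d(C,D) = 2.
toyTree <- function() ape::read.tree(text = "((A:1,B:2):1,(C:1,D:1):2);")

# Wrap a plain igraph as a CooccurrenceNetwork (toy edges get r = 0.9).
asNetwork <- function(g, n_samples = 30L) {
  if (igraph::ecount(g) > 0) {
    if (is.null(igraph::E(g)$r)) igraph::E(g)$r <- 0.9
    if (is.null(igraph::E(g)$p_adj)) igraph::E(g)$p_adj <- 1e-4
  }
  new("CooccurrenceNetwork", graph = g, corr_cut = 0.6, fdr_cut = 0.01,
      n_samples = as.integer(n_samples))
}

namedGraph <- function(edges, isolated = character()) {
  g <- igraph::make_graph(edges = as.character(edges), directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

# Two K5 cliques joined by a single bridge; planted partition has
# Q = 2 * (10/21 - (21/42)^2) = 0.452381.
twoCliqueGraph <- function() {
  el <- c()
  for (blk in c("a", "b")) {
    v <- paste0(blk, 1:5)
    for (i in 1:4) for (j in (i + 1):5) el <- c(el, v[i], v[j])
  }
  el <- c(el, "a1", "b1")
  namedGraph(el)
}

# Two 25-node modules (24-ring plus a hub adjacent to all ring nodes),
# hubs joined by one inter-module edge. Hub Zi = (24 - 3.84)/4.1151 = 4.899.
ringHubGraph <- function() {
  el <- c()
  for (blk in c("m1", "m2")) {
    ring <- sprintf("%s_r%02d", blk, 1:24)
    hub <- paste0(blk, "_hub")
    for (i in 1:24) el <- c(el, ring[i], ring[i %% 24 + 1])
    for (i in 1:24) el <- c(el, hub, ring[i])
  }
  el <- c(el, "m1_hub", "m2_hub")
  namedGraph(el)
}

ringHubPartition <- function() {
  v <- c(sprintf("m1_r%02d", 1:24), "m1_hub",
         sprintf("m2_r%02d", 1:24), "m2_hub")
  stats::setNames(rep(1:2, each = 25), v)
}

# Focal node with two edges into each of three modules: Pi = 2/3.
threeWayGraph <- function() {
  el <- c()
  for (b in 1:3) for (i in 1:2) el <- c(el, "focal", sprintf("m%d_%d", b, i))
  namedGraph(el)
}

threeWayPartition <- function() {
  v <- c("focal", sprintf("m%d_%d", rep(1:3, each = 2), rep(1:2, 3)))
  stats::setNames(c(1L, rep(1:3, each = 2)), v)
}

# Independent one-way PERMANOVA oracle via Gower centering: F computed from
# G = -1/2 J D^2 J and the hat matrix of group dummies.
permanovaOracleF <- function(dm, groups) {
  D2 <- as.matrix(dm)^2
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D2 %*% J
  X <- stats::model.matrix(~ factor(groups))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  k <- length(unique(groups))
  ss_b <- sum(diag(H %*% G %*% H))
  ss_w <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H)))
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

# Exact enumeration of distinct label assignments via positions of group "a".
permanovaOracleP <- function(dm, groups) {
  n <- length(groups)
  lab <- sort(unique(groups))
  stopifnot(length(lab) == 2)
  na <- sum(groups == lab[1])
  f_obs <- permanovaOracleF(dm, groups)
  combos <- utils::combn(n, na)
  f_all <- apply(combos, 2, function(pos) {
    g <- rep(lab[2], n); g[pos] <- lab[1]
    permanovaOracleF(dm, g)
  })
  mean(f_all >= f_obs - 1e-12)
}
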