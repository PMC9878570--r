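test_that("betaMNTD: identities, hand-computed pair, picante oracle", {
  tree <- toyTree()  # d(A,B)=3, max distance d(B,C)=d(B,D)=6
  m <- matrix(c(10, 0, 0, 0,
                 0, 5, 0, 0,
                 3, 3, 0, 0,
                 3, 3, 0, 0), 4, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("A", "B", "C", "D")))
  D <- betaMNTD(AbundanceTable(m), tree)
  # two single-taxon communities: delta(A,B)/delta_max = 3/6
  expect_equal(D["s1", "s2"], 3 / 6)
  # identical communities -> 0
  expect_equal(D["s3", "s4"], 0)
  expect_equal(unname(diag(D)), rep(0, 4))

  # abundance-weighted oracle: picante::comdistnt (unnormalized)
  set.seed(8)
  tr2 <- simulateTree(25, seed = 8)
  tab <- simulateNeutralCommunities(6, 25, J = 300, m = 0.5, seed = 8,
                                    taxon_ids = tr2$tip.label)
  mine <- betaMNTD(tab, tr2, normalize = FALSE)
  ref <- as.matrix(picante::comdistnt(counts(tab),
                                      ape::cophenetic.phylo(tr2),
                                      abundance.weighted = TRUE))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-12,
               ignore_attr = TRUE)

  # missing tip is reported by name
  m2 <- m; colnames(m2) <- c("A", "B", "C", "ZZZ"); m2[1, 4] <- 1
  expect_error(betaMNTD(AbundanceTable(m2), tree), "ZZZ")
  # empty community is an error
  m3 <- m; m3[1, ] <- 0
  expect_error(betaMNTD(AbundanceTable(m3), tree), "s1")
})

test_that("betaMNTD is invariant to global branch-length rescaling", {
  tr <- simulateTree(20, seed = 3)
  tab <- simulateNeutralCommunities(5, 20, J = 200, m = 0.4, seed = 3,
                                    taxon_ids = tr$tip.label)
  tr10 <- tr; tr10$edge.length <- tr10$edge.length * 10
  expect_equal(betaMNTD(tab, tr), betaMNTD(tab, tr10), tolerance = 1e-12)
})

test_that("tip-shuffle null keeps abundances fixed and is a no-op on a star tree", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  m <- matrix(c(4, 3, 0, 0, 1,
                0, 2, 2, 2, 0,
                1, 1, 1, 1, 1), 3, 5, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), LETTERS[1:5]))
  tab <- AbundanceTable(m)
  nd <- suppressWarnings(nullDissimilarity(tab, star, n_null = 20, seed = 1))
  # every patristic distance on a uniform star is 2 -> shuffling changes nothing
  for (b in 1:20)
    expect_equal(nd$null_draws[, , b], unname(nd$observed), tolerance = 1e-12)
  expect_warning(nullDissimilarity(tab, star, n_null = 20, seed = 1),
                 "n_null")
})

test_that("null mean stabilizes with the number of draws", {
  tr <- simulateTree(60, seed = 5)
  tab <- simulateNeutralCommunities(20, 60, J = 400, m = 0.2, seed = 5,
                                    taxon_ids = tr$tip.label)
  e500 <- nullDissimilarity(tab, tr, n_null = 500, seed = 1)$null_mean
  e1000 <- nullDissimilarity(tab, tr, n_null = 1000, seed = 2)$null_mean
  expect_lt(max(abs(e500 - e1000)), 0.01)
})

test_that("NST fixed points and monotonicity in the observed dissimilarity", {
  obs <- matrix(c(0, .4, .4, 0), 2, 2,
                dimnames = list(c("s1", "s2"), c("s1", "s2")))
  nullm <- obs
  fake <- list(observed = obs, null_mean = nullm, n_null = 100L)
  r <- pNST(fake, c("g", "g"))
  expect_equal(r@groups$pNST, 1)  # C = E -> pure-null fixed point

  # C = D_max = 1, E = 0.5 -> NST = 0
  obs2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = dimnames(obs))
  null2 <- matrix(c(0, .5, .5, 0), 2, 2, dimnames = dimnames(obs))
  r2 <- pNST(list(observed = obs2, null_mean = null2, n_null = 100L),
             c("g", "g"))
  expect_equal(r2@groups$pNST, 0)

  # moving C away from E in either direction never increases NST
  E <- 0.5
  cs <- seq(0, 1, by = 0.05)
  nst <- vapply(cs, function(C) {
    o <- matrix(c(0, C, C, 0), 2, 2, dimnames = dimnames(obs))
    e <- matrix(c(0, E, E, 0), 2, 2, dimnames = dimnames(obs))
    pNST(list(observed = o, null_mean = e, n_null = 1L), c("g", "g"))@groups$pNST
  }, numeric(1))
  below <- cs <= E
  expect_true(all(diff(nst[below]) >= -1e-12))   # rising toward C = E
  expect_true(all(diff(nst[!below]) <= 1e-12))   # falling past C = E
  expect_true(all(nst >= 0 & nst <= 1))
})

test_that("pNST is invariant to sample order and to branch-length rescaling", {
  tr <- simulateTree(40, seed = 9)
  tab <- simulateNeutralCommunities(8, 40, J = 300, m = 0.3, seed = 9,
                                    taxon_ids = tr$tip.label)
  g <- rep(c("u", "w"), 4)
  nd1 <- nullDissimilarity(tab, tr, n_null = 150, seed = 4)
  r1 <- pNST(nd1, g)

  ord <- c(5, 2, 8, 1, 7, 3, 6, 4)
  tab2 <- tab[ord, ]
  nd2 <- nullDissimilarity(tab2, tr, n_null = 150, seed = 4)
  r2 <- pNST(nd2, g[ord])
  expect_equal(sort(r1@groups$pNST), sort(r2@groups$pNST), tolerance = 0.05)

  tr10 <- tr; tr10$edge.length <- tr10$edge.length * 10
  nd3 <- nullDissimilarity(tab, tr10, n_null = 150, seed = 4)
  expect_equal(pNST(nd3, g)@groups$pNST, r1@groups$pNST, tolerance = 1e-10)
})
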