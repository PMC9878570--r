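test_that("robustness: complete-graph analytic case and matching expectation", {
  k20 <- igraph::make_full_graph(20)
  igraph::V(k20)$name <- paste0("v", 1:20)
  r <- robustness(asNetwork(k20), removal_fraction = 0.5, n_reps = 50, seed = 1)
  expect_true(all(r$robustness_reps == 0.5))  # K10 survivors never isolated
  expect_equal(r$robustness_mean, 0.5)

  # perfect matching on 20 nodes: each edge survives with C(18,8)/C(20,10)
  pm <- namedGraph(as.character(rbind(paste0("a", 1:10), paste0("b", 1:10))))
  rm_ <- robustness(asNetwork(pm), 0.5, n_reps = 3000, seed = 2)
  expect_equal(rm_$robustness_mean, 2 * 10 * choose(18, 8) / choose(20, 10) / 20,
               tolerance = 0.015)

  # reproducibility under a fixed seed
  ra <- robustness(asNetwork(pm), 0.5, n_reps = 50, seed = 9)
  rb <- robustness(asNetwork(pm), 0.5, n_reps = 50, seed = 9)
  expect_identical(ra$robustness_reps, rb$robustness_reps)
  expect_error(robustness(asNetwork(pm), 0), "removal_fraction")
})

test_that("robustness is monotone non-increasing in the removal fraction", {
  set.seed(15)
  for (i in 1:5) {
    g <- igraph::sample_gnp(40, 0.08)
    igraph::V(g)$name <- paste0("v", 1:40)
    net <- asNetwork(g)
    means <- sapply(c(0.2, 0.4, 0.6, 0.8), function(f)
      robustness(net, f, n_reps = 200, seed = i)$robustness_mean)
    expect_true(all(diff(means) <= 0.02))  # small MC slack
  }
})

test_that("vulnerability: triangle, 3-path and vertex-transitive graphs", {
  tri <- asNetwork(igraph::make_full_graph(3))
  igraph::V(tri@graph)$name <- paste0("v", 1:3)
  v <- vulnerability(tri)
  expect_equal(v$efficiency, 1)
  expect_equal(unname(v$node_vulnerability), rep(0, 3))
  expect_equal(v$vulnerability, 0)

  p3 <- asNetwork(namedGraph(c("a", "b", "b", "c")))
  vp <- vulnerability(p3)
  expect_equal(vp$efficiency, 5 / 6)
  expect_equal(vp$vulnerability, 1)  # deleting the middle disconnects all

  # complete graphs lose no efficiency under single deletions
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("v", 1:6)
  expect_equal(vulnerability(asNetwork(k6))$vulnerability, 0, tolerance = 1e-12)

  # vertex-transitive but not complete: every node equally (and positively)
  # vulnerable — ring of 7, hand value (E - E_minus) / E
  ring <- igraph::make_ring(7)
  igraph::V(ring)$name <- paste0("v", 1:7)
  vr <- vulnerability(asNetwork(ring))
  e_ring <- (1 + 1 + 1 / 2 + 1 / 2 + 1 / 3 + 1 / 3) / 6
  e_path6 <- 2 * (5 / 1 + 4 / 2 + 3 / 3 + 2 / 4 + 1 / 5) / (6 * 5)
  expect_equal(vr$efficiency, e_ring, tolerance = 1e-12)
  expect_equal(vr$vulnerability, (e_ring - e_path6) / e_ring, tolerance = 1e-12)
  expect_equal(unname(vr$node_vulnerability), rep(vr$vulnerability, 7),
               tolerance = 1e-12)

  edgeless <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(edgeless)$name <- paste0("v", 1:4)
  expect_warning(v0 <- vulnerability(asNetwork(edgeless)), "edgeless")
  expect_equal(v0$vulnerability, 0)
})

test_that("module detection recovers planted cliques with the hand-computed Q", {
  net <- asNetwork(twoCliqueGraph())
  mods <- detectModules(net)
  expect_equal(mods$n_modules, 2)
  # the planted split is recovered exactly
  mem <- mods$membership
  expect_equal(length(unique(mem[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(mem[paste0("b", 1:5)])), 1)
  expect_equal(mods$modularity, 2 * (10 / 21 - (21 / 42)^2), tolerance = 1e-12)

  # single clique: one module, Q = 0
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("v", 1:6)
  m1 <- detectModules(asNetwork(k6))
  expect_equal(m1$n_modules, 1)
  expect_equal(m1$modularity, 0)

  # determinism
  expect_identical(detectModules(net)$membership, mods$membership)
})

test_that("Zi-Pi roles: planted hub, even three-way connector, thresholds", {
  net <- asNetwork(ringHubGraph())
  roles <- nodeRoles(net, ringHubPartition())
  hub <- roles[roles$taxon == "m1_hub", ]
  expect_equal(hub$Zi, (24 - 96 / 25) / sqrt(mean((c(rep(3, 24), 24) - 96 / 25)^2)),
               tolerance = 1e-12)
  expect_equal(hub$Zi, 4.899, tolerance = 1e-3)
  expect_equal(hub$role, "module_hub")  # Pi small: 1 inter-module edge of 25
  ring <- roles[roles$taxon == "m1_r05", ]
  expect_equal(ring$role, "peripheral")
  expect_equal(ring$Pi, 0)  # all links inside its own module

  r3 <- nodeRoles(asNetwork(threeWayGraph()), threeWayPartition())
  focal <- r3[r3$taxon == "focal", ]
  expect_equal(focal$Pi, 2 / 3, tolerance = 1e-12)
  expect_equal(focal$role, "connector")

  # threshold equality goes to the lower class (cuts set to the node's own
  # exact values so the comparison is bitwise equality)
  r_eq <- nodeRoles(asNetwork(threeWayGraph()), threeWayPartition(),
                    zi_cut = focal$Zi, pi_cut = focal$Pi)
  expect_equal(r_eq[r_eq$taxon == "focal", "role"], "peripheral")

  # keystone set = non-peripheral; classification invariant to relabeling
  part2 <- threeWayPartition()
  part2[] <- c(7L, 3L, 9L)[part2]  # rename modules 1/2/3 -> 7/3/9
  r3b <- nodeRoles(asNetwork(threeWayGraph()), part2)
  expect_equal(r3b$role, r3$role)
  expect_identical(r3$keystone, r3$role != "peripheral")
})

test_that("stability responds to an urbanization-like gradient in the planted
           block strength (directional end-to-end property)", {
  urban <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  rho <- 0.97 - 0.45 * urban   # correlation strength decays with urbanization
  rob <- numeric(5); vul <- numeric(5)
  for (i in 1:5) {
    bt <- simulateBlockTable(n_samples = 40, n_blocks = 3, block_size = 8,
                             rho = rho[i], n_noise = 4, seed = 50 + i)
    net <- buildNetwork(bt)
    rob[i] <- robustness(net, 0.5, n_reps = 100, seed = i)$robustness_mean
    vul[i] <- vulnerability(net)$vulnerability
  }
  expect_lt(cor(urban, rob, method = "spearman"), 0)
  expect_gt(cor(urban, vul, method = "spearman"), 0)
})
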