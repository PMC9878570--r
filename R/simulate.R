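#' Simulate a pure-birth (Yule) phylogeny over the taxon set
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed (substream `"tree"`).
#' @param taxon_ids optional tip labels; defaults to `t0001`, `t0002`, ...
#' @return A rooted `phylo` with strictly positive branch lengths.
#' @export
simulateTree <- function(n_taxa, seed = 1L, taxon_ids = NULL) {
  stopifnot(n_taxa >= 2)
  if (is.null(taxon_ids))
    taxon_ids <- sprintf("t%04d", seq_len(n_taxa))
  stopifnot(length(taxon_ids) == n_taxa)
  tree <- withSubstream(seed, "tree",
                        ape::rphylo(n_taxa, birth = 1, death = 0))
  tree$tip.label <- taxon_ids
  tree
}

# Metacommunity relative abundances. "logseries": species abundances drawn
# from the logarithmic distribution with parameter x (long right tail typical
# of 16S surveys); "lognormal": exp(N(meanlog, sdlog)). Normalized to sum 1.
metacommunityAbundances <- function(n_taxa, dist = c("logseries", "lognormal"),
                                    x = 0.999, meanlog = 0, sdlog = 1.5) {
  dist <- match.arg(dist)
  if (dist == "logseries") {
    # inverse-CDF draw from P(k) = -x^k / (k log(1 - x))
    u <- stats::runif(n_taxa)
    kmax <- 100000L
    k <- seq_len(kmax)
    pk <- -x^k / (k * log1p(-x))
    cdf <- cumsum(pk)
    ab <- findInterval(u * cdf[kmax], cdf) + 1
  } else {
    ab <- stats::rlnorm(n_taxa, meanlog, sdlog)
  }
  ab / sum(ab)
}

#' Simulate neutrally assembled local communities (Hubbell model)
#'
#' Each sample is an independent local community of `J` individuals:
#' initialized as a multinomial draw from the metacommunity, then evolved
#' through `burnin_factor * J` zero-sum death-replacement events in which the
#' replacement is an immigrant from the metacommunity with probability `m`
#' and a local birth otherwise.
#'
#' @param n_samples number of local communities.
#' @param n_taxa metacommunity richness.
#' @param J local community size (>= 100).
#' @param m migration (immigration) rate in (0, 1].
#' @param meta_dist `"logseries"` (default) or `"lognormal"`.
#' @param burnin_factor death-replacement events per individual (default 25).
#' @param seed integer master seed (substream `"neutral"`).
#' @param taxon_ids optional taxon names matching a simulated tree.
#' @return An [AbundanceTable-class] whose rows each sum to `J`; the
#'   metacommunity relative abundances are attached as attribute `"meta"`.
#' @export
simulateNeutralCommunities <- function(n_samples, n_taxa, J = 1000L, m = 0.3,
                                       meta_dist = "logseries",
                                       burnin_factor = 25L, seed = 1L,
                                       taxon_ids = NULL) {
  stopifnot(J >= 100, m > 0, m <= 1, n_samples >= 1, n_taxa >= 2)
  if (is.null(taxon_ids)) taxon_ids <- sprintf("t%04d", seq_len(n_taxa))
  out <- withSubstream(seed, "neutral", {
    meta <- metacommunityAbundances(n_taxa, meta_dist)
    steps <- as.integer(burnin_factor) * as.integer(J)
    x <- matrix(0L, n_samples, n_taxa)
    for (i in seq_len(n_samples)) {
      init <- as.integer(stats::rmultinom(1, J, meta))
      x[i, ] <- .hubbell_steps(init, meta, m, steps)
    }
    list(x = x, meta = meta)
  })
  tab <- out$x
  dimnames(tab) <- list(sprintf("s%03d", seq_len(n_samples)), taxon_ids)
  res <- AbundanceTable(tab)
  attr(res, "meta") <- out$meta
  res
}

#' Simulate deterministically (niche) assembled communities
#'
#' Each taxon carries a niche optimum; a sample at environmental position
#' `env` is a multinomial draw of `J` individuals with probabilities
#' proportional to metacommunity abundance times a Gaussian niche kernel
#' exp(-(env - optimum)^2 / (2 sigma^2)). Small `sigma` means strong
#' environmental filtering. When a `tree` is supplied the optima are assigned
#' along the ladderized tip order of the phylogeny (mapped onto \[0, 1\]), the
#' limiting case of perfect niche conservatism: filtering then selects
#' phylogenetically clustered sets of taxa, so the deterministic signature is
#' visible to phylogenetic stochasticity measures. Without a tree the optima
#' are i.i.d. uniform (no phylogenetic signal).
#'
#' @param env numeric vector of environmental positions (e.g. urban_degree),
#'   one per sample, in \[0, 1\].
#' @param n_taxa metacommunity richness.
#' @param J reads per sample.
#' @param sigma niche breadth (> 0), in gradient units.
#' @param tree optional `phylo` over the taxa for trait conservatism.
#' @param meta_dist metacommunity distribution, as in
#'   [simulateNeutralCommunities()].
#' @param seed integer master seed (substream `"niche"`).
#' @param taxon_ids optional taxon names (default: the tree's tips, else
#'   `t0001`...).
#' @return An [AbundanceTable-class]; attribute `"optima"` carries the niche
#'   optima used.
#' @export
simulateNicheCommunities <- function(env, n_taxa, J = 1000L, sigma = 0.05,
                                     tree = NULL, meta_dist = "logseries",
                                     seed = 1L, taxon_ids = NULL) {
  stopifnot(sigma > 0, J >= 1, n_taxa >= 2, length(env) >= 1)
  if (is.null(taxon_ids))
    taxon_ids <- if (!is.null(tree)) tree$tip.label else sprintf("t%04d", seq_len(n_taxa))
  stopifnot(length(taxon_ids) == n_taxa)
  out <- withSubstream(seed, "niche", {
    meta <- metacommunityAbundances(n_taxa, meta_dist)
    if (is.null(tree)) {
      opt <- stats::runif(n_taxa)
      names(opt) <- taxon_ids
    } else {
      # perfect conservatism: optimum = position in the ladderized tip order
      lad <- ape::ladderize(tree)
      tips_in_order <- lad$tip.label[lad$edge[lad$edge[, 2] <= ape::Ntip(lad), 2]]
      opt <- stats::setNames(
        (match(tree$tip.label, tips_in_order) - 1) / (ape::Ntip(tree) - 1),
        tree$tip.label)
      opt <- opt[taxon_ids]
    }
    x <- matrix(0L, length(env), n_taxa)
    for (i in seq_along(env)) {
      w <- meta * exp(-(env[i] - opt)^2 / (2 * sigma^2))
      if (sum(w) <= 0) w <- meta  # gradient position outside every niche
      x[i, ] <- as.integer(stats::rmultinom(1, J, w / sum(w)))
    }
    list(x = x, opt = opt)
  })
  tab <- out$x
  dimnames(tab) <- list(sprintf("s%03d", seq_along(env)), taxon_ids)
  res <- AbundanceTable(tab)
  attr(res, "optima") <- out$opt
  res
}

#' Fast Sloan-model occupancy generator
#'
#' Direct generator whose occupancy obeys the Sloan neutral prediction
#' exactly in expectation: each taxon draws a mean relative abundance `p`
#' from the abundance distribution; each sample then draws a relative
#' abundance x from Beta(N m p, N m (1 - p)) and stores the count
#' round(N * x). A taxon is therefore detected (count >= 1) exactly when
#' x >= 0.5/N, i.e. the generator's detection limit is half a read; pass
#' `d = 0.5/N` when fitting these tables with [fitNCM()] (the value is
#' attached as attribute `"detection_limit"`). Rounding keeps the count
#' totals essentially unbiased for N*x, so count-derived mean abundances
#' match the generating `p`.
#'
#' @param n_taxa,n_samples dimensions.
#' @param N community size / sequencing depth (>= 100).
#' @param m migration rate in (0, 1].
#' @param abund_dist `"lognormal"` (default) or `"logseries"` mean-abundance
#'   distribution.
#' @param seed integer master seed (substream `"sloan"`).
#' @return An [AbundanceTable-class]; attribute `"p"` carries the true mean
#'   relative abundances.
#' @export
simulateSloanOccupancy <- function(n_taxa, n_samples, N = 33187, m = 0.078,
                                   abund_dist = "lognormal", seed = 1L) {
  stopifnot(N >= 100, m > 0, m <= 1, n_taxa >= 2, n_samples >= 2)
  out <- withSubstream(seed, "sloan", {
    p <- metacommunityAbundances(n_taxa, abund_dist)
    # guard the open interval (0, 1)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    x <- matrix(0L, n_samples, n_taxa)
    for (j in seq_len(n_taxa)) {
      rel <- stats::rbeta(n_samples, N * m * p[j], N * m * (1 - p[j]))
      x[, j] <- as.integer(round(N * rel))
    }
    list(x = x, p = p)
  })
  tab <- out$x
  dimnames(tab) <- list(sprintf("s%03d", seq_len(n_samples)),
                        sprintf("t%04d", seq_len(n_taxa)))
  res <- AbundanceTable(tab)
  attr(res, "p") <- out$p
  attr(res, "detection_limit") <- 0.5 / N
  res
}

#' Simulate a block-correlated abundance table with optional planted hubs
#'
#' Log-normal abundances driven by one latent Gaussian factor per block:
#' taxa in the same block share the factor with loading sqrt(rho) (pairwise
#' latent correlation rho); different blocks are independent. With
#' `hub_per_block = TRUE` a weak common factor (loading sqrt(tau)) is shared
#' by all block factors and one extra hub taxon per block tracks that common
#' factor directly, so each hub correlates moderately with every block
#' (planting connectors) while cross-block taxon-taxon correlations stay
#' below the usual 0.6 edge threshold. Because correlations are computed on
#' relative abundances, hub mode also (i) appends 40 independent background
#' taxa carrying most of the reads, so compositional closure does not
#' subtract the shared factor back out of every taxon, and (ii) narrows the
#' base-abundance spread. Separating the hub-block correlation (about
#' sqrt(rho * tau)) from the cross-block one (about rho * tau) around a 0.6
#' edge threshold additionally needs large sample counts (around 150),
#' because the sampling error of a Spearman estimate is about 1/sqrt(n - 3).
#'
#' @param n_samples number of samples (>= 4).
#' @param n_blocks,block_size planted module structure.
#' @param rho within-block latent correlation in \[0, 1).
#' @param n_noise additional independent (unstructured) taxa.
#' @param hub_per_block plant one connector hub per block.
#' @param tau common-factor share when hubs are planted (default 0.6).
#' @param depth reads per sample (multinomial thinning).
#' @param seed integer master seed (substream `"blocks"`).
#' @return An [AbundanceTable-class]; attribute `"blocks"` is the ground-truth
#'   assignment (named integer vector; 0 = noise/background taxa, -1 = hubs).
#' @export
simulateBlockTable <- function(n_samples = 30L, n_blocks = 3L, block_size = 10L,
                               rho = 0.9, n_noise = 5L, hub_per_block = FALSE,
                               tau = 0.6, depth = 50000L, seed = 1L) {
  stopifnot(rho >= 0, rho < 1, n_samples >= 4)
  n_struct <- n_blocks * block_size
  n_hub <- if (hub_per_block) n_blocks else 0L
  n_real <- n_struct + n_hub + n_noise
  n_bg <- if (hub_per_block) 40L else 0L
  n_taxa <- n_real + n_bg
  out <- withSubstream(seed, "blocks", {
    common <- stats::rnorm(n_samples)
    tau_eff <- if (hub_per_block) tau else 0
    gb <- sapply(seq_len(n_blocks), function(b)
      sqrt(tau_eff) * common + sqrt(1 - tau_eff) * stats::rnorm(n_samples))
    z <- matrix(0, n_samples, n_real)
    block_of <- integer(n_real)
    idx <- 1L
    for (b in seq_len(n_blocks)) {
      for (t in seq_len(block_size)) {
        z[, idx] <- sqrt(rho) * gb[, b] + sqrt(1 - rho) * stats::rnorm(n_samples)
        block_of[idx] <- b
        idx <- idx + 1L
      }
    }
    if (hub_per_block) for (b in seq_len(n_blocks)) {
      z[, idx] <- common + 0.05 * stats::rnorm(n_samples)
      block_of[idx] <- -1L
      idx <- idx + 1L
    }
    if (n_noise > 0) for (t in seq_len(n_noise)) {
      z[, idx] <- stats::rnorm(n_samples)
      block_of[idx] <- 0L
      idx <- idx + 1L
    }
    # taxon base log-abundances; a narrow spread in hub mode keeps every
    # structured taxon's counts large enough for stable Spearman ranks
    mu <- stats::rnorm(n_real, 0, if (hub_per_block) 0.5 else 1)
    ab <- exp(sweep(z, 2, mu, "+"))
    if (n_bg > 0) {
      # independent background holding ~6x the structured mass, spread over
      # many taxa so the log of the sample total is nearly constant
      bg_scale <- 6 * n_real / n_bg * exp(0.5)
      bg <- bg_scale * exp(matrix(stats::rnorm(n_samples * n_bg),
                                  n_samples, n_bg))
      ab <- cbind(ab, bg)
      block_of <- c(block_of, rep(0L, n_bg))
    }
    x <- t(apply(ab, 1, function(w) stats::rmultinom(1, depth, w / sum(w))))
    list(x = x, block_of = block_of)
  })
  ids <- sprintf("t%04d", seq_len(n_taxa))
  tab <- out$x
  dimnames(tab) <- list(sprintf("s%03d", seq_len(n_samples)), ids)
  res <- AbundanceTable(tab)
  attr(res, "blocks") <- stats::setNames(out$block_of, ids)
  res
}

#' Simulate a study-design metadata table
#'
#' Assigns each sample a habitat (U/W), host species, organ and environmental
#' covariates; `urban_degree` is high (0.6-1) in U and low (0-0.4) in W.
#'
#' @param sample_ids character vector of sample ids.
#' @param seed integer seed (substream `"metadata"`).
#' @return data.frame with rownames = sample ids and columns habitat, host,
#'   organ, urban_degree, PH, AT, bio_3, bio_18.
#' @export
simulateStudyMetadata <- function(sample_ids, seed = 1L) {
  n <- length(sample_ids)
  withSubstream(seed, "metadata", {
    habitat <- rep(c("U", "W"), length.out = n)
    df <- data.frame(
      habitat = habitat,
      host = sample(c("BG", "FM", "PN"), n, replace = TRUE),
      organ = sample(c("G", "SK"), n, replace = TRUE),
      urban_degree = ifelse(habitat == "U",
                            stats::runif(n, 0.6, 1), stats::runif(n, 0, 0.4)),
      PH = stats::rnorm(n, 7, 0.5),
      AT = stats::rnorm(n, 18, 3),
      bio_3 = stats::rnorm(n, 30, 5),
      bio_18 = stats::rnorm(n, 500, 100),
      row.names = sample_ids, stringsAsFactors = FALSE)
    df
  })
}
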