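---
title: "Quantifying assembly stochasticity and co-occurrence network stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying assembly stochasticity and co-occurrence network stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in **assemblyNet**, the
estimators and their numerical details, the design of the synthetic data
generators used to validate them, and the known limitations. All code chunks
are illustrative and not evaluated at build time; the package's behavior is
verified by its test suite and by `scripts/acceptance.R`.

## 1. The Sloan neutral community model

### Model

Sloan's continuous approximation to neutral community dynamics predicts, for
a metacommunity taxon with mean relative abundance $p$, that its relative
abundance $x$ across local communities of size $N$ with migration rate $m$
is Beta-distributed:

$$x \sim \mathrm{Beta}\big(Nmp,\; Nm(1-p)\big).$$

With a detection limit $d$ (the smallest relative abundance that registers
as presence), the predicted occurrence frequency is

$$\hat F(p) = 1 - I_d\big(Nmp, Nm(1-p)\big),$$

the complement of the regularized incomplete beta function at $d$
(`predictOccupancy()`). The single free shape parameter is the product
$Nm$; `fitNCM()` fixes $N$ from the data and estimates $m$.

### Estimation choices

- **Inputs.** For each taxon, mean relative abundance $\bar p_i$ and
  occurrence frequency $F_i$ across samples. $N$ defaults to the mean
  sample depth; it can be overridden with the `N` argument, in which case
  the fitted `m` for a given `d` is invariant to rescaling all counts
  (useful when comparing tables at different depths). $d$ defaults to
  $1/N$ (one read).
- **Optimization.** $R^2(m) = 1 - SS_{res}/SS_{tot}$, with $SS_{tot}$ taken
  about the mean observed frequency, is maximized over a 120-point
  logarithmic grid on $m \in [10^{-6}, 1]$ followed by `optimize()`
  (tolerance $10^{-8}$) on the bracketing interval. The grid stage guards
  against the flat/multimodal profiles that occur when occupancy is nearly
  saturated. $R^2$ can be negative; a fit with non-finite $R^2$ (e.g. all
  taxa at frequency 1) is flagged non-identifiable with a warning.
- **Envelope.** The 95% prediction envelope uses Wilson score intervals for
  $\hat F(p)$ at the number of samples, and taxa are partitioned into
  above / within / below.

```{r}
tab <- simulateSloanOccupancy(2000, 60, N = 33187, m = 0.078, seed = 1)
fit <- fitNCM(tab, d = attr(tab, "detection_limit"))
ncmSummary(fit)
```

## 2. betaMNTD, the null model, and pNST

### Observed dissimilarity

For communities $i, j$ with relative abundances $f$, the abundance-weighted
between-community mean nearest-taxon distance is

$$D_{ij} = \tfrac12 \Big( \sum_a f_{ia}\,\min_{b \in j} d_{ab}
                        + \sum_b f_{jb}\,\min_{a \in i} d_{ab} \Big),$$

with $d_{ab}$ the patristic (cophenetic) distance. `betaMNTD()` computes
per-sample columnwise minima over the cophenetic matrix followed by one
matrix product, and agrees with `picante::comdistnt(abundance.weighted =
TRUE)` to machine precision (verified in the tests).

### Null model and NST

The null randomizes taxon identities on the tips of the phylogeny while
holding every community's abundance structure fixed — implemented as a
permutation of the columns of the abundance matrix against the fixed
distance matrix. `nullDissimilarity()` draws `n_null` such randomizations
(default 1000; the acceptance runs use 200 for speed, which the tests show
is already stable at the reported margins).

Dissimilarities are normalized to $[0, 1]$ by the maximum patristic
distance, and for each pair the normalized stochasticity ratio compares the
observed value $C$ with the null expectation $E$:

$$\mathrm{NST}_{ij} =
\begin{cases}
(1 - C)/(1 - E) & C \ge E \quad (\text{more similar than the null})\\
C / E & C < E \quad (\text{more dissimilar than the null})
\end{cases}$$

so that 1 means "indistinguishable from the null" (fully stochastic) and 0
means maximal departure in either direction (deterministic attraction or
repulsion). Degenerate $0/0$ ratios are taken as 1. `pNST()` averages NST
over within-group pairs; values above 0.5 read as stochastic assembly,
below 0.5 as deterministic.

## 3. Co-occurrence networks

- **Filtering** (`filterTaxa()`): keep taxa with overall relative abundance
  strictly above $10^{-4}$ and detected in at least
  $\lceil 0.10\,n \rceil$ samples.
- **Edges** (`buildNetwork()`): Spearman correlations on relative
  abundances; an edge requires $|r| > 0.6$ and Benjamini–Hochberg adjusted
  $p < 0.01$. p-values use the t approximation
  $t = r\sqrt{(n-2)/(1-r^2)}$, adequate at the sample sizes where a
  correlation network is sensible ($n \ge 4$ enforced; in practice tens of
  samples). Correlations are computed once on a vectorized rank matrix.
- **Topology** (`networkTopology()`): density, degree/betweenness
  centralization, mean shortest path on the largest component, global
  clustering coefficient, greedy modularity, and degree statistics.
  `powerlawFit()` fits $\log \mathrm{freq}(k) \sim \log k$ by OLS and
  reports slope and $R^2$ (at least 3 distinct degrees required).
- **Per-sample subnetworks** (`sampleSubnetwork()`): the induced subgraph
  on the taxa present in one sample, with the same topology record.

### Stability

- **Robustness** (`robustness()`): remove $\lfloor f\,n \rfloor$ random
  nodes, then iteratively prune nodes left with no neighbors; the
  surviving fraction, averaged over replicates, is the robustness at
  removal fraction $f$. On a complete graph this equals $1 - f$ exactly; on
  a perfect matching it has a closed hypergeometric form — both are test
  oracles.
- **Vulnerability** (`vulnerability()`): global efficiency $E$ is the mean
  of $1/d_{uv}$ over ordered pairs (disconnected pairs contribute 0);
  vulnerability is $\max_i (E - E_{-i})/E$ over single-node deletions.
- **Modules and roles** (`detectModules()`, `nodeRoles()`): fast-greedy
  modularity with one robustness correction — the membership cut returned
  by igraph can drift below the single-community $Q = 0$ on dense graphs
  through floating-point error in the merge bookkeeping, so the package
  recomputes $Q$ at every dendrogram cut and keeps the maximum (ties go to
  the coarser partition). Zi is the within-module degree z-score using the
  population (divide-by-$n$) standard deviation; $P_i = 1 - \sum_s
  (k_{is}/k_i)^2$. Thresholds 2.5 and 0.62 with equality assigned to the
  lower class; connectors, module hubs and network hubs are keystones.

## 4. Supporting statistics

- `permanovaTest()` computes the PERMANOVA pseudo-F directly from squared
  dissimilarities; `anosimTest()` uses the rank statistic
  $R = (\bar r_B - \bar r_W)/(M/2)$. Both use add-one permutation p-values
  $(1 + \#\{F^\pi \ge F\})/(1 + n_{perm})$ and support exact enumeration of
  all label assignments on small designs ($n \le 10$), which the tests use
  as an oracle (cross-checked against `vegan::adonis2` / `vegan::anosim`).
- `brunnerMunzel()` implements the Brunner–Munzel rank statistic with
  Satterthwaite degrees of freedom; `kruskalPosthoc()` runs it pairwise
  after a Kruskal–Wallis omnibus, with BH adjustment. `wilcoxonFDR()` uses
  exact Wilcoxon p-values for $n \le 20$ without ties, normal approximation
  otherwise.
- `rdaAnalysis()` wraps `vegan::rda` (optionally Hellinger-transformed)
  and reports constrained axis fractions and a collinearity check.

## 5. Synthetic generator design

Each generator plants exactly the signal its analysis is supposed to
detect, so that the pipeline can be validated end to end without any
external data.

- **`simulateNeutralCommunities()`** is an individual-based Hubbell/Moran
  model (Rcpp kernel): each community starts as a multinomial draw from a
  metacommunity (log-series by default) and undergoes $25 J$ zero-sum
  death–replacement events, replacing with an immigrant with probability
  $m$. Burn-in of $25 J$ events ($25$ turnovers per individual) is well past
  the point where summary statistics stop drifting.
- **`simulateNicheCommunities()`** weights the metacommunity by a Gaussian
  kernel $\exp(-(env - opt)^2 / 2\sigma^2)$. When a tree is supplied, the
  optima are the positions of the tips in the *ladderized tip order* of the
  phylogeny mapped onto $[0,1]$ — the limiting case of perfect niche
  conservatism. This matters: with phylogenetically random optima,
  environmental filtering selects a phylogenetically random subset and
  betaMNTD-based pNST cannot see the determinism. Tip-order optima make
  filtering select clades, which is precisely the signal betaMNTD measures.
- **`simulateSloanOccupancy()`** draws each taxon-sample relative abundance
  from the fitted beta form and stores `round(N * x)` reads. Rounding makes
  the generator's detection limit exactly half a read, $d = 0.5/N$
  (attached as attribute `"detection_limit"`), and keeps count-derived mean
  abundances unbiased for the generating $p$; fitting with that $d$
  recovers $m$ to within a few percent, whereas a floor/ceiling generator
  or a mismatched $d$ biases $\hat m$ upward by 10–20%.
- **`simulateBlockTable()`** drives log-normal abundances with one latent
  Gaussian factor per block (within-block latent correlation `rho`),
  multinomially thinned to a fixed depth. With `hub_per_block = TRUE` the
  block factors share a weak common factor (share `tau = 0.6`) and each hub
  tracks that common factor, so hub–block correlations
  ($\approx\sqrt{\rho\tau} \approx 0.73$) clear the 0.6 edge threshold
  while cross-block correlations ($\approx \rho\tau \approx 0.54$) stay
  below it. Two compositional subtleties are handled explicitly:
  1. Correlations are computed on *relative* abundances. If the structured
     taxa dominate the sample total, dividing by that total subtracts the
     common factor back out of every taxon and the hub signal collapses.
     Hub mode therefore appends 40 independent background taxa holding
     about six times the structured mass, making the log sample total
     nearly constant.
  2. A Spearman estimate has sampling error $\approx 1/\sqrt{n-3}$ on the
     Fisher scale, so separating 0.73 from 0.54 around a 0.6 threshold
     needs on the order of 150 samples; with 30 samples both distributions
     straddle the cut and hub recovery is unreliable.
- **Seeding.** All generators draw from named substreams of a single master
  seed (`substreamSeed()`, an FNV-style hash folded below $2^{31}$), so
  pipelines are bit-reproducible per seed and components can be re-run
  independently without disturbing each other's streams.

## 6. Numerical choices, problem sizes, and limitations

- **Moran vs. Sloan mismatch.** Fitting the Sloan model to Hubbell/Moran
  simulations recovers `m` only qualitatively: the stationary beta
  concentration of the Moran model is $m(J-1)/(1-m)$, not $Jm$, so at
  moderate `m` the fitted value sits above the simulation parameter (the
  README example fits $\hat m = 0.14$ at simulation $m = 0.1$). Fitted `m`
  from the occupancy generator, whose data-generating process is the Sloan
  model itself, is recovered accurately; the tests therefore check
  monotonicity in `m` for Hubbell data and quantitative recovery (±15%)
  only for the occupancy generator.
- **Compositionality.** Spearman networks on relative abundances inherit
  the usual compositional caveats; the package applies the conventional
  thresholded-correlation definition rather than compositional
  alternatives, and its generators show how closure can both destroy (hub
  planting) and create (shared-total noise) correlation signal.
- **Permutation p-values** are add-one and hence never smaller than
  $1/(n_{perm}+1)$; type-I error at $\alpha = 0.05$ with 199 permutations
  is exact by construction and verified empirically in the tests
  ([0.03, 0.07] over 1000 null simulations).
- **Problem sizes.** The implementation targets study-scale inputs: up to a
  few hundred samples, a few thousand taxa for the NCM, a few hundred taxa
  for cophenetic/betaMNTD work ($O(T^2)$ memory for the distance matrix),
  and networks of up to a few thousand nodes. The full test suite runs in
  about a minute; the acceptance script in about ten seconds.
- **Ties.** Spearman p-values use the t approximation throughout (exact
  permutation p-values for rank correlations with ties are not attempted);
  Wilcoxon falls back to the normal approximation when ties are present.
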