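#' Batch Wilcoxon rank-sum tests with Benjamini-Hochberg correction
#'
#' One two-sided Mann-Whitney/Wilcoxon test per response variable between the
#' two levels of `groups`, with BH adjustment across the batch. The exact
#' null distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie correction
#' (and no continuity correction) is used.
#'
#' @param values numeric matrix or data.frame, samples x variables (a vector
#'   is treated as a single variable).
#' @param groups two-level factor/character vector, one entry per sample.
#' @return data.frame: variable, group_a, group_b, statistic, p, p_adj, method.
#' @export
wilcoxonFDR <- function(values, groups) {
  if (is.vector(values)) values <- matrix(values, ncol = 1,
                                          dimnames = list(NULL, "value"))
  values <- as.matrix(values)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("wilcoxonFDR requires exactly two groups")
  groups <- droplevels(groups)
  lv <- levels(groups)
  if (any(table(groups) == 0)) stop("both groups must be non-empty")
  res <- lapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    a <- v[groups == lv[1]]; b <- v[groups == lv[2]]
    if (length(unique(v)) == 1L) {
      warning("variable '", colnames(values)[j], "' is constant; p = 1")
      return(data.frame(statistic = length(a) * length(b) / 2, p = 1,
                        method = "wilcoxon_degenerate"))
    }
    ties <- anyDuplicated(v) > 0
    exact <- (length(v) <= 20L) && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = FALSE))
    data.frame(statistic = unname(wt$statistic), p = wt$p.value,
               method = if (exact) "wilcoxon_exact" else "wilcoxon_normal")
  })
  out <- do.call(rbind, res)
  data.frame(variable = colnames(values) %||% paste0("V", seq_len(ncol(values))),
             group_a = lv[1], group_b = lv[2],
             statistic = out$statistic, p = out$p,
             p_adj = stats::p.adjust(out$p, method = "BH"),
             method = out$method, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brunner-Munzel test (nonparametric Behrens-Fisher problem)
#'
#' Tests H0: P(X < Y) + 0.5 P(X = Y) = 1/2 without assuming equal variances
#' or distributional shape, using the rank-based statistic with Satterthwaite
#' degrees of freedom.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list: statistic, df, p (two-sided), estimate (the relative effect
#'   P(X < Y) + 0.5 P(X = Y)).
#' @export
brunnerMunzel <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("Brunner-Munzel needs at least 2 values per group")
  N <- n1 + n2
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  rx <- rank(x); ry <- rank(y)
  m1 <- mean(r1); m2 <- mean(r2)
  v1 <- sum((r1 - rx - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - ry - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  pst <- (m2 - (n2 + 1) / 2) / n1  # estimate of P(X<Y)+.5P(X=Y)
  denom <- sqrt(n1 * v1 + n2 * v2)
  if (denom == 0) {
    # identical rank configurations within groups (e.g. fully tied data)
    return(list(statistic = 0, df = NA_real_, p = 1, estimate = pst))
  }
  stat <- n1 * n2 * (m2 - m1) / (N * denom)
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  list(statistic = unname(stat), df = df, p = min(1, p), estimate = pst)
}

#' Kruskal-Wallis omnibus test with Brunner-Munzel post hoc comparisons
#'
#' The omnibus is the tie-corrected Kruskal-Wallis H with a chi-square
#' p-value. All pairwise group comparisons are then run as Brunner-Munzel
#' tests (the nonparametric Behrens-Fisher procedure) with BH adjustment;
#' pairs involving a group of fewer than 2 observations are skipped with a
#' warning.
#'
#' @param values numeric vector.
#' @param groups factor/character with k >= 2 levels.
#' @return list with `omnibus` (data.frame: statistic, df, p, method) and
#'   `pairwise` (data.frame: group_a, group_b, statistic, p, p_adj, method).
#' @export
kruskalPosthoc <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (length(unique(values)) == 1L) {
    omni <- data.frame(statistic = 0, df = k - 1, p = 1,
                       method = "kruskal_wallis", stringsAsFactors = FALSE)
  } else {
    kw <- stats::kruskal.test(values, groups)
    omni <- data.frame(statistic = unname(kw$statistic),
                       df = unname(kw$parameter), p = kw$p.value,
                       method = "kruskal_wallis", stringsAsFactors = FALSE)
  }
  combos <- utils::combn(levels(groups), 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    va <- values[groups == a]; vb <- values[groups == b]
    if (length(va) < 2 || length(vb) < 2) {
      warning("skipping pair ", a, " vs ", b, ": group with < 2 observations")
      return(NULL)
    }
    if (length(unique(c(va, vb))) == 1L)
      return(data.frame(group_a = a, group_b = b, statistic = 0, p = 1,
                        method = "brunner_munzel", stringsAsFactors = FALSE))
    bm <- brunnerMunzel(va, vb)
    data.frame(group_a = a, group_b = b, statistic = bm$statistic, p = bm$p,
               method = "brunner_munzel", stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  if (!is.null(pw) && nrow(pw)) pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
  list(omnibus = omni, pairwise = pw)
}

#' Spearman rank correlation with significance test
#'
#' Pearson correlation of mid-ranks; the p-value uses the exact permutation
#' distribution for n <= 9 without ties, otherwise the t approximation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return data.frame: statistic (rho), p, n, method.
#' @export
spearmanCorr <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation is undefined for a constant vector")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- n <= 9 && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  data.frame(statistic = unname(ct$estimate), p = ct$p.value, n = n,
             method = if (exact) "spearman_exact" else "spearman_t",
             stringsAsFactors = FALSE)
}
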