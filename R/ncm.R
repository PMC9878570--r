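#' Sloan neutral-model occupancy prediction
#'
#' Predicted probability that a taxon of mean relative abundance `p` is
#' detected (relative abundance above the detection limit `d`) in a local
#' community of `N` individuals receiving immigrants at rate `m`:
#' 1 - B(d; N m p, N m (1 - p)) with B the regularized incomplete beta
#' function.
#'
#' @param p mean relative abundance, in (0, 1) (vectorized).
#' @param N local community size / sequencing depth (>= 1).
#' @param m migration rate, in (0, 1].
#' @param d detection limit, in (0, 1); defaults to one read, 1/N.
#' @return Predicted occurrence frequency in \[0, 1\].
#' @export
predictOccupancy <- function(p, N, m, d = 1 / N) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  if (N < 1) stop("N must be >= 1")
  if (m <= 0 || m > 1) stop("m must lie in (0, 1]")
  if (d <= 0 || d >= 1) stop("d must lie strictly inside (0, 1)")
  stats::pbeta(d, N * m * p, N * m * (1 - p), lower.tail = FALSE)
}

#' Fit the Sloan neutral community model
#'
#' For every taxon, the observed occurrence frequency (fraction of samples
#' with at least one read) is paired with its mean relative abundance; the
#' migration rate m is then estimated by bounded least squares of observed
#' against predicted frequency over m in (0, 1), using a deterministic
#' log-spaced multi-start grid refined by golden-section search (tolerance
#' 1e-8). R^2 = 1 - SSE/SST with SST about the mean observed frequency and
#' may be negative. Taxa are partitioned against the 95% Wilson binomial
#' envelope around the predicted frequency at the observed number of samples.
#'
#' @param table an [AbundanceTable-class] with at least 5 taxa present.
#' @param d detection limit; defaults to 1/N (one read). Tables produced by
#'   [simulateSloanOccupancy()] have detection limit 0.5/N (see there).
#' @param conf_level confidence level of the Wilson envelope.
#' @param N local community size; defaults to the (uniform) sample depth, or
#'   the mean depth with a warning. Supply it explicitly when sequencing
#'   depth and community size differ (m is then estimated at that N, making
#'   the fit invariant to a constant rescaling of all counts).
#' @return An [NCMFit-class].
#' @export
fitNCM <- function(table, d = NULL, conf_level = 0.95, N = NULL) {
  stopifnot(is(table, "AbundanceTable"))
  x <- counts(table)
  depths <- rowSums(x)
  if (any(depths == 0)) stop("all-zero sample(s) present; rarefy/filter first")
  if (is.null(N)) {
    if (max(depths) - min(depths) > 1e-8) {
      N <- mean(depths)
      warning("sample depths are not uniform; using the mean depth N = ",
              format(N))
    } else N <- depths[[1]]
  }
  present <- colSums(x > 0) > 0
  x <- x[, present, drop = FALSE]
  if (ncol(x) < 5) stop("need at least 5 taxa present in at least 1 sample")
  n_samp <- nrow(x)
  p <- colMeans(sweep(x, 1, depths, "/"))
  freq <- colMeans(x > 0)
  if (all(freq == 1))
    warning("all taxa occur in every sample; the fit is non-identifiable")
  if (is.null(d)) d <- 1 / N
  sse <- function(m) {
    pred <- predictOccupancy(p, N, m, d)
    sum((freq - pred)^2)
  }
  # deterministic multi-start: coarse log grid, then golden-section refinement
  grid <- exp(seq(log(1e-5), log(1), length.out = 120))
  vals <- vapply(grid, sse, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(sse, lower = lo, upper = hi, tol = 1e-8)
  m_hat <- opt$minimum
  pred <- predictOccupancy(p, N, m_hat, d)
  sst <- sum((freq - mean(freq))^2)
  r2 <- if (sst > 0) 1 - opt$objective / sst else NA_real_
  ci <- wilsonInterval(pred, n_samp, conf_level)
  partition <- ifelse(freq > ci$upper, "above",
                      ifelse(freq < ci$lower, "below", "within"))
  taxa <- data.frame(taxon = colnames(x), mean_rel_abund = unname(p),
                     observed_freq = unname(freq), predicted_freq = unname(pred),
                     lower = ci$lower, upper = ci$upper,
                     partition = unname(partition), stringsAsFactors = FALSE)
  new("NCMFit", m = m_hat, N = as.numeric(N), Nm = as.numeric(N) * m_hat,
      r_squared = r2, detection_limit = d, taxa = taxa,
      n_samples = as.integer(n_samp))
}

# Wilson score interval for a proportion p_hat at sample size n.
wilsonInterval <- function(p_hat, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n
  center <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Summarize an NCM fit as a flat list
#'
#' @param fit an [NCMFit-class].
#' @return list with m, Nm, N, R2, n_taxa and the envelope partition counts.
#' @export
ncmSummary <- function(fit) {
  stopifnot(is(fit, "NCMFit"))
  tab <- table(factor(fit@taxa$partition, c("below", "within", "above")))
  list(m = fit@m, Nm = fit@Nm, N = fit@N, R2 = fit@r_squared,
       n_taxa = nrow(fit@taxa),
       partition_counts = as.list(stats::setNames(as.integer(tab), names(tab))))
}
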