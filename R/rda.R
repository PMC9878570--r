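#' Redundancy analysis of a community matrix on environmental covariates
#'
#' Centers both matrices, regresses the community on the covariates and
#' eigen-decomposes the fitted values (via [vegan::rda]); each constrained
#' axis is reported as its fraction of the total community variance.
#'
#' @param community samples x taxa numeric matrix (counts or relative
#'   abundances).
#' @param covariates samples x q numeric matrix/data.frame, q < n_samples,
#'   full column rank after centering.
#' @param transform `"none"` (default) or `"hellinger"`.
#' @return list of class `RDAResult`: `axis_fractions` (constrained axes,
#'   non-increasing), `constrained_fraction` (their sum), `site_scores`,
#'   `covariate_scores`, `fit` (the underlying vegan object).
#' @export
rdaAnalysis <- function(community, covariates, transform = c("none", "hellinger")) {
  transform <- match.arg(transform)
  community <- as.matrix(community)
  covariates <- as.data.frame(covariates)
  if (!all(vapply(covariates, is.numeric, logical(1))))
    stop("all covariates must be numeric")
  q <- ncol(covariates)
  if (q >= nrow(community)) stop("need fewer covariates than samples")
  cc <- scale(as.matrix(covariates), center = TRUE, scale = FALSE)
  qr_rank <- qr(cc)$rank
  if (qr_rank < q) {
    # name columns not adding rank
    keep <- qr(cc)$pivot[seq_len(qr_rank)]
    stop("rank-deficient covariates; collinear column(s): ",
         paste(colnames(covariates)[setdiff(seq_len(q), keep)], collapse = ", "))
  }
  if (transform == "hellinger")
    community <- vegan::decostand(community, method = "hellinger")
  fit <- vegan::rda(community ~ ., data = covariates)
  eig <- fit$CCA$eig
  fractions <- as.numeric(eig) / fit$tot.chi
  structure(list(
    axis_fractions = fractions,
    constrained_fraction = sum(fractions),
    site_scores = vegan::scores(fit, display = "sites",
                                choices = seq_along(eig)),
    covariate_scores = vegan::scores(fit, display = "bp",
                                     choices = seq_along(eig)),
    fit = fit), class = "RDAResult")
}

#' @export
print.RDAResult <- function(x, ...) {
  cat("Redundancy analysis\n")
  cat(sprintf("  constrained variance fraction: %.4f\n", x$constrained_fraction))
  for (i in seq_along(x$axis_fractions))
    cat(sprintf("  RDA%d: %.4f (%.2f%%)\n", i, x$axis_fractions[i],
                100 * x$axis_fractions[i]))
  invisible(x)
}
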