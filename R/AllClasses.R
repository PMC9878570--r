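#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib assemblyNet, .registration = TRUE
NULL

setOldClass("igraph")
setOldClass("phylo")

#' AbundanceTable: a samples x taxa count matrix
#'
#' The central container of the package: integer counts with samples as rows
#' and taxa (OTUs/ASVs) as columns. Row and column names are the sample and
#' taxon identifiers and must be unique.
#'
#' @slot counts integer-valued matrix, samples x taxa, non-negative, with
#'   unique rownames (sample ids) and colnames (taxon ids).
#'
#' @examples
#' tab <- AbundanceTable(matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 2,
#'                              dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
#' nSamples(tab)
#' @export
setClass("AbundanceTable", representation(counts = "matrix"))

setValidity("AbundanceTable", function(object) {
  x <- object@counts
  msg <- character()
  if (!is.numeric(x)) msg <- c(msg, "counts must be numeric")
  if (nrow(x) < 1L || ncol(x) < 1L)
    msg <- c(msg, "need at least 1 sample and 1 taxon")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    msg <- c(msg, "counts must carry sample (row) and taxon (column) names")
  else {
    if (anyDuplicated(rownames(x)))
      msg <- c(msg, sprintf("duplicate sample ids: %s",
                            paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")))
    if (anyDuplicated(colnames(x)))
      msg <- c(msg, sprintf("duplicate taxon ids: %s",
                            paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")))
  }
  if (is.numeric(x)) {
    if (anyNA(x)) msg <- c(msg, "counts contain NA")
    else {
      if (any(x < 0)) msg <- c(msg, "negative counts are not allowed")
      if (any(x != round(x))) msg <- c(msg, "counts must be integral")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param counts numeric matrix of non-negative integral counts, samples as
#'   rows, taxa as columns, both dimensions named.
#' @return An [AbundanceTable-class] object.
#' @export
AbundanceTable <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("AbundanceTable", counts = counts)
}

#' NCMFit: a fitted Sloan neutral community model
#'
#' @slot m estimated migration rate in (0, 1].
#' @slot N sampling depth (reads per sample) used by the fit.
#' @slot Nm product N * m.
#' @slot r_squared coefficient of determination of observed vs predicted
#'   occurrence frequency (can be negative).
#' @slot detection_limit the relative-abundance detection limit d.
#' @slot taxa per-taxon data.frame: taxon, mean_rel_abund, observed_freq,
#'   predicted_freq, lower, upper, partition.
#' @slot n_samples number of samples the frequencies were computed over.
#' @export
setClass("NCMFit", representation(
  m = "numeric", N = "numeric", Nm = "numeric", r_squared = "numeric",
  detection_limit = "numeric", taxa = "data.frame", n_samples = "integer"))

setValidity("NCMFit", function(object) {
  msg <- character()
  if (object@m <= 0 || object@m > 1) msg <- c(msg, "m must lie in (0, 1]")
  if (abs(object@Nm - object@N * object@m) > 1e-8 * max(1, object@Nm))
    msg <- c(msg, "Nm must equal N * m")
  if (is.finite(object@r_squared) && object@r_squared > 1 + 1e-12)
    msg <- c(msg, "r_squared cannot exceed 1")
  need <- c("taxon", "mean_rel_abund", "observed_freq", "predicted_freq",
            "lower", "upper", "partition")
  if (!all(need %in% names(object@taxa)))
    msg <- c(msg, "taxa table is missing required columns")
  else {
    pf <- object@taxa$predicted_freq
    if (any(pf < -1e-12 | pf > 1 + 1e-12)) msg <- c(msg, "predicted_freq outside [0,1]")
    if (!all(object@taxa$partition %in% c("above", "within", "below")))
      msg <- c(msg, "partition labels must be above/within/below")
  }
  if (length(msg)) msg else TRUE
})

#' PNSTResult: phylogenetic normalized stochasticity ratio
#'
#' @slot pairs data.frame with one row per sample pair: sample_i, sample_j,
#'   group (NA for between-group pairs), observed, null_mean, NST, ST.
#' @slot groups data.frame with per-group mean NST (the group pNST) and the
#'   number of within-group pairs.
#' @slot n_null number of null randomizations used.
#' @export
setClass("PNSTResult", representation(
  pairs = "data.frame", groups = "data.frame", n_null = "integer"))

setValidity("PNSTResult", function(object) {
  msg <- character()
  nst <- object@pairs$NST
  if (any(nst < -1e-9 | nst > 1 + 1e-9)) msg <- c(msg, "NST values outside [0,1]")
  p <- object@groups$pNST
  if (length(p) && any(p < -1e-9 | p > 1 + 1e-9)) msg <- c(msg, "pNST outside [0,1]")
  if (length(msg)) msg else TRUE
})

#' CooccurrenceNetwork: a thresholded Spearman co-occurrence graph
#'
#' An undirected simple graph whose vertices are taxa and whose edges are
#' taxon pairs passing both the correlation-magnitude and the FDR thresholds.
#' Edge attributes: `r` (Spearman correlation) and `p_adj` (BH-adjusted p).
#'
#' @slot graph the underlying [igraph::igraph] object.
#' @slot corr_cut correlation-magnitude threshold used (edges have |r| > cut).
#' @slot fdr_cut adjusted-p threshold used (edges have p_adj < cut).
#' @slot n_samples number of samples the correlations were computed over.
#' @export
setClass("CooccurrenceNetwork", representation(
  graph = "igraph", corr_cut = "numeric", fdr_cut = "numeric",
  n_samples = "integer"))

setValidity("CooccurrenceNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
  if (any(igraph::which_multiple(g))) msg <- c(msg, "multi-edges are not allowed")
  if (igraph::ecount(g) > 0) {
    r <- igraph::E(g)$r
    if (is.null(r)) msg <- c(msg, "edges must carry attribute 'r'")
    else if (any(abs(r) <= object@corr_cut - 1e-12))
      msg <- c(msg, "edge below the correlation threshold")
  }
  if (length(msg)) msg else TRUE
})

#' RunConfig: thresholds, depths and the master seed of a pipeline run
#'
#' Defaults mirror the analysis constants used throughout the package:
#' correlation cut 0.6, FDR cut 0.01, relative-abundance cut 1e-4 (0.01%),
#' prevalence cut 0.10, Zi cut 2.5, Pi cut 0.62, 50% node removal with 100
#' repetitions, 999 permutations, 1000 null randomizations.
#'
#' @slot corr_cut,fdr_cut,rel_abund_cut,prevalence_cut,zi_cut,pi_cut numeric thresholds.
#' @slot removal_fraction fraction of nodes removed per robustness repetition.
#' @slot removal_reps,n_permutations,n_null integer repetition counts.
#' @slot rarefaction_depth reads per sample after rarefaction (NA = skip).
#' @slot seed master seed; all stochastic stages draw named substreams from it.
#' @export
setClass("RunConfig", representation(
  corr_cut = "numeric", fdr_cut = "numeric", rel_abund_cut = "numeric",
  prevalence_cut = "numeric", zi_cut = "numeric", pi_cut = "numeric",
  removal_fraction = "numeric", removal_reps = "integer",
  n_permutations = "integer", n_null = "integer",
  rarefaction_depth = "numeric", seed = "integer"),
  prototype(corr_cut = 0.6, fdr_cut = 0.01, rel_abund_cut = 1e-4,
            prevalence_cut = 0.10, zi_cut = 2.5, pi_cut = 0.62,
            removal_fraction = 0.5, removal_reps = 100L,
            n_permutations = 999L, n_null = 1000L,
            rarefaction_depth = NA_real_, seed = 1L))

setValidity("RunConfig", function(object) {
  msg <- character()
  chk <- function(v, lo, hi, nm, lo_open = FALSE, hi_open = FALSE) {
    bad <- if (lo_open) v <= lo else v < lo
    bad <- bad || if (hi_open) v >= hi else v > hi
    if (bad) sprintf("%s must lie in %s%g, %g%s", nm,
                     if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]")
    else NULL
  }
  msg <- c(msg,
           chk(object@corr_cut, 0, 1, "corr_cut"),
           chk(object@fdr_cut, 0, 1, "fdr_cut", lo_open = TRUE),
           chk(object@rel_abund_cut, 0, 1, "rel_abund_cut", hi_open = TRUE),
           chk(object@prevalence_cut, 0, 1, "prevalence_cut", hi_open = TRUE),
           chk(object@removal_fraction, 0, 1, "removal_fraction",
               lo_open = TRUE, hi_open = TRUE))
  if (object@zi_cut < 0) msg <- c(msg, "zi_cut must be non-negative")
  chkpi <- chk(object@pi_cut, 0, 1, "pi_cut")
  msg <- c(msg, chkpi)
  if (object@removal_reps < 1L) msg <- c(msg, "removal_reps must be >= 1")
  if (object@n_permutations < 1L) msg <- c(msg, "n_permutations must be >= 1")
  if (object@n_null < 1L) msg <- c(msg, "n_null must be >= 1")
  if (is.na(object@seed) || object@seed < 0L)
    msg <- c(msg, "seed must be a non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param ... slot overrides, e.g. `runConfig(corr_cut = 0.7, seed = 42)`.
#' @return A validated [RunConfig-class] object.
#' @export
runConfig <- function(...) {
  args <- list(...)
  for (nm in c("removal_reps", "n_permutations", "n_null", "seed"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("RunConfig"), args))
}
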