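#' Read an abundance table from TSV (or BIOM-JSON)
#'
#' The expected layout is samples as rows and taxa as columns, with the first
#' column holding sample ids and a header row of taxon ids. Files written
#' taxa-as-rows (the QIIME convention) are transposed on load with
#' `taxa_as_rows = TRUE`.
#'
#' @param path path to a TSV file, or a BIOM-JSON file (requires the
#'   `biomformat` package) when `format = "biom"`.
#' @param taxa_as_rows logical; transpose after reading.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return An [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, taxa_as_rows = FALSE, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # taxa x samples
    return(AbundanceTable(t(m)))
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      row.names = 1, quote = "", comment.char = ""),
    error = function(e) stop("malformed TSV '", path, "': ", conditionMessage(e)))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))
    stop("non-numeric count column(s) in '", path, "': ",
         paste(names(df)[bad], collapse = ", "))
  }
  if (taxa_as_rows) m <- t(m)
  AbundanceTable(m)
}

#' Read a sample metadata table from TSV
#'
#' @param path TSV with a header; first column = sample id. Recognized
#'   categorical columns: `habitat` (U/W), `host`, `organ`; any numeric
#'   column is treated as an environmental covariate (e.g. `urban_degree`,
#'   `PH`, `AT`, `bio_3`, `bio_18`).
#' @return A data.frame with rownames = sample ids.
#' @export
readMetadataTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      row.names = 1, quote = "", comment.char = "",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed TSV '", path, "': ", conditionMessage(e)))
  if (anyDuplicated(rownames(df)))
    stop("duplicate sample ids in metadata: ",
         paste(unique(rownames(df)[duplicated(rownames(df))]), collapse = ", "))
  if ("urban_degree" %in% names(df)) {
    u <- df$urban_degree
    if (any(!is.na(u) & (u < 0 | u > 1)))
      stop("urban_degree must lie in [0, 1]")
  }
  df
}

#' Load an abundance table, metadata and (optionally) a phylogeny
#'
#' Validates the shared contract between the three artifacts: metadata sample
#' ids must be a superset of the table's. Taxa missing from the tree are not
#' an error here; phylogeny-aware operations raise the error when asked to
#' use such taxa.
#'
#' @param table_path,metadata_path,tree_path file paths; `tree_path` (Newick)
#'   may be `NULL`.
#' @param taxa_as_rows passed to [readAbundanceTable()].
#' @return A list with elements `table`, `metadata`, `tree` (NULL if absent).
#' @export
loadDataset <- function(table_path, metadata_path, tree_path = NULL,
                        taxa_as_rows = FALSE) {
  tab <- readAbundanceTable(table_path, taxa_as_rows = taxa_as_rows)
  meta <- readMetadataTable(metadata_path)
  missing_meta <- setdiff(sampleIDs(tab), rownames(meta))
  if (length(missing_meta))
    stop("metadata is missing sample(s): ", paste(missing_meta, collapse = ", "))
  tree <- NULL
  if (!is.null(tree_path)) {
    if (!file.exists(tree_path)) stop("file not found: ", tree_path)
    tree <- tryCatch(ape::read.tree(tree_path),
                     error = function(e) stop("malformed Newick '", tree_path,
                                              "': ", conditionMessage(e)))
    if (is.null(tree)) stop("malformed Newick '", tree_path, "'")
    if (anyDuplicated(tree$tip.label))
      stop("duplicate tip labels in tree: ",
           paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
    if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
      stop("negative branch lengths in tree")
  }
  list(table = tab, metadata = meta, tree = tree)
}

# Write a numeric data.frame/matrix as TSV with enough digits that re-reading
# reproduces every double bit-exactly.
writeTSVexact <- function(x, path, row_label = "id") {
  df <- as.data.frame(x, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  has_rn <- !is.null(rownames(x)) &&
    !identical(rownames(as.data.frame(x)), as.character(seq_len(nrow(df))))
  if (has_rn) {
    df <- cbind(stats::setNames(data.frame(rownames(as.data.frame(x))), row_label), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write analysis artifacts to a directory
#'
#' Dispatches on the class of each element of `results`: data.frames and
#' matrices become TSV, [CooccurrenceNetwork-class] objects become GraphML
#' plus an edge-list TSV, `phylo` trees become Newick, [AbundanceTable-class]
#' objects become count TSVs, and anything list-like of scalars becomes JSON.
#' Numeric TSV cells are written with 17 significant digits so a re-read
#' reproduces the stored doubles exactly.
#'
#' @param results named list of result objects (may be empty).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a data.frame manifest (name, file, format).
#' @export
writeArtifacts <- function(results, out_dir) {
  stopifnot(is.list(results))
  if (length(results) && is.null(names(results)))
    stop("results must be a named list")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  manifest <- data.frame(name = character(), file = character(),
                         format = character(), stringsAsFactors = FALSE)
  add <- function(name, file, format)
    manifest <<- rbind(manifest, data.frame(name = name, file = file,
                                            format = format, stringsAsFactors = FALSE))
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is(x, "CooccurrenceNetwork")) {
      fg <- file.path(out_dir, paste0(nm, ".graphml"))
      igraph::write_graph(x@graph, fg, format = "graphml")
      add(nm, fg, "graphml")
      fe <- file.path(out_dir, paste0(nm, "_edges.tsv"))
      writeTSVexact(networkEdges(x), fe)
      add(nm, fe, "tsv")
    } else if (is(x, "AbundanceTable")) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      writeTSVexact(counts(x), f, row_label = "sample_id")
      add(nm, f, "tsv")
    } else if (inherits(x, "phylo")) {
      f <- file.path(out_dir, paste0(nm, ".nwk"))
      ape::write.tree(x, f)
      add(nm, f, "newick")
    } else if (inherits(x, "dist")) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      writeTSVexact(as.matrix(x), f, row_label = "sample_id")
      add(nm, f, "tsv")
    } else if (is.data.frame(x) || is.matrix(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      writeTSVexact(x, f)
      add(nm, f, "tsv")
    } else if (is.list(x) || (is.atomic(x) && !is.null(names(x)))) {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      add(nm, f, "json")
    } else {
      stop("do not know how to serialize result '", nm, "' of class ",
           paste(class(x), collapse = "/"))
    }
  }
  invisible(manifest)
}

#' Read back a square distance matrix written by [writeArtifacts()]
#'
#' @param path TSV with an id column and a header of sample ids.
#' @return A numeric matrix with dimnames.
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}
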