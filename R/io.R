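#' Read / write genes-by-samples matrices as TSV
#'
#' TSV layout: genes in rows, first column = gene id, header = sample ids;
#' missing values as `NA`.
#'
#' @param path File path.
#' @return `read_matrix_tsv()` returns a numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' @rdname read_matrix_tsv
#' @param x Matrix with gene rownames.
#' @param id_column Name of the first (gene id) column.
#' @export
write_matrix_tsv <- function(x, path, id_column = "gene") {
  df <- as_tibble(as.data.frame(x), rownames = id_column)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a GCT 1.2 expression matrix
#'
#' GCT 1.2: a `#1.2` version line, a dimensions line, then a table with
#' `Name` and `Description` columns followed by one column per sample.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2)
  if (!startsWith(trimws(header[1]), "#1.2")) {
    imp_abort("Not a GCT 1.2 file (missing #1.2 header).", "bad_format")
  }
  df <- readr::read_tsv(path, skip = 2, show_col_types = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -(1:2)])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write a discretized call matrix with a JSON sidecar
#'
#' Writes calls as TSV and, next to it (`<path>.json`), the discretization
#' provenance: layer, the threshold multiplier used, and any thresholds
#' passed in `extra`.
#'
#' @param calls Call matrix from [discretize_expression()] or
#'   [categorize_cnv()].
#' @param path Output TSV path.
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path, extra = list()) {
  write_matrix_tsv(unclass(calls), path)
  meta <- c(list(layer = call_layer(calls), n_used = attr(calls, "n_used")),
            extra)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  m <- read_matrix_tsv(path)
  storage.mode(m) <- "integer"
  sidecar <- paste0(path, ".json")
  layer <- "GE"
  n_used <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$layer)) layer <- meta$layer
    n_used <- meta$n_used
  }
  new_call_matrix(m, layer = layer, n_used = n_used)
}

#' Write / read implication rule tables
#'
#' @param rules Rule tibble from [infer_network()] or
#'   [intersect_cohorts()].
#' @param path TSV file path.
#' @return `write_edges_tsv()` returns `path` invisibly; `read_edges_tsv()`
#'   a tibble.
#' @export
write_edges_tsv <- function(rules, path) {
  readr::write_tsv(as_tibble(rules), path)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a clinical table
#'
#' Thin TSV reader; expects at least `patient_id`, `time`, `event` columns.
#'
#' @param path TSV file path.
#' @return Tibble.
#' @export
read_clinical_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("patient_id", "time", "event")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    imp_abort(paste0("Clinical table lacks column(s): ",
                     paste(missing, collapse = ", ")), "bad_format")
  }
  df
}

#' Read a DepMap-style dependency score matrix
#'
#' CSV with cell lines in rows and `"SYMBOL (entrez)"` gene columns (the
#' DepMap convention); returned transposed to genes x cell lines with bare
#' symbols as rownames.
#'
#' @param path CSV file path.
#' @return Numeric matrix, genes x cell lines.
#' @export
read_dependency_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  lines <- df[[1]]
  m <- t(as.matrix(df[, -1]))
  storage.mode(m) <- "double"
  colnames(m) <- lines
  rownames(m) <- parse_depmap_genes(rownames(m))
  m
}
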