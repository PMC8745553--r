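#' Reference gene sets used throughout the pipeline
#'
#' Accessors for the fixed gene lists the analysis is anchored on: the 27
#' housekeeping genes used to calibrate expression discretization thresholds,
#' the seven prognostic signature genes, the 14 epithelial/mesenchymal
#' transition (EMT) marker genes, and the two immune-checkpoint genes whose
#' down-regulation is part of the mechanism-of-action signature.
#'
#' @return A character vector of HGNC gene symbols.
#' @examples
#' housekeeping_genes()
#' signature_genes()
#' @name gene_sets
NULL

#' @rdname gene_sets
#' @export
housekeeping_genes <- function() {
  c(
    "ACTB", "B2M", "CDKN1B", "ESD", "FLOT2", "GAPDH", "GRB2", "GUSB",
    "HMBS", "HPRT1", "HSP90AB1", "IPO8", "LDHA", "NONO", "PGK1", "POLR2A",
    "PPIA", "PPIH", "PPP1CA", "RHOA", "RPL13A", "SDCBP", "TBP", "TFRC",
    "UBC", "YAP1", "YWHAZ"
  )
}

#' @rdname gene_sets
#' @export
signature_genes <- function() {
  c("ABCC4", "CCL19", "SLC39A8", "CD27", "FUT7", "DAG1", "ZNF71")
}

#' @rdname gene_sets
#' @export
epithelial_markers <- function() {
  c(
    "CDH1", "EPCAM", "ESRP1", "ESRP2", "DDR1", "CTNNB1", "CD24", "CLDN7",
    "KRT8", "KRT19", "RAB25"
  )
}

#' @rdname gene_sets
#' @export
mesenchymal_markers <- function() {
  c("ZEB1", "VIM", "FN1")
}

#' @rdname gene_sets
#' @export
immune_checkpoint_genes <- function() {
  c("CD27", "CD274")
}
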