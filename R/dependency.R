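#' Construct a dependency screen
#'
#' Container for a genes x cell-lines knockout/knockdown effect matrix with
#' its control gene sets. Missing measurements are `NA` in `scores`.
#'
#' @param scores Numeric matrix, genes in rows (rownames = symbols), cell
#'   lines in columns.
#' @param essential Character vector of essential (positive) control genes;
#'   must be rows of `scores`.
#' @param nonessential Character vector of non-essential (negative) control
#'   genes; must be rows of `scores` and disjoint from `essential`.
#' @param assay `"CRISPR"` or `"RNAi"`.
#' @return A `dependency_screen` object.
#' @export
dependency_screen <- function(scores, essential, nonessential,
                              assay = c("CRISPR", "RNAi")) {
  assay <- match.arg(assay)
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  if (length(essential) == 0 || length(nonessential) == 0) {
    imp_abort("Both control sets must be nonempty.", "degenerate_controls")
  }
  if (length(intersect(essential, nonessential)) > 0) {
    imp_abort("Control sets must be disjoint.", "degenerate_controls")
  }
  missing <- setdiff(c(essential, nonessential), rownames(scores))
  if (length(missing) > 0) {
    imp_abort(paste0("Control genes absent from `scores`: ",
                     paste(missing, collapse = ", ")),
              "missing_gene", genes = missing)
  }
  structure(
    list(scores = scores, essential = essential, nonessential = nonessential,
         assay = assay, normalized = FALSE),
    class = "dependency_screen"
  )
}

#' @export
print.dependency_screen <- function(x, ...) {
  cat(sprintf(
    "<dependency_screen> %s: %d genes x %d cell lines (%d essential / %d non-essential controls)%s\n",
    x$assay, nrow(x$scores), ncol(x$scores), length(x$essential),
    length(x$nonessential), if (x$normalized) ", normalized" else ""
  ))
  invisible(x)
}

control_medians <- function(scores, genes, line) {
  vals <- scores[genes, line]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 3) {
    imp_abort(sprintf("Fewer than 3 measured control genes in cell line %s.", line),
              "degenerate_controls")
  }
  median(vals)
}

#' Normalize a CRISPR knockout screen on its control-set medians
#'
#' Per cell line, applies the affine map anchored on the two control medians
#' so that afterwards the median non-essential control effect is exactly 0
#' and the median essential control effect is exactly -1:
#' `x' = (x - med_ne) / (med_ne - med_e)`.
#'
#' @param screen A CRISPR [dependency_screen()].
#' @return The screen with normalized scores (`normalized = TRUE`).
#' @export
normalize_crispr <- function(screen) {
  stopifnot(inherits(screen, "dependency_screen"))
  out <- screen$scores
  for (line in colnames(out)) {
    med_ne <- control_medians(screen$scores, screen$nonessential, line)
    med_e <- control_medians(screen$scores, screen$essential, line)
    if (med_ne == med_e) {
      imp_abort(sprintf("Equal control medians in cell line %s.", line),
                "degenerate_controls")
    }
    out[, line] <- (screen$scores[, line] - med_ne) / (med_ne - med_e)
  }
  screen$scores <- out
  screen$normalized <- TRUE
  screen
}

#' Standardize an RNAi knockdown screen on across-line average scores
#'
#' Averages each gene across cell lines first (the knockdown screen's output
#' contract is at the gene-average level), then applies the two-point median
#' map on those averages so that the median averaged score of the positive
#' (essential) control set is exactly -1 and that of the negative
#' (non-essential) control set is exactly 0. The per-line matrix is rescaled
#' by the same affine map so downstream per-line thresholding stays on the
#' standardized scale.
#'
#' @param screen An RNAi [dependency_screen()].
#' @return The screen with rescaled per-line scores, `normalized = TRUE`,
#'   and an extra element `gene_scores`: the standardized per-gene averages.
#' @export
normalize_rnai <- function(screen) {
  stopifnot(inherits(screen, "dependency_screen"))
  gene_avg <- rowMeans(screen$scores, na.rm = TRUE)
  med_pos <- median(gene_avg[screen$essential], na.rm = TRUE)
  med_neg <- median(gene_avg[screen$nonessential], na.rm = TRUE)
  if (sum(!is.na(gene_avg[screen$essential])) < 3 ||
      sum(!is.na(gene_avg[screen$nonessential])) < 3) {
    imp_abort("Fewer than 3 measured control genes at the gene-average level.",
              "degenerate_controls")
  }
  if (med_pos == med_neg) {
    imp_abort("Equal control medians at the gene-average level.",
              "degenerate_controls")
  }
  rescale <- function(x) (x - med_neg) / (med_neg - med_pos)
  screen$gene_scores <- rescale(gene_avg)
  screen$scores <- rescale(screen$scores)
  screen$normalized <- TRUE
  screen
}

#' Significant-dependency indicator matrix
#'
#' @param screen A normalized [dependency_screen()].
#' @param threshold Dependency cutoff; a score strictly below it (default
#'   -0.5) marks a significant knockout/knockdown effect. Missing
#'   measurements are never significant.
#' @return Logical matrix, same shape as the score matrix.
#' @export
significant_dependency <- function(screen, threshold = -0.5) {
  stopifnot(inherits(screen, "dependency_screen"))
  sig <- screen$scores < threshold
  sig[is.na(sig)] <- FALSE
  sig
}

screen_sig_counts <- function(screen, threshold) {
  if (is.null(screen)) {
    return(tibble(gene = character(), n_sig = integer(), n_tested = integer()))
  }
  sig <- significant_dependency(screen, threshold)
  tibble(
    gene = rownames(screen$scores),
    n_sig = as.integer(rowSums(sig)),
    n_tested = as.integer(rowSums(!is.na(screen$scores)))
  )
}

#' Call proliferation genes by the majority (>= 50% of tested lines) rule
#'
#' A gene qualifies when it has a significant dependency score in at least
#' `fraction` of the cell lines in which it was actually tested (non-missing
#' denominator, inclusive bound), in the CRISPR screen or in the RNAi
#' screen. Genes tested in zero lines of both screens are excluded.
#'
#' @param crispr,rnai Normalized [dependency_screen()]s; either may be
#'   `NULL`.
#' @param fraction Inclusive tested-line fraction (default 0.5).
#' @param threshold Significance cutoff passed to
#'   [significant_dependency()].
#' @return Sorted character vector of qualifying gene symbols.
#' @export
proliferation_genes_majority <- function(crispr = NULL, rnai = NULL,
                                         fraction = 0.5, threshold = -0.5) {
  counts <- bind_rows(screen_sig_counts(crispr, threshold),
                      screen_sig_counts(rnai, threshold))
  if (nrow(counts) == 0) return(character())
  hits <- counts %>%
    filter(.data$n_tested > 0) %>%
    filter(.data$n_sig / .data$n_tested >= fraction) %>%
    pull(.data$gene)
  sort(unique(hits))
}

#' Call proliferation genes by the strict line-count rule
#'
#' A gene qualifies when its number of significantly dependent cell lines
#' exceeds `min_lines` (strictly more than 10 by default) in the CRISPR or
#' the RNAi screen.
#'
#' @inheritParams proliferation_genes_majority
#' @param min_lines Strict lower bound on the significant-line count
#'   (default 10).
#' @return Sorted character vector of qualifying gene symbols.
#' @export
proliferation_genes_count <- function(crispr = NULL, rnai = NULL,
                                      min_lines = 10, threshold = -0.5) {
  counts <- bind_rows(screen_sig_counts(crispr, threshold),
                      screen_sig_counts(rnai, threshold))
  if (nrow(counts) == 0) return(character())
  sort(unique(counts$gene[counts$n_sig > min_lines]))
}

#' Strip entrez suffixes from DepMap-style gene labels
#'
#' DepMap matrices label genes as `"SYMBOL (entrez)"`; this reduces them to
#' the bare symbol.
#'
#' @param x Character vector of gene labels.
#' @return Character vector of symbols.
#' @export
parse_depmap_genes <- function(x) {
  sub(" \\([0-9]+\\)$", "", x)
}
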