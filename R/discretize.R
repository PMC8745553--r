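#' Solve the housekeeping threshold-multiplier equation for one gene
#'
#' Finds the multiplier `n` such that the number of samples with expression
#' above `mean + n * sd` plus the number below `mean - n * sd` equals the
#' target fraction of all samples (by default 30%). The flagged count, as a
#' function of `n`, is a non-increasing step function that only changes at
#' the standardized absolute deviations `|x - mean| / sd`, so the solution is
#' found by exact breakpoint search rather than iteration. When the exact
#' target count is unattainable (ties in the deviations), the `n` whose count
#' is closest to the target is returned, preferring the smaller count on
#' ties; among n attaining the chosen count, the smallest is returned.
#'
#' @param values Numeric vector of expression values for one gene across
#'   samples (length >= 10, finite, non-constant).
#' @param target_fraction Target fraction of samples to flag as over- or
#'   under-expressed, in (0, 1). Default 0.30.
#' @return A single non-negative number, the threshold multiplier `n`.
#' @seealso [average_housekeeping_n()], [discretize_expression()]
#' @export
solve_threshold_n <- function(values, target_fraction = 0.30) {
  if (!is.numeric(values) || length(values) < 10) {
    imp_abort("`values` must be a numeric vector with at least 10 samples.",
              "insufficient_samples")
  }
  if (!all(is.finite(values))) {
    imp_abort("`values` must be finite.", "degenerate_input")
  }
  if (!is.numeric(target_fraction) || length(target_fraction) != 1 ||
      target_fraction <= 0 || target_fraction >= 1) {
    imp_abort("`target_fraction` must be a single number in (0, 1).",
              "bad_argument")
  }
  m <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s <= 0) {
    imp_abort("`values` has zero variance; the threshold equation is degenerate.",
              "degenerate_input")
  }
  d <- abs(values - m) / s
  n_total <- length(values)
  k_target <- round(target_fraction * n_total)

  # Flagged(n) = #{i : d_i > n}; candidates are 0 and the breakpoints.
  cand <- sort(unique(c(0, d)))
  counts <- vapply(cand, function(n) sum(d > n), integer(1))

  exact <- which(counts == k_target)
  if (length(exact) > 0) {
    return(cand[exact[1]])
  }
  gap <- abs(counts - k_target)
  best_gap <- min(gap)
  at_best <- which(gap == best_gap)
  # prefer the smaller count, then the smallest n attaining it
  chosen_count <- min(counts[at_best])
  cand[at_best[counts[at_best] == chosen_count][1]]
}

#' Cohort-level threshold multiplier from housekeeping genes
#'
#' Solves the threshold-multiplier equation per housekeeping gene (each gene
#' using its own row mean and standard deviation across samples) and returns
#' the mean of the per-gene solutions. This averaged multiplier is then
#' applied uniformly to every gene of the cohort by
#' [discretize_expression()].
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns.
#' @param housekeeping Character vector of housekeeping gene symbols that
#'   must all be present as rows of `expr`. Defaults to the 27-gene panel
#'   from [housekeeping_genes()].
#' @inheritParams solve_threshold_n
#' @return The averaged threshold multiplier (single number).
#' @export
average_housekeeping_n <- function(expr, housekeeping = housekeeping_genes(),
                                   target_fraction = 0.30) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  missing <- setdiff(housekeeping, rownames(expr))
  if (length(missing) > 0) {
    imp_abort(
      paste0("Housekeeping genes missing from `expr`: ",
             paste(missing, collapse = ", ")),
      "missing_gene", genes = missing
    )
  }
  per_gene <- vapply(
    housekeeping,
    function(g) solve_threshold_n(expr[g, ], target_fraction),
    numeric(1)
  )
  mean(per_gene)
}

new_call_matrix <- function(calls, layer, n_used = NULL, missing_mask = NULL) {
  storage.mode(calls) <- "integer"
  structure(
    calls,
    layer = layer,
    n_used = n_used,
    missing_mask = missing_mask,
    class = c("implinet_calls", class(calls))
  )
}

#' @export
print.implinet_calls <- function(x, ...) {
  cat(sprintf(
    "<implinet_calls> %d genes x %d samples, layer %s%s\n",
    nrow(x), ncol(x), attr(x, "layer"),
    if (!is.null(attr(x, "n_used"))) sprintf(", n_used = %.4g", attr(x, "n_used")) else ""
  ))
  tab <- table(factor(x, levels = c(-1L, 0L, 1L)))
  cat("calls: -1:", tab[["-1"]], " 0:", tab[["0"]], " 1:", tab[["1"]], "\n")
  invisible(x)
}

#' Discretize an expression matrix to three-level calls
#'
#' Each gene is called 1 (over-expressed) where its value exceeds
#' `mean + n * sd`, -1 (under-expressed) where it falls below
#' `mean - n * sd`, and 0 otherwise, with the mean and standard deviation
#' taken per gene across samples. Inequalities are strict. The multiplier `n`
#' is typically the cohort-level average from [average_housekeeping_n()].
#'
#' @inheritParams average_housekeeping_n
#' @param n Non-negative threshold multiplier applied to every gene.
#' @return An integer matrix of calls in \{-1, 0, 1\} with the same dimnames
#'   as `expr`, carrying attributes `layer = "GE"` and `n_used`.
#'   Zero-variance rows are called 0 everywhere (with a warning).
#' @export
discretize_expression <- function(expr, n) {
  stopifnot(is.matrix(expr), is.numeric(n), length(n) == 1, n >= 0)
  m <- rowMeans(expr)
  s <- apply(expr, 1, sd)
  flat <- !is.finite(s) | s == 0
  if (any(flat)) {
    warn(sprintf("%d zero-variance gene(s) called 0 everywhere.", sum(flat)))
    s[flat] <- Inf
  }
  # compare on the standardized scale so thresholds from solve_threshold_n
  # (which works on |x - m| / s) behave identically at breakpoints
  z <- sweep(sweep(expr, 1, m, `-`), 1, s, `/`)
  calls <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  calls[z > n] <- 1L
  calls[z < -n] <- -1L
  new_call_matrix(calls, layer = "GE", n_used = n)
}

#' Categorize copy-number values to three levels
#'
#' Copy-number values are categorized as 1 (amplification) at or above the
#' gain threshold, -1 (deletion) at or below the loss threshold, and 0
#' (normal) in between; both threshold comparisons are inclusive. With
#' thresholds `(0.5, -0.5)` an already three-level integer matrix passes
#' through unchanged. Non-finite entries are called 0 and recorded in a
#' per-cell missing mask attached as the `missing_mask` attribute.
#'
#' @param cnv Numeric matrix, genes in rows, samples in columns. Either
#'   continuous (e.g. log2 ratios) or pre-categorized \{-1, 0, 1\}.
#' @param gain_threshold,loss_threshold Inclusive category bounds with
#'   `gain_threshold > loss_threshold`. Defaults (0.3, -0.3) suit log2-ratio
#'   input; they are deliberately explicit configuration, never inferred.
#' @return Integer call matrix with attribute `layer = "CNV"`.
#' @export
categorize_cnv <- function(cnv, gain_threshold = 0.3, loss_threshold = -0.3) {
  stopifnot(is.matrix(cnv))
  if (!(gain_threshold > loss_threshold)) {
    imp_abort("`gain_threshold` must be greater than `loss_threshold`.",
              "bad_argument")
  }
  miss <- !is.finite(cnv)
  calls <- matrix(0L, nrow(cnv), ncol(cnv), dimnames = dimnames(cnv))
  calls[!miss & cnv >= gain_threshold] <- 1L
  calls[!miss & cnv <= loss_threshold] <- -1L
  new_call_matrix(calls, layer = "CNV",
                  missing_mask = if (any(miss)) miss else NULL)
}
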