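#' Categorize drug response from IC50/EC50 against the assay dose window
#'
#' A cell line is resistant when its IC50/EC50 exceeds the maximum tested
#' dose and sensitive when it falls below the minimum tested dose (both
#' strict, following the activity-vs-window rule). Values inside the window
#' (bounds inclusive) are trichotomized by log10-scale tertiles of
#' `[min_dose, max_dose]` into sensitive / partial / resistant — an
#' explicit in-window convention of this package, recorded in output
#' metadata by the pipeline.
#'
#' @param value Positive IC50/EC50 value(s), same units as the dose bounds
#'   (micromolar in the default PRISM window).
#' @param min_dose,max_dose Dose window; defaults 0.0006 and 10 (the
#'   eight-dose PRISM range).
#' @return Factor with levels `sensitive`, `partial`, `resistant` (NA input
#'   gives NA).
#' @export
categorize_response <- function(value, min_dose = 0.0006, max_dose = 10) {
  stopifnot(min_dose < max_dose, min_dose > 0)
  if (any(!is.na(value) & value <= 0)) {
    imp_abort("IC50/EC50 values must be positive.", "invalid_activity")
  }
  pos <- (log10(value) - log10(min_dose)) / (log10(max_dose) - log10(min_dose))
  out <- ifelse(
    value > max_dose, "resistant",
    ifelse(value < min_dose, "sensitive",
           ifelse(pos < 1 / 3, "sensitive",
                  ifelse(pos < 2 / 3, "partial", "resistant")))
  )
  factor(out, levels = c("sensitive", "partial", "resistant"))
}

#' Categorize a drug-activity table
#'
#' Applies [categorize_response()] row-wise to a tidy activity table.
#'
#' @param records Data frame with columns `value`, `min_dose`, `max_dose`
#'   (and typically `cell_line`, `drug`, `metric`).
#' @return The tibble with a `category` column appended.
#' @export
categorize_activity <- function(records) {
  records <- as_tibble(records)
  stopifnot(all(c("value", "min_dose", "max_dose") %in% names(records)))
  records %>%
    mutate(category = purrr::pmap_vec(
      list(.data$value, .data$min_dose, .data$max_dose),
      function(v, lo, hi) categorize_response(v, lo, hi)
    ))
}

#' Differential expression between sensitive and resistant cell lines
#'
#' Per gene: Welch (default) two-sample t-test of sensitive versus resistant
#' lines plus the linear-scale fold change `mean(sensitive) /
#' mean(resistant)`. A gene is reported when `p < p_cutoff` and the fold
#' change is outside `fc_bounds` (below 0.5 or above 2 by default). Lines
#' categorized `partial` are ignored (strict sensitive-vs-resistant
#' contrast).
#'
#' @param expr Expression (or protein) matrix, genes x cell lines, on a
#'   linear scale; set `log_input = TRUE` (with `log_base`) for logged
#'   matrices, in which case the t-test stays on the logged scale and fold
#'   changes are computed on de-logged means.
#' @param categories Response factor/vector per cell line (named by cell
#'   line, or in column order of `expr`), as from [categorize_response()].
#' @param p_cutoff Two-sided significance level (default 0.05).
#' @param fc_bounds Length-2 fold-change bounds, default `c(0.5, 2)`.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @param log_input,log_base Whether `expr` is logged, and the base.
#' @return Tibble: `gene`, `mean_sensitive`, `mean_resistant`, `t`, `p`,
#'   `fold_change`, `direction` (`higher-in-sensitive` /
#'   `higher-in-resistant`), `reported`.
#' @export
de_by_response <- function(expr, categories, p_cutoff = 0.05,
                           fc_bounds = c(0.5, 2), pooled = FALSE,
                           log_input = FALSE, log_base = 2) {
  stopifnot(is.matrix(expr))
  if (!is.null(names(categories))) {
    categories <- categories[colnames(expr)]
  } else {
    stopifnot(length(categories) == ncol(expr))
  }
  sens <- which(categories == "sensitive")
  res <- which(categories == "resistant")
  if (length(sens) < 3 || length(res) < 3) {
    imp_abort(sprintf(
      "Need >= 3 sensitive and >= 3 resistant lines (have %d and %d).",
      length(sens), length(res)), "insufficient_samples")
  }
  stats_mat <- apply(expr, 1, function(x) {
    ht <- t.test(x[sens], x[res], var.equal = pooled)
    ms <- mean(x[sens])
    mr <- mean(x[res])
    if (log_input) {
      ms <- log_base^ms
      mr <- log_base^mr
    }
    c(ms = ms, mr = mr, t = unname(ht$statistic), p = ht$p.value)
  })
  tibble(
    gene = rownames(expr),
    mean_sensitive = unname(stats_mat["ms", ]),
    mean_resistant = unname(stats_mat["mr", ]),
    t = unname(stats_mat["t", ]),
    p = unname(stats_mat["p", ]),
    fold_change = unname(stats_mat["ms", ] / stats_mat["mr", ])
  ) %>%
    mutate(
      direction = ifelse(.data$fold_change > 1,
                         "higher-in-sensitive", "higher-in-resistant"),
      reported = .data$p < p_cutoff &
        (.data$fold_change < fc_bounds[1] | .data$fold_change > fc_bounds[2])
    )
}

#' Volcano plot of a sensitive-vs-resistant DE table
#'
#' Log2 fold change against -log10 p, with the reported genes highlighted
#' and the filter bounds drawn.
#'
#' @param de Result tibble from [de_by_response()].
#' @param fc_bounds The fold-change bounds used (drawn as dashed lines).
#' @param p_cutoff The p cutoff used.
#' @return A ggplot object.
#' @export
plot_de <- function(de, fc_bounds = c(0.5, 2), p_cutoff = 0.05) {
  de <- as_tibble(de)
  ggplot2::ggplot(de, ggplot2::aes(x = log2(.data$fold_change),
                                   y = -log10(.data$p),
                                   colour = .data$reported)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = log2(fc_bounds), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (sensitive / resistant)",
                  y = "-log10 p", colour = "reported") +
    ggplot2::theme_minimal()
}

#' Per-gene mRNA-protein correlation
#'
#' Pearson correlation between each gene's mRNA profile and its protein
#' quantification(s) across shared cell lines. A gene may map to several
#' protein quantifications; each mapping yields a row.
#'
#' @param mrna Matrix, genes x cell lines.
#' @param protein Matrix, protein quantifications x cell lines (rownames =
#'   quantification ids).
#' @param pairs Data frame with columns `gene`, `protein_id`; by default
#'   rows with identical names in the two matrices are paired.
#' @param p_cutoff Significance level (default 0.05).
#' @param min_pairs Minimum shared cell lines per gene (default 5).
#' @return Tibble: `gene`, `protein_id`, `n`, `r`, `p`, `significant`,
#'   `note` (flags constant profiles, for which `r` is undefined).
#' @export
mrna_protein_correlation <- function(mrna, protein, pairs = NULL,
                                     p_cutoff = 0.05, min_pairs = 5) {
  stopifnot(is.matrix(mrna), is.matrix(protein))
  if (is.null(pairs)) {
    shared_genes <- intersect(rownames(mrna), rownames(protein))
    pairs <- tibble(gene = shared_genes, protein_id = shared_genes)
  }
  pairs <- as_tibble(pairs)
  lines <- intersect(colnames(mrna), colnames(protein))
  rows <- purrr::pmap(pairs[c("gene", "protein_id")], function(gene, protein_id) {
    x <- mrna[gene, lines]
    y <- protein[protein_id, lines]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]
    y <- y[ok]
    if (length(x) < min_pairs) {
      return(tibble(gene = gene, protein_id = protein_id, n = length(x),
                    r = NA_real_, p = NA_real_, significant = FALSE,
                    note = "too_few_pairs"))
    }
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(gene = gene, protein_id = protein_id, n = length(x),
                    r = NA_real_, p = NA_real_, significant = FALSE,
                    note = "constant_profile"))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(gene = gene, protein_id = protein_id, n = length(x),
           r = unname(ct$estimate), p = ct$p.value,
           significant = ct$p.value < p_cutoff, note = NA_character_)
  })
  bind_rows(rows)
}

#' Two-proportion z-test
#'
#' Pooled two-proportion z statistic, e.g. for comparing the fraction of
#' network genes with significant mRNA-protein correlation against the
#' genome background. One- and two-tailed p-values are both supported
#' (two-tailed default).
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param alternative `"two.sided"`, `"greater"` (p1 > p2) or `"less"`.
#' @return One-row tibble: `p1`, `p2`, `z`, `p`.
#' @export
proportion_test <- function(k1, n1, k2, n2,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- switch(alternative,
    two.sided = 2 * pnorm(-abs(z)),
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z)
  )
  tibble(p1 = p1, p2 = p2, z = z, p = p)
}
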