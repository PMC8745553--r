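#' Boolean implication rule types
#'
#' The four rule families scored on three-level calls. Each rule has a single
#' "error" corner cell in the 3x3 contingency table of (state of A, state of
#' B): observations falling in that cell violate the implication.
#'
#' * `UP_IMPLIES_NOTDOWN`: A up implies B not down, error cell (1, -1)
#' * `UP_IMPLIES_NOTUP`:   A up implies B not up, error cell (1, 1)
#' * `DOWN_IMPLIES_NOTDOWN`: A down implies B not down, error cell (-1, -1)
#' * `DOWN_IMPLIES_NOTUP`: A down implies B not up, error cell (-1, 1)
#'
#' `UP_IMPLIES_NOTDOWN` / `DOWN_IMPLIES_NOTUP` express a positive
#' (co-expression-like) relation; the other two express an inverse relation.
#'
#' @return Character vector of the four rule types, in the fixed order used
#'   for deterministic tie-breaking.
#' @export
rule_types <- function() {
  c("UP_IMPLIES_NOTDOWN", "UP_IMPLIES_NOTUP",
    "DOWN_IMPLIES_NOTDOWN", "DOWN_IMPLIES_NOTUP")
}

# error corner cell (A state, B state) of a rule type
rule_error_cell <- function(rule_type) {
  switch(rule_type,
    UP_IMPLIES_NOTDOWN   = c(1L, -1L),
    UP_IMPLIES_NOTUP     = c(1L, 1L),
    DOWN_IMPLIES_NOTDOWN = c(-1L, -1L),
    DOWN_IMPLIES_NOTUP   = c(-1L, 1L),
    imp_abort(paste0("Unknown rule type: ", rule_type), "bad_argument")
  )
}

#' Whether a rule type expresses a positive or inverse relation
#' @param rule_type One of [rule_types()].
#' @return `"positive"` or `"negative"`.
#' @export
rule_relation <- function(rule_type) {
  ifelse(rule_type %in% c("UP_IMPLIES_NOTDOWN", "DOWN_IMPLIES_NOTUP"),
         "positive", "negative")
}

check_calls <- function(x, arg) {
  if (!all(x[!is.na(x)] %in% c(-1L, 0L, 1L))) {
    imp_abort(sprintf("`%s` must contain calls in {-1, 0, 1}.", arg),
              "bad_argument")
  }
}

align_calls <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    shared <- intersect(names(a), names(b))
    a <- a[shared]
    b <- b[shared]
  } else if (length(a) != length(b)) {
    imp_abort("Unnamed call vectors must have equal length.", "bad_argument")
  }
  keep <- !is.na(a) & !is.na(b)
  list(a = as.integer(a[keep]), b = as.integer(b[keep]))
}

#' Build the 3x3 contingency table for a pair of call vectors
#'
#' Samples are paired by name when both vectors are named (alignment by the
#' intersection of sample ids), by position otherwise; pairs with a missing
#' call in either variable are dropped.
#'
#' @param a_calls,b_calls Integer call vectors over \{-1, 0, 1\} (NA =
#'   missing), optionally named by sample id.
#' @param min_samples Minimum retained sample count, below which an
#'   `implinet_insufficient_samples` error is thrown. Cohort-level inference
#'   uses 20 (see [infer_network()]); the default here is 0 so small tables
#'   can be inspected directly.
#' @return A 3x3 integer matrix with dimnames `c("-1","0","1")` (rows = state
#'   of A, columns = state of B); `sum(table)` is the retained sample count.
#' @export
build_table <- function(a_calls, b_calls, min_samples = 0) {
  check_calls(a_calls, "a_calls")
  check_calls(b_calls, "b_calls")
  al <- align_calls(a_calls, b_calls)
  n_kept <- length(al$a)
  if (n_kept < max(min_samples, 1)) {
    imp_abort(sprintf("Only %d paired samples retained (minimum %d).",
                      n_kept, max(min_samples, 1)),
              "insufficient_samples")
  }
  lv <- c(-1L, 0L, 1L)
  tab <- table(factor(al$a, levels = lv), factor(al$b, levels = lv))
  matrix(as.integer(tab), 3, 3, dimnames = list(A = c("-1", "0", "1"),
                                                B = c("-1", "0", "1")))
}

#' Score one implication rule on a contingency table
#'
#' Prediction-logic scoring of a single rule. With `N` samples, error count
#' `err` in the rule's corner cell, premise-row marginal `ra` and error-state
#' column marginal `cb`:
#' observed error rate `e_obs = err / N`; expected error rate under
#' independence `e_exp = (ra / N) * (cb / N)`; scope `U = e_exp`; precision
#' `del = 1 - e_obs / e_exp` (0 when `e_exp = 0`); and the one-tailed
#' statistic `z = (e_exp - e_obs) * sqrt(N) / sqrt(e_exp * (1 - e_exp))`.
#' A rule is significant when `z > z_crit` with positive scope and precision.
#'
#' @param tab 3x3 contingency table from [build_table()].
#' @param rule_type One of [rule_types()].
#' @param z_crit One-tailed critical value; 1.64 corresponds to alpha = 0.05.
#' @return One-row tibble with columns `rule_type`, `n`, `e_obs`, `e_exp`,
#'   `scope`, `precision`, `z`, `significant`.
#' @export
score_rule <- function(tab, rule_type, z_crit = 1.64) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(3, 3)))
  rule_type <- match.arg(rule_type, rule_types())
  n_total <- sum(tab)
  if (n_total <= 0) imp_abort("Empty contingency table.", "insufficient_samples")
  cell <- rule_error_cell(rule_type)
  ia <- as.character(cell[1])
  ib <- as.character(cell[2])
  err <- tab[ia, ib]
  e_obs <- err / n_total
  e_exp <- (sum(tab[ia, ]) / n_total) * (sum(tab[, ib]) / n_total)
  if (e_exp > 0) {
    precision <- 1 - e_obs / e_exp
    z <- if (e_exp < 1) {
      (e_exp - e_obs) * sqrt(n_total) / sqrt(e_exp * (1 - e_exp))
    } else {
      0
    }
  } else {
    precision <- 0
    z <- 0
  }
  tibble(
    rule_type = rule_type,
    n = n_total,
    e_obs = e_obs,
    e_exp = e_exp,
    scope = e_exp,
    precision = precision,
    z = z,
    significant = is.finite(z) && z > z_crit && e_exp > 0 && precision > 0
  )
}

#' Score all four rule types and return the best significant rule
#'
#' All four rule families are scored on the pair's contingency table. Each
#' A-to-B rule coincides with its B-to-A contrapositive (same error cell,
#' same marginal product), so scoring the four A-to-B rules covers both
#' directions. Among significant rules the winner has maximal precision;
#' ties are broken by larger scope, then by the fixed order of
#' [rule_types()].
#'
#' @inheritParams build_table
#' @inheritParams score_rule
#' @return One-row tibble (the winning rule) or `NULL` when no rule is
#'   significant.
#' @export
best_rule <- function(a_calls, b_calls, z_crit = 1.64, min_samples = 0) {
  tab <- build_table(a_calls, b_calls, min_samples = min_samples)
  scored <- score_pair_rules(tab, z_crit = z_crit)
  sig <- scored[scored$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(NULL)
  ord <- order(-sig$precision, -sig$scope,
               match(sig$rule_type, rule_types()))
  sig[ord[1], , drop = FALSE]
}

#' Score all four rule types on one contingency table
#' @inheritParams score_rule
#' @return Tibble with one row per rule type.
#' @export
score_pair_rules <- function(tab, z_crit = 1.64) {
  bind_rows(lapply(rule_types(), function(rt) score_rule(tab, rt, z_crit)))
}

#' Permutation null for one implication rule
#'
#' Independent verification of the z-test: the labels of `b_calls` are
#' permuted `reps` times and the p-value is the fraction of permutations
#' whose statistic is at least the observed one. With the marginals fixed by
#' permutation the statistic is a decreasing function of the error-cell
#' count, so the comparison reduces to counting permutations with an error
#' count no larger than observed (the conditional null of that count is
#' hypergeometric).
#'
#' @inheritParams build_table
#' @inheritParams score_rule
#' @param reps Number of permutations (>= 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return Permutation p-value in (0, 1].
#' @export
permutation_null <- function(a_calls, b_calls, rule_type, reps = 10000,
                             seed = NULL) {
  stopifnot(reps >= 1000)
  rule_type <- match.arg(rule_type, rule_types())
  al <- align_calls(a_calls, b_calls)
  cell <- rule_error_cell(rule_type)
  a_prem <- al$a == cell[1]
  b_err <- al$b == cell[2]
  n_prem <- sum(a_prem)
  obs <- sum(a_prem & b_err)
  if (n_prem == 0 || sum(b_err) == 0) return(1)  # e_exp = 0: all permutations tie
  draw <- function() sum(sample(b_err, n_prem))
  perm <- if (is.null(seed)) {
    vapply(seq_len(reps), function(i) draw(), integer(1))
  } else {
    withr::with_seed(seed, vapply(seq_len(reps), function(i) draw(), integer(1)))
  }
  mean(perm <= obs)
}

call_layer <- function(calls, default = "GE") {
  layer <- attr(calls, "layer")
  if (is.null(layer)) default else layer
}

#' Infer implication rules for requested gene pairs
#'
#' Scores each requested (source, target) pair between two call layers.
#' Layers may be GE-GE (co-expression), CNV-GE (copy-number-mediated
#' expression) or CNV-CNV (aberration co-occurrence); pass the same matrix
#' twice (or leave `calls_b` `NULL`) for a single-layer network.
#'
#' @param calls_a Call matrix for the source genes (rows = genes, columns =
#'   samples), e.g. from [discretize_expression()] or [categorize_cnv()].
#' @param calls_b Call matrix for the target genes; defaults to `calls_a`.
#' @param pairs Data frame with character columns `source` and `target`.
#' @param z_crit One-tailed critical value (default 1.64, alpha = 0.05).
#' @param min_samples Minimum shared-sample count per pair (default 20).
#' @param keep `"best"` returns at most one rule per pair (the
#'   [best_rule()] winner); `"significant"` returns every significant rule.
#' @param cohort Optional cohort label stored in a `cohort` column.
#' @return Tibble of rules with columns `source`, `source_layer`, `target`,
#'   `target_layer`, `rule_type`, `relation`, `n`, `e_obs`, `e_exp`, `scope`,
#'   `precision`, `z`, `significant` (and `cohort` when given). Pairs with no
#'   significant rule contribute no rows.
#' @export
infer_network <- function(calls_a, calls_b = NULL, pairs, z_crit = 1.64,
                          min_samples = 20, keep = c("best", "significant"),
                          cohort = NULL) {
  keep <- match.arg(keep)
  if (is.null(calls_b)) calls_b <- calls_a
  stopifnot(is.matrix(calls_a), is.matrix(calls_b))
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) return(empty_rules(cohort))
  stopifnot(all(c("source", "target") %in% names(pairs)))
  missing_a <- setdiff(unique(pairs$source), rownames(calls_a))
  missing_b <- setdiff(unique(pairs$target), rownames(calls_b))
  if (length(missing_a) + length(missing_b) > 0) {
    imp_abort(paste0("Genes absent from call matrices: ",
                     paste(unique(c(missing_a, missing_b)), collapse = ", ")),
              "missing_gene", genes = unique(c(missing_a, missing_b)))
  }
  shared <- intersect(colnames(calls_a), colnames(calls_b))
  if (length(shared) < min_samples) {
    imp_abort("Too few shared samples between the two layers.",
              "insufficient_samples")
  }
  layer_a <- call_layer(calls_a)
  layer_b <- call_layer(calls_b)
  rows <- purrr::pmap(pairs[c("source", "target")], function(source, target) {
    tab <- build_table(calls_a[source, shared], calls_b[target, shared],
                       min_samples = min_samples)
    scored <- if (keep == "best") {
      sig <- score_pair_rules(tab, z_crit)
      sig <- sig[sig$significant, , drop = FALSE]
      if (nrow(sig) == 0) return(NULL)
      ord <- order(-sig$precision, -sig$scope, match(sig$rule_type, rule_types()))
      sig[ord[1], , drop = FALSE]
    } else {
      sig <- score_pair_rules(tab, z_crit)
      sig <- sig[sig$significant, , drop = FALSE]
      if (nrow(sig) == 0) return(NULL)
      sig
    }
    mutate(scored, source = source, target = target, .before = 1)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty_rules(cohort))
  out <- mutate(out,
                source_layer = layer_a, target_layer = layer_b,
                relation = rule_relation(.data$rule_type)) %>%
    select("source", "source_layer", "target", "target_layer", "rule_type",
           "relation", "n", "e_obs", "e_exp", "scope", "precision", "z",
           "significant")
  if (!is.null(cohort)) out$cohort <- cohort
  out
}

empty_rules <- function(cohort = NULL) {
  out <- tibble(
    source = character(), source_layer = character(), target = character(),
    target_layer = character(), rule_type = character(), relation = character(),
    n = integer(), e_obs = numeric(), e_exp = numeric(), scope = numeric(),
    precision = numeric(), z = numeric(), significant = logical()
  )
  if (!is.null(cohort)) out$cohort <- character()
  out
}

#' Intersect implication rules across cohorts
#'
#' Keeps the (source, source layer, target, target layer, rule type) entries
#' that are significant in every supplied cohort with the same rule type — a
#' regulatory direction must replicate to survive. Pairs significant in
#' several cohorts but with non-matching rule types are dropped (a message
#' reports how many).
#'
#' @param ... Two or more rule tibbles from [infer_network()]. If a tibble
#'   lacks a `cohort` column its argument name (or positional label) is used.
#' @return Tibble keyed by the rule identity with columns `cohorts` (labels
#'   joined by `;`), `n_cohorts`, and per-cohort minima `min_precision`,
#'   `min_scope`, `min_z`.
#' @export
intersect_cohorts <- function(...) {
  cohort_list <- list(...)
  if (length(cohort_list) == 1 && is.list(cohort_list[[1]]) &&
      !is.data.frame(cohort_list[[1]])) {
    cohort_list <- cohort_list[[1]]
  }
  if (length(cohort_list) < 2) {
    imp_abort("Need rules from at least two cohorts.", "bad_argument")
  }
  labels <- names(cohort_list)
  if (is.null(labels)) labels <- rep("", length(cohort_list))
  tagged <- purrr::imap(cohort_list, function(rules, i) {
    rules <- as_tibble(rules)
    if (!"cohort" %in% names(rules)) {
      lab <- if (is.character(i) && nzchar(i)) i else paste0("cohort", i)
      rules$cohort <- rep(lab, nrow(rules))
    }
    filter(rules, .data$significant)
  })
  all_rules <- bind_rows(tagged)
  key <- c("source", "source_layer", "target", "target_layer")
  n_cohorts <- length(cohort_list)
  if (nrow(all_rules) == 0) {
    return(mutate(empty_rules()[, key], rule_type = character(),
                  relation = character(), cohorts = character(),
                  n_cohorts = integer(), min_precision = numeric(),
                  min_scope = numeric(), min_z = numeric()))
  }
  per_rule <- all_rules %>%
    distinct(.data$cohort, .data$source, .data$source_layer, .data$target,
             .data$target_layer, .data$rule_type, .data$relation,
             .data$precision, .data$scope, .data$z) %>%
    group_by(.data$source, .data$source_layer, .data$target,
             .data$target_layer, .data$rule_type, .data$relation) %>%
    summarise(
      cohorts = paste(sort(unique(.data$cohort)), collapse = ";"),
      n_cohorts = dplyr::n_distinct(.data$cohort),
      min_precision = min(.data$precision),
      min_scope = min(.data$scope),
      min_z = min(.data$z),
      .groups = "drop"
    )
  kept <- filter(per_rule, .data$n_cohorts == !!n_cohorts)
  dropped_pairs <- per_rule %>%
    filter(.data$n_cohorts < !!n_cohorts) %>%
    distinct(.data$source, .data$target)
  kept_pairs <- distinct(kept, .data$source, .data$target)
  n_dropped <- nrow(dplyr::anti_join(dropped_pairs, kept_pairs,
                                     by = c("source", "target")))
  if (n_dropped > 0) {
    inform(sprintf(
      "%d pair(s) significant in some cohorts were dropped (not replicated with the same rule type in all cohorts).",
      n_dropped))
  }
  kept
}
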