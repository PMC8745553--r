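#' Planted implication pairs for synthetic cohorts
#'
#' Convenience constructor for the `planted_edges` argument of
#' [gen_expression_cohort()]: `n_pairs` disjoint gene pairs named
#' `P<k>A` / `P<k>B` with a common relation and strength.
#'
#' @param n_pairs Number of pairs.
#' @param relation `"positive"` or `"negative"` (recycled).
#' @param strength Latent-factor loading in (0, 1] (recycled).
#' @return Tibble with columns `source`, `target`, `relation`, `strength`.
#' @export
planted_pairs <- function(n_pairs = 10, relation = "positive",
                          strength = 0.9) {
  k <- seq_len(n_pairs)
  tibble(
    source = sprintf("P%02dA", k),
    target = sprintf("P%02dB", k),
    relation = rep_len(relation, n_pairs),
    strength = rep_len(strength, n_pairs)
  )
}

#' Generate a synthetic expression cohort with planted implication structure
#'
#' Background genes are iid Gaussian; housekeeping genes are Gaussian with
#' unit variance (gene-specific means); each planted pair shares a latent
#' factor with loading equal to its strength, giving corner-cell depletion
#' after discretization — the Boolean-implication analogue of
#' co-expression. A strength of 0 yields independence; negative relations
#' load the second gene with the opposite sign. Different cohorts generated
#' from the same `planted_edges` with different seeds share the truth but
#' have independent noise.
#'
#' @param n_samples Number of samples (default 200).
#' @param n_background Number of unstructured background genes (default 30).
#' @param planted_edges Tibble from [planted_pairs()] (pair genes must be
#'   distinct from background and housekeeping names); `NULL` for none.
#' @param housekeeping Housekeeping gene names included as rows (default the
#'   27-gene panel).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return List with `expr` (matrix, genes x samples) and `truth` (list:
#'   `planted_edges`, `seed`, `n_samples`).
#' @export
gen_expression_cohort <- function(n_samples = 200, n_background = 30,
                                  planted_edges = planted_pairs(),
                                  housekeeping = housekeeping_genes(),
                                  seed = 1) {
  gen <- function() {
    rows <- list()
    for (g in housekeeping) {
      rows[[g]] <- rnorm(n_samples, mean = runif(1, 5, 10), sd = 1)
    }
    if (n_background > 0) {
      for (i in seq_len(n_background)) {
        rows[[sprintf("BG%03d", i)]] <- rnorm(n_samples)
      }
    }
    if (!is.null(planted_edges) && nrow(planted_edges) > 0) {
      planted_edges <- as_tibble(planted_edges)
      genes <- c(planted_edges$source, planted_edges$target)
      if (anyDuplicated(genes) > 0) {
        imp_abort("Planted pair genes must be distinct across pairs.",
                  "bad_argument")
      }
      for (i in seq_len(nrow(planted_edges))) {
        s <- planted_edges$strength[i]
        stopifnot(s >= 0, s <= 1)
        z <- rnorm(n_samples)
        flip <- if (planted_edges$relation[i] == "negative") -1 else 1
        rows[[planted_edges$source[i]]] <-
          s * z + sqrt(1 - s^2) * rnorm(n_samples)
        rows[[planted_edges$target[i]]] <-
          flip * s * z + sqrt(1 - s^2) * rnorm(n_samples)
      }
    }
    expr <- do.call(rbind, rows)
    colnames(expr) <- sprintf("S%03d", seq_len(n_samples))
    expr
  }
  expr <- withr::with_seed(seed, gen())
  list(expr = expr,
       truth = list(planted_edges = planted_edges, seed = seed,
                    n_samples = n_samples))
}

#' Generate CNV states with planted dosage effects on expression
#'
#' Copy-number states are drawn iid from \{-1, 0, 1\} with the given
#' frequencies. For each planted dosage pair the target gene's expression is
#' its own Gaussian noise plus `strength` times the source gene's CNV state
#' (a shift of one strength-unit of its standard deviation per copy-number
#' level) — the synthetic analogue of copy-number-mediated transcription.
#'
#' @param n_samples Number of samples.
#' @param n_background_cnv,n_background_expr Unstructured genes per layer.
#' @param dosage_pairs Tibble with `source` (CNV gene), `target` (expression
#'   gene), `strength` (>= 0).
#' @param cnv_freq Length-3 frequency vector for states (-1, 0, 1).
#' @param seed Integer seed.
#' @return List with `cnv` (integer matrix), `expr` (matrix) and `truth`.
#' @export
gen_cnv_with_dosage <- function(n_samples = 200, n_background_cnv = 10,
                                n_background_expr = 10,
                                dosage_pairs = tibble(
                                  source = "CNV01", target = "TGT01",
                                  strength = 1
                                ),
                                cnv_freq = c(0.2, 0.6, 0.2), seed = 1) {
  stopifnot(length(cnv_freq) == 3, all(cnv_freq >= 0))
  dosage_pairs <- as_tibble(dosage_pairs)
  gen <- function() {
    draw_states <- function() {
      sample(c(-1L, 0L, 1L), n_samples, replace = TRUE,
             prob = cnv_freq / sum(cnv_freq))
    }
    cnv_rows <- list()
    for (g in unique(dosage_pairs$source)) cnv_rows[[g]] <- draw_states()
    for (i in seq_len(n_background_cnv)) {
      cnv_rows[[sprintf("CNVBG%03d", i)]] <- draw_states()
    }
    expr_rows <- list()
    for (i in seq_len(nrow(dosage_pairs))) {
      expr_rows[[dosage_pairs$target[i]]] <-
        rnorm(n_samples) +
        dosage_pairs$strength[i] * cnv_rows[[dosage_pairs$source[i]]]
    }
    for (i in seq_len(n_background_expr)) {
      expr_rows[[sprintf("GEBG%03d", i)]] <- rnorm(n_samples)
    }
    samples <- sprintf("S%03d", seq_len(n_samples))
    cnv <- do.call(rbind, cnv_rows)
    expr <- do.call(rbind, expr_rows)
    colnames(cnv) <- samples
    colnames(expr) <- samples
    list(cnv = cnv, expr = expr)
  }
  mats <- withr::with_seed(seed, gen())
  list(cnv = mats$cnv, expr = mats$expr,
       truth = list(dosage_pairs = dosage_pairs, cnv_freq = cnv_freq,
                    seed = seed))
}

#' Generate proportional-hazards survival data
#'
#' Covariates are iid standard normal; event times are exponential with
#' hazard `baseline_rate * exp(sum(beta * x))` (months); censoring is
#' independent uniform on `(0, c_max)` with `c_max` calibrated so the
#' realized censoring fraction matches `censoring_rate`. Stage and
#' radiotherapy flags are drawn independently so the radiotherapy
#' differential-expression grouping can be exercised.
#'
#' @param n Number of patients.
#' @param betas Named vector of log-hazard coefficients; names become
#'   covariate columns. Default: the seven signature genes with
#'   `(0.5, -0.5, 0.3, 0, 0, 0, 0.2)`.
#' @param censoring_rate Target censoring fraction in `[0, 1)` (default 0.3).
#' @param baseline_median Median survival (months) at covariates 0
#'   (default 36).
#' @param seed Integer seed.
#' @return List with `clinical` (tibble: `patient_id`, `time`, `event`,
#'   `stage`, `radiotherapy`, one column per covariate) and `truth`.
#' @export
gen_survival <- function(n = 1000,
                         betas = setNames(c(0.5, -0.5, 0.3, 0, 0, 0, 0.2),
                                          signature_genes()),
                         censoring_rate = 0.3, baseline_median = 36,
                         seed = 1) {
  stopifnot(!is.null(names(betas)), censoring_rate >= 0, censoring_rate < 1)
  gen <- function() {
    x <- matrix(rnorm(n * length(betas)), n, length(betas),
                dimnames = list(NULL, names(betas)))
    lp <- as.numeric(x %*% betas)
    rate0 <- log(2) / baseline_median
    t_event <- rexp(n, rate = rate0 * exp(lp))
    if (censoring_rate > 0) {
      expected_censoring <- function(c_max) mean(pmin(t_event / c_max, 1))
      c_max <- uniroot(function(cc) expected_censoring(cc) - censoring_rate,
                       lower = 1e-6, upper = 1e6, tol = 1e-8)$root
      cens <- runif(n, 0, c_max)
    } else {
      cens <- rep(Inf, n)
    }
    tibble(
      patient_id = sprintf("PT%04d", seq_len(n)),
      time = pmin(t_event, cens),
      event = as.integer(t_event <= cens),
      stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
      radiotherapy = runif(n) < 0.5
    ) %>% bind_cols(as_tibble(x))
  }
  clinical <- withr::with_seed(seed, gen())
  list(clinical = clinical,
       truth = list(betas = betas, censoring_rate = censoring_rate,
                    baseline_median = baseline_median, seed = seed))
}

#' Generate a synthetic dependency screen with planted dependent genes
#'
#' True effects: essential controls centred at -1, non-essential controls
#' and background genes at 0, and each planted gene at `dependent_score` in
#' its dependent fraction of cell lines. Every cell line then distorts the
#' true effects by its own affine map (random scale and shift) so that the
#' control-median normalization has real work to do; a missing mask is
#' applied to non-control genes.
#'
#' @param n_background Background (non-control, non-planted) genes.
#' @param n_lines Cell lines.
#' @param n_essential,n_nonessential Control-set sizes.
#' @param planted Named numeric vector: gene name -> fraction of lines in
#'   which the gene is dependent. Default five genes at 0.7.
#' @param dependent_score True effect in dependent lines (default -0.9;
#'   compare with the -0.5 significance cutoff).
#' @param noise_sd Measurement noise on the true effects (default 0.05).
#' @param missing_rate Fraction of non-control measurements masked as NA.
#' @param assay `"CRISPR"` or `"RNAi"`.
#' @param seed Integer seed.
#' @return List with `screen` (a raw [dependency_screen()]) and `truth`.
#' @export
gen_dependency_screen <- function(n_background = 40, n_lines = 40,
                                  n_essential = 15, n_nonessential = 15,
                                  planted = setNames(rep(0.7, 5),
                                                     sprintf("DEP%02d", 1:5)),
                                  dependent_score = -0.9, noise_sd = 0.05,
                                  missing_rate = 0, assay = "CRISPR",
                                  seed = 1) {
  gen <- function() {
    ess <- sprintf("ESS%03d", seq_len(n_essential))
    ness <- sprintf("NE%03d", seq_len(n_nonessential))
    bg <- sprintf("BG%03d", seq_len(n_background))
    genes <- c(ess, ness, bg, names(planted))
    true <- matrix(rnorm(length(genes) * n_lines, 0, noise_sd),
                   length(genes), n_lines,
                   dimnames = list(genes, sprintf("CL%03d", seq_len(n_lines))))
    true[ess, ] <- true[ess, ] - 1
    for (g in names(planted)) {
      n_dep <- round(planted[[g]] * n_lines)
      dep_lines <- sample(n_lines, n_dep)
      true[g, dep_lines] <- true[g, dep_lines] + dependent_score
    }
    scale_c <- runif(n_lines, 1.5, 2.5)
    shift_c <- rnorm(n_lines, 0.2, 0.1)
    raw <- sweep(sweep(true, 2, scale_c, `*`), 2, shift_c, `+`)
    if (missing_rate > 0) {
      maskable <- c(bg, names(planted))
      mask <- matrix(runif(length(maskable) * n_lines) < missing_rate,
                     length(maskable), n_lines)
      raw[maskable, ][mask] <- NA
    }
    list(raw = raw, ess = ess, ness = ness)
  }
  parts <- withr::with_seed(seed, gen())
  screen <- dependency_screen(parts$raw, essential = parts$ess,
                              nonessential = parts$ness, assay = assay)
  list(screen = screen,
       truth = list(planted = planted, dependent_score = dependent_score,
                    missing_rate = missing_rate, n_lines = n_lines,
                    seed = seed))
}

#' Generate drug-activity records and matched expression
#'
#' Sensitive lines get IC50/EC50 below the minimum tested dose, resistant
#' lines above the maximum, partial responders inside the window; planted
#' differentially expressed genes separate the sensitive and resistant
#' groups at the requested means.
#'
#' @param n_sensitive,n_partial,n_resistant Cell-line counts per planted
#'   category.
#' @param n_background Unstructured genes in the expression matrix.
#' @param de_genes Character vector of planted DE gene names.
#' @param de_mean_sensitive,de_mean_resistant Group means for planted DE
#'   genes on the linear scale (defaults 10 and 4: fold change 2.5).
#' @param background_mean Mean of unstructured genes (default 8).
#' @param sd Within-group standard deviation (default 1).
#' @param drug Drug name recorded on the activity records.
#' @param min_dose,max_dose Assay dose window (default 0.0006 and 10).
#' @param seed Integer seed.
#' @return List with `activity` (tibble: `cell_line`, `drug`, `metric`,
#'   `value`, `min_dose`, `max_dose`, `true_category`), `expr` (matrix) and
#'   `truth`.
#' @export
gen_drug_activity <- function(n_sensitive = 8, n_partial = 8,
                              n_resistant = 8, n_background = 40,
                              de_genes = sprintf("DE%02d", 1:5),
                              de_mean_sensitive = 10, de_mean_resistant = 4,
                              background_mean = 8, sd = 1, drug = "drugA",
                              min_dose = 0.0006, max_dose = 10, seed = 1) {
  gen <- function() {
    n_lines <- n_sensitive + n_partial + n_resistant
    lines <- sprintf("CL%03d", seq_len(n_lines))
    cat3 <- rep(c("sensitive", "partial", "resistant"),
                c(n_sensitive, n_partial, n_resistant))
    lo <- log10(min_dose)
    hi <- log10(max_dose)
    value <- numeric(n_lines)
    value[cat3 == "sensitive"] <- 10^(lo - runif(n_sensitive, 0.3, 2))
    value[cat3 == "resistant"] <- 10^(hi + runif(n_resistant, 0.3, 2))
    value[cat3 == "partial"] <-
      10^runif(n_partial, lo + 0.4 * (hi - lo), lo + 0.6 * (hi - lo))
    activity <- tibble(
      cell_line = lines, drug = drug,
      metric = rep_len(c("IC50", "EC50"), n_lines),
      value = value, min_dose = min_dose, max_dose = max_dose,
      true_category = cat3
    )
    expr <- matrix(rnorm(n_background * n_lines, background_mean, sd),
                   n_background, n_lines,
                   dimnames = list(sprintf("BG%03d", seq_len(n_background)),
                                   lines))
    de <- matrix(rnorm(length(de_genes) * n_lines, background_mean, sd),
                 length(de_genes), n_lines,
                 dimnames = list(de_genes, lines))
    de[, cat3 == "sensitive"] <- rnorm(length(de_genes) * n_sensitive,
                                       de_mean_sensitive, sd)
    de[, cat3 == "resistant"] <- rnorm(length(de_genes) * n_resistant,
                                       de_mean_resistant, sd)
    list(activity = activity, expr = rbind(de, expr))
  }
  parts <- withr::with_seed(seed, gen())
  list(activity = parts$activity, expr = parts$expr,
       truth = list(de_genes = de_genes,
                    de_means = c(sensitive = de_mean_sensitive,
                                 resistant = de_mean_resistant),
                    dose_window = c(min_dose, max_dose), seed = seed))
}

#' Serialize a generator's ground truth as JSON
#'
#' @param truth The `truth` element returned by a generator.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
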