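#' Pipeline configuration with the study's printed constants as defaults
#'
#' Central configuration object: every stage reads its thresholds from here
#' and from nowhere else, and the full set is serialized into the run
#' manifest of [run_pipeline()].
#'
#' @param z_crit One-tailed implication z threshold (default 1.64, alpha =
#'   0.05).
#' @param target_fraction Housekeeping flagged-sample fraction (default
#'   0.30).
#' @param cnv_gain,cnv_loss CNV categorization thresholds (defaults 0.3 /
#'   -0.3 on log-ratio input).
#' @param dependency_threshold Significant-dependency cutoff (default -0.5).
#' @param proliferation_min_lines Strict line-count rule bound (default 10).
#' @param proliferation_fraction Majority-rule tested-line fraction
#'   (default 0.5).
#' @param risk_cutoff Risk-score stratification cutoff (default -0.74).
#' @param short_survival_max,long_survival_min Radiotherapy DE group bounds
#'   in months (defaults 20 and 58).
#' @param fc_bounds Fold-change filter bounds (default `c(0.5, 2)`).
#' @param dose_window IC50/EC50 assay window in micromolar (default
#'   `c(0.0006, 10)`).
#' @param min_samples Minimum shared samples per inferred pair (default 20).
#' @param min_seed_degree Distinct-seed bound for network membership
#'   (default 2).
#' @param seeds Seed gene list (default the seven signature genes).
#' @param seed Random seed for the run.
#' @return An `implinet_config` list.
#' @export
implinet_config <- function(z_crit = 1.64, target_fraction = 0.30,
                            cnv_gain = 0.3, cnv_loss = -0.3,
                            dependency_threshold = -0.5,
                            proliferation_min_lines = 10,
                            proliferation_fraction = 0.5,
                            risk_cutoff = -0.74,
                            short_survival_max = 20, long_survival_min = 58,
                            fc_bounds = c(0.5, 2),
                            dose_window = c(0.0006, 10),
                            min_samples = 20, min_seed_degree = 2,
                            seeds = signature_genes(), seed = 1) {
  structure(
    list(
      z_crit = z_crit, target_fraction = target_fraction,
      cnv_gain = cnv_gain, cnv_loss = cnv_loss,
      dependency_threshold = dependency_threshold,
      proliferation_min_lines = proliferation_min_lines,
      proliferation_fraction = proliferation_fraction,
      risk_cutoff = risk_cutoff,
      short_survival_max = short_survival_max,
      long_survival_min = long_survival_min,
      fc_bounds = fc_bounds, dose_window = dose_window,
      min_samples = min_samples, min_seed_degree = min_seed_degree,
      seeds = seeds, seed = seed
    ),
    class = "implinet_config"
  )
}

#' Run the synthetic end-to-end analysis
#'
#' Executes the pipeline stages in dependency order on two synthetic
#' cohorts sharing the same planted truth: generate cohorts, discretize
#' each with its housekeeping-calibrated threshold, infer implication rules
#' for the planted and decoy pairs, intersect the cohorts, assemble the
#' seed network, call proliferation genes on a synthetic screen, and export
#' a query signature. Each stage writes a plain-text artifact into
#' `out_dir`, and `manifest.json` records thresholds, seeds, per-file MD5
#' digests and package version — re-running with the same config reproduces
#' identical digests. On a stage failure the partial manifest (with the
#' failing stage and cause) is still written before the error propagates.
#'
#' @param config An [implinet_config()].
#' @param out_dir Output directory (created if needed).
#' @param expr_paths Optional named character vector of two expression TSV
#'   paths to use as cohorts instead of generating synthetic ones.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config = implinet_config(), out_dir,
                         expr_paths = NULL) {
  stopifnot(inherits(config, "implinet_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("implinet")),
    config = unclass(config),
    stages = list(),
    files = list()
  )
  current_stage <- NA_character_
  finish <- function() {
    paths <- unlist(manifest$files, use.names = FALSE)
    if (length(paths) > 0) {
      digests <- tools::md5sum(paths)
      manifest$digests <<- as.list(setNames(unname(digests), basename(paths)))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, fn) {
    current_stage <<- name
    result <- tryCatch(fn(), error = function(e) {
      manifest$failed_stage <<- list(stage = name,
                                     cause = conditionMessage(e))
      finish()
      imp_abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
                "stage_error")
    })
    manifest$stages[[name]] <<- "ok"
    result
  }
  art <- function(name) {
    path <- file.path(out_dir, name)
    manifest$files[[name]] <<- path
    path
  }

  cohorts <- run_stage("cohorts", function() {
    if (!is.null(expr_paths)) {
      if (!all(file.exists(expr_paths))) {
        stop("input expression file(s) not found: ",
             paste(expr_paths[!file.exists(expr_paths)], collapse = ", "))
      }
      lapply(expr_paths, read_matrix_tsv)
    } else {
      planted <- planted_pairs(n_pairs = 8, strength = 0.9)
      out <- list(
        cohort1 = gen_expression_cohort(planted_edges = planted,
                                        seed = config$seed)$expr,
        cohort2 = gen_expression_cohort(planted_edges = planted,
                                        seed = config$seed + 1000)$expr
      )
      write_matrix_tsv(out$cohort1, art("cohort1_expr.tsv"))
      write_matrix_tsv(out$cohort2, art("cohort2_expr.tsv"))
      out
    }
  })

  calls <- run_stage("discretize", function() {
    out <- lapply(cohorts, function(expr) {
      n_hat <- average_housekeeping_n(expr,
                                      housekeeping = intersect(housekeeping_genes(),
                                                               rownames(expr)),
                                      target_fraction = config$target_fraction)
      discretize_expression(expr, n_hat)
    })
    purrr::iwalk(out, function(cl, nm) {
      write_calls_tsv(cl, art(paste0(nm, "_calls.tsv")),
                      extra = list(target_fraction = config$target_fraction))
    })
    out
  })

  rules <- run_stage("infer", function() {
    genes <- setdiff(rownames(cohorts[[1]]), housekeeping_genes())
    planted_sources <- grep("A$", grep("^P", genes, value = TRUE), value = TRUE)
    pairs <- bind_rows(
      tibble(source = planted_sources,
             target = sub("A$", "B", planted_sources)),
      tibble(source = grep("^BG", genes, value = TRUE)[1:10],
             target = grep("^BG", genes, value = TRUE)[11:20])
    )
    out <- purrr::imap(calls, function(cl, nm) {
      infer_network(cl, pairs = pairs, z_crit = config$z_crit,
                    min_samples = config$min_samples, keep = "significant",
                    cohort = nm)
    })
    purrr::iwalk(out, function(r, nm) {
      write_edges_tsv(r, art(paste0(nm, "_edges.tsv")))
    })
    out
  })

  replicated <- run_stage("intersect", function() {
    out <- intersect_cohorts(rules)
    write_edges_tsv(out, art("replicated_edges.tsv"))
    out
  })

  network <- run_stage("assemble", function() {
    genes <- setdiff(rownames(cohorts[[1]]), housekeeping_genes())
    seeds <- grep("^P", genes, value = TRUE)
    if (length(seeds) == 0) seeds <- config$seeds
    net <- seed_filter(replicated, seeds = seeds,
                       min_seed_degree = config$min_seed_degree)
    write_network(net, art("network.graphml"))
    net
  })

  screen <- run_stage("dependency", function() {
    sc <- gen_dependency_screen(seed = config$seed)
    norm <- normalize_crispr(sc$screen)
    prolif <- proliferation_genes_count(crispr = norm,
                                        min_lines = config$proliferation_min_lines,
                                        threshold = config$dependency_threshold)
    write_grp(prolif, art("proliferation_genes.grp"))
    prolif
  })

  run_stage("signature", function() {
    sig <- build_mechanism_signature(proliferation = setdiff(screen, epithelial_markers()))
    write_gmt(sig, art("mechanism_signature.gmt"))
    sig
  })

  finish()
  invisible(manifest)
}
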