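new_multiomics_network <- function(nodes, edges, seeds, min_seed_degree) {
  structure(
    list(nodes = nodes, edges = edges, seeds = seeds,
         min_seed_degree = min_seed_degree),
    class = "multiomics_network"
  )
}

#' @export
print.multiomics_network <- function(x, ...) {
  cat(sprintf(
    "<multiomics_network> %d nodes (%d seeds, %d proliferation), %d edges\n",
    nrow(x$nodes), sum(x$nodes$is_seed), sum(x$nodes$is_proliferation),
    nrow(x$edges)
  ))
  invisible(x)
}

#' Assemble the seed-anchored multi-omics network
#'
#' Retains non-seed genes whose cross-cohort-significant edges connect them
#' to at least `min_seed_degree` distinct seed genes (distinct genes, not
#' edges: a gene linked twice to one seed through different layers counts
#' once). Seeds are always retained; edges whose endpoints are not both
#' retained are removed.
#'
#' @param edges Tibble of replicated rules, e.g. from [intersect_cohorts()]
#'   (any tibble with `source`/`target` columns works; a `cohorts` column is
#'   carried along).
#' @param seeds Character vector of seed gene symbols; defaults to the seven
#'   prognostic signature genes.
#' @param min_seed_degree Minimum number of distinct seed neighbours a
#'   non-seed gene needs to enter the network (default 2).
#' @return A `multiomics_network`: list with `nodes` (tibble: `gene`,
#'   `is_seed`, `is_proliferation`, `seed_degree`) and `edges` tibbles.
#' @export
seed_filter <- function(edges, seeds = signature_genes(), min_seed_degree = 2) {
  edges <- as_tibble(edges)
  stopifnot(all(c("source", "target") %in% names(edges)))
  long <- bind_rows(
    tibble(gene = edges$source, partner = edges$target),
    tibble(gene = edges$target, partner = edges$source)
  )
  seed_degree <- long %>%
    filter(.data$partner %in% seeds, !(.data$gene %in% seeds)) %>%
    distinct(.data$gene, .data$partner) %>%
    count(.data$gene, name = "seed_degree")
  kept_nonseed <- seed_degree$gene[seed_degree$seed_degree >= min_seed_degree]
  genes <- union(seeds, kept_nonseed)
  kept_edges <- filter(edges, .data$source %in% genes, .data$target %in% genes)
  nodes <- tibble(gene = genes) %>%
    left_join(seed_degree, by = "gene") %>%
    mutate(
      seed_degree = ifelse(is.na(.data$seed_degree), 0L, .data$seed_degree),
      is_seed = .data$gene %in% seeds,
      is_proliferation = FALSE
    ) %>%
    arrange(desc(.data$is_seed), .data$gene)
  if (nrow(kept_edges) == 0) {
    warn("No edges satisfy the seed-degree filter; returning an empty network.")
  }
  new_multiomics_network(nodes, kept_edges, seeds, min_seed_degree)
}

#' Flag proliferation genes in a network
#'
#' @param network A `multiomics_network`.
#' @param proliferation_genes Character vector, e.g. from
#'   [proliferation_genes_majority()].
#' @return The network with `is_proliferation` set on matching nodes.
#' @export
annotate_proliferation <- function(network, proliferation_genes) {
  stopifnot(inherits(network, "multiomics_network"))
  hit <- network$nodes$gene %in% proliferation_genes
  network$nodes$is_proliferation <- hit
  if (length(proliferation_genes) > 0 && !any(hit)) {
    warn("None of the proliferation genes occur in the network.")
  }
  inform(sprintf("%d node(s) flagged as proliferation genes.", sum(hit)))
  network
}

#' Differential expression between short- and long-survival patient groups
#'
#' Selects two disjoint patient groups from a clinical table (by default:
#' stage III/IV patients who received radiotherapy, split into survival
#' shorter than 20 months versus longer than 58 months) and runs a per-gene
#' two-sample t-test (Welch by default) between them.
#'
#' @param expr Expression matrix, genes x patients (columns named by
#'   patient id).
#' @param clinical Data frame with columns `patient_id`, `time` (months),
#'   and — when the default grouping is used — `stage` and `radiotherapy`.
#' @param short_max,long_min Group bounds in months (default 20 and 58;
#'   strict inequalities).
#' @param stages Stages retained before grouping (default III/IV; set `NULL`
#'   to keep all).
#' @param require_radiotherapy Keep only patients with `radiotherapy == TRUE`
#'   (default) before grouping.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @param p_cutoff Two-sided significance level (default 0.05).
#' @return Tibble: `gene`, `mean_short`, `mean_long`, `n_short`, `n_long`,
#'   `t`, `p`, `significant`.
#' @export
differential_expression_groups <- function(expr, clinical, short_max = 20,
                                           long_min = 58,
                                           stages = c("III", "IV"),
                                           require_radiotherapy = TRUE,
                                           pooled = FALSE, p_cutoff = 0.05) {
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  clinical <- as_tibble(clinical)
  stopifnot(all(c("patient_id", "time") %in% names(clinical)))
  pool <- clinical
  if (!is.null(stages)) pool <- filter(pool, .data$stage %in% stages)
  if (require_radiotherapy) pool <- filter(pool, .data$radiotherapy)
  short_ids <- pool$patient_id[pool$time < short_max]
  long_ids <- pool$patient_id[pool$time > long_min]
  short_ids <- intersect(short_ids, colnames(expr))
  long_ids <- intersect(long_ids, colnames(expr))
  if (length(short_ids) < 3 || length(long_ids) < 3) {
    imp_abort(sprintf("Groups too small (short %d, long %d; need >= 3 each).",
                      length(short_ids), length(long_ids)),
              "insufficient_samples")
  }
  res <- apply(expr, 1, function(x) {
    ht <- t.test(x[short_ids], x[long_ids], var.equal = pooled)
    c(mean_short = unname(mean(x[short_ids])),
      mean_long = unname(mean(x[long_ids])),
      t = unname(ht$statistic), p = ht$p.value)
  })
  tibble(
    gene = rownames(expr),
    mean_short = unname(res["mean_short", ]),
    mean_long = unname(res["mean_long", ]),
    n_short = length(short_ids),
    n_long = length(long_ids),
    t = unname(res["t", ]),
    p = unname(res["p", ])
  ) %>%
    mutate(significant = .data$p < p_cutoff)
}

#' Convert a multi-omics network to an igraph object
#'
#' Node flags (`is_seed`, `is_proliferation`) and all edge columns become
#' igraph attributes, so [write_network()] round-trips exactly.
#'
#' @param network A `multiomics_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "multiomics_network"))
  igraph::graph_from_data_frame(
    d = select(network$edges, "source", "target", dplyr::everything()),
    directed = FALSE,
    vertices = network$nodes
  )
}

#' Write / read a multi-omics network
#'
#' `write_network()` exports GraphML (via igraph) or SIF; `read_network()`
#' restores a `multiomics_network` from the GraphML export.
#'
#' @param network A `multiomics_network`.
#' @param path Output file.
#' @param format `"graphml"` or `"sif"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `multiomics_network`.
#' @export
write_network <- function(network, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    rel <- if ("rule_type" %in% names(network$edges)) {
      network$edges$rule_type
    } else {
      rep("associates", nrow(network$edges))
    }
    writeLines(paste(network$edges$source, rel, network$edges$target,
                     sep = "\t"), path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices")) %>%
    rename(gene = "name")
  if ("id" %in% names(nodes)) nodes$id <- NULL
  edges <- as_tibble(igraph::as_data_frame(g, what = "edges")) %>%
    rename(source = "from", target = "to")
  seeds <- nodes$gene[as.logical(nodes$is_seed)]
  nodes$is_seed <- as.logical(nodes$is_seed)
  nodes$is_proliferation <- as.logical(nodes$is_proliferation)
  if ("seed_degree" %in% names(nodes)) {
    nodes$seed_degree <- as.integer(nodes$seed_degree)
  }
  new_multiomics_network(nodes, edges, seeds, NA_integer_)
}

#' @export
tidy.multiomics_network <- function(x, ...) {
  x$edges
}

#' @export
glance.multiomics_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_seeds = sum(x$nodes$is_seed),
    n_proliferation = sum(x$nodes$is_proliferation),
    n_edges = nrow(x$edges)
  )
}

#' @export
autoplot.multiomics_network <- function(object, seed_layout = 1L, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed_layout, igraph::layout_with_fr(g))
  nodes <- object$nodes %>%
    mutate(x = xy[, 1], y = xy[, 2],
           role = case_when(.data$is_seed ~ "seed",
                            .data$is_proliferation ~ "proliferation",
                            TRUE ~ "network"))
  ends <- igraph::as_data_frame(g, what = "edges")
  seg <- tibble(
    x = nodes$x[match(ends$from, nodes$gene)],
    y = nodes$y[match(ends$from, nodes$gene)],
    xend = nodes$x[match(ends$to, nodes$gene)],
    yend = nodes$y[match(ends$to, nodes$gene)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$role), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$gene),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}
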