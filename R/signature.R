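#' Construct a connectivity-map query signature
#'
#' A named pair of disjoint up-/down-regulated gene lists with provenance,
#' ready for export as GRP or GMT query files.
#'
#' @param name Signature name.
#' @param up,down Character vectors of gene symbols (deduplicated, order
#'   preserved). They must not overlap.
#' @param provenance Named list recording the construction rule and its
#'   parameters.
#' @return A `query_signature` object.
#' @export
query_signature <- function(name, up, down, provenance = list()) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  clash <- intersect(up, down)
  if (length(clash) > 0) {
    imp_abort(paste0("Genes in both up and down lists: ",
                     paste(clash, collapse = ", ")),
              "consistency_error", genes = clash)
  }
  structure(list(name = name, up = up, down = down, provenance = provenance),
            class = "query_signature")
}

#' @export
print.query_signature <- function(x, ...) {
  cat(sprintf("<query_signature> %s: %d up / %d down genes\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' @export
tidy.query_signature <- function(x, ...) {
  bind_rows(
    tibble(gene = x$up, direction = "up"),
    tibble(gene = x$down, direction = "down")
  ) %>% mutate(signature = x$name, .before = 1)
}

#' Proliferation signature of a seed gene (or isoform) network
#'
#' Restricts the genes significantly co-expressed with a seed (e.g. ZNF71,
#' its KRAB isoform, or its KRAB-less isoform) to proliferation genes, and
#' partitions them into up-/down-regulated lists according to the consequent
#' state each implication rule assigns under the given seed direction: with
#' an up-regulated seed, positively related partners are up and inversely
#' related partners are down; with a down-regulated seed the partition
#' swaps. When a partner carries several significant rules the
#' highest-precision rule decides its sign.
#'
#' @param edges Rule tibble from [infer_network()] containing the seed's
#'   edges.
#' @param seed_gene The seed gene/isoform identifier as it appears in
#'   `edges`.
#' @param direction Seed state: `"up"` (up-regulated or not down-regulated)
#'   or `"down"`.
#' @param proliferation_genes Character vector restricting the partners.
#' @return A [query_signature()].
#' @export
build_isoform_signature <- function(edges, seed_gene,
                                    direction = c("up", "down"),
                                    proliferation_genes) {
  direction <- match.arg(direction)
  edges <- as_tibble(edges)
  touching <- filter(edges,
                     .data$source == seed_gene | .data$target == seed_gene)
  partners <- touching %>%
    mutate(partner = ifelse(.data$source == seed_gene,
                            .data$target, .data$source)) %>%
    filter(.data$partner %in% proliferation_genes)
  if (nrow(partners) == 0) {
    imp_abort("No proliferation genes co-expressed with the seed.",
              "empty_signature")
  }
  signed <- partners %>%
    group_by(.data$partner) %>%
    arrange(desc(.data$precision), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    mutate(sign = ifelse(.data$relation == "positive", 1L, -1L))
  if (direction == "down") signed$sign <- -signed$sign
  query_signature(
    name = paste(seed_gene, direction, sep = "_"),
    up = signed$partner[signed$sign > 0],
    down = signed$partner[signed$sign < 0],
    provenance = list(rule = "isoform_proliferation_network",
                      seed = seed_gene, direction = direction)
  )
}

#' Genes consistently associated with drug sensitivity
#'
#' From pooled [de_by_response()] output (across drugs and screening
#' datasets), keeps genes reported as higher-in-sensitive for at least one
#' drug and never reported as higher-in-resistant for any drug.
#'
#' @param de_results Tibble with columns `gene`, `direction`, `reported`
#'   (rows from one or more `de_by_response()` calls bound together).
#' @return Sorted character vector of gene symbols.
#' @export
drug_sensitive_genes <- function(de_results) {
  de_results <- as_tibble(de_results)
  reported <- filter(de_results, .data$reported)
  sens <- unique(reported$gene[reported$direction == "higher-in-sensitive"])
  res <- unique(reported$gene[reported$direction == "higher-in-resistant"])
  sort(setdiff(sens, res))
}

#' Mechanism-of-action query signature
#'
#' Builds the combined up/down lists encoding the intended mechanisms:
#' up-regulation of epithelial markers and drug-sensitive genes;
#' down-regulation of mesenchymal markers, proliferation genes and the
#' immune-checkpoint genes. Proliferation genes are excluded from the up
#' list (and epithelial markers from the down list's proliferation term):
#' `up = (epithelial + drug_sensitive) - proliferation`;
#' `down = mesenchymal + (proliferation - epithelial) + checkpoint`.
#'
#' @param drug_sensitive Character vector from [drug_sensitive_genes()].
#' @param proliferation Character vector, typically the strict line-count
#'   proliferation genes from [proliferation_genes_count()].
#' @param epithelial,mesenchymal EMT marker lists; defaults are the 11
#'   epithelial and 3 mesenchymal markers of the 14-gene EMT classifier.
#' @param checkpoint Immune-checkpoint genes to down-regulate (default CD27
#'   and CD274).
#' @return A [query_signature()] named `"mechanism_of_action"`.
#' @export
build_mechanism_signature <- function(drug_sensitive = character(),
                                      proliferation = character(),
                                      epithelial = epithelial_markers(),
                                      mesenchymal = mesenchymal_markers(),
                                      checkpoint = immune_checkpoint_genes()) {
  up <- setdiff(union(epithelial, drug_sensitive), proliferation)
  down <- Reduce(union, list(mesenchymal, setdiff(proliferation, epithelial),
                             checkpoint))
  query_signature(
    name = "mechanism_of_action",
    up = up,
    down = down,
    provenance = list(
      rule = "mechanism_of_action",
      n_epithelial = length(epithelial),
      n_mesenchymal = length(mesenchymal),
      n_drug_sensitive = length(drug_sensitive),
      n_proliferation = length(proliferation),
      checkpoint = checkpoint
    )
  )
}

canonical_edge_keys <- function(edges) {
  # contrapositive rule type when the pair is written in the swapped order
  swapped <- c(
    UP_IMPLIES_NOTDOWN = "DOWN_IMPLIES_NOTUP",
    DOWN_IMPLIES_NOTUP = "UP_IMPLIES_NOTDOWN",
    UP_IMPLIES_NOTUP = "UP_IMPLIES_NOTUP",
    DOWN_IMPLIES_NOTDOWN = "DOWN_IMPLIES_NOTDOWN"
  )
  edges %>%
    mutate(
      a = pmin(.data$source, .data$target),
      b = pmax(.data$source, .data$target),
      key_type = ifelse(.data$source <= .data$target,
                        .data$rule_type,
                        unname(swapped[.data$rule_type]))
    ) %>%
    select("a", "b", "key_type")
}

#' Edges whose co-expression pattern replicates under perturbation
#'
#' Returns the edges of `edges_patients` whose (gene pair, rule direction)
#' also occurs in `edges_knockdown` — the check that a tumor-derived
#' co-expression relation shows the same pattern after perturbation (e.g.
#' shRNA knock-down). Pairs are compared without regard to writing order:
#' an A-to-B rule matches its B-to-A contrapositive.
#'
#' @param edges_patients,edges_knockdown Rule tibbles from
#'   [infer_network()].
#' @return The confirmed subset of `edges_patients`.
#' @export
confirm_knockdown_concordance <- function(edges_patients, edges_knockdown) {
  edges_patients <- as_tibble(edges_patients)
  edges_knockdown <- as_tibble(edges_knockdown)
  if (nrow(edges_patients) == 0 || nrow(edges_knockdown) == 0) {
    return(edges_patients[integer(0), ])
  }
  keys_p <- canonical_edge_keys(edges_patients)
  keys_k <- distinct(canonical_edge_keys(edges_knockdown))
  hit <- vapply(seq_len(nrow(keys_p)), function(i) {
    any(keys_k$a == keys_p$a[i] & keys_k$b == keys_p$b[i] &
          keys_k$key_type == keys_p$key_type[i])
  }, logical(1))
  edges_patients[hit, ]
}

#' Write / read GRP gene-list files
#'
#' GRP is the one-gene-per-line plain-text list format; lines starting with
#' `#` are comments.
#'
#' @param genes Character vector.
#' @param path File path.
#' @return `write_grp()` returns `path` invisibly; `read_grp()` a character
#'   vector.
#' @export
write_grp <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_grp
#' @export
read_grp <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write / read GMT gene-set files
#'
#' GMT holds one named gene set per line: name, description, then genes,
#' tab-separated.
#'
#' @param sets Named list of character vectors, or a single
#'   [query_signature()] (exported as two sets, `<name>_UP` and
#'   `<name>_DOWN`; both lists must be nonempty).
#' @param path File path.
#' @param description Description field (recycled).
#' @return `write_gmt()` returns `path` invisibly; `read_gmt()` a named
#'   list of character vectors.
#' @export
write_gmt <- function(sets, path, description = "implinet") {
  if (inherits(sets, "query_signature")) {
    if (length(sets$up) == 0 || length(sets$down) == 0) {
      imp_abort("Both up and down lists must be nonempty for export.",
                "empty_signature")
    }
    sets <- setNames(
      list(sets$up, sets$down),
      paste0(sets$name, c("_UP", "_DOWN"))
    )
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(
    lapply(parts, function(p) p[-(1:2)]),
    vapply(parts, `[`, character(1), 1)
  )
}

#' Export a signature as a pair of GRP files
#'
#' @param signature A [query_signature()].
#' @param dir Output directory.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_signature_grp <- function(signature, dir) {
  stopifnot(inherits(signature, "query_signature"))
  if (length(signature$up) == 0 || length(signature$down) == 0) {
    imp_abort("Both up and down lists must be nonempty for export.",
              "empty_signature")
  }
  up_path <- file.path(dir, paste0(signature$name, "_UP.grp"))
  down_path <- file.path(dir, paste0(signature$name, "_DOWN.grp"))
  write_grp(signature$up, up_path)
  write_grp(signature$down, down_path)
  invisible(c(up_path, down_path))
}
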