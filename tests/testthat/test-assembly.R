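mk_edges <- function(pairs, cohorts = "c1;c2") {
  tibble::tibble(
    source = pairs[[1]], source_layer = "GE",
    target = pairs[[2]], target_layer = "GE",
    rule_type = "UP_IMPLIES_NOTDOWN", relation = "positive",
    cohorts = cohorts, n_cohorts = 2L,
    min_precision = 1, min_scope = 0.1, min_z = 3
  )
}

test_that("seed filtering needs two distinct seed neighbours", {
  edges <- mk_edges(list(
    c("ONESEED", "TWOSEED", "TWOSEED"),
    c("CD27", "CD27", "DAG1")
  ))
  net <- seed_filter(edges, seeds = signature_genes(), min_seed_degree = 2)
  expect_true("TWOSEED" %in% net$nodes$gene)
  expect_false("ONESEED" %in% net$nodes$gene)
  expect_true(all(signature_genes() %in% net$nodes$gene))
  # a gene connected twice to one seed through two layers still counts once
  dup <- mk_edges(list(c("DUP", "DUP"), c("CD27", "CD27")))
  dup$source_layer <- c("GE", "CNV")
  net_dup <- suppressWarnings(seed_filter(dup, min_seed_degree = 2))
  expect_false("DUP" %in% net_dup$nodes$gene)
})

test_that("seed filtering retains exactly the planted multi-seed genes", {
  withr::local_seed(17)
  true_genes <- sprintf("TRUE%02d", 1:12)
  decoys <- sprintf("DECOY%02d", 1:20)
  seeds <- signature_genes()
  src <- c()
  tgt <- c()
  for (g in true_genes) {
    picked <- sample(seeds, 2)
    src <- c(src, g, g)
    tgt <- c(tgt, picked)
  }
  for (g in decoys) {
    src <- c(src, g)
    tgt <- c(tgt, sample(seeds, 1))
  }
  net <- seed_filter(mk_edges(list(src, tgt)), seeds = seeds,
                     min_seed_degree = 2)
  expect_setequal(setdiff(net$nodes$gene, seeds), true_genes)

  # idempotence: filtering the retained edges again changes nothing
  net2 <- seed_filter(net$edges, seeds = seeds, min_seed_degree = 2)
  expect_identical(net2$nodes, net$nodes)
  expect_identical(net2$edges, net$edges)

  # removing a seed can only shrink the network
  net3 <- suppressWarnings(
    seed_filter(mk_edges(list(src, tgt)), seeds = seeds[-1],
                min_seed_degree = 2))
  expect_true(all(setdiff(net3$nodes$gene, seeds[-1]) %in%
                    setdiff(net$nodes$gene, seeds)))
})

test_that("proliferation annotation flags matching nodes and warns on misses", {
  net <- seed_filter(mk_edges(list(c("ERH", "ERH"), c("CD27", "DAG1"))))
  net <- suppressMessages(
    annotate_proliferation(net, c("ERH", "IFITM3", "NFS1", "KRT17")))
  expect_true(net$nodes$is_proliferation[net$nodes$gene == "ERH"])
  expect_identical(sum(net$nodes$is_proliferation), 1L)

  net0 <- suppressMessages(annotate_proliferation(net, character()))
  expect_false(any(net0$nodes$is_proliferation))
  expect_warning(suppressMessages(annotate_proliferation(net, "ZZZ")),
                 "None of the proliferation genes")
})

test_that("radiotherapy survival groups obey the month bounds exactly", {
  clinical <- radiotherapy_clinical(
    times = c(5, 19.9, 20, 30, 58, 58.1, 90, 10, 70),
    stage = c(rep("III", 7), "I", "II"),   # last two filtered out by stage
    radiotherapy = TRUE
  )
  expr <- matrix(rnorm(2 * 9), 2, 9,
                 dimnames = list(c("g1", "g2"), clinical$patient_id))
  # short < 20: PT001, PT002 (+ a third needed) -> enlarge groups
  clinical2 <- radiotherapy_clinical(c(5, 10, 15, 20, 39, 58, 60, 70, 80))
  expr2 <- matrix(rnorm(18), 2, 9,
                  dimnames = list(c("g1", "g2"), clinical2$patient_id))
  res <- differential_expression_groups(expr2, clinical2)
  expect_identical(unique(res$n_short), 3L)  # 5, 10, 15 (20 excluded)
  expect_identical(unique(res$n_long), 3L)   # 60, 70, 80 (58 excluded)

  expect_error(differential_expression_groups(expr, clinical),
               class = "implinet_insufficient_samples")
})

test_that("group differential expression detects planted shifts at stated power", {
  withr::local_seed(29)
  hits <- replicate(100, {
    clinical <- radiotherapy_clinical(c(runif(50, 1, 19), runif(50, 59, 120)))
    expr <- matrix(rnorm(100), 1, 100,
                   dimnames = list("g1", clinical$patient_id))
    expr[1, 1:50] <- expr[1, 1:50] + 1.5   # sd = 1
    differential_expression_groups(expr, clinical)$significant
  })
  expect_gte(mean(hits), 0.95)

  # identical group distributions stay non-significant
  clinical <- radiotherapy_clinical(c(runif(30, 1, 19), runif(30, 59, 120)))
  expr_null <- matrix(rep(rnorm(30), 2), 1, 60,
                      dimnames = list("g1", clinical$patient_id))
  res <- differential_expression_groups(expr_null, clinical)
  expect_false(res$significant)
  expect_gt(res$p, 0.9)
})

test_that("GraphML round-trip preserves nodes, edges and flags", {
  net <- seed_filter(mk_edges(list(c("ERH", "ERH", "KRT17", "KRT17"),
                                   c("CD27", "DAG1", "CD27", "ZNF71"))))
  net <- suppressMessages(annotate_proliferation(net, c("ERH", "KRT17")))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path)
  back <- read_network(path)
  expect_setequal(back$nodes$gene, net$nodes$gene)
  ord <- match(net$nodes$gene, back$nodes$gene)
  expect_identical(back$nodes$is_seed[ord], net$nodes$is_seed)
  expect_identical(back$nodes$is_proliferation[ord], net$nodes$is_proliferation)
  expect_identical(nrow(back$edges), nrow(net$edges))
  # the graph is undirected, so compare unordered endpoint pairs
  expect_setequal(paste(pmin(back$edges$source, back$edges$target),
                        pmax(back$edges$source, back$edges$target),
                        back$edges$rule_type),
                  paste(pmin(net$edges$source, net$edges$target),
                        pmax(net$edges$source, net$edges$target),
                        net$edges$rule_type))

  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(net, sif, format = "sif")
  expect_identical(length(readLines(sif)), nrow(net$edges))

  expect_identical(glance(net)$n_edges, 4L)
  expect_identical(nrow(tidy(net)), 4L)
})
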