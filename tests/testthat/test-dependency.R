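toy_screen <- function(assay = "CRISPR") {
  scores <- rbind(
    ESS1 = c(-0.8, -2.1), ESS2 = c(-0.8, -1.9), ESS3 = c(-0.8, -2.0),
    NE1 = c(0.2, 1.0), NE2 = c(0.2, 1.2), NE3 = c(0.2, 0.8),
    G1 = c(-0.3, 0.5), G2 = c(0.7, -2.0)
  )
  colnames(scores) <- c("L1", "L2")
  dependency_screen(scores, essential = c("ESS1", "ESS2", "ESS3"),
                    nonessential = c("NE1", "NE2", "NE3"), assay = assay)
}

test_that("CRISPR normalization anchors control medians at 0 and -1", {
  norm <- normalize_crispr(toy_screen())
  # L1: med_ne = 0.2, med_e = -0.8 -> raw -0.8 maps to -1, raw 0.2 to 0
  expect_equal(norm$scores["ESS1", "L1"], -1)
  expect_equal(norm$scores["NE1", "L1"], 0)
  for (line in colnames(norm$scores)) {
    expect_equal(median(norm$scores[norm$nonessential, line]), 0,
                 tolerance = 1e-12)
    expect_equal(median(norm$scores[norm$essential, line]), -1,
                 tolerance = 1e-12)
  }
  # an already-normalized screen is unchanged
  twice <- normalize_crispr(norm)
  expect_equal(twice$scores, norm$scores, tolerance = 1e-12)
})

test_that("normalization is affine per line and order-preserving", {
  gen <- gen_dependency_screen(seed = 13, missing_rate = 0.05)
  norm <- normalize_crispr(gen$screen)
  for (line in colnames(norm$scores)) {
    raw <- gen$screen$scores[, line]
    new <- norm$scores[, line]
    ok <- !is.na(raw)
    expect_equal(cor(rank(raw[ok]), rank(new[ok])), 1)
    expect_equal(median(new[norm$nonessential]), 0, tolerance = 1e-9)
    expect_equal(median(new[norm$essential]), -1, tolerance = 1e-9)
  }
})

test_that("RNAi standardization maps the averaged control medians to -1 and 0", {
  gen <- gen_dependency_screen(seed = 19, assay = "RNAi")
  norm <- normalize_rnai(gen$screen)
  expect_equal(median(norm$gene_scores[norm$essential]), -1, tolerance = 1e-12)
  expect_equal(median(norm$gene_scores[norm$nonessential]), 0,
               tolerance = 1e-12)
  # a screen already satisfying the contract passes through unchanged
  twice <- normalize_rnai(norm)
  expect_equal(twice$gene_scores, norm$gene_scores, tolerance = 1e-12)
  expect_equal(twice$scores, norm$scores, tolerance = 1e-12)

  # two-point map example: positive-control average median -2, negative 1
  sc <- rbind(P1 = rep(-2.5, 3), P2 = rep(-2, 3), P3 = rep(-1.5, 3),
              N1 = rep(0.5, 3), N2 = rep(1, 3), N3 = rep(1.5, 3))
  colnames(sc) <- paste0("L", 1:3)
  m <- normalize_rnai(dependency_screen(sc, paste0("P", 1:3), paste0("N", 1:3),
                                        assay = "RNAi"))
  expect_equal(unname(m$gene_scores["P2"]), -1)
  expect_equal(unname(m$gene_scores["N2"]), 0)
})

test_that("degenerate control sets are rejected", {
  sc <- matrix(rnorm(20), 5, 4,
               dimnames = list(paste0("g", 1:5), paste0("L", 1:4)))
  expect_error(dependency_screen(sc, c("g1", "g2"), c("g2", "g3")),
               class = "implinet_degenerate_controls")
  expect_error(dependency_screen(sc, character(), "g1"),
               class = "implinet_degenerate_controls")
  expect_error(dependency_screen(sc, c("g1", "gX"), c("g2", "g3")),
               class = "implinet_missing_gene")
  flat <- matrix(1, 6, 3, dimnames = list(paste0("g", 1:6), paste0("L", 1:3)))
  expect_error(
    normalize_crispr(dependency_screen(flat, paste0("g", 1:3),
                                       paste0("g", 4:6))),
    class = "implinet_degenerate_controls")
})

test_that("significance is strict at -0.5 and missing scores never qualify", {
  sc <- matrix(c(-0.51, -0.5, NA, 0), 4, 1,
               dimnames = list(c("a", "b", "c", "d"), "L1"))
  screen <- dependency_screen(rbind(sc,
                                    E1 = -1, E2 = -1, E3 = -1,
                                    N1 = 0, N2 = 0, N3 = 0),
                              paste0("E", 1:3), paste0("N", 1:3))
  sig <- significant_dependency(screen)
  expect_true(sig["a", 1])
  expect_false(sig["b", 1])   # boundary excluded
  expect_false(sig["c", 1])   # missing
  expect_false(sig["d", 1])
})

test_that("the majority rule is inclusive at 50% of tested lines", {
  crispr_39 <- boundary_screen(78, 39)
  crispr_38 <- boundary_screen(78, 38)
  rnai_40 <- boundary_screen(92, 40, gene = "G")
  expect_true("G" %in% proliferation_genes_majority(crispr = crispr_39))
  expect_false("G" %in% proliferation_genes_majority(crispr = crispr_38,
                                                     rnai = rnai_40))
  # denominator is the per-gene tested count, not the panel size
  sc <- boundary_screen(78, 39)
  sc$scores["G", 40:78] <- NA   # tested in 39 lines, significant in 39
  expect_true("G" %in% proliferation_genes_majority(crispr = sc))
})

test_that("the line-count rule is strict at its bound", {
  expect_true("G" %in% proliferation_genes_count(crispr = boundary_screen(40, 11)))
  expect_false("G" %in% proliferation_genes_count(crispr = boundary_screen(40, 10)))
  expect_identical(proliferation_genes_count(), character())
  # monotone: lowering the bound can only add genes
  scr <- boundary_screen(40, 11)
  expect_true(all(proliferation_genes_count(crispr = scr, min_lines = 10) %in%
                    proliferation_genes_count(crispr = scr, min_lines = 0)))
})

test_that("planted majority-dependent genes are recovered exactly", {
  gen <- gen_dependency_screen(seed = 23, missing_rate = 0.05)
  norm <- normalize_crispr(gen$screen)
  called <- proliferation_genes_majority(crispr = norm)
  expect_setequal(setdiff(called, norm$essential), names(gen$truth$planted))
  called_count <- proliferation_genes_count(crispr = norm, min_lines = 10)
  expect_setequal(setdiff(called_count, norm$essential),
                  names(gen$truth$planted))
})

test_that("DepMap-style gene labels reduce to symbols", {
  expect_identical(parse_depmap_genes(c("A1BG (1)", "NRAS (4893)", "TP53")),
                   c("A1BG", "NRAS", "TP53"))
})
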