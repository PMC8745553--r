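test_that("contingency tables tally paired calls and align by sample id", {
  tab <- build_table(c(1L, 1L, -1L), c(1L, -1L, -1L))
  expect_identical(sum(tab), 3L)
  expect_identical(tab["1", "1"], 1L)
  expect_identical(tab["1", "-1"], 1L)
  expect_identical(tab["-1", "-1"], 1L)

  zeros <- build_table(rep(0L, 25), rep(0L, 25))
  expect_identical(zeros["0", "0"], 25L)
  expect_identical(sum(zeros), 25L)

  a <- setNames(c(1L, 0L, -1L, 1L), paste0("s", 1:4))
  b <- setNames(c(1L, 0L, -1L), paste0("s", c(2, 3, 9)))
  tab2 <- build_table(a, b)
  expect_identical(sum(tab2), 2L)  # s2, s3 only

  expect_error(build_table(c(1L, 0L), c(0L, 1L), min_samples = 20),
               class = "implinet_insufficient_samples")
})

# borderline fixture: N = 20, A margins (down 6, normal 6, up 8),
# B margins (down 6, normal 7, up 7), empty error corner (A=1, B=-1)
borderline_table <- function() {
  matrix(c(4L, 1L, 1L, 2L, 2L, 2L, 0L, 4L, 4L), 3, 3, byrow = TRUE,
         dimnames = list(A = c("-1", "0", "1"), B = c("-1", "0", "1")))
}

test_that("prediction-logic scoring matches its formulas on the borderline table", {
  tab <- borderline_table()
  expect_identical(sum(tab), 20L)
  expect_equal(unname(rowSums(tab)["1"]), 8)
  expect_equal(unname(colSums(tab)["-1"]), 6)

  rule <- score_rule(tab, "UP_IMPLIES_NOTDOWN")
  expect_equal(rule$e_exp, 0.12)
  expect_equal(rule$e_obs, 0)
  expect_equal(rule$precision, 1)
  expect_equal(rule$scope, 0.12)
  expect_equal(rule$z, 0.12 * sqrt(20) / sqrt(0.12 * 0.88))
  expect_true(rule$z > 1.64)
  expect_true(rule$significant)

  # exact conditional null agrees: the z-test rejection is corroborated
  cv <- calls_from_table(tab)
  p_exact <- oracle_perm_p(cv$a, cv$b, "UP_IMPLIES_NOTDOWN")
  expect_lt(p_exact, 0.05)
  p_perm <- permutation_null(cv$a, cv$b, "UP_IMPLIES_NOTDOWN",
                             reps = 1e5, seed = 42)
  expect_lt(abs(p_perm - p_exact), 0.005)
})

test_that("independent (product) tables yield zero precision and no significance", {
  tab <- outer(c(10, 20, 10), c(8, 24, 8)) / 40
  storage.mode(tab) <- "integer"
  dimnames(tab) <- list(A = c("-1", "0", "1"), B = c("-1", "0", "1"))
  for (rt in rule_types()) {
    rule <- score_rule(tab, rt)
    expect_equal(rule$precision, 0)
    expect_false(rule$significant)
  }
  cv <- calls_from_table(tab)
  expect_null(best_rule(cv$a, cv$b))
})

test_that("scoring agrees with an independent cell-level oracle on random tables", {
  withr::local_seed(202)
  for (i in 1:200) {
    tab <- random_table()
    rt <- sample(rule_types(), 1)
    got <- score_rule(tab, rt)
    want <- oracle_score(tab, rt)
    expect_equal(got$e_obs, want$e_obs)
    expect_equal(got$e_exp, want$e_exp)
    expect_equal(got$precision, want$precision)
    expect_equal(got$z, want$z)
  }
})

test_that("a rule equals its contrapositive on the transposed table", {
  withr::local_seed(303)
  swap <- c(UP_IMPLIES_NOTDOWN = "DOWN_IMPLIES_NOTUP",
            UP_IMPLIES_NOTUP = "UP_IMPLIES_NOTUP",
            DOWN_IMPLIES_NOTDOWN = "DOWN_IMPLIES_NOTDOWN",
            DOWN_IMPLIES_NOTUP = "UP_IMPLIES_NOTDOWN")
  for (i in 1:50) {
    tab <- random_table()
    for (rt in rule_types()) {
      fwd <- score_rule(tab, rt)
      rev <- score_rule(t(tab), unname(swap[rt]))
      expect_equal(fwd$e_obs, rev$e_obs)
      expect_equal(fwd$e_exp, rev$e_exp)
      expect_equal(fwd$z, rev$z)
    }
  }
})

test_that("z scales with sqrt(N) at fixed error structure", {
  tab <- borderline_table()
  z1 <- score_rule(tab, "UP_IMPLIES_NOTDOWN")$z
  z4 <- score_rule(tab * 4L, "UP_IMPLIES_NOTDOWN")$z
  expect_equal(z4, 2 * z1)
})

test_that("the permutation null matches the exact hypergeometric null", {
  withr::local_seed(404)
  for (i in 1:5) {
    tab <- random_table(n_min = 30, n_max = 60)
    cv <- calls_from_table(tab)
    rt <- sample(rule_types(), 1)
    p_perm <- permutation_null(cv$a, cv$b, rt, reps = 5000, seed = 1000 + i)
    expect_lt(abs(p_perm - oracle_perm_p(cv$a, cv$b, rt)), 0.025)
  }
})

test_that("permutation p-values behave at the dependence extremes", {
  a <- rep(c(1L, 0L, -1L), each = 20)
  # perfectly positively dependent: the UP/NOTDOWN error corner is empty
  p_dep <- permutation_null(a, a, "UP_IMPLIES_NOTDOWN", reps = 2000, seed = 9)
  expect_lte(p_dep, 1 / 1000)

  # independent pairs: one-sided discrete p-values are stochastically
  # super-uniform, so rejections at 0.05 stay near or below nominal
  withr::local_seed(77)
  ps <- replicate(300, {
    a0 <- sample(c(-1L, 0L, 1L), 100, replace = TRUE, prob = c(.15, .7, .15))
    b0 <- sample(c(-1L, 0L, 1L), 100, replace = TRUE, prob = c(.15, .7, .15))
    permutation_null(a0, b0, "UP_IMPLIES_NOTDOWN", reps = 1000)
  })
  expect_lte(mean(ps < 0.05), 0.08)
  expect_gte(mean(ps), 0.45)
})

test_that("best_rule recovers planted relations and stays quiet on noise", {
  co_pos <- gen_expression_cohort(
    n_samples = 300, n_background = 0,
    planted_edges = planted_pairs(1, "positive", 0.95), seed = 21)
  co_neg <- gen_expression_cohort(
    n_samples = 300, n_background = 0,
    planted_edges = planted_pairs(1, "negative", 0.95), seed = 22)
  n_hat <- average_housekeeping_n(co_pos$expr)

  calls_pos <- discretize_expression(co_pos$expr, n_hat)
  win_pos <- best_rule(calls_pos["P01A", ], calls_pos["P01B", ])
  expect_false(is.null(win_pos))
  expect_identical(rule_relation(win_pos$rule_type), "positive")
  # the winner maximizes precision among the independently scored rules
  tab <- build_table(calls_pos["P01A", ], calls_pos["P01B", ])
  all4 <- vapply(rule_types(), function(rt) oracle_score(tab, rt)$precision,
                 numeric(1))
  expect_equal(win_pos$precision, max(all4[vapply(
    rule_types(), function(rt) oracle_score(tab, rt)$z > 1.64, logical(1))]))

  calls_neg <- discretize_expression(co_neg$expr,
                                     average_housekeeping_n(co_neg$expr))
  win_neg <- best_rule(calls_neg["P01A", ], calls_neg["P01B", ])
  expect_false(is.null(win_neg))
  expect_identical(rule_relation(win_neg$rule_type), "negative")

  withr::local_seed(88)
  none_rate <- mean(replicate(200, {
    a0 <- sample(c(-1L, 0L, 1L), 100, replace = TRUE, prob = c(.15, .7, .15))
    b0 <- sample(c(-1L, 0L, 1L), 100, replace = TRUE, prob = c(.15, .7, .15))
    is.null(best_rule(a0, b0))
  }))
  expect_gte(none_rate, 0.8)
})

test_that("infer_network handles layers, empty input and unknown genes", {
  expect_identical(nrow(infer_network(matrix(0L, 1, 30,
                                             dimnames = list("g", NULL)),
                                      pairs = tibble::tibble(source = character(),
                                                             target = character()))),
                   0L)

  dos <- gen_cnv_with_dosage(n_samples = 250, seed = 31)
  cnv_calls <- categorize_cnv(dos$cnv, 0.5, -0.5)
  ge_calls <- discretize_expression(dos$expr, 1.0)
  rules <- infer_network(cnv_calls, ge_calls,
                         pairs = dos$truth$dosage_pairs[, c("source", "target")],
                         keep = "significant")
  expect_gt(nrow(rules), 0)
  expect_identical(unique(rules$source_layer), "CNV")
  expect_identical(unique(rules$target_layer), "GE")
  expect_true("UP_IMPLIES_NOTDOWN" %in% rules$rule_type)

  expect_error(
    infer_network(ge_calls, pairs = tibble::tibble(source = "NOPE",
                                                   target = "TGT01")),
    class = "implinet_missing_gene")
})

test_that("cross-cohort intersection keeps only same-type replicated rules", {
  r1 <- tibble::tibble(
    source = c("A", "B", "C"), source_layer = "GE",
    target = c("X", "Y", "Z"), target_layer = "GE",
    rule_type = c("UP_IMPLIES_NOTDOWN", "UP_IMPLIES_NOTDOWN", "UP_IMPLIES_NOTUP"),
    relation = rule_relation(rule_type),
    n = 100L, e_obs = 0, e_exp = 0.1, scope = 0.1, precision = 1,
    z = 3, significant = TRUE, cohort = "c1"
  )
  r2 <- r1
  r2$cohort <- "c2"
  r2$rule_type[3] <- "DOWN_IMPLIES_NOTDOWN"   # direction flip for pair C-Z
  r2 <- r2[-2, ]                              # pair B-Y missing in cohort 2
  expect_message(kept <- intersect_cohorts(r1, r2), "dropped")
  expect_identical(kept$source, "A")
  expect_identical(kept$cohorts, "c1;c2")
  expect_identical(kept$n_cohorts, 2L)
})
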