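# Independent oracles and fixture builders used across the suite.

# Exhaustive solver for the threshold-multiplier equation: loop over every
# breakpoint, track the count, apply the stated tie rules step by step.
oracle_threshold_n <- function(values, target_fraction) {
  m <- mean(values)
  s <- sd(values)
  d <- abs(values - m) / s
  k <- round(target_fraction * length(values))
  best_n <- NA_real_
  best_gap <- Inf
  best_count <- Inf
  for (n in sort(unique(c(0, d)))) {
    cnt <- 0
    for (dev in d) {
      if (dev > n) cnt <- cnt + 1
    }
    gap <- abs(cnt - k)
    if (gap < best_gap || (gap == best_gap && cnt < best_count)) {
      best_gap <- gap
      best_count <- cnt
      best_n <- n
    }
  }
  best_n
}

# Direct prediction-logic scoring from raw cells (independent of score_rule).
oracle_score <- function(tab, rule_type) {
  idx <- list(
    UP_IMPLIES_NOTDOWN = c(3, 1), UP_IMPLIES_NOTUP = c(3, 3),
    DOWN_IMPLIES_NOTDOWN = c(1, 1), DOWN_IMPLIES_NOTUP = c(1, 3)
  )[[rule_type]]
  n <- sum(tab)
  e_obs <- tab[idx[1], idx[2]] / n
  e_exp <- sum(tab[idx[1], ]) * sum(tab[, idx[2]]) / n^2
  z <- if (e_exp > 0 && e_exp < 1) {
    (e_exp - e_obs) * sqrt(n) / sqrt(e_exp * (1 - e_exp))
  } else 0
  list(e_obs = e_obs, e_exp = e_exp,
       precision = if (e_exp > 0) 1 - e_obs / e_exp else 0, z = z)
}

# Exact conditional null of the error count given the table marginals.
oracle_perm_p <- function(a, b, rule_type) {
  cell <- list(
    UP_IMPLIES_NOTDOWN = c(1L, -1L), UP_IMPLIES_NOTUP = c(1L, 1L),
    DOWN_IMPLIES_NOTDOWN = c(-1L, -1L), DOWN_IMPLIES_NOTUP = c(-1L, 1L)
  )[[rule_type]]
  n_prem <- sum(a == cell[1])
  n_err <- sum(b == cell[2])
  obs <- sum(a == cell[1] & b == cell[2])
  if (n_prem == 0 || n_err == 0) return(1)
  phyper(obs, n_err, length(b) - n_err, n_prem)
}

# Random 3x3 table (Dirichlet(1) cell probabilities) and its call vectors.
random_table <- function(n_min = 20, n_max = 60) {
  p <- rexp(9)
  p <- p / sum(p)
  n <- sample(n_min:n_max, 1)
  counts <- as.vector(stats::rmultinom(1, n, p))
  matrix(counts, 3, 3, dimnames = list(A = c("-1", "0", "1"),
                                       B = c("-1", "0", "1")))
}

calls_from_table <- function(tab) {
  states <- c(-1L, 0L, 1L)
  a <- integer(0)
  b <- integer(0)
  for (i in 1:3) {
    for (j in 1:3) {
      a <- c(a, rep(states[i], tab[i, j]))
      b <- c(b, rep(states[j], tab[i, j]))
    }
  }
  list(a = a, b = b)
}

# One gene significant in exactly `sig_lines` of `n_lines` tested lines,
# with control genes already on the normalized scale.
boundary_screen <- function(n_lines, sig_lines, gene = "G") {
  scores <- rbind(
    matrix(rep(-1, 3 * n_lines), 3, dimnames = list(paste0("E", 1:3), NULL)),
    matrix(rep(0, 3 * n_lines), 3, dimnames = list(paste0("N", 1:3), NULL)),
    matrix(c(rep(-0.9, sig_lines), rep(0, n_lines - sig_lines)), 1,
           dimnames = list(gene, NULL))
  )
  colnames(scores) <- sprintf("L%03d", seq_len(n_lines))
  dependency_screen(scores, paste0("E", 1:3), paste0("N", 1:3))
}

# Minimal clinical fixture for the radiotherapy DE grouping.
radiotherapy_clinical <- function(times, stage = "III", radiotherapy = TRUE) {
  tibble::tibble(
    patient_id = sprintf("PT%03d", seq_along(times)),
    time = times,
    event = 1L,
    stage = stage,
    radiotherapy = radiotherapy
  )
}
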