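#' Randomly partition a patient table into training and testing sets
#'
#' Disjoint, exhaustive, seeded split: the training set holds
#' `round(fraction * N)` patients and the testing set the remainder (e.g.
#' 923 patients at fraction 0.5 split 462 / 461).
#'
#' @param data Data frame of patients.
#' @param fraction Training fraction, strictly between 0 and 1.
#' @param seed Optional integer seed; the same seed reproduces the split.
#' @return List with tibbles `training` and `testing`.
#' @export
random_partition <- function(data, fraction = 0.5, seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    imp_abort("`fraction` must be strictly between 0 and 1.", "bad_argument")
  }
  data <- as_tibble(data)
  n_total <- nrow(data)
  n_train <- round(fraction * n_total)
  idx <- if (is.null(seed)) {
    sample(n_total, n_train)
  } else {
    withr::with_seed(seed, sample(n_total, n_train))
  }
  list(training = data[sort(idx), ], testing = data[setdiff(seq_len(n_total), idx), ])
}

#' Fit the multivariate proportional-hazards risk model
#'
#' Standard Cox partial-likelihood fit of survival on the signature gene
#' covariates; its coefficient vector defines the per-patient risk score
#' used by [score_and_stratify()].
#'
#' @param data Data frame with survival columns and one numeric column per
#'   covariate.
#' @param covariates Character vector of covariate column names (default the
#'   seven signature genes).
#' @param time,event Names of the survival time (months) and event (0/1)
#'   columns.
#' @return A `risk_model` object wrapping the `survival::coxph` fit;
#'   supports [tidy()] and [glance()].
#' @export
fit_risk_model <- function(data, covariates = signature_genes(),
                           time = "time", event = "event") {
  data <- as_tibble(data)
  stopifnot(all(c(time, event, covariates) %in% names(data)))
  if (sum(data[[event]]) < 10) {
    imp_abort("Need at least 10 events to fit the risk model.", "model_error")
  }
  const <- covariates[vapply(covariates,
                             function(v) sd(data[[v]], na.rm = TRUE) == 0,
                             logical(1))]
  if (length(const) > 0) {
    imp_abort(paste0("Constant covariate(s): ", paste(const, collapse = ", ")),
              "model_error")
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- tryCatch(
    survival::coxph(fml, data = data),
    error = function(e) imp_abort(paste0("Cox fit failed: ", conditionMessage(e)),
                                  "model_error")
  )
  beta <- stats::coef(fit)
  names(beta) <- covariates
  if (any(!is.finite(beta))) {
    imp_abort("Cox fit did not converge to finite coefficients.", "model_error")
  }
  structure(
    list(fit = fit, coefficients = beta, covariates = covariates,
         loglik = fit$loglik[2], time = time, event = event),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> proportional-hazards risk score over",
      length(x$coefficients), "covariates\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) object$coefficients

#' @export
tidy.risk_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = x$covariates,
    estimate = unname(s[, "coef"]),
    std.error = unname(s[, "se(coef)"]),
    statistic = unname(s[, "z"]),
    p.value = unname(s[, "Pr(>|z|)"])
  )
}

#' @export
glance.risk_model <- function(x, ...) {
  tibble(
    n = x$fit$n,
    nevent = x$fit$nevent,
    loglik = x$loglik,
    concordance = unname(x$fit$concordance["concordance"])
  )
}

#' Compute risk scores and stratify patients at a fixed cutoff
#'
#' The risk score is the uncentered linear predictor `sum(beta_g * x_g)` —
#' no baseline term and no mean-centering, so a cutoff fitted on a training
#' set transfers verbatim to a testing set. Patients with a score strictly
#' below the cutoff are `low` risk; scores at or above it are `high`.
#' Patients with missing covariates are excluded (a message reports how
#' many).
#'
#' @param data Patient data frame containing the covariate columns.
#' @param model A `risk_model` or a named numeric coefficient vector.
#' @param cutoff Risk-score cutoff (default -0.74).
#' @return The input tibble (minus excluded patients) with `risk_score` and
#'   `stratum` (`factor` low/high) columns appended.
#' @export
score_and_stratify <- function(data, model, cutoff = -0.74) {
  beta <- if (inherits(model, "risk_model")) model$coefficients else model
  if (is.null(names(beta)) || !is.numeric(beta)) {
    imp_abort("`model` must be a risk_model or a named numeric vector.",
              "bad_argument")
  }
  data <- as_tibble(data)
  missing_cov <- setdiff(names(beta), names(data))
  if (length(missing_cov) > 0) {
    imp_abort(paste0("Covariate column(s) absent: ",
                     paste(missing_cov, collapse = ", ")),
              "missing_gene", genes = missing_cov)
  }
  x <- as.matrix(data[names(beta)])
  complete <- complete.cases(x)
  if (any(!complete)) {
    inform(sprintf("%d patient(s) excluded for missing covariates.",
                   sum(!complete)))
  }
  out <- data[complete, ]
  out$risk_score <- as.numeric(x[complete, , drop = FALSE] %*% beta)
  out$stratum <- factor(ifelse(out$risk_score < cutoff, "low", "high"),
                        levels = c("low", "high"))
  out
}

#' Kaplan-Meier comparison of the two risk strata
#'
#' Two-sided log-rank test between the strata plus the hazard ratio
#' (high vs low) with its 95% confidence interval from a one-covariate Cox
#' fit on the stratum indicator.
#'
#' @param data Stratified patient tibble from [score_and_stratify()].
#' @param time,event,stratum Column names.
#' @return One-row tibble: `p_logrank`, `hr`, `hr_low`, `hr_high`, `n_low`,
#'   `n_high`, `events_low`, `events_high`.
#' @export
km_logrank <- function(data, time = "time", event = "event",
                       stratum = "stratum") {
  data <- as_tibble(data)
  stopifnot(all(c(time, event, stratum) %in% names(data)))
  s <- data[[stratum]]
  if (!is.factor(s)) {
    # keep low as the reference level so the HR reads high-vs-low
    s <- if (setequal(unique(s), c("low", "high"))) {
      factor(s, levels = c("low", "high"))
    } else {
      factor(s)
    }
  }
  if (nlevels(droplevels(s)) != 2) {
    imp_abort("Exactly two non-empty strata are required.", "stratum_error")
  }
  ev_by <- tapply(data[[event]], s, sum)
  if (any(ev_by < 1, na.rm = TRUE)) {
    imp_abort("Each stratum needs at least one event.", "stratum_error")
  }
  surv <- survival::Surv(data[[time]], data[[event]])
  sd_fit <- survival::survdiff(surv ~ s)
  p_logrank <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  cox <- survival::coxph(surv ~ s)
  ci <- summary(cox)$conf.int
  lv <- levels(droplevels(s))
  tibble(
    p_logrank = p_logrank,
    hr = unname(ci[1, "exp(coef)"]),
    hr_low = unname(ci[1, 3]),
    hr_high = unname(ci[1, 4]),
    n_low = sum(s == lv[1]),
    n_high = sum(s == lv[2]),
    events_low = unname(ev_by[lv[1]]),
    events_high = unname(ev_by[lv[2]])
  )
}

#' Kaplan-Meier survival curves by stratum
#'
#' Step-curve data (and an optional display truncation, which never alters
#' any test) for plotting; used by [plot_km()].
#'
#' @inheritParams km_logrank
#' @param max_months Optional display truncation, e.g. 120 for the first
#'   ten years.
#' @return Tibble with `stratum`, `time`, `surv`, `n_risk`.
#' @export
km_curves <- function(data, time = "time", event = "event",
                      stratum = "stratum", max_months = NULL) {
  data <- as_tibble(data)
  s <- factor(data[[stratum]])
  fit <- survival::survfit(
    survival::Surv(data[[time]], data[[event]]) ~ s)
  strata_names <- rep(sub("^s=", "", names(fit$strata)), fit$strata)
  out <- tibble(
    stratum = strata_names,
    time = fit$time,
    surv = fit$surv,
    n_risk = fit$n.risk
  )
  if (!is.null(max_months)) out <- filter(out, .data$time <= max_months)
  out
}

#' @rdname km_curves
#' @export
plot_km <- function(data, time = "time", event = "event",
                    stratum = "stratum", max_months = NULL) {
  curves <- km_curves(data, time, event, stratum, max_months)
  anchors <- curves %>%
    group_by(.data$stratum) %>%
    summarise(time = 0, surv = 1, .groups = "drop")
  ggplot2::ggplot(bind_rows(anchors, curves),
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability",
                  colour = "Risk stratum") +
    ggplot2::theme_minimal()
}
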