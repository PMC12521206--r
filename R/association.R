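#' Residualize a predictor on genetic principal components
#'
#' Ancestry adjustment: replaces a predictor by its ordinary-least-squares
#' residuals from a linear regression on an intercept plus the first
#' `ncol(pcs)` principal components. The output is uncorrelated with every
#' PC (to numerical precision).
#'
#' @param values numeric predictor vector.
#' @param pcs numeric matrix of PCs, rows matching `values`.
#' @return Residual vector, names preserved.
#' @export
residualize_on_pcs <- function(values, pcs) {
  pcs <- as.matrix(pcs)
  stopifnot(length(values) == nrow(pcs))
  x <- cbind(`(Intercept)` = 1, pcs)
  fit <- lm.fit(x, values)
  if (fit$rank < ncol(x)) {
    dropped <- colnames(x)[is.na(fit$coefficients)]
    stop("rank-deficient PC matrix; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  setNames(as.numeric(fit$residuals), names(values))
}

#' Fit the adjusted logistic response model for one predictor
#'
#' Maximum-likelihood logistic regression of responder status on the
#' predictor plus age, sex, BMI and baseline exacerbations. A GRS predictor
#' is standardized to unit SD so the odds ratio is per SD; an allele-dosage
#' predictor is left on its 0/1/2 scale so the odds ratio is per allele
#' dose. Wald 95\% CI and two-sided p-value. Quasi-separation (a
#' standardized coefficient beyond 10 in absolute value, or a CI spanning
#' more than a 1000-fold range) is flagged, not suppressed — plain MLE is
#' reported.
#'
#' @param labels logical or 0/1 responder indicator (zero-baseline subjects
#'   must already be excluded).
#' @param predictor numeric predictor (QC'd score or dosage).
#' @param covariates data.frame with columns `age`, `sex`, `bmi`,
#'   `baseline_exacerbations` aligned with `labels`.
#' @param predictor_type `"grs"` (standardize, OR per SD) or `"dosage"`
#'   (raw, OR per allele).
#' @param score_id,cohort,drug labels carried into the result.
#' @return List of class `association_result`: `score_id`, `cohort`, `drug`,
#'   `odds_ratio`, `ci95` (length 2), `p`, `beta`, `se`, `n_responders`,
#'   `n_nonresponders`, `converged`, `separation_warning`, `reason`.
#' @export
fit_response_model <- function(labels, predictor, covariates,
                               predictor_type = c("grs", "dosage"),
                               score_id = NA_character_,
                               cohort = NA_character_, drug = NA_character_) {
  predictor_type <- match.arg(predictor_type)
  y <- as.integer(labels)
  stopifnot(all(y %in% 0:1))
  req <- c("age", "sex", "bmi", "baseline_exacerbations")
  stopifnot(all(req %in% names(covariates)))
  df <- data.frame(y = y, x = as.numeric(predictor),
                   covariates[req], stringsAsFactors = FALSE)
  cc <- complete.cases(df)
  if (sum(!cc) > 0)
    message(sum(!cc), " subject(s) dropped for missing data")
  df <- df[cc, ]
  base <- list(score_id = score_id, cohort = cohort, drug = drug,
               n_responders = sum(df$y == 1),
               n_nonresponders = sum(df$y == 0))
  fail <- function(reason) structure(c(base, list(
    odds_ratio = NA_real_, ci95 = c(NA_real_, NA_real_), p = NA_real_,
    beta = NA_real_, se = NA_real_, converged = FALSE,
    separation_warning = FALSE, reason = reason)),
    class = "association_result")
  if (base$n_responders < 2 || base$n_nonresponders < 2)
    stop("need at least 2 subjects per outcome class (got ",
         base$n_responders, "/", base$n_nonresponders, ")")
  if (sd(df$x) == 0) return(fail("constant predictor"))
  if (predictor_type == "grs") df$x <- (df$x - mean(df$x)) / sd(df$x)
  fit <- suppressWarnings(
    glm(y ~ x + age + sex + bmi + baseline_exacerbations,
        data = df, family = binomial()))
  beta <- unname(coef(fit)["x"])
  se <- sqrt(diag(vcov(fit)))[["x"]]
  ci <- exp(beta + c(-1, 1) * qnorm(0.975) * se)
  p <- 2 * pnorm(-abs(beta / se))
  # on the standardized scale for GRS; dosage has unit scale anyway
  sep <- abs(beta) > 10 || (ci[2] / ci[1]) > 1e3
  structure(c(base, list(
    odds_ratio = exp(beta), ci95 = ci, p = p, beta = beta, se = se,
    converged = fit$converged, separation_warning = sep, reason = NA_character_)),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s [%s, %s]: OR %.3f (%.3f-%.3f), p = %.3g, n = %d/%d%s\n",
              x$score_id, x$cohort %||% "?", x$drug %||% "?",
              x$odds_ratio, x$ci95[1], x$ci95[2], x$p,
              x$n_responders, x$n_nonresponders,
              if (isTRUE(x$separation_warning)) " [separation]" else ""))
  invisible(x)
}

#' Collect association results into a data.frame
#'
#' @param results list of `association_result` objects.
#' @return data.frame with one row per result.
#' @export
association_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(score_id = r$score_id, cohort = r$cohort, drug = r$drug,
               odds_ratio = r$odds_ratio, ci_low = r$ci95[1],
               ci_high = r$ci95[2], p = r$p,
               n_responders = r$n_responders,
               n_nonresponders = r$n_nonresponders,
               converged = r$converged,
               separation_warning = r$separation_warning,
               stringsAsFactors = FALSE)))
}

#' Screen one cohort's associations at a p-value threshold
#'
#' Strict `p < threshold` filter (the screening rule used to nominate
#' associations for replication); order preserved.
#'
#' @param results data.frame with a `p` column (e.g. [association_table()]).
#' @param p_threshold screening threshold (default 0.20).
#' @return The passing subset.
#' @export
screen_cohort <- function(results, p_threshold = 0.20) {
  results[!is.na(results$p) & results$p < p_threshold, , drop = FALSE]
}

#' Cross-cohort replication verdict
#'
#' Both cohorts must pass the screening threshold (`p < p_threshold`); the
#' association is `replicated_same_direction` when the two odds ratios lie
#' on the same side of 1, `replicated_opposing_direction` when on opposite
#' sides, otherwise `not_replicated`. An odds ratio exactly 1 is treated as
#' directionless (`not_replicated`).
#'
#' @param result_a,result_b `association_result`s (or lists with
#'   `odds_ratio` and `p`) for the same score and drug in the two cohorts.
#' @param p_threshold replication threshold (default 0.20).
#' @return List of class `replication_verdict`: `score_id`, `drug`,
#'   `verdict`.
#' @export
replication_verdict <- function(result_a, result_b, p_threshold = 0.20) {
  pa <- result_a$p; pb <- result_b$p
  da <- result_a$odds_ratio - 1; db <- result_b$odds_ratio - 1
  verdict <- if (is.na(pa) || is.na(pb) || pa >= p_threshold || pb >= p_threshold) {
    "not_replicated"
  } else if (da * db > 0) {
    "replicated_same_direction"
  } else if (da * db < 0) {
    "replicated_opposing_direction"
  } else {
    "not_replicated"  # an OR exactly 1 carries no direction
  }
  structure(list(score_id = result_a$score_id %||% NA_character_,
                 drug = result_a$drug %||% NA_character_, verdict = verdict),
            class = "replication_verdict")
}
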