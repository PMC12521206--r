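#' Sample random score sets from a pool
#'
#' Draws `n_sets` sets of `set_size` score ids, each without replacement
#' within the set and independently across sets, for empirical type-I-error
#' calibration of the association screen (defaults mirror two random
#' samples of 32 scores).
#'
#' @param pool character vector of available score ids (or a list of
#'   [grs_model]s, whose names are used).
#' @param set_size scores per set (default 32).
#' @param n_sets number of sets (default 2).
#' @param seed optional RNG seed for reproducible sampling.
#' @return List of character vectors.
#' @export
sample_random_scores <- function(pool, set_size = 32, n_sets = 2, seed = NULL) {
  if (is.list(pool)) pool <- names(pool)
  if (set_size > length(pool))
    stop("set_size (", set_size, ") exceeds pool size (", length(pool), ")")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_sets), function(s) sample(pool, set_size))
}

#' Empirical type-I error of the screen on null score sets
#'
#' Given association results for scores sampled under the null (no expected
#' association with response), computes the pooled fraction whose p-value
#' falls below the screening threshold — the empirical false-positive rate
#' of the single-cohort screen. Per-set pass counts are retained.
#'
#' @param results data.frame with columns `score_id` and `p` (e.g.
#'   [association_table()]); every sampled score must appear.
#' @param score_sets list of score-id sets from [sample_random_scores()].
#' @param p_threshold screening threshold (default 0.20).
#' @param target_fdr target false-discovery rate to flag against
#'   (default 0.20).
#' @return List of class `null_calibration_report`: `n_sets`, `set_size`,
#'   `p_threshold`, `per_set_pass`, `pooled_rate`, `target_fdr`,
#'   `within_target`.
#' @export
estimate_type1 <- function(results, score_sets, p_threshold = 0.20,
                           target_fdr = 0.20) {
  lookup <- setNames(results$p, results$score_id)
  per_set <- vapply(score_sets, function(ids) {
    if (!all(ids %in% names(lookup)))
      stop("missing association results for score(s): ",
           paste(setdiff(ids, names(lookup)), collapse = ", "))
    sum(lookup[ids] < p_threshold, na.rm = TRUE)
  }, numeric(1))
  set_sizes <- lengths(score_sets)
  pooled <- sum(per_set) / sum(set_sizes)
  structure(list(n_sets = length(score_sets), set_size = set_sizes,
                 p_threshold = p_threshold, per_set_pass = per_set,
                 pooled_rate = pooled, target_fdr = target_fdr,
                 within_target = pooled <= target_fdr),
            class = "null_calibration_report")
}

#' @export
print.null_calibration_report <- function(x, ...) {
  cat(sprintf(
    "null calibration: %d set(s) x %s scores, p<%.2g screen\n  pooled rate %.3f (target FDR <= %.2f: %s)\n",
    x$n_sets, paste(unique(x$set_size), collapse = "/"), x$p_threshold,
    x$pooled_rate, x$target_fdr, if (x$within_target) "within" else "EXCEEDED"))
  invisible(x)
}

#' Null-screen calibration on a synthetic cohort
#'
#' End-to-end empirical type-I-error estimate: simulates a cohort with zero
#' true score effects, runs score QC, phenotypes responders, PC-adjusts and
#' fits the logistic model for every score, then reports the pooled
#' fraction passing the screen. This is the machine that the screening
#' threshold's calibration claims rest on.
#'
#' @param n_subjects,n_scores,n_variants_per_score,n_variants cohort and
#'   score-pool dimensions.
#' @param p_threshold screening threshold (default 0.20).
#' @param seed root seed.
#' @return The `null_calibration_report`, with the per-score association
#'   table attached as attribute `"associations"`.
#' @export
run_null_calibration <- function(n_subjects = 400, n_scores = 500,
                                 n_variants = 800, n_variants_per_score = 20,
                                 p_threshold = 0.20, seed = 1L) {
  cfg <- sim_config(n_samples = n_subjects, n_variants = n_variants,
                    n_scores = n_scores,
                    n_variants_per_score = n_variants_per_score,
                    true_score_effects = 0, low_r2_fraction = 0,
                    decoy_fraction = 0, switch_fraction = 0.05, seed = seed)
  cohort <- simulate_cohort(cfg, "null")
  pcs <- compute_genotype_pcs(cohort$genotypes, 10)
  pheno <- phenotype_cohort(cohort$events, cohort$courses)
  keep <- pheno$label != "excluded_zero_baseline"
  y <- pheno$label[keep] == "responder"
  cov <- cohort$covariates[match(pheno$subject_id[keep],
                                 cohort$covariates$subject_id), ]
  pcs <- pcs[pheno$subject_id[keep], , drop = FALSE]
  results <- lapply(colnames(cohort$score_matrix), function(sid) {
    raw <- cohort$score_matrix[pheno$subject_id[keep], sid]
    z <- rank_inverse_normal(raw)
    adj <- residualize_on_pcs(z, pcs)
    fit_response_model(y, adj, cov, "grs", score_id = sid, cohort = "null")
  })
  tab <- association_table(results)
  sets <- list(tab$score_id)  # pool the full null battery
  rep <- estimate_type1(tab, sets, p_threshold)
  attr(rep, "associations") <- tab
  rep
}
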