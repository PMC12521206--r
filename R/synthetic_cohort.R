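#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic two-cohort generator.
#' Defaults describe a moderate-to-severe asthma cohort starting a biologic:
#' ~2 exacerbations/year at baseline, two latent subpopulations providing
#' ancestry structure for the PCs, and protein-score effects expressed in
#' log-odds of response per SD of the raw score.
#'
#' @param n_samples subjects per cohort.
#' @param n_variants biallelic variants simulated.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param n_scores number of GRS weight models to emit.
#' @param n_variants_per_score variants drawn (without replacement) per score.
#' @param true_score_effects log-odds of response per SD of raw score; a
#'   scalar (recycled), an unnamed vector of length `n_scores`, or a vector
#'   named by score id (unnamed scores get 0).
#' @param covariate_effects named log-odds per unit: `age` (per year, centered
#'   at 55), `sex` (male vs female), `bmi` (per kg/m2, centered at 29),
#'   `baseline_rate` (per baseline exacerbation, centered at the mean).
#' @param baseline_exacerbation_mean Poisson mean of baseline
#'   exacerbations/year (counts are capped at 10).
#' @param response_intercept log-odds of response at covariate centers.
#' @param subpopulation_divergence Balding-Nichols F between the two
#'   subpopulations, in \[0, 0.5\].
#' @param decoy_fraction expected decoy records per true event record, in
#'   \[0, 1\]. Decoys (out-of-range OCS, mistimed OCS, orphan asthma codes,
#'   out-of-window codes) are placed so they can never alter phenotyping.
#' @param n_trimodal_scores how many scores are built with one dominant
#'   weight (trimodal score distribution).
#' @param low_r2_fraction fraction of scores given training R2 below 0.01.
#' @param switch_fraction fraction of subjects switched to another biologic
#'   during follow-up (switch day uniform on 90..330).
#' @param drugs biologic names sampled per subject.
#' @param seed root RNG seed (integer).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_variants = 100,
                       maf_range = c(0.05, 0.5),
                       n_scores = 10, n_variants_per_score = 20,
                       true_score_effects = 0,
                       covariate_effects = c(age = 0.01, sex = -0.2,
                                             bmi = 0.02, baseline_rate = -0.1),
                       baseline_exacerbation_mean = 2,
                       response_intercept = 0,
                       subpopulation_divergence = 0.05,
                       decoy_fraction = 0.2,
                       n_trimodal_scores = 0,
                       low_r2_fraction = 0.2,
                       switch_fraction = 0.1,
                       drugs = c("omalizumab", "mepolizumab", "dupilumab"),
                       seed = 1L) {
  chk_count <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || x < 1 || x != floor(x))
      stop("invalid config: ", field, " must be a positive integer")
  }
  chk_count(n_samples, "n_samples"); chk_count(n_variants, "n_variants")
  chk_count(n_scores, "n_scores")
  chk_count(n_variants_per_score, "n_variants_per_score")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("invalid config: maf_range must lie within (0, 0.5]")
  if (subpopulation_divergence < 0 || subpopulation_divergence > 0.5)
    stop("invalid config: subpopulation_divergence must lie in [0, 0.5]")
  if (decoy_fraction < 0 || decoy_fraction > 1)
    stop("invalid config: decoy_fraction must lie in [0, 1]")
  if (n_variants_per_score > n_variants)
    stop("invalid config: n_variants_per_score exceeds n_variants")
  if (n_trimodal_scores > n_scores)
    stop("invalid config: n_trimodal_scores exceeds n_scores")
  if (baseline_exacerbation_mean <= 0)
    stop("invalid config: baseline_exacerbation_mean must be positive")
  req <- c("age", "sex", "bmi", "baseline_rate")
  if (!all(req %in% names(covariate_effects)))
    stop("invalid config: covariate_effects must name ",
         paste(req, collapse = ", "))
  structure(list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    maf_range = maf_range, n_scores = as.integer(n_scores),
    n_variants_per_score = as.integer(n_variants_per_score),
    true_score_effects = true_score_effects,
    covariate_effects = covariate_effects,
    baseline_exacerbation_mean = baseline_exacerbation_mean,
    response_intercept = response_intercept,
    subpopulation_divergence = subpopulation_divergence,
    decoy_fraction = decoy_fraction,
    n_trimodal_scores = as.integer(n_trimodal_scores),
    low_r2_fraction = low_r2_fraction,
    switch_fraction = switch_fraction, drugs = drugs,
    seed = as.integer(seed)), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate Hardy-Weinberg genotypes with two-subpopulation structure
#'
#' Per variant, an ancestral frequency is drawn uniformly from `maf_range`
#' and the two subpopulations receive Balding-Nichols frequencies
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` (identical frequencies when F = 0).
#' Genotypes are binomial(2) draws within subpopulation, i.e.
#' Hardy-Weinberg within subpopulation.
#'
#' @param config a [sim_config].
#' @param cohort_label prefix for subject ids.
#' @param variants optional variant metadata to reuse (ids, positions,
#'   alleles), so two cohorts share the loci a weight file refers to;
#'   frequencies and genotypes are still drawn fresh per cohort.
#' @return List: `genotypes` (a [grs_genotypes]), `subpop` (integer 1/2 per
#'   subject), `ancestral_maf` (numeric per variant).
#' @export
simulate_genotypes <- function(config, cohort_label = "cohortA",
                               variants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, paste0("genotypes:", cohort_label)))
  n <- config$n_samples
  m <- if (is.null(variants)) config$n_variants else nrow(variants)
  subjects <- sprintf("%s_S%04d", cohort_label, seq_len(n))
  subpop <- rep(1:2, length.out = n)
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  f <- config$subpopulation_divergence
  if (f > 0) {
    p1 <- rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    p2 <- rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    p1 <- pmin(pmax(p1, 1e-3), 1 - 1e-3)
    p2 <- pmin(pmax(p2, 1e-3), 1 - 1e-3)
  } else {
    p1 <- p; p2 <- p
  }
  geno <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    pj <- ifelse(subpop == 1, p1[j], p2[j])
    geno[, j] <- rbinom(n, 2L, pj)
  }
  if (is.null(variants)) {
    ref <- sample(BASES, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
    variants <- data.frame(
      variant_id = sprintf("var%05d", seq_len(m)),
      chrom = as.character(rep_len(1:22, m)),
      pos = 1000L + 100L * seq_len(m),
      ref = unname(ref), alt = unname(alt), stringsAsFactors = FALSE)
  }
  list(genotypes = grs_genotypes(geno, variants, subjects),
       subpop = subpop, ancestral_maf = p)
}

#' Simulate GRS weight models
#'
#' Draws `n_variants_per_score` variants without replacement per score with
#' Gaussian weights. The first `n_trimodal_scores` scores get one dominant
#' weight (1.0) and negligible others (1e-6), producing a trimodal score
#' distribution. A `low_r2_fraction` of scores receives a training R2 below
#' the 0.01 inclusion bound; the rest lie above it. About 20\% of rows list
#' the REF base as the effect allele, exercising allele harmonization.
#'
#' @param config a [sim_config].
#' @param variants the variant metadata of the simulated genotypes.
#' @return Named list of [grs_model] objects (`score_001`, ...).
#' @export
simulate_score_models <- function(config, variants) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_variants_per_score > nrow(variants))
    stop("n_variants_per_score exceeds available variants")
  set.seed(derive_seed(config$seed, "score_models"))
  ids <- sprintf("score_%03d", seq_len(config$n_scores))
  n_low <- round(config$low_r2_fraction * config$n_scores)
  low <- seq_len(config$n_scores) <= config$n_trimodal_scores + n_low &
    seq_len(config$n_scores) > config$n_trimodal_scores
  models <- lapply(seq_len(config$n_scores), function(s) {
    pick <- sort(sample.int(nrow(variants), config$n_variants_per_score))
    v <- variants[pick, ]
    w <- rnorm(nrow(v), 0, 0.15)
    if (s <= config$n_trimodal_scores) {
      w <- rep(1e-6, nrow(v))
      w[sample.int(nrow(v), 1)] <- 1.0
    }
    swap <- runif(nrow(v)) < 0.2
    effect <- ifelse(swap, v$ref, v$alt)
    other <- ifelse(swap, v$alt, v$ref)
    r2 <- if (low[s]) runif(1, 1e-4, 0.009) else runif(1, 0.02, 0.4)
    grs_model(ids[s],
              data.frame(variant_id = v$variant_id, chrom = v$chrom,
                         pos = v$pos, effect_allele = effect,
                         other_allele = other, weight = w,
                         stringsAsFactors = FALSE),
              r2)
  })
  setNames(models, ids)
}

# k event days in [lo, hi], pairwise separated by > min_gap so the
# deduplication rule cannot merge distinct true events.
.place_days <- function(k, lo, hi, min_gap = 15L) {
  if (k == 0) return(integer(0))
  stopifnot((hi - lo + 1) >= (k - 1) * min_gap + 1)
  for (try in 1:50) {
    days <- sort(sample(lo:hi, k))
    if (k == 1 || all(diff(days) >= min_gap)) return(days)
  }
  lo + (seq_len(k) - 1L) * min_gap  # deterministic fallback
}

# a day in [lo, hi] satisfying ok(day); NA when none found after 100 tries
.place_checked <- function(lo, hi, ok) {
  for (try in 1:100) {
    d <- sample(lo:hi, 1)
    if (ok(d)) return(d)
  }
  NA_integer_
}

#' Simulate outcomes, covariates, biologic courses and EHR event streams
#'
#' Baseline exacerbation counts are Poisson; responder status is drawn from
#' a logistic model on the standardized scores and covariates; follow-up
#' counts are drawn consistent with the drawn label under the annualized
#' >=50\%-reduction rule (censoring-aware). Every true exacerbation is
#' rendered either as a direct exacerbation code or as an asthma-related
#' code plus a qualifying OCS course (supply uniform on 3..28, lag uniform
#' on 0..7 days); decoy records that violate the temporal rules are added at
#' `decoy_fraction` and are placed such that they can never change the
#' phenotyped counts.
#'
#' @param config a [sim_config].
#' @param score_matrix numeric matrix, subjects x scores, of raw scores.
#' @param subjects subject ids (rownames of `score_matrix` if missing).
#' @param subpop per-subject subpopulation labels (stored in ground truth).
#' @return List: `covariates`, `courses`, `events` (data.frames) and
#'   `ground_truth` (per-subject true label and windowed counts).
#' @export
simulate_outcomes_and_events <- function(config, score_matrix,
                                         subjects = rownames(score_matrix),
                                         subpop = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "outcomes"))
  n <- length(subjects)
  stopifnot(nrow(score_matrix) == n)

  eff <- config$true_score_effects
  if (is.null(names(eff))) {
    eff <- rep_len(eff, ncol(score_matrix))
    names(eff) <- colnames(score_matrix)
  } else {
    full <- setNames(numeric(ncol(score_matrix)), colnames(score_matrix))
    full[intersect(names(eff), names(full))] <-
      eff[intersect(names(eff), names(full))]
    eff <- full
  }
  z <- scale(score_matrix)
  z[is.nan(z)] <- 0  # constant score columns carry no effect

  age <- pmin(pmax(round(rnorm(n, 55, 12)), 18), 90)
  sex <- rbinom(n, 1, 0.5)
  bmi <- pmin(pmax(round(rnorm(n, 29, 5), 1), 16), 55)
  baseline <- pmin(rpois(n, config$baseline_exacerbation_mean), 10L)

  ce <- config$covariate_effects
  lp <- config$response_intercept + as.numeric(z %*% eff) +
    ce[["age"]] * (age - 55) + ce[["sex"]] * sex +
    ce[["bmi"]] * (bmi - 29) +
    ce[["baseline_rate"]] * (baseline - config$baseline_exacerbation_mean)
  responder <- rbinom(n, 1, plogis(lp)) == 1

  drug <- sample(config$drugs, n, replace = TRUE)
  switched <- runif(n) < config$switch_fraction
  switch_day <- ifelse(switched, sample(90:330, n, replace = TRUE), NA_integer_)
  obs_days <- ifelse(is.na(switch_day), 365L, pmin(365L, switch_day))

  followup <- integer(n)
  for (i in seq_len(n)) {
    b <- baseline[i]; d <- obs_days[i]
    cap <- d %/% 15L
    k <- 0.5 * b * d / 365
    if (b == 0) {
      followup[i] <- 0L  # excluded from response analysis anyway
    } else if (responder[i]) {
      followup[i] <- min(rbinom(1, b, 0.35), floor(k), cap)
    } else {
      followup[i] <- min(max(floor(k) + 1L, rpois(1, max(b, 1))), cap)
    }
  }

  events <- vector("list", n)
  for (i in seq_len(n)) {
    d_end <- as.integer(min(364L, obs_days[i] - 1L))
    base_days <- .place_days(baseline[i], -365L, -1L)
    # keep >14-day gaps across window boundaries too, so deduplication
    # cannot merge a follow-up event into a late-baseline one
    fup_lo <- if (length(base_days)) max(0L, max(base_days) + 15L) else 0L
    fup_days <- .place_days(followup[i], fup_lo, d_end)
    true_days <- c(base_days, fup_days)
    recs <- list()
    asthma_days <- integer(0)   # asthma-related code days (real + decoy)
    valid_ocs <- integer(0)     # days of OCS with in-range supply
    for (d in true_days) {
      if (runif(1) < 0.5) {
        recs[[length(recs) + 1]] <- c(d, 1L, NA_integer_)  # exacerbation_code
      } else {
        ocs_day <- d + sample(0:7, 1)
        recs[[length(recs) + 1]] <- c(d, 2L, NA_integer_)  # asthma_related_code
        recs[[length(recs) + 1]] <- c(ocs_day, 3L, sample(3:28, 1))
        asthma_days <- c(asthma_days, d)
        valid_ocs <- c(valid_ocs, ocs_day)
      }
    }
    n_decoys <- rpois(1, config$decoy_fraction * (length(true_days) + 1))
    lo <- -430L; hi <- d_end
    for (dec in seq_len(n_decoys)) {
      type <- sample(1:4, 1)
      if (type == 1) {           # OCS with out-of-range days' supply
        recs[[length(recs) + 1]] <-
          c(sample(lo:hi, 1), 3L, sample(c(1:2, 29:45), 1))
      } else if (type == 2) {    # in-range OCS, but >7 days from any code
        d <- .place_checked(lo, hi, function(d)
          !any(d - asthma_days >= 0 & d - asthma_days <= 7))
        if (!is.na(d)) {
          recs[[length(recs) + 1]] <- c(d, 3L, sample(3:28, 1))
          valid_ocs <- c(valid_ocs, d)
        }
      } else if (type == 3) {    # asthma code with no qualifying OCS
        d <- .place_checked(lo, hi, function(d)
          !any(valid_ocs - d >= 0 & valid_ocs - d <= 7))
        if (!is.na(d)) {
          recs[[length(recs) + 1]] <- c(d, 2L, NA_integer_)
          asthma_days <- c(asthma_days, d)
        }
      } else {                   # exacerbation code outside both windows,
        # kept >14 days before day -365 so it cannot merge with or displace
        # a baseline event
        recs[[length(recs) + 1]] <- c(sample(-430:-381, 1), 1L, NA_integer_)
      }
    }
    if (length(recs)) {
      m <- do.call(rbind, recs)
      events[[i]] <- data.frame(subject_id = subjects[i], day = m[, 1],
                                kind = EHR_KINDS[m[, 2]],
                                days_supply = m[, 3], stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, events)
  if (is.null(events))
    events <- data.frame(subject_id = character(0), day = integer(0),
                         kind = character(0), days_supply = integer(0))
  rownames(events) <- NULL
  events <- events[order(events$subject_id, events$day, events$kind), ]
  rownames(events) <- NULL

  true_label <- ifelse(baseline == 0, "excluded_zero_baseline",
                       ifelse(responder, "responder", "non_responder"))
  list(
    covariates = data.frame(subject_id = subjects, age = age, sex = sex,
                            bmi = bmi, baseline_exacerbations = baseline,
                            stringsAsFactors = FALSE),
    courses = data.frame(subject_id = subjects, drug = drug, start_day = 0L,
                         switch_day = switch_day, stringsAsFactors = FALSE),
    events = events,
    ground_truth = data.frame(
      subject_id = subjects, true_label = true_label,
      baseline_count = baseline, followup_count = followup,
      followup_days_observed = obs_days,
      subpop = if (is.null(subpop)) NA_integer_ else subpop,
      stringsAsFactors = FALSE))
}

#' Simulate one complete cohort
#'
#' Chains [simulate_genotypes()], [simulate_score_models()] (unless models
#' are supplied, e.g. to share weight files between two cohorts), raw
#' scoring and [simulate_outcomes_and_events()].
#'
#' @param config a [sim_config].
#' @param cohort_label label prefixed to subject ids.
#' @param models optional pre-built list of [grs_model] objects.
#' @param variants optional shared variant metadata (see
#'   [simulate_genotypes()]).
#' @return List of class `sim_cohort`: `label`, `genotypes`, `models`,
#'   `score_matrix`, `covariates`, `courses`, `events`, `ground_truth`,
#'   `subpop`.
#' @export
simulate_cohort <- function(config, cohort_label = "cohortA", models = NULL,
                            variants = NULL) {
  g <- simulate_genotypes(config, cohort_label, variants)
  if (is.null(models))
    models <- simulate_score_models(config, g$genotypes$variants)
  score_matrix <- do.call(cbind, lapply(models, function(m)
    suppressWarnings(compute_scores(g$genotypes, m))$values))
  dimnames(score_matrix) <- list(g$genotypes$subjects, names(models))
  out <- simulate_outcomes_and_events(config, score_matrix,
                                      g$genotypes$subjects, g$subpop)
  structure(c(list(label = cohort_label, genotypes = g$genotypes,
                   models = models, score_matrix = score_matrix,
                   subpop = g$subpop), out),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the cohort in the pipeline's external formats: `genotypes.vcf`,
#' `score_weights.tsv`, `covariates.csv`, `ehr_events.csv`,
#' `biologic_courses.csv`, `ground_truth.csv`.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_score_file(cohort$models, file.path(dir, "score_weights.tsv"))
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  write.csv(cohort$events, file.path(dir, "ehr_events.csv"), row.names = FALSE)
  write.csv(cohort$courses, file.path(dir, "biologic_courses.csv"),
            row.names = FALSE)
  write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
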