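PIPELINE_DEFAULTS <- list(
  out_dir = "grsresp_run",
  seed = 1L,
  cohort_labels = c("cohortA", "cohortB"),
  sim = list(n_samples = 150, n_variants = 80, n_scores = 12,
             n_variants_per_score = 15, n_trimodal_scores = 1,
             low_r2_fraction = 0.2, decoy_fraction = 0.3,
             switch_fraction = 0.1, true_score_effects = 0),
  thresholds = list(r2 = 0.01, p_screen = 0.20, response_reduction = 0.5,
                    ocs_supply = c(3, 28), ocs_lag = 7, dedup_days = 14,
                    hl_bins = 10, confusion_threshold = 0.5),
  null_calibration = list(set_size = 32, n_sets = 2),
  drugs = c("omalizumab", "mepolizumab", "dupilumab"))

.check_range <- function(value, field, lo, hi, open_lo = FALSE) {
  bad <- if (open_lo) value <= lo | value > hi else value < lo | value > hi
  if (any(bad))
    stop("config field '", field, "' out of range ",
         if (open_lo) "(" else "[", lo, ", ", hi, "]: got ",
         paste(value, collapse = ", "))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills defaults for every
#' missing field, and range-checks all thresholds. An empty file yields the
#' full default configuration, whose thresholds are the published rules of
#' the analysis (R2 > 0.01, screen p < 0.20, >=50\% exacerbation reduction,
#' OCS supply 3-28 days within 7 days, 14-day dedup, 10 Hosmer-Lemeshow
#' bins, 0.5 confusion threshold).
#'
#' @param config path to a YAML file, or a list of overrides.
#' @return Validated list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- merge_lists(PIPELINE_DEFAULTS, config)
  th <- cfg$thresholds
  .check_range(th$r2, "thresholds.r2", 0, 1)
  .check_range(th$p_screen, "thresholds.p_screen", 0, 1, open_lo = TRUE)
  .check_range(th$response_reduction, "thresholds.response_reduction", 0, 1,
               open_lo = TRUE)
  if (length(th$ocs_supply) != 2 || th$ocs_supply[1] > th$ocs_supply[2] ||
      th$ocs_supply[1] < 1)
    stop("config field 'thresholds.ocs_supply' must be an ascending pair >= 1")
  .check_range(th$ocs_lag, "thresholds.ocs_lag", 0, 365)
  .check_range(th$dedup_days, "thresholds.dedup_days", 0, 365)
  .check_range(th$hl_bins, "thresholds.hl_bins", 2, 100)
  .check_range(th$confusion_threshold, "thresholds.confusion_threshold", 0, 1)
  if (length(cfg$cohort_labels) != 2)
    stop("config field 'cohort_labels' must name exactly two cohorts")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

# Association battery for one cohort: PC-adjusted logistic fit per QC'd
# score per drug. Scores excluded by QC are not fitted.
.associate_cohort <- function(cohort, qc, pheno, pcs, cfg) {
  keep <- pheno$label != "excluded_zero_baseline"
  results <- list()
  for (drug in cfg$drugs) {
    idx <- keep & pheno$drug == drug
    if (sum(pheno$label[idx] == "responder") < 2 ||
        sum(pheno$label[idx] == "non_responder") < 2) next
    sids <- pheno$subject_id[idx]
    y <- pheno$label[idx] == "responder"
    cov <- cohort$covariates[match(sids, cohort$covariates$subject_id), ]
    pcs_d <- pcs[sids, , drop = FALSE]
    for (q in qc) {
      if (q$disposition == "excluded_nonnormal") next
      type <- if (q$disposition == "converted_to_snp_dosage") "dosage" else "grs"
      vals <- q$values[sids]
      adj <- tryCatch(residualize_on_pcs(vals, pcs_d), error = function(e) NULL)
      if (is.null(adj)) next
      res <- tryCatch(
        fit_response_model(y, adj, cov, type, score_id = q$score_id,
                           cohort = cohort$label, drug = drug),
        error = function(e) NULL)
      if (!is.null(res)) results[[length(results) + 1]] <- res
    }
  }
  results
}

# One cohort through simulate -> write -> read-back -> score/QC -> phenotype.
.run_cohort <- function(cfg, label, models, variants, dir) {
  sim_args <- cfg$sim
  sim_args$seed <- derive_seed(cfg$seed, paste0("sim:", label))
  scfg <- do.call(sim_config, sim_args)
  cohort <- simulate_cohort(scfg, label, models = models, variants = variants)
  write_cohort(cohort, dir)
  # read back through the external formats so the run exercises them
  geno <- read_vcf_genotypes(file.path(dir, "genotypes.vcf"))
  mods <- read_score_file(file.path(dir, "score_weights.tsv"))
  mods <- filter_models_by_r2(mods, cfg$thresholds$r2)
  qc <- suppressWarnings(run_score_qc(mods, geno))
  pheno <- phenotype_cohort(
    cohort$events, cohort$courses,
    dedup_window_days = cfg$thresholds$dedup_days,
    supply_range = cfg$thresholds$ocs_supply,
    max_lag_days = cfg$thresholds$ocs_lag)
  write.csv(pheno, file.path(dir, "responders.csv"), row.names = FALSE)
  pcs <- compute_genotype_pcs(geno, 10)
  list(cohort = cohort, qc = qc, pheno = pheno, pcs = pcs)
}

#' Run the full pipeline on a (simulated) two-cohort study
#'
#' Executes simulate -> score -> QC -> phenotype -> associate -> screen ->
#' replicate -> null-calibrate -> evaluate with one root seed, writing all
#' stage artifacts plus an aggregate `report.json` under `out_dir`.
#' Identical configuration and seed give a byte-identical report.
#'
#' @param config a `pipeline_config`, a YAML path, or a list of overrides
#'   (see [validate_config()]).
#' @return The report list, invisibly; written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_all <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  labs <- cfg$cohort_labels

  a <- .run_cohort(cfg, labs[1], models = NULL, variants = NULL,
                   dir = file.path(cfg$out_dir, labs[1]))
  b <- .run_cohort(cfg, labs[2], models = a$cohort$models,
                   variants = a$cohort$genotypes$variants,
                   dir = file.path(cfg$out_dir, labs[2]))

  res_a <- .associate_cohort(a$cohort, a$qc, a$pheno, a$pcs, cfg)
  res_b <- .associate_cohort(b$cohort, b$qc, b$pheno, b$pcs, cfg)
  tab_a <- association_table(res_a)
  tab_b <- association_table(res_b)
  write.csv(rbind(tab_a, tab_b), file.path(cfg$out_dir, "associations.csv"),
            row.names = FALSE)

  screened_a <- screen_cohort(tab_a, cfg$thresholds$p_screen)
  verdicts <- list()
  for (i in seq_len(nrow(tab_a))) {
    j <- which(tab_b$score_id == tab_a$score_id[i] &
               tab_b$drug == tab_a$drug[i])
    if (!length(j)) next
    v <- replication_verdict(as.list(tab_a[i, ]), as.list(tab_b[j[1], ]),
                             cfg$thresholds$p_screen)
    verdicts[[length(verdicts) + 1]] <-
      data.frame(score_id = tab_a$score_id[i], drug = tab_a$drug[i],
                 verdict = v$verdict, stringsAsFactors = FALSE)
  }
  verdicts <- if (length(verdicts)) do.call(rbind, verdicts)
              else data.frame(score_id = character(0), drug = character(0),
                              verdict = character(0))
  write.csv(verdicts, file.path(cfg$out_dir, "verdicts.csv"),
            row.names = FALSE)

  # empirical type-I proxy on the (null-effect) score battery of cohort A
  nc <- cfg$null_calibration
  # single-drug screen (the drug with the most fitted scores), so the rate
  # is the per-test false-positive rate of one cohort screen
  null_report <- NULL
  if (nrow(tab_a) >= 2) {
    drug0 <- names(sort(table(tab_a$drug), decreasing = TRUE))[1]
    tab_d <- tab_a[tab_a$drug == drug0, , drop = FALSE]
    pool <- unique(tab_d$score_id)
    if (length(pool) >= 2) {
      sets <- sample_random_scores(pool, min(nc$set_size, length(pool)),
                                   nc$n_sets,
                                   seed = derive_seed(cfg$seed, "null_sets"))
      null_report <- estimate_type1(tab_d, sets, cfg$thresholds$p_screen)
      null_report$drug <- drug0
    }
  }

  # evaluate the strongest cohort-A association in both cohorts
  evaluation <- NULL
  if (nrow(screened_a) > 0) {
    top <- screened_a[order(screened_a$p), ][1, ]
    evaluation <- lapply(list(a, b), function(co) {
      q <- co$qc[[top$score_id]]
      if (is.null(q) || q$disposition == "excluded_nonnormal") return(NULL)
      idx <- co$pheno$label != "excluded_zero_baseline" &
        co$pheno$drug == top$drug
      sids <- co$pheno$subject_id[idx]
      y <- as.integer(co$pheno$label[idx] == "responder")
      if (length(unique(y)) < 2 || length(y) < 2 * cfg$thresholds$hl_bins)
        return(NULL)
      cov <- co$cohort$covariates[match(sids, co$cohort$covariates$subject_id), ]
      df <- data.frame(y = y, x = as.numeric(q$values[sids]), cov)
      fit <- suppressWarnings(glm(
        y ~ x + age + sex + bmi + baseline_exacerbations,
        data = df, family = binomial()))
      probs <- predict(fit, type = "response")
      rep <- performance_report(
        y, probs, model_label = paste(co$cohort$label, top$score_id, top$drug),
        n_bins = cfg$thresholds$hl_bins,
        threshold = cfg$thresholds$confusion_threshold)
      calibration_plot(y, probs,
                       file.path(cfg$out_dir,
                                 paste0("calibration_", co$cohort$label, ".png")),
                       n_bins = cfg$thresholds$hl_bins)
      unclass(rep)
    })
    evaluation <- evaluation[!vapply(evaluation, is.null, logical(1))]
  }

  report <- list(
    seed = cfg$seed,
    cohorts = lapply(list(a, b), function(co) list(
      label = co$cohort$label,
      n_subjects = length(co$cohort$genotypes$subjects),
      n_scores_qcd = length(co$qc),
      dispositions = table2list(score_qc_table(co$qc)$disposition),
      responders = table2list(co$pheno$label))),
    n_associations = c(nrow(tab_a), nrow(tab_b)),
    n_screened_cohort_a = nrow(screened_a),
    verdicts = table2list(verdicts$verdict),
    null_calibration = if (is.null(null_report)) NULL else
      unclass(null_report),
    evaluation = evaluation)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(report)
}

table2list <- function(x) as.list(table(x))
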