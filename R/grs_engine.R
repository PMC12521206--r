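#' Construct a GRS model
#'
#' A GRS model is one published score: a table of variant weights plus the
#' training-set R2 annotation used for the inclusion filter.
#'
#' @param score_id score identifier.
#' @param weights data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `weight`.
#' @param r2_train training R2 in \[0,1\].
#' @return An object of class `grs_model`.
#' @export
grs_model <- function(score_id, weights, r2_train) {
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele", "weight")
  missing_cols <- setdiff(req, names(weights))
  if (length(missing_cols))
    stop("weight table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(weights$variant_id))
    stop("duplicate variant within score ", score_id)
  if (any(weights$effect_allele == weights$other_allele))
    stop("effect_allele equals other_allele in score ", score_id)
  if (any(weights$pos < 1)) stop("positions must be 1-based (>= 1)")
  if (!is.numeric(r2_train) || r2_train < 0 || r2_train > 1)
    stop("r2_train must lie in [0,1]")
  structure(list(score_id = score_id,
                 weights = weights[req],
                 r2_train = r2_train),
            class = "grs_model")
}

#' @export
print.grs_model <- function(x, ...) {
  cat(sprintf("grs_model %s: %d variants, r2_train = %.4g\n",
              x$score_id, nrow(x$weights), x$r2_train))
  invisible(x)
}

SCORE_FILE_COLUMNS <- c("score_id", "variant_id", "chrom", "pos",
                        "effect_allele", "other_allele", "weight", "r2_train")

#' Read a GRS weight file
#'
#' Reads a tab-separated weight file (header `score_id variant_id chrom pos
#' effect_allele other_allele weight r2_train`, one row per variant) and
#' groups rows into [grs_model] objects. Malformed rows are rejected with
#' their line numbers.
#'
#' @param path TSV file path.
#' @return Named list of [grs_model] objects, in first-appearance order.
#' @export
read_score_file <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = c(chrom = "character"))
  missing_cols <- setdiff(SCORE_FILE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("score file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  # line numbers: header is line 1
  line <- seq_len(nrow(df)) + 1L
  bad <- df$effect_allele == df$other_allele
  if (any(bad))
    stop("effect_allele equals other_allele at line(s) ",
         paste(line[bad], collapse = ", "), " of ", path)
  bad <- !is.finite(df$weight) | !is.finite(df$pos) | df$pos < 1
  if (any(bad))
    stop("malformed weight/position at line(s) ",
         paste(line[bad], collapse = ", "), " of ", path)
  dup <- duplicated(df[c("score_id", "variant_id")])
  if (any(dup))
    stop("duplicate variant within score at line(s) ",
         paste(line[dup], collapse = ", "), " of ", path)
  ids <- unique(df$score_id)
  models <- lapply(ids, function(id) {
    rows <- df[df$score_id == id, , drop = FALSE]
    r2 <- unique(rows$r2_train)
    if (length(r2) != 1L)
      stop("inconsistent r2_train within score ", id, " in ", path)
    grs_model(id, rows[setdiff(SCORE_FILE_COLUMNS, c("score_id", "r2_train"))], r2)
  })
  setNames(models, ids)
}

#' Write GRS models to a weight file
#'
#' Inverse of [read_score_file()]; the round trip preserves all fields.
#'
#' @param models list of [grs_model] objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_file <- function(models, path) {
  rows <- lapply(models, function(m)
    cbind(score_id = m$score_id, m$weights, r2_train = m$r2_train))
  df <- do.call(rbind, rows)[SCORE_FILE_COLUMNS]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter GRS models on training R2
#'
#' Retains models whose training R2 strictly exceeds the threshold (the
#' inclusion rule is `r2 > threshold`, so a score sitting exactly at the
#' boundary is dropped). Order is preserved.
#'
#' @param models list of [grs_model] objects.
#' @param threshold non-negative R2 threshold (default 0.01).
#' @return The retained sub-list.
#' @export
filter_models_by_r2 <- function(models, threshold = 0.01) {
  stopifnot(threshold >= 0)
  keep <- vapply(models, function(m) m$r2_train > threshold, logical(1))
  models[keep]
}

# Align one weight-file variant against the VCF allele pair.
# Returns the per-subject effect-allele dose, or NULL on allele mismatch.
.aligned_dose <- function(alt_dose, ref, alt, effect, other) {
  if (effect == alt && other == ref) return(alt_dose)
  if (effect == ref && other == alt) return(2 - alt_dose)
  NULL
}

.is_strand_ambiguous <- function(a1, a2) {
  p <- paste0(a1, a2)
  p %in% c("AT", "TA", "CG", "GC")
}

#' Compute per-subject raw scores for one GRS model
#'
#' PLINK-style additive scoring: `score_s = sum_v weight_v * dose_{s,v}`
#' where `dose` counts the effect allele (0/1/2). Variants whose VCF alleles
#' are in the swapped order contribute `2 - alt_dose`; variants whose allele
#' pair matches in neither order are flagged mismatched, skipped, and a
#' warning is issued. Strand-ambiguous (A/T, C/G) variants are scored as
#' matched, with a warning; no frequency-based strand flipping is attempted.
#'
#' @param genotypes a [grs_genotypes] object.
#' @param model a [grs_model].
#' @param missing_policy `"skip"` (default: absent variants contribute
#'   nothing) or `"mean_dose"` (absent variants contribute the weight times
#'   the cohort mean dose of 2 x the effect-allele frequency, taken as the
#'   ALT frequency of the remaining variants is unknown, so the overall mean
#'   dose 1 is used when the variant is entirely absent). Missing variants
#'   are counted either way.
#' @return List of class `score_vector`: `score_id`, `values` (named numeric,
#'   one per subject), `n_variants_used`, `n_variants_missing`,
#'   `mismatched_variants` (character).
#' @export
compute_scores <- function(genotypes, model,
                           missing_policy = c("skip", "mean_dose")) {
  missing_policy <- match.arg(missing_policy)
  w <- model$weights
  n <- length(genotypes$subjects)
  values <- numeric(n)
  idx <- match(w$variant_id, genotypes$variants$variant_id)
  # fall back to chrom:pos lookup for ids absent from the VCF
  nohit <- is.na(idx)
  if (any(nohit)) {
    key_vcf <- paste(genotypes$variants$chrom, genotypes$variants$pos)
    idx[nohit] <- match(paste(w$chrom, w$pos)[nohit], key_vcf)
  }
  used <- 0L
  mismatched <- character(0)
  ambiguous <- character(0)
  for (k in seq_len(nrow(w))) {
    j <- idx[k]
    if (is.na(j)) next
    v <- genotypes$variants[j, ]
    dose <- .aligned_dose(genotypes$geno[, j], v$ref, v$alt,
                          w$effect_allele[k], w$other_allele[k])
    if (is.null(dose)) {
      mismatched <- c(mismatched, w$variant_id[k])
      idx[k] <- NA_integer_
      next
    }
    if (.is_strand_ambiguous(w$effect_allele[k], w$other_allele[k]))
      ambiguous <- c(ambiguous, w$variant_id[k])
    values <- values + w$weight[k] * dose
    used <- used + 1L
  }
  n_missing <- nrow(w) - used
  if (missing_policy == "mean_dose" && n_missing > 0) {
    absent <- is.na(idx)
    values <- values + sum(w$weight[absent]) * 1  # mean dose under MAF 0.5 prior
  }
  if (length(mismatched))
    warning("score ", model$score_id, ": allele mismatch, skipped variant(s) ",
            paste(mismatched, collapse = ", "))
  if (length(ambiguous))
    warning("score ", model$score_id, ": strand-ambiguous variant(s) scored as matched: ",
            paste(ambiguous, collapse = ", "))
  structure(list(score_id = model$score_id,
                 values = setNames(values, genotypes$subjects),
                 n_variants_used = used,
                 n_variants_missing = n_missing,
                 mismatched_variants = mismatched),
            class = "score_vector")
}

#' Rank-based inverse-normal transformation
#'
#' Maps values through `qnorm((rank - offset) / (n - 2*offset + 1))` with the
#' Blom offset 3/8 by default. Ties receive the average rank; ordering among
#' non-tied values is preserved.
#'
#' @param values numeric vector, length >= 2.
#' @param offset rank offset (Blom 3/8 default).
#' @return Transformed numeric vector, names preserved.
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  if (length(values) < 2) stop("rank-INT requires n >= 2")
  if (length(unique(values)) == 1L)
    stop("rank-INT undefined: all values identical")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  out <- qnorm((r - offset) / (n - 2 * offset + 1))
  names(out) <- names(values)
  out
}

#' Normality screen for a transformed score
#'
#' Shapiro-Wilk test on the (rank-normalized) score; the score is retained
#' when `p >= alpha`. Scores whose distribution remains non-normal after the
#' transform (e.g. dosage-dominated ones) are meant to be excluded here.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @param alpha exclusion level (default 0.05).
#' @return List: `statistic`, `p`, `include` (logical).
#' @export
screen_normality <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("normality screen supports 3 <= n <= 5000, got ", n)
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value,
       include = sw$p.value >= alpha)
}

# Mean silhouette width for a 1-d clustering.
.mean_silhouette <- function(values, cl) {
  s <- cluster::silhouette(cl, dist(values))
  mean(s[, "sil_width"])
}

#' Detect a trimodal score distribution
#'
#' A score dominated by one large-weight variant concentrates at three
#' dosage-driven modes. Detection: 3-means on the values, deterministically
#' initialized at the 1/6, 3/6 and 5/6 quantiles; the flag is true when all
#' three clusters hold at least 5\% of the mass and the mean silhouette
#' width is at least 0.6.
#'
#' @param values numeric vector, n >= 30.
#' @return Logical flag.
#' @export
detect_trimodal <- function(values) {
  if (length(values) < 30)
    stop("trimodality detection requires n >= 30, got ", length(values))
  centers <- unname(quantile(values, c(1, 3, 5) / 6, type = 1))
  if (length(unique(centers)) < 3 || length(unique(values)) < 3)
    return(FALSE)
  km <- kmeans(values, centers = matrix(centers, ncol = 1))
  if (any(km$size / length(values) < 0.05)) return(FALSE)
  .mean_silhouette(values, km$cluster) >= 0.6
}

#' Extract the top-effect-SNP allele dosage for a score
#'
#' For trimodal scores the score value is replaced by the 0/1/2 effect-allele
#' dose of the variant with the largest absolute weight (ties broken by the
#' lexicographically smallest variant id). The chosen variant must be present
#' in the genotypes; there is no silent fallback.
#'
#' @param model a [grs_model] (non-empty).
#' @param genotypes a [grs_genotypes] object.
#' @return List: `variant_id`, `dosage` (named integer vector per subject).
#' @export
extract_top_snp_dosage <- function(model, genotypes) {
  w <- model$weights
  if (nrow(w) == 0) stop("empty model ", model$score_id)
  top <- w[abs(w$weight) == max(abs(w$weight)), , drop = FALSE]
  top <- top[order(top$variant_id), , drop = FALSE][1, ]
  j <- match(top$variant_id, genotypes$variants$variant_id)
  if (is.na(j))
    stop("top-effect variant ", top$variant_id, " of score ", model$score_id,
         " absent from genotypes")
  v <- genotypes$variants[j, ]
  dose <- .aligned_dose(genotypes$geno[, j], v$ref, v$alt,
                        top$effect_allele, top$other_allele)
  if (is.null(dose))
    stop("allele mismatch for top-effect variant ", top$variant_id,
         " of score ", model$score_id)
  list(variant_id = top$variant_id,
       dosage = setNames(as.integer(dose), genotypes$subjects))
}

#' Score-QC cascade
#'
#' Applies, per score: raw scoring, trimodality detection (trimodal scores
#' are converted to the top-effect-SNP allele dosage), rank-based
#' inverse-normal transformation, and Shapiro-Wilk normality screening
#' (scores that remain non-normal are excluded). The cascade is
#' deterministic and per-score independent.
#'
#' @param models list of [grs_model] objects (already R2-filtered).
#' @param genotypes a [grs_genotypes] object.
#' @param alpha normality-screen exclusion level (default 0.05).
#' @param missing_policy passed to [compute_scores()].
#' @return Named list of `score_qc_result` lists with fields `score_id`,
#'   `disposition` (`included_as_grs`, `excluded_nonnormal`,
#'   `converted_to_snp_dosage`), `values` (transformed score or dosage),
#'   `normality_statistic`, `normality_p`, `trimodal`, `top_variant_id`.
#' @export
run_score_qc <- function(models, genotypes, alpha = 0.05,
                         missing_policy = "skip") {
  out <- lapply(models, function(m) {
    sv <- compute_scores(genotypes, m, missing_policy)
    tri <- detect_trimodal(sv$values)
    if (tri) {
      top <- extract_top_snp_dosage(m, genotypes)
      return(list(score_id = m$score_id,
                  disposition = "converted_to_snp_dosage",
                  values = top$dosage,
                  normality_statistic = NA_real_, normality_p = NA_real_,
                  trimodal = TRUE, top_variant_id = top$variant_id))
    }
    z <- rank_inverse_normal(sv$values)
    nrm <- screen_normality(z, alpha)
    list(score_id = m$score_id,
         disposition = if (nrm$include) "included_as_grs" else "excluded_nonnormal",
         values = z,
         normality_statistic = nrm$statistic, normality_p = nrm$p,
         trimodal = FALSE, top_variant_id = NA_character_)
  })
  setNames(out, vapply(models, function(m) m$score_id, character(1)))
}

#' Tabulate score-QC dispositions
#'
#' @param qc output of [run_score_qc()].
#' @return data.frame with one row per score.
#' @export
score_qc_table <- function(qc) {
  do.call(rbind, lapply(qc, function(q)
    data.frame(score_id = q$score_id, disposition = q$disposition,
               normality_statistic = q$normality_statistic,
               normality_p = q$normality_p, trimodal = q$trimodal,
               top_variant_id = q$top_variant_id,
               stringsAsFactors = FALSE)))
}
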