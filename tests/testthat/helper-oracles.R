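# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain double loops and textbook formulas.

# Brute-force additive score: explicit subject x variant double loop with
# hand-aligned alleles.
oracle_score <- function(genotypes, model) {
  n <- length(genotypes$subjects)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_len(nrow(model$weights))) {
      w <- model$weights[k, ]
      j <- which(genotypes$variants$variant_id == w$variant_id)
      if (!length(j)) next
      v <- genotypes$variants[j, ]
      ac <- genotypes$geno[i, j]
      if (w$effect_allele == v$alt && w$other_allele == v$ref) {
        s <- s + w$weight * ac
      } else if (w$effect_allele == v$ref && w$other_allele == v$alt) {
        s <- s + w$weight * (2 - ac)
      } # neither orientation: skipped, as a mismatch should be
    }
    out[i] <- s
  }
  out
}

# Newton-Raphson logistic MLE with explicit solve(); returns coefficients.
oracle_logistic <- function(X, y, tol = 1e-12, max_iter = 50) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Exhaustive pairwise concordance (Mann-Whitney) AUC with half credit for
# ties.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Small genotype fixture built directly, not via the simulator.
make_genotypes <- function(geno, ref = NULL, alt = NULL) {
  m <- ncol(geno)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  grs_genotypes(
    geno,
    data.frame(variant_id = sprintf("v%02d", seq_len(m)),
               chrom = "1", pos = 100L * seq_len(m),
               ref = ref, alt = alt, stringsAsFactors = FALSE),
    sprintf("S%03d", seq_len(nrow(geno))))
}

make_model <- function(variant_ids, weights, effect, other, pos = NULL,
                       score_id = "s1", r2 = 0.5) {
  grs_model(score_id,
            data.frame(variant_id = variant_ids, chrom = "1",
                       pos = pos %||% (100L * seq_along(variant_ids)),
                       effect_allele = effect, other_allele = other,
                       weight = weights, stringsAsFactors = FALSE),
            r2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
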