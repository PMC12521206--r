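test_that("score files round-trip through write and read", {
  m1 <- make_model(c("v01", "v02", "v03"), c(0.2, -0.4, 0.1),
                   effect = c("G", "G", "G"), other = c("A", "A", "A"),
                   score_id = "sA", r2 = 0.12)
  m2 <- make_model("v04", 1.5, "C", "T", pos = 999L, score_id = "sB",
                   r2 = 0.005)
  f <- tempfile(fileext = ".tsv")
  write_score_file(list(m1, m2), f)
  back <- read_score_file(f)
  expect_named(back, c("sA", "sB"))
  expect_equal(back$sA$weights, m1$weights)
  expect_equal(back$sB$r2_train, 0.005)
  expect_equal(nrow(back$sA$weights), 3)
})

test_that("malformed score files are rejected with line numbers", {
  header <- paste(c("score_id", "variant_id", "chrom", "pos", "effect_allele",
                    "other_allele", "weight", "r2_train"), collapse = "\t")
  f <- tempfile()
  writeLines(c(header,
               "s1\tv1\t1\t100\tA\tG\t0.5\t0.1",
               "s1\tv2\t1\t200\tC\tC\t0.2\t0.1"), f)
  expect_error(read_score_file(f), "line\\(s\\) 3")
  writeLines(c(header,
               "s1\tv1\t1\t100\tA\tG\t0.5\t0.1",
               "s1\tv1\t1\t100\tA\tG\t0.5\t0.1"), f)
  expect_error(read_score_file(f), "duplicate variant")
  writeLines(sub("\tr2_train", "", c(header, "s1\tv1\t1\t100\tA\tG\t0.5")), f)
  expect_error(read_score_file(f), "r2_train")
})

test_that("the R2 inclusion filter is strictly greater-than", {
  mods <- list(
    a = make_model("v01", 1, "G", "A", score_id = "a", r2 = 0.005),
    b = make_model("v01", 1, "G", "A", score_id = "b", r2 = 0.01),
    c = make_model("v01", 1, "G", "A", score_id = "c", r2 = 0.02))
  kept <- filter_models_by_r2(mods, 0.01)
  expect_named(kept, "c")
  expect_named(filter_models_by_r2(mods, 0), c("a", "b", "c"))
  expect_length(filter_models_by_r2(list(), 0.01), 0)
})

test_that("scoring handles identity, zero weights and missing variants", {
  g <- make_genotypes(matrix(c(0, 1, 2), ncol = 1))
  m <- make_model("v01", 1.0, "G", "A")
  expect_equal(unname(compute_scores(g, m)$values), c(0, 1, 2))
  m0 <- make_model("v01", 0, "G", "A")
  expect_equal(unname(compute_scores(g, m0)$values), c(0, 0, 0))
  # missing variant counted; skip policy scores over observed variants
  m2 <- make_model(c("v01", "zz9"), c(1, 5), c("G", "G"), c("A", "A"),
                   pos = c(100L, 9999L))
  sv <- compute_scores(g, m2)
  expect_equal(sv$n_variants_used, 1L)
  expect_equal(sv$n_variants_missing, 1L)
  expect_equal(unname(sv$values), c(0, 1, 2))
})

test_that("swapped-allele variants are harmonized; mismatches are skipped", {
  g <- make_genotypes(rbind(c(0, 2, 1), c(1, 0, 2)),
                      ref = c("A", "C", "T"), alt = c("G", "T", "A"))
  # v02 weight refers to the REF allele (C): dose must be 2 - alt_count
  m <- make_model(c("v01", "v02"), c(1, 10), effect = c("G", "C"),
                  other = c("A", "T"))
  expect_equal(unname(compute_scores(g, m)$values), c(0 + 0, 1 + 20))
  # alleles matching in neither orientation: flagged and skipped
  mbad <- make_model(c("v01", "v03"), c(1, 100), effect = c("G", "C"),
                     other = c("A", "G"))
  expect_warning(sv <- compute_scores(g, mbad), "mismatch")
  expect_equal(sv$mismatched_variants, "v03")
  expect_equal(unname(sv$values), c(0, 1))
})

test_that("scoring equals the brute-force allele-aligned oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(3:8, 1); m <- sample(2:6, 1)
    ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    g <- make_genotypes(matrix(sample(0:2, n * m, TRUE), n, m), ref, alt)
    swap <- runif(m) < 0.4
    mod <- make_model(sprintf("v%02d", 1:m), rnorm(m),
                      effect = ifelse(swap, ref, alt),
                      other = ifelse(swap, alt, ref))
    sv <- suppressWarnings(compute_scores(g, mod))
    expect_equal(unname(sv$values), oracle_score(g, mod), tolerance = 1e-12)
  }
})

test_that("scoring is linear in the weights and allele-swap invariant", {
  set.seed(7)
  g <- make_genotypes(matrix(sample(0:2, 60, TRUE), 10, 6))
  mod <- make_model(sprintf("v%02d", 1:6), rnorm(6),
                    effect = rep("G", 6), other = rep("A", 6))
  s1 <- compute_scores(g, mod)$values
  mod3 <- mod; mod3$weights$weight <- 3 * mod$weights$weight
  expect_equal(compute_scores(g, mod3)$values, 3 * s1, tolerance = 1e-14)
  # recode variant 1 in the VCF (swap REF/ALT, flip doses): scores unchanged
  g2 <- g
  g2$variants$ref[1] <- "G"; g2$variants$alt[1] <- "A"
  g2$geno[, 1] <- 2 - g2$geno[, 1]
  expect_equal(compute_scores(g2, mod)$values, s1, tolerance = 1e-14)
})

test_that("rank-INT matches the Blom closed form and its symmetries", {
  x <- c(3.2, -1, 10, 0.5, 7)
  z <- rank_inverse_normal(x)
  r <- c(3, 1, 5, 2, 4)  # hand-assigned ranks
  expect_equal(unname(z), qnorm((r - 0.375) / 5.25), tolerance = 1e-12)
  expect_equal(rank_inverse_normal(-x), -z, tolerance = 1e-12)
  expect_identical(order(unname(z)), order(x))
  # invariance to strictly monotone pre-transformation
  expect_equal(rank_inverse_normal(exp(x)), z, tolerance = 1e-12)
  set.seed(11)
  y <- rnorm(101)
  expect_lt(abs(mean(rank_inverse_normal(y))), 1e-6)
  expect_error(rank_inverse_normal(rep(1, 5)), "identical")
  expect_error(rank_inverse_normal(3), "n >= 2")
})

test_that("normality screen keeps rank-INT output and rejects dosage data", {
  set.seed(21)
  z <- rank_inverse_normal(rnorm(500))
  res <- screen_normality(z)
  expect_true(res$include)
  dosage <- sample(c(0, 1, 2), 500, TRUE, prob = c(0.25, 0.5, 0.25))
  # ties survive rank-INT, leaving a three-mass distribution
  res2 <- screen_normality(rank_inverse_normal(dosage))
  expect_false(res2$include)
  expect_error(screen_normality(c(1, 2)), "3 <= n")
})

test_that("trimodality detector fires on three-point masses only", {
  set.seed(31)
  tri <- sample(c(0, 0.5, 1), 400, TRUE, prob = c(0.25, 0.5, 0.25))
  expect_true(detect_trimodal(tri))
  expect_false(detect_trimodal(rnorm(500)))
  expect_error(detect_trimodal(rnorm(10)), "n >= 30")
})

test_that("top-effect SNP selection uses |weight| with lexicographic ties", {
  g <- make_genotypes(matrix(sample(0:2, 15, TRUE), 5, 3))
  m <- make_model(c("v01", "v02", "v03"), c(0.1, -0.5, 0.3),
                  effect = rep("G", 3), other = rep("A", 3))
  top <- extract_top_snp_dosage(m, g)
  expect_equal(top$variant_id, "v02")
  expect_equal(unname(top$dosage), unname(g$geno[, 2]))
  m1 <- make_model("v03", 0.2, "G", "A")
  expect_equal(extract_top_snp_dosage(m1, g)$variant_id, "v03")
  mt <- make_model(c("v03", "v01"), c(0.5, -0.5), rep("G", 2), rep("A", 2))
  expect_equal(extract_top_snp_dosage(mt, g)$variant_id, "v01")
  mabs <- make_model("zz1", 1, "G", "A", pos = 12345L)
  expect_error(extract_top_snp_dosage(mabs, g), "absent")
})

test_that("the QC cascade matches a step-by-step application of its parts", {
  cfg <- sim_config(n_samples = 250, n_variants = 60, n_scores = 8,
                    n_variants_per_score = 12, n_trimodal_scores = 2,
                    low_r2_fraction = 0, seed = 13)
  g <- simulate_genotypes(cfg, "A")$genotypes
  mods <- simulate_score_models(cfg, g$variants)
  qc <- suppressWarnings(run_score_qc(mods, g))
  for (id in names(mods)) {
    sv <- suppressWarnings(compute_scores(g, mods[[id]]))
    if (detect_trimodal(sv$values)) {
      expect_identical(qc[[id]]$disposition, "converted_to_snp_dosage")
      expect_identical(qc[[id]]$top_variant_id,
                       extract_top_snp_dosage(mods[[id]], g)$variant_id)
    } else {
      z <- rank_inverse_normal(sv$values)
      expected <- if (screen_normality(z)$include) "included_as_grs"
                  else "excluded_nonnormal"
      expect_identical(qc[[id]]$disposition, expected)
      expect_equal(qc[[id]]$values, z)
    }
  }
  # order independence across scores
  qc_rev <- suppressWarnings(run_score_qc(rev(mods), g))
  expect_identical(score_qc_table(qc)[names(mods), "disposition"],
                   score_qc_table(qc_rev)[names(mods), "disposition"])
})

test_that("VCF writing and reading preserve genotypes and metadata", {
  cfg <- sim_config(n_samples = 30, n_variants = 25, seed = 17)
  g <- simulate_genotypes(cfg, "A")$genotypes
  f <- tempfile(fileext = ".vcf")
  write_vcf(g, f)
  back <- read_vcf_genotypes(f)
  expect_equal(unname(back$geno), unname(g$geno))
  expect_equal(back$variants$variant_id, g$variants$variant_id)
  expect_equal(back$variants$ref, g$variants$ref)
  expect_equal(back$subjects, g$subjects)
})
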