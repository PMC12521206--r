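---
title: "Protein-predicting genetic risk scores and biologic response: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-predicting genetic risk scores and biologic response: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsresp)
```

## The problem

Biologic therapies for moderate-to-severe asthma (omalizumab, mepolizumab,
dupilumab) help some patients dramatically and others not at all, and there
is no accepted pre-treatment marker of who will respond. One candidate class
of markers is genetically predicted protein levels: published machine-learning
scores (weighted sums of allele dosages) trained to predict plasma protein
concentrations. Because the genotype precedes disease and treatment, an
association between such a genetic risk score (GRS) and treatment response is
less exposed to reverse causation than a measured protein level would be.

`grsresp` implements the full analysis as a reusable, tested pipeline:

1. **Scoring** — per-subject GRS from VCF genotypes and OmicsPred-style
   weight files, with allele harmonization.
2. **Score QC** — training-R² inclusion filter, rank-based inverse-normal
   transformation, normality screening, trimodality detection with fallback
   to the top-effect SNP's allele dosage.
3. **EHR phenotyping** — rule-based exacerbation detection around biologic
   initiation, with censoring at a switch to another biologic, and responder
   classification.
4. **Association** — ancestry adjustment by principal-component
   residualization and covariate-adjusted logistic regression.
5. **Replication** — two-cohort screening at p < 0.20 with direction-aware
   verdicts.
6. **Null calibration** — empirical type-I error of the screen on random
   score sets with no expected association.
7. **Performance** — AUROC with DeLong intervals and paired comparison,
   Hosmer–Lemeshow calibration, confusion metrics.

Because the real cohorts behind this design are access-controlled biobanks,
the package ships a synthetic two-cohort generator with known ground truth;
every stage is exercised end to end on simulated data.

## The models

### Scoring and score QC

For subject $s$ and score $g$ with variant weights $w_v$,

$$\mathrm{GRS}_{s,g} = \sum_{v} w_v \, d_{s,v},$$

where $d_{s,v} \in \{0,1,2\}$ counts the *effect* allele. When the VCF lists
the allele pair in the opposite orientation, $d = 2 - (\text{ALT count})$;
when neither orientation matches, the variant is flagged and skipped with a
warning. Strand-ambiguous (A/T, C/G) variants are scored as matched with a
logged warning — the synthetic data are strand-consistent, and
frequency-based strand flipping for real data is out of scope. Variants
absent from the genotypes are skipped by default (`missing_policy = "skip"`,
scoring over observed variants); a `mean_dose` policy is available that adds
the weight times an expected dose of 1 for fully absent variants (the
allele-frequency-agnostic expectation), since no cohort frequency exists for
a variant that was never observed.

Only scores whose training R² strictly exceeds 0.01 enter the analysis; the
strict inequality mirrors the published inclusion rule, so a score at
exactly 0.01 is dropped.

Scores are then rank-normalized with the Blom offset,

$$z_i = \Phi^{-1}\!\left(\frac{r_i - 3/8}{n + 1/4}\right),$$

ties receiving the average rank. A score that *remains* non-normal after
the transform — which happens exactly when heavy ties survive ranking, as
with dosage-dominated scores — is excluded by a Shapiro–Wilk screen at
$\alpha = 0.05$ (the test is applied after the transform; applying it
before would exclude nearly everything, defeating the transform's purpose).
A score whose distribution is *trimodal* — dominated by a single
large-weight variant, concentrating at the three dosage-driven modes — is
instead replaced by the 0/1/2 allele dosage of its largest-|weight| variant
(ties broken by the lexicographically smallest variant id, so the choice is
deterministic).

Trimodality itself needs an operational detector, since "trimodal" is a
visual judgement in practice. We use 3-means on the score values,
deterministically initialized at the 1/6, 3/6 and 5/6 quantiles, and flag
the score when every cluster holds ≥ 5 % of the mass and the mean
silhouette width is ≥ 0.6. On simulated data this cleanly separates
constructed one-dominant-variant scores (silhouette ≈ 1) from genuinely
polygenic ones (silhouette ≈ 0.5 for a Gaussian), and the 5 % mass floor
keeps a rare homozygote class from vetoing the flag.

### Phenotyping rules

An exacerbation is either (a) a visit coded directly as an asthma
exacerbation, or (b) an asthma-related code (wheezing, dyspnea, …) backed
by an oral corticosteroid course of 3–28 days' supply dispensed within 7
days of the event. Both bounds of both intervals are inclusive and the
prescription must fall on or after the event day — the published rule gives
the numbers but not the boundary conventions, so the package fixes them and
tests them explicitly. Candidate events closer than 14 days to an accepted
event are merged, since one clinical exacerbation typically generates
several proximate records; the window is a parameter (`dedup_window_days`).

Day 0 is biologic initiation. Baseline counts events in days −365..−1;
follow-up counts days 0..364, truncated the day before a switch to another
biologic. The responder definition is a ≥ 50 % drop in the *annualized*
rate: with `followup_days_observed` $D$ (= 365 or the switch day),

$$\text{responder} \iff \frac{365 \cdot \text{followup count}}{D}
  \le 0.5 \times \text{baseline count}.$$

Annualizing by observed person-days is this package's choice for handling
censored follow-up (the source design states censoring but not the
arithmetic); subjects with zero baseline exacerbations are excluded because
a percentage reduction is undefined for them.

### Association, screening, replication

Each QC'd predictor is first residualized on the first 10 genotype-derived
principal components (ordinary least squares with intercept), removing
ancestry confounding; the QC pipeline order is rank-INT → PC
residualization → per-SD standardization inside the model. The response
model is maximum-likelihood logistic regression,

$$\mathrm{logit}\, P(\text{responder}) = \beta_0 + \beta_1 x +
  \beta_2\,\text{age} + \beta_3\,\text{sex} + \beta_4\,\text{BMI} +
  \beta_5\,\text{baseline exacerbations},$$

with $x$ standardized to unit SD for a GRS (OR per SD) and raw 0/1/2 for a
dosage predictor (OR per allele). Wald 95 % CIs and two-sided p-values are
reported — the convention behind printed OR (CI) triples. Small per-drug
strata make quasi-separation a real possibility; the package reports plain
MLE and sets a `separation_warning` when a standardized coefficient exceeds
10 in absolute value or the CI spans a 1000-fold range, matching how such
results appear in practice (enormous CIs, not suppressed rows).

Screening is strict ($p < 0.20$) within a cohort; a score–drug pair
*replicates* when both cohorts pass the screen, with the verdict split by
whether the two odds ratios lie on the same side of 1. An OR exactly 1 is
directionless and yields `not_replicated`.

### Null calibration

The p < 0.20 screen is deliberately liberal, so its empirical false-positive
rate matters. `run_null_calibration()` simulates a cohort whose scores have
*zero* true effect on response, runs the complete scoring → QC →
phenotyping → adjustment → fit path per score, and reports the pooled
fraction passing the screen; `sample_random_scores()` supports the
two-random-sets-of-32 design on any score pool. The pooled (not
per-set-averaged) rate is reported, with per-set counts retained.

### Performance evaluation

AUROC uses the Mann–Whitney identity with half-credit ties; variance, CI
and the paired two-model comparison use DeLong's structural-components
method (via \pkg{pROC}, with the ROC direction fixed so an AUC below 0.5 is
reported as such, not silently flipped). The test suite checks the AUC
against an exhaustive pairwise-concordance oracle on every instance up to
n = 50. One caution surfaced by the suite: comparing *nested fitted* models
whose extra predictor is pure noise is a degenerate case for the DeLong
test (the AUC difference collapses toward zero faster than its variance
estimate), so rejections are far *below* nominal there; the nominal-level
property is tested where the test is valid, on paired but independent null
predictors.

Hosmer–Lemeshow bins subjects by deciles of predicted probability (ties
kept in one bin; bins with zero expected events or non-events merged with a
neighbor), computes $\sum (O-E)^2/E$ over events and non-events, and refers
it to $\chi^2$ with (bins − 2) degrees of freedom — the reference
distribution for probabilities fitted in-sample. Confusion metrics use a
0.5 threshold on the fitted probability by default; the AUROC and
calibration are apparent (in-sample), and are labelled as such.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions every calibration claim in this package refers to.

* **Genotypes.** Hardy–Weinberg within each of two subpopulations, with
  Balding–Nichols frequency divergence (F = 0.05 by default) between them.
  Two discrete subpopulations — rather than continuous admixture — are the
  simplest structure that makes PC residualization consequential; the PCs
  are always computed from the genotypes by the pipeline, never read from
  the simulation truth.
* **Scores.** Gaussian weights over variants drawn without replacement;
  configurable counts of trimodal (one dominant weight) and
  below-R²-threshold scores; ~20 % of weight rows list the REF base as the
  effect allele so harmonization is always exercised.
* **Outcomes.** Baseline exacerbations ~ Poisson(2/year, capped at 10);
  responder status from a logistic model with configurable per-SD score
  effects and covariate effects (defaults: age +0.01/yr, male −0.2,
  BMI +0.02/unit, baseline rate −0.1/event — modest, clinically plausible
  magnitudes); ~10 % of subjects switch biologic at a uniform day in
  90..330. Follow-up counts are drawn and then clamped into the
  label-consistent range implied by the annualized ≥ 50 % rule (a plain
  binomial thinning does not by itself guarantee consistency), so ground
  truth labels and the phenotyper's output agree by construction.
* **Events.** Each true exacerbation is rendered either as a direct
  exacerbation code or as an asthma-related code plus a qualifying OCS
  (supply uniform on 3..28, lag uniform on 0..7). Event days keep > 14-day
  gaps within *and across* window boundaries so deduplication cannot merge
  distinct true events. Decoys — OCS with out-of-range supply, correctly
  dosed OCS more than 7 days from any code, asthma codes with no qualifying
  OCS, codes before day −380 — are placed with two-sided checks so they can
  never create or absorb a candidate event. This is what makes the
  round-trip property exact: phenotyped counts equal ground truth for 100 %
  of subjects at any decoy fraction.

What the generator does **not** emulate: linkage disequilibrium, imputation
dosages, real ICD/RxNorm vocabularies, medication adherence, multi-switch
treatment histories, or continuous admixture. Passing tests therefore
demonstrate the pipeline's internal correctness and statistical calibration
under clean assumptions — not robustness to real-world coding noise.

## Numerical and scale choices

* The null-calibration study uses 500 null scores × 400 subjects × 10
  seeds — large enough that the Monte-Carlo standard error of the pooled
  pass rate is ≈ 0.006, small enough to run in well under a minute.
* Parameter-recovery checks use 200 simulations at n = 500 (true OR 1.7 per
  SD), and Wald CI coverage is verified at 93–97 % over 200 simulations at
  n = 500 (true OR 1.5).
* The end-to-end demo pipeline runs two cohorts of 150 subjects, 80
  variants and 12 scores; it is byte-identical across runs at a fixed seed
  because every stage derives its RNG stream from the root seed and a stage
  label.
* All event dates are integer days relative to biologic start; no calendar
  arithmetic anywhere.

## Worked example

```{r example, eval = FALSE}
library(grsresp)

cfg <- sim_config(n_samples = 300, n_scores = 10, n_variants = 100,
                  n_variants_per_score = 20, n_trimodal_scores = 1,
                  true_score_effects = c(score_005 = 0.5), seed = 7)
cohort <- simulate_cohort(cfg, "demo")

models <- filter_models_by_r2(cohort$models, 0.01)
qc <- run_score_qc(models, cohort$genotypes)
score_qc_table(qc)

pheno <- phenotype_cohort(cohort$events, cohort$courses)
table(pheno$label)

pcs <- compute_genotype_pcs(cohort$genotypes)
keep <- pheno$label != "excluded_zero_baseline"
y <- pheno$label[keep] == "responder"
cov <- cohort$covariates[match(pheno$subject_id[keep],
                               cohort$covariates$subject_id), ]
adj <- residualize_on_pcs(qc$score_005$values[pheno$subject_id[keep]],
                          pcs[pheno$subject_id[keep], ])
fit_response_model(y, adj, cov, "grs", score_id = "score_005",
                   cohort = "demo", drug = "any")
```

Or the whole pipeline in one call:

```{r runall, eval = FALSE}
run_all(list(out_dir = "demo_run", seed = 7))
```

## Known limitations

* Allele harmonization assumes strand-consistent data; A/T and C/G variants
  are scored as-is with a warning.
* The Shapiro–Wilk screen is limited to 3 ≤ n ≤ 5000 (the test's own
  supported range).
* Apparent (in-sample) discrimination and calibration only; no
  cross-validation.
* No multiple-testing correction — by design, the analysis uses a liberal
  screen plus replication plus empirical null calibration instead.
* Negative-binomial modeling of exacerbation counts is not implemented; the
  response endpoint here is binary, and no count-model result is part of
  the pipeline's outputs.
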