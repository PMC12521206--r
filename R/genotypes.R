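#' Genotype matrix container
#'
#' Holds hard-call genotypes as counts of the ALT allele (0/1/2) for a set of
#' subjects, together with variant metadata. This is the in-memory currency
#' passed to the scoring engine; it can be written to and read back from a
#' sites-by-samples VCF v4.2 with GT fields.
#'
#' @param geno integer matrix, subjects in rows, variants in columns; entries
#'   in \{0,1,2\} (ALT-allele dose).
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`; one row per column of `geno`.
#' @param subjects character vector of subject ids, one per row of `geno`.
#'
#' @return An object of class `grs_genotypes`: a list with elements `geno`,
#'   `variants`, `subjects`.
#' @export
grs_genotypes <- function(geno, variants, subjects) {
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) == length(subjects), ncol(geno) == nrow(variants))
  req <- c("variant_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop("variant metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id in variant metadata")
  if (any(geno < 0 | geno > 2, na.rm = TRUE))
    stop("genotype doses must lie in {0,1,2}")
  dimnames(geno) <- list(subjects, variants$variant_id)
  structure(list(geno = geno, variants = variants, subjects = subjects),
            class = "grs_genotypes")
}

#' @export
print.grs_genotypes <- function(x, ...) {
  cat(sprintf("grs_genotypes: %d subjects x %d variants\n",
              length(x$subjects), nrow(x$variants)))
  invisible(x)
}

#' Write genotypes as a VCF v4.2 file
#'
#' Emits a minimal, deterministic VCF (GT-only FORMAT, one sample column per
#' subject). Byte-identical output for identical input.
#'
#' @param genotypes a [grs_genotypes] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    gts <- gt_codes[genotypes$geno[, j] + 1L]
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j], v$alt[j],
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grsresp",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$subjects), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF v4.2 via \pkg{vcfR} and converts GT calls to ALT-allele
#' doses. Only biallelic sites with plain GT calls are supported.
#'
#' @param path VCF file path.
#' @return A [grs_genotypes] object.
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  variants <- data.frame(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  grs_genotypes(t(dose), variants, colnames(gt))
}

#' Principal components of the genotype matrix
#'
#' Computes ancestry PCs from the column-centered genotype matrix. Monomorphic
#' variants are dropped first. PCs are the standard input to the ancestry
#' residualization step of the association stage.
#'
#' @param genotypes a [grs_genotypes] object.
#' @param n_pcs number of components to return (default 10).
#' @return Numeric matrix (subjects x `n_pcs`) with columns `PC1..PCk`,
#'   rownames the subject ids.
#' @export
compute_genotype_pcs <- function(genotypes, n_pcs = 10) {
  g <- genotypes$geno
  g <- g[, apply(g, 2, function(x) length(unique(x)) > 1L), drop = FALSE]
  n_pcs <- min(n_pcs, nrow(g) - 1L, ncol(g))
  pc <- prcomp(g, center = TRUE, scale. = FALSE)
  out <- pc$x[, seq_len(n_pcs), drop = FALSE]
  colnames(out) <- paste0("PC", seq_len(n_pcs))
  rownames(out) <- genotypes$subjects
  out
}
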