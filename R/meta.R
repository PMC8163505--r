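#' Inverse-variance-weighted meta-analysis of two GWAS of the same trait
#'
#' Pools two summary datasets per SNP by fixed-effect inverse-variance
#' weighting: `beta = (ba/sa^2 + bb/sb^2) / (1/sa^2 + 1/sb^2)` with
#' `se = (1/sa^2 + 1/sb^2)^(-1/2)`. Shared SNPs are allele-harmonized to
#' the first dataset's orientation before pooling; SNPs present in only one
#' dataset pass through unchanged and are flagged via the `n_studies`
#' column (1 = single study, 2 = meta-analyzed). P-values of pooled SNPs
#' are recomputed from the pooled z-score.
#'
#' @param a,b [summary_dataset()] objects for the same trait.
#' @param palindromic_policy Passed to [harmonize()] for the shared SNPs.
#' @return A [summary_dataset()] whose records carry an `n_studies` column.
#' @export
meta_analyze_ivw <- function(a, b, palindromic_policy = "drop") {
  stopifnot(inherits(a, "summary_dataset"), inherits(b, "summary_dataset"))
  if (!identical(a$trait, b$trait))
    stop("cannot meta-analyze different traits: ", a$trait, " vs ", b$trait)
  shared <- intersect(a$records$snp_id, b$records$snp_id)
  pooled <- NULL
  if (length(shared) > 0) {
    h <- harmonize(list(a, b), palindromic_policy = palindromic_policy)
    wa <- 1 / h$se[, 1]^2
    wb <- 1 / h$se[, 2]^2
    beta <- (h$beta[, 1] * wa + h$beta[, 2] * wb) / (wa + wb)
    se <- 1 / sqrt(wa + wb)
    nsum <- rowSums(h$n, na.rm = TRUE)
    nsum[is.na(h$n[, 1]) & is.na(h$n[, 2])] <- NA_real_
    pooled <- data.frame(snp_id = h$snp_ids, chrom = h$chrom, pos = h$pos,
                         effect_allele = h$effect_allele,
                         other_allele = h$other_allele,
                         beta = beta, se = se,
                         pval = 2 * stats::pnorm(-abs(beta / se)),
                         n = nsum, eaf = h$eaf[, 1], n_studies = 2,
                         stringsAsFactors = FALSE)
  }
  singles <- function(d) {
    rec <- d$records[!(d$records$snp_id %in% shared),
                     c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                       "beta", "se", "pval", "n", "eaf"), drop = FALSE]
    if (nrow(rec) > 0) rec$n_studies <- 1
    rec
  }
  out <- rbind(pooled, singles(a), singles(b))
  summary_dataset(out, trait = a$trait,
                  name = paste(a$name, b$name, sep = "+"),
                  population = a$population,
                  overlap_tags = union(a$overlap_tags, b$overlap_tags),
                  trait_scale = a$trait_scale)
}

#' Validate the three-sample Mendelian randomization design
#'
#' The three-sample design uses one GWAS to select instruments and two
#' others to estimate the instrument-exposure and instrument-outcome
#' associations. To avoid winner's curse, the selection GWAS must share no
#' samples with either estimation GWAS. Exposure-outcome sample overlap is
#' tolerated only when the downstream estimator models it (as the
#' multivariable profile-likelihood estimator with a noise-correlation
#' matrix does; the univariable profile-score estimator does not).
#'
#' Overlap is judged from the datasets' `overlap_tags` (names of other
#' datasets sharing samples), checked symmetrically.
#'
#' @param selection,exposure,outcome [summary_dataset()] objects.
#' @param estimator_allows_overlap Does the downstream estimator support
#'   exposure-outcome sample overlap?
#' @return A design token (class `three_sample_design`) recording the roles
#'   and whether exposure-outcome overlap is present. Errors (naming the
#'   offending pair) if the selection GWAS overlaps either estimation GWAS,
#'   or if exposure-outcome overlap is present but unsupported.
#' @export
validate_three_sample <- function(selection, exposure, outcome,
                                  estimator_allows_overlap = FALSE) {
  overlaps <- function(x, y) {
    identical(x$name, y$name) ||
      y$name %in% x$overlap_tags || x$name %in% y$overlap_tags
  }
  if (overlaps(selection, exposure))
    stop("three-sample design violated: selection GWAS '", selection$name,
         "' shares samples with exposure GWAS '", exposure$name, "'")
  if (overlaps(selection, outcome))
    stop("three-sample design violated: selection GWAS '", selection$name,
         "' shares samples with outcome GWAS '", outcome$name, "'")
  eo <- overlaps(exposure, outcome)
  if (eo && !estimator_allows_overlap)
    stop("exposure GWAS '", exposure$name, "' shares samples with outcome GWAS '",
         outcome$name, "' and the declared estimator does not support overlap")
  structure(list(selection = selection$name, exposure = exposure$name,
                 outcome = outcome$name, exposure_outcome_overlap = eo),
            class = "three_sample_design")
}
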