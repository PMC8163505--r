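#' Instrument-level input for univariable MR
#'
#' Holds the harmonized per-SNP association estimates of the clumped
#' instrument set: exposure effect `gamma_hat` with standard error
#' `se_gamma`, outcome effect `Gamma_hat` with `se_Gamma`.
#'
#' @param gamma_hat,se_gamma Exposure associations and SEs.
#' @param Gamma_hat,se_Gamma Outcome associations and SEs.
#' @param snp_id Optional SNP identifiers.
#' @param selection_pval Optional selection-GWAS p-values (provenance).
#' @param datasets Optional named character vector recording which GWAS
#'   supplied each role.
#' @return Object of class `mr_input`.
#' @export
mr_input <- function(gamma_hat, se_gamma, Gamma_hat, se_Gamma, snp_id = NULL,
                     selection_pval = NULL, datasets = NULL) {
  n <- length(gamma_hat)
  stopifnot(length(se_gamma) == n, length(Gamma_hat) == n, length(se_Gamma) == n)
  if (any(se_gamma <= 0) || any(se_Gamma <= 0)) stop("all SEs must be > 0")
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(n))
  structure(list(gamma_hat = as.numeric(gamma_hat), se_gamma = as.numeric(se_gamma),
                 Gamma_hat = as.numeric(Gamma_hat), se_Gamma = as.numeric(se_Gamma),
                 snp_id = as.character(snp_id), n_snps = n,
                 selection_pval = selection_pval, datasets = datasets),
            class = "mr_input")
}

#' Instrument-level input for multivariable MR
#'
#' Like [mr_input()] but with a K-column matrix of exposure associations
#' and a (K+1)-dimensional noise-correlation matrix `R` capturing correlated
#' sampling errors from overlapping GWAS samples. Row/column order of `R`
#' is outcome first, then exposures 1..K.
#'
#' @param gamma_hat,se_gamma n-by-K matrices of exposure associations and
#'   SEs (column names are the exposure names).
#' @param Gamma_hat,se_Gamma Outcome associations and SEs.
#' @param R (K+1) x (K+1) noise-correlation matrix; identity when the
#'   cohorts share no samples. Must be symmetric with unit diagonal and
#'   positive semi-definite.
#' @param snp_id Optional SNP identifiers.
#' @param selection_pval Optional selection-GWAS p-values.
#' @return Object of class `mvmr_input`.
#' @export
mvmr_input <- function(gamma_hat, se_gamma, Gamma_hat, se_Gamma, R = NULL,
                       snp_id = NULL, selection_pval = NULL) {
  gamma_hat <- as.matrix(gamma_hat)
  se_gamma <- as.matrix(se_gamma)
  n <- nrow(gamma_hat)
  K <- ncol(gamma_hat)
  stopifnot(identical(dim(se_gamma), dim(gamma_hat)),
            length(Gamma_hat) == n, length(se_Gamma) == n)
  if (any(se_gamma <= 0) || any(se_Gamma <= 0)) stop("all SEs must be > 0")
  if (is.null(R)) R <- diag(K + 1)
  R <- as.matrix(R)
  stopifnot(nrow(R) == K + 1, ncol(R) == K + 1)
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("R must be positive semi-definite")
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(n))
  if (is.null(colnames(gamma_hat))) colnames(gamma_hat) <- paste0("exposure", seq_len(K))
  structure(list(gamma_hat = gamma_hat, se_gamma = se_gamma,
                 Gamma_hat = as.numeric(Gamma_hat), se_Gamma = as.numeric(se_Gamma),
                 R = R, snp_id = as.character(snp_id), n_snps = n, K = K,
                 exposures = colnames(gamma_hat), selection_pval = selection_pval),
            class = "mvmr_input")
}

#' @export
print.mr_input <- function(x, ...) {
  cat("MR input:", x$n_snps, "instruments\n")
  invisible(x)
}

#' @export
print.mvmr_input <- function(x, ...) {
  cat("Multivariable MR input:", x$n_snps, "instruments x", x$K, "exposures (",
      paste(x$exposures, collapse = ", "), ")\n")
  invisible(x)
}
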