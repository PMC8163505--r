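#' Simulation specification for synthetic GWAS summary data
#'
#' Collects the parameters of the synthetic generating model: a
#' block-diagonal AR(1) LD panel; spike-and-slab instrument effects on K
#' exposures; balanced or directional pleiotropy; polygenic heritabilities
#' and genetic correlation for LD-score-regression traits; cohort sample
#' sizes, overlap fractions and phenotypic correlations (noise correlation
#' = overlap fraction x phenotypic correlation). The seed is mandatory:
#' every simulated dataset is deterministic given its spec.
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: M = 20,000 panel SNPs in 50-SNP AR(1) blocks, cohorts of
#' N = 20,000.
#'
#' @param M Panel size (number of SNPs).
#' @param block_size SNPs per LD block.
#' @param rho AR(1) within-block correlation, |rho| < 1.
#' @param K Number of exposures.
#' @param beta True causal effect(s), length K.
#' @param prop_nonnull Spike-and-slab proportion of SNPs with nonzero
#'   exposure effect.
#' @param effect_sd SD of nonzero (slab) exposure effects.
#' @param tau SD of balanced pleiotropic effects among invalid instruments.
#' @param mu_alpha Mean of pleiotropic effects (0 = balanced, InSIDE-valid).
#' @param prop_invalid Proportion of SNPs with pleiotropic outcome effects.
#' @param h2 Heritabilities (length-2) for polygenic trait pairs.
#' @param rg Genetic correlation for polygenic trait pairs.
#' @param N Cohort sample size(s).
#' @param overlap_frac Fraction of shared samples between two cohorts.
#' @param pheno_cor Phenotypic correlation between the two traits.
#' @param seed Integer seed (mandatory).
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(M = 20000, block_size = 50, rho = 0.5, K = 1,
                            beta = 0.3, prop_nonnull = 0.2, effect_sd = 0.02,
                            tau = 0, mu_alpha = 0, prop_invalid = 0,
                            h2 = c(0.4, 0.4), rg = 0.5, N = 20000,
                            overlap_frac = 0, pheno_cor = 0, seed) {
  if (missing(seed)) stop("seed is mandatory in a simulation spec")
  stopifnot(abs(rho) < 1, prop_nonnull >= 0, prop_nonnull <= 1,
            prop_invalid >= 0, prop_invalid <= 1,
            overlap_frac >= 0, overlap_frac <= 1,
            all(h2 >= 0), all(h2 <= 1), abs(rg) <= 1, length(beta) == K)
  structure(list(M = M, block_size = block_size, rho = rho, K = K, beta = beta,
                 prop_nonnull = prop_nonnull, effect_sd = effect_sd, tau = tau,
                 mu_alpha = mu_alpha, prop_invalid = prop_invalid, h2 = h2,
                 rg = rg, N = N, overlap_frac = overlap_frac,
                 pheno_cor = pheno_cor, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a block-structured AR(1) LD panel
#'
#' Contiguous blocks of `block_size` SNPs with within-block correlation
#' `r_jk = rho^|j-k|`; cross-block correlation zero. Positions are spaced
#' 5 kb apart so whole blocks fall well inside the default 10 Mb clumping
#' window; blocks are split across chromosomes of ~5,000 SNPs. AR(1)
#' matrices are positive definite for |rho| < 1 by construction. The
#' result is deterministic (no randomness is consumed).
#'
#' `rho` may be a vector, recycled across blocks, to emulate the genome's
#' heterogeneous LD: real LD scores span orders of magnitude, and LD-score
#' regression identifies heritability from exactly that spread, so
#' polygenic simulations should mix tight and loose blocks (see
#' [ldsc_sim_rho()]).
#'
#' @param M Number of SNPs.
#' @param block_size SNPs per block (last block may be smaller).
#' @param rho AR(1) correlation(s), each |rho| < 1; recycled over blocks.
#' @return An [ld_panel()] with SNP ids `rs1 ... rsM` (zero-padded so
#'   lexicographic and numeric order agree).
#' @export
simulate_ld_panel <- function(M = 20000, block_size = 50, rho = 0.5) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  stopifnot(block_size >= 1)
  width <- nchar(as.character(M))
  ids <- sprintf("rs%0*d", width, seq_len(M))
  snps_per_chrom <- block_size * max(1, ceiling(5000 / block_size))
  chrom_idx <- (seq_len(M) - 1) %/% snps_per_chrom + 1
  chrom <- sprintf("%02d", chrom_idx)
  pos_in_chrom <- (seq_len(M) - 1) %% snps_per_chrom
  pos <- pos_in_chrom * 5000 + 1
  block <- (seq_len(M) - 1) %/% block_size + 1
  # a block never spans chromosomes because snps_per_chrom is a multiple
  sizes <- tabulate(block)
  rho_b <- rep_len(rho, length(sizes))
  ar1 <- function(n, r) r^abs(outer(seq_len(n), seq_len(n), "-"))
  templates <- new.env()
  block_cor <- lapply(seq_along(sizes), function(b) {
    key <- paste(sizes[b], rho_b[b])
    if (is.null(templates[[key]])) templates[[key]] <- ar1(sizes[b], rho_b[b])
    templates[[key]]
  })
  ld_panel(ids, chrom, pos, block, block_cor)
}

#' Default heterogeneous-LD profile for polygenic simulations
#'
#' A cycle of AR(1) correlations from near-linkage-equilibrium to strong
#' LD. With 50-SNP blocks this yields LD scores from about 1 to about 19,
#' the regressor spread LD-score regression needs.
#'
#' @return Numeric vector of block correlations.
#' @export
ldsc_sim_rho <- function() c(0, 0.3, 0.6, 0.9, 0.95)

# Draw noise for one block-structured trait pair: e1, e2 each N(0, Rblock)
# within blocks, cross-trait covariance a * Rblock (a = overlap fraction x
# phenotypic correlation). Returns an M x 2 matrix.
.correlated_panel_noise <- function(panel, a) {
  sizes <- vapply(panel$block_cor, nrow, integer(1))
  chol_cache <- list()
  e <- matrix(NA_real_, length(panel$snp_ids), 2)
  off <- 0
  for (b in seq_along(panel$block_cor)) {
    n <- sizes[b]
    key <- as.character(n)
    if (is.null(chol_cache[[key]]))
      chol_cache[[key]] <- t(chol(panel$block_cor[[b]]))
    L <- chol_cache[[key]]
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    e[off + seq_len(n), 1] <- L %*% z1
    e[off + seq_len(n), 2] <- L %*% (a * z1 + sqrt(1 - a^2) * z2)
    off <- off + n
  }
  e
}

# Multiply the block-diagonal panel correlation into a per-SNP vector.
.panel_smear <- function(panel, v) {
  out <- numeric(length(v))
  off <- 0
  for (b in seq_along(panel$block_cor)) {
    n <- nrow(panel$block_cor[[b]])
    out[off + seq_len(n)] <- panel$block_cor[[b]] %*% v[off + seq_len(n)]
    off <- off + n
  }
  out
}

.records_from_z <- function(panel, z, n) {
  se <- rep(1 / sqrt(n), length(z))
  data.frame(snp_id = panel$snp_ids, chrom = panel$chrom, pos = panel$pos,
             effect_allele = "A", other_allele = "G",
             beta = z * se, se = se, pval = 2 * stats::pnorm(-abs(z)),
             n = n, eaf = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate a genetically correlated pair of polygenic GWAS
#'
#' Generates marginal association z-scores for two polygenic traits over an
#' LD panel, with the moment structure LD-score regression assumes: per-SNP
#' causal effects are jointly normal with variance `h2_t / M` and
#' correlation `rg`; marginal z-scores are centred at
#' `sqrt(N_t) * sum_k r_jk b_tk` (LD smearing) with noise correlated
#' within blocks (covariance = the LD matrix) and across traits
#' (cross-covariance `a * r_jk` with
#' `a = overlap_frac x pheno_cor = rho N_s / sqrt(N1 N2)`), so that
#' `E[z1_j z2_j] = sqrt(N1 N2) rg sqrt(h2_1 h2_2) ell_j / M + a` holds by
#' construction.
#'
#' @param panel An [ld_panel()].
#' @param h2 Length-2 heritabilities.
#' @param rg Genetic correlation of the causal effects.
#' @param N Length-2 cohort sample sizes (recycled).
#' @param overlap_frac Fraction of cohort-1 samples shared with cohort 2.
#' @param pheno_cor Phenotypic correlation of the traits.
#' @param traits Trait names.
#' @param seed Integer seed.
#' @return List with two [summary_dataset()]s (`a`, `b`) and `truth`
#'   (causal effects and the analytic cross-intercept).
#' @export
simulate_polygenic_pair <- function(panel, h2 = c(0.4, 0.4), rg = 0.5,
                                    N = c(20000, 20000), overlap_frac = 0,
                                    pheno_cor = 0, traits = c("trait1", "trait2"),
                                    seed) {
  stopifnot(inherits(panel, "ld_panel"), all(h2 <= 1))
  N <- rep_len(N, 2)
  M <- length(panel$snp_ids)
  a <- overlap_frac * pheno_cor
  .with_seed(seed, {
    z1 <- stats::rnorm(M); z2 <- stats::rnorm(M)
    b1 <- sqrt(h2[1] / M) * z1
    b2 <- sqrt(h2[2] / M) * (rg * z1 + sqrt(1 - rg^2) * z2)
    mu1 <- sqrt(N[1]) * .panel_smear(panel, b1)
    mu2 <- sqrt(N[2]) * .panel_smear(panel, b2)
    e <- .correlated_panel_noise(panel, a)
    tags <- overlap_frac > 0
    da <- summary_dataset(.records_from_z(panel, mu1 + e[, 1], N[1]),
                          trait = traits[1], name = paste0(traits[1], "_gwas"),
                          overlap_tags = if (tags) paste0(traits[2], "_gwas") else character())
    db <- summary_dataset(.records_from_z(panel, mu2 + e[, 2], N[2]),
                          trait = traits[2], name = paste0(traits[2], "_gwas"),
                          overlap_tags = if (tags) paste0(traits[1], "_gwas") else character())
    list(a = da, b = db,
         truth = list(b1 = b1, b2 = b2, h2 = h2, rg = rg,
                      cross_intercept = a))
  })
}

#' Simulate instrument-level MR summary data
#'
#' Draws an instrument set directly at the summary level under the model
#' the profile-score estimators assume: exposure effects `gamma_j` from a
#' spike-and-slab (`prop_nonnull` nonzero, SD `effect_sd`); pleiotropic
#' direct effects `alpha_j ~ N(mu_alpha, tau^2)` for a `prop_invalid`
#' share of SNPs (InSIDE holds when `mu_alpha = 0`); outcome effects
#' `Gamma_j = beta' gamma_j + alpha_j`; observed statistics jointly normal
#' around the truth with the given SEs and cross-trait noise correlation
#' `R_noise` (order: outcome, exposures) capturing overlapping samples.
#'
#' @param n_snps Number of instruments.
#' @param beta True causal effect(s); length K.
#' @param se_gamma,se_Gamma SEs of the observed associations (scalar or
#'   per-SNP; default `1/sqrt(N)` for N = 20,000).
#' @param prop_nonnull,effect_sd Spike-and-slab exposure-effect model.
#' @param prop_invalid,tau,mu_alpha Pleiotropy model.
#' @param R_noise (K+1) x (K+1) noise-correlation matrix (identity =
#'   disjoint cohorts).
#' @param seed Integer seed.
#' @return List with `input` (an [mr_input()] for K = 1, else an
#'   [mvmr_input()] carrying `R_noise`) and `truth` (list with `beta`,
#'   `gamma`, `alpha`, `R_noise`).
#' @export
simulate_mr_summary <- function(n_snps = 200, beta = 0.3, se_gamma = 1 / sqrt(20000),
                                se_Gamma = 1 / sqrt(20000), prop_nonnull = 1,
                                effect_sd = 0.02, prop_invalid = 0, tau = 0,
                                mu_alpha = 0, R_noise = NULL, seed) {
  K <- length(beta)
  if (is.null(R_noise)) R_noise <- diag(K + 1)
  sx <- matrix(rep_len(se_gamma, n_snps * K), n_snps, K)
  sy <- rep_len(se_Gamma, n_snps)
  .with_seed(seed, {
    nonnull <- matrix(stats::runif(n_snps * K) < prop_nonnull, n_snps, K)
    gamma <- matrix(stats::rnorm(n_snps * K, 0, effect_sd), n_snps, K) * nonnull
    invalid <- stats::runif(n_snps) < prop_invalid
    alpha <- ifelse(invalid, stats::rnorm(n_snps, mu_alpha, tau), 0)
    Gamma <- drop(gamma %*% beta) + alpha
    L <- t(chol(R_noise))
    E <- matrix(stats::rnorm(n_snps * (K + 1)), n_snps) %*% t(L)
    Gamma_hat <- Gamma + sy * E[, 1]
    gamma_hat <- gamma + sx * E[, -1, drop = FALSE]
    input <- if (K == 1) {
      mr_input(drop(gamma_hat), drop(sx), Gamma_hat, sy)
    } else {
      mvmr_input(gamma_hat, sx, Gamma_hat, sy, R = R_noise)
    }
    list(input = input,
         truth = list(beta = beta, gamma = gamma, alpha = alpha,
                      invalid = invalid, R_noise = R_noise))
  })
}

# Randomly permute allele orientation and strand of a records table,
# recording the applied transforms so harmonization can be checked against
# ground truth. Swapping effect/other alleles negates beta.
.scramble_orientation <- function(records, swap, flip) {
  out <- records
  out$beta[swap] <- -records$beta[swap]
  ea <- ifelse(swap, records$other_allele, records$effect_allele)
  oa <- ifelse(swap, records$effect_allele, records$other_allele)
  out$effect_allele <- ifelse(flip, flip_strand(ea), ea)
  out$other_allele <- ifelse(flip, flip_strand(oa), oa)
  if (!is.null(out$eaf)) out$eaf[swap] <- 1 - records$eaf[swap]
  out
}

#' Simulate a complete three-sample MR study
#'
#' Generates one shared set of true per-SNP exposure effects (spike-and-
#' slab) and pleiotropic outcome effects over an LD panel, then three
#' cohort-level summary datasets with independent sampling noise: a
#' selection GWAS and an exposure GWAS of the exposure trait, and an
#' outcome GWAS of `Gamma = beta * gamma + alpha`. Marginal (LD-smeared)
#' effects and block-correlated noise mirror real GWAS structure. Random
#' allele swaps and strand flips are applied per dataset (ground truth
#' recorded) so harmonization is exercised end to end; alleles are drawn
#' from non-palindromic pairs. The selection cohort is always disjoint
#' from the estimation cohorts (requesting overlap is refused — this is
#' the design constraint the three-sample split exists for); the exposure
#' and outcome cohorts may overlap.
#'
#' @param panel An [ld_panel()].
#' @param beta True causal effect (scalar).
#' @param prop_nonnull,effect_sd Spike-and-slab exposure-effect model.
#' @param prop_invalid,tau,mu_alpha Pleiotropy model.
#' @param N Length-3 sample sizes (selection, exposure, outcome).
#' @param selection_overlap Must be 0; any other value is refused.
#' @param exposure_outcome_overlap Fraction of shared samples between the
#'   exposure and outcome cohorts.
#' @param pheno_cor Phenotypic exposure-outcome correlation for the
#'   overlapping samples.
#' @param seed Integer seed.
#' @return List with `selection`, `exposure`, `outcome`
#'   ([summary_dataset()]s), `panel`, and `truth` (per-SNP `gamma`,
#'   `alpha`, marginal effects, orientation scrambles, `beta`).
#' @export
simulate_three_sample_study <- function(panel, beta = 0.3, prop_nonnull = 0.2,
                                        effect_sd = 0.02, prop_invalid = 0,
                                        tau = 0, mu_alpha = 0,
                                        N = c(20000, 20000, 20000),
                                        selection_overlap = 0,
                                        exposure_outcome_overlap = 0,
                                        pheno_cor = 0, seed) {
  stopifnot(inherits(panel, "ld_panel"))
  if (selection_overlap != 0)
    stop("the selection cohort must be disjoint from the estimation cohorts; ",
         "refusing a spec with selection overlap")
  N <- rep_len(N, 3)
  M <- length(panel$snp_ids)
  a <- exposure_outcome_overlap * pheno_cor
  .with_seed(seed, {
    gamma <- stats::rnorm(M, 0, effect_sd) * (stats::runif(M) < prop_nonnull)
    alpha <- ifelse(stats::runif(M) < prop_invalid,
                    stats::rnorm(M, mu_alpha, tau), 0)
    gamma_marg <- .panel_smear(panel, gamma)
    Gamma_marg <- .panel_smear(panel, beta * gamma + alpha)

    allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                           byrow = TRUE)
    pick <- sample.int(4, M, replace = TRUE)
    base <- data.frame(snp_id = panel$snp_ids, chrom = panel$chrom,
                       pos = panel$pos, effect_allele = allele_pairs[pick, 1],
                       other_allele = allele_pairs[pick, 2],
                       eaf = stats::runif(M, 0.05, 0.95), stringsAsFactors = FALSE)
    make_ds <- function(mu, noise, n, trait, name, tags = character()) {
      se <- 1 / sqrt(n)
      rec <- base
      rec$beta <- mu + se * noise
      rec$se <- se
      rec$pval <- 2 * stats::pnorm(-abs(rec$beta / se))
      rec$n <- n
      swap <- stats::runif(M) < 0.5
      flip <- stats::runif(M) < 0.5
      list(ds = summary_dataset(.scramble_orientation(rec, swap, flip),
                                trait = trait, name = name, overlap_tags = tags),
           swap = swap, flip = flip)
    }
    e_sel <- .correlated_panel_noise(panel, 0)[, 1]
    e_est <- .correlated_panel_noise(panel, a)
    tags_exp <- if (exposure_outcome_overlap > 0) "outcome_gwas" else character()
    tags_out <- if (exposure_outcome_overlap > 0) "exposure_gwas" else character()
    sel <- make_ds(gamma_marg, e_sel, N[1], "exposure", "selection_gwas")
    exp_ <- make_ds(gamma_marg, e_est[, 1], N[2], "exposure", "exposure_gwas", tags_exp)
    out <- make_ds(Gamma_marg, e_est[, 2], N[3], "outcome", "outcome_gwas", tags_out)
    list(selection = sel$ds, exposure = exp_$ds, outcome = out$ds, panel = panel,
         truth = list(beta = beta, gamma = gamma, alpha = alpha,
                      gamma_marginal = gamma_marg, Gamma_marginal = Gamma_marg,
                      scrambles = list(selection = sel[c("swap", "flip")],
                                       exposure = exp_[c("swap", "flip")],
                                       outcome = out[c("swap", "flip")]),
                      noise_correlation = a))
  })
}
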