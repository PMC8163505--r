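# Weighted regression of y on [1, x] via block-wise sufficient statistics,
# returning the full-sample coefficients and every leave-one-block-out
# coefficient pair. Weights are held fixed across deletions.
.wls_jackknife <- function(x, y, w, block_id) {
  X1 <- w; Xx <- w * x; Xxx <- w * x^2
  Xy <- w * y; Xxy <- w * x * y
  sums <- function(v) as.vector(rowsum(v, block_id))
  S <- cbind(sums(X1), sums(Xx), sums(Xxx), sums(Xy), sums(Xxy))
  tot <- colSums(S)
  solve2 <- function(s) {
    # s = (sum w, sum wx, sum wx^2, sum wy, sum wxy)
    det <- s[1] * s[3] - s[2]^2
    c(intercept = (s[3] * s[4] - s[2] * s[5]) / det,
      slope = (s[1] * s[5] - s[2] * s[4]) / det)
  }
  full <- solve2(tot)
  loo <- t(apply(S, 1, function(s) solve2(tot - s)))
  list(full = full, loo = loo)
}

.jackknife_se <- function(theta_del, na_ok = FALSE) {
  if (na_ok) theta_del <- theta_del[!is.na(theta_del)]
  B <- length(theta_del)
  if (B < 2) return(NA_real_)
  sqrt((B - 1) / B * sum((theta_del - mean(theta_del))^2))
}

.ldsc_blocks <- function(m, n_blocks) {
  if (m < n_blocks) {
    n_blocks <- max(2L, m %/% 50L)
    warning("fewer SNPs than jackknife blocks; reduced to ", n_blocks, " blocks")
  }
  sort(rep_len(seq_len(n_blocks), m))
}

.match_scores <- function(records, scores) {
  idx <- match(scores$snp_ids, records$snp_id)
  keep <- !is.na(idx)
  list(rec = records[idx[keep], , drop = FALSE], ell = scores$ell[keep])
}

#' SNP heritability by LD-score regression
#'
#' Regresses per-SNP squared z-scores on LD scores: under a polygenic
#' model, `E[z_j^2] = N h2 ell_j / M + intercept`, so the slope times
#' `M / N` estimates the SNP heritability and the free intercept absorbs
#' confounding inflation. Weighting is two-step: an unweighted first pass
#' estimates h2, then the final pass uses heteroskedasticity weights
#' `1 / (ell_j (1 + N h2 ell_j / M)^2)`. Uncertainty comes from a
#' leave-one-block-out jackknife over contiguous SNP blocks (weights held
#' fixed).
#'
#' Negative h2 estimates are possible by sampling noise and are returned
#' as-is (flagged downstream), not clipped.
#'
#' @param stats A [summary_dataset()] with per-SNP `beta`, `se`, `n`.
#' @param scores [ld_scores()] for the reference panel; SNPs are matched by
#'   identifier and analyzed in panel order.
#' @param n_blocks Number of jackknife blocks (default 200), reduced with a
#'   warning when there are fewer SNPs than blocks.
#' @return List of class `h2_estimate`: `h2`, `h2_se`, `intercept`,
#'   `intercept_se`, `slope`, `M`, `n_snps`, `n_bar`, `n_blocks`.
#' @export
fit_h2 <- function(stats, scores, n_blocks = 200) {
  stopifnot(inherits(stats, "summary_dataset"), inherits(scores, "ld_scores"))
  mt <- .match_scores(stats$records, scores)
  z2 <- (mt$rec$beta / mt$rec$se)^2
  ell <- mt$ell
  m <- length(z2)
  if (m < 10) stop("too few SNPs matched to LD scores")
  nbar <- mean(mt$rec$n, na.rm = TRUE)
  if (is.na(nbar)) stop("per-SNP sample sizes required for LD-score regression")
  M <- scores$M
  block_id <- .ldsc_blocks(m, n_blocks)

  fit0 <- stats::lm.fit(cbind(1, ell), z2)
  h2_0 <- max(min(fit0$coefficients[2] * M / nbar, 1), 0)
  w <- 1 / (ell * (1 + nbar * h2_0 * ell / M)^2)
  jk <- .wls_jackknife(ell, z2, w, block_id)
  h2 <- unname(jk$full["slope"]) * M / nbar
  h2_del <- jk$loo[, "slope"] * M / nbar
  structure(list(h2 = h2, h2_se = .jackknife_se(h2_del),
                 intercept = unname(jk$full["intercept"]),
                 intercept_se = .jackknife_se(jk$loo[, "intercept"]),
                 slope = unname(jk$full["slope"]), M = M, n_snps = m,
                 n_bar = nbar, n_blocks = max(block_id), weights_h2 = h2_0),
            class = "h2_estimate")
}

#' Genetic correlation by bivariate LD-score regression
#'
#' Regresses the product of the two traits' z-scores on LD scores:
#' `E[z1_j z2_j] = sqrt(N1 N2) rho_g ell_j / M + intercept`, where the free
#' intercept absorbs the correlated sampling noise arising from overlapping
#' GWAS samples (`rho N_s / sqrt(N1 N2)`). The genetic correlation is
#' `rg = rho_g / sqrt(h2_1 h2_2)` with the heritabilities from univariate
#' fits on the same SNPs; its standard error comes from a
#' leave-one-block-out jackknife of the full rg functional (all three
#' regressions recomputed per deletion, weights held fixed).
#'
#' @param stats1,stats2 [summary_dataset()] objects; allele-harmonized to
#'   a common effect allele internally.
#' @param scores [ld_scores()] for the reference panel.
#' @param n_blocks Jackknife blocks (default 200).
#' @param palindromic_policy Passed to [harmonize()].
#' @return List of class `rg_estimate`: `rg`, `se_rg`, `rho_g`, `h2_1`,
#'   `h2_2`, `intercept_1`, `intercept_2`, `intercept_cross`,
#'   `intercept_cross_se`, `n_snps`, `flag` (NA or a reason when rg is
#'   undefined or out of range).
#' @export
fit_rg <- function(stats1, stats2, scores, n_blocks = 200,
                   palindromic_policy = "drop") {
  h <- harmonize(list(stats1, stats2), palindromic_policy = palindromic_policy)
  idx <- match(scores$snp_ids, h$snp_ids)
  keep <- !is.na(idx)
  idx <- idx[keep]
  ell <- scores$ell[keep]
  m <- length(idx)
  if (m < 10) stop("too few SNPs matched to LD scores")
  M <- scores$M
  z1 <- h$beta[idx, 1] / h$se[idx, 1]
  z2 <- h$beta[idx, 2] / h$se[idx, 2]
  n1 <- mean(h$n[idx, 1], na.rm = TRUE)
  n2 <- mean(h$n[idx, 2], na.rm = TRUE)
  if (is.na(n1) || is.na(n2)) stop("per-SNP sample sizes required")
  block_id <- .ldsc_blocks(m, n_blocks)

  first_pass_h2 <- function(z, n) {
    fit0 <- stats::lm.fit(cbind(1, ell), z^2)
    max(min(fit0$coefficients[2] * M / n, 1), 0)
  }
  h2c1 <- first_pass_h2(z1, n1)
  h2c2 <- first_pass_h2(z2, n2)
  a1 <- 1 + n1 * h2c1 * ell / M
  a2 <- 1 + n2 * h2c2 * ell / M
  jk1 <- .wls_jackknife(ell, z1^2, 1 / (ell * a1^2), block_id)
  jk2 <- .wls_jackknife(ell, z2^2, 1 / (ell * a2^2), block_id)
  jk12 <- .wls_jackknife(ell, z1 * z2, 1 / (ell * a1 * a2), block_id)

  h2_1 <- unname(jk1$full["slope"]) * M / n1
  h2_2 <- unname(jk2$full["slope"]) * M / n2
  rho_g <- unname(jk12$full["slope"]) * M / sqrt(n1 * n2)
  rg_of <- function(s1, s2, s12) {
    hh1 <- s1 * M / n1; hh2 <- s2 * M / n2
    if (hh1 <= 0 || hh2 <= 0) return(NA_real_)
    (s12 * M / sqrt(n1 * n2)) / sqrt(hh1 * hh2)
  }
  rg <- rg_of(jk1$full["slope"], jk2$full["slope"], jk12$full["slope"])
  flag <- NA_character_
  if (is.na(rg)) flag <- "h2 <= 0; rg undefined"
  else if (abs(rg) > 1) flag <- "rg outside [-1, 1]"
  rg_del <- vapply(seq_len(max(block_id)), function(b) {
    rg_of(jk1$loo[b, "slope"], jk2$loo[b, "slope"], jk12$loo[b, "slope"])
  }, numeric(1))
  n_bad <- sum(is.na(rg_del))
  if (n_bad > 0 && !is.na(rg))
    warning(n_bad, " jackknife deletions gave non-positive h2; dropped from SE")
  structure(list(rg = unname(rg), se_rg = .jackknife_se(rg_del, na_ok = TRUE),
                 rho_g = rho_g, h2_1 = h2_1, h2_2 = h2_2,
                 intercept_1 = unname(jk1$full["intercept"]),
                 intercept_2 = unname(jk2$full["intercept"]),
                 intercept_cross = unname(jk12$full["intercept"]),
                 intercept_cross_se = .jackknife_se(jk12$loo[, "intercept"]),
                 n_snps = m, n_blocks = max(block_id), flag = flag),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("rg = %.4f (jackknife SE %.4f), h2 = %.4f / %.4f, cross-intercept %.4f\n",
              x$rg, x$se_rg, x$h2_1, x$h2_2, x$intercept_cross))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Screen traits by genetic correlation with the traditional lipid panel
#'
#' Removes any trait whose estimated genetic correlation with at least one
#' reference trait (TG, LDL-C, HDL-C, ApoB, ApoA1) exceeds the threshold.
#' Such traits are largely co-determined with the traditional risk factors,
#' represent no independent mechanism, and cause multicollinearity in
#' multivariable MR. The removal record names the first offending reference
#' trait in the fixed column order.
#'
#' @param rg_table Numeric matrix of genetic correlations, rows = screened
#'   traits (rownames required), columns = reference traits. Columns are
#'   reordered to the canonical order when all five canonical names are
#'   present. Missing entries are treated as not exceeding the threshold.
#' @param threshold Removal threshold (default 0.8); the rule is a strict
#'   `>`.
#' @param absolute Compare `|rg|` (default) rather than signed rg; a
#'   correlation of -0.95 equally indicates shared genetic determination.
#' @return List of class `screening_result`: `kept` (trait names),
#'   `removed` (data.frame `trait`, `offending_trait`, `rg`),
#'   `reference_traits`, `threshold`.
#' @export
screen_traits <- function(rg_table, threshold = 0.8, absolute = TRUE) {
  canonical <- c("TG", "LDL-C", "HDL-C", "ApoB", "ApoA1")
  rg_table <- as.matrix(rg_table)
  if (all(canonical %in% colnames(rg_table)))
    rg_table <- rg_table[, canonical, drop = FALSE]
  vals <- if (absolute) abs(rg_table) else rg_table
  offend <- apply(vals, 1, function(r) {
    j <- which(!is.na(r) & r > threshold)
    if (length(j) == 0) NA_integer_ else j[1]
  })
  removed_idx <- which(!is.na(offend))
  removed <- data.frame(
    trait = rownames(rg_table)[removed_idx],
    offending_trait = colnames(rg_table)[offend[removed_idx]],
    rg = rg_table[cbind(removed_idx, offend[removed_idx])],
    stringsAsFactors = FALSE)
  structure(list(kept = rownames(rg_table)[is.na(offend)], removed = removed,
                 reference_traits = colnames(rg_table), threshold = threshold),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Trait screening at |rg| >", x$threshold, "with",
      paste(x$reference_traits, collapse = "/"), "\n")
  cat("  kept:", length(x$kept), " removed:", nrow(x$removed), "\n")
  invisible(x)
}

#' Bonferroni significance flags for genetic-correlation estimates
#'
#' Two-sided z-test of `rg = 0` per entry, flagged significant when the
#' p-value is at most `alpha / m` for `m` tested entries (family-wise error
#' rate control across the cells of a correlation matrix).
#'
#' @param rg Numeric vector of genetic correlations.
#' @param se Matching jackknife standard errors (must be positive where
#'   tested; entries with missing rg or se are untested and unflagged).
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests; defaults to the number of testable entries.
#' @return data.frame with `z`, `pval`, `flagged`.
#' @export
bonferroni_flags <- function(rg, se, alpha = 0.05, m = NULL) {
  testable <- !is.na(rg) & !is.na(se) & se > 0
  if (is.null(m)) m <- sum(testable)
  z <- ifelse(testable, rg / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(z = z, pval = p,
             flagged = !is.na(p) & p <= alpha / m)
}

#' Write a genetic-correlation matrix and screening report
#'
#' @param rg_matrix Trait-by-trait rg matrix.
#' @param screening A `screening_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screening <- function(rg_matrix, screening, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(rg_matrix, file.path(dir, "rg_matrix.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(screening$removed, file.path(dir, "screening_removed.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(screening$kept, file.path(dir, "screening_kept.txt"))
  invisible(dir)
}
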