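# Independent oracles used by the test suite. Each is a deliberately
# simple, brute-force re-derivation kept free of the package's own
# implementation paths.

# O(n^2) reference clumping: sort by (p, snp_id); accept a SNP iff every
# previously accepted SNP on the same chromosome within the window has
# r^2 < r2_max (looking r^2 up one pair at a time).
oracle_clump <- function(stats, panel, r2_max = 0.001, window_bp = 1e7,
                         p_max = NULL) {
  rec <- stats$records[stats$records$snp_id %in% panel$snp_ids, , drop = FALSE]
  if (!is.null(p_max)) rec <- rec[rec$pval <= p_max, , drop = FALSE]
  rec <- rec[order(rec$pval, rec$snp_id), , drop = FALSE]
  rec$pos <- panel$pos[match(rec$snp_id, panel$snp_ids)]
  rec$chrom <- panel$chrom[match(rec$snp_id, panel$snp_ids)]
  selected <- character(0)
  for (i in seq_len(nrow(rec))) {
    ok <- TRUE
    for (s in selected) {
      si <- match(s, rec$snp_id)
      if (rec$chrom[si] == rec$chrom[i] &&
          abs(rec$pos[si] - rec$pos[i]) <= window_bp &&
          ld_r2(panel, s, rec$snp_id[i]) >= r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) selected <- c(selected, rec$snp_id[i])
  }
  selected
}

# Dense grid search maximizer of the exact profile log-likelihood
# -1/2 sum_j (Gamma_hat - beta gamma_hat)^2 / (sY^2 + beta^2 sX^2),
# refined by golden-section around the best grid point.
oracle_profile_max <- function(input, lower = -2, upper = 2, n_grid = 40001) {
  pll <- function(b) {
    s2 <- input$se_Gamma^2 + b^2 * input$se_gamma^2
    -sum((input$Gamma_hat - b * input$gamma_hat)^2 / (2 * s2))
  }
  grid <- seq(lower, upper, length.out = n_grid)
  vals <- vapply(grid, pll, numeric(1))
  b0 <- grid[which.max(vals)]
  h <- (upper - lower) / (n_grid - 1)
  stats::optimize(pll, c(b0 - h, b0 + h), maximum = TRUE, tol = 1e-12)$maximum
}

# Standalone weight-CDF inversion for the weighted median: walk the sorted
# ratios accumulating weight; the estimate is the linear interpolation of
# the ratio at the point where the centred cumulative weight crosses 1/2.
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cdf <- numeric(length(w))
  acc <- 0
  for (i in seq_along(w)) {
    cdf[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  if (0.5 <= cdf[1]) return(r[1])
  for (i in 2:length(cdf)) {
    if (cdf[i] >= 0.5) {
      frac <- (0.5 - cdf[i - 1]) / (cdf[i] - cdf[i - 1])
      return(r[i - 1] + frac * (r[i] - r[i - 1]))
    }
  }
  r[length(r)]
}

# Direct weighted least squares of Gamma on the exposure associations with
# weights 1/sY^2, via the normal equations.
oracle_wls <- function(gamma_hat, Gamma_hat, se_Gamma) {
  W <- diag(1 / se_Gamma^2)
  drop(solve(t(gamma_hat) %*% W %*% gamma_hat, t(gamma_hat) %*% W %*% Gamma_hat))
}

# Small helper: records table for hand-built datasets.
toy_records <- function(snp_id, beta, se, ea = "A", oa = "G", chrom = "1",
                        pos = seq_along(snp_id) * 1000, pval = NA_real_,
                        n = 10000, eaf = NA_real_) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, beta = beta, se = se, pval = pval, n = n,
             eaf = eaf, stringsAsFactors = FALSE)
}

toy_dataset <- function(..., trait = "trait", name = trait,
                        overlap_tags = character()) {
  summary_dataset(toy_records(...), trait = trait, name = name,
                  overlap_tags = overlap_tags)
}
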