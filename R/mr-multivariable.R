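#' Estimate the noise-correlation matrix from null SNPs
#'
#' When GWAS cohorts share samples, the sampling errors of their
#' association estimates are correlated (analytically, overlap fraction
#' times phenotypic correlation). For SNPs with no genetic signal, the
#' observed z-scores are pure noise, so their cross-trait correlation
#' estimates the noise correlation.
#'
#' How null SNPs are chosen matters. The preferred mode supplies p-values
#' from a sample-disjoint selection GWAS (`selection_pval`): SNPs with
#' selection p at or above `2 pnorm(-z_max)` (p >= 0.5 at the default) are
#' treated as null, and because that truncation is independent of the
#' estimation datasets' sampling noise, the plain Pearson correlation of
#' their z-scores is unbiased. Without selection p-values, null SNPs are
#' those with `|z| <= z_max` for the pair of traits concerned; that box
#' truncation shrinks the sample correlation severely (for example a true
#' 0.3 appears as about 0.045 at the default threshold), so each pairwise
#' estimate is de-attenuated by numerically inverting the moment map
#' `rho -> cor(z1, z2 | |z1|, |z2| <= z_max)` of the truncated bivariate
#' normal (computed by product Gauss-Legendre quadrature). The assembled
#' matrix is projected to the nearest positive semi-definite correlation
#' matrix if needed.
#'
#' @param htab A `harmonized_table` over a genome-wide SNP set (not just
#'   the instruments); trait order is preserved (put the outcome first to
#'   match [mvmr_input()]).
#' @param z_max Null-SNP |z| ceiling (default `qnorm(0.75)` ~ 0.675).
#' @param selection_pval Optional per-SNP p-values from a sample-disjoint
#'   selection GWAS, aligned with `htab$snp_ids` (or named by SNP id).
#' @return Correlation matrix with attribute `n_null_snps` (minimum count
#'   used for any entry).
#' @export
estimate_noise_correlation <- function(htab, z_max = 0.675, selection_pval = NULL) {
  stopifnot(inherits(htab, "harmonized_table"))
  z <- htab$beta / htab$se
  K1 <- ncol(z)
  if (!is.null(selection_pval)) {
    if (!is.null(names(selection_pval)))
      selection_pval <- selection_pval[match(htab$snp_ids, names(selection_pval))]
    stopifnot(length(selection_pval) == nrow(z))
    null_snp <- !is.na(selection_pval) & selection_pval >= 2 * stats::pnorm(-z_max)
    m <- sum(null_snp)
    if (m < 100)
      stop("only ", m, " null SNPs by selection p-value; need >= 100")
    R <- stats::cor(z[null_snp, , drop = FALSE])
  } else {
    R <- diag(K1)
    dimnames(R) <- list(colnames(z), colnames(z))
    m <- Inf
    for (i in seq_len(K1 - 1)) {
      for (j in (i + 1):K1) {
        nn <- abs(z[, i]) <= z_max & abs(z[, j]) <= z_max
        m <- min(m, sum(nn))
        if (sum(nn) < 100)
          stop("only ", sum(nn), " null SNPs (|z| <= ", z_max,
               ") for traits ", i, " and ", j, "; need >= 100")
        r_t <- stats::cor(z[nn, i], z[nn, j])
        R[i, j] <- R[j, i] <- .detruncate_cor(r_t, z_max)
      }
    }
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 0) {
    nm <- dimnames(R)
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dimnames(R) <- nm
  }
  attr(R, "n_null_snps") <- m
  R
}

# Correlation of a standard bivariate normal truncated to the box
# [-a, a]^2, by product Gauss-Legendre quadrature; inverted by uniroot to
# recover rho from an observed truncated correlation.
.truncated_box_cor <- function(rho, a, n_nodes = 48) {
  gl <- pracma::gaussLegendre(n_nodes, -a, a)
  x <- gl$x
  wx <- gl$w * stats::dnorm(x)
  # conditional z2 | z1 = x is N(rho x, 1 - rho^2); integrate over [-a, a]
  sd2 <- sqrt(1 - rho^2)
  lo <- (-a - rho * x) / sd2
  hi <- (a - rho * x) / sd2
  p_in <- stats::pnorm(hi) - stats::pnorm(lo)
  # truncated-normal mean and second moment of z2 | z1 = x on [-a, a]
  num <- stats::dnorm(lo) - stats::dnorm(hi)
  mu_c <- rho * x + sd2 * num / p_in
  v_c <- (1 - rho^2) * (1 + (lo * stats::dnorm(lo) - hi * stats::dnorm(hi)) / p_in -
                          (num / p_in)^2)
  m00 <- sum(wx * p_in)
  m11 <- sum(wx * x * mu_c * p_in)
  m20 <- sum(wx * x^2 * p_in)
  m02 <- sum(wx * (v_c + mu_c^2) * p_in)
  (m11 / m00) / sqrt((m20 / m00) * (m02 / m00))
}

.detruncate_cor <- function(r_t, a) {
  if (is.na(r_t)) return(NA_real_)
  f <- function(rho) .truncated_box_cor(rho, a) - r_t
  if (f(-0.999) > 0) return(-1)
  if (f(0.999) < 0) return(1)
  stats::uniroot(f, c(-0.999, 0.999), tol = 1e-10)$root
}

# Shared pieces of the multivariable profile score. With contrast
# c(beta) = (1, -beta_1, ..., -beta_K) and per-SNP SE vector
# d_j = (sY_j, sX_1j, ..., sX_Kj), the residual variance is
# s_j^2 = (d_j * c)' R (d_j * c) + tau2 and
# d s_j^2 / d beta_k = -2 d_{j,k+1} (R u_j)_{k+1} with u_j = d_j * c.
.grapple_parts <- function(beta, tau2, input) {
  cvec <- c(1, -beta)
  D <- cbind(input$se_Gamma, input$se_gamma)
  U <- sweep(D, 2, cvec, "*")          # n x (K+1), rows u_j
  RU <- U %*% input$R
  s2 <- rowSums(U * RU) + tau2
  r <- input$Gamma_hat - drop(input$gamma_hat %*% beta)
  list(s2 = s2, s = sqrt(s2), t = r / sqrt(s2), RU = RU, D = D)
}

.grapple_score_j <- function(beta, tau2, input, loss, with_tau) {
  p <- .grapple_parts(beta, tau2, input)
  psi_t <- loss$psi(p$t)
  # ds2/dbeta_k / 2 = -d_{j,k+1} (RU)_{j,k+1}
  ds2_half <- -p$D[, -1, drop = FALSE] * p$RU[, -1, drop = FALSE]
  Uk <- input$gamma_hat * (psi_t / p$s) + ds2_half * (psi_t * p$t / p$s2)
  if (with_tau) cbind(Uk, psi_t * p$t - loss$delta) else Uk
}

#' Multivariable MR by robust profile likelihood (GRAPPLE-style)
#'
#' Estimates the joint causal effects of K exposures on the outcome under
#' the profile-likelihood model with correlated sampling noise: for SNP j,
#' the residual `Gamma_hat_j - beta' gamma_hat_j` has variance
#' `s_j^2 = c(beta)' D_j R D_j c(beta) + tau2`, with
#' `c(beta) = (1, -beta_1, ..., -beta_K)`, `D_j` the diagonal of per-SNP
#' SEs (outcome first), `R` the noise-correlation matrix from overlapping
#' samples, and `tau2 >= 0` the balanced-pleiotropy overdispersion. The K
#' robustified score equations
#' `sum_j [ psi(t_j) gamma_hat_kj / s_j + psi(t_j) t_j (d s_j^2 / d beta_k) / (2 s_j^2) ] = 0`
#' (the robustified derivative of the profile log-likelihood
#' `-1/2 sum_j r_j^2 / s_j^2`, mean zero at the truth)
#' are solved jointly with the dispersion equation
#' `sum_j [ psi(t_j) t_j - delta ] = 0` by damped Newton iteration with
#' restarts; covariance by the sandwich formula. With K = 1 and R identity
#' this reproduces [mr_raps()].
#'
#' @param input An [mvmr_input()] with `n_snps >= K + 2`.
#' @param loss A [robust_loss()] (default Huber, 1.345).
#' @param overdispersion Estimate `tau2` (default TRUE).
#' @param max_iter,tol Convergence controls.
#' @return Object of class `mvmr_estimate`: `beta` (named K-vector),
#'   `vcov`, `se`, `ci95` (K x 2), `tau2`, `exposures`, `n_snps`,
#'   `converged`.
#' @export
grapple_fit <- function(input, loss = robust_loss("huber"), overdispersion = TRUE,
                        max_iter = 200, tol = 1e-11) {
  stopifnot(inherits(input, "mvmr_input"), inherits(loss, "robust_loss"))
  K <- input$K
  if (input$n_snps < K + 2) stop("need at least K + 2 instruments")
  gram <- crossprod(input$gamma_hat / input$se_gamma)
  if (kappa(gram) > 1e8) {
    cc <- abs(stats::cov2cor(gram))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop("near-collinear exposure associations between '",
         input$exposures[worst[1]], "' and '", input$exposures[worst[2]],
         "' (Gram condition number ", format(kappa(gram), digits = 3), ")")
  }

  score_beta <- function(beta, tau2) {
    colSums(.grapple_score_j(beta, tau2, input, loss, with_tau = FALSE))
  }
  solve_tau <- function(beta) {
    f <- function(tau2) {
      p <- .grapple_parts(beta, tau2, input)
      sum(loss$psi(p$t) * p$t - loss$delta)
    }
    if (f(0) <= 0) return(0)
    hi <- stats::var(input$Gamma_hat - drop(input$gamma_hat %*% beta)) + 1
    for (i in 1:60) {
      if (f(hi) < 0) break
      hi <- hi * 2
    }
    if (f(hi) >= 0) stop("overdispersion equation has no root")
    stats::uniroot(f, c(0, hi), tol = 1e-14)$root
  }
  newton_beta <- function(beta, tau2) {
    for (it in 1:100) {
      g <- score_beta(beta, tau2)
      scale_k <- colSums(abs(input$gamma_hat) /
                           sqrt(.grapple_parts(beta, tau2, input)$s2)) + 1
      if (max(abs(g) / scale_k) < 1e-9) break
      J <- pracma::jacobian(function(b) score_beta(b, tau2), beta)
      step <- tryCatch(solve(J, g), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        cand <- beta - lambda * step
        gc2 <- sum(score_beta(cand, tau2)^2)
        if (gc2 <= sum(g^2) || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      if (max(abs(lambda * step)) < tol) { beta <- cand; break }
      beta <- cand
    }
    beta
  }

  # WLS start (the exact solution in the sigma_X -> 0, l2, tau2 = 0 limit)
  w <- 1 / input$se_Gamma^2
  Xw <- input$gamma_hat * sqrt(w)
  beta <- drop(solve(crossprod(Xw), crossprod(Xw, input$Gamma_hat * sqrt(w))))
  tau2 <- 0
  converged <- FALSE
  starts <- list(beta, beta * 0, beta * 1.5, beta * 0.5, -beta)
  for (s in seq_along(starts)) {
    b <- starts[[s]]
    t2 <- 0
    ok <- TRUE
    for (it in 1:max_iter) {
      b_new <- tryCatch(newton_beta(b, t2), error = function(e) NULL)
      if (is.null(b_new)) { ok <- FALSE; break }
      t2_new <- if (overdispersion)
        tryCatch(solve_tau(b_new), error = function(e) NULL) else 0
      if (is.null(t2_new)) { ok <- FALSE; break }
      done <- max(abs(b_new - b)) < tol && abs(t2_new - t2) < tol
      b <- b_new; t2 <- t2_new
      if (done) break
    }
    # scale-aware convergence: the score's natural size is sum |gamma|/s
    scale_k <- colSums(abs(input$gamma_hat) /
                         sqrt(.grapple_parts(b, t2, input)$s2)) + 1
    if (ok && max(abs(score_beta(b, t2)) / scale_k) < 1e-7) {
      beta <- b; tau2 <- t2; converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("GRAPPLE fit did not converge after ", length(starts),
         " restarts; last score norm ",
         format(max(abs(score_beta(beta, tau2))), digits = 3))

  free_tau <- overdispersion && tau2 > 0
  score_all <- function(theta) {
    b <- theta[seq_len(K)]
    t2 <- if (free_tau) theta[K + 1] else tau2
    .grapple_score_j(b, t2, input, loss, with_tau = free_tau)
  }
  theta <- if (free_tau) c(beta, tau2) else beta
  Uj <- score_all(theta)
  A <- pracma::jacobian(function(th) colSums(score_all(th)), theta)
  B <- crossprod(Uj)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% t(Ainv)
  Vb <- V[seq_len(K), seq_len(K), drop = FALSE]
  Vb <- (Vb + t(Vb)) / 2
  se <- sqrt(diag(Vb))
  names(beta) <- names(se) <- input$exposures
  dimnames(Vb) <- list(input$exposures, input$exposures)
  ci <- cbind(beta - stats::qnorm(0.975) * se, beta + stats::qnorm(0.975) * se)
  colnames(ci) <- c("lower", "upper")
  structure(list(beta = beta, vcov = Vb, se = se, ci95 = ci, tau2 = tau2,
                 tau2_se = if (free_tau) sqrt(V[K + 1, K + 1]) else NA_real_,
                 exposures = input$exposures, n_snps = input$n_snps,
                 loss = loss$name, converged = converged),
            class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat("Multivariable MR estimate (", x$n_snps, " instruments, tau2 = ",
      format(x$tau2, digits = 3), "):\n", sep = "")
  for (k in seq_along(x$beta)) {
    cat(sprintf("  %-12s %6.3f [%.3f, %.3f]\n", x$exposures[k], x$beta[k],
                x$ci95[k, 1], x$ci95[k, 2]))
  }
  invisible(x)
}

#' Per-exposure modified Cochran's Q instrument-strength statistic
#'
#' Measures how much independent association signal each exposure carries
#' beyond the other exposures. For exposure k, the other exposures' per-SNP
#' associations are regressed on exposure k's by error-weighted least
#' squares with weights `1 / (sX_kj^2 + delta' diag(sX_-k,j^2) delta)`
#' (the auxiliary coefficients `delta` refit until the weights converge);
#' `Q_k` is the weighted residual sum of squares with
#' `df = n_snps - K + 1`. A small `Q_k` relative to its chi-squared
#' reference (large p) flags conditionally weak instruments for that
#' exposure.
#'
#' @param input An [mvmr_input()] with `K >= 2`.
#' @return data.frame with one row per exposure: `exposure`, `Q`, `df`,
#'   `pval`, `weak` (TRUE when `Q/df < 3`).
#' @export
modified_q <- function(input) {
  stopifnot(inherits(input, "mvmr_input"), input$K >= 2)
  n <- input$n_snps
  K <- input$K
  df <- n - K + 1
  out <- lapply(seq_len(K), function(k) {
    y <- input$gamma_hat[, k]
    X <- input$gamma_hat[, -k, drop = FALSE]
    s2y <- input$se_gamma[, k]^2
    s2X <- input$se_gamma[, -k, drop = FALSE]^2
    delta <- rep(0, K - 1)
    for (it in 1:50) {
      w <- 1 / (s2y + drop(s2X %*% delta^2))
      Xw <- X * sqrt(w)
      delta_new <- drop(solve(crossprod(Xw), crossprod(Xw, y * sqrt(w))))
      if (max(abs(delta_new - delta)) < 1e-10) { delta <- delta_new; break }
      delta <- delta_new
    }
    w <- 1 / (s2y + drop(s2X %*% delta^2))
    Q <- sum(w * (y - drop(X %*% delta))^2)
    data.frame(exposure = input$exposures[k], Q = Q, df = df,
               pval = stats::pchisq(Q, df, lower.tail = FALSE),
               weak = Q / df < 3, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
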