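.mr_estimate <- function(beta, se, tau2, method, loss = NA_character_,
                         n_snps, converged = TRUE, multimodal = FALSE, ...) {
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  structure(c(list(beta = beta, se = se, ci95 = ci, odds_ratio = exp(beta),
                   or_ci95 = exp(ci), tau2 = tau2, method = method, loss = loss,
                   n_snps = n_snps, converged = converged, multimodal = multimodal),
              list(...)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d instruments): beta = %.4f, se = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$method, x$n_snps, x$beta, x$se, x$ci95[1], x$ci95[2]))
  cat(sprintf("  OR = %.4f [%.4f, %.4f]", x$odds_ratio, x$or_ci95[1], x$or_ci95[2]))
  if (!is.na(x$tau2)) cat(sprintf(", tau2 = %.3g", x$tau2))
  cat("\n")
  if (x$multimodal) cat("  WARNING: profile score has multiple roots\n")
  invisible(x)
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Inverse-variance weighted MR estimate
#'
#' The classical fixed-effect combination of per-SNP ratio estimates:
#' `beta = sum(g G / sY^2) / sum(g^2 / sY^2)` with fixed-effect standard
#' error `(sum g^2 / sY^2)^(-1/2)`. The random-effect (multiplicative
#' dispersion) variant inflates the SE by `max(1, sqrt(Q / (n - 1)))`,
#' where Q is Cochran's heterogeneity statistic at the IVW estimate; both
#' are returned, with the fixed-effect SE as `se`.
#'
#' @param input An [mr_input()] with at least 2 SNPs.
#' @return An `mr_estimate` (method `"IVW"`) with extra fields `se_fixed`,
#'   `se_random`, `Q`, `Q_df`, `Q_pval`.
#' @export
mr_ivw <- function(input) {
  stopifnot(inherits(input, "mr_input"), input$n_snps >= 2)
  g <- input$gamma_hat; G <- input$Gamma_hat; w <- 1 / input$se_Gamma^2
  if (all(g == 0)) stop("all exposure associations are zero")
  beta <- sum(g * G * w) / sum(g^2 * w)
  se_fixed <- 1 / sqrt(sum(g^2 * w))
  Q <- sum((G - beta * g)^2 * w)
  infl <- max(1, sqrt(Q / (input$n_snps - 1)))
  .mr_estimate(beta, se_fixed, NA_real_, "IVW", n_snps = input$n_snps,
               se_fixed = se_fixed, se_random = se_fixed * infl,
               Q = Q, Q_df = input$n_snps - 1,
               Q_pval = stats::pchisq(Q, input$n_snps - 1, lower.tail = FALSE))
}

#' Weighted-median MR estimate
#'
#' Ratio estimates `r_j = Gamma_hat_j / gamma_hat_j` with inverse-variance
#' weights `w_j = gamma_hat_j^2 / se_Gamma_j^2` (normalized). The estimate
#' is the 50% point of the weight CDF over the sorted ratios, with linear
#' interpolation between adjacent ratios (consistent when at least half the
#' weight comes from valid instruments). The SE comes from a seeded
#' parametric bootstrap resampling the summary statistics from their
#' normal sampling distributions.
#'
#' @param input An [mr_input()] with at least 3 SNPs; SNPs with
#'   `gamma_hat = 0` are excluded and logged in the result.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @return An `mr_estimate` (method `"weighted-median"`) with field
#'   `excluded` (SNP ids dropped for zero exposure association).
#' @export
mr_weighted_median <- function(input, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(input, "mr_input"))
  keep <- input$gamma_hat != 0
  excluded <- input$snp_id[!keep]
  g <- input$gamma_hat[keep]; G <- input$Gamma_hat[keep]
  sx <- input$se_gamma[keep]; sy <- input$se_Gamma[keep]
  if (length(g) < 3) stop("weighted median needs >= 3 usable instruments")
  point <- .weighted_median_point(G / g, g^2 / sy^2)
  boots <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      gb <- stats::rnorm(length(g), g, sx)
      Gb <- stats::rnorm(length(G), G, sy)
      ok <- gb != 0
      .weighted_median_point(Gb[ok] / gb[ok], gb[ok]^2 / sy[ok]^2)
    }, numeric(1))
  })
  .mr_estimate(point, stats::sd(boots), NA_real_, "weighted-median",
               n_snps = length(g), excluded = excluded, n_boot = n_boot)
}

# 50% point of the weight CDF over sorted ratios: with sorted ratios r_(j)
# and normalized weights w_(j), the CDF midpoints are S_j = cumsum(w)_j -
# w_j / 2; interpolate linearly in S to 0.5.
.weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  S <- cumsum(w) - w / 2
  if (0.5 <= S[1]) return(r[1])
  if (0.5 >= S[length(S)]) return(r[length(r)])
  stats::approx(S, r, xout = 0.5, ties = "ordered")$y
}

# Profile-score pieces shared by the RAPS solver. s2 is the residual
# variance sY^2 + beta^2 sX^2 + tau2; t the standardized residual; the
# beta-score is the robustified derivative of the profile log-likelihood,
# including the term from d s2 / d beta (without it the estimator is
# inconsistent whenever the exposure associations carry measurement error).
.raps_t <- function(beta, tau2, input) {
  s2 <- input$se_Gamma^2 + beta^2 * input$se_gamma^2 + tau2
  list(s2 = s2, s = sqrt(s2), t = (input$Gamma_hat - beta * input$gamma_hat) / sqrt(s2))
}

.raps_score_beta <- function(beta, tau2, input, loss) {
  p <- .raps_t(beta, tau2, input)
  psi_t <- loss$psi(p$t)
  sum(psi_t * input$gamma_hat / p$s +
        psi_t * p$t * beta * input$se_gamma^2 / p$s2)
}

.raps_score_tau <- function(beta, tau2, input, loss) {
  p <- .raps_t(beta, tau2, input)
  sum(loss$psi(p$t) * p$t - loss$delta)
}

# Scan f over a grid, refine every bracketed sign change by uniroot, and
# return all roots. The grid expands if no sign change is found inside.
.grid_roots <- function(f, lower = -2, upper = 2, n_grid = 201, max_expand = 4) {
  for (e in 0:max_expand) {
    lo <- lower * 2^e; hi <- upper * 2^e
    grid <- seq(lo, hi, length.out = n_grid * 2^min(e, 2))
    fv <- vapply(grid, f, numeric(1))
    ok <- is.finite(fv)
    grid <- grid[ok]; fv <- fv[ok]
    exact <- grid[fv == 0]
    sc <- which(fv[-1] * fv[-length(fv)] < 0)
    if (length(sc) > 0 || length(exact) > 0) {
      roots <- vapply(sc, function(i) {
        stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
      }, numeric(1))
      return(unique(c(exact, roots)))
    }
  }
  numeric(0)
}

#' Robust adjusted profile score (RAPS) MR estimate
#'
#' Fits the measurement-error model `Gamma_hat_j ~ N(beta gamma_j + alpha_j,
#' sY_j^2)`, `gamma_hat_j ~ N(gamma_j, sX_j^2)`, with balanced pleiotropic
#' effects `alpha_j ~ N(0, tau2)`. Standardized residuals are
#' `t_j = (Gamma_hat_j - beta gamma_hat_j) / s_j` with
#' `s_j^2 = sY_j^2 + beta^2 sX_j^2 + tau2`. The causal effect solves the
#' robustified profile-score equation
#' `sum_j [ psi(t_j) gamma_hat_j / s_j + psi(t_j) t_j beta sX_j^2 / s_j^2 ] = 0`.
#' For squared loss this is exactly the derivative of the profile
#' log-likelihood `-1/2 sum_j (Gamma_hat_j - beta gamma_hat_j)^2 / s_j^2`
#' obtained by maximizing out the per-SNP nuisance effects, and the score
#' has mean zero at the truth (the second term cancels the correlation
#' between the residual and the observed exposure association, which would
#' otherwise attenuate the estimate). It is solved jointly with the
#' overdispersion equation
#' `sum_j [ psi(t_j) t_j - delta ] = 0` under the constraint `tau2 >= 0`
#' (when the dispersion equation has no nonnegative root, `tau2` is fixed
#' at 0 and beta re-solved). Standard errors come from the sandwich
#' covariance of the stacked estimating equations.
#'
#' Roots are located by a bracketing grid scan refined by uniroot; when the
#' beta-equation has several widely separated roots the fit is flagged
#' multimodal and the root with the smallest robust profile objective is
#' reported.
#'
#' @param input An [mr_input()] with at least 3 SNPs.
#' @param loss A [robust_loss()]; default Huber with tuning 1.345.
#' @param overdispersion Estimate `tau2` (default TRUE)? When FALSE,
#'   `tau2` is fixed at 0.
#' @param max_iter,tol Convergence controls for the alternating solve.
#' @return An `mr_estimate` (method `"RAPS"`) with extra fields `tau2_se`
#'   (NA at the boundary), `n_iter`.
#' @export
mr_raps <- function(input, loss = robust_loss("huber"), overdispersion = TRUE,
                    max_iter = 100, tol = 1e-10) {
  stopifnot(inherits(input, "mr_input"), inherits(loss, "robust_loss"))
  if (input$n_snps < 3) stop("RAPS needs at least 3 instruments")

  solve_beta <- function(tau2) {
    roots <- .grid_roots(function(b) .raps_score_beta(b, tau2, input, loss))
    if (length(roots) == 0)
      stop("RAPS beta equation has no root in the search range; trace: tau2 = ", tau2)
    if (length(roots) == 1) return(list(beta = roots, multimodal = FALSE))
    obj <- vapply(roots, function(b) {
      p <- .raps_t(b, tau2, input)
      sum(loss$rho(p$t))
    }, numeric(1))
    spread <- diff(range(roots))
    list(beta = roots[which.min(obj)],
         multimodal = spread > 1e-4 * max(1, max(abs(roots))))
  }
  solve_tau <- function(beta) {
    f <- function(tau2) .raps_score_tau(beta, tau2, input, loss)
    if (f(0) <= 0) return(0)
    hi <- stats::var(input$Gamma_hat - beta * input$gamma_hat) + 1
    for (i in 1:60) {
      if (f(hi) < 0) break
      hi <- hi * 2
    }
    if (f(hi) >= 0) stop("overdispersion equation has no root; trace: beta = ", beta)
    stats::uniroot(f, c(0, hi), tol = 1e-14)$root
  }

  tau2 <- 0
  multimodal <- FALSE
  beta <- solve_beta(0)$beta
  iter <- 0
  if (overdispersion) {
    repeat {
      iter <- iter + 1
      tau2_new <- solve_tau(beta)
      sb <- solve_beta(tau2_new)
      multimodal <- multimodal || sb$multimodal
      done <- abs(sb$beta - beta) < tol && abs(tau2_new - tau2) < tol
      beta <- sb$beta
      tau2 <- tau2_new
      if (done || iter >= max_iter) break
    }
    if (iter >= max_iter)
      warning("RAPS alternating solve did not converge in ", max_iter, " iterations")
  } else {
    sb <- solve_beta(0)
    beta <- sb$beta
    multimodal <- sb$multimodal
  }

  at_boundary <- overdispersion && tau2 == 0
  free_tau <- overdispersion && !at_boundary
  score_j <- function(theta) {
    b <- theta[1]
    t2 <- if (free_tau) theta[2] else tau2
    p <- .raps_t(b, t2, input)
    psi_t <- loss$psi(p$t)
    u1 <- psi_t * input$gamma_hat / p$s +
      psi_t * p$t * b * input$se_gamma^2 / p$s2
    if (free_tau) cbind(u1, psi_t * p$t - loss$delta) else cbind(u1)
  }
  theta <- if (free_tau) c(beta, tau2) else beta
  U <- score_j(theta)
  Asum <- pracma::jacobian(function(th) colSums(score_j(th)), theta)
  B <- crossprod(U)
  V <- solve(Asum, B) %*% t(solve(Asum))
  tau2_se <- if (free_tau) sqrt(V[2, 2]) else NA_real_

  .mr_estimate(beta, sqrt(V[1, 1]), tau2, "RAPS", loss = loss$name, n_snps = input$n_snps,
               converged = iter < max_iter || !overdispersion,
               multimodal = multimodal, tau2_se = tau2_se, n_iter = iter)
}

#' Modified Cochran's Q heterogeneity statistic (univariable)
#'
#' `Q = sum_j (Gamma_hat_j - beta gamma_hat_j)^2 / (sY_j^2 + beta^2 sX_j^2)`
#' with `df = n - 1`; the exposure measurement-error term in the
#' denominator is the modification relative to the classical statistic.
#' Large Q signals heterogeneity (pleiotropy) at the supplied effect.
#'
#' @param input An [mr_input()] with at least 2 SNPs.
#' @param beta Causal-effect value at which residuals are evaluated.
#' @return List with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(input, beta) {
  stopifnot(inherits(input, "mr_input"), input$n_snps >= 2)
  s2 <- input$se_Gamma^2 + beta^2 * input$se_gamma^2
  Q <- sum((input$Gamma_hat - beta * input$gamma_hat)^2 / s2)
  df <- input$n_snps - 1
  list(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Residual diagnostics for a profile-score MR fit
#'
#' Returns the standardized residuals at the fitted effect and
#' overdispersion, theoretical normal quantiles for a QQ plot,
#' leave-one-out effect estimates, and a funnel-plot table (residual and
#' ratio estimate against instrument precision). Instruments with
#' `|t_j| > 3` are flagged as outliers.
#'
#' @param input An [mr_input()].
#' @param fit A converged `mr_estimate` (any method with a `beta`; `tau2`
#'   used when present).
#' @param loo Recompute leave-one-out estimates (default when at most 500
#'   instruments)? Uses the same method settings as `fit` for RAPS/IVW.
#' @param loss Loss for leave-one-out RAPS refits.
#' @return List of class `mr_diagnostics`: data.frame `table` (snp_id,
#'   residual, qq_theoretical, precision, ratio, outlier), vector
#'   `loo_beta` (or NULL), `outliers` (SNP ids).
#' @export
residual_diagnostics <- function(input, fit, loo = input$n_snps <= 500,
                                 loss = robust_loss("huber")) {
  stopifnot(inherits(input, "mr_input"), inherits(fit, "mr_estimate"))
  tau2 <- if (is.na(fit$tau2)) 0 else fit$tau2
  p <- .raps_t(fit$beta, tau2, input)
  tj <- p$t
  qq <- numeric(length(tj))
  qq[order(tj)] <- stats::qnorm(stats::ppoints(length(tj)))
  tab <- data.frame(snp_id = input$snp_id, residual = tj, qq_theoretical = qq,
                    precision = abs(input$gamma_hat) / input$se_Gamma,
                    ratio = ifelse(input$gamma_hat == 0, NA_real_,
                                   input$Gamma_hat / input$gamma_hat),
                    outlier = abs(tj) > 3, stringsAsFactors = FALSE)
  loo_beta <- NULL
  if (isTRUE(loo)) {
    refit <- function(sub) {
      if (fit$method == "RAPS")
        mr_raps(sub, loss = loss, overdispersion = !is.na(fit$tau2) && fit$tau2 > 0)$beta
      else mr_ivw(sub)$beta
    }
    loo_beta <- vapply(seq_len(input$n_snps), function(j) {
      sub <- mr_input(input$gamma_hat[-j], input$se_gamma[-j],
                      input$Gamma_hat[-j], input$se_Gamma[-j],
                      snp_id = input$snp_id[-j])
      refit(sub)
    }, numeric(1))
  }
  structure(list(table = tab, loo_beta = loo_beta,
                 outliers = input$snp_id[tab$outlier]),
            class = "mr_diagnostics")
}
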