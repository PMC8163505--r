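make_noise_table <- function(M, R, seed, se = 0.01) {
  set.seed(seed)
  L <- t(chol(R))
  E <- matrix(rnorm(M * nrow(R)), M) %*% t(L)
  ids <- sprintf("rs%05d", seq_len(M))
  ds <- lapply(seq_len(nrow(R)), function(k) {
    summary_dataset(toy_records(ids, beta = E[, k] * se, se = rep(se, M),
                                pos = seq_len(M) * 1000, n = round(1 / se^2)),
                    trait = paste0("trait", k))
  })
  harmonize(ds)
}

test_that("noise correlation is near zero for disjoint cohorts", {
  h <- make_noise_table(4000, diag(3), seed = 1)
  set.seed(2)
  selp <- stats::setNames(runif(4000), h$snp_ids)
  R <- estimate_noise_correlation(h, selection_pval = selp)
  m <- attr(R, "n_null_snps")
  expect_true(all(abs(R[upper.tri(R)]) < 3 / sqrt(m)))
})

test_that("overlap correlation is recovered with selection p-values and by de-truncation", {
  Rtrue <- diag(3)
  Rtrue[1, 2] <- Rtrue[2, 1] <- 0.3 # overlap 0.5 x phenotypic correlation 0.6
  h <- make_noise_table(12000, Rtrue, seed = 2)
  set.seed(3)
  selp <- runif(12000)
  names(selp) <- h$snp_ids
  R1 <- estimate_noise_correlation(h, selection_pval = selp)
  expect_lt(abs(R1[1, 2] - 0.3), 0.05)
  expect_lt(abs(R1[1, 3]), 0.05)
  # fallback mode: pairwise box truncation with analytic de-attenuation
  R2 <- estimate_noise_correlation(h)
  expect_lt(abs(R2[1, 2] - 0.3), 0.15)
})

test_that("noise correlation is invariant to SNP order", {
  h <- make_noise_table(2000, diag(2), seed = 4)
  R1 <- estimate_noise_correlation(h)
  perm <- sample(length(h$snp_ids))
  h2 <- h
  h2$snp_ids <- h$snp_ids[perm]
  h2$beta <- h$beta[perm, ]
  h2$se <- h$se[perm, ]
  R2 <- estimate_noise_correlation(h2)
  expect_equal(R1, R2, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the multivariable fit solves an exact linear system", {
  set.seed(10)
  g <- matrix(rnorm(100, 0, 0.1), 50, 2)
  Gam <- 0.2 * g[, 1] + 0.5 * g[, 2]
  inp <- mvmr_input(g, matrix(1e-7, 50, 2), Gam, rep(1e-7, 50))
  fit <- grapple_fit(inp, loss = robust_loss("l2"), overdispersion = FALSE)
  expect_equal(unname(fit$beta), c(0.2, 0.5), tolerance = 1e-6)
})

test_that("the WLS limit matches a direct weighted least-squares solve", {
  set.seed(11)
  g <- matrix(rnorm(200, 0, 0.1), 100, 2)
  Gam <- 0.3 * g[, 1] - 0.1 * g[, 2] + rnorm(100, 0, 0.02)
  sy <- runif(100, 0.01, 0.05)
  inp <- mvmr_input(g, matrix(1e-10, 100, 2), Gam, sy)
  fit <- grapple_fit(inp, loss = robust_loss("l2"), overdispersion = FALSE)
  expect_equal(unname(fit$beta), oracle_wls(g, Gam, sy), tolerance = 1e-8)
})

test_that("GRAPPLE with one exposure and identity R reproduces RAPS", {
  sim <- simulate_mr_summary(n_snps = 120, beta = 0.3, se_gamma = 0.007,
                             se_Gamma = 0.007, effect_sd = 0.02,
                             prop_invalid = 1, tau = 0.004, seed = 21)
  uni <- sim$input
  mv <- mvmr_input(matrix(uni$gamma_hat), matrix(uni$se_gamma),
                   uni$Gamma_hat, uni$se_Gamma)
  for (loss_name in c("l2", "huber")) {
    r <- mr_raps(uni, loss = robust_loss(loss_name))
    g <- grapple_fit(mv, loss = robust_loss(loss_name))
    expect_equal(unname(g$beta), r$beta, tolerance = 1e-8)
    expect_equal(g$tau2, r$tau2, tolerance = 1e-8)
  }
})

test_that("accounting for overlap removes bias that identity R leaves behind", {
  Rtrue <- matrix(0.3, 3, 3)
  diag(Rtrue) <- 1
  B <- Bid <- matrix(NA, 40, 2)
  cov_ok <- matrix(NA, 40, 2)
  for (r in 1:40) {
    sim <- simulate_mr_summary(n_snps = 300, beta = c(0.3, -0.2),
                               se_gamma = 1 / sqrt(20000),
                               se_Gamma = 1 / sqrt(20000), prop_nonnull = 1,
                               effect_sd = 0.02, prop_invalid = 1, tau = 0.003,
                               R_noise = Rtrue, seed = 1500 + r)
    fit <- grapple_fit(sim$input)
    B[r, ] <- fit$beta
    cov_ok[r, ] <- fit$ci95[, 1] <= c(0.3, -0.2) & c(0.3, -0.2) <= fit$ci95[, 2]
    inp_id <- mvmr_input(sim$input$gamma_hat, sim$input$se_gamma,
                         sim$input$Gamma_hat, sim$input$se_Gamma, R = diag(3))
    Bid[r, ] <- grapple_fit(inp_id)$beta
  }
  expect_lt(max(abs(colMeans(B) - c(0.3, -0.2))), 0.03)
  expect_true(all(abs(colMeans(Bid) - c(0.3, -0.2)) >
                    abs(colMeans(B) - c(0.3, -0.2))))
  expect_gte(mean(cov_ok), 0.85)
})

test_that("permuting exposures permutes the estimate consistently", {
  sim <- simulate_mr_summary(n_snps = 150, beta = c(0.3, -0.2),
                             se_gamma = 0.007, se_Gamma = 0.007,
                             effect_sd = 0.02, seed = 33)
  inp <- sim$input
  fit <- grapple_fit(inp)
  perm <- mvmr_input(inp$gamma_hat[, 2:1], inp$se_gamma[, 2:1],
                     inp$Gamma_hat, inp$se_Gamma, R = inp$R[c(1, 3, 2), c(1, 3, 2)])
  fit_p <- grapple_fit(perm)
  expect_equal(unname(fit_p$beta), unname(fit$beta[2:1]), tolerance = 1e-8)
  expect_equal(unname(fit_p$vcov), unname(fit$vcov[2:1, 2:1]), tolerance = 1e-6)
  # sandwich covariance is PSD
  expect_gte(min(eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("near-collinear exposures are rejected with the offending pair named", {
  set.seed(12)
  g1 <- rnorm(50, 0, 0.1)
  g <- cbind(a_trait = g1, b_trait = g1 * (1 + 1e-9))
  inp <- mvmr_input(g, matrix(0.01, 50, 2), rnorm(50), rep(0.1, 50))
  expect_error(grapple_fit(inp), "a_trait.*b_trait|collinear")
})

test_that("modified Q separates strong, collinear and null conditional instruments", {
  # strong independent exposures: Q/df well above 1
  sim <- simulate_mr_summary(n_snps = 100, beta = c(0.3, -0.2),
                             se_gamma = 0.002, se_Gamma = 0.007,
                             effect_sd = 0.02, seed = 41)
  q <- modified_q(sim$input)
  expect_true(all(q$Q / q$df > 3))
  expect_false(any(q$weak))
  expect_equal(q$df, rep(100 - 2 + 1, 2))

  # exposure collinear with the other: tiny conditional signal
  set.seed(42)
  g1 <- rnorm(80, 0, 0.05)
  g <- cbind(g1, 0.7 * g1 + rnorm(80, 0, 1e-4))
  inp <- mvmr_input(g, matrix(0.005, 80, 2), rnorm(80, 0, 0.05), rep(0.05, 80))
  qc <- modified_q(inp)
  expect_true(all(qc$weak))

  # null case: gamma_k pure noise given the others -> Q/df near 1
  # true gb is an exact multiple of true ga, so conditionally on the other
  # exposure gb carries measurement error only
  ratios <- numeric(30)
  for (r in 1:30) {
    set.seed(4300 + r)
    ga_t <- rnorm(100, 0, 0.05)
    ga <- ga_t + rnorm(100, 0, 0.004)
    gb <- 0.5 * ga_t + rnorm(100, 0, 0.004)
    inp2 <- mvmr_input(cbind(ga, gb), matrix(0.004, 100, 2),
                       rnorm(100, 0, 0.05), rep(0.05, 100))
    qn <- modified_q(inp2)
    ratios[r] <- qn$Q[2] / qn$df[2]
  }
  expect_lt(abs(mean(ratios) - 1), 0.25)
})
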