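test_that("robust losses have correct quadrature moments", {
  l2 <- robust_loss("l2")
  expect_identical(l2$delta, 1)
  expect_identical(l2$epsilon, 1)
  hub <- robust_loss("huber", 1.345)
  # closed form: E[psi(Z) Z] = 2 Phi(k) - 1 for the Huber score
  expect_equal(hub$delta, 2 * pnorm(1.345) - 1, tolerance = 1e-10)
  # psi is odd
  z <- seq(-5, 5, by = 0.5)
  for (loss in list(hub, robust_loss("tukey"))) {
    expect_equal(loss$psi(-z), -loss$psi(z))
    expect_lt(loss$delta, 1)
    expect_gt(loss$delta, 0)
  }
})

test_that("IVW reproduces hand-computed combinations", {
  inp <- mr_input(c(1, 1), c(1e-8, 1e-8), c(0.5, 0.3), c(0.1, 0.1))
  fit <- mr_ivw(inp)
  expect_equal(fit$beta, 0.4)
  expect_equal(fit$se_fixed, 0.1 / sqrt(2), tolerance = 1e-12)
  inp1 <- mr_input(c(2, 2), c(1e-8, 1e-8), c(1, 1), c(0.1, 0.1))
  expect_equal(mr_ivw(inp1)$beta, 0.5)
})

test_that("IVW is calibrated on valid instruments", {
  covered <- logical(120)
  ests <- numeric(120)
  for (r in 1:120) {
    sim <- simulate_mr_summary(n_snps = 100, beta = 0.3, se_gamma = 1e-6,
                               se_Gamma = 0.01, effect_sd = 0.1, seed = 600 + r)
    fit <- mr_ivw(sim$input)
    ests[r] <- fit$beta
    covered[r] <- fit$ci95[1] <= 0.3 && 0.3 <= fit$ci95[2]
  }
  expect_lt(abs(mean(ests) - 0.3), 3 * sd(ests) / sqrt(120))
  expect_gte(mean(covered), 0.89)
  expect_lte(mean(covered), 0.99)
})

test_that("weighted median matches the weight-CDF oracle", {
  # equal weights on three ratios: the middle one
  inp <- mr_input(c(1, 1, 1), rep(0.01, 3), c(0.2, 0.3, 0.4), rep(0.1, 3))
  expect_equal(mr_weighted_median(inp, n_boot = 10, seed = 1)$beta, 0.3)
  # dominant weight pulls the estimate to its ratio
  g <- c(sqrt(0.98), sqrt(0.01), sqrt(0.01))
  inp2 <- mr_input(g, rep(0.01, 3), c(0.1, 0.3, 0.5) * g, rep(1, 3))
  fit2 <- mr_weighted_median(inp2, n_boot = 10, seed = 1)
  expect_equal(fit2$beta, oracle_weighted_median(c(0.1, 0.3, 0.5), c(0.98, 0.01, 0.01)),
               tolerance = 1e-12)
  # random instances agree with the oracle
  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    g <- rnorm(n, 0, 1) + sign(rnorm(n)) * 0.5
    G <- rnorm(n)
    sy <- runif(n, 0.5, 2)
    inp3 <- mr_input(g, rep(0.01, n), G, sy)
    expect_equal(mr_weighted_median(inp3, n_boot = 2, seed = 1)$beta,
                 oracle_weighted_median(G / g, g^2 / sy^2), tolerance = 1e-12)
  }
})

test_that("weighted median resists up to half pleiotropic weight", {
  est <- numeric(60)
  for (r in 1:60) {
    set.seed(700 + r)
    n <- 100
    g <- rnorm(n, 0.05, 0.01)
    valid <- runif(n) > 0.3 # ~30% of weight pleiotropic at ratio 1
    G_true <- ifelse(valid, 0.3 * g, 1.0 * g)
    inp <- mr_input(g, rep(1e-4, n), G_true + rnorm(n, 0, 0.004), rep(0.004, n))
    est[r] <- mr_weighted_median(inp, n_boot = 2, seed = r)$beta
  }
  expect_lt(abs(mean(est) - 0.3), 0.05)
})

test_that("RAPS solves the exact-fit fixed point", {
  g <- c(0.1, -0.2, 0.3, 0.15, -0.05)
  inp <- mr_input(g, rep(1e-6, 5), 0.3 * g, rep(1e-6, 5))
  fit <- mr_raps(inp, loss = robust_loss("l2"), overdispersion = FALSE)
  expect_equal(fit$beta, 0.3, tolerance = 1e-8)
  fit2 <- mr_raps(inp, loss = robust_loss("huber"))
  expect_equal(fit2$beta, 0.3, tolerance = 1e-8)
  expect_equal(fit2$tau2, 0)
})

test_that("RAPS equals the dense grid-search profile-likelihood maximizer", {
  set.seed(99)
  for (i in 1:10) {
    sim <- simulate_mr_summary(n_snps = 100, beta = runif(1, -1, 1),
                               se_gamma = runif(1, 0.01, 0.03),
                               se_Gamma = runif(1, 0.01, 0.05),
                               effect_sd = 0.1, seed = 800 + i)
    fit <- mr_raps(sim$input, loss = robust_loss("l2"), overdispersion = FALSE)
    expect_equal(fit$beta, oracle_profile_max(sim$input, lower = -3, upper = 3),
                 tolerance = 1e-4)
  }
})

test_that("RAPS with sigma_X = 0, squared loss and tau2 = 0 is fixed-effect IVW", {
  set.seed(17)
  g <- rnorm(50, 0, 0.1)
  G <- 0.4 * g + rnorm(50, 0, 0.02)
  inp <- mr_input(g, rep(1e-12, 50), G, runif(50, 0.01, 0.05))
  raps <- mr_raps(inp, loss = robust_loss("l2"), overdispersion = FALSE)
  ivw <- mr_ivw(inp)
  expect_equal(raps$beta, ivw$beta, tolerance = 1e-10)
})

test_that("RAPS recovers effect and overdispersion with Huber loss", {
  est <- tau2 <- covered <- numeric(60)
  for (r in 1:60) {
    sim <- simulate_mr_summary(n_snps = 200, beta = 0.3,
                               se_gamma = 1 / sqrt(20000),
                               se_Gamma = 1 / sqrt(20000), prop_nonnull = 1,
                               effect_sd = 0.02, prop_invalid = 1, tau = 0.005,
                               seed = 900 + r)
    fit <- mr_raps(sim$input, loss = robust_loss("huber"))
    est[r] <- fit$beta
    tau2[r] <- fit$tau2
    covered[r] <- fit$ci95[1] <= 0.3 && 0.3 <= fit$ci95[2]
  }
  expect_lt(abs(mean(est) - 0.3), 0.02)
  expect_lt(abs(mean(tau2) - 2.5e-5), 1.25e-5)
  expect_gte(mean(covered), 0.85)
})

test_that("estimators are scale- and sign-equivariant", {
  sim <- simulate_mr_summary(n_snps = 50, beta = 0.4, se_gamma = 0.02,
                             se_Gamma = 0.02, effect_sd = 0.05, seed = 55)
  inp <- sim$input
  c0 <- 2.5
  scaled <- mr_input(c0 * inp$gamma_hat, c0 * inp$se_gamma, inp$Gamma_hat,
                     inp$se_Gamma)
  negated <- mr_input(inp$gamma_hat, inp$se_gamma, -inp$Gamma_hat, inp$se_Gamma)
  for (fitter in list(function(x) mr_ivw(x)$beta,
                      function(x) mr_weighted_median(x, n_boot = 2, seed = 1)$beta,
                      function(x) mr_raps(x)$beta)) {
    expect_equal(fitter(scaled), fitter(inp) / c0, tolerance = 1e-6)
    expect_equal(fitter(negated), -fitter(inp), tolerance = 1e-6)
  }
})

test_that("IVW, weighted median and RAPS agree on valid instruments", {
  sim <- simulate_mr_summary(n_snps = 150, beta = 0.3, se_gamma = 0.005,
                             se_Gamma = 0.007, effect_sd = 0.03, seed = 31)
  ivw <- mr_ivw(sim$input)
  wm <- mr_weighted_median(sim$input, seed = 2)
  raps <- mr_raps(sim$input)
  joint_se <- function(a, b) sqrt(a$se^2 + b$se^2)
  expect_lt(abs(ivw$beta - raps$beta), 3 * joint_se(ivw, raps))
  expect_lt(abs(wm$beta - raps$beta), 3 * joint_se(wm, raps))
})

test_that("modified Cochran's Q matches hand arithmetic and the null", {
  g <- c(0.1, 0.2)
  exact <- mr_input(g, rep(1e-9, 2), 0.3 * g, rep(0.1, 2))
  q0 <- cochran_q(exact, 0.3)
  expect_equal(q0$Q, 0)
  expect_equal(q0$pval, 1)

  # standardized residuals (1, -1): Q = 2, df = 1
  inp <- mr_input(c(1, 1), rep(1e-9, 2), c(1, -1), c(1, 1))
  q2 <- cochran_q(inp, 0)
  expect_equal(q2$Q, 2)
  expect_equal(q2$df, 1)
  expect_equal(q2$pval, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-10)

  # null distribution: Q/df -> 1 and p uniform
  pv <- numeric(300)
  for (r in 1:300) {
    sim <- simulate_mr_summary(n_snps = 40, beta = 0.3, se_gamma = 0.01,
                               se_Gamma = 0.01, effect_sd = 0.05,
                               seed = 1200 + r)
    pv[r] <- cochran_q(sim$input, 0.3)$pval
  }
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("residual diagnostics flag planted pleiotropic outliers", {
  g <- rep(0.1, 30)
  inp_exact <- mr_input(g, rep(1e-9, 30), 0.3 * g, rep(0.05, 30))
  d0 <- residual_diagnostics(inp_exact, mr_raps(inp_exact), loo = FALSE)
  expect_true(all(abs(d0$table$residual) < 1e-6))
  expect_equal(length(d0$outliers), 0)

  set.seed(8)
  n <- 60
  g <- rnorm(n, 0.08, 0.02)
  G <- 0.3 * g + rnorm(n, 0, 0.005)
  G[1] <- G[1] + 50 * 0.005 # planted direct effect, 50 outcome SEs
  inp <- mr_input(g, rep(1e-4, n), G, rep(0.005, n))
  # squared loss: a single planted outlier pulls the fit, so leaving it
  # out must move the estimate toward the truth
  fit <- mr_raps(inp, loss = robust_loss("l2"), overdispersion = FALSE)
  d <- residual_diagnostics(inp, fit, loo = TRUE, loss = robust_loss("l2"))
  expect_true(inp$snp_id[1] %in% d$outliers)
  # removing the outlier moves the estimate toward the truth
  expect_lt(abs(d$loo_beta[1] - 0.3), abs(fit$beta - 0.3))
})

test_that("residuals are normally distributed for valid instruments", {
  shapiro_ok <- logical(50)
  for (r in 1:50) {
    sim <- simulate_mr_summary(n_snps = 80, beta = 0.3, se_gamma = 0.005,
                               se_Gamma = 0.01, effect_sd = 0.05,
                               seed = 1400 + r)
    fit <- mr_raps(sim$input, overdispersion = FALSE)
    d <- residual_diagnostics(sim$input, fit, loo = FALSE)
    shapiro_ok[r] <- shapiro.test(d$table$residual)$p.value > 0.01
  }
  expect_gte(mean(shapiro_ok), 0.9)
})
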