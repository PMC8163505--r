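---
title: "Methods: summary-data Mendelian randomization for lipoprotein subfractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-data Mendelian randomization for lipoprotein subfractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipomr)
```

# The scientific problem

Lipoprotein subfraction traits (particle concentrations, lipid contents and
mean diameters of VLDL/IDL/LDL/HDL subclasses, measured by NMR) are strongly
genetically entangled with the traditional lipid panel (TG, LDL-C, HDL-C,
ApoB, ApoA1). Deciding whether any subfraction carries an *independent*
causal signal for coronary artery disease therefore needs three things this
package provides end to end:

1. **Genetic-correlation screening** — bivariate LD-score regression to find
   subfraction traits whose genetic basis is not essentially identical to a
   traditional lipid (|rg| below a threshold, default 0.8);
2. **Robust summary-data MR** — univariable (RAPS: robust adjusted profile
   score) and multivariable (profile likelihood with a noise-correlation
   matrix for overlapping GWAS samples) causal-effect estimation from
   clumped instruments, under a three-sample design that avoids winner's
   curse;
3. **Marker discovery** — threshold filters locating SNPs associated with
   the HDL-size traits and the disease but not the LDL/ApoB pathway.

Everything runs at desk scale against a synthetic GWAS generator whose
ground truth is stored beside each dataset, so every stage of the pipeline
is testable without multi-gigabyte downloads.

# Models and estimators

## The measurement-error model behind RAPS

For each clumped instrument $j$ the observed summary statistics are modeled
as
$$\hat\Gamma_j \sim N(\beta\gamma_j + \alpha_j,\ \sigma_{Yj}^2), \qquad
  \hat\gamma_j \sim N(\gamma_j,\ \sigma_{Xj}^2), \qquad
  \alpha_j \sim N(0, \tau^2),$$
where $\beta$ is the causal effect of the exposure (per SD) on the outcome
(log-odds for disease outcomes), $\gamma_j$ the true instrument-exposure
association, and $\alpha_j$ balanced ("InSIDE-valid") pleiotropic direct
effects with overdispersion variance $\tau^2 \ge 0$.

Profiling out the nuisance $\gamma_j$ leaves the profile log-likelihood
$-\tfrac12\sum_j r_j^2/s_j^2$ with residual
$r_j = \hat\Gamma_j - \beta\hat\gamma_j$ and variance
$s_j^2 = \sigma_{Yj}^2 + \beta^2\sigma_{Xj}^2 + \tau^2$. Note there is no
$\log s_j^2$ term: the nuisance is maximized out, not integrated out. With a
robust score $\psi$ (Huber 1.345 by default; squared loss and Tukey biweight
available) the estimating equations are
$$\sum_j \Big[\psi(t_j)\frac{\hat\gamma_j}{s_j}
  + \psi(t_j)\,t_j\,\frac{\beta\sigma_{Xj}^2}{s_j^2}\Big] = 0,
  \qquad \sum_j \big[\psi(t_j)t_j - \delta_\psi\big] = 0,$$
with $t_j = r_j/s_j$ and $\delta_\psi = E[\psi(Z)Z]$ under $Z\sim N(0,1)$.
The second term of the $\beta$-equation matters: the residual $r_j$ is
correlated with $\hat\gamma_j$ through the shared measurement error, and
without this term the estimator is *attenuated* (in our recovery suite the
naive variant biases $\hat\beta$ from 0.30 to about 0.27 and drops CI
coverage to roughly 78%). With the term, the score has exactly mean zero at
the truth and, for squared loss, the solution coincides with the
profile-likelihood maximizer — the identity the test suite checks against a
dense grid search.

$\tau^2$ is constrained nonnegative: when the dispersion equation has no
root with $\tau^2 > 0$, it is fixed at 0 and $\beta$ re-solved. Standard
errors come from the sandwich covariance of the stacked estimating
equations (empirical middle matrix, numerically differentiated bread).
Multiple well-separated roots of the $\beta$-equation are reported via a
`multimodal` flag, never silently resolved; the root with the smallest
robust objective $\sum_j \rho(t_j)$ is returned.

## Multivariable MR with overlapping samples

With $K$ exposures and contrast $c(\beta) = (1, -\beta_1, \dots, -\beta_K)$,
the residual variance generalizes to
$s_j^2 = c(\beta)^\top D_j R D_j c(\beta) + \tau^2$, where $D_j$ is the
diagonal of per-SNP standard errors (outcome first) and $R$ the
noise-correlation matrix induced by overlapping GWAS cohorts
(analytically, overlap fraction times phenotypic correlation). The $K$
score equations mirror the univariable form with
$\partial s_j^2/\partial\beta_k$ in place of $2\beta\sigma_{Xj}^2$, and are
solved by damped Newton iteration with restarts; with $K = 1$ and
$R = I$ the fit reproduces the univariable estimator to $10^{-8}$.

**Estimating $R$ from null SNPs.** SNPs without genetic signal have z-scores
that are pure sampling noise, so their cross-trait correlation estimates
$R$. How the null set is chosen matters more than it looks:

* *Preferred (what the pipeline does):* null SNPs are those with p ≥ 0.5 in
  the sample-disjoint *selection* GWAS. Because that truncation is
  independent of the estimation datasets' noise, the plain Pearson
  correlation of their z-scores is unbiased.
* *Fallback (no selection data):* truncating on the table's own z-scores
  ($|z| \le 0.675$ for the pair) shrinks the sample correlation severely —
  a true 0.3 appears as roughly 0.045 — so each pairwise estimate is
  de-attenuated by numerically inverting the moment map
  $\rho \mapsto \mathrm{cor}(z_1, z_2 \mid |z_1|,|z_2| \le a)$ of the
  truncated bivariate normal (Gauss-Legendre quadrature + root finding).
  This is unbiased but has a roughly 5-10x larger standard error than the
  preferred mode; with fewer than a few tens of thousands of null SNPs its
  entries are noisy.

**Conditional instrument strength.** The per-exposure modified Cochran's Q
regresses each exposure's associations on the others' by error-weighted
least squares (weights $1/(\sigma_{Xkj}^2 + \hat\delta^\top
\Sigma_{X,-k,j}\hat\delta)$, refit to convergence); $Q_k$ near its
$\chi^2_{n-K+1}$ reference means exposure $k$ adds no independent
association signal — the situation the genetic-correlation screening exists
to prevent.

## LD-score regression

Univariate: regress $z_j^2$ on LD scores $\ell_j$; the slope times $M/N$
estimates $h^2$, the free intercept absorbs confounding inflation.
Bivariate: regress $z_{1j} z_{2j}$ on $\ell_j$; the slope recovers the
genetic covariance and the free cross-intercept absorbs
$\rho N_s / \sqrt{N_1 N_2}$ from sample overlap — which is why genetic
correlations from partially overlapping GWAS remain valid. Weights are
two-step (unweighted first pass, then heteroskedasticity weights
$1/(\ell_j(1 + N h^2 \ell_j/M)^2)$ and their bivariate analogue); the
standard error of $\hat r_g = \hat\rho_g/\sqrt{\hat h_1^2 \hat h_2^2}$
comes from a 200-block leave-one-block-out jackknife of the *whole*
functional, computed from per-block sufficient statistics with weights held
at their full-sample values. Negative $\hat h^2$ (possible by sampling
noise) propagates as a flagged missing rg, never clipped. The block count
drops to $\lfloor n/50\rfloor$ with a warning when fewer SNPs than blocks
are available.

Screening removes a trait when $|\hat r_g| > 0.8$ with any of TG, LDL-C,
HDL-C, ApoB, ApoA1 (strict inequality; 0.8 itself is kept). The absolute
value is a deliberate choice — a correlation of $-0.95$ indicates shared
genetic determination just as strongly — and can be switched off
(`absolute = FALSE`).

## Design and plumbing rules

* **Three-sample design:** the selection GWAS must share no samples with
  either estimation GWAS (winner's curse); exposure-outcome overlap is
  allowed only when the estimator models it ($R$ above). Overlap is tracked
  by dataset name tags and checked symmetrically; using one dataset in two
  roles counts as overlap.
* **Clumping:** candidates sorted by ascending p (ties broken by SNP id for
  reproducibility), selected greedily subject to $r^2 < 0.001$ within 10 Mb
  against all previously selected SNPs; genome-wide mode applies no p-value
  truncation. Pairs farther apart than the window, or in different panel
  blocks, count as independent.
* **Harmonization:** effects re-expressed per copy of the first dataset's
  effect allele; allele swaps negate the effect, strand complements are
  matched before comparison; A/T and G/C palindromic SNPs are dropped by
  default (strand flips are indistinguishable from swaps without reliable
  frequencies), or kept when every dataset's effect-allele frequency is
  outside [0.42, 0.58] and all agree on the minor allele. SNPs are matched
  by identifier, not position, because public summary datasets mix genome
  builds; positions are used only inside one dataset's clumping windows.
* **Multiplicity:** Benjamini-Hochberg at FDR 0.05 across the traits
  analyzed together (family composition is configuration, since reasonable
  analysts group univariable and multivariable tests differently);
  Bonferroni at FWER 0.05 for the genetic-correlation matrix flags.
* **p-value underflow:** extreme associations whose two-sided normal p
  underflows double precision are clamped to the smallest positive double
  rather than rejected.

# The synthetic generator

The generator works at the summary-statistic level — no individual
genotypes — because that is exactly the resolution at which the estimators
operate, and it makes every moment checkable in closed form:

* **LD panels:** contiguous AR(1) blocks ($r_{jk} = \rho^{|j-k|}$,
  cross-block correlation exactly 0), 5 kb SNP spacing, chromosomes of
  5,000 SNPs. `rho` may vary across blocks; `ldsc_sim_rho()` mixes
  near-equilibrium and strong-LD blocks so LD scores span ~1-19, the
  regressor spread LD-score regression needs for identification — a single
  homogeneous `rho` leaves the slope nearly unidentified.
* **Polygenic trait pairs:** per-SNP causal effects jointly normal with
  variance $h^2/M$ and correlation $r_g$; marginal z-scores are LD-smeared
  means plus block-correlated noise with cross-trait covariance
  `overlap_frac * pheno_cor`, so
  $E[z_{1j}z_{2j}] = \sqrt{N_1N_2}\,\rho_g \ell_j/M + \rho N_s/\sqrt{N_1N_2}$
  holds by construction.
* **Instrument sets:** spike-and-slab exposure effects, pleiotropy
  $\alpha_j \sim N(\mu_\alpha, \tau^2)$ on an invalid subset (InSIDE holds
  when $\mu_\alpha = 0$), observed statistics jointly normal with an
  explicit noise-correlation matrix.
* **Three-sample studies:** one shared truth, three cohorts' noise draws,
  random allele swaps and strand flips per dataset (recorded, so
  harmonization is checked against ground truth); alleles are drawn from
  non-palindromic pairs by default. Requesting selection-estimation overlap
  is refused, mirroring the design constraint. Binary outcomes are emulated
  on the log-odds scale with normal error — the same approximation the
  estimators make.

What the generator does *not* emulate: realistic allele-frequency spectra,
population stratification, case-control ascertainment, or LD mismatch
between the analysis panel and the GWAS populations. Green tests therefore
certify the statistical machinery under its stated model, not robustness to
those real-data complications.

# Study sizes and numerical choices

Simulation suites use desk-scale sizes chosen once: panels of M = 20,000
SNPs in 50-SNP blocks and cohorts of N = 20,000 for LD-score regression
recovery; 200-300 instruments for estimator recovery; M = 2,000-SNP panels
for the 500-replicate end-to-end null calibration; a 4,000-SNP panel with
N = 10,000 cohorts and selection p ≤ 1e-3 for the winner's-curse
demonstration (the curse grows with the share of noise-driven selections,
so the demonstration deliberately uses a permissive threshold on a
moderate cohort — with very large selection GWAS the same mechanism exists
but is smaller than estimator noise).

Numerical details worth knowing: loss moments $\delta_\psi, \epsilon_\psi$
are computed by adaptive Gaussian quadrature at loss construction (the
Huber kink degrades fixed-node Hermite rules); the univariable
$\beta$-equation is solved by a bracketing grid scan (expanded up to
$\pm 32$) refined by `uniroot` at tolerance $10^{-12}$; the dispersion
equation by bracketed root finding on $[0, \infty)$ with the boundary
handled explicitly; multivariable Newton steps are damped by halving and
restarted from five dispersed starting points; convergence is judged on a
scale-aware score norm so nearly-noiseless inputs (SEs of $10^{-7}$ and
below) behave. Exposure Gram matrices with condition number above $10^8$
abort with the offending trait pair named, which is the multicollinearity
failure mode the screening step exists to avoid.

# Known limitations

* LD-score regression here is the plain (unpartitioned) flavor with
  block-jackknife uncertainty; stratified/annotation models are out of
  scope.
* The weighted-median bootstrap resamples summary statistics from their
  estimated sampling distributions; with very few instruments its SE is
  optimistic.
* The de-truncation fallback for the noise-correlation matrix assumes
  bivariate normality of null z-scores and inflates noise; prefer supplying
  selection p-values.
* Real-data reproduction of the published lipoprotein-CAD analyses needs
  the original GWAS downloads wired into a `study_config()`; the package
  enforces the published design topology (which datasets may select,
  estimate, and serve as outcome) and ships the published thresholds as
  defaults, but no GWAS data.
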