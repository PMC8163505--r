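#' Robust loss functions for profile-score MR estimation
#'
#' Constructs a loss object used by [mr_raps()] and [grapple_fit()]. The
#' score function `psi = rho'` is applied to standardized residuals; the
#' moments `delta = E[psi(Z) Z]` and `epsilon = E[psi(Z)^2]` under
#' `Z ~ N(0,1)` are needed by the overdispersion estimating equation and
#' the sandwich variance, and are computed once at construction by
#' adaptive Gaussian quadrature (exact for the squared loss, where
#' `delta = 1` identically; for the Huber score the quadrature agrees with
#' the closed form `2 Phi(k) - 1` to machine precision).
#'
#' @param name `"l2"` (squared loss, non-robust), `"huber"`, or `"tukey"`
#'   (biweight, redescending).
#' @param tuning Tuning constant; defaults 1.345 (huber) and 4.685 (tukey),
#'   the standard 95%-efficiency choices.
#' @return Object of class `robust_loss`: list with `name`, `tuning`,
#'   functions `rho`, `psi`, `dpsi`, and moments `delta`, `epsilon`.
#' @export
robust_loss <- function(name = c("huber", "l2", "tukey"), tuning = NULL) {
  name <- match.arg(name)
  if (is.null(tuning)) tuning <- switch(name, l2 = Inf, huber = 1.345, tukey = 4.685)
  k <- tuning
  fns <- switch(name,
    l2 = list(
      rho = function(z) z^2 / 2,
      psi = function(z) z,
      dpsi = function(z) rep(1, length(z))),
    huber = list(
      rho = function(z) ifelse(abs(z) <= k, z^2 / 2, k * abs(z) - k^2 / 2),
      psi = function(z) pmax(-k, pmin(k, z)),
      dpsi = function(z) as.numeric(abs(z) <= k)),
    tukey = list(
      rho = function(z) ifelse(abs(z) <= k, k^2 / 6 * (1 - (1 - (z / k)^2)^3), k^2 / 6),
      psi = function(z) ifelse(abs(z) <= k, z * (1 - (z / k)^2)^2, 0),
      dpsi = function(z) ifelse(abs(z) <= k, (1 - (z / k)^2) * (1 - 5 * (z / k)^2), 0)))
  quad <- function(f) {
    stats::integrate(function(z) f(z) * stats::dnorm(z), -Inf, Inf,
                     rel.tol = 1e-12, subdivisions = 400L)$value
  }
  delta <- if (name == "l2") 1 else quad(function(z) fns$psi(z) * z)
  epsilon <- if (name == "l2") 1 else quad(function(z) fns$psi(z)^2)
  structure(list(name = name, tuning = tuning, rho = fns$rho, psi = fns$psi,
                 dpsi = fns$dpsi, delta = delta, epsilon = epsilon),
            class = "robust_loss")
}

#' @export
print.robust_loss <- function(x, ...) {
  cat(sprintf("robust loss '%s' (tuning %.4g): delta = %.6f, epsilon = %.6f\n",
              x$name, x$tuning, x$delta, x$epsilon))
  invisible(x)
}
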