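#' Coefficients of the base-model growth-rate quadratic
#'
#' For the base model (no RNA degradation), assuming all constraints are
#' active at the optimum, the determinant method reduces maximum growth to
#' the unique positive root of a quadratic in the rescaled growth rate
#' \eqn{\hat\mu = \mu / \bar k^{el}_R \cdot \omega_R/\omega_{AA}}:
#' \deqn{(\alpha + \beta(1 - x_{rP}))\hat\mu^2 + (\gamma + x_{rP})\hat\mu - 1 = 0,}
#' with
#' \deqn{\alpha = \bar k^{el}_R (n_{AF}/k^{cat}_{AF})(\omega_{AA}/\omega_R)^2,}
#' \deqn{\beta = \bar k^{el}_R [ (n_{IC}/k^{cat}_{IC})(\omega_{AA}/\omega_C)
#'   + (n_{EAA}/k^{cat}_{EAA} + n_{ENT}/k^{cat}_{ENT}
#'   + n_{RNAP}/\bar k^{el}_{RNAP}) (\omega_{AA}/\omega_{NT}) ]
#'   (\omega_{AA}/\omega_R),}
#' \deqn{\gamma = \bar k^{el}_R [ (n_{IC}/k^{cat}_{IC})(\omega_{AA}/\omega_C)
#'   + n_{EAA}/k^{cat}_{EAA} ] (\omega_{AA}/\omega_R).}
#' The classification quantity
#' \eqn{\varepsilon = (\alpha+\beta)/\beta^2 + \gamma/\beta - 1}
#' determines the monotonicity of \eqn{\hat\mu(x_{rP})}: decreasing for
#' \eqn{\varepsilon > 0}, constant for \eqn{\varepsilon = 0}, increasing for
#' \eqn{\varepsilon < 0}.
#'
#' @param params an `rba_params` object (base model).
#' @return an object of class `rba_quadratic`: list with `alpha`, `beta`,
#'   `gamma`, `epsilon`, and `mu_hat_scale` (`kel_bar_R * omega_AA /
#'   omega_R`, the factor converting \eqn{\hat\mu} to \eqn{\mu} in per
#'   hour).
#' @export
quadratic_coefficients <- function(params) {
  stopifnot(inherits(params, "rba_params"))
  kR <- kel_bar_R(params)
  rAA_R <- params$omega_AA / params$omega_R
  alpha <- kR * (params$n_AF / params$kcat_AF) * rAA_R^2
  beta <- kR * (
    (params$n_IC / params$kcat_IC) * (params$omega_AA / params$omega_C) +
      (params$n_EAA / params$kcat_EAA + params$n_ENT / params$kcat_ENT +
         params$n_RNAP / kel_bar_RNAP(params)) *
      (params$omega_AA / params$omega_NT)
  ) * rAA_R
  gamma <- kR * (
    (params$n_IC / params$kcat_IC) * (params$omega_AA / params$omega_C) +
      params$n_EAA / params$kcat_EAA
  ) * rAA_R
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         epsilon = (alpha + beta) / beta^2 + gamma / beta - 1,
         mu_hat_scale = kR * rAA_R,
         note = "carbon-unit mass used for the importer mass ratio"),
    class = "rba_quadratic"
  )
}

#' @export
print.rba_quadratic <- function(x, ...) {
  cat(sprintf("<rba_quadratic> alpha %.4g, beta %.4g, gamma %.4g, epsilon %.4g\n",
              x$alpha, x$beta, x$gamma, x$epsilon))
  cat(sprintf("  mu = mu_hat * %.6g per hour\n", x$mu_hat_scale))
  invisible(x)
}

# positive root of a*z^2 + b*z - 1 = 0 with a >= 0, b > 0, in the
# cancellation-free form 2/(b + sqrt(b^2 + 4a)) (valid as a -> 0)
.positive_root <- function(a, b) 2 / (b + sqrt(b^2 + 4 * a))

#' Analytic maximum growth rate of the base model
#'
#' Evaluates the positive root of the growth-rate quadratic (see
#' [quadratic_coefficients()]) at a given composition and rescales it to
#' per-hour units. Applies to the base model only; the extended
#' (degradation) model has no closed form and is handled by
#' [maximize_growth()].
#'
#' @param params an `rba_params` object.
#' @param x_rP ribosomal protein mass fraction (vectorized over [0, 1]).
#' @param drop_alpha set the small assembly-factor coefficient
#'   \eqn{\alpha} to zero (the customary approximation; default FALSE).
#' @return growth rate(s), per hour.
#' @export
#' @examples
#' analytic_mu_max(ecoli_fixture("glc"), 0.36)
analytic_mu_max <- function(params, x_rP, drop_alpha = FALSE) {
  if (any(x_rP < 0 | x_rP > 1)) stop("analytic_mu_max: x_rP must lie in [0, 1]")
  q <- quadratic_coefficients(params)
  a <- (if (drop_alpha) 0 else q$alpha) + q$beta * (1 - x_rP)
  b <- q$gamma + x_rP
  .positive_root(a, b) * q$mu_hat_scale
}

#' Monotonicity class of the base-model growth curve
#'
#' Maps the sign of \eqn{\varepsilon} to the behavior of \eqn{\mu(x_{rP})}:
#' `"decreasing"` (optimum at the RNA-only composition), `"increasing"`
#' (optimum at the protein-only composition), or `"constant"` within a
#' dead-band `|epsilon| < 1e-12`.
#'
#' @param params an `rba_params` object.
#' @return one of `"decreasing"`, `"constant"`, `"increasing"`.
#' @export
monotonicity_class <- function(params) {
  eps <- quadratic_coefficients(params)$epsilon
  if (abs(eps) < 1e-12) "constant" else if (eps > 0) "decreasing" else "increasing"
}

#' Determinant residual of the homogenized base-model system
#'
#' Assembles the 12 base-model constraints at growth rate `mu`, homogenizes
#' them into the square matrix `B = cbind(A, -rhs)` (all inequalities
#' treated as active), equilibrates rows and columns to unit max-abs
#' coefficient, and returns `det(B)`. At the analytic maximum growth rate
#' the determinant vanishes; away from it, it does not.
#'
#' @param params an `rba_params` object.
#' @param x_rP ribosomal protein mass fraction.
#' @param mu growth rate, per hour.
#' @return scalar determinant of the row-normalized 12 x 12 matrix.
#' @export
determinant_residual <- function(params, x_rP, mu) {
  comp <- derive_composition(params, x_rP)
  sys <- build_constraints(params, comp, mu, "base")
  B <- cbind(sys$A, `-rhs` = -sys$rhs)
  if (nrow(B) != ncol(B))
    stop("determinant_residual: homogenized matrix is not square ",
         "(wrong variant?)")
  for (pass in 1:2) {
    rsc <- apply(abs(B), 1, max)
    rsc[rsc == 0] <- 1
    B <- B / rsc
    csc <- apply(abs(B), 2, max)
    csc[csc == 0] <- 1
    B <- sweep(B, 2, csc, "/")
  }
  det(B)
}
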