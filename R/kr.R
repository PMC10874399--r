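#' Autocatalytic-loop upper bounds on growth rate (fixed allocations)
#'
#' With the ribosome allocations to ribosomal protein and to RNA polymerase
#' held fixed (the Kostinski–Reuveni setting), the rP synthesis loop and the
#' RNAP/rRNA synthesis loop each bound growth rate:
#' \deqn{\mu \le \bar k^{el}_R \phi_{rP} / n_{rP} = \gamma_{rP}\, \phi_{rP}/x_{rP},}
#' \deqn{\mu^2 \le \bar k^{el}_R \bar k^{el}_{RNAP} \phi_{RNAP} /
#'       (n_{rRNA} n_{RNAP}), \quad i.e.\quad
#'       \mu \le \gamma_{RNAP} \sqrt{\phi_{RNAP}/(1-x_{rP})},}
#' with \eqn{\gamma_{rP} = \bar k^{el}_R \omega_{AA}/\omega_R} and
#' \eqn{\gamma_{RNAP} = \sqrt{\bar k^{el}_R \bar k^{el}_{RNAP}
#' \omega_{NT}/(\omega_R n_{RNAP})}}. The first bound decreases and the
#' second increases in \eqn{x_{rP}}; at the endpoints the respective bound
#' is infinite (returned as `Inf`).
#'
#' @param params an `rba_params` object.
#' @param x_rP ribosomal protein mass fraction in [0, 1].
#' @param phi_rP,phi_RNAP fixed ribosome allocations in (0, 1].
#' @return an object of class `rba_kr_bounds`: list with `gamma_rP`,
#'   `gamma_RNAP`, `bound_rP`, `bound_RNAP` (per hour), and the inputs.
#' @export
kr_bounds <- function(params, x_rP, phi_rP, phi_RNAP) {
  stopifnot(inherits(params, "rba_params"))
  if (any(phi_rP <= 0 | phi_rP > 1) || any(phi_RNAP <= 0 | phi_RNAP > 1))
    stop("kr_bounds: allocations must lie in (0, 1]")
  if (any(x_rP < 0 | x_rP > 1)) stop("kr_bounds: x_rP must lie in [0, 1]")
  g_rP <- kel_bar_R(params) * params$omega_AA / params$omega_R
  g_RNAP <- sqrt(kel_bar_R(params) * kel_bar_RNAP(params) *
                   params$omega_NT / (params$omega_R * params$n_RNAP))
  structure(
    list(gamma_rP = g_rP, gamma_RNAP = g_RNAP,
         bound_rP = ifelse(x_rP == 0, Inf, g_rP * phi_rP / x_rP),
         bound_RNAP = ifelse(x_rP == 1, Inf,
                             g_RNAP * sqrt(phi_RNAP / (1 - x_rP))),
         x_rP = x_rP, phi_rP = phi_rP, phi_RNAP = phi_RNAP),
    class = "rba_kr_bounds"
  )
}

#' @export
print.rba_kr_bounds <- function(x, ...) {
  cat(sprintf("<rba_kr_bounds> gamma_rP %.4g, gamma_RNAP %.4g\n",
              x$gamma_rP, x$gamma_RNAP))
  cat(sprintf("  at x_rP %.4g: rP bound %.6g/h, RNAP bound %.6g/h\n",
              x$x_rP[1], x$bound_rP[1], x$bound_RNAP[1]))
  invisible(x)
}

#' Optimal composition under the two-loop bounds
#'
#' With both allocations fixed and positive, the decreasing rP bound and
#' the increasing RNAP bound intersect at a unique composition
#' \eqn{x^* \in (0, 1)}; the common bound value there is the maximum growth
#' rate permitted by the two loops. The intersection is found by bracketed
#' root finding on the difference of the two bounds.
#'
#' @param params an `rba_params` object.
#' @param phi_rP,phi_RNAP fixed ribosome allocations in (0, 1].
#' @param tol root-finding tolerance on `x`.
#' @return list with `x_star` and `mu_star` (per hour).
#' @export
kr_optimal_composition <- function(params, phi_rP, phi_RNAP, tol = 1e-12) {
  f <- function(x) {
    b <- kr_bounds(params, x, phi_rP, phi_RNAP)
    b$bound_rP - b$bound_RNAP
  }
  eps <- 1e-12
  lo <- eps
  hi <- 1 - eps
  if (!(f(lo) > 0 && f(hi) < 0))
    stop("kr_optimal_composition: no sign change in bracket ",
         "(allocations must be positive)")
  x_star <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  list(x_star = x_star,
       mu_star = kr_bounds(params, x_star, phi_rP, phi_RNAP)$bound_rP)
}

#' Check a growth solution against the two-loop bounds
#'
#' Evaluates the bounds at the solution's own realized allocations; any
#' feasible solution of the full model must respect both (the bounds are
#' relaxations of the full constraint set).
#'
#' @param sol an `rba_solution` with positive allocations to rP and RNAP.
#' @param tol slack tolerance, per hour.
#' @return TRUE (invisibly) if `mu` respects both bounds, otherwise error.
#' @export
check_kr_bounds <- function(sol, tol = 1e-9) {
  stopifnot(inherits(sol, "rba_solution"))
  phi_rP <- sol$phi[["rP"]]
  phi_RNAP <- sol$phi[["RNAP"]]
  if (phi_rP <= 0 || phi_RNAP <= 0)
    stop("check_kr_bounds: solution has zero allocation to rP or RNAP")
  b <- kr_bounds(sol$params, sol$comp$x_rP, phi_rP, phi_RNAP)
  if (sol$mu > b$bound_rP + tol || sol$mu > b$bound_RNAP + tol)
    stop(sprintf("check_kr_bounds: mu %.9g exceeds bounds (rP %.9g, RNAP %.9g)",
                 sol$mu, b$bound_rP, b$bound_RNAP))
  invisible(TRUE)
}
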