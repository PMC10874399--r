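# Row/column scaling of a constraint system for numerical work: rows are
# rescaled to unit max-abs coefficient (the rhs follows), then columns are
# rescaled to unit max-abs so fluxes spanning ~6 orders of magnitude do not
# ill-condition the solves.
.scaled_system <- function(sys) {
  A <- sys$A
  rhs <- sys$rhs
  rsc <- apply(abs(A), 1, max)
  rsc[rsc == 0] <- 1
  A <- A / rsc
  rhs <- rhs / rsc
  csc <- apply(abs(A), 2, max)
  csc[csc == 0] <- 1
  A <- sweep(A, 2, csc, "/")
  list(A = A, rhs = rhs, sign = sys$sign, col_scale = csc)
}

#' Feasibility of a constraint system at its growth rate
#'
#' Tests whether any non-negative flux vector satisfies the system, by
#' solving a minimum-norm quadratic program over the (row- and
#' column-scaled) polytope: the dual active-set method either returns a
#' feasible point or proves the constraints inconsistent. The witness is
#' the minimum-norm feasible point in the scaled coordinates.
#'
#' @param sys an `rba_constraints` object.
#' @param tol feasibility tolerance on scaled rows for the witness check.
#' @return list with `feasible` (logical) and, if feasible, `witness`
#'   (named flux vector).
#' @export
is_feasible <- function(sys, tol = 1e-9) {
  stopifnot(inherits(sys, "rba_constraints"))
  s <- .scaled_system(sys)
  eq <- s$sign == "eq"
  nvar <- ncol(s$A)
  # constraints for solve.QP: equalities first, then >= rows, then x >= 0
  Amat <- t(rbind(s$A[eq, , drop = FALSE], s$A[!eq, , drop = FALSE],
                  diag(nvar)))
  bvec <- c(s$rhs[eq], s$rhs[!eq], rep(0, nvar))
  ans <- tryCatch(
    quadprog::solve.QP(Dmat = diag(nvar), dvec = rep(0, nvar),
                       Amat = Amat, bvec = bvec, meq = sum(eq)),
    error = function(e) e
  )
  if (inherits(ans, "error")) {
    if (grepl("inconsistent", conditionMessage(ans)))
      return(list(feasible = FALSE, witness = NULL))
    stop("is_feasible: solver failure: ", conditionMessage(ans))
  }
  y <- ans$solution
  y[y < 0 & y > -tol] <- 0
  resid <- drop(s$A %*% y) - s$rhs
  ok <- all(abs(resid[eq]) <= tol) && all(resid[!eq] >= -tol) && all(y >= -tol)
  if (!ok) return(list(feasible = FALSE, witness = NULL))
  x <- y / s$col_scale
  list(feasible = TRUE,
       witness = stats::setNames(as.numeric(x), colnames(sys$A)))
}

#' Assemble a growth solution from a flux witness
#'
#' @param sys an `rba_constraints` object.
#' @param fluxes named flux vector feasible for `sys`.
#' @param active_tol tolerance (scaled rows) for flagging active rows.
#' @return an object of class `rba_solution`: `mu`, `fluxes`,
#'   `concentrations`, `phi` (ribosome allocations), `active_rows`,
#'   `variant`, plus `params` and `comp`.
#' @export
as_growth_solution <- function(sys, fluxes, active_tol = 1e-7) {
  s <- .scaled_system(sys)
  resid <- drop(s$A %*% (fluxes * s$col_scale)) - s$rhs
  active <- names(which(abs(resid) <= active_tol))
  structure(
    list(mu = sys$mu,
         fluxes = fluxes,
         concentrations = concentrations_from_fluxes(sys, fluxes),
         phi = allocations(fluxes, sys$mu, sys$params, sys$comp, sys$variant),
         active_rows = active,
         variant = sys$variant,
         params = sys$params, comp = sys$comp),
    class = "rba_solution"
  )
}

#' @export
print.rba_solution <- function(x, ...) {
  cat(sprintf("<rba_solution> %s model, mu = %.6g/h, x_rP = %.4g\n",
              x$variant, x$mu, x$comp$x_rP))
  cat("  active rows:", paste(x$active_rows, collapse = ", "), "\n")
  invisible(x)
}

#' Hard upper bound on the growth rate bracket
#'
#' A provable ceiling on feasible growth, taken as the minimum over the
#' model's autocatalytic loops: the assembly-factor loop
#' (`mu^2 <= kel_bar_R * kcat_AF / n_AF`, valid at every composition), the
#' ribosomal-protein loop (`mu <= kel_bar_R / n_rP`, for `x_rP > 0`), and
#' the RNA-polymerase/rRNA loop
#' (`mu^2 <= kel_bar_R * kel_bar_RNAP / (n_rRNA * n_RNAP)`, for
#' `x_rP < 1`). Each follows from a capacity constraint chained with a
#' stoichiometric one, so every feasible growth rate lies below it.
#'
#' @param params an `rba_params` object.
#' @param comp optional `rba_composition`; if supplied, the
#'   composition-dependent loop ceilings sharpen the bound.
#' @return growth rate, per hour.
#' @export
mu_upper_bound <- function(params, comp = NULL) {
  ub <- sqrt(kel_bar_R(params) * params$kcat_AF / params$n_AF)
  if (!is.null(comp)) {
    n_rP_eff <- (1 - params$rp_import_fraction) * comp$n_rP
    if (n_rP_eff > 0)
      ub <- min(ub, kel_bar_R(params) / n_rP_eff)
    if (comp$n_rRNA > 0)
      ub <- min(ub, sqrt(kel_bar_R(params) * kel_bar_RNAP(params) /
                           (comp$n_rRNA * params$n_RNAP)))
  }
  ub
}

#' Maximum growth rate at a fixed ribosome composition
#'
#' Bisects on the growth rate: each candidate `mu` instantiates the
#' constraint system and tests linear feasibility; the supremum of feasible
#' growth rates is bracketed to within `tol`. The lower bracket is 0 and
#' the upper bracket is the autocatalytic-loop ceiling [mu_upper_bound()].
#'
#' @param params an `rba_params` object.
#' @param x_rP ribosomal protein mass fraction in [0, 1].
#' @param variant `"base"` or `"extended"`.
#' @param tol absolute bisection tolerance on `mu`, per hour.
#' @param rtol optional relative tolerance: bisection also stops only once
#'   the bracket is narrower than `rtol` times the current lower bound
#'   (default 0, i.e. absolute tolerance only).
#' @param accumulation_mode `"allow"` or `"forbid"` (see
#'   [build_constraints()]).
#' @return an `rba_solution` at the highest feasible growth rate found.
#' @export
#' @examples
#' sol <- maximize_growth(ecoli_fixture("glc"), x_rP = 0.36)
#' sol$mu
maximize_growth <- function(params, x_rP, variant = c("base", "extended"),
                            tol = 1e-6, rtol = 0,
                            accumulation_mode = c("allow", "forbid")) {
  variant <- match.arg(variant)
  accumulation_mode <- match.arg(accumulation_mode)
  if (tol <= 0) stop("maximize_growth: tol must be positive")
  comp <- derive_composition(params, x_rP)
  sys_at <- function(mu) build_constraints(params, comp, mu, variant,
                                           accumulation_mode)
  hi <- mu_upper_bound(params, comp) * (1 + 1e-9)
  lo <- 0
  f_lo <- NULL
  # seed the bracket: the model is feasible for small mu unless degenerate
  probe <- is_feasible(sys_at(tol))
  if (!probe$feasible)
    stop("maximize_growth: infeasible even as mu -> 0+ ",
         "(degenerate parameters)")
  lo <- tol
  f_lo <- probe
  while (hi - lo > min(tol, if (rtol > 0) rtol * lo else tol)) {
    mid <- (lo + hi) / 2
    f <- is_feasible(sys_at(mid))
    if (f$feasible) {
      lo <- mid
      f_lo <- f
    } else {
      hi <- mid
    }
  }
  as_growth_solution(sys_at(lo), f_lo$witness)
}

#' Sweep the composition grid and maximize growth at each point
#'
#' @param params an `rba_params` object.
#' @param grid sorted vector of ribosomal protein fractions in [0, 1].
#' @param variant `"base"` or `"extended"`.
#' @param tol bisection tolerance passed to [maximize_growth()].
#' @param keep_solutions keep the per-point `rba_solution` objects (default
#'   TRUE; disable to save memory in long pipelines).
#' @return an object of class `rba_sweep`: data frame `table` with columns
#'   `x_rP`, `mu_max`, `status`; `argmax` (x_rP of the grid maximum),
#'   `mu_at_argmax`; `interior` flag (TRUE iff the maximum beats both
#'   endpoints by more than `tol`); `solutions` (list, if kept);
#'   `variant`; `condition` label.
#' @export
sweep_composition <- function(params, grid = seq(0, 1, by = 0.01),
                              variant = c("base", "extended"),
                              tol = 1e-6, keep_solutions = TRUE) {
  variant <- match.arg(variant)
  if (any(grid < 0 | grid > 1)) stop("sweep_composition: grid must lie in [0, 1]")
  if (is.unsorted(grid)) stop("sweep_composition: grid must be sorted")
  mu <- rep(NA_real_, length(grid))
  status <- rep("ok", length(grid))
  sols <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    res <- tryCatch(maximize_growth(params, grid[i], variant, tol),
                    error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
      mu[i] <- 0
    } else {
      mu[i] <- res$mu
      if (keep_solutions) sols[[i]] <- res
    }
  }
  imax <- which.max(mu)
  interior <- imax != 1L && imax != length(grid) &&
    mu[imax] > max(mu[1], mu[length(grid)]) + tol
  structure(
    list(table = data.frame(x_rP = grid, mu_max = mu, status = status),
         argmax = grid[imax], mu_at_argmax = mu[imax],
         interior = interior,
         solutions = if (keep_solutions) sols,
         variant = variant, condition = params$condition_label),
    class = "rba_sweep"
  )
}

#' @export
print.rba_sweep <- function(x, ...) {
  cat(sprintf("<rba_sweep> %s model, %d grid points%s\n", x$variant,
              nrow(x$table),
              if (nzchar(x$condition)) paste0(", condition ", x$condition) else ""))
  cat(sprintf("  argmax x_rP = %.4g (mu = %.6g/h, %s optimum)\n",
              x$argmax, x$mu_at_argmax,
              if (x$interior) "interior" else "endpoint"))
  invisible(x)
}

#' Sanity checks for a growth solution
#'
#' Verifies non-negative fluxes and concentrations, the dry-mass
#' normalization `t(omega) %*% c = 1`, and the allocation budget
#' `sum(phi) <= 1`, at the stated tolerance.
#'
#' @param sol an `rba_solution` object.
#' @param tol absolute tolerance.
#' @return TRUE (invisibly) if all checks pass, otherwise an error.
#' @export
check_solution <- function(sol, tol = 1e-9) {
  stopifnot(inherits(sol, "rba_solution"))
  if (any(sol$fluxes < -tol)) stop("check_solution: negative flux")
  if (any(sol$concentrations < -tol)) stop("check_solution: negative concentration")
  w <- omega_species(sol$params, sol$comp, sol$variant)
  m <- sum(w * sol$concentrations[names(w)])
  if (abs(m - 1) > tol)
    stop(sprintf("check_solution: dry mass %.12g != 1", m))
  if (sum(sol$phi) > 1 + tol)
    stop(sprintf("check_solution: allocations sum to %.12g > 1", sum(sol$phi)))
  invisible(TRUE)
}
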