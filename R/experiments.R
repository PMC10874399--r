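#' RNA to protein mass ratio of a growth solution
#'
#' Total RNA mass per gram dry weight (rRNA inside ribosomes plus any free
#' rRNA) over total protein mass (all enzymes, ribosomal protein inside
#' ribosomes, and any free rP).
#'
#' @param sol an `rba_solution` object.
#' @return dimensionless mass ratio.
#' @export
rna_protein_ratio <- function(sol) {
  stopifnot(inherits(sol, "rba_solution"))
  p <- sol$params
  comp <- sol$comp
  cv <- sol$concentrations
  enz <- intersect(c("IC", "EAA", "ENT", "RNAP", "RNase", "AF"), names(cv))
  nlen <- c(IC = p$n_IC, EAA = p$n_EAA, ENT = p$n_ENT, RNAP = p$n_RNAP,
            RNase = p$n_RNase, AF = p$n_AF)
  rna <- p$omega_NT * comp$n_rRNA * (cv[["R"]] + cv[["rRNA"]])
  prot <- p$omega_AA * (sum(nlen[enz] * cv[enz]) +
                          comp$n_rP * (cv[["R"]] + cv[["rP"]]))
  if (prot <= 0) stop("rna_protein_ratio: zero protein mass")
  as.numeric(rna / prot)
}

#' RNAP flux branches across a growth-rate grid
#'
#' For each growth rate in `mu_grid`, enumerates the extreme solutions of
#' the constraint system and classifies each by its accumulation branch
#' (see [classify_branch()]). Below the maximum growth rate the transcription
#' flux `v_RNAP` splits into branches — excess rRNA, excess ribosomes, and
#' the no-accumulation solution — that converge at the maximum.
#'
#' @param params an `rba_params` object.
#' @param x_rP ribosomal protein mass fraction.
#' @param mu_grid vector of growth rates within (0, mu_max].
#' @param variant `"base"` or `"extended"`.
#' @return data frame with columns `mu`, `vertex`, `v_RNAP`, `branch`,
#'   `active_rows` (errors per grid point are recorded in an attribute
#'   `failures`, not fatal).
#' @export
rnap_flux_branches <- function(params, x_rP, mu_grid,
                               variant = c("base", "extended")) {
  variant <- match.arg(variant)
  out <- list()
  failures <- character()
  for (mu in mu_grid) {
    vx <- tryCatch(enumerate_extreme_solutions(params, x_rP, mu, variant),
                   error = function(e) e)
    if (inherits(vx, "error")) {
      failures <- c(failures, sprintf("mu=%.6g: %s", mu, conditionMessage(vx)))
      next
    }
    tab <- vertices_as_table(vx)
    out[[length(out) + 1L]] <-
      tab[, c("mu", "vertex", "v_RNAP", "branch", "active_rows")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "failures") <- failures
  res
}

#' Fraction of synthesized rRNA that is degraded
#'
#' Ratio of the RNase flux to the RNAP flux of an extended-model solution:
#' the share of transcribed rRNA that is broken down again rather than
#' assembled into ribosomes.
#'
#' @param sol an `rba_solution` from the extended model with `v_RNAP > 0`.
#' @return scalar in [0, 1).
#' @export
degraded_fraction <- function(sol) {
  stopifnot(inherits(sol, "rba_solution"))
  if (sol$variant != "extended")
    stop("degraded_fraction: undefined for the base model (no RNase)")
  if (sol$fluxes[["v_RNAP"]] <= 0)
    stop("degraded_fraction: v_RNAP must be positive")
  as.numeric(sol$fluxes[["v_RNase"]] / sol$fluxes[["v_RNAP"]])
}

#' Calibrate the maximal degradation rate to a target optimal composition
#'
#' Finds the `kdeg_max` for which the composition sweep of the extended
#' model attains its maximum at `target_x` (within grid resolution). The
#' sweep argmax is non-decreasing in `kdeg_max` (more degradation pressure
#' favors protein), so a log-spaced scan brackets the target and bisection
#' refines it.
#'
#' @param params an `rba_params` object with a `"constant"` or `"hill"`
#'   degradation scenario (its `K`, `n_hill` are kept; `kdeg_max` is the
#'   calibration variable).
#' @param target_x target optimal composition in (0, 1).
#' @param grid composition grid for the verification sweeps.
#' @param bounds log-search bounds on `kdeg_max`, per hour.
#' @param tol bisection tolerance passed to the sweeps.
#' @param max_iter bisection iteration cap.
#' @return list with `kdeg_max` (calibrated value), `sweep` (the verifying
#'   [sweep_composition()] result at that value), and `iterations`.
#' @export
calibrate_kdeg_max <- function(params, target_x = 0.36,
                               grid = seq(0, 1, by = 0.01),
                               bounds = c(1e-2, 1e4), tol = 1e-6,
                               max_iter = 40) {
  if (target_x <= 0 || target_x >= 1)
    stop("calibrate_kdeg_max: target_x must lie in (0, 1)")
  if (params$degradation$scenario == "none")
    stop("calibrate_kdeg_max: degradation scenario must be 'constant' or 'hill'")
  argmax_at <- function(kd) {
    p <- params
    p$degradation$kdeg_max <- kd
    sweep_composition(p, grid, "extended", tol, keep_solutions = FALSE)
  }
  step <- max(diff(grid))
  lo <- bounds[1]
  hi <- bounds[2]
  s_lo <- argmax_at(lo)
  s_hi <- argmax_at(hi)
  if (s_lo$argmax > target_x + step / 2 || s_hi$argmax < target_x - step / 2)
    stop(sprintf(paste0("calibrate_kdeg_max: target %.3g unreachable in bounds ",
                        "(argmax %.3g at kdeg_max %.3g, %.3g at %.3g)"),
                 target_x, s_lo$argmax, lo, s_hi$argmax, hi))
  it <- 0L
  best <- NULL
  while (it < max_iter) {
    it <- it + 1L
    mid <- sqrt(lo * hi)
    s_mid <- argmax_at(mid)
    if (abs(s_mid$argmax - target_x) <= step / 2) {
      best <- list(kdeg_max = mid, sweep = s_mid, iterations = it)
      break
    }
    if (s_mid$argmax < target_x) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-3) {
      best <- list(kdeg_max = mid, sweep = s_mid, iterations = it)
      break
    }
  }
  if (is.null(best))
    stop("calibrate_kdeg_max: did not converge within iteration cap")
  best
}

#' Summary panel across the packaged growth conditions
#'
#' Runs [maximize_growth()] (and optionally a full sweep) for each
#' condition and collects a tidy summary: maximum growth rate at the given
#' composition, the sweep argmax, the RNA/protein ratio, and (extended
#' model) the degraded-rRNA fraction.
#'
#' @param conditions character vector of condition labels
#'   (default [ecoli_conditions()]).
#' @param x_rP composition at which per-condition optima are computed.
#' @param variant `"base"` or `"extended"`.
#' @param sweep also run a composition sweep per condition (slower).
#' @param grid sweep grid (used if `sweep = TRUE`).
#' @param tol bisection tolerance.
#' @param params_fun function mapping a condition label to an `rba_params`
#'   (default [ecoli_fixture()]); override to run variants.
#' @return an object of class `rba_panel`: `summary` data frame plus lists
#'   of the per-condition solutions and sweeps.
#' @export
condition_panel <- function(conditions = ecoli_conditions(), x_rP = 0.36,
                            variant = c("base", "extended"), sweep = FALSE,
                            grid = seq(0, 1, by = 0.01), tol = 1e-6,
                            params_fun = ecoli_fixture) {
  variant <- match.arg(variant)
  sols <- list()
  sweeps <- list()
  rows <- list()
  for (cond in conditions) {
    p <- params_fun(cond)
    sol <- maximize_growth(p, x_rP, variant, tol)
    sols[[cond]] <- sol
    sw <- if (sweep) sweep_composition(p, grid, variant, tol,
                                       keep_solutions = FALSE)
    sweeps[[cond]] <- sw
    rows[[cond]] <- data.frame(
      condition = cond, x_rP = x_rP, mu_max = sol$mu,
      rna_protein = rna_protein_ratio(sol),
      degraded_fraction = if (variant == "extended")
        degraded_fraction(sol) else NA_real_,
      argmax = if (sweep) sw$argmax else NA_real_,
      mu_at_argmax = if (sweep) sw$mu_at_argmax else NA_real_
    )
  }
  structure(
    list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         solutions = sols, sweeps = sweeps, variant = variant),
    class = "rba_panel"
  )
}

#' @export
print.rba_panel <- function(x, ...) {
  cat(sprintf("<rba_panel> %s model, %d conditions\n", x$variant,
              nrow(x$summary)))
  print(x$summary)
  invisible(x)
}
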