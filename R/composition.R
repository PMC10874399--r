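#' Ribosome composition from the protein mass fraction
#'
#' At fixed ribosome molar mass `omega_R`, the protein mass fraction
#' \eqn{x_{rP}} determines the residue counts of the two moieties:
#' \deqn{n_{rRNA} = (1 - x_{rP}) \omega_R / \omega_{NT}, \qquad
#'       n_{rP} = x_{rP} \omega_R / \omega_{AA},}
#' so that \eqn{n_{rRNA}\omega_{NT} + n_{rP}\omega_{AA} = \omega_R} exactly.
#' Counts are kept as real numbers; the relation is continuous in
#' \eqn{x_{rP}} and rounding would create grid artifacts in sweeps.
#'
#' @param params an `rba_params` object.
#' @param x_rP ribosomal protein mass fraction in [0, 1].
#' @return an object of class `rba_composition`: list with `x_rP`,
#'   `n_rRNA` (NT), `n_rP` (AA).
#' @export
#' @examples
#' derive_composition(ecoli_fixture("glc"), 0.36)
derive_composition <- function(params, x_rP) {
  stopifnot(inherits(params, "rba_params"))
  if (!is.numeric(x_rP) || length(x_rP) != 1L || is.na(x_rP) ||
      x_rP < 0 || x_rP > 1)
    stop("derive_composition: x_rP must be a single number in [0, 1]")
  structure(
    list(
      x_rP = x_rP,
      n_rRNA = (1 - x_rP) * params$omega_R / params$omega_NT,
      n_rP = x_rP * params$omega_R / params$omega_AA
    ),
    class = "rba_composition"
  )
}

#' @export
print.rba_composition <- function(x, ...) {
  cat(sprintf("<rba_composition> x_rP = %.4g: n_rRNA = %.6g NT, n_rP = %.6g AA\n",
              x$x_rP, x$n_rRNA, x$n_rP))
  invisible(x)
}

#' Minimum rRNA degradation rate constant at a given composition
#'
#' Evaluates the degradation sub-model: 0 for scenario `"none"`,
#' `kdeg_max` for `"constant"`, and the cooperative-protection form
#' \eqn{k^{deg}_{max}(1 - x^n/(K^n + x^n))} for `"hill"`.
#'
#' @param deg an `rba_degradation` object (or an `rba_params`, whose
#'   degradation sub-model is used).
#' @param x_rP ribosomal protein mass fraction in [0, 1].
#' @return rate constant, per hour.
#' @export
kdeg_value <- function(deg, x_rP) {
  if (inherits(deg, "rba_params")) deg <- deg$degradation
  stopifnot(inherits(deg, "rba_degradation"))
  if (any(x_rP < 0 | x_rP > 1)) stop("kdeg_value: x_rP must lie in [0, 1]")
  switch(deg$scenario,
    none = rep(0, length(x_rP)),
    constant = rep(deg$kdeg_max, length(x_rP)),
    hill = {
      xn <- x_rP^deg$n_hill
      deg$kdeg_max * (1 - xn / (deg$K^deg$n_hill + xn))
    }
  )
}
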