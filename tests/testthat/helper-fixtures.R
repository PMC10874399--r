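# Shared fixtures for the suite. Everything is generated in code; the
# expensive glucose-condition objects are computed once per test run.

glc <- ecoli_fixture("glc")
glc_comp36 <- derive_composition(glc, 0.36)

# a parameter set engineered so the growth quadratic has (alpha ~ 0,
# beta ~ beta_target, gamma ~ 0): huge turnover numbers silence every term
# except the nucleotide-synthesis one, which is tuned to hit beta.
contrived_params <- function(beta_target) {
  # beta ~ kel_bar_R * (n_ENT/kcat_ENT) * (omega_AA/omega_NT) * (omega_AA/omega_R)
  # with omega_AA = 0.5, omega_NT = 1, omega_R = 100, kel_R = 1
  n_ENT <- beta_target / (1 * (0.5 / 1) * (0.5 / 100))
  parameter_set(
    omega_C = 0.25, omega_AA = 0.5, omega_NT = 1, omega_R = 100,
    n_IC = 1, n_EAA = 1, n_ENT = n_ENT, n_RNAP = 1, n_RNase = 1, n_AF = 1,
    kcat_IC = 1e12, kcat_EAA = 1e12, kcat_ENT = 1, kcat_AF = 1e12,
    kel_RNAP = 1e12, kel_R = 1, kdeg_RNase = 1,
    condition_label = sprintf("contrived beta=%g", beta_target)
  )
}

# collector for the conservation suite: tests register every solution they
# produce, and test-acceptance.R audits them all at the end of the run
.solution_log <- new.env(parent = emptyenv())
.solution_log$solutions <- list()

log_solution <- function(sol) {
  .solution_log$solutions[[length(.solution_log$solutions) + 1L]] <- sol
  invisible(sol)
}
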