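test_that("composition algebra is exact at the endpoints and in between", {
  p <- glc
  c0 <- derive_composition(p, 0)
  expect_identical(c0$n_rP, 0)
  expect_equal(c0$n_rRNA, p$omega_R / p$omega_NT)
  c1 <- derive_composition(p, 1)
  expect_identical(c1$n_rRNA, 0)
  expect_equal(c1$n_rP, p$omega_R / p$omega_AA)
  expect_equal(derive_composition(p, 0.36)$n_rP, 7400, tolerance = 1e-12)
  # mass split and inversion hold exactly on a fine grid
  for (x in seq(0, 1, by = 0.01)) {
    cc <- derive_composition(p, x)
    expect_equal(cc$n_rRNA * p$omega_NT + cc$n_rP * p$omega_AA, p$omega_R,
                 tolerance = 1e-14)
    expect_equal(cc$n_rP * p$omega_AA / p$omega_R, x, tolerance = 1e-14)
  }
  expect_error(derive_composition(p, 1.1), "x_rP")
})

test_that("degradation rate constant follows the cooperative model", {
  hill6 <- degradation_model("hill", kdeg_max = 10, K = 0.2, n_hill = 6)
  hill2 <- degradation_model("hill", kdeg_max = 10, K = 0.2, n_hill = 2)
  expect_identical(kdeg_value(hill6, 0), 10)
  expect_equal(kdeg_value(hill6, 0.2), 5) # half-saturation by definition
  expect_lt(kdeg_value(hill6, 0.36), kdeg_value(hill2, 0.36))
  expect_identical(kdeg_value(degradation_model("none"), 0.5), 0)
  expect_identical(kdeg_value(degradation_model("constant", kdeg_max = 3),
                              0.5), 3)
  # non-increasing in x for any Hill parameters
  for (n in c(1, 2, 6)) for (K in c(0.1, 0.2, 0.5)) {
    v <- kdeg_value(degradation_model("hill", 7, K, n), seq(0, 1, 0.05))
    expect_true(all(diff(v) <= 1e-12))
    expect_equal(v[1], 7)
  }
})

test_that("constraint systems have the documented shapes and signs", {
  comp <- glc_comp36
  base <- build_constraints(glc, comp, 0.5, "base")
  expect_identical(dim(base$A), c(12L, 11L))
  ext <- build_constraints(glc, comp, 0.5, "extended")
  expect_identical(dim(ext$A), c(14L, 13L))
  expect_true(all(c("cap RNase", "min deg") %in% rownames(ext$A)))
  expect_false(any(c("cap RNase", "min deg") %in% rownames(base$A)))
  expect_identical(unname(base$sign[c("C", "AA", "NT", "mass")]),
                   rep("eq", 4))
  expect_identical(unname(base$sign["rRNA"]), "ge")
  expect_true(all(base$rhs[setdiff(names(base$rhs), "mass")] == 0))
  expect_identical(unname(base$rhs["mass"]), 0.5)
  forb <- build_constraints(glc, comp, 0.5, "extended", "forbid")
  expect_identical(unname(forb$sign[c("rRNA", "cap R", "min deg")]),
                   rep("eq", 3))
  nodeg <- glc
  nodeg$degradation <- degradation_model("none")
  expect_error(build_constraints(nodeg, comp, 0.5, "extended"),
               "degradation")
})

test_that("constraint rows match their hand-derived forms", {
  # independent row-by-row reconstruction from the capacity/stoichiometry
  # derivation, for random parameter sets and compositions
  for (s in 1:10) {
    p <- random_parameters(s)
    p$degradation <- degradation_model("hill", kdeg_max = 2 + s, K = 0.2,
                                       n_hill = 1 + s %% 6)
    x <- stats::runif(1)
    comp <- derive_composition(p, x)
    mu <- stats::runif(1, 0.1, 2)
    sys <- build_constraints(p, comp, mu, "extended")
    A <- sys$A
    expect_equal(unname(A["C", c("v_IC", "v_EAA", "v_ENT")]),
                 c(1, -p$n_AA, -p$n_NT))
    expect_equal(unname(A["AA", c("v_EAA", "v_ENT", "w_IC", "w_rP")]),
                 c(1, -1, -p$n_IC, -comp$n_rP))
    expect_equal(unname(A["NT", c("v_ENT", "v_RNAP", "v_RNase")]),
                 c(1, -comp$n_rRNA, comp$n_rRNA))
    expect_equal(unname(A["rRNA", c("v_RNAP", "v_RNase", "v_AF")]),
                 c(1, -1, -1))
    expect_equal(unname(A["rP", c("v_AF", "w_rP")]), c(-1, 1))
    for (cap in c("IC", "EAA", "ENT", "AF"))
      expect_equal(unname(A[paste("cap", cap),
                            paste0(c("v_", "w_"), cap)]),
                   c(-mu, p[[paste0("kcat_", cap)]]))
    expect_equal(unname(A["cap RNAP", c("v_RNAP", "w_RNAP")]),
                 c(-mu * comp$n_rRNA, kel_bar_RNAP(p)))
    expect_equal(unname(A["cap RNase", c("v_RNase", "w_RNase")]),
                 c(-mu * comp$n_rRNA, p$kdeg_RNase))
    expect_equal(unname(A["cap R", "v_AF"]), kel_bar_R(p))
    expect_equal(unname(A["cap R", "w_RNAP"]), -mu * p$n_RNAP)
    expect_equal(unname(A["cap R", "w_rP"]), -mu * comp$n_rP)
    expect_equal(unname(A["min deg", c("v_RNase", "v_AF")]),
                 c(mu, -kdeg_value(p$degradation, x) * (1 - x)))
    expect_equal(unname(A["mass", "v_IC"]), p$omega_C)
  }
})

test_that("internal reactions conserve mass for random parameter sets", {
  for (s in 1:100) {
    p <- random_parameters(s)
    comp <- derive_composition(p, stats::runif(1))
    bal <- mass_balance_audit(p, comp, if (s %% 2) "base" else "extended")
    expect_equal(unname(bal["v_IC"]), p$omega_C, tolerance = 1e-12)
    internal <- setdiff(names(bal), "v_IC")
    expect_lt(max(abs(bal[internal])), 1e-9 * p$omega_R)
  }
})

test_that("mitochondrial import enters the dry-mass row as an exchange", {
  m <- variant_mitochondria(glc, 1 / 3)
  comp <- derive_composition(m, 0.36)
  bal <- mass_balance_audit(m, comp, "base")
  expect_equal(unname(bal["w_rP"]), comp$n_rP * m$omega_AA / 3,
               tolerance = 1e-12)
  sys <- build_constraints(m, comp, 0.5, "base")
  expect_equal(unname(sys$A["mass", "w_rP"]),
               comp$n_rP * m$omega_AA / 3, tolerance = 1e-12)
  # and the dry-mass normalization still holds at a feasible point
  sol <- maximize_growth(m, 0.36, "extended")
  log_solution(sol)
  w <- omega_species(m, comp, "extended")
  expect_equal(sum(w * sol$concentrations[names(w)]), 1, tolerance = 1e-9)
})

test_that("concentrations and allocations follow from fluxes", {
  sol <- maximize_growth(glc, 0.36, "base", tol = 1e-8)
  log_solution(sol)
  sys <- build_constraints(glc, glc_comp36, sol$mu, "base")
  cv <- concentrations_from_fluxes(sys, sol$fluxes)
  expect_equal(unname(cv["RNAP"]), sol$fluxes[["w_RNAP"]] / sol$mu)
  expect_equal(unname(cv["R"]), sol$fluxes[["v_AF"]] / sol$mu)
  w <- omega_species(glc, glc_comp36, "base")
  expect_equal(sum(w * cv[names(w)]), 1, tolerance = 1e-9)
  expect_error(concentrations_from_fluxes(sys, sol$fluxes, mu = -1), "mu")

  phi <- allocations(sol$fluxes, sol$mu, glc, glc_comp36, "base")
  expect_equal(unname(phi["rP"]),
               sol$mu * glc_comp36$n_rP * sol$fluxes[["w_rP"]] /
                 (kel_bar_R(glc) * sol$fluxes[["v_AF"]]))
  expect_lte(sum(phi), 1 + 1e-9)
  bad <- sol$fluxes
  bad[["v_AF"]] <- 0
  expect_error(allocations(bad, sol$mu, glc, glc_comp36, "base"), "v_AF")

  # no free rRNA on the no-accumulation branch
  sysf <- build_constraints(glc, glc_comp36, 0.5 * sol$mu, "base", "forbid")
  wit <- is_feasible(sysf)
  expect_true(wit$feasible)
  cvf <- concentrations_from_fluxes(sysf, wit$witness)
  expect_equal(unname(cvf["rRNA"]), 0, tolerance = 1e-12)
})

test_that("constraint tables export and round-trip through CSV", {
  sys <- build_constraints(glc, glc_comp36, 0.7, "extended")
  f <- tempfile(fileext = ".csv")
  df <- constraints_as_table(sys, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_identical(nrow(back), 14L)
  expect_equal(back$rhs, unname(sys$rhs))
  expect_equal(as.matrix(back[, colnames(sys$A)]),
               unname(sys$A), ignore_attr = TRUE)
})
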