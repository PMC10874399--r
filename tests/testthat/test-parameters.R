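test_that("loader converts per-second rates to per-hour and validates", {
  f <- tempfile(fileext = ".json")
  p <- ecoli_fixture("glc")
  obj <- jsonlite::read_json(write_parameters(p, f), simplifyVector = TRUE)
  obj$rates$kel_R <- list(value = 21, unit = "AA_per_s")
  obj$rates$kdeg_RNase <- list(value = 88, unit = "NT_per_s")
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  p2 <- load_parameters(f)
  expect_identical(p2$kel_R, 21 * 3600)
  expect_identical(p2$kdeg_RNase, 88 * 3600)

  # omitting a field is rejected with the field named
  obj$masses$omega_R <- NULL
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameters(f), "omega_R")

  obj$masses$omega_R <- p$omega_R
  obj$degradation$scenario <- "quadratic"
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameters(f), "scenario")
})

test_that("write/load round trip reproduces numeric content", {
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  p <- ecoli_fixture("lb")
  write_parameters(p, f1)
  p1 <- load_parameters(f1)
  numfields <- c("omega_C", "omega_AA", "omega_NT", "omega_R",
                 "n_AA", "n_NT", "n_IC", "n_EAA", "n_ENT", "n_RNAP",
                 "n_RNase", "n_AF", "kcat_IC", "kcat_EAA", "kcat_ENT",
                 "kcat_AF", "kel_RNAP", "f_act_RNAP", "phi_rRNA_RNAP",
                 "kel_R", "f_act_R", "kdeg_RNase", "rp_import_fraction")
  for (fld in numfields)
    expect_equal(p1[[fld]], p[[fld]], tolerance = 1e-12, label = fld)
  # a second round trip is exact (serialization is stable)
  write_parameters(p1, f2)
  p2 <- load_parameters(f2)
  for (fld in numfields) expect_identical(p2[[fld]], p1[[fld]], label = fld)
})

test_that("TSV parameter files load equivalently to JSON", {
  p <- ecoli_fixture("glc")
  f <- tempfile(fileext = ".tsv")
  rows <- rbind(
    data.frame(name = c("omega_C", "omega_AA", "omega_NT", "omega_R"),
               value = c(p$omega_C, p$omega_AA, p$omega_NT, p$omega_R),
               unit = ""),
    data.frame(name = c("n_IC", "n_EAA", "n_ENT", "n_RNAP", "n_RNase",
                        "n_AF"),
               value = c(p$n_IC, p$n_EAA, p$n_ENT, p$n_RNAP, p$n_RNase,
                         p$n_AF), unit = ""),
    data.frame(name = c("kcat_IC", "kcat_EAA", "kcat_ENT", "kcat_AF",
                        "kel_RNAP", "kel_R", "kdeg_RNase"),
               value = c(p$kcat_IC, p$kcat_EAA, p$kcat_ENT, p$kcat_AF,
                         p$kel_RNAP, p$kel_R, p$kdeg_RNase) / 3600,
               unit = "per_s"),
    data.frame(name = c("f_act_RNAP", "phi_rRNA_RNAP", "f_act_R"),
               value = c(p$f_act_RNAP, p$phi_rRNA_RNAP, p$f_act_R),
               unit = ""),
    data.frame(name = c("degradation.scenario", "degradation.kdeg_max",
                        "degradation.K", "degradation.n_hill"),
               value = c("hill", p$degradation$kdeg_max, 0.2, 6),
               unit = c("", "per_h", "", ""))
  )
  write.table(rows, f, sep = "\t", row.names = FALSE, quote = FALSE)
  p2 <- load_parameters(f)
  expect_equal(p2$kcat_EAA, p$kcat_EAA, tolerance = 1e-12)
  expect_equal(p2$degradation$kdeg_max, p$degradation$kdeg_max)
  expect_identical(p2$degradation$n_hill, 6)
})

test_that("fixtures satisfy the printed anchors", {
  for (cond in ecoli_conditions()) {
    p <- ecoli_fixture(cond)
    expect_identical(p$kel_R, 21 * 3600)
    expect_identical(p$kdeg_RNase, 88 * 3600)
    expect_true(p$f_act_R >= 0.80 && p$f_act_R <= 0.85)
    # protein moiety at the observed composition is the 7400-AA complex
    expect_equal(round(0.36 * p$omega_R / p$omega_AA), 7400)
  }
  expect_gt(ecoli_fixture("lb")$kcat_EAA, ecoli_fixture("glc")$kcat_EAA)
  # effective rates are products of rate and active fraction
  p <- ecoli_fixture("glc")
  expect_identical(kel_bar_R(p), p$kel_R * p$f_act_R)
  expect_identical(kel_bar_RNAP(p),
                   p$kel_RNAP * p$f_act_RNAP * p$phi_rRNA_RNAP)
  expect_error(ecoli_fixture("chemostat"))
})

test_that("fixture maximum growth rates are ordered poor to rich", {
  mus <- vapply(ecoli_conditions(), function(cond) {
    sol <- maximize_growth(ecoli_fixture(cond), 0.36, "base")
    log_solution(sol)
    sol$mu
  }, numeric(1))
  expect_true(all(diff(mus) > 0))
  # the fixture family is built to span realistic E. coli growth rates
  expect_lt(mus[["min1"]], 0.5)
  expect_gt(mus[["lb"]], 1.8)
})

test_that("random parameter sets are deterministic and always valid", {
  r1 <- random_parameters(1)
  r1b <- random_parameters(1)
  r2 <- random_parameters(2)
  expect_identical(unclass(r1)[1:22], unclass(r1b)[1:22])
  expect_false(identical(r1$kel_R, r2$kel_R))
  for (s in 1:100) expect_s3_class(random_parameters(s), "rba_params")
  # drawing does not disturb the caller's RNG stream
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(random_parameters(3))
  expect_identical(runif(1), a)
  expect_error(random_parameters(1, ranges = list(omega_C = c(2, 1))),
               "range")
})

test_that("validator rejects out-of-range and inconsistent fields", {
  p <- ecoli_fixture("glc")
  bad <- p
  bad$kcat_EAA <- -1
  expect_error(validate_parameters(bad), "kcat_EAA")
  bad <- p
  bad$f_act_R <- 1.2
  expect_error(validate_parameters(bad), "f_act_R")
  bad <- p
  bad$n_AA <- p$n_AA * 1.5 # breaks mass conservation of AA synthesis
  expect_error(validate_parameters(bad), "n_AA")
  expect_error(degradation_model("hill", K = 1.5), "K")
})

test_that("archaeal variant scales only the degradation ceiling", {
  p <- ecoli_fixture("glc")
  a <- variant_archaea(p, 2)
  expect_identical(a$degradation$kdeg_max, 2 * p$degradation$kdeg_max)
  expect_identical(a$kel_R, p$kel_R)
  expect_identical(variant_archaea(p, 1)$degradation$kdeg_max,
                   p$degradation$kdeg_max)
  base_only <- p
  base_only$degradation <- degradation_model("none")
  expect_error(variant_archaea(base_only, 2), "none")
})

test_that("mitochondrial variant discounts the translated rP length", {
  p <- ecoli_fixture("glc")
  m <- variant_mitochondria(p, 1 / 3)
  comp <- derive_composition(m, 0.36)
  sys <- build_constraints(m, comp, 0.5, "base")
  expect_equal(-sys$A["AA", "w_rP"], (2 / 3) * comp$n_rP)
  expect_equal(-sys$A["cap R", "w_rP"], 0.5 * (2 / 3) * comp$n_rP)
  # zero import is exactly the base parameterization
  m0 <- variant_mitochondria(p, 0)
  sys0 <- build_constraints(m0, comp, 0.5, "base")
  sysb <- build_constraints(p, comp, 0.5, "base")
  expect_identical(sys0$A, sysb$A)
  expect_error(variant_mitochondria(p, 1), "import_fraction")
})
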