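test_that("hand-solved quadratics are reproduced", {
  # alpha ~ 0, beta = 4, gamma ~ 0: mu_hat = 0.5 at x = 0, 1 at x = 1
  p4 <- contrived_params(4)
  q4 <- quadratic_coefficients(p4)
  expect_lt(q4$alpha, 1e-9)
  expect_equal(q4$beta, 4, tolerance = 1e-9)
  expect_lt(q4$gamma, 1e-9)
  expect_equal(q4$epsilon, -0.75, tolerance = 1e-6)
  expect_equal(analytic_mu_max(p4, 0) / q4$mu_hat_scale, 0.5,
               tolerance = 1e-6)
  expect_equal(analytic_mu_max(p4, 1) / q4$mu_hat_scale, 1,
               tolerance = 1e-6)
  expect_identical(monotonicity_class(p4), "increasing")

  # beta = 1 makes epsilon = 0: mu_hat constant at 1
  p1 <- contrived_params(1)
  expect_equal(quadratic_coefficients(p1)$epsilon, 0, tolerance = 1e-6)
  mu_hat <- analytic_mu_max(p1, seq(0, 1, 0.1)) /
    quadratic_coefficients(p1)$mu_hat_scale
  expect_equal(mu_hat, rep(1, 11), tolerance = 1e-6)
})

test_that("realistic fixtures are in the decreasing regime", {
  for (cond in ecoli_conditions()) {
    p <- ecoli_fixture(cond)
    q <- quadratic_coefficients(p)
    expect_gt(q$epsilon, 0)
    expect_true(all(unlist(q[c("alpha", "beta", "gamma")]) > 0))
    expect_identical(monotonicity_class(p), "decreasing")
    mu <- analytic_mu_max(p, seq(0, 1, 0.1))
    expect_true(all(diff(mu) < 0))
  }
})

test_that("epsilon definition and the positive root are consistent", {
  for (s in 1:20) {
    p <- random_parameters(s)
    q <- quadratic_coefficients(p)
    expect_equal(q$epsilon,
                 (q$alpha + q$beta) / q$beta^2 + q$gamma / q$beta - 1)
    for (x in c(0, 0.5, 1)) {
      mu_hat <- analytic_mu_max(p, x) / q$mu_hat_scale
      expect_gt(mu_hat, 0)
      # root residual of the quadratic itself
      expect_equal((q$alpha + q$beta * (1 - x)) * mu_hat^2 +
                     (q$gamma + x) * mu_hat - 1, 0, tolerance = 1e-12)
    }
    # finite differences confirm the epsilon-sign law
    mu <- analytic_mu_max(p, c(0.2, 0.4, 0.6))
    if (q$epsilon > 1e-9) expect_true(all(diff(mu) < 0))
    if (q$epsilon < -1e-9) expect_true(all(diff(mu) > 0))
  }
})

test_that("dropping alpha changes realistic curves by less than 1 percent", {
  for (cond in c("min1", "glc", "lb")) {
    p <- ecoli_fixture(cond)
    q <- quadratic_coefficients(p)
    expect_lt(q$alpha, 1e-3 * q$beta)
    xs <- seq(0, 1, by = 0.05)
    full <- analytic_mu_max(p, xs)
    apx <- analytic_mu_max(p, xs, drop_alpha = TRUE)
    expect_lt(max(abs(apx - full) / full), 0.01)
  }
})

test_that("the homogenized determinant vanishes exactly at the root", {
  B_shape <- function(p, x, mu) {
    sys <- build_constraints(p, derive_composition(p, x), mu, "base")
    dim(cbind(sys$A, -sys$rhs))
  }
  expect_identical(B_shape(glc, 0.36, 0.5), c(12L, 12L))
  for (s in 1:20) {
    p <- random_parameters(s)
    x <- stats::runif(1)
    root <- analytic_mu_max(p, x)
    at_root <- abs(determinant_residual(p, x, root))
    off <- abs(determinant_residual(p, x, 1.1 * root))
    expect_lt(at_root, 1e-8)
    expect_gt(off, 1e3 * at_root)
    expect_gt(off, 1e-12)
  }
  expect_error(determinant_residual(glc, 0.36, NULL), "mu|positive")
})

test_that("two-loop bounds reproduce printed arithmetic and scaling laws", {
  # with every ribosome on rP and the full 7400-AA complex, the rP loop
  # caps growth at 21*3600/7400 per hour
  p <- glc
  p$f_act_R <- 1
  b <- kr_bounds(p, 0.36, phi_rP = 1, phi_RNAP = 0.1)
  expect_equal(b$bound_rP, 21 * 3600 / 7400, tolerance = 1e-9)
  # square-root law in the RNAP allocation
  b1 <- kr_bounds(glc, 0.5, 0.3, 0.2)
  b2 <- kr_bounds(glc, 0.5, 0.3, 0.4)
  expect_equal(b2$bound_RNAP / b1$bound_RNAP, sqrt(2), tolerance = 1e-12)
  # endpoint behavior: the vanishing-moiety bound is infinite
  expect_identical(kr_bounds(glc, 0, 0.3, 0.2)$bound_rP, Inf)
  expect_identical(kr_bounds(glc, 1, 0.3, 0.2)$bound_RNAP, Inf)
  expect_error(kr_bounds(glc, 0.5, 0, 0.2), "allocations")
})

test_that("bound intersection solves the golden-ratio construction", {
  # gamma_rP * phi_rP = gamma_RNAP * sqrt(phi_RNAP) = 1 collapses the
  # intersection condition to x^2 = 1 - x
  b <- kr_bounds(glc, 0.5, 0.5, 0.5)
  phi_rP <- 1 / b$gamma_rP
  phi_RNAP <- 1 / b$gamma_RNAP^2
  opt <- kr_optimal_composition(glc, phi_rP, phi_RNAP)
  expect_equal(opt$x_star, (sqrt(5) - 1) / 2, tolerance = 1e-9)
  # curves cross: rP bound is the lower one to the right of x*, RNAP to the left
  right <- kr_bounds(glc, opt$x_star + 0.01, phi_rP, phi_RNAP)
  left <- kr_bounds(glc, opt$x_star - 0.01, phi_rP, phi_RNAP)
  expect_lt(right$bound_rP, right$bound_RNAP)
  expect_lt(left$bound_RNAP, left$bound_rP)
})

test_that("full-model optima respect the bounds at realized allocations", {
  for (cond in c("min1", "glc", "lb")) {
    sol <- maximize_growth(ecoli_fixture(cond), 0.36, "base")
    log_solution(sol)
    expect_silent(check_kr_bounds(sol))
    b <- kr_bounds(sol$params, 0.36, sol$phi[["rP"]], sol$phi[["RNAP"]])
    expect_lte(sol$mu, b$bound_rP + 1e-9)
    expect_lte(sol$mu, b$bound_RNAP + 1e-9)
  }
})
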