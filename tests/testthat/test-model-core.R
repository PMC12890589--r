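test_that("allometric rate functions match hand-evaluated values", {
  expect_identical(home_range(1, 0.9), 1)
  expect_equal(home_range(100, 0.9), 63.0957, tolerance = 1e-5)
  expect_equal(home_range(1e4, 0.7), 630.957, tolerance = 1e-5)
  expect_error(home_range(-1, 0.9), "positive")

  expect_equal(per_area_mortality(1e-6, 0.25, 100), 1 - exp(-100),
               tolerance = 1e-6)
  expect_equal(per_area_mortality(100, 0.25, 100), 0.98549,
               tolerance = 1e-5)
  expect_lt(per_area_mortality(1e12, 0.25, 100), 1e-10)

  p <- default_params()
  expect_equal(mortality_rate(p, "specialist"), 62.180, tolerance = 1e-4)
  expect_equal(mortality_rate(p, "generalist"), 24.754, tolerance = 1e-4)
  p1 <- default_params(b = 1)
  expect_equal(mortality_rate(p1, "specialist"), 1, tolerance = 1e-4)
})

test_that("per-area mortality is bounded in (0,1) and decreasing in mass", {
  # over the empirical mass range (below ~1 g the value is within double
  # round-off of its supremum 1)
  b <- 10^seq(log10(1.75), 8, length.out = 200)
  d <- per_area_mortality(b, 0.25, 100)
  expect_true(all(d > 0 & d < 1))
  expect_true(all(diff(d) < 0))
  # tiny rates survive at the largest masses instead of rounding to zero
  expect_gt(per_area_mortality(1e8, 0.25, 100), 0)
})

test_that("conversion efficiency supports constant and allometric forms", {
  expect_equal(conversion_efficiency(default_params()), 100)
  p <- default_params(kappa_mode = "allometric", C0 = 1, b0 = 0, C1 = 1, b1 = 0)
  expect_equal(conversion_efficiency(p), 0.5)
  p2 <- model_params(b = 3, kappa_mode = "allometric",
                     C0 = 2, b0 = 1, C1 = 2, b1 = 1)
  expect_equal(conversion_efficiency(p2), 3)
  expect_error(model_params(b = 100, kappa_mode = "allometric"),
               "requires C0")
})

test_that("parameter constructor enforces the model invariants", {
  expect_error(model_params(b = -5), "positive")
  expect_error(model_params(b = 1e9), "supported range")
  expect_warning(model_params(b = 0.5), "empirical")
  expect_error(model_params(b = 100, alpha = 1.2), "alpha")
  expect_error(model_params(b = 100, k1 = 0.6, k2 = 0.7), "k1 > k2")
  expect_error(model_params(b = 100, gamma = -1), "positive")
  expect_error(update_params(default_params(), nonsense = 1), "unknown")
  p <- update_params(default_params(), b = 300, alpha = 0.1)
  expect_equal(p$b, 300)
  expect_equal(p$alpha, 0.1)
})

test_that("ODE right-hand side matches hand evaluation and equilibria", {
  p <- default_params()
  rates <- ode_rhs(c(r1 = 1, r2 = 1, x1 = 1, x2 = 1), p)
  expect_equal(unname(rates["dr1"]), -0.2, tolerance = 1e-10)
  expect_equal(unname(rates["dr2"]), 0.3, tolerance = 1e-10)
  expect_equal(unname(rates["dx1"]), 100 - 62.18022, tolerance = 1e-4)
  expect_equal(unname(rates["dx2"]), 40 - 24.75439, tolerance = 1e-4)

  # no consumers: resources replenish at their rates
  r0 <- ode_rhs(c(r1 = 0.3, r2 = 0.7, x1 = 0, x2 = 0), p)
  expect_equal(unname(r0[c("dr1", "dr2")]), c(p$R1, p$R2))
})

test_that("closed-form equilibria annihilate the RHS", {
  eq <- coexistence_equilibrium(default_params())
  rates <- ode_rhs(c(r1 = eq$r1_star, r2 = eq$r2_star,
                     x1 = eq$x1_star, x2 = eq$x2_star), default_params())
  expect_lt(max(abs(rates)), 1e-10)

  set.seed(42)
  for (i in 1:25) {
    p <- random_params()
    if (mortality_rate(p, "generalist") == 0) next  # mortality underflow
    geq <- generalist_only_equilibrium(p)
    grates <- ode_rhs(c(r1 = geq$r1_star, r2 = geq$r2_star, x1 = 0,
                        x2 = geq$x2_star), p)
    expect_lt(max(abs(grates)) / max(1, geq$x2_star), 1e-9)
    gap <- geq$m2 / p$alpha - geq$m1
    if (gap > 0) {
      ceq <- coexistence_equilibrium(p)
      crates <- ode_rhs(c(r1 = ceq$r1_star, r2 = ceq$r2_star,
                          x1 = ceq$x1_star, x2 = ceq$x2_star), p)
      expect_lt(max(abs(crates)) / max(1, abs(ceq$x1_star), ceq$x2_star),
                1e-9)
    }
  }
})

test_that("generalist-only equilibrium matches oracle values and scalings", {
  p <- default_params()
  eq <- generalist_only_equilibrium(p)
  expect_equal(eq$x2_star, 6.0596, tolerance = 1e-4)
  expect_equal(eq$r1_star, 0.82513, tolerance = 1e-4)
  expect_equal(eq$r2_star, 0.41257, tolerance = 1e-4)
  expect_identical(eq$x1_star, 0)
  expect_identical(eq$f_star, 0)

  # doubling kappa halves resources and doubles the consumer
  eq2 <- generalist_only_equilibrium(update_params(p, kappa = 200))
  expect_equal(eq2$r1_star, eq$r1_star / 2)
  expect_equal(eq2$x2_star, eq$x2_star * 2)
  expect_equal(generalist_only_equilibrium(update_params(p, R2 = 0))$r2_star, 0)
})

test_that("coexistence equilibrium matches the long-integration oracle", {
  eq <- coexistence_equilibrium(default_params())
  # frozen terminal state of integrate_dynamics(b = 100, t_end = 1e5)
  expect_equal(eq$r1_star, 0.6218022, tolerance = 1e-5)
  expect_equal(eq$r2_star, 0.6159174, tolerance = 1e-5)
  expect_equal(eq$x1_star, 0.7964313, tolerance = 1e-5)
  expect_equal(eq$x2_star, 4.058986, tolerance = 1e-5)
  expect_equal(eq$f_star, 0.1640294, tolerance = 1e-6)
  expect_equal(eq$f_star,
               specialist_equilibrium_frequency(default_params()),
               tolerance = 1e-12)
})

test_that("coexistence condition and boundary mass behave as derived", {
  expect_true(coexistence_condition(default_params()))
  expect_false(coexistence_condition(default_params(b = 1e4)))
  bstar <- coexistence_boundary_mass(default_params())
  expect_equal(bstar, 0.3^-5, tolerance = 1e-10)
  expect_equal(bstar, 411.523, tolerance = 1e-4)
  expect_equal(specialist_frequency_raw(default_params(b = bstar)), 0,
               tolerance = 1e-10)
  # just inside/outside the boundary
  expect_true(coexistence_condition(default_params(b = bstar * 0.99)))
  expect_false(coexistence_condition(default_params(b = bstar * 1.01)))
  expect_lte(coexistence_equilibrium(default_params(b = 500))$x1_star, 0)
  expect_false(coexistence_equilibrium(default_params(b = 500))$exists)
})

test_that("equilibrium frequency: closed-form values and limits", {
  expect_equal(specialist_equilibrium_frequency(default_params()),
               0.16403, tolerance = 1e-4)
  # alpha -> 0 limit at b = 1: f* -> R1/(R1+R2) = 2/3
  p <- suppressWarnings(model_params(b = 1, alpha = 1e-9, R1 = 1, R2 = 0.5))
  expect_equal(specialist_equilibrium_frequency(p), 2 / 3, tolerance = 1e-6)
  # extinction side returns exactly 0, raw value goes negative
  expect_identical(specialist_equilibrium_frequency(default_params(b = 1e4)), 0)
  expect_lt(specialist_frequency_raw(default_params(b = 1e4)), 0)
})

test_that("frequency from mortality rates (interior equilibrium) agrees with
           the allometric closed form", {
  # f* written in terms of m1, m2 must agree with the b^k form: the shared
  # per-area death rate cancels
  set.seed(7)
  for (i in 1:1000) {
    p <- random_params()
    m1 <- mortality_rate(p, "specialist")
    m2 <- mortality_rate(p, "generalist")
    # the mortality-based form degenerates (0/0) once the shared per-area
    # death rate underflows to exactly zero at extreme masses
    if (m1 == 0 || m2 == 0) next
    gap <- m2 / p$alpha - m1
    f_m <- (p$R1 * gap / m1 - p$R2) /
      (p$R1 * gap / m1 + (1 / p$alpha - 1) * p$R2)
    expect_equal(specialist_frequency_raw(p), f_m, tolerance = 1e-12)
  }
})

test_that("equilibrium frequency is invariant to mortality shape and kappa
           form, and monotone in alpha and R2", {
  p <- default_params()
  f0 <- specialist_equilibrium_frequency(p)
  for (beta in c(0.1, 0.25, 0.5, 1)) {
    for (gamma in c(10, 50, 100, 300)) {
      expect_equal(specialist_equilibrium_frequency(
        update_params(p, beta = beta, gamma = gamma)), f0,
        tolerance = 1e-14)
    }
  }
  pa <- default_params(kappa_mode = "allometric",
                       C0 = 0.5, b0 = 0.25, C1 = 3, b1 = -0.2)
  expect_equal(specialist_equilibrium_frequency(pa), f0, tolerance = 1e-14)

  alphas <- seq(0.05, 0.6, by = 0.05)
  f_alpha <- vapply(alphas, function(a)
    specialist_equilibrium_frequency(update_params(p, alpha = a)), 0)
  expect_true(all(diff(f_alpha) <= 1e-12))
  r2s <- seq(0.1, 2, by = 0.1)
  f_r2 <- vapply(r2s, function(r)
    specialist_equilibrium_frequency(update_params(p, R2 = r)), 0)
  expect_true(all(diff(f_r2) <= 1e-12))
})

test_that("analytic Jacobian matches central finite differences", {
  p <- default_params()
  state <- c(r1 = 0.8, r2 = 0.4, x1 = 1.3, x2 = 2.1)
  J <- jacobian_matrix(p, state)
  h <- 1e-6
  for (j in 1:4) {
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    fd <- (ode_rhs(up, p) - ode_rhs(dn, p)) / (2 * h)
    expect_equal(unname(J[, j]), unname(fd), tolerance = 1e-6)
  }
})

test_that("equilibria are locally stable; non-equilibria are rejected", {
  st_co <- jacobian_stability(default_params(),
                              coexistence_equilibrium(default_params()))
  expect_true(st_co$stable)
  expect_length(st_co$eigenvalues, 4)

  p_big <- default_params(b = 1e4)
  st_gen <- jacobian_stability(p_big, generalist_only_equilibrium(p_big))
  expect_true(st_gen$stable)

  expect_error(
    jacobian_stability(default_params(),
                       c(r1 = 1, r2 = 1, x1 = 1, x2 = 1)),
    "not an equilibrium")

  eq <- equilibrium_state(default_params())
  expect_identical(eq$kind, "coexistence")
  expect_true(eq$stable)
  expect_identical(equilibrium_state(p_big)$kind, "generalist-only")
})

test_that("parameter configs round-trip through flat key-value files", {
  p <- default_params(b = 250, alpha = 0.15)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_params_config(p, path)
  p2 <- read_params_config(path)
  expect_equal(unclass(p2), unclass(p))
  pa <- default_params(kappa_mode = "allometric",
                       C0 = 0.5, b0 = 0.25, C1 = 3, b1 = -0.2)
  write_params_config(pa, path)
  expect_equal(conversion_efficiency(read_params_config(path)),
               conversion_efficiency(pa))
})
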