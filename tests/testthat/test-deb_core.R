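# Organism-level energy budget: rate equations, temperature correction,
# compound parameters, allometry, integrator.

test_that("Arrhenius correction matches its closed form and is 1 at T_R", {
  p <- default_deb
  expect_equal(temperature_correction(T_REF_C, p), 1)
  # hand evaluation of exp(T_A/T_R - T_A/T_K)
  expect_equal(temperature_correction(29.85, p),
               exp(3000 / 293 - 3000 / 303), tolerance = 1e-12)
  expect_equal(temperature_correction(29.85, p), 1.4020, tolerance = 1e-3)
  expect_equal(temperature_correction(9.85, p), 0.6963, tolerance = 2e-4)
  expect_error(temperature_correction(NA_real_, p), "finite")
  expect_error(temperature_correction(-280, p), "absolute zero")
})

test_that("compound parameters follow the standard definitions", {
  cp <- default_cp
  expect_equal(cp$E_m, 4.72 / 0.6)
  expect_equal(cp$g, 2.35 / (0.7 * 4.72 / 0.6)) # = 0.4268
  expect_equal(cp$k_M, 0.44 / 2.35)             # = 0.18723
  expect_equal(cp$g, 0.4268, tolerance = 1e-3)
  expect_equal(cp$L_inf, 37.55, tolerance = 1e-3)
  expect_equal(cp$L_inf, cp$L_m / default_deb$delta)
  # identity inputs collapse every compound parameter to 1
  ident <- deb_params(delta = 1, p_Am = 1, v_dot = 1, p_M = 1, E_G = 1,
                      kappa = 1)
  cpi <- compound_params(ident)
  expect_equal(unlist(cpi[c("g", "k_M", "L_inf")]), c(g = 1, k_M = 1,
                                                      L_inf = 1))
})

test_that("parameter invariants are enforced", {
  expect_error(deb_params(kappa = 1.5), "kappa")
  expect_error(deb_params(p_Am = -1), "p_Am")
  expect_error(deb_params(l_b = 0.2, l_f = 0.1), "l_b < l_f")
})

test_that("ingestion reduction is a decreasing sigmoid bounded by alpha", {
  p <- default_deb
  expect_equal(ingestion_reduction(p$l_f, p), p$alpha / 2) # 0.42
  expect_equal(ingestion_reduction(0.079, p), 0.7541, tolerance = 1e-4)
  expect_equal(ingestion_reduction(1, p), 0.00362, tolerance = 1e-3)
  l <- seq(0.02, 1, by = 0.01)
  sf <- ingestion_reduction(l, p)
  expect_true(all(diff(sf) < 0))
  expect_true(all(sf > 0 & sf < p$alpha))
  expect_error(ingestion_reduction(0, p), "length")
})

test_that("reserve, growth and reproduction rates match hand evaluations", {
  p <- default_deb
  # reserve equilibrium: e = (1 - s_f) f
  st <- deb_state(e = (1 - ingestion_reduction(0.3, p)) * 0.8, l = 0.3)
  expect_equal(reserve_rate(st, 0.8, T_REF_C, p), 0)
  expect_equal(reserve_rate(deb_state(e = 0.5, l = 0.3), 1, T_REF_C, p),
               0.10225, tolerance = 1e-4)
  # pre-feeding condition: f is forced to zero below l_b
  pre <- deb_state(e = 0.5, l = 0.05)
  expect_equal(reserve_rate(pre, 1, T_REF_C, p),
               -default_cp$k_M * default_cp$g * 0.5 / 0.05)

  expect_equal(growth_rate(deb_state(e = 0.4, l = 0.4), T_REF_C, p), 0)
  expect_equal(growth_rate(deb_state(e = 1, l = 0.5), T_REF_C, p),
               0.009334, tolerance = 1e-4)
  expect_equal(growth_rate(deb_state(e = 0.5, l = 0.3), T_REF_C, p),
               0.005748, tolerance = 1e-4)

  expect_equal(reproduction_rate(deb_state(e = 1, l = 1), T_REF_C, p), 406)
  expect_equal(reproduction_rate(deb_state(e = 1, l = 0.5), T_REF_C, p), 0)
  expect_equal(reproduction_rate(deb_state(e = 0.9, l = 0.8), T_REF_C, p),
               170.2, tolerance = 1e-3)
})

test_that("male appetite factor and scatter act through effective_f", {
  p <- default_deb
  male <- deb_state(e = 1, l = 0.7, is_male = TRUE, past_puberty = TRUE)
  female <- deb_state(e = 1, l = 0.7, is_male = FALSE, past_puberty = TRUE)
  expect_equal(effective_f(0.8, male, 1, p), 0.8 * 0.92)
  expect_equal(effective_f(0.8, female, 1, p), 0.8)
  expect_equal(effective_f(0, male, 1, p), 0)
  expect_equal(effective_f(0.9, female, 5, p), 1) # clamped
  expect_error(effective_f(1.2, female, 1, p), "f must")
})

test_that("length-mass allometry uses natural logs, mg and mm", {
  expect_equal(length_mass(30), 301.4, tolerance = 1e-3)
  expect_equal(length_mass(exp(5.193 / 3.205)), 1)
  L <- c(3, 5.054, 12, 30, 42)
  expect_equal(mass_length(length_mass(L)), L)
  expect_error(length_mass(-1), "positive")
})

test_that("the Euler stepper holds fixed points and matches von Bertalanffy", {
  p <- default_deb
  # fixed point: e* = (1 - s_f(l*)) f and l* = e*
  f <- 0.8
  l_star <- uniroot(function(l) (1 - ingestion_reduction(l, p)) * f - l,
                    c(0.05, 1), tol = 1e-12)$root
  st <- deb_state(e = l_star, l = l_star)
  out <- step_deb(st, f, T_REF_C, dt = 1, substeps = 10, params = p)
  expect_equal(out$e, st$e, tolerance = 1e-8)
  expect_equal(out$l, st$l, tolerance = 1e-8)

  # with s_f ~ 0 and e held at 1, l(t) follows the closed-form growth curve
  p0 <- deb_params(alpha = 1e-12)
  sim <- simulate_deb(times = 1:400, f = 1, T_c = T_REF_C, params = p0,
                      e0 = 1, l0 = 0.1, dt = 0.1)
  cp <- compound_params(p0)
  r_B <- cp$k_M * cp$g / (3 * (1 + cp$g))
  closed <- 1 - (1 - 0.1) * exp(-r_B * (1:400))
  expect_lt(max(abs(sim$l[, 1] - closed)), 1e-3)
})

test_that("Euler trajectories converge to the adaptive oracle (order ~ 1)", {
  skip_if_not_installed("deSolve")
  p <- default_deb
  f <- 0.9
  T_c <- 27
  cT <- temperature_correction(T_c, p)
  cp <- default_cp
  rhs <- function(t, y, parms) {
    e <- y[1]; l <- max(y[2], 1e-6)
    sf <- ingestion_reduction(l, p)
    fi <- if (l < p$l_b) 0 else f
    de <- cT * cp$k_M * cp$g / l * ((1 - sf) * fi - e)
    dl <- cT * cp$k_M * cp$g / (3 * (e + cp$g)) * (e - l)
    dR <- if (l < p$l_p) 0 else
      max(cT * p$R_M / (1 - p$l_p^3) *
            ((cp$g + l) / (cp$g + e) * e * l^2 - p$l_p^3), 0)
    list(c(de, dl, dR))
  }
  times <- seq(0, 400, by = 5)
  oracle <- deSolve::ode(c(e = 1, l = p$l_b, R = 0), times, rhs, NULL,
                         method = "lsoda", rtol = 1e-10, atol = 1e-10)
  err <- function(dt) {
    sim <- simulate_deb(times[-1], f = f, T_c = T_c, params = p, e0 = 1,
                        l0 = p$l_b, dt = dt)
    max(abs(sim$l[, 1] - oracle[-1, "l"]) * cp$L_inf)
  }
  e1 <- err(0.1)
  expect_lt(e1, 0.1) # < 0.1 mm physical length at the model's native step
  # halving dt roughly halves the error (first-order convergence)
  expect_lt(err(0.05), 0.75 * e1)
})

test_that("all rates share the Arrhenius factor: time rescaling reproduces
           the reference trajectory", {
  p <- default_deb
  cT <- temperature_correction(29, p)
  warm <- simulate_deb(times = c(50, 100), f = 0.9, T_c = 29, params = p,
                       dt = 0.01)
  cold <- simulate_deb(times = c(50, 100) * cT, f = 0.9, T_c = T_REF_C,
                       params = p, dt = 0.01)
  expect_equal(warm$l[, 1], cold$l[, 1], tolerance = 1e-3)
  expect_equal(warm$R[, 1], cold$R[, 1], tolerance = 1e-2)
})

test_that("full feeding produces a sigmoid physical-length curve", {
  sim <- simulate_deb(times = 1:300, f = 1, T_c = 27, params = default_deb)
  L <- sim$L[, 1]
  dL <- diff(L)
  expect_true(all(dL > 0))
  infl <- which.max(dL)
  expect_gt(infl, 5) # growth accelerates first (inflection exists) ...
  expect_lt(infl, 250) # ... then decelerates towards the asymptote
})

test_that("state validation rejects inadmissible values", {
  expect_error(deb_state(e = -0.1), "reserve")
  expect_error(deb_state(l = 0), "length")
  expect_error(deb_state(R = -2), "buffer")
  expect_error(step_deb(deb_state(), f = 2, T_c = 20), "f must")
  expect_error(step_deb(deb_state(), f = 1, T_c = 20, dt = -1), "dt")
})
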