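# Morris elementary effects and Sobol variance decomposition, checked
# against analytic oracles, plus the dummy-parameter negative control.

test_that("Morris designs have the OAT structure and are seed-stable", {
  des <- sensitivity_design(c("a", "b", "c", "d"), rep(0, 4), rep(1, 4),
                            method = "morris", r = 10, levels = 8, seed = 3)
  expect_equal(des$names, c("a", "b", "c", "d", "dummy"))
  X <- morris_design(des)
  k <- 5
  expect_equal(nrow(X), 10 * (k + 1)) # r (k + 1) evaluation points
  expect_true(all(X >= 0 & X <= 1))
  ch <- attr(X, "changed")
  for (i in which(ch > 0)) {
    d <- X[i, ] - X[i - 1, ]
    expect_equal(sum(d != 0), 1) # exactly one coordinate moves
    expect_equal(which(d != 0), ch[i], ignore_attr = TRUE)
  }
  # every parameter moves exactly once per trajectory
  expect_equal(as.vector(table(ch[ch > 0])), rep(10, k))
  expect_identical(X, morris_design(des)) # same seed, same design
})

test_that("Morris effects are exact on a linear model and flag interactions", {
  des <- sensitivity_design(c("x1", "x2", "x3"), rep(0, 3), rep(1, 3),
                            method = "morris", r = 12, seed = 7)
  X <- morris_design(des)
  a <- c(3, -1, 0.5)
  y <- X[, 1:3] %*% a # the dummy column is ignored by construction
  eff <- morris_effects(X, y)
  for (j in 1:3) {
    row <- eff[eff$parameter == paste0("x", j), ]
    expect_equal(row$mu, a[j], tolerance = 1e-10)
    expect_equal(row$mu_star, abs(a[j]), tolerance = 1e-10)
    expect_equal(row$sigma, 0, tolerance = 1e-10)
  }
  drow <- eff[eff$parameter == "dummy", ]
  expect_equal(drow$mu_star, 0, tolerance = 1e-12)
  expect_equal(drow$global, 0, tolerance = 1e-12)
  expect_true(all(eff$mu_star >= abs(eff$mu) - 1e-12))

  # interaction signature: y = x1 * x2 has sigma > 0 for both factors
  y2 <- X[, 1] * X[, 2]
  eff2 <- morris_effects(X, y2)
  expect_gt(eff2$sigma[eff2$parameter == "x1"], 0.05)
  expect_gt(eff2$sigma[eff2$parameter == "x2"], 0.05)
  expect_equal(eff2$sigma[eff2$parameter == "x3"], 0)
})

test_that("missing evaluations fail loudly", {
  des <- sensitivity_design("x1", 0, 1, method = "morris", r = 4)
  X <- morris_design(des)
  expect_error(morris_effects(X, rep(1, nrow(X) - 2)), "2 evaluation")
  expect_error(morris_effects(X, rep(NaN, nrow(X))), "non-finite")
})

test_that("Sobol indices recover analytic variance shares of an additive
           model", {
  des <- sensitivity_design(c("x1", "x2"), c(0, 0), c(1, 1),
                            method = "sobol", N = 4096, seed = 5)
  X <- sobol_design(des)
  expect_equal(nrow(X), (2 + 2 + 1) * 4096) # dummy appended: k = 3
  y <- 2 * X[, 1] + 1 * X[, 2]
  si <- sobol_indices(X, y)
  # variance shares 4/5 and 1/5; Si = STi for additive models
  expect_lt(abs(si$Si[si$parameter == "x1"] - 0.8), 0.05)
  expect_lt(abs(si$Si[si$parameter == "x2"] - 0.2), 0.05)
  expect_lt(max(abs(si$Si - si$STi)), 0.05)
  expect_lt(abs(sum(si$Si[si$parameter != "dummy"]) - 1), 0.05)
  expect_lt(abs(si$Si[si$parameter == "dummy"]), 0.05)
  # the dummy's total index is exactly zero under the Jansen estimator
  # (its hybrid matrix reproduces the base outputs)
  expect_lt(si$STi[si$parameter == "dummy"], 1e-12)
})

test_that("Sobol indices match the Ishigami closed form", {
  des <- sensitivity_design(c("x1", "x2", "x3"), rep(-pi, 3), rep(pi, 3),
                            method = "sobol", N = 8192, seed = 11,
                            dummy = FALSE)
  X <- sobol_design(des)
  si <- sobol_indices(X, ishigami_fn(X))
  truth <- ishigami_true()
  expect_lt(abs(si$Si[1] - truth[["S1"]]), 0.03)
  expect_lt(abs(si$Si[2] - truth[["S2"]]), 0.03)
  expect_lt(abs(si$Si[3]), 0.03)
  expect_lt(abs(si$STi[1] - truth[["ST1"]]), 0.03)
  expect_lt(abs(si$STi[2] - truth[["ST2"]]), 0.03)
  expect_true(all(si$STi >= si$Si - 0.03))
})

test_that("small Sobol samples warn and report bootstrap intervals", {
  des <- sensitivity_design(c("x1", "x2"), c(0, 0), c(1, 1),
                            method = "sobol", N = 64, seed = 2)
  X <- sobol_design(des)
  y <- X[, 1] + X[, 2]
  expect_warning(si <- sobol_indices(X, y), "bootstrap")
  expect_true(all(c("Si_lo", "Si_hi", "STi_lo", "STi_hi") %in% names(si)))
  expect_true(all(si$Si_lo <= si$Si & si$Si <= si$Si_hi))
})

test_that("the energy-budget batch evaluator feeds designs through the
           organism model", {
  rng <- deb_sensitivity_ranges()
  des <- sensitivity_design(rng$names, rng$lower, rng$upper,
                            method = "morris", r = 4, seed = 1)
  X <- morris_design(des)
  out <- deb_batch_output(X, times = c(25, 100), output = "length")
  expect_equal(dim(out), c(nrow(X), 2))
  expect_true(all(out > 0 & out < 80)) # plausible zebrafish lengths, mm
  expect_true(all(out[, 2] > out[, 1])) # fish grow between 25 and 100 dpf
  # eggs output: cumulative and non-negative for a mature female
  eggs <- deb_batch_output(X, times = c(100, 400), output = "eggs")
  expect_true(all(eggs >= 0))
  expect_true(all(eggs[, 2] >= eggs[, 1]))
})
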