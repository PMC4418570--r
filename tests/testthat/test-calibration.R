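# Likelihood, MCMC machinery, convergence diagnostics, histogram distance
# and the genetic-algorithm search.

make_exact_obs <- function() {
  # growth observations lying exactly on the model curve (known sd)
  ibm <- ibm_params()
  days <- c(49, 63, 77, 104)
  t_birth <- ibm$H_a / (27 - ibm$H_b)
  sim <- simulate_deb(days - t_birth, f = 0.8, T_c = 27,
                      params = deb_params())
  observation_set(growth = data.frame(
    group = "g1", day = days, mean_length = sim$L[, 1], sd = 0.5, n = 4,
    temperature = 27))
}

test_that("the Gaussian likelihood has its exact local geometry", {
  obs <- make_exact_obs()
  fg <- c(g1 = 0.8)
  ll0 <- log_likelihood(deb_params(), fg, obs)
  # data generated exactly by the model: any other f scores worse
  expect_gt(ll0, log_likelihood(deb_params(), c(g1 = 0.7), obs))
  expect_gt(ll0, log_likelihood(deb_params(), c(g1 = 0.9), obs))
  # perturbing one observed mean by +1 mm lowers the log-likelihood by
  # exactly 1 / (2 se^2), se = sd / sqrt(n) = 0.25
  obs2 <- obs
  obs2$growth$mean_length[2] <- obs2$growth$mean_length[2] + 1
  expect_equal(ll0 - log_likelihood(deb_params(), fg, obs2),
               1 / (2 * 0.25^2))
})

test_that("fecundity likelihood distinguishes the two experimental
           temperatures", {
  spec <- synthetic_spec(noise_length = 0, noise_eggs = 0)
  fec <- make_fecundity_data(spec)
  fg <- c(fec29 = 0.93, fec26 = 0.48)
  ll_right <- log_likelihood(deb_params(), fg, fec)
  swapped <- fec
  swapped$fecundity$temperature <- ifelse(
    swapped$fecundity$temperature == 29, 26, 29)
  expect_gt(ll_right, log_likelihood(deb_params(), fg, swapped))
})

test_that("inadmissible parameters and missing groups are handled", {
  obs <- make_exact_obs()
  bad <- unclass(deb_params())
  bad$l_b <- 0.3 # violates l_b < l_f
  expect_identical(log_likelihood(bad, c(g1 = 0.8), obs), -Inf)
  expect_error(log_likelihood(deb_params(), c(wrong = 0.8), obs), "group")
})

test_that("MCMC is seed-reproducible and reports acceptance", {
  obs <- make_exact_obs()
  f1 <- run_mcmc(obs, free = c("p_Am", "kappa"), chains = 2,
                 iterations = 600, seed = 4)
  f2 <- run_mcmc(obs, free = c("p_Am", "kappa"), chains = 2,
                 iterations = 600, seed = 4)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$acceptance > 0 & f1$acceptance < 1))
  # kept half of 600 iterations x 4 population members; 2 free + 1 latent f
  expect_equal(dim(f1$draws), c(1200, 3, 2))
})

test_that("Gelman-Rubin behaves at its limits", {
  # all chains sampling the same normal: R-hat near 1
  set.seed(8)
  a <- array(rnorm(3000), c(1000, 1, 3), dimnames = list(NULL, "x", NULL))
  expect_lt(gelman_rubin(a), 1.01)
  # chains stuck at different constants: R-hat diverges
  b <- array(rep(c(0, 5), each = 100), c(100, 1, 2),
             dimnames = list(NULL, "x", NULL))
  expect_gt(gelman_rubin(b), 1.2)
  expect_error(gelman_rubin(a[, , 1, drop = FALSE]), "2 chains")
})

test_that("histogram distance is positional and exact", {
  h1 <- data.frame(lower = 18:22, frequency = c(0.4, 0.3, 0.2, 0.1, 0))
  expect_equal(ibm_distance(h1, h1), 0)
  h2 <- data.frame(lower = 18:22, frequency = c(0.3, 0.4, 0.2, 0.1, 0))
  # two bins differing by +/- 0.1
  expect_equal(ibm_distance(h1, h2), 0.02)
  # permuting bin contents changes the distance: position matters
  h3 <- data.frame(lower = 18:22, frequency = rev(h1$frequency))
  expect_gt(ibm_distance(h1, h3), 0)
  h4 <- data.frame(lower = 19:23, frequency = h1$frequency)
  expect_error(ibm_distance(h1, h4), "bins")
})

# analytic surrogate for the GA: a censored length histogram whose shape
# responds smoothly to all three fitted parameters
surrogate_sim <- function(pi_a, pi_d, F_inputs) {
  mids <- 18:32 + 0.5
  mu <- 20 + 100 * pi_a + 50 * F_inputs
  sd <- 1.5 + 60 * pi_d
  f <- dnorm(mids, mu, sd)
  data.frame(lower = 18:32, frequency = f / sum(f))
}

test_that("the genetic algorithm recovers surrogate parameters and its
           best distance is monotone under elitism", {
  truth <- c(pi_a = 0.0292, pi_d = 0.0089, F_inputs = 0.0142)
  target <- surrogate_sim(truth[1], truth[2], truth[3])
  fit <- fit_ibm_params(target, simulator = surrogate_sim,
                        pop_size = 50, generations = 12, seed = 6)
  expect_lt(fit$distance, 1e-3)
  expect_true(all(diff(fit$trace$best) <= 1e-12)) # elitist monotonicity
  bounds <- c(pi_a = diff(c(0.005, 0.1)), pi_d = diff(c(0.0005, 0.05)),
              F_inputs = diff(c(0.001, 0.1)))
  # recovery within the search resolution along identifiable directions:
  # mu and sd of the surrogate pin 2 combinations of the 3 parameters
  mu_fit <- 20 + 100 * fit$par[["pi_a"]] + 50 * fit$par[["F_inputs"]]
  mu_true <- 20 + 100 * truth[[1]] + 50 * truth[[3]]
  expect_equal(mu_fit, mu_true, tolerance = 0.02)
  sd_fit <- 1.5 + 60 * fit$par[["pi_d"]]
  expect_equal(sd_fit, 1.5 + 60 * truth[[2]], tolerance = 0.05)
})

test_that("GA degenerate cases: identical genomes with no variation stay
           put; failed simulations score infinitely bad", {
  target <- surrogate_sim(0.03, 0.01, 0.01)
  fit <- fit_ibm_params(target, simulator = surrogate_sim,
                        bounds = list(pi_a = c(0.03, 0.0300001),
                                      pi_d = c(0.01, 0.0100001),
                                      F_inputs = c(0.01, 0.0100001)),
                        pop_size = 8, generations = 3, crossover = 0,
                        mutation = 0, seed = 1)
  expect_equal(fit$par[["pi_a"]], 0.03, tolerance = 1e-5)
  expect_equal(fit$trace$best, rep(fit$trace$best[1], 4))

  boom <- function(pi_a, pi_d, F_inputs) stop("simulation failed")
  fit2 <- fit_ibm_params(target, simulator = boom, pop_size = 6,
                         generations = 1, seed = 2)
  expect_identical(fit2$distance, Inf)
})

test_that("the default pond simulator plugs into the GA evaluation path", {
  sim <- default_ibm_simulator(days = 90, cutoff = 15, replicates = 1,
                               seed = 50, ibm = tiny_ibm(),
                               series = test_series)
  h <- sim(0.0292, 0.0089, 0.0142)
  expect_true(is.data.frame(h) && all(c("lower", "frequency") %in% names(h)))
  if (nrow(h) > 0) expect_equal(sum(h$frequency), 1)
})
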