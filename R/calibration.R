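# Bayesian calibration of the energy-budget layer and distance-based
# evolutionary search for the population-level parameters.

#' Bundle growth and fecundity observations for calibration
#'
#' @param growth data.frame with columns `group`, `day` (dpf), `mean_length`
#'   (mm), `sd` (mm), `n`, `temperature` (degrees C); or `NULL`.
#' @param fecundity data.frame with columns `group`, `day` (d since the start
#'   of monitoring), `cum_eggs`, `temperature` (degrees C), `l0` (scaled
#'   length of the monitored female); or `NULL`.
#' @return An object of class `observation_set`. Each group carries its own
#'   latent functional response `f`, fitted alongside the model parameters.
#' @export
observation_set <- function(growth = NULL, fecundity = NULL) {
  check <- function(df, cols, what) {
    if (is.null(df)) return(NULL)
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols)) {
      stop(what, " observations lack column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (g in unique(df$group)) {
      d <- df$day[df$group == g]
      if (is.unsorted(d, strictly = TRUE)) {
        stop(what, " days must be strictly increasing within group ", g,
             call. = FALSE)
      }
    }
    df
  }
  growth <- check(growth, c("group", "day", "mean_length", "sd", "n",
                            "temperature"), "growth")
  if (!is.null(growth) && any(growth$mean_length <= 0)) {
    stop("lengths must be positive", call. = FALSE)
  }
  fecundity <- check(fecundity, c("group", "day", "cum_eggs", "temperature",
                                  "l0"), "fecundity")
  groups <- c(if (!is.null(growth)) unique(as.character(growth$group)),
              if (!is.null(fecundity)) unique(as.character(fecundity$group)))
  if (anyDuplicated(groups)) {
    stop("group labels must be unique across growth and fecundity",
         call. = FALSE)
  }
  structure(list(growth = growth, fecundity = fecundity, groups = groups),
            class = "observation_set")
}

# builds a fast closure (params, f_groups) -> log-likelihood; simulates all
# groups in one vectorised pass of the batch integrator
make_log_likelihood <- function(obs, sd_eggs = 30, dt = 0.1,
                                ibm = ibm_params()) {
  gro <- obs$growth
  fec <- obs$fecundity
  g_groups <- if (!is.null(gro)) unique(as.character(gro$group)) else character(0)
  f_groups_id <- if (!is.null(fec)) unique(as.character(fec$group)) else character(0)
  cols <- c(g_groups, f_groups_id)
  Tg <- c(vapply(g_groups, function(g) gro$temperature[gro$group == g][1],
                 0), vapply(f_groups_id,
                            function(g) fec$temperature[fec$group == g][1], 0))
  l0f <- vapply(f_groups_id, function(g) fec$l0[fec$group == g][1], 0)

  # precompute the observation layout once: simulation time grid, and per
  # group its column, row indices, observed values and standard errors.
  # growth groups start at first feeding (mouth opening); observation ages
  # are dpf, so shift by the temperature-driven incubation time
  t_birth <- ibm$H_a / pmax(Tg - ibm$H_b, 0.1)
  sim_t <- sort(unique(c(
    unlist(lapply(seq_along(g_groups), function(i)
      gro$day[gro$group == g_groups[i]] - t_birth[i])),
    if (!is.null(fec)) fec$day
  )))
  stopifnot(all(sim_t > 0))
  layout <- c(
    lapply(seq_along(g_groups), function(i) {
      sub <- gro[gro$group == g_groups[i], ]
      list(col = i, rows = match(sub$day - t_birth[i], sim_t),
           y = sub$mean_length, se = sub$sd / sqrt(sub$n), kind = "L")
    }),
    lapply(seq_along(f_groups_id), function(j) {
      sub <- fec[fec$group == f_groups_id[j], ]
      list(col = length(g_groups) + j, rows = match(sub$day, sim_t),
           y = sub$cum_eggs, se = rep(sd_eggs, nrow(sub)), kind = "R")
    })
  )
  n_g <- length(g_groups)

  function(params, f_groups) {
    if (!all(cols %in% names(f_groups))) {
      stop("f_groups must be named for every observation group", call. = FALSE)
    }
    # inadmissible parameter sets score -Inf rather than erroring
    core <- c("delta", "p_Am", "v_dot", "kappa", "p_M", "E_G", "R_M")
    if (any(unlist(params[core]) <= 0) ||
        !(params$l_b < params$l_f && params$l_f < params$l_p) ||
        params$kappa > 1 || params$alpha > 1) {
      return(-Inf)
    }
    fg <- f_groups[cols]
    l0 <- c(rep(params$l_b, n_g), l0f)
    sim <- tryCatch(
      simulate_deb(sim_t, f = fg, T_c = Tg, params = params, e0 = 1, l0 = l0,
                   dt = dt),
      error = function(e) NULL)
    if (is.null(sim)) return(-Inf)
    ll <- 0
    for (lay in layout) {
      pred <- if (lay$kind == "L") sim$L[lay$rows, lay$col]
              else sim$R[lay$rows, lay$col]
      ll <- ll + sum(stats::dnorm(lay$y, pred, lay$se, log = TRUE))
    }
    if (!is.finite(ll)) -Inf else ll
  }
}

#' Gaussian log-likelihood of energy-budget parameters
#'
#' Simulates every observation group at its temperature and latent
#' functional response, then scores observed mean lengths (standard error
#' `sd / sqrt(n)` from the data) and cumulative egg counts (fixed
#' observation sd) under independent Gaussian errors.
#'
#' @param params a [deb_params()] object (or plain named list satisfying its
#'   invariants).
#' @param f_groups named vector: functional response per observation group.
#' @param obs an [observation_set()].
#' @param sd_eggs Gaussian sd of cumulative egg counts.
#' @param dt Euler sub-step (d).
#' @return Log-likelihood (`-Inf` when the simulation fails or parameters
#'   are inadmissible).
#' @export
log_likelihood <- function(params, f_groups, obs, sd_eggs = 30, dt = 0.1) {
  make_log_likelihood(obs, sd_eggs = sd_eggs, dt = dt)(params, f_groups)
}

# default transform table for the fitted parameter set
par_transforms <- function(free) {
  logit_pars <- c("kappa", "alpha", "f_lim", "l_b", "l_f", "l_p")
  type <- ifelse(free %in% logit_pars, "logit", "log")
  names(type) <- free
  type
}

to_internal <- function(x, type) {
  z <- numeric(length(x))
  names(z) <- names(type)
  lg <- type == "logit"
  z[lg] <- stats::qlogis(x[lg])
  z[!lg] <- log(x[!lg])
  z
}
to_natural <- function(z, type) {
  x <- numeric(length(z))
  names(x) <- names(type)
  lg <- type == "logit"
  x[lg] <- stats::plogis(z[lg])
  x[!lg] <- exp(z[!lg])
  x
}

#' Default weakly informative priors for the fitted parameter set
#'
#' Independent normal priors on the internal scale (log for positive
#' parameters, logit for fractions), centred at the default parameter values
#' with sd 0.2 (log scale, about +/- 20 percent) or 0.5 (logit scale).
#' Per-group functional responses carry no prior information: their
#' logit-normal(0, 1.75) prior is nearly flat on (0, 1).
#'
#' @param free names of the fitted energy-budget parameters.
#' @param groups observation group labels (one latent `f` each).
#' @param params a [deb_params()] object supplying the prior centres.
#' @return A list with `mean`, `sd`, `type` vectors over all sampled
#'   coordinates.
#' @export
default_priors <- function(free, groups, params = deb_params()) {
  type <- par_transforms(free)
  centre <- to_internal(unlist(params[free]), type)
  sd <- ifelse(type == "logit", 0.5, 0.2)
  f_names <- paste0("f_", groups)
  mean <- c(centre, stats::setNames(rep(0, length(groups)), f_names))
  sd <- c(sd, stats::setNames(rep(1.75, length(groups)), f_names))
  type <- c(type, stats::setNames(rep("logit", length(groups)), f_names))
  list(mean = mean, sd = sd, type = type)
}

#' Calibrate the energy-budget model by Metropolis MCMC
#'
#' Samples on the internal (log / logit) scale. The posterior has long,
#' curved compensation ridges (e.g. assimilation against the latent
#' functional responses) and can be multimodal, so the sampler is built for
#' that geometry: latent `f` coordinates are grid-initialised, a multi-start
#' Nelder-Mead search locates the posterior mode, the local inverse Hessian
#' seeds a pilot adaptive Metropolis chain (Haario covariance adaptation),
#' and the reporting chains are independent differential-evolution
#' Metropolis populations (proposals formed from sampled history
#' differences, with occasional unit-factor jumps that can hop between
#' modes). The first half of every chain is discarded as burn-in. The
#' sampled coordinates are the fitted energy-budget parameters plus one
#' latent functional response per observation group; `l_p` and `L_0` stay
#' fixed.
#'
#' @param obs an [observation_set()].
#' @param free names of the fitted parameters (default: the full fitted set).
#' @param priors a list as returned by [default_priors()].
#' @param chains number of chains (>= 3 recommended for diagnostics).
#' @param iterations iterations per chain (first half discarded as burn-in).
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param params baseline [deb_params()]; fixed parameters keep these values.
#' @param sd_eggs,dt passed to the likelihood.
#' @return An object of class `posterior_sample`: `draws` is a
#'   kept-iterations x parameters x chains array on the natural scale,
#'   plus `log_post`, `acceptance`, `seed`.
#' @export
run_mcmc <- function(obs, free = c("delta", "p_Am", "v_dot", "kappa",
                                   "alpha", "l_b", "l_f", "p_M", "E_G",
                                   "E_0", "R_M", "f_lim"),
                     priors = NULL, chains = 3, iterations = 4000, seed = 1,
                     params = deb_params(), sd_eggs = 30, dt = 0.1) {
  groups <- obs$groups
  if (is.null(priors)) priors <- default_priors(free, groups, params)
  d <- length(priors$mean)
  pnames <- names(priors$mean)
  loglik <- make_log_likelihood(obs, sd_eggs = sd_eggs, dt = dt)
  base <- unclass(params)

  log_post <- function(z) {
    lp <- sum(stats::dnorm(z, priors$mean, priors$sd, log = TRUE))
    nat <- to_natural(z, priors$type)
    p <- base
    p[free] <- nat[free]
    if (!(p$l_b < p$l_f && p$l_f < p$l_p)) return(-Inf)
    fg <- nat[paste0("f_", groups)]
    names(fg) <- groups
    ll <- loglik(p, fg)
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }

  burn <- floor(iterations / 2)
  n_members <- 4L # differential-evolution population size per chain
  kept <- (iterations - burn) * n_members
  draws <- array(NA_real_, c(kept, d, chains),
                 dimnames = list(NULL, pnames, paste0("chain", seq_len(chains))))
  lpmat <- matrix(NA_real_, kept, chains)
  acc_rate <- numeric(chains)

  # Laplace preconditioning: locate the posterior mode from the prior centre
  # and use the local inverse Hessian as the random-walk proposal covariance
  # (a long-standing recipe for ridge-shaped posteriors); chains start
  # over-dispersed around the mode
  set.seed(seed)
  neg_lp <- function(z) {
    v <- log_post(z)
    if (is.finite(v)) -v else 1e10
  }
  # initialise each latent f by a coordinate-wise grid search (the likelihood
  # has compensation ridges between f and the assimilation parameters, and a
  # mode search started at f = 0.5 can climb the wrong ridge)
  z0 <- priors$mean
  f_coords <- grep("^f_", pnames)
  f_grid <- stats::qlogis(seq(0.05, 0.99, by = 0.04))
  for (j in f_coords) {
    vals <- vapply(f_grid, function(v) {
      zz <- z0
      zz[j] <- v
      neg_lp(zz)
    }, 0)
    z0[j] <- f_grid[which.min(vals)]
  }
  # multi-start: the grid-initialised centre plus the best of a prior sample
  # (guards against secondary ridges trapping a single descent)
  cand <- matrix(stats::rnorm(40 * d, priors$mean, priors$sd), ncol = d,
                 byrow = TRUE)
  cand_lp <- apply(cand, 1, neg_lp)
  starts <- list(z0, cand[which.min(cand_lp), ])
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, neg_lp, method = "Nelder-Mead",
                      control = list(maxit = 2000))
    o <- stats::optim(o$par, neg_lp, method = "Nelder-Mead",
                      control = list(maxit = 2000)) # restart polishes ridges
    if (is.null(best) || o$value < best$value) best <- o
  }
  opt <- best
  mode_z <- opt$par
  H <- tryCatch(stats::optimHess(mode_z, neg_lp), error = function(e) NULL)
  Sigma <- NULL
  if (!is.null(H)) {
    eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
    lam <- pmax(eg$values, max(eg$values) * 1e-8)
    Sigma <- eg$vectors %*% diag(1 / lam, d) %*% t(eg$vectors)
  }
  if (is.null(Sigma)) Sigma <- diag(priors$sd^2, d)
  L0 <- t(chol(Sigma + diag(1e-12, d)))
  L_prop <- L0 * (2.38 / sqrt(d))

  # shared pilot chain: the local (Laplace) covariance understates the
  # global extent of curved compensation ridges, so one adaptive chain from
  # the mode re-estimates the proposal covariance (Haario), which is then
  # frozen and shared by all reporting chains
  pilot_n <- max(2000L, burn)
  z <- mode_z
  lp <- log_post(z)
  lambda <- 1
  Lch <- L_prop
  hist_z <- matrix(NA_real_, pilot_n, d)
  acc_win <- 0L
  for (it in seq_len(pilot_n)) {
    zp <- z + lambda * as.numeric(Lch %*% stats::rnorm(d))
    lpp <- log_post(zp)
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
      z <- zp; lp <- lpp
      acc_win <- acc_win + 1L
    }
    hist_z[it, ] <- z
    if (it %% 50 == 0) {
      lambda <- lambda * exp(clamp(acc_win / 50 - 0.23, -0.5, 0.5))
      acc_win <- 0L
    }
    if (it >= 500 && it %% 200 == 0) {
      S <- stats::cov(hist_z[seq_len(it), , drop = FALSE]) * (2.38^2 / d) +
        diag(1e-10, d)
      Lc <- tryCatch(t(chol(S)), error = function(e) NULL)
      if (!is.null(Lc)) {
        Lch <- Lc
        lambda <- 1
      }
    }
  }
  L_prop <- Lch
  # seed history for the differential-evolution populations: thinned pilot
  # trajectory (it spans the ridges the pilot explored)
  pilot_keep <- hist_z[seq(floor(pilot_n / 4), pilot_n, length.out = 300), ,
                       drop = FALSE]

  m <- n_members
  gamma0 <- 2.38 / sqrt(2 * d)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    Zh <- pilot_keep
    members <- matrix(NA_real_, m, d)
    lp_m <- numeric(m)
    for (i in seq_len(m)) {
      lp_i <- -Inf
      tries <- 0
      while (!is.finite(lp_i) && tries < 100) {
        members[i, ] <- mode_z + as.numeric(L_prop %*% stats::rnorm(d))
        lp_i <- log_post(members[i, ])
        tries <- tries + 1
      }
      if (!is.finite(lp_i)) {
        stop("could not find an admissible starting point", call. = FALSE)
      }
      lp_m[i] <- lp_i
    }
    acc <- 0L
    acc_win <- 0L
    consecutive_zero <- 0L
    at <- 0L
    for (it in seq_len(iterations)) {
      for (i in seq_len(m)) {
        ab <- sample.int(nrow(Zh), 2L)
        gam <- if (stats::runif(1) < 0.1) 1 else gamma0
        zp <- members[i, ] + gam * (Zh[ab[1], ] - Zh[ab[2], ]) +
          stats::rnorm(d, 0, 1e-3 * priors$sd)
        lpp <- log_post(zp)
        if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp_m[i]) {
          members[i, ] <- zp
          lp_m[i] <- lpp
          acc <- acc + 1L
          acc_win <- acc_win + 1L
        }
      }
      if (it %% 10 == 0) Zh <- rbind(Zh, members)
      if (it %% 100 == 0) {
        consecutive_zero <- if (acc_win == 0L) consecutive_zero + 1L else 0L
        if (consecutive_zero >= 5L) {
          stop("proposal adaptation failed: zero acceptance over a window",
               call. = FALSE)
        }
        acc_win <- 0L
      }
      if (it > burn) {
        for (i in seq_len(m)) {
          at <- at + 1L
          draws[at, , ch] <- to_natural(members[i, ], priors$type)
          lpmat[at, ch] <- lp_m[i]
        }
      }
    }
    acc_rate[ch] <- acc / (iterations * m)
  }
  structure(list(draws = draws, log_post = lpmat, acceptance = acc_rate,
                 seed = seed, free = free, groups = groups, priors = priors),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  dm <- dim(x$draws)
  cat(sprintf("Posterior sample: %d chains x %d kept draws x %d parameters\n",
              dm[3], dm[1], dm[2]))
  cat(sprintf("  acceptance: %s\n",
              paste(sprintf("%.2f", x$acceptance), collapse = ", ")))
  rh <- tryCatch(gelman_rubin(x), error = function(e) NULL)
  if (!is.null(rh)) cat(sprintf("  max Gelman-Rubin R-hat: %.3f\n", max(rh)))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance diagnostic: values near 1 indicate
#' that independent chains have converged to the same distribution; the
#' package's convergence criterion is R-hat < 1.2 for every parameter.
#'
#' @param sample a `posterior_sample` from [run_mcmc()], or a
#'   draws x parameters x chains array.
#' @return Named vector of R-hat values per parameter.
#' @export
gelman_rubin <- function(sample) {
  a <- if (inherits(sample, "posterior_sample")) sample$draws else sample
  if (length(dim(a)) != 3) stop("need a draws x parameters x chains array",
                                call. = FALSE)
  n <- dim(a)[1]; d <- dim(a)[2]; m <- dim(a)[3]
  if (m < 2) stop("Gelman-Rubin requires at least 2 chains", call. = FALSE)
  if (n < 10) stop("need at least 10 post-burn-in draws", call. = FALSE)
  rhat <- numeric(d)
  for (j in seq_len(d)) {
    ch <- a[, j, ]
    means <- colMeans(ch)
    W <- mean(apply(ch, 2, stats::var))
    B_over_n <- stats::var(means)
    var_hat <- (n - 1) / n * W + B_over_n
    rhat[j] <- if (W > 0) sqrt(var_hat / W)
               else if (B_over_n > 0) Inf else 1
  }
  stats::setNames(rhat, dimnames(a)[[2]])
}

#' Central credible intervals from a posterior sample
#'
#' @param sample a `posterior_sample`.
#' @param prob central probability mass (default 0.95).
#' @return Matrix with one row per parameter and columns `lower`, `median`,
#'   `upper` (chains pooled).
#' @export
credible_interval <- function(sample, prob = 0.95) {
  a <- sample$draws
  d <- dim(a)[2]
  alpha <- (1 - prob) / 2
  out <- t(vapply(seq_len(d), function(j) {
    stats::quantile(c(a[, j, ]), c(alpha, 0.5, 1 - alpha), names = FALSE)
  }, numeric(3)))
  dimnames(out) <- list(dimnames(a)[[2]], c("lower", "median", "upper"))
  out
}

#' Sum-of-squares distance between censored length histograms
#'
#' `sum((p_sim - p_obs)^2)` over 1-mm classes; both histograms must be
#' normalised over the same support (use [length_histogram()] with the same
#' cutoff and bin).
#'
#' @param simulated,observed data.frames with columns `lower`, `frequency`.
#' @return Non-negative sum of squared frequency differences.
#' @export
ibm_distance <- function(simulated, observed) {
  if (nrow(simulated) != nrow(observed) ||
      any(simulated$lower != observed$lower)) {
    stop("histograms are on different bins; align supports first",
         call. = FALSE)
  }
  sum((simulated$frequency - observed$frequency)^2)
}

# pad two histograms onto the union of their supports
align_histograms <- function(h1, h2, bin = 1) {
  lowers <- sort(union(h1$lower, h2$lower))
  if (length(lowers) == 0) {
    return(list(data.frame(lower = numeric(0), frequency = numeric(0)),
                data.frame(lower = numeric(0), frequency = numeric(0))))
  }
  full <- seq(min(lowers), max(lowers), by = bin)
  pad <- function(h) {
    f <- h$frequency[match(full, h$lower)]
    f[is.na(f)] <- 0
    data.frame(lower = full, frequency = f)
  }
  list(pad(h1), pad(h2))
}

#' Fit the population-level parameters by a genetic algorithm
#'
#' Generational genetic algorithm (tournament selection of size 3, crossover
#' rate 0.7, per-gene mutation rate 0.01, population 50, elitism) minimising
#' the sum-of-squares distance between a simulated and an observed censored
#' length histogram. The three fitted parameters are the natural mortality
#' scale `pi_a`, the density-dependent mortality constant `pi_d` and the
#' monsoon input fraction `F_inputs`.
#'
#' @param observed a histogram data.frame (`lower`, `frequency`) to match.
#' @param simulator function `(pi_a, pi_d, F_inputs)` returning a histogram
#'   data.frame; defaults to a full pond simulation via
#'   [default_ibm_simulator()]. Simulations of extinct populations score
#'   `Inf`.
#' @param bounds named list of `c(lower, upper)` search ranges.
#' @param pop_size,generations,crossover,mutation,tournament GA controls
#'   (defaults: 50, 10, 0.7, 0.01, 3).
#' @param elitism keep the best genome unchanged each generation?
#' @param seed integer seed for the whole search.
#' @return A list with `par` (named best parameters), `distance`, and a
#'   per-generation `trace` data.frame.
#' @export
fit_ibm_params <- function(observed,
                           simulator = default_ibm_simulator(),
                           bounds = list(pi_a = c(0.005, 0.1),
                                         pi_d = c(0.0005, 0.05),
                                         F_inputs = c(0.001, 0.1)),
                           pop_size = 50, generations = 10, crossover = 0.7,
                           mutation = 0.01, tournament = 3, elitism = TRUE,
                           seed = 1) {
  set.seed(seed)
  k <- length(bounds)
  nm <- names(bounds)
  lo <- vapply(bounds, `[`, 0, 1)
  hi <- vapply(bounds, `[`, 0, 2)
  evaluate <- function(genome) {
    h <- tryCatch(do.call(simulator, as.list(genome)), error = function(e) NULL)
    if (is.null(h) || nrow(h) == 0 || isTRUE(attr(h, "empty"))) return(Inf)
    al <- align_histograms(h, observed)
    ibm_distance(al[[1]], al[[2]])
  }
  pop <- matrix(stats::runif(pop_size * k, lo, hi), pop_size, k, byrow = TRUE,
                dimnames = list(NULL, nm))
  fit <- apply(pop, 1, evaluate)
  trace <- data.frame(generation = 0, best = min(fit),
                      mean = mean(fit[is.finite(fit)]))
  for (gen in seq_len(generations)) {
    newpop <- matrix(NA_real_, pop_size, k, dimnames = list(NULL, nm))
    start <- 1L
    if (elitism) {
      newpop[1L, ] <- pop[which.min(fit), ]
      start <- 2L
    }
    for (i in start:pop_size) {
      pick <- function() {
        cand <- sample.int(pop_size, tournament)
        pop[cand[which.min(fit[cand])], ]
      }
      p1 <- pick()
      child <- if (stats::runif(1) < crossover) {
        beta <- stats::runif(k)
        beta * p1 + (1 - beta) * pick()
      } else p1
      mut <- stats::runif(k) < mutation
      if (any(mut)) {
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0,
                                                0.1 * (hi - lo)[mut])
        child <- clamp(child, lo, hi)
      }
      newpop[i, ] <- child
    }
    pop <- newpop
    keep_fit <- if (elitism) c(trace$best[nrow(trace)],
                               apply(pop[-1L, , drop = FALSE], 1, evaluate))
                else apply(pop, 1, evaluate)
    fit <- keep_fit
    trace <- rbind(trace, data.frame(generation = gen, best = min(fit),
                                     mean = mean(fit[is.finite(fit)])))
  }
  best <- which.min(fit)
  list(par = stats::setNames(pop[best, ], nm), distance = fit[best],
       trace = trace)
}

#' Default full-pond simulator for the genetic-algorithm fit
#'
#' Returns a closure running the coupled pond simulation at the given
#' survival and monsoon-input parameters and summarising the final
#' population as a censored length histogram.
#'
#' @param days simulation horizon (d), default 1110.
#' @param cutoff censoring cutoff (mm), default 18.4.
#' @param replicates replicate runs averaged per evaluation.
#' @param seed base seed for the simulator's replicates.
#' @param deb,food,ibm,series baseline configuration.
#' @return A function `(pi_a, pi_d, F_inputs) -> histogram data.frame`.
#' @export
default_ibm_simulator <- function(days = 1110, cutoff = 18.4, replicates = 1,
                                  seed = 1000, deb = deb_params(),
                                  food = food_params(), ibm = ibm_params(),
                                  series = generate_monsoon_scenario()) {
  function(pi_a, pi_d, F_inputs) {
    ibm$pi_a <- pi_a
    ibm$pi_d <- pi_d
    food$F_inputs <- F_inputs
    hs <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      out <- run_ibm(days = days, deb = deb, food = food, ibm = ibm,
                     series = series, seed = seed + r, keep_state = TRUE)
      st <- attr(out, "state")
      if (length(st$fish$id) == 0) return(data.frame(lower = numeric(0),
                                                     frequency = numeric(0)))
      hs[[r]] <- length_histogram(fish_lengths(st), min_length = cutoff)
    }
    h <- hs[[1]]
    if (replicates > 1) {
      for (r in 2:replicates) {
        al <- align_histograms(h, hs[[r]])
        h <- data.frame(lower = al[[1]]$lower,
                        frequency = (al[[1]]$frequency * (r - 1) +
                                       al[[2]]$frequency) / r)
      }
    }
    h
  }
}
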