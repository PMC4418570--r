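# Seed-deterministic synthetic data generators: every calibration and
# comparison path is testable without external data.

#' Specification for synthetic observation generation
#'
#' @param deb generating [deb_params()].
#' @param growth_groups data.frame with one row per feeding group: columns
#'   `group`, `f`, `temperature`, `n`; defaults to three feeding regimes
#'   (daily, two days out of three, every other day) at 27 degrees C.
#' @param growth_days measurement schedule (dpf); the default is the 8-day
#'   juvenile monitoring schedule from 49 to 107 dpf.
#' @param fecundity_groups data.frame with columns `group`, `f`,
#'   `temperature`, `days` (monitoring duration), `l0`; defaults to the
#'   two-temperature design (29 degrees C for 21 d, 26 degrees C for 11 d).
#' @param noise_length measurement noise sd on individual lengths (mm).
#' @param noise_eggs observation noise sd on cumulative egg counts.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(deb = deb_params(),
                           growth_groups = data.frame(
                             group = c("food1", "food075", "food05"),
                             f = c(0.93, 0.81, 0.70),
                             temperature = 27, n = 15),
                           growth_days = c(49, 56, 63, 70, 77, 91, 104, 107),
                           fecundity_groups = data.frame(
                             group = c("fec29", "fec26"),
                             f = c(0.93, 0.48),
                             temperature = c(29, 26),
                             days = c(21, 11), l0 = 0.85),
                           noise_length = 0.5, noise_eggs = 20, seed = 1) {
  if (noise_length < 0 || noise_eggs < 0) {
    stop("noise sd must be >= 0", call. = FALSE)
  }
  if (is.unsorted(growth_days, strictly = TRUE)) {
    stop("growth days must be strictly increasing", call. = FALSE)
  }
  structure(list(deb = deb, growth_groups = growth_groups,
                 growth_days = growth_days,
                 fecundity_groups = fecundity_groups,
                 noise_length = noise_length, noise_eggs = noise_eggs,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate synthetic juvenile growth observations
#'
#' Simulates each feeding group from first feeding at its temperature and
#' functional response, draws `n` noisy individual lengths per measurement
#' day, and reports their mean, sd and count — the same table shape a growth
#' experiment produces.
#'
#' @param spec a [synthetic_spec()].
#' @return An [observation_set()] with a `growth` table.
#' @export
make_growth_data <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  gg <- spec$growth_groups
  ibm <- ibm_params()
  rows <- vector("list", nrow(gg))
  for (i in seq_len(nrow(gg))) {
    t_birth <- ibm$H_a / (gg$temperature[i] - ibm$H_b)
    sim <- simulate_deb(spec$growth_days - t_birth, f = gg$f[i],
                        T_c = gg$temperature[i], params = spec$deb)
    truth <- sim$L[, 1]
    n <- gg$n[i]
    obs <- vapply(truth, function(mu) {
      x <- mu + stats::rnorm(n, 0, spec$noise_length)
      c(mean(x), stats::sd(x))
    }, numeric(2))
    sd_obs <- if (spec$noise_length == 0) rep(spec$noise_length + 1e-8,
                                              length(truth)) else obs[2, ]
    mean_obs <- if (spec$noise_length == 0) truth else obs[1, ]
    rows[[i]] <- data.frame(group = gg$group[i], day = spec$growth_days,
                            mean_length = mean_obs, sd = sd_obs, n = n,
                            temperature = gg$temperature[i])
  }
  observation_set(growth = do.call(rbind, rows))
}

#' Generate synthetic fecundity observations
#'
#' Daily cumulative egg counts of a mature female at each experimental
#' temperature, from the reproduction dynamics plus Gaussian noise (kept
#' non-decreasing, as a cumulative count must be).
#'
#' @param spec a [synthetic_spec()].
#' @return An [observation_set()] with a `fecundity` table.
#' @export
make_fecundity_data <- function(spec = synthetic_spec()) {
  set.seed(spec$seed + 1L)
  fg <- spec$fecundity_groups
  rows <- vector("list", nrow(fg))
  for (i in seq_len(nrow(fg))) {
    days <- seq_len(fg$days[i])
    sim <- simulate_deb(days, f = fg$f[i], T_c = fg$temperature[i],
                        params = spec$deb, e0 = 1, l0 = fg$l0[i])
    truth <- sim$R[, 1]
    noisy <- truth + stats::rnorm(length(days), 0, spec$noise_eggs)
    noisy <- cummax(pmax(noisy, 0))
    if (spec$noise_eggs == 0) noisy <- truth
    rows[[i]] <- data.frame(group = fg$group[i], day = days,
                            cum_eggs = noisy, temperature = fg$temperature[i],
                            l0 = fg$l0[i])
  }
  observation_set(fecundity = do.call(rbind, rows))
}

#' Generate a synthetic field-style censored length histogram
#'
#' Runs the full pond simulation, samples `sample_n` fish longer than the
#' sampling cutoff (field gear misses small fish) and bins them at 1 mm — a
#' synthetic stand-in for field length-distribution surveys.
#'
#' @param days simulation horizon (d).
#' @param cutoff sampling cutoff (mm).
#' @param sample_n number of fish sampled (default 120).
#' @param seed integer seed.
#' @param deb,food,ibm,series configuration passed to [run_ibm()].
#' @return A histogram data.frame (`lower`, `frequency`) with attribute
#'   `sample_lengths`.
#' @export
make_field_histogram <- function(days = 1110, cutoff = 15, sample_n = 120,
                                 seed = 1, deb = deb_params(),
                                 food = food_params(), ibm = ibm_params(),
                                 series = generate_monsoon_scenario()) {
  out <- run_ibm(days = days, deb = deb, food = food, ibm = ibm,
                 series = series, seed = seed, keep_state = TRUE)
  st <- attr(out, "state")
  L <- fish_lengths(st)
  L <- L[L > cutoff]
  if (length(L) == 0) {
    h <- data.frame(lower = numeric(0), frequency = numeric(0))
    attr(h, "empty") <- TRUE
    return(h)
  }
  smp <- L[sample.int(length(L), min(sample_n, length(L)), replace = FALSE)]
  h <- length_histogram(smp, min_length = cutoff)
  attr(h, "sample_lengths") <- smp
  h
}
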