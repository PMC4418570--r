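#' Arrhenius temperature correction factor
#'
#' Multiplicative correction `exp(T_A / T_R - T_A / T_K)` with
#' `T_K = T + 273.15`, applied to the rate parameters `p_Am`, `v_dot` and
#' `p_M` (and hence to every derived rate). Equals 1 at the reference
#' temperature.
#'
#' @param T_c water temperature in degrees Celsius (vectorised).
#' @param params a [deb_params()] object (uses `T_A`, `T_R`).
#' @return Positive correction factor(s).
#' @export
#' @examples
#' temperature_correction(19.85, deb_params()) # 1 at T_K = 293 K
temperature_correction <- function(T_c, params) {
  if (!is.numeric(T_c) || any(!is.finite(T_c))) {
    stop("temperature must be finite numeric (degrees Celsius)", call. = FALSE)
  }
  if (any(T_c <= -273.15)) stop("temperature below absolute zero", call. = FALSE)
  exp(params$T_A / params$T_R - params$T_A / (T_c + 273.15))
}

#' Size-dependent ingestion reduction
#'
#' The fraction of potential assimilation lost by small fish:
#' `s_f(l) = alpha * (1 - (1 + l_f^3 / l^3)^-1)`, strictly decreasing in `l`,
#' tending to `alpha` for tiny larvae and to 0 for large fish. This term
#' replaces metabolic acceleration as the mechanism producing a sigmoid
#' growth curve.
#'
#' @param l scaled length (vectorised), > 0.
#' @param params a [deb_params()] object (uses `alpha`, `l_f`).
#' @return `s_f` in `[0, alpha)`.
#' @export
ingestion_reduction <- function(l, params) {
  if (any(l <= 0)) stop("scaled length must be > 0", call. = FALSE)
  lf3 <- params$l_f^3
  params$alpha * lf3 / (l^3 + lf3)
}

#' Construct an individual energy-budget state
#'
#' @param e scaled reserve density (-), >= 0.
#' @param l scaled length (-), in (0, 1] (a small tolerance above 1 is
#'   accepted since `e` may transiently exceed `l`'s asymptote).
#' @param R egg buffer: cumulative unspawned eggs (count), >= 0.
#' @param is_male logical flag(s).
#' @param past_puberty logical flag(s).
#' @return An object of class `deb_state`; all fields are parallel vectors,
#'   so one object can hold a whole cohort.
#' @export
deb_state <- function(e = 1, l = 0.079, R = 0, is_male = FALSE,
                      past_puberty = FALSE) {
  n <- max(length(e), length(l), length(R))
  s <- list(e = rep_len(as.numeric(e), n), l = rep_len(as.numeric(l), n),
            R = rep_len(as.numeric(R), n),
            is_male = rep_len(as.logical(is_male), n),
            past_puberty = rep_len(as.logical(past_puberty), n))
  if (any(s$e < 0)) stop("scaled reserve density must be >= 0", call. = FALSE)
  if (any(s$l <= 0) || any(s$l > 1 + 0.05)) {
    stop("scaled length must be in (0, 1] (plus small tolerance)", call. = FALSE)
  }
  if (any(s$R < 0)) stop("egg buffer must be >= 0", call. = FALSE)
  structure(s, class = "deb_state")
}

#' Rate of change of the scaled reserve density
#'
#' `de/dt = k_M * g / l * ((1 - s_f(l)) * f - e)`, with `k_M`
#' temperature-corrected and the functional response forced to 0 before
#' first feeding (`l < l_b`).
#'
#' @param state a [deb_state()].
#' @param f scaled functional response in `[0, 1]` (vectorised).
#' @param T_c water temperature, degrees Celsius.
#' @param params a [deb_params()] object.
#' @return de/dt (d^-1), vectorised over the state.
#' @export
reserve_rate <- function(state, f, T_c, params) {
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  if (any(state$l <= 0)) stop("scaled length must be > 0", call. = FALSE)
  cT <- temperature_correction(T_c, params)
  cp <- compound_params(params)
  f <- ifelse(state$l < params$l_b, 0, f)
  sf <- ingestion_reduction(state$l, params)
  cT * cp$k_M * cp$g / state$l * ((1 - sf) * f - state$e)
}

#' Rate of change of the scaled length (von Bertalanffy form)
#'
#' `dl/dt = r_B * (e - l)` with `r_B = k_M * g / (3 * (e + g))`,
#' temperature-corrected. Negative when reserves fall below the current
#' length (shrinking), which downstream steppers floor at a small positive
#' length.
#'
#' @inheritParams reserve_rate
#' @return dl/dt (d^-1).
#' @export
growth_rate <- function(state, T_c, params) {
  cT <- temperature_correction(T_c, params)
  cp <- compound_params(params)
  r_B <- cT * cp$k_M * cp$g / (3 * (state$e + cp$g))
  r_B * (state$e - state$l)
}

#' Egg production rate of a mature female
#'
#' `dR/dt = R_M / (1 - l_p^3) * ((g + l) / (g + e) * e * l^2 - l_p^3)`,
#' multiplied by the Arrhenius factor (the maximum reproduction rate is a
#' rate and scales with temperature like every other rate), clamped at 0
#' from below and exactly 0 before puberty (`l < l_p`). At `(e, l) = (1, 1)`
#' the bracket reduces to `1 - l_p^3`, so the rate equals `R_M`.
#'
#' @inheritParams reserve_rate
#' @return dR/dt (eggs d^-1).
#' @export
reproduction_rate <- function(state, T_c, params) {
  cT <- temperature_correction(T_c, params)
  g <- compound_params(params)$g
  lp3 <- params$l_p^3
  raw <- cT * params$R_M / (1 - lp3) *
    ((g + state$l) / (g + state$e) * state$e * state$l^2 - lp3)
  ifelse(state$l < params$l_p, 0, pmax(raw, 0))
}

#' Individual effective functional response
#'
#' Applies the per-fish energy-acquisition scatter and, for post-puberty
#' males, the appetite factor `f_lim`, then clamps to `[0, 1]`:
#' `f_ind = clamp(scatter * f * (f_lim if adult male else 1))`.
#'
#' @param f population-level functional response in `[0, 1]`.
#' @param state a [deb_state()] (uses `is_male`, `past_puberty`).
#' @param scatter positive per-individual multiplier(s).
#' @param params a [deb_params()] object (uses `f_lim`).
#' @return Individual functional response(s) in `[0, 1]`.
#' @export
effective_f <- function(f, state, scatter = 1, params) {
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  if (any(scatter <= 0)) stop("scatter must be > 0", call. = FALSE)
  male_factor <- ifelse(state$is_male & state$past_puberty, params$f_lim, 1)
  clamp(scatter * f * male_factor, 0, 1)
}

# Euler kernel shared by step_deb(), simulate_deb() and the IBM growth phase;
# thin wrapper over the compiled loop. e, l, R, f: vectors; female: logical
# (R accrues only for females; l >= l_p gates puberty inside the kernel).
# Parameter fields may be vectors for batch parameter sweeps.
deb_euler <- function(e, l, R, f, cT, params, cp, dt, substeps, female = TRUE) {
  n <- length(e)
  cpp_deb_euler(e, l, R, rep_len(as.numeric(f), n), as.numeric(cT),
                as.logical(female), as.numeric(params$l_b),
                as.numeric(params$l_p), as.numeric(params$l_f),
                as.numeric(params$alpha), as.numeric(cp$g),
                as.numeric(cp$k_M), as.numeric(params$R_M), dt,
                as.integer(substeps))
}

#' Advance an energy-budget state by explicit fixed-step integration
#'
#' Forward-Euler update of `(e, l, R)` over `dt` days using
#' [reserve_rate()], [growth_rate()] and [reproduction_rate()], with the
#' model's native sub-step of 1/10 day by default. The scaled length is
#' floored at a small positive value and the egg buffer is monotone
#' non-decreasing (spawning, which empties it, is an IBM event, not an
#' energy-budget flux).
#'
#' @param state a [deb_state()].
#' @param f functional response in `[0, 1]` (vectorised over individuals).
#' @param T_c water temperature, degrees Celsius.
#' @param dt time step (d).
#' @param substeps number of Euler sub-steps (default 10 per day).
#' @param params a [deb_params()] object.
#' @return The advanced [deb_state()].
#' @export
step_deb <- function(state, f, T_c, dt = 1, substeps = round(10 * dt),
                     params = deb_params()) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  substeps <- max(1L, as.integer(substeps))
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  cT <- temperature_correction(T_c, params)
  cp <- compound_params(params)
  female <- !state$is_male
  out <- deb_euler(state$e, state$l, state$R, f, cT, params, cp, dt, substeps,
                   female = female)
  state$e <- out$e
  state$l <- out$l
  state$R <- out$R
  state
}

#' Simulate energy-budget trajectories at constant food and temperature
#'
#' Batch integrator used by the sensitivity, calibration and fixture layers:
#' each of `n` columns is an independent individual/parameter combination
#' held at constant functional response and temperature. Parameter fields
#' may be scalars or length-`n` vectors, so whole Sobol/Morris designs are
#' integrated in one vectorised pass.
#'
#' @param times increasing vector of output times (d), measured from the
#'   start of the simulation.
#' @param f,T_c functional response and temperature, scalar or length `n`.
#' @param params a [deb_params()] object or a named list whose fields are
#'   scalars or length-`n` vectors.
#' @param e0,l0,R0 initial state, scalar or length `n` (defaults: freshly
#'   fed fish at first feeding).
#' @param male logical, scalar or length `n`; post-puberty males have their
#'   `f` multiplied by `f_lim` and accrue no eggs.
#' @param dt Euler sub-step (d), default 0.1.
#' @return A list with `times` and matrices `e`, `l`, `R`, `L`
#'   (`length(times)` x `n`), where `L` is physical length in mm.
#' @export
simulate_deb <- function(times, f = 1, T_c = 19.85, params = deb_params(),
                         e0 = 1, l0 = params$l_b, R0 = 0, male = FALSE,
                         dt = 0.1) {
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    stop("times must be strictly increasing and non-negative", call. = FALSE)
  }
  n <- max(length(f), length(T_c), length(e0), length(l0), length(male),
           lengths(unclass(params)))
  e <- rep_len(e0, n); l <- rep_len(l0, n); R <- rep_len(R0, n)
  f <- rep_len(f, n); male <- rep_len(male, n)
  cT <- rep_len(temperature_correction(T_c, params), n)
  cp <- compound_params(params)
  f_eff <- ifelse(male, params$f_lim * f, f)
  out_e <- out_l <- out_R <- matrix(NA_real_, length(times), n)
  t_now <- 0
  for (k in seq_along(times)) {
    span <- times[k] - t_now
    if (span > 0) {
      nsub <- max(1L, ceiling(span / dt))
      st <- deb_euler(e, l, R, f_eff, cT, params, cp, span, nsub,
                      female = !male)
      e <- st$e; l <- st$l; R <- st$R
      t_now <- times[k]
    }
    out_e[k, ] <- e; out_l[k, ] <- l; out_R[k, ] <- R
  }
  list(times = times, e = out_e, l = out_l, R = out_R,
       L = sweep(out_l, 2, rep_len(cp$L_inf, n), `*`))
}

#' Length-mass allometry
#'
#' `W = exp(W_a * log(L) + W_b)` with natural logarithms, standard length in
#' mm and wet mass in mg (the only convention that places a 30 mm fish near
#' 0.3 g). `mass_length()` is the exact inverse.
#'
#' @param L standard length (mm), > 0.
#' @param W wet mass (mg), > 0.
#' @param W_a allometric slope (log-mass per log-length).
#' @param W_b allometric intercept (log mg).
#' @return Wet mass in mg (or length in mm for the inverse).
#' @export
length_mass <- function(L, W_a = 3.205, W_b = -5.193) {
  if (any(!is.finite(L)) || any(L <= 0)) {
    stop("length must be positive and finite", call. = FALSE)
  }
  exp(W_a * log(L) + W_b)
}

#' @rdname length_mass
#' @export
mass_length <- function(W, W_a = 3.205, W_b = -5.193) {
  if (any(!is.finite(W)) || any(W <= 0)) {
    stop("mass must be positive and finite", call. = FALSE)
  }
  exp((log(W) - W_b) / W_a)
}
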