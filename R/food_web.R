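#' Parameters of the pond food sub-model
#'
#' All constants of the two-pool (autotrophic/heterotrophic) pond food web
#' with dissolved and sediment N and P cycling, following the classic
#' pond-aquaculture structure, plus the pond geometry and the monsoon input
#' fraction. Every rate constant drives exactly one flux in
#' [step_food_day()], so coverage is auditable.
#'
#' @param G2Kcal energy content of fish tissue (kcal g^-1).
#' @param s proportionality of food demand to fish biomass (-): the
#'   population functional response is `F / (F + s * B)`.
#' @param h_n,h_p Monod half-saturation constants for dissolved N and P
#'   (mg L^-1).
#' @param K_n N-fixation coefficient of phytoplankton (g kcal^-1 d^-1).
#' @param K_fn N content of fish food converted to excretion (g kcal^-1).
#' @param K_an,K_hn N content of autotrophic / heterotrophic material
#'   (g kcal^-1).
#' @param K_sn release rate of sediment N (d^-1).
#' @param K_nl loss rate of dissolved inorganic N to air (d^-1).
#' @param K_ap,K_hp P content of autotrophic / heterotrophic material
#'   (g kcal^-1).
#' @param K_pr sediment P release velocity (m d^-1).
#' @param K_ps dissolved P sedimentation velocity (m d^-1).
#' @param K_s sedimentation rate of heterotrophic food (d^-1).
#' @param K_d decomposition rate of heterotrophic food (d^-1).
#' @param lambda_max maximum phytoplankton growth rate (d^-1).
#' @param K_r phytoplankton respiration rate (d^-1).
#' @param K_ml transfer rate of autotrophic into heterotrophic food (d^-1).
#' @param Ir reference solar radiation (1e6 cal m^-2 d^-1); daily radiation
#'   is taken proportional to photoperiod / 12 h.
#' @param Ir_a,Ir_b light-extinction coefficients of the autotrophic and
#'   heterotrophic pools (pond kcal^-1).
#' @param T_opta optimal temperature for phytoplankton growth (degrees C).
#' @param k_T1,K_T2 curvature of the temperature response below/above
#'   `T_opta` (degrees C^-2).
#' @param F_inputs fraction of the reference nutrient stocks delivered to the
#'   water column on each monsoon day (-).
#' @param N_ref,P_ref reference nutrient stocks (g) scaling the monsoon
#'   inputs.
#' @param pond_area,pond_volume pond surface (m^2) and volume (m^3).
#' @return An object of class `food_params`.
#' @export
food_params <- function(G2Kcal = 1.88, s = 21.08, h_n = 0.2, h_p = 0.02,
                        K_n = 0.01, K_fn = 0.017, K_an = 0.0224,
                        K_hn = 0.0192, K_sn = 0.003, K_nl = 0.17,
                        K_ap = 0.001, K_hp = 0.001, K_pr = 0.0006,
                        K_ps = 0.28, K_s = 0.14, K_d = 0.12,
                        lambda_max = 1.6, K_r = 0.1, K_ml = 0.6,
                        Ir = 6.547, Ir_a = 0.000017, Ir_b = 0.000015,
                        T_opta = 30, k_T1 = 0.004, K_T2 = 0.008,
                        F_inputs = 0.0142, N_ref = 1000, P_ref = 100,
                        pond_area = 36, pond_volume = 18) {
  p <- as.list(environment())
  for (nm in names(p)) stop_if_not_number(p[[nm]], nm, lo = 0)
  structure(p, class = "food_params")
}

#' State of the pond food web
#'
#' @param A autotrophic food energy (kcal pond^-1).
#' @param H heterotrophic food energy (kcal pond^-1).
#' @param N_w,P_w dissolved inorganic N and P (mg L^-1).
#' @param N_s,P_s sediment N and P (g pond^-1).
#' @return An object of class `food_state`. Defaults are the package's
#'   pond initial conditions (a moderately eutrophic 36 m^2 pond).
#' @export
food_state <- function(A = 20000, H = 10000, N_w = 0.5, P_w = 0.05,
                       N_s = 2000, P_s = 5000) {
  s <- list(A = A, H = H, N_w = N_w, P_w = P_w, N_s = N_s, P_s = P_s)
  for (nm in names(s)) stop_if_not_number(s[[nm]], nm, lo = 0)
  structure(s, class = "food_state")
}

#' Temperature response of phytoplankton growth
#'
#' Gaussian-type response around the optimum:
#' `exp(-k_T1 * (T_opta - T)^2)` below the optimum and
#' `exp(-K_T2 * (T - T_opta)^2)` above it.
#'
#' @param T_c water temperature (degrees C), vectorised.
#' @param params a [food_params()] object.
#' @return Factor in (0, 1].
#' @export
temperature_factor <- function(T_c, params) {
  ifelse(T_c < params$T_opta,
         exp(-params$k_T1 * (params$T_opta - T_c)^2),
         exp(-params$K_T2 * (T_c - params$T_opta)^2))
}

#' Liebig nutrient limitation of phytoplankton growth
#'
#' Minimum of the two Monod terms `N_w / (h_n + N_w)` and
#' `P_w / (h_p + P_w)`.
#'
#' @param N_w,P_w dissolved N and P (mg L^-1), vectorised.
#' @param params a [food_params()] object.
#' @return Factor in `[0, 1)`.
#' @export
nutrient_limitation <- function(N_w, P_w, params) {
  if (any(N_w < 0) || any(P_w < 0)) {
    stop("nutrient concentrations must be >= 0", call. = FALSE)
  }
  pmin(N_w / (params$h_n + N_w), P_w / (params$h_p + P_w))
}

#' Light limitation with self-shading
#'
#' `min(1, I_day / Ir) * exp(-(Ir_a * A + Ir_b * H))`, where the daily solar
#' input `I_day` is proportional to photoperiod (equal to the reference
#' radiation `Ir` at a 12 h day).
#'
#' @param A,H autotrophic and heterotrophic pool sizes (kcal).
#' @param photoperiod day length (h).
#' @param params a [food_params()] object.
#' @return Factor in `[0, 1]`.
#' @export
light_factor <- function(A, H, photoperiod, params) {
  I_rel <- pmin(1, photoperiod / 12)
  I_rel * exp(-(params$Ir_a * A + params$Ir_b * H))
}

#' Population-level scaled functional response
#'
#' The pond's food is shared by all fish in proportion to their need
#' (paralleling feeding): one daily `f = F / (F + s * B)` with `F` the total
#' food energy and `B` the fish biomass in kcal. `f = 1` for fish-free ponds
#' with food, and 0 by convention when both arguments vanish.
#'
#' @param F_total available food energy, `A + H` (kcal).
#' @param biomass_kcal total fish biomass (kcal; `G2Kcal` x grams).
#' @param params a [food_params()] object.
#' @return `f` in `[0, 1]`.
#' @export
population_f <- function(F_total, biomass_kcal, params) {
  if (any(F_total < 0) || any(biomass_kcal < 0)) {
    stop("food and biomass must be >= 0", call. = FALSE)
  }
  denom <- F_total + params$s * biomass_kcal
  ifelse(denom == 0, 0, F_total / denom)
}

#' One-day explicit update of the pond food web
#'
#' Advances the six pools by one day. Fluxes (all per day): phytoplankton
#' growth `lambda_max * min(light, nutrient) * temperature_factor * A`,
#' respiration `K_r * A`, transfer to the heterotrophic pool `K_ml * A`,
#' heterotroph sedimentation `K_s * H` and decomposition `K_d * H`; the N
#' budget receives atmospheric fixation `K_n * A`, sediment release
#' `K_sn * N_s`, decomposition return `K_hn * K_d * H` and fish excretion
#' `K_fn * consumption`, and loses phytoplankton uptake `K_an * growth` and
#' atmospheric loss `K_nl * N_w`; the P budget is analogous with `K_ap`,
#' `K_hp` and the area-scaled exchange velocities `K_pr` (sediment release)
#' and `K_ps` (sedimentation). Monsoon days add `F_inputs` of the reference
#' stocks to the dissolved pools. Fish consumption is removed from `A` and
#' `H` proportionally to their sizes. Phytoplankton growth is additionally
#' capped so that one day's uptake cannot exceed the nutrients available in
#' the water column (a hard Liebig quota preventing explicit-step
#' overshoot). All pools are floored at zero (a flooring event beyond
#' numerical tolerance raises a mass-balance warning).
#'
#' @param state a [food_state()].
#' @param T_c water temperature (degrees C).
#' @param photoperiod day length (h).
#' @param consumption_kcal fish food consumption this day (kcal), at most
#'   `A + H`.
#' @param monsoon logical: is the monsoon input window active?
#' @param params a [food_params()] object.
#' @param fixation logical: include atmospheric N fixation (`K_n * A`)?
#'   Disable together with `monsoon` for a closed-system budget check.
#' @return The advanced [food_state()], with an attribute `"fluxes"` (named
#'   vector of every flux in g or kcal) supporting exact budget bookkeeping.
#' @export
step_food_day <- function(state, T_c, photoperiod, consumption_kcal = 0,
                          monsoon = FALSE, params = food_params(),
                          fixation = TRUE) {
  if (consumption_kcal < 0) stop("consumption must be >= 0", call. = FALSE)
  F_total <- state$A + state$H
  if (consumption_kcal > F_total + 1e-9) {
    stop("consumption exceeds available food", call. = FALSE)
  }
  V <- params$pond_volume      # m^3; mg/L * m^3 = g
  area <- params$pond_area

  light <- light_factor(state$A, state$H, photoperiod, params)
  nutr <- nutrient_limitation(state$N_w, state$P_w, params)
  tfac <- temperature_factor(T_c, params)
  growth <- params$lambda_max * min(light, nutr) * tfac * state$A
  resp <- params$K_r * state$A
  transfer <- params$K_ml * state$A
  sedH <- params$K_s * state$H
  decH <- params$K_d * state$H
  consA <- if (F_total > 0) consumption_kcal * state$A / F_total else 0
  consH <- consumption_kcal - consA

  N_w_g <- state$N_w * V
  P_w_g <- state$P_w * V
  fix <- if (fixation) params$K_n * state$A else 0
  releaseN <- params$K_sn * state$N_s
  returnN <- params$K_hn * decH
  excrN <- params$K_fn * consumption_kcal
  lossN <- params$K_nl * N_w_g
  sedN <- params$K_hn * sedH
  returnP <- params$K_hp * decH
  releaseP <- params$K_pr * area / V * state$P_s
  sedP_w <- params$K_ps * area / V * P_w_g
  sedP <- params$K_hp * sedH
  inN <- if (monsoon) params$F_inputs * params$N_ref else 0
  inP <- if (monsoon) params$F_inputs * params$P_ref else 0
  # hard Liebig cap: within one explicit day-step the bloom cannot take up
  # more N or P than the water column holds (keeps the budget exact)
  availN <- max(0, N_w_g + fix + releaseN + returnN + excrN + inN - lossN)
  availP <- max(0, P_w_g + returnP + releaseP + inP - sedP_w)
  if (params$K_an > 0) growth <- min(growth, availN / params$K_an)
  if (params$K_ap > 0) growth <- min(growth, availP / params$K_ap)
  uptakeN <- params$K_an * growth
  uptakeP <- params$K_ap * growth

  new <- list(
    A = state$A + growth - resp - transfer - consA,
    H = state$H + transfer - sedH - decH - consH,
    N_w = (N_w_g + fix + releaseN + returnN + excrN + inN - uptakeN - lossN) / V,
    P_w = (P_w_g + returnP + releaseP + inP - uptakeP - sedP_w) / V,
    N_s = state$N_s + sedN - releaseN,
    P_s = state$P_s + sedP + sedP_w - releaseP
  )
  low <- vapply(new, function(x) x < -1e-6, logical(1))
  if (any(low)) {
    warning("food-web mass balance: pool(s) floored at zero: ",
            paste(names(new)[low], collapse = ", "), call. = FALSE)
  }
  out <- food_state(A = max(new$A, 0), H = max(new$H, 0),
                    N_w = max(new$N_w, 0), P_w = max(new$P_w, 0),
                    N_s = max(new$N_s, 0), P_s = max(new$P_s, 0))
  attr(out, "fluxes") <- c(growth = growth, respiration = resp,
                           transfer = transfer, sed_H = sedH, dec_H = decH,
                           cons_A = consA, cons_H = consH, fix_N = fix,
                           uptake_N = uptakeN, release_N = releaseN,
                           return_N = returnN, excretion_N = excrN,
                           loss_N = lossN, sed_N = sedN,
                           uptake_P = uptakeP, return_P = returnP,
                           release_P = releaseP, sed_P_w = sedP_w,
                           sed_P = sedP, input_N = inN, input_P = inP)
  out
}

#' Total N and P inventories of the pond
#'
#' Sums dissolved, sediment and pool-bound nutrients (pools weighted by
#' their N/P content coefficients). Used by the closed-system budget checks.
#'
#' @param state a [food_state()].
#' @param params a [food_params()] object.
#' @return Named vector `c(N = , P = )` in grams.
#' @export
nutrient_totals <- function(state, params = food_params()) {
  V <- params$pond_volume
  c(N = state$N_w * V + state$N_s + params$K_an * state$A +
      params$K_hn * state$H,
    P = state$P_w * V + state$P_s + params$K_ap * state$A +
      params$K_hp * state$H)
}
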