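#' Parameters of the individual-based population model
#'
#' Pond geometry, initial population, reproduction thresholds, survival
#' constants, sex-determination constants, incubation degree-day constants
#' and the length-mass allometry. Defaults are the package's zebrafish pond
#' configuration (a 36 m^2, 0.5 m deep vegetated pond of 900 patches).
#'
#' @param W_d water depth (m).
#' @param W_v water volume (m^3).
#' @param grid_dim side of the square patch grid (30 -> 900 patches of
#'   20 x 20 cm).
#' @param Np_b,Np_v number of breeding-ground and vegetation-cover patches.
#' @param Nb_j,Nb_m,Nb_f initial numbers of juveniles, males and females.
#' @param End default simulation duration (d).
#' @param sigma log-sd of the lognormal inter-individual energy-acquisition
#'   scatter (median 1).
#' @param P_tau,T_tau photoperiod (h) and temperature (degrees C) thresholds
#'   gating reproduction.
#' @param H_half female biomass density inducing a 50 percent reduction of
#'   hatching (g m^-3).
#' @param H_max optimal hatching rate (-).
#' @param R_tau egg-buffer threshold and fixed clutch size (eggs).
#' @param SR_mu,SR_sigma mean and sd of the genetic male propensity
#'   (percent, truncated to `[0, 100]`).
#' @param SR_a,SR_b slope (degrees C^-1) and pivot temperature (degrees C)
#'   of the thermal effect on the brood male fraction.
#' @param pi_a natural mortality probability scale (d^-1).
#' @param pi_b allometric scaling exponent of mortality with mass (-).
#' @param pi_c density-independent mortality constant (d^-1).
#' @param pi_d density-dependent mortality constant for juveniles
#'   ((g m^-3)^-1 d^-1).
#' @param pi_p daily egg predation probability (d^-1).
#' @param pi_e,pi_g senescence slope (d^-2) and onset age (d).
#' @param H_a incubation requirement (degree-days above `H_b`).
#' @param H_b degree-day base temperature (degrees C).
#' @param W_a,W_b slope and intercept of the ln-mass / ln-length allometry
#'   (mass mg, length mm).
#' @param init_juvenile_l,init_adult_l scaled-length ranges for the founders;
#'   `NULL` means `(l_b, l_p)` and `(l_p, 0.9)` from the energy-budget
#'   parameters.
#' @param init_e initial scaled reserve density of the founders.
#' @return An object of class `ibm_params`.
#' @export
ibm_params <- function(W_d = 0.5, W_v = 18, grid_dim = 30, Np_b = 207,
                       Np_v = 207, Nb_j = 300, Nb_m = 35, Nb_f = 35,
                       End = 1110, sigma = 0.235, P_tau = 12, T_tau = 22.5,
                       H_half = 24, H_max = 0.89, R_tau = 263,
                       SR_mu = 50, SR_sigma = 23.1, SR_a = -0.0496,
                       SR_b = 27.9, pi_a = 0.0292, pi_b = -0.382,
                       pi_c = 0.9576, pi_d = 0.0089, pi_p = 0.025,
                       pi_e = 2.839e-6, pi_g = 550, H_a = 60.9, H_b = 10.3,
                       W_a = 3.205, W_b = -5.193,
                       init_juvenile_l = NULL, init_adult_l = NULL,
                       init_e = 0.9) {
  p <- as.list(environment())
  num <- setdiff(names(p), c("pi_b", "SR_a", "W_b", "init_juvenile_l",
                             "init_adult_l"))
  for (nm in num) stop_if_not_number(p[[nm]], nm, lo = 0)
  for (nm in c("pi_b", "SR_a", "W_b")) stop_if_not_number(p[[nm]], nm)
  if (p$Np_b + p$Np_v > p$grid_dim^2) {
    stop("more breeding + vegetation patches than grid patches", call. = FALSE)
  }
  if (p$H_max > 1 || p$pi_p > 1) {
    stop("H_max and pi_p are probabilities and must be <= 1", call. = FALSE)
  }
  structure(p, class = "ibm_params")
}
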