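#' Primary parameters of the zebrafish energy-budget model
#'
#' Constructs and validates the primary parameter set of the individual
#' energy-budget (DEB) model. Defaults are the fitted/fixed values for
#' zebrafish (AB strain): an Arrhenius temperature correction, a
#' surface-specific assimilation rate, energy conductance, the kappa
#' allocation rule, a size-dependent ingestion reduction (the package's
#' sigmoid-growth mechanism), and fixed scaled lengths at first feeding,
#' half-maximal assimilation and puberty.
#'
#' @param T_A Arrhenius temperature (K).
#' @param T_R reference temperature (K); rates are uncorrected at this
#'   body temperature.
#' @param delta shape coefficient (-), structural length = delta * physical
#'   length.
#' @param p_Am maximum surface-specific assimilation rate (J d^-1 mm^-2).
#' @param v_dot energy conductance (mm d^-1).
#' @param kappa fraction of mobilised reserve allocated to soma (-).
#' @param alpha fraction of food accessible at first feeding (-).
#' @param l_b,l_p,l_f scaled lengths at first feeding, puberty and
#'   half-maximal assimilation (-); must satisfy `l_b < l_f < l_p < 1`.
#' @param p_M volume-specific somatic maintenance rate (J d^-1 mm^-3).
#' @param E_G volume-specific cost of structure (J mm^-3).
#' @param E_0 initial energy content of an egg (J).
#' @param L_0 initial (egg) physical length (mm).
#' @param R_M maximum reproduction rate (eggs d^-1).
#' @param f_lim male appetite factor applied to the functional response
#'   after puberty (-).
#'
#' @return An object of class `deb_params` (a validated named list).
#' @seealso [compound_params()], [step_deb()]
#' @export
#' @examples
#' p <- deb_params()
#' compound_params(p)$L_inf # maximum physical length, mm
deb_params <- function(T_A = 3000, T_R = 293, delta = 0.20, p_Am = 4.72,
                       v_dot = 0.60, kappa = 0.70, alpha = 0.84,
                       l_b = 0.079, l_p = 0.58, l_f = 0.163,
                       p_M = 0.44, E_G = 2.35, E_0 = 1.25, L_0 = 0.25,
                       R_M = 406, f_lim = 0.92) {
  p <- list(T_A = T_A, T_R = T_R, delta = delta, p_Am = p_Am, v_dot = v_dot,
            kappa = kappa, alpha = alpha, l_b = l_b, l_p = l_p, l_f = l_f,
            p_M = p_M, E_G = E_G, E_0 = E_0, L_0 = L_0, R_M = R_M,
            f_lim = f_lim)
  for (nm in names(p)) stop_if_not_number(p[[nm]], nm, lo = .Machine$double.xmin)
  for (nm in c("kappa", "alpha", "f_lim", "l_b", "l_p", "l_f")) {
    if (p[[nm]] > 1) stop(sprintf("'%s' must be in (0, 1]", nm), call. = FALSE)
  }
  if (!(p$l_b < p$l_f && p$l_f < p$l_p && p$l_p < 1)) {
    stop("scaled lengths must satisfy l_b < l_f < l_p < 1", call. = FALSE)
  }
  structure(p, class = "deb_params")
}

#' Compound parameters derived from the primary energy-budget parameters
#'
#' Standard derived quantities: maximum reserve density `E_m = p_Am / v_dot`,
#' energy investment ratio `g = E_G / (kappa * E_m)`, maintenance rate
#' coefficient `k_M = p_M / E_G`, maximum structural length
#' `L_m = kappa * p_Am / p_M`, and maximum physical length
#' `L_inf = L_m / delta`.
#'
#' @param params a [deb_params()] object, or a named list of numeric vectors
#'   with the same fields (vectors are supported so that batches of parameter
#'   sets can be processed at once).
#' @return A list with elements `g`, `k_M`, `E_m`, `L_m`, `L_inf`.
#' @export
compound_params <- function(params) {
  E_m <- params$p_Am / params$v_dot
  g <- params$E_G / (params$kappa * E_m)
  k_M <- params$p_M / params$E_G
  L_m <- params$kappa * params$p_Am / params$p_M
  list(g = g, k_M = k_M, E_m = E_m, L_m = L_m, L_inf = L_m / params$delta)
}

#' @export
print.deb_params <- function(x, ...) {
  cat("Zebrafish energy-budget parameters\n")
  cp <- compound_params(x)
  df <- data.frame(value = unlist(x))
  print(df)
  cat(sprintf("derived: g = %.4f, k_M = %.5f d^-1, L_inf = %.2f mm\n",
              cp$g, cp$k_M, cp$L_inf))
  invisible(x)
}
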