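# shared fixtures for the test suite (built in code, no stored data)

default_deb <- deb_params()
default_cp <- compound_params(default_deb)
T_REF_C <- default_deb$T_R - 273.15 # 19.85 degC: correction factor is 1

# a tiny pond configuration that runs in well under a second
tiny_ibm <- function(...) {
  ibm_params(Nb_j = 30, Nb_m = 6, Nb_f = 6, ...)
}

# deterministic two-year forcing shared across tests
test_series <- generate_monsoon_scenario(years = 2)

# analytic Ishigami sensitivity indices (variance decomposition in closed
# form), the standard oracle for Sobol estimators
ishigami_fn <- function(X, a = 7, b = 0.1) {
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
}
ishigami_true <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V <- V1 + V2 + b^2 * pi^8 * (1 / 18 - 1 / 50)
  c(S1 = V1 / V, S2 = V2 / V, S3 = 0,
    ST1 = (V1 + b^2 * pi^8 * (1 / 18 - 1 / 50)) / V, ST2 = V2 / V)
}
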