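#' Define a sensitivity-analysis design
#'
#' Holds parameter names and ranges for a Morris elementary-effects screening
#' or a Sobol variance-decomposition analysis. A "dummy" parameter with no
#' influence on any model output is appended by default as a negative
#' control: its indices estimate the noise floor of the analysis.
#'
#' @param names parameter names.
#' @param lower,upper numeric bounds per parameter (finite, `lower < upper`).
#' @param method `"morris"` or `"sobol"`.
#' @param r number of Morris trajectories (>= 2).
#' @param levels number of Morris grid levels (even).
#' @param N Sobol base sample size.
#' @param seed integer seed used when generating the evaluation plan.
#' @param dummy append the dummy control parameter?
#' @return An object of class `sensitivity_design`.
#' @export
sensitivity_design <- function(names, lower, upper,
                               method = c("morris", "sobol"),
                               r = 20, levels = 8, N = 1024, seed = 1,
                               dummy = TRUE) {
  method <- match.arg(method)
  if (length(lower) != length(names) || length(upper) != length(names)) {
    stop("names, lower and upper must have equal length", call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop("ranges must be finite with lower < upper", call. = FALSE)
  }
  if (dummy && !"dummy" %in% names) {
    names <- c(names, "dummy")
    lower <- c(lower, 0)
    upper <- c(upper, 1)
  }
  if (method == "morris") {
    if (r < 2) stop("need at least 2 Morris trajectories", call. = FALSE)
    if (levels %% 2 != 0) stop("Morris levels must be even", call. = FALSE)
  }
  structure(list(names = names, lower = lower, upper = upper, method = method,
                 r = r, levels = levels, N = N, seed = seed),
            class = "sensitivity_design")
}

#' Morris one-at-a-time evaluation plan
#'
#' Builds `r` randomised trajectories of `k + 1` points each on a `levels`
#' grid: consecutive points within a trajectory differ in exactly one
#' coordinate by the standard step `delta = levels / (2 * (levels - 1))` (in
#' unit space), scaled to the parameter ranges.
#'
#' @param design a `"morris"` [sensitivity_design()].
#' @return A matrix of evaluation points (`r * (k + 1)` rows, one column per
#'   parameter), with attributes `trajectory`, `changed` (which parameter
#'   moved at each point) and `delta_signed` (the signed unit-space step).
#' @export
morris_design <- function(design) {
  stopifnot(inherits(design, "sensitivity_design"), design$method == "morris")
  set.seed(design$seed)
  k <- length(design$names)
  p <- design$levels
  delta <- p / (2 * (p - 1))
  grid0 <- seq(0, 1 - delta, length.out = p / 2) # base levels allowing +delta
  rows <- design$r * (k + 1)
  X <- matrix(NA_real_, rows, k, dimnames = list(NULL, design$names))
  changed <- integer(rows)
  dsign <- numeric(rows)
  traj <- rep(seq_len(design$r), each = k + 1)
  at <- 1L
  for (t in seq_len(design$r)) {
    x <- grid0[sample.int(length(grid0), k, replace = TRUE)]
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    # shift down-moves up so every move stays in [0, 1]
    x <- ifelse(sgn < 0, x + delta, x)
    order_k <- sample.int(k)
    X[at, ] <- x; changed[at] <- 0L; dsign[at] <- 0
    at <- at + 1L
    for (j in order_k) {
      x[j] <- x[j] + sgn[j] * delta
      X[at, ] <- x
      changed[at] <- j
      dsign[at] <- sgn[j] * delta
      at <- at + 1L
    }
  }
  X_scaled <- sweep(sweep(X, 2, design$upper - design$lower, `*`), 2,
                    design$lower, `+`)
  attr(X_scaled, "trajectory") <- traj
  attr(X_scaled, "changed") <- changed
  attr(X_scaled, "delta_signed") <- dsign
  attr(X_scaled, "design") <- design
  X_scaled
}

#' Morris elementary effects
#'
#' Computes, per parameter and output, the elementary effects normalised by
#' the unit-space step: the mean `mu`, the mean absolute value `mu_star`,
#' the standard deviation `sigma`, and a composite global index
#' `sqrt(mu_star^2 + sigma^2)` used for ranking.
#'
#' @param plan the matrix returned by [morris_design()].
#' @param outputs numeric vector or matrix (one column per model output, one
#'   row per plan row).
#' @return A data.frame with columns `parameter`, `output`, `mu`, `mu_star`,
#'   `sigma`, `global`.
#' @export
morris_effects <- function(plan, outputs) {
  design <- attr(plan, "design")
  changed <- attr(plan, "changed")
  dsign <- attr(plan, "delta_signed")
  outputs <- as.matrix(outputs)
  if (nrow(outputs) != nrow(plan)) {
    missing_pts <- nrow(plan) - nrow(outputs)
    stop(sprintf("outputs do not match the plan: %d evaluation(s) missing",
                 missing_pts), call. = FALSE)
  }
  if (any(!is.finite(outputs))) {
    stop("non-finite model outputs at plan rows: ",
         paste(utils::head(which(rowSums(!is.finite(outputs)) > 0), 10),
               collapse = ", "), call. = FALSE)
  }
  k <- ncol(plan)
  nout <- ncol(outputs)
  onames <- colnames(outputs) %||% paste0("y", seq_len(nout))
  res <- vector("list", nout)
  steps <- which(changed > 0L)
  for (o in seq_len(nout)) {
    ee <- (outputs[steps, o] - outputs[steps - 1L, o]) / dsign[steps]
    par <- changed[steps]
    mu <- tapply(ee, par, mean)
    mu_star <- tapply(abs(ee), par, mean)
    sigma <- tapply(ee, par, stats::sd)
    res[[o]] <- data.frame(parameter = design$names[as.integer(names(mu))],
                           output = onames[o], mu = as.numeric(mu),
                           mu_star = as.numeric(mu_star),
                           sigma = as.numeric(sigma),
                           global = sqrt(as.numeric(mu_star)^2 +
                                           as.numeric(sigma)^2))
  }
  do.call(rbind, res)
}

#' Saltelli paired-matrix evaluation plan for Sobol indices
#'
#' Stacks the base matrices `A`, `B` and the `k` hybrid matrices `AB_i`
#' (column `i` of `A` replaced by column `i` of `B`), giving `(k + 2) * N`
#' evaluation points.
#'
#' @param design a `"sobol"` [sensitivity_design()].
#' @return Evaluation matrix with attribute `design`.
#' @export
sobol_design <- function(design) {
  stopifnot(inherits(design, "sensitivity_design"), design$method == "sobol")
  set.seed(design$seed)
  k <- length(design$names)
  N <- design$N
  A <- matrix(stats::runif(N * k), N, k)
  B <- matrix(stats::runif(N * k), N, k)
  X <- rbind(A, B)
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    X <- rbind(X, ABi)
  }
  colnames(X) <- design$names
  X <- sweep(sweep(X, 2, design$upper - design$lower, `*`), 2, design$lower,
             `+`)
  attr(X, "design") <- design
  X
}

#' First-order and total Sobol sensitivity indices
#'
#' Jansen estimators on the Saltelli paired design:
#' `Si = (V - mean((f_B - f_ABi)^2) / 2) / V` and
#' `STi = mean((f_A - f_ABi)^2) / (2 * V)`. With small base samples
#' (`N < 100`) bootstrap confidence intervals are attached and a warning is
#' raised.
#'
#' @param plan the matrix returned by [sobol_design()].
#' @param outputs numeric vector or matrix of model outputs aligned with the
#'   plan rows.
#' @param boot number of bootstrap resamples for small-sample CIs.
#' @return A data.frame with columns `parameter`, `output`, `Si`, `STi` (and
#'   bootstrap 95 percent CI columns for small `N`).
#' @export
sobol_indices <- function(plan, outputs, boot = 200) {
  design <- attr(plan, "design")
  outputs <- as.matrix(outputs)
  if (nrow(outputs) != nrow(plan)) {
    stop("outputs do not match the Sobol plan", call. = FALSE)
  }
  k <- length(design$names)
  N <- design$N
  small <- N < 100
  if (small) {
    warning("Sobol base sample N < 100: indices are noisy, reporting ",
            "bootstrap CIs", call. = FALSE)
  }
  nout <- ncol(outputs)
  onames <- colnames(outputs) %||% paste0("y", seq_len(nout))
  res <- vector("list", nout)
  for (o in seq_len(nout)) {
    yA <- outputs[seq_len(N), o]
    yB <- outputs[N + seq_len(N), o]
    yAB <- matrix(outputs[2 * N + seq_len(N * k), o], N, k)
    est <- function(idx) {
      V <- stats::var(c(yA[idx], yB[idx]))
      Si <- (V - colMeans((yB[idx] - yAB[idx, , drop = FALSE])^2) / 2) / V
      STi <- colMeans((yA[idx] - yAB[idx, , drop = FALSE])^2) / (2 * V)
      rbind(Si, STi)
    }
    full <- est(seq_len(N))
    df <- data.frame(parameter = design$names, output = onames[o],
                     Si = full[1, ], STi = full[2, ])
    if (small) {
      bs <- replicate(boot, est(sample.int(N, N, replace = TRUE)))
      df$Si_lo <- apply(bs[1, , ], 1, stats::quantile, 0.025)
      df$Si_hi <- apply(bs[1, , ], 1, stats::quantile, 0.975)
      df$STi_lo <- apply(bs[2, , ], 1, stats::quantile, 0.025)
      df$STi_hi <- apply(bs[2, , ], 1, stats::quantile, 0.975)
    }
    res[[o]] <- df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Default screening ranges for the energy-budget sensitivity analysis
#'
#' Plus/minus a fraction (default 20 percent) around the default parameter
#' values, for the experimental temperature, the reference temperature and
#' every primary energy-budget parameter that the growth and reproduction
#' outputs depend on, plus the functional response `f`.
#'
#' @param params a [deb_params()] object.
#' @param T_exp nominal experimental temperature (degrees C).
#' @param f nominal functional response.
#' @param frac half-width of the ranges as a fraction of the nominal value.
#' @return A list with `names`, `lower`, `upper`.
#' @export
deb_sensitivity_ranges <- function(params = deb_params(), T_exp = 27,
                                   f = 0.9, frac = 0.2) {
  nominal <- c(T_exp = T_exp, T_R = params$T_R, delta = params$delta,
               p_Am = params$p_Am, v_dot = params$v_dot, kappa = params$kappa,
               alpha = params$alpha, l_b = params$l_b, l_f = params$l_f,
               p_M = params$p_M, E_G = params$E_G, R_M = params$R_M, f = f)
  lower <- nominal * (1 - frac)
  upper <- nominal * (1 + frac)
  upper["f"] <- min(upper["f"], 1)
  upper["kappa"] <- min(upper["kappa"], 1)
  upper["alpha"] <- min(upper["alpha"], 1)
  list(names = names(nominal), lower = unname(lower), upper = unname(upper))
}

#' Batch energy-budget model evaluator for sensitivity designs
#'
#' Maps each design row (columns named as in [deb_sensitivity_ranges()],
#' `dummy` ignored) to predicted physical length (mm) at the requested ages
#' and, optionally, cumulative eggs of a female.
#'
#' @param X evaluation matrix with named columns.
#' @param times ages (dpf) at which to record outputs.
#' @param output `"length"` or `"eggs"`; eggs are evaluated for a mature
#'   female (initial scaled length 0.85).
#' @param params baseline [deb_params()] supplying any parameter not present
#'   as a design column.
#' @param dt Euler sub-step (d).
#' @return Matrix of outputs, one row per design row, one column per time.
#' @export
deb_batch_output <- function(X, times = c(25, 50, 75, 100, 200, 400),
                             output = c("length", "eggs"),
                             params = deb_params(), dt = 0.1) {
  output <- match.arg(output)
  X <- as.matrix(X)
  n <- nrow(X)
  pick <- function(nm, fallback) if (nm %in% colnames(X)) X[, nm]
                                 else rep(fallback, n)
  p <- list(T_A = pick("T_A", params$T_A), T_R = pick("T_R", params$T_R),
            delta = pick("delta", params$delta),
            p_Am = pick("p_Am", params$p_Am),
            v_dot = pick("v_dot", params$v_dot),
            kappa = pick("kappa", params$kappa),
            alpha = pick("alpha", params$alpha),
            l_b = pick("l_b", params$l_b), l_p = pick("l_p", params$l_p),
            l_f = pick("l_f", params$l_f), p_M = pick("p_M", params$p_M),
            E_G = pick("E_G", params$E_G), E_0 = pick("E_0", params$E_0),
            L_0 = pick("L_0", params$L_0), R_M = pick("R_M", params$R_M),
            f_lim = pick("f_lim", params$f_lim))
  T_exp <- pick("T_exp", 27)
  f <- clamp(pick("f", 0.9), 0, 1)
  l0 <- if (output == "length") p$l_b else rep(0.85, n)
  sim <- simulate_deb(times, f = f, T_c = T_exp, params = p, e0 = 1, l0 = l0,
                      dt = dt)
  out <- if (output == "length") t(sim$L) else t(sim$R)
  colnames(out) <- paste0("t", times)
  out
}
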