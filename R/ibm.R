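# Spatial individual-based model: pond grid, life stages, movement, survival,
# incubation, sex determination, spawning, and the daily scheduler.
#
# Internal agent layout: parallel vectors (one element per living fish) in
# state$fish -- id, stage (0 juvenile / 1 female / 2 male), sex_latent (TRUE =
# will become male), age (dpf), gen, e, l, R, scatter, patch, terr (territory
# patch id for males, 0 = none). Broods are parallel vectors in state$broods.

STAGE_JUV <- 0L
STAGE_FEMALE <- 1L
STAGE_MALE <- 2L

# ---- grid ------------------------------------------------------------------

make_grid <- function(ibm) {
  n <- ibm$grid_dim
  np <- n * n
  habitat <- rep(1L, np) # 1 open, 2 vegetation, 3 breeding
  pick <- sample.int(np, ibm$Np_v + ibm$Np_b)
  habitat[pick[seq_len(ibm$Np_v)]] <- 2L
  habitat[pick[ibm$Np_v + seq_len(ibm$Np_b)]] <- 3L
  row <- ((seq_len(np) - 1L) %/% n) + 1L
  col <- ((seq_len(np) - 1L) %% n) + 1L
  neigh <- matrix(0L, np, 8)
  nneigh <- integer(np)
  offs <- cbind(rep(-1:1, each = 3), rep(-1:1, 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  for (k in seq_len(8)) {
    r2 <- row + offs[k, 1]; c2 <- col + offs[k, 2]
    ok <- r2 >= 1 & r2 <= n & c2 >= 1 & c2 <= n
    idx <- which(ok)
    nneigh[idx] <- nneigh[idx] + 1L
    neigh[cbind(idx, nneigh[idx])] <- (r2[idx] - 1L) * n + c2[idx]
  }
  # static vegetation-neighbour lookup for juvenile movement
  veg_neigh <- matrix(0L, np, 8)
  nveg <- integer(np)
  for (p in seq_len(np)) {
    vs <- neigh[p, seq_len(nneigh[p])]
    vs <- vs[habitat[vs] == 2L]
    nveg[p] <- length(vs)
    if (length(vs)) veg_neigh[p, seq_along(vs)] <- vs
  }
  list(n = n, npatch = np, habitat = habitat, neigh = neigh, nneigh = nneigh,
       veg_neigh = veg_neigh, nveg = nveg)
}

# random Moore neighbour for each patch in `patches` (vectorised)
random_neighbour <- function(grid, patches) {
  k <- 1L + as.integer(floor(stats::runif(length(patches)) *
                               grid$nneigh[patches]))
  grid$neigh[cbind(patches, k)]
}

# ---- exported demographic sub-models ---------------------------------------

#' Daily mortality probability of a fish
#'
#' Lorenzen-type size-dependent mortality `pi_a * pi_c * W^pi_b` (mass W in
#' mg), plus a density-dependent term `pi_d * D` for juveniles (D = total
#' fish biomass density, g m^-3), plus linear senescence
#' `pi_e * (age - pi_g)` beyond the ageing threshold; clamped to `[0, 1]`.
#'
#' @param mass_mg wet mass (mg), vectorised.
#' @param age age (dpf), vectorised.
#' @param juvenile logical, vectorised: does the density term apply?
#' @param biomass_density total fish biomass density (g m^-3).
#' @param params an [ibm_params()] object.
#' @return Daily death probability in `[0, 1]`.
#' @export
mortality_probability <- function(mass_mg, age, juvenile, biomass_density,
                                  params = ibm_params()) {
  m <- params$pi_a * params$pi_c * mass_mg^params$pi_b +
    params$pi_d * biomass_density * juvenile +
    params$pi_e * pmax(age - params$pi_g, 0)
  clamp(m, 0, 1)
}

#' Density-dependent hatching success
#'
#' `H_max * H_half / (H_half + density)`: the optimal hatching rate reduced
#' by half at the reference female biomass density.
#'
#' @param female_density female biomass density (g m^-3), >= 0.
#' @param params an [ibm_params()] object.
#' @return Hatching probability.
#' @export
hatch_success <- function(female_density, params = ibm_params()) {
  if (any(female_density < 0)) stop("density must be >= 0", call. = FALSE)
  params$H_max * params$H_half / (params$H_half + female_density)
}

#' Male fraction of a brood
#'
#' Genetic plus thermal sex determination: a genetic propensity
#' `G ~ Normal(SR_mu, SR_sigma)` truncated to `[0, 100]` percent, shifted by
#' the incubation temperature, `p = clamp01(G/100 + SR_a * (T - SR_b))`.
#'
#' @param T_mean mean incubation temperature (degrees C).
#' @param params an [ibm_params()] object.
#' @param n number of independent broods to draw.
#' @return Male fraction(s) in `[0, 1]`.
#' @export
brood_male_fraction <- function(T_mean, params = ibm_params(), n = 1) {
  if (params$SR_sigma == 0) {
    G <- rep(params$SR_mu, n)
  } else {
    lo <- stats::pnorm(0, params$SR_mu, params$SR_sigma)
    hi <- stats::pnorm(100, params$SR_mu, params$SR_sigma)
    G <- stats::qnorm(stats::runif(n, lo, hi), params$SR_mu, params$SR_sigma)
  }
  clamp(G / 100 + params$SR_a * (T_mean - params$SR_b), 0, 1)
}

#' Advance egg broods by one day
#'
#' Each brood suffers binomial egg predation at daily probability `pi_p`,
#' accumulates degree-days `max(0, T - H_b)`, and hatches once the
#' accumulated degree-days reach `H_a`; the hatchling count is
#' `round(n_eggs * hatch_success(female_density))`.
#'
#' @param broods a list of parallel vectors `n_eggs`, `age`, `dd`, `patch`,
#'   `gen`, `male_frac` (as held in an IBM state).
#' @param T_c water temperature (degrees C).
#' @param female_density female biomass density (g m^-3).
#' @param params an [ibm_params()] object.
#' @return A list with `broods` (surviving unhatched broods) and `hatch`
#'   (vectors `n`, `patch`, `gen`, `male_frac` describing hatching broods).
#' @export
egg_step <- function(broods, T_c, female_density, params = ibm_params()) {
  nb <- length(broods$n_eggs)
  empty <- list(n = integer(0), patch = integer(0), gen = integer(0),
                male_frac = numeric(0))
  if (nb == 0) return(list(broods = broods, hatch = empty))
  eggs <- stats::rbinom(nb, broods$n_eggs, 1 - params$pi_p)
  dd <- broods$dd + max(0, T_c - params$H_b)
  age <- broods$age + 1
  hatch_now <- dd >= params$H_a & eggs > 0L
  hs <- hatch_success(female_density, params)
  hatch <- list(n = as.integer(round(eggs[hatch_now] * hs)),
                patch = broods$patch[hatch_now],
                gen = broods$gen[hatch_now],
                male_frac = broods$male_frac[hatch_now])
  pos <- hatch$n > 0L
  hatch <- lapply(hatch, `[`, pos)
  keep <- !hatch_now & eggs > 0L
  broods <- list(n_eggs = eggs[keep], age = age[keep], dd = dd[keep],
                 patch = broods$patch[keep], gen = broods$gen[keep],
                 male_frac = broods$male_frac[keep])
  list(broods = broods, hatch = hatch)
}

#' Censored length histogram of a population
#'
#' Normalised 1-mm-class frequencies over fish longer than a sampling
#' cutoff, mirroring field length distributions in which small fish escape
#' capture. Bin edges are half-open `[k, k + bin)`.
#'
#' @param lengths numeric vector of standard lengths (mm), or an IBM state
#'   (its living fish are used).
#' @param min_length censoring cutoff (mm): only fish with
#'   `length > min_length` enter the histogram.
#' @param bin bin width (mm), default 1.
#' @return A data.frame with columns `lower` (bin lower edge) and
#'   `frequency` (sums to 1 when any fish qualify), with attributes
#'   `excluded_fraction` (fraction of fish at or below the cutoff) and
#'   `empty` (no fish qualified).
#' @export
length_histogram <- function(lengths, min_length = 18.4, bin = 1) {
  if (bin <= 0) stop("bin width must be > 0", call. = FALSE)
  if (inherits(lengths, "ibm_state")) {
    lengths <- fish_lengths(lengths)
  }
  n_all <- length(lengths)
  excl <- if (n_all) mean(lengths <= min_length) else NA_real_
  keep <- lengths[lengths > min_length]
  if (length(keep) == 0) {
    out <- data.frame(lower = numeric(0), frequency = numeric(0))
    attr(out, "excluded_fraction") <- excl
    attr(out, "empty") <- TRUE
    return(out)
  }
  lower <- floor(keep / bin) * bin
  tab <- table(lower)
  edges <- as.numeric(names(tab))
  full <- seq(min(edges), max(edges), by = bin)
  freq <- as.numeric(tab[match(full, edges)])
  freq[is.na(freq)] <- 0
  out <- data.frame(lower = full, frequency = freq / sum(freq))
  attr(out, "excluded_fraction") <- excl
  attr(out, "empty") <- FALSE
  out
}

# ---- state construction ----------------------------------------------------

fish_lengths <- function(state) {
  state$fish$l * state$cp$L_inf
}

#' Initialise a pond population
#'
#' Builds the patch grid (breeding grounds and vegetation assigned uniformly
#' at random) and places the founding population -- by default 300 juveniles,
#' 35 males and 35 females -- uniformly at random. Founder scaled lengths are
#' drawn uniformly between first feeding and puberty (juveniles) or above
#' puberty (adults); each fish gets a lognormal energy-acquisition scatter.
#' Uses the current RNG stream ([run_ibm()] seeds it).
#'
#' @param deb,food,ibm parameter objects ([deb_params()], [food_params()],
#'   [ibm_params()]).
#' @return An object of class `ibm_state`.
#' @export
init_population <- function(deb = deb_params(), food = food_params(),
                            ibm = ibm_params()) {
  grid <- make_grid(ibm)
  cp <- compound_params(deb)
  jr <- ibm$init_juvenile_l %||% c(deb$l_b, deb$l_p)
  ar <- ibm$init_adult_l %||% c(deb$l_p, 0.9)
  n_j <- ibm$Nb_j; n_m <- ibm$Nb_m; n_f <- ibm$Nb_f
  n <- n_j + n_m + n_f
  stage <- c(rep(STAGE_JUV, n_j), rep(STAGE_MALE, n_m), rep(STAGE_FEMALE, n_f))
  l <- c(stats::runif(n_j, jr[1], jr[2]), stats::runif(n_m + n_f, ar[1], ar[2]))
  age <- c(stats::runif(n_j, 30, 100), stats::runif(n_m + n_f, 200, 500))
  fish <- list(
    id = seq_len(n),
    stage = as.integer(stage),
    sex_latent = c(stats::runif(n_j) < 0.5, rep(TRUE, n_m), rep(FALSE, n_f)),
    age = age,
    gen = rep(0L, n),
    e = rep(ibm$init_e, n),
    l = l,
    R = rep(0, n),
    scatter = stats::rlnorm(n, 0, ibm$sigma),
    patch = sample.int(grid$npatch, n, replace = TRUE),
    terr = rep(0L, n)
  )
  broods <- list(n_eggs = integer(0), age = numeric(0), dd = numeric(0),
                 patch = integer(0), gen = integer(0), male_frac = numeric(0))
  structure(list(day = 0L, fish = fish, broods = broods, grid = grid,
                 owned = rep(FALSE, grid$npatch), food = food_state(),
                 f = 1, consumption = 0, next_id = n + 1L,
                 males_idx = which(stage == STAGE_MALE),
                 females_idx = which(stage == STAGE_FEMALE),
                 deb = deb, cp = cp, food_params = food, ibm = ibm),
            class = "ibm_state")
}

#' @export
print.ibm_state <- function(x, ...) {
  st <- x$fish$stage
  cat(sprintf(paste0("Pond population, day %d: %d fish ",
                     "(%d juveniles, %d females, %d males), %d broods\n"),
              x$day, length(st), sum(st == STAGE_JUV),
              sum(st == STAGE_FEMALE), sum(st == STAGE_MALE),
              length(x$broods$n_eggs)))
  cat(sprintf("  f = %.3f, food A = %.0f kcal, H = %.0f kcal\n",
              x$f, x$food$A, x$food$H))
  invisible(x)
}

# ---- movement --------------------------------------------------------------

#' Move all fish for one day
#'
#' In uniformly random order: juveniles on non-vegetation patches step to a
#' random vegetation patch in their Moore neighbourhood if any (staying put
#' once on vegetation), territory-less males claim a free breeding patch in
#' their neighbourhood (one territory per patch, first in random order wins)
#' or move randomly, spawning-ready females (full egg buffer inside the
#' reproduction window) move to a neighbouring patch holding a territorial
#' male if any, and everyone else moves to a random Moore neighbour.
#' Territorial males stay on their territory.
#'
#' @param state an `ibm_state`.
#' @param window_open logical: is reproduction environmentally permitted
#'   today?
#' @return The state with updated fish positions and territories.
#' @export
move_agents <- function(state, window_open = FALSE) {
  fish <- state$fish
  grid <- state$grid
  n <- length(fish$id)
  if (n == 0) return(state)

  fish$patch <- cpp_move_juveniles(fish$patch, fish$stage, grid$habitat,
                                   grid$neigh, grid$nneigh, grid$veg_neigh,
                                   grid$nveg)
  # cached adult index sets (maintained by daily_step; recompute if absent)
  males <- state$males_idx %||% which(fish$stage == STAGE_MALE)
  fem <- state$females_idx %||% which(fish$stage == STAGE_FEMALE)

  # territory-less males: claim a free breeding patch (own or neighbour)
  seekers <- males[fish$terr[males] == 0L]
  if (length(seekers)) {
    # uniformly random processing order; first claimant wins a contested patch
    seekers <- seekers[sample.int(length(seekers))]
    breeding <- grid$habitat == 3L
    for (i in seekers) {
      p <- fish$patch[i]
      cand <- c(p, grid$neigh[p, seq_len(grid$nneigh[p])])
      cand <- cand[breeding[cand] & !state$owned[cand]]
      if (length(cand)) {
        tgt <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
        fish$patch[i] <- tgt
        fish$terr[i] <- tgt
        state$owned[tgt] <- TRUE
      } else {
        fish$patch[i] <- random_neighbour(grid, p)
      }
    }
  }

  if (length(fem)) {
    is_ready <- window_open & fish$R[fem] >= state$ibm$R_tau
    ready <- fem[is_ready]
    rest <- fem[!is_ready]
    if (length(ready)) {
      ready <- ready[sample.int(length(ready))]
      for (i in ready) {
        p <- fish$patch[i]
        cand <- c(p, grid$neigh[p, seq_len(grid$nneigh[p])])
        cand <- cand[state$owned[cand]]
        if (length(cand)) {
          fish$patch[i] <- if (length(cand) == 1L) cand
                           else cand[sample.int(length(cand), 1L)]
        } else {
          fish$patch[i] <- random_neighbour(grid, p)
        }
      }
    }
    if (length(rest)) fish$patch[rest] <- random_neighbour(grid, fish$patch[rest])
  }

  state$fish <- fish
  state
}

# ---- the daily scheduler ---------------------------------------------------

drop_fish <- function(fish, keep) {
  lapply(fish, `[`, keep)
}

#' Advance the pond population by one day
#'
#' Executes the daily schedule: (1) environmental update -- temperature and
#' photoperiod from the forcing series, food-web step using yesterday's fish
#' consumption, and the shared functional response; (2) movement in random
#' order; (3) survival challenges; (4) energy-budget growth of survivors
#' (10 sub-steps) at their individual effective functional response;
#' (5) brood degree-day update and hatching, puberty transitions and
#' spawning; (6) daily summary. A census identity (today's count =
#' yesterday's + hatched - died) is asserted every step.
#'
#' @param state an `ibm_state` from [init_population()].
#' @param series an [env_series()] forcing.
#' @return The advanced state; the day's summary (named numeric vector) is
#'   in `attr(, "summary")`.
#' @export
daily_step <- function(state, series) {
  day <- state$day + 1L
  ibm <- state$ibm
  deb <- state$deb
  cp <- state$cp
  n_before <- length(state$fish$id)

  # (1) environment and food web (using yesterday's fish consumption)
  env <- conditions_at(series, day)
  T_c <- env$temperature
  photo <- env$photoperiod
  monsoon <- monsoon_active(day, series$monsoon_window)
  cons <- min(state$consumption, state$food$A + state$food$H)
  state$food <- step_food_day(state$food, T_c, photo, cons, monsoon,
                              state$food_params)
  window_open <- reproduction_window(T_c, photo, ibm$P_tau, ibm$T_tau)

  # (2) movement
  state <- move_agents(state, window_open)
  fish <- state$fish

  # (1 cont. / 3 / 4) shared functional response from start-of-day biomass,
  # survival challenges, then energy-budget growth of survivors -- fused in
  # one compiled pass over the population
  n <- length(fish$id)
  died <- 0L
  f_pop <- population_f(state$food$A + state$food$H, 0, state$food_params)
  surv_biomass_g <- 0
  fem_mass_mg <- 0
  if (n) {
    cT <- temperature_correction(T_c, deb)
    fd <- cpp_fish_day(fish$e, fish$l, fish$R, fish$scatter, fish$age,
                       fish$stage, fish$id, fish$gen, fish$patch, fish$terr,
                       fish$sex_latent, state$food$A + state$food$H,
                       state$food_params$s, state$food_params$G2Kcal,
                       ibm$W_v, cT, ibm$W_a, ibm$W_b, cp$L_inf,
                       ibm$pi_a, ibm$pi_b, ibm$pi_c, ibm$pi_d,
                       ibm$pi_e, ibm$pi_g,
                       deb$l_b, deb$l_p, deb$l_f, deb$alpha,
                       cp$g, cp$k_M, deb$R_M, deb$f_lim,
                       deb$delta, deb$p_Am, JOULES_PER_KCAL, 10L)
    sc <- fd$scalars
    died <- as.integer(sc[6])
    f_pop <- sc[2]
    fem_mass_mg <- sc[4]
    surv_biomass_g <- sc[3] / 1000
    if (length(fd$dead_terr)) state$owned[fd$dead_terr] <- FALSE
    fish <- list(id = fd$id, stage = fd$stage, sex_latent = fd$sex_latent,
                 age = fd$age, gen = fd$gen, e = fd$e, l = fd$l, R = fd$R,
                 scatter = fd$scatter, patch = fd$patch, terr = fd$terr)
  }
  state$consumption <- if (n) sc[1] else 0
  state$f <- f_pop

  # (5a) broods: predation, degree-days, hatching
  fem_density <- fem_mass_mg / 1000 / ibm$W_v
  es <- egg_step(state$broods, T_c, fem_density, ibm)
  state$broods <- es$broods
  hatched <- sum(es$hatch$n)
  if (hatched > 0) {
    nh <- es$hatch$n
    tot <- sum(nh)
    ids <- state$next_id:(state$next_id + tot - 1L)
    state$next_id <- state$next_id + tot
    fish <- list(
      id = c(fish$id, ids),
      stage = c(fish$stage, rep(STAGE_JUV, tot)),
      sex_latent = c(fish$sex_latent,
                     stats::runif(tot) < rep(es$hatch$male_frac, nh)),
      age = c(fish$age, rep(0, tot)),
      gen = c(fish$gen, rep(es$hatch$gen, nh)),
      e = c(fish$e, rep(1, tot)),
      l = c(fish$l, rep(deb$l_b, tot)),
      R = c(fish$R, rep(0, tot)),
      scatter = c(fish$scatter, stats::rlnorm(tot, 0, ibm$sigma)),
      patch = c(fish$patch, rep(es$hatch$patch, nh)),
      terr = c(fish$terr, rep(0L, tot))
    )
  }

  # (5b) puberty: reveal latent sex at l >= l_p (indices from the kernel,
  # valid because hatchlings are appended after the survivors)
  matured <- if (n) fd$matured else integer(0)
  to_male <- fish$sex_latent[matured]
  n_mat_male <- sum(to_male)
  if (length(matured)) {
    fish$stage[matured] <- STAGE_FEMALE + as.integer(to_male)
  }

  # updated adult index caches: kernel survivors plus today's maturations
  # (matured indices stay valid because hatchlings are appended at the end)
  males_idx <- c(if (n) fd$idx_male else integer(0), matured[to_male])
  females_idx <- c(if (n) fd$idx_fem else integer(0), matured[!to_male])

  # (5c) spawning: one ready female per territorial male per day
  spawns <- 0L
  if (window_open) {
    ready <- females_idx[fish$R[females_idx] >= ibm$R_tau]
    terr_males <- males_idx[fish$terr[males_idx] > 0L]
    if (length(ready) && length(terr_males)) {
      ready <- ready[sample.int(length(ready))]
      sel <- ready[!duplicated(fish$patch[ready])]
      hit <- match(fish$patch[sel], fish$terr[terr_males])
      sel <- sel[!is.na(hit)]
      if (length(sel)) {
        spawns <- length(sel)
        fish$R[sel] <- fish$R[sel] - ibm$R_tau
        nb <- list(n_eggs = rep(as.integer(ibm$R_tau), spawns),
                   age = rep(0, spawns), dd = rep(0, spawns),
                   patch = fish$patch[sel],
                   gen = fish$gen[sel] + 1L,
                   male_frac = brood_male_fraction(T_c, ibm, spawns))
        state$broods <- Map(c, state$broods, nb)
      }
    }
  }

  state$fish <- fish
  state$males_idx <- males_idx
  state$females_idx <- females_idx
  state$day <- day

  n_after <- length(fish$id)
  if (n_after != n_before - died + hatched) {
    stop(sprintf("census violation on day %d: %d != %d - %d + %d",
                 day, n_after, n_before, died, hatched), call. = FALSE)
  }

  # summary from kernel statistics plus the day's transitions; hatchlings all
  # share the length at first feeding. Biomass is start-of-day (survivors).
  L_hatch <- deb$l_b * cp$L_inf
  n_mat <- length(matured)
  n_surv_fem <- if (n) length(fd$idx_fem) else 0L
  n_surv_male <- if (n) length(fd$idx_male) else 0L
  n_surv <- if (n) length(fd$id) else 0L
  n_juv <- n_surv - n_surv_fem - n_surv_male - n_mat + hatched
  n_fem <- n_surv_fem + n_mat - n_mat_male
  n_male <- n_surv_male + n_mat_male
  summary_row <- c(
    day = day, temperature = T_c, photoperiod = photo, f = f_pop,
    n_fish = n_after, n_juvenile = n_juv,
    n_female = n_fem, n_male = n_male,
    n_broods = length(state$broods$n_eggs),
    eggs = sum(state$broods$n_eggs),
    biomass_g = surv_biomass_g,
    mean_length = if (n_after) ((if (n) sc[5] else 0) +
                                  hatched * L_hatch) / n_after else NA_real_,
    frac_le15 = if (n_after) ((if (n) sc[7] else 0) + hatched) / n_after
                else NA_real_,
    hatched = hatched, died = died, spawns = spawns,
    A = state$food$A, H = state$food$H,
    N_w = state$food$N_w, P_w = state$food$P_w
  )
  attr(state, "summary") <- summary_row
  state
}

#' Run the coupled energy-budget / individual-based pond simulation
#'
#' Seeds the RNG, initialises the population and steps it day by day,
#' collecting the daily summary table.
#'
#' @param days number of days to simulate.
#' @param deb,food,ibm parameter objects.
#' @param series environmental forcing ([env_series()]); defaults to the
#'   generated monsoon scenario.
#' @param seed integer seed; every random draw of the run flows from it.
#' @param keep_state return the final state as well?
#' @return A data.frame of daily summaries (one row per day), with the final
#'   `ibm_state` in `attr(, "state")` when `keep_state = TRUE`.
#' @export
run_ibm <- function(days = 1110, deb = deb_params(), food = food_params(),
                    ibm = ibm_params(), series = generate_monsoon_scenario(),
                    seed = 1, keep_state = FALSE) {
  set.seed(seed)
  state <- init_population(deb, food, ibm)
  rows <- vector("list", days)
  for (d in seq_len(days)) {
    state <- daily_step(state, series)
    rows[[d]] <- attr(state, "summary")
    if (length(state$fish$id) == 0 && length(state$broods$n_eggs) == 0) {
      rows <- rows[seq_len(d)]
      break
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  if (keep_state) attr(out, "state") <- state
  out
}
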