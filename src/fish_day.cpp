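#include <Rcpp.h>
using namespace Rcpp;

// One day of the per-fish pipeline, fused for speed.
// Pass 1: wet mass of every fish from the length-mass allometry, giving the
// start-of-day biomass, female biomass, and hence the shared functional
// response f = F / (F + s * B) and the biomass density driving juvenile
// mortality. Pass 2: mortality challenge (Lorenzen size term, density term
// for juveniles, senescence), compaction to survivors, energy-budget Euler
// growth (substeps per day) at the individual effective functional response
// (scatter, male appetite factor), and the day's assimilated energy (kcal).
// Stage coding: 0 juvenile, 1 female, 2 male. Uses R's RNG (one uniform per
// fish, in storage order) so runs are seed-reproducible.
// [[Rcpp::export]]
List cpp_fish_day(NumericVector e, NumericVector l, NumericVector R,
                  NumericVector scatter, NumericVector age,
                  IntegerVector stage, IntegerVector id, IntegerVector gen,
                  IntegerVector patch, IntegerVector terr,
                  LogicalVector sex_latent,
                  double F_total, double s_demand,
                  double G2Kcal, double volume, double cT,
                  double W_a, double W_b, double L_inf,
                  double pi_a, double pi_b, double pi_c, double pi_d,
                  double pi_e, double pi_g,
                  double l_b, double l_p, double l_f, double alpha,
                  double g, double k_M, double R_M, double f_lim,
                  double delta, double p_Am, double J_per_kcal,
                  int substeps) {
  R_xlen_t n = e.size();
  NumericVector W(n), Wpib(n);
  double biomass0 = 0.0, fem_mass = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double lw = W_a * log(l[i] * L_inf) + W_b; // ln mass (mg)
    W[i] = exp(lw);
    Wpib[i] = exp(pi_b * lw);
    biomass0 += W[i];
    if (stage[i] == 1) fem_mass += W[i];
  }
  double biomass_kcal = biomass0 / 1000.0 * G2Kcal;
  double denom = F_total + s_demand * biomass_kcal;
  double f_pop = denom > 0.0 ? F_total / denom : 0.0;
  double density = biomass0 / 1000.0 / volume;

  NumericVector u = runif(n);
  IntegerVector id2(n), gen2(n), patch2(n), terr2(n), stage2(n), dead_terr(n);
  LogicalVector sex2(n);
  NumericVector e2(n), l2(n), R2(n), age2(n), scatter2(n);
  R_xlen_t m = 0, ndead_terr = 0;
  double consumption = 0.0, biomass_surv0 = 0.0;
  double lf3 = l_f * l_f * l_f, lp3 = l_p * l_p * l_p;
  double kMg = cT * k_M * g;
  double Rcoef = cT * R_M / (1.0 - lp3);
  double h = 1.0 / substeps;
  double size_a = pi_a * pi_c;

  for (R_xlen_t i = 0; i < n; ++i) {
    double mort = size_a * Wpib[i];
    if (stage[i] == 0) mort += pi_d * density;
    if (age[i] > pi_g) mort += pi_e * (age[i] - pi_g);
    if (mort > 1.0) mort = 1.0;
    if (u[i] < mort) { // died; free any territory it owned
      if (terr[i] > 0) dead_terr[ndead_terr++] = terr[i];
      continue;
    }
    biomass_surv0 += W[i];

    double fi0 = scatter[i] * f_pop;
    if (stage[i] == 2) fi0 *= f_lim;
    if (fi0 > 1.0) fi0 = 1.0;
    double ei = e[i], li = l[i], Ri = R[i];
    bool fem = stage[i] == 1;
    if (li >= l_b) {
      double sf0 = alpha * lf3 / (li * li * li + lf3);
      double surf = delta * li * L_inf;
      consumption += cT * p_Am * (1.0 - sf0) * fi0 * surf * surf;
    }
    for (int ss = 0; ss < substeps; ++ss) {
      double fi = (li < l_b) ? 0.0 : fi0;
      double sf = alpha * lf3 / (li * li * li + lf3);
      double de = kMg / li * ((1.0 - sf) * fi - ei);
      double dl = kMg / (3.0 * (ei + g)) * (ei - li);
      if (fem && li >= l_p) {
        double dR = Rcoef * ((g + li) / (g + ei) * ei * li * li - lp3);
        if (dR > 0.0) Ri += h * dR;
      }
      ei += h * de;
      if (ei < 0.0) ei = 0.0;
      li += h * dl;
      if (li < 1e-6) li = 1e-6;
    }
    if (!R_finite(ei) || !R_finite(li) || !R_finite(Ri)) {
      stop("non-finite energy-budget state: e=%g l=%g R=%g (individual %d)",
           ei, li, Ri, (int)(i + 1));
    }
    e2[m] = ei;
    l2[m] = li;
    R2[m] = Ri;
    age2[m] = age[i] + 1.0;
    scatter2[m] = scatter[i];
    id2[m] = id[i];
    gen2[m] = gen[i];
    patch2[m] = patch[i];
    terr2[m] = terr[i];
    stage2[m] = stage[i];
    sex2[m] = sex_latent[i];
    ++m;
  }
  consumption /= J_per_kcal;

  // post-growth summary statistics over survivors (pre-puberty, pre-hatch)
  int n_fem = 0, n_male = 0, n_le15 = 0, n_mat = 0;
  double sum_L = 0.0;
  IntegerVector matured(m), idx_fem(m), idx_male(m);
  for (R_xlen_t j = 0; j < m; ++j) {
    int st = stage2[j];
    double L = l2[j] * L_inf;
    sum_L += L;
    if (L <= 15.0) ++n_le15;
    if (st == 0) {
      if (l2[j] >= l_p) matured[n_mat++] = (int)(j + 1);
    } else if (st == 1) {
      idx_fem[n_fem++] = (int)(j + 1);
    } else {
      idx_male[n_male++] = (int)(j + 1);
    }
  }
  // scalars: consumption (kcal), f, start-of-day biomass of survivors (mg),
  // start-of-day female biomass (mg), sum of post-growth lengths (mm),
  // died count, count of fish <= 15 mm
  NumericVector scalars = NumericVector::create(
    consumption, f_pop, biomass_surv0, fem_mass, sum_L,
    (double)(n - m), (double)n_le15);
  return List::create(
    _["e"] = NumericVector(e2.begin(), e2.begin() + m),
    _["l"] = NumericVector(l2.begin(), l2.begin() + m),
    _["R"] = NumericVector(R2.begin(), R2.begin() + m),
    _["age"] = NumericVector(age2.begin(), age2.begin() + m),
    _["scatter"] = NumericVector(scatter2.begin(), scatter2.begin() + m),
    _["id"] = IntegerVector(id2.begin(), id2.begin() + m),
    _["gen"] = IntegerVector(gen2.begin(), gen2.begin() + m),
    _["patch"] = IntegerVector(patch2.begin(), patch2.begin() + m),
    _["terr"] = IntegerVector(terr2.begin(), terr2.begin() + m),
    _["stage"] = IntegerVector(stage2.begin(), stage2.begin() + m),
    _["sex_latent"] = LogicalVector(sex2.begin(), sex2.begin() + m),
    _["matured"] = IntegerVector(matured.begin(), matured.begin() + n_mat),
    _["idx_fem"] = IntegerVector(idx_fem.begin(), idx_fem.begin() + n_fem),
    _["idx_male"] = IntegerVector(idx_male.begin(), idx_male.begin() + n_male),
    _["dead_terr"] = IntegerVector(dead_terr.begin(),
                                   dead_terr.begin() + ndead_terr),
    _["scalars"] = scalars);
}

// Relocate juveniles: a juvenile already on vegetation stays; otherwise it
// jumps to a uniformly random vegetation patch in its Moore neighbourhood if
// one exists, else to a random neighbour. One uniform draw per moving fish,
// in storage order (seed-reproducible). Patch ids are 1-based.
// [[Rcpp::export]]
IntegerVector cpp_move_juveniles(IntegerVector patch, IntegerVector stage,
                                 IntegerVector habitat, IntegerMatrix neigh,
                                 IntegerVector nneigh,
                                 IntegerMatrix veg_neigh,
                                 IntegerVector nveg) {
  R_xlen_t n = patch.size();
  IntegerVector out = clone(patch);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (stage[i] != 0) continue;
    int p = out[i] - 1;
    if (habitat[p] == 2) continue; // already on vegetation
    if (nveg[p] > 0) {
      int k = (int)(unif_rand() * nveg[p]);
      if (k >= nveg[p]) k = nveg[p] - 1;
      out[i] = veg_neigh(p, k);
    } else if (nneigh[p] > 0) {
      int k = (int)(unif_rand() * nneigh[p]);
      if (k >= nneigh[p]) k = nneigh[p] - 1;
      out[i] = neigh(p, k);
    }
  }
  return out;
}
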