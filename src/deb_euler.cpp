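#include <Rcpp.h>
using namespace Rcpp;

// parameter fields may be scalars (whole-population stepping) or one value
// per individual (batch designs); recycle accordingly
static inline double getp(const NumericVector& v, R_xlen_t i) {
  return v.size() == 1 ? v[0] : v[i];
}

// Forward-Euler kernel of the energy-budget model: advances (e, l, R) for n
// individuals over dt with `substeps` sub-steps. f is forced to 0 before
// first feeding (l < l_b); dR/dt is clamped at 0 from below, zero before
// puberty and for non-females; l is floored at a small positive value.
// [[Rcpp::export]]
List cpp_deb_euler(NumericVector e, NumericVector l, NumericVector R,
                   NumericVector f, NumericVector cT, LogicalVector female,
                   NumericVector l_b, NumericVector l_p, NumericVector l_f,
                   NumericVector alpha, NumericVector g, NumericVector k_M,
                   NumericVector R_M, double dt, int substeps) {
  R_xlen_t n = e.size();
  NumericVector e2 = clone(e), l2 = clone(l), R2 = clone(R);
  double h = dt / substeps;
  for (R_xlen_t i = 0; i < n; ++i) {
    double ei = e2[i], li = l2[i], Ri = R2[i];
    double gi = getp(g, i);
    double kMg = getp(cT, i) * getp(k_M, i) * gi;
    double lb = getp(l_b, i), lp = getp(l_p, i);
    double lf = getp(l_f, i), al = getp(alpha, i);
    double lf3 = lf * lf * lf, lp3 = lp * lp * lp;
    double Rcoef = getp(cT, i) * getp(R_M, i) / (1.0 - lp3);
    double fi0 = getp(f, i);
    bool fem = female.size() == 1 ? (female[0] != 0) : (female[i] != 0);
    for (int s = 0; s < substeps; ++s) {
      double fi = (li < lb) ? 0.0 : fi0;
      double sf = al * lf3 / (li * li * li + lf3);
      double de = kMg / li * ((1.0 - sf) * fi - ei);
      double dl = kMg / (3.0 * (ei + gi)) * (ei - li);
      double dR = Rcoef * ((gi + li) / (gi + ei) * ei * li * li - lp3);
      if (dR < 0.0 || li < lp || !fem) dR = 0.0;
      ei += h * de;
      if (ei < 0.0) ei = 0.0;
      li += h * dl;
      if (li < 1e-6) li = 1e-6;
      Ri += h * dR;
    }
    if (!R_finite(ei) || !R_finite(li) || !R_finite(Ri)) {
      stop("non-finite energy-budget state after step: e=%g l=%g R=%g "
           "(f=%g, individual %d)", ei, li, Ri, fi0, (int)(i + 1));
    }
    e2[i] = ei;
    l2[i] = li;
    R2[i] = Ri;
  }
  return List::create(_["e"] = e2, _["l"] = l2, _["R"] = R2);
}
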