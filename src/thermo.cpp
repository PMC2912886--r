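#include <Rcpp.h>
using namespace Rcpp;

// Activation score at one AP position: sum over activator sites of
// E_act * f, each term quenched by (1 - E_rep * f_j) for every repressor
// site j whose center lies within d bp.  f is the single-site isotherm
// K * v * q / (1 + K * v * q).
static double activation_at(const int ns, const int *tf, const double *center,
                            const double *q, const int *role,
                            const double *conc_col, const double *K,
                            const double *Ea, const double *Er, double d) {
  double f[256];
  for (int i = 0; i < ns; ++i) {
    double x = K[tf[i] - 1] * conc_col[tf[i] - 1] * q[i];
    f[i] = x / (1.0 + x);
  }
  double total = 0.0;
  for (int i = 0; i < ns; ++i) {
    if (role[i] <= 0) continue;
    double term = Ea[tf[i] - 1] * f[i];
    for (int j = 0; j < ns; ++j) {
      if (role[j] >= 0) continue;
      if (std::fabs(center[i] - center[j]) <= d)
        term *= 1.0 - Er[tf[j] - 1] * f[j];
    }
    total += term;
  }
  return total;
}

// [[Rcpp::export]]
NumericVector cpp_predict_profile(IntegerVector site_tf, NumericVector site_center,
                                  NumericVector site_q, IntegerVector site_role,
                                  NumericMatrix conc, NumericVector K,
                                  NumericVector Ea, NumericVector Er,
                                  double G0, double R0, double d) {
  const int ns = site_tf.size();
  if (ns > 256) stop("more than 256 sites on one CRM is unsupported");
  const int np = conc.ncol();
  const int ntf = conc.nrow();
  NumericVector out(np);
  std::vector<double> col(ntf);
  for (int x = 0; x < np; ++x) {
    for (int t = 0; t < ntf; ++t) col[t] = conc(t, x);
    double s = activation_at(ns, ns ? &site_tf[0] : nullptr,
                             ns ? &site_center[0] : nullptr,
                             ns ? &site_q[0] : nullptr,
                             ns ? &site_role[0] : nullptr,
                             col.data(), &K[0], &Ea[0], &Er[0], d);
    out[x] = R0 / (1.0 + std::exp(-(s - G0)));
  }
  return out;
}

static double pearson(const double *a, const double *b, int n) {
  double amin = a[0], amax = a[0], bmin = b[0], bmax = b[0];
  for (int i = 1; i < n; ++i) {
    amin = std::min(amin, a[i]); amax = std::max(amax, a[i]);
    bmin = std::min(bmin, b[i]); bmax = std::max(bmax, b[i]);
  }
  if (amin == amax || bmin == bmax) return 0.0;  // zero variance -> CC 0
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double saa = 0, sbb = 0, sab = 0;
  for (int i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return 0.0;  // zero variance -> CC 0
  return sab / std::sqrt(saa * sbb);
}

// [[Rcpp::export]]
double cpp_crm_cc(IntegerVector site_tf, NumericVector site_center,
                  NumericVector site_q, IntegerVector site_role,
                  NumericMatrix conc, NumericVector obs, NumericVector K,
                  NumericVector Ea, NumericVector Er,
                  double G0, double R0, double d) {
  NumericVector pred = cpp_predict_profile(site_tf, site_center, site_q,
                                           site_role, conc, K, Ea, Er,
                                           G0, R0, d);
  return pearson(&pred[0], &obs[0], pred.size());
}

// Mean CC over a list of precomputed CRM structs (fields: site_tf,
// site_center, site_q, site_role, conc, obs).  This is the simulated
// annealing objective.
// [[Rcpp::export]]
double cpp_objective(List crms, NumericVector K, NumericVector Ea,
                     NumericVector Er, double G0, double R0, double d) {
  const int nc = crms.size();
  if (nc == 0) stop("empty dataset");
  double total = 0.0;
  for (int c = 0; c < nc; ++c) {
    List cs = crms[c];
    IntegerVector tf = cs["site_tf"];
    NumericVector center = cs["site_center"];
    NumericVector q = cs["site_q"];
    IntegerVector role = cs["site_role"];
    NumericMatrix conc = cs["conc"];
    NumericVector obs = cs["obs"];
    total += cpp_crm_cc(tf, center, q, role, conc, obs, K, Ea, Er, G0, R0, d);
  }
  return total / nc;
}
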