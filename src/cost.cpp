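#include <Rcpp.h>
using namespace Rcpp;

// Weighted least-squares cost of the green-fraction curve for one stage-1
// group (shared shape parameters, per-plot amplitude). Hot path of the
// grid + simplex fit: called once per simplex evaluation.
// [[Rcpp::export(name = ".gf_cost_cpp")]]
double gf_cost_cpp(NumericVector gf, NumericVector gdd, NumericVector w,
                   IntegerVector plot_index, NumericVector la,
                   double r_g, double r_s, double t_g, double t_s,
                   double k) {
  const int n = gf.size();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    if (w[i] == 0.0) continue;
    const double xg = r_g * (gdd[i] - t_g);
    double growth;
    if (xg >= 0.0) {
      growth = 1.0 / (1.0 + std::exp(-xg));
    } else {
      const double e = std::exp(xg);
      growth = e / (1.0 + e);
    }
    double xs = r_s * (gdd[i] - t_s);
    if (xs > 700.0) xs = 700.0;
    double lai = la[plot_index[i] - 1] * (growth - std::exp(xs));
    if (lai < 0.0) lai = 0.0;
    const double pred = 1.0 - std::exp(-k * lai);
    const double r = gf[i] - pred;
    acc += r * r * w[i];
  }
  return acc;
}
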