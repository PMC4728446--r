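#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step explicit midpoint (RK2) integration of the Cartesian
// Euler-Bernoulli rod equation kappa*y'' = (A*y + B)*(1 + y'^2)^(3/2),
// with A and B already divided by kappa. Returns (y, y') at the end of the
// interval, or (NA, NA) when the slope leaves the graph parameterisation.

// [[Rcpp::export(name = ".rod_endpoint_cpp")]]
NumericVector rod_endpoint_cpp(double A, double B, double x_len,
                               double y, double v, int n_steps,
                               double max_slope) {
  const double h = x_len / n_steps;
  for (int i = 0; i < n_steps; ++i) {
    double a1 = (A * y + B) * std::pow(1.0 + v * v, 1.5);
    double ym = y + 0.5 * h * v;
    double vm = v + 0.5 * h * a1;
    double a2 = (A * ym + B) * std::pow(1.0 + vm * vm, 1.5);
    y += h * vm;
    v += h * a2;
    if (!std::isfinite(y) || !std::isfinite(v) || std::fabs(v) > max_slope)
      return NumericVector::create(NA_REAL, NA_REAL);
  }
  return NumericVector::create(y, v);
}
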