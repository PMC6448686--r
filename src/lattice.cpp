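#include <Rcpp.h>
using namespace Rcpp;

// psi-averaged paracrystalline hexagonal lattice factor in reduced units.
//
// The two hexagonal basis vectors sit at 0 and 60 degrees; each contributes
// a 1D paracrystalline interference factor (distortion of the second kind)
//   Z_k = (1 - g^2) / (1 - 2 g cos(x cos(psi - psi_k)) + g^2),
//   g   = exp(-x^2 dr^2 / 2),
// with x = q * a and dr = delta_a / a. The orientational average over the
// crystal rotation psi is an arithmetic mean on a uniform grid over
// [0, 2*pi), exact trapezoid quadrature for a periodic integrand.
//
// [[Rcpp::export]]
NumericVector psi_avg_lattice_cpp(NumericVector x, double dr, int n_psi) {
  if (n_psi < 1) stop("n_psi must be >= 1");
  const int nx = x.size();
  NumericVector out(nx);
  std::vector<double> cosA(n_psi), cosB(n_psi);
  const double two_pi = 2.0 * M_PI;
  const double shift = M_PI / 3.0;
  for (int k = 0; k < n_psi; ++k) {
    double psi = two_pi * k / n_psi;
    cosA[k] = std::cos(psi);
    cosB[k] = std::cos(psi - shift);
  }
  for (int i = 0; i < nx; ++i) {
    const double xi = x[i];
    if (xi <= 0.0) stop("reduced momentum transfer q*a must be > 0");
    const double g = std::exp(-0.5 * xi * xi * dr * dr);
    const double g2 = g * g;
    const double num = 1.0 - g2;
    double acc = 0.0;
    for (int k = 0; k < n_psi; ++k) {
      const double z1 = num / (1.0 - 2.0 * g * std::cos(xi * cosA[k]) + g2);
      const double z2 = num / (1.0 - 2.0 * g * std::cos(xi * cosB[k]) + g2);
      acc += z1 * z2;
    }
    out[i] = acc / n_psi;
  }
  return out;
}
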