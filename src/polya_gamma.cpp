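// Polya-Gamma PG(1, z) sampler (Devroye-style alternating-series rejection
// on the Jacobi J*(1, z/2) density; PG(1, z) = J*(1, z/2) / 4).
// Uses R's RNG so draws are reproducible under set.seed().
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TRUNC = 0.64;          // left/right split point of J*
static const double PISQ8 = M_PI * M_PI / 8.0;

// piecewise coefficients a_n(x) of the alternating series for J*(1, z)
static double a_coef(int n, double x) {
  double np = n + 0.5;
  if (x > TRUNC)
    return M_PI * np * std::exp(-np * np * M_PI * M_PI * x / 2.0);
  return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np * np / x);
}

// Inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC)
static double rtigauss(double z) {
  double mu_cap = 1.0 / z;  // may be Inf when z = 0
  double x;
  if (!(mu_cap < TRUNC)) {  // large mean (or z = 0): one-sided rejection
    for (;;) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      double alpha = std::exp(-0.5 * z * z * x);
      if (R::unif_rand() <= alpha) return x;
    }
  }
  for (;;) {
    double y = R::norm_rand();
    y = y * y;
    double muy = mu_cap * y;
    x = mu_cap + 0.5 * mu_cap * muy -
        0.5 * mu_cap * std::sqrt(4.0 * muy + muy * muy);
    if (R::unif_rand() > mu_cap / (mu_cap + x)) x = mu_cap * mu_cap / x;
    if (x < TRUNC) return x;
  }
}

// probability of proposing from the right (exponential) tail
static double right_tail_prob(double z) {
  double fz = PISQ8 + 0.5 * z * z;
  double b = std::sqrt(1.0 / TRUNC) * (TRUNC * z - 1.0);
  double a = -std::sqrt(1.0 / TRUNC) * (TRUNC * z + 1.0);
  double x0 = std::log(fz) + fz * TRUNC;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

static double draw_pg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double fz = PISQ8 + 0.5 * z * z;
  double p_right = right_tail_prob(z);
  for (;;) {
    double x;
    if (R::unif_rand() < p_right)
      x = TRUNC + R::exp_rand() / fz;
    else
      x = rtigauss(z);
    // squeeze: accept/reject via the alternating partial sums
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

// [[Rcpp::export(name = ".rpg1")]]
NumericVector rpg1(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_pg1(z[i]);  // RNGScope via Rcpp
  return out;
}
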