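#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Standard bivariate normal CDF and the rectangle probabilities /
// log-likelihood pieces needed for polychoric estimation.  The CDF follows
// the Gauss-Legendre quadrature scheme of Drezner & Wesolowsky as refined
// by Genz (1994, 2004), accurate to ~1e-15.

static const double TWOPI = 6.283185307179586;

// Gauss-Legendre abscissae/weights for |rho| bands (Genz BVND).
static const double XL6[3] = {-0.9324695142031522, -0.6612093864662647,
                              -0.2386191860831970};
static const double WL6[3] = {0.1713244923791705, 0.3607615730481384,
                              0.4679139345726904};
static const double XL12[6] = {-0.9815606342467191, -0.9041172563704750,
                               -0.7699026741943050, -0.5873179542866171,
                               -0.3678314989981802, -0.1252334085114692};
static const double WL12[6] = {0.04717533638651177, 0.1069393259953183,
                               0.1600783285433464,  0.2031674267230659,
                               0.2334925365383547,  0.2491470458134029};
static const double XL20[10] = {-0.9931285991850949, -0.9639719272779138,
                                -0.9122344282513259, -0.8391169718222188,
                                -0.7463319064601508, -0.6360536807265150,
                                -0.5108670019508271, -0.3737060887154196,
                                -0.2277858511416451, -0.07652652113349733};
static const double WL20[10] = {0.01761400713915212, 0.04060142980038694,
                                0.06267204833410906, 0.08327674157670475,
                                0.1019301198172404,  0.1181945319615184,
                                0.1316886384491766,  0.1420961093183821,
                                0.1491729864726037,  0.1527533871307259};

static inline double phid(double x) { return 0.5 * erfc(-x * M_SQRT1_2); }

// P(X > dh, Y > dk) for standard bivariate normal with correlation r.
static double bvnd_upper(double dh, double dk, double r) {
  const double *x;
  const double *w;
  int lg;
  if (std::fabs(r) < 0.3) {
    lg = 3; x = XL6; w = WL6;
  } else if (std::fabs(r) < 0.75) {
    lg = 6; x = XL12; w = WL12;
  } else {
    lg = 10; x = XL20; w = WL20;
  }
  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  if (std::fabs(r) < 0.925) {
    if (std::fabs(r) > 0.0) {
      double hs = (h * h + k * k) / 2.0, asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
          bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * TWOPI);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0.0) { k = -k; hk = -hk; }
    if (std::fabs(r) < 1.0) {
      double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0) {
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      }
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(TWOPI) * phid(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0) {
            bvn += a * w[i] * std::exp(asr2) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
          }
        }
      }
      bvn = -bvn / TWOPI;
    }
    if (r > 0.0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  return bvn;
}

// Phi2(a, b; r) = P(X <= a, Y <= b), handling infinite bounds.
static double phi2(double a, double b, double r) {
  if (!std::isfinite(a) && a < 0) return 0.0;
  if (!std::isfinite(b) && b < 0) return 0.0;
  if (!std::isfinite(a) && a > 0) return std::isfinite(b) ? phid(b) : 1.0;
  if (!std::isfinite(b) && b > 0) return phid(a);
  return bvnd_upper(-a, -b, r);
}

// Bivariate normal density, 0 at infinite arguments.
static double dbvn(double a, double b, double r) {
  if (!std::isfinite(a) || !std::isfinite(b)) return 0.0;
  double omr2 = 1.0 - r * r;
  double q = (a * a - 2.0 * r * a * b + b * b) / omr2;
  return std::exp(-q / 2.0) / (TWOPI * std::sqrt(omr2));
}

//' Bivariate standard normal CDF
//'
//' @param a,b numeric vectors of upper limits (recycled to common length);
//'   `-Inf`/`Inf` allowed.
//' @param rho correlation in (-1, 1), scalar.
//' @return vector of probabilities P(X <= a, Y <= b).
//' @export
// [[Rcpp::export]]
NumericVector pbvnorm(NumericVector a, NumericVector b, double rho) {
  R_xlen_t n = std::max(a.size(), b.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = phi2(a[i % a.size()], b[i % b.size()], rho);
  return out;
}

// Rectangle probabilities of all C_a x C_b cells given thresholds.
// ta, tb: finite or infinite interior thresholds (length C-1 each).
// [[Rcpp::export]]
NumericMatrix cell_probs_cpp(NumericVector ta, NumericVector tb, double rho) {
  int Ca = ta.size() + 1, Cb = tb.size() + 1;
  std::vector<double> a(Ca + 1), b(Cb + 1);
  a[0] = -INFINITY; a[Ca] = INFINITY;
  b[0] = -INFINITY; b[Cb] = INFINITY;
  for (int i = 0; i < Ca - 1; i++) a[i + 1] = ta[i];
  for (int i = 0; i < Cb - 1; i++) b[i + 1] = tb[i];
  // CDF grid
  std::vector<std::vector<double> > F(Ca + 1, std::vector<double>(Cb + 1));
  for (int i = 0; i <= Ca; i++)
    for (int j = 0; j <= Cb; j++) F[i][j] = phi2(a[i], b[j], rho);
  NumericMatrix P(Ca, Cb);
  for (int i = 0; i < Ca; i++)
    for (int j = 0; j < Cb; j++)
      P(i, j) = F[i + 1][j + 1] - F[i][j + 1] - F[i + 1][j] + F[i][j];
  return P;
}

// Olsson log-likelihood for a contingency table with thresholds held fixed.
// Cells with probability < floor_p contribute log(floor_p).
// [[Rcpp::export]]
double polychoric_loglik_cpp(NumericMatrix counts, NumericVector ta,
                             NumericVector tb, double rho, double floor_p) {
  NumericMatrix P = cell_probs_cpp(ta, tb, rho);
  double ll = 0.0;
  for (int i = 0; i < counts.nrow(); i++)
    for (int j = 0; j < counts.ncol(); j++)
      if (counts(i, j) > 0)
        ll += counts(i, j) * std::log(std::max(P(i, j), floor_p));
  return ll;
}

// d/drho of each cell probability: rectangle differences of the bivariate
// density (d Phi2(a,b;r)/dr = phi2-density at (a,b)).
// [[Rcpp::export]]
NumericMatrix cell_dprobs_cpp(NumericVector ta, NumericVector tb, double rho) {
  int Ca = ta.size() + 1, Cb = tb.size() + 1;
  std::vector<double> a(Ca + 1), b(Cb + 1);
  a[0] = -INFINITY; a[Ca] = INFINITY;
  b[0] = -INFINITY; b[Cb] = INFINITY;
  for (int i = 0; i < Ca - 1; i++) a[i + 1] = ta[i];
  for (int i = 0; i < Cb - 1; i++) b[i + 1] = tb[i];
  std::vector<std::vector<double> > D(Ca + 1, std::vector<double>(Cb + 1));
  for (int i = 0; i <= Ca; i++)
    for (int j = 0; j <= Cb; j++) D[i][j] = dbvn(a[i], b[j], rho);
  NumericMatrix dP(Ca, Cb);
  for (int i = 0; i < Ca; i++)
    for (int j = 0; j < Cb; j++)
      dP(i, j) = D[i + 1][j + 1] - D[i][j + 1] - D[i + 1][j] + D[i][j];
  return dP;
}
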