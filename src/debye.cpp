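#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// normalized sphere scattering amplitude 3(sin x - x cos x)/x^3, -> 1 at x=0
static inline double sphere_ff(double x) {
  if (x < 1e-4) return 1.0 - x * x / 10.0;
  return 3.0 * (std::sin(x) - x * std::cos(x)) / (x * x * x);
}

static inline double sinc(double x) {
  if (x < 1e-8) return 1.0;
  return std::sin(x) / x;
}

// Orientationally averaged Debye intensity of a bead model.
//   I(q) = sum_ij f_i(q) f_j(q) sinc(q r_ij),  f_i = w_i * phi(q R_i)
// Exact pair sum up to exact_limit beads; above that, pair distances are
// accumulated into a histogram of width bin_width per pair of bead-radius
// classes and the sum runs over bins.
// [[Rcpp::export]]
NumericVector debye_intensity_cpp(NumericMatrix pos, NumericVector w,
                                  NumericVector radius, NumericVector q,
                                  int exact_limit = 5000,
                                  double bin_width = 0.05) {
  const int n = pos.nrow();
  const int nq = q.size();
  if (n < 1) stop("debye_intensity_cpp: empty bead model");
  NumericVector I(nq);

  // group beads by radius so the per-bead form factor is computed per class
  std::vector<double> cls;
  std::vector<int> ci(n);
  for (int i = 0; i < n; ++i) {
    int c = -1;
    for (size_t k = 0; k < cls.size(); ++k)
      if (std::fabs(cls[k] - radius[i]) < 1e-12) { c = (int)k; break; }
    if (c < 0) { cls.push_back(radius[i]); c = (int)cls.size() - 1; }
    ci[i] = c;
  }
  const int nc = (int)cls.size();
  // F(iq, c) = phi(q * R_c)
  std::vector<double> F((size_t)nq * nc);
  for (int iq = 0; iq < nq; ++iq)
    for (int c = 0; c < nc; ++c)
      F[(size_t)iq * nc + c] = sphere_ff(q[iq] * cls[c]);

  // self terms per class: sum_i w_i^2
  std::vector<double> self(nc, 0.0);
  for (int i = 0; i < n; ++i) self[ci[i]] += w[i] * w[i];
  for (int iq = 0; iq < nq; ++iq) {
    double s = 0.0;
    for (int c = 0; c < nc; ++c) {
      double f = F[(size_t)iq * nc + c];
      s += self[c] * f * f;
    }
    I[iq] = s;
  }

  if (n <= exact_limit) {
    for (int i = 0; i < n; ++i) {
      const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
      const double wi = w[i];
      const int c1 = ci[i];
      for (int j = i + 1; j < n; ++j) {
        const double dx = xi - pos(j, 0);
        const double dy = yi - pos(j, 1);
        const double dz = zi - pos(j, 2);
        const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        const double wij = 2.0 * wi * w[j];
        const int c2 = ci[j];
        for (int iq = 0; iq < nq; ++iq) {
          I[iq] += wij * F[(size_t)iq * nc + c1] * F[(size_t)iq * nc + c2] *
                   sinc(q[iq] * r);
        }
      }
    }
    return I;
  }

  // histogram accelerator: weighted pair-distance histogram per class pair
  double maxd = 0.0;
  {
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) { lo[k] = pos(0, k); hi[k] = pos(0, k); }
    for (int i = 1; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        if (pos(i, k) < lo[k]) lo[k] = pos(i, k);
        if (pos(i, k) > hi[k]) hi[k] = pos(i, k);
      }
    for (int k = 0; k < 3; ++k) maxd += (hi[k] - lo[k]) * (hi[k] - lo[k]);
    maxd = std::sqrt(maxd);
  }
  const int nbins = (int)(maxd / bin_width) + 2;
  const int npair = nc * (nc + 1) / 2;
  std::vector<double> H((size_t)npair * nbins, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
    const double wi = w[i];
    const int c1 = ci[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - pos(j, 0);
      const double dy = yi - pos(j, 1);
      const double dz = zi - pos(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)(r / bin_width + 0.5);
      int lo = std::min(c1, ci[j]), hi2 = std::max(c1, ci[j]);
      int cp = lo * nc - lo * (lo + 1) / 2 + hi2;  // upper-triangle index
      H[(size_t)cp * nbins + b] += 2.0 * wi * w[j];
    }
  }
  for (int lo = 0; lo < nc; ++lo) {
    for (int hi2 = lo; hi2 < nc; ++hi2) {
      int cp = lo * nc - lo * (lo + 1) / 2 + hi2;
      for (int b = 0; b < nbins; ++b) {
        double wsum = H[(size_t)cp * nbins + b];
        if (wsum == 0.0) continue;
        const double rb = b * bin_width;
        for (int iq = 0; iq < nq; ++iq) {
          I[iq] += wsum * F[(size_t)iq * nc + lo] * F[(size_t)iq * nc + hi2] *
                   sinc(q[iq] * rb);
        }
      }
    }
  }
  return I;
}
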