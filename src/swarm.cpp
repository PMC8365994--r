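#include <Rcpp.h>
#include <functional>
#include <map>
#include <vector>
using namespace Rcpp;

// Deterministic unit direction for coincident pairs (r_ij < 1e-9), derived
// from the particle indices so the same configuration always resolves the
// same way.  Hash-to-angle; no state in the R RNG is consumed.
static inline double jitter_angle(int i, int j) {
  double s = std::sin(12.9898 * (i + 1) + 78.233 * (j + 1)) * 43758.5453;
  return 2.0 * M_PI * (s - std::floor(s));
}

static inline double wrap_angle(double a) {
  const double twopi = 2.0 * M_PI;
  double w = a - twopi * std::floor(a / twopi);
  if (w >= twopi) w -= twopi;   // guard against rounding at the boundary
  if (w < 0) w = 0.0;
  return w;
}

// One synchronous update of the swarm.  Neighbour bands, alignment sums and
// forces are all evaluated from the state at time t; xi is the per-particle
// standard-normal draw for the rotation-rate update (drawn in R, in particle
// index order).  Bands use strict inequalities: repulsive r < r_rep,
// annulus r_rep < r < l.
// [[Rcpp::export]]
List swarm_step_cpp(NumericVector x, NumericVector y,
                    NumericVector theta, NumericVector omega,
                    NumericVector xi,
                    double v0, double l, double r_rep,
                    double omega0, double sigma_omega, double tau,
                    double k_rep, double k_att, double align_gain) {
  const int n = x.size();
  NumericVector frx(n), fry(n), fax(n), fay(n), align(n);
  IntegerVector N(n);
  const double l2 = l * l;

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d2 = dx * dx + dy * dy;
      if (d2 >= l2) continue;
      double d = std::sqrt(d2);
      double ex, ey;
      if (d < 1e-9) {
        double a = jitter_angle(i, j);
        ex = std::cos(a); ey = std::sin(a);
        d = 0.0;
      } else {
        ex = dx / d; ey = dy / d;
      }
      if (d < r_rep) {
        double f = k_rep * (d - r_rep);     // negative: pushes i away from j
        frx[i] += f * ex; fry[i] += f * ey;
        frx[j] -= f * ex; fry[j] -= f * ey; // e_ji = -e_ij, same magnitude
      } else if (d > r_rep && d < l) {
        N[i] += 1; N[j] += 1;
        double s = std::sin(2.0 * (theta[j] - theta[i]));
        align[i] += s;
        align[j] -= s;                      // sin 2(ti - tj) = -sin 2(tj - ti)
        double fa = k_att / d;
        fax[i] += fa * ex; fay[i] += fa * ey;
        fax[j] -= fa * ex; fay[j] -= fa * ey;
      }
      // d == r_rep exactly: interacts in neither band
    }
  }

  NumericVector xn(n), yn(n), thn(n), omn(n);
  const double c_noise = std::sqrt(2.0 / tau) * sigma_omega;
  for (int i = 0; i < n; ++i) {
    omn[i] = omega[i] - (omega[i] - omega0) / tau + c_noise * xi[i];
    double al = (N[i] > 0) ? align_gain * align[i] / N[i] : 0.0;
    thn[i] = wrap_angle(theta[i] + omn[i] + al);
    double ax = (N[i] > 0) ? fax[i] / N[i] : 0.0;
    double ay = (N[i] > 0) ? fay[i] / N[i] : 0.0;
    xn[i] = x[i] + v0 * (std::cos(thn[i]) + frx[i] + ax);
    yn[i] = y[i] + v0 * (std::sin(thn[i]) + fry[i] + ay);
  }
  return List::create(_["x"] = xn, _["y"] = yn,
                      _["theta"] = thn, _["omega"] = omn);
}

// All interacting pairs (one orientation, i < j), with distance, the unit
// vector from i toward j, and the band label (1 repulsive, 2 annulus).
// [[Rcpp::export]]
DataFrame neighbor_pairs_cpp(NumericVector x, NumericVector y,
                             double r_rep, double l) {
  const int n = x.size();
  std::vector<int> vi, vj, band;
  std::vector<double> vd, vex, vey;
  const double l2 = l * l;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d2 = dx * dx + dy * dy;
      if (d2 >= l2) continue;
      double d = std::sqrt(d2);
      double ex, ey;
      if (d < 1e-9) {
        double a = jitter_angle(i, j);
        ex = std::cos(a); ey = std::sin(a);
      } else {
        ex = dx / d; ey = dy / d;
      }
      int b;
      if (d < r_rep) b = 1;
      else if (d > r_rep && d < l) b = 2;
      else continue;                        // exactly on a band boundary
      vi.push_back(i + 1); vj.push_back(j + 1);
      vd.push_back(d); vex.push_back(ex); vey.push_back(ey);
      band.push_back(b);
    }
  }
  return DataFrame::create(_["i"] = vi, _["j"] = vj, _["r_ij"] = vd,
                           _["ex"] = vex, _["ey"] = vey, _["band"] = band);
}

// Union-find single-linkage connected components: pairs with distance
// <= linkage (inclusive) are joined.  Returns 1-based component labels
// in first-touch order; relabelling by size happens in R.
// [[Rcpp::export]]
IntegerVector linkage_components_cpp(NumericVector x, NumericVector y,
                                     double linkage) {
  const int n = x.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  const double l2 = linkage * linkage;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx * dx + dy * dy <= l2) {
        int ra = find(i), rb = find(j);
        if (ra != rb) parent[rb] = ra;
      }
    }
  }
  IntegerVector lab(n);
  std::map<int, int> seen;
  int next = 1;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = seen.find(r);
    if (it == seen.end()) { seen[r] = next; lab[i] = next; ++next; }
    else lab[i] = it->second;
  }
  return lab;
}

// KS scan for the continuous power law.  Input must be sorted ascending.
// For every candidate lower cut-off (first occurrence of each distinct
// value with at least two distinct tail values), returns the tail MLE
// alpha = 1 + n_tail / sum(log(x/xmin)) and the KS distance between the
// tail empirical CDF (evaluated just above and just below each point) and
// the fitted CDF.
// [[Rcpp::export]]
DataFrame powerlaw_scan_cpp(NumericVector xs) {
  const int n = xs.size();
  std::vector<double> vxmin, valpha, vks;
  std::vector<int> vnt;
  // suffix sums of log x
  std::vector<double> slog(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) slog[i] = slog[i + 1] + std::log(xs[i]);
  for (int k = 0; k < n - 1; ++k) {
    if (k > 0 && xs[k] == xs[k - 1]) continue;     // distinct values only
    double xmin = xs[k];
    if (xs[n - 1] == xmin) break;                  // no distinct tail value
    int nt = n - k;
    double S = slog[k] - nt * std::log(xmin);
    if (S <= 0) continue;
    double alpha = 1.0 + nt / S;
    double D = 0.0;
    for (int i = 0; i < nt; ++i) {
      double F = 1.0 - std::pow(xs[k + i] / xmin, 1.0 - alpha);
      double hi = (double)(i + 1) / nt, lo = (double)i / nt;
      double d1 = std::fabs(F - hi), d2 = std::fabs(F - lo);
      if (d1 > D) D = d1;
      if (d2 > D) D = d2;
    }
    vxmin.push_back(xmin); valpha.push_back(alpha);
    vks.push_back(D); vnt.push_back(nt);
  }
  return DataFrame::create(_["xmin"] = vxmin, _["alpha"] = valpha,
                           _["n_tail"] = vnt, _["ks"] = vks);
}
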