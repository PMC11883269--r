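#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Version codes: 0 = threshold, 1 = mutual.
// Coupling codes: 0 = multiplicative, 1 = additive, 2 = demographic.

static int lead_of(const std::vector<double>& O, double alpha) {
  const int n = (int)O.size();
  int mx = 0;
  for (int i = 1; i < n; ++i)
    if (O[i] > O[mx]) mx = i;
  double second = -1.0e300;
  for (int i = 0; i < n; ++i)
    if (i != mx && O[i] > second) second = O[i];
  return (O[mx] - second >= alpha) ? (mx + 1) : 0;
}

static void multipliers(const std::vector<double>& O, int version, double K,
                        double m, double alpha, std::vector<double>& h) {
  const int n = (int)O.size();
  const double Km = std::pow(K, m);
  if (version == 0) {
    std::fill(h.begin(), h.end(), 1.0);
    const int lead = lead_of(O, alpha);
    if (lead > 0) {
      const double f = Km / (Km + std::pow(O[lead - 1], m));
      for (int i = 0; i < n; ++i) h[i] = (i == lead - 1) ? 1.0 : f;
    }
  } else {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += O[i];
    for (int i = 0; i < n; ++i) {
      const double s = tot - O[i];
      h[i] = Km / (Km + std::pow(s, m));
    }
  }
}

static inline double couple(double x, int coupling) {
  switch (coupling) {
    case 0: return x;
    case 1: return 1.0;
    default: return std::sqrt(x);
  }
}

// Euler-Maruyama integration of the five-lineage inner/outer model.
// Uses R's RNG: per step draws n normals for the outer components, then n
// for the inner components, so an R-side reimplementation drawing
// rnorm(n); rnorm(n) under the same seed reproduces it exactly.
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n, double r, double gamma, double sigma, double K, double m,
              double alpha, int version, int coupling, double t_end, double dt,
              int record_every) {
  const int nstep = (int)std::lround(t_end / dt);
  std::vector<double> O(n, 1.0), I(n, 0.0), h(n);
  const double sqdt = std::sqrt(dt);

  std::vector<int> rec_steps;
  for (int k = 0; k <= nstep; k += record_every) rec_steps.push_back(k);
  if (rec_steps.back() != nstep) rec_steps.push_back(nstep);
  const int nrec = (int)rec_steps.size();

  NumericVector times(nrec);
  NumericMatrix outer(nrec, n), inner(nrec, n);
  int ri = 0;
  auto record = [&](int k) {
    times[ri] = k * dt;
    for (int i = 0; i < n; ++i) {
      outer(ri, i) = O[i];
      inner(ri, i) = I[i];
    }
    ++ri;
  };
  record(0);

  for (int k = 1; k <= nstep; ++k) {
    multipliers(O, version, K, m, alpha, h);
    NumericVector zO = Rcpp::rnorm(n);
    NumericVector zI = Rcpp::rnorm(n);
    for (int i = 0; i < n; ++i) {
      const double dO = 0.5 * r * h[i] * O[i];
      const double dI = 0.5 * r * h[i] * O[i] + gamma * r * h[i] * I[i];
      double On = O[i] + dt * dO + sigma * couple(O[i], coupling) * sqdt * zO[i];
      double In = I[i] + dt * dI + sigma * couple(I[i], coupling) * sqdt * zI[i];
      if (!std::isfinite(On) || !std::isfinite(In))
        stop("non-finite state at step %d (t = %g h), lineage %d", k, k * dt,
             i + 1);
      O[i] = On > 0.0 ? On : 0.0;
      I[i] = In > 0.0 ? In : 0.0;
    }
    if (ri < nrec && rec_steps[ri] == k) record(k);
  }

  return List::create(_["times"] = times, _["outer"] = outer,
                      _["inner"] = inner);
}
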