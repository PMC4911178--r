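#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Overdamped Brownian dynamics of unit-diameter adhesive discs in a
// corrugated strip. Pair interactions act below the cutoff 1 + R. The
// corrugated upper boundary is supplied as a regularly spaced height table
// (clearances against it use vertical distance, valid for a slowly varying
// profile). Neighbour search keeps the nuclei x-sorted (the strip is
// quasi-one-dimensional, so an insertion-sort repair each step is O(n)) and
// sweeps forward while the x-gap is below the cutoff, accumulating each
// pair once.
//
// Noise comes from a xoshiro256++ stream (polar Box-Muller normals) whose
// 256-bit state is seeded from R's RNG, so trajectories are reproducible
// from set.seed() and the integer stream is platform-independent.

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform on (0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53 + 0x1.0p-54; }

  bool have_spare = false;
  double spare = 0.0;
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; have_spare = true;
    return u * f;
  }
};

struct WallTable {
  double x0, dx;
  const double* h;
  int n;
  double T;
  // vertical position of the upper boundary at x (linear table lookup)
  inline double top(double x) const {
    double u = (x - x0) / dx;
    if (u <= 0.0) return T + h[0];
    if (u >= n - 1) return T + h[n - 1];
    int k = (int)u;
    double f = u - k;
    return T + (1.0 - f) * h[k] + f * h[k + 1];
  }
};

} // namespace

// [[Rcpp::export(name = ".bd_run_cpp")]]
List bd_run_cpp(NumericMatrix start, IntegerVector entry_step,
                int n_steps, double dt,
                double krep, double S, double R, double D,
                double L, double T,
                NumericVector wall_h, double wall_x0, double wall_dx,
                IntegerVector snapshot_steps) {
  const int n = start.nrow();
  const double cutoff = 1.0 + R;
  const double cutoff2 = cutoff * cutoff;
  const double noise = std::sqrt(2.0 * D * dt);
  const bool interacting = (krep > 0.0 || S > 0.0);
  const double two_krep = 2.0 * krep;
  const double well = (R > 0.0) ? 2.0 * S / R : 0.0;

  std::vector<double> x(n), y(n), fx(n), fy(n);
  std::vector<char> act(n);
  for (int i = 0; i < n; ++i) { x[i] = start(i, 0); y[i] = start(i, 1); }

  // seed the fast stream from R's RNG so set.seed() governs everything
  Xoshiro rng;
  for (int k = 0; k < 4; ++k) {
    uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
    rng.s[k] = (a << 32) ^ b ^ (0x9E3779B97F4A7C15ULL * (k + 1));
  }
  for (int k = 0; k < 8; ++k) rng.next();  // warm up

  WallTable wall{wall_x0, wall_dx, wall_h.begin(), (int)wall_h.size(), T};

  // persistent x-sorted order (inactive nuclei sit at their entry position)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  auto repair_sort = [&]() {
    for (int a = 1; a < n; ++a) {
      int i = ord[a];
      double xi = x[i];
      int b = a - 1;
      while (b >= 0 && x[ord[b]] > xi) { ord[b + 1] = ord[b]; --b; }
      ord[b + 1] = i;
    }
  };
  repair_sort();

  const int nsnap = snapshot_steps.size();
  List snaps(nsnap);
  int isnap = 0;
  auto record = [&](int slot) {
    NumericMatrix m(n, 2);
    for (int i = 0; i < n; ++i) { m(i, 0) = x[i]; m(i, 1) = y[i]; }
    snaps[slot] = m;
  };
  while (isnap < nsnap && snapshot_steps[isnap] <= 0) { record(isnap); ++isnap; }

  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      act[i] = entry_step[i] <= s;
      fx[i] = 0.0; fy[i] = 0.0;
    }

    if (interacting) {
      for (int a = 0; a < n; ++a) {
        int i = ord[a];
        if (!act[i]) continue;
        double xi = x[i], yi = y[i];
        for (int b = a + 1; b < n; ++b) {
          int j = ord[b];
          double ddx = x[j] - xi;
          if (ddx > cutoff) break;
          if (!act[j]) continue;
          double ddy = y[j] - yi;
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 >= cutoff2 || d2 == 0.0) continue;
          double d = std::sqrt(d2);
          double f = (d < 1.0) ? two_krep * (1.0 - d)
                               : -well * (1.0 - (d - 1.0) / R);
          double g = f / d;
          fx[i] -= g * ddx; fy[i] -= g * ddy;   // push i away from j if f > 0
          fx[j] += g * ddx; fy[j] += g * ddy;
        }
        // walls: lower line y = 0, upper profile, end walls x = 0 and x = L
        if (yi < 0.5) fy[i] += krep * (0.5 - yi);
        double ct = wall.top(xi) - yi;          // clearance to upper boundary
        if (ct < 0.5) fy[i] -= krep * (0.5 - ct);
        if (xi < 0.5) fx[i] += krep * (0.5 - xi);
        double cr = L - xi;
        if (cr < 0.5) fx[i] -= krep * (0.5 - cr);
      }
    }

    if (D > 0.0) {
      for (int i = 0; i < n; ++i) {
        if (!act[i]) continue;
        x[i] += fx[i] * dt + noise * rng.norm();
        y[i] += fy[i] * dt + noise * rng.norm();
      }
    } else {
      for (int i = 0; i < n; ++i) {
        if (!act[i]) continue;
        x[i] += fx[i] * dt;
        y[i] += fy[i] * dt;
      }
    }
    for (int i = 0; i < n; ++i)
      if (act[i] && (!std::isfinite(x[i]) || !std::isfinite(y[i])))
        stop("non-finite position for nucleus %d at step %d (dt = %g)",
             i + 1, s, dt);
    repair_sort();

    while (isnap < nsnap && snapshot_steps[isnap] == s) { record(isnap); ++isnap; }
  }
  while (isnap < nsnap) { record(isnap); ++isnap; }

  NumericMatrix fin(n, 2);
  for (int i = 0; i < n; ++i) { fin(i, 0) = x[i]; fin(i, 1) = y[i]; }
  return List::create(_["positions"] = fin, _["snapshots"] = snaps);
}
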