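#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of y(t) on a sorted grid; constant extrapolation.
static double interp_grid(const NumericVector& gt, const NumericVector& gy,
                          double t) {
  int n = gt.size();
  if (t <= gt[0]) return gy[0];
  if (t >= gt[n - 1]) return gy[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (gt[mid] <= t) lo = mid; else hi = mid;
  }
  double w = (t - gt[lo]) / (gt[hi] - gt[lo]);
  return gy[lo] + w * (gy[hi] - gy[lo]);
}

// Hybrid simulation of tagged clones.
//
// Each clone starts from `founders[i]` cells at t = 0. Until `tau` cells die
// at rate c and do not divide. After `tau` each cell divides at the
// time-varying per-capita rate b(t) (the strain replication rate damped by
// the shared logistic saturation factor, tabulated on `grid_t`/`b_grid`)
// and dies at rate c. Simulation is an exact thinning (Ogata) algorithm
// using the running upper bound `b_runmax[t] = max_{s>=t} b(s)`; once a
// clone exceeds `switch_size` cells its extinction risk is negligible and it
// is propagated deterministically to `t_tot` using the tabulated cumulative
// birth integral `cumb(t) = int_0^t b(s) ds`:
//   n(T) = n(t_s) * exp( (cumb(T) - cumb(t_s)) - c * (T - t_s) ).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector simulate_clones_cpp(IntegerVector founders, double tau,
                                  double c, NumericVector grid_t,
                                  NumericVector b_grid,
                                  NumericVector b_runmax,
                                  NumericVector cumb, double t_tot,
                                  double switch_size) {
  int nclones = founders.size();
  NumericVector out(nclones);
  double cumb_T = interp_grid(grid_t, cumb, t_tot);

  for (int i = 0; i < nclones; ++i) {
    double n = founders[i];
    double t = 0.0;

    // lag phase: pure death at rate c
    if (tau > 0.0 && n > 0.0 && c > 0.0) {
      double tend = std::min(tau, t_tot);
      while (t < tend && n > 0.0) {
        double dt = exp_rand() / (n * c);
        if (t + dt >= tend) { t = tend; break; }
        t += dt;
        n -= 1.0;
      }
    }
    t = std::min(std::max(t, tau), t_tot);

    // growth phase: thinned birth-death
    while (t < t_tot && n > 0.0 && n < switch_size) {
      double bmax = interp_grid(grid_t, b_runmax, t);
      double rate = n * (bmax + c);
      if (rate <= 0.0) { t = t_tot; break; }
      double dt = exp_rand() / rate;
      t += dt;
      if (t >= t_tot) break;
      double u = unif_rand() * (bmax + c);
      double bt = interp_grid(grid_t, b_grid, t);
      if (u < bt) {
        n += 1.0;
      } else if (u < bt + c) {
        n -= 1.0;
      } // else: thinned, no event
    }

    // deterministic continuation for established clones
    if (n >= switch_size && t < t_tot) {
      double cumb_t = interp_grid(grid_t, cumb, t);
      n = n * std::exp((cumb_T - cumb_t) - c * (t_tot - t));
    }
    out[i] = n;
  }
  return out;
}
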