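#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact birth-death SSA for mRNA over one cell-cycle span [t0, t1] with a
// piecewise-constant transcription rate: rate segments are defined by
// interior change points `cuts` (cycle-age coordinates, ascending) and
// `rates` (length cuts.size() + 1). gamma is the per-molecule decay rate.
static int ssa_span(int M, double t0, double t1, double gamma,
                    const std::vector<double>& cuts,
                    const std::vector<double>& rates) {
  std::size_t seg = 0;
  while (seg < cuts.size() && cuts[seg] <= t0) ++seg;
  double t = t0;
  while (t < t1) {
    double seg_end = (seg < cuts.size() && cuts[seg] < t1) ? cuts[seg] : t1;
    double A = rates[seg];
    for (;;) {
      double a0 = A + gamma * M;
      if (a0 <= 0.0) { t = seg_end; break; }
      double dt = R::rexp(1.0 / a0);
      if (t + dt >= seg_end) { t = seg_end; break; }
      t += dt;
      if (R::unif_rand() * a0 < A) ++M; else --M;
    }
    ++seg;
  }
  return M;
}

// Build the within-cycle rate schedule for a phase-dependent model:
// rate k_g1 before the G1->S/G2/M transition at age `tau`, k_g1 * f after;
// optionally doubled from age `repl_age` (gene dosage after replication).
static void schedule(double tau, double f_rate, double k_g1,
                     bool dosage, double repl_age, double t_cyc,
                     std::vector<double>& cuts, std::vector<double>& rates) {
  cuts.clear(); rates.clear();
  std::vector<double> pts;
  if (tau > 0.0 && tau < t_cyc) pts.push_back(tau);
  if (dosage && repl_age > 0.0 && repl_age < t_cyc) pts.push_back(repl_age);
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  cuts = pts;
  double prev = 0.0;
  for (std::size_t i = 0; i <= cuts.size(); ++i) {
    double lo = (i == 0) ? 0.0 : cuts[i - 1];
    double r = (lo >= tau) ? f_rate : k_g1;
    if (dosage && lo >= repl_age) r *= 2.0;
    rates.push_back(r);
    prev = lo;
  }
  (void)prev;
}

//' @title Gillespie snapshot counts (internal)
//' @description Simulates mRNA birth-death through `n_burn` full cell cycles
//'   (binomial halving at each division) and then to each cell's sampled age,
//'   with a per-cycle randomized G1->S/G2/M rate transition. Uses R's RNG.
//' @keywords internal
// [[Rcpp::export(name = ".ssa_snapshot_cpp")]]
IntegerVector ssa_snapshot_cpp(NumericVector ages, double t_cyc,
                               double gamma, double k_g1, double k_sgm,
                               double bud_frac, double window,
                               bool dosage, double repl_frac, int n_burn) {
  int n = ages.size();
  IntegerVector out(n);
  std::vector<double> cuts, rates;
  double bud_age = bud_frac * t_cyc;
  double repl_age = repl_frac * t_cyc;
  for (int i = 0; i < n; ++i) {
    int M = (int)R::rpois(k_g1 / gamma);
    for (int c = 0; c < n_burn; ++c) {
      double tau = bud_age + (window > 0 ? R::unif_rand() * window : 0.0);
      if (tau > t_cyc) tau = t_cyc;
      schedule(tau, k_sgm, k_g1, dosage, repl_age, t_cyc, cuts, rates);
      M = ssa_span(M, 0.0, t_cyc, gamma, cuts, rates);
      M = (int)R::rbinom((double)M, 0.5);
    }
    double tau = bud_age + (window > 0 ? R::unif_rand() * window : 0.0);
    if (tau > t_cyc) tau = t_cyc;
    schedule(tau, k_sgm, k_g1, dosage, repl_age, t_cyc, cuts, rates);
    M = ssa_span(M, 0.0, ages[i], gamma, cuts, rates);
    out[i] = M;
  }
  return out;
}
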