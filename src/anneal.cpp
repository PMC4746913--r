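#include <Rcpp.h>

#include <cmath>
#include <random>

#include "netter_core.h"

using namespace Rcpp;
using netter::Engine;
using netter::Penalty;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(double seed)
      : gen(static_cast<std::uint64_t>(seed)) {}
  double unif01() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(gen);
  }
  int unif_int(int lo, int hi) {
    return std::uniform_int_distribution<int>(lo, hi)(gen);
  }
};

// One mutation: gamma distinct links, each displaced by a nonzero offset in
// [-Theta, Theta], target ranks clamped to [1, x], applied sequentially.
std::vector<std::pair<int, int>> propose(const Engine& eng, Rng& rng,
                                         int Gamma, int Theta) {
  int x = eng.x();
  int gamma = rng.unif_int(1, std::min(Gamma, x));
  std::vector<int> chosen;
  chosen.reserve(gamma);
  while (static_cast<int>(chosen.size()) < gamma) {
    int link = rng.unif_int(0, x - 1);
    bool dup = false;
    for (int c : chosen)
      if (c == link) {
        dup = true;
        break;
      }
    if (!dup) chosen.push_back(link);
  }
  std::vector<std::pair<int, int>> moves;
  moves.reserve(gamma);
  for (int link : chosen) {
    int theta = 0;
    while (theta == 0) theta = rng.unif_int(-Theta, Theta);
    moves.emplace_back(link, theta);  // resolved and clamped at apply time
  }
  return moves;
}

}  // namespace

// Single simulated-annealing run over the rank permutation held by an
// Engine built from the arguments. Returns the final ranks plus run
// diagnostics; bit-reproducible for a fixed seed.
// [[Rcpp::export]]
List cpp_anneal(IntegerVector reg, IntegerVector tgt, int n_nodes, int step,
                IntegerVector pen_stat, NumericVector pen_a,
                NumericVector pen_b, NumericVector pen_w,
                LogicalVector pen_clamp, NumericVector pi, double alpha,
                int iterations, int Gamma, int Theta, double T0, double mu,
                double window_frac, double accept_lo, double accept_hi,
                int max_restarts, double seed, bool accept_all,
                int check_every, int log_every) {
  if (iterations < 1) stop("iterations must be >= 1");
  if (Gamma < 1 || Theta < 1) stop("Gamma and Theta must be >= 1");
  if (mu <= 0 || mu >= 1) stop("mu must lie in (0, 1)");
  if (window_frac <= 0 || window_frac >= 1)
    stop("start window fraction must lie in (0, 1)");

  std::vector<Penalty> pens;
  bool track = false;
  for (int i = 0; i < pen_stat.size(); ++i) {
    pens.push_back(Penalty{pen_stat[i], pen_a[i], pen_b[i], pen_w[i],
                           pen_clamp[i] == TRUE});
    if (pen_w[i] > 0) track = true;
  }
  if (accept_all) track = false;  // costs are ignored entirely

  Engine eng(as<std::vector<int>>(reg), as<std::vector<int>>(tgt), n_nodes,
             step, pens, as<std::vector<double>>(pi), alpha, track);
  Rng rng(seed);

  // The temperature exists to make the *structural* landscape explorable;
  // beyond the structural cost's own span it only buys violations of the
  // divergence regularizer. Cap the automatic temperature at twice the
  // maximum attainable structural cost so a dominant alpha stays dominant
  // (the alpha -> infinity limit must freeze the ranking).
  double s_max = 0.0;
  for (const Penalty& p : pens) {
    double m = p.clamp ? std::max({0.0, p.b, p.a + p.b})
                       : std::max(std::fabs(p.b), std::fabs(p.a + p.b));
    s_max += p.w * m;
  }
  double pi_sum = 0.0;
  for (double v : pi) pi_sum += v;
  double T_cap = 2.0 * s_max * pi_sum;
  if (!(T_cap > 0)) T_cap = 1e-12;

  // Auto-calibrate T0 from the mean |delta cost| of 100 probe mutations so
  // the typical bad move starts near the target acceptance probability.
  double T0_cur = T0;
  if (!std::isfinite(T0_cur) || T0_cur <= 0) {
    double target = (accept_lo + accept_hi) / 2.0;
    double acc = 0.0;
    int m = 0;
    double base = eng.total();
    for (int k = 0; k < 100; ++k) {
      eng.apply_offsets(propose(eng, rng, Gamma, Theta));
      double d = std::fabs(eng.total() - base);
      eng.revert();
      if (d > 0) {
        acc += d;
        ++m;
      }
    }
    T0_cur = m > 0 ? (acc / m) / std::log(1.0 / target) : 1.0;
    T0_cur = std::min(T0_cur, T_cap);
  }

  int window = std::max(1, static_cast<int>(std::lround(window_frac *
                                                        iterations)));
  double window_ratio = NA_REAL;
  int restarts = 0;
  double max_err = 0.0;
  long long n_accepted = 0, bad_proposed = 0, bad_accepted = 0;
  std::vector<double> traj;
  int n_pen = static_cast<int>(pens.size());

  for (;;) {
    eng.reset_to_original();
    double T = T0_cur;
    double cur = accept_all ? 0.0 : eng.total();
    n_accepted = bad_proposed = bad_accepted = 0;
    bool restart_needed = false;
    traj.clear();

    for (int it = 1; it <= iterations; ++it) {
      eng.apply_offsets(propose(eng, rng, Gamma, Theta));
      bool acc;
      if (accept_all) {
        acc = true;
      } else {
        double cand = eng.total();
        double d = cand - cur;
        if (d < 0) {
          acc = true;
        } else {
          ++bad_proposed;
          acc = rng.unif01() < std::exp(-d / T);
          if (acc) ++bad_accepted;
        }
        if (acc) cur = cand;
      }
      if (acc) {
        eng.commit();
        ++n_accepted;
      } else {
        eng.revert();
      }
      T *= mu;

      if (check_every > 0 && it % check_every == 0) {
        double err = std::fabs(eng.scratch_total() -
                               (accept_all ? eng.total() : cur));
        if (err > max_err) max_err = err;
      }
      if (log_every > 0 && it % log_every == 0) {
        traj.push_back(it);
        traj.push_back(T);
        traj.push_back(accept_all ? eng.total() : cur);
        traj.push_back(eng.structural());
        traj.push_back(eng.divergence());
        traj.push_back(acc ? 1.0 : 0.0);
        std::vector<double> pb = eng.penalty_breakdown();
        for (double v : pb) traj.push_back(v);
      }

      if (it == window && !accept_all) {
        if (bad_proposed > 0) {
          double ratio =
              static_cast<double>(bad_accepted) / bad_proposed;
          window_ratio = ratio;
          if (ratio < accept_lo) {
            if (T0_cur < T_cap) {  // too cold: bad moves never accepted
              T0_cur = std::min(T0_cur * 2.0, T_cap);
              restart_needed = true;
            }
            // at the cap the divergence term dominates every structural
            // gain at any useful temperature: the frozen search is the
            // converged limit, so the run continues as-is
          } else if (ratio > accept_hi) {
            T0_cur /= 2.0;  // too hot: search degenerates to a shuffle
            restart_needed = true;
          }
        } else {
          window_ratio = NA_REAL;  // flat cost surface: nothing to calibrate
        }
        if (restart_needed) break;
      }
      if (it % 2048 == 0) Rcpp::checkUserInterrupt();
    }

    if (!restart_needed) break;
    ++restarts;
    if (restarts > max_restarts)
      stop("annealing calibration failed after %d restarts "
           "(last bad-move acceptance ratio %.3f)",
           restarts - 1, window_ratio);
  }

  IntegerVector ranks = wrap(eng.pos());
  List out = List::create(
      _["rank"] = ranks, _["bad_accept_ratio"] = window_ratio,
      _["restarts"] = restarts, _["T0"] = T0_cur,
      _["accepted"] = static_cast<double>(n_accepted),
      _["bad_proposed"] = static_cast<double>(bad_proposed),
      _["bad_accepted"] = static_cast<double>(bad_accepted),
      _["max_cost_err"] = max_err);
  if (log_every > 0) {
    int ncol = 6 + n_pen;
    int nrow = static_cast<int>(traj.size()) / ncol;
    NumericMatrix tm(nrow, ncol);
    for (int r = 0; r < nrow; ++r)
      for (int c = 0; c < ncol; ++c) tm(r, c) = traj[r * ncol + c];
    CharacterVector cn(ncol);
    cn[0] = "iteration";
    cn[1] = "temperature";
    cn[2] = "total";
    cn[3] = "structural";
    cn[4] = "divergence";
    cn[5] = "accepted";
    for (int j = 0; j < n_pen; ++j) cn[6 + j] = "penalty" + std::to_string(j + 1);
    colnames(tm) = cn;
    out["trajectory"] = tm;
  }
  return out;
}
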