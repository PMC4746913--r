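#include <Rcpp.h>

#include "netter_core.h"

using namespace Rcpp;
using netter::Engine;
using netter::GraphletCounter;
using netter::Penalty;

namespace {

std::vector<Penalty> make_penalties(IntegerVector stat, NumericVector a,
                                    NumericVector b, NumericVector w,
                                    LogicalVector clamp) {
  std::vector<Penalty> out;
  for (int i = 0; i < stat.size(); ++i)
    out.push_back(Penalty{stat[i], a[i], b[i], w[i], clamp[i] == TRUE});
  return out;
}

NumericVector counts_vector(const std::array<long long, 9>& c) {
  NumericVector out(9);
  CharacterVector nm(9);
  for (int i = 0; i < 9; ++i) {
    out[i] = static_cast<double>(c[i]);
    nm[i] = "G" + std::to_string(i);
  }
  out.attr("names") = nm;
  return out;
}

}  // namespace

// ---- graphlet counter ------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_graphlet_trace(int n_nodes, IntegerMatrix ops) {
  GraphletCounter gc(n_nodes);
  NumericMatrix out(ops.nrow(), 9);
  CharacterVector nm(9);
  for (int i = 0; i < 9; ++i) nm[i] = "G" + std::to_string(i);
  colnames(out) = nm;
  for (int i = 0; i < ops.nrow(); ++i) {
    int u = ops(i, 0) - 1, v = ops(i, 1) - 1;
    if (ops(i, 2) == 1)
      gc.add_edge(u, v);
    else
      gc.remove_edge(u, v);
    for (int k = 0; k < 9; ++k)
      out(i, k) = static_cast<double>(gc.counts()[k]);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_graphlet_counts(int n_nodes, IntegerMatrix edges) {
  GraphletCounter gc(n_nodes);
  for (int i = 0; i < edges.nrow(); ++i)
    gc.add_edge(edges(i, 0) - 1, edges(i, 1) - 1);
  return counts_vector(gc.counts());
}

// ---- subnetwork stack / engine --------------------------------------------

// [[Rcpp::export]]
SEXP cpp_engine_new(IntegerVector reg, IntegerVector tgt, int n_nodes,
                    int step, IntegerVector pen_stat, NumericVector pen_a,
                    NumericVector pen_b, NumericVector pen_w,
                    LogicalVector pen_clamp, NumericVector pi, double alpha,
                    bool track) {
  XPtr<Engine> ptr(
      new Engine(as<std::vector<int>>(reg), as<std::vector<int>>(tgt), n_nodes,
                 step, make_penalties(pen_stat, pen_a, pen_b, pen_w, pen_clamp),
                 as<std::vector<double>>(pi), alpha, track),
      true);
  return ptr;
}

// [[Rcpp::export]]
void cpp_engine_apply(SEXP xp, IntegerVector links, IntegerVector new_pos) {
  XPtr<Engine> eng(xp);
  std::vector<std::pair<int, int>> moves;
  for (int i = 0; i < links.size(); ++i)
    moves.emplace_back(links[i] - 1, new_pos[i]);
  eng->apply_moves(moves);
}

// [[Rcpp::export]]
void cpp_engine_revert(SEXP xp) { XPtr<Engine>(xp)->revert(); }

// [[Rcpp::export]]
void cpp_engine_commit(SEXP xp) { XPtr<Engine>(xp)->commit(); }

// [[Rcpp::export]]
int cpp_engine_txn_depth(SEXP xp) {
  return static_cast<int>(XPtr<Engine>(xp)->txn_depth());
}

// [[Rcpp::export]]
void cpp_engine_reset(SEXP xp) { XPtr<Engine>(xp)->reset_to_original(); }

// [[Rcpp::export]]
IntegerVector cpp_engine_ranks(SEXP xp) {
  return wrap(XPtr<Engine>(xp)->pos());
}

// [[Rcpp::export]]
IntegerVector cpp_engine_cuts(SEXP xp) {
  return wrap(XPtr<Engine>(xp)->cuts());
}

// [[Rcpp::export]]
NumericVector cpp_engine_counts(SEXP xp, int i) {
  XPtr<Engine> eng(xp);
  return counts_vector(eng->subnet(i - 1).gc.counts());
}

// [[Rcpp::export]]
NumericVector cpp_engine_ys(SEXP xp, int i) {
  XPtr<Engine> eng(xp);
  const netter::SubNet& sn = eng->subnet(i - 1);
  return NumericVector::create(_["graphlet"] = sn.y_g4(),
                               _["regulatory"] = sn.y_reg(),
                               _["antidominating"] = sn.y_anti());
}

// [[Rcpp::export]]
IntegerMatrix cpp_engine_edges(SEXP xp, int i) {
  XPtr<Engine> eng(xp);
  int c = eng->cuts().at(i - 1);
  IntegerMatrix out(c, 2);
  for (int k = 0; k < c; ++k) {
    int link = eng->order()[k];
    out(k, 0) = eng->reg_of(link) + 1;
    out(k, 1) = eng->tgt_of(link) + 1;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_engine_total(SEXP xp) { return XPtr<Engine>(xp)->total(); }

// [[Rcpp::export]]
double cpp_engine_structural(SEXP xp) { return XPtr<Engine>(xp)->structural(); }

// [[Rcpp::export]]
double cpp_engine_divergence(SEXP xp) { return XPtr<Engine>(xp)->divergence(); }

// [[Rcpp::export]]
double cpp_engine_scratch_total(SEXP xp) {
  return XPtr<Engine>(xp)->scratch_total();
}
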