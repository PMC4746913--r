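#include "netter_core.h"

#include <algorithm>

namespace netter {

namespace {
inline double sq(double v) { return v * v; }

inline long long pair_key(int u, int v, int n) {
  if (u > v) std::swap(u, v);
  return static_cast<long long>(u) * n + v;
}
}  // namespace

int classify4(int mask) {
  static const int edge_end[6][2] = {{0, 1}, {0, 2}, {0, 3},
                                     {1, 2}, {1, 3}, {2, 3}};
  int e = 0, deg[4] = {0, 0, 0, 0};
  for (int i = 0; i < 6; ++i) {
    if (mask >> i & 1) {
      ++e;
      ++deg[edge_end[i][0]];
      ++deg[edge_end[i][1]];
    }
  }
  if (e < 3) return -1;  // cannot connect 4 nodes
  int mind = deg[0], maxd = deg[0];
  for (int k = 1; k < 4; ++k) {
    mind = std::min(mind, deg[k]);
    maxd = std::max(maxd, deg[k]);
  }
  if (e == 3) {
    if (mind == 0) return -1;     // triangle + isolated node
    return maxd == 3 ? 1 : 0;     // G4 star : G3 path
  }
  if (e == 4) return maxd == 3 ? 3 : 2;  // G6 tailed triangle : G5 cycle
  return e == 5 ? 4 : 5;                 // G7 diamond : G8 K4
}

void GraphletCounter::check_nodes(int u, int v) const {
  if (u < 0 || v < 0 || u >= n_ || v >= n_)
    throw std::invalid_argument("node index out of range");
  if (u == v) throw std::invalid_argument("self-loops are not allowed");
}

void GraphletCounter::add_edge(int u, int v) {
  check_nodes(u, v);
  if (adj(u, v)) throw std::invalid_argument("edge already present");
  apply_delta(u, v, +1);
  nbr_[u].push_back(v);
  nbr_[v].push_back(u);
  mat_[static_cast<std::size_t>(u) * n_ + v] = 1;
  mat_[static_cast<std::size_t>(v) * n_ + u] = 1;
}

void GraphletCounter::remove_edge(int u, int v) {
  check_nodes(u, v);
  if (!adj(u, v)) throw std::invalid_argument("edge not present");
  for (int* e : {&u, &v}) {
    std::vector<int>& lst = nbr_[*e];
    int other = (e == &u) ? v : u;
    for (std::size_t i = 0; i < lst.size(); ++i)
      if (lst[i] == other) {
        lst[i] = lst.back();
        lst.pop_back();
        break;
      }
  }
  mat_[static_cast<std::size_t>(u) * n_ + v] = 0;
  mat_[static_cast<std::size_t>(v) * n_ + u] = 0;
  apply_delta(u, v, -1);
}

void GraphletCounter::apply_delta(int u, int v, int sign) {
  cnt_[0] += sign;  // G0 tracks the edge count

  // Precomputed classification of the 64 possible 4-node edge masks.
  static const std::array<int, 64> cls = [] {
    std::array<int, 64> t{};
    for (int m = 0; m < 64; ++m) t[m] = classify4(m);
    return t;
  }();

  // Union neighbourhood of the endpoints decides the 3-node deltas.
  ++stamp_;
  S_.clear();
  for (int w : nbr_[u])
    if (w != v) {
      S_.push_back(w);
      mark_[w] = stamp_;
    }
  for (int w : nbr_[v])
    if (w != u && mark_[w] != stamp_) {
      S_.push_back(w);
      mark_[w] = stamp_;
    }

  for (int w : S_) {
    if (adj(u, w) && adj(v, w)) {  // 2-path closes into a triangle
      cnt_[1] -= sign;
      cnt_[2] += sign;
    } else {
      cnt_[1] += sign;
    }
  }

  // 4-node deltas: every quadruple {u,v,w,z} connected before or after the
  // toggle has w,z within distance 2 of {u,v}, enumerated without repeats
  // as (pairs inside S) plus (w in S, z a neighbour of w outside S).
  auto handle = [&](int w, int z) {
    int m = 0;
    if (adj(u, w)) m |= 1 << 1;
    if (adj(u, z)) m |= 1 << 2;
    if (adj(v, w)) m |= 1 << 3;
    if (adj(v, z)) m |= 1 << 4;
    if (adj(w, z)) m |= 1 << 5;
    int before = cls[m];          // uv absent
    int after = cls[m | 1];       // uv present
    if (before >= 0) cnt_[3 + before] -= sign;
    if (after >= 0) cnt_[3 + after] += sign;
  };

  for (std::size_t i = 0; i < S_.size(); ++i)
    for (std::size_t j = i + 1; j < S_.size(); ++j) handle(S_[i], S_[j]);
  for (int w : S_)
    for (int z : nbr_[w])
      if (z != u && z != v && mark_[z] != stamp_) handle(w, z);
}

void SubNet::add_link(int reg, int tgt) {
  ++n_links;
  for (int node : {reg, tgt})
    if (inc[node]++ == 0) ++nodes_present;
  int d = outdeg[reg]++;
  if (d == 0)
    ++nodes_with_out;
  else
    --out_hist[d];
  if (d + 1 >= static_cast<int>(out_hist.size())) out_hist.resize(d + 2, 0);
  ++out_hist[d + 1];
  max_out = std::max(max_out, d + 1);

  long long key = pair_key(reg, tgt, n_nodes);
  if (++mult[key] == 1) gc.add_edge(reg, tgt);
}

void SubNet::remove_link(int reg, int tgt) {
  --n_links;
  for (int node : {reg, tgt})
    if (--inc[node] == 0) --nodes_present;
  int d = outdeg[reg]--;
  --out_hist[d];
  if (d - 1 == 0)
    --nodes_with_out;
  else
    ++out_hist[d - 1];
  while (max_out > 0 && out_hist[max_out] == 0) --max_out;

  long long key = pair_key(reg, tgt, n_nodes);
  auto it = mult.find(key);
  if (--(it->second) == 0) {
    mult.erase(it);
    gc.remove_edge(reg, tgt);
  }
}

Engine::Engine(std::vector<int> reg, std::vector<int> tgt, int n_nodes,
               int step, std::vector<Penalty> pens, std::vector<double> pi,
               double alpha, bool track)
    : reg_(std::move(reg)),
      tgt_(std::move(tgt)),
      n_nodes_(n_nodes),
      step_(step),
      pens_(std::move(pens)),
      pi_(std::move(pi)),
      alpha_(alpha),
      track_(track) {
  int x = static_cast<int>(reg_.size());
  if (x < 2) throw std::invalid_argument("ranking must contain >= 2 links");
  if (step_ < 1 || step_ >= x)
    throw std::invalid_argument("subnetwork step must satisfy 1 <= n < x");
  for (int c = step_; c < x; c += step_) cuts_.push_back(c);
  if (track_ && pi_.size() != cuts_.size())
    throw std::invalid_argument("pi must have one coefficient per subnetwork");
  reset_to_original();
}

void Engine::reset_to_original() {
  int x = this->x();
  pos_.resize(x);
  order_.resize(x);
  for (int i = 0; i < x; ++i) {
    pos_[i] = i + 1;
    order_[i] = i;
  }
  div_ = 0.0;
  txns_.clear();
  rebuild_nets();
}

void Engine::rebuild_nets() {
  nets_.clear();
  if (!track_) return;
  nets_.resize(cuts_.size());
  for (std::size_t i = 0; i < cuts_.size(); ++i) {
    nets_[i].init(n_nodes_);
    for (int k = 0; k < cuts_[i]; ++k) {
      int link = order_[k];
      nets_[i].add_link(reg_[link], tgt_[link]);
    }
  }
}

double Engine::penalty_cost(const SubNet& sn) const {
  double c = 0.0;
  for (const Penalty& p : pens_) {
    if (p.w == 0.0) continue;
    double y = p.stat == 0 ? sn.y_g4() : p.stat == 1 ? sn.y_reg() : sn.y_anti();
    double v = p.a * y + p.b;
    c += p.w * (p.clamp ? (v > 0.0 ? v : 0.0) : std::fabs(v));
  }
  return c;
}

double Engine::structural() const {
  if (!track_) return 0.0;
  double s = 0.0;
  for (std::size_t i = 0; i < nets_.size(); ++i)
    s += pi_[i] * penalty_cost(nets_[i]);
  return s;
}

std::vector<double> Engine::penalty_breakdown() const {
  std::vector<double> out(pens_.size(), 0.0);
  if (!track_) return out;
  for (std::size_t i = 0; i < nets_.size(); ++i) {
    const SubNet& sn = nets_[i];
    for (std::size_t j = 0; j < pens_.size(); ++j) {
      const Penalty& p = pens_[j];
      double y =
          p.stat == 0 ? sn.y_g4() : p.stat == 1 ? sn.y_reg() : sn.y_anti();
      double v = p.a * y + p.b;
      out[j] += pi_[i] * p.w * (p.clamp ? (v > 0.0 ? v : 0.0) : std::fabs(v));
    }
  }
  return out;
}

double Engine::scratch_total() const {
  double dv = 0.0;
  for (int k = 0; k < x(); ++k)
    dv += sq(static_cast<double>(k + 1) - (order_[k] + 1));
  double s = 0.0;
  if (track_) {
    for (std::size_t i = 0; i < cuts_.size(); ++i) {
      SubNet sn;
      sn.init(n_nodes_);
      for (int k = 0; k < cuts_[i]; ++k) {
        int link = order_[k];
        sn.add_link(reg_[link], tgt_[link]);
      }
      s += pi_[i] * penalty_cost(sn);
    }
  }
  return s + alpha_ * dv;
}

void Engine::do_move(int link, int q) {
  int p = pos_[link];
  if (p == q) return;

  // Record subnetwork membership swaps against the pre-move order.
  std::vector<std::array<int, 3>> swaps;  // {net index, entering, leaving}
  if (track_) {
    for (std::size_t i = 0; i < cuts_.size(); ++i) {
      int c = cuts_[i];
      if (p <= c && q > c)
        swaps.push_back({static_cast<int>(i), order_[c], link});
      else if (q <= c && p > c)
        swaps.push_back({static_cast<int>(i), link, order_[c - 1]});
    }
  }

  if (p < q) {  // displaced block shifts one rank up
    for (int r = p + 1; r <= q; ++r) {
      int l2 = order_[r - 1];
      order_[r - 2] = l2;
      pos_[l2] = r - 1;
      double o = l2 + 1;
      div_ += sq(r - 1 - o) - sq(r - o);
    }
  } else {  // displaced block shifts one rank down
    for (int r = p - 1; r >= q; --r) {
      int l2 = order_[r - 1];
      order_[r] = l2;
      pos_[l2] = r + 1;
      double o = l2 + 1;
      div_ += sq(r + 1 - o) - sq(r - o);
    }
  }
  order_[q - 1] = link;
  pos_[link] = q;
  double o = link + 1;
  div_ += sq(q - o) - sq(p - o);

  for (const auto& s : swaps) {
    SubNet& sn = nets_[s[0]];
    sn.add_link(reg_[s[1]], tgt_[s[1]]);
    sn.remove_link(reg_[s[2]], tgt_[s[2]]);
  }
}

void Engine::apply_moves(const std::vector<std::pair<int, int>>& moves) {
  std::vector<std::pair<int, int>> rec;
  rec.reserve(moves.size());
  for (const auto& m : moves) {
    if (m.first < 0 || m.first >= x())
      throw std::invalid_argument("move references an unknown link");
    if (m.second < 1 || m.second > x())
      throw std::invalid_argument("target rank out of range");
    rec.emplace_back(m.first, pos_[m.first]);
    do_move(m.first, m.second);
  }
  txns_.push_back(std::move(rec));
}

void Engine::apply_offsets(const std::vector<std::pair<int, int>>& offsets) {
  std::vector<std::pair<int, int>> rec;
  rec.reserve(offsets.size());
  for (const auto& m : offsets) {
    if (m.first < 0 || m.first >= x())
      throw std::invalid_argument("move references an unknown link");
    int q = pos_[m.first] + m.second;
    q = std::max(1, std::min(x(), q));
    rec.emplace_back(m.first, pos_[m.first]);
    do_move(m.first, q);
  }
  txns_.push_back(std::move(rec));
}

void Engine::commit() {
  if (txns_.empty()) throw std::runtime_error("no transaction to commit");
  txns_.pop_back();
}

void Engine::revert() {
  if (txns_.empty()) throw std::runtime_error("no transaction to revert");
  const auto& rec = txns_.back();
  for (auto it = rec.rbegin(); it != rec.rend(); ++it)
    do_move(it->first, it->second);
  txns_.pop_back();
}

}  // namespace netter
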