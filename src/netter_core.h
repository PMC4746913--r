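#ifndef NETTER_CORE_H
#define NETTER_CORE_H

#include <array>
#include <cmath>
#include <cstdint>
#include <set>
#include <stdexcept>
#include <unordered_map>
#include <utility>
#include <vector>

namespace netter {

// Classify the induced graph on 4 labelled nodes given a 6-bit edge mask
// (bit 0: uv, 1: uw, 2: uz, 3: vw, 4: vz, 5: wz).
// Returns 0..5 for G3 (path), G4 (star), G5 (cycle), G6 (tailed triangle),
// G7 (diamond), G8 (K4); -1 if the induced graph is not connected.
int classify4(int mask);

// Exact counts of connected induced 3- and 4-node subgraph classes
// (G0 = edge, G1 = 2-path, G2 = triangle, G3..G8 as above) of an
// undirected simple graph, maintained incrementally under single-edge
// insertion/deletion. The update enumerates only quadruples meeting the
// toggled edge through the distance-2 neighbourhood of its endpoints.
class GraphletCounter {
public:
  explicit GraphletCounter(int n_nodes = 0) { resize(n_nodes); }

  void resize(int n_nodes) {
    n_ = n_nodes;
    mat_.assign(static_cast<std::size_t>(n_) * n_, 0);
    nbr_.assign(n_, {});
    mark_.assign(n_, 0);
    stamp_ = 0;
    cnt_.fill(0);
  }

  bool has_edge(int u, int v) const {
    return u >= 0 && v >= 0 && u < n_ && v < n_ && adj(u, v);
  }

  void add_edge(int u, int v);
  void remove_edge(int u, int v);

  const std::array<long long, 9>& counts() const { return cnt_; }

private:
  int n_ = 0;
  std::vector<std::uint8_t> mat_;        // dense adjacency, O(1) lookup
  std::vector<std::vector<int>> nbr_;    // unsorted neighbour lists
  std::array<long long, 9> cnt_;
  std::vector<int> mark_;                // stamped scratch for set tests
  int stamp_ = 0;
  std::vector<int> S_;                   // scratch neighbourhood buffer

  bool adj(int a, int b) const {
    return mat_[static_cast<std::size_t>(a) * n_ + b] != 0;
  }
  void check_nodes(int u, int v) const;
  // Edge (u,v) must be absent; applies sign * (delta of adding uv).
  void apply_delta(int u, int v, int sign);
};

// One prefix subnetwork of the ranking: the directed edge set of the links
// ranked above a cut point, with cached statistics needed by the penalties.
struct SubNet {
  GraphletCounter gc;                       // undirected collapsed view
  std::unordered_map<long long, int> mult;  // undirected pair -> 1 or 2
  std::vector<int> outdeg;                  // directed out-degree per node
  std::vector<int> inc;                     // incident-link count per node
  std::vector<long long> out_hist;          // histogram of out-degrees >= 1
  int n_nodes = 0;
  int n_links = 0;
  int nodes_present = 0;
  int nodes_with_out = 0;
  int max_out = 0;

  void init(int nn) {
    n_nodes = nn;
    gc.resize(nn);
    mult.clear();
    outdeg.assign(nn, 0);
    inc.assign(nn, 0);
    out_hist.assign(2, 0);
    n_links = nodes_present = nodes_with_out = max_out = 0;
  }

  void add_link(int reg, int tgt);
  void remove_link(int reg, int tgt);

  // G4 relative frequency among connected 4-node graphlets (0 if none).
  double y_g4() const {
    long long denom = 0;
    for (int k = 3; k <= 8; ++k) denom += gc.counts()[k];
    return denom == 0 ? 0.0 : static_cast<double>(gc.counts()[4]) / denom;
  }
  // Fraction of present nodes with at least one outgoing link (0 if empty).
  double y_reg() const {
    return nodes_present == 0
               ? 0.0
               : static_cast<double>(nodes_with_out) / nodes_present;
  }
  // Max out-degree over total links (0 if no links).
  double y_anti() const {
    return n_links == 0 ? 0.0 : static_cast<double>(max_out) / n_links;
  }
};

struct Penalty {
  int stat;    // 0 = graphlet G4, 1 = regulatory, 2 = anti-dominating
  double a;
  double b;
  double w;
  bool clamp;  // zero cost left of the intercept instead of |.|
};

// The optimization state: a rank permutation of x directed links plus the
// nested prefix subnetworks at cut points n, 2n, ... < x, all updated
// incrementally per link move with exact transactional revert.
class Engine {
public:
  Engine(std::vector<int> reg, std::vector<int> tgt, int n_nodes, int step,
         std::vector<Penalty> pens, std::vector<double> pi, double alpha,
         bool track);

  int x() const { return static_cast<int>(reg_.size()); }
  int n_nodes() const { return n_nodes_; }
  bool tracking() const { return track_; }
  const std::vector<int>& cuts() const { return cuts_; }
  const std::vector<int>& order() const { return order_; }
  const std::vector<int>& pos() const { return pos_; }
  const SubNet& subnet(std::size_t i) const { return nets_.at(i); }
  int reg_of(int link) const { return reg_[link]; }
  int tgt_of(int link) const { return tgt_[link]; }

  double divergence() const { return div_; }
  double structural() const;
  double total() const { return structural() + alpha_ * div_; }
  // Per-penalty aggregated structural contribution (for trajectory logs).
  std::vector<double> penalty_breakdown() const;

  // From-scratch recomputation of the total cost for the current
  // permutation (fresh counters, no reliance on the incremental caches).
  double scratch_total() const;

  // Apply a batch of sequential moves as one revertible transaction.
  void apply_moves(const std::vector<std::pair<int, int>>& moves);
  // As apply_moves, but each move is (link, signed offset); the target rank
  // is resolved against the link's position at application time and clamped
  // to [1, x].
  void apply_offsets(const std::vector<std::pair<int, int>>& offsets);
  void commit();
  void revert();
  std::size_t txn_depth() const { return txns_.size(); }

  void reset_to_original();

private:
  std::vector<int> reg_, tgt_;
  int n_nodes_;
  int step_;
  std::vector<Penalty> pens_;
  std::vector<double> pi_;
  double alpha_;
  bool track_;

  std::vector<int> cuts_;
  std::vector<SubNet> nets_;
  std::vector<int> pos_;    // link -> 1-based rank
  std::vector<int> order_;  // 0-based rank index -> link
  double div_ = 0.0;
  std::vector<std::vector<std::pair<int, int>>> txns_;  // (link, old_pos)

  double penalty_cost(const SubNet& sn) const;
  void do_move(int link, int new_pos);
  void rebuild_nets();
};

}  // namespace netter

#endif
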