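// Maximum common connected induced subgraph (element- and bond-order-
// matched) between two heavy-atom graphs, by branch-and-bound search.
// Deterministic: atoms are processed in input order, candidate images in
// ascending index order. A wall-clock budget turns the exact search into a
// flagged lower bound when exceeded.
#include <Rcpp.h>
#include <chrono>
#include <vector>
using namespace Rcpp;

namespace {

struct McsState {
  int n1, n2;
  std::vector<int> el1, el2;            // element codes
  std::vector<std::vector<int>> adj1, adj2;  // bond-order code matrix (0 = none)
  std::vector<int> map1;                // G1 atom -> G2 atom (-1 unmapped)
  std::vector<char> used2;
  std::vector<char> excluded;           // G1 atoms excluded from this branch
  std::vector<int> avail1, avail2;      // per-element unmapped/usable counts
  int best, cur, u0;
  bool timed_out;
  long long nodes;
  std::chrono::steady_clock::time_point deadline;

  bool time_ok() {
    if (++nodes % 2048 == 0) {
      if (std::chrono::steady_clock::now() > deadline) timed_out = true;
    }
    return !timed_out;
  }

  int bound_extra() {
    int s = 0;
    for (size_t e = 0; e < avail1.size(); ++e)
      s += std::min(avail1[e], avail2[e]);
    return s;
  }

  // next frontier atom: smallest-index G1 atom >= u0, unmapped, not
  // excluded, adjacent to the mapped set
  int next_frontier() {
    for (int u = u0; u < n1; ++u) {
      if (map1[u] >= 0 || excluded[u]) continue;
      for (int a = u0; a < n1; ++a)
        if (map1[a] >= 0 && adj1[u][a]) return u;
    }
    return -1;
  }

  void search() {
    if (!time_ok()) return;
    if (cur > best) best = cur;
    if (cur + bound_extra() <= best) return;
    int u = next_frontier();
    if (u < 0) return;
    int e = el1[u];
    // branch 1: map u to each compatible v
    for (int v = 0; v < n2; ++v) {
      if (used2[v] || el2[v] != e) continue;
      bool ok = true;
      for (int a = u0; a < n1 && ok; ++a) {
        if (map1[a] < 0) continue;
        if (adj1[u][a] != adj2[v][map1[a]]) ok = false;
      }
      if (!ok) continue;
      map1[u] = v; used2[v] = 1; ++cur; --avail1[e]; --avail2[e];
      search();
      map1[u] = -1; used2[v] = 0; --cur; ++avail1[e]; ++avail2[e];
      if (timed_out) return;
    }
    // branch 2: exclude u from the subgraph
    excluded[u] = 1; --avail1[e];
    search();
    excluded[u] = 0; ++avail1[e];
  }
};

} // namespace

// [[Rcpp::export(name = ".mcs_size_cpp")]]
List mcs_size_cpp(IntegerVector el1, IntegerMatrix adj1,
                  IntegerVector el2, IntegerMatrix adj2,
                  int n_elements, double time_budget_s) {
  McsState st;
  st.n1 = el1.size(); st.n2 = el2.size();
  st.el1.assign(el1.begin(), el1.end());
  st.el2.assign(el2.begin(), el2.end());
  st.adj1.assign(st.n1, std::vector<int>(st.n1, 0));
  st.adj2.assign(st.n2, std::vector<int>(st.n2, 0));
  for (int i = 0; i < st.n1; ++i)
    for (int j = 0; j < st.n1; ++j) st.adj1[i][j] = adj1(i, j);
  for (int i = 0; i < st.n2; ++i)
    for (int j = 0; j < st.n2; ++j) st.adj2[i][j] = adj2(i, j);
  st.best = 0; st.timed_out = false; st.nodes = 0;
  st.deadline = std::chrono::steady_clock::now() +
    std::chrono::microseconds((long long)(time_budget_s * 1e6));
  std::vector<int> a2(n_elements, 0);
  for (int v = 0; v < st.n2; ++v) ++a2[st.el2[v]];

  for (int u0 = 0; u0 < st.n1 && !st.timed_out; ++u0) {
    // subgraphs whose minimum G1 index is u0
    st.u0 = u0;
    st.map1.assign(st.n1, -1);
    st.used2.assign(st.n2, 0);
    st.excluded.assign(st.n1, 0);
    st.avail1.assign(n_elements, 0);
    for (int u = u0; u < st.n1; ++u) ++st.avail1[st.el1[u]];
    st.avail2 = a2;
    st.cur = 0;
    if (st.bound_extra() <= st.best) continue;
    int e = st.el1[u0];
    for (int v = 0; v < st.n2 && !st.timed_out; ++v) {
      if (st.el2[v] != e) continue;
      st.map1[u0] = v; st.used2[v] = 1; st.cur = 1;
      --st.avail1[e]; --st.avail2[e];
      st.search();
      st.map1[u0] = -1; st.used2[v] = 0; st.cur = 0;
      ++st.avail1[e]; ++st.avail2[e];
    }
  }
  return List::create(_["size"] = st.best, _["timed_out"] = st.timed_out);
}
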