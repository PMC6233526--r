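// Canonical signature strings for atom-rooted subgraphs of bounded height.
//
// A signature of height h rooted at atom r encodes the induced subgraph of
// all atoms within graph distance h of r.  The canonical form is the
// lexicographic minimum over all depth-first serializations of that
// subgraph, found by branch-and-bound over branch orderings.  Grammar:
//   atom label, then ring-closure marks (bond + '@' + visit index of the
//   earlier endpoint, sorted by visit index), then one parenthesised
//   '(' bond serial ')' group per tree branch.  Closure marks are emitted
//   at the endpoint visited second; visit indices are 1-based in DFS order.
#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct SubGraph {
  int m;
  int root;                         // local index
  std::vector<std::string> lab;
  std::vector<std::vector<int> > nbr;
  std::vector<char> bond;           // m*m flat, 0 where no edge
  char bnd(int i, int j) const { return bond[i * m + j]; }
};

struct State {
  std::vector<int> vis;             // visit index, 0 = unvisited
  int k;                            // next visit index
  std::vector<char> used;           // m*m flat edge-used flags
  std::string str;
  std::vector<int> stack;           // nodes with branches still open
};

// true if the partial string can no longer beat `best`
bool prune(const std::string& part, const std::string& best) {
  if (part.size() <= best.size()) {
    int c = best.compare(0, part.size(), part);
    return c < 0;                   // best's prefix already smaller
  }
  int c = part.compare(0, best.size(), best);
  return c >= 0;                    // longer than best with prefix >= best
}

void step(const SubGraph& G, State st, std::string& best, bool& has_best) {
  if (has_best && prune(st.str, best)) return;
  if (st.stack.empty()) {
    if (!has_best || st.str < best) { best = st.str; has_best = true; }
    return;
  }
  int u = st.stack.back();
  std::vector<int> S;
  for (int v : G.nbr[u]) if (st.vis[v] == 0) S.push_back(v);
  if (S.empty()) {
    st.stack.pop_back();
    if (!st.stack.empty()) st.str += ')';
    step(G, std::move(st), best, has_best);
    return;
  }
  for (int v : S) {
    State s2 = st;
    s2.vis[v] = s2.k++;
    s2.used[u * G.m + v] = s2.used[v * G.m + u] = 1;
    s2.str += '(';
    s2.str += G.bnd(u, v);
    s2.str += G.lab[v];
    // ring closures from v to already-visited atoms over unused edges
    std::vector<int> cl;
    for (int w : G.nbr[v])
      if (s2.vis[w] > 0 && !s2.used[v * G.m + w]) cl.push_back(w);
    std::sort(cl.begin(), cl.end(),
              [&](int a, int b) { return s2.vis[a] < s2.vis[b]; });
    for (int w : cl) {
      s2.used[v * G.m + w] = s2.used[w * G.m + v] = 1;
      s2.str += G.bnd(v, w);
      s2.str += '@';
      s2.str += std::to_string(s2.vis[w]);
    }
    s2.stack.push_back(v);
    step(G, std::move(s2), best, has_best);
  }
}

std::string canon_serialize(const SubGraph& G) {
  State st;
  st.vis.assign(G.m, 0);
  st.vis[G.root] = 1;
  st.k = 2;
  st.used.assign(G.m * G.m, 0);
  st.str = G.lab[G.root];
  st.stack.push_back(G.root);
  std::string best;
  bool has_best = false;
  step(G, std::move(st), best, has_best);
  return best;
}

// induced subgraph of atoms within `height` of `root` (0-based global ids)
SubGraph ball_subgraph(const std::vector<std::string>& lab,
                       const std::vector<std::vector<int> >& nbr,
                       const std::vector<std::vector<char> >& bnd,
                       int root, int height) {
  int n = (int)lab.size();
  std::vector<int> dist(n, -1);
  std::vector<int> order;
  dist[root] = 0;
  order.push_back(root);
  for (size_t qi = 0; qi < order.size(); ++qi) {
    int u = order[qi];
    if (dist[u] >= height) continue;
    for (int v : nbr[u]) if (dist[v] < 0) {
      dist[v] = dist[u] + 1;
      order.push_back(v);
    }
  }
  std::vector<int> loc(n, -1);
  for (size_t i = 0; i < order.size(); ++i) loc[order[i]] = (int)i;
  SubGraph G;
  G.m = (int)order.size();
  G.root = 0;
  G.lab.resize(G.m);
  G.nbr.resize(G.m);
  G.bond.assign(G.m * G.m, 0);
  for (int i = 0; i < G.m; ++i) {
    int u = order[i];
    G.lab[i] = lab[u];
    for (size_t j = 0; j < nbr[u].size(); ++j) {
      int v = nbr[u][j];
      if (loc[v] >= 0) {
        G.nbr[i].push_back(loc[v]);
        G.bond[i * G.m + loc[v]] = bnd[u][j];
      }
    }
  }
  return G;
}

void build_graph(const CharacterVector& labels, const IntegerMatrix& edges,
                 const CharacterVector& bonds,
                 std::vector<std::string>& lab,
                 std::vector<std::vector<int> >& nbr,
                 std::vector<std::vector<char> >& bnd) {
  int n = labels.size();
  lab.resize(n);
  nbr.assign(n, std::vector<int>());
  bnd.assign(n, std::vector<char>());
  for (int i = 0; i < n; ++i) lab[i] = as<std::string>(labels[i]);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    char c = as<std::string>(bonds[e])[0];
    nbr[a].push_back(b); bnd[a].push_back(c);
    nbr[b].push_back(a); bnd[b].push_back(c);
  }
}

} // namespace

// [[Rcpp::export]]
std::string cpp_atom_signature(CharacterVector labels, IntegerMatrix edges,
                               CharacterVector bonds, int root, int height) {
  std::vector<std::string> lab;
  std::vector<std::vector<int> > nbr;
  std::vector<std::vector<char> > bnd;
  build_graph(labels, edges, bonds, lab, nbr, bnd);
  SubGraph G = ball_subgraph(lab, nbr, bnd, root - 1, height);
  return canon_serialize(G);
}

// All (atom, height) signatures of one molecule, atom-major within height.
// Result index: h_i * n_atoms + atom (0-based).
// [[Rcpp::export]]
CharacterVector cpp_all_signatures(CharacterVector labels, IntegerMatrix edges,
                                   CharacterVector bonds,
                                   IntegerVector heights) {
  std::vector<std::string> lab;
  std::vector<std::vector<int> > nbr;
  std::vector<std::vector<char> > bnd;
  build_graph(labels, edges, bonds, lab, nbr, bnd);
  int n = labels.size(), nh = heights.size();
  CharacterVector out(n * nh);
  for (int hi = 0; hi < nh; ++hi) {
    for (int a = 0; a < n; ++a) {
      SubGraph G = ball_subgraph(lab, nbr, bnd, a, heights[hi]);
      out[hi * n + a] = canon_serialize(G);
    }
  }
  return out;
}
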