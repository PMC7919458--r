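// Brute-force BFS over genome space under single DCJ operations.
//
// A genome on n markers is a matching of the 2n marker extremities
// (tail of marker i = 2i-1, head = 2i, 1-based): matched pairs are
// adjacencies, unmatched extremities are telomeres. Circular topology
// requires a perfect matching. This is the independent oracle against the
// closed-form adjacency-graph distance; it never looks at cycle structure.

#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <vector>
#include <string>
using namespace Rcpp;

typedef std::vector<int8_t> State;   // partner[i], 0-based; -1 = telomere

static std::string key_of(const State& s) {
  return std::string(s.begin(), s.end());
}

static void push_state(State s, int d,
                       std::unordered_map<std::string, int>& dist,
                       std::queue<State>& q) {
  std::string k = key_of(s);
  if (dist.find(k) == dist.end()) {
    dist.emplace(std::move(k), d);
    q.push(std::move(s));
  }
}

// [[Rcpp::export]]
List cpp_dcj_bfs(IntegerVector start_partner, bool linear) {
  int m = start_partner.size();           // 2n extremities
  State start(m);
  for (int i = 0; i < m; ++i) start[i] = (int8_t)(start_partner[i] - 1); // to 0-based, -1 telomere

  std::unordered_map<std::string, int> dist;
  std::queue<State> q;
  push_state(start, 0, dist, q);

  while (!q.empty()) {
    State s = q.front(); q.pop();
    int d = dist[key_of(s)];

    std::vector<std::pair<int,int> > adj;   // a < b
    std::vector<int> tel;
    for (int i = 0; i < m; ++i) {
      if (s[i] == -1) tel.push_back(i);
      else if (s[i] > i) adj.push_back(std::make_pair(i, (int)s[i]));
    }

    // two adjacencies -> two rejoinings
    for (size_t x = 0; x < adj.size(); ++x)
      for (size_t y = x + 1; y < adj.size(); ++y) {
        int a = adj[x].first, b = adj[x].second, c = adj[y].first, e = adj[y].second;
        State t = s;
        t[a] = c; t[c] = a; t[b] = e; t[e] = b;       // {a,c},{b,e}
        push_state(t, d + 1, dist, q);
        t = s;
        t[a] = e; t[e] = a; t[b] = c; t[c] = b;       // {a,e},{b,c}
        push_state(t, d + 1, dist, q);
      }

    if (linear) {
      // adjacency + telomere
      for (size_t x = 0; x < adj.size(); ++x)
        for (size_t y = 0; y < tel.size(); ++y) {
          int a = adj[x].first, b = adj[x].second, c = tel[y];
          State t = s;
          t[a] = c; t[c] = a; t[b] = -1;               // {a,c}, b telomere
          push_state(t, d + 1, dist, q);
          t = s;
          t[b] = c; t[c] = b; t[a] = -1;               // {b,c}, a telomere
          push_state(t, d + 1, dist, q);
        }
      // two telomeres -> adjacency
      for (size_t x = 0; x < tel.size(); ++x)
        for (size_t y = x + 1; y < tel.size(); ++y) {
          State t = s;
          t[tel[x]] = (int8_t)tel[y]; t[tel[y]] = (int8_t)tel[x];
          push_state(t, d + 1, dist, q);
        }
      // split adjacency -> two telomeres
      for (size_t x = 0; x < adj.size(); ++x) {
        State t = s;
        t[adj[x].first] = -1; t[adj[x].second] = -1;
        push_state(t, d + 1, dist, q);
      }
    }
  }

  // export: one row per visited state
  int nstates = (int)dist.size();
  IntegerMatrix states(nstates, m);
  IntegerVector dd(nstates);
  int r = 0;
  for (auto& kv : dist) {
    for (int i = 0; i < m; ++i) states(r, i) = (int)(int8_t)kv.first[i] + 1; // back to 1-based, 0 = telomere
    dd[r] = kv.second;
    ++r;
  }
  return List::create(_["partner"] = states, _["distance"] = dd);
}
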