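#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Censored multispecies coalescent on a population graph.
//
// The species tree or network is pre-digested in R into "populations":
// time segments with a start (recent) and end (old) boundary, measured in
// coalescent units before the present. Lineages alive at a population's end
// boundary are routed to route1, or to route2 with probability prob2 (the
// reticulation inheritance probability gamma). The root population has
// end = +Inf and route1 = -1; coalescence there continues to a single
// lineage. Within a population carrying k lineages the next coalescence
// waits Exp(k(k-1)/2), the standard censored (truncated) coalescent.

struct Merger {
  int c1, c2;
  double t;
};

static void simulate_one(const NumericVector& pop_start,
                         const NumericVector& pop_end,
                         const IntegerVector& route1,
                         const IntegerVector& route2,
                         const NumericVector& prob2,
                         const std::vector<int>& order,
                         const IntegerVector& lineage_pop,
                         std::vector<Merger>& mergers,
                         std::vector<double>& node_time) {
  const int npop = pop_start.size();
  const int n = lineage_pop.size();
  std::vector<std::vector<int> > members(npop);
  mergers.clear();
  node_time.assign(n, 0.0);
  for (int i = 0; i < n; ++i) members[lineage_pop[i]].push_back(i);

  int next_id = n;
  for (size_t oi = 0; oi < order.size(); ++oi) {
    const int p = order[oi];
    std::vector<int>& mem = members[p];
    double t = pop_start[p];
    const double tend = pop_end[p];
    while (mem.size() >= 2) {
      const double k = static_cast<double>(mem.size());
      const double rate = k * (k - 1.0) / 2.0;
      t += R::exp_rand() / rate;
      if (t >= tend) break;
      // uniform random unordered pair
      int i = static_cast<int>(unif_rand() * k);
      if (i >= (int)mem.size()) i = mem.size() - 1;
      int j = static_cast<int>(unif_rand() * (k - 1.0));
      if (j >= (int)mem.size() - 1) j = mem.size() - 2;
      if (j >= i) ++j;
      Merger m;
      m.c1 = mem[i];
      m.c2 = mem[j];
      m.t = t;
      mergers.push_back(m);
      node_time.push_back(t);
      // replace i with new node, remove j
      mem[i] = next_id++;
      mem.erase(mem.begin() + j);
    }
    if (route1[p] < 0) break;  // root population: fully coalesced
    for (size_t li = 0; li < mem.size(); ++li) {
      int target = route1[p];
      if (route2[p] >= 0 && unif_rand() < prob2[p]) target = route2[p];
      members[target].push_back(mem[li]);
    }
    mem.clear();
  }
}

static std::string canon(int node, int n,
                         const std::vector<Merger>& mergers,
                         const std::vector<std::string>& labels) {
  if (node < n) return labels[node];
  const Merger& m = mergers[node - n];
  std::string a = canon(m.c1, n, mergers, labels);
  std::string b = canon(m.c2, n, mergers, labels);
  if (b < a) std::swap(a, b);
  return "(" + a + "," + b + ")";
}

// [[Rcpp::export]]
CharacterVector msc_sim_topologies(NumericVector pop_start,
                                   NumericVector pop_end,
                                   IntegerVector route1,
                                   IntegerVector route2,
                                   NumericVector prob2,
                                   IntegerVector proc_order,
                                   IntegerVector lineage_pop,
                                   CharacterVector lineage_label,
                                   int reps) {
  const int n = lineage_pop.size();
  std::vector<int> order(proc_order.begin(), proc_order.end());
  std::vector<std::string> labels(n);
  for (int i = 0; i < n; ++i) labels[i] = as<std::string>(lineage_label[i]);
  CharacterVector out(reps);
  std::vector<Merger> mergers;
  std::vector<double> node_time;
  for (int r = 0; r < reps; ++r) {
    simulate_one(pop_start, pop_end, route1, route2, prob2, order,
                 lineage_pop, mergers, node_time);
    out[r] = canon(n + (int)mergers.size() - 1, n, mergers, labels);
  }
  return out;
}

// [[Rcpp::export]]
List msc_sim_trees(NumericVector pop_start,
                   NumericVector pop_end,
                   IntegerVector route1,
                   IntegerVector route2,
                   NumericVector prob2,
                   IntegerVector proc_order,
                   IntegerVector lineage_pop,
                   CharacterVector lineage_label,
                   int reps) {
  const int n = lineage_pop.size();
  std::vector<int> order(proc_order.begin(), proc_order.end());
  List out(reps);
  std::vector<Merger> mergers;
  std::vector<double> node_time;
  for (int r = 0; r < reps; ++r) {
    simulate_one(pop_start, pop_end, route1, route2, prob2, order,
                 lineage_pop, mergers, node_time);
    const int nm = mergers.size();  // = n - 1
    IntegerMatrix edge(2 * nm, 2);
    NumericVector elen(2 * nm);
    // ape numbering: tips 1..n, root n+1; merger m (1-based, chronological)
    // becomes node 2n - m so the last (oldest) merger is the root.
    int row = 0;
    for (int m = 0; m < nm; ++m) {
      const int pid = 2 * n - (m + 1);
      const int kids[2] = {mergers[m].c1, mergers[m].c2};
      for (int s = 0; s < 2; ++s) {
        const int c = kids[s];
        const int cid = (c < n) ? (c + 1) : (2 * n - (c - n + 1));
        edge(row, 0) = pid;
        edge(row, 1) = cid;
        elen(row) = mergers[m].t - node_time[c];
        ++row;
      }
    }
    out[r] = List::create(_["edge"] = edge, _["edge.length"] = elen,
                          _["Nnode"] = nm);
  }
  return out;
}
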