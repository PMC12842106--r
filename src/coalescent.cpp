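#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Structured-coalescent gene-tree simulator.
//
// Populations: k tip populations (ids 0..k-1) holding the sampled gene
// copies; merge event e (times strictly sorted, ascending) pools the
// populations listed in event_members[e] into a new population with id k+e.
// Within any population holding j lineages, pairs coalesce at rate
// j(j-1)/(2 Ne) per generation (continuous-time Kingman approximation,
// Ne in haploid gene copies). After the last event a single population
// must remain; it coalesces to one lineage.
//
// All randomness comes from R's RNG, so set.seed() upstream governs
// reproducibility bit-for-bit.

namespace {

struct Sim {
  int n;                      // tips
  std::vector<int> parent;    // length 2n-1, root has -1
  std::vector<double> age;    // node ages in generations (tips at 0)
  std::vector<int> tip_deme;  // length n, 0-based deme of each tip
};

// Coalesce lineages in `lin` over [t0, t_end]; exponential waits are
// memoryless so epoch boundaries need no special handling.
void coalesce_pop(std::vector<int> &lin, double t0, double t_end, double ne,
                  std::vector<int> &parent, std::vector<double> &age,
                  int &next_node) {
  double t = t0;
  while ((int)lin.size() >= 2) {
    int j = (int)lin.size();
    double rate = j * (j - 1.0) / (2.0 * ne);
    t += R::rexp(1.0 / rate);
    if (t > t_end) break;
    int a = (int)std::floor(unif_rand() * j);
    if (a >= j) a = j - 1;
    int b = (int)std::floor(unif_rand() * (j - 1));
    if (b >= j - 1) b = j - 2;
    if (b >= a) b += 1;
    int p = next_node++;
    parent[lin[a]] = p;
    parent[lin[b]] = p;
    age[p] = t;
    lin[a] = p;
    lin[b] = lin.back();
    lin.pop_back();
  }
}

Sim simulate_one(const IntegerVector &sizes, double ne,
                 const NumericVector &etimes,
                 const std::vector<std::vector<int> > &emembers) {
  int k = sizes.size();
  int n = 0;
  for (int i = 0; i < k; ++i) n += sizes[i];
  Sim s;
  s.n = n;
  int ntot = 2 * n - 1;
  s.parent.assign(ntot, -1);
  s.age.assign(ntot, 0.0);
  s.tip_deme.resize(n);

  int npop = k + (int)etimes.size();
  std::vector<std::vector<int> > pops(npop);
  int id = 0;
  for (int d = 0; d < k; ++d)
    for (int c = 0; c < sizes[d]; ++c) {
      s.tip_deme[id] = d;
      pops[d].push_back(id);
      ++id;
    }

  int next_node = n;
  double t_cur = 0.0;
  for (int e = 0; e < (int)etimes.size(); ++e) {
    double t_end = etimes[e];
    for (int p = 0; p < k + e; ++p)
      if (pops[p].size() >= 2)
        coalesce_pop(pops[p], t_cur, t_end, ne, s.parent, s.age, next_node);
    std::vector<int> &np = pops[k + e];
    for (size_t m = 0; m < emembers[e].size(); ++m) {
      int src = emembers[e][m];
      np.insert(np.end(), pops[src].begin(), pops[src].end());
      pops[src].clear();
    }
    t_cur = t_end;
  }
  // final (root) population runs to fixation of a single lineage
  for (int p = 0; p < npop; ++p)
    if (pops[p].size() >= 2)
      coalesce_pop(pops[p], t_cur, R_PosInf, ne, s.parent, s.age, next_node);
  if (next_node != ntot)
    stop("population-tree events do not unify all lineages");
  return s;
}

// Minimum deme-state transitions on the (strictly binary) simulated tree.
// Fitch sets as bitmasks; exact for unit-cost parsimony on binary trees.
// Node indices follow creation order, so every parent index exceeds its
// children's and a single ascending pass is a valid postorder.
int fitch_s(const Sim &s) {
  int n = s.n;
  if (n <= 1) return 0;
  int ntot = 2 * n - 1;
  std::vector<int> c1(ntot, -1), c2(ntot, -1);
  std::vector<unsigned int> mask(ntot, 0u);
  for (int i = 0; i < ntot - 1; ++i) {
    int p = s.parent[i];
    if (c1[p] < 0) c1[p] = i; else c2[p] = i;
  }
  for (int i = 0; i < n; ++i) mask[i] = 1u << s.tip_deme[i];
  int steps = 0;
  for (int i = n; i < ntot; ++i) {
    unsigned int m = mask[c1[i]] & mask[c2[i]];
    if (m == 0u) {
      m = mask[c1[i]] | mask[c2[i]];
      ++steps;
    }
    mask[i] = m;
  }
  return steps;
}

std::vector<std::vector<int> > unpack_members(const List &emembers) {
  std::vector<std::vector<int> > out(emembers.size());
  for (int e = 0; e < emembers.size(); ++e) {
    IntegerVector v = emembers[e];
    out[e].assign(v.begin(), v.end());
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_sim_batch(IntegerVector sizes, double ne, NumericVector etimes,
                   List emembers, int reps, bool keep_tmrca) {
  std::vector<std::vector<int> > mem = unpack_members(emembers);
  IntegerVector sv(reps);
  NumericVector tm(keep_tmrca ? reps : 0);
  for (int r = 0; r < reps; ++r) {
    Sim s = simulate_one(sizes, ne, etimes, mem);
    sv[r] = fitch_s(s);
    if (keep_tmrca) tm[r] = s.n > 1 ? s.age[2 * s.n - 2] : 0.0;
  }
  if (keep_tmrca)
    return List::create(_["s"] = sv, _["tmrca"] = tm);
  return List::create(_["s"] = sv);
}

// [[Rcpp::export]]
List cpp_sim_tree(IntegerVector sizes, double ne, NumericVector etimes,
                  List emembers) {
  std::vector<std::vector<int> > mem = unpack_members(emembers);
  Sim s = simulate_one(sizes, ne, etimes, mem);
  return List::create(_["parent"] = IntegerVector(s.parent.begin(), s.parent.end()),
                      _["age"] = NumericVector(s.age.begin(), s.age.end()),
                      _["deme"] = IntegerVector(s.tip_deme.begin(), s.tip_deme.end()),
                      _["s"] = fitch_s(s));
}
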