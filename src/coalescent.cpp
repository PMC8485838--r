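#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Structured Hudson coalescent for a single non-recombining haploid locus
// (cpDNA), with demographic events applied backward in time, plus an HKY
// finite-sites mutation overlay. All randomness goes through R's RNG so a
// set.seed() call on the R side makes a simulation reproducible.
//
// events: matrix with columns (time, type, a, b, c, x), times in generations,
//   sorted ascending. type 1 = merge (all lineages in pop a move to pop b),
//   type 2 = resize (pop a size set to x), type 3 = admixture (each lineage
//   in pop a moves to pop b with probability x, otherwise to pop c).
// Population sizes are haploid copy numbers: a pair of lineages in a pop of
// size N coalesces at rate 1/N per generation, so E[TMRCA] = N for n = 2.

static inline bool is_transition(int a, int b) {
  // bases coded A=0, C=1, G=2, T=3; transitions are A<->G and C<->T
  return (a + b == 2 && a != b) || (a + b == 4 && a != b && a != 2 && b != 2);
}

static int mutate_base(int b, double kappa, const std::vector<double>& freq) {
  double w[4];
  double tot = 0.0;
  for (int a = 0; a < 4; ++a) {
    if (a == b) { w[a] = 0.0; continue; }
    w[a] = freq[a] * (is_transition(a, b) ? kappa : 1.0);
    tot += w[a];
  }
  double u = R::runif(0.0, tot);
  double c = 0.0;
  for (int a = 0; a < 4; ++a) {
    c += w[a];
    if (u <= c && w[a] > 0.0) return a;
  }
  return b == 0 ? 3 : 0; // unreachable guard
}

static int sample_base(const std::vector<double>& freq) {
  double u = R::runif(0.0, 1.0);
  double c = 0.0;
  for (int a = 0; a < 4; ++a) {
    c += freq[a];
    if (u <= c) return a;
  }
  return 3;
}

struct Mut {
  int site;
  int node;   // mutation lies on the branch above `node`
  double t;   // time of the event (backward); larger = older
};

// [[Rcpp::export]]
List sim_scenario_cpp(IntegerVector sampleSizes, NumericVector popSizes,
                      NumericMatrix events, int L, double mu, double kappa,
                      NumericVector baseFreq) {
  int ngroup = sampleSizes.size();
  int npop = popSizes.size();
  if (ngroup > npop) stop("more sampled groups than populations");
  int n = 0;
  for (int g = 0; g < ngroup; ++g) n += sampleSizes[g];
  if (n < 2) stop("need at least 2 samples in total");
  int nnode = 2 * n - 1;

  std::vector<double> N(popSizes.begin(), popSizes.end());
  std::vector<std::vector<int> > active(npop);
  std::vector<double> ntime(nnode, 0.0);
  std::vector<int> parent(nnode, -1);

  int tip = 0;
  for (int g = 0; g < ngroup; ++g)
    for (int i = 0; i < sampleSizes[g]; ++i) active[g].push_back(tip++);

  int nev = events.nrow();
  int ev = 0;
  int nextNode = n;
  int nActive = n;
  double t = 0.0;

  while (nActive > 1) {
    double rate = 0.0;
    for (int p = 0; p < npop; ++p) {
      double k = (double)active[p].size();
      if (k >= 2.0) rate += k * (k - 1.0) / (2.0 * N[p]);
    }
    double tnext = R_PosInf;
    if (rate > 0.0) tnext = t + R::rexp(1.0 / rate);
    if (ev < nev && events(ev, 0) <= tnext) {
      t = events(ev, 0);
      int type = (int)events(ev, 1);
      int a = (int)events(ev, 2);
      int b = (int)events(ev, 3);
      if (type == 1) {                       // merge a -> b
        for (size_t i = 0; i < active[a].size(); ++i)
          active[b].push_back(active[a][i]);
        active[a].clear();
      } else if (type == 2) {                // resize a
        N[a] = events(ev, 5);
      } else if (type == 3) {                // admixture a -> b (x) / c (1-x)
        int cpop = (int)events(ev, 4);
        double r = events(ev, 5);
        for (size_t i = 0; i < active[a].size(); ++i) {
          if (R::runif(0.0, 1.0) < r) active[b].push_back(active[a][i]);
          else active[cpop].push_back(active[a][i]);
        }
        active[a].clear();
      } else stop("unknown event type");
      ++ev;
      continue;
    }
    if (rate <= 0.0) stop("lineages cannot coalesce: no further events and populations isolated");
    t = tnext;
    // choose population proportional to its coalescent rate
    double u = R::runif(0.0, rate), c = 0.0;
    int p = -1;
    for (int q = 0; q < npop; ++q) {
      double k = (double)active[q].size();
      if (k < 2.0) continue;
      c += k * (k - 1.0) / (2.0 * N[q]);
      if (u <= c) { p = q; break; }
    }
    if (p < 0) continue;
    int k = active[p].size();
    int i = (int)std::floor(R::runif(0.0, (double)k));
    int j = (int)std::floor(R::runif(0.0, (double)(k - 1)));
    if (i >= k) i = k - 1;
    if (j >= i) ++j;
    int ni = active[p][i], nj = active[p][j];
    int newNode = nextNode++;
    ntime[newNode] = t;
    parent[ni] = newNode;
    parent[nj] = newNode;
    if (i > j) std::swap(i, j);
    active[p].erase(active[p].begin() + j);
    active[p].erase(active[p].begin() + i);
    active[p].push_back(newNode);
    --nActive;
  }

  // mutation overlay: Poisson number of events per branch, uniform sites
  std::vector<Mut> muts;
  for (int v = 0; v < nnode - 1; ++v) {
    double len = ntime[parent[v]] - ntime[v];
    if (len <= 0.0) continue;
    int m = (int)R::rpois(len * mu * (double)L);
    for (int q = 0; q < m; ++q) {
      Mut mm;
      mm.site = (int)std::floor(R::runif(0.0, (double)L));
      if (mm.site >= L) mm.site = L - 1;
      mm.node = v;
      mm.t = ntime[v] + R::runif(0.0, len);
      muts.push_back(mm);
    }
  }

  std::map<int, std::vector<Mut> > bySite;
  for (size_t q = 0; q < muts.size(); ++q) bySite[muts[q].site].push_back(muts[q]);

  int S = (int)bySite.size();
  IntegerMatrix mat(n, S);
  IntegerVector pos(S);
  std::vector<double> freq(baseFreq.begin(), baseFreq.end());

  // children lists for root-to-tip traversal
  std::vector<std::vector<int> > child(nnode);
  int root = nnode - 1;
  for (int v = 0; v < nnode - 1; ++v) child[parent[v]].push_back(v);

  int sidx = 0;
  std::vector<int> state(nnode);
  for (std::map<int, std::vector<Mut> >::iterator it = bySite.begin();
       it != bySite.end(); ++it, ++sidx) {
    pos[sidx] = it->first + 1; // 1-based
    std::vector<Mut>& sm = it->second;
    state.assign(nnode, -1);
    state[root] = sample_base(freq);
    std::vector<int> stack;
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (v != root) {
        int s = state[parent[v]];
        // apply this branch's mutations oldest-first (descending backward time)
        std::vector<const Mut*> bm;
        for (size_t q = 0; q < sm.size(); ++q)
          if (sm[q].node == v) bm.push_back(&sm[q]);
        std::sort(bm.begin(), bm.end(),
                  [](const Mut* x, const Mut* y) { return x->t > y->t; });
        for (size_t q = 0; q < bm.size(); ++q) s = mutate_base(s, kappa, freq);
        state[v] = s;
      }
      for (size_t q = 0; q < child[v].size(); ++q) stack.push_back(child[v][q]);
    }
    for (int i = 0; i < n; ++i) mat(i, sidx) = state[i];
  }

  return List::create(_["pos"] = pos, _["mat"] = mat,
                      _["tmrca"] = ntime[root]);
}

// Neutral constant-size coalescent for one population, conditioned on a fixed
// number S of segregating sites (infinite-sites: mutations placed on branches
// with probability proportional to branch length, one site each). Returns an
// n x S 0/1 matrix (1 = derived allele).
// [[Rcpp::export]]
IntegerMatrix sim_fixed_s_cpp(int n, int S) {
  if (n < 2) stop("n must be >= 2");
  int nnode = 2 * n - 1;
  std::vector<double> ntime(nnode, 0.0);
  std::vector<int> parent(nnode, -1);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int nextNode = n;
  for (int k = n; k >= 2; --k) {
    double rate = (double)k * (k - 1.0) / 2.0;
    t += R::rexp(1.0 / rate);
    int i = (int)std::floor(R::runif(0.0, (double)k));
    int j = (int)std::floor(R::runif(0.0, (double)(k - 1)));
    if (i >= k) i = k - 1;
    if (j >= i) ++j;
    int newNode = nextNode++;
    ntime[newNode] = t;
    parent[active[i]] = newNode;
    parent[active[j]] = newNode;
    if (i > j) std::swap(i, j);
    active.erase(active.begin() + j);
    active.erase(active.begin() + i);
    active.push_back(newNode);
  }
  std::vector<double> blen(nnode - 1);
  double tot = 0.0;
  for (int v = 0; v < nnode - 1; ++v) {
    blen[v] = ntime[parent[v]] - ntime[v];
    tot += blen[v];
  }
  // tip sets below each node
  std::vector<std::vector<int> > child(nnode);
  for (int v = 0; v < nnode - 1; ++v) child[parent[v]].push_back(v);
  IntegerMatrix mat(n, S);
  for (int s = 0; s < S; ++s) {
    double u = R::runif(0.0, tot), c = 0.0;
    int v = nnode - 2;
    for (int q = 0; q < nnode - 1; ++q) {
      c += blen[q];
      if (u <= c) { v = q; break; }
    }
    std::vector<int> stack;
    stack.push_back(v);
    while (!stack.empty()) {
      int w = stack.back();
      stack.pop_back();
      if (w < n) mat(w, s) = 1;
      for (size_t q = 0; q < child[w].size(); ++q) stack.push_back(child[w][q]);
    }
  }
  return mat;
}
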