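// Hot path for ABC reference-table generation: structured haploid coalescent
// with discrete demographic events, HKY+gamma mutation by exact thinning, and
// the single-locus summary-statistic panel. All functions take an explicit
// integer seed so results are independent of R's RNG state and of row order.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

typedef std::mt19937_64 rng_t;

inline double rexp1(rng_t &rng) {
  std::exponential_distribution<double> d(1.0);
  return d(rng);
}
inline double runif1(rng_t &rng) {
  std::uniform_real_distribution<double> d(0.0, 1.0);
  return d(rng);
}
inline int rint(rng_t &rng, int n) { // uniform on 0..n-1
  std::uniform_int_distribution<int> d(0, n - 1);
  return d(rng);
}

} // namespace

// Structured coalescent under a backward-time demographic program.
// events: columns (time, kind, child, parentA, parentB, value) with kind
// 0 = merge (child lineages move to parentA), 1 = admixture (each child
// lineage moves to parentA with prob value, else parentB), 2 = size change
// (population child takes haploid size value from that time backward).
// Populations are 0-based. Returns parent pointers (-1 at root), node times
// and the per-leaf population.
// [[Rcpp::export]]
List cpp_simulate_genealogy(int n_pops, NumericVector pop_sizes,
                            NumericMatrix events, IntegerVector sample_sizes,
                            double seed) {
  rng_t rng((uint64_t)seed);
  int n = 0;
  for (int p = 0; p < n_pops; ++p) n += sample_sizes[p];
  if (n < 1) stop("at least one sampled lineage is required");

  std::vector<double> N(pop_sizes.begin(), pop_sizes.end());
  std::vector<bool> closed(n_pops, false);
  std::vector<std::vector<int>> act(n_pops); // active lineage node ids per pop

  int n_nodes = 2 * n - 1;
  std::vector<int> parent(n_nodes, -1);
  std::vector<double> time(n_nodes, 0.0);
  IntegerVector leaf_pop(n);

  int id = 0;
  for (int p = 0; p < n_pops; ++p)
    for (int k = 0; k < sample_sizes[p]; ++k) {
      act[p].push_back(id);
      leaf_pop[id] = p;
      ++id;
    }
  int next_node = n;

  // event order: ascending time, stable in input order
  int n_ev = events.nrow();
  std::vector<int> ord(n_ev);
  for (int i = 0; i < n_ev; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return events(a, 0) < events(b, 0);
  });

  double t = 0.0;
  int ev = 0;
  int alive = n;
  while (alive > 1) {
    // next coalescence candidate: minimum of per-population exponentials
    double wmin = R_PosInf;
    int pmin = -1;
    for (int p = 0; p < n_pops; ++p) {
      int k = (int)act[p].size();
      if (k < 2) continue;
      double rate = (double)k * (k - 1) / (2.0 * N[p]);
      double w = rexp1(rng) / rate;
      if (w < wmin) { wmin = w; pmin = p; }
    }
    double t_next_ev = (ev < n_ev) ? events(ord[ev], 0) : R_PosInf;

    if (t + wmin < t_next_ev) {
      // coalescence in population pmin
      t += wmin;
      std::vector<int> &L = act[pmin];
      int i = rint(rng, (int)L.size());
      int a = L[i]; L[i] = L.back(); L.pop_back();
      int j = rint(rng, (int)L.size());
      int b = L[j]; L[j] = L.back(); L.pop_back();
      parent[a] = next_node;
      parent[b] = next_node;
      time[next_node] = t;
      L.push_back(next_node);
      ++next_node;
      --alive;
    } else if (R_finite(t_next_ev)) {
      // apply demographic event
      t = t_next_ev;
      int e = ord[ev++];
      int kind = (int)events(e, 1);
      int child = (int)events(e, 2);
      int pa = (int)events(e, 3);
      int pb = (int)events(e, 4);
      double val = events(e, 5);
      if (kind == 2) {
        N[child] = val;
        continue;
      }
      if (closed[child]) stop("event child population already merged away");
      if (kind == 0) {
        if (closed[pa]) stop("merge parent population already merged away");
        for (int x : act[child]) act[pa].push_back(x);
        act[child].clear();
        closed[child] = true;
      } else if (kind == 1) {
        if (closed[pa] || closed[pb])
          stop("admixture parent population already merged away");
        for (int x : act[child]) {
          if (runif1(rng) < val) act[pa].push_back(x);
          else act[pb].push_back(x);
        }
        act[child].clear();
        closed[child] = true;
      } else stop("unknown event kind");
    } else {
      stop("lineages stranded in disconnected populations (no common root)");
    }
  }

  return List::create(_["parent"] = IntegerVector(parent.begin(), parent.end()),
                      _["time"] = NumericVector(time.begin(), time.end()),
                      _["leaf_pop"] = leaf_pop,
                      _["n_leaves"] = n);
}

// HKY mutation along a genealogy with per-site relative rates. The rate
// matrix q[i][j] = freq[j] * (kappa on A<->G / C<->T), normalised so the mean
// substitution rate at stationarity is 1; mu scales it per site per
// generation. Exact continuous-time simulation by thinning at the dominating
// exit rate. Base codes 0=A, 1=C, 2=G, 3=T.
// [[Rcpp::export]]
IntegerMatrix cpp_mutate(IntegerVector parent, NumericVector time, int n_leaves,
                         NumericVector site_rates, double mu, double kappa,
                         NumericVector base_freq, double seed) {
  rng_t rng((uint64_t)seed);
  int n_nodes = parent.size();
  int L = site_rates.size();

  double q[4][4], d[4];
  bool ts[4][4] = {{false, false, true, false},
                   {false, false, false, true},
                   {true, false, false, false},
                   {false, true, false, false}};
  double scale = 0.0;
  for (int i = 0; i < 4; ++i) {
    d[i] = 0.0;
    for (int j = 0; j < 4; ++j) {
      if (i == j) { q[i][j] = 0.0; continue; }
      q[i][j] = base_freq[j] * (ts[i][j] ? kappa : 1.0);
      d[i] += q[i][j];
    }
    scale += base_freq[i] * d[i];
  }
  double dmax = 0.0;
  for (int i = 0; i < 4; ++i) {
    d[i] /= scale;
    for (int j = 0; j < 4; ++j) q[i][j] /= scale;
    dmax = std::max(dmax, d[i]);
  }

  // cumulative site weights for event placement
  double R = 0.0;
  std::vector<double> cum(L);
  for (int s = 0; s < L; ++s) { R += site_rates[s]; cum[s] = R; }

  // children lists; root = node with parent -1
  std::vector<std::vector<int>> ch(n_nodes);
  int root = -1;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] < 0) root = v;
    else ch[parent[v]].push_back(v);
  }
  if (root < 0) stop("genealogy has no root");

  std::vector<std::vector<int>> seq(n_nodes);
  seq[root].resize(L);
  std::discrete_distribution<int> rbase(base_freq.begin(), base_freq.end());
  for (int s = 0; s < L; ++s) seq[root][s] = rbase(rng);

  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (int c : ch[v]) {
      seq[c] = seq[v];
      double dt = time[v] - time[c];
      if (dt < 0) stop("parent older than child violated");
      if (mu > 0 && R > 0 && dt > 0) {
        double lambda = mu * dt * R * dmax;
        std::poisson_distribution<long> rpois(lambda);
        long K = rpois(rng);
        for (long e = 0; e < K; ++e) {
          // pick site with prob site_rates[s]/R
          double u = runif1(rng) * R;
          int s = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
          if (s >= L) s = L - 1;
          int b = seq[c][s];
          if (runif1(rng) < d[b] / dmax) { // accept as a real event
            double u2 = runif1(rng) * d[b];
            double acc = 0.0;
            for (int j = 0; j < 4; ++j) {
              if (j == b) continue;
              acc += q[b][j];
              if (u2 <= acc) { seq[c][s] = j; break; }
            }
          }
        }
      }
      stack.push_back(c);
    }
    if (v >= n_leaves) { seq[v].clear(); seq[v].shrink_to_fit(); }
  }

  IntegerMatrix out(n_leaves, L);
  for (int i = 0; i < n_leaves; ++i)
    for (int s = 0; s < L; ++s) out(i, s) = seq[i][s];
  return out;
}

// Single-locus summary-statistic panel on a clean (no ambiguity) coded
// alignment. Per population: distinct haplotypes, segregating sites, mean and
// variance of pairwise differences, private segregating sites. Per requested
// pair: mean between-population differences, pooled haplotype count, Hudson
// FST (NA when between-population diversity is zero). Sequences are collapsed
// to unique haplotypes first so cost scales with haplotype count, not sample
// size.
// [[Rcpp::export]]
NumericVector cpp_summary_stats(IntegerMatrix seqs, IntegerVector pop,
                                int n_pops, IntegerMatrix pairs) {
  int n = seqs.nrow(), L = seqs.ncol();

  // collapse to unique haplotypes
  std::vector<int> hap_of(n, -1);
  std::vector<int> reps; // row index of each unique haplotype
  for (int i = 0; i < n; ++i) {
    for (size_t h = 0; h < reps.size(); ++h) {
      int r = reps[h];
      bool same = true;
      for (int s = 0; s < L; ++s)
        if (seqs(i, s) != seqs(r, s)) { same = false; break; }
      if (same) { hap_of[i] = (int)h; break; }
    }
    if (hap_of[i] < 0) { reps.push_back(i); hap_of[i] = (int)reps.size() - 1; }
  }
  int H = (int)reps.size();

  // haplotype counts per population
  std::vector<std::vector<double>> cnt(n_pops, std::vector<double>(H, 0.0));
  std::vector<double> nsz(n_pops, 0.0);
  for (int i = 0; i < n; ++i) {
    cnt[pop[i]][hap_of[i]] += 1.0;
    nsz[pop[i]] += 1.0;
  }

  // pairwise differences among unique haplotypes
  std::vector<std::vector<int>> dd(H, std::vector<int>(H, 0));
  for (int a = 0; a < H; ++a)
    for (int b = a + 1; b < H; ++b) {
      int diff = 0;
      for (int s = 0; s < L; ++s)
        if (seqs(reps[a], s) != seqs(reps[b], s)) ++diff;
      dd[a][b] = dd[b][a] = diff;
    }

  // per-site base masks per population (bit i set <=> base i present)
  std::vector<std::vector<unsigned char>> mask(
      n_pops, std::vector<unsigned char>(L, 0));
  for (int p = 0; p < n_pops; ++p)
    for (int h = 0; h < H; ++h) {
      if (cnt[p][h] <= 0) continue;
      int r = reps[h];
      for (int s = 0; s < L; ++s) mask[p][s] |= (unsigned char)(1 << seqs(r, s));
    }
  auto popcount = [](unsigned char m) {
    int c = 0; while (m) { c += m & 1; m >>= 1; } return c;
  };

  int n_pairs = pairs.nrow();
  NumericVector out(5 * n_pops + 3 * n_pairs);
  int k = 0;
  std::vector<double> pi_within(n_pops, NA_REAL);
  // with-replacement within-population mean differences (denominator n^2,
  // same convention as the cross-population mean, so FST of two identically
  // composed samples is exactly 0)
  std::vector<double> pi_wr(n_pops, NA_REAL);

  for (int p = 0; p < n_pops; ++p) {
    double np = nsz[p];
    int Hp = 0;
    for (int h = 0; h < H; ++h) if (cnt[p][h] > 0) ++Hp;
    int S = 0, Spriv = 0;
    for (int s = 0; s < L; ++s) {
      if (popcount(mask[p][s]) > 1) {
        ++S;
        unsigned char rest = 0;
        for (int q2 = 0; q2 < n_pops; ++q2)
          if (q2 != p) rest |= mask[q2][s];
        if (n_pops == 1 || popcount(rest) <= 1) ++Spriv;
      }
    }
    double pim = NA_REAL, piv = NA_REAL;
    if (np >= 2) {
      double pairs_n = np * (np - 1) / 2.0, sum = 0.0, sum2 = 0.0;
      for (int a = 0; a < H; ++a) {
        for (int b = a + 1; b < H; ++b) {
          double w = cnt[p][a] * cnt[p][b];
          sum += w * dd[a][b];
          sum2 += w * (double)dd[a][b] * dd[a][b];
        }
      }
      pim = sum / pairs_n;
      piv = sum2 / pairs_n - pim * pim;
      if (piv < 0) piv = 0;
      pi_wr[p] = 2.0 * sum / (np * np);
    } else {
      S = 0; Spriv = 0;
    }
    pi_within[p] = pim;
    out[k++] = Hp;
    out[k++] = S;
    out[k++] = pim;
    out[k++] = piv;
    out[k++] = Spriv;
  }

  for (int e = 0; e < n_pairs; ++e) {
    int A = pairs(e, 0), B = pairs(e, 1);
    double nA = nsz[A], nB = nsz[B];
    double cross = nA * nB, sum = 0.0;
    int Hpool = 0;
    for (int a = 0; a < H; ++a) {
      if (cnt[A][a] > 0 || cnt[B][a] > 0) ++Hpool;
      for (int b = 0; b < H; ++b) {
        double w = cnt[A][a] * cnt[B][b];
        if (w > 0) sum += w * dd[a][b];
      }
    }
    double dxy = (cross > 0) ? sum / cross : NA_REAL;
    double fst = NA_REAL;
    if (R_finite(dxy) && dxy > 0) {
      double wA = pi_wr[A], wB = pi_wr[B];
      double within;
      if (R_finite(wA) && R_finite(wB)) within = 0.5 * (wA + wB);
      else if (R_finite(wA)) within = wA;
      else if (R_finite(wB)) within = wB;
      else within = NA_REAL;
      if (R_finite(within)) fst = 1.0 - within / dxy;
    }
    out[k++] = dxy;
    out[k++] = Hpool;
    out[k++] = fst;
  }
  return out;
}
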