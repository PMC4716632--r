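// Collapsed direct-assignment Gibbs sampler for the hierarchical Dirichlet
// process over bags of edge tokens. Topics (CMNs) share a global stick-
// breaking measure G0 with concentration gamma; each document mixes active
// topics with concentration alpha; topic-edge distributions have a
// symmetric Dirichlet(eta) base measure over the V-edge vocabulary.
//
// All randomness goes through R's RNG so results are reproducible from
// set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct HdpState {
  int V, J, K;
  double eta, gamma_, alpha;
  std::vector<std::vector<int> > w;     // token ids per doc (0-based)
  std::vector<std::vector<int> > z;     // topic per token occurrence
  std::vector<std::vector<int> > n_ke;  // [K][V]
  std::vector<long> n_k;                // [K]
  std::vector<std::vector<int> > n_jk;  // [J][K]
  std::vector<double> g;                // stick weights of active topics
  double g_u;                           // unallocated mass
};

void grow_topic(HdpState &s) {
  s.n_ke.push_back(std::vector<int>(s.V, 0));
  s.n_k.push_back(0);
  for (int j = 0; j < s.J; ++j) s.n_jk[j].push_back(0);
  double b = R::rbeta(1.0, s.gamma_);
  s.g.push_back(b * s.g_u);
  s.g_u *= (1.0 - b);
  ++s.K;
}

// drop empty topics, remapping indices everywhere; their stick mass
// returns to the unallocated remainder
void compact(HdpState &s) {
  std::vector<int> remap(s.K, -1);
  int knew = 0;
  for (int k = 0; k < s.K; ++k) {
    if (s.n_k[k] > 0) remap[k] = knew++;
    else s.g_u += s.g[k];
  }
  if (knew == s.K) return;
  for (int k = 0; k < s.K; ++k) {
    int r = remap[k];
    if (r >= 0 && r != k) {
      s.n_ke[r].swap(s.n_ke[k]);
      s.n_k[r] = s.n_k[k];
      s.g[r] = s.g[k];
    }
  }
  s.n_ke.resize(knew);
  s.n_k.resize(knew);
  s.g.resize(knew);
  for (int j = 0; j < s.J; ++j) {
    std::vector<int> &row = s.n_jk[j];
    for (int k = 0; k < s.K; ++k) {
      int r = remap[k];
      if (r >= 0) row[r] = row[k];
    }
    row.resize(knew);
    for (size_t n = 0; n < s.z[j].size(); ++n) s.z[j][n] = remap[s.z[j][n]];
  }
  s.K = knew;
}

// resample G0 stick weights from their Dirichlet posterior given table
// counts drawn by the standard Chinese-restaurant auxiliary scheme
void resample_sticks(HdpState &s) {
  compact(s);
  std::vector<double> m(s.K, 0.0);
  for (int j = 0; j < s.J; ++j) {
    for (int k = 0; k < s.K; ++k) {
      int njk = s.n_jk[j][k];
      if (njk == 0) continue;
      double ag = s.alpha * s.g[k];
      int tables = 0;
      for (int i = 0; i < njk; ++i) {
        if (R::unif_rand() * (ag + i) < ag) ++tables;
      }
      m[k] += tables;
    }
  }
  double total = 0.0;
  std::vector<double> draw(s.K + 1);
  for (int k = 0; k < s.K; ++k) {
    draw[k] = R::rgamma(m[k], 1.0);
    total += draw[k];
  }
  draw[s.K] = R::rgamma(s.gamma_, 1.0);
  total += draw[s.K];
  if (total <= 0.0) {  // degenerate draw; fall back to uniform
    for (int k = 0; k <= s.K; ++k) draw[k] = 1.0;
    total = s.K + 1.0;
  }
  for (int k = 0; k < s.K; ++k) s.g[k] = draw[k] / total;
  s.g_u = draw[s.K] / total;
}

void sample_doc(HdpState &s, int j, std::vector<double> &p) {
  const std::vector<int> &doc = s.w[j];
  std::vector<int> &zj = s.z[j];
  for (size_t n = 0; n < doc.size(); ++n) {
    int e = doc[n];
    int old = zj[n];
    --s.n_ke[old][e];
    --s.n_k[old];
    --s.n_jk[j][old];
    if (p.size() < (size_t)(s.K + 1)) p.resize(s.K + 1);
    double tot = 0.0;
    for (int k = 0; k < s.K; ++k) {
      tot += (s.n_jk[j][k] + s.alpha * s.g[k]) *
             (s.n_ke[k][e] + s.eta) / (s.n_k[k] + s.V * s.eta);
      p[k] = tot;
    }
    tot += s.alpha * s.g_u / s.V;
    p[s.K] = tot;
    double u = R::unif_rand() * tot;
    int knew = 0;
    while (knew < s.K && p[knew] < u) ++knew;
    if (knew == s.K) grow_topic(s);
    ++s.n_ke[knew][e];
    ++s.n_k[knew];
    ++s.n_jk[j][knew];
    zj[n] = knew;
  }
}

}  // namespace

// [[Rcpp::export]]
List hdp_gibbs_cpp(List docs, int V, double eta, double gamma_, double alpha,
                   int burnin_sweeps, int sweeps, int resample_every) {
  HdpState s;
  s.V = V;
  s.J = docs.size();
  s.eta = eta;
  s.gamma_ = gamma_;
  s.alpha = alpha;
  s.w.resize(s.J);
  s.z.resize(s.J);
  s.n_jk.resize(s.J);
  // initialize: every token in one CMN; stick mass split evenly with the
  // unallocated remainder (resampled immediately during burn-in)
  s.K = 1;
  s.n_ke.assign(1, std::vector<int>(V, 0));
  s.n_k.assign(1, 0);
  s.g.assign(1, 0.5);
  s.g_u = 0.5;
  for (int j = 0; j < s.J; ++j) {
    IntegerVector d = docs[j];
    s.w[j].assign(d.begin(), d.end());
    s.z[j].assign(d.size(), 0);
    s.n_jk[j].assign(1, (int)d.size());
    s.n_k[0] += d.size();
    for (int n = 0; n < d.size(); ++n) ++s.n_ke[0][d[n]];
  }

  std::vector<double> p;
  IntegerVector k_trace(burnin_sweeps + sweeps);
  int sweep_i = 0;
  for (int b = 0; b < burnin_sweeps; ++b) {
    for (int j = 0; j < s.J; ++j) {
      sample_doc(s, j, p);
      if ((j + 1) % resample_every == 0) resample_sticks(s);
    }
    resample_sticks(s);
    k_trace[sweep_i++] = s.K;
  }
  for (int it = 0; it < sweeps; ++it) {
    for (int j = 0; j < s.J; ++j) sample_doc(s, j, p);
    resample_sticks(s);
    k_trace[sweep_i++] = s.K;
    if ((it + 1) % 100 == 0) Rcpp::checkUserInterrupt();
  }
  compact(s);

  IntegerMatrix n_ke(s.K, V);
  for (int k = 0; k < s.K; ++k)
    for (int e = 0; e < V; ++e) n_ke(k, e) = s.n_ke[k][e];
  IntegerMatrix n_jk(s.J, s.K);
  for (int j = 0; j < s.J; ++j)
    for (int k = 0; k < s.K; ++k) n_jk(j, k) = s.n_jk[j][k];
  List z(s.J);
  for (int j = 0; j < s.J; ++j) {
    IntegerVector zj(s.z[j].size());
    for (size_t n = 0; n < s.z[j].size(); ++n) zj[n] = s.z[j][n] + 1;
    z[j] = zj;
  }
  NumericVector g(s.K);
  for (int k = 0; k < s.K; ++k) g[k] = s.g[k];
  NumericVector n_k(s.K);
  for (int k = 0; k < s.K; ++k) n_k[k] = (double)s.n_k[k];

  return List::create(_["K"] = s.K, _["z"] = z, _["n_ke"] = n_ke,
                      _["n_k"] = n_k, _["n_jk"] = n_jk, _["g"] = g,
                      _["g_u"] = s.g_u, _["k_trace"] = k_trace);
}
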