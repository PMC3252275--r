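#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Adjacency is held as in-link lists: for each target node i, the source
// nodes in_src[i] and signs in_sgn[i] of its incoming links. The field of
// node i is h_i = sum_j c_ij sigma_j over its in-links; the synchronous
// update is sigma_i <- sign(h_i) with the fixed convention sign(0) = -1.

typedef std::vector<std::vector<int> > adj_t;

static inline void step_once(const adj_t &src, const adj_t &sgn,
                             std::vector<int> &sigma,
                             std::vector<int> &buf) {
  const int n = (int)sigma.size();
  for (int i = 0; i < n; ++i) {
    long h = 0;
    const std::vector<int> &s = src[i];
    const std::vector<int> &g = sgn[i];
    for (size_t k = 0; k < s.size(); ++k) h += g[k] * sigma[s[k]];
    buf[i] = (h > 0) ? 1 : -1;
  }
  sigma.swap(buf);
}

static void build_adj(const IntegerVector &tgt, const IntegerVector &lsrc,
                      const IntegerVector &lsgn, int n,
                      adj_t &src, adj_t &sgn) {
  src.assign(n, std::vector<int>());
  sgn.assign(n, std::vector<int>());
  for (int k = 0; k < tgt.size(); ++k) {
    src[tgt[k] - 1].push_back(lsrc[k] - 1);
    sgn[tgt[k] - 1].push_back(lsgn[k]);
  }
}

static void flatten_adj(const adj_t &src, const adj_t &sgn,
                        IntegerVector &tgt_out, IntegerVector &src_out,
                        IntegerVector &sgn_out) {
  long m = 0;
  for (size_t i = 0; i < src.size(); ++i) m += src[i].size();
  tgt_out = IntegerVector(m);
  src_out = IntegerVector(m);
  sgn_out = IntegerVector(m);
  long k = 0;
  for (size_t i = 0; i < src.size(); ++i) {
    for (size_t j = 0; j < src[i].size(); ++j, ++k) {
      tgt_out[k] = (int)i + 1;
      src_out[k] = src[i][j] + 1;
      sgn_out[k] = sgn[i][j];
    }
  }
}

static inline bool has_link(const adj_t &src, int tgt0, int from0) {
  const std::vector<int> &s = src[tgt0];
  for (size_t k = 0; k < s.size(); ++k) if (s[k] == from0) return true;
  return false;
}

// One epoch of T synchronous updates. Returns the final states, a per-node
// flag saying whether the state changed at least once, and (optionally) the
// recorded states of `monitor` (1-based) at every step.
// [[Rcpp::export]]
List cpp_epoch(int n, IntegerVector tgt, IntegerVector src, IntegerVector sgn,
               IntegerVector sigma0, int t_epoch,
               IntegerVector monitor) {
  adj_t asrc, asgn;
  build_adj(tgt, src, sgn, n, asrc, asgn);
  std::vector<int> sigma(sigma0.begin(), sigma0.end());
  std::vector<int> buf(n);
  std::vector<char> changed(n, 0);
  const int nm = monitor.size();
  IntegerMatrix rec(nm > 0 ? t_epoch : 0, nm);
  for (int t = 0; t < t_epoch; ++t) {
    std::vector<int> prev(sigma);
    step_once(asrc, asgn, sigma, buf);
    for (int i = 0; i < n; ++i) if (sigma[i] != prev[i]) changed[i] = 1;
    for (int j = 0; j < nm; ++j) rec(t, j) = sigma[monitor[j] - 1];
  }
  IntegerVector sig_out(sigma.begin(), sigma.end());
  LogicalVector ch(n);
  for (int i = 0; i < n; ++i) ch[i] = changed[i] != 0;
  return List::create(_["sigma"] = sig_out, _["changed"] = ch,
                      _["states"] = rec);
}

// Full simulation loop: `iterations` epochs of t_epoch synchronous steps,
// with one topology update after each epoch. mode 0 = adaptive (frozen node
// gains an in-link, active node loses one), mode 1 = probability-driven
// (global random add with p_add, delete with p_del). When `reset` is true
// the states are re-randomized at the start of every epoch; activity flags
// are accumulated only over steps >= t_transient so that the attractor, not
// the settling transient, decides frozen vs active. Uses R's RNG.
// [[Rcpp::export]]
List cpp_soc_run(int n, IntegerVector tgt, IntegerVector src, IntegerVector sgn,
                 IntegerVector sigma0, int t_epoch, int iterations,
                 int mode, double p_add, double p_del,
                 IntegerVector monitor, int record_from,
                 bool reset, int t_transient) {
  adj_t asrc, asgn;
  build_adj(tgt, src, sgn, n, asrc, asgn);
  std::vector<int> sigma(sigma0.begin(), sigma0.end());
  std::vector<int> buf(n);
  long m_links = tgt.size();

  NumericVector k_series(iterations);
  NumericVector frozen_frac(iterations);
  const int nm = monitor.size();
  int n_rec_epochs = 0;
  if (nm > 0 && record_from >= 1 && record_from <= iterations)
    n_rec_epochs = iterations - record_from + 1;
  IntegerMatrix rec((long)n_rec_epochs * t_epoch, nm);

  for (int it = 1; it <= iterations; ++it) {
    std::vector<char> changed(n, 0);
    bool recording = (n_rec_epochs > 0 && it >= record_from);
    long base = recording ? (long)(it - record_from) * t_epoch : 0;
    if (reset)
      for (int i = 0; i < n; ++i) sigma[i] = (unif_rand() < 0.5) ? -1 : 1;
    for (int t = 0; t < t_epoch; ++t) {
      std::vector<int> prev(sigma);
      step_once(asrc, asgn, sigma, buf);
      if (t >= t_transient)
        for (int i = 0; i < n; ++i) if (sigma[i] != prev[i]) changed[i] = 1;
      if (recording)
        for (int j = 0; j < nm; ++j) rec(base + t, j) = sigma[monitor[j] - 1];
    }
    long nfroz = 0;
    for (int i = 0; i < n; ++i) if (!changed[i]) ++nfroz;
    frozen_frac[it - 1] = (double)nfroz / n;

    if (mode == 0) {
      // adaptive: one random node; frozen -> add incoming link, active ->
      // delete a random incoming link; impossible moves leave the net alone
      int u = (int)(unif_rand() * n); if (u == n) u = n - 1;
      if (!changed[u]) {
        if ((long)asrc[u].size() < n - 1) {
          for (int tries = 0; tries < 10000; ++tries) {
            int v = (int)(unif_rand() * n); if (v == n) v = n - 1;
            if (v == u || has_link(asrc, u, v)) continue;
            int w = (unif_rand() < 0.5) ? -1 : 1;
            asrc[u].push_back(v);
            asgn[u].push_back(w);
            ++m_links;
            break;
          }
        }
      } else {
        if (!asrc[u].empty()) {
          int k = (int)(unif_rand() * asrc[u].size());
          if (k == (int)asrc[u].size()) --k;
          asrc[u][k] = asrc[u].back(); asrc[u].pop_back();
          asgn[u][k] = asgn[u].back(); asgn[u].pop_back();
          --m_links;
        }
      }
    } else {
      // probability-driven rewiring, independent of node activity
      if (unif_rand() < p_add && m_links < (long)n * (n - 1)) {
        for (int tries = 0; tries < 10000; ++tries) {
          int u = (int)(unif_rand() * n); if (u == n) u = n - 1;
          int v = (int)(unif_rand() * n); if (v == n) v = n - 1;
          if (v == u || has_link(asrc, u, v)) continue;
          int w = (unif_rand() < 0.5) ? -1 : 1;
          asrc[u].push_back(v);
          asgn[u].push_back(w);
          ++m_links;
          break;
        }
      }
      if (unif_rand() < p_del && m_links > 0) {
        long r = (long)(unif_rand() * m_links);
        if (r == m_links) --r;
        for (int i = 0; i < n; ++i) {
          long deg = (long)asrc[i].size();
          if (r < deg) {
            asrc[i][r] = asrc[i].back(); asrc[i].pop_back();
            asgn[i][r] = asgn[i].back(); asgn[i].pop_back();
            --m_links;
            break;
          }
          r -= deg;
        }
      }
    }
    k_series[it - 1] = (double)m_links / n;
  }

  IntegerVector tgt_out, src_out, sgn_out;
  flatten_adj(asrc, asgn, tgt_out, src_out, sgn_out);
  IntegerVector sig_out(sigma.begin(), sigma.end());
  return List::create(_["k_series"] = k_series,
                      _["frozen_frac"] = frozen_frac,
                      _["sigma"] = sig_out,
                      _["tgt"] = tgt_out, _["src"] = src_out,
                      _["sgn"] = sgn_out,
                      _["states"] = rec,
                      _["record_from"] = record_from);
}
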