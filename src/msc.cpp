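// Structured-coalescent simulation over a species tree with directed
// admixture pulses, infinite-sites mutation, and ABBA/BABA site-pattern
// counting. All randomness goes through R's RNG so that set.seed() in R
// makes every output reproducible.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <set>
#include <cstdio>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Event {
  double time;
  int type;   // 0 = speciation (merge child branches into node), 1 = pulse
  int node;   // speciation: species node; pulse: index into pulse arrays
  bool operator<(const Event& o) const {
    if (time != o.time) return time < o.time;
    return type < o.type;  // pulses never share a time with a speciation (validated in R)
  }
};

// One sampled gene tree in array form. Leaves are 0..n_lin-1, internal
// nodes are appended; node 2*n_lin-2 need not be the root, track root id.
struct GeneTree {
  int n_lin;
  std::vector<int> left, right;   // -1 for leaves
  std::vector<double> time;       // generations before present
  int root;
  double total_length() const {
    double s = 0.0;
    int n = (int)time.size();
    std::vector<double> tt(n);
    for (int v = 0; v < n; ++v) {
      if (left[v] >= 0) {
        s += time[v] - time[left[v]];
        s += time[v] - time[right[v]];
      }
    }
    return s;
  }
};

class MscSampler {
public:
  MscSampler(const IntegerVector& sp_parent, const NumericVector& sp_time,
             const NumericVector& sp_ne, const IntegerVector& lin_branch,
             const NumericVector& pulse_time, const IntegerVector& pulse_from,
             const IntegerVector& pulse_to, const NumericVector& pulse_gamma)
      : sp_parent_(as<std::vector<int> >(sp_parent)),
        sp_time_(as<std::vector<double> >(sp_time)),
        sp_ne_(as<std::vector<double> >(sp_ne)),
        lin_branch_(as<std::vector<int> >(lin_branch)),
        p_time_(as<std::vector<double> >(pulse_time)),
        p_from_(as<std::vector<int> >(pulse_from)),
        p_to_(as<std::vector<int> >(pulse_to)),
        p_gamma_(as<std::vector<double> >(pulse_gamma)) {
    int nsp = (int)sp_parent_.size();
    for (int v = 0; v < nsp; ++v) {
      bool internal = false;
      for (int u = 0; u < nsp; ++u)
        if (sp_parent_[u] == v) { internal = true; break; }
      if (internal) events_.push_back(Event{sp_time_[v], 0, v});
    }
    for (int j = 0; j < (int)p_time_.size(); ++j)
      events_.push_back(Event{p_time_[j], 1, j});
    std::sort(events_.begin(), events_.end());
  }

  GeneTree sample() const {
    int n = (int)lin_branch_.size();
    GeneTree g;
    g.n_lin = n;
    g.left.assign(2 * n - 1, -1);
    g.right.assign(2 * n - 1, -1);
    g.time.assign(2 * n - 1, 0.0);
    std::vector<int> node(n), branch(lin_branch_);
    for (int i = 0; i < n; ++i) node[i] = i;
    int next_node = n;
    double t = 0.0;
    size_t ev = 0;
    int active = n;
    while (active > 1) {
      double t_stop = (ev < events_.size()) ? events_[ev].time : R_PosInf;
      // coalescence phase within branches until t_stop
      for (;;) {
        double rate = 0.0;
        for (int i = 0; i < active; ++i)
          for (int j = i + 1; j < active; ++j)
            if (branch[i] == branch[j]) rate += 1.0 / (2.0 * sp_ne_[branch[i]]);
        if (rate <= 0.0) { t = t_stop; break; }
        double dt = R::rexp(1.0 / rate);
        if (t + dt >= t_stop) { t = t_stop; break; }
        t += dt;
        // choose a coalescing pair proportional to per-pair rate
        double u = R::runif(0.0, rate);
        int ci = -1, cj = -1;
        double acc = 0.0;
        for (int i = 0; i < active && ci < 0; ++i)
          for (int j = i + 1; j < active; ++j)
            if (branch[i] == branch[j]) {
              acc += 1.0 / (2.0 * sp_ne_[branch[i]]);
              if (u <= acc) { ci = i; cj = j; break; }
            }
        if (ci < 0) { ci = active - 2; cj = active - 1; }  // numeric guard
        int v = next_node++;
        g.left[v] = node[ci];
        g.right[v] = node[cj];
        g.time[v] = t;
        node[ci] = v;
        // remove cj
        node[cj] = node[active - 1];
        branch[cj] = branch[active - 1];
        --active;
        if (active == 1) break;
      }
      if (active == 1) break;
      if (ev < events_.size()) {
        const Event& e = events_[ev++];
        if (e.type == 0) {
          for (int i = 0; i < active; ++i)
            if (sp_parent_[branch[i]] == e.node) branch[i] = e.node;
        } else {
          double gam = p_gamma_[e.node];
          int from = p_from_[e.node], to = p_to_[e.node];
          if (gam > 0.0)  // gamma = 0 must not consume RNG draws (exact no-op)
            for (int i = 0; i < active; ++i)
              if (branch[i] == from && R::unif_rand() < gam) branch[i] = to;
        }
      }
    }
    g.root = node[0];
    return g;
  }

private:
  std::vector<int> sp_parent_;
  std::vector<double> sp_time_, sp_ne_;
  std::vector<int> lin_branch_;
  std::vector<double> p_time_;
  std::vector<int> p_from_, p_to_;
  std::vector<double> p_gamma_;
  std::vector<Event> events_;
};

void leaf_masks(const GeneTree& g, std::vector<uint64_t>& mask) {
  int n = (int)g.time.size();
  mask.assign(n, 0);
  // nodes are created in increasing time order, so children precede parents
  for (int v = 0; v < g.n_lin; ++v) mask[v] = (uint64_t)1 << v;
  for (int v = g.n_lin; v < n; ++v)
    mask[v] = mask[g.left[v]] | mask[g.right[v]];
}

void newick_rec(const GeneTree& g, int v, double parent_time,
                const std::vector<std::string>& labels, std::string& out) {
  if (g.left[v] < 0) {
    out += labels[v];
  } else {
    out += '(';
    newick_rec(g, g.left[v], g.time[v], labels, out);
    out += ',';
    newick_rec(g, g.right[v], g.time[v], labels, out);
    out += ')';
  }
  if (R_finite(parent_time)) {
    char buf[40];
    std::snprintf(buf, sizeof(buf), ":%.10g", parent_time - g.time[v]);
    out += buf;
  }
}

std::string to_newick(const GeneTree& g, const std::vector<std::string>& labels) {
  std::string s;
  newick_rec(g, g.root, R_PosInf, labels, s);
  s += ';';
  return s;
}

// Drop infinite-sites mutations on a tree over a segment of len integer
// positions; append (offset, leafmask) pairs.
void drop_mutations_on(const GeneTree& g, double mu, int len,
                       std::vector<int>& pos_out, std::vector<uint64_t>& mask_out) {
  std::vector<uint64_t> mask;
  leaf_masks(g, mask);
  uint64_t all = mask[g.root];
  std::set<int> used;
  int n = (int)g.time.size();
  for (int v = 0; v < n; ++v) {
    if (v == g.root) continue;
    // find parent time: nodes don't store parent, so scan once below
    ;
  }
  // build parent times
  std::vector<double> ptime(n, R_PosInf);
  for (int v = g.n_lin; v < n; ++v) {
    ptime[g.left[v]] = g.time[v];
    ptime[g.right[v]] = g.time[v];
  }
  for (int v = 0; v < n; ++v) {
    if (!R_finite(ptime[v])) continue;  // root
    double blen = ptime[v] - g.time[v];
    if (blen <= 0.0) continue;
    int nmut = (int)R::rpois(mu * (double)len * blen);
    for (int m = 0; m < nmut; ++m) {
      if ((int)used.size() >= len)
        stop("infinite-sites model exhausted: more mutations than positions in a segment; lower mu or enlarge windows");
      int p;
      do { p = (int)std::floor(R::runif(0.0, (double)len)); if (p >= len) p = len - 1; }
      while (used.count(p));
      used.insert(p);
      pos_out.push_back(p);
      mask_out.push_back(mask[v] & all);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate_genome(IntegerVector sp_parent, NumericVector sp_time,
                         NumericVector sp_ne, IntegerVector lin_branch,
                         NumericVector pulse_time, IntegerVector pulse_from,
                         IntegerVector pulse_to, NumericVector pulse_gamma,
                         CharacterVector lin_labels, int n_windows,
                         double window_len, double mu, int n_segments,
                         NumericVector seg_change_prob, bool want_trees,
                         bool want_geno) {
  int n_lin = lin_branch.size();
  if (n_lin > 64) stop("at most 64 lineages are supported");
  if (n_segments < 1) stop("n_segments must be >= 1");
  int seg_len = (int)(window_len / n_segments);
  if (seg_len < 1) stop("segment length below 1 bp");
  MscSampler sampler(sp_parent, sp_time, sp_ne, lin_branch, pulse_time,
                     pulse_from, pulse_to, pulse_gamma);
  std::vector<std::string> labels(n_lin);
  for (int i = 0; i < n_lin; ++i) labels[i] = as<std::string>(lin_labels[i]);

  std::vector<int> site_window;
  std::vector<double> site_pos;
  std::vector<uint64_t> site_mask;
  std::vector<std::string> tree_newick;
  std::vector<int> tree_window;
  std::vector<double> tree_start, tree_end;
  IntegerVector n_distinct(n_windows);

  for (int w = 0; w < n_windows; ++w) {
    double pw = seg_change_prob.size() == 1 ? seg_change_prob[0]
                                            : seg_change_prob[w];
    GeneTree g = sampler.sample();
    int distinct = 1;
    for (int s = 0; s < n_segments; ++s) {
      if (s > 0 && R::unif_rand() < pw) {
        g = sampler.sample();
        ++distinct;
      }
      double off = w * window_len + s * (double)seg_len;
      if (want_trees) {
        tree_newick.push_back(to_newick(g, labels));
        tree_window.push_back(w + 1);
        tree_start.push_back(off);
        tree_end.push_back(off + seg_len);
      }
      if (want_geno && mu > 0.0) {
        std::vector<int> pos;
        std::vector<uint64_t> msk;
        drop_mutations_on(g, mu, seg_len, pos, msk);
        // sort sites by position within the segment
        std::vector<int> ord(pos.size());
        for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int)k;
        std::sort(ord.begin(), ord.end(),
                  [&](int a, int b) { return pos[a] < pos[b]; });
        for (int k : ord) {
          site_window.push_back(w + 1);
          site_pos.push_back(off + pos[k]);
          site_mask.push_back(msk[k]);
        }
      }
    }
    n_distinct[w] = distinct;
  }

  R_xlen_t n_sites = (R_xlen_t)site_mask.size();
  IntegerMatrix geno(n_sites, n_lin);
  for (R_xlen_t i = 0; i < n_sites; ++i) {
    uint64_t m = site_mask[i];
    for (int j = 0; j < n_lin; ++j)
      geno(i, j) = (int)((m >> j) & 1);
  }
  colnames(geno) = lin_labels;

  return List::create(
      _["geno"] = geno, _["site_window"] = wrap(site_window),
      _["site_pos"] = wrap(site_pos), _["newick"] = wrap(tree_newick),
      _["tree_window"] = wrap(tree_window), _["tree_start"] = wrap(tree_start),
      _["tree_end"] = wrap(tree_end), _["n_distinct"] = n_distinct);
}

// ABBA/BABA counting for 0/1 (or any integer-coded biallelic) genotypes.
// Derived state is defined per site relative to the outgroup column of each
// quartet; sites with NA in any of the four columns are skipped for that
// quartet only.
// [[Rcpp::export]]
List cpp_count_patterns(IntegerMatrix geno, IntegerVector block, int n_block,
                        IntegerMatrix quartets) {
  R_xlen_t n_sites = geno.nrow();
  int K = quartets.nrow();
  if (block.size() != n_sites) stop("block vector length mismatch");
  NumericMatrix abba(n_block, K), baba(n_block, K);
  const int* blk = INTEGER(block);
  for (R_xlen_t s = 0; s < n_sites; ++s) {
    int b = blk[s] - 1;
    if (b < 0 || b >= n_block) stop("site falls outside the block partition");
  }
  // quartet-outer loop: contiguous column scans are cache-friendly
  for (int k = 0; k < K; ++k) {
    const int* c1 = &geno(0, quartets(k, 0) - 1);
    const int* c2 = &geno(0, quartets(k, 1) - 1);
    const int* c3 = &geno(0, quartets(k, 2) - 1);
    const int* c4 = &geno(0, quartets(k, 3) - 1);
    double* ab = &abba(0, k);
    double* ba = &baba(0, k);
    for (R_xlen_t s = 0; s < n_sites; ++s) {
      int g1 = c1[s], g2 = c2[s], g3 = c3[s], g4 = c4[s];
      if (g1 == NA_INTEGER || g2 == NA_INTEGER || g3 == NA_INTEGER ||
          g4 == NA_INTEGER)
        continue;
      int d1 = g1 != g4, d2 = g2 != g4, d3 = g3 != g4;
      if (d3 && d2 && !d1) ab[blk[s] - 1] += 1.0;
      else if (d3 && d1 && !d2) ba[blk[s] - 1] += 1.0;
    }
  }
  return List::create(_["abba"] = abba, _["baba"] = baba);
}

// Frequency-weighted variant: freq holds the derived-allele frequency per
// taxon (already polarized so that the outgroup column is the reference for
// the ancestral state); weights follow the standard population formulation
// abba = (1-p1) p2 p3 (1-p4), baba = p1 (1-p2) p3 (1-p4).
// [[Rcpp::export]]
List cpp_count_patterns_freq(NumericMatrix freq, IntegerVector block,
                             int n_block, IntegerMatrix quartets) {
  R_xlen_t n_sites = freq.nrow();
  int K = quartets.nrow();
  if (block.size() != n_sites) stop("block vector length mismatch");
  NumericMatrix abba(n_block, K), baba(n_block, K);
  for (R_xlen_t s = 0; s < n_sites; ++s) {
    int b = block[s] - 1;
    if (b < 0 || b >= n_block) stop("site falls outside the block partition");
    for (int k = 0; k < K; ++k) {
      double p1 = freq(s, quartets(k, 0) - 1), p2 = freq(s, quartets(k, 1) - 1),
             p3 = freq(s, quartets(k, 2) - 1), p4 = freq(s, quartets(k, 3) - 1);
      if (ISNAN(p1) || ISNAN(p2) || ISNAN(p3) || ISNAN(p4)) continue;
      abba(b, k) += (1.0 - p1) * p2 * p3 * (1.0 - p4);
      baba(b, k) += p1 * (1.0 - p2) * p3 * (1.0 - p4);
    }
  }
  return List::create(_["abba"] = abba, _["baba"] = baba);
}
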