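// Hudson-style coalescent simulator with recombination (piecewise-constant
// map with hotspots), multiple populations with exponential growth and
// migration, timed demographic events, and a trajectory-conditioned
// structured-coalescent sweep mode.
//
// Units follow the ms convention: time in units of 4*N0 generations,
// theta = 4*N0*mu*L per region, rho = 4*N0*r*L per region, sizes in units
// of N0, migration entries M_ij = 4*N0*m_ij (per-lineage backward rate of
// moving from deme i to deme j, per 4*N0 generations).  Positions live on
// [0, 1).

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Segment {
  double left, right;
  int node;    // current root of this interval's subtree
  int nsamp;   // number of samples subtended
};

struct Lineage {
  int pop;
  std::vector<Segment> segs;
};

struct Tables {
  std::vector<double> node_time;
  std::vector<double> e_left, e_right;
  std::vector<int> e_parent, e_child;
  int n_samples;
  void add_edge(double l, double r, int p, int c) {
    e_left.push_back(l); e_right.push_back(r);
    e_parent.push_back(p); e_child.push_back(c);
  }
};

// piecewise-constant recombination intensity on [0,1)
struct RecMap {
  std::vector<double> brk;   // 0 = b0 < b1 < ... < bk = 1
  std::vector<double> inten; // intensity per interval (basal = 1)
  std::vector<double> cum;   // cumulative mass at brk (cum[0] = 0)
  double rho;                // basal total rho for the region

  void init(double rho_, const std::vector<double>& hl,
            const std::vector<double>& hr,
            const std::vector<double>& hf) {
    rho = rho_;
    std::vector<std::pair<double, double>> hs;
    for (size_t i = 0; i < hl.size(); ++i)
      hs.push_back({hl[i], hr[i]});
    brk.clear(); inten.clear();
    brk.push_back(0.0);
    double cur = 0.0;
    for (size_t i = 0; i < hl.size(); ++i) {
      if (hl[i] > cur) { brk.push_back(hl[i]); inten.push_back(1.0); }
      brk.push_back(hr[i]); inten.push_back(hf[i]);
      cur = hr[i];
    }
    if (cur < 1.0) { brk.push_back(1.0); inten.push_back(1.0); }
    if (brk.back() < 1.0) brk.push_back(1.0);
    cum.assign(brk.size(), 0.0);
    for (size_t k = 1; k < brk.size(); ++k)
      cum[k] = cum[k - 1] + inten[k - 1] * (brk[k] - brk[k - 1]) * rho;
  }
  double mass(double a, double b) const { return cumat(b) - cumat(a); }
  double cumat(double u) const {
    size_t k = std::upper_bound(brk.begin(), brk.end(), u) - brk.begin();
    if (k == 0) return 0.0;
    if (k >= brk.size()) return cum.back();
    return cum[k - 1] + inten[k - 1] * (u - brk[k - 1]) * rho;
  }
  // inverse of cumat restricted to (cumat(a), cumat(b))
  double invert(double target) const {
    size_t k = std::upper_bound(cum.begin(), cum.end(), target) - cum.begin();
    if (k == 0) k = 1;
    if (k >= brk.size()) return brk.back();
    return brk[k - 1] + (target - cum[k - 1]) / (inten[k - 1] * rho);
  }
};

struct Pop {
  double size;     // x at time t_last (units of N0)
  double growth;   // ms alpha: x(t) = size * exp(-alpha * (t - t_last))
  double t_last;
  double size_at(double t) const {
    return size * std::exp(-growth * (t - t_last));
  }
};

struct Event {
  double time;
  int kind;  // 0 = ej(i->j), 1 = en(i,x), 2 = eg(i,alpha), 3 = em(i,j,x)
  int i, j;
  double x;
};

double runif01() { return unif_rand(); }

// waiting time to a coalescence in a growing/shrinking population:
// rate(dt) = base * exp(alpha * dt), base = k(k-1)/x(t_now)
double coal_wait(double base, double alpha) {
  if (base <= 0.0) return R_PosInf;
  double e = exp_rand();
  if (alpha == 0.0) return e / base;
  double arg = 1.0 + alpha * e / base;
  if (arg <= 0.0) return R_PosInf;
  return std::log(arg) / alpha;
}

// merge two lineages at time t; returns the merged lineage (may be empty)
Lineage coalesce_pair(const Lineage& a, const Lineage& b, double t,
                      Tables& tab) {
  int u = (int)tab.node_time.size();
  tab.node_time.push_back(t);
  Lineage out;
  out.pop = a.pop;
  // sweep over interval atoms defined by both segment lists
  std::vector<double> cuts;
  for (auto& s : a.segs) { cuts.push_back(s.left); cuts.push_back(s.right); }
  for (auto& s : b.segs) { cuts.push_back(s.left); cuts.push_back(s.right); }
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
  bool used = false;
  for (size_t k = 0; k + 1 < cuts.size(); ++k) {
    double l = cuts[k], r = cuts[k + 1];
    if (r <= l) continue;
    const Segment* sa = nullptr; const Segment* sb = nullptr;
    for (auto& s : a.segs) if (s.left <= l && s.right >= r) { sa = &s; break; }
    for (auto& s : b.segs) if (s.left <= l && s.right >= r) { sb = &s; break; }
    if (sa && sb) {
      used = true;
      tab.add_edge(l, r, u, sa->node);
      tab.add_edge(l, r, u, sb->node);
      int ns = sa->nsamp + sb->nsamp;
      if (ns < tab.n_samples)
        out.segs.push_back({l, r, u, ns});
      // else: interval reached its MRCA, drop it
    } else if (sa) {
      out.segs.push_back({l, r, sa->node, sa->nsamp});
    } else if (sb) {
      out.segs.push_back({l, r, sb->node, sb->nsamp});
    }
  }
  if (!used) tab.node_time.pop_back();  // no overlap: u unused
  // fuse adjacent segments with the same node
  std::vector<Segment> fused;
  for (auto& s : out.segs) {
    if (!fused.empty() && fused.back().right == s.left &&
        fused.back().node == s.node && fused.back().nsamp == s.nsamp)
      fused.back().right = s.right;
    else fused.push_back(s);
  }
  out.segs = fused;
  return out;
}

double lin_span_mass(const Lineage& L, const RecMap& rm) {
  if (L.segs.empty()) return 0.0;
  return rm.mass(L.segs.front().left, L.segs.back().right);
}

// split lineage at map-uniform breakpoint; returns (left, right) parts
std::pair<Lineage, Lineage> recombine(const Lineage& L, const RecMap& rm,
                                      double& bp_out) {
  double a = L.segs.front().left, b = L.segs.back().right;
  double target = rm.cumat(a) + runif01() * (rm.cumat(b) - rm.cumat(a));
  double u = rm.invert(target);
  if (u <= a) u = std::nextafter(a, b);
  if (u >= b) u = std::nextafter(b, a);
  bp_out = u;
  Lineage left, right;
  left.pop = right.pop = L.pop;
  for (auto& s : L.segs) {
    if (s.right <= u) left.segs.push_back(s);
    else if (s.left >= u) right.segs.push_back(s);
    else {
      left.segs.push_back({s.left, u, s.node, s.nsamp});
      right.segs.push_back({u, s.right, s.node, s.nsamp});
    }
  }
  return {left, right};
}

// drop infinite-sites mutations on the marginal trees; returns positions
// (sorted) and a 0/1 matrix n_samples x n_sites
void drop_mutations(const Tables& tab, double theta,
                    std::vector<double>& pos,
                    std::vector<std::vector<int>>& cols) {
  std::vector<double> cuts = tab.e_left;
  cuts.insert(cuts.end(), tab.e_right.begin(), tab.e_right.end());
  cuts.push_back(0.0); cuts.push_back(1.0);
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
  int n = tab.n_samples;
  for (size_t k = 0; k + 1 < cuts.size(); ++k) {
    double l = cuts[k], r = cuts[k + 1];
    if (r <= l) continue;
    // edges covering this atom
    std::vector<int> eidx;
    double total_len = 0.0;
    for (size_t e = 0; e < tab.e_left.size(); ++e) {
      if (tab.e_left[e] <= l && tab.e_right[e] >= r) {
        eidx.push_back((int)e);
        total_len += tab.node_time[tab.e_parent[e]] -
                     tab.node_time[tab.e_child[e]];
      }
    }
    if (eidx.empty()) continue;
    int nmut = (int)R::rpois(theta * (r - l) * total_len);
    if (nmut == 0) continue;
    // children map for descendant lookup
    std::map<int, std::vector<int>> kids;
    for (int e : eidx) kids[tab.e_parent[e]].push_back(tab.e_child[e]);
    for (int m = 0; m < nmut; ++m) {
      double pick = runif01() * total_len;
      int chosen = eidx[0];
      for (int e : eidx) {
        double len = tab.node_time[tab.e_parent[e]] -
                     tab.node_time[tab.e_child[e]];
        if (pick < len) { chosen = e; break; }
        pick -= len;
      }
      // leaves under the chosen edge's child
      std::vector<int> stack = {tab.e_child[chosen]};
      std::vector<int> col(n, 0);
      int nder = 0;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        if (v < n) { col[v] = 1; ++nder; }
        auto it = kids.find(v);
        if (it != kids.end())
          for (int c : it->second) stack.push_back(c);
      }
      if (nder == 0 || nder == n) continue;  // fixed in sample: not a SNP
      pos.push_back(l + runif01() * (r - l));
      cols.push_back(col);
    }
  }
  // sort by position
  std::vector<size_t> ord(pos.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t i, size_t j) { return pos[i] < pos[j]; });
  std::vector<double> p2; std::vector<std::vector<int>> c2;
  double last = -1.0;
  for (size_t i : ord) {
    double p = pos[i];
    if (p <= last) p = std::nextafter(last, 2.0);
    p2.push_back(p); c2.push_back(cols[i]); last = p;
  }
  pos = p2; cols = c2;
}

List tables_to_matrix(const Tables& tab, double theta,
                      const std::vector<double>& bps) {
  std::vector<double> pos;
  std::vector<std::vector<int>> cols;
  drop_mutations(tab, theta, pos, cols);
  int n = tab.n_samples, S = (int)pos.size();
  IntegerMatrix m(n, S);
  NumericVector p(S);
  for (int j = 0; j < S; ++j) {
    p[j] = pos[j];
    for (int i = 0; i < n; ++i) m(i, j) = cols[j][i];
  }
  return List::create(_["alleles"] = m, _["positions"] = p,
                      _["breakpoints"] = NumericVector(bps.begin(), bps.end()));
}

}  // namespace

// [[Rcpp::export]]
List sim_coalescent_cpp(IntegerVector sample_sizes,
                        NumericVector pop_size, NumericVector pop_growth,
                        NumericMatrix mig,
                        NumericVector ev_time, IntegerVector ev_kind,
                        IntegerVector ev_i, IntegerVector ev_j,
                        NumericVector ev_x,
                        double theta, double rho,
                        NumericVector hot_l, NumericVector hot_r,
                        NumericVector hot_f,
                        int reps) {
  int npop = sample_sizes.size();
  int ntot = 0;
  for (int p = 0; p < npop; ++p) ntot += sample_sizes[p];
  if (ntot < 2) stop("need at least 2 sampled haplotypes");
  RecMap rm;
  rm.init(rho, as<std::vector<double>>(hot_l),
          as<std::vector<double>>(hot_r), as<std::vector<double>>(hot_f));
  List out(reps);
  for (int rep = 0; rep < reps; ++rep) {
    Tables tab; tab.n_samples = ntot;
    std::vector<Lineage> lin;
    int id = 0;
    for (int p = 0; p < npop; ++p)
      for (int s = 0; s < sample_sizes[p]; ++s) {
        Lineage L; L.pop = p;
        L.segs.push_back({0.0, 1.0, id, 1});
        lin.push_back(L);
        tab.node_time.push_back(0.0);
        ++id;
      }
    std::vector<Pop> pops(npop);
    for (int p = 0; p < npop; ++p)
      pops[p] = {pop_size[p], pop_growth[p], 0.0};
    std::vector<std::vector<double>> M(npop, std::vector<double>(npop));
    for (int i = 0; i < npop; ++i)
      for (int j = 0; j < npop; ++j) M[i][j] = (i == j) ? 0.0 : mig(i, j);
    size_t next_ev = 0;
    double t = 0.0;
    std::vector<double> bps;
    long guard = 0;
    while (!lin.empty()) {
      if (++guard > 100000000L) stop("simulation did not terminate");
      // per-pop lineage counts
      std::vector<int> k(npop, 0);
      for (auto& L : lin) k[L.pop]++;
      // candidate waiting times
      double dt_best = R_PosInf;
      int what = -1, wpop = -1;
      for (int p = 0; p < npop; ++p) {
        if (k[p] < 2) continue;
        double base = (double)k[p] * (k[p] - 1) / pops[p].size_at(t);
        double dt = coal_wait(base, pops[p].growth);
        if (dt < dt_best) { dt_best = dt; what = 0; wpop = p; }
      }
      double migrate = 0.0;
      for (int p = 0; p < npop; ++p) {
        double row = 0.0;
        for (int q = 0; q < npop; ++q) row += M[p][q];
        migrate += k[p] * row;
      }
      if (migrate > 0.0) {
        double dt = exp_rand() / migrate;
        if (dt < dt_best) { dt_best = dt; what = 1; }
      }
      double recrate = 0.0;
      for (auto& L : lin) recrate += lin_span_mass(L, rm);
      if (recrate > 0.0) {
        double dt = exp_rand() / recrate;
        if (dt < dt_best) { dt_best = dt; what = 2; }
      }
      // demographic event before the sampled event?
      if (next_ev < (size_t)ev_time.size() &&
          t + dt_best > ev_time[next_ev]) {
        t = ev_time[next_ev];
        int kind = ev_kind[next_ev];
        int i = ev_i[next_ev], j = ev_j[next_ev];
        double x = ev_x[next_ev];
        if (kind == 0) {            // ej: move lineages i -> j
          for (auto& L : lin) if (L.pop == i) L.pop = j;
          for (int q = 0; q < npop; ++q) M[q][i] = 0.0;
          for (int q = 0; q < npop; ++q) M[i][q] = 0.0;
        } else if (kind == 1) {     // en: size change, growth reset
          pops[i] = {x, 0.0, t};
        } else if (kind == 2) {     // eg: growth change
          pops[i] = {pops[i].size_at(t), x, t};
        } else if (kind == 3) {     // em: single migration entry
          M[i][j] = x;
        }
        ++next_ev;
        continue;
      }
      if (!std::isfinite(dt_best)) {
        if (next_ev < (size_t)ev_time.size()) {
          t = ev_time[next_ev];
          continue;  // loop will re-enter and apply the event
        }
        stop("no possible events left but lineages remain (disconnected demes?)");
      }
      t += dt_best;
      if (what == 0) {              // coalescence in wpop
        std::vector<int> idx;
        for (size_t q = 0; q < lin.size(); ++q)
          if (lin[q].pop == wpop) idx.push_back((int)q);
        int a = (int)(runif01() * idx.size());
        int b = a;
        while (b == a) b = (int)(runif01() * idx.size());
        Lineage merged = coalesce_pair(lin[idx[a]], lin[idx[b]], t, tab);
        int ia = idx[a], ib = idx[b];
        if (ia < ib) std::swap(ia, ib);
        lin.erase(lin.begin() + ia);
        lin.erase(lin.begin() + ib);
        if (!merged.segs.empty()) lin.push_back(merged);
      } else if (what == 1) {       // migration
        double pick = runif01() * migrate;
        int chosen = -1, dest = -1;
        for (size_t q = 0; q < lin.size() && chosen < 0; ++q) {
          double row = 0.0;
          for (int d = 0; d < npop; ++d) row += M[lin[q].pop][d];
          if (pick < row) {
            chosen = (int)q;
            for (int d = 0; d < npop; ++d) {
              if (pick < M[lin[q].pop][d]) { dest = d; break; }
              pick -= M[lin[q].pop][d];
            }
          } else pick -= row;
        }
        if (chosen >= 0 && dest >= 0) lin[chosen].pop = dest;
      } else if (what == 2) {       // recombination
        double pick = runif01() * recrate;
        int chosen = -1;
        for (size_t q = 0; q < lin.size(); ++q) {
          double mass = lin_span_mass(lin[q], rm);
          if (pick < mass) { chosen = (int)q; break; }
          pick -= mass;
        }
        if (chosen >= 0) {
          double bp;
          auto parts = recombine(lin[chosen], rm, bp);
          if (!parts.first.segs.empty() && !parts.second.segs.empty()) {
            bps.push_back(bp);
            lin[chosen] = parts.first;
            lin.push_back(parts.second);
          }
        }
      }
    }
    out[rep] = tables_to_matrix(tab, theta, bps);
  }
  return out;
}

// Structured coalescent conditioned on a deterministic logistic sweep
// trajectory in a single constant-size population.  Samples 0..n_der-1
// carry the derived allele at the core.  Time is simulated in
// generations and stored in units of 4N.
// [[Rcpp::export]]
List sim_sweep_cpp(int n, int n_der, double theta, double rho,
                   NumericVector hot_l, NumericVector hot_r,
                   NumericVector hot_f,
                   double s, double N, double core_pos, int reps) {
  if (n_der < 1 || n_der >= n) stop("need 0 < n_der < n");
  RecMap rm;
  rm.init(rho, as<std::vector<double>>(hot_l),
          as<std::vector<double>>(hot_r), as<std::vector<double>>(hot_f));
  double x0 = n_der / (double)n;         // present-day derived frequency
  double xmin = 1.0 / (2.0 * N);
  double T = std::log(x0 * (1.0 - xmin) / ((1.0 - x0) * xmin)) / s;
  double fourN = 4.0 * N;
  double r_region = rho / fourN;         // recombination prob/gen, region
  List out(reps);
  for (int rep = 0; rep < reps; ++rep) {
    Tables tab; tab.n_samples = n;
    std::vector<Lineage> lin;
    std::vector<int> label;              // 1 = derived background
    for (int i = 0; i < n; ++i) {
      Lineage L; L.pop = 0;
      L.segs.push_back({0.0, 1.0, i, 1});
      lin.push_back(L);
      label.push_back(i < n_der ? 1 : 0);
      tab.node_time.push_back(0.0);
    }
    double g = 0.0;                      // generations before present
    long guard = 0;
    auto freq = [&](double gg) {
      return x0 / (x0 + (1.0 - x0) * std::exp(s * gg));
    };
    // --- sweep phase ---
    while (g < T) {
      if (++guard > 200000000L) stop("sweep simulation did not terminate");
      int kB = 0, kb = 0;
      for (size_t q = 0; q < lin.size(); ++q)
        (label[q] ? kB : kb)++;
      if (kB <= 1 && kb == 0 && lin.size() <= 1) break;
      double x = freq(g);
      double rateB = kB * (kB - 1) / 2.0 / (2.0 * N * x);
      double rateb = kb * (kb - 1) / 2.0 / (2.0 * N * (1.0 - x));
      double raterec = 0.0;
      for (auto& L : lin)
        raterec += lin_span_mass(L, rm) / fourN;  // per generation
      double total = rateB + rateb + raterec;
      if (total <= 0.0) { g = T; break; }
      double step = std::min(0.1 / total, T - g);
      if (runif01() > total * step) { g += step; continue; }
      g += runif01() * step;  // event somewhere inside the accepted slab
      double pick = runif01() * total;
      if (pick < rateB || pick < rateB + rateb) {
        int want = (pick < rateB) ? 1 : 0;
        std::vector<int> idx;
        for (size_t q = 0; q < lin.size(); ++q)
          if (label[q] == want) idx.push_back((int)q);
        if ((int)idx.size() < 2) continue;
        int a = (int)(runif01() * idx.size());
        int b = a; while (b == a) b = (int)(runif01() * idx.size());
        Lineage merged = coalesce_pair(lin[idx[a]], lin[idx[b]],
                                       g / fourN, tab);
        int ia = idx[a], ib = idx[b];
        if (ia < ib) std::swap(ia, ib);
        lin.erase(lin.begin() + ia); label.erase(label.begin() + ia);
        lin.erase(lin.begin() + ib); label.erase(label.begin() + ib);
        if (!merged.segs.empty()) {
          lin.push_back(merged); label.push_back(want);
        }
      } else {
        // recombination: split; the non-core part re-draws its background
        double cum = 0.0; int chosen = -1;
        double pick2 = runif01() * raterec;
        for (size_t q = 0; q < lin.size(); ++q) {
          cum += lin_span_mass(lin[q], rm) / fourN;
          if (pick2 < cum) { chosen = (int)q; break; }
        }
        if (chosen < 0) continue;
        double bp;
        auto parts = recombine(lin[chosen], rm, bp);
        if (parts.first.segs.empty() || parts.second.segs.empty()) continue;
        int old = label[chosen];
        int newlab = (runif01() < freq(g)) ? 1 : 0;
        bool core_left = core_pos < bp;
        lin[chosen] = parts.first;
        lin.push_back(parts.second);
        if (core_left) {
          label[chosen] = old; label.push_back(newlab);
        } else {
          label[chosen] = newlab; label.push_back(old);
        }
      }
    }
    // force remaining derived-background lineages to coalesce at the
    // sweep origin (the allele is a single copy at time T)
    {
      std::vector<int> idx;
      for (size_t q = 0; q < lin.size(); ++q)
        if (label[q]) idx.push_back((int)q);
      double gg = std::max(g, T);
      while (idx.size() > 1) {
        gg += 1.0;  // one generation apart, immaterial at this scale
        Lineage merged = coalesce_pair(lin[idx[0]], lin[idx[1]],
                                       gg / fourN, tab);
        int ia = idx[0], ib = idx[1];
        if (ia < ib) std::swap(ia, ib);
        lin.erase(lin.begin() + ia); label.erase(label.begin() + ia);
        lin.erase(lin.begin() + ib); label.erase(label.begin() + ib);
        if (!merged.segs.empty()) {
          lin.push_back(merged); label.push_back(0);
        }
        idx.clear();
        for (size_t q = 0; q < lin.size(); ++q)
          if (label[q]) idx.push_back((int)q);
      }
      for (size_t q = 0; q < label.size(); ++q) label[q] = 0;
      g = gg;
    }
    // --- neutral phase (single population, size N) ---
    while (!lin.empty()) {
      if (++guard > 200000000L) stop("simulation did not terminate");
      int kk = (int)lin.size();
      double ratec = kk * (kk - 1) / 2.0 / (2.0 * N);
      double raterec = 0.0;
      for (auto& L : lin) raterec += lin_span_mass(L, rm) / fourN;
      double total = ratec + raterec;
      if (total <= 0.0) break;
      g += exp_rand() / total;
      if (runif01() * total < ratec) {
        if (kk < 2) break;
        int a = (int)(runif01() * kk);
        int b = a; while (b == a) b = (int)(runif01() * kk);
        Lineage merged = coalesce_pair(lin[a], lin[b], g / fourN, tab);
        int ia = a, ib = b;
        if (ia < ib) std::swap(ia, ib);
        lin.erase(lin.begin() + ia);
        lin.erase(lin.begin() + ib);
        if (!merged.segs.empty()) lin.push_back(merged);
      } else {
        double pick2 = runif01() * raterec, cum = 0.0;
        int chosen = -1;
        for (size_t q = 0; q < lin.size(); ++q) {
          cum += lin_span_mass(lin[q], rm) / fourN;
          if (pick2 < cum) { chosen = (int)q; break; }
        }
        if (chosen < 0) continue;
        double bp;
        auto parts = recombine(lin[chosen], rm, bp);
        if (parts.first.segs.empty() || parts.second.segs.empty()) continue;
        lin[chosen] = parts.first;
        lin.push_back(parts.second);
      }
    }
    std::vector<double> nobps;
    out[rep] = tables_to_matrix(tab, theta, nobps);
  }
  return out;
}
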