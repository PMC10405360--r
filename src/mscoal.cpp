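// MCMC engine for the multispecies coalescent with introgression.
//
// The species network is passed as a population graph: one population per
// branch, each with lower/upper boundary ages tied to tau parameters, a
// theta parameter, and a transition at its top (enter the parent population,
// or choose between donor/recipient paths at an introgression event with
// probability phi). Gene trees are latent per-locus states: node ages,
// topology, per-node populations and per-branch choices at hybrid events.
//
// Kernels: per-theta multipliers, per-tau rubber-band moves (gene-tree node
// ages within the adjacent populations are remapped affinely, with the
// Jacobian), phi sliding windows reflected into [0,1], a whole-state scale
// move, per-locus node-age moves, narrow-exchange topology moves restricted
// to population-compatible rearrangements, and hybrid-path flips.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double TOL = 1e-12;
static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double POS_INF = std::numeric_limits<double>::infinity();

struct RNGx {
  uint64_t s[2];
  explicit RNGx(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    for (int i = 0; i < 2; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      s[i] = x ^ (x >> 31);
    }
  }
  uint64_t next() { // xorshift128+
    uint64_t x = s[0], y = s[1];
    s[0] = y;
    x ^= x << 23;
    s[1] = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s[1] + y;
  }
  double unif() { // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double rexp() { return -std::log(unif()); }
  int randint(int n) { return (int)(unif() * n) % n; }
};

struct Pop {
  int lo_tau, hi_tau;   // tau index or -1 (fixed 0 / unbounded root)
  int theta;            // theta parameter index
  int trans;            // 0 root, 1 single, 2 choice
  int to1, to2;         // pop indices (choice: to1 = donor w.p. phi)
  int phi;              // phi / hybrid index for choice pops, else -1
};

struct Locus {
  int ntip, nnode, npat;
  std::vector<int> pat;      // ntip x npat tip states 0..3 (state-major: [tip*npat+j])
  std::vector<double> wt;    // npat pattern weights
  std::vector<int> parent;   // nnode, -1 at gene root
  std::vector<double> age;   // nnode
  std::vector<int> pop;      // nnode, population at the node's own age
  std::vector<int8_t> choice; // nnode x H, -1 unset / 0 recipient / 1 donor
  double lnl;
  std::vector<int> cstat;    // coalescences per population
  std::vector<double> astat; // sum k(k-1)*dt per population
  std::vector<int> n1, n0;   // choice counts per hybrid
};

struct Backup {
  std::vector<int> parent, pop;
  std::vector<double> age;
  std::vector<int8_t> choice;
  double lnl;
  std::vector<int> cstat;
  std::vector<double> astat;
  std::vector<int> n1, n0;
};

struct Seg { int pop; double t0, t1; };

class Sampler {
public:
  int P, K, H, T;            // pops, tau params, hybrids/phis, theta params
  std::vector<Pop> pops;
  std::vector<double> tau, theta, phi;
  int root_tau;
  double prior_a_theta, prior_a_tau, prior_b_tau;
  std::vector<double> prior_b_theta;
  int n_other;               // non-root tau params (uniform-Dirichlet exponent)
  double beta;               // likelihood power (stepping stone)
  bool lik_on;

  std::vector<Locus> loci;
  int nloci;

  // aggregates over loci
  std::vector<double> Aagg;
  std::vector<int> Cagg, N1agg, N0agg;

  RNGx rng;

  // step sizes + acceptance bookkeeping
  std::vector<double> step_tau;
  double step_theta, step_phi, step_age, step_scale;
  std::vector<double> acc, att; // per move class

  // scratch
  std::vector<Seg> segbuf;
  std::vector<double> partial, logscale, tipK;
  std::vector<int> kids1, kids2, postorder;
  std::vector<Backup> bks;
  Backup bk1;

  Sampler(uint64_t seed) : rng(seed) {}

  double lo_age(int p) const { return pops[p].lo_tau < 0 ? 0.0 : tau[pops[p].lo_tau]; }
  double hi_age(int p) const { return pops[p].hi_tau < 0 ? POS_INF : tau[pops[p].hi_tau]; }

  // ---- stats & density ------------------------------------------------

  bool compute_stats(Locus& L) {
    std::fill(L.cstat.begin(), L.cstat.end(), 0);
    std::fill(L.astat.begin(), L.astat.end(), 0.0);
    std::fill(L.n1.begin(), L.n1.end(), 0);
    std::fill(L.n0.begin(), L.n0.end(), 0);
    segbuf.clear();
    for (int v = 0; v < L.nnode; ++v) {
      int p = L.pop[v];
      double t = L.age[v];
      if (t < lo_age(p) - TOL || t > hi_age(p) + TOL) return false;
      if (v >= L.ntip) L.cstat[p] += 1;
      int pa = L.parent[v];
      if (pa < 0) continue;
      double tend = L.age[pa];
      if (tend < t - TOL) return false;
      while (true) {
        double top = hi_age(p);
        double s1 = std::min(tend, top);
        segbuf.push_back({p, t, s1});
        if (tend <= top + TOL) break;
        const Pop& pp = pops[p];
        if (pp.trans == 1) {
          p = pp.to1;
        } else if (pp.trans == 2) {
          int8_t c = L.choice[(size_t)v * H + pp.phi];
          if (c < 0) return false;
          if (c) { L.n1[pp.phi] += 1; p = pp.to1; }
          else   { L.n0[pp.phi] += 1; p = pp.to2; }
        } else {
          return false; // escaped the root population
        }
        t = top;
      }
      if (p != L.pop[pa]) return false;
    }
    // accumulate k(k-1)dt per population from the presence segments
    std::sort(segbuf.begin(), segbuf.end(), [](const Seg& a, const Seg& b) {
      return a.pop < b.pop || (a.pop == b.pop && a.t0 < b.t0);
    });
    size_t i = 0;
    std::vector<double> ends;
    while (i < segbuf.size()) {
      int p = segbuf[i].pop;
      size_t j = i;
      while (j < segbuf.size() && segbuf[j].pop == p) ++j;
      // sweep over [i, j)
      ends.clear();
      double A = 0.0;
      // event-point sweep: starts at t0 (sorted), ends tracked in a heap-ish
      // vector; with <= 80 lineages a simple approach suffices
      std::vector<std::pair<double, int>> ev;
      for (size_t k = i; k < j; ++k) {
        ev.push_back({segbuf[k].t0, +1});
        ev.push_back({segbuf[k].t1, -1});
      }
      std::sort(ev.begin(), ev.end(),
                [](const std::pair<double,int>& a, const std::pair<double,int>& b) {
                  return a.first < b.first || (a.first == b.first && a.second < b.second);
                });
      double tprev = ev.empty() ? 0.0 : ev[0].first;
      long kk = 0;
      for (auto& e : ev) {
        A += (double)kk * (kk - 1) * (e.first - tprev);
        kk += e.second;
        tprev = e.first;
      }
      L.astat[p] += A;
      i = j;
    }
    return true;
  }

  double locus_logdens(const Locus& L) const {
    double d = 0.0;
    for (int p = 0; p < P; ++p) {
      double th = theta[pops[p].theta];
      if (L.cstat[p]) d += L.cstat[p] * (std::log(2.0) - std::log(th));
      if (L.astat[p] != 0.0) d -= L.astat[p] / th;
    }
    for (int h = 0; h < H; ++h) {
      if (L.n1[h]) d += L.n1[h] * std::log(phi[h]);
      if (L.n0[h]) d += L.n0[h] * std::log(1.0 - phi[h]);
    }
    return d;
  }

  // ---- likelihood (JC69 pruning on compressed patterns) ----------------

  void build_children(const Locus& L) {
    kids1.assign(L.nnode, -1);
    kids2.assign(L.nnode, -1);
    for (int v = 0; v < L.nnode; ++v) {
      int pa = L.parent[v];
      if (pa < 0) continue;
      if (kids1[pa] < 0) kids1[pa] = v; else kids2[pa] = v;
    }
  }

  double compute_lnl(Locus& L) {
    if (!lik_on || L.npat == 0) return 0.0;
    build_children(L);
    // post-order over internal nodes
    postorder.clear();
    std::vector<int> stack;
    int root = -1;
    for (int v = 0; v < L.nnode; ++v) if (L.parent[v] < 0) root = v;
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v < L.ntip) continue;
      postorder.push_back(v);
      stack.push_back(kids1[v]);
      stack.push_back(kids2[v]);
    }
    std::reverse(postorder.begin(), postorder.end());

    int npat = L.npat;
    partial.assign((size_t)L.nnode * 4 * npat, 0.0);
    logscale.assign(npat, 0.0);
    int scnt = 0;
    for (int v : postorder) {
      double* pv = &partial[(size_t)v * 4 * npat];
      for (int j = 0; j < 4 * npat; ++j) pv[j] = 1.0;
      for (int c : {kids1[v], kids2[v]}) {
        double d = L.age[v] - L.age[c];
        double e = std::exp(-4.0 * d / 3.0);
        double psame = 0.25 + 0.75 * e, pdiff = 0.25 * (1.0 - e);
        if (c < L.ntip) {
          const int* st = &L.pat[(size_t)c * npat];
          for (int j = 0; j < npat; ++j) {
            int s = st[j];
            for (int a = 0; a < 4; ++a)
              pv[(size_t)a * npat + j] *= (a == s) ? psame : pdiff;
          }
        } else {
          const double* pc = &partial[(size_t)c * 4 * npat];
          for (int j = 0; j < npat; ++j) {
            double sum = pc[j] + pc[npat + j] + pc[2 * npat + j] + pc[3 * npat + j];
            for (int a = 0; a < 4; ++a) {
              double x = pc[(size_t)a * npat + j];
              pv[(size_t)a * npat + j] *= pdiff * (sum - x) + psame * x;
            }
          }
        }
      }
      if (++scnt % 4 == 0) {
        for (int j = 0; j < npat; ++j) {
          double m = pv[j];
          for (int a = 1; a < 4; ++a) m = std::max(m, pv[(size_t)a * npat + j]);
          if (m > 0 && m < 1e-6) {
            for (int a = 0; a < 4; ++a) pv[(size_t)a * npat + j] /= m;
            logscale[j] += std::log(m);
          }
        }
      }
    }
    const double* pr = &partial[(size_t)root * 4 * npat];
    double lnl = 0.0;
    for (int j = 0; j < npat; ++j) {
      double site = 0.25 * (pr[j] + pr[npat + j] + pr[2 * npat + j] + pr[3 * npat + j]);
      lnl += L.wt[j] * (std::log(site) + logscale[j]);
    }
    return lnl;
  }

  // ---- choice repair along one branch ----------------------------------

  // walk the branch above node v to its parent's age; reuse stored choices,
  // sample missing ones (log-prob into qf), drop obsolete ones (log-prob of
  // re-sampling them into qr). returns final pop, or -1 when the walk fails.
  int walk_repair(Locus& L, int v, double tend, double& qf, double& qr,
                  std::vector<char>& enc) {
    std::fill(enc.begin(), enc.end(), 0);
    int p = L.pop[v];
    double t = L.age[v];
    (void)t;
    int guard = 0;
    while (true) {
      if (++guard > 1000) return -1;
      double top = hi_age(p);
      if (tend <= top + TOL) break;
      const Pop& pp = pops[p];
      if (pp.trans == 1) {
        p = pp.to1;
      } else if (pp.trans == 2) {
        int h = pp.phi;
        enc[h] = 1;
        int8_t c = L.choice[(size_t)v * H + h];
        if (c < 0) {
          double ph = phi[h];
          c = (rng.unif() < ph) ? 1 : 0;
          qf += std::log(c ? ph : 1.0 - ph);
          L.choice[(size_t)v * H + h] = c;
        }
        p = c ? pp.to1 : pp.to2;
      } else {
        return -1;
      }
    }
    for (int h = 0; h < H; ++h) {
      int8_t c = L.choice[(size_t)v * H + h];
      if (c >= 0 && !enc[h]) {
        qr += std::log(c ? phi[h] : 1.0 - phi[h]);
        L.choice[(size_t)v * H + h] = -1;
      }
    }
    return p;
  }

  // ---- backups ---------------------------------------------------------

  void save(const Locus& L, Backup& b) {
    b.parent = L.parent; b.pop = L.pop; b.age = L.age; b.choice = L.choice;
    b.lnl = L.lnl; b.cstat = L.cstat; b.astat = L.astat; b.n1 = L.n1; b.n0 = L.n0;
  }
  void restore(Locus& L, const Backup& b) {
    L.parent = b.parent; L.pop = b.pop; L.age = b.age; L.choice = b.choice;
    L.lnl = b.lnl; L.cstat = b.cstat; L.astat = b.astat; L.n1 = b.n1; L.n0 = b.n0;
  }

  void aggregates_from_scratch() {
    Cagg.assign(P, 0); Aagg.assign(P, 0.0);
    N1agg.assign(H, 0); N0agg.assign(H, 0);
    for (auto& L : loci) {
      for (int p = 0; p < P; ++p) { Cagg[p] += L.cstat[p]; Aagg[p] += L.astat[p]; }
      for (int h = 0; h < H; ++h) { N1agg[h] += L.n1[h]; N0agg[h] += L.n0[h]; }
    }
  }
  void agg_sub(const Locus& L) {
    for (int p = 0; p < P; ++p) { Cagg[p] -= L.cstat[p]; Aagg[p] -= L.astat[p]; }
    for (int h = 0; h < H; ++h) { N1agg[h] -= L.n1[h]; N0agg[h] -= L.n0[h]; }
  }
  void agg_add(const Locus& L) {
    for (int p = 0; p < P; ++p) { Cagg[p] += L.cstat[p]; Aagg[p] += L.astat[p]; }
    for (int h = 0; h < H; ++h) { N1agg[h] += L.n1[h]; N0agg[h] += L.n0[h]; }
  }

  // ---- priors ----------------------------------------------------------

  double logprior_theta(int t, double x) const {
    return -(prior_a_theta + 1.0) * std::log(x) - prior_b_theta[t] / x;
  }
  double logprior_tau_root(double x) const {
    return -(prior_a_tau + 1.0) * std::log(x) - prior_b_tau / x
           - (double)n_other * std::log(x); // uniform-Dirichlet interior times
  }

  // ---- moves -----------------------------------------------------------

  // fold x into [lo, hi] by reflection (closed form; symmetric for any
  // excursion size)
  static double reflect(double x, double lo, double hi) {
    double w = hi - lo;
    if (w <= 0) return lo;
    double z = (x - lo) / (2 * w);
    double y = (z - std::floor(z)) * 2 * w;
    if (y > w) y = 2 * w - y;
    return lo + y;
  }

  void move_theta(int tix, int cls) {
    att[cls] += 1;
    double x = theta[tix];
    double y = x * std::exp(step_theta * (rng.unif() - 0.5));
    // coalescent factors touching this theta
    double dd = 0.0;
    for (int p = 0; p < P; ++p) {
      if (pops[p].theta != tix) continue;
      dd += Cagg[p] * (std::log(x) - std::log(y));       // log(2/theta) terms
      dd -= Aagg[p] * (1.0 / y - 1.0 / x);
    }
    double dp = logprior_theta(tix, y) - logprior_theta(tix, x);
    double lacc = dd + dp + std::log(y / x); // multiplier Jacobian
    if (std::log(rng.unif()) < lacc) { theta[tix] = y; acc[cls] += 1; }
  }

  void move_phi(int h, int cls) {
    att[cls] += 1;
    double x = phi[h];
    double y = reflect(x + step_phi * (rng.unif() - 0.5), 0.0, 1.0);
    if (y <= 0.0 || y >= 1.0) return;
    double dd = N1agg[h] * (std::log(y) - std::log(x)) +
                N0agg[h] * (std::log(1 - y) - std::log(1 - x));
    if (std::log(rng.unif()) < dd) { phi[h] = y; acc[cls] += 1; }
  }

  void move_tau(int j, int cls) {
    att[cls] += 1;
    double t0 = tau[j];
    double lb = 0.0, ub = POS_INF;
    for (int p = 0; p < P; ++p) {
      if (pops[p].hi_tau == j) lb = std::max(lb, lo_age(p));
      if (pops[p].lo_tau == j) ub = std::min(ub, hi_age(p));
    }
    double ts = t0 + step_tau[j] * (rng.unif() - 0.5);
    if (std::isfinite(ub)) {
      ts = reflect(ts, lb, ub);
    } else {
      while (ts < lb) ts = 2 * lb - ts;
    }
    if (ts <= lb || ts >= ub) return;

    double logJ = 0.0, dlnl = 0.0, ddens = 0.0;
    bool ok = true;
    for (int i = 0; i < nloci; ++i) save(loci[i], bks[i]);
    double tau_old = tau[j];
    for (int i = 0; i < nloci && ok; ++i) {
      Locus& L = loci[i];
      bool touched = false;
      for (int v = L.ntip; v < L.nnode; ++v) {
        int p = L.pop[v];
        if (pops[p].hi_tau == j) {
          double lo = lo_age(p);
          L.age[v] = lo + (L.age[v] - lo) * (ts - lo) / (t0 - lo);
          logJ += std::log((ts - lo) / (t0 - lo));
          touched = true;
        } else if (pops[p].lo_tau == j) {
          double hi = hi_age(p);
          if (std::isfinite(hi)) {
            L.age[v] = ts + (L.age[v] - t0) * (hi - ts) / (hi - t0);
            logJ += std::log((hi - ts) / (hi - t0));
          } else {
            L.age[v] = L.age[v] + (ts - t0);
          }
          touched = true;
        }
      }
      double dens_old = locus_logdens(L);
      tau[j] = ts;
      if (!compute_stats(L)) { ok = false; tau[j] = tau_old; break; }
      tau[j] = tau_old;
      // density under the *proposed* tau uses the same theta/phi
      double dens_new;
      { tau[j] = ts; dens_new = locus_logdens(L); tau[j] = tau_old; }
      ddens += dens_new - dens_old;
      if (touched) {
        double l0 = L.lnl;
        L.lnl = compute_lnl(L);
        dlnl += L.lnl - l0;
      }
    }
    double dp = 0.0;
    if (j == root_tau) dp = logprior_tau_root(ts) - logprior_tau_root(t0);
    double lacc = beta * dlnl + ddens + dp + logJ;
    if (ok && std::log(rng.unif()) < lacc) {
      tau[j] = ts;
      aggregates_from_scratch();
      acc[cls] += 1;
    } else {
      for (int i = 0; i < nloci; ++i) restore(loci[i], bks[i]);
    }
  }

  void move_scale(int cls) {
    att[cls] += 1;
    double c = std::exp(step_scale * (rng.unif() - 0.5));
    for (int i = 0; i < nloci; ++i) save(loci[i], bks[i]);
    std::vector<double> tau0 = tau, theta0 = theta;
    double dlnl = 0.0, ddens = 0.0, dp = 0.0;
    long nscaled = (long)K + T;
    for (int k = 0; k < K; ++k) tau[k] *= c;
    for (int t = 0; t < T; ++t) {
      dp += logprior_theta(t, theta[t] * c) - logprior_theta(t, theta[t]);
      theta[t] *= c;
    }
    dp += logprior_tau_root(tau[root_tau]) - logprior_tau_root(tau0[root_tau]);
    bool ok = true;
    for (int i = 0; i < nloci && ok; ++i) {
      Locus& L = loci[i];
      double dens_old;
      { std::swap(tau, tau0); std::swap(theta, theta0);
        dens_old = locus_logdens(L);
        std::swap(tau, tau0); std::swap(theta, theta0); }
      for (int v = L.ntip; v < L.nnode; ++v) L.age[v] *= c;
      nscaled += L.nnode - L.ntip;
      if (!compute_stats(L)) { ok = false; break; }
      ddens += locus_logdens(L) - dens_old;
      double l0 = L.lnl;
      L.lnl = compute_lnl(L);
      dlnl += L.lnl - l0;
    }
    double lacc = beta * dlnl + ddens + dp + nscaled * std::log(c);
    if (ok && std::log(rng.unif()) < lacc) {
      aggregates_from_scratch();
      acc[cls] += 1;
    } else {
      tau = tau0; theta = theta0;
      for (int i = 0; i < nloci; ++i) restore(loci[i], bks[i]);
    }
  }

  void move_age(int i, int v, int cls, std::vector<char>& enc) {
    att[cls] += 1;
    Locus& L = loci[i];
    build_children(L);
    double la = std::max(L.age[kids1[v]], L.age[kids2[v]]);
    int pa = L.parent[v];
    double t0 = L.age[v], ts, logJ = 0.0;
    if (pa >= 0) {
      double ua = L.age[pa];
      ts = reflect(t0 + step_age * (rng.unif() - 0.5), la, ua);
      if (ts <= la || ts >= ua) return;
    } else {
      ts = la + (t0 - la) * std::exp(step_age * 20 * (rng.unif() - 0.5));
      logJ = std::log((ts - la) / (t0 - la));
    }
    save(L, bk1);
    agg_sub(L);
    double dens_old = locus_logdens(L), lnl_old = L.lnl;
    L.age[v] = ts;
    double qf = 0.0, qr = 0.0;
    int p1 = walk_repair(L, kids1[v], ts, qf, qr, enc);
    int p2 = walk_repair(L, kids2[v], ts, qf, qr, enc);
    bool ok = (p1 >= 0 && p2 >= 0 && p1 == p2);
    if (ok) {
      L.pop[v] = p1;
      if (pa >= 0) {
        int pend = walk_repair(L, v, L.age[pa], qf, qr, enc);
        ok = (pend >= 0 && pend == L.pop[pa]);
      }
    }
    if (ok) ok = compute_stats(L);
    if (ok) {
      double ddens = locus_logdens(L) - dens_old;
      L.lnl = compute_lnl(L);
      double lacc = beta * (L.lnl - lnl_old) + ddens + logJ + qr - qf;
      if (std::log(rng.unif()) < lacc) { agg_add(L); acc[cls] += 1; return; }
    }
    restore(L, bk1);
    agg_add(L);
  }

  void move_exchange(int i, int cls, std::vector<char>& enc) {
    Locus& L = loci[i];
    int ninternal = L.nnode - L.ntip;
    if (ninternal < 2) return;
    att[cls] += 1;
    build_children(L);
    // v: internal non-root node
    int v;
    do { v = L.ntip + rng.randint(ninternal); } while (L.parent[v] < 0);
    int p = L.parent[v];
    int c = rng.unif() < 0.5 ? kids1[v] : kids2[v];
    int s = (kids1[p] == v) ? kids2[p] : kids1[p];
    if (L.age[s] >= L.age[v]) return; // s must fit beneath v
    save(L, bk1);
    agg_sub(L);
    double dens_old = locus_logdens(L), lnl_old = L.lnl;
    L.parent[c] = p;
    L.parent[s] = v;
    double qf = 0.0, qr = 0.0;
    int es = walk_repair(L, s, L.age[v], qf, qr, enc);
    int ec = walk_repair(L, c, L.age[p], qf, qr, enc);
    bool ok = (es == L.pop[v]) && (ec == L.pop[p]) && es >= 0 && ec >= 0;
    if (ok) ok = compute_stats(L);
    if (ok) {
      double ddens = locus_logdens(L) - dens_old;
      L.lnl = compute_lnl(L);
      double lacc = beta * (L.lnl - lnl_old) + ddens + qr - qf;
      if (std::log(rng.unif()) < lacc) { agg_add(L); acc[cls] += 1; return; }
    }
    restore(L, bk1);
    agg_add(L);
  }

  void move_flip(int i, int cls, std::vector<char>& enc) {
    if (H == 0) return;
    Locus& L = loci[i];
    // collect flippable (branch, hybrid) pairs
    std::vector<std::pair<int,int>> cand;
    for (int v = 0; v < L.nnode; ++v)
      for (int h = 0; h < H; ++h)
        if (L.choice[(size_t)v * H + h] >= 0) cand.push_back({v, h});
    if (cand.empty()) return;
    att[cls] += 1;
    int pick = rng.randint((int)cand.size());
    int v = cand[pick].first, h = cand[pick].second;
    save(L, bk1);
    agg_sub(L);
    double dens_old = locus_logdens(L);
    L.choice[(size_t)v * H + h] = 1 - L.choice[(size_t)v * H + h];
    double qf = 0.0, qr = 0.0;
    int pa = L.parent[v];
    bool ok = pa >= 0;
    if (ok) {
      int pend = walk_repair(L, v, L.age[pa], qf, qr, enc);
      ok = (pend >= 0 && pend == L.pop[pa]);
    }
    if (ok) ok = compute_stats(L);
    if (ok) {
      int nnew = 0;
      for (int w = 0; w < L.nnode; ++w)
        for (int g = 0; g < H; ++g)
          if (L.choice[(size_t)w * H + g] >= 0) ++nnew;
      double ddens = locus_logdens(L) - dens_old;
      // ages unchanged: likelihood unchanged
      double lacc = ddens + qr - qf +
        std::log((double)cand.size()) - std::log((double)nnew);
      if (std::log(rng.unif()) < lacc) { agg_add(L); acc[cls] += 1; return; }
    }
    restore(L, bk1);
    agg_add(L);
  }

  // ---- audit -----------------------------------------------------------

  double audit() {
    double worst = 0.0;
    for (auto& L : loci) {
      Locus tmp = L;
      if (!compute_stats(tmp)) return R_PosInf;
      for (int p = 0; p < P; ++p) {
        worst = std::max(worst, std::fabs(tmp.astat[p] - L.astat[p]));
        worst = std::max(worst, (double)std::abs(tmp.cstat[p] - L.cstat[p]));
      }
      double l = compute_lnl(tmp);
      worst = std::max(worst, std::fabs(l - L.lnl));
    }
    return worst;
  }
};

static void sampler_setup(Sampler& S, List& engine, List& loci_in) {
  IntegerVector lo_tau = engine["lo_tau"], hi_tau = engine["hi_tau"],
    theta_ix = engine["theta_ix"], trans = engine["trans"],
    to1 = engine["to1"], to2 = engine["to2"], phi_ix = engine["phi_ix"];
  S.P = lo_tau.size();
  S.pops.resize(S.P);
  for (int p = 0; p < S.P; ++p) {
    S.pops[p] = {lo_tau[p], hi_tau[p], theta_ix[p], trans[p], to1[p], to2[p],
                 phi_ix[p]};
  }
  S.tau = as<std::vector<double>>(engine["tau"]);
  S.theta = as<std::vector<double>>(engine["theta"]);
  S.phi = as<std::vector<double>>(engine["phi"]);
  S.K = (int)S.tau.size();
  S.T = (int)S.theta.size();
  S.H = (int)S.phi.size();
  S.root_tau = as<int>(engine["root_tau"]);
  S.n_other = as<int>(engine["n_other"]);
  S.prior_a_theta = as<double>(engine["prior_a_theta"]);
  S.prior_b_theta = as<std::vector<double>>(engine["prior_b_theta"]);
  S.prior_a_tau = as<double>(engine["prior_a_tau"]);
  S.prior_b_tau = as<double>(engine["prior_b_tau"]);

  S.nloci = loci_in.size();
  S.loci.resize(S.nloci);
  for (int i = 0; i < S.nloci; ++i) {
    List li = loci_in[i];
    Locus& L = S.loci[i];
    IntegerMatrix pat = li["pat"];
    L.ntip = pat.nrow();
    L.npat = pat.ncol();
    L.pat.resize((size_t)L.ntip * L.npat);
    for (int r = 0; r < L.ntip; ++r)
      for (int j = 0; j < L.npat; ++j) L.pat[(size_t)r * L.npat + j] = pat(r, j);
    L.wt = as<std::vector<double>>(li["wt"]);
    L.parent = as<std::vector<int>>(li["parent"]);
    L.age = as<std::vector<double>>(li["age"]);
    L.pop = as<std::vector<int>>(li["pop"]);
    L.nnode = (int)L.parent.size();
    IntegerMatrix ch = li["choice"];
    L.choice.assign((size_t)L.nnode * std::max(S.H, 1), -1);
    if (S.H > 0) {
      for (int v = 0; v < L.nnode; ++v)
        for (int h = 0; h < S.H; ++h)
          L.choice[(size_t)v * S.H + h] = (int8_t)ch(v, h);
    }
    L.cstat.assign(S.P, 0);
    L.astat.assign(S.P, 0.0);
    L.n1.assign(std::max(S.H, 1), 0);
    L.n0.assign(std::max(S.H, 1), 0);
    if (!S.compute_stats(L)) stop("initial gene tree %d is invalid", i + 1);
    L.lnl = S.compute_lnl(L);
  }
  S.aggregates_from_scratch();
  S.bks.resize(S.nloci);
}

// Evaluate the JC69 pruning log-likelihood and coalescent log-density of a
// fixed state (no sampling); used to cross-check the compiled core against
// the reference R implementations.
// [[Rcpp::export]]
List eval_state_cpp(List engine, List loci_in) {
  Sampler S(1);
  S.beta = 1.0;
  S.lik_on = true;
  sampler_setup(S, engine, loci_in);
  NumericVector lnl(S.nloci), dens(S.nloci);
  for (int i = 0; i < S.nloci; ++i) {
    lnl[i] = S.loci[i].lnl;
    dens[i] = S.locus_logdens(S.loci[i]);
  }
  return List::create(_["lnl"] = lnl, _["logdens"] = dens);
}

// [[Rcpp::export]]
List run_mcmc_cpp(List engine, List loci_in, List cfg) {
  Sampler S((uint64_t)as<double>(cfg["seed"]));
  S.beta = as<double>(cfg["beta"]);
  S.lik_on = as<bool>(cfg["likelihood"]);
  sampler_setup(S, engine, loci_in);

  int burnin = as<int>(cfg["burnin"]);
  int nsamples = as<int>(cfg["nsamples"]);
  int thin = as<int>(cfg["thin"]);
  bool tune = as<bool>(cfg["tune"]);
  int nexch = as<int>(cfg["nexch"]);

  S.step_tau.assign(S.K, 0.0);
  for (int k = 0; k < S.K; ++k) S.step_tau[k] = std::max(S.tau[k] * 0.3, 1e-6);
  S.step_theta = 0.5;
  S.step_phi = 0.3;
  S.step_age = 0.0;
  for (int k = 0; k < S.K; ++k) S.step_age = std::max(S.step_age, S.tau[k]);
  S.step_age *= 0.2;
  if (S.step_age <= 0) S.step_age = 0.01;
  S.step_scale = 0.2;
  // move classes: 0 theta, 1 phi, 2..2+K-1 tau, then scale, age, exch, flip
  int ntauc = S.K;
  int cls_theta = 0, cls_phi = 1, cls_tau0 = 2, cls_scale = 2 + ntauc,
      cls_age = 3 + ntauc, cls_exch = 4 + ntauc, cls_flip = 5 + ntauc;
  int ncls = 6 + ntauc;
  S.acc.assign(ncls, 0.0);
  S.att.assign(ncls, 0.0);

  int ncol = S.K + S.T + S.H + 2;
  NumericMatrix out(nsamples, ncol);
  std::vector<char> enc(std::max(S.H, 1), 0);

  int total_sweeps = burnin + nsamples * thin;
  int rec = 0;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int k = 0; k < S.K; ++k) S.move_tau(k, cls_tau0 + k);
    S.move_scale(cls_scale);
    for (int t = 0; t < S.T; ++t) S.move_theta(t, cls_theta);
    for (int h = 0; h < S.H; ++h) S.move_phi(h, cls_phi);
    for (int i = 0; i < S.nloci; ++i) {
      Locus& L = S.loci[i];
      for (int v = L.ntip; v < L.nnode; ++v) S.move_age(i, v, cls_age, enc);
      for (int e = 0; e < nexch; ++e) S.move_exchange(i, cls_exch, enc);
      if (S.H) S.move_flip(i, cls_flip, enc);
    }
    // burn-in step-size tuning toward ~30% acceptance
    if (tune && sweep < burnin && (sweep + 1) % 50 == 0) {
      auto adapt = [&](double& stepv, int cls) {
        if (S.att[cls] < 1) return;
        double r = S.acc[cls] / S.att[cls];
        stepv *= std::exp(0.8 * (r - 0.3));
        stepv = std::min(std::max(stepv, 1e-9), 1e3);
        S.acc[cls] = S.att[cls] = 0.0;
      };
      adapt(S.step_theta, cls_theta);
      adapt(S.step_phi, cls_phi);
      for (int k = 0; k < S.K; ++k) adapt(S.step_tau[k], cls_tau0 + k);
      adapt(S.step_scale, cls_scale);
      adapt(S.step_age, cls_age);
    }
    if (sweep == burnin - 1) {
      std::fill(S.acc.begin(), S.acc.end(), 0.0);
      std::fill(S.att.begin(), S.att.end(), 0.0);
    }
    if (sweep >= burnin && (sweep - burnin + 1) % thin == 0 && rec < nsamples) {
      int col = 0;
      for (int k = 0; k < S.K; ++k) out(rec, col++) = S.tau[k];
      for (int t = 0; t < S.T; ++t) out(rec, col++) = S.theta[t];
      for (int h = 0; h < S.H; ++h) out(rec, col++) = S.phi[h];
      double lnl = 0.0, dens = 0.0;
      for (auto& L : S.loci) { lnl += L.lnl; dens += S.locus_logdens(L); }
      out(rec, col++) = lnl;
      out(rec, col++) = dens;
      ++rec;
    }
    if (sweep % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector accrate(ncls);
  for (int c = 0; c < ncls; ++c)
    accrate[c] = S.att[c] > 0 ? S.acc[c] / S.att[c] : NA_REAL;
  return List::create(
    _["samples"] = out,
    _["acc"] = accrate,
    _["audit"] = S.audit(),
    _["step_age"] = S.step_age
  );
}
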