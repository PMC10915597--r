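// Structured-coalescent simulator for three-population demographic models
// with population splits, pulse admixture, size changes, exponential growth
// and bottlenecks. Time runs backward from the present in generations.
//
// All randomness comes from a locally seeded mt19937_64 with explicit
// inverse-CDF transforms, so a (model, parameters, seed) triple is
// bit-reproducible and independent of R's global RNG state. That property
// is what makes common-random-numbers optimization of the Monte-Carlo
// likelihood possible.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// Event type codes shared with the R layer (see R/events.R)
enum EventType { EV_SPLIT = 1, EV_PULSE = 2, EV_SIZE = 3, EV_GROWTH = 4,
                 EV_BOTTLENECK = 5 };

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform on [0, 1): 53-bit mantissa, exactly reproducible
  double unif() {
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  double expo() { return -std::log(1.0 - unif()); }
  int unif_int(int n) {  // 0 .. n-1
    return (int)(unif() * n) % n;
  }
  int poisson(double mean) {
    // Knuth's method, chunked so exp(-mean) never underflows
    int total = 0;
    while (mean > 30.0) {
      total += poisson(30.0);
      mean -= 30.0;
    }
    double L = std::exp(-mean), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return total + k - 1;
  }
};

struct PopState {
  double ne_ref;   // diploid Ne at t_ref
  double t_ref;    // generations before present
  double growth;   // forward-time exponential rate; backward Ne shrinks as
                   // Ne(t) = ne_ref * exp(-growth * (t - t_ref))
  double ne_at(double t) const {
    if (growth == 0.0) return ne_ref;
    return ne_ref * std::exp(-growth * (t - t_ref));
  }
};

struct Lineage {
  int pop;
  int cfg[3];        // subtended leaves per leaf population
  uint64_t mask;     // subtended-leaf bitmask (<= 60 leaves total)
  double birth;      // time the lineage came into existence
};

struct Branch { uint64_t mask; int cfg[3]; double len; };

struct CoalRecord { int child1, child2, node; double time; };

// Waiting time to the next coalescence among k lineages in pop `ps`,
// starting at time t. Returns +Inf when growth makes the event unreachable.
double draw_coal_time(const PopState& ps, int k, double t, Rng& rng) {
  if (k < 2) return R_PosInf;
  double E = rng.expo();
  double C = (double)k * (k - 1) / (4.0 * ps.ne_ref);
  if (ps.growth == 0.0) return t + E / C;
  double g = ps.growth;
  double base = std::exp(g * (t - ps.t_ref));
  double rhs = base + g * E / C;
  if (rhs <= 0.0) return R_PosInf;
  return ps.t_ref + std::log(rhs) / g;
}

class Simulator {
public:
  int npop;
  std::vector<PopState> pops;
  NumericMatrix events;  // columns: time, type, a, b, value (sorted by time)
  std::vector<int> nsam; // haploid samples per population
  int ntot;

  Simulator(int npop_, NumericVector ne0, NumericVector g0,
            NumericMatrix events_, IntegerVector nsam_)
      : npop(npop_), events(events_) {
    pops.resize(npop);
    for (int p = 0; p < npop; ++p) {
      pops[p].ne_ref = ne0[p];
      pops[p].t_ref = 0.0;
      pops[p].growth = g0[p];
    }
    nsam.assign(nsam_.begin(), nsam_.end());
    ntot = 0;
    for (int p = 0; p < npop; ++p) ntot += nsam[p];
    if (ntot > 60) stop("total haploid sample size must be <= 60");
  }

  // One replicate. Collects per-branch (mask, cfg, length) into `branches`;
  // optionally records the coalescence history into `records`.
  double run(Rng& rng, std::vector<Branch>& branches,
             std::vector<CoalRecord>* records) {
    std::vector<PopState> ps(pops);
    std::vector<Lineage> lin;
    lin.reserve(ntot);
    int leaf = 0;
    for (int p = 0; p < npop; ++p) {
      for (int i = 0; i < nsam[p]; ++i) {
        Lineage L;
        L.pop = p;
        L.cfg[0] = L.cfg[1] = L.cfg[2] = 0;
        if (p < 3) L.cfg[p] = 1;
        L.mask = (uint64_t)1 << leaf;
        L.birth = 0.0;
        lin.push_back(L);
        ++leaf;
      }
    }
    std::vector<int> node_id;  // tree-node bookkeeping for records
    if (records) {
      node_id.resize(ntot);
      for (int i = 0; i < ntot; ++i) node_id[i] = i + 1;  // 1-based tips
    }
    int next_node = ntot + 1;

    double t = 0.0;
    int ev = 0;
    int nev = events.nrow();
    std::vector<int> count(npop);

    while ((int)lin.size() > 1) {
      std::fill(count.begin(), count.end(), 0);
      for (auto& L : lin) count[L.pop]++;
      double tmin = R_PosInf;
      int popmin = -1;
      for (int p = 0; p < npop; ++p) {
        double tc = draw_coal_time(ps[p], count[p], t, rng);
        if (tc < tmin) { tmin = tc; popmin = p; }
      }
      double tev = (ev < nev) ? events(ev, 0) : R_PosInf;

      if (tmin <= tev) {
        if (!R_finite(tmin)) stop("lineages cannot coalesce: stranded populations with no remaining events");
        // coalesce a random pair in popmin at tmin
        int k = count[popmin];
        int a = rng.unif_int(k), b = rng.unif_int(k - 1);
        if (b >= a) ++b;
        // map within-pop indices to lineage indices
        int ia = -1, ib = -1, seen = 0;
        for (int i = 0; i < (int)lin.size(); ++i) {
          if (lin[i].pop == popmin) {
            if (seen == a) ia = i;
            if (seen == b) ib = i;
            ++seen;
          }
        }
        // close the two child branches
        Branch bra{lin[ia].mask, {lin[ia].cfg[0], lin[ia].cfg[1], lin[ia].cfg[2]}, tmin - lin[ia].birth};
        Branch brb{lin[ib].mask, {lin[ib].cfg[0], lin[ib].cfg[1], lin[ib].cfg[2]}, tmin - lin[ib].birth};
        branches.push_back(bra);
        branches.push_back(brb);
        if (records) {
          CoalRecord r{node_id[ia], node_id[ib], next_node, tmin};
          records->push_back(r);
          node_id[ia] = next_node;
          ++next_node;
        }
        lin[ia].mask |= lin[ib].mask;
        lin[ia].cfg[0] += lin[ib].cfg[0];
        lin[ia].cfg[1] += lin[ib].cfg[1];
        lin[ia].cfg[2] += lin[ib].cfg[2];
        lin[ia].birth = tmin;
        lin.erase(lin.begin() + ib);
        if (records) node_id.erase(node_id.begin() + ib);
        t = tmin;
      } else {
        if (!R_finite(tev)) stop("lineages cannot coalesce: stranded populations with no remaining events");
        t = tev;
        int type = (int)events(ev, 1);
        int a = (int)events(ev, 2);
        int b = (int)events(ev, 3);
        double val = events(ev, 4);
        switch (type) {
          case EV_SPLIT:  // all lineages in child a move to parent b
            for (auto& L : lin) if (L.pop == a) L.pop = b;
            break;
          case EV_PULSE:  // forward a -> b; backward each lineage in b moves
                          // to a independently with probability val.
                          // p = 0 is a no-op and p = 1 a forced move; neither
                          // consumes random numbers, so adding such a pulse
                          // leaves a common-random-numbers run unchanged.
            if (val >= 1.0) {
              for (auto& L : lin) if (L.pop == b) L.pop = a;
            } else if (val > 0.0) {
              for (auto& L : lin)
                if (L.pop == b && rng.unif() < val) L.pop = a;
            }
            break;
          case EV_SIZE:
            ps[a].ne_ref = val; ps[a].t_ref = t; ps[a].growth = 0.0;
            break;
          case EV_GROWTH: {
            double cur = ps[a].ne_at(t);
            ps[a].ne_ref = cur; ps[a].t_ref = t; ps[a].growth = val;
            break;
          }
          case EV_BOTTLENECK: {
            double cur = ps[a].ne_at(t);
            ps[a].ne_ref = cur * val; ps[a].t_ref = t; ps[a].growth = 0.0;
            break;
          }
          default:
            stop("unknown event type code");
        }
        ++ev;
      }
    }
    return t;  // TMRCA
  }
};

inline int cell_index(const int cfg[3], int nA, int nB, int nC) {
  return cfg[0] + (nA + 1) * (cfg[1] + (nB + 1) * cfg[2]);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_expected_sfs")]]
List cpp_expected_sfs(int npop, NumericVector ne0, NumericVector g0,
                      NumericMatrix events, IntegerVector nsam,
                      int n_reps, double seed) {
  Simulator sim(npop, ne0, g0, events, nsam);
  int nA = nsam.size() > 0 ? nsam[0] : 0;
  int nB = nsam.size() > 1 ? nsam[1] : 0;
  int nC = nsam.size() > 2 ? nsam[2] : 0;
  int ncell = (nA + 1) * (nB + 1) * (nC + 1);
  NumericVector total(ncell), totsq(ncell);
  NumericVector tmrca(n_reps), treelen(n_reps);
  std::vector<double> repcell(ncell, 0.0);
  std::vector<int> touched;
  Rng rng((uint64_t)seed);
  std::vector<Branch> branches;
  for (int r = 0; r < n_reps; ++r) {
    branches.clear();
    touched.clear();
    tmrca[r] = sim.run(rng, branches, nullptr);
    double tl = 0.0;
    for (auto& b : branches) {
      tl += b.len;
      int idx = cell_index(b.cfg, nA, nB, nC);
      if (repcell[idx] == 0.0) touched.push_back(idx);
      repcell[idx] += b.len;
    }
    treelen[r] = tl;
    for (int idx : touched) {
      total[idx] += repcell[idx];
      totsq[idx] += repcell[idx] * repcell[idx];
      repcell[idx] = 0.0;
    }
  }
  return List::create(_["total"] = total, _["totsq"] = totsq,
                      _["tmrca"] = tmrca, _["treelen"] = treelen);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_simulate_snps")]]
IntegerMatrix cpp_simulate_snps(int npop, NumericVector ne0, NumericVector g0,
                                NumericMatrix events, IntegerVector nsam,
                                int n_loci, double seed) {
  Simulator sim(npop, ne0, g0, events, nsam);
  IntegerMatrix out(n_loci, sim.ntot);
  Rng rng((uint64_t)seed);
  std::vector<Branch> branches;
  for (int l = 0; l < n_loci; ++l) {
    branches.clear();
    sim.run(rng, branches, nullptr);
    double tl = 0.0;
    for (auto& b : branches) tl += b.len;
    // one segregating site per locus: branch chosen proportional to length
    double u = rng.unif() * tl, acc = 0.0;
    uint64_t mask = branches.back().mask;
    for (auto& b : branches) {
      acc += b.len;
      if (u <= acc) { mask = b.mask; break; }
    }
    for (int i = 0; i < sim.ntot; ++i)
      out(l, i) = (mask >> i) & 1 ? 1 : 0;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_simulate_infsites")]]
List cpp_simulate_infsites(int npop, NumericVector ne0, NumericVector g0,
                           NumericMatrix events, IntegerVector nsam,
                           int n_reps, double locus_mu, double seed) {
  // infinite-sites mutations: Poisson(locus_mu * branch length) per branch,
  // locus_mu = per-generation mutation rate for the whole locus
  Simulator sim(npop, ne0, g0, events, nsam);
  Rng rng((uint64_t)seed);
  List out(n_reps);
  std::vector<Branch> branches;
  for (int r = 0; r < n_reps; ++r) {
    branches.clear();
    sim.run(rng, branches, nullptr);
    std::vector<uint64_t> sites;
    for (auto& b : branches) {
      int nm = rng.poisson(locus_mu * b.len);
      for (int m = 0; m < nm; ++m) sites.push_back(b.mask);
    }
    IntegerMatrix mat(sim.ntot, (int)sites.size());
    for (int s = 0; s < (int)sites.size(); ++s)
      for (int i = 0; i < sim.ntot; ++i)
        mat(i, s) = (sites[s] >> i) & 1 ? 1 : 0;
    out[r] = mat;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_simulate_genealogy")]]
List cpp_simulate_genealogy(int npop, NumericVector ne0, NumericVector g0,
                            NumericMatrix events, IntegerVector nsam,
                            double seed) {
  Simulator sim(npop, ne0, g0, events, nsam);
  Rng rng((uint64_t)seed);
  std::vector<Branch> branches;
  std::vector<CoalRecord> records;
  double tmrca = sim.run(rng, branches, &records);
  int nrec = (int)records.size();
  IntegerMatrix merges(nrec, 3);
  NumericVector times(nrec);
  for (int i = 0; i < nrec; ++i) {
    merges(i, 0) = records[i].child1;
    merges(i, 1) = records[i].child2;
    merges(i, 2) = records[i].node;
    times[i] = records[i].time;
  }
  return List::create(_["merges"] = merges, _["times"] = times,
                      _["tmrca"] = tmrca, _["n_tips"] = sim.ntot);
}
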