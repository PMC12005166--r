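// Discrete-generation Wright-Fisher forward simulator with selection,
// linkage, piecewise-constant mutation/recombination maps, multi-population
// demography (size trajectories, founder events, migration epochs), a
// discrete DFE acting on exonic bases, fixation accounting for divergence,
// and conditioned single sweeps with restart-from-introduction semantics.
//
// All demographic semantics (event compilation, scaling) live on the R side;
// this engine consumes explicit per-generation size trajectories.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Mut {
  double pos;
  double sel;   // signed selection coefficient: <0 deleterious, >0 beneficial
  double h;     // dominance
  int element;  // 0 intergenic, 1 intron, 2 exon
  int gen;      // absolute generation of origin (burn-in counts from 0)
};

typedef std::vector<int> Hap;  // mutation ids, sorted by position

struct PiecewiseMap {
  std::vector<double> start, end, rate, cum;  // cum[i] = mass before piece i
  double total = 0.0;

  void init(const NumericMatrix& m) {
    int k = m.nrow();
    start.resize(k); end.resize(k); rate.resize(k); cum.resize(k + 1);
    cum[0] = 0.0;
    for (int i = 0; i < k; ++i) {
      start[i] = m(i, 0);
      end[i] = m(i, 1);
      rate[i] = m(i, 2);
      cum[i + 1] = cum[i] + rate[i] * (end[i] - start[i]);
    }
    total = cum[k];
  }

  // inverse CDF: map u in [0, total) to a position
  double sample_pos(double u) const {
    int k = (int)rate.size();
    int lo = 0, hi = k;
    while (lo + 1 < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] <= u) lo = mid; else hi = mid;
    }
    double within = (u - cum[lo]) / std::max(rate[lo], 1e-300);
    return start[lo] + within;
  }
};

struct Engine {
  std::mt19937_64 rng;
  std::vector<Mut> muts;
  std::vector<std::vector<Hap>> pops;  // pops[p] holds 2N haplotypes
  PiecewiseMap mu_map, rec_map;
  double L;

  // elements as sorted [start,end,type]
  std::vector<double> el_start, el_end;
  std::vector<int> el_type;

  // DFE
  std::vector<double> dfe_f, dfe_lo, dfe_hi, dfe_sign;
  double dfe_nref = 0, dfe_h = 0.5;
  bool has_dfe = false;
  std::discrete_distribution<int> dfe_class;

  // fixation log
  std::vector<double> fix_pos, fix_sel;
  std::vector<int> fix_gen, fix_el;

  int sweep_id = -1;
  bool sweep_globally_fixed = false;

  int element_at(double pos) const {
    if (el_start.empty()) return 0;
    int lo = 0, hi = (int)el_start.size();
    while (lo + 1 < hi) {
      int mid = (lo + hi) / 2;
      if (el_start[mid] <= pos) lo = mid; else hi = mid;
    }
    return (pos >= el_start[lo] && pos < el_end[lo]) ? el_type[lo] : 0;
  }

  double runif01() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
  }

  int new_mutation(double pos, int gen) {
    Mut m;
    m.pos = pos;
    m.element = element_at(pos);
    m.gen = gen;
    m.sel = 0.0;
    m.h = 0.5;
    if (has_dfe && m.element == 2) {
      int cls = dfe_class(rng);
      double two_ns = dfe_lo[cls] +
        runif01() * (dfe_hi[cls] - dfe_lo[cls]);
      double s = two_ns / (2.0 * dfe_nref);
      if (s > 1.0) s = 1.0;  // cap at lethal
      m.sel = dfe_sign[cls] * s;
      m.h = dfe_h;
    }
    muts.push_back(m);
    return (int)muts.size() - 1;
  }

  double fitness(const Hap& a, const Hap& b) const {
    double w = 1.0;
    size_t i = 0, j = 0;
    while (i < a.size() || j < b.size()) {
      if (i < a.size() && j < b.size() && a[i] == b[j]) {
        w *= std::max(0.0, 1.0 + muts[a[i]].sel);
        ++i; ++j;
      } else {
        bool take_a;
        if (i >= a.size()) take_a = false;
        else if (j >= b.size()) take_a = true;
        else {
          const Mut& ma = muts[a[i]];
          const Mut& mb = muts[b[j]];
          take_a = (ma.pos < mb.pos) || (ma.pos == mb.pos && a[i] < b[j]);
        }
        int id = take_a ? a[i++] : b[j++];
        w *= std::max(0.0, 1.0 + muts[id].h * muts[id].sel);
      }
    }
    return w;
  }

  // meiosis: recombine parent's two haplotypes, add new mutations
  Hap gamete(const Hap& a, const Hap& b, int gen) {
    Hap child;
    int n_co = (rec_map.total > 0)
      ? std::poisson_distribution<int>(rec_map.total)(rng) : 0;
    bool start_a = std::uniform_int_distribution<int>(0, 1)(rng) == 0;
    if (n_co == 0) {
      child = start_a ? a : b;
    } else {
      std::vector<double> bp(n_co);
      for (int i = 0; i < n_co; ++i) {
        bp[i] = rec_map.sample_pos(runif01() * rec_map.total);
      }
      std::sort(bp.begin(), bp.end());
      child.reserve(a.size() + b.size());
      size_t i = 0, j = 0;
      auto from_a = [&](double pos) {
        size_t seg = std::upper_bound(bp.begin(), bp.end(), pos) - bp.begin();
        return ((seg % 2 == 0) == start_a);
      };
      // merge by position, keeping each mutation iff its segment matches
      while (i < a.size() || j < b.size()) {
        bool take_a;
        if (i >= a.size()) take_a = false;
        else if (j >= b.size()) take_a = true;
        else if (a[i] == b[j]) {  // present on both: keep regardless
          child.push_back(a[i]);
          ++i; ++j;
          continue;
        } else {
          const Mut& ma = muts[a[i]];
          const Mut& mb = muts[b[j]];
          take_a = (ma.pos < mb.pos) || (ma.pos == mb.pos && a[i] < b[j]);
        }
        if (take_a) {
          if (from_a(muts[a[i]].pos)) child.push_back(a[i]);
          ++i;
        } else {
          if (!from_a(muts[b[j]].pos)) child.push_back(b[j]);
          ++j;
        }
      }
    }
    if (mu_map.total > 0) {
      int n_mut = std::poisson_distribution<int>(mu_map.total)(rng);
      for (int k = 0; k < n_mut; ++k) {
        double pos = mu_map.sample_pos(runif01() * mu_map.total);
        int id = new_mutation(pos, gen);
        auto cmp = [this](int x, int y) {
          return muts[x].pos < muts[y].pos ||
                 (muts[x].pos == muts[y].pos && x < y);
        };
        child.insert(std::lower_bound(child.begin(), child.end(), id, cmp), id);
      }
    }
    return child;
  }

  // remove globally fixed mutations from all haplotypes, log them
  void sweep_fixed(int gen, int burn_in) {
    long total = 0;
    for (auto& pp : pops) total += (long)pp.size();
    if (total == 0) return;
    std::unordered_map<int, long> counts;
    for (auto& pp : pops)
      for (auto& h : pp)
        for (int id : h) ++counts[id];
    std::vector<char> fixed(muts.size(), 0);
    bool any = false;
    for (auto& kv : counts) {
      if (kv.second == total) {
        fixed[kv.first] = 1;
        any = true;
        fix_gen.push_back(gen - burn_in);  // negative while still in burn-in
        fix_pos.push_back(muts[kv.first].pos);
        fix_sel.push_back(muts[kv.first].sel);
        fix_el.push_back(muts[kv.first].element);
        if (kv.first == sweep_id) sweep_globally_fixed = true;
      }
    }
    if (!any) return;
    for (auto& pp : pops)
      for (auto& h : pp) {
        h.erase(std::remove_if(h.begin(), h.end(),
                               [&](int id) { return fixed[id]; }),
                h.end());
      }
  }

  long count_in_pop(int id, int p) const {
    long c = 0;
    for (const auto& h : pops[p])
      c += std::count(h.begin(), h.end(), id);
    return c;
  }

  long count_total(int id) const {
    long c = 0;
    for (size_t p = 0; p < pops.size(); ++p) c += count_in_pop(id, (int)p);
    return c;
  }
};

}  // namespace

// [[Rcpp::export(name = ".wf_simulate")]]
List wf_simulate(List cfg) {
  Engine E;
  E.rng.seed((uint64_t)as<double>(cfg["seed"]));
  E.L = as<double>(cfg["L"]);
  E.mu_map.init(as<NumericMatrix>(cfg["mu_map"]));
  E.rec_map.init(as<NumericMatrix>(cfg["rec_map"]));

  NumericMatrix elements = cfg["elements"];
  for (int i = 0; i < elements.nrow(); ++i) {
    E.el_start.push_back(elements(i, 0));
    E.el_end.push_back(elements(i, 1));
    E.el_type.push_back((int)elements(i, 2));
  }

  if (cfg.containsElementNamed("dfe") && !Rf_isNull(cfg["dfe"])) {
    List dfe = cfg["dfe"];
    E.dfe_f = as<std::vector<double>>(dfe["f"]);
    E.dfe_lo = as<std::vector<double>>(dfe["lo"]);
    E.dfe_hi = as<std::vector<double>>(dfe["hi"]);
    E.dfe_sign = as<std::vector<double>>(dfe["sign"]);
    E.dfe_nref = as<double>(dfe["n_ref"]);
    E.dfe_h = as<double>(dfe["h"]);
    E.dfe_class = std::discrete_distribution<int>(E.dfe_f.begin(), E.dfe_f.end());
    E.has_dfe = true;
  }

  IntegerMatrix sizes = cfg["sizes"];  // (span+1) x n_pops
  int span = sizes.nrow() - 1;
  int n_pops = sizes.ncol();
  IntegerVector founder_src = cfg["founder_src"];  // -1 for root
  IntegerVector founder_gen = cfg["founder_gen"];  // post-burn-in g, -1 root
  List mig_mats = cfg["mig_mats"];
  IntegerVector mig_index = cfg["mig_index"];  // length span, 0-based or -1
  int burn_in = as<int>(cfg["burn_in"]);
  int fix_interval = as<int>(cfg["fix_interval"]);
  IntegerVector sample_sizes = cfg["sample_sizes"];

  bool have_sweep = cfg.containsElementNamed("sweep") && !Rf_isNull(cfg["sweep"]);
  int sweep_gen = -1, sweep_pop = -1, max_restarts = 0;
  double sweep_pos = 0, sweep_s = 0, sweep_h = 0.5;
  std::vector<int> cond_pops;
  if (have_sweep) {
    List sw = cfg["sweep"];
    sweep_gen = as<int>(sw["gen"]);
    sweep_pop = as<int>(sw["pop"]);
    sweep_pos = as<double>(sw["pos"]);
    sweep_s = as<double>(sw["s"]);
    sweep_h = as<double>(sw["h"]);
    cond_pops = as<std::vector<int>>(sw["condition_pops"]);
    max_restarts = as<int>(sw["max_restarts"]);
  }

  // ---- burn-in: single root population (index 0) at its g=0 size ----
  int N0 = sizes(0, 0);
  E.pops.assign(n_pops, {});
  E.pops[0].assign(2 * N0, Hap());

  auto step_pop = [&](int gen_abs, const std::vector<std::vector<Hap>>& prev,
                      const std::vector<std::discrete_distribution<int>*>& dists,
                      int target_pop, int new_size, const double* mig_row,
                      std::vector<Hap>& out) {
    out.clear();
    out.reserve(2 * new_size);
    std::uniform_real_distribution<double> U(0.0, 1.0);
    for (int i = 0; i < new_size; ++i) {
      int src = target_pop;
      if (mig_row) {
        double u = U(E.rng);
        double acc = 0.0;
        for (int q = 0; q < n_pops; ++q) {
          if (q == target_pop) continue;
          acc += mig_row[q];
          if (u < acc && !prev[q].empty()) { src = q; break; }
        }
      }
      if (prev[src].empty()) src = target_pop;
      std::discrete_distribution<int>& dist = *dists[src];
      int p1 = dist(E.rng);
      int p2 = dist(E.rng);
      out.push_back(E.gamete(prev[src][2 * p1], prev[src][2 * p1 + 1], gen_abs));
      out.push_back(E.gamete(prev[src][2 * p2], prev[src][2 * p2 + 1], gen_abs));
    }
  };

  auto advance = [&](int gen_abs, int g_next) {
    // g_next: post-burn-in generation index being created (<=0 during burn-in
    // means stay in root-only mode at size N0)
    std::vector<std::vector<Hap>> prev = std::move(E.pops);
    E.pops.assign(n_pops, {});

    // fitness distributions for all existing source pops
    std::vector<std::vector<double>> w(n_pops);
    std::vector<std::discrete_distribution<int>> dists(n_pops);
    for (int p = 0; p < n_pops; ++p) {
      int np = (int)prev[p].size() / 2;
      if (np == 0) continue;
      w[p].resize(np);
      bool all_zero = true;
      for (int i = 0; i < np; ++i) {
        w[p][i] = E.fitness(prev[p][2 * i], prev[p][2 * i + 1]);
        if (w[p][i] > 0) all_zero = false;
      }
      if (all_zero) std::fill(w[p].begin(), w[p].end(), 1.0);
      dists[p] = std::discrete_distribution<int>(w[p].begin(), w[p].end());
    }
    std::vector<std::discrete_distribution<int>*> dptr(n_pops);
    for (int p = 0; p < n_pops; ++p) dptr[p] = &dists[p];

    NumericMatrix mm;
    if (g_next >= 1 && mig_index[g_next - 1] >= 0) {
      mm = as<NumericMatrix>(mig_mats[mig_index[g_next - 1]]);
    }

    for (int p = 0; p < n_pops; ++p) {
      int new_size = (g_next <= 0) ? (p == 0 ? N0 : 0) : sizes(g_next, p);
      if (new_size == 0) continue;
      if (g_next >= 1 && founder_gen[p] == g_next) {
        // founding generation: all parents from the source population
        step_pop(gen_abs, prev, dptr, founder_src[p], new_size, nullptr,
                 E.pops[p]);
      } else {
        const double* row = nullptr;
        std::vector<double> rowbuf;
        if (mm.nrow() == n_pops) {
          rowbuf.resize(n_pops);
          for (int q = 0; q < n_pops; ++q) rowbuf[q] = mm(p, q);
          row = rowbuf.data();
        }
        int src_self = (prev[p].empty() && founder_src[p] >= 0)
                         ? founder_src[p] : p;
        if (prev[p].empty() && src_self == p) continue;  // defensive
        step_pop(gen_abs, prev, dptr, src_self, new_size, row, E.pops[p]);
      }
    }
  };

  int gen_abs = 0;
  for (int g = 1; g <= burn_in; ++g) {
    ++gen_abs;
    advance(gen_abs, 0);
    if (g % fix_interval == 0) E.sweep_fixed(gen_abs, burn_in);
  }
  E.sweep_fixed(gen_abs, burn_in);

  // snapshot support for conditioned sweeps
  std::vector<std::vector<Hap>> snap_pops;
  size_t snap_muts = 0, snap_fix = 0;
  int restarts = 0;

  auto introduce_sweep = [&]() {
    Mut m;
    m.pos = sweep_pos;
    m.sel = sweep_s;
    m.h = sweep_h;
    m.element = E.element_at(sweep_pos);
    m.gen = gen_abs;
    E.muts.push_back(m);
    E.sweep_id = (int)E.muts.size() - 1;
    E.sweep_globally_fixed = false;
    std::vector<Hap>& tp = E.pops[sweep_pop];
    if (tp.empty()) stop("Sweep target population is empty at introduction time.");
    int h = std::uniform_int_distribution<int>(0, (int)tp.size() - 1)(E.rng);
    auto cmp = [&](int x, int y) {
      return E.muts[x].pos < E.muts[y].pos ||
             (E.muts[x].pos == E.muts[y].pos && x < y);
    };
    tp[h].insert(std::lower_bound(tp[h].begin(), tp[h].end(), E.sweep_id, cmp),
                 E.sweep_id);
  };

  auto take_snapshot = [&]() {
    snap_pops = E.pops;
    snap_muts = E.muts.size();
    snap_fix = E.fix_gen.size();
  };
  auto restore_snapshot = [&]() {
    E.pops = snap_pops;
    E.muts.resize(snap_muts);
    E.fix_gen.resize(snap_fix);
    E.fix_pos.resize(snap_fix);
    E.fix_sel.resize(snap_fix);
    E.fix_el.resize(snap_fix);
    E.sweep_id = -1;
    E.sweep_globally_fixed = false;
  };

  int g = 0;
  while (g < span) {
    if (have_sweep && g == sweep_gen && E.sweep_id == -1) {
      take_snapshot();
      introduce_sweep();
    }
    ++g;
    ++gen_abs;
    advance(gen_abs, g);
    bool do_fix = (g % fix_interval == 0) || g == span;
    if (do_fix) E.sweep_fixed(gen_abs, burn_in);
    if (have_sweep && !cond_pops.empty() && g > sweep_gen &&
        E.sweep_id != -1 && do_fix && !E.sweep_globally_fixed) {
      if (E.count_total(E.sweep_id) == 0) {
        if (++restarts > max_restarts)
          stop("Conditioned sweep exceeded %d restart attempts.", max_restarts);
        restore_snapshot();
        g = sweep_gen;
        gen_abs = burn_in + sweep_gen;
        take_snapshot();
        introduce_sweep();
        continue;
      }
    }
    if (have_sweep && g == span) {
      bool ok = true;
      if (!E.sweep_globally_fixed) {
        for (int p : cond_pops) {
          long need = 2L * (long)sizes(span, p);
          if (E.count_in_pop(E.sweep_id, p) != need) { ok = false; break; }
        }
      }
      if (!ok) {
        if (++restarts > max_restarts)
          stop("Conditioned sweep exceeded %d restart attempts.", max_restarts);
        restore_snapshot();
        g = sweep_gen;
        gen_abs = burn_in + sweep_gen;
        take_snapshot();
        introduce_sweep();
      }
    }
  }

  // ---- sampling at present ----
  std::vector<int> hap_pop;
  std::vector<const Hap*> sampled;
  for (int p = 0; p < n_pops; ++p) {
    int ns = sample_sizes[p];
    if (ns == 0) continue;
    int np = (int)E.pops[p].size() / 2;
    if (ns > np) stop("Sample size exceeds population size at present.");
    std::vector<int> idx(np);
    for (int i = 0; i < np; ++i) idx[i] = i;
    std::shuffle(idx.begin(), idx.end(), E.rng);
    for (int i = 0; i < ns; ++i) {
      sampled.push_back(&E.pops[p][2 * idx[i]]);
      sampled.push_back(&E.pops[p][2 * idx[i] + 1]);
      hap_pop.push_back(p);
      hap_pop.push_back(p);
    }
  }

  std::unordered_map<int, int> site_of;
  std::vector<int> site_ids;
  for (const Hap* h : sampled)
    for (int id : *h)
      if (!site_of.count(id)) {
        site_of[id] = 0;
        site_ids.push_back(id);
      }
  std::sort(site_ids.begin(), site_ids.end(), [&](int x, int y) {
    return E.muts[x].pos < E.muts[y].pos ||
           (E.muts[x].pos == E.muts[y].pos && x < y);
  });
  for (size_t i = 0; i < site_ids.size(); ++i) site_of[site_ids[i]] = (int)i;

  int n_hap = (int)sampled.size();
  int n_sites = (int)site_ids.size();
  IntegerMatrix geno(n_hap, n_sites);
  for (int hh = 0; hh < n_hap; ++hh)
    for (int id : *sampled[hh]) geno(hh, site_of[id]) = 1;

  NumericVector pos_out(n_sites), sel_out(n_sites);
  IntegerVector el_out(n_sites);
  for (int i = 0; i < n_sites; ++i) {
    pos_out[i] = E.muts[site_ids[i]].pos;
    sel_out[i] = E.muts[site_ids[i]].sel;
    el_out[i] = E.muts[site_ids[i]].element;
  }

  bool sweep_in_sample = have_sweep && E.sweep_id >= 0 &&
    (E.sweep_globally_fixed || site_of.count(E.sweep_id));

  return List::create(
    _["positions"] = pos_out,
    _["geno"] = geno,
    _["hap_pop"] = IntegerVector(hap_pop.begin(), hap_pop.end()),
    _["site_sel"] = sel_out,
    _["site_element"] = el_out,
    _["fix_gen"] = IntegerVector(E.fix_gen.begin(), E.fix_gen.end()),
    _["fix_pos"] = NumericVector(E.fix_pos.begin(), E.fix_pos.end()),
    _["fix_sel"] = NumericVector(E.fix_sel.begin(), E.fix_sel.end()),
    _["fix_element"] = IntegerVector(E.fix_el.begin(), E.fix_el.end()),
    _["restarts"] = restarts,
    _["sweep_fixed_globally"] = E.sweep_globally_fixed,
    _["sweep_in_sample"] = sweep_in_sample,
    _["n_muts_total"] = (int)E.muts.size());
}
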