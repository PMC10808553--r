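// Agent-based germinal center simulation.
//
// Space is a sphere of lattice nodes (node = 5 um); the z < 0 hemisphere is
// the light zone (LZ, Tfh + FDC), z >= 0 the dark zone (DZ, stromal cells).
// B cells and Tfh occupy at most one per node; FDC somas/dendrites do not
// block.  Chemokine guidance fields (one sourced by FDCs, one by stromal
// cells) are precomputed once by iterative relaxation and bias the direction
// redraws of a persistent random walk.
//
// B-cell life cycle per the model: founder influx (Poisson) -> centroblast
// divisions with SHM -> unselected centrocyte searching antigen on FDC
// dendrites (capture probability min(1, Aff), floor 1e-8, one unit per
// success) -> apoptosis if nothing captured within the search time ->
// Tfh-contact phase (a Tfh polarizes only its contacted B cell with the
// most internalized antigen; 0.5 h of polarization within a 3 h window
// selects, expiry kills) -> recycling with an antigen-dependent number of
// divisions -> after the last division, antigen-retaining cells leave as
// output cells, others return to the light zone.
//
// The engine uses its own counter-based RNG streams (one per subsystem,
// derived from the run seed) so runs are reproducible independently of R's
// RNG state.

#include "docking.h"

#include <cstring>
#include <deque>
#include <unordered_map>
#include <unordered_set>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- RNG
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0xa0761d6478bd642fULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  int unif_int(int n) { return static_cast<int>(unif() * n); }
  double norm() {
    if (have_spare_) { have_spare_ = false; return spare_; }
    double u1 = unif(), u2 = unif();
    while (u1 <= 1e-300) u1 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare_ = r * std::sin(2.0 * M_PI * u2);
    have_spare_ = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
  int poisson(double lambda) {
    if (lambda <= 0) return 0;
    // inversion by multiplication; fine for the small per-step rates used
    double Lq = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > Lq);
    return k - 1;
  }
  bool have_spare_ = false;
  double spare_ = 0.0;
};

enum Stream { PLACE = 0, INFLUX, MOVE, DIVIDE, CAPTURE, TFH, OUTPUT, NSTREAM };

// ---------------------------------------------------------------- config
struct EngCfg {
  double node_size, gc_radius;
  int n_tfh, n_fdc, fdc_arms, n_stromal;
  double arm_length;
  double dt, capture_interval;
  double founder_inflow, inflow_duration;
  int founder_divisions;
  double cycle_mean, cycle_sd, shm_p;
  double antigen_total;
  double search_time, tfh_window, polarization_required, contact_duration;
  double asym_prob, output_asc_halflife, ab_rate, capture_min_affinity;
  double div_nmin, div_nmax, div_K, div_h;
  double sim_days, Emax, C;
  bool literal_aff;
  double speed_um_min, persistence_min, chemo_weight, stabilization;
  double snapshot_interval;
  double seed;
  bool audit_every_step;
};

double num(const List& l, const char* k) { return as<double>(l[k]); }

EngCfg read_cfg(const List& l) {
  EngCfg c;
  c.node_size = num(l, "node_size");
  c.gc_radius = num(l, "gc_radius");
  c.n_tfh = as<int>(l["n_tfh"]);
  c.n_fdc = as<int>(l["n_fdc"]);
  c.fdc_arms = as<int>(l["fdc_arms"]);
  c.n_stromal = as<int>(l["n_stromal"]);
  c.arm_length = num(l, "arm_length");
  c.dt = num(l, "dt");
  c.capture_interval = num(l, "capture_check_interval");
  c.founder_inflow = num(l, "founder_inflow");
  c.inflow_duration = num(l, "inflow_duration");
  c.founder_divisions = as<int>(l["founder_divisions"]);
  c.cycle_mean = num(l, "cycle_mean");
  c.cycle_sd = num(l, "cycle_sd");
  c.shm_p = num(l, "shm_p");
  c.antigen_total = num(l, "antigen_total");
  c.search_time = num(l, "search_time");
  c.tfh_window = num(l, "tfh_window");
  c.polarization_required = num(l, "polarization_required");
  c.contact_duration = num(l, "contact_duration");
  c.asym_prob = num(l, "asym_prob");
  c.output_asc_halflife = num(l, "output_asc_halflife");
  c.ab_rate = num(l, "ab_rate");
  c.capture_min_affinity = num(l, "capture_min_affinity");
  c.div_nmin = num(l, "div_nmin");
  c.div_nmax = num(l, "div_nmax");
  c.div_K = num(l, "div_K");
  c.div_h = num(l, "div_h");
  c.sim_days = num(l, "sim_days");
  c.Emax = num(l, "affinity_emax");
  c.C = num(l, "affinity_c");
  c.literal_aff = as<std::string>(l["affinity_mode"]) == "literal";
  c.speed_um_min = num(l, "speed");
  c.persistence_min = num(l, "persistence");
  c.chemo_weight = num(l, "chemo_weight");
  c.stabilization = num(l, "stabilization");
  c.snapshot_interval = num(l, "snapshot_interval");
  c.seed = num(l, "seed");
  c.audit_every_step = as<bool>(l["audit_every_step"]);
  return c;
}

// ---------------------------------------------------------------- agents
constexpr int MAXD = 8;   // max antigen domains
constexpr int MAXL = 9;   // max BCR length
constexpr int OCC_FREE = -1, OCC_OUT = -2;
constexpr int TFH_BASE = 1 << 28, STROMAL_ID = 1 << 29;

enum BState : uint8_t { CB = 0, CC_UNSEL = 1, CC_TFH = 2 };

struct BCell {
  bool alive = true;
  uint8_t state = CB;
  int pos = -1;
  std::array<uint8_t, MAXL> seq{};  // 0-based residue codes
  std::array<double, MAXD> aff{};
  int a = 0;
  int divs_left = 0;
  double cycle_left = 0, search_left = 0, window_left = 0, polar_acc = 0;
  double contact_left = 0;
  int contact_tfh = -1;
  int mutations = 0;
  int founder_domain = 0;  // 0-based
  int dir = 0;
  double persist_left = 0;
};

struct Tfh {
  int pos = -1;
  int dir = 0;
  double persist_left = 0;
  int contacts = 0;
};

struct OutputCell {
  double time;
  std::array<uint8_t, MAXL> seq;
  int mutations, a, founder_domain;
  std::array<double, MAXD> aff;
};

// ---------------------------------------------------------------- engine
class GC {
 public:
  GC(List cfgList, List domains, NumericMatrix U, IntegerMatrix poolSeqs,
     IntegerVector poolDomain, NumericVector cellSnapTimes)
      : cfg_(read_cfg(cfgList)), U_(clone(U)), keepalive_(domains) {
    nd_ = domains.size();
    if (nd_ < 1 || nd_ > MAXD) stop("between 1 and %d antigen domains supported", MAXD);
    for (int d = 0; d < nd_; ++d) {
      XPtr<PoseSet> p(as<SEXP>(domains[d]));
      ps_.push_back(p.get());
      if (p->n_prof() == 0) stop("domain %d has an empty pose set", d + 1);
    }
    L_ = ps_[0]->L;
    for (int d = 1; d < nd_; ++d)
      if (ps_[d]->L != L_) stop("all domains must share the BCR length");
    if (poolSeqs.ncol() != L_) stop("founder pool length does not match pose sets");
    Umin_ = R_PosInf;
    for (double v : U_) Umin_ = std::min(Umin_, v);
    pool_seqs_ = poolSeqs;
    pool_domain_ = poolDomain;
    snap_times_ = as<std::vector<double>>(cellSnapTimes);
    std::sort(snap_times_.begin(), snap_times_.end());
    for (int s = 0; s < NSTREAM; ++s)
      rng_[s].seed(static_cast<uint64_t>(cfg_.seed), s);
    init();
  }

  // ------------------------------------------------------------- geometry
  int R_ = 0, D_ = 0;
  std::size_t lin(int x, int y, int z) const {
    return (static_cast<std::size_t>(x + R_) * D_ + (y + R_)) * D_ + (z + R_);
  }
  bool in_sphere(int x, int y, int z) const {
    return x * x + y * y + z * z <= R_ * R_;
  }
  void delin(std::size_t idx, int& x, int& y, int& z) const {
    z = static_cast<int>(idx % D_) - R_;
    y = static_cast<int>((idx / D_) % D_) - R_;
    x = static_cast<int>(idx / (static_cast<std::size_t>(D_) * D_)) - R_;
  }

  void init() {
    R_ = static_cast<int>(std::lround(cfg_.gc_radius / cfg_.node_size));
    if (R_ < 3) stop("GC radius too small");
    D_ = 2 * R_ + 1;
    occ_.assign(static_cast<std::size_t>(D_) * D_ * D_, OCC_OUT);
    std::vector<std::size_t> lz_nodes, dz_nodes;
    for (int x = -R_; x <= R_; ++x)
      for (int y = -R_; y <= R_; ++y)
        for (int z = -R_; z <= R_; ++z)
          if (in_sphere(x, y, z)) {
            occ_[lin(x, y, z)] = OCC_FREE;
            (z < 0 ? lz_nodes : dz_nodes).push_back(lin(x, y, z));
          }
    n_nodes_ = lz_nodes.size() + dz_nodes.size();

    // FDC somas and dendrites (non-blocking), antigen on dendrite nodes
    Xoshiro& pr = rng_[PLACE];
    is_dendrite_.assign(occ_.size(), -1);
    int arm_nodes = static_cast<int>(std::lround(cfg_.arm_length / cfg_.node_size));
    for (int f = 0; f < cfg_.n_fdc; ++f) {
      std::size_t soma = lz_nodes[pr.unif_int(lz_nodes.size())];
      int x, y, z;
      delin(soma, x, y, z);
      add_dendrite(x, y, z);
      for (int arm = 0; arm < std::min(cfg_.fdc_arms, 6); ++arm)
        for (int k = 1; k <= arm_nodes; ++k) {
          int nx = x + k * DIRS[arm][0], ny = y + k * DIRS[arm][1],
              nz = z + k * DIRS[arm][2];
          if (in_sphere(nx, ny, nz)) add_dendrite(nx, ny, nz);
        }
    }
    if (dnodes_.empty()) stop("no FDC dendrite nodes inside the GC");

    // antigen: per-domain integer units spread uniformly over dendrite nodes
    ag_.assign(static_cast<std::size_t>(dnodes_.size()) * nd_, 0);
    ag_on_fdc_ = 0;
    long long tot = static_cast<long long>(std::llround(cfg_.antigen_total));
    for (int d = 0; d < nd_; ++d) {
      long long units = tot / nd_ + (d < tot % nd_ ? 1 : 0);
      long long base = units / static_cast<long long>(dnodes_.size());
      long long rem = units - base * static_cast<long long>(dnodes_.size());
      for (std::size_t k = 0; k < dnodes_.size(); ++k) ag_[k * nd_ + d] = base;
      // remainder goes to distinct random nodes, one extra unit each
      std::vector<std::size_t> idx(dnodes_.size());
      for (std::size_t k = 0; k < idx.size(); ++k) idx[k] = k;
      for (long long r = 0; r < rem; ++r) {
        std::size_t j = r + pr.unif_int(static_cast<int>(idx.size() - r));
        std::swap(idx[r], idx[j]);
        ag_[idx[r] * nd_ + d] += 1;
      }
      ag_on_fdc_ += units;
    }
    antigen_total_ = ag_on_fdc_;

    // Tfh in LZ, stromal in DZ (both occupy nodes)
    for (int t = 0; t < cfg_.n_tfh; ++t) {
      std::size_t n = random_free(lz_nodes, pr);
      Tfh tf;
      tf.pos = static_cast<int>(n);
      tf.dir = pr.unif_int(6);
      tf.persist_left = cfg_.persistence_min / 60.0 * pr.unif();
      occ_[n] = TFH_BASE + t;
      tfh_.push_back(tf);
    }
    for (int sY = 0; sY < cfg_.n_stromal; ++sY) {
      std::size_t n = random_free(dz_nodes, pr);
      occ_[n] = STROMAL_ID;
      stromal_.push_back(n);
    }

    // chemokine guidance fields (steady state by iterative relaxation)
    field_lz_ = relax_field(is_dendrite_, true);
    std::vector<int> srcS(occ_.size(), -1);
    for (std::size_t n : stromal_) srcS[n] = 1;
    field_dz_ = relax_field(srcS, false);

    t_ = 0;
    step_ = 0;
    capture_every_ = std::max(1L, std::lround(cfg_.capture_interval / cfg_.dt));
    snapshot_every_ = std::max(1L, std::lround(cfg_.snapshot_interval / cfg_.dt));
    record_metrics();
  }

  void add_dendrite(int x, int y, int z) {
    std::size_t n = lin(x, y, z);
    if (is_dendrite_[n] >= 0) return;
    is_dendrite_[n] = static_cast<int>(dnodes_.size());
    dnodes_.push_back(n);
  }

  std::size_t random_free(const std::vector<std::size_t>& nodes, Xoshiro& r) {
    for (int tries = 0; tries < 20000; ++tries) {
      std::size_t n = nodes[r.unif_int(static_cast<int>(nodes.size()))];
      if (occ_[n] == OCC_FREE) return n;
    }
    stop("could not find a free lattice node (GC too crowded)");
  }

  std::vector<float> relax_field(const std::vector<int>& src, bool) {
    std::vector<float> f(occ_.size(), 0.0f), g(occ_.size(), 0.0f);
    for (int it = 0; it < 120; ++it) {
      for (int x = -R_; x <= R_; ++x)
        for (int y = -R_; y <= R_; ++y)
          for (int z = -R_; z <= R_; ++z) {
            std::size_t n = lin(x, y, z);
            if (occ_[n] == OCC_OUT) continue;
            if (src[n] >= 0) { g[n] = 1.0f; continue; }
            float sum = 0.0f;
            for (int m = 0; m < 6; ++m) {
              int nx = x + DIRS[m][0], ny = y + DIRS[m][1], nz = z + DIRS[m][2];
              if (in_sphere(nx, ny, nz)) sum += f[lin(nx, ny, nz)];
            }
            g[n] = sum / 6.0f;
          }
      std::swap(f, g);
    }
    return f;
  }

  // ------------------------------------------------------------- affinity
  double to_aff(double E) const {
    return cfg_.literal_aff ? std::exp((E - cfg_.Emax) / cfg_.C)
                            : std::exp((cfg_.Emax - E) / cfg_.C);
  }

  uint64_t seq_key(const std::array<uint8_t, MAXL>& s) const {
    uint64_t k = 0;
    for (int i = 0; i < L_; ++i) k = (k << 5) | s[i];
    return k;
  }

  const std::array<double, MAXD>& affinities(const std::array<uint8_t, MAXL>& s) {
    uint64_t k = seq_key(s);
    auto it = memo_.find(k);
    if (it != memo_.end()) return it->second;
    std::array<double, MAXD> a{};
    for (int d = 0; d < nd_; ++d) {
      ScoreHit h = score_sequence(*ps_[d], s.data(), U_.begin(),
                                  cfg_.stabilization, Umin_, false, 0);
      a[d] = to_aff(h.energy);
    }
    return memo_.emplace(k, a).first->second;
  }

  double draw_cycle(Xoshiro& r) {
    for (int i = 0; i < 1000; ++i) {
      double v = cfg_.cycle_mean + cfg_.cycle_sd * r.norm();
      if (v > 0) return v;
    }
    return cfg_.cycle_mean;  // unreachable at sane parameters
  }

  int divisions_from_antigen(int a) const {
    if (a <= 0) return static_cast<int>(cfg_.div_nmin);
    double ah = std::pow(static_cast<double>(a), cfg_.div_h);
    double frac = ah / (ah + std::pow(cfg_.div_K, cfg_.div_h));
    return static_cast<int>(
        std::lround(cfg_.div_nmin + (cfg_.div_nmax - cfg_.div_nmin) * frac));
  }

  // ------------------------------------------------------------- stepping
  void run_until(double t_end) {
    long long nsteps = std::llround((t_end - t_) / cfg_.dt);
    for (long long i = 0; i < nsteps; ++i) {
      step_once();
      if ((step_ & 1023) == 0) checkUserInterrupt();
    }
  }

  void step_once() {
    ++step_;
    double t_next = t_ + cfg_.dt;
    influx();
    movement();
    dz_dynamics();
    if (step_ % capture_every_ == 0) capture();
    search_resolution();
    tfh_phase();
    output_dynamics();
    t_ = t_next;
    // drop dead cells from the live list
    live_.erase(std::remove_if(live_.begin(), live_.end(),
                               [&](int i) { return !cells_[i].alive; }),
                live_.end());
    if (cfg_.audit_every_step) audit();
    if (step_ % snapshot_every_ == 0) record_metrics();
    while (snap_cursor_ < snap_times_.size() &&
           t_ >= snap_times_[snap_cursor_] - 1e-9) {
      cell_snaps_.push_back(dump_cells());
      ++snap_cursor_;
    }
  }

  void influx() {
    if (t_ >= cfg_.inflow_duration) return;
    Xoshiro& r = rng_[INFLUX];
    int n = r.poisson(cfg_.founder_inflow * cfg_.dt);
    for (int i = 0; i < n; ++i) {
      // random free node anywhere in the GC
      std::size_t node = 0;
      bool found = false;
      for (int tries = 0; tries < 2000; ++tries) {
        int x = r.unif_int(D_) - R_, y = r.unif_int(D_) - R_,
            z = r.unif_int(D_) - R_;
        if (!in_sphere(x, y, z)) continue;
        node = lin(x, y, z);
        if (occ_[node] == OCC_FREE) { found = true; break; }
      }
      if (!found) continue;  // GC full; founder fails to enter
      int k = r.unif_int(pool_seqs_.nrow());
      BCell b;
      b.pos = static_cast<int>(node);
      for (int j = 0; j < L_; ++j)
        b.seq[j] = static_cast<uint8_t>(pool_seqs_(k, j) - 1);
      b.aff = affinities(b.seq);
      b.founder_domain = pool_domain_[k] - 1;
      b.state = CB;
      b.divs_left = cfg_.founder_divisions;
      b.cycle_left = draw_cycle(r);
      b.dir = r.unif_int(6);
      b.persist_left = cfg_.persistence_min / 60.0 * r.unif();
      occ_[node] = static_cast<int>(cells_.size());
      live_.push_back(static_cast<int>(cells_.size()));
      cells_.push_back(b);
      ++founders_arrived_;
    }
  }

  void move_agent(int& pos, int& dir, double& persist_left, int occ_id,
                  const std::vector<float>& field, Xoshiro& r) {
    persist_left -= cfg_.dt;
    int x, y, z;
    delin(pos, x, y, z);
    if (persist_left <= 0) {
      persist_left = cfg_.persistence_min / 60.0;
      if (r.unif() < cfg_.chemo_weight) {
        // steepest-ascent direction of the guidance field
        float bestv = -1.0f;
        int bestm = r.unif_int(6);
        for (int m = 0; m < 6; ++m) {
          int nx = x + DIRS[m][0], ny = y + DIRS[m][1], nz = z + DIRS[m][2];
          if (!in_sphere(nx, ny, nz)) continue;
          float v = field[lin(nx, ny, nz)];
          if (v > bestv) { bestv = v; bestm = m; }
        }
        dir = bestm;
      } else {
        dir = r.unif_int(6);
      }
    }
    double p_move = cfg_.speed_um_min * 60.0 * cfg_.dt / cfg_.node_size;
    if (r.unif() >= p_move) return;
    int nx = x + DIRS[dir][0], ny = y + DIRS[dir][1], nz = z + DIRS[dir][2];
    if (!in_sphere(nx, ny, nz)) { dir = r.unif_int(6); return; }
    std::size_t n = lin(nx, ny, nz);
    if (occ_[n] != OCC_FREE) return;  // blocked: stall
    occ_[n] = occ_id;
    occ_[pos] = OCC_FREE;
    pos = static_cast<int>(n);
  }

  void movement() {
    Xoshiro& r = rng_[MOVE];
    for (std::size_t t = 0; t < tfh_.size(); ++t) {
      if (tfh_[t].contacts > 0) continue;  // engaged Tfh stay put
      move_agent(tfh_[t].pos, tfh_[t].dir, tfh_[t].persist_left,
                 TFH_BASE + static_cast<int>(t), field_lz_, r);
    }
    for (int i : live_) {
      BCell& b = cells_[i];
      if (!b.alive || b.contact_tfh >= 0) continue;
      const std::vector<float>& f = (b.state == CB) ? field_dz_ : field_lz_;
      move_agent(b.pos, b.dir, b.persist_left, i, f, r);
    }
  }

  void dz_dynamics() {
    Xoshiro& r = rng_[DIVIDE];
    std::size_t n_live = live_.size();  // daughters appended are not iterated
    for (std::size_t li = 0; li < n_live; ++li) {
      int i = live_[li];
      BCell& b = cells_[i];
      if (!b.alive || b.state != CB) continue;
      b.cycle_left -= cfg_.dt;
      if (b.cycle_left > 0) continue;
      // attempt division: needs a free neighbor node for the daughter
      int x, y, z;
      delin(b.pos, x, y, z);
      int free_dirs[6], nfree = 0;
      for (int m = 0; m < 6; ++m) {
        int nx = x + DIRS[m][0], ny = y + DIRS[m][1], nz = z + DIRS[m][2];
        if (in_sphere(nx, ny, nz) && occ_[lin(nx, ny, nz)] == OCC_FREE)
          free_dirs[nfree++] = m;
      }
      if (nfree == 0) continue;  // deferred until space frees up
      int m = free_dirs[r.unif_int(nfree)];
      std::size_t dn = lin(x + DIRS[m][0], y + DIRS[m][1], z + DIRS[m][2]);

      BCell d = cells_[i];  // copy parent state
      d.pos = static_cast<int>(dn);
      d.dir = r.unif_int(6);
      BCell& p = cells_[i];

      // antigen split: asymmetric (all to one daughter) with prob asym_prob
      int a = p.a;
      if (r.unif() < cfg_.asym_prob) {
        if (r.unif() < 0.5) { p.a = a; d.a = 0; }
        else { p.a = 0; d.a = a; }
      } else {
        int half = a / 2;
        p.a = half; d.a = a - half;
        if (a % 2 == 1 && r.unif() < 0.5) std::swap(p.a, d.a);
      }
      p.divs_left -= 1;
      d.divs_left = p.divs_left;
      p.cycle_left = draw_cycle(r);
      d.cycle_left = draw_cycle(r);
      // SHM on both daughters independently
      mutate_cell(p, r);
      mutate_cell(d, r);

      occ_[dn] = static_cast<int>(cells_.size());
      int d_id = static_cast<int>(cells_.size());
      live_.push_back(d_id);
      cells_.push_back(d);
      // post-division fate for cells that completed their divisions
      finalize_if_done(i);
      finalize_if_done(d_id);
    }
  }

  void mutate_cell(BCell& b, Xoshiro& r) {
    bool changed = false;
    for (int j = 0; j < L_; ++j) {
      if (r.unif() < cfg_.shm_p) {
        int nr = r.unif_int(19);
        if (nr >= b.seq[j]) ++nr;
        b.seq[j] = static_cast<uint8_t>(nr);
        ++b.mutations;
        changed = true;
      }
    }
    if (changed) b.aff = affinities(b.seq);  // re-evaluate against all domains
  }

  void finalize_if_done(int i) {
    BCell& b = cells_[i];
    if (!b.alive || b.state != CB || b.divs_left > 0) return;
    if (b.a > 0) {
      // antigen-retaining cells exit as output cells
      OutputCell o;
      o.time = t_;
      o.seq = b.seq;
      o.mutations = b.mutations;
      o.a = b.a;
      o.founder_domain = b.founder_domain;
      o.aff = b.aff;
      outputs_.push_back(o);
      ag_removed_ += b.a;
      ag_in_cells_ -= b.a;
      ++pending_outputs_;
      remove_cell(i, false);
    } else {
      b.state = CC_UNSEL;
      b.search_left = cfg_.search_time;
    }
  }

  void capture() {
    Xoshiro& r = rng_[CAPTURE];
    for (int i : live_) {
      BCell& b = cells_[i];
      if (!b.alive || b.state != CC_UNSEL) continue;
      int dn = is_dendrite_[b.pos];
      if (dn < 0) continue;
      // target the domain of highest affinity among those still stocked here
      int best = -1;
      double bestAff = -1;
      for (int d = 0; d < nd_; ++d)
        if (ag_[static_cast<std::size_t>(dn) * nd_ + d] > 0 &&
            b.aff[d] > bestAff) {
          bestAff = b.aff[d];
          best = d;
        }
      if (best < 0 || bestAff < cfg_.capture_min_affinity) continue;
      if (r.unif() < std::min(1.0, bestAff)) {
        ag_[static_cast<std::size_t>(dn) * nd_ + best] -= 1;
        b.a += 1;
        ag_on_fdc_ -= 1;
        ag_in_cells_ += 1;
      }
    }
  }

  void search_resolution() {
    for (int i : live_) {
      BCell& b = cells_[i];
      if (!b.alive || b.state != CC_UNSEL) continue;
      b.search_left -= cfg_.dt;
      if (b.search_left > 0) continue;
      if (b.a == 0) {
        remove_cell(i, true);  // failed to capture: apoptosis
      } else {
        b.state = CC_TFH;
        b.window_left = cfg_.tfh_window;
        b.polar_acc = 0;
      }
    }
  }

  void tfh_phase() {
    Xoshiro& r = rng_[TFH];
    // contact maintenance and formation
    for (int i : live_) {
      BCell& b = cells_[i];
      if (!b.alive || b.state != CC_TFH) continue;
      if (b.contact_tfh >= 0) {
        b.contact_left -= cfg_.dt;
        if (b.contact_left <= 0) end_contact(b);
      }
      if (b.contact_tfh < 0) {
        int x, y, z;
        delin(b.pos, x, y, z);
        for (int m = 0; m < 6; ++m) {
          int nx = x + DIRS[m][0], ny = y + DIRS[m][1], nz = z + DIRS[m][2];
          if (!in_sphere(nx, ny, nz)) continue;
          int o = occ_[lin(nx, ny, nz)];
          if (o >= TFH_BASE && o < STROMAL_ID) {
            b.contact_tfh = o - TFH_BASE;
            b.contact_left = cfg_.contact_duration;
            tfh_[b.contact_tfh].contacts += 1;
            break;
          }
        }
      }
    }
    // each Tfh polarizes only the contacted B cell with the most antigen
    std::unordered_map<int, int> best;  // tfh -> b index
    for (int i : live_) {
      BCell& b = cells_[i];
      if (!b.alive || b.state != CC_TFH || b.contact_tfh < 0) continue;
      auto it = best.find(b.contact_tfh);
      if (it == best.end() || cells_[it->second].a < b.a ||
          (cells_[it->second].a == b.a && i < it->second))
        best[b.contact_tfh] = i;
    }
    for (auto& kv : best) cells_[kv.second].polar_acc += cfg_.dt;
    // window bookkeeping, selection and death
    for (int i : live_) {
      BCell& b = cells_[i];
      if (!b.alive || b.state != CC_TFH) continue;
      b.window_left -= cfg_.dt;
      if (b.polar_acc >= cfg_.polarization_required) {
        // selected: recycle to the DZ with antigen-dependent divisions
        end_contact(b);
        b.state = CB;
        b.divs_left = divisions_from_antigen(b.a);
        b.cycle_left = draw_cycle(r);
      } else if (b.window_left <= 0) {
        remove_cell(i, true);
      }
    }
  }

  void end_contact(BCell& b) {
    if (b.contact_tfh >= 0) {
      tfh_[b.contact_tfh].contacts -= 1;
      b.contact_tfh = -1;
      b.contact_left = 0;
    }
  }

  void remove_cell(int i, bool apoptotic) {
    BCell& b = cells_[i];
    if (!b.alive) return;
    end_contact(b);
    if (apoptotic) {
      ag_removed_ += b.a;
      ag_in_cells_ -= b.a;
      ++apoptosis_count_;
    }
    occ_[b.pos] = OCC_FREE;
    b.alive = false;
  }

  void output_dynamics() {
    Xoshiro& r = rng_[OUTPUT];
    if (pending_outputs_ > 0) {
      double p = 1.0 - std::exp(-M_LN2 / cfg_.output_asc_halflife * cfg_.dt);
      int conv = std::min(pending_outputs_, r.poisson(pending_outputs_ * p));
      pending_outputs_ -= conv;
      asc_ += conv;
    }
    antibody_ += asc_ * cfg_.ab_rate * cfg_.dt;
  }

  // ------------------------------------------------------------- audit
  void audit() {
    long long on_fdc = 0;
    for (long long v : ag_) on_fdc += v;
    long long in_cells = 0;
    for (int i : live_)
      if (cells_[i].alive) in_cells += cells_[i].a;
    if (on_fdc != ag_on_fdc_ || in_cells != ag_in_cells_ ||
        on_fdc + in_cells + ag_removed_ != antigen_total_)
      ++ledger_violations_;
    // occupancy: each living B cell and Tfh sits on its own node
    std::unordered_set<int> seen;
    for (int i : live_)
      if (cells_[i].alive &&
          (occ_[cells_[i].pos] != i || !seen.insert(cells_[i].pos).second))
        ++occupancy_violations_;
    for (std::size_t t = 0; t < tfh_.size(); ++t)
      if (occ_[tfh_[t].pos] != TFH_BASE + static_cast<int>(t) ||
          !seen.insert(tfh_[t].pos).second)
        ++occupancy_violations_;
  }

  // ------------------------------------------------------------- metrics
  void record_metrics() {
    int n_b = 0, n_cb = 0, n_cc = 0, n_tfhp = 0;
    std::array<double, MAXD> affsum{};
    double affmax_sum = 0;
    std::unordered_set<uint64_t> uniq;
    for (int i : live_) {
      const BCell& b = cells_[i];
      if (!b.alive) continue;
      ++n_b;
      n_cb += (b.state == CB);
      n_cc += (b.state == CC_UNSEL);
      n_tfhp += (b.state == CC_TFH);
      double mx = 0;
      for (int d = 0; d < nd_; ++d) {
        affsum[d] += b.aff[d];
        mx = std::max(mx, b.aff[d]);
      }
      affmax_sum += mx;
      uniq.insert(seq_key(b.seq));
    }
    m_time_.push_back(t_);
    m_nb_.push_back(n_b);
    m_ncb_.push_back(n_cb);
    m_ncc_.push_back(n_cc);
    m_ntfhp_.push_back(n_tfhp);
    for (int d = 0; d < nd_; ++d)
      m_aff_[d].push_back(n_b > 0 ? affsum[d] / n_b : NA_REAL);
    m_affmax_.push_back(n_b > 0 ? affmax_sum / n_b : NA_REAL);
    m_div_.push_back(static_cast<int>(uniq.size()));
    m_found_.push_back(founders_arrived_);
    m_out_.push_back(static_cast<int>(outputs_.size()));
    double oa = 0;
    for (const OutputCell& o : outputs_) {
      double mx = 0;
      for (int d = 0; d < nd_; ++d) mx = std::max(mx, o.aff[d]);
      oa += mx;
    }
    m_outaff_.push_back(outputs_.empty() ? NA_REAL : oa / outputs_.size());
    m_asc_.push_back(asc_);
    m_ab_.push_back(antibody_);
    m_agfdc_.push_back(static_cast<double>(ag_on_fdc_));
    m_agcell_.push_back(static_cast<double>(ag_in_cells_));
    m_agrem_.push_back(static_cast<double>(ag_removed_));
  }

  DataFrame dump_cells() const {
    std::vector<int> id, a, mut, fd;
    std::vector<std::string> seq, state;
    std::vector<std::vector<double>> aff(nd_);
    static const char* AA = "ACDEFGHIKLMNPQRSTVWY";
    static const char* STATES[3] = {"centroblast", "unselected_cc",
                                    "contacting_tfh"};
    for (int i : live_) {
      const BCell& b = cells_[i];
      if (!b.alive) continue;
      id.push_back(i + 1);
      std::string sq(L_, 'A');
      for (int j = 0; j < L_; ++j) sq[j] = AA[b.seq[j]];
      seq.push_back(sq);
      state.push_back(STATES[b.state]);
      a.push_back(b.a);
      mut.push_back(b.mutations);
      fd.push_back(b.founder_domain + 1);
      for (int d = 0; d < nd_; ++d) aff[d].push_back(b.aff[d]);
    }
    List cols = List::create(
        _["time"] = NumericVector(id.size(), t_), _["id"] = wrap(id),
        _["seq"] = wrap(seq), _["state"] = wrap(state), _["antigen"] = wrap(a),
        _["mutations"] = wrap(mut), _["founder_domain"] = wrap(fd));
    for (int d = 0; d < nd_; ++d)
      cols[std::string("aff_d") + std::to_string(d + 1)] = wrap(aff[d]);
    cols.attr("class") = "data.frame";
    cols.attr("row.names") = seq_len(static_cast<int>(id.size()));
    return cols;
  }

  // ------------------------------------------------------------- members
  EngCfg cfg_;
  NumericMatrix U_;
  List keepalive_;
  double Umin_ = 0;
  int nd_ = 0, L_ = 0;
  std::vector<PoseSet*> ps_;
  IntegerMatrix pool_seqs_;
  IntegerVector pool_domain_;
  Xoshiro rng_[NSTREAM];

  std::vector<int> occ_;
  std::size_t n_nodes_ = 0;
  std::vector<int> is_dendrite_;
  std::vector<std::size_t> dnodes_, stromal_;
  std::vector<long long> ag_;  // dendrite node x domain units
  std::vector<float> field_lz_, field_dz_;

  std::vector<BCell> cells_;
  std::vector<int> live_;
  std::vector<Tfh> tfh_;
  std::vector<OutputCell> outputs_;
  std::unordered_map<uint64_t, std::array<double, MAXD>> memo_;

  double t_ = 0;
  long long step_ = 0;
  long capture_every_ = 1, snapshot_every_ = 1;
  long long antigen_total_ = 0, ag_on_fdc_ = 0, ag_in_cells_ = 0,
            ag_removed_ = 0;
  int founders_arrived_ = 0, pending_outputs_ = 0, asc_ = 0;
  long long apoptosis_count_ = 0;
  double antibody_ = 0;
  long long ledger_violations_ = 0, occupancy_violations_ = 0;

  std::vector<double> m_time_, m_affmax_, m_outaff_, m_ab_, m_agfdc_,
      m_agcell_, m_agrem_;
  std::vector<double> m_aff_[MAXD];
  std::vector<int> m_nb_, m_ncb_, m_ncc_, m_ntfhp_, m_div_, m_found_, m_out_,
      m_asc_;

  std::vector<double> snap_times_;
  std::size_t snap_cursor_ = 0;
  std::vector<DataFrame> cell_snaps_;
};

}  // namespace

// [[Rcpp::export]]
SEXP cpp_gc_new(List cfg, List domains, NumericMatrix U,
                IntegerMatrix pool_seqs, IntegerVector pool_domain,
                NumericVector cell_snapshot_times) {
  return XPtr<GC>(new GC(cfg, domains, U, pool_seqs, pool_domain,
                         cell_snapshot_times),
                  true);
}

// [[Rcpp::export]]
void cpp_gc_run(SEXP gcxp, double t_end) {
  XPtr<GC> gc(gcxp);
  gc->run_until(t_end);
}

// [[Rcpp::export]]
List cpp_gc_state(SEXP gcxp) {
  XPtr<GC> gc(gcxp);
  return List::create(
      _["time"] = gc->t_, _["n_bcells"] = static_cast<int>(gc->live_.size()),
      _["n_tfh"] = static_cast<int>(gc->tfh_.size()),
      _["n_stromal"] = static_cast<int>(gc->stromal_.size()),
      _["n_dendrite_nodes"] = static_cast<int>(gc->dnodes_.size()),
      _["n_nodes"] = static_cast<double>(gc->n_nodes_),
      _["antigen_total"] = static_cast<double>(gc->antigen_total_),
      _["antigen_on_fdc"] = static_cast<double>(gc->ag_on_fdc_),
      _["antigen_in_cells"] = static_cast<double>(gc->ag_in_cells_),
      _["antigen_removed"] = static_cast<double>(gc->ag_removed_),
      _["founders_arrived"] = gc->founders_arrived_,
      _["apoptosis_count"] = static_cast<double>(gc->apoptosis_count_),
      _["pending_outputs"] = gc->pending_outputs_, _["asc"] = gc->asc_,
      _["antibody"] = gc->antibody_,
      _["ledger_violations"] = static_cast<double>(gc->ledger_violations_),
      _["occupancy_violations"] =
          static_cast<double>(gc->occupancy_violations_));
}

// [[Rcpp::export]]
List cpp_gc_antigen_per_domain(SEXP gcxp) {
  XPtr<GC> gc(gcxp);
  NumericVector per(gc->nd_);
  for (std::size_t k = 0; k < gc->dnodes_.size(); ++k)
    for (int d = 0; d < gc->nd_; ++d)
      per[d] += static_cast<double>(gc->ag_[k * gc->nd_ + d]);
  return List::create(_["on_fdc_per_domain"] = per);
}

// [[Rcpp::export]]
List cpp_gc_metrics(SEXP gcxp) {
  XPtr<GC> gc(gcxp);
  List out = List::create(
      _["time"] = wrap(gc->m_time_), _["n_bcells"] = wrap(gc->m_nb_),
      _["n_centroblasts"] = wrap(gc->m_ncb_),
      _["n_unselected"] = wrap(gc->m_ncc_),
      _["n_tfh_phase"] = wrap(gc->m_ntfhp_),
      _["mean_aff_max"] = wrap(gc->m_affmax_),
      _["diversity"] = wrap(gc->m_div_),
      _["founders_arrived"] = wrap(gc->m_found_),
      _["outputs_cum"] = wrap(gc->m_out_),
      _["mean_output_aff"] = wrap(gc->m_outaff_), _["asc"] = wrap(gc->m_asc_),
      _["antibody"] = wrap(gc->m_ab_),
      _["antigen_on_fdc"] = wrap(gc->m_agfdc_),
      _["antigen_in_cells"] = wrap(gc->m_agcell_),
      _["antigen_removed"] = wrap(gc->m_agrem_));
  List affs(gc->nd_);
  for (int d = 0; d < gc->nd_; ++d) affs[d] = wrap(gc->m_aff_[d]);
  out["mean_aff_domain"] = affs;
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_gc_cells(SEXP gcxp) {
  XPtr<GC> gc(gcxp);
  return gc->dump_cells();
}

// [[Rcpp::export]]
List cpp_gc_snapshots(SEXP gcxp) {
  XPtr<GC> gc(gcxp);
  return wrap(gc->cell_snaps_);
}

// [[Rcpp::export]]
List cpp_gc_outputs(SEXP gcxp) {
  XPtr<GC> gc(gcxp);
  static const char* AA = "ACDEFGHIKLMNPQRSTVWY";
  const std::size_t n = gc->outputs_.size();
  NumericVector time(n);
  IntegerVector mut(n), a(n), fd(n);
  CharacterVector seq(n);
  NumericMatrix aff(n, gc->nd_);
  for (std::size_t i = 0; i < n; ++i) {
    const auto& o = gc->outputs_[i];
    time[i] = o.time;
    mut[i] = o.mutations;
    a[i] = o.a;
    fd[i] = o.founder_domain + 1;
    std::string sq(gc->L_, 'A');
    for (int j = 0; j < gc->L_; ++j) sq[j] = AA[o.seq[j]];
    seq[i] = sq;
    for (int d = 0; d < gc->nd_; ++d) aff(i, d) = o.aff[d];
  }
  return List::create(_["time"] = time, _["seq"] = seq, _["mutations"] = mut,
                      _["antigen"] = a, _["founder_domain"] = fd,
                      _["aff"] = aff);
}

// [[Rcpp::export]]
void cpp_gc_audit_now(SEXP gcxp) {
  XPtr<GC> gc(gcxp);
  gc->audit();
}

// Division-time sampler used by the simulator (truncated-positive normal),
// exposed for direct inspection; uses the engine's own RNG seeded here.
// [[Rcpp::export]]
NumericVector cpp_draw_cycle_times(int n, double mean, double sd, double seed) {
  Xoshiro r;
  r.seed(static_cast<uint64_t>(seed), 12345);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double v;
    do { v = mean + sd * r.norm(); } while (v <= 0);
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_divisions_from_antigen(IntegerVector a, double nmin,
                                         double nmax, double K, double h) {
  IntegerVector out(a.size());
  for (int i = 0; i < a.size(); ++i) {
    if (a[i] <= 0) { out[i] = static_cast<int>(nmin); continue; }
    double ah = std::pow(static_cast<double>(a[i]), h);
    out[i] = static_cast<int>(
        std::lround(nmin + (nmax - nmin) * ah / (ah + std::pow(K, h))));
  }
  return out;
}
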