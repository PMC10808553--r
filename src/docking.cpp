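#include "docking.h"

using namespace Rcpp;

const int DIRS[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                        {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};

namespace {

// fixed-size hash key: first byte = code count, then the code bytes
template <int W>
struct Key {
  std::array<uint64_t, W> w{};
  bool operator==(const Key& o) const { return w == o.w; }
};

template <int W>
struct KeyHash {
  std::size_t operator()(const Key<W>& k) const {
    uint64_t h = 1469598103934665603ULL;
    for (uint64_t x : k.w) {
      h ^= x;
      h *= 1099511628211ULL;
    }
    return static_cast<std::size_t>(h);
  }
};

// lexicographic rank of pair (j, i), j < i, among all C(L,2) pairs
inline int pair_rank(int j, int i, int L) {
  return j * L - j * (j + 1) / 2 + (i - j - 1);
}

class Enumerator {
 public:
  Enumerator(const IntegerMatrix& ag_pos, int L, int min_contacts,
             double max_poses)
      : L_(L), min_contacts_(min_contacts), max_poses_(max_poses) {
    const int n = ag_pos.nrow();
    if (n == 0) stop("antigen is empty");
    if (L < 2) stop("BCR length must be >= 2");
    if (L > 9) stop("BCR length is limited to 9 residues");
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = hi[d] = ag_pos(0, d);
      for (int i = 1; i < n; ++i) {
        lo[d] = std::min(lo[d], ag_pos(i, d));
        hi[d] = std::max(hi[d], ag_pos(i, d));
      }
      // pad by L so that every chain able to touch the antigen fits
      org_[d] = lo[d] - L - 1;
      dim_[d] = hi[d] - lo[d] + 2 * (L + 1) + 1;
    }
    grid_.assign(static_cast<std::size_t>(dim_[0]) * dim_[1] * dim_[2], -1);
    chain_.assign(grid_.size(), -1);
    dist_.assign(grid_.size(), INT32_MAX);
    for (int i = 0; i < n; ++i) {
      std::size_t idx = lin(ag_pos(i, 0), ag_pos(i, 1), ag_pos(i, 2));
      if (grid_[idx] >= 0) stop("antigen occupies a lattice node twice");
      grid_[idx] = i;  // grid stores the antigen node index
    }
    bfs_contact_distance();
    ps_.L = L;
    ps_.min_contacts = min_contacts;
    ps_.n_ag = n;
    pos_.resize(L);
    moves_.resize(L - 1);
    codes_.reserve(64);
  }

  GeomPoseSet run() {
    // starts in (x, y, z) lexicographic order define the canonical pose order
    for (int x = org_[0]; x < org_[0] + dim_[0]; ++x)
      for (int y = org_[1]; y < org_[1] + dim_[1]; ++y)
        for (int z = org_[2]; z < org_[2] + dim_[2]; ++z) {
          std::size_t idx = lin(x, y, z);
          if (grid_[idx] >= 0) continue;           // antigen node
          if (dist_[idx] > L_ - 1) continue;       // cannot reach a contact
          place(0, x, y, z);
        }
    return std::move(ps_);
  }

 private:
  std::size_t lin(int x, int y, int z) const {
    return (static_cast<std::size_t>(x - org_[0]) * dim_[1] +
            (y - org_[1])) * dim_[2] + (z - org_[2]);
  }
  bool inside(int x, int y, int z) const {
    return x >= org_[0] && x < org_[0] + dim_[0] && y >= org_[1] &&
           y < org_[1] + dim_[1] && z >= org_[2] && z < org_[2] + dim_[2];
  }

  // BFS over free nodes from all antigen-adjacent free nodes; antigen blocks.
  void bfs_contact_distance() {
    std::vector<std::size_t> q;
    for (int x = org_[0]; x < org_[0] + dim_[0]; ++x)
      for (int y = org_[1]; y < org_[1] + dim_[1]; ++y)
        for (int z = org_[2]; z < org_[2] + dim_[2]; ++z) {
          std::size_t idx = lin(x, y, z);
          if (grid_[idx] >= 0) continue;
          for (int m = 0; m < 6; ++m) {
            int nx = x + DIRS[m][0], ny = y + DIRS[m][1], nz = z + DIRS[m][2];
            if (inside(nx, ny, nz) && grid_[lin(nx, ny, nz)] >= 0) {
              dist_[idx] = 0;
              q.push_back(idx);
              break;
            }
          }
        }
    std::size_t head = 0;
    while (head < q.size()) {
      std::size_t idx = q[head++];
      int32_t d = dist_[idx];
      const std::size_t sx = static_cast<std::size_t>(dim_[1]) * dim_[2];
      int x = static_cast<int>(idx / sx) + org_[0];
      int y = static_cast<int>((idx % sx) / dim_[2]) + org_[1];
      int z = static_cast<int>(idx % dim_[2]) + org_[2];
      for (int m = 0; m < 6; ++m) {
        int nx = x + DIRS[m][0], ny = y + DIRS[m][1], nz = z + DIRS[m][2];
        if (!inside(nx, ny, nz)) continue;
        std::size_t nidx = lin(nx, ny, nz);
        if (grid_[nidx] >= 0 || dist_[nidx] != INT32_MAX) continue;
        dist_[nidx] = d + 1;
        q.push_back(nidx);
      }
    }
  }

  void place(int i, int x, int y, int z) {
    std::size_t idx = lin(x, y, z);
    int added = 0, added_inter = 0;
    for (int m = 0; m < 6; ++m) {
      int nx = x + DIRS[m][0], ny = y + DIRS[m][1], nz = z + DIRS[m][2];
      if (!inside(nx, ny, nz)) continue;
      std::size_t nidx = lin(nx, ny, nz);
      int node = grid_[nidx];
      if (node >= 0) {
        codes_.push_back(static_cast<uint16_t>(i * ps_.n_ag + node));
        ++added;
        ++added_inter;
      } else {
        int j = chain_[nidx];
        if (j >= 0 && i - j >= 2) {
          codes_.push_back(
              static_cast<uint16_t>(L_ * ps_.n_ag + pair_rank(j, i, L_)));
          ++added;
        }
      }
    }
    ninter_ += added_inter;
    chain_[idx] = i;
    pos_[i] = {x, y, z};

    if (i == L_ - 1) {
      if (ninter_ >= min_contacts_) emit();
    } else if (ninter_ > 0 || dist_[idx] <= L_ - 1 - i) {
      // prune: if no contact yet, a contact node must still be reachable
      for (int m = 0; m < 6; ++m) {
        int nx = x + DIRS[m][0], ny = y + DIRS[m][1], nz = z + DIRS[m][2];
        if (!inside(nx, ny, nz)) continue;
        std::size_t nidx = lin(nx, ny, nz);
        if (grid_[nidx] >= 0 || chain_[nidx] >= 0) continue;
        moves_[i] = static_cast<uint8_t>(m);
        place(i + 1, nx, ny, nz);
      }
    }

    chain_[idx] = -1;
    for (int k = 0; k < added; ++k) codes_.pop_back();
    ninter_ -= added_inter;
  }

  void emit() {
    if (++ps_.total_poses > max_poses_)
      stop("pose enumeration exceeded max_poses (%.0f); increase the cap or "
           "use a smaller antigen/BCR length", max_poses_);
    long long pose_id = ps_.total_poses - 1;
    key_codes_.assign(codes_.begin(), codes_.end());
    std::sort(key_codes_.begin(), key_codes_.end());
    if (key_codes_.size() > 47) stop("contact profile too large to encode");
    Key<12> k;
    auto* bytes = reinterpret_cast<uint8_t*>(k.w.data());
    bytes[0] = static_cast<uint8_t>(key_codes_.size());
    std::memcpy(bytes + 2, key_codes_.data(),
                key_codes_.size() * sizeof(uint16_t));
    auto it = map_.find(k);
    if (it != map_.end()) {
      ps_.pose_count[it->second]++;
      return;
    }
    map_.emplace(k, static_cast<int>(ps_.n_prof()));
    if (ps_.off.empty()) ps_.off.push_back(0);
    ps_.codes.insert(ps_.codes.end(), key_codes_.begin(), key_codes_.end());
    ps_.off.push_back(ps_.codes.size());
    ps_.rep_pose.push_back(pose_id);
    ps_.pose_count.push_back(1);
    ps_.rep_start.push_back(pos_[0][0]);
    ps_.rep_start.push_back(pos_[0][1]);
    ps_.rep_start.push_back(pos_[0][2]);
    ps_.rep_moves.insert(ps_.rep_moves.end(), moves_.begin(), moves_.end());
  }

  int L_, min_contacts_;
  double max_poses_;
  int org_[3], dim_[3];
  std::vector<int> grid_;       // -1 free, else antigen node index
  std::vector<int> chain_;      // -1 free, else BCR residue index
  std::vector<int32_t> dist_;   // steps to nearest antigen-adjacent free node
  std::vector<std::array<int, 3>> pos_;
  std::vector<uint8_t> moves_;
  std::vector<uint16_t> codes_;
  std::vector<uint16_t> key_codes_;
  int ninter_ = 0;
  GeomPoseSet ps_;
  std::unordered_map<Key<12>, int, KeyHash<12>> map_;
};

}  // namespace

// ---------------------------------------------------------------------------
// geometry enumeration and residue projection

// [[Rcpp::export]]
SEXP cpp_enumerate_geometry(IntegerMatrix ag_pos, int L, int min_contacts,
                            double max_poses) {
  Enumerator en(ag_pos, L, min_contacts, max_poses);
  XPtr<GeomPoseSet> ptr(new GeomPoseSet(en.run()), true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_geomset_info(SEXP gpxp) {
  XPtr<GeomPoseSet> gp(gpxp);
  return List::create(_["L"] = gp->L, _["min_contacts"] = gp->min_contacts,
                      _["n_profiles"] = static_cast<double>(gp->n_prof()),
                      _["total_poses"] = static_cast<double>(gp->total_poses),
                      _["n_antigen_residues"] = gp->n_ag);
}

// Merge geometric profiles under one residue assignment (codes 1..20).
// [[Rcpp::export]]
SEXP cpp_project_poseset(SEXP gpxp, IntegerVector ag_res) {
  XPtr<GeomPoseSet> gp(gpxp);
  if (ag_res.size() != gp->n_ag)
    stop("residue assignment length %d does not match antigen size %d",
         static_cast<int>(ag_res.size()), gp->n_ag);
  for (int r : ag_res)
    if (r < 1 || r > 20) stop("antigen residue code out of range");
  const int L = gp->L, n_ag = gp->n_ag;
  const int intra_base = L * n_ag;
  PoseSet* out = new PoseSet();
  out->L = L;
  out->min_contacts = gp->min_contacts;
  out->n_ag = n_ag;
  out->total_poses = gp->total_poses;
  std::unordered_map<Key<8>, int, KeyHash<8>> map;
  map.reserve(gp->n_prof() / 4 + 16);
  std::vector<uint8_t> letter;
  letter.reserve(64);
  out->off.push_back(0);
  for (std::size_t p = 0; p < gp->n_prof(); ++p) {
    letter.clear();
    int ni = 0;
    for (std::size_t c = gp->off[p]; c < gp->off[p + 1]; ++c) {
      int code = gp->codes[c];
      if (code < intra_base) {
        int i = code / n_ag, node = code % n_ag;
        letter.push_back(static_cast<uint8_t>(i * 20 + (ag_res[node] - 1)));
        ++ni;
      } else {
        letter.push_back(static_cast<uint8_t>(180 + (code - intra_base)));
      }
    }
    std::sort(letter.begin(), letter.end());
    if (letter.size() > 62) stop("contact profile too large to encode");
    Key<8> k;
    auto* bytes = reinterpret_cast<uint8_t*>(k.w.data());
    bytes[0] = static_cast<uint8_t>(letter.size());
    std::copy(letter.begin(), letter.end(), bytes + 1);
    auto it = map.find(k);
    if (it != map.end()) {
      const int q = it->second;
      out->pose_count[q] += gp->pose_count[p];
      if (gp->rep_pose[p] < out->rep_pose[q]) {
        out->rep_pose[q] = gp->rep_pose[p];
        for (int d = 0; d < 3; ++d)
          out->rep_start[3 * q + d] = gp->rep_start[3 * p + d];
        for (int m = 0; m < L - 1; ++m)
          out->rep_moves[static_cast<std::size_t>(q) * (L - 1) + m] =
              gp->rep_moves[static_cast<std::size_t>(p) * (L - 1) + m];
      }
      continue;
    }
    map.emplace(k, static_cast<int>(out->n_prof()));
    out->codes.insert(out->codes.end(), letter.begin(), letter.end());
    out->off.push_back(out->codes.size());
    out->rep_pose.push_back(gp->rep_pose[p]);
    out->pose_count.push_back(gp->pose_count[p]);
    out->ninter.push_back(static_cast<uint16_t>(ni));
    out->nintra.push_back(static_cast<uint16_t>(letter.size() - ni));
    for (int d = 0; d < 3; ++d)
      out->rep_start.push_back(gp->rep_start[3 * p + d]);
    for (int m = 0; m < L - 1; ++m)
      out->rep_moves.push_back(
          gp->rep_moves[static_cast<std::size_t>(p) * (L - 1) + m]);
  }
  return XPtr<PoseSet>(out, true);
}

// ---------------------------------------------------------------------------
// scoring

void poseset_sort_order(PoseSet& ps, double s) {
  if (!std::isnan(ps.order_s) && ps.order_s == s) return;
  const std::size_t n = ps.n_prof();
  ps.order.resize(n);
  for (std::size_t i = 0; i < n; ++i) ps.order[i] = static_cast<int>(i);
  std::vector<double> w(n);
  for (std::size_t i = 0; i < n; ++i) w[i] = ps.ninter[i] + s * ps.nintra[i];
  std::stable_sort(ps.order.begin(), ps.order.end(),
                   [&](int a, int b) { return w[a] > w[b]; });
  ps.order_w.resize(n);
  for (std::size_t i = 0; i < n; ++i) ps.order_w[i] = w[ps.order[i]];
  ps.order_s = s;
}

ScoreHit score_sequence(PoseSet& ps, const uint8_t* seq, const double* U,
                        double s, double Umin, bool threshold_mode,
                        double thr) {
  poseset_sort_order(ps, s);
  // per-code weight lookup for this sequence
  double w[216];
  for (int i = 0; i < ps.L; ++i)
    for (int r = 0; r < 20; ++r) w[i * 20 + r] = U[seq[i] + 20 * r];
  for (int j = 0; j < ps.L; ++j)
    for (int i = j + 1; i < ps.L; ++i)
      if (i - j >= 2)
        w[180 + j * ps.L - j * (j + 1) / 2 + (i - j - 1)] =
            s * U[seq[j] + 20 * seq[i]];

  const double neg = std::min(Umin, 0.0);
  ScoreHit best{R_PosInf, std::numeric_limits<long long>::max(), -1};
  for (std::size_t k = 0; k < ps.order.size(); ++k) {
    const double bound = ps.order_w[k] * neg;
    if (threshold_mode) {
      if (best.energy <= thr) return best;   // early accept
      if (bound > thr) return best;          // no profile can reach thr
    } else if (bound > best.energy) {
      break;  // remaining profiles cannot improve the minimum
    }
    const int p = ps.order[k];
    double e = 0.0;
    for (std::size_t c = ps.off[p]; c < ps.off[p + 1]; ++c) e += w[ps.codes[c]];
    if (e < best.energy || (e == best.energy && ps.rep_pose[p] < best.pose)) {
      best.energy = e;
      best.pose = ps.rep_pose[p];
      best.prof = p;
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_poseset_info(SEXP psxp) {
  XPtr<PoseSet> ps(psxp);
  return List::create(_["L"] = ps->L, _["min_contacts"] = ps->min_contacts,
                      _["n_profiles"] = static_cast<double>(ps->n_prof()),
                      _["total_poses"] = static_cast<double>(ps->total_poses),
                      _["n_antigen_residues"] = ps->n_ag);
}

// Decode profiles for inspection: inter contacts (bcr index, antigen residue
// code), intra pairs, pose count and representative pose geometry.
// [[Rcpp::export]]
List cpp_poseset_profiles(SEXP psxp, IntegerVector idx) {
  XPtr<PoseSet> ps(psxp);
  const int L = ps->L;
  List out(idx.size());
  for (int q = 0; q < idx.size(); ++q) {
    int p = idx[q] - 1;
    if (p < 0 || p >= static_cast<int>(ps->n_prof()))
      stop("profile index out of range");
    std::vector<int> ii, ir, aj, ai;
    for (std::size_t c = ps->off[p]; c < ps->off[p + 1]; ++c) {
      int code = ps->codes[c];
      if (code < 180) {
        ii.push_back(code / 20 + 1);
        ir.push_back(code % 20 + 1);
      } else {
        int r = code - 180;
        int j = 0;
        while (r >= L - j - 1) { r -= L - j - 1; ++j; }
        aj.push_back(j + 1);
        ai.push_back(j + r + 2);
      }
    }
    IntegerVector start(3);
    for (int d = 0; d < 3; ++d) start[d] = ps->rep_start[3 * p + d];
    IntegerVector mv(L - 1);
    for (int m = 0; m < L - 1; ++m)
      mv[m] = ps->rep_moves[static_cast<std::size_t>(p) * (L - 1) + m] + 1;
    out[q] = List::create(
        _["inter_bcr"] = wrap(ii), _["inter_res"] = wrap(ir),
        _["intra_i"] = wrap(aj), _["intra_j"] = wrap(ai),
        _["pose_count"] = static_cast<double>(ps->pose_count[p]),
        _["rep_pose"] = static_cast<double>(ps->rep_pose[p] + 1),
        _["start"] = start, _["moves"] = mv);
  }
  return out;
}

static double matrix_min(const NumericMatrix& U) {
  double m = R_PosInf;
  for (double v : U) m = std::min(m, v);
  return m;
}

// [[Rcpp::export]]
List cpp_score_sequences(SEXP psxp, IntegerMatrix seqs, NumericMatrix U,
                         double s) {
  XPtr<PoseSet> ps(psxp);
  if (seqs.ncol() != ps->L)
    stop("sequence length %d does not match pose set BCR length %d",
         seqs.ncol(), ps->L);
  if (ps->n_prof() == 0)
    stop("pose set is empty: antigen unbindable at this min_contacts");
  const double Umin = matrix_min(U);
  const int n = seqs.nrow();
  NumericVector energy(n), pose(n);
  IntegerVector prof(n);
  std::vector<uint8_t> seq(ps->L);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < ps->L; ++j)
      seq[j] = static_cast<uint8_t>(seqs(i, j) - 1);
    ScoreHit h = score_sequence(*ps, seq.data(), U.begin(), s, Umin, false, 0);
    energy[i] = h.energy;
    pose[i] = static_cast<double>(h.pose + 1);
    prof[i] = h.prof + 1;
  }
  return List::create(_["energy"] = energy, _["pose"] = pose,
                      _["profile"] = prof);
}

// Rejection-sample founder sequences whose optimal energy is <= thrE.
// Uses R's RNG so that set.seed() at the R level governs reproducibility.
// [[Rcpp::export]]
List cpp_sample_founders(SEXP psxp, NumericMatrix U, double s, int quota,
                         double thrE, double max_attempts) {
  XPtr<PoseSet> ps(psxp);
  if (ps->n_prof() == 0)
    stop("pose set is empty: antigen unbindable at this min_contacts");
  const double Umin = matrix_min(U);
  const int L = ps->L;
  IntegerMatrix acc(quota, L);
  NumericVector accE(quota);
  std::vector<uint8_t> seq(L);
  double attempts = 0, bestSeen = R_PosInf;
  int got = 0;
  while (got < quota) {
    if (attempts >= max_attempts)
      stop("founder sampling: acceptance too low (%d/%d after %.0f attempts; "
           "best energy seen %.2f vs threshold %.2f)",
           got, quota, attempts, bestSeen, thrE);
    ++attempts;
    for (int j = 0; j < L; ++j)
      seq[j] = static_cast<uint8_t>(R::unif_rand() * 20);
    ScoreHit h = score_sequence(*ps, seq.data(), U.begin(), s, Umin, true, thrE);
    bestSeen = std::min(bestSeen, h.energy);
    if (h.energy <= thrE) {
      // exact optimum for the accepted sequence
      ScoreHit ex = score_sequence(*ps, seq.data(), U.begin(), s, Umin, false, 0);
      for (int j = 0; j < L; ++j) acc(got, j) = seq[j] + 1;
      accE[got] = ex.energy;
      ++got;
    }
    if (static_cast<long long>(attempts) % 4096 == 0) checkUserInterrupt();
  }
  return List::create(_["seqs"] = acc, _["energy"] = accE,
                      _["attempts"] = attempts);
}

// SHM operator: each residue independently replaced, with probability p, by a
// uniform draw among the 19 other residues.  Uses R's RNG.
// [[Rcpp::export]]
List cpp_shm_mutate(IntegerMatrix seqs, double p) {
  const int n = seqs.nrow(), L = seqs.ncol();
  IntegerMatrix out(n, L);
  IntegerVector nch(n);
  for (int i = 0; i < n; ++i) {
    int ch = 0;
    for (int j = 0; j < L; ++j) {
      int r = seqs(i, j);
      if (R::unif_rand() < p) {
        int nr = static_cast<int>(R::unif_rand() * 19) + 1;
        if (nr >= r) ++nr;
        r = nr;
        ++ch;
      }
      out(i, j) = r;
    }
    nch[i] = ch;
  }
  return List::create(_["seqs"] = out, _["n_changes"] = nch);
}
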