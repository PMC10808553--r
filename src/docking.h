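#pragma once

#include <Rcpp.h>
#include <array>
#include <cstring>
#include <cstdint>
#include <cmath>
#include <limits>
#include <string>
#include <unordered_map>
#include <vector>

// Exhaustive docking is split into two sequence-independent stages:
//
// 1. Geometry enumeration (GeomPoseSet): every self-avoiding L-chain around
//    the antigen with >= min_contacts non-covalent antigen adjacencies,
//    reduced to *geometric* contact profiles that record which antigen NODE
//    each BCR residue touches.  This depends only on the antigen's shape and
//    is reused across residue reassignments of the same structure.
//
// 2. Residue projection (PoseSet): for one residue assignment, geometric
//    profiles are mapped to residue-letter profiles (which antigen LETTER a
//    BCR position touches) and merged; poses with identical letter profiles
//    have identical energy for every BCR sequence, so scoring runs over the
//    merged set only.
//
// Contact codes:
//   GeomPoseSet (uint16): inter (bcr i, antigen node k) -> i*n_ag + k
//                         intra pair rank r              -> L*n_ag + r
//   PoseSet (uint8):      inter (bcr i, antigen letter a) -> i*20 + a  (<180)
//                         intra pair rank r               -> 180 + r
// The pair rank is the lexicographic rank among all C(L,2) index pairs,
// which needs L <= 9 for the uint8 encoding.
struct GeomPoseSet {
  int L = 0;
  int min_contacts = 1;
  int n_ag = 0;
  long long total_poses = 0;
  std::vector<std::size_t> off;    // n_prof + 1
  std::vector<uint16_t> codes;     // sorted code multiset per profile
  std::vector<long long> rep_pose;
  std::vector<long long> pose_count;
  std::vector<int32_t> rep_start;  // 3 per profile
  std::vector<uint8_t> rep_moves;  // L-1 per profile
  std::size_t n_prof() const { return rep_pose.size(); }
};

struct PoseSet {
  int L = 0;
  int min_contacts = 1;
  int n_ag = 0;
  long long total_poses = 0;

  std::vector<std::size_t> off;
  std::vector<uint8_t> codes;
  std::vector<long long> rep_pose;
  std::vector<long long> pose_count;
  std::vector<uint16_t> ninter, nintra;
  std::vector<int32_t> rep_start;
  std::vector<uint8_t> rep_moves;

  // scoring order cache: profile indices sorted by ninter + s*nintra (desc)
  double order_s = std::numeric_limits<double>::quiet_NaN();
  std::vector<int> order;
  std::vector<double> order_w;

  std::size_t n_prof() const { return rep_pose.size(); }
};

struct ScoreHit {
  double energy;
  long long pose;  // 0-based representative pose index of the optimum
  int prof;        // 0-based profile index, -1 if none
};

extern const int DIRS[6][3];

void poseset_sort_order(PoseSet& ps, double s);

// Exact minimum-energy scan with branch-and-bound early stop.  In
// `threshold_mode` the scan stops as soon as the accept/reject decision at
// `thr` is certain; the returned energy is then only exact on the accept
// side.
ScoreHit score_sequence(PoseSet& ps, const uint8_t* seq, const double* U,
                        double s, double Umin, bool threshold_mode,
                        double thr);
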