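// Lattice Monte-Carlo engine for a self-avoiding rod-coil multi-block chain.
// Cubic lattice, hard walls, Metropolis at kT = 1. Energy:
//   E = -eps_rr * (# non-bonded rod-rod nearest-neighbour contacts)
//       + kappa  * (# non-collinear bond pairs whose central bead is a rod)
// Local move set: end rotation, kink-jump (corner flip) and two-bead
// crankshaft; optional reptation. Reptation slides the label pattern along
// the spatial backbone, so its energy change is non-local and is recomputed
// in full. Uses R's RNG so set.seed() in R governs reproducibility.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

struct Vec3 { int x, y, z; };

struct Lattice {
  int L;
  std::vector<int> occ; // bead index + 1, 0 = empty
  Lattice(int L_) : L(L_), occ((size_t)L_ * L_ * L_, 0) {}
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < L && y >= 0 && y < L && z >= 0 && z < L;
  }
  inline size_t idx(int x, int y, int z) const {
    return ((size_t)z * L + y) * L + x;
  }
};

static double full_energy(const IntegerMatrix& C, const LogicalVector& rod,
                          const Lattice& lat, double eps, double kap) {
  int N = C.nrow();
  double E = 0.0;
  if (eps > 0) {
    for (int i = 0; i < N; ++i) {
      if (!rod[i]) continue;
      for (int d = 0; d < 6; ++d) {
        int x = C(i, 0) + DX[d], y = C(i, 1) + DY[d], z = C(i, 2) + DZ[d];
        if (!lat.inside(x, y, z)) continue;
        int j = lat.occ[lat.idx(x, y, z)] - 1;
        if (j > i && rod[j] && j != i + 1) E -= eps;
      }
    }
  }
  if (kap > 0) {
    for (int i = 1; i < N - 1; ++i) {
      if (!rod[i]) continue;
      int v1x = C(i, 0) - C(i - 1, 0), v1y = C(i, 1) - C(i - 1, 1),
          v1z = C(i, 2) - C(i - 1, 2);
      int v2x = C(i + 1, 0) - C(i, 0), v2y = C(i + 1, 1) - C(i, 1),
          v2z = C(i + 1, 2) - C(i, 2);
      if (v1x != v2x || v1y != v2y || v1z != v2z) E += kap;
    }
  }
  return E;
}

// --- generic 1- or 2-bead move machinery -------------------------------
// moved[] lists bead indices with proposed positions newp[]; positions of
// beads in moved[] are looked up there, everything else in C.

struct Move {
  int n;          // 1 or 2 moved beads
  int bead[2];
  Vec3 newp[2];
};

static inline bool get_pos(const IntegerMatrix& C, const Move& mv, bool use_new,
                           int k, Vec3& out) {
  for (int m = 0; m < mv.n; ++m)
    if (mv.bead[m] == k) {
      out = use_new ? mv.newp[m]
                    : Vec3{C(k, 0), C(k, 1), C(k, 2)};
      return true;
    }
  out = Vec3{C(k, 0), C(k, 1), C(k, 2)};
  return false;
}

// rod-rod contacts between one moved bead (at p) and static beads only
static int contacts_static(const IntegerMatrix& C, const LogicalVector& rod,
                           const Lattice& lat, const Move& mv, int i, Vec3 p) {
  if (!rod[i]) return 0;
  int c = 0;
  for (int d = 0; d < 6; ++d) {
    int nx = p.x + DX[d], ny = p.y + DY[d], nz = p.z + DZ[d];
    if (!lat.inside(nx, ny, nz)) continue;
    int j = lat.occ[lat.idx(nx, ny, nz)] - 1;
    if (j < 0 || !rod[j]) continue;
    if (j == i - 1 || j == i + 1 || j == i) continue;
    bool is_moved = false;
    for (int m = 0; m < mv.n; ++m) if (mv.bead[m] == j) is_moved = true;
    if (is_moved) continue;   // moved-moved pairs handled separately
    ++c;
  }
  return c;
}

// bending term of the angle centred at c, with moved-bead overrides
static double bend_term(const IntegerMatrix& C, const LogicalVector& rod,
                        double kap, int N, const Move& mv, bool use_new, int c) {
  if (c < 1 || c > N - 2 || !rod[c]) return 0.0;
  Vec3 a, b, d;
  get_pos(C, mv, use_new, c - 1, a);
  get_pos(C, mv, use_new, c, b);
  get_pos(C, mv, use_new, c + 1, d);
  int v1x = b.x - a.x, v1y = b.y - a.y, v1z = b.z - a.z;
  int v2x = d.x - b.x, v2y = d.y - b.y, v2z = d.z - b.z;
  return (v1x != v2x || v1y != v2y || v1z != v2z) ? kap : 0.0;
}

// non-bonded rod-rod contact between the two moved beads themselves
static int moved_pair_contact(const LogicalVector& rod, const Move& mv,
                              const IntegerMatrix& C, bool use_new) {
  if (mv.n < 2) return 0;
  int i = mv.bead[0], j = mv.bead[1];
  if (!rod[i] || !rod[j] || abs(i - j) == 1) return 0;
  Vec3 p, q;
  get_pos(C, mv, use_new, i, p);
  get_pos(C, mv, use_new, j, q);
  int d = abs(p.x - q.x) + abs(p.y - q.y) + abs(p.z - q.z);
  return d == 1 ? 1 : 0;
}

static double move_delta(const IntegerMatrix& C, const LogicalVector& rod,
                         const Lattice& lat, double eps, double kap,
                         const Move& mv) {
  int N = C.nrow();
  double dE = 0.0;
  if (eps > 0) {
    int oldc = 0, newc = 0;
    for (int m = 0; m < mv.n; ++m) {
      int i = mv.bead[m];
      Vec3 po{C(i, 0), C(i, 1), C(i, 2)};
      oldc += contacts_static(C, rod, lat, mv, i, po);
      newc += contacts_static(C, rod, lat, mv, i, mv.newp[m]);
    }
    oldc += moved_pair_contact(rod, mv, C, false);
    newc += moved_pair_contact(rod, mv, C, true);
    dE -= eps * (newc - oldc);
  }
  if (kap > 0) {
    int lo = mv.bead[0], hi = mv.bead[mv.n - 1];
    for (int c = lo - 1; c <= hi + 1; ++c)
      dE += bend_term(C, rod, kap, N, mv, true, c) -
            bend_term(C, rod, kap, N, mv, false, c);
  }
  return dE;
}

static void apply_move(IntegerMatrix& C, Lattice& lat, const Move& mv) {
  for (int m = 0; m < mv.n; ++m) {
    int i = mv.bead[m];
    lat.occ[lat.idx(C(i, 0), C(i, 1), C(i, 2))] = 0;
  }
  for (int m = 0; m < mv.n; ++m) {
    int i = mv.bead[m];
    C(i, 0) = mv.newp[m].x; C(i, 1) = mv.newp[m].y; C(i, 2) = mv.newp[m].z;
    lat.occ[lat.idx(mv.newp[m].x, mv.newp[m].y, mv.newp[m].z)] = i + 1;
  }
}

// is cell free, treating the moved beads' old positions as vacated?
static bool cell_free(const IntegerMatrix& C, const Lattice& lat,
                      const Move& mv, int x, int y, int z) {
  if (!lat.inside(x, y, z)) return false;
  int j = lat.occ[lat.idx(x, y, z)] - 1;
  if (j < 0) return true;
  for (int m = 0; m < mv.n; ++m) if (mv.bead[m] == j) return true;
  return false;
}

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(IntegerMatrix coords, LogicalVector rod, int L,
                double eps, double kap, double n_steps_d,
                bool use_local, bool use_end, bool use_reptation,
                double reptation_prob,
                int trace_every, int snapshot_every) {
  RNGScope scope;
  long long n_steps = (long long)n_steps_d;
  int N = coords.nrow();
  IntegerMatrix C = clone(coords);
  Lattice lat(L);
  for (int i = 0; i < N; ++i) {
    if (!lat.inside(C(i, 0), C(i, 1), C(i, 2)))
      stop("initial conformation is outside the lattice");
    size_t k = lat.idx(C(i, 0), C(i, 1), C(i, 2));
    if (lat.occ[k]) stop("initial conformation is self-intersecting");
    lat.occ[k] = i + 1;
  }
  for (int i = 1; i < N; ++i) {
    int d = abs(C(i, 0) - C(i - 1, 0)) + abs(C(i, 1) - C(i - 1, 1)) +
            abs(C(i, 2) - C(i - 1, 2));
    if (d != 1) stop("consecutive beads are not lattice-adjacent");
  }

  double E = full_energy(C, rod, lat, eps, kap);
  long long accepted = 0;
  std::vector<double> trace_E;
  std::vector<double> trace_step;
  List snapshots;
  std::vector<double> snap_steps;

  for (long long step = 1; step <= n_steps; ++step) {
    do {
      double u = unif_rand();
      if (use_reptation && u < reptation_prob && N >= 2) {
        bool headward = unif_rand() < 0.5;
        int dir = (int)(unif_rand() * 6); if (dir > 5) dir = 5;
        int grow = headward ? N - 1 : 0;  // end that gains the new bead
        int shed = headward ? 0 : N - 1;  // end that is vacated
        int nx = C(grow, 0) + DX[dir], ny = C(grow, 1) + DY[dir],
            nz = C(grow, 2) + DZ[dir];
        if (!lat.inside(nx, ny, nz)) break;
        int occ_there = lat.occ[lat.idx(nx, ny, nz)];
        if (occ_there != 0 && occ_there != shed + 1) break;
        IntegerMatrix Cn(N, 3);
        if (headward) {
          for (int i = 0; i < N - 1; ++i)
            for (int k = 0; k < 3; ++k) Cn(i, k) = C(i + 1, k);
          Cn(N - 1, 0) = nx; Cn(N - 1, 1) = ny; Cn(N - 1, 2) = nz;
        } else {
          for (int i = 1; i < N; ++i)
            for (int k = 0; k < 3; ++k) Cn(i, k) = C(i - 1, k);
          Cn(0, 0) = nx; Cn(0, 1) = ny; Cn(0, 2) = nz;
        }
        for (int i = 0; i < N; ++i)
          lat.occ[lat.idx(C(i, 0), C(i, 1), C(i, 2))] = 0;
        for (int i = 0; i < N; ++i)
          lat.occ[lat.idx(Cn(i, 0), Cn(i, 1), Cn(i, 2))] = i + 1;
        double En = full_energy(Cn, rod, lat, eps, kap);
        double dE = En - E;
        if (dE <= 0 || unif_rand() < exp(-dE)) {
          C = Cn; E = En; ++accepted;
        } else { // restore
          for (int i = 0; i < N; ++i)
            lat.occ[lat.idx(Cn(i, 0), Cn(i, 1), Cn(i, 2))] = 0;
          for (int i = 0; i < N; ++i)
            lat.occ[lat.idx(C(i, 0), C(i, 1), C(i, 2))] = i + 1;
        }
        break;
      }

      Move mv;
      bool crank = use_local && N >= 4 && unif_rand() < 0.5;
      if (crank) {
        // two-bead crankshaft: beads i, i+1 with anchors i-1, i+2 one
        // lattice unit apart rotate to one of the 3 other perpendicular
        // offsets (symmetric proposal)
        int i = 1 + (int)(unif_rand() * (N - 3));
        if (i > N - 3) i = N - 3;
        int ax = C(i - 1, 0), ay = C(i - 1, 1), az = C(i - 1, 2);
        int bx = C(i + 2, 0), by = C(i + 2, 1), bz = C(i + 2, 2);
        int ux = bx - ax, uy = by - ay, uz = bz - az;
        if (abs(ux) + abs(uy) + abs(uz) != 1) break;
        int wx = C(i, 0) - ax, wy = C(i, 1) - ay, wz = C(i, 2) - az;
        // enumerate the 4 unit offsets perpendicular to u, drop current
        int cand[3][3]; int nc = 0;
        for (int d = 0; d < 6; ++d) {
          if (DX[d] == ux && DY[d] == uy && DZ[d] == uz) continue;
          if (DX[d] == -ux && DY[d] == -uy && DZ[d] == -uz) continue;
          if (DX[d] == wx && DY[d] == wy && DZ[d] == wz) continue;
          cand[nc][0] = DX[d]; cand[nc][1] = DY[d]; cand[nc][2] = DZ[d]; ++nc;
        }
        int pick = (int)(unif_rand() * nc); if (pick > nc - 1) pick = nc - 1;
        mv.n = 2;
        mv.bead[0] = i; mv.bead[1] = i + 1;
        mv.newp[0] = Vec3{ax + cand[pick][0], ay + cand[pick][1],
                          az + cand[pick][2]};
        mv.newp[1] = Vec3{bx + cand[pick][0], by + cand[pick][1],
                          bz + cand[pick][2]};
      } else {
        int i = (int)(unif_rand() * N); if (i > N - 1) i = N - 1;
        mv.n = 1; mv.bead[0] = i;
        if (i == 0 || i == N - 1) {
          if (!use_end) break;
          int anchor = (i == 0) ? 1 : N - 2;
          int dir = (int)(unif_rand() * 6); if (dir > 5) dir = 5;
          mv.newp[0] = Vec3{C(anchor, 0) + DX[dir], C(anchor, 1) + DY[dir],
                            C(anchor, 2) + DZ[dir]};
        } else {
          if (!use_local) break;
          int dx = C(i + 1, 0) - C(i - 1, 0), dy = C(i + 1, 1) - C(i - 1, 1),
              dz = C(i + 1, 2) - C(i - 1, 2);
          if (dx * dx + dy * dy + dz * dz != 2) break; // collinear: no kink
          mv.newp[0] = Vec3{C(i - 1, 0) + C(i + 1, 0) - C(i, 0),
                            C(i - 1, 1) + C(i + 1, 1) - C(i, 1),
                            C(i - 1, 2) + C(i + 1, 2) - C(i, 2)};
        }
      }
      bool free_ok = true;
      for (int m = 0; m < mv.n; ++m)
        if (!cell_free(C, lat, mv, mv.newp[m].x, mv.newp[m].y, mv.newp[m].z))
          free_ok = false;
      // a moved bead may not land on another moved bead's new position
      if (mv.n == 2 && mv.newp[0].x == mv.newp[1].x &&
          mv.newp[0].y == mv.newp[1].y && mv.newp[0].z == mv.newp[1].z)
        free_ok = false;
      if (!free_ok) break;
      // no-op guard (end move may propose the current position)
      if (mv.n == 1 && mv.newp[0].x == C(mv.bead[0], 0) &&
          mv.newp[0].y == C(mv.bead[0], 1) && mv.newp[0].z == C(mv.bead[0], 2))
        break;
      double dE = move_delta(C, rod, lat, eps, kap, mv);
      if (dE <= 0 || unif_rand() < exp(-dE)) {
        apply_move(C, lat, mv);
        E += dE; ++accepted;
      }
    } while (0);

    if (trace_every > 0 && step % trace_every == 0) {
      trace_E.push_back(E);
      trace_step.push_back((double)step);
    }
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      snapshots.push_back(clone(C));
      snap_steps.push_back((double)step);
    }
  }

  return List::create(
    _["coords"] = C, _["energy"] = E,
    _["trace_step"] = NumericVector(trace_step.begin(), trace_step.end()),
    _["trace_energy"] = NumericVector(trace_E.begin(), trace_E.end()),
    _["accepted"] = (double)accepted, _["n_steps"] = (double)n_steps,
    _["snapshots"] = snapshots,
    _["snapshot_step"] = NumericVector(snap_steps.begin(), snap_steps.end()));
}
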