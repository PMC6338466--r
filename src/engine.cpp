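// Compiled kernels for the 2D filament-motor Langevin engine.
//
// Coordinates passed in and out are unwrapped; the minimum-image convention
// is applied to every pair vector, so interactions are computed in the
// periodic box of edge Lb.  All pair interactions assume cutoff < Lb/2.
//
// Determinism: a self-contained xoshiro256++ generator (seeded via
// splitmix64) drives the thermostat and the motor sampling, so a run is
// bit-reproducible for a given master seed on a single thread.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----

struct Xoshiro {
  uint64_t s[4];
  double cached_gauss;
  bool has_cached;

  explicit Xoshiro(uint64_t seed) : cached_gauss(0.0), has_cached(false) {
    // splitmix64 seeding
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1), never exactly 0
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // standard normal, polar Box-Muller with cache
  inline double gauss() {
    if (has_cached) {
      has_cached = false;
      return cached_gauss;
    }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    cached_gauss = v * f;
    has_cached = true;
    return u * f;
  }
};

static inline uint64_t substream_seed(uint64_t master, uint64_t stream) {
  // splitmix64 step of (master ^ stream-tag) keeps substreams decorrelated
  uint64_t x = master + 0x9E3779B97f4A7C15ULL * (stream + 1);
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// ------------------------------------------------------------- helpers ----

static inline double min_image(double d, double Lb) {
  return d - Lb * std::nearbyint(d / Lb);
}

// bead orientations: p_i points from bead i to bead i+1 within the same
// filament; the last bead of a filament reuses the preceding bond direction.
static void bead_orientations(const std::vector<double>& x,
                              const IntegerVector& fil,
                              double Lb,
                              std::vector<double>& p) {
  const int n = fil.size();
  for (int i = 0; i < n; ++i) {
    int j;
    if (i + 1 < n && fil[i + 1] == fil[i]) {
      j = i; // bond i -> i+1
    } else if (i > 0 && fil[i - 1] == fil[i]) {
      j = i - 1; // last bead: bond (i-1) -> i
    } else {
      p[2 * i] = 1.0; // single-bead filament: arbitrary fixed direction
      p[2 * i + 1] = 0.0;
      continue;
    }
    double dx = min_image(x[2 * (j + 1)] - x[2 * j], Lb);
    double dy = min_image(x[2 * (j + 1) + 1] - x[2 * j + 1], Lb);
    double r = std::sqrt(dx * dx + dy * dy);
    if (r <= 0.0) stop("zero-length bond while computing bead orientations");
    p[2 * i] = dx / r;
    p[2 * i + 1] = dy / r;
  }
}

// ------------------------------------------------------------ cell list ---

// Half-list (i<j) of bead pairs within `cutoff`, built via a cell list with
// automatic fallback to the all-pairs scan when the box holds < 3 cells per
// edge.  Same-filament adjacent (bonded) pairs are excluded when
// `exclude_bonded` is true.
static void build_pairs(const std::vector<double>& x,
                        const IntegerVector& fil,
                        double Lb, double cutoff, bool exclude_bonded,
                        std::vector<int>& pi, std::vector<int>& pj) {
  const int n = (int)x.size() / 2;
  pi.clear();
  pj.clear();
  const double c2 = cutoff * cutoff;
  int ncell = (int)std::floor(Lb / cutoff);
  if (ncell < 3) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (exclude_bonded && fil[i] == fil[j] && j == i + 1) continue;
        double dx = min_image(x[2 * i] - x[2 * j], Lb);
        double dy = min_image(x[2 * i + 1] - x[2 * j + 1], Lb);
        if (dx * dx + dy * dy < c2) {
          pi.push_back(i);
          pj.push_back(j);
        }
      }
    }
    return;
  }
  const double cell = Lb / ncell;
  std::vector<int> head(ncell * ncell, -1), nxt(n, -1), cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    double wx = x[2 * i] - Lb * std::floor(x[2 * i] / Lb);
    double wy = x[2 * i + 1] - Lb * std::floor(x[2 * i + 1] / Lb);
    int ix = (int)(wx / cell);
    int iy = (int)(wy / cell);
    if (ix >= ncell) ix = ncell - 1;
    if (iy >= ncell) iy = ncell - 1;
    cx[i] = ix;
    cy[i] = iy;
    int c = iy * ncell + ix;
    nxt[i] = head[c];
    head[c] = i;
  }
  for (int i = 0; i < n; ++i) {
    for (int ox = -1; ox <= 1; ++ox) {
      for (int oy = -1; oy <= 1; ++oy) {
        int ix = (cx[i] + ox + ncell) % ncell;
        int iy = (cy[i] + oy + ncell) % ncell;
        for (int j = head[iy * ncell + ix]; j >= 0; j = nxt[j]) {
          if (j <= i) continue;
          if (exclude_bonded && fil[i] == fil[j] && j == i + 1) continue;
          double dx = min_image(x[2 * i] - x[2 * j], Lb);
          double dy = min_image(x[2 * i + 1] - x[2 * j + 1], Lb);
          if (dx * dx + dy * dy < c2) {
            pi.push_back(i);
            pj.push_back(j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix x, IntegerVector fil,
                                 double Lb, double cutoff,
                                 bool exclude_bonded) {
  const int n = x.nrow();
  std::vector<double> xx(2 * n);
  for (int i = 0; i < n; ++i) {
    xx[2 * i] = x(i, 0);
    xx[2 * i + 1] = x(i, 1);
  }
  std::vector<int> pi, pj;
  build_pairs(xx, fil, Lb, cutoff, exclude_bonded, pi, pj);
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k] + 1; // 1-based for R
    out(k, 1) = pj[k] + 1;
  }
  return out;
}

// --------------------------------------------------------- force terms ----

struct ForceAccum {
  std::vector<double> F;
  double e_bond, e_angle, e_wca, e_mot;
  int n_mot;
  explicit ForceAccum(int n)
      : F(2 * n, 0.0), e_bond(0), e_angle(0), e_wca(0), e_mot(0), n_mot(0) {}
};

static void add_bond_forces(const std::vector<double>& x,
                            const IntegerVector& fil, double Lb, double ks,
                            double r0, ForceAccum& acc, bool want_energy) {
  const int n = fil.size();
  for (int i = 0; i + 1 < n; ++i) {
    if (fil[i + 1] != fil[i]) continue;
    double dx = min_image(x[2 * (i + 1)] - x[2 * i], Lb);
    double dy = min_image(x[2 * (i + 1) + 1] - x[2 * i + 1], Lb);
    double r = std::sqrt(dx * dx + dy * dy);
    if (r <= 0.0)
      stop("coincident adjacent beads (%d,%d): bond force undefined", i + 1,
           i + 2);
    double f = -ks * (r - r0) / r; // on bead i+1 along +d
    acc.F[2 * (i + 1)] += f * dx;
    acc.F[2 * (i + 1) + 1] += f * dy;
    acc.F[2 * i] -= f * dx;
    acc.F[2 * i + 1] -= f * dy;
    if (want_energy) acc.e_bond += 0.5 * ks * (r - r0) * (r - r0);
  }
}

static void add_angle_forces(const std::vector<double>& x,
                             const IntegerVector& fil, double Lb,
                             double kappa, double r0, ForceAccum& acc,
                             bool want_energy) {
  const int n = fil.size();
  const double kb = kappa / r0;
  for (int i = 1; i + 1 < n; ++i) {
    if (fil[i - 1] != fil[i] || fil[i + 1] != fil[i]) continue;
    double ax = min_image(x[2 * i] - x[2 * (i - 1)], Lb);
    double ay = min_image(x[2 * i + 1] - x[2 * (i - 1) + 1], Lb);
    double bx = min_image(x[2 * (i + 1)] - x[2 * i], Lb);
    double by = min_image(x[2 * (i + 1) + 1] - x[2 * i + 1], Lb);
    double na2 = ax * ax + ay * ay, nb2 = bx * bx + by * by;
    double na = std::sqrt(na2), nb = std::sqrt(nb2);
    if (na <= 0.0 || nb <= 0.0)
      stop("degenerate angle triplet at bead %d", i + 1);
    double inv = 1.0 / (na * nb);
    double c = (ax * bx + ay * by) * inv;
    // dc/da and dc/db
    double dax = bx * inv - c * ax / na2;
    double day = by * inv - c * ay / na2;
    double dbx = ax * inv - c * bx / nb2;
    double dby = ay * inv - c * by / nb2;
    // U = kb (1 - c): F_first = -dU/dr_{i-1} = -kb * dc/da * (-1)^... see below
    // grad_{r_{i-1}} c = -dc/da ; grad_{r_{i+1}} c = dc/db
    double f1x = -kb * dax, f1y = -kb * day;  // on bead i-1
    double f3x = kb * dbx, f3y = kb * dby;    // on bead i+1
    acc.F[2 * (i - 1)] += f1x;
    acc.F[2 * (i - 1) + 1] += f1y;
    acc.F[2 * (i + 1)] += f3x;
    acc.F[2 * (i + 1) + 1] += f3y;
    acc.F[2 * i] -= f1x + f3x;
    acc.F[2 * i + 1] -= f1y + f3y;
    if (want_energy) acc.e_angle += kb * (1.0 - c);
  }
}

static inline void wca_pair(const std::vector<double>& x, int i, int j,
                            double Lb, double eps, double sigma,
                            ForceAccum& acc, bool want_energy) {
  const double rc2 = std::pow(2.0, 1.0 / 3.0) * sigma * sigma;
  double dx = min_image(x[2 * i] - x[2 * j], Lb);
  double dy = min_image(x[2 * i + 1] - x[2 * j + 1], Lb);
  double r2 = dx * dx + dy * dy;
  if (r2 >= rc2) return;
  if (r2 < 1e-12 * sigma * sigma)
    stop("bead overlap r ~ 0 between beads %d and %d", i + 1, j + 1);
  double sr2 = sigma * sigma / r2;
  double sr6 = sr2 * sr2 * sr2;
  double f = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r2; // on i along +d
  acc.F[2 * i] += f * dx;
  acc.F[2 * i + 1] += f * dy;
  acc.F[2 * j] -= f * dx;
  acc.F[2 * j + 1] -= f * dy;
  if (want_energy) acc.e_wca += 4.0 * eps * (sr6 * sr6 - sr6) + eps;
}

// Effective-motor sampling + force.  The binding geometry selects antialigned
// pairs such that the (almost always extended) spring propels each filament
// toward its + end: the printed eligibility inequalities are applied to the
// vector d = r_j - r_i.
static void add_motor_forces(const std::vector<double>& x,
                             const IntegerVector& fil,
                             const std::vector<double>& p,
                             const std::vector<int>& pi,
                             const std::vector<int>& pj, double Lb, double km,
                             double deq, double dtm, double pa, double kBT,
                             Xoshiro& rng, ForceAccum& acc, bool want_energy,
                             std::vector<int>* keep) {
  if (pa <= 0.0) return;
  const double dt2 = dtm * dtm;
  for (size_t k = 0; k < pi.size(); ++k) {
    int i = pi[k], j = pj[k];
    if (fil[i] == fil[j]) continue;
    double dx = min_image(x[2 * j] - x[2 * i], Lb); // d = r_j - r_i
    double dy = min_image(x[2 * j + 1] - x[2 * i + 1], Lb);
    double r2 = dx * dx + dy * dy;
    if (r2 >= dt2) continue;
    if (!(p[2 * i] * dx + p[2 * i + 1] * dy > 0.0)) continue;
    if (!(p[2 * j] * dx + p[2 * j + 1] * dy < 0.0)) continue;
    double m = std::sqrt(r2);
    double e = m - deq;
    double rate = pa * std::exp(-0.5 * km * e * e / kBT);
    if (rng.unif() >= rate) continue;
    // spring: force on i is +km*e*dhat (toward j when extended)
    double f = km * e / m;
    acc.F[2 * i] += f * dx;
    acc.F[2 * i + 1] += f * dy;
    acc.F[2 * j] -= f * dx;
    acc.F[2 * j + 1] -= f * dy;
    acc.n_mot += 1;
    if (want_energy) acc.e_mot += 0.5 * km * e * e;
    if (keep) keep->push_back((int)k);
  }
}

// ------------------------------------------------- exported force terms ---

static std::vector<double> flatten(const NumericMatrix& x) {
  std::vector<double> xx(2 * x.nrow());
  for (int i = 0; i < x.nrow(); ++i) {
    xx[2 * i] = x(i, 0);
    xx[2 * i + 1] = x(i, 1);
  }
  return xx;
}

static List pack_forces(const ForceAccum& acc, double energy) {
  int n = (int)acc.F.size() / 2;
  NumericMatrix F(n, 2);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = acc.F[2 * i];
    F(i, 1) = acc.F[2 * i + 1];
  }
  return List::create(_["forces"] = F, _["energy"] = energy);
}

// [[Rcpp::export]]
List cpp_bond_forces(NumericMatrix x, IntegerVector fil, double Lb, double ks,
                     double r0) {
  std::vector<double> xx = flatten(x);
  ForceAccum acc(x.nrow());
  add_bond_forces(xx, fil, Lb, ks, r0, acc, true);
  return pack_forces(acc, acc.e_bond);
}

// [[Rcpp::export]]
List cpp_angle_forces(NumericMatrix x, IntegerVector fil, double Lb,
                      double kappa, double r0) {
  std::vector<double> xx = flatten(x);
  ForceAccum acc(x.nrow());
  add_angle_forces(xx, fil, Lb, kappa, r0, acc, true);
  return pack_forces(acc, acc.e_angle);
}

// [[Rcpp::export]]
List cpp_wca_forces(NumericMatrix x, IntegerVector fil, IntegerMatrix pairs,
                    double Lb, double eps, double sigma) {
  std::vector<double> xx = flatten(x);
  ForceAccum acc(x.nrow());
  for (int k = 0; k < pairs.nrow(); ++k)
    wca_pair(xx, pairs(k, 0) - 1, pairs(k, 1) - 1, Lb, eps, sigma, acc, true);
  return pack_forces(acc, acc.e_wca);
}

// [[Rcpp::export]]
List cpp_sample_motor_bonds(NumericMatrix x, IntegerVector fil, double Lb,
                            double km, double deq, double dtm, double pa,
                            double kBT, double seed) {
  std::vector<double> xx = flatten(x);
  const int n = x.nrow();
  std::vector<double> p(2 * n);
  bead_orientations(xx, fil, Lb, p);
  std::vector<int> pi, pj;
  build_pairs(xx, fil, Lb, dtm, false, pi, pj);
  Xoshiro rng(substream_seed((uint64_t)seed, 2));
  ForceAccum acc(n);
  std::vector<int> keep;
  add_motor_forces(xx, fil, p, pi, pj, Lb, km, deq, dtm, pa, kBT, rng, acc,
                   true, &keep);
  IntegerMatrix pairs(keep.size(), 2);
  NumericVector ext(keep.size());
  NumericMatrix mvec(keep.size(), 2);
  for (size_t q = 0; q < keep.size(); ++q) {
    int k = keep[q];
    pairs(q, 0) = pi[k] + 1;
    pairs(q, 1) = pj[k] + 1;
    double dx = min_image(xx[2 * pi[k]] - xx[2 * pj[k]], Lb);
    double dy = min_image(xx[2 * pi[k] + 1] - xx[2 * pj[k] + 1], Lb);
    mvec(q, 0) = dx; // m_ij = r_i - r_j
    mvec(q, 1) = dy;
    ext[q] = std::sqrt(dx * dx + dy * dy);
  }
  return List::create(_["pairs"] = pairs, _["extensions"] = ext,
                      _["bond_vectors"] = mvec, _["energy"] = acc.e_mot);
}

// [[Rcpp::export]]
List cpp_motor_forces(NumericMatrix x, IntegerMatrix pairs, double Lb,
                      double km, double deq) {
  std::vector<double> xx = flatten(x);
  ForceAccum acc(x.nrow());
  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double dx = min_image(xx[2 * j] - xx[2 * i], Lb);
    double dy = min_image(xx[2 * j + 1] - xx[2 * i + 1], Lb);
    double m = std::sqrt(dx * dx + dy * dy);
    if (m <= 0.0) stop("coincident motor-bonded beads");
    double f = km * (m - deq) / m;
    acc.F[2 * i] += f * dx;
    acc.F[2 * i + 1] += f * dy;
    acc.F[2 * j] -= f * dx;
    acc.F[2 * j + 1] -= f * dy;
    acc.e_mot += 0.5 * km * (m - deq) * (m - deq);
  }
  return pack_forces(acc, acc.e_mot);
}

// Raw motor partition sum between two bead sets (normalisation done in R).
// [[Rcpp::export]]
double cpp_qij_raw(NumericMatrix xa, NumericMatrix xb, double Lb, double km,
                   double deq, double dtm, double kBT) {
  double s = 0.0;
  for (int i = 0; i < xa.nrow(); ++i) {
    for (int j = 0; j < xb.nrow(); ++j) {
      double dx = min_image(xa(i, 0) - xb(j, 0), Lb);
      double dy = min_image(xa(i, 1) - xb(j, 1), Lb);
      double m = std::sqrt(dx * dx + dy * dy);
      if (m > dtm) continue;
      double e = m - deq;
      s += std::exp(-0.5 * km * e * e / kBT);
    }
  }
  return s;
}

// Local polar order psi for every filament of a frame: filament-level
// end-to-end orientations, bead-pair-resolved motor partition weights.
// Returns psi (NaN where the neighbourhood weight is zero) and the weight sum.
// [[Rcpp::export]]
List cpp_local_polar_order(NumericMatrix x, IntegerVector fil, double Lb,
                           double km, double deq, double dtm, double kBT,
                           int nb) {
  const int n = x.nrow();
  const int nf = n / nb;
  // COM and end-to-end orientation per filament (beads are stored in rank
  // order, consecutive per filament)
  std::vector<double> comx(nf), comy(nf), px(nf), py(nf);
  for (int f = 0; f < nf; ++f) {
    double sx = 0, sy = 0;
    for (int b = 0; b < nb; ++b) {
      sx += x(f * nb + b, 0);
      sy += x(f * nb + b, 1);
    }
    comx[f] = sx / nb;
    comy[f] = sy / nb;
    double ex = x(f * nb + nb - 1, 0) - x(f * nb, 0);
    double ey = x(f * nb + nb - 1, 1) - x(f * nb, 1);
    double r = std::sqrt(ex * ex + ey * ey);
    if (r <= 0.0) stop("zero end-to-end vector for filament %d", f + 1);
    px[f] = ex / r;
    py[f] = ey / r;
  }
  const double L = 0.0; // placeholder to keep signature simple
  (void)L;
  // pair cutoff on COM distance: two filaments can have bead pairs within
  // dtm only if their COMs are closer than contour + dtm
  double reach = dtm + (nb - 1) * 0.0;
  // conservative reach: half contour of each filament + dtm
  // (bead extent from COM is at most half the contour length)
  double half = 0.0;
  {
    // estimate max bead-to-COM distance per filament
    for (int f = 0; f < nf; ++f) {
      for (int b = 0; b < nb; ++b) {
        double dx = min_image(x(f * nb + b, 0) - comx[f], Lb);
        double dy = min_image(x(f * nb + b, 1) - comy[f], Lb);
        double r = std::sqrt(dx * dx + dy * dy);
        if (r > half) half = r;
      }
    }
  }
  reach = 2.0 * half + dtm;
  std::vector<double> num(nf, 0.0), den(nf, 0.0);
  for (int a = 0; a < nf; ++a) {
    for (int b = a + 1; b < nf; ++b) {
      double dx = min_image(comx[a] - comx[b], Lb);
      double dy = min_image(comy[a] - comy[b], Lb);
      if (dx * dx + dy * dy > reach * reach) continue;
      double q = 0.0;
      for (int ia = 0; ia < nb; ++ia) {
        for (int ib = 0; ib < nb; ++ib) {
          double ddx = min_image(x(a * nb + ia, 0) - x(b * nb + ib, 0), Lb);
          double ddy = min_image(x(a * nb + ia, 1) - x(b * nb + ib, 1), Lb);
          double m = std::sqrt(ddx * ddx + ddy * ddy);
          if (m > dtm) continue;
          double e = m - deq;
          q += std::exp(-0.5 * km * e * e / kBT);
        }
      }
      if (q <= 0.0) continue;
      double dot = px[a] * px[b] + py[a] * py[b];
      num[a] += dot * q;
      den[a] += q;
      num[b] += dot * q;
      den[b] += q;
    }
  }
  NumericVector psi(nf), qsum(nf);
  for (int f = 0; f < nf; ++f) {
    qsum[f] = den[f];
    psi[f] = den[f] > 0.0 ? num[f] / den[f] : NA_REAL;
  }
  return List::create(_["psi"] = psi, _["qsum"] = qsum);
}

// ------------------------------------------------------------ sampler -----

// [[Rcpp::export]]
NumericVector cpp_thermal_samples(int n, double gamma_, double kBT, double dt,
                                  double seed) {
  Xoshiro rng(substream_seed((uint64_t)seed, 1));
  double sd = std::sqrt(2.0 * gamma_ * kBT / dt);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sd * rng.gauss();
  return out;
}

// ------------------------------------------------------------- engine -----

// Velocity-Verlet Langevin run.  save_steps are 1-based step indices at which
// a frame (unwrapped coordinates) is stored after completing that step;
// a 0 entry stores the initial state.
// [[Rcpp::export]]
List cpp_run(NumericMatrix x0, NumericMatrix v0, IntegerVector fil,
             List par, int n_steps, IntegerVector save_steps, double seed,
             bool record_velocities) {
  const int n = x0.nrow();
  const double Lb = as<double>(par["box_edge"]);
  const double ks = as<double>(par["bond_stiffness"]);
  const double r0 = as<double>(par["bond_rest_length"]);
  const double kappa = as<double>(par["bend_modulus"]);
  const double eps = as<double>(par["wca_epsilon"]);
  const double sigma = as<double>(par["bead_diameter"]);
  const double km = as<double>(par["motor_stiffness"]);
  const double deq = as<double>(par["motor_rest_length"]);
  const double dtm = as<double>(par["motor_cutoff"]);
  const double pa = as<double>(par["motor_probability"]);
  const double mass = as<double>(par["bead_mass"]);
  const double gamma_ = as<double>(par["friction"]);
  const double kBT = as<double>(par["temperature"]);
  const double dt = as<double>(par["timestep"]);

  const double rcut = std::pow(2.0, 1.0 / 6.0) * sigma;
  const double list_cut = std::max(rcut, dtm);
  const double skin = 0.4 * sigma;
  const double noise_sd =
      kBT > 0.0 ? std::sqrt(2.0 * gamma_ * kBT / dt) : 0.0;

  std::vector<double> x = flatten(x0), v = flatten(v0);
  std::vector<double> xref(x); // positions at last list build
  std::vector<double> p(2 * n);
  std::vector<int> pi, pj;

  Xoshiro rng_therm(substream_seed((uint64_t)seed, 1));
  Xoshiro rng_mot(substream_seed((uint64_t)seed, 2));

  const int n_save = save_steps.size();
  NumericMatrix frames(n_save, 2 * n);
  NumericMatrix vels(record_velocities ? n_save : 0,
                     record_velocities ? 2 * n : 0);
  NumericMatrix energies(n_save, 4); // bond, angle, wca, motor
  IntegerVector motor_counts(n_save);
  IntegerVector out_steps(n_save);

  int save_idx = 0;
  // frames are stored column-blocked: columns 0..n-1 hold x, n..2n-1 hold y
  auto store_frame = [&](NumericMatrix& dst, int row,
                         const std::vector<double>& src) {
    for (int i = 0; i < n; ++i) {
      dst(row, i) = src[2 * i];
      dst(row, n + i) = src[2 * i + 1];
    }
  };
  auto maybe_save_initial = [&]() {
    while (save_idx < n_save && save_steps[save_idx] == 0) {
      store_frame(frames, save_idx, x);
      if (record_velocities) store_frame(vels, save_idx, v);
      out_steps[save_idx] = 0;
      ++save_idx;
    }
  };

  build_pairs(x, fil, Lb, list_cut + skin, true, pi, pj);

  auto compute_forces = [&](ForceAccum& acc, bool want_energy,
                            std::vector<int>* keep) {
    add_bond_forces(x, fil, Lb, ks, r0, acc, want_energy);
    add_angle_forces(x, fil, Lb, kappa, r0, acc, want_energy);
    for (size_t k = 0; k < pi.size(); ++k)
      wca_pair(x, pi[k], pj[k], Lb, eps, sigma, acc, want_energy);
    bead_orientations(x, fil, Lb, p);
    add_motor_forces(x, fil, p, pi, pj, Lb, km, deq, dtm, pa, kBT, rng_mot,
                     acc, want_energy, keep);
    // drag + thermal noise
    for (int i = 0; i < n; ++i) {
      double nx = noise_sd > 0.0 ? noise_sd * rng_therm.gauss() : 0.0;
      double ny = noise_sd > 0.0 ? noise_sd * rng_therm.gauss() : 0.0;
      acc.F[2 * i] += -gamma_ * v[2 * i] + nx;
      acc.F[2 * i + 1] += -gamma_ * v[2 * i + 1] + ny;
    }
  };

  maybe_save_initial();

  ForceAccum acc(n);
  compute_forces(acc, false, nullptr);

  const double max_disp2 = 0.25 * sigma * sigma; // (sigma/2)^2 per step
  const double half_skin = 0.5 * skin;

  for (int step = 1; step <= n_steps; ++step) {
    bool want_save = save_idx < n_save && save_steps[save_idx] == step;
    // half kick + drift
    double mx2 = 0.0;
    for (int i = 0; i < 2 * n; ++i) {
      v[i] += 0.5 * dt * acc.F[i] / mass;
    }
    for (int i = 0; i < n; ++i) {
      double ddx = dt * v[2 * i], ddy = dt * v[2 * i + 1];
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 > mx2) mx2 = d2;
      x[2 * i] += ddx;
      x[2 * i + 1] += ddy;
    }
    if (mx2 > max_disp2)
      stop("integration instability at step %d: bead displacement %.3g "
           "exceeds sigma/2 (timestep too large?)",
           step, std::sqrt(mx2));
    // neighbour-list refresh when any bead moved further than skin/2
    double worst = 0.0;
    for (int i = 0; i < n; ++i) {
      double ddx = x[2 * i] - xref[2 * i];
      double ddy = x[2 * i + 1] - xref[2 * i + 1];
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 > worst) worst = d2;
    }
    if (worst > half_skin * half_skin) {
      build_pairs(x, fil, Lb, list_cut + skin, true, pi, pj);
      xref = x;
    }
    // new forces + second half kick
    ForceAccum acc2(n);
    compute_forces(acc2, want_save, nullptr);
    for (int i = 0; i < 2 * n; ++i) v[i] += 0.5 * dt * acc2.F[i] / mass;
    acc.F.swap(acc2.F);
    acc.n_mot = acc2.n_mot;
    if (want_save) {
      store_frame(frames, save_idx, x);
      if (record_velocities) store_frame(vels, save_idx, v);
      energies(save_idx, 0) = acc2.e_bond;
      energies(save_idx, 1) = acc2.e_angle;
      energies(save_idx, 2) = acc2.e_wca;
      energies(save_idx, 3) = acc2.e_mot;
      motor_counts[save_idx] = acc2.n_mot;
      out_steps[save_idx] = step;
      ++save_idx;
    }
    if ((step & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix xf(n, 2), vf(n, 2);
  for (int i = 0; i < n; ++i) {
    xf(i, 0) = x[2 * i];
    xf(i, 1) = x[2 * i + 1];
    vf(i, 0) = v[2 * i];
    vf(i, 1) = v[2 * i + 1];
  }
  List out = List::create(
      _["frames"] = frames, _["steps"] = out_steps, _["energies"] = energies,
      _["motor_counts"] = motor_counts, _["x_final"] = xf, _["v_final"] = vf);
  if (record_velocities) out["velocities"] = vels;
  return out;
}
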