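// NVT Metropolis Monte Carlo engine for the 2D rose water model:
// Lennard-Jones disks plus an orientation-dependent hydrogen-bonding term
// (double-sided cubic radial switch times a 3-petal rose angular profile).
//
// Reduced units throughout: lengths in r_HB, energies in eps_HB, kB = 1.
//
// Hot-path design:
//  * Verlet neighbour lists (radius r_cut + skin) with the periodic image
//    shift of each pair stored at build time; positions are left unwrapped
//    between rebuilds (drift < skin/2 << L), so the inner loop is pure
//    loads and arithmetic with no minimum-image branching.
//  * A second, tighter list (r_u + skin) serves rotation moves, which only
//    touch the moving molecule's own half-bonds.
//  * No trigonometry per pair: cos/sin of phi and of 3*phi are cached per
//    particle, and sin(3*(theta - phi)) is expanded through the Cartesian
//    identities cos(3t) = (dx^3 - 3 dx dy^2)/r^3,
//    sin(3t) = (3 dx^2 dy - dy^3)/r^3.
//  * Rebuilds go through a coarse cell grid and are triggered when twice
//    the largest accumulated displacement plus the proposal diagonal could
//    exceed the skin.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ----------------------------------------------------------------- RNG ----
// xoshiro256++ seeded through splitmix64; deterministic given the run seed
// and independent of R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int pick(int n) { return (int)(unif() * n); }
};

// ----------------------------------------------------------- potential ----
struct RosePot {
  double eps_lj, sig2, four_eps, eps_hb, half_hb;
  double r_hb, r_l, r_u, rl2, ru2, a1, a2, inv_dl3, inv_du3;

  void init(const NumericVector& p) {
    eps_lj  = p["eps_lj"];
    double sig = p["sigma_lj"];
    sig2 = sig * sig;
    four_eps = 4.0 * eps_lj;
    eps_hb  = p["eps_hb"];
    half_hb = 0.5 * eps_hb;
    r_hb = p["r_hb"]; r_l = p["r_l"]; r_u = p["r_u"];
    rl2 = r_l * r_l; ru2 = r_u * r_u;
    a1 = p["a1"]; a2 = p["a2"];
    inv_dl3 = 1.0 / ((r_l - r_hb) * (r_l - r_hb) * (r_l - r_hb));
    inv_du3 = 1.0 / ((r_u - r_hb) * (r_u - r_hb) * (r_u - r_hb));
  }
  // switching function; call only with r_l <= r < r_u
  inline double sw(double r) const {
    if (r < r_hb) {
      double d = r_l - r;
      return (r_l + 2.0 * r - 3.0 * r_hb) * d * d * inv_dl3;
    }
    double d = r_u - r;
    return (r_u + 2.0 * r - 3.0 * r_hb) * d * d * inv_du3;
  }
  inline double dsw(double r) const {
    if (r < r_hb) return 6.0 * (r_l - r) * (r_hb - r) * inv_dl3;
    return 6.0 * (r_u - r) * (r_hb - r) * inv_du3;
  }
};

// -------------------------------------------------------------- engine ----
struct Engine {
  RosePot pot;
  int N;
  double L, halfL, T, rc, rc2;
  std::vector<double> x, y, phi, cphi, sphi, c3phi, s3phi, ux, uy;

  bool use_lists;
  double dmax_t, dmax_r;
  double skin, rv2, rvr2, thr2, maxdisp2;
  static const int VMAX = 96;
  std::vector<int> vlist, vcnt, rlist, rcnt;
  std::vector<double> vsx, vsy, rsx, rsy, dbx, dby;
  int nc; double cs;
  std::vector<int> chead, cnxt;
  long n_rebuilds;

  double delta_sum;   // sum of accepted move energy changes (drift check)
  Xoshiro rng;

  Engine(const NumericVector& x0, const NumericVector& y0,
         const NumericVector& phi0, const NumericVector& ux0,
         const NumericVector& uy0, double L_, double T_,
         const NumericVector& params, double rc_,
         double dmax_t_, double dmax_r_, uint64_t seed)
      : N((int)x0.size()), L(L_), halfL(0.5 * L_), T(T_),
        rc(rc_), rc2(rc_ * rc_), dmax_t(dmax_t_), dmax_r(dmax_r_),
        maxdisp2(0.0), n_rebuilds(0), delta_sum(0.0), rng(seed) {
    pot.init(params);
    x.assign(x0.begin(), x0.end());
    y.assign(y0.begin(), y0.end());
    phi.assign(phi0.begin(), phi0.end());
    ux.assign(ux0.begin(), ux0.end());
    uy.assign(uy0.begin(), uy0.end());
    cphi.resize(N); sphi.resize(N); c3phi.resize(N); s3phi.resize(N);
    for (int i = 0; i < N; ++i) set_orient(i, phi[i]);
    setup_lists();
  }

  inline void set_orient(int i, double p) {
    phi[i] = p;
    cphi[i] = std::cos(p); sphi[i] = std::sin(p);
    c3phi[i] = std::cos(3.0 * p); s3phi[i] = std::sin(3.0 * p);
  }

  inline double min_img(double d) const {
    if (d > halfL) return d - L;
    if (d < -halfL) return d + L;
    return d;
  }

  void setup_lists() {
    skin = std::max(1.0, 1.5 * dmax_t * M_SQRT2);
    double rvf = rc + skin;
    use_lists = (N >= 50) && (rvf < 0.5 * L);
    if (!use_lists) return;
    rv2 = rvf * rvf;
    double rvr = pot.r_u + skin;
    rvr2 = rvr * rvr;
    double thr = 0.5 * (skin - M_SQRT2 * dmax_t);
    thr2 = thr * thr;
    nc = (int)(L / rvf); if (nc < 3) nc = 3;
    cs = L / nc;
    vlist.resize((size_t)N * VMAX); rlist.resize((size_t)N * VMAX);
    vsx.resize((size_t)N * VMAX); vsy.resize((size_t)N * VMAX);
    rsx.resize((size_t)N * VMAX); rsy.resize((size_t)N * VMAX);
    vcnt.resize(N); rcnt.resize(N);
    dbx.resize(N); dby.resize(N);
    cnxt.resize(N);
    rebuild();
  }

  void rebuild() {
    ++n_rebuilds;
    for (int i = 0; i < N; ++i) {
      vcnt[i] = 0; rcnt[i] = 0; dbx[i] = 0.0; dby[i] = 0.0;
      if (x[i] >= L) x[i] -= L; else if (x[i] < 0.0) x[i] += L;
      if (y[i] >= L) y[i] -= L; else if (y[i] < 0.0) y[i] += L;
    }
    maxdisp2 = 0.0;
    chead.assign(nc * nc, -1);
    for (int i = 0; i < N; ++i) {
      int cx = (int)(x[i] / cs); if (cx >= nc) cx = nc - 1;
      int cy = (int)(y[i] / cs); if (cy >= nc) cy = nc - 1;
      int c = cy * nc + cx;
      cnxt[i] = chead[c]; chead[c] = i;
    }
    for (int i = 0; i < N; ++i) {
      int cx = (int)(x[i] / cs); if (cx >= nc) cx = nc - 1;
      int cy = (int)(y[i] / cs); if (cy >= nc) cy = nc - 1;
      for (int oy = -1; oy <= 1; ++oy) {
        int gy = cy + oy;
        double shy = 0.0;
        if (gy < 0) { gy += nc; shy = -L; } else if (gy >= nc) { gy -= nc; shy = L; }
        for (int ox = -1; ox <= 1; ++ox) {
          int gx = cx + ox;
          double shx = 0.0;
          if (gx < 0) { gx += nc; shx = -L; } else if (gx >= nc) { gx -= nc; shx = L; }
          for (int j = chead[gy * nc + gx]; j >= 0; j = cnxt[j]) {
            if (j <= i) continue;
            double dx = x[j] + shx - x[i], dy = y[j] + shy - y[i];
            double r2 = dx * dx + dy * dy;
            if (r2 < rv2) {
              if (vcnt[i] >= VMAX || vcnt[j] >= VMAX) {
                Rcpp::stop("neighbour list overflow (density too high?)");
              }
              size_t ei = (size_t)i * VMAX + vcnt[i];
              size_t ej = (size_t)j * VMAX + vcnt[j];
              vlist[ei] = j; vsx[ei] = shx; vsy[ei] = shy; ++vcnt[i];
              vlist[ej] = i; vsx[ej] = -shx; vsy[ej] = -shy; ++vcnt[j];
              if (r2 < rvr2) {
                size_t fi = (size_t)i * VMAX + rcnt[i];
                size_t fj = (size_t)j * VMAX + rcnt[j];
                rlist[fi] = j; rsx[fi] = shx; rsy[fi] = shy; ++rcnt[i];
                rlist[fj] = i; rsx[fj] = -shx; rsy[fj] = -shy; ++rcnt[j];
              }
            }
          }
        }
      }
    }
  }

  // full pair energy given displacement i -> j and r2 (call with r2 < rc2)
  inline double pair_e(double dx, double dy, double r2, int i, int j) const {
    double sr2 = pot.sig2 / r2, sr6 = sr2 * sr2 * sr2;
    double e = pot.four_eps * (sr6 * sr6 - sr6);
    if (r2 > pot.rl2 && r2 < pot.ru2) e += hb_pair(dx, dy, r2, i, j);
    return e;
  }

  // both half-bond energies of a pair; call only inside the HB window
  inline double hb_pair(double dx, double dy, double r2, int i, int j) const {
    double r = std::sqrt(r2);
    double invr2 = 1.0 / r2;
    double inv_r3 = invr2 * invr2 * r;
    double s = pot.sw(r);
    double wc = dx * (dx * dx - 3.0 * dy * dy) * inv_r3;  // cos(3 theta)
    double ws = dy * (3.0 * dx * dx - dy * dy) * inv_r3;  // sin(3 theta)
    // u = sin(3(theta - phi)); reversed direction flips both wc and ws
    double u1 =  ws * c3phi[i] - wc * s3phi[i];
    double u2 = -ws * c3phi[j] + wc * s3phi[j];
    return pot.half_hb * s *
      (pot.a2 * (u1 * u1 + u2 * u2) + pot.a1 * (u1 + u2));
  }

  // energy change for displacing particle i by (px, py)
  double delta_trans(int i, double xo, double yo, double px, double py) const {
    double accp = 0.0, accm = 0.0, dhb = 0.0;
    if (use_lists) {
      int cnt = vcnt[i];
      const int* lst = &vlist[(size_t)i * VMAX];
      const double* sx = &vsx[(size_t)i * VMAX];
      const double* sy = &vsy[(size_t)i * VMAX];
      for (int k = 0; k < cnt; ++k) {
        int j = lst[k];
        double dxo = x[j] + sx[k] - xo, dyo = y[j] + sy[k] - yo;
        double r2o = dxo * dxo + dyo * dyo;
        double dxn = dxo - px, dyn = dyo - py;
        double r2n = dxn * dxn + dyn * dyn;
        if (r2o < rc2) {
          double sr2 = pot.sig2 / r2o, sr6 = sr2 * sr2 * sr2;
          accm += pot.four_eps * (sr6 * sr6 - sr6);
          if (r2o > pot.rl2 && r2o < pot.ru2)
            dhb -= hb_pair(dxo, dyo, r2o, i, j);
        }
        if (r2n < rc2) {
          double sr2 = pot.sig2 / r2n, sr6 = sr2 * sr2 * sr2;
          accp += pot.four_eps * (sr6 * sr6 - sr6);
          if (r2n > pot.rl2 && r2n < pot.ru2)
            dhb += hb_pair(dxn, dyn, r2n, i, j);
        }
      }
    } else {
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        double dxo = min_img(x[j] - xo), dyo = min_img(y[j] - yo);
        double r2o = dxo * dxo + dyo * dyo;
        double dxn = min_img(x[j] - xo - px), dyn = min_img(y[j] - yo - py);
        double r2n = dxn * dxn + dyn * dyn;
        if (r2o < rc2) accm += pair_e(dxo, dyo, r2o, i, j);
        if (r2n < rc2) accp += pair_e(dxn, dyn, r2n, i, j);
      }
    }
    return accp - accm + dhb;
  }

  // energy change for re-orienting particle i (c3n/s3n = cos/sin of 3*new)
  double delta_rot(int i, double c3n, double s3n) const {
    double d = 0.0;
    double c3o = c3phi[i], s3o = s3phi[i];
    double xi = x[i], yi = y[i];
    double dc = c3n - c3o, ds = s3n - s3o;
    if (use_lists) {
      int cnt = rcnt[i];
      const int* lst = &rlist[(size_t)i * VMAX];
      const double* sx = &rsx[(size_t)i * VMAX];
      const double* sy = &rsy[(size_t)i * VMAX];
      for (int k = 0; k < cnt; ++k) {
        int j = lst[k];
        double dx = x[j] + sx[k] - xi, dy = y[j] + sy[k] - yi;
        double r2 = dx * dx + dy * dy;
        if (r2 <= pot.rl2 || r2 >= pot.ru2) continue;
        d += rot_term(dx, dy, r2, c3o, s3o, dc, ds);
      }
    } else {
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        double dx = min_img(x[j] - xi), dy = min_img(y[j] - yi);
        double r2 = dx * dx + dy * dy;
        if (r2 <= pot.rl2 || r2 >= pot.ru2) continue;
        d += rot_term(dx, dy, r2, c3o, s3o, dc, ds);
      }
    }
    return d;
  }
  inline double rot_term(double dx, double dy, double r2,
                         double c3o, double s3o,
                         double dc, double ds) const {
    double r = std::sqrt(r2);
    double invr2 = 1.0 / r2;
    double inv_r3 = invr2 * invr2 * r;
    double s = pot.sw(r);
    double wc = dx * (dx * dx - 3.0 * dy * dy) * inv_r3;
    double ws = dy * (3.0 * dx * dx - dy * dy) * inv_r3;
    double uo = ws * c3o - wc * s3o;
    double un = uo + ws * dc - wc * ds;
    return pot.half_hb * s * (pot.a2 * (un * un - uo * uo) + pot.a1 * (un - uo));
  }

  inline bool metropolis(double d) {
    if (d <= 0.0) return true;
    double ex = -d / T;
    if (ex < -700.0) return false;  // clamp: overlap-scale uphill moves
    return rng.unif() < std::exp(ex);
  }

  // one cycle: N translation attempts and N rotation attempts, particles
  // drawn independently and uniformly for each attempt
  void cycle(long& acc_t, long& acc_r) {
    for (int step = 0; step < N; ++step) {
      {   // translation
        if (use_lists && maxdisp2 > thr2) rebuild();
        int i = rng.pick(N);
        double px = (2.0 * rng.unif() - 1.0) * dmax_t;
        double py = (2.0 * rng.unif() - 1.0) * dmax_t;
        double d = delta_trans(i, x[i], y[i], px, py);
        if (metropolis(d)) {
          delta_sum += d;
          if (use_lists) {
            x[i] += px; y[i] += py;  // wrapped at the next rebuild
            dbx[i] += px; dby[i] += py;
            double d2 = dbx[i] * dbx[i] + dby[i] * dby[i];
            if (d2 > maxdisp2) maxdisp2 = d2;
          } else {
            double xn = x[i] + px, yn = y[i] + py;
            if (xn >= L) xn -= L; else if (xn < 0.0) xn += L;
            if (yn >= L) yn -= L; else if (yn < 0.0) yn += L;
            x[i] = xn; y[i] = yn;
          }
          ux[i] += px; uy[i] += py;
          ++acc_t;
        }
      }
      {   // rotation
        if (use_lists && maxdisp2 > thr2) rebuild();
        int i = rng.pick(N);
        double pn = phi[i] + (2.0 * rng.unif() - 1.0) * dmax_r;
        double c3n = std::cos(3.0 * pn), s3n = std::sin(3.0 * pn);
        double d = delta_rot(i, c3n, s3n);
        if (metropolis(d)) {
          delta_sum += d;
          phi[i] = pn;  // stored unreduced
          cphi[i] = std::cos(pn); sphi[i] = std::sin(pn);
          c3phi[i] = c3n; s3phi[i] = s3n;
          ++acc_r;
        }
      }
    }
  }

  void wrap_all() {
    for (int i = 0; i < N; ++i) {
      if (x[i] >= L) x[i] -= L; else if (x[i] < 0.0) x[i] += L;
      if (y[i] >= L) y[i] -= L; else if (y[i] < 0.0) y[i] += L;
    }
    // stored image shifts assume the pre-wrap coordinates
    maxdisp2 = 1e300;
  }

  double total_energy() const {
    double e = 0.0;
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double dx = min_img(x[j] - x[i]), dy = min_img(y[j] - y[i]);
        double r2 = dx * dx + dy * dy;
        if (r2 < rc2) e += pair_e(dx, dy, r2, i, j);
      }
    }
    return e;
  }

  // total energy through the neighbour lists (each pair stored twice)
  double total_energy_lists() {
    if (!use_lists) return total_energy();
    if (maxdisp2 > thr2) rebuild();
    double e = 0.0;
    for (int i = 0; i < N; ++i) {
      const int* lst = &vlist[(size_t)i * VMAX];
      const double* sx = &vsx[(size_t)i * VMAX];
      const double* sy = &vsy[(size_t)i * VMAX];
      for (int k = 0; k < vcnt[i]; ++k) {
        int j = lst[k];
        double dx = x[j] + sx[k] - x[i], dy = y[j] + sy[k] - y[i];
        double r2 = dx * dx + dy * dy;
        if (r2 < rc2) e += 0.5 * pair_e(dx, dy, r2, i, j);
      }
    }
    return e;
  }
};

// ------------------------------------------------------ frame sampling ----
// One O(N^2) pass per sampled frame: energy, virial sum, RDF histogram to
// L/2, per-particle 3- and 6-fold bond-orientational order, HB bond count.
struct FrameSample {
  double u, w, q3, q6, hb;
};

static FrameSample sample_frame(const Engine& E, double rdf_bin, int nbins,
                                double shell_cutoff, double hb_thr,
                                std::vector<double>& rdf_counts) {
  const RosePot& pot = E.pot;
  int N = E.N;
  double shell2 = shell_cutoff * shell_cutoff;
  std::vector<double> re3(N, 0.0), im3(N, 0.0), re6(N, 0.0), im6(N, 0.0);
  std::vector<int> nn(N, 0);
  double u = 0.0, w = 0.0;
  long bonds = 0;
  double inv_bin = 1.0 / rdf_bin;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dx = E.min_img(E.x[j] - E.x[i]), dy = E.min_img(E.y[j] - E.y[i]);
      double r2 = dx * dx + dy * dy;
      double r = std::sqrt(r2);
      int b = (int)(r * inv_bin);
      if (b < nbins) rdf_counts[b] += 1.0;
      if (r2 < E.rc2) {
        double sr2 = pot.sig2 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        u += pot.four_eps * (sr12 - sr6);
        w += -24.0 * pot.eps_lj * (2.0 * sr12 - sr6);  // r * dU_LJ/dr
        if (r2 > pot.rl2 && r2 < pot.ru2) {
          double invr2 = 1.0 / r2;
          double inv_r3 = invr2 * invr2 * r;
          double s = pot.sw(r);
          double wc = dx * (dx * dx - 3.0 * dy * dy) * inv_r3;
          double ws = dy * (3.0 * dx * dx - dy * dy) * inv_r3;
          double u1 =  ws * E.c3phi[i] - wc * E.s3phi[i];
          double u2 = -ws * E.c3phi[j] + wc * E.s3phi[j];
          double U1 = pot.a2 * u1 * u1 + pot.a1 * u1;
          double U2 = pot.a2 * u2 * u2 + pot.a1 * u2;
          u += pot.half_hb * s * (U1 + U2);
          w += pot.half_hb * (U1 + U2) * pot.dsw(r) * r;
          if (pot.half_hb * s * U1 < hb_thr && pot.half_hb * s * U2 < hb_thr)
            ++bonds;
        }
      }
      if (r2 < shell2) {
        double invr = 1.0 / r;
        double c = dx * invr, s_ = dy * invr;
        double c2 = c * c, s2_ = s_ * s_;
        double R3 = c * (c2 - 3.0 * s2_);      // cos(3 th)
        double I3 = s_ * (3.0 * c2 - s2_);     // sin(3 th)
        double R6 = R3 * R3 - I3 * I3, I6 = 2.0 * R3 * I3;
        re3[i] += R3; im3[i] += I3;
        re3[j] -= R3; im3[j] -= I3;            // opposite direction: z^3 flips
        re6[i] += R6; im6[i] += I6;
        re6[j] += R6; im6[j] += I6;            // even power: unchanged
        ++nn[i]; ++nn[j];
      }
    }
  }
  double q3 = 0.0, q6 = 0.0;
  for (int i = 0; i < N; ++i) {
    if (nn[i] > 0) {
      q3 += std::sqrt(re3[i] * re3[i] + im3[i] * im3[i]) / nn[i];
      q6 += std::sqrt(re6[i] * re6[i] + im6[i] * im6[i]) / nn[i];
    }
  }
  FrameSample out;
  out.u = u; out.w = w;
  out.q3 = q3 / N; out.q6 = q6 / N;
  out.hb = 2.0 * (double)bonds / N;
  return out;
}

// ------------------------------------------------------------ exports -----

// [[Rcpp::export]]
double total_energy_cpp(NumericVector x, NumericVector y, NumericVector phi,
                        double L, NumericVector params, double rc) {
  NumericVector z(x.size());
  Engine E(x, y, phi, z, z, L, 1.0, params, rc, 0.1, 0.4, 1u);
  return E.total_energy_lists();
}

// [[Rcpp::export]]
List mc_cycles_cpp(NumericVector x, NumericVector y, NumericVector phi,
                   NumericVector ux, NumericVector uy,
                   double L, double T, NumericVector params, double rc,
                   int n_cycles, double dmax_t, double dmax_r, double seed) {
  Engine E(x, y, phi, ux, uy, L, T, params, rc, dmax_t, dmax_r,
           (uint64_t)seed);
  double e0 = E.total_energy();
  long at = 0, ar = 0;
  for (int c = 0; c < n_cycles; ++c) E.cycle(at, ar);
  E.wrap_all();
  double e1 = E.total_energy();
  double att = (double)n_cycles * E.N;
  return List::create(
    _["x"] = NumericVector(E.x.begin(), E.x.end()),
    _["y"] = NumericVector(E.y.begin(), E.y.end()),
    _["phi"] = NumericVector(E.phi.begin(), E.phi.end()),
    _["ux"] = NumericVector(E.ux.begin(), E.ux.end()),
    _["uy"] = NumericVector(E.uy.begin(), E.uy.end()),
    _["acc_trans"] = at / att, _["acc_rot"] = ar / att,
    _["energy_initial"] = e0, _["energy_final"] = e1,
    _["delta_sum"] = E.delta_sum,
    _["used_lists"] = E.use_lists);
}

// [[Rcpp::export]]
List run_rose_mc_cpp(NumericVector x, NumericVector y, NumericVector phi,
                     double L, double T, NumericVector params, double rc,
                     List settings) {
  int n_equil          = as<int>(settings["n_equil_cycles"]);
  int n_series         = as<int>(settings["n_series"]);
  int cycles_series    = as<int>(settings["cycles_per_series"]);
  double dmax_t        = as<double>(settings["dmax_trans"]);
  double dmax_r        = as<double>(settings["dmax_rot"]);
  bool adjust          = as<bool>(settings["adjust_dmax"]);
  int sample_interval  = as<int>(settings["sample_interval_cycles"]);
  int msd_interval     = as<int>(settings["msd_interval_cycles"]);
  double rdf_bin       = as<double>(settings["rdf_bin_width"]);
  double shell_cutoff  = as<double>(settings["shell_cutoff"]);
  double hb_thr        = as<double>(settings["hb_threshold"]);
  double seed          = as<double>(settings["seed"]);
  bool store_frames    = as<bool>(settings["store_frames"]);

  NumericVector z(x.size());
  Engine E(x, y, phi, z, z, L, T, params, rc, dmax_t, dmax_r,
           (uint64_t)seed);
  int N = E.N;

  // ---- equilibration, with optional drive toward ~40% acceptance
  long at = 0, ar = 0;
  long at_equil = 0, ar_equil = 0;
  int adj_window = 1000;
  int since = 0;
  for (int c = 0; c < n_equil; ++c) {
    E.cycle(at, ar);
    ++since;
    if (adjust && since == adj_window) {
      double rt = (double)at / ((double)since * N);
      double rr = (double)ar / ((double)since * N);
      double ft = std::min(2.0, std::max(0.5, rt / 0.4));
      double fr = std::min(2.0, std::max(0.5, rr / 0.4));
      E.dmax_t = std::min(L / 4.0, std::max(1e-4, E.dmax_t * ft));
      E.dmax_r = std::min(M_PI,    std::max(1e-4, E.dmax_r * fr));
      E.setup_lists();  // skin and trigger depend on dmax_t
      at_equil += at; ar_equil += ar;
      at = 0; ar = 0; since = 0;
    }
  }
  at_equil += at; ar_equil += ar;
  // production: dmax frozen from here on
  double dmax_t_used = E.dmax_t, dmax_r_used = E.dmax_r;

  int nbins = (int)std::floor(0.5 * L / rdf_bin);
  int n_msd = cycles_series / msd_interval;
  NumericMatrix series(n_series, 8);
  colnames(series) = CharacterVector::create(
    "u_per_n", "w_sum", "q3", "q6", "hb", "acc_trans", "acc_rot", "n_samples");
  NumericMatrix rdf(n_series, nbins);
  NumericMatrix msd(n_series, n_msd);
  List frames(store_frames ? n_series : 0);

  // displacement accumulators restart at production start
  std::fill(E.ux.begin(), E.ux.end(), 0.0);
  std::fill(E.uy.begin(), E.uy.end(), 0.0);

  std::vector<double> ux0(N), uy0(N), counts(nbins);
  for (int s = 0; s < n_series; ++s) {
    std::copy(E.ux.begin(), E.ux.end(), ux0.begin());
    std::copy(E.uy.begin(), E.uy.end(), uy0.begin());
    std::fill(counts.begin(), counts.end(), 0.0);
    double su = 0, sw_ = 0, sq3 = 0, sq6 = 0, shb = 0;
    int nsamp = 0, imsd = 0;
    long sat = 0, sar = 0;
    for (int c = 1; c <= cycles_series; ++c) {
      E.cycle(sat, sar);
      if (c % msd_interval == 0) {
        double m = 0.0;
        for (int i = 0; i < N; ++i) {
          double dx = E.ux[i] - ux0[i], dy = E.uy[i] - uy0[i];
          m += dx * dx + dy * dy;
        }
        msd(s, imsd++) = m / N;
      }
      if (c % sample_interval == 0) {
        FrameSample f = sample_frame(E, rdf_bin, nbins, shell_cutoff,
                                     hb_thr, counts);
        su += f.u; sw_ += f.w; sq3 += f.q3; sq6 += f.q6; shb += f.hb;
        ++nsamp;
      }
    }
    series(s, 0) = su / nsamp / N;
    series(s, 1) = sw_ / nsamp;
    series(s, 2) = sq3 / nsamp;
    series(s, 3) = sq6 / nsamp;
    series(s, 4) = shb / nsamp;
    series(s, 5) = (double)sat / ((double)cycles_series * N);
    series(s, 6) = (double)sar / ((double)cycles_series * N);
    series(s, 7) = nsamp;
    for (int b = 0; b < nbins; ++b) rdf(s, b) = counts[b];
    if (store_frames) {
      Engine& Em = E;
      Em.wrap_all();
      frames[s] = List::create(
        _["x"] = NumericVector(E.x.begin(), E.x.end()),
        _["y"] = NumericVector(E.y.begin(), E.y.end()),
        _["phi"] = NumericVector(E.phi.begin(), E.phi.end()));
    }
  }
  E.wrap_all();

  double equil_att = n_equil > 0 ? (double)n_equil * N : 1.0;
  return List::create(
    _["series"] = series, _["rdf_counts"] = rdf, _["msd"] = msd,
    _["x"] = NumericVector(E.x.begin(), E.x.end()),
    _["y"] = NumericVector(E.y.begin(), E.y.end()),
    _["phi"] = NumericVector(E.phi.begin(), E.phi.end()),
    _["ux"] = NumericVector(E.ux.begin(), E.ux.end()),
    _["uy"] = NumericVector(E.uy.begin(), E.uy.end()),
    _["dmax_trans_used"] = dmax_t_used, _["dmax_rot_used"] = dmax_r_used,
    _["acc_trans_equil"] = at_equil / equil_att,
    _["acc_rot_equil"] = ar_equil / equil_att,
    _["rdf_bin_width"] = rdf_bin, _["nbins"] = nbins,
    _["r_cut"] = rc, _["used_cells"] = E.use_lists,
    _["frames"] = frames);
}
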