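// Brownian dynamics engine for a bead-spring lamellipodial actin network.
//
// Geometry: x periodic (width box_w), y unbounded (leading edge at y = 0,
// retrograde flow towards +y), z confined to [0, box_h] by soft walls.
// Units: pN, um, s throughout; 1 Pa = 1 pN/um^2.
//
// All randomness comes from a xoshiro256++ stream stored in the network
// state (seeded from R's RNG at state creation), so runs are reproducible
// from set.seed() and continue bit-identically across checkpoints.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <unordered_set>
#include <cstdint>
#include <cstring>

using namespace Rcpp;

static const int CH_SPRING = 0, CH_BEND = 1, CH_XL = 2, CH_EXCL = 3,
                 CH_LEAD = 4, CH_MOTOR = 5, CH_CONF = 6, CH_BRANCH = 7,
                 CH_THERM = 8, NCH = 9;

static const int XL_PERM = 1, XL_LONG = 2, XL_DYN = 3, XL_BRANCH = 4;

struct Par {
  double dt, k_actin, l0, l_p, kBT, k_xl, l0_xl, k_ex, d_ex;
  double zeta_b, kappa_FA, k_bind, k_unbind;
  double C_dynamic, k_dyn_off, tau_age, r_age;
  double add_rate, fil_len;
  int beads_per_fil;
  double F_push, F_pull_uniform, F_pull_back, F_pull_membrane;
  int pull_mode;            // 0 uniform, 1 back, 2 membrane
  double y_back;
  double eps_angle, cos_theta0;
  double box_w, box_h, confine_F;
  int monomers;
  double longlived_lifetime; // <= 0: permanent crosslinks are truly permanent
  double push_frac;
  // focal adhesion capsule: centre-line (fa_x0,fa_y0)-(fa_x1,fa_y1), radius,
  // height above z = 0
  bool fa_on;
  double fa_x0, fa_y0, fa_x1, fa_y1, fa_r, fa_h;
  bool periodic, top_wall, thermal_fa_drag;
  double skin, refresh_interval;
  double membrane_z;
};

static double getd(const List& p, const char* k) {
  return as<double>(p[k]);
}

static Par par_from_list(const List& p) {
  Par q;
  q.dt = getd(p, "dt");
  q.k_actin = getd(p, "k_actin");
  q.l0 = getd(p, "l0");
  q.l_p = getd(p, "l_p");
  q.kBT = getd(p, "kBT");
  q.k_xl = getd(p, "k_crosslink");
  q.l0_xl = getd(p, "l0_crosslink");
  q.k_ex = getd(p, "k_excluded");
  q.d_ex = getd(p, "d_excluded");
  q.zeta_b = getd(p, "zeta_b");
  q.kappa_FA = getd(p, "kappa_FA");
  q.k_bind = getd(p, "k_FA_bind");
  q.k_unbind = getd(p, "k_FA_unbind");
  q.C_dynamic = getd(p, "C_dynamic");
  q.k_dyn_off = getd(p, "k_dynamic_off");
  q.tau_age = getd(p, "tau_age");
  q.r_age = getd(p, "r_age");
  q.add_rate = getd(p, "filament_add_rate");
  q.fil_len = getd(p, "filament_length");
  q.beads_per_fil = as<int>(p["beads_per_filament"]);
  q.F_push = getd(p, "F_push_total");
  q.F_pull_uniform = getd(p, "F_pull_uniform");
  q.F_pull_back = getd(p, "F_pull_back");
  q.F_pull_membrane = getd(p, "F_pull_membrane");
  std::string pm = as<std::string>(p["pull_mode"]);
  q.pull_mode = (pm == "uniform") ? 0 : (pm == "back" ? 1 : 2);
  q.y_back = getd(p, "y_back_threshold");
  q.eps_angle = getd(p, "eps_angle");
  q.cos_theta0 = std::cos(getd(p, "theta_0") * M_PI / 180.0);
  q.box_w = getd(p, "box_width");
  q.box_h = getd(p, "box_height");
  q.confine_F = getd(p, "confine_force");
  q.monomers = as<int>(p["monomers_per_segment"]);
  double ll = getd(p, "longlived_lifetime");
  q.longlived_lifetime = R_IsNA(ll) ? -1.0 : ll;
  q.push_frac = getd(p, "push_frac");
  q.fa_on = as<bool>(p["fa_on"]);
  q.fa_x0 = getd(p, "fa_x0"); q.fa_y0 = getd(p, "fa_y0");
  q.fa_x1 = getd(p, "fa_x1"); q.fa_y1 = getd(p, "fa_y1");
  q.fa_r = getd(p, "fa_radius"); q.fa_h = getd(p, "fa_height");
  q.periodic = as<bool>(p["periodic"]);
  q.top_wall = as<bool>(p["top_wall"]);
  q.thermal_fa_drag = as<bool>(p["thermal_fa_drag"]);
  q.skin = getd(p, "skin");
  q.refresh_interval = getd(p, "refresh_interval");
  q.membrane_z = getd(p, "membrane_z");
  return q;
}

// xoshiro256++ PRNG; the state lives inside the network state so that
// checkpointed runs continue bit-identically and all stochastic events share
// one deterministic stream.
struct Rng {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform on (0, 1]
  double unif() { return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0); }
  // standard normal (Marsaglia polar); the spare is never kept across
  // steps (reset by the integrator) so split runs replay identically
  bool have_spare = false; double spare = 0;
  double normal() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; have_spare = true;
    return u * f;
  }
};

static uint64_t splitmix64(uint64_t& x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export]]
IntegerVector cpp_rng_seed(double seed) {
  uint64_t x = (uint64_t)seed;
  IntegerVector out(8);
  for (int k = 0; k < 4; ++k) {
    uint64_t v = splitmix64(x);
    int32_t lo, hi;
    std::memcpy(&lo, &v, 4);
    std::memcpy(&hi, ((char*)&v) + 4, 4);
    out[2 * k] = lo;
    out[2 * k + 1] = hi;
  }
  return out;
}

static Rng rng_from_ints(const IntegerVector& v) {
  Rng r;
  for (int k = 0; k < 4; ++k) {
    uint64_t x = 0;
    int32_t lo = v[2 * k], hi = v[2 * k + 1];
    std::memcpy(&x, &lo, 4);
    std::memcpy(((char*)&x) + 4, &hi, 4);
    r.s[k] = x;
  }
  if ((r.s[0] | r.s[1] | r.s[2] | r.s[3]) == 0) r.s[0] = 1;
  r.have_spare = false;
  return r;
}

static IntegerVector rng_to_ints(const Rng& r) {
  IntegerVector v(8);
  for (int k = 0; k < 4; ++k) {
    int32_t lo, hi;
    std::memcpy(&lo, &r.s[k], 4);
    std::memcpy(&hi, ((char*)&r.s[k]) + 4, 4);
    v[2 * k] = lo;
    v[2 * k + 1] = hi;
  }
  return v;
}

struct St {
  Rng rng;
  std::vector<double> x, y, z, birth, uid;
  std::vector<int> wrapn;          // count of +box_w wraps applied to x
  std::vector<char> bound;
  std::vector<int> fil;            // index into fils
  std::vector<std::vector<int> > fils;   // bead indices pointed -> barbed
  std::vector<std::vector<double> > taus;
  std::vector<int> fil_id;
  std::vector<int> xa, xb, xtype;
  std::vector<double> xtau;
  std::vector<int> bi, bj, bk;     // branch triplets (mother-prev, mother, daughter)
  double t, resid, next_refresh;
  double next_uid;
  double spawn_count;              // total insertions (alternation bookkeeping)
  int next_fil_id;
  long n_skipped_spawns;
  long n_overlap_kicks;
};

static St st_from_list(const List& s) {
  St q;
  NumericMatrix pos = s["pos"];
  int n = pos.nrow();
  q.x.resize(n); q.y.resize(n); q.z.resize(n);
  for (int i = 0; i < n; ++i) {
    q.x[i] = pos(i, 0); q.y[i] = pos(i, 1); q.z[i] = pos(i, 2);
  }
  q.birth = as<std::vector<double> >(s["birth"]);
  q.uid = as<std::vector<double> >(s["uid"]);
  q.wrapn = as<std::vector<int> >(s["wrapn"]);
  IntegerVector bnd = s["bound"];
  q.bound.resize(n);
  for (int i = 0; i < n; ++i) q.bound[i] = (char)bnd[i];
  List fb = s["fil_beads"], ft = s["fil_taus"];
  int nf = fb.size();
  q.fils.resize(nf); q.taus.resize(nf);
  q.fil.assign(n, -1);
  for (int f = 0; f < nf; ++f) {
    IntegerVector b = fb[f];
    NumericVector tv = ft[f];
    q.fils[f].resize(b.size());
    for (int k = 0; k < b.size(); ++k) {
      q.fils[f][k] = b[k] - 1;
      q.fil[b[k] - 1] = f;
    }
    q.taus[f] = as<std::vector<double> >(tv);
  }
  q.fil_id = as<std::vector<int> >(s["fil_ids"]);
  NumericMatrix xl = s["xl"];
  int nx = xl.nrow();
  q.xa.resize(nx); q.xb.resize(nx); q.xtype.resize(nx); q.xtau.resize(nx);
  for (int i = 0; i < nx; ++i) {
    q.xa[i] = (int)xl(i, 0) - 1;
    q.xb[i] = (int)xl(i, 1) - 1;
    q.xtype[i] = (int)xl(i, 2);
    q.xtau[i] = xl(i, 3);
  }
  NumericMatrix br = s["branches"];
  int nb = br.nrow();
  q.bi.resize(nb); q.bj.resize(nb); q.bk.resize(nb);
  for (int i = 0; i < nb; ++i) {
    q.bi[i] = (int)br(i, 0) - 1;
    q.bj[i] = (int)br(i, 1) - 1;
    q.bk[i] = (int)br(i, 2) - 1;
  }
  q.t = getd(s, "t");
  q.resid = getd(s, "resid");
  q.next_refresh = getd(s, "next_refresh");
  q.next_uid = getd(s, "next_uid");
  q.spawn_count = getd(s, "spawn_count");
  q.next_fil_id = as<int>(s["next_fil_id"]);
  q.n_skipped_spawns = (long)getd(s, "n_skipped_spawns");
  q.n_overlap_kicks = (long)getd(s, "n_overlap_kicks");
  q.rng = rng_from_ints(s["rngstate"]);
  return q;
}

static List st_to_list(const St& q) {
  int n = q.x.size();
  NumericMatrix pos(n, 3);
  IntegerVector bnd(n), wn(n);
  NumericVector birth(n), uid(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = q.x[i]; pos(i, 1) = q.y[i]; pos(i, 2) = q.z[i];
    bnd[i] = q.bound[i]; wn[i] = q.wrapn[i];
    birth[i] = q.birth[i]; uid[i] = q.uid[i];
  }
  colnames(pos) = CharacterVector::create("x", "y", "z");
  int nf = q.fils.size();
  List fb(nf), ft(nf);
  IntegerVector fids(nf);
  for (int f = 0; f < nf; ++f) {
    IntegerVector b(q.fils[f].size());
    for (size_t k = 0; k < q.fils[f].size(); ++k) b[k] = q.fils[f][k] + 1;
    fb[f] = b;
    ft[f] = wrap(q.taus[f]);
    fids[f] = q.fil_id[f];
  }
  int nx = q.xa.size();
  NumericMatrix xl(nx, 4);
  for (int i = 0; i < nx; ++i) {
    xl(i, 0) = q.xa[i] + 1; xl(i, 1) = q.xb[i] + 1;
    xl(i, 2) = q.xtype[i]; xl(i, 3) = q.xtau[i];
  }
  colnames(xl) = CharacterVector::create("a", "b", "type", "tau");
  int nb = q.bi.size();
  NumericMatrix br(nb, 3);
  for (int i = 0; i < nb; ++i) {
    br(i, 0) = q.bi[i] + 1; br(i, 1) = q.bj[i] + 1; br(i, 2) = q.bk[i] + 1;
  }
  colnames(br) = CharacterVector::create("i", "j", "k");
  return List::create(
    _["pos"] = pos, _["uid"] = uid, _["birth"] = birth, _["bound"] = bnd,
    _["wrapn"] = wn, _["fil_beads"] = fb, _["fil_taus"] = ft,
    _["fil_ids"] = fids, _["xl"] = xl, _["branches"] = br,
    _["t"] = q.t, _["resid"] = q.resid, _["next_refresh"] = q.next_refresh,
    _["next_uid"] = q.next_uid, _["spawn_count"] = q.spawn_count,
    _["next_fil_id"] = q.next_fil_id,
    _["n_skipped_spawns"] = (double)q.n_skipped_spawns,
    _["n_overlap_kicks"] = (double)q.n_overlap_kicks,
    _["rngstate"] = rng_to_ints(q.rng));
}

// ---- geometry helpers -------------------------------------------------------

static inline double minx(double dx, const Par& p) {
  if (!p.periodic) return dx;
  return dx - p.box_w * std::nearbyint(dx / p.box_w);
}

static inline void wrap_bead(St& s, int i, const Par& p) {
  if (!p.periodic) return;
  double w = p.box_w;
  if (s.x[i] >= 0 && s.x[i] < w) return;
  double k = std::floor(s.x[i] / w);
  s.x[i] -= k * w;
  s.wrapn[i] += (int)k;
}

// closest approach between 3D segments a0-a1, b0-b1; returns squared-free
// distance, witness parameters sa, sb in [0,1] measured from a0/b0.
// Parallel tie broken at the midpoints (sa = sb = 0.5) when the overlap is
// degenerate.
static double seg_seg(const double a0[3], const double a1[3],
                      const double b0[3], const double b1[3],
                      double& sa, double& sb) {
  double d1[3], d2[3], r[3];
  for (int c = 0; c < 3; ++c) {
    d1[c] = a1[c] - a0[c];
    d2[c] = b1[c] - b0[c];
    r[c] = a0[c] - b0[c];
  }
  double A = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double E = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double B = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
  double C = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
  double F = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  double den = A * E - B * B;
  if (den > 1e-14 * A * E) {
    sa = (B * F - C * E) / den;
    sa = std::max(0.0, std::min(1.0, sa));
  } else {
    sa = 0.5; // parallel: midpoint witness
  }
  sb = (E > 0) ? (B * sa + F) / E : 0.5;
  if (sb < 0.0) { sb = 0.0; sa = std::max(0.0, std::min(1.0, -C / A)); }
  else if (sb > 1.0) { sb = 1.0; sa = std::max(0.0, std::min(1.0, (B - C) / A)); }
  double dd = 0;
  for (int c = 0; c < 3; ++c) {
    double q = (a0[c] + sa * d1[c]) - (b0[c] + sb * d2[c]);
    dd += q * q;
  }
  return std::sqrt(dd);
}

// ---- segment (bond) enumeration and cell list -------------------------------

struct Seg { int i, j, f; };

static void list_segments(const St& s, std::vector<Seg>& segs) {
  segs.clear();
  for (size_t f = 0; f < s.fils.size(); ++f)
    for (size_t k = 0; k + 1 < s.fils[f].size(); ++k)
      segs.push_back(Seg{ s.fils[f][k], s.fils[f][k + 1], (int)f });
}

// candidate pairs of segments with closest approach possibly below cutoff.
// Cell list (counting sort, no per-cell allocation) over segment midpoints;
// pairs sharing a bead are excluded.
static void candidate_pairs(const St& s, const Par& p,
                            const std::vector<Seg>& segs, double cutoff,
                            std::vector<std::pair<int,int> >& pairs) {
  pairs.clear();
  int ns = segs.size();
  if (ns < 2) return;
  double edge = p.l0 + cutoff; // midpoints of interacting bonds are closer than this
  std::vector<double> mx(ns), my(ns), mz(ns);
  double ymin = 1e30, ymax = -1e30, zmin = 1e30, zmax = -1e30;
  for (int a = 0; a < ns; ++a) {
    double dx = minx(s.x[segs[a].j] - s.x[segs[a].i], p);
    mx[a] = s.x[segs[a].i] + 0.5 * dx;
    if (p.periodic) mx[a] -= p.box_w * std::floor(mx[a] / p.box_w);
    my[a] = 0.5 * (s.y[segs[a].i] + s.y[segs[a].j]);
    mz[a] = 0.5 * (s.z[segs[a].i] + s.z[segs[a].j]);
    ymin = std::min(ymin, my[a]); ymax = std::max(ymax, my[a]);
    zmin = std::min(zmin, mz[a]); zmax = std::max(zmax, mz[a]);
  }
  double xspan = p.periodic ? p.box_w : 0.0;
  double xmin = 0.0;
  if (!p.periodic) {
    double xma = -1e30; xmin = 1e30;
    for (int a = 0; a < ns; ++a) { xmin = std::min(xmin, mx[a]); xma = std::max(xma, mx[a]); }
    xspan = xma - xmin;
  }
  int ncx = std::max(1, (int)std::floor(xspan / edge));
  int ncy = std::max(1, (int)std::floor((ymax - ymin) / edge) + 1);
  int ncz = std::max(1, (int)std::floor((zmax - zmin) / edge) + 1);
  double ex = (xspan > 0) ? xspan / ncx : edge;
  size_t ncell = (size_t)ncx * ncy * ncz;
  std::vector<int> ci(ns), cj(ns), ck(ns), cell(ns);
  std::vector<int> start(ncell + 1, 0), order(ns);
  for (int a = 0; a < ns; ++a) {
    int icx = (int)std::floor((mx[a] - xmin) / ex);
    icx = std::max(0, std::min(ncx - 1, icx));
    int icy = std::max(0, std::min(ncy - 1, (int)std::floor((my[a] - ymin) / edge)));
    int icz = std::max(0, std::min(ncz - 1, (int)std::floor((mz[a] - zmin) / edge)));
    ci[a] = icx; cj[a] = icy; ck[a] = icz;
    cell[a] = (icz * ncy + icy) * ncx + icx;
    start[cell[a] + 1]++;
  }
  for (size_t c = 0; c < ncell; ++c) start[c + 1] += start[c];
  {
    std::vector<int> cur(start.begin(), start.end() - 1);
    for (int a = 0; a < ns; ++a) order[cur[cell[a]]++] = a;
  }
  double cut2 = (p.l0 + cutoff) * (p.l0 + cutoff);
  for (int a = 0; a < ns; ++a) {
    for (int ddz = 0; ddz <= 1; ++ddz)
    for (int ddy = -1; ddy <= 1; ++ddy)
    for (int ddx = -1; ddx <= 1; ++ddx) {
      if (ddz == 0 && (ddy < 0 || (ddy == 0 && ddx < 0))) continue;
      int icy = cj[a] + ddy, icz = ck[a] + ddz;
      if (icy < 0 || icy >= ncy || icz >= ncz) continue;
      int icx = ci[a] + ddx;
      if (p.periodic) icx = (icx % ncx + ncx) % ncx;
      else if (icx < 0 || icx >= ncx) continue;
      int cc = (icz * ncy + icy) * ncx + icx;
      bool same_cell = (ddx == 0 && ddy == 0 && ddz == 0);
      for (int q = start[cc]; q < start[cc + 1]; ++q) {
        int b = order[q];
        if (same_cell && b <= a) continue;
        const Seg& A = segs[a];
        const Seg& B = segs[b];
        if (A.i == B.i || A.i == B.j || A.j == B.i || A.j == B.j) continue;
        double dx = minx(mx[a] - mx[b], p);
        double dy = my[a] - my[b], dz = mz[a] - mz[b];
        if (dx * dx + dy * dy + dz * dz > cut2) continue;
        pairs.push_back(std::make_pair(a, b));
      }
    }
  }
}

// ---- forces ----------------------------------------------------------------

// helper: min-image separation vector r_i - r_j
static inline void sep(const St& s, const Par& p, int i, int j, double d[3]) {
  d[0] = minx(s.x[i] - s.x[j], p);
  d[1] = s.y[i] - s.y[j];
  d[2] = s.z[i] - s.z[j];
}

static void spring_forces(const St& s, const Par& p, double* F) {
  for (size_t f = 0; f < s.fils.size(); ++f) {
    const std::vector<int>& b = s.fils[f];
    for (size_t k = 0; k + 1 < b.size(); ++k) {
      int i = b[k], j = b[k + 1];
      double d[3]; sep(s, p, i, j, d);
      double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
      if (r <= 0) stop("coincident bonded beads (filament %d)", (int)f + 1);
      double mag = -p.k_actin * (r - p.l0) / r;
      for (int c = 0; c < 3; ++c) {
        F[3*i + c] += mag * d[c];
        F[3*j + c] -= mag * d[c];
      }
    }
  }
}

// gradient of cos(theta) for the triplet (i,j,k), u = rj - ri, v = rk - rj
static void cos_grad(const double u[3], const double v[3],
                     double gi[3], double gj[3], double gk[3], double& c) {
  double nu = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  double nv = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
  double uv = u[0]*v[0] + u[1]*v[1] + u[2]*v[2];
  c = uv / (nu * nv);
  for (int a = 0; a < 3; ++a) {
    double dcu = v[a] / (nu * nv) - c * u[a] / (nu * nu);
    double dcv = u[a] / (nu * nv) - c * v[a] / (nv * nv);
    gi[a] = -dcu;
    gj[a] = dcu - dcv;
    gk[a] = dcv;
  }
}

static void bending_forces(const St& s, const Par& p, double* F) {
  double kap = p.kBT * p.l_p / p.l0; // kappa/l0, E = (kappa/l0)(1 - cos)
  for (size_t f = 0; f < s.fils.size(); ++f) {
    const std::vector<int>& b = s.fils[f];
    for (size_t k = 0; k + 2 < b.size(); ++k) {
      int i = b[k], j = b[k + 1], m = b[k + 2];
      double u[3], v[3];
      sep(s, p, j, i, u);
      sep(s, p, m, j, v);
      double gi[3], gj[3], gk[3], c;
      cos_grad(u, v, gi, gj, gk, c);
      // F = -dE/dr = +(kappa/l0) dcos/dr
      for (int a = 0; a < 3; ++a) {
        F[3*i + a] += kap * gi[a];
        F[3*j + a] += kap * gj[a];
        F[3*m + a] += kap * gk[a];
      }
    }
  }
}

static void crosslink_forces(const St& s, const Par& p, double* F) {
  for (size_t q = 0; q < s.xa.size(); ++q) {
    int i = s.xa[q], j = s.xb[q];
    double kk = (s.xtype[q] == XL_BRANCH) ? p.k_actin : p.k_xl;
    double rl = (s.xtype[q] == XL_BRANCH) ? p.d_ex : p.l0_xl;
    double d[3]; sep(s, p, i, j, d);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (r <= 0) stop("coincident crosslinked beads");
    double mag = -kk * (r - rl) / r;
    for (int c = 0; c < 3; ++c) {
      F[3*i + c] += mag * d[c];
      F[3*j + c] -= mag * d[c];
    }
  }
}

static void excluded_forces(St& s, const Par& p,
                            const std::vector<Seg>& segs,
                            const std::vector<std::pair<int,int> >& pairs,
                            double* F) {
  for (size_t q = 0; q < pairs.size(); ++q) {
    const Seg& A = segs[pairs[q].first];
    const Seg& B = segs[pairs[q].second];
    // shift B by the x image closest to A's first bead
    double shift = minx(s.x[B.i] - s.x[A.i], p) - (s.x[B.i] - s.x[A.i]);
    double a0[3] = { s.x[A.i], s.y[A.i], s.z[A.i] };
    double a1[3] = { s.x[A.i] + minx(s.x[A.j] - s.x[A.i], p), s.y[A.j], s.z[A.j] };
    double b0[3] = { s.x[B.i] + shift, s.y[B.i], s.z[B.i] };
    double b1[3] = { s.x[B.i] + shift + minx(s.x[B.j] - s.x[B.i], p), s.y[B.j], s.z[B.j] };
    double sa, sb;
    double d = seg_seg(a0, a1, b0, b1, sa, sb);
    if (d >= p.d_ex) continue;
    double dir[3];
    if (d < 1e-9) {
      // exactly overlapping: random tiny kick, logged
      double nr = 0;
      for (int c = 0; c < 3; ++c) { dir[c] = s.rng.normal(); nr += dir[c]*dir[c]; }
      nr = std::sqrt(nr);
      for (int c = 0; c < 3; ++c) dir[c] /= nr;
      s.n_overlap_kicks++;
    } else {
      for (int c = 0; c < 3; ++c)
        dir[c] = ((a0[c] + sa * (a1[c] - a0[c])) - (b0[c] + sb * (b1[c] - b0[c]))) / d;
    }
    double mag = p.k_ex * (p.d_ex - d); // repulsive, on A along +dir
    for (int c = 0; c < 3; ++c) {
      F[3*A.i + c] += mag * dir[c] * (1.0 - sa);
      F[3*A.j + c] += mag * dir[c] * sa;
      F[3*B.i + c] -= mag * dir[c] * (1.0 - sb);
      F[3*B.j + c] -= mag * dir[c] * sb;
    }
  }
}

struct Trip { int i, j, k; };

static void list_triplets(const St& s, std::vector<Trip>& trips) {
  trips.clear();
  for (size_t f = 0; f < s.fils.size(); ++f)
    for (size_t k = 0; k + 2 < s.fils[f].size(); ++k)
      trips.push_back(Trip{ s.fils[f][k], s.fils[f][k + 1], s.fils[f][k + 2] });
}

static void spring_forces_flat(const St& s, const Par& p,
                               const std::vector<Seg>& segs, double* F) {
  for (size_t q = 0; q < segs.size(); ++q) {
    int i = segs[q].i, j = segs[q].j;
    double d[3]; sep(s, p, i, j, d);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (r <= 0) stop("coincident bonded beads");
    double mag = -p.k_actin * (r - p.l0) / r;
    for (int c = 0; c < 3; ++c) {
      F[3*i + c] += mag * d[c];
      F[3*j + c] -= mag * d[c];
    }
  }
}

static void bending_forces_flat(const St& s, const Par& p,
                                const std::vector<Trip>& trips, double* F) {
  double kap = p.kBT * p.l_p / p.l0;
  for (size_t q = 0; q < trips.size(); ++q) {
    int i = trips[q].i, j = trips[q].j, m = trips[q].k;
    double u[3], v[3];
    sep(s, p, j, i, u);
    sep(s, p, m, j, v);
    double gi[3], gj[3], gk[3], c;
    cos_grad(u, v, gi, gj, gk, c);
    for (int a = 0; a < 3; ++a) {
      F[3*i + a] += kap * gi[a];
      F[3*j + a] += kap * gj[a];
      F[3*m + a] += kap * gk[a];
    }
  }
}

// direction of pushing for filament f: barbed -> pointed unit vector of the
// pointed-end segment (bead0 - bead1).
static bool pointed_dir(const St& s, const Par& p, int f, double dir[3]) {
  const std::vector<int>& b = s.fils[f];
  if (b.size() < 2) return false;
  double d[3]; sep(s, p, b[0], b[1], d);
  double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  if (r <= 0) return false;
  for (int c = 0; c < 3; ++c) dir[c] = d[c] / r;
  return true;
}

static void leading_forces(const St& s, const Par& p, double* F,
                           double* sum = 0) {
  double Ftot = p.F_push * p.push_frac;
  for (size_t f = 0; f < s.fils.size(); ++f) {
    const std::vector<int>& b = s.fils[f];
    bool in = false;
    for (size_t k = 0; k < b.size(); ++k)
      if (s.y[b[k]] <= 0.0) { in = true; break; }
    if (!in) continue;
    double dir[3];
    if (!pointed_dir(s, p, f, dir)) continue;
    double per = Ftot / b.size();
    for (size_t k = 0; k < b.size(); ++k)
      for (int c = 0; c < 3; ++c) {
        F[3*b[k] + c] += per * dir[c];
        if (sum) sum[c] += per * dir[c];
      }
  }
}

static bool in_fa(const St& s, const Par& p, int i) {
  if (!p.fa_on) return false;
  if (s.z[i] < 0 || s.z[i] > p.fa_h) return false;
  // work in a frame centred on the capsule so the minimum image is applied
  // to the point as a whole, not to the projection arithmetic
  double cx = p.fa_x0 + 0.5 * minx(p.fa_x1 - p.fa_x0, p);
  double px = cx + minx(s.x[i] - cx, p);
  double vx = minx(p.fa_x1 - p.fa_x0, p), vy = p.fa_y1 - p.fa_y0;
  double x0 = cx - 0.5 * vx, y0 = 0.5 * (p.fa_y0 + p.fa_y1) - 0.5 * vy;
  double wx = px - x0, wy = s.y[i] - y0;
  double L2 = vx * vx + vy * vy;
  double tpar = (L2 > 0) ? std::max(0.0, std::min(1.0, (wx * vx + wy * vy) / L2)) : 0.0;
  double dx = wx - tpar * vx, dy = wy - tpar * vy;
  return dx * dx + dy * dy <= p.fa_r * p.fa_r;
}

static void motor_forces(const St& s, const Par& p, double* F,
                         double* sum = 0) {
  int n = s.x.size();
  if (p.pull_mode == 0) {
    for (int i = 0; i < n; ++i) F[3*i + 1] += p.F_pull_uniform;
    if (sum) sum[1] += n * p.F_pull_uniform;
  } else if (p.pull_mode == 1) {
    for (int i = 0; i < n; ++i)
      if (s.y[i] > p.y_back) {
        F[3*i + 1] += p.F_pull_back;
        if (sum) sum[1] += p.F_pull_back;
      }
  } else {
    // membrane pulling: beads near the substrate, outside the FA capsule,
    // pulled along the filament's barbed->pointed axis
    std::vector<char> has(s.fils.size(), 0);
    std::vector<std::array<double,3> > dirs(s.fils.size());
    for (size_t f = 0; f < s.fils.size(); ++f) {
      double d[3];
      if (pointed_dir(s, p, (int)f, d)) {
        has[f] = 1; dirs[f] = { d[0], d[1], d[2] };
      }
    }
    for (int i = 0; i < n; ++i) {
      if (s.z[i] < 0 || s.z[i] > p.membrane_z) continue;
      if (in_fa(s, p, i)) continue;
      int f = s.fil[i];
      if (f < 0 || !has[f]) continue;
      for (int c = 0; c < 3; ++c) {
        F[3*i + c] += p.F_pull_membrane * dirs[f][c];
        if (sum) sum[c] += p.F_pull_membrane * dirs[f][c];
      }
    }
  }
}

static void confine_forces(const St& s, const Par& p, double* F,
                           double* sum = 0) {
  int n = s.x.size();
  for (int i = 0; i < n; ++i) {
    if (s.z[i] < 0) {
      F[3*i + 2] += p.confine_F;
      if (sum) sum[2] += p.confine_F;
    } else if (p.top_wall && s.z[i] > p.box_h) {
      F[3*i + 2] -= p.confine_F;
      if (sum) sum[2] -= p.confine_F;
    }
  }
}

static void branch_forces(const St& s, const Par& p, double* F) {
  for (size_t q = 0; q < s.bi.size(); ++q) {
    int i = s.bi[q], j = s.bj[q], k = s.bk[q];
    double u[3], v[3];
    sep(s, p, j, i, u);
    sep(s, p, k, j, v);
    double gi[3], gj[3], gk[3], c;
    cos_grad(u, v, gi, gj, gk, c);
    double pref = -2.0 * p.eps_angle * (c - p.cos_theta0); // F = -dE/dr
    for (int a = 0; a < 3; ++a) {
      F[3*i + a] += pref * gi[a];
      F[3*j + a] += pref * gj[a];
      F[3*k + a] += pref * gk[a];
    }
  }
}

static void thermal_forces(St& s, const Par& p, double* F,
                           double* sum = 0) {
  int n = s.x.size();
  for (int i = 0; i < n; ++i) {
    double zeff = (s.bound[i] && p.thermal_fa_drag) ? p.kappa_FA * p.zeta_b : p.zeta_b;
    double sd = std::sqrt(2.0 * p.kBT * zeff / p.dt);
    for (int c = 0; c < 3; ++c) {
      double v = sd * s.rng.normal();
      F[3*i + c] += v;
      if (sum) sum[c] += v;
    }
  }
}

// [[Rcpp::export]]
List cpp_forces(List state, List params, bool include_thermal = false) {
  St s = st_from_list(state);
  Par p = par_from_list(params);
  if (include_thermal) {
    // independent thermal realization per call, governed by R's RNG
    uint64_t x = (uint64_t)(unif_rand() * 9007199254740992.0);
    for (int k = 0; k < 4; ++k) s.rng.s[k] = splitmix64(x);
    s.rng.have_spare = false;
  }
  int n = s.x.size();
  std::vector<Seg> segs;
  list_segments(s, segs);
  std::vector<std::pair<int,int> > pairs;
  candidate_pairs(s, p, segs, p.d_ex + p.skin, pairs);
  List out;
  const char* names[NCH] = { "spring", "bend", "crosslink", "excluded",
                             "leading", "motor", "confine", "branch_angle",
                             "thermal" };
  std::vector<double> buf;
  for (int ch = 0; ch < NCH; ++ch) {
    buf.assign(3 * n, 0.0);
    switch (ch) {
      case CH_SPRING: spring_forces(s, p, buf.data()); break;
      case CH_BEND: bending_forces(s, p, buf.data()); break;
      case CH_XL: crosslink_forces(s, p, buf.data()); break;
      case CH_EXCL: excluded_forces(s, p, segs, pairs, buf.data()); break;
      case CH_LEAD: leading_forces(s, p, buf.data()); break;
      case CH_MOTOR: motor_forces(s, p, buf.data()); break;
      case CH_CONF: confine_forces(s, p, buf.data()); break;
      case CH_BRANCH: branch_forces(s, p, buf.data()); break;
      case CH_THERM: if (include_thermal) thermal_forces(s, p, buf.data()); break;
    }
    NumericMatrix m(n, 3);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) m(i, c) = buf[3*i + c];
    out[names[ch]] = m;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_energy(List state, List params) {
  St s = st_from_list(state);
  Par p = par_from_list(params);
  double Es = 0, Eb = 0, Ex = 0, Ee = 0, Ea = 0;
  for (size_t f = 0; f < s.fils.size(); ++f) {
    const std::vector<int>& b = s.fils[f];
    for (size_t k = 0; k + 1 < b.size(); ++k) {
      double d[3]; sep(s, p, b[k], b[k+1], d);
      double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
      Es += 0.5 * p.k_actin * (r - p.l0) * (r - p.l0);
    }
    double kap = p.kBT * p.l_p / p.l0;
    for (size_t k = 0; k + 2 < b.size(); ++k) {
      double u[3], v[3];
      sep(s, p, b[k+1], b[k], u);
      sep(s, p, b[k+2], b[k+1], v);
      double gi[3], gj[3], gk[3], c;
      cos_grad(u, v, gi, gj, gk, c);
      Eb += kap * (1.0 - c);
    }
  }
  for (size_t q = 0; q < s.xa.size(); ++q) {
    double kk = (s.xtype[q] == XL_BRANCH) ? p.k_actin : p.k_xl;
    double rl = (s.xtype[q] == XL_BRANCH) ? p.d_ex : p.l0_xl;
    double d[3]; sep(s, p, s.xa[q], s.xb[q], d);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    Ex += 0.5 * kk * (r - rl) * (r - rl);
  }
  std::vector<Seg> segs;
  list_segments(s, segs);
  std::vector<std::pair<int,int> > pairs;
  candidate_pairs(s, p, segs, p.d_ex + p.skin, pairs);
  for (size_t q = 0; q < pairs.size(); ++q) {
    const Seg& A = segs[pairs[q].first];
    const Seg& B = segs[pairs[q].second];
    double shift = minx(s.x[B.i] - s.x[A.i], p) - (s.x[B.i] - s.x[A.i]);
    double a0[3] = { s.x[A.i], s.y[A.i], s.z[A.i] };
    double a1[3] = { s.x[A.i] + minx(s.x[A.j] - s.x[A.i], p), s.y[A.j], s.z[A.j] };
    double b0[3] = { s.x[B.i] + shift, s.y[B.i], s.z[B.i] };
    double b1[3] = { s.x[B.i] + shift + minx(s.x[B.j] - s.x[B.i], p), s.y[B.j], s.z[B.j] };
    double sa, sb;
    double d = seg_seg(a0, a1, b0, b1, sa, sb);
    if (d < p.d_ex) Ee += 0.5 * p.k_ex * (p.d_ex - d) * (p.d_ex - d);
  }
  for (size_t q = 0; q < s.bi.size(); ++q) {
    double u[3], v[3];
    sep(s, p, s.bj[q], s.bi[q], u);
    sep(s, p, s.bk[q], s.bj[q], v);
    double gi[3], gj[3], gk[3], c;
    cos_grad(u, v, gi, gj, gk, c);
    Ea += p.eps_angle * (c - p.cos_theta0) * (c - p.cos_theta0);
  }
  return NumericVector::create(
    _["spring"] = Es, _["bend"] = Eb, _["crosslink"] = Ex,
    _["excluded"] = Ee, _["branch_angle"] = Ea);
}

// [[Rcpp::export]]
List cpp_seg_closest(NumericVector a0, NumericVector a1, NumericVector b0,
                     NumericVector b1, double width, bool periodic) {
  double A0[3] = { a0[0], a0[1], a0[2] }, A1[3] = { a1[0], a1[1], a1[2] };
  double B0[3] = { b0[0], b0[1], b0[2] }, B1[3] = { b1[0], b1[1], b1[2] };
  double la = 0, lb = 0;
  for (int c = 0; c < 3; ++c) {
    la += (A1[c]-A0[c])*(A1[c]-A0[c]);
    lb += (B1[c]-B0[c])*(B1[c]-B0[c]);
  }
  if (la == 0 || lb == 0) stop("zero-length segment");
  if (periodic) {
    double dx = B0[0] - A0[0];
    double sh = (dx - width * std::nearbyint(dx / width)) - dx;
    B0[0] += sh; B1[0] += sh;
  }
  double sa, sb;
  double d = seg_seg(A0, A1, B0, B1, sa, sb);
  NumericVector pa(3), pb(3);
  for (int c = 0; c < 3; ++c) {
    pa[c] = A0[c] + sa * (A1[c] - A0[c]);
    pb[c] = B0[c] + sb * (B1[c] - B0[c]);
  }
  return List::create(_["distance"] = d, _["point_a"] = pa, _["point_b"] = pb,
                      _["s_a"] = sa, _["s_b"] = sb);
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(List state, List params, double cutoff) {
  St s = st_from_list(state);
  Par p = par_from_list(params);
  std::vector<Seg> segs;
  list_segments(s, segs);
  std::vector<std::pair<int,int> > cand;
  candidate_pairs(s, p, segs, cutoff, cand);
  std::vector<std::array<int,4> > keep;
  for (size_t q = 0; q < cand.size(); ++q) {
    const Seg& A = segs[cand[q].first];
    const Seg& B = segs[cand[q].second];
    double shift = minx(s.x[B.i] - s.x[A.i], p) - (s.x[B.i] - s.x[A.i]);
    double a0[3] = { s.x[A.i], s.y[A.i], s.z[A.i] };
    double a1[3] = { s.x[A.i] + minx(s.x[A.j] - s.x[A.i], p), s.y[A.j], s.z[A.j] };
    double b0[3] = { s.x[B.i] + shift, s.y[B.i], s.z[B.i] };
    double b1[3] = { s.x[B.i] + shift + minx(s.x[B.j] - s.x[B.i], p), s.y[B.j], s.z[B.j] };
    double sa, sb;
    if (seg_seg(a0, a1, b0, b1, sa, sb) < cutoff)
      keep.push_back({ A.i + 1, A.j + 1, B.i + 1, B.j + 1 });
  }
  IntegerMatrix out(keep.size(), 4);
  for (size_t q = 0; q < keep.size(); ++q)
    for (int c = 0; c < 4; ++c) out(q, c) = keep[q][c];
  colnames(out) = CharacterVector::create("i1", "j1", "i2", "j2");
  return out;
}

// ---- events ----------------------------------------------------------------

static double draw_lifetime(St& s, const Par& p) {
  return p.tau_age - std::log(s.rng.unif()) / p.r_age;
}

// bead-level neighbour candidates within [rmin, rmax]; returns bead pairs
static void bead_pairs_in_shell(const St& s, const Par& p, double rmin,
                                double rmax,
                                std::vector<std::pair<int,int> >& out) {
  out.clear();
  int n = s.x.size();
  if (n < 2) return;
  double edge = rmax;
  double ymin = 1e30, ymax = -1e30, zmin = 1e30, zmax = -1e30, xmin = 1e30, xma = -1e30;
  for (int i = 0; i < n; ++i) {
    ymin = std::min(ymin, s.y[i]); ymax = std::max(ymax, s.y[i]);
    zmin = std::min(zmin, s.z[i]); zmax = std::max(zmax, s.z[i]);
    xmin = std::min(xmin, s.x[i]); xma = std::max(xma, s.x[i]);
  }
  double xspan = p.periodic ? p.box_w : (xma - xmin);
  if (!p.periodic) xspan = std::max(xspan, edge);
  else xmin = 0.0;
  int ncx = std::max(1, (int)std::floor(xspan / edge));
  int ncy = std::max(1, (int)std::floor((ymax - ymin) / edge) + 1);
  int ncz = std::max(1, (int)std::floor((zmax - zmin) / edge) + 1);
  double ex = xspan / ncx;
  std::vector<std::vector<int> > cells((size_t)ncx * ncy * ncz);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    int icx = std::max(0, std::min(ncx - 1, (int)std::floor((s.x[i] - xmin) / ex)));
    int icy = std::max(0, std::min(ncy - 1, (int)std::floor((s.y[i] - ymin) / edge)));
    int icz = std::max(0, std::min(ncz - 1, (int)std::floor((s.z[i] - zmin) / edge)));
    ci[i] = icx; cj[i] = icy; ck[i] = icz;
    cells[(size_t)(icz * ncy + icy) * ncx + icx].push_back(i);
  }
  double r2min = rmin * rmin, r2max = rmax * rmax;
  for (int i = 0; i < n; ++i) {
    for (int ddz = 0; ddz <= 1; ++ddz)
    for (int ddy = -1; ddy <= 1; ++ddy)
    for (int ddx = -1; ddx <= 1; ++ddx) {
      if (ddz == 0 && (ddy < 0 || (ddy == 0 && ddx < 0))) continue;
      int icy = cj[i] + ddy, icz = ck[i] + ddz;
      if (icy < 0 || icy >= ncy || icz >= ncz) continue;
      int icx = ci[i] + ddx;
      if (p.periodic) icx = (icx % ncx + ncx) % ncx;
      else if (icx < 0 || icx >= ncx) continue;
      const std::vector<int>& cell = cells[(size_t)(icz * ncy + icy) * ncx + icx];
      for (size_t q = 0; q < cell.size(); ++q) {
        int j = cell[q];
        if (ddx == 0 && ddy == 0 && ddz == 0 && j <= i) continue;
        double d[3]; sep(s, p, i, j, d);
        double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
        if (r2 >= r2min && r2 <= r2max) out.push_back(std::make_pair(i, j));
      }
    }
  }
}

static int add_bead(St& s, const Par& p, double x, double y, double z) {
  if (p.periodic) x -= p.box_w * std::floor(x / p.box_w);
  s.x.push_back(x); s.y.push_back(y); s.z.push_back(z);
  s.birth.push_back(s.t);
  s.uid.push_back(s.next_uid);
  s.next_uid += 1;
  s.wrapn.push_back(0);
  s.bound.push_back(0);
  s.fil.push_back(-1);
  return (int)s.x.size() - 1;
}

// insert a straight filament: pointed end at (x0,y0,z0), direction dir
// (pointed -> barbed), nb beads at spacing l0. Returns filament index.
static int insert_filament(St& s, const Par& p, double x0, double y0,
                           double z0, const double dir[3], int nb) {
  std::vector<int> beads(nb);
  for (int k = 0; k < nb; ++k)
    beads[k] = add_bead(s, p, x0 + k * p.l0 * dir[0], y0 + k * p.l0 * dir[1],
                        z0 + k * p.l0 * dir[2]);
  std::vector<double> tv(nb - 1);
  for (int k = 0; k < nb - 1; ++k) tv[k] = s.t + draw_lifetime(s, p);
  int f = (int)s.fils.size();
  s.fils.push_back(beads);
  s.taus.push_back(tv);
  s.fil_id.push_back(s.next_fil_id++);
  for (int k = 0; k < nb; ++k) s.fil[beads[k]] = f;
  return f;
}

static void seed_permanent(St& s, const Par& p, int f) {
  // candidate pairs: (new-filament bead, other-filament bead), separation in
  // [0.03, 0.04]; pick up to 5 uniformly without replacement
  const std::vector<int>& nb = s.fils[f];
  std::unordered_set<int> mine(nb.begin(), nb.end());
  std::vector<std::pair<int,int> > all, cand;
  bead_pairs_in_shell(s, p, 0.03, 0.04, all);
  for (size_t q = 0; q < all.size(); ++q) {
    bool ain = mine.count(all[q].first) > 0, bin = mine.count(all[q].second) > 0;
    if (ain == bin) continue; // both on new filament or both elsewhere
    cand.push_back(all[q]);
  }
  int want = std::min((int)cand.size(), 5);
  for (int c = 0; c < want; ++c) {
    int pick = c + (int)std::floor(s.rng.unif() * (cand.size() - c));
    if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
    std::swap(cand[c], cand[pick]);
    s.xa.push_back(cand[c].first);
    s.xb.push_back(cand[c].second);
    if (p.longlived_lifetime > 0) {
      s.xtype.push_back(XL_LONG);
      s.xtau.push_back(s.t - p.longlived_lifetime * std::log(s.rng.unif()));
    } else {
      s.xtype.push_back(XL_PERM);
      s.xtau.push_back(R_PosInf);
    }
  }
}

// mode: 0 fan, 1 microspike near-existing, 2 microspike random-x, 3 branching
static int spawn_one(St& s, const Par& p, int mode) {
  int nb = p.beads_per_fil;
  if (mode == 3) {
    // branch nucleation: uniformly chosen interior mother bead with
    // y in [0.20, 0.25]
    std::vector<int> moms;
    for (size_t f = 0; f < s.fils.size(); ++f)
      for (size_t k = 1; k + 1 < s.fils[f].size(); ++k) {
        int b = s.fils[f][k];
        if (s.y[b] >= 0.20 && s.y[b] <= 0.25) moms.push_back(b);
      }
    if (moms.empty()) { s.n_skipped_spawns++; return -1; }
    int j = moms[std::min((int)(s.rng.unif() * moms.size()), (int)moms.size() - 1)];
    int fm = s.fil[j];
    const std::vector<int>& mb = s.fils[fm];
    size_t kj = std::find(mb.begin(), mb.end(), j) - mb.begin();
    int i = mb[kj - 1]; // pointed-side neighbour
    double m[3]; sep(s, p, j, i, m); // mother local direction, pointed->barbed
    double nm = std::sqrt(m[0]*m[0] + m[1]*m[1]);
    if (nm <= 0) { s.n_skipped_spawns++; return -1; }
    double mxn = m[0] / nm, myn = m[1] / nm;
    double sgn = (s.rng.unif() < 0.5) ? 1.0 : -1.0;
    double th = sgn * std::acos(p.cos_theta0);
    double dir[3] = { mxn * std::cos(th) - myn * std::sin(th),
                      mxn * std::sin(th) + myn * std::cos(th), 0.0 };
    double x0 = s.x[j] + p.d_ex * dir[0];
    double y0 = s.y[j] + p.d_ex * dir[1];
    double z0 = s.z[j];
    int f = insert_filament(s, p, x0, y0, z0, dir, nb);
    int k = s.fils[f][0];
    s.bi.push_back(i); s.bj.push_back(j); s.bk.push_back(k);
    s.xa.push_back(j); s.xb.push_back(k);
    s.xtype.push_back(XL_BRANCH); s.xtau.push_back(R_PosInf);
    return f;
  }
  bool vertical = false;
  if (mode == 1 || mode == 2) {
    // deterministic alternation: every other insertion is vertical
    vertical = (((long long)s.spawn_count) % 2LL) == 1LL;
  }
  double x0, z0 = s.rng.unif() * p.box_h, y0 = 0.5;
  double dir[3];
  if (vertical) {
    dir[0] = 0; dir[1] = -1; dir[2] = 0; // axis along y, barbed towards edge
    if (mode == 1) {
      std::vector<int> anch;
      for (size_t i = 0; i < s.x.size(); ++i)
        if (s.y[i] < 1.0) anch.push_back((int)i);
      if (!anch.empty()) {
        int a = anch[std::min((int)(s.rng.unif() * anch.size()), (int)anch.size() - 1)];
        x0 = s.x[a] + ((s.rng.unif() < 0.5) ? 0.035 : -0.035);
      } else {
        x0 = s.rng.unif() * p.box_w; // fall back to random x, logged
        s.n_skipped_spawns++;
      }
    } else {
      x0 = s.rng.unif() * p.box_w;
    }
  } else {
    x0 = s.rng.unif() * p.box_w;
    double phi = (s.rng.unif() * 140.0 - 70.0) * M_PI / 180.0; // in-plane
    double psi = (s.rng.unif() * 20.0 - 10.0) * M_PI / 180.0;  // out-of-plane
    dir[0] = std::sin(phi);
    dir[1] = -std::cos(phi) * std::cos(psi);
    dir[2] = -std::cos(phi) * std::sin(psi);
  }
  int f = insert_filament(s, p, x0, y0, z0, dir, nb);
  seed_permanent(s, p, f);
  return f;
}

static int spawn_filaments(St& s, const Par& p, double dt, int mode) {
  s.resid += p.add_rate * dt;
  int added = 0;
  while (s.resid >= 1.0) {
    s.resid -= 1.0;
    if (spawn_one(s, p, mode) >= 0) added++;
    s.spawn_count += 1;
  }
  return added;
}

static long dynamic_cap(const Par& p) {
  return (long)std::nearbyint(p.C_dynamic * 602.214 * p.box_w * 9.5 * p.box_h);
}

static int replenish_dynamic(St& s, const Par& p) {
  long cap = dynamic_cap(p);
  long have = 0;
  for (size_t q = 0; q < s.xtype.size(); ++q)
    if (s.xtype[q] == XL_DYN) have++;
  if (have >= cap) return 0;
  std::unordered_set<uint64_t> bonded;
  for (size_t q = 0; q < s.xa.size(); ++q) {
    uint64_t a = std::min(s.xa[q], s.xb[q]), b = std::max(s.xa[q], s.xb[q]);
    bonded.insert((a << 32) | b);
  }
  std::vector<std::pair<int,int> > all, cand;
  bead_pairs_in_shell(s, p, 0.03, 0.04, all);
  for (size_t q = 0; q < all.size(); ++q) {
    int a = all[q].first, b = all[q].second;
    if (s.fil[a] == s.fil[b]) continue; // never within one filament
    uint64_t key = ((uint64_t)std::min(a, b) << 32) | (uint64_t)std::max(a, b);
    if (bonded.count(key)) continue;
    cand.push_back(all[q]);
  }
  int want = (int)std::min((long)cand.size(), cap - have);
  for (int c = 0; c < want; ++c) {
    int pick = c + (int)std::floor(s.rng.unif() * (cand.size() - c));
    if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
    std::swap(cand[c], cand[pick]);
    s.xa.push_back(cand[c].first);
    s.xb.push_back(cand[c].second);
    s.xtype.push_back(XL_DYN);
    s.xtau.push_back(s.t - std::log(s.rng.unif()) / p.k_dyn_off);
  }
  return want;
}

static void fa_update(St& s, const Par& p, double dt) {
  if (!p.fa_on) return;
  double pb = 1.0 - std::exp(-p.k_bind * dt);
  double pu = 1.0 - std::exp(-p.k_unbind * dt);
  int n = s.x.size();
  for (int i = 0; i < n; ++i) {
    if (!in_fa(s, p, i)) {
      s.bound[i] = 0;
      continue;
    }
    if (s.bound[i]) {
      if (s.rng.unif() < pu) s.bound[i] = 0;
    } else {
      if (s.rng.unif() < pb) s.bound[i] = 1;
    }
  }
}

// remove expired actin bonds (splitting filaments; the barbed-side fragment
// keeps the filament id) and expired crosslinks, then prune single-bead
// filaments together with their crosslinks, repeating to a fixed point.
static void compact_beads(St& s, const std::vector<char>& dead) {
  int n = s.x.size();
  std::vector<int> remap(n, -1);
  int m = 0;
  for (int i = 0; i < n; ++i) if (!dead[i]) remap[i] = m++;
  if (m == n) return;
  for (int i = 0; i < n; ++i) {
    int r = remap[i];
    if (r < 0) continue;
    s.x[r] = s.x[i]; s.y[r] = s.y[i]; s.z[r] = s.z[i];
    s.birth[r] = s.birth[i]; s.uid[r] = s.uid[i];
    s.wrapn[r] = s.wrapn[i]; s.bound[r] = s.bound[i];
  }
  s.x.resize(m); s.y.resize(m); s.z.resize(m);
  s.birth.resize(m); s.uid.resize(m); s.wrapn.resize(m); s.bound.resize(m);
  for (size_t f = 0; f < s.fils.size(); ++f)
    for (size_t k = 0; k < s.fils[f].size(); ++k)
      s.fils[f][k] = remap[s.fils[f][k]];
  for (size_t q = 0; q < s.xa.size(); ++q) {
    s.xa[q] = remap[s.xa[q]];
    s.xb[q] = remap[s.xb[q]];
  }
  for (size_t q = 0; q < s.bi.size(); ++q) {
    s.bi[q] = remap[s.bi[q]];
    s.bj[q] = remap[s.bj[q]];
    s.bk[q] = remap[s.bk[q]];
  }
  s.fil.assign(m, -1);
  for (size_t f = 0; f < s.fils.size(); ++f)
    for (size_t k = 0; k < s.fils[f].size(); ++k)
      s.fil[s.fils[f][k]] = (int)f;
}

static void drop_crosslinks(St& s, const std::vector<char>& drop) {
  size_t m = 0;
  for (size_t q = 0; q < s.xa.size(); ++q) {
    if (drop[q]) continue;
    s.xa[m] = s.xa[q]; s.xb[m] = s.xb[q];
    s.xtype[m] = s.xtype[q]; s.xtau[m] = s.xtau[q];
    m++;
  }
  s.xa.resize(m); s.xb.resize(m); s.xtype.resize(m); s.xtau.resize(m);
}

static void prune_singletons(St& s) {
  for (;;) {
    std::vector<char> dead(s.x.size(), 0);
    bool any = false;
    std::vector<std::vector<int> > nf;
    std::vector<std::vector<double> > nt;
    std::vector<int> nid;
    for (size_t f = 0; f < s.fils.size(); ++f) {
      if (s.fils[f].size() <= 1) {
        for (size_t k = 0; k < s.fils[f].size(); ++k) {
          dead[s.fils[f][k]] = 1;
          any = true;
        }
      } else {
        nf.push_back(s.fils[f]);
        nt.push_back(s.taus[f]);
        nid.push_back(s.fil_id[f]);
      }
    }
    if (!any) return;
    s.fils.swap(nf); s.taus.swap(nt); s.fil_id.swap(nid);
    std::vector<char> dropx(s.xa.size(), 0);
    for (size_t q = 0; q < s.xa.size(); ++q)
      if (dead[s.xa[q]] || dead[s.xb[q]]) dropx[q] = 1;
    drop_crosslinks(s, dropx);
    // branch triplets referencing dead beads go too
    size_t m = 0;
    for (size_t q = 0; q < s.bi.size(); ++q) {
      if (dead[s.bi[q]] || dead[s.bj[q]] || dead[s.bk[q]]) continue;
      s.bi[m] = s.bi[q]; s.bj[m] = s.bj[q]; s.bk[m] = s.bk[q];
      m++;
    }
    s.bi.resize(m); s.bj.resize(m); s.bk.resize(m);
    compact_beads(s, dead);
    // single-bead removal cannot create new singletons directly, but a
    // filament emptied by repeated splits could; loop to fixed point
  }
}

static void expire_bonds(St& s, const Par& p) {
  // split filaments at expired bonds
  std::vector<std::vector<int> > nf;
  std::vector<std::vector<double> > nt;
  std::vector<int> nid;
  bool changed = false;
  for (size_t f = 0; f < s.fils.size(); ++f) {
    const std::vector<int>& b = s.fils[f];
    const std::vector<double>& tv = s.taus[f];
    std::vector<size_t> cuts;
    for (size_t k = 0; k < tv.size(); ++k)
      if (tv[k] <= s.t) cuts.push_back(k);
    if (cuts.empty()) {
      nf.push_back(b); nt.push_back(tv); nid.push_back(s.fil_id[f]);
      continue;
    }
    changed = true;
    size_t start = 0;
    std::vector<std::pair<size_t,size_t> > ranges; // [start, end] bead index
    for (size_t c = 0; c < cuts.size(); ++c) {
      ranges.push_back(std::make_pair(start, cuts[c]));
      start = cuts[c] + 1;
    }
    ranges.push_back(std::make_pair(start, b.size() - 1));
    // barbed-most fragment (last range) keeps the original id
    for (size_t rg = 0; rg < ranges.size(); ++rg) {
      std::vector<int> fb(b.begin() + ranges[rg].first,
                          b.begin() + ranges[rg].second + 1);
      std::vector<double> ftv;
      for (size_t k = ranges[rg].first; k < ranges[rg].second; ++k)
        ftv.push_back(tv[k]);
      nf.push_back(fb);
      nt.push_back(ftv);
      nid.push_back(rg + 1 == ranges.size() ? s.fil_id[f] : s.next_fil_id++);
    }
  }
  if (changed) {
    s.fils.swap(nf); s.taus.swap(nt); s.fil_id.swap(nid);
    s.fil.assign(s.x.size(), -1);
    for (size_t f = 0; f < s.fils.size(); ++f)
      for (size_t k = 0; k < s.fils[f].size(); ++k)
        s.fil[s.fils[f][k]] = (int)f;
  }
  // expired crosslinks
  std::vector<char> dropx(s.xa.size(), 0);
  bool anyx = false;
  for (size_t q = 0; q < s.xa.size(); ++q)
    if (s.xtau[q] <= s.t) { dropx[q] = 1; anyx = true; }
  if (anyx) drop_crosslinks(s, dropx);
  prune_singletons(s);
}

// ---- exported granular event ops -------------------------------------------

// [[Rcpp::export]]
List cpp_spawn_filaments(List state, List params, double dt, int mode) {
  St s = st_from_list(state);
  Par p = par_from_list(params);
  int added = spawn_filaments(s, p, dt, mode);
  return List::create(_["state"] = st_to_list(s), _["n_added"] = added);
}

// [[Rcpp::export]]
List cpp_seed_permanent(List state, List params, int fil_index) {
  St s = st_from_list(state);
  Par p = par_from_list(params);
  seed_permanent(s, p, fil_index - 1);
  return st_to_list(s);
}

// [[Rcpp::export]]
List cpp_replenish_dynamic(List state, List params) {
  St s = st_from_list(state);
  Par p = par_from_list(params);
  int added = replenish_dynamic(s, p);
  return List::create(_["state"] = st_to_list(s), _["n_added"] = added);
}

// [[Rcpp::export]]
List cpp_expire(List state, List params) {
  St s = st_from_list(state);
  Par p = par_from_list(params);
  expire_bonds(s, p);
  return st_to_list(s);
}

// [[Rcpp::export]]
List cpp_prune(List state, List params) {
  St s = st_from_list(state);
  prune_singletons(s);
  return st_to_list(s);
}

// [[Rcpp::export]]
List cpp_fa_update(List state, List params, double dt) {
  St s = st_from_list(state);
  Par p = par_from_list(params);
  fa_update(s, p, dt);
  return st_to_list(s);
}

// [[Rcpp::export]]
double cpp_dynamic_cap(List params) {
  Par p = par_from_list(params);
  return (double)dynamic_cap(p);
}

// [[Rcpp::export]]
LogicalVector cpp_in_fa(List state, List params) {
  St s = st_from_list(state);
  Par p = par_from_list(params);
  int n = s.x.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = in_fa(s, p, i);
  return out;
}

// ---- integrator ------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(List state, List params, int n_steps, int record_every,
             List flags, IntegerVector clamp_idx, NumericVector clamp_vy) {
  St s = st_from_list(state);
  Par p = par_from_list(params);
  bool do_thermal = as<bool>(flags["thermal"]);
  bool do_spawn = as<bool>(flags["spawn"]);
  bool do_expiry = as<bool>(flags["expiry"]);
  bool do_dynamic = as<bool>(flags["dynamic"]);
  bool do_fa_kinetics = as<bool>(flags["fa_kinetics"]);
  bool do_push = as<bool>(flags["push"]);
  bool do_motor = as<bool>(flags["motor"]);
  bool do_internal = as<bool>(flags["internal"]); // spring/bend/xl/excl/branch
  bool do_confine = as<bool>(flags["confine"]);
  int spawn_mode = as<int>(flags["spawn_mode"]);

  std::vector<char> clamped(s.x.size(), 0);
  std::vector<double> cvy(s.x.size(), 0.0);
  for (int q = 0; q < clamp_idx.size(); ++q) {
    int i = clamp_idx[q] - 1;
    if (i < 0 || i >= (int)s.x.size()) stop("clamp index out of range");
    clamped[i] = 1;
    cvy[i] = clamp_vy[q];
  }

  std::vector<Seg> segs;
  std::vector<Trip> trips;
  std::vector<std::pair<int,int> > pairs;
  bool need_rebuild = true;
  std::vector<double> ref_x, ref_y, ref_z; // positions at last rebuild
  double max_disp2_cap = (p.skin * 0.5) * (p.skin * 0.5);

  std::vector<double> F;
  // per-frame records
  std::vector<List> frames;
  std::vector<NumericMatrix> chanrec;
  int n_record = 0;

  for (int step = 0; step < n_steps; ++step) {
    int n = s.x.size();
    if ((int)clamped.size() != n) { // events resized bead arrays
      clamped.assign(n, 0);
      cvy.assign(n, 0.0);
      for (int q = 0; q < clamp_idx.size(); ++q) {
        int i = clamp_idx[q] - 1;
        if (i < (int)clamped.size()) { clamped[i] = 1; cvy[i] = clamp_vy[q]; }
      }
    }
    F.assign(3 * n, 0.0);
    s.rng.have_spare = false; // draws are a function of (state, step) only

    if (need_rebuild && do_internal) {
      list_segments(s, segs);
      list_triplets(s, trips);
      std::vector<std::pair<int,int> > cand;
      candidate_pairs(s, p, segs, p.d_ex + p.skin, cand);
      // keep only pairs verified within d_ex + skin by true segment
      // distance; completeness holds while per-bead drift stays < skin/2
      pairs.clear();
      for (size_t q = 0; q < cand.size(); ++q) {
        const Seg& A = segs[cand[q].first];
        const Seg& B = segs[cand[q].second];
        double shift = minx(s.x[B.i] - s.x[A.i], p) - (s.x[B.i] - s.x[A.i]);
        double a0[3] = { s.x[A.i], s.y[A.i], s.z[A.i] };
        double a1[3] = { s.x[A.i] + minx(s.x[A.j] - s.x[A.i], p), s.y[A.j], s.z[A.j] };
        double b0[3] = { s.x[B.i] + shift, s.y[B.i], s.z[B.i] };
        double b1[3] = { s.x[B.i] + shift + minx(s.x[B.j] - s.x[B.i], p), s.y[B.j], s.z[B.j] };
        double sa, sb;
        if (seg_seg(a0, a1, b0, b1, sa, sb) < p.d_ex + p.skin)
          pairs.push_back(cand[q]);
      }
      ref_x = s.x; ref_y = s.y; ref_z = s.z;
      need_rebuild = false;
    }

    if (do_internal) {
      spring_forces_flat(s, p, segs, F.data());
      bending_forces_flat(s, p, trips, F.data());
      crosslink_forces(s, p, F.data());
      excluded_forces(s, p, segs, pairs, F.data());
      branch_forces(s, p, F.data());
    }
    bool rec = record_every > 0 &&
               ((step + 1) % record_every == 0 || step + 1 == n_steps);
    double extsum[4][3] = { { 0 } }; // lead, motor, confine, thermal
    if (do_push) leading_forces(s, p, F.data(), extsum[0]);
    if (do_motor) motor_forces(s, p, F.data(), extsum[1]);
    if (do_confine) confine_forces(s, p, F.data(), extsum[2]);
    if (do_thermal) thermal_forces(s, p, F.data(), extsum[3]);

    // integrate
    double max_move2 = 0;
    double lim = 0.5 * p.l0;
    double fdrag[3] = { 0, 0, 0 }, adrag[3] = { 0, 0, 0 };
    for (int i = 0; i < n; ++i) {
      double dx, dy, dz;
      if (clamped[i]) {
        dx = 0; dy = cvy[i] * p.dt; dz = 0;
      } else {
        double zeff = s.bound[i] ? p.kappa_FA * p.zeta_b : p.zeta_b;
        dx = F[3*i + 0] / zeff * p.dt;
        dy = F[3*i + 1] / zeff * p.dt;
        dz = F[3*i + 2] / zeff * p.dt;
        double dd = dx * dx + dy * dy + dz * dz;
        if (dd > lim * lim)
          stop("instability: bead %d moved %g um in one step at t = %g s "
               "(limit %g um)", i + 1, std::sqrt(dd), s.t, lim);
        if (rec) {
          double* tgt = s.bound[i] ? adrag : fdrag;
          tgt[0] += zeff * dx / p.dt;
          tgt[1] += zeff * dy / p.dt;
          tgt[2] += zeff * dz / p.dt;
        }
      }
      s.x[i] += dx; s.y[i] += dy; s.z[i] += dz;
      wrap_bead(s, i, p);
      if (do_internal && !ref_x.empty() && i < (int)ref_x.size()) {
        double rx = minx(s.x[i] - ref_x[i], p), ry = s.y[i] - ref_y[i],
               rz = s.z[i] - ref_z[i];
        double m2 = rx * rx + ry * ry + rz * rz;
        if (m2 > max_move2) max_move2 = m2;
      }
    }
    if (do_internal && max_move2 > max_disp2_cap) need_rebuild = true;

    s.t += p.dt;

    // events (fixed order: FA binding, expiry/prune, dynamic refresh, insertion)
    if (do_fa_kinetics) fa_update(s, p, p.dt);
    if (do_expiry) {
      size_t nb_before = s.x.size();
      expire_bonds(s, p);
      if (s.x.size() != nb_before) need_rebuild = true;
      else if (do_internal) {
        // a split without removals still invalidates the segment list
        // (cheap check: bond count)
        size_t nbonds = 0;
        for (size_t f = 0; f < s.fils.size(); ++f) nbonds += s.fils[f].size() - 1;
        if (nbonds != segs.size()) need_rebuild = true;
      }
    }
    if (do_dynamic && s.t >= s.next_refresh) {
      replenish_dynamic(s, p);
      s.next_refresh += p.refresh_interval;
    }
    if (do_spawn) {
      if (spawn_filaments(s, p, p.dt, spawn_mode) > 0) need_rebuild = true;
    }

    if (rec) {
      int m = s.x.size();
      NumericMatrix fpos(m, 4);
      for (int i = 0; i < m; ++i) {
        fpos(i, 0) = s.uid[i];
        fpos(i, 1) = s.x[i] + s.wrapn[i] * p.box_w; // unwrapped x
        fpos(i, 2) = s.y[i];
        fpos(i, 3) = s.z[i];
      }
      colnames(fpos) = CharacterVector::create("uid", "x", "y", "z");
      frames.push_back(List::create(_["t"] = s.t, _["pos"] = fpos,
                                    _["n_beads"] = m));
      NumericMatrix cs(6, 3);
      for (int c = 0; c < 3; ++c) {
        cs(0, c) = extsum[0][c];
        cs(1, c) = extsum[1][c];
        cs(2, c) = extsum[2][c];
        cs(3, c) = extsum[3][c];
        cs(4, c) = fdrag[c];
        cs(5, c) = adrag[c];
      }
      rownames(cs) = CharacterVector::create("leading", "motor", "confine",
                                             "thermal", "fluid_drag", "fa_drag");
      chanrec.push_back(cs);
      n_record++;
    }
    if ((step & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  List fr(frames.size()), cr(chanrec.size());
  for (size_t q = 0; q < frames.size(); ++q) fr[q] = frames[q];
  for (size_t q = 0; q < chanrec.size(); ++q) cr[q] = chanrec[q];
  return List::create(_["state"] = st_to_list(s), _["frames"] = fr,
                      _["channel_sums"] = cr, _["n_frames"] = n_record);
}

// ---- virial stress ---------------------------------------------------------

// sigma_ij = -(1/V) sum over pair interactions of r_ab,i * F_a,j
// (tension positive). Channels: bonds, crosslinks, excluded volume, bending
// (triplet decomposed into its two arm pairs). Pairs with either bead in
// `exclude` are skipped.
// [[Rcpp::export]]
List cpp_virial(List state, List params, double volume, IntegerVector exclude) {
  St s = st_from_list(state);
  Par p = par_from_list(params);
  if (volume <= 0) stop("volume must be positive");
  int n = s.x.size();
  std::vector<char> ex(n, 0);
  for (int q = 0; q < exclude.size(); ++q) {
    int i = exclude[q] - 1;
    if (i >= 0 && i < n) ex[i] = 1;
  }
  double sig[3][3] = { { 0 } };
  // helper lambda to add one pair: displacement d (= r_a - r_b), force on a
  auto addpair = [&](int a, int b, const double d[3], const double Fa[3]) {
    if (ex[a] || ex[b]) return;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) sig[i][j] -= d[i] * Fa[j];
  };
  // bonds
  for (size_t f = 0; f < s.fils.size(); ++f) {
    const std::vector<int>& b = s.fils[f];
    for (size_t k = 0; k + 1 < b.size(); ++k) {
      int i = b[k], j = b[k + 1];
      double d[3]; sep(s, p, i, j, d);
      double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
      double mag = -p.k_actin * (r - p.l0) / r;
      double Fa[3] = { mag * d[0], mag * d[1], mag * d[2] };
      addpair(i, j, d, Fa);
    }
    // bending triplets decomposed into two arm pairs
    double kap = p.kBT * p.l_p / p.l0;
    for (size_t k = 0; k + 2 < b.size(); ++k) {
      int i = b[k], j = b[k + 1], m = b[k + 2];
      double u[3], v[3];
      sep(s, p, j, i, u);
      sep(s, p, m, j, v);
      double gi[3], gj[3], gk[3], c;
      cos_grad(u, v, gi, gj, gk, c);
      double Fi[3], Fk[3], du[3], dv[3];
      for (int a = 0; a < 3; ++a) {
        Fi[a] = kap * gi[a];
        Fk[a] = kap * gk[a];
        du[a] = -u[a]; // r_i - r_j
        dv[a] = v[a];  // r_m - r_j
      }
      addpair(i, j, du, Fi);
      addpair(m, j, dv, Fk);
    }
  }
  // crosslinks
  for (size_t q = 0; q < s.xa.size(); ++q) {
    int i = s.xa[q], j = s.xb[q];
    double kk = (s.xtype[q] == XL_BRANCH) ? p.k_actin : p.k_xl;
    double rl = (s.xtype[q] == XL_BRANCH) ? p.d_ex : p.l0_xl;
    double d[3]; sep(s, p, i, j, d);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    double mag = -kk * (r - rl) / r;
    double Fa[3] = { mag * d[0], mag * d[1], mag * d[2] };
    addpair(i, j, d, Fa);
  }
  // branch angle triplets
  for (size_t q = 0; q < s.bi.size(); ++q) {
    int i = s.bi[q], j = s.bj[q], k = s.bk[q];
    double u[3], v[3];
    sep(s, p, j, i, u);
    sep(s, p, k, j, v);
    double gi[3], gj[3], gk[3], c;
    cos_grad(u, v, gi, gj, gk, c);
    double pref = -2.0 * p.eps_angle * (c - p.cos_theta0);
    double Fi[3], Fk[3], du[3], dv[3];
    for (int a = 0; a < 3; ++a) {
      Fi[a] = pref * gi[a];
      Fk[a] = pref * gk[a];
      du[a] = -u[a];
      dv[a] = v[a];
    }
    addpair(i, j, du, Fi);
    addpair(k, j, dv, Fk);
  }
  // excluded volume: pair between closest points
  std::vector<Seg> segs;
  list_segments(s, segs);
  std::vector<std::pair<int,int> > pairs;
  candidate_pairs(s, p, segs, p.d_ex + p.skin, pairs);
  for (size_t q = 0; q < pairs.size(); ++q) {
    const Seg& A = segs[pairs[q].first];
    const Seg& B = segs[pairs[q].second];
    if (ex[A.i] || ex[A.j] || ex[B.i] || ex[B.j]) continue;
    double shift = minx(s.x[B.i] - s.x[A.i], p) - (s.x[B.i] - s.x[A.i]);
    double a0[3] = { s.x[A.i], s.y[A.i], s.z[A.i] };
    double a1[3] = { s.x[A.i] + minx(s.x[A.j] - s.x[A.i], p), s.y[A.j], s.z[A.j] };
    double b0[3] = { s.x[B.i] + shift, s.y[B.i], s.z[B.i] };
    double b1[3] = { s.x[B.i] + shift + minx(s.x[B.j] - s.x[B.i], p), s.y[B.j], s.z[B.j] };
    double sa, sb;
    double d = seg_seg(a0, a1, b0, b1, sa, sb);
    if (d >= p.d_ex || d < 1e-12) continue;
    double dd[3], Fa[3];
    double mag = p.k_ex * (p.d_ex - d);
    for (int c = 0; c < 3; ++c) {
      dd[c] = (a0[c] + sa * (a1[c] - a0[c])) - (b0[c] + sb * (b1[c] - b0[c]));
      Fa[c] = mag * dd[c] / d;
    }
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) sig[i][j] -= dd[i] * Fa[j];
  }
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = sig[i][j] / volume;
  colnames(out) = CharacterVector::create("x", "y", "z");
  rownames(out) = CharacterVector::create("x", "y", "z");
  double sigT = out(1, 1) - 0.5 * (out(0, 0) + out(2, 2));
  return List::create(_["sigma"] = out, _["sigma_T"] = sigT);
}

// ---- bond-crossing audit ----------------------------------------------------

// Detects segment pairs that pass through each other between two frames,
// assuming linear bead motion. Samples the interval for a sign flip of the
// mutual-orientation determinant while the segments are geometrically close.
// [[Rcpp::export]]
int cpp_crossings(NumericMatrix pos0, NumericMatrix pos1, IntegerMatrix segs,
                  double width, bool periodic, int nsub = 8) {
  int ns = segs.nrow();
  int count = 0;
  auto det = [&](const double* a0, const double* a1, const double* b0,
                 const double* b1) {
    double u[3], v[3], w[3];
    for (int c = 0; c < 3; ++c) {
      u[c] = a1[c] - a0[c];
      v[c] = b1[c] - b0[c];
      w[c] = b0[c] - a0[c];
    }
    return u[0]*(v[1]*w[2]-v[2]*w[1]) - u[1]*(v[0]*w[2]-v[2]*w[0])
         + u[2]*(v[0]*w[1]-v[1]*w[0]);
  };
  for (int a = 0; a < ns; ++a) {
    for (int b = a + 1; b < ns; ++b) {
      int i1 = segs(a, 0) - 1, j1 = segs(a, 1) - 1;
      int i2 = segs(b, 0) - 1, j2 = segs(b, 1) - 1;
      if (i1 == i2 || i1 == j2 || j1 == i2 || j1 == j2) continue;
      int lastsign = 0;
      bool flipped = false, close = false;
      for (int q = 0; q <= nsub; ++q) {
        double f = (double)q / nsub;
        double A0[3], A1[3], B0[3], B1[3];
        for (int c = 0; c < 3; ++c) {
          A0[c] = pos0(i1, c) + f * (pos1(i1, c) - pos0(i1, c));
          A1[c] = pos0(j1, c) + f * (pos1(j1, c) - pos0(j1, c));
          B0[c] = pos0(i2, c) + f * (pos1(i2, c) - pos0(i2, c));
          B1[c] = pos0(j2, c) + f * (pos1(j2, c) - pos0(j2, c));
        }
        if (periodic) {
          double dx = B0[0] - A0[0];
          double sh = (dx - width * std::nearbyint(dx / width)) - dx;
          B0[0] += sh; B1[0] += sh;
        }
        double d = det(A0, A1, B0, B1);
        double sa, sb;
        double dist = seg_seg(A0, A1, B0, B1, sa, sb);
        int sg = (d > 0) - (d < 0);
        if (sg != 0 && lastsign != 0 && sg != lastsign &&
            sa > 0 && sa < 1 && sb > 0 && sb < 1)
          flipped = true;
        if (dist < 0.05) close = true;
        if (sg != 0) lastsign = sg;
      }
      if (flipped && close) count++;
    }
  }
  return count;
}
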