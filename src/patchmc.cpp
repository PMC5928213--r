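// Kern-Frenkel two-species patchy-particle model and Gibbs-ensemble Monte
// Carlo inner loop. All lengths in units of the hard-core diameter sigma,
// energies in units of eps_PP, temperature in eps_PP/k_B.
//
// Box energies are derived from integer tallies of bonded pairs by species
// pair (n_PP, n_PR, n_RR), maintained incrementally, so the cached energy
// equals a from-scratch recomputation exactly (integer equality).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: mt19937_64 with explicit uniform mapping so streams are identical
// across platforms (std::uniform_real_distribution is implementation-defined).
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }  // [0,1)
  int unif_int(int n) {  // uniform on 0..n-1, rejection-free of modulo bias
    uint64_t lim = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t r;
    do { r = gen(); } while (r >= lim);
    return (int)(r % (uint64_t)n);
  }
};

// ---------------------------------------------------------------------------
struct Params {
  double sigma, lam, epsPP, epsPR, epsRR;
  double cosP, cosR;
  int mP, mR;
  double sigma2, rc2;  // rc = sigma + lam
};

static Params parse_params(const List& p) {
  Params q;
  q.sigma = as<double>(p["sigma"]);
  q.lam = as<double>(p["lam"]);
  q.epsPP = as<double>(p["eps_PP"]);
  q.epsPR = as<double>(p["eps_PR"]);
  q.epsRR = as<double>(p["eps_RR"]);
  q.cosP = as<double>(p["cos_theta_P"]);
  q.cosR = as<double>(p["cos_theta_R"]);
  q.mP = as<int>(p["m_P"]);
  q.mR = as<int>(p["m_R"]);
  q.sigma2 = q.sigma * q.sigma;
  double rc = q.sigma + q.lam;
  q.rc2 = rc * rc;
  return q;
}

// Reference patch directions for m patches on a unit sphere. m = 4 is the
// tetrahedral frame, m = 2 the two poles; m = 1 and m = 3 round out the small
// valences used in tests.
static void ref_dirs(int m, double d[12]) {
  const double s3 = 1.0 / std::sqrt(3.0);
  switch (m) {
    case 1:
      d[0] = 0; d[1] = 0; d[2] = 1;
      break;
    case 2:
      d[0] = 0; d[1] = 0; d[2] = 1;
      d[3] = 0; d[4] = 0; d[5] = -1;
      break;
    case 3:
      d[0] = 1;    d[1] = 0;                 d[2] = 0;
      d[3] = -0.5; d[4] = std::sqrt(3.0)/2;  d[5] = 0;
      d[6] = -0.5; d[7] = -std::sqrt(3.0)/2; d[8] = 0;
      break;
    case 4:
      d[0] = s3;  d[1] = s3;  d[2] = s3;
      d[3] = s3;  d[4] = -s3; d[5] = -s3;
      d[6] = -s3; d[7] = s3;  d[8] = -s3;
      d[9] = -s3; d[10] = -s3; d[11] = s3;
      break;
    default:
      Rcpp::stop("unsupported patch count m = %d (allowed: 1-4)", m);
  }
}

// Rotate the m reference directions of species s by unit quaternion q
// (w, x, y, z) and store into out (3*m doubles).
static void patch_world(const Params& prm, int s, const double* q, double* out) {
  int m = (s == 0) ? prm.mP : prm.mR;
  double ref[12];
  ref_dirs(m, ref);
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double R[9] = {
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)};
  for (int k = 0; k < m; ++k) {
    const double* v = ref + 3 * k;
    out[3 * k + 0] = R[0] * v[0] + R[1] * v[1] + R[2] * v[2];
    out[3 * k + 1] = R[3] * v[0] + R[4] * v[1] + R[5] * v[2];
    out[3 * k + 2] = R[6] * v[0] + R[7] * v[1] + R[8] * v[2];
  }
}

// Evaluate one pair given the minimum-image displacement d = r_j - r_i.
// Return -1 overlap, 1 bonded (in well, mutually facing patches), 0 otherwise.
// The bond condition factorises: exists alpha with rhat.n_i_alpha > cos(theta_i)
// AND exists beta with -rhat.n_j_beta > cos(theta_j).
static inline int eval_pair(const Params& prm, double dx, double dy, double dz,
                            int si, const double* pi, int sj, const double* pj) {
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 <= prm.sigma2) return -1;
  if (r2 > prm.rc2) return 0;
  double r = std::sqrt(r2);
  double hx = dx / r, hy = dy / r, hz = dz / r;
  int mi = (si == 0) ? prm.mP : prm.mR;
  double ci = (si == 0) ? prm.cosP : prm.cosR;
  bool oki = false;
  for (int a = 0; a < mi; ++a) {
    if (hx * pi[3 * a] + hy * pi[3 * a + 1] + hz * pi[3 * a + 2] > ci) {
      oki = true;
      break;
    }
  }
  if (!oki) return 0;
  int mj = (sj == 0) ? prm.mP : prm.mR;
  double cj = (sj == 0) ? prm.cosP : prm.cosR;
  for (int b = 0; b < mj; ++b) {
    if (-(hx * pj[3 * b] + hy * pj[3 * b + 1] + hz * pj[3 * b + 2]) > cj) return 1;
  }
  return 0;
}

// ---------------------------------------------------------------------------
struct Box {
  std::vector<int> sp;       // 0 = P, 1 = R
  std::vector<double> x, y, z;
  std::vector<double> q;     // 4 per particle (w, x, y, z)
  std::vector<double> patch; // 12 per particle, world-frame patch directions
  double L = 0;
  long long cPP = 0, cPR = 0, cRR = 0;  // bonded-pair tallies
  int nP = 0, nR = 0;
  int n() const { return (int)sp.size(); }
  double vol() const { return L * L * L; }
};

static inline double tallies_energy(const Params& prm, long long cPP,
                                    long long cPR, long long cRR) {
  return -((double)cPP * prm.epsPP + (double)cPR * prm.epsPR +
           (double)cRR * prm.epsRR);
}

// Bonds of a trial particle (species st at px,py,pz with patches patT)
// against every particle of box B except index `skip` (-1 for none).
// Returns false on hard-core overlap; otherwise fills partner counts by
// species (bP, bR).
static bool scan_particle(const Box& B, const Params& prm, int skip, int st,
                          double px, double py, double pz, const double* patT,
                          int& bP, int& bR) {
  bP = 0;
  bR = 0;
  const double L = B.L;
  int n = B.n();
  for (int j = 0; j < n; ++j) {
    if (j == skip) continue;
    double dx = B.x[j] - px, dy = B.y[j] - py, dz = B.z[j] - pz;
    dx -= L * std::nearbyint(dx / L);
    dy -= L * std::nearbyint(dy / L);
    dz -= L * std::nearbyint(dz / L);
    int v = eval_pair(prm, dx, dy, dz, st, patT, B.sp[j], &B.patch[12 * j]);
    if (v < 0) return false;
    if (v == 1) {
      if (B.sp[j] == 0) ++bP; else ++bR;
    }
  }
  return true;
}

// Full O(N^2) recomputation of a box's bonded-pair tallies with coordinates
// scaled by `scale` (1 for in-place). Returns false on overlap.
static bool recompute_box(const Box& B, const Params& prm, double scale,
                          long long& cPP, long long& cPR, long long& cRR) {
  cPP = cPR = cRR = 0;
  int n = B.n();
  double L = B.L * scale;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = (B.x[j] - B.x[i]) * scale;
      double dy = (B.y[j] - B.y[i]) * scale;
      double dz = (B.z[j] - B.z[i]) * scale;
      dx -= L * std::nearbyint(dx / L);
      dy -= L * std::nearbyint(dy / L);
      dz -= L * std::nearbyint(dz / L);
      int v = eval_pair(prm, dx, dy, dz, B.sp[i], &B.patch[12 * i], B.sp[j],
                        &B.patch[12 * j]);
      if (v < 0) return false;
      if (v == 1) {
        int t = B.sp[i] + B.sp[j];
        if (t == 0) ++cPP; else if (t == 1) ++cPR; else ++cRR;
      }
    }
  }
  return true;
}

static inline void wrap_coord(double& v, double L) {
  v -= L * std::floor(v / L);
  if (v >= L) v = 0;  // guard v slightly below 0 flushing to L
}

// Convert partner-species counts of a particle of species st into
// pair-type tally deltas.
static inline void partner_to_tallies(int st, int bP, int bR, long long& dPP,
                                      long long& dPR, long long& dRR) {
  if (st == 0) { dPP = bP; dPR = bR; dRR = 0; }
  else         { dPP = 0;  dPR = bP; dRR = bR; }
}

static void random_unit_quat(Rng& rng, double q[4]) {
  // Shoemake's method: uniform over SO(3)
  double u1 = rng.unif(), u2 = rng.unif(), u3 = rng.unif();
  double a = std::sqrt(1.0 - u1), b = std::sqrt(u1);
  double t2 = 2.0 * M_PI * u2, t3 = 2.0 * M_PI * u3;
  q[0] = b * std::cos(t3);
  q[1] = a * std::sin(t2);
  q[2] = a * std::cos(t2);
  q[3] = b * std::sin(t3);
}

static void random_axis(Rng& rng, double ax[3]) {
  // Marsaglia rejection on the unit disk
  double v1, v2, s;
  do {
    v1 = 2.0 * rng.unif() - 1.0;
    v2 = 2.0 * rng.unif() - 1.0;
    s = v1 * v1 + v2 * v2;
  } while (s >= 1.0 || s == 0.0);
  double f = std::sqrt(1.0 - s);
  ax[0] = 2.0 * v1 * f;
  ax[1] = 2.0 * v2 * f;
  ax[2] = 1.0 - 2.0 * s;
}

static inline void quat_mult(const double a[4], const double b[4], double out[4]) {
  out[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  out[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  out[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  out[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

// ---------------------------------------------------------------------------
// Moves. Each returns true if accepted.

static bool displacement_attempt(Box& B, const Params& prm, Rng& rng, double T,
                                 double dmax, double rotmax) {
  int n = B.n();
  if (n == 0) return false;
  int i = rng.unif_int(n);
  int st = B.sp[i];

  int bP0, bR0;
  scan_particle(B, prm, i, st, B.x[i], B.y[i], B.z[i], &B.patch[12 * i], bP0, bR0);

  double nx = B.x[i] + (2.0 * rng.unif() - 1.0) * dmax;
  double ny = B.y[i] + (2.0 * rng.unif() - 1.0) * dmax;
  double nz = B.z[i] + (2.0 * rng.unif() - 1.0) * dmax;
  wrap_coord(nx, B.L); wrap_coord(ny, B.L); wrap_coord(nz, B.L);

  double ax[3];
  random_axis(rng, ax);
  double ang = rng.unif() * rotmax;
  double half = 0.5 * ang, sh = std::sin(half);
  double dq[4] = {std::cos(half), ax[0] * sh, ax[1] * sh, ax[2] * sh};
  double nq[4];
  quat_mult(dq, &B.q[4 * i], nq);
  double norm = std::sqrt(nq[0]*nq[0] + nq[1]*nq[1] + nq[2]*nq[2] + nq[3]*nq[3]);
  for (int k = 0; k < 4; ++k) nq[k] /= norm;
  double npatch[12];
  patch_world(prm, st, nq, npatch);

  int bP1, bR1;
  if (!scan_particle(B, prm, i, st, nx, ny, nz, npatch, bP1, bR1)) return false;

  long long o0, o1, o2, n0, n1, n2;
  partner_to_tallies(st, bP0, bR0, o0, o1, o2);
  partner_to_tallies(st, bP1, bR1, n0, n1, n2);
  double dU = tallies_energy(prm, n0 - o0, n1 - o1, n2 - o2);
  if (dU > 0 && rng.unif() >= std::exp(-dU / T)) return false;

  B.x[i] = nx; B.y[i] = ny; B.z[i] = nz;
  for (int k = 0; k < 4; ++k) B.q[4 * i + k] = nq[k];
  int m = (st == 0) ? prm.mP : prm.mR;
  for (int k = 0; k < 3 * m; ++k) B.patch[12 * i + k] = npatch[k];
  B.cPP += n0 - o0; B.cPR += n1 - o1; B.cRR += n2 - o2;
  return true;
}

static bool exchange_attempt(Box& A, Box& B, const Params& prm, Rng& rng,
                             double T) {
  Box* src;
  Box* dst;
  if (rng.unif() < 0.5) { src = &A; dst = &B; } else { src = &B; dst = &A; }

  // species drawn uniformly among species with nonzero total count
  int totP = A.nP + B.nP, totR = A.nR + B.nR;
  int s;
  if (totP > 0 && totR > 0) s = (rng.unif() < 0.5) ? 0 : 1;
  else if (totP > 0) s = 0;
  else if (totR > 0) s = 1;
  else return false;

  int ns_src = (s == 0) ? src->nP : src->nR;
  if (ns_src == 0) return false;
  int ns_dst = (s == 0) ? dst->nP : dst->nR;

  // k-th particle of species s in the source box
  int k = rng.unif_int(ns_src), i = -1;
  for (int j = 0, c = 0; j < src->n(); ++j) {
    if (src->sp[j] == s && c++ == k) { i = j; break; }
  }

  int bPrem, bRrem;
  scan_particle(*src, prm, i, s, src->x[i], src->y[i], src->z[i],
                &src->patch[12 * i], bPrem, bRrem);

  double px = rng.unif() * dst->L;
  double py = rng.unif() * dst->L;
  double pz = rng.unif() * dst->L;
  double nq[4];
  random_unit_quat(rng, nq);
  double npatch[12];
  patch_world(prm, s, nq, npatch);
  int bPins, bRins;
  if (!scan_particle(*dst, prm, -1, s, px, py, pz, npatch, bPins, bRins))
    return false;

  long long r0, r1, r2, i0, i1, i2;
  partner_to_tallies(s, bPrem, bRrem, r0, r1, r2);
  partner_to_tallies(s, bPins, bRins, i0, i1, i2);
  double dU = tallies_energy(prm, i0, i1, i2) - tallies_energy(prm, r0, r1, r2);
  double acc = ((double)ns_src * dst->vol()) /
               (((double)ns_dst + 1.0) * src->vol()) * std::exp(-dU / T);
  if (acc < 1.0 && rng.unif() >= acc) return false;

  // remove i from src (swap with last), append to dst
  src->cPP -= r0; src->cPR -= r1; src->cRR -= r2;
  int last = src->n() - 1;
  if (i != last) {
    src->sp[i] = src->sp[last];
    src->x[i] = src->x[last]; src->y[i] = src->y[last]; src->z[i] = src->z[last];
    for (int t = 0; t < 4; ++t) src->q[4 * i + t] = src->q[4 * last + t];
    for (int t = 0; t < 12; ++t) src->patch[12 * i + t] = src->patch[12 * last + t];
  }
  src->sp.pop_back();
  src->x.pop_back(); src->y.pop_back(); src->z.pop_back();
  src->q.resize(4 * last);
  src->patch.resize(12 * last);
  if (s == 0) --src->nP; else --src->nR;

  dst->sp.push_back(s);
  dst->x.push_back(px); dst->y.push_back(py); dst->z.push_back(pz);
  for (int t = 0; t < 4; ++t) dst->q.push_back(nq[t]);
  for (int t = 0; t < 12; ++t) dst->patch.push_back(npatch[t]);
  if (s == 0) ++dst->nP; else ++dst->nR;
  dst->cPP += i0; dst->cPR += i1; dst->cRR += i2;
  return true;
}

static bool volume_attempt(Box& A, Box& B, const Params& prm, Rng& rng,
                           double T, double dlnmax) {
  double VA = A.vol(), VB = B.vol(), Vtot = VA + VB;
  double l = std::log(VA / VB) + (2.0 * rng.unif() - 1.0) * dlnmax;
  double el = std::exp(l);
  double VAn = Vtot * el / (1.0 + el);
  double VBn = Vtot - VAn;
  double sA = std::cbrt(VAn / VA), sB = std::cbrt(VBn / VB);

  long long aPP, aPR, aRR, bPP, bPR, bRR;
  if (!recompute_box(A, prm, sA, aPP, aPR, aRR)) return false;
  if (!recompute_box(B, prm, sB, bPP, bPR, bRR)) return false;

  double Uold = tallies_energy(prm, A.cPP + B.cPP, A.cPR + B.cPR, A.cRR + B.cRR);
  double Unew = tallies_energy(prm, aPP + bPP, aPR + bPR, aRR + bRR);
  double dU = Unew - Uold;
  double lnacc = (A.n() + 1.0) * std::log(VAn / VA) +
                 (B.n() + 1.0) * std::log(VBn / VB) - dU / T;
  if (lnacc < 0 && rng.unif() >= std::exp(lnacc)) return false;

  for (int j = 0; j < A.n(); ++j) { A.x[j] *= sA; A.y[j] *= sA; A.z[j] *= sA; }
  for (int j = 0; j < B.n(); ++j) { B.x[j] *= sB; B.y[j] *= sB; B.z[j] *= sB; }
  A.L *= sA; B.L *= sB;
  A.cPP = aPP; A.cPR = aPR; A.cRR = aRR;
  B.cPP = bPP; B.cPR = bPR; B.cRR = bRR;
  return true;
}

// ---------------------------------------------------------------------------
// Marshalling between R and Box

static Box box_from_r(const Params& prm, IntegerVector sp, NumericMatrix pos,
                      NumericMatrix quat, double L) {
  Box B;
  int n = sp.size();
  B.L = L;
  B.sp.resize(n);
  B.x.resize(n); B.y.resize(n); B.z.resize(n);
  B.q.resize(4 * n);
  B.patch.assign(12 * n, 0.0);
  for (int i = 0; i < n; ++i) {
    B.sp[i] = sp[i];
    if (sp[i] == 0) ++B.nP; else ++B.nR;
    B.x[i] = pos(i, 0); B.y[i] = pos(i, 1); B.z[i] = pos(i, 2);
    wrap_coord(B.x[i], L); wrap_coord(B.y[i], L); wrap_coord(B.z[i], L);
    for (int k = 0; k < 4; ++k) B.q[4 * i + k] = quat(i, k);
    patch_world(prm, B.sp[i], &B.q[4 * i], &B.patch[12 * i]);
  }
  if (!recompute_box(B, prm, 1.0, B.cPP, B.cPR, B.cRR))
    stop("initial configuration contains a hard-core overlap");
  return B;
}

static List box_to_r(const Box& B) {
  int n = B.n();
  IntegerVector sp(n);
  NumericMatrix pos(n, 3), quat(n, 4);
  for (int i = 0; i < n; ++i) {
    sp[i] = B.sp[i];
    pos(i, 0) = B.x[i]; pos(i, 1) = B.y[i]; pos(i, 2) = B.z[i];
    for (int k = 0; k < 4; ++k) quat(i, k) = B.q[4 * i + k];
  }
  return List::create(_["species"] = sp, _["pos"] = pos, _["quat"] = quat,
                      _["box_edge"] = B.L,
                      _["tallies"] = IntegerVector::create(
                          _["n_PP"] = (int)B.cPP, _["n_PR"] = (int)B.cPR,
                          _["n_RR"] = (int)B.cRR));
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_gibbs(List params, IntegerVector sp1, NumericMatrix pos1,
                   NumericMatrix quat1, double L1, IntegerVector sp2,
                   NumericMatrix pos2, NumericMatrix quat2, double L2,
                   double temperature, int n_disp, int n_exch, int n_vol,
                   double dmax, double rotmax, double dlnvmax, int n_equil,
                   int n_collect, int stride, double seed, int check_every,
                   bool adapt) {
  Params prm = parse_params(params);
  Rng rng((uint64_t)seed);
  Box A = box_from_r(prm, sp1, pos1, quat1, L1);
  Box B = box_from_r(prm, sp2, pos2, quat2, L2);
  double T = temperature;

  int per_cycle = n_disp + n_exch + n_vol;
  std::vector<uint8_t> seq(per_cycle);

  int nsamp = (stride > 0) ? n_collect / stride : 0;
  NumericMatrix samples(nsamp, 15);
  colnames(samples) = CharacterVector::create(
      "cycle", "n_P_I", "n_R_I", "volume_I", "energy_I", "n_PP_I", "n_PR_I",
      "n_RR_I", "n_P_II", "n_R_II", "volume_II", "energy_II", "n_PP_II",
      "n_PR_II", "n_RR_II");
  int isamp = 0;

  long long att[3] = {0, 0, 0}, acc[3] = {0, 0, 0};
  long long w_att = 0, w_acc = 0;  // adaptation window (displacement only)

  int total_cycles = n_equil + n_collect;
  for (int cyc = 0; cyc < total_cycles; ++cyc) {
    if (cyc % 128 == 0) Rcpp::checkUserInterrupt();
    bool in_equil = cyc < n_equil;

    // shuffled move sequence for this cycle
    int p = 0;
    for (int k = 0; k < n_disp; ++k) seq[p++] = 0;
    for (int k = 0; k < n_exch; ++k) seq[p++] = 1;
    for (int k = 0; k < n_vol; ++k) seq[p++] = 2;
    for (int k = per_cycle - 1; k > 0; --k) {
      int j = rng.unif_int(k + 1);
      std::swap(seq[k], seq[j]);
    }

    for (int k = 0; k < per_cycle; ++k) {
      int mv = seq[k];
      bool ok = false;
      if (mv == 0) {
        // uniform particle over both boxes => box weighted by occupancy
        int ntot = A.n() + B.n();
        if (ntot > 0) {
          int g = rng.unif_int(ntot);
          Box& Bx = (g < A.n()) ? A : B;
          ok = displacement_attempt(Bx, prm, rng, T, dmax, rotmax);
        }
        ++w_att;
        if (ok) ++w_acc;
      } else if (mv == 1) {
        ok = exchange_attempt(A, B, prm, rng, T);
      } else {
        ok = volume_attempt(A, B, prm, rng, T, dlnvmax);
      }
      ++att[mv];
      if (ok) ++acc[mv];
    }

    // step-size adaptation: equilibration only, frozen during collection
    if (adapt && in_equil && (cyc + 1) % 50 == 0 && w_att > 0) {
      double frac = (double)w_acc / (double)w_att;
      if (frac > 0.5) { dmax *= 1.05; rotmax *= 1.05; }
      else if (frac < 0.3) { dmax *= 0.95; rotmax *= 0.95; }
      double cap = 0.25 * std::min(A.L, B.L);
      if (dmax > cap) dmax = cap;
      if (dmax < 0.005) dmax = 0.005;
      if (rotmax > M_PI) rotmax = M_PI;
      if (rotmax < 0.01) rotmax = 0.01;
      w_att = w_acc = 0;
    }

    if (check_every > 0 && (cyc + 1) % check_every == 0) {
      long long tPP, tPR, tRR;
      if (!recompute_box(A, prm, 1.0, tPP, tPR, tRR) || tPP != A.cPP ||
          tPR != A.cPR || tRR != A.cRR)
        stop("bond-tally bookkeeping mismatch in box I at cycle %d", cyc + 1);
      if (!recompute_box(B, prm, 1.0, tPP, tPR, tRR) || tPP != B.cPP ||
          tPR != B.cPR || tRR != B.cRR)
        stop("bond-tally bookkeeping mismatch in box II at cycle %d", cyc + 1);
    }

    if (!in_equil && stride > 0 && (cyc - n_equil + 1) % stride == 0 &&
        isamp < nsamp) {
      samples(isamp, 0) = cyc + 1;
      samples(isamp, 1) = A.nP;
      samples(isamp, 2) = A.nR;
      samples(isamp, 3) = A.vol();
      samples(isamp, 4) = tallies_energy(prm, A.cPP, A.cPR, A.cRR);
      samples(isamp, 5) = (double)A.cPP;
      samples(isamp, 6) = (double)A.cPR;
      samples(isamp, 7) = (double)A.cRR;
      samples(isamp, 8) = B.nP;
      samples(isamp, 9) = B.nR;
      samples(isamp, 10) = B.vol();
      samples(isamp, 11) = tallies_energy(prm, B.cPP, B.cPR, B.cRR);
      samples(isamp, 12) = (double)B.cPP;
      samples(isamp, 13) = (double)B.cPR;
      samples(isamp, 14) = (double)B.cRR;
      ++isamp;
    }
  }

  NumericVector attempts = NumericVector::create(
      _["displacement"] = (double)att[0], _["exchange"] = (double)att[1],
      _["volume"] = (double)att[2]);
  NumericVector accepts = NumericVector::create(
      _["displacement"] = (double)acc[0], _["exchange"] = (double)acc[1],
      _["volume"] = (double)acc[2]);

  return List::create(
      _["samples"] = samples, _["box_I"] = box_to_r(A), _["box_II"] = box_to_r(B),
      _["attempts"] = attempts, _["accepts"] = accepts,
      _["final_steps"] = NumericVector::create(_["max_translation"] = dmax,
                                               _["max_rotation"] = rotmax));
}

// Bonded-pair tallies and total energy of one configuration.
// [[Rcpp::export]]
List cpp_box_tallies(List params, IntegerVector sp, NumericMatrix pos,
                     NumericMatrix quat, double L) {
  Params prm = parse_params(params);
  Box B;
  int n = sp.size();
  B.L = L;
  B.sp.resize(n);
  B.x.resize(n); B.y.resize(n); B.z.resize(n);
  B.q.resize(4 * n);
  B.patch.assign(12 * n, 0.0);
  for (int i = 0; i < n; ++i) {
    B.sp[i] = sp[i];
    B.x[i] = pos(i, 0); B.y[i] = pos(i, 1); B.z[i] = pos(i, 2);
    for (int k = 0; k < 4; ++k) B.q[4 * i + k] = quat(i, k);
    patch_world(prm, B.sp[i], &B.q[4 * i], &B.patch[12 * i]);
  }
  long long cPP, cPR, cRR;
  bool ok = recompute_box(B, prm, 1.0, cPP, cPR, cRR);
  return List::create(
      _["overlap"] = !ok, _["n_PP"] = (double)cPP, _["n_PR"] = (double)cPR,
      _["n_RR"] = (double)cRR,
      _["energy"] = ok ? tallies_energy(prm, cPP, cPR, cRR) : R_PosInf);
}

// Single-pair evaluation under minimum image. Returns overlap flag, the
// geometric bond indicator and the pair energy.
// [[Rcpp::export]]
List cpp_pair_energy(List params, int si, int sj, NumericVector ri,
                     NumericVector rj, NumericVector qi, NumericVector qj,
                     double L) {
  Params prm = parse_params(params);
  double pi_[12], pj_[12];
  double qi_[4] = {qi[0], qi[1], qi[2], qi[3]};
  double qj_[4] = {qj[0], qj[1], qj[2], qj[3]};
  patch_world(prm, si, qi_, pi_);
  patch_world(prm, sj, qj_, pj_);
  double dx = rj[0] - ri[0], dy = rj[1] - ri[1], dz = rj[2] - ri[2];
  if (L > 0) {
    dx -= L * std::nearbyint(dx / L);
    dy -= L * std::nearbyint(dy / L);
    dz -= L * std::nearbyint(dz / L);
  }
  int v = eval_pair(prm, dx, dy, dz, si, pi_, sj, pj_);
  double eps = (si + sj == 0) ? prm.epsPP : (si + sj == 1) ? prm.epsPR : prm.epsRR;
  return List::create(_["overlap"] = (v < 0), _["bonded"] = (v == 1),
                      _["energy"] = (v < 0) ? R_PosInf
                                            : ((v == 1) ? -eps : 0.0));
}

// All bonded pairs of a configuration (1-based indices). If energetic_only,
// pairs whose species combination has zero well depth are dropped.
// [[Rcpp::export]]
IntegerMatrix cpp_bond_pairs(List params, IntegerVector sp, NumericMatrix pos,
                             NumericMatrix quat, double L, bool energetic_only) {
  Params prm = parse_params(params);
  int n = sp.size();
  std::vector<double> patch(12 * n, 0.0);
  for (int i = 0; i < n; ++i) {
    double q[4] = {quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3)};
    patch_world(prm, sp[i], q, &patch[12 * i]);
  }
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(j, 0) - pos(i, 0);
      double dy = pos(j, 1) - pos(i, 1);
      double dz = pos(j, 2) - pos(i, 2);
      dx -= L * std::nearbyint(dx / L);
      dy -= L * std::nearbyint(dy / L);
      dz -= L * std::nearbyint(dz / L);
      int v = eval_pair(prm, dx, dy, dz, sp[i], &patch[12 * i], sp[j],
                        &patch[12 * j]);
      if (v == 1) {
        if (energetic_only) {
          int t = sp[i] + sp[j];
          double eps = (t == 0) ? prm.epsPP : (t == 1) ? prm.epsPR : prm.epsRR;
          if (eps <= 0) continue;
        }
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}
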