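// Polarized photon transport and single-scattering kernels.
//
// Spheres are handled by the Mie partial-wave series, infinitely long
// cylinders by the oblique-incidence scattering-matrix series (Bessel
// functions from the C++17 special math library).  The transport loop
// tracks an explicit orthonormal polarization frame (u, w, v) per photon,
// with the Stokes vector referenced to u; scattering angles are drawn by
// rejection against the polarization-conditioned phase function.

#include <Rcpp.h>
#include <cmath>
#include <complex>
#include <cstdint>
#include <limits>
#include <random>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;
static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// deterministic uniform RNG (independent of R's stream; seeded per call)
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform on the open interval (0, 1)
  double unif() {
    return (static_cast<double>(gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// ---------------------------------------------------------------------------
// Jones (amplitude) matrix -> Mueller matrix, Stokes order (I, Q, U, V) with
// Q referenced to the "parallel" basis vector.  M = A (J (x) conj(J)) A^-1.
static void jones_to_mueller(cplx j11, cplx j12, cplx j21, cplx j22,
                             double M[16]) {
  const cplx J[2][2] = {{j11, j12}, {j21, j22}};
  cplx K[4][4];
  for (int a = 0; a < 2; ++a)
    for (int c = 0; c < 2; ++c)
      for (int b = 0; b < 2; ++b)
        for (int d = 0; d < 2; ++d)
          K[2 * a + c][2 * b + d] = J[a][b] * std::conj(J[c][d]);
  const cplx i1(0.0, 1.0);
  const cplx A[4][4] = {{1, 0, 0, 1}, {1, 0, 0, -1}, {0, 1, 1, 0}, {0, i1, -i1, 0}};
  const cplx Ai[4][4] = {{0.5, 0.5, 0, 0},
                         {0, 0, 0.5, -0.5 * i1},
                         {0, 0, 0.5, 0.5 * i1},
                         {0.5, -0.5, 0, 0}};
  for (int r = 0; r < 4; ++r) {
    cplx row[4] = {0, 0, 0, 0};
    for (int k = 0; k < 4; ++k)
      for (int l = 0; l < 4; ++l) row[l] += A[r][k] * K[k][l];
    for (int cidx = 0; cidx < 4; ++cidx) {
      cplx val = 0;
      for (int l = 0; l < 4; ++l) val += row[l] * Ai[l][cidx];
      M[4 * r + cidx] = val.real();
    }
  }
}

// first row only (enough for phase-function evaluation)
static void jones_first_row(cplx j11, cplx j12, cplx j21, cplx j22,
                            double out[4]) {
  double n11 = std::norm(j11), n12 = std::norm(j12);
  double n21 = std::norm(j21), n22 = std::norm(j22);
  cplx c1 = j11 * std::conj(j12) + j21 * std::conj(j22);
  out[0] = 0.5 * (n11 + n12 + n21 + n22);
  out[1] = 0.5 * (n11 - n12 + n21 - n22);
  out[2] = c1.real();
  out[3] = c1.imag(); // Im(j11 j12* - j22 j21*) = +Im(c1)
}

// ---------------------------------------------------------------------------
// Mie series for homogeneous spheres (real relative index)

struct MieCoef {
  std::vector<cplx> a, b;
  int N;
};

static int series_order(double x) {
  return static_cast<int>(std::ceil(x + 4.0 * std::cbrt(x) + 2.0));
}

static MieCoef mie_coefficients(double x, double m) {
  if (!(x > 0)) stop("size parameter must be positive");
  MieCoef co;
  co.N = series_order(x);
  int NN = co.N + 15;
  double mx = m * x;
  std::vector<double> D(NN + 1, 0.0);
  for (int n = NN; n >= 1; --n) {
    double t = n / mx;
    D[n - 1] = t - 1.0 / (D[n] + t);
  }
  co.a.assign(co.N + 1, 0.0);
  co.b.assign(co.N + 1, 0.0);
  // Riccati-Bessel psi_n(x), chi_n(x) by upward recurrence
  double psi_m1 = std::cos(x), psi_0 = std::sin(x);
  double chi_m1 = -std::sin(x), chi_0 = std::cos(x);
  double psi_nm1 = psi_0, psi_nm2 = psi_m1;
  double chi_nm1 = chi_0, chi_nm2 = chi_m1;
  for (int n = 1; n <= co.N; ++n) {
    double psi_n = (2.0 * n - 1.0) / x * psi_nm1 - psi_nm2;
    double chi_n = (2.0 * n - 1.0) / x * chi_nm1 - chi_nm2;
    cplx xi_n(psi_n, -chi_n), xi_nm1(psi_nm1, -chi_nm1);
    double da = D[n] / m + n / x;
    double db = D[n] * m + n / x;
    co.a[n] = (da * psi_n - psi_nm1) / (da * xi_n - xi_nm1);
    co.b[n] = (db * psi_n - psi_nm1) / (db * xi_n - xi_nm1);
    psi_nm2 = psi_nm1; psi_nm1 = psi_n;
    chi_nm2 = chi_nm1; chi_nm1 = chi_n;
  }
  return co;
}

static void mie_S12(const MieCoef& co, double mu, cplx& S1, cplx& S2) {
  S1 = 0.0;
  S2 = 0.0;
  double pi_nm1 = 0.0, pi_n = 1.0; // pi_0, pi_1
  for (int n = 1; n <= co.N; ++n) {
    double tau_n = n * mu * pi_n - (n + 1.0) * pi_nm1;
    double f = (2.0 * n + 1.0) / (n * (n + 1.0));
    S1 += f * (co.a[n] * pi_n + co.b[n] * tau_n);
    S2 += f * (co.a[n] * tau_n + co.b[n] * pi_n);
    double pi_np1 = ((2.0 * n + 1.0) * mu * pi_n - (n + 1.0) * pi_nm1) / n;
    pi_nm1 = pi_n;
    pi_n = pi_np1;
  }
}

static double mie_qsca_internal(const MieCoef& co, double x) {
  double q = 0.0;
  for (int n = 1; n <= co.N; ++n) {
    q += (2.0 * n + 1.0) * (std::norm(co.a[n]) + std::norm(co.b[n]));
  }
  return 2.0 / (x * x) * q;
}

// [[Rcpp::export]]
List cpp_mie_amplitudes(double x, double m, NumericVector theta) {
  MieCoef co = mie_coefficients(x, m);
  int n = theta.size();
  ComplexVector S1(n), S2(n);
  for (int i = 0; i < n; ++i) {
    cplx s1, s2;
    mie_S12(co, std::cos(theta[i]), s1, s2);
    S1[i].r = s1.real(); S1[i].i = s1.imag();
    S2[i].r = s2.real(); S2[i].i = s2.imag();
  }
  return List::create(_["S1"] = S1, _["S2"] = S2, _["n_terms"] = co.N);
}

// [[Rcpp::export]]
double cpp_mie_qsca(double x, double m) {
  MieCoef co = mie_coefficients(x, m);
  return mie_qsca_internal(co, x);
}

// [[Rcpp::export]]
NumericMatrix cpp_single_scatter_mueller(double x, double m, double theta) {
  MieCoef co = mie_coefficients(x, m);
  cplx s1, s2;
  mie_S12(co, std::cos(theta), s1, s2);
  double M[16];
  jones_to_mueller(s2, 0.0, 0.0, s1, M);
  NumericMatrix out(4, 4);
  for (int r = 0; r < 4; ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = M[4 * r + c];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_jones_to_mueller(ComplexMatrix J) {
  if (J.nrow() != 2 || J.ncol() != 2) stop("J must be 2x2");
  double M[16];
  jones_to_mueller(cplx(J(0, 0).r, J(0, 0).i), cplx(J(0, 1).r, J(0, 1).i),
                   cplx(J(1, 0).r, J(1, 0).i), cplx(J(1, 1).r, J(1, 1).i), M);
  NumericMatrix out(4, 4);
  for (int r = 0; r < 4; ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = M[4 * r + c];
  return out;
}

// ---------------------------------------------------------------------------
// Infinite cylinder at oblique incidence.
//
// zeta is the angle between the incident direction and the cylinder axis
// (pi/2 = normal incidence).  Scattered directions lie on the cone making
// the same angle with the axis; Theta is the azimuth around the axis
// measured from the forward direction.  Case I: incident E parallel to the
// plane containing the axis and the incident direction; case II:
// perpendicular.

struct CylCoef {
  std::vector<cplx> a1, b1, a2, b2; // a_n^I, b_n^I, a_n^II, b_n^II
  int N;
  double xi;
};

static CylCoef cyl_coefficients(double x, double m, double zeta) {
  if (!(x > 0)) stop("size parameter must be positive");
  if (!(zeta > 0.0 && zeta <= PI / 2 + 1e-12))
    stop("zeta must lie in (0, pi/2]");
  double sz = std::sin(zeta), cz = std::cos(zeta);
  if (m * m <= cz * cz)
    stop("relative index too small for this incidence angle");
  CylCoef co;
  co.N = series_order(x);
  co.xi = x * sz;
  double xi = co.xi;
  double eta = x * std::sqrt(m * m - cz * cz);
  int N = co.N;
  co.a1.assign(N + 1, 0.0);
  co.b1.assign(N + 1, 0.0);
  co.a2.assign(N + 1, 0.0);
  co.b2.assign(N + 1, 0.0);
  std::vector<double> Jxi(N + 2), Jeta(N + 2), Yxi(N + 2);
  for (int n = 0; n <= N + 1; ++n) {
    Jxi[n] = std::cyl_bessel_j(static_cast<double>(n), xi);
    Jeta[n] = std::cyl_bessel_j(static_cast<double>(n), eta);
    Yxi[n] = std::cyl_neumann(static_cast<double>(n), xi);
  }
  const cplx i1(0.0, 1.0);
  double ratio = xi * xi / (eta * eta) - 1.0;
  for (int n = 0; n <= N; ++n) {
    // high orders at small xi: Y overflows and the coefficients are
    // negligible; leave them at zero
    if (!std::isfinite(Yxi[n]) || std::fabs(Yxi[n]) > 1e140) break;
    double Jp_xi = (n == 0) ? -Jxi[1] : 0.5 * (Jxi[n - 1] - Jxi[n + 1]);
    double Jp_eta = (n == 0) ? -Jeta[1] : 0.5 * (Jeta[n - 1] - Jeta[n + 1]);
    double Yp_xi = (n == 0) ? -Yxi[1] : 0.5 * (Yxi[n - 1] - Yxi[n + 1]);
    cplx H(Jxi[n], Yxi[n]);
    cplx Hp(Jp_xi, Yp_xi);
    cplx An = i1 * xi * (xi * Jp_eta * Jxi[n] - eta * Jeta[n] * Jp_xi);
    double Bn = xi * (m * m * xi * Jp_eta * Jxi[n] - eta * Jeta[n] * Jp_xi);
    double Cn = n * cz * eta * Jeta[n] * Jxi[n] * ratio;
    cplx Dn = n * cz * eta * Jeta[n] * H * ratio;
    cplx Vn = xi * (m * m * xi * Jp_eta * H - eta * Jeta[n] * Hp);
    cplx Wn = i1 * xi * (eta * Jeta[n] * Hp - xi * Jp_eta * H);
    cplx den = Wn * Vn + i1 * Dn * Dn;
    if (!std::isfinite(den.real()) || !std::isfinite(den.imag()) ||
        std::abs(den) == 0.0)
      continue;
    co.a1[n] = (Cn * Vn - Bn * Dn) / den;
    co.b1[n] = (Wn * Bn + i1 * Dn * Cn) / den;
    co.a2[n] = -(An * Vn - i1 * Cn * Dn) / den;
    co.b2[n] = -i1 * (Cn * Wn + An * Dn) / den;
  }
  return co;
}

// amplitude-matrix entries at azimuth Theta:
//   [Epar_s; Eperp_s] ~ [T1 T4; T3 T2] [Epar_i; Eperp_i]
static void cyl_T(const CylCoef& co, double Theta, cplx& T1, cplx& T2,
                  cplx& T3, cplx& T4) {
  const cplx i1(0.0, 1.0);
  double c1 = std::cos(Theta), s1v = std::sin(Theta);
  double cn = c1, cnm1 = 1.0, sn = s1v, snm1 = 0.0;
  T1 = co.b1[0];
  T2 = co.a2[0];
  T3 = 0.0;
  T4 = 0.0;
  for (int n = 1; n <= co.N; ++n) {
    T1 += 2.0 * co.b1[n] * cn;
    T2 += 2.0 * co.a2[n] * cn;
    T3 += -2.0 * i1 * co.a1[n] * sn;
    T4 += -2.0 * i1 * co.b2[n] * sn;
    double cnp1 = 2.0 * c1 * cn - cnm1;
    double snp1 = 2.0 * c1 * sn - snm1;
    cnm1 = cn; cn = cnp1;
    snm1 = sn; sn = snp1;
  }
}

// [[Rcpp::export]]
List cpp_cylinder_amplitudes(double x, double m, double zeta,
                             NumericVector Theta) {
  CylCoef co = cyl_coefficients(x, m, zeta);
  int n = Theta.size();
  ComplexVector T1(n), T2(n), T3(n), T4(n);
  for (int i = 0; i < n; ++i) {
    cplx t1, t2, t3, t4;
    cyl_T(co, Theta[i], t1, t2, t3, t4);
    T1[i].r = t1.real(); T1[i].i = t1.imag();
    T2[i].r = t2.real(); T2[i].i = t2.imag();
    T3[i].r = t3.real(); T3[i].i = t3.imag();
    T4[i].r = t4.real(); T4[i].i = t4.imag();
  }
  return List::create(_["T1"] = T1, _["T2"] = T2, _["T3"] = T3, _["T4"] = T4,
                      _["n_terms"] = co.N);
}

// scattering efficiencies (relative to the transverse size parameter
// xi = x sin(zeta)) for the two incident polarization cases
// [[Rcpp::export]]
NumericVector cpp_cylinder_qsca(double x, double m, double zeta) {
  CylCoef co = cyl_coefficients(x, m, zeta);
  double qI = std::norm(co.b1[0]), qII = std::norm(co.a2[0]);
  for (int n = 1; n <= co.N; ++n) {
    qI += 2.0 * (std::norm(co.b1[n]) + std::norm(co.a1[n]));
    qII += 2.0 * (std::norm(co.a2[n]) + std::norm(co.b2[n]));
  }
  return NumericVector::create(_["Q_par"] = 2.0 / co.xi * qI,
                               _["Q_perp"] = 2.0 / co.xi * qII);
}

// ---------------------------------------------------------------------------
// rejection sampling of scattering angles

struct SphereTable {
  MieCoef co;
  double env; // envelope over theta for a fully polarized beam
};

static SphereTable sphere_table(double x, double m) {
  SphereTable t{mie_coefficients(x, m), 0.0};
  const int ng = 1801;
  double mx = 0.0;
  for (int i = 0; i < ng; ++i) {
    double th = PI * i / (ng - 1.0);
    cplx s1, s2;
    mie_S12(t.co, std::cos(th), s1, s2);
    double s11 = 0.5 * (std::norm(s1) + std::norm(s2));
    double s12 = 0.5 * (std::norm(s2) - std::norm(s1));
    double f = std::sin(th) * (s11 + std::fabs(s12));
    if (f > mx) mx = f;
  }
  t.env = 1.05 * mx;
  return t;
}

// one draw of (theta, phi); stokes must be normalized to s0 = 1
static void draw_sphere_angles(const SphereTable& t, const double S[4],
                               Rng& rng, double& theta, double& phi,
                               double* m11out, double* m12out) {
  for (int it = 0; it < 100000; ++it) {
    double th = PI * rng.unif();
    double ph = 2.0 * PI * rng.unif();
    cplx s1, s2;
    mie_S12(t.co, std::cos(th), s1, s2);
    double s11 = 0.5 * (std::norm(s1) + std::norm(s2));
    double s12 = 0.5 * (std::norm(s2) - std::norm(s1));
    double qrot = S[1] * std::cos(2.0 * ph) + S[2] * std::sin(2.0 * ph);
    double f = std::sin(th) * (s11 + s12 * qrot);
    if (f > t.env)
      stop("rejection envelope violated in sphere angle sampling");
    if (f > rng.unif() * t.env) {
      theta = th;
      phi = ph;
      if (m11out) *m11out = s11;
      if (m12out) *m12out = s12;
      return;
    }
  }
  stop("sphere angle sampling failed to accept");
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_sphere_angles(NumericVector stokes, double x,
                                       double m, int n, double seed) {
  if (stokes.size() != 4 || stokes[0] <= 0) stop("invalid Stokes vector");
  double S[4];
  for (int i = 0; i < 4; ++i) S[i] = stokes[i] / stokes[0];
  SphereTable t = sphere_table(x, m);
  Rng rng(static_cast<uint64_t>(seed));
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double th, ph;
    draw_sphere_angles(t, S, rng, th, ph, nullptr, nullptr);
    out(i, 0) = th;
    out(i, 1) = ph;
  }
  colnames(out) = CharacterVector::create("theta", "phi");
  return out;
}

struct CylZetaTables {
  std::vector<CylCoef> co;
  std::vector<double> env; // envelope over Theta for fully polarized input
  // Theta-averaged first row of the single-scattering Mueller matrix
  // (components 3 and 4 vanish by parity): the total scattering strength
  // for a photon with Stokes S in the incidence-plane basis is
  // phi(S) = A[0] + A[1] * q.  The ratio phi(S) / A[0] is the
  // polarization-dependent collision-rate factor of aligned cylinders,
  // which spheres do not have.
  std::vector<double> A0, A1;
  // Per-length field attenuation exponents (units of mu_c * s) for the
  // coherent beam in the incidence-plane basis: E_par ~ exp(g1 mu_c s),
  // E_perp ~ exp(g2 mu_c s), fixed by the polarization-resolved scattering
  // rates (energy conservation).  This is the dichroic part of the
  // extinction matrix of aligned cylinders; the coherent phase part (form
  // birefringence) is deliberately not modeled -- in the optical models
  // studied here that effect is represented by the intrinsic birefringence
  // of the host medium, while cylinders act through scattering and
  // differential extinction.
  std::vector<double> g1, g2;
  int nz;
  double step;
};

static void cyl_env_avg(const CylCoef& co, double& env, double& A0,
                        double& A1) {
  int ng = std::max(256, 8 * co.N);
  double mx = 0.0, s0 = 0.0, s1 = 0.0;
  for (int i = 0; i < ng; ++i) {
    double Th = 2.0 * PI * i / ng;
    cplx t1, t2, t3, t4;
    cyl_T(co, Th, t1, t2, t3, t4);
    double row[4];
    jones_first_row(t1, t4, t3, t2, row);
    double f = row[0] +
      std::sqrt(row[1] * row[1] + row[2] * row[2] + row[3] * row[3]);
    if (f > mx) mx = f;
    s0 += row[0];
    s1 += row[1];
  }
  env = 1.1 * mx;
  A0 = s0 / ng;
  A1 = s1 / ng;
}

static CylZetaTables cyl_tables(double x, double m, int nz = 721) {
  CylZetaTables t;
  t.nz = nz;
  t.step = (PI / 2) / nz;
  t.co.reserve(nz);
  t.env.reserve(nz);
  t.A0.reserve(nz);
  t.A1.reserve(nz);
  for (int i = 1; i <= nz; ++i) {
    CylCoef c = cyl_coefficients(x, m, i * t.step);
    double env, a0, a1;
    cyl_env_avg(c, env, a0, a1);
    t.env.push_back(env);
    t.A0.push_back(a0);
    t.A1.push_back(a1);
    // f_par/perp = 1 +/- A1/A0 are the polarization-resolved scattering
    // rates relative to the unpolarized one charged by the free-path
    // sampling
    double gg1 = 0.0, gg2 = 0.0;
    if (a0 > 1e-300) {
      gg1 = -(1.0 + a1 / a0) / 2.0;
      gg2 = -(1.0 - a1 / a0) / 2.0;
    }
    t.g1.push_back(gg1);
    t.g2.push_back(gg2);
    t.co.push_back(std::move(c));
  }
  return t;
}

static int cyl_index(const CylZetaTables& t, double zeta) {
  int idx = static_cast<int>(std::lround(zeta / t.step)) - 1;
  if (idx < 0) idx = 0;
  if (idx >= t.nz) idx = t.nz - 1;
  return idx;
}

// Theta draw against the polarized cylinder phase function; S normalized,
// already referenced to the incidence-plane basis
static double draw_cyl_theta(const CylCoef& co, double env, const double S[4],
                             Rng& rng, double M16[16]) {
  for (int it = 0; it < 200000; ++it) {
    double Th = 2.0 * PI * rng.unif();
    cplx t1, t2, t3, t4;
    cyl_T(co, Th, t1, t2, t3, t4);
    double row[4];
    jones_first_row(t1, t4, t3, t2, row);
    double f = row[0] + row[1] * S[1] + row[2] * S[2] + row[3] * S[3];
    if (f > env)
      stop("rejection envelope violated in cylinder angle sampling");
    if (f > rng.unif() * env) {
      jones_to_mueller(t1, t4, t3, t2, M16);
      return Th;
    }
  }
  stop("cylinder angle sampling failed to accept");
}

// [[Rcpp::export]]
NumericVector cpp_sample_cylinder_angles(NumericVector stokes, double x,
                                         double m, double zeta, int n,
                                         double seed) {
  if (stokes.size() != 4 || stokes[0] <= 0) stop("invalid Stokes vector");
  if (!(zeta > 0)) stop("zeta = 0 (propagation along the cylinder axis)");
  double S[4];
  for (int i = 0; i < 4; ++i) S[i] = stokes[i] / stokes[0];
  CylCoef co = cyl_coefficients(x, m, zeta);
  double env, a0, a1;
  cyl_env_avg(co, env, a0, a1);
  Rng rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  double M16[16];
  for (int i = 0; i < n; ++i) out[i] = draw_cyl_theta(co, env, S, rng, M16);
  return out;
}

// ---------------------------------------------------------------------------
// transport

struct V3 {
  double x, y, z;
};
static inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 operator*(double s, V3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm3(V3 a) { return std::sqrt(dot(a, a)); }
static inline V3 normalize(V3 a) {
  double n = norm3(a);
  return {a.x / n, a.y / n, a.z / n};
}

// rotate the Stokes reference frame by beta about the propagation direction
static inline void stokes_rotate(double S[4], double beta) {
  double c2 = std::cos(2.0 * beta), s2 = std::sin(2.0 * beta);
  double q = S[1], u = S[2];
  S[1] = q * c2 + u * s2;
  S[2] = -q * s2 + u * c2;
}

static inline void apply_mueller16(const double M[16], double S[4]) {
  double out[4];
  for (int r = 0; r < 4; ++r) {
    out[r] = M[4 * r] * S[0] + M[4 * r + 1] * S[1] + M[4 * r + 2] * S[2] +
             M[4 * r + 3] * S[3];
  }
  for (int r = 0; r < 4; ++r) S[r] = out[r];
}

// retarder with fast axis along the current reference vector
static inline void apply_retarder0(double S[4], double delta) {
  double cd = std::cos(delta), sd = std::sin(delta);
  double u = S[2], v = S[3];
  S[2] = cd * u + sd * v;
  S[3] = -sd * u + cd * v;
}

// [[Rcpp::export]]
List cpp_transport(List cfg, NumericVector stokes_in, int n_photons,
                   double seed) {
  const double d = as<double>(cfg["thickness_um"]);
  const double mu_s = as<double>(cfg["mu_s_um"]);
  const double mu_c = as<double>(cfg["mu_c_um"]);
  const double lambda = as<double>(cfg["wavelength_um"]);
  const double dn = as<double>(cfg["delta_n"]);
  const double nmo = as<double>(cfg["n_host"]);
  const double nme = nmo + dn;
  NumericVector oax = cfg["optic_axis"], cax = cfg["cylinder_axis"];
  const V3 optic = normalize({oax[0], oax[1], oax[2]});
  const V3 cylax = normalize({cax[0], cax[1], cax[2]});
  const int nx = as<int>(cfg["image_pixels"]);
  const double pitch = as<double>(cfg["image_pitch_um"]);
  const double det_r = as<double>(cfg["detector_diameter_um"]) / 2.0;
  const double halfw = as<double>(cfg["lateral_halfwidth_um"]);
  const int max_events = as<int>(cfg["max_events"]);
  const double half_extent = nx * pitch / 2.0;
  const double mu_t = mu_s + mu_c;

  SphereTable sph;
  bool has_sph = mu_s > 0;
  if (has_sph) sph = sphere_table(as<double>(cfg["x_sphere"]), as<double>(cfg["m_sphere"]));
  CylZetaTables cyl;
  bool has_cyl = mu_c > 0;
  if (has_cyl)
    cyl = cyl_tables(as<double>(cfg["x_cylinder"]), as<double>(cfg["m_cylinder"]));

  Rng rng(static_cast<uint64_t>(seed));
  NumericVector image(nx * nx * 4); // sums of I,Q,U,V per pixel (lab frame)
  long n_det = 0, n_undet = 0, n_refl = 0, n_lost = 0;
  const double s0in = stokes_in[0];

  for (int ip = 0; ip < n_photons; ++ip) {
    V3 pos{0, 0, 0}, v{0, 0, 1}, u{1, 0, 0}, w{0, 1, 0};
    double S[4] = {stokes_in[0] / s0in, stokes_in[1] / s0in,
                   stokes_in[2] / s0in, stokes_in[3] / s0in};
    int events = 0;
    int fate = -1; // 0 detected, 1 undetected, 2 reflected, 3 lost
    while (true) {
      double s = (mu_t > 0) ? -std::log(rng.unif()) / mu_t
                            : std::numeric_limits<double>::infinity();
      double d_b = std::numeric_limits<double>::infinity();
      if (v.z > 0)
        d_b = (d - pos.z) / v.z;
      else if (v.z < 0)
        d_b = -pos.z / v.z;
      double step = std::min(s, d_b);
      if (!std::isfinite(step)) { fate = 3; break; } // v.z == 0 in vacuum
      // birefringent host acts as a continuous retarder along the segment
      if (dn > 0 && step > 0) {
        double cth = dot(v, optic);
        double sth2 = 1.0 - cth * cth;
        if (sth2 > 1e-24) {
          double ne_th =
              1.0 / std::sqrt(cth * cth / (nmo * nmo) + sth2 / (nme * nme));
          double delta = 2.0 * PI / lambda * (ne_th - nmo) * step;
          V3 p = normalize(optic - cth * v);
          double beta = std::atan2(dot(p, w), dot(p, u));
          stokes_rotate(S, beta);
          apply_retarder0(S, delta);
          stokes_rotate(S, -beta);
        }
      }
      // Extinction matrix of the aligned cylinders acting on the coherent
      // beam along the segment, relative to the scalar (unpolarized)
      // attenuation already charged by the free-path sampling: a diagonal
      // Jones operator diag(exp((g1 + 1/2) mu_c s), exp((g2 + 1/2) mu_c s))
      // in the incidence-plane basis.  Its real parts produce dichroic
      // extinction, its imaginary parts the form birefringence of the
      // cylinder suspension.  (The host-birefringence retarder above and
      // this operator share the laboratory X axis in the studied models,
      // so the within-segment operator ordering is immaterial there.)
      if (has_cyl && step > 0 && std::isfinite(step)) {
        V3 ax = cylax;
        double cza = dot(v, ax);
        if (cza < 0) { ax = -1.0 * ax; cza = -cza; }
        double sza2 = 1.0 - cza * cza;
        if (sza2 > 1e-12 && S[0] > 0) {
          int iz = cyl_index(cyl, std::acos(std::min(1.0, cza)));
          if (cyl.A0[iz] > 1e-300) {
            V3 epar = normalize(ax - cza * v);
            double beta = std::atan2(dot(epar, w), dot(epar, u));
            stokes_rotate(S, beta);
            double e1 = std::exp((cyl.g1[iz] + 0.5) * (mu_c * step));
            double e2 = std::exp((cyl.g2[iz] + 0.5) * (mu_c * step));
            double M16[16];
            jones_to_mueller(e1, 0.0, 0.0, e2, M16);
            apply_mueller16(M16, S);
            stokes_rotate(S, -beta);
          }
        }
      }
      pos = pos + step * v;
      if (step == d_b) {
        fate = (v.z > 0) ? 0 : 2;
        break;
      }
      if (std::fabs(pos.x) > halfw || std::fabs(pos.y) > halfw) {
        fate = 3;
        break;
      }
      // scattering event
      bool is_sphere = has_sph &&
        (!has_cyl || rng.unif() < mu_s / mu_t);
      // The Stokes vector carries the photon weight in s0.  Scattering
      // events sample the deflection from the polarization-conditioned
      // phase function of the *normalized* Stokes vector; the applied
      // Mueller matrix is then rescaled so that the expected weight change
      // equals the polarization-dependent total-scattering ratio
      // phi(S)/phi_unpol (identically 1 for spheres, where the
      // phase-function normalization is polarization independent).
      double w_in = S[0];
      double Sn[4] = {1.0, S[1] / w_in, S[2] / w_in, S[3] / w_in};
      if (is_sphere) {
        double th, ph;
        draw_sphere_angles(sph, Sn, rng, th, ph, nullptr, nullptr);
        stokes_rotate(S, ph);
        V3 u1 = std::cos(ph) * u + std::sin(ph) * w;
        V3 w1 = cross(v, u1);
        cplx s1, s2;
        mie_S12(sph.co, std::cos(th), s1, s2);
        double M16[16];
        jones_to_mueller(s2, 0.0, 0.0, s1, M16);
        apply_mueller16(M16, S);
        double scale = w_in / S[0]; // phi/phi_unpol = 1: weight preserved
        for (int k = 0; k < 4; ++k) S[k] *= scale;
        V3 vnew = std::cos(th) * v + std::sin(th) * u1;
        u = std::cos(th) * u1 - std::sin(th) * v;
        w = w1;
        v = vnew;
      } else {
        V3 ax = cylax;
        double cz = dot(v, ax);
        if (cz < 0) { ax = -1.0 * ax; cz = -cz; }
        double sz2 = 1.0 - cz * cz;
        if (sz2 > 1e-12) {
          double zeta = std::acos(std::min(1.0, cz));
          int iz = cyl_index(cyl, zeta);
          double env = cyl.env[iz];
          const CylCoef& co = cyl.co[iz];
          if (env > 0 && cyl.A0[iz] > 1e-300) {
            V3 epar = normalize(ax - cz * v);
            double beta = std::atan2(dot(epar, w), dot(epar, u));
            stokes_rotate(S, beta);
            double c2 = std::cos(2.0 * beta), s2b = std::sin(2.0 * beta);
            double qn = Sn[1] * c2 + Sn[2] * s2b;
            double un = -Sn[1] * s2b + Sn[2] * c2;
            double Snr[4] = {1.0, qn, un, Sn[3]};
            double M16[16];
            double Th = draw_cyl_theta(co, env, Snr, rng, M16);
            double phi = cyl.A0[iz] + cyl.A1[iz] * qn;
            apply_mueller16(M16, S);
            // weight update: w_out = w_in * phi(S)/A0
            double scale = (phi * w_in) / (S[0] * cyl.A0[iz]);
            for (int k = 0; k < 4; ++k) S[k] *= scale;
            V3 t1 = normalize(v - cz * ax);
            // the azimuth orientation around the axis is a convention;
            // all reported quantities are insensitive to it
            V3 t2 = cross(t1, ax);
            double szv = std::sqrt(sz2);
            V3 vnew = cz * ax + szv * (std::cos(Th) * t1 + std::sin(Th) * t2);
            vnew = normalize(vnew);
            double ces = dot(ax, vnew);
            u = normalize(ax - ces * vnew);
            v = vnew;
            w = cross(v, u);
          }
        }
        // propagation (nearly) along the axis: no deflection
      }
      // refresh frame orthonormality
      v = normalize(v);
      u = normalize(u - dot(u, v) * v);
      w = cross(v, u);
      if (++events >= max_events) {
        fate = 3;
        break;
      }
    }
    if (fate == 0) {
      // Reference the Stokes vector to the laboratory (X, Y) basis
      // parallel-transported from the surface normal to the exit direction
      // along the meridian (the collimation convention of an imaging
      // detector): e1 = Rot(z -> v) x_hat, rotating about z x v.  This
      // commutes with in-plane rotations of the whole system, so lab-frame
      // symmetries of the model survive detection exactly.
      double s2xy = v.x * v.x + v.y * v.y;
      V3 e1{1, 0, 0};
      if (s2xy > 1e-18) {
        double sxy = std::sqrt(s2xy);
        V3 k{-v.y / sxy, v.x / sxy, 0.0};
        V3 kxe = cross(k, e1);
        e1 = v.z * e1 + sxy * kxe + (dot(k, e1) * (1.0 - v.z)) * k;
      }
      double beta = std::atan2(dot(e1, w), dot(e1, u));
      stokes_rotate(S, beta);
      double r = std::sqrt(pos.x * pos.x + pos.y * pos.y);
      if (r <= det_r)
        ++n_det;
      else
        ++n_undet;
      int ix = static_cast<int>(std::floor((pos.x + half_extent) / pitch));
      int iy = static_cast<int>(std::floor((pos.y + half_extent) / pitch));
      if (ix >= 0 && ix < nx && iy >= 0 && iy < nx) {
        for (int k = 0; k < 4; ++k)
          image[ix + nx * iy + nx * nx * k] += S[k] * s0in;
      }
    } else if (fate == 2) {
      ++n_refl;
    } else {
      ++n_lost;
    }
  }
  image.attr("dim") = IntegerVector::create(nx, nx, 4);
  return List::create(
      _["image"] = image,
      _["counts"] = IntegerVector::create(
          _["transmitted_detected"] = n_det,
          _["transmitted_undetected"] = n_undet, _["reflected"] = n_refl,
          _["lost"] = n_lost));
}
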