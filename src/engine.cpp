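// Time-dependent rotating-frame Hamiltonian and piecewise-constant propagator
// for one 13C (spin 1/2) x 14N (spin 1) pair under MAS.
//
// Basis: |mS, mN> with mS = +1/2, -1/2 (outer) and mN = +1, 0, -1 (inner),
// index = 3*s + n, dimension 6. All frequencies in rad/s, times in s.
//
// Spatial tensors arrive as rotor-frame rank-2 spherical components
// A[0..4] <-> m = -2..2; the lab components at time t are
//   A_lab[m] = sum_{m'} A_rot[m'] exp(-i m' w_r t) d2ra(m', m)
// with d2ra the reduced Wigner matrix at the rotor-axis angle.
//
// First order (secular): A_lab_Q[0] * T20(N) + A_lab_D[0] * (2/sqrt6) IzSz
//                        + 2*pi*J IzSz + offN*Iz + offC*Sz + rf.
// Second order (instantaneous van Vleck, valid wQ << w0N):
//   H2 = sum_{m=1,2} (V_m^dag V_m - V_m V_m^dag) / (m * w0N)
// where V_m is the Delta mN = +m component of the non-secular coupling
// (quadrupole T2,+-1, T2,+-2 self terms; dipolar I+-Sz flip terms).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const std::complex<double> I1(0.0, 1.0);

struct Ops {
  cx_mat Iz, Ip, Im, Ix, Iy;      // 14N, embedded (6x6)
  cx_mat Sz, Sx, Sy;              // 13C, embedded
  cx_mat T20, T2p1, T2m1, T2p2, T2m2;   // standard 14N rank-2 tensors
  cx_mat IzSz;
  cx_mat Dp1, Dm1;                // dipolar N-flip spin factors I+-Sz
};

cx_mat kron2(const cx_mat& A, const cx_mat& B) { return kron(A, B); }

const Ops& ops() {
  static Ops o = [] {
    Ops p;
    cx_mat e2(2, 2, fill::eye), e3(3, 3, fill::eye);
    cx_mat nz(3, 3, fill::zeros), np(3, 3, fill::zeros);
    nz(0, 0) = 1.0; nz(2, 2) = -1.0;
    np(0, 1) = std::sqrt(2.0); np(1, 2) = std::sqrt(2.0);
    cx_mat nm = np.t();
    cx_mat sz(2, 2, fill::zeros), sp(2, 2, fill::zeros);
    sz(0, 0) = 0.5; sz(1, 1) = -0.5;
    sp(0, 1) = 1.0;
    cx_mat sm = sp.t();
    p.Iz = kron2(e2, nz);
    p.Ip = kron2(e2, np);
    p.Im = kron2(e2, nm);
    p.Ix = (p.Ip + p.Im) / 2.0;
    p.Iy = (p.Ip - p.Im) / (2.0 * I1);
    p.Sz = kron2(sz, e3);
    p.Sx = kron2((sp + sm) / 2.0, e3);
    p.Sy = kron2((sp - sm) / (2.0 * I1), e3);
    cx_mat eye6(6, 6, fill::eye);
    // standard (non Frobenius-normalised) spin-1 tensor operators
    p.T20 = (3.0 * p.Iz * p.Iz - 2.0 * eye6) / std::sqrt(6.0);
    p.T2p1 = -0.5 * (p.Iz * p.Ip + p.Ip * p.Iz);
    p.T2m1 = 0.5 * (p.Iz * p.Im + p.Im * p.Iz);
    p.T2p2 = 0.5 * p.Ip * p.Ip;
    p.T2m2 = 0.5 * p.Im * p.Im;
    p.IzSz = p.Iz * p.Sz;
    p.Dp1 = p.Ip * p.Sz;
    p.Dm1 = p.Im * p.Sz;
    return p;
  }();
  return o;
}

// lab-frame components m = -2..2 at time t from rotor-frame components
cx_vec lab_components(const cx_vec& Arot, const mat& d2ra, double wr, double t) {
  cx_vec ph(5), out(5, fill::zeros);
  for (int mp = -2; mp <= 2; ++mp)
    ph(mp + 2) = std::exp(-I1 * double(mp) * wr * t);
  for (int m = -2; m <= 2; ++m) {
    std::complex<double> acc(0.0, 0.0);
    for (int mp = -2; mp <= 2; ++mp)
      acc += Arot(mp + 2) * ph(mp + 2) * d2ra(mp + 2, m + 2);
    out(m + 2) = acc;
  }
  return out;
}

cx_mat ham_build(double t,
                 const cx_vec& AQrot, const cx_vec& ADrot, const mat& d2ra,
                 double wr, double w0N,
                 double w1N, double phN, double w1C, double phC,
                 double offN, double offC, double Jw,
                 bool second_order) {
  const Ops& o = ops();
  cx_vec AQ = lab_components(AQrot, d2ra, wr, t);
  cx_vec AD = lab_components(ADrot, d2ra, wr, t);

  double aq0 = std::real(AQ(2));
  double ad0 = std::real(AD(2));
  cx_mat H = aq0 * o.T20 + (ad0 * 2.0 / std::sqrt(6.0) + Jw) * o.IzSz
           + offN * o.Iz + offC * o.Sz;
  if (w1N != 0.0)
    H += w1N * (std::cos(phN) * o.Ix + std::sin(phN) * o.Iy);
  if (w1C != 0.0)
    H += w1C * (std::cos(phC) * o.Sx + std::sin(phC) * o.Sy);

  if (second_order) {
    // Delta mN = +1 and +2 components of the non-secular coupling.
    // Full coupling: sum_m (-1)^m A_{2,m} T_{2,-m}; the T_{2,+k} term carries
    // coefficient (-1)^k A_{2,-k} ... written out directly below.
    cx_mat V1 = -AQ(1) * o.T2p1 + 0.5 * AD(1) * o.Dp1;  // m = -1 coefficients
    cx_mat V2 = AQ(0) * o.T2p2;                          // m = -2 coefficient
    cx_mat H2 = (V1.t() * V1 - V1 * V1.t()) / w0N
              + (V2.t() * V2 - V2 * V2.t()) / (2.0 * w0N);
    H += H2;
  }
  return H;
}

} // namespace

// [[Rcpp::export]]
arma::cx_mat cpp_ham_at(double t,
                        const arma::cx_vec& AQrot, const arma::cx_vec& ADrot,
                        const arma::mat& d2ra,
                        double wr, double w0N,
                        double w1N, double phN, double w1C, double phC,
                        double offN, double offC, double Jw,
                        bool second_order) {
  return ham_build(t, AQrot, ADrot, d2ra, wr, w0N,
                   w1N, phN, w1C, phC, offN, offC, Jw, second_order);
}

// [[Rcpp::export]]
arma::cx_mat cpp_propagate(double t0, double duration, int n_steps,
                           const arma::cx_vec& AQrot, const arma::cx_vec& ADrot,
                           const arma::mat& d2ra,
                           double wr, double w0N,
                           double w1N, double phN, double w1C, double phC,
                           double offN, double offC, double Jw,
                           bool second_order) {
  cx_mat U(6, 6, fill::eye);
  const double dt = duration / n_steps;
  vec eval;
  cx_mat evec;
  for (int k = 0; k < n_steps; ++k) {
    double tm = t0 + (k + 0.5) * dt;  // midpoint: 2nd-order accurate
    cx_mat H = ham_build(tm, AQrot, ADrot, d2ra, wr, w0N,
                         w1N, phN, w1C, phC, offN, offC, Jw, second_order);
    eig_sym(eval, evec, H);
    cx_vec phase = exp(-I1 * conv_to<cx_vec>::from(eval) * dt);
    U = evec * diagmat(phase) * evec.t() * U;
  }
  return U;
}

// Efficiency/amplitude kernel for one crystallite: given the excitation-pulse
// period propagator this is pure matrix algebra, but it sits in C++ because the
// scans call it tens of thousands of times.
// Returns (eff, a_{-2}, a_{-1}, a_0, a_{+1}, a_{+2}).
// [[Rcpp::export]]
arma::vec cpp_sequence_kernel(const arma::cx_mat& U, int sel_order) {
  const Ops& o = ops();
  cx_mat rho = U * o.Sx * U.t();
  // N coherence order of element (i,j): mN(i) - mN(j), mN = 1 - (idx %% 3)
  vec amps(5, fill::zeros);
  cx_mat rf(6, 6, fill::zeros);
  for (int i = 0; i < 6; ++i) {
    int mi = 1 - (i % 3);
    for (int j = 0; j < 6; ++j) {
      int p = mi - (1 - (j % 3));
      amps(p + 2) += std::norm(rho(i, j));
      if (std::abs(p) == sel_order) rf(i, j) = rho(i, j);
    }
  }
  amps = sqrt(amps / 1.5);  // ||Sx||_F^2 = 1.5
  // ideal pi pulse on 13C about x: block swap with -i factors
  cx_mat pi6(6, 6, fill::zeros);
  for (int n = 0; n < 3; ++n) { pi6(n, 3 + n) = -I1; pi6(3 + n, n) = -I1; }
  cx_mat rho3 = U * (pi6 * rf * pi6.t()) * U.t();
  double eff = std::real(accu(rho3 % conv_to<cx_mat>::from(o.Sx))) / 1.5;
  vec out(6);
  out(0) = eff;
  out.subvec(1, 5) = amps;
  return out;
}
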