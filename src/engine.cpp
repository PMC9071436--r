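// Bead-spring semiflexible ring polymer with implicit-solvent Langevin
// dynamics (BAOAB splitting on velocity Verlet) and a designated soft
// (strand-crossing) segment whose location is updated in-run by one of five
// relocation models: static, random jump, curvilinear diffusion, jump to
// maximum local curvature, jump to maximum local density.
//
// Reduced units throughout: sigma = epsilon = k_BT = tau_B = 1 by default.
// Pair rules: bonded (1-2) pairs always FENE + steric LJ (a purely soft bond
// has no repulsive core and collapses); every other non-bonded pair is LJ
// unless one of the two beads belongs to the bound segment, in which case it
// uses the soft potential at the segment's current amplitude.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include "rng.h"

using namespace Rcpp;

namespace {

struct Pot {
  double sigma, eps, rc, rc2, K, R02, kappa;  // kappa = kT * lp / sigma
};

inline bool in_segment(int i, int start, int lT, int N) {
  if (lT <= 0) return false;
  int d = i - start;
  if (d < 0) d += N;
  return d < lT;
}

class Engine {
 public:
  Engine(NumericMatrix x0, const Pot& pot, double dt, double gamma, double kT,
         int seg_start, int lT, double A, uint64_t seed)
      : N_(x0.nrow()), pot_(pot), dt_(dt), gamma_(gamma), kT_(kT),
        seg_start_(seg_start), lT_(lT), A_(A), rng_(seed),
        skin_(1.0 * pot.sigma), rebuilds_(0) {
    x_.resize(3 * N_);
    v_.assign(3 * N_, 0.0);
    f_.assign(3 * N_, 0.0);
    for (int i = 0; i < N_; ++i)
      for (int d = 0; d < 3; ++d) x_[3 * i + d] = x0(i, d);
    update_membership();
    build_neighbors();
    forces();
  }

  void set_velocities(const NumericMatrix& v0) {
    for (int i = 0; i < N_; ++i)
      for (int d = 0; d < 3; ++d) v_[3 * i + d] = v0(i, d);
  }

  void maxwell_velocities() {
    if (kT_ <= 0) return;
    double s = std::sqrt(kT_);
    for (int i = 0; i < 3 * N_; ++i) v_[i] = s * rng_.gauss();
  }

  void set_segment(int start, int lT, double A) {
    seg_start_ = start; lT_ = lT; A_ = A;
    update_membership();
  }
  int seg_start() const { return seg_start_; }
  double amplitude() const { return A_; }
  int lT() const { return lT_; }

  KRng& rng() { return rng_; }

  // one BAOAB step
  void step() {
    double h = 0.5 * dt_;
    for (int i = 0; i < 3 * N_; ++i) v_[i] += h * f_[i];
    for (int i = 0; i < 3 * N_; ++i) x_[i] += h * v_[i];
    if (gamma_ > 0) {
      double c1 = std::exp(-gamma_ * dt_);
      double c2 = (kT_ > 0) ? std::sqrt(kT_ * (1.0 - c1 * c1)) : 0.0;
      for (int i = 0; i < 3 * N_; ++i) v_[i] = c1 * v_[i] + c2 * rng_.gauss();
    }
    for (int i = 0; i < 3 * N_; ++i) x_[i] += h * v_[i];
    // per-step displacement guard (dt * |v| bounds the move)
    double vmax2 = 0.0;
    for (int i = 0; i < N_; ++i) {
      double s = v_[3*i]*v_[3*i] + v_[3*i+1]*v_[3*i+1] + v_[3*i+2]*v_[3*i+2];
      if (s > vmax2) vmax2 = s;
    }
    if (dt_ * std::sqrt(vmax2) > pot_.sigma)
      stop("integration unstable: bead displacement exceeded sigma in one step");
    if (need_rebuild()) build_neighbors();
    forces();
    for (int i = 0; i < 3 * N_; ++i) v_[i] += h * f_[i];
  }

  // potential energies: pair (LJ+soft, incl. bonded steric), fene, bend
  void energies(double* pair, double* fene, double* bend) const {
    *pair = 0; *fene = 0; *bend = 0;
    for (int i = 0; i < N_; ++i) {
      int j = (i + 1) % N_;
      *fene += fene_energy(dist2(i, j), i);
      *bend += bend_energy(i);
    }
    for (int i = 0; i < N_; ++i)
      for (int j = i + 1; j < N_; ++j) {
        int d = std::min(j - i, N_ - (j - i));
        double r2 = dist2(i, j);
        *pair += (d == 1) ? lj_energy(r2) : pair_energy_nb(r2, i, j);
      }
  }

  double kinetic() const {
    double k = 0;
    for (int i = 0; i < 3 * N_; ++i) k += v_[i] * v_[i];
    return 0.5 * k;
  }

  // any bead of [start, start+lT) closer than 0.9 sigma to a non-bonded bead?
  bool segment_overlapped(int start, int lT) const {
    double lim = 0.81 * pot_.sigma * pot_.sigma;
    for (int a = 0; a < lT; ++a) {
      int i = (start + a) % N_;
      for (int j = 0; j < N_; ++j) {
        int d = std::abs(i - j);
        if (d <= 1 || d >= N_ - 1) continue;
        if (dist2(i, j) < lim) return true;
      }
    }
    return false;
  }

  NumericMatrix coords() const {
    NumericMatrix m(N_, 3);
    for (int i = 0; i < N_; ++i)
      for (int d = 0; d < 3; ++d) m(i, d) = x_[3 * i + d];
    return m;
  }
  NumericMatrix velocities() const {
    NumericMatrix m(N_, 3);
    for (int i = 0; i < N_; ++i)
      for (int d = 0; d < 3; ++d) m(i, d) = v_[3 * i + d];
    return m;
  }
  const std::vector<double>& xraw() const { return x_; }
  int N() const { return N_; }
  int rebuilds() const { return rebuilds_; }

  NumericMatrix force_matrix() const {
    NumericMatrix m(N_, 3);
    for (int i = 0; i < N_; ++i)
      for (int d = 0; d < 3; ++d) m(i, d) = f_[3 * i + d];
    return m;
  }

 private:
  int N_;
  Pot pot_;
  double dt_, gamma_, kT_;
  int seg_start_, lT_;
  double A_;
  KRng rng_;
  double skin_;
  int rebuilds_;
  std::vector<double> x_, v_, f_;
  std::vector<char> inseg_;
  std::vector<int> nl_;            // flattened (i, j) non-bonded pairs
  std::vector<double> x_build_;

  void update_membership() {
    inseg_.assign(N_, 0);
    for (int a = 0; a < lT_; ++a) inseg_[(seg_start_ + a) % N_] = 1;
  }

  double dist2(int i, int j) const {
    double dx = x_[3*i] - x_[3*j], dy = x_[3*i+1] - x_[3*j+1], dz = x_[3*i+2] - x_[3*j+2];
    return dx * dx + dy * dy + dz * dz;
  }

  void build_neighbors() {
    double rl = pot_.rc + skin_;
    double rl2 = rl * rl;
    nl_.clear();
    for (int i = 0; i < N_; ++i)
      for (int j = i + 1; j < N_; ++j) {
        int d = j - i;
        if (d == 1 || d == N_ - 1) continue;  // bonded pairs handled separately
        if (dist2(i, j) < rl2) { nl_.push_back(i); nl_.push_back(j); }
      }
    x_build_ = x_;
    ++rebuilds_;
  }

  bool need_rebuild() const {
    double lim = 0.25 * skin_ * skin_;
    for (int i = 0; i < N_; ++i) {
      double dx = x_[3*i] - x_build_[3*i], dy = x_[3*i+1] - x_build_[3*i+1],
             dz = x_[3*i+2] - x_build_[3*i+2];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  double lj_energy(double r2) const {
    if (r2 >= pot_.rc2) return 0.0;
    double s2 = pot_.sigma * pot_.sigma / r2;
    double s6 = s2 * s2 * s2;
    return 4.0 * pot_.eps * (s6 * s6 - s6) + pot_.eps;
  }

  double soft_energy(double r2) const {
    if (r2 >= pot_.rc2) return 0.0;
    double r = std::sqrt(r2);
    return A_ * (1.0 + std::cos(M_PI * r / pot_.rc));
  }

  double pair_energy_nb(double r2, int i, int j) const {
    if (inseg_[i] || inseg_[j]) return soft_energy(r2);
    return lj_energy(r2);
  }

  double fene_energy(double r2, int i) const {
    double q = r2 / pot_.R02;
    if (q >= 1.0)
      stop("FENE domain violation at bond starting at bead %d", i + 1);
    return -0.5 * pot_.K * pot_.R02 * std::log(1.0 - q);
  }

  double bend_energy(int i) const {
    // angle at bead i between bond vectors (i-1 -> i) and (i -> i+1)
    int im = (i - 1 + N_) % N_, ip = (i + 1) % N_;
    double ux = x_[3*i] - x_[3*im], uy = x_[3*i+1] - x_[3*im+1], uz = x_[3*i+2] - x_[3*im+2];
    double vx = x_[3*ip] - x_[3*i], vy = x_[3*ip+1] - x_[3*i+1], vz = x_[3*ip+2] - x_[3*i+2];
    double un = std::sqrt(ux*ux + uy*uy + uz*uz), vn = std::sqrt(vx*vx + vy*vy + vz*vz);
    if (un == 0 || vn == 0) stop("degenerate (zero-length) bond at bead %d", i + 1);
    double c = (ux*vx + uy*vy + uz*vz) / (un * vn);
    return pot_.kappa * (1.0 - c);
  }

  void forces() {
    std::fill(f_.begin(), f_.end(), 0.0);
    // bonded: FENE + steric LJ
    for (int i = 0; i < N_; ++i) {
      int j = (i + 1) % N_;
      double dx = x_[3*i] - x_[3*j], dy = x_[3*i+1] - x_[3*j+1], dz = x_[3*i+2] - x_[3*j+2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double q = r2 / pot_.R02;
      if (q >= 1.0)
        stop("FENE domain violation at bond starting at bead %d", i + 1);
      double ff = -pot_.K / (1.0 - q);  // dU/dr / r for FENE (attractive)
      if (r2 < pot_.rc2) {
        double s2 = pot_.sigma * pot_.sigma / r2;
        double s6 = s2 * s2 * s2;
        ff += 24.0 * pot_.eps * (2.0 * s6 * s6 - s6) / r2;
      }
      f_[3*i] += ff * dx; f_[3*i+1] += ff * dy; f_[3*i+2] += ff * dz;
      f_[3*j] -= ff * dx; f_[3*j+1] -= ff * dy; f_[3*j+2] -= ff * dz;
    }
    // bending
    for (int i = 0; i < N_; ++i) {
      int im = (i - 1 + N_) % N_, ip = (i + 1) % N_;
      double ux = x_[3*i] - x_[3*im], uy = x_[3*i+1] - x_[3*im+1], uz = x_[3*i+2] - x_[3*im+2];
      double vx = x_[3*ip] - x_[3*i], vy = x_[3*ip+1] - x_[3*i+1], vz = x_[3*ip+2] - x_[3*i+2];
      double un2 = ux*ux + uy*uy + uz*uz, vn2 = vx*vx + vy*vy + vz*vz;
      double un = std::sqrt(un2), vn = std::sqrt(vn2);
      if (un == 0 || vn == 0) stop("degenerate (zero-length) bond at bead %d", i + 1);
      double uv = ux*vx + uy*vy + uz*vz;
      double c = uv / (un * vn);
      // U = kappa (1 - c); F = kappa * dc/dr
      double k = pot_.kappa;
      // dc/dr_im = -( v/(un vn) - c u/un^2 )
      double gmx = -(vx / (un * vn) - c * ux / un2);
      double gmy = -(vy / (un * vn) - c * uy / un2);
      double gmz = -(vz / (un * vn) - c * uz / un2);
      // dc/dr_ip = u/(un vn) - c v/vn^2
      double gpx = ux / (un * vn) - c * vx / vn2;
      double gpy = uy / (un * vn) - c * vy / vn2;
      double gpz = uz / (un * vn) - c * vz / vn2;
      f_[3*im]   += k * gmx; f_[3*im+1] += k * gmy; f_[3*im+2] += k * gmz;
      f_[3*ip]   += k * gpx; f_[3*ip+1] += k * gpy; f_[3*ip+2] += k * gpz;
      f_[3*i]    -= k * (gmx + gpx);
      f_[3*i+1]  -= k * (gmy + gpy);
      f_[3*i+2]  -= k * (gmz + gpz);
    }
    // non-bonded pairs
    for (size_t p = 0; p < nl_.size(); p += 2) {
      int i = nl_[p], j = nl_[p + 1];
      double dx = x_[3*i] - x_[3*j], dy = x_[3*i+1] - x_[3*j+1], dz = x_[3*i+2] - x_[3*j+2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= pot_.rc2) continue;
      double ff;
      if (inseg_[i] || inseg_[j]) {
        double r = std::sqrt(r2);
        if (r < 1e-12) continue;  // soft potential: zero force at contact
        ff = A_ * M_PI / pot_.rc * std::sin(M_PI * r / pot_.rc) / r;
      } else {
        double s2 = pot_.sigma * pot_.sigma / r2;
        double s6 = s2 * s2 * s2;
        ff = 24.0 * pot_.eps * (2.0 * s6 * s6 - s6) / r2;
      }
      f_[3*i] += ff * dx; f_[3*i+1] += ff * dy; f_[3*i+2] += ff * dz;
      f_[3*j] -= ff * dx; f_[3*j+1] -= ff * dy; f_[3*j+2] -= ff * dz;
    }
  }
};

Pot make_pot(double sigma, double eps, double K, double R0, double lp, double kT) {
  Pot p;
  p.sigma = sigma; p.eps = eps;
  p.rc = std::pow(2.0, 1.0 / 6.0) * sigma;
  p.rc2 = p.rc * p.rc;
  p.K = K; p.R02 = R0 * R0;
  p.kappa = kT > 0 ? kT * lp / sigma : lp / sigma;  // kT=0 runs keep stiffness
  return p;
}

int select_maxcurv(const std::vector<double>& x, int N, int lT) {
  // Eq-5 style window sum of (1 - cos) over lT+1 consecutive joints
  std::vector<double> tx(N), ty(N), tz(N), c(N);
  for (int i = 0; i < N; ++i) {
    int j = (i + 1) % N;
    tx[i] = x[3*j] - x[3*i]; ty[i] = x[3*j+1] - x[3*i+1]; tz[i] = x[3*j+2] - x[3*i+2];
  }
  for (int i = 0; i < N; ++i) {
    int j = (i + 1) % N;
    double ni = std::sqrt(tx[i]*tx[i] + ty[i]*ty[i] + tz[i]*tz[i]);
    double nj = std::sqrt(tx[j]*tx[j] + ty[j]*ty[j] + tz[j]*tz[j]);
    if (ni == 0 || nj == 0) stop("degenerate (zero-length) bond vector");
    c[i] = 1.0 - (tx[i]*tx[j] + ty[i]*ty[j] + tz[i]*tz[j]) / (ni * nj);
  }
  int half = lT / 2;
  double best = -1.0; int besti = 0;
  for (int i = 0; i < N; ++i) {
    double s = 0;
    for (int j = -half; j <= half; ++j) s += c[((i + j) % N + N) % N];
    if (s > best + 1e-15) { best = s; besti = i; }
  }
  return besti;
}

int select_maxdens(const std::vector<double>& x, int N, double R) {
  double R2 = R * R;
  int best = -1, besti = 0;
  for (int i = 0; i < N; ++i) {
    int cnt = 0;
    for (int j = 0; j < N; ++j) {
      double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
      if (dx * dx + dy * dy + dz * dz < R2) ++cnt;  // includes j == i
    }
    if (cnt > best) { best = cnt; besti = i; }
  }
  return besti;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix x, int seg_start, int lT, double A,
                         double sigma, double eps, double K, double R0,
                         double lp, double kT) {
  Pot pot = make_pot(sigma, eps, K, R0, lp, kT);
  Engine e(x, pot, 0.01, 0.0, kT, seg_start - 1, lT, A, 1);
  return e.force_matrix();
}

// [[Rcpp::export]]
List cpp_energies(NumericMatrix x, int seg_start, int lT, double A,
                  double sigma, double eps, double K, double R0,
                  double lp, double kT) {
  Pot pot = make_pot(sigma, eps, K, R0, lp, kT);
  Engine e(x, pot, 0.01, 0.0, kT, seg_start - 1, lT, A, 1);
  double pair, fene, bend;
  e.energies(&pair, &fene, &bend);
  return List::create(_["pair"] = pair, _["fene"] = fene, _["bend"] = bend);
}

// [[Rcpp::export]]
int cpp_select_maxcurv(NumericMatrix x, int lT) {
  std::vector<double> xr(3 * x.nrow());
  for (int i = 0; i < x.nrow(); ++i)
    for (int d = 0; d < 3; ++d) xr[3 * i + d] = x(i, d);
  return select_maxcurv(xr, x.nrow(), lT) + 1;
}

// [[Rcpp::export]]
int cpp_select_maxdens(NumericMatrix x, double R) {
  std::vector<double> xr(3 * x.nrow());
  for (int i = 0; i < x.nrow(); ++i)
    for (int d = 0; d < 3; ++d) xr[3 * i + d] = x(i, d);
  return select_maxdens(xr, x.nrow(), R) + 1;
}

// Full Langevin run with optional in-run segment dynamics.
// mode: 0 static, 1 jump, 2 diffuse, 3 max_curvature, 4 max_density
// seg_start0 is 1-based; lT = 0 means no soft segment (pure LJ ring).
// [[Rcpp::export]]
List cpp_run(NumericMatrix x0, Nullable<NumericMatrix> v0,
             double sigma, double eps, double K, double R0, double lp,
             double dt, double gamma, double kT,
             int mode, int seg_start0, int lT, double A_soft, double A_unbind,
             double k_j, double k_d, double R_dens, int ramp_steps,
             double n_steps_d, int sample_every, int seed) {
  int64_t n_steps = static_cast<int64_t>(n_steps_d);
  Pot pot = make_pot(sigma, eps, K, R0, lp, kT);
  int N = x0.nrow();
  Engine e(x0, pot, dt, gamma, kT,
           ((seg_start0 - 1) % N + N) % N, lT, A_soft,
           static_cast<uint64_t>(seed));
  if (v0.isNotNull()) e.set_velocities(NumericMatrix(v0));
  else e.maxwell_velocities();

  int64_t n_frames = n_steps / sample_every + 1;
  NumericVector frames(static_cast<R_xlen_t>(n_frames) * N * 3);
  frames.attr("dim") = IntegerVector::create(N, 3, static_cast<int>(n_frames));
  NumericVector times(static_cast<int>(n_frames));
  IntegerVector seg_trace(static_cast<int>(n_frames));
  NumericVector amp_trace(static_cast<int>(n_frames));
  NumericMatrix etrace(static_cast<int>(n_frames), 4);
  std::vector<double> ev_time; std::vector<int> ev_old, ev_new;

  // event machinery
  bool jumping = (mode == 1 || mode == 3 || mode == 4);
  int64_t next_event = -1;
  if (jumping && k_j > 0)
    next_event = 1 + static_cast<int64_t>(-std::log(e.rng().unif()) / (k_j * dt));
  int64_t diff_every = -1;
  if (mode == 2 && k_d > 0)
    diff_every = std::max<int64_t>(1, static_cast<int64_t>(std::llround(1.0 / (k_d * dt))));
  bool ramping = false;
  int64_t ramp_end = -1;
  int ramp_extensions = 0;

  int frame = 0;
  auto record = [&](int64_t step) {
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d)
        frames[static_cast<R_xlen_t>(frame) * N * 3 + d * N + i] = e.xraw()[3 * i + d];
    times[frame] = step * dt;
    seg_trace[frame] = e.seg_start() + 1;
    amp_trace[frame] = e.lT() > 0 ? e.amplitude() : NA_REAL;
    double pair, fene, bend;
    e.energies(&pair, &fene, &bend);
    etrace(frame, 0) = pair; etrace(frame, 1) = fene; etrace(frame, 2) = bend;
    etrace(frame, 3) = e.kinetic();
    ++frame;
  };
  record(0);

  for (int64_t s = 1; s <= n_steps; ++s) {
    e.step();
    if (jumping && s == next_event && !ramping) {
      // begin unbinding ramp on the current segment
      ramping = true;
      ramp_extensions = 0;
      ramp_end = s + ramp_steps;
      e.set_segment(e.seg_start(), e.lT(), A_unbind);
    } else if (jumping && ramping && s == ramp_end) {
      if (e.segment_overlapped(e.seg_start(), e.lT()) && ramp_extensions < 50) {
        ramp_end = s + ramp_steps;  // strands not yet expelled: extend
        ++ramp_extensions;
      } else {
        // relocate: target evaluated now, at the moment of the jump
        int old = e.seg_start();
        int ns;
        if (mode == 1) {
          ns = e.rng().below(N);
        } else if (mode == 3) {
          int imc = select_maxcurv(e.xraw(), N, e.lT());
          ns = ((imc - e.lT() / 2) % N + N) % N;
        } else {
          int imd = select_maxdens(e.xraw(), N, R_dens);
          ns = ((imd - e.lT() / 2) % N + N) % N;
        }
        e.set_segment(ns, e.lT(), A_soft);
        ev_time.push_back(s * dt); ev_old.push_back(old + 1); ev_new.push_back(ns + 1);
        ramping = false;
        next_event = s + 1 +
          static_cast<int64_t>(-std::log(e.rng().unif()) / (k_j * dt));
      }
    }
    if (diff_every > 0 && s % diff_every == 0) {
      int old = e.seg_start();
      int dir = (e.rng().unif() < 0.5) ? -1 : 1;
      int ns = ((old + dir) % N + N) % N;
      e.set_segment(ns, e.lT(), A_soft);
      ev_time.push_back(s * dt); ev_old.push_back(old + 1); ev_new.push_back(ns + 1);
    }
    if (s % sample_every == 0) record(s);
  }

  colnames(etrace) = CharacterVector::create("pair", "fene", "bend", "kinetic");
  return List::create(
      _["frames"] = frames,
      _["times"] = times,
      _["seg_start"] = seg_trace,
      _["amplitude"] = amp_trace,
      _["energies"] = etrace,
      _["events"] = DataFrame::create(_["time"] = wrap(ev_time),
                                      _["old_index"] = wrap(ev_old),
                                      _["new_index"] = wrap(ev_new)),
      _["x_final"] = e.coords(),
      _["v_final"] = e.velocities(),
      _["neighbor_rebuilds"] = e.rebuilds());
}
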