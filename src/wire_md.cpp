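// Velocity-Verlet integrator for a minimal flexible 3-site water model in
// cylindrical confinement: Morse O-H stretch, harmonic H-O-H bend,
// O-O Lennard-Jones + site-charge Coulomb between molecules (minimum image
// on the declared periodic axes, no Ewald), and an optional flat-bottom
// harmonic radial wall about the box axis.  Equilibration uses stochastic
// velocity rescaling (CSVR) on the total kinetic energy; production is NVE.
// Units: Angstrom, fs, amu, kcal/mol.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double KCAL2INT = 4.184e-4;   // kcal/mol -> amu A^2/fs^2
static const double KB_KCAL = 1.9872041e-3;
static const double KC = 332.0637;         // Coulomb constant, kcal A/(mol e^2)

struct Params {
  double De, a, r0;          // Morse
  double ang_k, theta0;      // bend
  double lj_eps, lj_sig;     // O-O LJ
  double r_cut;              // shifted-force cutoff for intermolecular terms
  double wall_k, wall_R;     // flat-bottom radial wall
  arma::vec box;             // 3 edge lengths
  arma::uvec periodic;       // 3 flags
};

static inline void min_image(arma::vec::fixed<3>& d, const Params& P) {
  for (int ax = 0; ax < 3; ++ax)
    if (P.periodic[ax]) d[ax] -= P.box[ax] * std::round(d[ax] / P.box[ax]);
}

// fills forces (kcal/mol/A), returns potential energy (kcal/mol)
static double forces(const arma::mat& pos, arma::mat& F, const Params& P,
                     const arma::ivec& mol, const arma::imat& oh,
                     const arma::imat& ang, const arma::vec& q,
                     const arma::uvec& isO) {
  const int n = pos.n_rows;
  F.zeros();
  double V = 0.0;

  // Morse O-H
  for (arma::uword b = 0; b < oh.n_rows; ++b) {
    int o = oh(b, 0), h = oh(b, 1);
    arma::vec::fixed<3> d = (pos.row(h) - pos.row(o)).t();
    min_image(d, P);
    double r = arma::norm(d);
    double ex = std::exp(-P.a * (r - P.r0));
    V += P.De * (1.0 - ex) * (1.0 - ex);
    double dVdr = 2.0 * P.De * P.a * ex * (1.0 - ex);
    arma::vec::fixed<3> f = -dVdr * d / r;
    F.row(h) += f.t();
    F.row(o) -= f.t();
  }

  // harmonic bends (h1, o, h2)
  for (arma::uword b = 0; b < ang.n_rows; ++b) {
    int h1 = ang(b, 0), o = ang(b, 1), h2 = ang(b, 2);
    arma::vec::fixed<3> u = (pos.row(h1) - pos.row(o)).t();
    arma::vec::fixed<3> v = (pos.row(h2) - pos.row(o)).t();
    min_image(u, P); min_image(v, P);
    double nu = arma::norm(u), nv = arma::norm(v);
    double ct = arma::dot(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
    double dVdth = P.ang_k * (th - P.theta0);
    V += 0.5 * P.ang_k * (th - P.theta0) * (th - P.theta0);
    arma::vec::fixed<3> f1 = (dVdth / st) * (v / (nu * nv) - ct * u / (nu * nu));
    arma::vec::fixed<3> f2 = (dVdth / st) * (u / (nu * nv) - ct * v / (nv * nv));
    F.row(h1) += f1.t();
    F.row(h2) += f2.t();
    F.row(o) -= (f1 + f2).t();
  }

  // intermolecular: Coulomb (all site pairs) + LJ (O-O), both with
  // shifted-force truncation at r_cut so force and potential vanish
  // continuously there (required for NVE energy conservation under
  // minimum-image switching)
  const double rc = P.r_cut;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (mol[i] == mol[j]) continue;
      arma::vec::fixed<3> d = (pos.row(i) - pos.row(j)).t();
      min_image(d, P);
      double r2 = arma::dot(d, d);
      if (r2 >= rc * rc) continue;
      double r = std::sqrt(r2);
      double fmag = 0.0;                       // -dV/dr
      if (q[i] != 0.0 && q[j] != 0.0) {
        double qq = KC * q[i] * q[j];
        V += qq * (1.0 / r + r / (rc * rc) - 2.0 / rc);
        fmag += qq * (1.0 / r2 - 1.0 / (rc * rc));
      }
      if (isO[i] && isO[j] && P.lj_eps > 0.0) {
        double sr6 = std::pow(P.lj_sig * P.lj_sig / r2, 3.0);
        double src6 = std::pow(P.lj_sig * P.lj_sig / (rc * rc), 3.0);
        double f_r = 4.0 * P.lj_eps * (12.0 * sr6 * sr6 - 6.0 * sr6) / r;
        double f_rc = 4.0 * P.lj_eps * (12.0 * src6 * src6 - 6.0 * src6) / rc;
        double u_r = 4.0 * P.lj_eps * (sr6 * sr6 - sr6);
        double u_rc = 4.0 * P.lj_eps * (src6 * src6 - src6);
        V += u_r - u_rc + (r - rc) * f_rc;
        fmag += f_r - f_rc;
      }
      arma::vec::fixed<3> f = fmag * d / r;
      F.row(i) += f.t();
      F.row(j) -= f.t();
    }
  }

  // flat-bottom radial wall about the box axis
  if (P.wall_k > 0.0) {
    double cx = 0.5 * P.box[0], cy = 0.5 * P.box[1];
    for (int i = 0; i < n; ++i) {
      double dx = pos(i, 0) - cx, dy = pos(i, 1) - cy;
      double rho = std::sqrt(dx * dx + dy * dy);
      if (rho > P.wall_R) {
        double ex = rho - P.wall_R;
        V += 0.5 * P.wall_k * ex * ex;
        double fmag = -P.wall_k * ex / std::max(rho, 1e-12);
        F(i, 0) += fmag * dx;
        F(i, 1) += fmag * dy;
      }
    }
  }
  return V;
}

static double ekin(const arma::mat& vel, const arma::vec& mass) {
  // kinetic energy in kcal/mol
  double k = 0.0;
  for (arma::uword i = 0; i < vel.n_rows; ++i)
    k += 0.5 * mass[i] * arma::dot(vel.row(i), vel.row(i));
  return k / KCAL2INT;
}

// Bussi stochastic velocity rescaling factor (exact propagation of the
// kinetic-energy distribution); uses R's RNG so runs are seed-reproducible.
static double csvr_alpha2(double K, double Kbar, int Nf, double c) {
  double R1 = norm_rand();
  double S = (Nf > 1) ? 2.0 * R::rgamma(0.5 * (Nf - 1), 1.0) : 0.0;
  double t1 = Kbar / (Nf * K);
  return c + t1 * (1.0 - c) * (R1 * R1 + S) +
         2.0 * R1 * std::sqrt(c * (1.0 - c) * t1);
}

// [[Rcpp::export(name = ".run_md_cpp")]]
List run_md_cpp(arma::mat pos, arma::mat vel, arma::vec mass, arma::vec charge,
                arma::ivec mol, arma::imat oh_bonds, arma::imat angles,
                List params, double dt, int n_steps, int stride,
                bool thermostat, double target_T, double tau_T,
                double vmax) {
  Params P;
  P.De = params["morse_De"]; P.a = params["morse_a"]; P.r0 = params["morse_r0"];
  P.ang_k = params["angle_k"]; P.theta0 = params["angle_theta0"];
  P.lj_eps = params["lj_epsilon_OO"]; P.lj_sig = params["lj_sigma_OO"];
  P.r_cut = params["r_cut"];
  P.wall_k = params["wall_strength"]; P.wall_R = params["wall_radius"];
  P.box = as<arma::vec>(params["box"]);
  P.periodic = as<arma::uvec>(params["periodic"]);

  const int n = pos.n_rows;
  arma::uvec isO(n, arma::fill::zeros);
  for (arma::uword b = 0; b < oh_bonds.n_rows; ++b) isO[oh_bonds(b, 0)] = 1;

  const int Nf = 3 * n;
  const double Kbar = 0.5 * Nf * KB_KCAL * target_T;
  const double c_ts = std::exp(-dt / tau_T);

  arma::mat F(n, 3);
  double V = forces(pos, F, P, mol, oh_bonds, angles, charge, isO);

  int nrec = n_steps / stride + 1;
  arma::cube rpos(n, 3, nrec), rvel(n, 3, nrec);
  arma::vec rekin(nrec), repot(nrec), rtime(nrec);
  int rec = 0;
  rpos.slice(rec) = pos; rvel.slice(rec) = vel;
  rekin[rec] = ekin(vel, mass); repot[rec] = V; rtime[rec] = 0.0;
  ++rec;

  for (int step = 1; step <= n_steps; ++step) {
    // velocity Verlet
    for (int i = 0; i < n; ++i) {
      double am = KCAL2INT / mass[i];
      vel.row(i) += 0.5 * dt * am * F.row(i);
      pos.row(i) += dt * vel.row(i);
    }
    V = forces(pos, F, P, mol, oh_bonds, angles, charge, isO);
    for (int i = 0; i < n; ++i) {
      double am = KCAL2INT / mass[i];
      vel.row(i) += 0.5 * dt * am * F.row(i);
    }
    if (thermostat) {
      double K = ekin(vel, mass);
      if (K > 0) vel *= std::sqrt(std::max(0.0, csvr_alpha2(K, Kbar, Nf, c_ts)));
    }
    double vabs = arma::abs(vel).max();
    if (vabs > vmax)
      stop("integration blow-up at step %d (|v| = %.3g A/fs)", step, vabs);
    if (step % stride == 0) {
      rpos.slice(rec) = pos; rvel.slice(rec) = vel;
      rekin[rec] = ekin(vel, mass); repot[rec] = V; rtime[rec] = step * dt;
      ++rec;
    }
  }
  return List::create(_["positions"] = rpos, _["velocities"] = rvel,
                      _["time"] = rtime, _["ekin"] = rekin, _["epot"] = repot,
                      _["final_pos"] = pos, _["final_vel"] = vel);
}
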