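// Coarse-grained bead-spring peptide model and overdamped Langevin propagator.
// Units: kJ/mol, nm, ps, amu (GROMACS-style internal units).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct ChainPars {
  int n;
  const double *mass, *friction, *charge, *eps, *sigma, *hb, *angle_k, *theta0;
  double bond_k, bond_b0, debye_length, coulomb_ke;
};

ChainPars unpack_chain(const List &chain) {
  ChainPars p;
  NumericVector mass = chain["mass"], fric = chain["friction"],
                q = chain["charge"], eps = chain["lj_epsilon"],
                sig = chain["lj_sigma"], hb = chain["hbond_epsilon"],
                ak = chain["angle_k"], th0 = chain["angle_theta0"];
  p.n = mass.size();
  p.mass = REAL(mass); p.friction = REAL(fric); p.charge = REAL(q);
  p.eps = REAL(eps); p.sigma = REAL(sig); p.hb = REAL(hb);
  p.angle_k = REAL(ak); p.theta0 = REAL(th0);
  p.bond_k = as<double>(chain["bond_k"]);
  p.bond_b0 = as<double>(chain["bond_b0"]);
  p.debye_length = as<double>(chain["debye_length"]);
  p.coulomb_ke = as<double>(chain["coulomb_ke"]);
  return p;
}

// positions stored row-major as x[3*i + d]; forces accumulated in f.
double energy_forces(const ChainPars &p, const double *x, double *f) {
  const int n = p.n;
  double E = 0.0;
  for (int i = 0; i < 3 * n; ++i) f[i] = 0.0;

  // harmonic bonds between consecutive beads
  for (int i = 0; i + 1 < n; ++i) {
    double dx = x[3*i+3] - x[3*i], dy = x[3*i+4] - x[3*i+1],
           dz = x[3*i+5] - x[3*i+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < 1e-6) stop("overlapping beads (bond %d-%d)", i + 1, i + 2);
    double dr = r - p.bond_b0;
    E += 0.5 * p.bond_k * dr * dr;
    double fac = -p.bond_k * dr / r;   // force on bead i+1 along +d
    f[3*i+3] += fac * dx; f[3*i+4] += fac * dy; f[3*i+5] += fac * dz;
    f[3*i]   -= fac * dx; f[3*i+1] -= fac * dy; f[3*i+2] -= fac * dz;
  }

  // harmonic angles, parameters taken from the central bead
  for (int j = 1; j + 1 < n; ++j) {
    double ux = x[3*j-3] - x[3*j], uy = x[3*j-2] - x[3*j+1],
           uz = x[3*j-1] - x[3*j+2];
    double vx = x[3*j+3] - x[3*j], vy = x[3*j+4] - x[3*j+1],
           vz = x[3*j+5] - x[3*j+2];
    double nu = std::sqrt(ux*ux + uy*uy + uz*uz),
           nv = std::sqrt(vx*vx + vy*vy + vz*vz);
    double c = (ux*vx + uy*vy + uz*vz) / (nu * nv);
    if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double dth = th - p.theta0[j];
    double k = p.angle_k[j];
    if (k == 0.0) continue;
    E += 0.5 * k * dth * dth;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8;
    double coef = k * dth / s;         // = dV/dtheta / sin(theta)
    // dc/du and dc/dv
    double dcux = vx/(nu*nv) - c*ux/(nu*nu),
           dcuy = vy/(nu*nv) - c*uy/(nu*nu),
           dcuz = vz/(nu*nv) - c*uz/(nu*nu);
    double dcvx = ux/(nu*nv) - c*vx/(nv*nv),
           dcvy = uy/(nu*nv) - c*vy/(nv*nv),
           dcvz = uz/(nu*nv) - c*vz/(nv*nv);
    // F_i = -dV/dr_i ; dtheta/dc = -1/s
    f[3*j-3] += coef * dcux; f[3*j-2] += coef * dcuy; f[3*j-1] += coef * dcuz;
    f[3*j+3] += coef * dcvx; f[3*j+4] += coef * dcvy; f[3*j+5] += coef * dcvz;
    f[3*j]   -= coef * (dcux + dcvx);
    f[3*j+1] -= coef * (dcuy + dcvy);
    f[3*j+2] -= coef * (dcuz + dcvz);
  }

  // nonbonded: Lennard-Jones + Debye-screened Coulomb for |i - j| >= 3
  for (int i = 0; i < n; ++i) {
    for (int j = i + 3; j < n; ++j) {
      double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
             dz = x[3*i+2] - x[3*j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      double r = std::sqrt(r2);
      if (r < 1e-6) stop("overlapping beads (pair %d-%d)", i + 1, j + 1);
      double epsij = std::sqrt(p.eps[i] * p.eps[j]) +
                     std::sqrt(p.hb[i] * p.hb[j]);
      double sij = 0.5 * (p.sigma[i] + p.sigma[j]);
      double sr2 = sij * sij / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
      E += 4.0 * epsij * (sr12 - sr6);
      double fmag = 4.0 * epsij * (12.0 * sr12 - 6.0 * sr6) / r2; // F/r along d
      if (p.charge[i] != 0.0 && p.charge[j] != 0.0) {
        double pre = p.coulomb_ke * p.charge[i] * p.charge[j] *
                     std::exp(-r / p.debye_length);
        E += pre / r;
        fmag += pre * (1.0 / (r2 * r) + 1.0 / (p.debye_length * r2));
      }
      f[3*i]   += fmag * dx; f[3*i+1] += fmag * dy; f[3*i+2] += fmag * dz;
      f[3*j]   -= fmag * dx; f[3*j+1] -= fmag * dy; f[3*j+2] -= fmag * dz;
    }
  }
  return E;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cg_energy_cpp")]]
List cg_energy_cpp(NumericMatrix pos, List chain) {
  ChainPars p = unpack_chain(chain);
  if (pos.nrow() != p.n || pos.ncol() != 3)
    stop("positions must be an n_residues x 3 matrix");
  std::vector<double> x(3 * p.n), f(3 * p.n);
  for (int i = 0; i < p.n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = pos(i, d);
  double E = energy_forces(p, x.data(), f.data());
  NumericMatrix forces(p.n, 3);
  for (int i = 0; i < p.n; ++i)
    for (int d = 0; d < 3; ++d) forces(i, d) = f[3*i+d];
  return List::create(_["energy"] = E, _["forces"] = forces);
}

//' Overdamped Langevin propagation (Euler-Maruyama), optional constant
//' end-to-end pulling force along the instantaneous bead1 -> beadN axis.
//' Uses the R RNG stream; seed with set.seed() before calling.
//' @noRd
// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(NumericMatrix pos0, List chain, int n_steps, double dt,
                   double kT, double pull_force, bool fix_ends,
                   int record_stride, bool record_positions) {
  ChainPars p = unpack_chain(chain);
  const int n = p.n;
  if (pos0.nrow() != n || pos0.ncol() != 3)
    stop("positions must be an n_residues x 3 matrix");
  if (n_steps < 0 || record_stride < 1) stop("bad step counts");

  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = pos0(i, d);

  std::vector<double> mob(n), noise(n);
  for (int i = 0; i < n; ++i) {
    double mg = p.mass[i] * p.friction[i];
    mob[i] = dt / mg;                       // dt / (m*gamma)
    noise[i] = std::sqrt(2.0 * kT * dt / mg);
  }

  int nrec = n_steps / record_stride + 1;   // includes the initial frame
  NumericVector times(nrec), e2e(nrec);
  NumericVector posrec = record_positions ?
      NumericVector(Dimension(nrec, n, 3)) : NumericVector(0);

  int irec = 0;
  auto record = [&](int step) {
    times[irec] = step * dt;
    double dx = x[3*(n-1)] - x[0], dy = x[3*(n-1)+1] - x[1],
           dz = x[3*(n-1)+2] - x[2];
    e2e[irec] = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (record_positions)
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          posrec[irec + nrec * (i + n * d)] = x[3*i+d];
    ++irec;
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    energy_forces(p, x.data(), f.data());
    if (pull_force != 0.0) {
      double dx = x[3*(n-1)] - x[0], dy = x[3*(n-1)+1] - x[1],
             dz = x[3*(n-1)+2] - x[2];
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r > 1e-12) {
        double fac = pull_force / r;
        f[3*(n-1)] += fac * dx; f[3*(n-1)+1] += fac * dy;
        f[3*(n-1)+2] += fac * dz;
        f[0] -= fac * dx; f[1] -= fac * dy; f[2] -= fac * dz;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (fix_ends && (i == 0 || i == n - 1)) continue;
      for (int d = 0; d < 3; ++d)
        x[3*i+d] += mob[i] * f[3*i+d] + noise[i] * norm_rand();
    }
    if (step % record_stride == 0) {
      record(step);
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e3)
          stop("trajectory diverged (|x| > 1e3 nm); use a smaller dt");
    }
  }

  NumericMatrix final_pos(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) final_pos(i, d) = x[3*i+d];

  List out = List::create(_["times"] = times, _["end_to_end"] = e2e,
                          _["final"] = final_pos,
                          _["positions"] = record_positions ?
                              (SEXP)posrec : R_NilValue);
  return out;
}

//' 1-D overdamped Langevin in a tilted quartic double well
//' U(x) = h ((x/a)^2 - 1)^2 + tilt * x. Returns positions sampled every
//' record_stride steps after a burn-in.
//' @noRd
// [[Rcpp::export(name = ".run_langevin_1d_cpp")]]
NumericVector run_langevin_1d_cpp(double x0, int n_steps, double dt, double kT,
                                  double mgamma, double a, double h,
                                  double tilt, int record_stride,
                                  int burn_in) {
  std::vector<double> out;
  out.reserve(n_steps / record_stride + 1);
  double x = x0;
  double mob = dt / mgamma, noise = std::sqrt(2.0 * kT * dt / mgamma);
  for (int step = 1; step <= n_steps; ++step) {
    double u = x / a;
    double force = -4.0 * h * u * (u * u - 1.0) / a - tilt;
    x += mob * force + noise * norm_rand();
    if (!std::isfinite(x) || std::fabs(x) > 1e3)
      stop("1-D trajectory diverged; use a smaller dt");
    if (step > burn_in && step % record_stride == 0) out.push_back(x);
  }
  return NumericVector(out.begin(), out.end());
}
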