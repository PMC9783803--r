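// Synthetic hydrogen-bridge engines: analytic potentials, velocity-Verlet
// classical MD and staging path-integral MD, both with (massive) Nose-Hoover
// chain thermostats.  Internal units: Angstrom, fs, kcal/mol; masses are
// pre-multiplied on the R side by 1e7/4184 so that 1/2 m v^2 is in kcal/mol.
#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

struct Potential {
  int kind;              // 0 harmonic, 1 double_well, 2 coupled_bridge
  double k_harm, V0, a0, R0, kR, ca, cV;
};

static Potential make_pot(int kind, const List& par) {
  Potential p;
  p.kind   = kind;
  p.k_harm = as<double>(par["k_harm"]);
  p.V0     = as<double>(par["V0"]);
  p.a0     = as<double>(par["a0"]);
  p.R0     = as<double>(par["R0"]);
  p.kR     = as<double>(par["k_R"]);
  p.ca     = as<double>(par["c_a"]);
  p.cV     = as<double>(par["c_V"]);
  return p;
}

// energy at proton coordinate x (from bridge midpoint) and donor-acceptor
// distance R; fills -dV/dx and -dV/dR
static inline double pot_eval(const Potential& p, double x, double R,
                              double& fx, double& fR) {
  switch (p.kind) {
  case 0: {
    fx = -p.k_harm * x; fR = 0.0;
    return 0.5 * p.k_harm * x * x;
  }
  case 1: {
    const double s = (x / p.a0) * (x / p.a0) - 1.0;
    fx = -4.0 * p.V0 * x * s / (p.a0 * p.a0); fR = 0.0;
    return p.V0 * s * s;
  }
  default: {  // coupled bridge: well separation and barrier track R - R0
    const double dR = R - p.R0;
    const double a  = p.a0 + p.ca * dR;
    const double Vb = p.V0 + p.cV * dR;
    if (a <= 1e-3 || Vb < 0)
      stop("configuration error: bridge outside potential domain (a(R) <= 0 or V0(R) < 0)");
    const double s  = (x / a) * (x / a) - 1.0;
    fx = -4.0 * Vb * x * s / (a * a);
    fR = -(p.cV * s * s - 4.0 * Vb * p.ca * x * x * s / (a * a * a) + p.kR * dR);
    return Vb * s * s + 0.5 * p.kR * dR * dR;
  }
  }
}

// [[Rcpp::export]]
List cpp_potential(int kind, List par, NumericVector x, NumericVector R) {
  Potential p = make_pot(kind, par);
  const int n = x.size();
  NumericVector e(n), fx(n), fR(n);
  for (int i = 0; i < n; ++i) {
    double gx, gR;
    e[i] = pot_eval(p, x[i], R[i % R.size()], gx, gR);
    fx[i] = gx; fR[i] = gR;
  }
  return List::create(_["energy"] = e, _["fx"] = fx, _["fR"] = fR);
}

// ---------------------------------------------------------------------------
// Nose-Hoover chain, one chain per degree of freedom ("massive").
// Suzuki-Yoshida 3-term factorization, one cycle per half step.
struct NHChain {
  std::vector<double> v, Q;   // thermostat velocities and masses
  double kT;
  void init(int M, double kT_, double tau) {
    kT = kT_;
    v.assign(M, 0.0);
    Q.assign(M, kT_ * tau * tau);
  }
  // advance chain over interval dt_half, scaling particle velocity vel (mass m)
  void step(double& vel, double m, double dt_half) {
    static const double w[3] = { 1.3512071919596578,
                                -1.7024143839193153,
                                 1.3512071919596578 };
    const int M = (int)v.size();
    double kin = m * vel * vel;
    double scale = 1.0;
    for (int iw = 0; iw < 3; ++iw) {
      const double wdt = w[iw] * dt_half;
      // update thermostat velocities, tail first
      double G = (Q[M - 2] * v[M - 2] * v[M - 2] - kT) / Q[M - 1];
      v[M - 1] += 0.25 * wdt * G;
      for (int j = M - 2; j >= 0; --j) {
        const double ef = std::exp(-0.125 * wdt * v[j + 1]);
        G = (j == 0) ? (kin - kT) / Q[0]
                     : (Q[j - 1] * v[j - 1] * v[j - 1] - kT) / Q[j];
        v[j] = (v[j] * ef + 0.25 * wdt * G) * ef;
      }
      const double s = std::exp(-0.5 * wdt * v[0]);
      scale *= s;
      kin *= s * s;
      // reverse sweep with updated kinetic energy
      for (int j = 0; j <= M - 2; ++j) {
        const double ef = std::exp(-0.125 * wdt * v[j + 1]);
        G = (j == 0) ? (kin - kT) / Q[0]
                     : (Q[j - 1] * v[j - 1] * v[j - 1] - kT) / Q[j];
        v[j] = (v[j] * ef + 0.25 * wdt * G) * ef;
      }
      G = (Q[M - 2] * v[M - 2] * v[M - 2] - kT) / Q[M - 1];
      v[M - 1] += 0.25 * wdt * G;
    }
    vel *= scale;
  }
};

static inline void check_energy(double e, int step) {
  if (!std::isfinite(e) || std::fabs(e) > 1e6)
    stop("integration failure: |E| > 1e6 kcal/mol at step %d", step);
}

// ---------------------------------------------------------------------------
// Classical MD of the bridge: proton coordinate x (mass mx), and for the
// coupled bridge the donor-acceptor distance R (reduced mass mR).
// [[Rcpp::export]]
List cpp_simulate_md(int kind, List par, double mx, double mR,
                     double dt, int n_steps, int stride,
                     double temperature, double kB,
                     bool thermostat, int chain_length, double tau,
                     int seed, double x0, double R_init) {
  Potential p = make_pot(kind, par);
  const bool hasR = (p.kind == 2);
  const double kT = kB * temperature;

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double x = x0, R = hasR ? R_init : p.R0;
  double vx = gauss(rng) * std::sqrt(kT / mx);
  double vR = hasR ? gauss(rng) * std::sqrt(kT / mR) : 0.0;

  NHChain cx, cR;
  if (thermostat) {
    cx.init(chain_length, kT, tau);
    if (hasR) cR.init(chain_length, kT, tau);
  }

  double fx, fR;
  double epot = pot_eval(p, x, R, fx, fR);

  const int n_store = n_steps / stride;
  NumericVector sx(n_store), svx(n_store), sR(n_store), svR(n_store),
                sep(n_store), sek(n_store);
  int is = 0;
  for (int step = 1; step <= n_steps; ++step) {
    if (thermostat) {
      cx.step(vx, mx, 0.5 * dt);
      if (hasR) cR.step(vR, mR, 0.5 * dt);
    }
    vx += 0.5 * dt * fx / mx;
    x  += dt * vx;
    if (hasR) { vR += 0.5 * dt * fR / mR; R += dt * vR; }
    epot = pot_eval(p, x, R, fx, fR);
    vx += 0.5 * dt * fx / mx;
    if (hasR) vR += 0.5 * dt * fR / mR;
    if (thermostat) {
      cx.step(vx, mx, 0.5 * dt);
      if (hasR) cR.step(vR, mR, 0.5 * dt);
    }
    double ekin = 0.5 * mx * vx * vx + (hasR ? 0.5 * mR * vR * vR : 0.0);
    check_energy(epot + ekin, step);
    if (step % stride == 0) {
      sx[is] = x; svx[is] = vx; sR[is] = R; svR[is] = vR;
      sep[is] = epot; sek[is] = ekin; ++is;
    }
  }
  return List::create(_["x"] = sx, _["vx"] = svx, _["R"] = sR, _["vR"] = svR,
                      _["epot"] = sep, _["ekin"] = sek);
}

// ---------------------------------------------------------------------------
// Staging PIMD for the proton coordinate; the heavy coordinate R of the
// coupled bridge stays classical and feels the bead-averaged force.
// Staging variables: u1 = x1, uk = xk - ((k-1) x_{k+1} + x1)/k.
// [[Rcpp::export]]
List cpp_simulate_pimd(int kind, List par, double mx, double mR, int P,
                       double dt, int n_steps, int stride,
                       double temperature, double kB, double hbar,
                       int chain_length, double tau_centroid,
                       int seed, double x0, double R_init) {
  Potential p = make_pot(kind, par);
  const bool hasR = (p.kind == 2);
  const double kT = kB * temperature;
  const double beta = 1.0 / kT;
  const double wP = std::sqrt((double)P) / (beta * hbar);

  // staging masses: mbar[0] = m, mbar[k] = (k+1)/k * m (0-based)
  std::vector<double> mbar(P);
  mbar[0] = mx;
  for (int k = 1; k < P; ++k) mbar[k] = (double)(k + 1) / (double)k * mx;

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> u(P, 0.0), vu(P), fu(P), xb(P), dVdx(P);
  u[0] = x0;
  for (int k = 0; k < P; ++k) vu[k] = gauss(rng) * std::sqrt(kT / mbar[k]);
  double R = hasR ? R_init : p.R0;
  double vR = hasR ? gauss(rng) * std::sqrt(kT / mR) : 0.0;

  std::vector<NHChain> chains(P);
  const double tau_bead = (P > 1) ? 1.0 / wP : tau_centroid;
  chains[0].init(chain_length, kT, tau_centroid);
  for (int k = 1; k < P; ++k) chains[k].init(chain_length, kT, tau_bead);
  NHChain cR;
  if (hasR) cR.init(chain_length, kT, tau_centroid);

  double epot_mean = 0.0;
  // compute bead positions, potential forces on staging variables
  auto forces = [&](double& fRtot) {
    // inverse staging: x_k = u_k + ((k-1)/k) x_{k+1} + u1/k, x_{P+1} = x_1
    if (P > 1) {
      xb[P - 1] = u[P - 1] + u[0];
      for (int k = P - 1; k >= 2; --k)  // 1-based index k
        xb[k - 1] = u[k - 1] + ((double)(k - 1) / k) * xb[k] + u[0] / k;
    }
    xb[0] = u[0];
    double esum = 0.0, fsumR = 0.0;
    for (int k = 0; k < P; ++k) {
      double gx, gR;
      esum += pot_eval(p, xb[k], R, gx, gR);
      dVdx[k] = -gx;           // dV/dx_k
      fsumR += gR;             // -(dV/dR) contribution of bead k
    }
    epot_mean = esum / P;
    fRtot = fsumR / P;
    // potential-force recursion in staging variables
    double sum_all = 0.0;
    for (int k = 0; k < P; ++k) sum_all += dVdx[k];
    std::vector<double> dphi(P);
    dphi[0] = sum_all / P;
    for (int k = 2; k <= P; ++k)      // 1-based
      dphi[k - 1] = dVdx[k - 1] / P +
                    ((double)(k - 2) / (double)(k - 1)) * dphi[k - 2];
    // total staging force: potential + harmonic spring (no spring on u1)
    fu[0] = -dphi[0];
    for (int k = 1; k < P; ++k)
      fu[k] = -dphi[k] - mbar[k] * wP * wP * u[k];
  };

  double fR;
  forces(fR);

  const int n_store = n_steps / stride;
  NumericMatrix beads(n_store, P);
  NumericVector sR(n_store), sep(n_store);
  int is = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < P; ++k) chains[k].step(vu[k], mbar[k], 0.5 * dt);
    if (hasR) cR.step(vR, mR, 0.5 * dt);
    for (int k = 0; k < P; ++k) {
      vu[k] += 0.5 * dt * fu[k] / mbar[k];
      u[k]  += dt * vu[k];
    }
    if (hasR) { vR += 0.5 * dt * fR / mR; R += dt * vR; }
    forces(fR);
    for (int k = 0; k < P; ++k) vu[k] += 0.5 * dt * fu[k] / mbar[k];
    if (hasR) vR += 0.5 * dt * fR / mR;
    for (int k = 0; k < P; ++k) chains[k].step(vu[k], mbar[k], 0.5 * dt);
    if (hasR) cR.step(vR, mR, 0.5 * dt);
    check_energy(epot_mean, step);
    if (step % stride == 0) {
      for (int k = 0; k < P; ++k) beads(is, k) = xb[k];
      sR[is] = R; sep[is] = epot_mean; ++is;
    }
  }
  return List::create(_["beads"] = beads, _["R"] = sR, _["epot_mean"] = sep);
}
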