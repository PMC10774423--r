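#include <Rcpp.h>
using namespace Rcpp;

// Coarse-grained Go potential, energies in kcal/mol, lengths in Angstrom,
// time in ps, masses in amu.  Unit bridge: 1 kcal/mol = 418.4 amu A^2 / ps^2.
//
//   bonds       k (r - r0)^2
//   contacts    eps [ 5 (r0/r)^12 - 6 (r0/r)^10 ]   (minimum -eps at r = r0)
//   repulsion   eps_rep (sigma/r)^12                 (non-native pairs)
//   restraints  k (r - r0)^2                         (Zn-finger surrogate)
//   tethers     k |x - x0|^2                         (absolute position)

static const double KB = 0.0019872;     // kcal/mol/K
static const double KCAL2MD = 418.4;    // kcal/mol -> amu A^2/ps^2

struct CGModel {
  IntegerVector bi, bj; NumericVector br0, bk;
  IntegerVector ci, cj; NumericVector cr0, ceps;
  IntegerVector ri, rj; NumericVector rsig, reps;
  IntegerVector qi, qj; NumericVector qr0, qk;
  IntegerVector ti; NumericMatrix txyz; NumericVector tk;
};

static CGModel unpack(const List& m) {
  CGModel g;
  g.bi = m["bond_i"];  g.bj = m["bond_j"];  g.br0 = m["bond_r0"]; g.bk = m["bond_k"];
  g.ci = m["con_i"];   g.cj = m["con_j"];   g.cr0 = m["con_r0"];  g.ceps = m["con_eps"];
  g.ri = m["rep_i"];   g.rj = m["rep_j"];   g.rsig = m["rep_sigma"]; g.reps = m["rep_eps"];
  g.qi = m["res_i"];   g.qj = m["res_j"];   g.qr0 = m["res_r0"];  g.qk = m["res_k"];
  g.ti = m["teth_i"];  g.txyz = as<NumericMatrix>(m["teth_xyz"]); g.tk = m["teth_k"];
  return g;
}

// energy and (optionally) forces; coords is n x 3
static double eval_potential(const NumericMatrix& x, const CGModel& g,
                             NumericMatrix* force, NumericVector* terms) {
  const int n = x.nrow();
  double e_bond = 0, e_con = 0, e_rep = 0, e_res = 0, e_teth = 0;
  if (force) std::fill(force->begin(), force->end(), 0.0);

  auto pair_force = [&](int i, int j, double coef_over_r, double dx, double dy, double dz) {
    // force on i is -dE/dr * (r_i - r_j)/r = coef_over_r * d
    if (!force) return;
    (*force)(i, 0) += coef_over_r * dx; (*force)(i, 1) += coef_over_r * dy; (*force)(i, 2) += coef_over_r * dz;
    (*force)(j, 0) -= coef_over_r * dx; (*force)(j, 1) -= coef_over_r * dy; (*force)(j, 2) -= coef_over_r * dz;
  };

  for (int k = 0; k < g.bi.size(); ++k) {
    int i = g.bi[k] - 1, j = g.bj[k] - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double d = r - g.br0[k];
    e_bond += g.bk[k] * d * d;
    pair_force(i, j, -2.0 * g.bk[k] * d / r, dx, dy, dz);
  }
  for (int k = 0; k < g.ci.size(); ++k) {
    int i = g.ci[k] - 1, j = g.cj[k] - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double r2 = dx*dx + dy*dy + dz*dz;
    double s2 = g.cr0[k] * g.cr0[k] / r2;       // (r0/r)^2
    double s10 = s2*s2*s2*s2*s2, s12 = s10*s2;
    e_con += g.ceps[k] * (5.0*s12 - 6.0*s10);
    // dE/dr = eps*(-60 s12 + 60 s10)/r ; force coef over r = -dE/dr / r
    double coef = g.ceps[k] * 60.0 * (s12 - s10) / r2;
    pair_force(i, j, coef, dx, dy, dz);
  }
  for (int k = 0; k < g.ri.size(); ++k) {
    int i = g.ri[k] - 1, j = g.rj[k] - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double r2 = dx*dx + dy*dy + dz*dz;
    double sig2 = g.rsig[k] * g.rsig[k];
    if (r2 > 6.25 * sig2) continue;             // negligible beyond 2.5 sigma
    double s2 = sig2 / r2;
    double s12 = s2*s2*s2; s12 *= s12;
    e_rep += g.reps[k] * s12;
    pair_force(i, j, g.reps[k] * 12.0 * s12 / r2, dx, dy, dz);
  }
  for (int k = 0; k < g.qi.size(); ++k) {
    int i = g.qi[k] - 1, j = g.qj[k] - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double d = r - g.qr0[k];
    e_res += g.qk[k] * d * d;
    pair_force(i, j, -2.0 * g.qk[k] * d / r, dx, dy, dz);
  }
  for (int k = 0; k < g.ti.size(); ++k) {
    int i = g.ti[k] - 1;
    double dx = x(i,0)-g.txyz(k,0), dy = x(i,1)-g.txyz(k,1), dz = x(i,2)-g.txyz(k,2);
    e_teth += g.tk[k] * (dx*dx + dy*dy + dz*dz);
    if (force) {
      (*force)(i,0) -= 2.0*g.tk[k]*dx; (*force)(i,1) -= 2.0*g.tk[k]*dy; (*force)(i,2) -= 2.0*g.tk[k]*dz;
    }
  }
  (void)n;
  if (terms) {
    (*terms)[0] = e_bond; (*terms)[1] = e_con; (*terms)[2] = e_rep;
    (*terms)[3] = e_res;  (*terms)[4] = e_teth;
  }
  return e_bond + e_con + e_rep + e_res + e_teth;
}

// [[Rcpp::export]]
List cg_energy_cpp(NumericMatrix coords, List model, bool forces = false) {
  CGModel g = unpack(model);
  NumericMatrix f;
  NumericVector terms(5);
  terms.names() = CharacterVector::create("bond", "contact", "repulsion", "restraint", "tether");
  double e;
  if (forces) {
    f = NumericMatrix(coords.nrow(), 3);
    e = eval_potential(coords, g, &f, &terms);
  } else {
    e = eval_potential(coords, g, nullptr, &terms);
  }
  List out = List::create(_["energy"] = e, _["terms"] = terms);
  if (forces) out["forces"] = f;
  return out;
}

// BAOAB Langevin integrator.  Uses R's RNG (set.seed upstream controls it).
// Records coordinates and potential energy every `stride` steps (step
// multiples of stride, counting from 1).  temp in K, gamma in 1/ps, dt in ps.
// [[Rcpp::export]]
List cg_langevin_cpp(NumericMatrix coords, NumericMatrix vel, List model,
                     double mass, double dt, double gamma, double temp,
                     int n_steps, int stride) {
  CGModel g = unpack(model);
  const int n = coords.nrow();
  NumericMatrix x = clone(coords), v = clone(vel);
  NumericMatrix f(n, 3);
  double pe = eval_potential(x, g, &f, nullptr);
  if (!std::isfinite(pe)) stop("non-finite potential energy at start of run");

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const double sigma_v = std::sqrt(KB * temp * KCAL2MD / mass);
  const double acc = KCAL2MD / mass;      // F (kcal/mol/A) -> A/ps^2
  const double hdt = 0.5 * dt;

  int n_rec = (stride > 0) ? n_steps / stride : 0;
  NumericVector frames(n_rec > 0 ? (R_xlen_t)n_rec * n * 3 : 0);
  NumericVector energies(n_rec > 0 ? n_rec : 0);
  int rec = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v(i,d) += hdt * acc * f(i,d);
    // A: half drift
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) x(i,d) += hdt * v(i,d);
    // O: friction + noise
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v(i,d) = c1 * v(i,d) + c2 * sigma_v * norm_rand();
    // A: half drift
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) x(i,d) += hdt * v(i,d);
    // B: half kick with new forces
    pe = eval_potential(x, g, &f, nullptr);
    if (!std::isfinite(pe))
      stop("non-finite potential energy at step %d", step);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v(i,d) += hdt * acc * f(i,d);

    if (stride > 0 && step % stride == 0) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(R_xlen_t)rec + (R_xlen_t)n_rec * (i + (R_xlen_t)n * d)] = x(i,d);
      energies[rec] = pe;
      ++rec;
    }
  }

  List out = List::create(_["coords"] = x, _["vel"] = v, _["potential"] = pe,
                          _["energies"] = energies);
  if (n_rec > 0) {
    frames.attr("dim") = IntegerVector::create(n_rec, n, 3);
    out["frames"] = frames;
  }
  return out;
}
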