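#include <Rcpp.h>
using namespace Rcpp;

// Analytic toy potentials, kcal/mol; coordinates in Angstrom.
//  id 1: 1D double well      U = h (x^2 - 1)^2 + tilt * x
//  id 2: 2D double basin     U = h (x^2 - 1)^2 + tilt * x + 0.5 ky * y^2
static double toy_potential(int id, double h, double tilt, double ky,
                            const double *x, int d) {
  double s = x[0] * x[0] - 1.0;
  double u = h * s * s + tilt * x[0];
  if (id == 2 && d == 2) u += 0.5 * ky * x[1] * x[1];
  return u;
}

static void toy_force(int id, double h, double tilt, double ky,
                      const double *x, int d, double *f) {
  f[0] = -(4.0 * h * x[0] * (x[0] * x[0] - 1.0) + tilt);
  if (d == 2) f[1] = (id == 2) ? -ky * x[1] : 0.0;
}

// BAOAB Langevin integration with optional aMD boost on the total potential:
// when V < E the conservative force is scaled by alpha^2 / (alpha + E - V)^2,
// the derivative of the boosted potential w.r.t. the raw one. Positions are
// recorded every `stride` steps together with the raw potential V and the
// boost deltaV. Uses R's RNG so seeding is controlled from R.
// [[Rcpp::export(name = ".langevinBAOAB")]]
List langevinBAOAB(NumericVector x0, int nSteps, double dt, int stride,
                   double mass, double friction, double kT,
                   int potId, double h, double tilt, double ky,
                   bool boost, double E, double alpha, double guard) {
  int d = x0.size();
  if (d < 1 || d > 2) stop("toy dimension must be 1 or 2");
  int nOut = nSteps / stride;
  NumericMatrix samples(nOut, d);
  NumericVector Vout(nOut), dVout(nOut);

  double x[2] = {0.0, 0.0}, v[2] = {0.0, 0.0}, f[2] = {0.0, 0.0};
  for (int k = 0; k < d; ++k) x[k] = x0[k];

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(kT / mass * (1.0 - c1 * c1));

  double V = toy_potential(potId, h, tilt, ky, x, d);
  toy_force(potId, h, tilt, ky, x, d, f);
  double fac = 1.0;
  if (boost && V < E) {
    double aev = alpha + E - V;
    fac = alpha * alpha / (aev * aev);
  }

  int iout = 0;
  for (int step = 1; step <= nSteps; ++step) {
    for (int k = 0; k < d; ++k) v[k] += 0.5 * dt * fac * f[k] / mass;
    for (int k = 0; k < d; ++k) x[k] += 0.5 * dt * v[k];
    for (int k = 0; k < d; ++k) v[k] = c1 * v[k] + c2 * norm_rand();
    for (int k = 0; k < d; ++k) x[k] += 0.5 * dt * v[k];

    V = toy_potential(potId, h, tilt, ky, x, d);
    toy_force(potId, h, tilt, ky, x, d, f);
    fac = 1.0;
    double dV = 0.0;
    if (boost && V < E) {
      double aev = alpha + E - V;
      fac = alpha * alpha / (aev * aev);
      dV = (E - V) * (E - V) / aev;
    }
    for (int k = 0; k < d; ++k) v[k] += 0.5 * dt * fac * f[k] / mass;

    if (std::abs(x[0]) > guard || (d == 2 && std::abs(x[1]) > guard))
      stop("Langevin integration diverged at step %d (|x| > %.1f); "
           "reduce dt or check the potential parameters", step, guard);

    if (step % stride == 0) {
      for (int k = 0; k < d; ++k) samples(iout, k) = x[k];
      Vout[iout] = V;
      dVout[iout] = dV;
      ++iout;
    }
  }
  return List::create(_["samples"] = samples, _["V"] = Vout,
                      _["deltaV"] = dVout);
}
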