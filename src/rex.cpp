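#include <Rcpp.h>
using namespace Rcpp;

static const double R_KCAL = 1.9872e-3; // kcal/(mol K)
static const double DEG_PER_RAD_CONV = M_PI / 180.0;

// V(phi) = sum_j (Vn_j/2) * (1 + cos(n_j*phi - gamma_j)), phi/gamma degrees
static inline double potential(double phi,
                               const NumericVector &n,
                               const NumericVector &Vn,
                               const NumericVector &gamma) {
  double v = 0.0;
  for (int j = 0; j < n.size(); ++j)
    v += 0.5 * Vn[j] * (1.0 + std::cos((n[j] * phi - gamma[j]) * DEG_PER_RAD_CONV));
  return v;
}

static inline double wrapDeg(double x) {
  x -= 360.0 * std::floor((x + 180.0) / 360.0);
  if (x >= 180.0) x -= 360.0;
  return x;
}

// Metropolis sampling of a 1-torsion potential on a replica ladder with
// neighbor swaps every exchange_interval sweeps. Uses R's RNG stream, so
// set.seed() on the R side makes runs bit-identical. Draw order is fixed:
// per sweep, one proposal + one acceptance draw per replica (ascending
// temperature slot), then at exchange sweeps one draw per neighbor pair.
// [[Rcpp::export]]
List rex_sample_cpp(NumericVector n, NumericVector Vn, NumericVector gamma,
                    NumericVector temps, int sweeps, double startDeg,
                    double stepDeg, int exchangeInterval) {
  const int m = temps.size();
  NumericMatrix angles(sweeps, m);
  IntegerMatrix walkers(sweeps, m);
  std::vector<double> phi(m, wrapDeg(startDeg));
  std::vector<double> energy(m);
  std::vector<int> walker(m);
  std::vector<double> beta(m);
  for (int i = 0; i < m; ++i) {
    energy[i] = potential(phi[i], n, Vn, gamma);
    walker[i] = i + 1;
    beta[i] = 1.0 / (R_KCAL * temps[i]);
  }
  std::vector<int> logSweep, logPair, logAcc;

  RNGScope scope;
  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < m; ++i) {
      double prop = wrapDeg(phi[i] + (unif_rand() * 2.0 - 1.0) * stepDeg);
      double eProp = potential(prop, n, Vn, gamma);
      double dE = eProp - energy[i];
      double u = unif_rand();
      if (dE <= 0.0 || u < std::exp(-beta[i] * dE)) {
        phi[i] = prop;
        energy[i] = eProp;
      }
    }
    if (exchangeInterval > 0 && ((s + 1) % exchangeInterval == 0) && m > 1) {
      for (int p = 0; p < m - 1; ++p) {
        double arg = (beta[p] - beta[p + 1]) * (energy[p] - energy[p + 1]);
        double u = unif_rand();
        int acc = (arg >= 0.0 || u < std::exp(arg)) ? 1 : 0;
        if (acc) {
          std::swap(phi[p], phi[p + 1]);
          std::swap(energy[p], energy[p + 1]);
          std::swap(walker[p], walker[p + 1]);
        }
        logSweep.push_back(s + 1);
        logPair.push_back(p + 1);
        logAcc.push_back(acc);
      }
    }
    for (int i = 0; i < m; ++i) {
      angles(s, i) = phi[i];
      walkers(s, i) = walker[i];
    }
  }
  return List::create(
      _["angles"] = angles, _["walkers"] = walkers,
      _["exchange_sweep"] = wrap(logSweep), _["exchange_pair"] = wrap(logPair),
      _["exchange_accepted"] = wrap(logAcc));
}

// [[Rcpp::export]]
NumericVector torsion_potential_cpp(NumericVector phi, NumericVector n,
                                    NumericVector Vn, NumericVector gamma) {
  NumericVector out(phi.size());
  for (int i = 0; i < phi.size(); ++i)
    out[i] = potential(phi[i], n, Vn, gamma);
  return out;
}
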