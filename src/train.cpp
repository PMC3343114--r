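#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// rule codes: 0 standard, 1 bistable with error-driven state switching
// (previous *target* is the reference state), 2 no-state-switching control
// (the unit carries its own previous output, sequential sweeps).
//
// Patterns are stored as per-pattern lists of active input indices, so a
// drive costs O(f N) and silent inputs are never touched.  After every
// epoch all P constraints are evaluated exactly; zero violations means
// the sequence is learned.  The per-epoch trace records that exact count.

static inline bool satisfied(double h, int y, double the, double ks) {
  if (y == 1) return h > the + ks;
  return h <= the - ks;
}

// [[Rcpp::export(name = ".train_cpp")]]
List train_cpp(const IntegerMatrix& Xt,   // N x P, pattern mu in column mu
               const IntegerVector& y,
               double theta, double delta, double kappa, double eta,
               int rule, int max_epochs, bool sequential, bool constrained) {
  const int N = Xt.nrow(), P = Xt.ncol();
  std::vector<int> start(P + 1, 0);
  std::vector<int> act;                    // concatenated active index lists
  act.reserve((size_t)N * P / 2);
  for (int mu = 0; mu < P; ++mu) {
    const int* col = &Xt[(R_xlen_t)mu * N];
    for (int i = 0; i < N; ++i) if (col[i]) act.push_back(i);
    start[mu + 1] = (int)act.size();
  }

  std::vector<double> w(N, 0.0);           // start from silent synapses
  double sumw2 = 0.0;
  const double thUp = theta + delta / 2.0, thDn = theta - delta / 2.0;
  double updates = 0.0;
  bool conv = false;
  int epochs_used = 0, finalErr = -1;
  std::vector<double> errTrace;

  auto driveOf = [&](int mu) {
    double h = 0.0;
    for (int k = start[mu]; k < start[mu + 1]; ++k) h += w[act[k]];
    return h;
  };
  auto kmargin = [&]() {
    return kappa > 0.0 ? kappa * std::sqrt(sumw2 / N) : 0.0;
  };
  auto thetaEff = [&](int mu) {
    if (rule == 0 || delta == 0.0) return theta;
    if (mu == 0) return theta;               // midpoint rule, no predecessor
    return y[mu - 1] == 1 ? thDn : thUp;
  };
  auto applyStep = [&](int mu, int dir) {    // dir = y - yhat in {-1, +1}
    const double d = eta * dir;
    for (int k = start[mu]; k < start[mu + 1]; ++k) {
      const int i = act[k];
      double old = w[i], nw = old + d;
      if (constrained && nw < 0.0) nw = 0.0;
      sumw2 += nw * nw - old * old;
      w[i] = nw;
    }
    updates += 1.0;
  };
  // exact evaluation of the learned-sequence criterion
  auto evaluate = [&]() {
    int err = 0;
    if (rule == 2) {                         // free-run replay
      int state = 0;
      for (int mu = 0; mu < P; ++mu) {
        double h = driveOf(mu);
        double up = (mu == 0) ? theta : thUp;
        double dn = (mu == 0) ? theta : thDn;
        int out = (state == 0) ? (h > up ? 1 : 0) : (h < dn ? 0 : 1);
        if (out != y[mu]) ++err;
        state = out;
      }
    } else {
      const double ks = kmargin();
      for (int mu = 0; mu < P; ++mu)
        if (!satisfied(driveOf(mu), y[mu], thetaEff(mu), ks)) ++err;
    }
    return err;
  };

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    epochs_used = epoch;
    if (rule == 2) {
      int state = 0;
      for (int mu = 0; mu < P; ++mu) {
        double h = driveOf(mu);
        double up = (mu == 0) ? theta : thUp;
        double dn = (mu == 0) ? theta : thDn;
        int out = (state == 0) ? (h > up ? 1 : 0) : (h < dn ? 0 : 1);
        if (out != y[mu]) applyStep(mu, y[mu] - out);
        state = out;                         // error signal never resets it
      }
    } else {
      for (int t = 0; t < P; ++t) {
        int mu = sequential ? t : (int)std::floor(unif_rand() * P);
        if (mu >= P) mu = P - 1;
        double h = driveOf(mu);
        if (!satisfied(h, y[mu], thetaEff(mu), kmargin()))
          applyStep(mu, y[mu] == 1 ? 1 : -1);
      }
    }
    int err = evaluate();
    errTrace.push_back((double)err);
    finalErr = err;
    if (err == 0) { conv = true; break; }
  }

  return List::create(
    _["weights"] = NumericVector(w.begin(), w.end()),
    _["converged"] = conv,
    _["updates"] = updates,
    _["epochs"] = epochs_used,
    _["final_errors"] = finalErr,
    _["error_trace"] = NumericVector(errTrace.begin(), errTrace.end()));
}
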