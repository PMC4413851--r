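#include <Rcpp.h>
using namespace Rcpp;

// Factored gradient-descent trainer for the threshold-linear network.
//
// With fixed sensory weights the population activity takes only C
// distinct values (one per task condition), so every rank-1 update
// eta * g %*% t(A_c) lives in the span of the C activity columns and
// W can be carried exactly as W = G %*% t(Act) with G of size
// n_muscles x C.  Muscle drive for condition c is then
// W %*% Act[, c] = G %*% Gram[, c] with Gram = crossprod(Act).
// The trajectory is algebraically identical to the direct update; an
// R-level direct implementation backs the equivalence tests.
//
// Arguments:
//   gram      C x C Gram matrix of the activity columns
//   silent    length-C flag: condition produced no activity (skip update)
//   proj      2 x n_muscles x n_post projection array, flattened
//   targets   2 x K target matrix
//   k, kp     1-based per-trial target / posture indices
//   eta, lambda  learning parameters
// Returns: list(error = per-trial squared error, G = factored weights).
// [[Rcpp::export(name = ".train_factored_cpp")]]
List train_factored_cpp(NumericMatrix gram, LogicalVector silent,
                        NumericVector proj, int n_muscles, int n_post,
                        NumericMatrix targets, IntegerVector k,
                        IntegerVector kp, double eta, double lambda) {
  const int C = gram.ncol();
  const int K = targets.ncol();
  const int T = k.size();
  const int NM = n_muscles;

  NumericMatrix G(NM, C);
  NumericVector err(T);
  std::vector<double> u(NM), M(NM), g(NM);

  for (int t = 0; t < T; ++t) {
    const int kt = k[t] - 1;
    const int kpt = kp[t] - 1;
    const int cc = kpt * K + kt;
    const double vx = targets(0, kt), vy = targets(1, kt);

    if (silent[cc]) {  // no active neuron: no movement, no update
      err[t] = vx * vx + vy * vy;
      continue;
    }

    // muscle drive u = G %*% Gram[, cc]; rectified muscle activity M
    double x = 0.0, y = 0.0;
    for (int m = 0; m < NM; ++m) {
      double s = 0.0;
      for (int c = 0; c < C; ++c) s += G(m, c) * gram(c, cc);
      u[m] = s;
      M[m] = s > 0.0 ? s : 0.0;
      const double px = proj[0 + 2 * (m + NM * kpt)];
      const double py = proj[1 + 2 * (m + NM * kpt)];
      x += px * M[m];
      y += py * M[m];
    }
    const double ex = vx - x, ey = vy - y;
    err[t] = ex * ex + ey * ey;

    // gradient step: rows of W for muscles at or above the rectification
    // kink (u >= 0) receive eta * (P^T e - lambda * M); in factored form
    // only column cc of G moves.
    for (int m = 0; m < NM; ++m) {
      if (u[m] >= 0.0) {
        const double px = proj[0 + 2 * (m + NM * kpt)];
        const double py = proj[1 + 2 * (m + NM * kpt)];
        G(m, cc) += eta * (px * ex + py * ey - lambda * M[m]);
      }
    }
  }
  return List::create(_["error"] = err, _["G"] = G);
}
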