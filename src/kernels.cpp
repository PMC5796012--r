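// Scoring kernels: Fitch parsimony and Felsenstein pruning likelihood.
// Trees arrive as postorder edge lists (children before parents), tips as
// 4-bit state masks over (A, C, G, T) per site pattern.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
int fitch_count(IntegerMatrix edge, int n_tip, int n_node,
                IntegerMatrix tip_masks, IntegerVector weights) {
  const int npat = tip_masks.ncol();
  const int ne = edge.nrow();
  std::vector<int> state((size_t)n_node * npat, 0);
  std::vector<bool> seen(n_node, false);
  std::vector<int> changes(npat, 0);

  for (int i = 0; i < n_tip; ++i)
    for (int k = 0; k < npat; ++k)
      state[(size_t)i * npat + k] = tip_masks(i, k);

  for (int e = 0; e < ne; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    int *sp = &state[(size_t)p * npat];
    const int *sc = &state[(size_t)c * npat];
    if (!seen[p]) {
      for (int k = 0; k < npat; ++k) sp[k] = sc[k];
      seen[p] = true;
    } else {
      for (int k = 0; k < npat; ++k) {
        const int a = sp[k] & sc[k];
        if (a == 0) { sp[k] = sp[k] | sc[k]; ++changes[k]; }
        else sp[k] = a;
      }
    }
  }
  long total = 0;
  for (int k = 0; k < npat; ++k) total += (long)changes[k] * weights[k];
  return (int)total;
}

// [[Rcpp::export]]
double pruning_loglik(IntegerMatrix edge, int n_tip, int n_node,
                      NumericVector edge_length, IntegerMatrix tip_masks,
                      IntegerVector weights, NumericMatrix U,
                      NumericMatrix Uinv, NumericVector lambda,
                      NumericVector pi, NumericVector rates) {
  const int npat = tip_masks.ncol();
  const int ne = edge.nrow();
  const int ncat = rates.size();
  const int root = edge(ne - 1, 0) - 1;

  // per-pattern per-category log site likelihood
  std::vector<double> ll((size_t)npat * ncat);
  std::vector<double> partial((size_t)n_node * 4 * npat);
  std::vector<bool> seen(n_node);
  std::vector<double> logscale(npat);

  for (int cat = 0; cat < ncat; ++cat) {
    const double r = rates[cat];
    std::fill(seen.begin(), seen.end(), false);
    std::fill(logscale.begin(), logscale.end(), 0.0);

    for (int i = 0; i < n_tip; ++i) {
      double *pt = &partial[(size_t)i * 4 * npat];
      for (int k = 0; k < npat; ++k) {
        const int m = tip_masks(i, k);
        for (int s = 0; s < 4; ++s) pt[s * npat + k] = (m >> s) & 1 ? 1.0 : 0.0;
      }
    }

    for (int e = 0; e < ne; ++e) {
      const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      // P = U diag(exp(lambda r t)) Uinv, clamped at 0 against round-off
      double P[4][4];
      double ev[4];
      for (int m = 0; m < 4; ++m) ev[m] = std::exp(lambda[m] * r * edge_length[e]);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int m = 0; m < 4; ++m) s += U(i, m) * ev[m] * Uinv(m, j);
          P[i][j] = s > 0.0 ? s : 0.0;
        }
      double *pc = &partial[(size_t)c * 4 * npat];
      // rescale completed internal children to avoid underflow
      if (c >= n_tip) {
        for (int k = 0; k < npat; ++k) {
          double mx = pc[k];
          for (int s = 1; s < 4; ++s)
            if (pc[s * npat + k] > mx) mx = pc[s * npat + k];
          if (mx > 0.0 && mx != 1.0) {
            const double inv = 1.0 / mx;
            for (int s = 0; s < 4; ++s) pc[s * npat + k] *= inv;
            logscale[k] += std::log(mx);
          }
        }
      }
      double *pp = &partial[(size_t)p * 4 * npat];
      if (!seen[p]) {
        for (int i = 0; i < 4; ++i)
          for (int k = 0; k < npat; ++k) {
            double s = 0.0;
            for (int j = 0; j < 4; ++j) s += P[i][j] * pc[j * npat + k];
            pp[i * npat + k] = s;
          }
        seen[p] = true;
      } else {
        for (int i = 0; i < 4; ++i)
          for (int k = 0; k < npat; ++k) {
            double s = 0.0;
            for (int j = 0; j < 4; ++j) s += P[i][j] * pc[j * npat + k];
            pp[i * npat + k] *= s;
          }
      }
    }

    const double *pr = &partial[(size_t)root * 4 * npat];
    for (int k = 0; k < npat; ++k) {
      double s = 0.0;
      for (int i = 0; i < 4; ++i) s += pi[i] * pr[i * npat + k];
      ll[(size_t)k * ncat + cat] =
        (s > 0.0 ? std::log(s) : R_NegInf) + logscale[k];
    }
  }

  // average site likelihood over categories (equal weights), in log space
  const double logncat = std::log((double)ncat);
  double total = 0.0;
  for (int k = 0; k < npat; ++k) {
    const double *lk = &ll[(size_t)k * ncat];
    double mx = lk[0];
    for (int c = 1; c < ncat; ++c) if (lk[c] > mx) mx = lk[c];
    if (!std::isfinite(mx)) return R_NegInf;
    double s = 0.0;
    for (int c = 0; c < ncat; ++c) s += std::exp(lk[c] - mx);
    total += weights[k] * (mx + std::log(s) - logncat);
  }
  return total;
}
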