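#include <Rcpp.h>
using namespace Rcpp;

// Does the binary matrix contain any 2x2 checkerboard submatrix?
// A chain without one is frozen (no move can ever be accepted).
// [[Rcpp::export]]
bool has_checkerboard(const IntegerMatrix& x) {
  const int nr = x.nrow(), nc = x.ncol();
  for (int i = 0; i < nr - 1; ++i) {
    for (int j = i + 1; j < nr; ++j) {
      bool seen10 = false, seen01 = false;
      for (int c = 0; c < nc; ++c) {
        const int a = x(i, c), b = x(j, c);
        if (a == 1 && b == 0) seen10 = true;
        else if (a == 0 && b == 1) seen01 = true;
        if (seen10 && seen01) return true;
      }
    }
  }
  return false;
}

// SIM9 (fixed-fixed) swap chain: repeatedly pick a random pair of rows and
// pair of columns; if the 2x2 submatrix is a checkerboard, flip it. Row and
// column sums are invariant under every move. The proposal is symmetric, so
// the chain indexed by ATTEMPTS (not accepted swaps) is uniform over the
// fixed-marginal state space; burn_in and thin therefore count attempts.
// Sampling at accepted-swap counts would instead weight each state by its
// number of swappable submatrices. Uses R's RNG (seed from R).
// [[Rcpp::export]]
List sim9_chain(IntegerMatrix x, int n_null, double burn_in, double thin) {
  const int nr = x.nrow(), nc = x.ncol();
  if (nr < 2 || nc < 2) stop("need at least a 2x2 matrix");
  if (thin < 1) stop("thin must be >= 1");
  if (burn_in < 0) stop("burn_in must be >= 0");
  IntegerMatrix m = clone(x);
  List out(n_null);
  long long attempts = 0;
  int emitted = 0;
  const long long bi = (long long)burn_in, th = (long long)thin;
  while (emitted < n_null) {
    const int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1)); if (r2 >= r1) ++r2;
    const int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1)); if (c2 >= c1) ++c2;
    const int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
    if (a == d && b == c && a != b) {
      m(r1, c1) = b; m(r1, c2) = a; m(r2, c1) = d; m(r2, c2) = c;
    }
    ++attempts;
    if (attempts > bi && (attempts - bi) % th == 0)
      out[emitted++] = clone(m);
  }
  return out;
}
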