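// Compiled kernels for the pairwise structural aligner: the exhaustive
// gapless seed-window scan and the affine-gap dynamic program.  Everything
// else (score matrices, superposition, iteration control) lives in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// rmsd of the optimal proper superposition of two paired point sets,
// via the closed form Ga + Gb - 2*(s1 + s2 + sign*s3).
static double window_rmsd(const arma::mat& A, const arma::mat& B,
                          int ia, int ib, int w) {
  arma::mat a = A.rows(ia, ia + w - 1);
  arma::mat b = B.rows(ib, ib + w - 1);
  arma::rowvec ca = arma::mean(a, 0), cb = arma::mean(b, 0);
  a.each_row() -= ca;
  b.each_row() -= cb;
  arma::mat C = b.t() * a;           // 3x3 cross-covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, C)) return arma::datum::inf;
  double sgn = (arma::det(U) * arma::det(V) < 0.0) ? -1.0 : 1.0;
  double D = s(0) + s(1) + sgn * s(2);
  double msd = (arma::accu(a % a) + arma::accu(b % b) - 2.0 * D) / w;
  return msd > 0.0 ? std::sqrt(msd) : 0.0;
}

// Exhaustive scan over all gapless window pairs of length w; returns the
// 1-based window starts with minimal superposition rmsd (ties: first in
// row-major scan order, deterministic).
// [[Rcpp::export(name = ".seed_scan_cpp")]]
List seed_scan_cpp(const arma::mat& A, const arma::mat& B, int w) {
  const int na = A.n_rows, nb = B.n_rows;
  if (na < w || nb < w)
    stop("structures shorter than the seed window");
  double best = arma::datum::inf;
  int bi = -1, bj = -1;
  for (int i = 0; i + w <= na; ++i) {
    for (int j = 0; j + w <= nb; ++j) {
      double r = window_rmsd(A, B, i, j, w);
      if (r < best) { best = r; bi = i; bj = j; }
    }
  }
  return List::create(_["i"] = bi + 1, _["j"] = bj + 1, _["rmsd"] = best);
}

// Alignment with affine gaps over a similarity matrix S (higher =
// better; strongly negative cells are effectively forbidden).  The
// matched span is global (gaps are penalized inside it) but both ends are
// free: the path may start and end anywhere, so diverged termini and
// family-specific decorations are skipped without cost.  Traceback ties
// prefer diagonal, then up (gap consuming rows), then left.  Returns the
// matched index pairs, 1-based, strictly increasing in both columns.
// [[Rcpp::export(name = ".gotoh_semiglobal_cpp")]]
IntegerMatrix gotoh_semiglobal_cpp(const NumericMatrix& S,
                                   double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e300;
  // M: end in match; X: end in gap consuming rows; Y: gap consuming cols.
  arma::mat M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  arma::imat tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);
  M.fill(NEG); X.fill(NEG); Y.fill(NEG);
  tbM.zeros(); tbX.zeros(); tbY.zeros();
  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // match state: fresh start (0) or predecessor at (i-1, j-1)
      double bestp = 0.0; int tb = 0;
      double pm = M(i - 1, j - 1), px = X(i - 1, j - 1),
             py = Y(i - 1, j - 1);
      if (pm > bestp) { bestp = pm; tb = 1; }
      if (px > bestp) { bestp = px; tb = 2; }
      if (py > bestp) { bestp = py; tb = 3; }
      M(i, j) = S(i - 1, j - 1) + bestp;
      tbM(i, j) = tb;
      // vertical gap (consume row i); gap-to-gap transitions pay a
      // fresh open so unmatched stretches of both chains can be skipped
      double xm = M(i - 1, j) - gap_open, xx = X(i - 1, j) - gap_extend,
             xy = Y(i - 1, j) - gap_open;
      double bx = xm; int tx = 1;
      if (xx > bx) { bx = xx; tx = 2; }
      if (xy > bx) { bx = xy; tx = 3; }
      X(i, j) = bx; tbX(i, j) = tx;
      // horizontal gap (consume column j)
      double ym = M(i, j - 1) - gap_open, yx = X(i, j - 1) - gap_open,
             yy = Y(i, j - 1) - gap_extend;
      double by = ym; int ty = 1;
      if (yx > by) { by = yx; ty = 2; }
      if (yy > by) { by = yy; ty = 3; }
      Y(i, j) = by; tbY(i, j) = ty;
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }
  if (bi < 0 || best <= 0.0)
    return IntegerMatrix(0, 2);
  std::vector<int> ia, ib;
  int i = bi, j = bj, state = 1;  // 1 = M, 2 = X, 3 = Y, 0 = start
  while (i > 0 && j > 0 && state != 0) {
    if (state == 1) {
      ia.push_back(i); ib.push_back(j);
      state = tbM(i, j);
      --i; --j;
    } else if (state == 2) {
      state = tbX(i, j);
      --i;
    } else {
      state = tbY(i, j);
      --j;
    }
  }
  const int k = (int)ia.size();
  IntegerMatrix out(k, 2);
  for (int q = 0; q < k; ++q) {   // reverse into ascending order
    out(q, 0) = ia[k - 1 - q];
    out(q, 1) = ib[k - 1 - q];
  }
  return out;
}
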