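// Early-exit Hausdorff scan: for each point of one set, the inner minimum
// search is abandoned as soon as it drops below the running maximum, since
// such a point can no longer raise the directed distance. Identical result
// to the dense brute-force double-max, typically far fewer distance
// evaluations.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static double directed_max_min(const Rcpp::NumericMatrix& A,
                               const Rcpp::NumericMatrix& B) {
  double best = 0.0;
  for (int i = 0; i < A.nrow(); ++i) {
    double mn = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < B.nrow(); ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < mn) {
        mn = d2;
        if (mn <= best) break;
      }
    }
    if (mn > best) best = mn;
  }
  return best;
}

// [[Rcpp::export(name = ".hausdorff_points_cpp")]]
double hausdorff_points_cpp(Rcpp::NumericMatrix P, Rcpp::NumericMatrix Q) {
  if (P.ncol() != 3 || Q.ncol() != 3)
    Rcpp::stop("point matrices must have 3 columns");
  if (P.nrow() == 0 || Q.nrow() == 0)
    Rcpp::stop("point sets must be nonempty");
  return std::sqrt(std::max(directed_max_min(P, Q), directed_max_min(Q, P)));
}
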