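#include <Rcpp.h>
using namespace Rcpp;

// Concordant / discordant pair counts per feature for Kendall-tau scoring
// against +1/-1 class labels. Only between-class unordered pairs can be
// concordant or discordant (within-class pairs have sgn(y_j - y_k) = 0);
// for a pair (a in class +1, b in class -1) the pair is concordant when
// x_a > x_b and discordant when x_a < x_b. Exact value ties count as
// neither.
// [[Rcpp::export(name = ".kendallCounts")]]
NumericMatrix kendallCounts(NumericMatrix x, IntegerVector y) {
  const int n = x.nrow(), p = x.ncol();
  if (y.size() != n) stop("labels must match the number of rows");
  std::vector<int> pos, neg;
  pos.reserve(n); neg.reserve(n);
  for (int s = 0; s < n; ++s) {
    if (y[s] > 0) pos.push_back(s); else neg.push_back(s);
  }
  NumericMatrix out(p, 2);
  const int na = pos.size(), nb = neg.size();
  for (int f = 0; f < p; ++f) {
    double nc = 0.0, nd = 0.0;
    const double* col = &x(0, f);
    for (int ia = 0; ia < na; ++ia) {
      const double xa = col[pos[ia]];
      for (int ib = 0; ib < nb; ++ib) {
        const double xb = col[neg[ib]];
        if (xa > xb) nc += 1.0;
        else if (xa < xb) nd += 1.0;
      }
    }
    out(f, 0) = nc;
    out(f, 1) = nd;
  }
  return out;
}

// Leave-one-out decomposition of the signed concordance score. For the
// full sample, D[f] = sum over between-class pairs (a in +1, b in -1) of
// sign(x_a - x_b); S[i, f] is sample i's own contribution (all its
// between-class pairs). Removing sample i from a fold removes exactly its
// pairs, so the training-fold score is D[f] - S[i, f] -- one pass serves
// every LOOCV fold.
// [[Rcpp::export(name = ".kendallFoldScores")]]
List kendallFoldScores(NumericMatrix x, IntegerVector y) {
  const int n = x.nrow(), p = x.ncol();
  if (y.size() != n) stop("labels must match the number of rows");
  std::vector<int> pos, neg;
  for (int s = 0; s < n; ++s) {
    if (y[s] > 0) pos.push_back(s); else neg.push_back(s);
  }
  const int na = pos.size(), nb = neg.size();
  NumericVector D(p);
  NumericMatrix S(n, p);
  for (int f = 0; f < p; ++f) {
    const double* col = &x(0, f);
    double tot = 0.0;
    for (int ia = 0; ia < na; ++ia) {
      const int a = pos[ia];
      const double xa = col[a];
      double sa = 0.0;
      for (int ib = 0; ib < nb; ++ib) {
        const int b = neg[ib];
        const double xb = col[b];
        if (xa > xb)      { sa += 1.0; S(b, f) += 1.0; }
        else if (xa < xb) { sa -= 1.0; S(b, f) -= 1.0; }
      }
      S(a, f) = sa;
      tot += sa;
    }
    D[f] = tot;
  }
  return List::create(_["D"] = D, _["S"] = S);
}
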