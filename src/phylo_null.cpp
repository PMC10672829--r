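#include <Rcpp.h>
using namespace Rcpp;

// Nearest-taxon distances underpin MNTD and betaMNTD. The null model
// shuffles taxon labels on the distance matrix; rather than copying the
// matrix per draw, every routine takes a permutation `perm` (0-based,
// length = nrow(D)) and reads D(perm[i], perm[j]).

static inline double get(const NumericMatrix& D, const IntegerVector& perm,
                         int i, int j) {
  return D(perm[i], perm[j]);
}

// MNTD of one community: for each present taxon, distance to its nearest
// other present taxon; unweighted mean or abundance-weighted mean.
// idx: 0-based positions of present taxa in D; w: their relative abundances.
// [[Rcpp::export]]
double cpp_mntd(const NumericMatrix& D, const IntegerVector& idx,
                const NumericVector& w, bool weighted,
                const IntegerVector& perm) {
  const int k = idx.size();
  if (k < 2) stop("MNTD needs at least 2 taxa");
  double acc = 0.0;
  for (int i = 0; i < k; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < k; ++j) {
      if (j == i) continue;
      double d = get(D, perm, idx[i], idx[j]);
      if (d < best) best = d;
    }
    acc += weighted ? w[i] * best : best;
  }
  return weighted ? acc : acc / k;
}

// betaMNTD of one ordered pair direction: mean (weighted) distance from each
// taxon in a to its nearest taxon in b.
static double dir_mntd(const NumericMatrix& D, const IntegerVector& perm,
                       const IntegerVector& a, const NumericVector& wa,
                       const IntegerVector& b, bool weighted) {
  const int ka = a.size(), kb = b.size();
  double acc = 0.0;
  for (int i = 0; i < ka; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < kb; ++j) {
      double d = get(D, perm, a[i], b[j]);
      if (d < best) best = d;
    }
    acc += weighted ? wa[i] * best : best;
  }
  return weighted ? acc : acc / ka;
}

// [[Rcpp::export]]
double cpp_beta_mntd_pair(const NumericMatrix& D,
                          const IntegerVector& a, const NumericVector& wa,
                          const IntegerVector& b, const NumericVector& wb,
                          bool weighted, const IntegerVector& perm) {
  if (a.size() < 1 || b.size() < 1) stop("empty community");
  return 0.5 * (dir_mntd(D, perm, a, wa, b, weighted) +
                dir_mntd(D, perm, b, wb, a, weighted));
}

// Full pairwise betaMNTD matrix over samples. idx/w are lists (one entry per
// sample) of present-taxon positions and their relative abundances.
// [[Rcpp::export]]
NumericMatrix cpp_beta_mntd_all(const NumericMatrix& D, const List& idx,
                                const List& w, bool weighted,
                                const IntegerVector& perm) {
  const int n = idx.size();
  NumericMatrix out(n, n);
  std::vector<IntegerVector> ix(n);
  std::vector<NumericVector> wx(n);
  for (int i = 0; i < n; ++i) {
    ix[i] = as<IntegerVector>(idx[i]);
    wx[i] = as<NumericVector>(w[i]);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double v = 0.5 * (dir_mntd(D, perm, ix[i], wx[i], ix[j], weighted) +
                        dir_mntd(D, perm, ix[j], wx[j], ix[i], weighted));
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
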