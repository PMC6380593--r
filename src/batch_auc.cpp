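#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct ScoreLab {
  double score;
  int poor;
};

// Mann-Whitney AUC of "higher score => poor" with ties counted 1/2,
// computed from a sortable (score, label) buffer.
static double auc_buf(std::vector<ScoreLab>& buf, long n_poor, long n_good) {
  const int n = (int)buf.size();
  std::sort(buf.begin(), buf.end(),
            [](const ScoreLab& a, const ScoreLab& b) {
              return a.score < b.score;
            });
  double rank_sum_poor = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && buf[j + 1].score == buf[i].score) ++j;
    int poor_in_group = 0;
    for (int k = i; k <= j; ++k) poor_in_group += buf[k].poor;
    rank_sum_poor += poor_in_group * 0.5 * ((i + 1) + (j + 1));
    i = j + 1;
  }
  if (n_poor == 0 || n_good == 0) return NA_REAL;
  return (rank_sum_poor - 0.5 * n_poor * (n_poor + 1)) /
         ((double)n_poor * (double)n_good);
}

// Batch AUC of linear two-gene meta-genes.
// Z: n_test x p matrix, standardized with training statistics. pairs:
// m x 2 one-based column indices. W: m x 2 weights. Returns per-row AUC
// of score = W[k,1]*Z[,pairs[k,1]] + W[k,2]*Z[,pairs[k,2]] vs is_poor.
// [[Rcpp::export]]
NumericVector cpp_pair_auc(const NumericMatrix& Z, const IntegerMatrix& pairs,
                           const NumericMatrix& W,
                           const IntegerVector& is_poor) {
  const int n = Z.nrow(), m = pairs.nrow();
  long n_poor = 0, n_good = 0;
  std::vector<int> poor(n);
  for (int s = 0; s < n; ++s) {
    poor[s] = is_poor[s];
    (poor[s] ? n_poor : n_good)++;
  }
  const double* zbase = &Z(0, 0);
  NumericVector out(m);
  std::vector<ScoreLab> buf(n);
  for (int k = 0; k < m; ++k) {
    const double* zi = zbase + (size_t)(pairs(k, 0) - 1) * n;
    const double* zj = zbase + (size_t)(pairs(k, 1) - 1) * n;
    const double wi = W(k, 0), wj = W(k, 1);
    for (int s = 0; s < n; ++s) {
      buf[s].score = wi * zi[s] + wj * zj[s];
      buf[s].poor = poor[s];
    }
    out[k] = auc_buf(buf, n_poor, n_good);
  }
  return out;
}

// Per-column AUC of score = w[j] * Z[, j] (orientation via the sign of
// the fitted single-gene regression weight).
// [[Rcpp::export]]
NumericVector cpp_gene_auc(const NumericMatrix& Z, const NumericVector& w,
                           const IntegerVector& is_poor) {
  const int n = Z.nrow(), p = Z.ncol();
  long n_poor = 0, n_good = 0;
  std::vector<int> poor(n);
  for (int s = 0; s < n; ++s) {
    poor[s] = is_poor[s];
    (poor[s] ? n_poor : n_good)++;
  }
  const double* zbase = &Z(0, 0);
  NumericVector out(p);
  std::vector<ScoreLab> buf(n);
  for (int j = 0; j < p; ++j) {
    const double* zj = zbase + (size_t)j * n;
    for (int s = 0; s < n; ++s) {
      buf[s].score = w[j] * zj[s];
      buf[s].poor = poor[s];
    }
    out[j] = auc_buf(buf, n_poor, n_good);
  }
  return out;
}
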