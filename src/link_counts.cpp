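#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Row-standardise to zero mean / unit norm so Z * Z' is the Pearson
// correlation matrix. Constant rows are zeroed: their correlations are
// defined as 0 rather than propagating NaN.
static arma::mat row_standardise(const arma::mat &x) {
  arma::mat z = x.each_col() - arma::mean(x, 1);
  arma::vec nrm = arma::sqrt(arma::sum(arma::square(z), 1));
  for (arma::uword i = 0; i < z.n_rows; ++i) {
    if (nrm(i) > 1e-12) {
      z.row(i) /= nrm(i);
    } else {
      z.row(i).zeros();
    }
  }
  return z;
}

// Independently permute each row in place (Fisher-Yates, R's RNG).
static void permute_rows_inplace(arma::mat &m) {
  const arma::uword n = m.n_rows, s = m.n_cols;
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = s - 1; j > 0; --j) {
      arma::uword k = static_cast<arma::uword>(unif_rand() * (j + 1));
      if (k > j) k = j;
      std::swap(m(i, j), m(i, k));
    }
  }
}

// Count upper-triangle entries with |r| >= t for each threshold.
static arma::ivec upper_counts(const arma::mat &c, const arma::vec &thresholds) {
  arma::ivec counts(thresholds.n_elem, arma::fill::zeros);
  const arma::uword n = c.n_rows;
  for (arma::uword j = 1; j < n; ++j) {
    for (arma::uword i = 0; i < j; ++i) {
      const double a = std::abs(c(i, j));
      for (arma::uword t = 0; t < thresholds.n_elem; ++t) {
        if (a >= thresholds(t)) ++counts(t);
      }
    }
  }
  return counts;
}

//' Count coexpression links at each candidate threshold
//'
//' Number of unordered gene pairs whose absolute Pearson correlation meets or
//' exceeds each threshold, for a genes x samples matrix.
//'
//' @param x Numeric matrix (genes in rows, samples in columns).
//' @param thresholds Numeric vector of candidate thresholds.
//' @return Integer vector of link counts, one per threshold.
//' @keywords internal
// [[Rcpp::export]]
Rcpp::IntegerVector link_counts_cpp(const arma::mat &x,
                                    const arma::vec &thresholds) {
  arma::mat z = row_standardise(x);
  arma::mat c = z * z.t();
  return Rcpp::wrap(upper_counts(c, thresholds));
}

//' One surrogate dataset: independent row-wise permutation
//'
//' The permutation step of the surrogate generator, exposed so its contract
//' (each row keeps exactly its multiset of values) is testable in isolation.
//'
//' @param x Numeric matrix (genes x samples).
//' @return The matrix with each row independently permuted.
//' @keywords internal
// [[Rcpp::export]]
Rcpp::NumericMatrix permute_rows_cpp(const arma::mat &x) {
  arma::mat out = x;
  permute_rows_inplace(out);
  return Rcpp::wrap(out);
}

//' Surrogate-data link counts under row-wise permutation
//'
//' Repeats `n_shuffles` times: independently permute each gene's values
//' across samples (destroying inter-gene correlation while preserving each
//' gene's marginal distribution exactly), then count links at each threshold.
//' Permutations draw from R's RNG, so results are governed by `set.seed()`.
//'
//' @param x Numeric matrix (genes x samples).
//' @param n_shuffles Number of surrogate datasets.
//' @param thresholds Numeric vector of candidate thresholds.
//' @return Integer matrix, `n_shuffles` rows x `length(thresholds)` columns.
//' @keywords internal
// [[Rcpp::export]]
Rcpp::IntegerMatrix surrogate_link_counts_cpp(const arma::mat &x,
                                              int n_shuffles,
                                              const arma::vec &thresholds) {
  Rcpp::IntegerMatrix out(n_shuffles, thresholds.n_elem);
  arma::mat shuf(x.n_rows, x.n_cols);
  for (int rep = 0; rep < n_shuffles; ++rep) {
    shuf = x;
    permute_rows_inplace(shuf);
    arma::mat z = row_standardise(shuf);
    arma::mat c = z * z.t();
    arma::ivec counts = upper_counts(c, thresholds);
    for (arma::uword t = 0; t < thresholds.n_elem; ++t) {
      out(rep, t) = counts(t);
    }
  }
  return out;
}
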