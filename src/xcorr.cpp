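// Windowed forward-lag maximal cross-correlation kernel.
//
// For every window start s and ordered channel pair (i, j), maximizes over
// lags l = 0..L the Pearson correlation between Y[i, s : s+W-1-l] and
// Y[j, s+l : s+W-1] (channel i leading channel j). Segment cross-products
// come from one small matrix product per (window, lag); segment means and
// variances from cumulative sums. Zero-variance segments contribute
// correlation 0 at that lag (relative guard against cancellation noise in
// the cumulative sums).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(rng = false)]]
arma::cube window_max_xcorr_cpp(const arma::mat& Y,
                                const arma::ivec& starts,
                                const int W, const int L) {
  const arma::uword C = Y.n_rows;
  const arma::uword T = Y.n_cols;
  const arma::uword nwin = starts.n_elem;

  arma::mat cs1(C, T + 1, arma::fill::zeros);
  arma::mat cs2(C, T + 1, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    cs1.col(t + 1) = cs1.col(t) + Y.col(t);
    cs2.col(t + 1) = cs2.col(t) + arma::square(Y.col(t));
  }

  arma::cube res(C, C, nwin);
  arma::mat S(C, C);
  for (arma::uword w = 0; w < nwin; ++w) {
    const arma::uword s = static_cast<arma::uword>(starts[w] - 1); // 0-based
    arma::mat best(C, C);
    best.fill(-arma::datum::inf);
    for (int l = 0; l <= L; ++l) {
      const arma::uword n = W - l;
      S = Y.cols(s, s + n - 1) * Y.cols(s + l, s + l + n - 1).t();
      const arma::vec sa  = cs1.col(s + n) - cs1.col(s);
      const arma::vec ssa = cs2.col(s + n) - cs2.col(s);
      const arma::vec sb  = cs1.col(s + W) - cs1.col(s + l);
      const arma::vec ssb = cs2.col(s + W) - cs2.col(s + l);
      const arma::vec ma = sa / n, mb = sb / n;
      arma::vec va = ssa / n - arma::square(ma);
      arma::vec vb = ssb / n - arma::square(mb);
      for (arma::uword i = 0; i < C; ++i) {
        if (va[i] < 0) va[i] = 0;
        if (vb[i] < 0) vb[i] = 0;
      }
      const arma::vec dega = arma::conv_to<arma::vec>::from(
          va <= 1e-22 + 1e-13 * (ssa / n));
      const arma::vec degb = arma::conv_to<arma::vec>::from(
          vb <= 1e-22 + 1e-13 * (ssb / n));
      const arma::vec sda = arma::sqrt(va), sdb = arma::sqrt(vb);
      for (arma::uword j = 0; j < C; ++j) {
        const double mbj = mb[j], sdbj = sdb[j];
        const bool degj = degb[j] > 0.5;
        for (arma::uword i = 0; i < C; ++i) {
          double r;
          if (degj || dega[i] > 0.5) {
            r = 0.0;
          } else {
            r = (S(i, j) - n * ma[i] * mbj) / (n * sda[i] * sdbj);
            if (r > 1.0) r = 1.0;
            if (r < -1.0) r = -1.0;
          }
          if (r > best(i, j)) best(i, j) = r;
        }
      }
    }
    res.slice(w) = best;
  }
  return res;
}
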