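// Bootstrap null kernel for the mODP statistic.
//
// All module centers live in the alternative-only subspace (dimension
// r = df1 - df0), so gene-module distances reduce to r-dimensional
// coordinates; the full N-dimensional data enter only through their
// null-orthogonal residual norms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Warm-started clustering passes + mODP statistic for one (resampled)
// dataset given in coordinates: ZS (m x r) alternative-only coordinates,
// rssTot = ||Z - P0 Z||^2 per gene.
static vec recuratedStat(const mat& ZS, const vec& rssTot,
                         const mat& cen0, const vec& u1sq0,
                         const vec& u0sq0, const ivec& sizes0,
                         int N, int passes) {
  const int m = ZS.n_rows;
  const int K = cen0.n_rows;
  const int r = ZS.n_cols;

  vec rssS = sum(square(ZS), 1);
  vec s1sq = (rssTot - rssS);
  s1sq.transform([](double v) { return v > 1e-300 ? v : 1e-300; });
  s1sq /= N;
  vec s0sq = rssTot;
  s0sq.transform([](double v) { return v > 1e-300 ? v : 1e-300; });
  s0sq /= N;

  mat ZSt = ZS.t();                       // r x m, column-contiguous genes
  mat cent = cen0.t();                    // r x K
  vec u1sq = u1sq0, u0sq = u0sq0;
  ivec sizes = sizes0;
  ivec a(m), aold(m);
  aold.fill(-1);

  for (int pass = 0; pass < passes; ++pass) {
    vec cn(K);
    for (int k = 0; k < K; ++k) cn(k) = dot(cent.col(k), cent.col(k));
    bool changed = false;
    for (int i = 0; i < m; ++i) {
      const double* zi = ZSt.colptr(i);
      const double si1 = s1sq(i), zn = rssS(i);
      double best = datum::inf;
      int bestk = 0;
      for (int k = 0; k < K; ++k) {
        const double* ck = cent.colptr(k);
        double ip = 0;
        for (int l = 0; l < r; ++l) ip += zi[l] * ck[l];
        double d2 = zn - 2.0 * ip + cn(k);
        if (d2 < 0) d2 = 0;
        double del = (d2 + N * si1) / u1sq(k) + (d2 + N * u1sq(k)) / si1;
        if (del < best) { best = del; bestk = k; }
      }
      a(i) = bestk;
      if (a(i) != aold(i)) changed = true;
    }
    if (!changed) break;
    aold = a;
    mat cs(r, K, fill::zeros);
    vec s1s(K, fill::zeros), s0s(K, fill::zeros);
    ivec cnt(K, fill::zeros);
    for (int i = 0; i < m; ++i) {
      int k = a(i);
      cs.col(k) += ZSt.col(i);
      s1s(k) += s1sq(i);
      s0s(k) += s0sq(i);
      cnt(k) += 1;
    }
    for (int k = 0; k < K; ++k) {
      if (cnt(k) > 0) {
        cent.col(k) = cs.col(k) / cnt(k);
        u1sq(k) = s1s(k) / cnt(k);
        u0sq(k) = s0s(k) / cnt(k);
      }
    }
    sizes = cnt;
  }

  // log-sum-exp mODP statistic against the recurated modules
  const double halfLog2pi = 0.5 * N * std::log(2.0 * M_PI);
  vec cn(K);
  for (int k = 0; k < K; ++k) cn(k) = dot(cent.col(k), cent.col(k));
  std::vector<double> lw(K), lc1(K), lc0(K), invu1(K), invu0(K);
  for (int k = 0; k < K; ++k) {
    lw[k] = sizes(k) > 0 ? std::log((double)sizes(k)) : -datum::inf;
    lc1[k] = lw[k] - halfLog2pi - 0.5 * N * std::log(u1sq(k));
    lc0[k] = lw[k] - halfLog2pi - 0.5 * N * std::log(u0sq(k));
    invu1[k] = 0.5 / u1sq(k);
    invu0[k] = 0.5 / u0sq(k);
  }
  vec out(m);
  std::vector<double> buf1(K), buf0(K);
  for (int i = 0; i < m; ++i) {
    const double* zi = ZSt.colptr(i);
    double orth = rssTot(i) - rssS(i);
    if (orth < 0) orth = 0;
    double mx1 = -datum::inf, mx0 = -datum::inf;
    for (int k = 0; k < K; ++k) {
      const double* ck = cent.colptr(k);
      double ip = 0;
      for (int l = 0; l < r; ++l) ip += zi[l] * ck[l];
      double d2 = rssS(i) - 2.0 * ip + cn(k);
      if (d2 < 0) d2 = 0;
      buf1[k] = lc1[k] - (d2 + orth) * invu1[k];
      buf0[k] = lc0[k] - rssTot(i) * invu0[k];
      if (buf1[k] > mx1) mx1 = buf1[k];
      if (buf0[k] > mx0) mx0 = buf0[k];
    }
    double s1 = 0, s0 = 0;
    for (int k = 0; k < K; ++k) {
      if (std::isfinite(buf1[k])) s1 += std::exp(buf1[k] - mx1);
      if (std::isfinite(buf0[k])) s0 += std::exp(buf0[k] - mx0);
    }
    out(i) = (mx1 + std::log(s1)) - (mx0 + std::log(s0));
  }
  return out;
}

// [[Rcpp::export(name = ".recuratedStatCpp")]]
arma::vec recuratedStatCpp(const arma::mat& Z, const arma::mat& Q0,
                           const arma::mat& Qr, const arma::mat& cen0,
                           const arma::vec& u1sq0, const arma::vec& u0sq0,
                           const arma::ivec& sizes0, int passes) {
  const int N = Z.n_cols;
  mat Z0 = Z * Q0;
  mat ZS = Z * Qr;
  vec rssTot = sum(square(Z), 1) - sum(square(Z0), 1);
  return recuratedStat(ZS, rssTot, cen0, u1sq0, u0sq0, sizes0, N, passes);
}

// [[Rcpp::export(name = ".bootPoolCpp")]]
arma::vec bootPoolCpp(const arma::mat& R, const arma::mat& Q0,
                      const arma::mat& Qr, const arma::mat& cen0,
                      const arma::vec& u1sq0, const arma::vec& u0sq0,
                      const arma::ivec& sizes0, int B, int passes) {
  const int m = R.n_rows;
  const int N = R.n_cols;
  Rcpp::RNGScope scope;
  vec out(m * (size_t)B);
  mat Z(m, N);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i < m; ++i) {
        int c = (int)(unif_rand() * N);
        if (c >= N) c = N - 1;
        Z(i, j) = R(i, c);
      }
    }
    mat Z0 = Z * Q0;
    mat ZS = Z * Qr;
    vec rssTot = sum(square(Z), 1) - sum(square(Z0), 1);
    out.subvec((size_t)b * m, (size_t)(b + 1) * m - 1) =
      recuratedStat(ZS, rssTot, cen0, u1sq0, u0sq0, sizes0, N, passes);
  }
  return out;
}
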