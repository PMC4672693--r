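// Compiled fast path for the Gibbs sampler when no outcomes are missing.
// Mirrors the R implementation step for step; all randomness comes from R's
// RNG (unif_rand / norm_rand / R::rchisq / R::rgamma), so a chain is fully
// reproducible from set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Inverse-Wishart draw via the Bartlett decomposition: W ~ Wishart(df,
// scale^{-1}), return W^{-1}.  Matches the parameterisation with mean
// scale / (df - q - 1).
static arma::mat rinvwishart(double df, const arma::mat& scale) {
  const int q = scale.n_rows;
  arma::mat L = arma::chol(arma::inv_sympd(scale), "lower");
  arma::mat A(q, q, arma::fill::zeros);
  for (int i = 0; i < q; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat Sig = arma::inv_sympd(arma::symmatu(LA * LA.t()));
  return 0.5 * (Sig + Sig.t());
}

// [[Rcpp::export(.gibbs_chain_complete_cpp)]]
List gibbs_chain_complete_cpp(const arma::mat& Y,
                              const arma::ivec& bpat,     // 1-based
                              const List& Bs,
                              const arma::ivec& treated_rows,  // 1-based
                              arma::ivec C,                // current types
                              arma::mat alpha,             // (m+1) x m
                              arma::vec beta,
                              arma::vec gamma,
                              arma::mat Sigma,
                              const double coef_var,
                              const double wdf,
                              const arma::mat& Omega,
                              const arma::vec& gamma_conc, // length m+1
                              const int n_iter,
                              const int thin,
                              const bool keep_compliance) {
  const int n = Y.n_rows, m = Y.n_cols;
  const int pa = (m + 1) * m, p = pa + m;
  const int nb = Bs.size();
  const int n1 = treated_rows.n_elem;
  const int n_keep = n_iter / thin;
  const int npar = pa + m + (m + 1) + m * m;

  std::vector<arma::mat> B(nb);
  for (int b = 0; b < nb; ++b) B[b] = as<arma::mat>(Bs[b]);

  arma::mat Y1(n1, m);
  for (int k = 0; k < n1; ++k) Y1.row(k) = Y.row(treated_rows[k] - 1);

  arma::mat draws(n_keep, npar);
  IntegerMatrix Ckeep(keep_compliance ? n_keep : 0,
                      keep_compliance ? n1 : 0);
  std::vector<bool> absent(m + 1, false);

  arma::uvec jb(m);
  for (int j = 0; j < m; ++j) jb[j] = pa + j;

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    arma::mat Sinv = arma::inv_sympd(Sigma);

    // --- 1. impute latent compliance types (intervention arm) ------------
    if (n1 > 0) {
      arma::mat Mu = alpha;
      Mu.each_row() += beta.t();
      arma::mat MS = Mu * Sinv;                         // (m+1) x m
      arma::vec off = 0.5 * arma::sum(MS % Mu, 1) - arma::log(gamma);
      arma::mat lp = Y1 * MS.t();                       // n1 x (m+1)
      for (int k = 0; k < n1; ++k) {
        int best = 0;
        double bestv = -arma::datum::inf;
        for (int cc = 0; cc <= m; ++cc) {
          double g = -std::log(-std::log(unif_rand()));
          double v = lp(k, cc) - off(cc) + g;
          if (v > bestv) { bestv = v; best = cc; }
        }
        C[treated_rows[k] - 1] = best;
      }
    }

    // --- 2. draw coefficients --------------------------------------------
    arma::mat cnt(m + 1, nb, arma::fill::zeros);
    arma::cube ysum(m + 1, m, nb, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      const int b = bpat[i] - 1, c = C[i];
      cnt(c, b) += 1.0;
      ysum.slice(b).row(c) += Y.row(i);
    }
    std::vector<arma::mat> SB(nb), BSB(nb);
    for (int b = 0; b < nb; ++b) {
      SB[b] = Sinv * B[b];
      BSB[b] = B[b].t() * SB[b];
    }
    arma::mat P(p, p, arma::fill::zeros);
    arma::vec q(p, arma::fill::zeros);
    for (int c = 0; c <= m; ++c) {
      arma::uvec ii(m);
      for (int j = 0; j < m; ++j) ii[j] = j * (m + 1) + c;
      bool seen = false;
      for (int b = 0; b < nb; ++b) {
        const double nk = cnt(c, b);
        if (nk == 0.0) continue;
        seen = true;
        P(ii, ii) += nk * Sinv;
        P(ii, jb) += nk * SB[b];
        P(jb, jb) += nk * BSB[b];
        arma::vec sy = Sinv * ysum.slice(b).row(c).t();
        q(ii) += sy;
        q(jb) += B[b].t() * sy;
      }
      if (!seen) absent[c] = true;
    }
    P(jb, arma::regspace<arma::uvec>(0, pa - 1)) =
      P(arma::regspace<arma::uvec>(0, pa - 1), jb).t();
    P.diag() += 1.0 / coef_var;
    arma::mat U = arma::chol(P);                        // upper
    arma::vec mean_ = arma::solve(arma::trimatu(U),
                        arma::solve(arma::trimatl(U.t()), q));
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z[j] = norm_rand();
    arma::vec theta = mean_ + arma::solve(arma::trimatu(U), z);
    if (!theta.is_finite())
      stop("non-finite coefficient draw at iteration %d", it + 1);
    alpha = arma::reshape(theta.head(pa), m + 1, m);
    beta = theta.tail(m);

    // --- 3. draw covariance ----------------------------------------------
    arma::mat Beff(nb, m);
    for (int b = 0; b < nb; ++b) Beff.row(b) = (B[b] * beta).t();
    arma::mat E(n, m);
    for (int i = 0; i < n; ++i)
      E.row(i) = Y.row(i) - alpha.row(C[i]) - Beff.row(bpat[i] - 1);
    Sigma = rinvwishart(wdf + n, Omega + E.t() * E);

    // --- 4. draw type probabilities --------------------------------------
    arma::vec tc(m + 1, arma::fill::zeros);
    for (int i = 0; i < n; ++i) tc[C[i]] += 1.0;
    arma::vec g(m + 1);
    double gs = 0.0;
    for (int cc = 0; cc <= m; ++cc) {
      g[cc] = R::rgamma(gamma_conc[cc] + tc[cc], 1.0);
      gs += g[cc];
    }
    gamma = (gs > 0.0) ? arma::vec(g / gs)
                       : arma::vec(m + 1, arma::fill::value(1.0 / (m + 1)));

    if ((it + 1) % thin == 0) {
      arma::rowvec row(npar);
      row.cols(0, pa - 1) = arma::vectorise(alpha).t();
      row.cols(pa, pa + m - 1) = beta.t();
      row.cols(pa + m, pa + 2 * m) = gamma.t();
      row.cols(pa + 2 * m + 1, npar - 1) = arma::vectorise(Sigma).t();
      draws.row(kept) = row;
      if (keep_compliance)
        for (int k = 0; k < n1; ++k)
          Ckeep(kept, k) = C[treated_rows[k] - 1];
      ++kept;
    }
  }

  IntegerVector absent_types;
  for (int c = 0; c <= m; ++c) if (absent[c]) absent_types.push_back(c);
  return List::create(_["draws"] = draws,
                      _["Cdraws"] = Ckeep,
                      _["absent_types"] = absent_types);
}
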