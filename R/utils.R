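# Small distribution helpers used by the sampler.  All take/return plain
# matrices and rely on base stats for the underlying random number streams,
# so a chain is a pure function of its seed.

# log N(y; mu, Sigma) over the observed coordinates, vectorised over rows of
# a deviation matrix.  `U` is chol(Sigma_obs) (upper triangular).
.mvn_logdens <- function(dev, U) {
  # dev: k x q matrix of deviations (rows = subjects), U: q x q
  z <- backsolve(U, t(dev), transpose = TRUE)       # q x k
  q <- ncol(U)
  -0.5 * q * log(2 * pi) - sum(log(diag(U))) - 0.5 * colSums(z^2)
}

# One draw from the inverse Wishart IW(df, scale) in the parameterisation
# with mean scale / (df - q - 1) for df > q + 1.
.rinvwishart <- function(df, scale) {
  q <- ncol(scale)
  W <- stats::rWishart(1L, df, chol2inv(chol(scale)))[, , 1L]
  Sig <- chol2inv(chol(W))
  (Sig + t(Sig)) / 2
}

.rdirichlet <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  if (all(g == 0)) g[] <- 1 / length(conc)  # guard against total underflow
  g / sum(g)
}

# Draw one multivariate normal with mean m and covariance chol2inv(cholP)
# given the upper cholesky factor cholP of the precision matrix.
.rmvn_prec <- function(m, cholP) {
  z <- stats::rnorm(length(m))
  m + backsolve(cholP, z)
}

# Row-wise categorical sampling from unnormalised log-probabilities using the
# Gumbel-max trick (vectorised; returns 0-based categories).
.sample_categorical_log <- function(logp) {
  g <- -log(-log(matrix(stats::runif(length(logp)), nrow(logp), ncol(logp))))
  max.col(logp + g, ties.method = "first") - 1L
}

.is_square_pd <- function(S, tol = 1e-10) {
  is.matrix(S) && nrow(S) == ncol(S) &&
    isTRUE(all.equal(S, t(S), tolerance = 1e-8)) &&
    all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > tol * nrow(S))
}

# Deterministic per-replicate / per-chain sub-seed kept below 2^31.
.subseed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 1000003 + 7919 * as.numeric(index)) %% 2147483629)
}
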