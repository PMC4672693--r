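truth <- ref_truth()

test_that("compliance posterior handles observed, flat and general cases", {
  expect_equal(compliance_posterior(rnorm(5), r = 0, d = 2, truth),
               c(0, 0, 1, 0, 0, 0))
  # likelihood constant in c -> posterior equals the prior gamma
  m <- 2
  p_flat <- cace_params(matrix(5, m + 1, m), c(1, 1), rep(1 / 3, 3), diag(m),
                        scale = "visits")
  expect_equal(compliance_posterior(c(4, 7), 1, 0, p_flat), rep(1 / 3, 3),
               tolerance = 1e-12)
  # m = 2 oracle: direct evaluation of bivariate normal densities
  alpha <- rbind(c(0, 0), c(2, 1), c(-1, 3))
  gam <- c(0.5, 0.25, 0.25)
  p <- cace_params(alpha, c(0, 0), gam, diag(2), scale = "visits")
  y <- c(0, 0)
  dens <- vapply(1:3, function(k)
    prod(dnorm(y, alpha[k, ], 1)), numeric(1))
  expect_equal(compliance_posterior(y, 1, 0, p),
               gam * dens / sum(gam * dens), tolerance = 1e-12)
})

test_that("compliance posterior is a proper distribution, even near underflow", {
  set.seed(5)
  for (i in 1:30) {
    m <- sample(1:5, 1)
    p <- cace_params(matrix(rnorm((m + 1) * m, 0, 20), m + 1, m),
                     rnorm(m), as.numeric(longcace:::.rdirichlet(rep(1, m + 1))),
                     crossprod(matrix(rnorm(m * m), m)) + diag(m) * 0.1,
                     scale = "visits")
    y <- rnorm(m, 0, 50)
    y[sample(m, sample(0:(m - 1), 1))] <- NA
    post <- compliance_posterior(y, 1, 0, p)
    expect_simplex(post)
    expect_false(anyNA(post))
  }
  # extreme outcome far in the tails still renormalises
  post <- compliance_posterior(rep(1e4, 5), 1, 0, truth)
  expect_simplex(post)
})

test_that("coefficient draw centres on the GLS estimate under a flat prior", {
  # both arms with the latent types revealed: the model is then an ordinary
  # linear regression, and with a flat prior the conditional mean is the GLS
  # solution, here equal to OLS because the errors are iid
  set.seed(91)
  d <- generate_dataset(sim_config(n = 5000, base_seed = 91), 1)
  C <- attr(d, "true_C")
  design <- longcace:::.build_design(d, "visits")
  prior <- cace_prior(coef_variance = 1e8)
  draws <- replicate(120, longcace:::.update_coefficients(
    d$Y, C, design, truth$Sigma, prior)$beta)
  long <- which(!d$missing_mask, arr.ind = TRUE)
  i <- long[, 1]; j <- long[, 2]
  elapsed <- ifelse(d$R[i] == 1, j, pmax(j - C[i], 0))
  fac_cell <- factor(paste(C[i], j))
  E <- outer(elapsed, 1:5, "==") + 0
  ols <- lm(d$Y[long] ~ 0 + fac_cell + E)
  b_ols <- coef(ols)[paste0("E", 1:5)]
  expect_true(all(abs(b_ols - truth$beta) < 1))  # sanity on the oracle itself
  mc_se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - b_ols) < 4 * mc_se + 0.01))
})

test_that("zero prior variance pins coefficients to the prior mean", {
  d <- generate_dataset(sim_config(n = 50, base_seed = 7), 1)
  design <- longcace:::.build_design(d, "visits")
  upd <- longcace:::.update_coefficients(
    d$Y, d$D, design, diag(5), cace_prior(coef_variance = 1e-12))
  expect_lt(max(abs(upd$beta)), 1e-3)
  expect_lt(max(abs(upd$alpha)), 1e-3)
})

test_that("covariance draws concentrate on the residual covariance", {
  set.seed(13)
  resid <- matrix(rnorm(4000 * 5, 0, 8), 4000, 5)
  draws <- replicate(40, longcace:::.update_sigma(resid, 7, diag(5)))
  mean_draw <- apply(draws, 1:2, mean)
  expect_lt(max(abs(mean_draw - 64 * diag(5))), 4.5)
  # positive definiteness of every draw
  for (k in 1:40)
    expect_true(all(eigen(draws[, , k], symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  # n = 0: draw from the prior, mean scale/(df - m - 1)
  set.seed(13)
  prior_draws <- replicate(400, longcace:::.update_sigma(
    matrix(0, 0, 2), 8, diag(2))[1, 1])
  expect_equal(mean(prior_draws), 1 / (8 - 2 - 1), tolerance = 0.3)
  # m = 1 reduces to a scaled inverse chi-squared draw
  set.seed(99)
  r1 <- matrix(rnorm(500, 0, 3), ncol = 1)
  d1 <- replicate(200, longcace:::.update_sigma(r1, 3, diag(1))[1, 1])
  expect_equal(mean(d1), 9, tolerance = 1)
})

test_that("missing-outcome imputation follows the conditional normal", {
  y <- c(1, 2, 3)
  expect_identical(impute_missing_outcomes(y, rep(0, 3), diag(3)), y)
  # closed-form bivariate case: mean 1, variance 0.75
  set.seed(21)
  Sig <- rbind(c(1, 0.5), c(0.5, 1))
  draws <- replicate(4000, impute_missing_outcomes(c(2, NA), c(0, 0), Sig)[2])
  expect_equal(mean(draws), 1, tolerance = 0.06)
  expect_equal(var(draws), 0.75, tolerance = 0.08)
  # diagonal covariance: imputation ignores the observed coordinate
  set.seed(22)
  draws2 <- replicate(4000, impute_missing_outcomes(c(50, NA), c(0, 7),
                                                    diag(2))[2])
  expect_equal(mean(draws2), 7, tolerance = 0.07)
  # observed coordinate untouched
  out <- impute_missing_outcomes(c(2, NA), c(0, 0), Sig)
  expect_identical(out[1], 2)
})

test_that("type-probability draws are conjugate Dirichlet updates", {
  set.seed(31)
  g0 <- replicate(500, longcace:::.update_gamma(integer(0), 2, 1))
  expect_equal(rowMeans(g0), rep(1 / 3, 3), tolerance = 0.05)
  # huge counts dominate the prior and concentrate at the proportions
  C <- rep(0:5, round(9000 * ref_truth()$gamma))
  g <- replicate(50, longcace:::.update_gamma(C, 5, 1))
  expect_lt(max(abs(rowMeans(g) - truth$gamma)), 0.02)
  for (k in 1:50) expect_simplex(g[, k], tol = 1e-9)
  # m = 1: a Beta draw
  set.seed(32)
  b <- replicate(2000, longcace:::.update_gamma(c(0L, 1L, 1L), 1, 1)[2])
  expect_equal(mean(b), 3 / 5, tolerance = 0.04)  # Beta(2, 3) on gamma(0)... complement
})

test_that("the sampler recovers the generating effect curve", {
  d <- generate_dataset(sim_config(n = 300, base_seed = 1234), 1)
  fit <- cace_bayes(d, control = cace_control(n_iter = 2500, n_burnin = 500),
                    seed = 88)
  s <- summary(fit)$table
  b <- s[grep("^beta\\[", rownames(s)), ]
  expect_true(all(abs(b[, "mean"] - truth$beta) < 3 * b[, "sd"]))
  expect_lt(max(gelman_rubin(fit)), 1.2)
  # gamma draws live on the simplex, Sigma draws are PD
  draws <- longcace:::.pooled_draws(fit)
  gsum <- rowSums(draws[, grep("^gamma", colnames(draws))])
  expect_lt(max(abs(gsum - 1)), 1e-9)
  idx <- sample(nrow(draws), 25)
  for (k in idx) {
    Sig <- matrix(draws[k, grep("^Sigma", colnames(draws))], 5, 5)
    expect_true(all(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("chains are a pure function of their seeds", {
  d <- generate_dataset(sim_config(n = 80, base_seed = 6,
                                   missingness_rate = 0.15), 1)
  ctl <- cace_control(n_iter = 150, n_burnin = 50)
  f1 <- cace_bayes(d, control = ctl, seed = 42)
  f2 <- cace_bayes(d, control = ctl, seed = 42)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$compliance_draws, f2$compliance_draws)
  f3 <- cace_bayes(d, control = ctl, seed = 43)
  expect_false(identical(f1$chains, f3$chains))
})

test_that("degenerate latent structure reduces to the arm-difference fit", {
  # all control subjects never treated: no contamination
  cfg <- sim_config(n = 500, gamma_true = c(0, 0, 0, 0, 0, 1), base_seed = 55)
  d <- generate_dataset(cfg, 1)
  # types 0..4 are empty here, so their alpha rows fall back to the prior
  # (warned about); the effect curve itself stays identified
  fit <- suppressWarnings(
    cace_bayes(d, control = cace_control(n_iter = 1500, n_burnin = 300),
               seed = 9))
  b <- coef(fit)
  itt <- itt_differences(d)
  se <- summary(fit)$table[grep("^beta", longcace:::.param_names(5)), "sd"]
  expect_true(all(abs(b - itt) < 3 * se / sqrt(1)))
})

test_that("missing outcomes are handled by augmentation without bias", {
  cfg <- sim_config(n = 400, missingness_rate = 0.15, base_seed = 77)
  d <- generate_dataset(cfg, 1)
  expect_gt(sum(d$missing_mask), 0)
  fit <- cace_bayes(d, control = cace_control(n_iter = 2000, n_burnin = 400),
                    seed = 10)
  s <- summary(fit)$table
  b <- s[grep("^beta\\[", rownames(s)), ]
  expect_true(all(abs(b[, "mean"] - truth$beta) < 3.5 * b[, "sd"]))
})

test_that("Gelman-Rubin diagnostic behaves at its reference points", {
  set.seed(3)
  x <- rnorm(2000)
  expect_equal(unname(gelman_rubin(list(x, x))), 1, tolerance = 1e-3)
  # equal means and variances, independent noise -> about 1
  y <- rnorm(2000)
  expect_equal(unname(gelman_rubin(list(x, y))), 1, tolerance = 0.05)
  # constant chains at different values -> infinite
  expect_identical(unname(gelman_rubin(list(rep(1, 100), rep(2, 100)))), Inf)
  # identical constant chains -> 1 by convention
  expect_identical(unname(gelman_rubin(list(rep(1, 100), rep(1, 100)))), 1)
  expect_error(gelman_rubin(list(x)), "two chains")
  expect_error(gelman_rubin(list(x, y[1:10])), "equal length")
})

test_that("compiled and reference samplers agree on complete data", {
  d <- generate_dataset(sim_config(n = 200, base_seed = 57), 1)
  ctl_cpp <- cace_control(n_iter = 1200, n_burnin = 300)
  ctl_r <- cace_control(n_iter = 1200, n_burnin = 300, use_compiled = FALSE)
  f_cpp <- cace_bayes(d, control = ctl_cpp, seed = 19)
  f_r <- cace_bayes(d, control = ctl_r, seed = 19)
  s1 <- summary(f_cpp)$table
  s2 <- summary(f_r)$table
  sel <- grep("^(beta|gamma)\\[", rownames(s1))
  # same posterior up to Monte-Carlo error of the two short runs
  expect_true(all(abs(s1[sel, "mean"] - s2[sel, "mean"]) <
                    4 * s1[sel, "sd"] / sqrt(100) + 0.02))
  expect_true(all(s1[sel, "sd"] / s2[sel, "sd"] > 0.8 &
                    s1[sel, "sd"] / s2[sel, "sd"] < 1.25))
})
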