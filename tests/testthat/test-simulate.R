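test_that("generator reproduces the stated design and is deterministic", {
  cfg <- sim_config()
  expect_identical(cfg$n, 300L)
  expect_identical(cfg$m, 5L)
  expect_identical(cfg$n_replicates, 1000L)
  d <- generate_dataset(cfg, 1)
  expect_identical(d$n, 300L)
  expect_identical(d$m, 5L)
  expect_false(any(d$missing_mask))
  d2 <- generate_dataset(cfg, 1)
  expect_identical(d$Y, d2$Y)
  expect_identical(d$R, d2$R)
  expect_false(identical(d$Y, generate_dataset(cfg, 2)$Y))
})

test_that("generated outcomes follow the mean structure as noise vanishes", {
  cfg <- sim_config(n = 400, error_sd = 1e-4, base_seed = 12)
  d <- generate_dataset(cfg, 1)
  C <- attr(d, "true_C")
  truth <- ref_truth()
  # a control subject of type 2 at visit 1 is untreated: mean 25 - 1 = 24
  rows <- which(d$R == 0 & C == 2)
  expect_true(length(rows) > 0)
  expect_equal(unname(d$Y[rows, 1]), rep(24, length(rows)), tolerance = 1e-3)
  # every cell matches mean_visits
  for (i in sample(400, 25)) for (j in 1:5)
    expect_equal(d$Y[i, j], mean_visits(truth, C[i], d$R[i], j),
                 tolerance = 1e-3)
})

test_that("marginal frequencies converge to the configured rates", {
  cfg <- sim_config(n = 300, base_seed = 99, missingness_rate = 0.15)
  Cs <- unlist(lapply(1:30, function(r) {
    d <- generate_dataset(cfg, r)
    d$D[d$R == 0]
  }))
  frac5 <- mean(Cs == 5)
  expect_lt(abs(frac5 - 4 / 9), 3 * sqrt(4 / 9 * 5 / 9 / length(Cs)))
  miss <- mean(vapply(1:10, function(r)
    mean(generate_dataset(cfg, r)$missing_mask), numeric(1)))
  expect_lt(abs(miss - 0.15), 0.01)
  arm <- mean(vapply(1:10, function(r)
    mean(generate_dataset(cfg, r)$R), numeric(1)))
  expect_lt(abs(arm - 0.5), 0.03)
  # residual SD
  d <- generate_dataset(sim_config(n = 5000, base_seed = 1), 1)
  C <- attr(d, "true_C")
  truth <- ref_truth()
  resid <- d$Y - t(vapply(seq_len(d$n), function(i)
    vapply(1:5, function(j) mean_visits(truth, C[i], d$R[i], j), numeric(1)),
    numeric(5)))
  expect_lt(abs(sd(resid) - 8), 0.15)
})

test_that("the harness gives an oracle estimator zero bias and full coverage", {
  cfg <- sim_config(n = 60, n_replicates = 8, base_seed = 5)
  st <- run_study(cfg, estimators = c("oracle", "moment"))
  res <- st$results
  orc <- res[res$estimator == "oracle", ]
  expect_equal(orc$bias, rep(0, 5))
  expect_equal(orc$se, rep(0, 5))
  expect_equal(orc$coverage, rep(1, 5))
  # RMSE identity holds for every cell
  expect_equal(res$rmse, sqrt(res$bias^2 + res$se^2), tolerance = 1e-12)
  expect_true(all(res$coverage >= 0 & res$coverage <= 1, na.rm = TRUE))
})

test_that("study checkpointing resumes without duplicating replicates", {
  cfg <- sim_config(n = 60, n_replicates = 6, base_seed = 8)
  ck <- tempfile(fileext = ".csv")
  st_half <- run_study(sim_config(n = 60, n_replicates = 3, base_seed = 8),
                       estimators = "moment", checkpoint = ck)
  st_full <- run_study(cfg, estimators = "moment", checkpoint = ck)
  expect_identical(nrow(st_full$estimates), 6L * 5L)
  st_direct <- run_study(cfg, estimators = "moment")
  expect_equal(st_full$results$bias, st_direct$results$bias, tolerance = 1e-12)
})

test_that("summaries report the relative-efficiency comparison", {
  fake <- structure(list(
    results = data.frame(
      estimator = rep(c("bayes", "iv"), each = 2),
      j = c(1, 2, 1, 2), n_replicates = 100,
      bias = 0, se = c(1, 0.8, 1, 1), rmse = c(1, 0.8, 1, 1),
      coverage = c(0.95, 0.95, 0.9, 0.9),
      mc_se_bias = 0.1, mc_se_se = 0.07, mc_se_coverage = 0.02),
    estimates = NULL, n_failed = 0L,
    truth = ref_truth(), config = sim_config()), class = "cace_study")
  s <- summarize_study(fake)
  expect_equal(s$se_reduction$pct_reduction, c(0, 20))
})

test_that("failed estimator runs are logged and skipped, not fatal", {
  cfg <- sim_config(n = 8, n_replicates = 2, base_seed = 3)
  # n = 8 often leaves an arm empty at some visit -> moment estimator fails
  expect_no_error({
    st <- suppressMessages(run_study(cfg, estimators = "moment"))
  })
})
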