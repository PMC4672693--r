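# Fixtures built in code: a tiny 3-subject dataset and the reference
# simulation truth used throughout the tests.

tiny_dataset <- function(T_days = NULL, Y = NULL) {
  if (is.null(Y)) Y <- rbind(c(12, 14), c(20, 21), c(25, 24))
  trial_data(R = c(1, 0, 0), D = c(0, 1, 2), Y = Y,
             visit_days = c(90, 180), T_days = T_days)
}

# brute-force population expectation of the per-visit ITT difference under
# the visit-scale causal model (enumerates compliance types; independent of
# the recursion it is used to check)
population_itt <- function(params) {
  m <- length(params$beta)
  vapply(seq_len(m), function(j) {
    e1 <- sum(vapply(0:m, function(c)
      params$gamma[c + 1] * mean_visits(params, c, 1L, j), numeric(1)))
    e0 <- sum(vapply(0:m, function(c)
      params$gamma[c + 1] * mean_visits(params, c, 0L, j), numeric(1)))
    e1 - e0
  }, numeric(1))
}

ref_truth <- function() sim_truth(sim_config())

expect_simplex <- function(p, tol = 1e-12) {
  expect_true(all(p >= 0))
  expect_lt(abs(sum(p) - 1), tol)
}
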