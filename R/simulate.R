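#' Configuration of the synthetic-trial generator
#'
#' The generator emulates a two-arm trial with control-arm crossover: latent
#' compliance types drawn from \code{gamma_true}, type-specific untreated
#' trajectories, an additive effect of time since treatment on the visit
#' scale, and independent (optionally exchangeable-correlated) Gaussian
#' errors.  The defaults reproduce the reference simulation design: 1000
#' replicates of size 300 with five visits, equal randomisation, types
#' \code{gamma = (1/9, 1/9, 1/9, 1/9, 1/9, 4/9)}, untreated means 10 for
#' types 0 and 5, \code{25 - j} for types 1 and 2, \code{22 - 3|j - 3|} for
#' types 3 and 4, effect curve \code{beta(j) = 2(6 - j)}, iid
#' \code{N(0, 8^2)} errors and no missing data.
#'
#' @param n subjects per replicate dataset.
#' @param m number of post-randomisation visits.
#' @param p_treat randomisation probability of the intervention arm.
#' @param gamma_true compliance-type probabilities over \code{0..m}.
#' @param alpha_rule function \code{(c, j) -> mean untreated outcome}.
#' @param beta_rule function \code{(k) -> effect k visits after treatment}.
#' @param error_sd residual standard deviation (outcome units).
#' @param error_correlation exchangeable residual correlation (default 0).
#' @param visit_days day grid (used only for bookkeeping and the day-scale
#'   model; the generative mean is on the visit scale).
#' @param n_replicates number of replicate datasets.
#' @param missingness_rate per-cell missing-completely-at-random probability
#'   (default 0, as in the reference design).
#' @param base_seed integer; replicate \code{r} is generated from a seed
#'   derived deterministically from \code{(base_seed, r)}.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n = 300L, m = 5L, p_treat = 0.5,
                       gamma_true = c(rep(1 / 9, 5), 4 / 9),
                       alpha_rule = NULL, beta_rule = NULL,
                       error_sd = 8, error_correlation = 0,
                       visit_days = c(90, 180, 365, 550, 730),
                       n_replicates = 1000L, missingness_rate = 0,
                       base_seed = 1L) {
  if (is.null(alpha_rule))
    alpha_rule <- function(c, j)
      ifelse(c %in% c(0L, m), 10, ifelse(c %in% c(1L, 2L), 25 - j,
                                         22 - 3 * abs(j - 3)))
  if (is.null(beta_rule)) beta_rule <- function(k) 2 * (6 - k)
  stopifnot(length(gamma_true) == m + 1L, all(gamma_true >= 0),
            abs(sum(gamma_true) - 1) < 1e-8, error_sd > 0,
            error_correlation >= 0, error_correlation < 1,
            missingness_rate >= 0, missingness_rate < 1,
            length(visit_days) == m)
  structure(list(n = as.integer(n), m = as.integer(m), p_treat = p_treat,
                 gamma_true = gamma_true, alpha_rule = alpha_rule,
                 beta_rule = beta_rule, error_sd = error_sd,
                 error_correlation = error_correlation,
                 visit_days = visit_days,
                 n_replicates = as.integer(n_replicates),
                 missingness_rate = missingness_rate,
                 base_seed = as.integer(base_seed)),
            class = "sim_config")
}

#' True model parameters implied by a simulation configuration
#'
#' @param config a [sim_config] object.
#' @return a [cace_params] object on the visit scale.
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m
  alpha <- outer(0:m, seq_len(m), Vectorize(config$alpha_rule))
  beta <- vapply(seq_len(m), config$beta_rule, numeric(1L))
  rho <- config$error_correlation
  Sigma <- config$error_sd^2 * ((1 - rho) * diag(m) + rho)
  cace_params(alpha, beta, config$gamma_true, Sigma,
              scale = "visits", visit_days = config$visit_days)
}

#' Generate one synthetic trial dataset
#'
#' Deterministic given \code{(config$base_seed, replicate)}.  Arms are
#' Bernoulli, compliance types categorical; control-arm subjects depart at
#' their type's visit (\code{D = C}), intervention-arm subjects are treated
#' at baseline (\code{D = 0}) and their type stays latent (attached as
#' attribute \code{"true_C"} for harness checks, never used by estimators).
#'
#' @param config a [sim_config] object.
#' @param replicate replicate index (1-based).
#' @return a [trial_data] object.
#' @export
generate_dataset <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.subseed(config$base_seed, replicate))
  n <- config$n
  m <- config$m
  truth <- sim_truth(config)
  R <- stats::rbinom(n, 1L, config$p_treat)
  C <- .sample_categorical_log(
    matrix(log(config$gamma_true), n, m + 1L, byrow = TRUE))
  D <- ifelse(R == 1L, 0L, C)
  Mu <- truth$alpha[C + 1L, , drop = FALSE]
  for (j in seq_len(m)) {
    elapsed <- ifelse(R == 1L, j, pmax(j - C, 0L))
    Mu[, j] <- Mu[, j] +
      ifelse(elapsed > 0L, truth$beta[pmax(elapsed, 1L)], 0)
  }
  E <- matrix(stats::rnorm(n * m), n, m)
  if (config$error_correlation > 0) E <- E %*% chol(stats::cov2cor(truth$Sigma))
  Y <- Mu + config$error_sd * E
  if (config$missingness_rate > 0)
    Y[matrix(stats::runif(n * m) < config$missingness_rate, n, m)] <- NA
  out <- trial_data(R = R, D = D, Y = Y, visit_days = config$visit_days)
  attr(out, "true_C") <- C
  out
}

#' Run the estimator-comparison study
#'
#' For each replicate dataset, fits the requested estimators and records
#' point estimates of the effect curve and whether each nominal 95% interval
#' covers the truth; aggregates to bias, empirical SE, RMSE and coverage per
#' estimator and visit, with Monte-Carlo standard errors.  The \code{bayes}
#' estimator reports posterior means and equal-tailed credible intervals;
#' \code{iv} reports 2SLS with cluster-robust Wald intervals; \code{moment}
#' has point estimates only; \code{oracle} returns the truth with degenerate
#' intervals (a self-test of the harness).
#'
#' @param config a [sim_config] object.
#' @param estimators subset of \code{c("moment", "bayes", "iv", "oracle")}.
#' @param mcmc_control a [cace_control] for the \code{bayes} estimator;
#'   default 2 chains of 3000 iterations with 500 burn-in (short conjugate
#'   chains mix quickly for this model).
#' @param prior a [cace_prior] for the \code{bayes} estimator.
#' @param checkpoint optional path; per-replicate estimates are appended to
#'   this CSV so an interrupted study resumes where it stopped.
#' @param verbose print progress every 25 replicates.
#' @return object of class \code{cace_study}: list with \code{results} (long
#'   data frame of metrics), \code{estimates}, \code{coverage_raw},
#'   \code{n_failed}, \code{truth}, \code{config}.
#' @export
run_study <- function(config, estimators = c("moment", "bayes", "iv"),
                      mcmc_control = cace_control(n_iter = 3000L,
                                                  n_burnin = 500L),
                      prior = cace_prior(), checkpoint = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  estimators <- match.arg(estimators,
                          c("moment", "bayes", "iv", "oracle"),
                          several.ok = TRUE)
  m <- config$m
  truth <- sim_truth(config)
  beta_true <- truth$beta
  nrep <- config$n_replicates

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint)
    if (!nrow(done)) done <- NULL
  }
  done_reps <- if (is.null(done)) integer(0L) else
    unique(done$replicate[done$complete == 1L])
  if (!is.null(done)) done <- done[done$replicate %in% done_reps, ]
  rows <- list()
  if (!is.null(done) && nrow(done)) rows <- list(done)
  n_failed <- 0L

  for (r in seq_len(nrep)) {
    if (r %in% done_reps) next
    d <- generate_dataset(config, r)
    rep_rows <- list()
    ok <- TRUE
    for (est in estimators) {
      res <- tryCatch(
        .study_fit_one(est, d, beta_true, config, mcmc_control, prior, r),
        error = function(e) {
          message("replicate ", r, ", estimator ", est, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(res)) { ok <- FALSE; n_failed <- n_failed + 1L; next }
      rep_rows[[est]] <- res
    }
    if (length(rep_rows)) {
      block <- do.call(rbind, rep_rows)
      block$complete <- as.integer(ok)
      rows[[length(rows) + 1L]] <- block
      if (!is.null(checkpoint))
        utils::write.table(block, checkpoint, sep = ",", append = file.exists(checkpoint),
                           col.names = !file.exists(checkpoint),
                           row.names = FALSE, qmethod = "double")
    }
    if (verbose && r %% 25L == 0L)
      message("replicate ", r, " of ", nrep, " done")
  }
  est_log <- do.call(rbind, rows)
  results <- .aggregate_study(est_log, beta_true)
  structure(list(results = results, estimates = est_log,
                 n_failed = n_failed, truth = truth, config = config),
            class = "cace_study")
}

.study_fit_one <- function(est, d, beta_true, config, mcmc_control, prior,
                           replicate) {
  m <- length(beta_true)
  out <- switch(est,
    moment = {
      b <- cace_moment(d)$beta
      data.frame(estimate = b, lower = NA_real_, upper = NA_real_)
    },
    iv = {
      f <- fit_iv(d)
      data.frame(estimate = unname(f$beta), lower = unname(f$ci[, 1L]),
                 upper = unname(f$ci[, 2L]))
    },
    bayes = {
      fit <- cace_bayes(d, model = "visits", prior = prior,
                        control = mcmc_control,
                        seed = .subseed(config$base_seed + 1L, replicate))
      s <- .beta_summary(fit)
      data.frame(estimate = s$mean, lower = s$lower, upper = s$upper)
    },
    oracle = data.frame(estimate = beta_true, lower = beta_true,
                        upper = beta_true))
  cbind(data.frame(replicate = replicate, estimator = est, j = seq_len(m)),
        out)
}

.beta_summary <- function(fit) {
  draws <- .pooled_draws(fit)
  sel <- paste0("beta[", seq_len(fit$m), "]")
  b <- draws[, sel, drop = FALSE]
  list(mean = colMeans(b),
       lower = apply(b, 2L, stats::quantile, 0.025),
       upper = apply(b, 2L, stats::quantile, 0.975))
}

.aggregate_study <- function(est_log, beta_true) {
  out <- list()
  for (est in unique(est_log$estimator)) {
    for (j in seq_along(beta_true)) {
      sub <- est_log[est_log$estimator == est & est_log$j == j, ]
      nr <- nrow(sub)
      err <- sub$estimate - beta_true[j]
      bias <- mean(err)
      se <- stats::sd(sub$estimate)
      cov_flags <- ifelse(is.na(sub$lower), NA,
                          sub$lower <= beta_true[j] &
                            beta_true[j] <= sub$upper)
      coverage <- mean(cov_flags)
      out[[length(out) + 1L]] <- data.frame(
        estimator = est, j = j, n_replicates = nr,
        bias = bias, se = se, rmse = sqrt(bias^2 + se^2),
        coverage = coverage,
        mc_se_bias = se / sqrt(nr),
        mc_se_se = se / sqrt(2 * (nr - 1)),
        mc_se_coverage = if (all(is.na(cov_flags))) NA_real_ else
          sqrt(coverage * (1 - coverage) / nr))
    }
  }
  do.call(rbind, out)
}

#' Summarise an estimator-comparison study
#'
#' @param study a \code{cace_study} object from [run_study()].
#' @return list with the metric table, the per-visit percentage reduction in
#'   empirical SE of the Bayesian estimator relative to IV (when both were
#'   run), and per-estimator coverage; class \code{summary.cace_study}.
#' @export
summarize_study <- function(study) {
  stopifnot(inherits(study, "cace_study"))
  res <- study$results
  se_reduction <- NULL
  if (all(c("bayes", "iv") %in% res$estimator)) {
    sb <- res[res$estimator == "bayes", ]
    si <- res[res$estimator == "iv", ]
    sb <- sb[order(sb$j), ]; si <- si[order(si$j), ]
    se_reduction <- data.frame(
      j = sb$j,
      se_bayes = sb$se, se_iv = si$se,
      pct_reduction = 100 * (1 - sb$se / si$se))
  }
  coverage <- stats::aggregate(coverage ~ estimator, data = res, FUN = mean,
                               na.action = stats::na.omit)
  structure(list(results = res, se_reduction = se_reduction,
                 coverage = coverage, n_failed = study$n_failed),
            class = "summary.cace_study")
}

#' @export
summary.cace_study <- function(object, ...) summarize_study(object)

#' @export
print.summary.cace_study <- function(x, digits = 3L, ...) {
  cat("Estimator comparison over simulation replicates\n\n")
  print(cbind(x$results[, c("estimator", "j", "n_replicates")],
              round(x$results[, c("bias", "se", "rmse", "coverage")],
                    digits)), row.names = FALSE)
  if (!is.null(x$se_reduction)) {
    cat("\nEmpirical SE of Bayesian estimator relative to IV:\n")
    print(round(x$se_reduction, digits), row.names = FALSE)
    cat("mean SE reduction:",
        round(mean(x$se_reduction$pct_reduction), 1L), "%\n")
  }
  if (x$n_failed) cat("\n", x$n_failed, " estimator runs failed\n", sep = "")
  invisible(x)
}

#' @export
print.cace_study <- function(x, ...) {
  print(summarize_study(x))
  invisible(x)
}

#' Write study results and the per-replicate estimate log as CSV
#'
#' @param study a \code{cace_study}.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "cace_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "study_metrics.csv")
  f2 <- file.path(dir, "study_estimates.csv")
  utils::write.csv(study$results, f1, row.names = FALSE)
  utils::write.csv(study$estimates, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
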