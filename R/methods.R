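# S3 methods for fitted cace_fit objects.

#' @export
print.cace_fit <- function(x, digits = 3L, ...) {
  cat("Bayesian longitudinal CACE model (", x$model, " scale)\n", sep = "")
  cat("  ", x$n, " subjects, ", x$m, " visits; ",
      length(x$chains), " chains x ", x$n_iter, " iterations (burn-in ",
      x$n_burnin, ", thin ", x$thin, ")\n", sep = "")
  s <- summary(x)
  sel <- grep("^beta\\[", rownames(s$table))
  cat("  posterior means of the effect curve:\n")
  print(round(s$table[sel, c("mean", "sd", "q2.5", "q97.5", "rhat")], digits))
  invisible(x)
}

#' Posterior summaries of a fitted longitudinal CACE model
#'
#' @param object a \code{cace_fit}.
#' @param ... unused.
#' @return object of class \code{summary.cace_fit}: list with \code{table}
#'   (mean, sd, equal-tailed 2.5/97.5 percentiles and Gelman--Rubin R-hat per
#'   parameter, post burn-in) and \code{max_rhat}.
#' @export
summary.cace_fit <- function(object, ...) {
  draws <- .pooled_draws(object)
  rhat <- gelman_rubin(object)
  tab <- cbind(mean = colMeans(draws),
               sd = apply(draws, 2L, stats::sd),
               q2.5 = apply(draws, 2L, stats::quantile, 0.025),
               q97.5 = apply(draws, 2L, stats::quantile, 0.975),
               rhat = rhat)
  structure(list(table = tab, max_rhat = max(rhat, na.rm = TRUE),
                 model = object$model),
            class = "summary.cace_fit")
}

#' @export
print.summary.cace_fit <- function(x, digits = 3L, ...) {
  print(round(x$table, digits))
  cat("max R-hat:", round(x$max_rhat, 4L), "\n")
  invisible(x)
}

#' @export
coef.cace_fit <- function(object, which = c("beta", "all"), ...) {
  which <- match.arg(which)
  mu <- colMeans(.pooled_draws(object))
  if (which == "beta") mu[grep("^beta\\[", names(mu))] else mu
}

#' @export
confint.cace_fit <- function(object, parm = "beta", level = 0.95, ...) {
  draws <- .pooled_draws(object)
  sel <- grep(paste0("^", parm, "\\["), colnames(draws), value = TRUE)
  if (!length(sel)) sel <- intersect(parm, colnames(draws))
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  t(apply(draws[, sel, drop = FALSE], 2L, stats::quantile, pr))
}

# Posterior-mean parameters as a cace_params object.
.posterior_params <- function(fit) {
  mu <- colMeans(.pooled_draws(fit))
  m <- fit$m
  pa <- (m + 1L) * m
  Sigma <- matrix(mu[pa + m + (m + 1L) + seq_len(m * m)], m, m)
  cace_params(matrix(mu[seq_len(pa)], m + 1L, m),
              mu[pa + seq_len(m)],
              {
                g <- mu[pa + m + seq_len(m + 1L)]
                g / sum(g)
              },
              (Sigma + t(Sigma)) / 2,
              scale = fit$model, visit_days = fit$dataset$visit_days)
}

#' @export
fitted.cace_fit <- function(object, ...) {
  params <- .posterior_params(object)
  d <- object$dataset
  m <- d$m
  out <- matrix(NA_real_, d$n, m)
  for (i in seq_len(d$n)) {
    if (d$R[i] == 0L) {
      out[i, ] <- vapply(seq_len(m), function(j)
        if (object$model == "visits")
          mean_visits(params, d$D[i], 0L, j)
        else mean_days(params, d$D[i], 0L, j,
                       T = if (is.null(d$T_days)) NULL else d$T_days[i]),
        numeric(1L))
    } else {
      # average the type-specific means over the compliance posterior
      p <- compliance_posterior(d$Y[i, ], 1L, 0L, params)
      mu_c <- t(vapply(0:m, function(cc)
        params$alpha[cc + 1L, ] + params$beta, numeric(m)))
      out[i, ] <- drop(p %*% mu_c)
    }
  }
  out
}

#' @export
residuals.cace_fit <- function(object, standardize = FALSE, ...) {
  r <- object$dataset$Y - fitted(object)
  if (standardize) {
    s <- sqrt(diag(.posterior_params(object)$Sigma))
    r <- sweep(r, 2L, s, "/")
  }
  r
}

#' Plot the posterior effect curve
#'
#' Posterior means of the causal effect of treatment against time since
#' treatment (visits, or days for the day-scale model), with equal-tailed
#' 95% credible bands.
#'
#' @param x a \code{cace_fit}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.cace_fit <- function(x, ...) {
  s <- summary(x)$table
  sel <- grep("^beta\\[", rownames(s))
  est <- s[sel, "mean"]; lo <- s[sel, "q2.5"]; hi <- s[sel, "q97.5"]
  xx <- if (x$model == "days") x$dataset$visit_days else seq_along(est)
  graphics::plot(xx, est, type = "b", pch = 16,
                 ylim = range(lo, hi, 0),
                 xlab = if (x$model == "days") "days since treatment"
                        else "visits since treatment",
                 ylab = "causal effect (outcome units)", ...)
  graphics::arrows(xx, lo, xx, hi, angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Simulate datasets from the fitted model
#'
#' Draws new trial datasets from the generative model at the posterior-mean
#' parameters (visit-scale mean structure), with the design of the original
#' data (same size, randomisation fraction and visit grid).
#'
#' @param object a \code{cace_fit}.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of [trial_data] objects.
#' @export
simulate.cace_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  params <- .posterior_params(object)
  d <- object$dataset
  m <- d$m
  if (is.null(seed)) seed <- 1L
  cfg <- sim_config(
    n = d$n, m = m, p_treat = mean(d$R),
    gamma_true = params$gamma,
    alpha_rule = function(c, j) params$alpha[c + 1L, j],
    beta_rule = function(k) params$beta[k],
    error_sd = sqrt(mean(diag(params$Sigma))),
    visit_days = d$visit_days, n_replicates = nsim, base_seed = seed)
  lapply(seq_len(nsim), function(r) generate_dataset(cfg, r))
}

#' Export posterior (or point-estimate) summaries in a common CSV schema
#'
#' Writes one row per parameter with columns \code{parameter, mean, sd,
#' q2.5, q97.5, rhat} (interval and R-hat columns empty for point
#' estimators).
#'
#' @param object a \code{cace_fit}, \code{cace_moment}, \code{itt_fit} or
#'   \code{iv_fit}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_estimates_csv <- function(object, path) {
  tab <- if (inherits(object, "cace_fit")) {
    s <- summary(object)$table
    data.frame(parameter = rownames(s), mean = s[, "mean"], sd = s[, "sd"],
               q2.5 = s[, "q2.5"], q97.5 = s[, "q97.5"], rhat = s[, "rhat"])
  } else if (inherits(object, "cace_moment")) {
    nm <- c(paste0("beta[", seq_along(object$beta), "]"),
            paste0("gamma[", seq_along(object$gamma) - 1L, "]"))
    data.frame(parameter = nm, mean = c(object$beta, object$gamma),
               sd = NA_real_, q2.5 = NA_real_, q97.5 = NA_real_,
               rhat = NA_real_)
  } else if (inherits(object, "itt_fit")) {
    data.frame(parameter = names(object$delta), mean = object$delta,
               sd = object$se, q2.5 = object$ci[, 1L],
               q97.5 = object$ci[, 2L], rhat = NA_real_)
  } else if (inherits(object, "iv_fit")) {
    data.frame(parameter = names(object$beta), mean = object$beta,
               sd = object$se, q2.5 = object$ci[, 1L],
               q97.5 = object$ci[, 2L], rhat = NA_real_)
  } else stop("unsupported object")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
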