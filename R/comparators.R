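#' Intention-to-treat analysis of a longitudinal trial
#'
#' Maximum-likelihood fit of the multivariate-normal arm-means model: a mean
#' per arm per visit with a common unstructured covariance, estimated under
#' missing-at-random by EM over the missing outcome coordinates.  The
#' per-visit ITT effect is the intervention-minus-control mean difference;
#' its standard error comes from the observed information of the mean
#' parameters at the fitted covariance (asymptotically orthogonal to the
#' covariance parameters in the normal family).
#'
#' @param dataset a [trial_data] object.
#' @param tol relative log-likelihood convergence tolerance for EM.
#' @param max_iter EM iteration cap.
#' @param level confidence level for the reported intervals.
#' @return object of class \code{itt_fit}: list with an [itt_params] object
#'   (\code{params}), \code{delta}, \code{se}, \code{ci}, \code{loglik},
#'   \code{em_iterations}.
#' @export
fit_itt <- function(dataset, tol = 1e-8, max_iter = 10000L, level = 0.95) {
  stopifnot(inherits(dataset, "trial_data"))
  Y <- dataset$Y
  R <- dataset$R
  m <- dataset$m
  n <- dataset$n
  if (!any(R == 1L) || !any(R == 0L)) stop("both arms must be present")
  pats <- split(seq_len(n), apply(is.na(Y), 1L, paste, collapse = ""))

  mu <- rbind(colMeans(Y[R == 0L, , drop = FALSE], na.rm = TRUE),
              colMeans(Y[R == 1L, , drop = FALSE], na.rm = TRUE))
  if (anyNA(mu)) stop("a visit has no observed outcomes in one arm")
  Sigma <- diag(pmax(apply(Y, 2L, stats::var, na.rm = TRUE), 1e-8), m)

  loglik_prev <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    Yhat <- Y
    Cacc <- matrix(0, m, m)
    ll <- 0
    for (p in pats) {
      obs <- which(!is.na(Y[p[1L], ]))
      mis <- setdiff(seq_len(m), obs)
      M <- mu[R[p] + 1L, , drop = FALSE]
      if (length(obs)) {
        Soo <- Sigma[obs, obs, drop = FALSE]
        U <- chol(Soo)
        ll <- ll + sum(.mvn_logdens(Y[p, obs, drop = FALSE] -
                                      M[, obs, drop = FALSE], U))
        if (length(mis)) {
          Smo <- Sigma[mis, obs, drop = FALSE]
          A <- Smo %*% chol2inv(U)
          Yhat[p, mis] <- M[, mis, drop = FALSE] +
            (Y[p, obs, drop = FALSE] - M[, obs, drop = FALSE]) %*% t(A)
          Cm <- Sigma[mis, mis, drop = FALSE] - A %*% t(Smo)
          Cacc[mis, mis] <- Cacc[mis, mis] + length(p) * Cm
        }
      } else {
        Yhat[p, ] <- M
        Cacc <- Cacc + length(p) * Sigma
      }
    }
    for (r in 0:1) {
      rows <- which(R == r)
      mu[r + 1L, ] <- colMeans(Yhat[rows, , drop = FALSE])
    }
    Dev <- Yhat - mu[R + 1L, , drop = FALSE]
    Sigma <- (crossprod(Dev) + Cacc) / n
    if (is.finite(loglik_prev) &&
        abs(ll - loglik_prev) <= tol * (abs(loglik_prev) + tol)) break
    if (it >= max_iter)
      stop("EM did not converge within ", max_iter,
           " iterations (last log-likelihood ", signif(ll, 8), ")")
    loglik_prev <- ll
  }

  # information of arm means at Sigma-hat, per observation pattern
  info <- list(matrix(0, m, m), matrix(0, m, m))
  for (p in pats) {
    obs <- which(!is.na(Y[p[1L], ]))
    if (!length(obs)) next
    Ioo <- chol2inv(chol(Sigma[obs, obs, drop = FALSE]))
    full <- matrix(0, m, m)
    full[obs, obs] <- Ioo
    for (r in 0:1) info[[r + 1L]] <- info[[r + 1L]] + sum(R[p] == r) * full
  }
  v <- diag(chol2inv(chol(info[[1L]]))) + diag(chol2inv(chol(info[[2L]])))
  delta <- mu[2L, ] - mu[1L, ]
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = delta - z * se, upper = delta + z * se)
  rownames(ci) <- paste0("delta", seq_len(m))
  structure(list(params = itt_params(mu[1L, ], delta, Sigma),
                 delta = stats::setNames(delta, rownames(ci)),
                 se = se, ci = ci, level = level,
                 loglik = ll, em_iterations = it),
            class = "itt_fit")
}

#' @export
print.itt_fit <- function(x, digits = 3L, ...) {
  cat("Intention-to-treat fit (multivariate normal, MAR via EM)\n")
  tab <- cbind(estimate = x$delta, se = x$se, x$ci)
  print(round(tab, digits))
  cat("log-likelihood:", format(x$loglik), " (", x$em_iterations,
      " EM iterations)\n", sep = "")
  invisible(x)
}

#' @export
coef.itt_fit <- function(object, ...) object$delta

#' @export
confint.itt_fit <- function(object, parm, level = 0.95, ...) object$ci

#' Two-stage least-squares IV estimate of the per-visit causal effect
#'
#' Pooled 2SLS over person-visit rows (available cases): outcome regressed on
#' visit fixed effects and endogenous indicators of having been treated
#' exactly \code{k} visits ago (\code{k = 1..m}), instrumented by the
#' randomised arm interacted with visit.  Randomisation is a valid instrument
#' because it shifts when treatment is received but, by the exclusion
#' restriction, affects the outcome only through treatment.  Standard errors
#' are cluster-robust by subject, since a subject contributes up to \code{m}
#' correlated rows.
#'
#' @param dataset a [trial_data] object.
#' @param level confidence level for the Wald intervals.
#' @return object of class \code{iv_fit}: list with \code{beta}, \code{se},
#'   \code{vcov}, \code{ci}, \code{n_rows}, \code{n_clusters}.
#' @export
fit_iv <- function(dataset, level = 0.95) {
  stopifnot(inherits(dataset, "trial_data"))
  m <- dataset$m
  n <- dataset$n
  long <- which(!dataset$missing_mask, arr.ind = TRUE)
  i <- long[, 1L]
  j <- long[, 2L]
  y <- dataset$Y[long]
  elapsed <- ifelse(dataset$R[i] == 1L, j, pmax(j - dataset$D[i], 0L))
  V <- outer(j, seq_len(m), "==") + 0          # visit dummies
  E <- outer(elapsed, seq_len(m), "==") + 0    # treated exactly k visits ago
  Z <- cbind(V, V * dataset$R[i])              # exogenous + instruments
  X <- cbind(V, E)
  colnames(X) <- c(paste0("visit", seq_len(m)), paste0("beta", seq_len(m)))
  colnames(Z) <- c(paste0("visit", seq_len(m)), paste0("armxvisit", seq_len(m)))

  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- colnames(Z)[qz$pivot[(qz$rank + 1L):ncol(Z)]]
    stop("rank-deficient first stage; collinear instrument columns: ",
         paste(bad, collapse = ", "))
  }
  Xhat <- qr.fitted(qz, X)
  A <- crossprod(Xhat, X)
  if (qr(A)$rank < ncol(X))
    stop("rank-deficient second stage; an endogenous indicator is not ",
         "identified by the instruments")
  Ainv <- solve(A)
  b <- drop(Ainv %*% crossprod(Xhat, y))
  names(b) <- colnames(X)
  e <- y - drop(X %*% b)

  scores <- rowsum(Xhat * e, i)                # cluster sums of X-hat' e
  meat <- crossprod(scores)
  G <- nrow(scores)
  k <- ncol(X)
  adj <- G / (G - 1) * (length(y) - 1) / (length(y) - k)
  Vb <- adj * Ainv %*% meat %*% t(Ainv)
  dimnames(Vb) <- list(names(b), names(b))

  sel <- m + seq_len(m)
  beta <- b[sel]
  se <- sqrt(diag(Vb)[sel])
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = beta - z * se, upper = beta + z * se)
  structure(list(beta = beta, se = se, vcov = Vb[sel, sel], ci = ci,
                 coefficients = b, level = level,
                 n_rows = length(y), n_clusters = G),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, digits = 3L, ...) {
  cat("Two-stage least-squares CACE estimates",
      "(cluster-robust by subject)\n")
  print(round(cbind(estimate = x$beta, se = x$se, x$ci), digits))
  cat(x$n_rows, "person-visit rows,", x$n_clusters, "clusters\n")
  invisible(x)
}

#' @export
coef.iv_fit <- function(object, ...) object$beta

#' @export
vcov.iv_fit <- function(object, ...) object$vcov

#' @export
confint.iv_fit <- function(object, parm, level = 0.95, ...) object$ci
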