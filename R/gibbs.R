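#' Prior specification for the Bayesian longitudinal CACE model
#'
#' Independent zero-mean normal priors with a common large variance on every
#' untreated-mean and effect coefficient, an inverse-Wishart prior on the
#' residual covariance and a Dirichlet prior on the compliance-type
#' probabilities (the type model is saturated, so a proper prior is needed
#' for the Gibbs draws).
#'
#' @param coef_variance prior variance of each \code{alpha} and \code{beta}
#'   coefficient, on the squared outcome scale.  The default \code{1e6} is
#'   effectively flat for outcomes measured in tens of units.
#' @param wishart_df inverse-Wishart degrees of freedom; default \code{m + 2},
#'   the smallest integer value giving a finite prior mean.
#' @param wishart_scale inverse-Wishart scale matrix \code{Omega}; default
#'   identity.  Estimates are insensitive to this choice over several orders
#'   of magnitude.
#' @param gamma_conc Dirichlet concentration(s) for the type probabilities;
#'   default symmetric 1 (uniform on the simplex).
#' @return object of class \code{cace_prior}.
#' @export
cace_prior <- function(coef_variance = 1e6, wishart_df = NULL,
                       wishart_scale = NULL, gamma_conc = 1) {
  stopifnot(coef_variance > 0, all(gamma_conc > 0))
  structure(list(coef_variance = coef_variance, wishart_df = wishart_df,
                 wishart_scale = wishart_scale, gamma_conc = gamma_conc),
            class = "cace_prior")
}

#' Chain configuration for the Gibbs sampler
#'
#' @param n_iter iterations per chain.  The default (100000, with 10000
#'   burn-in and two chains) matches a conservative production run; short
#'   exploratory runs of a few thousand iterations mix well for this model
#'   because every update is a conjugate draw.
#' @param n_burnin burn-in iterations discarded by summaries.
#' @param n_chains number of chains (at least 2 for convergence diagnostics).
#' @param thin keep every \code{thin}-th iteration.
#' @param seeds optional integer seed per chain.
#' @param init optional list (recycled over chains) of initial values, each a
#'   list with scalars or full-size \code{alpha}, \code{beta}, and optionally
#'   \code{C} (initial latent type for intervention-arm subjects).  The
#'   defaults start the two chains from dispersed points
#'   (\code{alpha = 20, beta = -10} and \code{alpha = 10, beta = -5}, both
#'   with \code{C = 1}).
#' @param keep_compliance store the imputed compliance types per kept
#'   iteration (can be switched off for very large datasets).
#' @param use_compiled use the compiled sampler for complete-data fits
#'   (datasets with missing outcomes always use the reference R
#'   implementation).  Both paths are deterministic given the seed; they
#'   consume the RNG stream differently, so their draws are not
#'   draw-for-draw identical.
#' @return object of class \code{cace_control}.
#' @export
cace_control <- function(n_iter = 100000L, n_burnin = 10000L, n_chains = 2L,
                         thin = 1L, seeds = NULL, init = NULL,
                         keep_compliance = TRUE, use_compiled = TRUE) {
  stopifnot(n_iter >= 1L, n_burnin >= 0L, n_burnin < n_iter, n_chains >= 1L,
            thin >= 1L)
  if (!is.null(seeds) && length(seeds) != n_chains)
    stop("need one seed per chain")
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seeds = seeds, init = init,
                 keep_compliance = isTRUE(keep_compliance),
                 use_compiled = isTRUE(use_compiled)),
            class = "cace_control")
}

.default_inits <- list(list(alpha = 20, beta = -10, C = 1L),
                       list(alpha = 10, beta = -5, C = 1L))

#' Posterior probabilities of the latent compliance type
#'
#' For a control-arm subject the type equals the observed departure visit.
#' For an intervention-arm subject the type is latent and its conditional
#' distribution given the current parameters is multinomial, with
#' probabilities proportional to \code{gamma(c)} times the multivariate
#' normal density of the observed outcome coordinates under type \code{c}
#' (intervention-arm subjects are treated at baseline, so their mean under
#' type \code{c} is \code{alpha(c, j) + beta(j)} at visit \code{j} on either
#' time scale).  Computed in log space, so near-underflow likelihoods still
#' renormalise cleanly.
#'
#' @param y length-\code{m} outcome vector, \code{NA} = missing.
#' @param r arm indicator.
#' @param d observed departure visit (used when \code{r = 0}).
#' @param params a [cace_params] object.
#' @return probability vector over types \code{0..m} (sums to 1).
#' @export
compliance_posterior <- function(y, r, d, params) {
  stopifnot(inherits(params, "cace_params"))
  m <- length(params$beta)
  if (r == 0L) {
    p <- numeric(m + 1L)
    p[d + 1L] <- 1
    return(p)
  }
  obs <- which(!is.na(y))
  if (!length(obs)) return(params$gamma / sum(params$gamma))
  U <- chol(params$Sigma[obs, obs, drop = FALSE])
  logd <- vapply(0:m, function(cc) {
    mu <- params$alpha[cc + 1L, ] + params$beta
    .mvn_logdens(matrix(y[obs] - mu[obs], 1L), U)
  }, numeric(1L))
  lp <- log(params$gamma) + logd
  lp <- lp - max(lp[is.finite(lp)])
  p <- exp(lp)
  p / sum(p)
}

#' Conditional-normal imputation of missing outcome coordinates
#'
#' Draws the missing coordinates of a multivariate-normal outcome vector from
#' their conditional distribution given the observed coordinates, the current
#' mean and covariance; observed coordinates are returned untouched.  If all
#' coordinates are missing, the full vector is drawn from \code{N(mu, Sigma)}.
#'
#' @param y outcome vector with \code{NA} for missing coordinates.
#' @param mu current mean vector.
#' @param Sigma current covariance.
#' @return completed numeric vector.
#' @export
impute_missing_outcomes <- function(y, mu, Sigma) {
  mis <- which(is.na(y))
  if (!length(mis)) return(y)
  obs <- which(!is.na(y))
  if (!length(obs)) {
    U <- chol(Sigma)
    return(mu + drop(crossprod(U, stats::rnorm(length(mu)))))
  }
  Soo <- Sigma[obs, obs, drop = FALSE]
  Smo <- Sigma[mis, obs, drop = FALSE]
  A <- Smo %*% chol2inv(chol(Soo))
  cmean <- mu[mis] + drop(A %*% (y[obs] - mu[obs]))
  cvar <- Sigma[mis, mis, drop = FALSE] - A %*% t(Smo)
  U <- chol((cvar + t(cvar)) / 2)
  y[mis] <- cmean + drop(crossprod(U, stats::rnorm(length(mis))))
  y
}

# ---------------------------------------------------------------------------
# Design bookkeeping.  The mean of subject i is  alpha[C_i + 1, ] + B_i beta,
# where the m x m weight matrix B_i maps the effect grid onto visits.  B_i is
# fixed over iterations (it depends on arm and, for controls, the observed
# departure), so subjects are grouped into design cells (C, B-pattern); only
# the cell membership of intervention-arm subjects changes as C is imputed.

.build_design <- function(dataset, model) {
  m <- dataset$m
  n <- dataset$n
  grid <- dataset$visit_days
  Bs <- list()
  key <- character(0L)
  add_B <- function(B, k) {
    i <- match(k, key)
    if (!is.na(i)) return(i)
    Bs[[length(Bs) + 1L]] <<- B
    key[length(key) + 1L] <<- k
    length(Bs)
  }
  id_trt <- add_B(diag(m), "treated@0")
  bpat <- integer(n)
  for (i in seq_len(n)) {
    if (dataset$R[i] == 1L) { bpat[i] <- id_trt; next }
    cc <- dataset$D[i]
    if (model == "visits") {
      B <- matrix(0, m, m)
      for (j in seq_len(m)) if (cc < j) B[j, j - cc] <- 1
      bpat[i] <- add_B(B, paste0("v", cc))
    } else {
      Ti <- if (!is.null(dataset$T_days) && !is.na(dataset$T_days[i]) &&
                is.finite(dataset$T_days[i])) dataset$T_days[i]
            else if (cc == 0L) 0 else if (cc >= m) Inf else grid[cc]
      if (is.infinite(Ti)) {
        bpat[i] <- add_B(matrix(0, m, m), "never")
      } else {
        B <- .beta_day_weights(grid, grid - Ti)
        bpat[i] <- add_B(B, paste0("d", signif(Ti, 12)))
      }
    }
  }
  # missingness patterns
  pat_key <- apply(dataset$missing_mask, 1L, paste, collapse = "")
  pats <- lapply(split(seq_len(n), pat_key), function(rows) {
    list(rows = rows, mis = which(dataset$missing_mask[rows[1L], ]),
         obs = which(!dataset$missing_mask[rows[1L], ]))
  })
  p_alpha <- (m + 1L) * m
  list(m = m, n = n, Bs = Bs, bpat = bpat, pats = pats,
       p_alpha = p_alpha, p = p_alpha + m,
       treated_rows = which(dataset$R == 1L))
}

# m x p design matrix for cell (type c, B-pattern b): indicator of
# alpha(c, j) in visit-j row plus the beta weights.
.cell_design <- function(c, b, design) {
  m <- design$m
  X <- matrix(0, m, design$p)
  X[cbind(seq_len(m), (seq_len(m) - 1L) * (m + 1L) + c + 1L)] <- 1
  X[, design$p_alpha + seq_len(m)] <- design$Bs[[b]]
  X
}

# Conjugate draw of the stacked coefficient vector (alpha, beta) given
# complete data, complete types and the current covariance.  The normal
# equations are assembled per design cell from m x m blocks: the alpha block
# of type c couples only the indices of alpha(c, .), so the full p x p
# cross-product never needs to be formed from dense designs.  Types absent
# from the augmented data leave their alpha rows identified only by the
# prior; these draws fall back to the prior automatically and are counted.
.update_coefficients <- function(Ycomp, C, design, Sigma, prior) {
  m <- design$m
  p <- design$p
  pa <- design$p_alpha
  Sinv <- chol2inv(chol(Sigma))
  nb <- length(design$Bs) + 1L
  cell <- C * nb + design$bpat
  ids <- sort.int(unique(cell))
  idx <- match(cell, ids)
  ysum <- rowsum(Ycomp, idx, reorder = TRUE)
  ncell <- tabulate(idx, nbins = length(ids))
  SB <- lapply(design$Bs, function(B) Sinv %*% B)
  P <- matrix(0, p, p)
  q <- numeric(p)
  jb <- pa + seq_len(m)
  jstep <- (seq_len(m) - 1L) * (m + 1L)
  for (k in seq_along(ids)) {
    cid <- ids[k]
    ck <- cid %/% nb
    bk <- cid %% nb
    ii <- jstep + ck + 1L
    nk <- ncell[k]
    B <- design$Bs[[bk]]
    SBk <- SB[[bk]]
    P[ii, ii] <- P[ii, ii] + nk * Sinv
    P[ii, jb] <- P[ii, jb] + nk * SBk
    P[jb, jb] <- P[jb, jb] + nk * crossprod(B, SBk)
    sy <- Sinv %*% ysum[k, ]
    q[ii] <- q[ii] + sy
    q[jb] <- q[jb] + crossprod(B, sy)
  }
  P[jb, seq_len(pa)] <- t(P[seq_len(pa), jb])
  diag(P) <- diag(P) + 1 / prior$coef_variance
  cholP <- chol(P)
  mean_ <- backsolve(cholP, backsolve(cholP, q, transpose = TRUE))
  theta <- .rmvn_prec(mean_, cholP)
  absent <- setdiff(0:m, unique(C))
  list(alpha = matrix(theta[seq_len(pa)], m + 1L, m),
       beta = theta[jb],
       absent_types = absent)
}

# Inverse-Wishart draw of the residual covariance: df = prior df + n,
# scale = Omega + residual cross-product, so the conditional mean approaches
# the empirical residual covariance for large n.
.update_sigma <- function(resid, prior_df, prior_scale) {
  n <- nrow(resid)
  S <- if (n) crossprod(resid) else 0
  .rinvwishart(prior_df + n, prior_scale + S)
}

.update_gamma <- function(C, m, conc) {
  counts <- tabulate(C + 1L, nbins = m + 1L)
  .rdirichlet(rep_len(conc, m + 1L) + counts)
}

# ---------------------------------------------------------------------------

#' Fit the Bayesian longitudinal CACE model by Gibbs sampling
#'
#' Data augmentation over latent compliance types (intervention arm) and
#' missing-at-random outcomes, alternating with conjugate draws of the
#' coefficients (multivariate normal), the residual covariance (inverse
#' Wishart) and the type probabilities (Dirichlet).  Each iteration cycles:
#' impute \code{C} from its multinomial conditional using the observed
#' outcome coordinates; impute missing outcomes from their conditional
#' normal; draw \code{(alpha, beta)}; draw \code{Sigma}; draw \code{gamma}.
#'
#' @param dataset a [trial_data] object.
#' @param model \code{"visits"} (effect indexed by visits since treatment) or
#'   \code{"days"} (piecewise-linear effect in days since treatment; uses
#'   exact treatment days where recorded, otherwise the scheduled day of the
#'   departure visit).
#' @param prior a [cace_prior] object.
#' @param control a [cace_control] object.
#' @param seed optional integer; per-chain seeds are derived from it unless
#'   \code{control$seeds} is given.  Identical seeds give bit-identical
#'   chains.
#' @return object of class \code{cace_fit}; see [summary.cace_fit()],
#'   [coef.cace_fit()], [confint.cace_fit()], [gelman_rubin()].
#' @examples
#' cfg <- sim_config(n = 150, n_replicates = 1)
#' d <- generate_dataset(cfg, 1)
#' fit <- cace_bayes(d, control = cace_control(n_iter = 400, n_burnin = 100),
#'                   seed = 1)
#' coef(fit)
#' @export
cace_bayes <- function(dataset, model = c("visits", "days"),
                       prior = cace_prior(), control = cace_control(),
                       seed = NULL) {
  stopifnot(inherits(dataset, "trial_data"), inherits(prior, "cace_prior"),
            inherits(control, "cace_control"))
  model <- match.arg(model)
  m <- dataset$m
  n <- dataset$n
  wdf <- if (is.null(prior$wishart_df)) m + 2L else prior$wishart_df
  if (wdf < m) stop("wishart_df must be at least m")
  Omega <- if (is.null(prior$wishart_scale)) diag(m) else
    as.matrix(prior$wishart_scale)
  if (!.is_square_pd(Omega)) stop("wishart_scale must be symmetric PD")

  seeds <- control$seeds
  if (is.null(seeds)) {
    if (is.null(seed)) seed <- 1L
    seeds <- vapply(seq_len(control$n_chains), .subseed,
                    integer(1L), base_seed = seed)
  }
  inits <- control$init
  if (is.null(inits)) inits <- .default_inits
  design <- .build_design(dataset, model)

  chains <- vector("list", control$n_chains)
  Cdraws <- vector("list", control$n_chains)
  absent_seen <- integer(0L)
  for (ch in seq_len(control$n_chains)) {
    ini <- inits[[(ch - 1L) %% length(inits) + 1L]]
    res <- .run_one_chain(dataset, design, model, prior, wdf, Omega, control,
                          ini, seeds[ch])
    chains[[ch]] <- res$draws
    Cdraws[[ch]] <- res$Cdraws
    absent_seen <- union(absent_seen, res$absent_types)
  }
  if (length(absent_seen))
    warning("compliance type(s) ", paste(sort(absent_seen), collapse = ", "),
            " were absent from the augmented data in some iterations; ",
            "their alpha coefficients fall back to the prior there")
  structure(list(chains = chains, compliance_draws = Cdraws,
                 model = model, m = m, n = n,
                 n_iter = control$n_iter, n_burnin = control$n_burnin,
                 thin = control$thin, seeds = seeds, prior = prior,
                 control = control, dataset = dataset,
                 param_names = .param_names(m)),
            class = "cace_fit")
}

.param_names <- function(m) {
  c(paste0("alpha[", rep(0:m, m), ",", rep(1:m, each = m + 1L), "]"),
    paste0("beta[", 1:m, "]"),
    paste0("gamma[", 0:m, "]"),
    paste0("Sigma[", rep(1:m, m), ",", rep(1:m, each = m), "]"))
}

.run_one_chain <- function(dataset, design, model, prior, wdf, Omega,
                           control, ini, chain_seed) {
  set.seed(chain_seed)
  m <- dataset$m
  n <- dataset$n
  Y <- dataset$Y
  mask <- dataset$missing_mask
  any_missing <- any(mask)
  trt <- design$treated_rows
  n1 <- length(trt)

  # initial state
  alpha <- matrix(0, m + 1L, m)
  alpha[] <- if (is.null(ini$alpha)) 0 else ini$alpha
  beta <- rep_len(if (is.null(ini$beta)) 0 else ini$beta, m)
  C <- dataset$D
  C[trt] <- rep_len(if (is.null(ini$C)) 1L else as.integer(ini$C), n1)
  gamma <- {
    g0 <- tabulate(dataset$D[dataset$R == 0L] + 1L, nbins = m + 1L)
    if (sum(g0) == 0L) rep(1 / (m + 1L), m + 1L) else {
      g <- g0 + 0.5
      g / sum(g)
    }
  }
  Sigma <- diag(pmax(apply(Y, 2L, stats::var, na.rm = TRUE), 1e-6), m)
  if (anyNA(Sigma)) Sigma <- diag(m)
  Ycomp <- Y
  if (any_missing) {
    for (j in seq_len(m)) {
      mu_j <- mean(Y[, j], na.rm = TRUE)
      Ycomp[mask[, j], j] <- if (is.na(mu_j)) 0 else mu_j
    }
  }

  # complete-data fits take the compiled path (same algorithm, same RNG
  # sources, different stream consumption order)
  if (!any_missing && isTRUE(control$use_compiled)) {
    res <- .gibbs_chain_complete_cpp(
      Y = Y, bpat = design$bpat, Bs = design$Bs, treated_rows = trt,
      C = C, alpha = alpha, beta = beta, gamma = gamma, Sigma = Sigma,
      coef_var = prior$coef_variance, wdf = wdf, Omega = Omega,
      gamma_conc = rep_len(prior$gamma_conc, m + 1L),
      n_iter = control$n_iter, thin = control$thin,
      keep_compliance = control$keep_compliance && n1 > 0L)
    draws <- res$draws
    colnames(draws) <- .param_names(m)
    Ckeep <- if (control$keep_compliance && n1) res$Cdraws else NULL
    return(list(draws = draws, Cdraws = Ckeep,
                absent_types = as.integer(res$absent_types)))
  }

  # missingness-pattern groups among intervention-arm rows (for C imputation)
  trt_pats <- lapply(design$pats, function(p) {
    rows <- intersect(p$rows, trt)
    if (!length(rows)) NULL else list(rows = rows, obs = p$obs)
  })
  trt_pats <- Filter(Negate(is.null), trt_pats)
  mis_pats <- Filter(function(p) length(p$mis) > 0L, design$pats)

  n_keep <- control$n_iter %/% control$thin
  draws <- matrix(NA_real_, n_keep, length(.param_names(m)))
  colnames(draws) <- .param_names(m)
  Ckeep <- if (control$keep_compliance && n1)
    matrix(NA_integer_, n_keep, n1) else NULL
  absent_types <- integer(0L)
  kept <- 0L
  Beff <- matrix(0, length(design$Bs), m)

  for (it in seq_len(control$n_iter)) {
    # --- 1. impute latent compliance types (intervention arm) -------------
    # p(c | y_obs) ~ gamma(c) N(y_obs; mu_c, Sigma_obs); the y'S^-1 y term is
    # constant in c, so only the linear and quadratic mean terms are needed.
    if (n1) {
      lg <- log(gamma)
      Mu <- t(t(alpha) + beta)                 # (m+1) x m type means, treated
      for (p in trt_pats) {
        obs <- p$obs
        rows <- p$rows
        if (!length(obs)) {
          lp <- matrix(lg, length(rows), m + 1L, byrow = TRUE)
        } else {
          Sinv_o <- chol2inv(chol(Sigma[obs, obs, drop = FALSE]))
          Mo <- Mu[, obs, drop = FALSE]
          MS <- Mo %*% Sinv_o                  # (m+1) x q
          quad <- 0.5 * rowSums(MS * Mo)
          lp <- Y[rows, obs, drop = FALSE] %*% t(MS)
          lp <- lp - matrix(quad - lg, nrow(lp), m + 1L, byrow = TRUE)
        }
        C[rows] <- .sample_categorical_log(lp)
      }
    }
    # per-pattern beta contribution for current beta
    for (b in seq_along(design$Bs)) Beff[b, ] <- design$Bs[[b]] %*% beta
    # --- 2. impute missing outcomes --------------------------------------
    if (any_missing) {
      for (p in mis_pats) {
        rows <- p$rows
        mis <- p$mis
        obs <- p$obs
        M <- alpha[C[rows] + 1L, , drop = FALSE] +
          Beff[design$bpat[rows], , drop = FALSE]
        if (!length(obs)) {
          U <- chol(Sigma)
          z <- matrix(stats::rnorm(length(rows) * m), length(rows), m)
          Ycomp[rows, ] <- M + z %*% U
        } else {
          Soo <- Sigma[obs, obs, drop = FALSE]
          Smo <- Sigma[mis, obs, drop = FALSE]
          A <- Smo %*% chol2inv(chol(Soo))
          cvar <- Sigma[mis, mis, drop = FALSE] - A %*% t(Smo)
          U <- chol((cvar + t(cvar)) / 2)
          cmean <- M[, mis, drop = FALSE] +
            (Y[rows, obs, drop = FALSE] - M[, obs, drop = FALSE]) %*% t(A)
          z <- matrix(stats::rnorm(length(rows) * length(mis)),
                      length(rows), length(mis))
          Ycomp[rows, mis] <- cmean + z %*% U
        }
      }
    }
    # --- 3. draw coefficients --------------------------------------------
    upd <- .update_coefficients(Ycomp, C, design, Sigma, prior)
    alpha <- upd$alpha
    beta <- upd$beta
    absent_types <- union(absent_types, upd$absent_types)
    # --- 4. draw covariance ----------------------------------------------
    for (b in seq_along(design$Bs)) Beff[b, ] <- design$Bs[[b]] %*% beta
    M <- alpha[C + 1L, , drop = FALSE] + Beff[design$bpat, , drop = FALSE]
    Sigma <- .update_sigma(Ycomp - M, wdf, Omega)
    # --- 5. draw type probabilities --------------------------------------
    gamma <- .update_gamma(C, m, prior$gamma_conc)

    if (!all(is.finite(beta)) || !all(is.finite(alpha)))
      stop("non-finite coefficient draw at iteration ", it)
    if (it %% control$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- c(alpha, beta, gamma, Sigma)
      if (!is.null(Ckeep)) Ckeep[kept, ] <- C[trt]
    }
  }
  list(draws = draws, Cdraws = Ckeep, absent_types = absent_types)
}

#' Gelman--Rubin potential scale reduction factor
#'
#' Classic multi-chain R-hat: the square root of the ratio of the pooled
#' variance estimate (weighted within- plus between-chain variance) to the
#' mean within-chain variance, per scalar parameter.  Values near 1 indicate
#' the chains agree; chains stuck at different constants give \code{Inf}.
#'
#' @param chains a \code{cace_fit}, or a list of equal-length numeric vectors
#'   or matrices (iterations by parameters), one per chain.
#' @param discard_burnin for \code{cace_fit} input, drop the burn-in
#'   iterations first (default \code{TRUE}).
#' @return named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(chains, discard_burnin = TRUE) {
  if (inherits(chains, "cace_fit"))
    chains <- .fit_draw_list(chains, discard_burnin)
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least two chains")
  chains <- lapply(chains, function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 1L) else as.matrix(x)
  })
  iters <- vapply(chains, nrow, integer(1L))
  if (length(unique(iters)) != 1L) stop("chains must have equal length")
  nit <- iters[1L]
  if (nit < 2L) stop("chains too short")
  means <- do.call(rbind, lapply(chains, colMeans))
  vars <- do.call(rbind, lapply(chains, function(x) apply(x, 2L, stats::var)))
  W <- colMeans(vars)
  B <- nit * apply(means, 2L, stats::var)
  varplus <- (nit - 1) / nit * W + B / nit
  rhat <- sqrt(varplus / W)
  rhat[W == 0 & B == 0] <- 1
  rhat[W == 0 & B > 0] <- Inf
  nm <- colnames(chains[[1L]])
  if (!is.null(nm)) names(rhat) <- nm
  rhat
}

.fit_draw_list <- function(fit, discard_burnin = TRUE) {
  drop_n <- if (discard_burnin) fit$n_burnin %/% fit$thin else 0L
  lapply(fit$chains, function(x)
    if (drop_n > 0L) x[-seq_len(drop_n), , drop = FALSE] else x)
}

# pooled post-burn-in draws
.pooled_draws <- function(fit) do.call(rbind, .fit_draw_list(fit))
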