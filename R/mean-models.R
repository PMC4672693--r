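#' Model parameters for the longitudinal CACE model
#'
#' Bundles the parameters of the principal-stratification outcome model:
#' untreated mean trajectories per compliance type, the causal effect curve
#' in time since treatment, the compliance-type probabilities and the
#' unstructured residual covariance.
#'
#' @param alpha \code{(m+1) x m} matrix; \code{alpha[c+1, j]} is the mean
#'   untreated outcome at visit \code{j} for compliance type \code{c}
#'   (types \code{0..m}).
#' @param beta length-\code{m} vector; \code{beta[k]} is the causal effect of
#'   treatment \code{k} visits (scale \code{"visits"}) or \code{t_k} days
#'   (scale \code{"days"}) after receiving it.
#' @param gamma length-\code{m+1} probability vector over compliance types.
#' @param Sigma \code{m x m} symmetric positive-definite covariance.
#' @param scale \code{"visits"} or \code{"days"}.
#' @param visit_days day grid, required for scale \code{"days"}.
#' @return object of class \code{cace_params}.
#' @export
cace_params <- function(alpha, beta, gamma, Sigma,
                        scale = c("visits", "days"), visit_days = NULL) {
  scale <- match.arg(scale)
  alpha <- as.matrix(alpha)
  m <- length(beta)
  if (!all(dim(alpha) == c(m + 1L, m)))
    stop("alpha must be (m+1) x m with m = length(beta)")
  if (length(gamma) != m + 1L || any(gamma < 0) ||
      abs(sum(gamma) - 1) > 1e-8)
    stop("gamma must be a probability vector of length m+1")
  if (!.is_square_pd(as.matrix(Sigma)))
    stop("Sigma must be symmetric positive definite")
  if (scale == "days" && (is.null(visit_days) || length(visit_days) != m))
    stop("scale 'days' requires a visit_days grid of length m")
  structure(list(alpha = alpha, beta = as.numeric(beta),
                 gamma = as.numeric(gamma), Sigma = as.matrix(Sigma),
                 scale = scale, visit_days = visit_days),
            class = "cace_params")
}

#' Expected outcome under the visit-scale causal model
#'
#' The mean outcome at visit \code{j} for a subject of compliance type
#' \code{c} in arm \code{r}: the type-specific untreated mean
#' \code{alpha(c, j)}, plus the effect \code{beta(k)} of treatment received
#' \code{k} visits earlier.  Intervention-arm subjects are treated just after
#' baseline (\code{k = j}); control-arm subjects of type \code{c < j} were
#' treated just after visit \code{c} (\code{k = j - c}); control-arm subjects
#' with \code{c >= j} are untreated, which embodies the exclusion restriction:
#' their mean does not depend on the arm they would have been randomised to.
#'
#' @param params a [cace_params] object with scale \code{"visits"}.
#' @param c compliance type in \code{0..m} (vectorised).
#' @param r arm indicator 0/1 (vectorised).
#' @param j visit in \code{1..m} (vectorised).
#' @return expected outcome(s).
#' @export
mean_visits <- function(params, c, r, j) {
  stopifnot(inherits(params, "cace_params"), params$scale == "visits")
  m <- length(params$beta)
  k <- pmax(length(c), length(r), length(j))
  c <- rep_len(as.integer(c), k); r <- rep_len(as.integer(r), k)
  j <- rep_len(as.integer(j), k)
  if (any(j < 1L | j > m)) stop("visit j out of range 1..m")
  if (any(c < 0L | c > m)) stop("compliance type out of range 0..m")
  elapsed <- ifelse(r == 1L, j, pmax(j - c, 0L))
  a <- params$alpha[cbind(c + 1L, j)]
  a + ifelse(elapsed > 0L, params$beta[pmax(elapsed, 1L)], 0)
}

#' Piecewise-linear effect curve in days since treatment
#'
#' Interpolates the effect grid \code{beta[k]} (anchored at effect 0 for
#' elapsed time 0) at an arbitrary number of days since treatment.  For
#' \code{u <= 0} the effect is 0; at \code{u = t_k} it is exactly
#' \code{beta[k]}; between grid days it is linear; beyond \code{t_m} it is
#' held at \code{beta[m]}.
#'
#' @param beta effect values at \code{visit_days}.
#' @param visit_days day grid \code{t_1..t_m}.
#' @param u days since treatment (vectorised).
#' @return effect value(s).
#' @export
beta_at_days <- function(beta, visit_days, u) {
  W <- .beta_day_weights(visit_days, u)
  drop(W %*% beta)
}

# Interpolation weights: row i gives the linear weights on beta(1..m) whose
# inner product with beta equals beta_at_days(beta, grid, u[i]).
.beta_day_weights <- function(visit_days, u) {
  m <- length(visit_days)
  grid <- c(0, visit_days)
  W <- matrix(0, length(u), m)
  for (i in seq_along(u)) {
    ui <- u[i]
    if (is.na(ui) || ui <= 0) next
    if (ui >= visit_days[m]) { W[i, m] <- 1; next }
    k <- findInterval(ui, grid, left.open = TRUE)  # t_{k-1} < u <= t_k
    lo <- grid[k]; hi <- grid[k + 1L]
    w_hi <- (ui - lo) / (hi - lo)
    W[i, k] <- W[i, k] + w_hi
    if (k > 1L) W[i, k - 1L] <- W[i, k - 1L] + (1 - w_hi)
  }
  W
}

#' Expected outcome under the day-scale causal model
#'
#' As [mean_visits()] but with the treatment effect evaluated at the exact
#' number of days between treatment and the visit, via [beta_at_days()].
#' Intervention-arm subjects are treated at day 0, so their effect at visit
#' \code{j} is exactly \code{beta(j)}.  A control-arm subject treated at day
#' \code{T <= t_j} contributes \code{beta_at_days(t_j - T)}; if untreated by
#' visit \code{j}, the mean is the untreated trajectory alone.
#'
#' @param params a [cace_params] object with scale \code{"days"}.
#' @param c compliance type in \code{0..m}.
#' @param r arm indicator 0/1.
#' @param j visit in \code{1..m}.
#' @param T exact treatment day under control (\code{Inf} = never); must fall
#'   in the interval implied by \code{c}.  Defaults to \code{t_c} ("just
#'   after" visit \code{c}) when not recorded.
#' @return expected outcome.
#' @export
mean_days <- function(params, c, r, j, T = NULL) {
  stopifnot(inherits(params, "cace_params"), params$scale == "days")
  grid <- params$visit_days
  m <- length(params$beta)
  if (j < 1L || j > m) stop("visit j out of range")
  a <- params$alpha[c + 1L, j]
  if (r == 1L) return(a + params$beta[j])
  if (is.null(T)) {
    # fall back to the scheduled day: treated "just after" visit c, so the
    # elapsed time at visit j is the scheduled t_j - t_c (t_0 = 0)
    if (c >= j) return(a)
    u <- grid[j] - (if (c == 0L) 0 else grid[c])
    return(a + beta_at_days(params$beta, grid, u))
  }
  if (is.finite(T) && days_to_grouped(T, grid) != c)
    stop("treatment day T inconsistent with compliance type c")
  if (is.infinite(T) || T > grid[j]) return(a)
  a + beta_at_days(params$beta, grid, grid[j] - T)
}

#' Intention-to-treat model parameters and mean
#'
#' The ITT model describes the observed arm means directly: the mean control
#' outcome at each visit plus a per-visit effect of randomisation, with an
#' unstructured covariance.
#'
#' @param control_mean length-\code{m} control-arm mean per visit.
#' @param delta length-\code{m} ITT effect per visit.
#' @param Sigma_itt \code{m x m} covariance.
#' @return object of class \code{itt_params}.
#' @export
itt_params <- function(control_mean, delta, Sigma_itt) {
  m <- length(control_mean)
  stopifnot(length(delta) == m, .is_square_pd(as.matrix(Sigma_itt)))
  structure(list(control_mean = as.numeric(control_mean),
                 delta = as.numeric(delta),
                 Sigma_itt = as.matrix(Sigma_itt)),
            class = "itt_params")
}

#' @rdname itt_params
#' @param params an \code{itt_params} object.
#' @param r arm indicator 0/1.
#' @param j visit in \code{1..m}.
#' @export
mean_itt <- function(params, r, j) {
  stopifnot(inherits(params, "itt_params"))
  m <- length(params$control_mean)
  if (any(j < 1L | j > m)) stop("visit j out of range")
  params$control_mean[j] + params$delta[j] * (r == 1L)
}
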