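#' Recursive moment estimator of the longitudinal CACE
#'
#' Closed-form identification of the compliance-type probabilities, the
#' effect curve and the untreated trajectories from arm-wise moments.  Type
#' probabilities come from the control arm (where the type is observed); the
#' per-visit intention-to-treat differences are then unravelled forward in
#' time, because the ITT contrast at visit \code{j} mixes the full effect
#' \code{beta(j)} with the diluting effects of earlier control-arm departures:
#' \deqn{ITT(j) = \beta(j) - \sum_{c < j} \gamma(c) \beta(j - c).}
#' Inverting this triangular system gives
#' \code{beta(1) = ITT(1) / (1 - gamma(0))} and, for \code{j > 1},
#' \code{beta(j) = [ITT(j) + sum_{c=1}^{j-1} gamma(c) beta(j-c)] / (1 - gamma(0))}.
#' Means are available-case (missing at random).  The estimator is fast and
#' has no likelihood machinery; use [cace_bayes()] or [fit_iv()] for
#' interval estimates.
#'
#' @param dataset a [trial_data] object.
#' @return object of class \code{cace_moment}: list with \code{gamma},
#'   \code{itt} (per-visit arm differences), \code{beta}, \code{alpha}
#'   (cells without data are \code{NA}), \code{m}.
#' @export
cace_moment <- function(dataset) {
  stopifnot(inherits(dataset, "trial_data"))
  g <- estimate_gamma(dataset)
  itt <- itt_differences(dataset)
  b <- recursive_beta(itt, g)
  a <- estimate_alpha(dataset, b)
  structure(list(gamma = g, itt = itt, beta = b, alpha = a, m = dataset$m),
            class = "cace_moment")
}

#' @export
print.cace_moment <- function(x, digits = 3L, ...) {
  cat("Recursive moment estimates of the longitudinal CACE\n")
  cat("  gamma (type probabilities):",
      paste(round(x$gamma, digits), collapse = " "), "\n")
  tab <- rbind(`ITT difference` = x$itt, `CACE beta` = x$beta)
  colnames(tab) <- paste0("visit", seq_len(x$m))
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.cace_moment <- function(object, ...) {
  stats::setNames(object$beta, paste0("beta", seq_along(object$beta)))
}

#' Empirical compliance-type probabilities from the control arm
#'
#' @param dataset a [trial_data] object with a non-empty control arm.
#' @return probability vector over types \code{0..m}.
#' @export
estimate_gamma <- function(dataset) {
  stopifnot(inherits(dataset, "trial_data"))
  ctrl <- dataset$D[dataset$R == 0L]
  if (!length(ctrl)) stop("no control-arm subjects: gamma is not identified")
  as.numeric(table(factor(ctrl, levels = 0:dataset$m))) / length(ctrl)
}

#' Per-visit intention-to-treat mean differences
#'
#' Available-case mean outcome difference (intervention minus control) at each
#' visit.
#'
#' @param dataset a [trial_data] object.
#' @return length-\code{m} numeric vector.
#' @export
itt_differences <- function(dataset) {
  stopifnot(inherits(dataset, "trial_data"))
  vapply(seq_len(dataset$m), function(j) {
    y <- dataset$Y[, j]
    y1 <- y[dataset$R == 1L & !dataset$missing_mask[, j]]
    y0 <- y[dataset$R == 0L & !dataset$missing_mask[, j]]
    if (!length(y1) || !length(y0))
      stop("visit ", j, " has no observed outcomes in one arm")
    mean(y1) - mean(y0)
  }, numeric(1L))
}

#' Recursive inversion of ITT differences into the CACE effect curve
#'
#' @param itt length-\code{m} ITT differences.
#' @param gamma type probabilities over \code{0..m} with \code{gamma[1] < 1}
#'   (some control subjects remain untreated past baseline).
#' @return length-\code{m} effect estimates \code{beta(1..m)}.
#' @export
recursive_beta <- function(itt, gamma) {
  m <- length(itt)
  stopifnot(length(gamma) == m + 1L)
  g0 <- gamma[1L]
  if (g0 >= 1 - 1e-12)
    stop("gamma(0) = 1: every control subject departs immediately, ",
         "the effect curve is not identified")
  beta <- numeric(m)
  for (j in seq_len(m)) {
    carry <- if (j > 1L)
      sum(gamma[2:j] * beta[(j - 1L):1L]) else 0  # gamma(c) * beta(j - c)
    beta[j] <- (itt[j] + carry) / (1 - g0)
  }
  beta
}

#' Untreated trajectories from control-arm type-specific means
#'
#' Within the control arm the compliance type is observed, so the mean at
#' visit \code{j} in type \code{c} estimates \code{alpha(c, j)} directly while
#' the subject is untreated (\code{c >= j}) and \code{alpha(c, j) +
#' beta(j - c)} after departure; the supplied \code{beta} is subtracted in
#' the latter cells.
#'
#' @param dataset a [trial_data] object.
#' @param beta effect-curve estimates, e.g. from [recursive_beta()].
#' @return \code{(m+1) x m} matrix; cells with no control-arm data are
#'   \code{NA}.
#' @export
estimate_alpha <- function(dataset, beta) {
  stopifnot(inherits(dataset, "trial_data"))
  m <- dataset$m
  out <- matrix(NA_real_, m + 1L, m,
                dimnames = list(paste0("c", 0:m), paste0("visit", 1:m)))
  for (c in 0:m) {
    rows <- dataset$R == 0L & dataset$D == c
    if (!any(rows)) next
    for (j in seq_len(m)) {
      y <- dataset$Y[rows, j]
      y <- y[!is.na(y)]
      if (!length(y)) next
      adj <- if (c < j) beta[j - c] else 0
      out[c + 1L, j] <- mean(y) - adj
    }
  }
  out
}
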