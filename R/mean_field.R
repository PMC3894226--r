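#' Mean synaptic input per population
#'
#' The mean summed input ("field") of a neuron in population \eqn{\alpha} is
#' \deqn{\mu_\alpha = \sum_\beta K_{\alpha\beta} J_{\alpha\beta} m_\beta,}
#' summing over the local populations and the external drive. The external
#' term is retained in dc mode (the constant replacement has the same mean).
#'
#' @param spec a \code{network_spec}.
#' @param m named activities \code{c(E=, I=)}; the external rate is taken
#'   from the spec.
#' @return named vector \code{c(E=, I=)} of mean inputs.
#' @export
mean_input <- function(spec, m) {
  m3 <- c(E = unname(m["E"]), I = unname(m["I"]), X = spec$m_X)
  mu <- as.numeric((spec$K * spec$J) %*% m3)
  names(mu) <- c("E", "I")
  mu
}

#' Variance of the synaptic input per population
#'
#' Treating all afferents as independent, the variances of the single binary
#' inputs add up:
#' \deqn{\sigma^2_\alpha = \sum_\beta K_{\alpha\beta} J^2_{\alpha\beta}
#'   a_\beta, \qquad a_\beta = m_\beta (1 - m_\beta).}
#' In dc external mode the external term is omitted (a constant drive has no
#' variance).
#'
#' @inheritParams mean_input
#' @param a optional named population-averaged single-neuron variances
#'   \code{c(E=, I=)}; defaults to \code{m (1 - m)}. Supplying them separately
#'   matters in heterogeneous networks, where the across-neuron rate spread
#'   reduces the average time variance.
#' @return named vector \code{c(E=, I=)} of input variances.
#' @export
input_variance <- function(spec, m, a = NULL) {
  if (is.null(a)) a <- m * (1 - m)
  a_x <- if (spec$external_mode == "dc") 0 else spec$m_X * (1 - spec$m_X)
  a3 <- c(E = unname(a["E"]), I = unname(a["I"]), X = a_x)
  v <- as.numeric((spec$K * spec$J^2) %*% a3)
  names(v) <- c("E", "I")
  v
}

#' Input variance corrected for correlations among afferents
#'
#' Pairwise covariances among the afferents contribute cross terms to the
#' variance of the summed input. Counting ordered pairs of distinct afferents
#' exactly -- \eqn{K(K-1)} within a source block, \eqn{K_\beta K_\gamma}
#' across blocks -- gives
#' \deqn{\sigma^2_\alpha = \sum_\beta K_{\alpha\beta} J^2_{\alpha\beta} a_\beta
#'   + \sum_{\beta\gamma} J_{\alpha\beta} J_{\alpha\gamma}
#'     (K_{\alpha\beta} K_{\alpha\gamma} - \delta_{\beta\gamma} K_{\alpha\beta})
#'     c_{\beta\gamma}.}
#' With all \eqn{c = 0} this reduces exactly to \code{\link{input_variance}};
#' with a fully correlated source block (\eqn{c_{\beta\beta} = a_\beta}) it
#' gives the variance \eqn{(KJ)^2 a} of \eqn{K} identical signals. External
#' sources are mutually uncorrelated (\eqn{c_{XX} = 0}) but their covariance
#' with the local populations enters the cross terms.
#'
#' @inheritParams input_variance
#' @param cs a \code{correlation_structure} (or list with entries
#'   \code{c_EE, c_EI, c_II, c_EX, c_IX}).
#' @return named vector \code{c(E=, I=)}.
#' @export
input_variance_with_correlations <- function(spec, m, cs, a = NULL) {
  need <- c("c_EE", "c_EI", "c_II", "c_EX", "c_IX")
  if (!all(need %in% names(cs)))
    stop("missing covariance entries: ", paste(setdiff(need, names(cs)), collapse = ", "))
  base <- input_variance(spec, m, a)
  cmat <- matrix(c(cs$c_EE, cs$c_EI, cs$c_EX,
                   cs$c_EI, cs$c_II, cs$c_IX,
                   cs$c_EX, cs$c_IX, 0), 3, 3,
                 dimnames = list(c("E", "I", "X"), c("E", "I", "X")))
  if (spec$external_mode == "dc") cmat[, "X"] <- cmat["X", ] <- 0
  out <- base
  for (tg in c("E", "I")) {
    KJ <- spec$K[tg, ] * spec$J[tg, ]
    cross <- sum(outer(KJ, KJ) * cmat) -
      sum(spec$K[tg, ] * spec$J[tg, ]^2 * diag(cmat))
    out[tg] <- base[tg] + cross
  }
  out
}

#' Stationary activation probability under Gaussian input
#'
#' With the summed input approximated as Gaussian with mean \eqn{\mu} and
#' variance \eqn{\sigma^2}, the probability that a neuron with hard threshold
#' \eqn{\theta} is found active is the upper Gaussian tail mass
#' \deqn{m = \Phi\left(\frac{\mu - \theta}{\sigma}\right).}
#' At \eqn{\sigma = 0} the deterministic limit \eqn{H(\mu - \theta)} is
#' returned.
#'
#' @param mu mean input.
#' @param sigma input standard deviation (>= 0).
#' @param theta threshold.
#' @return activation probability in [0, 1].
#' @export
expected_activity <- function(mu, sigma, theta) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  ifelse(sigma == 0, as.numeric(mu > theta),
         stats::pnorm((mu - theta) / sigma))
}

#' Susceptibility of the stationary activation
#'
#' Derivative of \code{\link{expected_activity}} with respect to the mean
#' input: the Gaussian density of the input evaluated at the threshold,
#' \deqn{S = \frac{1}{\sqrt{2\pi}\,\sigma}
#'   \exp\left(-\frac{(\theta-\mu)^2}{2\sigma^2}\right).}
#' S quantifies how strongly a small shift of the mean input moves the
#' population activity; it carries the self-regulation property
#' \eqn{S \propto 1/\sigma}, so the product \eqn{S\sigma} is invariant under
#' a joint rescaling of weights and fluctuations.
#'
#' @inheritParams expected_activity
#' @return susceptibility (>= 0).
#' @export
susceptibility <- function(mu, sigma, theta) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  stats::dnorm(theta, mean = mu, sd = sigma)
}

#' Balance-condition starting point for the mean activities
#'
#' In the balanced regime the mean input must stay close to threshold, so the
#' linear cancellation condition \eqn{\mu_\alpha(m) = \theta_\alpha} gives a
#' coarse estimate of the activity. Solves the 2x2 linear system in
#' \eqn{(m_E, m_I)} (the external term is a constant offset) and clips the
#' result into (0, 1); a singular system falls back to 0.5.
#'
#' @param spec a \code{network_spec}.
#' @return named vector \code{c(E=, I=)}.
#' @export
balance_guess <- function(spec) {
  A <- (spec$K * spec$J)[, c("E", "I")]
  b <- spec$theta - (spec$K * spec$J)[, "X"] * spec$m_X
  sv <- svd(A)$d
  if (sv[2] > 1e-10 * max(sv[1], 1)) {
    m <- tryCatch(solve(A, b), error = function(e) NULL)
  } else {
    # rank-deficient balance system (homogeneous rows or a decoupled
    # population): assume equal activities and solve each informative row
    est <- numeric(0)
    for (r in 1:2) if (abs(sum(A[r, ])) > 1e-12) est <- c(est, b[r] / sum(A[r, ]))
    m <- rep(if (length(est)) mean(est) else 0.5, 2)
  }
  if (is.null(m) || anyNA(m) || any(!is.finite(m))) {
    m <- c(0.5, 0.5)
  } else if (any(m <= 0 | m >= 1)) {
    warning("balance solution outside (0,1); clipped")
    m <- pmin(pmax(m, 1e-3), 1 - 1e-3)
  }
  names(m) <- c("E", "I")
  m
}

# Residual of the self-consistency condition m = Phi((mu - theta)/sigma),
# optionally with correlation-corrected input variance.
mf_residual <- function(spec, m, cs = NULL, a = NULL) {
  mu <- mean_input(spec, m)
  v <- if (is.null(cs)) input_variance(spec, m, a)
       else input_variance_with_correlations(spec, m, cs, a)
  v <- pmax(v, 0)
  m - expected_activity(mu, sqrt(v), spec$theta)
}

#' Solve the self-consistent mean-field equations
#'
#' Finds the simultaneous root of
#' \eqn{m_\alpha = \Phi((\mu_\alpha(m) - \theta_\alpha)/\sigma_\alpha(m))}
#' for the two local populations by a damped Newton iteration with a
#' finite-difference Jacobian, started from \code{\link{balance_guess}}.
#' Populations whose input variance vanishes are handled through the
#' deterministic limit; their susceptibility is reported as 0 (the Gaussian
#' density degenerates) and flagged.
#'
#' @param spec a \code{network_spec}.
#' @param tolerance convergence tolerance on the residual (max norm).
#' @param max_iter maximum Newton iterations.
#' @param cs optional \code{correlation_structure}: if supplied, the input
#'   variance includes the afferent-correlation correction, as used by the
#'   iterative scheme in \code{\link{iterate_self_consistent}}.
#' @param start optional starting activities.
#' @return object of class \code{mean_field_state}: activities \code{m},
#'   input moments \code{mu}, \code{sigma2}, susceptibilities \code{S},
#'   convergence flag, residual, and saturation flag.
#' @export
solve_mean_field <- function(spec, tolerance = 1e-10, max_iter = 200,
                             cs = NULL, start = NULL) {
  validate_spec(spec)
  m <- if (is.null(start)) balance_guess(spec) else as_named(start, c("E", "I"), "start")
  m <- pmin(pmax(m, 1e-6), 1 - 1e-6)
  conv <- FALSE
  r <- mf_residual(spec, m, cs)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tolerance) { conv <- TRUE; break }
    eps <- 1e-7
    Jm <- matrix(0, 2, 2)
    for (j in 1:2) {
      mp <- m; mp[j] <- mp[j] + eps
      Jm[, j] <- (mf_residual(spec, mp, cs) - r) / eps
    }
    step <- tryCatch(solve(Jm, r), error = function(e) r) # gradient-ish fallback
    lambda <- 1
    repeat {
      m_new <- pmin(pmax(m - lambda * step, 0), 1)
      r_new <- mf_residual(spec, m_new, cs)
      if (max(abs(r_new)) < max(abs(r)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    m <- m_new; r <- r_new
  }
  mu <- mean_input(spec, m)
  v <- if (is.null(cs)) input_variance(spec, m)
       else input_variance_with_correlations(spec, m, cs)
  v <- pmax(v, 0)
  S <- ifelse(v > 0, stats::dnorm(spec$theta, mu, sqrt(v)), 0)
  degenerate <- v == 0
  structure(list(
    m = m, mu = mu, sigma2 = v, S = S,
    a = m * (1 - m),
    converged = conv, residual = max(abs(r)),
    saturated = any(m < 1e-6 | m > 1 - 1e-6),
    degenerate_sigma = degenerate,
    iterations = it), class = "mean_field_state")
}

#' @export
print.mean_field_state <- function(x, ...) {
  cat("Mean-field state", if (!x$converged) "(NOT converged)" else "", "\n")
  tab <- rbind(m = x$m, mu = x$mu, sigma2 = x$sigma2, S = x$S)
  print(round(tab, 6))
  cat(sprintf("  residual %.2e after %d iterations\n", x$residual, x$iterations))
  invisible(x)
}
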