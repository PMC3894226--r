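het_source_moments <- function(spec, M, q) {
  # per source population: mean M, second moment q of time-averaged activity
  list(M = c(E = unname(M["E"]), I = unname(M["I"]), X = spec$m_X),
       q = c(E = unname(q["E"]), I = unname(q["I"]), X = spec$m_X^2))
}

#' Across-neuron variance of the mean input
#'
#' With binomially distributed in-degrees, the time-averaged input differs
#' from neuron to neuron for two independent reasons: the number of synapses
#' varies (binomial variance \eqn{N_\beta p(1-p)}, each synapse carrying the
#' mean activity \eqn{J M_\beta}), and each neuron samples a random subset of
#' source neurons whose time-averaged activities are themselves distributed
#' (variance \eqn{q_\beta - M_\beta^2} per sampled source). The two
#' contributions add:
#' \deqn{\Delta\mu^2_\alpha = \sum_\beta J^2_{\alpha\beta}\left[
#'   N_\beta p_{\alpha\beta}(1-p_{\alpha\beta}) M_\beta^2
#'   + K_{\alpha\beta}\,(q_\beta - M_\beta^2)\right].}
#' The in-degree term vanishes for fixed in-degrees and becomes negligible in
#' large networks; it can be dropped via \code{include_indegree_term}.
#'
#' @param spec a \code{network_spec}.
#' @param M named population means of the time-averaged activity.
#' @param q named second moments of the time-averaged activity.
#' @param include_indegree_term include the synapse-number variability term.
#' @return list with per-population \code{total}, \code{indegree} and
#'   \code{rate} contributions (each named \code{c(E=, I=)}).
#' @export
input_mean_variance_across_neurons <- function(spec, M, q,
                                               include_indegree_term = TRUE) {
  sm <- het_source_moments(spec, M, q)
  indeg <- rate <- c(E = 0, I = 0)
  for (tg in c("E", "I")) {
    varK <- if (spec$indegree_rule == "binomial")
      spec$N * spec$p[tg, ] * (1 - spec$p[tg, ]) else rep(0, 3)
    indeg[tg] <- sum(spec$J[tg, ]^2 * varK * sm$M^2)
    rate[tg] <- sum(spec$J[tg, ]^2 * spec$K[tg, ] * (sm$q - sm$M^2))
  }
  if (!include_indegree_term) indeg[] <- 0
  list(total = indeg + rate, indegree = indeg, rate = rate)
}

het_components <- function(spec, M, q, include_indegree_term = TRUE) {
  sm <- het_source_moments(spec, M, q)
  mu_bar <- as.numeric((spec$K * spec$J) %*% sm$M)
  names(mu_bar) <- c("E", "I")
  a_src <- sm$M - sm$q                       # population-averaged variance M - q
  if (spec$external_mode == "dc") a_src["X"] <- 0
  sigma2 <- as.numeric((spec$K * spec$J^2) %*% a_src)
  names(sigma2) <- c("E", "I")
  dmu <- input_mean_variance_across_neurons(spec, M, q, include_indegree_term)
  list(mu_bar = mu_bar, sigma2 = sigma2, dmu2 = dmu$total, dmu = dmu)
}

#' Distribution of time-averaged single-neuron activity
#'
#' Pushing the Gaussian distribution of per-neuron mean inputs
#' \eqn{\mu_i \sim N(\bar\mu, \Delta\mu^2)} through the single-neuron gain
#' \eqn{m(\mu) = \Phi((\mu - \theta)/\sigma)} yields the density of
#' time-averaged activities
#' \deqn{\rho(m) = \frac{\sigma}{\phi(\Phi^{-1}(m))}\,
#'  N\!\left(\theta + \sigma\,\Phi^{-1}(m);\ \bar\mu,\ \Delta\mu^2\right).}
#' It integrates to one, and its first two moments reproduce the
#' self-consistent \eqn{M} and \eqn{q}.
#'
#' @param mu_bar mean of the per-neuron mean input.
#' @param dmu2 across-neuron variance of the mean input.
#' @param sigma2 time variance of the input (single neuron).
#' @param theta threshold.
#' @param grid activity values at which to evaluate the density (optional).
#' @return list with the vectorized \code{density} function, the evaluated
#'   \code{grid}/\code{value} table, and the quadrature \code{moments}
#'   (integral, first, second).
#' @export
activity_distribution <- function(mu_bar, dmu2, sigma2, theta,
                                  grid = seq(1e-4, 1 - 1e-4, length.out = 401)) {
  sigma <- sqrt(sigma2)
  if (dmu2 <= 0) {
    m0 <- expected_activity(mu_bar, sigma, theta)
    dens <- function(m) ifelse(abs(m - m0) < 1e-12, Inf, 0)
    return(list(density = dens, grid = grid, value = dens(grid),
                moments = c(mass = 1, M = m0, q = m0^2), degenerate = TRUE))
  }
  dens <- function(m) {
    z <- stats::qnorm(m)
    stats::dnorm(theta + sigma * z, mean = mu_bar, sd = sqrt(dmu2)) *
      sigma / stats::dnorm(z)
  }
  # moments by quadrature in mu-space over +-8 sd (well-conditioned at the edges)
  lo <- mu_bar - 8 * sqrt(dmu2); hi <- mu_bar + 8 * sqrt(dmu2)
  g <- function(mu, pw) stats::pnorm((mu - theta) / sigma)^pw *
    stats::dnorm(mu, mu_bar, sqrt(dmu2))
  mom <- vapply(0:2, function(pw)
    stats::integrate(g, lo, hi, pw = pw, rel.tol = 1e-10)$value, numeric(1))
  list(density = dens, grid = grid, value = dens(grid),
       moments = c(mass = mom[1], M = mom[2], q = mom[3]), degenerate = FALSE)
}

het_residual <- function(spec, x, include_indegree_term) {
  x <- unname(x)
  M <- c(E = x[1], I = x[2]); q <- c(E = x[3], I = x[4])
  cmp <- het_components(spec, M, q, include_indegree_term)
  out <- numeric(4)
  for (k in 1:2) {
    tg <- c("E", "I")[k]
    sig <- sqrt(max(cmp$sigma2[tg], 1e-300))
    dmu2 <- max(cmp$dmu2[tg], 0)
    M_new <- expected_activity(cmp$mu_bar[tg], sqrt(sig^2 + dmu2), spec$theta[tg])
    if (dmu2 == 0) {
      q_new <- M_new^2
    } else {
      lo <- cmp$mu_bar[tg] - 8 * sqrt(dmu2); hi <- cmp$mu_bar[tg] + 8 * sqrt(dmu2)
      q_new <- stats::integrate(function(mu)
        stats::pnorm((mu - spec$theta[tg]) / sig)^2 *
          stats::dnorm(mu, cmp$mu_bar[tg], sqrt(dmu2)),
        lo, hi, rel.tol = 1e-12)$value
    }
    out[k] <- M[tg] - M_new
    out[2 + k] <- q[tg] - q_new
  }
  out
}

#' Self-consistent heterogeneous mean-field solution
#'
#' Solves the coupled moment system for networks with distributed in-degrees:
#' the population mean \eqn{M_\alpha} and second moment \eqn{q_\alpha} of the
#' time-averaged single-neuron activity must be consistent with the input
#' moments they generate (mean input, its across-neuron variance, and the
#' time variance built from the population-averaged single-neuron variance
#' \eqn{a = M - q}). A damped Newton iteration with finite-difference
#' Jacobian is started from the homogeneous solution. At zero heterogeneity
#' the solution reduces to the homogeneous mean field with \eqn{q = M^2}.
#'
#' @param spec a \code{network_spec} (meaningful for the binomial rule).
#' @param tolerance residual tolerance.
#' @param max_iter Newton iteration cap.
#' @param include_indegree_term see
#'   \code{\link{input_mean_variance_across_neurons}}.
#' @return object of class \code{heterogeneous_state} with \code{M},
#'   \code{q}, \code{a = M - q}, the input moments, and the rate-spread
#'   variance \code{q - M^2} per population.
#' @export
solve_heterogeneous <- function(spec, tolerance = 1e-10, max_iter = 100,
                                include_indegree_term = TRUE) {
  mf <- solve_mean_field(spec)
  x <- c(mf$m["E"], mf$m["I"], mf$m["E"]^2, mf$m["I"]^2)
  r <- het_residual(spec, x, include_indegree_term)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tolerance) { conv <- TRUE; break }
    eps <- 1e-7
    Jm <- matrix(0, 4, 4)
    for (j in 1:4) {
      xp <- x; xp[j] <- xp[j] + eps
      Jm[, j] <- (het_residual(spec, xp, include_indegree_term) - r) / eps
    }
    step <- tryCatch(solve(Jm, r), error = function(e) r)
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      xn[1:2] <- pmin(pmax(xn[1:2], 1e-9), 1 - 1e-9)
      xn[3:4] <- pmin(pmax(xn[3:4], xn[1:2]^2), xn[1:2])  # M^2 <= q <= M
      rn <- het_residual(spec, xn, include_indegree_term)
      if (max(abs(rn)) < max(abs(r)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    x <- xn; r <- rn
  }
  x <- unname(x)
  M <- c(E = x[1], I = x[2]); q <- c(E = x[3], I = x[4])
  cmp <- het_components(spec, M, q, include_indegree_term)
  structure(list(
    M = M, q = q, a = M - q, rate_variance = q - M^2,
    mu_bar = cmp$mu_bar, sigma2 = cmp$sigma2, dmu2 = cmp$dmu2,
    dmu_split = cmp$dmu, include_indegree_term = include_indegree_term,
    converged = conv, residual = max(abs(r)), iterations = it),
    class = "heterogeneous_state")
}

#' @export
print.heterogeneous_state <- function(x, ...) {
  cat("Heterogeneous mean-field state",
      if (!x$converged) "(NOT converged)" else "", "\n")
  tab <- rbind(M = x$M, q = x$q, `q - M^2` = x$rate_variance,
               a = x$a, dmu2 = x$dmu2)
  print(signif(tab, 6))
  invisible(x)
}
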