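#' Fit the full analytical theory of a binary network
#'
#' Central entry point: solves the self-consistent mean field, the
#' population-averaged covariance structure, and (by default) the iterative
#' scheme that feeds the finite-size correlations back into the input
#' variance, for one network specification. The returned object carries the
#' working point, the effective connectivity and its spectrum, and the five
#' pairwise covariances, and has \code{print}, \code{summary}, \code{coef},
#' \code{simulate} and \code{plot} methods.
#'
#' @param spec a \code{network_spec} (e.g. from \code{\link{fixture_spec}} or
#'   \code{\link{load_config}}).
#' @param iterate include finite-size correlations self-consistently.
#' @param tolerance convergence tolerance.
#' @return object of class \code{binnet_theory}.
#' @export
network_theory <- function(spec, iterate = TRUE, tolerance = 1e-10) {
  validate_spec(spec)
  if (iterate) {
    it <- iterate_self_consistent(spec, tolerance)
    mf <- it$mf; cs <- it$cs
  } else {
    mf <- solve_mean_field(spec, tolerance)
    cs <- solve_correlations(spec, mf)
    it <- NULL
  }
  eff <- effective_couplings(spec, mf)
  structure(list(spec = spec, mf = mf, cs = cs, eff = eff,
                 spectrum = spectrum(eff), iterate = it,
                 input_corr = list(
                   E = input_correlation_theory(spec, mf, cs, "E"),
                   I = input_correlation_theory(spec, mf, cs, "I"))),
            class = "binnet_theory")
}

#' @export
print.binnet_theory <- function(x, ...) {
  cat("Binary-network correlation theory\n")
  cat(sprintf("  N_E = %d, N_I = %d, N_X = %d (%s external drive)\n",
              x$spec$N["E"], x$spec$N["I"], x$spec$N["X"],
              x$spec$external_mode))
  cat(sprintf("  working point: m_E = %.4f, m_I = %.4f%s\n",
              x$mf$m["E"], x$mf$m["I"],
              if (!is.null(x$iterate))
                sprintf("  (finite-size corrected, %d sweeps)", x$iterate$iterations)
              else ""))
  cat("  eigenvalues of the effective connectivity:",
      paste(format(x$spectrum$eigenvalues, digits = 4), collapse = ", "), "\n")
  cat("  pairwise covariances:\n")
  print(signif(covariance_vector(x$cs), 4))
  invisible(x)
}

#' @export
summary.binnet_theory <- function(object, ...) {
  x <- object
  print(x)
  cat("\n  input statistics per population:\n")
  print(signif(rbind(mu = x$mf$mu, sigma2 = x$mf$sigma2, S = x$mf$S), 5))
  qe <- x$input_corr$E
  cat(sprintf(
    "\n  input covariance of an E pair: shared %.4g + corr %.4g = %.4g (cancellation %.1f%%)\n",
    qe$shared["total"], qe$corr["total"], qe$total,
    100 * (1 - abs(qe$total) / max(abs(qe$shared["total"]), abs(qe$corr["total"])))))
  invisible(x)
}

#' @export
coef.binnet_theory <- function(object, ...) {
  c(m_E = unname(object$mf$m["E"]), m_I = unname(object$mf$m["I"]),
    covariance_vector(object$cs))
}

#' Simulate from a fitted network theory
#'
#' Runs the stochastic binary-network simulator for the specification the
#' theory was solved on, one independent realization and dynamics seed per
#' replicate, and returns the empirical statistics for comparison against
#' the theoretical covariances.
#'
#' @param object a \code{binnet_theory}.
#' @param nsim number of independent simulation replicates.
#' @param seed base seed of the reproducibility registry.
#' @param duration simulated time (default 500 tau).
#' @param n_pairs sampled pairs per covariance label.
#' @param ... passed to \code{\link{simulator_config}}.
#' @return for \code{nsim = 1} an \code{empirical_statistics}; otherwise a
#'   list of them.
#' @export
simulate.binnet_theory <- function(object, nsim = 1, seed = 1,
                                   duration = 500 * object$spec$tau,
                                   n_pairs = 1000, ...) {
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    seeds <- seed * 100 + s * 3 + c(0, 1, 2)
    real <- build_realization(object$spec, seeds[1])
    pairs <- sample_pairs(object$spec, n_pairs, seeds[3])
    cfg <- simulator_config(duration = duration, seed = seeds[2],
                            measurement_interval = object$spec$tau / 10, ...)
    rec <- simulate_network(real, cfg, pairs = pairs, init = object$mf$m)
    out[[s]] <- pairwise_covariances(rec)
  }
  if (nsim == 1) out[[1]] else out
}

#' Plot theoretical against simulated covariances
#'
#' @param x a \code{binnet_theory}.
#' @param empirical optional \code{empirical_statistics} (e.g. from
#'   \code{simulate}); drawn as points with 2-SE error bars over the theory
#'   values.
#' @param ... passed to \code{barplot}.
#' @return invisibly, the bar midpoints.
#' @export
plot.binnet_theory <- function(x, empirical = NULL, ...) {
  v <- covariance_vector(x$cs)
  mid <- graphics::barplot(v, ylab = "pairwise covariance",
                           names.arg = names(v),
                           main = "population-averaged covariances", ...)
  if (!is.null(empirical)) {
    lb <- sub("^c_", "", names(empirical$covariance))
    idx <- match(lb, names(v))
    graphics::points(mid[idx], empirical$covariance, pch = 19)
    graphics::arrows(mid[idx], empirical$covariance - 2 * empirical$se,
                     mid[idx], empirical$covariance + 2 * empirical$se,
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(mid)
}
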