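#' Effective linearized population couplings
#'
#' Linearizing the hard-threshold gain around the stationary state, the
#' effective coupling from population \eqn{\beta} onto population
#' \eqn{\alpha} is
#' \deqn{w_{\alpha\beta} = S_\alpha K_{\alpha\beta} J_{\alpha\beta},}
#' the product of the target's susceptibility, the in-degree, and the
#' synaptic weight. The 2x2 local block (columns E, I) governs the feedback
#' on population fluctuations; its eigenvalues classify the dynamics
#' (stability requires real parts below 1, a complex pair signals
#' oscillatory population modes).
#'
#' @param spec a \code{network_spec}.
#' @param mf a \code{mean_field_state} from \code{\link{solve_mean_field}}.
#' @return object of class \code{effective_connectivity}: matrix \code{w}
#'   (2x3), local block \code{w_local}, its eigenvalues, and a stability
#'   flag.
#' @export
effective_couplings <- function(spec, mf) {
  w <- spec$K * spec$J * mf$S[c("E", "I")]
  dimnames(w) <- dimnames(spec$K)
  wl <- w[, c("E", "I")]
  ev <- eigen(wl, only.values = TRUE)$values
  structure(list(w = w, w_local = wl, eigenvalues = ev,
                 stable = all(Re(ev) < 1 - 1e-6)),
            class = "effective_connectivity")
}

as_w_matrix <- function(w) {
  if (inherits(w, "effective_connectivity")) w$w else as_block_matrix(w, "w")
}

stop_if_singular <- function(M, lhs_desc) {
  if (abs(det(M)) < 1e-12 * max(1, max(abs(M)))^nrow(M)) {
    ev <- eigen(M, only.values = TRUE)$values
    bad <- ev[which.min(abs(ev))]
    stop(sprintf(
      "%s is singular (eigenvalue %s of the assembled system is ~0); the working point sits at the stability boundary",
      lhs_desc, format(bad, digits = 4)))
  }
}

#' Covariance between local neurons and the external sources
#'
#' The population-averaged covariances \eqn{c_{EX}, c_{IX}} between a local
#' neuron and an external source obey a closed 2x2 linear system driven only
#' by the external fluctuations \eqn{a_X/N_X}:
#' \deqn{(2 I - W_L)\, (c_{EX}, c_{IX})^T = (w_{EX}, w_{IX})^T\, a_X/N_X,}
#' where \eqn{W_L} is the local block of the effective connectivity. They are
#' independent of all other correlations in the network.
#'
#' @param w effective connectivity (matrix 2x3 or
#'   \code{effective_connectivity}).
#' @param a_X variance of a single external source (0 in dc mode).
#' @param N_X external population size.
#' @return named vector \code{c(c_EX=, c_IX=)}.
#' @export
solve_external_block <- function(w, a_X, N_X) {
  w <- as_w_matrix(w)
  M <- 2 * diag(2) - w[, c("E", "I")]
  stop_if_singular(M, "external covariance system (2I - W)")
  cx <- solve(M, w[, "X"] * a_X / N_X)
  c(c_EX = unname(cx[1]), c_IX = unname(cx[2]))
}

#' Covariances among local neurons
#'
#' Population-averaged pairwise covariances between local neurons obey the
#' linear system obtained from the linearized master equation, averaged over
#' disjoint pairs of neurons:
#' \deqn{2 c_{\alpha\beta} = \sum_\gamma \left[ w_{\alpha\gamma}
#'  (c_{\gamma\beta} + \delta_{\gamma\beta} a_\beta/N_\beta)
#'  + w_{\beta\gamma}(c_{\gamma\alpha} + \delta_{\gamma\alpha}
#'    a_\alpha/N_\alpha)\right],}
#' with \eqn{\gamma} running over E, I, X and \eqn{c_{XX} = 0}. The system in
#' \eqn{(c_{EE}, c_{EI}, c_{II})} is driven by the intrinsic fluctuations
#' \eqn{a_E/N_E}, \eqn{a_I/N_I} of the local neurons and by the external
#' covariances \eqn{c_{EX}, c_{IX}}; the solution is linear in these sources,
#' so external-only and intrinsic-only solves superpose exactly.
#'
#' @param w effective connectivity.
#' @param a named variances \code{c(E=, I=)}.
#' @param N named sizes \code{c(E=, I=)}.
#' @param c_external named vector \code{c(c_EX=, c_IX=)}.
#' @return named vector \code{c(c_EE=, c_EI=, c_II=)}.
#' @export
solve_internal_block <- function(w, a, N, c_external) {
  w <- as_w_matrix(w)
  cEX <- unname(c_external["c_EX"]); cIX <- unname(c_external["c_IX"])
  A <- matrix(c(
    2 - 2 * w["E", "E"], -2 * w["E", "I"],              0,
    -w["I", "E"],        2 - w["E", "E"] - w["I", "I"], -w["E", "I"],
    0,                   -2 * w["I", "E"],              2 - 2 * w["I", "I"]),
    nrow = 3, byrow = TRUE)
  b <- c(
    2 * w["E", "X"] * cEX + 2 * w["E", "E"] * a["E"] / N["E"],
    w["E", "X"] * cIX + w["I", "X"] * cEX +
      w["E", "I"] * a["I"] / N["I"] + w["I", "E"] * a["E"] / N["E"],
    2 * w["I", "X"] * cIX + 2 * w["I", "I"] * a["I"] / N["I"])
  stop_if_singular(A, "internal covariance system")
  cc <- solve(A, b)
  c(c_EE = cc[1], c_EI = cc[2], c_II = cc[3])
}

#' Solve the population-averaged covariance structure
#'
#' Composes the external and internal block solves into the full zero-lag
#' covariance structure of the network: single-neuron variances
#' \eqn{a_\alpha = m_\alpha(1-m_\alpha)} and the five population-averaged
#' pairwise covariances (EE, EI, II, EX, IX). The \code{sources} argument
#' exposes the linear decomposition of the solution into the contribution
#' driven by the external fluctuations (\eqn{\propto a_X/N_X}) and the one
#' driven by the intrinsic fluctuations of the local populations
#' (\eqn{\propto a_E/N_E, a_I/N_I}); the two add up to the full solution.
#'
#' @param spec a \code{network_spec}.
#' @param mf a \code{mean_field_state}.
#' @param sources \code{"full"}, \code{"external"} (only the \eqn{a_X}
#'   drive) or \code{"intrinsic"} (only the local drives).
#' @param a optional override of the local variances (used by the
#'   heterogeneous theory, where \eqn{a = M - q}).
#' @return object of class \code{correlation_structure}.
#' @export
solve_correlations <- function(spec, mf,
                               sources = c("full", "external", "intrinsic"),
                               a = NULL) {
  sources <- match.arg(sources)
  eff <- effective_couplings(spec, mf)
  if (!eff$stable)
    stop(sprintf("unstable working point: eigenvalue with Re = %.4f >= 1",
                 max(Re(eff$eigenvalues))))
  if (is.null(a)) a <- mf$a
  a_x <- if (spec$external_mode == "dc") 0 else spec$m_X * (1 - spec$m_X)
  a_x_src <- if (sources == "intrinsic") 0 else a_x
  a_loc <- if (sources == "external") c(E = 0, I = 0) else a[c("E", "I")]
  cx <- solve_external_block(eff, a_x_src, spec$N["X"])
  ci <- solve_internal_block(eff, a_loc, spec$N[c("E", "I")], cx)
  structure(list(
    a = c(E = unname(a["E"]), I = unname(a["I"]), X = a_x),
    c_EE = unname(ci["c_EE"]), c_EI = unname(ci["c_EI"]),
    c_II = unname(ci["c_II"]),
    c_EX = unname(cx["c_EX"]), c_IX = unname(cx["c_IX"]),
    sources = sources, eff = eff), class = "correlation_structure")
}

#' @export
print.correlation_structure <- function(x, ...) {
  cat(sprintf("Covariance structure (%s sources)\n", x$sources))
  v <- covariance_vector(x)
  print(signif(v, 5))
  cat(sprintf("  variances a_E = %.4g, a_I = %.4g, a_X = %.4g\n",
              x$a["E"], x$a["I"], x$a["X"]))
  invisible(x)
}

#' Extract the five covariances as a named vector
#' @param cs a \code{correlation_structure}.
#' @return named numeric (EE, EI, II, EX, IX).
#' @export
covariance_vector <- function(cs) {
  c(EE = cs$c_EE, EI = cs$c_EI, II = cs$c_II, EX = cs$c_EX, IX = cs$c_IX)
}

#' Closed-form covariance of a purely inhibitory network
#'
#' For a single inhibitory population with effective self-coupling
#' \eqn{w = S K J < 0} and no external fluctuations, the general system
#' collapses to the scalar form
#' \deqn{c = \frac{w\, a/N}{1 - w},}
#' which is strictly negative and approaches \eqn{-a/N} in the strong
#' negative-feedback limit \eqn{w \to -\infty}.
#'
#' @param w scalar effective self-coupling (negative).
#' @param a single-neuron variance.
#' @param N population size.
#' @return scalar covariance.
#' @export
inhibitory_covariance <- function(w, a, N) {
  (w * a / N) / (1 - w)
}

#' Iterative mean-field scheme including finite-size correlations
#'
#' The plain mean-field solution neglects correlations among afferents when
#' computing the input variance. This scheme alternates (i) a covariance
#' solve at the current working point with (ii) a mean-field and
#' susceptibility re-solve using the correlation-corrected input variance
#' (\code{\link{input_variance_with_correlations}}), until the largest change
#' across all activities and covariances falls below \code{tolerance}. If the
#' plain alternation oscillates, the covariance update is damped by 0.5.
#'
#' @param spec a \code{network_spec}.
#' @param tolerance convergence tolerance (max absolute change).
#' @param max_iter maximum sweeps.
#' @return list with the converged \code{mf} and \code{cs}, the iteration
#'   count, a convergence flag, and the trajectory of maximal changes.
#' @export
iterate_self_consistent <- function(spec, tolerance = 1e-10, max_iter = 100) {
  mf <- solve_mean_field(spec, tolerance)
  cs <- solve_correlations(spec, mf)
  trace <- numeric(0)
  converged <- FALSE
  damp <- 1
  prev_delta <- Inf
  for (it in seq_len(max_iter)) {
    mf2 <- solve_mean_field(spec, tolerance, cs = cs, start = mf$m)
    cs_new <- solve_correlations(spec, mf2)
    if (damp < 1) {
      for (f in c("c_EE", "c_EI", "c_II", "c_EX", "c_IX"))
        cs_new[[f]] <- damp * cs_new[[f]] + (1 - damp) * cs[[f]]
    }
    delta <- max(abs(mf2$m - mf$m),
                 abs(covariance_vector(cs_new) - covariance_vector(cs)))
    trace <- c(trace, delta)
    mf <- mf2; cs <- cs_new
    if (delta < tolerance) { converged <- TRUE; break }
    if (delta > prev_delta && damp == 1) damp <- 0.5  # oscillation guard
    prev_delta <- delta
  }
  list(mf = mf, cs = cs, iterations = it, converged = converged, trace = trace)
}

#' Theoretical decomposition of the input covariance of a pair
#'
#' The covariance between the summed inputs of two neurons in population
#' \eqn{\alpha} splits into a contribution from shared afferents and one from
#' correlations among distinct afferents:
#' \deqn{q^{shared} = \sum_\beta J^2_{\alpha\beta}
#'   \frac{K^2_{\alpha\beta}}{N_\beta} a_\beta, \qquad
#'   q^{corr} = \sum_{\beta\gamma} J_{\alpha\beta} J_{\alpha\gamma}
#'   K_{\alpha\beta} K_{\alpha\gamma} c_{\beta\gamma},}
#' using the expected shared-afferent count \eqn{K^2/N} per source block.
#' Their sum equals the quadratic form
#' \eqn{\sum_{\beta\gamma} \kappa_\beta \kappa_\gamma C_{\beta\gamma}} with
#' \eqn{\kappa_\beta = K_{\alpha\beta} J_{\alpha\beta}} and
#' \eqn{C_{\beta\gamma} = \delta_{\beta\gamma} a_\beta/N_\beta +
#' c_{\beta\gamma}} the covariance of the population-averaged activities --
#' i.e. the total input covariance is exactly the variance of the
#' population-averaged input signal. In feedback-dominated networks both
#' contributions are large and of opposite sign while their sum stays small:
#' the suppression of population-rate fluctuations by negative feedback is
#' the same phenomenon as the cancellation of input correlations.
#'
#' @param spec a \code{network_spec}.
#' @param mf a \code{mean_field_state}.
#' @param cs a \code{correlation_structure}.
#' @param target target population of the pair (\code{"E"} or \code{"I"}).
#' @return list with per-class and aggregate \code{shared} and \code{corr}
#'   contributions (classes E, I, X plus local/external/total aggregates),
#'   the \code{total} input covariance, the independently computed
#'   variance of the population-averaged input \code{popavg_variance}, and
#'   the algebraic \code{identity_residual} between the two.
#' @export
input_correlation_theory <- function(spec, mf, cs, target = "E") {
  kap <- spec$K[target, ] * spec$J[target, ]
  a_x <- cs$a["X"]
  a3 <- c(E = unname(cs$a["E"]), I = unname(cs$a["I"]), X = unname(a_x))
  N3 <- spec$N
  cmat <- matrix(c(cs$c_EE, cs$c_EI, cs$c_EX,
                   cs$c_EI, cs$c_II, cs$c_IX,
                   cs$c_EX, cs$c_IX, 0), 3, 3,
                 dimnames = list(names(kap), names(kap)))
  shared_class <- spec$J[target, ]^2 * spec$K[target, ]^2 / N3 * a3
  corr_class <- as.numeric(cmat %*% kap) * kap  # row sums of kap_b kap_g c_bg
  names(corr_class) <- names(kap)
  agg <- function(v) c(v, local = unname(v["E"] + v["I"]),
                       external = unname(v["X"]), total = sum(v))
  q_shared <- agg(shared_class)
  q_corr <- agg(corr_class)
  total <- unname(q_shared["total"] + q_corr["total"])
  # same quantity through the population-average route (different arithmetic)
  Cpop <- cmat + diag(a3 / N3)
  popavg <- as.numeric(t(kap) %*% Cpop %*% kap)
  list(shared = q_shared, corr = q_corr, total = total,
       popavg_variance = popavg,
       identity_residual = total - popavg)
}
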