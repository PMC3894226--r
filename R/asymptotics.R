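local_block <- function(w) {
  if (inherits(w, "effective_connectivity")) return(w$w_local)
  w <- as.matrix(w)
  if (all(dim(w) == c(2, 3))) w <- w[, 1:2]
  if (!all(dim(w) == c(2, 2))) stop("need a 2x2 local block")
  dimnames(w) <- list(c("E", "I"), c("E", "I"))
  w
}

#' Spectral summary of the effective local connectivity
#'
#' Closed-form eigenvalues of the 2x2 local effective-connectivity block,
#' \deqn{\lambda_\pm = \frac{\mathrm{tr}}{2} \pm
#'   \sqrt{\left(\frac{w_{EE}-w_{II}}{2}\right)^2 + w_{EI} w_{IE}},}
#' together with the two structural parameters that control them
#' independently: the \emph{shift} (half trace), which translates both real
#' parts rigidly, and the \emph{split} (the discriminant), whose sign decides
#' between a real pair and a complex-conjugate pair (oscillatory population
#' modes, the PING route to gamma oscillations). Homogeneous connectivity --
#' weights depending only on the source type -- makes the two rows linearly
#' dependent, so the determinant and one eigenvalue are exactly zero: the
#' network has a feedback-free direction along which population fluctuations
#' are only damped by the neuronal time constant.
#'
#' @param w an \code{effective_connectivity}, or a 2x2 (local) or 2x3
#'   coupling matrix.
#' @return object of class \code{spectral_summary}: \code{eigenvalues}
#'   (possibly complex), \code{shift}, \code{split} (discriminant),
#'   \code{det}, \code{stable}, \code{oscillatory}, \code{degenerate}.
#' @export
spectrum <- function(w) {
  wl <- local_block(w)
  tr <- wl["E", "E"] + wl["I", "I"]
  dt <- wl["E", "E"] * wl["I", "I"] - wl["E", "I"] * wl["I", "E"]
  disc <- ((wl["E", "E"] - wl["I", "I"]) / 2)^2 + wl["E", "I"] * wl["I", "E"]
  root <- sqrt(as.complex(disc))
  ev <- tr / 2 + c(1, -1) * root
  if (disc >= 0) ev <- Re(ev)
  # degenerate rows: the zero eigenvalue is exact (keep the +/- root order)
  if (dt == 0) ev <- c(tr / 2 + abs(tr / 2), tr / 2 - abs(tr / 2))
  structure(list(
    eigenvalues = ev, shift = tr / 2, split = disc, det = dt,
    stable = all(Re(ev) < 1 - 1e-6),
    oscillatory = disc < 0,
    degenerate = dt == 0,
    w_local = wl), class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat("Effective-connectivity spectrum\n")
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 5), collapse = ", "), "\n")
  cat(sprintf("  shift %.5g, split %.5g, det %.5g; %s, %s\n",
              x$shift, x$split, x$det,
              if (x$stable) "stable" else "UNSTABLE",
              if (x$oscillatory) "oscillatory (complex pair)" else "non-oscillatory"))
  invisible(x)
}

#' External and intrinsic contributions to the covariances
#'
#' The linear covariance system is driven by two kinds of sources: the
#' fluctuations of the finite external population (\eqn{\propto a_X/N_X})
#' and the fluctuations generated by the stochastic updates of the local
#' neurons themselves (\eqn{\propto a_E/N_E, a_I/N_I}). Solving the system
#' with each source class alone splits the full solution additively,
#' \eqn{c = c^{ext} + c^{int}}, exactly at any network size.
#'
#' The diagonal single-cell term \eqn{a_\alpha/N_\alpha} that converts the
#' covariance of population-averaged signals into a pairwise covariance can
#' be attributed to either side; \code{self_term = "external"} (default)
#' groups it with the tracking contribution, which reproduces the
#' infinite-size limit of the external part
#' (\code{\link{limit_inhomogeneous}}) and makes the intrinsic part decay
#' faster than \eqn{1/N} for invertible connectivity, while
#' \code{"intrinsic"} attributes it to the locally generated fluctuations,
#' so that dc-mode external drive yields an exactly vanishing external part.
#'
#' @param spec a \code{network_spec}.
#' @param mf optional \code{mean_field_state} (solved if missing).
#' @param self_term attribution of the diagonal \eqn{a/N} term.
#' @return object of class \code{limit_decomposition} with covariance
#'   vectors \code{full}, \code{external}, \code{intrinsic} and the maximal
#'   additivity residual.
#' @export
decompose_contributions <- function(spec, mf = NULL,
                                    self_term = c("external", "intrinsic")) {
  self_term <- match.arg(self_term)
  if (is.null(mf)) mf <- solve_mean_field(spec)
  full <- solve_correlations(spec, mf)
  ext <- covariance_vector(solve_correlations(spec, mf, sources = "external"))
  int <- covariance_vector(solve_correlations(spec, mf, sources = "intrinsic"))
  if (self_term == "external") {
    shift <- c(EE = unname(mf$a["E"] / spec$N["E"]),
               EI = 0,
               II = unname(mf$a["I"] / spec$N["I"]), EX = 0, IX = 0)
    ext <- ext - shift
    int <- int + shift
  }
  structure(list(full = covariance_vector(full), external = ext,
                 intrinsic = int, self_term = self_term,
                 residual = max(abs(ext + int - covariance_vector(full)))),
            class = "limit_decomposition")
}

#' @export
print.limit_decomposition <- function(x, ...) {
  cat(sprintf("Covariance decomposition (self term -> %s)\n", x$self_term))
  print(signif(rbind(full = x$full, external = x$external,
                     intrinsic = x$intrinsic), 5))
  invisible(x)
}

structural_kappa <- function(spec) {
  kap <- spec$K * spec$J
  list(local = kap[, c("E", "I")], x = kap[, "X"])
}

#' Leading-order covariances for invertible connectivity
#'
#' In the limit of large networks with an invertible local coupling matrix,
#' the covariances are dominated by the tracking of the external signal.
#' With \eqn{u = (KJ)_{local}^{-1} (KJ)_X} (susceptibilities cancel), the
#' leading \eqn{1/N} term is
#' \deqn{c^{ext}_{\alpha\beta} = u_\alpha u_\beta \frac{a_X}{N_X}
#'   - \delta_{\alpha\beta}\frac{a_\alpha}{N_\alpha}, \qquad
#'   c_{\alpha X} = -u_\alpha \frac{a_X}{N_X}.}
#' The locally generated contribution is a higher-order correction that
#' vanishes faster than \eqn{1/N}. Refuses degenerate (homogeneous)
#' connectivity, for which this limit does not exist -- use
#' \code{\link{limit_homogeneous}}.
#'
#' @param spec a \code{network_spec}.
#' @param mf optional \code{mean_field_state} (for the variances a).
#' @return named covariance vector (EE, EI, II, EX, IX).
#' @export
limit_inhomogeneous <- function(spec, mf = NULL) {
  sk <- structural_kappa(spec)
  dt <- det(sk$local)
  if (abs(dt) < 1e-10 * max(abs(sk$local))^2) {
    ev <- eigen(sk$local, only.values = TRUE)$values
    stop(sprintf(
      "local coupling matrix is singular (eigenvalue %s ~ 0): homogeneous connectivity; use limit_homogeneous()",
      format(ev[which.min(abs(ev))], digits = 4)))
  }
  if (is.null(mf)) mf <- solve_mean_field(spec)
  a_x <- if (spec$external_mode == "dc") 0 else spec$m_X * (1 - spec$m_X)
  u <- solve(sk$local, sk$x)
  s <- a_x / spec$N["X"]
  c(EE = unname(u[1]^2 * s - mf$a["E"] / spec$N["E"]),
    EI = unname(u[1] * u[2] * s),
    II = unname(u[2]^2 * s - mf$a["I"] / spec$N["I"]),
    EX = unname(-u[1] * s),
    IX = unname(-u[2] * s))
}

is_homogeneous_connectivity <- function(spec, tol = 1e-12) {
  all(abs(spec$K["E", ] * spec$J["E", ] - spec$K["I", ] * spec$J["I", ]) <=
        tol * max(1, max(abs(spec$K * spec$J))))
}

#' Leading-order covariances for homogeneous (degenerate) connectivity
#'
#' When synaptic weights depend only on the type of the sending neuron, the
#' local coupling matrix has linearly dependent rows and a zero eigenvalue;
#' the invertible-connectivity limit does not apply. Writing
#' \eqn{\kappa_\beta = K_\beta J_\beta} and
#' \eqn{\kappa_L = \kappa_E + \kappa_I < 0}, the covariance structure for
#' large networks is, to leading order,
#' \deqn{d = -\frac{\kappa_E a_E/N_E - \kappa_I a_I/N_I}{\kappa_L}, \quad
#'  c_{EI} = -\frac{1}{\kappa_L}\left[\frac{(\kappa_E-\kappa_I)d}{2}
#'  - \frac{\kappa_X^2 a_X}{\kappa_L N_X}
#'  + \frac{\kappa_E a_E/N_E + \kappa_I a_I/N_I}{2}\right],}
#' with \eqn{c_{EE} = c_{EI} + d}, \eqn{c_{II} = c_{EI} - d},
#' \eqn{c_{EX} = c_{IX} = -(\kappa_X/\kappa_L)\, a_X/N_X}. External and
#' intrinsic contributions both scale as \eqn{1/N}; the equidistant splitting
#' \eqn{d} between the three local covariances is purely intrinsic, so the
#' relative differences persist at all network sizes. All susceptibilities
#' have cancelled: only structural parameters remain.
#'
#' @inheritParams limit_inhomogeneous
#' @return named covariance vector with attributes \code{external} and
#'   \code{intrinsic} (the two additive parts).
#' @export
limit_homogeneous <- function(spec, mf = NULL) {
  if (!is_homogeneous_connectivity(spec, tol = 1e-9))
    stop("connectivity is not homogeneous (weights must depend only on the source type)")
  if (is.null(mf)) mf <- solve_mean_field(spec)
  sk <- structural_kappa(spec)
  kE <- sk$local["E", "E"]; kI <- sk$local["E", "I"]; kX <- sk$x["E"]
  kL <- kE + kI
  if (abs(kL) < 1e-12) stop("kappa_E + kappa_I = 0: doubly degenerate coupling")
  a_x <- if (spec$external_mode == "dc") 0 else spec$m_X * (1 - spec$m_X)
  gE <- mf$a["E"] / spec$N["E"]; gI <- mf$a["I"] / spec$N["I"]
  d <- -(kE * gE - kI * gI) / kL
  ext_unif <- unname(kX^2 * a_x / (kL^2 * spec$N["X"]))
  int_EI <- unname(-((kE - kI) * d / 2 + (kE * gE + kI * gI) / 2) / kL)
  cEI <- ext_unif + int_EI
  cX <- unname(-(kX / kL) * a_x / spec$N["X"])
  out <- c(EE = unname(cEI + d), EI = unname(cEI), II = unname(cEI - d),
           EX = cX, IX = cX)
  attr(out, "external") <- c(EE = ext_unif, EI = ext_unif, II = ext_unif,
                             EX = cX, IX = cX)
  attr(out, "intrinsic") <- c(EE = unname(int_EI + d), EI = int_EI,
                              II = unname(int_EI - d), EX = 0, IX = 0)
  out
}

#' Covariance structure implied by perfect tracking of the external drive
#'
#' If the population-averaged local activity perfectly tracked the external
#' signal, the fluctuation of the compound input would vanish and the local
#' populations would follow the external population with gain
#' \eqn{u = -\kappa_X/\kappa_L}. The implied covariances are
#' \deqn{c_{\alpha\beta} = u^2 \frac{a_X}{N_X}
#'  - \delta_{\alpha\beta} \frac{a_\alpha}{N_\alpha}, \qquad
#'  c_{\alpha X} = u\,\frac{a_X}{N_X}.}
#' By construction this structure satisfies the input-correlation
#' cancellation identity exactly (the variance of the population-averaged
#' input is zero), yet it misses the intrinsically generated contribution and
#' therefore differs from the finite-size solution: cancellation constrains
#' but does not determine the correlation structure. Provided for comparison
#' on homogeneous-connectivity networks, where tracking is in fact weak
#' because of the feedback-free eigendirection.
#'
#' @inheritParams limit_inhomogeneous
#' @return named covariance vector (EE, EI, II, EX, IX) with attribute
#'   \code{tracking_gain}.
#' @export
fast_tracking_prediction <- function(spec, mf = NULL) {
  if (!is_homogeneous_connectivity(spec, tol = 1e-9))
    stop("fast-tracking comparison is defined for homogeneous connectivity")
  if (is.null(mf)) mf <- solve_mean_field(spec)
  sk <- structural_kappa(spec)
  kL <- sk$local["E", "E"] + sk$local["E", "I"]
  u <- -sk$x["E"] / kL
  a_x <- if (spec$external_mode == "dc") 0 else spec$m_X * (1 - spec$m_X)
  s <- a_x / spec$N["X"]
  out <- c(EE = unname(u^2 * s - mf$a["E"] / spec$N["E"]),
           EI = unname(u^2 * s),
           II = unname(u^2 * s - mf$a["I"] / spec$N["I"]),
           EX = unname(u * s), IX = unname(u * s))
  attr(out, "tracking_gain") <- unname(u)
  out
}

#' Rescale a network specification along a size ladder
#'
#' Scales the three population sizes by \code{factor}. Under
#' \code{mode = "fixed_p"} the in-degrees grow proportionally (constant
#' connection probability, the strong-coupling ladder on which the effective
#' couplings grow as \eqn{\sqrt{N}}); under \code{mode = "fixed_K"} the
#' in-degrees stay constant. If \code{m_target} is given, thresholds are
#' re-derived so that the target activity is the exact mean-field fixed
#' point at the new size.
#'
#' @param spec a \code{network_spec}.
#' @param factor size multiplier.
#' @param mode \code{"fixed_p"} or \code{"fixed_K"}.
#' @param m_target optional activity at which to re-balance thresholds.
#' @return a rescaled \code{network_spec}.
#' @export
scale_spec <- function(spec, factor, mode = c("fixed_p", "fixed_K"),
                       m_target = NULL) {
  mode <- match.arg(mode)
  N <- spec$N * factor
  K <- if (mode == "fixed_p") spec$K * factor else spec$K
  out <- network_spec(N = N, K = K, J = spec$J, theta = spec$theta,
                      tau = spec$tau, m_X = spec$m_X,
                      external_mode = spec$external_mode,
                      indegree_rule = spec$indegree_rule)
  if (!is.null(m_target)) out <- rebalance_threshold(out, m_target)
  out
}

#' Derive thresholds placing the mean-field fixed point at a target activity
#'
#' Sets \eqn{\theta_\alpha = \mu_\alpha(m^*) - \sigma_\alpha(m^*)
#' \Phi^{-1}(m^*)}, which makes \eqn{m_E = m_I = m^*} an exact solution of
#' the self-consistency equation. With \eqn{m^* = 1/2} this coincides with
#' the balance condition \eqn{\theta = \mu}.
#'
#' @param spec a \code{network_spec}.
#' @param m_target desired mean activity in (0, 1).
#' @return the spec with updated thresholds.
#' @export
rebalance_threshold <- function(spec, m_target) {
  m <- c(E = m_target, I = m_target)
  mu <- mean_input(spec, m)
  sig <- sqrt(pmax(input_variance(spec, m), 0))
  spec$theta <- mu - sig * stats::qnorm(m_target)
  names(spec$theta) <- c("E", "I")
  spec
}

#' Covariance decomposition along a network-size ladder
#'
#' Evaluates \code{\link{decompose_contributions}} on geometrically scaled
#' copies of a base network and fits log-log slopes of the external and
#' intrinsic contributions against the network size, per covariance label.
#'
#' @param spec base \code{network_spec}.
#' @param factors size multipliers (default powers of two).
#' @param mode ladder convention, see \code{\link{scale_spec}}.
#' @param m_target thresholds are re-balanced to this activity on each rung
#'   (default: keep the base working activity).
#' @param self_term passed to \code{\link{decompose_contributions}}.
#' @return list with the per-rung table (data.frame) and fitted slopes.
#' @export
n_ladder <- function(spec, factors = 2^(0:6), mode = "fixed_p",
                     m_target = NULL, self_term = "external") {
  if (is.null(m_target)) m_target <- mean(solve_mean_field(spec)$m)
  rows <- lapply(factors, function(f) {
    sp <- scale_spec(spec, f, mode = mode, m_target = m_target)
    dec <- decompose_contributions(sp, self_term = self_term)
    data.frame(factor = f, N = unname(sp$N["E"] + sp$N["I"]),
               label = names(dec$full), full = unname(dec$full),
               external = unname(dec$external), intrinsic = unname(dec$intrinsic))
  })
  tab <- do.call(rbind, rows)
  fit_slope <- function(y, N) {
    ok <- abs(y) > 0
    if (sum(ok) < 3) return(NA_real_)
    stats::coef(stats::lm(log(abs(y[ok])) ~ log(N[ok])))[2]
  }
  slopes <- do.call(rbind, lapply(split(tab, tab$label), function(d)
    data.frame(label = d$label[1],
               slope_external = fit_slope(d$external, d$N),
               slope_intrinsic = fit_slope(d$intrinsic, d$N),
               slope_full = fit_slope(d$full, d$N))))
  list(table = tab, slopes = slopes)
}

#' Sweep the structural connectivity parameters
#'
#' Starting from a homogeneous base network with structural couplings
#' \eqn{\kappa_E = K_E J_E > 0} and \eqn{\kappa_I = K_I J_I < 0}, constructs
#' a family of networks in which either the eigenvalue \emph{shift} is swept
#' (\eqn{\kappa_{EE} = \kappa_E + \delta}, \eqn{\kappa_{II} = \kappa_I +
#' \delta}, off-diagonals fixed: both eigenvalues translate rigidly,
#' \eqn{\delta \in [-\kappa_E, 0]}, reaching vanishing excitatory
#' self-coupling on the left and degenerate rows on the right) or the
#' \emph{split} is swept (\eqn{\kappa_{EE} = t\kappa_E}, \eqn{\kappa_{II} =
#' t\kappa_I}, \eqn{t \in [0, 1]}: the discriminant crosses zero and the
#' real pair merges into a complex-conjugate pair; at \eqn{t = 0} only
#' cross-coupling remains, the oscillatory PING configuration). At every grid
#' point the thresholds are re-derived from the balance condition for the
#' target activity, the mean field and covariances are re-solved, and the
#' spectrum is recorded; unstable grid points are skipped with a reason.
#'
#' @param spec homogeneous base \code{network_spec}.
#' @param parameter \code{"shift"} or \code{"split"}.
#' @param grid parameter values (defaults to an evenly spaced grid over the
#'   admissible range).
#' @param n_points grid size when \code{grid} is NULL.
#' @param m_target activity at which thresholds are re-balanced.
#' @return data.frame with one row per admissible grid point: parameter
#'   value, structural eigenvalues (real and imaginary parts), effective
#'   eigenvalues, activities, and the five covariances; skipped points are
#'   reported in attribute \code{skipped}.
#' @export
structural_sweep <- function(spec, parameter = c("shift", "split"),
                             grid = NULL, n_points = 9, m_target = 0.5) {
  parameter <- match.arg(parameter)
  if (!is_homogeneous_connectivity(spec, tol = 1e-9))
    stop("structural sweep requires a homogeneous base network")
  sk <- structural_kappa(spec)
  kE <- sk$local["E", "E"]; kI <- sk$local["E", "I"]
  if (is.null(grid)) {
    grid <- if (parameter == "shift") seq(-kE, 0, length.out = n_points)
            else seq(0, 1, length.out = n_points)
  }
  rows <- list(); skipped <- list()
  for (g in grid) {
    sp <- spec
    if (parameter == "shift") {
      sp$J["E", "E"] <- (kE + g) / sp$K["E", "E"]
      sp$J["I", "I"] <- (kI + g) / sp$K["I", "I"]
    } else {
      sp$J["E", "E"] <- g * kE / sp$K["E", "E"]
      sp$J["I", "I"] <- g * kI / sp$K["I", "I"]
    }
    sp <- rebalance_threshold(sp, m_target)
    res <- try({
      mf <- solve_mean_field(sp)
      eff <- effective_couplings(sp, mf)
      spc <- spectrum(eff)
      if (!spc$stable) stop(sprintf("unstable: max Re(lambda) = %.4f",
                                    max(Re(spc$eigenvalues))))
      cs <- solve_correlations(sp, mf)
      kmat <- (sp$K * sp$J)[, c("E", "I")]
      nu <- spectrum(kmat)
      data.frame(parameter = g,
                 m_E = mf$m["E"], m_I = mf$m["I"],
                 re_lambda1 = Re(spc$eigenvalues[1]), re_lambda2 = Re(spc$eigenvalues[2]),
                 im_lambda1 = Im(as.complex(spc$eigenvalues))[1],
                 re_nu1 = Re(nu$eigenvalues[1]), re_nu2 = Re(nu$eigenvalues[2]),
                 im_nu1 = Im(as.complex(nu$eigenvalues))[1],
                 nu_split = nu$split, nu_det = nu$det,
                 oscillatory = spc$oscillatory,
                 c_EE = cs$c_EE, c_EI = cs$c_EI, c_II = cs$c_II,
                 c_EX = cs$c_EX, c_IX = cs$c_IX, row.names = NULL)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      skipped[[length(skipped) + 1]] <- data.frame(parameter = g,
                                                   reason = attr(res, "condition")$message)
    } else rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "parameter") <- parameter
  out
}
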