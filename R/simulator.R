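#' Configuration of a binary-network simulation
#'
#' @param duration total simulated time (same units as \code{tau}).
#' @param resolution time-grid step \code{dt}; defaults to \code{tau/100} of
#'   the simulated network.
#' @param delay synaptic transmission delay in grid steps (>= 1). Zero-lag
#'   covariances in the stationary state are insensitive to small delays.
#' @param measurement_interval interval at which network state is sampled for
#'   statistics; must be a multiple of \code{resolution}; defaults to the
#'   resolution itself.
#' @param seed integer seed for the dynamics (update times, stochastic gains,
#'   initial state).
#' @param transient initial stretch of time discarded from all statistics;
#'   defaults to \code{50 * tau}.
#' @return object of class \code{simulator_config}.
#' @export
simulator_config <- function(duration, resolution = NULL, delay = 1L,
                             measurement_interval = NULL, seed = 1L,
                             transient = NULL) {
  structure(list(duration = duration, resolution = resolution,
                 delay = as.integer(delay),
                 measurement_interval = measurement_interval,
                 seed = as.integer(seed), transient = transient),
            class = "simulator_config")
}

resolve_config <- function(config, spec) {
  tau <- spec$tau
  dt <- if (is.null(config$resolution)) tau / 100 else config$resolution
  if (dt <= 0) stop("resolution must be positive")
  meas <- if (is.null(config$measurement_interval)) dt else config$measurement_interval
  transient <- if (is.null(config$transient)) 50 * tau else config$transient
  if (config$delay < 1L) stop("delay must be at least one grid step")
  if (transient >= config$duration)
    stop("duration must exceed the transient")
  meas_every <- meas / dt
  if (abs(meas_every - round(meas_every)) > 1e-8)
    stop("measurement_interval must be a multiple of the resolution")
  list(dt = dt, meas = meas, transient = transient,
       n_steps = as.integer(round(config$duration / dt)),
       transient_steps = as.integer(round(transient / dt)),
       meas_every = as.integer(round(meas_every)),
       delay = config$delay, seed = config$seed, tau_steps = tau / dt)
}

#' Simulate the asynchronous binary-neuron dynamics
#'
#' Runs the stochastic dynamics of a concrete network realization: every
#' neuron is updated at independent Poisson time points with rate
#' \eqn{1/\tau}; upon update a local neuron becomes active iff its delayed
#' summed synaptic input exceeds its threshold, and an external source becomes
#' active with probability \eqn{m_X}. In \code{dc} external mode the external
#' sources are not simulated; each local neuron instead receives the constant
#' input \eqn{K_{\alpha X} J_{\alpha X} m_X}.
#'
#' @param real a \code{network_realization}.
#' @param config a \code{simulator_config}.
#' @param record_states if TRUE, the binary state of every neuron (including
#'   external sources) is stored at each measurement bin. Intended for small
#'   networks; large runs should instead pass \code{pairs} and use the
#'   streaming statistics.
#' @param pairs optional integer matrix (n x 2) of global neuron indices
#'   (1-based) whose zero-lag coincidences are accumulated on the fly, e.g.
#'   from \code{\link{sample_pairs}}.
#' @param init optional named vector \code{c(E=, I=)} of initial activation
#'   probabilities (warm start); defaults to the mean-field solution.
#' @return object of class \code{activity_record}.
#' @export
simulate_network <- function(real, config, record_states = FALSE,
                             pairs = NULL, init = NULL) {
  spec <- real$spec
  rc <- resolve_config(config, spec)
  n_e <- as.integer(spec$N["E"]); n_i <- as.integer(spec$N["I"])
  n_local <- n_e + n_i
  dc <- spec$external_mode == "dc"
  n_x <- if (dc) 0L else as.integer(spec$N["X"])

  ptr <- real$ptr; src <- real$src; w <- real$w
  if (dc) { # drop external edges: X sources are replaced by a constant
    keep <- src <= n_local
    len <- as.integer(tabulate(rep(seq_len(n_local), diff(ptr))[keep], n_local))
    ptr <- c(0L, cumsum(len)); src <- src[keep]; w <- w[keep]
  }
  pops <- rep(c("E", "I"), times = c(n_e, n_i))
  theta <- spec$theta[pops]
  dc_offset <- if (dc) spec$K[pops, "X"] * spec$J[pops, "X"] * spec$m_X
               else numeric(n_local)

  if (is.null(init)) {
    mf <- try(solve_mean_field(spec), silent = TRUE)
    init <- if (inherits(mf, "try-error")) c(E = 0.5, I = 0.5) else mf$m
  }
  p_init <- c(rep(init["E"], n_e), rep(init["I"], n_i), rep(spec$m_X, n_x))

  pair_mat <- if (is.null(pairs)) matrix(integer(0), 0, 2) else {
    pm <- as.matrix(pairs)[, 1:2, drop = FALSE]
    if (any(pm < 1 | pm > n_local + n_x))
      stop("pair indices outside the simulated network (dc mode has no external sources)")
    pm
  }

  res <- withr_seed(rc$seed, .simulate_binary_network(
    n_e, n_i, n_x,
    in_ptr = ptr, in_src = as.integer(src - 1L), in_w = w,
    theta = as.numeric(theta), dc_offset = as.numeric(dc_offset),
    m_x = spec$m_X, tau_steps = rc$tau_steps,
    n_steps = rc$n_steps, transient_steps = rc$transient_steps,
    meas_every = rc$meas_every, delay_steps = rc$delay,
    p_init = as.numeric(p_init),
    pairs = matrix(as.integer(pair_mat - 1L), ncol = 2),
    record_states = record_states))

  structure(list(
    spec = spec, seed = rc$seed,
    n_bins = res$n_bins,
    dt = rc$dt, measurement_interval = rc$meas, duration = config$duration,
    transient = rc$transient, delay_steps = rc$delay,
    n_neurons = n_local + n_x, n_external = n_x,
    population = c(pops, rep("X", n_x)),
    neuron_mean = res$neuron_sum / res$n_bins,
    pop_activity = sweep(res$pop_sums, 2, pmax(c(n_e, n_i, max(n_x, 1L)), 1L), "/"),
    pairs = if (nrow(pair_mat)) pair_mat else NULL,
    pair_labels = attr(pairs, "label"),
    pair_prod_mean = if (nrow(pair_mat)) res$pair_prod / res$n_bins else NULL,
    states = res$states), class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf(
    "Binary-network activity record: %d neurons (%d external), %d bins of %g\n",
    x$n_neurons, x$n_external, x$n_bins, x$measurement_interval))
  m <- activity_means(x)
  cat(sprintf("  mean activity: m_E = %.4f, m_I = %.4f%s\n", m["E"], m["I"],
              if (x$n_external > 0) sprintf(", m_X = %.4f", m["X"]) else ""))
  invisible(x)
}

#' Population-averaged mean activities of a record
#'
#' @param record an \code{activity_record}.
#' @return named vector of time- and population-averaged activities.
#' @export
activity_means <- function(record) {
  out <- c(E = mean(record$pop_activity[, 1]),
           I = mean(record$pop_activity[, 2]))
  if (record$n_external > 0) out <- c(out, X = mean(record$pop_activity[, 3]))
  out
}

#' Generate independent external source activity
#'
#' Reference implementation of the external-population dynamics used by the
#' simulator: each source is an independent two-state process updated at
#' Poisson times with rate \eqn{1/\tau}, becoming active with probability
#' \code{m_x} at every update, so its stationary mean is \code{m_x} and
#' distinct sources are uncorrelated.
#'
#' @param n number of sources.
#' @param m_x activation probability per update.
#' @param tau mean inter-update interval.
#' @param config a \code{simulator_config} (duration, measurement grid, seed).
#' @return binary matrix, measurement bins x sources.
#' @export
generate_external_activity <- function(n, m_x, tau, config) {
  if (m_x < 0 || m_x > 1) stop("m_x must lie in [0, 1]")
  dt <- if (is.null(config$resolution)) tau / 100 else config$resolution
  meas <- if (is.null(config$measurement_interval)) dt else config$measurement_interval
  times <- seq(0, config$duration, by = meas)
  withr_seed(config$seed, {
    out <- matrix(0L, length(times), n)
    for (s in seq_len(n)) {
      tu <- cumsum(stats::rexp(ceiling(3 * config$duration / tau) + 25, 1 / tau))
      while (tu[length(tu)] < config$duration)
        tu <- c(tu, tu[length(tu)] + cumsum(stats::rexp(25, 1 / tau)))
      vals <- c(stats::rbinom(1, 1, m_x), stats::rbinom(length(tu), 1, m_x))
      out[, s] <- vals[findInterval(times, tu) + 1L]
    }
    out
  })
}

#' Hard-threshold gain of a binary neuron
#'
#' The Heaviside activation used by the dynamics: active iff the summed input
#' strictly exceeds the threshold (H(0) = 0).
#'
#' @param h summed synaptic input.
#' @param theta threshold.
#' @return 0/1 numeric of the same length as \code{h}.
#' @export
gain_heaviside <- function(h, theta) {
  as.numeric(h > theta)
}
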