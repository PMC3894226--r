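pair_label_pops <- list(EE = c("E", "E"), EI = c("E", "I"), II = c("I", "I"),
                        EX = c("E", "X"), IX = c("I", "X"))

#' Sample disjoint neuron pairs per population-pair label
#'
#' Draws \code{n_pairs} pairs for each requested label. Pairs are disjoint
#' (no neuron appears twice within a label), which keeps the pair estimates
#' weakly dependent so that the standard error across pairs is meaningful.
#' If a population is too small the count is clamped with a warning.
#'
#' @param spec a \code{network_spec}.
#' @param n_pairs pairs per label.
#' @param seed RNG seed for the pair sampling stream.
#' @param labels subset of EE, EI, II, EX, IX.
#' @return integer matrix (total pairs x 2) of global neuron indices with a
#'   \code{label} attribute.
#' @export
sample_pairs <- function(spec, n_pairs = 1000, seed = 1,
                         labels = c("EE", "EI", "II", "EX", "IX")) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  off <- population_offsets(spec)
  if (spec$external_mode == "dc") labels <- setdiff(labels, c("EX", "IX"))
  withr_seed(seed, {
    rows <- list(); labs <- character(0)
    for (lb in labels) {
      pp <- pair_label_pops[[lb]]
      if (pp[1] == pp[2]) {
        n_avail <- floor(spec$N[pp[1]] / 2)
        n <- min(n_pairs, n_avail)
        if (n < n_pairs) warning(sprintf("label %s: only %d disjoint pairs available", lb, n))
        if (n < 1) next
        pick <- sample.int(spec$N[pp[1]], 2 * n) + off[pp[1]]
        m <- cbind(pick[seq_len(n)], pick[n + seq_len(n)])
      } else {
        n <- min(n_pairs, spec$N[pp[1]], spec$N[pp[2]])
        if (n < n_pairs) warning(sprintf("label %s: only %d disjoint pairs available", lb, n))
        if (n < 1) next
        m <- cbind(sample.int(spec$N[pp[1]], n) + off[pp[1]],
                   sample.int(spec$N[pp[2]], n) + off[pp[2]])
      }
      rows[[lb]] <- m
      labs <- c(labs, rep(lb, nrow(m)))
    }
    out <- do.call(rbind, rows)
    storage.mode(out) <- "integer"
    attr(out, "label") <- labs
    out
  })
}

per_pair_covariances <- function(record, pairs = NULL) {
  if (is.null(pairs)) {
    if (is.null(record$pairs))
      stop("record carries no pair statistics; pass pairs= or record states")
    prod_mean <- record$pair_prod_mean
    pairs <- record$pairs
    labs <- record$pair_labels
  } else {
    if (is.null(record$states))
      stop("record has no stored states; rerun with record_states = TRUE")
    S <- record$states
    prod_mean <- colMeans(S[, pairs[, 1], drop = FALSE] *
                          S[, pairs[, 2], drop = FALSE])
    labs <- attr(pairs, "label")
  }
  m <- record$neuron_mean
  cov <- prod_mean - m[pairs[, 1]] * m[pairs[, 2]]
  list(cov = cov, label = labs, pairs = pairs)
}

#' Empirical population-averaged pairwise covariances
#'
#' Estimates, from post-transient measurement bins, the mean activity and
#' population-averaged single-neuron variance of each population, and the
#' zero-lag covariance \eqn{\langle \delta n_i \delta n_j \rangle} averaged
#' over disjoint neuron pairs for each label (EE, EI, II, EX, IX). The
#' covariance of each pair uses the plug-in estimator (time average of the
#' product minus the product of the per-neuron time means over the same
#' window); the standard error is taken across pairs, which dominates the
#' uncertainty.
#'
#' @param record an \code{activity_record}. If it was produced with a
#'   streaming pair list (\code{pairs=} in \code{\link{simulate_network}}),
#'   those accumulators are used; otherwise pairs are sampled here and
#'   evaluated against the stored states.
#' @param n_pairs pairs per label when sampling here.
#' @param seed pair-sampling seed.
#' @return object of class \code{empirical_statistics}.
#' @export
pairwise_covariances <- function(record, n_pairs = 1000, seed = 1) {
  if (record$n_bins < 2) stop("empty post-transient measurement window")
  pairs <- NULL
  if (is.null(record$pairs))
    pairs <- sample_pairs(record$spec, n_pairs, seed)
  pc <- per_pair_covariances(record, pairs)
  pop <- record$population
  mean_activity <- tapply(record$neuron_mean, pop, mean)
  a_hat <- tapply(record$neuron_mean * (1 - record$neuron_mean), pop, mean)
  lev <- unique(pc$label)
  est <- t(vapply(lev, function(lb) {
    v <- pc$cov[pc$label == lb]
    c(value = mean(v), se = stats::sd(v) / sqrt(length(v)), n_pairs = length(v))
  }, numeric(3)))
  structure(list(
    mean_activity = mean_activity,
    variance = a_hat,
    covariance = est[, "value"],
    se = est[, "se"],
    n_pairs = est[, "n_pairs"],
    per_pair = pc,
    n_bins = record$n_bins), class = "empirical_statistics")
}

#' @export
print.empirical_statistics <- function(x, ...) {
  cat("Empirical statistics (", x$n_bins, " bins)\n", sep = "")
  cat("  mean activity: ", paste(sprintf("%s=%.4f", names(x$mean_activity),
                                         x$mean_activity), collapse = ", "), "\n")
  tab <- cbind(covariance = x$covariance, se = x$se, n_pairs = x$n_pairs)
  print(signif(tab, 4))
  invisible(x)
}

neuron_input_trace <- function(record, real, i) {
  ns <- neuron_sources(real, i)
  S <- record$states
  pop <- record$population
  split_by <- split(seq_along(ns$src), pop[ns$src])
  tot <- numeric(record$n_bins)
  parts <- list(E = numeric(record$n_bins), I = numeric(record$n_bins),
                X = numeric(record$n_bins))
  for (cl in names(split_by)) {
    idx <- split_by[[cl]]
    parts[[cl]] <- as.numeric(S[, ns$src[idx], drop = FALSE] %*% ns$w[idx])
    tot <- tot + parts[[cl]]
  }
  list(total = tot, E = parts$E, I = parts$I, X = parts$X, sources = ns)
}

#' Empirical decomposition of the input covariance of neuron pairs
#'
#' For each sampled pair of local neurons, the covariance between their
#' summed synaptic inputs is decomposed exactly into the contribution of
#' afferents the two neurons share and the contribution of correlations
#' between their distinct afferents, each further split into local and
#' external parts. The decomposition is algebraic (bilinearity of the
#' covariance), so shared + correlation components reproduce the directly
#' measured input covariance to accumulation tolerance.
#'
#' @param record an \code{activity_record} with stored states.
#' @param real the generating \code{network_realization} (identifies shared
#'   afferents).
#' @param pairs integer matrix (n x 2) of local neuron indices.
#' @return list with per-pair component matrix and pair-averaged components:
#'   shared/corr x local/external, the measured total, and the maximal
#'   decomposition residual.
#' @export
input_correlation_components_empirical <- function(record, real, pairs) {
  if (is.null(record$states)) stop("record has no stored states")
  S <- record$states
  B <- nrow(S)
  m <- record$neuron_mean
  v <- m * (1 - m)  # exact time variance of a binary trace
  pop <- record$population
  comp <- matrix(0, nrow(pairs), 6,
                 dimnames = list(NULL, c("shared_local", "shared_external",
                                         "corr_local", "corr_external",
                                         "total", "residual")))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    ti <- neuron_input_trace(record, real, i)
    tj <- neuron_input_trace(record, real, j)
    cov_t <- function(x, y) mean(x * y) - mean(x) * mean(y)
    total <- cov_t(ti$total, tj$total)
    loc_i <- ti$E + ti$I; loc_j <- tj$E + tj$I
    cov_loc <- cov_t(loc_i, loc_j)
    sh <- intersect(ti$sources$src, tj$sources$src)
    shared_local <- shared_external <- 0
    if (length(sh)) {
      wi <- ti$sources$w[match(sh, ti$sources$src)]
      wj <- tj$sources$w[match(sh, tj$sources$src)]
      ext <- pop[sh] == "X"
      shared_local <- sum((wi * wj * v[sh])[!ext])
      shared_external <- sum((wi * wj * v[sh])[ext])
    }
    corr_local <- cov_loc - shared_local
    corr_external <- total - cov_loc - shared_external
    comp[r, ] <- c(shared_local, shared_external, corr_local, corr_external,
                   total,
                   (shared_local + shared_external + corr_local + corr_external) - total)
  }
  list(per_pair = comp,
       mean = colMeans(comp[, 1:5, drop = FALSE]),
       shared = mean(comp[, 1] + comp[, 2]),
       corr = mean(comp[, 3] + comp[, 4]),
       total = mean(comp[, 5]),
       max_residual = max(abs(comp[, 6])))
}

#' Identity linking population-average variance to pairwise covariances
#'
#' For any set of signals \eqn{x_i, i = 1..N}, the variance of the population
#' average \eqn{\bar x} satisfies the algebraic identity
#' \deqn{\mathrm{Var}(\bar x) = \frac{\bar a}{N} +
#'   \left(1 - \frac{1}{N}\right) \bar c,}
#' with \eqn{\bar a} the average single-signal variance and \eqn{\bar c} the
#' average covariance over all distinct pairs. Computes both sides from the
#' same sample window -- the left from the population-averaged trace, the
#' right from per-neuron variances plus pair covariances (exhaustively
#' enumerated by default, or from a supplied pair subsample) -- and returns
#' the residual, which is exactly zero under exhaustive enumeration and
#' within pair-sampling error otherwise. This identity is why suppressed
#' fluctuations of the population-averaged input are equivalent to the
#' cancellation of pairwise input correlations.
#'
#' @param record an \code{activity_record} with stored states.
#' @param population which population to test.
#' @param pairs optional pair matrix for subsampled evaluation.
#' @return list with \code{lhs}, \code{rhs}, \code{residual}, \code{a_bar},
#'   \code{c_bar}, \code{n}.
#' @export
population_average_identity_check <- function(record, population = "E",
                                              pairs = NULL) {
  if (is.null(record$states)) stop("record has no stored states")
  idx <- which(record$population == population)
  N <- length(idx)
  S <- record$states[, idx, drop = FALSE]
  B <- nrow(S)
  xbar <- rowMeans(S)
  lhs <- mean(xbar^2) - mean(xbar)^2
  m <- colMeans(S)
  a_bar <- mean(m * (1 - m))
  if (is.null(pairs)) {
    # exhaustive: all distinct pairs via the cross-moment matrix
    M <- crossprod(S) / B - tcrossprod(m)
    c_bar <- (sum(M) - sum(diag(M))) / (N * (N - 1))
  } else {
    pc <- per_pair_covariances(record, pairs)
    c_bar <- mean(pc$cov)
  }
  rhs <- a_bar / N + (1 - 1 / N) * c_bar
  list(lhs = lhs, rhs = rhs, residual = lhs - rhs,
       a_bar = a_bar, c_bar = c_bar, n = N)
}
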