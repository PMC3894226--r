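#' Specify a three-population binary-neuron network
#'
#' Defines the parameterization of a recurrent network of two local
#' populations -- excitatory (\code{E}) and inhibitory (\code{I}) -- driven by
#' a finite external population (\code{X}) of pairwise-uncorrelated binary
#' sources. Neurons are binary units with a hard activation threshold
#' \eqn{\theta}; each neuron is updated at Poisson time points with mean
#' inter-update interval \eqn{\tau}. The local connectivity is a random graph
#' in which every neuron in population \eqn{\alpha} receives \eqn{K_{\alpha\beta}}
#' inputs of weight \eqn{J_{\alpha\beta}} from population \eqn{\beta}, either
#' exactly (\code{indegree_rule = "fixed"}) or binomially distributed with
#' connection probability \eqn{p_{\alpha\beta} = K_{\alpha\beta}/N_\beta}
#' (\code{indegree_rule = "binomial"}).
#'
#' The size \eqn{N_X} of the external population controls the amount of
#' shared external input: two local neurons drawing \eqn{K_{\alpha X}} sources
#' each from the pool of \eqn{N_X} share \eqn{K^2_{\alpha X}/N_X} of them on
#' average. With \eqn{K_{\alpha X} = N_X} all local neurons receive identical
#' external input. In \code{external_mode = "dc"} the fluctuating external
#' drive is replaced by its constant mean \eqn{K_{\alpha X} J_{\alpha X} m_X},
#' which contributes to the mean input but not to any variance or covariance.
#'
#' @param N named integer vector \code{c(E=, I=, X=)} of population sizes.
#' @param K 2x3 in-degree matrix, rows \code{E,I} (targets), columns
#'   \code{E,I,X} (sources).
#' @param J 2x3 synaptic weight matrix, same layout as \code{K}.
#' @param theta named numeric \code{c(E=, I=)} activation thresholds. Negative
#'   thresholds make neurons intrinsically active without excitatory input.
#' @param tau mean inter-update interval (time units).
#' @param m_X stationary mean activity of each external source, in [0, 1].
#' @param external_mode \code{"stochastic"} (binary external sources) or
#'   \code{"dc"} (external drive replaced by its constant mean).
#' @param indegree_rule \code{"fixed"} or \code{"binomial"}.
#' @param p optional 2x3 matrix of connection probabilities; defaults to
#'   \code{K/N} per source column. Required semantics for the binomial rule.
#' @return an object of class \code{network_spec}.
#' @export
network_spec <- function(N, K, J, theta, tau = 10, m_X = 0.1,
                         external_mode = c("stochastic", "dc"),
                         indegree_rule = c("fixed", "binomial"),
                         p = NULL) {
  external_mode <- match.arg(external_mode)
  indegree_rule <- match.arg(indegree_rule)
  N <- as_named(N, c("E", "I", "X"), "N")
  theta <- as_named(theta, c("E", "I"), "theta")
  K <- as_block_matrix(K, "K")
  J <- as_block_matrix(J, "J")
  if (is.null(p)) {
    p <- sweep(K, 2, N, "/")
  } else {
    p <- as_block_matrix(p, "p")
  }
  spec <- structure(
    list(N = N, K = K, J = J, theta = theta, tau = tau, m_X = m_X,
         external_mode = external_mode, indegree_rule = indegree_rule, p = p),
    class = "network_spec")
  validate_spec(spec)
  spec
}

as_named <- function(x, nm, what) {
  if (is.null(names(x))) {
    if (length(x) != length(nm))
      stop(sprintf("'%s' must have entries %s", what, paste(nm, collapse = ", ")))
    names(x) <- nm
  }
  x <- x[nm]
  if (anyNA(x)) stop(sprintf("'%s' must have entries %s", what, paste(nm, collapse = ", ")))
  x
}

as_block_matrix <- function(M, what) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(2L, 3L)))
    stop(sprintf("'%s' must be a 2x3 matrix (targets E,I x sources E,I,X)", what))
  dimnames(M) <- list(c("E", "I"), c("E", "I", "X"))
  M
}

#' Validate a network specification
#'
#' Checks all structural invariants: positive sizes, in-degrees not exceeding
#' source-population sizes, probabilities inside [0, 1], positive time
#' constant. Violations raise an itemized error.
#'
#' @param spec a \code{network_spec}.
#' @return the spec, invisibly.
#' @export
validate_spec <- function(spec) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (any(spec$N < 1)) add("population sizes N must be >= 1")
  if (spec$tau <= 0) add("time_constant tau must be > 0")
  if (spec$m_X < 0 || spec$m_X > 1) add("external rate m_X must lie in [0, 1]")
  if (any(spec$K < 0)) add("in-degrees K must be non-negative")
  for (tg in c("E", "I")) for (src in c("E", "I", "X")) {
    if (spec$K[tg, src] > spec$N[src])
      add(sprintf("K[%s,%s] = %d exceeds N_%s = %d",
                  tg, src, spec$K[tg, src], src, spec$N[src]))
  }
  if (spec$indegree_rule == "binomial" && (any(spec$p < 0) || any(spec$p > 1)))
    add("connection probabilities p must lie in [0, 1] for the binomial rule")
  if (length(problems))
    stop(paste(c("invalid network_spec:", paste(" -", problems)), collapse = "\n"))
  invisible(spec)
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Binary-neuron network specification\n")
  cat(sprintf("  N_E = %d, N_I = %d, N_X = %d   (tau = %g)\n",
              x$N["E"], x$N["I"], x$N["X"], x$tau))
  cat(sprintf("  external: m_X = %g, mode = %s; in-degree rule: %s\n",
              x$m_X, x$external_mode, x$indegree_rule))
  cat("  in-degrees K (target x source):\n")
  print(x$K)
  cat("  weights J:\n")
  print(x$J)
  cat(sprintf("  thresholds: theta_E = %g, theta_I = %g\n",
              x$theta["E"], x$theta["I"]))
  invisible(x)
}

# global neuron index layout: E = 1..N_E, I = N_E+1..N_E+N_I, X = rest
population_offsets <- function(spec) {
  c(E = 0L, I = as.integer(spec$N["E"]),
    X = as.integer(spec$N["E"] + spec$N["I"]))
}

#' Population membership of each neuron index
#'
#' @param spec a \code{network_spec}.
#' @return character vector of length \code{sum(N)} with entries E, I, X.
#' @export
population_index <- function(spec) {
  rep(c("E", "I", "X"), times = spec$N)
}

#' Draw a concrete random connectivity realization
#'
#' For every local target neuron and every source population, samples the set
#' of presynaptic sources uniformly without replacement (no multapses) and
#' excluding the target itself (no autapses). Under the fixed rule exactly
#' \eqn{K_{\alpha\beta}} sources are drawn; under the binomial rule the count
#' is first drawn as Binomial(\eqn{N_\beta}, \eqn{p_{\alpha\beta}}), which is
#' equivalent to independent Bernoulli edges.
#'
#' @param spec a \code{network_spec}.
#' @param seed integer seed; identical (spec, seed) give identical adjacency.
#' @return object of class \code{network_realization} with concatenated source
#'   lists in compressed (pointer) form: \code{src[ptr[i]:(ptr[i+1]-1)]} are the
#'   global indices of the afferents of local neuron \code{i}, \code{w} their
#'   weights.
#' @export
build_realization <- function(spec, seed) {
  validate_spec(spec)
  n_local <- as.integer(spec$N["E"] + spec$N["I"])
  off <- population_offsets(spec)
  withr_seed(seed, {
    srcs <- vector("list", n_local)
    ws <- vector("list", n_local)
    pops <- rep(c("E", "I"), times = spec$N[c("E", "I")])
    for (i in seq_len(n_local)) {
      tg <- pops[i]
      s_i <- integer(0); w_i <- numeric(0)
      for (src in c("E", "I", "X")) {
        Nsrc <- as.integer(spec$N[src])
        k <- as.integer(spec$K[tg, src])
        if (spec$indegree_rule == "binomial")
          k <- stats::rbinom(1L, Nsrc, spec$p[tg, src])
        if (k == 0L) next
        self <- if (src == tg) i - off[src] else 0L
        if (self > 0L) {
          if (k > Nsrc - 1L) k <- Nsrc - 1L   # cannot exceed pool minus self
          pick <- sample.int(Nsrc - 1L, k)
          pick <- ifelse(pick >= self, pick + 1L, pick)
        } else {
          pick <- sample.int(Nsrc, k)
        }
        s_i <- c(s_i, pick + off[src])
        w_i <- c(w_i, rep(spec$J[tg, src], length(pick)))
      }
      srcs[[i]] <- s_i
      ws[[i]] <- w_i
    }
    len <- lengths(srcs)
    structure(
      list(spec = spec, seed = seed,
           ptr = c(0L, cumsum(len)),
           src = as.integer(unlist(srcs, use.names = FALSE)),
           w = as.numeric(unlist(ws, use.names = FALSE))),
      class = "network_realization")
  })
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Afferent list of one neuron
#'
#' @param real a \code{network_realization}.
#' @param i local neuron index (1-based, E then I).
#' @return list with \code{src} (global indices) and \code{w} (weights).
#' @export
neuron_sources <- function(real, i) {
  idx <- seq.int(real$ptr[i] + 1L, length.out = real$ptr[i + 1L] - real$ptr[i])
  list(src = real$src[idx], w = real$w[idx])
}

#' Realized in-degree per local neuron and source population
#'
#' @param real a \code{network_realization}.
#' @return matrix (n_local x 3) of counts from E, I, X.
#' @export
realized_indegrees <- function(real) {
  spec <- real$spec
  off <- population_offsets(spec)
  n_local <- spec$N["E"] + spec$N["I"]
  pop_of <- cut(real$src, breaks = c(0, off["I"], off["X"], sum(spec$N)),
                labels = c("E", "I", "X"))
  tgt <- rep(seq_len(n_local), times = diff(real$ptr))
  tab <- table(factor(tgt, levels = seq_len(n_local)), pop_of)
  m <- matrix(as.integer(tab), nrow = n_local, dimnames = list(NULL, c("E", "I", "X")))
  m
}

#' Expected number of shared afferents from one source population
#'
#' Two local neurons drawing \eqn{K_a} and \eqn{K_b} sources independently and
#' uniformly without replacement from a pool of \eqn{N} share
#' \eqn{K_a K_b / N} of them in expectation (the mean of the hypergeometric
#' overlap). Under the binomial rule the same expression holds with
#' \eqn{K = pN}.
#'
#' @param spec a \code{network_spec}.
#' @param source source population, one of \code{"E"}, \code{"I"}, \code{"X"}.
#' @param target_a,target_b populations of the two neurons in the pair.
#' @return expected shared-source count (scalar).
#' @export
expected_shared_inputs <- function(spec, source, target_a = "E", target_b = target_a) {
  validate_spec(spec)
  Ka <- spec$K[target_a, source]
  Kb <- spec$K[target_b, source]
  N <- spec$N[source]
  unname(Ka * Kb / N)
}

#' Export a realization as an edge list
#'
#' @param real a \code{network_realization}.
#' @return data.frame with columns target (local index), source (global
#'   index), weight.
#' @export
realization_edges <- function(real) {
  n_local <- real$spec$N["E"] + real$spec$N["I"]
  data.frame(
    target = rep(seq_len(n_local), times = diff(real$ptr)),
    source = real$src,
    weight = real$w)
}
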