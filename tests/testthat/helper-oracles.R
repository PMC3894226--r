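# Shared helpers: small fixtures and independent oracles used across files.

# tiny three-population network for fast exact and simulation checks
tiny_spec <- function(N = c(E = 20, I = 20, X = 20), K = 5, m_target = 0.3,
                      J_E = 0.2, J_I = -0.8, J_X = 0.2, mode = "stochastic") {
  sp <- network_spec(
    N = N,
    K = matrix(K, 2, 3), J = matrix(rep(c(J_E, J_I, J_X), each = 2), 2, 3),
    theta = c(E = 0, I = 0), m_X = 0.2, external_mode = mode)
  rebalance_threshold(sp, m_target)
}

# Independent dense oracle for the population-averaged covariance system:
# assembles the full 5x5 linear system directly from the generic relation
#   2 c_ab = sum_g [ w_ag (c_gb + d_gb a_b/N_b) + w_bg (c_ga + d_ga a_a/N_a) ]
# over ordered label pairs, with c_XX = 0 and w_Xg = 0, and solves it with a
# single dense solve. Deliberately a different code path from the block
# solvers in the package.
dense_covariance_oracle <- function(spec, mf, a_override = NULL) {
  pops <- c("E", "I", "X")
  a <- c(mf$a[c("E", "I")], X = if (spec$external_mode == "dc") 0
         else spec$m_X * (1 - spec$m_X))
  if (!is.null(a_override)) a[names(a_override)] <- a_override
  N <- spec$N
  S <- c(mf$S, X = 0)
  w <- function(tg, src) {
    if (tg == "X") return(0)
    S[tg] * spec$K[tg, src] * spec$J[tg, src]
  }
  labels <- list(c("E", "E"), c("E", "I"), c("I", "I"), c("E", "X"), c("I", "X"))
  idx_of <- function(a1, b1) {
    for (k in seq_along(labels))
      if (setequal(c(a1, b1), labels[[k]]) &&
          sum(c(a1, b1) == "X") == sum(labels[[k]] == "X"))
        if (all(sort(c(a1, b1)) == sort(labels[[k]]))) return(k)
    NA_integer_
  }
  A <- matrix(0, 5, 5); b <- numeric(5)
  for (k in seq_along(labels)) {
    al <- labels[[k]][1]; be <- labels[[k]][2]
    A[k, k] <- A[k, k] + 2
    for (g in pops) {
      # term w_ag * (c_gb + d_gb a_b / N_b)
      if (!(g == "X" && be == "X")) {   # c_XX = 0
        j <- idx_of(g, be)
        if (!is.na(j)) A[k, j] <- A[k, j] - w(al, g)
      }
      if (g == be) b[k] <- b[k] + w(al, g) * a[be] / N[be]
      # mirror term w_bg * (c_ga + d_ga a_a / N_a)
      if (!(g == "X" && al == "X")) {
        j <- idx_of(g, al)
        if (!is.na(j)) A[k, j] <- A[k, j] - w(be, g)
      }
      if (g == al) b[k] <- b[k] + w(be, g) * a[al] / N[al]
    }
  }
  cc <- solve(A, b)
  names(cc) <- c("EE", "EI", "II", "EX", "IX")
  cc
}

# brute-force Monte-Carlo estimate of the expected overlap of two K-subsets
mc_shared_inputs <- function(N, K1, K2, n_rep = 4000) {
  mean(vapply(seq_len(n_rep), function(i)
    length(intersect(sample.int(N, K1), sample.int(N, K2))), numeric(1)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) /
              max(abs(expected), .Machine$double.eps), tol)
}
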